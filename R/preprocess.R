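#' Downsampling configuration
#'
#' Parameters of the two-step standardisation of sampling rate. Defaults
#' match the field protocol: a 60-min minimum sampling interval with
#' intermediate points retained for long (>20 m) fast movements, day-level
#' thinning triggered when a day holds more than 2 points above the dataset
#' daily average, and a target of 3-7 points per day (median 4). Navigation
#' trajectories use a finer 15-min minimum interval.
#'
#' @param min_interval_min Minimum sampling interval for space-use data
#'   (minutes).
#' @param fast_move_m Step length (metres) above which an intermediate point
#'   is retained even inside the minimum interval.
#' @param daily_excess A day is thinned when its fix count exceeds the
#'   dataset daily mean by more than this many points.
#' @param target_daily Fix count a thinned day is reduced toward.
#' @param nav_min_interval_min Minimum sampling interval for navigation
#'   trajectories (minutes).
#' @return A list of class `downsample_config`.
#' @export
downsample_config <- function(min_interval_min = 60,
                              fast_move_m = 20,
                              daily_excess = 2,
                              target_daily = 4,
                              nav_min_interval_min = 15) {
  stopifnot(fast_move_m > 0, min_interval_min > 0,
            min_interval_min > nav_min_interval_min,
            target_daily >= 1, daily_excess >= 0)
  structure(
    list(min_interval_min = min_interval_min,
         fast_move_m = fast_move_m,
         daily_excess = daily_excess,
         target_daily = target_daily,
         nav_min_interval_min = nav_min_interval_min),
    class = "downsample_config"
  )
}

# Step 1: reduce one day's fixes toward the target count with a deterministic
# greedy rule that always retains the first and last fix of the day and every
# fix annotated parental or mating, then adds the fix maximising the minimum
# time gap to already-kept fixes (earliest fix on ties).
thin_day_greedy <- function(day, target) {
  n <- nrow(day)
  keep <- rep(FALSE, n)
  keep[c(1, n)] <- TRUE
  keep[day$behavior %in% c("parental", "mating")] <- TRUE
  tt <- as.numeric(day$t)
  while (sum(keep) < min(target, n)) {
    gap <- vapply(seq_len(n), function(i) {
      if (keep[i]) return(-Inf)
      min(abs(tt[i] - tt[keep]))
    }, numeric(1))
    keep[which.max(gap)] <- TRUE
  }
  day[keep, ]
}

# Step 2: linear scan; keep a fix when at least `min_interval_min` has
# elapsed since the last kept fix OR it moved more than `fast_move_m` from
# the last kept fix. The first fix is always kept.
scan_min_interval <- function(fixes, min_interval_min, fast_move_m = Inf) {
  n <- nrow(fixes)
  if (n <= 1) return(fixes)
  keep <- logical(n)
  keep[1] <- TRUE
  last <- 1
  tt <- as.numeric(fixes$t)
  for (i in 2:n) {
    dt_min <- (tt[i] - tt[last]) / 60
    dd <- sqrt((fixes$x[i] - fixes$x[last])^2 +
                 (fixes$y[i] - fixes$y[last])^2)
    if (dt_min >= min_interval_min || dd > fast_move_m) {
      keep[i] <- TRUE
      last <- i
    }
  }
  fixes[keep, ]
}

#' Two-step downsampling of tracking data
#'
#' Standardises heterogeneous sampling rates so spatial metrics are
#' comparable across animals and datasets. Step 1 thins days whose fix count
#' exceeds the dataset daily mean by more than `daily_excess` points, keeping
#' the first and last fix of the day, all fixes with parental or mating
#' behaviour, and then the most temporally spread remaining fixes until the
#' target count is reached. Step 2 scans each animal's series in time and
#' keeps a fix only when `min_interval_min` minutes have elapsed since the
#' last kept fix, or when the animal moved more than `fast_move_m` metres
#' from the last kept fix (so long, fast movements keep their intermediate
#' points). The output is always a subset of the input rows, in time order,
#' and step 2 is idempotent.
#'
#' @param fixes A fix tibble (one or many animals).
#' @param cfg A [downsample_config()].
#' @return The downsampled fix tibble.
#' @export
downsample_two_step <- function(fixes, cfg = downsample_config()) {
  fixes <- as_fixes(fixes)
  if (nrow(fixes) <= 1) return(fixes)
  fixes$..date <- local_date(fixes$t)
  daily_n <- dplyr::count(fixes, .data$animal_id, .data$..date)
  mean_daily <- mean(daily_n$n)
  out <- fixes |>
    dplyr::group_by(.data$animal_id, .data$..date) |>
    dplyr::group_modify(function(day, key) {
      if (nrow(day) > mean_daily + cfg$daily_excess) {
        thin_day_greedy(day, cfg$target_daily)
      } else {
        day
      }
    }) |>
    dplyr::ungroup()
  out <- out[order(out$animal_id, out$t), ]
  out <- out |>
    dplyr::group_by(.data$animal_id) |>
    dplyr::group_modify(function(tr, key) {
      scan_min_interval(tr, cfg$min_interval_min, cfg$fast_move_m)
    }) |>
    dplyr::ungroup()
  out$..date <- NULL
  dplyr::relocate(out, "animal_id")
}

#' Minimum-interval downsampling (step 2 only)
#'
#' Applies only the linear-scan rule of [downsample_two_step()]: keep a fix
#' when `min_interval_min` minutes have elapsed since the last kept fix or
#' when it moved more than `fast_move_m` metres from it. Idempotent: the
#' output passes through unchanged.
#'
#' @param fixes A fix tibble (one or many animals).
#' @param min_interval_min Minimum sampling interval, minutes.
#' @param fast_move_m Fast-movement retention distance, metres.
#' @return The downsampled fix tibble.
#' @export
downsample_min_interval <- function(fixes, min_interval_min = 60,
                                    fast_move_m = 20) {
  fixes <- as_fixes(fixes)
  fixes |>
    dplyr::group_by(.data$animal_id) |>
    dplyr::group_modify(function(tr, key) {
      scan_min_interval(tr, min_interval_min, fast_move_m)
    }) |>
    dplyr::ungroup() |>
    dplyr::relocate("animal_id")
}

#' Downsample navigation trajectories to a minimum interval
#'
#' Time-only linear scan used for post-release trajectories: keeps the first
#' fix and every fix at least `interval_min` minutes after the last kept fix.
#'
#' @param fixes A fix tibble for one animal.
#' @param interval_min Minimum interval in minutes (field protocol: 15).
#' @return The downsampled fix tibble.
#' @export
nav_downsample <- function(fixes, interval_min = 15) {
  fixes <- as_fixes(fixes)
  scan_min_interval(fixes, interval_min, fast_move_m = Inf)
}

#' Label tracking days by behaviour and compute daily travel
#'
#' Classifies every fix, then every tracking day, as `parental`, `mating`, or
#' `other`. A fix is parental if annotated so or located within `radius_m` of
#' a known breeding pool (species/sex combinations listed in `pool_exempt`
#' are exempt from the pool-proximity rule: male *O. sylvatica* attend pools
#' without providing care). A fix is mating if annotated so or within
#' `radius_m` of an opposite-sex individual on the same day. A day is
#' `parental` when it has at least one parental fix (parental movements are
#' the largest, so parental overrides mating), else `mating` when it has at
#' least one mating fix, else `other`. Daily travel is the cumulative
#' Euclidean distance over that day's fixes, computed on whatever sampling
#' the input carries (downsample first for standardised values).
#'
#' @param fixes A fix tibble; columns `species` and `sex` enable the pool
#'   exemption and opposite-sex matching.
#' @param pools Optional data frame of breeding-pool coordinates (`x`, `y`).
#' @param encounters Optional data frame of other individuals' positions
#'   (`x`, `y`, `t`, `sex`) used for opposite-sex proximity.
#' @param radius_m Proximity radius in metres (default 1).
#' @param pool_exempt Data frame of `species`/`sex` combinations whose pool
#'   proximity does not count as parental behaviour.
#' @param window Optional length-2 POSIXct study window; fixes outside it
#'   are excluded with a warning.
#' @param temps Optional temperature log (`t`, `temp_c`); adds a
#'   `daytime_temp_c` column via [daytime_temperature()].
#' @return A tibble with one row per animal-day: `animal_id`, `date`,
#'   `day_type`, `daily_travel_m`, `n_fixes`, and optionally
#'   `daytime_temp_c`.
#' @export
label_behavior_days <- function(fixes, pools = NULL, encounters = NULL,
                                radius_m = 1,
                                pool_exempt = tibble::tibble(
                                  species = "Os", sex = "male"),
                                window = NULL,
                                temps = NULL) {
  fixes <- as_fixes(fixes)
  if (!is.null(window)) {
    out_of_window <- fixes$t < window[1] | fixes$t > window[2]
    if (any(out_of_window)) {
      warn(paste0(sum(out_of_window),
                  " fix(es) outside the study window excluded"))
      fixes <- fixes[!out_of_window, ]
    }
  }
  if (nrow(fixes) == 0) abort("no fixes to label")

  parental <- fixes$behavior == "parental"
  if (!is.null(pools) && nrow(pools) > 0) {
    near_pool <- vapply(seq_len(nrow(fixes)), function(i) {
      any(sqrt((pools$x - fixes$x[i])^2 + (pools$y - fixes$y[i])^2)
          <= radius_m)
    }, logical(1))
    exempt <- rep(FALSE, nrow(fixes))
    if (!is.null(pool_exempt) && nrow(pool_exempt) > 0 &&
        all(c("species", "sex") %in% names(fixes))) {
      key_fix <- paste(fixes$species, fixes$sex)
      key_ex <- paste(pool_exempt$species, pool_exempt$sex)
      exempt <- key_fix %in% key_ex
    }
    parental <- parental | (near_pool & !exempt)
  }

  mating <- fixes$behavior == "mating"
  if (!is.null(encounters) && nrow(encounters) > 0 &&
      "sex" %in% names(fixes)) {
    enc_date <- local_date(encounters$t)
    fix_date <- local_date(fixes$t)
    near_mate <- vapply(seq_len(nrow(fixes)), function(i) {
      same_day <- enc_date == fix_date[i] & encounters$sex != fixes$sex[i]
      if (!any(same_day)) return(FALSE)
      any(sqrt((encounters$x[same_day] - fixes$x[i])^2 +
                 (encounters$y[same_day] - fixes$y[i])^2) <= radius_m)
    }, logical(1))
    mating <- mating | near_mate
  }

  fixes$..parental <- parental
  fixes$..mating <- mating
  fixes$..date <- local_date(fixes$t)
  days <- fixes |>
    dplyr::group_by(.data$animal_id, date = .data$..date) |>
    dplyr::summarise(
      day_type = if (any(.data$..parental)) "parental"
                 else if (any(.data$..mating)) "mating"
                 else "other",
      daily_travel_m = path_length(.data$x, .data$y),
      n_fixes = dplyr::n(),
      .groups = "drop"
    )
  if (!is.null(temps)) {
    dt <- daytime_temperature(temps, dates = unique(days$date))
    days <- dplyr::left_join(days, dt, by = "date")
  }
  days
}

#' Daytime temperature from a logger series
#'
#' Averages all temperature readings recorded between sunrise and sunset for
#' each requested date. The study species are strictly diurnal, so nighttime
#' readings are irrelevant to their thermal environment. Sunrise/sunset
#' default to 06:00/18:00, appropriate for equatorial sites; override per
#' site if needed.
#'
#' @param temps Data frame with columns `t` (POSIXct) and `temp_c`.
#' @param dates Dates to summarise; default all dates present in `temps`.
#' @param sunrise,sunset Hours of day bounding the averaging window.
#' @return A tibble with `date` and `daytime_temp_c` (NA when a date has no
#'   daytime readings).
#' @export
daytime_temperature <- function(temps, dates = NULL,
                                sunrise = 6, sunset = 18) {
  stopifnot(all(c("t", "temp_c") %in% names(temps)))
  if (!inherits(temps$t, "POSIXct")) {
    temps$t <- as.POSIXct(temps$t, tz = "UTC")
  }
  if (is.null(dates)) dates <- unique(local_date(temps$t))
  hod <- hour_of_day(temps$t)
  tdate <- local_date(temps$t)
  in_day <- hod >= sunrise & hod <= sunset
  tibble::tibble(
    date = sort(dates),
    daytime_temp_c = vapply(sort(dates), function(d) {
      sel <- in_day & tdate == d
      if (!any(sel)) return(NA_real_)
      mean(temps$temp_c[sel])
    }, numeric(1))
  )
}

#' Mean daytime temperature over each animal's tracking period
#'
#' Averages the daily daytime temperatures (see [daytime_temperature()])
#' over the span of dates each animal was tracked, giving the per-animal
#' temperature covariate used in downstream models.
#'
#' @param temps Temperature log (`t`, `temp_c`).
#' @param fixes Fix tibble defining each animal's tracking period.
#' @inheritParams daytime_temperature
#' @return A tibble with `animal_id` and `mean_daytime_temp_c`.
#' @export
tracking_temperature <- function(temps, fixes, sunrise = 6, sunset = 18) {
  fixes <- as_fixes(fixes)
  spans <- fixes |>
    dplyr::group_by(.data$animal_id) |>
    dplyr::summarise(first = min(local_date(.data$t)),
                     last = max(local_date(.data$t)), .groups = "drop")
  daily <- daytime_temperature(temps, sunrise = sunrise, sunset = sunset)
  spans$mean_daytime_temp_c <- vapply(seq_len(nrow(spans)), function(i) {
    sel <- daily$date >= spans$first[i] & daily$date <= spans$last[i]
    if (!any(sel) || all(is.na(daily$daytime_temp_c[sel]))) return(NA_real_)
    mean(daily$daytime_temp_c[sel], na.rm = TRUE)
  }, numeric(1))
  spans[, c("animal_id", "mean_daytime_temp_c")]
}

#' Long-term movement extent from capture-recapture records
#'
#' For each animal, the maximum linear distance between all capture points,
#' reported only for animals whose captures span at least `min_gap_days`
#' days (short spans say little about long-term space use). The time span
#' between first and last capture is returned as a model covariate.
#'
#' @param fixes Fix tibble of capture points (`source` typically
#'   `"recapture"`).
#' @param min_gap_days Minimum span in days between first and last capture
#'   for the extent to be defined (default 30).
#' @return A tibble with `animal_id`, `n_captures`, `span_days`, and
#'   `extent_m` (NA when the span filter is not met).
#' @export
recapture_extent <- function(fixes, min_gap_days = 30) {
  fixes <- as_fixes(fixes)
  fixes |>
    dplyr::group_by(.data$animal_id) |>
    dplyr::summarise(
      n_captures = dplyr::n(),
      span_days = as.numeric(difftime(max(.data$t), min(.data$t),
                                      units = "days")),
      extent_m = if (dplyr::n() >= 2 &&
                     as.numeric(difftime(max(.data$t), min(.data$t),
                                         units = "days")) >= min_gap_days) {
        max_pairwise_dist(.data$x, .data$y)
      } else {
        NA_real_
      },
      .groups = "drop"
    )
}
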