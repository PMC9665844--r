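#' Behaviour categories recognised in fix tables
#'
#' Relocations carry one of four behaviour annotations: `parental` (tadpole
#' transport, egg provisioning, or pool attendance), `mating` (courtship or
#' amplexus), `other` (no notable behaviour observed), and `unknown` (a label
#' in the raw data that could not be interpreted).
#'
#' @export
fix_behaviors <- c("parental", "mating", "other", "unknown")

#' Study species codes
#'
#' Two-letter codes for the three study species: `Af` (*Allobates femoralis*),
#' `Dt` (*Dendrobates tinctorius*), `Os` (*Oophaga sylvatica*).
#'
#' @export
fix_species <- c("Af", "Dt", "Os")

#' Coerce a data frame to a validated fix table
#'
#' A fix table is a tibble with one row per relocation ("fix") and at least
#' the columns `animal_id` (character), `t` (POSIXct, timezone-naive local
#' time stored as UTC), `x`, `y` (planar metres in a local map frame), and
#' `behavior` (one of [fix_behaviors]). Optional columns `species`, `sex`,
#' `weight_g`, and `source` are preserved. Rows are sorted by animal and time
#' and coordinates are checked to be finite.
#'
#' @param df A data frame with at least id, time, and coordinate columns.
#' @param on_duplicate What to do when the same animal has two fixes at the
#'   same timestamp: `"error"` (default; silent merging hides data problems)
#'   or `"keep_first"`.
#' @return A tibble sorted by `animal_id` then `t`.
#' @examples
#' fixes <- tibble::tibble(
#'   animal_id = "f1",
#'   t = as.POSIXct("2026-01-01 08:00", tz = "UTC") + c(0, 3600),
#'   x = c(0, 3), y = c(0, 4)
#' )
#' as_fixes(fixes)
#' @export
as_fixes <- function(df, on_duplicate = c("error", "keep_first")) {
  on_duplicate <- match.arg(on_duplicate)
  need <- c("animal_id", "t", "x", "y")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("fix table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  df <- tibble::as_tibble(df)
  df$animal_id <- as.character(df$animal_id)
  if (!inherits(df$t, "POSIXct")) {
    tt <- if (is.character(df$t) || is.factor(df$t)) {
      suppressWarnings(readr::parse_datetime(as.character(df$t)))
    } else {
      tryCatch(as.POSIXct(df$t, tz = "UTC"),
               error = function(e) rep(as.POSIXct(NA), nrow(df)))
    }
    bad <- which(is.na(tt) & !is.na(df$t))
    if (length(bad) > 0) {
      abort(paste0("unparseable timestamp in row(s): ",
                   paste(head(bad, 5), collapse = ", ")))
    }
    df$t <- tt
  }
  for (cc in c("x", "y")) {
    v <- df[[cc]]
    if (!is.numeric(v)) {
      vn <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad) > 0) {
        abort(paste0("non-numeric coordinate '", cc, "' in row(s): ",
                     paste(head(bad, 5), collapse = ", ")))
      }
      df[[cc]] <- vn
    }
  }
  if (any(!is.finite(df$x)) || any(!is.finite(df$y))) {
    bad <- which(!is.finite(df$x) | !is.finite(df$y))
    abort(paste0("non-finite coordinate in row(s): ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  if (any(is.na(df$t))) abort("missing timestamp in fix table")
  if (!"behavior" %in% names(df)) {
    df$behavior <- "other"
  } else {
    beh <- as.character(df$behavior)
    beh[is.na(beh) | beh == ""] <- "other"
    unknown <- !(beh %in% fix_behaviors)
    if (any(unknown)) {
      warn(paste0("unknown behavior label(s) ",
                  paste(unique(beh[unknown]), collapse = ", "),
                  " set to 'unknown'"))
      beh[unknown] <- "unknown"
    }
    df$behavior <- beh
  }
  if (!"source" %in% names(df)) df$source <- "tracking"
  df <- dplyr::arrange(df, .data$animal_id, .data$t)
  dup <- duplicated(df[, c("animal_id", "t")])
  if (any(dup)) {
    if (on_duplicate == "error") {
      abort(paste0("duplicate (animal_id, t) fixes, e.g. animal ",
                   df$animal_id[which(dup)[1]], " at ",
                   format(df$t[which(dup)[1]]),
                   "; use on_duplicate = 'keep_first' to drop them"))
    }
    df <- df[!dup, ]
  }
  df
}

#' Read a delimited fix table into a validated fix tibble
#'
#' Reads a CSV/TSV file of relocations, renames columns according to `cols`,
#' and validates through [as_fixes()]. One file may contain many animals; the
#' result is grouped implicitly by `animal_id` and sorted by time.
#'
#' @param path Path to a delimited text file.
#' @param cols Named character vector mapping standard names to file column
#'   names, e.g. `c(animal_id = "id", t = "timestamp", x = "easting",
#'   y = "northing")`. Optional entries: `behavior`, `species`, `sex`,
#'   `weight_g`, `source`.
#' @param delim Field delimiter; `NULL` (default) guesses from the extension
#'   (`.tsv` gives tab, otherwise comma).
#' @inheritParams as_fixes
#' @return A fix tibble (see [as_fixes()]).
#' @export
read_fixes <- function(path,
                       cols = c(animal_id = "animal_id", t = "t",
                                x = "x", y = "y"),
                       delim = NULL,
                       on_duplicate = c("error", "keep_first")) {
  if (is.null(delim)) {
    delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  }
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  missing_cols <- setdiff(unname(cols), names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("file ", path, " lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  std <- c("animal_id", "t", "x", "y", "behavior", "species", "sex",
           "weight_g", "source")
  keep <- cols[names(cols) %in% std]
  df <- raw[, unname(keep), drop = FALSE]
  names(df) <- names(keep)
  as_fixes(df, on_duplicate = on_duplicate)
}

#' Write a fix table to CSV
#'
#' Writes a fix tibble with ISO-8601 timestamps so that reading it back with
#' [read_fixes()] reproduces the same fixes.
#'
#' @param fixes A fix tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fixes <- function(fixes, path) {
  fixes <- as_fixes(fixes)
  out <- fixes
  out$t <- format(out$t, "%Y-%m-%dT%H:%M:%S")
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
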