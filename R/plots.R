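#' Plot a kernel utilization distribution with its home-range contour
#'
#' Filled density raster with the `ud_level` contour overlaid.
#'
#' @param object A `frog_ud` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.frog_ud <- function(object, ...) {
  grid <- expand.grid(x = object$grid_x, y = object$grid_y)
  grid$density <- as.vector(object$density)
  contours <- tidy(object)
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$density)) +
    ggplot2::geom_path(data = contours,
                       ggplot2::aes(group = .data$contour),
                       colour = "white", linewidth = 0.6) +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "x (m)", y = "y (m)", fill = "UD",
                  title = sprintf("%d%% UD home range: %.1f m\u00b2",
                                  round(100 * object$ud_level),
                                  object$area_m2))
}

#' Plot an MCP movement extent over its fixes
#'
#' @param object A `frog_mcp` object.
#' @param fixes Optional fix tibble to overlay.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.frog_mcp <- function(object, fixes = NULL, ...) {
  hull <- tidy(object)
  p <- ggplot2::ggplot(hull, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_polygon(fill = "grey80", colour = "grey40") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)",
                  title = sprintf("Movement extent (MCP): %.1f m\u00b2",
                                  object$area_m2))
  if (!is.null(fixes)) {
    p <- p + ggplot2::geom_point(data = fixes, size = 0.8)
  }
  p
}

#' Homeward-normalized trajectory plot
#'
#' Overlays translocation trajectories in the common homeward frame
#' (release at the origin, home direction up), one colour per sex, faceted
#' by distance class when both are present.
#'
#' @param recs A list of [translocation_record()] objects.
#' @param animals Optional tibble with `animal_id` and `sex` for colouring.
#' @return A ggplot.
#' @export
plot_homeward <- function(recs, animals = NULL) {
  if (inherits(recs, "frog_transloc")) recs <- list(recs)
  paths <- purrr::map_dfr(recs, function(rec) {
    tr <- normalize_homeward(rec)
    tr$distance_class <- rec$distance_class
    tr$home_dist <- attr(tr, "home")[["y"]]
    tr
  })
  if (!is.null(animals)) {
    paths <- dplyr::left_join(paths,
                              animals[, c("animal_id", "sex")],
                              by = "animal_id")
  } else {
    paths$sex <- "unknown"
  }
  ggplot2::ggplot(paths, ggplot2::aes(x = .data$x, y = .data$y,
                                      group = .data$animal_id,
                                      colour = .data$sex)) +
    ggplot2::geom_path(alpha = 0.7) +
    ggplot2::geom_point(data = dplyr::distinct(paths, .data$distance_class,
                                               .data$home_dist),
                        ggplot2::aes(x = 0, y = .data$home_dist),
                        inherit.aes = FALSE, shape = 1, size = 4,
                        colour = "grey40") +
    ggplot2::facet_wrap(~distance_class, scales = "free") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "towards home (m)", colour = "sex")
}

#' Daily travel by behaviour-day type
#'
#' Boxplots of per-animal mean daily travel on parental, mating, and other
#' days (natural-log y scale, matching the reporting convention for spatial
#' variables).
#'
#' @param day_records Output of [label_behavior_days()].
#' @param animals Optional tibble with `animal_id`, `sex`, `species`.
#' @return A ggplot.
#' @export
plot_daily_travel <- function(day_records, animals = NULL) {
  per_animal <- day_records |>
    dplyr::group_by(.data$animal_id, .data$day_type) |>
    dplyr::summarise(mean_travel = mean(.data$daily_travel_m),
                     .groups = "drop")
  if (!is.null(animals)) {
    per_animal <- dplyr::left_join(per_animal, animals, by = "animal_id")
  }
  p <- ggplot2::ggplot(per_animal,
                       ggplot2::aes(x = .data$day_type,
                                    y = pmax(.data$mean_travel, 0.1)))
  if (!is.null(animals) && "sex" %in% names(per_animal)) {
    p <- p + ggplot2::geom_boxplot(ggplot2::aes(fill = .data$sex))
  } else {
    p <- p + ggplot2::geom_boxplot()
  }
  if (!is.null(animals) && "species" %in% names(per_animal)) {
    p <- p + ggplot2::facet_wrap(~species)
  }
  p + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "day type", y = "mean daily travel (m, log scale)")
}
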