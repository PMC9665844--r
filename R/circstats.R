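#' Circular mean direction and resultant length
#'
#' First trigonometric moment of an angle sample: mean direction
#' `atan2(sum sin, sum cos)` and mean resultant length
#' `|sum exp(i theta)| / n` in `[0, 1]`. When the resultant is numerically zero
#' the mean direction is undefined and reported as `NA`.
#'
#' @param angles Numeric vector of angles in radians.
#' @return One-row tibble with `n`, `mean_direction`, `resultant_length`.
#' @examples
#' circular_summary(c(0, pi / 2)) # mean pi/4, r = cos(pi/4)
#' @export
circular_summary <- function(angles) {
  angles <- angles[!is.na(angles)]
  if (length(angles) < 1) abort("need at least one angle")
  n <- length(angles)
  C <- sum(cos(angles))
  S <- sum(sin(angles))
  r <- sqrt(C^2 + S^2) / n
  tibble::tibble(
    n = n,
    mean_direction = if (r < 1e-12) NA_real_ else wrap_pi(atan2(S, C)),
    resultant_length = r
  )
}

#' Directed Rayleigh (V) test for a specified home direction
#'
#' Tests circular uniformity against the alternative of clustering around a
#' pre-specified direction `mu` (the home direction; 0 in the
#' homeward-normalized frame). The statistic is
#' `V = r * cos(theta_bar - mu)`, the resultant length projected onto the
#' expected direction; the large-sample test uses `u = V * sqrt(2 n)` with a
#' one-sided standard-normal upper-tail p-value. A seeded Monte-Carlo
#' p-value (uniform resampling of the angles) is available and is forced,
#' with a warning, when `n < 5`, where the asymptotic tail is unreliable.
#'
#' @param angles Numeric vector of angles in radians.
#' @param mu Specified mean direction under the alternative (radians).
#' @param method `"asymptotic"` (default) or `"montecarlo"`.
#' @param n_mc Monte-Carlo replicates.
#' @param seed Optional seed for the Monte-Carlo resampling.
#' @return Object of class `frog_vtest` with elements `V`, `u`, `p.value`,
#'   `n`, `mu`, `method`. Supports [tidy()] and [glance()].
#' @export
rayleigh_homeward <- function(angles, mu = 0,
                              method = c("asymptotic", "montecarlo"),
                              n_mc = 10000, seed = NULL) {
  method <- match.arg(method)
  angles <- angles[!is.na(angles)]
  n <- length(angles)
  if (n < 1) abort("need at least one angle")
  if (n < 5 && method == "asymptotic") {
    warn("n < 5: asymptotic V-test unreliable, using Monte-Carlo p-value")
    method <- "montecarlo"
  }
  v_stat <- function(a) {
    C <- sum(cos(a)); S <- sum(sin(a))
    r <- sqrt(C^2 + S^2) / length(a)
    r * cos(atan2(S, C) - mu)
  }
  V <- v_stat(angles)
  u <- V * sqrt(2 * n)
  p <- if (method == "asymptotic") {
    pnorm(u, lower.tail = FALSE)
  } else {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv())) {
        get(".Random.seed", globalenv())
      } else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(seed)
    }
    vnull <- replicate(n_mc, v_stat(runif(n, -pi, pi)))
    (1 + sum(vnull >= V)) / (n_mc + 1)
  }
  structure(
    list(V = V, u = u, p.value = p, n = n, mu = mu, method = method),
    class = "frog_vtest"
  )
}

#' @export
print.frog_vtest <- function(x, ...) {
  cat("Directed Rayleigh (V) test, mu =", signif(x$mu, 4), "\n")
  cat("  V =", signif(x$V, 4), " u =", signif(x$u, 4),
      " n =", x$n, " p =", format.pval(x$p.value), paste0("(", x$method, ")"),
      "\n")
  invisible(x)
}

#' @rdname rayleigh_homeward
#' @param x A `frog_vtest` object.
#' @param ... Unused.
#' @export
tidy.frog_vtest <- function(x, ...) {
  tibble::tibble(statistic = x$V, u = x$u, p.value = x$p.value,
                 n = x$n, mu = x$mu, method = x$method)
}

#' @rdname rayleigh_homeward
#' @export
glance.frog_vtest <- function(x, ...) tidy(x)

#' Undirected Rayleigh test of circular uniformity
#'
#' Classic Rayleigh test (no specified direction) for completeness, with the
#' standard finite-sample series correction to the p-value.
#'
#' @param angles Numeric vector of angles in radians.
#' @return Object of class `frog_rayleigh` with `r`, `statistic`
#'   (`Z = n r^2`), `p.value`, `n`.
#' @export
rayleigh_test <- function(angles) {
  angles <- angles[!is.na(angles)]
  n <- length(angles)
  if (n < 2) abort("need at least two angles")
  r <- circular_summary(angles)$resultant_length
  Z <- n * r^2
  p <- exp(-Z) * (1 + (2 * Z - Z^2) / (4 * n) -
                    (24 * Z - 132 * Z^2 + 76 * Z^3 - 9 * Z^4) / (288 * n^2))
  p <- min(max(p, 0), 1)
  structure(list(r = r, statistic = Z, p.value = p, n = n),
            class = "frog_rayleigh")
}

#' @export
print.frog_rayleigh <- function(x, ...) {
  cat("Rayleigh test: Z =", signif(x$statistic, 4), " r =", signif(x$r, 4),
      " n =", x$n, " p =", format.pval(x$p.value), "\n")
  invisible(x)
}

#' Two-group comparison of circular distributions via trigonometric MANOVA
#'
#' Maps each angle to its trigonometric components `(cos theta, sin theta)`
#' and compares the two groups with a one-way MANOVA on the bivariate
#' response. With two response variables the Wilks' lambda F transform is
#' exact. Pillai's trace is available as an alternative statistic.
#'
#' @param angles_a,angles_b Numeric vectors of angles (radians), one per
#'   group; each group needs at least 3 angles.
#' @param statistic `"wilks"` (default) or `"pillai"`.
#' @return Object of class `frog_trigtest` with `statistic` (approx. F),
#'   `df1`, `df2`, `p.value`, `wilks` (or `pillai`), `n`. Supports
#'   [tidy()]/[glance()].
#' @export
trig_group_test <- function(angles_a, angles_b,
                            statistic = c("wilks", "pillai")) {
  statistic <- match.arg(statistic)
  angles_a <- angles_a[!is.na(angles_a)]
  angles_b <- angles_b[!is.na(angles_b)]
  if (length(angles_a) < 3 || length(angles_b) < 3) {
    abort("each group needs at least 3 angles")
  }
  a <- c(angles_a, angles_b)
  g <- factor(rep(c("a", "b"), c(length(angles_a), length(angles_b))))
  Y <- cbind(cos = cos(a), sin = sin(a))
  resid_var <- vapply(split(as.data.frame(Y), g), function(d) {
    sum(stats::var(d$cos), stats::var(d$sin))
  }, numeric(1))
  if (all(resid_var < 1e-14)) {
    abort("both groups have zero variance in both trigonometric components")
  }
  fit <- manova(Y ~ g)
  test_name <- if (statistic == "wilks") "Wilks" else "Pillai"
  s <- summary(fit, test = test_name)$stats
  structure(
    list(statistic = s[1, "approx F"],
         df1 = s[1, "num Df"], df2 = s[1, "den Df"],
         p.value = s[1, "Pr(>F)"],
         lambda = s[1, 2],
         test = statistic,
         n = c(a = length(angles_a), b = length(angles_b))),
    class = "frog_trigtest"
  )
}

#' @export
print.frog_trigtest <- function(x, ...) {
  cat("Trigonometric MANOVA (", x$test, "): F(", x$df1, ", ", x$df2,
      ") = ", signif(x$statistic, 4), ", p = ", format.pval(x$p.value),
      "\n", sep = "")
  invisible(x)
}

#' @rdname trig_group_test
#' @param x A `frog_trigtest` object.
#' @param ... Unused.
#' @export
tidy.frog_trigtest <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df1 = x$df1, df2 = x$df2,
                 p.value = x$p.value, test = x$test,
                 n_a = x$n[["a"]], n_b = x$n[["b"]])
}

#' @rdname trig_group_test
#' @export
glance.frog_trigtest <- function(x, ...) tidy(x)
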