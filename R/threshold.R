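# Adaptive decision threshold: the positive scores form a mixture of a
# noise component and (when variants are present and separable) a
# second, high-score component. A smooth density is fitted to their
# histogram by Poisson regression on a natural cubic spline of the bin
# midpoints (Lindsey's method) and the cutoff S* is placed at the
# leftmost strict interior local minimum. When no trustworthy minimum
# exists the upper 95% quantile of the positive scores is used instead —
# a sign that the score model does not suffice to reliably separate the
# populations.
#
# Two complementary spline fits are used, because a single unpenalized
# fit cannot be both stiff where data are sparse and flexible where they
# are dense:
#   * the LOCATOR places its knots uniformly over the score range; it
#     resolves the shape of a between-population valley precisely, but
#     in near-empty tails it rings (oscillates to reach isolated
#     outliers), manufacturing spurious minima;
#   * the DETECTOR places its interior knots at quantiles of the
#     positive scores (flexibility follows the data mass) plus three
#     coarse range-covering knots; it is stiff in sparse tails but can
#     still ripple inside the dense bulk, producing shallow spurious
#     dips.
# A minimum of the detector fit is accepted only if the HISTOGRAM
# supports it: the windowed observed counts at the flanking density
# maxima must rise to at least `ratio` times the windowed counts at the
# minimum, plus an absolute slack, on BOTH sides. Bulk ripples (huge
# counts, tiny contrast) and scattered tail outliers (counts of ~1
# everywhere) both fail this, while genuine between-population valleys
# pass with wide margins. The leftmost accepted minimum defines the
# valley, and S* is the leftmost strict local minimum of the locator
# fit inside it.

#' Fit smooth densities to the histogram of positive scores
#'
#' Bins the positive scores into `n_bins` equal-width bins over
#' `(0, max(S)]` and models the counts as Poisson with log-mean a
#' natural cubic spline in the bin midpoint. Two fits are returned: the
#' locator (`fitted`; knots uniform over the range) and the detector
#' (`detector_fitted`; interior knots at quantiles of the positive
#' scores). The fitted bin means of each sum to the total count, so
#' `exp` of the linear predictor is a (scaled) density estimate.
#'
#' @param scores Numeric vector of site scores; only `scores > 0` are
#'   used.
#' @param n_bins Number of histogram bins (default 100).
#' @param df Degrees of freedom of each natural spline (default 7).
#' @param min_scores Minimum number of positive scores required for a
#'   fit (default 200); below it the fallback path is signalled.
#' @return An object of class `score_density` with elements `breaks`,
#'   `mids`, `counts`, `fitted`, `detector_fitted`, `df`, `n_pos` and
#'   `converged`; when no fit is available (too few scores or a
#'   non-convergent fit) `converged` is `FALSE` and the fitted values
#'   are `NULL`, with the reason recorded.
#' @export
fit_score_density <- function(scores, n_bins = 100L, df = 7L,
                              min_scores = 200L) {
  stopifnot(is.numeric(scores))
  pos <- scores[!is.na(scores) & scores > 0]
  fail <- function(reason, breaks = NULL, mids = NULL, counts = NULL) {
    structure(list(breaks = breaks, mids = mids, counts = counts,
                   fitted = NULL, detector_fitted = NULL, df = df,
                   n_pos = length(pos), converged = FALSE,
                   reason = reason),
              class = "score_density")
  }
  if (length(pos) < min_scores) {
    return(fail("fewer positive scores than min_scores"))
  }
  breaks <- seq(0, max(pos), length.out = n_bins + 1L)
  h <- graphics::hist(pos, breaks = breaks, plot = FALSE)
  pois_fit <- function(formula_rhs) {
    fit <- tryCatch(
      suppressWarnings(
        stats::glm(h$counts ~ formula_rhs, family = stats::poisson())
      ),
      error = function(e) e
    )
    if (inherits(fit, "error") || !fit$converged) NULL else
      unname(stats::fitted(fit))
  }
  locator <- pois_fit(splines::ns(h$mids, df = df))
  rng <- range(h$mids)
  knots <- sort(unique(c(
    stats::quantile(pos, seq_len(max(df - 1L, 1L)) / df, names = FALSE),
    rng[1] + diff(rng) * c(0.25, 0.5, 0.75)
  )))
  knots <- knots[knots > rng[1] & knots < rng[2]]
  detector <- pois_fit(splines::ns(h$mids, knots = knots,
                                   Boundary.knots = rng))
  if (is.null(locator) || is.null(detector)) {
    return(fail("Poisson-spline fit did not converge",
                breaks = breaks, mids = h$mids, counts = h$counts))
  }
  structure(list(breaks = breaks, mids = h$mids, counts = h$counts,
                 fitted = locator, detector_fitted = detector, df = df,
                 n_pos = length(pos), converged = TRUE, reason = NULL),
            class = "score_density")
}

#' @export
print.score_density <- function(x, ...) {
  if (x$converged) {
    cat("score_density: ", length(x$mids), " bins over (0, ",
        format(max(x$breaks)), "], df = ", x$df, ", n_pos = ", x$n_pos,
        "\n", sep = "")
  } else {
    cat("score_density: no fit (", x$reason, "), n_pos = ", x$n_pos,
        "\n", sep = "")
  }
  invisible(x)
}

# indices of strict interior local minima of a vector (plateaus and
# boundary bins never qualify)
.local_minima <- function(f) {
  n <- length(f)
  if (n < 3L) return(integer())
  i <- 2:(n - 1L)
  i[f[i] < f[i - 1L] & f[i] < f[i + 1L]]
}

# mean observed counts in a +-w bin window around bin i
.window_counts <- function(counts, i, w = 2L) {
  mean(counts[max(1L, i - w):min(length(counts), i + w)])
}

# detector minima whose valley is supported by the histogram: the
# windowed counts at both flanking fitted maxima must reach
# ratio * (windowed counts at the minimum) + slack
.supported_minima <- function(f, counts, ratio = 2, slack = 5) {
  cand <- .local_minima(f)
  n <- length(f)
  keep <- vapply(cand, function(i) {
    l <- which.max(f[seq_len(i - 1L)])
    r <- i + which.max(f[(i + 1L):n])
    cv <- .window_counts(counts, i)
    min(.window_counts(counts, l), .window_counts(counts, r)) >=
      ratio * cv + slack
  }, logical(1))
  cand[keep]
}

#' Choose the adaptive cutoff from the fitted score densities
#'
#' Scans the detector fit for strict interior local minima (value lower
#' than both neighbours; plateaus and boundary bins never qualify) that
#' the histogram itself supports: the observed counts, averaged over a
#' +-2 bin window, must rise from the minimum to both flanking density
#' maxima by at least a factor `prominence_ratio` plus
#' `prominence_count` counts. Shallow ripples in the dense bulk (huge
#' counts, tiny contrast) and scattered tail outliers (~1 count per bin
#' everywhere) both fail this requirement, while genuine
#' between-population valleys pass it with wide margins; a second
#' population needs to reach roughly `prominence_count` sites per bin
#' around its mode to be declared separable. The leftmost accepted
#' minimum defines the valley between its flanking density maxima, and
#' the cutoff is the leftmost strict local minimum of the locator fit
#' inside that valley.
#'
#' If no prominent minimum exists, the empirical upper quantile (default
#' 95%) of the positive scores is used, with a warning that the score
#' model does not suffice to reliably call the variants.
#'
#' @param density A `score_density` from [fit_score_density()], or
#'   `NULL` to force the fallback.
#' @param scores The score vector (used for the fallback quantile; only
#'   positive scores are considered).
#' @param fallback_quantile Quantile of the positive scores used when no
#'   acceptable minimum exists (default 0.95).
#' @param prominence_ratio,prominence_count Histogram support required
#'   to accept a detector minimum (defaults 2 and 5): the windowed
#'   counts at both flanking maxima must reach
#'   `prominence_ratio * (counts at the minimum) + prominence_count`.
#' @return An object of class `threshold_result`: `s_star`, `rule`
#'   (`"leftmost_local_minimum"` or `"quantile_fallback"`), the
#'   `density`, `n_pos`, `bin_width` and `fallback_quantile`.
#' @export
find_cutoff <- function(density, scores, fallback_quantile = 0.95,
                        prominence_ratio = 2, prominence_count = 5) {
  pos <- scores[!is.na(scores) & scores > 0]
  if (!length(pos)) {
    stop("no positive scores: cannot choose a threshold")
  }
  rule <- "quantile_fallback"
  s_star <- NA_real_
  if (!is.null(density)) {
    stopifnot(inherits(density, "score_density"))
    if (density$converged) {
      fB <- density$detector_fitted
      # tolerate hand-built densities carrying a single fit
      if (is.null(fB)) fB <- density$fitted
      fA <- density$fitted
      acc <- .supported_minima(fB, density$counts,
                               ratio = prominence_ratio,
                               slack = prominence_count)
      if (length(acc)) {
        i <- acc[1L]
        lpos <- which.max(fB[seq_len(i - 1L)])
        rpos <- i + which.max(fB[(i + 1L):length(fB)])
        inside <- .local_minima(fA)
        inside <- inside[inside > lpos & inside < rpos]
        j <- if (length(inside)) inside[1L] else i
        rule <- "leftmost_local_minimum"
        s_star <- density$mids[j]
      }
    }
  }
  if (rule == "quantile_fallback") {
    warning("no prominent local minimum in the fitted score density: ",
            "the score model does not suffice to reliably call the ",
            "variants; falling back to the upper ",
            format(100 * fallback_quantile),
            "% quantile of the positive scores")
    s_star <- unname(stats::quantile(pos, fallback_quantile))
  }
  structure(
    list(s_star = s_star, rule = rule, density = density,
         n_pos = length(pos),
         bin_width = if (!is.null(density$breaks))
           diff(density$breaks[1:2]) else NA_real_,
         fallback_quantile = fallback_quantile),
    class = "threshold_result"
  )
}

#' Fit the score density and choose the cutoff in one step
#'
#' @inheritParams fit_score_density
#' @inheritParams find_cutoff
#' @return A `threshold_result`; see [find_cutoff()].
#' @export
choose_threshold <- function(scores, n_bins = 100L, df = 7L,
                             min_scores = 200L,
                             fallback_quantile = 0.95,
                             prominence_ratio = 2,
                             prominence_count = 5) {
  dens <- fit_score_density(scores, n_bins = n_bins, df = df,
                            min_scores = min_scores)
  find_cutoff(dens, scores, fallback_quantile = fallback_quantile,
              prominence_ratio = prominence_ratio,
              prominence_count = prominence_count)
}

#' @export
print.threshold_result <- function(x, ...) {
  cat("threshold_result: S* = ", format(x$s_star), " (", x$rule, "), ",
      x$n_pos, " positive scores\n", sep = "")
  invisible(x)
}

#' Diagnostic plot of the positive-score histogram, fit and cutoff
#'
#' @param x A `threshold_result`.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.threshold_result <- function(x, ...) {
  d <- x$density
  if (is.null(d) || is.null(d$counts)) {
    stop("threshold_result carries no histogram to plot")
  }
  graphics::plot(d$mids, d$counts, type = "h", col = "grey60",
                 xlab = "score S", ylab = "sites per bin", ...)
  if (!is.null(d$fitted)) {
    graphics::lines(d$mids, d$fitted, col = "red", lwd = 2)
  }
  graphics::abline(v = x$s_star, col = "blue", lty = 3, lwd = 2)
  graphics::legend("topright", bty = "n",
                   legend = c("histogram", "Poisson-spline fit",
                              sprintf("S* = %.3g (%s)", x$s_star, x$rule)),
                   col = c("grey60", "red", "blue"),
                   lty = c(1, 1, 3), lwd = 2)
  invisible(x)
}

#' Serialize a threshold result to a small JSON report
#'
#' @param x A `threshold_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_threshold_report <- function(x, path) {
  stopifnot(inherits(x, "threshold_result"))
  d <- x$density
  rep <- list(
    s_star = x$s_star, rule = x$rule, n_pos = x$n_pos,
    bin_width = x$bin_width, fallback_quantile = x$fallback_quantile,
    df = if (!is.null(d)) d$df else NULL,
    converged = if (!is.null(d)) d$converged else FALSE,
    mids = d$mids, counts = d$counts, fitted = d$fitted,
    detector_fitted = d$detector_fitted
  )
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", pretty = TRUE)
  invisible(path)
}
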