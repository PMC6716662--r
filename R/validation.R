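#' Step-count deviation in percent
#'
#' Deviation of a detected step count from the ground-truth (video) count:
#' `(estimated / truth - 1) * 100`.
#'
#' @param estimated Detected step count.
#' @param truth Ground-truth step count (> 0).
#' @return Percent deviation (positive = overcount).
#' @export
step_count_deviation <- function(estimated, truth) {
  if (any(truth <= 0)) stop("ground-truth count must be positive")
  (estimated / truth - 1) * 100
}

#' Bland-Altman limits of agreement
#'
#' Differences are `estimated - reference`; limits of agreement are the mean
#' difference plus/minus 1.96 standard deviations of the differences
#' (n - 1 denominator).
#'
#' @param estimates,references Paired speed vectors, m/s, equal length >= 2.
#' @return Named list `mean_difference`, `lower_limit`, `upper_limit` (m/s).
#' @export
bland_altman <- function(estimates, references) {
  if (length(estimates) != length(references)) stop("length mismatch")
  if (length(estimates) < 2) stop("need at least 2 pairs")
  d <- estimates - references
  md <- mean(d); s <- stats::sd(d)
  list(mean_difference = md, lower_limit = md - 1.96 * s,
       upper_limit = md + 1.96 * s)
}

#' Regression agreement of estimates on reference
#'
#' Ordinary least-squares fit of the estimates on the reference values;
#' perfect agreement gives intercept 0 and slope 1 (the diagonal).
#'
#' @param estimates,references Paired vectors, >= 3 pairs; the reference
#'   must have positive variance.
#' @return Named list `intercept`, `slope`.
#' @export
regression_agreement <- function(estimates, references) {
  if (length(estimates) != length(references)) stop("length mismatch")
  if (length(estimates) < 3) stop("need at least 3 pairs")
  if (stats::var(references) <= 0) stop("reference variance is zero")
  cf <- stats::coef(stats::lm(estimates ~ references))
  list(intercept = unname(cf[1]), slope = unname(cf[2]))
}

#' Root-mean-square error
#'
#' @param estimates,references Paired vectors, equal length >= 1.
#' @return `sqrt(mean((estimates - references)^2))`.
#' @export
rmse <- function(estimates, references) {
  if (length(estimates) != length(references)) stop("length mismatch")
  sqrt(mean((estimates - references)^2))
}

#' Mean speed differences grouped by reference-speed range
#'
#' Groups paired (estimated, reference) section speeds into reference-speed
#' bins (left-closed, right-open) and reports, per bin, the mean reference
#' speed, mean estimated speed, and their difference
#' `mean reference - mean estimated` (so an overestimating algorithm shows
#' a negative difference), plus a one-sample t-test of the per-pair
#' differences against zero.
#'
#' @param paired Data frame with columns `estimated` and `reference` (m/s).
#' @param bins Bin edges in m/s, default `c(0, 1, 1.5)` (the slow-walker
#'   split at 1 m/s).
#' @param algorithm Label recorded in the output rows.
#' @return Data frame: `speed_range`, `mean_reference`, `mean_estimated`,
#'   `difference`, `n`, `t`, `p`, `algorithm`. Empty bins produce no row
#'   (with a warning).
#' @export
grouped_mean_difference <- function(paired, bins = c(0, 1, 1.5),
                                    algorithm = "stepwave") {
  stopifnot(all(c("estimated", "reference") %in% names(paired)))
  out <- lapply(seq_len(length(bins) - 1), function(i) {
    sel <- paired$reference >= bins[i] & paired$reference < bins[i + 1]
    rng <- sprintf("[%.1f, %.1f)", bins[i], bins[i + 1])
    if (!any(sel)) {
      warning("empty speed bin ", rng)
      return(NULL)
    }
    mr <- mean(paired$reference[sel]); me <- mean(paired$estimated[sel])
    d <- paired$reference[sel] - paired$estimated[sel]
    tp <- if (sum(sel) >= 2 && stats::sd(d) > 1e-10 * max(1, abs(mean(d)))) {
      ht <- stats::t.test(d, mu = 0)
      c(unname(ht$statistic), ht$p.value)
    } else c(NA_real_, NA_real_)
    data.frame(speed_range = rng, mean_reference = mr, mean_estimated = me,
               difference = mr - me, n = sum(sel), t = tp[1], p = tp[2],
               algorithm = algorithm, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' One-sample t-test of differences against zero
#'
#' @param differences Numeric vector, n >= 2, nonzero variance.
#' @return Named list `t`, `p` (two-sided).
#' @export
one_sample_ttest <- function(differences) {
  if (length(differences) < 2) stop("need at least 2 differences")
  if (stats::sd(differences) == 0) stop("zero variance: t undefined")
  ht <- stats::t.test(differences, mu = 0)
  list(t = unname(ht$statistic), p = ht$p.value)
}

#' Bland-Altman agreement plot
#'
#' Differences (estimated - reference) against pair means, with the mean
#' difference (solid) and the 1.96 SD limits of agreement (dashed).
#'
#' @param estimates,references Paired speeds, m/s.
#' @param ... Passed to [graphics::plot()].
#' @return The [bland_altman()] list, invisibly.
#' @export
plot_bland_altman <- function(estimates, references, ...) {
  ba <- bland_altman(estimates, references)
  m <- (estimates + references) / 2
  graphics::plot(m, estimates - references,
                 xlab = "Mean of estimated and reference speed (m/s)",
                 ylab = "Estimated - reference (m/s)", ...)
  graphics::abline(h = ba$mean_difference, lty = 1)
  graphics::abline(h = c(ba$lower_limit, ba$upper_limit), lty = 2)
  invisible(ba)
}
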