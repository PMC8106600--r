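#' Fraction of observations inside a simulated percentile band
#'
#' Confronts monitoring observations at a site with the simulated
#' concentration distribution of the corresponding segment: the coverage is
#' the fraction of observations falling inside the `[P_lo, P_hi]` band of
#' the samples.  For observations drawn from the simulated distribution
#' itself the expected coverage equals `(hi - lo)/100` (80% for the default
#' 10th-to-90th percentile band).
#'
#' Observations below a limit of quantification can be excluded
#' (`loq_handling = "exclude"`, the default) or substituted by `loq/2`.
#'
#' @param observations Numeric vector of measured concentrations, ng/l.
#' @param samples Numeric vector of simulated concentrations for the
#'   site's segment (see [segment_samples()]).
#' @param lo,hi Band percentiles, `0 <= lo < hi <= 100`.
#' @param loq Limit of quantification, ng/l (`NA` = no censoring).
#' @param loq_handling `"exclude"` or `"half"`.
#' @return Coverage fraction in `[0, 1]`.
#' @export
band_coverage <- function(observations, samples, lo = 10, hi = 90,
                          loq = NA_real_, loq_handling = c("exclude", "half")) {
  loq_handling <- match.arg(loq_handling)
  if (length(observations) == 0) stop("no observations")
  if (!(lo < hi)) stop("lo must be < hi")
  if (!is.na(loq)) {
    cens <- observations < loq
    if (loq_handling == "exclude") {
      observations <- observations[!cens]
      if (length(observations) == 0)
        stop("all observations censored below the LOQ")
    } else {
      observations[cens] <- loq / 2
    }
  }
  band <- stats::quantile(samples, c(lo, hi) / 100, type = 7, names = FALSE)
  mean(observations >= band[1] & observations <= band[2])
}

# Dixon r10 two-tailed critical values, n = 3..30 (Rorabacher 1991).
.dixon_r10 <- data.frame(
  n = 3:30,
  q05 = c(0.970, 0.829, 0.710, 0.625, 0.568, 0.526, 0.493, 0.466, 0.444,
          0.426, 0.410, 0.396, 0.384, 0.374, 0.365, 0.356, 0.349, 0.342,
          0.337, 0.331, 0.326, 0.321, 0.317, 0.312, 0.308, 0.305, 0.301,
          0.298),
  q01 = c(0.994, 0.926, 0.821, 0.740, 0.680, 0.634, 0.598, 0.568, 0.542,
          0.522, 0.503, 0.488, 0.475, 0.463, 0.452, 0.442, 0.433, 0.425,
          0.418, 0.411, 0.404, 0.399, 0.393, 0.388, 0.384, 0.380, 0.376,
          0.372))

#' Dixon Q test for a single outlier in a small sample
#'
#' The classic r10 ratio for small samples (`3 <= n <= 30`): after sorting,
#' `Q = gap / range` for whichever extreme (minimum or maximum) has the
#' larger gap to its neighbour; the value is an outlier if `Q` exceeds the
#' two-tailed critical value for `n` at the chosen significance level.  At
#' most one outlier is flagged per call; iterate externally to find more.
#'
#' @param values Numeric vector, `3 <= length <= 30`.
#' @param alpha Significance level, `0.05` or `0.01`.
#' @return A list with `outlier` (index into `values`, or `NA` if none),
#'   `value`, `Q`, `critical`.
#' @export
dixon_q_test <- function(values, alpha = c(0.05, 0.01)) {
  alpha <- match.arg(as.character(alpha[1]), c("0.05", "0.01"))
  n <- length(values)
  if (n < 3 || n > 30) stop("Dixon Q test requires 3 <= n <= 30")
  rng <- diff(range(values))
  if (rng == 0)
    return(list(outlier = NA_integer_, value = NA_real_, Q = 0,
                critical = NA_real_))
  s <- sort(values)
  gap_lo <- s[2] - s[1]
  gap_hi <- s[n] - s[n - 1]
  if (gap_hi >= gap_lo) {
    suspect <- s[n]
    Q <- gap_hi / rng
  } else {
    suspect <- s[1]
    Q <- gap_lo / rng
  }
  crit <- .dixon_r10[[if (alpha == "0.05") "q05" else "q01"]][n - 2]
  idx <- if (Q > crit) which(values == suspect)[1] else NA_integer_
  list(outlier = idx,
       value = if (is.na(idx)) NA_real_ else suspect,
       Q = Q, critical = crit)
}
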