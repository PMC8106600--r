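#' Monte Carlo configuration
#'
#' @param n_iterations Number of model realisations (default 10000).
#' @param seed Integer seed; every run with the same catchment, substance
#'   and config is bit-identical.
#' @param vary_flow Draw river flows from their lognormal variability
#'   distributions (one shared quantile per iteration)?
#' @param vary_consumption Draw per-capita consumption (lognormal with the
#'   substance's `consumption_rsd`)?
#' @param vary_removal Draw removal efficiencies (normal truncated to
#'   `[0,1]`, `removal_rsd`)?
#' @return An object of class `mc_config`.
#' @export
mc_config <- function(n_iterations = 10000, seed = 1,
                      vary_flow = TRUE, vary_consumption = FALSE,
                      vary_removal = FALSE) {
  if (!is.finite(n_iterations) || n_iterations < 1)
    stop("n_iterations must be >= 1")
  structure(list(n_iterations = as.integer(n_iterations),
                 seed = as.integer(seed),
                 vary_flow = isTRUE(vary_flow),
                 vary_consumption = isTRUE(vary_consumption),
                 vary_removal = isTRUE(vary_removal)),
            class = "mc_config")
}

#' Probabilistic simulation of per-segment concentrations
#'
#' Runs `n_iterations` steady-state routings.  Per iteration the draws are
#' made in a fixed order from a single RNG stream seeded by the config
#' (flow quantiles first, then consumption factors, then removal
#' efficiencies per treatment category in alphabetical order), so results
#' are reproducible across platforms.  Flow uses one shared quantile per
#' iteration across all segments: the whole basin is wet or dry together.
#' Substance-parameter draws are independent of the flow quantile.
#'
#' @param ct A [catchment()].
#' @param sub A [substance()].
#' @param config An [mc_config()].
#' @param weights Hospital allocation weights, required iff `sub$f_site > 0`
#'   (see [allocate_hospital_weights()]).
#' @return An object of class `mc_result`: per-segment concentration
#'   sample vectors (ng/l) of length `n_iterations`.
#' @export
run_probabilistic <- function(ct, sub, config = mc_config(), weights = NULL) {
  stopifnot(inherits(config, "mc_config"))
  n <- config$n_iterations
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(config$seed, kind = "Mersenne-Twister")

  sg <- ct$segments
  # 1. flow quantiles
  if (config$vary_flow) {
    u <- stats::runif(n)
    flows <- sample_flows(ct, u)
    if (!is.matrix(flows))
      flows <- matrix(flows, ncol = 1, dimnames = list(sg$segment_id, NULL))
  } else {
    flows <- matrix(sg$mq, nrow = nrow(sg), ncol = n,
                    dimnames = list(sg$segment_id, NULL))
  }
  # 2. consumption factors (lognormal, mean 1, relative SD consumption_rsd)
  if (config$vary_consumption && sub$consumption_rsd > 0) {
    sdlog <- sqrt(log(1 + sub$consumption_rsd^2))
    cons_factor <- stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  } else {
    cons_factor <- rep(1, n)
  }
  # 3. removal efficiencies per category (truncated normal on [0,1])
  infl <- influent_loads(sub, ct, weights)
  w <- ct$wwtps
  overrides <- attr(ct, "removal_override")
  if (config$vary_removal && sub$removal_rsd > 0) {
    cats <- sort(names(sub$removal))
    rem_draw <- matrix(NA_real_, length(cats), n, dimnames = list(cats, NULL))
    for (cat_i in cats) {
      m <- sub$removal[[cat_i]]
      s <- sub$removal_rsd * m
      if (s == 0) {
        rem_draw[cat_i, ] <- m
      } else {
        plo <- stats::pnorm(0, m, s)
        phi <- stats::pnorm(1, m, s)
        rem_draw[cat_i, ] <- stats::qnorm(stats::runif(n, plo, phi), m, s)
      }
    }
    loads <- matrix(0, nrow(w), n, dimnames = list(w$wwtp_id, NULL))
    for (i in seq_len(nrow(w))) {
      cat_i <- w$treatment_category[i]
      r <- rem_draw[cat_i, ]
      if (!is.null(overrides)) {  # scenario overrides are treated as exact
        ov <- overrides[[w$wwtp_id[i]]]
        if (!is.null(ov) && cat_i %in% names(ov)) r <- ov[[cat_i]]
      }
      loads[i, ] <- infl[[w$wwtp_id[i]]] * (1 - r)
    }
  } else {
    eff <- .effluent_loads(sub, ct, weights)
    loads <- matrix(eff, nrow(w), n, dimnames = list(w$wwtp_id, NULL))
  }
  loads <- sweep(loads, 2, cons_factor, `*`)

  res <- .route_matrix(ct, loads, .effluent_flows(ct), flows, k_total(sub))
  structure(list(samples = res$conc, segment_id = sg$segment_id,
                 config = config, substance = sub$name),
            class = "mc_result")
}

#' @export
print.mc_result <- function(x, ...) {
  cat(sprintf("<mc_result> %s: %d segments x %d realisations (seed %d)\n",
              x$substance, nrow(x$samples), ncol(x$samples), x$config$seed))
  invisible(x)
}

#' Extract the concentration sample vector of one segment
#'
#' @param result An `mc_result` from [run_probabilistic()].
#' @param segment_id Segment to extract.
#' @return Numeric vector of sampled concentrations, ng/l.
#' @export
segment_samples <- function(result, segment_id) {
  stopifnot(inherits(result, "mc_result"))
  if (!(segment_id %in% rownames(result$samples)))
    stop("no result for segment ", segment_id)
  result$samples[segment_id, ]
}

#' Summarise a simulation into per-segment mean and percentiles
#'
#' Percentiles use linear interpolation between order statistics
#' (`stats::quantile` type 7).
#'
#' @param result An `mc_result` from [run_probabilistic()] or a
#'   `routing_state` from [route_steady_state()] (for which all
#'   percentiles equal the deterministic concentration).
#' @param percentiles Percentiles to report, each in `[0, 100]`.
#' @return A data.frame with columns `segment_id`, `mean` and one `p<q>`
#'   column per requested percentile, concentrations in ng/l.
#' @export
summarize <- function(result, percentiles = c(10, 50, 90)) {
  if (any(!is.finite(percentiles)) ||
      any(percentiles < 0) || any(percentiles > 100))
    stop("percentiles must lie in [0, 100]")
  UseMethod("summarize")
}

#' @export
summarize.mc_result <- function(result, percentiles = c(10, 50, 90)) {
  qs <- t(apply(result$samples, 1, stats::quantile,
                probs = percentiles / 100, type = 7, names = FALSE))
  if (length(percentiles) == 1) qs <- matrix(qs, ncol = 1)
  colnames(qs) <- sprintf("p%g", percentiles)
  out <- data.frame(segment_id = result$segment_id,
                    mean = unname(rowMeans(result$samples)),
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- cbind(out, as.data.frame(qs, row.names = NULL))
  rownames(out) <- NULL
  out
}

#' @export
summarize.routing_state <- function(result, percentiles = c(10, 50, 90)) {
  out <- data.frame(segment_id = result$segment_id,
                    mean = result$conc_ng_l,
                    stringsAsFactors = FALSE, row.names = NULL)
  for (p in percentiles)
    out[[sprintf("p%g", p)]] <- result$conc_ng_l
  out
}
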