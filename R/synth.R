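#' Configuration for the synthetic-catchment generator
#'
#' The generator emulates the structure real catchment databases share:
#' a dendritic (tree-shaped) network of short segments, accumulated flows
#' with `MNQ <= Q50 <= MQ`, treatment plants from village to city scale
#' with an exact quota of small (<1000 inhabitants) plants, hospitals
#' attached to plants, and a gauge at the outlet.
#'
#' @param n_segments Number of river segments (>= 1).
#' @param n_wwtps Number of treatment plants.
#' @param n_hospitals Number of hospitals.
#' @param seed Mandatory integer seed; generation is fully reproducible.
#' @param outlet_mq Mean flow at the outlet, m3/s; local contributions are
#'   rescaled after accumulation so the outlet MQ matches exactly.
#' @param population_range Range of connected inhabitants for plants at or
#'   above 1000 inhabitants.
#' @param small_fraction Fraction of plants below 1000 inhabitants; the
#'   count `round(small_fraction * n_wwtps)` is exact by construction.
#' @param mq_q50_ratio Range of the per-segment MQ/Q50 ratio (>= 1).
#' @param patient_range Range of annual patient counts per hospital.
#' @param n_sites Number of monitoring sites to place.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_segments = 50, n_wwtps = 5, n_hospitals = 2,
                         seed = 1, outlet_mq = 10,
                         population_range = c(1000, 100000),
                         small_fraction = 0.2,
                         mq_q50_ratio = c(1.05, 1.6),
                         patient_range = c(5000, 50000),
                         n_sites = 3) {
  stopifnot(n_segments >= 1, n_wwtps >= 0, n_hospitals >= 0,
            outlet_mq > 0, small_fraction >= 0, small_fraction <= 1,
            mq_q50_ratio[1] >= 1, diff(mq_q50_ratio) >= 0)
  if (missing(seed)) stop("seed is mandatory")
  structure(as.list(environment()), class = "synth_config")
}

#' Generate a synthetic catchment
#'
#' Builds a random dendritic network by recursive bifurcation (each step
#' extends or splits a random headwater, so acyclicity and a unique outlet
#' hold by construction), draws segment lengths uniformly in (200, 2000] m,
#' accumulates lognormal local runoff into MQ (rescaled so the outlet MQ
#' equals `outlet_mq` exactly), derives Q50 and MNQ below it, places
#' plants, hospitals, an outlet gauge (observed = modelled, so calibration
#' is the identity) and monitoring sites.  The result always passes
#' [validate_catchment()].
#'
#' @param config A [synth_config()].
#' @return A [catchment()].
#' @export
generate <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(config$seed, kind = "Mersenne-Twister")
  n <- config$n_segments

  # --- topology: edges (from, to) over integer node ids; node 1 = outlet
  from <- integer(n); to <- integer(n)
  from[1] <- 2L; to[1] <- 1L
  n_nodes <- 2L
  n_seg <- 1L
  tips <- 1L  # headwater segment indices
  while (n_seg < n) {
    t <- if (length(tips) == 1) tips else sample(tips, 1)
    bifurcate <- (n - n_seg >= 2) && stats::runif(1) < 0.4
    n_new <- if (bifurcate) 2L else 1L
    for (j in seq_len(n_new)) {
      n_seg <- n_seg + 1L
      n_nodes <- n_nodes + 1L
      from[n_seg] <- n_nodes
      to[n_seg] <- from[t]
      tips <- c(tips, n_seg)
    }
    tips <- setdiff(tips, t)
  }
  seg_id <- sprintf("S%04d", seq_len(n))
  node_id <- sprintf("N%04d", seq_len(n_nodes))

  length_m <- stats::runif(n, 200, 2000)

  # --- coordinates: walk upstream from the outlet
  nx <- numeric(n_nodes); ny <- numeric(n_nodes)
  ang <- stats::runif(n, 0, 2 * pi)
  # process segments so that to-node coords exist before from-node coords
  done <- rep(FALSE, n_nodes); done[1] <- TRUE
  pending <- seq_len(n)
  while (length(pending) > 0) {
    ready <- pending[done[to[pending]]]
    for (i in ready) {
      nx[from[i]] <- nx[to[i]] + length_m[i] * cos(ang[i])
      ny[from[i]] <- ny[to[i]] + length_m[i] * sin(ang[i])
      done[from[i]] <- TRUE
    }
    pending <- setdiff(pending, ready)
  }

  # --- flows: lognormal local runoff, accumulated downstream
  local <- stats::rlnorm(n, meanlog = 0, sdlog = 0.8)
  acc <- numeric(n)
  acc_done <- rep(FALSE, n)
  while (any(!acc_done)) {
    for (i in which(!acc_done)) {
      ups <- which(to == from[i])
      if (all(acc_done[ups]) || length(ups) == 0) {
        acc[i] <- local[i] + sum(acc[ups])
        acc_done[i] <- TRUE
      }
    }
  }
  outlet_seg <- which(to == 1L)
  scale <- config$outlet_mq / acc[outlet_seg]
  mq <- acc * scale
  local <- local * scale
  ratio <- stats::runif(n, config$mq_q50_ratio[1], config$mq_q50_ratio[2])
  q50 <- mq / ratio
  mnq <- q50 * stats::runif(n, 0.3, 0.8)

  segments <- data.frame(
    segment_id = seg_id, from_node = node_id[from], to_node = node_id[to],
    length = length_m, mq = mq, mnq = mnq, q50 = q50,
    v_ref = stats::runif(n, 0.2, 1.0), v_exponent = 0.4,
    x = (nx[from] + nx[to]) / 2, y = (ny[from] + ny[to]) / 2,
    local_mq = local, stringsAsFactors = FALSE)
  nodes <- data.frame(node_id = node_id, x = nx, y = ny,
                      stringsAsFactors = FALSE)

  # --- WWTPs on distinct nodes that have a downstream segment
  candidates <- unique(from)  # every from-node feeds exactly one segment
  if (config$n_wwtps > length(candidates))
    stop("more WWTPs requested than available nodes")
  wn <- if (config$n_wwtps > 0)
    sample(candidates, config$n_wwtps) else integer(0)
  n_small <- round(config$small_fraction * config$n_wwtps)
  pop <- numeric(config$n_wwtps)
  if (n_small > 0)
    pop[seq_len(n_small)] <- round(stats::runif(n_small, 100, 999))
  if (config$n_wwtps > n_small)
    pop[(n_small + 1):config$n_wwtps] <- round(stats::runif(
      config$n_wwtps - n_small,
      max(1000, config$population_range[1]), config$population_range[2]))
  wwtps <- data.frame(
    wwtp_id = sprintf("W%03d", seq_len(config$n_wwtps)),
    discharge_node = node_id[wn],
    population_connected = pop,
    treatment_category = sample(treatment_categories(), config$n_wwtps,
                                replace = TRUE,
                                prob = c(0.05, 0.1, 0.15, 0.7)),
    effluent_flow = NA_real_, x = nx[wn], y = ny[wn],
    stringsAsFactors = FALSE)

  hospitals <- NULL
  if (config$n_hospitals > 0) {
    if (config$n_wwtps == 0) stop("hospitals need WWTPs to discharge into")
    flags <- rep("", config$n_hospitals)
    flags[sample.int(config$n_hospitals, 1)] <- "radiology"
    hospitals <- data.frame(
      hospital_id = sprintf("H%03d", seq_len(config$n_hospitals)),
      receiving_wwtp = sample(wwtps$wwtp_id, config$n_hospitals,
                              replace = TRUE),
      patients_per_year = round(stats::runif(config$n_hospitals,
                                             config$patient_range[1],
                                             config$patient_range[2])),
      beds = NA_real_, department_flags = flags, stringsAsFactors = FALSE)
    hospitals$beds <- round(hospitals$patients_per_year / 100)
  }

  gauges <- data.frame(gauge_id = "G001", node = node_id[1L],
                       observed_mq = mq[outlet_seg],
                       observed_mnq = mnq[outlet_seg],
                       stringsAsFactors = FALSE)

  n_sites <- min(config$n_sites, n)
  site_segs <- order(mq, decreasing = TRUE)[seq_len(n_sites)]
  monitoring_sites <- if (n_sites > 0)
    data.frame(site_id = sprintf("M%02d", seq_len(n_sites)),
               node = node_id[from[site_segs]], stringsAsFactors = FALSE)
  else NULL

  catchment(segments, nodes, wwtps, hospitals, gauges, monitoring_sites)
}

#' Simulate monitoring observations from a model result
#'
#' Draws bootstrap observations from each site's simulated concentration
#' sample vector, optionally perturbed by multiplicative lognormal
#' measurement noise with mean 1, to enable band-coverage and outlier
#' tests without real monitoring data.
#'
#' @param ct A [catchment()] with monitoring sites.
#' @param result An `mc_result` from [run_probabilistic()].
#' @param sites Character vector of site ids (default: all sites).
#' @param n_per_site Observations per site.
#' @param seed Integer seed.
#' @param noise_sd Standard deviation of the log of the multiplicative
#'   measurement error (0 = none).
#' @return Named list, site_id -> numeric vector of observations (ng/l).
#' @export
generate_observations <- function(ct, result,
                                  sites = ct$monitoring_sites$site_id,
                                  n_per_site = 10, seed = 1, noise_sd = 0) {
  ms <- ct$monitoring_sites
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(seed, kind = "Mersenne-Twister")
  out <- list()
  for (sid in sites) {
    row <- ms[ms$site_id == sid, ]
    if (nrow(row) == 0) stop("unknown monitoring site ", sid)
    seg_i <- .segment_at_node(ct$segments, row$node)
    if (is.na(seg_i)) stop("site ", sid, " node not on the network")
    seg <- ct$segments$segment_id[seg_i]
    if (!(seg %in% rownames(result$samples)))
      stop("no simulated result for segment ", seg, " (site ", sid, ")")
    obs <- sample(result$samples[seg, ], n_per_site, replace = TRUE)
    if (noise_sd > 0)
      obs <- obs * stats::rlnorm(n_per_site, -noise_sd^2 / 2, noise_sd)
    out[[sid]] <- obs
  }
  out
}
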