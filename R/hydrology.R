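#' Accumulate local runoff contributions down the network
#'
#' Each segment's flow is its own local contribution plus the flow of all
#' direct upstream segments; flows are therefore non-decreasing downstream
#' and the outlet carries the sum of all contributions.
#'
#' @param ct A [catchment()].
#' @param local Named numeric vector of local contributions (m3/s), one
#'   entry per segment (names are `segment_id`s); all values `>= 0`.
#' @return Named numeric vector of accumulated flow per segment, in
#'   topological order of the names.
#' @export
accumulate_flow <- function(ct, local) {
  sg <- ct$segments
  if (is.null(names(local)) || !setequal(names(local), sg$segment_id))
    stop("local must be a named vector covering every segment_id")
  if (any(!is.finite(local)) || any(local < 0))
    stop("local contributions must be finite and >= 0")
  ord <- topological_order(ct)
  up <- .upstream_index(sg)
  names(up) <- sg$segment_id
  flow <- numeric(length(ord))
  names(flow) <- ord
  for (sid in ord) {
    ups <- sg$segment_id[up[[sid]]]
    flow[sid] <- local[[sid]] + sum(flow[ups])
  }
  flow
}

#' Calibrate modelled flows to gauge observations
#'
#' Every segment is scaled by the correction factor
#' `observed_mq / modelled flow` of its nearest downstream gauge, so that
#' modelled flow matches the observation exactly at every gauge.  Segments
#' downstream of the last gauge inherit the factor of the nearest upstream
#' gauge (where branches disagree, the branch with the larger modelled flow
#' wins); segments with no gauge anywhere on their path keep factor 1.
#'
#' A gauge at a node observes the flow entering that node, i.e. the sum of
#' modelled flows over segments ending there.
#'
#' @param ct A [catchment()].
#' @param modeled Named numeric vector of modelled flow per segment (m3/s).
#' @param gauges data.frame as in `ct$gauges`; defaults to `ct$gauges`.
#' @return Named numeric vector of calibrated flows (same names as
#'   `modeled`).
#' @export
calibrate_to_gauges <- function(ct, modeled, gauges = ct$gauges) {
  sg <- ct$segments
  if (is.null(names(modeled)) || !setequal(names(modeled), sg$segment_id))
    stop("modeled must be a named vector covering every segment_id")
  if (nrow(gauges) == 0) return(modeled)

  gauge_factor <- numeric(0)  # node -> factor
  for (i in seq_len(nrow(gauges))) {
    g <- gauges[i, ]
    ends <- sg$segment_id[sg$to_node == g$node]
    if (length(ends) == 0)
      stop("gauge ", g$gauge_id, " sits on a node with no inflowing segment")
    m <- sum(modeled[ends])
    if (m <= 0)
      stop("modelled flow at gauge ", g$gauge_id, " is zero; cannot calibrate")
    gauge_factor[[g$node]] <- g$observed_mq / m
  }

  ord <- topological_order(ct)
  rownames(sg) <- sg$segment_id
  # nearest downstream gauge: walk down from each segment's to_node
  down_of_node <- stats::setNames(sg$segment_id, sg$from_node)
  factor_down <- rep(NA_real_, nrow(sg))
  names(factor_down) <- sg$segment_id
  for (sid in sg$segment_id) {
    node <- sg[sid, "to_node"]
    repeat {
      if (node %in% names(gauge_factor)) {
        factor_down[sid] <- gauge_factor[[node]]
        break
      }
      nxt <- down_of_node[node]
      if (is.na(nxt)) break
      node <- sg[nxt, "to_node"]
    }
  }
  # fill the gauge-free tail from upstream, main stem first
  up <- .upstream_index(sg)
  names(up) <- sg$segment_id
  fac <- factor_down
  for (sid in ord) {
    if (!is.na(fac[sid])) next
    ups <- sg$segment_id[up[[sid]]]
    ups <- ups[!is.na(fac[ups])]
    if (length(ups) == 0) {
      fac[sid] <- 1
    } else {
      fac[sid] <- fac[ups[which.max(modeled[ups])]]
    }
  }
  modeled * fac[names(modeled)]
}

#' Fit a lognormal flow-variability distribution from MQ and Q50
#'
#' River flow is modelled as lognormal with median `q50` and mean `mq`:
#' `mu = ln(q50)` and `sigma = sqrt(2 ln(mq/q50))`, the unique lognormal
#' with those two anchors.  `mq == q50` yields the degenerate constant-flow
#' distribution (`sigma = 0`).
#'
#' @param mq Mean flow, m3/s.
#' @param q50 Median flow, m3/s; `0 < q50 <= mq`.
#' @return An object of class `flow_distribution` with fields `mu`, `sigma`.
#' @export
fit_flow_distribution <- function(mq, q50) {
  if (!is.finite(q50) || q50 <= 0) stop("q50 must be > 0")
  if (!is.finite(mq) || mq < q50) stop("mq must be >= q50")
  structure(list(mu = log(q50), sigma = sqrt(2 * log(mq / q50))),
            class = "flow_distribution")
}

#' @export
print.flow_distribution <- function(x, ...) {
  cat(sprintf("<flow_distribution> median %.4g m3/s, mean %.4g m3/s (sigma = %.4g)\n",
              exp(x$mu), exp(x$mu + x$sigma^2 / 2), x$sigma))
  invisible(x)
}

#' Sample per-segment flows at a shared quantile
#'
#' One quantile `u` drives all segments (rank-correlated sampling): the
#' whole basin is wet or dry together, preserving mass-balance coherence at
#' confluences.  `flow = exp(mu + sigma * qnorm(u))` per segment, so
#' `u = 0.5` reproduces Q50 exactly on every segment.
#'
#' @param ct A [catchment()].
#' @param u Quantile in (0, 1), shared across segments.  May be a vector;
#'   the result is then a segments x draws matrix.
#' @return Named numeric vector (or matrix, one column per `u`) of flows in
#'   m3/s.
#' @export
sample_flows <- function(ct, u) {
  if (any(!is.finite(u)) || any(u <= 0) || any(u >= 1))
    stop("u must lie strictly inside (0, 1)")
  sg <- ct$segments
  sigma <- sqrt(2 * log(sg$mq / sg$q50))
  z <- stats::qnorm(u)
  # q50 * exp(sigma z) so the median draw (z = 0) is Q50 bit-exactly
  out <- sg$q50 * exp(outer(sigma, z))
  rownames(out) <- sg$segment_id
  if (length(u) == 1) out[, 1] else out
}

#' Travel time through a segment at a given flow
#'
#' Flow velocity follows a hydraulic-geometry power law
#' `v = v_ref * (Q / MQ)^v_exponent`; travel time is `length / v` converted
#' to hours.
#'
#' @param segment One-row data.frame (a row of `ct$segments`) or a list with
#'   fields `length`, `mq`, `v_ref`, `v_exponent`.
#' @param flow Flow in m3/s, `> 0`.  Vectorised over `flow`.
#' @return Travel time in hours.
#' @export
travel_time <- function(segment, flow) {
  if (any(!is.finite(flow)) || any(flow <= 0)) stop("flow must be > 0")
  v <- segment$v_ref * (flow / segment$mq)^segment$v_exponent
  (segment$length / v) / 3600
}
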