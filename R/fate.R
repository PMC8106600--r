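# g/day -> ng/l conversion against a flow in m3/s:
# (g/d * 1e9 ng/g) / (Q m3/s * 86400 s/d * 1000 l/m3)
.CONC_FACTOR <- 1e9 / (86400 * 1000)

#' Total pseudo-first-order in-stream loss rate
#'
#' Sedimentation, volatilisation and degradation (photolysis, hydrolysis,
#' biodegradation) are lumped into additive pseudo-first-order rates:
#' `k_total = k_deg + k_sed + k_vol`.
#'
#' @param sub A [substance()].
#' @return Loss rate in 1/h.
#' @export
k_total <- function(sub) {
  ks <- c(sub$k_deg, sub$k_sed, sub$k_vol)
  if (any(!is.finite(ks)) || any(ks < 0)) stop("loss rates must be >= 0")
  sum(ks)
}

# Core routing over a matrix of flow realisations.
#   loads      named vector (wwtp_id -> g/d) or n_wwtp x n_iter matrix
#   eff_flows  named vector (wwtp_id -> m3/d)
#   river_flow named vector (segment_id -> m3/s) or n_seg x n_iter matrix
# Returns list of n_seg x n_iter matrices: m_in, m_out, q, conc.
.route_matrix <- function(ct, loads, eff_flows, river_flow, k) {
  sg <- ct$segments
  n <- nrow(sg)
  ord <- topological_order(ct)
  idx <- match(ord, sg$segment_id)
  up <- .upstream_index(sg)

  if (is.matrix(river_flow)) {
    Q_nat <- river_flow[sg$segment_id, , drop = FALSE]
  } else {
    Q_nat <- matrix(river_flow[sg$segment_id], ncol = 1,
                    dimnames = list(sg$segment_id, NULL))
  }
  n_iter <- ncol(Q_nat)
  if (!is.matrix(loads))
    loads <- matrix(loads, nrow = length(loads), ncol = n_iter,
                    dimnames = list(names(loads), NULL))

  # point inputs per segment: WWTP loads/effluent flows entering at from_node
  load_node <- matrix(0, n, n_iter)
  effq_node <- numeric(n)  # m3/s, constant across iterations
  w <- ct$wwtps
  for (i in seq_len(nrow(w))) {
    si <- which(sg$from_node == w$discharge_node[i])
    if (length(si) == 0) {
      if (any(loads[w$wwtp_id[i], ] > 0))
        stop("WWTP ", w$wwtp_id[i], " discharges at node ",
             w$discharge_node[i], " with no downstream segment")
      next
    }
    load_node[si, ] <- load_node[si, ] + loads[w$wwtp_id[i], ]
    effq_node[si] <- effq_node[si] + eff_flows[[w$wwtp_id[i]]] / 86400
  }

  m_in <- matrix(0, n, n_iter)
  m_out <- matrix(0, n, n_iter)
  q_tot <- matrix(0, n, n_iter)
  effq_cum <- numeric(n)
  for (i in idx) {
    ui <- up[[i]]
    effq_cum[i] <- effq_node[i] + sum(effq_cum[ui])
    min_i <- load_node[i, ]
    if (length(ui) == 1) {
      min_i <- min_i + m_out[ui, ]
    } else if (length(ui) > 1) {
      min_i <- min_i + colSums(m_out[ui, , drop = FALSE])
    }
    qi <- Q_nat[i, ] + effq_cum[i]
    if (any(qi <= 0 & min_i > 0))
      stop("segment ", sg$segment_id[i],
           " receives load but carries zero flow")
    m_in[i, ] <- min_i
    q_tot[i, ] <- qi
    if (k > 0) {
      tau <- (sg$length[i] /
                (sg$v_ref[i] * (qi / sg$mq[i])^sg$v_exponent[i])) / 3600
      m_out[i, ] <- min_i * exp(-k * tau)
    } else {
      m_out[i, ] <- min_i
    }
  }
  conc <- ifelse(q_tot > 0, m_in / q_tot * .CONC_FACTOR, 0)
  dimnames(conc) <- list(sg$segment_id, NULL)
  dimnames(m_in) <- dimnames(m_out) <- dimnames(q_tot) <- dimnames(conc)
  list(m_in = m_in, m_out = m_out, q = q_tot, conc = conc)
}

#' Deterministic steady-state routing of effluent loads
#'
#' Processes segments in topological order.  At each segment start the mass
#' flows of all direct upstream segments and any WWTP loads discharged at
#' the segment's head node mix completely; the concentration is reported
#' there (after mixing), so the discharge segment shows the local maximum.
#' Along the segment the mass decays as `exp(-k_total * tau)` with `tau`
#' the travel time at the segment's current flow.  Effluent flow is added
#' to the river flow from the discharge node downstream, which matters for
#' small creeks where treated wastewater dominates dilution.
#'
#' @param ct A [catchment()].
#' @param effluent_loads Named vector, wwtp_id -> effluent load in g/day.
#' @param effluent_flows Named vector, wwtp_id -> effluent flow in m3/day.
#' @param river_flows Named vector, segment_id -> natural river flow in
#'   m3/s (e.g. the `mq` column, or a draw from [sample_flows()]).
#' @param sub A [substance()] (only its loss rates are used here).
#' @return A `routing_state` data.frame with columns `segment_id`,
#'   `flow_m3s` (flow including effluent), `mass_in_g_d` (mass flow at
#'   segment start), `load_g_d` (mass flow at segment end) and `conc_ng_l`.
#' @export
route_steady_state <- function(ct, effluent_loads, effluent_flows,
                               river_flows, sub) {
  res <- .route_matrix(ct, effluent_loads, effluent_flows, river_flows,
                       k_total(sub))
  sg <- ct$segments
  out <- data.frame(segment_id = sg$segment_id,
                    flow_m3s = res$q[sg$segment_id, 1],
                    mass_in_g_d = res$m_in[sg$segment_id, 1],
                    load_g_d = res$m_out[sg$segment_id, 1],
                    conc_ng_l = res$conc[sg$segment_id, 1],
                    stringsAsFactors = FALSE, row.names = NULL)
  outlet <- sg$segment_id[!(sg$to_node %in% sg$from_node)]
  structure(out, class = c("routing_state", "data.frame"), outlet = outlet)
}

#' Mass-balance residual of a routed state
#'
#' For a conservative substance (`k_total = 0`) the mass flow leaving the
#' outlet must equal the sum of all effluent loads; the residual is the
#' absolute difference in g/day.  With losses active the outlet mass flow
#' is strictly below the input.
#'
#' @param state A `routing_state` from [route_steady_state()].
#' @param effluent_loads The loads that were routed, g/day.
#' @param sub The routed [substance()].
#' @return Residual in g/day (only meaningful for `k_total = 0`).
#' @export
mass_balance_check <- function(state, effluent_loads, sub) {
  outlet <- attr(state, "outlet")
  m_out <- sum(state$load_g_d[state$segment_id %in% outlet])
  abs(m_out - sum(effluent_loads))
}
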