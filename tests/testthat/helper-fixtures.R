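# Shared fixtures: tiny hand-made catchments and an independent
# path-enumeration routing oracle used to cross-check the engine.

# 3-segment chain  A (head) -> B -> C (outlet), nodes n1..n4,
# optional WWTP discharging at n2 (into segment B).
chain3 <- function(mq = c(1, 2, 3), local = c(1, 1, 1), with_wwtp = TRUE,
                   effluent_flow = NA_real_, v_ref = 0.5, v_exponent = 0,
                   length = c(1000, 1000, 1000), population = 10000) {
  segments <- data.frame(
    segment_id = c("A", "B", "C"),
    from_node = c("n1", "n2", "n3"), to_node = c("n2", "n3", "n4"),
    length = length, mq = mq, mnq = 0.5 * mq, q50 = 0.8 * mq,
    v_ref = v_ref, v_exponent = v_exponent,
    x = c(500, 1500, 2500), y = 0, local_mq = local,
    stringsAsFactors = FALSE)
  nodes <- data.frame(node_id = c("n1", "n2", "n3", "n4"),
                      x = c(0, 1000, 2000, 3000), y = 0,
                      stringsAsFactors = FALSE)
  wwtps <- if (with_wwtp) data.frame(
    wwtp_id = "W1", discharge_node = "n2", population_connected = population,
    treatment_category = "activated_sludge", effluent_flow = effluent_flow,
    x = 1000, y = 0, stringsAsFactors = FALSE) else NULL
  catchment(segments, nodes, wwtps)
}

# Y-confluence: A (a1->c1) and B (b1->c1) merge into C (c1->o)
y_confluence <- function(mq = c(2, 3, 5), local = c(2, 3, 0)) {
  segments <- data.frame(
    segment_id = c("A", "B", "C"),
    from_node = c("a1", "b1", "c1"), to_node = c("c1", "c1", "o"),
    length = 1000, mq = mq, mnq = 0.5 * mq, q50 = 0.8 * mq,
    v_ref = 0.5, v_exponent = 0,
    x = c(-500, 500, 0), y = c(1000, 1000, -500), local_mq = local,
    stringsAsFactors = FALSE)
  nodes <- data.frame(node_id = c("a1", "b1", "c1", "o"),
                      x = c(-1000, 1000, 0, 0), y = c(2000, 2000, 0, -1000),
                      stringsAsFactors = FALSE)
  catchment(segments, nodes)
}

test_substance <- function(k_deg = 0, k_sed = 0, k_vol = 0, f_site = 0,
                           consumption = 1, excretion = 1,
                           removal_eff = 0) {
  substance("testine", consumption, excretion, f_site = f_site,
            removal = stats::setNames(rep(removal_eff, 4),
                                      treatment_categories()),
            k_deg = k_deg, k_sed = k_sed, k_vol = k_vol)
}

mq_vector <- function(ct) stats::setNames(ct$segments$mq, ct$segments$segment_id)

# brute-force upstream segment sets by transitive expansion (oracle)
upstream_sets <- function(ct) {
  sg <- ct$segments
  n <- nrow(sg)
  direct <- lapply(seq_len(n),
                   function(i) which(sg$to_node == sg$from_node[i]))
  sets <- direct
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      grown <- unique(c(sets[[i]], unlist(sets[sets[[i]]])))
      if (length(grown) > length(sets[[i]])) {
        sets[[i]] <- grown
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  lapply(sets, function(s) sg$segment_id[s])
}

# Independent routing oracle: per-source path enumeration.  For every WWTP,
# walk its load down the unique path to the outlet, decaying by
# exp(-k * tau) per traversed segment; a segment's concentration is the sum
# of surviving source masses divided by its flow.  No topological order, no
# shared code with the engine.
route_oracle <- function(ct, loads, eff_flows, river_flows, k) {
  sg <- ct$segments
  n <- nrow(sg)
  ups <- upstream_sets(ct)
  names(ups) <- sg$segment_id
  # flow incl. effluent: add every plant discharging at or above the segment
  q_tot <- numeric(n)
  for (i in seq_len(n)) {
    heads <- c(sg$from_node[i],
               sg$from_node[match(ups[[i]], sg$segment_id)])
    w_in <- ct$wwtps$wwtp_id[ct$wwtps$discharge_node %in% heads]
    q_tot[i] <- river_flows[[sg$segment_id[i]]] +
      sum(eff_flows[w_in]) / 86400
  }
  names(q_tot) <- sg$segment_id
  tau <- function(i) {
    q <- q_tot[[sg$segment_id[i]]]
    (sg$length[i] / (sg$v_ref[i] * (q / sg$mq[i])^sg$v_exponent[i])) / 3600
  }
  next_seg <- function(i) {
    j <- which(sg$from_node == sg$to_node[i])
    if (length(j) == 0) NA_integer_ else j
  }
  m_in <- stats::setNames(numeric(n), sg$segment_id)
  for (wi in seq_len(nrow(ct$wwtps))) {
    w <- ct$wwtps[wi, ]
    i <- which(sg$from_node == w$discharge_node)
    mass <- loads[[w$wwtp_id]]
    while (!is.na(i)) {
      m_in[sg$segment_id[i]] <- m_in[sg$segment_id[i]] + mass
      mass <- mass * exp(-k * tau(i))
      i <- next_seg(i)
    }
  }
  conc <- ifelse(q_tot > 0, m_in / q_tot * 1e9 / 86400000, 0)
  list(m_in = m_in, q = q_tot, conc = conc)
}
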