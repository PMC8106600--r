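test_that("loss rates are additive", {
  expect_equal(k_total(test_substance()), 0)
  expect_equal(k_total(test_substance(k_deg = 0.1, k_sed = 0.02,
                                      k_vol = 0.03)), 0.15)
  expect_equal(k_total(test_substance(k_sed = 0.07)), 0.07)
})

test_that("routing closes units: 86.4 g/d into 1 m3/s gives 1000 ng/l", {
  ct <- chain3(mq = c(1, 1, 1), local = c(1, 0, 0), effluent_flow = 0)
  sub <- test_substance()
  state <- route_steady_state(ct, c(W1 = 86.4), c(W1 = 0),
                              mq_vector(ct), sub)
  conc <- stats::setNames(state$conc_ng_l, state$segment_id)
  expect_equal(conc[["B"]], 1000)
  expect_equal(conc[["C"]], 1000)  # conservative, same flow
  expect_equal(conc[["A"]], 0)     # upstream of the discharge
})

test_that("k_total * tau = ln 2 halves the mass over one segment", {
  # v_exponent 0, v_ref 0.5 m/s, length 1800 m -> tau = 1 h exactly
  ct <- chain3(mq = c(1, 1, 1), local = c(1, 0, 0), effluent_flow = 0,
               v_ref = 0.5, v_exponent = 0, length = rep(1800, 3))
  sub <- test_substance(k_deg = log(2))
  state <- route_steady_state(ct, c(W1 = 100), c(W1 = 0),
                              mq_vector(ct), sub)
  m <- stats::setNames(state$load_g_d, state$segment_id)
  m_in <- stats::setNames(state$mass_in_g_d, state$segment_id)
  expect_equal(m[["B"]], 50)
  expect_equal(m_in[["C"]], 50)
  expect_equal(m[["C"]], 25)
})

test_that("routing matches the per-source path-enumeration oracle", {
  for (seed in c(3, 17)) {
    ct <- generate(synth_config(n_segments = 40, n_wwtps = 5,
                                n_hospitals = 0, seed = seed))
    sub <- test_substance(k_deg = 0.05, k_sed = 0.01)
    loads <- riverpec:::.effluent_loads(sub, ct)
    effq <- riverpec:::.effluent_flows(ct)
    flows <- mq_vector(ct)
    state <- route_steady_state(ct, loads, effq, flows, sub)
    oracle <- route_oracle(ct, loads, effq, flows, k_total(sub))
    expect_equal(stats::setNames(state$conc_ng_l, state$segment_id),
                 oracle$conc[state$segment_id], tolerance = 1e-9)
    expect_equal(stats::setNames(state$flow_m3s, state$segment_id),
                 oracle$q[state$segment_id], tolerance = 1e-12)
  }
})

test_that("mass balance holds exactly for conservative substances", {
  ct <- generate(synth_config(n_segments = 35, n_wwtps = 6, n_hospitals = 0,
                              seed = 23))
  sub <- test_substance()
  loads <- riverpec:::.effluent_loads(sub, ct)
  state <- route_steady_state(ct, loads, riverpec:::.effluent_flows(ct),
                              mq_vector(ct), sub)
  expect_lt(mass_balance_check(state, loads, sub) / sum(loads), 1e-9)

  # with losses the outlet mass is strictly below the input
  subk <- test_substance(k_deg = 0.1)
  statek <- route_steady_state(ct, loads, riverpec:::.effluent_flows(ct),
                               mq_vector(ct), subk)
  outlet <- attr(statek, "outlet")
  expect_lt(statek$load_g_d[statek$segment_id == outlet], sum(loads))

  # two-source toy: outlet mass equals L1 + L2 exactly
  ct2 <- chain3()
  ct2$wwtps <- rbind(ct2$wwtps, within(ct2$wwtps, {
    wwtp_id <- "W2"; discharge_node <- "n3"
  }))
  st2 <- route_steady_state(ct2, c(W1 = 7, W2 = 5),
                            c(W1 = 0, W2 = 0), mq_vector(ct2), sub)
  expect_equal(st2$load_g_d[st2$segment_id == "C"], 12)
})

test_that("concentrations are linear and superposable in the loads", {
  ct <- generate(synth_config(n_segments = 30, n_wwtps = 4, n_hospitals = 0,
                              seed = 31))
  sub <- test_substance(k_deg = 0.08)
  effq <- riverpec:::.effluent_flows(ct)
  flows <- mq_vector(ct)
  loads <- riverpec:::.effluent_loads(sub, ct)

  c1 <- route_steady_state(ct, loads, effq, flows, sub)$conc_ng_l
  c2 <- route_steady_state(ct, 2 * loads, effq, flows, sub)$conc_ng_l
  expect_equal(c2, 2 * c1, tolerance = 1e-12)

  # superposition: each source alone, flows held identical
  ids <- names(loads)
  parts <- lapply(ids, function(w) {
    solo <- stats::setNames(ifelse(ids == w, loads, 0), ids)
    route_steady_state(ct, solo, effq, flows, sub)$conc_ng_l
  })
  expect_equal(Reduce(`+`, parts), c1, tolerance = 1e-9)
})

test_that("more dilution never raises a downstream concentration", {
  ct <- generate(synth_config(n_segments = 25, n_wwtps = 3, n_hospitals = 0,
                              seed = 41))
  sub <- test_substance(k_deg = 0.05)
  effq <- riverpec:::.effluent_flows(ct)
  loads <- riverpec:::.effluent_loads(sub, ct)
  flows <- mq_vector(ct)
  base <- route_steady_state(ct, loads, effq, flows, sub)$conc_ng_l
  flows_wet <- flows * 1.5
  wet <- route_steady_state(ct, loads, effq, flows_wet, sub)$conc_ng_l
  expect_true(all(wet <= base + 1e-12))
})

test_that("a uniform channel reproduces the closed-form decay profile", {
  # 10 equal segments, constant flow and velocity: C(x) = C0 exp(-k x / v)
  n <- 10
  segments <- data.frame(
    segment_id = sprintf("S%02d", 1:n),
    from_node = sprintf("n%02d", 1:n), to_node = sprintf("n%02d", 2:(n + 1)),
    length = 1000, mq = 1, mnq = 0.5, q50 = 1, v_ref = 0.4, v_exponent = 0,
    x = 0, y = 0, stringsAsFactors = FALSE)
  nodes <- data.frame(node_id = sprintf("n%02d", 1:(n + 1)), x = 0, y = 0)
  wwtps <- data.frame(wwtp_id = "W1", discharge_node = "n01",
                      population_connected = 0,
                      treatment_category = "activated_sludge",
                      effluent_flow = 0, x = 0, y = 0,
                      stringsAsFactors = FALSE)
  ct <- catchment(segments, nodes, wwtps)
  k <- 0.3  # 1/h
  sub <- test_substance(k_deg = k)
  state <- route_steady_state(ct, c(W1 = 86.4), c(W1 = 0),
                              mq_vector(ct), sub)
  v <- 0.4 * 3600  # m/h
  x_start <- (seq_len(n) - 1) * 1000
  expected <- 1000 * exp(-k * x_start / v)
  expect_equal(state$conc_ng_l[match(segments$segment_id,
                                     state$segment_id)],
               expected, tolerance = 1e-12)
})

test_that("loads into a dry segment are rejected with the segment named", {
  ct <- chain3(mq = c(0, 0, 0), local = c(0, 0, 0), effluent_flow = 0)
  ct$segments$mnq <- 0; ct$segments$q50 <- 0
  sub <- test_substance()
  expect_error(route_steady_state(ct, c(W1 = 10), c(W1 = 0),
                                  stats::setNames(rep(0, 3), c("A", "B", "C")),
                                  sub),
               "segment B")
})
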