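# catchment with plants at controlled positions/sizes for re-routing tests
reroute_fixture <- function(pops, xs, effluent = rep(NA_real_, length(pops))) {
  ct <- chain3()
  n <- length(pops)
  ct$wwtps <- data.frame(
    wwtp_id = sprintf("W%d", seq_len(n)),
    discharge_node = rep(c("n1", "n2", "n3"), length.out = n),
    population_connected = pops, treatment_category = "activated_sludge",
    effluent_flow = effluent, x = xs, y = 0, stringsAsFactors = FALSE)
  ct
}

test_that("re-routing moves small plants to the closest larger plant", {
  # no plant below threshold: identity, empty log
  ct <- reroute_fixture(c(5000, 8000), c(0, 1000))
  out <- reroute_small_wwtps(ct, 1000)
  expect_identical(out$wwtps, ct$wwtps)
  expect_identical(nrow(attr(out, "reroute_log")), 0L)

  # one small plant, unique larger neighbour
  ct2 <- reroute_fixture(c(800, 5000), c(0, 1000))
  out2 <- reroute_small_wwtps(ct2, 1000)
  expect_identical(out2$wwtps$wwtp_id, "W2")
  expect_equal(out2$wwtps$population_connected, 5800)
  log2 <- attr(out2, "reroute_log")
  expect_identical(log2$source, "W1")
  expect_identical(log2$target, "W2")
  expect_equal(log2$distance_m, 1000)

  # two equidistant targets: lower wwtp_id wins
  ct3 <- reroute_fixture(c(5000, 800, 5000), c(-1000, 0, 1000))
  out3 <- reroute_small_wwtps(ct3, 1000)
  expect_identical(attr(out3, "reroute_log")$target, "W1")

  # hospitals follow their plant
  ct4 <- reroute_fixture(c(900, 4000), c(0, 500))
  ct4$hospitals <- data.frame(hospital_id = "H1", receiving_wwtp = "W1",
                              patients_per_year = 1000, beds = 10,
                              department_flags = "", stringsAsFactors = FALSE)
  out4 <- reroute_small_wwtps(ct4, 1000)
  expect_identical(out4$hospitals$receiving_wwtp, "W2")

  expect_error(reroute_small_wwtps(reroute_fixture(c(200, 300), c(0, 1)),
                                   1000), "threshold")
})

test_that("re-routing conserves population and conservative effluent load", {
  ct <- generate(synth_config(n_segments = 60, n_wwtps = 10,
                              n_hospitals = 0, seed = 13,
                              small_fraction = 0.4))
  out <- reroute_small_wwtps(ct, 1000)
  expect_identical(sum(out$wwtps$population_connected),
                   sum(ct$wwtps$population_connected))
  expect_lt(nrow(out$wwtps), nrow(ct$wwtps))
  # equal removal everywhere: total effluent load unchanged
  sub <- test_substance(removal_eff = 0.35)
  expect_equal(sum(riverpec:::.effluent_loads(sub, out)),
               sum(riverpec:::.effluent_loads(sub, ct)), tolerance = 1e-12)
  # and total effluent flow too
  expect_equal(sum(riverpec:::.effluent_flows(out)),
               sum(riverpec:::.effluent_flows(ct)), tolerance = 1e-12)
})

test_that("treatment upgrades override removal for one plant only", {
  ct <- generate(synth_config(n_segments = 30, n_wwtps = 4, n_hospitals = 0,
                              seed = 19))
  sub <- test_substance(removal_eff = 0.3)
  wid <- ct$wwtps$wwtp_id[1]
  cat1 <- ct$wwtps$treatment_category[1]

  up <- upgrade_treatment(ct, wid, stats::setNames(1.0, cat1))
  loads_up <- riverpec:::.effluent_loads(sub, up)
  loads_ref <- riverpec:::.effluent_loads(sub, ct)
  expect_equal(loads_up[[wid]], 0)
  expect_equal(loads_up[names(loads_up) != wid],
               loads_ref[names(loads_ref) != wid])

  # override equal to the category default changes nothing
  same <- upgrade_treatment(ct, wid, stats::setNames(0.3, cat1))
  expect_equal(riverpec:::.effluent_loads(sub, same), loads_ref)

  expect_error(upgrade_treatment(ct, "nope", c(activated_sludge = 0.9)),
               "unknown WWTP")
  expect_error(upgrade_treatment(ct, wid, stats::setNames(1.2, cat1)),
               "\\[0, 1\\]")
})

test_that("an upgrade shrinks a segment's concentration by the superposition factor", {
  # two equal sources onto one segment; upgrading one to 0.9 removal while
  # the default is 0 leaves 0.5 + 0.5 * 0.1 = 55% of the concentration
  ct <- chain3()
  ct$wwtps <- rbind(ct$wwtps, within(ct$wwtps, wwtp_id <- "W2"))
  ct$wwtps$effluent_flow <- 0
  sub <- test_substance()
  run <- function(ctx) {
    st <- route_steady_state(ctx, riverpec:::.effluent_loads(sub, ctx),
                             riverpec:::.effluent_flows(ctx),
                             mq_vector(ctx), sub)
    st$conc_ng_l[st$segment_id == "B"]
  }
  ref <- run(ct)
  act <- run(upgrade_treatment(ct, "W2", c(activated_sludge = 0.9)))
  expect_equal(act / ref, 0.55, tolerance = 1e-12)
})

test_that("consumption change propagates linearly to all concentrations", {
  ct <- generate(synth_config(n_segments = 20, n_wwtps = 3, n_hospitals = 0,
                              seed = 29))
  sub <- test_substance(k_deg = 0.05)
  run <- function(s) {
    st <- route_steady_state(ct, riverpec:::.effluent_loads(s, ct),
                             riverpec:::.effluent_flows(ct),
                             mq_vector(ct), s)
    st$conc_ng_l
  }
  base <- run(sub)
  expect_equal(run(change_consumption(sub, 2)), 2 * base, tolerance = 1e-12)
  expect_equal(run(change_consumption(sub, 0)), 0 * base)
  expect_equal(run(change_consumption(sub, 1)), base)
  expect_error(change_consumption(sub, -1), ">= 0")
})

toy_summary <- function(ids, values) {
  data.frame(segment_id = ids, mean = values, stringsAsFactors = FALSE)
}

test_that("scenario comparison classifies by the 5% insignificance band", {
  ct <- chain3(length = c(1000, 1000, 1000))
  ref <- toy_summary(c("A", "B", "C"), c(10, 10, 10))

  same <- compare(ref, ref, ct)
  expect_true(all(same$class == "insignificant"))
  expect_equal(attr(same, "improved_km"), 0)
  expect_equal(attr(same, "deteriorated_km"), 0)

  act <- toy_summary(c("A", "B", "C"), c(9, 11, 10.1))  # -10%, +10%, +1%
  cmp <- compare(ref, act, ct)
  expect_identical(stats::setNames(cmp$class, cmp$segment_id),
                   c(A = "improved", B = "deteriorated",
                     C = "insignificant"))
  expect_equal(attr(cmp, "improved_km"), 1)
  expect_equal(attr(cmp, "deteriorated_km"), 1)

  # eps = 0: every nonzero change is classified
  cmp0 <- compare(ref, act, ct, eps = 0)
  expect_true(all(cmp0$class != "insignificant"))

  # 0/0 counts as no change
  ref0 <- toy_summary(c("A", "B", "C"), c(0, 10, 10))
  act0 <- toy_summary(c("A", "B", "C"), c(0, 10, 10))
  expect_identical(compare(ref0, act0, ct)$class[1], "insignificant")

  expect_error(compare(ref, toy_summary(c("A", "B"), c(1, 2)), ct),
               "segment sets")
})

test_that("threshold crossings account flow length above and below", {
  ct <- chain3(length = c(1000, 2000, 1500))
  ref <- toy_summary(c("A", "B", "C"), c(30, 40, 20))
  expect_equal(unname(threshold_crossings(ref, ref, ct, 35)), c(0, 0, 0))

  act <- toy_summary(c("A", "B", "C"), c(40, 30, 20))  # A up, B down
  tc <- threshold_crossings(ref, act, ct, 35)
  expect_equal(tc[["newly_above_km"]], 1)
  expect_equal(tc[["newly_below_km"]], 2)
  expect_equal(tc[["net_relief_km"]], 1)

  # antisymmetry of the net relief
  rc <- threshold_crossings(act, ref, ct, 35)
  expect_equal(rc[["net_relief_km"]], -tc[["net_relief_km"]])

  # a single segment crossing down contributes exactly its length
  one_up <- toy_summary(c("A", "B", "C"), c(30, 40, 20))
  one_dn <- toy_summary(c("A", "B", "C"), c(30, 20, 20))
  expect_equal(threshold_crossings(one_up, one_dn, ct, 35)[["net_relief_km"]],
               2)
})

test_that("exceedance length sums segment lengths above a threshold", {
  ct <- chain3(length = c(1000, 2000, 1500))
  smry <- toy_summary(c("A", "B", "C"), c(1, 2, 3))
  expect_equal(exceedance_length(smry, ct, 10), 0)
  expect_equal(exceedance_length(smry, ct, 2.5), 1.5)
  expect_equal(exceedance_length(smry, ct, 1.5), 3.5)
  # hand-summed accounting on a 10-segment fixture
  n <- 10
  segs <- data.frame(
    segment_id = sprintf("S%02d", 1:n),
    from_node = sprintf("n%02d", 1:n), to_node = sprintf("n%02d", 2:(n + 1)),
    length = seq(200, 2000, length.out = n), mq = 1, mnq = 0.5, q50 = 0.9,
    v_ref = 0.5, v_exponent = 0, x = 0, y = 0, stringsAsFactors = FALSE)
  ct10 <- catchment(segs, data.frame(node_id = sprintf("n%02d", 1:(n + 1)),
                                     x = 0, y = 0))
  vals <- c(5, 40, 5, 40, 5, 40, 5, 40, 5, 40)
  smry10 <- toy_summary(segs$segment_id, vals)
  expect_equal(exceedance_length(smry10, ct10, 35),
               sum(segs$length[vals > 35]) / 1000)
})
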