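# Per-sweep cell rules: Monod growth, contact inhibition, polarisation,
# activation, differentiation, fate decisions, SASP phases, clearance,
# background removal, TIMP, ECM production/degradation and mitosis.

test_that("Monod growth increment: zero, half-saturation and saturation limits", {
  expect_equal(monod_growth_increment(0.03, 0, 0.5), 0)
  expect_equal(monod_growth_increment(0.03, 0.5, 0.5), 0.015)
  expect_equal(monod_growth_increment(0.03, 1e9, 0.5), 0.03, tolerance = 1e-8)
  expect_error(monod_growth_increment(0.03, -1, 0.5), ">= 0")
  # monotone non-decreasing in concentration
  cc <- sort(runif(50, 0, 10))
  expect_true(all(diff(monod_growth_increment(1, cc, 0.7)) >= 0))
})

test_that("contact-inhibition gate: boundary convention is grow at Rs == T_CI", {
  expect_true(contact_inhibition_gate(1, 0.5))
  expect_false(contact_inhibition_gate(0, 0.5))
  expect_true(contact_inhibition_gate(0.5, 0.5))
})

test_that("macrophage polarisation switches strictly above INF_thr", {
  expect_equal(polarize_macrophage(c(0, 0.3, 0.6), 0.3), c("M2", "M2", "M1"))
})

test_that("fibroblast activation is strict-threshold and persistent", {
  expect_false(activate_fibroblast(FALSE, 0, 0.3))
  expect_false(activate_fibroblast(FALSE, 0.3, 0.3))
  expect_true(activate_fibroblast(FALSE, 0.31, 0.3))
  expect_true(activate_fibroblast(TRUE, 0, 0.3))
})

test_that("differentiation is binomial with the configured probability", {
  set.seed(42)
  n <- 1e4
  hits <- differentiate_myofibroblast(rep(TRUE, n), 0.25)
  se <- sqrt(0.25 * 0.75 / n)
  expect_lt(abs(mean(hits) - 0.25), 3 * se)
  expect_false(any(differentiate_myofibroblast(rep(FALSE, 100), 1)))
  expect_true(all(differentiate_myofibroblast(rep(TRUE, 100), 1)))
})

test_that("myofibroblast fate: apoptosis gates and senescence calibration", {
  expect_equal(myofibroblast_fate(0, 0, TRUE, 1, ecm_thr = 6, inf_thr = 0.3),
               "apoptosis")
  expect_equal(myofibroblast_fate(10, 0.5, TRUE, 0, 6, 0.3), "apoptosis")
  expect_equal(myofibroblast_fate(10, 0, FALSE, 1, 6, 0.3), "survive")
  expect_equal(myofibroblast_fate(6, 0, TRUE, 1, 6, 0.3), "survive") # == is neither
  set.seed(7)
  n <- 1e4
  fates <- myofibroblast_fate(rep(10, n), rep(0, n), TRUE, 0.15, 6, 0.3)
  frac <- mean(fates == "senesce")
  se <- sqrt(0.15 * 0.85 / n)
  expect_lt(abs(frac - 0.15), 3 * se)
})

test_that("SASP phase switches at T_NIS and pre-existing cells stay fibrolytic", {
  expect_equal(update_sasp_phase(0, 3), "fibrogenic")
  expect_equal(update_sasp_phase(2.99, 3), "fibrogenic")
  expect_equal(update_sasp_phase(3, 3), "fibrolytic")
  expect_equal(update_sasp_phase(0, 3, preexisting = TRUE), "fibrolytic")
})

test_that("senescent clearance gives the two triggers an equal chance", {
  set.seed(3)
  n <- 2e4
  by_contact <- clear_senescent(rep(1, n), rep(0, n), 0.3, 0.5)
  by_inf <- clear_senescent(rep(0, n), rep(1, n), 0.3, 0.5)
  expect_false(any(clear_senescent(rep(0, 100), rep(0, 100), 0.3, 1)))
  expect_true(all(clear_senescent(rep(1, 100), rep(0, 100), 0.3, 1)))
  # two-proportion test at alpha = 0.01: rates indistinguishable
  tst <- prop.test(c(sum(by_contact), sum(by_inf)), c(n, n))
  expect_gt(tst$p.value, 0.01)
})

test_that("per-sweep probability conversions match Bernoulli sampling", {
  expect_equal(per_sweep_probability(0.15, 1), 0.15)
  expect_equal(per_sweep_probability(0.15, 1 / 64),
               1 - (1 - 0.15)^(1 / 64))
  expect_equal(per_sweep_probability(0.5, 0.25, "rate"), 1 - exp(-0.125))
  # mu-to-probability calibration: removal fraction ~ p over many draws
  set.seed(9)
  p_rm <- per_sweep_probability(0.64, 1 / 64, "rate")  # = 1 - exp(-0.01)
  n <- 1e4
  hits <- runif(n) < p_rm
  se <- sqrt(p_rm * (1 - p_rm) / n)
  expect_lt(abs(mean(hits) - p_rm), 3 * se)
})

test_that("TIMP rule subtracts MMP_thr at myofibroblast COMs, clamped at zero", {
  p <- fixture_params()
  thr <- p$thresholds$mmp_thr
  for (mmp0 in c(0, thr, 3 * thr)) {
    # fresh cell each time (a myofibroblast without ECM contact apoptoses
    # during the same sweep, after the TIMP step)
    sim <- fixture_sim(list(list(x = 3:5, y = 3:5, type = "Myofibroblast")),
                       params = p)
    set_field_matrix(sim, "mmp", matrix(mmp0, 12, 12))
    behaviour_sweep(sim)
    expect_equal(field_matrix(sim, "mmp")[4, 4], max(0, mmp0 - thr),
                 tolerance = 1e-12)
  }
})

test_that("ECM degradation removes exactly the over-threshold ECM cells", {
  p <- fixture_params()
  cells <- list(list(x = 2, y = 2, type = "ECM"),
                list(x = 8, y = 8, type = "ECM"),
                list(x = 2, y = 8, type = "ECM"))
  sim <- fixture_sim(cells, params = p)
  mmp <- matrix(0, 12, 12)
  mmp[8, 8] <- 2 * p$thresholds$mmp_thr     # only this one exceeds
  set_field_matrix(sim, "mmp", mmp)
  behaviour_sweep(sim)
  tab <- cell_table(sim)
  expect_setequal(tab$id[tab$type_name == "ECM"], c(1, 3))
  expect_equal(sim$counters$ecm_degraded, 1)
})

test_that("ECM production is PDGF-gated and myofibroblasts deposit double", {
  p <- fixture_params(rules = list(sweep_period_mcs = 3200))  # 1 sweep = 1 day
  below <- fixture_sim(list(list(x = 5:7, y = 5:7, type = "Fibroblast")),
                       params = p)
  below$flags$activated <- TRUE
  behaviour_sweep(below)
  expect_equal(sum(cell_table(below)$type_name == "ECM"), 0)

  count_ecm <- function(type, seed) {
    sim <- fixture_sim(list(list(x = 5:7, y = 5:7, type = type)),
                       width = 20, height = 20, params = p, seed = seed)
    sim$flags$activated <- TRUE
    set_field_matrix(sim, "pdgf",
                     matrix(p$thresholds$pdgf_f * 2, 20, 20))
    set.seed(seed)
    behaviour_sweep(sim)
    sum(cell_table(sim)$type_name == "ECM")
  }
  nf <- mean(vapply(1:4, function(s) count_ecm("Fibroblast", s), 0))
  nm <- mean(vapply(1:4, function(s) count_ecm("Myofibroblast", s), 0))
  expect_equal(nf, p$rules$ecm_fib_per_day, tolerance = 0.35)
  expect_equal(nm / nf, 2, tolerance = 0.3)
})

test_that("mitosis splits a block cell into two near-equal daughters", {
  p <- fixture_params()
  sim <- fixture_sim(list(list(x = 5:8, y = 5:8, type = "Fibroblast")),
                     width = 16, height = 16, params = p)
  sim$flags$orig_tv <- 8        # doubling volume = 16 = current volume
  div <- dermalCPM:::cpp_divide_cells(sim$ptr, 1L)
  expect_equal(nrow(div), 1)
  tab <- dermalCPM:::cpp_cells_table(sim$ptr)
  expect_equal(sort(tab$volume), c(8, 8))
  # below doubling volume: no division in a sweep
  sim2 <- fixture_sim(list(list(x = 5:8, y = 5:8, type = "Fibroblast")),
                      params = p)
  sim2$flags$orig_tv <- 10      # 2 * 10 - 1 > 16
  behaviour_sweep(sim2)
  expect_equal(nrow(cell_table(sim2)), 1)
})

test_that("random-axis division through the COM balances daughters", {
  p <- fixture_params()
  diffs <- vapply(1:300, function(seed) {
    sim <- fixture_sim(list(list(x = 5:8, y = 5:8, type = "Fibroblast")),
                       width = 16, height = 16, params = p, seed = seed)
    div <- dermalCPM:::cpp_divide_cells(sim$ptr, 1L)
    tab <- dermalCPM:::cpp_cells_table(sim$ptr)
    abs(diff(tab$volume))
  }, 0)
  expect_gte(mean(diffs <= 1), 0.99)
})

test_that("juxtacrine and paracrine senescence follow contact + field gates", {
  p <- fixture_params(rules = list(t_sen = 0, t_sen_unit = "days", p_snc = 0))
  th <- p$thresholds
  base <- list(list(x = 3:5, y = 3:5, type = "Myofibroblast"),
               list(x = 6:8, y = 3:5, type = "SenescentMyofibroblast"))
  # ensure the myofibroblast survives its fate checks: plenty of ECM contact
  ecm <- lapply(2:5, function(i) list(x = 2, y = i, type = "ECM"))

  # fibrogenic neighbour + PDGF above SNC_thr -> juxtacrine
  sim <- fixture_sim(c(base, ecm), params = p)
  sim$flags$sen_clock[2] <- 0
  set_field_matrix(sim, "pdgf", matrix(th$snc_thr * 1.5, 12, 12))
  behaviour_sweep(sim)
  expect_equal(cell_table(sim)$type_name[1], "SenescentMyofibroblast")
  expect_equal(sim$counters$juxtacrine, 1)

  # fibrogenic neighbour but PDGF below SNC_thr -> no transition
  sim2 <- fixture_sim(c(base, ecm), params = p)
  sim2$flags$sen_clock[2] <- 0
  set_field_matrix(sim2, "pdgf", matrix(th$snc_thr * 0.5, 12, 12))
  behaviour_sweep(sim2)
  expect_equal(cell_table(sim2)$type_name[1], "Myofibroblast")

  # fibrolytic neighbour + INF below INF_thr -> no transition
  sim3 <- fixture_sim(c(base, ecm), params = p)
  sim3$flags$sen_clock[2] <- p$rules$t_nis_days + 1
  behaviour_sweep(sim3)
  expect_equal(cell_table(sim3)$type_name[1], "Myofibroblast")

  # no senescent neighbour -> no transition even with permissive fields
  sim4 <- fixture_sim(c(base[1], ecm), params = p)
  set_field_matrix(sim4, "pdgf", matrix(th$snc_thr * 2, 12, 12))
  behaviour_sweep(sim4)
  expect_equal(cell_table(sim4)$type_name[1], "Myofibroblast")
})

test_that("background removal: CSF1 withdrawal removes macrophages", {
  p <- fixture_params(rules = list(mu = 0))
  sim <- fixture_sim(list(list(x = 3:5, y = 3:5, type = "Macrophage")),
                     params = p)
  # CSF1 = 0 < csf1_thr everywhere
  behaviour_sweep(sim)
  expect_equal(nrow(cell_table(sim)), 0)
  # above threshold: survives with mu = 0
  sim2 <- fixture_sim(list(list(x = 3:5, y = 3:5, type = "Macrophage")),
                      params = p)
  set_field_matrix(sim2, "csf1", matrix(p$thresholds$csf1_thr * 2, 12, 12))
  behaviour_sweep(sim2)
  expect_equal(nrow(cell_table(sim2)), 1)
})

test_that("senescence bookkeeping balances inductions against clearances", {
  p <- sim_params(init = list(width = 48, height = 48, wound_margin = 12,
                              n_macrophages = 2, n_preexisting = 2))
  sim <- build_initial_state(p, seed = 5)
  for (i in 1:40) { run_mcs(sim, 25, fields = TRUE); behaviour_sweep(sim) }
  tab <- cell_table(sim)
  current <- sum(tab$type_name %in% c("SenescentMyofibroblast",
                                      "InflammatorySenescent"))
  cnt <- sim$counters
  expect_equal(cnt$primary + cnt$juxtacrine + cnt$paracrine +
                 cnt$preexisting - cnt$cleared, current)
})

test_that("with P_SNC = 0 and no pre-existing cells, no senescent cell ever exists", {
  p <- fixture_params(rules = list(p_snc = 0))
  sim <- build_initial_state(p, seed = 6)
  for (i in 1:30) {
    run_mcs(sim, 25, fields = TRUE)
    behaviour_sweep(sim)
    tab <- cell_table(sim)
    expect_equal(sum(tab$type_name %in% c("SenescentMyofibroblast",
                                          "InflammatorySenescent")), 0)
  }
})
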