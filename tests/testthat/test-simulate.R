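test_that("simulation output is deterministic in the root seed", {
  p <- tiny_sim_params(sd_dic_rel = 0.02, sd_delta_permil = 5, seed = 7)
  a <- simulate_incubation(p)
  b <- simulate_incubation(p)
  expect_identical(a$incubation, b$incubation)
  expect_identical(a$amino_acids, b$amino_acids)
  p2 <- tiny_sim_params(sd_dic_rel = 0.02, sd_delta_permil = 5, seed = 8)
  c <- simulate_incubation(p2)
  expect_false(identical(a$incubation$dic_umol, c$incubation$dic_umol))
  expect_identical(a$truth, c$truth)  # truth is noise-free
})

test_that("carbon and 13C ledgers close without noise", {
  p <- tiny_sim_params()
  tr <- simulate_incubation(p)$truth
  s0 <- p$label_umol_13c / p$x_substrate
  # substrate carbon: remaining + biomass + respired == added
  expect_equal(
    tr$substrate_pool_c + tr$biomass_c + tr$q_substrate_dic_c,
    rep(s0, nrow(tr)), tolerance = 1e-9
  )
  # 13C: every substrate-derived pool carries x_substrate
  expect_equal(
    p$x_substrate * (tr$substrate_pool_c + tr$biomass_c) + tr$di13c_true,
    rep(p$label_umol_13c, nrow(tr)), tolerance = 1e-9
  )
  # DIC bookkeeping is consistent with the pool ledgers
  expect_equal(
    tr$dic_treat_umol,
    p$dic0_umol + tr$q_substrate_dic_c + tr$indigenous_true_c,
    tolerance = 1e-9
  )
})

test_that("no priming flux means no treatment-control difference", {
  p <- tiny_sim_params(alpha = 0)
  tr <- simulate_incubation(p)$truth
  expect_equal(tr$priming_true_c, rep(0, nrow(tr)), tolerance = 1e-12)
})

test_that("cumulative mineralization is monotone and priming grows with alpha", {
  p <- tiny_sim_params()
  tr <- simulate_incubation(p)$truth
  expect_true(all(diff(tr$di13c_true) >= 0))
  tr_hi <- simulate_incubation(tiny_sim_params(alpha = 2 * p$alpha))$truth
  expect_true(all(tr_hi$priming_true_c[-1] > tr$priming_true_c[-1]))
})

test_that("halving the integration step changes harvests by under 0.1%", {
  tr1 <- simulate_incubation(tiny_sim_params())$truth
  tr2 <- simulate_incubation(tiny_sim_params(step_days = 0.5))$truth
  for (col in c("di13c_true", "indigenous_true_c", "b13_true")) {
    d <- tr1[[col]][-1]
    expect_lt(max(abs(tr2[[col]][-1] - d) / pmax(abs(d), 1e-12)), 1e-3)
  }
})

test_that("the pipeline is an identity on noise-free simulator output", {
  p <- default_paper_scenario()
  sim <- simulate_incubation(p)
  est <- analyze_incubation(
    sim$incubation, sim$amino_acids,
    x_substrate = p$x_substrate, label_umol_13c = p$label_umol_13c,
    units_12c = "total_c"
  )
  joined <- dplyr::inner_join(est, sim$truth, by = c("depth_zone", "day")) |>
    dplyr::filter(.data$day > 0)
  expect_equal(joined$di13c_umol_mean, joined$di13c_true, tolerance = 1e-6)
  expect_equal(joined$di12c_umol_mean, joined$indigenous_true_c,
               tolerance = 1e-6)
  expect_equal(joined$b13_umol, joined$b13_true, tolerance = 1e-6)
  expect_equal(joined$cue, joined$cue_realized, tolerance = 1e-6)
})

test_that("the calibrated default scenario reproduces the printed summary", {
  p <- default_paper_scenario()
  sim <- simulate_incubation(p)
  est <- analyze_incubation(
    sim$incubation, sim$amino_acids,
    x_substrate = p$x_substrate, label_umol_13c = p$label_umol_13c
  )
  d400 <- dplyr::filter(est, .data$day == 400)
  expect_equal(round(100 * d400$fraction_mineralized), 63)
  expect_equal(round(d400$cue, 2), 0.09)
  expect_equal(round(d400$priming_factor, 1), 2.5)
  d8 <- dplyr::filter(est, .data$day == 8)
  expect_equal(round(d8$cue, 2), 0.58)
  # measured columns land near the published shallow-lipid values
  expect_equal(d400$di13c_umol_mean, 10.4, tolerance = 0.1)
  expect_equal(d400$priming_umol, 30.6, tolerance = 0.1)
  expect_equal(d400$di12c_control_umol, 21.0, tolerance = 0.1)
  expect_equal(d400$b13_umol, 1.08, tolerance = 0.01)
})

test_that("parameter recovery is exact at zero noise", {
  p <- tiny_sim_params()
  rec <- recovery_experiment(p, n_seeds = 1)
  expect_true(all(abs(rec$median_rel_error) < 1e-3))
})
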