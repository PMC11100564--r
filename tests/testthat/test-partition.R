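test_that("substrate_fraction handles end-member limits and bad input", {
  x_bg <- delta_to_atom_fraction(-20)
  expect_equal(substrate_fraction(x_bg, x_bg, 0.99), 0)
  expect_equal(substrate_fraction(0.99, x_bg, 0.99), 1)
  # inversion of the forward mixing oracle
  x_mix <- (90 * delta_to_atom_fraction(0) + 10 * 0.99) / 100
  expect_equal(substrate_fraction(x_mix, delta_to_atom_fraction(0), 0.99),
               0.1, tolerance = 1e-4)
  expect_error(substrate_fraction(0.5, 0.99, 0.5), "indistinguishable")
  expect_warning(substrate_fraction(0.9, 0.01, 0.5), "clipped")
  expect_equal(suppressWarnings(substrate_fraction(0.9, 0.01, 0.5)), 1)
})

test_that("a treated series identical to the control partitions to zero label", {
  days <- c(0, 10, 30)
  fx <- make_partition_fixture(days, di13c_sched = c(0, 0, 0),
                               indig_sched = c(0, 20, 50),
                               ctrl_sched = c(0, 20, 50))
  part <- partition_incubation(fx, x_substrate = 0.99, units_12c = "total_c")
  expect_equal(part$f_substrate, rep(0, 3))
  expect_equal(part$di13c_umol, rep(0, 3))
  expect_equal(part$di12c_umol, c(0, 20, 50), tolerance = 1e-9)
  expect_equal(part$di12c_control_umol, c(0, 20, 50), tolerance = 1e-9)
})

test_that("partitioning inverts forward-simulated schedules exactly", {
  days <- c(0, 100, 300)
  fx <- make_partition_fixture(days, di13c_sched = c(0, 5, 10),
                               indig_sched = c(0, 20, 50))
  part <- partition_incubation(fx, x_substrate = 0.99, units_12c = "total_c")
  expect_equal(part$di13c_umol, c(0, 5, 10), tolerance = 1e-6)
  expect_equal(part$di12c_umol, c(0, 20, 50), tolerance = 1e-6)

  # 12C units differ from total carbon by the (1 - x_bg) factor
  part12 <- partition_incubation(fx, x_substrate = 0.99, units_12c = "12c")
  expect_equal(part12$di12c_umol, part$di12c_umol * (1 - part$x_bg),
               tolerance = 1e-12)
})

test_that("a fixture inverted from the published day-400 row reproduces it", {
  days <- c(0, 8, 46, 180, 400)
  fx <- make_partition_fixture(
    days,
    di13c_sched = c(0, 0.7, 6, 6.9, 10.4),
    indig_sched = c(0, 2, 7, 17.1, 51.6),
    ctrl_sched = c(0, 0.7, 4.0, 16.5, 21.0)
  )
  part <- partition_incubation(fx, x_substrate = 0.99, units_12c = "total_c")
  d400 <- part[part$day == 400, ]
  expect_equal(d400$di13c_umol, 10.4, tolerance = 1e-6)
  expect_equal(d400$di12c_umol, 51.6, tolerance = 1e-6)
  expect_equal(d400$di12c_umol - d400$di12c_control_umol, 30.6,
               tolerance = 1e-6)
})

test_that("mass balance closes at every time point", {
  set.seed(11)
  for (i in 1:10) {
    days <- c(0, sort(sample(1:400, 4)))
    di13 <- c(0, cumsum(runif(4, 0, 3)))
    ind <- c(0, cumsum(runif(4, 0, 15)))
    fx <- make_partition_fixture(days, di13, ind, dic0 = runif(1, 50, 300))
    part <- partition_incubation(fx, x_substrate = 0.99,
                                 units_12c = "total_c")
    total_prod <- (fx$dic_umol[fx$treatment == "lipid"] -
                     fx$dic_umol[fx$treatment == "lipid"][1])
    expect_equal(part$di13c_umol / 0.99 + part$di12c_umol, total_prod,
                 tolerance = 1e-9)
  }
})

test_that("control series on a different day grid are interpolated", {
  x_bg <- delta_to_atom_fraction(-20)
  treated_days <- c(0, 8, 33)
  control_days <- c(0, 13, 46)
  # treated bottle: pure substrate signal on constant background
  sub_c <- c(0, 1, 3)
  dic_t <- 100 + sub_c
  x_t <- (100 * x_bg + sub_c * 0.99) / dic_t
  fx <- dplyr::bind_rows(
    tibble::tibble(treatment = "lipid", depth_zone = "20-45", replicate = 1L,
                   day = treated_days, dic_umol = dic_t,
                   d13c_dic_permil = atom_fraction_to_delta(x_t)),
    tibble::tibble(treatment = "control", depth_zone = "20-45", replicate = 1L,
                   day = control_days, dic_umol = c(100, 102, 106),
                   d13c_dic_permil = atom_fraction_to_delta(rep(x_bg, 3)))
  )
  part <- partition_incubation(fx, x_substrate = 0.99, units_12c = "total_c")
  expect_equal(part$di13c_umol, sub_c * 0.99, tolerance = 1e-6)
  # control production linearly interpolated: day 8 of a 2/13-days ramp
  expect_equal(part$di12c_control_umol[part$day == 8], 2 * 8 / 13,
               tolerance = 1e-9)
})

test_that("missing day 0 and missing controls are handled explicitly", {
  days <- c(0, 10)
  fx <- make_partition_fixture(days, c(0, 1), c(0, 5))
  expect_error(
    partition_incubation(fx[fx$day != 0 | fx$treatment == "control", ],
                         x_substrate = 0.99),
    "day-0"
  )
  expect_warning(
    partition_incubation(fx[fx$treatment != "control", ], x_substrate = 0.99),
    "no control series"
  )
})

test_that("priming is the treatment-control difference and is antisymmetric", {
  pr <- priming(51.6, 21.0)
  expect_equal(pr$priming_umol, 30.6)
  expect_equal(round(pr$priming_factor, 1), 2.5)
  deep <- priming(100, 16.0)
  expect_equal(deep$priming_umol, 84)
  expect_equal(deep$priming_factor, 6.25)
  expect_equal(priming(10, 10)$priming_umol, 0)
  expect_equal(priming(10, 10)$priming_factor, 1)
  # antisymmetry under swapping the roles
  expect_equal(priming(33, 12)$priming_umol, -priming(12, 33)$priming_umol)
  expect_true(is.na(priming(5, 0)$priming_factor))
})

test_that("replicate summaries average triplicates and carry priming", {
  days <- c(0, 100)
  fx <- dplyr::bind_rows(lapply(1:3, function(r) {
    make_partition_fixture(days, c(0, 5 + r * 0.3), c(0, 20),
                           ctrl_sched = c(0, 10), replicate = r)
  }))
  summ <- partition_incubation(fx, x_substrate = 0.99,
                               units_12c = "total_c") |>
    summarize_partition()
  d <- summ[summ$day == 100, ]
  expect_equal(d$di13c_umol_mean, mean(5 + (1:3) * 0.3), tolerance = 1e-6)
  expect_equal(d$di13c_umol_sd, sd(5 + (1:3) * 0.3), tolerance = 1e-4)
  expect_equal(d$priming_umol, 10, tolerance = 1e-6)
  expect_equal(d$priming_factor, 2, tolerance = 1e-6)
})
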