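test_that("amino-acid carbon normalisation follows stoichiometry", {
  gly <- tibble::tibble(aa_code = "Gly", conc_nmol_per_g = 500)
  out <- aa_mole_c(gly)
  expect_equal(out$umol_c_per_g, 1.0)
  expect_equal(out$mole_c_fraction, 1.0)

  two <- tibble::tibble(aa_code = c("Gly", "Phe"),
                        conc_nmol_per_g = c(100, 100))
  out2 <- aa_mole_c(two)
  expect_equal(out2$mole_c_fraction, c(2 / 11, 9 / 11))

  expect_error(aa_mole_c(two[0, ]), "empty")
  expect_error(
    aa_mole_c(tibble::tibble(aa_code = "Xyz", conc_nmol_per_g = 1)), "Xyz"
  )
})

test_that("protein 13C recovers forward-mixed label and subtracts background", {
  x_nat <- delta_to_atom_fraction(-15)
  bg <- make_aa_profile(c("Ala", "Gly"), c(0.5, 0.3), x_nat)
  expect_equal(protein_13c(bg, bg)$protein_13c_umol, 0, tolerance = 1e-12)

  # forward oracle: add 0.10 umol C of pure-label alanine onto background
  add_c <- 0.10
  tot_ala <- 0.5 + add_c
  x_ala <- (0.5 * x_nat + add_c * 0.99) / tot_ala
  labelled <- make_aa_profile(c("Ala", "Gly"), c(tot_ala, 0.3),
                              c(x_ala, x_nat), day = 400)
  got <- protein_13c(labelled, bg)$protein_13c_umol
  expect_equal(got, add_c * (0.99 - x_nat), tolerance = 1e-9)

  # per-bottle scaling through the dry mass
  labelled5 <- dplyr::mutate(labelled, dry_mass_g = 5)
  expect_equal(protein_13c(labelled5, bg)$protein_13c_umol, 5 * got,
               tolerance = 1e-9)

  # mismatched amino-acid sets fall back to the intersection with a warning
  expect_warning(
    out <- protein_13c(labelled, bg[bg$aa_code == "Ala", ]),
    "intersection"
  )
  expect_equal(out$protein_13c_umol, add_c * (0.99 - x_nat),
               tolerance = 1e-9)
})

test_that("protein to biomass conversion uses the 60% protein share", {
  expect_equal(protein_to_biomass(0.65), 1.08, tolerance = 0.005 / 1.08)
  expect_equal(protein_to_biomass(0), 0)
  expect_equal(protein_to_biomass(0.6), 1.0)
  expect_equal(protein_to_biomass(1, protein_fraction = 0.5), 2)
})

test_that("carbon use efficiency matches published cells and is scale-free", {
  expect_equal(round(cue(0.95, 0.7), 2), 0.58)
  expect_equal(round(cue(1.85, 6), 2), 0.24)
  expect_equal(cue(0, 3), 0)
  expect_warning(out <- cue(0, 0), "undefined")
  expect_true(is.na(out))
  for (a in c(0.1, 2, 100)) {
    expect_equal(cue(a * 1.85, a * 6), cue(1.85, 6), tolerance = 1e-12)
  }
})

test_that("equal-CUE biomass estimate matches published cells and its identity", {
  c1 <- cue(0.95, 0.7)
  expect_equal(round(estimate_indigenous_biomass(c1, 1.3 + 0.7), 2), 2.71)
  c2 <- cue(0.47, 0.8)
  expect_equal(round(estimate_indigenous_biomass(c2, 8.2 + 2.1), 2), 6.05)
  expect_equal(estimate_indigenous_biomass(0, 10), 0)
  expect_error(estimate_indigenous_biomass(1, 10), "CUE")

  # algebraic identity: b12 / (b12 + di12c_total) = cue
  for (cc in c(0.05, 0.3, 0.9)) {
    b12 <- estimate_indigenous_biomass(cc, 7.3)
    expect_equal(b12 / (b12 + 7.3), cc, tolerance = 1e-12)
  }
})

test_that("every published summary row is reconstructed from its measured cells", {
  ref <- read_reference_summary()
  derived <- ref |>
    dplyr::rename(cue_printed = "cue", b12_printed = "b12_umol") |>
    derive_summary()
  expect_equal(nrow(derived), 8)
  expect_true(all(abs(derived$cue - derived$cue_printed) <= 0.01 + 1e-9))
  expect_true(all(abs(derived$b12_umol - derived$b12_printed) <= 0.02 + 1e-9))
})

test_that("degradation index standardises composition and ignores scale", {
  model <- dauwe_di_model()
  # a profile exactly at the reference means scores zero
  ref_prof <- tibble::tibble(aa_code = model$table$aa_code,
                             conc_nmol_per_g = model$table$mean_molpct)
  expect_equal(degradation_index(ref_prof, model), 0, tolerance = 1e-12)
  expect_equal(degradation_index(
    dplyr::mutate(ref_prof, conc_nmol_per_g = conc_nmol_per_g * 37), model
  ), 0, tolerance = 1e-12)

  # two-variable toy model, hand evaluation:
  # (70-60)/10 * 0.5 + (30-40)/5 * (-0.2) = 0.9
  toy <- di_model(tibble::tibble(aa_code = c("Gly", "Ala"),
                                 mean_molpct = c(60, 40),
                                 sd_molpct = c(10, 5),
                                 loading = c(0.5, -0.2)))
  expect_equal(degradation_index(
    tibble::tibble(aa_code = c("Gly", "Ala"), conc_nmol_per_g = c(70, 30)),
    toy
  ), 0.9, tolerance = 1e-12)

  # perturbing along the loadings moves the score in the loading direction:
  # fresh plankton-like material is enriched in positively loaded acids
  fresh <- dplyr::mutate(
    ref_prof,
    conc_nmol_per_g = conc_nmol_per_g * (1 + 0.3 * (model$table$loading > 0))
  )
  degraded <- dplyr::mutate(
    ref_prof,
    conc_nmol_per_g = conc_nmol_per_g * (1 + 0.3 * (model$table$loading < 0))
  )
  expect_gt(degradation_index(fresh, model), 0)
  expect_lt(degradation_index(degraded, model), 0)

  expect_error(degradation_index(ref_prof[-1, ], model),
               model$table$aa_code[1])
})
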