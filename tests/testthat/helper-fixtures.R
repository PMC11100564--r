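# Forward-constructed fixtures: build measurement tables from known true
# schedules so that the analysis can be checked by inversion. These are the
# oracles -- they use only the mixing arithmetic, never the pipeline.

# One treated + one control series from true cumulative schedules.
# di13c_sched: umol 13C mineralized from substrate (cumulative since day 0);
# indig_sched: umol total indigenous C mineralized in the treated bottle;
# ctrl_sched: same for the control bottle.
make_partition_fixture <- function(days,
                                   di13c_sched,
                                   indig_sched,
                                   ctrl_sched = indig_sched * 0,
                                   x_sub = 0.99,
                                   delta_bg = -20,
                                   dic0 = 100,
                                   treatment = "lipid",
                                   depth_zone = "20-45",
                                   replicate = 1L) {
  x_bg <- delta_to_atom_fraction(delta_bg)
  sub_c <- di13c_sched / x_sub
  dic_t <- dic0 + sub_c + indig_sched
  x_t <- (dic0 * x_bg + sub_c * x_sub + indig_sched * x_bg) / dic_t
  dic_c <- dic0 + ctrl_sched
  x_c <- rep(x_bg, length(days))
  dplyr::bind_rows(
    tibble::tibble(
      treatment = treatment, depth_zone = depth_zone, replicate = replicate,
      day = days, dic_umol = dic_t,
      d13c_dic_permil = atom_fraction_to_delta(x_t)
    ),
    tibble::tibble(
      treatment = "control", depth_zone = depth_zone, replicate = replicate,
      day = days, dic_umol = dic_c,
      d13c_dic_permil = atom_fraction_to_delta(x_c)
    )
  )
}

# A tiny amino-acid profile with given per-acid carbon amounts (umol C/g)
# and atom fractions.
make_aa_profile <- function(aa_code, umol_c_per_g, x, dry_mass_g = 1,
                            day = 0, replicate = 1L,
                            treatment = "lipid", depth_zone = "20-45") {
  counts <- aa_carbon_counts()
  n_c <- counts$carbon_atoms[match(aa_code, counts$aa_code)]
  tibble::tibble(
    treatment = treatment, depth_zone = depth_zone,
    replicate = replicate, day = day,
    aa_code = aa_code,
    conc_nmol_per_g = umol_c_per_g / n_c * 1000,
    d13c_permil = atom_fraction_to_delta(x),
    dry_mass_g = dry_mass_g
  )
}

# Reference harvest-day summary shipped with the package.
read_reference_summary <- function() {
  readr::read_csv(
    system.file("extdata", "lipid_incubation_summary.csv",
                package = "sedprime"),
    comment = "#", show_col_types = FALSE
  )
}

# Small fast simulator parameter set for property tests.
tiny_sim_params <- function(...) {
  sim_params(harvest_days = c(0, 5, 20, 60), n_replicates = 2, ...)
}
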