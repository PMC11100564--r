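#' Full tracer mass-balance analysis of an incubation data set
#'
#' Runs the whole analysis chain on tidy measurement tables: partitions the
#' evolved DIC of every labelled bottle into substrate-derived and
#' indigenous carbon against the unamended control
#' ([partition_incubation()]), averages replicates and quantifies priming
#' ([summarize_partition()]), quantifies 13C in new biomass from the
#' amino-acid profiles ([protein_13c()], [protein_to_biomass()]), and
#' derives carbon use efficiency and the equal-CUE estimate of biomass
#' built from indigenous OM.
#'
#' @param incubation Incubation measurements (incubation schema; see
#'   [read_incubation_csv()]), containing control and amended bottles.
#' @param amino_acids Optional amino-acid profiles (amino-acid schema) for
#'   the amended bottles; when `NULL` the biomass/CUE columns are `NA`.
#' @param x_substrate 13C atom fraction of the added substrate.
#' @param label_umol_13c Optional micromoles of 13C added; enables the
#'   `fraction_mineralized` column.
#' @param protein_fraction Protein share of biomass carbon (default 0.6).
#' @param units_12c Units for indigenous carbon, see
#'   [partition_incubation()].
#' @param aa_background Baseline for amino-acid excess 13C: `"day0"`
#'   (default) uses the day-0 profiles of the same treatment, `"control"`
#'   the control-treatment profiles.
#' @param noise_tol Passed to [substrate_fraction()].
#' @param r_standard Isotope standard ratio.
#' @return A tibble with one row per treatment x depth x harvest day:
#'   `di13c_umol_mean` (and sd), `priming_umol`, `di12c_control_umol`,
#'   `b13_umol`, `b12_umol`, `cue`, plus `di12c_umol_mean`,
#'   `priming_factor`, `f_substrate_mean` and (when the label amount is
#'   given) `fraction_mineralized`. If the input contains only control
#'   bottles, a control-production summary is returned with the
#'   treatment-dependent columns `NA`.
#' @export
analyze_incubation <- function(incubation, amino_acids = NULL,
                               x_substrate,
                               label_umol_13c = NULL,
                               protein_fraction = 0.6,
                               units_12c = c("12c", "total_c"),
                               aa_background = c("day0", "control"),
                               noise_tol = 0.05,
                               r_standard = R_VPDB) {
  units_12c <- match.arg(units_12c)
  aa_background <- match.arg(aa_background)
  incubation <- tibble::as_tibble(incubation)

  if (all(incubation$treatment == "control")) {
    bg <- control_background(incubation, r_standard)
    scale <- if (units_12c == "12c") (1 - bg$x_bg) else 1
    return(tibble::tibble(
      treatment = "control",
      depth_zone = bg$depth_zone,
      day = bg$day,
      di13c_umol_mean = NA_real_, di13c_umol_sd = NA_real_,
      di12c_umol_mean = NA_real_, di12c_umol_sd = NA_real_,
      di12c_control_umol = bg$production_umol * scale,
      priming_umol = NA_real_, priming_factor = NA_real_,
      f_substrate_mean = NA_real_, f_substrate_sd = NA_real_,
      b13_umol = NA_real_, cue = NA_real_, b12_umol = NA_real_
    ))
  }

  summ <- partition_incubation(
    incubation, x_substrate = x_substrate, r_standard = r_standard,
    units_12c = units_12c, noise_tol = noise_tol
  ) |>
    summarize_partition()

  if (!is.null(amino_acids) && nrow(tibble::as_tibble(amino_acids)) > 0) {
    amino_acids <- tibble::as_tibble(amino_acids)
    b13 <- amino_acids |>
      dplyr::filter(.data$treatment != "control") |>
      dplyr::group_by(trt_ = .data$treatment, depth_ = .data$depth_zone) |>
      dplyr::group_modify(function(d, key) {
        bg_rows <- if (aa_background == "day0") {
          dplyr::filter(d, .data$day == 0)
        } else {
          dplyr::filter(amino_acids, .data$treatment == "control",
                        .data$depth_zone == key$depth_)
        }
        if (nrow(bg_rows) == 0) {
          rlang::abort(sprintf(
            "no %s background amino-acid profile for %s / %s",
            aa_background, key$trt_, key$depth_
          ))
        }
        protein_13c(d, bg_rows, r_standard = r_standard)
      }) |>
      dplyr::ungroup() |>
      dplyr::group_by(.data$trt_, .data$depth_, .data$day) |>
      dplyr::summarise(
        b13_umol = protein_to_biomass(mean(.data$protein_13c_umol),
                                      protein_fraction),
        b13_umol_sd = protein_to_biomass(stats::sd(.data$protein_13c_umol),
                                         protein_fraction),
        .groups = "drop"
      ) |>
      dplyr::rename(treatment = "trt_", depth_zone = "depth_")
    summ <- dplyr::left_join(
      summ, b13, by = c("treatment", "depth_zone", "day")
    )
  } else {
    summ$b13_umol <- NA_real_
    summ$b13_umol_sd <- NA_real_
  }

  summ <- summ |>
    dplyr::mutate(
      cue = dplyr::if_else(
        !is.na(.data$b13_umol) & .data$b13_umol + .data$di13c_umol_mean > 0,
        .data$b13_umol / (.data$b13_umol + .data$di13c_umol_mean),
        NA_real_
      ),
      b12_umol = estimate_indigenous_biomass(.data$cue, .data$di12c_umol_mean)
    )
  if (!is.null(label_umol_13c)) {
    summ$fraction_mineralized <-
      fraction_mineralized(summ$di13c_umol_mean, label_umol_13c)
  }
  summ
}

#' Degradation kinetics of an analysed incubation
#'
#' Summarises rate constants per treatment and depth from the output of
#' [analyze_incubation()]: the closed-form single-pool constant at the last
#' harvest day ([first_order_k()]) and, when at least four harvest days are
#' available, the two-pool fit ([fit_two_g()]).
#'
#' @param summary Output of [analyze_incubation()] with a
#'   `fraction_mineralized` column.
#' @param year_days Days per year, default [DAYS_PER_YEAR].
#' @return A tibble `depth_zone, treatment, model, k1_per_yr, k2_per_yr,
#'   g1, g2, rms` with one `first_order` and (data permitting) one
#'   `two_g` row per series.
#' @export
kinetics_summary <- function(summary, year_days = DAYS_PER_YEAR) {
  if (!"fraction_mineralized" %in% names(summary)) {
    rlang::abort("summary lacks fraction_mineralized; pass label_umol_13c to analyze_incubation()")
  }
  summary |>
    dplyr::filter(!is.na(.data$fraction_mineralized)) |>
    dplyr::group_by(.data$depth_zone, .data$treatment) |>
    dplyr::group_modify(function(d, key) {
      d <- dplyr::arrange(d, .data$day)
      last <- d[nrow(d), ]
      rows <- tibble::tibble(
        model = "first_order",
        k1_per_yr = first_order_k(last$fraction_mineralized,
                                  last$day / year_days),
        k2_per_yr = NA_real_, g1 = 1, g2 = NA_real_, rms = NA_real_
      )
      if (nrow(d) >= 4) {
        fit <- fit_two_g(d$day, d$fraction_mineralized,
                         year_days = year_days)
        rows <- dplyr::bind_rows(rows, tibble::tibble(
          model = "two_g", k1_per_yr = fit$k1, k2_per_yr = fit$k2,
          g1 = fit$g1, g2 = fit$g2, rms = fit$rms
        ))
      }
      rows
    }) |>
    dplyr::ungroup()
}

round_display <- function(report) {
  report |>
    dplyr::mutate(
      dplyr::across(dplyr::any_of(c(
        "di13c_umol_mean", "di13c_umol_sd", "di12c_umol_mean",
        "di12c_umol_sd", "di12c_control_umol", "priming_umol",
        "b13_umol", "b13_umol_sd", "b12_umol"
      )), ~ round(.x, 2)),
      dplyr::across(dplyr::any_of(c("cue", "f_substrate_mean",
                                    "f_substrate_sd",
                                    "fraction_mineralized")),
                    ~ round(.x, 2)),
      dplyr::across(dplyr::any_of("priming_factor"), ~ round(.x, 1))
    )
}

#' Run the complete pipeline from a configuration
#'
#' Reads the measurement tables named in a [read_run_config()]
#' configuration (or list with the same fields), analyses them, and
#' assembles the report bundle: the harvest-day summary in the
#' conventional column order (substrate mineralization, priming, control
#' production, biomass, equal-CUE biomass estimate, CUE), the kinetics
#' summary, and the per-replicate partition table. All tables carry full
#' precision; a display copy of the summary is rounded the way such tables
#' are printed (masses to 2 decimals, CUE to 2 decimals). When `out_dir`
#' is set, the tables are also written there as CSV (`report_full.csv`,
#' `report_display.csv`, `kinetics.csv`, `partition_replicates.csv`);
#' re-running with the same configuration rewrites byte-identical files.
#'
#' @param config A `run_config`, a path to a YAML configuration, or a list
#'   with the same fields.
#' @return A list of class `run_report` with elements `summary`,
#'   `summary_display`, `kinetics`, `partition`, `substrate`,
#'   `label_umol_13c`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  cfg <- config
  spec <- substrate_spec(
    cfg$substrate$mass_ug, cfg$substrate$carbon_content,
    cfg$substrate$atom_percent_13c,
    label = cfg$substrate$label %||% ""
  )
  label <- label_quantity(spec)
  r_standard <- cfg$r_standard %||% R_VPDB
  units_12c <- cfg$units_12c %||% "12c"

  incubation <- if (is.data.frame(cfg$incubation_csv)) {
    tibble::as_tibble(cfg$incubation_csv)
  } else {
    read_incubation_csv(cfg$incubation_csv)
  }
  amino_acids <- if (is.null(cfg$amino_acid_csv)) {
    NULL
  } else if (is.data.frame(cfg$amino_acid_csv)) {
    tibble::as_tibble(cfg$amino_acid_csv)
  } else {
    read_amino_acid_csv(cfg$amino_acid_csv)
  }

  control_only <- all(incubation$treatment == "control")
  summary <- analyze_incubation(
    incubation, amino_acids,
    x_substrate = spec$atom_percent_13c / 100,
    label_umol_13c = label,
    protein_fraction = cfg$protein_fraction %||% 0.6,
    units_12c = units_12c,
    aa_background = cfg$aa_background %||% "day0",
    noise_tol = cfg$noise_tol %||% 0.05,
    r_standard = r_standard
  )
  order_cols <- intersect(
    c("treatment", "depth_zone", "day", "di13c_umol_mean", "di13c_umol_sd",
      "priming_umol", "di12c_control_umol", "b13_umol", "b13_umol_sd",
      "b12_umol", "cue", "di12c_umol_mean", "di12c_umol_sd",
      "priming_factor", "f_substrate_mean", "f_substrate_sd",
      "fraction_mineralized"),
    names(summary)
  )
  summary <- dplyr::select(summary, dplyr::all_of(order_cols)) |>
    dplyr::arrange(.data$treatment, .data$depth_zone, .data$day)

  kinetics <- if (control_only) {
    tibble::tibble()
  } else {
    kinetics_summary(summary, year_days = cfg$year_days %||% DAYS_PER_YEAR)
  }
  partition <- if (control_only) {
    tibble::tibble()
  } else {
    partition_incubation(
      incubation, x_substrate = spec$atom_percent_13c / 100,
      r_standard = r_standard, units_12c = units_12c,
      noise_tol = cfg$noise_tol %||% 0.05
    )
  }

  report <- structure(
    list(
      summary = summary,
      summary_display = round_display(summary),
      kinetics = kinetics,
      partition = partition,
      substrate = spec,
      label_umol_13c = label
    ),
    class = "run_report"
  )
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_table_csv(report$summary, file.path(cfg$out_dir, "report_full.csv"))
    write_table_csv(report$summary_display,
                    file.path(cfg$out_dir, "report_display.csv"))
    if (nrow(kinetics) > 0) {
      write_table_csv(kinetics, file.path(cfg$out_dir, "kinetics.csv"))
    }
    if (nrow(partition) > 0) {
      write_table_csv(partition,
                      file.path(cfg$out_dir, "partition_replicates.csv"))
    }
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> substrate %s: %.4g umol 13C added\n",
              if (nzchar(x$substrate$label)) x$substrate$label else "(unnamed)",
              x$label_umol_13c))
  print(x$summary_display)
  invisible(x)
}
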