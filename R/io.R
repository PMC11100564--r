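INCUBATION_HEADER <- c("treatment", "depth_zone", "replicate", "day",
                       "dic_umol", "d13c_dic_permil")
AA_HEADER <- c("treatment", "depth_zone", "replicate", "day", "aa_code",
               "conc_nmol_per_g", "d13c_permil", "dry_mass_g")

check_header <- function(path, expected) {
  lines <- readLines(path, n = 200L, warn = FALSE)
  first <- which(!startsWith(trimws(lines), "#") & nzchar(trimws(lines)))[1]
  if (is.na(first)) rlang::abort(sprintf("%s: empty file", path))
  header <- strsplit(lines[first], ",", fixed = TRUE)[[1]]
  if (!identical(trimws(header), expected)) {
    rlang::abort(sprintf(
      "%s: header mismatch at line %d\n  expected: %s\n  found:    %s",
      path, first, paste(expected, collapse = ","), lines[first]
    ))
  }
  first
}

read_schema_csv <- function(path, expected, col_types, key_cols) {
  header_line <- check_header(path, expected)
  # readr's own parsing warning is superseded by the structured error below
  df <- suppressWarnings(
    readr::read_csv(path, comment = "#", col_types = col_types,
                    progress = FALSE)
  )
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    rlang::abort(sprintf(
      "%s: %d parsing problem(s), first at line %d column %s: %s",
      path, nrow(probs), probs$row[1] + header_line, probs$col[1],
      probs$expected[1]
    ))
  }
  if (nrow(df) == 0) {
    rlang::warn(sprintf("%s: header only, no records", path))
    return(df)
  }
  key <- do.call(paste, c(df[key_cols], sep = "\r"))
  dup <- duplicated(key)
  if (any(dup)) {
    rlang::abort(sprintf(
      "%s: duplicated key (%s) at data row(s) %s",
      path, paste(key_cols, collapse = ", "),
      paste(which(dup) + header_line, collapse = ", ")
    ))
  }
  df
}

#' Read an incubation measurement table
#'
#' Reads and validates the per-bottle DIC time series. The header must
#' match `treatment,depth_zone,replicate,day,dic_umol,d13c_dic_permil`
#' exactly; lines starting with `#` are treated as comments. Non-numeric
#' fields and duplicated `(treatment, depth_zone, replicate, day)` keys are
#' errors that name the offending line.
#'
#' @param path Path to a CSV file.
#' @return A tibble in the incubation schema (possibly empty, with a
#'   warning, for a header-only file).
#' @export
read_incubation_csv <- function(path) {
  read_schema_csv(
    path, INCUBATION_HEADER,
    readr::cols(
      treatment = readr::col_character(),
      depth_zone = readr::col_character(),
      replicate = readr::col_integer(),
      day = readr::col_double(),
      dic_umol = readr::col_double(),
      d13c_dic_permil = readr::col_double()
    ),
    key_cols = c("treatment", "depth_zone", "replicate", "day")
  )
}

#' Read a hydrolyzable amino-acid table
#'
#' Header must match
#' `treatment,depth_zone,replicate,day,aa_code,conc_nmol_per_g,d13c_permil,dry_mass_g`
#' exactly. Validation as in [read_incubation_csv()].
#'
#' @param path Path to a CSV file.
#' @return A tibble in the amino-acid schema.
#' @export
read_amino_acid_csv <- function(path) {
  read_schema_csv(
    path, AA_HEADER,
    readr::cols(
      treatment = readr::col_character(),
      depth_zone = readr::col_character(),
      replicate = readr::col_integer(),
      day = readr::col_double(),
      aa_code = readr::col_character(),
      conc_nmol_per_g = readr::col_double(),
      d13c_permil = readr::col_double(),
      dry_mass_g = readr::col_double()
    ),
    key_cols = c("treatment", "depth_zone", "replicate", "day", "aa_code")
  )
}

#' Write a table as CSV at full precision
#'
#' Thin wrapper over [readr::write_csv()] (which writes full double
#' precision), so that write-then-read round trips are lossless.
#'
#' @param x Data frame.
#' @param path Output path.
#' @return `x`, invisibly.
#' @export
write_table_csv <- function(x, path) {
  readr::write_csv(x, path, progress = FALSE)
  invisible(x)
}

#' Read a run configuration file
#'
#' A run configuration is a YAML file mirroring the arguments of
#' [run_pipeline()]: input paths (`incubation_csv`, optional
#' `amino_acid_csv`), the substrate specification (`substrate:` with
#' `mass_ug`, `carbon_content`, `atom_percent_13c`, optional `label`), and
#' optional policies (`units_12c`, `aa_background`, `protein_fraction`,
#' `noise_tol`, `year_days`, `r_standard`, `out_dir`).
#'
#' @param path Path to a YAML file.
#' @return A validated named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(f) {
    if (is.null(f)) return(NULL)
    if (file.exists(f)) f else file.path(base, f)
  }
  cfg$incubation_csv <- resolve(cfg$incubation_csv)
  cfg$amino_acid_csv <- resolve(cfg$amino_acid_csv)
  if (is.null(cfg$incubation_csv) || !file.exists(cfg$incubation_csv)) {
    rlang::abort("config: incubation_csv missing or file not found")
  }
  if (!is.null(cfg$amino_acid_csv) && !file.exists(cfg$amino_acid_csv)) {
    rlang::abort("config: amino_acid_csv file not found")
  }
  if (is.null(cfg$substrate) ||
      !all(c("mass_ug", "carbon_content", "atom_percent_13c") %in%
             names(cfg$substrate))) {
    rlang::abort("config: substrate must give mass_ug, carbon_content, atom_percent_13c")
  }
  if (!is.null(cfg$units_12c) &&
      !cfg$units_12c %in% c("12c", "total_c")) {
    rlang::abort("config: units_12c must be '12c' or 'total_c'")
  }
  if (!is.null(cfg$aa_background) &&
      !cfg$aa_background %in% c("day0", "control")) {
    rlang::abort("config: aa_background must be 'day0' or 'control'")
  }
  structure(cfg, class = "run_config")
}
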