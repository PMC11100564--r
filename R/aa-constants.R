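#' Carbon atoms per amino acid
#'
#' Stoichiometric carbon counts for the amino acids quantified in sediment
#' hydrolysates (three-letter codes, plus GABA and 2-AAA). Shipped as a
#' plain-text constants table under `inst/extdata`.
#'
#' @return A tibble with columns `aa_code` and `carbon_atoms`.
#' @export
aa_carbon_counts <- function() {
  path <- system.file("extdata", "aa_carbon_counts.tsv", package = "sedprime",
                      mustWork = TRUE)
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  col_types = readr::cols(
                    aa_code = readr::col_character(),
                    carbon_atoms = readr::col_integer()
                  ))
}

#' Build a degradation-index model
#'
#' A degradation-index (DI) model is a reference table of amino-acid mole-%
#' statistics and factor loadings: `DI = sum_i [(mole%_i - mean_i) / sd_i] *
#' loading_i`. Use this constructor to supply your own coefficient set; the
#' packaged default is [dauwe_di_model()].
#'
#' @param table Data frame with columns `aa_code`, `mean_molpct`,
#'   `sd_molpct`, `loading`. Standard deviations must be positive.
#' @return An object of class `di_model`.
#' @export
di_model <- function(table) {
  table <- tibble::as_tibble(table)
  req <- c("aa_code", "mean_molpct", "sd_molpct", "loading")
  missing <- setdiff(req, names(table))
  if (length(missing) > 0) {
    rlang::abort(paste0("di_model table lacks column(s): ",
                        paste(missing, collapse = ", ")))
  }
  stopifnot(all(table$sd_molpct > 0), all(is.finite(table$loading)))
  if (anyDuplicated(table$aa_code)) {
    rlang::abort("duplicated amino-acid codes in di_model table")
  }
  structure(list(table = table[req]), class = "di_model")
}

#' Packaged degradation-index coefficients
#'
#' Reference means, standard deviations and first principal-component
#' loadings of amino-acid mole-% composition, after Dauwe et al. (1999),
#' used to score organic-matter freshness. See the shipped file's header
#' for provenance notes.
#'
#' @return A `di_model` object.
#' @export
dauwe_di_model <- function() {
  path <- system.file("extdata", "dauwe_di_coefficients.tsv",
                      package = "sedprime", mustWork = TRUE)
  di_model(readr::read_tsv(path, comment = "#", show_col_types = FALSE))
}

#' @export
print.di_model <- function(x, ...) {
  cat(sprintf("<di_model> %d amino acids\n", nrow(x$table)))
  print(x$table, n = nrow(x$table))
  invisible(x)
}
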