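#' Bundled reference fixtures
#'
#' Small plain-text data files shipped with the package: the printed homolog
#' column profiles at the four engineered sites, the published folding and
#' binding energy tables used for bookkeeping tests, the published
#' mode-frequency table, and the published titration table.
#'
#' Available names:
#' * `"table1_profiles"` - homolog residue counts per site (tibble in
#'   [column_profiles()] layout).
#' * `"table3_folding"` - per-force-field folding energy changes (tibble).
#' * `"table3_summary"` - monomer-averaged and calibrated folding values.
#' * `"table5_binding"` - per-force-field binding energy changes.
#' * `"table6_modes"` - per-force-field mode frequencies in GHz.
#' * `"table2_pka"` - titration values for the affected residues.
#'
#' @param name Fixture name.
#' @return A tibble (profiles are normalized so frequencies are included).
#' @export
fixture_bundle <- function(name) {
  files <- c(
    table1_profiles = "table1_profiles.tsv",
    table3_folding = "table3_folding.tsv",
    table3_summary = "table3_summary.tsv",
    table5_binding = "table5_binding.tsv",
    table6_modes = "table6_modes.tsv",
    table2_pka = "table2_pka.tsv"
  )
  if (!name %in% names(files)) {
    abort(paste0("unknown fixture '", name, "'; available: ",
                 paste(names(files), collapse = ", ")))
  }
  path <- system.file("extdata", files[[name]], package = "mutsmith")
  if (path == "") abort(paste0("fixture file missing from installation: ", files[[name]]))
  df <- as_tibble(read.delim(path, sep = "\t", stringsAsFactors = FALSE))
  if (name == "table1_profiles") df <- profiles_from_counts(df)
  df
}
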