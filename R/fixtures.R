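# Named, deterministic inputs for every benchmark experiment. Each
# fixture derives its seed from the master seed and a stable hash of its
# name, so adding fixtures never perturbs existing ones.

.fixture_names <- c("rep_coop_mrna", "rep_coop_mirna", "rep_tdmd",
                    "screen_mmi2_10k", "screen_mmi3_10k",
                    "tissue_wt", "tissue_mir27ko", "tissue_mir196ko",
                    "ra_pulse", "catalog_small")

.name_hash <- function(name) {
  sum(utf8ToInt(name) * (31^(seq_len(nchar(name)) %% 8))) %% 100003L
}

#' Materialize a named fixture
#'
#' Returns the canonical inputs of the package's benchmark experiments:
#' the three representative bistable parameter sets (`rep_coop_mrna`:
#' cooperative mRNA degradation a2 = 10; `rep_coop_mirna`: cooperative miRNA
#' degradation b2 = 0.1; `rep_tdmd`: target-directed miRNA degradation
#' a2 = b1 = 1.8), the 10,000-set screen draws, the wild-type and knockout
#' tissue configurations, the RA-pulse protocol, and a small site catalog.
#'
#' @param name Fixture name; see `fixture_names()`.
#' @param master_seed Master seed from which per-fixture seeds are derived.
#' @return The fixture inputs (type depends on the fixture).
#' @examples
#' fixture("rep_coop_mrna")
#' @export
fixture <- function(name, master_seed = 20260101L) {
  if (!name %in% .fixture_names) stop("unknown fixture: ", name)
  seed <- (master_seed + .name_hash(name)) %% 2147483647L
  switch(name,
    rep_coop_mrna = mmi_parameters(2, a = c(1, 10), b = c(1, 1)),
    rep_coop_mirna = mmi_parameters(2, a = c(1, 1), b = c(1, 0.1)),
    rep_tdmd = mmi_parameters(2, a = c(1, 1.8), b = c(1.8, 1)),
    screen_mmi2_10k = sample_parameters(10000L, 0.125, 16, 2L, seed = seed),
    screen_mmi3_10k = sample_parameters(10000L, 0.125, 16, 3L, seed = seed),
    tissue_wt = list(spec = cell_model_spec("mmi_S"),
                     field = make_morphogen_field(seed = seed)),
    tissue_mir27ko = list(spec = knockout(cell_model_spec("mmi_S"), "miR-27"),
                          field = make_morphogen_field(seed = seed)),
    tissue_mir196ko = list(spec = knockout(cell_model_spec("mmi_S"), "miR-196"),
                           field = make_morphogen_field(seed = seed)),
    ra_pulse = list(ra_high = 1, ra_low = 0.08, t_switch = 40),
    catalog_small = generate_catalog(n_genes = 200L, n_families = 5L,
                                     site_lambda = 0.3, seed = seed))
}

#' Registered fixture names
#' @return Character vector.
#' @export
fixture_names <- function() .fixture_names

#' Export all fixtures to disk
#'
#' Writes every registered fixture in plain-text form (YAML configs, CSV
#' parameter tables, TSV catalogs) under `dir`.
#'
#' @param dir Output directory (created if absent).
#' @param master_seed Master seed.
#' @return Invisibly, the vector of files written.
#' @export
export_fixtures <- function(dir, master_seed = 20260101L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  wr <- function(fname) { files <<- c(files, fname); fname }
  for (nm in c("rep_coop_mrna", "rep_coop_mirna", "rep_tdmd")) {
    write_mmi_config(fixture(nm, master_seed),
                     wr(file.path(dir, paste0(nm, ".yaml"))))
  }
  for (nm in c("screen_mmi2_10k", "screen_mmi3_10k")) {
    utils::write.csv(as.data.frame(fixture(nm, master_seed)),
                     wr(file.path(dir, paste0(nm, ".csv"))), row.names = FALSE)
  }
  cs <- fixture("catalog_small", master_seed)
  write_site_catalog(cs$catalog, wr(file.path(dir, "catalog_small.tsv")))
  yaml::write_yaml(cs$truth, wr(file.path(dir, "catalog_small_truth.yaml")))
  yaml::write_yaml(fixture("ra_pulse", master_seed),
                   wr(file.path(dir, "ra_pulse.yaml")))
  invisible(files)
}
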