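#' Run the cleavage-mapping pipeline end to end
#'
#' Convenience driver for the simulation -> digestion -> site-calling ->
#' spectrum-validation chain. Given a configuration it simulates (or loads)
#' the peptide evidence, calls cleavage sites, validates the top call with a
#' simulated acquired/predicted spectrum pair and the bootstrap spectrum
#' contrast angle, and writes every stage output plus a manifest to the
#' output directory. Identical configurations produce identical outputs.
#'
#' @param config List with elements:
#'   \describe{
#'     \item{seed}{Integer master seed (required).}
#'     \item{out_dir}{Output directory (created if absent).}
#'     \item{fasta}{Optional path to a protein FASTA; when absent a protein
#'       of `protein_length` residues is simulated.}
#'     \item{protein_length}{Simulated protein length (default 200).}
#'     \item{planted_sites}{Cleavage bonds to plant when simulating
#'       (default one site at 64).}
#'     \item{decoy_rate}{Decoy fraction for the simulated table (default 0.05).}
#'     \item{min_products}{Concordance requirement for site calls (default 2).}
#'     \item{k, n_boot}{Top-k and bootstrap size for the SCA (defaults 8, 20).}
#'     \item{tolerance_ppm}{Fragment matching tolerance (default 20).}
#'   }
#' @return Manifest list: config, per-stage output paths, the site calls and
#'   the SCA result; also written as `manifest.json`.
#' @export
run_pipeline <- function(config) {
  defaults <- list(protein_length = 200L, planted_sites = 64L,
                   decoy_rate = 0.05, min_products = 2L, k = 8L,
                   n_boot = 20L, tolerance_ppm = 20)
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  if (is.null(config$seed)) stop("config$seed is required")
  if (is.null(config$out_dir)) stop("config$out_dir is required")
  if (!is.null(config$fasta) && !file.exists(config$fasta)) {
    stop("input FASTA not found: ", config$fasta)
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()

  if (!is.null(config$fasta)) {
    protein <- read_fasta(config$fasta)[[1]]
  } else {
    protein <- generate_protein(config$protein_length, config$seed)
  }
  sim <- simulate_shedding_identifications(
    protein, config$planted_sites, decoy_rate = config$decoy_rate,
    seed = config$seed)
  paths$peptides <- file.path(config$out_dir, "peptides.tsv")
  write_table_tsv(sim$peptides, paths$peptides)

  evidence <- collect_terminus_evidence(sim$peptides,
                                        stats::setNames(list(protein), protein$id))
  calls <- call_cleavage_sites(evidence, min_products = config$min_products)
  paths$sites <- file.path(config$out_dir, "sites.tsv")
  write_table_tsv(calls, paths$sites)

  sca <- NULL
  if (nrow(calls) > 0L) {
    top_pep <- strsplit(calls$n_side_peptides[1], ";", fixed = TRUE)[[1]][1]
    pair <- simulate_spectrum_pair(top_pep, seed = config$seed + 1L,
                                   tolerance_ppm = config$tolerance_ppm)
    matched <- match_fragment_sets(pair$acquired, pair$predicted, top_pep,
                                   tolerance = config$tolerance_ppm)
    sca <- bootstrap_sca(matched, k = config$k, n_boot = config$n_boot,
                         seed = config$seed + 2L)
    paths$sca <- file.path(config$out_dir, "sca.json")
    jsonlite::write_json(
      list(peptide = top_pep, sca = sca$sca, k_used = sca$k_used,
           n_boot = sca$n_boot, median = sca$median, q1 = sca$q1, q3 = sca$q3,
           values = sca$bootstrap_values),
      paths$sca, auto_unbox = TRUE, digits = NA)
  }

  manifest <- list(
    config = config[order(names(config))],
    protein = list(id = protein$id, length = protein_length(protein)),
    outputs = paths,
    n_peptides = nrow(sim$peptides),
    calls = calls,
    sca = if (is.null(sca)) NULL else sca$sca)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  manifest
}
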