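#' Build a simulator configuration
#'
#' Defaults encode the experimental regime the simulator emulates at desk
#' scale: two proteomes whose size ratio matches a large algal database
#' against a small bacterial one (about 4.6:1), log-normally distributed
#' protein copy mass spanning several orders of magnitude, a bacterium
#' contributing at most 10% of coculture biomass, a fixed injected peptide
#' load, and three biological replicates per condition.
#'
#' @param n_proteins_alga,n_proteins_bacterium proteome sizes. Defaults 460
#'   and 100 preserve the ~4.6:1 entry-count ratio of the full databases
#'   (32,670 algal vs 7,105 bacterial entries) at desk scale.
#' @param abundance_meanlog,abundance_sdlog log-normal parameters (natural
#'   log) of per-protein relative copy mass; `sdlog = 1.5` spans roughly four
#'   orders of magnitude, typical of proteome-wide dynamic range.
#' @param peptides_per_protein mean observable peptides per protein; counts
#'   are drawn as `1 + Poisson(mean - 1)` so every protein has at least one.
#' @param sharing_rate fraction of peptides given a second candidate parent.
#' @param cross_organism_sharing among shared peptides, the fraction whose
#'   second parent is drawn from the other organism (tryptic peptides rarely
#'   collide across kingdoms; default 0.02).
#' @param ionization_sdlog log-normal sd of per-peptide ionization response.
#' @param bacterial_fraction_coculture bacterial biomass share in coculture;
#'   default 0.10, the bacterium's share "at best".
#' @param total_load injected peptide mass in micrograms; default 0.5
#'   (a 5 microlitre injection of a 0.10 ug/ul digest).
#' @param replicates biological replicates per condition (default 3).
#' @param biological_sdlog2 per-replicate log2 sd applied to protein
#'   abundances before digestion (default 0.25, ~19% CV).
#' @param ratio_error_sdlog2 log2 sd of the multiplicative error between the
#'   mono-mix target ratio and the coculture ratio; default 0.5 reflects the
#'   roughly two-fold uncertainty of CFU-based bacterial density estimates.
#' @param regulated_fraction,effect_size optional default perturbation: the
#'   fraction of proteins whose coculture abundance is shifted, and the
#'   absolute log2 shift (sign drawn at random). Default: no true effects.
#' @return A validated [SimConfig-class] object.
#' @seealso [acquisitionConfig()], [simulateExperiment()]
#' @examples
#' cfg <- simConfig(n_proteins_alga = 50L, n_proteins_bacterium = 20L)
#' cfg
#' @export
simConfig <- function(n_proteins_alga = 460L,
                      n_proteins_bacterium = 100L,
                      abundance_meanlog = 0,
                      abundance_sdlog = 1.5,
                      peptides_per_protein = 6,
                      sharing_rate = 0.05,
                      cross_organism_sharing = 0.02,
                      ionization_sdlog = 0.7,
                      bacterial_fraction_coculture = 0.10,
                      total_load = 0.5,
                      replicates = 3L,
                      biological_sdlog2 = 0.25,
                      ratio_error_sdlog2 = 0.5,
                      regulated_fraction = 0,
                      effect_size = 2) {
  new("SimConfig",
      n_proteins_alga = as.integer(n_proteins_alga),
      n_proteins_bacterium = as.integer(n_proteins_bacterium),
      abundance_meanlog = abundance_meanlog,
      abundance_sdlog = abundance_sdlog,
      peptides_per_protein = peptides_per_protein,
      sharing_rate = sharing_rate,
      cross_organism_sharing = cross_organism_sharing,
      ionization_sdlog = ionization_sdlog,
      bacterial_fraction_coculture = bacterial_fraction_coculture,
      total_load = total_load,
      replicates = as.integer(replicates),
      biological_sdlog2 = biological_sdlog2,
      ratio_error_sdlog2 = ratio_error_sdlog2,
      regulated_fraction = regulated_fraction,
      effect_size = effect_size)
}

#' Build an acquisition configuration
#'
#' @param top_n precursors fragmented per retention-time window; default 12,
#'   the standard "top 12" data-dependent method.
#' @param n_rt_windows retention-time windows per run. Together with `top_n`
#'   this sets the run's identification capacity (`top_n * n_rt_windows`
#'   peptides). The default 90 is calibrated so that, at the default
#'   composition and softness, coculture roughly halves bacterial protein
#'   detection relative to bacterial monoculture -- the suppression
#'   magnitude reported for real instrument runs.
#' @param detection_floor minimum peptide amount (same units as the injected
#'   load) that can be reported even when selected.
#' @param selection_softness temperature of stochastic precursor selection:
#'   peptides are drawn without replacement with probability proportional to
#'   `amount^(1/selection_softness)`. 0 gives deterministic top-N. The
#'   default 0.2 is calibrated so that replicate injections of a competitive
#'   sample share roughly 75% of their peptide identifications, the
#'   run-to-run reproducibility typical of DDA; larger values make the
#'   instrument unrealistically erratic, smaller ones unrealistically exact.
#' @param noise_sigma log2-scale sd of multiplicative measurement noise
#'   (default 0.3, ~23% CV, typical label-free precision).
#' @param response_gain detector response converting on-column amount to
#'   reported area counts (default 1e9 counts per microgram), so reported
#'   log2 abundances sit in the positive 15-25 range of real extracted-ion
#'   areas -- the scale regime the sum-of-log2 roll-up presumes.
#' @param n_fine_bins fine hydrophobicity bins collected before round-robin
#'   concatenation into fractions; default 110, one per minute of a
#'   110-minute collection window.
#' @return A validated [AcquisitionConfig-class] object.
#' @export
acquisitionConfig <- function(top_n = 12L,
                              n_rt_windows = 90L,
                              detection_floor = 1e-7,
                              selection_softness = 0.2,
                              noise_sigma = 0.3,
                              response_gain = 1e9,
                              n_fine_bins = 110L) {
  new("AcquisitionConfig",
      top_n = as.integer(top_n),
      n_rt_windows = as.integer(n_rt_windows),
      detection_floor = detection_floor,
      selection_softness = selection_softness,
      noise_sigma = noise_sigma,
      response_gain = response_gain,
      n_fine_bins = as.integer(n_fine_bins))
}

#' Construct a peptide-to-protein candidate map
#'
#' @param pairs data.frame with columns `peptide` and `protein_id`, one row
#'   per candidate relationship.
#' @param proteins data.frame with columns `protein_id`, `gene_id`,
#'   `organism` and `fasta_order` (position in the concatenated search
#'   database; used as the final parsimony tie-break).
#' @return A [PeptideProteinMap-class].
#' @export
peptideProteinMap <- function(pairs, proteins) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  proteins <- as.data.frame(proteins, stringsAsFactors = FALSE)
  if (is.null(proteins$gene_id)) proteins$gene_id <- proteins$protein_id
  if (is.null(proteins$organism)) proteins$organism <- "alga"
  if (is.null(proteins$fasta_order)) proteins$fasta_order <- seq_len(nrow(proteins))
  new("PeptideProteinMap", pairs = pairs, proteins = proteins)
}

#' Construct a protein quantification matrix
#'
#' @param log2 numeric matrix of log2 abundances (rows = genes, columns =
#'   samples); NA marks "not detected".
#' @param organism character vector of organism labels, one per row.
#' @param gene_id gene identifiers; defaults to rownames of `log2`.
#' @param uniquePeptides optional integer matrix, same shape as `log2`, of
#'   observed unique-peptide counts per gene and sample.
#' @param colData optional data.frame of sample annotation (`sample_id`,
#'   `condition`, `replicate`, ...); rownames are matched to columns.
#' @return A [ProteinQuantMatrix-class].
#' @examples
#' m <- matrix(c(10, 12, NA, 11, 13, 9), nrow = 3,
#'             dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' pqm <- proteinQuantMatrix(m, organism = c("alga", "alga", "bacterium"))
#' pqm
#' @export
proteinQuantMatrix <- function(log2, organism, gene_id = rownames(log2),
                               uniquePeptides = NULL, colData = NULL) {
  log2 <- as.matrix(log2)
  if (is.null(gene_id)) gene_id <- paste0("gene", seq_len(nrow(log2)))
  rownames(log2) <- gene_id
  if (is.null(colnames(log2))) colnames(log2) <- paste0("sample", seq_len(ncol(log2)))
  organism <- rep_len(as.character(organism), nrow(log2))
  asy <- list(log2 = log2)
  if (!is.null(uniquePeptides)) {
    uniquePeptides <- as.matrix(uniquePeptides)
    dimnames(uniquePeptides) <- dimnames(log2)
    asy$uniquePeptides <- uniquePeptides
  }
  if (is.null(colData)) {
    colData <- S4Vectors::DataFrame(sample_id = colnames(log2),
                                    row.names = colnames(log2))
  } else {
    colData <- S4Vectors::DataFrame(colData)
    if (is.null(colData$sample_id)) colData$sample_id <- colnames(log2)
    rownames(colData) <- colnames(log2)
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = asy,
    rowData = S4Vectors::DataFrame(gene_id = gene_id, organism = organism),
    colData = colData)
  new("ProteinQuantMatrix", se)
}
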