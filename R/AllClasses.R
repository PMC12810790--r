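## S4 classes: simulator configuration, acquisition configuration, the
## peptide-to-protein candidate map, and the central proteins x samples
## container (a SummarizedExperiment subclass).

#' Simulator configuration
#'
#' Holds the stated world of a simulated two-organism DDA experiment: proteome
#' sizes, abundance and peptide-sharing structure, the coculture biomass
#' ratio, injection load, replicate structure and noise levels. Build with
#' [simConfig()], which documents every parameter and its default.
#'
#' @slot n_proteins_alga,n_proteins_bacterium proteome sizes (counts).
#' @slot abundance_meanlog,abundance_sdlog log-normal (natural-log scale)
#'   parameters of per-protein relative copy mass.
#' @slot peptides_per_protein mean observable peptides per protein.
#' @slot sharing_rate fraction of peptides carrying a second parent protein.
#' @slot cross_organism_sharing among shared peptides, fraction whose second
#'   parent belongs to the other organism.
#' @slot ionization_sdlog log-normal sd of per-peptide ionization efficiency.
#' @slot bacterial_fraction_coculture bacterial share of biomass in coculture.
#' @slot total_load injected peptide mass (micrograms).
#' @slot replicates biological replicates per condition.
#' @slot biological_sdlog2 per-replicate log2 sd of protein abundance.
#' @slot ratio_error_sdlog2 log2 sd of the mono-mix target-ratio error.
#' @slot regulated_fraction,effect_size default truth perturbation: fraction
#'   of proteins regulated in coculture and the absolute log2 effect applied.
#' @exportClass SimConfig
setClass("SimConfig", representation(
  n_proteins_alga = "integer",
  n_proteins_bacterium = "integer",
  abundance_meanlog = "numeric",
  abundance_sdlog = "numeric",
  peptides_per_protein = "numeric",
  sharing_rate = "numeric",
  cross_organism_sharing = "numeric",
  ionization_sdlog = "numeric",
  bacterial_fraction_coculture = "numeric",
  total_load = "numeric",
  replicates = "integer",
  biological_sdlog2 = "numeric",
  ratio_error_sdlog2 = "numeric",
  regulated_fraction = "numeric",
  effect_size = "numeric"
))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (!.isCount(object@n_proteins_alga)) msg <- c(msg, "n_proteins_alga must be a positive integer")
  if (!.isCount(object@n_proteins_bacterium)) msg <- c(msg, "n_proteins_bacterium must be a positive integer")
  if (!.isProb(object@sharing_rate)) msg <- c(msg, "sharing_rate must lie in [0, 1]")
  if (!.isProb(object@cross_organism_sharing)) msg <- c(msg, "cross_organism_sharing must lie in [0, 1]")
  if (!.isProb(object@bacterial_fraction_coculture)) msg <- c(msg, "bacterial_fraction_coculture must lie in [0, 1]")
  if (object@peptides_per_protein < 1) msg <- c(msg, "peptides_per_protein must be >= 1")
  if (object@abundance_sdlog < 0) msg <- c(msg, "abundance_sdlog must be >= 0")
  if (object@ionization_sdlog < 0) msg <- c(msg, "ionization_sdlog must be >= 0")
  if (object@total_load <= 0) msg <- c(msg, "total_load must be > 0")
  if (!.isCount(object@replicates)) msg <- c(msg, "replicates must be a positive integer")
  if (object@biological_sdlog2 < 0) msg <- c(msg, "biological_sdlog2 must be >= 0")
  if (object@ratio_error_sdlog2 < 0) msg <- c(msg, "ratio_error_sdlog2 must be >= 0")
  if (!.isProb(object@regulated_fraction)) msg <- c(msg, "regulated_fraction must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Acquisition configuration
#'
#' Parameters of the stochastic top-N precursor selection model. Build with
#' [acquisitionConfig()].
#'
#' @slot top_n precursors fragmented per retention-time window.
#' @slot n_rt_windows retention-time windows per LC-MS run.
#' @slot detection_floor minimum on-column amount reportable.
#' @slot selection_softness temperature of the weighted rank selection
#'   (0 = deterministic top-N by amount).
#' @slot noise_sigma log2-scale sd of multiplicative measurement noise.
#' @slot response_gain detector response: reported area counts per unit of
#'   on-column amount.
#' @slot n_fine_bins fine hydrophobicity bins used for fraction concatenation.
#' @exportClass AcquisitionConfig
setClass("AcquisitionConfig", representation(
  top_n = "integer",
  n_rt_windows = "integer",
  detection_floor = "numeric",
  selection_softness = "numeric",
  noise_sigma = "numeric",
  response_gain = "numeric",
  n_fine_bins = "integer"
))

setValidity("AcquisitionConfig", function(object) {
  msg <- character()
  if (!.isCount(object@top_n)) msg <- c(msg, "top_n must be >= 1")
  if (!.isCount(object@n_rt_windows)) msg <- c(msg, "n_rt_windows must be >= 1")
  if (object@detection_floor < 0) msg <- c(msg, "detection_floor must be >= 0")
  if (object@selection_softness < 0) msg <- c(msg, "selection_softness must be >= 0")
  if (object@noise_sigma < 0) msg <- c(msg, "noise_sigma must be >= 0")
  if (object@response_gain <= 0) msg <- c(msg, "response_gain must be > 0")
  if (!.isCount(object@n_fine_bins)) msg <- c(msg, "n_fine_bins must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Peptide-to-protein candidate map
#'
#' Candidate relationships between observed peptide sequences and the protein
#' entries of the concatenated two-organism search database, preserving
#' database order (which breaks parsimony ties). Build with
#' [peptideProteinMap()] or derive from a digest via [digestProteins()].
#'
#' @slot pairs data.frame with columns `peptide`, `protein_id`; one row per
#'   candidate relationship.
#' @slot proteins data.frame with columns `protein_id`, `gene_id`,
#'   `organism`, `fasta_order`; `fasta_order` is a strict total order.
#' @exportClass PeptideProteinMap
setClass("PeptideProteinMap", representation(
  pairs = "data.frame",
  proteins = "data.frame"
))

setValidity("PeptideProteinMap", function(object) {
  msg <- character()
  pr <- object@proteins
  pa <- object@pairs
  need_pr <- c("protein_id", "gene_id", "organism", "fasta_order")
  if (!all(need_pr %in% names(pr))) {
    return(sprintf("proteins must have columns: %s", paste(need_pr, collapse = ", ")))
  }
  if (!all(c("peptide", "protein_id") %in% names(pa))) {
    return("pairs must have columns peptide, protein_id")
  }
  if (anyDuplicated(pr$protein_id)) msg <- c(msg, "protein_ids must be unique")
  if (anyDuplicated(pr$fasta_order) || any(is.na(pr$fasta_order))) {
    msg <- c(msg, "fasta_order must be a strict total order (no ties, no NA)")
  }
  if (nrow(pa)) {
    if (any(is.na(pa$peptide)) || any(!nzchar(pa$peptide))) {
      msg <- c(msg, "pairs contain empty peptide entries")
    }
    if (!all(pa$protein_id %in% pr$protein_id)) {
      msg <- c(msg, "pairs reference unknown protein_ids")
    }
    if (anyDuplicated(pa[, c("peptide", "protein_id")])) {
      msg <- c(msg, "duplicate peptide-protein pairs")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Protein quantification matrix
#'
#' Gene-level log2 abundances across samples, with the organism label of every
#' gene and per-sample counts of observed unique (single-candidate) peptides.
#' Extends [SummarizedExperiment::SummarizedExperiment]; assay `"log2"` holds
#' the abundances (NA = not detected, never zero-filled), assay
#' `"uniquePeptides"` the unique-peptide counts. `rowData` carries `gene_id`
#' and `organism`; `colData` carries at least `sample_id`, and `condition` and
#' `replicate` when a design is known.
#'
#' @exportClass ProteinQuantMatrix
setClass("ProteinQuantMatrix", contains = "SummarizedExperiment")

setValidity("ProteinQuantMatrix", function(object) {
  msg <- character()
  if (!"log2" %in% names(assays(object))) {
    return("assay 'log2' is required")
  }
  x <- assay(object, "log2")
  if (any(is.infinite(x), na.rm = TRUE)) msg <- c(msg, "log2 assay contains infinite values")
  rd <- rowData(object)
  if (!all(c("gene_id", "organism") %in% names(rd))) {
    msg <- c(msg, "rowData must contain gene_id and organism")
  } else {
    org <- as.character(rd$organism)
    if (length(org) && (any(is.na(org)) || length(unique(org)) > 2)) {
      msg <- c(msg, "organism labels must be non-NA with at most two distinct values")
    }
  }
  if (length(msg)) msg else TRUE
})
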