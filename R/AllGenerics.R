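#' Accessors for ProteinQuantMatrix
#'
#' `organisms()` returns the per-gene organism labels, `geneIds()` the gene
#' identifiers, `log2Abundance()` the log2 abundance matrix (NA = not
#' detected), and `uniquePeptideCounts()` the per-sample unique-peptide count
#' matrix (NULL if unknown).
#'
#' @param x a [ProteinQuantMatrix-class].
#' @return See individual descriptions.
#' @name pqm-accessors
#' @aliases organisms geneIds log2Abundance uniquePeptideCounts
#' @examples
#' m <- matrix(c(10, 12, 11, 13), nrow = 2,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' pqm <- proteinQuantMatrix(m, organism = "alga")
#' organisms(pqm)
#' log2Abundance(pqm)
NULL

#' @rdname pqm-accessors
#' @export
setGeneric("organisms", function(x) standardGeneric("organisms"))

#' @rdname pqm-accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname pqm-accessors
#' @export
setGeneric("log2Abundance", function(x) standardGeneric("log2Abundance"))

#' @rdname pqm-accessors
#' @export
setGeneric("uniquePeptideCounts", function(x) standardGeneric("uniquePeptideCounts"))

#' @rdname pqm-accessors
setMethod("organisms", "ProteinQuantMatrix", function(x) {
  setNames(as.character(rowData(x)$organism), rownames(x))
})

#' @rdname pqm-accessors
setMethod("geneIds", "ProteinQuantMatrix", function(x) {
  as.character(rowData(x)$gene_id)
})

#' @rdname pqm-accessors
setMethod("log2Abundance", "ProteinQuantMatrix", function(x) assay(x, "log2"))

#' @rdname pqm-accessors
setMethod("uniquePeptideCounts", "ProteinQuantMatrix", function(x) {
  if ("uniquePeptides" %in% names(assays(x))) assay(x, "uniquePeptides") else NULL
})

setMethod("show", "ProteinQuantMatrix", function(object) {
  x <- assay(object, "log2")
  org <- table(as.character(rowData(object)$organism))
  cat(sprintf("ProteinQuantMatrix: %d genes x %d samples\n", nrow(x), ncol(x)))
  cat("  organisms:", paste(sprintf("%s (%d)", names(org), org), collapse = ", "), "\n")
  cat(sprintf("  missing entries: %.1f%%\n", 100 * mean(is.na(x))))
  cond <- colData(object)$condition
  if (!is.null(cond)) {
    tb <- table(as.character(cond))
    cat("  conditions:", paste(sprintf("%s (%d)", names(tb), tb), collapse = ", "), "\n")
  }
  invisible(NULL)
})

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig\n")
  cat(sprintf("  proteomes: alga %d, bacterium %d proteins\n",
              object@n_proteins_alga, object@n_proteins_bacterium))
  cat(sprintf("  abundance ~ lognormal(%.2f, %.2f); %.1f peptides/protein; sharing %.2f\n",
              object@abundance_meanlog, object@abundance_sdlog,
              object@peptides_per_protein, object@sharing_rate))
  cat(sprintf("  coculture bacterial fraction %.2f; load %.2f ug; %d replicates\n",
              object@bacterial_fraction_coculture, object@total_load,
              object@replicates))
  cat(sprintf("  biological sd (log2) %.2f; mono-mix ratio error sd (log2) %.2f\n",
              object@biological_sdlog2, object@ratio_error_sdlog2))
  invisible(NULL)
})

setMethod("show", "AcquisitionConfig", function(object) {
  cat("AcquisitionConfig\n")
  cat(sprintf("  top %d per window x %d windows (capacity %d); softness %.2f\n",
              object@top_n, object@n_rt_windows,
              object@top_n * object@n_rt_windows, object@selection_softness))
  cat(sprintf("  detection floor %.2g; noise sd (log2) %.2f; %d fine bins\n",
              object@detection_floor, object@noise_sigma, object@n_fine_bins))
  invisible(NULL)
})

setMethod("show", "PeptideProteinMap", function(object) {
  cat(sprintf("PeptideProteinMap: %d peptides, %d proteins, %d pairs\n",
              length(unique(object@pairs$peptide)), nrow(object@proteins),
              nrow(object@pairs)))
  invisible(NULL)
})
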