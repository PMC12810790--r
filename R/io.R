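## File formats: FASTA, peptide observation TSVs, protein matrix TSVs.

#' Read a protein FASTA file
#'
#' Reads an amino-acid FASTA preserving record order, which defines the
#' database order used by the parsimony tie-break. Duplicate identifiers are
#' an error.
#'
#' @param path FASTA file.
#' @return an [Biostrings::AAStringSet]; names are the first whitespace-
#'   delimited token of each header.
#' @export
readProteomeFasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  aa <- Biostrings::readAAStringSet(path)
  names(aa) <- sub("\\s.*$", "", names(aa))
  dup <- names(aa)[duplicated(names(aa))]
  if (length(dup)) {
    stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  aa
}

#' Read and write peptide observation tables
#'
#' The interchange format is TSV with columns `sample_id`, `fraction`,
#' `peptide`, `candidate_proteins` (semicolon-joined, database order) and
#' `abundance`; lines starting with `#` are header comments carrying the
#' package version, seed and configuration digest.
#'
#' @param path TSV file.
#' @return `readPeptideObservations()`: the observation data.frame.
#' @export
readPeptideObservations <- function(path) {
  obs <- .readTsv(path)
  need <- c("sample_id", "fraction", "peptide", "candidate_proteins", "abundance")
  missing_cols <- setdiff(need, names(obs))
  if (length(missing_cols)) {
    stop("observation table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  obs
}

#' @rdname readPeptideObservations
#' @param observations observation data.frame (as produced by
#'   [simulateExperiment()]).
#' @param seed,config stamped into the header comment.
#' @export
writePeptideObservations <- function(observations, path, seed = NA,
                                     config = NULL) {
  .writeTsv(observations, path, seed = seed, config = config)
}

#' Derive a peptide-to-protein map from an observation table
#'
#' Rebuilds the candidate map from the `candidate_proteins` column, with
#' database order taken from a protein table or assumed from first
#' appearance.
#'
#' @param observations observation data.frame.
#' @param proteins optional data.frame `protein_id`, `gene_id`, `organism`,
#'   `fasta_order`; reconstructed (first-appearance order, organism
#'   `"alga"`) when absent.
#' @return a [PeptideProteinMap-class].
#' @export
mapFromObservations <- function(observations, proteins = NULL) {
  peps <- unique(observations[, c("peptide", "candidate_proteins")])
  cand <- strsplit(peps$candidate_proteins, ";", fixed = TRUE)
  pairs <- data.frame(peptide = rep(peps$peptide, lengths(cand)),
                      protein_id = unlist(cand), stringsAsFactors = FALSE)
  pairs <- unique(pairs)
  if (is.null(proteins)) {
    ids <- unique(unlist(cand))
    proteins <- data.frame(protein_id = ids, gene_id = ids,
                           organism = "alga", fasta_order = seq_along(ids),
                           stringsAsFactors = FALSE)
  }
  peptideProteinMap(pairs, proteins)
}

#' Write and read a protein quantification matrix
#'
#' TSV with columns `gene_id`, `organism`, then one column per sample;
#' empty cells encode missing values.
#'
#' @param x a [ProteinQuantMatrix-class].
#' @param path TSV file.
#' @param seed,config stamped into the header comment.
#' @return `writeProteinMatrix()` returns `path`; `readProteinMatrix()` a
#'   [ProteinQuantMatrix-class] (without unique-peptide counts, which the
#'   TSV does not carry).
#' @export
writeProteinMatrix <- function(x, path, seed = NA, config = NULL) {
  stopifnot(is(x, "ProteinQuantMatrix"))
  df <- data.frame(gene_id = as.character(rowData(x)$gene_id),
                   organism = as.character(rowData(x)$organism),
                   as.data.frame(log2Abundance(x), check.names = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  .writeTsv(df, path, seed = seed, config = config)
}

#' @rdname writeProteinMatrix
#' @param design optional data.frame (`sample_id`, `condition`, `replicate`)
#'   re-attached as `colData`.
#' @export
readProteinMatrix <- function(path, design = NULL) {
  df <- .readTsv(path)
  stopifnot(all(c("gene_id", "organism") %in% names(df)))
  value_cols <- setdiff(names(df), c("gene_id", "organism"))
  m <- as.matrix(df[, value_cols, drop = FALSE])
  mode(m) <- "double"
  rownames(m) <- df$gene_id
  cd <- NULL
  if (!is.null(design)) {
    cd <- design[match(value_cols, design$sample_id), , drop = FALSE]
  }
  proteinQuantMatrix(m, organism = df$organism, gene_id = df$gene_id,
                     colData = cd)
}
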