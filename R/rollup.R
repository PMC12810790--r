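## Peptide-level normalization and protein (gene) roll-up.

#' Mean central-tendency normalization of peptide abundances
#'
#' Log2-transforms peptide abundances and shifts each sample additively so
#' that every sample's mean equals the grand mean (the mean of per-sample
#' means) across the processing batch. Within-sample differences are
#' preserved exactly. Fractionated and unfractionated data should be
#' normalized as separate batches (separate calls).
#'
#' @param observations data.frame with columns `sample_id`, `peptide`,
#'   `abundance` (strictly positive), and optionally `fraction`,
#'   `candidate_proteins`.
#' @return the input with two added columns: `log2_abundance` and
#'   `norm_log2` (the shifted value).
#' @examples
#' obs <- data.frame(sample_id = rep(c("s1", "s2"), each = 2),
#'                   peptide = c("a", "b", "a", "b"),
#'                   abundance = c(2^9, 2^11, 2^11, 2^13))
#' centralTendencyNormalize(obs)$norm_log2
#' @export
centralTendencyNormalize <- function(observations) {
  stopifnot(all(c("sample_id", "peptide", "abundance") %in% names(observations)))
  if (!nrow(observations)) {
    observations$log2_abundance <- numeric(0)
    observations$norm_log2 <- numeric(0)
    return(observations)
  }
  if (any(observations$abundance <= 0 | !is.finite(observations$abundance))) {
    stop("abundances must be positive and finite", call. = FALSE)
  }
  lg <- log2(observations$abundance)
  sample_means <- tapply(lg, observations$sample_id, mean)
  grand <- mean(sample_means)
  shift <- grand - sample_means[as.character(observations$sample_id)]
  observations$log2_abundance <- lg
  observations$norm_log2 <- lg + as.numeric(shift)
  observations
}

#' Roll peptide values up to gene-level abundances
#'
#' Assigned, normalized peptide values are grouped by gene and summed per
#' sample (a peptide observed in several fractions of one sample first sums
#' into that sample). The default scale follows the simple roll-up
#' convention of summing the normalized log2 values themselves; `mode =
#' "log2_sum"` instead sums the back-transformed intensities and reports
#' their log2, which keeps protein fold changes on the peptide fold-change
#' scale. Genes with no observed peptide in a sample are missing (NA), never
#' zero. The count of observed unique (single-candidate) peptides is
#' recorded per gene and sample.
#'
#' @param observations output of [centralTendencyNormalize()].
#' @param assignment output of [assignParsimony()].
#' @param map the [PeptideProteinMap-class] used for assignment.
#' @param design optional data.frame (`sample_id`, `condition`, `replicate`)
#'   defining the full sample set and annotation; samples without
#'   observations become all-missing columns.
#' @param mode `"sum_log2"` (default) or `"log2_sum"`, see Details.
#' @return a [ProteinQuantMatrix-class].
#' @seealso [buildProteinMatrix()] for the one-call chain.
#' @export
rollupProteins <- function(observations, assignment, map, design = NULL,
                           mode = c("sum_log2", "log2_sum")) {
  mode <- match.arg(mode)
  stopifnot("norm_log2" %in% names(observations))
  dt <- data.table::as.data.table(
    observations[, c("sample_id", "peptide", "norm_log2")])
  m <- match(dt$peptide, assignment$peptide)
  if (anyNA(m)) stop("observed peptides missing from the assignment", call. = FALSE)
  dt[, gene_id := assignment$gene_id[m]]
  dt[, is_unique := assignment$is_unique[m]]
  ## collapse fractions: one value per peptide and sample
  dt <- dt[, .(norm_log2 = sum(norm_log2), is_unique = is_unique[1]),
           by = .(sample_id, gene_id, peptide)]
  agg <- dt[, .(
    value = if (mode == "sum_log2") sum(norm_log2) else log2(sum(2 ^ norm_log2)),
    n_unique = sum(is_unique)
  ), by = .(sample_id, gene_id)]

  sample_ids <- if (!is.null(design)) design$sample_id else sort(unique(agg$sample_id))
  genes <- map@proteins[!duplicated(map@proteins$gene_id),
                        c("gene_id", "organism")]
  genes <- genes[genes$gene_id %in% agg$gene_id, , drop = FALSE]
  genes <- genes[order(genes$gene_id), , drop = FALSE]

  x <- matrix(NA_real_, nrow(genes), length(sample_ids),
              dimnames = list(genes$gene_id, sample_ids))
  up <- matrix(0L, nrow(genes), length(sample_ids),
               dimnames = list(genes$gene_id, sample_ids))
  ri <- match(agg$gene_id, genes$gene_id)
  ci <- match(agg$sample_id, sample_ids)
  keep <- !is.na(ci)
  x[cbind(ri[keep], ci[keep])] <- agg$value[keep]
  up[cbind(ri[keep], ci[keep])] <- agg$n_unique[keep]

  cd <- if (!is.null(design)) {
    S4Vectors::DataFrame(design, row.names = design$sample_id)
  } else NULL
  proteinQuantMatrix(x, organism = genes$organism, gene_id = genes$gene_id,
                     uniquePeptides = up, colData = cd)
}

#' Filter to quantifiable proteins
#'
#' Keeps genes supported by at least `min_unique` distinct unique
#' (single-candidate) peptides somewhere in the experiment and detected in
#' at least `min_reps` replicates of at least one condition. Refiltering is
#' idempotent.
#'
#' @param x a [ProteinQuantMatrix-class] whose `colData` carries `condition`
#'   and `replicate`.
#' @param min_unique minimum distinct unique peptides (default 2).
#' @param min_reps minimum replicates of some condition with a value
#'   (default 2).
#' @return the filtered [ProteinQuantMatrix-class]; the numbers retained per
#'   organism are stored in `metadata(x)$filter_report`.
#' @export
filterQuantifiable <- function(x, min_unique = 2L, min_reps = 2L) {
  stopifnot(is(x, "ProteinQuantMatrix"))
  cond <- colData(x)$condition
  if (is.null(cond)) stop("colData must carry a condition column", call. = FALSE)
  reps_per_cond <- table(as.character(cond))
  if (any(reps_per_cond < min_reps)) {
    stop("design error: every condition needs at least ", min_reps,
         " replicates", call. = FALSE)
  }
  if (nrow(x) == 0L) return(x)
  up <- uniquePeptideCounts(x)
  if (is.null(up)) stop("unique peptide counts are required for filtering", call. = FALSE)
  vals <- log2Abundance(x)
  ## unique-peptide support: max per-sample count of distinct unique peptides
  enough_unique <- apply(up, 1L, max) >= min_unique
  detected <- !is.na(vals)
  by_cond <- vapply(unique(as.character(cond)), function(cc) {
    rowSums(detected[, cond == cc, drop = FALSE]) >= min_reps
  }, logical(nrow(x)))
  if (is.null(dim(by_cond))) by_cond <- matrix(by_cond, nrow = nrow(x))
  enough_reps <- rowSums(by_cond) >= 1L
  keep <- enough_unique & enough_reps
  out <- x[keep, ]
  report <- as.list(table(as.character(rowData(out)$organism)))
  report$total <- sum(keep)
  report$dropped <- sum(!keep)
  metadata(out)$filter_report <- report
  out
}

#' Peptide observations to a filtered protein matrix, in one call
#'
#' Chains [centralTendencyNormalize()], [assignParsimony()],
#' [rollupProteins()] and (when a design is given) [filterQuantifiable()].
#'
#' @inheritParams rollupProteins
#' @param filter apply the quantifiability filter (default TRUE when a
#'   design with conditions is supplied).
#' @param min_unique,min_reps passed to [filterQuantifiable()].
#' @return a [ProteinQuantMatrix-class].
#' @export
buildProteinMatrix <- function(observations, map, design = NULL,
                               mode = c("sum_log2", "log2_sum"),
                               filter = !is.null(design),
                               min_unique = 2L, min_reps = 2L) {
  mode <- match.arg(mode)
  norm <- centralTendencyNormalize(observations)
  asn <- assignParsimony(map)
  pqm <- rollupProteins(norm, asn, map, design = design, mode = mode)
  if (filter) pqm <- filterQuantifiable(pqm, min_unique, min_reps)
  pqm
}
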