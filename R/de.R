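## Differential expression with LOQ gating, Z-scores, and the group-level
## detection-count and abundance-distribution comparisons.

#' Differential protein expression between two conditions
#'
#' Per gene with at least `min_reps` non-missing replicates in both arms
#' (missing values are excluded, never imputed): Welch's two-sample t-test
#' on log2 values, fold change `mean(treatment) - mean(control)`,
#' Benjamini-Hochberg adjustment applied per organism over exactly the
#' tested genes. A call is significant when `|log2_fc| > 1`, `p_adj < 0.05`,
#' and the mean log2 abundance exceeds the limit of quantitation in both
#' arms. Genes where both arms have zero variance are handled explicitly:
#' equal means give p = 1; unequal means are flagged `degenerate` and left
#' untested (never silently significant).
#'
#' @param x a [ProteinQuantMatrix-class] with `condition` in its `colData`.
#' @param contrast character of length 2: `c(treatment, control)`; the fold
#'   change is treatment minus control.
#' @param loq named LOQ vector from [computeLoq()]; computed from `x` (per
#'   organism) when NULL.
#' @param min_reps minimum non-missing replicates per arm (default 2).
#' @param fc_cut,alpha significance gates (defaults 1 and 0.05).
#' @return data.frame with one row per tested or untested gene: `gene_id`,
#'   `organism`, `n_treat`, `n_ctrl`, `mean_treat`, `mean_ctrl`, `log2_fc`,
#'   `t_stat`, `df`, `p_value`, `p_adj`, `above_loq_treat`,
#'   `above_loq_ctrl`, `tested`, `degenerate`, `significant`, `direction`.
#' @examples
#' m <- cbind(matrix(rnorm(12, 10), 2), matrix(rnorm(12, 13), 2))
#' # see the vignette for a full worked example
#' @export
differentialExpression <- function(x, contrast, loq = NULL, min_reps = 2L,
                                   fc_cut = 1, alpha = 0.05) {
  stopifnot(is(x, "ProteinQuantMatrix"), length(contrast) == 2L)
  cond <- as.character(colData(x)$condition)
  if (is.null(cond) || !all(contrast %in% cond)) {
    stop("contrast conditions not found in colData(x)$condition", call. = FALSE)
  }
  if (is.null(loq)) loq <- computeLoq(x, scope = "organism")
  X <- log2Abundance(x)
  A <- X[, cond == contrast[1], drop = FALSE]
  B <- X[, cond == contrast[2], drop = FALSE]
  org <- as.character(rowData(x)$organism)
  loq_of <- if (length(loq) == 1L && names(loq)[1] == "experiment") {
    setNames(rep(loq, length(unique(org))), unique(org))
  } else loq

  n <- nrow(X)
  res <- data.frame(
    gene_id = as.character(rowData(x)$gene_id), organism = org,
    n_treat = rowSums(!is.na(A)), n_ctrl = rowSums(!is.na(B)),
    mean_treat = rowMeans(A, na.rm = TRUE), mean_ctrl = rowMeans(B, na.rm = TRUE),
    log2_fc = NA_real_, t_stat = NA_real_, df = NA_real_,
    p_value = NA_real_, p_adj = NA_real_,
    above_loq_treat = NA, above_loq_ctrl = NA,
    tested = FALSE, degenerate = FALSE,
    significant = FALSE, direction = "none",
    stringsAsFactors = FALSE)
  res$mean_treat[res$n_treat == 0L] <- NA_real_
  res$mean_ctrl[res$n_ctrl == 0L] <- NA_real_

  eligible <- which(res$n_treat >= min_reps & res$n_ctrl >= min_reps)
  n_degenerate <- 0L
  for (i in eligible) {
    a <- A[i, !is.na(A[i, ])]
    b <- B[i, !is.na(B[i, ])]
    res$log2_fc[i] <- mean(a) - mean(b)
    if (stats::var(a) == 0 && stats::var(b) == 0) {
      if (isTRUE(all.equal(mean(a), mean(b)))) {
        res$t_stat[i] <- 0; res$p_value[i] <- 1; res$tested[i] <- TRUE
      } else {
        res$degenerate[i] <- TRUE
        n_degenerate <- n_degenerate + 1L
      }
      next
    }
    tt <- stats::t.test(a, b, var.equal = FALSE)
    res$t_stat[i] <- unname(tt$statistic)
    res$df[i] <- unname(tt$parameter)
    res$p_value[i] <- tt$p.value
    res$tested[i] <- TRUE
  }
  if (n_degenerate > 0L) {
    warning(n_degenerate, " gene(s) with zero variance in both arms and ",
            "unequal means were flagged degenerate and not tested",
            call. = FALSE)
  }
  ## BH family: the genes actually tested, per organism
  for (o in unique(org)) {
    fam <- which(res$tested & org == o)
    res$p_adj[fam] <- stats::p.adjust(res$p_value[fam], method = "BH")
  }
  res$above_loq_treat <- res$mean_treat > loq_of[org]
  res$above_loq_ctrl <- res$mean_ctrl > loq_of[org]
  sig <- res$tested & !is.na(res$p_adj) &
    abs(res$log2_fc) > fc_cut & res$p_adj < alpha &
    res$above_loq_treat & res$above_loq_ctrl
  sig[is.na(sig)] <- FALSE
  res$significant <- sig
  res$direction[sig & res$log2_fc > 0] <- "increased"
  res$direction[sig & res$log2_fc < 0] <- "decreased"
  attr(res, "contrast") <- contrast
  attr(res, "loq") <- loq_of
  res
}

#' Per-protein Z-scores across condition means
#'
#' For each gene: condition means of the (normalized) log2 values, computed
#' over non-missing replicates, then standardized across conditions to mean
#' 0 and sample sd 1. Genes whose condition means are constant get all-zero
#' Z-scores and are flagged in the `"flat"` attribute.
#'
#' @param x a [ProteinQuantMatrix-class] with `condition` in `colData`.
#' @param conditions conditions to include (default: all, in first-seen
#'   order).
#' @param min_conditions genes need a non-missing mean in at least this many
#'   conditions (default 2); others are dropped.
#' @return matrix genes x conditions of Z-scores, with attribute `"flat"`
#'   (logical, zero-variance genes) and `"means"` (the condition means).
#' @export
computeZScores <- function(x, conditions = NULL, min_conditions = 2L) {
  stopifnot(is(x, "ProteinQuantMatrix"))
  cond <- as.character(colData(x)$condition)
  if (is.null(conditions)) conditions <- unique(cond)
  X <- log2Abundance(x)
  means <- vapply(conditions, function(cc) {
    rowMeans(X[, cond == cc, drop = FALSE], na.rm = TRUE)
  }, numeric(nrow(X)))
  means <- matrix(means, nrow = nrow(X),
                  dimnames = list(rownames(X), conditions))
  means[is.nan(means)] <- NA_real_
  keep <- rowSums(!is.na(means)) >= min_conditions
  means <- means[keep, , drop = FALSE]
  mu <- rowMeans(means, na.rm = TRUE)
  sdv <- apply(means, 1L, stats::sd, na.rm = TRUE)
  flat <- sdv == 0 | is.na(sdv)
  z <- (means - mu) / ifelse(flat, 1, sdv)
  z[flat, ] <- 0
  rownames(z) <- rownames(X)[keep]
  attr(z, "flat") <- setNames(flat, rownames(z))
  attr(z, "means") <- means
  z
}

#' Compare detected-protein counts between two sample groups
#'
#' Two-tailed Student's t-test (equal variances) on per-replicate counts of
#' detected proteins, the test used for count comparisons between sample
#' groups.
#'
#' @param counts_a,counts_b numeric vectors of per-replicate detected
#'   counts (each length >= 2), or a [ProteinQuantMatrix-class] plus two
#'   condition names via `groups`.
#' @param x optional [ProteinQuantMatrix-class]; when given, counts are
#'   `colSums(!is.na(...))` of the two conditions named in `groups`.
#' @param groups character of length 2, used with `x`.
#' @param organism optional organism label to restrict the count to.
#' @return list `statistic`, `p_value`, `mean_a`, `mean_b`, `counts_a`,
#'   `counts_b`.
#' @export
compareDetectionCounts <- function(counts_a = NULL, counts_b = NULL,
                                   x = NULL, groups = NULL, organism = NULL) {
  if (!is.null(x)) {
    stopifnot(is(x, "ProteinQuantMatrix"), length(groups) == 2L)
    X <- log2Abundance(x)
    if (!is.null(organism)) {
      X <- X[as.character(rowData(x)$organism) == organism, , drop = FALSE]
    }
    cond <- as.character(colData(x)$condition)
    counts_a <- colSums(!is.na(X[, cond == groups[1], drop = FALSE]))
    counts_b <- colSums(!is.na(X[, cond == groups[2], drop = FALSE]))
  }
  if (length(counts_a) < 2L || length(counts_b) < 2L) {
    stop("each group needs at least 2 replicates", call. = FALSE)
  }
  if (stats::var(counts_a) == 0 && stats::var(counts_b) == 0) {
    p <- if (isTRUE(all.equal(mean(counts_a), mean(counts_b)))) 1 else NA_real_
    return(list(statistic = if (is.na(p)) NA_real_ else 0, p_value = p,
                mean_a = mean(counts_a), mean_b = mean(counts_b),
                counts_a = counts_a, counts_b = counts_b,
                degenerate = is.na(p)))
  }
  tt <- stats::t.test(counts_a, counts_b, var.equal = TRUE)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       mean_a = mean(counts_a), mean_b = mean(counts_b),
       counts_a = counts_a, counts_b = counts_b, degenerate = FALSE)
}

#' Compare abundance distributions between two sample groups
#'
#' Wilcoxon rank-sum (Mann-Whitney) test on per-protein replicate-averaged
#' abundances, restricted to proteins detected in at least `min_reps`
#' replicates of both groups -- the distribution comparison annotated on
#' abundance histograms.
#'
#' @param x a [ProteinQuantMatrix-class] with `condition` in `colData`.
#' @param group_a,group_b condition names.
#' @param organism optional organism restriction.
#' @param min_reps detection requirement per group (default 2).
#' @return list `statistic` (W), `p_value`, `median_a`, `median_b`,
#'   `n_proteins`.
#' @export
compareDistributions <- function(x, group_a, group_b, organism = NULL,
                                 min_reps = 2L) {
  stopifnot(is(x, "ProteinQuantMatrix"))
  X <- log2Abundance(x)
  if (!is.null(organism)) {
    X <- X[as.character(rowData(x)$organism) == organism, , drop = FALSE]
  }
  cond <- as.character(colData(x)$condition)
  A <- X[, cond == group_a, drop = FALSE]
  B <- X[, cond == group_b, drop = FALSE]
  shared <- rowSums(!is.na(A)) >= min_reps & rowSums(!is.na(B)) >= min_reps
  if (!any(shared)) stop("no proteins detected in both groups", call. = FALSE)
  ma <- rowMeans(A[shared, , drop = FALSE], na.rm = TRUE)
  mb <- rowMeans(B[shared, , drop = FALSE], na.rm = TRUE)
  wt <- stats::wilcox.test(ma, mb)
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       median_a = stats::median(ma), median_b = stats::median(mb),
       n_proteins = sum(shared))
}
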