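## Clustering, ordination and term enrichment.

#' k-means clustering of protein Z-score profiles
#'
#' Standard k-means (high `iter.max`, multiple seeded restarts) on a
#' complete matrix of per-condition Z-scores, plus the within-cluster
#' sum-of-squares elbow curve over `k = 1..k_max` used to choose k.
#'
#' @param z complete numeric matrix (genes x conditions), e.g. from
#'   [computeZScores()]; rows with missing values are dropped.
#' @param k number of clusters.
#' @param iter_max maximum k-means iterations (default 1000).
#' @param nstart random restarts (default 25).
#' @param k_max upper end of the elbow curve (default `min(10, n - 1)`).
#' @param seed integer seed making the clustering deterministic.
#' @return list `cluster` (named integer vector in 1..k), `k`, `centers`,
#'   `inertia` (total within-cluster SS at `k`), `elbow` (data.frame `k`,
#'   `wss`).
#' @export
clusterProteins <- function(z, k, iter_max = 1000L, nstart = 25L,
                            k_max = NULL, seed = 1L) {
  z <- as.matrix(z)
  z <- z[stats::complete.cases(z), , drop = FALSE]
  if (!.isCount(k)) stop("k must be a positive integer", call. = FALSE)
  if (k > nrow(z)) stop("k exceeds the number of genes", call. = FALSE)
  if (is.null(k_max)) k_max <- max(k, min(10L, nrow(z) - 1L))
  ## Hartigan-Wong emits benign quick-transfer/convergence warnings on tiny
  ## or duplicate-heavy inputs even at high iter.max; muffle only those.
  quiet_kmeans <- function(...) {
    withCallingHandlers(
      stats::kmeans(...),
      warning = function(w) {
        if (grepl("did not converge|Quick-TRANSFER", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
  }
  withr::with_seed(seed, {
    fits <- lapply(seq_len(k_max), function(kk) {
      quiet_kmeans(z, centers = kk, iter.max = iter_max, nstart = nstart)
    })
  })
  fit <- fits[[k]]
  list(cluster = setNames(fit$cluster, rownames(z)),
       k = as.integer(k),
       centers = fit$centers,
       inertia = fit$tot.withinss,
       elbow = data.frame(k = seq_len(k_max),
                          wss = vapply(fits, function(f) f$tot.withinss,
                                       numeric(1))))
}

#' Principal component analysis of samples
#'
#' PCA of samples on proteins that are above the limit of quantitation and
#' non-missing in every sample (the completeness rule for ordination on DDA
#' data). Columns are centered, not scaled, matching the convention of the
#' standard implementations; set `scale = TRUE` to scale.
#'
#' @param x a [ProteinQuantMatrix-class] (at least 3 samples).
#' @param loq named LOQ vector from [computeLoq()], or NULL to compute it
#'   per organism from `x`; use `loq = -Inf` to disable the gate.
#' @param scale scale proteins to unit variance (default FALSE).
#' @return list `scores` (samples x components), `explained` (percent
#'   variance per component), `n_proteins`, `sdev`.
#' @export
pcaSamples <- function(x, loq = NULL, scale = FALSE) {
  stopifnot(is(x, "ProteinQuantMatrix"))
  if (ncol(x) < 3L) stop("PCA needs at least 3 samples", call. = FALSE)
  X <- log2Abundance(x)
  org <- as.character(rowData(x)$organism)
  if (is.null(loq)) loq <- computeLoq(x, scope = "organism")
  gate <- if (length(loq) == 1L && is.null(names(loq))) {
    rep(loq, nrow(X))
  } else if (length(loq) == 1L && identical(names(loq), "experiment")) {
    rep(unname(loq), nrow(X))
  } else unname(loq[org])
  keep <- rowSums(is.na(X)) == 0L &
    rowSums(X > gate, na.rm = TRUE) == ncol(X)
  if (sum(keep) < 2L) stop("fewer than 2 proteins pass the completeness/LOQ rule",
                           call. = FALSE)
  pc <- stats::prcomp(t(X[keep, , drop = FALSE]), center = TRUE, scale. = scale)
  expl <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x, explained = expl, n_proteins = sum(keep), sdev = pc$sdev)
}

#' Hypergeometric term over-representation with Holm correction
#'
#' For every term annotating the universe, the one-sided hypergeometric
#' probability of observing at least the seen number of hits in the
#' significant list, Holm-adjusted across the tested terms.
#'
#' @param sig_list character vector of significant gene ids (must be a
#'   subset of `universe`).
#' @param universe character vector of background gene ids (typically the
#'   organism's quantified proteins).
#' @param term_map data.frame `gene_id`, `term_id` and optionally
#'   `term_name`.
#' @param min_size only test terms with at least this many universe members
#'   (default 2).
#' @param alpha significance threshold on the adjusted p (default 0.05).
#' @return data.frame `term_id`, `term_name`, `hits_in_list`, `list_size`,
#'   `hits_in_universe`, `universe_size`, `p_value`, `p_adj`, `significant`,
#'   ordered by p.
#' @export
enrichTerms <- function(sig_list, universe, term_map, min_size = 2L,
                        alpha = 0.05) {
  universe <- unique(as.character(universe))
  sig_list <- unique(as.character(sig_list))
  if (!all(sig_list %in% universe)) {
    stop("sig_list must be a subset of the universe", call. = FALSE)
  }
  empty <- data.frame(term_id = character(), term_name = character(),
                      hits_in_list = integer(), list_size = integer(),
                      hits_in_universe = integer(), universe_size = integer(),
                      p_value = numeric(), p_adj = numeric(),
                      significant = logical())
  if (!length(sig_list)) return(empty)
  tm <- unique(term_map[term_map$gene_id %in% universe,
                        intersect(c("gene_id", "term_id", "term_name"),
                                  names(term_map))])
  if (!nrow(tm)) return(empty)
  if (is.null(tm$term_name)) tm$term_name <- tm$term_id
  N <- length(universe)
  n <- length(sig_list)
  terms <- split(tm$gene_id, tm$term_id)
  term_names <- tapply(tm$term_name, tm$term_id, `[`, 1L)
  K <- lengths(terms)
  keep <- K >= min_size
  terms <- terms[keep]; K <- K[keep]
  if (!length(terms)) return(empty)
  hits <- vapply(terms, function(g) sum(sig_list %in% g), integer(1))
  ## P(X >= hits) for X ~ Hypergeom(N, K, n)
  p <- stats::phyper(hits - 1L, K, N - K, n, lower.tail = FALSE)
  res <- data.frame(term_id = names(terms),
                    term_name = as.character(term_names[names(terms)]),
                    hits_in_list = hits, list_size = n,
                    hits_in_universe = as.integer(K), universe_size = N,
                    p_value = p,
                    p_adj = stats::p.adjust(p, method = "holm"),
                    stringsAsFactors = FALSE)
  res$significant <- res$p_adj < alpha
  res <- res[order(res$p_value, res$term_id), ]
  rownames(res) <- NULL
  res
}
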