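## Independent reference implementations used as test oracles. These are
## deliberately written as plain literal loops/formulas, separate from the
## package's vectorized code paths.

## Literal rule-by-rule parsimony oracle: for each peptide, apply rules
## (a) unique, (b) single candidate with independent unique evidence,
## (c) strictly most other non-unique peptides, (d) smallest database order.
oracle_parsimony <- function(pairs, proteins) {
  cand <- split(pairs$protein_id, pairs$peptide)
  n_cand <- vapply(cand, length, integer(1))
  unique_peps <- names(cand)[n_cand == 1L]
  prot_unique <- unique(unlist(cand[unique_peps]))
  out <- character(length(cand))
  names(out) <- names(cand)
  for (p in names(cand)) {
    cs <- cand[[p]]
    if (length(cs) == 1L) { out[p] <- cs; next }
    ## (b): candidates with a *different* uniquely-mapping peptide
    b <- character(0)
    for (c1 in cs) {
      if (c1 %in% prot_unique) {
        others <- unique_peps[vapply(unique_peps, function(q) {
          q != p && cand[[q]][1] == c1
        }, logical(1))]
        if (length(others) > 0L) b <- c(b, c1)
      }
    }
    if (length(b) == 1L) { out[p] <- b; next }
    ## (c): count other non-unique peptides per candidate
    counts <- integer(length(cs)); names(counts) <- cs
    for (c1 in cs) {
      k <- 0L
      for (q in names(cand)) {
        if (q != p && length(cand[[q]]) > 1L && c1 %in% cand[[q]]) k <- k + 1L
      }
      counts[c1] <- k
    }
    best <- names(counts)[counts == max(counts)]
    if (length(best) == 1L) { out[p] <- best; next }
    ## (d): first occurrence in the database
    ord <- proteins$fasta_order[match(best, proteins$protein_id)]
    out[p] <- best[which.min(ord)]
  }
  data.frame(peptide = names(out), protein_id = unname(out),
             stringsAsFactors = FALSE)
}

## Random small bipartite peptide-protein maps (<= 15 peptides, 8 proteins).
random_map <- function(seed) {
  set.seed(seed)
  n_prot <- sample(2:8, 1)
  n_pep <- sample(2:15, 1)
  prot_ids <- paste0("P", seq_len(n_prot))
  pairs <- do.call(rbind, lapply(seq_len(n_pep), function(i) {
    k <- sample(1:min(3, n_prot), 1, prob = c(0.5, 0.3, 0.2)[1:min(3, n_prot)])
    data.frame(peptide = paste0("pep", i),
               protein_id = sample(prot_ids, k),
               stringsAsFactors = FALSE)
  }))
  proteins <- data.frame(protein_id = prot_ids, gene_id = prot_ids,
                         organism = "alga",
                         fasta_order = sample(n_prot),
                         stringsAsFactors = FALSE)
  peptideProteinMap(pairs, proteins)
}

## Welch two-sample t-test from the textbook formulas.
oracle_welch <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

## Benjamini-Hochberg from the step-up definition.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  adj[o] <- rev(cummin(rev(p[o] * m / seq_len(m))))
  pmin(adj, 1)
}

## Holm from the step-down definition.
oracle_holm <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  adj[o] <- pmin(1, cummax(p[o] * (m - seq_len(m) + 1)))
  adj
}

## Upper-tail hypergeometric probability by direct binomial-coefficient sums.
oracle_hyper_tail <- function(hits, K, N, n) {
  ks <- hits:min(K, n)
  sum(exp(lchoose(K, ks) + lchoose(N - K, n - ks) - lchoose(N, n)))
}

## Exact two-sided Wilcoxon rank-sum p by full enumeration (no ties).
oracle_wilcox_exact <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  idx <- utils::combn(nx + ny, nx)
  ws <- apply(idx, 2, function(ii) sum(r[ii]) - nx * (nx + 1) / 2)
  if (w_obs > nx * ny / 2) {
    p <- 2 * mean(ws >= w_obs)
  } else {
    p <- 2 * mean(ws <= w_obs)
  }
  list(W = w_obs, p = min(p, 1))
}

## Tiny two-organism experiment configuration used across tests.
tiny_sim_config <- function(...) {
  simConfig(n_proteins_alga = 40L, n_proteins_bacterium = 15L,
            peptides_per_protein = 4, ratio_error_sdlog2 = 0, ...)
}

tiny_acq <- function(...) acquisitionConfig(n_rt_windows = 12L, ...)

## Small protein matrix with a 2-condition, 3-replicate design.
make_pqm <- function(values, organism = "alga",
                     conditions = rep(c("T", "C"), each = 3)) {
  colnames(values) <- paste0(conditions, "_", stats::ave(seq_along(conditions),
                                                         conditions,
                                                         FUN = seq_along))
  cd <- data.frame(sample_id = colnames(values), condition = conditions,
                   replicate = as.integer(sub(".*_", "", colnames(values))))
  proteinQuantMatrix(values, organism = organism, colData = cd)
}
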