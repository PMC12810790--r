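## Sample composition, fraction concatenation, and the stochastic top-N
## acquisition model.

#' Mix two organism states into one injected sample
#'
#' Computes per-peptide on-column amounts for a sample that combines the two
#' organisms at a given biomass ratio under a fixed total peptide load. Each
#' (peptide, parent protein) pair contributes
#' `total_load * organism_fraction * within-organism share`, where the share
#' is the pair's `abundance * ionization` weight normalized within its
#' organism; a peptide's amount is the sum over its parents. Fractions of 0
#' or 1 reproduce the pure monoculture compositions exactly.
#'
#' @param proteome list from [generateProteomes()] (uses `peptides` and
#'   `map`).
#' @param abundances named numeric vector of current per-protein abundances
#'   (e.g. a truth column, possibly with replicate jitter). Defaults to the
#'   proteome's base abundances.
#' @param bacterial_fraction bacterial share of biomass, in `[0, 1]`.
#' @param total_load injected peptide mass (default 0.5 ug).
#' @param condition label stored on the composition.
#' @return data.frame (`peptide`, `amount`, `hydrophobicity`, `organism`)
#'   restricted to peptides with positive amount, with attributes
#'   `condition`, `bacterial_fraction`, `total_load`, `fraction_index`.
#' @examples
#' pr <- generateProteomes(simConfig(n_proteins_alga = 20L,
#'                                   n_proteins_bacterium = 10L), seed = 1)
#' cc <- mixSamples(pr, bacterial_fraction = 0.1)
#' sum(cc$amount)
#' @export
mixSamples <- function(proteome, abundances = NULL, bacterial_fraction,
                       total_load = 0.5, condition = "sample") {
  if (!.isProb(bacterial_fraction)) {
    stop("bacterial_fraction must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(total_load > 0)
  proteins <- proteome$map@proteins
  pairs <- proteome$map@pairs
  peptides <- proteome$peptides
  if (is.null(abundances)) {
    abundances <- setNames(proteome$proteins$base_abundance,
                           proteome$proteins$protein_id)
  }
  pidx <- match(pairs$protein_id, proteins$protein_id)
  org <- proteins$organism[pidx]
  w <- abundances[pairs$protein_id] *
    peptides$ionization[match(pairs$peptide, peptides$peptide)]
  frac <- ifelse(org == "bacterium", bacterial_fraction, 1 - bacterial_fraction)
  amount_pair <- numeric(length(w))
  for (o in unique(org)) {
    sel <- org == o & frac > 0
    if (any(sel)) {
      amount_pair[sel] <- total_load * frac[sel] * w[sel] / sum(w[org == o])
    }
  }
  amt <- tapply(amount_pair, pairs$peptide, sum)
  comp <- data.frame(peptide = names(amt), amount = as.numeric(amt),
                     stringsAsFactors = FALSE)
  m <- match(comp$peptide, peptides$peptide)
  comp$hydrophobicity <- peptides$hydrophobicity[m]
  comp$organism <- peptides$organism[m]
  comp <- comp[comp$amount > 0, , drop = FALSE]
  comp <- comp[order(comp$peptide), , drop = FALSE]
  rownames(comp) <- NULL
  attr(comp, "condition") <- condition
  attr(comp, "bacterial_fraction") <- bacterial_fraction
  attr(comp, "total_load") <- total_load
  attr(comp, "fraction_index") <- NA_integer_
  comp
}

#' Concatenate a composition into peptide fractions
#'
#' Bins peptides by hydrophobicity into `n_fine_bins` fine equal-count bins
#' (the per-minute collection vials of a high-pH reversed-phase separation)
#' and assigns fine bins round-robin to `n_fractions` output compositions:
#' bin 1 to fraction 1, ..., bin `n_fractions` to fraction `n_fractions`,
#' bin `n_fractions + 1` back to fraction 1, and so on. Each peptide lands in
#' exactly one fraction, so the union of the fractions equals the input and
#' total amount is conserved.
#'
#' @param composition output of [mixSamples()].
#' @param n_fractions number of concatenated fractions (1 returns the input
#'   unchanged; typical choices 6, 12, 24).
#' @param n_fine_bins fine bins collected before concatenation (default 110);
#'   raised to `n_fractions` if smaller.
#' @return list of compositions, one per fraction, each with
#'   `fraction_index` set.
#' @export
fractionate <- function(composition, n_fractions, n_fine_bins = 110L) {
  if (!.isCount(n_fractions)) stop("n_fractions must be >= 1", call. = FALSE)
  n_fractions <- as.integer(n_fractions)
  if (n_fractions == 1L) {
    out <- composition
    attr(out, "fraction_index") <- 1L
    return(list(out))
  }
  n_fine_bins <- max(as.integer(n_fine_bins), n_fractions)
  n <- nrow(composition)
  rk <- rank(composition$hydrophobicity, ties.method = "first")
  fine <- ceiling(rk * n_fine_bins / n)
  frac_of_bin <- ((seq_len(n_fine_bins) - 1L) %% n_fractions) + 1L
  fr <- frac_of_bin[fine]
  lapply(seq_len(n_fractions), function(j) {
    out <- composition[fr == j, , drop = FALSE]
    rownames(out) <- NULL
    for (a in c("condition", "bacterial_fraction", "total_load")) {
      attr(out, a) <- attr(composition, a)
    }
    attr(out, "fraction_index") <- j
    out
  })
}

#' Simulate one data-dependent acquisition run
#'
#' Places peptides into retention-time windows by hydrophobicity rank
#' (equal-count windows), then within each window selects up to `top_n`
#' peptides without replacement with probability proportional to
#' `amount^(1/selection_softness)`; softness 0 is deterministic top-N by
#' amount. Selected peptides whose amount reaches the detection floor are
#' reported with abundance
#' `amount * response_gain * 2^Normal(0, noise_sigma)` (an extracted-ion
#' area); everything else is absent from the output (missing, never zero).
#'
#' @param composition output of [mixSamples()] (or one fraction of it).
#' @param acq an [AcquisitionConfig-class].
#' @param seed integer seed; the run is a pure function of
#'   `(composition, acq, seed)`.
#' @return data.frame `peptide`, `abundance`, `fraction` (the composition's
#'   fraction index, 1 if unfractionated).
#' @examples
#' pr <- generateProteomes(simConfig(n_proteins_alga = 20L,
#'                                   n_proteins_bacterium = 10L), seed = 1)
#' cc <- mixSamples(pr, bacterial_fraction = 0.1)
#' obs <- simulateDdaRun(cc, acquisitionConfig(n_rt_windows = 5L), seed = 7)
#' nrow(obs)
#' @export
simulateDdaRun <- function(composition, acq, seed = 1L) {
  stopifnot(is(acq, "AcquisitionConfig"))
  validObject(acq)
  n <- nrow(composition)
  frac_idx <- attr(composition, "fraction_index")
  if (is.null(frac_idx) || is.na(frac_idx)) frac_idx <- 1L
  if (n == 0L) {
    return(data.frame(peptide = character(), abundance = numeric(),
                      fraction = integer()))
  }
  withr::with_seed(seed, {
    rk <- rank(composition$hydrophobicity, ties.method = "first")
    window <- ceiling(rk * acq@n_rt_windows / n)
    ## Gumbel top-k per window == successive sampling without replacement
    ## with weights amount^(1/softness); softness 0 degenerates to ranking
    ## by amount alone.
    if (acq@selection_softness == 0) {
      key <- log(composition$amount)
    } else {
      gumbel <- -log(-log(stats::runif(n)))
      key <- log(composition$amount) / acq@selection_softness + gumbel
    }
    ord <- order(window, -key)
    pos <- ave(seq_along(ord), window[ord], FUN = seq_along)
    selected <- ord[pos <= acq@top_n]
    selected <- selected[composition$amount[selected] >= acq@detection_floor]
    noise <- 2 ^ stats::rnorm(length(selected), 0, acq@noise_sigma)
    out <- data.frame(peptide = composition$peptide[selected],
                      abundance = composition$amount[selected] *
                        acq@response_gain * noise,
                      fraction = frac_idx,
                      stringsAsFactors = FALSE)
    out <- out[order(out$peptide), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}
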