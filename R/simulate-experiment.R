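## Whole-experiment simulation: replicate structure, the four culture
## conditions, mono-mix ratio error, fraction concatenation, and seed
## bookkeeping.

.SIM_CONDITIONS <- c("algal_mono", "bacterial_mono", "coculture", "mono_mix")

#' Simulate a complete multi-condition DDA experiment
#'
#' Generates the two proteomes, applies true coculture effects, then for
#' every condition and biological replicate: jitters protein abundances on
#' the log2 scale (biological variation, applied before digestion), mixes
#' the two organisms at the condition's biomass ratio under fixed load,
#' optionally concatenates into fractions, and runs the stochastic top-N
#' acquisition on each fraction. The mono-mix control uses
#' monoculture-derived abundances (no coculture effects) at a target ratio
#' equal to the coculture's times a multiplicative log-normal error, the way
#' a CFU-based blend misses its target. All randomness is split
#' deterministically from the master seed, so runs are reproducible
#' sample-by-sample.
#'
#' @param config a [SimConfig-class].
#' @param acq an [AcquisitionConfig-class].
#' @param effects optional data.frame (`protein_id`, `log2_effect`) of true
#'   coculture effects; if NULL and `config` has a positive
#'   `regulated_fraction`, that fraction is perturbed at random with
#'   magnitude `effect_size` and random sign.
#' @param conditions subset of `"algal_mono"`, `"bacterial_mono"`,
#'   `"coculture"`, `"mono_mix"` to acquire (default: all four).
#' @param n_fractions scalar or named vector (by condition) of fraction
#'   counts (default 1, unfractionated).
#' @param seed master integer seed.
#' @return list with:
#' \describe{
#'   \item{observations}{data.frame `sample_id`, `fraction`, `peptide`,
#'     `candidate_proteins` (semicolon-joined, database order), `abundance`.}
#'   \item{design}{data.frame `sample_id`, `condition`, `replicate`,
#'     `bacterial_fraction`, `n_fractions`.}
#'   \item{truth}{ground-truth table (see [simTruth()]).}
#'   \item{proteome}{the [generateProteomes()] output used.}
#' }
#' @examples
#' sim <- simulateExperiment(
#'   simConfig(n_proteins_alga = 40L, n_proteins_bacterium = 15L),
#'   acquisitionConfig(n_rt_windows = 10L),
#'   conditions = c("coculture", "mono_mix"), seed = 3)
#' table(sim$design$condition)
#' @export
simulateExperiment <- function(config, acq, effects = NULL,
                               conditions = .SIM_CONDITIONS,
                               n_fractions = 1L, seed = 1L) {
  stopifnot(is(config, "SimConfig"), is(acq, "AcquisitionConfig"))
  validObject(config); validObject(acq)
  conditions <- match.arg(conditions, .SIM_CONDITIONS, several.ok = TRUE)
  if (config@replicates < 2L) {
    stop("design error: at least 2 replicates are required", call. = FALSE)
  }
  nf <- if (length(n_fractions) == 1L && is.null(names(n_fractions))) {
    setNames(rep(as.integer(n_fractions), length(conditions)), conditions)
  } else {
    out <- setNames(rep(1L, length(conditions)), conditions)
    out[names(n_fractions)] <- as.integer(n_fractions)
    out
  }
  if (any(nf < 1L)) stop("n_fractions must be >= 1", call. = FALSE)

  proteome <- generateProteomes(config, seed = seed)
  truth <- simTruth(proteome$proteins)
  if (!is.null(effects)) {
    truth <- imposeEffects(truth, protein_ids = effects$protein_id,
                           log2_effect = effects$log2_effect)
  } else if (config@regulated_fraction > 0) {
    truth <- imposeEffects(truth, fraction = config@regulated_fraction,
                           log2_effect = config@effect_size, seed = seed)
  }

  is_bact <- proteome$proteins$organism == "bacterium"
  cocc_frac <- config@bacterial_fraction_coculture
  obs_list <- list()
  design <- list()
  k <- 0L
  for (cond in conditions) {
    for (rep_i in seq_len(config@replicates)) {
      k <- k + 1L
      sample_id <- sprintf("%s_%d", cond, rep_i)
      s_seed <- .splitSeed(seed, 10L + k)
      ## biological state and target ratio for this replicate
      state <- withr::with_seed(s_seed, {
        base <- switch(cond,
          coculture = truth$abundance_coculture,
          truth$abundance_mono)
        ab <- base * 2 ^ stats::rnorm(length(base), 0, config@biological_sdlog2)
        bf <- switch(cond,
          algal_mono = 0,
          bacterial_mono = 1,
          coculture = cocc_frac,
          mono_mix = min(1, cocc_frac *
            2 ^ stats::rnorm(1, 0, config@ratio_error_sdlog2)))
        list(ab = setNames(ab, truth$protein_id), bf = bf)
      })
      comp <- mixSamples(proteome, abundances = state$ab,
                         bacterial_fraction = state$bf,
                         total_load = config@total_load, condition = cond)
      fracs <- fractionate(comp, nf[[cond]], n_fine_bins = acq@n_fine_bins)
      runs <- lapply(seq_along(fracs), function(j) {
        simulateDdaRun(fracs[[j]], acq, seed = .splitSeed(s_seed, j))
      })
      runs <- do.call(rbind, runs)
      if (nrow(runs)) runs$sample_id <- sample_id
      obs_list[[k]] <- runs
      design[[k]] <- data.frame(sample_id = sample_id, condition = cond,
                                replicate = rep_i,
                                bacterial_fraction = state$bf,
                                n_fractions = nf[[cond]],
                                stringsAsFactors = FALSE)
    }
  }
  observations <- do.call(rbind, obs_list)
  observations <- observations[, c("sample_id", "fraction", "peptide", "abundance")]
  rownames(observations) <- NULL
  observations$candidate_proteins <- .candidateString(observations$peptide,
                                                      proteome$map)
  observations <- observations[, c("sample_id", "fraction", "peptide",
                                   "candidate_proteins", "abundance")]
  list(observations = observations,
       design = do.call(rbind, design),
       truth = truth,
       proteome = proteome)
}

## semicolon-joined candidate lists in database order, one per peptide
.candidateString <- function(peptides, map) {
  pr <- map@proteins
  pa <- map@pairs
  ord <- pr$fasta_order[match(pa$protein_id, pr$protein_id)]
  pa <- pa[order(pa$peptide, ord), ]
  joined <- tapply(pa$protein_id, pa$peptide, paste, collapse = ";")
  as.character(joined[peptides])
}
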