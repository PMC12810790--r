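## Synthetic two-organism proteomes: proteins with log-normal copy mass,
## peptide catalogs with controllable sharing, and the ground-truth table
## used for recovery testing.

.AA_LETTERS <- names(.KYTE_DOOLITTLE)

## Random tryptic-looking peptide sequences: uniform internal composition
## over the 18 non-K/R residues, terminated by K or R. Lengths follow a
## shifted geometric over the allowed 6-40 range (short peptides dominate a
## real digest).
.randomPeptides <- function(n) {
  len <- 6L + pmin(rgeom_int(n, 0.12), 34L)
  internal <- setdiff(.AA_LETTERS, c("K", "R"))
  vapply(len, function(l) {
    paste0(paste(sample(internal, l - 1L, replace = TRUE), collapse = ""),
           sample(c("K", "R"), 1L))
  }, character(1))
}

rgeom_int <- function(n, prob) as.integer(stats::rgeom(n, prob))

#' Generate two synthetic proteomes and their peptide catalog
#'
#' Draws two organisms' protein sets with log-normal relative copy mass, a
#' peptide catalog (random tryptic-like sequences with GRAVY-based
#' hydrophobicity and log-normal ionization efficiency), and a candidate
#' peptide-to-protein map in which a configurable fraction of peptides is
#' shared by a second protein (rarely across organisms). `fasta_order`
#' follows the concatenated-database convention: all algal entries first,
#' then all bacterial entries.
#'
#' @param config a [SimConfig-class] from [simConfig()].
#' @param seed integer seed; the result is a pure function of
#'   `(config, seed)`.
#' @return list with elements:
#' \describe{
#'   \item{proteins}{data.frame `protein_id`, `gene_id`, `organism`,
#'     `base_abundance`, `fasta_order`.}
#'   \item{peptides}{data.frame `peptide`, `ionization`, `hydrophobicity`,
#'     `organism` (`"shared"` when parents span organisms), `n_parents`.}
#'   \item{map}{a [PeptideProteinMap-class].}
#' }
#' @examples
#' pr <- generateProteomes(simConfig(n_proteins_alga = 30L,
#'                                   n_proteins_bacterium = 10L), seed = 1)
#' head(pr$proteins)
#' @export
generateProteomes <- function(config, seed = 1L) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  withr::with_seed(.splitSeed(seed, 1L), {
    n_a <- config@n_proteins_alga
    n_b <- config@n_proteins_bacterium
    proteins <- data.frame(
      protein_id = c(sprintf("ALG%04d", seq_len(n_a)), sprintf("BAC%04d", seq_len(n_b))),
      organism = rep(c("alga", "bacterium"), c(n_a, n_b)),
      base_abundance = stats::rlnorm(n_a + n_b, config@abundance_meanlog,
                                     config@abundance_sdlog),
      fasta_order = seq_len(n_a + n_b),
      stringsAsFactors = FALSE)
    proteins$gene_id <- proteins$protein_id

    n_pep_per <- 1L + stats::rpois(nrow(proteins), config@peptides_per_protein - 1)
    parent <- rep(seq_len(nrow(proteins)), n_pep_per)
    n_pep <- length(parent)
    seqs <- .randomPeptides(n_pep)
    dup <- duplicated(seqs)
    while (any(dup)) {  # random collisions are vanishingly rare; regenerate
      seqs[dup] <- .randomPeptides(sum(dup))
      dup <- duplicated(seqs)
    }
    pairs <- data.frame(peptide = seqs, protein_idx = parent, stringsAsFactors = FALSE)

    ## sharing: each peptide independently gains one extra parent with
    ## probability sharing_rate; the extra parent is from the other organism
    ## with probability cross_organism_sharing, else from the same one.
    shared <- which(stats::runif(n_pep) < config@sharing_rate)
    if (length(shared)) {
      extra <- vapply(shared, function(i) {
        own <- parent[i]
        own_org <- proteins$organism[own]
        cross <- stats::runif(1) < config@cross_organism_sharing
        pool <- which((proteins$organism == own_org) != cross)
        pool <- setdiff(pool, own)
        if (!length(pool)) return(NA_integer_)
        if (length(pool) == 1L) pool else sample(pool, 1L)
      }, integer(1))
      ok <- !is.na(extra)
      if (any(ok)) {
        pairs <- rbind(pairs, data.frame(peptide = seqs[shared[ok]],
                                         protein_idx = extra[ok],
                                         stringsAsFactors = FALSE))
      }
    }
    pairs$protein_id <- proteins$protein_id[pairs$protein_idx]
    pairs <- unique(pairs[, c("peptide", "protein_id")])

    ## per-peptide physical attributes; hydrophobicity is GRAVY plus jitter
    gravy <- vapply(seqs, gravyScore, numeric(1), USE.NAMES = FALSE)
    peptides <- data.frame(
      peptide = seqs,
      ionization = stats::rlnorm(n_pep, 0, config@ionization_sdlog),
      hydrophobicity = gravy + stats::runif(n_pep, -0.25, 0.25),
      stringsAsFactors = FALSE)
    np <- table(pairs$peptide)
    peptides$n_parents <- as.integer(np[peptides$peptide])
    org_by_pep <- tapply(proteins$organism[match(pairs$protein_id, proteins$protein_id)],
                         pairs$peptide, function(o) {
                           u <- unique(o)
                           if (length(u) == 1L) u else "shared"
                         })
    peptides$organism <- as.character(org_by_pep[peptides$peptide])

    map <- peptideProteinMap(
      pairs,
      proteins[, c("protein_id", "gene_id", "organism", "fasta_order")])
    list(proteins = proteins[, c("protein_id", "gene_id", "organism",
                                 "base_abundance", "fasta_order")],
         peptides = peptides, map = map)
  })
}

#' Build or perturb a ground-truth table
#'
#' `simTruth()` initializes a truth table from a protein set (no effects:
#' coculture equals monoculture). `imposeEffects()` multiplies selected
#' proteins' coculture abundance by `2^effect` and records them as regulated.
#'
#' @param proteins data.frame from [generateProteomes()] (needs
#'   `protein_id`, `gene_id`, `organism`, `base_abundance`).
#' @return data.frame with columns `protein_id`, `gene_id`, `organism`,
#'   `abundance_mono`, `abundance_coculture`, `true_log2fc`, `is_regulated`.
#' @examples
#' pr <- generateProteomes(simConfig(n_proteins_alga = 20L,
#'                                   n_proteins_bacterium = 10L), seed = 1)
#' tr <- simTruth(pr$proteins)
#' tr <- imposeEffects(tr, protein_ids = tr$protein_id[1], log2_effect = 2)
#' tr[1, ]
#' @export
simTruth <- function(proteins) {
  data.frame(
    protein_id = proteins$protein_id,
    gene_id = proteins$gene_id,
    organism = proteins$organism,
    abundance_mono = proteins$base_abundance,
    abundance_coculture = proteins$base_abundance,
    true_log2fc = 0,
    is_regulated = FALSE,
    stringsAsFactors = FALSE)
}

#' @rdname simTruth
#' @param truth a truth table from [simTruth()].
#' @param protein_ids explicit proteins to perturb; unknown ids are an error.
#' @param log2_effect log2 effect size(s), recycled over `protein_ids`.
#' @param fraction alternatively, perturb a random fraction of proteins with
#'   effects of magnitude `log2_effect` and random sign.
#' @param seed seed used only when `fraction` sampling is requested.
#' @export
imposeEffects <- function(truth, protein_ids = NULL, log2_effect = 2,
                          fraction = NULL, seed = 1L) {
  if (!is.null(fraction)) {
    stopifnot(.isProb(fraction))
    withr::with_seed(.splitSeed(seed, 2L), {
      n <- max(0L, round(fraction * nrow(truth)))
      idx <- if (n > 0) sample(nrow(truth), n) else integer(0)
      protein_ids <- truth$protein_id[idx]
      log2_effect <- abs(log2_effect) * sample(c(-1, 1), length(idx), replace = TRUE)
    })
  }
  if (!length(protein_ids)) return(truth)
  idx <- match(protein_ids, truth$protein_id)
  if (anyNA(idx)) {
    stop("unknown protein id(s): ",
         paste(protein_ids[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  eff <- rep_len(log2_effect, length(idx))
  truth$abundance_coculture[idx] <- truth$abundance_coculture[idx] * 2^eff
  truth$true_log2fc[idx] <- truth$true_log2fc[idx] + eff
  truth$is_regulated[idx] <- TRUE
  truth
}
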