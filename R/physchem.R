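## Sequence-based physicochemical properties: isoelectric point (EMBOSS pKa
## set), GRAVY hydropathy (Kyte-Doolittle) and molecular weight (Expasy
## average residue masses). These feed both the proteome characterization
## and the simulator's hydrophobicity proxy.

## EMBOSS pKa value set: terminal amine/carboxyl plus ionizable side chains.
.PKA_EMBOSS <- c(Nterm = 8.6, Cterm = 3.6,
                 C = 8.5, D = 3.9, E = 4.1, H = 6.5,
                 K = 10.8, R = 12.5, Y = 10.1)

## Kyte-Doolittle hydropathy index.
.KYTE_DOOLITTLE <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
  L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

## Expasy average residue masses (Da); a residue is the amino acid minus one
## water, so a chain's mass is the residue sum plus one water.
.MASS_EXPASY <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)

.MASS_WATER <- 18.01524

.aaVector <- function(sequence) {
  if (length(sequence) != 1L || is.na(sequence) || !nzchar(sequence)) {
    stop("sequence must be a single non-empty string", call. = FALSE)
  }
  strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
}

.dropNonstandard <- function(aa, what) {
  bad <- !(aa %in% names(.KYTE_DOOLITTLE))
  if (any(bad)) {
    warning(sprintf("%d nonstandard residue(s) (%s) excluded from %s",
                    sum(bad), paste(unique(aa[bad]), collapse = ","), what),
            call. = FALSE)
  }
  aa[!bad]
}

## Henderson-Hasselbalch net charge at a given pH. Basic groups (N-terminus,
## H, K, R) contribute +n/(1+10^(pH-pKa)); acidic groups (C-terminus, C, D,
## E, Y) contribute -n/(1+10^(pKa-pH)).
.netCharge <- function(counts, pH) {
  basic <- c("Nterm", "H", "K", "R")
  acidic <- c("Cterm", "C", "D", "E", "Y")
  pos <- sum(counts[basic] / (1 + 10 ^ (pH - .PKA_EMBOSS[basic])))
  neg <- sum(counts[acidic] / (1 + 10 ^ (.PKA_EMBOSS[acidic] - pH)))
  pos - neg
}

#' Isoelectric point of a polypeptide
#'
#' pH at which the modeled net charge is zero, found by bisection on the
#' Henderson-Hasselbalch net-charge function using the EMBOSS pKa set
#' (free termini plus C, D, E, H, K, R, Y side chains). Nonstandard letters
#' are excluded from the charge model with a warning.
#'
#' @param sequence single amino-acid string.
#' @param tol bisection tolerance in pH units (default 1e-4).
#' @return The pI in pH units.
#' @examples
#' isoelectricPoint("GG")      # termini only: midpoint of the terminal pKas
#' isoelectricPoint("ACDEFGHIKLMNPQRSTVWY")
#' @export
isoelectricPoint <- function(sequence, tol = 1e-4) {
  aa <- .dropNonstandard(.aaVector(sequence), "the charge model")
  groups <- c("Nterm", "Cterm", "C", "D", "E", "H", "K", "R", "Y")
  counts <- setNames(numeric(length(groups)), groups)
  counts["Nterm"] <- 1
  counts["Cterm"] <- 1
  tab <- table(aa)
  side <- intersect(names(tab), groups)
  counts[side] <- counts[side] + as.numeric(tab[side])
  lo <- 0; hi <- 14
  ## net charge is strictly decreasing in pH
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (.netCharge(counts, mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Grand average of hydropathy (GRAVY)
#'
#' Mean Kyte-Doolittle hydropathy over the sequence's residues. Unknown
#' letters are excluded with a warning.
#'
#' @param sequence single amino-acid string.
#' @return The GRAVY score (dimensionless).
#' @examples
#' gravyScore("VVV")   # 4.2, the valine index value
#' @export
gravyScore <- function(sequence) {
  aa <- .dropNonstandard(.aaVector(sequence), "GRAVY")
  if (!length(aa)) stop("no standard residues in sequence", call. = FALSE)
  mean(.KYTE_DOOLITTLE[aa])
}

#' Molecular weight of a polypeptide
#'
#' Sum of Expasy average residue masses plus one water. Nonstandard letters
#' are assigned the mean standard residue mass, with a warning.
#'
#' @param sequence single amino-acid string.
#' @return Average-mass molecular weight in Daltons.
#' @examples
#' molecularWeight("G")    # 75.07
#' molecularWeight("GG")   # 132.12
#' @export
molecularWeight <- function(sequence) {
  aa <- .aaVector(sequence)
  known <- aa %in% names(.MASS_EXPASY)
  if (any(!known)) {
    warning(sprintf("%d nonstandard residue(s) assigned the mean residue mass",
                    sum(!known)), call. = FALSE)
  }
  sum(.MASS_EXPASY[aa[known]]) + sum(!known) * mean(.MASS_EXPASY) + .MASS_WATER
}

#' Physicochemical profile of a protein set
#'
#' Computes pI, GRAVY and molecular weight for every sequence.
#'
#' @param sequences named character vector or
#'   [Biostrings::AAStringSet] of protein sequences.
#' @return data.frame with columns `protein_id`, `pI`, `gravy`, `mw`.
#' @seealso [readProteomeFasta()]
#' @export
physchemProfile <- function(sequences) {
  if (is(sequences, "AAStringSet")) sequences <- setNames(as.character(sequences), names(sequences))
  ids <- names(sequences)
  if (is.null(ids)) ids <- paste0("protein", seq_along(sequences))
  data.frame(
    protein_id = ids,
    pI = vapply(sequences, isoelectricPoint, numeric(1), USE.NAMES = FALSE),
    gravy = vapply(sequences, gravyScore, numeric(1), USE.NAMES = FALSE),
    mw = vapply(sequences, molecularWeight, numeric(1), USE.NAMES = FALSE),
    stringsAsFactors = FALSE)
}

#' In-silico tryptic digestion
#'
#' Cleaves each protein after K or R, except before proline, allowing up to
#' `missed` missed cleavages, and keeps peptides within the given length
#' range -- the standard convention for trypsin.
#'
#' @param sequences named character vector or [Biostrings::AAStringSet];
#'   names become protein identifiers (database order is preserved).
#' @param missed maximum missed cleavages (default 1).
#' @param length_range keep peptides whose length lies in this range
#'   (default 6 to 40).
#' @return A [PeptideProteinMap-class] whose `pairs` are the distinct
#'   peptide/protein relationships and whose `proteins` keep input order as
#'   `fasta_order`. Organism labels default to `"alga"`; set them afterwards
#'   or supply gene/organism metadata via [peptideProteinMap()].
#' @export
digestProteins <- function(sequences, missed = 1L, length_range = c(6L, 40L)) {
  if (is(sequences, "AAStringSet")) sequences <- setNames(as.character(sequences), names(sequences))
  ids <- names(sequences)
  if (is.null(ids)) ids <- paste0("protein", seq_along(sequences))
  pairs <- vector("list", length(sequences))
  for (i in seq_along(sequences)) {
    frag <- .trypticFragments(sequences[[i]], missed, length_range)
    if (length(frag)) {
      pairs[[i]] <- data.frame(peptide = frag, protein_id = ids[i],
                               stringsAsFactors = FALSE)
    }
  }
  pairs <- do.call(rbind, pairs)
  if (is.null(pairs)) pairs <- data.frame(peptide = character(), protein_id = character())
  pairs <- unique(pairs)
  proteins <- data.frame(protein_id = ids, gene_id = ids, organism = "alga",
                         fasta_order = seq_along(ids), stringsAsFactors = FALSE)
  peptideProteinMap(pairs, proteins)
}

.trypticFragments <- function(sequence, missed, length_range) {
  aa <- .aaVector(sequence)
  n <- length(aa)
  ## cut after position i if aa[i] is K/R and aa[i+1] is not P
  cut_after <- which(aa %in% c("K", "R"))
  cut_after <- cut_after[cut_after == n | aa[pmin(cut_after + 1L, n)] != "P"]
  bounds <- c(0L, cut_after, if (!n %in% cut_after) n)
  starts <- head(bounds, -1L) + 1L
  ends <- bounds[-1L]
  out <- character(0)
  for (m in 0:missed) {
    i <- seq_len(length(starts) - m)
    if (!length(i)) break
    s <- starts[i]; e <- ends[i + m]
    len <- e - s + 1L
    keep <- len >= length_range[1] & len <= length_range[2]
    out <- c(out, substring(sequence, s[keep], e[keep]))
  }
  unique(out)
}
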