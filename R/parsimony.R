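## Parsimony assignment of shared peptides to single proteins.

#' Assign each peptide to exactly one protein by parsimony
#'
#' Applies the standard four-rule cascade, taking the first rule that
#' decides:
#' \enumerate{
#'   \item a peptide mapping to a single protein is assigned to it;
#'   \item a non-unique peptide whose candidates include exactly one protein
#'     that also carries a different uniquely-mapping peptide is assigned to
#'     that protein (with several such candidates the rule does not decide
#'     and the cascade continues);
#'   \item otherwise the candidate carrying strictly the most \emph{other}
#'     non-uniquely-mapping peptides wins;
#'   \item remaining ties are broken by the first occurrence in the search
#'     database (`fasta_order`).
#' }
#'
#' @param map a [PeptideProteinMap-class].
#' @return data.frame `peptide`, `protein_id`, `gene_id`, `rule`
#'   (`"a"`..`"d"`), `is_unique`.
#' @examples
#' map <- peptideProteinMap(
#'   pairs = data.frame(peptide = c("p1", "p2", "p2"),
#'                      protein_id = c("A", "A", "B")),
#'   proteins = data.frame(protein_id = c("A", "B")))
#' assignParsimony(map)
#' @export
assignParsimony <- function(map) {
  stopifnot(is(map, "PeptideProteinMap"))
  validObject(map)
  pairs <- map@pairs
  proteins <- map@proteins
  if (!nrow(pairs)) {
    return(data.frame(peptide = character(), protein_id = character(),
                      gene_id = character(), rule = character(),
                      is_unique = logical()))
  }
  dt <- data.table::as.data.table(pairs)
  dt[, n_cand := .N, by = peptide]
  ## evidence tables
  uniq_pep <- dt[n_cand == 1L]
  has_unique <- unique(uniq_pep$protein_id)
  nonuniq_count <- dt[n_cand > 1L, .(n_nonuniq = .N), by = protein_id]
  dt[, fasta_order := proteins$fasta_order[match(protein_id, proteins$protein_id)]]
  dt[, n_nonuniq := nonuniq_count$n_nonuniq[match(protein_id, nonuniq_count$protein_id)]]
  dt[is.na(n_nonuniq), n_nonuniq := 0L]
  dt[, has_uniq := protein_id %in% has_unique]

  pickOne <- function(protein_id, n_cand, has_uniq, n_nonuniq, fasta_order) {
    if (n_cand[1] == 1L) return(list(protein_id = protein_id[1], rule = "a"))
    ## rule b: exactly one candidate with independent unique evidence
    if (sum(has_uniq) == 1L) {
      return(list(protein_id = protein_id[has_uniq], rule = "b"))
    }
    ## rule c: most other non-unique peptides (excluding this one; the
    ## peptide counts once for every candidate, so the offset cancels)
    best <- n_nonuniq == max(n_nonuniq)
    if (sum(best) == 1L) {
      return(list(protein_id = protein_id[best], rule = "c"))
    }
    ## rule d: first occurrence in the database
    cand <- which(best)
    winner <- cand[which.min(fasta_order[cand])]
    list(protein_id = protein_id[winner], rule = "d")
  }
  res <- dt[, pickOne(protein_id, n_cand, has_uniq, n_nonuniq, fasta_order),
            by = peptide]
  out <- as.data.frame(res)
  out$gene_id <- proteins$gene_id[match(out$protein_id, proteins$protein_id)]
  out$is_unique <- out$rule == "a"
  out <- out[order(out$peptide), c("peptide", "protein_id", "gene_id",
                                   "rule", "is_unique")]
  rownames(out) <- NULL
  out
}
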