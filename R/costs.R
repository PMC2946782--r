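#' Edit-operation cost model
#'
#' Weights for the string edit operations used by all CDR3 distances.
#' Matches are free and substitutions cost 1. Gaps are charged affinely:
#' the first position of each maximal run of contiguous insertions or
#' deletions carries the per-gap opening surcharge `gap_open` (charged
#' once per gap, whatever its length) and each further position costs
#' `gap_extend`. The defaults (3 and 1) penalize opening a gap three
#' times as much as a substitution, reflecting that length-changing
#' events are rare in clonally-related junctions. Setting
#' `gap_open = gap_extend = substitution` recovers the classical
#' unit-cost Levenshtein distance.
#'
#' A strictly positive `gap_extend` matters for the normalized distances:
#' with free gap extensions the weight of deleting one string wholesale
#' and inserting the other is bounded by `2 * gap_open`, which drags the
#' normalized distance of arbitrary unrelated sequences toward zero and
#' defeats any fixed clonal threshold.
#'
#' @param match cost of an aligned identical pair (default 0).
#' @param substitution cost of an aligned mismatching pair (default 1).
#'   `N` mismatches every base, including `N`.
#' @param gap_open cost of the first position of an indel run (default 3).
#' @param gap_extend cost of each subsequent position (default 1).
#' @return An object of class `cost_model`.
#' @examples
#' cost_model()                                 # defaults: 0 / 1 / 3 / 1
#' cost_model(gap_open = 1, gap_extend = 1)     # unit-cost Levenshtein
#' @export
cost_model <- function(match = 0, substitution = 1, gap_open = 3,
                       gap_extend = 1) {
  stopifnot(match >= 0, substitution >= 0, gap_open > 0, gap_extend >= 0)
  structure(list(match = match, substitution = substitution,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "cost_model")
}

#' Germline mismatch penalty scheme
#'
#' Penalties added to the NED numerator when two sequences carry different
#' IGHV or IGHJ germline assignments. The default scheme charges 5 for a
#' different IGHV subgroup, 3 for a different gene within a subgroup and 1
#' for a different allele of the same gene; IGHJ genes have no subgroup
#' tier, so only the gene (3) and allele (1) penalties apply.
#'
#' @param v_subgroup,v_gene,v_allele IGHV penalties, `v_allele <= v_gene <=
#'   v_subgroup`.
#' @param j_gene,j_allele IGHJ penalties, `j_allele <= j_gene`.
#' @return An object of class `penalty_scheme`.
#' @export
penalty_scheme <- function(v_subgroup = 5, v_gene = 3, v_allele = 1,
                           j_gene = 3, j_allele = 1) {
  stopifnot(0 <= v_allele, v_allele <= v_gene, v_gene <= v_subgroup,
            0 <= j_allele, j_allele <= j_gene)
  structure(list(v_subgroup = v_subgroup, v_gene = v_gene,
                 v_allele = v_allele, j_gene = j_gene, j_allele = j_allele),
            class = "penalty_scheme")
}
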