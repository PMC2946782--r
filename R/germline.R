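#' Parse an IMGT-style germline gene label
#'
#' Splits a label such as `"IGHV1-2*01"` into its nomenclature tiers:
#' subgroup (`IGHV1`), gene (`IGHV1-2`) and allele (`01`). IGHJ genes are
#' not classified into subgroups, so for `locus = "J"` only gene and allele
#' are populated. When an aligner reports several equally likely
#' assignments (e.g. `"IGHV1-2*01 or IGHV1-2*05"`, or comma-separated),
#' the first listed is used.
#'
#' @param label germline label string.
#' @param locus `"V"` or `"J"`; the label must start with `IGHV`/`IGHJ`
#'   accordingly.
#' @return a list of class `germline_call` with elements `raw`, `locus`,
#'   `subgroup` (`NA` for J), `gene`, `allele` (`NA` when absent).
#' @examples
#' parse_call("IGHV1-2*01", "V")
#' parse_call("IGHJ4*02", "J")
#' @export
parse_call <- function(label, locus = c("V", "J")) {
  locus <- match.arg(locus)
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  raw <- label
  # first of several alternative assignments
  label <- strsplit(trimws(label), "\\s+or\\s+|,")[[1]][1]
  label <- trimws(label)
  prefix <- paste0("IGH", locus)
  if (!startsWith(label, prefix))
    stop("label '", raw, "' does not start with ", prefix, call. = FALSE)
  star <- regexpr("*", label, fixed = TRUE)
  if (star > 0) {
    gene <- substr(label, 1L, star - 1L)
    allele <- substr(label, star + 1L, nchar(label))
    if (!nzchar(allele)) allele <- NA_character_
  } else {
    gene <- label
    allele <- NA_character_
  }
  subgroup <- NA_character_
  if (locus == "V") {
    digits <- regmatches(gene, regexpr("^IGHV[0-9]+", gene))
    if (length(digits) == 0L)
      stop("cannot determine IGHV subgroup from '", raw, "'", call. = FALSE)
    subgroup <- digits
  }
  structure(list(raw = raw, locus = locus, subgroup = subgroup,
                 gene = gene, allele = allele),
            class = "germline_call")
}

as_call <- function(x, locus) {
  if (inherits(x, "germline_call")) x else parse_call(x, locus)
}

#' Germline mismatch penalties
#'
#' `v_penalty()` applies the IGHV cascade: 0 when both sequences carry the
#' same gene and allele, the allele penalty when only the allele differs
#' (or is missing in one call), the gene penalty when the genes differ
#' within a subgroup, and the subgroup penalty when the subgroups differ.
#' `j_penalty()` applies the same cascade without the subgroup tier.
#' Exactly one tier fires for every pair.
#'
#' @param a,b [parse_call()] results (or raw labels, parsed on the fly).
#' @param penalties a [penalty_scheme()].
#' @return a single non-negative penalty.
#' @examples
#' v_penalty("IGHV1-2*01", "IGHV1-2*02")   # 1, allele mismatch
#' v_penalty("IGHV1-2*01", "IGHV3-23*01")  # 5, subgroup mismatch
#' j_penalty("IGHJ4*02", "IGHJ6*01")       # 3, gene mismatch
#' @export
v_penalty <- function(a, b, penalties = penalty_scheme()) {
  a <- as_call(a, "V"); b <- as_call(b, "V")
  stopifnot(a$locus == "V", b$locus == "V")
  if (a$gene == b$gene) {
    if (identical(a$allele, b$allele) && !is.na(a$allele)) return(0)
    if (is.na(a$allele) && is.na(b$allele)) return(0)
    return(penalties$v_allele)
  }
  if (a$subgroup == b$subgroup) return(penalties$v_gene)
  penalties$v_subgroup
}

#' @rdname v_penalty
#' @export
j_penalty <- function(a, b, penalties = penalty_scheme()) {
  a <- as_call(a, "J"); b <- as_call(b, "J")
  stopifnot(a$locus == "J", b$locus == "J")
  if (a$gene == b$gene) {
    if (identical(a$allele, b$allele) && !is.na(a$allele)) return(0)
    if (is.na(a$allele) && is.na(b$allele)) return(0)
    return(penalties$j_allele)
  }
  penalties$j_gene
}

#' Germline-aware normalized edit distance (NED_VJ)
#'
#' The clonal-relatedness distance between two sequences: the normalized
#' edit distance between their CDR3s with the IGHV and IGHJ mismatch
#' penalties `S_V` and `S_J` added to the numerator,
#' `min over paths P of (W(P) + S_V + S_J) / L(P)`.
#' Since `S_V + S_J` is constant for a pair, this is [ned()] with
#' `offset = S_V + S_J`; the minimizing path is re-optimized under the
#' shifted numerator rather than inherited from the Levenshtein optimum.
#'
#' @param a,b CDR3 records: lists (or one-row data frames) with elements
#'   `cdr3`, `v_call`, `j_call`, as produced by [extract_cdr3()].
#' @param costs a [cost_model()].
#' @param penalties a [penalty_scheme()].
#' @return a single non-negative distance.
#' @examples
#' a <- list(cdr3 = "TGTGCGAGAGG", v_call = "IGHV1-2*01", j_call = "IGHJ4*02")
#' b <- list(cdr3 = "TGTGCGAGAGG", v_call = "IGHV1-2*02", j_call = "IGHJ4*02")
#' ned_vj(a, b)   # (0 + 1 + 0) / 11
#' @export
ned_vj <- function(a, b, costs = cost_model(), penalties = penalty_scheme()) {
  sv <- v_penalty(a$v_call, b$v_call, penalties)
  sj <- j_penalty(a$j_call, b$j_call, penalties)
  ned(a$cdr3, b$cdr3, costs, offset = sv + sj)
}
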