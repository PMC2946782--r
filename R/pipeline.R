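#' Identify clonally-related sequence sets
#'
#' End-to-end pipeline: extract CDR3s from partitioned records, compute
#' the pairwise distance matrix under the chosen metric (NED_VJ by
#' default), agglomerate by average linkage and cut the dendrogram at the
#' clonal threshold.
#'
#' @param records partitioned-sequence data frame
#'   ([parse_partitioned_file()] `$records` or
#'   [simulate_repertoire()] `$records`).
#' @param vlib,jlib CDR3 starting/ending length libraries (named integer
#'   vectors; see [build_v_start_library()], [build_j_end_library()] or
#'   [read_library_tsv()]).
#' @param metric distance measure, one of `"ned_vj"`, `"ned"`, `"pned"`,
#'   `"ld"`.
#' @param tau clonal distance threshold (default 0.32).
#' @param strict cut strictly below `tau` (default) or at-or-below.
#' @param costs a [cost_model()].
#' @param penalties a [penalty_scheme()].
#' @return list with `assignments` (data frame `seq_id`, `set_id`,
#'   `set_size`; excluded records appear as singletons), `sets`,
#'   `singletons`, `tree` (dendrogram root), `trajectory` (merge-height
#'   data frame), `cdr3` (extracted records) and `excluded`.
#' @examples
#' pools <- synthetic_germlines(seed = 1)
#' sim <- simulate_repertoire(n_clones = 5, pools = pools, seed = 2)
#' res <- clonal_sets(sim$records, pools$vlib, pools$jlib)
#' head(res$assignments)
#' @export
clonal_sets <- function(records, vlib, jlib,
                        metric = c("ned_vj", "ned", "pned", "ld"),
                        tau = 0.32, strict = TRUE,
                        costs = cost_model(), penalties = penalty_scheme()) {
  metric <- match.arg(metric)
  ex <- extract_cdr3(records, vlib, jlib)
  if (nrow(ex$records) < 2L)
    stop("fewer than 2 sequences with extractable CDR3s")
  d <- build_matrix(ex$records, metric, costs, penalties)
  tree <- upgma(d)
  cut <- cut_tree(tree, tau = tau, strict = strict)
  assignments <- cut$assignments
  if (nrow(ex$excluded) > 0L) {
    assignments <- rbind(assignments, data.frame(
      seq_id = ex$excluded$seq_id, set_id = NA_integer_, set_size = 1L,
      stringsAsFactors = FALSE))
  }
  list(assignments = assignments, sets = cut$sets,
       singletons = cut$singletons, tree = tree,
       trajectory = merge_trajectory(tree),
       cdr3 = ex$records, excluded = ex$excluded)
}
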