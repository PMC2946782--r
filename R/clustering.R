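#' Dendrogram node constructors
#'
#' Dendrograms are binary merge trees represented as nested lists:
#' `dendro_leaf(id)` wraps a sequence id, `dendro_merge(height, a, b)` an
#' internal merge of two subtrees at a given height. `dendro_members()`
#' returns the sorted leaf ids beneath a node.
#'
#' @param id leaf sequence id.
#' @param height merge height (the average-linkage distance).
#' @param a,b child nodes.
#' @param node a dendrogram node.
#' @export
dendro_leaf <- function(id) {
  list(leaf = TRUE, id = id)
}

#' @rdname dendro_leaf
#' @export
dendro_merge <- function(height, a, b) {
  list(leaf = FALSE, height = height, children = list(a, b))
}

#' @rdname dendro_leaf
#' @export
dendro_members <- function(node) {
  if (isTRUE(node$leaf)) return(node$id)
  sort(c(dendro_members(node$children[[1]]),
         dendro_members(node$children[[2]])))
}

#' Pairwise distance matrix over CDR3 records
#'
#' Computes all `n(n-1)/2` pairwise distances between extracted CDR3
#' records under the chosen metric. For `"ned_vj"` the IGHV/IGHJ germline
#' mismatch penalties of each pair are added to the NED numerator
#' (see [ned_vj()]).
#'
#' @param records CDR3 record data frame ([extract_cdr3()] `$records`).
#' @param metric one of `"ned_vj"` (default), `"ned"`, `"pned"`, `"ld"`.
#' @param costs a [cost_model()].
#' @param penalties a [penalty_scheme()] (used by `"ned_vj"` only).
#' @return symmetric numeric matrix with zero diagonal; `dimnames` are the
#'   sequence ids.
#' @export
build_matrix <- function(records, metric = c("ned_vj", "ned", "pned", "ld"),
                         costs = cost_model(), penalties = penalty_scheme()) {
  metric <- match.arg(metric)
  n <- nrow(records)
  if (n < 2L) stop("need at least 2 records to build a distance matrix")
  cdr3 <- toupper(records$cdr3)
  bad <- !grepl("^[ACGTN]+$", cdr3)
  if (any(bad))
    stop("invalid CDR3 for: ", paste(records$seq_id[bad], collapse = ", "))
  offsets <- matrix(0, n, n)
  if (metric == "ned_vj") {
    vcalls <- lapply(records$v_call, parse_call, locus = "V")
    jcalls <- lapply(records$j_call, parse_call, locus = "J")
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        offsets[i, j] <- v_penalty(vcalls[[i]], vcalls[[j]], penalties) +
          j_penalty(jcalls[[i]], jcalls[[j]], penalties)
        offsets[j, i] <- offsets[i, j]
      }
    }
  }
  base_metric <- if (metric == "ned_vj") "ned" else metric
  d <- cpp_distance_matrix(cdr3, offsets, base_metric,
                           costs$match, costs$substitution,
                           costs$gap_open, costs$gap_extend)
  dimnames(d) <- list(records$seq_id, records$seq_id)
  d
}

# average distance between two clusters recomputed from the original matrix
pair_key <- function(a, b) sort(c(a, b))

#' Average-linkage (UPGMA) agglomeration
#'
#' Builds a dendrogram by repeatedly merging the pair of clusters with the
#' smallest unweighted mean of the original pairwise distances between
#' their members. Ties are broken deterministically by the
#' lexicographically smallest pair of smallest-member ids. Average linkage
#' produces monotone merge heights (no inversions); this is asserted on
#' every run.
#'
#' @param d symmetric distance matrix with sequence ids as `dimnames`
#'   (from [build_matrix()]).
#' @return the root dendrogram node (see [dendro_leaf()]).
#' @export
upgma <- function(d) {
  ids <- rownames(d)
  if (is.null(ids)) stop("distance matrix must carry sequence ids as dimnames")
  n <- length(ids)
  if (n == 1L) return(dendro_leaf(ids[1]))
  stopifnot(isTRUE(all.equal(d, t(d))), all(diag(d) == 0))

  nodes <- lapply(ids, dendro_leaf)
  sizes <- rep(1L, n)
  min_id <- ids
  D <- d
  diag(D) <- Inf
  active <- rep(TRUE, n)
  prev_h <- -Inf
  for (step in seq_len(n - 1L)) {
    act <- which(active)
    sub <- D[act, act, drop = FALSE]
    h <- min(sub)
    # candidate pairs at the minimum; deterministic tie-break on the
    # lexicographically smallest (sorted) pair of smallest-member ids
    cand <- which(sub == h, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    keys <- apply(cand, 1L, function(rc) {
      paste(pair_key(min_id[act[rc[1]]], min_id[act[rc[2]]]), collapse = "\r")
    })
    pick <- cand[order(keys)[1], ]
    i <- act[pick[1]]; j <- act[pick[2]]

    stopifnot(h >= prev_h - 1e-12)   # no inversions under average linkage
    prev_h <- h
    merged <- dendro_merge(h, nodes[[i]], nodes[[j]])
    # unweighted average over original distances via Lance-Williams update
    others <- setdiff(act, c(i, j))
    if (length(others) > 0L) {
      D[i, others] <- (sizes[i] * D[i, others] + sizes[j] * D[j, others]) /
        (sizes[i] + sizes[j])
      D[others, i] <- D[i, others]
    }
    nodes[[i]] <- merged
    sizes[i] <- sizes[i] + sizes[j]
    min_id[i] <- min(min_id[i], min_id[j])
    active[j] <- FALSE
    D[j, ] <- Inf; D[, j] <- Inf
  }
  nodes[[which(active)]]
}

#' Cut a dendrogram into clonal sets
#'
#' Extracts the maximal subtrees all of whose internal merge heights lie
#' below the threshold. Subtrees with at least two leaves become clonal
#' sets, numbered by decreasing size then lexicographic smallest member;
#' remaining leaves are singletons.
#'
#' @param tree dendrogram root from [upgma()].
#' @param tau distance threshold (default 0.32, the empirical cutoff below
#'   which a cluster is considered clonally related).
#' @param strict if `TRUE` (default) subtree heights must be strictly
#'   below `tau`; if `FALSE`, at or below.
#' @return list with `sets` (named list of member id vectors),
#'   `singletons` (character vector) and `assignments` (data frame
#'   `seq_id`, `set_id` — `NA` for singletons — and `set_size`).
#' @export
cut_tree <- function(tree, tau = 0.32, strict = TRUE) {
  below <- function(h) if (strict) h < tau else h <= tau
  sets <- list()
  singles <- character(0)
  descend <- function(node) {
    if (isTRUE(node$leaf)) {
      singles <<- c(singles, node$id)
    } else if (below(node$height)) {
      # heights are monotone, so the root height bounds the subtree
      sets[[length(sets) + 1L]] <<- dendro_members(node)
    } else {
      descend(node$children[[1]])
      descend(node$children[[2]])
    }
  }
  descend(tree)
  if (length(sets) > 0L) {
    ord <- order(-lengths(sets),
                 vapply(sets, function(s) s[1], character(1)))
    sets <- sets[ord]
    names(sets) <- seq_along(sets)
  }
  assignments <- data.frame(
    seq_id = c(unlist(sets, use.names = FALSE), singles),
    set_id = c(rep(seq_along(sets), lengths(sets)),
               rep(NA_integer_, length(singles))),
    set_size = c(rep(lengths(sets), lengths(sets)),
                 rep(1L, length(singles))),
    stringsAsFactors = FALSE)
  rownames(assignments) <- NULL
  list(sets = sets, singletons = sort(singles), assignments = assignments)
}

#' Merge trajectory of a dendrogram
#'
#' The sequence of merge heights in agglomeration order (non-decreasing
#' under average linkage). Plotting height against merge index gives the
#' evaluation graph used to choose the clonal threshold: the curve rises
#' slowly while clonally-related sequences merge, then sharply once
#' unrelated sequences start to join.
#'
#' @param tree dendrogram root from [upgma()].
#' @return data frame with `merge_index` and `height`; empty for a single
#'   leaf.
#' @export
merge_trajectory <- function(tree) {
  heights <- numeric(0)
  walk <- function(node) {
    if (!isTRUE(node$leaf)) {
      heights <<- c(heights, node$height)
      walk(node$children[[1]])
      walk(node$children[[2]])
    }
  }
  walk(tree)
  heights <- sort(heights)
  data.frame(merge_index = seq_along(heights), height = heights)
}

#' Compare predicted clonal sets with a benchmark labelling
#'
#' A sequence is counted correct if and only if its predicted clonal set
#' contains exactly the same members as its benchmark set. The metrics are
#' the number of predicted sets below the threshold, the sequences they
#' contain, the predicted sets that differ from every benchmark set, the
#' members of such differing sets, and the percentage correct,
#' `100 * (n_seqs_below - n_incorrect_seqs) / n_seqs_below`.
#'
#' @param pred predicted sets: the list returned by [cut_tree()], or a
#'   list of member id vectors.
#' @param truth benchmark labelling: data frame with `seq_id` and `set_id`
#'   (`NA` or `"singleton"` for unclustered sequences).
#' @return list of class `eval_metrics` with `n_clusters_below`,
#'   `n_seqs_below`, `n_clusters_diff`, `n_incorrect_seqs`, `pct_correct`.
#' @export
evaluate <- function(pred, truth) {
  sets <- if (is.list(pred) && !is.null(pred$sets)) pred$sets else pred
  truth$set_id <- as.character(truth$set_id)
  truth$set_id[truth$set_id %in% "singleton"] <- NA_character_
  pred_ids <- unlist(sets, use.names = FALSE)
  missing <- setdiff(pred_ids, truth$seq_id)
  if (length(missing) > 0L)
    stop("predicted ids missing from truth: ", paste(missing, collapse = ", "))
  # benchmark set of each sequence (singletons are their own set)
  truth_sets <- split(truth$seq_id, truth$set_id)
  truth_of <- stats::setNames(vector("list", nrow(truth)), truth$seq_id)
  for (s in truth_sets) for (id in s) truth_of[[id]] <- sort(s)
  for (id in truth$seq_id[is.na(truth$set_id)]) truth_of[[id]] <- id

  n_clusters_below <- length(sets)
  n_seqs_below <- length(pred_ids)
  n_clusters_diff <- 0L
  n_incorrect <- 0L
  for (s in sets) {
    s <- sort(s)
    if (!identical(truth_of[[s[1]]], s)) {
      n_clusters_diff <- n_clusters_diff + 1L
      n_incorrect <- n_incorrect + length(s)
    }
  }
  pct <- if (n_seqs_below == 0L) NA_real_ else
    100 * (n_seqs_below - n_incorrect) / n_seqs_below
  structure(list(n_clusters_below = n_clusters_below,
                 n_seqs_below = n_seqs_below,
                 n_clusters_diff = n_clusters_diff,
                 n_incorrect_seqs = n_incorrect,
                 pct_correct = pct),
            class = "eval_metrics")
}

#' @export
print.eval_metrics <- function(x, ...) {
  cat("Clonal set evaluation\n")
  cat("  clusters below threshold: ", x$n_clusters_below, "\n", sep = "")
  cat("  sequences in clusters:    ", x$n_seqs_below, "\n", sep = "")
  cat("  clusters differing:       ", x$n_clusters_diff, "\n", sep = "")
  cat("  incorrectly assigned:     ", x$n_incorrect_seqs, "\n", sep = "")
  cat("  correctly clustered (%):  ",
      formatC(x$pct_correct, format = "f", digits = 1), "\n", sep = "")
  invisible(x)
}
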