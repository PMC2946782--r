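# shared test helpers: random sequence generation, an independent O(n^3)
# re-averaging UPGMA reference, tree canonicalization, ARI convenience

rand_nt <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

rand_dist_matrix <- function(n, ids = sprintf("s%02d", seq_len(n))) {
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  vals <- runif(n * (n - 1) / 2)
  d[upper.tri(d)] <- vals
  d[lower.tri(d)] <- t(d)[lower.tri(d)]
  d
}

# independent average-linkage reference: at every step recompute the mean
# of the ORIGINAL pairwise distances over all cross-pairs (no incremental
# update), with the same smallest-member-pair tie-break
ref_upgma <- function(d) {
  ids <- rownames(d)
  n <- length(ids)
  if (n == 1L) return(dendro_leaf(ids[1]))
  clusters <- lapply(seq_len(n), function(i) i)
  nodes <- lapply(ids, dendro_leaf)
  repeat {
    k <- length(clusters)
    if (k == 1L) break
    best <- NULL
    for (a in seq_len(k - 1L)) {
      for (b in (a + 1L):k) {
        avg <- mean(d[clusters[[a]], clusters[[b]]])
        key <- paste(sort(c(min(ids[clusters[[a]]]),
                            min(ids[clusters[[b]]]))), collapse = "\r")
        if (is.null(best) || avg < best$avg ||
            (avg == best$avg && key < best$key))
          best <- list(a = a, b = b, avg = avg, key = key)
      }
    }
    merged_node <- dendro_merge(best$avg, nodes[[best$a]], nodes[[best$b]])
    merged_members <- c(clusters[[best$a]], clusters[[best$b]])
    keep <- setdiff(seq_len(k), c(best$a, best$b))
    clusters <- c(clusters[keep], list(merged_members))
    nodes <- c(nodes[keep], list(merged_node))
  }
  nodes[[1]]
}

# canonical form: children ordered by smallest member id, so trees from
# different implementations compare structurally
canonical_tree <- function(node) {
  if (isTRUE(node$leaf)) return(node)
  kids <- lapply(node$children, canonical_tree)
  mins <- vapply(kids, function(k) dendro_members(k)[1], character(1))
  list(leaf = FALSE, height = node$height, children = kids[order(mins)])
}

expect_tree_equal <- function(a, b, tol = 1e-12) {
  a <- canonical_tree(a); b <- canonical_tree(b)
  cmp <- function(x, y) {
    if (isTRUE(x$leaf) || isTRUE(y$leaf)) {
      expect_identical(isTRUE(x$leaf), isTRUE(y$leaf))
      expect_identical(x$id, y$id)
    } else {
      expect_lt(abs(x$height - y$height), tol)
      cmp(x$children[[1]], y$children[[1]])
      cmp(x$children[[2]], y$children[[2]])
    }
  }
  cmp(a, b)
}

# clone-recovery ARI: singletons become their own labels
recovery_ari <- function(res, truth) {
  pred <- res$assignments$set_id[match(truth$seq_id, res$assignments$seq_id)]
  pred[is.na(pred)] <- -seq_len(sum(is.na(pred)))
  mclust::adjustedRandIndex(pred, truth$clone_id)
}

run_recovery <- function(shm, seed, n_clones = 30, size_range = c(2L, 8L)) {
  pools <- synthetic_germlines(seed = seed)
  sim <- simulate_repertoire(n_clones = n_clones, size_range = size_range,
                             pools = pools, shm_rate = shm, seed = seed + 1L)
  res <- clonal_sets(sim$records, pools$vlib, pools$jlib)
  recovery_ari(res, sim$truth)
}
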