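toy_matrix <- function() {
  d <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  d["A", "B"] <- d["B", "A"] <- 0.1
  d["A", "C"] <- d["C", "A"] <- 0.4
  d["B", "C"] <- d["C", "B"] <- 0.6
  d
}

test_that("build_matrix is symmetric, zero-diagonal and matches per-pair calls", {
  recs <- data.frame(seq_id = c("r1", "r2"),
                     cdr3 = c("ACGTACGT", "ACGTACGT"),
                     v_call = "IGHV1-2*01", j_call = "IGHJ4*02",
                     stringsAsFactors = FALSE)
  d <- build_matrix(recs)
  expect_equal(unname(d), matrix(0, 2, 2))

  set.seed(41)
  pools <- synthetic_germlines(seed = 41)
  sim <- simulate_repertoire(n_clones = 5, size_range = c(2L, 2L),
                             pools = pools, shm_rate = 0.05, seed = 42)
  ex <- extract_cdr3(sim$records, pools$vlib, pools$jlib)
  d2 <- build_matrix(ex$records, metric = "ned_vj")
  expect_identical(d2, t(d2))
  expect_true(all(diag(d2) == 0))
  for (i in 1:9) {
    for (j in (i + 1):10) {
      expect_equal(d2[i, j],
                   ned_vj(as.list(ex$records[i, ]), as.list(ex$records[j, ])),
                   tolerance = 1e-12)
    }
  }
  # plain metrics agree with their scalar counterparts on a pair
  d_ld <- build_matrix(ex$records, metric = "ld")
  expect_equal(d_ld[1, 2], ld(ex$records$cdr3[1], ex$records$cdr3[2]))
  d_pn <- build_matrix(ex$records, metric = "pned")
  expect_equal(d_pn[1, 2], pned(ex$records$cdr3[1], ex$records$cdr3[2]))
})

test_that("upgma reproduces the hand-checked three-point agglomeration", {
  tree <- upgma(toy_matrix())
  expect_equal(tree$height, 0.5)            # mean(0.4, 0.6)
  kids <- canonical_tree(tree)$children
  expect_equal(dendro_members(kids[[1]]), c("A", "B"))
  expect_equal(kids[[1]]$height, 0.1)
  expect_equal(dendro_members(tree), c("A", "B", "C"))

  single <- matrix(0, 1, 1, dimnames = list("only", "only"))
  expect_equal(upgma(single), dendro_leaf("only"))
})

test_that("upgma agrees with the re-averaging reference and with hclust", {
  set.seed(51)
  for (k in 1:30) {
    n <- sample(3:15, 1)
    d <- rand_dist_matrix(n)
    tree <- upgma(d)
    expect_tree_equal(tree, ref_upgma(d), tol = 1e-12)
    # independent implementation: sorted merge heights from stats::hclust
    hc <- stats::hclust(stats::as.dist(d), method = "average")
    expect_equal(sort(merge_trajectory(tree)$height), sort(hc$height),
                 tolerance = 1e-12)
  }
})

test_that("cut_tree extracts subtrees below the threshold", {
  tree <- upgma(toy_matrix())
  cut <- cut_tree(tree, tau = 0.32)
  expect_equal(cut$sets, list(`1` = c("A", "B")))
  expect_equal(cut$singletons, "C")
  expect_equal(cut$assignments$set_size[cut$assignments$seq_id == "C"], 1L)

  expect_equal(length(cut_tree(tree, tau = 0.05)$sets), 0L)
  all_in <- cut_tree(tree, tau = 0.7)
  expect_equal(all_in$sets, list(`1` = c("A", "B", "C")))

  # boundary: strict vs inclusive comparison at the merge height
  expect_equal(length(cut_tree(tree, tau = 0.1)$sets), 0L)
  expect_equal(length(cut_tree(tree, tau = 0.1, strict = FALSE)$sets), 1L)
})

test_that("planted families at separated distances are recovered exactly", {
  ids <- c("f1a", "f1b", "f1c", "f2a", "f2b")
  d <- matrix(0.7, 5, 5, dimnames = list(ids, ids))
  diag(d) <- 0
  d[1:3, 1:3] <- 0.05; d[4:5, 4:5] <- 0.08
  diag(d) <- 0
  cut <- cut_tree(upgma(d), tau = 0.32)
  expect_equal(cut$sets, list(`1` = c("f1a", "f1b", "f1c"),
                              `2` = c("f2a", "f2b")))
})

test_that("merge trajectories are the non-decreasing agglomeration heights", {
  traj <- merge_trajectory(upgma(toy_matrix()))
  expect_equal(traj$merge_index, 1:2)
  expect_equal(traj$height, c(0.1, 0.5))
  expect_equal(nrow(merge_trajectory(dendro_leaf("x"))), 0L)

  set.seed(61)
  for (k in 1:100) {
    d <- rand_dist_matrix(sample(2:12, 1))
    expect_true(all(diff(merge_trajectory(upgma(d))$height) >= -1e-12))
  }
})

test_that("clustering output is invariant to input record order", {
  set.seed(71)
  pools <- synthetic_germlines(seed = 71)
  sim <- simulate_repertoire(n_clones = 8, size_range = c(2L, 4L),
                             pools = pools, shm_rate = 0.02, seed = 72)
  res1 <- clonal_sets(sim$records, pools$vlib, pools$jlib)
  perm <- sample(nrow(sim$records))
  res2 <- clonal_sets(sim$records[perm, ], pools$vlib, pools$jlib)
  expect_equal(res1$sets, res2$sets)
})

test_that("evaluation metrics follow the exact-set-match definition", {
  truth <- data.frame(seq_id = c("a", "b", "c", "d", "e", "f"),
                      set_id = c("1", "1", "2", "2", NA, NA),
                      stringsAsFactors = FALSE)

  perfect <- evaluate(list(c("a", "b"), c("c", "d")), truth)
  expect_equal(perfect$n_clusters_diff, 0L)
  expect_equal(perfect$n_incorrect_seqs, 0L)
  expect_equal(perfect$pct_correct, 100)

  lumped <- evaluate(list(c("a", "b", "c", "d")), truth)
  expect_equal(lumped$n_clusters_below, 1L)
  expect_equal(lumped$n_seqs_below, 4L)
  expect_equal(lumped$n_clusters_diff, 1L)
  expect_equal(lumped$n_incorrect_seqs, 4L)
  expect_equal(lumped$pct_correct, 0)

  # two true sets plus a spurious pairing of benchmark singletons
  spurious <- evaluate(list(c("a", "b"), c("c", "d"), c("e", "f")), truth)
  expect_equal(spurious$n_clusters_diff, 1L)
  expect_equal(spurious$n_incorrect_seqs, 2L)
  expect_equal(spurious$pct_correct, 100 * 4 / 6, tolerance = 1e-12)

  expect_error(evaluate(list(c("a", "zz")), truth), "zz")
})
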