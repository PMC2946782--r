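test_that("simulation is deterministic given a seed", {
  pools <- synthetic_germlines(seed = 81)
  s1 <- simulate_repertoire(n_clones = 6, pools = pools, shm_rate = 0.05,
                            seed = 82)
  s2 <- simulate_repertoire(n_clones = 6, pools = pools, shm_rate = 0.05,
                            seed = 82)
  expect_identical(s1$records, s2$records)
  expect_identical(s1$truth, s2$truth)
})

test_that("somatic hypermutation substitutes at the requested rate", {
  set.seed(91)
  s <- rand_nt(200)
  expect_identical(apply_shm(s, 0), s)
  mutated <- apply_shm(strrep("A", 50), 1)
  expect_false(grepl("A", mutated))
  expect_equal(nchar(mutated), 50L)

  # empirical rate over 1e5 positions concentrates around 0.05
  long <- strrep("ACGT", 25000)
  hits <- sum(strsplit(apply_shm(long, 0.05), "")[[1]] !=
                strsplit(long, "")[[1]])
  expect_lt(abs(hits / 1e5 - 0.05), 0.005)
})

test_that("noiseless clones have identical junctions and zero intra-clone distance", {
  pools <- synthetic_germlines(seed = 92)
  sim <- simulate_repertoire(n_clones = 4, clone_sizes = 3, pools = pools,
                             shm_rate = 0, seed = 93)
  expect_equal(nrow(sim$records), 12L)
  ex <- extract_cdr3(sim$records, pools$vlib, pools$jlib)
  by_clone <- split(ex$records$cdr3, sim$truth$clone_id)
  for (cd in by_clone) expect_equal(length(unique(cd)), 1L)

  a <- as.list(ex$records[1, ]); b <- as.list(ex$records[2, ])
  expect_equal(ned_vj(a, b), 0)

  # across clones with different V genes the germline penalty keeps the
  # distance strictly positive even for identical junction content
  other <- which(sim$truth$clone_id != 1)[1]
  cc <- as.list(ex$records[other, ])
  if (parse_call(a$v_call, "V")$gene != parse_call(cc$v_call, "V")$gene)
    expect_gt(ned_vj(a, cc), 0)
})

test_that("chimera injection swaps the V gene but preserves the junction", {
  pools <- synthetic_germlines(seed = 94)
  sim <- simulate_repertoire(n_clones = 6, clone_sizes = 4, pools = pools,
                             shm_rate = 0, seed = 95)
  sim0 <- inject_chimeras(sim, rate = 0)
  expect_identical(sim0$records, sim$records)

  set.seed(96)
  simc <- inject_chimeras(sim, rate = 0.5)
  expect_identical(simc$truth$seq_id, simc$records$seq_id)
  expect_true(any(simc$truth$is_chimera))

  ex0 <- extract_cdr3(sim$records, pools$vlib, pools$jlib)
  exc <- extract_cdr3(simc$records, pools$vlib, pools$jlib)
  chim <- simc$truth$is_chimera
  # junction untouched, V call changed to a different gene
  expect_identical(exc$records$cdr3, ex0$records$cdr3)
  changed <- simc$records$v_call != sim$records$v_call
  expect_identical(changed, chim)

  # a chimera's distance to a former clone-mate is exactly S_V / |CDR3|
  i <- which(chim)[1]
  mates <- which(simc$truth$clone_id == simc$truth$clone_id[i] & !chim)
  if (length(mates) > 0) {
    j <- mates[1]
    sv <- v_penalty(simc$records$v_call[i], simc$records$v_call[j])
    a <- as.list(exc$records[i, ]); b <- as.list(exc$records[j, ])
    expect_gt(sv, 0)
    expect_equal(ned_vj(a, b), sv / nchar(a$cdr3))
    # the germline-aware distance separates the chimera; plain NED cannot
    expect_equal(ned(a$cdr3, b$cdr3), 0)
  }
})

test_that("clone size specification is validated and honoured", {
  pools <- synthetic_germlines(seed = 97)
  sim <- simulate_repertoire(n_clones = 3, clone_sizes = c(2, 5, 7),
                             pools = pools, seed = 98)
  expect_equal(as.vector(table(sim$truth$clone_id)), c(2L, 5L, 7L))
  expect_error(simulate_repertoire(n_clones = 2, clone_sizes = c(2, 2, 2),
                                   pools = pools, seed = 99),
               "more clone sizes")
  expect_error(simulate_repertoire(n_clones = 2, clone_sizes = 0,
                                   pools = pools, seed = 99), ">= 1")
})
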