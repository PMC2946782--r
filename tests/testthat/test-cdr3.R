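make_gapped_v <- function(name, tail_len, pre_nt = 230L) {
  # IMGT-gapped framework of 312 positions, then `tail_len` CDR3 nucleotides
  chars <- rep(".", 312L)
  chars[sort(sample(312L, pre_nt))] <- sample(c("A", "C", "G", "T"),
                                              pre_nt, replace = TRUE)
  data.frame(name = name,
             gapped_seq = paste0(paste(chars, collapse = ""),
                                 rand_nt(tail_len)),
             stringsAsFactors = FALSE)
}

test_that("the CDR3 starting length library counts nucleotides from IMGT codon 105", {
  set.seed(11)
  germ <- rbind(make_gapped_v("IGHV1-1*01", 8L),
                make_gapped_v("IGHV1-2*01", 11L))
  germ$ungapped_seq <- gsub(".", "", germ$gapped_seq, fixed = TRUE)
  lib <- build_v_start_library(germ)
  expect_identical(lib, c("IGHV1-1*01" = 8L, "IGHV1-2*01" = 11L))

  # truncated before position 313: zero with a warning
  short <- data.frame(name = "IGHV9-9*01",
                      gapped_seq = substr(germ$gapped_seq[1], 1, 310),
                      stringsAsFactors = FALSE)
  short$ungapped_seq <- gsub(".", "", short$gapped_seq, fixed = TRUE)
  expect_warning(lib2 <- build_v_start_library(short), "codon 105")
  expect_identical(unname(lib2), 0L)

  # all-gap tail after position 312 contributes nothing
  gappy <- data.frame(name = "IGHV8-8*01",
                      gapped_seq = paste0(substr(germ$gapped_seq[1], 1, 312),
                                          "......."),
                      stringsAsFactors = FALSE)
  gappy$ungapped_seq <- gsub(".", "", gappy$gapped_seq, fixed = TRUE)
  expect_identical(unname(build_v_start_library(gappy)), 0L)

  expect_error(build_v_start_library(germ[0, ]), "empty")
})

test_that("the CDR3 ending length library locates the first J-TRP codon", {
  germ <- data.frame(name = c("IGHJ1*01", "IGHJ2*01", "IGHJ3*01"),
                     ungapped_seq = c("ATTACTGGTTCGAC", "TGGAAA", "AAACCC"),
                     stringsAsFactors = FALSE)
  germ$gapped_seq <- germ$ungapped_seq
  expect_warning(lib <- build_j_end_library(germ), "IGHJ3")
  expect_identical(lib, c("IGHJ1*01" = 5L, "IGHJ2*01" = 0L))

  # overlapping TGGs and an in-frame hint
  frame <- data.frame(name = "IGHJ4*01", ungapped_seq = "AATGGATGGCC",
                      gapped_seq = "AATGGATGGCC", stringsAsFactors = FALSE)
  expect_identical(unname(build_j_end_library(frame)), 2L)
  expect_identical(
    unname(build_j_end_library(frame, frame_hint = c("IGHJ4*01" = 0L))), 6L)
})

test_that("library builders recover the lengths planted in synthetic germlines", {
  pools <- synthetic_germlines(v_tail_lens = c(7L, 9L, 12L, 8L),
                               j_head_lens = c(5L, 9L, 14L), seed = 21)
  expect_identical(build_v_start_library(pools$v), pools$vlib)
  expect_identical(build_j_end_library(pools$j), pools$jlib)
})

test_that("library TSVs round-trip and rebuild byte-identically", {
  pools <- synthetic_germlines(seed = 22)
  lib <- build_v_start_library(pools$v)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_library_tsv(lib, f1)
  expect_identical(read_library_tsv(f1), lib)
  write_library_tsv(build_v_start_library(pools$v), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("CDR3 extraction concatenates V tail, N1, D, N2 and J head", {
  vlib <- c("IGHV1-2*01" = 9L)
  jlib <- c("IGHJ4*02" = 5L)
  rec <- data.frame(seq_id = "s1", v_call = "IGHV1-2*01",
                    d_call = "IGHD3-10*01", j_call = "IGHJ4*02",
                    seg_v = "AAAAATGTGCGAGA", seg_n1 = "CC", seg_d = "GGTAT",
                    seg_n2 = "A", seg_j = "ACTACTTTGAC",
                    stringsAsFactors = FALSE)
  out <- extract_cdr3(rec, vlib, jlib)
  expect_equal(out$records$cdr3, "TGTGCGAGACCGGTATAACTAC")
  expect_false(out$records$truncated)

  # aligner-reported V shorter than the library length: clamped
  rec$seg_v <- "GAGA"
  out2 <- suppressMessages(extract_cdr3(rec, vlib, jlib))
  expect_equal(out2$records$cdr3, "GAGACCGGTATAACTAC")
  expect_true(out2$records$truncated)

  # empty N1/D/N2: CDR3 is V tail + J head
  rec$seg_v <- "AAAAATGTGCGAGA"
  rec$seg_n1 <- ""; rec$seg_d <- ""; rec$seg_n2 <- ""
  out3 <- extract_cdr3(rec, vlib, jlib)
  expect_equal(out3$records$cdr3, "TGTGCGAGAACTAC")

  # allele absent from library: gene-level fallback
  rec$v_call <- "IGHV1-2*05"
  out4 <- extract_cdr3(rec, vlib, jlib)
  expect_equal(out4$records$cdr3, "TGTGCGAGAACTAC")

  # unknown germline: excluded with a reason, not an error
  rec$v_call <- "IGHV7-77*01"
  out5 <- extract_cdr3(rec, vlib, jlib)
  expect_equal(nrow(out5$records), 0L)
  expect_match(out5$excluded$reason, "starting length library")
})

test_that("extracted CDR3 length equals the sum of clamped segment contributions", {
  pools <- synthetic_germlines(seed = 23)
  sim <- simulate_repertoire(n_clones = 40, size_range = c(2L, 8L),
                             pools = pools, shm_rate = 0.03, seed = 24)
  recs <- sim$records
  # push past 1000 records by replicating with fresh ids
  while (nrow(recs) < 1000) {
    extra <- sim$records
    extra$seq_id <- paste0(extra$seq_id, "_r", nrow(recs))
    recs <- rbind(recs, extra)
  }
  out <- extract_cdr3(recs, pools$vlib, pools$jlib)
  expect_equal(nrow(out$records), nrow(recs))
  m <- match(out$records$seq_id, recs$seq_id)
  expected_len <-
    pmin(pools$vlib[recs$v_call[m]], nchar(recs$seg_v[m])) +
    nchar(recs$seg_n1[m]) + nchar(recs$seg_d[m]) + nchar(recs$seg_n2[m]) +
    pmin(pools$jlib[recs$j_call[m]], nchar(recs$seg_j[m]))
  expect_equal(nchar(out$records$cdr3), unname(expected_len))
})
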