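#' Synthetic germline gene pools
#'
#' Builds small artificial IGHV, IGHD and IGHJ germline repertoires for
#' simulation and testing. V genes are emitted as IMGT-gapped sequences
#' with a planted CDR3 starting length (the number of nucleotides at or
#' after the first nucleotide of codon 105, gapped position 313), spread
#' over several subgroups, genes and alleles so that every germline
#' penalty tier can fire. J genes carry a planted J-TRP (`TGG`) offset.
#' The planted lengths are returned alongside, so library builders can be
#' checked against them.
#'
#' By default every V gene gets the same CDR3 starting length (9 nt, the
#' typical germline contribution beyond the conserved 2nd-CYS codon);
#' pass a vector to `v_tail_lens` to vary it per gene.
#'
#' @param n_v,n_d,n_j pool sizes.
#' @param v_tail_lens planted CDR3 starting length(s), recycled over V
#'   genes.
#' @param j_head_lens planted J-TRP offset(s), recycled over J genes.
#' @param d_len_range length range for D genes.
#' @param seed optional RNG seed.
#' @return list with data frames `v`, `d`, `j` (columns as in
#'   [read_germline_fasta()]) and the planted libraries `vlib`, `jlib`
#'   (named integer vectors).
#' @export
synthetic_germlines <- function(n_v = 25, n_d = 25, n_j = 6,
                                v_tail_lens = 9L,
                                j_head_lens = c(5L, 8L, 11L, 14L),
                                d_len_range = c(10L, 20L),
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bases <- c("A", "C", "G", "T")
  rand_nt <- function(n) paste(sample(bases, n, replace = TRUE), collapse = "")

  # V: subgroup / gene / allele layout chosen so all penalty tiers occur
  # (two alleles of one gene, two genes in one subgroup, three subgroups)
  layout <- list(c(1, 1, 1), c(1, 1, 2), c(1, 2, 1), c(2, 1, 1),
                 c(2, 1, 2), c(2, 2, 1), c(3, 1, 1), c(3, 2, 1))
  if (n_v > length(layout))
    layout <- c(layout, lapply(seq_len(n_v - length(layout)), function(i)
      c((i - 1) %% 3 + 1, 2 + i, 1)))
  layout <- layout[seq_len(n_v)]
  v_names <- vapply(layout, function(l)
    sprintf("IGHV%d-%d*%02d", l[1], l[2], l[3]), character(1))
  v_tails <- rep_len(as.integer(v_tail_lens), n_v)
  v_gapped <- character(n_v)
  pre_len <- 312L
  for (i in seq_len(n_v)) {
    # framework+CDR1/2 region: ~230 nt with IMGT '.' gap blocks up to pos 312
    n_nt <- 230L
    chars <- rep(".", pre_len)
    pos <- sort(sample(pre_len, n_nt))
    chars[pos] <- sample(bases, n_nt, replace = TRUE)
    v_gapped[i] <- paste0(paste(chars, collapse = ""), rand_nt(v_tails[i]))
  }
  v <- data.frame(name = v_names, gapped_seq = v_gapped,
                  ungapped_seq = gsub(".", "", v_gapped, fixed = TRUE),
                  stringsAsFactors = FALSE)

  # D: short random genes
  d_names <- sprintf("IGHD%d-%d*01", rep(1:3, length.out = n_d),
                     seq_len(n_d))
  d_seqs <- vapply(seq_len(n_d), function(i)
    rand_nt(sample_from(d_len_range[1]:d_len_range[2])), character(1))
  d <- data.frame(name = d_names, gapped_seq = d_seqs,
                  ungapped_seq = d_seqs, stringsAsFactors = FALSE)

  # J: planted first-TGG offset; head avoids G so no earlier TGG can form
  j_heads <- rep_len(as.integer(j_head_lens), n_j)
  j_genes <- seq_len(n_j)
  j_alleles <- rep(1L, n_j)
  j_names <- sprintf("IGHJ%d*%02d", j_genes, j_alleles)
  j_seqs <- vapply(seq_len(n_j), function(i) {
    head <- paste(sample(c("A", "C", "T"), j_heads[i], replace = TRUE),
                  collapse = "")
    tail <- paste(sample(c("A", "C", "T"), 15, replace = TRUE), collapse = "")
    paste0(head, "TGG", tail)
  }, character(1))
  j <- data.frame(name = j_names, gapped_seq = j_seqs,
                  ungapped_seq = j_seqs, stringsAsFactors = FALSE)

  list(v = v, d = d, j = j,
       vlib = stats::setNames(v_tails, v_names),
       jlib = stats::setNames(j_heads, j_names))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# sample() treats a length-1 vector as 1:n; this draws uniformly from the
# values of `v` regardless of its length
sample_from <- function(v, n = 1L) v[sample.int(length(v), n, replace = TRUE)]

#' Somatic hypermutation as i.i.d. point substitutions
#'
#' Substitutes each position independently with probability `rate` to a
#' uniformly chosen different base (an `N` becomes a random base). Length
#' is preserved; no indels and no hotspot targeting.
#'
#' @param seq nucleotide string.
#' @param rate per-site substitution probability in `[0, 1)` (or exactly 1
#'   to force substitution everywhere).
#' @return mutated string.
#' @export
apply_shm <- function(seq, rate) {
  stopifnot(rate >= 0, rate <= 1)
  n <- nchar(seq)
  if (n == 0L || rate == 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  hit <- stats::runif(n) < rate
  if (any(hit)) {
    bases <- c("A", "C", "G", "T")
    chars[hit] <- vapply(chars[hit], function(b) {
      sample(setdiff(bases, b), 1L)
    }, character(1), USE.NAMES = FALSE)
  }
  paste(chars, collapse = "")
}

#' Simulate a labelled clonal repertoire
#'
#' Emulates the biology the clustering method targets: each clone is one
#' V-D-J rearrangement (germline V, D and J drawn from the pools, with
#' random non-templated N1/N2 additions at the joints), and each member
#' sequence is an independent somatic-hypermutation variant of that
#' rearrangement. Output is in the partitioned-sequence form of
#' [parse_partitioned_file()], with the true germline calls, plus a truth
#' table of clone labels — so the whole pipeline can be validated against
#' a known clonal partition.
#'
#' @param n_clones number of clones.
#' @param clone_sizes explicit member counts (recycled to `n_clones`), or
#'   `NULL` to sample.
#' @param size_range when sampling, sizes are uniform over this range.
#' @param pools germline pools from [synthetic_germlines()].
#' @param n_len_range length range for the N1 and N2 regions.
#' @param shm_rate per-site substitution probability applied independently
#'   to every member sequence.
#' @param chimera_rate probability that a member is converted into a
#'   chimera (see [inject_chimeras()]).
#' @param unique_junctions if `TRUE` (default), clone rearrangements are
#'   redrawn until every pair of naive CDR3s is at least
#'   `min_junction_dist` apart under plain NED, so the planted partition
#'   is identifiable and truth recovery is well-posed.
#' @param min_junction_dist minimum naive-junction NED between clones
#'   when `unique_junctions` is `TRUE`; defaults to the clonal threshold
#'   0.32 (set to 0 to require only non-identical junctions).
#' @param seed optional RNG seed; the output is deterministic given the
#'   seed.
#' @return list with `records` (partitioned-sequence data frame), `truth`
#'   (data frame `seq_id`, `clone_id`, `is_chimera`) and `pools`.
#' @export
simulate_repertoire <- function(n_clones = 30, clone_sizes = NULL,
                                size_range = c(2L, 8L),
                                pools = synthetic_germlines(),
                                n_len_range = c(2L, 8L),
                                shm_rate = 0, chimera_rate = 0,
                                unique_junctions = TRUE,
                                min_junction_dist = 0.32, seed = NULL) {
  stopifnot(n_clones >= 1, shm_rate >= 0, shm_rate < 1,
            chimera_rate >= 0, chimera_rate < 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(clone_sizes)) {
    clone_sizes <- sample_from(size_range[1]:size_range[2], n_clones)
  } else {
    if (length(clone_sizes) > n_clones)
      stop("more clone sizes than clones")
    clone_sizes <- rep_len(as.integer(clone_sizes), n_clones)
  }
  if (any(clone_sizes < 1)) stop("clone sizes must be >= 1")
  bases <- c("A", "C", "G", "T")
  rand_nt <- function(n) if (n == 0L) "" else
    paste(sample(bases, n, replace = TRUE), collapse = "")

  naive_cdr3 <- function(re) {
    vt <- pools$vlib[[re$v_call]]
    jh <- pools$jlib[[re$j_call]]
    nv <- nchar(re$seg_v)
    paste0(substr(re$seg_v, nv - min(vt, nv) + 1L, nv),
           re$n1, re$d_seq, re$n2, substr(re$seg_j, 1L, jh))
  }
  draw_rearrangement <- function() {
    vi <- sample(nrow(pools$v), 1L)
    di <- sample(nrow(pools$d), 1L)
    ji <- sample(nrow(pools$j), 1L)
    list(v_call = pools$v$name[vi], d_call = pools$d$name[di],
         j_call = pools$j$name[ji],
         seg_v = pools$v$ungapped_seq[vi],
         d_seq = pools$d$ungapped_seq[di],
         seg_j = pools$j$ungapped_seq[ji],
         n1 = rand_nt(sample_from(n_len_range[1]:n_len_range[2])),
         n2 = rand_nt(sample_from(n_len_range[1]:n_len_range[2])))
  }

  separated <- function(cd) {
    if (cd %in% seen_cdr3) return(FALSE)
    if (min_junction_dist <= 0) return(TRUE)
    all(vapply(seen_cdr3, function(s) ned(cd, s) >= min_junction_dist,
               logical(1)))
  }
  rearr <- vector("list", n_clones)
  seen_cdr3 <- character(0)
  for (cl in seq_len(n_clones)) {
    for (attempt in 1:1000) {
      re <- draw_rearrangement()
      cd <- naive_cdr3(re)
      if (!unique_junctions || separated(cd)) break
      if (attempt == 1000)
        stop("could not draw separated clone junctions; enlarge the pools")
    }
    seen_cdr3 <- c(seen_cdr3, cd)
    rearr[[cl]] <- re
  }

  rows <- list()
  labels <- list()
  for (cl in seq_len(n_clones)) {
    re <- rearr[[cl]]
    for (k in seq_len(clone_sizes[cl])) {
      id <- sprintf("c%03d_s%02d", cl, k)
      rows[[length(rows) + 1L]] <- data.frame(
        seq_id = id, v_call = re$v_call, d_call = re$d_call,
        j_call = re$j_call,
        seg_v = apply_shm(re$seg_v, shm_rate),
        seg_n1 = apply_shm(re$n1, shm_rate),
        seg_d = apply_shm(re$d_seq, shm_rate),
        seg_n2 = apply_shm(re$n2, shm_rate),
        seg_j = apply_shm(re$seg_j, shm_rate),
        stringsAsFactors = FALSE)
      labels[[length(labels) + 1L]] <- data.frame(
        seq_id = id, clone_id = cl, is_chimera = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  records <- do.call(rbind, rows)
  truth <- do.call(rbind, labels)
  out <- list(records = records, truth = truth, pools = pools)
  if (chimera_rate > 0)
    out <- inject_chimeras(out, rate = chimera_rate)
  out
}

#' Inject chimeric sequences into a simulated repertoire
#'
#' Chimeric artifacts arise from in-vitro recombination of two template
#' molecules: the junction (CDR3) of one sequence fused to the V region of
#' another, so the CDR3 is unchanged but the V gene call differs. Each
#' sequence is converted with probability `rate`: it receives the V call
#' and V segment body of a germline gene from a different V gene, while
#' its CDR3-proximal V tail and everything downstream are kept. Requires
#' the default pools (common planted CDR3 starting length), so the CDR3
#' is preserved exactly.
#'
#' @param sim result of [simulate_repertoire()].
#' @param rate per-sequence conversion probability.
#' @return `sim` with modified `records` and `is_chimera` flags set.
#' @export
inject_chimeras <- function(sim, rate) {
  stopifnot(rate >= 0, rate < 1)
  if (rate == 0) return(sim)
  pools <- sim$pools
  if (length(unique(pools$vlib)) != 1L)
    stop("chimera injection requires a common planted CDR3 starting length")
  vt <- pools$vlib[[1]]
  records <- sim$records
  truth <- sim$truth
  for (i in seq_len(nrow(records))) {
    if (stats::runif(1) >= rate) next
    cur_gene <- parse_call(records$v_call[i], "V")$gene
    donor_ok <- vapply(pools$v$name,
                       function(n) parse_call(n, "V")$gene != cur_gene,
                       logical(1))
    if (!any(donor_ok)) next
    di <- sample(which(donor_ok), 1L)
    donor_seq <- pools$v$ungapped_seq[di]
    nv <- nchar(records$seg_v[i])
    old_tail <- substr(records$seg_v[i], nv - min(vt, nv) + 1L, nv)
    donor_body <- substr(donor_seq, 1L, nchar(donor_seq) - vt)
    records$seg_v[i] <- paste0(donor_body, old_tail)
    records$v_call[i] <- pools$v$name[di]
    truth$is_chimera[i] <- TRUE
  }
  sim$records <- records
  sim$truth <- truth
  sim
}
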