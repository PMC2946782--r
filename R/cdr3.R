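# IMGT unique numbering: codon c occupies gapped nucleotide positions
# 3*(c-1)+1 .. 3*(c-1)+3 (1-based). The CDR3 spans codons 105-117; the
# first nucleotide of codon 105 is gapped position 313. The J-TRP 118
# tryptophan codon (the first TGG of the J gene) marks the end of CDR3 and
# is itself excluded.
CDR3_START_GAPPED_POS <- 313L

#' Build the CDR3 starting length library from IMGT-gapped IGHV germlines
#'
#' For each IGHV germline gene, counts the nucleotides between the CDR3
#' start (first nucleotide of IMGT codon 105, gapped position 313) and the
#' 3' end of the gene. This "V tail length" is the number of germline-encoded
#' nucleotides each rearranged V segment contributes to the CDR3. Genes whose
#' gapped sequence ends before position 313 get length 0 with a warning.
#'
#' @param germlines data frame from [read_germline_fasta()] with
#'   IMGT-gapped sequences (`gapped_seq` uses `'.'` for gaps).
#' @return named integer vector (a CDR3 starting length library).
#' @export
build_v_start_library <- function(germlines) {
  if (nrow(germlines) == 0L) stop("empty IGHV germline repertoire")
  lens <- vapply(seq_len(nrow(germlines)), function(i) {
    g <- germlines$gapped_seq[i]
    if (nchar(g) < CDR3_START_GAPPED_POS) {
      warning("germline ", germlines$name[i],
              " ends before IMGT codon 105; CDR3 starting length set to 0")
      return(0L)
    }
    tail_part <- substr(g, CDR3_START_GAPPED_POS, nchar(g))
    nchar(gsub(".", "", tail_part, fixed = TRUE))
  }, integer(1))
  stats::setNames(lens, germlines$name)
}

#' Build the CDR3 ending length library from IGHJ germlines
#'
#' For each IGHJ germline gene, locates the J-TRP codon (the first `TGG`)
#' and records its 0-based offset: the number of J 5' nucleotides included
#' in the CDR3 (the TGG itself is excluded). With a `frame_hint`, only
#' offsets in that reading frame are considered; otherwise the first
#' occurrence at any offset is used. Genes with no `TGG` are excluded from
#' the library with a warning.
#'
#' @param germlines data frame from [read_germline_fasta()] (ungapped
#'   sequences are used).
#' @param frame_hint optional named integer vector of per-gene reading
#'   frames (0, 1 or 2).
#' @return named integer vector (a CDR3 ending length library).
#' @export
build_j_end_library <- function(germlines, frame_hint = NULL) {
  if (nrow(germlines) == 0L) stop("empty IGHJ germline repertoire")
  out <- integer(0)
  for (i in seq_len(nrow(germlines))) {
    s <- germlines$ungapped_seq[i]
    nm <- germlines$name[i]
    starts <- gregexpr("(?=TGG)", s, perl = TRUE)[[1]]
    starts <- starts[starts > 0] - 1L          # 0-based offsets
    if (!is.null(frame_hint) && nm %in% names(frame_hint))
      starts <- starts[starts %% 3L == frame_hint[[nm]] %% 3L]
    if (length(starts) == 0L) {
      warning("no TGG (J-TRP) codon in germline ", nm,
              "; excluded from the CDR3 ending length library")
      next
    }
    out[nm] <- min(starts)
  }
  out
}

lookup_length <- function(lib, call, locus) {
  if (call %in% names(lib)) return(lib[[call]])
  gene <- parse_call(call, locus)$gene
  if (gene %in% names(lib)) return(lib[[gene]])
  lib_genes <- vapply(names(lib),
                      function(n) parse_call(n, locus)$gene, character(1))
  hit <- which(lib_genes == gene)
  if (length(hit) > 0L) return(lib[[hit[1]]])
  NA_integer_
}

#' Extract CDR3 nucleotide sequences from partitioned records
#'
#' Builds each sequence's CDR3 by concatenating the 3' tail of the V
#' segment (its length looked up in the CDR3 starting length library), the
#' N1, D and N2 segments in full, and the 5' head of the J segment (length
#' from the CDR3 ending length library). Library lookup is by full allele
#' label with a gene-level fallback. When an aligner-reported segment is
#' shorter than the library length the contribution is clamped to the
#' segment (flagged in the `truncated` column). Records whose V or J call
#' is absent from the libraries, or whose CDR3 comes out empty, are
#' excluded with a reason; clustering proceeds without them.
#'
#' @param records partitioned-sequence data frame
#'   ([parse_partitioned_file()] `$records`).
#' @param vlib,jlib CDR3 starting/ending length libraries (named integer
#'   vectors).
#' @return list with `records` (data frame: `seq_id`, `cdr3`, `v_call`,
#'   `j_call`, `truncated`) and `excluded` (data frame: `seq_id`,
#'   `reason`).
#' @export
extract_cdr3 <- function(records, vlib, jlib) {
  n <- nrow(records)
  out <- vector("list", n)
  excl <- list()
  for (i in seq_len(n)) {
    r <- records[i, ]
    vlen <- lookup_length(vlib, r$v_call, "V")
    if (is.na(vlen)) {
      excl[[length(excl) + 1L]] <- data.frame(
        seq_id = r$seq_id,
        reason = paste0("v_call '", r$v_call, "' not in CDR3 starting length library"))
      next
    }
    jlen <- lookup_length(jlib, r$j_call, "J")
    if (is.na(jlen)) {
      excl[[length(excl) + 1L]] <- data.frame(
        seq_id = r$seq_id,
        reason = paste0("j_call '", r$j_call, "' not in CDR3 ending length library"))
      next
    }
    nv <- nchar(r$seg_v); nj <- nchar(r$seg_j)
    v_take <- min(vlen, nv)
    j_take <- min(jlen, nj)
    cdr3 <- paste0(substr(r$seg_v, nv - v_take + 1L, nv),
                   r$seg_n1, r$seg_d, r$seg_n2,
                   substr(r$seg_j, 1L, j_take))
    if (!nzchar(cdr3)) {
      excl[[length(excl) + 1L]] <- data.frame(
        seq_id = r$seq_id, reason = "empty CDR3")
      next
    }
    out[[i]] <- data.frame(seq_id = r$seq_id, cdr3 = cdr3,
                           v_call = r$v_call, j_call = r$j_call,
                           truncated = (v_take < vlen) || (j_take < jlen),
                           stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  records_out <- if (length(out) == 0L)
    data.frame(seq_id = character(0), cdr3 = character(0),
               v_call = character(0), j_call = character(0),
               truncated = logical(0), stringsAsFactors = FALSE)
  else do.call(rbind, out)
  rownames(records_out) <- NULL
  excluded <- if (length(excl) == 0L)
    data.frame(seq_id = character(0), reason = character(0),
               stringsAsFactors = FALSE)
  else do.call(rbind, excl)
  if (any(records_out$truncated))
    message(sum(records_out$truncated),
            " record(s) had segments shorter than the library length; ",
            "CDR3 contribution clamped to the segment")
  list(records = records_out, excluded = excluded)
}
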