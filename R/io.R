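#' Default field order of the partitioned-sequence dialect
#'
#' Aligner output is a semicolon-separated text file, one sequence per
#' line. The column layout differs between partitioners, so the parser
#' takes a configurable field-order vector; this is the default layout.
#'
#' @export
default_dialect <- c("seq_id", "v_call", "d_call", "j_call",
                     "seg_v", "seg_n1", "seg_d", "seg_n2", "seg_j")

#' Read a partitioned IGH sequence file
#'
#' Parses the semicolon-separated dialect emitted by IGH partitioning
#' aligners: per record a sequence id, the IGHV/IGHD/IGHJ germline calls
#' and the V, N1, D, N2, J nucleotide segments. Segments are upper-cased on
#' ingest. Records violating the record invariants (empty id, empty V or J
#' segment, characters outside `A,C,G,T,N`) are routed to a rejects table
#' with a reason, never silently dropped; structural problems (too few
#' fields, duplicated ids) abort with an informative error.
#'
#' @param file path to the file, a connection, or a character vector of
#'   lines (via `text`).
#' @param dialect character vector naming, in file order, the fields
#'   `seq_id`, `v_call`, `d_call`, `j_call`, `seg_v`, `seg_n1`, `seg_d`,
#'   `seg_n2`, `seg_j`. Extra trailing fields in the file are ignored.
#' @param text optional character vector of lines, used instead of `file`.
#' @return a list with `records` (data frame, one row per accepted
#'   sequence) and `rejects` (data frame with `line`, `seq_id`, `reason`).
#' @examples
#' parse_partitioned_file(text =
#'   "s1;IGHV1-2*01;IGHD3-10*01;IGHJ4*02;TGTGCGAGA;CC;GGTAT;A;ACTACTGG")
#' @export
parse_partitioned_file <- function(file = NULL, dialect = default_dialect,
                                   text = NULL) {
  required <- c("seq_id", "v_call", "d_call", "j_call",
                "seg_v", "seg_n1", "seg_d", "seg_n2", "seg_j")
  if (!all(required %in% dialect))
    stop("dialect must name all of: ", paste(required, collapse = ", "))
  lines <- if (!is.null(text)) text else readLines(file, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)

  empty_records <- function() {
    as.data.frame(setNames(rep(list(character(0)), length(required)),
                           required), stringsAsFactors = FALSE)
  }
  rejects <- data.frame(line = integer(0), seq_id = character(0),
                        reason = character(0), stringsAsFactors = FALSE)
  if (length(idx) == 0L)
    return(list(records = empty_records(), rejects = rejects))

  rows <- vector("list", length(idx))
  rej <- list()
  for (k in seq_along(idx)) {
    lineno <- idx[k]
    fields <- strsplit(lines[lineno], ";", fixed = TRUE)[[1]]
    if (length(fields) < length(dialect))
      stop("line ", lineno, ": expected at least ", length(dialect),
           " semicolon-separated fields, found ", length(fields))
    rec <- as.list(trimws(fields[seq_along(dialect)]))
    names(rec) <- dialect
    rec <- rec[required]
    for (s in c("seg_v", "seg_n1", "seg_d", "seg_n2", "seg_j"))
      rec[[s]] <- toupper(rec[[s]])

    reason <- NULL
    if (!nzchar(rec$seq_id)) reason <- "empty seq_id"
    else if (!nzchar(rec$seg_v)) reason <- "empty V segment"
    else if (!nzchar(rec$seg_j)) reason <- "empty J segment"
    else {
      segs <- unlist(rec[c("seg_v", "seg_n1", "seg_d", "seg_n2", "seg_j")])
      bad <- !grepl("^[ACGTN]*$", segs)
      if (any(bad))
        reason <- paste0("non-ACGTN characters in ",
                         sub("seg_", "", names(segs)[bad][1]), " segment")
    }
    if (is.null(reason)) {
      rows[[k]] <- rec
    } else {
      rej[[length(rej) + 1L]] <- data.frame(
        line = lineno, seq_id = rec$seq_id, reason = reason,
        stringsAsFactors = FALSE)
    }
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  records <- if (length(rows) == 0L) empty_records() else
    do.call(rbind, lapply(rows, as.data.frame, stringsAsFactors = FALSE))
  if (length(rej) > 0L) rejects <- do.call(rbind, rej)
  dup <- records$seq_id[duplicated(records$seq_id)]
  if (length(dup) > 0L)
    stop("duplicated seq_id: ", paste(unique(dup), collapse = ", "))
  rownames(records) <- NULL
  list(records = records, rejects = rejects)
}

#' Write the rejects report of a parse
#'
#' @param rejects the `rejects` data frame from [parse_partitioned_file()].
#' @param file output path.
#' @export
write_rejects_tsv <- function(rejects, file) {
  utils::write.table(rejects, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Read a germline repertoire FASTA
#'
#' Reads plain or IMGT-gapped FASTA (gaps as `'.'`). The entry name is the
#' header token up to the first whitespace; IMGT-style headers of the form
#' `"X|IGHV1-2*01|Homo sapiens|..."` use the second `'|'`-separated field
#' (controlled by `imgt_header`; the default auto-detects a `'|'`).
#'
#' @param file FASTA path.
#' @param gapped logical; if `TRUE`, `'.'` gap characters are permitted
#'   and retained in `gapped_seq`.
#' @param imgt_header `TRUE`, `FALSE` or `NA` (auto-detect).
#' @return data frame with `name`, `gapped_seq`, `ungapped_seq`; order as
#'   in the file.
#' @export
read_germline_fasta <- function(file, gapped = FALSE, imgt_header = NA) {
  set <- Biostrings::readBStringSet(file)
  if (length(set) == 0L) stop("empty FASTA: ", file)
  headers <- names(set)
  name_of <- function(h) {
    use_imgt <- if (is.na(imgt_header)) grepl("|", h, fixed = TRUE) else imgt_header
    if (use_imgt) {
      parts <- strsplit(h, "|", fixed = TRUE)[[1]]
      if (length(parts) < 2L)
        stop("IMGT-style header expected to contain '|': ", h)
      trimws(parts[2])
    } else {
      strsplit(trimws(h), "\\s+")[[1]][1]
    }
  }
  nm <- vapply(headers, name_of, character(1), USE.NAMES = FALSE)
  dup <- nm[duplicated(nm)]
  if (length(dup) > 0L)
    stop("duplicate germline names: ", paste(unique(dup), collapse = ", "))
  seqs <- toupper(as.character(set))
  allowed <- if (gapped) "^[ACGTN.]*$" else "^[ACGTN]*$"
  bad <- !grepl(allowed, seqs)
  if (any(bad))
    stop("non-nucleotide characters in germline sequence(s): ",
         paste(nm[bad], collapse = ", "))
  data.frame(name = nm, gapped_seq = seqs,
             ungapped_seq = gsub(".", "", seqs, fixed = TRUE),
             stringsAsFactors = FALSE)
}

#' Read/write a CDR3 length library
#'
#' Two-column TSV (germline name, integer length); `'#'` comment lines are
#' allowed. Libraries are represented as named integer vectors.
#'
#' @param lib named integer vector.
#' @param file path.
#' @return `read_library_tsv()` returns a named integer vector.
#' @export
write_library_tsv <- function(lib, file) {
  df <- data.frame(name = names(lib), length = as.integer(lib))
  utils::write.table(df, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' @rdname write_library_tsv
#' @export
read_library_tsv <- function(file) {
  df <- utils::read.table(file, sep = "\t", comment.char = "#",
                          col.names = c("name", "length"),
                          colClasses = c("character", "integer"))
  stats::setNames(as.integer(df$length), df$name)
}

#' Write/read clonal set assignments as CSV
#'
#' One row per input sequence: `seq_id`, `set_id`, `set_size`. Sequences
#' not placed in any clonal set carry the `"singleton"` token as `set_id`
#' and `set_size` 1. Rows are ordered by set id then sequence id, clonal
#' sets before singletons.
#'
#' @param assignments data frame with columns `seq_id`, `set_id` (integer,
#'   `NA` for singletons), `set_size`, as produced by [cut_tree()].
#' @param file path.
#' @export
write_assignments_csv <- function(assignments, file) {
  a <- assignments
  out <- data.frame(
    seq_id = a$seq_id,
    set_id = ifelse(is.na(a$set_id), "singleton", as.character(a$set_id)),
    set_size = a$set_size,
    stringsAsFactors = FALSE)
  ord <- order(is.na(a$set_id), a$set_id, a$seq_id)
  utils::write.csv(out[ord, , drop = FALSE], file, row.names = FALSE,
                   quote = FALSE)
}

#' @rdname write_assignments_csv
#' @return `read_assignments_csv()` returns the assignments data frame
#'   (`set_id` integer with `NA` for singletons).
#' @export
read_assignments_csv <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE,
                        colClasses = c("character", "character", "integer"))
  df$set_id <- suppressWarnings(
    ifelse(df$set_id == "singleton", NA_integer_, as.integer(df$set_id)))
  df
}

#' Serialize a dendrogram to XML
#'
#' Internal merges become nested `<node height="...">` elements (heights
#' printed with six decimal places); leaves become `<leaf id="..."/>`.
#' `read_dendrogram_xml()` inverts the writer, recovering topology and
#' heights at the printed precision.
#'
#' @param tree a dendrogram node as built by [upgma()].
#' @param file path.
#' @export
write_dendrogram_xml <- function(tree, file) {
  serialize <- function(node) {
    if (isTRUE(node$leaf))
      return(sprintf('<leaf id="%s"/>', node$id))
    paste0(sprintf('<node height="%.6f">', node$height),
           serialize(node$children[[1]]), serialize(node$children[[2]]),
           "</node>")
  }
  writeLines(serialize(tree), file)
  invisible(file)
}

#' @rdname write_dendrogram_xml
#' @export
read_dendrogram_xml <- function(file) {
  doc <- xml2::read_xml(file)
  parse_node <- function(el) {
    nm <- xml2::xml_name(el)
    if (nm == "leaf") {
      dendro_leaf(xml2::xml_attr(el, "id"))
    } else if (nm == "node") {
      kids <- xml2::xml_children(el)
      if (length(kids) != 2L)
        stop("dendrogram <node> must have exactly two children")
      dendro_merge(as.numeric(xml2::xml_attr(el, "height")),
                   parse_node(kids[[1]]), parse_node(kids[[2]]))
    } else stop("unexpected XML element: ", nm)
  }
  parse_node(xml2::xml_root(doc))
}
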