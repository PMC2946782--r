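#' @title CDR3 edit distances
#'
#' @description
#' Distances between nucleotide strings under the affine gap cost model
#' ([cost_model()]):
#'
#' * `ld()` — the (block-gap) Levenshtein distance: the minimum total weight
#'   of any edit path transforming `x` into `y`.
#' * `pned()` — post-normalized edit distance: `ld(x, y) / max(m, n)`.
#' * `ned()` — normalized edit distance: the minimum over all edit paths of
#'   `(W + offset) / L`, where `W` is the path weight and `L` its length
#'   (every aligned pair and every inserted or deleted symbol counts 1).
#'   The `offset` is a constant added to the numerator; the V/J germline
#'   penalties of [ned_vj()] enter this way. Unlike `pned()`, the
#'   minimizing path of `ned()` need not be a Levenshtein-optimal path.
#'
#' All three are symmetric and zero on identical strings.
#'
#' @param x,y nucleotide strings over `A,C,G,T,N` (case-insensitive).
#' @param costs a [cost_model()].
#' @param offset non-negative constant added to the NED numerator.
#' @param method `"parametric"` (default) solves the ratio minimization by
#'   Dinkelbach fractional programming, `"dp"` by the path-length-indexed
#'   dynamic program over `(i, j, k <= m + n)` states. Both are exact;
#'   the parametric solver is much faster on long strings.
#' @return a single numeric distance.
#' @examples
#' ld("ACGT", "AGGT")    # 1 substitution
#' ld("AAAA", "AA")      # 4: one deletion run of length 2 (open 3 + extend 1)
#' pned("ACGT", "AGGT")  # 0.25
#' ned("AAAA", "AA")     # 1.0: weight 4 over a path of length 4
#' ned("A", "")          # 3.0: a single deletion (weight 3, length 1)
#' @name cdr3_distances
NULL

check_nt <- function(x, arg = deparse(substitute(x))) {
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop(arg, " must be a single string", call. = FALSE)
  x <- toupper(x)
  if (!grepl("^[ACGTN]*$", x))
    stop(arg, " contains characters outside A,C,G,T,N", call. = FALSE)
  x
}

#' @rdname cdr3_distances
#' @export
ld <- function(x, y, costs = cost_model()) {
  x <- check_nt(x); y <- check_nt(y)
  cpp_ld(x, y, costs$match, costs$substitution, costs$gap_open,
         costs$gap_extend)
}

#' @rdname cdr3_distances
#' @export
pned <- function(x, y, costs = cost_model()) {
  x <- check_nt(x); y <- check_nt(y)
  denom <- max(nchar(x), nchar(y))
  if (denom == 0L) return(0)
  cpp_ld(x, y, costs$match, costs$substitution, costs$gap_open,
         costs$gap_extend) / denom
}

#' @rdname cdr3_distances
#' @export
ned <- function(x, y, costs = cost_model(), offset = 0,
                method = c("parametric", "dp")) {
  method <- match.arg(method)
  x <- check_nt(x); y <- check_nt(y)
  stopifnot(offset >= 0)
  if (nchar(x) == 0L && nchar(y) == 0L) {
    if (offset > 0) stop("NED with a positive offset is undefined for two empty strings")
    return(0)
  }
  f <- if (method == "parametric") cpp_ned else cpp_ned_dp
  f(x, y, costs$match, costs$substitution, costs$gap_open,
    costs$gap_extend, offset)
}

#' Exhaustive-path NED oracle
#'
#' Computes the normalized edit distance by explicit enumeration of every
#' edit path between two short strings, tracking the gap state so that
#' opening and extending an indel run are charged their respective costs.
#' Independent of the dynamic programs
#' in [ned()]; intended as a test oracle. Guarded to `m + n <= 12`.
#'
#' @inheritParams cdr3_distances
#' @return the minimum of `(W + offset) / L` over all edit paths.
#' @export
brute_force_ned <- function(x, y, costs = cost_model(), offset = 0) {
  x <- check_nt(x); y <- check_nt(y)
  m <- nchar(x); n <- nchar(y)
  if (m + n > 12L) stop("brute_force_ned is limited to m + n <= 12")
  if (m == 0L && n == 0L) {
    if (offset > 0) stop("NED with a positive offset is undefined for two empty strings")
    return(0)
  }
  xs <- strsplit(x, "")[[1]]
  ys <- strsplit(y, "")[[1]]
  best <- Inf
  # state: position (i, j), accumulated weight w, path length l,
  # last op (0 none/aligned, 1 delete, 2 insert)
  recurse <- function(i, j, w, l, last) {
    if (i == m && j == n) {
      best <<- min(best, (w + offset) / l)
      return(invisible())
    }
    if (i < m && j < n) {
      cc <- if (xs[i + 1] == ys[j + 1] && xs[i + 1] != "N")
        costs$match else costs$substitution
      recurse(i + 1, j + 1, w + cc, l + 1, 0L)
    }
    if (i < m)
      recurse(i + 1, j,
              w + if (last == 1L) costs$gap_extend else costs$gap_open,
              l + 1, 1L)
    if (j < n)
      recurse(i, j + 1,
              w + if (last == 2L) costs$gap_extend else costs$gap_open,
              l + 1, 2L)
    invisible()
  }
  recurse(0L, 0L, 0, 0L, 0L)
  best
}
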