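#' Reference Nussinov fill
#'
#' Fills the N x N score matrix `S` of the maximum-base-pair recurrence
#'
#' \deqn{S(i,j) = \max\big( S(i+1,j-1) + \sigma(i,j),\;
#'   \max_{i \le k < j} S(i,k) + S(k+1,j) \big)}
#'
#' in the serial order of the folding loop nest: `i` descending from `N-1`,
#' `j` ascending from `i+1`, all split updates (statement `s1`, reading
#' `S[i][i+k]` and `S[i+k+1][j]`) before the diagonal update (statement
#' `s2`). Only the upper triangle `i < j` is written; the diagonal and lower
#' triangle stay 0. `S[0][N-1]` (R index `S[1, N]`) is the maximum number of
#' base pairs.
#'
#' @param seq An [rna_sequence()] (or string, coerced).
#' @param rule A [pairing_rule()].
#' @return Integer N x N matrix.
#' @examples
#' S <- fill_reference("GGGAAACCC")
#' S[1, 9]   # maximum number of base pairs
#' @export
fill_reference <- function(seq, rule = pairing_rule()) {
  seq <- as_rna_sequence(seq)
  n <- seq$length
  S <- matrix(0L, n, n)
  if (n == 1L) return(S)
  lut <- pair_lookup(rule)
  codes <- seq_codes(seq)
  minsep <- rule$min_separation
  for (r in (n - 1L):1L) {           # r = i + 1, descending i
    for (cc in (r + 1L):n) {         # cc = j + 1, ascending j
      best <- max(S[r, r:(cc - 1L)] + S[(r + 1L):cc, cc])     # s1, all k
      sig <- if (cc - r >= minsep) lut[codes[r], codes[cc]] else 0L
      inner <- if (cc - 1L >= r + 1L) S[r + 1L, cc - 1L] else 0L
      S[r, cc] <- max(best, inner + sig)                      # s2
    }
  }
  S
}

#' Maximum base pairs, from a filled matrix
#'
#' @param S A matrix produced by any fill.
#' @return `S[0][N-1]`, the score of the whole strand.
#' @export
max_pairs <- function(S) S[1L, ncol(S)]

#' Brute-force structure enumeration oracle
#'
#' Exhaustively enumerates every non-crossing set of disjoint allowed pairs
#' with `j - i >= 2` and returns the maximum cardinality. Independent of the
#' dynamic-programming fill; exponential, so `N` is capped.
#'
#' @inheritParams fill_reference
#' @param cap Refuse sequences longer than this (default 16).
#' @return Integer: maximum number of pairs.
#' @examples
#' brute_force_max_pairs("GCGC")   # 1: only (0,3) satisfies j - i >= 2
#' @export
brute_force_max_pairs <- function(seq, rule = pairing_rule(), cap = 16L) {
  seq <- as_rna_sequence(seq)
  n <- seq$length
  if (n > cap) stop(sprintf("N = %d exceeds enumeration cap %d", n, cap))
  lut <- pair_lookup(rule)
  codes <- seq_codes(seq)
  minsep <- rule$min_separation
  # enumerate over interval [a, b] (1-based): leave a unpaired, or pair a with m
  enum <- function(a, b) {
    if (a >= b) return(0L)
    best <- enum(a + 1L, b)
    for (m in seq.int(a + 1L, b)) {
      if (m - a >= minsep && lut[codes[a], codes[m]] == 1L) {
        cand <- 1L + enum(a + 1L, m - 1L) + enum(m + 1L, b)
        if (cand > best) best <- cand
      }
    }
    best
  }
  enum(1L, n)
}

#' Secondary structure traceback
#'
#' Recovers one maximum-scoring non-crossing structure from a filled matrix.
#' Deterministic tie-break: the pairing branch is preferred over splits, then
#' the smallest split point `k`, recursing into the left part first.
#'
#' @param S Matrix produced by any fill over `seq`.
#' @inheritParams fill_reference
#' @return An object of class `rna_structure`: list with `pairs` (m x 2
#'   integer matrix, 1-based, i < j), `dot_bracket` (string of length N) and
#'   `n_pairs`. The pair count always equals `S[0][N-1]`.
#' @examples
#' s <- traceback_structure(fill_reference("ACGU"), "ACGU")
#' s$dot_bracket   # "(..)"
#' @export
traceback_structure <- function(S, seq, rule = pairing_rule()) {
  seq <- as_rna_sequence(seq)
  n <- seq$length
  stopifnot(is.matrix(S), nrow(S) == n, ncol(S) == n)
  validate_dp_matrix(S, mirrored = n > 1L && any(S[lower.tri(S)] != 0L))
  lut <- pair_lookup(rule)
  codes <- seq_codes(seq)
  minsep <- rule$min_separation
  pairs <- list()
  walk <- function(r, cc) {          # 1-based interval ends
    while (r < cc) {
      if (S[r, cc] == 0L) return(invisible())
      sig <- if (cc - r >= minsep) lut[codes[r], codes[cc]] else 0L
      inner <- if (cc - 1L >= r + 1L) S[r + 1L, cc - 1L] else 0L
      if (sig == 1L && S[r, cc] == inner + 1L) {
        pairs[[length(pairs) + 1L]] <<- c(r, cc)
        r <- r + 1L; cc <- cc - 1L
        next
      }
      found <- FALSE
      for (m in r:(cc - 1L)) {       # smallest split first
        if (S[r, cc] == S[r, m] + S[m + 1L, cc]) {
          walk(r, m)                 # left part first
          r <- m + 1L
          found <- TRUE
          break
        }
      }
      if (!found) stop("inconsistent score matrix: no branch reproduces the cell")
    }
  }
  walk(1L, n)
  pm <- if (length(pairs)) do.call(rbind, pairs) else matrix(integer(), 0L, 2L)
  colnames(pm) <- c("i", "j")
  db <- rep(".", n)
  if (nrow(pm)) { db[pm[, 1]] <- "("; db[pm[, 2]] <- ")" }
  structure(list(pairs = pm, dot_bracket = paste(db, collapse = ""),
                 n_pairs = nrow(pm), sequence = seq$residues, id = seq$id),
            class = "rna_structure")
}

#' @export
print.rna_structure <- function(x, ...) {
  cat(if (is.null(x$id)) "<rna_structure>" else sprintf("<rna_structure '%s'>", x$id),
      sprintf("%d pairs", x$n_pairs), "\n")
  cat(" ", x$sequence, "\n ", x$dot_bracket, "\n")
  invisible(x)
}

#' Validate score-matrix invariants
#'
#' Checks that a fill result is a plausible Nussinov matrix: non-negative,
#' monotone in both directions along the upper triangle
#' (`S[i][j] >= S[i+1][j]`, `S[i][j] >= S[i][j-1]`, implied by the split
#' terms at `k = i` and `k = j-1`), and bounded by `floor((j-i+1)/2)`.
#'
#' @param S Integer matrix.
#' @param mirrored Allow a mirrored lower triangle (the cache-efficient
#'   schedule stores the transpose there); otherwise the diagonal and lower
#'   triangle must be 0.
#' @return Invisibly `TRUE`; stops with a message on the first violation.
#' @export
validate_dp_matrix <- function(S, mirrored = FALSE) {
  n <- nrow(S)
  stopifnot(is.matrix(S), ncol(S) == n)
  if (any(S < 0L)) stop("negative entries in score matrix")
  if (any(diag(S) != 0L)) stop("nonzero diagonal")
  low <- S[lower.tri(S)]
  if (!mirrored && any(low != 0L)) stop("nonzero lower triangle")
  if (mirrored && any(S[lower.tri(S)] != t(S)[lower.tri(S)])) {
    stop("lower triangle is not the transpose of the upper one")
  }
  if (n >= 2L) {
    for (r in 1L:(n - 1L)) {
      cs <- (r + 1L):n
      if (any(S[r, cs] > ((cs - r + 1L) %/% 2L))) stop("entry above floor((j-i+1)/2) bound")
      if (any(S[r, cs] < S[cbind(pmin(r + 1L, cs), cs)])) stop("row monotonicity violated")
      if (any(S[r, cs] < S[r, pmax(cs - 1L, r)])) stop("column monotonicity violated")
    }
  }
  invisible(TRUE)
}
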