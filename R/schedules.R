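#' Diagonal-synchronized fill (Chang's schedule)
#'
#' Computes the score matrix diagonal by diagonal: after the main diagonal
#' and the one just above it are initialized to zero, cells on each diagonal
#' `d = j - i` are mutually independent and may be computed concurrently by
#' `workers` threads; a barrier separates diagonals. The result equals
#' [fill_reference()] bit-exactly and is independent of `workers`.
#'
#' Worker parallelism is a contract (independent cells per diagonal), not an
#' OS-thread implementation: the executor is serial, and `.shuffle_seed`
#' exercises the contract by computing the cells of each diagonal in a
#' random order.
#'
#' @inheritParams fill_reference
#' @param workers Declared parallel width; must be >= 1.
#' @param .shuffle_seed Optional seed; when set, cells within each diagonal
#'   are visited in a seeded random order (testing hook for the
#'   independence contract).
#' @return Integer N x N matrix, upper triangle filled.
#' @export
chang_fill <- function(seq, rule = pairing_rule(), workers = 1L, .shuffle_seed = NULL) {
  seq <- as_rna_sequence(seq)
  if (!is.numeric(workers) || workers < 1L) stop("workers must be >= 1")
  n <- seq$length
  S <- matrix(0L, n, n)
  if (n == 1L) return(S)
  lut <- pair_lookup(rule)
  codes <- seq_codes(seq)
  minsep <- rule$min_separation
  for (d in 2L:n) {                         # diagonal offset in 1-based cols
    rows <- 1L:(n - d + 1L)
    if (!is.null(.shuffle_seed) && length(rows) > 1L) {
      rows <- with_seed(.shuffle_seed + d, sample(rows))
    }
    for (r in rows) {                       # barrier between diagonals
      cc <- r + d - 1L
      best <- max(S[r, r:(cc - 1L)] + S[(r + 1L):cc, cc])
      sig <- if (cc - r >= minsep) lut[codes[r], codes[cc]] else 0L
      inner <- if (cc - 1L >= r + 1L) S[r + 1L, cc - 1L] else 0L
      S[r, cc] <- max(best, inner + sig)
    }
  }
  S
}

#' Cache-efficient transposed fill (Li's schedule)
#'
#' Same diagonal-by-diagonal schedule as [chang_fill()], but the lower
#' triangle of `S` stores the transpose of the finalized upper triangle:
#' after each cell `(row, col)` is computed its value is mirrored to
#' `(col, row)`. The split term then reads the column operand `S(k+1, col)`
#' from the mirrored row `S[col][k+1]`, so both operands of the split are
#' row-contiguous reads. The upper triangle equals [fill_reference()]
#' bit-exactly.
#'
#' @inheritParams chang_fill
#' @return Integer N x N matrix; upper triangle filled, lower triangle its
#'   transpose.
#' @export
li_fill <- function(seq, rule = pairing_rule(), workers = 1L, .shuffle_seed = NULL) {
  seq <- as_rna_sequence(seq)
  if (!is.numeric(workers) || workers < 1L) stop("workers must be >= 1")
  n <- seq$length
  S <- matrix(0L, n, n)
  if (n == 1L) return(S)
  lut <- pair_lookup(rule)
  codes <- seq_codes(seq)
  minsep <- rule$min_separation
  for (d in 2L:n) {
    rows <- 1L:(n - d + 1L)
    if (!is.null(.shuffle_seed) && length(rows) > 1L) {
      rows <- with_seed(.shuffle_seed + d, sample(rows))
    }
    for (r in rows) {
      cc <- r + d - 1L
      # both reads run along rows: S[r, k] and the mirrored S[cc, k+1]
      best <- max(S[r, r:(cc - 1L)] + S[cc, (r + 1L):cc])
      sig <- if (cc - r >= minsep) lut[codes[r], codes[cc]] else 0L
      inner <- if (cc - 1L >= r + 1L) S[r + 1L, cc - 1L] else 0L
      S[r, cc] <- max(best, inner + sig)
      S[cc, r] <- S[r, cc]                 # mirror the finalized value
    }
  }
  S
}

#' Fold a sequence under a named schedule
#'
#' Registry front end over the four execution schedules. All schedules
#' produce the same upper triangle; they differ in iteration order, memory
#' access pattern and parallel structure.
#'
#' @inheritParams fill_reference
#' @param schedule One of `"reference"`, `"chang"`, `"li"`, `"tiled"`.
#' @param B Tile-size vector `c(b1, b2, b3)`, used by the tiled schedule.
#' @param workers Declared parallel width for the non-reference schedules.
#' @return Integer N x N score matrix.
#' @examples
#' S <- fold("GGGAAACCC", schedule = "tiled", B = c(1, 4, 2))
#' max_pairs(S)
#' @export
fold <- function(seq, schedule = c("reference", "chang", "li", "tiled"),
                 rule = pairing_rule(), B = c(1L, 96L, 8L), workers = 1L) {
  schedule <- match.arg(schedule)
  switch(schedule,
         reference = fill_reference(seq, rule),
         chang = chang_fill(seq, rule, workers),
         li = li_fill(seq, rule, workers),
         tiled = tiled_fill(seq, rule, B = B, workers = workers))
}
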