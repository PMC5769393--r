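#' RNA sequences and pairing rules
#'
#' `rna_sequence()` builds a validated RNA sequence object from a character
#' string. Input is normalized before validation: lower case is folded to
#' upper case and `T` is mapped to `U` (DNA-alphabet FASTA files are common).
#' Any residue outside `{A, C, G, U}` after normalization is a hard error
#' that names the offending 1-based position.
#'
#' @param x A single character string of residues.
#' @param id Optional record identifier (kept from FASTA headers).
#' @return An object of class `rna_sequence`: a list with elements
#'   `residues` (normalized string), `length` and `id`.
#' @examples
#' rna_sequence("gattaca")   # normalized to GAUUACA
#' @export
rna_sequence <- function(x, id = NULL) {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    stop("`x` must be a single character string")
  }
  res <- chartr("acgutT", "ACGUUU", x)
  if (nchar(res) < 1L) stop("empty sequence")
  chars <- strsplit(res, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% c("A", "C", "G", "U"))
  if (length(bad) > 0L) {
    stop(sprintf("illegal residue '%s' at position %d%s",
                 chars[bad[1]], bad[1],
                 if (is.null(id)) "" else sprintf(" in record '%s'", id)))
  }
  structure(list(residues = res, length = nchar(res), id = id),
            class = "rna_sequence")
}

#' @export
print.rna_sequence <- function(x, ...) {
  hdr <- if (is.null(x$id)) "<rna_sequence>" else sprintf("<rna_sequence '%s'>", x$id)
  cat(hdr, sprintf("length %d", x$length), "\n")
  shown <- if (x$length > 60) paste0(substr(x$residues, 1, 57), "...") else x$residues
  cat(" ", shown, "\n")
  invisible(x)
}

#' @export
length.rna_sequence <- function(x) x$length

as_rna_sequence <- function(x, id = NULL) {
  if (inherits(x, "rna_sequence")) x else rna_sequence(x, id = id)
}

#' Base-pairing rule
#'
#' The pairing predicate of the folding recurrence. Residues `i`, `j` may
#' pair when the unordered residue pair is allowed and the indices are
#' separated by at least `min_separation` (`j - i >= 2` encodes the usual
#' "at least one unpaired base between the partners", i.e. `i < j - 1`).
#' The default allows Watson-Crick pairs A-U and G-C plus the G-U wobble;
#' set `wobble = FALSE` for strict Watson-Crick pairing.
#'
#' @param pairs Character vector of two-letter residue pairs (unordered;
#'   both orientations are filled in automatically).
#' @param wobble Include the G-U wobble pair in the default set.
#' @param min_separation Minimum `j - i` for a pair; fixed at 2 by the
#'   recurrence and validated, exposed for completeness.
#' @return An object of class `pairing_rule`.
#' @examples
#' pairing_rule()                  # A-U, G-C, G-U
#' pairing_rule(wobble = FALSE)    # A-U, G-C
#' pairing_rule(pairs = character())  # nothing pairs: folds are all-zero
#' @export
pairing_rule <- function(pairs = NULL, wobble = TRUE, min_separation = 2L) {
  if (is.null(pairs)) {
    pairs <- c("AU", "GC", if (wobble) "GU")
  }
  if (length(pairs) > 0L) {
    stopifnot(all(nchar(pairs) == 2L))
    pairs <- toupper(pairs)
  }
  rev2 <- function(p) paste0(substr(p, 2, 2), substr(p, 1, 1))
  allowed <- unique(c(pairs, vapply(pairs, rev2, character(1), USE.NAMES = FALSE)))
  min_separation <- as.integer(min_separation)
  if (!identical(min_separation, 2L)) {
    stop("min_separation is fixed to 2 by the recurrence (i < j - 1)")
  }
  structure(list(allowed = allowed, min_separation = min_separation),
            class = "pairing_rule")
}

#' @export
print.pairing_rule <- function(x, ...) {
  cat("<pairing_rule>", if (length(x$allowed)) paste(sort(x$allowed), collapse = " ") else "(empty)",
      sprintf("| min separation %d", x$min_separation), "\n")
  invisible(x)
}

# 0/1 pair matrix over residue codes, used by the fill loops
pair_lookup <- function(rule) {
  m <- matrix(0L, 4, 4, dimnames = list(c("A", "C", "G", "U"), c("A", "C", "G", "U")))
  for (p in rule$allowed) m[substr(p, 1, 1), substr(p, 2, 2)] <- 1L
  m
}

# residues as integer codes 1..4 (A,C,G,U)
seq_codes <- function(seq) {
  match(strsplit(seq$residues, "", fixed = TRUE)[[1]], c("A", "C", "G", "U"))
}

#' Pairing indicator sigma(i, j)
#'
#' Returns 1 when residues at 0-based positions `i` and `j` form an allowed
#' pair with `j - i >= 2`, else 0. Indices are 0-based to mirror the folding
#' loop nest; user-facing structure reports are 1-based.
#'
#' @param seq An [rna_sequence()] (or string, coerced).
#' @param i,j 0-based positions with `0 <= i < j <= N-1`.
#' @param rule A [pairing_rule()].
#' @return Integer 0 or 1.
#' @examples
#' sigma("GAC", 0, 2)   # 1: G-C with j - i = 2
#' sigma("GC", 0, 1)    # 0: adjacent residues never pair
#' @export
sigma <- function(seq, i, j, rule = pairing_rule()) {
  seq <- as_rna_sequence(seq)
  i <- as.integer(i); j <- as.integer(j)
  n <- seq$length
  if (any(i < 0L) || any(j > n - 1L) || any(i >= j)) {
    stop("need 0 <= i < j <= N-1")
  }
  lut <- pair_lookup(rule)
  codes <- seq_codes(seq)
  as.integer(j - i >= rule$min_separation & lut[cbind(codes[i + 1L], codes[j + 1L])] == 1L)
}
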