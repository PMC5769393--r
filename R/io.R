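#' Read RNA sequences from a FASTA file
#'
#' Parses multi-record FASTA (via Biostrings), then normalizes each record:
#' case folded to upper, `T` mapped to `U`. A residue outside
#' `{A, C, G, U}` after normalization is an error naming the record and the
#' 1-based position. Record ids are preserved.
#'
#' @param path Path to a FASTA file.
#' @return List of [rna_sequence()] objects (possibly empty).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  recs <- Biostrings::readBStringSet(path, format = "fasta")
  ids <- sub("\\s.*$", "", names(recs))
  lapply(seq_along(recs), function(r) {
    rna_sequence(as.character(recs[[r]]), id = ids[r])
  })
}

#' Generate a seeded synthetic RNA strand
#'
#' Draws residues i.i.d. from the given base frequencies with an explicit
#' seed, emulating randomly generated strands of configurable length and
#' composition. The same specification always yields the same sequence;
#' the caller's RNG state is untouched.
#'
#' @param length Strand length (>= 1).
#' @param base_frequencies Probabilities for A, C, G, U; must sum to 1
#'   (tolerance 1e-9).
#' @param seed Integer seed.
#' @param id Optional record id (default `synth<seed>_<length>`).
#' @return An [rna_sequence()].
#' @examples
#' synth_rna(10, seed = 42)
#' @export
synth_rna <- function(length, base_frequencies = rep(0.25, 4), seed = 1L,
                      id = NULL) {
  n <- as.integer(length)
  if (length(n) != 1L || is.na(n) || n < 1L) stop("length must be >= 1")
  p <- as.numeric(base_frequencies)
  if (length(p) != 4L || any(is.na(p)) || any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    stop("base_frequencies must be 4 non-negative values summing to 1")
  }
  res <- with_seed(seed, sample(c("A", "C", "G", "U"), n, replace = TRUE, prob = p))
  rna_sequence(paste(res, collapse = ""),
               id = if (is.null(id)) sprintf("synth%d_%d", seed, n) else id)
}

#' Write structures and reports
#'
#' `write_structure()` writes dot-bracket text, two lines per record
#' (sequence, then brackets). `write_pairs()` writes the pair list as TSV
#' with 1-based columns `i`, `j`, `residues`. `write_tss()` writes a
#' tile-size-selection report as CSV (columns `b1`, `b2`, `b3`, `valid`,
#' `runtime_s`, `rank`), rank ascending. `write_violations()` writes a
#' [validate_schedule()] report as TSV. All writers are byte-stable given
#' identical inputs.
#'
#' @param structures One `rna_structure` or a list of them.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_structure <- function(structures, path) {
  if (inherits(structures, "rna_structure")) structures <- list(structures)
  con <- file(path, "w")
  on.exit(close(con))
  for (s in structures) {
    if (!is.null(s$id)) writeLines(paste0(">", s$id), con)
    writeLines(c(s$sequence, s$dot_bracket), con)
  }
  invisible(path)
}

#' @rdname write_structure
#' @param structure One `rna_structure`.
#' @export
write_pairs <- function(structure, path) {
  pm <- structure$pairs
  res <- strsplit(structure$sequence, "", fixed = TRUE)[[1]]
  df <- data.frame(i = pm[, 1], j = pm[, 2],
                   residues = if (nrow(pm)) paste0(res[pm[, 1]], "-", res[pm[, 2]])
                              else character())
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_structure
#' @param records A [tss_search()] result.
#' @export
write_tss <- function(records, path) {
  df <- as.data.frame(records)[, c("b1", "b2", "b3", "valid", "runtime_s", "rank")]
  df <- df[order(is.na(df$rank), df$rank), , drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_structure
#' @param violations A [validate_schedule()] report.
#' @export
write_violations <- function(violations, path) {
  utils::write.table(violations, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
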