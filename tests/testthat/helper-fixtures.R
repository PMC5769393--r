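# Shared fixtures: seeded synthetic strands and the tile-size grid the
# construction suite sweeps. Everything is generated in code at test time.

`%||%` <- function(a, b) if (is.null(a)) b else a

fixture_tile_sizes <- function() {
  list(c(1L, 1L, 1L), c(1L, 2L, 2L), c(2L, 2L, 2L),
       c(2L, 3L, 5L), c(1L, 4L, 2L), c(3L, 3L, 3L))
}

# deterministic family of random strands: lengths cycle over 2..64
fixture_sequences <- function(n_seqs, lengths = 2:64, seed0 = 5000L) {
  lens <- rep_len(lengths, n_seqs)
  lapply(seq_len(n_seqs), function(r) synth_rna(lens[r], seed = seed0 + r))
}

upper_only <- function(S) {
  S[lower.tri(S)] <- 0L
  S
}

# structure invariants: allowed pairs with j - i >= 2, disjoint, non-crossing
expect_valid_structure <- function(st, seq, rule = pairing_rule()) {
  pm <- st$pairs
  if (nrow(pm) == 0L) return(invisible(TRUE))
  expect_true(all(pm[, 1] < pm[, 2]))
  expect_true(all(pm[, 2] - pm[, 1] >= rule$min_separation))
  expect_equal(anyDuplicated(c(pm[, 1], pm[, 2])), 0L)
  res <- strsplit(seq$residues, "", fixed = TRUE)[[1]]
  expect_true(all(paste0(res[pm[, 1]], res[pm[, 2]]) %in% rule$allowed))
  if (nrow(pm) > 1L) {
    for (a in seq_len(nrow(pm) - 1L)) {
      i <- pm[a, 1]; j <- pm[a, 2]
      p <- pm[-seq_len(a), 1, drop = TRUE]; q <- pm[-seq_len(a), 2, drop = TRUE]
      crossing <- (i < p & p < j & j < q) | (p < i & i < q & q < j)
      expect_false(any(crossing))
    }
  }
  invisible(TRUE)
}
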