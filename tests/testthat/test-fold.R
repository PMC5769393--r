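test_that("sigma implements the pairing predicate with minimum separation", {
  expect_identical(sigma("GAC", 0, 2), 1L)          # G-C, j - i = 2
  expect_identical(sigma("GC", 0, 1), 0L)           # adjacent: never pairs
  expect_identical(sigma("ACAAAC", 0, 5), 0L)       # A-C not allowed
  expect_identical(sigma("GAU", 0, 2, pairing_rule(wobble = FALSE)), 0L)
  expect_identical(sigma("GAU", 0, 2, pairing_rule(wobble = TRUE)), 1L)
  expect_error(sigma("ACGU", 2, 1), "i < j")
  expect_error(sigma("ACGU", 0, 4), "i < j|N-1")
})

test_that("input normalization folds case, maps T to U and rejects others", {
  expect_identical(rna_sequence("gattaca")$residues, "GAUUACA")
  expect_error(rna_sequence("ACGN"), "position 4")
  expect_error(rna_sequence(""), "empty")
})

test_that("reference fill reproduces hand-checked and oracle scores", {
  expect_identical(max_pairs(fill_reference("AAAA")), 0L)
  expect_identical(max_pairs(fill_reference("ACGU")), 1L)
  expect_identical(max_pairs(fill_reference("GGGAAACCC")), 3L)
  expect_identical(fill_reference("A"), matrix(0L, 1, 1))
  expect_error(fill_reference(""), "empty")
})

test_that("brute-force enumeration oracle handles the base cases and its cap", {
  expect_identical(brute_force_max_pairs("AAAA"), 0L)
  expect_identical(brute_force_max_pairs("GC"), 0L)   # length 2: no pair fits
  expect_identical(brute_force_max_pairs("GCGC"), 1L) # only (0,3) has j-i >= 2
  expect_error(brute_force_max_pairs(synth_rna(17, seed = 1)), "cap")
})

test_that("fill equals the enumeration oracle and keeps matrix invariants", {
  seqs <- fixture_sequences(60, lengths = 2:20, seed0 = 300L)
  for (q in seqs) {
    S <- fill_reference(q)
    expect_true(validate_dp_matrix(S))
    if (q$length <= 14) {
      expect_identical(max_pairs(S), brute_force_max_pairs(q))
    }
  }
})

test_that("an empty pairing rule yields the all-zero matrix", {
  empty <- pairing_rule(pairs = character())
  for (sd in 1:5) {
    q <- synth_rna(sample(2:30, 1), seed = sd)
    expect_true(all(fill_reference(q, empty) == 0L))
  }
})

test_that("traceback returns a valid maximum structure, deterministically", {
  st <- traceback_structure(fill_reference("AAAA"), "AAAA")
  expect_identical(st$dot_bracket, "....")
  expect_identical(st$n_pairs, 0L)
  st <- traceback_structure(fill_reference("ACGU"), "ACGU")
  expect_identical(st$dot_bracket, "(..)")
  expect_identical(unname(st$pairs[1, ]), c(1L, 4L))  # 1-based report of (0,3)
  for (sd in 1:20) {
    q <- synth_rna(sample(2:40, 1), seed = 700 + sd)
    S <- fill_reference(q)
    st <- traceback_structure(S, q)
    expect_identical(st$n_pairs, max_pairs(S))
    expect_valid_structure(st, q)
    expect_identical(st$dot_bracket, traceback_structure(S, q)$dot_bracket)
  }
})

test_that("traceback rejects an inconsistent score matrix", {
  S <- fill_reference("GGGAAACCC")
  S[1, 9] <- S[1, 9] + 5L
  expect_error(traceback_structure(S, "GGGAAACCC"))
})
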