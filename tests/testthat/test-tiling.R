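test_that("original tiles block the execution order and partition the domain", {
  N <- 4L
  inst <- enumerate_instances(N)
  # a single all-covering tile
  t0 <- original_tile_of(inst, c(N, N, N), N)
  expect_true(all(t0 == 0L))
  # unit tiles: s1(0,1,0) lands in (ii, jj, kk) = (3, 0, 0)
  t1 <- original_tile_of(inst, c(1, 1, 1), N)
  r <- which(inst$stmt == "s1" & inst$i == 0 & inst$j == 1 & inst$k == 0)
  expect_identical(unlist(t1[r, ], use.names = FALSE), c(3L, 0L, 0L))
  expect_true(all(t1 >= 0L))
  # partition: tile sizes assign every instance exactly once
  for (B in fixture_tile_sizes()) {
    tt <- original_tile_of(inst, B, N)
    expect_identical(nrow(tt), nrow(inst))
    expect_identical(sum(lengths(split(seq_len(nrow(inst)),
                                       paste(tt$ii, tt$jj, tt$kk)))), nrow(inst))
  }
})

test_that("closure-applied and closed-form tile corrections agree everywhere", {
  for (N in c(4L, 7L, 11L, 14L)) {
    for (B in fixture_tile_sizes()) {
      a <- build_valid_tiles(N, B, method = "closure")
      b <- build_valid_tiles(N, B, method = "closed_form")
      expect_identical(a$instances, b$instances)
    }
  }
})

test_that("the literal slicing set algebra reproduces build_valid_tiles", {
  # TILE_ITR = TILE - R+(TILE_GT); TVLD_LT = (R+(TILE_ITR) & TILE_LT) - R+(TILE_GT)
  for (N in c(5L, 8L)) {
    g <- build_dependence_graph(N)
    clo <- transitive_closure(g, "closed_form")
    for (B in list(c(1L, 2L, 2L), c(2L, 2L, 2L), c(2L, 3L, 5L))) {
      tm <- build_valid_tiles(N, B)
      ins <- tm$instances
      okey <- tile_key(data.frame(ii = ins$ii, jj = ins$jj, kk = ins$kk), N, B)
      sets <- tile_sets(tm)
      for (key in sort(unique(okey))) {
        tile <- ins$idx[okey == key]
        gt <- ins$idx[okey > key]
        lt <- ins$idx[okey < key]
        r_gt <- unique(clo$dst[clo$src %in% gt])
        itr <- setdiff(tile, r_gt)
        r_itr <- unique(clo$dst[clo$src %in% itr])
        tvld_lt <- setdiff(intersect(r_itr, lt), r_gt)
        id <- paste(tile_key_decode(key, N, B), collapse = ".")
        expect_identical(sort(itr), sort(unname(sets$TILE_ITR[[id]] %||% integer())))
        expect_identical(sort(tvld_lt), sort(unname(sets$TVLD_LT[[id]] %||% integer())))
      }
    }
  }
})

test_that("corrections only delay work: moved instances join later tiles, s2 never moves", {
  for (N in c(4L, 9L, 13L, 16L)) {
    for (B in fixture_tile_sizes()) {
      tm <- build_valid_tiles(N, B, method = "closed_form")
      ins <- tm$instances
      ok <- tile_key(data.frame(ii = ins$ii, jj = ins$jj, kk = ins$kk), N, B)
      ck <- tile_key(data.frame(ii = ins$cii, jj = ins$cjj, kk = ins$ckk), N, B)
      expect_true(all(ck >= ok))
      expect_true(all(ck[ins$moved] > ok[ins$moved]))
      expect_true(all(ins$stmt[ins$moved] == "s1"))
      # corrected tiles partition: each instance appears once by construction,
      # and the corrected sets cover the union of the originals
      expect_identical(sort(unlist(tile_sets(tm)$TILE_VLD, use.names = FALSE)),
                       ins$idx)
    }
  }
})

test_that("lexicographic execution of corrected tiles has no violations", {
  for (N in c(4L, 6L, 10L, 15L)) {
    g <- cached_graph(N)
    for (B in fixture_tile_sizes()) {
      tm <- build_valid_tiles(N, B, method = "closed_form")
      expect_identical(nrow(validate_schedule(tm, g)), 0L)
    }
  }
})

test_that("validator flags invalid orders and rejects non-permutations", {
  tm <- build_valid_tiles(6, c(1, 2, 2))
  g <- cached_graph(6L)
  ord <- lex_tile_order(tm)
  vio <- validate_schedule(tm, g, ord[rev(seq_len(nrow(ord))), ])
  expect_gt(nrow(vio), 0)
  expect_true(all(c("src_stmt", "dst_tile") %in% names(vio)))
  expect_error(validate_schedule(tm, g, ord[-1, ]), "permutation")
  # a single-tile map is valid under its only order
  tm1 <- build_valid_tiles(5, c(5, 5, 5))
  expect_identical(nrow(validate_schedule(tm1, cached_graph(5L))), 0L)
  expect_identical(nrow(lex_tile_order(tm1)), 1L)
})

test_that("wavefronts honor all dependences and members are independent", {
  tm <- build_valid_tiles(8, c(8, 8, 8))
  wf <- wavefronts(tm)
  expect_identical(length(wf), 1L)                 # single tile, single wave
  expect_identical(nrow(wf[[1]][[1]]), 1L)
  for (N in c(6L, 12L)) {
    g <- cached_graph(N)
    for (B in list(c(1L, 2L, 2L), c(2L, 3L, 5L), c(3L, 3L, 3L))) {
      tm <- build_valid_tiles(N, B)
      wf <- wavefronts(tm, g)                      # errors on contract violation
      # members within one wavefront are pairwise independent
      ins <- tm$instances
      member <- paste(ins$cii, ins$cjj)
      w <- ins$cii + ins$cjj
      e <- g$edges
      cross <- member[e$src] != member[e$dst]
      expect_true(all(w[e$src][cross] < w[e$dst][cross]))
      # and the closure agrees (sampled): no same-wave cross-member reach
      clo <- cached_closure(N)
      crossc <- member[clo$src] != member[clo$dst]
      expect_true(all(w[clo$src][crossc] < w[clo$dst][crossc]))
    }
  }
})
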