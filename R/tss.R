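#' Candidate grid for tile-size selection
#'
#' Per-dimension candidate lists. The default list is the 20-value search
#' set `{1, 2, 4, 6, 8, 12, 16, 24, 32, 40, 48, 64, 96, 128, 150, 200,
#' 256, 300, 400, 512}` in every dimension, giving a search space of
#' 20^3 = 8000 tile sizes.
#'
#' @param b1,b2,b3 Integer candidate vectors (all >= 1).
#' @return An object of class `tss_grid`.
#' @export
tss_grid <- function(b1 = tss_default_candidates(),
                     b2 = tss_default_candidates(),
                     b3 = tss_default_candidates()) {
  chk <- function(v, nm) {
    v <- as.integer(v)
    if (length(v) == 0L) stop(sprintf("empty candidate list for %s", nm))
    if (any(is.na(v)) || any(v < 1L)) stop(sprintf("candidates for %s must be >= 1", nm))
    v
  }
  structure(list(b1 = chk(b1, "b1"), b2 = chk(b2, "b2"), b3 = chk(b3, "b3")),
            class = "tss_grid")
}

#' @rdname tss_grid
#' @export
tss_default_candidates <- function() {
  c(1L, 2L, 4L, 6L, 8L, 12L, 16L, 24L, 32L, 40L, 48L, 64L,
    96L, 128L, 150L, 200L, 256L, 300L, 400L, 512L)
}

#' Enumerate a candidate grid
#'
#' Cartesian product of the per-dimension candidate lists, in deterministic
#' lexicographic order of `(b1, b2, b3)`.
#'
#' @param grid A [tss_grid()].
#' @return Data frame `b1`, `b2`, `b3`, one row per candidate tile size.
#' @examples
#' nrow(tss_enumerate(tss_grid()))   # 8000
#' @export
tss_enumerate <- function(grid = tss_grid()) {
  stopifnot(inherits(grid, "tss_grid"))
  out <- expand.grid(b3 = sort(grid$b3), b2 = sort(grid$b2), b1 = sort(grid$b1),
                     KEEP.OUT.ATTRS = FALSE)[, c("b1", "b2", "b3")]
  rownames(out) <- NULL
  out
}

#' Empirical tile-size selection search
#'
#' For each candidate tile size: check validity (membership in the
#' pre-verified `b1 = 1` family, or the full dependence oracle at the proxy
#' size `proxy_n`), then time the tiled fill -- one warm-up run followed by
#' `repeats` measured runs whose median is recorded -- and finally rank the
#' valid candidates by ascending runtime (ties broken by lexicographic
#' `(b1, b2, b3)`, so the ranking is stable under permutation of the
#' records). The timer is injectable: tests pass a deterministic function
#' `function(B, seq, rule) -> seconds`, making the search a pure function
#' of its inputs; the default timer measures [tiled_fill()] wall time.
#' Absolute runtimes are hardware-bound and never asserted, only ranked.
#'
#' @inheritParams fill_reference
#' @param grid A [tss_grid()].
#' @param repeats Measured runs per candidate (>= 1); the median is kept.
#' @param timer `NULL` for the real timer, or an injected deterministic
#'   function.
#' @param seed Seed controlling any randomness in the search bookkeeping.
#' @param proxy_n Desk-scale size for oracle validation of `b1 > 1`
#'   candidates.
#' @return Data frame of class `tss_result`: `b1`, `b2`, `b3`, `valid`,
#'   `runtime_s` (NA for invalid or failed candidates), `failed`, `rank`
#'   (NA for unranked records).
#' @export
tss_search <- function(seq, grid = tss_grid(), repeats = 3L, timer = NULL,
                       seed = 1L, rule = pairing_rule(), proxy_n = 16L) {
  seq <- as_rna_sequence(seq)
  stopifnot(inherits(grid, "tss_grid"))
  repeats <- as.integer(repeats)
  if (is.na(repeats) || repeats < 1L) stop("repeats must be >= 1")
  cand <- tss_enumerate(grid)
  real_timer <- is.null(timer)
  if (real_timer) {
    timer <- function(B, seq, rule) {
      tiled_fill(seq, rule, B = B, validate = "none")          # warm-up
      med <- stats::median(vapply(seq_len(repeats), function(r) {
        unname(system.time(tiled_fill(seq, rule, B = B, validate = "none"))["elapsed"])
      }, numeric(1)))
      med
    }
  }
  n <- nrow(cand)
  valid <- logical(n); runtime <- rep(NA_real_, n); failed <- logical(n)
  for (r in seq_len(n)) {
    B <- c(cand$b1[r], cand$b2[r], cand$b3[r])
    valid[r] <- if (B[1] == 1L) TRUE else {
      tm <- build_valid_tiles(max(4L, min(seq$length, as.integer(proxy_n))), B,
                              method = "closed_form")
      nrow(validate_schedule(tm, cached_graph(tm$N))) == 0L
    }
    if (!valid[r]) next
    tv <- tryCatch(timer(B, seq, rule), error = function(e) NA_real_)
    if (is.na(tv)) failed[r] <- TRUE else runtime[r] <- as.numeric(tv)
  }
  if (!any(valid & !failed)) stop("no valid candidate could be timed")
  out <- cbind(cand, valid = valid, runtime_s = runtime, failed = failed)
  out$rank <- NA_integer_
  ok <- which(valid & !failed)
  o <- ok[order(runtime[ok], cand$b1[ok], cand$b2[ok], cand$b3[ok])]
  out$rank[o] <- seq_along(o)
  class(out) <- c("tss_result", class(out))
  attr(out, "seed") <- seed
  attr(out, "repeats") <- repeats
  out
}
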