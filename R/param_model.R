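#' Fit the sparse integer factor model to one factor pair
#'
#' Two fixed-tile-size codes generated with the same structure differ only
#' in the integer factors at matching code positions. Each factor `y` obeys
#' the general model
#'
#' \deqn{y = a_0 b_1 b_2 + a_1 b_1 + a_2 b_2 + a_3 b_3 + a_4}
#'
#' with unknown integer coefficients of which at most two are nonzero. Given
#' the factors `y1`, `y2` observed at the same position under tile sizes
#' `B1`, `B2`, the pair of linear equations is solved exactly over integer
#' supports of size at most two, searched in a fixed priority order:
#' the constant alone; single linear terms (`b1`, `b2`, `b3`); a linear term
#' plus constant; pairs of linear terms; finally supports involving the
#' bilinear term `b1*b2`. The first rank with an exact solution wins; two
#' solutions at the same rank raise an ambiguity error listing the
#' candidates (never a silent choice), and no solution at any rank raises an
#' "unmodellable factor pair" error.
#'
#' @param y1,y2 Integer factors observed at the same code position of the
#'   two fixed codes.
#' @param B1,B2 Tile-size vectors of the two codes; defaults are the prime
#'   choices `c(23, 47, 113)` and `c(37, 79, 167)`, which keep the two
#'   equations independent for every support.
#' @return An object of class `factor_model`: list with integer
#'   coefficients `a0..a4`, the `formula` string, and the inputs.
#' @examples
#' fit_factor_model(93, 153)     # 2*b1 + b2
#' fit_factor_model(1081, 2923)  # b1*b2
#' @export
fit_factor_model <- function(y1, y2, B1 = c(23L, 47L, 113L), B2 = c(37L, 79L, 167L)) {
  B1 <- tile_size(B1); B2 <- tile_size(B2)
  if (all(B1 == B2)) stop("B1 and B2 must differ in at least one coordinate")
  y1 <- as.numeric(y1); y2 <- as.numeric(y2)
  if (y1 != round(y1) || y2 != round(y2)) stop("factors must be integers")
  # model basis evaluated at the two tile sizes: (b1*b2, b1, b2, b3, 1)
  basis <- rbind(c(B1[1] * B1[2], B1, 1), c(B2[1] * B2[2], B2, 1))
  colnames(basis) <- c("a0", "a1", "a2", "a3", "a4")
  y <- c(y1, y2)

  solve_support <- function(support) {        # columns of `basis` to use
    a <- numeric(5)
    if (length(support) == 0L) {
      if (all(y == 0)) return(a) else return(NULL)
    }
    M <- basis[, support, drop = FALSE]
    if (length(support) == 1L) {
      m <- M[, 1]
      if (any(m == 0)) return(NULL)
      v <- y / m
      if (v[1] != v[2] || v[1] != round(v[1])) return(NULL)
      a[support] <- v[1]
      return(a)
    }
    det <- M[1, 1] * M[2, 2] - M[1, 2] * M[2, 1]
    if (det == 0) return(NULL)
    n1 <- y[1] * M[2, 2] - M[1, 2] * y[2]
    n2 <- M[1, 1] * y[2] - y[1] * M[2, 1]
    if (n1 %% det != 0 || n2 %% det != 0) return(NULL)
    a[support[1]] <- n1 / det
    a[support[2]] <- n2 / det
    if (any(a[support] == 0)) return(NULL)    # genuinely size-2 supports only
    a
  }

  ranks <- list(
    constant      = list(integer(), 5L),
    linear        = list(2L, 3L, 4L),
    linear_const  = list(c(2L, 5L), c(3L, 5L), c(4L, 5L)),
    linear_pair   = list(c(2L, 3L), c(2L, 4L), c(3L, 4L)),
    bilinear      = list(1L, c(1L, 5L), c(1L, 2L), c(1L, 3L), c(1L, 4L)))

  for (rank in names(ranks)) {
    sols <- Filter(Negate(is.null), lapply(ranks[[rank]], solve_support))
    sols <- unique(sols)
    if (length(sols) == 1L) {
      a <- as.integer(sols[[1]])
      return(structure(list(a0 = a[1], a1 = a[2], a2 = a[3], a3 = a[4], a4 = a[5],
                            formula = coeff_formula(a), y1 = y1, y2 = y2,
                            B1 = B1, B2 = B2, rank = rank),
                       class = "factor_model"))
    }
    if (length(sols) > 1L) {
      forms <- vapply(sols, coeff_formula, character(1))
      stop(sprintf("ambiguous factor pair (%g, %g): rank '%s' admits %s",
                   y1, y2, rank, paste(forms, collapse = " and ")))
    }
  }
  stop(sprintf("unmodellable factor pair (%g, %g) under B1/B2", y1, y2))
}

# render integer coefficients (a0..a4) as a factor expression in b1,b2,b3
coeff_formula <- function(a) {
  terms <- character()
  lab <- c("b1*b2", "b1", "b2", "b3")
  for (t in 1:4) {
    if (a[t] == 0) next
    co <- if (abs(a[t]) == 1) "" else paste0(abs(a[t]), "*")
    terms <- c(terms, paste0(if (a[t] < 0) "-" else if (length(terms)) "+" else "",
                             co, lab[t]))
  }
  if (a[5] != 0 || length(terms) == 0L) {
    terms <- c(terms, paste0(if (a[5] < 0) "-" else if (length(terms)) "+" else "",
                             abs(a[5])))
  }
  paste(terms, collapse = "")
}

#' @export
print.factor_model <- function(x, ...) {
  cat(sprintf("<factor_model> y = %s  (fits %g, %g)\n", x$formula, x$y1, x$y2))
  invisible(x)
}

#' Evaluate a fitted factor model at a tile size
#'
#' @param coeffs A [fit_factor_model()] result (or list with `a0..a4`).
#' @param B Tile sizes `c(b1, b2, b3)`.
#' @return Integer `a0*b1*b2 + a1*b1 + a2*b2 + a3*b3 + a4`. Round trip:
#'   `predict_factor(fit_factor_model(y1, y2, B1, B2), B1) == y1` (and
#'   likewise for `B2`) for every fittable pair.
#' @examples
#' predict_factor(fit_factor_model(93, 153), c(23, 47, 113))   # 93
#' @export
predict_factor <- function(coeffs, B) {
  B <- tile_size(B)
  as.integer(coeffs$a0 * B[1] * B[2] + coeffs$a1 * B[1] +
               coeffs$a2 * B[2] + coeffs$a3 * B[3] + coeffs$a4)
}

#' Fit the factor model across all positions of a code pair
#'
#' Fits each `(y1, y2)` pair independently and tabulates the solutions the
#' way the construction reports them: observed factors, coefficients
#' `a0..a4` and the recovered formula. Per-pair failures (ambiguous or
#' unmodellable pairs) are collected, not raised, with their positions.
#'
#' @param pairs Data frame with columns `y1`, `y2` and optionally
#'   `position` (labels; default row numbers).
#' @inheritParams fit_factor_model
#' @return Data frame: `position`, `y1`, `y2`, `a0..a4`, `formula`, `error`
#'   (NA for fitted rows).
#' @export
fit_code_model <- function(pairs, B1 = c(23L, 47L, 113L), B2 = c(37L, 79L, 167L)) {
  stopifnot(is.data.frame(pairs), all(c("y1", "y2") %in% names(pairs)))
  if (nrow(pairs) == 0L) {
    return(data.frame(position = character(), y1 = numeric(), y2 = numeric(),
                      a0 = integer(), a1 = integer(), a2 = integer(),
                      a3 = integer(), a4 = integer(), formula = character(),
                      error = character()))
  }
  pos <- if ("position" %in% names(pairs)) as.character(pairs$position)
         else as.character(seq_len(nrow(pairs)))
  rows <- lapply(seq_len(nrow(pairs)), function(r) {
    fm <- tryCatch(fit_factor_model(pairs$y1[r], pairs$y2[r], B1, B2),
                   error = function(e) e)
    if (inherits(fm, "error")) {
      data.frame(position = pos[r], y1 = pairs$y1[r], y2 = pairs$y2[r],
                 a0 = NA_integer_, a1 = NA_integer_, a2 = NA_integer_,
                 a3 = NA_integer_, a4 = NA_integer_, formula = NA_character_,
                 error = conditionMessage(fm))
    } else {
      data.frame(position = pos[r], y1 = pairs$y1[r], y2 = pairs$y2[r],
                 a0 = fm$a0, a1 = fm$a1, a2 = fm$a2, a3 = fm$a3, a4 = fm$a4,
                 formula = fm$formula, error = NA_character_)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
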