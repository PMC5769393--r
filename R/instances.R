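#' Enumerate statement instances of the folding loop nest
#'
#' The folding loop nest has two statements: `s1`, the split update
#' `S[i][j] = max(S[i][j], S[i][i+k] + S[i+k+1][j])` with
#' `0 <= k <= j-i-1`, and `s2`, the diagonal update
#' `S[i][j] = max(S[i][j], S[i+1][j-1] + sigma(i,j))` (recorded with
#' `k = 0`). The serial schedule runs `i` descending from `N-1`, `j`
#' ascending from `i+1`, all `s1` of a cell (k ascending) before its `s2`.
#'
#' @param N Strand length (>= 1).
#' @return A data frame with one row per instance in serial order: columns
#'   `stmt` ("s1"/"s2"), `i`, `j`, `k` (0-based) and `t`, the 0-based serial
#'   timestamp (row number minus one; a bijection onto `0..M-1`).
#' @examples
#' enumerate_instances(2)   # s1(0,1,0) then s2(0,1)
#' @export
enumerate_instances <- function(N) {
  N <- as.integer(N)
  if (length(N) != 1L || is.na(N) || N < 1L) stop("N must be a positive integer")
  if (N == 1L) {
    out <- data.frame(stmt = character(), i = integer(), j = integer(),
                      k = integer(), t = integer())
    return(out)
  }
  blocks <- vector("list", N - 1L)
  bi <- 0L
  for (i in (N - 2L):0L) {            # i = N-1 has an empty j range
    js <- (i + 1L):(N - 1L)
    lens <- js - i                     # s1 count per cell: j - i
    s1_j <- rep.int(js, lens)
    s1_k <- sequence(lens) - 1L
    cell <- data.frame(
      stmt = c(rep.int("s1", length(s1_j)), rep.int("s2", length(js))),
      i = i,
      j = c(s1_j, js),
      k = c(s1_k, rep.int(0L, length(js))))
    # within fixed i: order by j, then s1 (k ascending) before s2
    cell <- cell[order(cell$j, cell$stmt == "s2", cell$k), , drop = FALSE]
    bi <- bi + 1L
    blocks[[bi]] <- cell
  }
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out$t <- seq_len(nrow(out)) - 1L
  out
}

#' Build the exact instance-level dependence graph
#'
#' For each memory cell of `S`, the time-ordered accesses are collected
#' (each instance reads and rewrites its own cell; `s1(i,j,k)` additionally
#' reads `S[i][i+k]` and `S[i+k+1][j]`; `s2(i,j)` reads `S[i+1][j-1]`), and
#' a direct dependence edge joins each pair of consecutive conflicting
#' accesses (at least one of the two a write): the read-modify-write chain
#' along a cell's own instances, then an edge from the final write to every
#' later external read. Reads of never-written cells (the diagonal and the
#' lower triangle) produce no edges. The transitive closure of these direct
#' edges equals the closure of all-pairs conflict edges.
#'
#' @param N Strand length (>= 2).
#' @return An object of class `dependence_graph`: list with `N`,
#'   `instances` (from [enumerate_instances()], plus 1-based `idx`) and
#'   `edges` (data frame `src`, `dst` of instance indices; every edge has
#'   `t[src] < t[dst]`).
#' @export
build_dependence_graph <- function(N) {
  N <- as.integer(N)
  if (length(N) != 1L || is.na(N) || N < 2L) stop("N must be >= 2")
  inst <- enumerate_instances(N)
  inst$idx <- seq_len(nrow(inst))
  cell_key <- inst$i * N + inst$j           # the cell each instance writes

  # chain along each cell's own instances (consecutive read-modify-writes)
  o <- order(cell_key, inst$t)
  k_o <- cell_key[o]
  same <- k_o[-1L] == k_o[-length(k_o)]
  chain <- data.frame(src = inst$idx[o][-length(o)][same],
                      dst = inst$idx[o][-1L][same])

  # last writer of every cell is its s2 instance
  s2 <- inst[inst$stmt == "s2", , drop = FALSE]
  writer <- integer(N * N)                  # 0 = never written
  writer[s2$i * N + s2$j + 1L] <- s2$idx

  # external reads of written, off-diagonal cells
  s1 <- inst[inst$stmt == "s1", , drop = FALSE]
  rd <- data.frame(
    a = c(s1$i,            s1$i + s1$k + 1L, s2$i + 1L),
    b = c(s1$i + s1$k,     s1$j,             s2$j - 1L),
    reader = c(s1$idx, s1$idx, s2$idx))
  rd <- rd[rd$a < rd$b, , drop = FALSE]     # drop diagonal / degenerate reads
  src <- writer[rd$a * N + rd$b + 1L]
  keep <- src > 0L
  flow <- data.frame(src = src[keep], dst = rd$reader[keep])

  edges <- rbind(chain, flow)
  edges <- edges[order(inst$t[edges$src], inst$t[edges$dst]), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(N = N, instances = inst, edges = edges),
            class = "dependence_graph")
}

#' @export
print.dependence_graph <- function(x, ...) {
  cat(sprintf("<dependence_graph> N = %d: %d instances, %d direct edges\n",
              x$N, nrow(x$instances), nrow(x$edges)))
  invisible(x)
}

#' Closed-form reachability predicate
#'
#' Vectorized test of whether instance `p` reaches instance `q` through the
#' dependence graph, without materializing any edges. Writing `cell(x)` for
#' the cell instance `x` updates, `p` reaches `q` iff either both share a
#' cell and `p` runs earlier, or `cell(p)` is strictly nested inside
#' `cell(q)` (`iq <= ip <= jp <= jq`) and the chain can enter `q`'s cell no
#' later than `q`: always when `ip > iq` (the suffix operand `S[i+k+1][j]`
#' is read from `k = 0` on), and when `ip = iq` only from split
#' `k = jp - iq` on (so `q = s2`, or `q = s1(kq)` with `kq >= jp - iq`).
#' Verified against brute-force graph reachability in the test suite.
#'
#' @param p,q Data frames of instances (columns `stmt`, `i`, `j`, `k`, `t`),
#'   recycled against each other row-wise.
#' @return Logical vector.
#' @export
instance_reaches <- function(p, q) {
  n <- max(nrow(p), nrow(q))
  ix <- function(d) d[rep_len(seq_len(nrow(d)), n), , drop = FALSE]
  p <- ix(p); q <- ix(q)
  same <- p$i == q$i & p$j == q$j
  nested <- q$i <= p$i & p$j <= q$j & !same
  entry <- p$i > q$i | q$stmt == "s2" | q$k >= p$j - q$i
  (same & p$t < q$t) | (nested & entry)
}

#' Transitive closure of the dependence graph
#'
#' Returns the full reachability relation as an instance-index pair table.
#' Two routes: `"closed_form"` evaluates [instance_reaches()] over all
#' ordered instance pairs; `"brute"` runs graph reachability (breadth-first
#' search per source, via igraph) over the direct edges and serves as the
#' independent oracle. Both are exact; the closed form is the fast path.
#'
#' @param graph A [build_dependence_graph()] result.
#' @param method `"closed_form"` or `"brute"`.
#' @return Data frame `src`, `dst` (instance indices), ordered.
#' @export
transitive_closure <- function(graph, method = c("closed_form", "brute")) {
  method <- match.arg(method)
  inst <- graph$instances
  m <- nrow(inst)
  if (method == "closed_form") {
    ps <- rep(seq_len(m), times = m)
    qs <- rep(seq_len(m), each = m)
    ip <- inst$i[ps]; jp <- inst$j[ps]; tp <- inst$t[ps]
    iq <- inst$i[qs]; jq <- inst$j[qs]; tq <- inst$t[qs]
    same <- ip == iq & jp == jq
    hit <- (same & tp < tq) |
      (!same & iq <= ip & jp <= jq &
         (ip > iq | inst$stmt[qs] == "s2" | inst$k[qs] >= jp - iq))
    out <- data.frame(src = ps[hit], dst = qs[hit])
  } else {
    g <- igraph::graph_from_edgelist(as.matrix(graph$edges), directed = TRUE)
    if (igraph::vcount(g) < m) g <- igraph::add_vertices(g, m - igraph::vcount(g))
    d <- igraph::distances(g, mode = "out")
    hit <- is.finite(d) & d > 0
    out <- data.frame(src = row(hit)[hit], dst = col(hit)[hit])
  }
  out <- out[order(out$src, out$dst), , drop = FALSE]
  rownames(out) <- NULL
  out
}
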