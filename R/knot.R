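#' KMT chain reduction
#'
#' Iteratively removes a vertex whenever the triangle spanned by it and its
#' two neighbours is intersected by no other chain segment, which preserves
#' the knot type while shrinking the polygon (never below 3 vertices).
#' Reduction is idempotent.
#'
#' @param conf a [ring_conformation()] or N x 3 matrix (closed ring)
#' @return list with `coords` (reduced polygon) and `index` (1-based original
#'   bead indices of the surviving vertices)
#' @export
kmt_reduce <- function(conf) {
  cpp_kmt(as.matrix(conf))
}

#' Alexander determinant at -1 (knot determinant)
#'
#' Projects the ring onto a plane chosen by a seeded random rotation
#' (re-drawn if the projection is degenerate), extracts the underpass list,
#' builds the Alexander matrix, deletes one row and column and evaluates the
#' determinant at t = -1 in exact integer arithmetic. |Delta(-1)| equals q
#' for (2,q) torus knots and 1 for the unknot; it is odd for every knot.
#'
#' @param conf closed ring ([ring_conformation()] or matrix)
#' @param seed projection seed; the result is a topological invariant, so it
#'   does not depend on the seed, only the retry sequence does
#' @param reduce run [kmt_reduce()] first (cheaper and numerically safer)
#' @return non-negative integer-valued scalar |Delta(-1)|
#' @export
#' @examples
#' alexander_det(make_torus_knot(120, 3, verify = FALSE))  # 3
alexander_det <- function(conf, seed = 1L, reduce = TRUE) {
  x <- as.matrix(conf)
  if (reduce && nrow(x) > 16) x <- cpp_kmt(x)$coords
  cpp_alexander(x, as.integer(seed))
}

#' Is the ring knotted?
#'
#' `TRUE` iff the knot determinant differs from 1. Determinant-1 knots exist
#' only at 10+ crossings, far above the complexity scale handled here.
#' @inheritParams alexander_det
#' @export
is_knotted <- function(conf, seed = 1L) alexander_det(conf, seed) != 1

# close an open arc either directly (end-to-end bridge) or through two
# distant points placed far outward from the centroid; pick the closure
# whose added segments take part in fewer projected crossings (minimally
# interfering closure) and return its determinant
arc_closure_det <- function(arc, centroid, far, seed) {
  k <- nrow(arc)
  a <- arc[1, ]; b <- arc[k, ]
  # candidate 1: direct bridge = closing edge k of the polygon as-is
  cost_direct <- cpp_crossing_count(arc, seed, k)
  # candidate 2: rays outward from the centroid to distant points
  u1 <- a - centroid; u2 <- b - centroid
  n1 <- sqrt(sum(u1^2)); n2 <- sqrt(sum(u2^2))
  if (n1 < 1e-9) u1 <- c(1, 0, 0) else u1 <- u1 / n1
  if (n2 < 1e-9) u2 <- c(1, 0, 0) else u2 <- u2 / n2
  far_poly <- rbind(arc, centroid + far * u2, centroid + far * u1)
  cost_far <- cpp_crossing_count(far_poly, seed, c(k, k + 1, k + 2))
  if (cost_direct < cost_far) {
    cpp_alexander(arc, seed)
  } else {
    cpp_alexander(far_poly, seed)
  }
}

#' Determinant of a closed-off open arc
#'
#' Closes an open sub-chain with the minimally interfering closure (direct
#' end-to-end bridge vs rays to points at `far_factor` times the radius of
#' gyration outward from the centroid, whichever adds fewer projected
#' crossings) and returns the Alexander determinant of the result. Querying
#' the entire ring as an arc reproduces [alexander_det()].
#'
#' @param arc open polyline (k x 3 matrix)
#' @param centroid,rg reference centroid and radius of gyration (default:
#'   computed from the arc itself)
#' @param far_factor distance of the closure points in units of `rg`
#' @param seed projection seed
#' @export
arc_determinant <- function(arc, centroid = colMeans(arc),
                            rg = radius_of_gyration(arc),
                            far_factor = 100, seed = 1L) {
  arc <- as.matrix(arc)
  arc_closure_det(arc, centroid, far_factor * max(rg, 1e-6), seed)
}

#' Locate the shortest physically knotted arc
#'
#' Bottom-up search for the shortest sub-arc whose minimally interfering
#' closure carries the whole ring's knot type while the complementary arc
#' closes to the unknot. The search runs on the KMT-reduced polygon (whose
#' vertices keep their original bead indices); for large reduced polygons a
#' strided scan with local refinement bounds the cost unless `exact = TRUE`.
#'
#' @param conf a [ring_conformation()]
#' @param seed projection seed
#' @param exact scan every start index (default: stride `max(1, m/100)`)
#' @return NULL for the unknot, else list(arc_start, arc_end, l_k, det):
#'   1-based bead indices of the arc boundaries (the arc runs from
#'   `arc_start` forward, cyclically, to `arc_end`) and its length in beads
#' @export
find_knotted_arc <- function(conf, seed = 1L, exact = FALSE) {
  x <- as.matrix(conf)
  N <- nrow(x)
  red <- cpp_kmt(x)
  target <- cpp_alexander(red$coords, as.integer(seed))
  if (target == 1) return(NULL)
  m <- nrow(red$coords)
  centroid <- colMeans(x)
  far <- 100 * max(radius_of_gyration(x), 1e-6)
  stride <- if (exact) 1L else max(1L, m %/% 100L)

  # every candidate sub-arc of the reduced polygon, ranked by its length in
  # ORIGINAL beads (reduced edges can bridge very different bead counts, so
  # bottom-up minimality must be measured on the original ring)
  starts <- seq(1L, m, by = stride)
  cand <- expand.grid(s = starts, len = 2:(m - 1))
  i0 <- red$index[((cand$s - 1L) %% m) + 1L]
  i1 <- red$index[((cand$s - 1L + cand$len) %% m) + 1L]
  cand$beads <- ((i1 - i0) %% N) + 1L
  cand <- cand[order(cand$beads, cand$s), ]

  for (r in seq_len(nrow(cand))) {
    s <- cand$s[r]; len <- cand$len[r]
    idx <- ((s - 1L + 0:len) %% m) + 1L
    arc <- red$coords[idx, , drop = FALSE]
    if (arc_closure_det(arc, centroid, far, seed) != target) next
    cidx <- ((s - 1L + len + 0:(m - len)) %% m) + 1L
    comp <- red$coords[cidx, , drop = FALSE]
    if (arc_closure_det(comp, centroid, far, seed) != 1) next
    a0 <- red$index[idx[1]]
    a1 <- red$index[idx[len + 1L]]
    return(list(arc_start = a0, arc_end = a1,
                l_k = ((a1 - a0) %% N) + 1L, det = target))
  }
  # no proper sub-arc qualified: the whole ring is the minimal knotted arc
  list(arc_start = red$index[1], arc_end = red$index[m],
       l_k = N, det = target)
}

#' Per-conformation knot report
#'
#' Knot determinant, knottedness flag and (for knotted rings) the shortest
#' knotted arc. The determinant of any knot is odd; an even value would mark
#' a degenerate projection and is rejected internally.
#'
#' @inheritParams find_knotted_arc
#' @param arcs also locate the knotted arc (slower)
#' @return list of class `knot_report` with `det_minus1`, `is_knotted`,
#'   `arc_start`, `arc_end`, `l_k`
#' @export
knot_report <- function(conf, seed = 1L, arcs = TRUE) {
  det <- alexander_det(conf, seed)
  rep <- list(det_minus1 = det, is_knotted = det != 1,
              arc_start = NA_integer_, arc_end = NA_integer_,
              l_k = NA_integer_)
  if (det != 1 && arcs) {
    arc <- find_knotted_arc(conf, seed)
    rep$arc_start <- arc$arc_start
    rep$arc_end <- arc$arc_end
    rep$l_k <- arc$l_k
  }
  class(rep) <- "knot_report"
  rep
}

#' @export
print.knot_report <- function(x, ...) {
  cat("knot_report: |A(-1)| =", x$det_minus1,
      if (x$is_knotted) paste0("(knotted, arc ", x$arc_start, "..", x$arc_end,
                               ", l_k = ", x$l_k, ")") else "(unknot)", "\n")
  invisible(x)
}

#' Topology trace of a trajectory
#'
#' Evaluates the knot determinant (and optionally the knotted arc) on every
#' recorded frame, producing the per-replica time series consumed by the
#' ensemble observables.
#'
#' @param traj a `kr_trajectory`
#' @param seed projection seed
#' @param arcs also localise the knotted arc per frame (slow)
#' @param replica replica identifier stored in the output
#' @return data frame (class `topology_trace`) with columns time, det and,
#'   if requested, arc_start, arc_end, l_k
#' @export
trace_topology <- function(traj, seed = 1L, arcs = FALSE, replica = 1L) {
  nf <- dim(traj$frames)[3]
  det <- integer(nf)
  a0 <- a1 <- lk <- rep(NA_integer_, nf)
  for (i in seq_len(nf)) {
    f <- traj$frames[, , i]
    det[i] <- alexander_det(f, seed)
    if (arcs && det[i] != 1) {
      arc <- find_knotted_arc(f, seed)
      a0[i] <- arc$arc_start; a1[i] <- arc$arc_end; lk[i] <- arc$l_k
    }
  }
  out <- data.frame(time = traj$times, det = det, replica = replica)
  if (arcs) { out$arc_start <- a0; out$arc_end <- a1; out$l_k <- lk }
  class(out) <- c("topology_trace", "data.frame")
  out
}

#' Does a bead index fall inside a knotted arc?
#'
#' Cyclic membership test for the arc running forward from `arc_start` to
#' `arc_end` on a ring of N beads.
#' @param i bead index (vectorised)
#' @param arc list with `arc_start` and `arc_end` as from [find_knotted_arc()]
#' @param N ring size
#' @export
in_arc <- function(i, arc, N) {
  ((i - arc$arc_start) %% N) <= ((arc$arc_end - arc$arc_start) %% N)
}
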