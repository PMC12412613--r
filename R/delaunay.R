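# Bowyer-Watson Delaunay triangulation. Written in-package because no
# triangulation library is available; adequate for the few hundred
# particles of a cluster analysis.

# circumcircle of triangle (3 x 2 matrix); returns center and squared radius
#' @keywords internal
#' @noRd
circumcircle <- function(p) {
  ax <- p[1, 1]; ay <- p[1, 2]
  bx <- p[2, 1]; by <- p[2, 2]
  cx <- p[3, 1]; cy <- p[3, 2]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  if (abs(d) < 1e-12) return(list(center = c(NA, NA), r2 = Inf))
  ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
           (cx^2 + cy^2) * (ay - by)) / d
  uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
           (cx^2 + cy^2) * (bx - ax)) / d
  list(center = c(ux, uy), r2 = (ux - ax)^2 + (uy - ay)^2)
}

#' Delaunay triangulation edges
#'
#' Bowyer-Watson incremental triangulation; returns the unique edges as an
#' index matrix. Duplicated points are not allowed.
#'
#' @param pts numeric matrix, n x 2 (x, y).
#' @return Integer matrix m x 2 of point indices (i < j), one row per
#'   Delaunay edge. Zero rows for n < 2; the single pair for n = 2.
#' @export
delaunay_edges <- function(pts) {
  stopifnot(is.matrix(pts), ncol(pts) == 2)
  n <- nrow(pts)
  if (n < 2) return(matrix(integer(0), 0, 2))
  if (n == 2) return(matrix(c(1L, 2L), 1, 2))
  if (anyDuplicated(round(pts, 9))) stop("duplicate points")

  # super-triangle enclosing everything
  rng <- apply(pts, 2, range)
  d <- max(rng[2, ] - rng[1, ], 1)
  mid <- colMeans(rng)
  super <- rbind(mid + c(-20 * d, -10 * d),
                 mid + c(20 * d, -10 * d),
                 mid + c(0, 20 * d))
  allp <- rbind(pts, super)
  si <- n + 1:3
  tris <- list(c(si[1], si[2], si[3]))
  circ <- list(circumcircle(super))

  for (i in seq_len(n)) {
    p <- allp[i, ]
    bad <- vapply(seq_along(tris), function(t) {
      cc <- circ[[t]]
      sum((p - cc$center)^2) < cc$r2 * (1 + 1e-12)
    }, logical(1))
    # boundary polygon = edges of bad triangles not shared by two bad ones
    edges <- do.call(rbind, lapply(tris[bad], function(tr)
      rbind(sort(tr[1:2]), sort(tr[2:3]), sort(tr[c(1, 3)]))))
    if (is.null(edges)) next
    key <- paste(edges[, 1], edges[, 2])
    keep <- !(key %in% key[duplicated(key)])
    poly <- edges[keep, , drop = FALSE]
    tris <- tris[!bad]
    circ <- circ[!bad]
    for (e in seq_len(nrow(poly))) {
      tr <- c(poly[e, 1], poly[e, 2], i)
      cc <- circumcircle(allp[tr, , drop = FALSE])
      if (!is.finite(cc$r2)) next   # degenerate (collinear) sliver
      tris[[length(tris) + 1]] <- tr
      circ[[length(circ) + 1]] <- cc
    }
  }
  # drop triangles using super-triangle vertices, collect edges
  res <- do.call(rbind, lapply(tris, function(tr) {
    if (any(tr > n)) return(NULL)
    rbind(sort(tr[1:2]), sort(tr[2:3]), sort(tr[c(1, 3)]))
  }))
  if (is.null(res)) {
    # all points collinear: fall back to chain along the line
    o <- order(pts[, 1], pts[, 2])
    return(cbind(pmin(o[-n], o[-1]), pmax(o[-n], o[-1])))
  }
  res <- unique(res)
  res[order(res[, 1], res[, 2]), , drop = FALSE]
}
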