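# Triangular meshes and the finite-element representation of a Matern
# Gaussian field (alpha = 2 in two dimensions): Delaunay triangulation,
# lumped mass and stiffness matrices, sparse precision, and barycentric
# projection of observation sites onto mesh nodes.

# Incremental (Bowyer-Watson) Delaunay triangulation of a planar point set.
# Coordinates are centred and scaled first; circumcircles are cached so the
# cavity search is vectorised over triangles.
.delaunay <- function(pts) {
  n <- nrow(pts)
  if (n < 3L) stop_fmt("need at least 3 points to triangulate")
  ctr <- colMeans(pts)
  scl <- max(apply(pts, 2, function(z) diff(range(z))), 1e-12)
  p <- sweep(pts, 2, ctr) / scl
  if (abs(det(cov(p))) < 1e-18 && n >= 3L) {
    # guard against a fully collinear site set
    sv <- svd(sweep(p, 2, colMeans(p)))$d
    if (sv[2] < 1e-10) stop_fmt("degenerate (collinear) point set")
  }
  big <- rbind(c(-30, -15), c(30, -15), c(0, 40))
  allp <- rbind(p, big)

  circum <- function(i, j, k) {
    ax <- allp[i, 1]; ay <- allp[i, 2]
    bx <- allp[j, 1]; by <- allp[j, 2]
    cx <- allp[k, 1]; cy <- allp[k, 2]
    d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
    if (abs(d) < 1e-14) return(c(Inf, Inf, Inf))
    ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
             (cx^2 + cy^2) * (ay - by)) / d
    uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
             (cx^2 + cy^2) * (bx - ax)) / d
    c(ux, uy, (ux - ax)^2 + (uy - ay)^2)
  }

  tri <- matrix(c(n + 1L, n + 2L, n + 3L), ncol = 3)
  cc <- matrix(circum(n + 1L, n + 2L, n + 3L), ncol = 3)
  for (ip in seq_len(n)) {
    px <- p[ip, 1]; py <- p[ip, 2]
    bad <- (px - cc[, 1])^2 + (py - cc[, 2])^2 <= cc[, 3] * (1 + 1e-12)
    if (!any(bad)) next  # duplicate point outside all circles; skip
    badt <- tri[bad, , drop = FALSE]
    edges <- rbind(badt[, c(1, 2)], badt[, c(2, 3)], badt[, c(3, 1)])
    key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    keep_edge <- !(key %in% key[duplicated(key)])
    cavity <- edges[keep_edge, , drop = FALSE]
    tri <- tri[!bad, , drop = FALSE]
    cc <- cc[!bad, , drop = FALSE]
    newt <- cbind(cavity, ip)
    newcc <- t(apply(newt, 1, function(r) circum(r[1], r[2], r[3])))
    ok <- is.finite(newcc[, 3])
    tri <- rbind(tri, newt[ok, , drop = FALSE])
    cc <- rbind(cc, newcc[ok, , drop = FALSE])
  }
  keep <- rowSums(tri > n) == 0
  tri <- tri[keep, , drop = FALSE]
  # consistent (counter-clockwise) orientation
  for (r in seq_len(nrow(tri))) {
    a <- tri[r, ]
    det2 <- (p[a[2], 1] - p[a[1], 1]) * (p[a[3], 2] - p[a[1], 2]) -
      (p[a[3], 1] - p[a[1], 1]) * (p[a[2], 2] - p[a[1], 2])
    if (det2 < 0) tri[r, ] <- a[c(1, 3, 2)]
  }
  tri
}

#' Build a triangular mesh over observation sites
#'
#' Delaunay triangulation of a node set that is dense near the sites (fine
#' grid spacing `fine_edge` within a neighbourhood of any site) and coarse
#' over a buffered extension of the site hull (`coarse_edge` spacing), so the
#' triangles are finer where site density is high. Deterministic given the
#' inputs and `seed` (a tiny seeded jitter on grid nodes avoids degenerate
#' co-circular configurations).
#'
#' @param sites two-column matrix of planar site coordinates (see
#'   [project_coords()] for the longitude/latitude projection).
#' @param fine_edge target edge length near sites.
#' @param coarse_edge target edge length in the outer buffer.
#' @param buffer width of the outer extension beyond the site bounding box.
#' @param seed integer seed for the node jitter.
#' @return An object of class `reef_mesh` with `loc` (node coordinates,
#'   sites first) and `tri` (triangle index triplets).
#' @export
build_mesh <- function(sites, fine_edge, coarse_edge = 4 * fine_edge,
                       buffer = 2 * coarse_edge, seed = 1L) {
  sites <- as.matrix(sites)
  if (nrow(sites) < 3L) stop_fmt("need at least 3 sites")
  stopifnot(fine_edge > 0, coarse_edge >= fine_edge, buffer >= 0)
  sv <- svd(sweep(sites, 2, colMeans(sites)))$d
  if (sv[2] < 1e-9 * max(sv[1], 1)) stop_fmt("degenerate (collinear) site set")
  usite <- unique(round(sites / (0.25 * fine_edge))) * (0.25 * fine_edge)
  bb <- rbind(apply(sites, 2, min), apply(sites, 2, max))

  grid_pts <- function(spacing, expand) {
    xs <- seq(bb[1, 1] - expand, bb[2, 1] + expand, by = spacing)
    ys <- seq(bb[1, 2] - expand, bb[2, 2] + expand, by = spacing)
    as.matrix(expand.grid(x = xs, y = ys))
  }
  fine <- grid_pts(fine_edge, 2 * fine_edge)
  # keep fine nodes only near some site
  near <- vapply(seq_len(nrow(fine)), function(i) {
    min((fine[i, 1] - usite[, 1])^2 + (fine[i, 2] - usite[, 2])^2)
  }, numeric(1)) <= (3 * fine_edge)^2
  fine <- fine[near, , drop = FALSE]
  coarse <- grid_pts(coarse_edge, buffer)

  add_if_clear <- function(nodes, cand, tol) {
    for (i in seq_len(nrow(cand))) {
      d2 <- (cand[i, 1] - nodes[, 1])^2 + (cand[i, 2] - nodes[, 2])^2
      if (min(d2) > tol^2) nodes <- rbind(nodes, cand[i, ])
    }
    nodes
  }
  nodes <- usite
  nodes <- add_if_clear(nodes, fine, 0.45 * fine_edge)
  nodes <- add_if_clear(nodes, coarse, 0.45 * coarse_edge)

  n_grid <- nrow(nodes) - nrow(usite)
  if (n_grid > 0) {
    set.seed(substream_seed(seed, "mesh-jitter"))
    jit <- matrix(rnorm(2 * n_grid, sd = 1e-3 * fine_edge), ncol = 2)
    nodes[(nrow(usite) + 1):nrow(nodes), ] <-
      nodes[(nrow(usite) + 1):nrow(nodes), ] + jit
  }
  tri <- .delaunay(nodes)
  structure(list(loc = nodes, tri = tri, fine_edge = fine_edge,
                 coarse_edge = coarse_edge, buffer = buffer),
            class = "reef_mesh")
}

#' Project site coordinates to a local equal-area plane
#'
#' Equirectangular projection in kilometres about the site centroid, with
#' the longitude scale shrunk by the cosine of the central latitude. Adequate
#' for regional extents; distances enter the Matern kernel, so the
#' projection is documented and kept fixed.
#'
#' @param lon,lat coordinates in degrees.
#' @param center optional `c(lon0, lat0)`; defaults to the centroid.
#' @return Two-column matrix of planar coordinates (km), with the centre
#'   stored in `attr(, "center")`.
#' @export
project_coords <- function(lon, lat, center = NULL) {
  if (is.null(center)) center <- c(mean(lon), mean(lat))
  x <- (lon - center[1]) * 111.320 * cos(center[2] * pi / 180)
  y <- (lat - center[2]) * 110.574
  out <- cbind(x = x, y = y)
  attr(out, "center") <- center
  out
}

#' Finite-element matrices of a mesh
#'
#' Lumped mass matrix `C` (diagonal) and stiffness matrix `G` of linear
#' basis functions on the triangulation.
#'
#' @param mesh a `reef_mesh`.
#' @return List with sparse `C`, `G`, and the node count `n`.
#' @export
fem_matrices <- function(mesh) {
  loc <- mesh$loc; tri <- mesh$tri
  n <- nrow(loc)
  ii <- jj <- xx <- numeric(0)
  cdiag <- numeric(n)
  for (r in seq_len(nrow(tri))) {
    v <- tri[r, ]
    x <- loc[v, 1]; y <- loc[v, 2]
    b <- c(y[2] - y[3], y[3] - y[1], y[1] - y[2])
    cvec <- c(x[3] - x[2], x[1] - x[3], x[2] - x[1])
    area <- abs((x[2] - x[1]) * (y[3] - y[1]) - (x[3] - x[1]) * (y[2] - y[1])) / 2
    if (area <= 0) next
    Ke <- (outer(b, b) + outer(cvec, cvec)) / (4 * area)
    ii <- c(ii, rep(v, each = 3)); jj <- c(jj, rep(v, times = 3))
    xx <- c(xx, as.numeric(t(Ke)))
    cdiag[v] <- cdiag[v] + area / 3
  }
  G <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
  G <- (G + Matrix::t(G)) / 2
  list(C = Matrix::Diagonal(n, cdiag), G = G, n = n)
}

#' Sparse precision of the finite-element Matern field
#'
#' For smoothness order alpha = 2 in two dimensions,
#' `Q = tau^2 (kappa^4 C + 2 kappa^2 G + G C^{-1} G)`; the closed-form
#' marginal variance is `1 / (4 pi kappa^2 tau^2)` and the correlation range
#' (correlation ~0.13) is `sqrt(8) / kappa`.
#'
#' @param fem output of [fem_matrices()] (or a `reef_mesh`, triangulated on
#'   the fly).
#' @param kappa,tau positive scale parameters.
#' @return Sparse symmetric positive-definite precision matrix.
#' @export
spde_precision <- function(fem, kappa, tau) {
  if (inherits(fem, "reef_mesh")) fem <- fem_matrices(fem)
  if (kappa <= 0 || tau <= 0) stop_fmt("kappa and tau must be positive")
  Cinv <- Matrix::Diagonal(fem$n, 1 / Matrix::diag(fem$C))
  Q <- tau^2 * (kappa^4 * fem$C + 2 * kappa^2 * fem$G +
                  fem$G %*% Cinv %*% fem$G)
  Matrix::drop0(Matrix::forceSymmetric(Q))
}

#' Closed-form marginal variance of the Matern field
#'
#' @param kappa,tau positive scale parameters.
#' @return The stationary marginal variance `1 / (4 pi kappa^2 tau^2)`.
#' @export
spde_field_variance <- function(kappa, tau) 1 / (4 * pi * kappa^2 * tau^2)

#' Draw samples of a Gaussian field from its sparse precision
#'
#' @param Q sparse precision matrix.
#' @param n number of draws.
#' @param seed integer seed.
#' @return Matrix with one column per draw.
#' @export
spde_sample <- function(Q, n = 1L, seed = 1L) {
  set.seed(seed)
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(Q), LDL = FALSE, perm = TRUE)
  z <- matrix(rnorm(nrow(Q) * n), nrow(Q), n)
  y <- Matrix::solve(ch, z, system = "Lt")
  as.matrix(Matrix::solve(ch, y, system = "Pt"))
}

#' Barycentric projection of points onto mesh nodes
#'
#' @param mesh a `reef_mesh`.
#' @param points two-column matrix of planar coordinates.
#' @return Sparse matrix `A` (points x nodes) of barycentric weights; an
#'   error is raised for points outside every triangle.
#' @export
mesh_project <- function(mesh, points) {
  points <- as.matrix(points)
  loc <- mesh$loc; tri <- mesh$tri
  m <- nrow(tri)
  ax <- loc[tri[, 1], 1]; ay <- loc[tri[, 1], 2]
  d1x <- loc[tri[, 2], 1] - ax; d1y <- loc[tri[, 2], 2] - ay
  d2x <- loc[tri[, 3], 1] - ax; d2y <- loc[tri[, 3], 2] - ay
  den <- d1x * d2y - d2x * d1y
  ii <- jj <- ww <- numeric(0)
  for (k in seq_len(nrow(points))) {
    qx <- points[k, 1] - ax; qy <- points[k, 2] - ay
    l1 <- (qx * d2y - qy * d2x) / den
    l2 <- (d1x * qy - d1y * qx) / den
    inside <- which(l1 >= -1e-9 & l2 >= -1e-9 & l1 + l2 <= 1 + 1e-9)
    if (length(inside) == 0L) {
      stop_fmt("point %d falls outside the mesh", k)
    }
    t0 <- inside[1]
    w <- c(1 - l1[t0] - l2[t0], l1[t0], l2[t0])
    ii <- c(ii, rep(k, 3)); jj <- c(jj, tri[t0, ]); ww <- c(ww, w)
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = ww,
                       dims = c(nrow(points), nrow(loc)))
}
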