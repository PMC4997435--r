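#' Build a space-time tetrahedral mesh
#'
#' Delaunay-tetrahedralizes the scaled point cloud (x, y, c*t) of a sample
#' table, attaching the measured values to the vertices. One global mesh is
#' built per time scale; the linear shape functions on its tetrahedra define
#' the interpolant.
#'
#' Duplicate space-time locations (same site measured twice on a day) are
#' merged by their arithmetic mean with a warning. Tie configurations that a
#' site-by-day measurement grid produces in abundance (any two sites on any
#' two days form an exactly cocircular rectangle) are broken by a
#' deterministic, reproducible joggle of about 1e-10 of the cloud extent;
#' the joggled coordinates are stored as the mesh geometry so that all
#' weights derived from the mesh are mutually consistent. Tetrahedra with
#' volume at or below `volume_tolerance` (in scaled units cubed) are flagged
#' degenerate; queries landing in one are resolved through a neighbouring
#' tetrahedron.
#'
#' @param samples An [st_samples()] table.
#' @param scale A [time_scale()] (or bare positive number c).
#' @param volume_tolerance Degeneracy threshold for tetrahedron volumes.
#' @return An object of class `st_mesh`: vertices (scaled coordinates),
#'   vertex values, tetrahedra (vertex index quadruples), face-neighbour
#'   table, volumes and degeneracy flags, plus the time scale used.
#' @examples
#' s <- data.frame(site_id = letters[1:4], x = c(0, 1, 0, 0),
#'                 y = c(0, 0, 1, 0), t = c(1, 1, 1, 6), w = 1:4)
#' m <- build_mesh(st_samples(s), time_scale(1 / 5))
#' m$volumes # one tetrahedron, volume 1/6
#' @export
build_mesh <- function(samples, scale, volume_tolerance = 1e-12) {
  samples <- st_samples(samples)
  scale <- as_time_scale(scale)
  pts <- st_coords(samples, scale)
  key <- paste(pts[, 1], pts[, 2], pts[, 3], sep = "\r")
  dup <- duplicated(key)
  n_merged <- 0L
  if (any(dup)) {
    n_merged <- sum(dup)
    warning(sprintf(
      "%d duplicate space-time locations merged by arithmetic mean",
      n_merged), call. = FALSE)
    w <- tapply(samples$w, key, mean)
    keep <- !dup
    pts <- pts[keep, , drop = FALSE]
    values <- as.numeric(w[key[keep]])
    site_id <- samples$site_id[keep]
    tt <- samples$t[keep]
  } else {
    values <- samples$w
    site_id <- samples$site_id
    tt <- samples$t
  }
  if (nrow(pts) < 4L)
    stop("mesh construction needs at least 4 unique space-time points, got ",
         nrow(pts), call. = FALSE)
  dl <- delaunay3d_cpp(pts)
  vols <- tet_volumes(dl$points, dl$tets)
  structure(list(
    points = dl$points,
    values = values,
    site_id = site_id,
    t = tt,
    tets = dl$tets,
    neighbors = dl$neighbors,
    volumes = vols,
    degenerate = vols <= volume_tolerance,
    scale = scale,
    volume_tolerance = volume_tolerance,
    n_merged = n_merged
  ), class = "st_mesh")
}

#' @export
print.st_mesh <- function(x, ...) {
  cat(sprintf(
    "<st_mesh> %d vertices, %d tetrahedra (%d degenerate), %s\n",
    nrow(x$points), nrow(x$tets), sum(x$degenerate), x$scale$label))
  cat(sprintf("  hull volume (scaled units^3): %g\n", sum(x$volumes)))
  invisible(x)
}

# unsigned tetrahedron volumes |det|/6, vectorized over the tet table
tet_volumes <- function(points, tets) {
  a <- points[tets[, 1], , drop = FALSE]
  u <- points[tets[, 2], , drop = FALSE] - a
  v <- points[tets[, 3], , drop = FALSE] - a
  w <- points[tets[, 4], , drop = FALSE] - a
  cx <- v[, 2] * w[, 3] - v[, 3] * w[, 2]
  cy <- v[, 3] * w[, 1] - v[, 1] * w[, 3]
  cz <- v[, 1] * w[, 2] - v[, 2] * w[, 1]
  abs(u[, 1] * cx + u[, 2] * cy + u[, 3] * cz) / 6
}

#' Barycentric shape-function weights within one tetrahedron
#'
#' The linear shape functions of a tetrahedron assign a query point four
#' weights n_i = V_i / V, the volumes of the sub-tetrahedra obtained by
#' replacing vertex i with the query, over the volume of the whole
#' tetrahedron (signed consistently, so points outside get at least one
#' negative weight). The weights always sum to 1; as the query approaches
#' vertex i, n_i tends to 1 and the others to 0.
#'
#' @param tetra 4 x 3 numeric matrix of vertex coordinates (rows are
#'   vertices in scaled (x, y, c*t) space).
#' @param query Numeric length-3 query point in the same coordinates.
#' @param volume_tolerance Reject tetrahedra flatter than this.
#' @return Numeric vector `c(n1, n2, n3, n4)`.
#' @export
shape_weights <- function(tetra, query, volume_tolerance = 1e-12) {
  tetra <- as.matrix(tetra)
  stopifnot(nrow(tetra) == 4L, ncol(tetra) == 3L, length(query) == 3L)
  query <- as.numeric(query)
  det4 <- function(m) det(rbind(m[2, ] - m[1, ], m[3, ] - m[1, ],
                                m[4, ] - m[1, ]))
  V6 <- det4(tetra)
  if (abs(V6) / 6 <= volume_tolerance)
    stop("degenerate tetrahedron: volume below tolerance", call. = FALSE)
  n <- numeric(4)
  for (i in 1:4) {
    sub <- tetra
    sub[i, ] <- query
    n[i] <- det4(sub) / V6
  }
  names(n) <- paste0("n", 1:4)
  n
}

#' Locate queries in a space-time mesh
#'
#' Finds, for each query point, a tetrahedron containing it (all shape
#' weights >= -1e-9). Points outside the convex hull of the mesh vertices
#' get `NA` ("outside" is a value, not an error). Queries landing in a
#' degenerate sliver are resolved through a neighbouring tetrahedron when
#' one contains them.
#'
#' @param mesh An [build_mesh()] result.
#' @param queries Data frame with columns `x`, `y`, `t` (day index), or a
#'   3-column matrix of already-scaled (x, y, c*t) coordinates.
#' @param tol Containment tolerance on the barycentric weights.
#' @return List with integer vector `tet` (NA = outside) and an n x 4
#'   matrix `weights` of the shape-function weights in the located tet.
#' @export
locate_tetra <- function(mesh, queries, tol = 1e-9) {
  stopifnot(inherits(mesh, "st_mesh"))
  q <- query_coords(mesh, queries)
  res <- locate_weights_cpp(mesh$points, mesh$tets, mesh$neighbors,
                            mesh$degenerate, q, tol)
  tet <- res$tet
  tet[tet == 0L] <- NA_integer_
  list(tet = tet, weights = res$weights)
}

query_coords <- function(mesh, queries) {
  if (is.matrix(queries)) {
    stopifnot(ncol(queries) == 3L)
    return(queries)
  }
  if (!all(c("x", "y", "t") %in% names(queries)))
    stop("queries need columns x, y, t (or a 3-column scaled matrix)",
         call. = FALSE)
  st_coords(queries, mesh$scale)
}

#' Shape-function spatiotemporal interpolation
#'
#' Evaluates the piecewise-linear interpolant w(x, y, c*t) = sum n_i w_i
#' over the mesh: each query inside the convex hull gets the weighted sum
#' of the four vertex values of its containing tetrahedron. The result is
#' continuous across shared facets, reproduces the vertex values, and at
#' every interior point is a convex combination of the four surrounding
#' measurements.
#'
#' Queries outside the hull have no containing tetrahedron; the
#' `outside` policy decides between `"missing"` (NA, the default),
#' `"nearest"` (value of the nearest mesh vertex in scaled space) and
#' `"idw"` (inverse-distance weighting over the mesh vertices, a meshless
#' fallback for hull-boundary artifacts).
#'
#' @param mesh An [build_mesh()] result.
#' @param queries Data frame with `x`, `y`, `t` columns.
#' @param scale Optional; if supplied it must match the mesh's time scale
#'   (guards against interpolating with a mesh built under another c).
#' @param outside Out-of-hull policy, see Details.
#' @param idw_neighbors,idw_exponent IDW fallback configuration used when
#'   `outside = "idw"`.
#' @return Numeric vector of interpolated concentrations (NA where the
#'   policy leaves outside queries missing).
#' @export
sf_interpolate <- function(mesh, queries, scale = NULL,
                           outside = c("missing", "nearest", "idw"),
                           idw_neighbors = 3L, idw_exponent = 5) {
  stopifnot(inherits(mesh, "st_mesh"))
  outside <- match.arg(outside)
  if (!is.null(scale)) {
    scale <- as_time_scale(scale)
    if (abs(scale$c - mesh$scale$c) > 1e-12 * max(1, mesh$scale$c))
      stop(sprintf(
        "time-scale mismatch: mesh built with c=%g, queries use c=%g",
        mesh$scale$c, scale$c), call. = FALSE)
  }
  q <- query_coords(mesh, queries)
  nq <- nrow(q)
  out <- rep(NA_real_, nq)
  if (nq == 0L) return(out)
  # walk locality: process queries in lexicographic space-time order
  ord <- order(q[, 1], q[, 2], q[, 3])
  loc <- locate_weights_cpp(mesh$points, mesh$tets, mesh$neighbors,
                            mesh$degenerate, q[ord, , drop = FALSE], 1e-9)
  inside <- loc$tet > 0L
  if (any(!inside)) {
    # queries on the hull boundary can miss by the tie joggle (~1e-10 of
    # the extent); retry them with a boundary tolerance that still
    # excludes genuinely outside points
    re <- locate_weights_cpp(mesh$points, mesh$tets, mesh$neighbors,
                             mesh$degenerate,
                             q[ord[!inside], , drop = FALSE], 1e-7)
    if (any(re$tet > 0L)) {
      loc$tet[!inside][re$tet > 0L] <- re$tet[re$tet > 0L]
      loc$weights[which(!inside)[re$tet > 0L], ] <-
        re$weights[re$tet > 0L, , drop = FALSE]
      inside <- loc$tet > 0L
    }
  }
  if (any(inside)) {
    vi <- mesh$tets[loc$tet[inside], , drop = FALSE]
    vals <- matrix(mesh$values[vi], ncol = 4L)
    out[ord[inside]] <- rowSums(loc$weights[inside, , drop = FALSE] * vals)
  }
  if (any(!inside) && outside != "missing") {
    qo <- q[ord[!inside], , drop = FALSE]
    k <- if (outside == "nearest") 1L else
      min(as.integer(idw_neighbors), nrow(mesh$points))
    nn <- knn_cpp(mesh$points, qo, k)
    out[ord[!inside]] <- idw_from_nn(nn, mesh$values,
                                     p = if (outside == "nearest") 1 else
                                       idw_exponent)
  }
  out
}
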