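#' Dipole orientation field
#'
#' Per-vertex unit dipole-orientation vectors together with provenance: the
#' estimator that produced them and the surface they refer to.
#'
#' @param vectors V x 3 matrix of unit vectors.
#' @param method One of "downsampled_normals", "cortical_patch_statistics",
#'   "original_normals", "link_vectors", "variational".
#' @param surface One of "pial", "white", "combined".
#' @param parameters Optional named list of estimator parameters.
#' @return Object of class `orientation_field`.
#' @export
orientation_field <- function(vectors,
                              method = c("downsampled_normals",
                                         "cortical_patch_statistics",
                                         "original_normals", "link_vectors",
                                         "variational"),
                              surface = c("pial", "white", "combined"),
                              parameters = list()) {
  method <- match.arg(method)
  surface <- match.arg(surface)
  vectors <- as.matrix(vectors)
  dimnames(vectors) <- NULL
  stopifnot(ncol(vectors) == 3)
  n <- row_norms(vectors)
  if (any(abs(n - 1) > 1e-9)) stop("orientation vectors must have unit length")
  structure(list(vectors = vectors, method = method, surface = surface,
                 parameters = parameters, n = nrow(vectors)),
            class = "orientation_field")
}

#' @export
print.orientation_field <- function(x, ...) {
  cat(sprintf("orientation_field: %d vectors, method=%s, surface=%s\n",
              x$n, x$method, x$surface))
  invisible(x)
}

#' Downsampled surface normals orientation estimator
#'
#' At each vertex of the decimated mesh, the mean of the unit normals of its
#' adjacent faces, renormalized. This is the most common convention, but the
#' decimation distorts faces and hence biases the normals.
#'
#' @param decimated A decimated `triangle_mesh`.
#' @param surface Surface label for provenance.
#' @return An `orientation_field`.
#' @export
downsampled_normals <- function(decimated, surface = "pial") {
  orientation_field(vertex_normals(decimated), "downsampled_normals", surface)
}

#' Cortical patch statistics orientation estimator
#'
#' For each decimated vertex, averages the vertex normals of the original
#' (non-decimated) mesh over the vertices adjacent to the corresponding
#' original vertex (the 1-ring, excluding the center vertex itself), then
#' renormalizes.
#'
#' @param original The original `triangle_mesh`.
#' @param dmap The `decimation_map` relating decimated to original vertices.
#' @param surface Surface label for provenance.
#' @return An `orientation_field`.
#' @export
cortical_patch_statistics <- function(original, dmap, surface = "pial") {
  stopifnot(inherits(dmap, "decimation_map"),
            dmap$n_original == original$n_vertices)
  vn <- vertex_normals(original)
  adj <- vertex_adjacency(original)
  vec <- t(vapply(dmap$retained, function(r) {
    nb <- adj[[r]]
    if (!length(nb)) stop(sprintf("original vertex %d has no neighbors", r))
    colMeans(vn[nb, , drop = FALSE])
  }, numeric(3)))
  orientation_field(normalize_rows(vec, "patch-mean normal"),
                    "cortical_patch_statistics", surface)
}

#' Original surface normals orientation estimator
#'
#' Vertex normals computed on the original, non-decimated mesh, sampled at
#' the retained vertices; avoids decimation-induced distortion of the faces.
#'
#' @inheritParams cortical_patch_statistics
#' @return An `orientation_field`.
#' @export
original_normals <- function(original, dmap, surface = "pial") {
  stopifnot(inherits(dmap, "decimation_map"),
            dmap$n_original == original$n_vertices)
  vn <- vertex_normals(original)
  orientation_field(vn[dmap$retained, , drop = FALSE], "original_normals", surface)
}

#' Link vectors orientation estimator
#'
#' The unit vector from each pial vertex to the corresponding white-matter
#' vertex, `v_i = (w_i - p_i) / ||w_i - p_i||` — a direct approximation of
#' cortical-column orientation. The field is identical (up to sign) seen from
#' either surface: the white-surface field is the exact negation.
#'
#' @param pair A (decimated) `surface_pair`.
#' @param surface "pial" (default) or "white"; the white field is the
#'   negated pial field.
#' @return An `orientation_field`.
#' @export
link_vectors <- function(pair, surface = "pial") {
  stopifnot(inherits(pair, "surface_pair"))
  d <- pair$white$vertices - pair$pial$vertices
  n <- row_norms(d)
  bad <- which(n < 1e-12)
  if (length(bad)) stop(sprintf("coincident pial/white vertices at index %d", bad[1]))
  v <- d / n
  if (surface == "white") v <- -v
  orientation_field(v, "link_vectors", surface)
}

#' Variational vector field orientation estimator
#'
#' Constructs a field of correspondence vectors on the original surface pair
#' by projected gradient descent on the energy
#' \deqn{E(v) = \sum_i [\alpha(1 - v_i n_i^{pial}) + \alpha(1 - v_i n_i^{white})
#'   + \beta \sum_{j \in N(i)} (1 - v_i v_j)]}
#' which pushes vectors toward both surface normals (first two terms) and
#' toward mutual parallelism (neighbor term). Vectors are renormalized after
#' every step; the step size is found by backtracking halving, so the energy
#' is non-increasing. The field is initialized from the link vectors and, on
#' convergence, sampled at the retained decimated vertices.
#'
#' @param original_pair The original-resolution `surface_pair`.
#' @param dmap The `decimation_map`.
#' @param weights Length-2 numeric `(alpha, beta)`; both > 0 (beta = 0
#'   allowed, reducing to the per-vertex mean-normal closed form).
#' @param max_iter Maximum descent iterations.
#' @param tol Convergence threshold on the energy decrease.
#' @param surface Surface label for provenance.
#' @return An `orientation_field`; attribute `"converged"` records whether
#'   the energy decrease fell below `tol` within `max_iter` (a
#'   non-convergence is a warning, not an error).
#' @export
variational_field <- function(original_pair, dmap, weights = c(1, 0.5),
                              max_iter = 1000, tol = 1e-8, surface = "pial") {
  stopifnot(inherits(original_pair, "surface_pair"), inherits(dmap, "decimation_map"),
            weights[1] > 0, weights[2] >= 0)
  alpha <- weights[1]; beta <- weights[2]
  np <- vertex_normals(original_pair$pial)
  nw <- vertex_normals(original_pair$white)
  # descend toward the outward normals: flip the (inward) link initialization
  v <- -link_vectors(original_pair)$vectors
  adj <- vertex_adjacency(original_pair$pial)
  N <- original_pair$pial$n_vertices
  A <- Matrix::sparseMatrix(
    i = rep(seq_len(N), lengths(adj)), j = unlist(adj), x = 1, dims = c(N, N))
  deg <- lengths(adj)

  energy <- function(v) {
    sum(alpha * (1 - rowSums(v * np)) + alpha * (1 - rowSums(v * nw))) +
      beta * sum(deg - rowSums(v * as.matrix(A %*% v)))
  }
  grad <- function(v) -alpha * (np + nw) - 2 * beta * as.matrix(A %*% v)

  E <- energy(v)
  trace <- E
  converged <- FALSE
  step0 <- 0.1
  for (it in seq_len(max_iter)) {
    g <- grad(v)
    step <- step0
    improved <- FALSE
    while (step > 1e-12) {
      v_new <- normalize_rows(v - step * g, label = NULL)
      E_new <- energy(v_new)
      if (E_new < E) { improved <- TRUE; break }
      step <- step / 2
    }
    if (!improved) { converged <- TRUE; break }
    dE <- E - E_new
    v <- v_new; E <- E_new
    trace <- c(trace, E)
    if (dE < tol) { converged <- TRUE; break }
  }
  if (!converged) warning("variational field did not converge within max_iter")
  out <- orientation_field(v[dmap$retained, , drop = FALSE], "variational", surface,
                           parameters = list(alpha = alpha, beta = beta,
                                             max_iter = max_iter, tol = tol))
  attr(out, "converged") <- converged
  attr(out, "energy_trace") <- trace
  out
}

#' Angular difference between two vectors
#'
#' `atan2(||v1 x v2||, v1 . v2)` in degrees — numerically stable for nearly
#' parallel and nearly antiparallel vectors, symmetric in its arguments, and
#' independent of vector magnitudes.
#'
#' @param v1,v2 Nonzero 3-vectors, or n x 3 matrices (rowwise).
#' @return Angle(s) in degrees in \[0, 180\].
#' @export
angular_difference <- function(v1, v2) {
  if (is.null(dim(v1))) v1 <- matrix(v1, ncol = 3)
  if (is.null(dim(v2))) v2 <- matrix(v2, ncol = 3)
  if (any(row_norms(v1) < 1e-12) || any(row_norms(v2) < 1e-12)) {
    stop("angular_difference requires nonzero vectors")
  }
  cr <- cross3(v1, v2)
  ang <- atan2(row_norms(cr), rowSums(v1 * v2)) * 180 / pi
  if (nrow(v1) == 1) ang[1] else ang
}

#' Summary of angular differences between two orientation fields
#'
#' @param f1,f2 `orientation_field`s with equal vertex counts.
#' @param fold_to_90 Fold angles > 90 degrees to `180 - angle`, treating the
#'   0/180 sign ambiguity as irrelevant (off by default).
#' @param breaks Histogram bin width in degrees.
#' @return List with `angles` (per vertex), `mean`, `sd`, and `histogram`
#'   (counts per bin).
#' @export
field_difference_summary <- function(f1, f2, fold_to_90 = FALSE, breaks = 5) {
  stopifnot(inherits(f1, "orientation_field"), inherits(f2, "orientation_field"))
  if (f1$n != f2$n) stop("orientation fields have mismatched vertex counts")
  ang <- angular_difference(f1$vectors, f2$vectors)
  if (length(ang) == 1) ang <- rep(ang, f1$n)  # single-vertex edge case
  if (fold_to_90) ang <- pmin(ang, 180 - ang)
  h <- hist(ang, breaks = seq(0, 180, by = breaks), plot = FALSE)
  list(angles = ang, mean = mean(ang), sd = sd(ang),
       histogram = setNames(h$counts, head(h$breaks, -1)))
}

#' Rotate a vector onto a cone of given half-angle
#'
#' Returns a random point on the edge of the cone defined by the reference
#' vector and the angular distance: the output makes exactly `angle_deg`
#' with `v`, with the azimuth around the cone drawn uniformly.
#'
#' @param v Reference 3-vector (normalized silently if non-unit).
#' @param angle_deg Cone half-angle in degrees, in \[0, 180\].
#' @param seed Optional integer seed (draws from the current RNG stream when
#'   NULL).
#' @return A unit 3-vector.
#' @export
rotate_on_cone <- function(v, angle_deg, seed = NULL) {
  stopifnot(angle_deg >= 0, angle_deg <= 180)
  v <- v / sqrt(sum(v^2))
  if (angle_deg == 0) return(v)
  az <- if (is.null(seed)) runif(1, 0, 2 * pi) else
    withr::with_seed(seed, runif(1, 0, 2 * pi))
  rotate_on_cone_az(v, angle_deg, az)
}

# deterministic worker: given azimuth, rotate v by angle on its cone
rotate_on_cone_az <- function(v, angle_deg, az) {
  # orthonormal frame {e1, e2} perpendicular to v
  ref <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * v) * v
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(v[2] * e1[3] - v[3] * e1[2], v[3] * e1[1] - v[1] * e1[3],
          v[1] * e1[2] - v[2] * e1[1])
  th <- angle_deg * pi / 180
  out <- cos(th) * v + sin(th) * (cos(az) * e1 + sin(az) * e2)
  out / sqrt(sum(out^2))
}

#' Rotate a whole orientation field on per-vertex cones
#'
#' Applies [rotate_on_cone()] to every vector of a field with independent
#' uniform azimuths — the perturbation model used to build rotated candidate
#' orientation models in the simulation experiments.
#'
#' @param field An `orientation_field`.
#' @param angle_deg Rotation angle (degrees).
#' @param seed Integer seed for the azimuth draws.
#' @return An `orientation_field` with the same method/surface tags and a
#'   `rotation_deg` entry in `parameters`.
#' @export
rotate_field_on_cone <- function(field, angle_deg, seed) {
  stopifnot(inherits(field, "orientation_field"))
  az <- withr::with_seed(seed, runif(field$n, 0, 2 * pi))
  vec <- t(vapply(seq_len(field$n), function(i) {
    rotate_on_cone_az(field$vectors[i, ], angle_deg, az[i])
  }, numeric(3)))
  out <- orientation_field(vec, field$method, field$surface,
                           parameters = c(field$parameters,
                                          list(rotation_deg = angle_deg, seed = seed)))
  out
}
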