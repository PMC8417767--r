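#' Icosphere mesh
#'
#' Geodesic sphere obtained by repeated 4-way subdivision of an icosahedron
#' with projection onto the sphere. Faces are wound so normals point outward.
#'
#' @param subdivisions Number of subdivision rounds (0 = icosahedron).
#' @param radius Sphere radius (mm).
#' @return A `triangle_mesh` with `10 * 4^subdivisions + 2` vertices.
#' @export
icosphere <- function(subdivisions = 3, radius = 1) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(1 + phi^2)
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    nv <- nrow(v)
    mid <- new.env(hash = TRUE)
    midpoint <- function(a, b) {
      key <- sprintf("%d_%d", min(a, b), max(a, b))
      if (!is.null(id <- mid[[key]])) return(id)
      p <- (v[a, ] + v[b, ]) / 2
      p <- p / sqrt(sum(p^2))
      v <<- rbind(v, p)
      mid[[key]] <- nrow(v)
      nrow(v)
    }
    newf <- matrix(0L, nrow(f) * 4, 3)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; cc <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      newf[(i - 1) * 4 + 1:4, ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                         c(cc, ca, bc), c(ab, bc, ca))
    }
    f <- newf
  }
  triangle_mesh(v * radius, f)
}

# Real spherical harmonics Y_lm evaluated at unit directions (n x 3).
# Returns an n x (sum over l of 2l+1) matrix for l = 1..lmax.
real_sph_harm <- function(dirs, lmax) {
  theta <- acos(pmin(pmax(dirs[, 3], -1), 1))       # polar angle
  phi <- atan2(dirs[, 2], dirs[, 1])
  ct <- cos(theta)
  out <- NULL
  for (l in seq_len(lmax)) {
    P <- pracma::legendre(l, ct)                    # (l+1) x n, m = 0..l
    for (m in 0:l) {
      norm <- sqrt((2 * l + 1) / (4 * pi) * factorial(l - m) / factorial(l + m))
      if (m == 0) {
        out <- cbind(out, norm * P[1, ])
      } else {
        out <- cbind(out, sqrt(2) * norm * P[m + 1, ] * cos(m * phi),
                          sqrt(2) * norm * P[m + 1, ] * sin(m * phi))
      }
    }
  }
  out
}

# Laplacian-style smoothing of a per-vertex vector field (mean over 1-ring,
# repeated), renormalized to unit length.
smooth_field <- function(mesh, field, iterations = 3) {
  adj <- vertex_adjacency(mesh)
  for (it in seq_len(iterations)) {
    field <- t(vapply(seq_len(mesh$n_vertices), function(i) {
      colMeans(field[c(i, adj[[i]]), , drop = FALSE])
    }, numeric(3)))
    field <- normalize_rows(field, label = "smoothed normal")
  }
  field
}

#' Synthetic folded cortical surface pair
#'
#' Emulates a pial/white surface pair with one-to-one vertex correspondence:
#' the pial surface is an icosphere of the given radius, radially displaced by
#' a band-limited random spherical-harmonic field (degrees 1..`fold_degree`,
#' RMS amplitude `fold_amplitude_mm`); the white surface is the pial surface
#' displaced inward along the smoothed vertex-normal field by `thickness_mm`.
#' `fold_amplitude_mm = 0` yields concentric spheres — the analytic-limit
#' fixture in which all orientation estimators agree with the radial
#' direction.
#'
#' @param subdivisions Icosphere subdivision level (default 4, ~2562 vertices).
#' @param fold_amplitude_mm RMS radial displacement of the folding field (mm).
#' @param fold_degree Maximum spherical-harmonic degree of the folding field.
#' @param thickness_mm Nominal cortical thickness (mm).
#' @param radius_mm Mean pial radius (mm).
#' @param seed Integer seed for the folding coefficients.
#' @return A `surface_pair` at original (non-decimated) resolution.
#' @export
make_cortical_pair <- function(subdivisions = 4, fold_amplitude_mm = 3,
                               fold_degree = 8, thickness_mm = 2.5,
                               radius_mm = 70, seed = 1) {
  stopifnot(subdivisions >= 2, thickness_mm > 0, fold_amplitude_mm >= 0)
  sph <- icosphere(subdivisions, radius = 1)
  dirs <- sph$vertices
  r <- rep(radius_mm, nrow(dirs))
  if (fold_amplitude_mm > 0) {
    B <- real_sph_harm(dirs, fold_degree)
    coef <- withr::with_seed(seed, rnorm(ncol(B)))
    disp <- as.numeric(B %*% coef)
    disp <- disp * fold_amplitude_mm / sqrt(mean(disp^2))
    r <- r + disp
  }
  pial <- triangle_mesh(dirs * r, sph$faces)
  nrm <- smooth_field(pial, vertex_normals(pial), iterations = 3)
  white_v <- pial$vertices - thickness_mm * nrm
  white <- triangle_mesh(white_v, sph$faces, validate = FALSE)
  # inward displacement beyond the local curvature radius turns the white
  # surface inside out: its outward-wound normals then face the centroid
  wc <- (white_v[sph$faces[, 1], ] + white_v[sph$faces[, 2], ] +
           white_v[sph$faces[, 3], ]) / 3
  outward <- rowSums(face_normals(white) * sweep(wc, 2, colMeans(white_v)))
  if (any(outward <= 0) || any(row_norms(white_v) >= row_norms(pial$vertices))) {
    stop("white surface self-intersects: reduce thickness_mm or fold_amplitude_mm")
  }
  surface_pair(pial, white)
}

#' Synthetic MEG helmet sensor array
#'
#' Quasi-uniform (Fibonacci lattice) sensor coverage of the upper portion of
#' a sphere, emulating a 275-channel axial-gradiometer whole-head system.
#' Sensitive axes are radial; fiducials sit at canonical nasion/LPA/RPA
#' points on the sphere equator.
#'
#' @param n_sensors Number of channels.
#' @param radius_mm Helmet radius (mm).
#' @param kind "axial_gradiometer" or "magnetometer".
#' @param baseline_mm Gradiometer baseline (mm).
#' @return A `sensor_array`.
#' @export
make_helmet <- function(n_sensors = 275, radius_mm = 110,
                        kind = "axial_gradiometer", baseline_mm = 50) {
  stopifnot(n_sensors >= 4)
  # Fibonacci lattice over the spherical cap z/r in (-1/3, 1]: 2/3 of the sphere
  i <- seq_len(n_sensors) - 0.5
  z <- 1 - (i / n_sensors) * (4 / 3)          # from 1 down to -1/3
  phi <- pi * (1 + sqrt(5)) * i
  rho <- sqrt(pmax(0, 1 - z^2))
  dirs <- cbind(rho * cos(phi), rho * sin(phi), z)
  fid <- rbind(nasion = c(0, radius_mm, 0),
               LPA = c(-radius_mm, 0, 0),
               RPA = c(radius_mm, 0, 0))
  sensor_array(positions = dirs * radius_mm, orientations = dirs,
               kind = kind, baseline_mm = baseline_mm, fiducials = fid)
}
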