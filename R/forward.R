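#' MEG sensor array
#'
#' @param positions S x 3 matrix of sensor (pickup coil) positions, mm.
#' @param orientations S x 3 matrix of unit sensitive-axis vectors.
#' @param kind "magnetometer" or "axial_gradiometer".
#' @param baseline_mm Gradiometer baseline (mm; outer coil sits at
#'   `position + baseline * orientation`).
#' @param fiducials 3 x 3 matrix with rows nasion, LPA, RPA (mm).
#' @return Object of class `sensor_array`.
#' @export
sensor_array <- function(positions, orientations,
                         kind = c("axial_gradiometer", "magnetometer"),
                         baseline_mm = 50, fiducials = NULL) {
  kind <- match.arg(kind)
  positions <- as.matrix(positions)
  orientations <- normalize_rows(as.matrix(orientations), label = "sensor axis")
  stopifnot(ncol(positions) == 3, nrow(positions) == nrow(orientations))
  if (is.null(fiducials)) {
    r <- max(row_norms(positions))
    fiducials <- rbind(nasion = c(0, r, 0), LPA = c(-r, 0, 0), RPA = c(r, 0, 0))
  }
  structure(list(positions = positions, orientations = orientations,
                 kind = kind, baseline_mm = baseline_mm,
                 fiducials = as.matrix(fiducials),
                 n_sensors = nrow(positions)),
            class = "sensor_array")
}

#' @export
print.sensor_array <- function(x, ...) {
  cat(sprintf("sensor_array: %d %s channels%s\n", x$n_sensors, x$kind,
              if (x$kind == "axial_gradiometer")
                sprintf(" (baseline %g mm)", x$baseline_mm) else ""))
  invisible(x)
}

# Magnetic field of current dipoles in a homogeneous conducting sphere
# (Sarvas closed form), evaluated at field points strictly outside the
# conductor. positions/fieldpoints in mm relative to lab frame, center the
# sphere center (mm), moments in nA*m; returns fT, rows = field points,
# one block per dipole handled by the callers.
#
# B(r) = mu0/(4*pi*F^2) * (F * (Q x r0) - ((Q x r0) . r) * gradF)
# with r0 the dipole location, a = r - r0, F = a*(r*a + r^2 - r0.r),
# gradF = (a^2/r + (a.r)/a + 2a + 2r)*r - (a + 2r + (a.r)/a)*r0.
sarvas_field <- function(dipole_pos_mm, moment_nAm, field_pos_mm, center_mm) {
  r0 <- matrix((dipole_pos_mm - center_mm) * 1e-3, 1)          # 1 x 3, meters
  q <- matrix(moment_nAm * 1e-9, 1)                            # A*m
  r <- sweep(field_pos_mm, 2, center_mm) * 1e-3                # n x 3
  a_vec <- r - r0[rep(1, nrow(r)), ]
  a <- row_norms(a_vec)
  rn <- row_norms(r)
  r0_dot_r <- as.numeric(r %*% t(r0))
  a_dot_r <- rowSums(a_vec * r)
  F <- a * (rn * a + rn^2 - r0_dot_r)
  gF <- (a^2 / rn + a_dot_r / a + 2 * a + 2 * rn) * r -
        (a + 2 * rn + a_dot_r / a) * r0[rep(1, nrow(r)), ]
  qxr0 <- cross3(q, r0)[rep(1, nrow(r)), ]
  B <- 1e-7 * (F * qxr0 - rowSums(qxr0 * r) * gF) / F^2        # Tesla
  B * 1e15                                                     # fT
}

#' Lead field of oriented dipoles in a spherical conductor
#'
#' Computes the channels x sources gain matrix for unit dipoles (1 nA·m along
#' each source orientation) in a homogeneous conducting sphere, projected
#' onto each sensor's sensitive axis. Axial gradiometers measure the field
#' difference between the pickup coil and a second coil displaced by the
#' baseline along the sensitive axis. Output units: fT per nA·m.
#'
#' @param positions V x 3 source positions (mm), strictly inside the sphere.
#' @param orientations V x 3 unit source orientations.
#' @param sensors A `sensor_array`; all coils strictly outside the sources'
#'   bounding sphere.
#' @param sphere_center Conductor sphere center (mm, length-3).
#' @return Object of class `lead_field` with `gain` (S x V, fT/nA·m),
#'   `source_positions`, `source_orientations`, `sphere_center`.
#' @export
sphere_leadfield <- function(positions, orientations, sensors, sphere_center) {
  basis <- sphere_leadfield_basis(positions, sensors, sphere_center)
  orient_leadfield(basis, orientations)
}

#' Orientation-free lead field basis
#'
#' Gains of three orthogonal unit dipoles (x, y, z; 1 nA·m) at every source
#' position. The lead field for any orientation field is then a linear
#' combination of the three (see [orient_leadfield()]), which makes sweeping
#' over many candidate orientation models cheap.
#'
#' @inheritParams sphere_leadfield
#' @return Object of class `leadfield_basis`: list of three S x V gain
#'   matrices `gx`, `gy`, `gz` plus geometry.
#' @export
sphere_leadfield_basis <- function(positions, sensors, sphere_center) {
  positions <- as.matrix(positions)
  stopifnot(inherits(sensors, "sensor_array"), length(sphere_center) == 3)
  src_r <- row_norms(sweep(positions, 2, sphere_center))
  coils <- sensors$positions
  if (sensors$kind == "axial_gradiometer") {
    coils <- rbind(coils, sensors$positions + sensors$baseline_mm * sensors$orientations)
  }
  coil_r <- row_norms(sweep(coils, 2, sphere_center))
  if (any(coil_r <= max(src_r))) {
    stop("a sensor coil lies inside the bounding sphere of the sources")
  }
  V <- nrow(positions); S <- sensors$n_sensors
  gx <- gy <- gz <- matrix(0, S, V)
  ex <- c(1, 0, 0); ey <- c(0, 1, 0); ez <- c(0, 0, 1)
  proj <- function(B) {
    b1 <- rowSums(B[seq_len(S), , drop = FALSE] * sensors$orientations)
    if (sensors$kind == "axial_gradiometer") {
      b2 <- rowSums(B[S + seq_len(S), , drop = FALSE] * sensors$orientations)
      b1 - b2
    } else b1
  }
  for (i in seq_len(V)) {
    gx[, i] <- proj(sarvas_field(positions[i, ], ex, coils, sphere_center))
    gy[, i] <- proj(sarvas_field(positions[i, ], ey, coils, sphere_center))
    gz[, i] <- proj(sarvas_field(positions[i, ], ez, coils, sphere_center))
  }
  structure(list(gx = gx, gy = gy, gz = gz,
                 source_positions = positions,
                 sphere_center = as.numeric(sphere_center),
                 sensors = sensors),
            class = "leadfield_basis")
}

#' Orient a lead field basis with a dipole orientation field
#'
#' @param basis A `leadfield_basis`.
#' @param orientations V x 3 unit orientations (or an `orientation_field`).
#' @return A `lead_field`.
#' @export
orient_leadfield <- function(basis, orientations) {
  stopifnot(inherits(basis, "leadfield_basis"))
  if (inherits(orientations, "orientation_field")) orientations <- orientations$vectors
  orientations <- as.matrix(orientations)
  stopifnot(nrow(orientations) == ncol(basis$gx))
  gain <- sweep(basis$gx, 2, orientations[, 1], `*`) +
          sweep(basis$gy, 2, orientations[, 2], `*`) +
          sweep(basis$gz, 2, orientations[, 3], `*`)
  structure(list(gain = gain,
                 source_positions = basis$source_positions,
                 source_orientations = orientations,
                 sphere_center = basis$sphere_center),
            class = "lead_field")
}

#' @export
print.lead_field <- function(x, ...) {
  cat(sprintf("lead_field: %d channels x %d sources (fT per nA*m)\n",
              nrow(x$gain), ncol(x$gain)))
  invisible(x)
}

#' Fit a sphere center to mesh vertices by least squares
#'
#' Algebraic (Coope) least-squares sphere fit; used to place the conductor
#' sphere for the forward model.
#'
#' @param vertices N x 3 matrix (mm).
#' @return Length-3 center (mm).
#' @export
fit_sphere_center <- function(vertices) {
  A <- cbind(2 * vertices, 1)
  b <- rowSums(vertices^2)
  sol <- qr.solve(A, b)
  sol[1:3]
}

#' Apply a random rigid co-registration error to a sensor array
#'
#' Emulates between-session co-registration error: one rigid transform —
#' a translation of the given magnitude in a uniformly random direction,
#' composed with a rotation of the given magnitude about a uniformly random
#' axis through the fiducial centroid — applied to sensor positions,
#' orientations, and fiducials. The equivalent of perturbing the fiducial
#' coils and re-co-registering.
#'
#' @param sensors A `sensor_array`.
#' @param translation_mm Translation magnitude (mm).
#' @param rotation_deg Rotation magnitude (degrees).
#' @param seed Integer seed for the random direction/axis.
#' @return Transformed `sensor_array`; the transform is attached as
#'   attribute `"transform"` (list with `rotation`, `translation`, `pivot`).
#' @export
apply_coregistration_error <- function(sensors, translation_mm, rotation_deg, seed) {
  stopifnot(translation_mm >= 0, rotation_deg >= 0)
  if (translation_mm == 0 && rotation_deg == 0) {
    attr(sensors, "transform") <- list(rotation = diag(3), translation = c(0, 0, 0),
                                       pivot = colMeans(sensors$fiducials))
    return(sensors)
  }
  rnd <- withr::with_seed(seed, {
    u <- rnorm(3); ax <- rnorm(3)
    list(dir = u / sqrt(sum(u^2)), axis = ax / sqrt(sum(ax^2)))
  })
  R <- rotation_matrix(rnd$axis, rotation_deg * pi / 180)
  pivot <- colMeans(sensors$fiducials)
  tr <- translation_mm * rnd$dir
  xf <- function(p) sweep(sweep(p, 2, pivot) %*% t(R), 2, pivot + tr, `+`)
  out <- sensor_array(positions = xf(sensors$positions),
                      orientations = sensors$orientations %*% t(R),
                      kind = sensors$kind, baseline_mm = sensors$baseline_mm,
                      fiducials = xf(sensors$fiducials))
  attr(out, "transform") <- list(rotation = R, translation = tr, pivot = pivot)
  out
}
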