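#' Construct an axial-gradiometer sensor array on a spherical cap
#'
#' Places `n` first-order axial gradiometers quasi-uniformly (Fibonacci
#' lattice) on a spherical cap above the head, with radial coil
#' orientations. Each gradiometer measures the radial field difference
#' between a pickup coil and a second coil offset outward by `baseline`.
#'
#' @param n number of channels (default 125).
#' @param head_radius radius of the spherically symmetric conductor in
#'   meters (default 0.09).
#' @param standoff distance from scalp sphere to the pickup coils, meters
#'   (default 0.02).
#' @param baseline gradiometer baseline in meters (default 0.05).
#' @param cap_angle polar half-angle of the sensor cap in radians
#'   (default `pi / 2.4`, i.e. a 75 degree cap).
#' @param coil_diameter coil diameter, meters; metadata only (the forward
#'   model uses the point-magnetometer approximation).
#' @return An object of class `sensor_array` with `channel_names`,
#'   `positions` (n x 3, m), `orientations` (n x 3 radial unit vectors),
#'   `baseline`, `head_radius` and `n_channels`.
#' @export
#' @examples
#' arr <- make_sensor_array(125)
#' range(sqrt(rowSums(arr$positions^2)))  # all at head_radius + standoff
make_sensor_array <- function(n = 125L, head_radius = 0.09, standoff = 0.02,
                              baseline = 0.05, cap_angle = pi / 2.4,
                              coil_diameter = 0.0155) {
  n <- as.integer(n)
  if (n < 1L) stop("`n` must be at least 1")
  if (head_radius <= 0 || standoff <= 0 || baseline <= 0) {
    stop("non-physical radii: head_radius, standoff and baseline must be > 0")
  }
  r <- head_radius + standoff
  if (n == 1L) {
    theta <- 0
    phi <- 0
  } else {
    u <- (seq_len(n) - 0.5) / n
    theta <- acos(1 - u * (1 - cos(cap_angle)))
    golden <- pi * (3 - sqrt(5))
    phi <- (seq_len(n) - 1) * golden
  }
  pos <- r * cbind(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
  ori <- pos / sqrt(rowSums(pos^2))
  structure(list(channel_names = sprintf("MEG%03d", seq_len(n)),
                 positions = pos, orientations = ori, baseline = baseline,
                 head_radius = head_radius, standoff = standoff,
                 cap_angle = cap_angle, coil_diameter = coil_diameter,
                 n_channels = n),
            class = "sensor_array")
}

#' @export
print.sensor_array <- function(x, ...) {
  cat("<sensor_array>", x$n_channels, "axial gradiometers, baseline",
      x$baseline * 1000, "mm, conductor radius", x$head_radius * 1000,
      "mm\n")
  invisible(x)
}

#' Default ROI centers for the six-region mismatch network
#'
#' Left/right mirror triplets for primary auditory cortex (A1), superior
#' temporal gyrus (STG) and inferior frontal gyrus (IFG), expressed in the
#' single-sphere head frame (meters). These are plausible template
#' positions for the synthetic geometry, configurable in every function
#' that takes ROI centers; they are not a co-registered atlas.
#'
#' @return A 6 x 3 matrix with rownames `lA1, rA1, lSTG, rSTG, lIFG, rIFG`.
#' @export
default_roi_centers <- function() {
  m <- rbind(
    lA1  = c(-0.048, -0.022, 0.028),
    rA1  = c( 0.048, -0.022, 0.028),
    lSTG = c(-0.064, -0.028, 0.022),
    rSTG = c( 0.064, -0.028, 0.022),
    lIFG = c(-0.055,  0.040, 0.022),
    rIFG = c( 0.055,  0.040, 0.022))
  colnames(m) <- c("x", "y", "z")
  m
}

#' Construct a labeled source grid inside the conductor sphere
#'
#' A regular cubic grid clipped to the sphere interior; voxels within
#' `roi_radius` of an ROI center receive that ROI's label (nearest center
#' wins if spheres overlap).
#'
#' @param spacing grid spacing in meters (default 0.01).
#' @param roi_centers matrix of ROI centers with rownames, as from
#'   [default_roi_centers()].
#' @param roi_radius labeling radius around each center, meters
#'   (default 0.013).
#' @param radius outer radius of the grid, meters; must be strictly inside
#'   the conductor (default 0.078).
#' @return An object of class `source_grid` with `positions` (m x 3),
#'   `roi_labels` (character, `"none"` outside ROIs), `spacing`.
#' @export
make_source_grid <- function(spacing = 0.01, roi_centers = default_roi_centers(),
                             roi_radius = 0.013, radius = 0.078) {
  if (spacing <= 0) stop("`spacing` must be > 0")
  if (any(sqrt(rowSums(roi_centers^2)) >= radius)) {
    stop("all ROI centers must lie strictly inside the grid radius")
  }
  k <- floor(radius / spacing)
  ax <- (-k:k) * spacing
  pos <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  pos <- pos[sqrt(rowSums(pos^2)) < radius, , drop = FALSE]
  labels <- rep("none", nrow(pos))
  d2 <- sapply(seq_len(nrow(roi_centers)), function(i) {
    rowSums(sweep(pos, 2, roi_centers[i, ])^2)
  })
  nearest <- max.col(-d2, ties.method = "first")
  within <- d2[cbind(seq_len(nrow(pos)), nearest)] <= roi_radius^2
  labels[within] <- rownames(roi_centers)[nearest[within]]
  missing <- setdiff(rownames(roi_centers), unique(labels))
  if (length(missing)) {
    stop("empty ROI(s): ", paste(missing, collapse = ", "),
         " — increase roi_radius relative to the grid spacing")
  }
  structure(list(positions = pos, roi_labels = labels, spacing = spacing,
                 roi_centers = roi_centers, roi_radius = roi_radius,
                 radius = radius),
            class = "source_grid")
}

#' @export
print.source_grid <- function(x, ...) {
  cat("<source_grid>", nrow(x$positions), "voxels, spacing",
      x$spacing * 1000, "mm\n")
  tab <- table(x$roi_labels[x$roi_labels != "none"])
  cat("  ROI voxels:", paste(names(tab), tab, sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

#' Magnetic field of a current dipole in a homogeneous conducting sphere
#'
#' Closed-form (Sarvas) field of a current dipole inside a spherically
#' symmetric conductor centered at the origin, evaluated at points outside
#' the sphere. Radial dipole moments produce no external field.
#'
#' @param sensors matrix of field points (n x 3, m), outside the sphere.
#' @param position dipole position (length-3, m), strictly inside the
#'   sphere and away from its center.
#' @param moment dipole moment vector (length-3, A m).
#' @return n x 3 matrix of magnetic field vectors in tesla.
#' @export
sarvas_field <- function(sensors, position, moment) {
  if (is.null(dim(sensors))) sensors <- matrix(sensors, ncol = 3L)
  r0 <- as.numeric(position)
  q <- as.numeric(moment)
  a <- sweep(sensors, 2, r0)           # r - r0
  an <- sqrt(rowSums(a^2))
  rn <- sqrt(rowSums(sensors^2))
  ar <- rowSums(a * sensors)           # a . r
  r0r <- as.vector(sensors %*% r0)     # r0 . r
  Fv <- an * (rn * an + rn^2 - r0r)
  cF <- an^2 / rn + ar / an + 2 * an + 2 * rn
  cR0 <- an + 2 * rn + ar / an
  gradF <- sensors * cF - outer(cR0, r0)
  qxr0 <- cross3(q, r0)                # 1 x 3
  qxr0_r <- as.vector(sensors %*% as.numeric(qxr0))
  1e-7 / Fv^2 * (Fv * matrix(qxr0, nrow(sensors), 3L, byrow = TRUE) -
                   gradF * qxr0_r)
}

# Orthonormal tangential basis at a source position (columns e1, e2,
# both perpendicular to the radial direction).
tangential_basis <- function(position) {
  rn <- unit(as.numeric(position))
  ref <- if (abs(rn[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- unit(as.numeric(cross3(ref, rn)))
  e2 <- as.numeric(cross3(rn, e1))
  cbind(e1, e2)
}

#' Lead field of a source-grid vertex for an axial-gradiometer array
#'
#' Returns the channels x 2 matrix mapping the two orthonormal tangential
#' unit moments at `position` to the measured gradiometer signals
#' (pickup-coil field minus field at the coil offset by the baseline along
#' the coil orientation, both projected on the coil orientation). The
#' radial moment is magnetically silent in the spherical conductor, so two
#' tangential columns form a complete basis.
#'
#' @param position source position (length-3, m), strictly inside the
#'   conductor and not at its center.
#' @param array a [make_sensor_array()] object.
#' @return channels x 2 numeric matrix in tesla per ampere-meter, with the
#'   tangential basis attached as attribute `"basis"` (3 x 2).
#' @export
dipole_leadfield <- function(position, array) {
  stopifnot(inherits(array, "sensor_array"))
  r0 <- as.numeric(position)
  rn <- sqrt(sum(r0^2))
  if (rn >= array$head_radius) stop("source position outside the conductor")
  if (rn < 1e-6) stop("source position at the sphere center is degenerate")
  basis <- tangential_basis(r0)
  p1 <- array$positions
  p2 <- array$positions + array$baseline * array$orientations
  L <- sapply(1:2, function(j) {
    q <- basis[, j]
    b1 <- rowSums(sarvas_field(p1, r0, q) * array$orientations)
    b2 <- rowSums(sarvas_field(p2, r0, q) * array$orientations)
    b1 - b2
  })
  if (!all(is.finite(L))) stop("non-finite leadfield entries")
  dimnames(L) <- list(array$channel_names, c("t1", "t2"))
  attr(L, "basis") <- basis
  L
}

#' Voxel centroid of a region of interest
#'
#' The ROI voxel nearest to all other ROI voxels (minimal summed Euclidean
#' distance); ties resolved to the lowest voxel index.
#'
#' @param grid a [make_source_grid()] object.
#' @param roi ROI label.
#' @return Index (into `grid$positions`) of the centroid voxel.
#' @export
roi_centroid <- function(grid, roi) {
  idx <- which(grid$roi_labels == roi)
  if (!length(idx)) stop("empty ROI: ", roi)
  if (length(idx) == 1L) return(idx)
  P <- grid$positions[idx, , drop = FALSE]
  D <- as.matrix(stats::dist(P))
  idx[which.min(rowSums(D))]
}
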