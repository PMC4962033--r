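#' Pack compartment centres in a box
#'
#' Deterministic max-min placement: points start at seeded uniform positions
#' and are iteratively pushed away from their nearest neighbour, clamped to
#' the box. Used to place compartment cores far enough apart that inflated
#' cores stay disjoint.
#'
#' @param n number of points
#' @param lower,upper length-3 box corners
#' @param n_iter repulsion iterations
#' @param seed integer seed
#' @return n x 3 matrix with attribute `min_sep` (achieved minimum pairwise
#'   distance)
#' @export
pack_centers <- function(n, lower, upper, n_iter = 600, seed = 1L) {
  span <- upper - lower
  x <- with_seed(seed, matrix(stats::runif(3 * n), n, 3)) *
    matrix(span, n, 3, byrow = TRUE) + matrix(lower, n, 3, byrow = TRUE)
  if (n == 1) return(structure(x, min_sep = Inf))
  step <- 0.08 * max(span)
  for (it in seq_len(n_iter)) {
    d <- as.matrix(stats::dist(x))
    diag(d) <- Inf
    nn <- apply(d, 1, which.min)
    v <- x - x[nn, , drop = FALSE]
    len <- sqrt(rowSums(v^2))
    len[len == 0] <- 1
    x <- x + step * v / len
    x <- pmin(pmax(x, matrix(lower, n, 3, byrow = TRUE)),
              matrix(upper, n, 3, byrow = TRUE))
    step <- step * 0.992
  }
  d <- as.matrix(stats::dist(x)); diag(d) <- Inf
  structure(x, min_sep = min(d))
}

# Superposed radial displacement of all compartment cores at reference
# positions X (voxel coords, n x 3). Each core of radius r expands uniformly
# by linear factor s about its centre; outside the core the displacement
# continues as the volume-preserving radial map rho^3 = r^3 + (s^3-1) r1^3,
# so all of a compartment's volume change is carried by its core and the
# tail is divergence-free.
phantom_u <- function(X, centers, radii, svec) {
  U <- matrix(0, nrow(X), 3)
  for (k in seq_len(nrow(centers))) {
    s <- svec[k]
    if (abs(s - 1) < 1e-12) next
    dx <- X[, 1] - centers[k, 1]
    dy <- X[, 2] - centers[k, 2]
    dz <- X[, 3] - centers[k, 3]
    r2 <- dx * dx + dy * dy + dz * dz
    r1 <- radii[k]
    A <- (s^3 - 1) * r1^3
    fac <- rep(s - 1, length(r2))
    # exact (1+q)^(1/3)-1 near the core, 3-term series in q = A/r^3 in the
    # far field where |q| < 0.08 (error < 1e-5)
    far <- r2 >= (2.5 * r1)^2
    mid <- !far & r2 >= r1 * r1
    if (any(mid)) {
      r3 <- r2[mid] * sqrt(r2[mid])
      fac[mid] <- ((r3 + A) / r3)^(1 / 3) - 1
    }
    if (any(far)) {
      q <- A / (r2[far] * sqrt(r2[far]))
      fac[far] <- q * (1 / 3 + q * (-1 / 9 + q * (5 / 81)))
    }
    U[, 1] <- U[, 1] + fac * dx
    U[, 2] <- U[, 2] + fac * dy
    U[, 3] <- U[, 3] + fac * dz
  }
  U
}

phantom_forward <- function(X, centers, radii, svec) {
  X + phantom_u(X, centers, radii, svec)
}

# Invert y = x + u(x) by damped fixed-point iteration (|grad u| << 1).
phantom_inverse <- function(Y, centers, radii, svec, n_iter = 2L, refine = 5L) {
  X <- Y - phantom_u(Y, centers, radii, svec)
  for (i in seq_len(n_iter - 1L))
    X <- Y - phantom_u(X, centers, radii, svec)
  # extra sharpening where displacement is large (inside/near cores); in the
  # far field |grad u| is tiny and two sweeps already converge
  U <- Y - X
  big <- which(rowSums(U^2) > 0.16)
  if (length(big)) {
    Xb <- X[big, , drop = FALSE]; Yb <- Y[big, , drop = FALSE]
    for (i in seq_len(refine))
      Xb <- Yb - phantom_u(Xb, centers, radii, svec)
    X[big, ] <- Xb
  }
  X
}

#' Render a 4D synthetic lung image series with ground truth
#'
#' Produces one 3D volume per frame of the respiratory cycle by analytically
#' warping a band-limited speckle reference (frame 1, end expiration). Each
#' endpoint's compartment is a spherical core that dilates uniformly so its
#' volume change equals the regional volume change of the mechanics model;
#' outside the core the radial warp is volume-preserving, so the texture is
#' continuous everywhere and each region's entire volume change is carried
#' by its core. The airway lumen is burned into the reference at a distinct
#' low intensity (and is warped along with the tissue) so that flood-fill
#' segmentation can be exercised on the rendered frames.
#'
#' @param tree the `airway_tree` whose endpoint tips are the compartment
#'   centres (positions in micrometres)
#' @param mechanics result of [simulate_compartments()] for `tree`
#' @param grid_shape integer length-3 voxel grid dimensions
#' @param voxel_spacing isotropic voxel spacing (micrometres)
#' @param texture_seed seed for the speckle texture
#' @param core_radius compartment core radius in voxels (scalar or one per
#'   endpoint)
#' @param texture_corr speckle correlation length (voxels)
#' @param lumen_intensity intensity of the airway lumen (texture spans
#'   0.2 to 1)
#' @param render_lumen logical; burn the airway lumen into the texture
#' @param supersample integer factor of the master texture grid. All
#'   frames - including the reference - are sampled from a common
#'   supersampled master through the same interpolation, so every frame
#'   carries the same effective point-spread function (as reconstructed CT
#'   frames do); rendering the reference frame as a raw texture would give
#'   it an unrealistically sharper response than the warped frames and bias
#'   motion estimates between them
#' @return an object of class `lung_phantom`: frames (`volumes`, a list of
#'   3D arrays), `frame_times`, voxel spacing, the tree, mechanics and
#'   ground-truth accessors (`displacement(points, f1, f2)` in voxels,
#'   `jacobian(points, f1, f2)`, `labels()` ownership array,
#'   `lumen_mask()` rasterized lumen of the reference frame)
#' @export
render_volumes <- function(tree, mechanics, grid_shape, voxel_spacing,
                           texture_seed = 1L, core_radius = 13,
                           texture_corr = 1.5, lumen_intensity = 0.05,
                           render_lumen = TRUE, supersample = 2L) {
  grid_shape <- as.integer(grid_shape)
  if (voxel_spacing <= 0) stop("voxel spacing must be positive")
  comp <- mechanics$compartments
  n <- nrow(comp)
  n_frames <- ncol(mechanics$flows)
  centers <- cbind(comp$cx, comp$cy, comp$cz) / voxel_spacing + 1  # 1-based voxels
  radii <- rep_len(core_radius, n)

  vcore_ul <- 4 / 3 * pi * (radii * voxel_spacing)^3 * 1e-9
  # warp reference: a fictitious state slightly below end expiration, so
  # that *every* frame (including frame 1) is rendered through a
  # spatially-varying warp and all frames carry the same interpolation
  # response; displacements between frames are unaffected
  tv_k <- apply(mechanics$volumes, 1, max) - apply(mechanics$volumes, 1, min)
  v_ref <- mechanics$volumes[, 1] - 0.25 * tv_k
  dv_ul <- mechanics$volumes[, seq_len(n_frames), drop = FALSE] - v_ref
  srel <- 1 + dv_ul / vcore_ul
  if (any(srel <= 0)) stop("compartment deflates below its core volume")
  smat <- srel^(1 / 3)                     # n x n_frames linear scale factors
  smax <- apply(smat, 1, max)

  # disjointness of inflated cores and containment in the grid
  if (n > 1) {
    d <- as.matrix(stats::dist(centers))
    need <- outer(radii * smax, radii * smax, "+") + 2
    diag(need) <- 0
    if (any(d < need))
      stop("overlapping compartment regions: cores would intersect at peak inflation")
  }
  marg <- radii * smax + 2
  if (any(centers < marg + 1) ||
      any(centers > matrix(grid_shape, n, 3, byrow = TRUE) - marg))
    stop("compartment cores too close to the grid boundary")

  ss <- as.integer(supersample)
  master <- speckle_texture(grid_shape * ss, texture_corr * ss, texture_seed)
  lumen <- NULL
  if (render_lumen) {
    lum_hi <- rasterize_lumen(tree, grid_shape * ss, voxel_spacing / ss)
    master <- master + (lumen_intensity - master) * lum_hi
    lumen <- lum_hi[seq(1, dim(lum_hi)[1], by = ss),
                    seq(1, dim(lum_hi)[2], by = ss),
                    seq(1, dim(lum_hi)[3], by = ss)]
  }

  nx <- grid_shape[1]; ny <- grid_shape[2]; nz <- grid_shape[3]
  gx <- rep.int(seq_len(nx), ny * nz)
  gy <- rep.int(rep.int(seq_len(ny), rep.int(nx, ny)), nz)
  gz <- rep.int(seq_len(nz), rep.int(nx * ny, nz))
  Y <- cbind(gx, gy, gz)

  # frame voxel i sits at master coordinate ss*(i-1)+1; a quarter-voxel
  # offset keeps even the unwarped reference off the master lattice so all
  # frames share the interpolation response
  to_master <- function(X) ss * (X - 1 + 0.25) + 1
  sample_master <- function(X) {
    Xm <- to_master(X)
    array(trilinear(master, Xm[, 1], Xm[, 2], Xm[, 3]), grid_shape)
  }
  volumes <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    if (f > 1L && all(abs(smat[, f] - smat[, 1]) < 1e-12)) {
      volumes[[f]] <- volumes[[1]]
      next
    }
    X0 <- if (all(abs(smat[, f] - 1) < 1e-12)) Y else
      phantom_inverse(Y, centers, radii, smat[, f])
    volumes[[f]] <- sample_master(X0)
  }

  displacement <- function(points, f1, f2) {
    points <- matrix(points, ncol = 3)
    X0 <- phantom_inverse(points, centers, radii, smat[, f1], n_iter = 6L)
    phantom_forward(X0, centers, radii, smat[, f2]) - points
  }
  jacobian <- function(points, f1, f2) {
    points <- matrix(points, ncol = 3)
    X0 <- phantom_inverse(points, centers, radii, smat[, f1], n_iter = 6L)
    J <- rep(1, nrow(X0))
    for (k in seq_len(n)) {
      r2 <- (X0[, 1] - centers[k, 1])^2 + (X0[, 2] - centers[k, 2])^2 +
        (X0[, 3] - centers[k, 3])^2
      core <- r2 < radii[k]^2
      J[core] <- smat[k, f2]^3 / smat[k, f1]^3
    }
    J
  }
  labels <- function() {
    best <- rep(1L, nrow(Y)); bd <- rep(Inf, nrow(Y))
    for (k in seq_len(n)) {
      d2 <- (gx - centers[k, 1])^2 + (gy - centers[k, 2])^2 +
        (gz - centers[k, 3])^2
      sel <- d2 < bd
      best[sel] <- k; bd[sel] <- d2[sel]
    }
    array(comp$endpoint_id[best], grid_shape)
  }

  structure(list(
    volumes = volumes,
    frame_times = mechanics$times_knots[seq_len(n_frames)],
    voxel_spacing = voxel_spacing,
    grid_shape = grid_shape,
    tree = tree,
    mechanics = mechanics,
    centers = centers, core_radii = radii, scales = smat,
    displacement = displacement, jacobian = jacobian, labels = labels,
    lumen_mask = function() lumen
  ), class = "lung_phantom")
}

# Rasterize the airway lumen: for every tree segment, voxels within the
# local radius of the centreline get weight 1, with a 1-voxel soft edge.
rasterize_lumen <- function(tree, grid_shape, voxel_spacing) {
  w <- array(0, grid_shape)
  for (s in seq_along(tree$paths)) {
    p <- tree$paths[[s]]
    idx <- match(p, tree$nodes$id)
    pts <- as.matrix(tree$nodes[idx, c("x", "y", "z")]) / voxel_spacing + 1
    rads <- tree$nodes$radius[idx] / voxel_spacing
    for (i in seq_len(length(p) - 1L)) {
      a <- pts[i, ]; b <- pts[i + 1L, ]
      ra <- rads[i]; rb <- rads[i + 1L]
      rmax <- max(ra, rb) + 1.5
      lo <- pmax(floor(pmin(a, b) - rmax), 1)
      hi <- pmin(ceiling(pmax(a, b) + rmax), grid_shape)
      xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
      bx <- rep.int(xs, length(ys) * length(zs))
      by <- rep.int(rep.int(ys, rep.int(length(xs), length(ys))), length(zs))
      bz <- rep.int(zs, rep.int(length(xs) * length(ys), length(zs)))
      ab <- b - a
      len2 <- sum(ab^2)
      t <- if (len2 == 0) rep(0, length(bx)) else
        pmin(pmax(((bx - a[1]) * ab[1] + (by - a[2]) * ab[2] +
                     (bz - a[3]) * ab[3]) / len2, 0), 1)
      dx <- bx - (a[1] + t * ab[1]); dy <- by - (a[2] + t * ab[2])
      dz <- bz - (a[3] + t * ab[3])
      d <- sqrt(dx * dx + dy * dy + dz * dz)
      r <- ra + t * (rb - ra)
      val <- pmin(pmax(r + 0.5 - d, 0), 1)
      sub <- w[xs, ys, zs]
      w[xs, ys, zs] <- pmax(sub, array(val, dim = c(length(xs), length(ys), length(zs))))
    }
  }
  w
}

#' Build a complete synthetic subject (phantom) in one call
#'
#' Packs disjoint compartment centres into the voxel grid, grows an airway
#' tree whose endpoint tips terminate at the centres, simulates
#' single-compartment RC mechanics for every endpoint under the ventilation
#' protocol and disease configuration, and renders the 4D image cycle with
#' ground truth. A single integer seed controls centre packing, tree
#' jitter, mechanical draws and texture.
#'
#' @param n_endpoints number of terminal airways / compartments
#' @param grid_shape voxel grid dimensions (default 128^3)
#' @param voxel_spacing voxel size (micrometres)
#' @param protocol a [ventilation_protocol()]
#' @param disease a [disease_config()]; its `seed` is overridden by `seed`
#' @param core_radius compartment core radius (voxels)
#' @param center_margin minimum distance from a compartment centre to the
#'   grid boundary (voxels)
#' @param compliance_per_volume regional compliance per unit resting volume;
#'   the default gives a tidal fraction of about 5 percent
#' @param seed master seed
#' @param ... further arguments passed to [render_volumes()]
#' @return a `lung_phantom` (see [render_volumes()])
#' @export
lung_phantom <- function(n_endpoints = 16, grid_shape = c(128, 128, 128),
                         voxel_spacing = 15.3,
                         protocol = ventilation_protocol(),
                         disease = disease_config(),
                         core_radius = 13, center_margin = 26,
                         compliance_per_volume = 0.0075,
                         seed = 1L, ...) {
  grid_shape <- as.integer(grid_shape)
  centers <- pack_centers(n_endpoints,
                          lower = rep(center_margin, 3),
                          upper = grid_shape - center_margin,
                          seed = seed)
  dom <- rbind(c(0, 0, 0), (grid_shape - 1) * voxel_spacing)
  tree <- generate_tree(max(1, ceiling(log2(n_endpoints))),
                        domain = dom, seed = seed + 1L,
                        targets = (centers - 1) * voxel_spacing,
                        radius0 = 4.5 * voxel_spacing)
  disease$seed <- as.integer(seed + 2L)
  total_ul <- prod(grid_shape) * voxel_spacing^3 * 1e-9
  mech <- simulate_compartments(tree, protocol, disease,
                                rest_volumes = rep(total_ul / n_endpoints, n_endpoints),
                                compliance_per_volume = compliance_per_volume)
  render_volumes(tree, mech, grid_shape, voxel_spacing,
                 texture_seed = seed + 3L, core_radius = core_radius, ...)
}

#' @export
print.lung_phantom <- function(x, ...) {
  cat(sprintf("4D lung phantom: %s grid, %d frames, %d compartments\n",
              paste(x$grid_shape, collapse = "x"),
              length(x$volumes), nrow(x$mechanics$compartments)))
  invisible(x)
}
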