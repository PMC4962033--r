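#' Configuration for 3D cross-correlation velocimetry
#'
#' Defaults follow standard volumetric PIV practice on lung CT data:
#' cubic interrogation regions of 64 voxels per side with window centres
#' spaced 16 voxels apart, three-point Gaussian sub-voxel peak refinement
#' and a normalized-median outlier test.
#'
#' @param window_size interrogation window edge length in voxels (>= 8)
#' @param window_spacing spacing between window centres in voxels
#'   (0 < spacing <= window_size)
#' @param subpixel `"gaussian"` (three-point Gaussian fit, parabolic
#'   fallback) or `"parabolic"`
#' @param weighting interrogation-window apodization: `"none"` (uniform,
#'   the default) or `"hann"`; Hann weighting suppresses window-truncation
#'   bias and is recommended for windows smaller than about 32 voxels
#' @param validation_threshold normalized-median test threshold
#' @param validation_eps noise floor of the normalized-median test (voxels)
#' @return an object of class `piv_config`
#' @export
piv_config <- function(window_size = 64L, window_spacing = 16L,
                       subpixel = c("gaussian", "parabolic"),
                       weighting = c("none", "hann"),
                       validation_threshold = 2, validation_eps = 0.1) {
  window_size <- as.integer(window_size)
  window_spacing <- as.integer(window_spacing)
  if (window_size < 8L) stop("window_size must be at least 8 voxels")
  if (window_spacing < 1L || window_spacing > window_size)
    stop("window_spacing must be in (0, window_size]")
  structure(list(window_size = window_size, window_spacing = window_spacing,
                 subpixel = match.arg(subpixel),
                 weighting = match.arg(weighting),
                 validation_threshold = validation_threshold,
                 validation_eps = validation_eps),
            class = "piv_config")
}

#' Sub-voxel correlation peak location
#'
#' Separable three-point fit per axis through the integer peak of a
#' correlation map: a Gaussian fit on the log values when the three samples
#' are positive, otherwise a parabolic fit (flagged). The centre value must
#' be the neighborhood maximum; the offset lies in (-1, 1) per axis.
#'
#' @param neigh a 3 x 3 x 3 array of correlation values around the peak
#' @return list with `offset` (length 3, voxels) and `fallback` (logical,
#'   TRUE when any axis used the parabolic fallback)
#' @export
subpixel_peak <- function(neigh) {
  stopifnot(all(dim(neigh) == c(3, 3, 3)))
  c0 <- neigh[2, 2, 2]
  off <- numeric(3)
  fallback <- FALSE
  for (ax in 1:3) {
    v <- switch(ax, neigh[, 2, 2], neigh[2, , 2], neigh[2, 2, ])
    if (v[1] == v[3]) next                      # symmetric: offset 0
    if (all(v > 0)) {
      l <- log(v)
      den <- 2 * (l[1] - 2 * l[2] + l[3])
      if (den < 0) { off[ax] <- (l[1] - l[3]) / den; next }
    }
    den <- 2 * (v[1] - 2 * v[2] + v[3])
    if (den < 0) { off[ax] <- (v[1] - v[3]) / den; fallback <- TRUE }
  }
  off <- pmin(pmax(off, -0.999), 0.999)
  list(offset = off, fallback = fallback)
}

#' Measure 3D displacement between two volumes by windowed cross-correlation
#'
#' For every interrogation-window centre on a regular grid (and inside the
#' optional mask), computes the zero-normalized circular cross-correlation
#' of the two windows by FFT, takes the correlation peak as the integer
#' displacement (wrapped to half the window size) and refines it to
#' sub-voxel precision. Windows that would extend beyond the volume are
#' omitted from the grid; zero-variance windows are flagged invalid.
#'
#' @param vol_a,vol_b 3D arrays of identical shape (frame f and f+1)
#' @param mask optional 3D logical array; centres where `mask` is FALSE are
#'   flagged `"masked"` and carry no vector
#' @param config a [piv_config()]
#' @param frame_pair optional length-2 integer identifier stored with the
#'   field
#' @return an object of class `displacement_field`: `u` (nx x ny x nz x 3
#'   array of displacements in voxels), `quality` (character array:
#'   `"valid"`, `"masked"`, `"invalid"`, `"fallback"`), `centers` (list of
#'   centre coordinates per axis, voxels), `spacing` (voxels), `frame_pair`
#' @export
cross_correlate_windows <- function(vol_a, vol_b, mask = NULL,
                                    config = piv_config(),
                                    frame_pair = c(1L, 2L)) {
  stopifnot(all(dim(vol_a) == dim(vol_b)))
  if (!is.null(mask)) stopifnot(all(dim(mask) == dim(vol_a)))
  d <- dim(vol_a)
  w <- config$window_size
  o <- w %/% 2L
  centers <- lapply(1:3, function(ax) {
    cs <- seq(o, d[ax] - o + (w %% 2L == 0L) * 0L, by = config$window_spacing)
    cs[cs - o + 1L >= 1L & cs - o + w <= d[ax]]
  })
  nx <- length(centers[[1]]); ny <- length(centers[[2]]); nz <- length(centers[[3]])
  if (nx * ny * nz == 0) stop("no interrogation window fits inside the volume")
  u <- array(NA_real_, c(nx, ny, nz, 3))
  quality <- array("masked", c(nx, ny, nz))
  half <- w / 2
  wt <- NULL
  if (config$weighting == "hann") {
    h1 <- 0.5 * (1 - cos(2 * pi * (seq_len(w) - 0.5) / w))
    wt <- outer(outer(h1, h1), h1)
  }
  # zero-normalize a window: remove the (weighted) mean, apodize, unit norm
  znorm <- function(v) {
    if (is.null(wt)) v <- v - mean(v)
    else { v <- v - sum(v * wt) / sum(wt); v <- v * wt }
    n <- sqrt(sum(v * v))
    if (n == 0) return(NULL)
    v / n
  }
  for (iz in seq_len(nz)) for (iy in seq_len(ny)) for (ix in seq_len(nx)) {
    cx <- centers[[1]][ix]; cy <- centers[[2]][iy]; cz <- centers[[3]][iz]
    if (!is.null(mask) && !mask[cx, cy, cz]) next
    rx <- (cx - o + 1L):(cx - o + w)
    ry <- (cy - o + 1L):(cy - o + w)
    rz <- (cz - o + 1L):(cz - o + w)
    wa <- znorm(vol_a[rx, ry, rz])
    wb <- znorm(vol_b[rx, ry, rz])
    if (is.null(wa) || is.null(wb)) { quality[ix, iy, iz] <- "invalid"; next }
    fa <- Conj(fft(wa))
    cc <- Re(fft(fa * fft(wb), inverse = TRUE))
    pk3 <- arrayInd(which.max(cc), c(w, w, w))
    shift <- pk3 - 1L
    shift <- ifelse(shift > half, shift - w, shift)
    # discrete window offset: re-correlate against the b-window shifted by
    # the integer displacement, so that at the true shift the two windows
    # hold identical content and the correlation map is exactly symmetric
    # about its peak (removes window-truncation bias)
    rx2 <- rx + shift[1]; ry2 <- ry + shift[2]; rz2 <- rz + shift[3]
    if (rx2[1] >= 1L && ry2[1] >= 1L && rz2[1] >= 1L &&
        rx2[w] <= d[1] && ry2[w] <= d[2] && rz2[w] <= d[3]) {
      wb2 <- znorm(vol_b[rx2, ry2, rz2])
      if (!is.null(wb2)) {
        cc <- Re(fft(fa * fft(wb2), inverse = TRUE))
        pk3 <- arrayInd(which.max(cc), c(w, w, w))
        s1 <- pk3 - 1L
        s1 <- ifelse(s1 > half, s1 - w, s1)
        shift <- shift + s1
      }
    }
    # 3x3x3 neighborhood with cyclic wrap (the correlation map is periodic)
    nb <- cc[ ((pk3[1] - 2L):(pk3[1])) %% w + 1L,
              ((pk3[2] - 2L):(pk3[2])) %% w + 1L,
              ((pk3[3] - 2L):(pk3[3])) %% w + 1L ]
    sp <- subpixel_peak(nb)
    u[ix, iy, iz, ] <- shift + sp$offset
    quality[ix, iy, iz] <- if (sp$fallback) "fallback" else "valid"
  }
  structure(list(u = u, quality = quality, centers = centers,
                 spacing = config$window_spacing,
                 window_size = w,
                 frame_pair = as.integer(frame_pair)),
            class = "displacement_field")
}

#' @export
print.displacement_field <- function(x, ...) {
  nq <- table(x$quality)
  cat(sprintf("Displacement field %dx%dx%d (spacing %d voxels): %s\n",
              dim(x$quality)[1], dim(x$quality)[2], dim(x$quality)[3],
              x$spacing,
              paste(names(nq), nq, sep = "=", collapse = ", ")))
  invisible(x)
}

piv_vector_ok <- function(quality) quality %in% c("valid", "fallback", "replaced")

#' Normalized-median validation of a displacement field
#'
#' Applies the normalized-median test to every vector over its 26-voxel
#' neighborhood on the window grid: the residual of a vector against the
#' componentwise median of its valid neighbours, normalized by the median
#' neighbour residual plus a small noise floor, must not exceed
#' `threshold`. Outliers are replaced by the neighbour median and flagged
#' `"replaced"`; vectors whose neighbourhood contains no valid vector are
#' flagged `"invalid"`. Masked vectors are untouched.
#'
#' @param field a `displacement_field`
#' @param threshold normalized residual threshold (default 2)
#' @param eps noise floor (voxels)
#' @return the field with outliers replaced and quality flags updated
#' @export
validate_displacements <- function(field, threshold = 2, eps = 0.1) {
  dq <- dim(field$quality)
  if (any(dq < 3)) stop("field must have at least 3x3x3 vectors")
  ok <- array(piv_vector_ok(field$quality), dq)
  u_new <- field$u
  q_new <- field$quality
  for (iz in seq_len(dq[3])) for (iy in seq_len(dq[2])) for (ix in seq_len(dq[1])) {
    if (field$quality[ix, iy, iz] == "masked") next
    xs <- max(1, ix - 1):min(dq[1], ix + 1)
    ys <- max(1, iy - 1):min(dq[2], iy + 1)
    zs <- max(1, iz - 1):min(dq[3], iz + 1)
    sel <- ok[xs, ys, zs]
    sel[match(ix, xs), match(iy, ys), match(iz, zs)] <- FALSE
    if (!any(sel)) {
      if (field$quality[ix, iy, iz] != "invalid") q_new[ix, iy, iz] <- "invalid"
      next
    }
    nb <- matrix(NA_real_, sum(sel), 3)
    for (cc in 1:3) {
      blk <- field$u[xs, ys, zs, cc]
      nb[, cc] <- blk[sel]
    }
    med <- apply(nb, 2, stats::median)
    res_nb <- sqrt(rowSums((nb - matrix(med, nrow(nb), 3, byrow = TRUE))^2))
    r0 <- stats::median(res_nb)
    if (field$quality[ix, iy, iz] == "invalid") {
      # repair previously-invalid vectors from their neighbours
      u_new[ix, iy, iz, ] <- med
      q_new[ix, iy, iz] <- "replaced"
      next
    }
    res <- sqrt(sum((field$u[ix, iy, iz, ] - med)^2))
    if (res / (r0 + eps) > threshold) {
      u_new[ix, iy, iz, ] <- med
      q_new[ix, iy, iz] <- "replaced"
    }
  }
  field$u <- u_new
  field$quality <- q_new
  field
}

#' Run velocimetry over a full image cycle
#'
#' Correlates every successive frame pair of a volume series, including the
#' cyclic pair (last frame against the first), and validates each field.
#'
#' @param volumes list of 3D arrays (one per frame)
#' @param mask optional 3D logical array
#' @param config a [piv_config()]
#' @param validate logical; apply [validate_displacements()]
#' @return list of `displacement_field`s, one per frame pair `f -> f+1`
#'   (cyclic)
#' @export
piv_cycle <- function(volumes, mask = NULL, config = piv_config(),
                      validate = TRUE) {
  nf <- length(volumes)
  out <- vector("list", nf)
  for (f in seq_len(nf)) {
    g <- if (f == nf) 1L else f + 1L
    fld <- cross_correlate_windows(volumes[[f]], volumes[[g]], mask, config,
                                   frame_pair = c(f, g))
    if (validate && all(dim(fld$quality) >= 3))
      fld <- validate_displacements(fld, config$validation_threshold,
                                    config$validation_eps)
    out[[f]] <- fld
  }
  out
}
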