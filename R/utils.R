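# internal helpers shared across modules

# Evaluate an expression with a temporarily-seeded RNG, restoring the caller's
# RNG state afterwards so library code never perturbs user-level randomness.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' Trilinear interpolation of a 3D array
#'
#' Samples `vol` at fractional voxel coordinates (1-based); points outside
#' the grid are clamped to the border.
#'
#' @param vol 3D array
#' @param x,y,z coordinate vectors of equal length
#' @return vector of interpolated values
#' @export
trilinear <- function(vol, x, y, z) {
  d <- dim(vol)
  x <- pmin(pmax(x, 1), d[1]); y <- pmin(pmax(y, 1), d[2]); z <- pmin(pmax(z, 1), d[3])
  x0 <- pmin(floor(x), d[1] - 1L); y0 <- pmin(floor(y), d[2] - 1L); z0 <- pmin(floor(z), d[3] - 1L)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  idx <- function(i, j, k) (k - 1) * d[1] * d[2] + (j - 1) * d[1] + i
  v000 <- vol[idx(x0,     y0,     z0)]
  v100 <- vol[idx(x0 + 1, y0,     z0)]
  v010 <- vol[idx(x0,     y0 + 1, z0)]
  v110 <- vol[idx(x0 + 1, y0 + 1, z0)]
  v001 <- vol[idx(x0,     y0,     z0 + 1)]
  v101 <- vol[idx(x0 + 1, y0,     z0 + 1)]
  v011 <- vol[idx(x0,     y0 + 1, z0 + 1)]
  v111 <- vol[idx(x0 + 1, y0 + 1, z0 + 1)]
  (v000 * (1 - fx) + v100 * fx) * (1 - fy) * (1 - fz) +
    (v010 * (1 - fx) + v110 * fx) * fy       * (1 - fz) +
    (v001 * (1 - fx) + v101 * fx) * (1 - fy) * fz +
    (v011 * (1 - fx) + v111 * fx) * fy       * fz
}

#' Band-limited speckle texture
#'
#' White noise low-pass filtered with a Gaussian kernel of the requested
#' correlation length, rescaled to `[lo, hi]`. The phantom's stand-in for
#' the speckled appearance of lung parenchyma.
#'
#' @param shape integer length-3 grid dimensions
#' @param corr_length speckle correlation length (voxels)
#' @param seed integer seed
#' @param lo,hi output intensity range
#' @return 3D array
#' @export
speckle_texture <- function(shape, corr_length = 1.5, seed = 1L,
                            lo = 0.2, hi = 1) {
  noise <- with_seed(seed, array(stats::rnorm(prod(shape)), shape))
  freq2 <- function(n) {
    f <- c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1)) / n
    f^2
  }
  fx <- freq2(shape[1]); fy <- freq2(shape[2]); fz <- freq2(shape[3])
  # Gaussian transfer function exp(-2 pi^2 sigma^2 f^2), sigma = corr/2
  s2 <- (corr_length / 2)^2
  g <- exp(-2 * pi^2 * s2 * (outer(outer(fx, fy, "+"), fz, "+")))
  sm <- Re(fft(fft(noise) * g, inverse = TRUE)) / prod(shape)
  rng <- range(sm)
  lo + (sm - rng[1]) / (rng[2] - rng[1]) * (hi - lo)
}

# md5 of a serialized R object via a temp file (base tools only)
object_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
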