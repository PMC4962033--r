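test_that("default configuration matches standard interrogation settings", {
  cfg <- piv_config()
  expect_equal(cfg$window_size, 64L)
  expect_equal(cfg$window_spacing, 16L)
  expect_equal(cfg$subpixel, "gaussian")
  expect_equal(cfg$weighting, "none")
  expect_error(piv_config(window_size = 4), "at least 8")
  expect_error(piv_config(window_spacing = 80), "window_spacing")
})

test_that("integer cyclic shifts are recovered exactly at interior windows", {
  a <- speckle_texture(c(96, 96, 96), seed = 5)
  cfg <- piv_config(window_size = 32, window_spacing = 16)
  for (s in list(c(3L, 0L, 0L), c(-2L, 4L, 0L), c(0L, 0L, 6L))) {
    b <- a
    if (s[1] != 0) b <- b[(seq_len(96) - 1 - s[1]) %% 96 + 1, , ]
    if (s[2] != 0) b <- b[, (seq_len(96) - 1 - s[2]) %% 96 + 1, ]
    if (s[3] != 0) b <- b[, , (seq_len(96) - 1 - s[3]) %% 96 + 1]
    fld <- cross_correlate_windows(a, b, config = cfg)
    # interior: windows whose offset window stays inside the volume
    cs <- fld$centers
    keep <- list()
    for (ax in 1:3) {
      lo <- if (s[ax] < 0) which(cs[[ax]] + s[ax] - 16 >= 0) else seq_along(cs[[ax]])
      hi <- if (s[ax] > 0) which(cs[[ax]] + s[ax] + 16 <= 96) else seq_along(cs[[ax]])
      keep[[ax]] <- intersect(lo, hi)
    }
    u <- fld$u[keep[[1]], keep[[2]], keep[[3]], , drop = FALSE]
    for (ax in 1:3)
      expect_equal(as.vector(u[, , , ax]),
                   rep(s[ax], length(u[, , , ax])), tolerance = 1e-12)
  }
})

test_that("a half-voxel band-limited shift is recovered within 0.1 voxel", {
  a <- speckle_texture(c(128, 128, 128), seed = 6)
  b <- shift_fft_z(a, 0.5)
  fld <- cross_correlate_windows(a, b, config = piv_config())  # 64^3 / 16
  uz <- fld$u[, , 1:4, 3]                    # interior along z
  expect_lt(max(abs(uz - 0.5)), 0.1)
  expect_lt(abs(mean(uz) - 0.5), 0.05)
})

test_that("sub-voxel peak fit matches closed forms and falls back when needed", {
  # symmetric neighborhood: zero offset
  nb <- array(0.5, c(3, 3, 3)); nb[2, 2, 2] <- 1
  expect_equal(subpixel_peak(nb)$offset, c(0, 0, 0))
  # Gaussian samples exp(-(x-0.3)^2) at x = -1, 0, 1 on one axis
  nb <- array(0.2, c(3, 3, 3))
  nb[, 2, 2] <- exp(-(c(-1, 0, 1) - 0.3)^2)
  nb[2, , 2] <- c(0.2, nb[2, 2, 2], 0.2)
  nb[2, 2, ] <- c(0.2, nb[2, 2, 2], 0.2)
  sp <- subpixel_peak(nb)
  expect_equal(sp$offset[1], 0.3, tolerance = 1e-12)
  # a non-positive asymmetric triple forces the parabolic fallback
  nb <- array(0.2, c(3, 3, 3))
  nb[2, 2, 2] <- 1
  nb[2, , 2] <- c(-0.1, 1, 0.3)
  sp <- subpixel_peak(nb)
  expect_true(sp$fallback)
  expect_equal(sp$offset[2], (-0.1 - 0.3) / (2 * (-0.1 - 2 + 0.3)),
               tolerance = 1e-12)
  expect_true(all(abs(sp$offset) < 1))
})

test_that("zero-variance windows are flagged invalid and masks are honoured", {
  a <- array(1, c(32, 32, 32))
  b <- a
  fld <- cross_correlate_windows(a, b, config = piv_config(window_size = 16,
                                                           window_spacing = 8))
  expect_true(all(fld$quality == "invalid"))
  a2 <- speckle_texture(c(32, 32, 32), seed = 2)
  mask <- array(FALSE, c(32, 32, 32)); mask[16, 16, 16] <- TRUE
  fld2 <- cross_correlate_windows(a2, a2, mask = mask,
                                  config = piv_config(window_size = 16,
                                                      window_spacing = 8))
  expect_equal(sum(fld2$quality != "masked"), 1)
})

test_that("normalized-median validation replaces a single planted outlier and nothing else", {
  u <- array(0, c(5, 5, 5, 3)); u[, , , 1] <- 1.5
  fld <- structure(list(u = u, quality = array("valid", c(5, 5, 5)),
                        centers = list(1:5 * 8, 1:5 * 8, 1:5 * 8),
                        spacing = 8L, window_size = 16L,
                        frame_pair = c(1L, 2L)),
                   class = "displacement_field")
  clean <- validate_displacements(fld)
  expect_true(all(clean$quality == "valid"))
  expect_equal(clean$u, fld$u)
  fld$u[3, 3, 3, ] <- c(11.5, 0, 0)       # 10-voxel outlier
  fixed <- validate_displacements(fld)
  expect_equal(sum(fixed$quality == "replaced"), 1)
  expect_equal(fixed$quality[3, 3, 3], "replaced")
  expect_equal(fixed$u[3, 3, 3, ], c(1.5, 0, 0))
})

test_that("validation flags agree with a direct normalized-median recomputation", {
  set.seed(42)
  dq <- c(6, 6, 6)
  u <- array(rnorm(prod(dq) * 3, sd = 0.3), c(dq, 3))
  u[2, 5, 3, ] <- c(5, -4, 3)
  u[5, 2, 4, ] <- c(-6, 0, 2)
  fld <- structure(list(u = u, quality = array("valid", dq),
                        centers = list(1:6 * 8, 1:6 * 8, 1:6 * 8),
                        spacing = 8L, window_size = 16L,
                        frame_pair = c(1L, 2L)),
                   class = "displacement_field")
  out <- validate_displacements(fld, threshold = 2, eps = 0.1)
  # brute-force oracle applied vector by vector
  for (iz in 1:6) for (iy in 1:6) for (ix in 1:6) {
    xs <- max(1, ix - 1):min(6, ix + 1)
    ys <- max(1, iy - 1):min(6, iy + 1)
    zs <- max(1, iz - 1):min(6, iz + 1)
    nb <- NULL
    for (k in zs) for (j in ys) for (i in xs)
      if (!(i == ix && j == iy && k == iz)) nb <- rbind(nb, u[i, j, k, ])
    med <- apply(nb, 2, median)
    r0 <- median(sqrt(rowSums(sweep(nb, 2, med)^2)))
    res <- sqrt(sum((u[ix, iy, iz, ] - med)^2))
    flagged <- res / (r0 + 0.1) > 2
    expect_equal(unname(out$quality[ix, iy, iz]),
                 if (flagged) "replaced" else "valid")
  }
})

test_that("a full cycle yields one field per frame pair including the wrap pair", {
  ph <- fx_small_phantom()
  flds <- fx_e2e()$fields
  expect_length(flds, 16)
  expect_equal(flds[[16]]$frame_pair, c(16L, 1L))
  expect_equal(flds[[1]]$frame_pair, c(1L, 2L))
})

test_that("velocimetry recovers the phantom displacement field", {
  e2e <- fx_e2e()
  P <- e2e$piv_points
  ut <- e2e$ph$displacement(P, 4, 5)
  ue <- matrix(e2e$fields[[4]]$u, ncol = 3)
  err <- sqrt(rowSums((ue - ut)^2))
  expect_lt(median(err, na.rm = TRUE), 0.5)   # well under half a voxel
})
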