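# rasterize line segments with a radius into a logical mask (test helper)
tube_mask <- function(dim, segs, radius) {
  m <- array(FALSE, dim)
  idx <- as.matrix(expand.grid(x = seq_len(dim[1]), y = seq_len(dim[2]),
                               z = seq_len(dim[3])))
  for (s in segs) {
    a <- s[[1]]; b <- s[[2]]
    ab <- b - a; len2 <- sum(ab^2)
    t <- pmin(pmax(((idx[, 1] - a[1]) * ab[1] + (idx[, 2] - a[2]) * ab[2] +
                      (idx[, 3] - a[3]) * ab[3]) / len2, 0), 1)
    d2 <- (idx[, 1] - a[1] - t * ab[1])^2 + (idx[, 2] - a[2] - t * ab[2])^2 +
      (idx[, 3] - a[3] - t * ab[3])^2
    m[d2 <= radius^2] <- TRUE
  }
  m
}

test_that("flood fill recovers a two-level tube exactly and rejects bad seeds", {
  vol <- array(100, c(30, 30, 30))
  tube <- tube_mask(c(30, 30, 30), list(list(c(15, 15, 3), c(15, 15, 27))), 3)
  vol[tube] <- 10
  mask <- suppressWarnings(flood_fill_segment(vol, c(15, 15, 15), c(0, 50)))
  expect_identical(mask, tube)
  expect_error(flood_fill_segment(vol, c(2, 2, 2), c(0, 50)), "seed intensity")
  # re-running is bit-identical
  mask2 <- suppressWarnings(flood_fill_segment(vol, c(15, 15, 15), c(0, 50)))
  expect_identical(mask, mask2)
})

test_that("chessboard distance transform counts erosion layers", {
  m <- array(FALSE, c(9, 9, 9)); m[3:7, 3:7, 3:7] <- TRUE
  dt <- dt_chessboard(m)
  expect_equal(dt[5, 5, 5], 3L)   # centre of a 5-cube survives 3 erosions
  expect_equal(dt[3, 3, 3], 1L)
  expect_true(all(dt[!m] == 0))
})

test_that("a Y-shaped mask skeletonizes into one bifurcation", {
  segs <- list(list(c(20, 20, 4), c(20, 20, 20)),
               list(c(20, 20, 20), c(10, 12, 36)),
               list(c(20, 20, 20), c(30, 28, 36)))
  m <- tube_mask(c(40, 40, 40), segs, 2.2)
  tr <- skeletonize_to_graph(m, c(20, 20, 4))
  expect_equal(n_segments(tr), 3)
  expect_length(find_endpoints(tr), 2)
  # endpoint tips land near the prescribed branch tips
  tips <- t(vapply(find_endpoints(tr), function(s) segment_tip(tr, s),
                   numeric(3))) + 1
  target <- rbind(c(10, 12, 36), c(30, 28, 36))
  d <- as.matrix(dist(rbind(tips, target)))[1:2, 3:4]
  expect_lt(max(apply(d, 2, min)), 4)
})

test_that("a straight cylinder gives a single degenerate segment", {
  m <- tube_mask(c(20, 20, 40), list(list(c(10, 10, 4), c(10, 10, 36))), 2.5)
  tr <- skeletonize_to_graph(m, c(10, 10, 4))
  expect_equal(n_segments(tr), 1)
  eps <- find_endpoints(tr)
  expect_length(eps, 0)
  expect_true(attr(eps, "degenerate"))
})

test_that("the skeleton stays inside the mask", {
  segs <- list(list(c(20, 20, 4), c(20, 20, 20)),
               list(c(20, 20, 20), c(10, 12, 36)),
               list(c(20, 20, 20), c(30, 28, 36)))
  m <- tube_mask(c(40, 40, 40), segs, 2.2)
  tr <- skeletonize_to_graph(m, c(20, 20, 4))
  for (p in tr$paths) {
    xyz <- as.matrix(tr$nodes[match(p, tr$nodes$id), c("x", "y", "z")]) + 1
    expect_true(all(m[xyz]))
  }
})

# descendant endpoint sets of every segment, as a canonical set-of-sets,
# with endpoints identified by an arbitrary labelling function
topology_signature <- function(tree, label) {
  eps <- find_endpoints(tree)
  labs <- vapply(eps, label, numeric(1))
  kids <- vector("list", n_segments(tree))
  for (s in seq_len(n_segments(tree))) {
    p <- tree$parent[s]
    if (!is.na(p)) kids[[p]] <- c(kids[[p]], s)
  }
  desc <- function(s) {
    if (!length(kids[[s]])) {
      i <- match(s, eps)
      return(if (is.na(i)) numeric(0) else labs[i])
    }
    sort(unlist(lapply(kids[[s]], desc)))
  }
  sig <- lapply(seq_len(n_segments(tree)), desc)
  sig <- sig[lengths(sig) > 0]
  sort(vapply(sig, function(v) paste(v, collapse = ","), character(1)))
}

test_that("segmentation of the phantom reference frame recovers the airway tree", {
  e2e <- fx_e2e()
  seg <- fx_segmented()
  ph <- e2e$ph
  lum_soft <- ph$lumen_mask()
  # voxel count agrees with the rendered lumen up to the anti-aliased rim
  n_fill <- sum(seg$lumen)
  n_core <- sum(lum_soft >= 1)
  n_any <- sum(lum_soft > 0)
  expect_gte(n_fill, 0.8 * n_core)
  expect_lte(n_fill, n_any)
  # endpoint count matches the generator
  expect_length(find_endpoints(seg$tree), 16)
  expect_equal(n_segments(seg$tree), 31)
  # every recovered tip sits at a distinct true compartment centre
  tips <- t(vapply(find_endpoints(seg$tree),
                   function(s) segment_tip(seg$tree, s), numeric(3))) /
    ph$voxel_spacing + 1
  d <- as.matrix(dist(rbind(tips, ph$centers)))[1:16, 17:32]
  nearest <- apply(d, 1, which.min)
  expect_setequal(nearest, 1:16)
  expect_lt(max(apply(d, 2, min)), 5)
  # parent-daughter relations match the generator topology: identify each
  # endpoint by its nearest true centre and compare descendant sets
  lab_rec <- function(s) {
    tip <- segment_tip(seg$tree, s) / ph$voxel_spacing + 1
    which.min(colSums((t(ph$centers) - tip)^2))
  }
  lab_true <- function(s) {
    tip <- segment_tip(ph$tree, s) / ph$voxel_spacing + 1
    which.min(colSums((t(ph$centers) - tip)^2))
  }
  expect_identical(topology_signature(seg$tree, lab_rec),
                   topology_signature(ph$tree, lab_true))
})
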