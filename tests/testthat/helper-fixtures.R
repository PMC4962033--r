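# Shared fixtures. Expensive objects (the full 16-compartment phantom and
# its analysis) are built once per test run and cached in this environment.
fx_cache <- new.env(parent = emptyenv())

fx_get <- function(name, builder) {
  if (!exists(name, envir = fx_cache)) assign(name, builder(), envir = fx_cache)
  get(name, envir = fx_cache)
}

# band-limited sub-voxel shift of a 3D array along z (cyclic)
shift_fft_z <- function(a, s) {
  d <- dim(a)
  kz <- c(seq(0, floor(d[3] / 2)), seq(-ceiling(d[3] / 2) + 1, -1)) / d[3]
  ph <- array(rep(exp(-2i * pi * kz * s), each = d[1] * d[2]), d)
  Re(fft(fft(a) * ph, inverse = TRUE)) / prod(d)
}

# small two-compartment phantom for warp/expansion oracles
fx_small_phantom <- function() fx_get("small_phantom", function() {
  lung_phantom(n_endpoints = 2, grid_shape = c(64, 64, 64),
               core_radius = 9, center_margin = 20, seed = 3)
})

# the full study phantom: 16 endpoints, 128^3, 16 frames, with velocimetry,
# expansion, tissue assignment, regional volume changes and metrics
fx_e2e <- function() fx_get("e2e", function() {
  ph <- lung_phantom(seed = 11)
  protocol <- ventilation_protocol()
  cfg <- piv_config(window_size = 16, window_spacing = 8, weighting = "hann")
  fields <- piv_cycle(ph$volumes, config = cfg)
  exps <- lapply(fields, expansion_field, refine = 2)
  pcs <- fields[[1]]$centers
  pnx <- length(pcs[[1]]); pny <- length(pcs[[2]]); pnz <- length(pcs[[3]])
  piv_points <- cbind(rep.int(pcs[[1]], pny * pnz),
                      rep.int(rep.int(pcs[[2]], rep.int(pnx, pny)), pnz),
                      rep.int(pcs[[3]], rep.int(pnx * pny, pnz)))
  cs <- exps[[1]]$centers
  nx <- length(cs[[1]]); ny <- length(cs[[2]]); nz <- length(cs[[3]])
  P <- cbind(rep.int(cs[[1]], ny * nz),
             rep.int(rep.int(cs[[2]], rep.int(nx, ny)), nz),
             rep.int(cs[[3]], rep.int(nx * ny, nz)))
  cell_ul <- (exps[[1]]$spacing * ph$voxel_spacing)^3 * 1e-9
  assignment <- assign_tissue((P - 1) * ph$voxel_spacing, ph$tree, cell_ul)
  dv <- vapply(seq_along(exps), function(f)
    regional_volume_change(exps[[f]], assignment)$delta_v,
    numeric(length(assignment$endpoint_ids)))
  flows <- endpoint_flows(dv, protocol, assignment$endpoint_ids)
  seg_flows <- propagate_flows(ph$tree, flows)
  metrics <- endpoint_metrics_table(flows, assignment$volumes, protocol)
  truth_dv <- ph$mechanics$volumes[, 2:17] - ph$mechanics$volumes[, 1:16]
  list(ph = ph, protocol = protocol, fields = fields, exps = exps,
       grid_points = P, piv_points = piv_points,
       assignment = assignment, dv = dv, flows = flows,
       seg_flows = seg_flows, metrics = metrics, truth_dv = truth_dv)
})

# flood-fill + skeletonization of the study phantom's reference frame
fx_segmented <- function() fx_get("segmented", function() {
  e2e <- fx_e2e()
  ph <- e2e$ph
  vol1 <- ph$volumes[[1]]
  lm <- ph$lumen_mask()
  top <- which(lm[, , dim(vol1)[3] - 2] > 0.5, arr.ind = TRUE)
  seedv <- c(top[1, 1], top[1, 2], dim(vol1)[3] - 2L)
  lum <- suppressWarnings(flood_fill_segment(vol1, seedv, c(-Inf, 0.12)))
  tree <- skeletonize_to_graph(lum, seedv, voxel_spacing = ph$voxel_spacing)
  list(seed_vox = seedv, lumen = lum, tree = tree)
})

# a small full-pipeline run reused by several tests (run twice for the
# determinism check)
fx_pipeline <- function() fx_get("pipeline", function() {
  out <- file.path(tempdir(), "lf4d_pipeline")
  cfg <- pipeline_config(
    seed = 5, output_dir = out,
    phantom = list(n_endpoints = 8, grid_shape = c(64, 64, 64),
                   core_radius = 7, center_margin = 14))
  res1 <- run_pipeline(cfg)
  files <- sort(list.files(out, full.names = TRUE))
  files <- files[basename(files) != "run.log"]
  sums1 <- tools::md5sum(files)
  res2 <- run_pipeline(cfg)
  sums2 <- tools::md5sum(files)
  list(cfg = cfg, res = res2, files = files, sums1 = sums1, sums2 = sums2)
})

# mechanics-level cohorts for reference-model / LDI / clustering checks
fx_cohort <- function() fx_get("cohort", function() {
  protocol <- ventilation_protocol()
  healthy <- lapply(1:7, function(i)
    simulate_subject_mechanics(230, protocol, disease_config(seed = i),
                               seed = i * 10)$metrics)
  model <- fit_reference(do.call(rbind, healthy))
  list(protocol = protocol, healthy = healthy, model = model)
})
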