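#' Default pipeline configuration
#'
#' Returns the full configuration list for [run_pipeline()] with defaults
#' filled in; any element can be overridden via `...` (nested lists are
#' merged shallowly per section).
#'
#' @param ... named sections to override (`seed`, `output_dir`, `protocol`,
#'   `phantom`, `piv`, `expansion`, `tree`, `write_volumes`)
#' @return configuration list
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    output_dir = "lungflow4d_out",
    write_volumes = FALSE,
    protocol = list(pip = 12, peep = 2, period = 0.45,
                    t_insp = 0.15, t_exp = 0.30, n_frames = 16),
    phantom = list(n_endpoints = 16, grid_shape = c(128, 128, 128),
                   voxel_spacing = 15.3, core_radius = 13,
                   center_margin = 26,
                   disease = list(diseased_volume_fraction = 0,
                                  healthy_tau_mean = 0.12,
                                  healthy_tau_sd = 0.022,
                                  diseased_tau_mean = 0.22,
                                  diseased_tau_sd = 0.037,
                                  blockage_fraction = 0)),
    input = NULL,                       # manifest path for real volume series
    piv = list(window_size = 16, window_spacing = 8, weighting = "hann",
               validation_threshold = 2, validation_eps = 0.1),
    expansion = list(method = "jacobian", refine = 2),
    tree = list(source = "phantom",     # "phantom", "segment" or an SWC path
                lumen_window = c(-Inf, 0.12),
                prune_factor = 2)
  )
  ov <- list(...)
  for (nm in names(ov)) {
    if (is.list(cfg[[nm]]) && is.list(ov[[nm]])) {
      for (k in names(ov[[nm]])) cfg[[nm]][[k]] <- ov[[nm]][[k]]
    } else cfg[[nm]] <- ov[[nm]]
  }
  cfg
}

#' Run the full regional lung function pipeline
#'
#' Executes the stages end to end: obtain a 4D volume series (either the
#' synthetic phantom or a series read from `config$input`), measure lung
#' motion by windowed cross-correlation for all cyclic frame pairs, convert
#' displacement gradients to tissue expansion, obtain the airway tree
#' (phantom ground truth, flood-fill + skeletonization of the reference
#' frame, or an SWC file), assign tissue to endpoints, compute regional
#' airflow by continuity, and derive endpoint metrics. All tables are
#' written to `config$output_dir` with the seed and a configuration hash in
#' every header; rerunning the same configuration reproduces identical
#' files.
#'
#' @param config list from [pipeline_config()], or the path of a YAML file
#'   with the same structure
#' @return list with `metrics` (endpoint metrics data frame), `seg_flows`,
#'   `tree`, `assignment`, `global_tau`, `summary`, `files`
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) {
    y <- yaml::read_yaml(config)
    config <- if (is.null(y)) pipeline_config() else do.call(pipeline_config, y)
  }
  t_start <- Sys.time()
  cfg_hash <- object_hash(config)
  meta <- list(seed = config$seed, config_hash = cfg_hash,
               package = as.character(utils::packageVersion("lungflow4d")))
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out, "run.log")
  logf <- function(fmt, ...) {
    line <- sprintf("%s %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                    sprintf(fmt, ...))
    cat(line, "\n", file = log_path, append = TRUE)
  }
  logf("pipeline start (seed %d, config %s)", config$seed, cfg_hash)

  protocol <- do.call(ventilation_protocol, config$protocol)
  files <- character(0)

  # --- stage: volumes ------------------------------------------------------
  phantom <- NULL
  if (is.null(config$input)) {
    dis <- do.call(disease_config, c(config$phantom$disease,
                                     list(seed = config$seed + 2L)))
    phantom <- lung_phantom(n_endpoints = config$phantom$n_endpoints,
                            grid_shape = config$phantom$grid_shape,
                            voxel_spacing = config$phantom$voxel_spacing,
                            protocol = protocol, disease = dis,
                            core_radius = config$phantom$core_radius,
                            center_margin = config$phantom$center_margin,
                            seed = config$seed)
    volumes <- phantom$volumes
    frame_times <- phantom$frame_times
    spacing <- phantom$voxel_spacing
    logf("phantom rendered: %s grid, %d endpoints",
         paste(config$phantom$grid_shape, collapse = "x"),
         config$phantom$n_endpoints)
    if (isTRUE(config$write_volumes)) {
      files <- c(files, write_volume_series(volumes, frame_times,
                                            file.path(out, "volumes"),
                                            spacing))
      files <- c(files, write_table_with_meta(
        phantom$mechanics$compartments,
        file.path(out, "phantom_truth.csv"), meta))
    }
  } else {
    vs <- read_volume_series(config$input)
    volumes <- vs$volumes; frame_times <- vs$frame_times
    spacing <- vs$voxel_spacing
    logf("volumes read from %s (%d frames)", config$input, length(volumes))
  }

  # --- stage: velocimetry --------------------------------------------------
  piv_cfg <- piv_config(window_size = config$piv$window_size,
                        window_spacing = config$piv$window_spacing,
                        weighting = config$piv$weighting,
                        validation_threshold = config$piv$validation_threshold,
                        validation_eps = config$piv$validation_eps)
  fields <- piv_cycle(volumes, config = piv_cfg)
  logf("velocimetry: %d frame pairs, %d vectors each",
       length(fields), sum(fields[[1]]$quality != "masked"))
  files <- c(files, write_displacement_fields(
    fields, file.path(out, "displacement_fields.csv"), meta))

  # --- stage: expansion ----------------------------------------------------
  exps <- lapply(fields, expansion_field, method = config$expansion$method,
                 refine = config$expansion$refine %||% 1L)

  # --- stage: airway tree --------------------------------------------------
  src <- config$tree$source
  if (identical(src, "phantom")) {
    if (is.null(phantom)) stop("tree source 'phantom' needs a phantom run")
    tree <- phantom$tree
  } else if (identical(src, "segment")) {
    ref_frame <- which.min(vapply(seq_along(volumes), function(f)
      sum(volumes[[f]]), numeric(1)))  # peak expiration: minimum content
    vol <- volumes[[ref_frame]]
    seed_vox <- config$tree$seed_point
    if (is.null(seed_vox)) {
      # default: darkest voxel on the top slab (tracheal opening)
      top <- vol[, , dim(vol)[3]]
      ij <- arrayInd(which.min(top), dim(top))
      seed_vox <- c(ij[1], ij[2], dim(vol)[3])
    }
    lum <- flood_fill_segment(vol, seed_vox, config$tree$lumen_window)
    tree <- skeletonize_to_graph(lum, seed_vox, voxel_spacing = spacing,
                                 prune_factor = config$tree$prune_factor)
    logf("segmented airway tree: %d segments", n_segments(tree))
  } else {
    tree <- read_swc(src)
  }
  files <- c(files, {
    write_swc(tree, file.path(out, "airway_tree.swc"))
    write_table_with_meta(as_segment_table(tree),
                          file.path(out, "airway_segments.csv"), meta)
  })

  # --- stage: tissue linking and flows ------------------------------------
  e1 <- exps[[1]]
  cs <- e1$centers
  nx <- length(cs[[1]]); ny <- length(cs[[2]]); nz <- length(cs[[3]])
  P <- cbind(rep.int(cs[[1]], ny * nz),
             rep.int(rep.int(cs[[2]], rep.int(nx, ny)), nz),
             rep.int(cs[[3]], rep.int(nx * ny, nz)))
  cell_ul <- (e1$spacing * spacing)^3 * 1e-9
  assignment <- assign_tissue((P - 1) * spacing, tree, cell_ul)
  dv <- vapply(seq_along(exps), function(f)
    regional_volume_change(exps[[f]], assignment)$delta_v,
    numeric(length(assignment$endpoint_ids)))
  flows <- endpoint_flows(dv, protocol, assignment$endpoint_ids)
  seg_flows <- propagate_flows(tree, flows)
  files <- c(files, write_flow_waveforms(
    seg_flows, interval_midpoints(protocol),
    file.path(out, "segment_flows.csv"), meta))

  # --- stage: metrics ------------------------------------------------------
  metrics <- endpoint_metrics_table(flows, assignment$volumes, protocol)
  files <- c(files, write_table_with_meta(
    metrics, file.path(out, "endpoint_metrics.csv"), meta))
  trachea_vol <- volume_waveform(seg_flows[tree$root, ], protocol)
  gtau <- global_time_constant(trachea_vol, protocol)
  tau_ok <- metrics$tau_exp[is.finite(metrics$tau_exp)]
  summary <- data.frame(
    seed = config$seed, config_hash = cfg_hash,
    n_endpoints = nrow(metrics),
    global_tau_exp_s = as.numeric(gtau),
    median_tau_s = stats::median(tau_ok),
    sd_tau_s = stats::sd(tau_ok),
    mean_tau_s = mean(tau_ok),
    total_volume_ul = sum(assignment$volumes),
    total_tidal_volume_ul = sum(metrics$tv, na.rm = TRUE))
  files <- c(files, write_table_with_meta(
    summary, file.path(out, "subject_summary.csv"), meta))
  logf("done in %.1f s", as.numeric(difftime(Sys.time(), t_start, units = "secs")))

  list(metrics = metrics, seg_flows = seg_flows, tree = tree,
       assignment = assignment, fields = fields,
       global_tau = gtau, summary = summary, phantom = phantom,
       files = files)
}

#' Simulate a subject at the mechanics level (no imaging)
#'
#' Builds a synthetic subject directly from the compartment mechanics:
#' an airway tree with `n_endpoints` terminal branches, per-endpoint RC
#' draws under `disease`, steady-state flow waveforms sampled on the frame
#' grid, and the endpoint metrics table. This is the fast path for
#' cohort-level analyses (reference model, LDI, time-constant
#' distributions), where image rendering and velocimetry would only
#' propagate the per-endpoint waveforms unchanged.
#'
#' @param n_endpoints terminal branches per subject (a few hundred in a
#'   fully segmented small-animal airway tree)
#' @param protocol a [ventilation_protocol()]
#' @param disease a [disease_config()]
#' @param seed subject seed (controls tree, volumes and draws)
#' @param total_rest_volume total end-expiratory volume (uL)
#' @param volume_jitter sd of log-normal jitter on regional volumes
#' @return list with `metrics`, `mechanics`, `tree`
#' @export
simulate_subject_mechanics <- function(n_endpoints = 230,
                                       protocol = ventilation_protocol(),
                                       disease = disease_config(),
                                       seed = 1L,
                                       total_rest_volume = 500,
                                       volume_jitter = 0.2) {
  targets <- with_seed(seed, matrix(stats::runif(3 * n_endpoints, 100, 900),
                                    n_endpoints, 3))
  tree <- generate_tree(max(1, ceiling(log2(n_endpoints))),
                        targets = targets, seed = seed)
  vols <- with_seed(seed + 1L,
                    exp(stats::rnorm(n_endpoints, 0, volume_jitter)))
  vols <- vols / sum(vols) * total_rest_volume
  disease$seed <- as.integer(seed + 2L)
  mech <- simulate_compartments(tree, protocol, disease, rest_volumes = vols)
  flows <- structure(list(flows = mech$flows,
                          times = mech$times_mid,
                          endpoint_ids = mech$compartments$endpoint_id,
                          missing = rep(FALSE, n_endpoints)),
                     class = "flow_set")
  metrics <- endpoint_metrics_table(flows, mech$compartments$rest_volume,
                                    protocol)
  list(metrics = metrics, mechanics = mech, tree = tree)
}

#' Cohort analysis of per-subject endpoint metrics
#'
#' Pools healthy endpoints to fit the reference model, computes the Lung
#' Disease Index and time-constant distribution statistics per subject,
#' clusters subjects in the (median tau, sd tau) plane, and compares
#' groups (healthy vs diseased) by unpaired two-tailed t-tests on mean
#' tau and LDI.
#'
#' @param metrics_list list of endpoint metrics tables, one per subject
#' @param groups character vector (`"healthy"` / `"diseased"`) per subject
#' @param degree polynomial degree of the reference model
#' @param level prediction-interval confidence level
#' @param k number of phenotype clusters
#' @param seed seed for clustering restarts
#' @param bin_width histogram bin width (s)
#' @param t_exp expiration time used for histogram range (s)
#' @return list with `model`, `subjects` (summary data frame), `clusters`,
#'   `tests`, `histograms`
#' @export
cohort_analysis <- function(metrics_list, groups, degree = 2, level = 0.99,
                            k = 4, seed = 1L, bin_width = 0.02, t_exp = 0.3) {
  stopifnot(length(metrics_list) == length(groups))
  healthy_pool <- do.call(rbind, metrics_list[groups == "healthy"])
  if (is.null(healthy_pool) || !nrow(healthy_pool))
    stop("cohort needs at least one healthy subject to fit the reference")
  model <- fit_reference(healthy_pool, degree = degree, level = level)
  n <- length(metrics_list)
  hists <- vector("list", n)
  subjects <- do.call(rbind, lapply(seq_len(n), function(i) {
    m <- metrics_list[[i]]
    st <- distribution_stats(m$tau_exp, bin_width = bin_width, t_exp = t_exp)
    hists[[i]] <<- st
    data.frame(subject_id = i, group = groups[i],
               median_tau = st$median, sd_tau = st$sd, mean_tau = st$mean,
               ldi = lung_disease_index(m, model),
               total_volume_ul = sum(m$v_ee),
               n_endpoints = nrow(m))
  }))
  clusters <- if (n >= k) cluster_phenotypes(subjects, k = k, seed = seed)
  else NULL
  if (!is.null(clusters)) {
    subjects$cluster <- clusters$labels
    subjects$angle_from_p <- clusters$angles
  }
  tests <- NULL
  if (all(c("healthy", "diseased") %in% groups) &&
      sum(groups == "healthy") >= 2 && sum(groups == "diseased") >= 2) {
    h <- subjects$group == "healthy"
    tests <- list(
      mean_tau = compare_groups(subjects$mean_tau[h], subjects$mean_tau[!h]),
      ldi = compare_groups(subjects$ldi[h], subjects$ldi[!h]))
  }
  list(model = model, subjects = subjects, clusters = clusters,
       tests = tests, histograms = hists)
}
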