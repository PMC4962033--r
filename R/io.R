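#' Write a 4D volume series as NIfTI files with a manifest
#'
#' One NIfTI file per frame plus `manifest.csv` listing each frame's file
#' and acquisition time.
#'
#' @param volumes list of 3D arrays
#' @param frame_times frame times (s)
#' @param dir output directory (created if needed)
#' @param voxel_spacing voxel size (micrometres), stored in the NIfTI
#'   header (as millimetres) and the manifest
#' @param prefix file-name prefix
#' @return path of the manifest, invisibly
#' @export
write_volume_series <- function(volumes, frame_times, dir,
                                voxel_spacing = 1, prefix = "frame") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(length(volumes))
  for (f in seq_along(volumes)) {
    files[f] <- sprintf("%s_%03d.nii.gz", prefix, f)
    img <- RNifti::asNifti(volumes[[f]],
                           pixdim = rep(voxel_spacing / 1000, 3))
    RNifti::writeNifti(img, file.path(dir, files[f]))
  }
  manifest <- data.frame(frame = seq_along(volumes), file = files,
                         time_s = frame_times,
                         voxel_spacing_um = voxel_spacing)
  mp <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mp, row.names = FALSE)
  invisible(mp)
}

#' Read a 4D volume series from a manifest
#'
#' @param manifest_path path to a `manifest.csv` written by
#'   [write_volume_series()]
#' @return list with `volumes`, `frame_times`, `voxel_spacing`
#' @export
read_volume_series <- function(manifest_path) {
  man <- utils::read.csv(manifest_path)
  dir <- dirname(manifest_path)
  volumes <- lapply(man$file, function(f) {
    v <- RNifti::readNifti(file.path(dir, f))
    array(as.numeric(v), dim(v))
  })
  list(volumes = volumes, frame_times = man$time_s,
       voxel_spacing = man$voxel_spacing_um[1])
}

field_table <- function(field) {
  dq <- dim(field$quality)
  idx <- which(array(TRUE, dq), arr.ind = TRUE)
  data.frame(ix = idx[, 1], iy = idx[, 2], iz = idx[, 3],
             cx = field$centers[[1]][idx[, 1]],
             cy = field$centers[[2]][idx[, 2]],
             cz = field$centers[[3]][idx[, 3]],
             ux = as.vector(field$u[, , , 1]),
             uy = as.vector(field$u[, , , 2]),
             uz = as.vector(field$u[, , , 3]),
             quality = as.vector(field$quality))
}

#' Write displacement fields of a cycle as CSV
#'
#' One table with all frame pairs; grid metadata in comment header lines.
#'
#' @param fields list of `displacement_field`s (see [piv_cycle()])
#' @param path output CSV path
#' @param meta optional named list written into the header
#' @export
write_displacement_fields <- function(fields, path, meta = list()) {
  tabs <- lapply(fields, function(f) {
    tb <- field_table(f)
    cbind(frame_a = f$frame_pair[1], frame_b = f$frame_pair[2], tb)
  })
  all_tab <- do.call(rbind, tabs)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# displacement fields (voxels); window %d, spacing %d",
                     fields[[1]]$window_size, fields[[1]]$spacing), con)
  for (nm in names(meta))
    writeLines(sprintf("# %s: %s", nm, meta[[nm]]), con)
  utils::write.csv(all_tab, con, row.names = FALSE)
  invisible(path)
}

#' Write per-segment flow waveforms as tidy CSV
#'
#' @param seg_flows matrix from [propagate_flows()] (segments x times)
#' @param times interval midpoint times (s)
#' @param path output CSV path
#' @param meta optional named list written into the header
#' @export
write_flow_waveforms <- function(seg_flows, times, path, meta = list()) {
  tab <- data.frame(segment_id = rep(seq_len(nrow(seg_flows)), each = length(times)),
                    time_s = rep(times, nrow(seg_flows)),
                    flow_ul_s = as.vector(t(seg_flows)))
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(meta))
    writeLines(sprintf("# %s: %s", nm, meta[[nm]]), con)
  utils::write.csv(tab, con, row.names = FALSE)
  invisible(path)
}

#' Write a data frame as CSV with a provenance comment header
#'
#' @param df data frame
#' @param path output path
#' @param meta named list of header fields (e.g. seed, config hash)
#' @export
write_table_with_meta <- function(df, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(meta))
    writeLines(sprintf("# %s: %s", nm, meta[[nm]]), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a CSV written by [write_table_with_meta()]
#' @param path CSV path
#' @return data frame
#' @export
read_table_with_meta <- function(path) {
  utils::read.csv(path, comment.char = "#")
}
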