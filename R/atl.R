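#' Assign lung tissue to supplying airway endpoints
#'
#' Every masked grid point is assigned to the endpoint whose distal node is
#' nearest (Euclidean distance in micrometres), ties broken toward the
#' smaller endpoint id; per-endpoint supplied tissue volumes are tallied
#' from the assigned cell count.
#'
#' @param points n x 3 matrix of grid-point positions (micrometres); rows
#'   with any NA are left unassigned (index 0)
#' @param tree an `airway_tree` with at least one endpoint
#' @param cell_volume volume represented by one grid point (uL)
#' @return an object of class `region_assignment`: `endpoint_ids` (in
#'   [find_endpoints()] order), `index` (per point, position of its
#'   endpoint in `endpoint_ids`, 0 if unassigned), `volumes` (uL per
#'   endpoint), `cell_volume`
#' @export
assign_tissue <- function(points, tree, cell_volume = 1) {
  eps <- find_endpoints(tree)
  if (!length(eps)) stop("degenerate tree: no endpoints to assign tissue to")
  points <- as.matrix(points)
  tips <- t(vapply(eps, function(s) segment_tip(tree, s), numeric(3)))
  n <- nrow(points)
  best <- integer(n); bd <- rep(Inf, n)
  usable <- !apply(is.na(points), 1, any)
  for (k in seq_along(eps)) {
    d2 <- (points[, 1] - tips[k, 1])^2 + (points[, 2] - tips[k, 2])^2 +
      (points[, 3] - tips[k, 3])^2
    sel <- usable & (d2 < bd)   # strict: ties stay with the earlier k
    best[sel] <- k; bd[sel] <- d2[sel]
  }
  # ties toward the smaller endpoint *id* (not traversal position)
  ord <- order(eps)
  for (k in ord) {
    d2 <- (points[, 1] - tips[k, 1])^2 + (points[, 2] - tips[k, 2])^2 +
      (points[, 3] - tips[k, 3])^2
    tie <- usable & (d2 == bd) & (eps[best] > eps[k])
    best[tie] <- k
  }
  structure(list(endpoint_ids = eps,
                 index = best,
                 volumes = as.numeric(tabulate(best, length(eps))) * cell_volume,
                 cell_volume = cell_volume),
            class = "region_assignment")
}

#' @export
print.region_assignment <- function(x, ...) {
  cat(sprintf("Region assignment: %d endpoints, %d grid points, total volume %.3g uL\n",
              length(x$endpoint_ids), sum(x$index > 0), sum(x$volumes)))
  invisible(x)
}

#' Endpoint airflow waveforms from regional volume changes
#'
#' Regional airflow through each supplying airway is the regional tissue
#' volume change per frame interval divided by the interval duration,
#' indexed to interval midpoints. Inspiratory flow (into tissue) is
#' positive. Endpoints with a missing interval are flagged and their
#' waveform set to NA.
#'
#' @param delta_v matrix of regional volume changes (uL), endpoints x
#'   intervals, cyclic over the cycle (interval f spans frame f to f+1)
#' @param protocol a [ventilation_protocol()]
#' @param endpoint_ids endpoint ids labelling the rows
#' @return an object of class `flow_set`: `flows` (uL/s, endpoints x
#'   n_frames), `times` (midpoints, s), `endpoint_ids`, `missing` (logical)
#' @export
endpoint_flows <- function(delta_v, protocol, endpoint_ids = seq_len(nrow(delta_v))) {
  delta_v <- as.matrix(delta_v)
  if (ncol(delta_v) != protocol$n_frames)
    stop("need one volume change per frame interval")
  dt <- protocol$period / protocol$n_frames
  flows <- delta_v / dt
  miss <- apply(is.na(flows), 1, any)
  flows[miss, ] <- NA_real_
  structure(list(flows = flows, times = interval_midpoints(protocol),
                 endpoint_ids = endpoint_ids, missing = miss),
            class = "flow_set")
}

#' Propagate endpoint airflows up the airway tree by continuity
#'
#' At every bifurcation the flow through the parent segment equals the sum
#' of the flows through its daughters; starting from the endpoint flows,
#' a post-order traversal recursively sums daughter airflows so that every
#' segment of the tree (up to the trachea) carries a flow waveform.
#' Endpoints with missing waveforms are treated as zero with a warning.
#'
#' @param tree an `airway_tree`
#' @param flows a `flow_set` of endpoint waveforms (rows follow
#'   `flows$endpoint_ids`)
#' @return matrix of flow waveforms (uL/s), one row per tree segment
#' @export
propagate_flows <- function(tree, flows) {
  ns <- n_segments(tree)
  nt <- ncol(flows$flows)
  out <- matrix(0, ns, nt)
  fl <- flows$flows
  if (any(flows$missing)) {
    warning("missing endpoint waveforms treated as zero flow")
    fl[flows$missing, ] <- 0
  }
  out[flows$endpoint_ids, ] <- fl
  kids <- tree_children(tree)
  # post-order: process children before parents
  order_post <- integer(0)
  stack <- tree$root
  while (length(stack)) {
    s <- stack[length(stack)]; stack <- stack[-length(stack)]
    order_post <- c(s, order_post)
    stack <- c(stack, kids[[s]])
  }
  for (s in order_post) {
    ch <- kids[[s]]
    if (!is.null(ch) && length(ch))
      out[s, ] <- colSums(out[ch, , drop = FALSE])
  }
  rownames(out) <- seq_len(ns)
  out
}

#' Grid-point positions of a displacement/expansion grid
#'
#' Helper giving the physical positions (micrometres) of all grid points of
#' a field in array order.
#'
#' @param field a `displacement_field` or `expansion_map`
#' @param voxel_spacing voxel size (micrometres)
#' @return n x 3 matrix of positions
#' @export
grid_positions <- function(field, voxel_spacing) {
  cs <- field$centers
  nx <- length(cs[[1]]); ny <- length(cs[[2]]); nz <- length(cs[[3]])
  cbind(rep.int(cs[[1]], ny * nz),
        rep.int(rep.int(cs[[2]], rep.int(nx, ny)), nz),
        rep.int(cs[[3]], rep.int(nx * ny, nz))) |>
    (\(m) (m - 1) * voxel_spacing)()
}
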