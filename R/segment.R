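# --- voxel-graph helpers (26-connectivity on 3D grids) ---------------------

neighbor_offsets26 <- function() {
  g <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
  as.matrix(g[!(g$di == 0 & g$dj == 0 & g$dk == 0), ])
}

# shift a 3D array by (di,dj,dk), padding with `fill`
shift_array <- function(a, di, dj, dk, fill = FALSE) {
  d <- dim(a)
  out <- array(fill, d)
  sx <- max(1, 1 + di):min(d[1], d[1] + di)
  sy <- max(1, 1 + dj):min(d[2], d[2] + dj)
  sz <- max(1, 1 + dk):min(d[3], d[3] + dk)
  out[sx, sy, sz] <- a[sx - di, sy - dj, sz - dk]
  out
}

#' Flood-fill segmentation of the airway lumen
#'
#' Extracts the 26-connected component of voxels whose intensity lies in
#' `intensity_window`, starting from a seed inside the lumen. Used to
#' segment the low-intensity airway lumen from a reconstructed volume at
#' peak expiration.
#'
#' @param volume 3D array
#' @param seed_point integer length-3 voxel index (1-based)
#' @param intensity_window `c(lo, hi)` intensity range of the lumen
#' @return 3D logical mask; warns when the component touches the volume
#'   boundary (possible leak)
#' @export
flood_fill_segment <- function(volume, seed_point, intensity_window) {
  d <- dim(volume)
  seed_point <- as.integer(seed_point)
  sv <- volume[seed_point[1], seed_point[2], seed_point[3]]
  if (sv < intensity_window[1] || sv > intensity_window[2])
    stop("seed intensity outside the intensity window")
  allowed <- volume >= intensity_window[1] & volume <= intensity_window[2]
  offs <- neighbor_offsets26()
  visited <- array(FALSE, d)
  seed_idx <- seed_point[1] + (seed_point[2] - 1L) * d[1] +
    (seed_point[3] - 1L) * d[1] * d[2]
  visited[seed_idx] <- TRUE
  frontier <- seed_idx
  nxy <- d[1] * d[2]
  while (length(frontier)) {
    ci <- arrayInd(frontier, d)
    ii <- rep(ci[, 1], each = 26L) + rep_len(offs[, 1], 26L * nrow(ci))
    jj <- rep(ci[, 2], each = 26L) + rep_len(offs[, 2], 26L * nrow(ci))
    kk <- rep(ci[, 3], each = 26L) + rep_len(offs[, 3], 26L * nrow(ci))
    inb <- ii >= 1L & ii <= d[1] & jj >= 1L & jj <= d[2] & kk >= 1L & kk <= d[3]
    cand <- ii[inb] + (jj[inb] - 1L) * d[1] + (kk[inb] - 1L) * nxy
    cand <- unique(cand[allowed[cand] & !visited[cand]])
    visited[cand] <- TRUE
    frontier <- cand
  }
  ci <- which(visited)
  co <- arrayInd(ci, d)
  if (any(co == 1L) || any(sweep(co, 2, d, "==")))
    warning("segmented component touches the volume boundary (possible leak)")
  visited
}

#' Chessboard distance transform of a binary mask
#'
#' Distance (in erosion steps with a 26-neighbourhood, i.e. Chebyshev
#' metric) from each foreground voxel to the background. Used as the local
#' airway radius along the skeleton.
#'
#' @param mask 3D logical array
#' @return 3D integer array (0 outside the mask, >= 1 inside)
#' @export
dt_chessboard <- function(mask) {
  d <- array(0L, dim(mask))
  m <- mask
  offs <- neighbor_offsets26()
  while (any(m)) {
    d <- d + m
    er <- m
    for (r in seq_len(nrow(offs)))
      er <- er & shift_array(m, offs[r, 1], offs[r, 2], offs[r, 3])
    m <- er
  }
  d
}

# Dijkstra over the mask's 26-connected voxel graph with a centreness
# penalty: stepping into a voxel costs 1 + penalty * (max(dt) - dt), so
# shortest paths run along tube centres (where dt is largest) instead of
# hugging walls. Integer costs allow a Dial bucket queue. Returns the
# cost field and predecessors.
mask_dijkstra <- function(mask, root_idx, dt, penalty = 4L) {
  d <- dim(mask)
  offs <- neighbor_offsets26()
  nxy <- d[1] * d[2]
  rmax <- max(dt)
  wcost <- array(1L, d)
  wcost[mask] <- 1L + penalty * (rmax - dt[mask])
  dist <- array(.Machine$integer.max, d)
  pred <- array(0L, d)
  dist[root_idx] <- 0L
  buckets <- list()
  buckets[[1]] <- root_idx   # bucket b holds voxels with dist == b-1
  b <- 1L
  while (b <= length(buckets)) {
    cur <- buckets[[b]]
    buckets[b] <- list(NULL)
    if (!is.null(cur)) {
      cur <- cur[dist[cur] == b - 1L]    # lazy deletion
      if (length(cur)) {
        ci <- arrayInd(cur, d)
        src <- rep(cur, each = 26L)
        ii <- rep(ci[, 1], each = 26L) + rep_len(offs[, 1], 26L * nrow(ci))
        jj <- rep(ci[, 2], each = 26L) + rep_len(offs[, 2], 26L * nrow(ci))
        kk <- rep(ci[, 3], each = 26L) + rep_len(offs[, 3], 26L * nrow(ci))
        inb <- ii >= 1L & ii <= d[1] & jj >= 1L & jj <= d[2] &
          kk >= 1L & kk <= d[3]
        cand <- ii[inb] + (jj[inb] - 1L) * d[1] + (kk[inb] - 1L) * nxy
        src <- src[inb]
        nd <- (b - 1L) + wcost[cand]
        keep <- mask[cand] & nd < dist[cand]
        cand <- cand[keep]; src <- src[keep]; nd <- nd[keep]
        if (length(cand)) {
          ord <- order(cand, nd)
          cand <- cand[ord]; src <- src[ord]; nd <- nd[ord]
          first <- !duplicated(cand)
          cand <- cand[first]; src <- src[first]; nd <- nd[first]
          dist[cand] <- nd
          pred[cand] <- src
          for (lv in unique(nd)) {
            bi <- lv + 1L
            if (bi > length(buckets)) buckets[[bi]] <- integer(0)
            buckets[[bi]] <- c(buckets[[bi]], cand[nd == lv])
          }
        }
      }
    }
    b <- b + 1L
  }
  list(dist = dist, pred = pred)
}

# breadth-first search over a mask from a root voxel; returns hop distance
# and predecessor (linear indices; 0 where unreached)
mask_bfs <- function(mask, root_idx) {
  d <- dim(mask)
  offs <- neighbor_offsets26()
  nxy <- d[1] * d[2]
  dist <- array(-1L, d)
  pred <- array(0L, d)
  dist[root_idx] <- 0L
  frontier <- root_idx
  lvl <- 0L
  while (length(frontier)) {
    lvl <- lvl + 1L
    ci <- arrayInd(frontier, d)
    src <- rep(frontier, each = 26L)
    ii <- rep(ci[, 1], each = 26L) + rep_len(offs[, 1], 26L * nrow(ci))
    jj <- rep(ci[, 2], each = 26L) + rep_len(offs[, 2], 26L * nrow(ci))
    kk <- rep(ci[, 3], each = 26L) + rep_len(offs[, 3], 26L * nrow(ci))
    inb <- ii >= 1L & ii <= d[1] & jj >= 1L & jj <= d[2] & kk >= 1L & kk <= d[3]
    cand <- ii[inb] + (jj[inb] - 1L) * d[1] + (kk[inb] - 1L) * nxy
    src <- src[inb]
    keep <- mask[cand] & dist[cand] < 0L
    cand <- cand[keep]; src <- src[keep]
    if (length(cand)) {
      first <- !duplicated(cand)
      cand <- cand[first]; src <- src[first]
      dist[cand] <- lvl
      pred[cand] <- src
    }
    frontier <- cand
  }
  list(dist = dist, pred = pred)
}

#' Skeletonize a binary airway mask into a rooted tree graph
#'
#' Extracts a centreline tree by geodesic farthest-point tracing: starting
#' from the root (the mask voxel nearest `root_hint`), the farthest
#' uncovered voxel (by 26-connected hop distance) is traced back to the
#' existing skeleton, the new branch added, and mask voxels within the
#' local radius of the branch marked covered; this repeats until the whole
#' mask is covered. Chains are split into segments at junctions, and leaf
#' segments shorter than `prune_factor` times the local radius at their
#' attachment are pruned. Per-node radius is the chessboard
#' distance-transform value.
#'
#' @param mask 3D logical array (one connected component)
#' @param root_hint integer length-3 voxel index near the tracheal opening
#' @param voxel_spacing voxel size (micrometres) for node positions/radii
#' @param prune_factor leaf segments shorter than `prune_factor * radius`
#'   at their attachment are removed (default 2)
#' @param max_branches safety cap on traced branches
#' @return an `airway_tree`; a single-segment result has zero endpoints
#'   and carries attribute `degenerate = TRUE` on [find_endpoints()]
#' @export
skeletonize_to_graph <- function(mask, root_hint, voxel_spacing = 1,
                                 prune_factor = 2, max_branches = 1000L) {
  d <- dim(mask)
  nxy <- d[1] * d[2]
  vox <- which(mask)
  if (!length(vox)) stop("empty mask")
  co <- arrayInd(vox, d)
  rh <- as.numeric(root_hint)
  root_idx <- vox[which.min((co[, 1] - rh[1])^2 + (co[, 2] - rh[2])^2 +
                              (co[, 3] - rh[3])^2)]
  bfs <- mask_bfs(mask, root_idx)
  if (any(bfs$dist[vox] < 0L))
    warning("mask is not a single connected component; using the root component")
  dt <- dt_chessboard(mask)
  dij <- mask_dijkstra(mask, root_idx, dt)
  offs <- neighbor_offsets26()

  covered <- !mask
  in_skel <- array(FALSE, d)
  chains <- list()

  propagate_cover <- function(chain) {
    budget <- array(-1L, d)
    # generous coverage radius: voxels within 2 r + 3 of the centreline
    # belong to the branch's tube (under-coverage spawns parallel duplicate
    # centrelines along the same airway)
    budget[chain] <- as.integer(ceiling(2 * dt[chain])) + 3L
    frontier <- chain
    repeat {
      ci <- arrayInd(frontier, d)
      bsrc <- rep(budget[frontier] - 1L, each = 26L)
      ii <- rep(ci[, 1], each = 26L) + rep_len(offs[, 1], 26L * nrow(ci))
      jj <- rep(ci[, 2], each = 26L) + rep_len(offs[, 2], 26L * nrow(ci))
      kk <- rep(ci[, 3], each = 26L) + rep_len(offs[, 3], 26L * nrow(ci))
      inb <- ii >= 1L & ii <= d[1] & jj >= 1L & jj <= d[2] & kk >= 1L & kk <= d[3]
      cand <- ii[inb] + (jj[inb] - 1L) * d[1] + (kk[inb] - 1L) * nxy
      bsrc <- bsrc[inb]
      keep <- mask[cand] & bsrc > budget[cand] & bsrc >= 0L
      cand <- cand[keep]; bsrc <- bsrc[keep]
      if (!length(cand)) break
      ord <- order(cand, -bsrc)
      cand <- cand[ord]; bsrc <- bsrc[ord]
      first <- !duplicated(cand)
      cand <- cand[first]; bsrc <- bsrc[first]
      budget[cand] <- bsrc
      frontier <- cand
    }
    covered <<- covered | budget >= 0L
  }

  # first branch: root to the farthest voxel
  n_br <- 0L
  repeat {
    unc <- which(!covered & bfs$dist >= 0L)
    if (!length(unc) || n_br >= max_branches) break
    tip <- unc[which.max(bfs$dist[unc])]
    # trace back along centred (Dijkstra) predecessors to the skeleton
    # (or to the root for the first branch)
    path <- tip
    v <- tip
    while (!in_skel[v] && v != root_idx) {
      v <- dij$pred[v]
      path <- c(path, v)
    }
    path <- rev(path)  # from attachment (or root) to tip
    if (length(path) < 2 && n_br > 0L) { covered[tip] <- TRUE; next }
    in_skel[path] <- TRUE
    chains[[length(chains) + 1L]] <- path
    propagate_cover(path)
    n_br <- n_br + 1L
  }

  # node-level adjacency of the skeleton
  skel_vox <- which(in_skel)
  id_of <- new.env(hash = TRUE, size = length(skel_vox))
  for (i in seq_along(skel_vox)) assign(as.character(skel_vox[i]), i, envir = id_of)
  nid <- function(v) get(as.character(v), envir = id_of)
  adj <- vector("list", length(skel_vox))
  add_edge <- function(a, b) {
    ia <- nid(a); ib <- nid(b)
    if (!(ib %in% adj[[ia]])) { adj[[ia]] <<- c(adj[[ia]], ib); adj[[ib]] <<- c(adj[[ib]], ia) }
  }
  for (ch in chains)
    for (i in seq_len(length(ch) - 1L)) add_edge(ch[i], ch[i + 1L])

  # walk from the root, splitting chains at junctions
  root_id <- nid(root_idx)
  coords <- arrayInd(skel_vox, d)
  seg_parent <- integer(0); seg_paths <- list()
  visited_n <- logical(length(skel_vox))
  walk <- function(par_seg, start_ids) {
    chain <- start_ids
    repeat {
      last <- chain[length(chain)]
      visited_n[last] <<- TRUE
      nxt <- setdiff(adj[[last]], which(visited_n))
      # drop neighbours already inside the chain (diagonal double-links)
      nxt <- setdiff(nxt, chain)
      if (length(nxt) == 1L) { chain <- c(chain, nxt); next }
      seg_parent[length(seg_parent) + 1L] <<- par_seg
      seg_paths[[length(seg_parent)]] <<- chain
      seg <- length(seg_parent)
      for (b in nxt) { visited_n[b] <<- TRUE; walk(seg, c(last, b)) }
      return(invisible())
    }
  }
  visited_n[root_id] <- TRUE
  walk(NA_integer_, root_id)

  # prune short leaf segments, merging pass-through junctions afterwards
  repeat {
    kids <- split(seq_along(seg_parent)[-1][!is.na(seg_parent[-1])],
                  seg_parent[-1][!is.na(seg_parent[-1])])
    n_kids <- integer(length(seg_parent))
    n_kids[as.integer(names(kids))] <- lengths(kids)
    seg_len <- vapply(seg_paths, function(p) {
      if (length(p) < 2) return(0)
      sum(sqrt(rowSums((coords[p[-1], , drop = FALSE] -
                          coords[p[-length(p)], , drop = FALSE])^2)))
    }, numeric(1))
    leaf <- which(n_kids == 0 & !is.na(seg_parent))
    att_r <- vapply(leaf, function(s) dt[skel_vox[seg_paths[[s]][1]]], numeric(1))
    short <- leaf[seg_len[leaf] < prune_factor * att_r + 2]
    if (!length(short)) break
    keep <- setdiff(seq_along(seg_parent), short)
    remap <- match(seq_along(seg_parent), keep)
    seg_parent <- seg_parent[keep]
    seg_parent <- ifelse(is.na(seg_parent), NA_integer_, remap[seg_parent])
    seg_paths <- seg_paths[keep]
    # merge parents left with a single daughter
    repeat {
      tab <- table(seg_parent[!is.na(seg_parent)])
      single <- as.integer(names(tab)[tab == 1])
      merged <- FALSE
      for (p in single) {
        child <- which(!is.na(seg_parent) & seg_parent == p)
        if (length(child) != 1) next
        seg_paths[[p]] <- c(seg_paths[[p]], seg_paths[[child]][-1])
        gkids <- which(!is.na(seg_parent) & seg_parent == child)
        seg_parent[gkids] <- p
        keep2 <- setdiff(seq_along(seg_parent), child)
        remap2 <- match(seq_along(seg_parent), keep2)
        seg_parent <- seg_parent[keep2]
        seg_parent <- ifelse(is.na(seg_parent), NA_integer_, remap2[seg_parent])
        seg_paths <- seg_paths[keep2]
        merged <- TRUE
        break
      }
      if (!merged) break
    }
  }

  used <- sort(unique(unlist(seg_paths)))
  node_map <- match(seq_along(skel_vox), used)
  nodes <- data.frame(id = seq_along(used),
                      x = (coords[used, 1] - 1) * voxel_spacing,
                      y = (coords[used, 2] - 1) * voxel_spacing,
                      z = (coords[used, 3] - 1) * voxel_spacing,
                      radius = dt[skel_vox[used]] * voxel_spacing)
  paths2 <- lapply(seg_paths, function(p) node_map[p])
  airway_tree(nodes, seg_parent, paths2)
}
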