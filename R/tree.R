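#' Airway tree objects
#'
#' An `airway_tree` is a rooted branching graph of airway segments. Nodes
#' carry 3D positions (micrometres) and local radii; each segment is an
#' ordered path of nodes from its proximal to its distal end, and every
#' non-root segment has exactly one parent. The root segment is the trachea.
#' An *endpoint* is a segment that has a parent but no daughters - the most
#' distal segmentable airway, each supplying a region of lung tissue.
#'
#' @param nodes data frame with columns `id`, `x`, `y`, `z`, `radius`
#' @param parent integer vector of parent segment ids (NA for the root)
#' @param paths list (one element per segment) of node-id vectors, ordered
#'   proximal to distal
#' @return an object of class `airway_tree`
#' @export
airway_tree <- function(nodes, parent, paths) {
  n <- length(parent)
  stopifnot(length(paths) == n, all(!is.na(nodes$x)))
  root <- which(is.na(parent))
  if (length(root) != 1) stop("tree must have exactly one root segment")
  # acyclicity / reachability
  kids <- split(seq_len(n)[-root], parent[-root])
  seen <- logical(n); stack <- root
  while (length(stack)) {
    s <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (seen[s]) stop("cycle detected in segment graph")
    seen[s] <- TRUE
    ch <- kids[[as.character(s)]]
    if (!is.null(ch)) stack <- c(stack, ch)
  }
  if (!all(seen)) stop("segments disconnected from root")
  structure(list(nodes = nodes, parent = parent, paths = paths,
                 root = root), class = "airway_tree")
}

#' @export
print.airway_tree <- function(x, ...) {
  eps <- find_endpoints(x)
  cat(sprintf("Airway tree: %d segments, %d nodes, %d endpoints\n",
              length(x$parent), nrow(x$nodes), length(eps)))
  invisible(x)
}

#' Number of segments in an airway tree
#' @param tree an `airway_tree`
#' @return integer count
#' @export
n_segments <- function(tree) length(tree$parent)

tree_children <- function(tree) {
  n <- n_segments(tree)
  kids <- vector("list", n)
  for (s in seq_len(n)) {
    p <- tree$parent[s]
    if (!is.na(p)) kids[[p]] <- c(kids[[p]], s)
  }
  kids
}

#' Distal node position of a segment
#' @param tree an `airway_tree`
#' @param segment segment id
#' @return numeric length-3 position (micrometres)
#' @export
segment_tip <- function(tree, segment) {
  nid <- tree$paths[[segment]][length(tree$paths[[segment]])]
  unlist(tree$nodes[match(nid, tree$nodes$id), c("x", "y", "z")], use.names = FALSE)
}

#' Endpoints of an airway tree
#'
#' Endpoints are segments with a parent but no daughters. The order is
#' deterministic: depth-first from the root, daughters visited in
#' lexicographic order of their distal-node positions. A single-segment
#' (root-only) tree has no endpoints and is flagged degenerate.
#'
#' @param tree an `airway_tree`
#' @return integer vector of endpoint segment ids; attribute `degenerate`
#'   is TRUE when the tree has a root but no endpoints
#' @export
find_endpoints <- function(tree) {
  kids <- tree_children(tree)
  out <- integer(0)
  visit <- function(s) {
    ch <- kids[[s]]
    if (is.null(ch) || !length(ch)) {
      if (!is.na(tree$parent[s])) out <<- c(out, s)
      return(invisible())
    }
    tips <- lapply(ch, function(c2) segment_tip(tree, c2))
    ord <- do.call(order, as.data.frame(do.call(rbind, tips)))
    for (c2 in ch[ord]) visit(c2)
  }
  visit(tree$root)
  structure(out, degenerate = length(out) == 0L)
}

norm3 <- function(v) sqrt(sum(v^2))
unit3 <- function(v) v / norm3(v)
cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])

perp_basis <- function(d) {
  u <- if (abs(d[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  p1 <- unit3(cross3(d, u))
  list(p1 = p1, p2 = cross3(d, p1))
}

#' Generate a synthetic bifurcating airway tree
#'
#' Builds a rooted binary tree inside a rectangular domain: the trachea
#' descends from the top face and each generation bifurcates symmetrically
#' at `branch_angle` with daughter lengths scaled by `length_ratio`, the
#' bifurcation plane rotating by the golden angle each generation (with
#' seeded jitter). Alternatively, when `targets` is supplied, the recursion
#' splits the target set and terminates one leaf exactly at each target
#' position, so airway tips can be matched to prescribed compartment
#' centres; `n_generations` is then ignored except for validation.
#'
#' @param n_generations number of bifurcation generations (>= 1); the tree
#'   has `2^n_generations` endpoints
#' @param branch_angle half-angle between daughters (radians)
#' @param length_ratio daughter/parent length ratio
#' @param domain 2 x 3 matrix `rbind(lower, upper)` of the bounding box
#'   (micrometres)
#' @param seed integer seed for azimuthal jitter
#' @param targets optional n x 3 matrix of endpoint positions (micrometres)
#' @param trunk_fraction trachea length as a fraction of the domain height
#' @param radius0 trachea radius (micrometres); daughters shrink by 0.78 per
#'   generation
#' @param jitter sd of angular jitter (radians)
#' @return an `airway_tree`
#' @export
generate_tree <- function(n_generations, branch_angle = 0.6,
                          length_ratio = 0.75,
                          domain = rbind(c(0, 0, 0), c(1000, 1000, 1000)),
                          seed = 1L, targets = NULL,
                          trunk_fraction = 0.25, radius0 = NULL,
                          jitter = 0.05) {
  if (is.null(targets) && n_generations < 1)
    stop("degenerate tree: n_generations must be at least 1")
  lo <- domain[1, ]; hi <- domain[2, ]
  ext <- hi - lo
  if (is.null(radius0)) radius0 <- 0.045 * min(ext)

  nodes <- list()   # rows id,x,y,z,radius
  parent <- integer(0)
  paths <- list()
  nid <- 0L
  add_node <- function(pos, radius) {
    nid <<- nid + 1L
    nodes[[nid]] <<- c(nid, pos, radius)
    nid
  }
  add_segment <- function(par, n_from, n_to) {
    parent[length(parent) + 1L] <<- par
    paths[[length(parent)]] <<- c(n_from, n_to)
    length(parent)
  }

  if (is.null(targets)) {
    ngen <- as.integer(n_generations)
    start <- c(lo[1] + ext[1] / 2, lo[2] + ext[2] / 2, hi[3])
    dir0 <- c(0, 0, -1)
    L0 <- trunk_fraction * ext[3]
    rng <- with_seed(seed, stats::rnorm(ngen, 0, jitter))
    golden <- pi * (3 - sqrt(5))
    n_start <- add_node(start, radius0)
    n_tr <- add_node(start + L0 * dir0, radius0)
    s_root <- add_segment(NA_integer_, n_start, n_tr)
    recurse <- function(seg, node_id, pos, dir, g, radius) {
      if (g > ngen) return(invisible())
      L <- L0 * length_ratio^g
      phi <- g * golden + rng[g]
      b <- perp_basis(dir)
      e <- cos(phi) * b$p1 + sin(phi) * b$p2
      for (sgn in c(-1, 1)) {
        d <- unit3(cos(branch_angle) * dir + sgn * sin(branch_angle) * e)
        p2 <- pos + L * d
        n2 <- add_node(p2, radius * 0.78)
        s2 <- add_segment(seg, node_id, n2)
        recurse(s2, n2, p2, d, g + 1L, radius * 0.78)
      }
    }
    recurse(s_root, n_tr, start + L0 * dir0, dir0, 1L, radius0)
  } else {
    targets <- as.matrix(targets)
    if (nrow(targets) < 2) stop("need at least 2 targets")
    cen <- colMeans(targets)
    start <- c(cen[1], cen[2], hi[3])
    tv <- c(cen[1], cen[2], max(targets[, 3])) - start
    # keep every internal segment at least ~4 radii long so the bifurcation
    # spacing stays resolvable by centreline extraction (airways are a few
    # diameters long); never overshoot 90% of the way to the aim point
    step_frac <- function(aim_len, radius, frac) {
      if (aim_len <= 0) return(frac)
      min(max(frac, 4 * radius / aim_len), 0.9)
    }
    trunk_end <- start + step_frac(norm3(tv), radius0, trunk_fraction) * tv
    n_start <- add_node(start, radius0)
    n_tr <- add_node(trunk_end, radius0)
    s_root <- add_segment(NA_integer_, n_start, n_tr)
    recurse_t <- function(seg, node_id, pos, tg, radius) {
      spread <- apply(tg, 2, function(v) diff(range(v)))
      ax <- which.max(spread)
      ord <- order(tg[, ax])
      h1 <- ord[seq_len(floor(length(ord) / 2))]
      groups <- list(tg[h1, , drop = FALSE], tg[-h1, , drop = FALSE])
      for (grp in groups) {
        if (nrow(grp) == 1) {
          n2 <- add_node(grp[1, ], radius * 0.78)
          add_segment(seg, node_id, n2)
        } else {
          d <- colMeans(grp) - pos
          wp <- pos + step_frac(norm3(d), radius * 0.78, 0.5) * d
          n2 <- add_node(wp, radius * 0.78)
          s2 <- add_segment(seg, node_id, n2)
          recurse_t(s2, n2, wp, grp, radius * 0.78)
        }
      }
    }
    recurse_t(s_root, n_tr, trunk_end, targets, radius0)
  }

  nd <- as.data.frame(do.call(rbind, nodes))
  names(nd) <- c("id", "x", "y", "z", "radius")
  pos <- as.matrix(nd[, c("x", "y", "z")])
  inside <- pos[, 1] >= lo[1] & pos[, 1] <= hi[1] &
    pos[, 2] >= lo[2] & pos[, 2] <= hi[2] &
    pos[, 3] >= lo[3] & pos[, 3] <= hi[3]
  if (!all(inside)) stop("generated tree does not fit inside the domain")
  airway_tree(nd, parent, paths)
}

#' Segment-level summary table
#'
#' @param tree an `airway_tree`
#' @return data frame with `segment_id`, `parent_id`, `endpoint`
#' @export
as_segment_table <- function(tree) {
  eps <- find_endpoints(tree)
  data.frame(segment_id = seq_along(tree$parent),
             parent_id = tree$parent,
             endpoint = seq_along(tree$parent) %in% eps)
}

#' Write an airway tree in SWC format
#'
#' One row per node: `id type x y z radius parent`, parent -1 at the root.
#'
#' @param tree an `airway_tree`
#' @param path output file
#' @export
write_swc <- function(tree, path) {
  np <- rep(-1L, nrow(tree$nodes))
  for (s in seq_along(tree$paths)) {
    p <- tree$paths[[s]]
    if (length(p) > 1)
      np[match(p[-1], tree$nodes$id)] <- p[-length(p)]
  }
  df <- data.frame(id = tree$nodes$id, type = 2L,
                   x = tree$nodes$x, y = tree$nodes$y, z = tree$nodes$z,
                   radius = tree$nodes$radius, parent = np)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# SWC airway tree (id type x y z radius parent)", con)
  utils::write.table(df, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an SWC file into an airway tree
#'
#' Node chains are split into segments at branch points; the node with
#' parent -1 roots the tree.
#'
#' @param path SWC file
#' @return an `airway_tree`
#' @export
read_swc <- function(path) {
  df <- utils::read.table(path, comment.char = "#",
                          col.names = c("id", "type", "x", "y", "z", "radius", "parent"))
  nodes <- df[, c("id", "x", "y", "z", "radius")]
  kids <- split(df$id, factor(df$parent, levels = df$id))
  root_node <- df$id[df$parent == -1]
  if (length(root_node) != 1) stop("SWC must have exactly one root node")
  parent <- integer(0); paths <- list()
  walk <- function(par_seg, from) {
    repeat {
      chain <- from
      ch <- kids[[as.character(chain[length(chain)])]]
      while (!is.null(ch) && length(ch) == 1) {
        chain <- c(chain, ch)
        ch <- kids[[as.character(ch)]]
      }
      parent[length(parent) + 1L] <<- par_seg
      paths[[length(parent)]] <<- chain
      seg <- length(parent)
      if (is.null(ch) || !length(ch)) return(invisible())
      for (c2 in ch) walk(seg, c(chain[length(chain)], c2))
      return(invisible())
    }
  }
  walk(NA_integer_, root_node)
  airway_tree(nodes, parent, paths)
}
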