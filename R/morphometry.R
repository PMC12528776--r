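# Skeleton-based branch morphometry: centerline extraction, branch graph,
# generation-percentage classes, length, tortuosity and branching angles.

#' Skeletonize an airway mask
#'
#' Topology-preserving 3D thinning of the largest 26-connected component to
#' a one-voxel-wide centerline (endpoints preserved).
#'
#' @param airway a `binary_mask`.
#' @return A `binary_mask` holding the skeleton.
#' @export
skeletonize_airway <- function(airway) {
  grid <- airway$grid
  comp <- largest_component(airway$voxels, grid)
  sk <- .thin3d(comp$voxels, grid$shape)
  binary_mask(array(sk, dim = grid$shape), grid)
}

# 26-neighbour adjacency among a set of voxels given as (iz, iy, ix) rows
skeleton_adjacency <- function(coords, shape) {
  nz <- shape[1]; ny <- shape[2]; nx <- shape[3]
  lin <- coords[, 1] + nz * ((coords[, 2] - 1L) + ny * (coords[, 3] - 1L))
  ord <- order(lin)
  off <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  off <- off[!(off$dz == 0 & off$dy == 0 & off$dx == 0), ]
  nb <- vector("list", nrow(coords))
  for (k in seq_len(nrow(off))) {
    zz <- coords[, 1] + off$dz[k]
    yy <- coords[, 2] + off$dy[k]
    xx <- coords[, 3] + off$dx[k]
    ok <- zz >= 1L & zz <= nz & yy >= 1L & yy <= ny & xx >= 1L & xx <= nx
    cand <- rep(NA_integer_, nrow(coords))
    cand[ok] <- match(zz[ok] + nz * ((yy[ok] - 1L) + ny * (xx[ok] - 1L)), lin)
    hit <- which(!is.na(cand))
    for (i in hit) nb[[i]] <- c(nb[[i]], cand[i])
  }
  nb
}

#' Build a rooted airway graph from a skeleton
#'
#' Junction voxels (>= 3 skeleton neighbours) are clustered into nodes,
#' endpoint voxels become leaf/root nodes, and the degree-2 chains between
#' them become branches. The tree is rooted at the most superior endpoint
#' (the top of the trachea) and generations are assigned by edge depth
#' (trachea = 0). Spurious leaf branches shorter than `prune_mm` are pruned
#' and pass-through nodes merged, a standard cleanup for thinning artifacts.
#' Cycles (rare thinning artifacts) are broken at the back edge with a
#' warning.
#'
#' @param skeleton a `binary_mask` from [skeletonize_airway()].
#' @param prune_mm prune threshold for leaf twigs (mm); 0 disables.
#' @param k centerline samples used for branch direction vectors.
#' @return An `airway_graph`: `branches` data frame (id, parent, gen,
#'   length_mm, tortuosity, angle_to_parent_deg, sibling_angle_deg, n_points)
#'   and `points` (list of n x 3 mm matrices, columns z, y, x).
#' @export
build_graph <- function(skeleton, prune_mm = 3, k = 5L) {
  grid <- skeleton$grid
  coords <- which(skeleton$voxels, arr.ind = TRUE)
  if (nrow(coords) < 2L)
    airtree_error("skeleton has fewer than 2 voxels", "airtree_empty_mask")
  nb <- skeleton_adjacency(coords, grid$shape)
  deg <- lengths(nb)
  m <- nrow(coords)

  # node assignment: endpoints singleton nodes, junction voxels clustered
  is_junction <- deg >= 3L
  node_of <- rep(NA_integer_, m)
  n_nodes <- 0L
  if (any(is_junction)) {
    jidx <- which(is_junction)
    seen <- logical(m)
    for (s in jidx) {
      if (seen[s]) next
      n_nodes <- n_nodes + 1L
      stack <- s; seen[s] <- TRUE
      while (length(stack)) {
        v <- stack[[1]]; stack <- stack[-1]
        node_of[v] <- n_nodes
        for (u in nb[[v]]) if (is_junction[u] && !seen[u]) {
          seen[u] <- TRUE; stack <- c(stack, u)
        }
      }
    }
  }
  for (s in which(deg == 1L)) {
    n_nodes <- n_nodes + 1L
    node_of[s] <- n_nodes
  }
  if (all(is.na(node_of)))
    airtree_error("skeleton is a closed loop with no endpoints",
                  "airtree_bad_skeleton")

  # trace branches between nodes through degree-2 chains
  used_step <- new.env(hash = TRUE)
  step_key <- function(a, b) paste0(a, ":", b)
  raw_branches <- list()
  for (v in which(!is.na(node_of))) {
    for (u in nb[[v]]) {
      if (!is.na(node_of[u]) && node_of[u] == node_of[v]) next
      if (!is.null(used_step[[step_key(v, u)]])) next
      path <- c(v, u)
      prev <- v; cur <- u
      while (is.na(node_of[cur])) {
        nxt <- setdiff(nb[[cur]], prev)
        # drop neighbours already on the path (tight-turn chains)
        nxt <- setdiff(nxt, path)
        if (length(nxt) == 0L) { cur <- NA_integer_; break }
        prev <- cur; cur <- nxt[1]
        path <- c(path, cur)
      }
      if (is.na(cur)) next   # dangling chain, already ends at an endpoint voxel
      used_step[[step_key(v, u)]] <- TRUE
      used_step[[step_key(cur, path[length(path) - 1L])]] <- TRUE
      raw_branches[[length(raw_branches) + 1L]] <-
        list(a = node_of[v], b = node_of[cur], path = path)
    }
  }
  if (!length(raw_branches))
    airtree_error("no branches traced from the skeleton", "airtree_bad_skeleton")

  # root: most superior endpoint voxel (fall back to any node voxel)
  ep <- which(deg == 1L)
  if (!length(ep)) ep <- which(!is.na(node_of))
  root_voxel <- ep[which.min(coords[ep, 1])]
  root_node <- node_of[root_voxel]

  # orient branches by BFS from the root over the node graph
  nbr_branches <- vector("list", n_nodes)
  for (i in seq_along(raw_branches)) {
    br <- raw_branches[[i]]
    nbr_branches[[br$a]] <- c(nbr_branches[[br$a]], i)
    nbr_branches[[br$b]] <- c(nbr_branches[[br$b]], i)
  }
  visited_node <- logical(n_nodes)
  visited_branch <- logical(length(raw_branches))
  oriented <- list()
  queue <- list(list(node = root_node, parent_branch = 0L))
  visited_node[root_node] <- TRUE
  n_cycles <- 0L
  while (length(queue)) {
    cur <- queue[[1]]; queue <- queue[-1]
    for (bi in nbr_branches[[cur$node]]) {
      if (visited_branch[bi]) next
      br <- raw_branches[[bi]]
      other <- if (br$a == cur$node) br$b else br$a
      visited_branch[bi] <- TRUE
      if (visited_node[other]) { n_cycles <- n_cycles + 1L; next }
      visited_node[other] <- TRUE
      path <- br$path
      if (node_of[path[1]] != cur$node || is.na(node_of[path[1]])) path <- rev(path)
      oriented[[length(oriented) + 1L]] <-
        list(id = length(oriented) + 1L, parent = cur$parent_branch,
             from = cur$node, to = other, path = path)
      queue[[length(queue) + 1L]] <-
        list(node = other, parent_branch = length(oriented))
    }
  }
  if (n_cycles > 0L)
    warning(sprintf("%d skeleton cycle(s) broken during graph construction",
                    n_cycles))

  sp <- grid$spacing
  pts <- lapply(oriented, function(b)
    cbind(z = (coords[b$path, 1] - 1) * sp[1],
          y = (coords[b$path, 2] - 1) * sp[2],
          x = (coords[b$path, 3] - 1) * sp[3]))
  parent <- vapply(oriented, function(b) b$parent, integer(1))

  tree <- prune_and_merge(pts, parent, prune_mm)
  finalize_graph(tree$pts, tree$parent, k)
}

polyline_length <- function(P) {
  if (nrow(P) < 2L) return(0)
  sum(sqrt(rowSums((P[-1, , drop = FALSE] - P[-nrow(P), , drop = FALSE])^2)))
}

smooth_polyline <- function(P, h = 2L) {
  n <- nrow(P)
  if (n <= 2L) return(P)
  out <- P
  for (i in 2:(n - 1L)) {
    w <- max(1L, i - h):min(n, i + h)
    out[i, ] <- colMeans(P[w, , drop = FALSE])
  }
  out
}

# prune short leaf twigs, then merge pass-through chains of branches
prune_and_merge <- function(pts, parent, prune_mm) {
  repeat {
    n <- length(pts)
    children <- lapply(seq_len(n), function(i) which(parent == i))
    is_leaf <- lengths(children) == 0L
    len <- vapply(pts, polyline_length, numeric(1))
    drop <- which(is_leaf & len < prune_mm & parent > 0L)
    # never drop all children of a node at once in a way that leaves none:
    # dropping twigs is safe because merging below restores pass-throughs
    if (!length(drop)) break
    keep <- setdiff(seq_len(n), drop)
    remap <- match(seq_len(n), keep)
    pts <- pts[keep]
    parent <- vapply(parent[keep], function(p) if (p > 0L) remap[p] else 0L,
                     integer(1))
    # merge branches whose parent now has a single child
    repeat {
      n2 <- length(pts)
      nchild <- tabulate(parent[parent > 0L], nbins = n2)
      merge_child <- which(parent > 0L & nchild[pmax(parent, 1L)] == 1L &
                             parent != seq_len(n2))
      # only merge when the child's parent is itself not the root pseudo-node
      if (!length(merge_child)) break
      ci <- merge_child[1]
      pi <- parent[ci]
      pts[[pi]] <- rbind(pts[[pi]], pts[[ci]][-1, , drop = FALSE])
      keep2 <- setdiff(seq_len(n2), ci)
      remap2 <- match(seq_len(n2), keep2)
      parent[parent == ci] <- NA_integer_   # children of ci reattach to pi
      newpar <- parent
      newpar[is.na(newpar)] <- pi
      pts <- pts[keep2]
      parent <- vapply(newpar[keep2], function(p) if (p > 0L) remap2[p] else 0L,
                       integer(1))
    }
  }
  list(pts = pts, parent = parent)
}

# Direction over k centerline samples, skipping `skip` points next to the
# node: the skeleton of two merging tubes stays fused for roughly one tube
# radius past the geometric junction, and those catch-up voxels bias angles.
branch_direction <- function(P, at = c("start", "end"), k = 5L, skip = 3L) {
  at <- match.arg(at)
  n <- nrow(P)
  if (at == "start") {
    s <- min(skip + 1L, n - 1L)
    e <- min(s + k, n)
  } else {
    e <- max(n - skip, 2L)
    s <- max(e - k, 1L)
  }
  v <- P[e, ] - P[s, ]
  nv <- sqrt(sum(v^2))
  if (nv == 0) return(c(NA_real_, NA_real_, NA_real_))
  v / nv
}

angle_deg <- function(u, v) {
  if (anyNA(u) || anyNA(v)) return(NA_real_)
  acos(min(1, max(-1, sum(u * v)))) * 180 / pi
}

finalize_graph <- function(pts, parent, k = 5L) {
  n <- length(pts)
  pts_s <- lapply(pts, smooth_polyline)
  len <- vapply(pts_s, polyline_length, numeric(1))
  chord <- vapply(pts_s, function(P)
    sqrt(sum((P[nrow(P), ] - P[1, ])^2)), numeric(1))
  tort <- ifelse(chord > 0, len / chord, NA_real_)
  short <- sum(vapply(pts, nrow, integer(1)) < k)
  if (short > 0L)
    warning(sprintf("%d branch(es) shorter than %d centerline points; directions use all available points",
                    short, k))
  gen <- integer(n)
  ord <- integer(0)
  queue <- which(parent == 0L)
  gen[queue] <- 0L
  while (length(queue)) {
    b <- queue[1]; queue <- queue[-1]
    ord <- c(ord, b)
    ch <- which(parent == b)
    gen[ch] <- gen[b] + 1L
    queue <- c(queue, ch)
  }
  dir_start <- t(vapply(pts_s, branch_direction, numeric(3), at = "start", k = k))
  dir_end <- t(vapply(pts_s, branch_direction, numeric(3), at = "end", k = k))
  ang_par <- rep(NA_real_, n)
  sib <- rep(NA_real_, n)
  for (b in seq_len(n)) {
    if (parent[b] > 0L)
      ang_par[b] <- angle_deg(dir_end[parent[b], ], dir_start[b, ])
  }
  for (p in seq_len(n)) {
    ch <- which(parent == p)
    if (length(ch) == 2L) {
      a <- angle_deg(dir_start[ch[1], ], dir_start[ch[2], ])
      sib[ch] <- a
    }
  }
  branches <- data.frame(
    id = seq_len(n),
    parent = ifelse(parent > 0L, parent, NA_integer_),
    gen = gen,
    length_mm = len,
    tortuosity = tort,
    angle_to_parent_deg = ang_par,
    sibling_angle_deg = sib,
    n_points = vapply(pts, nrow, integer(1)))
  structure(list(branches = branches, points = pts_s), class = "airway_graph")
}

#' @export
print.airway_graph <- function(x, ...) {
  cat(sprintf("<airway_graph %d branches, max generation %d>\n",
              nrow(x$branches), max(x$branches$gen)))
  invisible(x)
}

#' Generation-percentage branch classes
#'
#' Each branch's generation percentage is `100 * gen / max generation on
#' any root-to-leaf path through the branch` (i.e. the deepest descendant
#' leaf). Classes: `>= 70` terminal, `>= 40` small, `< 40` medium
#' (boundaries closed on the left).
#'
#' @param graph an `airway_graph`.
#' @param t_terminal,t_small percentage thresholds.
#' @return character vector of classes, one per branch; attribute
#'   `percentage` carries the raw percentages.
#' @export
generation_percent_classes <- function(graph, t_terminal = 70, t_small = 40) {
  br <- graph$branches
  n <- nrow(br)
  maxgen <- br$gen
  # propagate deepest descendant generation upward (children have larger ids
  # is not guaranteed after merging, so iterate to a fixed point)
  repeat {
    upd <- maxgen
    for (b in seq_len(n)) {
      p <- br$parent[b]
      if (!is.na(p) && upd[p] < maxgen[b]) upd[p] <- maxgen[b]
    }
    if (identical(upd, maxgen)) break
    maxgen <- upd
  }
  pctg <- ifelse(maxgen > 0, 100 * br$gen / maxgen, 0)
  cls <- ifelse(pctg >= t_terminal, "terminal",
                ifelse(pctg >= t_small, "small", "medium"))
  attr(cls, "percentage") <- pctg
  cls
}

#' Per-branch morphometry table
#'
#' @param graph an `airway_graph`.
#' @return data frame with one row per branch: id, parent, generation,
#'   class, length_mm, tortuosity, angle_to_parent_deg, sibling_angle_deg.
#' @export
branch_metrics <- function(graph) {
  cls <- generation_percent_classes(graph)
  out <- graph$branches[, c("id", "parent", "gen", "length_mm", "tortuosity",
                            "angle_to_parent_deg", "sibling_angle_deg")]
  out$class <- as.character(cls)
  out$generation_pct <- attr(cls, "percentage")
  out[, c("id", "parent", "gen", "class", "generation_pct", "length_mm",
          "tortuosity", "angle_to_parent_deg", "sibling_angle_deg")]
}

#' One-call morphometry from an airway mask
#'
#' [skeletonize_airway()] then [build_graph()] then [branch_metrics()].
#'
#' @param airway a `binary_mask`.
#' @param prune_mm leaf-twig prune threshold (mm).
#' @return data frame from [branch_metrics()]; the graph is attached as
#'   attribute `graph`.
#' @export
airway_morphometry <- function(airway, prune_mm = 3) {
  sk <- skeletonize_airway(airway)
  g <- build_graph(sk, prune_mm = prune_mm)
  out <- branch_metrics(g)
  attr(out, "graph") <- g
  out
}
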