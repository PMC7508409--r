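#' Build a validated stream network from an edge table
#'
#' A stream network is a dendritic (tree-shaped) set of directed edges, each
#' flowing from an upstream node (`from_node`) to a downstream node
#' (`to_node`). Exactly one node — the outlet — has no outgoing edge, and
#' every edge must drain to it. Each edge carries a positive `length` and a
#' positive additive-function value (`afv`, e.g. Shreve magnitude or
#' watershed area) used to split tail-up covariance weights at confluences.
#'
#' @param edge_table data frame with columns `edge_id`, `from_node`,
#'   `to_node`, `length` and optionally `afv`. When `afv` is absent it is
#'   filled with Shreve magnitudes (see [shreve_afv()]); when present it must
#'   be positive and non-decreasing in the downstream direction.
#' @param node_xy optional data frame with columns `node`, `x`, `y` giving
#'   planar coordinates of the nodes (used only by spatially balanced
#'   designs and Euclidean distance options).
#'
#' @return An object of class `stream_network`: a list with elements
#'   `edges` (the validated edge table augmented with `up_dist_from`,
#'   `up_dist_to` and `down_edge`), `outlet_node`, `node_updist` (named
#'   vector of network distances from the outlet to each node) and
#'   `node_xy`.
#'
#' @details Distances are measured along the network; a node's `up_dist` is
#'   the total edge length separating it from the outlet. Validation rejects
#'   cycles, multiple outlets, nodes with more than one downstream edge, and
#'   non-positive edge lengths, each with an error naming the offender.
#'
#' @examples
#' y <- data.frame(edge_id = c("e1", "e2", "e3"),
#'                 from_node = c("A", "B", "C"),
#'                 to_node = c("C", "C", "O"),
#'                 length = 1)
#' net <- build_network(y)
#' net$node_updist
#' @export
build_network <- function(edge_table, node_xy = NULL) {
  required <- c("edge_id", "from_node", "to_node", "length")
  missing_cols <- setdiff(required, names(edge_table))
  if (length(missing_cols) > 0) {
    stop("edge_table is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  edges <- as.data.frame(edge_table, stringsAsFactors = FALSE)
  edges$edge_id <- as.character(edges$edge_id)
  edges$from_node <- as.character(edges$from_node)
  edges$to_node <- as.character(edges$to_node)
  if (anyDuplicated(edges$edge_id)) {
    stop("duplicated edge_id: ", edges$edge_id[duplicated(edges$edge_id)][1])
  }
  bad_len <- which(!is.finite(edges$length) | edges$length <= 0)
  if (length(bad_len) > 0) {
    stop("non-positive length on edge ", edges$edge_id[bad_len[1]])
  }

  # out-degree <= 1: a node may feed at most one downstream edge
  dup_from <- edges$from_node[duplicated(edges$from_node)]
  if (length(dup_from) > 0) {
    stop("node with out-degree > 1: ", dup_from[1])
  }

  nodes <- unique(c(edges$from_node, edges$to_node))
  has_out <- nodes %in% edges$from_node
  outlets <- nodes[!has_out]
  if (length(outlets) > 1) {
    stop("multiple outlets detected: ", paste(outlets, collapse = ", "),
         " (split the input into one file per network)")
  }
  if (length(outlets) == 0) {
    stop("cycle detected: no outlet node exists")
  }
  outlet <- outlets[1]

  # downstream edge of each edge (NA for the outlet edge)
  down_idx <- match(edges$to_node, edges$from_node)
  edges$down_edge <- edges$edge_id[down_idx]

  # every edge must reach the outlet in at most |E| hops (else a cycle)
  n_edge <- nrow(edges)
  for (i in seq_len(n_edge)) {
    j <- i
    for (step in seq_len(n_edge + 1)) {
      j <- down_idx[j]
      if (is.na(j)) break
      if (step > n_edge) stop("cycle detected involving edge ", edges$edge_id[i])
    }
  }

  # node up_dist by walking upstream from the outlet
  node_updist <- stats::setNames(rep(NA_real_, length(nodes)), nodes)
  node_updist[outlet] <- 0
  frontier <- outlet
  while (length(frontier) > 0) {
    nxt <- character(0)
    for (nd in frontier) {
      inc <- which(edges$to_node == nd)
      if (length(inc) > 0) {
        node_updist[edges$from_node[inc]] <- node_updist[nd] + edges$length[inc]
        nxt <- c(nxt, edges$from_node[inc])
      }
    }
    frontier <- nxt
  }
  if (anyNA(node_updist)) {
    stop("cycle detected: nodes unreachable from the outlet: ",
         paste(names(node_updist)[is.na(node_updist)], collapse = ", "))
  }
  edges$up_dist_to <- unname(node_updist[edges$to_node])
  edges$up_dist_from <- unname(node_updist[edges$from_node])

  net <- structure(
    list(edges = edges, outlet_node = outlet, node_updist = node_updist,
         node_xy = node_xy),
    class = "stream_network"
  )
  if (!"afv" %in% names(edges)) {
    net <- shreve_afv(net)
  } else {
    bad_afv <- which(!is.finite(edges$afv) | edges$afv <= 0)
    if (length(bad_afv) > 0) {
      stop("non-positive afv on edge ", edges$edge_id[bad_afv[1]])
    }
    down_afv <- edges$afv[down_idx]
    viol <- which(!is.na(down_afv) & down_afv < edges$afv - 1e-9)
    if (length(viol) > 0) {
      stop("afv decreases downstream of edge ", edges$edge_id[viol[1]])
    }
  }
  net
}

#' @export
print.stream_network <- function(x, ...) {
  cat("stream_network:", nrow(x$edges), "edges,",
      length(x$node_updist), "nodes, outlet", x$outlet_node, "\n")
  cat("  total length", format(sum(x$edges$length)), "| headwater edges:",
      sum(!x$edges$from_node %in% x$edges$to_node), "\n")
  invisible(x)
}

#' Fill additive-function values with Shreve stream magnitudes
#'
#' Headwater edges (edges with no upstream edge) are assigned `afv = 1`;
#' every other edge receives the sum of the `afv` of its immediate upstream
#' edges. The result is non-decreasing downstream, as required for tail-up
#' confluence weights.
#'
#' @param net a `stream_network`.
#' @return The network with `edges$afv` (re)computed.
#' @export
shreve_afv <- function(net) {
  stopifnot(inherits(net, "stream_network"))
  edges <- net$edges
  # process in order of decreasing distance from the outlet: upstream first
  ord <- order(edges$up_dist_to, decreasing = TRUE)
  afv <- stats::setNames(rep(NA_real_, nrow(edges)), edges$edge_id)
  for (i in ord) {
    ups <- which(edges$to_node == edges$from_node[i])
    afv[i] <- if (length(ups) == 0) 1 else sum(afv[ups])
  }
  net$edges$afv <- unname(afv)
  net
}

headwater_edges <- function(net) {
  e <- net$edges
  e$edge_id[!e$from_node %in% e$to_node]
}

outlet_edge <- function(net) {
  e <- net$edges
  e$edge_id[is.na(e$down_edge)]
}

#' Confluence nodes of a network
#'
#' @param net a `stream_network`.
#' @return Character vector of node ids where two or more edges converge
#'   into one downstream edge.
#' @export
confluence_nodes <- function(net) {
  e <- net$edges
  tab <- table(e$to_node)
  ju <- names(tab)[tab >= 2]
  ju[ju %in% e$from_node] # must also have a downstream edge
}

# edge ids on the downstream path of `edge_id`, excluding the edge itself
edge_path_down <- function(net, edge_id) {
  e <- net$edges
  i <- match(edge_id, e$edge_id)
  path <- character(0)
  nxt <- e$down_edge[i]
  while (!is.na(nxt)) {
    path <- c(path, nxt)
    nxt <- e$down_edge[match(nxt, e$edge_id)]
  }
  path
}

#' Validate a site table against a network
#'
#' Sites live on edges and are located by `up_dist`, the network distance
#' from the outlet. A site's `up_dist` must fall within the span of its
#' edge, and `site_id` values must be unique.
#'
#' @param net a `stream_network`.
#' @param sites data frame with columns `site_id`, `edge_id`, `up_dist` and
#'   optionally `x`, `y` plus covariate columns.
#' @return The validated site data frame (character ids, row names dropped).
#' @export
validate_sites <- function(net, sites) {
  required <- c("site_id", "edge_id", "up_dist")
  missing_cols <- setdiff(required, names(sites))
  if (length(missing_cols) > 0) {
    stop("site table is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  sites$site_id <- as.character(sites$site_id)
  sites$edge_id <- as.character(sites$edge_id)
  if (anyDuplicated(sites$site_id)) {
    stop("duplicated site_id: ", sites$site_id[duplicated(sites$site_id)][1])
  }
  idx <- match(sites$edge_id, net$edges$edge_id)
  if (anyNA(idx)) {
    stop("unknown edge_id for site ", sites$site_id[which(is.na(idx))[1]])
  }
  lo <- net$edges$up_dist_to[idx]
  hi <- net$edges$up_dist_from[idx]
  bad <- which(sites$up_dist < lo - 1e-9 | sites$up_dist > hi + 1e-9)
  if (length(bad) > 0) {
    stop("site ", sites$site_id[bad[1]], " has up_dist outside its edge span")
  }
  rownames(sites) <- NULL
  sites
}

#' Hydrologic distance structure for a set of sites
#'
#' Computes, for every pair of sites, the downstream distances to the
#' closest common point on their paths to the outlet (`A`), the total
#' hydrologic separation (`H = A + t(A)`), the flow-connectivity indicator
#' (`F`, true when one site lies on the other's path to the outlet) and the
#' tail-up confluence weights
#' \eqn{W_{ij} = \sqrt{afv_{up}/afv_{down}}} for flow-connected pairs
#' (0 otherwise, 1 on the diagonal), where each site contributes the `afv`
#' of the edge it sits on.
#'
#' @param net a `stream_network`.
#' @param sites a site table (see [validate_sites()]).
#' @return An object of class `stream_dist`: list with matrices `H`, `A`,
#'   `F`, `W` (site ids as dimnames) and the validated `sites` table.
#' @export
distance_structure <- function(net, sites) {
  sites <- validate_sites(net, sites)
  m <- nrow(sites)
  ids <- sites$site_id
  ud <- sites$up_dist
  e <- net$edges
  eidx <- match(sites$edge_id, e$edge_id)
  afv_site <- e$afv[eidx]

  # per-edge downstream paths, memoised over the unique edges present
  uedges <- unique(sites$edge_id)
  paths <- lapply(uedges, function(id) edge_path_down(net, id))
  names(paths) <- uedges
  # junction up_dist for a pair of edges = up_dist of the from-node of the
  # most upstream edge common to both downstream paths
  junction_updist <- function(ea, eb) {
    pa <- c(ea, paths[[ea]])
    pb <- c(eb, paths[[eb]])
    common <- intersect(pa, pb)
    c_edge <- common[1] # paths share a suffix; first common edge is most upstream
    unname(net$node_updist[e$from_node[match(c_edge, e$edge_id)]])
  }

  A <- matrix(0, m, m, dimnames = list(ids, ids))
  F_ <- matrix(FALSE, m, m, dimnames = list(ids, ids))
  W <- diag(1, m)
  dimnames(W) <- list(ids, ids)
  diag(F_) <- TRUE

  for (i in seq_len(m)[-1]) {
    for (j in seq_len(i - 1)) {
      ei <- sites$edge_id[i]; ej <- sites$edge_id[j]
      if (ei == ej) {
        A[i, j] <- max(ud[i] - ud[j], 0)
        A[j, i] <- max(ud[j] - ud[i], 0)
        F_[i, j] <- F_[j, i] <- TRUE
        W[i, j] <- W[j, i] <- 1 # same edge: afv ratio is 1
      } else if (ei %in% paths[[ej]]) {
        # i's edge lies on j's downstream path: j upstream, i downstream
        A[j, i] <- ud[j] - ud[i]
        F_[i, j] <- F_[j, i] <- TRUE
        W[i, j] <- W[j, i] <- sqrt(afv_site[j] / afv_site[i])
      } else if (ej %in% paths[[ei]]) {
        A[i, j] <- ud[i] - ud[j]
        F_[i, j] <- F_[j, i] <- TRUE
        W[i, j] <- W[j, i] <- sqrt(afv_site[i] / afv_site[j])
      } else {
        u <- junction_updist(ei, ej)
        A[i, j] <- ud[i] - u
        A[j, i] <- ud[j] - u
      }
    }
  }
  H <- A + t(A)
  structure(list(H = H, A = A, F = F_, W = W, sites = sites),
            class = "stream_dist")
}

#' @export
print.stream_dist <- function(x, ...) {
  m <- nrow(x$H)
  cat("stream_dist over", m, "sites;",
      sum(x$F[upper.tri(x$F)]), "flow-connected pairs of",
      choose(m, 2), "\n")
  invisible(x)
}

# subset a distance structure to site indices `idx` (may repeat indices,
# e.g. for repeated measurements at a site)
dist_subset <- function(dist, idx) {
  structure(list(H = dist$H[idx, idx, drop = FALSE],
                 A = dist$A[idx, idx, drop = FALSE],
                 F = dist$F[idx, idx, drop = FALSE],
                 W = dist$W[idx, idx, drop = FALSE],
                 sites = dist$sites[idx, , drop = FALSE]),
            class = "stream_dist")
}

#' Generate a random synthetic dendritic network
#'
#' Builds a full binary confluence tree with `n_headwaters` headwater edges
#' (hence `2 * n_headwaters - 1` edges) by randomly merging subtrees, drawing
#' edge lengths from `length_law`, filling Shreve `afv`, and embedding the
#' tree in the plane (headwaters spread along the x-axis, y equal to network
#' distance from the outlet) so that spatially balanced designs have
#' coordinates to work with.
#'
#' @param n_headwaters number of headwater (source) edges, at least 1.
#' @param seed integer seed; the same seed always yields the same network.
#' @param length_law either a function `n -> n positive lengths` or a list
#'   `list(dist = "uniform", min =, max =)` /
#'   `list(dist = "lognormal", meanlog =, sdlog =)`. Default: lengths
#'   uniform on (0.5, 1.5).
#' @return A `stream_network` with planar node coordinates.
#' @export
synth_network <- function(n_headwaters, seed = 1L, length_law = NULL) {
  if (n_headwaters < 1) stop("n_headwaters must be at least 1")
  draw_lengths <- make_length_law(length_law)
  withr::with_seed(seed, {
    n_edge <- 2L * n_headwaters - 1L
    lens <- draw_lengths(n_edge)
    if (any(lens <= 0)) stop("length_law produced non-positive lengths")
    edge_id <- paste0("e", seq_len(n_edge))
    from_node <- character(n_edge)
    to_node <- character(n_edge)
    # active edges whose downstream node is still open
    hw <- seq_len(n_headwaters)
    from_node[hw] <- paste0("H", hw)
    active <- hw
    next_edge <- n_headwaters + 1L
    next_junction <- 1L
    while (length(active) > 1) {
      pick <- sample(length(active), 2L)
      a <- active[pick[1]]; b <- active[pick[2]]
      jn <- paste0("J", next_junction)
      next_junction <- next_junction + 1L
      to_node[a] <- jn
      to_node[b] <- jn
      from_node[next_edge] <- jn
      active <- c(active[-pick], next_edge)
      next_edge <- next_edge + 1L
    }
    to_node[active] <- "O"
    edges <- data.frame(edge_id = edge_id, from_node = from_node,
                        to_node = to_node, length = lens,
                        stringsAsFactors = FALSE)
    net <- build_network(edges)
    net$node_xy <- layout_network(net)
    net
  })
}

make_length_law <- function(length_law) {
  if (is.null(length_law)) {
    return(function(n) stats::runif(n, 0.5, 1.5))
  }
  if (is.function(length_law)) return(length_law)
  stopifnot(is.list(length_law), !is.null(length_law$dist))
  switch(length_law$dist,
    uniform = function(n) stats::runif(n, length_law$min, length_law$max),
    lognormal = function(n) stats::rlnorm(n, length_law$meanlog, length_law$sdlog),
    exponential = function(n) stats::rexp(n, length_law$rate),
    stop("unknown length_law dist: ", length_law$dist)
  )
}

# dendrogram-style planar embedding: leaves at x = 1..H in tree order,
# internal nodes at the mean x of their children; y = up_dist
layout_network <- function(net) {
  e <- net$edges
  hw_nodes <- setdiff(e$from_node, e$to_node)
  x <- stats::setNames(rep(NA_real_, length(net$node_updist)),
                       names(net$node_updist))
  x[hw_nodes] <- seq_along(hw_nodes)
  ord <- order(e$up_dist_to, decreasing = TRUE)
  for (i in ord) {
    nd <- e$to_node[i]
    ups <- e$from_node[e$to_node == nd]
    if (all(!is.na(x[ups]))) x[nd] <- mean(x[ups])
  }
  data.frame(node = names(x), x = unname(x),
             y = unname(net$node_updist), stringsAsFactors = FALSE)
}

#' Place candidate sampling sites along network edges
#'
#' Regular placement puts `n_per_edge` sites at fractions
#' `i / (n_per_edge + 1)` of each edge's length (measured from the
#' downstream end), so sites never coincide with confluence nodes. Random
#' placement draws positions uniformly along each edge.
#'
#' @param net a `stream_network`.
#' @param n_per_edge sites per edge, at least 1.
#' @param type `"regular"` (default) or `"random"`.
#' @param seed integer seed, used only for random placement.
#' @param prefix site-id prefix.
#' @param fracs optional explicit placement fractions, overriding
#'   `n_per_edge`/`type`: a numeric vector in (0, 1) applied to every edge,
#'   or a list of such vectors recycled across edges (e.g. to emulate
#'   surveys with confluence clusters on some segments and mid-segment
#'   sites on others). Fractions are measured from the downstream end.
#' @return A site table with planar coordinates interpolated along edges
#'   when the network has node coordinates.
#' @export
place_sites <- function(net, n_per_edge = 1L, type = c("regular", "random"),
                        seed = 1L, prefix = "s", fracs = NULL) {
  type <- match.arg(type)
  e <- net$edges
  if (!is.null(fracs)) {
    if (!is.list(fracs)) fracs <- list(fracs)
    if (any(unlist(fracs) <= 0 | unlist(fracs) >= 1)) {
      stop("placement fractions must lie strictly inside (0, 1)")
    }
    per_edge <- rep_len(fracs, nrow(e))
    frac <- unlist(per_edge)
    edge_rep <- rep(seq_len(nrow(e)), times = lengths(per_edge))
    up_dist <- e$up_dist_to[edge_rep] + frac * e$length[edge_rep]
    sites <- data.frame(
      site_id = paste0(prefix, seq_along(edge_rep)),
      edge_id = e$edge_id[edge_rep],
      up_dist = up_dist,
      stringsAsFactors = FALSE
    )
    if (!is.null(net$node_xy)) {
      xy <- site_xy(net, sites$edge_id, frac)
      sites$x <- xy$x
      sites$y <- xy$y
    }
    return(validate_sites(net, sites))
  }
  if (n_per_edge < 1) stop("n_per_edge must be at least 1")
  frac <- if (type == "regular") {
    rep(seq_len(n_per_edge) / (n_per_edge + 1), times = nrow(e))
  } else {
    withr::with_seed(seed, stats::runif(n_per_edge * nrow(e)))
  }
  edge_rep <- rep(seq_len(nrow(e)), each = n_per_edge)
  up_dist <- e$up_dist_to[edge_rep] + frac * e$length[edge_rep]
  sites <- data.frame(
    site_id = paste0(prefix, seq_along(edge_rep)),
    edge_id = e$edge_id[edge_rep],
    up_dist = up_dist,
    stringsAsFactors = FALSE
  )
  if (!is.null(net$node_xy)) {
    xy <- site_xy(net, sites$edge_id, frac)
    sites$x <- xy$x
    sites$y <- xy$y
  }
  validate_sites(net, sites)
}

# interpolate coordinates along an edge; frac measured from downstream end
site_xy <- function(net, edge_id, frac) {
  e <- net$edges
  i <- match(edge_id, e$edge_id)
  nx <- stats::setNames(net$node_xy$x, net$node_xy$node)
  ny <- stats::setNames(net$node_xy$y, net$node_xy$node)
  list(x = unname(nx[e$to_node[i]] + frac * (nx[e$from_node[i]] - nx[e$to_node[i]])),
       y = unname(ny[e$to_node[i]] + frac * (ny[e$from_node[i]] - ny[e$to_node[i]])))
}

#' Read an edge table or site table from CSV
#'
#' `read_edges()` expects columns `edge_id,from_node,to_node,length[,afv]`;
#' `read_sites()` expects `site_id,edge_id,up_dist[,x,y][,covariates...]`.
#' Files are UTF-8 with a header row and `.` as decimal separator.
#'
#' @param path CSV file path.
#' @return `read_edges()`: a `stream_network`; `read_sites()`: a site
#'   data frame (validated if `net` is supplied).
#' @param net optional `stream_network` used to validate the sites.
#' @export
read_edges <- function(path) {
  build_network(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_edges
#' @export
read_sites <- function(path, net = NULL) {
  sites <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(net)) sites <- validate_sites(net, sites) else {
    sites$site_id <- as.character(sites$site_id)
    sites$edge_id <- as.character(sites$edge_id)
  }
  sites
}

#' @rdname read_edges
#' @param sites site table to write.
#' @export
write_sites <- function(sites, path) {
  utils::write.csv(sites, path, row.names = FALSE)
  invisible(path)
}
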