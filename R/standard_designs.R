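#' Simple random sampling design
#'
#' Uniform sample of `n` candidate sites without replacement.
#'
#' @param candidates candidate site table (or a [design_problem()]).
#' @param n design size.
#' @param seed integer seed.
#' @return Sorted integer vector of candidate indices.
#' @export
srs_design <- function(candidates, n, seed = 1L) {
  N <- n_candidates(candidates)
  if (n > N) stop("n exceeds the number of candidates")
  sort(withr::with_seed(seed, sample.int(N, n)))
}

n_candidates <- function(candidates) {
  if (inherits(candidates, "design_problem")) candidates$n_cand
  else nrow(candidates)
}

cand_table <- function(candidates) {
  if (inherits(candidates, "design_problem")) candidates$candidates
  else candidates
}

#' Spatially balanced (GRTS-style) design
#'
#' Orders the candidates by hierarchical quadrant-recursive randomisation:
#' the bounding box is recursively split into four quadrants, with an
#' independent random permutation of the quadrant labels in every cell at
#' every level, until each cell holds at most one candidate; candidates are
#' then sorted in reverse-hierarchical order and the first `n` taken. Any
#' prefix of the ordering is spatially balanced, so for a fixed seed
#' successive draws of increasing `n` are nested ("master sample"
#' behaviour). Inclusion probabilities are equal; no agreement with any
#' particular survey package is implied beyond the balance property.
#'
#' @inheritParams srs_design
#' @return Sorted integer vector of candidate indices.
#' @export
grts_design <- function(candidates, n, seed = 1L) {
  ord <- grts_order(candidates, seed)
  if (n > length(ord)) stop("n exceeds the number of candidates")
  sort(ord[seq_len(n)])
}

#' Full GRTS-style (reverse-hierarchical) candidate ordering
#'
#' @inheritParams srs_design
#' @return Integer permutation of the candidate indices; prefixes of it are
#'   spatially balanced designs.
#' @export
grts_order <- function(candidates, seed = 1L) {
  cand <- cand_table(candidates)
  if (is.null(cand$x) || is.null(cand$y)) {
    stop("spatially balanced designs need x,y candidate coordinates")
  }
  N <- nrow(cand)
  if (N == 1) return(1L)
  max_depth <- 25L
  addr <- matrix(0L, N, max_depth)
  withr::with_seed(seed, {
    # every cell keeps recursing (even singletons follow their geometric
    # subcell), so all addresses are comparable at any common depth
    recurse <- function(idx, xlim, ylim, level) {
      if (level > max_depth) return(invisible())
      xm <- mean(xlim); ym <- mean(ylim)
      q <- 1L + (cand$x[idx] > xm) + 2L * (cand$y[idx] > ym)
      perm <- sample(0:3)
      addr[idx, level] <<- perm[q]
      bounds <- list(list(c(xlim[1], xm), c(ylim[1], ym)),
                     list(c(xm, xlim[2]), c(ylim[1], ym)),
                     list(c(xlim[1], xm), c(ym, ylim[2])),
                     list(c(xm, xlim[2]), c(ym, ylim[2])))
      for (qq in 1:4) {
        sub <- idx[q == qq]
        if (length(sub) > 0) {
          recurse(sub, bounds[[qq]][[1]], bounds[[qq]][[2]], level + 1L)
        }
      }
    }
    recurse(seq_len(N), range(cand$x), range(cand$y), 1L)
    # resolution depth: smallest depth at which all (non co-located)
    # addresses are distinct
    D <- max_depth
    for (k in seq_len(max_depth)) {
      keys_k <- apply(addr[, seq_len(k), drop = FALSE], 1, paste, collapse = "")
      if (!anyDuplicated(keys_k)) { D <- k; break }
    }
    # reverse-hierarchical ordering: first digit least significant
    key <- as.numeric(addr[, seq_len(D), drop = FALSE] %*% 4^(seq_len(D) - 1))
    order(key, stats::runif(N)) # random tie-break for co-located points
  })
}

#' GRTS variants anchored to the network structure
#'
#' `grts_mouth()` forces the candidate nearest the outlet (minimum
#' `up_dist`) into the design and fills the remainder by GRTS ordering.
#' `grts_cluster()` orders the confluence junctions spatially (GRTS on the
#' junction coordinates), and for each selected junction takes the nearest
#' candidate on each of its three incident edges (the two upstream and the
#' downstream segment) as a cluster, until fewer than `cluster_size` slots
#' remain; the remainder is filled by GRTS ordering. A junction is used
#' only while unselected candidates exist on all three incident edges.
#'
#' @param net a `stream_network`.
#' @inheritParams srs_design
#' @param cluster_size sites per confluence cluster (default 3: one per
#'   incident edge).
#' @return Sorted integer vector of candidate indices.
#' @export
grts_mouth <- function(candidates, n, seed = 1L) {
  cand <- cand_table(candidates)
  mouth <- which.min(cand$up_dist)
  if (n == 1) return(mouth)
  ord <- grts_order(candidates, seed)
  ord <- ord[ord != mouth]
  sort(c(mouth, ord[seq_len(n - 1)]))
}

#' @rdname grts_mouth
#' @export
grts_cluster <- function(net, candidates, n, cluster_size = 3L, seed = 1L) {
  cand <- cand_table(candidates)
  junctions <- confluence_nodes(net)
  incid <- lapply(junctions, junction_edges, net = net)
  ok <- vapply(incid, function(ed) {
    all(vapply(ed, function(e) any(cand$edge_id == e), logical(1)))
  }, logical(1))
  if (!any(ok)) {
    stop("no confluence has candidates on all three incident edges")
  }
  junctions <- junctions[ok]
  incid <- incid[ok]
  # spatial ordering of junctions: GRTS on junction coordinates when
  # available, seeded random order otherwise
  j_ord <- if (!is.null(net$node_xy)) {
    jxy <- net$node_xy[match(junctions, net$node_xy$node), ]
    grts_order(data.frame(site_id = junctions, x = jxy$x, y = jxy$y), seed)
  } else {
    withr::with_seed(seed, sample(length(junctions)))
  }
  chosen <- integer(0)
  for (ji in j_ord) {
    if (n - length(chosen) < cluster_size) break
    cl <- junction_cluster(net, cand, junctions[ji], incid[[ji]],
                           cluster_size, exclude = chosen)
    if (!is.null(cl)) chosen <- c(chosen, cl)
  }
  fill <- setdiff(grts_order(candidates, seed), chosen)
  sort(c(chosen, fill[seq_len(n - length(chosen))]))
}

junction_edges <- function(net, node) {
  e <- net$edges
  c(e$edge_id[e$to_node == node], e$edge_id[e$from_node == node])
}

# nearest unselected candidate on each incident edge, then next-nearest
# across edges until cluster_size sites (NULL if any edge has none left)
junction_cluster <- function(net, cand, node, edges, cluster_size, exclude) {
  jd <- unname(net$node_updist[node])
  per_edge <- lapply(edges, function(e) {
    i <- setdiff(which(cand$edge_id == e), exclude)
    i[order(abs(cand$up_dist[i] - jd))]
  })
  if (any(vapply(per_edge, length, integer(1)) == 0)) return(NULL)
  cl <- vapply(per_edge, `[`, integer(1), 1)
  if (cluster_size > length(edges)) {
    rest <- setdiff(unlist(per_edge), cl)
    rest <- rest[order(abs(cand$up_dist[rest] - jd))]
    cl <- c(cl, rest[seq_len(min(cluster_size - length(cl), length(rest)))])
  }
  cl
}

#' Heuristic headwater and tributary designs
#'
#' `headwater_singles()` ("H1"): one candidate nearest the outlet plus
#' `n - 1` randomly chosen candidates on headwater edges.
#' `trib_triplets()` ("C3"/"C4"): as many confluence triplets as fit (the
#' nearest candidate on each of the three edges meeting at a confluence,
#' confluences in seeded random order), remaining slots allocated to
#' candidates on headwater edges; with `with_mouth = TRUE` one slot is
#' reserved for the candidate on the outlet segment nearest the outlet.
#'
#' @param net a `stream_network`.
#' @inheritParams srs_design
#' @param with_mouth reserve a slot for the outlet-segment candidate.
#' @return Sorted integer vector of candidate indices.
#' @export
headwater_singles <- function(net, candidates, n, seed = 1L) {
  cand <- cand_table(candidates)
  mouth <- which.min(cand$up_dist)
  hw <- which(cand$edge_id %in% headwater_edges(net))
  hw <- setdiff(hw, mouth)
  if (length(hw) < n - 1) {
    stop("insufficient headwater candidates: need ", n - 1, ", have ",
         length(hw))
  }
  picks <- withr::with_seed(seed, sample(hw, n - 1))
  sort(c(mouth, picks))
}

#' @rdname headwater_singles
#' @export
trib_triplets <- function(net, candidates, n, with_mouth = FALSE, seed = 1L) {
  cand <- cand_table(candidates)
  chosen <- integer(0)
  if (with_mouth) {
    out_e <- outlet_edge(net)
    om <- which(cand$edge_id == out_e)
    if (length(om) == 0) stop("no candidate on the outlet segment")
    chosen <- om[which.min(cand$up_dist[om])]
  }
  junctions <- confluence_nodes(net)
  withr::with_seed(seed, {
    j_ord <- sample(length(junctions))
    for (ji in j_ord) {
      if (n - length(chosen) < 3) break
      cl <- junction_cluster(net, cand, junctions[ji],
                             junction_edges(net, junctions[ji]), 3L,
                             exclude = chosen)
      if (!is.null(cl)) chosen <- c(chosen, cl)
    }
    r <- n - length(chosen)
    if (r > 0) {
      hw <- setdiff(which(cand$edge_id %in% headwater_edges(net)), chosen)
      if (length(hw) < r) {
        stop("insufficient headwater candidates for the ", r, " remaining slots")
      }
      chosen <- c(chosen, sample(hw, r))
    }
  })
  sort(chosen)
}

#' Construct a space-filling design by greedy exchange
#'
#' Maximises the maximin or Morris-Mitchell score over designs of size `n`
#' (no prior draws are involved; the Monte-Carlo draw count is forced to
#' one).
#'
#' @param ctx a [design_problem()].
#' @param n design size (`>= 2`).
#' @param criterion `"maximin"` or `"morris_mitchell"`.
#' @param p Morris-Mitchell power.
#' @param K random restarts.
#' @param seed integer seed.
#' @return As [greedy_exchange()].
#' @export
spacefill_design <- function(ctx, n, criterion = c("maximin", "morris_mitchell"),
                             p = 2, K = 1L, seed = 1L) {
  criterion <- match.arg(criterion)
  if (n < 2) stop("space-filling designs need n >= 2")
  cfg <- eu_config(criterion, p = p)
  greedy_exchange(ctx, n, cfg, K = K, seed = seed)
}

#' Draw a standard design by scheme name
#'
#' Dispatches to the probability-based and heuristic schemes by their
#' short or descriptive identifiers: `SRS`, `GRTS`/`G1`,
#' `GRTSmouth`/`G2`, `GRTSclus`/`G4`, `H1`/`Headwater.Clusts.and.Singles`,
#' `C3`/`Trib.Sets.Head.Singles.sample`,
#' `C4`/`Trib.Sets.Head.Singles.Mouth.sample`.
#'
#' @param scheme scheme identifier (see above).
#' @param net a `stream_network`.
#' @inheritParams srs_design
#' @param cluster_size for the clustered GRTS variant.
#' @return Sorted integer vector of candidate indices.
#' @export
standard_design <- function(scheme, net, candidates, n, seed = 1L,
                            cluster_size = 3L) {
  switch(scheme,
    SRS = srs_design(candidates, n, seed),
    G1 = , GRTS = grts_design(candidates, n, seed),
    G2 = , GRTSmouth = grts_mouth(candidates, n, seed),
    G4 = , GRTSclus = grts_cluster(net, candidates, n, cluster_size, seed),
    H1 = , Headwater.Clusts.and.Singles =
      headwater_singles(net, candidates, n, seed),
    C3 = , Trib.Sets.Head.Singles.sample =
      trib_triplets(net, candidates, n, with_mouth = FALSE, seed = seed),
    C4 = , Trib.Sets.Head.Singles.Mouth.sample =
      trib_triplets(net, candidates, n, with_mouth = TRUE, seed = seed),
    stop("unknown design scheme: ", scheme)
  )
}
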