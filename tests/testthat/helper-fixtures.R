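# shared fixtures: all built in code, deterministic given their seeds

# the three-edge Y: two headwaters A, B joining at C, outlet O; unit lengths
y_network <- function() {
  build_network(data.frame(
    edge_id = c("e1", "e2", "e3"),
    from_node = c("A", "B", "C"),
    to_node = c("C", "C", "O"),
    length = 1
  ))
}

y_sites <- function() {
  data.frame(site_id = c("s1", "s2", "s3"),
             edge_id = c("e1", "e2", "e3"),
             up_dist = c(2, 2, 0))
}

# candidates at integer positions on a single straight edge; iid responses
# under a nugget-only model, so closed-form toys apply
line_ctx <- function(positions = 0:10, components = "nugget", ...) {
  net <- build_network(data.frame(edge_id = "e1", from_node = "A",
                                  to_node = "O",
                                  length = max(positions) + 1))
  cand <- data.frame(site_id = paste0("c", seq_along(positions)),
                     edge_id = "e1", up_dist = positions)
  design_problem(net, cand, components = components, ...)
}

theta_nugget <- function(s2 = 1) cov_params(sigma2_nugget = s2)
theta_full <- function() cov_params(1, 6, 1, 6, 0.5)

# random dendritic instance with sites; sizes drawn deterministically from
# the seed
random_instance <- function(seed, n_headwaters = NULL, n_per_edge = 1L,
                            predictions = FALSE,
                            components = c("tailup", "taildown", "nugget")) {
  if (is.null(n_headwaters)) {
    n_headwaters <- withr::with_seed(seed, sample(3:6, 1))
  }
  net <- synth_network(n_headwaters, seed = seed,
                       length_law = list(dist = "uniform", min = 0.5, max = 2))
  cand <- place_sites(net, n_per_edge, type = "random", seed = seed + 1L)
  preds <- if (predictions) {
    place_sites(net, 1L, type = "random", seed = seed + 2L, prefix = "p")
  }
  design_problem(net, cand, predictions = preds, components = components)
}

# the frozen survey layout used for parameter-recovery experiments:
# confluence clusters (two close sites at the downstream end, one near the
# upstream end) alternating with cluster + mid-segment edges
survey_layout <- function(n_headwaters = 25L, seed = 42L) {
  net <- synth_network(n_headwaters, seed = seed,
                       length_law = list(dist = "uniform", min = 1, max = 3))
  cand <- place_sites(net, fracs = list(c(0.03, 0.08, 0.97),
                                        c(0.03, 0.5, 0.97)))
  list(net = net, candidates = cand,
       dist = distance_structure(net, cand))
}

# independent path-to-outlet walker used as the distance oracle: step from
# the site down its edge chain, recording nodes and their up_dists
oracle_path <- function(net, edge_id, up_dist) {
  e <- net$edges
  i <- match(edge_id, e$edge_id)
  nodes <- character(0); ud <- numeric(0)
  repeat {
    nodes <- c(nodes, e$to_node[i]); ud <- c(ud, e$up_dist_to[i])
    nxt <- e$down_edge[i]
    if (is.na(nxt)) break
    i <- match(nxt, e$edge_id)
  }
  data.frame(node = nodes, up_dist = ud)
}

# brute-force pairwise hydrologic quantities for two sites
oracle_pair <- function(net, s1, s2) {
  p1 <- oracle_path(net, s1$edge_id, s1$up_dist)
  p2 <- oracle_path(net, s2$edge_id, s2$up_dist)
  if (s1$edge_id == s2$edge_id) {
    a <- max(s1$up_dist - s2$up_dist, 0)
    b <- max(s2$up_dist - s1$up_dist, 0)
    return(list(H = abs(s1$up_dist - s2$up_dist), A12 = a, A21 = b,
                F = TRUE))
  }
  # is one site's edge traversed by the other's path? then flow-connected
  e1_on_p2 <- s1$edge_id %in% path_edges(net, s2$edge_id)
  e2_on_p1 <- s2$edge_id %in% path_edges(net, s1$edge_id)
  if (e1_on_p2) {
    return(list(H = s2$up_dist - s1$up_dist, A12 = 0,
                A21 = s2$up_dist - s1$up_dist, F = TRUE))
  }
  if (e2_on_p1) {
    return(list(H = s1$up_dist - s2$up_dist,
                A12 = s1$up_dist - s2$up_dist, A21 = 0, F = TRUE))
  }
  common <- intersect(p1$node, p2$node)
  ju <- max(p1$up_dist[p1$node %in% common])
  list(H = (s1$up_dist - ju) + (s2$up_dist - ju),
       A12 = s1$up_dist - ju, A21 = s2$up_dist - ju, F = FALSE)
}

path_edges <- function(net, edge_id) {
  e <- net$edges
  out <- character(0)
  nxt <- e$down_edge[match(edge_id, e$edge_id)]
  while (!is.na(nxt)) {
    out <- c(out, nxt)
    nxt <- e$down_edge[match(nxt, e$edge_id)]
  }
  out
}
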