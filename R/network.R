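#' Build the correlation network from a ring set
#'
#' Nucleotides become nodes and each significant pairwise correlation an
#' undirected edge. Edge weight is the correlation strength |phi|; the
#' sign (+1 co-modification, -1 mutual exclusion) is kept as an edge
#' attribute so that modularity optimization, which requires non-negative
#' weights, can still use every edge.
#'
#' @param rings a `ring_set`.
#' @return a `ring_network` (unfiltered).
#' @export
build_graph <- function(rings) {
  stopifnot(inherits(rings, "ring_set"))
  if (nrow(rings) == 0L) stop("empty ring set", call. = FALSE)
  key <- paste(rings$i, rings$j)
  if (anyDuplicated(key))
    stop("duplicate pair in ring set: ", key[duplicated(key)][1],
         call. = FALSE)
  nodes <- sort(unique(c(rings$i, rings$j)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(rings$i), to = as.character(rings$j),
               weight = abs(rings$phi), sign = sign(rings$phi),
               phi = rings$phi),
    directed = FALSE, vertices = data.frame(name = as.character(nodes)))
  structure(list(graph = g, L = attr(rings, "L"), weight_min = NULL,
                 kcore_k = NULL, filtered = FALSE),
            class = "ring_network")
}

#' @export
print.ring_network <- function(x, ...) {
  cat(sprintf("<ring_network> %d nodes, %d edges%s\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              if (x$filtered)
                sprintf(" (filtered: weight > %g, k-core %d)",
                        x$weight_min, x$kcore_k) else " (unfiltered)"))
  invisible(x)
}

#' Filter the network by edge strength and k-core
#'
#' Restricts the network population by requiring that (i) the correlation
#' strength of every edge be greater than `weight_min` and (ii) every node
#' retain at least `kcore_k` connections: after the weight cut, nodes of
#' degree below k are removed iteratively until stable (the k-core).
#'
#' @param g a `ring_network`.
#' @param weight_min minimum edge strength, exclusive (default 0.015).
#' @param kcore_k k-core order (default 3).
#' @return filtered `ring_network` (possibly empty).
#' @export
filter_graph <- function(g, weight_min = 0.015, kcore_k = 3) {
  stopifnot(inherits(g, "ring_network"))
  gg <- igraph::delete_edges(
    g$graph, which(igraph::E(g$graph)$weight <= weight_min))
  core <- igraph::coreness(gg)
  gg <- igraph::induced_subgraph(gg, which(core >= kcore_k))
  structure(list(graph = gg, L = g$L, weight_min = weight_min,
                 kcore_k = as.integer(kcore_k), filtered = TRUE),
            class = "ring_network")
}

#' Louvain community detection
#'
#' Partitions the filtered network by modularity maximization (Louvain)
#' on edge weights at the given resolution. The run is seeded, so the
#' partition is reproducible; community ids are relabeled 0, 1, ... by
#' decreasing community size (ties broken by smallest member position).
#'
#' @param g a filtered, non-empty `ring_network`.
#' @param resolution modularity resolution ("sensitivity"), default 1.0.
#' @param seed RNG seed fixing the node visiting order.
#' @return a `community_partition` data frame (position, community) with
#'   attributes `modularity`, `resolution`, `seed`.
#' @export
detect_communities <- function(g, resolution = 1.0, seed = 1L) {
  stopifnot(inherits(g, "ring_network"))
  if (igraph::vcount(g$graph) == 0L)
    stop("cannot detect communities in an empty graph", call. = FALSE)
  set.seed(seed)
  cl <- igraph::cluster_louvain(g$graph,
                                weights = igraph::E(g$graph)$weight,
                                resolution = resolution)
  memb <- igraph::membership(cl)
  pos <- as.integer(igraph::V(g$graph)$name)
  # relabel by decreasing size, ties by smallest member position
  sz <- table(memb)
  first_pos <- tapply(pos, memb, min)
  o <- order(-as.integer(sz), as.integer(first_pos))
  relabel <- setNames(seq_along(o) - 1L, names(sz)[o])
  community <- as.integer(relabel[as.character(memb)])
  mod <- igraph::modularity(g$graph, memb,
                            weights = igraph::E(g$graph)$weight,
                            resolution = resolution)
  df <- data.frame(position = pos, community = community)
  df <- df[order(df$position), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("community_partition", "data.frame"),
            modularity = mod, resolution = resolution, seed = seed)
}

#' @export
print.community_partition <- function(x, ...) {
  cat(sprintf(
    "<community_partition> %d nodes, %d communities, modularity %.4f (resolution %g)\n",
    nrow(x), length(unique(x$community)), attr(x, "modularity"),
    attr(x, "resolution")))
  print(table(community = x$community))
  invisible(x)
}

#' Node weighted degrees and strength categories
#'
#' The weighted degree (strength) of a node is the sum of the weights of
#' its incident edges. Nodes are categorized as strong (weighted degree
#' greater than 0.25), medium (0.1 to 0.25, both ends included) or weak
#' (below 0.1).
#'
#' @param g a `ring_network`.
#' @param strong_min,weak_max category boundaries (defaults 0.25 / 0.1).
#' @return data frame: position, degree, weighted_degree, category.
#' @export
node_strengths <- function(g, strong_min = 0.25, weak_max = 0.1) {
  stopifnot(inherits(g, "ring_network"))
  wd <- igraph::strength(g$graph, weights = igraph::E(g$graph)$weight)
  dg <- igraph::degree(g$graph)
  category <- ifelse(wd > strong_min, "strong",
                     ifelse(wd < weak_max, "weak", "medium"))
  df <- data.frame(position = as.integer(igraph::V(g$graph)$name),
                   degree = as.integer(dg), weighted_degree = as.numeric(wd),
                   category = category)
  df <- df[order(df$position), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, strong_min = strong_min, weak_max = weak_max,
            class = c("node_strengths", "data.frame"))
}

# upper nearest-rank percentile: value at rank min(n, floor(q*n) + 1)
nearest_rank <- function(w, q) {
  ws <- sort(w)
  ws[min(length(ws), floor(q * length(ws)) + 1L)]
}

#' Edge strength categories by weight percentile
#'
#' Edges are ranked by correlation strength and categorized as strong (at
#' or above the 75th percentile), medium (50th to 75th) or weak (below the
#' 50th), using the upper nearest-rank percentile convention. With fewer
#' than 4 edges ranking is meaningless and every edge is `unranked`.
#'
#' @param g a `ring_network`.
#' @return data frame: i, j, weight, sign, category; percentile thresholds
#'   stored as attributes `p50`, `p75`.
#' @export
edge_categories <- function(g) {
  stopifnot(inherits(g, "ring_network"))
  ep <- igraph::ends(g$graph, igraph::E(g$graph))
  i <- as.integer(ep[, 1]); j <- as.integer(ep[, 2])
  sw <- pmin(i, j); lw <- pmax(i, j)
  w <- igraph::E(g$graph)$weight
  s <- igraph::E(g$graph)$sign
  if (length(w) < 4L) {
    category <- rep("unranked", length(w))
    p50 <- NA_real_; p75 <- NA_real_
  } else {
    p50 <- nearest_rank(w, 0.50)
    p75 <- nearest_rank(w, 0.75)
    category <- ifelse(w >= p75, "strong",
                       ifelse(w >= p50, "medium", "weak"))
  }
  df <- data.frame(i = sw, j = lw, weight = w, sign = s,
                   category = category)
  df <- df[order(df$i, df$j), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, p50 = p50, p75 = p75,
            class = c("edge_categories", "data.frame"))
}

#' Edges connecting two communities
#'
#' Extracts every edge with one endpoint in community `a` and the other in
#' community `b` (order of `a` and `b` is immaterial). These
#' cross-community correlations are the through-space connections that
#' link structural domains.
#'
#' @param g a `ring_network`.
#' @param partition a `community_partition` covering `g`.
#' @param a,b community ids.
#' @return data frame: i, j, weight, sign, community_i, community_j.
#' @export
cross_community_edges <- function(g, partition, a, b) {
  stopifnot(inherits(g, "ring_network"),
            inherits(partition, "community_partition"))
  known <- unique(partition$community)
  if (!(a %in% known) || !(b %in% known))
    stop("unknown community id", call. = FALSE)
  comm <- setNames(partition$community, partition$position)
  ep <- igraph::ends(g$graph, igraph::E(g$graph))
  pi <- pmin(as.integer(ep[, 1]), as.integer(ep[, 2]))
  pj <- pmax(as.integer(ep[, 1]), as.integer(ep[, 2]))
  ci <- comm[as.character(pi)]; cj <- comm[as.character(pj)]
  keep <- (ci == a & cj == b) | (ci == b & cj == a)
  keep[is.na(keep)] <- FALSE
  df <- data.frame(i = pi[keep], j = pj[keep],
                   weight = igraph::E(g$graph)$weight[keep],
                   sign = igraph::E(g$graph)$sign[keep],
                   community_i = as.integer(ci[keep]),
                   community_j = as.integer(cj[keep]))
  df <- df[order(df$i, df$j), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Differential edges between two conditions
#'
#' Compares edge strengths over the union of the two networks' edge sets
#' (an edge absent from one network counts with weight 0 there). An edge
#' is `strengthened` when `weight_b - weight_a >= delta_min`, `weakened`
#' when `<= -delta_min`, else `unchanged`.
#'
#' @param a,b `ring_network` objects on the same reference (a = baseline,
#'   b = comparison condition).
#' @param delta_min classification threshold on the weight change
#'   (default 0.01).
#' @return an `edge_deltas` data frame: i, j, weight_a, weight_b, delta,
#'   class.
#' @export
differential_edges <- function(a, b, delta_min = 0.01) {
  stopifnot(inherits(a, "ring_network"), inherits(b, "ring_network"))
  if (!is.null(a$L) && !is.null(b$L) && a$L != b$L)
    stop("networks disagree on reference length", call. = FALSE)
  edge_df <- function(g) {
    ep <- igraph::ends(g$graph, igraph::E(g$graph))
    pi <- pmin(as.integer(ep[, 1]), as.integer(ep[, 2]))
    pj <- pmax(as.integer(ep[, 1]), as.integer(ep[, 2]))
    data.frame(key = paste(pi, pj), i = pi, j = pj,
               weight = igraph::E(g$graph)$weight)
  }
  ea <- edge_df(a); eb <- edge_df(b)
  keys <- union(ea$key, eb$key)
  ia <- match(keys, ea$key); ib <- match(keys, eb$key)
  i <- ifelse(is.na(ia), eb$i[ib], ea$i[ia])
  j <- ifelse(is.na(ia), eb$j[ib], ea$j[ia])
  wa <- ifelse(is.na(ia), 0, ea$weight[ia])
  wb <- ifelse(is.na(ib), 0, eb$weight[ib])
  delta <- wb - wa
  cls <- ifelse(delta >= delta_min, "strengthened",
                ifelse(delta <= -delta_min, "weakened", "unchanged"))
  df <- data.frame(i = i, j = j, weight_a = wa, weight_b = wb,
                   delta = delta, class = cls)
  df <- df[order(df$i, df$j), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, delta_min = delta_min,
            class = c("edge_deltas", "data.frame"))
}

#' Export a network as GraphML
#'
#' Writes the graph with node attributes (position id, community,
#' weighted_degree, degree, strength_category) and edge attributes
#' (weight, sign, strength_category) for downstream graph tools.
#'
#' @param g a `ring_network`.
#' @param partition optional `community_partition`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_graphml <- function(g, partition = NULL, path) {
  stopifnot(inherits(g, "ring_network"))
  gg <- g$graph
  ns <- node_strengths(g)
  ord <- match(as.integer(igraph::V(gg)$name), ns$position)
  gg <- igraph::set_vertex_attr(gg, "weighted_degree",
                                value = ns$weighted_degree[ord])
  gg <- igraph::set_vertex_attr(gg, "degree", value = ns$degree[ord])
  gg <- igraph::set_vertex_attr(gg, "strength_category",
                                value = ns$category[ord])
  if (!is.null(partition)) {
    comm <- setNames(partition$community, partition$position)
    gg <- igraph::set_vertex_attr(
      gg, "community",
      value = as.integer(comm[igraph::V(gg)$name]))
  }
  ec <- edge_categories(g)
  ep <- igraph::ends(gg, igraph::E(gg))
  key <- paste(pmin(as.integer(ep[, 1]), as.integer(ep[, 2])),
               pmax(as.integer(ep[, 1]), as.integer(ep[, 2])))
  gg <- igraph::set_edge_attr(
    gg, "strength_category",
    value = ec$category[match(key, paste(ec$i, ec$j))])
  igraph::write_graph(gg, path, format = "graphml")
  invisible(path)
}

#' Write a community partition as TSV
#' @param partition a `community_partition`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_communities <- function(partition, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "#ringmapr\tcommunities\tv1\tmodularity=%.6g\tresolution=%g\tseed=%d",
    attr(partition, "modularity"), attr(partition, "resolution"),
    as.integer(attr(partition, "seed"))), con)
  write.table(as.data.frame(partition), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write differential edges as TSV
#' @param deltas an `edge_deltas` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edge_deltas <- function(deltas, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#ringmapr\tedge_deltas\tv1\tdelta_min=%g",
                     attr(deltas, "delta_min")), con)
  df <- as.data.frame(deltas)
  for (cl in c("weight_a", "weight_b", "delta"))
    df[[cl]] <- formatC(df[[cl]], digits = 6, format = "g")
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
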