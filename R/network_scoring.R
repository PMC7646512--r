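#' Default path-length weight vector
#'
#' Weights (beta0..beta3) applied to the path-product terms KS0..KS3 for
#' paths of length 1..4. Note the published default sums to 0.85, not 1;
#' it is used verbatim and never renormalized.
#'
#' @return numeric vector of length 4.
#' @export
ksp_default_beta <- function() c(0.25, 0.225, 0.1875, 0.1875)

check_beta <- function(beta) {
  if (!is.numeric(beta) || length(beta) != 4L || any(is.na(beta)) ||
      any(beta < 0))
    stop("beta must be 4 non-negative numbers (weights for KS0..KS3)")
  as.numeric(beta)
}

#' Build the integrated kinase-substrate / PPI network
#'
#' Takes the union of the kinase-substrate edges and the PPI edges over the
#' union of their node sets, then keeps only the largest connected component
#' (ties broken by the component containing the lexicographically smallest
#' node id). A kinase-substrate edge is weighted by the number of distinct
#' phosphosites of that substrate catalyzed by the kinase; PPI edges have
#' weight 1; a pair supported by both gets the larger of the two weights.
#' A node is flagged as a kinase iff it appears in the kinase column of
#' `pairs`, even when it is also somebody's substrate.
#'
#' @param pairs deduplicated pair table ([read_kinase_substrate_table()]).
#' @param ppi deduplicated PPI edge table ([read_ppi_table()]).
#' @return a `ksp_network`: list with `graph` (weighted undirected igraph)
#'   and `kinases` (character vector of kinase node ids in the retained
#'   component).
#' @export
build_integrated_network <- function(pairs, ppi = NULL) {
  if (is.null(pairs) || nrow(pairs) == 0L)
    stop("no kinase-substrate pairs supplied")
  ks <- data.table::as.data.table(pairs)[
    , .(weight = as.numeric(length(unique(position)))),
    by = .(a = kinase_id, b = substrate_id)]
  ks <- ks[a != b]
  edges <- data.table::data.table(
    a = pmin(ks$a, ks$b), b = pmax(ks$a, ks$b), weight = ks$weight)
  if (!is.null(ppi) && nrow(ppi) > 0L) {
    pe <- data.table::data.table(a = ppi$protein_a, b = ppi$protein_b,
                                 weight = 1)
    edges <- rbind(edges, pe)
    # same pair supported by both evidence types: keep the larger weight
    edges <- edges[, .(weight = max(weight)), by = .(a, b)]
  }
  if (nrow(edges) == 0L) stop("integrated network has no edges")
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  comp <- igraph::components(g)
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    # tie: keep the component holding the lexicographically smallest node
    first_node <- vapply(best, function(ci) {
      min(igraph::V(g)$name[comp$membership == ci])
    }, character(1))
    best <- best[order(first_node)][1L]
  }
  keep <- igraph::V(g)$name[comp$membership == best]
  g <- igraph::induced_subgraph(g, keep)
  kin <- sort(intersect(unique(pairs$kinase_id), igraph::V(g)$name))
  structure(list(graph = g, kinases = kin), class = "ksp_network")
}

#' Assemble a network directly from a weighted edge list
#'
#' Low-level constructor used when the edge weights are already known
#' (e.g. a persisted network, or hand-built graphs in tests); no largest
#' component filtering is applied beyond a connectivity check.
#'
#' @param edges data.frame with columns `from`, `to`, `weight` (weight
#'   defaults to 1 when absent).
#' @param kinases character vector of node ids flagged as kinases.
#' @return a `ksp_network`.
#' @export
ksp_network_from_edges <- function(edges, kinases = character(0)) {
  edges <- as.data.frame(edges)
  if (!"weight" %in% names(edges)) edges$weight <- 1
  if (any(edges$weight <= 0)) stop("edge weights must be positive")
  g <- igraph::graph_from_data_frame(edges[, c(1, 2)], directed = FALSE)
  igraph::E(g)$weight <- edges$weight
  if (igraph::any_multiple(g)) stop("duplicate edges in edge list")
  if (!igraph::is_connected(g)) stop("edge list describes a disconnected graph")
  structure(list(graph = g,
                 kinases = sort(intersect(kinases, igraph::V(g)$name))),
            class = "ksp_network")
}

#' @export
print.ksp_network <- function(x, ...) {
  cat(sprintf("<ksp_network: %d nodes (%d kinases), %d edges>\n",
              igraph::vcount(x$graph), length(x$kinases),
              igraph::ecount(x$graph)))
  invisible(x)
}

net_adjacency <- function(net) {
  g <- net$graph
  n <- igraph::vcount(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  w <- igraph::E(g)$weight
  nbr <- vector("list", n)
  wts <- vector("list", n)
  for (i in seq_len(n)) { nbr[[i]] <- integer(0); wts[[i]] <- numeric(0) }
  for (e in seq_len(nrow(el))) {
    a <- el[e, 1]; b <- el[e, 2]
    nbr[[a]] <- c(nbr[[a]], b); wts[[a]] <- c(wts[[a]], w[e])
    nbr[[b]] <- c(nbr[[b]], a); wts[[b]] <- c(wts[[b]], w[e])
  }
  list(nbr = nbr, wts = wts, names = igraph::V(g)$name)
}

net_weight_matrix <- function(net) {
  m <- igraph::as_adjacency_matrix(net$graph, attr = "weight", sparse = FALSE)
  storage.mode(m) <- "double"
  m
}

node_index <- function(net, id) {
  i <- match(id, igraph::V(net$graph)$name)
  if (is.na(i)) stop("unknown node: ", id)
  i
}

#' Degree-based punitive factor
#'
#' Damps the affinity of highly connected (over-studied) nodes. Nodes of
#' degree <= 2 get factor 1; otherwise the factor falls linearly in
#' log2-degree from 1 down to 0.8 at the maximum-degree node:
#' `1 - 0.2 * (log2 d_x - min_i log2 d_i) / (max_i log2 d_i - min_i log2 d_i)`
#' with min/max over all nodes of the network. A network whose log-degrees
#' are all equal (degenerate 0/0) gets factor 1.
#'
#' @param net a `ksp_network`.
#' @param node node identifier.
#' @return number in `[0.8, 1]`.
#' @export
punitive_factor <- function(net, node) {
  deg <- igraph::degree(net$graph)
  d <- deg[[node_index(net, node)]]
  if (d <= 2) return(1)
  ld <- log2(deg)
  lo <- min(ld); hi <- max(ld)
  if (hi == lo) return(1)
  # clamp guards floating-point drift at the ends of the [0.8, 1] image
  min(1, max(0.8, 1 - 0.2 * (log2(d) - lo) / (hi - lo)))
}

# sums of edge-weight products over simple paths start -> v of length 1..4,
# accumulated for every endpoint v in one DFS; intermediates never revisit
# any node on the current path (including start)
path_products_from <- function(adj, start, max_len = 4L) {
  n <- length(adj$nbr)
  acc <- matrix(0, n, max_len)
  visited <- logical(n)
  visited[start] <- TRUE
  recurse <- function(node, depth, prod) {
    nb <- adj$nbr[[node]]
    ww <- adj$wts[[node]]
    for (j in seq_along(nb)) {
      v <- nb[j]
      if (visited[v]) next
      p <- prod * ww[j]
      acc[v, depth] <<- acc[v, depth] + p
      if (depth < max_len) {
        visited[v] <<- TRUE
        recurse(v, depth + 1L, p)
        visited[v] <<- FALSE
      }
    }
  }
  recurse(start, 1L, 1)
  acc
}

#' Path-product terms KS0..KS3 between a kinase and a protein
#'
#' KS_l sums, over connections of length l+1 between the kinase and the
#' protein, the product of the edge weights along the connection: KS0 is
#' the direct edge weight, KS1 runs over common neighbours, KS2 and KS3
#' over length-3 and length-4 connections through the neighbourhoods of
#' both endpoints. In the default `"simple"` mode the intermediate nodes
#' exclude both endpoints and are pairwise distinct (simple paths). The
#' `"literal"` mode evaluates the nested neighbourhood sums exactly as
#' written, which also counts degenerate walks that revisit an endpoint;
#' algebraically those sums equal the entries of the 1st-4th powers of
#' the weighted adjacency matrix.
#'
#' @param net a `ksp_network`.
#' @param kinase,protein node identifiers, distinct.
#' @param mode `"simple"` or `"literal"`.
#' @return named numeric vector `c(KS0, KS1, KS2, KS3)`.
#' @export
ks_terms <- function(net, kinase, protein, mode = c("simple", "literal")) {
  mode <- match.arg(mode)
  ik <- node_index(net, kinase)
  in_ <- node_index(net, protein)
  if (ik == in_) stop("kinase and protein must be distinct nodes")
  if (mode == "simple") {
    acc <- path_products_from(net_adjacency(net), ik)
    out <- acc[in_, ]
  } else {
    w <- net_weight_matrix(net)
    w2 <- w %*% w
    w3 <- w2 %*% w
    w4 <- w3 %*% w
    out <- c(w[ik, in_], w2[ik, in_], w3[ik, in_], w4[ik, in_])
  }
  stats::setNames(out, c("KS0", "KS1", "KS2", "KS3"))
}

#' Network affinity score between a kinase and a protein
#'
#' The beta-weighted sum of the KS0..KS3 path-product terms, damped by the
#' punitive factor of the kinase:
#' `(beta0*KS0 + beta1*KS1 + beta2*KS2 + beta3*KS3) * p_d(kinase)`.
#'
#' @inheritParams ks_terms
#' @param beta length-4 non-negative weight vector; see [ksp_default_beta()].
#' @return non-negative number.
#' @export
ksp_score <- function(net, kinase, protein, beta = ksp_default_beta(),
                      mode = c("simple", "literal")) {
  beta <- check_beta(beta)
  ks <- ks_terms(net, kinase, protein, mode = mode)
  sum(beta * ks) * punitive_factor(net, kinase)
}

#' Build the kinase-protein bipartite affinity graph
#'
#' Scores every (kinase, non-kinase protein) pair of the network and stores
#' the affinity wherever it is nonzero, yielding the weighted bipartite
#' graph used to rank candidate kinases for a query site.
#'
#' @param net a `ksp_network`.
#' @param beta length-4 weight vector.
#' @param mode path semantics passed to [ks_terms()].
#' @return a `ksp_affinity`: list with `edges` (data.table kinase_id,
#'   protein_id, score), `kinases`, `proteins` (non-kinase node ids) and
#'   the `beta`/`mode` used.
#' @export
build_affinity_graph <- function(net, beta = ksp_default_beta(),
                                 mode = c("simple", "literal")) {
  mode <- match.arg(mode)
  beta <- check_beta(beta)
  names_v <- igraph::V(net$graph)$name
  kin <- net$kinases
  prot <- setdiff(names_v, kin)
  prot_idx <- match(prot, names_v)
  deg <- igraph::degree(net$graph)
  ld <- log2(deg)
  lo <- min(ld); hi <- max(ld)
  pd <- ifelse(deg <= 2 | hi == lo, 1,
               pmin(1, pmax(0.8, 1 - 0.2 * (ld - lo) / (hi - lo))))
  adj <- if (mode == "simple") net_adjacency(net) else NULL
  if (mode == "literal") {
    w <- net_weight_matrix(net)
    w2 <- w %*% w; w3 <- w2 %*% w; w4 <- w3 %*% w
  }
  res <- vector("list", length(kin))
  for (i in seq_along(kin)) {
    ik <- match(kin[i], names_v)
    acc <- if (mode == "simple") {
      path_products_from(adj, ik)
    } else {
      cbind(w[ik, ], w2[ik, ], w3[ik, ], w4[ik, ])
    }
    sc <- as.numeric(acc[prot_idx, , drop = FALSE] %*% beta) * pd[ik]
    nz <- sc != 0
    if (any(nz))
      res[[i]] <- data.table::data.table(kinase_id = kin[i],
                                         protein_id = prot[nz],
                                         score = sc[nz])
  }
  edges <- data.table::rbindlist(res)
  structure(list(edges = edges, kinases = kin, proteins = prot,
                 beta = beta, mode = mode),
            class = "ksp_affinity")
}

#' @export
print.ksp_affinity <- function(x, ...) {
  cat(sprintf("<ksp_affinity: %d kinases x %d proteins, %d nonzero scores (%s mode)>\n",
              length(x$kinases), length(x$proteins), nrow(x$edges), x$mode))
  invisible(x)
}

rank_candidates <- function(scores, top_k) {
  # descending score, lexicographic kinase id on ties; exact fp comparison
  ord <- order(-scores$score, scores$kinase_id)
  utils::head(scores[ord], top_k)
}

#' Rank candidate kinases for a phosphosite by network affinity
#'
#' The affinity of a site equals the affinity of its substrate protein, so
#' every site of one substrate shares the same network ranking. Returns at
#' most `top_k` kinases, descending by score, ties broken lexicographically.
#' A substrate absent from the affinity graph yields an empty ranking with
#' attribute `substrate_missing = TRUE`.
#'
#' @param affinity a `ksp_affinity`.
#' @param site a `phosphosite` (or any list with `substrate_id`).
#' @param top_k maximum number of candidates (default 10).
#' @return data.table with columns `kinase_id`, `score`.
#' @export
rank_kinases_network <- function(affinity, site, top_k = 10L) {
  stopifnot(top_k >= 1L)
  sub <- site$substrate_id
  hits <- affinity$edges[affinity$edges$protein_id == sub,
                         c("kinase_id", "score")]
  missing <- !(sub %in% affinity$proteins)
  out <- rank_candidates(hits, top_k)
  data.table::setattr(out, "substrate_missing", missing)
  out
}

#' Persist an affinity graph as a TSV file
#' @param affinity a `ksp_affinity`.
#' @param path output TSV path.
#' @export
write_affinity_graph <- function(affinity, path) {
  data.table::fwrite(affinity$edges, path, sep = "\t")
  invisible(path)
}
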