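# Independent brute-force oracles. These deliberately avoid the package's
# DFS / matrix-power code paths: the simple-path oracle enumerates ordered
# intermediate tuples, the literal oracle evaluates the nested neighbourhood
# sums with explicit loops, and the AUROC oracle counts concordant pairs.

weight_matrix_of <- function(net) {
  igraph::as_adjacency_matrix(net$graph, attr = "weight", sparse = FALSE)
}

# sum over simple paths k -> n of length len (edges), intermediates distinct
# and excluding both endpoints, of the product of edge weights
oracle_simple_paths <- function(w, k, n, len) {
  v <- seq_len(nrow(w))
  if (len == 1L) return(w[k, n])
  inter <- setdiff(v, c(k, n))
  if (length(inter) < len - 1L) return(0)
  tuples <- as.matrix(expand.grid(rep(list(inter), len - 1L)))
  total <- 0
  for (r in seq_len(nrow(tuples))) {
    tup <- tuples[r, ]
    if (anyDuplicated(tup)) next
    path <- c(k, tup, n)
    prod <- 1
    for (e in seq_len(len)) {
      prod <- prod * w[path[e], path[e + 1L]]
      if (prod == 0) break
    }
    total <- total + prod
  }
  total
}

oracle_ks_simple <- function(net, kinase, protein) {
  w <- weight_matrix_of(net)
  nm <- igraph::V(net$graph)$name
  k <- match(kinase, nm); n <- match(protein, nm)
  vapply(1:4, function(l) oracle_simple_paths(w, k, n, l), numeric(1))
}

# literal evaluation of the printed nested sums over neighbour sets
oracle_ks_literal <- function(net, kinase, protein) {
  w <- weight_matrix_of(net)
  nm <- igraph::V(net$graph)$name
  k <- match(kinase, nm); n <- match(protein, nm)
  nbrs <- function(x) which(w[x, ] > 0)
  common <- function(i, j) intersect(nbrs(i), nbrs(j))
  ks0 <- w[k, n]
  ks1 <- 0
  for (v in common(k, n)) ks1 <- ks1 + w[k, v] * w[v, n]
  ks2 <- 0
  for (vp in nbrs(k)) for (vq in common(vp, n))
    ks2 <- ks2 + w[k, vp] * w[vp, vq] * w[vq, n]
  ks3 <- 0
  for (vx in nbrs(k)) for (vy in nbrs(n)) for (vc in common(vx, vy))
    ks3 <- ks3 + w[k, vx] * w[vx, vc] * w[vc, vy] * w[vy, n]
  c(ks0, ks1, ks2, ks3)
}

# random connected weighted graph as a ksp_network; first node is a kinase
random_connected_net <- function(n_nodes, p = 0.4) {
  repeat {
    g <- igraph::sample_gnp(n_nodes, p)
    if (igraph::is_connected(g) && igraph::ecount(g) > 0) break
  }
  el <- igraph::as_edgelist(g)
  ids <- sprintf("N%02d", seq_len(n_nodes))
  edges <- data.frame(from = ids[el[, 1]], to = ids[el[, 2]],
                      weight = sample(c(0.5, 1, 2, 3), nrow(el),
                                      replace = TRUE))
  ksp_network_from_edges(edges, kinases = ids[1])
}

# AUROC as the fraction of (positive, negative) pairs ranked concordantly,
# ties counted 1/2
oracle_auroc <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# tiny deterministic pair table: k kinases x s sites on distinct substrates
toy_pairs <- function(peps_by_kinase, substrate_of = NULL) {
  rows <- list()
  for (k in names(peps_by_kinase)) {
    peps <- peps_by_kinase[[k]]
    subs <- if (is.null(substrate_of)) paste0("SUB_", k) else substrate_of[[k]]
    rows[[k]] <- data.table::data.table(
      kinase_id = k, substrate_id = rep_len(subs, length(peps)),
      position = seq_along(peps) * 10L,
      residue = substr(peps, 8, 8), peptide = peps)
  }
  data.table::rbindlist(rows)
}

rand_peptide <- function(centre = "S") {
  ch <- sample(kspnet:::AA20, 15, replace = TRUE)
  ch[8] <- centre
  paste0(ch, collapse = "")
}
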