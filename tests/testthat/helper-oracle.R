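# Shared fixtures and independent oracles.

# Brute-force graphlet orbit counter: enumerates every node subset of size
# 2-4, classifies connected induced subgraphs by degree sequence. Written
# independently of the package's ESU counter; used as the oracle.
brute_orbits <- function(g) {
  A <- as.matrix(igraph::as_adjacency_matrix(g)) > 0
  n <- nrow(A)
  O <- matrix(0L, n, 15)
  connected_subset <- function(idx) {
    k <- length(idx)
    seen <- logical(k); seen[1] <- TRUE; queue <- 1L
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(A[idx[v], idx] & !seen)
      seen[nb] <- TRUE; queue <- c(queue, nb)
    }
    all(seen)
  }
  bump <- function(nodes, orbit) O[nodes, orbit + 1L] <<- O[nodes, orbit + 1L] + 1L
  if (n >= 2) for (cmb in utils::combn(n, 2, simplify = FALSE))
    if (A[cmb[1], cmb[2]]) bump(cmb, 0)
  if (n >= 3) for (cmb in utils::combn(n, 3, simplify = FALSE)) {
    d <- rowSums(A[cmb, cmb]); e <- sum(d) / 2
    if (e == 2 && connected_subset(cmb)) { bump(cmb[d == 1], 1); bump(cmb[d == 2], 2) }
    if (e == 3) bump(cmb, 3)
  }
  if (n >= 4) for (cmb in utils::combn(n, 4, simplify = FALSE)) {
    if (!connected_subset(cmb)) next
    d <- rowSums(A[cmb, cmb]); e <- sum(d) / 2
    if (e == 3 && max(d) == 3) { bump(cmb[d == 1], 6); bump(cmb[d == 3], 7) }
    else if (e == 3) { bump(cmb[d == 1], 4); bump(cmb[d == 2], 5) }
    else if (e == 4 && max(d) == 3) { bump(cmb[d == 1], 9); bump(cmb[d == 2], 10); bump(cmb[d == 3], 11) }
    else if (e == 4) bump(cmb, 8)
    else if (e == 5) { bump(cmb[d == 2], 12); bump(cmb[d == 3], 13) }
    else bump(cmb, 14)
  }
  rownames(O) <- igraph::V(g)$name
  O
}

named_gnp <- function(n, p, seed) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("n%03d", seq_len(n))
  g
}

# small triangle / path networks used across tests
k3_net <- function() coocnet(
  data.frame(name = c("a", "b", "c"), kind = "OTU"),
  data.frame(node1 = c("a", "a", "b"), node2 = c("b", "c", "c"),
             sign = "copresence"))

p3_net <- function() coocnet(
  data.frame(name = c("a", "b", "c"), kind = "OTU"),
  data.frame(node1 = c("a", "b"), node2 = c("b", "c"), sign = "copresence"))

# toy otu table: 3 OTUs x 6 samples over 2 sites x 3 replicates
toy_otu <- function() {
  counts <- matrix(c(5, 0, 2, 4, 1, 3,
                     0, 0, 0, 1, 2, 0,
                     9, 8, 7, 6, 5, 4), 3, 6, byrow = TRUE,
                   dimnames = list(c("OTU1", "OTU2", "OTU3"),
                                   paste0("S", 1:6)))
  meta <- data.frame(sample = paste0("S", 1:6),
                     site = rep(1:2, each = 3),
                     replicate = rep(1:3, 2),
                     section = rep(1:2, each = 3))
  otu_table(counts,
            taxonomy = c("k__Bacteria; p__Actinobacteria; g__X",
                         "k__Bacteria; p__Proteobacteria; g__Y",
                         "k__Bacteria; p__Nitrospirae; g__Nitrospira"),
            sample_meta = meta)
}

# cached small simulated dataset shared across test files
.sim_cache <- new.env(parent = emptyenv())
sim_small <- function(n_otus = 100, seed = 11) {
  key <- paste(n_otus, seed)
  if (is.null(.sim_cache[[key]]))
    .sim_cache[[key]] <- simulate_dataset(
      simulation_config(n_otus = n_otus, seed = seed))
  .sim_cache[[key]]
}

identity_seqsim <- function(ids) {
  m <- diag(1, length(ids))
  dimnames(m) <- list(ids, ids)
  m
}
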