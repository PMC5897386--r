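# Graphlet degree vectors: per-node automorphism-orbit counts of connected
# induced subgraphs on 2-4 nodes (orbits 0-14, standard numbering) with an
# optional exhaustive size-5 extension, plus the log-scaled signature
# similarity used for topological node comparison.

#' Graphlet degree vector of every node
#'
#' Counts, for every node, how many connected induced subgraphs on up to
#' `max_graphlet` nodes it touches at each automorphism orbit. Orbits 0-14
#' (graphlets on 2-4 nodes) follow the standard numbering: orbit 0 is the
#' node degree, orbits 1/2 the path-3 end/centre, 3 the triangle, 4/5 the
#' path-4 end/middle, 6/7 the claw leaf/centre, 8 the 4-cycle, 9/10/11 the
#' tailed triangle tail/cycle/attachment, 12/13 the diamond rim/hub and 14
#' the 4-clique. With `max_graphlet = 5` a further 58 orbit columns are
#' appended by exhaustive enumeration; their order is the package's canonical
#' one (graphlets sorted by edge count then canonical adjacency string), and
#' because enumeration is exhaustive this option is intended for small
#' graphs.
#'
#' Edge signs are ignored: the graph is treated as simple and undirected.
#'
#' @param net a `coocnet`/`igraph`.
#' @param max_graphlet largest graphlet size, one of 3, 4, 5 (default 4).
#' @return integer matrix, nodes x orbits, with node names as row names.
#' @export
graphlet_degree_vector <- function(net, max_graphlet = 4) {
  if (!max_graphlet %in% c(3, 4, 5))
    stop("max_graphlet must be 3, 4 or 5")
  g <- igraph::simplify(as_igraph_net(net))
  n <- igraph::vcount(g)
  nm <- igraph::V(g)$name
  if (is.null(nm)) nm <- as.character(seq_len(n))
  el <- igraph::as_edgelist(g, names = FALSE)
  O <- orbit_counts_cpp(n, matrix(as.integer(el - 1), ncol = 2))
  rownames(O) <- nm
  colnames(O) <- paste0("O", 0:14)
  if (max_graphlet == 3) return(O[, 1:4, drop = FALSE])
  if (max_graphlet == 4) return(O)
  O5 <- .count_orbits5(g)
  rownames(O5) <- nm
  cbind(O, O5)
}

#' Similarity of two graphlet signatures
#'
#' Per-orbit distance `D_i = w_i |log(u_i + 1) - log(v_i + 1)| /
#' log(max(u_i, v_i) + 2)`; similarity is `1 - sum(D_i) / sum(w_i)`, in
#' \[0, 1\], with unit weights by default.
#'
#' @param u_sig,v_sig equal-length orbit-count vectors.
#' @param weights per-orbit weights (default all 1).
#' @return similarity in \[0, 1\].
#' @export
signature_similarity <- function(u_sig, v_sig, weights = NULL) {
  if (length(u_sig) != length(v_sig))
    stop("signatures must have equal length")
  if (is.null(weights)) weights <- rep(1, length(u_sig))
  D <- weights * abs(log(u_sig + 1) - log(v_sig + 1)) /
    log(pmax(u_sig, v_sig) + 2)
  1 - sum(D) / sum(weights)
}

# all-pairs signature similarity between the rows of two signature matrices
.signature_similarity_matrix <- function(S1, S2, weights = NULL) {
  stopifnot(ncol(S1) == ncol(S2))
  if (is.null(weights)) weights <- rep(1, ncol(S1))
  D <- matrix(0, nrow(S1), nrow(S2), dimnames = list(rownames(S1),
                                                     rownames(S2)))
  for (k in seq_len(ncol(S1))) {
    u <- S1[, k]; v <- S2[, k]
    D <- D + weights[k] * abs(outer(log(u + 1), log(v + 1), "-")) /
      log(outer(u, v, pmax) + 2)
  }
  1 - D / sum(weights)
}

## ---- size-5 extension (exhaustive; small graphs) ----

.permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  out
}

.canon5 <- function(adj, perms) {
  # minimum upper-triangle bit string over vertex permutations; returns the
  # string and the first permutation attaining it
  iu <- which(upper.tri(adj))
  best <- NULL; best_perm <- NULL
  for (r in seq_len(nrow(perms))) {
    p <- perms[r, ]
    key <- paste(adj[p, p][iu] * 1L, collapse = "")
    if (is.null(best) || key < best) { best <- key; best_perm <- p }
  }
  list(key = best, perm = best_perm)
}

# catalogue of connected 5-node graphs: canonical key -> orbit ids per
# canonical vertex position (orbit ids start at 15, assigned in order of
# (edge count, canonical key))
.graphlet5_catalog <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    perms <- .permutations(5L)
    iu <- which(upper.tri(matrix(0, 5, 5)))
    seen <- list()
    for (bits in 0:(2^10 - 1)) {
      v <- as.integer(intToBits(bits))[1:10]
      adj <- matrix(0L, 5, 5)
      adj[iu] <- v
      adj <- adj + t(adj)
      g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
      if (!igraph::is_connected(g)) next
      key <- .canon5(adj, perms)$key
      if (is.null(seen[[key]])) seen[[key]] <- list(adj = adj, e = sum(v))
    }
    keys <- names(seen)
    ord <- order(vapply(seen, `[[`, numeric(1), "e")[keys], keys)
    keys <- keys[ord]
    orbit_base <- 15L
    catalog <- list()
    for (key in keys) {
      adj <- seen[[key]]$adj
      # automorphisms of the canonical representative
      canon <- .canon5(adj, perms)
      cadj <- adj[canon$perm, canon$perm]
      orbit_of <- seq_len(5)
      for (r in seq_len(nrow(perms))) {
        p <- perms[r, ]
        if (all(cadj[p, p] == cadj)) {
          # permuted graph equal: vertex i in the permuted labelling
          # corresponds to vertex p[i]; i and p[i] share an orbit
          for (i in 1:5) {
            a <- min(orbit_of[i], orbit_of[p[i]])
            orbit_of[orbit_of == orbit_of[i] | orbit_of == orbit_of[p[i]]] <- a
          }
        }
      }
      uo <- sort(unique(orbit_of))
      ids <- orbit_base + match(orbit_of, uo) - 1L
      catalog[[key]] <- list(cadj = cadj, orbit_ids = ids)
      orbit_base <- orbit_base + length(uo)
    }
    cache <<- list(catalog = catalog, n_orbits = orbit_base - 15L,
                   perms = perms)
    cache
  }
})

.count_orbits5 <- function(g) {
  cat5 <- .graphlet5_catalog()
  n <- igraph::vcount(g)
  O <- matrix(0L, n, cat5$n_orbits,
              dimnames = list(NULL, paste0("O", 15:(15 + cat5$n_orbits - 1))))
  if (n < 5) return(O)
  adjm <- as.matrix(igraph::as_adjacency_matrix(g)) > 0
  nbrs <- lapply(seq_len(n), function(i) which(adjm[i, ]))
  # ESU enumeration of connected induced subgraphs of size 5
  visit <- function(sub, ext) {
    if (length(sub) == 5) {
      adj <- adjm[sub, sub] * 1L
      cn <- .canon5(adj, cat5$perms)
      entry <- cat5$catalog[[cn$key]]
      # vertex sub[i] maps to canonical position where? cn$perm maps new
      # positions to old: cadj = adj[perm, perm]; canonical position j holds
      # original index perm[j]
      cols <- entry$orbit_ids - 14L
      for (j in 1:5) O[sub[cn$perm[j]], cols[j]] <<-
          O[sub[cn$perm[j]], cols[j]] + 1L
      return(invisible())
    }
    while (length(ext)) {
      w <- ext[1]; ext <- ext[-1]
      excl <- nbrs[[w]]
      excl <- excl[excl > sub[1] & !excl %in% sub &
                     !vapply(excl, function(u) any(adjm[u, sub]), logical(1))]
      visit(c(sub, w), c(ext, excl))
    }
  }
  for (v in seq_len(n)) {
    ext <- nbrs[[v]]
    ext <- ext[ext > v]
    visit(v, ext)
  }
  O
}
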