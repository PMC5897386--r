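# Alpha-weighted global network alignment: sequence identity + graphlet
# topology node scores, deterministic greedy seed-and-extend optimisation
# with a conserved-edge bonus, edge correctness / symmetric substructure
# scoring, the alpha scan, and validation against randomised networks.
#
# Alpha convention: alpha = 1 aligns on sequence identity only, alpha = 0 on
# graphlet topology only (the microbial-network convention adopted here; note
# this is flipped relative to the original protein-network aligner's alpha).

#' Pairwise global-alignment sequence identity
#'
#' Needleman-Wunsch global alignment (match 1, mismatch -1, gap -2 by
#' default); identity is the number of matching columns divided by the
#' alignment length.
#'
#' @param seqs named character vector of A/C/G/T/N sequences, a
#'   `Biostrings::DNAStringSet`, or a FASTA file path.
#' @param match,mismatch,gap scoring parameters.
#' @return a [seq_similarity()] matrix.
#' @export
pairwise_identity <- function(seqs, match = 1, mismatch = -1, gap = -2) {
  if (is.character(seqs) && length(seqs) == 1 && file.exists(seqs))
    seqs <- Biostrings::readDNAStringSet(seqs)
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  n <- length(seqs)
  if (n < 2) stop("need at least 2 sequences")
  if (any(Biostrings::width(seqs) == 0)) stop("empty sequence")
  nm <- names(seqs)
  if (is.null(nm)) nm <- paste0("seq", seq_len(n))
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = FALSE)
  idm <- diag(1, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    aln <- Biostrings::pairwiseAlignment(seqs[[i]], seqs[[j]],
                                         type = "global",
                                         substitutionMatrix = mat,
                                         gapOpening = 0, gapExtension = -gap)
    a <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
    b <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
    idm[i, j] <- idm[j, i] <- sum(a == b & a != "-") / length(a)
  }
  dimnames(idm) <- list(nm, nm)
  seq_similarity(idm)
}

#' Alpha-weighted node score
#'
#' `score = alpha * seqsim + (1 - alpha) * toposim`. VARIABLE nodes have
#' sequence similarity 1 for identical variable names and 0 otherwise.
#'
#' @param u,v node names (informational only).
#' @param alpha mixing weight in \[0, 1\].
#' @param seqsim,toposim similarities in \[0, 1\].
#' @return the mixed score.
#' @export
node_score <- function(u, v, alpha, seqsim, toposim) {
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  alpha * seqsim + (1 - alpha) * toposim
}

# assemble the base score matrix for two networks; cross-kind pairs get -Inf
.alignment_scores_matrix <- function(g1, g2, alpha, seqsim, max_graphlet,
                                     gdv1 = NULL, gdv2 = NULL) {
  n1 <- igraph::V(g1)$name; n2 <- igraph::V(g2)$name
  k1 <- igraph::vertex_attr(g1, "kind"); k2 <- igraph::vertex_attr(g2, "kind")
  if (is.null(k1)) k1 <- rep("OTU", length(n1))
  if (is.null(k2)) k2 <- rep("OTU", length(n2))
  if (is.null(gdv1)) gdv1 <- graphlet_degree_vector(g1, max_graphlet)
  if (is.null(gdv2)) gdv2 <- graphlet_degree_vector(g2, max_graphlet)
  topo <- .signature_similarity_matrix(gdv1[n1, , drop = FALSE],
                                       gdv2[n2, , drop = FALSE])
  seqm <- matrix(0, length(n1), length(n2), dimnames = list(n1, n2))
  o1 <- n1[k1 == "OTU"]; o2 <- n2[k2 == "OTU"]
  if (!is.null(seqsim)) {
    miss <- c(setdiff(o1, rownames(seqsim)), setdiff(o2, colnames(seqsim)))
    if (length(miss))
      stop("sequence similarity missing for node(s): ",
           paste(utils::head(miss, 3), collapse = ", "))
    seqm[o1, o2] <- seqsim[o1, o2]
  } else if (alpha > 0) {
    # identity fallback: same name -> 1
    common <- intersect(o1, o2)
    seqm[cbind(common, common)] <- 1
  }
  v1 <- n1[k1 == "VARIABLE"]; v2 <- n2[k2 == "VARIABLE"]
  if (length(v1) && length(v2))
    seqm[v1, v2] <- outer(v1, v2, "==") * 1
  S <- alpha * seqm + (1 - alpha) * topo
  cross <- outer(k1, k2, "!=")
  S[cross] <- -Inf
  S
}

#' Align two co-occurrence networks
#'
#' Deterministic greedy seed-and-extend: a candidate pair's utility is its
#' alpha-weighted node score plus `edge_bonus` times the number of already
#' aligned neighbour pairs the pair would conserve. The best candidate is
#' committed repeatedly (ties broken by lexicographic id pair), until no
#' candidate reaches `min_score` or the smaller network is exhausted. Only
#' same-kind pairs (OTU-OTU, VARIABLE-VARIABLE) are eligible; edge signs are
#' ignored for topology.
#'
#' @param net1,net2 non-empty `coocnet`/`igraph` networks.
#' @param alpha sequence weight in \[0, 1\] (see [node_score()]).
#' @param seqsim sequence-identity matrix covering the OTU nodes of both
#'   networks (rows: net1, columns: net2, by name); may be `NULL` at
#'   `alpha = 0`, or to fall back to name identity.
#' @param edge_bonus utility bonus per conserved neighbour pair
#'   (default 0.5).
#' @param min_score stop threshold on candidate utility (default 0).
#' @param max_graphlet graphlet size for topology signatures (default 4).
#' @param gdv1,gdv2 optional precomputed [graphlet_degree_vector()] matrices.
#' @return an object of class `alignment_result`: list with `alpha`,
#'   `mapping` (`data.frame` node1, node2, score), `ec`, `ss` (percent),
#'   `conserved` (conserved edge `data.frame`).
#' @export
align_networks <- function(net1, net2, alpha, seqsim = NULL, edge_bonus = 0.5,
                           min_score = 0, max_graphlet = 4,
                           gdv1 = NULL, gdv2 = NULL) {
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  g1 <- as_igraph_net(net1); g2 <- as_igraph_net(net2)
  if (igraph::vcount(g1) == 0 || igraph::vcount(g2) == 0)
    stop("both networks must be non-empty")
  S <- .alignment_scores_matrix(g1, g2, alpha, seqsim, max_graphlet,
                                gdv1, gdv2)
  n1 <- rownames(S); n2 <- colnames(S)
  # id-sorted orders make the lexicographic tie-break a plain first-index scan
  S <- S[order(n1), order(n2), drop = FALSE]
  n1 <- rownames(S); n2 <- colnames(S)
  nb1 <- lapply(igraph::adjacent_vertices(g1, n1), function(v) v$name)
  nb2 <- lapply(igraph::adjacent_vertices(g2, n2), function(v) v$name)
  names(nb1) <- n1; names(nb2) <- n2
  B <- matrix(0, nrow(S), ncol(S), dimnames = dimnames(S))
  free1 <- rep(TRUE, length(n1)); names(free1) <- n1
  free2 <- rep(TRUE, length(n2)); names(free2) <- n2
  pairs <- list()
  limit <- min(length(n1), length(n2))
  eps <- 1e-12
  while (length(pairs) < limit) {
    M <- S + B
    M[!free1, ] <- -Inf
    M[, !free2] <- -Inf
    mx <- max(M)
    if (!is.finite(mx) || mx < min_score) break
    hit <- which(M >= mx - eps, arr.ind = TRUE)
    # lexicographic (node1, node2) tie-break on the id-sorted matrix
    hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
    i <- hit[1, 1]; j <- hit[1, 2]
    u <- n1[i]; v <- n2[j]
    pairs[[length(pairs) + 1]] <- data.frame(node1 = u, node2 = v,
                                             score = S[i, j],
                                             stringsAsFactors = FALSE)
    free1[i] <- FALSE; free2[j] <- FALSE
    au <- nb1[[u]]; av <- nb2[[v]]
    au <- au[free1[au]]; av <- av[free2[av]]
    if (length(au) && length(av))
      B[au, av] <- B[au, av] + edge_bonus
  }
  mapping <- if (length(pairs)) do.call(rbind, pairs)
             else data.frame(node1 = character(), node2 = character(),
                             score = numeric(), stringsAsFactors = FALSE)
  res <- structure(list(alpha = alpha, mapping = mapping,
                        ec = NA_real_, ss = NA_real_, conserved = NULL),
                   class = "alignment_result")
  sc <- alignment_scores(res, g1, g2)
  res$ec <- sc$ec; res$ss <- sc$ss; res$conserved <- sc$conserved
  res
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("alignment_result: alpha %.2f, %d pairs, EC %.2f%%, SS %.2f%%\n",
              x$alpha, nrow(x$mapping),
              if (is.na(x$ec)) NaN else x$ec,
              if (is.na(x$ss)) NaN else x$ss))
  invisible(x)
}

#' Edge correctness and symmetric substructure score of an alignment
#'
#' With the smaller-edge-count network as source, f the mapping and C the
#' number of source edges mapped onto edges of the target:
#' `EC = 100 C / |E_source|` and
#' `SS = 100 C / (|E_source| + |E_target induced on f(V_source)| - C)`.
#'
#' @param result an `alignment_result` (or its `mapping` data.frame).
#' @param net1,net2 the aligned networks, in the order used for alignment.
#' @return list with `ec`, `ss` (percent; `NA` when the source edge set is
#'   empty) and `conserved` (the conserved source edges).
#' @export
alignment_scores <- function(result, net1, net2) {
  mapping <- if (inherits(result, "alignment_result")) result$mapping
             else as.data.frame(result)
  g1 <- as_igraph_net(net1); g2 <- as_igraph_net(net2)
  if (igraph::ecount(g2) < igraph::ecount(g1)) {
    mapping <- data.frame(node1 = mapping$node2, node2 = mapping$node1,
                          stringsAsFactors = FALSE)
    tmp <- g1; g1 <- g2; g2 <- tmp
  }
  e1 <- igraph::ecount(g1)
  if (e1 == 0)
    return(list(ec = NA_real_, ss = NA_real_,
                conserved = data.frame(node1 = character(),
                                       node2 = character())))
  f <- stats::setNames(mapping$node2, mapping$node1)
  el1 <- igraph::as_edgelist(g1, names = TRUE)
  a <- f[el1[, 1]]; b <- f[el1[, 2]]
  ok <- !is.na(a) & !is.na(b)
  conserved <- rep(FALSE, nrow(el1))
  if (any(ok)) {
    adj2 <- igraph::as_adjacency_matrix(g2, sparse = TRUE) > 0
    ai <- match(a[ok], rownames(adj2))
    bi <- match(b[ok], colnames(adj2))
    conserved[ok] <- adj2[cbind(ai, bi)]
  }
  C <- sum(conserved)
  img <- unname(f[!is.na(f)])
  img <- intersect(img, igraph::V(g2)$name)
  e2_ind <- igraph::ecount(igraph::induced_subgraph(g2, img))
  ec <- 100 * C / e1
  ss <- 100 * C / (e1 + e2_ind - C)
  list(ec = ec, ss = ss,
       conserved = data.frame(node1 = el1[conserved, 1],
                              node2 = el1[conserved, 2],
                              stringsAsFactors = FALSE))
}

#' Scan the alignment mixing weight alpha
#'
#' Aligns the two networks at every grid point and tabulates EC, SS and the
#' number of nodes aligned to themselves. The consensus alpha maximises the
#' harmonic mean of EC and SS (ties resolved towards the smaller alpha).
#'
#' @param net1,net2 networks.
#' @param grid alpha grid (default 0, 0.1, ..., 1).
#' @param seqsim sequence-identity matrix (see [align_networks()]).
#' @param ... further arguments to [align_networks()].
#' @return list with `table` (`data.frame`: alpha, ec, ss, n_self),
#'   `consensus_alpha` and `results` (the alignment_result objects).
#' @export
alpha_scan <- function(net1, net2, grid = seq(0, 1, by = 0.1),
                       seqsim = NULL, ...) {
  g1 <- as_igraph_net(net1); g2 <- as_igraph_net(net2)
  gdv1 <- graphlet_degree_vector(g1)
  gdv2 <- graphlet_degree_vector(g2)
  results <- lapply(grid, function(a)
    align_networks(g1, g2, alpha = a, seqsim = seqsim,
                   gdv1 = gdv1, gdv2 = gdv2, ...))
  tab <- data.frame(alpha = grid,
                    ec = vapply(results, `[[`, numeric(1), "ec"),
                    ss = vapply(results, `[[`, numeric(1), "ss"),
                    n_self = vapply(results, function(r)
                      sum(r$mapping$node1 == r$mapping$node2), numeric(1)))
  hm <- ifelse(is.na(tab$ec) | is.na(tab$ss) | (tab$ec + tab$ss) == 0, 0,
               2 * tab$ec * tab$ss / (tab$ec + tab$ss))
  best <- which(hm >= max(hm) - 1e-9)
  consensus <- tab$alpha[best[which.min(tab$alpha[best])]]
  list(table = tab, consensus_alpha = consensus, results = results)
}

#' Compare a real alignment against randomised-network alignments
#'
#' Aligns `net1` to `net2`, then to `n_random` edge-shuffled randomisations
#' of `net2` ([randomize_network()]), and reports z-scores of the real EC
#' and SS against the random score distributions.
#'
#' @param net1,net2 networks.
#' @param n_random number of randomisations (must be >= 1).
#' @param alpha mixing weight.
#' @param seqsim sequence-identity matrix.
#' @param seed integer RNG seed.
#' @param ... further arguments to [align_networks()].
#' @return list with `ec`, `ss` (real scores), `random_ec`, `random_ss`,
#'   `z_ec`, `z_ss` (`Inf` flagged when the random sd is 0).
#' @export
compare_to_random <- function(net1, net2, n_random = 20, alpha = 0,
                              seqsim = NULL, seed = 1, ...) {
  if (n_random < 1) stop("n_random must be >= 1")
  real <- align_networks(net1, net2, alpha = alpha, seqsim = seqsim, ...)
  rnd <- lapply(seq_len(n_random), function(i) {
    nr <- randomize_network(net2, seed = derive_seed(seed, paste0("rand", i)))
    align_networks(net1, nr, alpha = alpha, seqsim = seqsim, ...)
  })
  rec <- vapply(rnd, `[[`, numeric(1), "ec")
  rss <- vapply(rnd, `[[`, numeric(1), "ss")
  zf <- function(x, xs) {
    s <- stats::sd(xs)
    if (is.na(s) || s == 0) {
      if (x > mean(xs)) Inf else if (x < mean(xs)) -Inf else 0
    } else (x - mean(xs)) / s
  }
  list(ec = real$ec, ss = real$ss, random_ec = rec, random_ss = rss,
       z_ec = zf(real$ec, rec), z_ss = zf(real$ss, rss))
}

#' Export hiveplot data for an alignment
#'
#' Emits, per node: its axis (network 1 or 2), sub-axis (core/noncore), rank
#' by log relative abundance within its axis, and size by degree centrality;
#' plus the alignment edges. Written as JSON for downstream rendering.
#'
#' @param aln an `alignment_result`.
#' @param net1,net2 the aligned networks.
#' @param otu the community [otu_table()] (for relative abundances).
#' @param core character vector of core OTU ids.
#' @param path output JSON path.
#' @return the exported list, invisibly.
#' @export
hiveplot_export <- function(aln, net1, net2, otu, core, path) {
  rel <- relative_abundance(otu)
  mean_rel <- rowMeans(rel)
  node_rows <- function(g, axis) {
    nm <- igraph::V(g)$name
    kind <- igraph::vertex_attr(g, "kind")
    if (is.null(kind)) kind <- rep("OTU", length(nm))
    ab <- ifelse(nm %in% names(mean_rel), mean_rel[nm], NA)
    lg <- log10(pmax(ab, 1e-12))
    deg <- igraph::degree(g)
    data.frame(node = nm, axis = axis,
               sub_axis = ifelse(kind != "OTU", "variable",
                                 ifelse(nm %in% core, "core", "noncore")),
               abundance_rank = rank(-lg, ties.method = "first"),
               degree_centrality = deg / max(1, igraph::vcount(g) - 1),
               stringsAsFactors = FALSE)
  }
  out <- list(nodes = rbind(node_rows(as_igraph_net(net1), 1L),
                            node_rows(as_igraph_net(net2), 2L)),
              alignment = aln$mapping,
              alpha = aln$alpha, ec = aln$ec, ss = aln$ss)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(out)
}
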