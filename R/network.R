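# Signed co-occurrence network container, GraphML / edge-TSV IO, whole-graph
# statistics, degree-distribution model choice and the edge-shuffling
# randomisation null.

#' Construct a co-occurrence network
#'
#' A `coocnet` is an undirected simple graph over OTU and VARIABLE nodes.
#' Vertex attributes: `kind` ("OTU" or "VARIABLE"), `taxonomy` (OTU only,
#' may be `NA`), optional `core` flag. Edge attributes: `sign` ("copresence"
#' or "exclusion") and, for inferred networks, `q` (merged BH-adjusted
#' p-value) and the four observed measure scores.
#'
#' @param nodes `data.frame` with columns `name`, `kind` and optionally
#'   `taxonomy`, `core`.
#' @param edges `data.frame` with columns `node1`, `node2`, `sign` and
#'   optionally `q` and measure scores; may be empty or `NULL`.
#' @return an `igraph` object with class `coocnet` prepended.
#' @export
coocnet <- function(nodes, edges = NULL) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  if (!all(c("name", "kind") %in% names(nodes)))
    stop("nodes needs 'name' and 'kind' columns")
  if (anyDuplicated(nodes$name))
    stop("duplicate node name(s): ",
         paste(unique(nodes$name[duplicated(nodes$name)]), collapse = ", "))
  if (!all(nodes$kind %in% c("OTU", "VARIABLE")))
    stop("kind must be 'OTU' or 'VARIABLE'")
  if (is.null(edges) || nrow(edges) == 0) {
    g <- igraph::make_empty_graph(n = 0, directed = FALSE)
    g <- igraph::add_vertices(g, nrow(nodes))
    for (cn in names(nodes))
      g <- igraph::set_vertex_attr(g, if (cn == "name") "name" else cn,
                                   value = nodes[[cn]])
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    if (!all(c("node1", "node2") %in% names(edges)))
      stop("edges needs 'node1' and 'node2' columns")
    if (any(edges$node1 == edges$node2)) stop("self-loop edges not allowed")
    key <- paste(pmin(edges$node1, edges$node2),
                 pmax(edges$node1, edges$node2))
    if (anyDuplicated(key)) stop("parallel edges not allowed")
    miss <- setdiff(c(edges$node1, edges$node2), nodes$name)
    if (length(miss)) stop("edge endpoint(s) not in node table: ",
                           paste(utils::head(miss, 3), collapse = ", "))
    g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                       vertices = nodes)
  }
  class(g) <- unique(c("coocnet", class(g)))
  g
}

as_igraph_net <- function(net) {
  if (igraph::is_igraph(net)) return(net)
  stop("expected an igraph/coocnet object")
}

#' OTU node names of a network
#' @param net a `coocnet`/`igraph`.
#' @return character vector of OTU node names.
#' @export
otu_nodes <- function(net) {
  g <- as_igraph_net(net)
  kind <- igraph::vertex_attr(g, "kind")
  nm <- igraph::V(g)$name
  if (is.null(kind)) nm else nm[kind == "OTU"]
}

#' Write a co-occurrence network to GraphML or edge TSV
#'
#' GraphML preserves all node and edge attributes (node kind, taxonomy, core
#' flag, centrality, abundance flag, edge sign, measure scores, merged
#' q-value) and round-trips through [read_network()]. The edge TSV holds one
#' edge per line: `node1`, `node2`, `sign`, `q`.
#'
#' @param net a `coocnet`/`igraph`.
#' @param path output path.
#' @param format `"graphml"` or `"edge-tsv"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("graphml", "edge-tsv")) {
  format <- match.arg(format)
  g <- as_igraph_net(net)
  if (format == "graphml") {
    cg <- g
    class(cg) <- "igraph"
    igraph::write_graph(cg, path, format = "graphml")
  } else {
    ed <- igraph::as_data_frame(g, what = "edges")
    names(ed)[1:2] <- c("node1", "node2")
    if (!"sign" %in% names(ed)) ed$sign <- NA_character_
    if (!"q" %in% names(ed)) ed$q <- NA_real_
    utils::write.table(ed[c("node1", "node2", "sign", "q")], path,
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
  }
  invisible(path)
}

#' Read a network written by [write_network()]
#' @param path input path.
#' @param format `"graphml"` or `"edge-tsv"`.
#' @return a `coocnet`.
#' @export
read_network <- function(path, format = c("graphml", "edge-tsv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    g <- igraph::delete_vertex_attr(g, "id")
    class(g) <- unique(c("coocnet", class(g)))
    return(g)
  }
  ed <- utils::read.delim(path, check.names = FALSE)
  nodes <- data.frame(name = unique(c(ed$node1, ed$node2)),
                      kind = "OTU", stringsAsFactors = FALSE)
  coocnet(nodes, ed)
}

#' Parse a supplementary network node/edge table (TSV export)
#'
#' Reads a TSV export of a published per-section network table and reports the
#' node and edge composition: number of OTU nodes, VARIABLE nodes and, when
#' edge columns are present, co-presence and exclusion edge counts. Parsing is
#' header-name driven; when the headers are not recognised the function fails
#' listing the headers it found rather than guessing a mapping. Spreadsheet
#' originals must be exported to TSV first (no XLSX reader is used).
#'
#' @param path TSV path.
#' @param section section id (1 or 2), recorded in the output.
#' @param column_map optional named list overriding header detection; entries
#'   among `id`, `kind`, `taxonomy`, `node1`, `node2`, `sign`.
#' @return list with `nodes` (data.frame), `edges` (data.frame or `NULL`),
#'   `network` (a [coocnet()] when edges are available, else `NULL`) and
#'   `counts` (named list: `n_nodes`, `n_otu`, `n_variable`, and edge counts
#'   when available).
#' @export
read_supplementary_network_table <- function(path, section, column_map = NULL) {
  stopifnot(section %in% c(1, 2))
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = "character")
  if (nrow(df) == 0) stop("empty table: ", path)
  hdr <- names(df)
  pick <- function(role, candidates) {
    if (!is.null(column_map[[role]])) {
      if (!column_map[[role]] %in% hdr)
        stop("column_map['", role, "'] = '", column_map[[role]],
             "' not among headers: ", paste(hdr, collapse = ", "))
      return(column_map[[role]])
    }
    hit <- hdr[tolower(hdr) %in% candidates]
    if (length(hit)) hit[1] else NA_character_
  }
  id_col <- pick("id", c("id", "name", "otu", "otu id", "#otu id", "node"))
  kind_col <- pick("kind", c("kind", "type", "node type"))
  tax_col <- pick("taxonomy", c("taxonomy", "lineage", "taxon"))
  n1_col <- pick("node1", c("node1", "source", "from"))
  n2_col <- pick("node2", c("node2", "target", "to"))
  sign_col <- pick("sign", c("sign", "interaction", "association"))
  has_edges <- !is.na(n1_col) && !is.na(n2_col)
  if (is.na(id_col) && !has_edges)
    stop("unrecognised layout; detected column headers: ",
         paste(hdr, collapse = ", "))

  known_vars <- c("pH", "Temperature", "RelativeHumidity", "Relative Humidity",
                  "N_total", "N total", "C_total", "C total", "P", "S", "Cu",
                  "Fe", "Zn", "K", "Ca", "Na", "Mg", "NO3", "NH4", "EC")
  if (!is.na(id_col)) {
    nodes <- data.frame(name = df[[id_col]], stringsAsFactors = FALSE)
    if (!is.na(kind_col)) {
      kd <- toupper(df[[kind_col]])
      nodes$kind <- ifelse(grepl("VAR", kd), "VARIABLE", "OTU")
    } else {
      nodes$kind <- ifelse(nodes$name %in% known_vars |
                             !grepl("^(OTU|[0-9])", nodes$name, ignore.case = TRUE) &
                             nodes$name %in% known_vars,
                           "VARIABLE", "OTU")
      nodes$kind[nodes$name %in% known_vars] <- "VARIABLE"
    }
    if (!is.na(tax_col)) nodes$taxonomy <- df[[tax_col]]
    nodes <- unique(nodes)
  } else {
    nm <- unique(c(df[[n1_col]], df[[n2_col]]))
    nodes <- data.frame(name = nm,
                        kind = ifelse(nm %in% known_vars, "VARIABLE", "OTU"),
                        stringsAsFactors = FALSE)
  }
  edges <- NULL
  net <- NULL
  counts <- list(section = section,
                 n_nodes = nrow(nodes),
                 n_otu = sum(nodes$kind == "OTU"),
                 n_variable = sum(nodes$kind == "VARIABLE"))
  if (has_edges) {
    edges <- data.frame(node1 = df[[n1_col]], node2 = df[[n2_col]],
                        stringsAsFactors = FALSE)
    if (!is.na(sign_col)) {
      sg <- tolower(df[[sign_col]])
      edges$sign <- ifelse(grepl("co|pos|\\+", sg), "copresence", "exclusion")
    } else edges$sign <- NA_character_
    miss <- setdiff(unique(c(edges$node1, edges$node2)), nodes$name)
    if (length(miss))
      nodes <- rbind(nodes[names(nodes) %in% c("name", "kind")],
                     data.frame(name = miss,
                                kind = ifelse(miss %in% known_vars,
                                              "VARIABLE", "OTU")))
    net <- coocnet(nodes, edges)
    counts$n_edges <- nrow(edges)
    counts$n_copresence <- sum(edges$sign == "copresence", na.rm = TRUE)
    counts$n_exclusion <- sum(edges$sign == "exclusion", na.rm = TRUE)
    counts$n_nodes <- nrow(nodes)
    counts$n_otu <- sum(nodes$kind == "OTU")
    counts$n_variable <- sum(nodes$kind == "VARIABLE")
  }
  list(nodes = nodes, edges = edges, network = net, counts = counts)
}

#' Whole-graph statistics of a network
#'
#' Clustering coefficient is the mean local transitivity with nodes of degree
#' < 2 contributing 0; characteristic path length is the mean shortest-path
#' length over connected (reachable) node pairs; density is 2E / (N (N - 1));
#' heterogeneity is sd(degree) / mean(degree).
#'
#' @param net a `coocnet`/`igraph`.
#' @return list with `n_nodes`, `n_edges`, `clustering`, `path_length`,
#'   `density`, `heterogeneity`, `degree_sequence`, `verdict` (see
#'   [degree_distribution_verdict()]).
#' @export
network_stats <- function(net) {
  g <- as_igraph_net(net)
  n <- igraph::vcount(g)
  m <- igraph::ecount(g)
  deg <- igraph::degree(g)
  cl <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  clustering <- if (n) mean(cl) else NA_real_
  pl <- NA_real_
  if (m > 0) {
    d <- igraph::distances(g)
    vals <- d[upper.tri(d)]
    vals <- vals[is.finite(vals) & vals > 0]
    pl <- if (length(vals)) mean(vals) else NA_real_
  }
  dens <- if (n > 1) 2 * m / (n * (n - 1)) else NA_real_
  het <- if (n && mean(deg) > 0) stats::sd(deg) / mean(deg) else 0
  if (n && stats::sd(deg) == 0) het <- 0
  list(n_nodes = n, n_edges = m, clustering = clustering,
       path_length = pl, density = dens, heterogeneity = het,
       degree_sequence = unname(deg),
       verdict = degree_distribution_verdict(deg))
}

#' Degree-distribution model verdict: random-graph vs power-law
#'
#' Fits a zero-truncated Poisson (the Erdos-Renyi-like model) and a discrete
#' power law with `xmin = 1` (zeta distribution) to the positive degrees by
#' maximum likelihood and compares them by a Vuong-normalised log-likelihood
#' ratio. `|LR| < 2` (or fewer than 30 positive degrees) is inconclusive.
#'
#' @param x a network or a numeric degree sequence.
#' @return one of `"erdos-renyi-like"`, `"power-law-like"`, `"inconclusive"`.
#' @export
degree_distribution_verdict <- function(x) {
  deg <- if (is.numeric(x)) x else igraph::degree(as_igraph_net(x))
  d <- deg[deg >= 1]
  n <- length(d)
  if (n < 30 || length(unique(d)) < 2) return("inconclusive")
  # zero-truncated Poisson MLE: mean(d) = lambda / (1 - exp(-lambda))
  mbar <- mean(d)
  f <- function(l) l / (1 - exp(-l)) - mbar
  lam <- stats::uniroot(f, c(1e-8, max(mbar * 2, 1)))$root
  ll_pois <- stats::dpois(d, lam, log = TRUE) - log(1 - exp(-lam))
  # zeta distribution MLE over alpha
  sl <- sum(log(d))
  nll <- function(a) a * sl + n * log(pracma::zeta(a))
  a_hat <- stats::optimize(nll, c(1.01, 20))$minimum
  ll_pl <- -a_hat * log(d) - log(pracma::zeta(a_hat))
  li <- ll_pois - ll_pl
  s <- stats::sd(li)
  if (s == 0) return("inconclusive")
  # Vuong-normalised LR; heavy tails inflate its sd, so an indecisive LR
  # falls back to the Clarke sign test on the per-observation contributions
  z <- sum(li) / (s * sqrt(n))
  if (z >= 2) return("erdos-renyi-like")
  if (z <= -2) return("power-law-like")
  zs <- (mean(li > 0) - 0.5) * 2 * sqrt(n)
  if (zs >= 2) "erdos-renyi-like"
  else if (zs <= -2) "power-law-like"
  else "inconclusive"
}

#' Randomise a network by edge shuffling
#'
#' One shuffle move picks a random edge (n_i, n_j), removes it and inserts an
#' edge between two nodes chosen at random among the remaining nodes
#' (excluding n_i and n_j), redrawing on self-loops or duplicate edges. The
#' number of moves equals the number of edges, so the node set and the edge
#' count are preserved exactly.
#'
#' @param net a `coocnet`/`igraph`.
#' @param seed integer RNG seed.
#' @return the randomised `coocnet`.
#' @export
randomize_network <- function(net, seed) {
  g <- as_igraph_net(net)
  m <- igraph::ecount(g)
  if (m == 0) return(net)
  nodes <- igraph::V(g)$name
  n <- length(nodes)
  if (n < 4) stop("need at least 4 nodes to shuffle an edge")
  ed <- igraph::as_edgelist(g, names = TRUE)
  sign_attr <- igraph::edge_attr(g, "sign")
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  have <- new.env(hash = TRUE, parent = emptyenv())
  for (k in key(ed[, 1], ed[, 2])) assign(k, TRUE, envir = have)
  old_seed <- .save_seed(); on.exit(.restore_seed(old_seed))
  set.seed(as.integer(seed))
  for (mv in seq_len(m)) {
    e <- sample.int(m, 1)
    ni <- ed[e, 1]; nj <- ed[e, 2]
    pool <- nodes[!(nodes %in% c(ni, nj))]
    repeat {
      ab <- sample(pool, 2)
      k <- key(ab[1], ab[2])
      if (!exists(k, envir = have, inherits = FALSE)) break
    }
    rm(list = key(ni, nj), envir = have)
    assign(k, TRUE, envir = have)
    ed[e, 1] <- ab[1]; ed[e, 2] <- ab[2]
  }
  nd <- igraph::as_data_frame(g, what = "vertices")
  edf <- data.frame(node1 = ed[, 1], node2 = ed[, 2],
                    stringsAsFactors = FALSE)
  if (!is.null(sign_attr)) edf$sign <- sign_attr
  if (!"kind" %in% names(nd)) nd$kind <- "OTU"
  coocnet(nd, edf)
}

.save_seed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
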