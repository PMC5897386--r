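# Ensemble co-occurrence inference: four-measure pair scoring, candidate-edge
# selection by measure-consistent thresholding, renormalised permutation +
# bootstrap edge testing, Brown/Benjamini-Hochberg merging and network
# assembly.

.measures <- c("pearson", "spearman", "bray-curtis", "kullback-leibler")

#' Pairwise association score between two profiles
#'
#' Pearson and Spearman act on the profiles as given (invariant under affine
#' rescaling); Bray-Curtis is `sum|x - y| / sum(x + y)`; Kullback-Leibler is
#' the symmetrised divergence `0.5 (KL(p||q) + KL(q||p))` on pseudocounted
#' profiles normalised to distributions over samples (raw KL is undefined at
#' zeros and asymmetric).
#'
#' @param x,y numeric non-negative profiles of equal length >= 4.
#' @param measure one of `"pearson"`, `"spearman"`, `"bray-curtis"`,
#'   `"kullback-leibler"`.
#' @param pseudocount added to each entry before normalising for KL
#'   (default 1 count).
#' @return the score; `NA` when undefined (constant profile for a
#'   correlation, empty profiles for Bray-Curtis).
#' @export
pair_score <- function(x, y, measure = .measures, pseudocount = 1) {
  measure <- match.arg(measure)
  if (length(x) != length(y)) stop("profiles must have equal length")
  if (length(x) < 4) stop("need at least 4 paired observations")
  switch(measure,
    pearson = {
      if (stats::sd(x) == 0 || stats::sd(y) == 0) NA_real_
      else stats::cor(x, y)
    },
    spearman = {
      if (stats::sd(x) == 0 || stats::sd(y) == 0) NA_real_
      else stats::cor(x, y, method = "spearman")
    },
    `bray-curtis` = {
      s <- sum(x + y)
      if (s == 0) NA_real_ else sum(abs(x - y)) / s
    },
    `kullback-leibler` = {
      p <- (x + pseudocount) / sum(x + pseudocount)
      q <- (y + pseudocount) / sum(y + pseudocount)
      0.5 * (sum(p * log(p / q)) + sum(q * log(q / p)))
    })
}

# column-wise measure kernel; X, Y matrices with profiles in columns
.measure_cols <- function(X, Y, measure) {
  switch(measure,
    pearson = ,
    spearman = {
      if (measure == "spearman") {
        X <- apply(X, 2, rank); Y <- apply(Y, 2, rank)
        if (is.null(dim(X))) X <- matrix(X, nrow = 1)
        if (is.null(dim(Y))) Y <- matrix(Y, nrow = 1)
      }
      Xc <- sweep(X, 2, colMeans(X))
      Yc <- sweep(Y, 2, colMeans(Y))
      den <- sqrt(colSums(Xc^2) * colSums(Yc^2))
      out <- colSums(Xc * Yc) / den
      out[den == 0] <- NA_real_
      out
    },
    `bray-curtis` = {
      # profiles compared as sample distributions (scale-free): each column
      # is normalised to sum 1 before the Bray-Curtis formula
      sx <- colSums(X); sy <- colSums(Y)
      bad <- sx == 0 | sy == 0
      sx[sx == 0] <- 1; sy[sy == 0] <- 1
      Xn <- sweep(X, 2, sx, "/"); Yn <- sweep(Y, 2, sy, "/")
      out <- colSums(abs(Xn - Yn)) / colSums(Xn + Yn)
      out[bad] <- NA_real_
      out
    },
    `kullback-leibler` = {
      P <- sweep(X, 2, colSums(X), "/")
      Q <- sweep(Y, 2, colSums(Y), "/")
      0.5 * (colSums(P * log(P / Q)) + colSums(Q * log(Q / P)))
    })
}

# min-max scale variable rows to [0, 1]; constant rows map to 0.5
.minmax_rows <- function(m) {
  t(apply(m, 1, function(r) {
    rng <- range(r)
    if (rng[2] > rng[1]) (r - rng[1]) / (rng[2] - rng[1]) else rep(0.5, length(r))
  }))
}

# pseudocounted distribution profiles (rows sum to 1) used by the KL measure
.kl_profiles <- function(counts, varmat = NULL, pseudocount = 1,
                         var_pseudo = 1e-3) {
  P <- counts + pseudocount
  P <- sweep(P, 1, rowSums(P), "/")
  if (!is.null(varmat) && nrow(varmat)) {
    V <- varmat + var_pseudo
    V <- sweep(V, 1, rowSums(V), "/")
    P <- rbind(P, V)
  }
  P
}

#' Association score matrices for all node pairs
#'
#' Computes the four measures over all pairs of profile rows: OTU rows are
#' table-relative abundances (KL uses pseudocounted count profiles), variable
#' rows are min-max scaled to \[0, 1\].
#'
#' @param counts OTU count matrix (OTUs x samples).
#' @param varmat optional abiotic variable matrix (variables x samples).
#' @return named list of symmetric score matrices (`NA` where undefined).
#' @export
score_matrices <- function(counts, varmat = NULL) {
  rel <- relative_abundance(counts)
  prof <- if (!is.null(varmat) && nrow(varmat))
    rbind(rel, .minmax_rows(varmat)) else rel
  tp <- t(prof)
  pe <- suppressWarnings(stats::cor(tp))
  sp <- suppressWarnings(stats::cor(tp, method = "spearman"))
  constant <- apply(prof, 1, stats::sd) == 0
  pe[constant, ] <- NA; pe[, constant] <- NA
  sp[constant, ] <- NA; sp[, constant] <- NA
  rs <- rowSums(prof)
  rs[rs == 0] <- 1
  bc <- as.matrix(vegan::vegdist(prof / rs, method = "bray"))
  P <- .kl_profiles(counts, if (!is.null(varmat) && nrow(varmat))
    .minmax_rows(varmat))
  A <- P %*% t(log(P))
  kl <- 0.5 * (diag(A) - A + t(diag(A) - A))
  dimnames(kl) <- dimnames(bc) <- dimnames(pe)
  list(pearson = pe, spearman = sp, `bray-curtis` = bc,
       `kullback-leibler` = kl)
}

#' Select candidate edges consistent across all four measures
#'
#' Every unordered node pair is ranked by each measure from most co-present
#' to most exclusive (correlations descending; dissimilarities ascending).
#' Each measure nominates its strongest `n_pos` co-presence and `n_neg`
#' exclusion pairs (capped at half the rankable pairs so a pair is never
#' nominated for both signs); candidates are the pairs nominated with the
#' same sign by all four measures whose Pearson and Spearman correlation
#' signs agree with that sign. Pairs with an undefined measure are never
#' candidates.
#'
#' @param otu an [otu_table()] (a section slice), already filtered.
#' @param abiotic optional [abiotic_table()] for the same samples.
#' @param variables abiotic variables to include as nodes.
#' @param n_pos,n_neg per-measure nomination counts (default 1000 each).
#' @param minocc drop OTUs occurring in fewer than `minocc` samples
#'   (default 10).
#' @return `data.frame` of candidates: `node1`, `node2`, `sign`, the four
#'   observed scores and the node kinds.
#' @export
select_candidates <- function(otu, abiotic = NULL,
                              variables = c("pH", "RelativeHumidity",
                                            "Temperature", "N_total",
                                            "C_total", "P", "S", "Cu",
                                            "Fe", "Zn"),
                              n_pos = 1000, n_neg = 1000, minocc = 10) {
  counts <- otu$counts
  keep <- rowSums(counts > 0) >= minocc
  counts <- counts[keep, , drop = FALSE]
  varmat <- NULL
  if (!is.null(abiotic)) {
    vars <- intersect(variables, rownames(abiotic$values))
    varmat <- abiotic$values[vars, colnames(counts), drop = FALSE]
  }
  sm <- score_matrices(counts, varmat)
  nodes <- rownames(sm$pearson)
  kind <- c(rep("OTU", nrow(counts)),
            rep("VARIABLE", if (is.null(varmat)) 0 else nrow(varmat)))
  names(kind) <- nodes
  np <- length(nodes)
  if (np < 2) return(.empty_candidates())
  iu <- which(upper.tri(sm$pearson), arr.ind = TRUE)
  a <- nodes[iu[, 1]]; b <- nodes[iu[, 2]]
  cand <- data.frame(node1 = pmin(a, b), node2 = pmax(a, b),
                     stringsAsFactors = FALSE)
  for (m in .measures) cand[[m]] <- sm[[m]][iu]
  ok <- stats::complete.cases(cand[.measures])
  cand <- cand[ok, , drop = FALSE]
  P <- nrow(cand)
  if (P == 0) return(.empty_candidates())
  if (n_pos > P || n_neg > P)
    warning("fewer rankable pairs (", P, ") than requested; using all")
  cap_pos <- min(n_pos, ceiling(P / 2))
  cap_neg <- min(n_neg, floor(P / 2))
  in_pos <- in_neg <- rep(TRUE, P)
  for (m in .measures) {
    s <- cand[[m]]
    decreasing <- m %in% c("pearson", "spearman")
    o <- order(if (decreasing) -s else s, cand$node1, cand$node2)
    r <- integer(P); r[o] <- seq_len(P)   # 1 = most co-present
    in_pos <- in_pos & (r <= cap_pos)
    in_neg <- in_neg & (r > P - cap_neg)
  }
  in_pos <- in_pos & cand$pearson > 0 & cand$spearman > 0
  in_neg <- in_neg & cand$pearson < 0 & cand$spearman < 0
  pos <- cand[in_pos, , drop = FALSE]
  pos$sign <- rep("copresence", nrow(pos))
  neg <- cand[in_neg, , drop = FALSE]
  neg$sign <- rep("exclusion", nrow(neg))
  out <- rbind(pos, neg)
  if (nrow(out)) {
    out$kind1 <- unname(kind[out$node1])
    out$kind2 <- unname(kind[out$node2])
    out <- out[order(out$node1, out$node2), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

.empty_candidates <- function() {
  df <- data.frame(node1 = character(), node2 = character(),
                   pearson = numeric(), spearman = numeric(),
                   check.names = FALSE, stringsAsFactors = FALSE)
  df$`bray-curtis` <- numeric(); df$`kullback-leibler` <- numeric()
  df$sign <- character(); df$kind1 <- character(); df$kind2 <- character()
  df
}

#' Renormalised permutation and bootstrap test of one candidate edge
#'
#' The permutation null shuffles one member's counts across samples and
#' renormalises every sample of the full table so compositional totals are
#' restored (the variable member of an OTU-variable pair is never shuffled or
#' renormalised: it is not a count). The measure is recomputed for each of
#' `n` draws; the p-value is the two-sided Gaussian tail probability of the
#' observed score under the null mean and sd, so `n = 1000` still resolves
#' p < 0.001. The bootstrap resamples samples with replacement `n_boot` times
#' and reports a percentile 95% interval; the edge is flagged `killed` when
#' the null mean lies inside that interval (unstable evidence).
#'
#' @param x,y raw count profiles (or variable measurement profiles).
#' @param totals per-sample totals of the full count table (for
#'   renormalisation); defaults to `x + y` only if omitted — pass the real
#'   table totals in pipeline use.
#' @param measure one of the four measure names.
#' @param n permutation draws (default 1000).
#' @param n_boot bootstrap draws (default `n`).
#' @param seed integer RNG seed.
#' @param x_is_otu,y_is_otu whether each member is an OTU count row.
#' @return list: `measure`, `observed`, `null_mean`, `null_sd`, `p`, `ci`
#'   (bootstrap 2.5%/97.5%), `killed`, `n`, `n_boot`.
#' @export
reboot_edge_test <- function(x, y, totals = NULL, measure = .measures,
                             n = 1000, n_boot = n, seed = 1,
                             x_is_otu = TRUE, y_is_otu = TRUE) {
  measure <- match.arg(measure)
  ns <- length(x)
  if (length(y) != ns) stop("profiles must have equal length")
  if (is.null(totals)) totals <- x + y
  old_seed <- .save_seed(); on.exit(.restore_seed(old_seed))
  set.seed(as.integer(seed))

  obs <- .reboot_observed(x, y, totals, measure, x_is_otu, y_is_otu)
  if (is.na(obs)) stop("observed score undefined for this pair")

  # which member is shuffled: the first OTU member, else x
  shuffle_x <- x_is_otu || !y_is_otu
  null_scores <- .reboot_null(x, y, totals, measure, n, shuffle_x,
                              x_is_otu, y_is_otu)
  mu <- mean(null_scores); sdv <- stats::sd(null_scores)
  p <- if (sdv > 0) 2 * stats::pnorm(-abs(obs - mu) / sdv)
       else as.numeric(abs(obs - mu) < 1e-12)
  boot_scores <- .reboot_boot(x, y, totals, measure, n_boot,
                              x_is_otu, y_is_otu)
  ci <- stats::quantile(boot_scores, c(0.025, 0.975), na.rm = TRUE,
                        names = FALSE)
  killed <- mu >= ci[1] && mu <= ci[2]
  list(measure = measure, observed = obs, null_mean = mu, null_sd = sdv,
       p = unname(p), ci = ci, killed = killed, n = n, n_boot = n_boot)
}

.reboot_observed <- function(x, y, totals, measure, x_is_otu, y_is_otu) {
  if (measure == "kullback-leibler") {
    px <- if (x_is_otu) x + 1 else x + 1e-3
    py <- if (y_is_otu) y + 1 else y + 1e-3
    return(pair_score(px / sum(px), py / sum(py), "kullback-leibler",
                      pseudocount = 0))
  }
  rx <- if (x_is_otu) x / totals else x
  ry <- if (y_is_otu) y / totals else y
  if (measure == "bray-curtis") {
    if (sum(rx) == 0 || sum(ry) == 0) return(NA_real_)
    rx <- rx / sum(rx); ry <- ry / sum(ry)
  }
  pair_score(rx, ry, measure, pseudocount = 1)
}

# matrix of n shuffled-and-renormalised score draws
.reboot_null <- function(x, y, totals, measure, n, shuffle_x,
                         x_is_otu, y_is_otu) {
  ns <- length(x)
  draw <- function(k) vapply(seq_len(k), function(i) sample.int(ns),
                             integer(ns))
  idx <- draw(n)
  compute <- function(idx) {
    if (shuffle_x) {
      Xs <- matrix(x[idx], ns)
      if (x_is_otu) {
        totp <- (totals - x) + Xs
        X <- Xs / totp
        Y <- if (y_is_otu) matrix(y, ns, ncol(idx)) / totp
             else matrix(y, ns, ncol(idx))
      } else {
        X <- Xs
        Y <- matrix(if (y_is_otu) y / totals else y, ns, ncol(idx))
      }
      if (measure == "kullback-leibler") {
        X <- if (x_is_otu) Xs + 1 else Xs + 1e-3
        Y <- matrix(if (y_is_otu) y + 1 else y + 1e-3, ns, ncol(idx))
      }
    } else {
      Ys <- matrix(y[idx], ns)
      if (y_is_otu) {
        totp <- (totals - y) + Ys
        Y <- Ys / totp
        X <- if (x_is_otu) matrix(x, ns, ncol(idx)) / totp
             else matrix(x, ns, ncol(idx))
      } else {
        Y <- Ys
        X <- matrix(if (x_is_otu) x / totals else x, ns, ncol(idx))
      }
      if (measure == "kullback-leibler") {
        Y <- if (y_is_otu) Ys + 1 else Ys + 1e-3
        X <- matrix(if (x_is_otu) x + 1 else x + 1e-3, ns, ncol(idx))
      }
    }
    .measure_cols(X, Y, measure)
  }
  out <- compute(idx)
  attempts <- 0
  while (anyNA(out) && attempts < 10) {
    bad <- which(is.na(out))
    out[bad] <- compute(draw(length(bad)))
    attempts <- attempts + 1
  }
  out[is.na(out)] <- mean(out, na.rm = TRUE)
  out
}

.reboot_boot <- function(x, y, totals, measure, n_boot, x_is_otu, y_is_otu) {
  ns <- length(x)
  idx <- vapply(seq_len(n_boot), function(i)
    sample.int(ns, replace = TRUE), integer(ns))
  if (measure == "kullback-leibler") {
    X <- matrix((if (x_is_otu) x + 1 else x + 1e-3)[idx], ns)
    Y <- matrix((if (y_is_otu) y + 1 else y + 1e-3)[idx], ns)
  } else {
    rx <- if (x_is_otu) x / totals else x
    ry <- if (y_is_otu) y / totals else y
    X <- matrix(rx[idx], ns)
    Y <- matrix(ry[idx], ns)
  }
  .measure_cols(X, Y, measure)
}

#' Merge per-measure p-values and correct across edges
#'
#' Per edge, the measure p-values are merged by Brown's method: Fisher's
#' statistic with an empirical covariance correction, the covariance of
#' `-2 log p` between measures estimated across all edges (plain Fisher when
#' the estimate is unavailable). Merged p-values are then Benjamini-Hochberg
#' adjusted across edges.
#'
#' @param pmat numeric matrix, edges x measures; `NA` entries (killed or
#'   undefined measures) are dropped from that edge's merge.
#' @return `data.frame` with `p_merged` and `q`.
#' @export
merge_and_correct <- function(pmat) {
  pmat <- as.matrix(pmat)
  if (!nrow(pmat)) return(data.frame(p_merged = numeric(), q = numeric()))
  pm <- pmin(pmax(pmat, 1e-300), 1)
  X <- -2 * log(pm)
  k_all <- ncol(pm)
  # null covariance of -2 log p between measures, estimated as 4 * rank
  # correlation across edges (bounded by the null variance 4; a raw
  # across-edge covariance would be inflated by effect-size heterogeneity)
  covm <- matrix(0, k_all, k_all)
  cc <- stats::complete.cases(X)
  if (sum(cc) >= 10 && k_all > 1) {
    cm <- suppressWarnings(stats::cor(X[cc, , drop = FALSE],
                                      method = "spearman"))
    cm[!is.finite(cm)] <- 0
    covm <- 4 * pmin(pmax(cm, 0), 1)
    diag(covm) <- 0
  }
  p_merged <- vapply(seq_len(nrow(pm)), function(i) {
    use <- which(!is.na(pmat[i, ]))
    k <- length(use)
    if (k == 0) return(NA_real_)
    xs <- sum(X[i, use])
    mu <- 2 * k
    vr <- 4 * k + 2 * sum(covm[use, use][upper.tri(matrix(0, k, k))])
    if (vr <= 0) vr <- 4 * k
    f <- 2 * mu^2 / vr
    cc_ <- vr / (2 * mu)
    stats::pchisq(xs / cc_, df = f, lower.tail = FALSE)
  }, numeric(1))
  q <- rep(NA_real_, length(p_merged))
  ok <- !is.na(p_merged)
  q[ok] <- stats::p.adjust(p_merged[ok], method = "BH")
  data.frame(p_merged = p_merged, q = q)
}

#' Infer the signed co-occurrence network of one section
#'
#' Runs the full ensemble procedure: occurrence filtering, four-measure
#' candidate selection (1,000 positive and 1,000 negative edges consistent
#' across all measures by default), renormalised permutation + bootstrap
#' testing of every candidate under every measure, Brown/BH merging, and
#' assembly of the surviving signed edges into a network whose nodes are the
#' incident OTUs and abiotic variables.
#'
#' @param otu an [otu_table()] slice for the section (filters from
#'   [filter_replicate_consistency()] / [filter_min_samples()] applied by the
#'   caller).
#' @param abiotic optional [abiotic_table()] covering the same samples.
#' @param variables abiotic variables eligible as nodes.
#' @param n_pos,n_neg,minocc candidate-selection parameters.
#' @param n_perm permutation draws per edge and measure (default 1000).
#' @param n_boot bootstrap draws (default `n_perm`).
#' @param q_cut BH-adjusted significance level (default 0.05).
#' @param min_support minimum number of measures that must survive the
#'   bootstrap kill rule for an edge to be eligible (default 2, so an edge
#'   retained on a single unstable measure is discarded).
#' @param seed integer RNG seed.
#' @param details return intermediate tables as well.
#' @return a [coocnet()]; with `details = TRUE`, a list with `net`,
#'   `candidates` and `tests`.
#' @export
build_network <- function(otu, abiotic = NULL,
                          variables = c("pH", "RelativeHumidity",
                                        "Temperature", "N_total", "C_total",
                                        "P", "S", "Cu", "Fe", "Zn"),
                          n_pos = 1000, n_neg = 1000, minocc = 10,
                          n_perm = 1000, n_boot = n_perm, q_cut = 0.05,
                          min_support = 2, seed = 1, details = FALSE) {
  cand <- select_candidates(otu, abiotic, variables, n_pos, n_neg, minocc)
  counts <- otu$counts[rowSums(otu$counts > 0) >= minocc, , drop = FALSE]
  totals <- colSums(counts)
  varmat <- NULL
  if (!is.null(abiotic)) {
    vars <- intersect(variables, rownames(abiotic$values))
    varmat <- .minmax_rows(abiotic$values[vars, colnames(counts),
                                          drop = FALSE])
  }
  profile_of <- function(id, kind) {
    if (kind == "OTU") counts[id, ] else varmat[id, ]
  }
  nc <- nrow(cand)
  pmat <- matrix(NA_real_, nc, length(.measures),
                 dimnames = list(NULL, .measures))
  killed <- matrix(FALSE, nc, length(.measures),
                   dimnames = list(NULL, .measures))
  if (nc) for (i in seq_len(nc)) {
    x <- profile_of(cand$node1[i], cand$kind1[i])
    y <- profile_of(cand$node2[i], cand$kind2[i])
    es <- derive_seed(seed, paste0("edge:", cand$node1[i], "|",
                                   cand$node2[i]))
    for (m in .measures) {
      tr <- reboot_edge_test(x, y, totals, m, n = n_perm, n_boot = n_boot,
                             seed = derive_seed(es, m),
                             x_is_otu = cand$kind1[i] == "OTU",
                             y_is_otu = cand$kind2[i] == "OTU")
      pmat[i, m] <- tr$p
      killed[i, m] <- tr$killed
    }
  }
  puse <- pmat
  puse[killed] <- NA
  mg <- merge_and_correct(puse)
  keep <- !is.na(mg$q) & mg$q < q_cut &
    rowSums(!killed) >= min_support
  edges <- cbind(cand[keep, c("node1", "node2", "sign", .measures),
                      drop = FALSE],
                 q = mg$q[keep])
  if (nrow(edges) == 0) warning("no edges retained; empty network")
  node_names <- unique(c(edges$node1, edges$node2))
  kind_all <- c(stats::setNames(cand$kind1, cand$node1),
                stats::setNames(cand$kind2, cand$node2))
  nodes <- data.frame(name = node_names,
                      kind = unname(kind_all[node_names]),
                      stringsAsFactors = FALSE)
  nodes$taxonomy <- NA_character_
  if (!is.null(otu$taxonomy)) {
    hit <- nodes$name %in% names(otu$taxonomy)
    nodes$taxonomy[hit] <- unname(otu$taxonomy[nodes$name[hit]])
  }
  net <- coocnet(nodes, edges)
  if (details) list(net = net, candidates = cand,
                    tests = list(p = pmat, killed = killed, merged = mg))
  else net
}
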