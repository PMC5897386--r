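# Pre-inference filtering and diversity statistics: replicate-consistency and
# occurrence filters, relative abundances, Shannon index, Faith's PD,
# rarefaction curves and abundance-environment correlations.

#' Keep OTUs consistently observed across replicates
#'
#' An OTU is kept iff at some site it is present (count > 0) in at least
#' `min_reps` of that site's replicates. All samples are retained.
#'
#' @param t an [otu_table()] with sample metadata.
#' @param min_reps minimum replicates with presence at a single site
#'   (default 2, i.e. "2 of 3").
#' @return filtered `otu_table`.
#' @export
filter_replicate_consistency <- function(t, min_reps = 2) {
  if (is.null(t$sample_meta)) stop("sample metadata required")
  sites <- unique(t$sample_meta$site)
  reps_per_site <- table(t$sample_meta$site)
  if (any(reps_per_site < min_reps))
    stop("site(s) with fewer than min_reps replicates: ",
         paste(names(reps_per_site)[reps_per_site < min_reps], collapse = ", "))
  pres <- t$counts > 0
  keep <- rep(FALSE, nrow(pres))
  for (s in sites) {
    cols <- t$sample_meta$sample[t$sample_meta$site == s]
    keep <- keep | rowSums(pres[, cols, drop = FALSE]) >= min_reps
  }
  subset_otu_table(t, otus = rownames(t$counts)[keep])
}

#' Keep OTUs occurring in at least `min_samples` samples
#'
#' Occurrence means count > 0 in the table passed in (apply per section before
#' network inference).
#'
#' @param t an [otu_table()].
#' @param min_samples occurrence threshold (default 5).
#' @return filtered `otu_table`.
#' @export
filter_min_samples <- function(t, min_samples = 5) {
  occ <- rowSums(t$counts > 0)
  subset_otu_table(t, otus = rownames(t$counts)[occ >= min_samples])
}

#' Per-sample relative abundances
#' @param t an [otu_table()] or a count matrix.
#' @return matrix of proportions; every column sums to 1.
#' @export
relative_abundance <- function(t) {
  m <- if (inherits(t, "otu_table")) t$counts else as.matrix(t)
  tot <- colSums(m)
  zero <- colnames(m)[tot == 0]
  if (length(zero))
    stop("zero-total sample(s): ", paste(zero, collapse = ", "))
  sweep(m, 2, tot, "/")
}

#' Shannon diversity of a count vector
#'
#' H = -sum p_i log_base(p_i) over nonzero proportions. Base 2 (bits) by
#' default, matching the QIIME convention.
#'
#' @param counts non-negative numeric vector.
#' @param base logarithm base.
#' @return Shannon index.
#' @export
shannon <- function(counts, base = 2) {
  counts <- counts[counts > 0]
  if (!length(counts)) stop("total count must be > 0")
  p <- counts / sum(counts)
  -sum(p * log(p, base = base))
}

#' Faith's phylogenetic diversity
#'
#' Sum of branch lengths of the minimal subtree spanning the present tips and
#' the tree root.
#'
#' @param tree an `ape::phylo` tree or a newick file path.
#' @param present_otus character vector of present tip labels.
#' @return PD in branch-length units (0 for an empty set).
#' @export
faith_pd <- function(tree, present_otus) {
  if (is.character(tree) && length(tree) == 1 && file.exists(tree))
    tree <- ape::read.tree(tree)
  if (!inherits(tree, "phylo")) stop("tree must be a phylo object or file")
  present_otus <- unique(as.character(present_otus))
  if (!length(present_otus)) return(0)
  miss <- setdiff(present_otus, tree$tip.label)
  if (length(miss)) stop("tip(s) not in tree: ", paste(miss, collapse = ", "))
  comm <- matrix(0, 1, length(tree$tip.label),
                 dimnames = list("community", tree$tip.label))
  comm[1, present_otus] <- 1
  as.numeric(picante::pd(comm, tree, include.root = TRUE)$PD)
}

#' Rarefaction curves
#'
#' For every retained sample and every depth on the schedule, the metric is
#' averaged over `iters` independent subsamples drawn without replacement.
#' Samples with fewer sequences than `max_depth` are excluded, mirroring the
#' standard practice of dropping the shallowest samples rather than
#' extrapolating.
#'
#' @param t an [otu_table()].
#' @param max_depth standardised depth (default 3900 sequences).
#' @param step depth increment (default 389).
#' @param iters subsamples per depth (default 10).
#' @param metric `"richness"` or `"shannon"`.
#' @param seed integer RNG seed.
#' @return list with `depths`, `mean` and `sd` (samples x depths matrices),
#'   and `excluded` (sample ids below `max_depth`).
#' @export
rarefaction <- function(t, max_depth = 3900, step = 389, iters = 10,
                        metric = c("richness", "shannon"), seed = 1) {
  metric <- match.arg(metric)
  tot <- colSums(t$counts)
  keep <- names(tot)[tot >= max_depth]
  excluded <- setdiff(colnames(t$counts), keep)
  depths <- unique(c(seq(step, max_depth, by = step), max_depth))
  fmetric <- switch(metric,
                    richness = function(v) sum(v > 0),
                    shannon = function(v) shannon(v))
  mu <- sdm <- matrix(NA_real_, length(keep), length(depths),
                      dimnames = list(keep, depths))
  old_seed <- .save_seed(); on.exit(.restore_seed(old_seed))
  set.seed(as.integer(seed))
  for (s in keep) {
    v <- round(t$counts[, s])
    storage.mode(v) <- "integer"
    for (j in seq_along(depths)) {
      vals <- vapply(seq_len(iters), function(i) {
        # rrarefy warns about count scaling on perfectly valid integer data
        sub <- suppressWarnings(vegan::rrarefy(v, depths[j]))
        fmetric(as.numeric(sub))
      }, numeric(1))
      mu[s, j] <- mean(vals)
      sdm[s, j] <- stats::sd(vals)
    }
  }
  list(depths = depths, mean = mu, sd = sdm, metric = metric,
       excluded = excluded)
}

#' Rank correlation between an abundance profile and a variable
#'
#' Spearman (default) rank correlation with a two-sided p-value, used for
#' phylum-level trend tables and node environment-correlation flags. Constant
#' input yields an undefined correlation, flagged rather than forced to zero.
#'
#' @param x abundance profile (numeric).
#' @param v variable profile (numeric, same length).
#' @param method correlation method (default `"spearman"`).
#' @return list with `rho`, `p` and `defined`.
#' @export
env_correlation <- function(x, v, method = "spearman") {
  if (length(x) != length(v)) stop("profiles must have equal length")
  if (length(x) < 4) stop("need at least 4 paired observations")
  if (stats::sd(x) == 0 || stats::sd(v) == 0)
    return(list(rho = NA_real_, p = NA_real_, defined = FALSE))
  ct <- suppressWarnings(stats::cor.test(x, v, method = method,
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, defined = TRUE)
}
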