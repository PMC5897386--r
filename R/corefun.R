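# Core/noncore decomposition of two section networks, node characterisation
# (hubs, abundance, environment correlation), aligned-to-self counting, and
# rule-based functional profiling with group comparisons.

#' Core / noncore decomposition of two networks
#'
#' Core OTUs appear in both networks' OTU node sets; noncore OTUs are
#' exclusive to one. VARIABLE nodes are excluded.
#'
#' @param net1,net2 `coocnet`/`igraph` networks with comparable OTU ids.
#' @return list of class `core_decomposition`: `core`, `noncore1`,
#'   `noncore2` (character vectors).
#' @export
core_decompose <- function(net1, net2) {
  o1 <- otu_nodes(net1); o2 <- otu_nodes(net2)
  structure(list(core = sort(intersect(o1, o2)),
                 noncore1 = sort(setdiff(o1, o2)),
                 noncore2 = sort(setdiff(o2, o1))),
            class = "core_decomposition")
}

#' @export
print.core_decomposition <- function(x, ...) {
  cat(sprintf("core_decomposition: %d core, %d noncore (net1), %d noncore (net2)\n",
              length(x$core), length(x$noncore1), length(x$noncore2)))
  invisible(x)
}

#' Core OTUs aligned to themselves
#'
#' Counts mapping pairs (u -> v) with u = v and u in the core set: core OTUs
#' that retain their association pattern across the two environments.
#'
#' @param aln an `alignment_result` over the same two networks.
#' @param core character vector of core OTU ids.
#' @return list with `count`, `fraction` (`NA` flagged for an empty core)
#'   and `otus` (the aligned-to-self core ids).
#' @export
aligned_to_self <- function(aln, core) {
  self <- aln$mapping$node1[aln$mapping$node1 == aln$mapping$node2]
  hits <- intersect(self, core)
  list(count = length(hits),
       fraction = if (length(core)) length(hits) / length(core) else NA_real_,
       otus = sort(hits))
}

#' Flag hub, abundant and environment-correlated nodes
#'
#' Hubs are OTU nodes strictly above the 90th percentile of degree
#' centrality within the network (top decile); abundant nodes exceed `abundance_cut`
#' mean relative abundance; a node is environment-correlated with a variable
#' when its abundance-variable Spearman correlation is significant
#' (p < 0.05) and its |rho| is at or above the 90th percentile of the
#' significant |rho| values for that variable.
#'
#' @param net a `coocnet`.
#' @param table an [otu_table()] covering the network's OTUs (the section
#'   slice).
#' @param abiotic optional [abiotic_table()] for the same samples (enables
#'   environment-correlation flags).
#' @param variables variables to test.
#' @param decile top fraction for the hub and correlation flags
#'   (default 0.10).
#' @param abundance_cut mean relative-abundance threshold (default 0.001,
#'   i.e. 0.1%).
#' @return `data.frame`: node, degree_centrality, is_hub, mean_rel_abundance,
#'   is_abundant, env_correlated (comma-separated variable names).
#' @export
flag_nodes <- function(net, table, abiotic = NULL,
                       variables = c("pH", "Fe", "Cu", "Zn", "N_total"),
                       decile = 0.10, abundance_cut = 0.001) {
  g <- as_igraph_net(net)
  otus <- otu_nodes(g)
  deg <- igraph::degree(g)[otus] / max(1, igraph::vcount(g) - 1)
  cut_deg <- stats::quantile(deg, 1 - decile, names = FALSE, type = 7)
  is_hub <- deg > cut_deg
  rel <- relative_abundance(table)
  mra <- rep(NA_real_, length(otus)); names(mra) <- otus
  hit <- otus[otus %in% rownames(rel)]
  mra[hit] <- rowMeans(rel[hit, , drop = FALSE])
  env <- rep("", length(otus)); names(env) <- otus
  if (!is.null(abiotic)) {
    vars <- intersect(variables, rownames(abiotic$values))
    for (v in vars) {
      prof <- abiotic$values[v, colnames(rel)]
      res <- lapply(hit, function(o)
        env_correlation(rel[o, ], prof))
      rho <- vapply(res, function(r)
        if (isTRUE(r$defined)) abs(r$rho) else NA_real_, numeric(1))
      p <- vapply(res, function(r)
        if (isTRUE(r$defined)) r$p else NA_real_, numeric(1))
      sig <- !is.na(p) & p < 0.05
      if (any(sig)) {
        thr <- stats::quantile(rho[sig], 1 - decile, names = FALSE)
        sel <- sig & rho >= thr
        env[hit[sel]] <- ifelse(nzchar(env[hit[sel]]),
                                paste(env[hit[sel]], v, sep = ","), v)
      }
    }
  }
  data.frame(node = otus,
             degree_centrality = unname(deg),
             is_hub = unname(is_hub),
             mean_rel_abundance = unname(mra),
             is_abundant = unname(!is.na(mra) & mra > abundance_cut),
             env_correlated = unname(env),
             stringsAsFactors = FALSE)
}

#' Map OTUs to function categories with a rule set
#'
#' An OTU receives a category when any rule's pattern equals its lineage
#' value at the rule's rank; multiple categories are allowed.
#'
#' @param rules a [rule_set()].
#' @param taxonomy named character vector of rank-prefixed lineage strings.
#' @return named list: OTU id -> character vector of categories (possibly
#'   empty).
#' @export
apply_rules <- function(rules, taxonomy) {
  ranks <- c(kingdom = "k__", phylum = "p__", class = "c__", order = "o__",
             family = "f__", genus = "g__")
  bad <- which(!rules$rank %in% names(ranks))
  if (length(bad))
    stop("malformed rule at line ", bad[1], ": unknown rank '",
         rules$rank[bad[1]], "'")
  parse_rank <- function(lin, prefix) {
    parts <- trimws(strsplit(lin, ";", fixed = TRUE)[[1]])
    hit <- parts[startsWith(parts, prefix)]
    if (length(hit)) hit[1] else NA_character_
  }
  out <- lapply(taxonomy, function(lin) {
    if (is.na(lin)) return(character())
    cats <- character()
    for (i in seq_len(nrow(rules))) {
      val <- parse_rank(lin, ranks[[rules$rank[i]]])
      if (!is.na(val) && val == rules$pattern[i])
        cats <- c(cats, rules$category[i])
    }
    unique(cats)
  })
  names(out) <- names(taxonomy)
  out
}

#' Per-site functional profile of an OTU set
#'
#' For every site, a category's share is the summed abundance of the set's
#' OTUs labelled with that category relative to the set's own total
#' abundance in the sample (replicate shares averaged within site). Using
#' the set's abundance as denominator makes a small set's profile
#' comparable with the whole community's — the community value is then the
#' abundance-weighted mixture of a set's and its complement's values, and
#' lies between them. The profile reports the mean and sd across the
#' requested sites, as percentages.
#'
#' @param otu_set character vector of OTU ids (empty set allowed).
#' @param table the community [otu_table()] with sample metadata.
#' @param labels OTU -> categories mapping from [apply_rules()].
#' @param sites integer vector of sites to average over.
#' @param categories categories to report (default: all in `labels`).
#' @param group label recorded with the profile.
#' @return object of class `function_profile`: `data.frame` with `category`,
#'   `mean`, `sd` (percent) plus a `per_site` matrix attribute
#'   (categories x sites).
#' @export
function_profile <- function(otu_set, table, labels, sites = 1:8,
                             categories = NULL, group = "set") {
  if (is.null(table$sample_meta)) stop("sample metadata required")
  if (is.null(categories))
    categories <- sort(unique(unlist(labels)))
  rel <- relative_abundance(table)
  meta <- table$sample_meta
  sites <- intersect(sites, unique(meta$site))
  if (length(sites) < 1) stop("no valid sites requested")
  per_site <- matrix(0, length(categories), length(sites),
                     dimnames = list(categories, sites))
  set_in <- intersect(otu_set, rownames(rel))
  for (cat_i in seq_along(categories)) {
    members <- set_in[vapply(labels[set_in], function(l)
      categories[cat_i] %in% l, logical(1))]
    for (s_i in seq_along(sites)) {
      cols <- meta$sample[meta$site == sites[s_i]]
      denom <- if (length(set_in))
        colSums(rel[set_in, cols, drop = FALSE]) else rep(0, length(cols))
      num <- if (length(members))
        colSums(rel[members, cols, drop = FALSE]) else rep(0, length(cols))
      share <- ifelse(denom > 0, num / denom, 0)
      per_site[cat_i, s_i] <- mean(share) * 100
    }
  }
  df <- data.frame(category = categories,
                   mean = rowMeans(per_site),
                   sd = apply(per_site, 1, stats::sd),
                   group = group, stringsAsFactors = FALSE)
  attr(df, "per_site") <- per_site
  class(df) <- c("function_profile", class(df))
  df
}

#' Compare functional profiles across groups
#'
#' Per category: one-way ANOVA across three or more groups, a two-sample
#' t-test (equal variances) for exactly two. Per-site shares are the
#' observations; p-values are reported raw (no multiplicity correction).
#' Categories with zero variance in every group are skipped and flagged.
#'
#' @param profiles named list of [function_profile()] objects (>= 2), each
#'   built over at least 2 sites.
#' @return `data.frame`: category, test, statistic, p, flag, plus per-group
#'   mean columns.
#' @export
compare_profiles <- function(profiles) {
  if (length(profiles) < 2) stop("need at least 2 profiles")
  if (is.null(names(profiles)))
    names(profiles) <- paste0("group", seq_along(profiles))
  mats <- lapply(profiles, attr, "per_site")
  if (any(vapply(mats, ncol, integer(1)) < 2))
    stop("each profile needs at least 2 sites")
  cats <- sort(unique(unlist(lapply(mats, rownames))))
  rows <- lapply(cats, function(cc) {
    vals <- lapply(mats, function(m)
      if (cc %in% rownames(m)) m[cc, ] else rep(0, ncol(m)))
    means <- vapply(vals, mean, numeric(1))
    if (all(vapply(vals, function(v) stats::sd(v) == 0, logical(1))))
      return(data.frame(category = cc, test = NA_character_,
                        statistic = NA_real_, p = NA_real_,
                        flag = "zero-variance",
                        t(means), check.names = FALSE))
    if (length(vals) == 2) {
      tt <- stats::t.test(vals[[1]], vals[[2]], var.equal = TRUE)
      data.frame(category = cc, test = "t", statistic = unname(tt$statistic),
                 p = tt$p.value, flag = "", t(means), check.names = FALSE)
    } else {
      df <- data.frame(y = unlist(vals),
                       g = factor(rep(names(vals), lengths(vals))))
      fit <- stats::aov(y ~ g, data = df)
      sm <- summary(fit)[[1]]
      data.frame(category = cc, test = "anova",
                 statistic = sm$`F value`[1], p = sm$`Pr(>F)`[1],
                 flag = "", t(means), check.names = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
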