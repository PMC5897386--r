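# Synthetic gradient-community generator with planted ground truth.
#
# The generator emulates a two-section altitudinal soil transect: 8 sites x 3
# replicates, a monotone pH 8.8 -> 5.7 gradient with co-varying temperature /
# humidity / nutrients, log-normal-dominated abundances, a core OTU set shared
# between the two site sections, section-exclusive OTUs whose association
# roles are swapped between sections, and a core-enriched nitrogen-fixation
# function label. Associations are planted through a sparse latent-factor
# model: each association-bearing OTU carries a signed factor combination
# (unique across the community), OTUs sharing a factor with same-sign loadings
# co-occur, opposite signs exclude, and role-swap partners carry identical
# loading patterns but distinct taxonomy.

#' Derive a stage seed from a master seed
#'
#' Deterministic, platform-independent mixing of a master seed and a stage
#' name, kept below 2^31 - 1 so it is always a valid R seed.
#'
#' @param master integer master seed.
#' @param stage character stage name.
#' @return integer seed.
#' @export
derive_seed <- function(master, stage) {
  chars <- utf8ToInt(paste0(stage, ":", master))
  s <- sum(chars * 31^((seq_along(chars) - 1) %% 5))
  as.integer((s + as.numeric(master) %% 2147483647) %% 2147483646 + 1)
}

#' Simulation configuration
#'
#' Defaults encode the transect study design: 8 sites x 3 replicates (sites
#' 1-4 form section 1, sites 5-8 section 2), sequencing depths between 3,900
#' and 26,000 reads, 600 OTUs of which 230 are core (present in both
#' sections) and 80 pairs are role-swapped section-exclusive partners, and 12
#' latent association factors (three tied to abiotic variables, the rest
#' biotic). `n_core` and `n_roleswap_pairs` default to the full-design
#' fractions (230/600 and 80/600) when `n_otus` is changed.
#'
#' @param n_sites,n_replicates transect design.
#' @param n_otus community size.
#' @param n_core OTUs present in both sections.
#' @param n_roleswap_pairs section-exclusive OTU pairs sharing a loading
#'   pattern.
#' @param n_latent_factors number of latent association factors.
#' @param depth_range integer range of per-sample sequencing depths.
#' @param dominance log-normal sd of baseline log-abundances (controls how
#'   much of the community the top OTUs hold).
#' @param dispersion per-cell log-normal noise sd added on top of the factor
#'   model for association-bearing OTUs.
#' @param background_dispersion per-cell noise sd of background OTUs
#'   (rare-biosphere taxa fluctuate more than niche-entrenched ones;
#'   default 1).
#' @param effect_size total loading magnitude of an association-bearing OTU
#'   (split as `effect_size / sqrt(combo size)` per factor).
#' @param baseline_shift mean log-abundance boost of association-bearing
#'   OTUs, keeping planted edges above the occurrence filter.
#' @param combo_size_probs sampling probabilities of factor-combination
#'   sizes 1 and 2 for core and extra OTUs (role-swap pairs always carry a
#'   reserved multi-factor combination unique to the pair, which gives them
#'   a topologically identifiable neighbourhood).
#' @param positive_sign_prob probability that a loading is positive.
#' @param extra_factor_prob probability that a non-core, non-swap
#'   section-exclusive OTU carries a factor combination (default 0: the
#'   extra OTUs are rare-biosphere background, so the planted module
#'   structure is exactly symmetric between sections).
#' @param edge_coupling_min minimum |loading product| relative to
#'   `effect_size^2` for a factor-sharing pair to count as a planted edge;
#'   pairs coupled only through weak secondary loadings are background
#'   structure, not truth (default 0.45).
#' @param minocc section occurrence threshold a planted edge's OTUs must
#'   survive (planted edges are conditioned on discoverability; default 10).
#' @param nfix_base probability that a noncore OTU carries a
#'   nitrogen-fixation genus.
#' @param nfix_enrichment fold enrichment of that probability in core OTUs
#'   (default 10).
#' @param other_function_prob probability that a non-nitrogen-fixing OTU
#'   carries some other rule-bearing genus.
#' @param env_factor_vars abiotic variables that anchor environmental
#'   factors.
#' @param env_noise replicate-level measurement noise of abiotic variables
#'   (relative; additive on pH).
#' @param seed mandatory integer master seed.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_sites = 8, n_replicates = 3, n_otus = 600,
                              n_core = NULL, n_roleswap_pairs = NULL,
                              n_latent_factors = 12,
                              depth_range = c(3900, 26000),
                              dominance = 1.8, dispersion = 0.15,
                              background_dispersion = 1,
                              effect_size = 1.8, baseline_shift = 2,
                              combo_size_probs = c(0.95, 0.05),
                              positive_sign_prob = 0.85,
                              edge_coupling_min = 0.45,
                              extra_factor_prob = 0, minocc = 10,
                              nfix_base = 0.015, nfix_enrichment = 10,
                              other_function_prob = 0.35,
                              env_factor_vars = c("pH"),
                              env_noise = 0.04, seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (is.null(n_core)) n_core <- round(n_otus * 230 / 600)
  if (is.null(n_roleswap_pairs)) n_roleswap_pairs <- round(n_otus * 80 / 600)
  cfg <- list(n_sites = n_sites, n_replicates = n_replicates,
              n_otus = n_otus, n_core = n_core,
              n_roleswap_pairs = n_roleswap_pairs,
              n_latent_factors = n_latent_factors,
              depth_range = depth_range, dominance = dominance,
              dispersion = dispersion,
              background_dispersion = background_dispersion,
              effect_size = effect_size,
              baseline_shift = baseline_shift,
              combo_size_probs = combo_size_probs,
              positive_sign_prob = positive_sign_prob,
              extra_factor_prob = extra_factor_prob, minocc = minocc,
              edge_coupling_min = edge_coupling_min,
              nfix_base = nfix_base, nfix_enrichment = nfix_enrichment,
              other_function_prob = other_function_prob,
              env_factor_vars = env_factor_vars,
              env_noise = env_noise, seed = as.integer(seed))
  if (cfg$n_core + 2 * cfg$n_roleswap_pairs > cfg$n_otus)
    stop("infeasible config: n_core + 2 * n_roleswap_pairs > n_otus")
  if (length(depth_range) != 2 || depth_range[1] < 1 ||
      depth_range[2] < depth_range[1])
    stop("invalid depth_range")
  if (n_latent_factors < length(cfg$env_factor_vars))
    stop("need at least as many factors as env_factor_vars")
  class(cfg) <- "simulation_config"
  cfg
}

#' Generate the abiotic gradient table
#'
#' pH declines monotonically from 8.8 (site 1, low elevation) to 5.7 (site
#' 8); temperature declines and relative humidity rises with site index; Fe,
#' P, Zn, total C and Cu are enriched towards the high-elevation sites while
#' K and Ca decrease; N derivatives, Mg, S, Na and EC stay flat up to
#' replicate noise.
#'
#' @param cfg a [simulation_config()].
#' @return an [abiotic_table()] with sample metadata.
#' @export
generate_gradient <- function(cfg) {
  old_seed <- .save_seed(); on.exit(.restore_seed(old_seed))
  set.seed(derive_seed(cfg$seed, "gradient"))
  ns <- cfg$n_sites; nr <- cfg$n_replicates
  site_profile <- list(
    pH = seq(8.8, 5.7, length.out = ns),
    Temperature = seq(13, 4, length.out = ns),
    RelativeHumidity = seq(20, 70, length.out = ns),
    Fe = seq(5, 30, length.out = ns),
    P = seq(2.33, 26.33, length.out = ns),
    Zn = seq(0.5, 3, length.out = ns),
    C_total = seq(0.37, 1.1, length.out = ns),
    Cu = seq(0.4, 2.5, length.out = ns),
    K = seq(800, 300, length.out = ns),
    Ca = seq(3000, 900, length.out = ns),
    N_total = rep(0.04, ns), NO3 = rep(8, ns), NH4 = rep(4, ns),
    Mg = rep(120, ns), S = rep(15, ns), Na = rep(50, ns),
    EC = rep(0.6, ns))
  site <- rep(seq_len(ns), each = nr)
  repl <- rep(seq_len(nr), times = ns)
  samples <- sprintf("S%dR%d", site, repl)
  vals <- matrix(NA_real_, length(site_profile), length(samples),
                 dimnames = list(names(site_profile), samples))
  for (v in names(site_profile)) {
    base <- site_profile[[v]][site]
    if (v == "pH") {
      vals[v, ] <- pmin(14, pmax(0, base + stats::rnorm(length(base), 0,
                                                        cfg$env_noise)))
    } else {
      vals[v, ] <- base * (1 + stats::rnorm(length(base), 0, cfg$env_noise))
      if (v == "RelativeHumidity") vals[v, ] <- pmin(100, pmax(0, vals[v, ]))
    }
  }
  meta <- data.frame(sample = samples, site = site, replicate = repl,
                     section = ifelse(site <= ns / 2, 1L, 2L),
                     stringsAsFactors = FALSE)
  abiotic_table(vals, sample_meta = meta)
}

# reserved combos for role-swap pairs: unsigned factor subsets, unique per
# pair, drawn from sizes 2 then 3 so every pair has an identifiable
# multi-factor neighbourhood
.swap_combos <- function(K, n_pairs) {
  pool2 <- utils::combn(K, 2)
  pool2 <- pool2[, sample.int(ncol(pool2)), drop = FALSE]
  combos <- lapply(seq_len(min(n_pairs, ncol(pool2))),
                   function(i) pool2[, i])
  if (n_pairs > ncol(pool2)) {
    pool3 <- utils::combn(K, 3)
    pool3 <- pool3[, sample.int(ncol(pool3)), drop = FALSE]
    extra <- n_pairs - ncol(pool2)
    if (extra > ncol(pool3))
      stop("factor combination pool exhausted; increase n_latent_factors")
    combos <- c(combos, lapply(seq_len(extra), function(i) pool3[, i]))
  }
  combos
}

.combo_key <- function(cmb) paste(sort(cmb), collapse = "-")

# factor score matrix for one section: environmental rows pass through as
# standardised profiles; biotic rows are Gram-Schmidt orthogonalised against
# the constant vector (so orthogonality means exactly zero sample
# correlation), the environmental profiles and each other, then scaled to
# unit sd. When the sample space is exhausted the remaining factors fall
# back to random centred scores.
.orth_factors <- function(env_block, K) {
  n <- ncol(env_block)
  out <- matrix(0, K, n)
  basis <- list(rep(1, n) / sqrt(n))
  add_basis <- function(v) {
    for (b in basis) v <- v - sum(v * b) * b
    nv <- sqrt(sum(v^2))
    if (nv < 1e-8) return(NULL)
    v / nv
  }
  for (i in seq_len(K)) {
    if (i <= nrow(env_block)) {
      out[i, ] <- env_block[i, ]
      b <- add_basis(env_block[i, ])
      if (!is.null(b)) basis[[length(basis) + 1]] <- b
    } else if (length(basis) < n) {
      b <- NULL
      while (is.null(b)) b <- add_basis(stats::rnorm(n))
      basis[[length(basis) + 1]] <- b
      out[i, ] <- b / stats::sd(b)
    } else {
      v <- as.numeric(scale(stats::rnorm(n)))
      out[i, ] <- v
    }
  }
  out
}

# iid combo draw (sizes 1-2) avoiding the reserved swap combos; factors are
# drawn with linearly decreasing weights so clique sizes are heterogeneous
# (size is then a topological fingerprint of the module); the first,
# environment-anchored factors host the largest cliques and any factor that
# could not be orthogonalised within the sample space (the last) the
# smallest
.draw_combo <- function(K, size_probs, reserved_keys) {
  fw <- rev(seq_len(K))
  for (try in 1:100) {
    s <- sample.int(length(size_probs), 1, prob = size_probs)
    cmb <- sort(sample.int(K, s, prob = fw))
    if (!(.combo_key(cmb) %in% reserved_keys)) return(cmb)
  }
  stop("could not draw a non-reserved factor combination")
}

.phyla <- c("Actinobacteria", "Proteobacteria", "Acidobacteria",
            "Bacteroidetes", "Chloroflexi", "Firmicutes",
            "Gemmatimonadetes", "Nitrospirae", "Planctomycetes",
            "Verrucomicrobia")
.phyla_base <- c(0.22, 0.22, 0.12, 0.08, 0.08, 0.07, 0.07, 0.04, 0.05, 0.05)

.function_genera <- list(
  nfix = list(genera = c("Bradyrhizobium", "Azospirillum", "Rhizobium",
                         "Mesorhizobium", "Frankia", "Azotobacter"),
              phyla = c("Proteobacteria", "Proteobacteria", "Proteobacteria",
                        "Proteobacteria", "Actinobacteria", "Proteobacteria")),
  other = list(genera = c("Arthrobacter", "Streptomyces", "Pseudomonas",
                          "Bacillus", "Sphingomonas", "Rubrobacter",
                          "Nitrospira", "Nitrosomonas", "Nitrobacter",
                          "Clostridium", "Lactobacillus", "Methylobacter",
                          "Methylobacterium", "Geobacter", "Thiobacillus"),
               phyla = c("Actinobacteria", "Actinobacteria", "Proteobacteria",
                         "Firmicutes", "Proteobacteria", "Actinobacteria",
                         "Nitrospirae", "Proteobacteria", "Proteobacteria",
                         "Firmicutes", "Firmicutes", "Proteobacteria",
                         "Proteobacteria", "Proteobacteria",
                         "Proteobacteria")))

.lineage <- function(phylum, genus) {
  sprintf("k__Bacteria; p__%s; c__%s_c; o__%s_o; f__%s_f; g__%s",
          phylum, phylum, phylum, phylum, genus)
}

#' Generate the synthetic community and its planted truth
#'
#' Builds per-sample expected log-abundances from the latent-factor model,
#' draws counts by multinomial sampling at a per-sample depth, emits a
#' taxonomy-consistent pairwise sequence-identity matrix (same genus
#' 0.97-0.995, same phylum 0.85-0.93, cross-phylum 0.75-0.83) and records the
#' planted ground truth (signed true edges per section, core set, role-swap
#' map).
#'
#' @param cfg a [simulation_config()].
#' @param gradient the matching [generate_gradient()] output.
#' @return list with `otu` ([otu_table()]), `identity` ([seq_similarity()]),
#'   `truth` (class `synthetic_truth`) and `proportions` (the model's
#'   noise-free per-sample proportions, for calibration checks).
#' @export
generate_community <- function(cfg, gradient) {
  old_seed <- .save_seed(); on.exit(.restore_seed(old_seed))
  set.seed(derive_seed(cfg$seed, "community"))
  n <- cfg$n_otus
  K <- cfg$n_latent_factors
  ids <- sprintf("OTU%04d", seq_len(n))
  meta <- gradient$sample_meta
  samples <- meta$sample
  nsamp <- length(samples)

  ## roles
  core <- ids[seq_len(cfg$n_core)]
  np <- cfg$n_roleswap_pairs
  swapA <- ids[cfg$n_core + seq_len(np)]
  swapB <- ids[cfg$n_core + np + seq_len(np)]
  extras <- setdiff(ids, c(core, swapA, swapB))
  extras1 <- extras[seq_len(floor(length(extras) / 2))]
  extras2 <- setdiff(extras, extras1)
  in_s1 <- ids %in% c(core, swapA, extras1)
  in_s2 <- ids %in% c(core, swapB, extras2)

  ## taxonomy: section-skewed phylum mix, distinct genera for swap partners
  skew <- function(boost_phylum) {
    p <- .phyla_base
    p[.phyla == boost_phylum] <- p[.phyla == boost_phylum] + 0.15
    p / sum(p)
  }
  phylum <- character(n); names(phylum) <- ids
  phylum[core] <- sample(.phyla, length(core), TRUE, .phyla_base)
  phylum[c(swapA, extras1)] <- sample(.phyla, np + length(extras1), TRUE,
                                      skew("Actinobacteria"))
  phylum[c(swapB, extras2)] <- sample(.phyla, np + length(extras2), TRUE,
                                      skew("Proteobacteria"))
  genus <- sprintf("%s_g%02d", substr(phylum, 1, 4),
                   sample.int(12, n, TRUE))
  names(genus) <- ids
  # role-swap partners must differ in taxonomy
  same <- genus[swapA] == genus[swapB] & phylum[swapA] == phylum[swapB]
  while (any(same)) {
    genus[swapB[same]] <- sprintf("%s_g%02d", substr(phylum[swapB[same]], 1, 4),
                                  sample.int(12, sum(same), TRUE))
    same <- genus[swapA] == genus[swapB] & phylum[swapA] == phylum[swapB]
  }

  ## nitrogen-fixation and other function-bearing genera
  p_nfix <- ifelse(ids %in% core, pmin(1, cfg$nfix_base * cfg$nfix_enrichment),
                   cfg$nfix_base)
  is_nfix <- stats::runif(n) < p_nfix
  k <- sum(is_nfix)
  if (k) {
    pick <- sample.int(length(.function_genera$nfix$genera), k, TRUE)
    genus[is_nfix] <- .function_genera$nfix$genera[pick]
    phylum[is_nfix] <- .function_genera$nfix$phyla[pick]
  }
  is_other <- !is_nfix & stats::runif(n) < cfg$other_function_prob
  k <- sum(is_other)
  if (k) {
    pick <- sample.int(length(.function_genera$other$genera), k, TRUE)
    genus[is_other] <- .function_genera$other$genera[pick]
    phylum[is_other] <- .function_genera$other$phyla[pick]
  }
  taxonomy <- .lineage(phylum, genus)
  names(taxonomy) <- ids

  ## latent factors: env-anchored (standardised abiotic profiles) + biotic.
  ## Biotic factor scores are drawn orthogonal to the environmental profiles
  ## and to each other within each section: latent community axes are
  ## independent by construction, so associations between OTUs on different
  ## factors are not planted by accident at this design's sample size.
  fmat <- matrix(0, K, nsamp, dimnames = list(NULL, samples))
  env_vars <- cfg$env_factor_vars
  for (sec in 1:2) {
    cols <- which(meta$section == sec)
    env_block <- matrix(0, length(env_vars), length(cols))
    for (i in seq_along(env_vars)) {
      row <- gradient$values[env_vars[i], cols]
      env_block[i, ] <- if (stats::sd(row) > 0) as.numeric(scale(row)) else 0
    }
    fmat[, cols] <- .orth_factors(env_block, K)
  }

  ## signed factor combinations; swap pairs get reserved unique combos
  loadings <- matrix(0, n, K, dimnames = list(ids, NULL))
  reserved <- .swap_combos(K, np)
  reserved_keys <- vapply(reserved, .combo_key, character(1))
  for (i in seq_len(np)) {
    combo <- reserved[[i]]
    sgn <- ifelse(stats::runif(length(combo)) < cfg$positive_sign_prob, 1, -1)
    # asymmetric split: a strong primary clique membership plus a moderate
    # secondary one that makes the pair's neighbourhood identifiable
    wts <- c(0.87, 0.5, 0.3)[seq_along(combo)]
    wts <- wts / sqrt(sum(wts^2))
    loadings[swapA[i], combo] <- sgn * cfg$effect_size * wts
  }
  others <- c(core, extras[stats::runif(length(extras)) <
                             cfg$extra_factor_prob])
  for (id in others) {
    combo <- .draw_combo(K, cfg$combo_size_probs, reserved_keys)
    sgn <- ifelse(stats::runif(length(combo)) < cfg$positive_sign_prob, 1, -1)
    loadings[id, combo] <- sgn * cfg$effect_size / sqrt(length(combo))
  }
  loadings[swapB, ] <- loadings[swapA, ]
  has_factor <- rowSums(loadings != 0) > 0

  ## baseline log-abundances: log-normal background; association bearers sit
  ## at a characteristic level of their factors (niche-sharing taxa have
  ## similar abundance scales, which keeps planted pairs consistent across
  ## the dissimilarity measures as well as the correlations), floored so
  ## planted edges stay above the occurrence filter
  baseline <- stats::rnorm(n, -1, cfg$dominance)
  factor_level <- stats::rnorm(K, cfg$baseline_shift, 0.35)
  bl <- apply(loadings != 0, 1, function(z)
    if (any(z)) mean(factor_level[z]) else NA_real_)
  boost <- pmax(bl + stats::rnorm(n, 0, 0.2), cfg$baseline_shift - 1)
  baseline[has_factor] <- boost[has_factor]
  names(baseline) <- ids

  ## expected log-abundance and counts
  present <- outer(in_s1, meta$section == 1) | outer(in_s2, meta$section == 2)
  dimnames(present) <- list(ids, samples)
  disp <- ifelse(has_factor, cfg$dispersion, cfg$background_dispersion)
  loglam <- baseline + loadings %*% fmat +
    matrix(stats::rnorm(n * nsamp), n, nsamp) * disp
  lam <- exp(loglam) * present
  props <- sweep(lam, 2, colSums(lam), "/")
  depths <- sample(seq(cfg$depth_range[1], cfg$depth_range[2]), nsamp,
                   replace = TRUE)
  counts <- matrix(0, n, nsamp, dimnames = list(ids, samples))
  for (j in seq_len(nsamp))
    counts[, j] <- stats::rmultinom(1, depths[j], props[, j])

  ## planted true edges per section, conditioned on discoverability: both
  ## endpoints must clear the occurrence filter in that section's samples
  edge_rows <- list()
  share <- (loadings != 0) %*% t(loadings != 0)
  wmat <- loadings %*% t(loadings)
  for (sec in 1:2) {
    occ <- rowSums(counts[, meta$section == sec, drop = FALSE] > 0)
    memb <- (if (sec == 1) in_s1 else in_s2) & occ >= cfg$minocc
    cand <- which(memb & has_factor)
    if (length(cand) > 1) {
      pr <- which(share[cand, cand] > 0 & upper.tri(share[cand, cand]),
                  arr.ind = TRUE)
      if (nrow(pr)) {
        a <- ids[cand[pr[, 1]]]; b <- ids[cand[pr[, 2]]]
        w <- wmat[cbind(cand[pr[, 1]], cand[pr[, 2]])]
        keep <- abs(w) >= cfg$edge_coupling_min * cfg$effect_size^2
        edge_rows[[length(edge_rows) + 1]] <- data.frame(
          section = sec, node1 = pmin(a[keep], b[keep]),
          node2 = pmax(a[keep], b[keep]),
          sign = ifelse(w[keep] > 0, "copresence", "exclusion"),
          type = "otu-otu", stringsAsFactors = FALSE)
      }
    }
    # OTU-variable edges through environment-anchored factors
    for (i in seq_along(env_vars)) {
      hit <- which(memb & abs(loadings[, i]) >=
                     sqrt(cfg$edge_coupling_min) * cfg$effect_size)
      if (length(hit))
        edge_rows[[length(edge_rows) + 1]] <- data.frame(
          section = sec, node1 = ids[hit], node2 = env_vars[i],
          sign = ifelse(loadings[hit, i] > 0, "copresence", "exclusion"),
          type = "otu-variable", stringsAsFactors = FALSE)
    }
  }
  true_edges <- do.call(rbind, edge_rows)

  ## sequence identities stratified by taxonomy
  upper <- upper.tri(matrix(0, n, n))
  idm <- matrix(stats::runif(n * n, 0.75, 0.83), n, n)
  same_ph <- outer(phylum, phylum, "==")
  same_ge <- same_ph & outer(genus, genus, "==")
  idm[same_ph] <- stats::runif(sum(same_ph), 0.85, 0.93)
  idm[same_ge] <- stats::runif(sum(same_ge), 0.97, 0.995)
  idm[lower.tri(idm)] <- t(idm)[lower.tri(idm)]
  diag(idm) <- 1
  dimnames(idm) <- list(ids, ids)

  truth <- structure(list(
    true_edges = true_edges,
    core_set = core,
    roleswap_map = stats::setNames(swapB, swapA),
    section_otus = list(`1` = ids[in_s1], `2` = ids[in_s2]),
    loadings = loadings,
    env_factor_vars = env_vars,
    function_labels = NULL), class = "synthetic_truth")

  list(otu = otu_table(counts, taxonomy = taxonomy, sample_meta = meta),
       identity = seq_similarity(idm),
       truth = truth,
       proportions = props)
}

#' Attach function labels to a synthetic truth
#'
#' Applies the bundled FAPROTAX-style rule set to the community taxonomy and
#' stores the resulting OTU -> category labels in the truth object. Because
#' `generate_community` plants nitrogen-fixation genera into core OTUs at
#' `nfix_enrichment` times the noncore rate, the labelled core set is
#' function-enriched by construction (no enrichment when the factor is 1).
#'
#' @param truth a `synthetic_truth`.
#' @param otu the matching community [otu_table()].
#' @param cfg the [simulation_config()] used.
#' @return list with `rules` (a [rule_set()]), `labels` (named list OTU ->
#'   categories) and the updated `truth`.
#' @export
plant_functions <- function(truth, otu, cfg) {
  rules <- default_rules()
  labels <- apply_rules(rules, otu$taxonomy)
  truth$function_labels <- labels
  list(rules = rules, labels = labels, truth = truth)
}

#' Run the full generator and optionally write its artifacts
#'
#' @param cfg a [simulation_config()].
#' @param out_dir optional directory; when given, writes `otu_table.tsv`,
#'   `sample_meta.tsv`, `abiotic.tsv`, `identity.tsv`, `rules.tsv` and
#'   `truth.json`.
#' @return list with `otu`, `abiotic`, `identity`, `truth`, `rules`,
#'   `labels`, `proportions`, `config`.
#' @export
simulate_dataset <- function(cfg, out_dir = NULL) {
  gradient <- generate_gradient(cfg)
  comm <- generate_community(cfg, gradient)
  pf <- plant_functions(comm$truth, comm$otu, cfg)
  out <- list(otu = comm$otu, abiotic = gradient, identity = comm$identity,
              truth = pf$truth, rules = pf$rules, labels = pf$labels,
              proportions = comm$proportions, config = cfg)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_otu_table(out$otu, file.path(out_dir, "otu_table.tsv"),
                    meta_path = file.path(out_dir, "sample_meta.tsv"))
    write_abiotic_table(out$abiotic, file.path(out_dir, "abiotic.tsv"))
    write_similarity_matrix(out$identity, file.path(out_dir, "identity.tsv"))
    write_rules(out$rules, file.path(out_dir, "rules.tsv"))
    truth_json <- list(true_edges = out$truth$true_edges,
                       core_set = out$truth$core_set,
                       roleswap_map = as.list(out$truth$roleswap_map),
                       section_otus = out$truth$section_otus,
                       function_labels = out$truth$function_labels)
    jsonlite::write_json(truth_json, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

#' Build the noise-free planted network of one section
#'
#' Turns the planted true edge set into a [coocnet()]; used for topology
#' recovery experiments where the edge set itself must be exact.
#'
#' @param truth a `synthetic_truth`.
#' @param section section id (1 or 2).
#' @param include_variables include OTU-variable edges and VARIABLE nodes.
#' @param taxonomy optional named taxonomy vector to attach to OTU nodes.
#' @return a [coocnet()].
#' @export
truth_network <- function(truth, section, include_variables = FALSE,
                          taxonomy = NULL) {
  ed <- truth$true_edges[truth$true_edges$section == section, , drop = FALSE]
  if (!include_variables) ed <- ed[ed$type == "otu-otu", , drop = FALSE]
  otus <- truth$section_otus[[as.character(section)]]
  nodes <- data.frame(name = otus, kind = "OTU", stringsAsFactors = FALSE)
  if (!is.null(taxonomy)) nodes$taxonomy <- unname(taxonomy[otus])
  if (include_variables) {
    vars <- unique(ed$node2[ed$type == "otu-variable"])
    if (length(vars)) {
      vdf <- data.frame(name = vars, kind = "VARIABLE",
                        stringsAsFactors = FALSE)
      if (!is.null(taxonomy)) vdf$taxonomy <- NA_character_
      nodes <- rbind(nodes, vdf)
    }
  }
  coocnet(nodes, ed[c("node1", "node2", "sign")])
}

#' Score an inferred network against the planted truth
#'
#' Precision, recall and F1 of the inferred edge set against the planted
#' edges of the section (unordered node pairs; OTU-OTU edges by default).
#' Sign accuracy is reported over the true-positive edges.
#'
#' @param net inferred `coocnet`.
#' @param truth a `synthetic_truth`.
#' @param section section id.
#' @param include_variables also count OTU-variable edges.
#' @return list with `tp`, `fp`, `fn`, `precision`, `recall`, `f1`,
#'   `sign_accuracy`.
#' @export
edge_recovery <- function(net, truth, section, include_variables = FALSE) {
  g <- as_igraph_net(net)
  ed <- igraph::as_data_frame(g, what = "edges")
  kind <- stats::setNames(igraph::vertex_attr(g, "kind"), igraph::V(g)$name)
  if (!include_variables && nrow(ed))
    ed <- ed[kind[ed$from] == "OTU" & kind[ed$to] == "OTU", , drop = FALSE]
  te <- truth$true_edges[truth$true_edges$section == section, , drop = FALSE]
  if (!include_variables) te <- te[te$type == "otu-otu", , drop = FALSE]
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  inf_key <- if (nrow(ed)) key(ed$from, ed$to) else character()
  true_key <- key(te$node1, te$node2)
  tp_keys <- intersect(inf_key, true_key)
  tp <- length(tp_keys); fp <- length(setdiff(inf_key, true_key))
  fn <- length(setdiff(true_key, inf_key))
  prec <- if (tp + fp) tp / (tp + fp) else NA_real_
  rec <- if (tp + fn) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0)
    2 * prec * rec / (prec + rec) else 0
  sign_acc <- NA_real_
  if (tp && "sign" %in% names(ed)) {
    inf_sign <- stats::setNames(ed$sign, inf_key)
    true_sign <- stats::setNames(te$sign, true_key)
    sign_acc <- mean(inf_sign[tp_keys] == true_sign[tp_keys])
  }
  list(tp = tp, fp = fp, fn = fn, precision = prec, recall = rec, f1 = f1,
       sign_accuracy = sign_acc)
}

#' Fraction of role-swap pairs recovered by an alignment
#'
#' A pair (a in section 1, b in section 2) counts as recovered when the
#' alignment maps a exactly to b.
#'
#' @param aln an `alignment_result` from [align_networks()] (section 1
#'   network first).
#' @param truth a `synthetic_truth`.
#' @return list with `recovered`, `total`, `fraction`.
#' @export
swap_recovery <- function(aln, truth) {
  map <- stats::setNames(aln$mapping$node2, aln$mapping$node1)
  a <- names(truth$roleswap_map)
  b <- unname(truth$roleswap_map)
  hit <- !is.na(map[a]) & map[a] == b
  list(recovered = sum(hit), total = length(a),
       fraction = if (length(a)) mean(hit) else NA_real_)
}
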