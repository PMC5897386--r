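# End-to-end orchestration: simulate (or load), filter, profile, infer both
# section networks, align/scan, decompose and functionally profile, with a
# machine-readable run report. Every stochastic stage receives a seed derived
# from the master seed and the stage name, so stages can be re-run in
# isolation and a rerun with the same configuration reproduces the report
# byte for byte.

#' Default pipeline configuration
#'
#' Parameter defaults follow the transect study design: replicate filter 2/3,
#' occurrence filter 5 samples, network minocc 10, 1,000 positive and 1,000
#' negative candidate edges, 1,000 permutation/bootstrap draws, alpha grid
#' 0-1 by 0.1, hub/correlation decile 0.10, abundance cut 0.1%, rarefaction
#' to 3,900 sequences in steps of 389 with 10 iterations.
#'
#' @param seed master seed (mandatory).
#' @param out_dir output directory for artifacts (`NULL`: no files written).
#' @param simulate generate data with [simulate_dataset()] (`TRUE`) or read
#'   the files in `paths` (`FALSE`).
#' @param sim list of [simulation_config()] overrides.
#' @param paths named list of input paths (`otu`, `meta`, `abiotic`,
#'   `identity`, `rules`) used when `simulate = FALSE`.
#' @param ... scalar parameter overrides (`min_reps`, `min_samples`,
#'   `minocc`, `n_pos`, `n_neg`, `n_perm`, `q_cut`, `alpha_grid`,
#'   `decile`, `abundance_cut`, `variables`, `rarefaction_depth`,
#'   `rarefaction_step`, `rarefaction_iters`, `do_rarefaction`).
#' @return list of class `run_config`.
#' @export
pipeline_config <- function(seed, out_dir = NULL, simulate = TRUE,
                            sim = list(), paths = list(), ...) {
  if (missing(seed)) stop("seed is mandatory")
  cfg <- list(seed = as.integer(seed), out_dir = out_dir,
              simulate = simulate, sim = sim, paths = paths,
              min_reps = 2, min_samples = 5, minocc = 10,
              n_pos = 1000, n_neg = 1000, n_perm = 1000, q_cut = 0.05,
              alpha_grid = seq(0, 1, by = 0.1),
              decile = 0.10, abundance_cut = 0.001,
              variables = c("pH", "RelativeHumidity", "Temperature",
                            "N_total", "C_total", "P", "S", "Cu", "Fe", "Zn"),
              rarefaction_depth = 3900, rarefaction_step = 389,
              rarefaction_iters = 10, do_rarefaction = TRUE)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown option(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  class(cfg) <- "run_config"
  cfg
}

#' Run the full co-occurrence comparison pipeline
#'
#' Stages, in order: data (simulate or load), replicate-consistency filter,
#' per-section occurrence filter, diversity/rarefaction, per-section network
#' inference, alpha-scan alignment of the two networks, core/noncore
#' decomposition with aligned-to-self counting and node flags, and
#' functional profiling with group comparisons. The report records the OTU
#' counts surviving each filter, nodes/edges and statistics per network,
#' EC/SS per alpha, core/noncore sizes, the aligned-to-self fraction and the
#' function comparison table, along with all seeds and the package version.
#'
#' @param config a [pipeline_config()], a list of its arguments, or a YAML
#'   file path of those arguments.
#' @return the run report (list), invisibly written to
#'   `<out_dir>/report.json` when `out_dir` is set.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!inherits(config, "run_config"))
    config <- do.call(pipeline_config, config)
  cfg <- config

  if (!cfg$simulate) {
    need <- c("otu", "meta", "abiotic", "identity")
    miss <- setdiff(need, names(cfg$paths))
    if (length(miss))
      stop("config missing required path(s): ", paste(miss, collapse = ", "))
    absent <- unlist(cfg$paths[need])[!file.exists(unlist(cfg$paths[need]))]
    if (length(absent))
      stop("input file(s) not found: ", paste(absent, collapse = ", "))
  }
  if (!is.null(cfg$out_dir))
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  art <- function(name) if (is.null(cfg$out_dir)) NULL
                        else file.path(cfg$out_dir, name)
  report <- list(package = "otunet",
                 version = as.character(utils::packageVersion("otunet")),
                 seed = cfg$seed, stages = list())

  ## stage: data
  if (cfg$simulate) {
    sim_args <- cfg$sim
    sim_args$seed <- derive_seed(cfg$seed, "simulate")
    scfg <- do.call(simulation_config, sim_args)
    dat <- simulate_dataset(scfg, out_dir = art("data"))
    otu <- dat$otu; abiotic <- dat$abiotic; identity <- dat$identity
    rules <- dat$rules; labels <- dat$labels; truth <- dat$truth
  } else {
    otu <- read_otu_table(cfg$paths$otu, meta_path = cfg$paths$meta)
    abiotic <- read_abiotic_table(cfg$paths$abiotic,
                                  meta_path = cfg$paths$meta)
    identity <- read_similarity_matrix(cfg$paths$identity)
    rules <- if (!is.null(cfg$paths$rules)) read_rules(cfg$paths$rules)
             else default_rules()
    labels <- apply_rules(rules, otu$taxonomy)
    truth <- NULL
  }
  report$stages$data <- list(n_otus = n_otus(otu), n_samples = n_samples(otu))

  ## stage: filters
  otu_f <- filter_replicate_consistency(otu, cfg$min_reps)
  report$stages$replicate_filter <- list(n_otus = n_otus(otu_f))
  sections <- list()
  for (sec in 1:2) {
    sl <- section_slice(otu_f, sec)
    sl <- filter_min_samples(sl, cfg$min_samples)
    sections[[sec]] <- sl
    report$stages[[paste0("section", sec, "_filter")]] <-
      list(n_otus = n_otus(sl), n_samples = n_samples(sl))
  }

  ## stage: diversity
  if (isTRUE(cfg$do_rarefaction)) {
    rar <- rarefaction(otu_f, max_depth = cfg$rarefaction_depth,
                       step = cfg$rarefaction_step,
                       iters = cfg$rarefaction_iters,
                       seed = derive_seed(cfg$seed, "rarefaction"))
    report$stages$diversity <- list(
      richness = apply(otu_f$counts > 0, 2, sum),
      shannon = apply(otu_f$counts, 2, shannon),
      rarefaction_excluded = rar$excluded,
      rarefied_richness = stats::setNames(
        rar$mean[, ncol(rar$mean)], rownames(rar$mean)))
  }

  ## stage: networks
  abv <- abiotic$values
  nets <- list()
  for (sec in 1:2) {
    samples <- colnames(sections[[sec]]$counts)
    ab_sec <- abiotic_table(abv[, samples, drop = FALSE])
    net <- build_network(sections[[sec]], ab_sec, variables = cfg$variables,
                         n_pos = cfg$n_pos, n_neg = cfg$n_neg,
                         minocc = cfg$minocc, n_perm = cfg$n_perm,
                         q_cut = cfg$q_cut,
                         seed = derive_seed(cfg$seed, paste0("net", sec)))
    nets[[sec]] <- net
    st <- network_stats(net)
    ed <- igraph::edge_attr(net, "sign")
    report$stages[[paste0("network", sec)]] <- list(
      n_nodes = st$n_nodes,
      n_otu_nodes = length(otu_nodes(net)),
      n_variable_nodes = st$n_nodes - length(otu_nodes(net)),
      n_edges = st$n_edges,
      n_copresence = sum(ed == "copresence"),
      n_exclusion = sum(ed == "exclusion"),
      clustering = st$clustering, path_length = st$path_length,
      density = st$density, heterogeneity = st$heterogeneity,
      degree_verdict = st$verdict)
    if (!is.null(cfg$out_dir))
      write_network(net, art(sprintf("network_section%d.graphml", sec)))
  }

  ## stage: alignment
  n1 <- igraph::vcount(nets[[1]]); n2 <- igraph::vcount(nets[[2]])
  if (n1 > 0 && n2 > 0) {
    scan <- alpha_scan(nets[[1]], nets[[2]], grid = cfg$alpha_grid,
                       seqsim = identity)
    best <- scan$results[[match(scan$consensus_alpha, cfg$alpha_grid)]]
    report$stages$alignment <- list(
      table = scan$table, consensus_alpha = scan$consensus_alpha,
      ec = best$ec, ss = best$ss, n_pairs = nrow(best$mapping))
    if (!is.null(cfg$out_dir))
      utils::write.table(best$mapping, art("alignment.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
  } else {
    scan <- NULL; best <- NULL
    report$stages$alignment <- list(skipped = "empty network")
  }

  ## stage: core / function analysis
  dec <- core_decompose(nets[[1]], nets[[2]])
  report$stages$core <- list(n_core = length(dec$core),
                             n_noncore1 = length(dec$noncore1),
                             n_noncore2 = length(dec$noncore2))
  if (!is.null(best)) {
    ats <- aligned_to_self(best, dec$core)
    report$stages$core$aligned_to_self <- ats$count
    report$stages$core$aligned_to_self_fraction <- ats$fraction
  }
  flags <- lapply(1:2, function(sec)
    flag_nodes(nets[[sec]], sections[[sec]],
               abiotic_table(abv[, colnames(sections[[sec]]$counts),
                                 drop = FALSE]),
               decile = cfg$decile, abundance_cut = cfg$abundance_cut))
  report$stages$flags <- list(
    n_hubs1 = sum(flags[[1]]$is_hub), n_hubs2 = sum(flags[[2]]$is_hub),
    n_abundant1 = sum(flags[[1]]$is_abundant),
    n_abundant2 = sum(flags[[2]]$is_abundant))

  cats <- sort(unique(rules$category))
  profs <- list(
    core = function_profile(dec$core, otu_f, labels, sites = 1:8,
                            categories = cats, group = "core"),
    noncore1 = function_profile(dec$noncore1, otu_f, labels, sites = 1:4,
                                categories = cats, group = "noncore1"),
    noncore2 = function_profile(dec$noncore2, otu_f, labels, sites = 5:8,
                                categories = cats, group = "noncore2"),
    community = function_profile(rownames(otu_f$counts), otu_f, labels,
                                 sites = 1:8, categories = cats,
                                 group = "community"))
  cmp <- compare_profiles(profs[c("core", "noncore1", "noncore2")])
  report$stages$functions <- list(
    profiles = lapply(profs, function(p) p[c("category", "mean", "sd")]),
    comparison = cmp)

  if (!is.null(cfg$out_dir))
    jsonlite::write_json(report, art("report.json"), auto_unbox = TRUE,
                         digits = NA, dataframe = "rows")
  invisible(report)
}
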