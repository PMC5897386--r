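test_that("gradient has the transect's pH endpoints, trends and determinism", {
  cfg <- simulation_config(seed = 21)
  g <- generate_gradient(cfg)
  site_mean <- function(v, s) mean(g$values[v, g$sample_meta$site == s])
  expect_equal(site_mean("pH", 1), 8.8, tolerance = 0.05)
  expect_equal(site_mean("pH", 8), 5.7, tolerance = 0.05)
  # co-varying trends: temperature down, humidity up, Fe/P/Zn/C/Cu up, K/Ca down
  expect_gt(site_mean("Temperature", 1), site_mean("Temperature", 8))
  expect_lt(site_mean("RelativeHumidity", 1), site_mean("RelativeHumidity", 8))
  for (v in c("Fe", "P", "Zn", "C_total", "Cu"))
    expect_lt(site_mean(v, 1), site_mean(v, 8))
  for (v in c("K", "Ca"))
    expect_gt(site_mean(v, 1), site_mean(v, 8))

  # zero noise -> strictly monotone pH
  g0 <- generate_gradient(simulation_config(seed = 21, env_noise = 0))
  expect_true(all(diff(g0$values["pH", seq(1, 24, by = 3)]) < 0))

  # determinism
  g2 <- generate_gradient(simulation_config(seed = 21))
  expect_identical(g$values, g2$values)
})

test_that("community generation is deterministic and obeys design invariants", {
  d1 <- sim_small(n_otus = 120, seed = 31)
  d2 <- simulate_dataset(simulation_config(n_otus = 120, seed = 31))
  expect_identical(d1$otu$counts, d2$otu$counts)
  expect_identical(d1$truth$true_edges, d2$truth$true_edges)
  expect_identical(unclass(d1$identity), unclass(d2$identity))

  tr <- d1$truth
  # role-swap pairs disjoint from the core set
  expect_length(intersect(c(names(tr$roleswap_map), tr$roleswap_map),
                          tr$core_set), 0)
  # every true edge joins nodes co-present in its section and above minocc
  for (sec in 1:2) {
    ed <- tr$true_edges[tr$true_edges$section == sec &
                          tr$true_edges$type == "otu-otu", ]
    otus <- tr$section_otus[[as.character(sec)]]
    expect_true(all(c(ed$node1, ed$node2) %in% otus))
    sl <- section_slice(d1$otu, sec, drop_absent = FALSE)
    occ <- rowSums(sl$counts > 0)
    expect_true(all(occ[unique(c(ed$node1, ed$node2))] >= 10))
  }
  # section symmetry of the planted design: swap partners mirror exclusives
  expect_true(all(names(tr$roleswap_map) %in% tr$section_otus[["1"]]))
  expect_true(all(tr$roleswap_map %in% tr$section_otus[["2"]]))
  expect_false(any(names(tr$roleswap_map) %in% tr$section_otus[["2"]]))
  # swap partners carry identical loadings but different taxonomy
  expect_equal(tr$loadings[names(tr$roleswap_map), ],
               tr$loadings[tr$roleswap_map, ], ignore_attr = TRUE)
  tax <- d1$otu$taxonomy
  expect_true(all(tax[names(tr$roleswap_map)] != tax[tr$roleswap_map]))
})

test_that("infeasible configurations are rejected", {
  expect_error(simulation_config(n_otus = 100, n_core = 80,
                                 n_roleswap_pairs = 20, seed = 1),
               "infeasible")
  expect_error(simulation_config(seed = 1, depth_range = c(500, 100)),
               "depth_range")
  expect_error(simulation_config(n_otus = 100), "seed")
})

test_that("abundances are log-normal dominated: top 50 OTUs hold 50-75%", {
  dat <- simulate_dataset(simulation_config(seed = 77))
  rel <- relative_abundance(dat$otu)
  top50 <- mean(apply(rel, 2, function(p) sum(sort(p, decreasing = TRUE)[1:50])))
  expect_gt(top50, 0.50)
  expect_lt(top50, 0.75)
})

test_that("sequence identities are taxonomy-stratified with unit diagonal", {
  dat <- sim_small()
  idm <- dat$identity
  expect_equal(unname(diag(idm)), rep(1, nrow(idm)))
  expect_true(all(idm >= 0.75 | idm == 1))
  tax <- dat$otu$taxonomy
  gen <- sub(".*g__", "", tax)
  phy <- sub(".*p__([^;]*);.*", "\\1", tax)
  ids <- rownames(idm)
  same_gen <- outer(gen[ids], gen[ids], "==") & outer(phy[ids], phy[ids], "==")
  off <- upper.tri(idm)
  expect_true(all(idm[off & same_gen] >= 0.97))
  expect_true(all(idm[off & !same_gen] < 0.95))
})

test_that("planted positive pairs co-vary across section samples", {
  hits <- vapply(1:20, function(sd) {
    dat <- simulate_dataset(simulation_config(n_otus = 80, seed = 600 + sd))
    ed <- subset(dat$truth$true_edges,
                 section == 1 & type == "otu-otu" & sign == "copresence")
    if (nrow(ed) == 0) return(NA)
    s1 <- section_slice(dat$otu, 1)
    r1 <- relative_abundance(s1)
    i <- sample(nrow(ed), 1)
    cor(r1[ed$node1[i], ], r1[ed$node2[i], ], method = "spearman") > 0
  }, logical(1))
  expect_gte(mean(hits, na.rm = TRUE), 0.95)
})

test_that("function labels encode the core nitrogen-fixation enrichment", {
  dat <- sim_small(n_otus = 150, seed = 41)
  lab <- dat$labels
  nf <- names(lab)[vapply(lab, function(l) "nitrogen_fixation" %in% l,
                          logical(1))]
  core <- dat$truth$core_set
  noncore <- setdiff(rownames(dat$otu$counts), core)
  expect_gt(mean(core %in% nf), mean(noncore %in% nf))
  # core/noncore nitrogen-fixation shares bracket the whole community's
  prof <- function(set, sites) {
    p <- function_profile(set, dat$otu, lab, sites = sites)
    p$mean[p$category == "nitrogen_fixation"]
  }
  all_ids <- rownames(dat$otu$counts)
  whole <- prof(all_ids, 1:8)
  core_share <- prof(core, 1:8)
  noncore_share <- prof(noncore, 1:8)
  expect_gte(whole, min(core_share, noncore_share))
  expect_lte(whole, max(core_share, noncore_share))

  # enrichment 1 -> core and noncore label rates statistically comparable
  d0 <- simulate_dataset(simulation_config(n_otus = 300, seed = 42,
                                           nfix_enrichment = 1,
                                           nfix_base = 0.1))
  nf0 <- names(d0$labels)[vapply(d0$labels, function(l)
    "nitrogen_fixation" %in% l, logical(1))]
  core0 <- d0$truth$core_set
  tt <- prop.test(c(sum(core0 %in% nf0), sum(!rownames(d0$otu$counts) %in% core0 &
                                               rownames(d0$otu$counts) %in% nf0)),
                  c(length(core0), nrow(d0$otu$counts) - length(core0)))
  expect_gt(tt$p.value, 0.01)
})

test_that("simulate_dataset writes a complete, re-loadable artifact set", {
  td <- withr::local_tempdir()
  dat <- simulate_dataset(simulation_config(n_otus = 60, seed = 8),
                          out_dir = td)
  expect_true(all(file.exists(file.path(td,
    c("otu_table.tsv", "sample_meta.tsv", "abiotic.tsv", "identity.tsv",
      "rules.tsv", "truth.json")))))
  back <- read_otu_table(file.path(td, "otu_table.tsv"),
                         meta_path = file.path(td, "sample_meta.tsv"))
  expect_equal(back$counts, dat$otu$counts)
})
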