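test_that("replicate-consistency filter keeps OTUs present in >= min_reps at a site", {
  t <- toy_otu()
  # OTU2 present in 2/3 replicates at site 2 only -> kept at default
  f <- filter_replicate_consistency(t)
  expect_setequal(rownames(f$counts), c("OTU1", "OTU2", "OTU3"))
  # OTU present once per site -> dropped
  counts <- t$counts
  counts["OTU2", ] <- c(1, 0, 0, 1, 0, 0)
  t2 <- otu_table(counts, sample_meta = t$sample_meta)
  expect_false("OTU2" %in% rownames(filter_replicate_consistency(t2)$counts))
  # min_reps = 1 keeps everything with any nonzero count
  counts["OTU2", ] <- 0
  t3 <- otu_table(counts, sample_meta = t$sample_meta)
  f3 <- filter_replicate_consistency(t3, min_reps = 1)
  expect_setequal(rownames(f3$counts), c("OTU1", "OTU3"))
  # too few replicates at a site errors
  t4 <- subset_otu_table(t, samples = c("S1", "S4", "S5", "S6"))
  expect_error(filter_replicate_consistency(t4, 2), "fewer")
  # idempotence and sample-order invariance
  expect_equal(filter_replicate_consistency(f)$counts, f$counts)
  perm <- subset_otu_table(t, samples = rev(colnames(t$counts)))
  fp <- filter_replicate_consistency(perm)
  expect_setequal(rownames(fp$counts), rownames(f$counts))
})

test_that("occurrence filter applies the 5-sample boundary exactly", {
  counts <- rbind(four = c(1, 1, 1, 1, 0, 0),
                  five = c(1, 1, 1, 1, 1, 0))
  colnames(counts) <- paste0("S", 1:6)
  t <- otu_table(counts)
  kept <- rownames(filter_min_samples(t, 5)$counts)
  expect_equal(kept, "five")
  expect_setequal(rownames(filter_min_samples(t, 0)$counts),
                  rownames(counts))
})

test_that("relative abundance columns sum to one and are scale invariant", {
  t <- toy_otu()
  rel <- relative_abundance(t)
  expect_equal(unname(colSums(rel)), rep(1, 6), tolerance = 1e-12)
  expect_equal(relative_abundance(t$counts * 10), rel)
  z <- t$counts; z[, 2] <- 0
  expect_error(relative_abundance(otu_table(z)), "S2")
  expect_equal(unname(relative_abundance(matrix(c(2, 2), 2, 1,
    dimnames = list(c("a", "b"), "s")))[, 1]), c(0.5, 0.5))
})

test_that("shannon index matches closed forms in bits", {
  expect_equal(shannon(c(5, 5, 5, 5)), 2)
  expect_equal(shannon(c(7, 0, 0)), 0)
  expect_equal(shannon(c(1, 1, 2)), 1.5)
  expect_equal(shannon(c(1, 1), base = exp(1)), log(2))
  expect_error(shannon(c(0, 0)), "total")
})

test_that("faith PD spans present tips and the root", {
  tree <- ape::read.tree(text = "((A:1,B:1):2,C:3);")
  expect_equal(faith_pd(tree, c("A", "B")), 4)
  expect_equal(faith_pd(tree, c("A", "B", "C")), 7)
  expect_equal(faith_pd(tree, character()), 0)
  expect_equal(faith_pd(tree, "C"), 3)
  expect_error(faith_pd(tree, "Z"), "Z")
  # oracle: manual union of root-to-tip edge paths on a random tree
  set.seed(2)
  rt <- ape::rtree(12)
  tips <- sample(rt$tip.label, 5)
  parent <- integer(max(rt$edge)); elen <- numeric(max(rt$edge))
  parent[rt$edge[, 2]] <- rt$edge[, 1]
  elen[rt$edge[, 2]] <- rt$edge.length
  used <- logical(max(rt$edge))
  root <- length(rt$tip.label) + 1L
  for (tp in match(tips, rt$tip.label)) {
    v <- tp
    while (v != root && !used[v]) { used[v] <- TRUE; v <- parent[v] }
  }
  expect_equal(faith_pd(rt, tips), sum(elen[used]))
})

test_that("rarefaction follows the subsampling schedule", {
  dat <- sim_small()
  rar <- rarefaction(dat$otu, max_depth = 3900, step = 389, iters = 4,
                     seed = 3)
  expect_equal(rar$depths, c(seq(389, 3890, by = 389), 3900))
  expect_true(all(colSums(dat$otu$counts)[rownames(rar$mean)] >= 3900))
  # full-depth subsample of a sample equals its observed richness
  tot <- colSums(dat$otu$counts)
  s <- names(tot)[which.min(tot)]
  one <- subset_otu_table(dat$otu, samples = s)
  r1 <- rarefaction(one, max_depth = tot[s], step = tot[s], iters = 3, seed = 1)
  expect_equal(unname(r1$mean[s, ncol(r1$mean)]), sum(one$counts > 0))
  expect_equal(unname(r1$sd[s, ncol(r1$sd)]), 0)
  # mean richness rises with depth (monotone up to subsampling noise)
  trend <- apply(rar$mean, 1, function(r) cor(rar$depths, r, method = "spearman"))
  expect_true(all(trend > 0.7))
  expect_true(all(rar$mean[, ncol(rar$mean)] >= rar$mean[, 1]))
  # single-OTU sample has richness 1 at every depth
  single <- otu_table(matrix(1000, 1, 1, dimnames = list("A", "S")))
  rs <- rarefaction(single, max_depth = 1000, step = 250, iters = 2, seed = 1)
  expect_true(all(rs$mean == 1))
})

test_that("environment correlation flags undefined cases and hits the closed forms", {
  expect_equal(env_correlation(1:8, (1:8)^2)$rho, 1)
  expect_equal(env_correlation(1:8, 8:1)$rho, -1)
  const <- env_correlation(rep(2, 8), rnorm(8))
  expect_false(const$defined)
  expect_true(is.na(const$rho))
  expect_error(env_correlation(1:3, 1:3), "at least 4")
  # null calibration: |rho| significant at ~5% under exchangeability
  set.seed(9)
  rej <- mean(replicate(400, env_correlation(rnorm(12), rnorm(12))$p < 0.05))
  expect_gt(rej, 0.02)
  expect_lt(rej, 0.09)
})
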