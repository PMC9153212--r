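# The synthetic-cohort generator: determinism, forward-model correctness,
# contamination and BAF observations.

test_that("configuration invariants are enforced", {
  expect_error(sim_config(n_clusters = 0L), class = "mc_invalid_config")
  expect_error(sim_config(base_error_rate = 1.2), class = "mc_invalid_config")
  expect_error(sim_config(contamination_fractions = c(0, 1)), class = "mc_invalid_config")
  expect_error(sim_config(contamination_fractions = 0.1), class = "mc_invalid_config")  # wrong length
  expect_error(sim_config(cnv_events = list(list(branch = 9L, chrom = "chr1",
                                                 major_cn = 2L, minor_cn = 1L))),
               class = "mc_invalid_config")
  expect_error(sim_config(mutations_per_cluster = c(5L, 2L)), class = "mc_invalid_config")
})

test_that("truth generation is deterministic and degenerates gracefully", {
  cfg <- sim_config(n_clusters = 5L, seed = 17L)
  t1 <- simulate_truth(cfg)
  t2 <- simulate_truth(cfg)
  expect_identical(serialize(t1, NULL), serialize(t2, NULL))

  # single cluster: trunk only, everything truncal
  cfg1 <- sim_config(n_clusters = 1L, min_ccf_separation = 0, seed = 2L)
  tr <- simulate_truth(cfg1)
  expect_length(tr$tree$parent, 1L)
  expect_true(all(tr$variants$cluster == "N1"))
  expect_equal(unname(tr$node_ccf["N1", ]), rep(1, cfg1$n_regions))
})

test_that("a convergent driver is planted on two distinct branches", {
  cfg <- sim_config(n_clusters = 5L, convergent_driver = "PIK3CA", seed = 19L)
  truth <- simulate_truth(cfg)
  hits <- truth$variants[truth$variants$gene == "PIK3CA", ]
  expect_gte(nrow(hits), 2L)
  expect_gte(length(unique(hits$cluster)), 2L)
  expect_false("N1" %in% hits$cluster)
  expect_identical(anyDuplicated(hits$pos), 0L)
})

test_that("truth compositions conserve mass and CCFs never increase downward", {
  cfg <- sim_config(seed = 23L)
  truth <- simulate_truth(cfg)
  expect_equal(unname(colSums(truth$compositions)), rep(1, cfg$n_regions),
               tolerance = 1e-12)
  for (nd in names(truth$tree$parent)) {
    p <- truth$tree$parent[[nd]]
    if (!is.na(p)) expect_true(all(truth$node_ccf[p, ] >= truth$node_ccf[nd, ] - 1e-12))
  }
})

test_that("read counts follow the CCF forward model", {
  # founder in a diploid context at purity 0.8: expected VAF 0.4
  cfg <- sim_config(n_clusters = 1L, n_regions = 1L, min_ccf_separation = 0,
                    base_error_rate = 0, seed = 29L)
  truth <- simulate_truth(cfg)
  truth$purities[] <- 0.8
  alts <- numeric(200)
  depths <- numeric(200)
  for (r in 1:200) {
    rc <- simulate_read_counts(truth, cfg, seed = r)
    alts[r] <- sum(rc$alt)
    depths[r] <- sum(rc$alt + rc$ref)
  }
  expect_equal(sum(alts) / sum(depths), 0.4, tolerance = 0.005)
})

test_that("absent variants yield only error-driven reads", {
  cfg <- sim_config(n_clusters = 2L, n_regions = 2L, p_multi_lineage = 0,
                    min_ccf_separation = 0, base_error_rate = 0, seed = 31L)
  truth <- simulate_truth(cfg)
  # force the subclone absent everywhere
  truth$compositions["N2", ] <- 0
  truth$compositions["N1", ] <- 1
  truth$node_ccf["N2", ] <- 0
  rc <- simulate_read_counts(truth, cfg, seed = 5L)
  sub <- truth$variants$variant_id[truth$variants$cluster == "N2"]
  expect_true(all(rc$alt[sub, ] == 0))

  # with e = 1e-3 and depth 2500, absent sites average ~2.5 mutant reads
  cfg2 <- sim_config(n_clusters = 2L, n_regions = 2L, p_multi_lineage = 0,
                     min_ccf_separation = 0, base_error_rate = 1e-3, seed = 31L)
  tot <- 0; nobs <- 0
  for (r in 1:50) {
    rc2 <- simulate_read_counts(truth, cfg2, seed = 1000 + r)
    tot <- tot + sum(rc2$alt[sub, ])
    nobs <- nobs + length(sub) * 2
  }
  expect_equal(tot / nobs, 2.5, tolerance = 0.15)
})

test_that("empirical VAF converges to the model expectation at high depth", {
  cfg <- sim_config(n_clusters = 4L, base_error_rate = 0, seed = 37L)
  truth <- simulate_truth(cfg)
  v_exp <- multiclone:::sim_expected_vaf(truth, truth$compositions, truth$purities)
  rc <- simulate_read_counts(truth, cfg, seed = 38L, depth_mean = 1e6)
  v_obs <- vaf_matrix(rc)
  expect_lt(mean(abs(v_obs - v_exp)), 1e-3)
  expect_lt(max(abs(v_obs - v_exp)), 5e-3)  # extreme over ~500 cells
})

test_that("BAF segments reproduce composite copy and folded deviation", {
  # bi-allelic duplication at CP 0.6: AI-invisible but c = 3.2
  cfg <- sim_config(n_clusters = 1L, n_regions = 1L, min_ccf_separation = 0,
                    snps_per_segment = 4000L, baf_noise_sd = 1e-4, c_noise_sd = 1e-6,
                    cnv_events = list(list(branch = 1L, chrom = "chr4",
                                           major_cn = 2L, minor_cn = 2L)),
                    seed = 41L)
  truth <- simulate_truth(cfg)
  truth$purities[] <- 0.6
  segs <- simulate_baf_segments(truth, cfg, seed = 42L)
  expect_equal(segs$c, 3.2, tolerance = 1e-4)
  expect_lt(segs$folded_baf_dev, 0.005)

  # pure one-copy loss: unfolded BAF in {0, 1}, folded deviation 0.5
  cfg2 <- sim_config(n_clusters = 1L, n_regions = 1L, min_ccf_separation = 0,
                     snps_per_segment = 500L, baf_noise_sd = 1e-6, c_noise_sd = 1e-6,
                     cnv_events = list(list(branch = 1L, chrom = "chr17",
                                            major_cn = 1L, minor_cn = 0L)),
                     seed = 43L)
  truth2 <- simulate_truth(cfg2)
  truth2$purities[] <- 1
  segs2 <- simulate_baf_segments(truth2, cfg2, seed = 44L)
  expect_equal(segs2$folded_baf_dev, 0.5, tolerance = 1e-4)

  # absent segment: folded deviation at the noise floor only
  truth2$purities[] <- 0
  segs3 <- simulate_baf_segments(truth2, cfg2, seed = 45L)
  expect_lt(segs3$folded_baf_dev, 0.001)
})

test_that("contaminated normals mix the configured clone subset", {
  cfg <- sim_config(n_clusters = 4L, n_normals = 3L,
                    contamination_fractions = c(0, 0.02, 0.12),
                    base_error_rate = 0, seed = 47L)
  truth <- simulate_truth(cfg)
  # configure the subsets by hand: pure; trunk only; trunk + one subclone
  sub <- setdiff(names(truth$tree$parent), "N1")[1L]
  truth$normal_support <- list(G1 = "N1", G2 = "N1", G3 = c("N1", sub))
  rc <- simulate_contaminated_normals(truth, cfg, seed = 48L)

  expect_true(all(rc$alt[, "G1"] == 0))  # phi = 0, e = 0

  # phi = 0.02 trunk-only: founder VAF ~ 0.01
  founder_rows <- truth$variants$variant_id[truth$variants$cluster == "N1"]
  v <- sum(rc$alt[founder_rows, "G2"]) / sum((rc$alt + rc$ref)[founder_rows, "G2"])
  expect_lt(abs(v - 0.01), 0.002)

  # subset contract: only clusters carried by the contaminating clones
  # (the subclone and its ancestors, including the trunk) show signal
  on_nodes <- c("N1", sub, tree_ancestors(truth$tree, sub))
  carried <- unique(truth$variants$cluster[rc$alt[, "G3"] > 0])
  expect_true(all(carried %in% on_nodes))
  off <- truth$variants$variant_id[!truth$variants$cluster %in% on_nodes]
  if (length(off)) expect_true(all(rc$alt[off, "G3"] == 0))
})

test_that("the full cohort simulation is reproducible end to end", {
  cfg <- sim_config(n_clusters = 4L, seed = 53L,
                    cnv_events = list(list(branch = 1L, chrom = "chr14",
                                           major_cn = 1L, minor_cn = 0L)))
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(serialize(c1, NULL), serialize(c2, NULL))
  expect_identical(c1$counts$samples,
                   c(c1$tumor_counts$samples, c1$normal_counts$samples))
  expect_identical(nrow(c1$meta), length(c1$counts$samples))
})
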