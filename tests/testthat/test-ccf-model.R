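# The purity/copy-number/multiplicity algebra and copy-model enumeration.

test_that("composite copy number matches hand-evaluated mixtures", {
  expect_equal(composite_copy(0.3, 0, 5), 2)      # no CNV-bearing cells
  expect_equal(composite_copy(1, 1, 3), 3)        # pure clonal gain
  expect_equal(composite_copy(0.6, 1, 3), 2.6)
  expect_equal(composite_copy(0.8, 0.5, 0), 1.2)  # subclonal homozygous loss
})

test_that("cnv_ccf inverts composite_copy and rejects infeasible states", {
  expect_equal(cnv_ccf(2, 3, 0.8), 0)
  expect_equal(cnv_ccf(2.6, 3, 0.6), 1)
  expect_error(cnv_ccf(2.9, 3, 0.6), class = "mc_model_infeasible")  # f = 1.5
  expect_error(cnv_ccf(2.5, 2, 0.8), class = "mc_undefined_state")   # CN-LOH
  expect_error(cnv_ccf(2.5, 3, 0), class = "mc_no_tumor")
})

test_that("expected VAF follows v = t f g n / c", {
  expect_equal(expected_vaf(0.8, 1, 1, 1, 2), 0.4)
  expect_equal(expected_vaf(0.8, 1, 0, 1, 2), 0)
  expect_equal(expected_vaf(0.6, 1, 1, 2, 2.6), 0.46154, tolerance = 1e-4)
  expect_error(expected_vaf(0.8, 1, 1, 1, 0), class = "mc_invalid_input")
})

test_that("mutation_g inverts the VAF model and enforces g in [0, 1]", {
  expect_equal(mutation_g(0.1, 2, 0.8, 0.5, 1), 0.5)
  expect_error(mutation_g(0.45, 2, 0.8, 0.5, 1), class = "mc_model_infeasible")  # g = 2.25
  expect_error(mutation_g(0.1, 2, 0.8, 0, 1), class = "mc_degenerate_model")
})

test_that("mutation CCF is g * f and bounded by both factors", {
  expect_equal(mutation_ccf(1, 1), 1)
  expect_equal(mutation_ccf(0.5, 0.5), 0.25)
  set.seed(41)
  g <- runif(200); f <- runif(200)
  expect_true(all(mutation_ccf(g, f) <= pmin(g, f) + 1e-12))
})

test_that("expected_vaf is strictly monotone in each parameter", {
  set.seed(42)
  for (rep in 1:50) {
    t <- runif(1, 0.2, 0.9); f <- runif(1, 0.2, 0.9); g <- runif(1, 0.2, 0.9)
    n <- sample(1:3, 1); M <- sample(c(3, 4), 1)
    v0 <- expected_vaf(t, f, g, n, composite_copy(t, f, M))
    eps <- 0.05
    expect_gt(expected_vaf(t + eps, f, g, n, composite_copy(t + eps, f, M)), v0)
    expect_gt(expected_vaf(t, f + eps, g, n, composite_copy(t, f + eps, M)), v0)
    expect_gt(expected_vaf(t, f, g + eps, n, composite_copy(t, f, M)), v0)
    expect_gt(expected_vaf(t, f, g, n + 1, composite_copy(t, f, M)), v0)
  }
})

make_single_variant_counts <- function(alt, depth, samples = names(alt)) {
  variants <- data.frame(variant_id = "V1", chrom = "chr7", pos = 100L,
                         ref = "A", alt = "T", gene = NA, stringsAsFactors = FALSE)
  ref <- matrix(depth - alt, 1, dimnames = list("V1", samples))
  altm <- matrix(alt, 1, dimnames = list("V1", samples))
  read_counts(variants, ref, altm)
}

test_that("a diploid context admits exactly one copy model", {
  alt <- c(A1 = 1000, A2 = 800)
  counts <- make_single_variant_counts(alt, c(A1 = 2500, A2 = 2500))
  m <- enumerate_copy_models("V1", counts, c(A1 = 0.8, A2 = 0.8))
  expect_true(m$resolved)
  expect_identical(m$timing, "diploid_context")
  expect_identical(nrow(m$candidates), 1L)
})

test_that("the true multiplicity model ranks first on simulated (2,1) segments", {
  # oracle: forward-simulate a mutation predating a clonal 3-copy gain
  # (n = 2 on the major haplotype) and check the enumeration ranks it first
  set.seed(7)
  wins <- 0L
  n_rep <- 300L
  samples <- paste0("A", 1:4)
  seg <- list(major_cn = 2L, minor_cn = 1L,
              per_sample = data.frame(sample = samples, c = NA_real_, f = 1))
  for (r in seq_len(n_rep)) {
    t <- rbeta(4, 8, 2)
    names(t) <- samples
    cc <- composite_copy(t, 1, 3)
    seg$per_sample$c <- cc
    # g and n enter the VAF only through their product, so a duplicated
    # mutation (n = 2) is distinguishable from (n = 1, 2g) only when
    # 2g > 1; simulate the clonal-duplication regime the cohort shows
    g_true <- runif(1, 0.6, 1)
    v <- t * 1 * g_true * 2 / cc
    depth <- rpois(4, 2500)
    alt <- rbinom(4, depth, v)
    counts <- make_single_variant_counts(stats::setNames(alt, samples),
                                         stats::setNames(depth, samples))
    m <- suppressWarnings(enumerate_copy_models("V1", counts, t, segment = seg))
    if (isTRUE(m$resolved) && m$n == 2L && m$timing == "before_cnv_on_major") wins <- wins + 1L
  }
  expect_gte(wins / n_rep, 0.95)
})

test_that("a focal mutant-allele amplicon is recognized from its VAF", {
  # the de facto mutant amplicon: observed v ~ t * f * 7 / c
  samples <- paste0("A", 1:3)
  t <- c(A1 = 0.8, A2 = 0.7, A3 = 0.85)
  f <- c(A1 = 0.4, A2 = 0.3, A3 = 0.2)
  cc <- composite_copy(t, f, 8)
  v <- t * f * 1 * 7 / cc
  depth <- rep(2500, 3)
  counts <- make_single_variant_counts(stats::setNames(round(v * depth), samples),
                                       stats::setNames(depth, samples))
  seg <- list(major_cn = 7L, minor_cn = 1L,
              per_sample = data.frame(sample = samples, c = cc, f = f))
  m <- suppressWarnings(enumerate_copy_models("V1", counts, t, segment = seg))
  expect_true(m$resolved)
  expect_identical(m$timing, "before_cnv_on_major")
  expect_identical(m$n, 7L)
})

test_that("feasibility rejection is symmetric between mutation_g and enumeration", {
  # v implying g = 2.25 under the only candidate model must be rejected by
  # both entry points
  samples <- c("A1", "A2")
  t <- c(A1 = 0.8, A2 = 0.8)
  counts <- make_single_variant_counts(c(A1 = 1125, A2 = 1125), c(A1 = 2500, A2 = 2500))
  seg <- list(major_cn = 1L, minor_cn = 1L,
              per_sample = data.frame(sample = samples, c = c(2, 2), f = c(0.5, 0.5)))
  expect_error(mutation_g(0.45, 2, 0.8, 0.5, 1), class = "mc_model_infeasible")
  m <- suppressWarnings(enumerate_copy_models("V1", counts, t, segment = seg))
  cand <- m$candidates
  expect_false(any(cand$feasible[cand$timing == "after_cnv"]))
})
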