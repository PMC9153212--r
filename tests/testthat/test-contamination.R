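# Tumor-in-normal detection: error model, tumor fraction, two-stage test.

panel_of <- function(alt_per_site, depth_per_site, n_sites = 3L, n_samples = 4L) {
  variants <- data.frame(variant_id = paste0("V", seq_len(n_sites)), chrom = "chr1",
                         pos = seq_len(n_sites), ref = "A", alt = "T", gene = NA,
                         stringsAsFactors = FALSE)
  samples <- paste0("PN", seq_len(n_samples))
  alt <- matrix(alt_per_site, n_sites, n_samples,
                dimnames = list(variants$variant_id, samples))
  ref <- matrix(depth_per_site, n_sites, n_samples,
                dimnames = list(variants$variant_id, samples)) - alt
  read_counts(variants, ref, alt)
}

test_that("the error model pools panel counts with a pseudocount and floor", {
  # zero alt reads at 10,000x per site over 1 panel sample: (0 + 0.5) / (10^4 + 1)
  panel <- panel_of(0, 10000, n_samples = 1L)
  em <- build_error_model(panel)
  expect_equal(unname(em$rate["V1"]), 0.5 / 10001)

  # a systematic artifact site keeps a high rate
  panel2 <- panel_of(0, 5000, n_samples = 1L)
  panel2$alt["V2", ] <- 50
  panel2$ref["V2", ] <- 4950
  em2 <- build_error_model(panel2)
  expect_equal(unname(em2$rate["V2"]), 50.5 / 5001, tolerance = 1e-9)

  # the floor applies when the pooled rate would drop below it
  panel3 <- panel_of(0, 1e6, n_samples = 4L)
  em3 <- build_error_model(panel3, floor = 1e-6)
  expect_equal(unname(em3$rate["V1"]), 1e-6)

  # empty panel falls back to the fixed floor with a warning
  expect_warning(em4 <- build_error_model(panel, exclude = panel$samples), "empty panel")
  expect_identical(em4$source, "fixed")
})

test_that("tumor fraction inverts the founder VAF", {
  counts <- panel_of(0, 2500, n_sites = 1L, n_samples = 1L)
  counts$alt["V1", ] <- 25L   # VAF 0.01
  counts$ref["V1", ] <- 2475L
  expect_equal(estimate_tumor_fraction(counts, "PN1", "V1")$fraction, 0.02)

  counts$alt["V1", ] <- 0L
  counts$ref["V1", ] <- 2500L
  expect_equal(estimate_tumor_fraction(counts, "PN1", "V1")$fraction, 0)

  # duplicated-founder model: v = 0.06, M = 3, n = 2 -> 2v / (2 - v)
  counts$alt["V1", ] <- 150L
  counts$ref["V1", ] <- 2350L
  est <- estimate_tumor_fraction(counts, "PN1", "V1", founder_model = c(M = 3L, n = 2L))
  expect_equal(est$fraction, 0.12 / 1.94, tolerance = 1e-9)

  # shallow founder coverage warns
  shallow <- panel_of(0, 50, n_sites = 1L, n_samples = 1L)
  expect_warning(estimate_tumor_fraction(shallow, "PN1", "V1"), "low-confidence")
})

test_that("the founder gate is decisive at 2% tumor fraction and deep coverage", {
  # oracle: exact binomial tail at n = 2500, rate 1e-3, 25 mutant reads
  expect_lt(pbinom(24, 2500, 1e-3, lower.tail = FALSE), 1e-10)

  set.seed(61)
  panel <- panel_of(0, 2500, n_sites = 2L, n_samples = 8L)
  panel$alt[] <- rbinom(length(panel$alt), 2500, 1e-3)
  panel$ref[] <- 2500 - panel$alt
  em <- build_error_model(panel)
  tested <- panel_of(0, 2500, n_sites = 2L, n_samples = 1L)
  tested$alt["V1", ] <- 25L
  tested$ref["V1", ] <- 2475L
  call <- test_presence(tested, "PN1", "V1", list(B = "V2"), em)
  expect_lt(call$founder_p, 1e-10)
  expect_equal(call$tumor_fraction, 0.02)
})

test_that("no cluster is ever called when the founder gate fails", {
  set.seed(62)
  n_sites <- 12L
  panel <- panel_of(0, 2500, n_sites = n_sites, n_samples = 8L)
  panel$alt[] <- rbinom(length(panel$alt), 2500, 1e-3)
  panel$ref[] <- 2500 - panel$alt
  em <- build_error_model(panel)
  tested <- panel_of(0, 2500, n_sites = n_sites, n_samples = 1L)
  # plant a blazing cluster signal but keep the founder clean
  tested$alt[paste0("V", 2:6), ] <- 100
  clusters <- list(B = paste0("V", 2:6), C = paste0("V", 7:12))
  call <- test_presence(tested, "PN1", "V1", clusters, em)
  expect_equal(call$tumor_fraction, 0)
  expect_identical(nrow(call$clusters), 0L)
})

test_that("present clusters are called and siblings are not", {
  set.seed(63)
  n_sites <- 13L
  phi <- 0.12
  panel <- panel_of(0, 2500, n_sites = n_sites, n_samples = 8L)
  panel$alt[] <- rbinom(length(panel$alt), 2500, 1e-3)
  panel$ref[] <- 2500 - panel$alt
  em <- build_error_model(panel)
  tested <- panel_of(0, 2500, n_sites = n_sites, n_samples = 1L)
  # V1 founder + cluster B present at CCF 1 within the contamination
  present <- c("V1", paste0("V", 2:6))
  tested$alt[present, ] <- rbinom(length(present), 2500, phi / 2 * (1 - 1e-3) + 1e-3)
  tested$alt[paste0("V", 7:13), ] <- rbinom(7, 2500, 1e-3)
  tested$ref[] <- 2500 - tested$alt
  clusters <- list(B = paste0("V", 2:6), C = paste0("V", 7:13))
  call <- test_presence(tested, "PN1", "V1", clusters, em)
  expect_lt(abs(call$tumor_fraction - phi), 0.03)
  tab <- call$clusters
  expect_true(tab$present[tab$cluster_id == "B"])
  expect_false(tab$present[tab$cluster_id == "C"])
  expect_equal(tab$ccf[tab$cluster_id == "B"], 1, tolerance = 0.15)
})

test_that("increasing tumor fraction never decreases the expected founder signal", {
  # monotonicity of the forward model feeding the gate statistic
  depths <- 2500
  phis <- seq(0, 0.3, by = 0.05)
  means <- depths * (phis / 2 * (1 - 1e-3) + (1 - phis / 2) * 1e-3)
  expect_true(all(diff(means) > 0))
})
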