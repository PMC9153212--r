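# Region decomposition, CNV placement, variant classification and lineage
# statistics.

test_that("founder filling reproduces the documented decomposition", {
  tr <- clone_tree(c(T = NA, X = "T", Y = "T"))
  ccf <- matrix(c(1, 0.6, 0.3), 3, 1, dimnames = list(c("T", "X", "Y"), "A1"))
  comp <- decompose_regions(tr, ccf, c(A1 = 0.8))
  frac <- stats::setNames(comp$fraction, comp$node)
  expect_equal(frac[["X"]], 0.6)
  expect_equal(frac[["Y"]], 0.3)
  expect_equal(frac[["T"]], 0.1)
  expect_equal(sum(frac), 1)
})

test_that("a sample with only the truncal cluster is pure founder clone", {
  tr <- clone_tree(c(T = NA, X = "T"))
  ccf <- matrix(c(1, 0), 2, 1, dimnames = list(c("T", "X"), "A1"))
  comp <- decompose_regions(tr, ccf, c(A1 = 0.9))
  expect_equal(comp$fraction[comp$node == "T"], 1)
})

test_that("decomposition flags low-purity and multi-lineage regions", {
  tr <- clone_tree(c(T = NA, X = "T", Y = "T"))
  ccf <- matrix(c(1, 1, 0.6, 0.9, 0.3, 0.02), nrow = 3, byrow = TRUE,
                dimnames = list(c("T", "X", "Y"), c("A1", "A2")))
  comp <- decompose_regions(tr, ccf, c(A1 = 0.8, A2 = 0.04))
  expect_true(all(comp$inferred_only[comp$sample_id == "A2"]))
  expect_false(any(comp$inferred_only[comp$sample_id == "A1"]))
  expect_true(all(comp$multi_lineage[comp$sample_id == "A1"]))   # X 0.6 and Y 0.3
  expect_false(any(comp$multi_lineage[comp$sample_id == "A2"]))  # Y at 0.02 < 0.05
})

test_that("children exceeding a parent beyond tolerance is an inconsistency", {
  tr <- clone_tree(c(T = NA, X = "T", Y = "X"))
  ccf <- matrix(c(1, 0.5, 0.7), 3, 1, dimnames = list(c("T", "X", "Y"), "A1"))
  expect_error(decompose_regions(tr, ccf, c(A1 = 0.8)), class = "mc_inconsistency")
})

test_that("compositions always sum to one", {
  set.seed(12)
  for (r in 1:20) {
    cfg <- sim_config(n_clusters = sample(2:6, 1), seed = sample.int(1e6, 1))
    truth <- suppressWarnings(simulate_truth(cfg))
    comp <- decompose_regions(truth$tree, truth$node_ccf, truth$purities, tol = 1e-9)
    sums <- tapply(comp$fraction, comp$sample_id, sum)
    expect_equal(as.numeric(sums), rep(1, length(sums)), tolerance = 1e-9)
  }
})

test_that("variant classes follow the presence pattern over usable samples", {
  variants <- data.frame(variant_id = paste0("V", 1:3), chrom = "chr1",
                         pos = 1:3, ref = "A", alt = "T", gene = NA,
                         stringsAsFactors = FALSE)
  samples <- c("A1", "A2", "A3")
  alt <- rbind(c(900, 850, 870),   # truncal
               c(400, 350, 0),     # shared
               c(0, 0, 200))       # private
  ref <- 2500 - alt
  dimnames(alt) <- dimnames(ref) <- list(variants$variant_id, samples)
  counts <- read_counts(variants, ref, alt)
  cls <- classify_variants(counts, c(A1 = 0.7, A2 = 0.7, A3 = 0.7))
  expect_identical(unname(cls$class), c("truncal", "shared", "private"))
  expect_equal(cls$summary$count[cls$summary$class == "shared"], 1L)

  # fewer than two usable samples is undefined
  expect_error(classify_variants(counts, c(A1 = 0.7, A2 = 0.01, A3 = 0.01)),
               class = "mc_classification_undefined")
})

test_that("lineage statistics measure molecular age and average CCF", {
  tr <- clone_tree(c(T = NA, L1 = "T", L2 = "T", D = "L2"),
                   branch_mutation_count = c(T = 11, L1 = 30, L2 = 10, D = 25))
  ccf <- matrix(c(1, 1, 0.9, 0.6, 0.05, 0.3, 0.02, 0.1), nrow = 4, byrow = TRUE,
                dimnames = list(c("T", "L1", "L2", "D"), c("A1", "A2")))
  pur <- c(A1 = 0.8, A2 = 0.8)
  comp <- decompose_regions(tr, ccf, pur)
  st <- lineage_stats(tr, comp, pur)
  st <- st[order(st$lineage_id), ]
  # single-cluster lineage of 30 mutations: age 30
  expect_equal(st$molecular_age[st$lineage_id == "L1"], 30)
  # deepest path through D: 10 + 25
  expect_equal(st$molecular_age[st$lineage_id == "L2"], 35)
  # average CCF = mean over regions of the lineage's summed clone fractions
  expect_equal(st$average_ccf[st$lineage_id == "L1"], mean(c(0.9, 0.6)), tolerance = 1e-9)
  expect_equal(st$average_ccf[st$lineage_id == "L2"], mean(c(0.05, 0.3)), tolerance = 1e-9)

  # two-region lineage CCFs (0.9, 0.6) average 0.75
  expect_equal(st$average_ccf[st$lineage_id == "L1"], 0.75)
  # correlation undefined below three lineages
  expect_true(is.na(lineage_age_ccf_cor(st)$r))
})

test_that("CNV events land on the node matching their CP profile", {
  samples <- c("A1", "A2", "A3")
  pur <- c(A1 = 0.8, A2 = 0.7, A3 = 0.75)
  ccf <- matrix(c(1, 1, 1, 0.7, 0.2, 0.5, 0.1, 0.6, 0.3), nrow = 3, byrow = TRUE,
                dimnames = list(c("C1", "C2", "C3"), samples))
  tr <- clone_tree(c(C1 = NA, C2 = "C1", C3 = "C1"))
  attr(tr, "ccf") <- ccf
  mk_seg <- function(id, chrom, cp) {
    data.frame(segment_id = id, sample = samples, chrom = chrom, start = 1L,
               end = 100L, major_cn = 2L, minor_cn = 1L, c = 2 + cp, ai = NA,
               cp = cp, f = cp / pur, stringsAsFactors = FALSE)
  }
  segs <- rbind(mk_seg("chr10:1-100", "chr10", pur * 1),          # truncal
                mk_seg("chr17:1-100", "chr17", pur * ccf["C2", ]))  # on C2
  tr <- place_cnv_events(tr, segs, pur)
  ev <- tr$cnv_events
  expect_identical(ev$node[ev$chrom == "chr10"], "C1")
  expect_identical(ev$node[ev$chrom == "chr17"], "C2")
})
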