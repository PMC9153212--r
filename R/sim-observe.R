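# Observation layer of the simulator: read counts from the CCF forward
# model, het-SNP BAF segment summaries, and contaminated normal samples.

# Expected VAF matrix (variants x samples) for an arbitrary set of samples
# described by clone-fraction columns `comp` (nodes x samples) and cell
# purities `t`. For each variant, v = t * sum_k frac_k * mult_k / c with
# mult_k the mutant-allele multiplicity in clone k and c the composite copy
# number of the covering segment in that sample (2 when diploid).
sim_expected_vaf <- function(truth, comp, t) {
  tree <- truth$tree
  nodes <- rownames(comp)
  samples <- colnames(comp)
  subtree_of <- lapply(stats::setNames(nm = nodes), function(n) tree_subtree(tree, n))
  # CNV node CCF per sample and composite copy per (cnv, sample)
  cnv <- truth$cnv_events
  cnv_f <- cnv_c <- NULL
  if (nrow(cnv)) {
    cnv_f <- t(vapply(cnv$node, function(n) colSums(comp[subtree_of[[n]], , drop = FALSE]),
                      numeric(length(samples))))
    if (length(samples) == 1L) cnv_f <- matrix(cnv_f, ncol = 1L)
    rownames(cnv_f) <- cnv$cnv_id
    colnames(cnv_f) <- samples
    M <- cnv$major_cn + cnv$minor_cn
    cnv_c <- 2 + sweep(cnv_f, 1L, M - 2, `*`) * rep(t[samples], each = nrow(cnv))
    dimnames(cnv_c) <- dimnames(cnv_f)
  }
  cm <- truth$copy_models
  if (!all(truth$variants$variant_id %in% cm$variant_id)) {
    mc_stop("variant without a copy model in the simulation truth", "mc_inconsistent_truth")
  }
  v <- matrix(0, nrow(truth$variants), length(samples),
              dimnames = list(truth$variants$variant_id, samples))
  for (i in seq_len(nrow(truth$variants))) {
    b_m <- truth$variants$cluster[i]
    carriers <- subtree_of[[b_m]]
    mi <- cm[cm$variant_id == truth$variants$variant_id[i], ]
    mult <- stats::setNames(rep(1, length(carriers)), carriers)
    cc <- rep(2, length(samples))
    if (!is.na(mi$cnv_id)) {
      j <- match(mi$cnv_id, cnv$cnv_id)
      in_cnv <- carriers %in% subtree_of[[cnv$node[j]]]
      if (startsWith(mi$timing, "before")) mult[in_cnv] <- mi$n
      cc <- cnv_c[mi$cnv_id, ]
    }
    num <- as.vector(mult %*% comp[carriers, samples, drop = FALSE])
    v[i, ] <- t[samples] * num / cc
  }
  v
}

#' Simulate deep-sequencing read counts for the tumor regions
#'
#' For each variant and region the expected VAF comes from the CCF forward
#' model (truth clone fractions, purity and copy model); the sequenced depth
#' is Poisson around the configured mean (floored at 1) and the mutant read
#' count is Binomial with success probability `v (1 - e) + (1 - v) e`,
#' mixing in the symmetric per-read error rate `e`. Deterministic given
#' `(truth, config, seed)`.
#'
#' @param truth a `"sim_truth"`.
#' @param config the [sim_config()] used to build it.
#' @param seed integer seed.
#' @param depth_mean mean depth (default the deep tier,
#'   `config$deep_depth`; pass `config$wes_depth` for the exome-like tier).
#' @return a [read_counts] object over the tumor regions.
#' @export
simulate_read_counts <- function(truth, config, seed = config$seed,
                                 depth_mean = config$deep_depth) {
  stopifnot(inherits(truth, "sim_truth"))
  with_seed(seed, {
    v <- sim_expected_vaf(truth, truth$compositions, truth$purities)
    sim_counts_from_vaf(v, depth_mean, config$base_error_rate, truth$variants)
  })
}

sim_counts_from_vaf <- function(v, depth_mean, error_rate, variants) {
  n <- length(v)
  depth <- matrix(pmax(1L, stats::rpois(n, depth_mean)), nrow(v), ncol(v))
  p <- v * (1 - error_rate) + (1 - v) * error_rate
  alt <- matrix(stats::rbinom(n, as.vector(depth), as.vector(p)), nrow(v), ncol(v))
  dimnames(alt) <- dimnames(depth) <- dimnames(v)
  read_counts(variants = variants, ref = depth - alt, alt = alt)
}

#' Simulate het-SNP BAF segment observations
#'
#' For each CNV segment and tumor region, draws `snps_per_segment` germline
#' heterozygous SNP BAFs. Each SNP's B allele lands on the major or minor
#' haplotype with equal probability (array data are unphased), the mean BAF
#' follows the mixture of normal cells and CNV-bearing cells at the
#' segment's cellular prevalence `CP = t * f`, and Gaussian noise
#' (`baf_noise_sd`) is added and truncated to `[0, 1]`. The emitted summary
#' per (segment, sample) is the mean folded deviation `|BAF - 0.5|`, the
#' noisy composite copy number and the SNP count.
#'
#' @param truth a `"sim_truth"`.
#' @param config the [sim_config()] used to build it.
#' @param seed integer seed.
#' @return data frame with columns `sample`, `chrom`, `start`, `end`, `c`,
#'   `folded_baf_dev`, `n_snps` (empty when the truth has no CNV events).
#' @export
simulate_baf_segments <- function(truth, config, seed = config$seed) {
  stopifnot(inherits(truth, "sim_truth"))
  cnv <- truth$cnv_events
  samples <- colnames(truth$compositions)
  if (!nrow(cnv)) {
    return(data.frame(sample = character(), chrom = character(), start = integer(),
                      end = integer(), c = numeric(), folded_baf_dev = numeric(),
                      n_snps = integer(), stringsAsFactors = FALSE))
  }
  with_seed(seed, {
    tree <- truth$tree
    rows <- list()
    for (j in seq_len(nrow(cnv))) {
      sub <- tree_subtree(tree, cnv$node[j])
      a <- cnv$major_cn[j]; b <- cnv$minor_cn[j]; M <- a + b
      for (s in samples) {
        f <- sum(truth$compositions[sub, s])
        cp <- truth$purities[[s]] * f
        c_true <- 2 + cp * (M - 2)
        on_major <- stats::runif(config$snps_per_segment) < 0.5
        b_copies <- ifelse(on_major, a, b)
        baf_mean <- ((1 - cp) * 1 + cp * b_copies) / c_true
        baf <- clamp(stats::rnorm(config$snps_per_segment, baf_mean, config$baf_noise_sd), 0, 1)
        rows[[length(rows) + 1L]] <- data.frame(
          sample = s, chrom = cnv$chrom[j], start = cnv$start[j], end = cnv$end[j],
          c = c_true + stats::rnorm(1L, 0, config$c_noise_sd),
          folded_baf_dev = mean(abs(baf - 0.5)),
          n_snps = config$snps_per_segment, stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Simulate contaminated (histologically normal) samples
#'
#' Each normal sample is a mixture of normal tissue and a tumor fraction
#' `phi` drawn from the configuration (`phi` may be 0). The tumor portion is
#' composed of a configured subset of clones — emulating the
#' lineage-specific trails left by invading subclones — with Dirichlet
#' fractions over the subset. Read counts are generated exactly as for
#' tumor regions with `phi` in the role of purity.
#'
#' @param truth a `"sim_truth"`.
#' @param config the [sim_config()] used to build it.
#' @param seed integer seed.
#' @param depth_mean mean depth.
#' @return a [read_counts] object over the normal samples.
#' @export
simulate_contaminated_normals <- function(truth, config, seed = config$seed,
                                          depth_mean = config$deep_depth) {
  stopifnot(inherits(truth, "sim_truth"))
  with_seed(seed, {
    nodes <- rownames(truth$compositions)
    normals <- names(truth$contamination)
    comp <- matrix(0, length(nodes), length(normals), dimnames = list(nodes, normals))
    for (g in normals) {
      sup <- truth$normal_support[[g]]
      comp[sup, g] <- rdirichlet1(rep(2, length(sup)))
    }
    v <- sim_expected_vaf(truth, comp, truth$contamination)
    rc <- sim_counts_from_vaf(v, depth_mean, config$base_error_rate, truth$variants)
    attr(rc, "normal_compositions") <- comp
    rc
  })
}

#' Simulate a complete cohort (truth plus all observations)
#'
#' Convenience wrapper tying the four generator stages together with
#' derived seeds, and building the sample metadata table.
#'
#' @param config a [sim_config()].
#' @param seed integer master seed (defaults to `config$seed`); stage seeds
#'   are derived from it.
#' @return list with `truth`, `tumor_counts`, `normal_counts`, `counts`
#'   (both combined), `segments`, `meta`.
#' @export
simulate_cohort <- function(config, seed = config$seed) {
  truth <- simulate_truth(config, seed = seed)
  tumor <- simulate_read_counts(truth, config, seed = seed + 1L)
  normal <- simulate_contaminated_normals(truth, config, seed = seed + 2L)
  segments <- simulate_baf_segments(truth, config, seed = seed + 3L)
  counts <- read_counts(variants = truth$variants,
                        ref = cbind(tumor$ref, normal$ref),
                        alt = cbind(tumor$alt, normal$alt))
  meta <- data.frame(
    sample_id = c(tumor$samples, normal$samples),
    patient_id = "P1",
    tissue_class = c(rep("tumor", length(tumor$samples)),
                     rep("normal", length(normal$samples))),
    region_label = c(tumor$samples, normal$samples),
    spatial_position = c(seq(0, 1 - 1e-9, length.out = length(tumor$samples)),
                         rep(NA_real_, length(normal$samples))),
    anatomical_site = c(rep("pons", length(tumor$samples)),
                        rep("extrapontine", length(normal$samples))),
    stringsAsFactors = FALSE
  )
  list(truth = truth, tumor_counts = tumor, normal_counts = normal,
       counts = counts, segments = segments, meta = meta)
}
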