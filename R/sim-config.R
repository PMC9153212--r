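# Configuration for the synthetic multi-region cohort generator. Defaults
# emulate a diffuse-midline-glioma-like autopsy cohort: one truncal founder
# SNV present in every tumor cell, a handful of mutation clusters arranged
# on a tree, 3-7 deeply sequenced tumor regions with admixed lineages in
# about half of them, purities centered near 0.8, ~2500X deep coverage, and
# histologically normal samples carrying 0-12% tumor contamination.

#' Simulation configuration
#'
#' @param n_regions number of tumor regions (cohort range 3-7).
#' @param n_normals number of histologically normal samples.
#' @param n_clusters number of mutation clusters (tree nodes; cohort range
#'   4-15 per patient).
#' @param mutations_per_cluster length-2 integer range of cluster sizes.
#' @param founder_gene_label gene label for the truncal founder mutation.
#' @param purity_shape `c(alpha, beta)` of the Beta purity prior
#'   (default `c(8, 2)`, median ~0.82, matching a cohort median of 0.8).
#' @param deep_depth mean depth of the targeted deep-sequencing tier.
#' @param wes_depth mean depth of the exome-like tier (used when
#'   `depth_mean` overrides ask for it).
#' @param base_error_rate per-read error probability after in-silico error
#'   suppression (default 1e-5: cleaned deep sequencing has residual
#'   backgrounds orders of magnitude below the 0.002-VAF detection floor;
#'   raise to ~1e-3 to emulate uncleaned data).
#' @param cnv_events list of CNV specifications, each a list with `branch`
#'   (node index, 1 = trunk), `chrom`, `major_cn`, `minor_cn`, optional
#'   `focal` flag; at most one event per chromosome.
#' @param convergent_driver optional gene label mutated independently on at
#'   least two distinct branches.
#' @param contamination_fractions tumor fractions of the normal samples
#'   (length `n_normals`, each in `[0, 1)`).
#' @param admixture_concentration Dirichlet concentration of region
#'   compositions (5 keeps minor admixtures in the reported 5-50% range).
#' @param snps_per_segment simulated het SNPs per segment and sample.
#' @param baf_noise_sd per-SNP Gaussian BAF noise.
#' @param c_noise_sd Gaussian noise on the observed composite copy number.
#' @param p_multi_lineage probability a region is co-occupied by two
#'   lineages (~50% of regions in multi-region cohorts).
#' @param min_ccf_separation minimum over cluster pairs of the maximal
#'   per-region CCF difference; compositions are redrawn (up to 200 times)
#'   until satisfied.
#' @param before_cnv_major_prob probability that a mutation predating a CNV
#'   sits on the major haplotype (the founder mutation always does,
#'   mirroring mutant-allele duplication).
#' @param age_ccf_coupling exponent coupling a lineage's occupancy weight to
#'   its mutation count (0 = no coupling).
#' @param normal_contamination_nodes optional list (length `n_normals`) of
#'   node-id vectors forming each normal's contaminating clone subset;
#'   `NULL` draws trunk plus at most one descendant at random.
#' @param seed default seed used when the simulation functions are not given
#'   one explicitly.
#' @return validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_regions = 5L,
                       n_normals = 2L,
                       n_clusters = 8L,
                       mutations_per_cluster = c(8L, 20L),
                       founder_gene_label = "H3F3A",
                       purity_shape = c(8, 2),
                       deep_depth = 2500,
                       wes_depth = 100,
                       base_error_rate = 1e-5,
                       cnv_events = list(),
                       convergent_driver = NULL,
                       contamination_fractions = c(0, 0.02),
                       admixture_concentration = 5,
                       snps_per_segment = 50L,
                       baf_noise_sd = 0.03,
                       c_noise_sd = 0.03,
                       p_multi_lineage = 0.5,
                       min_ccf_separation = 0.15,
                       before_cnv_major_prob = 0.5,
                       age_ccf_coupling = 0,
                       normal_contamination_nodes = NULL,
                       seed = 1L) {
  cfg <- as.list(environment())
  for (fld in c("n_regions", "n_normals", "n_clusters", "snps_per_segment")) {
    if (!is_count(cfg[[fld]])) {
      mc_stop(sprintf("%s must be a count >= 1", fld), "mc_invalid_config")
    }
  }
  if (length(mutations_per_cluster) != 2L || any(mutations_per_cluster < 1) ||
      mutations_per_cluster[1L] > mutations_per_cluster[2L]) {
    mc_stop("mutations_per_cluster must be an increasing range of counts", "mc_invalid_config")
  }
  if (!is.numeric(base_error_rate) || base_error_rate < 0 || base_error_rate >= 1) {
    mc_stop("base_error_rate must be a probability in [0, 1)", "mc_invalid_config")
  }
  if (length(contamination_fractions) != n_normals) {
    mc_stop("contamination_fractions must have one entry per normal sample", "mc_invalid_config")
  }
  if (any(contamination_fractions < 0 | contamination_fractions >= 1)) {
    mc_stop("contamination fractions must lie in [0, 1)", "mc_invalid_config")
  }
  if (any(purity_shape <= 0) || deep_depth < 1 || wes_depth < 1 ||
      admixture_concentration <= 0) {
    mc_stop("purity_shape, depths and admixture_concentration must be positive", "mc_invalid_config")
  }
  seen_chrom <- character()
  for (ev in cnv_events) {
    if (is.null(ev$branch) || ev$branch < 1 || ev$branch > n_clusters) {
      mc_stop("cnv event references a nonexistent branch", "mc_invalid_config")
    }
    if (is.null(ev$chrom) || is.null(ev$major_cn) || is.null(ev$minor_cn) ||
        ev$major_cn < ev$minor_cn || ev$minor_cn < 0) {
      mc_stop("cnv event needs chrom and major_cn >= minor_cn >= 0", "mc_invalid_config")
    }
    if (ev$chrom %in% seen_chrom) {
      mc_stop("at most one cnv event per chromosome", "mc_invalid_config")
    }
    seen_chrom <- c(seen_chrom, ev$chrom)
  }
  if (!is.null(normal_contamination_nodes) &&
      length(normal_contamination_nodes) != n_normals) {
    mc_stop("normal_contamination_nodes must have one entry per normal", "mc_invalid_config")
  }
  structure(cfg, class = "sim_config")
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}
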