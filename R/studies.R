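# Simulation studies at study-like settings (4-7 deeply sequenced regions,
# ~2500X, purity ~ Beta(8, 2), clusters of >= 8 mutations, cluster CCF
# profiles separated by >= 0.15). These drive the package's property-based
# validation: parameter recovery, CNV timing, contamination testing,
# variant classification and the lineage age-CCF relation.

map_clusters_to_truth <- function(assignment, truth_cluster) {
  vapply(split(names(assignment), assignment), function(members) {
    names(which.max(table(truth_cluster[members])))
  }, "")
}

#' Parameter-recovery study on synthetic cohorts
#'
#' For each replicate: simulate a cohort (diploid genome, defaults of
#' [sim_config()] with 4-7 regions drawn at random), run the inference
#' chain ([analyze_patient()] without normals), and score purity recovery,
#' exact recovery of the variant-level ancestry relation, per-region
#' composition L1 error (estimated clusters mapped to truth nodes by
#' majority membership), and truncal/shared/private classification
#' accuracy against the generating truth.
#'
#' @param n_replicates number of simulated patients.
#' @param seed master seed; replicate seeds are derived from it.
#' @param config_overrides named list of [sim_config()] overrides.
#' @param options [analyze_patient()] option overrides.
#' @return list with per-replicate vectors (`purity_err`, `ancestry_exact`,
#'   `comp_l1`, `class_acc`) and a `summary` of the headline rates.
#' @export
run_recovery_study <- function(n_replicates = 200L, seed = 1L,
                               config_overrides = list(), options = list()) {
  purity_err <- numeric()
  ancestry_exact <- logical(n_replicates)
  comp_l1 <- numeric()
  class_acc <- numeric(n_replicates)
  for (i in seq_len(n_replicates)) {
    rep_seed <- seed + i * 7919L
    n_regions <- with_seed(rep_seed, sample(4:7, 1L))
    cfg_args <- utils::modifyList(list(n_regions = n_regions, seed = rep_seed),
                                  config_overrides)
    cfg <- do.call(sim_config, cfg_args)
    truth <- simulate_truth(cfg)
    counts <- simulate_read_counts(truth, cfg, seed = rep_seed + 1L)
    meta <- data.frame(sample_id = counts$samples, patient_id = "P1",
                       tissue_class = "tumor", region_label = counts$samples,
                       stringsAsFactors = FALSE)
    res <- analyze_patient(counts, meta, truth$founder_id,
                           options = utils::modifyList(list(seed = rep_seed), options))

    # purity
    est_t <- purity_vector(res$purities)
    purity_err <- c(purity_err, abs(est_t[names(truth$purities)] - truth$purities))

    # variant-level ancestry relation
    cl_true <- stats::setNames(truth$variants$cluster, truth$variants$variant_id)
    vids <- names(res$clusters$assignment)
    A_true <- tree_ancestry_matrix(truth$tree)
    A_est <- tree_ancestry_matrix(res$tree)
    ct <- cl_true[vids]; ce <- res$clusters$assignment[vids]
    ancestry_exact[i] <-
      identical(unname(A_true[ct, ct]), unname(A_est[ce, ce])) &&
      identical(outer(ct, ct, `==`) |> unname(), outer(ce, ce, `==`) |> unname())

    # composition L1 with majority mapping of clusters to truth nodes
    cmap <- map_clusters_to_truth(res$clusters$assignment, cl_true)
    usable <- res$purities$sample_id[res$purities$t >= 0.05]
    for (s in usable) {
      est <- stats::setNames(rep(0, nrow(truth$compositions)), rownames(truth$compositions))
      d <- res$composition[res$composition$sample_id == s, ]
      for (j in seq_len(nrow(d))) {
        nd <- cmap[[d$node[j]]]
        est[nd] <- est[nd] + d$fraction[j]
      }
      comp_l1 <- c(comp_l1, sum(abs(est - truth$compositions[, s])))
    }

    # classification against the generating truth
    use <- colnames(res$classification$presence)
    pres_true <- truth$node_ccf[cl_true[rownames(res$classification$presence)], use,
                                drop = FALSE] > 0
    np <- rowSums(pres_true)
    cls_true <- ifelse(np == length(use), "truncal",
                       ifelse(np >= 2, "shared", ifelse(np == 1, "private", "undetected")))
    class_acc[i] <- mean(res$classification$class == cls_true)
  }
  list(purity_err = purity_err,
       ancestry_exact = ancestry_exact,
       comp_l1 = comp_l1,
       class_acc = class_acc,
       summary = list(
         purity_within_003 = mean(purity_err <= 0.03),
         purity_mae = mean(purity_err),
         ancestry_recovery = mean(ancestry_exact),
         comp_l1_within_01 = mean(comp_l1 <= 0.1),
         classification_accuracy = mean(class_acc),
         n_replicates = n_replicates))
}

#' Early-versus-late CNV timing study
#'
#' Replicates the focused timing analysis of an arm-level event (the
#' chr17p-loss situation): an event is truly truncal (early; CP equals the
#' purity in every region) or on a subclonal branch (late; CP tracks the
#' branch CCF), observed CPs carry Gaussian noise, and [fit_cnv_timing()]
#' chooses between the two placements.
#'
#' @param n_replicates number of simulated events.
#' @param seed master seed.
#' @param n_regions regions per replicate.
#' @param cp_noise_sd sd of the CP measurement noise.
#' @return list with `correct` (logical vector) and `accuracy`.
#' @export
run_timing_study <- function(n_replicates = 500L, seed = 1L, n_regions = 4L,
                             cp_noise_sd = 0.03) {
  correct <- with_seed(seed, {
    vapply(seq_len(n_replicates), function(i) {
      t <- stats::setNames(stats::rbeta(n_regions, 8, 2), paste0("A", seq_len(n_regions)))
      branch_ccf <- stats::setNames(stats::runif(n_regions, 0.2, 0.9), names(t))
      early <- stats::runif(1) < 0.5
      cp_true <- if (early) t else t * branch_ccf
      obs <- clamp(cp_true + stats::rnorm(n_regions, 0, cp_noise_sd), 0, 1)
      placements <- list(trunk = stats::setNames(rep(1, n_regions), names(t)),
                         branch = branch_ccf)
      fit <- fit_cnv_timing(obs, placements, t, tol = 0.1)
      fit$resolved && fit$node == (if (early) "trunk" else "branch")
    }, logical(1))
  })
  list(correct = correct, accuracy = mean(correct))
}

#' Contamination-testing study on simulated normal samples
#'
#' Simulates normal brain samples with tumor fractions drawn from
#' `phi_levels` (including pure normals), an error-model panel of pure
#' normals, and lineage-specific contaminating clone subsets (trunk plus
#' one random subclone). Reports the founder-gate type-I error on pure
#' normals, detection power at 2% tumor fraction, and the empirical false
#' discovery rate of cluster presence calls.
#'
#' @param n_samples number of tested normal samples.
#' @param seed master seed.
#' @param phi_levels tumor-fraction levels cycled over the samples.
#' @param q_threshold FDR level of the cluster calls.
#' @param depth_mean sequencing depth of the normals.
#' @param n_panel panel size for the error model.
#' @param error_rate per-read residual error rate of the simulated normals.
#' @param n_pure_extra additional pure normals tested only at the founder
#'   gate, so the type-I estimate has little Monte-Carlo noise.
#' @return list with per-sample results and a `summary` (type-I error,
#'   power at 2%, cluster FDR, sensitivity of cluster calls).
#' @export
run_contamination_study <- function(n_samples = 1000L, seed = 1L,
                                    phi_levels = c(0, 0.005, 0.02, 0.12),
                                    q_threshold = 0.05, depth_mean = 2500,
                                    n_panel = 8L, error_rate = 1e-3,
                                    n_pure_extra = 1500L) {
  # run at a deliberately pessimistic residual error rate (1e-3): the
  # contamination test must stay calibrated even on weakly cleaned data
  cfg <- sim_config(seed = seed, base_error_rate = error_rate)
  truth <- simulate_truth(cfg)
  nodes <- rownames(truth$compositions)
  founder <- truth$founder_id
  member_map <- split(truth$variants$variant_id, truth$variants$cluster)
  subtree_of <- lapply(stats::setNames(nm = nodes), function(n) tree_subtree(truth$tree, n))

  with_seed(seed + 1L, {
    # panel of pure normals
    comp0 <- matrix(0, length(nodes), n_panel,
                    dimnames = list(nodes, paste0("PN", seq_len(n_panel))))
    v0 <- sim_expected_vaf(truth, comp0, stats::setNames(rep(0, n_panel), colnames(comp0)))
    panel <- sim_counts_from_vaf(v0, depth_mean, cfg$base_error_rate, truth$variants)
    em <- build_error_model(panel)

    phi <- rep(phi_levels, length.out = n_samples)
    ids <- paste0("G", seq_len(n_samples))
    comp <- matrix(0, length(nodes), n_samples, dimnames = list(nodes, ids))
    support <- vector("list", n_samples)
    for (j in seq_len(n_samples)) {
      sup <- "N1"
      if (length(nodes) > 1L) sup <- c(sup, sample(setdiff(nodes, "N1"), 1L))
      support[[j]] <- sup
      comp[sup, j] <- rdirichlet1(rep(2, length(sup)))
    }
    v <- sim_expected_vaf(truth, comp, stats::setNames(phi, ids))
    counts <- sim_counts_from_vaf(v, depth_mean, cfg$base_error_rate, truth$variants)

    founder_sig <- logical(n_samples)
    n_calls <- n_fp <- n_true_present <- n_tp <- 0L
    for (j in seq_len(n_samples)) {
      call <- test_presence(counts, ids[j], founder, member_map, em,
                            q_threshold = q_threshold, exclude_clusters = "N1")
      founder_sig[j] <- call$tumor_fraction > 0
      present_true <- if (phi[j] > 0) {
        nodes[vapply(nodes, function(b) any(subtree_of[[b]] %in% support[[j]]), logical(1))]
      } else character()
      present_true <- setdiff(present_true, "N1")
      called <- call$clusters$cluster_id[call$clusters$present]
      n_calls <- n_calls + length(called)
      n_fp <- n_fp + sum(!called %in% present_true)
      n_true_present <- n_true_present + length(present_true) * (phi[j] > 0)
      n_tp <- n_tp + sum(called %in% present_true)
    }
    # dedicated pure normals for a low-noise type-I estimate: only the
    # founder gate runs, which is all a pure normal ever reaches
    extra_sig <- logical(0)
    if (n_pure_extra > 0L) {
      fd <- truth$founder_id
      depth0 <- pmax(1L, stats::rpois(n_pure_extra, depth_mean))
      alt0 <- stats::rbinom(n_pure_extra, depth0, error_rate)
      p0 <- error_tail_p(alt0, depth0, em, fd)
      extra_sig <- p0 < 0.05
    }
    list(phi = phi, founder_significant = founder_sig,
         summary = list(
           type1_error = mean(c(founder_sig[phi == 0], extra_sig)),
           power_2pct = mean(founder_sig[phi == 0.02]),
           cluster_fdr = n_fp / max(1L, n_calls),
           cluster_sensitivity = n_tp / max(1L, n_true_present),
           n_samples = n_samples))
  })
}

#' Lineage age versus average-CCF study
#'
#' Generates synthetic cohorts in which a lineage's occupancy is coupled to
#' its mutation accrual (`age_ccf_coupling`), accumulates 10 major lineages
#' per cohort across simulated patients with multi-lineage phylogenies (a
#' single-lineage patient's lone lineage holds the whole tumor at any age,
#' so such patients are excluded, as in multi-region cohort practice),
#' measures each lineage's molecular age and average CCF through the
#' package's decomposition and lineage statistics, and tests the Pearson
#' correlation. Older lineages have had more time to expand, so the
#' correlation should be positive. The default coupling exponent 1.6
#' reflects the reported pattern of a lineage at twice the molecular age
#' holding about thrice the average CCF.
#'
#' @param n_cohorts number of 10-lineage cohorts.
#' @param seed master seed.
#' @param coupling value of `age_ccf_coupling` passed to the generator.
#' @return list with per-cohort `r` and `p_value`, and a `summary` with the
#'   fraction of cohorts showing a significantly positive correlation.
#' @export
run_age_ccf_study <- function(n_cohorts = 20L, seed = 1L, coupling = 1.6) {
  r <- p <- rep(NA_real_, n_cohorts)
  for (co in seq_len(n_cohorts)) {
    stats_all <- NULL
    attempt <- 0L
    while ((is.null(stats_all) || nrow(stats_all) < 10L) && attempt < 30L) {
      attempt <- attempt + 1L
      rep_seed <- seed + co * 104729L + attempt * 7919L
      cfg <- sim_config(n_clusters = 6L, mutations_per_cluster = c(5L, 60L),
                        age_ccf_coupling = coupling, seed = rep_seed)
      st <- tryCatch({
        truth <- simulate_truth(cfg)
        counts <- simulate_read_counts(truth, cfg, seed = rep_seed + 1L)
        purities <- estimate_purity(counts, truth$founder_id)
        models <- lapply(stats::setNames(nm = counts$variants$variant_id), function(vid) {
          enumerate_copy_models(vid, counts, purity_vector(purities))
        })
        ccf <- compute_ccf_matrix(counts, purities, models)
        truncal <- truth$variants$variant_id[truth$variants$cluster == "N1"]
        purities <- refine_purity(purities, ccf, truncal)
        ccf <- compute_ccf_matrix(counts, purities, models)
        # cluster CCFs at the generating assignment, statistics on the
        # generating topology: this study validates the lineage measures,
        # not topology recovery (covered by run_recovery_study)
        cl_ccf <- t(vapply(rownames(truth$compositions), function(nd) {
          members <- truth$variants$variant_id[truth$variants$cluster == nd]
          colMeans(ccf$ccf[members, , drop = FALSE], na.rm = TRUE)
        }, numeric(ncol(ccf$ccf))))
        if (length(tree_children(truth$tree, "N1")) < 2L) NULL  # single-lineage patient
        else {
          comps <- decompose_regions(truth$tree, cl_ccf, purities, tol = 0.1)
          lineage_stats(truth$tree, comps, purities)
        }
      }, error = function(e) NULL)
      if (!is.null(st)) stats_all <- rbind(stats_all, as.data.frame(st))
    }
    if (!is.null(stats_all) && nrow(stats_all) >= 10L) {
      ct <- lineage_age_ccf_cor(utils::head(stats_all, 10L))
      r[co] <- ct$r
      p[co] <- ct$p_value
    }
  }
  positive_sig <- !is.na(r) & r > 0 & p < 0.05
  list(r = r, p_value = p,
       summary = list(positive_significant_rate = mean(positive_sig),
                      median_r = stats::median(r, na.rm = TRUE),
                      n_cohorts = n_cohorts))
}
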