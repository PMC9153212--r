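# End-to-end orchestration: purity -> CNV calibration -> copy models -> CCF
# -> superclone check -> clustering -> tree -> CNV placement -> region
# decomposition -> classification -> lineage statistics -> contamination.

#' Subset a read-count matrix to a set of samples
#'
#' @param counts a [read_counts] object.
#' @param samples sample ids to keep.
#' @return a [read_counts] object.
#' @export
subset_counts <- function(counts, samples) {
  missing <- setdiff(samples, counts$samples)
  if (length(missing)) {
    mc_stop(sprintf("samples not in count matrix: %s", paste(missing, collapse = ", ")),
            "mc_consistency_error")
  }
  read_counts(counts$variants, counts$ref[, samples, drop = FALSE],
              counts$alt[, samples, drop = FALSE])
}

# Map each variant to its covering calibrated segment (or NULL for diploid):
# returns a named list in the shape enumerate_copy_models() expects.
segment_for_variants <- function(variants, calib) {
  out <- stats::setNames(vector("list", nrow(variants)), variants$variant_id)
  if (is.null(calib) || !nrow(calib)) return(out)
  for (seg_id in unique(calib$segment_id)) {
    d <- calib[calib$segment_id == seg_id, , drop = FALSE]
    if (is.na(d$major_cn[1L])) next
    hit <- variants$chrom == d$chrom[1L] &
      variants$pos >= d$start[1L] & variants$pos <= d$end[1L]
    seg <- list(major_cn = d$major_cn[1L], minor_cn = d$minor_cn[1L],
                segment_id = seg_id,
                per_sample = data.frame(sample = d$sample, c = d$c, f = d$f,
                                        stringsAsFactors = FALSE))
    for (vid in variants$variant_id[hit]) out[[vid]] <- seg
  }
  out
}

default_options <- function() {
  list(tol = 0.05, cp_tol = 0.1, purity_cutoff = 0.05,
       detection = list(min_alt = 3L, min_vaf = 0.002),
       q_threshold = 0.05, founder_alpha = 0.05,
       k_range = NULL, n_restarts = 8L, ccf_cap = 1.5,
       baf_noise_sd = 0, truncal_min_ccf = 0.9, seed = 1L)
}

#' Analyse one patient's multi-region cohort
#'
#' Runs the full inference chain on in-memory objects. Stage order: founder
#' purity, segment calibration, copy-model enumeration, CCF matrix, purity
#' refinement against the founder clone, superclone check, mutation
#' clustering, tree construction, CNV placement, region decomposition,
#' variant classification, lineage statistics, and (when normal samples are
#' present) contamination testing with a leave-one-out error panel.
#'
#' @param counts a [read_counts] object over all samples.
#' @param meta sample metadata table (see [read_sample_meta()]).
#' @param founder_id founder variant row id.
#' @param founder_model integer `c(M, n)` at the founder locus.
#' @param segments optional segment observation table.
#' @param options named list overriding entries of the defaults: `tol`
#'   (CCF tolerance 0.05), `cp_tol` (CP tolerance 0.1), `purity_cutoff`
#'   (0.05), `detection`, `q_threshold`, `k_range`, `n_restarts`,
#'   `baf_noise_sd`, `seed`.
#' @return list with `purities`, `segments`, `copy_models`, `ccf`,
#'   `superclone_report`, `clusters`, `tree`, `composition`,
#'   `classification`, `lineage_stats`, `age_ccf`, `contamination`,
#'   `unresolved_variants`.
#' @export
analyze_patient <- function(counts, meta, founder_id,
                            founder_model = c(M = 2L, n = 1L),
                            segments = NULL, options = list()) {
  opts <- utils::modifyList(default_options(), options)
  res <- list()
  stage <- "setup"
  fail <- function(e) {
    mc_stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
            "mc_stage_failure", stage = stage, partial = res, parent = e)
  }
  tryCatch({
    tumor_samples <- meta$sample_id[meta$tissue_class == "tumor"]
    normal_samples <- meta$sample_id[meta$tissue_class == "normal"]
    tcounts <- subset_counts(counts, tumor_samples)

    stage <- "purity"
    purities <- estimate_purity(tcounts, founder_id, founder_model)

    stage <- "segments"
    calib <- NULL
    if (!is.null(segments) && nrow(segments)) {
      calib <- calibrate_segments(segments, purities, tol = opts$tol,
                                  baf_noise_sd = opts$baf_noise_sd)
    }

    stage <- "copy_models"
    seg_map <- segment_for_variants(tcounts$variants, calib)
    models <- lapply(stats::setNames(nm = tcounts$variants$variant_id), function(vid) {
      enumerate_copy_models(vid, tcounts, purity_vector(purities),
                            segment = seg_map[[vid]], tol = opts$tol,
                            detection = opts$detection)
    })

    stage <- "ccf"
    ccf <- compute_ccf_matrix(tcounts, purities, models, cap = opts$ccf_cap)
    usable <- purities$sample_id[purities$t >= opts$purity_cutoff]
    mins <- apply(ccf$ccf[, usable, drop = FALSE], 1L, min, na.rm = TRUE)
    truncal_ids <- rownames(ccf$ccf)[is.finite(mins) & mins >= opts$truncal_min_ccf]
    if (!founder_id %in% truncal_ids) truncal_ids <- c(founder_id, truncal_ids)

    stage <- "purity_refinement"
    purities <- refine_purity(purities, ccf, truncal_ids)
    if (!is.null(calib)) {
      calib <- calibrate_segments(segments, purities, tol = opts$tol,
                                  baf_noise_sd = opts$baf_noise_sd)
      seg_map <- segment_for_variants(tcounts$variants, calib)
    }
    models <- lapply(stats::setNames(nm = tcounts$variants$variant_id), function(vid) {
      enumerate_copy_models(vid, tcounts, purity_vector(purities),
                            segment = seg_map[[vid]], tol = opts$tol,
                            detection = opts$detection)
    })
    # the founder is a designation, not an inference: it is clonal by
    # definition and must never drop out of the analysis
    if (!models[[founder_id]]$resolved) {
      models[[founder_id]] <- enumerate_copy_models(
        founder_id, tcounts, purity_vector(purities),
        segment = seg_map[[founder_id]], tol = 1e6, detection = opts$detection)
    }
    ccf <- compute_ccf_matrix(tcounts, purities, models, cap = opts$ccf_cap)

    stage <- "superclone"
    # cluster-level check: the founder clone's mean CCF profile (single
    # variants exceed 1 by noise alone; the clone must not)
    tr_ids <- intersect(truncal_ids, rownames(ccf$ccf))
    truncal_mean <- rbind(truncal = colMeans(ccf$ccf[tr_ids, , drop = FALSE], na.rm = TRUE))
    sc <- check_superclone(truncal_mean, purities, "truncal", tol = opts$tol)
    purities <- sc$purities
    if (nrow(sc$report)) {
      for (s in sc$report$sample_id) {
        ccf$ccf[, s] <- ccf$ccf[, s] / sc$report$scale[sc$report$sample_id == s]
        ccf$se[, s] <- ccf$se[, s] / sc$report$scale[sc$report$sample_id == s]
      }
    }
    res <- list(purities = purities, segments = calib, copy_models = models,
                ccf = ccf, superclone_report = sc$report,
                unresolved_variants = attr(ccf, "unresolved"))

    stage <- "clustering"
    clusters <- cluster_mutations(ccf, tcounts, purities, models,
                                  k_range = opts$k_range, seed = opts$seed,
                                  n_restarts = opts$n_restarts)
    res$clusters <- clusters

    stage <- "tree"
    root_id <- unname(clusters$assignment[founder_id])
    tree <- build_tree(clusters$ccf, purities, tol = opts$tol,
                       mutation_counts = clusters$size,
                       purity_cutoff = opts$purity_cutoff, root_id = root_id,
                       se = clusters$se)
    if (!is.null(calib) && nrow(calib)) {
      tree <- place_cnv_events(tree, calib, purities, cluster_ccf = attr(tree, "ccf"),
                               tol = opts$cp_tol)
    }
    res$tree <- tree

    stage <- "decomposition"
    res$composition <- decompose_regions(tree, clusters$ccf, purities,
                                         tol = opts$tol,
                                         purity_cutoff = opts$purity_cutoff)

    stage <- "classification"
    res$classification <- classify_variants(tcounts, purities,
                                            detection = opts$detection,
                                            purity_cutoff = opts$purity_cutoff)

    stage <- "lineage_stats"
    if (length(tree_children(tree, tree$root))) {
      res$lineage_stats <- lineage_stats(tree, res$composition, purities,
                                         purity_cutoff = opts$purity_cutoff)
      res$age_ccf <- lineage_age_ccf_cor(res$lineage_stats)
    }

    stage <- "contamination"
    if (length(normal_samples)) {
      ncounts <- subset_counts(counts, normal_samples)
      trunk_cluster <- unname(clusters$assignment[founder_id])
      res$contamination <- lapply(stats::setNames(nm = normal_samples), function(g) {
        em <- build_error_model(ncounts, exclude = g)
        test_presence(ncounts, g, founder_id, clusters, em,
                      founder_model = founder_model,
                      q_threshold = opts$q_threshold, alpha = opts$founder_alpha,
                      exclude_clusters = trunk_cluster)
      })
    }
    res
  }, error = function(e) {
    if (inherits(e, "mc_stage_failure")) stop(e)
    fail(e)
  })
}

#' Run the pipeline end to end and write its outputs
#'
#' Accepts a configuration list (or a YAML file path) declaring either a
#' simulation (`simulate:` entries are passed to [sim_config()]) or real
#' inputs (`inputs:` with `counts`, `meta` and optionally `segments`
#' paths plus a `founder:` block with `variant_id`, `M`, `n`). Writes the
#' purity table, calibrated segments, CCF matrix, cluster table, tree
#' (JSON + Newick), region compositions, classification, lineage
#' statistics, contamination report and a run manifest into `out_dir`.
#' Deterministic given the configuration and seed.
#'
#' @param config list or YAML path.
#' @param out_dir output directory (created if absent).
#' @return the [analyze_patient()] result list, invisibly, with the
#'   simulation truth attached when simulating.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  has_sim <- !is.null(config$simulate)
  has_inputs <- !is.null(config$inputs)
  if (has_sim == has_inputs) {
    mc_stop("exactly one of 'simulate' and 'inputs' must be configured", "mc_invalid_config")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L
  options <- config$options %||% list()
  options$seed <- options$seed %||% seed

  truth <- NULL
  if (has_sim) {
    cfg <- do.call(sim_config, utils::modifyList(config$simulate, list(seed = seed)))
    sim <- simulate_cohort(cfg)
    truth <- sim$truth
    counts <- sim$counts
    meta <- sim$meta
    segments <- sim$segments
    founder_id <- truth$founder_id
    fm <- truth$copy_models[truth$copy_models$variant_id == founder_id, ]
    founder_model <- if (!is.na(fm$cnv_id)) {
      ev <- truth$cnv_events[truth$cnv_events$cnv_id == fm$cnv_id, ]
      c(M = ev$major_cn + ev$minor_cn, n = fm$n)
    } else c(M = 2L, n = 1L)
    options$baf_noise_sd <- options$baf_noise_sd %||% cfg$baf_noise_sd
  } else {
    meta <- read_sample_meta(config$inputs$meta)
    counts <- read_variant_counts(config$inputs$counts, meta)
    segments <- if (!is.null(config$inputs$segments)) read_segments(config$inputs$segments)
    founder_id <- config$founder$variant_id
    founder_model <- c(M = config$founder$M %||% 2L, n = config$founder$n %||% 1L)
  }

  manifest <- list(package = "multiclone",
                   version = as.character(utils::packageVersion("multiclone")),
                   seed = seed, founder = list(variant_id = founder_id,
                                               M = unname(founder_model[[1L]]),
                                               n = unname(founder_model[[2L]])),
                   config = config, complete = FALSE)
  write_manifest <- function() {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  }

  res <- tryCatch(
    analyze_patient(counts, meta, founder_id, founder_model, segments, options),
    error = function(e) {
      partial <- e$partial %||% list()
      manifest$failed_stage <<- e$stage %||% "unknown"
      write_pipeline_outputs(partial, out_dir)
      write_manifest()
      stop(e)
    })

  write_pipeline_outputs(res, out_dir)
  if (!is.null(truth)) attr(res, "truth") <- truth
  manifest$complete <- TRUE
  write_manifest()
  invisible(res)
}

write_pipeline_outputs <- function(res, out_dir) {
  tsv <- function(d, name) utils::write.table(d, file.path(out_dir, name), sep = "\t",
                                              quote = FALSE, row.names = FALSE)
  if (!is.null(res$purities)) tsv(as.data.frame(res$purities), "purity.tsv")
  if (!is.null(res$segments)) tsv(as.data.frame(res$segments), "segments_calibrated.tsv")
  if (!is.null(res$ccf)) {
    d <- data.frame(variant_id = rownames(res$ccf$ccf), res$ccf$ccf,
                    check.names = FALSE, stringsAsFactors = FALSE)
    tsv(d, "ccf.tsv")
  }
  if (!is.null(res$clusters)) {
    cl <- res$clusters
    d <- data.frame(cluster_id = rownames(cl$ccf), size = cl$size[rownames(cl$ccf)],
                    members = vapply(rownames(cl$ccf), function(k)
                      paste(names(cl$assignment)[cl$assignment == k], collapse = ","), ""),
                    cl$ccf, check.names = FALSE, stringsAsFactors = FALSE)
    tsv(d, "clusters.tsv")
  }
  if (!is.null(res$tree)) {
    write_tree(res$tree, file.path(out_dir, "tree.json"), file.path(out_dir, "tree.nwk"))
  }
  if (!is.null(res$composition)) write_composition(res$composition, file.path(out_dir, "composition.tsv"))
  if (!is.null(res$classification)) {
    tsv(data.frame(variant_id = names(res$classification$class),
                   class = unname(res$classification$class), stringsAsFactors = FALSE),
        "classification.tsv")
    tsv(res$classification$summary, "classification_summary.tsv")
  }
  if (!is.null(res$lineage_stats)) tsv(as.data.frame(res$lineage_stats), "lineage_stats.tsv")
  if (!is.null(res$contamination)) {
    rows <- lapply(res$contamination, function(cl) {
      base <- data.frame(sample_id = cl$sample_id, tumor_fraction = cl$tumor_fraction,
                         ci_lo = cl$ci[1L], ci_hi = cl$ci[2L], founder_p = cl$founder_p,
                         stringsAsFactors = FALSE)
      if (nrow(cl$clusters)) cbind(base[rep(1L, nrow(cl$clusters)), ], cl$clusters)
      else cbind(base, data.frame(cluster_id = NA, p = NA, q = NA, present = NA, ccf = NA))
    })
    tsv(do.call(rbind, rows), "contamination.tsv")
  }
  invisible(out_dir)
}
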