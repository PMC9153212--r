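# Placing CNV events on the clone tree, decomposing each region into clone
# fractions with founder filling, variant sharing classification, and
# per-lineage molecular age / average-CCF statistics.

#' Assign CNV events to tree nodes
#'
#' Each calibrated segment is assigned to the node whose per-sample CCF
#' profile matches the segment's `CP / t` within tolerance, delegating the
#' choice to [fit_cnv_timing()] over all tree nodes. A segment whose CP
#' tracks the purity in every region is truncal and lands on the root;
#' events matching no node are reported unplaced.
#'
#' @param tree a `"clone_tree"` whose node ids are cluster ids with CCF rows
#'   in `cluster_ccf`.
#' @param segments a `"cnv_segments"` table from [calibrate_segments()].
#' @param purities `"purity_estimates"` table or named purity vector.
#' @param cluster_ccf cluster CCF matrix (defaults to `attr(tree, "ccf")`).
#' @param tol CP agreement tolerance.
#' @return the tree with `$cnv_events` filled (`node`, `segment_id`,
#'   `major_cn`, `minor_cn`, `rss`) and an `"unplaced"` attribute listing
#'   segments matching no node.
#' @export
place_cnv_events <- function(tree, segments, purities, cluster_ccf = NULL, tol = 0.1) {
  cluster_ccf <- cluster_ccf %||% attr(tree, "ccf")
  stopifnot(!is.null(cluster_ccf))
  placements <- lapply(stats::setNames(nm = rownames(cluster_ccf)),
                       function(id) cluster_ccf[id, ])
  events <- NULL
  unplaced <- character()
  for (seg_id in unique(segments$segment_id)) {
    d <- segments[segments$segment_id == seg_id, , drop = FALSE]
    obs <- stats::setNames(d$cp, d$sample)
    obs <- obs[!is.na(obs)]
    obs <- obs[names(obs) %in% colnames(cluster_ccf)]
    if (!length(obs) || is.na(d$major_cn[1L])) {
      unplaced <- c(unplaced, seg_id)
      next
    }
    fit <- fit_cnv_timing(obs, placements, purities, tol)
    if (!fit$resolved) {
      unplaced <- c(unplaced, seg_id)
      next
    }
    events <- rbind(events, data.frame(
      node = fit$node, segment_id = seg_id,
      chrom = d$chrom[1L], start = d$start[1L], end = d$end[1L],
      major_cn = d$major_cn[1L], minor_cn = d$minor_cn[1L],
      rss = fit$residuals$rss[1L], stringsAsFactors = FALSE))
  }
  tree$cnv_events <- events %||% data.frame(node = character(), stringsAsFactors = FALSE)
  attr(tree, "unplaced") <- unplaced
  tree
}

#' Decompose each region into clone fractions
#'
#' The fraction of cancer cells belonging to the clone at a node is that
#' node's CCF minus the summed CCF of its children (clipped at zero when
#' within `-tol`). A founder clone holding the remaining
#' `1 - sum(non-root fractions)` is added when positive: truncal variants
#' define the most recent common ancestor, and any cancer cells not claimed
#' by a descendant cluster belong to it (or to a rare descendant whose
#' private mutations escaped detection). Samples below the purity cutoff are
#' flagged `inferred_only`: their compositions come from clusters measured
#' in high-purity samples and may understate local diversity.
#'
#' @param tree a `"clone_tree"`.
#' @param ccf cluster CCF matrix (rows must cover the tree's node ids;
#'   defaults to `attr(tree, "ccf")`); may include extra samples.
#' @param purities `"purity_estimates"` table or named purity vector.
#' @param tol negative-fraction tolerance; a deficit beyond it is an error.
#' @param purity_cutoff threshold for the `inferred_only` flag.
#' @param lineage_fraction_min a region is flagged `multi_lineage` when more
#'   than one child-of-root lineage holds at least this fraction.
#' @return data frame of class `"region_composition"`: one row per
#'   (sample, node) with `fraction`, plus per-sample `purity`,
#'   `inferred_only` and `multi_lineage`.
#' @export
decompose_regions <- function(tree, ccf = NULL, purities, tol = 0.05,
                              purity_cutoff = 0.05, lineage_fraction_min = 0.05) {
  ccf <- ccf %||% attr(tree, "ccf")
  t <- if (inherits(purities, "purity_estimates")) purity_vector(purities) else purities
  ids <- names(tree$parent)
  stopifnot(all(ids %in% rownames(ccf)))
  lineages <- tree_children(tree, tree$root)
  out <- NULL
  for (s in colnames(ccf)) {
    frac <- stats::setNames(numeric(length(ids)), ids)
    for (id in ids) {
      kids <- tree_children(tree, id)
      fr <- ccf[id, s] - sum(ccf[kids, s])
      if (id == tree$root) next
      if (is.na(fr)) fr <- 0
      if (fr < -tol && t[s] >= purity_cutoff) {
        mc_stop(sprintf("node '%s' in sample '%s': children CCFs exceed the node's by %.3f",
                        id, s, -fr), "mc_inconsistency")
      }
      frac[id] <- max(fr, 0)
    }
    nonroot <- sum(frac[setdiff(ids, tree$root)])
    frac[tree$root] <- max(0, 1 - nonroot)
    if (sum(frac) > 1) frac <- frac / sum(frac)  # deficit beyond founder filling
    lin_frac <- vapply(lineages, function(l) sum(frac[tree_subtree(tree, l)]), numeric(1))
    out <- rbind(out, data.frame(
      sample_id = s, node = ids, fraction = as.numeric(frac),
      purity = unname(t[s]),
      inferred_only = unname(t[s]) < purity_cutoff,
      multi_lineage = sum(lin_frac > lineage_fraction_min) > 1L,
      stringsAsFactors = FALSE, row.names = NULL))
  }
  class(out) <- c("region_composition", "data.frame")
  out
}

#' Classify variants as truncal, shared or private
#'
#' Applies the detection rule per tumor sample (default: at least 3 mutant
#' reads and VAF >= 0.002, the resolution of error-suppressed deep
#' sequencing) over samples with purity at or above the cutoff, then maps
#' each variant's presence pattern: present in all usable samples = truncal,
#' in two or more but not all = shared, in exactly one = private.
#'
#' @param counts a [read_counts] object.
#' @param purities `"purity_estimates"` table or named purity vector; only
#'   tumor samples should be present.
#' @param detection list with `min_alt`, `min_vaf`.
#' @param purity_cutoff samples below it are not used.
#' @return list with `class` (named vector, `"undetected"` when a variant is
#'   seen nowhere), `presence` (logical matrix) and `summary` (counts and
#'   percentages per class).
#' @export
classify_variants <- function(counts, purities,
                              detection = list(min_alt = 3L, min_vaf = 0.002),
                              purity_cutoff = 0.05) {
  stopifnot(inherits(counts, "read_counts"))
  t <- if (inherits(purities, "purity_estimates")) purity_vector(purities) else purities
  usable <- names(t)[t >= purity_cutoff]
  usable <- intersect(counts$samples, usable)
  if (length(usable) < 2L) {
    mc_stop("variant classification needs at least two samples above the purity cutoff",
            "mc_classification_undefined")
  }
  alt <- counts$alt[, usable, drop = FALSE]
  depth <- alt + counts$ref[, usable, drop = FALSE]
  vaf <- ifelse(depth > 0, alt / depth, 0)
  presence <- alt >= detection$min_alt & vaf >= detection$min_vaf
  npres <- rowSums(presence)
  cls <- ifelse(npres == length(usable), "truncal",
                ifelse(npres >= 2L, "shared",
                       ifelse(npres == 1L, "private", "undetected")))
  cls <- stats::setNames(cls, rownames(alt))
  tab <- table(factor(cls, levels = c("truncal", "shared", "private", "undetected")))
  summary <- data.frame(class = names(tab), count = as.integer(tab),
                        percent = 100 * as.integer(tab) / sum(tab),
                        stringsAsFactors = FALSE)
  list(class = cls, presence = presence, summary = summary)
}

#' Per-lineage molecular age and average CCF
#'
#' A lineage is an immediate child branch of the founder. Its molecular age
#' is the number of mutations from the trunk (excluded) to its most distant
#' descendant node; its average CCF sums the clone fractions of all
#' subclones descending from the lineage in each qualifying region
#' (purity >= `purity_cutoff`) and averages over those regions. Regions
#' where the lineage is absent contribute zero.
#'
#' @param tree a `"clone_tree"`.
#' @param comps a `"region_composition"` table from [decompose_regions()].
#' @param purities `"purity_estimates"` table or named purity vector.
#' @param purity_cutoff regions below it are excluded.
#' @return data frame of class `"lineage_stats"` with one row per lineage:
#'   `lineage_id`, `molecular_age`, `average_ccf`, `n_regions`, and an
#'   attribute `"excluded_regions"`.
#' @seealso [lineage_age_ccf_cor()] for the cohort-level correlation.
#' @export
lineage_stats <- function(tree, comps, purities, purity_cutoff = 0.05) {
  t <- if (inherits(purities, "purity_estimates")) purity_vector(purities) else purities
  lineages <- tree_children(tree, tree$root)
  if (!length(lineages)) {
    mc_stop("tree has no lineage (no child of the founder)", "mc_invalid_tree")
  }
  samples <- unique(comps$sample_id)
  keep <- samples[t[samples] >= purity_cutoff]
  excluded <- setdiff(samples, keep)
  rows <- lapply(lineages, function(l) {
    nodes <- tree_subtree(tree, l)
    # molecular age: deepest cumulative mutation count below the trunk
    depth_of <- function(id) {
      path <- c(id, tree_ancestors(tree, id))
      path <- path[seq_len(which(path == l))]  # up to and including the lineage root
      sum(tree$branch_mutation_count[path])
    }
    age <- max(vapply(nodes, depth_of, numeric(1)))
    per_region <- vapply(keep, function(s) {
      d <- comps[comps$sample_id == s & comps$node %in% nodes, , drop = FALSE]
      sum(d$fraction)
    }, numeric(1))
    data.frame(lineage_id = l, molecular_age = age,
               average_ccf = mean(per_region), n_regions = length(keep),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("lineage_stats", "data.frame")
  attr(out, "excluded_regions") <- excluded
  out
}

#' Correlation of molecular age and average CCF across lineages
#'
#' Pearson correlation across the lineages of one or more patients; a more
#' expansive occupancy is expected for lineages with longer evolution time.
#'
#' @param stats_table a `"lineage_stats"` table (rows from several patients
#'   may be concatenated).
#' @return list with `r`, `p_value`, `n`; `r` and `p_value` are `NA` with
#'   fewer than 3 lineages.
#' @export
lineage_age_ccf_cor <- function(stats_table) {
  n <- nrow(stats_table)
  if (n < 3L) return(list(r = NA_real_, p_value = NA_real_, n = n))
  ct <- stats::cor.test(stats_table$molecular_age, stats_table$average_ccf,
                        method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = n)
}
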