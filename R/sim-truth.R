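# Ground-truth generation: a random clone tree with mutation clusters,
# allele-specific CNV events, per-region clone compositions and purities.
# Truth CCFs are tree-consistent by construction: the CCF of a node is the
# sum of clone fractions over the node and its descendants, so a parent's
# CCF can never fall below a child's.

# Draw a random rooted topology (node 1 = trunk) and cluster sizes.
draw_topology <- function(config) {
  k <- config$n_clusters
  nodes <- paste0("N", seq_len(k))
  parent <- stats::setNames(rep(NA_character_, k), nodes)
  if (k > 1L) {
    for (i in 2:k) parent[i] <- nodes[sample.int(i - 1L, 1L)]
  }
  sizes <- stats::setNames(
    sample(seq(config$mutations_per_cluster[1L], config$mutations_per_cluster[2L]),
           k, replace = TRUE), nodes)
  clone_tree(parent, branch_mutation_count = sizes)
}

#' Simulate the ground truth of a multi-region cohort
#'
#' Builds a random rooted clone tree with `n_clusters` cluster-bearing
#' nodes (node `N1` is the trunk and carries the founder variant), attaches
#' the configured CNV events to their branches, draws per-region clone
#' compositions (trunk plus one or two lineage subtrees per region,
#' Dirichlet weights) and purities, and records the implied mutation copy
#' model of every variant. Tree and compositions are redrawn until every
#' cluster is observable, cluster CCF profiles are separated by
#' `min_ccf_separation`, and the occupancy patterns identify the generating
#' tree uniquely with a noise margin — a multi-region design that cannot
#' resolve its own phylogeny is not a usable study instance.
#' Deterministic given `(config, seed)`.
#'
#' @param config a [sim_config()].
#' @param seed integer seed (defaults to `config$seed`).
#' @return object of class `"sim_truth"`: list with `tree` (a
#'   `"clone_tree"`), `variants`, `founder_id`, `copy_models`,
#'   `compositions` (nodes x regions), `node_ccf` (truth cluster CCFs),
#'   `purities`, `cnv_events`, `contamination`, `normal_support`, `config`.
#' @export
simulate_truth <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(seed, {
    k <- config$n_clusters
    nodes <- paste0("N", seq_len(k))
    regions <- paste0("A", seq_len(config$n_regions))

    draw_support <- function(tree, lineages, lineage_age) {
      support <- "N1"
      if (length(lineages)) {
        # each additional lineage joins a region with probability
        # p_multi_lineage: with two lineages ~half of regions are admixed,
        # and patients with more lineages can show three- and four-branch
        # admixtures, as multi-region cohorts do
        n_lin <- 1L + stats::rbinom(1L, length(lineages) - 1L, config$p_multi_lineage)
        n_lin <- min(n_lin, length(lineages))
        lin_w <- rep(1, length(lineages))
        if (config$age_ccf_coupling > 0) {
          lin_w <- (lineage_age / mean(lineage_age))^config$age_ccf_coupling
        }
        chosen <- sample(lineages, n_lin, prob = lin_w)
        for (l in chosen) {
          # random downward-closed connected subset rooted at the lineage head
          keep <- l
          queue <- tree_children(tree, l)
          while (length(queue)) {
            nd <- queue[[1L]]
            queue <- queue[-1L]
            if (stats::runif(1) < 0.6) {
              keep <- c(keep, nd)
              queue <- c(queue, tree_children(tree, nd))
            }
          }
          support <- c(support, keep)
        }
      }
      support
    }

    separation <- function(ccf) {
      if (nrow(ccf) < 2L) return(Inf)
      pairs <- utils::combn(nrow(ccf), 2L)
      min(apply(pairs, 2L, function(p) max(abs(ccf[p[1L], ] - ccf[p[2L], ]))))
    }

    # joint tree/composition draw: accept instances in which every cluster
    # is observable (peak CCF >= 0.05 somewhere), cluster profiles are
    # separated, and the occupancy patterns pin down the generating tree
    # uniquely with a noise margin (0.05, the scale of the inference
    # tolerances); redraw the topology when 60 composition draws cannot
    # identify it (deep chains may be unresolvable with few regions)
    best <- NULL
    for (tree_try in seq_len(25L)) {
      tree <- draw_topology(config)
      sizes <- tree$branch_mutation_count
      subtree_of <- lapply(stats::setNames(nm = nodes), function(n) tree_subtree(tree, n))
      lineages <- tree_children(tree, "N1")
      lineage_of <- stats::setNames(rep(NA_character_, k), nodes)
      for (l in lineages) lineage_of[subtree_of[[l]]] <- l
      lineage_age <- vapply(stats::setNames(nm = lineages), function(l) {
        max(vapply(subtree_of[[l]], function(nd) {
          path <- c(nd, tree_ancestors(tree, nd))
          sum(sizes[path[seq_len(which(path == l))]])
        }, numeric(1)))
      }, numeric(1))

      for (comp_try in seq_len(60L)) {
        comp <- matrix(0, k, config$n_regions, dimnames = list(nodes, regions))
        for (r in seq_len(config$n_regions)) {
          support <- draw_support(tree, lineages, lineage_age)
          alpha <- rep(config$admixture_concentration, length(support))
          if (config$age_ccf_coupling > 0) {
            w <- ifelse(is.na(lineage_of[support]), 1,
                        (lineage_age[lineage_of[support]] / mean(lineage_age))^config$age_ccf_coupling)
            alpha <- alpha * w
          }
          comp[support, r] <- rdirichlet1(alpha)
        }
        ccf <- t(vapply(nodes, function(n) colSums(comp[subtree_of[[n]], , drop = FALSE]),
                        numeric(config$n_regions)))
        dimnames(ccf) <- list(nodes, regions)
        sep <- separation(ccf)
        covered <- sum(apply(ccf, 1L, max) >= 0.05)
        identifiable <- covered == k && sep >= config$min_ccf_separation &&
          count_feasible_trees(ccf, "N1", tol = 0.05) == 1L
        score <- covered + (sep >= config$min_ccf_separation) + 2 * identifiable
        if (is.null(best) || score > best$score ||
            (score == best$score && sep > best$sep)) {
          best <- list(tree = tree, sizes = sizes, subtree_of = subtree_of,
                       lineage_of = lineage_of, lineage_age = lineage_age,
                       comp = comp, ccf = ccf, sep = sep, covered = covered,
                       score = score, identifiable = identifiable)
        }
        if (identifiable) break
      }
      if (best$identifiable) break
    }
    if (!best$identifiable) {
      warning(sprintf("truth draw: CCF separation %.3f (requested %.3f), %d/%d clusters observable, tree identifiability not reached",
                      best$sep, config$min_ccf_separation, best$covered, k), call. = FALSE)
    }
    tree <- best$tree
    sizes <- best$sizes
    subtree_of <- best$subtree_of
    compositions <- best$comp
    node_ccf <- best$ccf

    # variants: uniform over autosomes, unique positions
    n_var <- sum(sizes)
    chroms <- paste0("chr", 1:22)
    variants <- data.frame(
      variant_id = sprintf("V%04d", seq_len(n_var)),
      chrom = sample(chroms, n_var, replace = TRUE),
      pos = sample.int(1.2e8, n_var),
      ref = sample(c("A", "C", "G", "T"), n_var, replace = TRUE),
      alt = NA_character_,
      gene = sprintf("GENE%03d", sample.int(400, n_var, replace = TRUE)),
      cluster = rep(nodes, times = sizes),
      stringsAsFactors = FALSE
    )
    variants$alt <- vapply(variants$ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1L), "")
    founder_id <- variants$variant_id[variants$cluster == "N1"][1L]
    variants$gene[variants$variant_id == founder_id] <- config$founder_gene_label

    if (!is.null(config$convergent_driver)) {
      branches <- setdiff(nodes, "N1")
      if (length(branches) < 2L) {
        mc_stop("convergent_driver needs at least two non-trunk branches", "mc_invalid_config")
      }
      picked <- sample(branches, 2L)
      for (b in picked) {
        cand <- which(variants$cluster == b & variants$variant_id != founder_id)
        variants$gene[cand[1L]] <- config$convergent_driver
      }
    }

    # CNV events
    if (length(config$cnv_events)) {
      cnv <- do.call(rbind, lapply(seq_along(config$cnv_events), function(i) {
        ev <- config$cnv_events[[i]]
        focal <- isTRUE(ev$focal)
        data.frame(cnv_id = paste0("CNV", i), node = nodes[ev$branch],
                   chrom = ev$chrom,
                   start = if (focal) 5e7 else 1L,
                   end = if (focal) 5.2e7 else 1.3e8,
                   major_cn = as.integer(ev$major_cn), minor_cn = as.integer(ev$minor_cn),
                   focal = focal, stringsAsFactors = FALSE)
      }))
    } else {
      cnv <- data.frame(cnv_id = character(), node = character(), chrom = character(),
                        start = integer(), end = integer(), major_cn = integer(),
                        minor_cn = integer(), focal = logical(), stringsAsFactors = FALSE)
    }

    # mutation copy models implied by variant/CNV branch relations
    copy_models <- data.frame(variant_id = variants$variant_id,
                              cnv_id = NA_character_, timing = "diploid_context",
                              n = 1L, haplotype = NA_character_,
                              stringsAsFactors = FALSE)
    for (j in seq_len(nrow(cnv))) {
      covers <- variants$chrom == cnv$chrom[j] &
        variants$pos >= cnv$start[j] & variants$pos <= cnv$end[j]
      for (i in which(covers)) {
        b_m <- variants$cluster[i]
        b_c <- cnv$node[j]
        copy_models$cnv_id[i] <- cnv$cnv_id[j]
        before <- b_c %in% subtree_of[[b_m]]  # mutation branch is ancestor-or-same
        if (before) {
          on_major <- if (variants$variant_id[i] == founder_id) TRUE
                      else stats::runif(1) < config$before_cnv_major_prob
          copy_models$timing[i] <- if (on_major) "before_cnv_on_major" else "before_cnv_on_minor"
          copy_models$n[i] <- if (on_major) cnv$major_cn[j] else cnv$minor_cn[j]
          copy_models$haplotype[i] <- if (on_major) "major" else "minor"
        } else {
          copy_models$timing[i] <- "after_cnv"
          copy_models$n[i] <- 1L
        }
      }
    }

    purities <- stats::setNames(
      stats::rbeta(config$n_regions, config$purity_shape[1L], config$purity_shape[2L]),
      regions)

    # contaminating clone subsets for the normal samples
    normals <- paste0("G", seq_len(config$n_normals))
    contamination <- stats::setNames(config$contamination_fractions, normals)
    normal_support <- config$normal_contamination_nodes
    if (is.null(normal_support)) {
      normal_support <- lapply(seq_len(config$n_normals), function(i) {
        sup <- "N1"
        if (k > 1L && stats::runif(1) < 0.7) sup <- c(sup, sample(setdiff(nodes, "N1"), 1L))
        sup
      })
    }
    names(normal_support) <- normals
    bad <- unlist(normal_support)[!unlist(normal_support) %in% nodes]
    if (length(bad)) {
      mc_stop(sprintf("contaminating clone subset references nodes not on the tree: %s",
                      paste(unique(bad), collapse = ", ")), "mc_inconsistent_truth")
    }

    structure(list(
      tree = tree, variants = variants, founder_id = founder_id,
      copy_models = copy_models, compositions = compositions,
      node_ccf = node_ccf, purities = purities, cnv_events = cnv,
      contamination = contamination, normal_support = normal_support,
      config = config
    ), class = "sim_truth")
  })
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("<sim_truth> %d clusters, %d variants, %d regions, %d normals\n",
              length(x$tree$parent), nrow(x$variants), ncol(x$compositions),
              length(x$contamination)))
  invisible(x)
}
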