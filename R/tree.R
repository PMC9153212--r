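# Clone trees and their construction from cluster CCF profiles under the
# sum's rule (pigeonhole principle: within a sample, children's CCFs cannot
# sum beyond their parent's) and the crossing rule (two clusters whose CCF
# ordering reverses between samples cannot be ancestor and descendant).

#' Construct a clone tree
#'
#' @param parent named character vector mapping each node id to its parent id
#'   (`NA` for the root).
#' @param cluster_id optional named vector mapping node id to mutation
#'   cluster id (defaults to the node id itself).
#' @param branch_mutation_count named integer vector of mutations acquired on
#'   the branch leading into each node (defaults to 0).
#' @param cnv_events data frame of CNV events with at least a `node` column.
#' @param ambiguous named list: node id -> character vector of alternative
#'   parents consistent with the data.
#' @return object of class `"clone_tree"`.
#' @export
clone_tree <- function(parent, cluster_id = NULL, branch_mutation_count = NULL,
                       cnv_events = NULL, ambiguous = list()) {
  ids <- names(parent)
  if (is.null(ids) || anyDuplicated(ids)) {
    mc_stop("parent map must be a named vector with unique node ids", "mc_invalid_tree")
  }
  root <- ids[is.na(parent)]
  if (length(root) != 1L) {
    mc_stop(sprintf("tree must have exactly one root, found %d", length(root)), "mc_invalid_tree")
  }
  if (any(!parent[!is.na(parent)] %in% ids)) {
    mc_stop("parent map references unknown node", "mc_invalid_tree")
  }
  # acyclicity / reachability: walk up from every node
  for (id in ids) {
    seen <- character()
    cur <- id
    while (!is.na(parent[[cur]])) {
      if (cur %in% seen) mc_stop("cyclic parent map", "mc_invalid_tree")
      seen <- c(seen, cur)
      cur <- parent[[cur]]
    }
    if (cur != root) mc_stop("node not reachable from root", "mc_invalid_tree")
  }
  bmc <- stats::setNames(rep(0L, length(ids)), ids)
  if (!is.null(branch_mutation_count)) bmc[names(branch_mutation_count)] <- as.integer(branch_mutation_count)
  cl <- stats::setNames(ids, ids)
  if (!is.null(cluster_id)) cl[names(cluster_id)] <- cluster_id
  structure(list(
    parent = parent,
    root = root,
    cluster_id = cl,
    branch_mutation_count = bmc,
    cnv_events = cnv_events %||% data.frame(node = character(), stringsAsFactors = FALSE),
    ambiguous = ambiguous
  ), class = "clone_tree")
}

#' @export
print.clone_tree <- function(x, ...) {
  cat(sprintf("<clone_tree> %d nodes, root '%s'\n", length(x$parent), x$root))
  for (id in names(x$parent)) {
    amb <- if (id %in% names(x$ambiguous) && length(x$ambiguous[[id]]))
      sprintf("  [alt parents: %s]", paste(x$ambiguous[[id]], collapse = ", ")) else ""
    cat(sprintf("  %s <- %s (%d mutations)%s\n", id,
                ifelse(is.na(x$parent[[id]]), "(root)", x$parent[[id]]),
                x$branch_mutation_count[[id]], amb))
  }
  invisible(x)
}

tree_children <- function(tree, node) {
  names(tree$parent)[!is.na(tree$parent) & tree$parent == node]
}

tree_ancestors <- function(tree, node) {
  out <- character()
  cur <- tree$parent[[node]]
  while (!is.na(cur)) {
    out <- c(out, cur)
    cur <- tree$parent[[cur]]
  }
  out
}

tree_subtree <- function(tree, node) {
  out <- node
  stack <- tree_children(tree, node)
  while (length(stack)) {
    cur <- stack[[1L]]
    stack <- stack[-1L]
    out <- c(out, cur)
    stack <- c(stack, tree_children(tree, cur))
  }
  out
}

# node_id x node_id logical matrix: is row an ancestor (proper) of column?
tree_ancestry_matrix <- function(tree) {
  ids <- names(tree$parent)
  m <- matrix(FALSE, length(ids), length(ids), dimnames = list(ids, ids))
  for (id in ids) m[tree_ancestors(tree, id), id] <- TRUE
  m
}

# Count rooted arborescences over the CCF profiles satisfying ancestor
# dominance and the sum's rule (stopping at `cap`). With noise-free truth
# CCFs and a tiny tolerance this measures identifiability: a count of 1
# means the CCF profiles pin down the generating tree uniquely.
count_feasible_trees <- function(ccf, root_id, tol = 1e-9, cap = 2L) {
  ids <- rownames(ccf)
  k <- length(ids)
  root <- match(root_id, ids)
  if (k == 1L) return(1L)
  ord <- setdiff(order(-rowMeans(ccf), ids), root)
  cand <- lapply(seq_len(k), function(i) {
    if (i == root) return(integer())
    js <- setdiff(seq_len(k), i)
    js[vapply(js, function(j) all(ccf[j, ] >= ccf[i, ] - tol), logical(1))]
  })
  cnt <- 0L
  parent <- integer(k)
  childsum <- matrix(0, k, ncol(ccf))
  rec <- function(pos) {
    if (cnt >= cap) return()
    if (pos > length(ord)) {
      if (tree_assignment_ok(parent, ccf, tol)) cnt <<- cnt + 1L
      return()
    }
    i <- ord[pos]
    for (p in cand[[i]]) {
      cur <- p
      cyc <- FALSE
      while (cur != 0L) {
        if (cur == i) { cyc <- TRUE; break }
        cur <- parent[cur]
      }
      if (cyc) next
      ns <- childsum[p, ] + ccf[i, ]
      if (any(ns > ccf[p, ] + tol)) next
      parent[i] <<- p
      childsum[p, ] <<- ns
      rec(pos + 1L)
      childsum[p, ] <<- childsum[p, ] - ccf[i, ]
      parent[i] <<- 0L
    }
  }
  rec(1L)
  cnt
}

#' Relation between two clusters' multi-sample CCF profiles
#'
#' Under the crossing rule, cluster `a` can be an ancestor of cluster `b`
#' only if `a`'s CCF is at least `b`'s (within `tol`) in every shared
#' sample. If each exceeds the other beyond `tol` in different samples the
#' clusters sit on branching lineages; if both dominance directions hold
#' within tolerance the relation is ambiguous.
#'
#' @param a,b numeric CCF vectors named by sample.
#' @param tol absolute CCF tolerance.
#' @return one of `"a_can_contain_b"`, `"b_can_contain_a"`, `"branching"`,
#'   `"ambiguous"`.
#' @export
pairwise_relation <- function(a, b, tol = 0.05) {
  shared <- intersect(names(a)[!is.na(a)], names(b)[!is.na(b)])
  if (!length(shared)) {
    mc_stop("clusters share no sample with defined CCF", "mc_incomparable")
  }
  av <- a[shared]; bv <- b[shared]
  a_ge <- all(av >= bv - tol)
  b_ge <- all(bv >= av - tol)
  crossing <- any(av > bv + tol) && any(bv > av + tol)
  if (crossing) return("branching")
  if (a_ge && b_ge) return("ambiguous")
  if (a_ge) return("a_can_contain_b")
  "b_can_contain_a"
}

# Feasibility of a fully assigned parent vector (indices; 0 = root's "parent")
# against the sum's rule and ancestor dominance. Shared by the search.
# With `h = NULL` both rules use the fixed absolute tolerance `tol`;
# otherwise `h` is a per-(cluster, sample) noise halfwidth and the slack is
# h_i + h_j for dominance and h_p + sqrt(sum of children h^2) for the sum
# rule (independent measurement errors add in quadrature).
tree_assignment_ok <- function(parent_idx, ccf, tol, h = NULL) {
  k <- nrow(ccf)
  # ancestor dominance (subsumes the crossing rule for ancestor pairs)
  for (i in seq_len(k)) {
    cur <- parent_idx[i]
    while (cur != 0L) {
      slack <- if (is.null(h)) tol else h[i, ] + h[cur, ]
      if (any(ccf[i, ] > ccf[cur, ] + slack)) return(FALSE)
      cur <- parent_idx[cur]
    }
  }
  # sum rule at every node, every sample
  for (p in seq_len(k)) {
    kids <- which(parent_idx == p)
    if (length(kids)) {
      slack <- if (is.null(h)) tol
               else h[p, ] + sqrt(colSums(h[kids, , drop = FALSE]^2))
      if (any(colSums(ccf[kids, , drop = FALSE]) > ccf[p, ] + slack)) return(FALSE)
    }
  }
  TRUE
}

tree_assignment_score <- function(parent_idx, ccf, w, tol) {
  k <- nrow(ccf)
  violation <- 0
  for (p in seq_len(k)) {
    kids <- which(parent_idx == p)
    if (length(kids)) {
      violation <- violation + sum(pmax(0, colSums(ccf[kids, , drop = FALSE]) - ccf[p, ]))
    }
  }
  dist <- 0
  for (i in seq_len(k)) {
    if (parent_idx[i] != 0L) {
      dist <- dist + sum(w * (ccf[parent_idx[i], ] - ccf[i, ])^2)
    }
  }
  c(violation = violation, dist = dist)
}

#' Build a clone tree from cluster CCF profiles
#'
#' Enumerates rooted arborescences over the clusters (root = the truncal
#' cluster with CCF near 1 in every retained sample) satisfying, in every
#' sample, ancestor dominance (the crossing rule) and the sum's rule at
#' every node. Among constraint-satisfying trees, each node is attached to
#' its nearest dominating parent: the tree minimizing the purity-weighted
#' squared CCF distance between children and parents is returned, with
#' ties broken by total sum-rule violation and then lexicographically for
#' determinism. Parents taken by a node in any other constraint-satisfying
#' tree are recorded in `$ambiguous`.
#'
#' Samples with purity below `purity_cutoff` (5% by default) are excluded
#' from construction; samples with higher purity carry more weight, since
#' they measure CCF more accurately.
#'
#' @param ccf numeric matrix of cluster CCFs (rows: clusters, columns:
#'   samples), e.g. `$ccf` of [cluster_mutations()].
#' @param purities `"purity_estimates"` table or named purity vector.
#' @param tol absolute CCF tolerance for both rules.
#' @param se optional matrix of per-(cluster, sample) CCF standard errors
#'   (e.g. `$se` of [cluster_mutations()]). When given, the rule slacks
#'   adapt to the measurement precision (3 standard errors, floored at
#'   0.0075 and capped at `tol/2` per cluster) instead of using the fixed
#'   `tol` — deep sequencing resolves CCF differences far smaller than any
#'   fixed tolerance safe for noisy clusters.
#' @param mutation_counts named integer vector of cluster sizes, stored as
#'   branch mutation counts.
#' @param purity_cutoff samples below this purity are not used.
#' @param root_id optional explicit root cluster; by default the cluster
#'   whose minimum CCF across retained samples is highest (and at least
#'   `1 - 2 tol`).
#' @param max_feasible safety cap on the number of enumerated
#'   constraint-satisfying trees.
#' @return a `"clone_tree"` with attributes `ccf` (the input matrix over
#'   retained samples), `n_feasible`, and `alternatives` (parent maps of
#'   other constraint-satisfying trees, up to 50).
#' @export
build_tree <- function(ccf, purities, tol = 0.05, mutation_counts = NULL,
                       purity_cutoff = 0.05, root_id = NULL,
                       max_feasible = 50000L, se = NULL) {
  t <- if (inherits(purities, "purity_estimates")) purity_vector(purities) else purities
  keep <- colnames(ccf)[t[colnames(ccf)] >= purity_cutoff]
  if (!length(keep)) {
    mc_stop("no sample passes the purity cutoff for tree construction", "mc_infeasible_phylogeny")
  }
  ccf <- ccf[, keep, drop = FALSE]
  w <- t[keep]
  ids <- rownames(ccf)
  k <- length(ids)
  h <- NULL
  if (!is.null(se)) {
    h <- se[ids, keep, drop = FALSE]
    h[!is.finite(h)] <- tol / 2
    h <- clamp(3 * h, 0.0075, tol / 2)
  }

  if (is.null(root_id)) {
    mins <- apply(ccf, 1L, min, na.rm = TRUE)
    ok <- mins >= 1 - 2 * tol
    if (!any(ok)) {
      mc_stop("no truncal cluster (CCF ~ 1 in all retained samples) found to root the tree",
              "mc_infeasible_phylogeny")
    }
    root_id <- ids[ok][which.max(rowMeans(ccf, na.rm = TRUE)[ok])]
  }
  root <- match(root_id, ids)
  ccf[is.na(ccf)] <- 0

  if (k == 1L) {
    tr <- clone_tree(stats::setNames(NA_character_, ids),
                     branch_mutation_count = mutation_counts)
    attr(tr, "ccf") <- ccf
    attr(tr, "n_feasible") <- 1L
    attr(tr, "alternatives") <- list()
    return(tr)
  }

  # order non-root nodes by decreasing purity-weighted mean CCF, then name
  wmean <- as.vector(ccf %*% w) / sum(w)
  ord <- setdiff(order(-wmean, ids), root)

  # candidate parents: nodes that dominate (can contain) the child everywhere
  cand <- lapply(seq_len(k), function(i) {
    if (i == root) return(integer())
    js <- setdiff(seq_len(k), i)
    js <- js[vapply(js, function(j) {
      slack <- if (is.null(h)) tol else h[i, ] + h[j, ]
      all(ccf[j, ] >= ccf[i, ] - slack)
    }, logical(1))]
    js[order(-wmean[js], ids[js])]
  })
  if (any(vapply(setdiff(seq_len(k), root), function(i) length(cand[[i]]) == 0L, logical(1)))) {
    bad <- ids[setdiff(seq_len(k), root)][vapply(setdiff(seq_len(k), root),
                                                 function(i) length(cand[[i]]) == 0L, logical(1))]
    mc_stop(sprintf("no admissible parent for cluster(s) %s: crossing rule violated against every candidate",
                    paste(bad, collapse = ", ")), "mc_infeasible_phylogeny")
  }

  feasible <- list()
  overflow <- FALSE
  parent_idx <- integer(k)  # 0 = none assigned yet; root stays 0
  childsum <- matrix(0, k, ncol(ccf))

  has_cycle <- function(i, p) {
    cur <- p
    while (cur != 0L) {
      if (cur == i) return(TRUE)
      cur <- parent_idx[cur]
    }
    FALSE
  }

  childh2 <- matrix(0, k, ncol(ccf))
  recurse <- function(pos) {
    if (overflow) return()
    if (pos > length(ord)) {
      if (tree_assignment_ok(parent_idx, ccf, tol, h)) {
        if (length(feasible) >= max_feasible) {
          overflow <<- TRUE
        } else {
          feasible[[length(feasible) + 1L]] <<- parent_idx
        }
      }
      return()
    }
    i <- ord[pos]
    for (p in cand[[i]]) {
      if (has_cycle(i, p)) next
      new_sum <- childsum[p, ] + ccf[i, ]
      slack <- if (is.null(h)) tol else h[p, ] + sqrt(childh2[p, ] + h[i, ]^2)
      if (any(new_sum > ccf[p, ] + slack)) next  # sum-rule prune
      parent_idx[i] <<- p
      childsum[p, ] <<- new_sum
      if (!is.null(h)) childh2[p, ] <<- childh2[p, ] + h[i, ]^2
      recurse(pos + 1L)
      childsum[p, ] <<- childsum[p, ] - ccf[i, ]
      if (!is.null(h)) childh2[p, ] <<- childh2[p, ] - h[i, ]^2
      parent_idx[i] <<- 0L
    }
  }
  recurse(1L)

  if (!length(feasible)) {
    mc_stop("no tree satisfies the sum and crossing rules; revisit clustering or purity estimates",
            "mc_infeasible_phylogeny")
  }
  if (overflow) {
    warning(sprintf("more than %d constraint-satisfying trees; ambiguity sets may be incomplete",
                    max_feasible), call. = FALSE)
  }

  scores <- vapply(feasible, tree_assignment_score, numeric(2), ccf = ccf, w = w, tol = tol)
  lex <- vapply(feasible, function(p) paste(sprintf("%03d", p), collapse = ""), character(1))
  score_order <- order(scores["dist", ], scores["violation", ], lex)
  best <- score_order[1L]
  chosen <- feasible[[best]]

  ambiguous <- list()
  for (i in setdiff(seq_len(k), root)) {
    alts <- sort(unique(vapply(feasible, `[`, 0L, i)))
    alts <- setdiff(alts, chosen[i])
    if (length(alts)) ambiguous[[ids[i]]] <- ids[alts]
  }

  parent <- stats::setNames(ids[replace(chosen, chosen == 0L, NA_integer_)], ids)
  tr <- clone_tree(parent, branch_mutation_count = mutation_counts, ambiguous = ambiguous)
  attr(tr, "ccf") <- ccf
  attr(tr, "n_feasible") <- length(feasible)
  alt_keep <- setdiff(score_order, best)[seq_len(min(50L, length(feasible) - 1L))]
  attr(tr, "alternatives") <- lapply(feasible[alt_keep], function(p) {
    stats::setNames(ids[replace(p, p == 0L, NA_integer_)], ids)
  })
  tr
}
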