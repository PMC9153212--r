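# Independent oracles used across the suite. These re-derive expected
# results by brute force or from first principles, without calling the
# implementation they check.

# Forward BAF mixture model for a het SNP whose B allele sits on the minor
# haplotype of an (a, b) segment carried by a fraction cp of all cells.
oracle_baf_minor <- function(cp, a, b) {
  ((1 - cp) * 1 + cp * b) / (2 * (1 - cp) + (a + b) * cp)
}
oracle_folded_ai <- function(cp, a, b) abs(oracle_baf_minor(cp, a, b) - 0.5)

# Composite copy number of an (a, b) segment at prevalence cp.
oracle_composite <- function(cp, M) 2 * (1 - cp) + M * cp

# ---- brute-force clone-tree oracle -----------------------------------------
# Enumerates every parent function over the clusters (root fixed), filters
# acyclic ones, applies ancestor dominance and the sum rule at fixed
# tolerance, and selects by the same published criteria: smallest
# purity-weighted squared parent-child CCF distance, then total sum-rule
# violation, then the lexicographically smallest parent vector.
oracle_tree_feasible <- function(ccf, root, tol) {
  k <- nrow(ccf)
  others <- setdiff(seq_len(k), root)
  if (!length(others)) return(list(integer(k)))
  choices <- lapply(others, function(i) setdiff(seq_len(k), i))
  grid <- as.matrix(do.call(expand.grid, choices))
  out <- list()
  for (g in seq_len(nrow(grid))) {
    parent <- integer(k)
    parent[others] <- grid[g, ]
    # acyclic and rooted?
    ok <- TRUE
    for (i in others) {
      seen <- integer()
      cur <- i
      repeat {
        if (cur == root) break
        if (cur %in% seen || parent[cur] == 0L) { ok <- FALSE; break }
        seen <- c(seen, cur)
        cur <- parent[cur]
      }
      if (!ok) break
    }
    if (!ok) next
    # ancestor dominance on every ancestor-descendant pair
    for (i in others) {
      cur <- parent[i]
      while (ok && cur != 0L) {
        if (any(ccf[i, ] > ccf[cur, ] + tol)) ok <- FALSE
        cur <- parent[cur]
      }
      if (!ok) break
    }
    if (!ok) next
    # sum rule
    for (p in seq_len(k)) {
      kids <- which(parent == p)
      if (length(kids) && any(colSums(ccf[kids, , drop = FALSE]) > ccf[p, ] + tol)) {
        ok <- FALSE
        break
      }
    }
    if (ok) out[[length(out) + 1L]] <- parent
  }
  out
}

oracle_tree_select <- function(feasible, ccf, w) {
  dist <- vapply(feasible, function(parent) {
    d <- 0
    for (i in seq_len(nrow(ccf))) {
      if (parent[i] != 0L) d <- d + sum(w * (ccf[parent[i], ] - ccf[i, ])^2)
    }
    d
  }, numeric(1))
  viol <- vapply(feasible, function(parent) {
    v <- 0
    for (p in seq_len(nrow(ccf))) {
      kids <- which(parent == p)
      if (length(kids)) v <- v + sum(pmax(0, colSums(ccf[kids, , drop = FALSE]) - ccf[p, ]))
    }
    v
  }, numeric(1))
  lex <- vapply(feasible, function(p) paste(sprintf("%03d", p), collapse = ""), character(1))
  feasible[[order(dist, viol, lex)[1L]]]
}

# Random solvable tree instance: a random topology with Dirichlet clone
# fractions per sample, returning truth parents and the implied CCFs.
oracle_random_instance <- function(k, S, seed) {
  set.seed(seed)
  parent <- integer(k)
  for (i in seq_len(k)[-1L]) parent[i] <- sample.int(i - 1L, 1L)
  frac <- matrix(rgamma(k * S, shape = 1), k, S)
  frac <- sweep(frac, 2L, colSums(frac), `/`)
  subtree <- function(n) {
    out <- n
    repeat {
      add <- which(parent %in% out & !seq_len(k) %in% out)
      if (!length(add)) break
      out <- c(out, add)
    }
    out
  }
  ccf <- t(vapply(seq_len(k), function(n) colSums(frac[subtree(n), , drop = FALSE]),
                  numeric(S)))
  rownames(ccf) <- paste0("K", seq_len(k))
  colnames(ccf) <- paste0("S", seq_len(S))
  list(parent = parent, ccf = ccf)
}

# Shared, lazily computed recovery study (used by several acceptance
# blocks); kept small enough to run inside the test budget.
recovery_cache <- new.env(parent = emptyenv())
get_recovery_study <- function() {
  if (is.null(recovery_cache$res)) {
    recovery_cache$res <- suppressWarnings(run_recovery_study(n_replicates = 200L, seed = 20260924L))
  }
  recovery_cache$res
}

make_meta <- function(counts, tissue = "tumor") {
  data.frame(sample_id = counts$samples, patient_id = "P1",
             tissue_class = tissue, region_label = counts$samples,
             stringsAsFactors = FALSE)
}
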