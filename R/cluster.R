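# Group mutations into clusters sharing a per-sample CCF profile: a finite
# binomial mixture over multi-region read counts, fit by EM with k-means
# initialization and model size chosen by BIC. Clusters of any size are
# retained — small clusters can be critical for the phylogeny (a subclone
# may be distinguishable from its parent by a single SNV).

# Per-variant, per-sample factor q such that expected VAF = q * CCF:
# q = t * n / c under the variant's copy model.
vaf_per_ccf <- function(counts, purities, copy_models) {
  t <- if (inherits(purities, "purity_estimates")) purity_vector(purities) else purities
  samples <- counts$samples
  vids <- names(copy_models)[vapply(copy_models, function(m) isTRUE(m$resolved), logical(1))]
  q <- matrix(NA_real_, length(vids), length(samples), dimnames = list(vids, samples))
  for (vid in vids) {
    m <- copy_models[[vid]]
    q[vid, ] <- t[samples] * m$n / m$c[samples]
  }
  q
}

# Per-cluster log-likelihood of each variant at cluster profile phi
# (length S). The success probability mixes the model VAF with the residual
# per-read error rate e: p = e + (1 - 2e) * q * phi.
cluster_loglik <- function(alt, depth, q, phi, error_rate = 1e-3) {
  p <- error_rate + (1 - 2 * error_rate) * q * rep(phi, each = nrow(q))
  p[p > 1 - 1e-9] <- 1 - 1e-9
  ll <- alt * log(p) + (depth - alt) * log1p(-p)
  rowSums(ll, na.rm = TRUE)
}

em_binomial_mixture <- function(alt, depth, q, phi0, max_iter = 500L,
                                rel_tol = 1e-8, error_rate = 1e-3) {
  n <- nrow(alt); k <- nrow(phi0)
  phi <- phi0
  pi_k <- rep(1 / k, k)
  prev_ll <- -Inf
  ll_mat <- matrix(0, n, k)
  dq <- depth * q
  for (iter in seq_len(max_iter)) {
    for (j in seq_len(k)) ll_mat[, j] <- cluster_loglik(alt, depth, q, phi[j, ], error_rate)
    lw <- sweep(ll_mat, 2L, log(pi_k), `+`)
    tot <- log_sum_exp_rows(lw)
    ll <- sum(tot)
    r <- exp(lw - tot)
    pi_k <- colMeans(r)
    pi_k[pi_k < 1e-12] <- 1e-12
    pi_k <- pi_k / sum(pi_k)
    # quasi-ML update: E[alt] = depth * (e + (1 - 2e) q phi), so per
    # (cluster, sample) phi = sum r (alt - depth e) / ((1 - 2e) sum r depth q)
    for (j in seq_len(k)) {
      num <- colSums(r[, j] * (alt - depth * error_rate), na.rm = TRUE)
      den <- (1 - 2 * error_rate) * colSums(r[, j] * dq, na.rm = TRUE)
      upd <- num / den
      bad <- !is.finite(upd)
      upd[bad] <- phi[j, bad]
      upd[upd < 0] <- 0
      upd[upd > 1] <- 1
      phi[j, ] <- upd
    }
    if (is.finite(prev_ll) && abs(ll - prev_ll) <= rel_tol * (abs(prev_ll) + 1)) break
    prev_ll <- ll
  }
  for (j in seq_len(k)) ll_mat[, j] <- cluster_loglik(alt, depth, q, phi[j, ], error_rate)
  lw <- sweep(ll_mat, 2L, log(pi_k), `+`)
  tot <- log_sum_exp_rows(lw)
  list(phi = phi, pi = pi_k, loglik = sum(tot),
       assignment = max.col(lw, ties.method = "first"),
       converged = iter < max_iter, iterations = iter)
}

#' Cluster mutations by their multi-region CCF profiles
#'
#' Fits, for each candidate cluster count `k` in `k_range`, a `k`-component
#' mixture where a variant's likelihood is the product over samples of
#' `Binomial(alt; depth, expected VAF at the cluster CCF under the
#' variant's copy model)`. Components are initialized from k-means on the
#' raw CCF matrix (plus random restarts), the best of `n_restarts` fits is
#' kept per `k`, and `k` is chosen by BIC. Cluster labels are canonicalized
#' by descending mean CCF so output is seed-stable. Variants with partially
#' missing CCF rows (zero-depth cells) are assigned by maximum likelihood
#' over their covered samples.
#'
#' @param ccf a `"ccf_matrix"` from [compute_ccf_matrix()].
#' @param counts a [read_counts] object.
#' @param purities `"purity_estimates"` table or named purity vector.
#' @param copy_models named list of resolved `"copy_model"` objects.
#' @param k_range integer candidate numbers of clusters (default
#'   `1:min(15, n_variants)`, reflecting the 4-15 clones per patient seen in
#'   multi-region glioma cohorts).
#' @param seed integer seed; the fit is deterministic given it.
#' @param n_restarts EM initializations per `k` (k-means, the previous `k`'s
#'   fit with its worst-explained cluster split, and random variant rows).
#' @param max_iter,rel_tol EM convergence controls.
#' @param error_rate residual per-read error rate mixed into the success
#'   probability, `p = e + (1 - 2e) * expected VAF`.
#' @return object of class `"mutation_clusters"`: list with `assignment`
#'   (named vector variant -> cluster id), `ccf` (clusters x samples), `se`,
#'   `size`, `bic` (per `k`), `loglik`, `k`.
#' @export
cluster_mutations <- function(ccf, counts, purities, copy_models,
                              k_range = NULL, seed = 1L, n_restarts = 8L,
                              max_iter = 500L, rel_tol = 1e-8, error_rate = 1e-3) {
  stopifnot(inherits(ccf, "ccf_matrix"), inherits(counts, "read_counts"))
  q <- vaf_per_ccf(counts, purities, copy_models)
  vids <- rownames(q)
  if (!length(vids)) mc_stop("no variant with a resolved copy model to cluster", "mc_invalid_config")
  samples <- counts$samples
  alt <- counts$alt[vids, samples, drop = FALSE]
  depth <- alt + counts$ref[vids, samples, drop = FALSE]
  mode(alt) <- "numeric"; mode(depth) <- "numeric"
  # zero-depth cells carry no likelihood
  q[depth == 0] <- NA_real_
  x <- ccf$ccf[vids, samples, drop = FALSE]
  ximp <- x
  rm_ <- rowMeans(x, na.rm = TRUE)
  for (i in seq_len(nrow(ximp))) ximp[i, is.na(ximp[i, ])] <- rm_[i]
  ximp[is.na(ximp)] <- 0

  k_range <- k_range %||% seq_len(min(15L, length(vids)))
  if (!length(k_range)) mc_stop("empty k_range", "mc_invalid_config")
  k_range <- k_range[k_range <= length(vids)]

  k_range <- sort(k_range)
  hc <- stats::hclust(stats::dist(ximp), method = "ward.D2")
  with_seed(seed, {
    fits <- list()
    bic <- stats::setNames(rep(NA_real_, length(k_range)), k_range)
    worse_streak <- 0L
    prev_fit <- NULL
    for (k in k_range) {
      # initializations: k-means on the CCF rows; the best (k-1)-fit with its
      # worst-explained cluster split in two (keeps the likelihood close to
      # monotone in k); random variant rows as centers for the rest
      inits <- list()
      if (k == 1L) {
        inits <- list(matrix(colMeans(ximp), 1L))
      } else {
        km <- tryCatch(stats::kmeans(ximp, centers = k, nstart = 20L),
                       error = function(e) NULL)
        if (!is.null(km)) inits <- c(inits, list(clamp(km$centers, 0, 1)))
        # Ward hierarchical cut: deterministic and robust for the well
        # separated profiles deep sequencing produces
        hc_cut <- stats::cutree(hc, k = k)
        hcent <- t(vapply(split(seq_len(nrow(ximp)), hc_cut),
                          function(idx) colMeans(ximp[idx, , drop = FALSE]),
                          numeric(ncol(ximp))))
        inits <- c(inits, list(clamp(hcent, 0, 1)))
        if (!is.null(prev_fit)) {
          resp <- prev_fit$assignment
          deficit <- vapply(seq_len(nrow(prev_fit$phi)), function(j) {
            members <- which(resp == j)
            if (!length(members)) return(-Inf)
            -sum(cluster_loglik(alt[members, , drop = FALSE],
                                depth[members, , drop = FALSE],
                                q[members, , drop = FALSE], prev_fit$phi[j, ]))
          }, numeric(1))
          worst <- which.max(deficit)
          members <- which(resp == worst)
          extra <- if (length(members) >= 2L) {
            km2 <- tryCatch(stats::kmeans(ximp[members, , drop = FALSE], centers = 2L),
                            error = function(e) NULL)
            if (!is.null(km2)) clamp(km2$centers, 0, 1)
          }
          if (is.null(extra)) {
            extra <- rbind(prev_fit$phi[worst, ], clamp(prev_fit$phi[worst, ] + 0.05, 0, 1))
          }
          inits <- c(inits, list(rbind(prev_fit$phi[-worst, , drop = FALSE], extra)))
        }
        n_rand <- max(0L, n_restarts - length(inits))
        for (r in seq_len(n_rand)) {
          inits <- c(inits, list(ximp[sample.int(nrow(ximp), k), , drop = FALSE]))
        }
      }
      best <- NULL
      for (phi0 in inits) {
        fit <- em_binomial_mixture(alt, depth, q, phi0, max_iter, rel_tol, error_rate)
        if (is.null(best) || fit$loglik > best$loglik) best <- fit
      }
      if (is.null(best)) next
      if (!best$converged) {
        warning(sprintf("EM did not fully converge for k = %d; best-so-far kept", k),
                call. = FALSE)
      }
      npar <- (k - 1) + k * ncol(alt)
      bic[as.character(k)] <- -2 * best$loglik + npar * log(length(vids))
      fits[[as.character(k)]] <- best
      prev_fit <- best
      # BIC is convex-ish in k here; stop after two consecutive increases
      worse_streak <- if (bic[as.character(k)] > min(bic, na.rm = TRUE)) worse_streak + 1L else 0L
      if (worse_streak >= 2L) break
    }
    if (!length(fits)) mc_stop("no mixture fit succeeded", "mc_invalid_config")
    k_best <- names(fits)[which.min(bic[names(fits)])]
    fit <- fits[[k_best]]
  })

  # drop components that end up with no members, then canonicalize labels
  # by descending mean CCF profile
  occupied <- sort(unique(fit$assignment))
  fit$phi <- fit$phi[occupied, , drop = FALSE]
  fit$assignment <- match(fit$assignment, occupied)
  ord <- order(-rowMeans(fit$phi))
  relabel <- match(seq_along(ord), ord)
  cluster_ids <- paste0("C", seq_along(ord))
  assignment <- stats::setNames(cluster_ids[relabel[fit$assignment]], vids)
  phi <- fit$phi[ord, , drop = FALSE]
  dimnames(phi) <- list(cluster_ids, samples)

  size <- stats::setNames(as.integer(table(factor(assignment, levels = cluster_ids))),
                          cluster_ids)
  # standard errors of the cluster profiles from pooled member depth
  se <- phi
  for (j in seq_along(cluster_ids)) {
    members <- names(assignment)[assignment == cluster_ids[j]]
    dsum <- colSums(depth[members, , drop = FALSE] * q[members, , drop = FALSE]^2,
                    na.rm = TRUE)
    v <- phi[j, ] * colMeans(q[members, , drop = FALSE], na.rm = TRUE)
    se[j, ] <- ifelse(dsum > 0, sqrt(pmax(v * (1 - v), 0)) / sqrt(dsum), NA_real_)
  }

  structure(list(assignment = assignment, ccf = phi, se = se, size = size,
                 k = as.integer(k_best), bic = bic, loglik = fit$loglik),
            class = "mutation_clusters")
}

#' @export
print.mutation_clusters <- function(x, ...) {
  cat(sprintf("<mutation_clusters> k = %d over %d variants\n", x$k, length(x$assignment)))
  print(round(x$ccf, 3))
  invisible(x)
}
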