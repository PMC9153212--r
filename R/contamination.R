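# Detection and quantification of rare tumor subclones in histologically
# normal samples: a two-stage scheme gated on the founder mutation, with
# per-cluster Fisher-combined exact binomial tests under Benjamini-Hochberg
# false discovery rate control.

#' Build a per-site sequencing error model from a panel of normals
#'
#' Per-site error rate `(sum alt + 0.5) / (sum depth + 1)` across the panel
#' (a pseudocount-regularized pooled rate), floored at a global minimum.
#' Sites with systematic artifacts get correspondingly high rates, which
#' protects against false contamination calls at those sites.
#'
#' @param panel_counts a [read_counts] object holding the panel samples
#'   (uncontaminated normals; exclude the sample being tested).
#' @param floor global minimum rate (default 1e-6, the residual error of
#'   error-suppressed deep sequencing).
#' @param exclude sample ids to drop from the panel (for leave-one-out use).
#' @return object of class `"error_model"`: list with `rate` (named per-site
#'   vector, capped below 0.5), `floor`, `source`.
#' @export
build_error_model <- function(panel_counts, floor = 1e-6, exclude = character()) {
  stopifnot(inherits(panel_counts, "read_counts"))
  keep <- setdiff(panel_counts$samples, exclude)
  if (!length(keep)) {
    warning("empty panel of normals; falling back to the fixed floor rate", call. = FALSE)
    rate <- stats::setNames(rep(floor, nrow(panel_counts$alt)), rownames(panel_counts$alt))
    return(structure(list(rate = rate, floor = floor, source = "fixed"),
                     class = "error_model"))
  }
  alt <- rowSums(panel_counts$alt[, keep, drop = FALSE])
  depth <- alt + rowSums(panel_counts$ref[, keep, drop = FALSE])
  rate <- (alt + 0.5) / (depth + 1)
  rate <- clamp(pmax(rate, floor), floor, 0.5 - 1e-12)
  # Jeffreys posterior of the per-site rate; tests integrate over it
  # (beta-binomial) so panel sampling noise cannot inflate the test size
  a <- pmax(alt + 0.5, floor * (depth + 1))
  b <- depth - alt + 0.5
  ids <- rownames(panel_counts$alt)
  structure(list(rate = stats::setNames(rate, ids), floor = floor,
                 alpha = stats::setNames(a, ids), beta = stats::setNames(b, ids),
                 source = "panel_of_normals"),
            class = "error_model")
}

#' Estimate the tumor fraction of a normal sample from the founder VAF
#'
#' The same clonality inversion as [estimate_purity()] applied to a normal
#' sample: with a diploid founder locus the fraction of tumor cells is
#' `2 v`. A 95% binomial confidence interval on the VAF is propagated.
#'
#' @param counts a [read_counts] object containing the normal sample.
#' @param sample_id the normal sample to assess.
#' @param founder_id row id of the founder variant.
#' @param founder_model integer `c(M, n)` at the founder locus.
#' @return list with `fraction`, `ci` (length-2), `vaf`, `depth`,
#'   `low_confidence` (depth < 100).
#' @export
estimate_tumor_fraction <- function(counts, sample_id, founder_id,
                                    founder_model = c(M = 2L, n = 1L)) {
  alt <- counts$alt[founder_id, sample_id]
  depth <- alt + counts$ref[founder_id, sample_id]
  if (depth == 0) mc_stop("founder has no coverage in the tested sample", "mc_invalid_input")
  low <- depth < 100
  if (low) warning("founder depth < 100: low-confidence tumor fraction", call. = FALSE)
  M <- as.numeric(founder_model[[1L]]); n <- as.numeric(founder_model[[2L]])
  inv <- function(v) {
    den <- n - v * (M - 2)
    if (den <= 0) 1 else clamp(2 * v / den, 0, 1)
  }
  v <- alt / depth
  ci_v <- if (alt > 0) stats::binom.test(alt, depth)$conf.int else c(0, 3 / depth)
  list(fraction = inv(v), ci = c(inv(ci_v[1L]), inv(ci_v[2L])),
       vaf = v, depth = unname(depth), low_confidence = low)
}

# One-sided exact binomial upper tail: P(X >= alt | depth, rate).
binom_tail_p <- function(alt, depth, rate) {
  ifelse(depth == 0 | alt == 0, 1,
         stats::pbinom(alt - 1, depth, rate, lower.tail = FALSE))
}

# One-sided upper tail integrating the Beta posterior of the error rate:
# P(X >= k) under BetaBinomial(n, a, b). Falls back to the binomial tail
# when the error model carries no posterior (fixed source).
error_tail_p <- function(alt, depth, error_model, site) {
  if (is.null(error_model$alpha)) {
    return(binom_tail_p(alt, depth, error_model$rate[[site]]))
  }
  a <- error_model$alpha[[site]]
  b <- error_model$beta[[site]]
  vapply(seq_along(alt), function(i) {
    k <- alt[i]; n <- depth[i]
    if (n == 0 || k == 0) return(1)
    x <- 0:(k - 1)
    lower <- sum(exp(lchoose(n, x) + lbeta(x + a, n - x + b) - lbeta(a, b)))
    max(1 - lower, 1e-300)
  }, numeric(1))
}

#' Test a normal sample for residual tumor content
#'
#' Stage 1 gates on the founder mutation: a one-sided exact binomial test of
#' the founder alt count against the error model. Only if the founder is
#' significant (p < `alpha`) does stage 2 run: for every non-truncal
#' cluster, member-site one-sided binomial p-values are combined by Fisher's
#' method, Benjamini-Hochberg is applied across the clusters of the sample,
#' and a cluster is called present at `q <= q_threshold`. For present
#' clusters the CCF within the contaminating tumor population is computed
#' with the tumor fraction playing the role of purity. No cluster is ever
#' called in a sample whose founder test failed.
#'
#' @param counts a [read_counts] object with the tested normal sample.
#' @param sample_id the normal sample.
#' @param founder_id founder variant row id.
#' @param clusters a `"mutation_clusters"` object, or a named list mapping
#'   cluster id -> member variant ids.
#' @param error_model an `"error_model"` covering the tested sites.
#' @param founder_model integer `c(M, n)` at the founder locus.
#' @param q_threshold FDR level for cluster presence calls.
#' @param alpha founder-gate significance level.
#' @param exclude_clusters clusters not to test (the truncal cluster is
#'   already covered by the founder gate).
#' @return object of class `"contamination_call"`: list with `sample_id`,
#'   `founder_p`, `founder_vaf`, `tumor_fraction` (0 when the gate fails),
#'   `ci`, and `clusters` (data frame with `p`, `q`, `present`, `ccf`).
#' @export
test_presence <- function(counts, sample_id, founder_id, clusters, error_model,
                          founder_model = c(M = 2L, n = 1L),
                          q_threshold = 0.05, alpha = 0.05,
                          exclude_clusters = character()) {
  member_map <- if (inherits(clusters, "mutation_clusters")) {
    split(names(clusters$assignment), clusters$assignment)
  } else clusters
  member_map <- member_map[setdiff(names(member_map), exclude_clusters)]

  alt_f <- counts$alt[founder_id, sample_id]
  depth_f <- alt_f + counts$ref[founder_id, sample_id]
  p_f <- error_tail_p(alt_f, depth_f, error_model, founder_id)
  vaf_f <- if (depth_f > 0) alt_f / depth_f else NA_real_

  empty <- data.frame(cluster_id = character(), p = numeric(), q = numeric(),
                      present = logical(), ccf = numeric(), stringsAsFactors = FALSE)
  if (!is.finite(p_f) || p_f >= alpha) {
    return(structure(list(sample_id = sample_id, founder_p = p_f, founder_vaf = vaf_f,
                          tumor_fraction = 0, ci = c(0, 0), clusters = empty),
                     class = "contamination_call"))
  }
  tf <- estimate_tumor_fraction(counts, sample_id, founder_id, founder_model)

  rows <- lapply(names(member_map), function(cl) {
    members <- intersect(member_map[[cl]], rownames(counts$alt))
    members <- setdiff(members, founder_id)
    if (!length(members)) return(NULL)
    alt <- counts$alt[members, sample_id]
    depth <- alt + counts$ref[members, sample_id]
    ps <- vapply(seq_along(members), function(m) {
      error_tail_p(alt[m], depth[m], error_model, members[m])
    }, numeric(1))
    ps <- clamp(ps, 1e-300, 1)
    x2 <- -2 * sum(log(ps))
    p_comb <- stats::pchisq(x2, df = 2 * length(ps), lower.tail = FALSE)
    # cluster CCF within the contaminating population (diploid-equivalent)
    v <- sum(alt) / max(sum(depth), 1)
    ccf <- if (tf$fraction > 0) clamp(2 * v / tf$fraction, 0, 1.5) else NA_real_
    data.frame(cluster_id = cl, p = p_comb, ccf = ccf, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab) || !nrow(tab)) {
    tab <- empty
  } else {
    tab$q <- stats::p.adjust(tab$p, method = "BH")
    tab$present <- tab$q <= q_threshold
    tab$ccf[!tab$present] <- NA_real_
    tab <- tab[order(tab$q), c("cluster_id", "p", "q", "present", "ccf")]
    rownames(tab) <- NULL
  }
  structure(list(sample_id = sample_id, founder_p = p_f, founder_vaf = vaf_f,
                 tumor_fraction = tf$fraction, ci = tf$ci, clusters = tab),
            class = "contamination_call")
}

#' @export
print.contamination_call <- function(x, ...) {
  cat(sprintf("<contamination_call> %s: tumor fraction %.4f (founder p = %.3g)\n",
              x$sample_id, x$tumor_fraction, x$founder_p))
  if (nrow(x$clusters)) print(x$clusters)
  invisible(x)
}
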