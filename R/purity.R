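# Tumor purity from the clonality of a designated founder mutation
# (in diffuse midline glioma: the H3F3A or HIST1H3B K27M substitution,
# present in every cancer cell), plus the superclone check.

#' Estimate tumor purity from the founder mutation
#'
#' The founder mutation is clonal and truncal by definition (`f = g = 1`), so
#' its expected VAF is `v = t n / (2 + t (M - 2))` with `(M, n)` the copy
#' state and mutant multiplicity at the founder locus. Inverting,
#' \deqn{t = 2 v / (n - v (M - 2))}
#' which reduces to `t = 2 v` for a diploid founder locus. The standard error
#' is propagated from the binomial error of the VAF via the delta method, and
#' `t` is clipped into `[0, 1]` with a warning at the upper boundary.
#'
#' @param counts a [read_counts] object.
#' @param founder_id row identifier of the founder variant in `counts`.
#' @param founder_model integer vector `c(M, n)`: total copy state and mutant
#'   multiplicity at the founder locus (default diploid, `c(2, 1)`).
#' @param samples samples to estimate (default: all samples in `counts`).
#' @return data frame of class `"purity_estimates"` with columns `sample_id`,
#'   `t`, `standard_error`, `founder_vaf`, `depth`, `superclone_adjusted`.
#' @export
#' @examples
#' # a diploid founder VAF of 0.4 implies purity 0.8
estimate_purity <- function(counts, founder_id, founder_model = c(M = 2L, n = 1L),
                            samples = NULL) {
  stopifnot(inherits(counts, "read_counts"))
  samples <- samples %||% counts$samples
  M <- as.numeric(founder_model[[1L]])
  n <- as.numeric(founder_model[[2L]])
  alt <- counts$alt[founder_id, samples]
  ref <- counts$ref[founder_id, samples]
  depth <- alt + ref
  if (any(depth == 0)) {
    mc_stop(sprintf("founder variant '%s' has zero depth in sample(s) %s",
                    founder_id, paste(samples[depth == 0], collapse = ", ")),
            "mc_invalid_input")
  }
  v <- alt / depth
  denom <- n - v * (M - 2)
  if (any(denom <= 0)) {
    mc_stop(sprintf(
      "observed founder VAF %.3f exceeds what copy model (M=%g, n=%g) allows",
      v[which(denom <= 0)[1L]], M, n), "mc_impossible_model")
  }
  t_raw <- 2 * v / denom
  se_v <- sqrt(v * (1 - v) / depth)
  # delta method: dt/dv = 2 n / (n - v (M - 2))^2
  se_t <- 2 * n / denom^2 * se_v
  if (any(t_raw > 1)) {
    warning(sprintf("purity estimate > 1 clipped to 1 in sample(s) %s",
                    paste(samples[t_raw > 1], collapse = ", ")), call. = FALSE)
  }
  out <- data.frame(
    sample_id = samples,
    t = clamp(t_raw, 0, 1),
    standard_error = se_t,
    founder_vaf = v,
    depth = depth,
    superclone_adjusted = FALSE,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  class(out) <- c("purity_estimates", "data.frame")
  out
}

purity_vector <- function(purities) {
  stats::setNames(purities$t, purities$sample_id)
}

#' Detect and resolve superclones by rescaling purity
#'
#' A truncal mutation cluster or truncal CNV with apparent CCF > 1 (a
#' "superclone") is diagnostic of underestimated tumor purity. For each
#' sample whose maximal truncal CCF exceeds `1 + tol`, the purity is rescaled
#' upward by that maximum (CCF is proportional to `1/t`, so the rescaled
#' maximum becomes exactly 1) and the CCF matrix column is recomputed. A
#' rescale that would push `t` above 1 is unresolvable and raises an error.
#'
#' @param ccf a `ccf_matrix` object (see [compute_ccf_matrix()]) or a plain
#'   numeric matrix of CCFs (rows: variants or clusters, columns: samples).
#' @param purities a `"purity_estimates"` table.
#' @param truncal_ids rownames of `ccf` that are truncal (present in all
#'   regions); these drive the check.
#' @param tol tolerance above 1 before a CCF counts as a superclone.
#' @return list with `purities` (adjusted), `ccf` (recomputed) and `report`
#'   (data frame naming adjusted samples and scale factors).
#' @export
check_superclone <- function(ccf, purities, truncal_ids, tol = 0.05) {
  mat <- if (inherits(ccf, "ccf_matrix")) ccf$ccf else ccf
  se <- if (inherits(ccf, "ccf_matrix")) ccf$se else NULL
  missing_ids <- setdiff(truncal_ids, rownames(mat))
  if (length(missing_ids)) {
    mc_stop(sprintf("truncal ids not in CCF matrix: %s", paste(missing_ids, collapse = ", ")),
            "mc_invalid_input")
  }
  report <- data.frame(sample_id = character(), scale = numeric(), t_old = numeric(),
                       t_new = numeric(), stringsAsFactors = FALSE)
  for (s in purities$sample_id) {
    if (!s %in% colnames(mat)) next
    mx <- suppressWarnings(max(mat[truncal_ids, s], na.rm = TRUE))
    if (!is.finite(mx) || mx <= 1 + tol) next
    i <- which(purities$sample_id == s)
    t_new <- purities$t[i] * mx
    if (t_new > 1 + 1e-9) {
      mc_stop(sprintf(
        "sample %s: resolving superclone (max truncal CCF %.3f) needs purity %.3f > 1",
        s, mx, t_new), "mc_unresolvable_superclone")
    }
    purities$t[i] <- min(t_new, 1)
    purities$superclone_adjusted[i] <- TRUE
    mat[, s] <- mat[, s] / mx
    if (!is.null(se)) se[, s] <- se[, s] / mx
    report <- rbind(report, data.frame(sample_id = s, scale = mx,
                                       t_old = t_new / mx, t_new = t_new,
                                       stringsAsFactors = FALSE))
  }
  out_ccf <- if (inherits(ccf, "ccf_matrix")) {
    ccf$ccf <- mat
    ccf$se <- se
    ccf
  } else mat
  list(purities = purities, ccf = out_ccf, report = report)
}

#' Refine purity with the founder cluster's clonality
#'
#' A single founder site measures clonality with binomial noise
#' (sd of `2 v` at 2500X and purity 0.8 is about 0.02). The founder clone,
#' however, is defined by *all* truncal variants; rescaling the single-site
#' estimate so that the founder cluster's mean CCF becomes exactly 1 uses
#' every truncal site and is the two-sided generalization of the superclone
#' check (which only ever rescales upward).
#'
#' @param purities a `"purity_estimates"` table.
#' @param ccf CCF matrix (variants x samples) computed at the current purity.
#' @param truncal_ids rownames of the founder cluster's variants.
#' @return adjusted `"purity_estimates"` table (clipped to `[0, 1]`).
#' @export
refine_purity <- function(purities, ccf, truncal_ids) {
  mat <- if (inherits(ccf, "ccf_matrix")) ccf$ccf else ccf
  truncal_ids <- intersect(truncal_ids, rownames(mat))
  if (!length(truncal_ids)) return(purities)
  for (i in seq_len(nrow(purities))) {
    s <- purities$sample_id[i]
    if (!s %in% colnames(mat)) next
    m <- mean(mat[truncal_ids, s], na.rm = TRUE)
    if (is.finite(m) && m > 0) {
      purities$t[i] <- clamp(purities$t[i] * m, 0, 1)
    }
  }
  purities
}
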