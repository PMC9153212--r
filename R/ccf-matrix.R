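# Per-variant, per-sample cancer cell fractions from read counts, purities
# and resolved mutation copy models.

#' Compute the CCF matrix
#'
#' For each variant and sample, `CCF = g * f = v * c / (t * n)` using the
#' variant's resolved copy model (multiplicity `n`, per-sample composite
#' copy `c` and CNV CCF `f` of the overlapping segment; a diploid context
#' has `c = 2`, `f = 1`). Cells with zero depth are absent (`NA`), never
#' zero — "not covered" is distinct from "reference". The standard error is
#' propagated from the binomial error of the VAF. Raw CCFs may exceed 1 (up
#' to `cap`) before superclone resolution; see [check_superclone()].
#'
#' @param counts a [read_counts] object.
#' @param purities `"purity_estimates"` table or named purity vector.
#' @param copy_models named list of `"copy_model"` objects (see
#'   [enumerate_copy_models()]), one per variant. Variants without a resolved
#'   model are excluded and reported via the `"unresolved"` attribute.
#' @param cap upper cap on raw CCF values.
#' @return object of class `"ccf_matrix"`: list with `ccf` and `se` matrices
#'   (variants x samples).
#' @export
compute_ccf_matrix <- function(counts, purities, copy_models, cap = 1.5) {
  stopifnot(inherits(counts, "read_counts"))
  t <- if (inherits(purities, "purity_estimates")) purity_vector(purities) else purities
  samples <- counts$samples
  resolved <- vapply(copy_models, function(m) isTRUE(m$resolved), logical(1))
  unresolved <- names(copy_models)[!resolved]
  models <- copy_models[resolved]
  vids <- names(models)

  ccf <- matrix(NA_real_, length(vids), length(samples), dimnames = list(vids, samples))
  se <- ccf
  for (vid in vids) {
    m <- models[[vid]]
    alt <- counts$alt[vid, samples]
    depth <- alt + counts$ref[vid, samples]
    v <- ifelse(depth > 0, alt / depth, NA_real_)
    cc <- m$c[samples]
    raw <- v * cc / (t[samples] * m$n)
    ccf[vid, ] <- clamp(raw, 0, cap)
    se[vid, ] <- cc / (t[samples] * m$n) * sqrt(v * (1 - v) / depth)
  }
  out <- structure(list(ccf = ccf, se = se), class = "ccf_matrix")
  attr(out, "unresolved") <- unresolved
  out
}

#' @export
print.ccf_matrix <- function(x, ...) {
  cat(sprintf("<ccf_matrix> %d variants x %d samples\n", nrow(x$ccf), ncol(x$ccf)))
  un <- attr(x, "unresolved")
  if (length(un)) cat(sprintf("  %d unresolved variants excluded\n", length(un)))
  invisible(x)
}
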