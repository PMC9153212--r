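# Core algebra linking tumor purity, copy-number state, mutation multiplicity,
# variant allele fraction (VAF) and cancer cell fraction (CCF).
#
# A sample is a mixture of diploid normal cells (fraction 1 - t) and tumor
# cells (purity t). A CNV with integer state M is carried by a fraction f of
# tumor cells; a mutation with mutant-allele multiplicity n is carried by a
# fraction g of the CNV-bearing cells, so its CCF is g * f.

#' Composite copy number of a segment in a mixed sample
#'
#' The copy number a molecular assay measures at a locus is a mixture of the
#' diploid normal cells, the tumor cells without the CNV, and the tumor cells
#' carrying the CNV at integer state `M`:
#' \deqn{c = (1-t)\,2 + t\,[(1-f)\,2 + f M]}
#'
#' @param t tumor purity in `[0, 1]`.
#' @param f CNV cancer cell fraction in `[0, 1]` (fraction of tumor cells
#'   bearing the event).
#' @param M integer copy-number state of the CNV-bearing cells (0, 1, 3, ...).
#' @return composite copy number `c` (vectorized over its arguments).
#' @seealso [cnv_ccf()] for the inversion, [expected_vaf()] for the VAF model.
#' @export
#' @examples
#' composite_copy(0.6, 1, 3)  # clonal single-copy gain at purity 0.6 -> 2.6
composite_copy <- function(t, f, M) {
  stopifnot(all(t >= 0 & t <= 1), all(f >= 0 & f <= 1), all(M >= 0))
  (1 - t) * 2 + t * ((1 - f) * 2 + f * M)
}

#' CNV cancer cell fraction from the composite copy number
#'
#' Inverts [composite_copy()]: `f = (c - 2) / ((M - 2) t)`. A result outside
#' `[0, 1]` beyond `tol` is infeasible and signals that the assumed state `M`
#' is wrong; within `tol` the value is clamped into `[0, 1]`.
#'
#' `M = 2` is rejected: a copy-neutral LOH leaves `c = 2` for every `f`, so
#' its prevalence must be calibrated from allelic imbalance
#' (see [infer_segment_cp()]), not from `c`.
#'
#' @param c composite copy number.
#' @param M integer CNV state (not 2).
#' @param t tumor purity (> 0).
#' @param tol feasibility tolerance on `f`.
#' @return CNV CCF `f` in `[0, 1]`.
#' @export
cnv_ccf <- function(c, M, t, tol = 0.05) {
  if (any(M == 2)) {
    mc_stop("M = 2 leaves the composite copy number uninformative; resolve CN-LOH from allelic imbalance",
            "mc_undefined_state")
  }
  if (any(t <= 0)) mc_stop("cnv_ccf() requires tumor purity t > 0", "mc_no_tumor")
  f <- (c - 2) / ((M - 2) * t)
  if (any(f < -tol | f > 1 + tol)) {
    mc_stop(sprintf("inferred CNV CCF %.4g outside [0, 1] (tol %.3g): state M = %d infeasible",
                    f[which(f < -tol | f > 1 + tol)[1L]], tol, M[1L]),
            "mc_model_infeasible", f = f)
  }
  clamp(f, 0, 1)
}

#' Expected variant allele fraction under the general mixture model
#'
#' \deqn{v = t f g n / c}
#' where `n` is the mutant-allele multiplicity in the mutation-bearing cells
#' and `c` the composite copy number at the locus.
#'
#' @param t tumor purity.
#' @param f CNV CCF.
#' @param g fraction of CNV-bearing cells carrying the mutation.
#' @param n mutant-allele multiplicity (positive integer).
#' @param c composite copy number (> 0).
#' @return expected VAF.
#' @export
#' @examples
#' expected_vaf(0.8, 1, 1, 1, 2)  # clonal diploid mutation -> t / 2 = 0.4
expected_vaf <- function(t, f, g, n, c) {
  if (any(c <= 0)) mc_stop("composite copy number must be positive", "mc_invalid_input")
  t * f * g * n / c
}

#' Mutation-bearing fraction g from an observed VAF
#'
#' Inverts [expected_vaf()]: `g = v c / (t f n)`. The feasibility condition
#' `g` in `[0, 1]` (within `tol`) must hold or the assumed copy model is
#' wrong and an alternative model has to be considered; outside the tolerance
#' a classed `"mc_model_infeasible"` error is raised.
#'
#' @param v observed VAF.
#' @param c composite copy number.
#' @param t tumor purity.
#' @param f CNV CCF.
#' @param n mutant-allele multiplicity.
#' @param tol feasibility tolerance.
#' @return `g`, clamped into `[0, 1]`.
#' @export
mutation_g <- function(v, c, t, f, n, tol = 0.05) {
  if (any(t * f * n == 0)) {
    mc_stop("t * f * n = 0: mutation fraction g is undefined under this model", "mc_degenerate_model")
  }
  g <- v * c / (t * f * n)
  if (any(g < -tol | g > 1 + tol)) {
    mc_stop(sprintf("inferred g = %.4g outside [0, 1] (tol %.3g): consider an alternative copy model",
                    g[which(g < -tol | g > 1 + tol)[1L]], tol),
            "mc_model_infeasible", g = g)
  }
  clamp(g, 0, 1)
}

#' Cancer cell fraction of a mutation
#'
#' `CCF = g * f`: the fraction of tumor cells carrying the mutation is the
#' fraction of CNV-bearing cells with the mutation times the fraction of
#' tumor cells with the CNV.
#'
#' @param g mutation fraction within CNV-bearing cells, in `[0, 1]`.
#' @param f CNV CCF in `[0, 1]`.
#' @return CCF in `[0, 1]`.
#' @export
mutation_ccf <- function(g, f) {
  stopifnot(all(g >= 0 & g <= 1), all(f >= 0 & f <= 1))
  g * f
}

# Candidate (timing, n) pairs permitted by an allele-specific segment state.
# A mutation acquired after the CNV (or on a diploid background) has n = 1;
# one acquired before the CNV sits on the major or the minor haplotype and is
# carried at that haplotype's copy number.
copy_model_candidates <- function(major_cn = NULL, minor_cn = NULL) {
  if (is.null(major_cn)) {
    return(data.frame(timing = "diploid_context", n = 1L, stringsAsFactors = FALSE))
  }
  out <- data.frame(timing = "after_cnv", n = 1L, stringsAsFactors = FALSE)
  if (major_cn >= 1) {
    out <- rbind(out, data.frame(timing = "before_cnv_on_major", n = as.integer(major_cn)))
  }
  if (minor_cn >= 1) {
    out <- rbind(out, data.frame(timing = "before_cnv_on_minor", n = as.integer(minor_cn)))
  }
  out
}

#' Enumerate feasible mutation copy models for one variant
#'
#' Considers every (timing, multiplicity) pair permitted by the overlapping
#' segment's allele-specific state, fits the mutation-bearing fraction `g`
#' per sample, and keeps only candidates feasible (`g` in `[0, 1]` within
#' `tol`) in every sample where the variant is detected. A single model must
#' explain all regions because one mutation belongs to a single lineage:
#' independent recurrence of the same variant is vanishingly rare at somatic
#' mutation rates. Retained candidates are ranked by the summed squared
#' residual between observed and model-expected VAF; exact ties prefer
#' `after_cnv` (the parsimonious default) and then smaller multiplicity.
#'
#' @param variant_id row identifier of the variant in `counts`.
#' @param counts a [read_counts] object.
#' @param purities named vector of per-sample purity `t`.
#' @param segment `NULL` for a diploid context, or a list with `major_cn`,
#'   `minor_cn` and a per-sample data frame `per_sample` holding columns
#'   `sample`, `c` (composite copy) and `f` (CNV CCF).
#' @param tol feasibility tolerance on `g`.
#' @param detection list with `min_alt` and `min_vaf`: a variant is "detected"
#'   in a sample when both thresholds are met, and only detected samples
#'   constrain feasibility.
#' @return an object of class `"copy_model"`: a list with `variant_id`,
#'   `resolved`, the chosen `timing` and `n`, per-sample `g`, `c`, `f`, and a
#'   `candidates` data frame with the full ranking. When no candidate is
#'   feasible, `resolved` is `FALSE` and the variant is flagged, not dropped.
#' @export
enumerate_copy_models <- function(variant_id, counts, purities, segment = NULL,
                                  tol = 0.05,
                                  detection = list(min_alt = 3L, min_vaf = 0.002)) {
  stopifnot(inherits(counts, "read_counts"))
  samples <- counts$samples
  if (!variant_id %in% rownames(counts$alt)) {
    mc_stop(sprintf("variant '%s' not present in the count matrix", variant_id), "mc_invalid_input")
  }
  alt <- counts$alt[variant_id, samples]
  ref <- counts$ref[variant_id, samples]
  depth <- alt + ref
  if (all(depth == 0)) {
    mc_stop(sprintf("variant '%s' has no coverage in any sample", variant_id), "mc_invalid_input")
  }
  t <- purities[samples]
  v <- ifelse(depth > 0, alt / depth, NA_real_)
  detected <- !is.na(v) & alt >= detection$min_alt & v >= detection$min_vaf

  if (is.null(segment)) {
    cc <- rep(2, length(samples))
    ff <- rep(1, length(samples))
    cand <- copy_model_candidates()
  } else {
    per <- segment$per_sample
    idx <- match(samples, per$sample)
    cc <- per$c[idx]
    ff <- per$f[idx]
    cand <- copy_model_candidates(segment$major_cn, segment$minor_cn)
  }

  se_v <- ifelse(depth > 0, sqrt(pmax(v * (1 - v), 0) / depth), NA_real_)
  rows <- lapply(seq_len(nrow(cand)), function(i) {
    n <- cand$n[i]
    denom <- t * ff * n
    g <- ifelse(!is.na(v) & denom > 0, v * cc / denom, NA_real_)
    # feasibility slack widens with the binomial measurement error of g
    # (low-purity samples measure g with little precision)
    slack <- pmax(tol, 3 * se_v * cc / pmax(denom, 1e-12))
    # a detected variant in a sample where the model says no mutant copies can
    # exist (f = 0 or n = 0) is itself an infeasibility
    bad_support <- detected & (denom == 0)
    feas <- !any(bad_support) &&
      all(g[detected] >= -slack[detected] & g[detected] <= 1 + slack[detected], na.rm = TRUE)
    gcl <- clamp(g, 0, 1)
    vhat <- t * ff * gcl * n / cc
    rss <- sum((v[detected] - vhat[detected])^2, na.rm = TRUE)
    list(timing = cand$timing[i], n = n, feasible = feas, rss = rss, g = gcl)
  })
  candidates <- data.frame(
    timing = vapply(rows, `[[`, "", "timing"),
    n = vapply(rows, `[[`, 0L, "n"),
    feasible = vapply(rows, `[[`, NA, "feasible"),
    rss = vapply(rows, `[[`, 0, "rss"),
    stringsAsFactors = FALSE
  )
  # ranking: feasible first, then residual, ties prefer after_cnv then small n
  timing_pref <- match(candidates$timing,
                       c("after_cnv", "diploid_context", "before_cnv_on_major", "before_cnv_on_minor"))
  ord <- order(!candidates$feasible, candidates$rss, timing_pref, candidates$n)
  candidates <- candidates[ord, , drop = FALSE]
  rows <- rows[ord]
  rownames(candidates) <- NULL

  resolved <- any(candidates$feasible)
  best <- if (resolved) which(candidates$feasible)[1L] else NA_integer_
  out <- list(
    variant_id = variant_id,
    resolved = resolved,
    timing = if (resolved) candidates$timing[best] else NA_character_,
    n = if (resolved) candidates$n[best] else NA_integer_,
    g = if (resolved) stats::setNames(rows[[best]]$g, samples) else NULL,
    c = stats::setNames(cc, samples),
    f = stats::setNames(ff, samples),
    detected = stats::setNames(detected, samples),
    candidates = candidates
  )
  class(out) <- "copy_model"
  if (!resolved) {
    warning(sprintf("variant '%s': no feasible copy model; flagged unresolved", variant_id),
            call. = FALSE)
  }
  out
}

#' @export
print.copy_model <- function(x, ...) {
  cat(sprintf("<copy_model> %s: %s\n", x$variant_id,
              if (x$resolved) sprintf("%s (n = %d)", x$timing, x$n) else "UNRESOLVED"))
  print(x$candidates)
  invisible(x)
}
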