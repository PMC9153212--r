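# Allelic-imbalance calibration of CNV cellular prevalence, and early-vs-late
# timing of copy-number events against candidate tree placements.
#
# An unbalanced somatic copy change shifts the B-allele fraction (BAF) of
# germline heterozygous SNPs away from 0.5. With allele-specific state
# (a, b), a >= b, total M = a + b, carried by a fraction CP of *all* cells,
# the folded BAF deviation is
#     AI = CP (a - b) / (2 (2 + CP (M - 2)))
# while the composite copy number is c = 2 + CP (M - 2). Bi-allelic
# duplication (a = b) is AI-invisible and must be resolved from c alone.

# Model-expected folded BAF deviation for state (a, b) at prevalence cp.
expected_ai <- function(cp, a, b) {
  M <- a + b
  cp * (a - b) / (2 * (2 + cp * (M - 2)))
}

# Model-expected composite copy number for total state M at prevalence cp.
expected_c <- function(cp, M) 2 + cp * (M - 2)

default_cnv_states <- function() {
  list(c(1L, 0L), c(2L, 0L), c(2L, 1L), c(3L, 1L), c(2L, 2L), c(7L, 1L))
}

#' Infer CNV cellular prevalence from allelic imbalance
#'
#' For each candidate allele-specific state `(a, b)` with imbalance
#' `d = a - b` and total copy `M = a + b`:
#' * if `d > 0`, the prevalence is calibrated from the allelic imbalance,
#'   `CP = 4 AI / (d - 2 AI (M - 2))`, and scored by the agreement of the
#'   implied composite copy number with the observed one (for CN-LOH this
#'   is the departure of `c` from 2, since `c` is uninformative about CP);
#' * if `d = 0` (bi-allelic duplication), AI carries no signal and CP is
#'   determined from `c` alone, scored by the residual AI.
#'
#' Candidates whose CP falls outside `[0, 1]` beyond `tol` are rejected.
#' Exact score ties are broken toward the smallest total copy number: states
#' `(1+k, 1)` at prevalence `x` are observationally identical to `(2, 1)` at
#' prevalence `k x`, so when both fit, the fewest-copies explanation is
#' reported and the scaled alternatives are listed in `$alternatives`.
#'
#' @param ai folded BAF deviation in `[0, 0.5]`.
#' @param c observed composite copy number.
#' @param candidates list of integer pairs `c(a, b)` with `a >= b >= 0`.
#' @param tol CP feasibility tolerance.
#' @return list with `resolved`, best `a`, `b`, `cp`, `score`, and an
#'   `alternatives` data frame with one row per candidate.
#' @export
#' @examples
#' infer_segment_cp(0.25, 2 - 2 / 3)  # one-copy loss at CP = 2/3
infer_segment_cp <- function(ai, c, candidates = default_cnv_states(), tol = 0.05) {
  stopifnot(ai >= 0, ai <= 0.5 + 1e-9)
  rows <- lapply(candidates, function(st) {
    a <- st[[1L]]; b <- st[[2L]]
    stopifnot(a >= b, b >= 0)
    d <- a - b
    M <- a + b
    cp <- NA_real_
    score <- Inf
    feasible <- FALSE
    if (d > 0) {
      den <- d - 2 * ai * (M - 2)
      if (den > 0) {
        cp <- 4 * ai / den
        if (cp >= -tol && cp <= 1 + tol) {
          cp <- clamp(cp, 0, 1)
          feasible <- TRUE
          # residual of the second observable, in copy units: confounded
          # scaled states tie exactly and fall to the parsimony tie-break
          score <- abs(c - expected_c(cp, M))
        }
      }
    } else {
      if (M != 2) {
        cp <- (c - 2) / (M - 2)
        if (cp >= -tol && cp <= 1 + tol) {
          cp <- clamp(cp, 0, 1)
          feasible <- TRUE
          score <- 4 * ai  # residual imbalance a balanced state cannot produce
        }
      }
    }
    data.frame(a = a, b = b, M = M, cp = cp, score = score, feasible = feasible)
  })
  alternatives <- do.call(rbind, rows)
  # scores agreeing to 1e-7 are observationally tied (scaled gain states are
  # exactly confounded); parsimony then prefers the fewest copies
  ord <- order(!alternatives$feasible, round(alternatives$score, 7L),
               alternatives$M, -alternatives$a)
  alternatives <- alternatives[ord, , drop = FALSE]
  rownames(alternatives) <- NULL
  if (!any(alternatives$feasible)) {
    warning("no candidate CNV state fits the observed (AI, c); segment unresolved",
            call. = FALSE)
    return(list(resolved = FALSE, a = NA_integer_, b = NA_integer_, cp = NA_real_,
                score = NA_real_, alternatives = alternatives))
  }
  list(resolved = TRUE,
       a = alternatives$a[1L], b = alternatives$b[1L],
       cp = alternatives$cp[1L], score = alternatives$score[1L],
       alternatives = alternatives)
}

# Invert the folded-normal bias of mean |BAF - 0.5| under Gaussian BAF noise:
# given an observed mean deviation m and a known noise sd s, return the
# underlying deviation mu with E|N(mu, s)| = m (0 when m is below the
# noise floor s * sqrt(2/pi)).
debias_folded_ai <- function(m, sd) {
  if (sd <= 0) return(m)
  folded_mean <- function(mu) {
    sd * sqrt(2 / pi) * exp(-mu^2 / (2 * sd^2)) + mu * (1 - 2 * stats::pnorm(-mu / sd))
  }
  vapply(m, function(mi) {
    if (!is.finite(mi) || mi <= folded_mean(0)) return(0)
    if (mi >= folded_mean(0.5)) return(0.5)
    stats::uniroot(function(mu) folded_mean(mu) - mi, c(0, 0.5), tol = 1e-10)$root
  }, numeric(1))
}

#' Calibrate a table of segment observations
#'
#' Groups the observation table by segment (chrom/start/end), enforces one
#' allele-specific state `(a, b)` per segment across all samples of the
#' patient (choosing the state with the smallest summed calibration score
#' over samples carrying the event, ties to fewest copies), then computes
#' each sample's cellular prevalence CP under that state and the CNV CCF
#' `f = CP / t`.
#'
#' @param seg_obs data frame as read by [read_segments()]: columns `sample`,
#'   `chrom`, `start`, `end`, `c`, `folded_baf_dev`, `n_snps`.
#' @param purities a `"purity_estimates"` table or named purity vector.
#' @param candidates candidate states, as in [infer_segment_cp()].
#' @param tol CP feasibility tolerance.
#' @param baf_noise_sd known sd of per-SNP BAF noise; when positive, the
#'   folded-normal bias of the mean deviation is removed before calibration.
#' @param presence_cp minimum CP for a sample to vote on the shared state.
#' @return data frame of class `"cnv_segments"`: one row per (segment,
#'   sample) with columns `segment_id`, `sample`, `chrom`, `start`, `end`,
#'   `major_cn`, `minor_cn`, `c`, `ai`, `cp`, `f`.
#' @export
calibrate_segments <- function(seg_obs, purities, candidates = default_cnv_states(),
                               tol = 0.05, baf_noise_sd = 0, presence_cp = 0.05) {
  t <- if (inherits(purities, "purity_estimates")) purity_vector(purities) else purities
  seg_obs$segment_id <- paste0(seg_obs$chrom, ":", seg_obs$start, "-", seg_obs$end)
  out <- lapply(split(seg_obs, seg_obs$segment_id), function(d) {
    ai <- debias_folded_ai(d$folded_baf_dev, baf_noise_sd)
    fits <- lapply(seq_len(nrow(d)), function(i) {
      infer_segment_cp(min(ai[i], 0.5), d$c[i], candidates, tol)
    })
    # vote on one (a, b) per patient using samples that carry the event
    score_by_state <- NULL
    for (i in seq_along(fits)) {
      alt <- fits[[i]]$alternatives
      if (!fits[[i]]$resolved || !isTRUE(fits[[i]]$cp >= presence_cp)) next
      alt$key <- paste(alt$a, alt$b)
      alt$score[!alt$feasible] <- 10  # heavy penalty, still comparable
      score_by_state <- rbind(score_by_state, alt[, c("key", "a", "b", "M", "score")])
    }
    if (is.null(score_by_state)) {
      state <- c(NA_integer_, NA_integer_)
    } else {
      agg <- stats::aggregate(score ~ key + a + b + M, data = score_by_state, FUN = sum)
      agg <- agg[order(round(agg$score, 7L), agg$M, -agg$a), , drop = FALSE]
      state <- c(agg$a[1L], agg$b[1L])
    }
    cp <- rep(NA_real_, nrow(d))
    if (!is.na(state[1L])) {
      a <- state[1L]; b <- state[2L]; d_ab <- a - b; M <- a + b
      for (i in seq_len(nrow(d))) {
        cp[i] <- if (d_ab > 0) {
          den <- d_ab - 2 * ai[i] * (M - 2)
          if (den > 0) clamp(4 * ai[i] / den, 0, 1) else NA_real_
        } else {
          clamp((d$c[i] - 2) / (M - 2), 0, 1)
        }
      }
    }
    ts <- t[d$sample]
    data.frame(
      segment_id = d$segment_id, sample = d$sample,
      chrom = d$chrom, start = d$start, end = d$end,
      major_cn = state[1L], minor_cn = state[2L],
      c = d$c, ai = ai, cp = cp,
      f = ifelse(is.na(cp) | ts <= 0, NA_real_, clamp(cp / ts, 0, 1)),
      stringsAsFactors = FALSE, row.names = NULL
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("cnv_segments", "data.frame")
  res
}

#' Fit the tree placement (timing) of a CNV event
#'
#' A CNV placed on a tree node is carried by exactly the tumor cells
#' descending from that node, so its predicted cellular prevalence in sample
#' `s` is `purity_s * CCF_s(node)`. A truncal (early) event predicts
#' `CP = t` everywhere — the signature of clonality matching the tumor
#' purity in each region — while a late event tracks its branch's CCF
#' profile. A placement is feasible when predicted and observed CP agree
#' within `tol` in every sample; among feasible placements the one with the
#' smallest summed squared residual wins, and all residuals are reported.
#'
#' @param observed_cp named vector of observed CP per sample.
#' @param placements named list: candidate node id -> named vector of that
#'   node's CCF per sample.
#' @param purities `"purity_estimates"` table or named purity vector.
#' @param tol absolute CP agreement tolerance (default 0.1; array-derived CP
#'   noise dominates).
#' @return list with `resolved`, best `node`, and a `residuals` data frame
#'   (one row per placement with `rss` and `feasible`).
#' @export
fit_cnv_timing <- function(observed_cp, placements, purities, tol = 0.1) {
  t <- if (inherits(purities, "purity_estimates")) purity_vector(purities) else purities
  samples <- names(observed_cp)
  rows <- lapply(names(placements), function(node) {
    pred <- t[samples] * placements[[node]][samples]
    resid <- pred - observed_cp
    data.frame(node = node,
               rss = sum(resid^2, na.rm = TRUE),
               max_abs = max(abs(resid), na.rm = TRUE),
               feasible = all(abs(resid) <= tol, na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  residuals <- do.call(rbind, rows)
  residuals <- residuals[order(!residuals$feasible, residuals$rss), , drop = FALSE]
  rownames(residuals) <- NULL
  if (!any(residuals$feasible)) {
    return(list(resolved = FALSE, node = NA_character_, residuals = residuals))
  }
  list(resolved = TRUE, node = residuals$node[1L], residuals = residuals)
}
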