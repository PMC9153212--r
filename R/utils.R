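# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Signal a classed multiclone error
#'
#' All validation failures raise conditions subclassed under
#' `"multiclone_error"` so callers can catch specific failure modes
#' (e.g. `"mc_model_infeasible"`) rather than matching message text.
#'
#' @param message error message.
#' @param class condition subclass, e.g. `"mc_invalid_config"`.
#' @param ... fields attached to the condition object.
#' @keywords internal
#' @noRd
mc_stop <- function(message, class, ...) {
  stop(errorCondition(message, ..., class = c(class, "multiclone_error", "error")))
}

# Evaluate `code` under `set.seed(seed)` without disturbing the caller's RNG
# stream. Every stochastic operation in the package funnels through this, so
# identical (config, seed) pairs give identical output.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# Clamp x into [lo, hi].
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Stable log-sum-exp over the rows of a matrix (column loop beats apply()
# for the small K this package sees).
log_sum_exp_rows <- function(m) {
  mx <- m[, 1L]
  if (ncol(m) > 1L) for (j in 2:ncol(m)) {
    mj <- m[, j]
    gt <- mj > mx
    mx[gt] <- mj[gt]
  }
  mx + log(rowSums(exp(m - mx)))
}

is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) && x >= 1 && x == floor(x)

is_prob <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) && x > 0 && x < 1
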