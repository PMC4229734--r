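# broom-style tidiers for fitted result objects.

#' Tidy a fold-difference result
#'
#' @param x A `fold_diff` from [fold_difference()].
#' @param ... Unused.
#' @return Tibble with one row per random trial (`trial`, `random_count`,
#'   `fold`).
#' @method tidy fold_diff
#' @export
tidy.fold_diff <- function(x, ...) {
  tibble(
    trial = seq_len(x$n_trials),
    random_count = x$per_trial_counts,
    fold = x$per_trial_folds
  )
}

#' @rdname tidy.fold_diff
#' @return `glance()`: one-row summary tibble.
#' @method glance fold_diff
#' @export
glance.fold_diff <- function(x, ...) {
  tibble(
    mode = x$mode,
    test_size = x$test_size,
    observed = x$observed,
    n_trials = x$n_trials,
    mean_fold = x$mean_fold,
    sd_fold = x$sd_fold,
    direction = x$direction,
    floored_trials = x$floored_trials
  )
}

#' Tidy a Monte-Carlo p-value result
#'
#' @param x An `mc_pvalue` from [mc_pvalue()] or [pdi_degree_null()].
#' @param ... Unused.
#' @return One-row tibble.
#' @method tidy mc_pvalue
#' @export
tidy.mc_pvalue <- function(x, ...) {
  tibble(
    observed = x$observed,
    n_sims = x$n_sims,
    n_as_extreme = x$n_as_extreme,
    ci_level = x$ci_level,
    tail = x$tail,
    p_value = x$p_value,
    null_mean = x$null_mean %||% NA_real_
  )
}

#' @rdname tidy.mc_pvalue
#' @method glance mc_pvalue
#' @export
glance.mc_pvalue <- function(x, ...) {
  tidy.mc_pvalue(x)
}
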