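# Reporter assays: transcription-shutoff decay fitting and
# loading-normalized relative expression with significance tests.

#' Fit a half-life to a transcription-shutoff series
#'
#' Ordinary least squares of `ln(signal / loading)` on time; under
#' single-exponential decay the slope is `-ln2 / half_life`. A slope of
#' zero or above (no decay) is flagged rather than inverted. Scaling the
#' signal or the loading control by any positive constant only moves the
#' intercept, so the half-life is invariant to it.
#'
#' @param times Minutes since shutoff (>= 3 distinct values).
#' @param signal Target band intensities (> 0).
#' @param loading Loading-control intensities (> 0); scalar or per-point.
#' @return List: `half_life` (min, `NA` if non-decaying), `intercept`
#'   (log ratio at t = 0), `r_squared`, `decaying`.
#' @export
fit_shutoff_halflife <- function(times, signal, loading = 1) {
  assert_that(length(unique(times)) >= 3, "at least 3 time points required")
  assert_that(all(signal > 0) && all(loading > 0),
              "signals and loading must be > 0")
  ly <- log(signal / loading)
  fit <- lm(ly ~ times)
  slope <- coef(fit)[["times"]]
  tss <- sum((ly - mean(ly))^2)
  r2 <- if (tss == 0) 1 else 1 - sum(fit$residuals^2) / tss
  if (slope >= 0) {
    return(list(half_life = NA_real_, intercept = coef(fit)[[1]],
                r_squared = r2, decaying = FALSE))
  }
  list(half_life = log(2) / (-slope), intercept = coef(fit)[[1]],
       r_squared = r2, decaying = TRUE)
}

#' Average per-replicate half-lives by condition
#'
#' Arithmetic mean and sample (n-1) standard deviation of replicate
#' half-life fits, the way repeated shutoff determinations are reported.
#'
#' @param half_lives Numeric vector of per-replicate half-lives, minutes.
#' @param condition Condition label per value.
#' @return Tibble: `condition`, `n`, `mean_half_life`, `sd_half_life`
#'   (`NA` for a single determination).
#' @export
average_halflives <- function(half_lives, condition) {
  assert_that(length(half_lives) == length(condition) &&
                length(half_lives) >= 1,
              "half_lives and condition must be aligned and non-empty")
  tibble::tibble(half_life = half_lives, condition = condition) |>
    dplyr::group_by(condition) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_half_life = mean(half_life),
                     sd_half_life = sd(half_life),
                     .groups = "drop")
}

#' Loading-normalized relative reporter expression with t-tests
#'
#' Each replicate's target/loading ratio is divided by the mean ratio of
#' the control condition, so the control averages exactly 1.0; every other
#' condition is compared with the control by a two-sided unpaired Welch
#' t-test on the relative values.
#'
#' @param quants Tibble with columns `condition`, `replicate`,
#'   `target_signal`, `loading_signal`.
#' @param control_condition Name of the reference condition (>= 2
#'   replicates present).
#' @return List with `quants` (input plus `relative_value`) and `tests`
#'   (tibble `condition`, `mean_relative`, `p_value` vs control; `p_value`
#'   is `NA` with a note when both groups have zero variance).
#' @export
relative_expression <- function(quants, control_condition) {
  needed <- c("condition", "replicate", "target_signal", "loading_signal")
  assert_that(all(needed %in% names(quants)),
              paste("quants needs columns", paste(needed, collapse = ", ")))
  assert_that(sum(quants$condition == control_condition) >= 2,
              "control condition must be present with >= 2 replicates")
  assert_that(all(quants$target_signal > 0) && all(quants$loading_signal > 0),
              "signals must be > 0")
  ratio <- quants$target_signal / quants$loading_signal
  ctrl_mean <- mean(ratio[quants$condition == control_condition])
  quants$relative_value <- ratio / ctrl_mean
  ctrl <- quants$relative_value[quants$condition == control_condition]
  tests <- lapply(setdiff(unique(quants$condition), control_condition),
                  function(cond) {
    v <- quants$relative_value[quants$condition == cond]
    p <- if (var(v) + var(ctrl) == 0) {
      if (mean(v) == mean(ctrl)) 1 else NA_real_
    } else {
      t.test(v, ctrl)$p.value
    }
    tibble::tibble(condition = cond, mean_relative = mean(v), p_value = p)
  })
  tests <- dplyr::bind_rows(
    tibble::tibble(condition = control_condition, mean_relative = 1,
                   p_value = NA_real_),
    tests)
  list(quants = tibble::as_tibble(quants), tests = tests)
}
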