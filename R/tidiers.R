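# broom-style tidiers for fitted objects.

#' Tidy an axevol regression
#'
#' @param x an `axevol_ols` object.
#' @param ... unused.
#' @return A tibble with one row per term: `term`, `estimate`, `std.error`,
#'   `statistic`, `p.value`.
#' @export
tidy.axevol_ols <- function(x, ...) {
  x$coefficients
}

#' @rdname tidy.axevol_ols
#' @return For `glance()`: a one-row tibble with `r.squared`, `sigma`,
#'   `nobs`, `through_origin`.
#' @export
glance.axevol_ols <- function(x, ...) {
  tibble(
    r.squared = x$r.squared,
    sigma = summary(x$fit)$sigma,
    nobs = x$n,
    through_origin = x$through_origin
  )
}

#' Tidy a posterior chain into per-branch rate summaries
#'
#' @param x a `posterior_chain`.
#' @param prob credible-interval mass.
#' @param ... unused.
#' @return The [branch_rate_summary()] tibble.
#' @export
tidy.posterior_chain <- function(x, prob = 0.9, ...) {
  branch_rate_summary(x, prob = prob)
}

#' @rdname tidy.posterior_chain
#' @return For `glance()`: a one-row tibble with sample counts, posterior
#'   medians of `sigma2_0` and the shift count `k`, and the minimum scalar
#'   ESS.
#' @export
glance.posterior_chain <- function(x, ...) {
  e <- suppressWarnings(ess(x))
  tibble(
    n_samples = nrow(x$draws),
    n_generations = x$n_generations,
    burnin_frac = x$burnin_frac,
    sigma2_0_median = median(x$draws$sigma2_0),
    k_median = median(x$draws$k),
    k_mean = mean(x$draws$k),
    min_ess = min(e$ess)
  )
}
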