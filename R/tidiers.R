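# broom-style tidy()/glance() methods for the fitted objects.

#' @exportS3Method generics::tidy
tidy.dispersion_fit <- function(x, ...) {
  if (is.null(x$params)) {
    return(tibble(term = character(0), estimate = numeric(0)))
  }
  tibble(
    term = c("k_ex", "p_b", "delta_omega", "r2_0"),
    estimate = c(x$params$k_ex, x$params$p_b, x$params$delta_omega,
                 x$params$r2_0),
    unit = c("1/s", "fraction", "rad/s", "1/s")
  )
}

#' @exportS3Method generics::glance
glance.dispersion_fit <- function(x, ...) {
  tibble(delta_r2eff = x$delta_r2eff, chi2 = x$chi2,
         chi2_flat = x$chi2_flat, preferred = x$preferred,
         f_pvalue = x$f_pvalue, n_points = x$n_points, status = x$status)
}

#' @exportS3Method generics::tidy
tidy.hdx_fit <- function(x, ...) {
  tibble(term = c("rate", "amplitude", "offset"),
         estimate = c(x$rate, x$amplitude, x$offset),
         std.error = c(x$rate_se, NA_real_, NA_real_),
         unit = c("1/s", "intensity", "intensity"))
}

#' @exportS3Method generics::glance
glance.hdx_fit <- function(x, ...) {
  tibble(rate = x$rate, rate_se = x$rate_se, status = x$status,
         t_first = x$t_first)
}

#' @exportS3Method generics::tidy
tidy.diffusion_fit <- function(x, ...) {
  tibble(term = c("d_coeff", "i0"),
         estimate = c(x$d_coeff, x$i0),
         unit = c("m^2/s", "intensity"))
}

#' @exportS3Method generics::glance
glance.diffusion_fit <- function(x, ...) {
  tibble(d_coeff = x$d_coeff, fit_rmsd = x$fit_rmsd, status = x$status)
}

#' @exportS3Method generics::tidy
tidy.standard_curve <- function(x, ...) {
  tibble(term = c("slope", "intercept", "blank"),
         estimate = c(x$slope, x$intercept, x$blank))
}

#' @exportS3Method generics::glance
glance.standard_curve <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept, blank = x$blank,
         fit_r2 = x$fit_r2)
}

#' @exportS3Method generics::tidy
tidy.isoform_comparison <- function(x, ...) x$posthoc

#' @exportS3Method generics::glance
glance.isoform_comparison <- function(x, ...) {
  tibble(friedman_statistic = x$friedman$statistic, df = x$friedman$df,
         p_value = x$friedman$p_value, n = x$n, k = x$k)
}

#' @exportS3Method generics::tidy
tidy.rank_comparison <- function(x, ...) {
  tibble(isoform = x$flexibility_order,
         flexibility_rank = seq_along(x$flexibility_order),
         ige_rank = match(x$flexibility_order, x$ige_order))
}

#' @exportS3Method generics::glance
glance.rank_comparison <- function(x, ...) {
  tibble(spearman_rho = x$spearman_rho,
         is_exact_inverse = x$is_exact_inverse)
}
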