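# ggplot2 graphics for the main result types.

#' @exportS3Method ggplot2::autoplot
autoplot.dispersion_fit <- function(object, ...) {
  prof <- object$profile
  p <- ggplot2::ggplot(prof, ggplot2::aes(x = .data$nu_cpmg_hz,
                                          y = .data$r2eff)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$r2eff - .data$sigma,
                                          ymax = .data$r2eff + .data$sigma)) +
    ggplot2::labs(x = expression(nu[CPMG] ~ "(Hz)"),
                  y = expression(R[2 * ",eff"] ~ (s^-1)))
  if (!is.null(object$params) && object$status == "ok") {
    grid <- tibble(nu_cpmg_hz = seq(min(prof$nu_cpmg_hz),
                                    max(prof$nu_cpmg_hz), length.out = 80))
    grid$r2eff <- simulate_r2eff_exact(object$params, grid$nu_cpmg_hz,
                                       object$t_relax)
    p <- p + ggplot2::geom_line(data = grid, colour = "firebrick")
  }
  p
}

#' Bar plot of the threshold-based flexibility summary
#'
#' @param summary Tibble from [flexibility_summary()].
#' @return A ggplot object.
#' @export
plot_flexibility_summary <- function(summary) {
  ggplot2::ggplot(summary,
                  ggplot2::aes(x = factor(.data$threshold),
                               y = .data$percent_exceeding,
                               fill = .data$isoform)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = expression(Delta * R[2 * ",eff"] ~ "threshold" ~
                                   (s^-1)),
                  y = "% residues exceeding", fill = "isoform")
}

#' @exportS3Method ggplot2::autoplot
autoplot.hdx_fit <- function(object, series = NULL, ...) {
  stopifnot(!is.null(series))
  p <- ggplot2::ggplot(series, ggplot2::aes(x = .data$time_s,
                                            y = .data$intensity)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "time since mixing (s)", y = "peak intensity")
  if (object$status %in% c("ok", "too_slow")) {
    grid <- tibble(time_s = seq(min(series$time_s), max(series$time_s),
                                length.out = 100))
    grid$intensity <- object$amplitude * exp(-object$rate * grid$time_s) +
      object$offset
    p <- p + ggplot2::geom_line(data = grid, colour = "steelblue")
  }
  p
}

#' Box plot of the cohort specific-IgE distributions
#'
#' Boxes span the quartiles; whiskers cover the most extreme values within
#' 1.5 IQR of the box; points beyond are drawn individually.
#'
#' @param values Tibble with `isoform` and `kU_L` columns.
#' @return A ggplot object.
#' @export
plot_cohort_ige <- function(values) {
  ggplot2::ggplot(values, ggplot2::aes(x = .data$isoform, y = .data$kU_L,
                                       fill = .data$isoform)) +
    ggplot2::geom_boxplot(coef = 1.5, show.legend = FALSE) +
    ggplot2::labs(x = "isoform", y = "specific IgE (kU/L)")
}

#' @exportS3Method ggplot2::autoplot
autoplot.rank_comparison <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$flexibility_rank,
                                  y = .data$ige_rank,
                                  label = .data$isoform)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_text(vjust = -0.8) +
    ggplot2::labs(x = "flexibility rank (1 = most flexible)",
                  y = "IgE rank (1 = highest binding)")
}
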