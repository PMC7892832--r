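# PFG stimulated-echo diffusion: Stejskal-Tanner attenuation fits and
# Stokes-Einstein hydrodynamic radii, with the 20-best-residue aggregation.

BOLTZMANN_J_K <- 1.380649e-23

#' Stejskal-Tanner gradient attenuation
#'
#' Normalized stimulated-echo attenuation
#' `I/I0 = exp(-D * gamma^2 * g^2 * delta^2 * (Delta - delta/3))`.
#'
#' @param d Translational diffusion coefficient, m^2/s.
#' @param g Gradient strength(s), T/m.
#' @param delta_small Gradient pulse duration, s.
#' @param delta_big Diffusion time, s.
#' @param gamma Gyromagnetic ratio, rad/(s T) (1H default).
#' @return Attenuation ratio(s) in (0, 1].
#' @export
st_attenuation <- function(d, g, delta_small = 4e-3, delta_big = 0.160,
                           gamma = 2.6752e8) {
  exp(-d * st_b_factor(g, delta_small, delta_big, gamma))
}

# Stejskal-Tanner b-factor, s/m^2
st_b_factor <- function(g, delta_small, delta_big, gamma) {
  gamma^2 * g^2 * delta_small^2 * (delta_big - delta_small / 3)
}

#' Convert gradient strengths from G/cm to T/m
#'
#' @param g_G_per_cm Gradient strength in gauss per centimetre.
#' @return Gradient strength in tesla per metre (1 G/cm = 0.01 T/m).
#' @export
gauss_cm_to_T_m <- function(g_G_per_cm) g_G_per_cm * 0.01

#' Read a PFG diffusion intensity table
#'
#' Tab-separated with header columns `isoform residue aa gradient_G_per_cm
#' intensity`, preceded by comment header lines `#delta_ms <value>` and
#' `#Delta_ms <value>` carrying the gradient pulse duration and diffusion
#' time.
#'
#' @param path File path.
#' @return A tibble of records with attributes `delta_small` and
#'   `delta_big` (seconds).
#' @export
read_pfg_table <- function(path) {
  hdr <- readLines(path, n = 10)
  get_ms <- function(tag) {
    ln <- grep(paste0("^#", tag, "_ms"), hdr, value = TRUE)
    if (length(ln) == 0) return(NA_real_)
    as.numeric(strsplit(ln[1], "\\s+")[[1]][2]) / 1000
  }
  df <- read.delim(path, comment.char = "#",
                   colClasses = c(isoform = "character"))
  need <- c("isoform", "residue", "aa", "gradient_G_per_cm", "intensity")
  if (!all(need %in% names(df))) {
    stop("PFG table must have columns: ", paste(need, collapse = " "),
         call. = FALSE)
  }
  out <- as_tibble(df)
  attr(out, "delta_small") <- get_ms("delta")
  attr(out, "delta_big") <- get_ms("Delta")
  out
}

#' Fit a diffusion coefficient from a gradient attenuation series
#'
#' Log-space least squares: `log I(g) = log i0 - D * b(g)` is linear in `D`
#' with `b` the Stejskal-Tanner factor, so the fit is an ordinary linear
#' regression. The residual summary `fit_rmsd` is the root-mean-square of
#' residuals on the normalized-intensity scale, which ranks residues for
#' the best-`n` aggregation.
#'
#' @param gradients Gradient strengths, T/m, strictly increasing.
#' @param intensities Peak intensities (> 0), same length.
#' @param delta_small Gradient pulse duration, s.
#' @param delta_big Diffusion time, s.
#' @param gamma Gyromagnetic ratio, rad/(s T).
#' @return An object of class `diffusion_fit`: `d_coeff` (m^2/s), `i0`,
#'   `fit_rmsd`, `status`.
#' @export
fit_diffusion <- function(gradients, intensities, delta_small = 4e-3,
                          delta_big = 0.160, gamma = 2.6752e8) {
  keep <- intensities > 0
  g <- gradients[keep]
  y <- intensities[keep]
  res <- list(d_coeff = NA_real_, i0 = NA_real_, fit_rmsd = NA_real_,
              status = "ok")
  class(res) <- "diffusion_fit"
  if (length(g) < 4) {
    res$status <- "unfittable"
    return(res)
  }
  b <- st_b_factor(g, delta_small, delta_big, gamma)
  fit <- lm(log(y) ~ b)
  d <- -coef(fit)[[2]]
  i0 <- exp(coef(fit)[[1]])
  if (!is.finite(d) || d <= 0) {
    res$status <- "failed"
    return(res)
  }
  pred <- i0 * exp(-d * b)
  res$d_coeff <- d
  res$i0 <- i0
  res$fit_rmsd <- sqrt(mean(((y - pred) / i0)^2))
  res
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat("<diffusion_fit>", x$status, "\n")
  if (x$status == "ok") {
    cat(sprintf("  D = %.5g m^2/s, i0 = %.4g, fit RMSD = %.3g\n",
                x$d_coeff, x$i0, x$fit_rmsd))
  }
  invisible(x)
}

#' Stokes-Einstein hydrodynamic radius
#'
#' `R_h = k_B T / (6 pi eta D)`, reported in Angstrom.
#'
#' @param d Diffusion coefficient, m^2/s.
#' @param temperature_K Temperature, K.
#' @param viscosity_Pa_s Solvent viscosity, Pa s.
#' @return Hydrodynamic radius in Angstrom.
#' @examples
#' stokes_einstein_radius(1.3192e-10) # ~18.6 A
#' @export
stokes_einstein_radius <- function(d, temperature_K = 298.15,
                                   viscosity_Pa_s = 8.90e-4) {
  stopifnot(all(d > 0), temperature_K > 0, viscosity_Pa_s > 0)
  1e10 * BOLTZMANN_J_K * temperature_K / (6 * pi * viscosity_Pa_s * d)
}

#' Diffusion coefficient giving a stated hydrodynamic radius
#'
#' Inverse of [stokes_einstein_radius()]; used for simulation and round
#' trips.
#'
#' @param r_h Hydrodynamic radius, Angstrom.
#' @inheritParams stokes_einstein_radius
#' @return Diffusion coefficient in m^2/s.
#' @export
diffusion_from_radius <- function(r_h, temperature_K = 298.15,
                                  viscosity_Pa_s = 8.90e-4) {
  BOLTZMANN_J_K * temperature_K / (6 * pi * viscosity_Pa_s * r_h * 1e-10)
}

#' Fit diffusion for every residue in a PFG table
#'
#' @param records Tibble from [read_pfg_table()] (gradients in G/cm).
#' @param delta_small,delta_big,gamma Acquisition parameters; default to the
#'   table attributes when present.
#' @param temperature_K,viscosity_Pa_s Stokes-Einstein constants.
#' @return A tibble with one row per (isoform, residue): `d_coeff`, `i0`,
#'   `fit_rmsd`, `r_h`, `status`.
#' @export
fit_pfg_table <- function(records, delta_small = NULL, delta_big = NULL,
                          gamma = 2.6752e8, temperature_K = 298.15,
                          viscosity_Pa_s = 8.90e-4) {
  delta_small <- delta_small %||% attr(records, "delta_small") %||% 4e-3
  delta_big <- delta_big %||% attr(records, "delta_big") %||% 0.160
  if (is.na(delta_small) || is.na(delta_big)) {
    stop("delta_small / delta_big not given and absent from table header",
         call. = FALSE)
  }
  records |>
    dplyr::group_by(.data$isoform, .data$residue, .data$aa) |>
    dplyr::group_modify(function(d, key) {
      d <- dplyr::arrange(d, .data$gradient_G_per_cm)
      f <- fit_diffusion(gauss_cm_to_T_m(d$gradient_G_per_cm), d$intensity,
                         delta_small, delta_big, gamma)
      tibble(
        d_coeff = f$d_coeff, i0 = f$i0, fit_rmsd = f$fit_rmsd,
        r_h = if (f$status == "ok") {
          stokes_einstein_radius(f$d_coeff, temperature_K, viscosity_Pa_s)
        } else NA_real_,
        status = f$status
      )
    }) |>
    dplyr::ungroup()
}

#' Aggregate hydrodynamic radii over the best-fitting residues
#'
#' Selects the `n_best` successful per-residue fits with the smallest
#' residual RMS and returns the mean and standard deviation of their
#' hydrodynamic radii. With fewer than `n_best` successful fits, all are
#' used with a warning.
#'
#' @param fits Per-residue fit tibble from [fit_pfg_table()] (columns
#'   `fit_rmsd`, `r_h`, `status`).
#' @param n_best Number of residues to aggregate (default 20).
#' @return A tibble with `r_h_mean`, `r_h_sd`, `n_used`.
#' @export
aggregate_rh <- function(fits, n_best = 20) {
  ok <- fits[fits$status == "ok" & is.finite(fits$r_h), , drop = FALSE]
  if (nrow(ok) == 0) stop("no successful diffusion fits", call. = FALSE)
  if (nrow(ok) < n_best) {
    warning("fewer than ", n_best, " successful fits; aggregating over ",
            nrow(ok), call. = FALSE)
    n_best <- nrow(ok)
  }
  sel <- ok[order(ok$fit_rmsd), , drop = FALSE][seq_len(n_best), ]
  tibble(
    r_h_mean = mean(sel$r_h),
    r_h_sd = if (n_best > 1) sd(sel$r_h) else 0,
    n_used = n_best
  )
}
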