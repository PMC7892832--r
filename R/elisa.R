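# Indirect-ELISA IgE quantification: log-linear standard curve, specific-IgE
# conversion to kU/L, cohort summaries and the nonparametric comparisons
# (Shapiro-Wilk, Friedman + aligned post hoc, Spearman).

#' Read an ELISA plate table
#'
#' Comma-separated with header columns `row,col,content,analyte,replicate,
#' sample_id,a650`. Standards carry `content = "standard"` and
#' `analyte = "ng_per_ml:<value>"`; serum wells carry `content = "serum"`,
#' the isoform label in `analyte`, and the patient identifier in
#' `sample_id`.
#'
#' @param path File path.
#' @return A tibble of wells.
#' @export
read_elisa_plate <- function(path) {
  df <- utils::read.csv(path, colClasses = c(analyte = "character",
                                             sample_id = "character"))
  need <- c("row", "col", "content", "analyte", "replicate", "sample_id",
            "a650")
  if (!all(need %in% names(df))) {
    stop("plate table must have columns: ", paste(need, collapse = ","),
         call. = FALSE)
  }
  as_tibble(df)
}

#' Fit the log-linear ELISA standard curve
#'
#' Blank-subtracts the mean zero-standard absorbance, then fits an ordinary
#' least-squares line of blank-corrected mean A650 against log10
#' concentration over the non-zero standards:
#' `A = intercept + slope * log10(conc ng/mL)`.
#'
#' @param plate Plate tibble (see [read_elisa_plate()]).
#' @return An object of class `standard_curve`: `slope`, `intercept`,
#'   `blank`, `fit_r2`, `conc_range` (ng/mL span of the standards).
#' @export
fit_standard_curve <- function(plate) {
  std <- plate[plate$content == "standard", , drop = FALSE]
  conc <- as.numeric(sub("^ng_per_ml:", "", std$analyte))
  if (anyNA(conc)) stop("standard analyte labels must be ng_per_ml:<value>",
                        call. = FALSE)
  blank <- mean(std$a650[conc == 0])
  if (is.nan(blank)) blank <- 0
  nz <- conc > 0
  d <- dplyr::summarise(
    dplyr::group_by(tibble(conc = conc[nz], a650 = std$a650[nz]), .data$conc),
    a650 = mean(.data$a650), .groups = "drop"
  )
  if (nrow(d) < 3) stop("need >= 3 non-zero standard concentrations",
                        call. = FALSE)
  fit <- lm(I(a650 - blank) ~ log10(conc), data = d)
  slope <- coef(fit)[[2]]
  if (!is.finite(slope) || slope <= 0) {
    stop("invalid assay: non-positive standard-curve slope", call. = FALSE)
  }
  structure(list(slope = slope, intercept = coef(fit)[[1]], blank = blank,
                 fit_r2 = suppressWarnings(summary(fit)$r.squared),
                 conc_range = range(d$conc)),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "<standard_curve> A650 = %.4g + %.4g * log10(ng/mL) + blank %.4g (R^2 %.4f)\n",
    x$intercept, x$slope, x$blank, x$fit_r2))
  invisible(x)
}

#' Quantify specific IgE from triplicate absorbances
#'
#' Inverts the standard curve for the triplicate mean,
#' `conc = 10^((mean A650 - blank - intercept) / slope)`, then converts
#' ng/mL to kU/L via the IU mass equivalence (`iu_ng` ng per IU, kU/L =
#' IU/mL) and the serum dilution factor. The triplicate spread is
#' propagated through the inverse curve to a kU/L standard deviation.
#' Absorbances at/below blank report as below-detection; values above the
#' highest standard extrapolate with a flag.
#'
#' @param curve A [fit_standard_curve()] result.
#' @param a650 Numeric vector of replicate absorbances (typically 3).
#' @param serum_dilution Serum dilution factor (default 2 for 1:2 v/v).
#' @param iu_ng Nanograms of IgE per IU (default 2.4).
#' @return A tibble with `kU_L`, `kU_L_sd`, `conc_ng_mL`, `status`
#'   (`"ok"`, `"below_detection"`, `"extrapolated_high"`).
#' @export
quantify_specific_ige <- function(curve, a650, serum_dilution = 2,
                                  iu_ng = 2.4) {
  m <- mean(a650)
  corr <- m - curve$blank
  if (corr <= 0) {
    return(tibble(kU_L = NA_real_, kU_L_sd = NA_real_,
                  conc_ng_mL = NA_real_, status = "below_detection"))
  }
  inv <- function(a) 10^((a - curve$blank - curve$intercept) / curve$slope)
  conc <- inv(m)
  # delta-method propagation of the triplicate sd through the inverse curve
  a_sd <- if (length(a650) > 1) sd(a650) else 0
  conc_sd <- conc * log(10) / curve$slope * a_sd
  k <- serum_dilution / iu_ng
  status <- if (conc > curve$conc_range[2]) "extrapolated_high" else "ok"
  tibble(kU_L = conc * k, kU_L_sd = conc_sd * k, conc_ng_mL = conc,
         status = status)
}

#' Quantify every serum well group on a plate
#'
#' Fits the standard curve, then quantifies each (patient, isoform)
#' triplicate.
#'
#' @param plate Plate tibble (see [read_elisa_plate()]).
#' @inheritParams quantify_specific_ige
#' @return A tibble with one row per (sample_id, isoform): `kU_L`,
#'   `kU_L_sd`, `conc_ng_mL`, `status`.
#' @export
quantify_plate <- function(plate, serum_dilution = 2, iu_ng = 2.4) {
  curve <- fit_standard_curve(plate)
  plate[plate$content == "serum", , drop = FALSE] |>
    dplyr::group_by(sample_id = .data$sample_id, isoform = .data$analyte) |>
    dplyr::group_modify(function(d, key) {
      quantify_specific_ige(curve, d$a650, serum_dilution, iu_ng)
    }) |>
    dplyr::ungroup()
}

#' Cohort summary of specific-IgE values
#'
#' Per-isoform median, range, quartiles, Tukey whisker bounds (most extreme
#' data within 1.5 IQR of the box) and outliers, matching the usual
#' box-plot definition.
#'
#' @param values Tibble with columns `isoform` and `kU_L` (one row per
#'   patient and isoform).
#' @return A tibble with one row per isoform: `median`, `min`, `max`,
#'   `q25`, `q75`, `whisker_low`, `whisker_high`, `outliers` (list-column),
#'   `n`.
#' @export
cohort_summary <- function(values) {
  stopifnot(nrow(values) >= 1)
  values |>
    dplyr::group_by(.data$isoform) |>
    dplyr::group_modify(function(d, key) {
      x <- d$kU_L[is.finite(d$kU_L)]
      q <- quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
      iqr <- q[3] - q[1]
      lo <- min(x[x >= q[1] - 1.5 * iqr])
      hi <- max(x[x <= q[3] + 1.5 * iqr])
      tibble(median = q[2], min = min(x), max = max(x),
             q25 = q[1], q75 = q[3],
             whisker_low = lo, whisker_high = hi,
             outliers = list(x[x < lo | x > hi]), n = length(x))
    }) |>
    dplyr::ungroup()
}

#' Compare isoform IgE distributions across a cohort
#'
#' Runs the repeated-measures nonparametric battery on a complete
#' patients-by-isoforms matrix: per-isoform Shapiro-Wilk normality tests,
#' the Friedman rank test across isoforms, and Friedman-aligned pairwise
#' post-hoc comparisons (Dunn-type z on within-patient rank sums) with
#' Bonferroni adjustment.
#'
#' @param matrix Numeric matrix or data frame, patients in rows, isoforms in
#'   columns (column names are the isoform labels), no missing cells.
#' @param alpha Significance level used for the `significant` flags.
#' @return An object of class `isoform_comparison` with elements
#'   `shapiro` (tibble), `friedman` (tibble: `statistic`, `df`, `p_value`),
#'   `posthoc` (tibble of pairwise comparisons), `n`, `k`, `alpha`.
#' @export
compare_isoforms <- function(matrix, alpha = 0.05) {
  m <- as.matrix(matrix)
  if (anyNA(m)) stop("matrix must be complete (no missing cells)",
                     call. = FALSE)
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) stop("need >= 2 patients and >= 2 isoforms",
                           call. = FALSE)
  labs <- colnames(m) %||% paste0("col", seq_len(k))

  shapiro <- tibble(
    isoform = labs,
    p_value = apply(m, 2, function(x) {
      if (length(unique(x)) < 3) NA_real_ else shapiro.test(x)$p.value
    }),
    normal = .data$p_value > alpha
  )

  ranks <- t(apply(m, 1, rank))
  rank_sums <- colSums(ranks)
  if (all(apply(m, 1, function(x) length(unique(x)) == 1))) {
    fr_stat <- 0; fr_p <- 1
  } else {
    fr <- friedman.test(m)
    fr_stat <- unname(fr$statistic); fr_p <- fr$p.value
  }
  friedman <- tibble(statistic = fr_stat, df = k - 1, p_value = fr_p)

  # Dunn-type pairwise z-tests on mean within-patient ranks, Bonferroni
  se <- sqrt(k * (k + 1) / (6 * n))
  pairs <- utils::combn(k, 2)
  n_cmp <- ncol(pairs)
  posthoc <- purrr::map_dfr(seq_len(n_cmp), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    z <- abs(rank_sums[i1] - rank_sums[i2]) / n / se
    p_raw <- 2 * pnorm(z, lower.tail = FALSE)
    tibble(isoform_a = labs[i1], isoform_b = labs[i2], z = z,
           p_raw = p_raw, p_adj = min(1, p_raw * n_cmp))
  })
  posthoc$significant <- posthoc$p_adj < alpha

  structure(list(shapiro = shapiro, friedman = friedman, posthoc = posthoc,
                 n = n, k = k, alpha = alpha),
            class = "isoform_comparison")
}

#' @export
print.isoform_comparison <- function(x, ...) {
  cat(sprintf("<isoform_comparison> %d patients x %d isoforms\n", x$n, x$k))
  cat(sprintf("  Friedman chi^2 = %.4g (df %d), p = %.3g\n",
              x$friedman$statistic, x$friedman$df, x$friedman$p_value))
  sig <- x$posthoc[x$posthoc$significant, , drop = FALSE]
  cat("  significant pairs (Bonferroni, alpha ", x$alpha, "): ",
      if (nrow(sig)) paste(sig$isoform_a, "-", sig$isoform_b, collapse = ", ")
      else "none", "\n", sep = "")
  invisible(x)
}

#' Spearman rank correlation against a reference measurement
#'
#' Average-rank tie handling; a constant vector yields an undefined
#' correlation, reported as `NA` with `status = "undefined"`.
#'
#' @param x,y Paired numeric vectors, n >= 3.
#' @return A tibble with `rho`, `p_value`, `n`, `status`.
#' @export
spearman_vs_reference <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    return(tibble(rho = NA_real_, p_value = NA_real_, n = length(x),
                  status = "undefined"))
  }
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  tibble(rho = unname(ct$estimate), p_value = ct$p.value, n = length(x),
         status = "ok")
}
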