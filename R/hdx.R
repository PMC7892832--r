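# Hydrogen-deuterium exchange kinetics: single-exponential decay fits of
# time-resolved SOFAST-HMQC peak intensities and censoring-aware
# classification of accelerated residues between isoforms.

#' Read an H/D-exchange intensity table
#'
#' Tab-separated with header columns `isoform residue aa time_s intensity`;
#' `time_s` is the acquisition-midpoint time of each plane since D2O mixing.
#'
#' @param path File path.
#' @return A tibble of intensity records.
#' @export
read_hdx_table <- function(path) {
  df <- read.delim(path, colClasses = c(isoform = "character"))
  need <- c("isoform", "residue", "aa", "time_s", "intensity")
  if (!all(need %in% names(df))) {
    stop("HDX table must have columns: ", paste(need, collapse = " "),
         call. = FALSE)
  }
  as_tibble(df)
}

#' Fit a single-exponential H/D-exchange decay
#'
#' Least-squares fit of `I(t) = amplitude * exp(-rate * t) + offset` to a
#' per-residue intensity time series. The offset is fixed to zero unless the
#' series has flattened out at a late-time plateau exceeding
#' `3 * noise_floor`. Degenerate series are
#' censored rather than fitted: `status = "too_fast"` when the first plane
#' is already at/below the noise floor (the proton exchanged within the dead
#' time), `"too_slow"` when no appreciable decay occurs over the sampled
#' window.
#'
#' @param series Tibble with columns `time_s` (strictly increasing) and
#'   `intensity` (>= 4 points).
#' @param noise_floor Intensity noise floor used for censoring and the
#'   offset decision.
#' @return An object of class `hdx_fit`: `rate` (1/s), `amplitude`,
#'   `offset`, `rate_se`, `status` (`"ok"`, `"too_fast"`, `"too_slow"`,
#'   `"unfittable"`), and `t_first` (first-plane time, used for censored
#'   rate bounds).
#' @export
fit_hdx_decay <- function(series, noise_floor = 0) {
  t <- series$time_s
  y <- series$intensity
  res <- list(rate = NA_real_, amplitude = NA_real_, offset = 0,
              rate_se = NA_real_, status = "ok", t_first = t[1])
  class(res) <- "hdx_fit"
  if (length(t) < 4) {
    res$status <- "unfittable"
    return(res)
  }
  if (is.unsorted(t, strictly = TRUE)) {
    stop("time_s must be strictly increasing", call. = FALSE)
  }
  if (all(y <= noise_floor) || y[1] <= noise_floor) {
    res$status <- "too_fast"
    return(res)
  }
  n_tail <- max(2L, floor(length(y) / 4))
  plateau <- mean(tail(y, n_tail))
  # a plateau requires the series to have flattened out: high but still
  # decaying tails are slow exchange, not a baseline offset
  q3 <- mean(y[seq(length(y) - 2 * n_tail + 1, length(y) - n_tail)])
  flattened <- abs(q3 - plateau) < max(noise_floor, 1e-12)
  fit_offset <- flattened && plateau > 3 * noise_floor && noise_floor > 0
  # no-appreciable-decay guard: < 5% drop from the first to the last quarter
  head_mean <- mean(head(y, n_tail))
  if (head_mean > 0 && (head_mean - plateau) / head_mean < 0.05) {
    res$status <- "too_slow"
    res$rate <- 0
    res$amplitude <- head_mean
    return(res)
  }
  # log-linear initial estimate on the above-floor early points
  pos <- y > max(noise_floor, 0.02 * y[1])
  init_rate <- if (sum(pos) >= 2) {
    max(-coef(lm(log(y[pos]) ~ t[pos]))[[2]], 1e-8)
  } else {
    log(2) / (t[2] - t[1])
  }
  df <- data.frame(t = t, y = y)
  fit <- tryCatch({
    if (fit_offset) {
      nls(y ~ A * exp(-k * t) + c0, data = df,
          start = list(A = y[1] - plateau, k = init_rate, c0 = plateau),
          control = nls.control(maxiter = 200, warnOnly = TRUE,
                                scaleOffset = 1))
    } else {
      nls(y ~ A * exp(-k * t), data = df,
          start = list(A = y[1], k = init_rate),
          control = nls.control(maxiter = 200, warnOnly = TRUE,
                                scaleOffset = 1))
    }
  }, error = function(e) NULL)
  if (is.null(fit)) {
    res$status <- "unfittable"
    return(res)
  }
  cf <- coef(fit)
  se <- tryCatch(
    suppressWarnings(summary(fit)$coefficients["k", "Std. Error"]),
    error = function(e) NA_real_)
  res$rate <- max(unname(cf[["k"]]), 0)
  res$amplitude <- unname(cf[["A"]])
  res$offset <- if (fit_offset) unname(cf[["c0"]]) else 0
  res$rate_se <- se
  res
}

#' @export
print.hdx_fit <- function(x, ...) {
  cat("<hdx_fit>", x$status, "\n")
  if (x$status %in% c("ok", "too_slow")) {
    cat(sprintf("  rate = %.4g 1/s (se %.3g), amplitude = %.4g, offset = %.4g\n",
                x$rate, x$rate_se, x$amplitude, x$offset))
  }
  invisible(x)
}

#' Acceleration ratio between two H/D-exchange fits
#'
#' Ratio of exchange rates `rate_b / rate_a` (test over reference). When the
#' test series is censored as `too_fast` (decayed within the dead time) and
#' the reference is fitted, a lower bound is returned instead, using
#' `rate_b >= ln(2) / t_first` with `t_first` the first-plane midpoint time:
#' the proton must have lost at least half its signal by then.
#'
#' @param fit_a Reference-isoform [fit_hdx_decay()] result.
#' @param fit_b Test-isoform [fit_hdx_decay()] result.
#' @return A list with `ratio`, `censored` (logical: ratio is a lower
#'   bound), and `status` (`"ok"` or `"indeterminate"`).
#' @export
acceleration_ratio <- function(fit_a, fit_b) {
  ok_a <- fit_a$status == "ok"
  ok_b <- fit_b$status == "ok"
  if (ok_a && ok_b) {
    return(list(ratio = fit_b$rate / fit_a$rate, censored = FALSE,
                status = "ok"))
  }
  if (ok_a && fit_b$status == "too_fast") {
    bound <- (log(2) / fit_b$t_first) / fit_a$rate
    return(list(ratio = bound, censored = TRUE, status = "ok"))
  }
  list(ratio = NA_real_, censored = NA, status = "indeterminate")
}

#' Fit H/D-exchange decays for every residue in a table
#'
#' @param records Tibble of H/D-exchange records (see [read_hdx_table()]).
#' @param noise_floor Intensity noise floor passed to [fit_hdx_decay()].
#' @return A tibble with one row per (isoform, residue): `rate`,
#'   `amplitude`, `offset`, `rate_se`, `status`, `t_first`.
#' @export
fit_hdx_table <- function(records, noise_floor = 0) {
  records |>
    dplyr::group_by(.data$isoform, .data$residue, .data$aa) |>
    dplyr::group_modify(function(d, key) {
      f <- fit_hdx_decay(dplyr::arrange(d, .data$time_s), noise_floor)
      tibble(rate = f$rate, amplitude = f$amplitude, offset = f$offset,
             rate_se = f$rate_se, status = f$status, t_first = f$t_first)
    }) |>
    dplyr::ungroup()
}

#' Residues with accelerated H/D exchange between isoforms
#'
#' Residues present in both fit tables whose test/reference rate ratio (or
#' censored lower bound) meets the fold-acceleration cutoff. Residues whose
#' ratio is indeterminate (both censored, or a censored reference) are
#' excluded and reported via the returned attribute `indeterminate`.
#'
#' @param fits_ref Reference-isoform fit tibble from [fit_hdx_table()].
#' @param fits_test Test-isoform fit tibble.
#' @param cutoff Fold-acceleration cutoff (default 4).
#' @return Sorted integer vector of residue indices; attribute
#'   `indeterminate` lists excluded residues.
#' @export
accelerated_residue_set <- function(fits_ref, fits_test, cutoff = 4) {
  common <- intersect(fits_ref$residue, fits_test$residue)
  hits <- integer(0)
  indet <- integer(0)
  for (r in common) {
    a <- fits_ref[fits_ref$residue == r, ][1, ]
    b <- fits_test[fits_test$residue == r, ][1, ]
    fa <- list(status = a$status, rate = a$rate, t_first = a$t_first)
    fb <- list(status = b$status, rate = b$rate, t_first = b$t_first)
    ar <- acceleration_ratio(fa, fb)
    if (ar$status == "indeterminate") {
      indet <- c(indet, r)
    } else if (is.finite(ar$ratio) && ar$ratio >= cutoff) {
      hits <- c(hits, r)
    }
  }
  structure(sort(as.integer(hits)), indeterminate = sort(as.integer(indet)))
}
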