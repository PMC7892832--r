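# Combine per-isoform flexibility metrics and cohort IgE medians into the
# flexibility-versus-IgE rank comparison.

#' Build an isoform panel
#'
#' Pairs a per-isoform flexibility metric (by default the percentage of
#' residues with dispersion amplitude above the first threshold) with the
#' cohort IgE metric (median kU/L).
#'
#' @param flexibility Named numeric vector or tibble (`isoform`, `value`).
#' @param ige Named numeric vector or tibble (`isoform`, `value`).
#' @return A tibble with columns `isoform`, `flexibility`, `ige`.
#' @export
isoform_panel <- function(flexibility, ige) {
  to_tbl <- function(x, nm) {
    if (is.numeric(x) && !is.null(names(x))) {
      x <- tibble(isoform = names(x), value = unname(x))
    }
    stats::setNames(as_tibble(x)[, 1:2], c("isoform", nm))
  }
  out <- dplyr::inner_join(to_tbl(flexibility, "flexibility"),
                           to_tbl(ige, "ige"), by = "isoform")
  if (nrow(out) < length(unique(c(
    if (is.numeric(flexibility)) names(flexibility) else NULL)))) {
    nf_msg("isoform_panel: label sets differ; using the intersection")
  }
  if (nrow(out) < 3) {
    stop("need >= 3 isoforms for a meaningful rank comparison",
         call. = FALSE)
  }
  out
}

#' Rank isoforms by a metric, largest first
#'
#' Ties are broken lexicographically by label with a warning.
#'
#' @param metric Named numeric vector, or tibble with `isoform` and a value
#'   column.
#' @return Character vector of labels in descending metric order.
#' @export
rank_isoforms <- function(metric) {
  if (!is.numeric(metric)) {
    tb <- as_tibble(metric)
    metric <- stats::setNames(tb[[2]], tb[[1]])
  }
  if (length(metric) == 0) stop("empty metric", call. = FALSE)
  if (anyDuplicated(metric)) {
    warning("ties in metric; broken lexicographically by label",
            call. = FALSE)
  }
  names(sort(metric, decreasing = TRUE))
}

#' Flexibility-versus-IgE rank comparison
#'
#' Spearman rank correlation between the two per-isoform metrics, plus the
#' two descending orderings; `is_exact_inverse` is `TRUE` only when the
#' orderings are exact reversals (`rho = -1`, no ties). With a handful of
#' isoforms no p-value is meaningful, so none is reported.
#'
#' @param panel Tibble from [isoform_panel()].
#' @return An object of class `rank_comparison`: `flexibility_order`,
#'   `ige_order`, `spearman_rho`, `is_exact_inverse`.
#' @export
inverse_relation <- function(panel) {
  stopifnot(all(c("isoform", "flexibility", "ige") %in% names(panel)))
  has_ties <- anyDuplicated(panel$flexibility) || anyDuplicated(panel$ige)
  rho <- stats::cor(rank(panel$flexibility), rank(panel$ige))
  structure(list(
    flexibility_order = suppressWarnings(
      rank_isoforms(setNames(panel$flexibility, panel$isoform))),
    ige_order = suppressWarnings(
      rank_isoforms(setNames(panel$ige, panel$isoform))),
    spearman_rho = rho,
    is_exact_inverse = !has_ties && isTRUE(all.equal(rho, -1))
  ), class = "rank_comparison")
}

#' @export
print.rank_comparison <- function(x, ...) {
  cat("<rank_comparison>\n")
  cat("  flexibility: ", paste(x$flexibility_order, collapse = " > "), "\n")
  cat("  IgE:         ", paste(x$ige_order, collapse = " > "), "\n")
  cat(sprintf("  Spearman rho = %.3f%s\n", x$spearman_rho,
              if (x$is_exact_inverse) " (exact inverse ranking)" else ""))
  invisible(x)
}
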