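# Shared residue/sequence conventions for the 160-residue PR-10 scaffold
# (Gly1-Cys160), the secondary-structure map, and the analysis configuration.

#' Number of residues in the PR-10 scaffold analysed here
#'
#' The four Cor a 1.04 isoforms span Gly1-Cys160; residue numbering is 1-based
#' and matches the deposited sequence throughout the package.
#' @export
PR10_N_RESIDUES <- 160L

#' The canonical isoform labels
#' @export
PR10_ISOFORMS <- c("0401", "0402", "0403", "0404")

#' Secondary-structure map of the Cor a 1.04 fold
#'
#' Returns the ten secondary-structure elements of the canonical PR-10 fold
#' (seven-stranded antiparallel beta-sheet plus three alpha-helices) with
#' their residue ranges. Residues outside every element are loops/termini.
#'
#' @return A tibble with columns `element`, `start`, `end`, `kind`
#'   (`"strand"` or `"helix"`), ordered along the sequence.
#' @examples
#' default_sse_map()
#' @export
default_sse_map <- function() {
  tibble(
    element = c("beta1", "alpha1", "alpha2", "beta2", "beta3",
                "beta4", "beta5", "beta6", "beta7", "alpha3"),
    start   = c(2L, 15L, 26L, 39L, 51L, 64L, 79L, 96L, 112L, 131L),
    end     = c(11L, 24L, 34L, 45L, 59L, 75L, 87L, 106L, 123L, 155L),
    kind    = c("strand", "helix", "helix", "strand", "strand",
                "strand", "strand", "strand", "strand", "helix")
  )
}

#' Classify residues by secondary-structure element
#'
#' Maps 1-based residue indices to the containing secondary-structure
#' element, or `"loop"` for residues outside every element (loops and the
#' N-/C-termini). The mapping is total and deterministic: elements do not
#' overlap, so every residue has exactly one label.
#'
#' @param residue Integer vector of residue indices in `[1, 160]`.
#' @param sse_map Secondary-structure map as returned by [default_sse_map()].
#' @return Character vector of element names / `"loop"`, same length as
#'   `residue`.
#' @examples
#' sse_of_residue(c(5, 13, 160))
#' @export
sse_of_residue <- function(residue, sse_map = default_sse_map()) {
  if (!is.numeric(residue) || any(is.na(residue))) {
    stop("`residue` must be numeric without NA", call. = FALSE)
  }
  if (any(residue < 1L | residue > PR10_N_RESIDUES)) {
    stop("residue index out of range [1, ", PR10_N_RESIDUES, "]", call. = FALSE)
  }
  residue <- as.integer(residue)
  out <- rep("loop", length(residue))
  for (i in seq_len(nrow(sse_map))) {
    hit <- residue >= sse_map$start[i] & residue <= sse_map$end[i]
    out[hit] <- sse_map$element[i]
  }
  out
}

#' Default analysis configuration
#'
#' Central declarative configuration shared by all stages. Physical
#' constants default to water at 25 degC; thresholds and cutoffs follow the
#' comparative study design.
#'
#' Keys:
#' \describe{
#'   \item{`temperature_K`}{sample temperature for Stokes-Einstein, K.}
#'   \item{`viscosity_Pa_s`}{solvent viscosity, Pa s.}
#'   \item{`t_relax_s`}{CPMG constant-time relaxation delay, s.}
#'   \item{`flex_thresholds_s^-1`}{dispersion-amplitude thresholds for the
#'     flexibility summary, 1/s.}
#'   \item{`hdx_acceleration_cutoff`}{fold-acceleration defining the
#'     accelerated-exchange residue set.}
#'   \item{`seed`}{random seed for the synthetic generators.}
#' }
#' plus secondary keys: `gamma_1H_rad_s_T` (1H gyromagnetic ratio),
#' `delta_small_s` (gradient pulse length), `hdx_dead_time_s` (mixing dead
#' time), `serum_dilution`, `iu_ng` (IgE IU-to-ng mass equivalence).
#'
#' @return Named list of configuration values.
#' @export
default_config <- function() {
  list(
    temperature_K = 298.15,
    viscosity_Pa_s = 8.90e-4,
    t_relax_s = 0.030,
    `flex_thresholds_s^-1` = c(1, 3, 5, 10),
    hdx_acceleration_cutoff = 4,
    seed = 1L,
    gamma_1H_rad_s_T = 2.6752e8,
    delta_small_s = 4e-3,
    hdx_dead_time_s = 60,
    serum_dilution = 2,
    iu_ng = 2.4
  )
}

#' Read / write the analysis configuration
#'
#' Configuration files are YAML; unknown keys are kept, missing keys fall
#' back to [default_config()].
#'
#' @param path File path.
#' @param config Named list as produced by [default_config()].
#' @return `read_config()` returns the merged configuration list;
#'   `write_config()` returns `path` invisibly.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  utils::modifyList(default_config(), user)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Restraints-per-residue bookkeeping
#'
#' Divides restraint totals by the chain length and rounds to the reported
#' precision (one decimal), as used in structure-statistics tables.
#'
#' @param total Numeric vector of restraint counts.
#' @param n_residues Chain length (default the 160-residue PR-10 scaffold).
#' @param digits Decimal places to round to.
#' @return Numeric vector of per-residue values.
#' @examples
#' restraints_per_residue(5436) # 34.0
#' @export
restraints_per_residue <- function(total, n_residues = PR10_N_RESIDUES,
                                   digits = 1) {
  stopifnot(n_residues > 0)
  round(total / n_residues, digits)
}

#' Published restraint totals for the four Cor a 1.04 depositions
#'
#' Experimental-restraint totals from the structure-determination statistics
#' of the four hazelnut isoform depositions (6Y3H, 6Y3I, 6Y3K, 6Y3L),
#' usable as input to [restraints_per_residue()].
#'
#' @return A tibble with columns `isoform`, `pdb_id`, `total_restraints`,
#'   `long_range_restraints`.
#' @export
cor_a1_restraint_totals <- function() {
  tibble(
    isoform = PR10_ISOFORMS,
    pdb_id = c("6Y3H", "6Y3I", "6Y3K", "6Y3L"),
    total_restraints = c(5436L, 4470L, 4793L, 3066L),
    long_range_restraints = c(1350L, 926L, 997L, 491L)
  )
}

# internal: package-wide verbosity-aware message
nf_msg <- function(..., verbose = getOption("nmrflex.verbose", TRUE)) {
  if (isTRUE(verbose)) message(...)
  invisible(NULL)
}
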