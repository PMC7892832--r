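# Multi-model structure ensembles: PDB reading (via bio3d), Kabsch
# superposition, intra-ensemble pairwise RMSD and cross-structure RMSD.

#' Construct a structure ensemble
#'
#' An ordered multi-model coordinate set with shared atom ordering. Model 1
#' is the lowest-energy model by NMR deposition convention. Atom selections
#' are resolved by name: backbone = N, CA, C; heavy = all non-hydrogen
#' atoms. Hydrogens are retained in the object but excluded from both
#' selections.
#'
#' @param atoms Tibble of per-atom metadata with columns `resno`, `resid`,
#'   `elety` (PDB atom name), `element` (element symbol).
#' @param coords List of `n_models` numeric matrices (n_atoms x 3), Angstrom.
#' @return An object of class `structure_ensemble`.
#' @export
structure_ensemble <- function(atoms, coords) {
  stopifnot(length(coords) >= 1,
            all(vapply(coords, nrow, 1L) == nrow(atoms)))
  structure(list(atoms = as_tibble(atoms), coords = coords,
                 n_models = length(coords)),
            class = "structure_ensemble")
}

#' @export
print.structure_ensemble <- function(x, ...) {
  cat(sprintf("<structure_ensemble> %d model(s), %d atoms, residues %d-%d\n",
              x$n_models, nrow(x$atoms), min(x$atoms$resno),
              max(x$atoms$resno)))
  invisible(x)
}

#' Read a multi-model PDB file as a structure ensemble
#'
#' Parses MODEL/ENDMDL records via `bio3d::read.pdb`. Alternate locations
#' are resolved to the highest-occupancy copy; hydrogens are retained but
#' excluded from the backbone/heavy selections. Inconsistent atom sets
#' across models abort with an error.
#'
#' @param path PDB file path.
#' @return A [structure_ensemble()].
#' @export
read_pdb_ensemble <- function(path) {
  ragged <- FALSE
  pdb <- tryCatch(
    withCallingHandlers(
      bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
      warning = function(w) {
        if (grepl("multiple", conditionMessage(w))) ragged <<- TRUE
        invokeRestart("muffleWarning")
      }
    ),
    error = function(e) {
      stop("failed to read PDB ensemble: ", conditionMessage(e),
           call. = FALSE)
    }
  )
  if (ragged) {
    stop("inconsistent atom sets across models in ", path, call. = FALSE)
  }
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  idx <- as.integer(rownames(at))
  # resolve altLoc to highest occupancy per (chain, resno, atom name)
  occ <- if (!is.null(at$o)) ifelse(is.na(at$o), 1, at$o) else rep(1, nrow(at))
  keyv <- paste(at$chain, at$resno, at$elety)
  keep <- unlist(lapply(split(seq_along(keyv), keyv),
                        function(i) i[which.max(occ[i])]), use.names = FALSE)
  keep <- sort(keep)
  at <- at[keep, , drop = FALSE]
  idx <- idx[keep]
  element <- if (!is.null(at$elesy) && !all(is.na(at$elesy)) &&
                 !all(at$elesy == "")) {
    toupper(trimws(at$elesy))
  } else {
    # infer from the atom name: strip leading digits, take first letter
    substr(gsub("^[0-9]+", "", trimws(at$elety)), 1, 1)
  }
  atoms <- tibble(resno = at$resno, resid = at$resid,
                  elety = trimws(at$elety), element = element)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  cols <- as.vector(rbind(3 * idx - 2, 3 * idx - 1, 3 * idx))
  coords <- lapply(seq_len(nrow(xyz)), function(m) {
    matrix(xyz[m, cols], ncol = 3, byrow = TRUE)
  })
  structure_ensemble(atoms, coords)
}

#' Indices of the selected atoms of an ensemble
#'
#' @param e A [structure_ensemble()].
#' @param selection `"backbone"` (N, CA, C) or `"heavy"` (all non-hydrogen).
#' @return Integer indices into the ensemble's atom table.
#' @export
ensemble_selection <- function(e, selection = c("backbone", "heavy")) {
  selection <- match.arg(selection)
  if (selection == "backbone") {
    which(e$atoms$elety %in% c("N", "CA", "C"))
  } else {
    which(e$atoms$element != "H")
  }
}

#' Optimal-superposition (Kabsch) RMSD
#'
#' Minimum root-mean-square deviation between two paired coordinate sets
#' over all proper rigid motions (rotation + translation), computed by the
#' Kabsch/SVD algorithm with the proper-rotation (det = +1) correction.
#'
#' @param a,b Numeric matrices (n x 3), n >= 3, rows paired.
#' @return RMSD in the coordinate units (Angstrom for structures).
#' @export
kabsch_rmsd <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) != nrow(b) || ncol(a) != 3 || ncol(b) != 3) {
    stop("coordinate sets must be paired n x 3 matrices", call. = FALSE)
  }
  if (nrow(a) < 3) stop("need at least 3 atoms", call. = FALSE)
  ac <- sweep(a, 2, colMeans(a))
  bc <- sweep(b, 2, colMeans(b))
  if (max(abs(ac)) == 0 || max(abs(bc)) == 0) {
    stop("degenerate coordinate set", call. = FALSE)
  }
  h <- crossprod(ac, bc)           # t(ac) %*% bc
  s <- svd(h)
  d <- sign(det(s$u %*% t(s$v)))
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  sqrt(mean(rowSums((ac %*% rot - bc)^2)))
}

#' Mean pairwise RMSD within an ensemble
#'
#' Mean of [kabsch_rmsd()] over all unordered model pairs on the selected
#' atoms; each pair is superposed independently (no mean-structure fit).
#'
#' @param e A [structure_ensemble()] with >= 2 models.
#' @param selection `"backbone"` (N, CA, C) or `"heavy"` (non-hydrogen).
#' @return A tibble with `selection`, `rmsd_mean`, `rmsd_sd`, `n_pairs`,
#'   `n_atoms`.
#' @export
ensemble_pairwise_rmsd <- function(e, selection = c("backbone", "heavy")) {
  selection <- match.arg(selection)
  if (e$n_models < 2) stop("need at least 2 models", call. = FALSE)
  sel <- ensemble_selection(e, selection)
  pairs <- utils::combn(e$n_models, 2)
  vals <- apply(pairs, 2, function(p) {
    kabsch_rmsd(e$coords[[p[1]]][sel, , drop = FALSE],
                e$coords[[p[2]]][sel, , drop = FALSE])
  })
  tibble(selection = selection, rmsd_mean = mean(vals),
         rmsd_sd = if (length(vals) > 1) sd(vals) else 0,
         n_pairs = ncol(pairs), n_atoms = length(sel))
}

#' RMSD between two structures (one model each)
#'
#' Kabsch RMSD between a chosen model of each ensemble on their common
#' selected atoms, matched by residue number and atom name. Model 1 (the
#' lowest-energy deposition model) is the default pick for both.
#'
#' @param a,b [structure_ensemble()] objects.
#' @param model_a,model_b Model indices to compare.
#' @param selection `"backbone"` or `"heavy"`.
#' @return A tibble with `rmsd`, `n_atoms`.
#' @export
cross_structure_rmsd <- function(a, b, model_a = 1, model_b = 1,
                                 selection = c("backbone", "heavy")) {
  selection <- match.arg(selection)
  sel_a <- ensemble_selection(a, selection)
  sel_b <- ensemble_selection(b, selection)
  key_a <- paste(a$atoms$resno[sel_a], a$atoms$elety[sel_a])
  key_b <- paste(b$atoms$resno[sel_b], b$atoms$elety[sel_b])
  common <- intersect(key_a, key_b)
  if (length(common) < 3) stop("no common residues/atoms", call. = FALSE)
  ia <- sel_a[match(common, key_a)]
  ib <- sel_b[match(common, key_b)]
  tibble(
    rmsd = kabsch_rmsd(a$coords[[model_a]][ia, , drop = FALSE],
                       b$coords[[model_b]][ib, , drop = FALSE]),
    n_atoms = length(common)
  )
}

#' Write a structure ensemble to a PDB file
#'
#' Emits standard MODEL/ATOM/ENDMDL records (PDB v3 fixed columns), one
#' MODEL block per ensemble member.
#'
#' @param e A [structure_ensemble()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb_ensemble <- function(e, path) {
  con <- file(path, "w")
  on.exit(close(con))
  at <- e$atoms
  for (m in seq_len(e$n_models)) {
    writeLines(sprintf("MODEL     %4d", m), con)
    xyz <- e$coords[[m]]
    lines <- sprintf(
      "ATOM  %5d %-4s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      seq_len(nrow(at)),
      ifelse(nchar(at$elety) < 4, paste0(" ", at$elety), at$elety),
      at$resid, at$resno, xyz[, 1], xyz[, 2], xyz[, 3], at$element
    )
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
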