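#' Load atomic coordinates from a PDB file
#'
#' Reads a structure with bio3d, drops hydrogens (crystal structures at
#' ribosome resolutions lack reliable hydrogen positions), and resolves
#' alternate locations by keeping the highest-occupancy atom of each
#' (chain, residue, atom name) group. Author residue numbering is
#' preserved so 23S positions like 2451 address residues directly.
#'
#' @param path PDB (or mmCIF, where supported by the installed bio3d) file.
#' @return Tibble with one row per atom: `chain`, `resno`, `resid`,
#'   `elety`, `elesy`, `x`, `y`, `z`, `o`, `b`.
#' @export
load_structure <- function(path) {
  if (!file.exists(path)) ptc_abort(sprintf("File not found: %s", path))
  pdb <- if (grepl("\\.cif$", path, ignore.case = TRUE) &&
             "read.cif" %in% getNamespaceExports("bio3d")) {
    bio3d::read.cif(path, verbose = FALSE)
  } else {
    bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
  }
  at <- tibble::as_tibble(pdb$atom)
  if (nrow(at) == 0) ptc_abort("No atoms parsed from file")
  elesy <- toupper(trimws(as.character(at$elesy)))
  ## fall back to the atom-name convention where the element column is blank
  no_elem <- is.na(elesy) | elesy == ""
  elesy[no_elem] <- substr(gsub("^[0-9]+", "", trimws(at$elety[no_elem])), 1, 1)
  at$elesy <- elesy
  at <- at[!(elesy %in% c("H", "D")), , drop = FALSE]
  if (nrow(at) == 0) {
    ptc_abort("No heavy atoms remain after hydrogen filtering",
              class = "ptcflex_empty_selection")
  }
  at$o[is.na(at$o)] <- 1
  at |>
    dplyr::group_by(.data$chain, .data$resno, .data$insert, .data$elety) |>
    dplyr::slice_max(.data$o, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$chain, .data$resno, .data$eleno) |>
    dplyr::select("chain", "resno", "resid", "elety", "elesy",
                  "x", "y", "z", "o", "b")
}

#' Geometric center of a set of atoms
#'
#' Unweighted mean of the heavy-atom coordinates, the "average center"
#' used for nucleotide and tRNA reference points.
#'
#' @param atoms Tibble with `x`, `y`, `z` columns (>= 1 row).
#' @return Named numeric vector `c(x, y, z)` in Angstrom.
#' @export
geometric_center <- function(atoms) {
  stopifnot(is.data.frame(atoms), all(c("x", "y", "z") %in% names(atoms)))
  if (nrow(atoms) == 0) ptc_abort("Empty atom selection", class = "ptcflex_empty_selection")
  if (!all(is.finite(c(atoms$x, atoms$y, atoms$z)))) ptc_abort("Non-finite coordinates")
  c(x = mean(atoms$x), y = mean(atoms$y), z = mean(atoms$z))
}

#' Geometric center of selected residues
#'
#' @param structure Atom tibble from [load_structure()].
#' @param chain Chain identifier.
#' @param resno Residue number(s); a reference point such as the tRNA A76
#'   plus its attached amino-acid moiety is selected by passing both
#'   residue numbers.
#' @return Named numeric center `c(x, y, z)`.
#' @export
residue_center <- function(structure, chain, resno) {
  sel <- dplyr::filter(structure, .data$chain == !!chain, .data$resno %in% !!resno)
  if (nrow(sel) == 0) {
    ptc_abort(sprintf("No atoms for chain %s residue(s) %s", chain,
                      paste(resno, collapse = ",")),
              class = "ptcflex_empty_selection")
  }
  geometric_center(sel)
}

#' @rdname residue_center
#' @export
reference_point <- residue_center

## coordinates as an n x 3 matrix
as_xyz <- function(atoms) cbind(atoms$x, atoms$y, atoms$z)

#' Kabsch least-squares rigid superposition
#'
#' Finds the proper rotation `R` and translation `t` minimizing the RMSD
#' between `mobile %*% R + t` and `fixed` over paired points, via SVD of
#' the cross-covariance matrix with the reflection guard.
#'
#' @param mobile,fixed Numeric matrices (n x 3) of paired coordinates,
#'   n >= 3, not collinear.
#' @return List of class `kabsch_fit`: `rotation` (3 x 3), `translation`
#'   (length 3), `rmsd` (Angstrom) and `n`.
#' @export
kabsch_superpose <- function(mobile, fixed) {
  mobile <- as.matrix(mobile); fixed <- as.matrix(fixed)
  if (!all(dim(mobile) == dim(fixed)) || ncol(mobile) != 3) {
    ptc_abort("mobile and fixed must be equal-size n x 3 matrices")
  }
  n <- nrow(mobile)
  if (n < 3) ptc_abort("Superposition needs at least 3 paired points",
                       class = "ptcflex_degenerate_superposition")
  cm <- colMeans(mobile); cf <- colMeans(fixed)
  P <- sweep(mobile, 2, cm); Q <- sweep(fixed, 2, cf)
  ## collinear selections leave the rotation about the shared axis free
  if (sum(svd(P)$d > 1e-8 * max(svd(P)$d, 1)) < 2) {
    ptc_abort("Shared points are collinear; superposition is underdetermined",
              class = "ptcflex_degenerate_superposition")
  }
  s <- svd(t(P) %*% Q)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  aligned <- P %*% R
  rmsd <- sqrt(mean(rowSums((aligned - Q)^2)))
  translation <- cf - as.numeric(cm %*% R)
  structure(list(rotation = R, translation = translation, rmsd = rmsd, n = n),
            class = "kabsch_fit")
}

#' @export
print.kabsch_fit <- function(x, ...) {
  cat(sprintf("Kabsch superposition over %d points: RMSD %.4g A\n", x$n, x$rmsd))
  invisible(x)
}

#' Apply a rigid transform to coordinates
#'
#' @param atoms Atom tibble (with `x`, `y`, `z`) or n x 3 matrix.
#' @param fit A [kabsch_superpose()] result.
#' @return Same type as the input, coordinates transformed.
#' @export
apply_transform <- function(atoms, fit) {
  stopifnot(inherits(fit, "kabsch_fit"))
  if (is.data.frame(atoms)) {
    xyz <- as_xyz(atoms) %*% fit$rotation
    atoms$x <- xyz[, 1] + fit$translation[1]
    atoms$y <- xyz[, 2] + fit$translation[2]
    atoms$z <- xyz[, 3] + fit$translation[3]
    atoms
  } else {
    sweep(as.matrix(atoms) %*% fit$rotation, 2, fit$translation, "+")
  }
}

#' Superpose one structure onto another over shared atoms
#'
#' Pairs atoms present in both structures by (chain, residue number, atom
#' name) — by default the phosphorus atoms, a robust sparse selection for
#' placing tRNAs from one ribosome structure into another's frame — then
#' applies the Kabsch fit to the whole mobile structure.
#'
#' @param mobile,fixed Atom tibbles from [load_structure()].
#' @param chain Optional chain to restrict the shared selection to.
#' @param elety Atom name(s) used for pairing (default `"P"`).
#' @return List: `structure` (transformed mobile tibble) and `fit`.
#' @export
superpose <- function(mobile, fixed, chain = NULL, elety = "P") {
  sel <- function(s) {
    if (!is.null(chain)) s <- dplyr::filter(s, .data$chain %in% !!chain)
    dplyr::filter(s, .data$elety %in% !!elety)
  }
  key <- function(s) paste(s$chain, s$resno, s$elety)
  ms <- sel(mobile); fs <- sel(fixed)
  shared <- intersect(key(ms), key(fs))
  ms <- ms[match(shared, key(ms)), ]
  fs <- fs[match(shared, key(fs)), ]
  if (length(shared) < 3) {
    ptc_abort("Fewer than 3 shared atoms for superposition",
              class = "ptcflex_degenerate_superposition")
  }
  fit <- kabsch_superpose(as_xyz(ms), as_xyz(fs))
  list(structure = apply_transform(mobile, fit), fit = fit)
}

#' Nucleotide distances to tRNA reference points
#'
#' Euclidean distance from each nucleotide's geometric (heavy-atom) center
#' to the A-site and P-site reference centers (typically the average
#' center of each tRNA's A76 plus its attached amino-acid moiety).
#' Positions absent from the structure are reported with `NA` distances
#' and a warning rather than failing the whole map.
#'
#' @param structure Atom tibble from [load_structure()].
#' @param positions Integer vector of residue numbers (23S positions).
#' @param chain Chain holding the 23S rRNA.
#' @param ref_a,ref_p Reference centers `c(x, y, z)` from
#'   [reference_point()].
#' @return Tibble `position`, `dist_a_site`, `dist_p_site` (Angstrom).
#' @export
nucleotide_distances <- function(structure, positions, chain, ref_a, ref_p) {
  stopifnot(length(ref_a) == 3, length(ref_p) == 3)
  res <- purrr::map_dfr(positions, function(p) {
    sel <- dplyr::filter(structure, .data$chain == !!chain, .data$resno == p)
    if (nrow(sel) == 0) {
      return(tibble::tibble(position = p, dist_a_site = NA_real_, dist_p_site = NA_real_))
    }
    ctr <- geometric_center(sel)
    tibble::tibble(
      position = p,
      dist_a_site = sqrt(sum((ctr - ref_a)^2)),
      dist_p_site = sqrt(sum((ctr - ref_p)^2))
    )
  })
  if (anyNA(res$dist_a_site)) {
    rlang::warn(sprintf("Position(s) missing from structure: %s",
                        paste(res$position[is.na(res$dist_a_site)], collapse = ", ")))
  }
  res
}

#' Bin positions into ordered mutational-flexibility shells
#'
#' Quantile (equal-count) binning of flexibility scores into `n_shells`
#' ordered groups, shell 1 holding the least flexible positions. Ties are
#' broken toward the lower shell, so identical scores always share a
#' shell and shell index is non-decreasing in score. Explicit score
#' thresholds may be supplied instead of quantile binning.
#'
#' @param scores Tibble with `position` and `score` (e.g. from
#'   [flexibility_scores()]).
#' @param n_shells Number of shells (default 4, labelled lowest,
#'   medium/low, medium/high, highest).
#' @param thresholds Optional increasing numeric cut points of length
#'   `n_shells - 1`; scores below the first threshold fall in shell 1.
#' @return Tibble `position`, `score`, `shell`, `shell_label`.
#' @export
assign_shells <- function(scores, n_shells = 4, thresholds = NULL) {
  stopifnot(is.data.frame(scores), all(c("position", "score") %in% names(scores)))
  n <- nrow(scores)
  if (n < n_shells) ptc_abort("Fewer scored positions than shells")
  if (is.null(thresholds)) {
    r <- rank(scores$score, ties.method = "min")
    shell <- pmin(ceiling(r / (n / n_shells)), n_shells)
  } else {
    if (length(thresholds) != n_shells - 1 || is.unsorted(thresholds, strictly = TRUE)) {
      ptc_abort("thresholds must be strictly increasing and of length n_shells - 1")
    }
    shell <- findInterval(scores$score, thresholds) + 1L
  }
  labels <- if (n_shells == 4) {
    c("lowest", "medium/low", "medium/high", "highest")
  } else {
    paste("shell", seq_len(n_shells))
  }
  tibble::tibble(
    position = scores$position,
    score = scores$score,
    shell = as.integer(shell),
    shell_label = factor(labels[shell], levels = labels)
  )
}

#' Write a B-factor attribute map for structure viewers
#'
#' Sets the B-factor of every atom of each mapped residue to its
#' flexibility score (rounded to the PDB's 2-decimal precision) and every
#' unmapped residue to a sentinel, then writes a PDB that any molecular
#' viewer can color as a heat map.
#'
#' @param pdb_file Input PDB path (written back through bio3d, so the
#'   file round-trips through [load_structure()]).
#' @param scores Tibble `position`, `score`.
#' @param chain Chain holding the mapped residues.
#' @param out_file Output PDB path.
#' @param sentinel B-factor for unmapped residues (default -1).
#' @return `out_file`, invisibly.
#' @export
write_attribute_pdb <- function(pdb_file, scores, chain, out_file, sentinel = -1) {
  stopifnot(all(c("position", "score") %in% names(scores)))
  pdb <- bio3d::read.pdb(pdb_file, rm.alt = FALSE, verbose = FALSE)
  b <- rep(sentinel, nrow(pdb$atom))
  hit <- pdb$atom$chain == chain & pdb$atom$resno %in% scores$position
  idx <- match(pdb$atom$resno[hit], scores$position)
  b[hit] <- round(scores$score[idx], 2)
  if (!any(hit)) {
    ptc_abort(sprintf("No residues of chain %s match the scored positions", chain),
              class = "ptcflex_empty_selection")
  }
  pdb$atom$b <- b
  bio3d::write.pdb(pdb, file = out_file, b = b)
  invisible(out_file)
}
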