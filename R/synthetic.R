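## Seeded generators emulating every input the pipeline consumes, with the
## generating parameters returned as ground truth so parameter-recovery
## tests need no external data.

## multiplicative Gaussian noise, CV-parameterized, floored at 0
mult_noise <- function(x, cv) {
  if (cv == 0) return(x)
  pmax(x * (1 + cv * stats::rnorm(length(x))), 0)
}

#' Generate a synthetic aligned FASTA panel
#'
#' Draws each alignment column independently from specified nucleotide
#' frequencies (emulating a pre-aligned LSU rRNA alignment), inserts gaps
#' at a fixed per-character rate, and emits a gap-free reference record
#' (the per-column majority base) so reference positions map 1:1 to
#' columns. The generating distribution and its exact entropy are
#' returned as ground truth.
#'
#' @param column_frequencies Tibble (or matrix) with columns `A`, `C`,
#'   `G`, `U`, one row per alignment column; rows must sum to 1.
#' @param n_records Number of non-reference records.
#' @param gap_rate Per-character gap probability in non-reference records.
#' @param seed Integer seed; identical seeds give identical output.
#' @param reference_id Name of the emitted reference record.
#' @return List: `alignment` (named character vector, reference first) and
#'   `truth` (tibble `position`, `A`, `C`, `G`, `U`, `entropy_true`).
#' @export
synth_alignment <- function(column_frequencies, n_records = 200, gap_rate = 0.05,
                            seed = 1, reference_id = "E_coli_ref") {
  freqs <- as.matrix(as.data.frame(column_frequencies)[, RNA_BASES])
  if (any(freqs < 0) || any(abs(rowSums(freqs) - 1) > 1e-8)) {
    ptc_abort("Column frequencies must be non-negative and sum to 1 per column")
  }
  if (gap_rate < 0 || gap_rate >= 1) ptc_abort("gap_rate must be in [0, 1)")
  set.seed(seed)
  n_col <- nrow(freqs)
  chars <- vapply(seq_len(n_col), function(j) {
    sample(RNA_BASES, n_records, replace = TRUE, prob = freqs[j, ])
  }, character(n_records))
  chars <- matrix(chars, nrow = n_records)
  if (gap_rate > 0) chars[stats::runif(length(chars)) < gap_rate] <- "-"
  recs <- apply(chars, 1, paste, collapse = "")
  ref <- paste(RNA_BASES[max.col(freqs, ties.method = "first")], collapse = "")
  aln <- c(stats::setNames(ref, reference_id),
           stats::setNames(recs, sprintf("rec_%04d", seq_len(n_records))))
  entropy_true <- apply(freqs, 1, function(p) {
    p <- p[p > 0]; -sum(p * log(p))
  })
  list(
    alignment = aln,
    truth = tibble::tibble(position = seq_len(n_col),
                           A = freqs[, "A"], C = freqs[, "C"],
                           G = freqs[, "G"], U = freqs[, "U"],
                           entropy_true = entropy_true)
  )
}

#' Write an alignment to FASTA
#'
#' @param alignment Named character vector of aligned sequences.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(alignment, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(alignment), path)
  invisible(path)
}

#' Generate saturating reporter kinetics
#'
#' Concentration follows the single-exponential saturation
#' `plateau * (1 - exp(-(rate / plateau) * t))`, whose initial slope equals
#' the bulk translation rate; a zero plateau gives a flat zero trace
#' (a dead mutant). The trace is converted to fluorescence through an
#' emitted linear standard curve, and multiplicative Gaussian noise of the
#' given CV is applied per replicate.
#'
#' @param sample_id Sample label.
#' @param true_rate Initial synthesis rate (uM protein/h).
#' @param plateau Saturation yield (uM).
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @param horizon Trace length (h).
#' @param dt Sampling interval (h).
#' @param n_replicates Independent replicate traces.
#' @param seed Integer seed.
#' @param curve_slope,curve_intercept Emitted standard curve (uM/RFU, uM).
#' @return List: `traces` (tibble `sample_id`, `replicate`, `time_h`,
#'   `signal`, `unit = "RFU"`), `curve_points` (tibble `rfu`, `um`) and
#'   `truth` (list `true_rate`, `plateau`).
#' @export
synth_kinetics <- function(sample_id = "WT", true_rate = 1.03, plateau = 10,
                           noise_cv = 0, horizon = 20, dt = 0.25,
                           n_replicates = 1, seed = 1,
                           curve_slope = 0.01, curve_intercept = 0) {
  if (plateau < 0) ptc_abort("plateau must be non-negative")
  if (horizon <= 0) ptc_abort("horizon must be positive")
  set.seed(seed)
  times <- seq(0, horizon, by = dt)
  conc <- if (plateau == 0) rep(0, length(times)) else {
    plateau * (1 - exp(-(true_rate / plateau) * times))
  }
  rfu <- (conc - curve_intercept) / curve_slope
  traces <- purrr::map_dfr(seq_len(n_replicates), function(r) {
    tibble::tibble(sample_id = sample_id, replicate = r, time_h = times,
                   signal = mult_noise(rfu, noise_cv), unit = "RFU")
  })
  um <- seq(0, max(plateau, 1) * 1.2, length.out = 8)
  list(
    traces = traces,
    curve_points = tibble::tibble(rfu = (um - curve_intercept) / curve_slope, um = um),
    truth = list(true_rate = true_rate, plateau = plateau)
  )
}

#' Generate a synthetic sucrose-gradient trace set
#'
#' The sample trace is a sum of per-species Gaussian peaks (with known
#' areas) plus a linear baseline drift plus a stray background peak set;
#' the blank trace carries the drift alone and the background trace the
#' stray peaks alone (already baseline-corrected), so
#' [correct_trace()] recovers the pure species signal.
#'
#' @param peaks Tibble `species`, `center_mm`, `sigma_mm`, `area`; a
#'   warning is raised for a peak center outside its species window of
#'   [default_boundaries()].
#' @param baseline_drift Numeric `(intercept, slope)` of the linear drift.
#' @param stray Tibble of background peaks (`center_mm`, `sigma_mm`,
#'   `area`).
#' @param noise_cv CV of multiplicative noise on the sample trace.
#' @param grid Gradient-distance grid (mm).
#' @param seed Integer seed.
#' @param sample_id Sample label.
#' @return List: `sample`, `blank`, `background` (tibbles `distance_mm`,
#'   `a254`), `traces` (long tibble with `sample_id`, `kind`) and `truth`
#'   (the peaks table).
#' @export
synth_gradient <- function(peaks,
                           baseline_drift = c(0.02, 0.001),
                           stray = tibble::tibble(center_mm = 9, sigma_mm = 1.5, area = 0.05),
                           noise_cv = 0, grid = seq(5, 62, by = 0.25),
                           seed = 1, sample_id = "sample") {
  stopifnot(all(c("species", "center_mm", "sigma_mm", "area") %in% names(peaks)))
  bounds <- default_boundaries()
  chk <- dplyr::inner_join(peaks, bounds, by = "species")
  off <- chk$center_mm < chk$start | chk$center_mm > chk$end
  if (any(off)) {
    rlang::warn(sprintf("Peak center outside its species window: %s",
                        paste(chk$species[off], collapse = ", ")))
  }
  set.seed(seed)
  gauss <- function(tbl) {
    if (nrow(tbl) == 0) return(rep(0, length(grid)))
    rowSums(vapply(seq_len(nrow(tbl)),
                   function(i) tbl$area[i] * stats::dnorm(grid, tbl$center_mm[i], tbl$sigma_mm[i]),
                   numeric(length(grid))))
  }
  drift <- baseline_drift[1] + baseline_drift[2] * grid
  peak_sig <- gauss(peaks)
  stray_sig <- gauss(stray)
  sample <- tibble::tibble(distance_mm = grid,
                           a254 = mult_noise(peak_sig + stray_sig + drift, noise_cv))
  blank <- tibble::tibble(distance_mm = grid, a254 = drift)
  background <- tibble::tibble(distance_mm = grid, a254 = stray_sig)
  traces <- dplyr::bind_rows(
    dplyr::mutate(sample, sample_id = sample_id, kind = "sample"),
    dplyr::mutate(blank, sample_id = sample_id, kind = "blank"),
    dplyr::mutate(background, sample_id = sample_id, kind = "background")
  )
  list(sample = sample, blank = blank, background = background,
       traces = traces, truth = peaks)
}

#' Generate a toy 3D structure with known distances
#'
#' Builds each nucleotide as a four-atom heavy-atom cluster whose
#' geometric center sits at a prescribed radius from its designated tRNA
#' reference point, plus two A76-like reference residues. Nucleotide
#' centers are placed in the plane perpendicular to the axis joining the
#' two reference points, so the distance to the *other* reference point is
#' `sqrt(ref_sep^2 + radius^2)` exactly; both distances are returned as
#' ground truth.
#'
#' @param layout Tibble `position`, `site` (`"A"` or `"P"`), `radius`
#'   (Angstrom, > 0).
#' @param ref_sep Distance (Angstrom) between the A-site and P-site
#'   reference centers.
#' @param seed Integer seed (randomizes the in-plane direction only).
#' @param file Output PDB path.
#' @return List: `file`, `truth` (tibble `position`, `site`, `radius`,
#'   `dist_a_true`, `dist_p_true`), `ref_centers` (list `A`, `P`), and the
#'   chain ids used (`nt_chain = "A"`, A-site ref chain `"B"`, P-site ref
#'   chain `"C"`, both at residue 76).
#' @export
synth_structure <- function(layout, ref_sep = 25, seed = 1,
                            file = tempfile(fileext = ".pdb")) {
  stopifnot(all(c("position", "site", "radius") %in% names(layout)))
  if (any(layout$radius <= 0)) ptc_abort("radii must be > 0")
  if (any(!layout$site %in% c("A", "P"))) ptc_abort("site must be 'A' or 'P'")
  set.seed(seed)
  ref_a <- c(0, 0, 0)
  ref_p <- c(ref_sep, 0, 0)
  theta <- stats::runif(nrow(layout), 0, 2 * pi)
  centers <- t(vapply(seq_len(nrow(layout)), function(i) {
    ref <- if (layout$site[i] == "A") ref_a else ref_p
    ref + layout$radius[i] * c(0, cos(theta[i]), sin(theta[i]))
  }, numeric(3)))
  if (anyDuplicated(round(centers, 3)) > 0) {
    rlang::warn("Prescribed nucleotide centers overlap")
  }
  ## symmetric offsets: mean exactly zero, so the cluster center is exact
  offs <- rbind(c(.5, .5, .5), c(.5, -.5, -.5), c(-.5, .5, -.5), c(-.5, -.5, .5))
  elety <- c("C1", "C2", "C3", "N1")
  build <- function(center, chain, resno, resid) {
    tibble::tibble(
      chain = chain, resno = resno, resid = resid, elety = elety,
      x = center[1] + offs[, 1], y = center[2] + offs[, 2], z = center[3] + offs[, 3]
    )
  }
  atoms <- dplyr::bind_rows(
    purrr::map_dfr(seq_len(nrow(layout)), function(i) {
      build(centers[i, ], "A", layout$position[i], "N")
    }),
    build(ref_a, "B", 76L, "A"),
    build(ref_p, "C", 76L, "A")
  )
  bio3d::write.pdb(
    pdb = NULL, file = file,
    xyz = as.numeric(t(as.matrix(atoms[, c("x", "y", "z")]))),
    resno = atoms$resno, resid = atoms$resid, chain = atoms$chain,
    eleno = seq_len(nrow(atoms)), elety = atoms$elety,
    o = rep(1, nrow(atoms)), b = rep(0, nrow(atoms)),
    elesy = substr(atoms$elety, 1, 1)
  )
  dist_to <- function(ref) sqrt(rowSums(sweep(centers, 2, ref)^2))
  list(
    file = file,
    truth = tibble::tibble(
      position = layout$position, site = layout$site, radius = layout$radius,
      dist_a_true = dist_to(ref_a), dist_p_true = dist_to(ref_p)
    ),
    ref_centers = list(A = ref_a, P = ref_p),
    nt_chain = "A", a_ref_chain = "B", p_ref_chain = "C", ref_resno = 76L
  )
}

#' Generate premature stop-codon readthrough signals
#'
#' Each mutant's endpoint signal on a construct is
#' `construct_signal * propensity * relative_activity`, so the
#' activity-normalized readthrough recovers the ground-truth propensity;
#' the wild type has propensity and activity 1. Multiplicative Gaussian
#' noise is applied per replicate.
#'
#' @param truth Tibble `sample_id`, `propensity`, `relative_activity`
#'   (mutants only; the wild type is added automatically).
#' @param constructs Tibble `stop_codon`, `aa_position` (default: UAG at
#'   amino acids 50, 100, 116 and 216).
#' @param base_signal Wild-type endpoint signal per construct (recycled).
#' @param noise_cv CV of the multiplicative noise.
#' @param n_replicates Replicates per sample x construct.
#' @param seed Integer seed.
#' @return List: `signals` (tibble `sample_id`, `stop_codon`,
#'   `aa_position`, `replicate`, `signal`) and `truth`.
#' @export
synth_readthrough <- function(truth,
                              constructs = tibble::tibble(
                                stop_codon = "UAG",
                                aa_position = c(50L, 100L, 116L, 216L)
                              ),
                              base_signal = 1000, noise_cv = 0,
                              n_replicates = 1, seed = 1) {
  stopifnot(all(c("sample_id", "propensity", "relative_activity") %in% names(truth)))
  set.seed(seed)
  constructs$base_signal <- rep_len(base_signal, nrow(constructs))
  all_samples <- dplyr::bind_rows(
    tibble::tibble(sample_id = "WT", propensity = 1, relative_activity = 1),
    truth
  )
  signals <- tidyr::crossing(all_samples, constructs,
                             replicate = seq_len(n_replicates)) |>
    dplyr::mutate(
      signal = mult_noise(.data$base_signal * .data$propensity * .data$relative_activity,
                          noise_cv)
    ) |>
    dplyr::select("sample_id", "stop_codon", "aa_position", "replicate", "signal")
  list(signals = signals, truth = truth)
}

#' Ground truth for a full synthetic mutant panel
#'
#' Builds a self-consistent set of generating parameters for the default
#' study design: 61 scanned positions x 3 mutants + wild type. A- and
#' P-loop positions get a flexibility gradient tied to their constructed
#' distance from the tRNA reference points (closest positions least
#' flexible, the span of distances running 4-36 Angstrom); PTC-ring
#' positions get a seeded mixture of low-, medium- and high-flexibility
#' classes, independent of distance. Per-position flexibility equals the
#' sum of its three per-mutant activity truths by construction. Alignment
#' column frequencies concentrate probability on the wild-type base more
#' strongly at less flexible positions, and five gradient samples span
#' assembly states from wild-type-like (subunit ratio ~1.4) to severely
#' assembly-defective (~16.8).
#'
#' @param seed Integer seed.
#' @return List with elements `positions`, `mutants` (per-mutant
#'   `activity_true`, `propensity_true`), `flexibility` (per-position
#'   `score_true`), `layout` (structure radii), `column_frequencies`,
#'   `gradient_samples` (named list of peak tables) and `kinetics`
#'   (wild-type `true_rate`, `plateau`).
#' @export
default_panel_truth <- function(seed = 1) {
  set.seed(seed)
  pos <- region_positions()
  ## structure layout: loops prescribed from their cognate reference point,
  ## ring positions from the P-site reference
  a_loop <- pos$position[pos$region == "A-loop"]
  p_loop <- pos$position[pos$region == "P-loop"]
  ring <- pos$position[pos$region == "PTC-ring"]
  a_rad <- 4 + 2.2 * abs(a_loop - 2553)              # G2553 sits 4 A from the A site
  p_rad <- 4 + 7 * abs(p_loop - 2252)                # G2252 sits 4 A from the P site
  ref_sep <- sqrt(36^2 - max(a_rad)^2)               # farthest A-loop nt is 36 A from the P site
  layout <- dplyr::bind_rows(
    tibble::tibble(position = a_loop, site = "A", radius = a_rad),
    tibble::tibble(position = p_loop, site = "P", radius = p_rad),
    tibble::tibble(position = ring, site = "P",
                   radius = stats::runif(length(ring), 6, 24))
  ) |> dplyr::arrange(.data$position)
  dist_p <- ifelse(layout$site == "P", layout$radius,
                   sqrt(ref_sep^2 + layout$radius^2))
  names(dist_p) <- layout$position
  ## per-position flexibility truth
  flex <- vapply(seq_len(nrow(pos)), function(i) {
    p <- pos$position[i]
    if (pos$region[i] %in% c("A-loop", "P-loop")) {
      0.1 + 2.8 * (dist_p[[as.character(p)]] - 4) / (36 - 4)
    } else {
      cls <- sample(1:3, 1, prob = c(0.55, 0.25, 0.20))
      switch(cls, stats::runif(1, 0, 0.5), stats::runif(1, 0.5, 1.5), stats::runif(1, 1.5, 2.9))
    }
  }, numeric(1))
  flexibility <- tibble::tibble(position = pos$position, region = pos$region,
                                score_true = flex)
  ## split each position's flexibility across its three mutants
  mutants <- enumerate_mutants()
  w <- matrix(stats::rgamma(nrow(pos) * 3, shape = 5), ncol = 3)
  w <- w / rowSums(w)
  mutants$activity_true <- as.numeric(t(w * flex))
  ## a few high-readthrough mutants against a tight baseline
  mutants$propensity_true <- exp(stats::rnorm(nrow(mutants), 0, 0.2))
  hot <- sample(which(mutants$activity_true > 0.05), 4)
  mutants$propensity_true[hot] <- stats::runif(4, 5, 15)
  ## alignment columns: less flexible positions are more conserved
  eps <- 0.02 + 0.25 * pmin(flex / 3, 1)
  freqs <- t(vapply(seq_len(nrow(pos)), function(i) {
    p <- stats::setNames(rep(eps[i] / 3, 4), RNA_BASES)
    p[pos$wt_base[i]] <- 1 - eps[i]
    p
  }, numeric(4)))
  column_frequencies <- tibble::as_tibble(freqs)
  column_frequencies$position <- pos$position
  ## gradient samples: WT-like through assembly-defective
  grad_peaks <- function(a30, a50, a70, apoly) {
    tibble::tibble(
      species = c("30S", "50S", "70S", "polysomes"),
      center_mm = c(17, 25, 35, 50),
      sigma_mm = c(1.2, 1.2, 1.5, 2.5),
      area = c(a30, a50, a70, apoly)
    )
  }
  gradient_samples <- list(
    WT       = grad_peaks(1.20, 1.60, 0.70, 1.30),
    A2062U   = grad_peaks(1.20, 1.60, 0.75, 1.25),
    U2585G   = grad_peaks(1.50, 1.90, 0.80, 0.40),
    A2451U   = grad_peaks(1.70, 2.10, 0.60, 0.20),
    G2455A   = grad_peaks(1.68, 1.68, 0.192, 0.008)
  )
  list(
    positions = pos, mutants = mutants, flexibility = flexibility,
    layout = layout, ref_sep = ref_sep,
    column_frequencies = column_frequencies,
    gradient_samples = gradient_samples,
    kinetics = list(true_rate = 1.03, plateau = 10)
  )
}

#' Generate a complete synthetic input bundle
#'
#' Emits every file the pipeline consumes — aligned FASTA, standard-curve
#' and kinetic-trace TSVs for the wild type plus all mutants, readthrough
#' signal TSV, gradient trace TSV and a toy PDB — from one ground truth
#' and one seed. Mutant kinetics share the wild type's saturation constant
#' (rate and plateau both scale with the activity truth), so noiseless
#' relative activities recover the truth exactly.
#'
#' @param truth Ground truth from [default_panel_truth()]; `NULL` builds
#'   one from `seed`.
#' @param noise_cv CV of the multiplicative measurement noise (0 for a
#'   noiseless bundle).
#' @param seed Integer seed.
#' @param dir Output directory (created if needed).
#' @param n_replicates Replicates per kinetic/readthrough measurement.
#' @return List: `dir`, `paths` (named file paths), `truth`, and in-memory
#'   copies of the generated tables (`alignment`, `kinetics`,
#'   `curve_points`, `readthrough`, `gradients`).
#' @export
synth_panel <- function(truth = NULL, noise_cv = 0.1, seed = 1,
                        dir = tempfile("panel"), n_replicates = 3) {
  if (is.null(truth)) truth <- default_panel_truth(seed)
  if (!all(abs(truth$flexibility$score_true -
               tapply(truth$mutants$activity_true, truth$mutants$position, sum)[
                 as.character(truth$flexibility$position)]) < 1e-8)) {
    ptc_abort("Inconsistent truth: flexibility must equal the sum of mutant activities")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ## alignment
  aln <- synth_alignment(truth$column_frequencies, n_records = 400,
                         gap_rate = 0.05, seed = seed + 11L)
  ## kinetics: wild type plus every mutant, shared saturation constant
  wt <- truth$kinetics
  samples <- dplyr::bind_rows(
    tibble::tibble(sample_id = "WT", activity_true = 1),
    tibble::tibble(sample_id = truth$mutants$mutant_id,
                   activity_true = truth$mutants$activity_true)
  )
  kin <- purrr::map_dfr(seq_len(nrow(samples)), function(i) {
    synth_kinetics(
      sample_id = samples$sample_id[i],
      true_rate = wt$true_rate * samples$activity_true[i],
      plateau = wt$plateau * samples$activity_true[i],
      noise_cv = noise_cv, n_replicates = n_replicates,
      seed = seed + 100L + i
    )$traces
  })
  curve_points <- synth_kinetics(seed = seed)$curve_points
  ## readthrough on the default construct set
  rt <- synth_readthrough(
    truth = dplyr::select(truth$mutants, sample_id = "mutant_id",
                          propensity = "propensity_true",
                          relative_activity = "activity_true"),
    noise_cv = noise_cv, n_replicates = n_replicates, seed = seed + 7L
  )
  ## gradients
  grads <- purrr::imap_dfr(truth$gradient_samples, function(peaks, id) {
    synth_gradient(peaks, noise_cv = noise_cv, seed = seed + 23L + match(id, names(truth$gradient_samples)),
                   sample_id = id)$traces
  })
  ## toy structure
  strc <- synth_structure(truth$layout, ref_sep = truth$ref_sep,
                          seed = seed + 31L,
                          file = file.path(dir, "structure.pdb"))
  paths <- list(
    alignment = file.path(dir, "alignment.fasta"),
    kinetics = file.path(dir, "kinetics.tsv"),
    standard_curve = file.path(dir, "standard_curve.tsv"),
    readthrough = file.path(dir, "readthrough.tsv"),
    gradients = file.path(dir, "gradients.tsv"),
    structure = strc$file
  )
  write_fasta(aln$alignment, paths$alignment)
  readr::write_tsv(kin, paths$kinetics)
  readr::write_tsv(curve_points, paths$standard_curve)
  readr::write_tsv(rt$signals, paths$readthrough)
  readr::write_tsv(grads, paths$gradients)
  truth$alignment_truth <- aln$truth
  truth$structure_truth <- strc$truth
  list(dir = dir, paths = paths, truth = truth,
       alignment = aln$alignment, kinetics = kin, curve_points = curve_points,
       readthrough = rt$signals, gradients = grads,
       structure = strc)
}
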