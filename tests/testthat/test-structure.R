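test_that("PDB loading keeps heavy atoms and resolves altlocs by occupancy", {
  # minimal 3-atom residue
  f <- write_pdb_lines(c(
    pdb_atom_line(1, "C1", x = 1, y = 2, z = 3),
    pdb_atom_line(2, "C2", x = 2, y = 2, z = 3),
    pdb_atom_line(3, "N1", x = 3, y = 2, z = 3, elem = "N")
  ))
  s <- load_structure(f)
  expect_equal(nrow(s), 3)
  expect_equal(unique(s$resno), 1)

  # altloc A (occ 0.7) wins over B (occ 0.3)
  f2 <- write_pdb_lines(c(
    pdb_atom_line(1, "C1", alt = "A", x = 1, occ = 0.7),
    pdb_atom_line(2, "C1", alt = "B", x = 9, occ = 0.3),
    pdb_atom_line(3, "C2", x = 5)
  ))
  s2 <- load_structure(f2)
  expect_equal(nrow(s2), 2)
  expect_equal(s2$x[s2$elety == "C1"], 1)

  # hydrogen-only residue leaves nothing to work with
  f3 <- write_pdb_lines(c(
    pdb_atom_line(1, "H1", elem = "H"),
    pdb_atom_line(2, "H2", x = 1, elem = "H")
  ))
  expect_error(load_structure(f3), class = "ptcflex_empty_selection")
})

test_that("geometric centers equal the brute-force coordinate mean", {
  expect_equal(unname(geometric_center(tibble::tibble(x = 1, y = 2, z = 3))),
               c(1, 2, 3))
  expect_equal(unname(geometric_center(tibble::tibble(x = c(0, 2), y = 0, z = 0))),
               c(1, 0, 0))
  set.seed(15)
  atoms <- tibble::tibble(x = rnorm(10), y = rnorm(10), z = rnorm(10))
  # independent summation oracle
  oracle <- c(sum(atoms$x), sum(atoms$y), sum(atoms$z)) / 10
  expect_equal(unname(geometric_center(atoms)), oracle)
  expect_error(geometric_center(atoms[0, ]), class = "ptcflex_empty_selection")
})

test_that("Kabsch superposition recovers rigid motions exactly", {
  set.seed(8)
  fixed <- matrix(rnorm(30), ncol = 3)

  # identity
  fit <- kabsch_superpose(fixed, fixed)
  expect_equal(fit$rmsd, 0, tolerance = 1e-10)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-10)

  # pure translation by (1, 2, 3): recovered translation is its inverse
  fit_t <- kabsch_superpose(sweep(fixed, 2, c(-1, -2, -3)), fixed)
  expect_equal(fit_t$rmsd, 0, tolerance = 1e-10)
  expect_equal(unname(fit_t$translation), c(-1, -2, -3), tolerance = 1e-10)

  # random rotation + translation: RMSD ~ 0 and the composed motion is identity
  R <- rotation_matrix(c(1, 2, 0.5), 1.1)
  mobile <- sweep(fixed %*% t(R), 2, c(4, -2, 7), "+")
  fit_r <- kabsch_superpose(mobile, fixed)
  expect_lt(fit_r$rmsd, 1e-6)
  expect_equal(apply_transform(mobile, fit_r), fixed, tolerance = 1e-9)

  # degenerate selections
  expect_error(kabsch_superpose(fixed[1:2, ], fixed[1:2, ]),
               class = "ptcflex_degenerate_superposition")
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(kabsch_superpose(line, line),
               class = "ptcflex_degenerate_superposition")
})

test_that("structure-level superposition pairs shared atoms by name", {
  set.seed(4)
  fixed <- tibble::tibble(
    chain = "A", resno = 1:6, resid = "N", elety = "P", elesy = "P",
    x = rnorm(6), y = rnorm(6), z = rnorm(6), o = 1, b = 0
  )
  R <- rotation_matrix(c(0, 1, 1), 0.7)
  xyz <- as.matrix(fixed[, c("x", "y", "z")]) %*% t(R)
  mobile <- fixed
  mobile$x <- xyz[, 1] + 3; mobile$y <- xyz[, 2] - 1; mobile$z <- xyz[, 3]
  out <- superpose(mobile, fixed, chain = "A", elety = "P")
  expect_lt(out$fit$rmsd, 1e-9)
  expect_equal(out$structure$x, fixed$x, tolerance = 1e-9)
})

test_that("nucleotide distances are Euclidean center-to-center", {
  s <- tibble::tibble(
    chain = "A", resno = c(10L, 10L, 11L), resid = "N", elety = c("C1", "C2", "C1"),
    elesy = "C", x = c(2, 4, 0), y = c(4, 4, 0), z = 0, o = 1, b = 0
  )
  # residue 10 center (3, 4, 0): 3-4-5 triangle from the origin
  d <- nucleotide_distances(s, c(10, 11), "A", ref_a = c(0, 0, 0), ref_p = c(3, 4, 0))
  expect_equal(d$dist_a_site, c(5, 0))
  expect_equal(d$dist_p_site, c(0, 5))
  # missing residues are reported, not fatal
  expect_warning(d2 <- nucleotide_distances(s, c(10, 99), "A", c(0, 0, 0), c(1, 0, 0)),
                 "99")
  expect_true(is.na(d2$dist_a_site[2]))
})

test_that("toy structures built at prescribed radii reproduce those distances", {
  layout <- tibble::tibble(position = c(2548L, 2553L, 2560L, 2251L, 2252L),
                           site = c("A", "A", "A", "P", "P"),
                           radius = c(12, 4, 19.4, 8, 36))
  syn <- synth_structure(layout, ref_sep = 25, seed = 3)
  s <- load_structure(syn$file)
  ra <- reference_point(s, syn$a_ref_chain, syn$ref_resno)
  rp <- reference_point(s, syn$p_ref_chain, syn$ref_resno)
  d <- nucleotide_distances(s, layout$position, syn$nt_chain, ra, rp)
  m <- dplyr::left_join(d, syn$truth, by = "position")
  # PDB coordinates carry 3 decimals; distances agree to that precision
  expect_lt(max(abs(m$dist_a_site - m$dist_a_true)), 5e-3)
  expect_lt(max(abs(m$dist_p_site - m$dist_p_true)), 5e-3)
  prescribed <- ifelse(m$site == "A", m$dist_a_site, m$dist_p_site)
  expect_equal(prescribed, m$radius, tolerance = 5e-3)
})

test_that("distances are invariant under a joint rigid motion", {
  layout <- tibble::tibble(position = c(1L, 2L, 3L, 4L), site = c("A", "A", "P", "P"),
                           radius = c(5, 10, 7, 20))
  syn <- synth_structure(layout, ref_sep = 30, seed = 6)
  s <- load_structure(syn$file)
  R <- rotation_matrix(c(2, -1, 1), 2.2)
  fit <- structure(list(rotation = R, translation = c(10, -5, 3)),
                   class = "kabsch_fit")
  s2 <- apply_transform(s, fit)
  d1 <- nucleotide_distances(s, layout$position, "A",
                             reference_point(s, "B", 76), reference_point(s, "C", 76))
  d2 <- nucleotide_distances(s2, layout$position, "A",
                             reference_point(s2, "B", 76), reference_point(s2, "C", 76))
  expect_equal(d1$dist_a_site, d2$dist_a_site, tolerance = 1e-9)
  expect_equal(d1$dist_p_site, d2$dist_p_site, tolerance = 1e-9)
})

test_that("shell assignment is an ordered quantile binning with low-shell ties", {
  four <- tibble::tibble(position = 1:4, score = c(0, 1, 2, 3))
  expect_equal(assign_shells(four)$shell, 1:4)

  tied <- tibble::tibble(position = 1:6, score = rep(2, 6))
  expect_true(all(assign_shells(tied)$shell == 1L))

  eight <- tibble::tibble(position = 1:8, score = seq(0, 3, length.out = 8))
  sh <- assign_shells(eight)
  expect_equal(sh$shell, rep(1:4, each = 2))
  expect_equal(levels(sh$shell_label),
               c("lowest", "medium/low", "medium/high", "highest"))

  # monotone: higher score never lands in a lower shell
  set.seed(31)
  for (i in 1:10) {
    sc <- tibble::tibble(position = 1:12, score = round(runif(12, 0, 3), 1))
    sh <- assign_shells(sc)
    ord <- order(sh$score)
    expect_false(is.unsorted(sh$shell[ord]))
  }

  # explicit thresholds
  thr <- assign_shells(four, thresholds = c(0.5, 1.5, 2.5))
  expect_equal(thr$shell, 1:4)
  expect_error(assign_shells(four[1:3, ], n_shells = 4), "Fewer")
})

test_that("B-factor attribute maps round-trip through the loader", {
  layout <- tibble::tibble(position = c(5L, 6L, 7L), site = "A", radius = c(4, 8, 12))
  syn <- synth_structure(layout, seed = 2)
  scores <- tibble::tibble(position = c(5L, 6L), score = c(2.5, 1.234))
  out <- tempfile(fileext = ".pdb")
  write_attribute_pdb(syn$file, scores, chain = "A", out_file = out)
  s <- load_structure(out)
  expect_true(all(s$b[s$chain == "A" & s$resno == 5] == 2.5))
  expect_true(all(s$b[s$chain == "A" & s$resno == 6] == 1.23))  # 2-decimal precision
  expect_true(all(s$b[s$chain == "A" & s$resno == 7] == -1))    # sentinel
  expect_true(all(s$b[s$chain %in% c("B", "C")] == -1))
  expect_error(write_attribute_pdb(syn$file, scores, chain = "Z", out_file = out),
               class = "ptcflex_empty_selection")
})
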