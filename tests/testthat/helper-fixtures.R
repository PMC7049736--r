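# Shared fixture builders and independent oracles.

# alignment from a list of per-record strings
make_alignment <- function(...) {
  recs <- c(...)
  if (is.null(names(recs))) names(recs) <- paste0("rec", seq_along(recs))
  recs
}

# brute-force entropy oracle: enumerate each record's symbol at a column,
# drop non-ACGU, tabulate, and evaluate -sum p log p directly
entropy_oracle <- function(records, column) {
  chars <- vapply(strsplit(records, ""), `[`, character(1), column)
  chars <- chars[chars %in% c("A", "C", "G", "U")]
  stopifnot(length(chars) > 0)
  p <- as.numeric(table(chars)) / length(chars)
  -sum(p * log(p))
}

# brute-force left-rectangle oracle written as an explicit loop
riemann_oracle <- function(x, y, start, end) {
  total <- 0
  for (i in seq_len(length(x) - 1)) {
    if (x[i] >= start && x[i] < end) total <- total + y[i] * (x[i + 1] - x[i])
  }
  total
}

# noiseless saturating concentration trace as a plain tibble in uM
exp_trace <- function(sample_id, rate, plateau, horizon = 20, dt = 0.25) {
  t <- seq(0, horizon, by = dt)
  s <- if (plateau == 0) rep(0, length(t)) else plateau * (1 - exp(-(rate / plateau) * t))
  tibble::tibble(sample_id = sample_id, time_h = t, signal = s, unit = "uM")
}

# minimal hand-written PDB fixture (fixed-column format)
write_pdb_lines <- function(lines, file = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), file)
  file
}

pdb_atom_line <- function(serial, name, alt = " ", resname = "LIG", chain = "A",
                          resno = 1, x = 0, y = 0, z = 0, occ = 1, b = 0, elem = "C") {
  sprintf("ATOM  %5d %-4s%s%-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name, alt, resname, chain, resno, x, y, z, occ, b, elem)
}

# small 3D rotation matrix about an arbitrary axis
rotation_matrix <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
}
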