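#' Active-site region definitions of the E. coli 23S rRNA
#'
#' Returns the nucleotide intervals that make up the three active-site
#' regions scanned in a PTC saturation mutagenesis study: the central
#' PTC-ring (G2057–C2063, G2447–C2456, C2496–C2507, G2582–G2588, A2602,
#' C2606–C2611), the A-loop (U2548–A2560) and the P-loop (G2250–C2254).
#' Coordinates are 1-based, inclusive, in E. coli 23S rRNA numbering.
#'
#' @return A tibble with columns `region`, `start`, `end` (one row per
#'   contiguous interval).
#' @examples
#' ptc_regions()
#' @export
ptc_regions <- function() {
  tibble::tribble(
    ~region,     ~start, ~end,
    "PTC-ring",   2057L, 2063L,
    "PTC-ring",   2447L, 2456L,
    "PTC-ring",   2496L, 2507L,
    "PTC-ring",   2582L, 2588L,
    "PTC-ring",   2602L, 2602L,
    "PTC-ring",   2606L, 2611L,
    "A-loop",     2548L, 2560L,
    "P-loop",     2250L, 2254L
  )
}

#' Wild-type base identities for the scanned 23S positions
#'
#' Bundled reference identities for the 61 study positions, in E. coli 23S
#' numbering (e.g. A2451, U2585, G2553). Positions never named in the study
#' nomenclature carry the E. coli reference identity; pass your own table to
#' downstream functions to override for other organisms or numbering.
#'
#' @return A tibble with columns `position`, `wt_base`.
#' @export
ptc_reference_bases <- function() {
  seg <- function(start, bases) {
    b <- strsplit(bases, "")[[1]]
    tibble::tibble(position = seq(start, start + length(b) - 1L), wt_base = b)
  }
  dplyr::bind_rows(
    seg(2057L, "GAAAGAC"),
    seg(2250L, "GGGGC"),
    seg(2447L, "GAUAACAUGC"),
    seg(2496L, "CACAUCGAUGUC"),
    seg(2548L, "UGGCUGUUCGCCA"),
    seg(2582L, "GGUUUAG"),
    seg(2602L, "A"),
    seg(2606L, "CGGUCC")
  ) |>
    dplyr::arrange(.data$position)
}

## validate a region interval table: start <= end, pairwise disjoint
validate_regions <- function(regions) {
  stopifnot(all(c("region", "start", "end") %in% names(regions)))
  bad <- regions$start > regions$end
  if (any(bad)) {
    ptc_abort(sprintf(
      "Inverted interval(s): %s",
      paste(sprintf("%d-%d", regions$start[bad], regions$end[bad]), collapse = ", ")
    ), class = "ptcflex_invalid_region")
  }
  srt <- regions[order(regions$start), ]
  if (nrow(srt) > 1 && any(srt$start[-1] <= srt$end[-nrow(srt)])) {
    ptc_abort("Region intervals overlap", class = "ptcflex_invalid_region")
  }
  invisible(regions)
}

#' Enumerate nucleotide positions of one or more regions
#'
#' @param regions Interval table as returned by [ptc_regions()]; may be
#'   filtered to a single region.
#' @param region Optional region name to restrict to.
#' @return Tibble `region`, `position`, sorted by position within region,
#'   each position exactly once.
#' @examples
#' nrow(enumerate_positions(ptc_regions(), "PTC-ring")) # 43
#' @export
enumerate_positions <- function(regions = ptc_regions(), region = NULL) {
  if (!is.null(region)) regions <- dplyr::filter(regions, .data$region %in% !!region)
  if (nrow(regions) == 0) ptc_abort("No matching region")
  validate_regions(regions)
  regions |>
    dplyr::rowwise() |>
    dplyr::reframe(region = .data$region, position = seq(.data$start, .data$end)) |>
    dplyr::arrange(.data$region, .data$position)
}

#' Positions with their wild-type identities
#'
#' Joins enumerated positions with a reference-base table and fails loudly
#' on any position lacking a reference identity.
#'
#' @inheritParams enumerate_positions
#' @param ref_bases Tibble `position`, `wt_base`; default [ptc_reference_bases()].
#' @return Tibble `region`, `position`, `wt_base`.
#' @export
region_positions <- function(regions = ptc_regions(), region = NULL,
                             ref_bases = ptc_reference_bases()) {
  pos <- enumerate_positions(regions, region)
  out <- dplyr::left_join(pos, ref_bases, by = "position")
  if (anyNA(out$wt_base)) {
    ptc_abort(sprintf("No reference base for position(s): %s",
                      paste(out$position[is.na(out$wt_base)], collapse = ", ")),
              class = "ptcflex_missing_reference_base")
  }
  if (!all(out$wt_base %in% RNA_BASES)) {
    ptc_abort("Reference bases must be A, C, G or U")
  }
  out
}

#' Enumerate every single-point mutant of the scanned regions
#'
#' Three mutants per position (the wild-type base excluded), named in the
#' conventional `A2451C` style. Ordering is deterministic: by position, then
#' mutant base A < C < G < U.
#'
#' @inheritParams region_positions
#' @return Tibble `region`, `position`, `wt_base`, `mut_base`, `mutant_id`.
#' @examples
#' nrow(enumerate_mutants(ptc_regions(), "PTC-ring")) # 129
#' @export
enumerate_mutants <- function(regions = ptc_regions(), region = NULL,
                              ref_bases = ptc_reference_bases()) {
  region_positions(regions, region, ref_bases) |>
    dplyr::rowwise() |>
    dplyr::reframe(
      region = .data$region, position = .data$position, wt_base = .data$wt_base,
      mut_base = setdiff(RNA_BASES, .data$wt_base)
    ) |>
    dplyr::mutate(mutant_id = format_mutant_id(.data$wt_base, .data$position, .data$mut_base)) |>
    dplyr::arrange(.data$region, .data$position, .data$mut_base)
}

#' Format and parse canonical mutant names
#'
#' `format_mutant_id()` builds names like `"A2451C"`; `parse_mutant_id()`
#' inverts it, validating the RNA alphabet and that the mutant base differs
#' from the wild type. Both are vectorised and round-trip exactly.
#'
#' @param wt_base,mut_base Wild-type and mutant bases (A/C/G/U).
#' @param position 23S position (positive integer).
#' @param x Character vector of mutant names.
#' @return `format_mutant_id()`: character vector. `parse_mutant_id()`:
#'   tibble `mutant_id`, `wt_base`, `position`, `mut_base`.
#' @export
format_mutant_id <- function(wt_base, position, mut_base) {
  stopifnot(all(wt_base %in% RNA_BASES), all(mut_base %in% RNA_BASES))
  if (any(wt_base == mut_base)) ptc_abort("Mutant base equals wild-type base")
  paste0(wt_base, position, mut_base)
}

#' @rdname format_mutant_id
#' @export
parse_mutant_id <- function(x) {
  m <- stringr::str_match(x, "^([ACGU])(\\d+)([ACGU])$")
  if (anyNA(m[, 1])) {
    ptc_abort(sprintf("Unparseable mutant name(s): %s",
                      paste(x[is.na(m[, 1])], collapse = ", ")))
  }
  if (any(m[, 2] == m[, 4])) ptc_abort("Mutant base equals wild-type base")
  tibble::tibble(
    mutant_id = x,
    wt_base = m[, 2],
    position = as.integer(m[, 3]),
    mut_base = m[, 4]
  )
}
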