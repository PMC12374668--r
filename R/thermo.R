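#' Paired region between two strands
#'
#' Describes an antiparallel Watson-Crick duplex formed between a span of
#' `strand_a` and a span of `strand_b`. Spans are 0-based half-open
#' intervals on the respective 5'->3' sequences; position
#' `span_a[1] + t` of strand a pairs position `span_b[2] - 1 - t` of
#' strand b. A zero-length span is permitted and represents "no
#' interaction".
#'
#' @param strand_a,strand_b DNA strings, 5'->3'.
#' @param span_a,span_b Integer vectors `c(start, end)`, 0-based half-open.
#'   Default to the full length of each strand.
#' @return A `dt_duplex_region` list with fields `strand_a`, `strand_b`,
#'   `span_a`, `span_b` and `n_bp`.
#' @export
#' @examples
#' duplex_region("ACGT", "ACGT") # 4-bp self-complementary duplex
duplex_region <- function(strand_a, strand_b,
                          span_a = NULL, span_b = NULL) {
  strand_a <- as_dna(strand_a, "strand_a")
  strand_b <- as_dna(strand_b, "strand_b")
  if (is.null(span_a)) span_a <- c(0L, nchar(strand_a))
  if (is.null(span_b)) span_b <- c(0L, nchar(strand_b))
  check_span <- function(span, strand, what) {
    if (length(span) != 2L || span[1] < 0 || span[2] < span[1] ||
      span[2] > nchar(strand)) {
      rlang::abort(sprintf("%s is not a valid 0-based half-open span", what))
    }
  }
  check_span(span_a, strand_a, "span_a")
  check_span(span_b, strand_b, "span_b")
  n_bp <- span_a[2] - span_a[1]
  if (n_bp != span_b[2] - span_b[1]) {
    rlang::abort("span_a and span_b must have equal lengths")
  }
  structure(
    list(
      strand_a = strand_a, strand_b = strand_b,
      span_a = as.integer(span_a), span_b = as.integer(span_b),
      n_bp = as.integer(n_bp)
    ),
    class = "dt_duplex_region"
  )
}

#' @noRd
region_top_seq <- function(region) {
  substr(region$strand_a, region$span_a[1] + 1L, region$span_a[2])
}

#' @noRd
region_bottom_seq <- function(region) {
  substr(region$strand_b, region$span_b[1] + 1L, region$span_b[2])
}

#' @noRd
region_is_complementary <- function(region) {
  if (region$n_bp == 0L) {
    return(TRUE)
  }
  region_top_seq(region) == reverse_complement(region_bottom_seq(region))
}

# Nearest-neighbor energy of a fully paired duplex whose top strand reads
# `top` 5'->3': stacking over adjacent steps + initiation + terminal A/T
# penalties + entropic monovalent-salt correction (0.368 cal/(mol K) per
# internal phosphate pair, i.e. per stack).
#' @noRd
nn_duplex_energy <- function(top, params) {
  n <- nchar(top)
  if (n == 0L) {
    return(0.0)
  }
  tab <- load_nn_table(params$nn_table_id)
  dh <- tab$dh[["init"]]
  ds <- tab$ds[["init"]]
  if (n > 1L) {
    steps <- substring(top, 1:(n - 1), 2:n)
    dh <- dh + sum(tab$dh[steps])
    ds <- ds + sum(tab$ds[steps])
  }
  ends <- substring(top, c(1L, n), c(1L, n))
  n_at_ends <- sum(ends %in% c("A", "T"))
  dh <- dh + n_at_ends * tab$dh[["term_AT"]]
  ds <- ds + n_at_ends * tab$ds[["term_AT"]]
  ds <- ds + 0.368 * (n - 1L) * log(params$monovalent_salt)
  unname(dh - params$temperature * ds / 1000)
}

#' Duplex standard free energy
#'
#' Nearest-neighbor free energy, in kcal/mol at the configured temperature
#' and salt, of the paired region: the sum of stacking terms over adjacent
#' paired steps plus duplex initiation, terminal A-T penalties and an
#' entropic monovalent-salt correction. More negative means more stable.
#' An empty paired span returns `0.0` (no interaction).
#'
#' @param region A [duplex_region()].
#' @param params A [thermo_params()] object.
#' @return Free energy in kcal/mol.
#' @export
#' @examples
#' duplex_dg(duplex_region("ACGT", "ACGT"), thermo_params())
duplex_dg <- function(region, params = thermo_params()) {
  stopifnot(inherits(region, "dt_duplex_region"))
  if (region$n_bp == 0L) {
    return(0.0)
  }
  if (!region_is_complementary(region)) {
    rlang::abort("invalid duplex: paired span is not Watson-Crick complementary")
  }
  nn_duplex_energy(region_top_seq(region), params)
}

#' Duplex stability decision
#'
#' A residual duplex is considered stable (holds its bridge) when its free
#' energy is at least as favourable as the hold threshold; the boundary case
#' counts as stable.
#'
#' @inheritParams duplex_dg
#' @param dg_hold Hold threshold in kcal/mol.
#' @return `TRUE` iff `duplex_dg(region, params) <= dg_hold` (within a
#'   1e-9 kcal/mol absolute tolerance at the boundary).
#' @export
duplex_is_stable <- function(region, params = thermo_params(),
                             dg_hold = -8.0) {
  duplex_dg(region, params) <= dg_hold + 1e-9
}

#' Adjusted minimum free energy (AMFE)
#'
#' The per-base-pair stability score of an interface complex: the minimum
#' internal free energy of the complex divided by the total number of
#' nucleotide pairs in its complementary region.
#'
#' @param complex_dg Complex free energy in kcal/mol.
#' @param n_bp Number of base pairs in the complementary region (>= 1).
#' @return AMFE in kcal/mol per base pair.
#' @export
#' @examples
#' amfe(-30, 20)
amfe <- function(complex_dg, n_bp) {
  if (any(n_bp == 0)) {
    rlang::abort("undefined AMFE: n_bp must be >= 1")
  }
  complex_dg / n_bp
}

#' Hairpin minimum free energy
#'
#' Minimum free energy over all admissible intramolecular hairpins of a
#' single strand, under a restricted hairpin-only model: a contiguous stem
#' of >= 2 Watson-Crick pairs closed by a terminal loop of >= 3 nt, with no
#' bulges or internal loops. Stem energy is the nearest-neighbor duplex
#' energy of the stem; the loop contributes an additive size penalty. When
#' no admissible hairpin exists the function returns `Inf` (the
#' "no-structure" sentinel, which passes any free-energy floor).
#'
#' @param seq DNA string.
#' @param params A [thermo_params()] object.
#' @return Minimum hairpin free energy in kcal/mol, or `Inf` if the
#'   sequence cannot form any admissible hairpin.
#' @export
#' @examples
#' hairpin_mfe("GGGGGAAAACCCCC") # strong 5-bp stem, 4-nt loop
#' hairpin_mfe("AAAAAAAAAA") # Inf: no stem possible
hairpin_mfe <- function(seq, params = thermo_params()) {
  seq <- as_dna(seq)
  n <- nchar(seq)
  if (n < 2L * 2L + 3L) {
    return(Inf)
  }
  b <- dna_chars(seq)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  best <- Inf
  # (i, j) = outermost pair (1-based); stem extends inward while pairs hold
  # and the terminal loop keeps >= 3 nt.
  for (i in seq_len(n - 6L)) {
    for (j in seq.int(i + 6L, n)) {
      if (comp[[b[i]]] != b[j]) next
      k_max <- (j - i - 3L + 1L) %/% 2L
      k <- 1L
      while (k < k_max && comp[[b[i + k]]] == b[j - k]) {
        k <- k + 1L
      }
      if (k < 2L) next
      for (kk in 2L:k) {
        stem_top <- substr(seq, i, i + kk - 1L)
        dg <- nn_duplex_energy(stem_top, params) +
          loop_penalty(j - i + 1L - 2L * kk, params)
        if (dg < best) best <- dg
      }
    }
  }
  best
}

#' Does a sequence pass a hairpin free-energy floor?
#'
#' @inheritParams hairpin_mfe
#' @param floor Floor in kcal/mol; the sequence passes when its hairpin MFE
#'   is `>= floor` (the no-structure sentinel always passes).
#' @return Logical.
#' @export
passes_hairpin_floor <- function(seq, floor = 0, params = thermo_params()) {
  hairpin_mfe(seq, params) >= floor - 1e-9
}
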