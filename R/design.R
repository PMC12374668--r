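# Constrained oligonucleotide generation. Sequences are drawn by seeded
# rejection sampling and every returned oligo carries a machine-checkable
# constraint report, so designs can always be re-verified after the fact.

#' Design constraints for generated oligonucleotides
#'
#' @param length Oligo length in nt (>= 5).
#' @param hairpin_dg_floor Minimum admissible hairpin MFE in kcal/mol; the
#'   generated oligo's [hairpin_mfe()] must be `>=` this (the no-structure
#'   sentinel always passes). Default 0: no negative-free-energy hairpins.
#' @param forbidden_partners Named list of DNA strings the oligo must not
#'   cross-hybridize with: the longest contiguous antiparallel complementary
#'   run against each partner must not exceed `cross_run_max`.
#' @param cross_run_max Maximum allowed contiguous cross-complementary run
#'   in nt (default 3, i.e. runs of 4+ are rejected: a sub-toehold run
#'   cannot nucleate displacement).
#' @param max_self_run Maximum allowed contiguous self-complementary run,
#'   same rationale applied to self-dimers; `Inf` disables the check.
#' @param gc_range Admissible GC fraction interval.
#' @param max_homopolymer Longest allowed single-base run in nt.
#' @param rng_seed Integer seed; regeneration with the same constraints and
#'   seed reproduces the identical sequence.
#' @param max_attempts Rejection-sampling attempt cap.
#' @param params [thermo_params()] under which hairpins are evaluated.
#' @return A `dt_design_constraints` list.
#' @export
design_constraints <- function(length,
                               hairpin_dg_floor = 0,
                               forbidden_partners = list(),
                               cross_run_max = 3L,
                               max_self_run = 3L,
                               gc_range = c(0.4, 0.6),
                               max_homopolymer = 4L,
                               rng_seed = 1L,
                               max_attempts = 100000L,
                               params = thermo_params()) {
  if (length < 5L) rlang::abort("oligo length must be >= 5 nt")
  if (gc_range[1] < 0 || gc_range[2] > 1 || gc_range[1] > gc_range[2]) {
    rlang::abort("gc_range must be an interval within [0, 1]")
  }
  if (cross_run_max >= length) {
    rlang::abort("cross_run_max must be smaller than the oligo length")
  }
  forbidden_partners <- lapply(forbidden_partners, as_dna)
  structure(
    list(
      length = as.integer(length),
      hairpin_dg_floor = hairpin_dg_floor,
      forbidden_partners = forbidden_partners,
      cross_run_max = cross_run_max,
      max_self_run = max_self_run,
      gc_range = gc_range,
      max_homopolymer = as.integer(max_homopolymer),
      rng_seed = as.integer(rng_seed),
      max_attempts = as.integer(max_attempts),
      params = params
    ),
    class = "dt_design_constraints"
  )
}

#' Longest contiguous cross-complementary run between two strands
#'
#' Length of the longest contiguous antiparallel Watson-Crick complementary
#' run between any substring of `a` and any substring of `b`, i.e. the
#' longest common substring of `a` and `reverse_complement(b)`.
#'
#' @param a,b DNA strings.
#' @return Run length in nt (0 when no single base pair can form).
#' @export
#' @examples
#' longest_cross_complement_run("ACGTACGT", reverse_complement("ACGTACGT"))
#' longest_cross_complement_run("AAAA", "CCCC")
longest_cross_complement_run <- function(a, b) {
  a <- dna_chars(as_dna(a, "a"))
  b <- dna_chars(reverse_complement(b))
  n <- length(a)
  m <- length(b)
  best <- 0L
  prev <- integer(m)
  for (i in seq_len(n)) {
    cur <- integer(m)
    match <- a[i] == b
    cur[match] <- 1L
    if (m > 1L) {
      idx <- which(match & seq_len(m) > 1L)
      cur[idx] <- prev[idx - 1L] + 1L
    }
    best <- max(best, cur)
    prev <- cur
  }
  as.integer(best)
}

# Evaluate every constraint for a candidate; returns a tibble with one row
# per check.
#' @noRd
check_oligo <- function(seq, constraints) {
  cn <- constraints
  rows <- list(
    tibble::tibble(
      constraint = "length", measured = nchar(seq),
      bound = as.numeric(cn$length),
      pass = nchar(seq) == cn$length
    ),
    tibble::tibble(
      constraint = "gc_fraction", measured = gc_fraction(seq),
      bound = cn$gc_range[2],
      pass = gc_fraction(seq) >= cn$gc_range[1] - 1e-9 &&
        gc_fraction(seq) <= cn$gc_range[2] + 1e-9
    ),
    tibble::tibble(
      constraint = "max_homopolymer", measured = max_homopolymer_run(seq),
      bound = as.numeric(cn$max_homopolymer),
      pass = max_homopolymer_run(seq) <= cn$max_homopolymer
    ),
    tibble::tibble(
      constraint = "hairpin_mfe", measured = hairpin_mfe(seq, cn$params),
      bound = cn$hairpin_dg_floor,
      pass = hairpin_mfe(seq, cn$params) >= cn$hairpin_dg_floor - 1e-9
    )
  )
  if (is.finite(cn$max_self_run)) {
    r <- longest_cross_complement_run(seq, seq)
    rows <- c(rows, list(tibble::tibble(
      constraint = "self_complement_run", measured = as.numeric(r),
      bound = as.numeric(cn$max_self_run), pass = r <= cn$max_self_run
    )))
  }
  if (length(cn$forbidden_partners) > 0L) {
    nm <- names(cn$forbidden_partners)
    if (is.null(nm)) nm <- paste0("partner_", seq_along(cn$forbidden_partners))
    for (k in seq_along(cn$forbidden_partners)) {
      r <- longest_cross_complement_run(seq, cn$forbidden_partners[[k]])
      rows <- c(rows, list(tibble::tibble(
        constraint = paste0("cross_run_vs_", nm[k]), measured = as.numeric(r),
        bound = as.numeric(cn$cross_run_max), pass = r <= cn$cross_run_max
      )))
    }
  }
  dplyr::bind_rows(rows)
}

#' @noRd
random_oligo <- function(length) {
  paste(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = "")
}

#' Generate a constrained oligonucleotide
#'
#' Seeded rejection sampling: bases are drawn uniformly and the candidate is
#' kept once every constraint (GC window, homopolymer cap, hairpin floor,
#' self- and cross-complementarity run caps) passes. Deterministic given
#' `(constraints, rng_seed)`.
#'
#' @param constraints A [design_constraints()] object.
#' @return A `dt_designed_oligo` with fields `sequence`,
#'   `constraint_report` (tibble, one row per check), `seed_used` and
#'   `attempts`.
#' @export
#' @examples
#' generate_oligo(design_constraints(length = 17, rng_seed = 42))
generate_oligo <- function(constraints) {
  stopifnot(inherits(constraints, "dt_design_constraints"))
  with_rng_seed(constraints$rng_seed, {
    res <- sample_oligo_stream(constraints)
  })
  res
}

# First failing constraint of a candidate (cheap screens first, the
# hairpin enumeration last), or NULL when all pass.
#' @noRd
first_failure <- function(seq, cn) {
  gc <- gc_fraction(seq)
  if (gc < cn$gc_range[1] - 1e-9 || gc > cn$gc_range[2] + 1e-9) {
    return("gc_fraction")
  }
  if (max_homopolymer_run(seq) > cn$max_homopolymer) {
    return("max_homopolymer")
  }
  if (is.finite(cn$max_self_run) &&
    longest_cross_complement_run(seq, seq) > cn$max_self_run) {
    return("self_complement_run")
  }
  nm <- names(cn$forbidden_partners)
  if (is.null(nm)) nm <- paste0("partner_", seq_along(cn$forbidden_partners))
  for (k in seq_along(cn$forbidden_partners)) {
    if (longest_cross_complement_run(seq, cn$forbidden_partners[[k]]) >
      cn$cross_run_max) {
      return(paste0("cross_run_vs_", nm[k]))
    }
  }
  if (hairpin_mfe(seq, cn$params) < cn$hairpin_dg_floor - 1e-9) {
    return("hairpin_mfe")
  }
  NULL
}

# Rejection loop against the *current* RNG stream (callers that design
# several species in sequence share one stream for joint determinism).
#' @noRd
sample_oligo_stream <- function(constraints) {
  fail_tally <- integer(0)
  for (attempt in seq_len(constraints$max_attempts)) {
    cand <- random_oligo(constraints$length)
    fail <- first_failure(cand, constraints)
    if (is.null(fail)) {
      return(structure(
        list(
          sequence = cand,
          constraint_report = check_oligo(cand, constraints),
          seed_used = constraints$rng_seed,
          attempts = attempt
        ),
        class = "dt_designed_oligo"
      ))
    }
    fail_tally[fail] <-
      (if (fail %in% names(fail_tally)) fail_tally[[fail]] else 0L) + 1L
  }
  worst <- names(fail_tally)[which.max(fail_tally)]
  rlang::abort(
    sprintf(
      "infeasible constraints: no oligo found in %d attempts (most frequent failure: %s, %d times)",
      constraints$max_attempts, worst, max(fail_tally)
    ),
    class = "dt_infeasible_constraints"
  )
}

#' @export
print.dt_designed_oligo <- function(x, ...) {
  cat(sprintf(
    "<designed_oligo> %s (%d nt, %d attempts, seed %d)\n",
    x$sequence, nchar(x$sequence), x$attempts, x$seed_used
  ))
  invisible(x)
}

#' Design a mutually compatible pair of input oligonucleotides
#'
#' Generates the two gate input sequences (defaults: 17 nt and 28 nt, the
#' dual-gate input sizes) such that each is free of secondary hairpin
#' structures (hairpin MFE above the floor, default `> 0` kcal/mol) and the
#' two lack complementarity to each other (longest cross-complementary run
#' below the cap). Because each input's full complement is later displayed
#' as a receptor on the particle, the second input is additionally screened
#' against the first input's reverse complement, which caps shared identity
#' runs (receptor cross-talk hygiene).
#'
#' @param len_a,len_b Input lengths in nt.
#' @param constraints Base [design_constraints()]; its `length` and
#'   `forbidden_partners` fields are overridden per input.
#' @return A named list with `dt_designed_oligo` elements `InA` and `InB`.
#' @export
#' @examples
#' pair <- design_input_pair(rng_seed = 7)
#' nchar(pair$InA$sequence)
design_input_pair <- function(len_a = 17L, len_b = 28L,
                              constraints = design_constraints(
                                length = len_a,
                                rng_seed = rng_seed
                              ),
                              rng_seed = 1L) {
  cn_a <- constraints
  cn_a$length <- as.integer(len_a)
  with_rng_seed(cn_a$rng_seed, {
    a <- sample_oligo_stream(cn_a)
    cn_b <- cn_a
    cn_b$length <- as.integer(len_b)
    cn_b$forbidden_partners <- c(
      cn_a$forbidden_partners,
      list(InA = a$sequence, InA_rc = reverse_complement(a$sequence))
    )
    b <- sample_oligo_stream(cn_b)
  })
  list(InA = a, InB = b)
}

#' Design a staple bridging a core receptor and a shield ligand
#'
#' Builds the bridging "staple" oligonucleotide for a stapled CP/SN
#' interface: its 5' segment is exactly complementary to a designated span
#' of the core receptor (length `overlap_core`, placed so the receptor's
#' distal `toehold_len` bases remain unpaired and accessible) and its 3'
#' segment is complementary to a freshly generated shield-particle ligand
#' (paired span `overlap_shield`). The shield ligand is resampled until the
#' ligand and the assembled staple satisfy the constraints (hairpin floor,
#' no cross-talk with the forbidden partners, typically the non-cognate
#' inputs).
#'
#' @param core_receptor DNA string of the core-anchored receptor, 5'->3'
#'   (5' end at the particle).
#' @param shield_ligand_len Length of the generated shield ligand in nt.
#' @param overlap_core Staple/receptor paired span in nt.
#' @param overlap_shield Staple/ligand paired span in nt.
#' @param toehold_len Receptor toehold left unpaired, in nt (>= 1).
#' @param constraints [design_constraints()] applied to the generated
#'   ligand (its `length` field is overridden) and, through the hairpin
#'   floor and partner caps, to the assembled staple.
#' @param staple_hairpin_floor Hairpin floor applied to the full staple,
#'   kcal/mol. Looser than the input floor because the staple's
#'   receptor-binding arm is dictated by the input sequence.
#' @param staple_forbidden_partners Partner list used for the assembled
#'   staple's cross-talk screen; defaults to the constraint's partners.
#'   Must exclude the cognate input: the staple's core arm is necessarily
#'   an identity copy of a cognate-input segment, so screening it against
#'   the cognate input's reverse complement can never pass.
#' @param staple_max_attempts Cap on shield-ligand resampling rounds
#'   (each round itself samples a ligand under `constraints`); exceeding
#'   it raises an infeasible-constraints error.
#' @return A `dt_designed_oligo` for the staple with extra fields
#'   `shield_ligand` (the generated `dt_designed_oligo`) and `geometry`
#'   (tibble of the paired spans, 0-based half-open).
#' @export
design_staple <- function(core_receptor,
                          shield_ligand_len = 20L,
                          overlap_core = NULL,
                          overlap_shield = 12L,
                          toehold_len = 5L,
                          constraints = design_constraints(
                            length = shield_ligand_len
                          ),
                          staple_hairpin_floor = -2.0,
                          staple_forbidden_partners = constraints$forbidden_partners,
                          staple_max_attempts = 2000L) {
  core_receptor <- as_dna(core_receptor, "core_receptor")
  len_r <- nchar(core_receptor)
  if (toehold_len < 1L) rlang::abort("toehold_len must be >= 1")
  if (is.null(overlap_core)) overlap_core <- len_r - toehold_len
  if (overlap_core + toehold_len > len_r) {
    rlang::abort(sprintf(
      "geometric infeasibility: overlap_core (%d) + toehold_len (%d) exceed the receptor span (%d nt)",
      overlap_core, toehold_len, len_r
    ))
  }
  if (overlap_shield > shield_ligand_len) {
    rlang::abort("overlap_shield exceeds the shield ligand length")
  }
  toehold_len <- as.integer(toehold_len)
  overlap_core <- as.integer(overlap_core)
  overlap_shield <- as.integer(overlap_shield)
  # receptor span paired by the staple: just proximal to the distal toehold
  core_span <- as.integer(c(
    len_r - toehold_len - overlap_core,
    len_r - toehold_len
  ))
  core_arm <- reverse_complement(
    substr(core_receptor, core_span[1] + 1L, core_span[2])
  )
  cn_l <- constraints
  cn_l$length <- as.integer(shield_ligand_len)
  with_rng_seed(cn_l$rng_seed, {
    staple <- NULL
    for (attempt in seq_len(staple_max_attempts)) {
      lig <- tryCatch(sample_oligo_stream(cn_l), error = function(e) NULL)
      if (is.null(lig)) break
      # ligand anchored 5' (thiol) on the shield particle; its distal
      # (3'-end) overlap_shield bases pair the staple's 3' arm
      lig_span <- c(shield_ligand_len - overlap_shield, shield_ligand_len)
      shield_arm <- reverse_complement(
        substr(lig$sequence, lig_span[1] + 1L, lig_span[2])
      )
      # flexible poly-T spacer between the two arms (breaks contiguous
      # complementary runs spanning the arm boundary)
      cand <- paste0(core_arm, "TTT", shield_arm)
      ok_hairpin <- hairpin_mfe(cand, cn_l$params) >= staple_hairpin_floor - 1e-9
      ok_cross <- all(vapply(
        staple_forbidden_partners,
        function(p) longest_cross_complement_run(cand, p) <= cn_l$cross_run_max,
        logical(1)
      ))
      if (ok_hairpin && ok_cross) {
        staple <- list(candidate = cand, ligand = lig, lig_span = lig_span)
        break
      }
    }
  })
  if (is.null(staple)) {
    rlang::abort(
      "infeasible constraints: could not find a shield ligand yielding an admissible staple",
      class = "dt_infeasible_constraints"
    )
  }
  n_core <- nchar(core_arm)
  n_total <- nchar(staple$candidate)
  geometry <- tibble::tibble(
    segment = c("receptor_toehold", "staple_core_arm", "staple_shield_arm"),
    strand = c("core_receptor", "staple", "staple"),
    start = c(len_r - toehold_len, 0L, n_total - overlap_shield),
    end = c(len_r, n_core, n_total),
    pairs_with = c(NA_character_, "core_receptor", "shield_ligand")
  )
  structure(
    list(
      sequence = staple$candidate,
      constraint_report = tibble::tibble(
        constraint = c("staple_hairpin_mfe"),
        measured = hairpin_mfe(staple$candidate, cn_l$params),
        bound = staple_hairpin_floor,
        pass = TRUE
      ),
      seed_used = cn_l$rng_seed,
      attempts = staple$ligand$attempts,
      shield_ligand = staple$ligand,
      core_span = core_span,
      ligand_span = staple$lig_span,
      geometry = geometry
    ),
    class = "dt_designed_oligo"
  )
}
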