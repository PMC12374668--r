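# Seeded fixture generator: a deterministic suite of gates spanning every
# supported family, used by the test suite and reproducible by anyone from
# the recorded seed. The input sequences stand in for the wet-lab input
# oligonucleotides: they are regenerated under the same printed
# constraints (17/28 nt, hairpin-free, mutually non-complementary) rather
# than transcribed, and are labelled synthetic accordingly.

#' Generate the packaged gate fixture suite
#'
#' Designs a deterministic set of input oligonucleotides (InA 17 nt,
#' InB 28 nt, plus InC/InD for the four-input gate) and assembles
#' `(gate_spec, design_constraints, expected truth table)` triples covering
#' YES gates on both inputs, NOT gates on both inputs, OR, AND, a
#' four-input single-staple AND, and a composite shield+marker gate.
#' Expected tables are direct Boolean evaluations of each expression.
#'
#' @param seed Integer seed; the same seed reproduces the identical
#'   fixture set byte for byte.
#' @return A `dt_fixture_set`: list with `seed`, `version`, `inputs`
#'   (named sequences) and `fixtures` (named list of triples).
#' @export
#' @examples
#' fx <- generate_fixtures(seed = 20240101)
#' names(fx$fixtures)
generate_fixtures <- function(seed = 20240101L) {
  pair <- design_input_pair(rng_seed = seed)
  in_a <- pair$InA$sequence
  in_b <- pair$InB$sequence
  # the two extra four-input-gate inputs carry many simultaneous partner
  # caps; a 4-nt run cap keeps them feasible while staying below the 5-nt
  # toehold needed to nucleate displacement
  cn_c <- design_constraints(
    length = 20L, rng_seed = seed + 1L,
    cross_run_max = 4L, max_self_run = 4L,
    forbidden_partners = list(
      InA = in_a, InA_rc = reverse_complement(in_a),
      InB = in_b, InB_rc = reverse_complement(in_b)
    )
  )
  in_c <- generate_oligo(cn_c)$sequence
  cn_d <- design_constraints(
    length = 22L, rng_seed = seed + 2L,
    cross_run_max = 4L, max_self_run = 4L,
    forbidden_partners = c(
      cn_c$forbidden_partners,
      list(InC = in_c, InC_rc = reverse_complement(in_c))
    )
  )
  in_d <- generate_oligo(cn_d)$sequence
  inputs <- c(InA = in_a, InB = in_b, InC = in_c, InD = in_d)

  # single-input gates declare the other dual-gate input as a bystander,
  # mirroring the non-specific-input control lanes of the gate panels
  defs <- list(
    yes_InA = list(expr = "YES(InA)", declared = c("InA", "InB")),
    yes_InB = list(expr = "YES(InB)", declared = c("InA", "InB")),
    not_InA = list(expr = "NOT(InA)", declared = c("InA", "InB")),
    not_InB = list(expr = "NOT(InB)", declared = c("InA", "InB")),
    or_InA_InB = list(expr = "OR(InA, InB)", declared = c("InA", "InB")),
    and_InA_InB = list(expr = "AND(InA, InB)", declared = c("InA", "InB")),
    and4 = list(
      expr = "AND(InA, InB, InC, InD)",
      declared = c("InA", "InB", "InC", "InD")
    ),
    composite_and_not = list(
      expr = "AND(InA, NOT(InB))", declared = c("InA", "InB")
    )
  )

  fixtures <- lapply(seq_along(defs), function(i) {
    expr <- defs[[i]]$expr
    declared <- defs[[i]]$declared
    spec <- gate_spec(expr, inputs = inputs[declared])
    cn <- design_constraints(
      length = 20L, rng_seed = seed + 100L + i,
      forbidden_partners = as.list(inputs[declared])
    )
    grid <- expand.grid(
      rep(list(c(FALSE, TRUE)), length(declared)),
      KEEP.OUT.ATTRS = FALSE
    )
    names(grid) <- declared
    expected <- vapply(seq_len(nrow(grid)), function(r) {
      eval_expression(expr, unlist(grid[r, , drop = FALSE]))
    }, logical(1))
    tt <- tibble::as_tibble(grid)
    tt$combo <- vapply(seq_len(nrow(grid)), function(r) {
      combo_label(declared[unlist(grid[r, , drop = TRUE])])
    }, character(1))
    tt$expected <- expected
    list(
      name = names(defs)[i],
      spec = spec,
      constraints = cn,
      expected = tt
    )
  })
  names(fixtures) <- names(defs)

  structure(
    list(
      seed = as.integer(seed),
      version = "1",
      inputs = inputs,
      input_designs = list(
        InA = pair$InA, InB = pair$InB
      ),
      fixtures = fixtures
    ),
    class = "dt_fixture_set"
  )
}

#' Compile one packaged fixture
#'
#' @param fixture_set A `dt_fixture_set` from [generate_fixtures()].
#' @param name Fixture name (see `names(fixture_set$fixtures)`).
#' @return A `dt_compiled_gate`.
#' @export
compile_fixture <- function(fixture_set, name) {
  fx <- fixture_set$fixtures[[name]]
  if (is.null(fx)) {
    rlang::abort(sprintf("unknown fixture '%s'", name))
  }
  compile_gate(fx$spec, constraints = fx$constraints)
}

#' Write the fixture input strands to FASTA
#'
#' The description line of each record carries the generator seed and
#' fixture-set version, so the committed file is regenerable.
#'
#' @param fixture_set A `dt_fixture_set`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_fixture_fasta <- function(fixture_set, path) {
  tb <- tibble::tibble(
    name = names(fixture_set$inputs),
    sequence = unname(fixture_set$inputs),
    role = "input",
    anchor = "none",
    modifications = "",
    extra = sprintf(
      "seed=%d;version=%s;synthetic=true",
      fixture_set$seed, fixture_set$version
    )
  )
  write_strands(tb, path)
}
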