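test_that("generation is deterministic given constraints and seed", {
  cn <- design_constraints(length = 17, rng_seed = 42)
  o1 <- generate_oligo(cn)
  o2 <- generate_oligo(cn)
  expect_identical(o1$sequence, o2$sequence)
  expect_identical(o1$attempts, o2$attempts)
  o3 <- generate_oligo(design_constraints(length = 17, rng_seed = 43))
  expect_false(identical(o1$sequence, o3$sequence))
})

test_that("impossible constraint sets fail fast with the dominant culprit", {
  cn <- design_constraints(
    length = 10, gc_range = c(1, 1), max_self_run = 1,
    rng_seed = 1, max_attempts = 300
  )
  err <- expect_error(
    generate_oligo(cn),
    class = "dt_infeasible_constraints"
  )
  expect_match(conditionMessage(err), "most frequent failure")
})

test_that("constraint reports are independently re-verifiable", {
  partner <- "GTTTCCTACCATCTGAA"
  cn <- design_constraints(
    length = 24, rng_seed = 9,
    forbidden_partners = list(p1 = partner)
  )
  o <- generate_oligo(cn)
  rep <- tidy(o)
  expect_true(all(rep$pass))
  # re-check every measured value with the independent oracles
  expect_equal(
    rep$measured[rep$constraint == "hairpin_mfe"],
    oracle_hairpin_mfe(o$sequence),
    tolerance = 1e-9
  )
  expect_equal(
    rep$measured[rep$constraint == "cross_run_vs_p1"],
    oracle_cross_run(o$sequence, partner)
  )
  expect_equal(
    rep$measured[rep$constraint == "self_complement_run"],
    oracle_cross_run(o$sequence, o$sequence)
  )
  expect_lte(max_homopolymer_run(o$sequence), cn$max_homopolymer)
  gc <- gc_fraction(o$sequence)
  expect_true(gc >= cn$gc_range[1] && gc <= cn$gc_range[2])
})

test_that("cross-complement runs match the brute-force scan", {
  a <- "ACGTACGTAC"
  expect_identical(
    longest_cross_complement_run(a, reverse_complement(a)),
    nchar(a)
  )
  expect_identical(longest_cross_complement_run("AAAA", "CCCC"), 0L)
  set.seed(77)
  for (i in 1:50) {
    x <- random_seq(20)
    y <- random_seq(20)
    expect_identical(
      longest_cross_complement_run(x, y),
      as.integer(oracle_cross_run(x, y)),
      label = paste(x, y)
    )
  }
})

test_that("the default input pair reproduces the published design rules", {
  pair <- design_input_pair(rng_seed = 7)
  # unequal sizes: 17 nt and 28 nt
  expect_identical(nchar(pair$InA$sequence), 17L)
  expect_identical(nchar(pair$InB$sequence), 28L)
  # complete absence of secondary hairpin structures (dG > 0 kcal/mol)
  expect_gt(hairpin_mfe(pair$InA$sequence), 0)
  expect_gt(hairpin_mfe(pair$InB$sequence), 0)
  # lack of complementarity to each other: run below the 4-nt cap
  expect_lt(
    longest_cross_complement_run(pair$InA$sequence, pair$InB$sequence), 4
  )
  # reproducible by seed
  pair2 <- design_input_pair(rng_seed = 7)
  expect_identical(pair$InA$sequence, pair2$InA$sequence)
  expect_identical(pair$InB$sequence, pair2$InB$sequence)
})

test_that("staples leave exactly the toehold unpaired on the receptor", {
  receptor <- "TAGCAACAAGTCGCCTA"
  st <- design_staple(receptor,
    toehold_len = 5,
    constraints = design_constraints(length = 20, rng_seed = 5)
  )
  expect_identical(st$core_span, c(0L, 12L)) # 17 - 5 toehold
  geom <- st$geometry
  toe <- geom[geom$segment == "receptor_toehold", ]
  expect_identical(toe$end - toe$start, 5L)
  # the staple's 5' arm is exactly complementary to the receptor span
  arm <- substr(st$sequence, 1, 12)
  expect_identical(arm, reverse_complement(substr(receptor, 1, 12)))
  # staple:receptor duplex energy matches the hand-summed oracle
  expect_equal(
    duplex_dg(duplex_region(
      substr(receptor, 1, 12), arm
    ), thermo_params()),
    oracle_duplex_dg(substr(receptor, 1, 12)),
    tolerance = 1e-9
  )
})

test_that("staples avoid cross-talk with named non-cognate inputs", {
  # co-designed pair: the receptor is the complement of InA, so its fixed
  # core arm inherits InA's bounded cross-talk against InB
  pair <- design_input_pair(rng_seed = 7)
  receptor <- reverse_complement(pair$InA$sequence)
  in_b <- pair$InB$sequence
  st <- design_staple(receptor,
    constraints = design_constraints(
      length = 20, rng_seed = 11,
      forbidden_partners = list(InB = in_b)
    )
  )
  expect_lte(longest_cross_complement_run(st$sequence, in_b), 3L)
  expect_lte(
    longest_cross_complement_run(st$shield_ligand$sequence, in_b), 3L
  )
})

test_that("staple geometry rejects impossible overlaps", {
  expect_error(
    design_staple("ACGTACGTAC", overlap_core = 9, toehold_len = 5),
    "geometric infeasibility"
  )
})

test_that("feasible oligo-scale constraint sets succeed across seeds", {
  set.seed(2024)
  lens <- sample(15:45, 20, replace = TRUE)
  for (i in seq_along(lens)) {
    o <- generate_oligo(design_constraints(
      length = lens[i], hairpin_dg_floor = 0, rng_seed = 5000 + i
    ))
    expect_identical(nchar(o$sequence), as.integer(lens[i]))
  }
})
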