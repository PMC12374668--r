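test_that("a stapled YES gate compiles to the three-strand interface", {
  g <- get_gate("yes_InA")
  expect_setequal(
    g$strands$role,
    c("core_receptor", "staple", "shield_ligand")
  )
  expect_identical(nrow(g$strands), 3L)
  # output marker co-localized on the core receptor
  expect_match(
    g$strands$modifications[g$strands$role == "core_receptor"],
    "3'-biotin"
  )
  # receptor fully complementary to the input, toehold distal
  fx <- get_fixtures()
  receptor <- g$strands$sequence[g$strands$role == "core_receptor"]
  expect_identical(receptor, reverse_complement(fx$inputs[["InA"]]))
  im <- g$invasion_map
  expect_identical(nrow(im), 1L)
  expect_identical(im$toehold_end - im$toehold_start, 5L)
})

test_that("direct architecture supports YES but not staple-requiring gates", {
  fx <- get_fixtures()
  spec_yes <- gate_spec("YES(InA)",
    inputs = fx$inputs["InA"],
    architecture = "direct"
  )
  g <- compile_gate(spec_yes, design_constraints(length = 20, rng_seed = 1))
  expect_setequal(g$strands$role, c("core_receptor", "shield_ligand"))
  spec_or <- gate_spec("OR(InA, InB)",
    inputs = fx$inputs[c("InA", "InB")],
    architecture = "direct"
  )
  expect_error(
    compile_gate(spec_or, design_constraints(length = 20, rng_seed = 1)),
    "architecture requires staple"
  )
})

test_that("AND gates partition one junction into disjoint migration spans", {
  g <- get_gate("and_InA_InB")
  im <- g$invasion_map
  expect_identical(nrow(im), 2L)
  expect_identical(length(unique(im$junction_id)), 1L)
  # disjoint spans
  a <- im[1, ]
  b <- im[2, ]
  expect_true(a$migration_end <= b$migration_start ||
    b$migration_end <= a$migration_start)
  # their union covers the incumbent pairing of that junction
  pr <- g$assembled_pairs[
    !is.na(g$assembled_pairs$junction_id) &
      g$assembled_pairs$junction_id == im$junction_id[1],
  ]
  expect_identical(
    sum(pr$end_a - pr$start_a),
    sum(im$migration_end - im$migration_start)
  )
})

test_that("OR gates sever either of two junctions on one staple", {
  g <- get_gate("or_InA_InB")
  expect_identical(nrow(g$strands), 3L) # receptor, staple, ligand
  sev <- g$junctions[g$junctions$severable, ]
  expect_identical(nrow(sev), 2L)
  im <- g$invasion_map
  expect_identical(sort(unique(im$anchor_strand)), sort(c("i-r1", "N1")))
})

test_that("four-input AND stays on a single staple", {
  g <- get_gate("and4")
  expect_identical(nrow(g$strands), 3L)
  expect_identical(nrow(g$invasion_map), 4L)
  expect_identical(length(unique(g$invasion_map$junction_id)), 1L)
})

test_that("infeasible cooperative partitions are rejected with evidence", {
  fx <- get_fixtures()
  # 6-nt inputs leave 1-nt migration segments after the 5-nt toehold:
  # far above any workable hold threshold
  expect_error(
    compile_gate(
      gate_spec("AND(u, v)", inputs = c(u = "ACGTGC", v = "TGACCA")),
      design_constraints(length = 20, rng_seed = 1)
    ),
    class = "dt_infeasible_partition"
  )
})

test_that("compilation is deterministic and round-trips through JSON", {
  fx <- get_fixtures()
  g1 <- compile_fixture(fx, "yes_InB")
  g2 <- compile_fixture(fx, "yes_InB")
  expect_identical(g1$strands, g2$strands)
  expect_identical(g1$assembled_pairs, g2$assembled_pairs)

  f1 <- tempfile(fileext = ".json")
  f2 <- tempfile(fileext = ".json")
  write_compiled_gate(g1, f1)
  g3 <- read_compiled_gate(f1)
  write_compiled_gate(g3, f2)
  expect_identical(
    readBin(f1, "raw", file.size(f1)),
    readBin(f2, "raw", file.size(f2))
  )
  expect_identical(g3$strands, g1$strands)
  expect_identical(g3$invasion_map, g1$invasion_map)
})

test_that("the pairing map is an involution with accessible toeholds", {
  for (nm in c("yes_InA", "or_InA_InB", "and4", "composite_and_not")) {
    g <- get_gate(nm)
    v <- validate_design(g)
    expect_true(
      all(v$pass[v$check %in% c(
        "pairing_complementarity", "pairing_involution",
        "toehold_accessible"
      )]),
      label = nm
    )
  }
})

test_that("freshly compiled gates pass the full design validation", {
  for (nm in names(get_fixtures()$fixtures)) {
    v <- validate_design(get_gate(nm))
    expect_true(all(v$pass), label = nm)
  }
})

test_that("a staple mutated toward a non-cognate input fails cross-talk", {
  g <- get_gate("yes_InA")
  fx <- get_fixtures()
  bad <- g
  idx <- which(bad$strands$role == "staple")
  s <- bad$strands$sequence[idx]
  # splice an 8-nt reverse-complement window of the non-cognate input
  insert <- reverse_complement(substr(fx$inputs[["InB"]], 1, 8))
  bad$strands$sequence[idx] <- paste0(
    substr(s, 1, nchar(s) - 8), insert
  )
  v <- validate_design(bad)
  bad_rows <- v[v$check == "cross_talk" & grepl("InB vs N1", v$target), ]
  expect_false(any(bad_rows$pass))
})

test_that("separate and amplified output modes add the 30-nt output receptor", {
  fx <- get_fixtures()
  spec <- gate_spec("YES(InA)",
    inputs = fx$inputs["InA"],
    output_mode = "separate"
  )
  g <- compile_gate(spec, design_constraints(length = 20, rng_seed = 2))
  orec <- g$strands[g$strands$role == "output_receptor", ]
  expect_identical(nrow(orec), 1L)
  expect_identical(nchar(orec$sequence), 30L)
  # designed to avoid pronounced secondary structure (>= -2 kcal/mol)
  expect_gte(hairpin_mfe(orec$sequence), -2.0)
  # no displacement-competent complementarity with the inputs
  expect_lte(
    longest_cross_complement_run(orec$sequence, fx$inputs[["InA"]]), 4L
  )

  spec_amp <- gate_spec("YES(InA)",
    inputs = fx$inputs["InA"],
    output_mode = "amplified"
  )
  g2 <- compile_gate(spec_amp, design_constraints(length = 20, rng_seed = 2))
  expect_true("output_ligand" %in% g2$strands$role)
  expect_identical(
    g2$strands$anchor[g2$strands$role == "output_ligand"],
    "auxiliary_particle"
  )
})
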