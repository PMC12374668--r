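test_that("empty paired span has zero interaction energy", {
  reg <- duplex_region("ACGT", "ACGT", span_a = c(0, 0), span_b = c(0, 0))
  expect_identical(duplex_dg(reg), 0.0)
  expect_false(duplex_is_stable(reg, dg_hold = -1))
})

test_that("duplex free energy matches the hand-summed table lookup", {
  p <- thermo_params()
  # 4-bp duplex: three stacks + initiation + two terminal A/T penalties
  expect_equal(
    duplex_dg(duplex_region("ACGT", "ACGT"), p),
    oracle_duplex_dg("ACGT"),
    tolerance = 1e-12
  )
  # GC-only duplex: no terminal penalty
  expect_equal(
    duplex_dg(duplex_region("GCGC", "GCGC"), p),
    oracle_duplex_dg("GCGC"),
    tolerance = 1e-12
  )
  # longer mixed duplex at assembly conditions (25 C, 0.5 M salt)
  top <- "GATTACAGATTACAGT"
  pa <- assembly_params()
  expect_equal(
    duplex_dg(duplex_region(top, reverse_complement(top)), pa),
    oracle_duplex_dg(top, temperature = 298.15, salt = 0.5),
    tolerance = 1e-12
  )
})

test_that("non-complementary spans are rejected", {
  expect_error(
    duplex_dg(duplex_region("ACGT", "GGGG")),
    "invalid duplex"
  )
})

test_that("duplex energy is invariant under reversing the duplex", {
  set.seed(11)
  p <- thermo_params()
  for (i in 1:25) {
    n <- sample(2:30, 1)
    top <- random_seq(n)
    fwd <- duplex_dg(duplex_region(top, reverse_complement(top)), p)
    # read from the other end: both strands reverse-complemented
    rev <- duplex_dg(duplex_region(
      reverse_complement(top),
      top
    ), p)
    expect_equal(fwd, rev, tolerance = 1e-9)
  }
})

test_that("adding a stacked pair never destabilizes, for all 16 stacks", {
  p <- thermo_params()
  bases <- c("A", "C", "G", "T")
  for (x in bases) {
    for (y in bases) {
      shorter <- paste0("GC", x) # anchor so both ends well-defined
      longer <- paste0(shorter, y)
      dg_s <- duplex_dg(duplex_region(shorter, reverse_complement(shorter)), p)
      dg_l <- duplex_dg(duplex_region(longer, reverse_complement(longer)), p)
      expect_lte(dg_l, dg_s + 1e-9)
    }
  }
})

test_that("raising monovalent salt never destabilizes a duplex", {
  top <- "GATTACAGATTACA"
  salts <- c(0.02, 0.05, 0.1, 0.15, 0.3, 0.5, 0.8, 1.0)
  dgs <- vapply(salts, function(s) {
    duplex_dg(
      duplex_region(top, reverse_complement(top)),
      thermo_params(monovalent_salt = s)
    )
  }, numeric(1))
  expect_true(all(diff(dgs) <= 1e-12))
})

test_that("stability cutoff uses the at-least-as-stable tie rule", {
  p <- thermo_params()
  reg <- duplex_region("GCGCGC", "GCGCGC")
  dg <- duplex_dg(reg, p)
  expect_true(duplex_is_stable(reg, p, dg_hold = dg)) # boundary: stable
  expect_true(duplex_is_stable(reg, p, dg_hold = dg + 1))
  expect_false(duplex_is_stable(reg, p, dg_hold = dg - 1))
  # a long GC-rich duplex is far below the default cutoff
  expect_true(duplex_is_stable(
    duplex_region("GCGGCCGCGGCCGCGGCCGC", "GCGGCCGCGGCCGCGGCCGC"),
    p
  ))
})

test_that("amfe is the plain energy-per-pair ratio", {
  expect_equal(amfe(-30.0, 20), -1.5)
  expect_equal(amfe(0.0, 7), 0.0)
  expect_error(amfe(-10, 0), "undefined AMFE")
  set.seed(3)
  for (i in 1:20) {
    x <- stats::runif(1, -3, 0)
    k <- sample(1:40, 1)
    expect_equal(amfe(x * k, k), x, tolerance = 1e-12)
  }
})

test_that("amfe of a staple complex matches the table-lookup oracle", {
  p <- thermo_params()
  st <- design_staple("TAGCAACAAGTCGCCTA",
    constraints = design_constraints(length = 20, rng_seed = 5)
  )
  core_top <- substr("TAGCAACAAGTCGCCTA", st$core_span[1] + 1, st$core_span[2])
  lig_top <- substr(
    st$shield_ligand$sequence, st$ligand_span[1] + 1, st$ligand_span[2]
  )
  dg_complex <- duplex_dg(
    duplex_region(core_top, reverse_complement(core_top)), p
  ) +
    duplex_dg(duplex_region(lig_top, reverse_complement(lig_top)), p)
  n_bp <- nchar(core_top) + nchar(lig_top)
  expect_equal(
    amfe(dg_complex, n_bp),
    (oracle_duplex_dg(core_top) + oracle_duplex_dg(lig_top)) / n_bp,
    tolerance = 1e-9
  )
})

test_that("sequences without a possible stem report no structure", {
  expect_identical(hairpin_mfe("AAAAAAAAAA"), Inf)
  expect_identical(hairpin_mfe("ACGT"), Inf) # too short for stem + loop
  expect_true(passes_hairpin_floor("AAAAAAAAAA", floor = 50))
})

test_that("a designed single-hairpin sequence scores stem + loop penalty", {
  # GGGC arms with a 5-nt A-loop: the dominant placement is the 4-bp stem
  seq <- "GGGCAAAAAGCCC"
  p <- thermo_params()
  stem_loop <- duplex_dg(duplex_region("GGGC", "GCCC"), p) + loop_penalty(5, p)
  expect_equal(hairpin_mfe(seq, p), stem_loop, tolerance = 1e-9)
  expect_equal(hairpin_mfe(seq, p), oracle_hairpin_mfe(seq), tolerance = 1e-9)
})

test_that("hairpin MFE is mirror-symmetric under reverse complement", {
  set.seed(21)
  for (i in 1:30) {
    s <- random_seq(sample(7:25, 1))
    expect_equal(
      hairpin_mfe(s), hairpin_mfe(reverse_complement(s)),
      tolerance = 1e-9
    )
  }
})

test_that("hairpin MFE equals exhaustive stem/loop enumeration", {
  set.seed(101)
  for (i in 1:250) {
    s <- random_seq(sample(5:12, 1))
    expect_equal(
      hairpin_mfe(s), oracle_hairpin_mfe(s),
      tolerance = 1e-9, label = s
    )
  }
})

test_that("loop penalties extrapolate logarithmically past the table", {
  p <- thermo_params()
  expect_equal(loop_penalty(3, p), 3.5, tolerance = 1e-12)
  expect_gt(loop_penalty(45, p), loop_penalty(30, p))
  expect_error(loop_penalty(2, p), "forbidden")
})

test_that("degenerate alphabet and empty sequences are rejected", {
  expect_error(as_dna("ACGN"), "non-ACGT")
  expect_error(as_dna(""), "non-empty")
  expect_error(hairpin_mfe("ACGRT"), "non-ACGT")
})
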