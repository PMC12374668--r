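test_that("single-input gates switch only on their cognate input", {
  # YES(InA): signal high iff InA present, with or without the bystander
  g <- get_gate("yes_InA")
  p <- sim_params()
  expect_equal(simulate_gate(g, character(0), p)$signal, p$signal_min)
  expect_equal(simulate_gate(g, "InA", p)$signal, p$signal_max)
  rep <- get_report("yes_InA")
  expect_true(rep$correct)
  expect_identical(rep$truth_table$output, rep$truth_table$expected)
})

test_that("NOT gates invert polarity: the marker leaves with the input", {
  g <- get_gate("not_InA")
  p <- sim_params()
  r0 <- simulate_gate(g, character(0), p)
  r1 <- simulate_gate(g, "InA", p)
  expect_equal(r0$signal, p$signal_max)
  expect_equal(r1$signal, p$signal_min)
  expect_true(r0$marker_present)
  expect_false(r1$marker_present)
  # pointwise complement of the YES table on the same input
  yes_tt <- truth_table(get_gate("yes_InA"))$truth_table
  not_tt <- truth_table(g)$truth_table
  expect_identical(not_tt$output, !yes_tt$output)
})

test_that("OR fires on either or both inputs, AND only on both", {
  p <- sim_params()
  g_or <- get_gate("or_InA_InB")
  expect_equal(simulate_gate(g_or, "InA", p)$signal, p$signal_max)
  expect_equal(simulate_gate(g_or, "InB", p)$signal, p$signal_max)
  expect_equal(simulate_gate(g_or, c("InA", "InB"), p)$signal, p$signal_max)
  expect_equal(simulate_gate(g_or, character(0), p)$signal, p$signal_min)

  g_and <- get_gate("and_InA_InB")
  expect_equal(simulate_gate(g_and, c("InA", "InB"), p)$signal, p$signal_max)
  for (cb in list(character(0), "InA", "InB")) {
    expect_equal(simulate_gate(g_and, cb, p)$signal, p$signal_min)
  }
})

test_that("a blocked toehold makes invasion a no-op", {
  g <- get_gate("yes_InA")
  state <- dnatransformr:::new_sim_state(g)
  im <- g$invasion_map[1, ]
  # artificially occupy the toehold with a blocker strand
  state$pairs <- dplyr::bind_rows(
    state$pairs,
    tibble::tibble(
      pair_id = 999L, strand_a = im$anchor_strand,
      start_a = im$toehold_start, end_a = im$toehold_end,
      strand_b = "blocker", start_b = 0L,
      end_b = im$toehold_end - im$toehold_start,
      junction_id = NA_integer_
    )
  )
  out <- displacement_step(state, "InA", g, sim_params())
  expect_identical(out$pairs, state$pairs)
  expect_length(out$trace, 0)
  expect_error(
    displacement_step(state, "nope", g, sim_params()),
    "unknown invader"
  )
})

test_that("a lone AND input leaves a stable residual, verified thermodynamically", {
  g <- get_gate("and_InA_InB")
  p <- sim_params()
  r <- simulate_gate(g, "InA", p)
  expect_identical(nrow(r$trace), 1L)
  ev <- r$trace[1, ]
  expect_false(ev$incumbent_dissociated)
  # the residual is the InB migration segment; check against the oracle
  im <- g$invasion_map[g$invasion_map$input == "InB", ]
  anchor_seq <- g$strands$sequence[g$strands$name == im$anchor_strand]
  seg <- substr(anchor_seq, im$migration_start + 1, im$migration_end)
  expect_equal(ev$residual_dg, oracle_duplex_dg(seg), tolerance = 1e-9)
  expect_lte(ev$residual_dg, p$dg_hold - g$and_margin + 1e-9)
  # the full pair, by contrast, dissociates the staple completely
  r2 <- simulate_gate(g, c("InA", "InB"), p)
  expect_true(any(r2$trace$incumbent_dissociated))
})

test_that("the final state is order-independent for every permutation", {
  perms2 <- list(c("InA", "InB"), c("InB", "InA"))
  for (nm in c("or_InA_InB", "and_InA_InB", "composite_and_not")) {
    g <- get_gate(nm)
    base <- simulate_gate(g, c("InA", "InB"), input_order = perms2[[1]])
    for (ord in perms2[-1]) {
      alt <- simulate_gate(g, c("InA", "InB"), input_order = ord)
      expect_identical(alt$detached, base$detached, label = nm)
      expect_identical(alt$signal, base$signal, label = nm)
      expect_identical(alt$marker_present, base$marker_present, label = nm)
    }
  }
  # sampled permutations for the four-input gate
  g4 <- get_gate("and4")
  ins <- names(g4$inputs)
  base <- simulate_gate(g4, ins, input_order = ins)
  set.seed(5)
  for (i in 1:4) {
    ord <- sample(ins)
    alt <- simulate_gate(g4, ins, input_order = ord)
    expect_identical(alt$detached, base$detached)
    expect_identical(alt$signal, base$signal)
  }
})

test_that("strands are conserved and pairings stay within bounds", {
  for (nm in c("yes_InA", "or_InA_InB", "and4")) {
    g <- get_gate(nm)
    lens <- stats::setNames(nchar(g$strands$sequence), g$strands$name)
    ins <- names(g$inputs)
    for (cb in list(character(0), ins[1], ins)) {
      r <- simulate_gate(g, cb)
      fp <- r$final_pairs
      for (i in seq_len(nrow(fp))) {
        if (fp$strand_a[i] %in% names(lens)) {
          expect_lte(fp$end_a[i], lens[[fp$strand_a[i]]])
          expect_gte(fp$start_a[i], 0L)
        }
      }
      # no strand disappears: the strand table is untouched by simulation
      expect_identical(
        sort(g$strands$name),
        sort(unique(get_gate(nm)$strands$name))
      )
    }
  }
})

test_that("gate metrics follow their defining identities", {
  m <- gate_metrics(c(1.0, 0.04), "YES(a)", list("a", character(0)))
  expect_equal(m$threshold, 0.2) # sqrt(1.0 * 0.04)
  expect_equal(m$shield_ratio, 25)
  expect_true(m$correct)
  m2 <- gate_metrics(c(1.0, 0.1), "YES(a)", list("a", character(0)))
  expect_equal(m2$shield_ratio, 10)
  expect_error(
    gate_metrics(c(0.5, 0.5), "YES(a)", list("a", character(0))),
    class = "dt_degenerate_gate"
  )
})

test_that("noiseless false states are identical, so leakage CV is zero", {
  rep <- get_report("and_InA_InB")
  false_sig <- rep$truth_table$signal[!rep$truth_table$expected]
  expect_identical(length(unique(false_sig)), 1L)
  expect_identical(rep$leakage_cv, 0)
})

test_that("multiplicative noise is seeded and reproducible", {
  g <- get_gate("yes_InA")
  p <- sim_params(noise_cv = 0.04, rng_seed = 31)
  r1 <- truth_table(g, p)
  r2 <- truth_table(g, p)
  expect_identical(r1$truth_table$signal, r2$truth_table$signal)
  expect_false(identical(
    r1$truth_table$signal,
    truth_table(g, sim_params(noise_cv = 0.04, rng_seed = 32))$truth_table$signal
  ))
})

test_that("deeper staple/receptor overlap never weakens resting shielding", {
  fx <- get_fixtures()
  margins <- vapply(3:7, function(t_len) {
    g <- compile_gate(
      gate_spec("YES(InA)", inputs = fx$inputs["InA"]),
      design_constraints(length = 20, rng_seed = 3),
      toehold_len = t_len
    )
    # resting stability of the severable receptor:staple duplex
    st <- dnatransformr:::new_sim_state(g)
    j <- g$junctions$junction_id[g$junctions$severable][1]
    dnatransformr:::junction_residual_dg(st, g, j, thermo_params())
  }, numeric(1))
  # toehold shrinks -> overlap grows -> resting duplex monotonically stronger
  expect_true(all(diff(margins) >= -1e-9))
})

test_that("composite gates expose markers only when every shield departs", {
  g <- get_gate("composite_and_not")
  p <- sim_params()
  expect_equal(simulate_gate(g, "InA", p)$signal, p$signal_max)
  expect_equal(simulate_gate(g, c("InA", "InB"), p)$signal, p$signal_min)
  expect_equal(simulate_gate(g, "InB", p)$signal, p$signal_min)
  expect_equal(simulate_gate(g, character(0), p)$signal, p$signal_min)
})
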