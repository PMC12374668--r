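# Domain-level toehold-mediated strand-displacement semantics. The default
# (equilibrium) mode is deterministic and order-independent: each present
# input that finds its toehold accessible pairs it and migrates through its
# migration span; an incumbent strand dissociates from a junction as soon
# as the junction's residual duplex no longer clears the hold threshold.
# Endpoint readouts (incubation followed by washing) make this
# equilibrium-like semantics the natural default; the kinetic layer in
# kinetics.R adds time courses on top of the same displacement steps.

#' Simulation parameters
#'
#' @param thermo [thermo_params()] used for residual-duplex energies.
#' @param dg_hold Residual-duplex stability cutoff in kcal/mol: residuals
#'   at least this stable keep their bridge attached (ties count as
#'   stable). Default -8, around the stability of 5-6 mixed base pairs.
#' @param toehold_min Minimum accessible toehold length in nt required to
#'   initiate displacement.
#' @param signal_max Analog output of the fully unshielded core, arbitrary
#'   units (normalized scale).
#' @param signal_min Fully shielded background signal.
#' @param noise_cv Coefficient of variation of optional multiplicative
#'   Gaussian signal noise (0 disables noise).
#' @param kinetic_mode Logical; when `TRUE`, [kinetic_simulate()] applies.
#' @param rng_seed Integer seed for noise and kinetic sampling.
#' @param input_concentration Input oligonucleotide concentration in mol/L
#'   (kinetic mode only; default 1e-6 M).
#' @return A `dt_sim_params` list.
#' @export
sim_params <- function(thermo = thermo_params(),
                       dg_hold = -8.0,
                       toehold_min = 3L,
                       signal_max = 1.0,
                       signal_min = 0.04,
                       noise_cv = 0,
                       kinetic_mode = FALSE,
                       rng_seed = 1L,
                       input_concentration = 1e-6) {
  if (!(signal_max > signal_min && signal_min > 0)) {
    rlang::abort("signal_max > signal_min > 0 is required")
  }
  if (toehold_min < 1L) rlang::abort("toehold_min must be >= 1")
  structure(
    list(
      thermo = thermo, dg_hold = dg_hold,
      toehold_min = as.integer(toehold_min),
      signal_max = signal_max, signal_min = signal_min,
      noise_cv = noise_cv, kinetic_mode = isTRUE(kinetic_mode),
      rng_seed = as.integer(rng_seed),
      input_concentration = input_concentration
    ),
    class = "dt_sim_params"
  )
}

#' @noRd
new_sim_state <- function(gate) {
  list(
    pairs = gate$assembled_pairs,
    trace = list()
  )
}

# Is span [s0, s1) on `strand` free of pairing in the current state?
#' @noRd
span_unpaired <- function(state, strand, s0, s1) {
  p <- state$pairs
  hit_a <- p$strand_a == strand & p$start_a < s1 & p$end_a > s0
  hit_b <- p$strand_b == strand & p$start_b < s1 & p$end_b > s0
  !any(hit_a | hit_b)
}

# Residual free energy of a junction: sum of the duplex energies of its
# remaining paired segments (each segment scored as an independent helix).
#' @noRd
junction_residual_dg <- function(state, gate, junction_id, params) {
  rows <- state$pairs[!is.na(state$pairs$junction_id) &
    state$pairs$junction_id == junction_id, ]
  if (nrow(rows) == 0L) {
    return(0.0)
  }
  seqs <- gate$strands$sequence[match(rows$strand_a, gate$strands$name)]
  sum(vapply(seq_len(nrow(rows)), function(i) {
    nn_duplex_energy(substr(seqs[i], rows$start_a[i] + 1L, rows$end_a[i]),
      params = params
    )
  }, numeric(1)))
}

#' Apply one toehold-mediated displacement step
#'
#' If the invader's toehold span is unpaired in the current state (and at
#' least `toehold_min` nt long), the invader pairs its toehold and
#' migrates through its migration span, unpairing the incumbent there.
#' The incumbent dissociates from the junction entirely iff the junction's
#' residual paired region fails [duplex_is_stable()]; otherwise the
#' partially displaced state is retained (the basis of AND cooperativity).
#' Returns the state unchanged (no-op) when the toehold is blocked or the
#' site is already displaced.
#'
#' @param state Simulation state as created internally by [simulate_gate()]
#'   (list with a `pairs` tibble and a `trace` list).
#' @param invader Input name; must appear in `gate$invasion_map`.
#' @param gate A `dt_compiled_gate`.
#' @param params A [sim_params()] object.
#' @return The updated state.
#' @export
displacement_step <- function(state, invader, gate, params = sim_params()) {
  sites <- gate$invasion_map[gate$invasion_map$input == invader, ]
  if (nrow(sites) == 0L) {
    rlang::abort(sprintf("unknown invader '%s'", invader))
  }
  for (i in seq_len(nrow(sites))) {
    state <- attempt_invasion(state, sites[i, ], gate, params)
  }
  state
}

# Can this invasion site fire in the current state? (accessible toehold of
# sufficient length, incumbent still paired over the migration span)
#' @noRd
site_enabled <- function(state, site, params) {
  toe_len <- site$toehold_end - site$toehold_start
  if (toe_len < params$toehold_min) {
    return(FALSE)
  }
  if (!span_unpaired(
    state, site$anchor_strand, site$toehold_start, site$toehold_end
  )) {
    return(FALSE)
  }
  p <- state$pairs
  any(
    p$strand_a == site$anchor_strand & p$strand_b == site$incumbent &
      p$start_a < site$migration_end & p$end_a > site$migration_start
  )
}

# Apply a single invasion site; no-op (state returned unchanged) when the
# site is not enabled.
#' @noRd
attempt_invasion <- function(state, site, gate, params) {
  if (!site_enabled(state, site, params)) {
    return(state)
  }
  p <- state$pairs
  idx <- which(
    p$strand_a == site$anchor_strand & p$strand_b == site$incumbent &
      p$start_a < site$migration_end & p$end_a > site$migration_start
  )
  state$pairs <- p[-idx, ]
  # invader now occupies toehold + migration span on the anchor strand
  state$pairs <- dplyr::bind_rows(
    state$pairs,
    tibble::tibble(
      pair_id = max(c(0L, gate$assembled_pairs$pair_id)) +
        length(state$trace) + 1L,
      strand_a = site$anchor_strand,
      start_a = as.integer(min(site$migration_start, site$toehold_start)),
      end_a = as.integer(max(site$migration_end, site$toehold_end)),
      strand_b = paste0("input:", site$input),
      start_b = 0L,
      end_b = as.integer(
        max(site$migration_end, site$toehold_end) -
          min(site$migration_start, site$toehold_start)
      ),
      junction_id = NA_integer_
    )
  )
  residual <- junction_residual_dg(state, gate, site$junction_id,
    params = params$thermo
  )
  dissociated <- residual > params$dg_hold + 1e-9
  if (dissociated) {
    keep <- is.na(state$pairs$junction_id) |
      state$pairs$junction_id != site$junction_id
    state$pairs <- state$pairs[keep, ]
  }
  state$trace[[length(state$trace) + 1L]] <- tibble::tibble(
    invader = site$input,
    junction_id = site$junction_id,
    toehold_nt = as.integer(site$toehold_end - site$toehold_start),
    bases_migrated = as.integer(site$migration_end - site$migration_start),
    residual_dg = residual,
    incumbent_dissociated = dissociated
  )
  state
}

# Connectivity of the strand/particle graph under the current pairing:
# returns the set of node names reachable from the core particle.
#' @noRd
core_component <- function(state, gate) {
  edges <- rbind(
    cbind(state$pairs$strand_a, state$pairs$strand_b),
    cbind(
      gate$strands$name[gate$strands$anchor != "none"],
      gate$strands$anchor[gate$strands$anchor != "none"]
    )
  )
  reach <- "core_particle"
  repeat {
    hit <- edges[, 1] %in% reach | edges[, 2] %in% reach
    nxt <- unique(c(reach, edges[hit, 1], edges[hit, 2]))
    if (length(nxt) == length(reach)) {
      return(reach)
    }
    reach <- nxt
  }
}

#' @noRd
attachment_summary <- function(state, gate) {
  comp <- core_component(state, gate)
  shield_assemblies <- gate$assemblies$assembly_id[
    gate$assemblies$kind == "shield"
  ]
  shield_detached <- !(paste0("shield_particle_", shield_assemblies) %in% comp)
  names(shield_detached) <- paste0("shield_", shield_assemblies)
  marker_present <- vapply(seq_len(nrow(gate$markers)), function(i) {
    gate$markers$strand[i] %in% comp
  }, logical(1))
  list(
    shield_detached = shield_detached,
    marker_present = marker_present,
    all_shields_detached = all(shield_detached),
    exposed_fraction = if (all(shield_detached)) {
      if (nrow(gate$markers) == 0L) 0 else mean(marker_present)
    } else {
      0
    }
  )
}

#' Simulate a gate against one input combination
#'
#' Applies [displacement_step()] for every present input iteratively until
#' a fixpoint (the result is order-independent), then maps the final
#' attachment state to an analog signal: the output marker is exposed iff
#' every shield assembly is disconnected from the core particle, and the
#' signal interpolates linearly between `signal_min` and `signal_max` by
#' the fraction of marker strands that remain core-attached and exposed.
#'
#' @param gate A `dt_compiled_gate`.
#' @param combo Character vector of present input names (subset of the
#'   gate's declared inputs); empty vector for the no-input state.
#' @param params A [sim_params()] object.
#' @param input_order Optional processing order of the present inputs
#'   (used by order-independence checks); default sorted order.
#' @return A `dt_simulation_result` list: `input_combo`, `detached`
#'   (named logical per shield bridge), `marker_present`, `signal`,
#'   `exposed_fraction` and `trace` (tibble of displacement events).
#' @export
simulate_gate <- function(gate, combo = character(0), params = sim_params(),
                          input_order = NULL) {
  stopifnot(inherits(gate, "dt_compiled_gate"))
  combo <- as.character(combo)
  unknown <- setdiff(combo, names(gate$inputs))
  if (length(unknown) > 0L) {
    rlang::abort(sprintf(
      "combo contains undeclared inputs: %s", paste(unknown, collapse = ", ")
    ))
  }
  order_in <- input_order %||% sort(combo)
  if (!setequal(order_in, combo)) {
    rlang::abort("input_order must be a permutation of combo")
  }
  state <- new_sim_state(gate)
  max_rounds <- 2L * nrow(gate$invasion_map) + 2L
  round <- 0L
  repeat {
    round <- round + 1L
    if (round > max_rounds) {
      rlang::abort("internal error: displacement fixpoint not reached")
    }
    n_events <- length(state$trace)
    for (x in order_in) {
      if (!x %in% gate$invasion_map$input) next # declared bystander
      state <- displacement_step(state, x, gate, params)
    }
    if (length(state$trace) == n_events) break
  }
  att <- attachment_summary(state, gate)
  signal <- params$signal_min +
    (params$signal_max - params$signal_min) * att$exposed_fraction
  if (params$noise_cv > 0) {
    signal <- signal * max(0, 1 + stats::rnorm(1L, 0, params$noise_cv))
  }
  structure(
    list(
      input_combo = combo,
      detached = att$shield_detached,
      marker_present = att$marker_present,
      exposed_fraction = att$exposed_fraction,
      signal = signal,
      trace = if (length(state$trace)) {
        dplyr::bind_rows(state$trace)
      } else {
        tibble::tibble(
          invader = character(0), junction_id = integer(0),
          toehold_nt = integer(0), bases_migrated = integer(0),
          residual_dg = numeric(0), incumbent_dissociated = logical(0)
        )
      },
      final_pairs = state$pairs
    ),
    class = "dt_simulation_result"
  )
}

#' @noRd
combo_label <- function(combo) {
  if (length(combo) == 0L) "none" else paste(sort(combo), collapse = "+")
}

#' Gate metrics from a combo-to-signal map
#'
#' Computes the report metrics used throughout: the geometric-mean
#' switching threshold `sqrt(max * min)`, the shield ratio
#' (max-state over min-state signal), the leakage CV (coefficient of
#' variation over all false-state signals) and the correctness verdict
#' (every true-state signal above threshold, every false-state signal
#' below).
#'
#' @param signals Numeric vector of analog signals, one per combination.
#' @param expression Boolean expression evaluated per combination to
#'   obtain the expected output.
#' @param combos List of character vectors (present inputs per
#'   combination), parallel to `signals`.
#' @return A list with `threshold`, `shield_ratio`, `leakage_cv`,
#'   `expected` and `correct`.
#' @export
gate_metrics <- function(signals, expression, combos) {
  if (length(signals) == 0L) rlang::abort("empty signal map")
  smax <- max(signals)
  smin <- min(signals)
  if (smax <= smin) {
    rlang::abort("degenerate gate: maximum and minimum outputs coincide",
      class = "dt_degenerate_gate"
    )
  }
  inputs <- expr_inputs(expression)
  expected <- vapply(combos, function(cb) {
    eval_expression(expression, stats::setNames(inputs %in% cb, inputs))
  }, logical(1))
  threshold <- sqrt(smax * smin)
  false_sig <- signals[!expected]
  leakage_cv <- if (length(false_sig) >= 2L && mean(false_sig) > 0) {
    stats::sd(false_sig) / mean(false_sig)
  } else {
    0
  }
  correct <- all(signals[expected] > threshold) &&
    all(signals[!expected] < threshold)
  list(
    threshold = threshold,
    shield_ratio = smax / smin,
    leakage_cv = leakage_cv,
    expected = expected,
    correct = correct
  )
}

#' Full truth table and gate report
#'
#' Simulates all `2^n` input combinations of a compiled gate (n <= 4) and
#' assembles the gate report: per-combination analog signal and thresholded
#' Boolean output, the geometric-mean threshold, shield ratio, leakage CV
#' and correctness verdict.
#'
#' @param gate A `dt_compiled_gate`.
#' @param params A [sim_params()] object; when `noise_cv > 0` signals are
#'   noisy and the run is seeded by `params$rng_seed`.
#' @return A `dt_gate_report`; its `truth_table` field is a tibble with one
#'   logical column per input plus `combo`, `signal`, `output` and
#'   `expected`.
#' @export
#' @examples
#' # see the package vignette for end-to-end examples
truth_table <- function(gate, params = sim_params()) {
  stopifnot(inherits(gate, "dt_compiled_gate"))
  inputs <- names(gate$inputs)
  if (length(inputs) > 4L) {
    rlang::abort("truth tables are limited to gates with at most 4 inputs")
  }
  grid <- expand.grid(
    rep(list(c(FALSE, TRUE)), length(inputs)),
    KEEP.OUT.ATTRS = FALSE
  )
  names(grid) <- inputs
  combos <- lapply(seq_len(nrow(grid)), function(i) {
    inputs[unlist(grid[i, , drop = TRUE])]
  })
  results <- with_rng_seed(params$rng_seed, {
    lapply(combos, function(cb) simulate_gate(gate, cb, params))
  })
  signals <- vapply(results, `[[`, numeric(1), "signal")
  metrics <- gate_metrics(signals, gate$expression, combos)
  tt <- tibble::as_tibble(grid)
  tt$combo <- vapply(combos, combo_label, character(1))
  tt$signal <- signals
  tt$output <- signals > metrics$threshold
  tt$expected <- metrics$expected
  structure(
    list(
      expression = gate$expression,
      truth_table = tt,
      threshold = metrics$threshold,
      shield_ratio = metrics$shield_ratio,
      leakage_cv = metrics$leakage_cv,
      correct = metrics$correct &&
        identical(tt$output, tt$expected),
      results = results
    ),
    class = "dt_gate_report"
  )
}

#' @export
print.dt_gate_report <- function(x, ...) {
  cat(sprintf(
    "<gate_report> %s\n  threshold %.3f (geometric mean), shield ratio %.1f, leakage CV %.3f, %s\n",
    x$expression, x$threshold, x$shield_ratio, x$leakage_cv,
    if (x$correct) "CORRECT" else "INCORRECT"
  ))
  print(x$truth_table[, c("combo", "signal", "output", "expected")])
  invisible(x)
}
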