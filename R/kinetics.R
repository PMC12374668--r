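# Optional stochastic kinetic layer. Displacement events fire as a
# continuous-time Markov jump process over the same domain-level invasion
# sites as the equilibrium mode; the effective bimolecular rate grows
# exponentially with toehold length up to a saturation length, the regime
# observed for toehold-mediated displacement. For thermodynamically
# decisive designs the long-horizon endpoint coincides with the
# equilibrium-mode result.

#' Effective displacement rate constant for a given toehold length
#'
#' @param toehold_nt Accessible toehold length in nt (0 = blunt leak).
#' @param k_bm Base bimolecular rate constant at zero effective toehold
#'   benefit, 1/(M s).
#' @param fold_per_nt Multiplicative rate gain per toehold nucleotide.
#' @param toehold_sat Saturation length in nt beyond which additional
#'   toehold bases no longer accelerate displacement.
#' @param leak Leak rate constant for a zero-length toehold, 1/(M s).
#' @return Rate constant in 1/(M s); non-decreasing in `toehold_nt`.
#' @export
#' @examples
#' toehold_rate(0)
#' toehold_rate(5) / toehold_rate(4)
toehold_rate <- function(toehold_nt, k_bm = 1.0, fold_per_nt = 10,
                         toehold_sat = 6L, leak = 1e-9) {
  ifelse(
    toehold_nt <= 0L,
    leak,
    k_bm * fold_per_nt^pmin(toehold_nt, toehold_sat)
  )
}

#' Stochastic kinetic simulation of gate disassembly
#'
#' Gillespie-style simulation over the coarse reactions (toehold binding +
#' branch migration, treated as one effective displacement event per
#' invasion site, followed by dissociation of destabilized incumbents).
#' Seeded and reproducible; the endpoint attachment state is evaluated
#' with the same connectivity semantics as [simulate_gate()].
#'
#' @param gate A `dt_compiled_gate`.
#' @param combo Character vector of present input names.
#' @param params A [sim_params()] with `kinetic_mode = TRUE` and a
#'   positive `input_concentration` (mol/L).
#' @param horizon Simulated time horizon in seconds (default 3600, one
#'   incubation hour).
#' @param rate_args List of arguments passed to [toehold_rate()].
#' @return A `dt_kinetic_result` list: `times` (tibble time course of
#'   displacement events), `signal`, `detached`, `exposed_fraction`.
#' @export
kinetic_simulate <- function(gate, combo, params = sim_params(kinetic_mode = TRUE),
                             horizon = 3600, rate_args = list()) {
  stopifnot(inherits(gate, "dt_compiled_gate"))
  if (!isTRUE(params$kinetic_mode)) {
    rlang::abort("kinetic_mode is off in params")
  }
  if (is.null(params$input_concentration) ||
    !is.numeric(params$input_concentration) ||
    params$input_concentration <= 0) {
    rlang::abort("missing concentrations: set input_concentration (mol/L)")
  }
  combo <- as.character(combo)
  state <- new_sim_state(gate)
  sites <- gate$invasion_map[gate$invasion_map$input %in% combo, ]
  t_now <- 0
  events <- list()
  with_rng_seed(params$rng_seed, {
    repeat {
      enabled <- which(vapply(
        seq_len(nrow(sites)),
        function(i) site_enabled(state, sites[i, ], params),
        logical(1)
      ))
      if (length(enabled) == 0L) break
      rates <- vapply(enabled, function(i) {
        h <- sites$toehold_end[i] - sites$toehold_start[i]
        do.call(toehold_rate, c(list(toehold_nt = h), rate_args)) *
          params$input_concentration
      }, numeric(1))
      total <- sum(rates)
      t_now <- t_now + stats::rexp(1L, total)
      if (t_now > horizon) break
      pick <- enabled[sample.int(length(enabled), 1L, prob = rates / total)]
      state <- attempt_invasion(state, sites[pick, ], gate, params)
      events[[length(events) + 1L]] <- tibble::tibble(
        time = t_now,
        invader = sites$input[pick],
        junction_id = sites$junction_id[pick]
      )
    }
  })
  att <- attachment_summary(state, gate)
  structure(
    list(
      input_combo = combo,
      times = if (length(events)) {
        dplyr::bind_rows(events)
      } else {
        tibble::tibble(
          time = numeric(0), invader = character(0),
          junction_id = integer(0)
        )
      },
      detached = att$shield_detached,
      exposed_fraction = att$exposed_fraction,
      signal = params$signal_min +
        (params$signal_max - params$signal_min) * att$exposed_fraction
    ),
    class = "dt_kinetic_result"
  )
}
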