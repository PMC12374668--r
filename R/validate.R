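#' Re-verify a compiled gate against its design constraints
#'
#' Aggregates the sequence-level checks over a compiled object: pairing-map
#' consistency (Watson-Crick complementarity of every assembled duplex, no
#' base paired twice), toehold accessibility for every declared invasion
#' site, hairpin floors for every interface strand, cross-talk of each
#' input against all strands it is not meant to invade, stability of
#' static staple/shield-ligand duplexes, and the residual-stability
#' separation of cooperative (AND) junctions. The report carries failures
#' rather than raising them.
#'
#' @param gate A `dt_compiled_gate`.
#' @param params A [thermo_params()] object for the energy checks.
#' @param cross_run_max Cross-talk cap in nt (longest tolerated
#'   complementary run between an input and a non-cognate strand; the
#'   default 4 stays below the 5-nt default toehold, so tolerated runs
#'   cannot nucleate displacement).
#' @param hairpin_floor_derived Hairpin floor for strands whose sequence
#'   is dictated by the inputs (receptors, staples, marker strands),
#'   kcal/mol.
#' @param hairpin_floor_generated Hairpin floor for freely generated
#'   strands (shield ligands), kcal/mol.
#' @return A tibble with columns `check`, `target`, `measured`, `bound`,
#'   `pass`.
#' @export
validate_design <- function(gate, params = thermo_params(),
                            cross_run_max = 4L,
                            hairpin_floor_derived = -2.0,
                            hairpin_floor_generated = 0) {
  stopifnot(inherits(gate, "dt_compiled_gate"))
  rows <- list()
  add <- function(check, target, measured, bound, pass) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      check = check, target = target, measured = as.numeric(measured),
      bound = as.numeric(bound), pass = pass
    )
  }
  seqs <- stats::setNames(gate$strands$sequence, gate$strands$name)
  p <- gate$assembled_pairs

  # complementarity of every assembled duplex region
  n_bad <- 0L
  for (i in seq_len(nrow(p))) {
    reg <- duplex_region(
      seqs[[p$strand_a[i]]], seqs[[p$strand_b[i]]],
      span_a = c(p$start_a[i], p$end_a[i]),
      span_b = c(p$start_b[i], p$end_b[i])
    )
    if (!region_is_complementary(reg)) n_bad <- n_bad + 1L
  }
  add("pairing_complementarity", "assembled_pairs", n_bad, 0, n_bad == 0L)

  # no base paired to two partners
  n_overlap <- 0L
  for (s in names(seqs)) {
    spans <- rbind(
      as.matrix(p[p$strand_a == s, c("start_a", "end_a")]),
      matrix(
        c(p$start_b[p$strand_b == s], p$end_b[p$strand_b == s]),
        ncol = 2
      )
    )
    if (nrow(spans) > 1L) {
      ord <- order(spans[, 1])
      spans <- spans[ord, , drop = FALSE]
      n_overlap <- n_overlap +
        sum(spans[-1, 1] < spans[-nrow(spans), 2])
    }
  }
  add("pairing_involution", "all_strands", n_overlap, 0, n_overlap == 0L)

  # toehold accessibility in the assembled state
  st0 <- new_sim_state(gate)
  for (i in seq_len(nrow(gate$invasion_map))) {
    im <- gate$invasion_map[i, ]
    free <- span_unpaired(st0, im$anchor_strand, im$toehold_start, im$toehold_end)
    add(
      "toehold_accessible", im$input,
      (im$toehold_end - im$toehold_start) * as.integer(free), 1,
      free && (im$toehold_end - im$toehold_start) >= 1L
    )
  }

  # hairpin floors; freely generated species (shield ligands behind a
  # static staple arm, separate output receptors) are held to the strict
  # floor, strands dictated by the input sequences to the loose one
  generated_strands <- c(
    gate$junctions$downstream[!gate$junctions$severable],
    gate$strands$name[gate$strands$role == "output_receptor"]
  )
  for (i in seq_len(nrow(gate$strands))) {
    s <- gate$strands[i, ]
    floor_i <- if (s$name %in% generated_strands &&
      s$role != "output_receptor") {
      hairpin_floor_generated
    } else {
      hairpin_floor_derived
    }
    mfe <- hairpin_mfe(s$sequence, params)
    add(
      "hairpin_floor", s$name, min(mfe, 99), floor_i,
      mfe >= floor_i - 1e-9
    )
  }

  # cross-talk: each input vs every strand it is not meant to invade
  for (x in names(gate$inputs)) {
    anchors <- unique(
      gate$invasion_map$anchor_strand[gate$invasion_map$input == x]
    )
    for (s in setdiff(names(seqs), anchors)) {
      run <- longest_cross_complement_run(gate$inputs[[x]], seqs[[s]])
      add(
        "cross_talk", paste0(x, " vs ", s), run, cross_run_max,
        run <= cross_run_max
      )
    }
  }

  # static (non-severable) duplexes must hold the bridge
  static_j <- gate$junctions$junction_id[!gate$junctions$severable]
  for (j in static_j) {
    dg <- junction_residual_dg(st0, gate, j, params)
    add(
      "static_duplex_stable", paste0("junction_", j), dg, gate$dg_hold,
      dg <= gate$dg_hold + 1e-9
    )
  }

  # cooperative-junction separation: each single remaining segment stable
  # with margin; full displacement leaves nothing
  multi <- gate$junctions[gate$junctions$severable &
    gate$junctions$n_inputs > 1L, ]
  for (j in multi$junction_id) {
    segs <- p[!is.na(p$junction_id) & p$junction_id == j, ]
    dgs <- vapply(seq_len(nrow(segs)), function(i) {
      nn_duplex_energy(
        substr(
          seqs[[segs$strand_a[i]]], segs$start_a[i] + 1L, segs$end_a[i]
        ),
        params
      )
    }, numeric(1))
    add(
      "and_residual_separation", paste0("junction_", j),
      max(dgs), gate$dg_hold - gate$and_margin,
      all(dgs <= gate$dg_hold - gate$and_margin + 1e-9)
    )
  }

  dplyr::bind_rows(rows)
}
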