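# Gate compilation: translate a Boolean specification into the strand set,
# assembled pairing map and invasion sites of a particle-disassembly
# architecture.
#
# Layout conventions (all spans 0-based half-open, strands stored 5'->3'):
#  * Every bridge between the core particle and a shield particle (or a
#    marker strand) is a chain of strands
#        core receptor -- staple_1 -- ... -- staple_{m-1} -- terminal
#    with one severable junction per OR term of the bridge's condition.
#    A junction's upstream (core-proximal) strand carries, for each input
#    of the term, a block  [migration][toehold]  equal to the input's
#    reverse complement; the downstream strand pairs the migration
#    segments only, so every toehold is unpaired and accessible in the
#    assembled state. Invasion pairs the input with the upstream strand
#    and displaces the downstream strand segment by segment; a junction is
#    severed when its residual duplex no longer satisfies the hold
#    threshold.
#  * Single-junction shield bridges additionally end in a static
#    staple/shield-ligand duplex (the stapled YES layout); the "direct"
#    architecture drops the staple and pairs receptor and shield ligand
#    directly.

#' Boolean gate specification
#'
#' @param expression Boolean expression over named inputs (string or parsed
#'   node), using YES/NOT/AND/OR with fan-in at most 4 per staple bridge.
#' @param inputs Named character vector or list mapping every input name
#'   used in the expression to its 5'->3' sequence.
#' @param architecture Interface layout: `"N_staple"` (default; best
#'   shielding in practice), `"U_staple"`, or `"direct"` (staple-free,
#'   single-input bridges only).
#' @param output_mode How output marker accessibility is realized:
#'   `"colocalized"` (marker on the input receptor), `"separate"`
#'   (marker on a dedicated 30-nt output receptor) or `"amplified"`
#'   (separate receptor plus an auxiliary-particle ligand).
#' @return A `dt_gate_spec` list.
#' @export
#' @examples
#' gate_spec("AND(InA, InB)",
#'   inputs = c(InA = "ACGTACGTACGTACGTA", InB = "TGCATGCATGCATGCATGCATGCATGCA")
#' )
gate_spec <- function(expression,
                      inputs,
                      architecture = c("N_staple", "U_staple", "direct"),
                      output_mode = c("colocalized", "separate", "amplified")) {
  architecture <- match.arg(architecture)
  output_mode <- match.arg(output_mode)
  node <- parse_expression(expression)
  inputs <- vapply(as.list(inputs), as_dna, character(1))
  used <- expr_inputs(node)
  missing <- setdiff(used, names(inputs))
  if (length(missing) > 0L) {
    rlang::abort(sprintf(
      "no sequence provided for input(s): %s", paste(missing, collapse = ", ")
    ))
  }
  # inputs beyond those referenced are kept as declared bystanders: they
  # appear in truth tables (non-specific controls) and in cross-talk
  # screens, but drive no invasion site
  structure(
    list(
      expression = expr_to_string(node),
      node = node,
      inputs = inputs,
      architecture = architecture,
      output_mode = output_mode
    ),
    class = "dt_gate_spec"
  )
}

#' @export
print.dt_gate_spec <- function(x, ...) {
  cat(sprintf(
    "<gate_spec> %s  [%s, %s]\n  inputs: %s\n",
    x$expression, x$architecture, x$output_mode,
    paste(sprintf("%s (%d nt)", names(x$inputs), nchar(x$inputs)),
      collapse = ", "
    )
  ))
  invisible(x)
}

# Build the upstream-strand region and pairing layout for one junction.
# Returns the junction's upstream subsequence plus block geometry relative
# to the start of that subsequence.
#' @noRd
junction_layout <- function(term_inputs, input_seqs, toehold_len) {
  blocks <- lapply(term_inputs, function(x) {
    rc <- reverse_complement(input_seqs[[x]])
    len <- nchar(rc)
    if (len <= toehold_len) {
      rlang::abort(sprintf(
        "input %s (%d nt) is not longer than the %d-nt toehold",
        x, len, toehold_len
      ))
    }
    list(
      input = x,
      mig = substr(rc, 1L, len - toehold_len),
      toe = substr(rc, len - toehold_len + 1L, len)
    )
  })
  seqs <- vapply(blocks, function(b) paste0(b$mig, b$toe), character(1))
  offsets <- cumsum(c(0L, nchar(seqs)))[seq_along(seqs)]
  geom <- tibble::tibble(
    input = vapply(blocks, `[[`, character(1), "input"),
    mig_start = offsets,
    mig_end = offsets + nchar(vapply(blocks, `[[`, character(1), "mig")),
    toe_start = offsets + nchar(vapply(blocks, `[[`, character(1), "mig")),
    toe_end = offsets + nchar(seqs)
  )
  list(
    useq = paste(seqs, collapse = ""),
    geom = geom,
    migs = vapply(blocks, `[[`, character(1), "mig")
  )
}

# Flexible spacer inserted between independent duplex-forming segments of
# a derived strand; breaks contiguous complementary runs that would
# otherwise span segment boundaries and decouples adjacent helices.
ARM_SPACER <- "TTT"

# Downstream arm pairing the migration segments of a junction layout:
# antiparallel, so the last upstream segment pairs first on the arm.
# Multi-segment arms are joined with a 3-nt spacer; returns the arm parts
# and the 0-based arm start of each upstream segment's pairing region (in
# upstream segment order).
#' @noRd
downstream_arm <- function(layout) {
  segs_rev <- rev(vapply(layout$migs, reverse_complement, character(1)))
  lens_rev <- nchar(segs_rev)
  starts_rev <- cumsum(c(0L, utils::head(
    lens_rev + nchar(ARM_SPACER),
    -1L
  )))
  list(
    parts = segs_rev,
    starts = rev(starts_rev)
  )
}

# Candidate spacer triplets tried when joining derived-strand segments;
# all have fixed length 3 so pairing offsets are spacer-independent.
SPACER_CANDIDATES <- c("TTT", "TCT", "CTT", "TTC", "CCT", "TCC", "CTC", "CCC")

# Join derived-strand segments with the spacer that keeps the longest
# cross-complementary run against every screen sequence at or below
# `cap` (falling back to the minimax choice). Deterministic.
#' @noRd
join_with_spacer <- function(parts, screens = character(0), cap = 4L) {
  parts <- parts[nzchar(parts)]
  if (length(parts) <= 1L) {
    return(list(seq = paste(parts, collapse = ""), spacer = ARM_SPACER))
  }
  best <- NULL
  for (sp in SPACER_CANDIDATES) {
    cand <- paste(parts, collapse = sp)
    run <- if (length(screens)) {
      max(vapply(
        screens,
        function(s) longest_cross_complement_run(s, cand), integer(1)
      ))
    } else {
      0L
    }
    if (is.null(best) || run < best$run) {
      best <- list(seq = cand, spacer = sp, run = run)
    }
    if (run <= cap) break
  }
  best
}

#' Compile a Boolean gate into a DNA-interface architecture
#'
#' Translates a [gate_spec()] into the complete strand set, the
#' domain-level pairing map of the assembled (shielded) state and the
#' invasion site of every input. Shield bridges realize the positive part
#' of the expression (any staple-chain junction severed disconnects core
#' and shield); NOT terms become marker-bearing strands that are displaced
#' from the core when their release condition fires. Compilation is
#' deterministic given `(spec, design_constraints)`.
#'
#' @param spec A [gate_spec()].
#' @param constraints [design_constraints()] governing the generated
#'   (non-input-derived) species: shield ligands and separate output
#'   receptors. Its `rng_seed` seeds all sequence generation.
#' @param toehold_len Toehold length in nt left accessible per input
#'   (default 5; the strand-displacement-limited regime).
#' @param shield_ligand_len,overlap_shield Length of generated shield
#'   ligands and their paired span with the terminal staple.
#' @param dg_hold Residual-duplex hold threshold, kcal/mol, used to verify
#'   cooperative (AND) partitions at compile time.
#' @param and_margin Required stability margin, kcal/mol: every proper
#'   subset of a cooperative junction's inputs must leave a residual at
#'   least this far below `dg_hold`.
#' @return A `dt_compiled_gate` object.
#' @export
compile_gate <- function(spec,
                         constraints = design_constraints(
                           length = shield_ligand_len
                         ),
                         toehold_len = 5L,
                         shield_ligand_len = 20L,
                         overlap_shield = 12L,
                         dg_hold = -8.0,
                         and_margin = 2.0) {
  stopifnot(inherits(spec, "dt_gate_spec"))
  plan <- normalize_expression(spec$node)
  params <- constraints$params
  input_seqs <- as.list(spec$inputs)

  if (spec$architecture == "direct") {
    ok <- all(vapply(
      plan$shields,
      function(s) length(s$terms) == 1L && length(s$terms[[1]]) == 1L,
      logical(1)
    ))
    if (!ok) {
      rlang::abort(
        "architecture requires staple: 'direct' interfaces support only single-input (YES) bridges",
        class = "dt_architecture_error"
      )
    }
  }

  strands <- list()
  pairs <- list()
  junctions <- list()
  invasions <- list()
  assemblies <- list()
  markers <- list()
  pair_id <- 0L
  junc_id <- 0L

  add_strand <- function(name, sequence, role, anchor, modifications = "") {
    strands[[length(strands) + 1L]] <<- tibble::tibble(
      name = name, sequence = sequence, role = role, anchor = anchor,
      modifications = modifications
    )
  }
  add_pair <- function(sa, a0, a1, sb, b0, b1, junction = NA_integer_) {
    pair_id <<- pair_id + 1L
    pairs[[pair_id]] <<- tibble::tibble(
      pair_id = pair_id, strand_a = sa,
      start_a = as.integer(a0), end_a = as.integer(a1),
      strand_b = sb, start_b = as.integer(b0), end_b = as.integer(b1),
      junction_id = junction
    )
  }

  # forbidden partners for generated species: all inputs and their reverse
  # complements (the latter are displayed as receptors on the particle)
  gen_partners <- c(
    stats::setNames(input_seqs, names(input_seqs)),
    stats::setNames(
      lapply(input_seqs, reverse_complement),
      paste0(names(input_seqs), "_rc")
    )
  )

  build_bridge <- function(cond, assembly_id, kind, seed_offset) {
    terms <- cond$terms
    m <- length(terms)
    layouts <- lapply(terms, junction_layout, input_seqs, toehold_len)
    r_name <- paste0("i-r", assembly_id)
    terminal_role <- if (kind == "shield") "shield_ligand" else "output_ligand"
    terminal_name <- if (kind == "shield") {
      paste0("i-rl", assembly_id)
    } else {
      paste0("o-l", assembly_id)
    }
    terminal_anchor <- if (kind == "shield") {
      paste0("shield_particle_", assembly_id)
    } else {
      "none"
    }

    # chain node names: receptor, staples, terminal
    n_staples <- if (kind == "shield" && m == 1L &&
      spec$architecture != "direct") {
      1L
    } else {
      m - 1L
    }
    staple_names <- if (n_staples > 0L) {
      paste0("N", assembly_id, c("", letters)[seq_len(n_staples)])
    } else {
      character(0)
    }
    nodes <- c(r_name, staple_names, terminal_name)

    # sequences are assembled left-to-right along the chain; node j's
    # sequence = [downstream arm of junction j] + [upstream region of
    # junction j+1 or static shield arm]
    node_seq <- stats::setNames(vector("list", length(nodes)), nodes)
    node_seq[[r_name]] <- layouts[[1]]$useq

    ligand_design <- NULL
    static_arm <- NULL
    staple_override <- NULL
    if (kind == "shield" && m == 1L && spec$architecture != "direct") {
      # single-junction stapled bridge: generate the shield ligand and
      # screen the *assembled* staple (arm segments + spacer + static
      # shield arm) for hairpins and cross-talk against every input
      cn <- constraints
      cn$length <- as.integer(shield_ligand_len)
      cn$rng_seed <- as.integer((constraints$rng_seed + seed_offset) %%
        .Machine$integer.max)
      cn$forbidden_partners <- c(constraints$forbidden_partners, gen_partners)
      # generated species are screened at the sub-toehold cap (4 nt, as in
      # validate_design): the stricter input-design cap over many partners
      # would make sampling infeasible without adding real specificity
      cn$cross_run_max <- max(cn$cross_run_max, 4L)
      cn$max_self_run <- max(cn$max_self_run, 4L)
      arm1 <- downstream_arm(layouts[[1]])
      screens <- unlist(input_seqs)
      with_rng_seed(cn$rng_seed, {
        for (attempt in seq_len(cn$max_attempts)) {
          lig <- sample_oligo_stream(cn)
          sa <- reverse_complement(substr(
            lig$sequence, shield_ligand_len - overlap_shield + 1L,
            shield_ligand_len
          ))
          jn <- join_with_spacer(c(arm1$parts, sa), screens)
          ok_run <- !length(screens) || max(vapply(
            screens,
            function(s) longest_cross_complement_run(s, jn$seq),
            integer(1)
          )) <= 4L
          if (ok_run &&
            hairpin_mfe(jn$seq, cn$params) >= -2.0 - 1e-9) {
            ligand_design <- lig
            static_arm <- sa
            staple_override <- jn$seq
            break
          }
        }
      })
      if (is.null(staple_override)) {
        rlang::abort(
          "infeasible constraints: no admissible shield ligand/staple combination found",
          class = "dt_infeasible_constraints"
        )
      }
    }

    # walk the junctions
    for (j in seq_len(m)) {
      junc_id <<- junc_id + 1L
      up <- nodes[j]
      down <- nodes[j + 1L]
      lay <- layouts[[j]]
      up_offset <- nchar(node_seq[[up]] %||% "") - nchar(lay$useq)
      # downstream arm prepends the next node's sequence: the upstream
      # region of the next junction, or (single-staple shield bridges)
      # the static shield arm
      arm <- downstream_arm(lay)
      tail_part <- if (j < m) {
        layouts[[j + 1L]]$useq
      } else if (!is.null(static_arm) && down != terminal_name) {
        static_arm
      } else {
        ""
      }
      node_seq[[down]] <- if (!is.null(staple_override) &&
        down != terminal_name) {
        staple_override
      } else {
        join_with_spacer(
          c(arm$parts, tail_part),
          screens = unlist(input_seqs)
        )$seq
      }
      junctions[[junc_id]] <<- tibble::tibble(
        junction_id = junc_id, assembly_id = assembly_id,
        upstream = up, downstream = down, severable = TRUE,
        n_inputs = nrow(lay$geom)
      )
      # pairing: migration segment i of the upstream region pairs the
      # downstream arm antiparallel (last segment first)
      seg_lens <- nchar(lay$migs)
      arm_starts <- arm$starts
      for (i in seq_len(nrow(lay$geom))) {
        g <- lay$geom[i, ]
        add_pair(
          up, up_offset + g$mig_start, up_offset + g$mig_end,
          down, arm_starts[i], arm_starts[i] + seg_lens[i],
          junction = junc_id
        )
        invasions[[length(invasions) + 1L]] <<- tibble::tibble(
          input = g$input,
          anchor_strand = up,
          toehold_start = as.integer(up_offset + g$toe_start),
          toehold_end = as.integer(up_offset + g$toe_end),
          migration_start = as.integer(up_offset + g$mig_start),
          migration_end = as.integer(up_offset + g$mig_end),
          incumbent = down,
          junction_id = junc_id,
          assembly_id = assembly_id
        )
      }
    }

    # strands of this chain
    marker_here <- kind == "marker"
    add_strand(r_name, node_seq[[r_name]], "core_receptor", "core_particle",
      modifications = paste0(
        "5'-NH2",
        if (plan$constitutive_marker && spec$output_mode == "colocalized" &&
          assembly_id == 1L && kind == "shield") {
          ";3'-biotin"
        } else {
          ""
        }
      )
    )
    for (s in staple_names) add_strand(s, node_seq[[s]], "staple", "none")
    if (kind == "shield") {
      if (spec$architecture == "direct" || m > 1L) {
        add_strand(terminal_name, node_seq[[terminal_name]], "shield_ligand",
          terminal_anchor,
          modifications = "5'-SH"
        )
      } else {
        # generated ligand: arm pairing recorded against the designed oligo
        add_strand(terminal_name, ligand_design$sequence, "shield_ligand",
          terminal_anchor,
          modifications = "5'-SH"
        )
        lig_len <- nchar(ligand_design$sequence)
        st_name <- staple_names[1]
        st_len <- nchar(node_seq[[st_name]])
        junc_id <<- junc_id + 1L
        junctions[[junc_id]] <<- tibble::tibble(
          junction_id = junc_id, assembly_id = assembly_id,
          upstream = st_name, downstream = terminal_name, severable = FALSE,
          n_inputs = 0L
        )
        add_pair(
          st_name, st_len - overlap_shield, st_len,
          terminal_name, lig_len - overlap_shield, lig_len,
          junction = junc_id
        )
      }
    } else {
      add_strand(terminal_name, node_seq[[terminal_name]], "output_ligand",
        "none",
        modifications = "3'-biotin"
      )
      markers[[length(markers) + 1L]] <<- tibble::tibble(
        strand = terminal_name, constitutive = FALSE,
        assembly_id = assembly_id
      )
    }
    assemblies[[length(assemblies) + 1L]] <<- tibble::tibble(
      assembly_id = assembly_id, kind = kind,
      condition = paste(
        vapply(terms, paste, character(1), collapse = "*"),
        collapse = "+"
      )
    )
  }

  aid <- 0L
  for (s in plan$shields) {
    aid <- aid + 1L
    build_bridge(s, aid, "shield", seed_offset = 97L * aid)
  }
  for (mk in plan$markers) {
    aid <- aid + 1L
    build_bridge(mk, aid, "marker", seed_offset = 97L * aid)
  }

  # constitutive output marker
  if (plan$constitutive_marker) {
    if (spec$output_mode == "colocalized") {
      first_receptor <- paste0("i-r", 1L)
      markers[[length(markers) + 1L]] <- tibble::tibble(
        strand = first_receptor, constitutive = TRUE, assembly_id = 1L
      )
    } else {
      cn <- constraints
      cn$length <- 30L
      cn$hairpin_dg_floor <- -2.0
      cn$rng_seed <- as.integer((constraints$rng_seed + 7919L) %%
        .Machine$integer.max)
      cn$forbidden_partners <- c(constraints$forbidden_partners, gen_partners)
      cn$cross_run_max <- max(cn$cross_run_max, 4L)
      cn$max_self_run <- max(cn$max_self_run, 4L)
      orec <- generate_oligo(cn)
      add_strand("o-rec1", orec$sequence, "output_receptor", "core_particle",
        modifications = if (spec$output_mode == "amplified") {
          "5'-NH2"
        } else {
          "5'-NH2;3'-biotin"
        }
      )
      markers[[length(markers) + 1L]] <- tibble::tibble(
        strand = "o-rec1", constitutive = TRUE, assembly_id = NA_integer_
      )
      if (spec$output_mode == "amplified") {
        arm <- reverse_complement(substr(orec$sequence, 16L, 30L))
        add_strand("o-rec1_ligand", arm, "output_ligand",
          "auxiliary_particle",
          modifications = "5'-biotin;3'-SH"
        )
      }
    }
  }

  gate <- structure(
    list(
      expression = spec$expression,
      inputs = spec$inputs,
      architecture = spec$architecture,
      output_mode = spec$output_mode,
      strands = dplyr::bind_rows(strands),
      assembled_pairs = dplyr::bind_rows(pairs),
      junctions = dplyr::bind_rows(junctions),
      invasion_map = dplyr::bind_rows(invasions),
      assemblies = dplyr::bind_rows(assemblies),
      markers = dplyr::bind_rows(markers),
      toehold_len = as.integer(toehold_len),
      dg_hold = dg_hold,
      and_margin = and_margin,
      seed = constraints$rng_seed
    ),
    class = "dt_compiled_gate"
  )
  check_and_partitions(gate, params)
  gate
}

# Verify cooperative-junction partitions: every proper input subset of a
# multi-input junction must leave a residual duplex clearing the hold
# threshold by the configured margin (worst case: the single weakest
# remaining segment).
#' @noRd
check_and_partitions <- function(gate, params) {
  multi <- gate$junctions[gate$junctions$severable & gate$junctions$n_inputs > 1L, ]
  for (j in multi$junction_id) {
    segs <- gate$assembled_pairs[
      !is.na(gate$assembled_pairs$junction_id) &
        gate$assembled_pairs$junction_id == j,
    ]
    seq_up <- gate$strands$sequence[match(segs$strand_a, gate$strands$name)]
    dgs <- vapply(seq_len(nrow(segs)), function(i) {
      nn_duplex_energy(
        substr(seq_up[i], segs$start_a[i] + 1L, segs$end_a[i]), params
      )
    }, numeric(1))
    bad <- dgs > gate$dg_hold - gate$and_margin + 1e-9
    if (any(bad)) {
      lens <- segs$end_a - segs$start_a
      rlang::abort(sprintf(
        "infeasible AND partition at junction %d: segment lengths (%s) leave residuals (%s kcal/mol) above the %.1f kcal/mol hold threshold minus the %.1f margin",
        j, paste(lens[bad], collapse = ", "),
        paste(sprintf("%.2f", dgs[bad]), collapse = ", "),
        gate$dg_hold, gate$and_margin
      ), class = "dt_infeasible_partition")
    }
  }
  invisible(gate)
}

#' @export
print.dt_compiled_gate <- function(x, ...) {
  cat(sprintf(
    "<compiled_gate> %s  [%s, %s]\n  %d strands, %d junctions, %d invasion sites, %d marker strand(s)\n",
    x$expression, x$architecture, x$output_mode,
    nrow(x$strands), nrow(x$junctions), nrow(x$invasion_map),
    nrow(x$markers)
  ))
  invisible(x)
}
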