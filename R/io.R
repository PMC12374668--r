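# File formats: FASTA for strands (description-line metadata as
# semicolon-separated key=value tokens), JSON for gate specs and compiled
# gates, TSV/JSON for truth tables and reports, JSON-lines for event
# traces.

#' @noRd
role_default_anchor <- function(role) {
  switch(role,
    core_receptor = "core_particle",
    output_receptor = "core_particle",
    shield_ligand = "shield_particle_1",
    output_ligand = "none",
    staple = "none",
    input = "none",
    "none"
  )
}

#' Read strands from a FASTA file
#'
#' Description lines are parsed as `>name key=value;key=value;...`;
#' recognized keys are `role`, `anchor` and `modification`; unknown tokens
#' are preserved verbatim in the `extra` column. Lowercase bases are
#' uppercased on read (with a message); any non-ACGT base is an error
#' naming the offending record.
#'
#' @param path FASTA file path.
#' @return A tibble with columns `name`, `sequence`, `role`, `anchor`,
#'   `modifications`, `extra`; zero rows (with a warning) for an empty
#'   file.
#' @export
read_strands <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("file not found: %s", path))
  }
  if (file.size(path) == 0L ||
    all(!nzchar(trimws(readLines(path, warn = FALSE))))) {
    rlang::warn(sprintf("empty FASTA file: %s", path))
    return(tibble::tibble(
      name = character(0), sequence = character(0), role = character(0),
      anchor = character(0), modifications = character(0),
      extra = character(0)
    ))
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      rlang::abort(sprintf("malformed FASTA in %s: %s", path, conditionMessage(e)))
    }
  )
  out <- vector("list", length(set))
  for (i in seq_along(set)) {
    header <- names(set)[i]
    toks <- strsplit(header, "\\s+")[[1]]
    name <- toks[1]
    seq_raw <- as.character(set[[i]])
    if (grepl("[acgt]", seq_raw)) {
      rlang::inform(sprintf("record '%s': lowercase bases uppercased", name))
    }
    seq_up <- toupper(seq_raw)
    if (grepl("[^ACGT]", seq_up)) {
      rlang::abort(sprintf(
        "record '%s' (entry %d) contains non-ACGT bases", name, i
      ))
    }
    kv <- character(0)
    if (length(toks) > 1L) {
      kv <- unlist(strsplit(paste(toks[-1], collapse = " "), ";"))
    }
    has_eq <- grepl("=", kv, fixed = TRUE)
    keys <- sub("=.*$", "", kv[has_eq])
    vals <- sub("^[^=]*=", "", kv[has_eq])
    get1 <- function(k, default) {
      if (k %in% keys) vals[match(k, keys)] else default
    }
    role <- get1("role", "input")
    known <- keys %in% c("role", "anchor", "modification")
    extra <- paste(c(kv[!has_eq], kv[has_eq][!known]), collapse = ";")
    out[[i]] <- tibble::tibble(
      name = name,
      sequence = seq_up,
      role = role,
      anchor = get1("anchor", role_default_anchor(role)),
      modifications = get1("modification", ""),
      extra = extra
    )
  }
  dplyr::bind_rows(out)
}

#' Write strands to FASTA
#'
#' Inverse of [read_strands()]: metadata is serialized into the
#' description line as semicolon-separated key=value tokens. Sequences are
#' written on a single line each, so output is byte-stable.
#'
#' @param strands Tibble with at least `name` and `sequence`; optional
#'   `role`, `anchor`, `modifications`, `extra`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_strands <- function(strands, path) {
  n <- nrow(strands)
  lines <- character(0)
  for (i in seq_len(n)) {
    toks <- c(
      if ("role" %in% names(strands)) paste0("role=", strands$role[i]),
      if ("anchor" %in% names(strands)) paste0("anchor=", strands$anchor[i]),
      if ("modifications" %in% names(strands) &&
        nzchar(strands$modifications[i])) {
        paste0("modification=", strands$modifications[i])
      },
      if ("extra" %in% names(strands) && nzchar(strands$extra[i])) {
        strands$extra[i]
      }
    )
    header <- paste0(
      ">", strands$name[i],
      if (length(toks)) paste0(" ", paste(toks, collapse = ";")) else ""
    )
    lines <- c(lines, header, strands$sequence[i])
  }
  writeLines(lines, path)
  invisible(path)
}

# ---- gate spec JSON --------------------------------------------------------

#' Write / read a gate specification as JSON
#'
#' @param spec A [gate_spec()].
#' @param path JSON file path.
#' @return `write_gate_spec()` returns `path` invisibly;
#'   `read_gate_spec()` returns a `dt_gate_spec`.
#' @export
write_gate_spec <- function(spec, path) {
  stopifnot(inherits(spec, "dt_gate_spec"))
  jsonlite::write_json(
    list(
      expression = spec$expression,
      inputs = as.list(spec$inputs),
      architecture = spec$architecture,
      output_mode = spec$output_mode
    ),
    path,
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(path)
}

#' @rdname write_gate_spec
#' @export
read_gate_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("expression", "inputs")) {
    if (is.null(x[[f]])) {
      rlang::abort(sprintf("gate spec %s: missing field '%s'", path, f))
    }
  }
  gate_spec(
    expression = x$expression,
    inputs = unlist(x$inputs),
    architecture = x$architecture %||% "N_staple",
    output_mode = x$output_mode %||% "colocalized"
  )
}

# ---- compiled gate JSON ----------------------------------------------------

#' @noRd
gate_int_cols <- list(
  assembled_pairs = c(
    "pair_id", "start_a", "end_a", "start_b", "end_b", "junction_id"
  ),
  junctions = c("junction_id", "assembly_id", "n_inputs"),
  invasion_map = c(
    "toehold_start", "toehold_end", "migration_start", "migration_end",
    "junction_id", "assembly_id"
  ),
  assemblies = "assembly_id",
  markers = "assembly_id"
)

#' Serialize / restore a compiled gate
#'
#' The JSON round trip is lossless: reading a written gate and writing it
#' again reproduces the file byte for byte.
#'
#' @param gate A `dt_compiled_gate`.
#' @param path JSON file path.
#' @return `write_compiled_gate()` returns `path` invisibly;
#'   `read_compiled_gate()` returns the `dt_compiled_gate`.
#' @export
write_compiled_gate <- function(gate, path) {
  stopifnot(inherits(gate, "dt_compiled_gate"))
  payload <- list(
    expression = gate$expression,
    inputs = as.list(gate$inputs),
    architecture = gate$architecture,
    output_mode = gate$output_mode,
    strands = as.data.frame(gate$strands),
    assembled_pairs = as.data.frame(gate$assembled_pairs),
    junctions = as.data.frame(gate$junctions),
    invasion_map = as.data.frame(gate$invasion_map),
    assemblies = as.data.frame(gate$assemblies),
    markers = as.data.frame(gate$markers),
    toehold_len = gate$toehold_len,
    dg_hold = gate$dg_hold,
    and_margin = gate$and_margin,
    seed = gate$seed
  )
  jsonlite::write_json(payload, path,
    auto_unbox = TRUE, pretty = TRUE,
    digits = NA, na = "null"
  )
  invisible(path)
}

#' @rdname write_compiled_gate
#' @export
read_compiled_gate <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_tbl <- function(name) {
    df <- x[[name]]
    tb <- tibble::as_tibble(df)
    for (col in intersect(gate_int_cols[[name]] %||% character(0), names(tb))) {
      tb[[col]] <- as.integer(tb[[col]])
    }
    tb
  }
  structure(
    list(
      expression = x$expression,
      inputs = unlist(x$inputs),
      architecture = x$architecture,
      output_mode = x$output_mode,
      strands = as_tbl("strands"),
      assembled_pairs = as_tbl("assembled_pairs"),
      junctions = as_tbl("junctions"),
      invasion_map = as_tbl("invasion_map"),
      assemblies = as_tbl("assemblies"),
      markers = as_tbl("markers"),
      toehold_len = as.integer(x$toehold_len),
      dg_hold = x$dg_hold,
      and_margin = x$and_margin,
      seed = as.integer(x$seed)
    ),
    class = "dt_compiled_gate"
  )
}

# ---- report output ---------------------------------------------------------

#' Write a gate report as TSV or JSON
#'
#' The TSV carries one row per input combination (`combo`, `signal`,
#' `output`, `expected`) plus the scalar metrics repeated on every row for
#' flat-file consumers; the JSON variant nests them.
#'
#' @param report A `dt_gate_report` from [truth_table()].
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_gate_report <- function(report, path, format = c("tsv", "json")) {
  stopifnot(inherits(report, "dt_gate_report"))
  format <- match.arg(format)
  tt <- report$truth_table
  if (format == "tsv") {
    out <- tt[, c("combo", "signal", "output", "expected")]
    out$threshold <- report$threshold
    out$shield_ratio <- report$shield_ratio
    out$leakage_cv <- report$leakage_cv
    out$correct <- report$correct
    utils::write.table(out, path,
      sep = "\t", quote = FALSE,
      row.names = FALSE
    )
  } else {
    jsonlite::write_json(
      list(
        expression = report$expression,
        threshold = report$threshold,
        shield_ratio = report$shield_ratio,
        leakage_cv = report$leakage_cv,
        correct = report$correct,
        truth_table = as.data.frame(tt[, c(
          "combo", "signal", "output", "expected"
        )])
      ),
      path,
      auto_unbox = TRUE, pretty = TRUE, digits = NA
    )
  }
  invisible(path)
}

#' Write displacement event traces as JSON lines
#'
#' One JSON record per displacement event.
#'
#' @param result A `dt_simulation_result` from [simulate_gate()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(result, path) {
  stopifnot(inherits(result, "dt_simulation_result"))
  con <- file(path, "w")
  on.exit(close(con))
  tr <- result$trace
  for (i in seq_len(nrow(tr))) {
    writeLines(
      jsonlite::toJSON(as.list(tr[i, ]), auto_unbox = TRUE, digits = NA),
      con
    )
  }
  invisible(path)
}
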