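# Nearest-neighbor parameter tables are shipped as TSV under inst/extdata and
# cached per session; `nn_table_id` / `loop_penalty_model` name the files so
# alternative parameterizations can be dropped in without code changes.

the <- new.env(parent = emptyenv())

#' @noRd
load_nn_table <- function(nn_table_id = "nn_unified_dna") {
  key <- paste0("nn_", nn_table_id)
  if (!is.null(the[[key]])) {
    return(the[[key]])
  }
  path <- system.file("extdata", paste0(nn_table_id, ".tsv"),
    package = "dnatransformr", mustWork = FALSE
  )
  if (!nzchar(path)) {
    rlang::abort(sprintf("unknown nearest-neighbor table '%s'", nn_table_id))
  }
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  dh <- stats::setNames(tab$dh, tab$step)
  ds <- stats::setNames(tab$ds, tab$step)
  the[[key]] <- list(dh = dh, ds = ds)
  the[[key]]
}

#' @noRd
load_loop_table <- function(loop_penalty_model = "hairpin_loops") {
  key <- paste0("loop_", loop_penalty_model)
  if (!is.null(the[[key]])) {
    return(the[[key]])
  }
  path <- system.file("extdata", paste0(loop_penalty_model, ".tsv"),
    package = "dnatransformr", mustWork = FALSE
  )
  if (!nzchar(path)) {
    rlang::abort(sprintf("unknown loop-penalty model '%s'", loop_penalty_model))
  }
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  the[[key]] <- stats::setNames(tab$dg37, tab$loop_size)
  the[[key]]
}

#' Thermodynamic model parameters
#'
#' Bundles the conditions under which duplex and hairpin free energies are
#' evaluated. Defaults reflect gate *operation* conditions (37 C in PBS,
#' 0.15 M monovalent salt); [assembly_params()] gives the high-salt
#' room-temperature conditions under which the shielded nanostructures are
#' assembled (25 C, 0.5 M NaCl).
#'
#' @param temperature Absolute temperature in kelvin (> 0).
#' @param monovalent_salt Monovalent cation concentration in mol/L, in
#'   `(0, 2]`.
#' @param nn_table_id Identifier of the shipped nearest-neighbor table.
#' @param loop_penalty_model Identifier of the shipped hairpin-loop penalty
#'   table.
#' @return A `dt_thermo_params` list.
#' @export
#' @examples
#' thermo_params()
#' assembly_params()
thermo_params <- function(temperature = 310.15,
                          monovalent_salt = 0.15,
                          nn_table_id = "nn_unified_dna",
                          loop_penalty_model = "hairpin_loops") {
  if (!is.numeric(temperature) || temperature <= 0) {
    rlang::abort("temperature must be a positive number of kelvin")
  }
  if (!is.numeric(monovalent_salt) ||
    monovalent_salt <= 0 || monovalent_salt > 2.0) {
    rlang::abort("monovalent_salt must lie in (0, 2] mol/L")
  }
  structure(
    list(
      temperature = temperature,
      monovalent_salt = monovalent_salt,
      nn_table_id = nn_table_id,
      loop_penalty_model = loop_penalty_model
    ),
    class = "dt_thermo_params"
  )
}

#' @rdname thermo_params
#' @export
assembly_params <- function() {
  thermo_params(temperature = 298.15, monovalent_salt = 0.5)
}

#' @export
print.dt_thermo_params <- function(x, ...) {
  cat(sprintf(
    "<thermo_params> %.2f K, %.2g M Na+, table '%s'\n",
    x$temperature, x$monovalent_salt, x$nn_table_id
  ))
  invisible(x)
}

# Gas constant, kcal/(mol K)
R_KCAL <- 0.0019872

# Reference temperature of the shipped dg37 loop table, K
T_REF <- 310.15

#' Hairpin-loop free energy penalty
#'
#' Size-dependent terminal-loop penalty, rescaled from the tabulated 37 C
#' values assuming a purely entropic loop term; sizes beyond the table are
#' extrapolated logarithmically.
#'
#' @param loop_size Loop length in nt (>= 3).
#' @param params A [thermo_params()] object.
#' @return Penalty in kcal/mol (positive).
#' @export
loop_penalty <- function(loop_size, params = thermo_params()) {
  if (any(loop_size < 3)) {
    rlang::abort("hairpin loops shorter than 3 nt are sterically forbidden")
  }
  tab <- load_loop_table(params$loop_penalty_model)
  sizes <- as.integer(names(tab))
  nmax <- max(sizes)
  dg37 <- ifelse(
    loop_size <= nmax,
    tab[as.character(pmin(loop_size, nmax))],
    tab[as.character(nmax)] +
      1.75 * R_KCAL * T_REF * log(loop_size / nmax)
  )
  unname(dg37) * params$temperature / T_REF
}
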