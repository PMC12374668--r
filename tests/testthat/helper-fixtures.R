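# Shared fixture cache: the seeded fixture suite and its compiled gates
# and reports are built once per test run.

.fx_cache <- new.env(parent = emptyenv())

FIXTURE_SEED <- 20240101L

get_fixtures <- function() {
  if (is.null(.fx_cache$fx)) {
    .fx_cache$fx <- generate_fixtures(seed = FIXTURE_SEED)
  }
  .fx_cache$fx
}

get_gate <- function(name) {
  key <- paste0("gate_", name)
  if (is.null(.fx_cache[[key]])) {
    .fx_cache[[key]] <- compile_fixture(get_fixtures(), name)
  }
  .fx_cache[[key]]
}

get_report <- function(name) {
  key <- paste0("report_", name)
  if (is.null(.fx_cache[[key]])) {
    .fx_cache[[key]] <- truth_table(get_gate(name))
  }
  .fx_cache[[key]]
}

# render a normalized-architecture random expression from the supported
# single-particle grammar: a conjunction of positive bridge conditions
# (literal / OR / cooperative AND, in DNF) and NOT terms, every input used
# at most once
random_supported_expression <- function(vars) {
  n <- length(vars)
  vars <- sample(vars)
  # split the variables into 1..n components
  n_comp <- sample.int(n, 1)
  comp_of <- sort(sample.int(n_comp, n, replace = TRUE))
  conds <- split(vars, comp_of)
  render_cond <- function(v) {
    if (length(v) == 1) {
      return(v)
    }
    # random DNF: partition into terms
    t_of <- sort(sample.int(length(v), length(v), replace = TRUE))
    terms <- split(v, t_of)
    parts <- vapply(terms, function(tv) {
      if (length(tv) == 1) tv else paste0("AND(", paste(tv, collapse = ", "), ")")
    }, character(1))
    if (length(parts) == 1) parts[[1]] else paste0("OR(", paste(parts, collapse = ", "), ")")
  }
  # marker components are NOT(condition); an all-marker draw becomes a
  # disjunction of NOT terms, otherwise markers join the conjunction
  if (stats::runif(1) < 0.2) {
    rendered <- vapply(conds, function(cond) {
      paste0("NOT(", render_cond(cond), ")")
    }, character(1))
    if (length(rendered) == 1) {
      return(rendered[[1]])
    }
    return(paste0("OR(", paste(rendered, collapse = ", "), ")"))
  }
  rendered <- vapply(conds, function(cond) {
    if (stats::runif(1) < 0.35) {
      paste0("NOT(", render_cond(cond), ")")
    } else {
      render_cond(cond)
    }
  }, character(1))
  if (length(rendered) == 1) {
    return(rendered[[1]])
  }
  paste0("AND(", paste(rendered, collapse = ", "), ")")
}
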