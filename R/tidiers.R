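#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a gate report into its truth table
#'
#' @param x A `dt_gate_report`.
#' @param ... Unused.
#' @return The truth-table tibble (`combo`, one logical column per input,
#'   `signal`, `output`, `expected`).
#' @method tidy dt_gate_report
#' @export
tidy.dt_gate_report <- function(x, ...) {
  x$truth_table
}

#' One-row summary of a gate report
#'
#' @param x A `dt_gate_report`.
#' @param ... Unused.
#' @return A one-row tibble with `expression`, `n_inputs`, `threshold`,
#'   `shield_ratio`, `leakage_cv`, `correct`.
#' @method glance dt_gate_report
#' @export
glance.dt_gate_report <- function(x, ...) {
  tibble::tibble(
    expression = x$expression,
    n_inputs = sum(!names(x$truth_table) %in%
      c("combo", "signal", "output", "expected")),
    threshold = x$threshold,
    shield_ratio = x$shield_ratio,
    leakage_cv = x$leakage_cv,
    correct = x$correct
  )
}

#' Tidy a compiled gate into its strand table
#'
#' @param x A `dt_compiled_gate`.
#' @param ... Unused.
#' @return The strand tibble (`name`, `sequence`, `role`, `anchor`,
#'   `modifications`).
#' @method tidy dt_compiled_gate
#' @export
tidy.dt_compiled_gate <- function(x, ...) {
  x$strands
}

#' Tidy a designed oligo into its constraint report
#'
#' @param x A `dt_designed_oligo`.
#' @param ... Unused.
#' @return The constraint-report tibble.
#' @method tidy dt_designed_oligo
#' @export
tidy.dt_designed_oligo <- function(x, ...) {
  x$constraint_report
}

#' Plot a gate truth table
#'
#' Bar chart of the analog signal per input combination, coloured by the
#' expected Boolean output, with the geometric-mean switching threshold as
#' a dashed line — the standard way these gate panels are drawn.
#'
#' @param object A `dt_gate_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dt_gate_report
#' @export
autoplot.dt_gate_report <- function(object, ...) {
  tt <- object$truth_table
  tt$combo <- factor(tt$combo, levels = tt$combo)
  ggplot2::ggplot(
    tt,
    ggplot2::aes(x = .data$combo, y = .data$signal, fill = .data$expected)
  ) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(
      yintercept = object$threshold, linetype = "dashed", colour = "red"
    ) +
    ggplot2::labs(
      title = object$expression,
      x = "input combination",
      y = "normalized output signal",
      fill = "expected"
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
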