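#' Equilibrium dose sweep over a glucose grid
#'
#' Closed-form equilibria across a grid of clamped glucose values,
#' decomposed into newly secreted and returned peripheral monomer. The
#' two fractions are glucose-independent (they follow from the
#' equilibrium ratio `d_i/k`) and sum to 1; at zero secretion they are
#' undefined and emitted as `NA`.
#'
#' @param params A [kinetic_params()] object.
#' @param glucose Nonempty vector of glucose values, mM.
#' @return A tibble with columns `glucose_mM`, `h_pM`, `d_pM`, `m_pM`,
#'   `Ip_pM`, `total_monomer_pM`, `new_fraction`, `peripheral_fraction`.
#' @export
#' @examples
#' dose_sweep(default_params(), glucose = c(4, 5, 7, 16.5))
dose_sweep <- function(params, glucose) {
  stopifnot(length(glucose) > 0)
  eq <- islet_equilibrium(params, glucose)
  eq |>
    dplyr::mutate(
      new_fraction = dplyr::if_else(.data$total_monomer_pM > 0,
                                    .data$m_pM / .data$total_monomer_pM,
                                    NA_real_),
      peripheral_fraction = dplyr::if_else(.data$total_monomer_pM > 0,
                                           .data$Ip_pM / .data$total_monomer_pM,
                                           NA_real_))
}

#' Step response to a glucose clamp from the empty islet
#'
#' Simulates the model from the all-zero state at glucose stepped from 0
#' to `glucose` at t = 0, and reports the time for returned peripheral
#' insulin to first come within 10% of its equilibrium value (the
#' trajectory is monotone, so "reaching its maximum" is operationalized
#' as entering this band). `NA` if `t_end` is shorter than the crossing.
#'
#' @param params A [kinetic_params()] object.
#' @param glucose Clamp level, mM; > 0.
#' @param t_end Simulation length, min.
#' @param dt_out Output grid spacing, min.
#' @param fraction Fraction of equilibrium defining "settled"; default 0.9.
#' @return A list of class `islet_step` with elements `trace` (an
#'   `islet_trace` tibble), `equilibrium` (one-row tibble),
#'   `time_to_settle` (min or `NA`), `glucose`, `fraction`.
#' @export
#' @examples
#' st <- step_response(default_params(), glucose = 10, t_end = 120)
#' st$time_to_settle
step_response <- function(params, glucose, t_end = 120, dt_out = 0.1,
                          fraction = 0.9) {
  stopifnot(is.numeric(glucose), length(glucose) == 1, glucose > 0)
  trace <- simulate_clamp(params, glucose, t_end, dt_out,
                          init = islet_state())
  eq <- islet_equilibrium(params, glucose)
  t_settle <- time_to_fraction(trace, "Ip_pM", fraction, eq$Ip_pM)
  structure(list(trace = trace, equilibrium = eq,
                 time_to_settle = t_settle,
                 glucose = glucose, fraction = fraction),
            class = "islet_step")
}

#' @export
print.islet_step <- function(x, ...) {
  cat(sprintf("Glucose step 0 -> %g mM from the empty islet\n", x$glucose))
  cat(sprintf("  equilibrium Ip* = %.4g pM, total monomer = %.4g pM\n",
              x$equilibrium$Ip_pM, x$equilibrium$total_monomer_pM))
  if (is.na(x$time_to_settle)) {
    cat(sprintf("  Ip did not come within %.0f%% of equilibrium by t = %g min\n",
                100 * (1 - x$fraction), max(x$trace$time_min)))
  } else {
    cat(sprintf("  Ip within %.0f%% of equilibrium at t = %.3g min\n",
                100 * (1 - x$fraction), x$time_to_settle))
  }
  invisible(x)
}

#' Validate predicted peripheral insulin against observations
#'
#' Predicted peripheral insulin is the equilibrium `Ip*` at each observed
#' glucose level; the report lists predictions, observations and relative
#' errors (relative to the observation).
#'
#' @param params A [kinetic_params()] object.
#' @param observed Data frame with columns `glucose_mM`, `insulin_pM`;
#'   defaults to the packaged observed dose response.
#' @return A tibble of class `validation_report` with columns
#'   `glucose_mM`, `predicted_pM`, `observed_pM`, `rel_error`. Supports
#'   [generics::glance()] (maximum absolute relative error) and
#'   [ggplot2::autoplot()].
#' @export
#' @examples
#' rep <- validate_peripheral(default_params())
#' rep
#' glance(rep)
validate_peripheral <- function(params, observed = observed_dose_response()) {
  stopifnot(is.data.frame(observed))
  if (nrow(observed) == 0) {
    stop("observed table must have at least one row", call. = FALSE)
  }
  req <- c("glucose_mM", "insulin_pM")
  if (!all(req %in% names(observed))) {
    stop("observed table must have columns glucose_mM, insulin_pM",
         call. = FALSE)
  }
  eq <- islet_equilibrium(params, observed$glucose_mM)
  out <- tibble::tibble(
    glucose_mM = observed$glucose_mM,
    predicted_pM = eq$Ip_pM,
    observed_pM = observed$insulin_pM,
    rel_error = (eq$Ip_pM - observed$insulin_pM) / observed$insulin_pM)
  class(out) <- c("validation_report", class(out))
  out
}

#' @rdname validate_peripheral
#' @param x A `validation_report`.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.validation_report <- function(x, ...) {
  tibble::tibble(max_abs_rel_error = max(abs(x$rel_error)),
                 n_levels = nrow(x))
}

#' Plot methods for simulation and validation results
#'
#' `autoplot.islet_trace` shows the four concentration pools over time;
#' `autoplot.islet_step` additionally marks the equilibrium and settling
#' time; `autoplot.validation_report` plots predicted vs observed
#' peripheral insulin; `plot_dose_sweep` shows the monomer decomposition
#' across glucose.
#'
#' @param object The result object.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.islet_trace <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object, cols = c("h_pM", "d_pM", "m_pM", "Ip_pM"),
    names_to = "species", values_to = "concentration_pM")
  long$species <- factor(long$species,
                         levels = c("h_pM", "d_pM", "m_pM", "Ip_pM"),
                         labels = c("hexamer", "dimer", "new monomer",
                                    "peripheral monomer"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_min,
                                     y = .data$concentration_pM,
                                     colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (min)", y = "Concentration (pM)",
                  colour = NULL,
                  title = sprintf("Glucose clamp at %g mM",
                                  object$glucose_mM[1])) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.islet_trace
#' @exportS3Method ggplot2::autoplot
autoplot.islet_step <- function(object, ...) {
  p <- autoplot.islet_trace(object$trace) +
    ggplot2::geom_hline(yintercept = object$equilibrium$Ip_pM,
                        linetype = "dashed", colour = "grey40")
  if (!is.na(object$time_to_settle)) {
    p <- p + ggplot2::geom_vline(xintercept = object$time_to_settle,
                                 linetype = "dotted", colour = "grey40")
  }
  p
}

#' @rdname autoplot.islet_trace
#' @exportS3Method ggplot2::autoplot
autoplot.validation_report <- function(object, ...) {
  long <- tidyr::pivot_longer(object, cols = c("predicted_pM", "observed_pM"),
                              names_to = "source", values_to = "insulin_pM")
  long$source <- sub("_pM$", "", long$source)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$glucose_mM,
                                     y = .data$insulin_pM,
                                     colour = .data$source)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Glucose (mM)", y = "Peripheral insulin (pM)",
                  colour = NULL, title = "Predicted vs observed dose response") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.islet_trace
#' @param sweep A tibble from [dose_sweep()].
#' @export
plot_dose_sweep <- function(sweep, ...) {
  long <- tidyr::pivot_longer(sweep, cols = c("m_pM", "Ip_pM"),
                              names_to = "pool", values_to = "concentration_pM")
  long$pool <- factor(long$pool, levels = c("Ip_pM", "m_pM"),
                      labels = c("returned peripheral", "newly secreted"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$glucose_mM,
                                     y = .data$concentration_pM,
                                     fill = .data$pool)) +
    ggplot2::geom_area(position = "stack") +
    ggplot2::labs(x = "Glucose (mM)", y = "Monomeric insulin (pM)",
                  fill = NULL,
                  title = "Equilibrium intra-islet monomer decomposition") +
    ggplot2::theme_minimal()
}
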