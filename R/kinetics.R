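#' Rate constants of the four-state islet insulin model
#'
#' Assembles and validates the full parameter set of the kinetic model:
#' hexamer-to-dimer dissolution (`p`), dimer-to-hexamer aggregation (`q`),
#' dimer-to-monomer dissolution (`p_hat`), monomer-to-dimer aggregation
#' (`q_hat`), insulin degradation (`d_i`, applied to both local and
#' peripheral insulin), transfer of local monomer out to the circulation
#' (`c`), the return coefficient coupling local monomer production to
#' returned peripheral insulin (`k`), and the Hill secretion parameters.
#'
#' A dimer dissolves to two monomers faster than a hexamer dissolves to
#' three dimers, so `p_hat > p` is enforced.
#'
#' @param p Hexamer -> dimer dissolution rate, 1/min.
#' @param q Dimer -> hexamer aggregation coefficient, L^2/pmol^2.
#' @param p_hat Dimer -> monomer dissolution rate, 1/min; must exceed `p`.
#' @param q_hat Monomer -> dimer aggregation coefficient, L/pmol.
#' @param d_i Insulin degradation rate (local and peripheral), 1/min.
#' @param c Transfer rate of local monomer to the circulation, 1/min.
#' @param k Return coefficient for peripheral insulin, 1/min.
#' @param hill A [hill_params()] object.
#' @return An object of class `kinetic_params`.
#' @seealso [default_params()] for the calibrated default set.
#' @export
kinetic_params <- function(p, q, p_hat, q_hat, d_i, c, k, hill) {
  stopifnot(inherits(hill, "hill_params"))
  rates <- c(p = p, p_hat = p_hat, d_i = d_i, c = c, k = k)
  if (any(!is.finite(rates)) || any(rates <= 0)) {
    stop("rate constants p, p_hat, d_i, c, k must be strictly positive",
         call. = FALSE)
  }
  if (q < 0 || q_hat < 0) {
    stop("aggregation coefficients q, q_hat must be nonnegative",
         call. = FALSE)
  }
  if (p_hat <= p) {
    stop("p_hat must exceed p (dimers dissolve faster than hexamers)",
         call. = FALSE)
  }
  structure(list(p = p, q = q, p_hat = p_hat, q_hat = q_hat,
                 d_i = d_i, c = c, k = k, hill = hill),
            class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("<kinetic_params>\n")
  cat(sprintf("  p = %.4g /min, p_hat = %.4g /min\n", x$p, x$p_hat))
  cat(sprintf("  q = %.4g L^2/pmol^2, q_hat = %.4g L/pmol\n", x$q, x$q_hat))
  cat(sprintf("  d_i = %.5g /min, c = %.5g /min, k = %.5g /min\n",
              x$d_i, x$c, x$k))
  print(x$hill)
  prov <- attr(x, "provenance")
  if (!is.null(prov)) cat("  (calibrated: see param_provenance())\n")
  invisible(x)
}

#' Islet state vector
#'
#' Concentrations (pM) of the four tracked species: hexamer particles `h`,
#' dimers `d`, newly secreted local monomer `m`, and returned peripheral
#' monomer `Ip`. All components must be nonnegative.
#'
#' @param h,d,m,Ip Concentrations in pM.
#' @return A named numeric vector of class `islet_state`.
#' @export
islet_state <- function(h = 0, d = 0, m = 0, Ip = 0) {
  x <- c(h = h, d = d, m = m, Ip = Ip)
  if (any(!is.finite(x)) || any(x < 0)) {
    stop("state components must be finite and nonnegative", call. = FALSE)
  }
  structure(x, class = c("islet_state", "numeric"))
}

#' Right-hand side of the four-state kinetic model
#'
#' Time derivatives (pM/min) of the islet state under a clamped glucose
#' concentration:
#' \deqn{dh/dt = s(G)/6 - p (h - q d^3)}
#' \deqn{dd/dt = 3 p (h - q d^3) - \hat p (d - \hat q m^2)}
#' \deqn{dm/dt = 2 \hat p (d - \hat q m^2) - (c + d_i) m}
#' \deqn{dI_p/dt = k m - d_i I_p}
#' Secretion enters as hexamers, hence the division of the Hill rate
#' \eqn{s(G)} by 6; the stoichiometric factors 3 and 2 convert one hexamer
#' to three dimers and one dimer to two monomers.
#'
#' @param state An [islet_state()] or named nonnegative vector
#'   `(h, d, m, Ip)`.
#' @param glucose Clamped glucose, mM; nonnegative scalar.
#' @param params A [kinetic_params()] object.
#' @return Named numeric derivative vector `(h, d, m, Ip)` in pM/min.
#' @export
islet_rhs <- function(state, glucose, params) {
  stopifnot(inherits(params, "kinetic_params"),
            is.numeric(glucose), length(glucose) == 1, glucose >= 0)
  x <- unclass(state)
  if (any(x < 0)) stop("state components must be nonnegative", call. = FALSE)
  s <- hill_rate(glucose, params$hill)
  hex_flux <- params$p * (x[["h"]] - params$q * x[["d"]]^3)
  dim_flux <- params$p_hat * (x[["d"]] - params$q_hat * x[["m"]]^2)
  c(h = s / 6 - hex_flux,
    d = 3 * hex_flux - dim_flux,
    m = 2 * dim_flux - (params$c + params$d_i) * x[["m"]],
    Ip = params$k * x[["m"]] - params$d_i * x[["Ip"]])
}

#' Closed-form equilibrium of the kinetic model
#'
#' The model has a unique, globally asymptotically stable fixed point at
#' every clamped glucose, computed explicitly in dependency order:
#' \deqn{m^* = s(G)/(c + d_i), \quad I_p^* = (k/d_i) m^*,}
#' \deqn{d^* = s(G)/(2\hat p) + \hat q m^{*2}, \quad
#'       h^* = s(G)/(6p) + q d^{*3}.}
#'
#' @param params A [kinetic_params()] object.
#' @param glucose Clamped glucose value(s), mM; nonnegative.
#' @return A tibble with one row per glucose value and columns
#'   `glucose_mM`, `h_pM`, `d_pM`, `m_pM`, `Ip_pM`, `total_monomer_pM`
#'   (= `m_pM + Ip_pM`).
#' @export
#' @examples
#' islet_equilibrium(default_params(), glucose = c(5, 7, 16.5))
islet_equilibrium <- function(params, glucose) {
  stopifnot(inherits(params, "kinetic_params"), is.numeric(glucose))
  if (any(glucose < 0)) stop("glucose must be nonnegative", call. = FALSE)
  s <- hill_rate(glucose, params$hill)
  m <- s / (params$c + params$d_i)
  Ip <- (params$k / params$d_i) * m
  d <- s / (2 * params$p_hat) + params$q_hat * m^2
  h <- s / (6 * params$p) + params$q * d^3
  tibble::tibble(glucose_mM = glucose, h_pM = h, d_pM = d, m_pM = m,
                 Ip_pM = Ip, total_monomer_pM = m + Ip)
}

#' Equilibrium ratio of new to returned monomeric insulin
#'
#' At steady state the ratio of newly secreted local monomer to returned
#' peripheral monomer is glucose-independent and equals `d_i / k`: it
#' depends only on how fast insulin degrades relative to how strongly the
#' periphery feeds back. Under the default calibration it is 1/3, i.e. 25%
#' of intra-islet monomeric insulin is new and 75% is returned.
#'
#' @param params A [kinetic_params()] object.
#' @return Dimensionless scalar `m* / Ip*`.
#' @export
new_to_peripheral_ratio <- function(params) {
  stopifnot(inherits(params, "kinetic_params"))
  params$d_i / params$k
}

#' Total intra-islet monomeric insulin at equilibrium
#'
#' The sum `m* + Ip*` of newly secreted and returned monomer, the
#' concentration relevant for autocrine/paracrine signaling at the insulin
#' receptor.
#'
#' @inheritParams islet_equilibrium
#' @return Total monomer concentration(s), pM.
#' @export
total_intra_islet_monomer <- function(params, glucose) {
  islet_equilibrium(params, glucose)$total_monomer_pM
}

#' Simulate the kinetic model under a glucose clamp
#'
#' Integrates the four-state system at a fixed glucose with a
#' stiff-capable adaptive solver (lsoda, relative tolerance 1e-8,
#' absolute tolerance 1e-10 pM). The default initial condition is the
#' empty islet; by global stability, the trajectory approaches the
#' closed-form equilibrium regardless of the starting state.
#'
#' @param params A [kinetic_params()] object.
#' @param glucose Clamped glucose, mM; nonnegative scalar.
#' @param t_end End time, min; > 0.
#' @param dt_out Output grid spacing, min.
#' @param init Initial [islet_state()].
#' @return A tibble of class `islet_trace` with columns `time_min`,
#'   `h_pM`, `d_pM`, `m_pM`, `Ip_pM`, `total_monomer_pM`, `glucose_mM`.
#' @export
#' @examples
#' tr <- simulate_clamp(default_params(), glucose = 10, t_end = 60)
#' tail(tr, 3)
simulate_clamp <- function(params, glucose, t_end, dt_out = 0.1,
                           init = islet_state()) {
  stopifnot(inherits(params, "kinetic_params"),
            is.numeric(t_end), t_end > 0, dt_out > 0)
  times <- seq(0, t_end, by = dt_out)
  if (times[length(times)] < t_end) times <- c(times, t_end)
  deriv <- function(t, y, parms) list(islet_rhs(y, glucose, params))
  sol <- deSolve::lsoda(y = unclass(init), times = times, func = deriv,
                        parms = NULL, rtol = 1e-8, atol = 1e-10)
  diagn <- attr(sol, "istate")
  if (!is.null(diagn) && diagn[1] < 0) {
    stop("ODE solver failed (istate = ", diagn[1], "); see deSolve::lsoda",
         call. = FALSE)
  }
  out <- tibble::tibble(
    time_min = sol[, "time"],
    h_pM = sol[, "h"], d_pM = sol[, "d"], m_pM = sol[, "m"],
    Ip_pM = sol[, "Ip"])
  out$total_monomer_pM <- out$m_pM + out$Ip_pM
  out$glucose_mM <- glucose
  class(out) <- c("islet_trace", class(out))
  out
}

#' Time for a trace component to come within a fraction of a reference
#'
#' Returns the first time at which `component` is within
#' `(1 - fraction) * reference` of `reference`, with linear interpolation
#' between output points. Used to quantify how fast the peripheral insulin
#' pool settles after a glucose step. Returns `NA_real_` if the trace
#' never reaches the band ("not reached").
#'
#' @param trace An `islet_trace` tibble from [simulate_clamp()].
#' @param component Column name, e.g. `"Ip_pM"`.
#' @param fraction Fraction of the reference to reach, in (0, 1].
#' @param reference Reference level, pM (typically the equilibrium value).
#' @return Time in minutes, or `NA_real_` if the band is never entered.
#' @export
time_to_fraction <- function(trace, component = "Ip_pM", fraction, reference) {
  stopifnot(is.data.frame(trace), component %in% names(trace),
            is.numeric(fraction), fraction > 0, fraction <= 1,
            is.numeric(reference))
  y <- trace[[component]]
  t <- trace$time_min
  band <- abs(y - reference) <= (1 - fraction) * abs(reference) + 1e-300
  if (!any(band)) return(NA_real_)
  i <- which(band)[1]
  if (i == 1) return(t[1])
  # linear interpolation of |y - reference| crossing the band edge
  gap0 <- abs(y[i - 1] - reference)
  gap1 <- abs(y[i] - reference)
  edge <- (1 - fraction) * abs(reference)
  if (gap0 == gap1) return(t[i])
  t[i - 1] + (gap0 - edge) / (gap0 - gap1) * (t[i] - t[i - 1])
}
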