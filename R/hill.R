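#' Hill dose-response parameters for glucose-stimulated insulin secretion
#'
#' Container for the three parameters of the secretion response
#' \eqn{s(G) = \sigma G^\gamma / (\alpha^\gamma + G^\gamma)}: the maximum
#' secretion rate, the half-saturation glucose and the Hill exponent.
#'
#' @param sigma Maximum secretion rate, pM/min; > 0.
#' @param alpha Half-saturation glucose, mM; > 0.
#' @param gamma Hill exponent, dimensionless; >= 1.
#' @return An object of class `hill_params`.
#' @export
#' @examples
#' hill_params(sigma = 100, alpha = 9, gamma = 3)
hill_params <- function(sigma, alpha, gamma) {
  stopifnot(is.numeric(sigma), length(sigma) == 1,
            is.numeric(alpha), length(alpha) == 1,
            is.numeric(gamma), length(gamma) == 1)
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  if (alpha <= 0) stop("alpha must be > 0", call. = FALSE)
  if (gamma < 1) stop("gamma must be >= 1", call. = FALSE)
  structure(list(sigma = sigma, alpha = alpha, gamma = gamma),
            class = "hill_params")
}

#' @export
print.hill_params <- function(x, ...) {
  cat(sprintf(
    "<hill_params> sigma = %.4g pM/min, alpha = %.4g mM, gamma = %.4g\n",
    x$sigma, x$alpha, x$gamma))
  invisible(x)
}

#' Glucose-stimulated insulin secretion rate
#'
#' Evaluates the saturating Hill response
#' \eqn{s(G) = \sigma G^\gamma / (\alpha^\gamma + G^\gamma)}. The output is
#' monotone nondecreasing in glucose, equals `sigma / 2` at `G = alpha`, and
#' is bounded above by `sigma`.
#'
#' @param glucose Glucose concentration(s), mM; must be nonnegative.
#' @param params A [hill_params()] object.
#' @return Secretion rate(s) in pM/min, same length as `glucose`.
#' @export
#' @examples
#' hill_rate(c(0, 9, 100), hill_params(100, 9, 3))
hill_rate <- function(glucose, params) {
  stopifnot(inherits(params, "hill_params"), is.numeric(glucose))
  if (any(glucose < 0)) {
    stop("glucose must be nonnegative", call. = FALSE)
  }
  g <- params$gamma
  out <- params$sigma * glucose^g / (params$alpha^g + glucose^g)
  # 0^gamma/0^gamma at G = 0 with alpha > 0 is already 0, but guard anyway
  out[glucose == 0] <- 0
  out
}

check_secretion_data <- function(data, min_points = 3L) {
  stopifnot(is.data.frame(data))
  req <- c("glucose_mM", "rate_pM_per_min")
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols) > 0) {
    stop("secretion data must have columns ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(data$glucose_mM <= 0)) {
    stop("glucose values must be strictly positive", call. = FALSE)
  }
  if (any(data$rate_pM_per_min < 0)) {
    stop("secretion rates must be nonnegative", call. = FALSE)
  }
  if (length(unique(data$glucose_mM)) < min_points) {
    stop("at least ", min_points, " distinct glucose values are required",
         call. = FALSE)
  }
  invisible(data)
}

#' Default multi-start grid and box bounds for the Hill fit
#'
#' The residual sum of squares of the Hill model is multimodal in the
#' exponent, so the fit is run from a fixed grid of starting values and the
#' best converged minimum is kept. Bounds keep the parameters in their
#' physically meaningful ranges.
#'
#' @return `hill_fit_starts()`: a tibble of starting triples.
#'   `hill_fit_bounds()`: a list with `lower` and `upper` named vectors.
#' @export
hill_fit_starts <- function() {
  tidyr::expand_grid(sigma = c(50, 100, 150),
                     alpha = c(5, 10, 15),
                     gamma = c(1, 2, 3, 4))
}

#' @rdname hill_fit_starts
#' @export
hill_fit_bounds <- function() {
  list(lower = c(sigma = 1e-8, alpha = 1e-8, gamma = 1),
       upper = c(sigma = 500, alpha = 50, gamma = 6))
}

#' Fit the Hill secretion response by least squares
#'
#' Minimizes the unweighted residual sum of squares of observed secretion
#' rates against the Hill response, using bounded Levenberg-Marquardt from
#' every starting triple in `starts` and keeping the best converged
#' solution (ties broken toward the smallest Hill exponent).
#'
#' @param data Data frame with columns `glucose_mM`, `rate_pM_per_min`
#'   (extra columns such as `provenance` are ignored). At least 3 distinct
#'   glucose values are required.
#' @param starts Data frame of starting values with columns `sigma`,
#'   `alpha`, `gamma`; defaults to [hill_fit_starts()].
#' @param bounds List with `lower` and `upper` named vectors; defaults to
#'   [hill_fit_bounds()].
#' @return An object of class `hill_fit`: a list with elements `params`
#'   (a [hill_params()]), `sse` (achieved residual sum of squares,
#'   (pM/min)^2), `n_converged` (number of converged starts) and `data`
#'   (the fitting data as a tibble). Supports [generics::tidy()],
#'   [generics::glance()], `predict()` and [ggplot2::autoplot()].
#' @export
#' @examples
#' fit <- fit_hill(secretion_table())
#' fit
#' glance(fit)
fit_hill <- function(data, starts = hill_fit_starts(), bounds = hill_fit_bounds()) {
  check_secretion_data(data)
  g_obs <- data$glucose_mM
  r_obs <- data$rate_pM_per_min

  resid_fn <- function(par) {
    r_obs - par[["sigma"]] * g_obs^par[["gamma"]] /
      (par[["alpha"]]^par[["gamma"]] + g_obs^par[["gamma"]])
  }

  runs <- purrr::pmap(starts, function(sigma, alpha, gamma) {
    par0 <- c(sigma = sigma, alpha = alpha, gamma = gamma)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = par0, fn = resid_fn,
                         lower = bounds$lower, upper = bounds$upper,
                         control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (is.null(fit) || !fit$info %in% 1:4) return(NULL)
    list(par = stats::coef(fit), sse = sum(resid_fn(stats::coef(fit))^2))
  })
  runs <- purrr::compact(runs)
  if (length(runs) == 0) {
    stop("Hill fit failed to converge from any starting value; ",
         "check the data scale and bounds", call. = FALSE)
  }
  sses <- purrr::map_dbl(runs, "sse")
  gammas <- purrr::map_dbl(runs, ~ .x$par[["gamma"]])
  # best SSE; among near-ties (1e-8 relative) take the smallest exponent
  tol <- min(sses) * 1e-8 + 1e-12
  candidates <- which(sses <= min(sses) + tol)
  best <- candidates[which.min(gammas[candidates])]
  par <- runs[[best]]$par

  structure(
    list(params = hill_params(par[["sigma"]], par[["alpha"]], par[["gamma"]]),
         sse = runs[[best]]$sse,
         n_converged = length(runs),
         data = tibble::as_tibble(data)),
    class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat("Hill secretion fit (unweighted least squares)\n")
  print(x$params)
  cat(sprintf("  SSE = %.4g (pM/min)^2 on %d points; %d/%d starts converged\n",
              x$sse, nrow(x$data), x$n_converged, nrow(hill_fit_starts())))
  invisible(x)
}

#' @export
predict.hill_fit <- function(object, glucose, ...) {
  hill_rate(glucose, object$params)
}

#' Tidy and summarize a Hill secretion fit
#'
#' @param x,object A `hill_fit` object.
#' @param ... Unused.
#' @return `tidy()`: one row per parameter with `term`, `estimate`, `unit`.
#'   `glance()`: one row with `sse`, `rmse`, `nobs`, `n_converged`.
#' @exportS3Method generics::tidy
tidy.hill_fit <- function(x, ...) {
  tibble::tibble(
    term = c("sigma", "alpha", "gamma"),
    estimate = c(x$params$sigma, x$params$alpha, x$params$gamma),
    unit = c("pM/min", "mM", ""))
}

#' @rdname tidy.hill_fit
#' @exportS3Method generics::glance
glance.hill_fit <- function(x, ...) {
  tibble::tibble(
    sse = x$sse,
    rmse = sqrt(x$sse / nrow(x$data)),
    nobs = nrow(x$data),
    n_converged = x$n_converged)
}

#' @rdname tidy.hill_fit
#' @exportS3Method ggplot2::autoplot
autoplot.hill_fit <- function(object, ...) {
  grid <- tibble::tibble(
    glucose_mM = seq(0, max(object$data$glucose_mM) * 1.05, length.out = 200))
  grid$rate_pM_per_min <- hill_rate(grid$glucose_mM, object$params)
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$glucose_mM, y = .data$rate_pM_per_min)) +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Glucose (mM)", y = "Insulin secretion rate (pM/min)",
                  title = "Hill secretion dose response") +
    ggplot2::theme_minimal()
}
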