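#' Specification for synthetic secretion-rate datasets
#'
#' Describes the generative model behind the fitting stage: rates drawn
#' from a Hill dose response at fixed glucose design points with additive
#' Gaussian noise, truncated at zero (secretion rates cannot be
#' negative). Mirrors the design of the packaged secretion table by
#' default.
#'
#' @param hill A [hill_params()] object.
#' @param glucose Design points, mM; strictly positive.
#' @param noise_sd Noise standard deviation, pM/min; >= 0.
#' @param n_replicates Number of replicate datasets.
#' @param seed Integer seed making generation reproducible.
#' @return A list of class `synth_spec`.
#' @export
synth_spec <- function(hill,
                       glucose = c(3, 4, 5, 7, 9, 16.5, 25),
                       noise_sd = 5, n_replicates = 1, seed = 1L) {
  stopifnot(inherits(hill, "hill_params"), length(glucose) > 0,
            all(glucose > 0), noise_sd >= 0, n_replicates >= 1)
  structure(list(hill = hill, glucose = glucose, noise_sd = noise_sd,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "synth_spec")
}

#' Generate synthetic secretion datasets
#'
#' Pure function of the spec: the same spec (including its seed) always
#' yields the same data. Rates are `hill_rate(G) + N(0, noise_sd)`,
#' truncated at zero.
#'
#' @param spec A [synth_spec()] object.
#' @return A tibble with columns `glucose_mM`, `rate_pM_per_min`,
#'   `provenance`, `replicate`.
#' @export
#' @examples
#' gen_secretion_data(synth_spec(hill_params(100, 9, 3), noise_sd = 0))
gen_secretion_data <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  truth <- hill_rate(spec$glucose, spec$hill)
  withr::with_seed(spec$seed, {
    purrr::map_dfr(seq_len(spec$n_replicates), function(rep) {
      noise <- if (spec$noise_sd > 0) {
        stats::rnorm(length(truth), 0, spec$noise_sd)
      } else {
        rep(0, length(truth))
      }
      tibble::tibble(
        glucose_mM = spec$glucose,
        rate_pM_per_min = pmax(truth + noise, 0),
        provenance = sprintf("synthetic: Hill(%.4g, %.4g, %.4g), sd %.3g",
                             spec$hill$sigma, spec$hill$alpha,
                             spec$hill$gamma, spec$noise_sd),
        replicate = rep)
    })
  })
}

#' Generate random nonnegative initial islet states
#'
#' Draws `n` states with components independently uniform on
#' `[0, upper_bound]`; used to probe positivity, boundedness and global
#' convergence of the kinetic model from arbitrary starting conditions.
#'
#' @param n Number of states; >= 1.
#' @param upper_bound Upper bound per component, pM; > 0.
#' @param seed Integer seed.
#' @return A tibble with `n` rows and columns `h`, `d`, `m`, `Ip` (pM).
#' @export
gen_initial_states <- function(n, upper_bound = 1e4, seed = 1L) {
  stopifnot(n >= 1, upper_bound > 0)
  withr::with_seed(as.integer(seed), {
    tibble::tibble(h = stats::runif(n, 0, upper_bound),
                   d = stats::runif(n, 0, upper_bound),
                   m = stats::runif(n, 0, upper_bound),
                   Ip = stats::runif(n, 0, upper_bound))
  })
}

#' Randomly perturb selected rate constants
#'
#' Multiplies each selected rate by an independent log-uniform factor
#' drawn between `factor_bounds[1]` and `factor_bounds[2]`. Errors if the
#' perturbed set violates the parameter invariants (notably
#' `p_hat > p`). Used for sensitivity analyses, e.g. verifying that the
#' equilibrium monomer pools are invariant to the oligomer kinetics.
#'
#' @param params A [kinetic_params()] object.
#' @param which Names of rates to perturb, a subset of
#'   `c("p", "q", "p_hat", "q_hat", "d_i", "c", "k")`.
#' @param factor_bounds Length-2 positive vector of multiplicative bounds.
#' @param seed Integer seed.
#' @return A new `kinetic_params` object.
#' @export
perturb_params <- function(params, which = c("p", "p_hat", "q", "q_hat"),
                           factor_bounds = c(0.1, 10), seed = 1L) {
  stopifnot(inherits(params, "kinetic_params"),
            length(factor_bounds) == 2, all(factor_bounds > 0),
            factor_bounds[1] <= factor_bounds[2])
  allowed <- c("p", "q", "p_hat", "q_hat", "d_i", "c", "k")
  bad <- setdiff(which, allowed)
  if (length(bad) > 0) {
    stop("cannot perturb: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  vals <- params[allowed]
  withr::with_seed(as.integer(seed), {
    factors <- exp(stats::runif(length(which),
                                log(factor_bounds[1]),
                                log(factor_bounds[2])))
  })
  vals[which] <- purrr::map2_dbl(vals[which], factors, `*`)
  kinetic_params(p = vals$p, q = vals$q, p_hat = vals$p_hat,
                 q_hat = vals$q_hat, d_i = vals$d_i, c = vals$c,
                 k = vals$k, hill = params$hill)
}
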