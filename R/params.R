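#' Parameter sets for the stochastic May-Leonard model variants
#'
#' Three parameterisations are supported. The general-variance (GV) model
#' splits the net per-capita growth rate into an explicit birth rate `b` and
#' death rate `d` (net rate `b - d`), so that for fixed `r` the demographic noise
#' can be made arbitrarily large by raising both. The minimal model is the
#' `d = 0` special case, the minimum-variance member of that family. The
#' three-pool model describes a central pattern generator of three neural
#' pools of `omega` cells each, coupled by cyclic inhibition of strength
#' `gamma` and driven by endogenous activation at rate `mu/tau`.
#'
#' `omega` is the system size: the single-species carrying capacity for the
#' GV/minimal models (any positive real; it only scales rates, states stay
#' integer), and the number of cells per pool for the three-pool model (a
#' positive integer, since it bounds the state space).
#'
#' @param b,d Per-capita birth and death rates (1/time); requires `b - d > 0`.
#' @param r Net per-capita growth rate (1/time), positive.
#' @param alpha Competition strength of species `i+1` on species `i`
#'   (dimensionless, cyclic indices), `alpha >= 0`.
#' @param beta Competition strength of species `i+2` on species `i`,
#'   `beta >= 0`.
#' @param omega System size (see Details).
#' @param tau Time constant of the three-pool model (time), `tau > 0`.
#' @param gamma Inhibition strength (dimensionless), `gamma >= 0`.
#' @param mu Endogenous activation rate (dimensionless), `mu >= 0`.
#'
#' @return An object of class `gv_params`, `minimal_params` or
#'   `three_pool_params` (all also `ml_params`): a named list of validated
#'   parameters.
#'
#' @examples
#' gv_params(b = 2, d = 1, alpha = 0.8, beta = 1.3, omega = 30)
#' minimal_params(r = 1, alpha = 0.8, beta = 1.3, omega = 30)
#' three_pool_params(tau = 1, gamma = 2.4, mu = 1e-5, omega = 10)
#' @name ml_params
NULL

check_num <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (strict && x <= lower) {
    stop(sprintf("invalid parameters: `%s` must be > %s (got %g)",
                 name, format(lower), x), call. = FALSE)
  }
  if (!strict && x < lower) {
    stop(sprintf("invalid parameters: `%s` must be >= %s (got %g)",
                 name, format(lower), x), call. = FALSE)
  }
  invisible(x)
}

#' @rdname ml_params
#' @export
gv_params <- function(b = 2, d = 1, alpha = 0.8, beta = 1.3, omega = 30) {
  check_num(b, "b", 0, strict = TRUE)
  check_num(d, "d", 0)
  check_num(alpha, "alpha", 0)
  check_num(beta, "beta", 0)
  check_num(omega, "omega", 0, strict = TRUE)
  if (b - d <= 0) {
    stop("invalid parameters: net growth rate `b - d` must be > 0",
         call. = FALSE)
  }
  structure(list(b = b, d = d, alpha = alpha, beta = beta, omega = omega),
            class = c("gv_params", "ml_params"))
}

#' @rdname ml_params
#' @export
minimal_params <- function(r = 1, alpha = 0.8, beta = 1.3, omega = 30) {
  check_num(r, "r", 0, strict = TRUE)
  check_num(alpha, "alpha", 0)
  check_num(beta, "beta", 0)
  check_num(omega, "omega", 0, strict = TRUE)
  structure(list(r = r, alpha = alpha, beta = beta, omega = omega),
            class = c("minimal_params", "ml_params"))
}

#' @rdname ml_params
#' @export
three_pool_params <- function(tau = 1, gamma = 2.4, mu = 1e-5, omega = 10) {
  check_num(tau, "tau", 0, strict = TRUE)
  check_num(gamma, "gamma", 0)
  check_num(mu, "mu", 0)
  check_num(omega, "omega", 0, strict = TRUE)
  if (abs(omega - round(omega)) > 1e-8 || omega < 1) {
    stop("invalid parameters: `omega` must be a positive integer for the ",
         "three-pool model (it bounds the state space)", call. = FALSE)
  }
  structure(list(tau = tau, gamma = gamma, mu = mu, omega = as.integer(round(omega))),
            class = c("three_pool_params", "ml_params"))
}

#' @export
print.ml_params <- function(x, ...) {
  model <- switch(class(x)[1],
    gv_params = "general-variance May-Leonard",
    minimal_params = "minimal (zero-death) May-Leonard",
    three_pool_params = "three-pool central pattern generator"
  )
  cat("<", model, " parameters>\n", sep = "")
  for (nm in names(x)) cat("  ", nm, " = ", format(x[[nm]]), "\n", sep = "")
  invisible(x)
}

#' Model tag of a parameter set
#' @param params An `ml_params` object.
#' @return One of `"gv"`, `"minimal"`, `"threepool"`.
#' @export
model_tag <- function(params) {
  switch(class(params)[1],
    gv_params = "gv",
    minimal_params = "minimal",
    three_pool_params = "threepool",
    stop("not an ml_params object")
  )
}
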