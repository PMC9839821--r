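#' Build a single mass-action reaction
#'
#' Reactions are specified by their reactant stoichiometry (which determines
#' the combinatorial propensity), an optional complement-species stoichiometry
#' (reactants counted as `omega - N_i`, used for the inactive cells of the
#' three-pool model), the net change they apply to the state, a microscopic
#' rate constant and a label.
#'
#' @param reactants Integer vector of reactant stoichiometries over the
#'   species (length = number of species).
#' @param change Integer vector: net stoichiometric change applied to the
#'   state when the reaction fires.
#' @param c Microscopic rate constant (units depend on reaction order).
#' @param label Text tag, e.g. `"birth"`, `"homocidal"`, `"inhibition"`.
#' @param complements Integer vector of stoichiometries over complement counts
#'   `omega - N_i` (defaults to all zero).
#' @return A list of class `ml_reaction`.
#' @export
reaction <- function(reactants, change, c, label = "",
                     complements = integer(length(reactants))) {
  stopifnot(length(reactants) == length(change),
            length(complements) == length(reactants))
  if (c < 0) stop("rate constant must be nonnegative")
  if (sum(reactants) + sum(complements) > 2L) {
    stop("total reactant order must be at most 2")
  }
  structure(list(reactants = as.integer(reactants),
                 complements = as.integer(complements),
                 change = as.integer(change),
                 c = as.numeric(c), label = label),
            class = "ml_reaction")
}

#' Assemble a reaction network from individual reactions
#'
#' Low-level constructor for custom networks (the model-specific builders
#' [build_gv_network()], [build_minimal_network()] and
#' [build_three_pool_network()] are usually preferable). `omega` is only
#' used by reactions with complement reactants and by bounded networks.
#'
#' @param reactions List of [reaction()] objects.
#' @param n_species Number of species.
#' @param omega System size (default 1).
#' @param model Model tag stored on the network.
#' @param bounded Bound every species at `omega`?
#' @return A `reaction_network`.
#' @export
reaction_network <- function(reactions, n_species, omega = 1,
                             model = "custom", bounded = FALSE) {
  stopifnot(length(reactions) >= 1,
            all(vapply(reactions, inherits, logical(1), "ml_reaction")))
  new_reaction_network(model, list(omega = omega), reactions,
                       as.integer(n_species), bounded = bounded)
}

new_reaction_network <- function(model, params, reactions, n_species,
                                 bounded = FALSE) {
  nr <- length(reactions)
  pull <- function(fld) {
    matrix(unlist(lapply(reactions, `[[`, fld)), nrow = nr,
           ncol = n_species, byrow = TRUE)
  }
  Rct <- pull("reactants")
  Cmp <- pull("complements")
  S <- pull("change")
  structure(list(
    model = model,
    params = params,
    n_species = n_species,
    reactions = tibble::tibble(
      label = vapply(reactions, `[[`, character(1), "label"),
      rate_constant = vapply(reactions, `[[`, numeric(1), "c")
    ),
    Rct = Rct, Cmp = Cmp, S = S,
    rate = vapply(reactions, `[[`, numeric(1), "c"),
    omega = params$omega,
    state_bounds = if (bounded) rep(params$omega, n_species) else NULL
  ), class = "reaction_network")
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("<reaction network: ", x$model, ", ", nrow(x$S), " reactions, ",
      x$n_species, " species", sep = "")
  if (!is.null(x$state_bounds)) cat(", bounded at omega =", x$omega)
  cat(">\n")
  df <- x$reactions
  df$change <- apply(x$S, 1, function(s) paste(sprintf("%+d", s), collapse = ","))
  print(df, n = nrow(df))
  invisible(x)
}

cyc <- function(i, k) ((i - 1 + k) %% 3) + 1

e3 <- function(i) {
  v <- integer(3)
  v[i] <- 1L
  v
}

#' Reaction network of the general-variance May-Leonard model
#'
#' Fifteen reactions (five templates for each of the three species, cyclic
#' indices): birth `A_i -> 2A_i` (rate constant `b`), death `A_i -> 0` (`d`),
#' homocidal competition `2A_i -> A_i` (`2/omega`), and the two heterocidal
#' competitions `A_i + A_{i+1} -> A_{i+1}` (`alpha/omega`) and
#' `A_i + A_{i+2} -> A_{i+2}` (`beta/omega`). Every reaction changes exactly
#' one species by one individual.
#'
#' @param params A [gv_params()] object.
#' @return A `reaction_network`.
#' @export
build_gv_network <- function(params) {
  stopifnot(inherits(params, "gv_params"))
  w <- params$omega
  rx <- list()
  for (i in 1:3) {
    rx <- c(rx, list(
      reaction(e3(i), e3(i), params$b, "birth"),
      reaction(e3(i), -e3(i), params$d, "death"),
      reaction(2L * e3(i), -e3(i), 2 / w, "homocidal"),
      reaction(e3(i) + e3(cyc(i, 1)), -e3(i), params$alpha / w, "heterocidal"),
      reaction(e3(i) + e3(cyc(i, 2)), -e3(i), params$beta / w, "heterocidal")
    ))
  }
  new_reaction_network("gv", params, rx, 3L)
}

#' Reaction network of the minimal (zero-death) May-Leonard model
#'
#' Twelve reactions: the general-variance network with the individual death
#' reactions removed (`r` equal to `b`, `d = 0`). With no `A_i -> 0` channel, the only
#' death mechanism is homocidal competition, which requires at least two
#' individuals, so total extinction is unreachable from nonzero states.
#'
#' @param params A [minimal_params()] object.
#' @return A `reaction_network`.
#' @export
build_minimal_network <- function(params) {
  stopifnot(inherits(params, "minimal_params"))
  w <- params$omega
  rx <- list()
  for (i in 1:3) {
    rx <- c(rx, list(
      reaction(e3(i), e3(i), params$r, "birth"),
      reaction(2L * e3(i), -e3(i), 2 / w, "homocidal"),
      reaction(e3(i) + e3(cyc(i, 1)), -e3(i), params$alpha / w, "heterocidal"),
      reaction(e3(i) + e3(cyc(i, 2)), -e3(i), params$beta / w, "heterocidal")
    ))
  }
  new_reaction_network("minimal", params, rx, 3L)
}

#' Reaction network of the three-pool central pattern generator model
#'
#' Nine reactions over the active counts `N_i`, with the inactive counts
#' `M_i = omega - N_i` implicit: self-activation `A_i + I_i -> 2A_i`
#' (`1/(tau*omega)`), inhibition of pool `i` by pool `i+1`
#' `A_i + A_{i+1} -> I_i + A_{i+1}` (`gamma/(tau*omega)`), and endogenous
#' activation `I_i -> A_i` (`mu/tau`). Each reaction toggles one cell between
#' active and inactive, so `N_i + M_i = omega` is conserved and every
#' reachable state stays in `[0, omega]^3`.
#'
#' @param params A [three_pool_params()] object.
#' @return A bounded `reaction_network`.
#' @export
build_three_pool_network <- function(params) {
  stopifnot(inherits(params, "three_pool_params"))
  w <- params$omega
  tau <- params$tau
  rx <- list()
  for (i in 1:3) {
    rx <- c(rx, list(
      reaction(e3(i), e3(i), 1 / (tau * w), "self-activation",
               complements = e3(i)),
      reaction(e3(i) + e3(cyc(i, 1)), -e3(i), params$gamma / (tau * w),
               "inhibition"),
      reaction(integer(3), e3(i), params$mu / tau, "endogenous",
               complements = e3(i))
    ))
  }
  new_reaction_network("threepool", params, rx, 3L, bounded = TRUE)
}

#' Build the reaction network for a parameter set
#' @param params An `ml_params` object.
#' @return A `reaction_network`.
#' @export
build_network <- function(params) {
  switch(model_tag(params),
    gv = build_gv_network(params),
    minimal = build_minimal_network(params),
    threepool = build_three_pool_network(params)
  )
}

#' Single- and two-species minimal subnetworks
#'
#' After extinctions the minimal model reduces to lower-dimensional
#' subsystems. `single_species_subnet()` is the surviving-species chain
#' (birth at rate `r` times `N`, homocidal death at rate `N(N-1)/omega`), whose
#' stationary law is the truncated Poisson. `two_species_subnet()` is the
#' system on the plane `N_3 = 0` used for the conditional second-extinction
#' analysis: species 1 is killed by species 2 at rate `alpha/omega` per pair,
#' species 2 by species 1 at rate `beta/omega` per pair.
#'
#' @param params A [minimal_params()] object.
#' @return A `reaction_network` over 1 or 2 species.
#' @export
single_species_subnet <- function(params) {
  stopifnot(inherits(params, "minimal_params"))
  w <- params$omega
  rx <- list(
    reaction(1L, 1L, params$r, "birth"),
    reaction(2L, -1L, 2 / w, "homocidal")
  )
  new_reaction_network("minimal1", params, rx, 1L)
}

#' @rdname single_species_subnet
#' @export
two_species_subnet <- function(params) {
  stopifnot(inherits(params, "minimal_params"))
  w <- params$omega
  rx <- list(
    reaction(c(1L, 0L), c(1L, 0L), params$r, "birth"),
    reaction(c(0L, 1L), c(0L, 1L), params$r, "birth"),
    reaction(c(2L, 0L), c(-1L, 0L), 2 / w, "homocidal"),
    reaction(c(0L, 2L), c(0L, -1L), 2 / w, "homocidal"),
    reaction(c(1L, 1L), c(-1L, 0L), params$alpha / w, "heterocidal"),
    reaction(c(1L, 1L), c(0L, -1L), params$beta / w, "heterocidal")
  )
  new_reaction_network("minimal2", params, rx, 2L)
}

#' Combinatorial mass-action propensities at a state
#'
#' The propensity of a reaction with rate constant `c` is `c` times the
#' number of distinct reactant combinations: `N` for a first-order reactant,
#' `N_A N_B` for `A + B`, and `N(N-1)/2` for `2A`. Complement reactants
#' contribute `omega - N_i`. A propensity is zero whenever a reactant count
#' falls below its stoichiometry.
#'
#' @param net A `reaction_network`.
#' @param state Integer vector of species counts.
#' @return Numeric vector of nonnegative rates, one per reaction.
#' @export
propensities <- function(net, state) {
  check_state(net, state)
  drop(propensity_matrix(net, matrix(state, nrow = 1)))
}

check_state <- function(net, state) {
  if (length(state) != net$n_species || any(state < 0) ||
      any(state != round(state))) {
    stop("state must be ", net$n_species, " nonnegative integers",
         call. = FALSE)
  }
  if (!is.null(net$state_bounds) && any(state > net$state_bounds)) {
    stop("state exceeds the bound omega = ", net$omega, call. = FALSE)
  }
  invisible(state)
}

# Propensities for many states at once: states is an n x n_species matrix,
# returns an n x n_reactions matrix. Used by the generator builder.
propensity_matrix <- function(net, states) {
  n <- nrow(states)
  nr <- nrow(net$S)
  A <- matrix(rep(net$rate, each = n), n, nr)
  for (j in seq_len(nr)) {
    for (k in seq_len(net$n_species)) {
      r <- net$Rct[j, k]
      if (r == 1L) {
        A[, j] <- A[, j] * states[, k]
      } else if (r == 2L) {
        A[, j] <- A[, j] * states[, k] * (states[, k] - 1) / 2
      }
      cm <- net$Cmp[j, k]
      if (cm == 1L) {
        A[, j] <- A[, j] * pmax(net$omega - states[, k], 0)
      } else if (cm == 2L) {
        M <- pmax(net$omega - states[, k], 0)
        A[, j] <- A[, j] * M * (M - 1) / 2
      }
    }
  }
  A[A < 0] <- 0
  A
}

#' Deterministic mean-field drift
#'
#' The right-hand side of the mean-field equations, written with the
#' macroscopic `N^2` self-limitation term (not the combinatorial `N(N-1)`):
#' for the GV model `dN_i/dt = N_i[(b-d) - N_i/omega - alpha N_{i+1}/omega -
#' beta N_{i+2}/omega]`, for the minimal model the same with `r` in place of
#' `b - d`, and for the three-pool model `dN_i/dt = (1/tau)[N_i(1 - N_i/omega
#' - gamma N_{i+1}/omega) + mu(omega - N_i)]`.
#'
#' The expected instantaneous increment rate of the stochastic model equals
#' this drift plus the combinatorial correction `+N_i/omega` per species for
#' the GV/minimal networks (the homocidal propensity uses `N(N-1)` rather
#' than `N^2`); the three-pool network matches its drift exactly.
#'
#' @param params An `ml_params` object (a `reaction_network` is also
#'   accepted; its parameter set is used).
#' @param point Nonnegative real 3-vector.
#' @return Real 3-vector of time derivatives.
#' @export
drift <- function(params, point) {
  if (inherits(params, "reaction_network")) params <- params$params
  if (length(point) != 3 || any(point < 0)) {
    stop("point must be a nonnegative 3-vector", call. = FALSE)
  }
  drift_raw(params, point)
}

# no validation; used inside ODE solvers
drift_raw <- function(params, N) {
  w <- params$omega
  N2 <- N[c(2, 3, 1)]
  N3 <- N[c(3, 1, 2)]
  if (inherits(params, "three_pool_params")) {
    (N * (1 - N / w - params$gamma * N2 / w) + params$mu * (w - N)) /
      params$tau
  } else {
    r <- if (inherits(params, "gv_params")) params$b - params$d else params$r
    N * (r - N / w - params$alpha * N2 / w - params$beta * N3 / w)
  }
}
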