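#' Bijective map between lattice states and linear indices
#'
#' Row-major enumeration of the truncated lattice `{0..n_max}^d` in dimension
#' order `(N_1, ..., N_d)`: `N_d` varies fastest.
#'
#' @param n_max Per-dimension maximum count.
#' @param d Number of dimensions (species).
#' @return A list with `n_states`, `encode(states)` (matrix or vector of
#'   states to 1-based indices) and `decode(idx)` (indices to a state
#'   matrix).
#' @export
lattice_index_map <- function(n_max, d = 3L) {
  stopifnot(n_max >= 1)
  M1 <- n_max + 1L
  wts <- M1^((d - 1L):0L)
  list(
    n_max = n_max, d = d, n_states = M1^d,
    encode = function(states) {
      if (is.null(dim(states))) states <- matrix(states, nrow = 1)
      if (any(states < 0) || any(states > n_max)) {
        stop("state outside the lattice {0..", n_max, "}^", d, call. = FALSE)
      }
      as.integer(states %*% wts + 1)
    },
    decode = function(idx) {
      idx0 <- idx - 1L
      out <- matrix(0L, length(idx), d)
      for (k in d:1) {
        out[, k] <- as.integer(idx0 %% M1)
        idx0 <- idx0 %/% M1
      }
      colnames(out) <- paste0("N", seq_len(d))
      out
    }
  )
}

#' Infinitesimal generator on a truncated lattice
#'
#' Assembles the sparse transition-rate operator of a reaction network over
#' the lattice `{0..n_max}^d`, with rates given by the combinatorial
#' mass-action propensities. Transitions that would leave the lattice are
#' deleted ("adjoint reflecting" truncation at `N_i = n_max`; the unique
#' choice that conserves probability without adding fictitious transitions).
#' States matching `absorbing` have their outgoing rates zeroed. Every row of
#' the returned operator sums to zero and absorbing rows are identically
#' zero.
#'
#' @param net A `reaction_network`.
#' @param n_max Truncation level (defaults to `2 * omega` for unbounded
#'   networks and to `omega` for bounded ones). Stationary-distribution
#'   comparisons require `n_max >= r*omega + 10*sqrt(r*omega)`.
#' @param absorbing One of `"none"`, `"any_zero"` (all states with some
#'   `N_i = 0`; the coordinate-plane extinction boundary), `"origin"`, an
#'   integer vector of 1-based state indices, or a predicate
#'   `function(states)` returning a logical vector.
#' @return An object of class `ml_generator`: list with the sparse operator
#'   `Q`, the state matrix `states`, logical `absorbing`, the `map`, `n_max`
#'   and the network.
#' @export
build_generator <- function(net, n_max = NULL, absorbing = "none") {
  stopifnot(inherits(net, "reaction_network"))
  if (is.null(n_max)) {
    n_max <- if (is.null(net$state_bounds)) ceiling(2 * net$omega)
             else net$omega
  }
  if (n_max < 1) stop("n_max must be at least 1")
  if (!is.null(net$state_bounds) && n_max > net$omega) {
    stop("n_max cannot exceed the bound omega = ", net$omega)
  }
  d <- net$n_species
  map <- lattice_index_map(n_max, d)
  n <- map$n_states
  states <- map$decode(seq_len(n))

  ab <- switch(
    class(absorbing)[1],
    character = switch(absorbing,
      none = rep(FALSE, n),
      any_zero = rowSums(states == 0L) > 0L,
      origin = rowSums(states) == 0L,
      stop("unknown absorbing spec: ", absorbing)),
    "function" = absorbing(states),
    {
      v <- rep(FALSE, n)
      v[as.integer(absorbing)] <- TRUE
      v
    }
  )

  A <- propensity_matrix(net, states)
  A[ab, ] <- 0
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (j in seq_len(nrow(net$S))) {
    pos <- which(A[, j] > 0)
    if (!length(pos)) next
    tgt <- states[pos, , drop = FALSE] +
      matrix(net$S[j, ], length(pos), d, byrow = TRUE)
    inb <- rowSums(tgt >= 0L & tgt <= n_max) == d
    pos <- pos[inb]
    if (!length(pos)) next
    ii <- c(ii, pos)
    jj <- c(jj, map$encode(tgt[inb, , drop = FALSE]))
    xx <- c(xx, A[pos, j])
  }
  Q <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
  Q <- Q - Matrix::Diagonal(n, Matrix::rowSums(Q))
  structure(list(Q = Q, states = states, absorbing = ab, map = map,
                 n_max = n_max, net = net),
            class = "ml_generator")
}

#' @export
print.ml_generator <- function(x, ...) {
  cat("<infinitesimal generator: ", nrow(x$Q), " states (n_max = ",
      x$n_max, "), ", sum(x$absorbing), " absorbing, model ", x$net$model,
      ">\n", sep = "")
  invisible(x)
}

# transient/absorbing blocks
gen_blocks <- function(G) {
  tr <- which(!G$absorbing)
  ab <- which(G$absorbing)
  list(tr = tr, ab = ab,
       Qtt = G$Q[tr, tr, drop = FALSE],
       Qta = G$Q[tr, ab, drop = FALSE])
}

default_classes <- function(G) {
  ab_states <- G$states[G$absorbing, , drop = FALSE]
  if (nrow(ab_states) == 0) stop("absorbing set is empty")
  zero_ix <- apply(ab_states == 0L, 1, function(z) which(z)[1])
  if (anyNA(zero_ix)) {
    return(list(absorbed = seq_len(nrow(ab_states))))
  }
  split(seq_len(nrow(ab_states)), paste0("N", zero_ix, "=0"))
}

#' First-passage hitting probabilities
#'
#' Solves the backward absorbing-chain system for the probability, from each
#' transient initial state, of absorption into each class of absorbing
#' states: with generator blocks `Q_TT` (transient-transient) and `Q_TA`
#' (transient-absorbing), the hitting probabilities solve
#' `Q_TT h + Q_TA 1_class = 0`. For the extinction problem the default
#' classes are the coordinate planes `N_i = 0`.
#'
#' @param G An `ml_generator` with a nonempty absorbing set reachable from
#'   every transient state.
#' @param classes Optional named list of index vectors partitioning the
#'   absorbing states (indices within the absorbing subset).
#' @return A tibble of class `ml_hitting`: transient state coordinates plus
#'   one probability column per class; attributes `residual` (maximum
#'   absolute backward-equation residual) and `classes`.
#' @export
hitting_probabilities <- function(G, classes = NULL) {
  bl <- gen_blocks(G)
  if (length(bl$ab) == 0) stop("absorbing set is empty")
  if (is.null(classes)) classes <- default_classes(G)
  Ind <- matrix(0, length(bl$ab), length(classes),
                dimnames = list(NULL, names(classes)))
  for (k in seq_along(classes)) Ind[classes[[k]], k] <- 1
  B <- as.matrix(bl$Qta %*% Ind)
  H <- tryCatch(as.matrix(Matrix::solve(bl$Qtt, -B)),
                error = function(e) {
                  stop("singular backward system; the absorbing set may be ",
                       "unreachable from some transient states: ",
                       conditionMessage(e), call. = FALSE)
                })
  resid <- max(abs(bl$Qtt %*% H + B))
  out <- tibble::as_tibble(as.data.frame(G$states[bl$tr, , drop = FALSE]))
  for (k in colnames(Ind)) out[[k]] <- H[, k]
  structure(out, class = c("ml_hitting", class(out)),
            residual = resid, classes = classes)
}

#' Mean absorption (first-passage) times
#'
#' Solves the backward system `Q_TT tau = -1` for the mean time to reach the
#' absorbing set from every transient state; `tau = 0` on absorbing states.
#'
#' @param G An `ml_generator` with a reachable, nonempty absorbing set.
#' @return A tibble of class `ml_fpt`: all lattice states with their mean
#'   absorption time `tau` (zero on absorbing states) and a logical
#'   `absorbing` column; attribute `residual`.
#' @export
mean_absorption_time <- function(G) {
  bl <- gen_blocks(G)
  if (length(bl$ab) == 0) stop("absorbing set is empty")
  ones <- rep(1, length(bl$tr))
  tau_t <- tryCatch(as.numeric(Matrix::solve(bl$Qtt, -ones)),
                    error = function(e) {
                      stop("singular backward system; the absorbing set may ",
                           "be unreachable from some transient states: ",
                           conditionMessage(e), call. = FALSE)
                    })
  resid <- max(abs(bl$Qtt %*% tau_t + ones))
  tau <- numeric(nrow(G$states))
  tau[bl$tr] <- tau_t
  out <- tibble::as_tibble(as.data.frame(G$states))
  out$tau <- tau
  out$absorbing <- G$absorbing
  structure(out, class = c("ml_fpt", class(out)), residual = resid)
}

#' Distribution over absorbing states reached first
#'
#' Forward (adjoint) formulation of the first-passage location problem: given
#' an initial distribution over transient states, returns the probability of
#' first hitting each individual absorbing state. This is the per-state
#' refinement of [hitting_probabilities()].
#'
#' @param G An `ml_generator` with a nonempty absorbing set.
#' @param init Either a single state (integer vector) or a tibble/data frame
#'   of states with a `prob` column.
#' @return A tibble: absorbing state coordinates with their hitting
#'   probability `prob`; attribute `residual`.
#' @export
absorption_distribution <- function(G, init) {
  bl <- gen_blocks(G)
  if (length(bl$ab) == 0) stop("absorbing set is empty")
  p <- numeric(nrow(G$states))
  if (is.numeric(init) && is.null(dim(init))) {
    p[G$map$encode(as.integer(round(init)))] <- 1
  } else {
    init <- as.data.frame(init)
    cols <- paste0("N", seq_len(G$net$n_species))
    p[G$map$encode(as.matrix(init[, cols]))] <- init$prob
  }
  if (abs(sum(p) - 1) > 1e-8) stop("initial distribution must sum to 1")
  if (any(p[bl$ab] > 0)) stop("initial distribution puts mass on absorbing states")
  w <- as.numeric(Matrix::solve(Matrix::t(bl$Qtt), -p[bl$tr]))
  m <- as.numeric(Matrix::t(bl$Qta) %*% w)
  out <- tibble::as_tibble(as.data.frame(G$states[bl$ab, , drop = FALSE]))
  out$prob <- m
  structure(out, residual = abs(sum(m) - 1))
}

#' Conditional second-extinction densities
#'
#' Conditioned on species 3 going extinct first, the remaining two species
#' form a two-dimensional competitive subsystem on the plane `N_3 = 0`
#' (species 1 killed by species 2 at rate `alpha/omega` per pair, species 2
#' by species 1 at `beta/omega`). Starting from an entry distribution over
#' that plane, this solves the two-species first-passage location problem
#' with absorbing boundaries `N_1 = 0` and `N_2 = 0` and returns (i) the
#' density of `N_1` at the moment species 2 goes extinct and (ii) the
#' density of `N_2` at the moment species 1 goes extinct. The two total
#' masses (the conditional probabilities of who goes extinct second) sum to
#' one.
#'
#' @param params A [minimal_params()] object.
#' @param entry Entry distribution over `{N_3 = 0, N_1 >= 1, N_2 >= 1}`: a
#'   data frame with columns `N1`, `N2`, `prob`, or `NULL` to compute it
#'   from the three-dimensional problem started at `init3`.
#' @param init3 Initial state of the three-dimensional problem used when
#'   `entry` is `NULL` (default `round(omega/3) * (1,1,1)`).
#' @param n_max Truncation level (default `2 * omega`).
#' @return An object of class `ml_second_extinction`: list with tibbles
#'   `species2_extinct` (`N1`, `prob`) and `species1_extinct` (`N2`,
#'   `prob`), the named `masses` vector, and the `entry` distribution used.
#' @export
conditional_second_extinction <- function(params, entry = NULL, init3 = NULL,
                                          n_max = NULL) {
  stopifnot(inherits(params, "minimal_params"))
  if (is.null(n_max)) n_max <- ceiling(2 * params$omega)
  if (is.null(entry)) {
    net3 <- build_minimal_network(params)
    G3 <- build_generator(net3, n_max, absorbing = "any_zero")
    if (is.null(init3)) init3 <- rep(round(params$omega / 3), 3)
    hit3 <- absorption_distribution(G3, init3)
    entry <- dplyr::filter(hit3, .data$N3 == 0L, .data$N1 >= 1L,
                           .data$N2 >= 1L)
    entry$prob <- entry$prob / sum(entry$prob)
  }
  entry <- as.data.frame(entry)
  if (abs(sum(entry$prob) - 1) > 1e-8 || any(entry$N1 < 1) ||
      any(entry$N2 < 1)) {
    stop("entry distribution must sum to 1 over states with N1, N2 >= 1")
  }
  net2 <- two_species_subnet(params)
  G2 <- build_generator(net2, n_max, absorbing = "any_zero")
  hit2 <- absorption_distribution(G2, entry[, c("N1", "N2", "prob")])
  d2 <- dplyr::filter(hit2, .data$N2 == 0L, .data$N1 >= 1L)[, c("N1", "prob")]
  d1 <- dplyr::filter(hit2, .data$N1 == 0L, .data$N2 >= 1L)[, c("N2", "prob")]
  structure(list(
    species2_extinct = tibble::as_tibble(d2),
    species1_extinct = tibble::as_tibble(d1),
    masses = c(species2_second = sum(d2$prob),
               species1_second = sum(d1$prob)),
    entry = tibble::as_tibble(entry)
  ), class = "ml_second_extinction")
}

#' @export
print.ml_second_extinction <- function(x, ...) {
  cat("<conditional second-extinction densities | species 3 extinct first>\n")
  cat("  P(species 2 extinct second) =", format(x$masses[1], digits = 6), "\n")
  cat("  P(species 1 extinct second) =", format(x$masses[2], digits = 6), "\n")
  invisible(x)
}

#' Stationary distribution of a truncated chain
#'
#' Computes the probability vector annihilated by the adjoint of the
#' generator, normalised and componentwise nonnegative. The chain is first
#' restricted to the set reachable from `init` (when given); the stationary
#' distribution is supported on the unique closed communicating class of
#' that restriction. If several closed classes are reachable the problem is
#' ambiguous and an error is raised.
#'
#' @param G An `ml_generator` built with `absorbing = "none"` (states with
#'   no enabled reaction, such as the origin of the general-variance model,
#'   are naturally absorbing).
#' @param init Optional initial state (integer vector) selecting the
#'   communicating structure.
#' @return A tibble: all lattice states with their stationary probability
#'   `prob` (zero off the closed class); attribute `residual` (maximum
#'   absolute adjoint residual).
#' @export
stationary_distribution <- function(G, init = NULL) {
  if (any(G$absorbing)) {
    warning("generator was built with explicit absorbing states; ",
            "stationary analysis treats their zero rows as natural")
  }
  n <- nrow(G$Q)
  g <- igraph::graph_from_adjacency_matrix(
    G$Q != 0 & !Matrix::Diagonal(n, TRUE), mode = "directed")
  keep <- seq_len(n)
  if (!is.null(init)) {
    v0 <- G$map$encode(as.integer(round(init)))
    keep <- sort(as.integer(igraph::subcomponent(g, v0, mode = "out")))
  }
  gs <- igraph::induced_subgraph(g, keep)
  comp <- igraph::components(gs, mode = "strong")$membership
  el <- igraph::as_edgelist(gs, names = FALSE)
  open_classes <- unique(comp[el[, 1]][comp[el[, 1]] != comp[el[, 2]]])
  closed <- setdiff(unique(comp), open_classes)
  if (length(closed) != 1) {
    stop("ambiguous stationary distribution: ", length(closed),
         " closed communicating classes are reachable",
         if (is.null(init)) " (supply an initial state)" else "")
  }
  cls <- keep[comp == closed]
  prob <- numeric(n)
  if (length(cls) == 1L) {
    prob[cls] <- 1
    resid <- 0
  } else {
    Qc <- Matrix::t(G$Q[cls, cls, drop = FALSE])
    b <- c(rep(0, length(cls) - 1L), 1)
    Qc[length(cls), ] <- 1
    pc <- as.numeric(Matrix::solve(Qc, b))
    resid <- max(abs(Matrix::t(G$Q[cls, cls, drop = FALSE]) %*% pc))
    if (min(pc) < -1e-8) {
      stop("numerically ambiguous null space (min component ",
           format(min(pc)), ", residual ", format(resid), ")")
    }
    pc[pc < 0] <- 0
    prob[cls] <- pc / sum(pc)
  }
  out <- tibble::as_tibble(as.data.frame(G$states))
  out$prob <- prob
  structure(out, residual = resid)
}

#' Initial state along the corner-to-centre segment
#'
#' The segment joining the single-species corner `(omega, 0, 0)` to the
#' symmetric point `(omega/3)(1,1,1)`, parameterised by `s` in `[0, 1]`:
#' `[omega(1-s) + omega*s/3, omega*s/3, omega*s/3]`, rounded componentwise
#' to the nearest integer.
#'
#' @param s Segment parameter in `[0, 1]`.
#' @param omega System size.
#' @return Integer 3-vector.
#' @export
segment_initial_state <- function(s, omega) {
  if (s < 0 || s > 1) stop("s must lie in [0, 1]")
  as.integer(round(c(omega * (1 - s) + omega * s / 3,
                     omega * s / 3, omega * s / 3)))
}

#' Restrict a per-state field to a lattice plane
#'
#' Keeps the rows of a per-state field (e.g. a mean-absorption-time table)
#' whose coordinates satisfy `N_1 + ... + N_d = plane_sum`. The default
#' plane is the simplex through the single-species carrying-capacity
#' corners, `sum = omega`.
#'
#' @param field A data frame with state coordinate columns `N1`, `N2`, ...
#' @param plane_sum Required coordinate sum.
#' @return The restricted field (same columns).
#' @export
plane_slice <- function(field, plane_sum) {
  cols <- grep("^N\\d+$", names(field), value = TRUE)
  tot <- Reduce(`+`, lapply(cols, function(k) field[[k]]))
  out <- field[tot == plane_sum, , drop = FALSE]
  if (nrow(out) == 0) stop("the plane does not intersect the lattice")
  out
}
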