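#' Integrate the deterministic mean-field equations
#'
#' Solves the mean-field ODE system of the chosen model with a stiff-capable
#' integrator (`deSolve::ode`, lsoda). Heteroclinic trajectories approach the
#' coordinate planes exponentially, so components may be clamped at zero when
#' evaluating the right-hand side; reported values never fall below `-atol`.
#'
#' @param params An `ml_params` object.
#' @param init Nonnegative real 3-vector of initial populations (extensive
#'   counts, or intensive fractions if `omega = 1`).
#' @param t_max Duration of integration (> 0).
#' @param rtol,atol Relative and absolute tolerances.
#' @param n_out Number of equally spaced output points (default scales with
#'   `t_max`, at least 1001).
#' @return A tibble of class `ml_ode` with columns `t`, `N1`, `N2`, `N3` and
#'   attributes `params`, `rtol`, `atol`.
#' @export
integrate_meanfield <- function(params, init, t_max, rtol = 1e-8,
                                atol = 1e-10, n_out = NULL) {
  stopifnot(inherits(params, "ml_params"))
  if (t_max <= 0) stop("t_max must be positive")
  if (length(init) != 3 || any(init < 0)) {
    stop("initial point must be a nonnegative 3-vector")
  }
  if (is.null(n_out)) {
    n_out <- min(200001L, max(1001L, as.integer(round(100 * t_max)) + 1L))
  }
  times <- seq(0, t_max, length.out = n_out)
  rhs <- function(t, y, p) list(drift_raw(params, pmax(y, 0)))
  out <- deSolve::ode(y = c(N1 = init[1], N2 = init[2], N3 = init[3]),
                      times = times, func = rhs, parms = NULL,
                      rtol = rtol, atol = atol)
  out <- as.data.frame(out)
  if (nrow(out) < n_out || !is.finite(out$N1[nrow(out)])) {
    last_t <- out$time[max(which(stats::complete.cases(out)))]
    stop("integration failed; last valid time ", format(last_t))
  }
  traj <- tibble::tibble(t = out$time, N1 = out$N1, N2 = out$N2, N3 = out$N3)
  structure(traj,
            class = c("ml_ode", class(traj)),
            params = params, rtol = rtol, atol = atol)
}

#' Orientation of passage through the Poincare sections
#'
#' Each section `P_i` is the triangle with vertices `(0,0,0)`,
#' `(omega,omega,omega)` and `omega*e_i`. The valid crossing direction is
#' fixed once per model by evaluating the mean-field drift at the section
#' centroid `(omega/2)(1,1,1) + (omega/4) e_i` and taking the sign of the
#' flux `d(N_{i+1} - N_{i+2})/dt` through the plane; by cyclic symmetry the
#' sign is common to all three sections.
#'
#' @param params An `ml_params` object.
#' @return `+1` or `-1`.
#' @export
section_orientation <- function(params) {
  w <- params$omega
  p <- rep(w / 2, 3) + (w / 4) * c(1, 0, 0)
  d <- drift_raw(params, p)
  s <- sign(d[2] - d[3])
  if (s == 0) stop("degenerate flux through the section centroid")
  as.integer(s)
}

# refine a bracketed zero of D_j(t) using local spline interpolation
refine_crossing <- function(tt, D, i, window = 4L) {
  lo <- max(1L, i - window)
  hi <- min(length(tt), i + 1L + window)
  f <- stats::splinefun(tt[lo:hi], D[lo:hi])
  stats::uniroot(f, lower = tt[i], upper = tt[i + 1], tol = 1e-13)$root
}

#' Section passage times of a continuous trajectory
#'
#' Detects crossings of the three Poincare sections by interpolated sign
#' changes of `N_{i+1} - N_{i+2}` (not step endpoints), keeping only
#' crossings in the model's orientation (see [section_orientation()]) that
#' lie inside the section triangle, i.e. satisfy
#' `N_i >= (N_{i+1} + N_{i+2})/2` at the crossing point. Consecutive events
#' on the same section are collapsed to the first.
#'
#' @param traj An `ml_ode` trajectory from [integrate_meanfield()].
#' @param omega System size (defaults to the trajectory's parameter set).
#' @return An object of class `ml_cycle_times`: a list with `events` (tibble
#'   `section`, `time`), `durations` (successive differences of passage
#'   times) and `circuits` (durations of completed circuits returning to the
#'   first section visited after passing through both others).
#' @export
section_passage_times <- function(traj, omega = NULL) {
  params <- attr(traj, "params")
  if (is.null(omega) && !is.null(params)) omega <- params$omega
  orient <- if (!is.null(params)) section_orientation(params) else 0L
  tt <- traj$t
  X <- cbind(traj$N1, traj$N2, traj$N3)
  interp <- lapply(1:3, function(k) stats::splinefun(tt, X[, k]))
  events <- list()
  for (j in 1:3) {
    jp <- cyc(j, 1)
    jq <- cyc(j, 2)
    D <- X[, jp] - X[, jq]
    s <- sign(D)
    idx <- which(s[-length(s)] * s[-1] < 0)
    for (i in idx) {
      tc <- refine_crossing(tt, D, i)
      y <- vapply(interp, function(f) f(tc), numeric(1))
      if (orient != 0 && sign(s[i + 1]) != orient) next
      if (y[j] < (y[jp] + y[jq]) / 2) next
      events[[length(events) + 1L]] <- c(section = j, time = tc)
    }
  }
  if (length(events) == 0) {
    warning("no section crossings found")
    ev <- tibble::tibble(section = integer(), time = numeric())
  } else {
    ev <- dplyr::arrange(tibble::tibble(
      section = vapply(events, `[[`, numeric(1), "section"),
      time = vapply(events, `[[`, numeric(1), "time")
    ), .data$time)
    keep <- c(TRUE, diff(ev$section) != 0)
    ev <- ev[keep, ]
  }
  new_cycle_times(ev)
}

new_cycle_times <- function(ev) {
  structure(list(
    events = ev,
    durations = diff(ev$time),
    circuits = circuit_durations(ev$section, ev$time)
  ), class = "ml_cycle_times")
}

# reduce a sequence of section visits to completed-circuit durations,
# anchored at the first section visited
circuit_durations <- function(sec, tt) {
  if (length(sec) < 4) return(numeric())
  anchor <- sec[1]
  t_anchor <- tt[1]
  seen <- logical(3)
  out <- numeric()
  for (i in seq_along(sec)[-1]) {
    if (sec[i] == anchor) {
      if (all(seen[-anchor])) out <- c(out, tt[i] - t_anchor)
      t_anchor <- tt[i]
      seen[] <- FALSE
    }
    seen[sec[i]] <- TRUE
  }
  out
}

#' @export
print.ml_cycle_times <- function(x, ...) {
  cat("<section passage record: ", nrow(x$events), " events, ",
      length(x$circuits), " completed circuits>\n", sep = "")
  if (length(x$circuits)) {
    cat("  circuit durations:",
        paste(format(x$circuits, digits = 6), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Deterministic oscillation period of the three-pool model
#'
#' Integrates the three-pool mean-field equations until successive
#' full-circuit return times to the first-visited section agree to a
#' relative tolerance, discarding the transient. With `mu = 0` the model is a
#' rescaled May-Leonard system whose cycling is heteroclinic (cycle durations
#' grow without bound), so no finite period exists and an error is raised.
#'
#' @param params A [three_pool_params()] object with `mu > 0`.
#' @param rtol Relative convergence tolerance between successive circuit
#'   durations.
#' @param init Initial point (default `omega * (1, 0.8, 0.2)`).
#' @param max_t Maximum integration time before giving up.
#' @return The period (time units), with attribute `"n_circuits"`.
#' @export
deterministic_period <- function(params, rtol = 1e-6, init = NULL,
                                 max_t = 5000) {
  stopifnot(inherits(params, "ml_params"))
  if (inherits(params, "three_pool_params") && params$mu == 0) {
    stop("mu = 0: heteroclinic regime, no finite period exists")
  }
  w <- params$omega
  if (is.null(init)) init <- w * c(1, 0.8, 0.2)
  t_max <- 200 * if (inherits(params, "three_pool_params")) params$tau else 1
  repeat {
    traj <- integrate_meanfield(params, init, t_max)
    circ <- section_passage_times(traj)$circuits
    n <- length(circ)
    if (n >= 3 &&
        abs(circ[n] - circ[n - 1]) <= rtol * abs(circ[n]) &&
        abs(circ[n - 1] - circ[n - 2]) <= rtol * abs(circ[n])) {
      return(structure(circ[n], n_circuits = n))
    }
    if (t_max >= max_t) {
      stop("period did not converge within t = ", t_max,
           "; last circuit durations: ",
           paste(format(utils::tail(circ, 3), digits = 8), collapse = ", "))
    }
    t_max <- min(2 * t_max, max_t)
  }
}
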