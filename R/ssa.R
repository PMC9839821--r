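#' Exact stochastic simulation (Gillespie direct method)
#'
#' Simulates the continuous-time Markov jump process defined by a reaction
#' network: waiting times are exponential with rate equal to the total
#' propensity and the firing reaction is chosen with probability proportional
#' to its propensity. The simulation is exact (no tau-leaping). Identical
#' `(net, init, t_max, seed)` give identical trajectories.
#'
#' @param net A `reaction_network`.
#' @param init Initial state: nonnegative integer vector (non-integer values
#'   are rounded to the nearest integer componentwise).
#' @param t_max Time horizon (> 0).
#' @param seed Integer seed; if `NULL` the current RNG state is used.
#' @param record Keep the full jump path? If `FALSE`, only the initial and
#'   final states are stored (summaries such as extinction times, section
#'   visits and cycle lengths are still tracked).
#' @param stop Early-stopping rule: `"none"`, `"first_extinction"` (stop at
#'   the first jump at which any species count reaches 0), or `"cycles"`
#'   (stop once `max_cycles` completed circuits have been observed).
#' @param detect_crossings Track Poincare-section visits and cycle lengths
#'   (3-species networks only; implied by `stop = "cycles"`).
#' @param max_cycles Number of completed circuits at which to stop when
#'   `stop = "cycles"`.
#' @param max_steps Safety cap on the number of jumps.
#' @return A tibble of class `ml_trajectory` with columns `t`, `N1`, ...
#'   (event times; states are right-continuous step functions) and attributes
#'   `terminal` (one of `"t_max"`, `"absorbed"`, `"stop_predicate"`,
#'   `"max_steps"`), `t_end`, `n_jumps`, `seed`, `extinctions` (first time
#'   each species reached 0, `NA` if never), `crossings` (tibble of section
#'   visits), `cycles` (completed circuit durations), `final` and `params`.
#' @export
gillespie <- function(net, init, t_max, seed = NULL, record = TRUE,
                      stop = c("none", "first_extinction", "cycles"),
                      detect_crossings = NULL, max_cycles = 1000000L,
                      max_steps = 1e9) {
  stopifnot(inherits(net, "reaction_network"))
  stop <- match.arg(stop)
  init <- as.integer(round(init))
  check_state(net, init)
  if (t_max <= 0) stop("t_max must be positive")
  if (is.null(detect_crossings)) {
    detect_crossings <- net$n_species == 3L && (record || stop == "cycles")
  }
  detect_crossings <- detect_crossings && net$n_species == 3L
  if (stop == "cycles") detect_crossings <- TRUE
  orient <- if (detect_crossings) section_orientation(net$params) else 0L
  if (!is.null(seed)) set.seed(seed)
  res <- ssa_core(net$S, net$Rct, net$Cmp, net$rate,
                  as.numeric(net$omega %||% 0), init, t_max,
                  record, switch(stop, none = 0L, first_extinction = 1L,
                                 cycles = 2L),
                  detect_crossings, orient, as.integer(max_cycles),
                  max_steps)
  as_ml_trajectory(res, net, init, seed, record)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_ml_trajectory <- function(res, net, init, seed, record) {
  ns <- net$n_species
  nm <- paste0("N", seq_len(ns))
  if (record) {
    df <- tibble::as_tibble(stats::setNames(
      c(list(res$times), lapply(seq_len(ns), function(k) res$states[, k])),
      c("t", nm)))
  } else {
    df <- tibble::as_tibble(stats::setNames(
      c(list(c(0, res$t_end)),
        lapply(seq_len(ns), function(k) c(init[k], res$final[k]))),
      c("t", nm)))
  }
  terminal <- c("t_max", "absorbed", "stop_predicate",
                "max_steps")[res$reason + 1L]
  if (terminal == "max_steps") {
    warning("simulation stopped at max_steps before reaching t_max")
  }
  structure(df,
            class = c("ml_trajectory", class(df)),
            model = net$model, params = net$params, seed = seed,
            recorded = record, terminal = terminal, t_end = res$t_end,
            n_jumps = res$n_jumps, final = res$final,
            extinctions = stats::setNames(res$extinction, nm),
            crossings = tibble::tibble(section = res$ev_sec,
                                       time = res$ev_t),
            cycles = res$cycles)
}

#' Extinction record of a jump trajectory
#'
#' For each species, the first time its count reaches zero. Species that
#' never reach zero are omitted. Uses the times tracked during simulation
#' when available, otherwise recomputes them from the recorded path.
#'
#' @param traj An `ml_trajectory`.
#' @return A tibble of class `ml_extinctions` with columns `species`, `time`,
#'   ordered by time, and attribute `survivors` (species indices whose count
#'   never reached zero).
#' @export
extinction_events <- function(traj) {
  ext <- attr(traj, "extinctions")
  if (is.null(ext)) {
    nm <- grep("^N\\d+$", names(traj), value = TRUE)
    ext <- vapply(nm, function(k) {
      i <- which(traj[[k]] == 0)
      if (length(i)) traj$t[i[1]] else NA_real_
    }, numeric(1))
  }
  idx <- unname(which(!is.na(ext)))
  out <- tibble::tibble(species = idx, time = unname(ext[idx]))
  out <- dplyr::arrange(out, .data$time)
  structure(out, class = c("ml_extinctions", class(out)),
            survivors = unname(which(is.na(ext))))
}

#' Poincare-section crossings of a jump trajectory
#'
#' Applies the discrete crossing rule to a recorded path: a visit to section
#' `P_i` occurs at a jump where `D_i = N_{i+1} - N_{i+2}` changes sign in the
#' model's orientation (ties `D_i = 0` are attributed to the side being
#' left), subject to `N_i >= max(N_{i+1}, N_{i+2})` so that only the
#' section's triangle counts, and only when the section differs from the one
#' currently occupied. Completed circuits (returns to the first-visited
#' section after passing through both others) are reduced to cycle lengths.
#'
#' @param traj An `ml_trajectory` over 3 species (any data frame with
#'   columns `t`, `N1`, `N2`, `N3` is accepted).
#' @param omega System size; must match the network's bound when bounded.
#' @param use_recorded Recompute from the recorded path (`TRUE`) rather than
#'   using the crossing record tracked during simulation.
#' @param orientation Crossing orientation override: `+1`, `-1` or `0`
#'   (either direction). Defaults to [section_orientation()] of the
#'   trajectory's parameter set, or `0` for bare data frames.
#' @return An `ml_cycle_times` object (see [section_passage_times()]).
#' @export
section_crossings <- function(traj, omega = NULL, use_recorded = FALSE,
                              orientation = NULL) {
  params <- attr(traj, "params")
  if (!is.null(omega) && !is.null(params) &&
      !is.null(params$omega) && inherits(params, "three_pool_params") &&
      omega != params$omega) {
    stop("omega does not match the network bound")
  }
  cr <- attr(traj, "crossings")
  if (!use_recorded && is.null(orientation) && !is.null(cr) && nrow(cr) > 0) {
    return(new_cycle_times(cr))
  }
  if (!all(c("N1", "N2", "N3") %in% names(traj))) {
    stop("crossing detection requires a 3-species trajectory")
  }
  orient <- if (!is.null(orientation)) as.integer(orientation)
            else if (!is.null(params)) section_orientation(params) else 0L
  X <- cbind(traj$N1, traj$N2, traj$N3)
  res <- crossings_path(X, traj$t, orient)
  new_cycle_times(tibble::tibble(section = res$ev_sec, time = res$ev_t))
}

#' Seeded ensembles of stochastic simulations
#'
#' Runs `n_reps` independent trajectories with per-replicate seeds
#' `base_seed + k`, so results are reproducible and independent of execution
#' order. Per-replicate reductions (extinction times and ordering, completed
#' cycle lengths, final state) are returned as one tibble row per replicate;
#' failed replicates are flagged in the `ok` column rather than dropped.
#'
#' @inheritParams gillespie
#' @param n_reps Number of replicates (>= 1).
#' @param base_seed Integer base seed.
#' @param reduce Which reductions to keep: any of `"extinction"`, `"cycles"`.
#'   The final state and terminal reason are always kept.
#' @param ... Passed on to [gillespie()] (e.g. `stop`, `max_cycles`).
#' @return A tibble with one row per replicate: `rep`, `seed`, `ok`,
#'   `terminal`, `t_end`, `n_jumps`, final counts, and depending on `reduce`:
#'   `t_ext1..3`, `first_extinct`, `t_first_extinct`, `survivor`, and/or
#'   `n_cycles` plus a `cycles` list-column.
#' @export
ensemble <- function(net, init, n_reps, t_max, base_seed,
                     reduce = c("extinction"),
                     stop = c("none", "first_extinction", "cycles"),
                     max_cycles = 1000000L, max_steps = 1e9) {
  stopifnot(inherits(net, "reaction_network"), n_reps >= 1)
  reduce <- match.arg(reduce, c("extinction", "cycles"), several.ok = TRUE)
  stop <- match.arg(stop)
  init <- as.integer(round(init))
  check_state(net, init)
  ns <- net$n_species
  detect <- ("cycles" %in% reduce || stop == "cycles") && ns == 3L
  orient <- if (detect) section_orientation(net$params) else 0L
  stop_code <- switch(stop, none = 0L, first_extinction = 1L, cycles = 2L)
  terminal_lvls <- c("t_max", "absorbed", "stop_predicate", "max_steps")

  ok <- logical(n_reps)
  terminal <- character(n_reps)
  errors <- character(n_reps)
  t_end <- n_jumps <- numeric(n_reps)
  fin <- matrix(NA_integer_, n_reps, ns)
  ext <- matrix(NA_real_, n_reps, ns)
  cyc_list <- if ("cycles" %in% reduce) vector("list", n_reps)
  omega_num <- as.numeric(net$omega %||% 0)

  for (k in seq_len(n_reps)) {
    set.seed(base_seed + k)
    res <- tryCatch(
      ssa_core(net$S, net$Rct, net$Cmp, net$rate, omega_num, init, t_max,
               FALSE, stop_code, detect, orient, as.integer(max_cycles),
               max_steps),
      error = function(e) e)
    if (inherits(res, "error")) {
      ok[k] <- FALSE
      errors[k] <- conditionMessage(res)
      terminal[k] <- NA_character_
      next
    }
    ok[k] <- TRUE
    terminal[k] <- terminal_lvls[res$reason + 1L]
    t_end[k] <- res$t_end
    n_jumps[k] <- res$n_jumps
    fin[k, ] <- res$final
    ext[k, ] <- res$extinction
    if ("cycles" %in% reduce) cyc_list[[k]] <- res$cycles
  }

  out <- tibble::tibble(rep = seq_len(n_reps),
                        seed = base_seed + seq_len(n_reps),
                        ok = ok, terminal = terminal,
                        t_end = t_end, n_jumps = n_jumps)
  if (any(!ok)) out$error <- ifelse(ok, NA_character_, errors)
  for (s in seq_len(ns)) out[[paste0("final", s)]] <- fin[, s]
  if ("extinction" %in% reduce) {
    for (s in seq_len(ns)) out[[paste0("t_ext", s)]] <- ext[, s]
    n_ext <- rowSums(!is.na(ext))
    out$first_extinct <- vapply(seq_len(n_reps), function(k) {
      if (n_ext[k] == 0) NA_integer_ else which.min(ext[k, ])
    }, integer(1))
    out$t_first_extinct <- vapply(seq_len(n_reps), function(k) {
      if (n_ext[k] == 0) NA_real_ else min(ext[k, ], na.rm = TRUE)
    }, numeric(1))
    out$survivor <- vapply(seq_len(n_reps), function(k) {
      if (n_ext[k] == ns - 1L) which(is.na(ext[k, ]))[1] else NA_integer_
    }, integer(1))
  }
  if ("cycles" %in% reduce) {
    out$n_cycles <- lengths(cyc_list)
    out$cycles <- cyc_list
  }
  out
}

#' Summarise numeric ensemble reductions
#'
#' Mean, variance and standard error of every numeric reduction column of an
#' [ensemble()] table, across successful replicates.
#'
#' @param ens A tibble returned by [ensemble()].
#' @return A tibble with columns `quantity`, `n`, `mean`, `var`, `se`.
#' @export
summarise_ensemble <- function(ens) {
  ens <- dplyr::filter(ens, .data$ok)
  num <- setdiff(names(ens)[vapply(ens, is.numeric, logical(1))],
                 c("rep", "seed"))
  purrr::map_dfr(num, function(nm) {
    x <- ens[[nm]]
    x <- x[!is.na(x)]
    tibble::tibble(quantity = nm, n = length(x), mean = mean(x),
                   var = stats::var(x),
                   se = stats::sd(x) / sqrt(length(x)))
  })
}

#' Write a trajectory and its metadata to disk
#'
#' The trajectory is written as CSV with header `t,N1,N2,N3` (event times;
#' states are right-continuous step functions) and a JSON sidecar records the
#' model, parameters, seed and terminal reason.
#'
#' @param traj An `ml_trajectory`.
#' @param path CSV output path; the sidecar is written next to it with
#'   extension `.json`.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.csv(as.data.frame(traj)[, c("t", grep("^N\\d+$", names(traj),
                                                     value = TRUE))],
                   path, row.names = FALSE, quote = FALSE)
  meta <- list(model = attr(traj, "model"),
               params = unclass(attr(traj, "params")),
               seed = attr(traj, "seed"),
               terminal = attr(traj, "terminal"),
               t_end = attr(traj, "t_end"),
               n_jumps = attr(traj, "n_jumps"))
  jsonlite::write_json(meta, sub("\\.[^.]*$", ".json", path),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
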