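#' Truncated Poisson stationary law of the surviving species
#'
#' The minimal model's sole-survivor stationary distribution is a Poisson law
#' with mean `r*omega` conditioned on `N >= 1`:
#' `pi(N) = (r*omega)^N / (N! (exp(r*omega) - 1))`. The probability mass
#' function is evaluated in log space for stability and satisfies the
#' detailed-balance recursion `pi(N+1)/pi(N) = r*omega/(N+1)` exactly.
#'
#' @param r Net growth rate (> 0).
#' @param omega System size (> 0).
#' @param n_max Upper end of the evaluation window; must be large enough
#'   that the neglected tail mass is below `1e-12`.
#' @return A tibble of class `truncated_poisson` with columns `n` (1..n_max)
#'   and `pmf`; attribute `rate` (`r*omega`).
#' @export
truncated_poisson <- function(r, omega, n_max) {
  stopifnot(r > 0, omega > 0, n_max >= 1)
  lambda <- r * omega
  logZ <- lambda + log1p(-exp(-lambda))  # log(exp(lambda) - 1)
  n <- seq_len(n_max)
  pmf <- exp(n * log(lambda) - lfactorial(n) - logZ)
  tail_mass <- stats::ppois(n_max, lambda, lower.tail = FALSE) /
    (-expm1(-lambda))
  if (tail_mass >= 1e-12) {
    stop("n_max too small: neglected tail mass ", format(tail_mass),
         " (need < 1e-12)")
  }
  structure(tibble::tibble(n = n, pmf = pmf),
            class = c("truncated_poisson", class(tibble::tibble())),
            rate = lambda)
}

#' Pearson chi-squared goodness-of-fit with minimum-expected-count binning
#'
#' Compares observed counts on an ordered discrete support against a
#' reference probability mass function. Adjacent support points are merged
#' left to right until every expected count reaches `min_expected` (the
#' classical rule of 5 by default; a trailing underfilled bin is merged into
#' its neighbour). The statistic is referred to a chi-squared law with
#' (number of merged bins - 1) degrees of freedom.
#'
#' @param observed Nonnegative integer counts, aligned with `expected`.
#' @param expected Reference probabilities (or weights; renormalised), same
#'   length as `observed`.
#' @param min_expected Minimum expected count per merged bin.
#' @return A list of class `ml_gof`: `statistic`, `df`, `p.value`, `n`, and
#'   the merged `bins` tibble (`first`, `last`, `observed`, `expected`).
#' @export
chi2_gof <- function(observed, expected, min_expected = 5) {
  if (length(observed) != length(expected)) {
    stop("observed and expected must have the same length")
  }
  if (any(observed < 0) || sum(observed) <= 0) {
    stop("observed counts must be nonnegative with positive total")
  }
  n <- sum(observed)
  e <- n * expected / sum(expected)
  first <- integer(0); last <- integer(0)
  O <- numeric(0); E <- numeric(0)
  acc_o <- 0; acc_e <- 0; start <- 1L
  for (i in seq_along(observed)) {
    acc_o <- acc_o + observed[i]
    acc_e <- acc_e + e[i]
    if (acc_e >= min_expected || i == length(observed)) {
      first <- c(first, start); last <- c(last, i)
      O <- c(O, acc_o); E <- c(E, acc_e)
      acc_o <- 0; acc_e <- 0; start <- i + 1L
    }
  }
  k <- length(E)
  if (k >= 2 && E[k] < min_expected) {
    E[k - 1] <- E[k - 1] + E[k]; O[k - 1] <- O[k - 1] + O[k]
    last[k - 1] <- last[k]
    E <- E[-k]; O <- O[-k]; first <- first[-k]; last <- last[-k]
    k <- k - 1L
  }
  if (k < 2) stop("fewer than 2 bins after merging; not enough data")
  stat <- sum((O - E)^2 / E)
  df <- k - 1L
  structure(list(statistic = stat, df = df,
                 p.value = stats::pchisq(stat, df, lower.tail = FALSE),
                 n = n,
                 bins = tibble::tibble(first = first, last = last,
                                       observed = O, expected = E)),
            class = "ml_gof")
}

#' @export
print.ml_gof <- function(x, ...) {
  cat("chi-squared GOF: X2 =", format(x$statistic, digits = 5),
      " df =", x$df, " p =", format(x$p.value, digits = 4),
      " (n =", x$n, ",", nrow(x$bins), "bins)\n")
  invisible(x)
}

#' Rate-limiting-step Gamma approximation of the cycle length
#'
#' In the small-`omega`, small-`mu` regime each leg of a three-pool cycle is
#' dominated by a single endogenous-activation event out of a saturated
#' corner state, with exponential waiting time of rate `omega * mu / tau`.
#' The cycle length, a sum of three such i.i.d. legs, is then Gamma with
#' shape 3 and scale `tau/(mu * omega)`, giving mean `T_a = 3*tau/(omega*mu)`
#' and coefficient of variation `CV_a = 1/sqrt(3)` independent of all
#' parameters.
#'
#' @param tau Time constant (> 0).
#' @param mu Endogenous activation rate (> 0).
#' @param omega Pool size (> 0).
#' @return A named list with `T_a` and `CV_a`.
#' @export
gamma_cycle_approx <- function(tau, mu, omega) {
  stopifnot(tau > 0, mu > 0, omega > 0)
  list(T_a = 3 * tau / (omega * mu), CV_a = 1 / sqrt(3))
}

#' Maximum-likelihood Gamma fit
#'
#' Fits a two-parameter Gamma distribution to positive samples by maximum
#' likelihood (via [MASS::fitdistr()]).
#'
#' @param samples At least 30 positive values with nonzero variance.
#' @return An object of class `ml_gamma_fit`: list with `shape`, `scale`,
#'   `rate`, standard errors, `loglik` and `n`. Supports [tidy()] and
#'   [glance()].
#' @export
fit_gamma <- function(samples) {
  samples <- as.numeric(samples)
  if (length(samples) < 30) stop("need at least 30 samples")
  if (any(samples <= 0)) stop("samples must be positive")
  if (stats::var(samples) == 0) {
    stop("degenerate samples: zero variance, Gamma fit is undefined")
  }
  # optim's exploratory steps can evaluate dgamma at invalid parameters;
  # those NaN warnings are part of normal convergence
  fit <- withCallingHandlers(
    MASS::fitdistr(samples, "gamma"),
    warning = function(w) {
      if (grepl("NaNs produced", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  est <- fit$estimate
  se <- fit$sd
  structure(list(shape = unname(est["shape"]),
                 rate = unname(est["rate"]),
                 scale = 1 / unname(est["rate"]),
                 se_shape = unname(se["shape"]),
                 se_rate = unname(se["rate"]),
                 loglik = fit$loglik, n = length(samples),
                 samples = samples),
            class = "ml_gamma_fit")
}

#' @export
print.ml_gamma_fit <- function(x, ...) {
  cat("Gamma MLE: shape =", format(x$shape, digits = 5),
      "(se", format(x$se_shape, digits = 3), "), scale =",
      format(x$scale, digits = 5), " n =", x$n, "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.ml_gamma_fit <- function(x, ...) {
  tibble::tibble(term = c("shape", "rate"),
                 estimate = c(x$shape, x$rate),
                 std.error = c(x$se_shape, x$se_rate))
}

#' @export
glance.ml_gamma_fit <- function(x, ...) {
  tibble::tibble(shape = x$shape, scale = x$scale, logLik = x$loglik,
                 nobs = x$n)
}

#' @export
glance.ml_gof <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df, p.value = x$p.value,
                 nobs = x$n, n.bins = nrow(x$bins))
}

#' Cycle-length summary statistics
#'
#' Mean, unbiased variance and coefficient of variation of a sample of cycle
#' durations, with standard errors (the CV standard error by the delta
#' method using sample moments; a bootstrap alternative is available). When
#' three-pool parameters are supplied the Gamma rate-limiting approximants
#' `T_a`, `CV_a` of [gamma_cycle_approx()] are attached together with
#' `delta_cv = cv - CV_a`.
#'
#' @param samples At least 2 positive cycle durations.
#' @param params Optional [three_pool_params()] for the approximants.
#' @param se_method `"delta"` or `"bootstrap"`.
#' @param boot_n Bootstrap replicates when `se_method = "bootstrap"`.
#' @return A one-row tibble of class `ml_cycle_stats`: `n`, `mean`,
#'   `se_mean`, `var`, `se_var`, `cv`, `se_cv`, and when `params` is given
#'   `T_a`, `CV_a`, `delta_cv`.
#' @export
cycle_summary <- function(samples, params = NULL,
                          se_method = c("delta", "bootstrap"),
                          boot_n = 1000) {
  se_method <- match.arg(se_method)
  x <- as.numeric(samples)
  n <- length(x)
  if (n < 2) stop("need at least 2 samples")
  m <- mean(x)
  v <- stats::var(x)
  s <- sqrt(v)
  cv <- s / m
  mu3 <- mean((x - m)^3)
  mu4 <- mean((x - m)^4)
  se_mean <- s / sqrt(n)
  se_var <- sqrt(max(mu4 - v^2, 0) / n)
  if (v == 0) {
    se_cv <- 0
  } else if (se_method == "delta") {
    v_m <- v / n
    v_s <- max(mu4 - v^2, 0) / (4 * v * n)
    c_ms <- mu3 / (2 * s * n)
    var_cv <- v_s / m^2 + (v / m^4) * v_m - 2 * (s / m^3) * c_ms
    se_cv <- sqrt(max(var_cv, 0))
  } else {
    cvs <- vapply(seq_len(boot_n), function(i) {
      b <- sample(x, n, replace = TRUE)
      stats::sd(b) / mean(b)
    }, numeric(1))
    se_cv <- stats::sd(cvs)
  }
  out <- tibble::tibble(n = n, mean = m, se_mean = se_mean, var = v,
                        se_var = se_var, cv = cv, se_cv = se_cv)
  if (!is.null(params)) {
    stopifnot(inherits(params, "three_pool_params"))
    ap <- gamma_cycle_approx(params$tau, params$mu, params$omega)
    out$T_a <- ap$T_a
    out$CV_a <- ap$CV_a
    out$delta_cv <- cv - ap$CV_a
  }
  structure(out, class = c("ml_cycle_stats", class(out)))
}

#' Empirical stationary occupancy of the surviving species
#'
#' Runs the minimal model to its sole-survivor regime and estimates the
#' stationary law of the surviving species' count. The trajectory is
#' simulated past the second extinction, a burn-in of ten mean reaction
#' times after that extinction is discarded, and the remaining step function
#' is sampled at regularly spaced clock times (an unbiased discretisation of
#' the time-weighted occupancy; the spacing should exceed the chain's
#' relaxation time `1/r` so the sampled counts are approximately
#' independent).
#'
#' @param params A [minimal_params()] object.
#' @param init Initial state (default `round(omega/3)` per species, with a
#'   floor of one individual).
#' @param t_max Total simulated time.
#' @param seed Integer seed.
#' @param spacing Clock-time spacing between samples (default `5/r`).
#' @return A list of class `ml_occupancy`: `counts` (tibble `n`, `count` for
#'   the surviving species), `survivor`, `n_samples`, `t_settle` (end of
#'   burn-in), and the trajectory's terminal time.
#' @export
stationary_occupancy <- function(params, init = NULL, t_max = 1e4,
                                 seed = NULL, spacing = NULL) {
  stopifnot(inherits(params, "minimal_params"))
  if (is.null(init)) init <- pmax(rep(round(params$omega / 3), 3), 1)
  if (is.null(spacing)) spacing <- 5 / params$r
  net <- build_minimal_network(params)
  tr <- gillespie(net, init, t_max, seed = seed, record = TRUE,
                  detect_crossings = FALSE)
  ext <- attr(tr, "extinctions")
  if (sum(!is.na(ext)) != 2) {
    stop("trajectory did not reach the sole-survivor regime within t_max")
  }
  survivor <- which(is.na(ext))
  t2 <- max(ext, na.rm = TRUE)
  # burn-in: ten mean reaction times after the second extinction
  after <- tr$t > t2
  mean_dt <- (attr(tr, "t_end") - t2) / max(sum(after), 1)
  t_settle <- t2 + 10 * mean_dt
  t_samp <- seq(t_settle, attr(tr, "t_end"), by = spacing)
  nvals <- tr[[paste0("N", survivor)]]
  idx <- findInterval(t_samp, tr$t)
  samples <- nvals[idx]
  tab <- table(factor(samples, levels = 0:max(samples)))
  structure(list(
    counts = tibble::tibble(n = as.integer(names(tab)),
                            count = as.integer(tab)),
    survivor = survivor, n_samples = length(samples),
    t_settle = t_settle, t_end = attr(tr, "t_end")
  ), class = "ml_occupancy")
}

#' Test the sole-survivor occupancy against the truncated Poisson law
#'
#' Convenience pipeline: estimate the surviving-species occupancy with
#' [stationary_occupancy()] and compare it against the analytic truncated
#' Poisson stationary distribution with [chi2_gof()].
#'
#' @inheritParams stationary_occupancy
#' @param n_max Support window for the reference law (default large enough
#'   for a negligible tail).
#' @param min_expected Binning threshold passed to [chi2_gof()].
#' @return An `ml_gof` object with the occupancy attached as attribute
#'   `"occupancy"`.
#' @export
check_survivor_stationary <- function(params, init = NULL, t_max = 1e4,
                                      seed = NULL, spacing = NULL,
                                      n_max = NULL, min_expected = 5) {
  occ <- stationary_occupancy(params, init = init, t_max = t_max,
                              seed = seed, spacing = spacing)
  lambda <- params$r * params$omega
  if (is.null(n_max)) {
    n_max <- max(ceiling(lambda + 12 * sqrt(lambda) + 30),
                 max(occ$counts$n))
  }
  ref <- truncated_poisson(params$r, params$omega, n_max)
  obs <- integer(n_max)
  nonzero <- occ$counts[occ$counts$n >= 1, ]
  obs[nonzero$n] <- nonzero$count
  gof <- chi2_gof(obs, ref$pmf, min_expected = min_expected)
  attr(gof, "occupancy") <- occ
  gof
}
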