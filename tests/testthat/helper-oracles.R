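# Independent oracles used across the test files. These deliberately avoid
# the package's vectorised propensity code and C++ simulation loop.

# longhand propensities, written directly from the reaction rate laws
oracle_prop_gv <- function(p, N) {
  w <- p$omega
  out <- numeric(0)
  for (i in 1:3) {
    ip <- i %% 3 + 1
    iq <- ip %% 3 + 1
    out <- c(out,
             p$b * N[i],
             p$d * N[i],
             (2 / w) * N[i] * (N[i] - 1) / 2,
             (p$alpha / w) * N[i] * N[ip],
             (p$beta / w) * N[i] * N[iq])
  }
  out
}

oracle_prop_minimal <- function(p, N) {
  w <- p$omega
  out <- numeric(0)
  for (i in 1:3) {
    ip <- i %% 3 + 1
    iq <- ip %% 3 + 1
    out <- c(out,
             p$r * N[i],
             (2 / w) * N[i] * (N[i] - 1) / 2,
             (p$alpha / w) * N[i] * N[ip],
             (p$beta / w) * N[i] * N[iq])
  }
  out
}

oracle_prop_threepool <- function(p, N) {
  w <- p$omega
  M <- w - N
  out <- numeric(0)
  for (i in 1:3) {
    ip <- i %% 3 + 1
    out <- c(out,
             N[i] * M[i] / (p$tau * w),
             p$gamma * N[i] * N[ip] / (p$tau * w),
             p$mu * M[i] / p$tau)
  }
  out
}

# reference Gillespie in pure R, consuming the RNG stream in the same order
# as the compiled core (one exponential, one uniform per jump)
r_gillespie <- function(net, init, t_max, seed) {
  set.seed(seed)
  N <- as.integer(init)
  t <- 0
  path <- list(c(0, N))
  repeat {
    a <- propensities(net, N)
    a0 <- sum(a)
    if (a0 <= 0) break
    dt <- stats::rexp(1) / a0
    if (t + dt > t_max) break
    t <- t + dt
    j <- findInterval(stats::runif(1) * a0, cumsum(a), left.open = TRUE) + 1L
    N <- N + net$S[j, ]
    path[[length(path) + 1L]] <- c(t, N)
  }
  do.call(rbind, path)
}

# naive R implementation of the discrete section-visit rule, independent of
# the C++ detector
r_crossings <- function(X, tt, orient) {
  sgn <- sign(X[1, c(2, 3, 1)] - X[1, c(3, 1, 2)])
  cur <- -1L
  ev_sec <- integer(0)
  ev_t <- numeric(0)
  for (j in 1:3) {
    jp <- j %% 3 + 1
    jq <- jp %% 3 + 1
    if (X[1, jp] == X[1, jq] && X[1, j] >= X[1, jp]) {
      ev_sec <- c(ev_sec, j)
      ev_t <- c(ev_t, tt[1])
      cur <- j
      break
    }
  }
  for (i in seq_len(nrow(X))[-1]) {
    for (j in 1:3) {
      jp <- j %% 3 + 1
      jq <- jp %% 3 + 1
      D <- X[i, jp] - X[i, jq]
      s <- sign(D)
      if (s != 0) {
        if (sgn[j] != 0 && s != sgn[j] && (orient == 0 || s == orient) &&
            X[i, j] >= max(X[i, jp], X[i, jq]) && j != cur) {
          ev_sec <- c(ev_sec, j)
          ev_t <- c(ev_t, tt[i])
          cur <- j
        }
        sgn[j] <- s
      }
    }
  }
  list(section = ev_sec, time = ev_t)
}

# one corner-to-corner revolution of the lattice triangle, by unit steps
revolution_path <- function(omega, n_rev = 1) {
  legs <- function() {
    rbind(
      cbind(omega, 1:omega, 0),            # raise N2
      cbind((omega - 1):0, omega, 0),      # lower N1
      cbind(0, omega, 1:omega),            # raise N3
      cbind(0, (omega - 1):0, omega),      # lower N2
      cbind(1:omega, 0, omega),            # raise N1
      cbind(omega, 0, (omega - 1):0)       # lower N3
    )
  }
  X <- rbind(c(omega, 0, 0), do.call(rbind, replicate(n_rev, legs(),
                                                      simplify = FALSE)))
  colnames(X) <- c("N1", "N2", "N3")
  X
}

expect_tv_less <- function(p, q, tol) {
  expect_lt(0.5 * sum(abs(p - q)), tol)
}
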