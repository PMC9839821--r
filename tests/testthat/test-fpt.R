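test_that("the lattice index map is a bijection", {
  map <- lattice_index_map(7, 3)
  expect_equal(map$n_states, 8^3)
  states <- map$decode(seq_len(map$n_states))
  expect_equal(map$encode(states), seq_len(map$n_states))
  expect_equal(map$decode(map$encode(c(3L, 0L, 7L))),
               matrix(c(3L, 0L, 7L), 1, dimnames = list(NULL,
                                                        c("N1", "N2", "N3"))))
  map2 <- lattice_index_map(5, 2)
  expect_equal(map2$n_states, 36)
  expect_equal(map2$encode(map2$decode(seq_len(36))), seq_len(36))
})

test_that("generators conserve probability and respect structure", {
  pm <- minimal_params(r = 1, alpha = 0.8, beta = 1.3, omega = 5)
  G <- build_generator(build_minimal_network(pm), 10, absorbing = "any_zero")
  expect_lt(max(abs(Matrix::rowSums(G$Q))), 1e-12)
  offdiag <- G$Q - Matrix::Diagonal(nrow(G$Q), Matrix::diag(G$Q))
  expect_gte(min(offdiag@x), 0)
  # absorbing rows identically zero
  ab <- which(G$absorbing)
  expect_equal(Matrix::nnzero(G$Q[ab, ]), 0L)
  # GV lattice with absorbing origin only stores (2*omega+1)^3 states
  pg <- gv_params(b = 2, d = 1, alpha = 0.8, beta = 1.3, omega = 4)
  Gg <- build_generator(build_gv_network(pg), absorbing = "origin")
  expect_equal(nrow(Gg$Q), (2 * 4 + 1)^3)
  # single-species minimal chain: no death transition out of N = 1
  n1 <- single_species_subnet(pm)
  G1 <- build_generator(n1, 20)
  expect_equal(G1$Q[G1$map$encode(1L), G1$map$encode(0L)], 0)
})

test_that("hitting probabilities recover the gambler's-ruin closed form", {
  M <- 15L
  p_up <- 0.9
  q_dn <- 1.4
  net <- reaction_network(list(reaction(0L, 1L, p_up, "up"),
                               reaction(0L, -1L, q_dn, "down")), 1L)
  G <- build_generator(net, M, absorbing = function(s)
    s[, 1] == 0L | s[, 1] == M)
  ab_states <- G$states[G$absorbing, 1]
  classes <- list(ruin = which(ab_states == 0L),
                  win = which(ab_states == M))
  hp <- hitting_probabilities(G, classes)
  rho <- q_dn / p_up
  i <- hp$N1
  expect_equal(hp$win, (1 - rho^i) / (1 - rho^M), tolerance = 1e-10)
  expect_equal(hp$ruin + hp$win, rep(1, nrow(hp)), tolerance = 1e-10)
  expect_lt(attr(hp, "residual"), 1e-10)
})

test_that("mean absorption times match the pure-death closed form", {
  d_rate <- 0.7
  net <- reaction_network(list(reaction(1L, -1L, d_rate, "death")), 1L)
  G <- build_generator(net, 12, absorbing = function(s) s[, 1] == 0L)
  ft <- mean_absorption_time(G)
  closed <- vapply(ft$N1, function(N) sum(1 / (seq_len(N) * d_rate)),
                   numeric(1))
  expect_equal(ft$tau, closed, tolerance = 1e-10)
  expect_true(all(ft$tau[ft$absorbing] == 0))
})

test_that("symmetric starts make the three extinction planes equally likely", {
  pm <- minimal_params(r = 1, alpha = 0.8, beta = 1.3, omega = 9)
  G <- build_generator(build_minimal_network(pm), 18, absorbing = "any_zero")
  hp <- hitting_probabilities(G)
  row <- hp[hp$N1 == 3 & hp$N2 == 3 & hp$N3 == 3, ]
  expect_equal(unlist(row[, c("N1=0", "N2=0", "N3=0")], use.names = FALSE),
               rep(1 / 3, 3), tolerance = 1e-8)
  # rows are probability distributions
  tot <- hp[["N1=0"]] + hp[["N2=0"]] + hp[["N3=0"]]
  expect_lt(max(abs(tot - 1)), 1e-8)
})

test_that("first-passage fields are equivariant under cyclic relabeling", {
  pm <- minimal_params(r = 1, alpha = 0.8, beta = 1.3, omega = 6)
  G <- build_generator(build_minimal_network(pm), 12, absorbing = "any_zero")
  ft <- mean_absorption_time(G)
  key <- function(a, b, c) paste(a, b, c)
  tau_map <- stats::setNames(ft$tau, key(ft$N1, ft$N2, ft$N3))
  # the dynamics are invariant under (N1,N2,N3) -> (N3,N1,N2)
  expect_equal(unname(tau_map[key(ft$N3, ft$N1, ft$N2)]), ft$tau,
               tolerance = 1e-9)
})

test_that("exact mean extinction times agree with Gillespie ensembles", {
  pm <- minimal_params(r = 1, alpha = 0.8, beta = 1.3, omega = 6)
  net <- build_minimal_network(pm)
  G <- build_generator(net, 12, absorbing = "any_zero")
  ft <- mean_absorption_time(G)
  for (st in list(c(2L, 2L, 2L), c(4L, 1L, 1L))) {
    exact <- ft$tau[ft$N1 == st[1] & ft$N2 == st[2] & ft$N3 == st[3]]
    ens <- ensemble(net, st, 3000, 1e5, base_seed = 800 + st[1],
                    stop = "first_extinction")
    m <- mean(ens$t_first_extinct)
    se <- sd(ens$t_first_extinct) / sqrt(nrow(ens))
    expect_lt(abs(m - exact), 4 * se)
  }
})

test_that("conditional second-extinction densities behave as documented", {
  # exchange-symmetric competition: both orders equally likely
  ps <- minimal_params(r = 1, alpha = 1.05, beta = 1.05, omega = 8)
  entry <- data.frame(N1 = c(3L, 5L), N2 = c(3L, 5L), prob = c(0.6, 0.4))
  se_sym <- conditional_second_extinction(ps, entry = entry)
  expect_equal(sum(se_sym$masses), 1, tolerance = 1e-8)
  expect_equal(unname(se_sym$masses[1]), 0.5, tolerance = 1e-8)
  # asymmetric competition: species 2 (killed at rate beta > alpha) goes
  # extinct second more often
  pa <- minimal_params(r = 1, alpha = 0.8, beta = 1.3, omega = 8)
  se_a <- conditional_second_extinction(pa)
  expect_equal(sum(se_a$masses), 1, tolerance = 1e-8)
  expect_gt(se_a$masses["species2_second"], 0.5)
  expect_error(conditional_second_extinction(pa,
    entry = data.frame(N1 = 1L, N2 = 1L, prob = 0.5)), "sum to 1")
})

test_that("stationary distributions identify the correct closed classes", {
  # GV: the origin is the unique stationary law
  pg <- gv_params(b = 2, d = 1, alpha = 0.8, beta = 1.3, omega = 3)
  Gg <- build_generator(build_gv_network(pg), 6, absorbing = "none")
  sg <- stationary_distribution(Gg, init = c(1, 1, 1))
  expect_equal(sg$prob[sg$N1 == 0 & sg$N2 == 0 & sg$N3 == 0], 1)
  expect_equal(sum(sg$prob), 1)
  # single-species minimal chain: truncated Poisson (detailed balance)
  pm <- minimal_params(r = 1, alpha = 0.8, beta = 1.3, omega = 10)
  G1 <- build_generator(single_species_subnet(pm), 40, absorbing = "none")
  s1 <- stationary_distribution(G1, init = 1L)
  ref <- truncated_poisson(1, 10, 40)
  expect_tv_less(s1$prob[s1$N1 >= 1], ref$pmf, 1e-10)
  # without an initial state the reducible chain is ambiguous
  expect_error(stationary_distribution(G1), "closed communicating classes")
})

test_that("segment initial states follow the printed parameterisation", {
  expect_equal(segment_initial_state(0, 30), c(30L, 0L, 0L))
  expect_equal(segment_initial_state(1, 30), c(10L, 10L, 10L))
  expect_equal(segment_initial_state(0.5, 30), c(20L, 5L, 5L))
  expect_error(segment_initial_state(1.2, 30), "0, 1")
})

test_that("plane slices restrict fields faithfully", {
  pm <- minimal_params(r = 1, alpha = 0.8, beta = 1.3, omega = 6)
  G <- build_generator(build_minimal_network(pm), 12, absorbing = "any_zero")
  ft <- mean_absorption_time(G)
  sl <- plane_slice(ft, 6)
  expect_true(all(sl$N1 + sl$N2 + sl$N3 == 6))
  # three-fold rotational symmetry on the slice
  key <- function(a, b, c) paste(a, b, c)
  m <- stats::setNames(sl$tau, key(sl$N1, sl$N2, sl$N3))
  expect_equal(unname(m[key(sl$N3, sl$N1, sl$N2)]), sl$tau,
               tolerance = 1e-9)
  # the slice maximum sits at the lattice state nearest the interior
  # equilibrium omega*r/(1+alpha+beta)*(1,1,1)
  eq <- rep(6 / 3.1, 3)
  best <- sl[which.max(sl$tau), c("N1", "N2", "N3")]
  dists <- sqrt((sl$N1 - eq[1])^2 + (sl$N2 - eq[2])^2 + (sl$N3 - eq[3])^2)
  expect_equal(unlist(best, use.names = FALSE),
               unlist(sl[which.min(dists), c("N1", "N2", "N3")],
                      use.names = FALSE))
  # a constant field slices to a constant; empty planes error
  cf <- data.frame(N1 = 0:3, N2 = 3:0, N3 = 0L, value = 2)
  expect_equal(unique(plane_slice(cf, 3)$value), 2)
  expect_error(plane_slice(cf, 99), "does not intersect")
})
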