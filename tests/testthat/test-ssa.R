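test_that("the compiled core reproduces a pure-R Gillespie exactly", {
  pm <- minimal_params(r = 1, alpha = 0.8, beta = 1.3, omega = 8)
  net <- build_minimal_network(pm)
  for (seed in c(7, 23)) {
    ref <- r_gillespie(net, c(3, 3, 3), 5, seed)
    tr <- gillespie(net, c(3, 3, 3), 5, seed = seed)
    expect_equal(nrow(tr), nrow(ref))
    expect_equal(as.matrix(as.data.frame(tr)), ref, tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
  pt <- three_pool_params(tau = 1, gamma = 2.4, mu = 0.05, omega = 6)
  nt <- build_three_pool_network(pt)
  ref <- r_gillespie(nt, c(6, 0, 0), 20, 99)
  tr <- gillespie(nt, c(6, 0, 0), 20, seed = 99)
  expect_equal(as.matrix(as.data.frame(tr)), ref, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("identical seeds give identical trajectories", {
  pm <- minimal_params(r = 1, alpha = 0.8, beta = 1.3, omega = 10)
  net <- build_minimal_network(pm)
  a <- gillespie(net, c(3, 3, 4), 40, seed = 5)
  b <- gillespie(net, c(3, 3, 4), 40, seed = 5)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_identical(attr(a, "extinctions"), attr(b, "extinctions"))
})

test_that("zero total propensity absorbs immediately", {
  pg <- gv_params(b = 2, d = 1, alpha = 0.8, beta = 1.3, omega = 5)
  tr <- gillespie(build_gv_network(pg), c(0, 0, 0), 10, seed = 1)
  expect_equal(attr(tr, "terminal"), "absorbed")
  expect_equal(attr(tr, "n_jumps"), 0)
  pt <- three_pool_params(tau = 1, gamma = 2.4, mu = 0, omega = 4)
  tr2 <- gillespie(build_three_pool_network(pt), c(0, 0, 0), 10, seed = 1)
  expect_equal(attr(tr2, "terminal"), "absorbed")
})

test_that("a single enabled reaction fires deterministically", {
  pm <- minimal_params(r = 1, alpha = 0.8, beta = 1.3, omega = 30)
  net <- build_minimal_network(pm)
  for (seed in 1:5) {
    tr <- gillespie(net, c(0, 0, 1), 50, seed = seed)
    expect_equal(unlist(tr[2, c("N1", "N2", "N3")], use.names = FALSE),
                 c(0, 0, 2))
  }
})

test_that("pure-birth ensembles track the exponential mean", {
  yule <- reaction_network(list(reaction(1L, 1L, 0.5, "birth")), 1L)
  finals <- vapply(1:400, function(k) {
    attr(gillespie(yule, 5, 3, seed = 2000 + k, record = FALSE), "final")
  }, integer(1))
  theory <- 5 * exp(0.5 * 3)
  se <- sd(finals) / sqrt(length(finals))
  expect_lt(abs(mean(finals) - theory), 3 * se)
})

test_that("extinction records report first zeros in time order", {
  # handcrafted path: species 2 first reaches zero at t = 5
  df <- tibble::tibble(t = c(0, 2, 5, 8, 9),
                       N1 = c(3, 3, 3, 2, 2),
                       N2 = c(2, 1, 0, 0, 0),
                       N3 = c(4, 4, 4, 4, 3))
  ev <- extinction_events(df)
  expect_equal(ev$species[1], 2)
  expect_equal(ev$time[1], 5)
  expect_equal(attr(ev, "survivors"), c(1L, 3L))

  # minimal model long run: exactly two extinctions, one survivor
  pm <- minimal_params(r = 1, alpha = 0.8, beta = 1.3, omega = 8)
  tr <- gillespie(build_minimal_network(pm), c(3, 3, 3), 2000, seed = 17)
  ev2 <- extinction_events(tr)
  expect_equal(nrow(ev2), 2L)
  expect_length(attr(ev2, "survivors"), 1L)

  # GV run to absorption: all three go extinct
  pg <- gv_params(b = 2, d = 1, alpha = 0.8, beta = 1.3, omega = 8)
  tr3 <- gillespie(build_gv_network(pg), c(3, 3, 3), 1e6, seed = 4)
  expect_equal(attr(tr3, "terminal"), "absorbed")
  expect_equal(nrow(extinction_events(tr3)), 3L)
})

test_that("section crossings on a constructed revolution path", {
  w <- 6L
  # two revolutions plus the first step of a third, which closes circuit 2
  X <- rbind(revolution_path(w, n_rev = 2), c(6L, 1L, 0L))
  tt <- seq_len(nrow(X)) - 1
  df <- tibble::as_tibble(cbind(t = tt, X))
  cr <- section_crossings(df, orientation = 0L)
  # start on P1 at t = 0, then one crossing per section per revolution
  expect_equal(cr$events$section[1], 1L)
  expect_equal(cr$events$time[1], 0)
  expect_equal(as.vector(table(factor(cr$events$section, 1:3))),
               c(3L, 2L, 2L))
  expect_length(cr$circuits, 2L)
  # matches the independent R implementation of the rule
  oracle <- r_crossings(X, tt, 0L)
  expect_equal(cr$events$section, oracle$section)
  expect_equal(cr$events$time, oracle$time)
})

test_that("paths confined to one sector never cross the other sections", {
  # N1 > N2 > N3 throughout
  X <- cbind(N1 = c(9, 9, 8, 9, 8, 9), N2 = c(5, 6, 5, 4, 5, 6),
             N3 = c(1, 2, 1, 0, 1, 2))
  df <- tibble::as_tibble(cbind(t = 0:5, X))
  cr <- section_crossings(df, orientation = 0L)
  expect_false(any(cr$events$section %in% c(2L, 3L)))
})

test_that("compiled and R crossing detectors agree on stochastic paths", {
  pt <- three_pool_params(tau = 1, gamma = 2.4, mu = 0.05, omega = 5)
  nt <- build_three_pool_network(pt)
  tr <- gillespie(nt, c(5, 0, 0), 200, seed = 31)
  cr <- section_crossings(tr, use_recorded = TRUE)
  X <- as.matrix(as.data.frame(tr)[, c("N1", "N2", "N3")])
  oracle <- r_crossings(X, tr$t, section_orientation(pt))
  expect_equal(cr$events$section, oracle$section)
  expect_equal(cr$events$time, oracle$time)
  # inline detection during simulation matches post-hoc detection
  inline <- attr(tr, "crossings")
  expect_equal(inline$section, oracle$section)
  expect_equal(inline$time, oracle$time)
  # trajectory started on P1 records it at t = 0
  expect_equal(inline$section[1], 1L)
  expect_equal(inline$time[1], 0)
})

test_that("ensembles are reproducible and reduce to single runs", {
  pm <- minimal_params(r = 1, alpha = 0.8, beta = 1.3, omega = 9)
  net <- build_minimal_network(pm)
  e1 <- ensemble(net, c(3, 3, 3), 5, 50, base_seed = 70,
                 stop = "first_extinction")
  e2 <- ensemble(net, c(3, 3, 3), 5, 50, base_seed = 70,
                 stop = "first_extinction")
  expect_identical(e1, e2)
  g <- gillespie(net, c(3, 3, 3), 50, seed = 71, record = FALSE,
                 stop = "first_extinction")
  expect_equal(e1$t_end[1], attr(g, "t_end"))
  expect_equal(unlist(e1[1, c("final1", "final2", "final3")],
                      use.names = FALSE), attr(g, "final"))
})

test_that("first extinctions from a symmetric start are equally likely", {
  pm <- minimal_params(r = 1, alpha = 0.8, beta = 1.3, omega = 9)
  net <- build_minimal_network(pm)
  ens <- ensemble(net, c(3, 3, 3), 1500, 1e5, base_seed = 300,
                  stop = "first_extinction")
  frac <- tabulate(ens$first_extinct, 3) / nrow(ens)
  se <- sqrt((1 / 3) * (2 / 3) / nrow(ens))
  expect_true(all(abs(frac - 1 / 3) < 3 * se))
})

test_that("the minimal model has no transition into total extinction", {
  # structural check on the assembled generator: no off-diagonal flux into
  # the origin column
  pm <- minimal_params(r = 1, alpha = 0.8, beta = 1.3, omega = 4)
  G <- build_generator(build_minimal_network(pm), 8, absorbing = "none")
  origin <- G$map$encode(c(0L, 0L, 0L))
  col <- G$Q[, origin]
  col[origin] <- 0
  expect_equal(Matrix::nnzero(col), 0L)
})

test_that("trajectory CSV round-trips with its metadata sidecar", {
  pm <- minimal_params(r = 1, alpha = 0.8, beta = 1.3, omega = 8)
  tr <- gillespie(build_minimal_network(pm), c(3, 3, 3), 5, seed = 2)
  path <- file.path(tempdir(), "traj.csv")
  write_trajectory(tr, path)
  back <- utils::read.csv(path)
  expect_equal(names(back), c("t", "N1", "N2", "N3"))
  expect_equal(back$N1, tr$N1)
  meta <- jsonlite::read_json(sub("csv$", "json", path))
  expect_equal(meta$model, "minimal")
  expect_equal(meta$seed, 2)
  unlink(c(path, sub("csv$", "json", path)))
})
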