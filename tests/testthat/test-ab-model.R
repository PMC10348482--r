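test_that("K = 1 collapses to the per-column Bernoulli MLE", {
  Y <- rand_bm(30, 8, p = 0.4, seed = 2)
  fit <- fit_ab(Y, K = 1, n_iter = 50, n_restarts = 2, seed = 5)
  expect_lt(max(abs(fit$beta[1, ] - colMeans(Y))), 1e-6)
  expect_true(all(abs(fit$gamma[, 1] - 1) < 1e-8))
})

test_that("two clean blocks are recovered essentially exactly at K = 2", {
  Y <- block_bm(40, 10)
  fit <- fit_ab(Y, K = 2, n_iter = 300, n_restarts = 5, seed = 9)
  V <- fitted(fit)
  expect_lt(max(abs(V - unclass(Y))), 0.05)
})

test_that("an all-ones matrix is fit perfectly (log-likelihood ~ 0)", {
  Y <- suppressWarnings(binary_matrix(matrix(1L, 6, 5)))
  for (K in c(1, 3)) {
    fit <- fit_ab(Y, K = K, n_iter = 100, n_restarts = 1, seed = 1)
    expect_lt(abs(as.numeric(logLik(fit))), 1e-6)
  }
})

test_that("log-likelihood is non-decreasing on every restart (property)", {
  for (i in 1:10) {
    set.seed(100 + i)
    G <- sample(10:40, 1); F <- sample(5:15, 1)
    Y <- matrix(rbinom(G * F, 1, runif(1, 0.2, 0.8)), G, F)
    storage.mode(Y) <- "double"
    K <- sample(2:4, 1)
    gamma0 <- matrix(rgamma(G * K, 1), G, K)
    gamma0 <- gamma0 / rowSums(gamma0)
    beta0 <- matrix(runif(K * F, 0.25, 0.75), K, F)
    res <- guildAB:::ab_em_run(Y, gamma0, beta0, 150L, 0)
    expect_true(all(diff(res$loglik_trace) >= -1e-9),
                info = paste("dataset", i))
  }
})

test_that("fits are reproducible from the documented seed", {
  Y <- rand_bm(25, 10, seed = 4)
  f1 <- fit_ab(Y, K = 3, n_iter = 100, n_restarts = 3, seed = 77)
  f2 <- fit_ab(Y, K = 3, n_iter = 100, n_restarts = 3, seed = 77)
  expect_identical(f1$gamma, f2$gamma)
  expect_identical(f1$beta, f2$beta)
  expect_identical(f1$loglik_trace, f2$loglik_trace)
})

test_that("fit invariants hold: simplex rows, unit-interval beta and V", {
  Y <- rand_bm(40, 12, p = 0.35, seed = 6)
  fit <- fit_ab(Y, K = 4, n_iter = 200, n_restarts = 2, seed = 8)
  expect_true(all(abs(rowSums(fit$gamma) - 1) < 1e-8))
  expect_true(all(fit$gamma >= 0))
  expect_true(all(fit$beta >= 0 & fit$beta <= 1))
  V <- fitted(fit)
  expect_true(all(V >= 0 & V <= 1))
  # aspects reported in descending total-weight order
  expect_true(all(diff(colSums(fit$gamma)) <= 1e-9))
})

test_that("the likelihood plateaus well before the iteration cap", {
  base <- generate_base_matrix(200, 50, n_latent = 3, density = 0.3,
                               seed = 21)
  fit <- fit_ab(base, K = 3, n_iter = 500, n_restarts = 1, seed = 13,
                tol = 0)
  tr <- fit$loglik_trace
  expect_length(tr, 500L)
  total_gain <- tr[500] - tr[1]
  late_gain <- tr[500] - tr[400]
  expect_lt(late_gain, 0.001 * total_gain)
})

test_that("row permutation permutes gamma and leaves beta fixed (fixed init)", {
  set.seed(42)
  G <- 20; F <- 8; K <- 3
  Y <- matrix(rbinom(G * F, 1, 0.4), G, F); storage.mode(Y) <- "double"
  gamma0 <- matrix(rgamma(G * K, 1), G, K); gamma0 <- gamma0 / rowSums(gamma0)
  beta0 <- matrix(runif(K * F, 0.25, 0.75), K, F)
  perm <- sample(G)
  r1 <- guildAB:::ab_em_run(Y, gamma0, beta0, 100L, 0)
  r2 <- guildAB:::ab_em_run(Y[perm, ], gamma0[perm, ], beta0, 100L, 0)
  expect_equal(r2$gamma, r1$gamma[perm, ], tolerance = 1e-10)
  expect_equal(r2$beta, r1$beta, tolerance = 1e-10)
})

test_that("invalid K is rejected", {
  Y <- rand_bm(5, 4, seed = 1)
  expect_error(fit_ab(Y, K = 0), "positive")
  expect_error(fit_ab(Y, K = 5), "cannot exceed")
})

test_that("responsibilities follow Bayes' rule and sum to one", {
  # hand-evaluated case: gamma = (0.6, 0.4), beta_.f = (0.9, 0.1), Y = 1
  gamma <- matrix(c(0.6, 0.4), 1, 2)
  beta <- matrix(c(0.9, 0.1), 2, 1)
  fit <- toy_fit(gamma, beta)
  Y1 <- suppressWarnings(binary_matrix(matrix(1L, 1, 1)))
  w <- responsibilities(fit, Y1)
  expect_equal(as.vector(w), c(0.54 / 0.58, 0.04 / 0.58), tolerance = 1e-12)

  # K = 1: responsibility is 1 everywhere
  f1 <- toy_fit(matrix(1, 3, 1), matrix(c(0.2, 0.5, 0.9), 1, 3))
  w1 <- responsibilities(f1, rand_bm(3, 3, seed = 2))
  expect_true(all(w1 == 1))

  # identical beta across aspects: responsibility for Y = 1 equals gamma
  f2 <- toy_fit(matrix(c(0.3, 0.7), 1, 2), matrix(0.5, 2, 2))
  w2 <- responsibilities(f2, suppressWarnings(binary_matrix(matrix(1L, 1, 2))))
  expect_equal(unname(w2[1, 1, ]), c(0.3, 0.7), tolerance = 1e-12)

  # sums to one for every cell on a fitted model
  Y <- rand_bm(15, 6, seed = 3)
  fit <- fit_ab(Y, K = 3, n_iter = 50, n_restarts = 1, seed = 2)
  w <- responsibilities(fit)
  expect_true(all(abs(apply(w, c(1, 2), sum) - 1) < 1e-8))

  expect_error(responsibilities(fit, rand_bm(4, 6, seed = 1)), "dimensions")
})

test_that("model methods are coherent (predict, simulate, residuals)", {
  Y <- rand_bm(30, 10, p = 0.4, seed = 12)
  fit <- fit_ab(Y, K = 2, n_iter = 150, n_restarts = 2, seed = 3)
  expect_equal(predict(fit), fitted(fit))
  # fold-in on the training rows lands near the training gamma
  g <- predict(fit, newdata = Y, type = "gamma", n_iter = 300)
  expect_lt(mean(abs(g - fit$gamma)), 0.1)
  sims <- simulate(fit, nsim = 2, seed = 9)
  expect_length(sims, 2L)
  expect_equal(dim(sims[[1]]), dim(Y))
  r <- residuals(fit)
  expect_equal(dim(r), dim(Y))
  expect_true(all(abs(r) <= 1))
})

test_that("fit serialization round-trips parameters through TSV", {
  Y <- rand_bm(12, 6, seed = 5)
  fit <- fit_ab(Y, K = 2, n_iter = 50, n_restarts = 1, seed = 4)
  dir <- withr::local_tempdir()
  write_ab_fit(fit, dir)
  back <- read_ab_fit(dir)
  expect_equal(back$gamma, fit$gamma, tolerance = 1e-12)
  expect_equal(back$beta, fit$beta, tolerance = 1e-12)
  expect_equal(back$K, fit$K)
  expect_equal(back$seed, fit$seed)
})
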