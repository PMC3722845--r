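test_that("reference-category softmax has its closed forms", {
  expect_equal(category_probs(rep(0, 6)), rep(1 / 6, 6))
  expect_equal(category_probs(c(0, log(2), 0, 0, 0, 0)),
               c(1, 2, 1, 1, 1, 1) / 7)
  set.seed(1)
  P <- category_probs(random_eta(50))
  expect_true(all(abs(rowSums(P) - 1) < 1e-12))
  expect_true(all(P > 0 & P < 1))
  expect_error(category_probs(c(0, Inf, 0, 0, 0, 0)), "finite")
})

test_that("identification identity: log(P_j/P_1) equals the linear predictor", {
  set.seed(2)
  eta <- random_eta(500, scale = 5)
  P <- category_probs(eta)
  expect_lt(max(abs(log(P[, -1] / P[, 1]) - eta[, -1])), 1e-10)
})

test_that("probabilities are invariant to a constant shift of all log means", {
  set.seed(3)
  eta <- random_eta(20)
  expect_equal(category_probs(eta), category_probs(eta + 7.3))
})

test_that("log-likelihood sums observation terms and splits by wave", {
  d <- std_data()
  des <- build_design(d$panel, d$cohort, 1)
  st0 <- initialize_state(des)
  expect_equal(log_likelihood(des, st0), length(des$y) * log(1 / 6))
  set.seed(4)
  st <- st0; st$beta[] <- rnorm(length(st$beta), 0, 0.3)
  expect_equal(log_likelihood(des, st, waves = 1) +
                 log_likelihood(des, st, waves = 2:3),
               log_likelihood(des, st))
  expect_gte(deviance_state(des, st), 0)
})

test_that("fitted frequencies reproduce the count-based saturated log-likelihood", {
  set.seed(5)
  y <- sample(1:6, 300, replace = TRUE, prob = c(0.3, 0.2, 0.15, 0.15, 0.1, 0.1))
  f <- tabulate(y, 6) / 300
  des <- toy_design(y, X = matrix(1, 300, 1), Z = NULL,
                    wave = rep(2L, 300), variant = 1L, L = 6L,
                    contrast = NULL)
  st <- initialize_state(des)
  st$beta[1, ] <- log(f[-1] / f[1])
  expect_equal(log_likelihood(des, st), sum(tabulate(y, 6) * log(f)))
})

test_that("C++ kernels agree with a plain R computation", {
  set.seed(6)
  eta <- random_eta(80)
  y <- sample(1:6, 80, replace = TRUE)
  P <- category_probs(eta)
  r_ll <- sum(log(P[cbind(1:80, y)]))
  expect_equal(sedbayes:::cpp_loglik(eta, y), r_ll)
  g <- sample(1:4, 80, replace = TRUE)
  expect_equal(sum(sedbayes:::cpp_loglik_group(eta, y, g, 4)), r_ll)
  expect_equal(sedbayes:::cpp_loglik_group(eta, y, g, 4),
               as.vector(tapply(log(P[cbind(1:80, y)]), g, sum)),
               ignore_attr = TRUE)
  newcol <- eta[, 3] + 0.5
  eta2 <- eta; eta2[, 3] <- newcol
  expect_equal(sedbayes:::cpp_loglik_upd(eta, y, 3, newcol),
               sedbayes:::cpp_loglik(eta2, y))
})

test_that("marginal deviance kernel matches brute-force integration", {
  set.seed(7)
  N <- 6L
  y <- sample(1:6, 2 * N, replace = TRUE)
  pat <- rep(1:N, each = 2)
  eta0 <- random_eta(2 * N)
  sd_k <- c(0.5, 1, 0.2, 0.8, 0.3)
  Zm <- matrix(rnorm(64 * 5), 64, 5)
  got <- sedbayes:::cpp_marginal_dev(eta0, y, pat, N, sd_k, Zm,
                                     rep(TRUE, 2 * N))
  want <- 0
  for (i in 1:N) {
    rows <- which(pat == i)
    lik_m <- sapply(1:64, function(m) {
      e <- eta0[rows, , drop = FALSE]
      e[, -1] <- e[, -1] + rep(sd_k * Zm[m, ], each = length(rows))
      P <- category_probs(e)
      prod(P[cbind(seq_along(rows), y[rows])])
    })
    want <- want + log(mean(lik_m))
  }
  expect_equal(got, -2 * want)
})
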