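test_that("cohort generation honours the study design and is reproducible", {
  coh <- generate_cohort(127, c(30, 31, 32, 34), seed = 1)
  base <- coh[coh$wave == 1, ]
  expect_equal(unname(table(base$group)), c(30, 31, 32, 34),
               ignore_attr = TRUE)
  expect_equal(nrow(coh), 127 * 3)
  expect_true(all(coh$weight_kg >= 6 & coh$weight_kg <= 46))
  expect_true(all(coh$age_months >= 4 & coh$age_months <= 156))
  expect_true(all(coh$sex %in% 0:1) && all(coh$comp %in% 0:1))
  # vitals exist for every (patient, wave) and vary across waves
  expect_false(anyNA(coh$sbp))
  expect_gt(stats::sd(coh$sbp[coh$patient_id == 1]), 0)
  # baseline covariates constant within patient
  expect_true(all(tapply(coh$weight_kg, coh$patient_id,
                         function(x) diff(range(x))) == 0))
  expect_identical(coh, generate_cohort(127, c(30, 31, 32, 34), seed = 1))
  expect_false(identical(coh, generate_cohort(127, c(30, 31, 32, 34), seed = 2)))
  expect_error(generate_cohort(100, c(30, 31, 32, 34), seed = 1), "sum")
})

test_that("null model yields uniform level frequencies at every wave", {
  coh <- generate_cohort(10000, c(2500, 2500, 2500, 2500), seed = 3)
  truth <- truth_record(2, beta = 0, gamma = 0)
  pan <- simulate_panel(coh, truth, seed = 4)
  for (w in 1:3) {
    f <- tabulate(pan$level[pan$wave == w], 6) / 10000
    se <- sqrt((1 / 6) * (5 / 6) / 10000)
    expect_true(all(abs(f - 1 / 6) < 3 * se),
                info = sprintf("wave %d: %s", w, paste(round(f, 4), collapse = " ")))
  }
})

test_that("strong diagonal lag effects produce sticky transitions matching the softmax oracle", {
  g <- 6
  p_stay_exact <- exp(g) / (exp(g) + 5)   # previous level j >= 2, stay at j
  gamma <- matrix(0, 5, 5); diag(gamma) <- g
  truth <- truth_record(2, beta = 0, gamma = gamma,
                        baseline = c(0, rep(0.2, 5)))
  coh <- generate_cohort(2000, c(500, 500, 500, 500), seed = 5)
  pan <- simulate_panel(coh, truth, seed = 6)
  lev <- matrix(pan$level, ncol = 3, byrow = TRUE)
  stay <- mean(c(lev[, 2] == lev[, 1], lev[, 3] == lev[, 2]))
  expect_gt(stay, 0.9)
  se <- sqrt(p_stay_exact * (1 - p_stay_exact) / (2 * 2000))
  expect_lt(abs(stay - p_stay_exact), 4 * se)
})

test_that("random effects induce within-patient concordance above independence", {
  truth <- truth_record(1, beta = 0, Sigma = 4)
  coh <- generate_cohort(4000, c(1000, 1000, 1000, 1000), seed = 7)
  pan <- simulate_panel(coh, truth, seed = 8)
  lev <- matrix(pan$level, ncol = 3, byrow = TRUE)
  conc <- mean(lev[, 2] == lev[, 3])
  # Monte-Carlo oracle: integrate alpha out by simulation
  set.seed(9)
  A <- matrix(rnorm(20000 * 5, 0, 2), ncol = 5)
  P <- exp(cbind(0, A)); P <- P / rowSums(P)
  conc_oracle <- mean(rowSums(P^2))
  indep <- sum(colMeans(P)^2)
  expect_gt(conc, indep + 0.05)
  expect_lt(abs(conc - conc_oracle), 0.03)
})

test_that("without random effects waves are conditionally independent", {
  truth <- truth_record(2, beta = 0, gamma = 0)
  rejections <- 0L
  for (r in 1:20) {
    coh <- generate_cohort(600, c(150, 150, 150, 150), seed = 100 + r)
    pan <- simulate_panel(coh, truth, seed = 200 + r)
    lev <- matrix(pan$level, ncol = 3, byrow = TRUE)
    p <- suppressWarnings(stats::chisq.test(table(lev[, 2], lev[, 3]))$p.value)
    rejections <- rejections + (p < 0.05)
  }
  expect_lte(rejections, 4)
})

test_that("panel simulation is deterministic and respects invariants", {
  d <- std_data()
  pan2 <- simulate_panel(d$cohort, d$truth, seed = 102)
  expect_identical(d$panel$level, pan2$level)
  expect_true(all(d$panel$level %in% 1:6))
  expect_equal(nrow(d$panel), 127 * 3)
  expect_false(anyDuplicated(paste(d$panel$patient_id, d$panel$wave)) > 0)
})
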