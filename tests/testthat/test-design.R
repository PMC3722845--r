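test_that("variant registry matches the five-model table", {
  v <- lapply(1:5, variant_spec)
  expect_equal(sapply(v, `[[`, "has_lag"), c(FALSE, TRUE, TRUE, TRUE, TRUE))
  expect_equal(sapply(v, `[[`, "lag_time_varying"),
               c(FALSE, FALSE, FALSE, TRUE, TRUE))
  expect_equal(sapply(v, `[[`, "has_random_effect"),
               c(TRUE, FALSE, TRUE, FALSE, TRUE))
  expect_error(variant_spec(6), "1..5")
})

test_that("lag indicators one-hot encode the previous level with Sed1 as reference", {
  # one patient per previous level, identical wave-2 response
  pan <- data.frame(patient_id = rep(1:6, each = 2),
                    wave = rep(1:2, 6),
                    level = as.integer(rbind(1:6, rep(2, 6))))
  coh <- generate_cohort(6, c(2, 2, 1, 1), seed = 1, n_waves = 2)
  d <- build_design(pan, coh, 2)
  expect_equal(nrow(d$Z), 6)
  expect_equal(unname(d$Z[1, ]), rep(0, 5))       # previous level 1
  for (j in 2:6) {
    expect_equal(sum(d$Z[j, ]), 1)
    expect_equal(unname(which(d$Z[j, ] == 1)), j - 1)
  }
})

test_that("row counts follow the variant's likelihood support", {
  d <- std_data()
  expect_equal(length(build_design(d$panel, d$cohort, 1)$y), 3 * 127)
  for (v in 2:5)
    expect_equal(length(build_design(d$panel, d$cohort, v)$y), 2 * 127)
})

test_that("lag variants demand the previous wave", {
  d <- std_data()
  pan23 <- d$panel[d$panel$wave >= 2, ]
  expect_error(build_design(pan23, d$cohort, 3), "previous wave")
  expect_silent(build_design(pan23, d$cohort, 1))
})

test_that("per-contrast mode subsets and recodes the response", {
  d <- std_data()
  dd <- build_design(d$panel, d$cohort, 3, contrast = 6)
  full <- build_design(d$panel, d$cohort, 3)
  expect_equal(dd$L, 2L)
  expect_true(all(dd$y %in% 1:2))
  expect_equal(length(dd$y), sum(full$y %in% c(1L, 6L)))
  expect_equal(ncol(dd$Z), 5)                      # lag history keeps 6 levels
  expect_error(build_design(d$panel, d$cohort, 3, contrast = 1), "2..6")
})

test_that("malformed panels are rejected", {
  d <- std_data()
  bad <- d$panel; bad$level[5] <- 9L
  expect_error(build_design(bad, d$cohort, 2), "level outside 1..6")
  dup <- rbind(d$panel, d$panel[1, ])
  expect_error(build_design(dup, d$cohort, 2), "duplicate")
})

test_that("standardization is reproducible between simulation and fit", {
  d <- std_data()
  d1 <- build_design(d$panel, d$cohort, 3, standardize = TRUE)
  cont <- c("age_months", "weight_kg", "sbp", "pul", "osat")
  expect_true(all(abs(colMeans(
    sedbayes:::covariate_matrix(d$cohort, standardize = TRUE)[, cont])) < 1e-10))
  d2 <- build_design(d$panel, d$cohort, 3, standardize = TRUE,
                     scaling = d1$scaling)
  expect_identical(d1$X, d2$X)
})
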