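test_that("the parameter-type classifier is complete and has 12 types", {
  tpl <- build_template(design_full(L = 2), mi = "strong")
  tm <- parameter_type_map(tpl)
  expect_length(tm, count_free_parameters(tpl))
  expect_equal(length(unique(tm)), 12)
  between <- c("loading_S", "loading_CM", "loading_M", "cov_L2",
               "latent_mean", "intercept", "var_L2", "resid_L2")
  within <- c("loading_UM", "var_L1", "cov_L1", "resid_L1")
  expect_setequal(unique(tm), c(between, within))
  ## without a structurally different non-reference method there is no
  ## loading_M type, but everything else is classified
  tm2 <- parameter_type_map(build_template(design_ri(L = 2)))
  expect_false("loading_M" %in% tm2)
  expect_equal(length(unique(tm2)), 11)
})

test_that("parameter bias aggregation follows its defining ratio", {
  tm <- c(a = "loading_S", b = "loading_S", c = "var_L2")
  est <- cbind(a = c(1.1, 1.1), b = c(2, 2), c = c(0.5, 0.7))
  ## single parameter, mean 1.1 vs truth 1.0: bias 0.1
  expect_equal(unname(peb(est[, "a", drop = FALSE], c(a = 1), tm)), 0.1)
  ## exact recovery: zero for every type
  truth <- c(a = 1.1, b = 2, c = 0.6)
  out <- peb(est, truth, tm)
  expect_equal(unname(out[c("loading_S", "var_L2")]), c(0, 0))
  ## zero-truth parameters are excluded with a note
  expect_message(peb(est, c(a = 1, b = 0, c = 0.6), tm), "true value 0")
})

test_that("SE bias aggregation follows its defining ratio", {
  tm <- c(a = "loading_S")
  est <- cbind(a = c(0.9, 1.1))          # empirical SD = sqrt(0.02) ...
  ses <- cbind(a = c(0.10, 0.10))
  sd_emp <- sd(est[, 1])
  expect_equal(unname(seb(ses, est, tm)), abs(0.10 - sd_emp) / sd_emp)
  ## SEs equal to the SD give zero
  ses2 <- cbind(a = rep(sd_emp, 2))
  expect_equal(unname(seb(ses2, est, tm)), 0)
})

test_that("peb and seb agree with straight-loop reference code", {
  set.seed(7)
  n_par <- 20; n_rep <- 30
  labs <- sprintf("p%02d", seq_len(n_par))
  tm <- setNames(sample(c("t1", "t2", "t3"), n_par, replace = TRUE), labs)
  truth <- setNames(runif(n_par, 0.2, 2), labs)
  est <- matrix(rnorm(n_rep * n_par, rep(truth, each = n_rep), 0.2),
                n_rep, dimnames = list(NULL, labs))
  ses <- matrix(abs(rnorm(n_rep * n_par, 0.2, 0.02)), n_rep,
                dimnames = list(NULL, labs))

  loop_peb <- sapply(unique(tm), function(ty) {
    vals <- c()
    for (p in labs[tm == ty]) {
      vals <- c(vals, abs(mean(est[, p]) - truth[p]) / truth[p])
    }
    mean(vals)
  })
  expect_equal(peb(est, truth, tm)[names(loop_peb)], loop_peb)

  loop_seb <- sapply(unique(tm), function(ty) {
    vals <- c()
    for (p in labs[tm == ty]) {
      sd_p <- sd(est[, p])
      vals <- c(vals, abs(mean(ses[, p]) - sd_p) / sd_p)
    }
    mean(vals)
  })
  expect_equal(seb(ses, est, tm)[names(loop_seb)], loop_seb)
})

test_that("replication seeds are deterministic, distinct, and in range", {
  s1 <- replication_seed(1, 1, 1:500)
  expect_identical(s1, replication_seed(1, 1, 1:500))
  expect_equal(anyDuplicated(s1), 0)
  expect_true(all(s1 > 0 & s1 < 2^31))
  expect_false(any(replication_seed(2, 1, 1:500) == s1))
})

test_that("condition runs are reproducible and handle edge cases", {
  design <- design_ri(L = 1, n_targets = 80, n_raters = 3)
  expect_error(run_condition(design_ri(L = 1, n_targets = 10, n_raters = 3),
                             n_reps = 1),
               "free")
  empty <- run_condition(design, n_reps = 0, base_seed = 1)
  expect_equal(empty$n_reps, 0)
  expect_null(empty$peb)

  a <- run_condition(design, "low", n_reps = 2, base_seed = 3, se = FALSE,
                     chisq = FALSE)
  b <- run_condition(design, "low", n_reps = 2, base_seed = 3, se = FALSE,
                     chisq = FALSE)
  expect_identical(a$estimates, b$estimates)
  expect_identical(a$peb, b$peb)
  expect_equal(a$convergence_rate, 1)
})

test_that("chi-square calibration is diagonal under the null", {
  set.seed(99)
  x <- rchisq(4000, df = 30)
  cal <- chisq_calibration(x, 30)
  expect_equal(cal$observed, cal$p, tolerance = 0.03)
  rej <- attr(cal, "rejection")
  expect_equal(unname(rej), 0.05, tolerance = 0.02)
  ## straight-loop duplicate of the empirical alpha
  expect_equal(unname(rej), sum(x > qchisq(0.95, 30)) / length(x))
  ## mixed degrees of freedom are grouped automatically
  y <- c(x[1:100], rchisq(100, df = 5))
  cal2 <- chisq_calibration(y, c(rep(30, 100), rep(5, 100)))
  expect_setequal(unique(cal2$df), c(5, 30))
  expect_warning(chisq_calibration(x[1:10], 30), "fewer than 50")
})
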