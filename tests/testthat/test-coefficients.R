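test_that("population coefficients reproduce the target variance shares", {
  design <- design_full(L = 2)
  low <- compute_coefficients(
    derive_population_params(population_targets("low"), design))
  int <- low$role == "interchangeable_set"
  str <- low$role == "nonreference_structural"
  expect_equal(mean(low$con_observed[int]), 0.30)
  expect_equal(mean(low$ums_observed[int]), 0.25)
  expect_equal(mean(low$cms_observed[int]), 0.25)
  expect_equal(mean(low$ms_observed[str]), 0.50)
  expect_equal(mean(low$rel), 0.80)

  high <- compute_coefficients(
    derive_population_params(population_targets("high"), design))
  expect_equal(mean(high$con_observed[high$role == "interchangeable_set"]),
               0.60)
  expect_equal(mean(high$ms_observed[high$role == "nonreference_structural"]),
               0.20)
  expect_equal(mean(high$rel), 0.80)
})

test_that("true-variance share identities hold for random parameter sets", {
  for (seed in 1:8) {
    co <- compute_coefficients(random_params(design_full(L = 2), seed))
    int <- co$role == "interchangeable_set"
    str <- co$role == "nonreference_structural"
    ## structural non-reference: consistency + method specificity = 1
    expect_equal(co$con_true[str] + co$ms_true[str],
                 rep(1, sum(str)), tolerance = 1e-12)
    ## interchangeable: consistency + common + unique specificity = 1
    expect_equal(co$con_true[int] + co$cms_true[int] + co$ums_true[int],
                 rep(1, sum(int)), tolerance = 1e-12)
    ## rater consistency = consistency + common method specificity
    expect_equal(co$rc_true[int], co$con_true[int] + co$cms_true[int],
                 tolerance = 1e-12)
    ## observed scale: systematic shares + error share = 1
    expect_equal(co$con_observed[int] + co$cms_observed[int] +
                   co$ums_observed[int] + (1 - co$rel[int]),
                 rep(1, sum(int)), tolerance = 1e-12)
    expect_equal(co$con_observed[str] + co$ms_observed[str],
                 co$rel[str], tolerance = 1e-12)
  }
})

test_that("vanishing method loadings give pure consistency", {
  params <- random_params(design_ri(L = 1), 3)
  params$Lambda_B[, params$factors_B$type == "CM"] <- 0
  params$Lambda_W[] <- 0
  co <- compute_coefficients(params)
  int <- co$role == "interchangeable_set"
  expect_equal(co$con_true[int], rep(1, sum(int)))
  expect_equal(co$cms_true[int], rep(0, sum(int)))
  expect_equal(co$ums_true[int], rep(0, sum(int)))
})

test_that("zero true variance yields an explicit undefined marker", {
  design <- design_ri(L = 1)
  params <- random_params(design, 4)
  params$Lambda_B[] <- 0
  params$Lambda_W[] <- 0
  co <- compute_coefficients(params)
  expect_true(all(is.na(co$con_true)))
  expect_true(all(is.na(co$rc_true[co$role == "interchangeable_set"])))
})

test_that("rater consistency equals the brute-force intraclass correlation", {
  ## simulate error-free rater scores directly from the latent variables and
  ## compare their between-target variance share with the rc coefficient
  design <- design_ri(L = 1, n_targets = 30000, n_raters = 2)
  pop <- derive_population_params(population_targets("low"), design)
  co <- compute_coefficients(pop)
  set.seed(2024)
  n_t <- 30000
  S <- rnorm(n_t); CM <- rnorm(n_t)
  lamS <- pop$Lambda_B[pop$vars$level == "rater",
                       pop$factors_B$type == "S"][1]
  lamCM <- pop$Lambda_B[pop$vars$level == "rater",
                        pop$factors_B$type == "CM"][1]
  lamUM <- pop$Lambda_W[1, 1]
  score <- function() lamS * S + lamCM * CM + lamUM * rnorm(n_t)
  r1 <- score(); r2 <- score()
  icc <- cov(r1, r2) / sqrt(var(r1) * var(r2))
  rc <- co$rc_true[co$role == "interchangeable_set"][1]
  expect_equal(icc, rc, tolerance = 0.02)
})

test_that("latent mean change is recovered and null means stay null", {
  design <- design_ri(L = 2, n_targets = 300, n_raters = 4)
  tpl <- build_template(design, mi = "strong")
  ## population without mean change: estimate within sampling error of zero
  pop0 <- derive_population_params(population_targets("low"), design,
                                   mean_change = 0)
  fit0 <- fit_ml(tpl, data = simulate_dataset(pop0, design, seed = 61))
  m0 <- latent_state_means(fit0)
  expect_lt(abs(m0$estimate), 3 * m0$se)
  ## exact population moments: estimate equals the aligned population mean
  pop <- derive_population_params(population_targets("low"), design,
                                  mean_change = 0.5)
  truth <- align_params(pop, tpl)
  st <- make_exact_stats(tpl, truth, T_n = 300, n_r = 4)
  fit <- fit_ml(tpl, stats = st)
  m <- latent_state_means(fit)
  want <- unname(truth$factor_means[truth$factors_B$type == "S" &
                                      truth$factors_B$l == 2])
  expect_equal(m$estimate, want, tolerance = 1e-4)
})

test_that("latent mean change needs strong invariance", {
  design <- design_ri(L = 2, n_targets = 150, n_raters = 3)
  pop <- derive_population_params(population_targets("low"), design)
  dat <- simulate_dataset(pop, design, seed = 5)
  fit_weak <- fit_ml(build_template(design, mi = "weak"), data = dat,
                     se = FALSE, chisq = FALSE)
  expect_error(latent_state_means(fit_weak), "strong")
})
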