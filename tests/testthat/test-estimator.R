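test_that("sufficient statistics match a hand computation on a toy dataset", {
  design <- design_spec(2, 1, c("reference_structural", "interchangeable_set"),
                        1, n_targets = 2, n_raters = 2)
  tpl <- build_template(design, mi = "configural")
  bn <- tpl$vars$name[tpl$vars$level == "between"]
  wn <- tpl$vars$name[tpl$vars$level == "rater"]
  tt <- data.frame(target_id = 1:2)
  tt[bn] <- list(c(1, 3), c(2, 5))
  rt <- data.frame(target_id = c(1, 1, 2, 2), rater_id = c(1, 2, 1, 2))
  rt[wn] <- list(c(1, 3, 2, 4), c(1, 5, 0, 2))
  st <- compute_sufficient_stats(list(target_table = tt, rater_table = rt),
                                 tpl)
  expect_length(st$groups, 1)
  g <- st$groups[[1]]
  ## cluster means: (2,3) and (3,1); between vectors [x; ybar]
  expect_equal(unname(g$mean), c(2, 3.5, 2.5, 2))
  ## pooled within scatter of deviations (-1,-2),(1,2),(-1,-1),(1,1)
  expect_equal(unname(g$SW), matrix(c(4, 6, 6, 10), 2))
  dev1 <- c(1, 2, 2, 3) - g$mean
  expect_equal(unname(g$SB), 2 * outer(unname(dev1), unname(dev1)))
  expect_equal(g$d, 2)
})

test_that("all raters identical within targets give zero within scatter", {
  design <- design_ri(L = 1, n_targets = 5, n_raters = 3)
  tpl <- build_template(design)
  pop <- derive_population_params(population_targets("low"), design)
  dat <- simulate_dataset(pop, design, seed = 1)
  wn <- tpl$vars$name[tpl$vars$level == "rater"]
  first <- !duplicated(dat$rater_table$target_id)
  for (cn in wn) {
    dat$rater_table[[cn]] <- rep(dat$rater_table[[cn]][first], each = 3)
  }
  st <- compute_sufficient_stats(dat, tpl)
  expect_equal(max(abs(st$groups[[1]]$SW)), 0)
})

test_that("sufficient statistics are invariant to row order", {
  design <- design_ri(L = 1, n_targets = 12, n_raters = 3)
  pop <- derive_population_params(population_targets("low"), design)
  dat <- simulate_dataset(pop, design, seed = 8)
  tpl <- build_template(design)
  st1 <- compute_sufficient_stats(dat, tpl)
  set.seed(1)
  shuf <- dat
  shuf$rater_table <- shuf$rater_table[sample(nrow(shuf$rater_table)), ]
  st2 <- compute_sufficient_stats(shuf, tpl)
  expect_equal(st1$groups, st2$groups)
  expect_equal(st1$grand_mean, st2$grand_mean)
})

test_that("missing columns are reported by name", {
  design <- design_ri(L = 1, n_targets = 5, n_raters = 2)
  pop <- derive_population_params(population_targets("low"), design)
  dat <- simulate_dataset(pop, design, seed = 1)
  tpl <- build_template(design)
  names(dat$rater_table)[3] <- "wrong"
  expect_error(compute_sufficient_stats(dat, tpl), "Y\\[1.1.2.1\\]")
})

test_that("structured likelihood equals the dense per-target oracle", {
  configs <- list(
    list(design = design_full(L = 2, n_targets = 12, n_raters = 3),
         mi = "strong", seed = 21),
    list(design = design_ri(L = 1, n_targets = 10, n_raters = 2),
         mi = "configural", seed = 22),
    list(design = design_ref_only(L = 2, n_targets = 15), mi = "strong",
         seed = 23))
  for (cfg in configs) {
    tpl <- build_template(cfg$design, mi = cfg$mi)
    pop <- derive_population_params(population_targets("low"), cfg$design)
    ap <- align_params(pop, tpl)
    dat <- simulate_dataset(pop, cfg$design, seed = cfg$seed)
    st <- compute_sufficient_stats(dat, tpl)
    ll <- loglikelihood(tpl, ap, st)
    dense <- dense_loglik(dat, tpl, ap)
    expect_lt(abs(ll - dense) / abs(dense), 1e-8)
    ## compiled path agrees with the R reference path
    cm <- lscom:::compile_model(tpl)
    cpp <- -0.5 * lscom:::cpp_neg2ll(lscom:::params_to_theta(cm, ap),
                                     cm$cpp, lscom:::stats_for_cpp(st))
    expect_lt(abs(cpp - ll) / abs(ll), 1e-10)
  }
  ## unbalanced clusters against the dense oracle
  nr <- rep(2:4, length.out = 9)
  design <- design_spec(3, 1, c("reference_structural", "interchangeable_set"),
                        1, n_targets = 9, n_raters = nr)
  tpl <- build_template(design, mi = "configural")
  pop <- derive_population_params(population_targets("high"), design)
  ap <- align_params(pop, tpl)
  dat <- simulate_dataset(pop, design, seed = 31)
  st <- compute_sufficient_stats(dat, tpl)
  expect_lt(abs(loglikelihood(tpl, ap, st) - dense_loglik(dat, tpl, ap)) /
              abs(dense_loglik(dat, tpl, ap)), 1e-8)
})

test_that("group decomposition is consistent under artificial splitting", {
  design <- design_ri(L = 1, n_targets = 20, n_raters = 3)
  tpl <- build_template(design)
  pop <- derive_population_params(population_targets("low"), design)
  ap <- align_params(pop, tpl)
  dat <- simulate_dataset(pop, design, seed = 13)
  st <- compute_sufficient_stats(dat, tpl)
  half <- function(ids) {
    d <- list(target_table = dat$target_table[
                dat$target_table$target_id %in% ids, ],
              rater_table = dat$rater_table[
                dat$rater_table$target_id %in% ids, ])
    compute_sufficient_stats(d, tpl)
  }
  stA <- half(1:10); stB <- half(11:20)
  split_stats <- st
  split_stats$groups <- c(stA$groups, stB$groups)
  expect_equal(loglikelihood(tpl, ap, split_stats),
               loglikelihood(tpl, ap, st), tolerance = 1e-10)
  ## likelihood is invariant to target relabeling
  relab <- dat
  perm <- c(20:1)
  relab$target_table$target_id <- perm
  relab$rater_table$target_id <- perm[relab$rater_table$target_id]
  expect_equal(loglikelihood(tpl, ap, compute_sufficient_stats(relab, tpl)),
               loglikelihood(tpl, ap, st), tolerance = 1e-10)
})

test_that("fitting exact moments recovers the population with zero misfit", {
  design <- design_full(L = 2, n_targets = 400, n_raters = 5)
  tpl <- build_template(design, mi = "strong")
  pop <- derive_population_params(population_targets("low"), design)
  truth <- align_params(pop, tpl)
  st <- make_exact_stats(tpl, truth, T_n = 400, n_r = 5)
  fit <- fit_ml(tpl, stats = st, se = FALSE)
  expect_true(fit$converged)
  expect_lt(fit$chi_square, 1e-3)
  cm <- fit$cm
  tr <- lscom:::natural_from_params(cm, truth)
  expect_lt(max(abs(fit$estimates$estimate - tr[fit$estimates$label])), 1e-3)
})

test_that("refitting from the solution is immediately stationary", {
  design <- design_ri(L = 1, n_targets = 120, n_raters = 4)
  tpl <- build_template(design)
  pop <- derive_population_params(population_targets("low"), design)
  dat <- simulate_dataset(pop, design, seed = 17)
  fit <- fit_ml(tpl, data = dat, se = FALSE, chisq = FALSE)
  refit <- fit_ml(tpl, data = dat, start = fit$params, se = FALSE,
                  chisq = FALSE)
  expect_true(refit$converged)
  expect_lte(refit$iterations, 2)
  expect_equal(refit$logL, fit$logL, tolerance = 1e-8)
})

test_that("the saturated model dominates and matches its own moments", {
  design <- design_ri(L = 1, n_targets = 40, n_raters = 2, I = 2)
  tpl <- build_template(design, mi = "configural")
  pop <- derive_population_params(population_targets("low"), design)
  dat <- simulate_dataset(pop, design, seed = 41)
  st <- compute_sufficient_stats(dat, tpl)
  sat <- fit_saturated(st)
  fit <- fit_ml(tpl, data = dat, se = FALSE)
  ## nesting: saturated logL is an upper bound; chi-square is nonnegative
  expect_gte(sat$logL, fit$logL - 1e-6)
  expect_gte(fit$chi_square, 0)
  ## the reported maximum equals the dense likelihood at the fitted moments
  dense_at <- dense_loglik_moments(dat, tpl, sat$mu, sat$Sigma_B, sat$Sigma_W)
  expect_lt(abs(dense_at - sat$logL) / abs(sat$logL), 1e-8)
  ## no perturbed candidate does better (maximum property, dense oracle)
  set.seed(1)
  for (r in 1:5) {
    mu2 <- sat$mu + rnorm(length(sat$mu), 0, 0.02)
    S2 <- sat$Sigma_W + diag(0.02, nrow(sat$Sigma_W))
    expect_lt(dense_loglik_moments(dat, tpl, mu2, sat$Sigma_B, S2), sat$logL)
  }
  ## the numeric route agrees with the closed form on balanced data
  num <- lscom:::saturated_numeric(st)
  expect_equal(num$logL, sat$logL, tolerance = 1e-4)
})

test_that("improper-solution detection flags constructed violations", {
  design <- design_ri(L = 2, n_targets = 100, n_raters = 3)
  pop <- derive_population_params(population_targets("low"), design)
  clean <- detect_heywood(pop)
  expect_false(clean$any)

  corr12 <- pop
  corr12$Phi_B[1, 2] <- corr12$Phi_B[2, 1] <- 1.2
  flagged <- detect_heywood(corr12)
  expect_true(flagged$flags$correlation_gt_1)
  expect_true(flagged$flags$Phi_B_nonPSD)

  negt <- pop
  negt$theta_B[1] <- -0.05
  expect_true(detect_heywood(negt)$flags$negative_theta)
})

test_that("estimates concentrate on the truth as samples grow", {
  design_small <- design_ri(L = 1, n_targets = 100, n_raters = 3)
  design_large <- design_ri(L = 1, n_targets = 600, n_raters = 10)
  err <- function(design, seeds) {
    tpl <- build_template(design)
    pop <- derive_population_params(population_targets("low"), design)
    cm <- lscom:::compile_model(tpl)
    tr <- lscom:::natural_from_params(cm, align_params(pop, tpl))
    mean(vapply(seeds, function(s) {
      dat <- simulate_dataset(pop, design, seed = s)
      fit <- fit_ml(tpl, data = dat, se = FALSE, chisq = FALSE)
      mean(abs(fit$estimates$estimate - tr[fit$estimates$label]))
    }, numeric(1)))
  }
  seeds <- 101:108
  expect_lt(err(design_large, seeds), err(design_small, seeds))
})

test_that("underidentified fits warn but still return a result", {
  design <- design_ri(L = 1, n_targets = 15, n_raters = 2)
  tpl <- build_template(design)
  pop <- derive_population_params(population_targets("low"), design)
  dat <- simulate_dataset(pop, design, seed = 2)
  expect_warning(fit <- fit_ml(tpl, data = dat, se = FALSE, chisq = FALSE,
                               n_starts = 0),
                 "fewer targets")
  expect_s3_class(fit, "lscom_fit")
})

test_that("invariance restrictions never raise the likelihood", {
  design <- design_ri(L = 2, n_targets = 200, n_raters = 4)
  pop <- derive_population_params(population_targets("low"), design)
  dat <- simulate_dataset(pop, design, seed = 55)
  cmp <- compare_mi(design, dat, levels = c("weak", "strong", "strict"),
                    chisq = TRUE)
  expect_true(all(diff(cmp$logL) <= 1e-6))
  expect_true(all(diff(cmp$chi_square) >= -1e-6))
  expect_true(all(cmp$converged))
})
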