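test_that("factor inventories follow the measurement equations", {
  ## reference method only: a plain latent state model, no method factors
  tpl <- build_template(design_ref_only(L = 3), mi = "configural")
  expect_equal(sum(tpl$factors_B$type == "S"), 3)
  expect_equal(sum(tpl$factors_B$type %in% c("M", "CM")), 0)
  expect_equal(nrow(tpl$factors_W), 0)
  expect_equal(tpl$p_w, 0)

  ## reference + interchangeable: one state, one common and one unique
  ## method factor per construct-occasion, no M factors
  tpl <- build_template(design_ri(L = 1), mi = "configural")
  expect_equal(as.vector(table(tpl$factors_B$type)[c("CM", "S")]), c(1, 1))
  expect_equal(sum(tpl$factors_B$type == "M"), 0)
  expect_equal(nrow(tpl$factors_W), 1)

  ## loadings follow the role: reference rows touch only S, structural
  ## non-reference rows S+M, interchangeable rows S+CM+UM
  tpl <- build_template(design_full(L = 2))
  tp <- tpl$params
  for (v in seq_len(nrow(tpl$vars))) {
    kinds <- tp$kind[tp$row == tpl$vars$name[v] & grepl("loading", tp$kind)]
    expected <- switch(tpl$vars$role[v],
      reference_structural = "loading_S",
      nonreference_structural = c("loading_S", "loading_M"),
      interchangeable_set = c("loading_S", "loading_CM", "loading_UM"))
    expect_setequal(kinds, expected)
  }
})

test_that("each latent factor is scaled by exactly one fixed loading", {
  for (mi in c("configural", "strong")) {
    tpl <- build_template(design_full(L = 2, J = 2), mi = mi)
    tp <- tpl$params
    all_factors <- c(tpl$factors_B$name, tpl$factors_W$name)
    for (f in all_factors) {
      fixed <- tp[grepl("loading", tp$kind) & tp$col == f &
                    tp$status == "fixed", ]
      expect_equal(nrow(fixed), 1L, info = f)
      expect_equal(fixed$value, 1)
      ## variance of that factor is free (never both fixed)
      v <- tp[tp$kind %in% c("var_B", "var_W") & tp$row == f, ]
      expect_equal(v$status, "free", info = f)
    }
  }
})

test_that("free-parameter counts match the enumeration oracle", {
  cases <- expand.grid(
    J = 1:2, L = 1:3,
    methods = c("ref", "ri", "full"),
    mi = c("configural", "weak", "strong", "strict"),
    stringsAsFactors = FALSE)
  for (r in seq_len(nrow(cases))) {
    roles <- switch(cases$methods[r],
      ref = "reference_structural",
      ri = c("reference_structural", "interchangeable_set"),
      full = c("reference_structural", "nonreference_structural",
               "interchangeable_set"))
    design <- design_spec(3, cases$J[r], roles, cases$L[r], 500,
                          if (length(roles) > 1) 5 else 0)
    got <- count_free_parameters(build_template(design, mi = cases$mi[r]))
    want <- oracle_free_count(3, cases$J[r], cases$L[r], roles, cases$mi[r])
    expect_equal(got, want,
                 info = paste(cases[r, ], collapse = "/"))
  }
})

test_that("hand-frozen counts and the large-model bound hold", {
  ## latent state model, 3 indicators, 2 occasions, strong invariance:
  ## 2 loadings + 3 intercepts + 1 latent mean + 3 state (co)variances +
  ## 6 residuals = 15
  expect_equal(count_free_parameters(
    build_template(design_ref_only(L = 2), mi = "strong")), 15)
  ## full three-method model, 1 construct, 2 occasions, strong: 58
  expect_equal(count_free_parameters(
    build_template(design_full(L = 2), mi = "strong")), 58)
  ## largest grid model exceeds 100 free parameters
  big <- count_free_parameters(
    build_template(design_full(L = 4, J = 2), mi = "strong"))
  expect_equal(big, 332)
  expect_gt(big, 100)
})

test_that("a fully fixed inventory counts zero free parameters", {
  tpl <- build_template(design_ri(L = 1))
  tpl$params$status <- "fixed"
  expect_equal(count_free_parameters(tpl), 0)
})

test_that("invariance nesting and design monotonicity hold", {
  design <- design_full(L = 3)
  counts <- vapply(c("configural", "weak", "strong", "strict"),
                   function(mi) {
                     count_free_parameters(build_template(design, mi = mi))
                   }, integer(1))
  expect_true(all(diff(counts) <= 0))

  base <- count_free_parameters(build_template(design_full(L = 2)))
  expect_gte(count_free_parameters(build_template(design_full(L = 3))), base)
  expect_gte(count_free_parameters(build_template(design_full(L = 2, J = 2))),
             base)
  expect_gte(count_free_parameters(build_template(design_full(L = 2))),
             count_free_parameters(build_template(design_ri(L = 2))))
})

test_that("templates round-trip through serialization", {
  tpl <- build_template(design_full(L = 2), mi = "strong")
  path <- withr::local_tempfile(fileext = ".yml")
  write_template(tpl, path)
  back <- read_template(path)
  expect_identical(back$params, tpl$params)
  expect_identical(back$mi, tpl$mi)
  expect_identical(back$design$methods, tpl$design$methods)
})
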