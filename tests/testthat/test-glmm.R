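# a small two-group dataset reused across fixtures
fixture_records <- function(seed = 21, n = 25, theta1 = 1.5, sigma_u = 0.5) {
  gw <- tibble::tibble(group = c("control", "treated"), w_cs_cr = c(0.45, 0.05))
  generate_preferences(gw, behavior_params(n_per_group = n, theta1 = theta1,
                                           sigma_u = sigma_u), seed = seed)
}

test_that("design matrix uses treatment coding with deterministic columns", {
  recs <- apply_retention_filter(fixture_records())
  d <- build_design(recs, "test_by_training")
  expect_equal(d$terms, c("(Intercept)", "testpost", "trainingtreated",
                          "testpost:trainingtreated"))
  expect_equal(d$ref_group, "control")
  d1 <- build_design(recs[recs$group == "control", ], "test_only")
  expect_equal(d1$terms, c("(Intercept)", "testpost"))
  expect_error(build_design(recs[0, ]), "no records")
  expect_error(build_design(recs[recs$group == "control", ], "test_by_training"),
               "two groups")
})

test_that("an animal whose pre-test was rejected keeps its post row", {
  recs <- make_records(
    animal_id = c("a1", "a1", "a2", "a2"),
    group = "g", test = c("pre", "post", "pre", "post"),
    sc = c(3, 60, 50, 40), scn = c(3, 60, 70, 80))  # a1 pre total 6 s
  kept <- apply_retention_filter(recs)
  d <- build_design(kept, "test_only")
  expect_equal(d$n_obs, 3)
  expect_equal(d$n_animals, 2)
})

test_that("with sigma_u = 0 the fit reduces to pooled logistic regression", {
  # every animal identical: pre 150/240, post 90/240; the pooled MLE of the
  # post effect is the log odds-ratio 2*log(3/5)
  recs <- make_records(
    animal_id = rep(c("a", "b", "c"), each = 2),
    group = "g", test = rep(c("pre", "post"), 3),
    sc = rep(c(150, 90), 3), scn = rep(c(90, 150), 3))
  fit <- fit_preference_glmm(recs, design = "test_only", sigma_u = 0)
  expect_true(fit$converged)
  expect_equal(unname(fit$beta["testpost"]), 2 * log(3 / 5), tolerance = 1e-6)
  expect_equal(unname(fit$beta["(Intercept)"]), log(150 / 90), tolerance = 1e-6)
  # identical to glm
  g <- glm(cbind(sc, scn) ~ test,
           data = data.frame(sc = rep(c(150, 90), 3), scn = rep(c(90, 150), 3),
                             test = factor(rep(c("pre", "post"), 3),
                                           levels = c("pre", "post"))),
           family = binomial)
  expect_equal(unname(fit$beta), unname(coef(g)), tolerance = 1e-6)
})

test_that("fits are deterministic and stable across quadrature precision", {
  recs <- fixture_records()
  f1 <- fit_preference_glmm(recs)
  f2 <- fit_preference_glmm(recs)
  expect_identical(f1$beta, f2$beta)

  f25 <- fit_preference_glmm(recs, quadrature_nodes = 25)
  expect_lt(max(abs(f1$beta - f25$beta)), 1e-4)
  expect_lt(abs(f1$sigma_u - f25$sigma_u), 1e-4)

  fl <- fit_preference_glmm(recs, quadrature_nodes = 1)  # Laplace
  expect_true(fl$converged)
  expect_lt(max(abs(fl$beta - f1$beta)), 0.05)
})

test_that("estimates match lme4 on matched data", {
  skip_if_not_installed("lme4")
  recs <- apply_retention_filter(fixture_records(seed = 31))
  fit <- fit_preference_glmm(recs, filter_retained = FALSE)
  df <- recs
  df$test <- factor(df$test, levels = c("pre", "post"))
  df$training <- factor(df$group, levels = c("control", "treated"))
  m <- lme4::glmer(
    cbind(seconds_conditioned, seconds_control) ~ test * training +
      (1 | animal_id),
    data = df, family = binomial, nAGQ = 9)
  expect_lt(max(abs(lme4::fixef(m) - fit$beta)), 1e-2)
  expect_lt(abs(sqrt(unlist(lme4::VarCorr(m))) - fit$sigma_u), 1e-2)
})

test_that("parameter recovery: estimates fall within 3 SE of the truth", {
  theta0 <- 0.2; theta1 <- 1.2
  gw <- tibble::tibble(group = c("control", "treated"), w_cs_cr = c(0, 0.8))
  bp <- behavior_params(n_per_group = 40, theta0 = theta0, theta1 = theta1,
                        sigma_u = 0.5)
  recs <- generate_preferences(gw, bp, seed = 101)
  fit <- fit_preference_glmm(recs)
  expect_true(fit$converged)
  truth <- c(theta0, 0, 0, -theta1 * 0.8)  # control group has no decline
  expect_true(all(abs(fit$beta - truth) < 3 * fit$se))
  expect_equal(fit$sigma_u, 0.5, tolerance = 0.35)
})

test_that("Wald table carries z, two-sided p and the 0.05 flag", {
  recs <- fixture_records()
  fit <- fit_preference_glmm(recs)
  w <- wald_tests(fit)
  expect_equal(w$statistic, unname(fit$beta / fit$se))
  expect_equal(w$p.value, unname(2 * pnorm(-abs(fit$beta / fit$se))))
  expect_equal(w$significant, w$p.value < 0.05)
  expect_equal(tidy(fit), w)
  g <- glance(fit)
  expect_equal(g$n_obs, fit$n_obs)

  bad <- fit
  bad$converged <- FALSE
  expect_error(wald_tests(bad), "converge")
})

test_that("analyze_experiment reproduces the blocking summary pattern", {
  gw <- tibble::tibble(group = c("control", "blocking"),
                       w_cs_cr = c(0.42, 0.024))
  recs <- generate_preferences(gw, behavior_params(theta1 = 2), seed = 51)
  an <- analyze_experiment(recs)
  expect_s3_class(an$fit, "pe_glmm")
  # control declines post vs pre; blocked group does not
  gd <- an$group_declines
  expect_true(gd$significant_decline[gd$group == "control"])
  expect_false(gd$significant_decline[gd$group == "blocking"])
  cells <- an$cells
  ctrl_pre <- cells$median[cells$group == "control" & cells$test == "pre"]
  ctrl_post <- cells$median[cells$group == "control" & cells$test == "post"]
  blk_pre <- cells$median[cells$group == "blocking" & cells$test == "pre"]
  blk_post <- cells$median[cells$group == "blocking" & cells$test == "post"]
  expect_lt(ctrl_post, ctrl_pre - 0.1)
  expect_lt(abs(blk_post - blk_pre), 0.1)
  # the interaction term is reported and positive (control-relative recovery)
  expect_true("testpost:trainingblocking" %in% an$wald$term)

  empty <- recs[recs$seconds_conditioned + recs$seconds_control < 10, ]
  expect_error(analyze_experiment(empty), "retention")
})
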