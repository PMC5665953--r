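test_that("dopamine activity is the rectified US prediction error", {
  lp <- learning_params()
  st <- circuit_state(c("X", "Y"))

  expect_equal(da_activity(st, "X", 1, lp), 1)  # nothing predicted
  st$w_cs_da["X"] <- 1
  expect_equal(da_activity(st, "X", 1, lp), 0)  # fully predicted US
  st$w_cs_da["X"] <- 0.6
  expect_equal(da_activity(st, "X", 1, lp), 0.4)
  expect_equal(da_activity(st, "X", 0, lp), 0)  # rectification floor
  lp_signed <- learning_params(rectify_error = FALSE)
  expect_equal(da_activity(st, "X", 0, lp_signed), -0.6)
  # summed over the presented set
  st$w_cs_da["Y"] <- 0.3
  expect_equal(da_activity(st, c("X", "Y"), 1, lp), 1 - 0.9)
  expect_error(da_activity(st, "X", -1, lp))
})

test_that("one trial updates both pathways, gated by flupentixol only", {
  lp <- learning_params(salience = uniform_salience)
  ev <- list(kind = "paired", cs = "X", us = 1)
  st0 <- circuit_state("X")

  st <- apply_trial(st0, ev, pharmacology_state(), lp)
  expect_equal(unname(st$w_cs_cr["X"]), 0.3)
  expect_equal(unname(st$w_cs_da["X"]), 0.3)

  st_flu <- apply_trial(st0, ev, pharmacology_state(flupentixol_active = TRUE), lp)
  expect_equal(unname(st_flu$w_cs_cr["X"]), 0)     # response pathway blocked
  expect_equal(unname(st_flu$w_cs_da["X"]), 0.3)   # prediction pathway spared

  st_epi <- apply_trial(st0, ev, pharmacology_state(epinastine_active = TRUE), lp)
  expect_equal(st_epi$w_cs_cr, st$w_cs_cr)         # no effect on aversive circuit
  expect_equal(st_epi$w_cs_da, st$w_cs_da)

  st_us <- apply_trial(st0, list(kind = "us_alone", cs = "", us = 1),
                       pharmacology_state(), lp)
  expect_equal(unname(st_us$w_cs_cr["X"]), 0)      # no eligible CS
  expect_error(apply_trial(st0, list(kind = "paired", cs = "Z", us = 1),
                           pharmacology_state(), lp),
               "unknown stimulus")
})

test_that("simulated lone-CS acquisition matches the closed form exactly", {
  for (alpha in c(0.05, 0.3, 0.7, 1)) {
    for (lambda in c(0.5, 1, 2)) {
      lp <- learning_params(lambda_us = lambda, alpha_cr = alpha,
                            alpha_da = alpha, salience = uniform_salience)
      traj <- run_protocol(make_lone_protocol(12), lp)
      fw <- final_weights(traj)
      expected <- closed_form_single_cs(12, alpha, lambda)
      expect_equal(fw$w_cs_cr, expected, tolerance = 1e-12)
      expect_equal(fw$w_cs_da, expected, tolerance = 1e-12)
    }
  }
  expect_equal(closed_form_single_cs(0, 0.3), 0)
  expect_equal(closed_form_single_cs(2, 0.3), 0.51)
  expect_equal(closed_form_single_cs(1000, 0.3, 2), 2)  # asymptote
  expect_error(closed_form_single_cs(2, 1.5))
})

test_that("weights are non-negative, bounded and monotone; error decays", {
  lp <- learning_params(salience = uniform_salience)
  traj <- run_protocol(make_lone_protocol(30), lp)
  expect_true(all(traj$w_cs_cr >= 0) && all(traj$w_cs_da >= 0))
  expect_true(all(traj$w_cs_cr <= lp$lambda_us + 1e-12))
  expect_true(all(diff(traj$w_cs_cr) >= 0))
  expect_true(all(diff(traj$delta) <= 1e-12))
})

test_that("unpaired CS/US sequences leave the circuit unchanged", {
  lp <- learning_params(salience = uniform_salience)
  p <- build_protocol("auto_blocking_control")
  traj <- run_protocol(p, lp)
  ph1 <- traj[traj$phase == 1, ]
  expect_true(all(ph1$w_cs_cr == 0) && all(ph1$w_cs_da == 0))
  # and the day-2 pairings then follow plain 2-trial acquisition
  expect_equal(final_weights(traj)$w_cs_cr, 0.51, tolerance = 1e-12)
})

test_that("epinastine leaves the whole trajectory element-wise unchanged", {
  lp <- learning_params(salience = uniform_salience)
  p_epi <- build_protocol("epinastine_control")
  p_off <- p_epi
  p_off$phases$epinastine <- FALSE
  t_epi <- run_protocol(p_epi, lp)
  t_off <- run_protocol(p_off, lp)
  expect_equal(tibble::as_tibble(t_epi), tibble::as_tibble(t_off))
})

test_that("trajectory matches the independent hand-iterated oracle", {
  lp <- learning_params(salience = uniform_salience)
  p <- build_protocol("blocking_olfactory")
  traj <- run_protocol(p, lp)
  ora <- oracle_two_pathway(
    stimuli = c("odor_maple", "pattern_white_center"),
    cs_list = c(replicate(8, "pattern_white_center", simplify = FALSE),
                replicate(2, c("odor_maple", "pattern_white_center"),
                          simplify = FALSE)),
    us = rep(1, 10))
  fw <- final_weights(traj)
  expect_equal(setNames(fw$w_cs_cr, fw$stimulus), ora$w_cr, tolerance = 1e-12)
  expect_equal(setNames(fw$w_cs_da, fw$stimulus), ora$w_da, tolerance = 1e-12)
})

test_that("learned verdict thresholds the response-pathway weight", {
  lp <- learning_params(salience = uniform_salience)
  expect_equal(learned_verdict(run_protocol(build_protocol("control_Y_plus"), lp)),
               "learned")                       # 0.51 >= 0.1
  st <- circuit_state("X")
  expect_equal(learned_verdict(st, "X", threshold = 0.1), "not_learned")
  st$w_cs_cr["X"] <- 0.030
  expect_equal(learned_verdict(st, "X", threshold = 0.1), "not_learned")
  expect_error(learned_verdict(st, "nope", threshold = 0.1), "unknown stimulus")
})

test_that("default visual salience equates 8-trial visual with 2-trial olfactory", {
  lp <- learning_params()  # salience visual = 0.28
  t_vis <- run_protocol(make_lone_protocol(8, "pattern_white_center"), lp)
  t_olf <- run_protocol(make_lone_protocol(2, "odor_maple"), lp)
  expect_equal(final_weights(t_vis)$w_cs_cr, final_weights(t_olf)$w_cs_cr,
               tolerance = 0.02)
})
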