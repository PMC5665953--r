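test_that("builders reproduce the published designs trial for trial", {
  p <- build_protocol("blocking_olfactory")
  ph1 <- p$events[p$events$phase == 1, ]
  ph2 <- p$events[p$events$phase == 2, ]
  expect_equal(nrow(ph1), 8)
  expect_true(all(ph1$kind == "paired") && all(ph1$cs == "pattern_white_center"))
  expect_equal(nrow(ph2), 2)
  expect_true(all(ph2$cs == "odor_maple+pattern_white_center"))
  expect_equal(unique(p$phases$iti_s[p$phases$phase == 1]), 300)  # 5 min ITI
  expect_equal(p$phases$gap_after_s[1], 1200)                     # 20 min gap
  expect_equal(p$target, "odor_maple")

  u <- build_protocol("unpaired_control_olfactory")
  u1 <- u$events[u$events$phase == 1, ]
  expect_equal(sum(u1$kind == "cs_alone"), 8)
  expect_equal(sum(u1$kind == "us_alone"), 8)
  # each CS-US separation is 150 s (2.5 min)
  sep <- u1$time_s[u1$kind == "us_alone"] - u1$time_s[u1$kind == "cs_alone"]
  expect_true(all(sep == 150))

  ab <- build_protocol("auto_blocking_flupentixol")
  expect_true(ab$phases$flupentixol[1])
  expect_false(ab$phases$flupentixol[2])       # drug-free after recovery
  expect_equal(ab$phases$day, c(1L, 2L))       # phase 2 on the next day
  expect_equal(sum(ab$events$phase == 1), 6)
  expect_equal(sum(ab$events$phase == 2), 2)
  abc <- build_protocol("auto_blocking_control")
  expect_equal(unique(abc$phases$iti_s[abc$phases$phase == 1]), 150)  # 2.5 min

  epi <- build_protocol("epinastine_control")
  expect_true(epi$phases$epinastine[1] && !epi$phases$flupentixol[1])

  bv <- build_protocol("blocking_visual")
  expect_equal(sum(bv$events$phase == 1), 2)
  expect_equal(sum(bv$events$phase == 2), 8)
  expect_equal(bv$target, "pattern_white_center")

  expect_equal(nrow(build_protocol("compound_olfactory")$events), 2)
  expect_equal(nrow(build_protocol("compound_visual")$events), 8)

  expect_error(build_protocol("no_such_design"), "Valid names")
})

test_that("all builders validate with zero violations", {
  for (nm in protocol_names()) {
    expect_length(validate_protocol(build_protocol(nm)), 0)
  }
  # counterbalanced odor identity
  p <- build_protocol("control_Y_plus", conditioned_odor = "vanilla")
  expect_equal(p$target, "odor_vanilla")
  expect_length(validate_protocol(p), 0)
})

test_that("validator reports structural violations without raising", {
  p <- build_protocol("control_Y_plus")
  p$phases$iti_s <- 0
  expect_match(validate_protocol(p), "iti_s must be positive", all = FALSE)

  # cs_alone followed 3 s later by us_alone: inside the 5 s pairing window
  q <- protocol(
    name = "bad_window", target = "X",
    stimuli = tibble::tibble(stimulus = "X", modality = "olfactory"),
    phases = tibble::tibble(phase = 1L, label = "a", day = 1L, iti_s = 300,
                            flupentixol = FALSE, epinastine = FALSE),
    events = tibble::tibble(phase = 1L, trial = c(1L, 1L),
                            kind = c("cs_alone", "us_alone"),
                            cs = c("X", ""), us = c(0L, 1L),
                            time_s = c(0, 6))  # 6 - (0 + 3 s CS) = 3 s gap
  )
  expect_match(validate_protocol(q), "pairing window", all = FALSE)

  r <- build_protocol("control_Y_plus")
  r$events$cs[1] <- "odor_unknown"
  expect_match(validate_protocol(r), "unknown stimulus", all = FALSE)
})

test_that("protocols round-trip through YAML and JSON losslessly", {
  p <- build_protocol("blocking_olfactory")
  for (ext in c(".yaml", ".json")) {
    f <- withr::local_tempfile(fileext = ext)
    write_protocol(p, f)
    expect_equal(read_protocol(f), p)
  }
})

test_that("a document missing its target fails to parse at /target", {
  f <- withr::local_tempfile(fileext = ".yaml")
  write_protocol(build_protocol("control_Y_plus"), f)
  doc <- yaml::read_yaml(f)
  doc$target <- NULL
  yaml::write_yaml(doc, f)
  expect_error(read_protocol(f), "/target")
})

test_that("a hand-written multi-phase custom protocol parses and validates", {
  f <- withr::local_tempfile(fileext = ".yaml")
  custom <- protocol(
    name = "custom3", target = "odor_maple",
    stimuli = tibble::tibble(stimulus = c("odor_maple", "pattern_white_center"),
                             modality = c("olfactory", "visual")),
    phases = tibble::tibble(phase = 1:3, label = c("a", "b", "c"),
                            day = c(1L, 1L, 2L), iti_s = 300,
                            flupentixol = c(TRUE, FALSE, FALSE),
                            epinastine = FALSE),
    events = tibble::tibble(
      phase = c(1L, 2L, 3L), trial = 1L, kind = "paired",
      cs = c("odor_maple", "pattern_white_center",
             "odor_maple+pattern_white_center"),
      us = 1L, time_s = 0)
  )
  write_protocol(custom, f)
  back <- read_protocol(f)
  expect_equal(back, custom)
  expect_length(validate_protocol(back), 0)
  expect_s3_class(run_protocol(back), "pe_trajectory")
})
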