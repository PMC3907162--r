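test_that("the do-case table has exactly 3 failure and 3 success cases", {
  tab <- dispatch_table()
  expect_identical(nrow(tab), 6L)
  expect_identical(sort(tab$case), c("F1", "F2", "F3", "S1", "S2", "S3"))
  expect_identical(sum(tab$state == "FAILURE"), 3L)
  expect_identical(sum(tab$state == "SUCCESS"), 3L)
  # dispatch is total on the six cases and errors elsewhere
  for (i in seq_len(nrow(tab)))
    expect_silent(dispatch(tab$phase[i], tab$state[i]))
  expect_error(dispatch("REWARD", "SUCCESS"), "undefined dispatch case")
})

test_that("dispatch maps each situation to the prescribed command", {
  # black screen, no target -> present the fixation target
  expect_identical(as.character(dispatch("PRE", "FAILURE")), "grendot")
  # gaze at target location before any target -> same re-presentation
  expect_identical(as.character(dispatch("PRE", "SUCCESS")), "grendot")
  # initial fixation complete -> test stimulus
  expect_identical(as.character(dispatch("FIX", "SUCCESS")), "SndPICn")
  # failures during fixation or test, and test success -> black screen
  expect_identical(as.character(dispatch("FIX", "FAILURE")), "blank")
  expect_identical(as.character(dispatch("TEST", "FAILURE")), "blank")
  expect_identical(as.character(dispatch("TEST", "SUCCESS")), "blank")
})

test_that("association trials place the paired stimulus at screen center", {
  task <- task_spec("ASSOCIATION", pairs = list(c("call1.wav", "img1.png")))
  plan <- plan_trial(task)
  expect_identical(plan$fixation_token, "grendot")
  expect_identical(plan$test_token, "SndPICn")
  expect_identical(plan$target_pos, c(0, 0))
  expect_identical(plan$side, "CENTER")
  expect_identical(plan$pair, c("call1.wav", "img1.png"))
})

test_that("left/right side draws are uniform and seed-reproducible", {
  task <- task_spec("LEFT_RIGHT", offset_deg = 10)
  set.seed(11)
  sides <- replicate(10000, plan_trial(task)$side)
  frac_left <- mean(sides == "LEFT")
  expect_lt(abs(frac_left - 0.5), 3 * sqrt(0.25 / 10000))
  set.seed(11)
  again <- replicate(10000, plan_trial(task)$side)
  expect_identical(sides, again)
  # the plan's position matches the drawn side
  set.seed(3)
  p <- plan_trial(task)
  expect_identical(p$target_pos[1], if (p$side == "LEFT") -10 else 10)
})

test_that("distracter tasks place stimuli as specified", {
  sd_task <- task_spec("SINGLE_DISTRACTER",
                       pairs = list(c("a.wav", "a.png"), c("b.wav", "b.png")),
                       offset_deg = 8)
  set.seed(5)
  p <- plan_trial(sd_task)
  expect_identical(length(p$distracters), 1L)
  # target and distracter on opposite sides
  expect_identical(p$distracters[[1]]$pos[1], -p$target_pos[1])
  # fixed-position task copies its positions verbatim on every trial
  md <- task_spec("MULTI_DISTRACTER",
                  distracter_positions = list(c(-8, 0), c(8, 0), c(0, 8)))
  for (k in 1:3) {
    pm <- plan_trial(md)
    expect_identical(lapply(pm$distracters, `[[`, "pos"),
                     list(c(-8, 0), c(8, 0), c(0, 8)))
  }
  expect_error(task_spec("MULTI_DISTRACTER"), "config error")
})

test_that("scenario switching rolls the data file over losslessly", {
  out <- tempfile("sess"); dir.create(out)
  s <- session_open("subj01", "ASSOCIATION", out)
  cfg <- oracle_monitor_cfg()
  res <- run_trial(
    data.frame(t_us = seq(0, 1.5e6, by = 1000), x = 2048, y = 2048),
    cfg, c(1948, 2348, 1948, 2348))
  session_record_trial(s, res)
  first_file <- s$data_file
  switch_scenario(s, "LEFT_RIGHT")
  expect_false(identical(s$data_file, first_file))
  expect_identical(s$trial_counter, 0L)
  # first file is closed and complete
  d1 <- read.csv(first_file)
  expect_identical(nrow(d1), 1L)
  expect_identical(d1$outcome, "REWARDED")
  # zero-trial switch leaves a header-only file behind
  switch_scenario(s, "ASSOCIATION")
  files <- session_quit(s)
  expect_identical(length(files), 3L)
  expect_identical(nrow(read.csv(files[2])), 0L)
  expect_true(all(file.exists(files)))
})
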