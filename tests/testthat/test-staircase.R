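test_that("configuration validates schedule lengths and stop rules", {
  cfg <- staircase_config(6, c(1, 0.5), 1, max_trials = 36)
  expect_s3_class(cfg, "staircase_config")
  expect_s3_class(staircase_config(6, c(1, 0.5, 0.2), c(2, 4), max_trials = 50),
                  "staircase_config")
  expect_error(staircase_config(6, c(1, 0.5), numeric(0), max_trials = 36),
               class = "amtrack_config_error")
  expect_error(staircase_config(6, c(1, -0.5), 1, max_trials = 36),
               class = "amtrack_config_error")
  expect_error(staircase_config(6, 1, max_trials = NULL, max_reversals = NULL),
               class = "amtrack_config_error")
  expect_error(staircase_config(6, 1, n_up = 2, max_trials = 10),
               class = "amtrack_config_error")
})

test_that("initialization starts at the configured value with empty history", {
  sc <- staircase_init(paper_staircase_config())
  expect_equal(sc$value, 6)
  expect_equal(sc$trial_index, 0L)
  expect_equal(sc$consecutive_correct, 0L)
  expect_equal(nrow(staircase_reversals(sc)), 0L)
  expect_false(staircase_is_finished(sc))
})

test_that("3-down-1-up updates move, reset and record reversals correctly", {
  cfg <- paper_staircase_config()
  # three consecutive correct answers execute one down step of the initial size
  sc <- drive_staircase(c(TRUE, TRUE), cfg)
  expect_equal(sc$value, 6)                       # counter below criterion
  sc <- staircase_update(sc, TRUE)
  expect_equal(sc$value, 5)
  expect_equal(sc$consecutive_correct, 0L)

  # a wrong answer steps up; direction change records a reversal and the
  # schedule advances so the next executed step uses 0.5 dB
  expect_equal(staircase_current_step(sc), 1)
  sc <- staircase_update(sc, FALSE)
  expect_equal(sc$value, 6)
  rev <- staircase_reversals(sc)
  expect_equal(nrow(rev), 1L)
  expect_equal(rev$step, 1)                       # size in effect when reversing
  expect_equal(staircase_current_step(sc), 0.5)
  # C, C, W: the two corrects cause no movement, the wrong steps up
  sc2 <- drive_staircase(c(TRUE, TRUE, FALSE), cfg)
  expect_equal(sc2$value, 7)
  expect_equal(staircase_history(sc2)$value, c(6, 6, 6))

  # updating a finished staircase is an error
  done <- drive_staircase(rep(TRUE, 9), paper_staircase_config(max_trials = 9))
  expect_true(staircase_is_finished(done))
  expect_error(staircase_update(done, TRUE), class = "amtrack_state_error")
})

test_that("fixed 20-trial sequence matches the independent replay oracle", {
  answers <- c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE, FALSE,
               TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE)
  cfg <- staircase_config(6, c(1, 0.5, 0.2), c(1, 3), max_trials = 20)
  sc <- drive_staircase(answers, cfg)
  oracle <- replay_updown(answers, 6, c(1, 0.5, 0.2), c(1, 3))
  expect_equal(staircase_history(sc)$value, oracle$presented)
  expect_equal(sc$value, oracle$final)
  expect_equal(staircase_reversals(sc)$trial, oracle$rev_trials)
  expect_equal(staircase_reversals(sc)$step, oracle$rev_steps)
})

test_that("replay oracle equivalence holds over many random configurations", {
  set.seed(20240917)
  for (case in 1:1000) {
    n <- sample(10:40, 1)
    answers <- runif(n) < runif(1, 0.4, 0.95)
    n_steps <- sample(1:3, 1)
    steps <- round(runif(n_steps, 0.1, 2), 2)
    cps <- if (n_steps > 1) sort(sample(1:6, n_steps - 1)) else numeric(0)
    mode <- sample(c("reversal", "trial"), 1)
    start <- round(runif(1, -5, 8), 1)
    nd <- sample(2:4, 1)
    cfg <- staircase_config(start, steps, cps, n_down = nd,
                            schedule_mode = mode, max_trials = n)
    sc <- drive_staircase(answers, cfg)
    oracle <- replay_updown(answers, start, steps, cps, n_down = nd, mode = mode)
    expect_equal(sc$value, oracle$final)
    expect_equal(staircase_history(sc)$value, oracle$presented)
    expect_equal(staircase_reversals(sc)$trial, oracle$rev_trials)
  }
})

test_that("tracked value stays on the lattice spanned by the step sizes", {
  set.seed(7)
  cfg <- staircase_config(6, c(1, 0.5), 1, max_trials = 60)
  for (rep in 1:20) {
    sc <- drive_staircase(runif(60) < 0.7, cfg)
    vals <- c(staircase_history(sc)$value, sc$value)
    # every visited value is start + a*1 + b*0.5 for integers a, b
    expect_true(all(abs((vals - 6) * 2 - round((vals - 6) * 2)) < 1e-9))
  }
})

test_that("staircase drifts toward the 79.4% point under a Bernoulli observer", {
  # symmetric steps: above-target success probability drives the value down,
  # below-target probability drives it up
  set.seed(99)
  drift <- function(p) {
    cfg <- staircase_config(0, 0.5, n_down = 3, max_trials = 400)
    sc <- staircase_init(cfg)
    for (i in 1:400) sc <- staircase_update(sc, runif(1) < p)
    sc$value
  }
  high <- replicate(12, drift(0.95))
  low <- replicate(12, drift(0.55))
  expect_true(mean(high < 0) > 0.9)
  expect_true(mean(low > 0) > 0.9)
})

test_that("step schedule saturates beyond the last change point", {
  cfg <- staircase_config(6, c(1, 0.5), 1, max_trials = 200)
  sc <- staircase_init(cfg)
  expect_equal(staircase_current_step(sc), 1)
  # force many reversals: alternate CCC / W
  sc <- drive_staircase(rep(c(TRUE, TRUE, TRUE, FALSE), 20), cfg)
  expect_gt(nrow(staircase_reversals(sc)), 5)
  expect_equal(staircase_current_step(sc), 0.5)

  # by-trial schedule keys on completed trials instead
  cfg_t <- staircase_config(6, c(1, 0.5), 3, schedule_mode = "trial",
                            max_trials = 10)
  sc_t <- drive_staircase(c(TRUE, TRUE, TRUE, TRUE), cfg_t)
  h <- staircase_history(sc_t)
  expect_equal(h$step, c(1, 1, 1, 0.5))
})

test_that("stop rules trigger on trials or reversals", {
  cfg <- paper_staircase_config(max_trials = 36)
  sc <- drive_staircase(runif(36) < 0.8, cfg)
  expect_true(staircase_is_finished(sc))

  cfg_r <- staircase_config(6, 0.5, max_reversals = 8, max_trials = 10000)
  sc_r <- staircase_init(cfg_r)
  set.seed(3)
  while (!staircase_is_finished(sc_r))
    sc_r <- staircase_update(sc_r, runif(1) < 0.7)
  expect_equal(nrow(staircase_reversals(sc_r)), 8L)
})

test_that("value saturates at configured bounds", {
  cfg <- staircase_config(1, 1, n_down = 1, max_trials = 10,
                          min_value = 0, max_value = 2)
  sc <- drive_staircase(rep(TRUE, 5), cfg)   # 1-down: every correct steps down
  expect_equal(sc$value, 0)
  sc2 <- drive_staircase(rep(FALSE, 5), cfg)
  expect_equal(sc2$value, 2)
})
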