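make_trace <- function(series, time, a395, role = "sample", trial = 1L) {
  tibble::tibble(series = series, time = time, a395 = a395, role = role,
                 trial = trial)
}

test_that("inhibition preprocessing subtracts buffer and scales to control", {
  time <- 0:60
  buf1 <- make_trace("b1", time, 0.05 + 0 * time, role = "buffer_blank")
  buf2 <- make_trace("b2", time, 0.07 + 0 * time, role = "buffer_blank")
  ctrl <- make_trace("c", time, 0.06 + 0.5 / (1 + exp(-0.2 * (time - 20))),
                     role = "zero_rna_control")
  samp <- make_trace("s", time, 0.06 + 0.2 / (1 + exp(-0.2 * (time - 20))))
  out <- preprocess_inhibition(dplyr::bind_rows(buf1, buf2, ctrl, samp))
  # control self-normalizes to a max of exactly 1
  expect_equal(max(out$a395[out$series == "c"]), 1.0)
  # a trace equal to the buffer mean becomes all zeros
  flat <- make_trace("f", time, 0.06 + 0 * time)
  out2 <- preprocess_inhibition(dplyr::bind_rows(buf1, buf2, ctrl, flat))
  expect_equal(out2$a395[out2$series == "f"], rep(0, length(time)))
  # elementwise oracle on a random trace
  withr::local_seed(2)
  y <- runif(length(time), 0.1, 0.9)
  rnd <- make_trace("r", time, y)
  out3 <- preprocess_inhibition(dplyr::bind_rows(buf1, buf2, ctrl, rnd))
  ctrl_net <- ctrl$a395 - 0.06
  expect_equal(out3$a395[out3$series == "r"], (y - 0.06) / max(ctrl_net))
})

test_that("inhibition preprocessing validates its trial structure", {
  time <- 0:30
  samp <- make_trace("s", time, runif(31))
  expect_error(preprocess_inhibition(samp), "buffer_blank")
  buf <- make_trace("b", time, rep(0, 31), role = "buffer_blank")
  expect_error(preprocess_inhibition(dplyr::bind_rows(buf, samp)),
               "zero_rna_control")
  bad_ctrl <- make_trace("c", time, rep(-0.1, 31), role = "zero_rna_control")
  expect_error(preprocess_inhibition(dplyr::bind_rows(buf, bad_ctrl, samp)),
               "control maximum")
})

test_that("reversal normalization anchors the pre-RNA level at 1", {
  time <- 0:120
  flat <- tibble::tibble(time = time, a395 = rep(0.8, 121))
  out <- preprocess_reversal(flat, rna_add_time = 60)
  expect_equal(out$a395[out$time == 60], 1.0)
  # scale invariance
  scaled <- tibble::tibble(time = time, a395 = 3 * flat$a395)
  expect_equal(preprocess_reversal(scaled, 60)$a395, out$a395)
  # arithmetic oracle with k_pre = 5: anchor is mean of times 55..59
  withr::local_seed(6)
  y <- runif(121, 0.2, 1)
  rnd <- tibble::tibble(time = time, a395 = y)
  out2 <- preprocess_reversal(rnd, 60)
  expect_equal(out2$a395, y / mean(y[time %in% 55:59]))
  expect_error(preprocess_reversal(rnd, 3), "points before")
})

test_that("trace AUC matches closed forms and a fine Riemann oracle", {
  const <- tibble::tibble(time = 0:60, a395 = rep(1, 61))
  expect_equal(trace_auc(const, 0, 60)$raw_auc, 60)
  ramp <- tibble::tibble(time = 0:100, a395 = seq(0, 1, length.out = 101))
  expect_equal(trace_auc(ramp, 0, 100)$raw_auc, 50)
  # Riemann oracle with linear interpolation on a random 1-min trace
  withr::local_seed(10)
  tr <- tibble::tibble(time = 0:90, a395 = runif(91))
  fine_t <- seq(10, 80, by = 1e-3)
  fine_y <- approx(tr$time, tr$a395, fine_t)$y
  riemann <- sum((fine_y[-1] + fine_y[-length(fine_y)]) / 2 * 1e-3)
  expect_equal(trace_auc(tr, 10, 80)$raw_auc, riemann, tolerance = 1e-6)
  # additivity
  expect_equal(trace_auc(tr, 0, 40)$raw_auc + trace_auc(tr, 40, 90)$raw_auc,
               trace_auc(tr, 0, 90)$raw_auc, tolerance = 1e-9)
  # normalization against a control
  expect_equal(trace_auc(const, 0, 60, control_auc = 120)$normalized_auc, 0.5)
  expect_error(trace_auc(tr, -5, 50), "outside")
  expect_error(trace_auc(tr, 50, 20), "t0 < t1")
})

test_that("sedimentation fractions conserve mass", {
  expect_equal(unlist(sedimentation_fractions(1, 1)), c(fraction_pellet = 0.5,
               fraction_supernatant = 0.5))
  expect_equal(sedimentation_fractions(0, 5)$fraction_supernatant, 1)
  withr::local_seed(12)
  p <- runif(20); s <- runif(20)
  fr <- sedimentation_fractions(p, s)
  expect_equal(fr$fraction_pellet + fr$fraction_supernatant, rep(1, 20))
  expect_error(sedimentation_fractions(0, 0), "both")
  expect_error(sedimentation_fractions(-1, 2), ">= 0")
})

test_that("post-addition AUC decreases with inhibitor strength", {
  aucs <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(s) {
    tr <- simulate_turbidity(mode = "reversal", inhibitor_strength = s,
                             sigma = 0, rna_add_time = 60, seed = 1)
    norm <- preprocess_reversal(tr, 60)
    trace_auc(norm, 60, 180)$raw_auc
  }, numeric(1))
  expect_true(all(diff(aucs) <= 0))
})

test_that("zero inhibitor strength leaves the post-addition trace flat", {
  tr <- simulate_turbidity(mode = "reversal", inhibitor_strength = 0,
                           sigma = 0.01, rna_add_time = 60, t_mid = 20,
                           seed = 5)
  norm <- preprocess_reversal(tr, 60)
  post <- norm$a395[norm$time >= 120]    # well past the logistic rise
  expect_lt(abs(mean(post) - 1), 0.05)
})
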