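# a small shared problem: short white-noise transient + step steady pair
small_problem <- function(seed = 3) {
  if (is.null(.test_cache$problem))
    .test_cache$problem <- suppressWarnings(synth_fit_targets(seed = seed))
  .test_cache$problem
}

truth_values <- function(pr) unlist(unclass(pr$base)[pr$free])

test_that("loss vanishes at the generating parameters", {
  pr <- small_problem()
  expect_equal(osn_loss(truth_values(pr), pr), 0)
  expect_gt(osn_loss(truth_values(pr) * 1.5, pr), 0)
})

test_that("loss decomposes linearly in lambda", {
  pr <- small_problem()
  x <- truth_values(pr) * c(0.8, 1.2, 0.9)
  comp <- osn_loss(x, pr, components = TRUE)
  expect_equal(comp$loss, comp$L1 + 40 * comp$L2)
  pr0 <- pr; pr0$lambda <- 0
  expect_equal(osn_loss(x, pr0), comp$L1)
  pr2 <- pr; pr2$lambda <- 80
  expect_equal(osn_loss(x, pr2), comp$L1 + 80 * comp$L2)
})

test_that("problem construction validates its inputs", {
  pr <- small_problem()
  expect_error(fit_problem(pr$stimuli, pr$targets, c("transient", "bogus"),
                           pr$rates), "transient")
  expect_error(fit_problem(list(), list(), character(0), pr$rates),
               "at least one")
  expect_error(fit_problem(pr$stimuli, pr$targets, pr$set, pr$rates,
                           free = "not_a_parameter"), "unknown")
})

test_that("differential evolution improves and keeps an elitist trace", {
  pr <- small_problem()
  fit <- fit_de(pr, pop = 10, iters = 6, seed = 2)
  expect_true(all(diff(fit$trace) <= 0))
  expect_lte(fit$loss, fit$trace[1])
  expect_named(fit$values, pr$free)
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(glance(fit)$loss, fit$loss)
})

test_that("feedback-power sweep is minimised at the generating exponent", {
  pr <- small_problem()
  sw <- suppressWarnings(power_sweep(pr, powers = seq(1, 6) / 6))
  expect_equal(nrow(sw), 6)
  expect_equal(sw$power[which.min(sw$loss)], 2 / 3)
  expect_equal(min(sw$loss), 0)
  # exponent 1 reproduces the integer-power feedback variant
  pr1 <- pr; pr1$base$feedback_power <- 1
  expect_equal(sw$loss[sw$power == 1], osn_loss(truth_values(pr), pr1))
})

test_that("gradient ablation is inert iff targets carry no gradient code", {
  # gradient-rich targets: ablation strictly increases the loss
  pr <- small_problem()
  ab <- gradient_ablation(pr)
  expect_equal(ab$loss_full, 0)
  expect_gt(ab$loss_ablated, ab$loss_full)
  # targets generated without the gradient term: losses coincide
  pr0 <- suppressWarnings(synth_fit_targets(otp_params(gamma = 0), seed = 4))
  ab0 <- gradient_ablation(pr0)
  expect_equal(ab0$loss_full, ab0$loss_ablated)
})
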