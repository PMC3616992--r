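# fast problem settings shared by the calibration tests
fast_problem <- function(...) {
  calibration_problem(sim_dt = 8, sim_rtol = 1e-5, sim_atol = 1e-7, ...)
}

test_that("the shipped calibrated set satisfies the full constraint suite", {
  prob <- fast_problem()
  cost <- calibration_cost(calib, prob)
  expect_length(attr(cost, "violated"), 0)
  expect_lt(as.numeric(cost), 10)   # fits the three endpoints closely
})

test_that("each violated constraint adds exactly the penalty weight", {
  prob <- fast_problem()
  # swapping the oligomerization rates breaks autocatalysis dominance
  swapped <- do.call(apoptosis_params,
                     utils::modifyList(unclass(calib),
                                       list(k_dim = calib$k_auto,
                                            k_auto = calib$k_dim)))
  c0 <- calibration_cost(calib, prob)
  c1 <- calibration_cost(swapped, prob)
  expect_true("autocatalysis_dominance" %in% attr(c1, "violated"))
  # a threshold above the parental Bax total can never be crossed
  high <- do.call(apoptosis_params,
                  utils::modifyList(unclass(calib), list(bax_star = 60)))
  c2 <- calibration_cost(high, prob)
  expect_true("crossing_window" %in% attr(c2, "violated"))
  penalty <- prob$penalty_weight
  expect_equal(as.numeric(c2) - sum(attr(c2, "residuals")^2),
               penalty * length(attr(c2, "violated")))
})

test_that("cost is invariant under datapoint reordering", {
  prob1 <- fast_problem()
  dp <- calibration_datapoints()
  prob2 <- fast_problem(datapoints = dp[c(3, 1, 2), ])
  expect_equal(as.numeric(calibration_cost(calib, prob1)),
               as.numeric(calibration_cost(calib, prob2)))
})

test_that("a perfect fit with no violations costs zero", {
  # datapoints taken from the model's own predictions
  dp <- calibration_datapoints()
  sim <- vapply(seq_len(nrow(dp)), function(i)
    simulate_apoptosis(cells[[dp$cell_line[i]]], calib, dp$rx[[i]],
                       dt = 8, rtol = 1e-5, atol = 1e-7)$apoptotic_pct,
    numeric(1))
  dp$observed <- sim
  prob <- fast_problem(datapoints = dp)
  expect_equal(as.numeric(calibration_cost(calib, prob)), 0,
               tolerance = 1e-10)
})

test_that("with no free parameters calibrate returns the reference set", {
  prob <- fast_problem(free = character(0))
  fit <- calibrate_apoptosis(prob, seed = 1)
  expect_equal(fit$params, apoptosis_params())
  expect_equal(fit$cost, as.numeric(calibration_cost(apoptosis_params(),
                                                     prob)))
})

test_that("calibration is reproducible given a seed", {
  prob <- fast_problem()
  st <- list(unlist(unclass(calib)[prob$free]))
  a <- calibrate_apoptosis(prob, seed = 5, starts = st, maxiter = 5,
                           stop_fitness = -1)
  b <- calibrate_apoptosis(prob, seed = 5, starts = st, maxiter = 5,
                           stop_fitness = -1)
  expect_identical(coef(a), coef(b))
})

test_that("calibration recovers endpoints generated by a known model", {
  # endpoints simulated from the shipped calibrated set, noise-free
  ep <- gen_apoptosis_endpoints(calib, noise = noise_model("none"))
  dp <- data.frame(cell_line = ep$cell_line, observed = ep$observed)
  dp$rx <- ep$rx
  prob <- fast_problem(datapoints = dp)
  fit <- calibrate_apoptosis(prob, seed = 7, maxiter = 200)
  refit <- vapply(seq_len(nrow(dp)), function(i)
    simulate_apoptosis(cells[[dp$cell_line[i]]], fit$params, dp$rx[[i]],
                       dt = 4, rtol = 1e-6, atol = 1e-8)$apoptotic_pct,
    numeric(1))
  expect_lt(max(abs(refit - dp$observed)), 2)
})
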