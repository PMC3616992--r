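test_that("an empty treatment changes nothing except switching stimulus off", {
  mod <- apply_treatment(cells$parental, parental_bik_params(), calib,
                         treatment_spec())
  expect_equal(mod$cell, cells$parental)
  expect_equal(mod$bik, parental_bik_params())
  expect_equal(mod$net$kact, 0)
  expect_equal(mod$net$ktrunc, 0)
  expect_equal(mod$state, build_initial_state(cells$parental))
})

test_that("Src inhibition re-equilibrates the Bik steady state before t = 0", {
  mod <- apply_treatment(cells$src, src_bik_params(), calib, sts_herb)
  # 98% inhibition lifts the Src steady state from 9.2 back toward 50 nM
  expect_equal(mod$cell$Bik_ss, 48.17, tolerance = 1e-3)
  expect_equal(mod$state[["Bik_in"]], mod$cell$Bik_ss)
  full <- apply_treatment(cells$src, src_bik_params(), calib,
                          treatment_spec(staurosporine = TRUE,
                                         src_inhibition = 1))
  expect_equal(full$cell$Bik_ss, 50)
})

test_that("pool depletion dissociates complexes when tBid no longer fits", {
  rx <- treatment_spec(staurosporine = TRUE, bcl2_depletion = 545)
  mod <- apply_treatment(cells$parental, parental_bik_params(), calib, rx)
  expect_equal(mod$state[["Bcl2"]], 0)
  expect_equal(mod$state[["C_tbid"]], 0)
  expect_equal(mod$state[["tBid"]], 1)   # the displaced tBid starts free
  # partial depletion keeps all tBid complexed
  rx2 <- treatment_spec(staurosporine = TRUE, bcl2_depletion = 182)
  mod2 <- apply_treatment(cells$parental, parental_bik_params(), calib, rx2)
  expect_equal(mod2$state[["C_tbid"]], 1)
  expect_equal(mod2$state[["Bcl2"]], 545 - 182 - 1)
})

test_that("treatment application is a pure function of its inputs", {
  rx <- treatment_spec(staurosporine = TRUE, src_inhibition = 0.98,
                       bcl2_depletion = 100, bax_delta = 10, tbid_up = 5)
  a <- apply_treatment(cells$src, src_bik_params(), calib, rx)
  b <- apply_treatment(cells$src, src_bik_params(), calib, rx)
  expect_identical(a$state, b$state)
  expect_identical(a$cell, b$cell)
})

test_that("knob caps and floors hold", {
  rx <- treatment_spec(staurosporine = TRUE, bax_delta = 100, tbid_up = 100)
  mod <- apply_treatment(cells$parental, parental_bik_params(), calib, rx)
  expect_equal(mod$state[["BaxC"]], 0)                     # floored
  expect_equal(mod$cell$tBid0, cells$parental$Bid_total)   # capped
  expect_error(treatment_spec(bcl2_depletion = -5), "non-negative")
})

test_that("BH3-mimetic exposure alone never kills in this system", {
  pct <- abt_alone_scan(cells$parental, calib, c(0, 182, 400, 545, 600))
  expect_lt(max(pct), 1)
  expect_lt(pct[1], 0.1)
})

test_that("dose responses are monotone and parental cells die more", {
  deps <- c(0, 182, 400)
  par_pct <- vapply(deps, function(d)
    sim_fast(cells$parental,
             treatment_spec(staurosporine = TRUE,
                            bcl2_depletion = d))$apoptotic_pct, numeric(1))
  src_pct <- vapply(deps, function(d)
    sim_fast(cells$src,
             treatment_spec(staurosporine = TRUE,
                            bcl2_depletion = d))$apoptotic_pct, numeric(1))
  expect_true(all(diff(par_pct) >= 0))
  expect_true(all(diff(src_pct) >= 0))
  expect_true(all(par_pct >= src_pct))
  # toxicity falls monotonically as Bax is removed
  bax_pct <- vapply(c(0, 15, 30, 45), function(d)
    sim_fast(cells$parental,
             treatment_spec(staurosporine = TRUE,
                            bax_delta = d))$apoptotic_pct, numeric(1))
  expect_true(all(diff(bax_pct) <= 0))
})
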