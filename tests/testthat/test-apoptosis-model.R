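test_that("network derivatives match a per-reaction oracle on random states", {
  set.seed(101)
  for (i in 1:25) {
    s <- random_state()
    p <- if (i %% 2) table2 else calib
    expect_equal(apoptosis_rhs(s, p), reference_rhs(s, p),
                 tolerance = 1e-14)
  }
})

test_that("conserved sums have identically zero derivative", {
  set.seed(202)
  for (i in 1:10) {
    d <- apoptosis_rhs(random_state(), table2)
    expect_equal(d[["Bik_in"]] + d[["Bik_act"]] + d[["C_bik"]], 0)
    expect_equal(d[["Bid"]] + d[["tBid"]] + d[["C_tbid"]], 0)
    expect_equal(d[["BaxC"]] + d[["BaxO"]] + d[["BaxOligo"]] + d[["C_bax"]], 0)
    expect_equal(d[["Bcl2"]] + d[["C_bik"]] + d[["C_tbid"]] + d[["C_bax"]], 0)
  }
})

test_that("the all-zero state and the resting state are fixed points", {
  zero <- random_state() * 0
  expect_true(all(apoptosis_rhs(zero, table2) == 0))
  # without the stimulus (kact = ktrunc = 0) the built initial state is steady
  p0 <- apoptosis_params(kact = 0, ktrunc = 0)
  for (cell in cells) {
    y0 <- build_initial_state(cell)
    expect_lt(max(abs(apoptosis_rhs(y0[names(y0) != "n"], p0))), 1e-12)
  }
})

test_that("autocatalytic oligomerization dominates the dimeric route", {
  s <- random_state() * 0
  s[c("BaxO", "BaxOligo")] <- 10
  fl <- apoptosis_fluxes(s, table2)
  # monomer flux through R8 vs R7 at equal pools: 0.0144*100 / (2*0.000185*100)
  expect_equal(fl[["R8"]] / (2 * fl[["R7"]]), 38.92, tolerance = 1e-3)
  expect_gt(table2$k_auto / table2$k_dim, 10)
})

test_that("initial states follow the resting rules and Table-1 totals", {
  y <- build_initial_state(parental_cell())
  expect_equal(y[["BaxC"]], 48)
  expect_equal(y[["Bcl2"]], 544)
  expect_equal(y[["Bid"]], 51)
  expect_equal(y[["C_tbid"]], 1)
  expect_equal(y[["tBid"]], 0)
  ys <- build_initial_state(src_cell())
  expect_equal(ys[["BaxC"]], 100)
  expect_equal(ys[["Bcl2"]], 599)
  expect_equal(ys[["Bid"]], 39)
  y0 <- build_initial_state(cell_line_spec("x", 10, 20, 100, 5, tBid0 = 0))
  expect_equal(y0[["C_tbid"]], 0)
  expect_equal(y0[["Bcl2"]], 100)
  expect_error(cell_line_spec("x", 10, 20, 100, 5, tBid0 = 6), "tBid0")
})

test_that("the death law is Hill-gated with the expected limits", {
  expect_equal(survival_rhs(100, 0, table2), 0)
  expect_equal(survival_rhs(80, table2$bax_star, table2),
               -table2$a * 80 / 2)
  # saturated death for 480 min decays survival exponentially at rate a
  rhs <- function(t, y, p) list(survival_rhs(y, 1e6 * p$bax_star, p))
  out <- deSolve::ode(c(n = 100), c(0, 480), rhs, table2,
                      rtol = 1e-10, atol = 1e-12)
  expect_equal(unname(out[2, "n"]), 100 * exp(-0.0205 * 480),
               tolerance = 1e-6)
  expect_equal(unname(out[2, "n"]), 0.0053, tolerance = 0.01)
})

test_that("trajectories conserve totals, stay non-negative, and n never rises", {
  for (cell in cells) {
    for (rx in list(sts, sts_herb)) {
      s <- simulate_apoptosis(cell, calib, rx)
      expect_lt(s$conservation_drift, 1e-6)
      expect_gt(min(s$trajectory), -1e-9)
      expect_true(all(diff(s$trajectory[, "n"]) <= 1e-12))
    }
  }
})

test_that("apoptosis requires the staurosporine stimulus", {
  for (cell in cells) {
    s <- sim_fast(cell, treatment_spec())
    expect_lt(s$apoptotic_pct, 0.1)
  }
})

test_that("apoptosis increases with the simulation horizon", {
  pct <- vapply(c(240, 360, 480), function(te)
    sim_fast(cells$parental, sts, t_end = te)$apoptotic_pct, numeric(1))
  expect_true(all(diff(pct) >= 0))
})

test_that("higher resting Bik sensitizes the population to the stimulus", {
  bik_levels <- c(5, 9.2, 25, 50)
  pct <- vapply(bik_levels, function(b) {
    cell <- cell_line_spec("x", b, 48, 545, 52, 1)
    sim_fast(cell, sts)$apoptotic_pct
  }, numeric(1))
  expect_true(all(diff(pct) >= 0))
  # parental vs Src ordering under staurosporine alone
  expect_gt(sim_fast(cells$parental, sts)$apoptotic_pct,
            sim_fast(cells$src, sts)$apoptotic_pct)
})

test_that("oligomerization is driven by autocatalysis, not dimerization", {
  no_dim <- do.call(apoptosis_params,
                    utils::modifyList(unclass(calib), list(k_dim = 0)))
  base <- sim_fast(cells$parental, sts)
  # seed a trace of oligomer so autocatalysis can ignite without R7
  cell_seeded <- cells$parental
  mod <- apply_treatment(cell_seeded, parental_bik_params(), no_dim, sts)
  y0 <- mod$state
  y0["BaxOligo"] <- 0.05
  y0["BaxC"] <- y0["BaxC"] - 0.05
  out <- deSolve::ode(y0, seq(0, 480, 4), bcl2dyn:::.network_ode,
                      unclass(mod$net), method = "lsoda",
                      rtol = 1e-6, atol = 1e-8)
  pct_no_dim <- 100 - out[nrow(out), "n"]
  expect_lt(abs(pct_no_dim - base$apoptotic_pct), 5)
  # without autocatalysis the threshold is never crossed in parental cells
  no_auto <- do.call(apoptosis_params,
                     utils::modifyList(unclass(calib), list(k_auto = 0)))
  s <- sim_fast(cells$parental, sts, params = no_auto)
  expect_false(is.finite(bcl2dyn:::.crossing_time(s)))
})

test_that("the activation rate follows from the colocalization fraction", {
  expect_equal(estimate_kact(0.45, 120), 0.005, tolerance = 0.01)
  expect_equal(estimate_kact(0, 60), 0)
  expect_equal(estimate_kact(0.632, 100), 0.01, tolerance = 1e-3)
  expect_error(estimate_kact(1, 60), "fraction")
})

test_that("the apoptotic threshold fraction is the product of the two shares", {
  expect_equal(threshold_fraction(0.33, 0.38), 0.1254)
  expect_equal(threshold_fraction(1, 1), 1)
  expect_equal(threshold_fraction(0.5, 0.2), 0.1)
  expect_error(threshold_fraction(1.2, 0.5), "fraction")
})
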