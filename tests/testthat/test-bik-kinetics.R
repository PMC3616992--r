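test_that("turnover derivatives vanish at the analytic steady state", {
  sets <- list(parental_bik_params(), src_bik_params(),
               bik_params(kS = 0.3, kubi = 0.01, Vmax = 0.5, Km = 5),
               bik_params(kS = 1, kubi = 0, Vmax = 2, Km = 10))
  for (p in sets) {
    ss <- bik_steady_state(p)
    d <- bik_rhs(c(Bik = ss[["Bik"]], BikUb = ss[["BikUb"]]), p)
    expect_lt(max(abs(d)), 1e-9)
  }
})

test_that("parental defaults hold Bik at 50 nM with zero net flux", {
  p <- parental_bik_params()
  expect_equal(p$Vmax, 0)
  expect_equal(bik_steady_state(p)[["Bik"]], 50)
  d <- bik_rhs(c(Bik = 50, BikUb = 0.2), p)
  expect_equal(d[["Bik"]], 0)
})

test_that("a Michaelis-Menten pair solved for the 9.2 nM Src steady state balances", {
  # (Vmax, Km) chosen so kS = kubi*B + Vmax*B/(Km+B) at B = 9.2
  p <- bik_params(kS = 0.139, kubi = 1 / 360, Vmax = 0.36, Km = 20)
  d <- bik_rhs(c(Bik = 9.2, BikUb = 0.139), p)
  expect_lt(abs(d[["Bik"]]), 1e-3)
})

test_that("steady-state ratio of Src-transformed to parental Bik is ~0.18", {
  ratio <- bik_steady_state(src_bik_params())[["Bik"]] /
    bik_steady_state(parental_bik_params())[["Bik"]]
  expect_equal(ratio, 0.184, tolerance = 1e-12)
  expect_lt(abs(ratio - 0.18), 0.005 + 1e-12)
})

test_that("steady state degenerates and errors as the balance dictates", {
  expect_equal(bik_steady_state(bik_params(kS = 0, kubi = 0.01))[["Bik"]], 0)
  expect_error(bik_steady_state(bik_params(kS = 1, kubi = 0, Vmax = 0)),
               "removal")
  expect_error(bik_params(kS = -1, kubi = 0.1), "non-negative")
})

test_that("steady state is monotone in each rate across a parameter grid", {
  base <- list(kS = 0.14, kubi = 1 / 360, Vmax = 0.3, Km = 20)
  ss_of <- function(...) {
    a <- utils::modifyList(base, list(...))
    bik_steady_state(do.call(bik_params, a))[["Bik"]]
  }
  grid <- c(0.5, 1, 2, 4)
  expect_true(all(diff(sapply(grid, function(g) ss_of(kubi = base$kubi * g))) < 0))
  expect_true(all(diff(sapply(grid, function(g) ss_of(Vmax = base$Vmax * g))) < 0))
  expect_true(all(diff(sapply(grid, function(g) ss_of(kS = base$kS * g))) > 0))
  expect_true(all(diff(sapply(grid, function(g) ss_of(Km = base$Km * g))) > 0))
})

test_that("ubiquitylated pool obeys flux balance kdeg * BikUb = kS", {
  for (p in list(parental_bik_params(), src_bik_params(),
                 bik_params(kS = 2, kubi = 0.03, Vmax = 1, Km = 7,
                            kdeg = 0.5))) {
    ss <- bik_steady_state(p)
    expect_equal(p$kdeg * ss[["BikUb"]], p$kS, tolerance = 1e-12)
  }
})

test_that("long integration of the turnover ODE converges to the closed form", {
  for (p in list(parental_bik_params(), src_bik_params(),
                 bik_params(kS = 0.5, kubi = 0.002, Vmax = 0.8, Km = 40))) {
    rhs <- function(t, y, pp) list(unname(bik_rhs(y, pp)))
    ss <- bik_steady_state(p)[["Bik"]]
    # 5000 min is ~14 times the slowest turnover time constant, enough to
    # close a 1 nM displacement to well under 1e-6 nM
    out <- deSolve::ode(c(Bik = ss - 1, BikUb = 0), c(0, 5000), rhs, p,
                        method = "lsoda", rtol = 1e-10, atol = 1e-12)
    expect_lt(abs(out[2, "Bik"] - ss), 1e-6)
  }
})

test_that("accumulation profile is linear growth from the initial level", {
  expect_equal(accumulation_profile(0, 37, 0.2), 37)
  # with the parental defaults Bik merely doubles over six hours
  p <- parental_bik_params()
  expect_equal(accumulation_profile(360, 50, p$kS), 100)
  expect_equal(accumulation_profile(720, 50, 0.139), 150.08)
  expect_error(accumulation_profile(-1, 50, 0.1), "non-negative")
})

test_that("herbimycin rescales Vmax and restores the parental steady state", {
  p <- src_bik_params()
  expect_identical(apply_herbimycin(p, 0), p)
  h <- apply_herbimycin(p, 0.98)
  expect_equal(h$Vmax, p$Vmax * 0.02)
  expect_equal(h[c("kS", "kubi", "Km")], p[c("kS", "kubi", "Km")])
  full <- apply_herbimycin(p, 1)
  expect_equal(bik_steady_state(full)[["Bik"]], 50)
  expect_error(apply_herbimycin(p, 1.2), "fraction")
})

test_that("chase decay matches the closed form when the Src branch is off", {
  tt <- seq(0, 360, by = 30)
  p <- parental_bik_params()
  expect_equal(simulate_bik_decay(p, tt), exp(-p$kubi * tt),
               tolerance = 1e-10)
  # with the branch on, decay is faster everywhere past t = 0
  src <- simulate_bik_decay(src_bik_params(), tt)
  expect_true(all(src[-1] < exp(-p$kubi * tt)[-1]))
})
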