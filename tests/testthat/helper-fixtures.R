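# Shared fixtures: the calibrated parameter set, reference cell lines and a
# coarse-grid simulation wrapper used by property tests (tight-tolerance
# runs are exercised separately).

calib <- calibrated_apoptosis_params()
table2 <- apoptosis_params()
cells <- list(parental = parental_cell(), src = src_cell())

sim_fast <- function(cell, rx, params = calib, t_end = 480) {
  simulate_apoptosis(cell, params, rx, t_end = t_end, dt = 4,
                     rtol = 1e-6, atol = 1e-8)
}

sts <- treatment_spec(staurosporine = TRUE)
sts_herb <- treatment_spec(staurosporine = TRUE, src_inhibition = 0.98)

# random non-negative network state (named, in species order)
random_state <- function() {
  s <- stats::runif(11, 0, 100)
  names(s) <- c("Bik_in", "Bik_act", "C_bik", "Bid", "tBid", "C_tbid",
                "BaxC", "BaxO", "BaxOligo", "Bcl2", "C_bax")
  c(s, n = stats::runif(1, 0, 100))
}

# hand-written network derivatives, assembled reaction by reaction from the
# kinetic rate laws -- an oracle independent of the package's
# stoichiometry-matrix route
reference_rhs <- function(state, p) {
  with(as.list(c(state, unclass(p))), {
    r1 <- kact * Bik_in
    r2 <- k_bik_bcl2 * Bik_act * Bcl2
    r3 <- ktrunc * Bid
    r4 <- k_tbid_bcl2 * tBid * Bcl2
    r5 <- k_disp * C_tbid * Bik_act
    r6 <- kcat_bax * tBid * BaxC / (Km_bax + BaxC)
    r7 <- k_dim * BaxO^2
    r8 <- k_auto * BaxO * BaxOligo
    r9 <- k_bax_bcl2 * BaxO * Bcl2
    r10 <- k_back * BaxO
    c(Bik_in = -r1, Bik_act = r1 - r2 - r5, C_bik = r2 + r5,
      Bid = -r3, tBid = r3 - r4 + r5, C_tbid = r4 - r5,
      BaxC = -r6 + r10, BaxO = r6 - 2 * r7 - r8 - r9 - r10,
      BaxOligo = 2 * r7 + r8, Bcl2 = -r2 - r4 - r9, C_bax = r9)
  })
}
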