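# The mitochondrial-apoptosis reaction network: eleven species of the Bcl-2
# family plus the percentage of surviving cells.  Spontaneous reactions follow
# the law of mass action; Bax activation by tBid is catalytic ("kiss and
# run") and follows Michaelis-Menten kinetics.  Reactions, with the Table-2
# style numbering used throughout the code:
#   R1  Bik_in -> Bik_act                 kact * Bik_in
#   R2  Bik_act + Bcl2 -> C_bik          k_bik_bcl2 * Bik_act * Bcl2
#   R3  Bid -> tBid                       ktrunc * Bid
#   R4  tBid + Bcl2 -> C_tbid            k_tbid_bcl2 * tBid * Bcl2
#   R5  C_tbid + Bik_act -> C_bik + tBid k_disp * C_tbid * Bik_act
#   R6  BaxC -> BaxO                      kcat_bax * tBid * BaxC / (Km_bax + BaxC)
#   R7  2 BaxO -> 2 BaxOligo              event rate k_dim * BaxO^2 (2 monomers/event)
#   R8  BaxO + BaxOligo -> 2 BaxOligo     k_auto * BaxO * BaxOligo
#   R9  BaxO + Bcl2 -> C_bax             k_bax_bcl2 * BaxO * Bcl2
#   R10 BaxO -> BaxC                      k_back * BaxO
# BaxOligo is tracked in monomer equivalents so the Bax conservation law is
# linear.  Complexes do not dissociate (except through R5 and through
# BH3-mimetic pre-incubation, see treatments).

.species <- c("Bik_in", "Bik_act", "C_bik", "Bid", "tBid", "C_tbid",
              "BaxC", "BaxO", "BaxOligo", "Bcl2", "C_bax")

# stoichiometry matrix (species x reactions), used by the RHS and available
# to tests as an independent flux-times-stoichiometry route
.stoich <- local({
  S <- matrix(0, nrow = 11, ncol = 10,
              dimnames = list(.species, paste0("R", 1:10)))
  S["Bik_in", "R1"] <- -1; S["Bik_act", "R1"] <- 1
  S["Bik_act", "R2"] <- -1; S["Bcl2", "R2"] <- -1; S["C_bik", "R2"] <- 1
  S["Bid", "R3"] <- -1; S["tBid", "R3"] <- 1
  S["tBid", "R4"] <- -1; S["Bcl2", "R4"] <- -1; S["C_tbid", "R4"] <- 1
  S["C_tbid", "R5"] <- -1; S["Bik_act", "R5"] <- -1
  S["C_bik", "R5"] <- 1; S["tBid", "R5"] <- 1
  S["BaxC", "R6"] <- -1; S["BaxO", "R6"] <- 1
  S["BaxO", "R7"] <- -2; S["BaxOligo", "R7"] <- 2
  S["BaxO", "R8"] <- -1; S["BaxOligo", "R8"] <- 1
  S["BaxO", "R9"] <- -1; S["Bcl2", "R9"] <- -1; S["C_bax", "R9"] <- 1
  S["BaxO", "R10"] <- -1; S["BaxC", "R10"] <- 1
  S
})

#' Parameters of the mitochondrial-apoptosis network
#'
#' Defaults are the published reference values of the thirteen network
#' parameters plus the apoptotic threshold.  Units: first-order rates in
#' 1/min, association rates in 1/(nM min), `Km_bax` and `bax_star` in nM,
#' `gamma` dimensionless, `a` in 1/min.
#'
#' @param kact Bik activation (ER to mitochondria relocation) rate.
#' @param k_bik_bcl2 association of active Bik with the anti-apoptotic pool.
#' @param ktrunc Bid truncation rate (tBid formation during apoptosis).
#' @param k_tbid_bcl2 association of tBid with the anti-apoptotic pool.
#' @param k_disp displacement of tBid from its complex by active Bik.
#' @param kcat_bax catalytic rate of Bax activation by tBid.
#' @param Km_bax Michaelis constant of Bax activation.
#' @param k_dim dimeric Bax oligomerization rate.
#' @param k_auto autocatalytic Bax oligomerization rate.
#' @param k_bax_bcl2 association of open Bax with the anti-apoptotic pool.
#' @param k_back spontaneous closing of open Bax.
#' @param gamma steepness of the death law.
#' @param a maximal death rate of the cell population.
#' @param bax_star apoptotic threshold on oligomerized Bax
#'   (monomer equivalents, nM); 13 nM is 13% of the 100 nM Bax total of the
#'   Src-transformed reference line.
#' @return an object of class `apoptosis_params` (a named list).
#' @seealso [calibrated_apoptosis_params()] for the calibrated set this
#'   package uses for all endpoint predictions.
#' @export
apoptosis_params <- function(kact = 0.005, k_bik_bcl2 = 0.000105,
                             ktrunc = 0.00014, k_tbid_bcl2 = 0.000087,
                             k_disp = 0.88, kcat_bax = 0.0104, Km_bax = 114,
                             k_dim = 0.000185, k_auto = 0.0144,
                             k_bax_bcl2 = 0.000021, k_back = 0.007,
                             gamma = 4.15, a = 0.0205, bax_star = 13) {
  p <- list(kact = kact, k_bik_bcl2 = k_bik_bcl2, ktrunc = ktrunc,
            k_tbid_bcl2 = k_tbid_bcl2, k_disp = k_disp, kcat_bax = kcat_bax,
            Km_bax = Km_bax, k_dim = k_dim, k_auto = k_auto,
            k_bax_bcl2 = k_bax_bcl2, k_back = k_back, gamma = gamma, a = a,
            bax_star = bax_star)
  bad <- vapply(p, function(v) !is.numeric(v) || length(v) != 1L ||
                  is.na(v) || v < 0, logical(1))
  if (any(bad)) stop("non-negative scalar required for: ",
                     paste(names(p)[bad], collapse = ", "))
  structure(p, class = "apoptosis_params")
}

#' @export
print.apoptosis_params <- function(x, ...) {
  cat("Mitochondrial-apoptosis network parameters:\n")
  print(unlist(x))
  invisible(x)
}

#' Calibrated network parameters
#'
#' The parameter set obtained by running [calibrate_apoptosis()] on the three
#' endpoint datapoints (parental staurosporine 80%, parental staurosporine +
#' herbimycin 80%, Src-transformed staurosporine + herbimycin 99%) under the
#' full constraint suite, with the default multi-start schedule and seed 42.
#' All endpoint predictions in this package (BH3-mimetic arms, therapy
#' designs) use this set; `calibrate_apoptosis()` re-derives it.
#'
#' @return an `apoptosis_params` object.
#' @export
calibrated_apoptosis_params <- function() {
  do.call(apoptosis_params, as.list(.calibrated_values))
}

# regenerated by data-raw/calibrate-defaults.R; best CMA-ES solution (cost
# 0.29, all constraints satisfied)
.calibrated_values <- c(
  kact = 0.005, k_bik_bcl2 = 0.000105, ktrunc = 0.00179123491513163,
  k_tbid_bcl2 = 8.7e-05, k_disp = 0.141203199221546,
  kcat_bax = 0.0400124054972571, Km_bax = 141.226739920046,
  k_dim = 0.000610408318922038, k_auto = 0.0857076583258941,
  k_bax_bcl2 = 4.02242972950491e-06, k_back = 7.51838559488738e-05,
  gamma = 7.90796731846801, a = 0.022258571942605, bax_star = 13)

#' Cell-line specification
#'
#' Total Bcl-2 family concentrations and the Bik steady state for one cell
#' line (nM).  `Bcl2_total` lumps Bcl-2, Bcl-xL and Mcl-1 into a single
#' anti-apoptotic pool.
#'
#' @param label cell-line name.
#' @param Bik_ss steady-state Bik concentration (nM).
#' @param Bax_total total Bax (nM).
#' @param Bcl2_total total anti-apoptotic pool (nM).
#' @param Bid_total total Bid (nM).
#' @param tBid0 pre-existing tBid (nM), all complexed at rest.
#' @return an object of class `cell_line_spec`.
#' @export
cell_line_spec <- function(label, Bik_ss, Bax_total, Bcl2_total, Bid_total,
                           tBid0 = 1) {
  num <- c(Bik_ss = Bik_ss, Bax_total = Bax_total, Bcl2_total = Bcl2_total,
           Bid_total = Bid_total, tBid0 = tBid0)
  if (any(!is.finite(num)) || any(num < 0))
    stop("cell-line concentrations must be finite and non-negative")
  if (tBid0 > Bid_total) stop("tBid0 cannot exceed Bid_total")
  structure(c(list(label = as.character(label)), as.list(num)),
            class = "cell_line_spec")
}

#' @export
print.cell_line_spec <- function(x, ...) {
  cat("Cell line:", x$label, "\n")
  print(unlist(x[-1]))
  invisible(x)
}

#' Reference cell lines
#'
#' Total protein concentrations for parental NIH-3T3 fibroblasts
#' (Bik 50, Bax 48, anti-apoptotic pool 545, Bid 52, tBid 1 nM) and their
#' Src-transformed counterpart (9.2, 100, 600, 40, 1 nM).
#'
#' @return a `cell_line_spec` object.
#' @export
parental_cell <- function() cell_line_spec("parental", 50, 48, 545, 52, 1)

#' @rdname parental_cell
#' @export
src_cell <- function() cell_line_spec("src", 9.2, 100, 600, 40, 1)

#' Initial network state for a cell line at rest
#'
#' Pre-stimulus rules: all Bik inactive at its steady state; all Bax closed;
#' all pre-existing tBid trapped in complexes with the anti-apoptotic pool;
#' no Bcl2:BaxO complexes; free Bid and Bcl2 follow from the conservation
#' laws; 100% of cells alive.  This state is a steady state of the network
#' when the death stimulus is off.
#'
#' @param cell a [cell_line_spec()].
#' @return named numeric vector of the 11 species (nM) plus `n` (%).
#' @export
build_initial_state <- function(cell) {
  stopifnot(inherits(cell, "cell_line_spec"))
  if (cell$tBid0 > cell$Bcl2_total)
    stop("tBid0 exceeds the anti-apoptotic pool: cannot complex all tBid")
  c(Bik_in = cell$Bik_ss, Bik_act = 0, C_bik = 0,
    Bid = cell$Bid_total - cell$tBid0, tBid = 0, C_tbid = cell$tBid0,
    BaxC = cell$Bax_total, BaxO = 0, BaxOligo = 0,
    Bcl2 = cell$Bcl2_total - cell$tBid0, C_bax = 0, n = 100)
}

# per-reaction fluxes at a state; exported for inspection and used by the RHS
#' Reaction fluxes of the apoptosis network
#'
#' @param state named state vector (see [build_initial_state()]).
#' @param params an [apoptosis_params()] object.
#' @return named vector of the ten reaction fluxes (nM/min; R7 is the event
#'   rate `k_dim * BaxO^2`, which moves two monomers per event).
#' @export
apoptosis_fluxes <- function(state, params) {
  s <- as.list(state[.species])
  with(c(s, unclass(params)), c(
    R1 = kact * Bik_in,
    R2 = k_bik_bcl2 * Bik_act * Bcl2,
    R3 = ktrunc * Bid,
    R4 = k_tbid_bcl2 * tBid * Bcl2,
    R5 = k_disp * C_tbid * Bik_act,
    R6 = kcat_bax * tBid * BaxC / (Km_bax + BaxC),
    R7 = k_dim * BaxO^2,
    R8 = k_auto * BaxO * BaxOligo,
    R9 = k_bax_bcl2 * BaxO * Bcl2,
    R10 = k_back * BaxO))
}

#' Time derivatives of the apoptosis network
#'
#' Mass-action right-hand side of the eleven-species network (the survival
#' variable is handled by [survival_rhs()]).  The four conserved sums (total
#' Bik, total Bid, total Bax, total anti-apoptotic pool) have identically
#' zero derivative.
#'
#' @inheritParams apoptosis_fluxes
#' @return named vector of derivatives for the 11 species (nM/min).
#' @export
apoptosis_rhs <- function(state, params) {
  stopifnot(inherits(params, "apoptosis_params"))
  if (any(state[.species] < 0)) stop("negative species concentrations")
  drop(.stoich %*% apoptosis_fluxes(state, params))[.species]
}

#' Death rate of the surviving-cell population
#'
#' `dn/dt = -a * n * BaxOligo^gamma / (BaxOligo^gamma + bax_star^gamma)`:
#' a Hill-gated death law that engages when oligomerized Bax reaches the
#' apoptotic threshold `bax_star` and saturates at the maximal rate `a`.
#'
#' @param n percentage of surviving cells, in `[0, 100]`.
#' @param BaxOligo oligomerized Bax (nM, monomer equivalents).
#' @param params an [apoptosis_params()] object.
#' @return `dn/dt` in %/min (always non-positive).
#' @export
survival_rhs <- function(n, BaxOligo, params) {
  stopifnot(inherits(params, "apoptosis_params"))
  if (n < 0 || n > 100) stop("n must be in [0, 100]")
  if (BaxOligo < 0) stop("BaxOligo must be non-negative")
  if (BaxOligo == 0) return(0)
  h <- BaxOligo^params$gamma
  -params$a * n * h / (h + params$bax_star^params$gamma)
}

# combined RHS in deSolve form
.network_ode <- function(t, y, p) {
  s <- y[.species]
  fl <- c(p$kact * s[["Bik_in"]],
          p$k_bik_bcl2 * s[["Bik_act"]] * s[["Bcl2"]],
          p$ktrunc * s[["Bid"]],
          p$k_tbid_bcl2 * s[["tBid"]] * s[["Bcl2"]],
          p$k_disp * s[["C_tbid"]] * s[["Bik_act"]],
          p$kcat_bax * s[["tBid"]] * s[["BaxC"]] / (p$Km_bax + s[["BaxC"]]),
          p$k_dim * s[["BaxO"]]^2,
          p$k_auto * s[["BaxO"]] * s[["BaxOligo"]],
          p$k_bax_bcl2 * s[["BaxO"]] * s[["Bcl2"]],
          p$k_back * s[["BaxO"]])
  ds <- drop(.stoich %*% fl)
  h <- s[["BaxOligo"]]^p$gamma
  dn <- if (s[["BaxOligo"]] <= 0) 0 else
    -p$a * y[["n"]] * h / (h + p$bax_star^p$gamma)
  list(c(ds, dn))
}

#' Simulate the apoptosis network for one cell line
#'
#' Integrates the network plus the survival law with a stiff solver from the
#' resting state (after applying `treatment`, see [apply_treatment()]) to
#' `t_end`.  Staurosporine switches Bik activation (`kact`) and Bid
#' truncation (`ktrunc`) on at `t = 0`; without it both are 0 and the resting
#' state does not move.
#'
#' @param cell a [cell_line_spec()].
#' @param params an [apoptosis_params()] object.
#' @param treatment a [treatment_spec()]; default no treatment.
#' @param t_end simulation horizon (min).
#' @param bik Bik turnover parameters for the cell line, used only when the
#'   treatment inhibits Src (the Bik steady state re-equilibrates before the
#'   stimulus); defaults to the parental/Src shipped sets matched by label.
#' @param dt output resolution (min).
#' @param rtol,atol solver tolerances.
#' @return an object of class `apoptosis_sim`: list with `times`,
#'   `trajectory` (matrix, one column per state variable), `apoptotic_pct`,
#'   `conservation_drift` (max relative drift of the four conserved sums),
#'   `cell`, `treatment`, `params`.
#' @export
simulate_apoptosis <- function(cell, params, treatment = treatment_spec(),
                               t_end = 480, bik = NULL, dt = 1,
                               rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(cell, "cell_line_spec"),
            inherits(params, "apoptosis_params"))
  if (t_end <= 0) stop("t_end must be positive")
  mod <- apply_treatment(cell, bik %||% .default_bik(cell), params, treatment)
  y0 <- mod$state
  times <- seq(0, t_end, by = dt)
  out <- deSolve::ode(y0, times, .network_ode, unclass(mod$net),
                      method = "lsoda", rtol = rtol, atol = atol)
  if (attr(out, "istate")[1] < 0)
    stop("integrator failure: istate = ", attr(out, "istate")[1])
  traj <- out[, -1, drop = FALSE]
  drift <- .conservation_drift(traj)
  structure(list(times = out[, "time"], trajectory = traj,
                 apoptotic_pct = 100 - traj[nrow(traj), "n"],
                 conservation_drift = drift, cell = mod$cell,
                 treatment = treatment, params = mod$net),
            class = "apoptosis_sim")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.default_bik <- function(cell) {
  if (identical(cell$label, "src")) src_bik_params() else parental_bik_params()
}

.conserved_sums <- function(traj) {
  cbind(Bik = traj[, "Bik_in"] + traj[, "Bik_act"] + traj[, "C_bik"],
        Bid = traj[, "Bid"] + traj[, "tBid"] + traj[, "C_tbid"],
        Bax = traj[, "BaxC"] + traj[, "BaxO"] + traj[, "BaxOligo"] +
          traj[, "C_bax"],
        Bcl2 = traj[, "Bcl2"] + traj[, "C_bik"] + traj[, "C_tbid"] +
          traj[, "C_bax"])
}

.conservation_drift <- function(traj) {
  cs <- .conserved_sums(traj)
  ref <- cs[1, ]
  ref[ref == 0] <- 1
  max(abs(sweep(cs, 2, cs[1, ]) / rep(ref, each = nrow(cs))))
}

#' @export
print.apoptosis_sim <- function(x, ...) {
  cat(sprintf("Apoptosis simulation: %s, %s\n", x$cell$label,
              format(x$treatment)))
  cat(sprintf("  t_end = %g min, apoptotic cells = %.2f%%\n",
              max(x$times), x$apoptotic_pct))
  cat(sprintf("  conservation drift = %.2e\n", x$conservation_drift))
  invisible(x)
}

#' @export
summary.apoptosis_sim <- function(object, ...) {
  tr <- object$trajectory
  structure(list(apoptotic_pct = object$apoptotic_pct,
                 final = tr[nrow(tr), ],
                 peak_BaxOligo = max(tr[, "BaxOligo"]),
                 threshold_crossing = .crossing_time(object),
                 conservation_drift = object$conservation_drift),
            class = "summary.apoptosis_sim")
}

#' @export
print.summary.apoptosis_sim <- function(x, ...) {
  cat(sprintf("apoptotic cells: %.2f%%\n", x$apoptotic_pct))
  cat(sprintf("peak oligomerized Bax: %.2f nM (threshold crossing at %s min)\n",
              x$peak_BaxOligo,
              if (is.finite(x$threshold_crossing)) x$threshold_crossing
              else "never"))
  cat(sprintf("conservation drift: %.2e\n", x$conservation_drift))
  invisible(x)
}

.crossing_time <- function(sim) {
  i <- which(sim$trajectory[, "BaxOligo"] >= sim$params$bax_star)
  if (length(i)) sim$times[i[1]] else Inf
}

#' @export
plot.apoptosis_sim <- function(x, species = c("BaxOligo", "tBid", "Bik_act"),
                               ...) {
  old <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1.5, 1))
  on.exit(graphics::par(old))
  graphics::matplot(x$times, x$trajectory[, species, drop = FALSE],
                    type = "l", lty = 1, xlab = "time (min)",
                    ylab = "concentration (nM)", ...)
  graphics::abline(h = x$params$bax_star, lty = 3)
  graphics::legend("topleft", legend = species, col = seq_along(species),
                   lty = 1, bty = "n")
  graphics::plot(x$times, x$trajectory[, "n"], type = "l",
                 xlab = "time (min)", ylab = "surviving cells (%)",
                 ylim = c(0, 100))
  invisible(x)
}

#' Estimate the Bik activation rate from a colocalization fraction
#'
#' First-order relocation gives a mitochondrial fraction
#' `1 - exp(-kact * t)`; inverting at the observed fraction yields
#' `kact = -log(1 - fraction) / t`.  The measured 45% at 2 h gives the
#' reference value 0.005 per min.
#'
#' @param mito_fraction fraction of Bik at the mitochondria, in `[0, 1)`.
#' @param t exposure time (min), positive.
#' @return activation rate (1/min).
#' @export
estimate_kact <- function(mito_fraction, t) {
  if (any(mito_fraction < 0) || any(mito_fraction >= 1))
    stop("mito_fraction must be in [0, 1)")
  if (any(t <= 0)) stop("t must be positive")
  -log(1 - mito_fraction) / t
}

#' Activated share of total Bax behind the apoptotic threshold
#'
#' The threshold is derived as (share of Bax at the mitochondria) x
#' (activated share of mitochondrial Bax); with the measured 33% and 38%
#' this gives ~12.5%, i.e. ~13% of the reference Bax total.
#'
#' @param mito_share fraction of total Bax at the mitochondria.
#' @param active_share activated fraction of mitochondrial Bax.
#' @return activated fraction of total Bax.
#' @export
threshold_fraction <- function(mito_share, active_share) {
  if (any(mito_share < 0 | mito_share > 1) ||
      any(active_share < 0 | active_share > 1))
    stop("shares must be fractions in [0, 1]")
  mito_share * active_share
}
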