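# Bik turnover: synthesis at constant rate kS, removal by spontaneous
# ubiquitylation (kubi) and by a Src/Erk-dependent Michaelis-Menten branch
# (Vmax, Km), followed by proteasomal degradation of the polyubiquitylated
# form (kdeg).

#' Bik turnover parameters
#'
#' Rate constants of Bik synthesis, ubiquitylation and degradation for one
#' cell line.  Units: `kS` in nM/min, `kubi` and `kdeg` in 1/min, `Vmax` in
#' nM/min, `Km` in nM.  `kdeg` is fixed to 1 by convention; it only sets the
#' turnover of the polyubiquitylated pool and does not influence Bik itself.
#'
#' @param kS Bik synthesis rate (nM/min).
#' @param kubi spontaneous ubiquitylation rate (1/min).
#' @param Vmax maximal velocity of the Src-dependent ubiquitylation branch
#'   (nM/min); 0 in parental cells, where the branch is inactive.
#' @param Km Michaelis constant of the Src-dependent branch (nM).
#' @param kdeg proteasomal degradation rate of polyubiquitylated Bik (1/min).
#' @return an object of class `bik_params` (a named list).
#' @seealso [parental_bik_params()], [src_bik_params()], [bik_steady_state()]
#' @export
bik_params <- function(kS, kubi, Vmax = 0, Km = 20, kdeg = 1) {
  for (v in c(kS = kS, kubi = kubi, Vmax = Vmax, Km = Km, kdeg = kdeg)) {
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
      stop("all Bik parameters must be single non-negative numbers")
  }
  structure(list(kS = kS, kubi = kubi, Vmax = Vmax, Km = Km, kdeg = kdeg),
            class = "bik_params")
}

#' @export
print.bik_params <- function(x, ...) {
  cat("Bik turnover parameters (nM, min):\n")
  print(unlist(x))
  invisible(x)
}

#' Default Bik parameters for parental fibroblasts
#'
#' The Src-dependent branch is inactive (`Vmax = 0`).  `kubi` defaults to
#' 1/360 per min, so that with degradation switched off Bik would exactly
#' double in six hours; `kS = 50 * kubi` anchors the parental steady state at
#' 50 nM.
#'
#' @param kubi spontaneous ubiquitylation rate (1/min).
#' @param Bik_ss target steady-state concentration (nM).
#' @return a `bik_params` object.
#' @export
parental_bik_params <- function(kubi = 1 / 360, Bik_ss = 50) {
  bik_params(kS = Bik_ss * kubi, kubi = kubi, Vmax = 0, Km = 20)
}

#' Default Bik parameters for Src-transformed fibroblasts
#'
#' Shares `kS` and `kubi` with the parental set and adds the Src-dependent
#' Michaelis-Menten branch.  Only the lumped ratio `Vmax / (Km + Bik_ss)` is
#' identified by steady-state data, so `Km` is fixed (20 nM by default) and
#' `Vmax` is solved from the steady-state balance at the observed Src steady
#' state (9.2 nM).
#'
#' @param Bik_ss Src-transformed steady-state Bik concentration (nM).
#' @param Km Michaelis constant of the Src-dependent branch (nM).
#' @param kubi spontaneous ubiquitylation rate (1/min).
#' @param parental_ss parental steady state anchoring `kS` (nM).
#' @return a `bik_params` object.
#' @export
src_bik_params <- function(Bik_ss = 9.2, Km = 20, kubi = 1 / 360,
                           parental_ss = 50) {
  kS <- parental_ss * kubi
  Vmax <- (kS / Bik_ss - kubi) * (Km + Bik_ss)
  if (Vmax < 0)
    stop("Src steady state above parental steady state is not reachable")
  bik_params(kS = kS, kubi = kubi, Vmax = Vmax, Km = Km)
}

#' Time derivatives of the Bik turnover model
#'
#' @param state named numeric vector with components `Bik` and `BikUb` (nM).
#' @param params a [bik_params()] object.
#' @return named vector of derivatives (nM/min).
#' @export
bik_rhs <- function(state, params) {
  stopifnot(inherits(params, "bik_params"))
  Bik <- state[["Bik"]]; BikUb <- state[["BikUb"]]
  if (Bik < 0 || BikUb < 0) stop("negative Bik concentrations")
  ubi <- params$kubi * Bik + params$Vmax * Bik / (params$Km + Bik)
  d <- c(Bik = params$kS - ubi, BikUb = ubi - params$kdeg * BikUb)
  if (any(!is.finite(d))) stop("non-finite Bik derivatives")
  d
}

#' Steady state of the Bik turnover model
#'
#' Solves `kS = kubi * Bik + Vmax * Bik / (Km + Bik)`, a quadratic in Bik with
#' a unique non-negative root; `BikUb` follows from flux balance
#' (`kdeg * BikUb = kS` at steady state).  When `Vmax = 0` the root is
#' `kS / kubi` exactly.
#'
#' @param params a [bik_params()] object.
#' @return named vector `c(Bik, BikUb)` in nM.
#' @export
bik_steady_state <- function(params) {
  stopifnot(inherits(params, "bik_params"))
  if (params$kubi <= 0 && params$Vmax <= 0)
    stop("no steady state: all removal rates are zero")
  if (params$Vmax == 0) {
    if (params$kubi <= 0) stop("no steady state: all removal rates are zero")
    Bik <- params$kS / params$kubi
  } else if (params$kubi == 0) {
    # kS * (Km + B) = Vmax * B  =>  B = kS * Km / (Vmax - kS)
    if (params$kS >= params$Vmax)
      stop("synthesis exceeds maximal removal capacity: no steady state")
    Bik <- params$kS * params$Km / (params$Vmax - params$kS)
  } else {
    # kubi*B^2 + (kubi*Km + Vmax - kS)*B - kS*Km = 0
    a <- params$kubi
    b <- params$kubi * params$Km + params$Vmax - params$kS
    cc <- -params$kS * params$Km
    Bik <- (-b + sqrt(b^2 - 4 * a * cc)) / (2 * a)
  }
  c(Bik = Bik, BikUb = params$kS / params$kdeg)
}

#' Bik level under the accumulation hypothesis
#'
#' If an apoptotic stress switched off both ubiquitylation routes while
#' leaving synthesis unchanged, Bik would grow linearly:
#' `Bik(t) = Bik0 + kS * t`.  Evaluated at six hours with the default
#' parental rates this predicts only a doubling, which is the argument
#' against an accumulation-based trigger of apoptosis.
#'
#' @param t time since stress onset (min), non-negative.
#' @param Bik0 initial Bik concentration (nM).
#' @param kS synthesis rate (nM/min).
#' @return Bik concentration (nM) at `t`.
#' @export
accumulation_profile <- function(t, Bik0, kS) {
  if (any(t < 0)) stop("t must be non-negative")
  Bik0 + kS * t
}

#' Apply Src-kinase inhibition (herbimycin) to Bik parameters
#'
#' Herbimycin exposure is modelled as a fractional reduction of the maximal
#' velocity of the Src-dependent ubiquitylation branch (98% by default, the
#' measured drop in Src Y416 phosphorylation).
#'
#' @param params a [bik_params()] object.
#' @param inhibition fraction of `Vmax` removed, in `[0, 1]`.
#' @return a `bik_params` object with `Vmax` rescaled.
#' @export
apply_herbimycin <- function(params, inhibition = 0.98) {
  stopifnot(inherits(params, "bik_params"))
  if (!is.numeric(inhibition) || length(inhibition) != 1L ||
      is.na(inhibition) || inhibition < 0 || inhibition > 1)
    stop("inhibition must be a fraction in [0, 1]")
  params$Vmax <- params$Vmax * (1 - inhibition)
  params
}

#' Simulate a cycloheximide-chase Bik decay curve
#'
#' Chase conditions: synthesis is blocked (`kS = 0`) and the relative Bik
#' level `Bik(t) / Bik(0)` is followed.  With `Vmax = 0` the decay is
#' `exp(-kubi * t)` in closed form; otherwise the one-dimensional ODE is
#' integrated.  The absolute starting level defaults to the steady state of
#' `params`, which matters because the Michaelis-Menten branch is nonlinear.
#'
#' @param params a [bik_params()] object.
#' @param times sampling times (min), starting at 0.
#' @param Bik0 starting concentration (nM); default the steady state.
#' @return numeric vector of relative levels, 1 at `t = 0`.
#' @export
simulate_bik_decay <- function(params, times, Bik0 = NULL) {
  stopifnot(inherits(params, "bik_params"))
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (is.null(Bik0)) Bik0 <- bik_steady_state(params)[["Bik"]]
  if (params$Vmax == 0) return(exp(-params$kubi * (times - times[1])))
  rhs <- function(t, y, p) {
    B <- y[1]
    list(-p$kubi * B - p$Vmax * B / (p$Km + B))
  }
  tt <- times - times[1]
  out <- deSolve::ode(c(B = Bik0), tt, rhs, params, method = "lsoda",
                      rtol = 1e-10, atol = 1e-12)
  unname(out[, "B"] / Bik0)
}
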