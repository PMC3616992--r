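# Declarative treatment layer.  Drugs and genetic perturbations map onto
# parameter and initial-condition changes; pre-incubated agents (Src
# inhibitor, BH3 mimetic) act before t = 0, so the resting state is
# re-derived after applying them.  Identical changes are applied to both
# cell lines, mimicking systemic exposure.

#' Treatment specification
#'
#' @param staurosporine logical; the cytotoxic stimulus.  When `TRUE`, Bik
#'   activation and Bid truncation switch on at `t = 0`; when `FALSE` both
#'   stay off and the resting state does not move.
#' @param src_inhibition fraction of the Src-dependent Bik ubiquitylation
#'   velocity removed before the stimulus (0.98 models herbimycin); the Bik
#'   steady state re-equilibrates before `t = 0`.
#' @param bcl2_depletion nM removed from the total anti-apoptotic pool
#'   (BH3-mimetic surrogate, e.g. ABT-737).  Pre-incubation also dissociates
#'   complexes: if the depleted pool can no longer hold all pre-existing
#'   tBid, the remainder starts free.
#' @param bax_delta nM removed from total Bax (down-regulator), floored at 0.
#' @param bcl2_delta_generic signed nM change of the anti-apoptotic pool
#'   (generic up-/down-regulator), applied after `bcl2_depletion`.
#' @param tbid_up nM added to the pre-existing tBid pool, capped at
#'   `Bid_total`.
#' @return an object of class `treatment_spec`.
#' @export
treatment_spec <- function(staurosporine = FALSE, src_inhibition = 0,
                           bcl2_depletion = 0, bax_delta = 0,
                           bcl2_delta_generic = 0, tbid_up = 0) {
  if (!is.logical(staurosporine) || length(staurosporine) != 1L ||
      is.na(staurosporine))
    stop("staurosporine must be TRUE or FALSE")
  if (src_inhibition < 0 || src_inhibition > 1)
    stop("src_inhibition must be a fraction in [0, 1]")
  if (bcl2_depletion < 0 || bax_delta < 0 || tbid_up < 0)
    stop("bcl2_depletion, bax_delta and tbid_up must be non-negative")
  structure(list(staurosporine = staurosporine,
                 src_inhibition = src_inhibition,
                 bcl2_depletion = bcl2_depletion, bax_delta = bax_delta,
                 bcl2_delta_generic = bcl2_delta_generic,
                 tbid_up = tbid_up),
            class = "treatment_spec")
}

#' @export
format.treatment_spec <- function(x, ...) {
  parts <- character(0)
  if (x$staurosporine) parts <- "STS"
  if (x$src_inhibition > 0)
    parts <- c(parts, sprintf("Src-inh %.0f%%", 100 * x$src_inhibition))
  if (x$bcl2_depletion > 0)
    parts <- c(parts, sprintf("Bcl2 -%g nM", x$bcl2_depletion))
  if (x$bcl2_delta_generic != 0)
    parts <- c(parts, sprintf("Bcl2 %+g nM", x$bcl2_delta_generic))
  if (x$bax_delta > 0) parts <- c(parts, sprintf("Bax -%g nM", x$bax_delta))
  if (x$tbid_up > 0) parts <- c(parts, sprintf("tBid +%g nM", x$tbid_up))
  if (!length(parts)) parts <- "untreated"
  paste(parts, collapse = " + ")
}

#' @export
print.treatment_spec <- function(x, ...) {
  cat("Treatment:", format(x), "\n")
  invisible(x)
}

#' Apply a treatment to a cell line
#'
#' Order of application: (1) Src inhibition rescales the Bik `Vmax` and the
#' Bik steady state re-equilibrates to its new value before the stimulus;
#' (2) the anti-apoptotic pool is depleted (and changed by the generic
#' delta), dissociating tBid complexes that no longer fit; (3) Bax is
#' down-regulated; (4) the pre-existing tBid pool is raised; (5)
#' staurosporine toggles `kact` and `ktrunc` on (they are zeroed when it is
#' absent).  The returned initial state reflects all pre-incubations.
#'
#' @param cell a [cell_line_spec()].
#' @param bik Bik turnover parameters of the cell line ([bik_params()]).
#' @param net an [apoptosis_params()] object.
#' @param rx a [treatment_spec()].
#' @return list with modified `cell`, `bik`, `net` and the initial `state`.
#' @export
apply_treatment <- function(cell, bik, net, rx) {
  stopifnot(inherits(cell, "cell_line_spec"), inherits(bik, "bik_params"),
            inherits(net, "apoptosis_params"), inherits(rx, "treatment_spec"))
  if (rx$src_inhibition > 0) {
    bik <- apply_herbimycin(bik, rx$src_inhibition)
    cell$Bik_ss <- bik_steady_state(bik)[["Bik"]]
  }
  cell$Bcl2_total <- max(cell$Bcl2_total - rx$bcl2_depletion +
                           rx$bcl2_delta_generic, 0)
  cell$Bax_total <- max(cell$Bax_total - rx$bax_delta, 0)
  cell$tBid0 <- min(cell$tBid0 + rx$tbid_up, cell$Bid_total)
  # initial complexation after pre-incubation: the pool binds what it can,
  # the unbound remainder of the pre-existing tBid starts free
  ctb <- min(cell$tBid0, cell$Bcl2_total)
  state <- c(Bik_in = cell$Bik_ss, Bik_act = 0, C_bik = 0,
             Bid = cell$Bid_total - cell$tBid0, tBid = cell$tBid0 - ctb,
             C_tbid = ctb, BaxC = cell$Bax_total, BaxO = 0, BaxOligo = 0,
             Bcl2 = cell$Bcl2_total - ctb, C_bax = 0, n = 100)
  if (!rx$staurosporine) {
    net$kact <- 0
    net$ktrunc <- 0
  }
  list(cell = cell, bik = bik, net = net, state = state)
}

#' Apoptosis across a BH3-mimetic dose scan without the death stimulus
#'
#' Simulates increasing depletion of the anti-apoptotic pool with
#' staurosporine off.  In this biological system no dose induces death: the
#' resting tBid pool is too small to drive Bax oligomerization even when the
#' whole anti-apoptotic pool is neutralized (the system is not
#' "primed for death").
#'
#' @param cell a [cell_line_spec()].
#' @param net an [apoptosis_params()] object.
#' @param depletions numeric vector of depletions (nM).
#' @param bik optional [bik_params()] for the cell line.
#' @param t_end horizon (min).
#' @return numeric vector of apoptotic percentages, one per depletion.
#' @export
abt_alone_scan <- function(cell, net, depletions, bik = NULL, t_end = 480) {
  vapply(depletions, function(d) {
    simulate_apoptosis(cell, net,
                       treatment_spec(staurosporine = FALSE,
                                      bcl2_depletion = d),
                       t_end = t_end, bik = bik)$apoptotic_pct
  }, numeric(1))
}

#' Shipped treatment arms
#'
#' The six scenario arms used throughout: untreated, staurosporine alone,
#' staurosporine + herbimycin, staurosporine + ABT-737 (182 nM pool
#' depletion), staurosporine + Bax down-regulation alone, and a
#' representative optimal four-agent combination.
#'
#' @return named list of [treatment_spec()] objects.
#' @export
scenario_arms <- function() {
  list(none = treatment_spec(),
       sts = treatment_spec(staurosporine = TRUE),
       sts_herbimycin = treatment_spec(staurosporine = TRUE,
                                       src_inhibition = 0.98),
       sts_abt737 = treatment_spec(staurosporine = TRUE,
                                   bcl2_depletion = 182),
       sts_bax_down = treatment_spec(staurosporine = TRUE, bax_delta = 40),
       optimal_4agent = treatment_spec(staurosporine = TRUE,
                                       src_inhibition = 1,
                                       bcl2_depletion = 550, bax_delta = 42,
                                       tbid_up = 0))
}
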