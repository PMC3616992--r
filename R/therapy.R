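# In-silico therapy design.  Staurosporine is the cytotoxic backbone of
# every design; the four free knobs are Src inhibition, depletion of the
# anti-apoptotic pool, Bax down-regulation and tBid up-regulation, applied
# identically to both cell lines.  Efficacy is the apoptotic percentage in
# the Src-transformed (cancer) population, toxicity the apoptotic percentage
# in the parental (healthy) population; a design is feasible when toxicity
# stays at or below the tolerability cap (1% by default).

.knob_ranges <- function() {
  list(src_inhibition = c(0, 1),
       bcl2_depletion = c(0, 600),
       bax_delta = c(0, 48),
       tbid_up = c(0, 52))
}

.design_rx <- function(values) {
  do.call(treatment_spec,
          c(list(staurosporine = TRUE), as.list(values)))
}

#' Evaluate a therapy design on both cell lines
#'
#' @param values named numeric vector of knob settings (any subset of
#'   `src_inhibition`, `bcl2_depletion`, `bax_delta`, `tbid_up`).
#' @param params an [apoptosis_params()] object (the calibrated set by
#'   default).
#' @param cells named list with `parental` and `src` [cell_line_spec()]s.
#' @param tox_cap tolerability cap on parental apoptosis (%).
#' @param penalty cost added when the cap is exceeded.
#' @param dt,rtol,atol solver settings.
#' @return an object of class `therapy_design`: list with `values`,
#'   `efficacy`, `toxicity`, `feasible`, `cost`.
#' @export
evaluate_design <- function(values, params = calibrated_apoptosis_params(),
                            cells = list(parental = parental_cell(),
                                         src = src_cell()),
                            tox_cap = 1, penalty = 1000,
                            dt = 1, rtol = 1e-8, atol = 1e-10) {
  rx <- .design_rx(values)
  tox <- simulate_apoptosis(cells$parental, params, rx, dt = dt,
                            rtol = rtol, atol = atol)$apoptotic_pct
  eff <- simulate_apoptosis(cells$src, params, rx, dt = dt,
                            rtol = rtol, atol = atol)$apoptotic_pct
  structure(list(values = values, efficacy = eff, toxicity = tox,
                 feasible = tox <= tox_cap,
                 cost = (100 - eff) + penalty * (tox > tox_cap)),
            class = "therapy_design")
}

#' @export
print.therapy_design <- function(x, ...) {
  cat("Therapy design:", format(.design_rx(x$values)), "\n")
  cat(sprintf("  efficacy %.2f%% (Src), toxicity %.2f%% (parental), %s\n",
              x$efficacy, x$toxicity,
              if (x$feasible) "feasible" else "infeasible"))
  cat(sprintf("  cost = %.4g\n", x$cost))
  invisible(x)
}

#' Therapy cost of a design
#'
#' Percentage of surviving cancer cells plus a flat penalty when parental
#' toxicity exceeds the cap.
#'
#' @inheritParams evaluate_design
#' @return scalar cost.
#' @export
therapy_cost <- function(values, params = calibrated_apoptosis_params(),
                         cells = list(parental = parental_cell(),
                                      src = src_cell()),
                         tox_cap = 1, penalty = 1000, ...) {
  evaluate_design(values, params, cells, tox_cap, penalty, ...)$cost
}

# inner optimization of a knob subset: coarse grid (or Latin-hypercube for
# >2 knobs) pre-scan to escape the flat penalty plateau, then CMA-ES polish
# on the unit cube
.optimize_knobs <- function(knobs, params, cells, tox_cap, penalty, seed,
                            grid_n = 10L, maxiter = 60L, dt = 4,
                            rtol = 1e-6, atol = 1e-8) {
  ranges <- .knob_ranges()[knobs]
  k <- length(knobs)
  scale <- function(u) {
    v <- vapply(seq_len(k), function(i)
      ranges[[i]][1] + u[i] * diff(ranges[[i]]), numeric(1))
    stats::setNames(v, knobs)
  }
  obj <- function(u) therapy_cost(scale(u), params, cells, tox_cap, penalty,
                                  dt = dt, rtol = rtol, atol = atol)
  if (k == 0L)
    return(evaluate_design(stats::setNames(numeric(0), character(0)),
                           params, cells, tox_cap, penalty))
  if (k <= 2L) {
    pts <- as.matrix(expand.grid(rep(list(seq(0, 1, length.out = grid_n)),
                                     k)))
  } else {
    set.seed(seed)
    m <- max(grid_n^2, 16L * k)
    pts <- vapply(seq_len(k), function(j)      # Latin hypercube
      (sample.int(m) - stats::runif(m)) / m, numeric(m))
  }
  vals <- apply(pts, 1, obj)
  u0 <- pts[which.min(vals), ]
  r <- cma_es(obj, u0, sigma0 = 0.15, lower = 0, upper = 1,
              maxiter = maxiter, seed = seed, stop_fitness = 0.1)
  best_u <- if (r$value < min(vals)) r$par else u0
  evaluate_design(scale(best_u), params, cells, tox_cap, penalty)
}

#' Optimize a multi-agent therapy
#'
#' Minimizes [therapy_cost()] over the requested knobs (all four by
#' default): a stratified pre-scan seeds a CMA-ES search on the scaled knob
#' space; the best design is re-evaluated at tight solver tolerances.
#'
#' @param knobs character vector of knobs to free.
#' @param params an [apoptosis_params()] object.
#' @param cells named list with `parental` and `src` [cell_line_spec()]s.
#' @param tox_cap tolerability cap (%).
#' @param penalty flat penalty for exceeding the cap.
#' @param seed integer seed.
#' @param maxiter CMA-ES generations.
#' @return a `therapy_design` object.
#' @export
optimize_therapy <- function(knobs = c("src_inhibition", "bcl2_depletion",
                                       "bax_delta", "tbid_up"),
                             params = calibrated_apoptosis_params(),
                             cells = list(parental = parental_cell(),
                                          src = src_cell()),
                             tox_cap = 1, penalty = 1000, seed = 42L,
                             maxiter = 80L) {
  stopifnot(all(knobs %in% names(.knob_ranges())))
  .optimize_knobs(knobs, params, cells, tox_cap, penalty, seed,
                  maxiter = maxiter)
}

#' Rank one- and two-agent combinations
#'
#' Exhaustively optimizes every knob subset of size at most `max_agents`
#' (staurosporine always on) under the toxicity cap and reports efficacy,
#' toxicity and feasibility per subset, ranked by cost.
#'
#' @param max_agents 1 or 2.
#' @inheritParams optimize_therapy
#' @return data frame with one row per subset: `agents`, the optimized knob
#'   values, `efficacy`, `toxicity`, `feasible`, `cost`.
#' @export
rank_combinations <- function(max_agents = 2L,
                              params = calibrated_apoptosis_params(),
                              cells = list(parental = parental_cell(),
                                           src = src_cell()),
                              tox_cap = 1, penalty = 1000, seed = 42L) {
  stopifnot(max_agents %in% 1:2)
  knobs <- names(.knob_ranges())
  subsets <- list(character(0))
  subsets <- c(subsets, as.list(knobs))
  if (max_agents == 2L)
    subsets <- c(subsets, utils::combn(knobs, 2L, simplify = FALSE))
  rows <- lapply(seq_along(subsets), function(i) {
    d <- .optimize_knobs(subsets[[i]], params, cells, tox_cap, penalty,
                         seed = seed + i)
    vals <- stats::setNames(rep(0, length(knobs)), knobs)
    vals[names(d$values)] <- d$values
    data.frame(agents = paste(subsets[[i]], collapse = "+"),
               t(vals), efficacy = d$efficacy, toxicity = d$toxicity,
               feasible = d$feasible, cost = d$cost)
  })
  out <- do.call(rbind, rows)
  out$agents[out$agents == ""] <- "(staurosporine alone)"
  out[order(out$cost), ]
}
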