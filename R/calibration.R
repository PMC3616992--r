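# Constrained calibration of the apoptosis network: least squares on
# endpoint apoptosis percentages plus a flat 1000-per-violation penalty on
# trajectory/parameter constraints, minimized by CMA-ES in log10 space with
# a multi-start schedule.

.default_free <- c("ktrunc", "k_disp", "kcat_bax", "Km_bax", "k_dim",
                   "k_auto", "k_bax_bcl2", "k_back", "gamma", "a")

.default_bounds <- function() {
  list(lower = c(ktrunc = 1e-6, k_disp = 1e-6, kcat_bax = 1e-6,
                 Km_bax = 1e-2, k_dim = 1e-6, k_auto = 1e-6,
                 k_bax_bcl2 = 1e-6, k_back = 1e-6, gamma = 1, a = 1e-4),
       upper = c(ktrunc = 1, k_disp = 1, kcat_bax = 10, Km_bax = 1e3,
                 k_dim = 1, k_auto = 1, k_bax_bcl2 = 1, k_back = 1,
                 gamma = 8, a = 1))
}

# simulation context shared by datapoint residuals and constraints; arms are
# simulated once per cost evaluation, on a coarse grid for speed
.calibration_context <- function(params, problem) {
  cache <- new.env(parent = emptyenv())
  sim <- function(cell, rx) {
    key <- paste(cell$label, format(rx))
    if (!is.null(cache[[key]])) return(cache[[key]])
    s <- simulate_apoptosis(cell, params, rx, t_end = problem$t_end,
                            dt = problem$sim_dt, rtol = problem$sim_rtol,
                            atol = problem$sim_atol)
    cache[[key]] <- s
    s
  }
  list(params = params, problem = problem, sim = sim,
       cells = problem$cells)
}

#' Constraint suite for network calibration
#'
#' Named predicates evaluated on a candidate parameter set and its simulated
#' trajectories; each unsatisfied predicate adds `penalty_weight` to the
#' calibration cost.
#'
#' * `crossing_window`: oligomerized Bax crosses the apoptotic threshold in
#'   parental cells between 6 and 8 h of staurosporine.
#' * `activated_bax_cap`: activated Bax (everything that left the closed
#'   form) stays below 20% of total Bax during the first 6 h of
#'   staurosporine in Src-transformed cells.
#' * `autocatalysis_dominance`: `k_auto / k_dim > 10`.
#' * `association_bounds`: all association rates within
#'   `[1e-6, 1]` /(nM min) (diffusion-limited range).
#' * `src_resistance`: Src-transformed cells stay below 20% apoptosis under
#'   staurosporine alone.
#' * `no_death_unprimed`: full depletion of the anti-apoptotic pool without
#'   staurosporine kills less than 1% of parental cells (the system is not
#'   primed for death).
#'
#' @param include character vector naming the predicates to keep.
#' @return named list of predicate functions `function(ctx) -> logical`.
#' @export
constraint_suite <- function(include = c("crossing_window",
                                         "activated_bax_cap",
                                         "autocatalysis_dominance",
                                         "association_bounds",
                                         "src_resistance",
                                         "no_death_unprimed")) {
  all <- list(
    crossing_window = function(ctx) {
      s <- ctx$sim(ctx$cells$parental, treatment_spec(staurosporine = TRUE))
      tc <- .crossing_time(s)
      is.finite(tc) && tc >= 360 && tc <= 480
    },
    activated_bax_cap = function(ctx) {
      s <- ctx$sim(ctx$cells$src, treatment_spec(staurosporine = TRUE))
      i <- s$times <= 360
      tot <- ctx$cells$src$Bax_total
      max(tot - s$trajectory[i, "BaxC"]) <= 0.20 * tot
    },
    autocatalysis_dominance = function(ctx)
      ctx$params$k_auto / ctx$params$k_dim > 10,
    association_bounds = function(ctx) {
      r <- unlist(ctx$params[c("k_bik_bcl2", "k_tbid_bcl2", "k_dim",
                               "k_auto", "k_bax_bcl2", "k_disp")])
      all(r >= 1e-6 & r <= 1)
    },
    src_resistance = function(ctx) {
      s <- ctx$sim(ctx$cells$src, treatment_spec(staurosporine = TRUE))
      s$apoptotic_pct <= 20
    },
    no_death_unprimed = function(ctx) {
      cell <- ctx$cells$parental
      s <- ctx$sim(cell, treatment_spec(staurosporine = FALSE,
                                        bcl2_depletion = cell$Bcl2_total))
      s$apoptotic_pct < 1
    })
  all[include]
}

#' Default calibration datapoints
#'
#' The three printed endpoint measurements: parental staurosporine 80%,
#' parental staurosporine + herbimycin 80%, Src-transformed staurosporine +
#' herbimycin 99% apoptotic cells after 8 h.
#'
#' @return data frame with columns `cell_line`, `rx` (list of
#'   [treatment_spec()]) and `observed` (%).
#' @export
calibration_datapoints <- function() {
  sts <- treatment_spec(staurosporine = TRUE)
  herb <- treatment_spec(staurosporine = TRUE, src_inhibition = 0.98)
  d <- data.frame(cell_line = c("parental", "parental", "src"),
                  observed = c(80, 80, 99))
  d$rx <- list(sts, herb, herb)
  d
}

#' Define a calibration problem
#'
#' @param datapoints data frame as returned by [calibration_datapoints()].
#' @param constraints predicate list from [constraint_suite()].
#' @param free names of the free network parameters.
#' @param bounds list with named vectors `lower`, `upper` for the free
#'   parameters (natural units; the search is in log10 space).
#' @param penalty_weight cost added per unsatisfied constraint.
#' @param cells named list with `parental` and `src` [cell_line_spec()]s.
#' @param t_end simulation horizon (min).
#' @param sim_dt,sim_rtol,sim_atol solver settings used during optimization
#'   (coarser than the reporting defaults, for speed).
#' @return an object of class `calibration_problem`.
#' @export
calibration_problem <- function(datapoints = calibration_datapoints(),
                                constraints = constraint_suite(),
                                free = .default_free,
                                bounds = .default_bounds(),
                                penalty_weight = 1000,
                                cells = list(parental = parental_cell(),
                                             src = src_cell()),
                                t_end = 480, sim_dt = 4,
                                sim_rtol = 1e-6, sim_atol = 1e-8) {
  if (penalty_weight <= 0) stop("penalty_weight must be positive")
  stopifnot(all(free %in% names(bounds$lower)),
            all(free %in% names(bounds$upper)))
  structure(list(datapoints = datapoints, constraints = constraints,
                 free = free, bounds = bounds,
                 penalty_weight = penalty_weight, cells = cells,
                 t_end = t_end, sim_dt = sim_dt, sim_rtol = sim_rtol,
                 sim_atol = sim_atol),
            class = "calibration_problem")
}

#' Calibration cost of a parameter set
#'
#' Sum of squared residuals between simulated and observed apoptotic
#' percentages plus `penalty_weight` times the number of unsatisfied
#' constraints.  A simulation failure returns a large sentinel value.
#'
#' @param params an [apoptosis_params()] object.
#' @param problem a [calibration_problem()].
#' @return scalar cost with attributes `residuals` (per datapoint) and
#'   `violated` (names of unsatisfied constraints).
#' @export
calibration_cost <- function(params, problem) {
  ctx <- .calibration_context(params, problem)
  out <- tryCatch({
    resid <- vapply(seq_len(nrow(problem$datapoints)), function(i) {
      d <- problem$datapoints[i, ]
      s <- ctx$sim(problem$cells[[d$cell_line]], d$rx[[1]])
      s$apoptotic_pct - d$observed
    }, numeric(1))
    ok <- vapply(problem$constraints, function(f)
      isTRUE(f(ctx)), logical(1))
    cost <- sum(resid^2) + problem$penalty_weight * sum(!ok)
    attr(cost, "residuals") <- resid
    attr(cost, "violated") <- names(problem$constraints)[!ok]
    cost
  }, error = function(e) {
    structure(1e8, residuals = NULL, violated = "simulation_failure")
  })
  out
}

# multi-start initial points, in natural units of the free parameters.
# Endpoint data leave the Bid-truncation axis essentially unconstrained a
# priori, so the starts are dispersed along it (and along the catalytic Bax
# activation rate) around the published reference values.
.default_starts <- function(free) {
  ref <- unlist(unclass(apoptosis_params())[free])
  tweak <- function(...) {
    x <- ref
    mods <- list(...)
    x[names(mods)] <- unlist(mods)
    x
  }
  list(tweak(ktrunc = 1e-3, kcat_bax = 0.05),
       tweak(),
       tweak(ktrunc = 3e-3),
       tweak(ktrunc = 0.01, kcat_bax = 0.005))
}

#' Calibrate the apoptosis network
#'
#' Multi-start CMA-ES minimization of [calibration_cost()] in log10 space.
#' Starts are tried in order; the schedule stops early once a start reaches
#' `stop_fitness` (all constraints satisfied and endpoints fitted to within
#' a fraction of a percentage point).  Deterministic given `seed`.
#'
#' @param problem a [calibration_problem()].
#' @param seed integer seed.
#' @param starts list of named start vectors (natural units); default a
#'   dispersed multi-start schedule around the reference values.
#' @param maxiter CMA-ES generations per start.
#' @param stop_fitness early-stop cost.
#' @return an object of class `apoptosis_fit`: list with `params` (the best
#'   [apoptosis_params()]), `cost`, `residuals`, `violated`, `trace`,
#'   `starts` (per-start best costs), `problem`, `seed`.
#' @export
calibrate_apoptosis <- function(problem = calibration_problem(), seed = 42L,
                                starts = NULL, maxiter = 250L,
                                stop_fitness = 0.5) {
  free <- problem$free
  if (is.null(starts)) starts <- .default_starts(free)
  if (!length(starts)) stop("at least one start is required")
  base <- apoptosis_params()
  lb <- log10(problem$bounds$lower[free])
  ub <- log10(problem$bounds$upper[free])
  make_params <- function(x) {
    v <- as.list(10^x)
    names(v) <- free
    do.call(apoptosis_params, utils::modifyList(unclass(base), v))
  }
  if (!length(free)) {                      # degenerate: nothing to fit
    cost <- calibration_cost(base, problem)
    return(structure(list(params = base, cost = as.numeric(cost),
                          residuals = attr(cost, "residuals"),
                          violated = attr(cost, "violated"),
                          trace = as.numeric(cost), starts = numeric(0),
                          problem = problem, seed = seed),
                     class = "apoptosis_fit"))
  }
  objective <- function(x) as.numeric(calibration_cost(make_params(x),
                                                       problem))
  best <- NULL
  per_start <- numeric(0)
  for (i in seq_along(starts)) {
    x0 <- log10(starts[[i]][free])
    r <- cma_es(objective, x0, sigma0 = 0.5, lower = lb, upper = ub,
                maxiter = maxiter, seed = seed + i - 1L,
                stop_fitness = stop_fitness)
    per_start[i] <- r$value
    if (is.null(best) || r$value < best$value) best <- r
    if (best$value <= stop_fitness) break
  }
  params <- make_params(best$par)
  cost <- calibration_cost(params, problem)
  structure(list(params = params, cost = as.numeric(cost),
                 residuals = attr(cost, "residuals"),
                 violated = attr(cost, "violated"), trace = best$trace,
                 starts = per_start, problem = problem, seed = seed),
            class = "apoptosis_fit")
}

#' @export
print.apoptosis_fit <- function(x, ...) {
  cat("Calibrated apoptosis network\n")
  cat(sprintf("  cost = %.4g (%d datapoints, %d constraints, %d start(s))\n",
              x$cost, nrow(x$problem$datapoints),
              length(x$problem$constraints), length(x$starts)))
  if (length(x$violated)) cat("  violated:", paste(x$violated,
                                                   collapse = ", "), "\n")
  print(unlist(unclass(x$params)[x$problem$free]))
  invisible(x)
}

#' @export
coef.apoptosis_fit <- function(object, ...) {
  unlist(unclass(object$params)[object$problem$free])
}

#' @export
summary.apoptosis_fit <- function(object, ...) {
  d <- object$problem$datapoints
  fitted <- d$observed + object$residuals
  structure(list(coef = coef(object), cost = object$cost,
                 endpoints = data.frame(cell_line = d$cell_line,
                                        treatment = vapply(d$rx, format, ""),
                                        observed = d$observed,
                                        fitted = fitted),
                 violated = object$violated),
            class = "summary.apoptosis_fit")
}

#' @export
print.summary.apoptosis_fit <- function(x, ...) {
  print(x$endpoints)
  cat(sprintf("cost = %.4g\n", x$cost))
  if (length(x$violated)) cat("violated:", paste(x$violated,
                                                 collapse = ", "), "\n")
  print(x$coef)
  invisible(x)
}
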