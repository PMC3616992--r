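# Fitting Bik turnover parameters to chase-style decay time courses.
# Chase data are relative (fraction of the t = 0 level), which removes the
# synthesis rate from the likelihood; kS is therefore anchored by the
# parental steady state (50 nM) and only reported, never fitted.
#
# The optimizer does not search (Vmax, Km) directly: that pair is
# ill-conditioned (a broad compensation valley where a shifted kubi plus a
# pseudo-zeroth-order Michaelis-Menten term mimics the true decay).  The
# search coordinates are kubi, the lumped initial-slope contribution
# lump = Vmax / (Km + B0), and Km, with B0 = kS / (kubi + lump) the
# self-consistent steady state; Vmax = lump * (Km + B0) is derived.  In
# these coordinates the only weak direction is Km itself, and a CMA-ES run
# plus a quasi-Newton polish recovers noise-free parameters to numerical
# precision.

#' Fit Bik turnover parameters to decay time courses
#'
#' Least-squares fit of the chase-decay model to one or more relative decay
#' courses, minimized by [cma_es()] in log10 parameter space.  Every cell
#' line gets its own Michaelis-Menten pair (`Vmax`, `Km`); the spontaneous
#' rate `kubi` is shared across cell lines by default.  Courses labelled
#' `treatment == "herbimycin"` are fitted with `Vmax` scaled by 0.02.  The
#' starting level of a course is the steady state implied by the candidate
#' parameters (with `kS = 50 * kubi`), so the nonlinearity of the
#' Src-dependent branch is probed by the decay shape.
#'
#' @param timecourses data frame with columns `time_min`, `rel_level`,
#'   `cell_line`, `treatment` (`"none"` or `"herbimycin"`).
#' @param shared_kubi logical; estimate a single `kubi` across cell lines.
#' @param seed integer seed for the optimizer.
#' @param maxiter CMA-ES generations.
#' @param bounds length-2 numeric, common search interval for all rates.
#' @param parental_ss steady-state anchor for `kS` (nM).
#' @return an object of class `bik_fit`: list with `params` (named list of
#'   [bik_params()] per cell line), `residual_norm` (sum of squared
#'   residuals), `trace` (optimizer best-so-far), `converged`, `data`.
#' @export
fit_bik <- function(timecourses, shared_kubi = TRUE, seed = 42L,
                    maxiter = 250L, bounds = c(1e-6, 10),
                    parental_ss = 50) {
  req <- c("time_min", "rel_level", "cell_line", "treatment")
  if (!all(req %in% names(timecourses)))
    stop("timecourses must have columns ", paste(req, collapse = ", "))
  lines <- unique(timecourses$cell_line)
  courses <- split(timecourses,
                   interaction(timecourses$cell_line, timecourses$treatment,
                               drop = TRUE))
  # free parameters: kubi (1 shared or 1 per line) + (lump, Km) per line
  kubi_names <- if (shared_kubi) "kubi" else paste0("kubi.", lines)
  mm_names <- as.vector(rbind(paste0("lump.", lines), paste0("Km.", lines)))
  par_names <- c(kubi_names, mm_names)
  npts <- nrow(timecourses)
  if (npts < length(par_names))
    stop("fewer data points (", npts, ") than free parameters (",
         length(par_names), ")")

  unpack <- function(x) {
    names(x) <- par_names
    lapply(stats::setNames(lines, lines), function(ln) {
      kubi <- 10^x[[if (shared_kubi) "kubi" else paste0("kubi.", ln)]]
      lump <- 10^x[[paste0("lump.", ln)]]
      Km <- 10^x[[paste0("Km.", ln)]]
      B0 <- parental_ss * kubi / (kubi + lump)
      bik_params(kS = parental_ss * kubi, kubi = kubi,
                 Vmax = lump * (Km + B0), Km = Km)
    })
  }
  objective <- function(x) {
    pl <- tryCatch(unpack(x), error = function(e) NULL)
    if (is.null(pl)) return(1e8)
    ss <- 0
    for (cr in courses) {
      p <- pl[[as.character(cr$cell_line[1])]]
      if (identical(as.character(cr$treatment[1]), "herbimycin"))
        p <- apply_herbimycin(p, 0.98)
      pred <- tryCatch(simulate_bik_decay(p, cr$time_min),
                       error = function(e) NULL)
      if (is.null(pred) || any(!is.finite(pred))) return(1e8)
      ss <- ss + sum((pred - cr$rel_level)^2)
    }
    ss
  }
  lb <- stats::setNames(rep(log10(bounds[1]), length(par_names)), par_names)
  ub <- stats::setNames(rep(log10(bounds[2]), length(par_names)), par_names)
  lb[grep("^lump", par_names)] <- -9     # the branch may be fully inactive
  lb[grep("^Km", par_names)] <- -2       # Km is a concentration, not a rate
  ub[grep("^Km", par_names)] <- 3
  x0 <- stats::setNames(rep(log10(1 / 360), length(par_names)), par_names)
  x0[grep("^lump", par_names)] <- log10(0.01)
  x0[grep("^Km", par_names)] <- log10(20)
  fit <- cma_es(objective, x0, sigma0 = 0.3, lower = lb, upper = ub,
                maxiter = maxiter, seed = seed, stop_fitness = 1e-12)
  pol <- stats::optim(fit$par, objective, method = "L-BFGS-B",
                      lower = lb, upper = ub,
                      control = list(maxit = 1000, factr = 1e2))
  best <- if (pol$value < fit$value) pol$par else fit$par
  value <- min(pol$value, fit$value)
  structure(list(params = unpack(best), residual_norm = value,
                 trace = fit$trace, converged = fit$converged ||
                   value <= 1e-12,
                 shared_kubi = shared_kubi, data = timecourses),
            class = "bik_fit")
}

#' @export
print.bik_fit <- function(x, ...) {
  cat("Bik decay fit (", length(x$params), " cell line(s), ",
      nrow(x$data), " points)\n", sep = "")
  cat(sprintf("residual sum of squares: %.4g\n", x$residual_norm))
  for (ln in names(x$params)) {
    p <- x$params[[ln]]
    cat(sprintf("  %s: kubi = %.4g /min, Vmax = %.4g nM/min, Km = %.4g nM\n",
                ln, p$kubi, p$Vmax, p$Km))
  }
  invisible(x)
}

#' @export
coef.bik_fit <- function(object, ...) {
  out <- unlist(lapply(object$params, function(p)
    c(kubi = p$kubi, Vmax = p$Vmax, Km = p$Km)))
  out
}

#' @export
summary.bik_fit <- function(object, ...) {
  halflife <- vapply(object$params, function(p) {
    ss <- bik_steady_state(p)[["Bik"]]
    log(2) / (p$kubi + p$Vmax / (p$Km + ss))
  }, numeric(1))
  structure(list(coef = coef(object), residual_norm = object$residual_norm,
                 halflife_min = halflife, converged = object$converged),
            class = "summary.bik_fit")
}

#' @export
print.summary.bik_fit <- function(x, ...) {
  print(x$coef)
  cat(sprintf("residual sum of squares: %.4g\n", x$residual_norm))
  cat("initial decay half-life (min):\n")
  print(round(x$halflife_min, 1))
  invisible(x)
}

#' @export
predict.bik_fit <- function(object, times, cell_line, treatment = "none",
                            ...) {
  p <- object$params[[cell_line]]
  if (is.null(p)) stop("unknown cell line: ", cell_line)
  if (identical(treatment, "herbimycin")) p <- apply_herbimycin(p, 0.98)
  simulate_bik_decay(p, times)
}

#' @export
residuals.bik_fit <- function(object, ...) {
  d <- object$data
  pred <- numeric(nrow(d))
  for (key in split(seq_len(nrow(d)),
                    interaction(d$cell_line, d$treatment, drop = TRUE))) {
    pred[key] <- predict(object, d$time_min[key],
                         as.character(d$cell_line[key[1]]),
                         as.character(d$treatment[key[1]]))
  }
  d$rel_level - pred
}
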