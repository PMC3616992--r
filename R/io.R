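# Serialization glue: decay courses as CSV, parameter sets and run
# configurations as YAML, scenario runs writing tidy trajectory CSVs plus an
# endpoint summary and a conservation audit.

#' Read and write decay time courses
#'
#' CSV with columns `time_min`, `rel_level`, `cell_line`, `treatment`.
#' Reading validates the schema: times strictly increasing within each
#' course, relative levels within `[0, 1.5]`.
#'
#' @param path file path.
#' @return `read_decay_csv` returns the validated data frame.
#' @export
read_decay_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("time_min", "rel_level", "cell_line", "treatment")
  miss <- setdiff(req, names(d))
  if (length(miss))
    stop("decay CSV is missing columns: ", paste(miss, collapse = ", "))
  for (idx in split(seq_len(nrow(d)),
                    interaction(d$cell_line, d$treatment, drop = TRUE))) {
    if (any(diff(d$time_min[idx]) <= 0))
      stop("time_min must be strictly increasing within each course")
  }
  if (any(d$rel_level < 0 | d$rel_level > 1.5))
    stop("rel_level must lie in [0, 1.5]")
  d
}

#' @param x data frame of decay courses.
#' @rdname read_decay_csv
#' @export
write_decay_csv <- function(x, path) {
  utils::write.csv(x[c("time_min", "rel_level", "cell_line", "treatment")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Read and write parameter sets as YAML
#'
#' Bik parameter sets are keyed by cell line; apoptosis parameter sets are a
#' flat mapping.  Values round-trip at full double precision.
#'
#' @param x a [bik_params()], [apoptosis_params()], [cell_line_spec()] or a
#'   named list of them.
#' @param path file path.
#' @return `read_params_yaml` returns the reconstructed object(s).
#' @export
write_params_yaml <- function(x, path) {
  strip <- function(o) {
    if (inherits(o, c("bik_params", "apoptosis_params", "cell_line_spec")))
      c(list(.type = class(o)[1]), unclass(o))
    else if (is.list(o)) lapply(o, strip)
    else o
  }
  writeLines(yaml::as.yaml(strip(x), precision = 15), path)
  invisible(path)
}

#' @rdname write_params_yaml
#' @export
read_params_yaml <- function(path) {
  rebuild <- function(o) {
    if (is.list(o) && !is.null(o$.type)) {
      type <- o$.type
      o$.type <- NULL
      switch(type,
             bik_params = do.call(bik_params, o),
             apoptosis_params = do.call(apoptosis_params, o),
             cell_line_spec = do.call(cell_line_spec, o),
             stop("unknown parameter type: ", type))
    } else if (is.list(o)) lapply(o, rebuild)
    else o
  }
  rebuild(yaml::read_yaml(path))
}

#' Run configuration
#'
#' Bundles everything a scenario run needs; unknown fields are rejected so
#' that configs stay forward-compatible.
#'
#' @param cells named list of [cell_line_spec()]s.
#' @param params an [apoptosis_params()] object.
#' @param arms named list of [treatment_spec()]s.
#' @param t_end horizon (min).
#' @param dt output resolution (min).
#' @param rtol,atol solver tolerances (must be positive).
#' @param seed integer seed recorded with every output.
#' @return an object of class `run_config`.
#' @export
run_config <- function(cells = list(parental = parental_cell(),
                                    src = src_cell()),
                       params = calibrated_apoptosis_params(),
                       arms = scenario_arms(), t_end = 480, dt = 1,
                       rtol = 1e-8, atol = 1e-10, seed = 1L) {
  if (rtol <= 0 || atol <= 0) stop("solver tolerances must be positive")
  if (t_end <= 0 || dt <= 0) stop("t_end and dt must be positive")
  structure(list(cells = cells, params = params, arms = arms, t_end = t_end,
                 dt = dt, rtol = rtol, atol = atol, seed = as.integer(seed)),
            class = "run_config")
}

.config_fields <- c("cells", "params", "arms", "t_end", "dt", "rtol",
                    "atol", "seed")

#' Read a run configuration from YAML
#'
#' @param path file path.
#' @return a [run_config()] object.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), .config_fields)
  if (length(unknown))
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  rebuild_rx <- function(o) do.call(treatment_spec, o)
  args <- list()
  if (!is.null(raw$cells))
    args$cells <- lapply(raw$cells, function(o) do.call(cell_line_spec, o))
  if (!is.null(raw$params)) args$params <- do.call(apoptosis_params,
                                                   raw$params)
  if (!is.null(raw$arms)) args$arms <- lapply(raw$arms, rebuild_rx)
  for (f in c("t_end", "dt", "rtol", "atol", "seed"))
    if (!is.null(raw[[f]])) args[[f]] <- raw[[f]]
  do.call(run_config, args)
}

#' Run treatment scenarios and write their outputs
#'
#' Simulates the selected arms for every cell line in the configuration and
#' writes, under `dir`: one tidy trajectory CSV per (cell line, arm), an
#' endpoint summary `summary.csv` (`cell_line`, `treatment`,
#' `apoptotic_pct`) and a conservation audit `conservation.csv`.  A run log
#' records seed, tolerances and package version.
#'
#' @param config a [run_config()].
#' @param scenarios character vector of arm names; default all arms.
#' @param dir output directory (created if missing).
#' @return the endpoint summary data frame, invisibly.
#' @export
run_scenario <- function(config, scenarios = names(config$arms),
                         dir = tempfile("scenario")) {
  stopifnot(inherits(config, "run_config"))
  missing <- setdiff(scenarios, names(config$arms))
  if (length(missing))
    stop("unknown scenario(s): ", paste(missing, collapse = ", "))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list(); audit <- list()
  for (arm in scenarios) {
    for (cl in names(config$cells)) {
      sim <- simulate_apoptosis(config$cells[[cl]], config$params,
                                config$arms[[arm]], t_end = config$t_end,
                                dt = config$dt, rtol = config$rtol,
                                atol = config$atol)
      tidy <- data.frame(time = rep(sim$times, ncol(sim$trajectory)),
                         species = rep(colnames(sim$trajectory),
                                       each = length(sim$times)),
                         value = as.vector(sim$trajectory),
                         cell_line = cl, treatment = arm)
      utils::write.csv(tidy, file.path(dir, paste0("trajectory_", cl, "_",
                                                   arm, ".csv")),
                       row.names = FALSE)
      rows[[paste(cl, arm)]] <- data.frame(cell_line = cl, treatment = arm,
                                           apoptotic_pct = sim$apoptotic_pct)
      audit[[paste(cl, arm)]] <-
        data.frame(cell_line = cl, treatment = arm,
                   conservation_drift = sim$conservation_drift)
    }
  }
  summary <- do.call(rbind, rows)
  utils::write.csv(summary, file.path(dir, "summary.csv"),
                   row.names = FALSE)
  utils::write.csv(do.call(rbind, audit), file.path(dir, "conservation.csv"),
                   row.names = FALSE)
  writeLines(c(sprintf("seed: %d", config$seed),
               sprintf("rtol: %g  atol: %g  dt: %g", config$rtol,
                       config$atol, config$dt),
               sprintf("package: bcl2dyn %s",
                       as.character(utils::packageVersion("bcl2dyn")))),
             file.path(dir, "run-log.txt"))
  invisible(summary)
}
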