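#' Load a run configuration
#'
#' Reads a YAML configuration holding the model parameters, solver
#' settings, and protocol, filling anything unspecified from the packaged
#' default configuration (the reference parameterization). Unknown keys
#' are an error, as are invariant violations (reported by key name).
#'
#' @param path Path to a YAML file, or `NULL` for the packaged defaults.
#' @return A `run_config`: list with elements `model` (a
#'   [model_params()]), `simple` (a [simple_params()]), `solver`
#'   (`tol`, `max_iter`, `grid_mode`, `interruptible`), `protocol` (a
#'   [protocol()]), `n_trials`, and `seed`.
#' @export
load_config <- function(path = NULL) {
  defaults <- yaml::read_yaml(system.file("extdata", "default_config.yaml",
                                          package = "interforage",
                                          mustWork = TRUE))
  cfg <- defaults
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    for (section in names(user)) {
      if (!(section %in% names(defaults)))
        stop("unknown config section '", section, "'", call. = FALSE)
      if (is.list(user[[section]])) {
        for (key in names(user[[section]])) {
          if (!(key %in% names(defaults[[section]])))
            stop("unknown config key '", section, ".", key, "'",
                 call. = FALSE)
          cfg[[section]][[key]] <- user[[section]][[key]]
        }
      } else cfg[[section]] <- user[[section]]
    }
  }
  m <- cfg$model
  m$delta_by_action <- unlist(m$delta_by_action)
  m$tau_set <- as.numeric(unlist(m$tau_set))
  model <- do.call(model_params, m)
  s <- cfg$simple
  s$tau_set <- as.integer(unlist(s$tau_set))
  simple <- do.call(simple_params, s)
  proto <- protocol(data.frame(
    duration = vapply(cfg$protocol, `[[`, numeric(1), "duration"),
    predator = vapply(cfg$protocol, `[[`, character(1), "predator")))
  structure(list(model = model, simple = simple, solver = cfg$solver,
                 protocol = proto, n_trials = cfg$n_trials,
                 seed = cfg$seed),
            class = "run_config")
}

#' Save a run configuration
#'
#' Writes a [load_config()] object back to YAML; loading the result
#' reproduces the configuration exactly.
#'
#' @param cfg A `run_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  m <- unclass(cfg$model)
  m$delta_by_action <- as.list(m$delta_by_action)
  m$tau_set <- as.numeric(m$tau_set)
  s <- unclass(cfg$simple)
  s$tau_set <- as.integer(s$tau_set)
  out <- list(
    model = m, simple = s, solver = cfg$solver,
    protocol = lapply(seq_len(nrow(cfg$protocol$segments)), function(i) {
      list(duration = cfg$protocol$segments$duration[i],
           predator = cfg$protocol$segments$predator[i])
    }),
    n_trials = cfg$n_trials, seed = cfg$seed)
  yaml::write_yaml(out, path)
  invisible(path)
}

# numbers formatted to full precision so CSV round trips are exact
.fmt_num <- function(x) sprintf("%.17g", x)

#' Write a solved policy to CSV + JSON
#'
#' Writes one CSV per location with columns
#' `beta_P, beta_G, action, tau, value` (numbers at full precision, so
#' files are byte-reproducible across runs) and a JSON sidecar recording
#' the parameters, convergence diagnostics, and package version.
#'
#' @param sol A [value_iteration()] solution.
#' @param prefix Output path prefix; files `<prefix>_refuge.csv`,
#'   `<prefix>_patch.csv`, `<prefix>_meta.json` are written.
#' @return `prefix`, invisibly.
#' @export
write_solution <- function(sol, prefix) {
  g <- sol$grid
  b <- .grid_beliefs(g)
  for (loc in names(sol$policy)) {
    df <- data.frame(beta_P = .fmt_num(b$beta_P), beta_G = .fmt_num(b$beta_G),
                     action = sol$policy[[loc]]$action,
                     tau = .fmt_num(sol$policy[[loc]]$tau),
                     value = .fmt_num(sol$value[[loc]]))
    utils::write.csv(df, paste0(prefix, "_", loc, ".csv"),
                     row.names = FALSE, quote = FALSE)
  }
  p <- unclass(sol$params)
  p$delta_by_action <- as.list(p$delta_by_action)
  meta <- list(params = p, interruptible = sol$interruptible,
               grid_mode = sol$grid_mode, d_beta = g$d_beta,
               tol = sol$tol, iterations = sol$iterations,
               residual = sol$residual, converged = sol$converged,
               package_version =
                 as.character(utils::packageVersion("interforage")))
  jsonlite::write_json(meta, paste0(prefix, "_meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(prefix)
}

#' Read a solved policy written by [write_solution()]
#'
#' Restores the value and policy tables exactly. Continue-value tables
#' (used by the interrupt rule during simulation) are not serialized;
#' re-solve with [value_iteration()] when they are needed.
#'
#' @param prefix Path prefix used when writing.
#' @return A `forage_solution` (without `continue_value`).
#' @export
read_solution <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"),
                              simplifyVector = TRUE)
  pm <- meta$params
  pm$delta_by_action <- unlist(pm$delta_by_action)
  p <- do.call(model_params, pm)
  g <- belief_grid(meta$d_beta)
  value <- list(); policy <- list()
  for (loc in c("refuge", "patch")) {
    f <- paste0(prefix, "_", loc, ".csv")
    if (!file.exists(f)) stop("missing solution file '", f, "'",
                              call. = FALSE)
    df <- utils::read.csv(f, stringsAsFactors = FALSE)
    need <- c("beta_P", "beta_G", "action", "tau", "value")
    if (!all(need %in% names(df)))
      stop("solution file '", f, "' lacks columns: ",
           paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
    if (nrow(df) != g$N)
      stop("solution file '", f, "' has ", nrow(df), " rows; grid needs ",
           g$N, call. = FALSE)
    value[[loc]] <- as.numeric(df$value)
    policy[[loc]] <- list(action = df$action, tau = as.numeric(df$tau))
  }
  structure(list(params = p, grid = g, interruptible = meta$interruptible,
                 grid_mode = meta$grid_mode, value = value, policy = policy,
                 continue_value = NULL,
                 tau_steps = as.integer(round(p$tau_set / p$dt)),
                 iterations = meta$iterations, residual = meta$residual,
                 converged = meta$converged, tol = meta$tol),
            class = "forage_solution")
}
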