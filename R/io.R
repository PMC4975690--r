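.CONFIG_KEYS <- c("schema_version", "preset", "engine", "variant", "seed",
                  "n_generations", "n_replicates", "record_every", "out",
                  "model", "env", "ibm")

.merge_section <- function(constructor, base, override, section) {
  allowed <- names(formals(constructor))
  if (!is.null(override)) {
    bad <- setdiff(names(override), allowed)
    if (length(bad))
      param_error(sprintf("unknown key(s) in '%s' section: %s",
                          section, paste(bad, collapse = ", ")))
  }
  args <- unclass(base)
  args[names(override)] <- override
  do.call(constructor, args[intersect(names(args), allowed)])
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration, optionally starts from a named preset
#' (key `preset`), overrides individual `model` / `env` / `ibm` fields,
#' and re-validates everything through the parameter constructors.
#' Unknown keys anywhere are errors — silent typos are the main failure
#' mode for parameter-heavy models.
#'
#' @param path path to a YAML file.
#' @return A `"run_config"` list with elements `model`, `env`, `ibm`,
#'   plus run-level settings (`engine`, `variant`, `seed`,
#'   `n_generations`, `n_replicates`, `record_every`, `out`,
#'   `schema_version`).
#' @export
load_config <- function(path) {
  if (!file.exists(path))
    param_error(sprintf("config file '%s' does not exist", path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  bad <- setdiff(names(raw), .CONFIG_KEYS)
  if (length(bad))
    param_error(sprintf("unknown top-level config key(s): %s",
                        paste(bad, collapse = ", ")))
  base <- if (!is.null(raw$preset)) preset(raw$preset) else {
    structure(list(model = model_params(), env = env_params(),
                   ibm = ibm_params(), schema_version = 1L),
              class = "run_config")
  }
  cfg <- base
  cfg$model <- .merge_section(model_params, base$model, raw$model, "model")
  cfg$env <- .merge_section(env_params, base$env, raw$env, "env")
  cfg$ibm <- .merge_section(ibm_params, base$ibm, raw$ibm, "ibm")
  if (cfg$env$scenario == "two_patch" &&
      is.null(raw$env$dispersal_d) && is.null(base$env$dispersal_d))
    param_error("two_patch scenario requires 'dispersal_d'")
  for (k in c("engine", "variant", "seed", "n_generations", "n_replicates",
              "record_every", "out"))
    if (!is.null(raw[[k]])) cfg[[k]] <- raw[[k]]
  if (!is.null(cfg$engine) &&
      !cfg$engine %in% c("analytic", "ibm"))
    param_error(sprintf("unknown engine '%s'", cfg$engine))
  cfg$schema_version <- if (!is.null(raw$schema_version))
    as.integer(raw$schema_version) else 1L
  if (cfg$schema_version != 1L)
    param_error(sprintf("unsupported schema_version %s", cfg$schema_version))
  class(cfg) <- "run_config"
  cfg
}

#' Serialize a run configuration to YAML
#'
#' Inverse of [load_config()]: `load_config(save_config(cfg, path))`
#' reproduces the configuration.
#'
#' @param config a `"run_config"`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  out <- list(schema_version = config$schema_version,
              model = unclass(config$model),
              env = unclass(config$env),
              ibm = unclass(config$ibm))
  for (k in c("engine", "variant", "seed", "n_generations", "n_replicates",
              "record_every", "out"))
    if (!is.null(config[[k]])) out[[k]] <- config[[k]]
  yaml::write_yaml(out, path, precision = 15L)
  invisible(path)
}

.TRAJ_COLUMNS <- c("generation", "engine", "replicate", "a_bar", "b_bar",
                   "m_bar", "z_bar", "sigma_z2", "theta", "epsilon",
                   "mean_fitness")

#' Write a trajectory to a delimited table
#'
#' Fixed column order (`generation`, `engine`, `replicate`, `a_bar`,
#' `b_bar`, `m_bar`, `z_bar`, `sigma_z2`, `theta`, `epsilon`,
#' `mean_fitness`); numeric values are written with 17 significant
#' digits so a read-back reproduces the doubles bit-for-bit.
#'
#' @param trajectory a trajectory data frame.
#' @param path output path; extension `.csv` selects comma separation,
#'   anything else tab.
#' @param engine,replicate labels stored in the corresponding columns.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path, engine = "analytic",
                             replicate = 1L) {
  df <- data.frame(generation = trajectory$generation,
                   engine = engine, replicate = as.integer(replicate))
  for (v in setdiff(.TRAJ_COLUMNS, c("generation", "engine", "replicate")))
    df[[v]] <- trajectory[[v]]
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a trajectory written by [write_trajectory()]
#'
#' @param path input path (.csv or tab-separated).
#' @return A trajectory data frame.
#' @export
read_trajectory <- function(path) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  class(df) <- c("matevolve_trajectory", "data.frame")
  df
}

#' Aggregate replicate trajectories
#'
#' Per-generation mean and standard deviation across replicate runs for
#' the mean traits, the mean phenotype and mean fitness.
#'
#' @param replicates list of trajectory data frames with identical
#'   `generation` columns.
#' @return Data frame with `generation` plus `<var>_mean` / `<var>_sd`
#'   columns for `a_bar`, `b_bar`, `m_bar`, `z_bar`, `mean_fitness`.
#' @export
aggregate_replicates <- function(replicates) {
  stopifnot(length(replicates) >= 1)
  gen <- replicates[[1]]$generation
  for (r in replicates)
    if (!identical(r$generation, gen))
      param_error("replicate trajectories have mismatched generations")
  out <- data.frame(generation = gen)
  for (v in c("a_bar", "b_bar", "m_bar", "z_bar", "mean_fitness")) {
    mat <- vapply(replicates, function(r) r[[v]], numeric(length(gen)))
    mat <- matrix(mat, nrow = length(gen))
    out[[paste0(v, "_mean")]] <- rowMeans(mat)
    out[[paste0(v, "_sd")]] <- apply(mat, 1, stats::sd)
  }
  out
}

#' @export
print.run_config <- function(x, ...) {
  cat("matevolve run configuration")
  if (!is.null(x$preset)) cat(sprintf(" (preset '%s')", x$preset))
  cat("\n")
  print(x$model)
  print(x$env)
  invisible(x)
}
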