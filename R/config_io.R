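.task_defaults <- function(task) {
  switch(task,
    gridworld = agent_config(a = 1.0, s = 0.5, epsilon = 0, gamma = 0.01,
                             preference = c(0.995, 0.005), forgetting = 0),
    flanker = agent_config(a = 1.0, s = 2.5, epsilon = 0.05, gamma = 0.5,
                           forgetting = 0.05),
    taskswitch = agent_config(a = 0.001, s = 2.5, epsilon = 0.05,
                              gamma = 0.1, contingency_init = 3,
                              forgetting = 0),
    stop("unknown task: ", task))
}

.known_keys <- list(
  top = c("task", "n_agents", "seed", "outdir", "agent", "task_spec"),
  agent = c("a", "s", "epsilon", "gamma", "forgetting", "t_sample",
            "t_nd", "max_samples", "preference", "contingency_init",
            "preference_mode", "mixture_mode", "no_bias",
            "no_habit_update", "no_context_inference"),
  gridworld = c("rows", "cols", "start_cell", "goal_cells", "miniblocks",
                "trials_per_miniblock", "switch_at"),
  flanker = c("n_trials", "p_congruent", "bias", "target_strength"),
  taskswitch = c("training_length", "n_runs", "run_length", "single_task"))

#' Load and validate a run configuration
#'
#' Accepts YAML or JSON. Unknown keys raise an error naming them;
#' out-of-range values raise the range check of the corresponding
#' constructor. Omitted fields are filled with the task's documented
#' defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` configuration.
#' @return A `bcc_run_config`: `task`, `n_agents`, `seed`, `outdir`,
#'   `agent` (an [agent_config()]) and `task_spec` (the task's spec
#'   object).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  as_run_config(raw)
}

#' Build a run configuration from a plain list
#'
#' @param raw Named list as parsed from YAML/JSON; must name a `task`.
#' @return A `bcc_run_config` (see [load_config()]).
#' @export
as_run_config <- function(raw) {
  if (is.null(raw$task)) stop("config must name a `task`")
  task <- match.arg(raw$task, c("gridworld", "flanker", "taskswitch"))
  unknown <- setdiff(names(raw), .known_keys$top)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  agent_raw <- raw$agent %||% list()
  unknown <- setdiff(names(agent_raw), .known_keys$agent)
  if (length(unknown))
    stop("unknown agent keys: ", paste(unknown, collapse = ", "))
  defaults <- .task_defaults(task)
  agent <- do.call(agent_config,
                   utils::modifyList(unclass(defaults), agent_raw))
  spec_raw <- raw$task_spec %||% list()
  unknown <- setdiff(names(spec_raw), .known_keys[[task]])
  if (length(unknown))
    stop("unknown task_spec keys: ", paste(unknown, collapse = ", "))
  spec <- do.call(switch(task, gridworld = gridworld_spec,
                         flanker = flanker_spec,
                         taskswitch = taskswitch_spec),
                  spec_raw)
  n_agents <- as.integer(raw$n_agents %||% 50L)
  if (n_agents < 1L) stop("`n_agents` must be >= 1")
  seed <- as.integer(raw$seed %||% 1L)
  structure(list(task = task, n_agents = n_agents, seed = seed,
                 outdir = raw$outdir %||% ".",
                 agent = agent, task_spec = spec),
            class = "bcc_run_config")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Serialize a run configuration
#'
#' Writes the resolved configuration (defaults filled in) as YAML; a
#' config round-trips losslessly through [load_config()].
#'
#' @param config A `bcc_run_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "bcc_run_config"))
  out <- list(task = config$task, n_agents = config$n_agents,
              seed = config$seed, outdir = config$outdir,
              agent = unclass(config$agent),
              task_spec = unclass(config$task_spec))
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Write trial records to CSV
#'
#' Fixed, documented column order (the order of [empty_records()]'s
#' template); floats at full precision.
#'
#' @param records Trial-record data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  template <- names(empty_records(0L))
  missing <- setdiff(template, names(records))
  if (length(missing))
    stop("records are missing columns: ", paste(missing, collapse = ", "))
  utils::write.csv(records[, template], path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read trial records from CSV
#'
#' Columns are matched by name, so files with shuffled columns are
#' accepted; the exact inverse of [write_records()].
#'
#' @param path Path to a records CSV.
#' @return Trial-record data frame in canonical column order.
#' @export
read_records <- function(path) {
  if (!file.exists(path)) stop("records file not found: ", path)
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e)
                   stop("malformed records file: ", conditionMessage(e)))
  template <- empty_records(0L)
  missing <- setdiff(names(template), names(df))
  if (length(missing))
    stop("malformed records file (missing columns): ",
         paste(missing, collapse = ", "))
  df <- df[, names(template)]
  for (nm in names(template)) {
    if (is.logical(template[[nm]])) df[[nm]] <- as.logical(df[[nm]])
    else if (is.integer(template[[nm]])) df[[nm]] <- as.integer(df[[nm]])
  }
  df
}
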