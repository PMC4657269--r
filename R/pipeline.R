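# Configuration-driven pipeline entry point shared by the command-line
# wrapper (inst/scripts/rcfba) and scripted use.

#' Validate a run configuration
#'
#' @param config a list (e.g. from a YAML/JSON file) with fields
#'   \code{task} (solve, sweep, graph-metrics, essentiality, compare),
#'   \code{model}, and task-specific fields: \code{env} (environment
#'   config path), \code{phi0}, \code{r} or \code{rMin}/\code{rMax}/
#'   \code{steps}, \code{sigma}, \code{reps}, \code{seed},
#'   \code{carriers} (path to one-id-per-line list), \code{labels},
#'   \code{out}
#' @return the config with defaults filled in; stops naming the first
#'   invalid field
#' @export
validateRunConfig <- function(config) {
  tasks <- c("solve", "sweep", "graph-metrics", "essentiality", "compare")
  if (is.null(config$task) || !config$task %in% tasks)
    stop("config field 'task' must be one of: ", paste(tasks, collapse = ", "))
  if (config$task != "compare") {
    if (is.null(config$model)) stop("config field 'model' is required")
    if (!file.exists(config$model))
      stop("config field 'model': file not found: ", config$model)
  }
  if (config$task %in% c("solve", "sweep")) {
    if (is.null(config$env)) stop("config field 'env' is required")
    if (!file.exists(config$env))
      stop("config field 'env': file not found: ", config$env)
  }
  config$phi0 <- as.numeric(config$phi0 %||% 100)
  if (config$phi0 <= 0) stop("config field 'phi0' must be positive")
  config$seed <- as.integer(config$seed %||% 1)
  config$sigma <- as.numeric(config$sigma %||% 0)
  config$reps <- as.integer(config$reps %||% 1)
  config
}

readCarrierList <- function(path) {
  if (is.null(path)) return(defaultCarriers())
  ln <- trimws(readLines(path))
  ln[nzchar(ln) & !grepl("^#", ln)]
}

writeRunManifest <- function(out, config) {
  manifest <- list(
    package = "rcfba",
    version = as.character(utils::packageVersion("rcfba")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config)
  jsonlite::write_json(manifest, paste0(out, ".manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
}

#' Run a configured analysis
#'
#' Dispatches on \code{config$task}, writes the task's TSV/JSON output
#' next to a manifest recording configuration and package version, and
#' returns the main result invisibly.
#'
#' @param config config list or path to a YAML/JSON config file
#' @return the task result, invisibly
#' @export
runPipeline <- function(config) {
  if (is.character(config)) {
    config <- if (tolower(tools::file_ext(config)) == "json")
      jsonlite::fromJSON(config, simplifyVector = FALSE)
    else yaml::read_yaml(config)
  }
  config <- validateRunConfig(config)
  carriers <- readCarrierList(config$carriers)
  out <- config$out %||% paste0("rcfba_", config$task, ".out")

  result <- switch(config$task,
    "solve" = {
      u <- readUniverse(config$model, biomass = config$biomass,
                        carriers = carriers)
      envs <- readEnvironments(config$env)
      p <- rcfbaParams(phi0 = config$phi0, r = as.numeric(config$r %||% 0))
      sol <- solveRcfba(u, envs, p)
      jsonlite::write_json(
        list(status = solutionStatus(sol),
             objective = objectiveValue(sol),
             growth = as.list(growthRates(sol)),
             switching = as.list(switchingInvestments(sol)),
             selected = selectedReactions(sol),
             regulons = countRegulons(sol)$count,
             nu = apply(fluxes(sol), 2, as.list),
             phi = apply(investments(sol), 2, as.list)),
        out, auto_unbox = TRUE, digits = NA)
      sol
    },
    "sweep" = {
      u <- readUniverse(config$model, biomass = config$biomass,
                        carriers = carriers)
      envs <- readEnvironments(config$env)
      p <- rcfbaParams(phi0 = config$phi0)
      grid <- seq(as.numeric(config$rMin %||% 0),
                  as.numeric(config$rMax %||% 2.5),
                  length.out = as.integer(config$steps %||% 200))
      prof <- if (config$sigma > 0 || config$reps > 1)
        monteCarloSweep(u, envs, p, grid, sigma = config$sigma,
                        nReps = config$reps, seed = config$seed,
                        carriers = carriers)
      else sweepR(u, envs, p, grid, carriers = carriers)
      utils::write.table(as.data.frame(prof), out, sep = "\t",
                         row.names = FALSE, quote = FALSE)
      prof
    },
    "graph-metrics" = {
      u <- readUniverse(config$model, biomass = config$biomass,
                        carriers = carriers)
      m <- structuralMetrics(buildGraph(u, carriers = carriers))
      flat <- lapply(m, as.numeric)
      utils::write.table(as.data.frame(flat), out, sep = "\t",
                         row.names = FALSE, quote = FALSE)
      m
    },
    "essentiality" = {
      u <- readUniverse(config$model, biomass = config$biomass,
                        carriers = carriers)
      screen <- deletionScreen(u, fluxBound = as.numeric(
        config$fluxBound %||% 1000))
      utils::write.table(screen, out, sep = "\t", row.names = FALSE,
                         quote = FALSE)
      screen
    },
    "compare" = {
      if (is.null(config$models)) stop("config field 'models' is required")
      paths <- if (length(config$models) == 1 && dir.exists(config$models[[1]]))
        list.files(config$models[[1]], pattern = "\\.(json|xml|sbml|tsv)$",
                   full.names = TRUE)
      else unlist(config$models)
      if (is.null(config$labels)) stop("config field 'labels' is required")
      rep <- compareGroups(paths, config$labels, carriers = carriers)
      utils::write.table(rep, out, sep = "\t", row.names = FALSE,
                         quote = FALSE)
      rep
    })
  writeRunManifest(out, config)
  invisible(result)
}
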