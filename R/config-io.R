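# Flat key = value configuration files for simulation scenarios.
#
# Schema (one `key = value` per line, `#` comments allowed):
#   n_cells_initial, duration_days, time_step_days, cycle_length_days,
#   s_phase_fraction, refractory_days, disintegration_days,
#   fraction_insulin_positive, rng_seed, scenario_name  -- scalars
#   recruitment_hazard  -- "rate" or "from_day:rate,from_day:rate,..."
#   death_hazard        -- "rate" or "state:rate,state:rate,..."
#   label_windows       -- "Analog:start:end,Analog:start:end"

#' Read a simulation config from a flat key-value file
#'
#' @param path Path to the config file.
#' @param ... Overrides applied on top of the file (any [sim_config()]
#'   argument).
#' @return A [sim_config()].
#' @export
read_sim_config <- function(path, ...) {
  if (!file.exists(path)) stop_config("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z_]+)\\s*=\\s*(.*)$", lines))
  bad <- lines[vapply(kv, length, integer(1)) != 3]
  if (length(bad)) stop_config("malformed config line: '", bad[1], "'")
  keys <- vapply(kv, `[[`, character(1), 2)
  vals <- trimws(vapply(kv, `[[`, character(1), 3))
  names(vals) <- keys

  args <- list()
  num_keys <- c("n_cells_initial", "duration_days", "time_step_days",
                "cycle_length_days", "s_phase_fraction", "refractory_days",
                "disintegration_days", "fraction_insulin_positive", "rng_seed")
  for (k in num_keys) {
    if (k %in% keys) {
      v <- suppressWarnings(as.numeric(vals[[k]]))
      if (is.na(v)) stop_config("config key '", k, "' is not numeric: ", vals[[k]])
      args[[k]] <- v
    }
  }
  if ("scenario_name" %in% keys) args$scenario_name <- vals[["scenario_name"]]
  if ("recruitment_hazard" %in% keys) {
    args$recruitment_hazard <- parse_hazard_schedule(vals[["recruitment_hazard"]])
  }
  if ("death_hazard" %in% keys) {
    args$death_hazard <- parse_death_hazard(vals[["death_hazard"]])
  }
  if ("label_windows" %in% keys) {
    args$label_windows <- parse_label_windows(vals[["label_windows"]])
  }
  args <- modifyList(args, list(...))
  do.call(sim_config, args)
}

parse_hazard_schedule <- function(s) {
  if (!grepl(":", s)) return(as.numeric(s))
  parts <- strsplit(strsplit(s, ",")[[1]], ":")
  if (any(vapply(parts, length, integer(1)) != 2)) {
    stop_config("recruitment_hazard schedule must be 'from_day:rate,...' pairs")
  }
  data.frame(from_day = as.numeric(vapply(parts, `[[`, character(1), 1)),
             rate = as.numeric(vapply(parts, `[[`, character(1), 2)))
}

parse_death_hazard <- function(s) {
  if (!grepl(":", s)) return(as.numeric(s))
  parts <- strsplit(strsplit(s, ",")[[1]], ":")
  setNames(as.numeric(vapply(parts, `[[`, character(1), 2)),
           vapply(parts, `[[`, character(1), 1))
}

parse_label_windows <- function(s) {
  if (!nzchar(s) || identical(tolower(s), "none")) return(list())
  parts <- strsplit(strsplit(s, ",")[[1]], ":")
  lapply(parts, function(p) {
    if (length(p) != 3) stop_config("label_windows must be 'Analog:start:end,...'")
    label_window(p[1], as.numeric(p[2]), as.numeric(p[3]))
  })
}

#' Write a simulation config to a flat key-value file
#'
#' @param config A [sim_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  sched <- config$recruitment_hazard
  dh <- config$death_hazard
  lines <- c(
    paste("scenario_name =", config$scenario_name),
    paste("n_cells_initial =", config$n_cells_initial),
    paste("duration_days =", config$duration_days),
    paste("time_step_days =", config$time_step_days),
    paste("recruitment_hazard =",
          paste(sprintf("%g:%g", sched$from_day, sched$rate), collapse = ",")),
    paste("death_hazard =",
          paste(sprintf("%s:%g", names(dh), dh), collapse = ",")),
    paste("cycle_length_days =", config$cycle_length_days),
    paste("s_phase_fraction =", config$s_phase_fraction),
    paste("refractory_days =", config$refractory_days),
    paste("disintegration_days =", config$disintegration_days),
    paste("fraction_insulin_positive =", config$fraction_insulin_positive),
    if (length(config$label_windows)) {
      paste("label_windows =",
            paste(vapply(config$label_windows, function(w) {
              sprintf("%s:%g:%g", w$analog_name, w$start_day, w$end_day)
            }, character(1)), collapse = ","))
    },
    paste("rng_seed =", config$rng_seed)
  )
  writeLines(lines, path)
  invisible(path)
}

config_hash <- function(config) {
  f <- tempfile(fileext = ".cfg")
  on.exit(unlink(f), add = TRUE)
  write_sim_config(config, f)
  unname(tools::md5sum(f))
}

# meta.json run manifest; one per output directory
write_manifest <- function(dir, command, config = NULL, seed = NULL,
                           extra = NULL) {
  meta <- list(
    command = command,
    tool = "betakin",
    version = as.character(utils::packageVersion("betakin")),
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config
  )
  if (inherits(config, "sim_config")) {
    meta$config_hash <- config_hash(config)
    meta$config <- unclass_config_for_meta(config)
  }
  if (!is.null(extra)) meta <- c(meta, extra)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(meta)
}
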