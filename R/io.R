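#' Write or read a timing--mass dataset as CSV
#'
#' Datasets travel as UTF-8 CSV with header `timing_day,mass_kg` and '.' as
#' the decimal separator.
#'
#' @param data Data frame with columns `timing_day` and `mass_kg`.
#' @param path Output path.
#' @return `write_dataset`: `path`, invisibly. `read_dataset`: the data
#'   frame.
#' @export
write_dataset <- function(data, path) {
  stopifnot(is.data.frame(data),
            all(c("timing_day", "mass_kg") %in% names(data)))
  utils::write.csv(data[c("timing_day", "mass_kg")], path,
                   row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  d <- utils::read.csv(path, fileEncoding = "UTF-8")
  if (!all(c("timing_day", "mass_kg") %in% names(d)))
    stop("dataset CSV must have columns 'timing_day' and 'mass_kg'",
         call. = FALSE)
  d
}

#' Read a run configuration from YAML or JSON
#'
#' Keys mirror the [sim_config()] fields (`n`, `timing_shape`,
#' `timing_scale`, `timing_shift`, `intercept_log`, `daily_multiplier`,
#' `mass_shape`, `seed`); unknown keys raise an error naming the key.
#' An optional `schemes` key holds a list of breakpoint specs such as
#' `{kind: interval, interval_width: 5}`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return List with elements `config` (a [sim_config()]) and `schemes`
#'   (list of [break_scheme()] objects, possibly empty).
#' @export
read_run_config <- function(path) {
  ## keep YAML-1.1 boolean-like keys ("n", "y", "yes", "no") as strings
  keep_str <- list("bool#yes" = function(x) x, "bool#no" = function(x) x)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path, handlers = keep_str)
  else if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  else stop("config must be a .yaml/.yml or .json file", call. = FALSE)
  scheme_raw <- raw$schemes
  raw$schemes <- NULL
  known <- names(formals(sim_config))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  cfg <- do.call(sim_config, raw)
  schemes <- lapply(scheme_raw, function(s) do.call(break_scheme, s))
  list(config = cfg, schemes = schemes)
}

#' Write a provenance record for a run
#'
#' Serializes the configuration, master seed, package version and a
#' timestamp as JSON, so that any output table can be traced back to the
#' exact generating conditions.
#'
#' @param path Output path for the JSON record.
#' @param config A [sim_config()].
#' @param seed Master seed of the run.
#' @param extra Optional named list of additional fields.
#' @return `path`, invisibly.
#' @export
write_provenance <- function(path, config, seed = config$seed,
                             extra = NULL) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  class(cfg) <- NULL
  cfg$nonlinear_curve <- if (is.null(cfg$nonlinear_curve)) NULL else
    paste(deparse(cfg$nonlinear_curve), collapse = " ")
  rec <- c(list(package = "splitcost",
                version = as.character(utils::packageVersion("splitcost")),
                timestamp = format(Sys.time(), tz = "UTC",
                                   "%Y-%m-%dT%H:%M:%SZ"),
                seed = seed,
                config = cfg),
           extra)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, null = "null",
                       digits = NA)
  invisible(path)
}
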