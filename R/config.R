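#' Load a run configuration file
#'
#' Reads a flat `key: value` text configuration (one pair per line, `#`
#' starts a comment, blank lines ignored). Recognised keys are the 14 model
#' parameter names plus the run directives `variant`, `out_dir`, `log_level`,
#' `seed`, `init` (four comma-separated numbers), `t_end`, `dt_out`,
#' `sweep_param`, `sweep_from`, `sweep_to`, `sweep_n`, `k_from`, `k_to`,
#' `k_n`, `zeta_from`, `zeta_to`, `zeta_n`. Unrecognised keys are an error
#' that lists the valid keys; absent parameters take the canonical defaults.
#'
#' @param path path to the configuration file.
#' @return A `run_config` object: list with `params` (a [ward_params()]),
#'   `variant`, and the remaining directives.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_]+)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(m) != 3)
      stop("cannot parse config line: '", ln, "'", call. = FALSE)
    kv[[m[2]]] <- trimws(m[3])
  }
  build_config(kv)
}

## internal: assemble and validate a run_config from a key->string mapping
build_config <- function(kv) {
  param_keys <- names(param_defaults())
  num_keys <- c("seed", "t_end", "dt_out", "sweep_from", "sweep_to",
                "sweep_n", "k_from", "k_to", "k_n", "zeta_from", "zeta_to",
                "zeta_n")
  str_keys <- c("variant", "out_dir", "log_level", "sweep_param", "init")
  valid <- c(param_keys, num_keys, str_keys)
  unknown <- setdiff(names(kv), valid)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         "\nvalid keys: ", paste(valid, collapse = ", "), call. = FALSE)
  as_num <- function(key, v) {
    x <- suppressWarnings(as.numeric(v))
    if (is.na(x)) stop("config key '", key, "' is not numeric: '", v, "'",
                       call. = FALSE)
    x
  }
  overrides <- list()
  cfg <- list(variant = "balanced", out_dir = ".", log_level = "info",
              seed = 1, t_end = 500, dt_out = 0.5, init = NULL,
              sweep_param = "zeta", sweep_from = 0, sweep_to = 3,
              sweep_n = 50, k_from = 10, k_to = 1000, k_n = 10,
              zeta_from = 0.001, zeta_to = 3, zeta_n = 10)
  for (key in names(kv)) {
    v <- kv[[key]]
    if (key %in% param_keys) overrides[[key]] <- as_num(key, v)
    else if (key %in% num_keys) cfg[[key]] <- as_num(key, v)
    else if (key == "init") {
      parts <- strsplit(v, ",")[[1]]
      if (length(parts) != 4)
        stop("config key 'init' needs four comma-separated numbers",
             call. = FALSE)
      cfg$init <- vapply(seq_along(parts),
                         function(i) as_num("init", parts[i]), numeric(1))
    } else cfg[[key]] <- v
  }
  check_variant(cfg$variant)
  cfg$params <- validate_params(overrides)
  structure(cfg, class = "run_config")
}

#' Write a run configuration file
#'
#' Serialises a `run_config` in the flat `key: value` dialect read by
#' [load_config()]. Parameters are written at full precision, so a written
#' configuration reloads to an identical object.
#'
#' @param config a `run_config` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  fmt <- function(x) format(x, digits = 17, scientific = FALSE, trim = TRUE)
  lines <- character()
  for (nm in names(param_defaults()))
    lines <- c(lines, paste0(nm, ": ", fmt(config$params[[nm]])))
  for (nm in c("variant", "out_dir", "log_level", "sweep_param"))
    lines <- c(lines, paste0(nm, ": ", config[[nm]]))
  for (nm in c("seed", "t_end", "dt_out", "sweep_from", "sweep_to",
               "sweep_n", "k_from", "k_to", "k_n", "zeta_from", "zeta_to",
               "zeta_n"))
    lines <- c(lines, paste0(nm, ": ", fmt(config[[nm]])))
  if (!is.null(config$init))
    lines <- c(lines, paste0("init: ", paste(fmt(config$init),
                                             collapse = ",")))
  writeLines(lines, path)
  invisible(path)
}
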