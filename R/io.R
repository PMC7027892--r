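#' @section File formats:
#' Trajectories and time courses travel as plain CSV with the header
#' `time_hr,biomass_g_L,substrate_g_L,mu_per_hr` (the rate column is dropped
#' for observed time courses, the substrate column may be absent). All
#' floating-point output is printed with 12 significant digits so written
#' files round-trip losslessly to that precision. Dilution sweeps use
#' `D_per_hr,S_star_g_L,X_star_g_L,productivity_g_L_hr,branch`. Run
#' configuration is a flat mapping with keys `model`, `mu_max`, `K_s`,
#' `X_m`, `Y_xs` and either `X_0`,`S_0` (batch) or `D`,`S_F` (CSTR), read
#' from JSON or from flat `key: value` YAML.
#' @name hybridgrowth_io
NULL

fmt12 <- function(x) {
  if (is.numeric(x)) sprintf("%.12g", x) else as.character(x)
}

write_csv12 <- function(df, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  writeLines(paste(names(df), collapse = ","), con)
  if (nrow(df)) {
    cols <- lapply(df, fmt12)
    writeLines(do.call(paste, c(cols, sep = ",")), con)
  }
  invisible(path)
}

#' Write / read a batch trajectory CSV
#'
#' @param traj a `batch_trajectory` (from [sample_trajectory()] or
#'   [integrate_batch()]).
#' @param path file path.
#' @return `write_trajectory_csv` returns `path` invisibly;
#'   `read_trajectory_csv` returns a data frame with the trajectory columns.
#' @export
write_trajectory_csv <- function(traj, path) {
  write_csv12(as.data.frame(traj), path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write / read an observed or synthetic time course CSV
#'
#' The seed and noise level of a synthetic time course are recorded in a
#' `#`-comment header line so a generation run is reproducible from the file
#' alone.
#'
#' @param data a `timecourse_data` or data frame with `time_hr`,
#'   `biomass_g_L` and optionally `substrate_g_L`.
#' @param path file path.
#' @return `write_timecourse_csv` returns `path` invisibly;
#'   `read_timecourse_csv` returns a data frame (error messages name the
#'   offending row on malformed input).
#' @export
write_timecourse_csv <- function(data, path) {
  comment <- NULL
  if (!is.null(attr(data, "seed")))
    comment <- sprintf("synthetic: model=%s noise_cv=%s seed=%d",
                       attr(data, "model"), fmt12(attr(data, "noise_cv")),
                       attr(data, "seed"))
  keep <- intersect(c("time_hr", "biomass_g_L", "substrate_g_L"), names(data))
  write_csv12(as.data.frame(data)[keep], path, comment = comment)
}

#' @rdname write_timecourse_csv
#' @export
read_timecourse_csv <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  if (length(body) < 2L)
    stop("malformed time-course CSV '", path, "': no data rows", call. = FALSE)
  header <- strsplit(body[1], ",", fixed = TRUE)[[1]]
  if (!all(c("time_hr", "biomass_g_L") %in% header))
    stop("malformed time-course CSV '", path,
         "': header must contain time_hr and biomass_g_L", call. = FALSE)
  rows <- strsplit(body[-1], ",", fixed = TRUE)
  n_col <- length(header)
  for (i in seq_along(rows)) {
    if (length(rows[[i]]) != n_col)
      stop("malformed time-course CSV '", path, "': row ", i,
           " has ", length(rows[[i]]), " fields, expected ", n_col,
           call. = FALSE)
    vals <- suppressWarnings(as.numeric(rows[[i]]))
    if (any(is.na(vals) & rows[[i]] != "NA" & nzchar(rows[[i]])))
      stop("malformed time-course CSV '", path, "': row ", i,
           " contains a non-numeric field", call. = FALSE)
  }
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        stringsAsFactors = FALSE)
  df
}

#' Write a dilution sweep CSV
#'
#' @param sweep a `dilution_sweep` from [dilution_sweep()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(sweep, path) {
  write_csv12(as.data.frame(sweep), path)
}

# Minimal flat `key: value` YAML mapping reader (no installed R YAML parser;
# the run configuration is flat by contract). Supports comments and quoted
# strings; everything that parses as a number becomes numeric.
read_flat_yaml <- function(path) {
  lines <- readLines(path)
  lines <- sub("(^|\\s)#.*$", "", lines)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^\\s*([A-Za-z0-9_.-]+)\\s*:\\s*(.*?)\\s*$", ln))[[1]]
    if (length(m) != 3L)
      stop("cannot parse config line: '", ln,
           "' (expected flat 'key: value' mapping)", call. = FALSE)
    key <- m[2]; val <- m[3]
    val <- gsub('^"|"$|^\'|\'$', "", val)
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}

#' Read a run configuration (JSON or flat YAML)
#'
#' A run configuration is a flat mapping with keys `model`, `mu_max`, `K_s`,
#' `X_m`, `Y_xs` and either the batch block `X_0`, `S_0` or the CSTR block
#' `D`, `S_F` (exactly one of the two), plus optional `seed`, `noise_cv`,
#' `t_max`, `n_points`. Unknown keys are rejected. JSON is detected by a
#' leading `{`; anything else is parsed as a flat `key: value` YAML mapping.
#'
#' @param path config file path.
#' @return named list with a `growth_parameters` object under `$parameters`,
#'   `$model`, and `$batch` ([batch_conditions()]) or `$cstr`
#'   ([cstr_conditions()]) plus any optional scalars.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  first <- trimws(paste(readLines(path, warn = FALSE), collapse = "\n"))
  raw <- if (startsWith(first, "{")) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    read_flat_yaml(path)
  }
  known <- c("model", "mu_max", "K_s", "X_m", "Y_xs", "X_0", "S_0",
             "D", "S_F", "seed", "noise_cv", "t_max", "n_points")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  resolve_config(raw)
}

# Validate a flat config mapping (possibly already merged with CLI
# overrides) into typed objects.
resolve_config <- function(raw) {
  need <- function(keys, where) {
    missing <- keys[!vapply(keys, function(k)
      !is.null(raw[[k]]) && !is.na(raw[[k]]), logical(1))]
    if (length(missing))
      stop("config is missing required field(s) for ", where, ": ",
           paste(missing, collapse = ", "), call. = FALSE)
  }
  need(c("model", "mu_max", "K_s", "X_m", "Y_xs"), "the growth model")
  has_batch <- !is.null(raw$X_0) || !is.null(raw$S_0)
  has_cstr <- !is.null(raw$D) || !is.null(raw$S_F)
  if (has_batch && has_cstr)
    stop("config must contain exactly one of the batch (X_0, S_0) and CSTR (D, S_F) blocks, not both",
         call. = FALSE)
  out <- list(
    model = model_kind(raw$model),
    parameters = growth_parameters(raw$mu_max, raw$K_s, raw$X_m, raw$Y_xs))
  if (has_batch) {
    need(c("X_0", "S_0"), "batch culture")
    out$batch <- batch_conditions(raw$X_0, raw$S_0)
  }
  if (has_cstr) {
    need("S_F", "CSTR culture")
    out$cstr <- list(D = raw$D, S_F = raw$S_F)
  }
  for (k in c("seed", "noise_cv", "t_max", "n_points"))
    out[[k]] <- raw[[k]]
  out
}

#' Serialize a fit result to JSON
#'
#' Parameter names in the JSON match the config schema (`mu_max`, `K_s`,
#' `X_m`, `Y_xs`), so a fit output can seed a simulation config.
#'
#' @param fit a `fit_result` from [fit_batch()].
#' @param path file path; `NULL` returns the JSON string instead.
#' @return `path` invisibly, or the JSON string when `path = NULL`.
#' @export
write_fit_json <- function(fit, path = NULL) {
  obj <- list(
    schema_version = 1L,
    model = fit$model,
    parameters = unclass(fit$parameters),
    initial_state = fit$initial_state,
    rss = fit$rss,
    std_errors = as.list(fit$std_errors),
    converged = fit$converged,
    xm_identifiable = fit$xm_identifiable,
    n_obs = fit$n_obs)
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                           na = "null")
  if (is.null(path)) return(as.character(json))
  writeLines(json, path)
  invisible(path)
}
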