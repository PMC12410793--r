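trace_columns <- c("time_min", "glucose_true", "cgm", "cgm_missing",
                   "insulin_U", "meal_g", "projection_5min",
                   "x2", "x3", "x4", "x5", "d_hat", "solver_status")

#' Write / read a closed-loop trace CSV
#'
#' Single flat dialect: comma-separated, UTF-8, header row, minute
#' timestamps. Numeric values are written with enough digits for a
#' lossless (1e-9) round trip; missing CGM samples are empty fields with
#' the `cgm_missing` flag set.
#'
#' @param trace a `closed_loop_trace` (or data frame with the trace
#'   columns).
#' @param path file path.
#' @return `read_trace` returns a `closed_loop_trace`.
#' @export
write_trace <- function(trace, path) {
  miss <- setdiff(trace_columns, names(trace))
  if (length(miss)) {
    stop("trace is missing column(s): ", paste(miss, collapse = ", "))
  }
  df <- as.data.frame(trace)[trace_columns]
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) {
    ifelse(is.na(v), "", sprintf("%.12g", v))
  })
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  hdr <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
  miss <- setdiff(trace_columns, hdr)
  if (length(miss)) {
    stop("line 1: trace header missing column(s): ",
         paste(miss, collapse = ", "))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  numcols <- setdiff(trace_columns, c("solver_status", "cgm_missing"))
  for (cn in numcols) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    bad <- which(!is.na(df[[cn]]) & nzchar(df[[cn]]) & is.na(v))
    if (length(bad)) {
      stop("line ", bad[1] + 1L, ": non-numeric value '", df[[cn]][bad[1]],
           "' in column ", cn)
    }
    df[[cn]] <- v
  }
  df$cgm_missing <- df$cgm_missing %in% c("TRUE", "true", "1")
  df$cgm[df$cgm_missing] <- NA_real_
  df <- df[trace_columns]
  class(df) <- c("closed_loop_trace", "data.frame")
  df
}

default_config <- function() {
  list(
    controller = list(Hp = 100, Hu = 30, T = 5, R = 10, P = 1e4,
                      ridge = 1e-7, quantum = 0),
    zone = list(y_lo = 90, y_hi = 130, u_min = 0, u_max = 1),
    estimator = list(disturbance = "input", q_x = 1e-4, q_d = 1,
                     r_y = 25, gain = "time-varying"),
    scenario = list(duration_min = 4320, y0 = 400,
                    meal_gap_min = c(120, 240), meal_carbs_g = c(1, 5),
                    sensor = list(dropout_prob = 0.01,
                                  outlier_prob = 0.005, outlier_mag = 75,
                                  noise_sd = 2, quantum = 1)),
    identification = list(global_budget = 200, ftol = 1e-3, xtol = 1e-3,
                          max_iter = 40, smooth_factor = 0.25)
  )
}

merge_config <- function(defaults, user, path = character()) {
  prov <- list()
  for (key in names(user)) {
    if (!key %in% names(defaults)) {
      stop("unknown configuration key: ",
           paste(c(path, key), collapse = "."))
    }
    if (is.list(defaults[[key]]) && is.list(user[[key]])) {
      sub <- merge_config(defaults[[key]], user[[key]], c(path, key))
      defaults[[key]] <- sub$config
      prov <- c(prov, sub$provenance)
    } else {
      defaults[[key]] <- user[[key]]
      prov[[paste(c(path, key), collapse = ".")]] <- "user"
    }
  }
  list(config = defaults, provenance = prov)
}

#' Load a configuration file with defaults and provenance
#'
#' JSON configuration with sections `controller`, `zone`, `estimator`,
#' `scenario`, `identification`. Any key absent from the file takes its
#' documented default; unknown keys are an error. The returned tree
#' carries a `provenance` attribute naming every user-overridden key.
#'
#' @param path JSON file, or `NULL` for pure defaults.
#' @return configuration list with attribute `provenance`.
#' @export
load_config <- function(path = NULL) {
  defaults <- default_config()
  user <- if (is.null(path)) list() else {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = FALSE,
                        simplifyDataFrame = FALSE)
  }
  if (is.null(user)) user <- list()
  m <- merge_config(defaults, user)
  cfg <- m$config
  attr(cfg, "provenance") <- m$provenance
  cfg
}

config_objects <- function(cfg) {
  list(
    cfg = controller_config(Hp = cfg$controller$Hp, Hu = cfg$controller$Hu,
                            T = cfg$controller$T, R = cfg$controller$R,
                            P = cfg$controller$P,
                            ridge = cfg$controller$ridge,
                            quantum = cfg$controller$quantum),
    zone = zone_spec(cfg$zone$y_lo, cfg$zone$y_hi,
                     cfg$zone$u_min, cfg$zone$u_max),
    dist = disturbance_model(cfg$estimator$disturbance),
    estimator = list(q_x = cfg$estimator$q_x, q_d = cfg$estimator$q_d,
                     r_y = cfg$estimator$r_y, gain = cfg$estimator$gain),
    sensor = do.call(sensor_model, cfg$scenario$sensor)
  )
}

#' Write a run manifest
#'
#' Records everything needed to re-execute a run bit-identically: the
#' full configuration snapshot (with provenance), seeds, package version,
#' per-stage timings and MD5 digests of input/output files.
#'
#' @param path manifest output path (JSON).
#' @param config configuration tree used.
#' @param seed run seed.
#' @param files named character vector of files to digest.
#' @param timings named numeric vector of per-stage elapsed seconds.
#' @return the manifest list, invisibly.
#' @export
write_manifest <- function(path, config, seed, files = character(),
                           timings = numeric()) {
  digests <- if (length(files)) {
    existing <- files[file.exists(files)]
    as.list(tools::md5sum(existing))
  } else list()
  man <- list(
    package = "ofzmpc",
    version = as.character(utils::packageVersion("ofzmpc")),
    seed = seed,
    config = config,
    provenance = attr(config, "provenance"),
    timings_sec = as.list(timings),
    file_md5 = digests)
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(man)
}
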