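#' Physiological model parameters
#'
#' Constructs and validates the six scalar parameters of the five-compartment
#' glucose-insulin model for one subject.
#'
#' @param p0 endogenous glucose production at zero insulin (mg/dL/min).
#' @param p1 hepatic autoregulation (1/min). May be zero: identified rodent
#'   models are sometimes reported with p1 rounded to 0.00, in which case the
#'   glycemia compartment behaves as an integrator and the zero-insulin
#'   equilibrium `p0/p1` is unbounded.
#' @param p2 insulin sensitivity (mg/dL/U).
#' @param p3 carbohydrate bioavailability (mg/dL/g).
#' @param p4 time-to-maximum effective insulin concentration (min).
#' @param p5 time-to-maximum glucose appearance rate (min).
#'
#' @return An object of class `model_parameters` (named numeric vector
#'   p0..p5).
#' @examples
#' model_parameters(p0 = 2.48, p1 = 0.01, p2 = 368.12,
#'                  p3 = 9.5, p4 = 4.95, p5 = 20.45)
#' @export
model_parameters <- function(p0, p1, p2, p3 = 9.5, p4, p5 = 20.45) {
  p <- c(p0 = p0, p1 = p1, p2 = p2, p3 = p3, p4 = p4, p5 = p5)
  if (any(!is.finite(p))) {
    stop("model parameters must be finite numbers: ",
         paste(names(p)[!is.finite(p)], collapse = ", "))
  }
  # p1 = 0 is tolerated (printed precision of identified models); the other
  # five must be strictly positive (p4, p5 appear as 1/p4, 1/p5).
  strict <- p[c("p0", "p2", "p3", "p4", "p5")]
  if (any(strict <= 0)) {
    stop("model parameter must be strictly positive: ",
         paste(names(strict)[strict <= 0], collapse = ", "))
  }
  if (p[["p1"]] < 0) stop("model parameter must be non-negative: p1")
  structure(p, class = "model_parameters")
}

#' @export
print.model_parameters <- function(x, ...) {
  cat("Glucose-insulin model parameters:\n")
  u <- c("mg/dL/min", "1/min", "mg/dL/U", "mg/dL/g", "min", "min")
  for (i in seq_along(x)) {
    cat(sprintf("  %-3s %10.4g  %s\n", names(unclass(x))[i], unclass(x)[i], u[i]))
  }
  invisible(x)
}

as_model_parameters <- function(p) {
  if (inherits(p, "model_parameters")) return(p)
  p <- unlist(p)
  need <- c("p0", "p1", "p2", "p3", "p4", "p5")
  if (!all(need %in% names(p))) {
    stop("parameter set must name all of p0..p5; missing: ",
         paste(setdiff(need, names(p)), collapse = ", "))
  }
  model_parameters(p[["p0"]], p[["p1"]], p[["p2"]],
                   p[["p3"]], p[["p4"]], p[["p5"]])
}

#' Identified parameter sets of the thirteen diabetic-rat models
#'
#' Packaged fixture with the per-subject parameter sets identified from
#' bolus-response CGM data (p3 and p5 held at 9.5 and 20.45 for all
#' subjects). Two subjects (DR7, DR11) have p1 printed as 0.00; see
#' [model_parameters()].
#'
#' @param rat optional subject id (e.g. `"DR3"`); if given, returns that
#'   subject's `model_parameters`, otherwise the full data frame.
#' @return A data frame (rat, p0..p5) or a single `model_parameters`.
#' @export
rat_models <- function(rat = NULL) {
  path <- system.file("extdata", "rat_model_parameters.csv",
                      package = "ofzmpc", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.null(rat)) return(tab)
  row <- tab[tab$rat == rat, , drop = FALSE]
  if (nrow(row) != 1L) stop("unknown rat id: ", rat)
  model_parameters(row$p0, row$p1, row$p2, row$p3, row$p4, row$p5)
}

#' Per-rat trial outcome table (glycemic control, insulin, body weight)
#'
#' Packaged per-subject outcome fixture used by the cohort summary and
#' correlation reports: mean/SD/CV of interstitial glycemia, percent time
#' below 70, in 70-180 and above 180 mg/dL, severe-hypoglycemia event
#' counts, total and maximal insulin, and initial/final body weight.
#'
#' @return data frame with one row per subject.
#' @export
rat_outcomes <- function() {
  path <- system.file("extdata", "rat_trial_outcomes.csv",
                      package = "ofzmpc", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read / write a parameter set as a flat key-value JSON section
#'
#' @param params a `model_parameters` object.
#' @param path file path.
#' @return `read_parameters` returns a `model_parameters` object.
#' @export
write_parameters <- function(params, path) {
  params <- as_model_parameters(params)
  jsonlite::write_json(as.list(unclass(params)), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_parameters
#' @export
read_parameters <- function(path) {
  as_model_parameters(jsonlite::read_json(path, simplifyVector = TRUE))
}
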