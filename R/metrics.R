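# Glycemic bands tiling (0, Inf): <54, [54,70), [70,180], (180,250], >250.
band_of <- function(g) {
  findInterval(g, c(54, 70, 180 + 1e-12, 250 + 1e-12)) + 1L
}
band_labels <- c("<54", "54-70", "70-180", "180-250", ">250")

#' Glycemic outcome report for a glucose/insulin trace
#'
#' Percent time in the five clinical bands (<54, 54-70, 70-180, 180-250,
#' >250 mg/dL, tiling the positive axis; 70 and 180 belong to the
#' normoglycemic band), per-band event counts, glucose summaries and
#' insulin totals. An event is a maximal run of consecutive samples in a
#' band lasting at least `event_min_min` minutes, with runs in the same
#' band separated by less than `event_merge_min` minutes merged; no events
#' are counted for the normoglycemic band.
#'
#' @param glucose a `closed_loop_trace` (its CGM column, missing samples
#'   dropped) or a numeric glucose series on a uniform grid (mg/dL).
#' @param insulin numeric bolus series (U); taken from the trace when one
#'   is given.
#' @param T sampling period (min).
#' @param event_min_min,event_merge_min episode rule (min); the defaults
#'   (15, 30) are a documented convention, not used by any table
#'   aggregate.
#' @return object of class `glycemic_report` (list): `mean`, `sd`, `cv`
#'   (%), `pt` (named percent-time vector over the five bands), `events`,
#'   `total_insulin`, `insulin_per_day`, `peak`, `nadir`, `n`.
#' @export
glycemic_report <- function(glucose, insulin = NULL, T = 5,
                            event_min_min = 15, event_merge_min = 30) {
  if (inherits(glucose, "closed_loop_trace") || is.data.frame(glucose)) {
    tr <- glucose
    if (is.null(insulin)) insulin <- tr$insulin_U
    glucose <- tr$cgm
    glucose[is.na(glucose)] <- tr$glucose_true[is.na(glucose)]
    if ("time_min" %in% names(tr) && nrow(tr) > 1L) {
      T <- diff(tr$time_min[1:2])
    }
  }
  glucose <- glucose[is.finite(glucose)]
  n <- length(glucose)
  if (n == 0L) stop("empty glucose series")
  bands <- band_of(glucose)
  pt <- 100 * tabulate(bands, 5L) / n
  names(pt) <- band_labels

  min_len <- max(1L, ceiling(event_min_min / T))
  merge_gap <- max(0L, ceiling(event_merge_min / T) - 1L)
  events <- integer(5)
  for (b in c(1L, 2L, 4L, 5L)) {
    inb <- bands == b
    r <- rle(inb)
    # merge in-band runs separated by short out-of-band gaps
    if (length(r$lengths) > 2L) {
      vals <- r$values; lens <- r$lengths
      i <- 2L
      while (i < length(vals)) {
        if (!vals[i] && vals[i - 1L] && vals[i + 1L] &&
            lens[i] <= merge_gap) {
          lens[i - 1L] <- lens[i - 1L] + lens[i] + lens[i + 1L]
          vals <- vals[-c(i, i + 1L)]; lens <- lens[-c(i, i + 1L)]
        } else i <- i + 1L
      }
      r <- list(values = vals, lengths = lens)
    }
    events[b] <- sum(r$values & r$lengths >= min_len)
  }
  names(events) <- band_labels

  m <- mean(glucose); s <- stats::sd(glucose)
  total_ins <- if (is.null(insulin)) NA_real_ else sum(insulin, na.rm = TRUE)
  per_day <- if (is.null(insulin)) NA_real_ else
    total_ins / (n * T / 1440)
  structure(list(mean = m, sd = s, cv = 100 * s / m, pt = pt,
                 events = events, total_insulin = total_ins,
                 insulin_per_day = per_day,
                 peak = max(glucose), nadir = min(glucose), n = n),
            class = "glycemic_report")
}

#' @export
print.glycemic_report <- function(x, ...) {
  cat(sprintf("Glycemia: mean %.2f mg/dL, SD %.2f, CV %.2f%% (n = %d)\n",
              x$mean, x$sd, x$cv, x$n))
  cat("Band (mg/dL)  ", sprintf("%9s", names(x$pt)), "\n", sep = "")
  cat("PT (%)        ", sprintf("%9.2f", x$pt), "\n", sep = "")
  cat("Events        ", sprintf("%9d", x$events), "\n", sep = "")
  if (is.finite(x$total_insulin)) {
    cat(sprintf("Insulin: %.2f U total (%.2f U/day)\n",
                x$total_insulin, x$insulin_per_day))
  }
  invisible(x)
}

#' Median absolute relative difference with bootstrap CI
#'
#' `ARD_i = |pred_i - ref_i| / ref_i * 100`; the point estimate is the
#' median and the confidence interval a seeded percentile bootstrap over
#' paired resamples. Pairs with non-positive reference are excluded (with
#' a count in the result).
#'
#' @param predictions,references equal-length numeric vectors.
#' @param n_boot bootstrap replicates (default 5000).
#' @param seed integer seed.
#' @param conf confidence level.
#' @return list: `medard` (%), `ci` (length 2), `n`, `n_excluded`,
#'   `n_boot`.
#' @export
medard <- function(predictions, references, n_boot = 5000, seed = 1,
                   conf = 0.95) {
  if (length(predictions) != length(references)) {
    stop("predictions and references must have equal length")
  }
  keep <- is.finite(predictions) & is.finite(references) & references > 0
  n_exc <- sum(!keep)
  if (n_exc > 0) {
    warning(n_exc, " pair(s) excluded (non-positive or missing reference)")
  }
  p <- predictions[keep]; r <- references[keep]
  if (!length(p)) stop("no valid pairs")
  ard <- abs(p - r) / r * 100
  point <- stats::median(ard)
  set.seed(substream_seed(seed, "medard-boot"))
  boots <- replicate(n_boot, {
    i <- sample.int(length(ard), replace = TRUE)
    stats::median(ard[i])
  })
  alpha <- (1 - conf) / 2
  ci <- unname(stats::quantile(boots, c(alpha, 1 - alpha)))
  list(medard = point, ci = ci, n = length(ard), n_excluded = n_exc,
       n_boot = n_boot)
}

#' Precision-based sample size
#'
#' Number of subjects needed to estimate a mean with margin `margin` at
#' the confidence implied by `z`: `n = ceiling((z * sigma / margin)^2)`.
#'
#' @param z two-sided critical value (1.96 for 95%).
#' @param sigma expected SD (mg/dL).
#' @param margin desired precision (mg/dL).
#' @return integer sample size.
#' @export
precision_sample_size <- function(z, sigma, margin) {
  stopifnot(z > 0, sigma > 0)
  if (!is.numeric(margin) || margin <= 0) {
    stop("precision margin must be > 0")
  }
  as.integer(ceiling((z * sigma / margin)^2))
}

#' Pearson correlation with two-sided p-value
#'
#' @param x,y equal-length numeric vectors (n >= 3).
#' @return list: `r`, `p`, `n`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: zero variance in input")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Cohort summary: per-column mean, SD and CV
#'
#' Sample (n-1) SD accompanies the mean; the coefficient of variation is
#' reported under both conventions, as a fraction: `cv_n` uses the
#' population (n) SD and `cv_n1` the sample SD.
#'
#' @param tab per-subject data frame.
#' @param columns columns to summarize (default: all numeric).
#' @return data frame with one row per column: mean, sd (n-1), cv_n,
#'   cv_n1, n.
#' @export
cohort_summary <- function(tab, columns = NULL) {
  if (is.null(columns)) {
    columns <- names(tab)[vapply(tab, is.numeric, logical(1))]
  }
  if (nrow(tab) < 2L) stop("cohort summary needs at least 2 subjects")
  out <- lapply(columns, function(cn) {
    v <- tab[[cn]]
    n <- sum(is.finite(v))
    m <- mean(v, na.rm = TRUE)
    s1 <- stats::sd(v, na.rm = TRUE)
    s0 <- s1 * sqrt((n - 1) / n)
    data.frame(column = cn, mean = m, sd = s1,
               cv_n = s0 / m, cv_n1 = s1 / m, n = n)
  })
  do.call(rbind, out)
}
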