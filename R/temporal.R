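# Lab-marker trend analysis: ordinary least-squares trend fitting with a
# slope significance test, and the temporality basis linking significant
# in-exposure trends to symptoms via a knowledge map.

#' Construct a lab-marker time series
#'
#' @param patient_id Patient identifier.
#' @param marker Marker name (e.g. platelets, urea, glucose, creatinine).
#' @param time Numeric times in days from the first observation; strictly
#'   increasing.
#' @param value Finite marker values (in the marker's units).
#' @return An object of class `marker_series`.
#' @export
marker_series <- function(patient_id, marker, time, value) {
  time <- as.numeric(time)
  value <- as.numeric(value)
  if (length(time) != length(value) || length(time) == 0L) {
    stop(depdst_error("time and value must be equal-length, non-empty", "series"))
  }
  if (any(!is.finite(time)) || any(!is.finite(value))) {
    stop(depdst_error("times and values must be finite", "series"))
  }
  if (any(diff(time) <= 0)) {
    stop(depdst_error("times must be strictly increasing", "series"))
  }
  structure(list(patient_id = patient_id, marker = marker,
                 time = time, value = value), class = "marker_series")
}

#' Fit a linear trend to a marker series
#'
#' Ordinary least squares of marker value on time in days,
#' `L = beta0 + beta1 * t + eps`, with the two-sided t-test of the slope
#' (`H0: beta1 = 0`; equivalently the regression F-test with one numerator
#' degree of freedom). A significant positive slope is an increasing trend,
#' a significant negative slope decreasing, otherwise none.
#'
#' @param series A [marker_series], or a numeric time vector when `value` is
#'   given.
#' @param value Marker values when `series` is a bare time vector.
#' @param alpha Significance level used to set the reported direction
#'   (default 0.05).
#' @return An object of class `trend_result`: `beta0`, `beta1` (per day),
#'   `sigma2` (residual variance), `p_value`, `direction`
#'   (increasing/decreasing/none), `n`.
#' @examples
#' fit_trend(marker_series("p1", "platelets", 0:9, 2 + 3 * (0:9)))
#' @export
fit_trend <- function(series, value = NULL, alpha = 0.05) {
  if (inherits(series, "marker_series")) {
    t <- series$time; y <- series$value
  } else {
    t <- as.numeric(series); y <- as.numeric(value)
  }
  n <- length(t)
  if (n < 3L) stop(depdst_error("need at least 3 observations", "series"))
  if (max(t) == min(t)) stop(depdst_error("all times equal", "series"))
  tbar <- mean(t); ybar <- mean(y)
  sxx <- sum((t - tbar)^2)
  sxy <- sum((t - tbar) * (y - ybar))
  beta1 <- sxy / sxx
  beta0 <- ybar - beta1 * tbar
  resid <- y - beta0 - beta1 * t
  rss <- sum(resid^2)
  sigma2 <- rss / (n - 2L)
  se <- sqrt(sigma2 / sxx)
  if (se == 0) {
    p <- if (abs(beta1) > 0) 0 else 1
  } else {
    p <- 2 * stats::pt(-abs(beta1 / se), df = n - 2L)
  }
  res <- structure(list(beta0 = beta0, beta1 = beta1, sigma2 = sigma2,
                        p_value = p, direction = "none", n = n),
                   class = "trend_result")
  res$direction <- classify_trend(res, alpha)
  res
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf("Linear trend: slope %.4g/day (intercept %.4g, sigma2 %.4g)\n",
              x$beta1, x$beta0, x$sigma2))
  cat(sprintf("  H0: slope = 0, p = %.4g -> %s\n", x$p_value, x$direction))
  invisible(x)
}

#' Classify a fitted trend at a significance level
#'
#' Rejects `H0: beta1 = 0` when `p_value < alpha`; the slope sign then gives
#' the direction.
#'
#' @param result A `trend_result`.
#' @param alpha Significance level in (0, 1).
#' @return `"increasing"`, `"decreasing"` or `"none"`.
#' @export
classify_trend <- function(result, alpha = 0.05) {
  stopifnot(inherits(result, "trend_result"))
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop(depdst_error("alpha must lie in (0, 1)", "alpha"))
  }
  if (is.na(result$p_value) || result$p_value >= alpha) return("none")
  if (result$beta1 > 0) "increasing" else if (result$beta1 < 0) "decreasing" else "none"
}

#' Fit trends for every patient x marker series in a lab table
#'
#' Series with fewer than 3 observations are kept but reported with direction
#' `"none"` and a missing p-value, so downstream they contribute no temporal
#' support rather than an error.
#'
#' @param labs Data frame with columns `patient_id`, `marker`, `date`
#'   (Date or ISO-8601 string), `value`.
#' @param alpha Significance level.
#' @return Data frame with one row per series: patient_id, marker, n, beta0,
#'   beta1, sigma2, p_value, direction, mid_date (midpoint of the observation
#'   window, used for exposure overlap).
#' @export
fit_marker_trends <- function(labs, alpha = 0.05) {
  need <- c("patient_id", "marker", "date", "value")
  if (!all(need %in% names(labs))) {
    stop(depdst_error("labs must have columns patient_id, marker, date, value",
                      "labs_format"))
  }
  labs$date <- as.Date(labs$date)
  key <- paste(labs$patient_id, labs$marker, sep = "\x1f")
  idx <- split(seq_len(nrow(labs)), key)
  rows <- lapply(idx, function(i) {
    d <- labs[i, , drop = FALSE]
    d <- d[order(d$date), , drop = FALSE]
    d <- d[!duplicated(d$date), , drop = FALSE]
    base <- data.frame(patient_id = d$patient_id[1L], marker = d$marker[1L],
                       n = nrow(d), stringsAsFactors = FALSE)
    if (nrow(d) < 3L) {
      cbind(base, beta0 = NA_real_, beta1 = NA_real_, sigma2 = NA_real_,
            p_value = NA_real_, direction = "none",
            mid_date = d$date[1L] + as.numeric(d$date[nrow(d)] - d$date[1L]) / 2)
    } else {
      tr <- fit_trend(as.numeric(d$date - d$date[1L]), d$value, alpha = alpha)
      cbind(base, beta0 = tr$beta0, beta1 = tr$beta1, sigma2 = tr$sigma2,
            p_value = tr$p_value, direction = tr$direction,
            mid_date = d$date[1L] + as.numeric(d$date[nrow(d)] - d$date[1L]) / 2)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build the temporality basis
#'
#' A triple (patient, drug, symptom) enters the basis when a significant
#' marker trend for that patient has its window midpoint inside one of the
#' patient's exposure windows for the drug (extended by `lag` days), and the
#' (marker, direction) pair maps to the symptom in the knowledge map. The map
#' is an explicit knowledge input encoding clinical experience (e.g.
#' decreasing platelets can manifest as bleeding or edema); it is never
#' inferred from data.
#'
#' @param trends Data frame from [fit_marker_trends()] (needs patient_id,
#'   marker, direction, mid_date).
#' @param exposures Data frame with patient_id, drug, start_date, end_date.
#' @param marker_symptom_map Data frame with marker, direction, symptom.
#' @param lag Days appended to each exposure window (default 30).
#' @return An object of class `temporality_basis`: a unique data frame of
#'   (patient_id, drug, symptom) triples.
#' @export
build_temporality_basis <- function(trends, exposures, marker_symptom_map,
                                    lag = 30) {
  exposures$start_date <- as.Date(exposures$start_date)
  exposures$end_date <- as.Date(exposures$end_date)
  if (any(exposures$end_date < exposures$start_date)) {
    stop(depdst_error("exposure with end date before start date", "exposure"))
  }
  trends <- trends[trends$direction != "none", , drop = FALSE]
  out <- data.frame(patient_id = character(0), drug = character(0),
                    symptom = character(0), stringsAsFactors = FALSE)
  if (nrow(trends) > 0L) {
    hit <- merge(trends, marker_symptom_map, by = c("marker", "direction"))
    if (nrow(hit) > 0L) {
      hit <- merge(hit, exposures, by = "patient_id")
      mid <- as.Date(hit$mid_date)
      keep <- mid >= hit$start_date & mid <= hit$end_date + lag
      hit <- hit[keep, c("patient_id", "drug", "symptom"), drop = FALSE]
      hit$patient_id <- as.character(hit$patient_id)
      hit$drug <- as.character(hit$drug)
      hit$symptom <- as.character(hit$symptom)
      out <- unique(hit)
    }
  }
  rownames(out) <- NULL
  class(out) <- c("temporality_basis", "data.frame")
  out
}

#' Temporal-dependence credibility component
#'
#' Pure membership test: 1 when the record's (patient, drug, symptom) triple
#' is supported by the temporality basis, else 0. Vectorized over records.
#'
#' @param patient_id,drug,symptom Vectors identifying the records.
#' @param basis A `temporality_basis`.
#' @return Integer vector of 0/1 indicators.
#' @export
dep_temporal <- function(patient_id, drug, symptom, basis) {
  stopifnot(inherits(basis, "temporality_basis"))
  if (nrow(basis) == 0L) return(rep(0L, length(patient_id)))
  keys <- paste(patient_id, drug, symptom, sep = "\x1f")
  bkeys <- paste(basis$patient_id, basis$drug, basis$symptom, sep = "\x1f")
  as.integer(keys %in% bkeys)
}
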