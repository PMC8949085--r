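# Credibility index: the four dependency components (causal arc strength,
# chi-square correlation, interaction effect size, temporal trend) and their
# integration into a normalized first-principal-component index.

#' Correlation credibility component from a contingency table
#'
#' Runs the Pearson chi-square test of independence (no continuity
#' correction) on the record's disease-by-symptom contingency table and
#' returns `1 - p`. With `direction = "p"` the raw p-value is returned
#' instead; the two conventions encode opposite readings of what a strong
#' disease-symptom association means for ADR credibility, and the package
#' defaults to `1 - p`.
#'
#' @param contingency Matrix (at least 2x2) of non-negative integer counts
#'   with a positive grand total and no zero row/column margin.
#' @param direction `"one_minus_p"` (default) or `"p"`.
#' @return A value in \[0, 1\].
#' @examples
#' dep_correlation(matrix(c(20, 10, 10, 20), 2))
#' @export
dep_correlation <- function(contingency, direction = c("one_minus_p", "p")) {
  direction <- match.arg(direction)
  tab <- as.matrix(contingency)
  if (nrow(tab) < 2L || ncol(tab) < 2L) {
    stop(depdst_error("contingency table must be at least 2x2", "contingency"))
  }
  if (any(!is.finite(tab)) || any(tab < 0) || any(abs(tab - round(tab)) > 1e-8)) {
    stop(depdst_error("counts must be non-negative integers", "contingency"))
  }
  if (sum(tab) <= 0) {
    stop(depdst_error("grand total must be positive", "contingency"))
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop(depdst_error("degenerate margin: a row or column sums to zero",
                      "degenerate_margin"))
  }
  p <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))$p.value
  if (direction == "one_minus_p") 1 - p else p
}

#' Effect-size credibility component
#'
#' An ADR in which several concurrently administered drugs could each explain
#' the symptom is less believable than one with an isolated exposure: the
#' component is `1 / n` for `n` concurrent drugs. Vectorized.
#'
#' @param n_drugs Positive integer count(s) of concurrently administered
#'   drugs.
#' @return Value(s) in (0, 1\].
#' @export
dep_effect_size <- function(n_drugs) {
  if (length(n_drugs) == 0L || any(!is.finite(n_drugs)) ||
      any(n_drugs != round(n_drugs))) {
    stop(depdst_error("n_drugs must be integer counts", "effect_size"))
  }
  if (any(n_drugs < 1)) {
    stop(depdst_error("no exposure: record lists zero drugs", "no_exposure"))
  }
  1 / n_drugs
}

#' Disease-by-symptom contingency tables at patient level
#'
#' For every (disease, symptom) pair occurring among the candidate records,
#' builds the 2x2 patient-level table crossing "patient has the disease"
#' against "patient exhibited the symptom", which feeds [dep_correlation()].
#'
#' @param candidates Data frame with patient_id, disease, symptom.
#' @param registry Data frame with patient_id and disease (one row per
#'   patient).
#' @return Named list of 2x2 matrices, keyed `"disease::symptom"`.
#' @export
disease_symptom_contingencies <- function(candidates, registry) {
  pairs <- unique(candidates[, c("disease", "symptom")])
  pat_dis <- stats::setNames(as.character(registry$disease),
                             as.character(registry$patient_id))
  sym_pat <- split(as.character(candidates$patient_id),
                   as.character(candidates$symptom))
  out <- list()
  patients <- names(pat_dis)
  for (i in seq_len(nrow(pairs))) {
    d <- as.character(pairs$disease[i]); s <- as.character(pairs$symptom[i])
    has_d <- pat_dis[patients] == d
    has_s <- patients %in% sym_pat[[s]]
    tab <- matrix(c(sum(has_d & has_s), sum(has_d & !has_s),
                    sum(!has_d & has_s), sum(!has_d & !has_s)),
                  nrow = 2, byrow = TRUE,
                  dimnames = list(disease = c("yes", "no"),
                                  symptom = c("yes", "no")))
    out[[paste(d, s, sep = "::")]] <- tab
  }
  out
}

#' Assemble per-record credibility components
#'
#' One row per candidate record, each component produced by its own
#' operation: causal arc strength ([dep_causal_strength()]), chi-square
#' correlation ([dep_correlation()] on the record's disease x symptom table),
#' effect size ([dep_effect_size()] on the concurrent drug count), and
#' temporal support ([dep_temporal()]). Component errors are re-raised with
#' the offending record id attached.
#'
#' @param candidates Data frame with record_id, patient_id, disease, drug,
#'   symptom, n_drugs.
#' @param strength_table An `arc_strength_table`.
#' @param contingencies Named list from [disease_symptom_contingencies()].
#' @param basis A `temporality_basis`.
#' @param correlation_direction Passed to [dep_correlation()].
#' @return Data frame: record_id, dep_causal_strength, dep_correlation,
#'   dep_effect_size, dep_temporal.
#' @export
assemble_components <- function(candidates, strength_table, contingencies,
                                basis,
                                correlation_direction = c("one_minus_p", "p")) {
  correlation_direction <- match.arg(correlation_direction)
  n <- nrow(candidates)
  if (n == 0L) {
    return(data.frame(record_id = character(0), dep_causal_strength = numeric(0),
                      dep_correlation = numeric(0), dep_effect_size = numeric(0),
                      dep_temporal = integer(0)))
  }
  # cache pairwise lookups; components are pair-level, records are many
  strength_cache <- new.env(parent = emptyenv())
  corr_cache <- new.env(parent = emptyenv())
  causal <- numeric(n); corr <- numeric(n)
  for (i in seq_len(n)) {
    id <- as.character(candidates$record_id[i])
    withCallingHandlers(
      {
        dkey <- paste(candidates$drug[i], candidates$symptom[i], sep = "\x1f")
        if (is.null(strength_cache[[dkey]])) {
          strength_cache[[dkey]] <- dep_causal_strength(
            as.character(candidates$drug[i]),
            as.character(candidates$symptom[i]), strength_table)
        }
        causal[i] <- strength_cache[[dkey]]
        ckey <- paste(candidates$disease[i], candidates$symptom[i], sep = "::")
        if (is.null(corr_cache[[ckey]])) {
          tab <- contingencies[[ckey]]
          if (is.null(tab)) {
            stop(depdst_error(sprintf("no contingency table for pair %s", ckey),
                              "contingency"))
          }
          corr_cache[[ckey]] <- dep_correlation(tab, correlation_direction)
        }
        corr[i] <- corr_cache[[ckey]]
      },
      error = function(e) {
        stop(errorCondition(paste0("record ", id, ": ", conditionMessage(e)),
                            class = class(e)))
      })
  }
  data.frame(
    record_id = as.character(candidates$record_id),
    dep_causal_strength = causal,
    dep_correlation = corr,
    dep_effect_size = dep_effect_size(candidates$n_drugs),
    dep_temporal = dep_temporal(candidates$patient_id, candidates$drug,
                                candidates$symptom, basis),
    stringsAsFactors = FALSE)
}

#' Integrate credibility components into the PCA index
#'
#' Takes the covariance matrix of the component columns, extracts the unit
#' eigenvector of the largest eigenvalue (the direction of maximum variance),
#' orients it so its coordinates sum to a non-negative value, and projects
#' every record onto it. The projections are min-max normalized to \[0, 1\]
#' over the batch; the normalization bounds are stored so held-out records
#' can reuse them via [predict.credibility_index()].
#'
#' @param components Numeric matrix or data frame (n records x k components,
#'   k >= 2); non-numeric columns such as `record_id` are dropped.
#' @param standardize Use the correlation-scale PCA (columns standardized)
#'   instead of the covariance matrix. Default `FALSE`.
#' @param tie_tol Eigenvalue tie tolerance; ties are broken by the
#'   lexicographically larger oriented eigenvector.
#' @return An object of class `credibility_index`: loadings, covariance,
#'   eigenvalues, raw and normalized per-record values, normalization bounds.
#' @export
pca_integrate <- function(components, standardize = FALSE, tie_tol = 1e-9) {
  X <- as.data.frame(components)
  X <- X[, vapply(X, is.numeric, logical(1)), drop = FALSE]
  X <- as.matrix(X)
  if (nrow(X) < 2L) {
    stop(depdst_error("need at least two records for PCA integration", "pca_n"))
  }
  vars <- apply(X, 2L, stats::var)
  if (all(vars == 0)) {
    stop(depdst_error("degenerate covariance: all components constant",
                      "degenerate_covariance"))
  }
  center <- colMeans(X)
  scale_ <- rep(1, ncol(X))
  Z <- X
  if (standardize) {
    scale_ <- sqrt(vars)
    scale_[scale_ == 0] <- 1
    Z <- sweep(X, 2L, scale_, "/")  # covariance is centering-invariant
  }
  S <- stats::cov(Z)
  eig <- eigen(S, symmetric = TRUE)
  top <- which(eig$values >= eig$values[1L] - tie_tol)
  orient <- function(e) {
    s <- sum(e)
    if (s < 0) return(-e)
    if (s == 0) {
      nz <- which(e != 0)[1L]
      if (length(nz) && e[nz] < 0) return(-e)
    }
    e
  }
  cand <- lapply(top, function(j) orient(eig$vectors[, j]))
  if (length(cand) > 1L) {
    # deterministic tie-break: lexicographically larger oriented eigenvector
    best <- cand[[1L]]
    for (e in cand[-1L]) {
      cmp <- which(e != best)[1L]
      if (!is.na(cmp) && e[cmp] > best[cmp]) best <- e
    }
    e <- best
  } else {
    e <- cand[[1L]]
  }
  raw <- as.numeric(Z %*% e)
  normalized <- normalize_index(raw)
  structure(list(loadings = stats::setNames(e, colnames(X)),
                 covariance = S, eigenvalues = eig$values,
                 raw = raw, normalized = normalized,
                 bounds = c(min = min(raw), max = max(raw)),
                 center = center, scale = scale_, standardize = standardize),
            class = "credibility_index")
}

#' @export
print.credibility_index <- function(x, ...) {
  cat("Credibility index (first principal component of",
      length(x$loadings), "components)\n")
  cat("Loadings:\n")
  print(round(x$loadings, 4))
  cat(sprintf("Explained variance: %.1f%%\n",
              100 * x$eigenvalues[1L] / sum(x$eigenvalues)))
  invisible(x)
}

#' @export
coef.credibility_index <- function(object, ...) object$loadings

#' Score new records with a fitted credibility index
#'
#' Projects new component rows onto the stored loadings and rescales with the
#' training min-max bounds, clipping to \[0, 1\].
#'
#' @param object A `credibility_index`.
#' @param newdata Matrix or data frame with the same component columns.
#' @param ... Unused.
#' @return Numeric vector of normalized index values in \[0, 1\].
#' @export
predict.credibility_index <- function(object, newdata, ...) {
  X <- as.data.frame(newdata)
  X <- X[, names(object$loadings), drop = FALSE]
  X <- as.matrix(X)
  if (object$standardize) {
    X <- sweep(X, 2L, object$scale, "/")
  }
  raw <- as.numeric(X %*% object$loadings)
  lo <- object$bounds["max"] - object$bounds["min"]
  pmin(pmax((raw - object$bounds["min"]) / lo, 0), 1)
}

#' Min-max normalize index values to \[0, 1\]
#'
#' @param x Numeric vector with at least one finite value and `max > min`.
#' @return `(x - min) / (max - min)`; order preserving.
#' @export
normalize_index <- function(x) {
  x <- as.numeric(x)
  if (length(x) == 0L || all(!is.finite(x))) {
    stop(depdst_error("need at least one finite value", "constant_index"))
  }
  lo <- min(x); hi <- max(x)
  if (hi == lo) {
    stop(depdst_error("constant index: max equals min", "constant_index"))
  }
  (x - lo) / (hi - lo)
}

#' Low-credibility cutoff (first quartile)
#'
#' The upper limit of the low-credibility zone is the first quartile of the
#' normalized index (linear-interpolation quantile, type 7). Records with
#' index at or below the cutoff are flagged low-credibility. The cutoff is
#' always recomputed from the data at hand, never hard-coded.
#'
#' @param normalized Numeric vector of at least 4 normalized index values.
#' @return The first-quartile threshold.
#' @export
low_credibility_cutoff <- function(normalized) {
  if (length(normalized) < 4L) {
    stop(depdst_error("need at least 4 values for a quartile cutoff", "cutoff_n"))
  }
  stats::quantile(normalized, probs = 0.25, type = 7, names = FALSE)
}

#' Persist a credibility index (loadings, covariance, bounds) as JSON
#'
#' @param ci A `credibility_index`.
#' @param path Optional output file.
#' @return JSON string (invisibly when written).
#' @export
ci_to_json <- function(ci, path = NULL) {
  stopifnot(inherits(ci, "credibility_index"))
  obj <- list(loadings = as.list(ci$loadings),
              covariance = ci$covariance,
              eigenvalues = ci$eigenvalues,
              bounds = as.list(ci$bounds),
              center = as.list(ci$center),
              scale = as.numeric(ci$scale),
              standardize = ci$standardize)
  txt <- as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Restore a credibility index from JSON
#'
#' The restored object scores new data via [predict.credibility_index()];
#' per-record raw/normalized values of the original batch are not persisted.
#'
#' @param txt JSON string or file path produced by [ci_to_json()].
#' @return A `credibility_index` (without the training batch scores).
#' @export
ci_from_json <- function(txt) {
  if (length(txt) == 1L && file.exists(txt)) txt <- paste(readLines(txt), collapse = "")
  obj <- jsonlite::fromJSON(txt)
  structure(list(loadings = unlist(obj$loadings),
                 covariance = as.matrix(obj$covariance),
                 eigenvalues = as.numeric(obj$eigenvalues),
                 raw = NULL, normalized = NULL,
                 bounds = unlist(obj$bounds),
                 center = unlist(obj$center),
                 scale = as.numeric(obj$scale),
                 standardize = isTRUE(obj$standardize)),
            class = "credibility_index")
}
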