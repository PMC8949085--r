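# Evidence generation: random-forest class probabilities turned into basic
# probability assignments conditioned by the credibility index, plus
# knowledge-base (medicine leaflet) masses and Dempster fusion.

#' Train the random-forest evidence model
#'
#' Fits a probability forest whose class probabilities later become singleton
#' masses of a basic probability assignment. Defaults: 500 trees,
#' square-root feature sampling per split, per-seed subsampling; fully
#' deterministic given the seed (single-threaded).
#'
#' @param data Data frame of encoded features plus the target column; no
#'   missing values.
#' @param target Name of the categorical target column (at least 2 classes,
#'   at least 20 rows).
#' @param seed Integer seed.
#' @param num_trees Number of trees (default 500).
#' @param mtry Features per split; default `floor(sqrt(p))`.
#' @param ... Further arguments passed to [ranger::ranger()].
#' @return An object of class `bpa_model` wrapping the fitted forest with its
#'   class levels.
#' @export
train_bpa_model <- function(data, target, seed, num_trees = 500,
                            mtry = NULL, ...) {
  if (!target %in% names(data)) {
    stop(depdst_error(sprintf("target column '%s' not in data", target),
                      "target"))
  }
  y <- factor(data[[target]])
  if (nlevels(y) < 2L) {
    stop(depdst_error("target has a single class", "single_class"))
  }
  if (nrow(data) < 20L) {
    stop(depdst_error("need at least 20 rows to train", "too_few_rows"))
  }
  if (anyNA(data)) {
    stop(depdst_error("data contains missing values", "missing_values"))
  }
  df <- data
  df[[target]] <- y
  p <- ncol(df) - 1L
  fit <- ranger::ranger(
    dependent.variable.name = target, data = df,
    probability = TRUE, num.trees = num_trees,
    mtry = if (is.null(mtry)) max(1L, floor(sqrt(p))) else mtry,
    seed = as.integer(seed), num.threads = 1L,
    respect.unordered.factors = "order", ...)
  structure(list(forest = fit, classes = levels(y), target = target,
                 seed = as.integer(seed)),
            class = "bpa_model")
}

#' @export
print.bpa_model <- function(x, ...) {
  cat("Random-forest evidence model:", x$forest$num.trees, "trees,",
      length(x$classes), "classes\n")
  cat("Classes:", paste(x$classes, collapse = ", "), "\n")
  cat(sprintf("OOB Brier score: %.4f\n", x$forest$prediction.error))
  invisible(x)
}

#' Basic probability assignment from class probabilities
#'
#' Converts a probability vector into a mass function conditioned by the
#' record's credibility index `ci`: each singleton receives `ci * p_k` and
#' the whole frame keeps `1 - ci`, so distrust in the record becomes
#' explicit ignorance rather than spread probability.
#'
#' @param probs Named non-negative vector over the frame's hypotheses
#'   (normalized internally).
#' @param ci Credibility in \[0, 1\].
#' @param frame A [dst_frame] whose hypotheses match `names(probs)`.
#' @return A valid `mass_function` with singleton and whole-frame focal sets.
#' @export
bpa_from_probs <- function(probs, ci, frame) {
  if (!inherits(frame, "dst_frame")) frame <- dst_frame(frame)
  if (!is.numeric(ci) || length(ci) != 1L || is.na(ci) || ci < 0 || ci > 1) {
    stop(depdst_error("ci must be a single value in [0, 1]", "credibility_range"))
  }
  if (is.null(names(probs)) || !setequal(names(probs), unclass(frame))) {
    stop(depdst_error("probability names must match the frame hypotheses",
                      "frame_mismatch"))
  }
  if (any(probs < 0)) stop(depdst_error("negative probability", "negative_mass"))
  s <- sum(probs)
  if (s <= 0) stop(depdst_error("probabilities sum to zero", "mass_sum"))
  probs <- probs / s
  m <- stats::setNames(as.numeric(probs) * ci, names(probs))
  m[theta_key(frame)] <- 1 - ci
  mass_function(frame, m)
}

#' Predict per-record BPAs from the evidence model
#'
#' @param model A `bpa_model`.
#' @param newdata Feature rows to score.
#' @param ci Credibility index per row (recycled if length 1).
#' @param frame A [dst_frame]; its hypotheses must equal the model classes.
#' @return A list of `mass_function`s, one per row.
#' @export
predict_bpa <- function(model, newdata, ci, frame) {
  stopifnot(inherits(model, "bpa_model"))
  if (!inherits(frame, "dst_frame")) frame <- dst_frame(frame)
  if (!setequal(unclass(frame), model$classes)) {
    stop(depdst_error("frame hypotheses do not match model classes",
                      "frame_mismatch"))
  }
  probs <- stats::predict(model$forest, data = newdata,
                          num.threads = 1L)$predictions
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1,
                                           dimnames = list(NULL, model$classes))
  ci <- rep_len(ci, nrow(probs))
  lapply(seq_len(nrow(probs)), function(i) {
    bpa_from_probs(stats::setNames(probs[i, model$classes], model$classes),
                   ci[i], frame)
  })
}

#' Held-out class probabilities by stratified cross-validation
#'
#' Evaluation-time probabilities come from k-fold held-out predictions so the
#' generated masses are not optimistically sharp; inference on new records
#' uses the full model instead.
#'
#' @inheritParams train_bpa_model
#' @param folds Number of stratified folds (default 5).
#' @return List with `probs` (n x classes matrix of held-out probabilities),
#'   `predicted` (argmax class per row), `fold` (fold assignment).
#' @export
heldout_probs <- function(data, target, seed, folds = 5, num_trees = 500,
                          ...) {
  y <- factor(data[[target]])
  if (nlevels(y) < 2L) stop(depdst_error("target has a single class", "single_class"))
  if (any(table(y) < 2L)) {
    stop(depdst_error(
      sprintf("class(es) with fewer than 2 records cannot be stratified: %s",
              paste(names(which(table(y) < 2L)), collapse = ", ")),
      "degenerate_folds"))
  }
  fold <- integer(nrow(data))
  with_seed(child_seed(seed, 1L), {
    for (cl in levels(y)) {
      idx <- which(y == cl)
      fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  })
  probs <- matrix(0, nrow(data), nlevels(y),
                  dimnames = list(NULL, levels(y)))
  for (k in seq_len(folds)) {
    tr <- data[fold != k, , drop = FALSE]
    te <- data[fold == k, , drop = FALSE]
    if (nrow(te) == 0L) next
    m <- train_bpa_model(tr, target, seed = child_seed(seed, 100L + k),
                         num_trees = num_trees, ...)
    pk <- stats::predict(m$forest, data = te, num.threads = 1L)$predictions
    if (is.null(dim(pk))) pk <- matrix(pk, nrow = 1, dimnames = list(NULL, m$classes))
    probs[fold == k, colnames(pk)] <- pk
  }
  predicted <- factor(colnames(probs)[max.col(probs, ties.method = "first")],
                      levels = levels(y))
  list(probs = probs, predicted = predicted, fold = fold)
}

#' Mass function from the medicine-leaflet knowledge base
#'
#' Known drug-reaction pairs carry a source credibility `c`; the resulting
#' mass puts `c` on the supporting hypothesis and `1 - c` on the whole frame.
#' A pair absent from the knowledge base yields the vacuous mass (absence of
#' documentation is not evidence against).
#'
#' @param kb Data frame with columns drug, reaction, credibility (unique
#'   pairs, credibility in \[0, 1\]).
#' @param drug,symptom The record's candidate pair.
#' @param frame A [dst_frame].
#' @param hypothesis Frame hypothesis supported by a known pair; defaults to
#'   `symptom` (symptom-framed analyses) but is typically `"ADR"` under the
#'   cause framing.
#' @return A valid `mass_function`.
#' @export
leaflet_mass <- function(kb, drug, symptom, frame, hypothesis = symptom) {
  if (!inherits(frame, "dst_frame")) frame <- dst_frame(frame)
  if (!hypothesis %in% unclass(frame)) {
    stop(depdst_error(sprintf("hypothesis '%s' not in frame", hypothesis),
                      "subset"))
  }
  hit <- which(kb$drug == drug & kb$reaction == symptom)
  if (length(hit) == 0L) return(vacuous_mass(frame))
  cred <- kb$credibility[hit[1L]]
  if (is.na(cred) || cred < 0 || cred > 1) {
    stop(depdst_error("knowledge-base credibility outside [0, 1]",
                      "credibility_range"))
  }
  m <- stats::setNames(c(cred, 1 - cred), c(hypothesis, theta_key(frame)))
  mass_function(frame, m)
}

#' Fuse a generated BPA with external evidence
#'
#' Delegates to [dempster_combine()] and augments the result with the belief
#' of every singleton hypothesis.
#'
#' @param bpa,external `mass_function`s over the same frame.
#' @return A `fusion_result` with an extra `belief` element (named vector of
#'   singleton beliefs).
#' @export
fuse <- function(bpa, external) {
  res <- dempster_combine(bpa, external)
  hyps <- as.character(unclass(res$combined$frame))
  res$belief <- stats::setNames(
    vapply(hyps, function(h) belief(res$combined, h), numeric(1)), hyps)
  res
}

#' Read a leaflet knowledge base CSV
#'
#' @param path CSV with columns drug, reaction, credibility.
#' @return Validated data frame.
#' @export
read_leaflet_kb <- function(path) {
  kb <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("drug", "reaction", "credibility")
  if (!all(need %in% names(kb))) {
    stop(depdst_error("leaflet KB must have columns drug, reaction, credibility",
                      "kb_format"))
  }
  if (anyDuplicated(kb[, c("drug", "reaction")])) {
    stop(depdst_error("duplicate drug-reaction pairs in knowledge base",
                      "kb_format"))
  }
  if (any(kb$credibility < 0 | kb$credibility > 1)) {
    stop(depdst_error("knowledge-base credibility outside [0, 1]",
                      "credibility_range"))
  }
  kb
}
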