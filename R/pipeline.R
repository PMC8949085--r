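# Pipeline: classification metrics, the three-scenario benchmark, batch
# evidence fusion, and the dep_dst() fitting front door with S3 methods.

#' Confusion-matrix classification metrics
#'
#' Accuracy plus precision and recall averaged over classes. With macro
#' averaging (the default), per-class precision/recall are computed from the
#' confusion matrix and averaged; a class never predicted contributes a
#' precision of 0. Micro averaging collapses to accuracy for single-label
#' classification and is provided for completeness.
#'
#' @param predicted,actual Equal-length class vectors (factors or character).
#' @param average `"macro"` (default) or `"micro"`.
#' @return List with `accuracy`, `precision`, `recall`, and the per-class
#'   `table` of precision/recall.
#' @export
compute_metrics <- function(predicted, actual, average = c("macro", "micro")) {
  average <- match.arg(average)
  if (length(predicted) != length(actual) || length(actual) == 0L) {
    stop(depdst_error("predicted and actual must be equal-length, non-empty",
                      "metrics_input"))
  }
  lev <- union(levels(factor(actual)), levels(factor(predicted)))
  p <- factor(predicted, levels = lev)
  a <- factor(actual, levels = lev)
  cm <- table(predicted = p, actual = a)
  acc <- sum(diag(cm)) / sum(cm)
  prec <- diag(cm) / rowSums(cm)
  prec[is.nan(prec)] <- 0
  rec <- diag(cm) / colSums(cm)
  present <- colSums(cm) > 0
  per_class <- data.frame(class = lev, precision = as.numeric(prec),
                          recall = as.numeric(rec), stringsAsFactors = FALSE)
  if (average == "macro") {
    list(accuracy = acc, precision = mean(prec[present]),
         recall = mean(rec[present]), table = per_class)
  } else {
    list(accuracy = acc, precision = acc, recall = acc, table = per_class)
  }
}

# one binary exposure column per drug, aligned to the candidate records
drug_indicator_columns <- function(candidates, prescriptions,
                                   drugs = sort(unique(prescriptions$drug))) {
  expo <- split(prescriptions$drug, prescriptions$patient_id)
  out <- matrix(0L, nrow(candidates), length(drugs),
                dimnames = list(NULL, paste0("takes_", drugs)))
  for (i in seq_len(nrow(candidates))) {
    hit <- intersect(expo[[as.character(candidates$patient_id[i])]], drugs)
    out[i, paste0("takes_", hit)] <- 1L
  }
  as.data.frame(out)
}

scenario_features <- function(scenario, candidates, registry, comps,
                              prescriptions = NULL,
                              drug_vocab = NULL) {
  base <- merge(candidates, registry[, c("patient_id", "age", "sex")],
                by = "patient_id", sort = FALSE)
  base <- base[order(match(base$record_id, candidates$record_id)), ]
  feats <- data.frame(
    age = base$age, sex = factor(base$sex),
    disease = factor(base$disease), drug = factor(base$drug),
    symptom = factor(base$symptom), n_drugs = base$n_drugs)
  if (!is.null(prescriptions)) {
    if (is.null(drug_vocab)) drug_vocab <- sort(unique(prescriptions$drug))
    feats <- cbind(feats, drug_indicator_columns(candidates, prescriptions,
                                                 drug_vocab))
  }
  if (scenario == "base") return(feats)
  comps <- comps[match(base$record_id, comps$record_id), ]
  noncausal <- comps[, c("dep_correlation", "dep_effect_size", "dep_temporal")]
  feats <- cbind(feats, noncausal)
  if (scenario == "base_ci") {
    feats$ic_pca <- pca_integrate(noncausal)$normalized
    return(feats)
  }
  if (scenario == "base_ci_bayes") {
    feats$dep_causal_strength <- comps$dep_causal_strength
    full <- comps[, c("dep_causal_strength", "dep_correlation",
                      "dep_effect_size", "dep_temporal")]
    feats$ic_pca <- pca_integrate(full)$normalized
    return(feats)
  }
  stop(depdst_error(sprintf("unknown scenario '%s'", scenario), "scenario"))
}

# patient-level structure-learning table: disease + per-drug and per-symptom
# binary indicators, restricted to drugs/symptoms that actually vary
structure_table <- function(candidates, registry, prescriptions) {
  pid <- registry$patient_id
  tab <- data.frame(disease = registry$disease, row.names = NULL,
                    stringsAsFactors = FALSE)
  for (d in sort(unique(prescriptions$drug))) {
    v <- pid %in% prescriptions$patient_id[prescriptions$drug == d]
    if (length(unique(v)) > 1L) tab[[d]] <- ifelse(v, "yes", "no")
  }
  for (s in sort(unique(candidates$symptom))) {
    v <- pid %in% candidates$patient_id[candidates$symptom == s]
    if (length(unique(v)) > 1L) tab[[s]] <- ifelse(v, "yes", "no")
  }
  tab
}

compute_all_components <- function(sim, seed, mcmc_iter = 1500,
                                   mcmc_burn = 300, alpha = 0.05, lag = 30,
                                   undirected_strength = TRUE,
                                   correlation_direction = "one_minus_p") {
  trends <- fit_marker_trends(sim$labs, alpha = alpha)
  basis <- build_temporality_basis(trends, sim$prescriptions,
                                   sim$marker_symptom_map, lag = lag)
  contingencies <- disease_symptom_contingencies(sim$candidates, sim$registry)
  stab <- structure_table(sim$candidates, sim$registry, sim$prescriptions)
  samples <- sample_structures_mcmc(stab, n_iter = mcmc_iter,
                                    burn_in = mcmc_burn,
                                    seed = child_seed(seed, 11L))
  strengths <- arc_strength(samples, nodes = names(stab),
                            undirected = undirected_strength)
  comps <- assemble_components(sim$candidates, strengths, contingencies,
                               basis, correlation_direction)
  list(components = comps, basis = basis, contingencies = contingencies,
       strengths = strengths, trends = trends)
}

#' Run the three-scenario benchmark
#'
#' For each seed: simulate a synthetic EHR (or reuse supplied data), compute
#' the credibility components, build the nested feature sets -- `base`
#' (covariates only), `base_ci` (plus correlation/effect-size/temporal
#' components and their PCA index), `base_ci_bayes` (plus the Bayesian arc
#' strength and the full four-component index) -- train the random-forest
#' evidence model under stratified k-fold cross-validation, and score the
#' held-out predictions against the generator's ground truth. Reports
#' per-seed metrics, means, dispersions, relative improvements over `base`,
#' and one-sided paired t-tests of the final scenario against `base`.
#'
#' @param params [world_params()] for the generator (its seed anchors the
#'   per-seed replicate seeds).
#' @param scenarios Character subset of
#'   `c("base", "base_ci", "base_ci_bayes")`, in nested order.
#' @param n_seeds Number of simulation replicates (default 10).
#' @param folds Stratified CV folds (default 5).
#' @param num_trees Trees per forest (default 300 at benchmark scale).
#' @param mcmc_iter,mcmc_burn Structure-MCMC iterations and burn-in per
#'   replicate.
#' @param average Metric averaging, see [compute_metrics()].
#' @param verbose Print progress to stderr.
#' @return An object of class `benchmark_report`: `per_seed` (long data
#'   frame), `summary` (per scenario: mean/sd of each metric and relative
#'   improvement vs base), `tests` (paired one-sided p-values last scenario
#'   vs base).
#' @export
run_benchmark <- function(params, scenarios = c("base", "base_ci", "base_ci_bayes"),
                          n_seeds = 10, folds = 5, num_trees = 300,
                          mcmc_iter = 1500, mcmc_burn = 300,
                          average = "macro", verbose = FALSE) {
  stopifnot(inherits(params, "world_params"))
  scenarios <- match.arg(scenarios, several.ok = TRUE)
  if (length(scenarios) < 2L) {
    stop(depdst_error("need at least two scenarios to benchmark", "scenario"))
  }
  if (n_seeds < 1L) stop(depdst_error("n_seeds must be >= 1", "params"))
  rows <- list()
  for (s in seq_len(n_seeds)) {
    seed_s <- child_seed(params$seed, 1000L + s)
    p_s <- params
    p_s$seed <- seed_s
    sim <- simulate_ehr(p_s)
    cc <- compute_all_components(sim, seed = seed_s,
                                 mcmc_iter = mcmc_iter, mcmc_burn = mcmc_burn)
    labels <- sim$truth$label[match(sim$candidates$record_id,
                                    sim$truth$record_id)]
    for (sc in scenarios) {
      feats <- scenario_features(sc, sim$candidates, sim$registry,
                                 cc$components, sim$prescriptions)
      feats$.label <- factor(labels)
      ho <- heldout_probs(feats, ".label", seed = child_seed(seed_s, 77L),
                          folds = folds, num_trees = num_trees)
      met <- compute_metrics(ho$predicted, feats$.label, average = average)
      rows[[length(rows) + 1L]] <- data.frame(
        seed = s, scenario = sc, accuracy = met$accuracy,
        precision = met$precision, recall = met$recall,
        stringsAsFactors = FALSE)
      if (verbose) {
        message(sprintf("seed %d %-14s acc %.3f prec %.3f rec %.3f",
                        s, sc, met$accuracy, met$precision, met$recall))
      }
    }
  }
  per_seed <- do.call(rbind, rows)
  agg <- function(metric) {
    mm <- tapply(per_seed[[metric]], per_seed$scenario, mean)[scenarios]
    ss <- tapply(per_seed[[metric]], per_seed$scenario, stats::sd)[scenarios]
    list(mean = mm, sd = ss)
  }
  sm <- lapply(c(accuracy = "accuracy", precision = "precision",
                 recall = "recall"), agg)
  summary_df <- data.frame(
    scenario = scenarios,
    accuracy = as.numeric(sm$accuracy$mean),
    accuracy_sd = as.numeric(sm$accuracy$sd),
    precision = as.numeric(sm$precision$mean),
    precision_sd = as.numeric(sm$precision$sd),
    recall = as.numeric(sm$recall$mean),
    recall_sd = as.numeric(sm$recall$sd),
    stringsAsFactors = FALSE)
  base_row <- summary_df[summary_df$scenario == scenarios[1L], ]
  for (metric in c("accuracy", "precision", "recall")) {
    summary_df[[paste0(metric, "_improve")]] <-
      (summary_df[[metric]] - base_row[[metric]]) / base_row[[metric]]
  }
  tests <- NULL
  if (n_seeds >= 2L && length(scenarios) >= 2L) {
    last <- scenarios[length(scenarios)]
    tests <- vapply(c("accuracy", "precision", "recall"), function(metric) {
      x <- per_seed[[metric]][per_seed$scenario == last]
      y <- per_seed[[metric]][per_seed$scenario == scenarios[1L]]
      if (stats::sd(x - y) == 0) return(if (mean(x - y) > 0) 0 else 1)
      stats::t.test(x, y, paired = TRUE, alternative = "greater")$p.value
    }, numeric(1))
  }
  structure(list(per_seed = per_seed, summary = summary_df, tests = tests,
                 scenarios = scenarios, n_seeds = n_seeds),
            class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat(sprintf("Benchmark over %d seed(s):\n", x$n_seeds))
  df <- x$summary
  df[-1] <- lapply(df[-1], function(v) round(v, 3))
  print(df, row.names = FALSE)
  if (!is.null(x$tests)) {
    cat(sprintf("One-sided paired test %s > %s: acc p=%.3g, prec p=%.3g, rec p=%.3g\n",
                x$scenarios[length(x$scenarios)], x$scenarios[1L],
                x$tests["accuracy"], x$tests["precision"], x$tests["recall"]))
  }
  invisible(x)
}

#' Export a benchmark report as CSV
#'
#' Columns: dataset (scenario), accuracy, precision, recall, and per-metric
#' relative improvement over the base scenario.
#'
#' @param report A `benchmark_report`.
#' @param path Optional output file.
#' @return The report data frame (invisibly when written).
#' @export
benchmark_to_csv <- function(report, path = NULL) {
  stopifnot(inherits(report, "benchmark_report"))
  out <- report$summary
  names(out)[names(out) == "scenario"] <- "dataset"
  if (is.null(path)) return(out)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}

#' Fuse per-record evidence with the leaflet knowledge base
#'
#' For every record: build the credibility-conditioned BPA from the supplied
#' class probabilities, combine it with the leaflet mass for the record's
#' drug-symptom pair, and report the fused singleton beliefs and conflict.
#' Fusion failures (total conflict) flag the record and the batch continues.
#'
#' @param probs Matrix (records x hypotheses) of class probabilities.
#' @param ci Per-record credibility index values in \[0, 1\].
#' @param candidates Data frame with record_id, drug, symptom.
#' @param kb Leaflet knowledge base (drug, reaction, credibility); may be
#'   empty or `NULL`, in which case fused beliefs equal the BPA beliefs.
#' @param frame A [dst_frame] matching the probability columns.
#' @param kb_hypothesis Hypothesis supported by a knowledge-base hit
#'   (default `"ADR"` for the cause framing; use the symptom itself under a
#'   symptom framing).
#' @return Data frame: record_id, one `bel_*` column per hypothesis,
#'   `conflict`, `flagged`.
#' @export
run_fusion <- function(probs, ci, candidates, kb, frame,
                       kb_hypothesis = "ADR") {
  if (!inherits(frame, "dst_frame")) frame <- dst_frame(frame)
  n <- nrow(candidates)
  hyps <- as.character(unclass(frame))
  bel <- matrix(NA_real_, n, length(hyps), dimnames = list(NULL, hyps))
  conflict <- numeric(n)
  flagged <- logical(n)
  ci <- rep_len(ci, n)
  for (i in seq_len(n)) {
    bpa <- bpa_from_probs(stats::setNames(probs[i, hyps], hyps), ci[i], frame)
    ext <- if (is.null(kb) || nrow(kb) == 0L) vacuous_mass(frame) else {
      leaflet_mass(kb, candidates$drug[i], candidates$symptom[i], frame,
                   hypothesis = kb_hypothesis)
    }
    res <- tryCatch(fuse(bpa, ext), depdst_error_conflict = function(e) NULL)
    if (is.null(res)) {
      flagged[i] <- TRUE
      res <- fuse(bpa, vacuous_mass(frame))
      conflict[i] <- 1
    } else {
      conflict[i] <- res$conflict
    }
    bel[i, ] <- res$belief[hyps]
  }
  out <- data.frame(record_id = candidates$record_id, bel,
                    conflict = conflict, flagged = flagged,
                    stringsAsFactors = FALSE)
  names(out)[seq_along(hyps) + 1L] <- paste0("bel_", hyps)
  out
}

# ---- dep_dst: the model-fitting front door ----------------------------------

#' Fit the dependency-aware evidence-fusion model
#'
#' The main entry point: takes EHR-style tables (candidate ADR records,
#' patient registry, prescriptions, lab series, a marker-to-symptom knowledge
#' map and optionally a leaflet knowledge base) plus per-record training
#' labels, and fits the full pipeline: lab-trend analysis and the temporality
#' basis; disease-symptom chi-square components; BDeu-scored structure MCMC
#' and drug-symptom arc strengths; the four-component PCA credibility index
#' with its first-quartile low-credibility cutoff; and the random-forest
#' evidence model whose class probabilities, discounted by the index, become
#' Dempster-Shafer BPAs fused with the leaflet evidence.
#'
#' @param candidates Data frame: record_id, patient_id, disease, drug,
#'   symptom, n_drugs.
#' @param registry Data frame: patient_id, age, sex, disease.
#' @param prescriptions Data frame: patient_id, drug, start_date, end_date.
#' @param labs Data frame: patient_id, marker, date, value.
#' @param marker_symptom_map Data frame: marker, direction, symptom.
#' @param labels Training labels per candidate record (e.g. adjudicated or
#'   generator truth), in candidate order.
#' @param leaflet_kb Optional knowledge base (drug, reaction, credibility).
#' @param seed Integer seed controlling the MCMC walk and the forest.
#' @param alpha Trend-test significance level (default 0.05).
#' @param lag Exposure lag in days for the temporality basis (default 30).
#' @param num_trees Forest size (default 500).
#' @param mcmc_iter,mcmc_burn Structure-MCMC iterations/burn-in.
#' @param correlation_direction See [dep_correlation()].
#' @param undirected_strength Pool arc orientations (default `TRUE`; MCMC
#'   often cannot resolve Markov-equivalent orientations).
#' @param prune_low_ci Drop (rather than just flag) records at or below the
#'   low-credibility cutoff before training. Default `FALSE`.
#' @return An object of class `dep_dst` with components, the credibility
#'   index, cutoff, arc strengths, basis, the fitted forest and training
#'   metadata; supports `print`, `summary`, `coef`, `predict` and `plot`.
#' @seealso [predict.dep_dst()], [run_benchmark()], [run_fusion()]
#' @export
dep_dst <- function(candidates, registry, prescriptions, labs,
                    marker_symptom_map, labels, leaflet_kb = NULL, seed = 1,
                    alpha = 0.05, lag = 30, num_trees = 500,
                    mcmc_iter = 2000, mcmc_burn = 500,
                    correlation_direction = c("one_minus_p", "p"),
                    undirected_strength = TRUE, prune_low_ci = FALSE) {
  correlation_direction <- match.arg(correlation_direction)
  if (length(labels) != nrow(candidates)) {
    stop(depdst_error("labels must match candidate records", "labels"))
  }
  sim <- list(candidates = candidates, registry = registry,
              prescriptions = prescriptions, labs = labs,
              marker_symptom_map = marker_symptom_map)
  cc <- compute_all_components(sim, seed = seed, mcmc_iter = mcmc_iter,
                               mcmc_burn = mcmc_burn, alpha = alpha,
                               lag = lag,
                               undirected_strength = undirected_strength,
                               correlation_direction = correlation_direction)
  comp_cols <- c("dep_causal_strength", "dep_correlation",
                 "dep_effect_size", "dep_temporal")
  ci <- pca_integrate(cc$components[, comp_cols])
  cutoff <- low_credibility_cutoff(ci$normalized)
  drug_vocab <- sort(unique(prescriptions$drug))
  feats <- scenario_features("base_ci_bayes", candidates, registry,
                             cc$components, prescriptions, drug_vocab)
  feats$.label <- factor(labels)
  keep <- rep(TRUE, nrow(feats))
  if (prune_low_ci) keep <- ci$normalized > cutoff
  model <- train_bpa_model(feats[keep, , drop = FALSE], ".label",
                           seed = child_seed(seed, 5L),
                           num_trees = num_trees)
  structure(list(components = cc$components, ci = ci, cutoff = cutoff,
                 strengths = cc$strengths, basis = cc$basis,
                 trends = cc$trends, contingencies = cc$contingencies,
                 model = model, frame = dst_frame(model$classes),
                 prescriptions = prescriptions, drug_vocab = drug_vocab,
                 leaflet_kb = leaflet_kb, labels = factor(labels),
                 features = feats, kept = keep, seed = seed,
                 alpha = alpha, lag = lag,
                 correlation_direction = correlation_direction,
                 call = match.call()),
            class = "dep_dst")
}

#' @export
print.dep_dst <- function(x, ...) {
  cat("Dependency-aware DST evidence model\n")
  cat(sprintf("  %d candidate records, %d patients in temporality basis\n",
              nrow(x$components), length(unique(x$basis$patient_id))))
  cat("  Credibility-index loadings:\n")
  print(round(x$ci$loadings, 4))
  cat(sprintf("  Low-credibility cutoff (first quartile): %.3f\n", x$cutoff))
  cat(sprintf("  Evidence forest: %d trees over classes %s\n",
              x$model$forest$num.trees,
              paste(x$model$classes, collapse = ", ")))
  invisible(x)
}

#' @export
summary.dep_dst <- function(object, ...) {
  comp <- object$components
  flagged <- sum(object$ci$normalized <= object$cutoff)
  fitted_metrics <- compute_metrics(
    factor(object$model$classes[max.col(
      stats::predict(object$model$forest,
                     data = object$features[object$kept, , drop = FALSE],
                     num.threads = 1L)$predictions, ties.method = "first")],
      levels = object$model$classes),
    object$labels[object$kept])
  out <- list(
    n_records = nrow(comp),
    component_summary = vapply(
      comp[, c("dep_causal_strength", "dep_correlation", "dep_effect_size",
               "dep_temporal")],
      function(v) c(mean = mean(v), sd = stats::sd(v)), numeric(2)),
    loadings = object$ci$loadings,
    explained_variance = object$ci$eigenvalues[1L] / sum(object$ci$eigenvalues),
    cutoff = object$cutoff, n_low_credibility = flagged,
    in_sample = fitted_metrics[c("accuracy", "precision", "recall")])
  class(out) <- "summary.dep_dst"
  out
}

#' @export
print.summary.dep_dst <- function(x, ...) {
  cat("Dependency-aware DST evidence model --", x$n_records, "records\n\n")
  cat("Credibility components (mean, sd):\n")
  print(round(x$component_summary, 4))
  cat(sprintf("\nIndex loadings (%.1f%% variance explained):\n",
              100 * x$explained_variance))
  print(round(x$loadings, 4))
  cat(sprintf("\nLow-credibility cutoff %.3f flags %d record(s)\n",
              x$cutoff, x$n_low_credibility))
  cat(sprintf("In-sample accuracy %.3f, macro precision %.3f, macro recall %.3f\n",
              x$in_sample$accuracy, x$in_sample$precision, x$in_sample$recall))
  invisible(x)
}

#' @export
coef.dep_dst <- function(object, ...) object$ci$loadings

#' Predict fused beliefs from a fitted model
#'
#' Scores candidate records with the evidence forest, conditions the
#' resulting BPAs by the records' credibility index (training bounds are
#' reused for new data), fuses with the leaflet knowledge base and returns
#' singleton beliefs plus conflict. With `newdata = NULL` the training
#' records are scored.
#'
#' @param object A fitted `dep_dst`.
#' @param newdata Optional list with elements `candidates` and `registry`
#'   (new records must reference drugs/symptoms/diseases known at fit time;
#'   their components are computed from the fitted arc strengths, basis and
#'   contingency tables).
#' @param type `"belief"` (default; fused beliefs via [run_fusion()]),
#'   `"bpa"` (list of mass functions), or `"prob"` (forest probabilities).
#' @param ... Unused.
#' @return See `type`.
#' @export
predict.dep_dst <- function(object, newdata = NULL,
                            type = c("belief", "bpa", "prob"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    candidates <- object$features
    cand_meta <- data.frame(record_id = object$components$record_id,
                            drug = as.character(object$features$drug),
                            symptom = as.character(object$features$symptom),
                            stringsAsFactors = FALSE)
    feats <- object$features
    ci_vals <- pmin(pmax((object$ci$raw - object$ci$bounds["min"]) /
                           diff(object$ci$bounds[c("min", "max")]), 0), 1)
  } else {
    candidates <- newdata$candidates
    comps <- assemble_components(candidates, object$strengths,
                                 object$contingencies, object$basis,
                                 object$correlation_direction)
    presc_new <- if (!is.null(newdata$prescriptions)) newdata$prescriptions
                 else object$prescriptions
    feats <- scenario_features("base_ci_bayes", candidates, newdata$registry,
                               comps, presc_new, object$drug_vocab)
    # index for held-out records reuses the training loadings and bounds
    comp_cols <- names(object$ci$loadings)
    feats$ic_pca <- predict(object$ci, comps[, comp_cols])
    cand_meta <- data.frame(record_id = candidates$record_id,
                            drug = as.character(candidates$drug),
                            symptom = as.character(candidates$symptom),
                            stringsAsFactors = FALSE)
    ci_vals <- feats$ic_pca
  }
  feats$.label <- NULL
  probs <- stats::predict(object$model$forest, data = feats,
                          num.threads = 1L)$predictions
  if (type == "prob") return(probs)
  if (type == "bpa") {
    return(lapply(seq_len(nrow(probs)), function(i) {
      bpa_from_probs(probs[i, object$model$classes], ci_vals[i], object$frame)
    }))
  }
  run_fusion(probs, ci_vals, cand_meta, object$leaflet_kb, object$frame,
             kb_hypothesis = if ("ADR" %in% unclass(object$frame)) "ADR"
                             else unclass(object$frame)[1L])
}

#' Histogram of the normalized credibility index
#'
#' @param x A fitted `dep_dst`.
#' @param ... Passed to [graphics::hist()].
#' @return Invisibly, the hist object. The dashed line marks the
#'   first-quartile low-credibility cutoff.
#' @export
plot.dep_dst <- function(x, ...) {
  h <- graphics::hist(x$ci$normalized, breaks = 20,
                      main = "Credibility index",
                      xlab = "normalized IC-PCA", ...)
  graphics::abline(v = x$cutoff, lty = 2)
  invisible(h)
}
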