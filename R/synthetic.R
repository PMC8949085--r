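# Synthetic EHR generator: a generating world with known drug-caused
# reactions (ADR), disease-caused symptoms (confounding by indication),
# polypharmacy, background noise, and drug-induced lab-marker trends, with
# ground-truth labels for recovery experiments.

MARKERS <- data.frame(
  marker = c("creatinine", "glucose", "urea", "platelets"),
  baseline = c(0.9, 90, 30, 250),
  sd = c(0.08, 8, 4, 20),
  # drug-induced direction a marker typically moves when it signals toxicity
  direction = c("increasing", "increasing", "increasing", "decreasing"),
  stringsAsFactors = FALSE)

#' Parameters of the synthetic generating world
#'
#' Defaults describe a mid-size oncology-like cohort: 1000 patients over one
#' year, 5 diseases, 20 drugs with polypharmacy (mean 3, max 6 concurrent
#' drugs), 10 symptoms; 10% of drug-symptom pairs are true ADRs and 20% of
#' disease-symptom pairs are confounded (the disease itself causes the
#' symptom), with per-encounter emission probabilities drawn around
#' `adr_prob`/`confound_prob`; half of the true ADR mechanisms also manifest
#' as a lab-marker trend; monthly lab sampling.
#'
#' @param n_patients,n_diseases,n_drugs,n_symptoms Entity counts (>= 1).
#' @param adr_rate Fraction of (drug, symptom) pairs that are true ADRs.
#' @param confound_rate Fraction of (disease, symptom) pairs where the
#'   disease causes the symptom.
#' @param adr_prob,confound_prob Center of the per-encounter emission
#'   probability for true pairs (each pair draws uniformly within 0.15 of
#'   the center, clipped to (0, 1)).
#' @param poly_mean,poly_max Mean and cap of the per-patient concurrent drug
#'   count (1 + truncated Poisson).
#' @param trend_fraction Fraction of true ADR pairs realized through a
#'   marker trend.
#' @param noise_symptom_prob Background probability that a symptom appears
#'   with no cause.
#' @param leaflet_coverage Fraction of true ADR pairs documented in the
#'   emitted leaflet knowledge base.
#' @param seed Mandatory integer seed; the whole world is deterministic in
#'   it (base R Mersenne-Twister).
#' @return A validated `world_params` list.
#' @export
world_params <- function(n_patients = 1000, n_diseases = 5, n_drugs = 20,
                         n_symptoms = 10, adr_rate = 0.1, confound_rate = 0.2,
                         adr_prob = 0.4, confound_prob = 0.4,
                         poly_mean = 3, poly_max = 6, trend_fraction = 0.5,
                         noise_symptom_prob = 0.02, leaflet_coverage = 0.7,
                         seed) {
  if (missing(seed)) stop(depdst_error("seed is mandatory", "seed"))
  p <- list(n_patients = n_patients, n_diseases = n_diseases,
            n_drugs = n_drugs, n_symptoms = n_symptoms, adr_rate = adr_rate,
            confound_rate = confound_rate, adr_prob = adr_prob,
            confound_prob = confound_prob, poly_mean = poly_mean,
            poly_max = poly_max, trend_fraction = trend_fraction,
            noise_symptom_prob = noise_symptom_prob,
            leaflet_coverage = leaflet_coverage, seed = as.integer(seed))
  counts <- c("n_patients", "n_diseases", "n_drugs", "n_symptoms")
  for (nm in counts) {
    if (!is.numeric(p[[nm]]) || p[[nm]] < 1) {
      stop(depdst_error(sprintf("%s must be >= 1", nm), "params"))
    }
  }
  probs <- c("adr_rate", "confound_rate", "adr_prob", "confound_prob",
             "trend_fraction", "noise_symptom_prob", "leaflet_coverage")
  for (nm in probs) {
    if (!is.numeric(p[[nm]]) || p[[nm]] < 0 || p[[nm]] > 1) {
      stop(depdst_error(sprintf("%s must lie in [0, 1]", nm), "params"))
    }
  }
  if (p$adr_rate == 0 && p$confound_rate == 0 && p$noise_symptom_prob == 0) {
    stop(depdst_error("no signal to generate: adr_rate, confound_rate and noise all zero",
                      "no_signal"))
  }
  if (p$poly_max < 1 || p$poly_mean < 1) {
    stop(depdst_error("polypharmacy mean and max must be >= 1", "params"))
  }
  structure(p, class = "world_params")
}

draw_pair_prob <- function(n, center) {
  lo <- max(center - 0.15, 0.01)
  hi <- min(center + 0.15, 0.99)
  stats::runif(n, lo, hi)
}

#' Generate the synthetic world (ground-truth causal structure)
#'
#' Samples the set of true ADR (drug, symptom) edges and confounded
#' (disease, symptom) edges exactly (without replacement, `round(rate * n)`
#' pairs each), their per-encounter emission probabilities, the marker
#' effects realizing a fraction of the ADRs as lab trends, the
#' marker-to-symptom knowledge map, and the leaflet knowledge base covering
#' a subset of the true ADRs.
#'
#' @param params A [world_params()] object.
#' @return An object of class `synthetic_world`: drug/disease emission
#'   matrices, `true_adr_pairs`, `confound_pairs`, `marker_effects`,
#'   `marker_symptom_map`, `leaflet_kb`, entity vocabularies, `params`.
#' @export
generate_world <- function(params) {
  stopifnot(inherits(params, "world_params"))
  with_seed(params$seed, {
    drugs <- sprintf("DRG%02d", seq_len(params$n_drugs))
    symptoms <- sprintf("SYM%02d", seq_len(params$n_symptoms))
    diseases <- sprintf("DIS%02d", seq_len(params$n_diseases))
    n_ds <- params$n_drugs * params$n_symptoms
    n_cs <- params$n_diseases * params$n_symptoms
    n_adr <- round(params$adr_rate * n_ds)
    n_conf <- round(params$confound_rate * n_cs)
    adr_idx <- if (n_adr > 0) sample.int(n_ds, n_adr) else integer(0)
    conf_idx <- if (n_conf > 0) sample.int(n_cs, n_conf) else integer(0)
    drug_cpt <- matrix(0, params$n_drugs, params$n_symptoms,
                       dimnames = list(drugs, symptoms))
    drug_cpt[adr_idx] <- draw_pair_prob(n_adr, params$adr_prob)
    dis_cpt <- matrix(0, params$n_diseases, params$n_symptoms,
                      dimnames = list(diseases, symptoms))
    dis_cpt[conf_idx] <- draw_pair_prob(n_conf, params$confound_prob)
    adr_pairs <- data.frame(
      drug = drugs[(adr_idx - 1L) %% params$n_drugs + 1L],
      symptom = symptoms[(adr_idx - 1L) %/% params$n_drugs + 1L],
      stringsAsFactors = FALSE)
    conf_pairs <- data.frame(
      disease = diseases[(conf_idx - 1L) %% params$n_diseases + 1L],
      symptom = symptoms[(conf_idx - 1L) %/% params$n_diseases + 1L],
      stringsAsFactors = FALSE)
    # marker effects: a fraction of true ADR mechanisms move a lab marker
    n_trend <- round(params$trend_fraction * n_adr)
    marker_effects <- data.frame(drug = character(0), symptom = character(0),
                                 marker = character(0), direction = character(0),
                                 slope = numeric(0), stringsAsFactors = FALSE)
    if (n_trend > 0) {
      rows <- sample.int(n_adr, n_trend)
      mk <- MARKERS[((seq_len(n_trend) - 1L) %% nrow(MARKERS)) + 1L, ]
      sgn <- ifelse(mk$direction == "increasing", 1, -1)
      # slope sized so a 360-day exposure moves the marker ~8 noise sds
      marker_effects <- data.frame(
        drug = adr_pairs$drug[rows], symptom = adr_pairs$symptom[rows],
        marker = mk$marker, direction = mk$direction,
        slope = sgn * 8 * mk$sd / 360, stringsAsFactors = FALSE)
    }
    marker_symptom_map <- unique(marker_effects[, c("marker", "direction",
                                                    "symptom")])
    n_kb <- round(params$leaflet_coverage * n_adr)
    kb_rows <- if (n_kb > 0) sample.int(n_adr, n_kb) else integer(0)
    leaflet_kb <- data.frame(
      drug = adr_pairs$drug[kb_rows], reaction = adr_pairs$symptom[kb_rows],
      credibility = stats::runif(n_kb, 0.6, 0.95), stringsAsFactors = FALSE)
    structure(list(drugs = drugs, symptoms = symptoms, diseases = diseases,
                   drug_symptom_cpt = drug_cpt, disease_symptom_cpt = dis_cpt,
                   true_adr_pairs = adr_pairs, confound_pairs = conf_pairs,
                   marker_effects = marker_effects,
                   marker_symptom_map = marker_symptom_map,
                   leaflet_kb = leaflet_kb, params = params),
              class = "synthetic_world")
  })
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat("Synthetic EHR world:", x$params$n_patients, "patients,",
      length(x$diseases), "diseases,", length(x$drugs), "drugs,",
      length(x$symptoms), "symptoms\n")
  cat("  true ADR pairs:", nrow(x$true_adr_pairs),
      "| confounded disease-symptom pairs:", nrow(x$confound_pairs),
      "| marker-trend ADRs:", nrow(x$marker_effects), "\n")
  invisible(x)
}

#' Generate candidate ADR records, prescriptions and patient registry
#'
#' Per patient: one disease, a truncated-Poisson number of concurrently
#' prescribed drugs with exposure windows inside a one-year observation
#' period, and symptom emissions from three mechanisms -- the disease's
#' confounded symptoms (truth `DISEASE`), each drug's true ADR symptoms
#' (truth `ADR`), and background noise (truth `OTHER`). Disease- and
#' noise-caused symptoms are attributed to a random concurrent drug, which
#' is exactly the confounding the analysis must see through. Truth labels
#' are returned separately so the pipeline can run blind.
#'
#' @param world A `synthetic_world`.
#' @param params Its [world_params()] (defaults to `world$params`).
#' @return List with `candidates` (record_id, patient_id, disease, drug,
#'   symptom, onset_date, n_drugs), `truth` (record_id, label),
#'   `prescriptions` (patient_id, drug, start_date, end_date), `registry`
#'   (patient_id, age, sex, disease).
#' @export
generate_records <- function(world, params = world$params) {
  stopifnot(inherits(world, "synthetic_world"))
  origin <- as.Date("2019-01-01")
  with_seed(child_seed(params$seed, 2L), {
    n <- params$n_patients
    pid <- sprintf("P%05d", seq_len(n))
    disease <- sample(world$diseases, n, replace = TRUE)
    age <- pmin(pmax(round(stats::rnorm(n, 60, 12)), 18), 95)
    sex <- sample(c("F", "M"), n, replace = TRUE)
    registry <- data.frame(patient_id = pid, age = age, sex = sex,
                           disease = disease, stringsAsFactors = FALSE)
    presc <- list(); cand <- list(); truth <- list()
    rid <- 0L
    for (i in seq_len(n)) {
      k <- min(1L + stats::rpois(1L, params$poly_mean - 1), params$poly_max,
               length(world$drugs))
      my_drugs <- sample(world$drugs, k)
      start <- origin + round(stats::runif(k, 0, 120))
      end <- start + round(stats::runif(k, 90, 270))
      presc[[i]] <- data.frame(patient_id = pid[i], drug = my_drugs,
                               start_date = start, end_date = end,
                               stringsAsFactors = FALSE)
      emit <- function(drug, symptom, label, window_start, window_end) {
        rid <<- rid + 1L
        onset <- window_start +
          round(stats::runif(1L, 0, as.numeric(window_end - window_start)))
        cand[[length(cand) + 1L]] <<- data.frame(
          record_id = sprintf("R%06d", rid), patient_id = pid[i],
          disease = disease[i], drug = drug, symptom = symptom,
          onset_date = onset, n_drugs = k, stringsAsFactors = FALSE)
        truth[[length(truth) + 1L]] <<- data.frame(
          record_id = sprintf("R%06d", rid), label = label,
          stringsAsFactors = FALSE)
      }
      # drug-caused reactions
      for (j in seq_len(k)) {
        pr <- world$drug_symptom_cpt[my_drugs[j], ]
        hits <- which(stats::runif(length(pr)) < pr)
        for (s in hits) {
          emit(my_drugs[j], world$symptoms[s], "ADR", start[j], end[j])
        }
      }
      # disease-caused symptoms, attributed to a random concurrent drug
      prd <- world$disease_symptom_cpt[disease[i], ]
      hits <- which(stats::runif(length(prd)) < prd)
      for (s in hits) {
        j <- if (k > 1L) sample.int(k, 1L) else 1L
        emit(my_drugs[j], world$symptoms[s], "DISEASE", start[j], end[j])
      }
      # background noise
      hits <- which(stats::runif(length(world$symptoms)) < params$noise_symptom_prob)
      for (s in hits) {
        j <- if (k > 1L) sample.int(k, 1L) else 1L
        emit(my_drugs[j], world$symptoms[s], "OTHER", start[j], end[j])
      }
    }
    candidates <- do.call(rbind, cand)
    if (is.null(candidates)) {
      candidates <- data.frame(record_id = character(0), patient_id = character(0),
                               disease = character(0), drug = character(0),
                               symptom = character(0),
                               onset_date = as.Date(character(0)),
                               n_drugs = integer(0))
    }
    truth_df <- do.call(rbind, truth)
    if (is.null(truth_df)) {
      truth_df <- data.frame(record_id = character(0), label = character(0))
    }
    list(candidates = candidates, truth = truth_df,
         prescriptions = do.call(rbind, presc), registry = registry)
  })
}

#' Generate lab-marker time series
#'
#' Every patient gets a monthly (jittered) series per marker over one year:
#' baseline plus Gaussian noise, and -- when the patient is exposed to a drug
#' with a marker effect -- the effect slope accumulating inside the exposure
#' window. Patients without an exposed effect are statistically flat.
#'
#' @param world A `synthetic_world`.
#' @param records Output of [generate_records()].
#' @param params Its [world_params()] (defaults to `world$params`).
#' @return Labs data frame: patient_id, marker, date, value.
#' @export
generate_marker_series <- function(world, records, params = world$params) {
  stopifnot(inherits(world, "synthetic_world"))
  origin <- as.Date("2019-01-01")
  with_seed(child_seed(params$seed, 3L), {
    presc <- records$prescriptions
    reg <- records$registry
    out <- vector("list", nrow(reg) * nrow(MARKERS))
    z <- 0L
    for (i in seq_len(nrow(reg))) {
      pid <- reg$patient_id[i]
      my <- presc[presc$patient_id == pid, , drop = FALSE]
      eff <- merge(my, world$marker_effects, by = "drug")
      days <- 30 * (0:11) + round(stats::runif(12, -5, 5))
      days <- sort(unique(pmax(days, 0)))
      dates <- origin + days
      for (m in seq_len(nrow(MARKERS))) {
        vals <- MARKERS$baseline[m] + stats::rnorm(length(days), 0, MARKERS$sd[m])
        if (nrow(eff) > 0L) {
          em <- eff[eff$marker == MARKERS$marker[m], , drop = FALSE]
          for (r in seq_len(nrow(em))) {
            inside <- dates >= em$start_date[r] & dates <= em$end_date[r]
            vals[inside] <- vals[inside] +
              em$slope[r] * as.numeric(dates[inside] - em$start_date[r])
            after <- dates > em$end_date[r]
            vals[after] <- vals[after] +
              em$slope[r] * as.numeric(em$end_date[r] - em$start_date[r])
          }
        }
        z <- z + 1L
        out[[z]] <- data.frame(patient_id = pid, marker = MARKERS$marker[m],
                               date = dates, value = vals,
                               stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, out[seq_len(z)])
  })
}

#' Simulate a complete synthetic EHR
#'
#' Convenience wrapper: world, records, labs and leaflet knowledge base in
#' one call.
#'
#' @param params A [world_params()] object.
#' @return List with `world`, `candidates`, `truth`, `prescriptions`,
#'   `registry`, `labs`, `leaflet_kb`, `marker_symptom_map`.
#' @export
simulate_ehr <- function(params) {
  world <- generate_world(params)
  rec <- generate_records(world, params)
  labs <- generate_marker_series(world, rec, params)
  c(list(world = world), rec,
    list(labs = labs, leaflet_kb = world$leaflet_kb,
         marker_symptom_map = world$marker_symptom_map))
}

#' Export a synthetic EHR to plain-text files
#'
#' Writes registry, prescriptions, candidates, labs, leaflet-KB and
#' marker-symptom-map CSVs plus a ground-truth JSON (record labels and the
#' generating parameters, kept separate so the analytic pipeline can run
#' blind). Files round-trip losslessly through [read_ehr()].
#'
#' @param sim Output of [simulate_ehr()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
export_ehr <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (file.access(dir, 2) != 0) {
    stop(depdst_error(sprintf("directory '%s' is not writable", dir), "io"))
  }
  wcsv <- function(df, name) {
    for (cl in names(df)) if (inherits(df[[cl]], "Date")) {
      df[[cl]] <- format(df[[cl]], "%Y-%m-%d")
    }
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    p
  }
  files <- c(
    wcsv(sim$registry, "registry.csv"),
    wcsv(sim$prescriptions, "prescriptions.csv"),
    wcsv(sim$candidates, "candidates.csv"),
    wcsv(sim$labs, "labs.csv"),
    wcsv(sim$leaflet_kb, "leaflet_kb.csv"),
    wcsv(sim$marker_symptom_map, "marker_symptom_map.csv"))
  gt <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(
    list(labels = stats::setNames(as.list(sim$truth$label), sim$truth$record_id),
         params = unclass(sim$world$params)),
    gt, auto_unbox = TRUE, digits = NA)
  invisible(c(files, gt))
}

#' Read a synthetic EHR exported by [export_ehr()]
#'
#' @param dir Directory containing the CSV/JSON files.
#' @return List with the same tables (dates parsed back to `Date`), plus
#'   `truth` and `params` from the ground-truth JSON when present.
#' @export
read_ehr <- function(dir) {
  rcsv <- function(name, datecols = character(0)) {
    p <- file.path(dir, name)
    if (!file.exists(p)) return(NULL)
    df <- utils::read.csv(p, stringsAsFactors = FALSE)
    for (cl in intersect(datecols, names(df))) df[[cl]] <- as.Date(df[[cl]])
    df
  }
  out <- list(
    registry = rcsv("registry.csv"),
    prescriptions = rcsv("prescriptions.csv", c("start_date", "end_date")),
    candidates = rcsv("candidates.csv", "onset_date"),
    labs = rcsv("labs.csv", "date"),
    leaflet_kb = rcsv("leaflet_kb.csv"),
    marker_symptom_map = rcsv("marker_symptom_map.csv"))
  gt <- file.path(dir, "ground_truth.json")
  if (file.exists(gt)) {
    obj <- jsonlite::fromJSON(gt)
    out$truth <- data.frame(record_id = names(obj$labels),
                            label = unlist(obj$labels),
                            stringsAsFactors = FALSE, row.names = NULL)
    out$params <- obj$params
  }
  out
}
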