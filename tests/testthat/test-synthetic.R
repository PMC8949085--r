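test_that("world generation is exact in pair counts and deterministic per seed", {
  p <- world_params(n_patients = 50, adr_rate = 0.1, seed = 61)
  w <- generate_world(p)
  expect_equal(nrow(w$true_adr_pairs), 20)  # 0.1 * 20 drugs * 10 symptoms
  expect_false(anyDuplicated(paste(w$true_adr_pairs$drug,
                                   w$true_adr_pairs$symptom)) > 0)
  w2 <- generate_world(p)
  expect_identical(w, w2)
  p0 <- world_params(n_patients = 50, adr_rate = 0, seed = 61)
  expect_equal(nrow(generate_world(p0)$true_adr_pairs), 0)
  expect_error(world_params(n_patients = 50, adr_rate = 0, confound_rate = 0,
                            noise_symptom_prob = 0, seed = 1),
               class = "depdst_error_no_signal")
  expect_error(world_params(n_patients = 50), class = "depdst_error_seed")
})

test_that("record labels follow the generating mechanisms", {
  # no disease emission, no noise: everything is a true ADR
  p <- world_params(n_patients = 60, confound_rate = 0,
                    noise_symptom_prob = 0, seed = 62)
  rec <- generate_records(generate_world(p))
  expect_true(all(rec$truth$label == "ADR"))
  # no drug emission, no noise: everything is disease-caused
  p2 <- world_params(n_patients = 60, adr_rate = 0, noise_symptom_prob = 0,
                     seed = 63)
  rec2 <- generate_records(generate_world(p2))
  expect_true(all(rec2$truth$label == "DISEASE"))
  # determinism
  p3 <- world_params(n_patients = 40, seed = 64)
  w3 <- generate_world(p3)
  expect_identical(generate_records(w3), generate_records(w3))
})

test_that("label mix matches the analytic expectation from the emission model", {
  p <- world_params(n_patients = 1000, seed = 65)
  w <- generate_world(p)
  rec <- generate_records(w)
  # conditional on the realized prescriptions and diseases, expected counts
  # are sums of the emission probabilities
  e_adr <- sum(w$drug_symptom_cpt[rec$prescriptions$drug, ])
  e_dis <- sum(w$disease_symptom_cpt[rec$registry$disease, ])
  e_oth <- nrow(rec$registry) * length(w$symptoms) * p$noise_symptom_prob
  expected <- c(ADR = e_adr, DISEASE = e_dis, OTHER = e_oth)
  observed <- table(rec$truth$label)[names(expected)]
  tot_e <- sum(expected); tot_o <- sum(observed)
  for (lab in names(expected)) {
    expect_lt(abs(observed[lab] / tot_o - expected[lab] / tot_e), 0.05)
  }
})

test_that("emission frequencies converge to the world CPT", {
  p <- world_params(n_patients = 5000, seed = 66)
  w <- generate_world(p)
  rec <- generate_records(w)
  pair <- w$true_adr_pairs[1, ]
  exposed <- rec$prescriptions$patient_id[rec$prescriptions$drug == pair$drug]
  n_exp <- length(exposed)
  adr_ids <- rec$truth$record_id[rec$truth$label == "ADR"]
  hits <- sum(rec$candidates$record_id %in% adr_ids &
                rec$candidates$drug == pair$drug &
                rec$candidates$symptom == pair$symptom)
  p_true <- w$drug_symptom_cpt[pair$drug, pair$symptom]
  se <- sqrt(p_true * (1 - p_true) / n_exp)
  expect_lt(abs(hits / n_exp - p_true), 3 * se)
})

test_that("marker series carry drug-induced trends only for exposed patients", {
  p <- world_params(n_patients = 250, trend_fraction = 1, seed = 67)
  sim <- simulate_ehr(p)
  eff <- sim$world$marker_effects[1, ]
  exposed <- unique(sim$prescriptions$patient_id[sim$prescriptions$drug == eff$drug])
  # control patients must avoid every drug that moves this marker
  marker_drugs <- sim$world$marker_effects$drug[
    sim$world$marker_effects$marker == eff$marker]
  touched <- unique(sim$prescriptions$patient_id[
    sim$prescriptions$drug %in% marker_drugs])
  trends <- fit_marker_trends(sim$labs[sim$labs$marker == eff$marker, ])
  hit <- trends[trends$patient_id %in% exposed, ]
  miss <- trends[!trends$patient_id %in% touched, ]
  # power on exposed series (slope sized at ~8 noise sd over a full window)
  expect_gte(mean(hit$direction == eff$direction), 0.85)
  # unexposed series flat: rejections near the nominal rate
  expect_lte(mean(miss$direction != "none"), 0.10)
})

test_that("the leaflet KB covers the configured fraction of true ADRs", {
  p <- world_params(n_patients = 30, leaflet_coverage = 0.7, seed = 68)
  w <- generate_world(p)
  expect_equal(nrow(w$leaflet_kb), round(0.7 * nrow(w$true_adr_pairs)))
  kb_pairs <- paste(w$leaflet_kb$drug, w$leaflet_kb$reaction)
  adr_pairs <- paste(w$true_adr_pairs$drug, w$true_adr_pairs$symptom)
  expect_true(all(kb_pairs %in% adr_pairs))
  expect_true(all(w$leaflet_kb$credibility >= 0 & w$leaflet_kb$credibility <= 1))
})

test_that("EHR export and read round-trip losslessly", {
  sim <- tiny_sim(seed = 69, n_patients = 40)
  dir <- withr::local_tempdir()
  files <- export_ehr(sim, dir)
  expect_true(all(file.exists(files)))
  back <- read_ehr(dir)
  expect_equal(back$candidates, sim$candidates)
  expect_equal(back$prescriptions, sim$prescriptions)
  expect_equal(back$registry, sim$registry)
  expect_equal(back$labs$value, sim$labs$value)
  expect_identical(back$truth$label[match(sim$truth$record_id, back$truth$record_id)],
                   sim$truth$label)
  expect_equal(back$params$n_patients, 40)
})
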