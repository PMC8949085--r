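test_that("CPT estimation uses Laplace-smoothed frequencies and rows sum to 1", {
  # 100 records, 51 with the reaction: smoothed (51+1)/(100+2)
  d <- data.frame(drug = rep("Dactomicin", 100),
                  reaction = rep(c("yes", "no"), c(51, 49)))
  d$drug[1:50] <- "Morphine"  # second level so drug varies
  net <- fit_cpts(d, data.frame(from = "drug", to = "reaction"))
  n_dact <- sum(d$drug == "Dactomicin")
  n_yes <- sum(d$drug == "Dactomicin" & d$reaction == "yes")
  expect_equal(net$cpts$reaction$prob["yes", "Dactomicin"],
               (n_yes + 1) / (n_dact + 2))
  for (v in names(net$cpts)) {
    expect_equal(unname(colSums(net$cpts[[v]]$prob)),
                 rep(1, ncol(net$cpts[[v]]$prob)), tolerance = 1e-9)
  }
  # deterministic child converges to (n+1)/(n+2)
  d2 <- data.frame(disease = rep(c("d1", "d2"), each = 200),
                   symptom = rep(c("yes", "no"), each = 200))
  net2 <- fit_cpts(d2, data.frame(from = "disease", to = "symptom"))
  expect_equal(net2$cpts$symptom$prob["yes", "d1"], 201 / 202)
  # empty parent set: marginal distribution
  expect_equal(nrow(net2$cpts$disease$prob), 2)
  expect_equal(sum(net2$cpts$disease$prob), 1, tolerance = 1e-9)
  expect_error(fit_cpts(d2, data.frame(from = c("disease", "symptom"),
                                       to = c("symptom", "disease"))),
               class = "depdst_error_cyclic_dag")
  expect_error(fit_cpts(d2, data.frame(from = "ghost", to = "symptom")),
               class = "depdst_error_unseen_node")
})

test_that("joint probability is the chain-rule product", {
  # two-node net with forced CPTs (no smoothing noise): check via direct product
  net <- fit_cpts(data.frame(A = c("0", "1"), B = c("0", "1")),
                  data.frame(from = "A", to = "B"))
  net$cpts$A$prob[, 1] <- c(0.5, 0.5)
  net$cpts$B$prob[, "0"] <- c(0.9, 0.1)
  net$cpts$B$prob[, "1"] <- c(0.49, 0.51)
  expect_equal(joint_probability(net, list(A = "1", B = "1")), 0.5 * 0.51)
  expect_equal(joint_probability(net, list(A = "0", B = "1")), 0.5 * 0.1)
  net$cpts$B$prob[, "0"] <- c(1, 0)
  expect_equal(joint_probability(net, list(A = "0", B = "1")), 0)
  expect_error(joint_probability(net, list(A = "1")),
               class = "depdst_error_missing_node")
  expect_error(joint_probability(net, list(A = "1", B = "2")),
               class = "depdst_error_unknown_state")
})

test_that("conditional queries agree with full-joint enumeration", {
  set.seed(7)
  for (rep in 1:5) {
    n <- 400
    disease <- sample(c("yes", "no"), n, TRUE)
    drug <- sample(c("yes", "no"), n, TRUE)
    symptom <- ifelse(runif(n) < 0.2 + 0.4 * (disease == "yes") +
                        0.3 * (drug == "yes"), "yes", "no")
    d <- data.frame(disease, drug, symptom)
    net <- fit_cpts(d, data.frame(from = c("disease", "drug"),
                                  to = c("symptom", "symptom")))
    joint <- oracle_joint_table(net)
    # marginal with no evidence
    q0 <- conditional_query(net, "symptom")
    m0 <- tapply(joint$p, joint$symptom, sum)
    expect_equal(as.numeric(q0[names(m0)]), as.numeric(m0 / sum(m0)),
                 tolerance = 1e-12)
    # conditioned on both parents
    q1 <- conditional_query(net, "symptom",
                            list(disease = "yes", drug = "no"))
    sel <- joint$disease == "yes" & joint$drug == "no"
    m1 <- tapply(joint$p[sel], joint$symptom[sel], sum)
    expect_equal(as.numeric(q1[names(m1)]), as.numeric(m1 / sum(m1)),
                 tolerance = 1e-12)
  }
  # independence in the DAG: query equals marginal
  d <- data.frame(a = rep(c("x", "y"), 50), b = rep(c("u", "v"), each = 50))
  net <- fit_cpts(d, NULL)
  expect_equal(conditional_query(net, "a", list(b = "u")),
               conditional_query(net, "a"), tolerance = 1e-12)
})

test_that("structure MCMC is seed-deterministic, acyclic, and finds dependence", {
  set.seed(1)
  n <- 2000
  x <- sample(c("a", "b"), n, TRUE)
  y <- ifelse(runif(n) < ifelse(x == "a", 0.85, 0.15), "y1", "y0")
  w <- sample(c("u", "v"), n, TRUE)   # independent of everything
  d <- data.frame(x = x, y = y, w = w)
  s <- sample_structures_mcmc(d, n_iter = 1500, burn_in = 300, seed = 99)
  expect_length(s, 1200)
  s2 <- sample_structures_mcmc(d, n_iter = 1500, burn_in = 300, seed = 99)
  expect_identical(s, s2)
  # every sampled graph is a DAG
  for (g in s[seq(1, length(s), by = 97)]) {
    edges <- as.data.frame(g, stringsAsFactors = FALSE)
    expect_no_error(depdst:::topo_order(names(d), edges))
  }
  st <- arc_strength(s, nodes = names(d), undirected = TRUE)
  expect_gt(dep_causal_strength("x", "y", st), 0.95)
  expect_lt(dep_causal_strength("x", "w", st), 0.20)
  expect_lt(dep_causal_strength("y", "w", st), 0.20)
  expect_error(sample_structures_mcmc(d, n_iter = 100, burn_in = 100, seed = 1),
               class = "depdst_error_bad_iterations")
  d$konst <- "same"
  expect_error(sample_structures_mcmc(d, 100, 10, 1),
               class = "depdst_error_constant_column")
  expect_error(sample_structures_mcmc(d, 100, 10, 1), "konst")
})

test_that("arc strength is an exact sample frequency with optional pooling", {
  e1 <- matrix(c("a", "b"), 1, 2, dimnames = list(NULL, c("from", "to")))
  e0 <- matrix(character(0), 0, 2, dimnames = list(NULL, c("from", "to")))
  samples <- c(rep(list(e1), 250), rep(list(e0), 750))
  st <- arc_strength(samples, nodes = c("a", "b", "c"))
  expect_equal(dep_causal_strength("a", "b", st), 0.25)
  expect_equal(dep_causal_strength("b", "a", st), 0)
  expect_equal(dep_causal_strength("a", "c", st), 0)
  expect_equal(st$entries$strength * st$n_samples,
               round(st$entries$strength * st$n_samples), tolerance = 1e-9)
  # pooling counts either orientation
  erev <- matrix(c("b", "a"), 1, 2, dimnames = list(NULL, c("from", "to")))
  stu <- arc_strength(c(rep(list(e1), 250), rep(list(erev), 250),
                        rep(list(e0), 500)),
                      nodes = c("a", "b"), undirected = TRUE)
  expect_equal(dep_causal_strength("a", "b", stu), 0.5)
  expect_equal(dep_causal_strength("b", "a", stu), 0.5)
  expect_error(arc_strength(list(), nodes = "a"),
               class = "depdst_error_empty_samples")
  expect_error(dep_causal_strength("zz", "b", st),
               class = "depdst_error_unknown_node")
})

test_that("the bundled drug-reaction and disease-symptom CPT fixtures validate", {
  for (f in c("example_drug_reaction_cpt.csv", "example_disease_symptom_cpt.csv")) {
    tab <- cpt_import(system.file("extdata", f, package = "depdst"))
    expect_gt(nrow(tab), 0)
    # every conditional row is a proper two-point distribution
    key <- paste(tab$node, tab$parent_state)
    sums <- tapply(tab$probability, key, sum)
    expect_true(all(abs(sums - 1) < 1e-9))
  }
  # the classic 49/51 edema row
  tab <- cpt_import(system.file("extdata", "example_drug_reaction_cpt.csv",
                                package = "depdst"))
  expect_equal(tab$probability[tab$parent_state == "Dactomicin" &
                                 tab$node == "edema" & tab$state == "yes"], 0.51)
})

test_that("CPT CSV interchange mirrors the long drug/reaction layout", {
  d <- data.frame(drug = rep(c("Dactomicin", "Morphine"), each = 50),
                  reaction = rep(c("yes", "no", "yes", "no"), c(26, 24, 10, 40)))
  net <- fit_cpts(d, data.frame(from = "drug", to = "reaction"))
  path <- withr::local_tempfile(fileext = ".csv")
  cpt_export(net, path)
  back <- cpt_import(path)
  expect_setequal(names(back),
                  c("parent_node", "parent_state", "node", "state", "probability"))
  row <- back[back$node == "reaction" & back$parent_state == "Dactomicin" &
                back$state == "yes", ]
  expect_equal(row$probability, net$cpts$reaction$prob["yes", "Dactomicin"])
  bad <- back
  bad$probability[1] <- bad$probability[1] + 0.5
  expect_error(cpt_import(bad), class = "depdst_error_cpt_rowsum")
})
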