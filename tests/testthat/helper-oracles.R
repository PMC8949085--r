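# Independent oracles and random fixture builders used across the suite.

# all non-empty subsets of a frame, as character vectors
powerset_nonempty <- function(frame) {
  n <- length(frame)
  out <- list()
  for (mask in seq_len(2^n - 1L)) {
    out[[mask]] <- frame[as.logical(bitwAnd(mask, 2^(seq_len(n) - 1L)))]
  }
  out
}

# brute-force orthogonal sum over the full powerset-pair product; masses are
# named vectors keyed by "a|b" canonical keys (frame order)
oracle_combine <- function(m1, m2, frame) {
  key <- function(members) paste(frame[sort(match(members, frame))], collapse = "|")
  subsets <- powerset_nonempty(frame)
  acc <- numeric(0)
  conflict <- 0
  for (A in subsets) {
    for (B in subsets) {
      w <- unname(m1[key(A)]) * unname(m2[key(B)])
      if (is.na(w) || w == 0) next
      C <- intersect(A, B)
      if (length(C) == 0L) conflict <- conflict + w
      else {
        k <- key(C)
        acc[k] <- (if (is.na(acc[k])) 0 else acc[k]) + w
      }
    }
  }
  list(masses = acc / (1 - conflict), conflict = conflict)
}

# random valid mass over a frame: a few focal subsets, normalized exp draws
random_mass <- function(frame, max_focal = 4L) {
  subsets <- powerset_nonempty(frame)
  k <- sample(seq_len(min(max_focal, length(subsets))), 1L)
  picks <- sample(seq_along(subsets), k)
  w <- stats::rexp(k) + 1e-3
  w <- w / sum(w)
  keys <- vapply(picks, function(i) {
    paste(frame[sort(match(subsets[[i]], frame))], collapse = "|")
  }, character(1))
  stats::setNames(w, keys)
}

# chain-rule joint table computed directly in the test, independent of the
# package's inference code path
oracle_joint_table <- function(net) {
  grid <- expand.grid(net$nodes, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  grid$p <- vapply(seq_len(nrow(grid)), function(i) {
    a <- as.list(grid[i, names(net$nodes), drop = FALSE])
    p <- 1
    for (v in names(net$nodes)) {
      cpt <- net$cpts[[v]]
      row <- match(a[[v]], cpt$states)
      col <- if (length(cpt$parents) == 0L) 1L else {
        match(paste(unlist(a[cpt$parents]), collapse = "\x1f"),
              colnames(cpt$prob))
      }
      p <- p * cpt$prob[row, col]
    }
    p
  }, numeric(1))
  grid
}

# small labelled world for pipeline tests
tiny_sim <- function(seed = 301, n_patients = 150) {
  simulate_ehr(world_params(n_patients = n_patients, seed = seed))
}

labels_for <- function(sim) {
  sim$truth$label[match(sim$candidates$record_id, sim$truth$record_id)]
}
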