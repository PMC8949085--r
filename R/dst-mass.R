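# Dempster-Shafer core: frames of discernment, mass functions (BPAs),
# the orthogonal sum, belief/plausibility, and credibility discounting.

#' Create a frame of discernment
#'
#' A frame of discernment is the exhaustive, mutually exclusive set of
#' hypotheses over which evidence is expressed. Subsets of the frame are keyed
#' canonically (members in frame order joined by `"|"`), so set equality of
#' focal elements is exact.
#'
#' @param hypotheses Character vector of distinct hypothesis labels. Labels may
#'   not contain the reserved characters `"|"` (subset separator) or be `"*"`
#'   (which denotes the whole frame in the JSON dialect).
#' @return An object of class `dst_frame`: the label vector with its order
#'   fixed.
#' @examples
#' dst_frame(c("ADR", "DIS", "OTH"))
#' @export
dst_frame <- function(hypotheses) {
  hypotheses <- as.character(hypotheses)
  if (length(hypotheses) == 0L) {
    stop(depdst_error("frame must contain at least one hypothesis", "empty_frame"))
  }
  if (anyDuplicated(hypotheses)) {
    stop(depdst_error("hypothesis labels must be unique", "duplicate_hypothesis"))
  }
  if (any(hypotheses == "*") || any(grepl("|", hypotheses, fixed = TRUE))) {
    stop(depdst_error("hypothesis labels may not be '*' or contain '|'",
                      "bad_hypothesis_label"))
  }
  structure(hypotheses, class = "dst_frame")
}

#' @export
print.dst_frame <- function(x, ...) {
  cat("Frame of discernment (", length(x), " hypotheses): {",
      paste(unclass(x), collapse = ", "), "}\n", sep = "")
  invisible(x)
}

depdst_error <- function(msg, class) {
  errorCondition(msg, class = c(paste0("depdst_error_", class), "depdst_error"))
}

# canonical key for a subset of `frame`; "" is the empty set
subset_key <- function(members, frame) {
  if (length(members) == 0L) return("")
  idx <- match(members, frame)
  if (anyNA(idx)) {
    stop(depdst_error(
      sprintf("subset members not in frame: %s",
              paste(members[is.na(idx)], collapse = ", ")), "subset"))
  }
  paste(frame[sort(unique(idx))], collapse = "|")
}

key_members <- function(key, frame) {
  if (key == "" ) return(character(0))
  if (key == "*") return(as.character(unclass(frame)))
  strsplit(key, "|", fixed = TRUE)[[1L]]
}

theta_key <- function(frame) paste(unclass(frame), collapse = "|")

#' Construct and validate a mass function (basic probability assignment)
#'
#' A mass function assigns belief mass to subsets of a frame of discernment.
#' The three BPA axioms are enforced: every mass lies in \[0, 1\], the empty
#' set carries zero mass, and the masses sum to one (within `tol`, after which
#' they are renormalized exactly). Focal elements are the subsets with
#' strictly positive mass.
#'
#' @param frame A [dst_frame] or character vector of hypotheses.
#' @param masses Named numeric vector or list. Names are subsets: hypothesis
#'   labels joined by `"|"` (order irrelevant), with `"*"` denoting the whole
#'   frame.
#' @param tol Tolerance on the unit-sum axiom (default `1e-9`).
#' @return An object of class `mass_function` with elements `frame` and
#'   `masses` (named numeric over focal elements, canonically keyed).
#' @examples
#' f <- dst_frame(c("ADR", "DIS", "OTH"))
#' mass_function(f, c("ADR" = 0.8, "*" = 0.2))
#' @export
mass_function <- function(frame, masses, tol = 1e-9) {
  if (!inherits(frame, "dst_frame")) frame <- dst_frame(frame)
  m <- unlist(masses)
  if (length(m) == 0L) stop(depdst_error("no masses supplied", "mass_sum"))
  if (is.null(names(m)) || any(!nzchar(names(m)) & m > 0)) {
    if (is.null(names(m))) stop(depdst_error("masses must be named by subset", "subset"))
  }
  if (!is.numeric(m) || anyNA(m)) {
    stop(depdst_error("masses must be numeric and non-missing", "negative_mass"))
  }
  if (any(m < 0)) {
    stop(depdst_error(sprintf("negative mass on subset '%s'",
                              names(m)[which(m < 0)[1L]]), "negative_mass"))
  }
  if (any(m > 1 + tol)) {
    stop(depdst_error("mass values must lie in [0, 1]", "negative_mass"))
  }
  keys <- vapply(names(m), function(k) {
    subset_key(key_members(k, frame), frame)
  }, character(1))
  empty <- keys == ""
  if (any(m[empty] > 0)) {
    stop(depdst_error("mass on empty set must be zero", "empty_set_mass"))
  }
  m <- m[!empty]
  keys <- keys[!empty]
  if (anyDuplicated(keys)) {
    m <- tapply(m, keys, sum)
    keys <- names(m)
    m <- as.numeric(m)
  }
  s <- sum(m)
  if (abs(s - 1) > tol) {
    stop(depdst_error(sprintf("masses sum to %.10g, not 1", s), "mass_sum"))
  }
  if (s != 1) {
    m <- m / s
    i <- which.max(m)
    m[i] <- m[i] + (1 - sum(m))  # exact unit sum after renormalization
  }
  keep <- m > 0
  masses <- stats::setNames(as.numeric(m[keep]), keys[keep])
  masses <- masses[order_subset_keys(names(masses), frame)]
  structure(list(frame = frame, masses = masses), class = "mass_function")
}

order_subset_keys <- function(keys, frame) {
  sz <- vapply(keys, function(k) length(key_members(k, frame)), integer(1))
  first <- vapply(keys, function(k) match(key_members(k, frame)[1L], frame), integer(1))
  order(sz, first)
}

#' Validate a mass function against the BPA axioms
#'
#' Checks (and returns) an existing `mass_function`, or builds one from a
#' frame plus named masses. Violations raise classed errors:
#' `depdst_error_negative_mass`, `depdst_error_empty_set_mass`,
#' `depdst_error_mass_sum`, `depdst_error_subset`.
#'
#' @param m A `mass_function`, or a named numeric vector of masses.
#' @param frame Required when `m` is a bare vector.
#' @param tol Tolerance on the unit-sum axiom.
#' @return The validated `mass_function`.
#' @export
validate_mass <- function(m, frame = NULL, tol = 1e-9) {
  if (inherits(m, "mass_function")) {
    return(mass_function(m$frame, m$masses, tol = tol))
  }
  if (is.null(frame)) stop(depdst_error("a frame is required", "subset"))
  mass_function(frame, m, tol = tol)
}

#' @export
print.mass_function <- function(x, digits = 5, ...) {
  cat("Mass function on {", paste(unclass(x$frame), collapse = ", "), "}\n", sep = "")
  show <- names(x$masses)
  show[show == theta_key(x$frame)] <- "Theta"
  for (i in seq_along(x$masses)) {
    cat(sprintf("  m({%s}) = %.*g\n", show[i], digits, x$masses[i]))
  }
  invisible(x)
}

mass_lookup <- function(m, key) {
  v <- m$masses[key]
  ifelse(is.na(v), 0, v)
}

#' Combine two mass functions with Dempster's rule
#'
#' The orthogonal sum: for every pair of focal elements the intersection
#' receives the product mass; mass landing on the empty set is the conflict
#' `K`, and the rest is renormalized by `1 - K`. Combination is commutative
#' and (up to floating point) associative, so n-ary fusion may be performed as
#' a left fold.
#'
#' @param m1,m2 Valid `mass_function`s over the same frame.
#' @param conflict_tol Total conflict is declared when `K >= 1 - conflict_tol`
#'   (default `1e-12`).
#' @param drop_tol Combined masses below this are dropped and the rest
#'   renormalized, keeping focal sets sparse.
#' @return An object of class `fusion_result`: list with `combined`
#'   (a `mass_function`) and `conflict` (the scalar `K` in `[0, 1)`).
#' @examples
#' f <- dst_frame(c("ADR", "DIS", "OTH"))
#' john <- mass_function(f, c("ADR" = 0.8, "*" = 0.2))
#' paul <- mass_function(f, c("DIS" = 0.7, "ADR" = 0.2, "*" = 0.1))
#' dempster_combine(john, paul)
#' @export
dempster_combine <- function(m1, m2, conflict_tol = 1e-12, drop_tol = 1e-15) {
  stopifnot(inherits(m1, "mass_function"), inherits(m2, "mass_function"))
  if (!identical(unclass(m1$frame), unclass(m2$frame))) {
    stop(depdst_error("mass functions are defined over different frames",
                      "frame_mismatch"))
  }
  frame <- m1$frame
  acc <- new.env(parent = emptyenv())
  conflict <- 0
  mem1 <- lapply(names(m1$masses), key_members, frame = frame)
  mem2 <- lapply(names(m2$masses), key_members, frame = frame)
  for (i in seq_along(mem1)) {
    for (j in seq_along(mem2)) {
      w <- m1$masses[[i]] * m2$masses[[j]]
      if (w == 0) next
      inter <- intersect(mem1[[i]], mem2[[j]])
      if (length(inter) == 0L) {
        conflict <- conflict + w
      } else {
        k <- subset_key(inter, frame)
        acc[[k]] <- (if (is.null(acc[[k]])) 0 else acc[[k]]) + w
      }
    }
  }
  if (conflict >= 1 - conflict_tol) {
    stop(depdst_error("sources fully conflicting: conflict mass K is 1", "conflict"))
  }
  keys <- ls(acc)
  vals <- vapply(keys, function(k) acc[[k]], numeric(1)) / (1 - conflict)
  keep <- vals >= drop_tol
  vals <- vals[keep] / sum(vals[keep])
  combined <- mass_function(frame, stats::setNames(vals, keys[keep]))
  structure(list(combined = combined, conflict = conflict),
            class = "fusion_result")
}

#' @export
print.fusion_result <- function(x, ...) {
  cat(sprintf("Dempster combination (conflict K = %.5g)\n", x$conflict))
  print(x$combined, ...)
  if (!is.null(x$belief)) {
    cat("Singleton beliefs:\n")
    for (h in names(x$belief)) cat(sprintf("  Bel({%s}) = %.5g\n", h, x$belief[h]))
  }
  invisible(x)
}

#' Belief of a hypothesis set
#'
#' `Bel(A)` is the total mass committed to subsets of `A`: the minimum support
#' the evidence gives `A`.
#'
#' @param m A valid `mass_function`.
#' @param A Character vector of hypotheses (a subset of the frame); the empty
#'   vector is the empty set.
#' @return A value in \[0, 1\].
#' @export
belief <- function(m, A) {
  stopifnot(inherits(m, "mass_function"))
  Aset <- key_members(subset_key(A, m$frame), m$frame)
  if (length(Aset) == 0L) return(0)
  tot <- 0
  for (k in names(m$masses)) {
    if (all(key_members(k, m$frame) %in% Aset)) tot <- tot + m$masses[[k]]
  }
  tot
}

#' Plausibility of a hypothesis set
#'
#' `Pl(A)` sums the masses of every focal element intersecting `A`; it is the
#' dual of belief, `Pl(A) = 1 - Bel(complement of A)`, and always bounds
#' `Bel(A)` from above.
#'
#' @inheritParams belief
#' @return A value in \[0, 1\].
#' @export
plausibility <- function(m, A) {
  stopifnot(inherits(m, "mass_function"))
  Aset <- key_members(subset_key(A, m$frame), m$frame)
  if (length(Aset) == 0L) return(0)
  tot <- 0
  for (k in names(m$masses)) {
    if (length(intersect(key_members(k, m$frame), Aset)) > 0L) {
      tot <- tot + m$masses[[k]]
    }
  }
  tot
}

#' Discount a mass function by a source credibility
#'
#' Scales every focal mass on a proper subset by `credibility` and moves the
#' remaining `1 - credibility` onto the whole frame (total ignorance). With
#' credibility 1 the source is kept as-is; with credibility 0 it becomes the
#' vacuous mass.
#'
#' @param m A valid `mass_function`.
#' @param credibility A value in \[0, 1\].
#' @return The discounted `mass_function`.
#' @export
discount <- function(m, credibility) {
  stopifnot(inherits(m, "mass_function"))
  if (!is.numeric(credibility) || length(credibility) != 1L ||
      is.na(credibility) || credibility < 0 || credibility > 1) {
    stop(depdst_error("credibility must be a single value in [0, 1]",
                      "credibility_range"))
  }
  tk <- theta_key(m$frame)
  new <- m$masses * credibility
  new[tk] <- 1 - credibility + credibility * mass_lookup(m, tk)
  mass_function(m$frame, new)
}

#' Vacuous mass function (total ignorance)
#'
#' @param frame A [dst_frame] or character vector of hypotheses.
#' @return A `mass_function` with all mass on the whole frame.
#' @export
vacuous_mass <- function(frame) {
  if (!inherits(frame, "dst_frame")) frame <- dst_frame(frame)
  mass_function(frame, stats::setNames(1, theta_key(frame)))
}

#' Serialize a mass function to JSON
#'
#' Dialect: `{"frame": [...], "masses": {"a|b": 0.2, "*": 0.1}}` with `"*"`
#' denoting the whole frame and `"|"` joining subset members. The round trip
#' through [mass_from_json()] is bit exact.
#'
#' @param m A valid `mass_function`.
#' @return A JSON string.
#' @export
mass_to_json <- function(m) {
  stopifnot(inherits(m, "mass_function"))
  keys <- names(m$masses)
  keys[keys == theta_key(m$frame)] <- "*"
  esc <- function(s) gsub('"', '\\\\"', gsub("\\\\", "\\\\\\\\", s))
  # %.17g round-trips IEEE doubles exactly; jsonlite's numeric formatting
  # does not, and the dialect requires a bit-exact round trip
  frame_json <- paste0('"', esc(as.character(unclass(m$frame))), '"',
                       collapse = ",")
  mass_json <- paste0('"', esc(keys), '":',
                      vapply(as.numeric(m$masses),
                             function(v) sprintf("%.17g", v), character(1)),
                      collapse = ",")
  sprintf('{"frame":[%s],"masses":{%s}}', frame_json, mass_json)
}

#' Deserialize a mass function from JSON
#'
#' @param txt JSON produced by [mass_to_json()] (or in the same dialect).
#' @return A `mass_function`.
#' @export
mass_from_json <- function(txt) {
  obj <- jsonlite::fromJSON(txt, simplifyVector = TRUE)
  mass_function(dst_frame(obj$frame), unlist(obj$masses))
}
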