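# Assign continental origin from a fragment-length profile against a marker
# panel, requiring concordant independent markers, and quantify the residual
# risk that an apparently fixed marker segregates undetected.

#' Continents compatible with one locus observation
#'
#' A continent is compatible iff every fragment length expected for it at
#' this locus (the dye-labeled digest fragments for a PCR-RFLP locus, the
#' amplicon length otherwise) is matched by an observed length within
#' `tolerance_bp`. When a single observed length sits within tolerance of two
#' *different* expected lengths the locus cannot be read unambiguously and is
#' declared uninformative (empty vote, `informative` attribute `FALSE`); an
#' expected length shared verbatim by several continents is not ambiguous, it
#' simply votes for all of them.
#'
#' @param locus A panel locus (element of `marker_panel$loci`).
#' @param observed Integer vector of sized fragment lengths.
#' @param tolerance_bp Sizing tolerance in bp (default 1).
#' @param dye_offsets Named integer vector of per-dye sizing offsets
#'   (instrument bias, e.g. `c(FAM = -3)` when FAM peaks read 3 bp short).
#'   Observed lengths are corrected by subtracting the offset of the locus's
#'   labeling dye before comparison.
#' @return Character vector of compatible continents with attributes
#'   `informative` (logical) and `locus`.
#' @export
locus_vote <- function(locus, observed, tolerance_bp = 1L,
                       dye_offsets = integer(0)) {
  observed <- as.integer(observed)
  observed <- observed[!is.na(observed)]
  expected <- locus_expectations(locus)
  dye <- locus_label_dye(locus)
  offset <- if (dye %in% names(dye_offsets)) as.integer(dye_offsets[[dye]]) else 0L
  adjusted <- observed - offset

  vote <- structure(character(0), informative = FALSE, locus = locus$name)
  if (!length(observed)) return(vote)

  all_expected <- sort(unique(unlist(expected)))
  for (o in adjusted) {
    near <- all_expected[abs(all_expected - o) <= tolerance_bp]
    if (length(near) > 1L) return(vote)  # straddles two expected lengths
  }
  compatible <- names(expected)[vapply(expected, function(e) {
    all(vapply(e, function(x) any(abs(adjusted - x) <= tolerance_bp), logical(1)))
  }, logical(1))]
  structure(compatible, informative = length(compatible) > 0L,
            locus = locus$name)
}

locus_expectations <- function(locus) {
  if (!is.null(locus$digest) && length(locus$digest$expected_labeled)) {
    locus$digest$expected_labeled
  } else {
    lapply(as.list(locus$expected_lengths), function(x) x)
  }
}

locus_label_dye <- function(locus) {
  dyes <- setdiff(c(locus$forward_primer$dye, locus$reverse_primer$dye), "none")
  if (length(unique(dyes)) == 1L) dyes[1L] else "none"
}

#' Assign a continental origin from a fragment profile
#'
#' Collects [locus_vote()]s for all informative loci and intersects them. The
#' verdict is a continent only when the intersection is exactly that
#' continent and at least `min_markers` independent loci were informative;
#' an empty intersection is `inconsistent` (conflicting markers, e.g. a
#' mixed or mislabeled sample), fewer informative loci than required is
#' `insufficient`, a multi-continent intersection is `ambiguous`.
#'
#' @param profile A [fragment_profile()].
#' @param panel A `marker_panel`.
#' @param min_markers Minimum number of concordant informative loci
#'   (default 2).
#' @param tolerance_bp,dye_offsets Passed to [locus_vote()].
#' @return A `continent_call`: list with `specimen_id`, `verdict`
#'   (`Asia` / `Europe` / `NorthAmerica` / `ambiguous` / `inconsistent` /
#'   `insufficient`), `informative_loci` and the per-locus `votes`.
#' @export
assign_continent <- function(profile, panel, min_markers = 2L,
                             tolerance_bp = 1L, dye_offsets = integer(0)) {
  stopifnot(inherits(profile, "fragment_profile"), inherits(panel, "marker_panel"))
  loci <- intersect(names(panel$loci), names(profile$observations))
  if (!length(loci)) {
    abort_oak("profile shares no locus with the panel", "oakorigin_input_error")
  }
  votes <- list()
  for (l in loci) {
    obs <- profile$observations[[l]]
    if (length(obs) == 1L && is.na(obs)) next  # NO-DATA locus
    votes[[l]] <- locus_vote(panel$loci[[l]], obs, tolerance_bp, dye_offsets)
  }
  informative <- Filter(function(v) isTRUE(attr(v, "informative")), votes)
  verdict <- if (length(informative) == 0L) {
    "insufficient"
  } else {
    isect <- Reduce(intersect, informative)
    if (length(isect) == 0L) "inconsistent"
    else if (length(informative) < min_markers) "insufficient"
    else if (length(isect) > 1L) "ambiguous"
    else isect
  }
  structure(list(specimen_id = profile$specimen_id, verdict = verdict,
                 informative_loci = length(informative), votes = votes),
            class = "continent_call")
}

#' @export
print.continent_call <- function(x, ...) {
  cat(sprintf("<continent_call> %s: %s (%d informative loci)\n",
              x$specimen_id, x$verdict, x$informative_loci))
  for (l in names(x$votes)) {
    v <- x$votes[[l]]
    cat(sprintf("  %-12s %s\n", l,
                if (length(v)) paste(v, collapse = ", ") else "uninformative"))
  }
  invisible(x)
}

#' Exact binomial upper bound for zero observed events
#'
#' The Clopper-Pearson upper confidence limit on the population frequency of
#' a variant never observed in `n` sampled individuals: the largest frequency
#' still consistent, at the chosen confidence, with seeing 0 carriers. Closed
#' form: `1 - alpha^(1/n)` one-sided, `1 - (alpha/2)^(1/n)` two-sided, with
#' `alpha = 1 - confidence`. Strictly decreasing in `n`.
#'
#' @param n Number of individuals screened (vectorized).
#' @param confidence Confidence level (default 0.95).
#' @param sidedness `"two"` (default, the usual 95% CI convention) or
#'   `"one"`.
#' @return Upper bound(s) as a proportion in (0, 1\].
#' @export
upper_bound_zero_observed <- function(n, confidence = 0.95,
                                      sidedness = c("two", "one")) {
  sidedness <- match.arg(sidedness)
  if (!length(n) || any(is.na(n)) || any(n < 1) || any(n != as.integer(n))) {
    abort_oak("'n' must contain integers >= 1", "oakorigin_parameter_error")
  }
  if (confidence <= 0 || confidence >= 1) {
    abort_oak("'confidence' must lie in (0, 1)", "oakorigin_parameter_error")
  }
  alpha <- 1 - confidence
  tail <- if (sidedness == "one") alpha else alpha / 2
  1 - tail^(1 / n)
}

#' Combined fixation risk over independent markers
#'
#' For markers screened in `ns` individuals each, multiplies the per-marker
#' upper bounds of [upper_bound_zero_observed()] into the probability that a
#' variant escaping detection at *every* marker is nonetheless segregating --
#' the residual risk of a wrong continent call based on those markers jointly.
#' Marker independence is assumed; chloroplast loci are physically linked, so
#' treat the product as an approximation (see the package vignette).
#'
#' @param ns Integer vector of per-marker sample counts (length >= 1).
#' @param confidence,sidedness Passed to [upper_bound_zero_observed()].
#' @return A `risk_estimate`: list with `per_marker` (data frame of `n` and
#'   `upper_bound`), `confidence`, `sidedness`, `combined` (proportion) and
#'   `combined_pct`.
#' @export
combined_risk <- function(ns, confidence = 0.95, sidedness = c("two", "one")) {
  sidedness <- match.arg(sidedness)
  if (!length(ns)) {
    abort_oak("'ns' must contain at least one sample count",
              "oakorigin_parameter_error")
  }
  bounds <- upper_bound_zero_observed(ns, confidence, sidedness)
  structure(list(per_marker = data.frame(n = as.integer(ns),
                                         upper_bound = bounds),
                 confidence = confidence, sidedness = sidedness,
                 combined = prod(bounds), combined_pct = 100 * prod(bounds)),
            class = "risk_estimate")
}

#' @export
print.risk_estimate <- function(x, ...) {
  cat(sprintf("<risk_estimate> %g%% %s-sided exact binomial bounds\n",
              100 * x$confidence, x$sidedness))
  for (i in seq_len(nrow(x$per_marker))) {
    cat(sprintf("  n = %4d  upper bound = %.6f (%.4f%%)\n",
                x$per_marker$n[i], x$per_marker$upper_bound[i],
                100 * x$per_marker$upper_bound[i]))
  }
  cat(sprintf("  combined risk = %.3g (%.4g%%)\n", x$combined, x$combined_pct))
  invisible(x)
}
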