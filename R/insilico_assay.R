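# In-silico genotyping assay: locate primers on a template, predict the PCR
# amplicon, digest it with a restriction enzyme, and determine which fragments
# are visible through dye-labeled primers on a capillary trace.

#' Construct a primer pair
#'
#' @param forward_seq,reverse_seq Primer sequences written 5'->3' (the reverse
#'   primer as its own sequence; it binds the reverse strand).
#' @param forward_dye,reverse_dye Fluorescent dye, one of `FAM`, `VIC`, `PET`
#'   or `none`.
#' @return A `primer_pair` object.
#' @export
primer_pair <- function(forward_seq, reverse_seq,
                        forward_dye = "none", reverse_dye = "none") {
  mk <- function(seq, dye, side) {
    seq <- toupper(seq)
    if (!is_dna(seq, allow_n = FALSE) || nchar(seq) < 15L) {
      abort_oak(sprintf("%s primer must be >= 15 bp of A,C,G,T", side),
                "oakorigin_parameter_error")
    }
    if (!dye %in% DYES) {
      abort_oak(sprintf("unknown dye '%s'", dye), "oakorigin_config_error")
    }
    list(seq = seq, dye = dye)
  }
  structure(list(forward = mk(forward_seq, forward_dye, "forward"),
                 reverse = mk(reverse_seq, reverse_dye, "reverse")),
            class = "primer_pair")
}

as_primer_pair <- function(x) {
  if (inherits(x, "primer_pair")) return(x)
  # a panel locus
  primer_pair(x$forward_primer$seq, x$reverse_primer$seq,
              x$forward_primer$dye, x$reverse_primer$dye)
}

#' Construct a restriction enzyme
#'
#' @param name Enzyme name.
#' @param site Recognition site in IUPAC DNA (e.g. `GANTC` for HinfI).
#' @param cut_offset Cut position on the top strand, counted in bases after
#'   the site's first base (HinfI cuts G^ANTC, offset 1).
#' @return A `restriction_enzyme` object.
#' @export
restriction_enzyme <- function(name, site, cut_offset) {
  site <- toupper(site)
  if (grepl("[^ACGTRYSWKMBDHVN]", site)) {
    abort_oak(sprintf("site '%s' is not IUPAC DNA", site), "oakorigin_config_error")
  }
  cut_offset <- check_count(cut_offset, "cut_offset")
  if (cut_offset > nchar(site)) {
    abort_oak("cut_offset must lie within the recognition site",
              "oakorigin_config_error")
  }
  structure(list(name = name, site = site, cut_offset = cut_offset),
            class = "restriction_enzyme")
}

#' HinfI (G^ANTC)
#' @return A [restriction_enzyme()].
#' @export
hinfI <- function() restriction_enzyme("HinfI", "GANTC", 1L)

# all exact-orientation matches of `pattern` in `template` with their mismatch
# counts; returns data.frame(start, end, mismatches)
primer_matches <- function(pattern, template, max_mismatch) {
  t <- Biostrings::DNAString(template)
  p <- Biostrings::DNAString(pattern)
  m <- Biostrings::matchPattern(p, t, max.mismatch = max_mismatch)
  if (length(m) == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      mismatches = integer(0)))
  }
  st <- IRanges::start(m)
  mm <- Biostrings::neditStartingAt(p, t, starting.at = st, with.indels = FALSE)
  data.frame(start = st, end = IRanges::end(m), mismatches = as.integer(mm))
}

#' Locate a primer on a template
#'
#' Searches the given strand with the primer itself and the reverse strand
#' with its reverse complement, allowing up to `max_mismatch` substitutions.
#' The unique best hit (fewest mismatches) is returned; a missing site is a
#' `NULL` result (downstream code records `NO-DATA`), while two equally good
#' hits raise an ambiguity error because the amplicon would be undefined.
#'
#' @param template Template DNA string.
#' @param primer Primer sequence 5'->3'.
#' @param max_mismatch Maximum Hamming distance (default 0).
#' @return `NULL`, or a list with `position` (1-based start of the matching
#'   template region), `end` and `strand` (`"forward"` / `"reverse"`).
#' @export
find_primer_site <- function(template, primer, max_mismatch = 0L) {
  template <- toupper(template)
  primer <- toupper(primer)
  if (!nzchar(template) || !nzchar(primer)) {
    abort_oak("template and primer must be non-empty", "oakorigin_parameter_error")
  }
  fwd <- primer_matches(primer, template, max_mismatch)
  rev <- primer_matches(revcomp(primer), template, max_mismatch)
  hits <- rbind(cbind(fwd, strand = rep("forward", nrow(fwd))),
                cbind(rev, strand = rep("reverse", nrow(rev))))
  if (nrow(hits) == 0L) return(NULL)
  best <- hits[hits$mismatches == min(hits$mismatches), , drop = FALSE]
  if (nrow(best) > 1L) {
    abort_oak(sprintf("primer matches the template at %d equally good sites",
                      nrow(best)), "oakorigin_ambiguity_error")
  }
  list(position = best$start[1L], end = best$end[1L], strand = best$strand[1L])
}

#' Predict a PCR amplicon
#'
#' Locates the forward primer on the top strand and the reverse primer's
#' binding site (its reverse complement) downstream of it; the amplicon spans
#' from the forward primer's 5' end to the reverse primer's 5' end inclusive,
#' so its length includes both primer sites. Inverted primer orientation or a
#' product above `max_product_bp` yields no amplicon (`NULL`).
#'
#' @param template Template DNA string.
#' @param pair A [primer_pair()] or a panel locus.
#' @param max_mismatch Substitutions tolerated per primer (default 0; raise it
#'   to emulate degraded-template amplification).
#' @param max_product_bp Product size cap (default 2000).
#' @param locus Optional locus name carried on the result.
#' @return `NULL`, or an `amplicon`: list with `locus`, `sequence`, `length`,
#'   `start`, `end` (1-based closed template interval) and the primer pair.
#' @export
amplify <- function(template, pair, max_mismatch = 0L, max_product_bp = 2000L,
                    locus = NA_character_) {
  pair <- as_primer_pair(pair)
  template <- toupper(template)
  fwd_hits <- primer_matches(pair$forward$seq, template, max_mismatch)
  rev_hits <- primer_matches(revcomp(pair$reverse$seq), template, max_mismatch)
  pick_best <- function(h, which) {
    if (nrow(h) == 0L) return(NULL)
    best <- h[h$mismatches == min(h$mismatches), , drop = FALSE]
    if (nrow(best) > 1L) {
      abort_oak(sprintf("%s primer matches the template at %d equally good sites",
                        which, nrow(best)), "oakorigin_ambiguity_error")
    }
    best
  }
  fwd <- pick_best(fwd_hits, "forward")
  rev <- pick_best(rev_hits, "reverse")
  if (is.null(fwd) || is.null(rev)) return(NULL)
  if (rev$start <= fwd$start) return(NULL)          # inverted orientation
  len <- rev$end - fwd$start + 1L
  if (len > max_product_bp) return(NULL)
  structure(list(locus = locus,
                 sequence = substr(template, fwd$start, rev$end),
                 length = len, start = fwd$start, end = rev$end,
                 pair = pair),
            class = "amplicon")
}

#' @export
print.amplicon <- function(x, ...) {
  cat(sprintf("<amplicon>%s %d bp (template %d..%d)\n",
              if (is.na(x$locus)) "" else paste0(" ", x$locus),
              x$length, x$start, x$end))
  invisible(x)
}

#' Digest an amplicon with a restriction enzyme
#'
#' Cuts at every occurrence of the recognition site on the top strand (IUPAC
#' codes in the site match accordingly), `cut_offset` bases after the site
#' start. For a site that is its own reverse complement under IUPAC matching
#' (such as HinfI's GANTC) top-strand scanning equals double-strand
#' digestion. Digestion is assumed complete; fragments are reported 5'->3'
#' and their lengths always sum to the amplicon length.
#'
#' @param amplicon An `amplicon` from [amplify()], or a plain DNA string.
#' @param enzyme A [restriction_enzyme()].
#' @return A `digest_result`: data frame with columns `length`,
#'   `carries_5prime`, `carries_3prime`, one row per fragment in 5'->3' order.
#' @export
digest <- function(amplicon, enzyme) {
  stopifnot(inherits(enzyme, "restriction_enzyme"))
  seq <- if (inherits(amplicon, "amplicon")) amplicon$sequence else toupper(amplicon)
  n <- nchar(seq)
  m <- Biostrings::matchPattern(enzyme$site, Biostrings::DNAString(seq),
                                fixed = FALSE)
  cuts <- IRanges::start(m) + enzyme$cut_offset - 1L
  cuts <- sort(unique(cuts[cuts >= 1L & cuts < n]))
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, n)
  out <- data.frame(length = ends - starts + 1L,
                    carries_5prime = starts == 1L,
                    carries_3prime = ends == n)
  structure(out, class = c("digest_result", "data.frame"),
            amplicon_length = n)
}

#' Dye-visible fragment lengths of a digest
#'
#' A fragment shows up on the capillary trace iff it retains an amplicon end
#' whose primer carries a dye: the 5'-terminal fragment is visible when the
#' forward primer is labeled, the 3'-terminal fragment when the reverse
#' primer is; internal fragments are never visible.
#'
#' @param result A `digest_result` from [digest()].
#' @param pair The [primer_pair()] used for amplification (or a panel locus).
#' @return Sorted (decreasing) unique visible fragment lengths; empty when no
#'   primer is labeled.
#' @export
visible_fragments <- function(result, pair) {
  pair <- as_primer_pair(pair)
  vis <- (result$carries_5prime & pair$forward$dye != "none") |
         (result$carries_3prime & pair$reverse$dye != "none")
  sort(unique(result$length[vis]), decreasing = TRUE)
}

#' Fragment profile container
#'
#' @param specimen_id Specimen identifier.
#' @param observations Named list mapping locus name to an integer vector of
#'   sized fragment lengths, or `NA` for a locus with no data.
#' @return A `fragment_profile` object.
#' @export
fragment_profile <- function(specimen_id, observations) {
  stopifnot(is.list(observations), !is.null(names(observations)))
  bad <- vapply(observations, function(x) {
    !(length(x) == 1L && is.na(x)) && any(x <= 0L)
  }, logical(1))
  if (any(bad)) {
    abort_oak("fragment lengths must be positive", "oakorigin_value_error")
  }
  structure(list(specimen_id = specimen_id, observations = observations),
            class = "fragment_profile")
}

#' @export
print.fragment_profile <- function(x, ...) {
  cat(sprintf("<fragment_profile> %s\n", x$specimen_id))
  for (l in names(x$observations)) {
    o <- x$observations[[l]]
    cat(sprintf("  %-12s %s\n", l,
                if (length(o) == 1L && is.na(o)) "NO-DATA"
                else paste(o, collapse = "/")))
  }
  invisible(x)
}

#' Run the full assay on one haplotype
#'
#' Per panel locus: amplify; when a digest is configured, digest the amplicon
#' and report the dye-visible fragment lengths, otherwise report the amplicon
#' length. A locus whose primers do not locate is recorded as missing data
#' (`NA`), emulating a failed PCR.
#'
#' @param haplotype Template DNA string (e.g. a whole chloroplast haplotype).
#' @param panel A `marker_panel`.
#' @param specimen_id Identifier stored on the profile.
#' @param max_mismatch Substitutions tolerated per primer (default 0).
#' @return A [fragment_profile()].
#' @export
profile_specimen <- function(haplotype, panel, specimen_id = "specimen",
                             max_mismatch = 0L) {
  stopifnot(inherits(panel, "marker_panel"))
  obs <- lapply(panel$loci, function(locus) {
    amp <- amplify(haplotype, locus, max_mismatch = max_mismatch,
                   locus = locus$name)
    if (is.null(amp)) return(NA_integer_)
    if (!is.null(locus$digest)) {
      enz <- restriction_enzyme(locus$digest$enzyme, locus$digest$site,
                                locus$digest$cut_offset)
      visible_fragments(digest(amp, enz), amp$pair)
    } else {
      amp$length
    }
  })
  fragment_profile(specimen_id, obs)
}
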