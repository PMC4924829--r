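# Screen two sample groups (pools or individual sets) for continent-diagnostic
# fixed differences, and triage indel candidates by repeat context and by the
# fragment-length difference they would produce in an assay.

#' Fixed differences between two variant matrices
#'
#' A row is a candidate fixed difference when one group carries the variant at
#' a frequency in `[min_freq_pct, 100]` in every deviating sample while the
#' other group has no call at that reference position. The comparison is
#' symmetric: both directions are screened and the carrier group recorded.
#' When `reference` is supplied, indel candidates are annotated with their
#' repeat context via [classify_repeat_context()].
#'
#' @param matrix_a,matrix_b `variant_matrix` objects mapped to the same
#'   reference.
#' @param min_freq_pct Lower frequency bound of the fixation screen
#'   (default 95).
#' @param reference Optional [reference_sequence()] (or list) for
#'   repeat-context classification.
#' @return A data frame of candidate markers: the matrix row fields plus
#'   `alt_allele` (deviating alleles, `/`-collapsed when mixed), `carrier`
#'   (`"A"` or `"B"`), `group_a_freq_pct` / `group_b_freq_pct` (mean
#'   frequency over deviating samples; 0 in the non-carrying group),
#'   `length_diff_bp` (the indel length; 0 for SNP/MNP), `repeat_context` and
#'   `status` (all `"candidate"`).
#' @export
fixed_differences <- function(matrix_a, matrix_b, min_freq_pct = 95,
                              reference = NULL) {
  stopifnot(inherits(matrix_a, "variant_matrix"),
            inherits(matrix_b, "variant_matrix"))
  ids_a <- matrix_a$reference_ids
  ids_b <- matrix_b$reference_ids
  if (length(ids_a) && length(ids_b) && !setequal(ids_a, ids_b)) {
    abort_oak("the two matrices are mapped to different references",
              "oakorigin_consistency_error")
  }
  ref_map <- NULL
  if (!is.null(reference)) {
    refs <- if (inherits(reference, "reference_sequence")) list(reference) else reference
    ref_map <- stats::setNames(refs, vapply(refs, `[[`, character(1), "id"))
  }

  one_direction <- function(carrier, other, label) {
    tb <- carrier$table
    if (nrow(tb) == 0L) return(NULL)
    other_pos <- paste(other$table$ref_name, other$table$position, sep = "\r")
    freq_cols <- paste0("freq_", carrier$samples)
    alt_cols <- paste0("alt_", carrier$samples)
    keep <- logical(nrow(tb))
    mean_freq <- numeric(nrow(tb))
    alt_out <- character(nrow(tb))
    for (i in seq_len(nrow(tb))) {
      fr <- as.numeric(tb[i, freq_cols])
      fr <- fr[!is.na(fr)]
      alts <- as.character(tb[i, alt_cols])
      alts <- alts[!alts %in% c("REF-MATCH", "NO-DATA")]
      keep[i] <- tb$n_deviating[i] >= 1L &&
        all(fr >= min_freq_pct & fr <= 100) &&
        !paste(tb$ref_name[i], tb$position[i], sep = "\r") %in% other_pos
      mean_freq[i] <- if (length(fr)) mean(fr) else NA_real_
      alt_out[i] <- paste(unique(alts), collapse = "/")
    }
    if (!any(keep)) return(NULL)
    tb <- tb[keep, , drop = FALSE]
    data.frame(
      ref_name = tb$ref_name, position = tb$position, type = tb$type,
      length = tb$length, ref_allele = tb$ref, alt_allele = alt_out[keep],
      carrier = label,
      group_a_freq_pct = if (label == "A") mean_freq[keep] else 0,
      group_b_freq_pct = if (label == "B") mean_freq[keep] else 0,
      length_diff_bp = ifelse(tb$type %in% c("insertion", "deletion"),
                              tb$length, 0L),
      left_flank = tb$left_flank, right_flank = tb$right_flank,
      stringsAsFactors = FALSE
    )
  }

  out <- rbind(one_direction(matrix_a, matrix_b, "A"),
               one_direction(matrix_b, matrix_a, "B"))
  if (is.null(out)) {
    out <- data.frame(ref_name = character(0), position = integer(0),
                      type = character(0), length = integer(0),
                      ref_allele = character(0), alt_allele = character(0),
                      carrier = character(0), group_a_freq_pct = numeric(0),
                      group_b_freq_pct = numeric(0), length_diff_bp = integer(0),
                      left_flank = character(0), right_flank = character(0),
                      stringsAsFactors = FALSE)
  }
  out <- out[order(out$ref_name, out$position), , drop = FALSE]
  rownames(out) <- NULL
  out$repeat_context <- vapply(seq_len(nrow(out)), function(i) {
    if (!out$type[i] %in% c("insertion", "deletion") || is.null(ref_map)) {
      return(if (out$type[i] %in% c("insertion", "deletion")) NA_character_ else "none")
    }
    classify_repeat_context(ref_map[[out$ref_name[i]]], out[i, ])
  }, character(1))
  out$status <- rep("candidate", nrow(out))
  out
}

#' Classify the repeat context of an indel
#'
#' `homopolymer`: the indel allele is a single repeated base and the reference
#' run of that base at the locus (including the deleted bases for a deletion)
#' reaches `min_homopolymer_run`. `microsatellite`: the allele is an integer
#' number of copies of a 2-6 bp motif, and the motif is tandemly repeated at
#' least `min_motif_repeats` times in phase at the locus. Otherwise `none`.
#' Indels in either repeat class are poor assay markers: replication slippage
#' makes their length polymorphic within populations.
#'
#' @param reference A [reference_sequence()].
#' @param row A candidate/matrix row (list or one-row data frame) with fields
#'   `position`, `type` (or `var_type`), `length` and the allele fields
#'   (`ref_allele` and `alt_allele`).
#' @param min_homopolymer_run Minimum run length (default 5).
#' @param min_motif_repeats Minimum tandem motif copies (default 3).
#' @return One of `"homopolymer"`, `"microsatellite"`, `"none"`.
#' @export
classify_repeat_context <- function(reference, row, min_homopolymer_run = 5L,
                                    min_motif_repeats = 3L) {
  stopifnot(inherits(reference, "reference_sequence"))
  type <- row$type %||% row$var_type
  if (!type %in% c("insertion", "deletion")) {
    abort_oak("repeat context is defined for insertions and deletions only",
              "oakorigin_type_error")
  }
  allele <- if (type == "deletion") row$ref_allele else row$alt_allele
  allele <- sub("/.*$", "", allele)  # first allele when samples disagree
  pos <- row$position
  len <- nchar(allele)
  seq <- reference$sequence
  n <- reference$length
  base_at <- function(i) substr(seq, i, i)

  # homopolymer: uniform allele extended by the surrounding reference run
  bases <- strsplit(allele, "")[[1L]]
  if (length(unique(bases)) == 1L) {
    b <- bases[1L]
    if (type == "deletion") {
      run <- len
      i <- pos - 1L
      while (i >= 1L && base_at(i) == b) { run <- run + 1L; i <- i - 1L }
      i <- pos + len
      while (i <= n && base_at(i) == b) { run <- run + 1L; i <- i + 1L }
    } else {
      run <- 0L
      i <- pos
      while (i >= 1L && base_at(i) == b) { run <- run + 1L; i <- i - 1L }
      i <- pos + 1L
      while (i <= n && base_at(i) == b) { run <- run + 1L; i <- i + 1L }
    }
    if (run >= min_homopolymer_run) return("homopolymer")
  }

  # microsatellite: tandem copies of a 2-6 bp motif in phase with the allele
  for (k in 2:6) {
    if (len %% k != 0L || len < k) next
    motif <- substr(allele, 1L, k)
    if (strrep(motif, len %/% k) != allele) next
    copies <- if (type == "deletion") len %/% k else 0L
    right_anchor <- if (type == "deletion") pos + len else pos + 1L
    left_anchor <- if (type == "deletion") pos - k else pos - k + 1L
    j <- left_anchor
    while (j >= 1L && substr(seq, j, j + k - 1L) == motif) {
      copies <- copies + 1L; j <- j - k
    }
    j <- right_anchor
    while (j + k - 1L <= n && substr(seq, j, j + k - 1L) == motif) {
      copies <- copies + 1L; j <- j + k
    }
    if (copies >= min_motif_repeats) return("microsatellite")
  }
  "none"
}

#' Triage indel candidates by size and repeat context
#'
#' Applies the marker-selection rules to candidates from
#' [fixed_differences()]: indels in a repeat context are removed
#' (`removed_repeat`, when `exclude_repeat_context`), indels whose
#' fragment-length difference falls below `min_length_diff_bp` are removed
#' (`removed_short`), the rest are `selected`. SNP/MNP candidates keep status
#' `candidate`: usable for PCR-RFLP design but not preferred for
#' length-based assays. Selected markers sort first, by descending length
#' difference.
#'
#' @param candidates Data frame from [fixed_differences()].
#' @param min_length_diff_bp Minimum fragment-length difference in bp. No
#'   default: 4 suits a within-hemisphere (Eurasia) screen, 2 a
#'   New-World/Old-World screen; an explicit choice avoids a silently wrong
#'   one.
#' @param exclude_repeat_context Drop homopolymer/microsatellite indels
#'   (default `TRUE`).
#' @return The candidate data frame with updated `status`, selected rows
#'   first in descending `length_diff_bp` order.
#' @export
select_indel_markers <- function(candidates, min_length_diff_bp,
                                 exclude_repeat_context = TRUE) {
  min_length_diff_bp <- check_count(min_length_diff_bp, "min_length_diff_bp", 1L)
  if (nrow(candidates) == 0L) return(candidates)
  is_indel <- candidates$type %in% c("insertion", "deletion")
  status <- candidates$status
  for (i in which(is_indel)) {
    ctx <- candidates$repeat_context[i]
    status[i] <- if (exclude_repeat_context && !is.na(ctx) && ctx != "none") {
      "removed_repeat"
    } else if (candidates$length_diff_bp[i] < min_length_diff_bp) {
      "removed_short"
    } else {
      "selected"
    }
  }
  candidates$status <- status
  ord <- order(candidates$status != "selected", -candidates$length_diff_bp,
               candidates$position)
  out <- candidates[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
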