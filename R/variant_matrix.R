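# Merge per-sample variant call tables into a multi-individual matrix with
# per-position summary statistics and primer-design flanking sequences.
#
# Rows are keyed by (ref_name, position, var_type, length): two samples
# sharing an event of the same type and span share a row even when their alt
# alleles differ (the per-sample cells stay comparable); events differing in
# type or indel length occupy separate rows.

#' Flanking-sequence policy
#'
#' Two distance thresholds (bp) govern how much flanking sequence is emitted
#' around a variant for primer design. Per side, with `d` the distance to the
#' nearest other variant on that side: `d <= lower_bp` yields no flank;
#' `lower_bp < d <= upper_bp` yields a flank of `lower_bp`; otherwise (or with
#' no neighbouring variant) a flank of `upper_bp`.
#'
#' @param lower_bp Lower distance threshold (default 50).
#' @param upper_bp Upper distance threshold (default 75).
#' @return A `flank_policy` object.
#' @export
flank_policy <- function(lower_bp = 50L, upper_bp = 75L) {
  lower_bp <- check_count(lower_bp, "lower_bp", min = 1L)
  upper_bp <- check_count(upper_bp, "upper_bp", min = 1L)
  if (lower_bp > upper_bp) {
    abort_oak("flank policy requires lower_bp <= upper_bp", "oakorigin_parameter_error")
  }
  structure(list(lower_bp = lower_bp, upper_bp = upper_bp), class = "flank_policy")
}

#' Minimum-coverage policy for reference-matching cells
#'
#' A sample without a call at a variant position counts as matching the
#' reference only when its coverage there is at least `min_cov`; below that
#' (or without coverage information) the cell is `NO-DATA`.
#'
#' @param min_cov Minimum read depth (default 8).
#' @return A `coverage_policy` object.
#' @export
coverage_policy <- function(min_cov = 8L) {
  structure(list(min_cov = check_count(min_cov, "min_cov")),
            class = "coverage_policy")
}

#' Mean forward/reverse balance of the reads supporting a variant
#'
#' For each call the balance is `min(F, R) / (F + R)`, 0.5 for perfectly
#' strand-balanced support and 0 when all supporting reads come from one
#' strand; a low average flags likely systematic sequencing error. Calls with
#' `F + R == 0` are skipped.
#'
#' @param calls Data frame of variant calls at one matrix row (columns
#'   `forward_count`, `reverse_count`).
#' @return Mean balance over contributing calls, in \[0, 0.5\], or `NA` when
#'   no call contributes.
#' @export
mean_forward_reverse_balance <- function(calls) {
  f <- calls$forward_count
  r <- calls$reverse_count
  keep <- (f + r) > 0L
  if (!any(keep)) return(NA_real_)
  mean(pmin(f[keep], r[keep]) / (f[keep] + r[keep]))
}

#' Flanking sequences around a focal variant
#'
#' Applies the dual-threshold rule of [flank_policy()] per side independently,
#' measuring distances between variant anchor positions in reference
#' coordinates. Flanks exclude the focal reference footprint and are truncated
#' at the sequence ends.
#'
#' @param reference A [reference_sequence()].
#' @param all_variant_positions Sorted integer vector of anchor positions of
#'   all variants on this reference (must contain `focal_position`).
#' @param focal_position Anchor position of the focal variant.
#' @param policy A [flank_policy()].
#' @param footprint Number of reference bases occupied by the focal variant
#'   (its `length` for SNP/MNP/deletion; 1 for an insertion, which is anchored
#'   at the base left of the inserted sequence).
#' @return A list with `left` and `right` flank strings (possibly empty).
#' @export
flanking_sequences <- function(reference, all_variant_positions, focal_position,
                               policy = flank_policy(), footprint = 1L) {
  stopifnot(inherits(reference, "reference_sequence"))
  if (!focal_position %in% all_variant_positions) {
    abort_oak(sprintf("focal position %d is not among the supplied variant positions",
                      focal_position), "oakorigin_input_error")
  }
  others <- all_variant_positions[all_variant_positions != focal_position]
  side_len <- function(d) {
    if (is.na(d) || d > policy$upper_bp) policy$upper_bp
    else if (d > policy$lower_bp) policy$lower_bp
    else 0L
  }
  d_left <- if (any(others < focal_position)) {
    focal_position - max(others[others < focal_position])
  } else NA_integer_
  d_right <- if (any(others > focal_position)) {
    min(others[others > focal_position]) - focal_position
  } else NA_integer_
  len_l <- side_len(d_left)
  len_r <- side_len(d_right)
  left_from <- max(1L, focal_position - len_l)
  left_to <- focal_position - 1L
  right_from <- focal_position + footprint
  right_to <- min(reference$length, right_from + len_r - 1L)
  list(
    left = if (len_l > 0L && left_to >= left_from) {
      substr(reference$sequence, left_from, left_to)
    } else "",
    right = if (len_r > 0L && right_to >= right_from) {
      substr(reference$sequence, right_from, right_to)
    } else ""
  )
}

#' Merge per-sample variant tables into a multi-individual matrix
#'
#' Combines validated per-sample call tables (see [read_variant_table()]) into
#' one row per distinct `(ref_name, position, type, length)` event. For every
#' row the three summary statistics are computed: the number of individual
#' alleles deviating from the reference, the number of alleles matching the
#' reference with at least the minimum coverage, and the mean forward/reverse
#' balance of the deviating calls (flagged critical below
#' `balance_threshold`). Samples without a call at a row are `REF-MATCH` when
#' their coverage at that position reaches `cov_policy$min_cov`, otherwise
#' `NO-DATA`; without coverage tables all non-calling samples are `NO-DATA`.
#' Flanking sequences follow [flanking_sequences()].
#'
#' @param tables A list of per-sample call data frames (each with a single
#'   `sample_id`), or one combined data frame.
#' @param reference A [reference_sequence()] or list of them (multi-contig).
#' @param coverage Optional list of coverage data frames (or one combined
#'   data frame) as returned by [read_coverage_table()].
#' @param cov_policy A [coverage_policy()].
#' @param flank_pol A [flank_policy()].
#' @param balance_threshold Rows with mean balance strictly below this are
#'   flagged `critical_balance` (default 0.2).
#' @return A `variant_matrix`.
#' @export
merge_variant_tables <- function(tables, reference, coverage = NULL,
                                 cov_policy = coverage_policy(),
                                 flank_pol = flank_policy(),
                                 balance_threshold = 0.2) {
  refs <- if (inherits(reference, "reference_sequence")) list(reference) else reference
  ref_map <- stats::setNames(refs, vapply(refs, `[[`, character(1), "id"))

  calls <- if (is.data.frame(tables)) tables else do.call(rbind, tables)
  cov_samples <- if (is.null(coverage)) character(0) else {
    cv <- if (is.data.frame(coverage)) coverage else do.call(rbind, coverage)
    unique(cv$sample_id)
  }
  if (is.null(calls) || nrow(calls) == 0L) {
    return(new_variant_matrix(empty_matrix_table(sort(cov_samples)),
                              sort(cov_samples), names(ref_map)))
  }
  validate_variant_calls(calls, origin = "merged input")
  # the sample universe: every sample with calls or coverage information
  samples <- sort(unique(c(calls$sample_id, cov_samples)))

  bad_ref <- setdiff(unique(calls$ref_name), names(ref_map))
  if (length(bad_ref)) {
    abort_oak(sprintf("calls refer to unknown reference '%s'", bad_ref[1L]),
              "oakorigin_consistency_error")
  }
  ref_len <- vapply(ref_map, `[[`, integer(1), "length")
  beyond <- calls$position > ref_len[calls$ref_name]
  if (any(beyond)) {
    i <- which(beyond)[1L]
    abort_oak(sprintf("call at %s:%d lies beyond the reference end (%d bp)",
                      calls$ref_name[i], calls$position[i], ref_len[calls$ref_name[i]]),
              "oakorigin_consistency_error")
  }
  dup <- duplicated(calls[, c("sample_id", "ref_name", "position", "var_type")])
  if (any(dup)) {
    i <- which(dup)[1L]
    abort_oak(sprintf("duplicate call for sample '%s' at %s:%d (%s)",
                      calls$sample_id[i], calls$ref_name[i], calls$position[i],
                      calls$var_type[i]),
              "oakorigin_input_error")
  }

  cov_lookup <- build_coverage_lookup(coverage)

  key <- paste(calls$ref_name, calls$position, calls$var_type, calls$length,
               sep = "\r")
  groups <- split(seq_len(nrow(calls)), key)
  anchors_by_ref <- lapply(split(calls$position, calls$ref_name),
                           function(p) sort(unique(p)))

  rows <- lapply(groups, function(idx) {
    g <- calls[idx, , drop = FALSE]
    ref_alleles <- unique(g$ref_allele)
    if (length(ref_alleles) > 1L) {
      abort_oak(sprintf("conflicting reference alleles at %s:%d",
                        g$ref_name[1L], g$position[1L]),
                "oakorigin_consistency_error")
    }
    alt <- cov <- freq <- stats::setNames(vector("list", length(samples)), samples)
    for (s in samples) {
      j <- which(g$sample_id == s)
      if (length(j)) {
        alt[[s]] <- g$alt_allele[j]
        cov[[s]] <- g$coverage[j]
        freq[[s]] <- g$frequency_pct[j]
      } else {
        depth <- cov_lookup(s, g$ref_name[1L], g$position[1L])
        cov[[s]] <- depth
        alt[[s]] <- if (!is.na(depth) && depth >= cov_policy$min_cov) {
          "REF-MATCH"
        } else "NO-DATA"
        freq[[s]] <- NA_real_
      }
    }
    n_dev <- sum(!unlist(alt) %in% c("REF-MATCH", "NO-DATA"))
    n_match <- sum(unlist(alt) == "REF-MATCH")
    bal <- mean_forward_reverse_balance(g)
    ref <- ref_map[[g$ref_name[1L]]]
    footprint <- if (g$var_type[1L] == "insertion") 1L else g$length[1L]
    fl <- flanking_sequences(ref, anchors_by_ref[[g$ref_name[1L]]],
                             g$position[1L], flank_pol, footprint)
    c(list(ref_name = g$ref_name[1L], position = g$position[1L],
           length = g$length[1L], type = g$var_type[1L],
           ref = g$ref_allele[1L]),
      stats::setNames(alt, paste0("alt_", samples)),
      stats::setNames(cov, paste0("cov_", samples)),
      stats::setNames(freq, paste0("freq_", samples)),
      list(n_deviating = n_dev, n_matching_min_cov = n_match,
           mean_fr_balance = bal,
           critical_balance = !is.na(bal) && bal < balance_threshold,
           left_flank = fl$left, right_flank = fl$right))
  })
  table <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  table <- table[order(table$ref_name, table$position, table$type, table$length), ,
                 drop = FALSE]
  for (s in samples) {
    table[[paste0("cov_", s)]] <- as.integer(table[[paste0("cov_", s)]])
  }
  new_variant_matrix(table, samples, names(ref_map))
}

empty_matrix_table <- function(samples) {
  cols <- c(MATRIX_HEAD_COLS,
            paste0("alt_", samples), paste0("cov_", samples),
            paste0("freq_", samples), MATRIX_TAIL_COLS)
  proto <- list(ref_name = character(0), position = integer(0),
                length = integer(0), type = character(0), ref = character(0),
                n_deviating = integer(0), n_matching_min_cov = integer(0),
                mean_fr_balance = numeric(0), critical_balance = logical(0),
                left_flank = character(0), right_flank = character(0))
  out <- lapply(cols, function(cl) {
    if (cl %in% names(proto)) proto[[cl]]
    else if (startsWith(cl, "cov_")) integer(0)
    else if (startsWith(cl, "freq_")) numeric(0)
    else character(0)
  })
  names(out) <- cols
  as.data.frame(out, stringsAsFactors = FALSE, check.names = FALSE)
}

build_coverage_lookup <- function(coverage) {
  if (is.null(coverage)) {
    return(function(sample, ref, pos) NA_integer_)
  }
  cov <- if (is.data.frame(coverage)) coverage else do.call(rbind, coverage)
  env <- new.env(parent = emptyenv(), size = max(1L, nrow(cov)))
  keys <- paste(cov$sample_id, cov$ref_name, cov$position, sep = "\r")
  for (i in seq_along(keys)) assign(keys[i], cov$depth[i], envir = env)
  function(sample, ref, pos) {
    v <- get0(paste(sample, ref, pos, sep = "\r"), envir = env)
    if (is.null(v)) NA_integer_ else as.integer(v)
  }
}

#' Filter a variant matrix
#'
#' Retains rows where every deviating sample's alt-allele frequency lies in
#' `[min_freq_pct, max_freq_pct]` (both inclusive), at least
#' `min_samples_deviating` samples deviate, and the variant type is among
#' `types`. The input matrix is left unchanged.
#'
#' @param matrix A `variant_matrix`.
#' @param min_freq_pct,max_freq_pct Frequency window in percent (defaults
#'   95 and 100, the fixed-difference screen).
#' @param min_samples_deviating Minimum number of deviating samples
#'   (default 1).
#' @param types Variant types to keep (default: all four).
#' @return A new, filtered `variant_matrix`.
#' @export
filter_matrix <- function(matrix, min_freq_pct = 95, max_freq_pct = 100,
                          min_samples_deviating = 1L, types = VAR_TYPES) {
  stopifnot(inherits(matrix, "variant_matrix"))
  if (min_freq_pct > max_freq_pct || min_freq_pct < 0 || max_freq_pct > 100) {
    abort_oak("frequency window must satisfy 0 <= min <= max <= 100",
              "oakorigin_parameter_error")
  }
  tb <- matrix$table
  if (nrow(tb) == 0L) return(matrix)
  freq_cols <- paste0("freq_", matrix$samples)
  keep <- vapply(seq_len(nrow(tb)), function(i) {
    fr <- as.numeric(tb[i, freq_cols])
    fr <- fr[!is.na(fr)]
    all(fr >= min_freq_pct & fr <= max_freq_pct) &&
      tb$n_deviating[i] >= min_samples_deviating &&
      tb$type[i] %in% types
  }, logical(1))
  new_variant_matrix(tb[keep, , drop = FALSE], matrix$samples,
                     matrix$reference_ids)
}
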