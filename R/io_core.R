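# Readers/writers: FASTA references, variant/coverage call tables (CSV),
# the multi-individual variant matrix (CSV) and the marker-panel JSON.
#
# Coordinate conventions used throughout the package:
#   * positions are 1-based and fully closed;
#   * an insertion is anchored at the reference base immediately LEFT of the
#     inserted bases (ref allele "-"), a deletion at its first deleted base
#     (alt allele "-");
#   * frequency_pct is alt-supporting reads / total reads at the position x 100.

#' Construct a reference sequence
#'
#' @param id Sequence identifier (first whitespace-separated token of a FASTA
#'   header).
#' @param sequence DNA string over the alphabet `A,C,G,T,N`; lower case is
#'   accepted and upper-cased.
#' @return An object of class `reference_sequence` with fields `id`,
#'   `sequence` and `length`.
#' @export
reference_sequence <- function(id, sequence) {
  if (length(id) != 1L || !nzchar(id)) {
    abort_oak("reference id must be a non-empty string", "oakorigin_format_error")
  }
  sequence <- toupper(as.character(sequence))
  if (length(sequence) != 1L || !nzchar(sequence)) {
    abort_oak(sprintf("reference '%s' has an empty sequence", id),
              "oakorigin_format_error")
  }
  if (!is_dna(sequence)) {
    bad <- regmatches(sequence, regexpr("[^ACGTN]", sequence))
    abort_oak(sprintf(
      "reference '%s' contains letter '%s'; only A,C,G,T,N are supported", id, bad),
      "oakorigin_format_error")
  }
  structure(list(id = id, sequence = sequence, length = nchar(sequence)),
            class = "reference_sequence")
}

#' @export
print.reference_sequence <- function(x, ...) {
  cat(sprintf("<reference_sequence> %s (%d bp)\n", x$id, x$length))
  invisible(x)
}

#' Read a FASTA file of reference sequences
#'
#' Sequences are upper-cased and validated against the `A,C,G,T,N` alphabet;
#' IUPAC ambiguity codes other than `N` are rejected because downstream primer
#' matching and digestion assume unambiguous templates. Record order is
#' preserved.
#'
#' @param path Path to a FASTA file.
#' @return A list of [reference_sequence()] objects.
#' @export
read_fasta <- function(path) {
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) abort_oak(
                    sprintf("cannot parse FASTA '%s': %s", path, conditionMessage(e)),
                    "oakorigin_format_error"))
  if (length(set) == 0L) {
    abort_oak(sprintf("FASTA '%s' contains no records", path), "oakorigin_format_error")
  }
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    abort_oak(sprintf("duplicate FASTA id '%s' in '%s'", ids[duplicated(ids)][1L], path),
              "oakorigin_format_error")
  }
  out <- lapply(seq_along(set), function(i) {
    reference_sequence(ids[i], as.character(set[[i]]))
  })
  out
}

#' Write reference sequences to FASTA
#'
#' @param seqs A list of [reference_sequence()] objects (a single object is
#'   also accepted).
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (inherits(seqs, "reference_sequence")) seqs <- list(seqs)
  dna <- Biostrings::DNAStringSet(vapply(seqs, `[[`, character(1), "sequence"))
  names(dna) <- vapply(seqs, `[[`, character(1), "id")
  Biostrings::writeXStringSet(dna, path, width = width)
  invisible(path)
}

# canonical external headers
VARIANT_CSV_HEADER <- c("sample", "ref_name", "position", "type", "length",
                        "ref", "alt", "frequency", "coverage", "forward", "reverse")
COVERAGE_CSV_HEADER <- c("sample", "ref_name", "position", "depth")

check_header <- function(got, want, path) {
  missing <- setdiff(want, got)
  if (length(missing)) {
    abort_oak(sprintf("'%s' is missing required column(s): %s",
                      path, paste(missing, collapse = ", ")),
              "oakorigin_format_error")
  }
  extra <- setdiff(got, want)
  if (length(extra)) {
    abort_oak(sprintf("'%s' has unexpected column(s): %s",
                      path, paste(extra, collapse = ", ")),
              "oakorigin_format_error")
  }
}

#' Read a per-sample variant call table
#'
#' Parses the canonical comma-separated call table with header
#' `sample,ref_name,position,type,length,ref,alt,frequency,coverage,forward,reverse`
#' into a validated data frame of variant calls. Every row is checked against
#' the call invariants (allele/type consistency, strand counts bounded by
#' coverage, frequency in \[0,100\]); a violation is reported with its data row
#' number rather than silently coerced.
#'
#' @param path Path to the CSV file.
#' @return A data frame with columns `sample_id`, `ref_name`, `position`,
#'   `var_type`, `length`, `ref_allele`, `alt_allele`, `frequency_pct`,
#'   `coverage`, `forward_count`, `reverse_count`, sorted by
#'   `(ref_name, position)`.
#' @export
read_variant_table <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         strip.white = TRUE)
  check_header(names(raw), VARIANT_CSV_HEADER, path)
  df <- data.frame(
    sample_id = raw$sample,
    ref_name = raw$ref_name,
    position = suppressWarnings(as.integer(raw$position)),
    var_type = raw$type,
    length = suppressWarnings(as.integer(raw$length)),
    ref_allele = toupper(raw$ref),
    alt_allele = toupper(raw$alt),
    frequency_pct = suppressWarnings(as.numeric(raw$frequency)),
    coverage = suppressWarnings(as.integer(raw$coverage)),
    forward_count = suppressWarnings(as.integer(raw$forward)),
    reverse_count = suppressWarnings(as.integer(raw$reverse)),
    stringsAsFactors = FALSE
  )
  validate_variant_calls(df, origin = path)
  df[order(df$ref_name, df$position, df$sample_id), , drop = FALSE]
}

validate_variant_calls <- function(df, origin = "variant table") {
  fail <- function(i, why) {
    abort_oak(sprintf("%s, row %d: %s", origin, i, why), "oakorigin_value_error")
  }
  for (i in seq_len(nrow(df))) {
    r <- df[i, ]
    if (anyNA(c(r$position, r$length, r$coverage, r$forward_count,
                r$reverse_count, r$frequency_pct))) {
      fail(i, "non-numeric value in a numeric column")
    }
    if (!r$var_type %in% VAR_TYPES) {
      fail(i, sprintf("unknown variant type '%s'", r$var_type))
    }
    if (r$position < 1L) fail(i, "position must be >= 1")
    if (r$length < 1L) fail(i, "length must be >= 1")
    if (r$frequency_pct < 0 || r$frequency_pct > 100) {
      fail(i, sprintf("frequency %.3f outside [0, 100]", r$frequency_pct))
    }
    if (r$coverage < 0L || r$forward_count < 0L || r$reverse_count < 0L) {
      fail(i, "coverage and strand counts must be >= 0")
    }
    if (r$forward_count + r$reverse_count > r$coverage) {
      fail(i, sprintf("forward + reverse (%d) exceeds coverage (%d)",
                      r$forward_count + r$reverse_count, r$coverage))
    }
    ok_allele <- function(x, gap_ok) is_dna(x, allow_n = FALSE, allow_gap = gap_ok) && nzchar(x)
    switch(r$var_type,
      SNP = {
        if (r$length != 1L) fail(i, "SNP must have length 1")
        if (nchar(r$ref_allele) != 1L || nchar(r$alt_allele) != 1L ||
            !ok_allele(r$ref_allele, FALSE) || !ok_allele(r$alt_allele, FALSE)) {
          fail(i, "SNP alleles must be single bases")
        }
      },
      MNP = {
        if (nchar(r$ref_allele) != r$length || nchar(r$alt_allele) != r$length ||
            !ok_allele(r$ref_allele, FALSE) || !ok_allele(r$alt_allele, FALSE)) {
          fail(i, "MNP alleles must both span the stated length")
        }
      },
      insertion = {
        if (r$ref_allele != "-") fail(i, "insertion must have ref allele '-'")
        if (nchar(r$alt_allele) != r$length || !ok_allele(r$alt_allele, FALSE)) {
          fail(i, "insertion alt allele must span the stated length")
        }
      },
      deletion = {
        if (r$alt_allele != "-") fail(i, "deletion must have alt allele '-'")
        if (nchar(r$ref_allele) != r$length || !ok_allele(r$ref_allele, FALSE)) {
          fail(i, "deletion ref allele must span the stated length")
        }
      }
    )
  }
  invisible(df)
}

#' Read a per-sample coverage table
#'
#' @param path Path to a CSV file with header `sample,ref_name,position,depth`.
#' @return A data frame with columns `sample_id`, `ref_name`, `position`,
#'   `depth`. Positions need not be contiguous; duplicate
#'   `(sample, ref_name, position)` records are rejected.
#' @export
read_coverage_table <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         strip.white = TRUE)
  check_header(names(raw), COVERAGE_CSV_HEADER, path)
  df <- data.frame(
    sample_id = raw$sample,
    ref_name = raw$ref_name,
    position = suppressWarnings(as.integer(raw$position)),
    depth = suppressWarnings(as.integer(raw$depth)),
    stringsAsFactors = FALSE
  )
  if (nrow(df) == 0L) return(df)
  bad <- which(is.na(df$position) | is.na(df$depth))
  if (length(bad)) {
    abort_oak(sprintf("%s, row %d: non-numeric position or depth", path, bad[1L]),
              "oakorigin_value_error")
  }
  if (any(df$depth < 0L)) {
    abort_oak(sprintf("%s, row %d: negative depth", path, which(df$depth < 0L)[1L]),
              "oakorigin_value_error")
  }
  key <- paste(df$sample_id, df$ref_name, df$position, sep = "\r")
  if (anyDuplicated(key)) {
    i <- which(duplicated(key))[1L]
    abort_oak(sprintf("%s, row %d: duplicate coverage record (%s, %s, %d)",
                      path, i, df$sample_id[i], df$ref_name[i], df$position[i]),
              "oakorigin_value_error")
  }
  df
}

#' Write a variant call table in the canonical CSV dialect
#'
#' @param calls Data frame as returned by [read_variant_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(calls, path) {
  out <- data.frame(
    sample = calls$sample_id, ref_name = calls$ref_name,
    position = calls$position, type = calls$var_type, length = calls$length,
    ref = calls$ref_allele, alt = calls$alt_allele,
    frequency = calls$frequency_pct, coverage = calls$coverage,
    forward = calls$forward_count, reverse = calls$reverse_count,
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a coverage table in the canonical CSV dialect
#'
#' @param coverage Data frame as returned by [read_coverage_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coverage_table <- function(coverage, path) {
  out <- data.frame(
    sample = coverage$sample_id, ref_name = coverage$ref_name,
    position = coverage$position, depth = coverage$depth,
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

MATRIX_HEAD_COLS <- c("ref_name", "position", "length", "type", "ref")
MATRIX_TAIL_COLS <- c("n_deviating", "n_matching_min_cov", "mean_fr_balance",
                      "critical_balance", "left_flank", "right_flank")

#' Write a multi-individual variant matrix to CSV
#'
#' Column layout: reference name, position, variant length, calling type,
#' reference allele; then, per individual (ordered by sample id), the
#' alternative allele (`REF-MATCH` / `NO-DATA` tokens for non-deviating
#' cells), the coverage and the alt-allele frequency; then the summary
#' statistics and the two flanking sequences. The written file reads back to
#' an identical matrix via [read_variant_matrix()].
#'
#' @param matrix A `variant_matrix` (see [merge_variant_tables()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variant_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "variant_matrix"))
  con <- tryCatch(file(path, "w"),
                  error = function(e) abort_oak(
                    sprintf("cannot open '%s' for writing", path), "oakorigin_io_error"))
  on.exit(close(con))
  utils::write.csv(matrix$table, con, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Read a multi-individual variant matrix from CSV
#'
#' @param path Path to a CSV produced by [write_variant_matrix()].
#' @param reference_ids Optional character vector of reference ids the matrix
#'   maps to (recorded on the object; defaults to the ids present in the file).
#' @return A `variant_matrix` object.
#' @export
read_variant_matrix <- function(path, reference_ids = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                        na.strings = "")
  check_matrix_header(names(df), path)
  samples <- sub("^alt_", "", grep("^alt_", names(df), value = TRUE))
  for (col in c("position", "length", "n_deviating", "n_matching_min_cov",
                paste0("cov_", samples))) {
    df[[col]] <- as.integer(df[[col]])
  }
  for (col in c("mean_fr_balance", paste0("freq_", samples))) {
    df[[col]] <- as.numeric(df[[col]])
  }
  df$critical_balance <- as.logical(df$critical_balance)
  for (col in c("left_flank", "right_flank")) {
    df[[col]][is.na(df[[col]])] <- ""
  }
  new_variant_matrix(df, samples,
                     reference_ids %||% unique(df$ref_name))
}

check_matrix_header <- function(got, path) {
  samples <- sub("^alt_", "", grep("^alt_", got, value = TRUE))
  want <- c(MATRIX_HEAD_COLS,
            paste0("alt_", samples), paste0("cov_", samples),
            paste0("freq_", samples), MATRIX_TAIL_COLS)
  if (!identical(got, want)) {
    abort_oak(sprintf("'%s' is not a variant-matrix CSV (unexpected column layout)", path),
              "oakorigin_format_error")
  }
}

new_variant_matrix <- function(table, samples, reference_ids) {
  rownames(table) <- NULL
  structure(list(table = table, samples = samples,
                 reference_ids = reference_ids),
            class = "variant_matrix")
}

#' @export
print.variant_matrix <- function(x, ...) {
  cat(sprintf("<variant_matrix> %d variant row(s) x %d sample(s) [%s]\n",
              nrow(x$table), length(x$samples),
              paste(x$reference_ids, collapse = ", ")))
  invisible(x)
}

#' @export
dim.variant_matrix <- function(x) c(nrow(x$table), length(x$samples))

#' @export
as.data.frame.variant_matrix <- function(x, ...) x$table

# ---- marker panel -----------------------------------------------------------

#' Read a marker-panel description from JSON
#'
#' A panel bundles, per locus: the primer pair (sequence plus fluorescent
#' dye), the expected amplicon length per continent, and optionally a
#' restriction digest (enzyme name, IUPAC recognition site, cut offset on the
#' top strand, and the expected dye-labeled fragment lengths per continent).
#'
#' @param path Path to a panel JSON file.
#' @return A `marker_panel`: a list with `name` and a named list `loci`.
#' @seealso [default_panel()] for the packaged five-locus white-oak panel.
#' @export
read_panel <- function(path) {
  spec <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                   error = function(e) abort_oak(
                     sprintf("cannot parse panel JSON '%s': %s",
                             path, conditionMessage(e)),
                     "oakorigin_format_error"))
  if (is.null(spec$loci) || !length(spec$loci)) {
    abort_oak(sprintf("panel '%s' defines no loci", path), "oakorigin_config_error")
  }
  loci <- lapply(spec$loci, validate_panel_locus, path = path)
  names(loci) <- vapply(loci, `[[`, character(1), "name")
  if (anyDuplicated(names(loci))) {
    abort_oak(sprintf("panel '%s' has duplicate locus names", path),
              "oakorigin_config_error")
  }
  structure(list(name = spec$name %||% basename(path), loci = loci),
            class = "marker_panel")
}

validate_panel_locus <- function(locus, path) {
  cfg_err <- function(fmt, ...) abort_oak(
    sprintf(paste0("panel '%s': ", fmt), path, ...), "oakorigin_config_error")
  name <- locus$name %||% cfg_err("locus without a name")
  primer <- function(p, side) {
    if (is.null(p$seq)) cfg_err("locus '%s' lacks a %s primer sequence", name, side)
    seq <- toupper(p$seq)
    if (!is_dna(seq, allow_n = FALSE) || nchar(seq) < 15L) {
      cfg_err("locus '%s' %s primer must be >= 15 bp of A,C,G,T", name, side)
    }
    dye <- p$dye %||% "none"
    if (!dye %in% DYES) cfg_err("locus '%s' %s primer has unknown dye '%s'",
                                name, side, dye)
    list(name = p$name %||% side, seq = seq, dye = dye)
  }
  fwd <- primer(locus$forward_primer, "forward")
  rev <- primer(locus$reverse_primer, "reverse")
  exp_len <- unlist(locus$expected_lengths)
  if (is.null(exp_len) || !length(exp_len)) {
    cfg_err("locus '%s' lacks expected_lengths", name)
  }
  if (!all(names(exp_len) %in% CONTINENTS)) {
    cfg_err("locus '%s' expected_lengths has unknown continent '%s'",
            name, setdiff(names(exp_len), CONTINENTS)[1L])
  }
  if (any(exp_len != as.integer(exp_len)) || any(exp_len <= 0)) {
    cfg_err("locus '%s' expected lengths must be positive integers", name)
  }
  digest <- NULL
  if (!is.null(locus$digest)) {
    d <- locus$digest
    if (is.null(d$enzyme) || !nzchar(d$enzyme)) {
      cfg_err("locus '%s' configures a digest but names no enzyme", name)
    }
    site <- toupper(d$site %||% cfg_err("locus '%s' digest lacks a site", name))
    if (grepl("[^ACGTRYSWKMBDHVN]", site)) {
      cfg_err("locus '%s' digest site '%s' is not IUPAC DNA", name, site)
    }
    off <- d$cut_offset %||% cfg_err("locus '%s' digest lacks cut_offset", name)
    if (off < 0 || off > nchar(site)) {
      cfg_err("locus '%s' digest cut_offset outside [0, site length]", name)
    }
    labeled <- lapply(d$expected_labeled %||% list(), function(x) as.integer(unlist(x)))
    if (length(labeled) && !all(names(labeled) %in% CONTINENTS)) {
      cfg_err("locus '%s' expected_labeled has unknown continent keys", name)
    }
    digest <- list(enzyme = d$enzyme, site = site, cut_offset = as.integer(off),
                   expected_labeled = labeled)
  }
  list(name = name, forward_primer = fwd, reverse_primer = rev,
       expected_lengths = vapply(exp_len, as.integer, integer(1)),
       digest = digest)
}

#' The packaged five-locus white-oak panel
#'
#' Loads the panel shipped with the package: the psaI-ycf4, psbE-petL, trnLF
#' and trnCD length markers and the trnDT PCR-RFLP marker (HinfI), with the
#' primer dyes and expected per-continent fragment lengths used for
#' continent-of-origin genotyping of white oaks.
#'
#' @return A `marker_panel`.
#' @export
default_panel <- function() {
  read_panel(system.file("extdata", "white_oak_panel.json",
                         package = "oakorigin", mustWork = TRUE))
}

#' Write a marker panel to JSON
#'
#' @param panel A `marker_panel`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "marker_panel"))
  loci <- lapply(unname(panel$loci), function(l) {
    out <- list(name = l$name,
                forward_primer = l$forward_primer,
                reverse_primer = l$reverse_primer,
                expected_lengths = as.list(l$expected_lengths))
    if (!is.null(l$digest)) {
      out$digest <- list(enzyme = l$digest$enzyme, site = l$digest$site,
                         cut_offset = l$digest$cut_offset,
                         expected_labeled = lapply(l$digest$expected_labeled, as.list))
    }
    out
  })
  jsonlite::write_json(list(name = panel$name, loci = loci), path,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @export
print.marker_panel <- function(x, ...) {
  cat(sprintf("<marker_panel> %s: %d loci (%s)\n", x$name, length(x$loci),
              paste(names(x$loci), collapse = ", ")))
  invisible(x)
}

#' Reference fragment-length profiles of validated white oak species
#'
#' Loads the packaged table of published fragment lengths for 13 white oak
#' species from three continents: per species, the continent of record, the
#' number of individuals screened (overall and for the trnDT PCR-RFLP
#' marker), and the sized fragment lengths at each of the five panel loci.
#' trnDT entries list the dye-labeled HinfI fragments only (the internal
#' unlabeled Asian 30-bp fragment is invisible on a capillary trace); a blank
#' trnDT cell means the marker was not typed for that species.
#'
#' @param path Path to a profiles CSV; defaults to the packaged table.
#' @return A data frame, one row per species, with locus columns holding
#'   fragment lengths as `/`-separated integers (empty string = not typed).
#' @export
read_species_profiles <- function(path = NULL) {
  path <- path %||% system.file("extdata", "white_oak_species_profiles.csv",
                                package = "oakorigin", mustWork = TRUE)
  utils::read.csv(path, check.names = FALSE, colClasses = "character",
                  strip.white = TRUE)
}

#' Convert species profile rows into fragment profiles
#'
#' @param profiles Data frame from [read_species_profiles()].
#' @param loci Locus column names; defaults to the packaged panel loci present
#'   in the table.
#' @return A named list of `fragment_profile` objects (names = species), each
#'   carrying a `continent` attribute.
#' @export
species_fragment_profiles <- function(profiles,
                                      loci = intersect(names(default_panel()$loci),
                                                       names(profiles))) {
  out <- lapply(seq_len(nrow(profiles)), function(i) {
    obs <- lapply(loci, function(l) {
      cell <- profiles[[l]][i]
      if (is.na(cell) || !nzchar(cell)) return(NA_integer_)
      as.integer(strsplit(cell, "/", fixed = TRUE)[[1L]])
    })
    names(obs) <- loci
    p <- fragment_profile(profiles$species[i], obs)
    attr(p, "continent") <- profiles$continent[i]
    p
  })
  names(out) <- profiles$species
  out
}
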