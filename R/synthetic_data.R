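# Seeded generators: a reference chloroplast-like sequence carrying the five
# marker loci, per-continent haplotypes whose in-silico assay reproduces the
# panel's expected fragment lengths, and pooled-sequencing variant/coverage
# tables with the statistical structure the discovery pipeline assumes.
#
# All randomness flows from one seed. Component k draws from the derived
# sub-seed (seed * 1000003 + k) mod 2147483629, so reference construction and
# variant simulation are independently reproducible.

sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 2147483629 * 1000003 + k) %% 2147483629)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

`substr_set<-` <- function(x, start, value) {
  substr(x, start, start + nchar(value) - 1L) <- value
  x
}

#' Simulation configuration
#'
#' Study conditions for the pooled-sequencing simulation: two pools of
#' `n_individuals` each (emulating 20-individual continental pools), fixed
#' inter-continental differences called at 95-100% read frequency, private
#' low-frequency noise calls, overdispersed coverage, and a binomial
#' forward/reverse read split.
#'
#' @param seed Integer master seed.
#' @param reference_length Reference length in bp (default 20000; must leave
#'   room for the five marker loci).
#' @param n_individuals Individuals per pool (default 20).
#' @param noise_rate Expected noise variants per kb per sample (default 0.05).
#' @param coverage_mean Mean read depth (default 40).
#' @param coverage_dispersion Negative-binomial size parameter (default 10).
#' @param fwd_rev_split Binomial probability that a supporting read is on the
#'   forward strand (default 0.5).
#' @param fixed_freq_range Frequency window (percent) for planted fixed
#'   variants (default `c(95, 100)`).
#' @param noise_freq_range Frequency window for noise variants (default
#'   `c(5, 90)`: drawn strictly below the 95% screen so the fixation boundary
#'   is never straddled by chance).
#' @return A `sim_config` object.
#' @export
simulation_config <- function(seed = 1L, reference_length = 20000L,
                              n_individuals = 20L, noise_rate = 0.05,
                              coverage_mean = 40L, coverage_dispersion = 10,
                              fwd_rev_split = 0.5,
                              fixed_freq_range = c(95, 100),
                              noise_freq_range = c(5, 90)) {
  structure(list(
    seed = check_count(seed, "seed"),
    reference_length = check_count(reference_length, "reference_length", 1L),
    n_individuals = check_count(n_individuals, "n_individuals", 1L),
    noise_rate = noise_rate, coverage_mean = coverage_mean,
    coverage_dispersion = coverage_dispersion, fwd_rev_split = fwd_rev_split,
    fixed_freq_range = fixed_freq_range, noise_freq_range = noise_freq_range
  ), class = "sim_config")
}

# per-locus layout of the continent cassettes, derived from the panel:
# insert lengths between the two primer sites, indel placements, and for the
# PCR-RFLP locus the restriction-site placements realizing the expected
# labeled fragment lengths.
build_cassettes <- function(panel) {
  loci <- panel$loci
  cassettes <- list(Asia = character(0), Europe = character(0),
                    NorthAmerica = character(0))
  for (nm in names(loci)) {
    l <- loci[[nm]]
    f <- l$forward_primer$seq
    r_rc <- revcomp(l$reverse_primer$seq)
    primer_bp <- nchar(f) + nchar(r_rc)
    len_E <- l$expected_lengths[["Europe"]] - primer_bp
    if (len_E < 60L) {
      abort_oak(sprintf("locus '%s': expected length leaves too little insert", nm),
                "oakorigin_config_error")
    }
    ins <- list()
    ins$Europe <- random_dna(len_E)
    if (is.null(l$digest)) {
      # length-only locus: continents differing from Europe get a deletion
      # at offset 40, inside a fixed non-repetitive context so repeat-context
      # triage classifies the event as 'none'; continents sharing the Europe
      # length share its sequence verbatim
      diffs <- vapply(c(Asia = "Asia", NorthAmerica = "NorthAmerica"),
                      function(cont) l$expected_lengths[["Europe"]] -
                        l$expected_lengths[[cont]], numeric(1))
      if (any(diffs < 0L)) abort_oak(
        sprintf("locus '%s': only deletions relative to Europe are modeled", nm),
        "oakorigin_config_error")
      for (cont in names(diffs)[diffs > 0L]) {
        d <- diffs[[cont]]
        window <- indel_window(d)
        ins$Europe <- `substr_set<-`(ins$Europe, 36L, paste0("ACTG", window, "GACT"))
        ins[[cont]] <- paste0(substr(ins$Europe, 1L, 39L),
                              substr(ins$Europe, 40L + d, len_E))
      }
      for (cont in names(diffs)[diffs == 0L]) ins[[cont]] <- ins$Europe
    } else {
      ins <- build_rflp_inserts(l, ins$Europe)
    }
    for (cont in names(cassettes)) {
      stopifnot(nchar(ins[[cont]]) + primer_bp == l$expected_lengths[[cont]])
      cassettes[[cont]][nm] <- paste0(f, ins[[cont]], r_rc)
    }
  }
  cassettes
}

# fixed, repeat-free strings for planted deletions of a given size
indel_window <- function(d) {
  pool <- c("TCAG", "TGCAC", "GTCATC", "TCAGGAC", "TCAGGATC")
  w <- pool[vapply(pool, nchar, integer(1)) == d]
  if (!length(w)) w <- substr("TCAGGATCAGTCGATCCTGA", 1L, d)
  w[1L]
}

# the PCR-RFLP locus: Europe carries one restriction site; Asia gains a
# second site through a SNP; North America carries a 2-bp insertion upstream
# of the shared site. Site placements are solved from the expected labeled
# fragment lengths (first labeled fragment = 5' cut position; Asia's second
# cut at first + second labeled length).
build_rflp_inserts <- function(l, europe_insert) {
  f_len <- nchar(l$forward_primer$seq)
  site <- l$digest$site          # GANTC for HinfI
  stopifnot(identical(site, "GANTC"))
  lab <- l$digest$expected_labeled
  cut_E <- lab$Europe[1L]                       # 5' labeled fragment length
  # Asia's second cut leaves the 3'-labeled fragment; the unlabeled remainder
  # sits between the two cuts (internal fragments carry no dye)
  cut_A2 <- l$expected_lengths[["Asia"]] - lab$Asia[2L]
  ins <- list()
  e <- europe_insert
  # scrub any chance occurrence of the recognition site, then plant:
  # shared site at insert offset cut_E - f_len; Asia's SNP position at
  # cut_A2 - f_len creates the second site, Europe differs by its last base.
  off1 <- cut_E - f_len
  off2 <- cut_A2 - f_len
  stopifnot(off1 > 4L, off2 > off1 + 4L, off2 + 4L < nchar(e) - 4L)
  fixed_windows <- rbind(c(off1, off1 + 4L), c(off2, off2 + 4L),
                         c(37L, 44L))
  e <- `substr_set<-`(e, 37L, "TTACCGGA")       # context of the NA insertion
  e <- `substr_set<-`(e, off1, "GAATC")
  e <- `substr_set<-`(e, off2, "GAATG")         # Europe: SNP breaks site 2
  e <- scrub_site(e, "GA[ACGT]TC", keep = c(off1), fixed_windows)
  ins$Europe <- e
  asia <- `substr_set<-`(e, off2 + 4L, "C")     # GAATG -> GAATC
  ins$Asia <- asia
  ins$NorthAmerica <- paste0(substr(e, 1L, 40L), "CT",
                             substr(e, 41L, nchar(e)))
  ins
}

# remove unplanned occurrences of a restriction-site pattern by mutating one
# base outside the fixed windows; iterates until clean
scrub_site <- function(seq, pattern, keep, fixed_windows) {
  in_fixed <- function(p) any(p >= fixed_windows[, 1L] & p <= fixed_windows[, 2L])
  for (iter in 1:100) {
    hits <- gregexpr(pattern, seq)[[1L]]
    hits <- hits[hits > 0L & !hits %in% keep]
    if (!length(hits)) return(seq)
    h <- hits[1L]
    # offsets within the site that break the pattern when mutated (not N)
    for (rel in c(0L, 1L, 3L, 4L)) {
      p <- h + rel
      if (!in_fixed(p)) {
        repl <- c("C", "C", "A", "G")[match(rel, c(0L, 1L, 3L, 4L))]
        seq <- `substr_set<-`(seq, p, repl)
        break
      }
    }
  }
  abort_oak("could not scrub spurious restriction sites", "oakorigin_config_error")
}

#' Generate a synthetic reference carrying the marker panel
#'
#' Builds a random backbone of `reference_length` bp with the five marker-locus
#' cassettes embedded in forward orientation (the Asian haplotype is the
#' reference, matching the use of an Asian chloroplast genome as mapping
#' reference), plus the backbone features the discovery scenario needs: a
#' 7-bp T homopolymer and two non-repetitive 2-bp deletion contexts. The
#' per-continent cassettes realize the panel's expected amplicon lengths and
#' digest patterns exactly; construction is verified by running the in-silico
#' assay on every continent haplotype and deterministically re-drawn (from
#' the same master seed) in the astronomically unlikely event of a collision
#' such as a chance second primer site.
#'
#' @param config A [simulation_config()].
#' @param panel A `marker_panel` (default: the packaged panel).
#' @return A `cp_reference`: list with `reference` (a
#'   [reference_sequence()]), `panel`, `segments`, `cassettes` (per
#'   continent), `planted` (truth table of the fixed differences carried by
#'   the European pool relative to the Asian reference) and `config`.
#' @export
generate_reference <- function(config = simulation_config(),
                               panel = default_panel()) {
  stopifnot(inherits(config, "sim_config"), inherits(panel, "marker_panel"))
  for (attempt in 0:19) {
    set.seed(sub_seed(config$seed, 1L + attempt * 1000L))
    obj <- try(build_reference_once(config, panel), silent = TRUE)
    if (!inherits(obj, "try-error") && reference_is_valid(obj)) return(obj)
    if (inherits(obj, "try-error") &&
        inherits(attr(obj, "condition"), "oakorigin_config_error")) {
      stop(attr(obj, "condition"))
    }
  }
  abort_oak("failed to construct a valid synthetic reference", "oakorigin_config_error")
}

build_reference_once <- function(config, panel) {
  cassettes <- build_cassettes(panel)
  locus_order <- names(panel$loci)
  asia_len <- sum(nchar(cassettes$Asia))
  n_seg <- length(locus_order) + 1L
  backbone_total <- config$reference_length - asia_len
  if (backbone_total < n_seg * 60L) {
    abort_oak(sprintf(
      "reference_length %d too short for the panel (need >= %d)",
      config$reference_length, asia_len + n_seg * 60L),
      "oakorigin_config_error")
  }
  seg_len <- rep(backbone_total %/% n_seg, n_seg)
  seg_len[n_seg] <- seg_len[n_seg] + backbone_total %% n_seg
  segments <- lapply(seg_len, random_dna)

  # backbone features for the discovery scenario, planted mid-segment
  mid <- function(i) seg_len[i] %/% 2L
  segments[[2L]] <- `substr_set<-`(segments[[2L]], mid(2L) - 1L, "ATTTTTTTG")
  segments[[3L]] <- `substr_set<-`(segments[[3L]], mid(3L) - 3L, "ATGCGTAC")
  segments[[5L]] <- `substr_set<-`(segments[[5L]], mid(5L) - 3L, "CATGACTT")

  # assemble the Asian reference and record cassette start positions
  pieces <- character(0)
  cassette_start <- integer(length(locus_order))
  pos <- 0L
  for (i in seq_along(locus_order)) {
    pieces <- c(pieces, segments[[i]])
    pos <- pos + seg_len[i]
    cassette_start[i] <- pos + 1L
    pieces <- c(pieces, cassettes$Asia[[locus_order[i]]])
    pos <- pos + nchar(cassettes$Asia[[locus_order[i]]])
  }
  pieces <- c(pieces, segments[[n_seg]])
  asia_seq <- paste(pieces, collapse = "")
  names(cassette_start) <- locus_order
  reference <- reference_sequence("cp_ref", asia_seq)

  planted <- planted_truth(panel, cassettes, cassette_start, seg_len, reference)
  structure(list(reference = reference, panel = panel, segments = segments,
                 segment_lengths = seg_len, cassettes = cassettes,
                 cassette_start = cassette_start, locus_order = locus_order,
                 planted = planted, config = config),
            class = "cp_reference")
}

# fixed differences carried by the European pool relative to the Asian
# reference: the two Eurasian spacer indels (Europe has insertions where Asia
# is deleted), the PCR-RFLP SNP, plus the extra planted indels the triage
# rules must reject (a homopolymer 1-bp insertion and two 2-bp deletions).
planted_truth <- function(panel, cassettes, cassette_start, seg_len, reference) {
  ref_seq <- reference$sequence
  rows <- list()
  add <- function(label, position, var_type, length, ref_allele, alt_allele) {
    rows[[length(rows) + 1L]] <<- data.frame(
      label = label, ref_name = reference$id, position = position,
      var_type = var_type, length = length, ref_allele = ref_allele,
      alt_allele = alt_allele, stringsAsFactors = FALSE)
  }
  for (nm in names(panel$loci)) {
    l <- panel$loci[[nm]]
    d <- l$expected_lengths[["Europe"]] - l$expected_lengths[["Asia"]]
    f_len <- nchar(l$forward_primer$seq)
    if (is.null(l$digest)) {
      if (d > 0L) {
        # Asia lacks d bases that Europe carries after insert offset 39
        anchor <- cassette_start[[nm]] - 1L + f_len + 39L
        add(nm, anchor, "insertion", d, "-", indel_window(d))
      }
    } else {
      # the SNP creating Asia's second restriction site
      lab <- l$digest$expected_labeled
      snp_pos <- cassette_start[[nm]] - 1L +
        l$expected_lengths[["Asia"]] - lab$Asia[2L] + 4L
      add(paste0(nm, "_SNP"), snp_pos, "SNP", 1L,
          substr(ref_seq, snp_pos, snp_pos), "G")
    }
  }
  mid <- function(i) seg_len[i] %/% 2L
  seg_start <- function(i) {
    # segment i begins after i-1 segments and i-1 cassettes
    sum(seg_len[seq_len(i - 1L)]) +
      sum(vapply(cassettes$Asia, nchar, integer(1))[seq_len(i - 1L)]) + 1L
  }
  # 1-bp T insertion anchored inside the 7-T homopolymer run
  t_anchor <- seg_start(2L) - 1L + mid(2L) + 3L
  add("homopolymer_T", t_anchor, "insertion", 1L, "-", "T")
  # two 2-bp deletions in non-repetitive context
  del1 <- seg_start(3L) - 1L + mid(3L)
  add("short_indel_1", del1, "deletion", 2L,
      substr(ref_seq, del1, del1 + 1L), "-")
  del2 <- seg_start(5L) - 1L + mid(5L)
  add("short_indel_2", del2, "deletion", 2L,
      substr(ref_seq, del2, del2 + 1L), "-")
  out <- do.call(rbind, rows)
  # internal consistency: deletion/SNP ref alleles must equal the reference
  for (i in seq_len(nrow(out))) {
    if (out$var_type[i] %in% c("deletion", "SNP")) {
      stopifnot(substr(ref_seq, out$position[i],
                       out$position[i] + nchar(out$ref_allele[i]) - 1L) ==
                  out$ref_allele[i])
    }
  }
  out[order(out$position), , drop = FALSE]
}

reference_is_valid <- function(obj) {
  ok <- tryCatch({
    for (cont in CONTINENTS) {
      hap <- generate_haplotype(obj, cont)
      prof <- profile_specimen(hap, obj$panel, cont)
      for (nm in names(obj$panel$loci)) {
        l <- obj$panel$loci[[nm]]
        want <- if (!is.null(l$digest)) {
          sort(l$digest$expected_labeled[[cont]], decreasing = TRUE)
        } else {
          l$expected_lengths[[cont]]
        }
        if (!identical(as.integer(prof$observations[[nm]]), as.integer(want))) {
          return(FALSE)
        }
      }
    }
    # the homopolymer run must be intact
    run <- gregexpr("ATTTTTTTG", obj$reference$sequence)[[1L]]
    length(run) == 1L && run[1L] > 0L
  }, error = function(e) FALSE)
  isTRUE(ok)
}

#' Assemble a continent haplotype
#'
#' Interleaves the shared backbone segments with the continent's locus
#' cassettes; the in-silico assay on the result reproduces that continent's
#' expected fragment-length row exactly.
#'
#' @param ref A `cp_reference` from [generate_reference()].
#' @param continent `"Asia"`, `"Europe"` or `"NorthAmerica"`.
#' @return A DNA string.
#' @export
generate_haplotype <- function(ref, continent) {
  stopifnot(inherits(ref, "cp_reference"))
  continent <- match.arg(continent, CONTINENTS)
  pieces <- character(0)
  for (i in seq_along(ref$locus_order)) {
    pieces <- c(pieces, ref$segments[[i]],
                ref$cassettes[[continent]][[ref$locus_order[i]]])
  }
  paste(c(pieces, ref$segments[[length(ref$segments)]]), collapse = "")
}

#' Simulate pooled-sequencing variant and coverage tables
#'
#' Produces per-sample variant call tables for two pools mapped against the
#' Asian reference: an Asian pool carrying only low-frequency private noise,
#' and a European pool in which every planted fixed difference of
#' `ref$planted` is called in every individual at a frequency drawn from
#' `fixed_freq_range`. Noise calls are private SNPs at `noise_rate` per kb
#' per sample with frequencies from `noise_freq_range`; coverage is
#' negative-binomial around `coverage_mean`; supporting reads split between
#' strands by `fwd_rev_split`. Sparse coverage tables are emitted at all
#' variant positions so that non-calling samples can be classified as
#' reference-matching. Fully reproducible under the configuration seed.
#'
#' @param config A [simulation_config()].
#' @param ref A `cp_reference` from [generate_reference()].
#' @return A list with `variant_tables` (named list of per-sample call data
#'   frames), `coverage_tables`, `groups` (data frame `sample_id`, `group`
#'   with groups `"Asia"` and `"Europe"`) and `truth` (the planted table).
#' @export
simulate_variant_tables <- function(config, ref) {
  stopifnot(inherits(config, "sim_config"), inherits(ref, "cp_reference"))
  set.seed(sub_seed(config$seed, 2L))
  n <- config$n_individuals
  samples_a <- sprintf("asia_%02d", seq_len(n))
  samples_b <- sprintf("eur_%02d", seq_len(n))
  L <- ref$reference$length
  ref_seq <- ref$reference$sequence
  planted <- ref$planted
  forbidden <- unique(unlist(lapply(seq_len(nrow(planted)), function(i) {
    planted$position[i] + seq(-2L, planted$length[i] + 1L)
  })))

  draw_cov <- function(k) {
    pmax(stats::rnbinom(k, mu = config$coverage_mean,
                        size = config$coverage_dispersion), 4L)
  }
  call_row <- function(sample, position, var_type, len, ref_allele, alt_allele,
                       freq) {
    cov <- draw_cov(1L)
    alt_reads <- min(cov, round(cov * freq / 100))
    fwd <- stats::rbinom(1L, alt_reads, config$fwd_rev_split)
    data.frame(sample_id = sample, ref_name = ref$reference$id,
               position = position, var_type = var_type, length = len,
               ref_allele = ref_allele, alt_allele = alt_allele,
               frequency_pct = freq, coverage = cov,
               forward_count = fwd, reverse_count = alt_reads - fwd,
               stringsAsFactors = FALSE)
  }
  noise_calls <- function(sample) {
    k <- stats::rpois(1L, config$noise_rate * L / 1000)
    if (k == 0L) return(NULL)
    pos <- sample.int(L, 2L * k + 10L)
    pos <- setdiff(pos, forbidden)[seq_len(min(k, length(setdiff(pos, forbidden))))]
    if (!length(pos)) return(NULL)
    do.call(rbind, lapply(pos, function(p) {
      b <- substr(ref_seq, p, p)
      alt <- sample(setdiff(c("A", "C", "G", "T"), b), 1L)
      call_row(sample, p, "SNP", 1L, b, alt,
               stats::runif(1L, config$noise_freq_range[1L],
                            config$noise_freq_range[2L]))
    }))
  }

  variant_tables <- list()
  for (s in samples_a) {
    tab <- noise_calls(s)
    variant_tables[[s]] <- tab %||% empty_call_table()
  }
  for (s in samples_b) {
    fixed <- do.call(rbind, lapply(seq_len(nrow(planted)), function(i) {
      call_row(s, planted$position[i], planted$var_type[i], planted$length[i],
               planted$ref_allele[i], planted$alt_allele[i],
               stats::runif(1L, config$fixed_freq_range[1L],
                            config$fixed_freq_range[2L]))
    }))
    tab <- rbind(fixed, noise_calls(s))
    variant_tables[[s]] <- tab[order(tab$position), , drop = FALSE]
  }

  all_pos <- sort(unique(unlist(lapply(variant_tables, `[[`, "position"))))
  coverage_tables <- lapply(stats::setNames(nm = c(samples_a, samples_b)),
                            function(s) {
    data.frame(sample_id = s, ref_name = ref$reference$id, position = all_pos,
               depth = draw_cov(length(all_pos)), stringsAsFactors = FALSE)
  })

  groups <- data.frame(sample_id = c(samples_a, samples_b),
                       group = rep(c("Asia", "Europe"), each = n),
                       stringsAsFactors = FALSE)
  list(variant_tables = variant_tables, coverage_tables = coverage_tables,
       groups = groups, truth = planted)
}

empty_call_table <- function() {
  data.frame(sample_id = character(0), ref_name = character(0),
             position = integer(0), var_type = character(0),
             length = integer(0), ref_allele = character(0),
             alt_allele = character(0), frequency_pct = numeric(0),
             coverage = integer(0), forward_count = integer(0),
             reverse_count = integer(0), stringsAsFactors = FALSE)
}

#' Write a simulated data set to disk
#'
#' Writes the reference FASTA, the panel JSON, and per-sample variant and
#' coverage CSVs in the canonical dialect under `dir`
#' (`variants/<sample>.csv`, `coverage/<sample>.csv`), plus `groups.csv` and
#' the planted truth table.
#'
#' @param sim Result of [simulate_variant_tables()].
#' @param ref The `cp_reference` the simulation ran against.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, ref, dir) {
  dir.create(file.path(dir, "variants"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "coverage"), recursive = TRUE, showWarnings = FALSE)
  write_fasta(ref$reference, file.path(dir, "reference.fa"))
  write_panel(ref$panel, file.path(dir, "panel.json"))
  for (s in names(sim$variant_tables)) {
    write_variant_table(sim$variant_tables[[s]],
                        file.path(dir, "variants", paste0(s, ".csv")))
    write_coverage_table(sim$coverage_tables[[s]],
                         file.path(dir, "coverage", paste0(s, ".csv")))
  }
  utils::write.csv(sim$groups, file.path(dir, "groups.csv"), row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(sim$truth, file.path(dir, "truth.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(dir)
}
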