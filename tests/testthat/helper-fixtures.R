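# Shared fixtures: small hand-built call sets, a random-data generator for
# property tests, and a brute-force per-position recount of the matrix
# summary statistics used as the independent oracle.

ref_500 <- function(seed = 42L) {
  set.seed(seed)
  reference_sequence("r1", paste(sample(c("A", "C", "G", "T"), 500, TRUE),
                                 collapse = ""))
}

call_df <- function(sample_id, position, var_type = "SNP", length = 1L,
                    ref_allele = "A", alt_allele = "G", frequency_pct = 100,
                    coverage = 20L, forward_count = 10L, reverse_count = 10L,
                    ref_name = "r1") {
  data.frame(sample_id = sample_id, ref_name = ref_name, position = position,
             var_type = var_type, length = length, ref_allele = ref_allele,
             alt_allele = alt_allele, frequency_pct = frequency_pct,
             coverage = coverage, forward_count = forward_count,
             reverse_count = reverse_count, stringsAsFactors = FALSE)
}

cov_df <- function(sample_id, position, depth, ref_name = "r1") {
  data.frame(sample_id = sample_id, ref_name = ref_name, position = position,
             depth = as.integer(depth), stringsAsFactors = FALSE)
}

snp_at <- function(ref, pos) {
  b <- substr(ref$sequence, pos, pos)
  list(ref = b, alt = setdiff(c("A", "C", "G", "T"), b)[1L])
}

# random multi-sample call/coverage set over a 500-bp reference
make_random_dataset <- function(seed) {
  set.seed(seed)
  ref <- reference_sequence("r1", paste(sample(c("A", "C", "G", "T"), 500, TRUE),
                                        collapse = ""))
  n_samples <- sample(1:5, 1)
  samples <- paste0("S", seq_len(n_samples))
  n_var <- sample(1:30, 1)
  pos <- sort(sample(seq(10L, 480L, by = 6L), n_var))
  calls <- list()
  for (i in seq_len(n_var)) {
    type <- sample(c("SNP", "MNP", "insertion", "deletion"), 1)
    len <- switch(type, SNP = 1L, MNP = sample(2:4, 1), sample(1:4, 1))
    p <- pos[i]
    ref_a <- switch(type,
      insertion = "-",
      substr(ref$sequence, p, p + len - 1L))
    alt_a <- switch(type,
      SNP = sample(setdiff(c("A", "C", "G", "T"), ref_a), 1),
      MNP = chartr("ACGT", "TGCA", ref_a),
      deletion = "-",
      insertion = paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = ""))
    carriers <- sample(samples, sample(seq_len(n_samples), 1))
    for (s in carriers) {
      cov <- sample(10:50, 1)
      freq <- runif(1, 50, 100)
      alt_reads <- min(cov, round(cov * freq / 100))
      fwd <- rbinom(1, alt_reads, 0.5)
      calls[[length(calls) + 1L]] <- call_df(
        s, p, type, len, ref_a, alt_a, freq, cov, fwd, alt_reads - fwd)
    }
  }
  calls <- do.call(rbind, calls)
  coverage <- do.call(rbind, lapply(samples, function(s) {
    cov_df(s, pos, sample(0:30, n_var, replace = TRUE))
  }))
  list(ref = ref, calls = calls, coverage = coverage, samples = samples)
}

# brute-force oracle: recount the three summary statistics per variant row
oracle_row_stats <- function(calls, coverage, min_cov = 8L) {
  samples <- sort(unique(calls$sample_id))
  key <- paste(calls$ref_name, calls$position, calls$var_type, calls$length,
               sep = "\r")
  rows <- lapply(split(seq_len(nrow(calls)), key), function(idx) {
    g <- calls[idx, , drop = FALSE]
    n_match <- 0L
    for (s in setdiff(samples, g$sample_id)) {
      d <- coverage$depth[coverage$sample_id == s &
                          coverage$ref_name == g$ref_name[1L] &
                          coverage$position == g$position[1L]]
      if (length(d) && d[1L] >= min_cov) n_match <- n_match + 1L
    }
    keep <- g$forward_count + g$reverse_count > 0L
    bal <- if (any(keep)) {
      mean((pmin(g$forward_count, g$reverse_count) /
              (g$forward_count + g$reverse_count))[keep])
    } else NA_real_
    data.frame(ref_name = g$ref_name[1L], position = g$position[1L],
               type = g$var_type[1L], length = g$length[1L],
               n_deviating = nrow(g), n_matching_min_cov = n_match,
               mean_fr_balance = bal, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$ref_name, out$position, out$type, out$length), , drop = FALSE]
}

write_lines_tmp <- function(lines, ext = ".csv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
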