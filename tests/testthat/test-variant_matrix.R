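test_that("merging applies the REF-MATCH / NO-DATA coverage rule", {
  ref <- ref_500()
  s <- snp_at(ref, 100)
  one_call <- list(call_df("S1", 100, ref_allele = s$ref, alt_allele = s$alt))

  # S2 covered at depth 15 >= 8 -> REF-MATCH
  m <- merge_variant_tables(one_call, ref,
                            coverage = list(cov_df("S2", 100, 15)))
  expect_equal(m$table$n_deviating, 1L)
  expect_equal(m$table$n_matching_min_cov, 1L)
  expect_equal(m$table$alt_S2, "REF-MATCH")

  # depth below the threshold -> NO-DATA
  m2 <- merge_variant_tables(c(one_call, list(call_df("S2", 200))), ref,
                             coverage = list(cov_df("S2", 100, 5)))
  expect_equal(m2$table$alt_S2[m2$table$position == 100], "NO-DATA")

  # without coverage tables all non-calling samples are NO-DATA
  m3 <- merge_variant_tables(c(one_call, list(call_df("S2", 200))), ref)
  expect_equal(m3$table$alt_S2[m3$table$position == 100], "NO-DATA")
  expect_equal(m3$table$n_matching_min_cov, c(0L, 0L))

  # both samples deviate
  m4 <- merge_variant_tables(
    c(one_call, list(call_df("S2", 100, ref_allele = s$ref, alt_allele = s$alt))),
    ref)
  expect_equal(m4$table$n_deviating, 2L)
  expect_equal(m4$table$n_matching_min_cov, 0L)

  # no tables -> empty matrix
  expect_equal(nrow(merge_variant_tables(list(), ref)$table), 0L)
})

test_that("merging rejects inconsistent input", {
  ref <- ref_500()
  expect_error(merge_variant_tables(list(call_df("S1", 600)), ref),
               "beyond", class = "oakorigin_consistency_error")
  expect_error(
    merge_variant_tables(list(rbind(call_df("S1", 100, ref_allele = "A", alt_allele = "G"),
                                    call_df("S1", 100, ref_allele = "A", alt_allele = "C"))),
                         ref),
    "duplicate", class = "oakorigin_input_error")
  expect_error(merge_variant_tables(list(call_df("S1", 10, ref_name = "nope")),
                                    ref),
               "unknown reference", class = "oakorigin_consistency_error")
})

test_that("events sharing a position but differing in type or span split rows", {
  ref <- ref_500()
  s <- snp_at(ref, 100)
  del2 <- substr(ref$sequence, 100, 101)
  m <- merge_variant_tables(
    list(call_df("S1", 100, "SNP", 1L, s$ref, s$alt),
         call_df("S2", 100, "deletion", 2L, del2, "-")),
    ref)
  expect_equal(nrow(m$table), 2L)
  expect_setequal(m$table$type, c("SNP", "deletion"))
})

test_that("forward/reverse balance is the mean of min(F,R)/(F+R) over supported calls", {
  expect_equal(mean_forward_reverse_balance(call_df("S1", 1, forward_count = 10L,
                                                    reverse_count = 10L)), 0.5)
  expect_equal(mean_forward_reverse_balance(call_df("S1", 1, forward_count = 20L,
                                                    reverse_count = 0L)), 0)
  two <- rbind(call_df("S1", 1, forward_count = 9L, reverse_count = 3L),
               call_df("S2", 1, forward_count = 3L, reverse_count = 9L))
  expect_equal(mean_forward_reverse_balance(two), 0.25)
  # unsupported calls are skipped; all-unsupported is undefined
  three <- rbind(two, call_df("S3", 1, forward_count = 0L, reverse_count = 0L))
  expect_equal(mean_forward_reverse_balance(three), 0.25)
  none <- call_df("S1", 1, forward_count = 0L, reverse_count = 0L)
  expect_true(is.na(mean_forward_reverse_balance(none)))
})

test_that("flanking sequences follow the dual-threshold rule per side", {
  set.seed(7)
  ref <- reference_sequence("r1", paste(sample(c("A", "C", "G", "T"), 2000, TRUE),
                                        collapse = ""))
  pol <- flank_policy(50, 75)

  # isolated variant: full upper-threshold flanks
  fl <- flanking_sequences(ref, 1000L, 1000L, pol)
  expect_equal(nchar(fl$left), 75L)
  expect_equal(nchar(fl$right), 75L)
  expect_equal(fl$left, substr(ref$sequence, 925, 999))
  expect_equal(fl$right, substr(ref$sequence, 1001, 1075))

  # right neighbour at distance 60 (between thresholds) -> lower-length flank
  fl2 <- flanking_sequences(ref, c(1000L, 1060L), 1000L, pol)
  expect_equal(nchar(fl2$left), 75L)
  expect_equal(nchar(fl2$right), 50L)

  # neighbour at exactly the lower threshold -> no flank on that side
  fl3 <- flanking_sequences(ref, c(950L, 1000L), 1000L, pol)
  expect_equal(fl3$left, "")
  expect_equal(nchar(fl3$right), 75L)

  # neighbour at exactly the upper threshold -> lower-length flank
  fl4 <- flanking_sequences(ref, c(1000L, 1075L), 1000L, pol)
  expect_equal(nchar(fl4$right), 50L)

  # truncation at the contig start
  fl5 <- flanking_sequences(ref, 10L, 10L, pol)
  expect_equal(fl5$left, substr(ref$sequence, 1, 9))
  expect_equal(nchar(fl5$left), 9L)

  # truncation at the contig end
  fl6 <- flanking_sequences(ref, 1990L, 1990L, pol, footprint = 1L)
  expect_equal(nchar(fl6$right), 10L)

  expect_error(flanking_sequences(ref, c(10L, 20L), 15L, pol),
               class = "oakorigin_input_error")
})

test_that("matrix flanks exclude the focal footprint and match the reference", {
  ref <- ref_500()
  del <- substr(ref$sequence, 200, 203)
  m <- merge_variant_tables(list(call_df("S1", 200, "deletion", 4L, del, "-")),
                            ref)
  expect_equal(m$table$left_flank, substr(ref$sequence, 125, 199))
  expect_equal(m$table$right_flank, substr(ref$sequence, 204, 278))
})

test_that("frequency filtering is inclusive at both bounds", {
  ref <- ref_500()
  s1 <- snp_at(ref, 100); s2 <- snp_at(ref, 300)
  m <- merge_variant_tables(
    list(rbind(call_df("S1", 100, ref_allele = s1$ref, alt_allele = s1$alt,
                       frequency_pct = 98),
               call_df("S1", 300, ref_allele = s2$ref, alt_allele = s2$alt,
                       frequency_pct = 94)),
         call_df("S2", 100, ref_allele = s1$ref, alt_allele = s1$alt,
                 frequency_pct = 100)),
    ref)
  kept <- filter_matrix(m, 95, 100)
  expect_equal(kept$table$position, 100L)   # the 94% row is removed
  expect_equal(nrow(filter_matrix(m, 0, 100)$table), nrow(m$table))  # identity
  expect_error(filter_matrix(m, 80, 60), class = "oakorigin_parameter_error")
  # type restriction
  expect_equal(nrow(filter_matrix(m, 0, 100, types = "deletion")$table), 0L)
})

test_that("merging is invariant to the order tables are supplied", {
  d <- make_random_dataset(11)
  tables <- split(d$calls, d$calls$sample_id)
  m1 <- merge_variant_tables(tables, d$ref, d$coverage)
  m2 <- merge_variant_tables(rev(tables), d$ref, d$coverage)
  expect_equal(m1$table, m2$table)
  expect_equal(m1$samples, m2$samples)
})

test_that("summary statistics agree with a brute-force per-position recount", {
  for (seed in c(1, 2, 3, 5, 8, 13, 21, 34)) {
    d <- make_random_dataset(seed)
    m <- merge_variant_tables(d$calls, d$ref, d$coverage)
    oracle <- oracle_row_stats(d$calls, d$coverage)
    expect_equal(nrow(m$table), nrow(oracle))
    expect_equal(m$table$position, oracle$position)
    expect_equal(m$table$n_deviating, oracle$n_deviating)
    expect_equal(m$table$n_matching_min_cov, oracle$n_matching_min_cov)
    expect_equal(m$table$mean_fr_balance, oracle$mean_fr_balance)
    # every row: n_deviating equals the number of non-token cells
    alt_cols <- paste0("alt_", m$samples)
    for (i in seq_len(nrow(m$table))) {
      cells <- as.character(m$table[i, alt_cols])
      expect_equal(m$table$n_deviating[i],
                   sum(!cells %in% c("REF-MATCH", "NO-DATA")))
    }
    # flanks always equal the corresponding reference substring
    for (i in seq_len(nrow(m$table))) {
      lf <- m$table$left_flank[i]
      if (nzchar(lf)) {
        p <- m$table$position[i]
        expect_equal(lf, substr(d$ref$sequence, p - nchar(lf), p - 1L))
      }
    }
  }
})
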