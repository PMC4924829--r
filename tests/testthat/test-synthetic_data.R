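test_that("reference construction is deterministic under the seed", {
  r1 <- generate_reference(simulation_config(seed = 5))
  r2 <- generate_reference(simulation_config(seed = 5))
  r3 <- generate_reference(simulation_config(seed = 6))
  expect_identical(r1$reference$sequence, r2$reference$sequence)
  expect_identical(r1$planted, r2$planted)
  expect_false(identical(r1$reference$sequence, r3$reference$sequence))
  expect_equal(r1$reference$length, 20000L)
})

test_that("every panel primer occurs exactly once, in the correct orientation", {
  ref <- generate_reference(simulation_config(seed = 5))
  for (cont in c("Asia", "Europe", "NorthAmerica")) {
    hap <- Biostrings::DNAString(generate_haplotype(ref, cont))
    for (l in ref$panel$loci) {
      expect_equal(Biostrings::countPattern(l$forward_primer$seq, hap), 1L)
      expect_equal(Biostrings::countPattern(
        Biostrings::reverseComplement(Biostrings::DNAString(l$reverse_primer$seq)),
        hap), 1L)
      # and never on the wrong strand
      expect_equal(Biostrings::countPattern(
        Biostrings::reverseComplement(Biostrings::DNAString(l$forward_primer$seq)),
        hap), 0L)
    }
  }
})

test_that("Eurasian haplotypes differ by the 4-bp and 6-bp spacer indels", {
  ref <- generate_reference(simulation_config(seed = 5))
  asia <- generate_haplotype(ref, "Asia")
  europe <- generate_haplotype(ref, "Europe")
  d_psaI <- amplify(europe, ref$panel$loci[["psaI-ycf4"]])$length -
    amplify(asia, ref$panel$loci[["psaI-ycf4"]])$length
  d_psbE <- amplify(europe, ref$panel$loci[["psbE-petL"]])$length -
    amplify(asia, ref$panel$loci[["psbE-petL"]])$length
  expect_equal(d_psaI, 4L)
  expect_equal(d_psbE, 6L)
  # the Old World loci are identical between Asia and Europe
  expect_equal(amplify(asia, ref$panel$loci[["trnLF"]])$length,
               amplify(europe, ref$panel$loci[["trnLF"]])$length)
})

test_that("a reference too short for the panel is rejected", {
  expect_error(generate_reference(simulation_config(seed = 1,
                                                    reference_length = 1000L)),
               "too short", class = "oakorigin_config_error")
})

test_that("planted truth matches the reference sequence it annotates", {
  ref <- generate_reference(simulation_config(seed = 9))
  tr <- ref$planted
  expect_setequal(tr$var_type, c("insertion", "deletion", "SNP"))
  expect_equal(sort(tr$length[tr$var_type != "SNP"]), c(1L, 2L, 2L, 4L, 6L))
  for (i in which(tr$var_type %in% c("deletion", "SNP"))) {
    expect_equal(substr(ref$reference$sequence, tr$position[i],
                        tr$position[i] + nchar(tr$ref_allele[i]) - 1L),
                 tr$ref_allele[i])
  }
  # the homopolymer insertion is anchored inside a T run
  hp <- tr[tr$label == "homopolymer_T", ]
  expect_equal(substr(ref$reference$sequence, hp$position, hp$position), "T")
  expect_equal(classify_repeat_context(ref$reference, as.list(hp)), "homopolymer")
})

test_that("simulation without noise produces exactly the planted calls", {
  cfg <- simulation_config(seed = 3, noise_rate = 0)
  ref <- generate_reference(cfg)
  sim <- simulate_variant_tables(cfg, ref)
  asia <- sim$variant_tables[sim$groups$group == "Asia"]
  europe <- sim$variant_tables[sim$groups$group == "Europe"]
  expect_true(all(vapply(asia, nrow, integer(1)) == 0L))
  for (tab in europe) {
    expect_equal(sort(tab$position), sort(ref$planted$position))
    expect_true(all(tab$frequency_pct >= 95 & tab$frequency_pct <= 100))
    expect_true(all(tab$forward_count + tab$reverse_count <= tab$coverage))
  }
})

test_that("simulated tables are byte-identical across runs with one seed", {
  cfg <- simulation_config(seed = 17, reference_length = 5000L,
                           n_individuals = 4L)
  out1 <- tempfile(); out2 <- tempfile()
  for (d in c(out1, out2)) {
    ref <- generate_reference(cfg)
    write_simulation(simulate_variant_tables(cfg, ref), ref, d)
  }
  files <- list.files(out1, recursive = TRUE)
  expect_true(length(files) > 10L)
  for (f in files) {
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)), label = f)
  }
})

test_that("the full pipeline recovers exactly the planted fixed differences", {
  cfg <- simulation_config(seed = 23)
  ref <- generate_reference(cfg)
  sim <- simulate_variant_tables(cfg, ref)
  ma <- merge_variant_tables(sim$variant_tables[sim$groups$group == "Asia"],
                             ref$reference,
                             sim$coverage_tables[sim$groups$group == "Asia"])
  mb <- merge_variant_tables(sim$variant_tables[sim$groups$group == "Europe"],
                             ref$reference,
                             sim$coverage_tables[sim$groups$group == "Europe"])
  cand <- fixed_differences(ma, mb, min_freq_pct = 95,
                            reference = ref$reference)
  # the screen recovers the planted set and nothing else
  expect_setequal(cand$position, ref$planted$position)
  expect_equal(sum(cand$type %in% c("insertion", "deletion")), 5L)
  # triage leaves exactly the two longest spacer indels
  sel <- select_indel_markers(cand, min_length_diff_bp = 4)
  chosen <- sel[sel$status == "selected", ]
  expect_equal(chosen$length_diff_bp, c(6L, 4L))
  expect_setequal(
    chosen$position,
    ref$planted$position[ref$planted$label %in% c("psaI-ycf4", "psbE-petL")])
  # assignment of generated haplotypes returns the intended continent
  for (cont in c("Asia", "Europe", "NorthAmerica")) {
    prof <- profile_specimen(generate_haplotype(ref, cont), ref$panel, cont)
    expect_equal(assign_continent(prof, ref$panel)$verdict, cont)
  }
})

test_that("boundary frequencies behave as planted: 95 passes, 94 does not", {
  ref <- generate_reference(simulation_config(seed = 4, reference_length = 5000L))
  b <- ref$reference$sequence
  pos <- c(1200L, 1210L)
  mk <- function(freq, p) {
    s <- substr(b, p, p)
    call_df("P1", p, ref_allele = s, alt_allele = setdiff(c("A","C","G","T"), s)[1],
            frequency_pct = freq, ref_name = ref$reference$id)
  }
  ma <- merge_variant_tables(list(rbind(mk(95, pos[1]), mk(94, pos[2]))),
                             ref$reference)
  mb <- merge_variant_tables(list(), ref$reference)
  cand <- fixed_differences(ma, mb)
  expect_equal(cand$position, pos[1])
})
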