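# a fixed reference carrying the panel, shared across assay tests
assay_ref <- generate_reference(simulation_config(seed = 101L))
assay_panel <- assay_ref$panel
haps <- sapply(c("Asia", "Europe", "NorthAmerica"), function(cont) {
  generate_haplotype(assay_ref, cont)
})

test_that("primer sites are located on either strand, uniquely", {
  tpl <- "ACGTACGTTTGCAGGCATTACCGGATCCA"
  p <- substr(tpl, 1, 16)
  hit <- find_primer_site(tpl, p)
  expect_equal(hit$position, 1L)
  expect_equal(hit$strand, "forward")

  # primer equal to the reverse complement of a template suffix
  suffix <- substr(tpl, 14, 29)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(suffix)))
  hit2 <- find_primer_site(tpl, rc)
  expect_equal(hit2$position, 14L)
  expect_equal(hit2$strand, "reverse")

  # two equally good sites are an ambiguity, absence is NULL
  twice <- paste0(p, "TTTTTTTTTT", p)
  expect_error(find_primer_site(twice, p), class = "oakorigin_ambiguity_error")
  expect_null(find_primer_site(tpl, "GGGGGGGGGGGGGGGG"))

  # one mismatch is found when allowed
  p_mut <- paste0("T", substr(p, 2, 16))
  expect_null(find_primer_site(tpl, p_mut, max_mismatch = 0))
  expect_equal(find_primer_site(tpl, p_mut, max_mismatch = 1)$position, 1L)
})

test_that("amplicon lengths on continent haplotypes match the panel expectations", {
  for (cont in names(haps)) {
    for (nm in names(assay_panel$loci)) {
      amp <- amplify(haps[[cont]], assay_panel$loci[[nm]], locus = nm)
      expect_equal(amp$length, assay_panel$loci[[nm]]$expected_lengths[[cont]],
                   info = paste(cont, nm))
      expect_equal(nchar(amp$sequence), amp$length)
      expect_equal(amp$end - amp$start + 1L, amp$length)
    }
  }
})

test_that("amplification fails cleanly without a primer site or with inverted primers", {
  pair <- primer_pair(strrep("ACGT", 5), strrep("GTCA", 5))
  expect_null(amplify("TTTTTTTTTTTTTTTTTTTTTTTTTTTTTT", pair))
  # reverse site upstream of forward site -> no product
  tpl <- paste0(revcomp_str <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(strrep("GTCA", 5)))),
    "AAAAAAAAAA", strrep("ACGT", 5))
  expect_null(amplify(tpl, pair))
  # product-size cap
  amp_tpl <- paste0(strrep("ACGT", 5), strrep("A", 100), revcomp_str)
  expect_false(is.null(amplify(amp_tpl, pair)))
  expect_null(amplify(amp_tpl, pair, max_product_bp = 100L))
})

test_that("digestion cuts at every HinfI site and conserves total length", {
  trnDT <- assay_panel$loci[["trnDT"]]
  enz <- hinfI()

  asia <- digest(amplify(haps[["Asia"]], trnDT), enz)
  expect_equal(nrow(asia), 3L)
  expect_setequal(asia$length, c(86L, 71L, 30L))
  expect_equal(sum(asia$length), 187L)
  expect_equal(sum(asia$carries_5prime), 1L)
  expect_equal(sum(asia$carries_3prime), 1L)

  europe <- digest(amplify(haps[["Europe"]], trnDT), enz)
  expect_equal(sort(europe$length), c(86L, 101L))
  na <- digest(amplify(haps[["NorthAmerica"]], trnDT), enz)
  expect_equal(sort(na$length), c(88L, 101L))

  # no recognition site -> a single fragment carrying both ends
  uncut <- digest("ACGTACGTACGT", enz)
  expect_equal(uncut$length, 12L)
  expect_true(uncut$carries_5prime & uncut$carries_3prime)
})

test_that("digest conservation and strand symmetry hold on random sequences", {
  set.seed(99)
  enz <- hinfI()
  # GANTC is its own reverse-complement class, so the bottom strand carries a
  # site wherever the top strand does; HinfI leaves 3-nt 5' overhangs, so the
  # bottom-strand cut mirrors the top-strand cut with offset |site| - 1
  enz_bottom <- restriction_enzyme("HinfI-bottom", "GANTC", 4L)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
    d <- digest(s, enz)
    expect_equal(sum(d$length), 300L)
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    # the two strands see the same number of cuts...
    d_rc <- digest(rc, enz)
    expect_equal(nrow(d_rc), nrow(d))
    # ...and with the mirrored cut offset, identical fragment boundaries
    d_mirror <- digest(rc, enz_bottom)
    expect_equal(d_mirror$length, rev(d$length))
  }
})

test_that("only fragments retaining a labeled amplicon end are visible", {
  trnDT <- assay_panel$loci[["trnDT"]]
  asia_amp <- amplify(haps[["Asia"]], trnDT)
  res <- digest(asia_amp, hinfI())
  expect_equal(visible_fragments(res, asia_amp$pair), c(86L, 71L))

  # uncut amplicon, single labeled primer
  pair1 <- primer_pair(strrep("ACGT", 5), strrep("GTCA", 5), forward_dye = "FAM")
  uncut <- digest("ACGTACGTACGTACGTACGT", hinfI())
  expect_equal(visible_fragments(uncut, pair1), 20L)

  # no labeled primer -> nothing visible
  pair0 <- primer_pair(strrep("ACGT", 5), strrep("GTCA", 5))
  expect_length(visible_fragments(res, pair0), 0L)
})

test_that("specimen profiling reproduces the per-continent fragment rows", {
  expected <- list(
    Asia = list(`psaI-ycf4` = 174L, `psbE-petL` = 179L, trnLF = 135L,
                trnCD = 123L, trnDT = c(86L, 71L)),
    Europe = list(`psaI-ycf4` = 178L, `psbE-petL` = 185L, trnLF = 135L,
                  trnCD = 123L, trnDT = c(101L, 86L)),
    NorthAmerica = list(`psaI-ycf4` = 178L, `psbE-petL` = 185L, trnLF = 130L,
                        trnCD = 115L, trnDT = c(101L, 88L)))
  for (cont in names(expected)) {
    prof <- profile_specimen(haps[[cont]], assay_panel, cont)
    expect_equal(prof$observations, expected[[cont]], info = cont)
  }
})

test_that("a locus whose primer site is destroyed profiles as missing data", {
  hap <- haps[["Asia"]]
  fwd <- assay_panel$loci[["trnLF"]]$forward_primer$seq
  pos <- regexpr(fwd, hap, fixed = TRUE)
  expect_gt(pos, 0L)
  broken <- hap
  # scramble the first 6 bases of the primer site
  substr(broken, pos, pos + 5L) <- "NNNNNN"
  broken <- gsub("N", "C", broken)  # keep a clean alphabet
  prof <- profile_specimen(broken, assay_panel, "broken")
  expect_true(is.na(prof$observations$trnLF))
  expect_equal(prof$observations$`psaI-ycf4`, 174L)
})
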