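test_that("primer sites are found with mismatch and 3'-exact rules", {
  primer <- "ACGTACGTTGCAGGCATCAT"
  left <- paste(rep("G", 50), collapse = "")
  right <- paste(rep("C", 50), collapse = "")
  tpl <- paste0(left, primer, right)
  hit <- find_primer_sites(tpl, primer, 0)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$start, 51L)
  expect_equal(hit$strand, "+")

  # one internal mismatch: found at max_mismatches 1, not at 0
  mut <- primer
  substr(mut, 10, 10) <- "A"  # internal base change (was G at pos 10? set A)
  tpl_mut <- paste0(left, mut, right)
  expect_equal(nrow(find_primer_sites(tpl_mut, primer, 0)), 0L)
  expect_equal(nrow(find_primer_sites(tpl_mut, primer, 1)), 1L)

  # a 3'-terminal mismatch is never tolerated
  mut3 <- primer
  substr(mut3, nchar(primer), nchar(primer)) <- "A"  # 3' base was T
  tpl3 <- paste0(left, mut3, right)
  expect_equal(nrow(find_primer_sites(tpl3, primer, 2)), 0L)

  # minus strand: plant the reverse complement
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(primer)))
  tplm <- paste0(left, rc, right)
  hitm <- find_primer_sites(tplm, primer, 0)
  expect_equal(hitm$strand, "-")

  # IUPAC ambiguity codes in the primer match their base sets
  ambig <- sub("^ACGT", "ACGN", primer)
  expect_equal(nrow(find_primer_sites(tpl, ambig, 0)), 1L)

  # primer longer than template: empty result, not an error
  expect_equal(nrow(find_primer_sites("ACGT", primer, 0)), 0L)
  # invalid characters are an error
  expect_error(find_primer_sites("ACXT", primer, 0), "invalid IUPAC")
  expect_error(find_primer_sites(tpl, "AC-T", 0), "invalid IUPAC")
})

test_that("site scanning equals a brute-force sliding-window comparison", {
  set.seed(99)
  for (rep in 1:25) {
    tpl_chars <- sample(c("A", "C", "G", "T"), 600, replace = TRUE)
    primer <- paste(sample(c("A", "C", "G", "T"), 12, replace = TRUE),
                    collapse = "")
    # plant one exact copy and one mutated copy to guarantee signal
    at <- sample(1:(600 - 12), 1)
    tpl_chars[at:(at + 11)] <- strsplit(primer, "")[[1]]
    tpl <- paste(tpl_chars, collapse = "")
    for (mm in 0:1) {
      got <- sort_sites(find_primer_sites(tpl, primer, mm))
      want <- sort_sites(brute_force_sites(tpl, primer, mm))
      expect_equal(got[c("start", "end", "strand")],
                   want[c("start", "end", "strand")],
                   info = sprintf("rep %d mm %d", rep, mm))
    }
  }
})

test_that("amplicon prediction reproduces the multiplex product sizes", {
  primers <- cs_demo_primers()
  tpl <- cs_fixture_templates()
  ae <- primers[primers$name == "A-E", ]
  ab <- primers[primers$name == "alpha-beta", ]
  gb <- primers[primers$name == "gamma-B", ]

  amp <- predict_amplicons(tpl$Cs29, ae, template_id = "Cs29")
  expect_equal(nrow(amp), 1L)
  expect_equal(amp$length, 318)

  amp_wt <- predict_amplicons(tpl$wt, ab)
  expect_equal(amp_wt$length, 394)
  # the Cs29 junction pair yields nothing on the wildtype haplotype
  expect_equal(nrow(predict_amplicons(tpl$wt, ae)), 0L)

  amp_cs6 <- predict_amplicons(tpl$Cs6, gb)
  expect_equal(amp_cs6$length, 525)
})

test_that("divergent primer sites do not amplify", {
  primers <- cs_demo_primers()
  ae <- primers[primers$name == "A-E", ]
  # plant forward primer twice on the plus strand: no convergent pair
  set.seed(7)
  fwd <- ae$forward
  bg <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE), collapse = "")
  tpl <- paste0(bg, fwd, strrep("A", 50), fwd, bg)
  pair <- list(name = "AE-div", forward = fwd, reverse = fwd)
  # both sites are plus-strand only; reverse-complement sites are absent
  expect_equal(nrow(predict_amplicons(tpl, pair)), 0L)
})

test_that("product length is capped by max_product", {
  primers <- cs_demo_primers()
  gb <- primers[primers$name == "gamma-B", ]
  tpl <- cs_fixture_templates()$Cs6
  expect_equal(nrow(predict_amplicons(tpl, gb, max_product = 500)), 0L)
  expect_equal(predict_amplicons(tpl, gb, max_product = 525)$length, 525)
})

test_that("multiplex band patterns follow the allele composition", {
  tpl <- cs_fixture_templates()
  primers <- cs_demo_primers()
  pat <- function(...) multiplex_pattern(diploid_genotype(c(...)), tpl, primers)$sizes
  expect_equal(pat("Cs29", "wt"), c(318, 394))
  expect_equal(pat("wt", "wt"), 394)
  expect_equal(pat("Cs29", "Cs29"), 318)
  expect_equal(pat("Cs6", "wt"), c(394, 525))
  expect_equal(pat("Cs6", "Cs6"), c(394, 525))   # dominant-marker collapse
  expect_equal(pat("Cs29", "Cs6"), c(318, 394, 525))
  expect_error(multiplex_pattern(diploid_genotype(c("Cs9", "wt")), tpl, primers),
               "Cs9")
})

test_that("band interpretation decodes the marker table", {
  call <- interpret_bands(band_pattern(c(318, 394)))
  expect_equal(call$cs29_genotype, "het")
  expect_equal(call$cs6_status, "negative")

  call2 <- interpret_bands(band_pattern(c(318, 394, 525)))
  expect_equal(call2$cs29_genotype, "het")
  expect_equal(call2$cs6_status, "positive")
  expect_match(call2$cs6_note, "indistinguishable")

  call3 <- interpret_bands(band_pattern(394))
  expect_equal(call3$cs29_genotype, "non-carrier")
  expect_equal(call3$cs6_status, "negative")

  # no interpretable band class: a failed reaction, not a genotype
  fail <- interpret_bands(structure(list(animal = "x", sizes = numeric()),
                                    class = "band_pattern"))
  expect_equal(fail$status, "failed")
  expect_true(is.na(fail$cs29_genotype))
  fail2 <- interpret_bands(band_pattern(525))
  expect_equal(fail2$status, "failed")

  # bands matching no marker are reported unassigned
  call4 <- interpret_bands(band_pattern(c(318, 394, 610)))
  expect_equal(call4$unassigned, 610)
  expect_equal(call4$cs29_genotype, "het")
})

test_that("band matching is tolerance-monotone until classes collide", {
  # 410 is outside 3% of 394 (382-406) but inside 5%
  expect_equal(interpret_bands(band_pattern(c(318, 410)),
                               size_tolerance = 0.03)$unassigned, 410)
  expect_equal(interpret_bands(band_pattern(c(318, 410)),
                               size_tolerance = 0.05)$cs29_genotype, "het")
  # a tolerance so wide that marker classes collide is rejected
  expect_error(interpret_bands(band_pattern(394), size_tolerance = 0.2),
               "not separated")
})

test_that("PCR genotyping round-trips up to Cs6 dominance", {
  tpl <- cs_fixture_templates()
  primers <- cs_demo_primers()
  for (nm in names(genotype_space())) {
    g <- genotype_space()[[nm]]
    call <- interpret_bands(multiplex_pattern(g, tpl, primers))
    expect_equal(call$status, "pass", info = nm)
    g_counts <- unclass(g)
    cs29_true <- if ("Cs29" %in% names(g_counts)) g_counts[["Cs29"]] else 0L
    cs29_called <- c("non-carrier" = 0L, het = 1L, hom = 2L)[[call$cs29_genotype]]
    expect_equal(cs29_called, cs29_true, info = nm)
    cs6_true <- "Cs6" %in% names(g_counts)
    expect_equal(call$cs6_status == "positive", cs6_true, info = nm)
    # dosage of Cs6 is deliberately not recoverable
    if (cs6_true) expect_match(call$cs6_note, "indistinguishable")
  }
})
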