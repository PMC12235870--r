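# Shared fixtures: the two 1.5 Mbp regions of interest, tiled at 10 kbp
# into 150 scorable windows each, and allele models whose gained segments
# coincide with those regions.

test_kit_region <- function() genomic_region("6", 70000000, 71500000, "KIT")
test_cs6_region <- function() genomic_region("29", 20000000, 21500000, "Cs6_chr29")

test_models <- function() {
  cs_allele_models(kit_region = test_kit_region(),
                   cs6_region = test_cs6_region())
}

test_regions <- function() list(test_kit_region(), test_cs6_region())

# brute-force primer-site scanner, independent of the implementation:
# plain character-by-character IUPAC comparison on both strands with the
# 3'-terminal base required to match exactly
brute_force_sites <- function(template, primer, max_mismatches) {
  sets <- Biostrings::IUPAC_CODE_MAP
  tpl <- strsplit(as.character(template), "")[[1]]
  hits <- list()
  for (strand in c("+", "-")) {
    p <- if (strand == "+") primer else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(primer)))
    pc <- strsplit(p, "")[[1]]
    L <- length(pc)
    if (L > length(tpl)) next
    t3 <- if (strand == "+") L else 1L  # site index of the primer's 3' base
    for (i in seq_len(length(tpl) - L + 1)) {
      sub <- tpl[i:(i + L - 1)]
      ok <- mapply(function(a, b) grepl(b, sets[[a]], fixed = TRUE), pc, sub)
      if (sum(!ok) <= max_mismatches && ok[t3])
        hits[[length(hits) + 1L]] <-
          data.frame(start = i, end = i + L - 1, strand = strand,
                     stringsAsFactors = FALSE)
    }
  }
  if (!length(hits))
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  do.call(rbind, hits)
}

# order site tables for comparison
sort_sites <- function(df) {
  df <- df[order(df$strand, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# sample genotype counts of a cohort of n animals at HWE allele freq q
hwe_cohort_counts <- function(n, q) {
  k <- stats::rbinom(n, 2, q)
  c(hom = sum(k == 2), het = sum(k == 1), "non-carrier" = sum(k == 0))
}
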