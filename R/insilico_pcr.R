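# In-silico breakpoint PCR: primer-site scanning, amplicon prediction,
# multiplex band patterns, and decoding with dominant-marker semantics.

IUPAC <- Biostrings::IUPAC_CODE_MAP

iupac_base_match <- function(pattern_char, subject_char) {
  # TRUE if the base sets of the two IUPAC codes intersect
  ps <- strsplit(IUPAC[[pattern_char]], "")[[1]]
  ss <- strsplit(IUPAC[[subject_char]], "")[[1]]
  length(intersect(ps, ss)) > 0
}

check_dna <- function(x, what) {
  chars <- unique(strsplit(toupper(x), "")[[1]])
  bad <- setdiff(chars, names(IUPAC))
  if (length(bad))
    stop(what, " contains invalid IUPAC characters: ",
         paste(bad, collapse = ", "))
  toupper(x)
}

new_primer_table <- function(df) {
  need <- c("name", "forward", "reverse")
  if (!all(need %in% names(df)))
    stop("primer table needs columns name, forward, reverse")
  if (!"expected_size" %in% names(df)) df$expected_size <- NA_integer_
  if (!"marker_for" %in% names(df)) df$marker_for <- NA_character_
  df$forward <- vapply(df$forward, check_dna, "", what = "forward primer")
  df$reverse <- vapply(df$reverse, check_dna, "", what = "reverse primer")
  if (any(!nzchar(df$forward)) || any(!nzchar(df$reverse)))
    stop("primer sequences must be non-empty")
  sz <- df$expected_size
  too_small <- !is.na(sz) &
    (sz <= nchar(df$forward) | sz <= nchar(df$reverse))
  if (any(too_small))
    stop("expected_size must exceed the primer lengths for pair(s): ",
         paste(df$name[too_small], collapse = ", "))
  rownames(df) <- NULL
  class(df) <- c("primer_table", "data.frame")
  df
}

#' Scan a template for primer annealing sites
#'
#' Finds every position where the primer matches the template with at most
#' `max_mismatches` mismatches, on the plus strand (primer as given) and
#' the minus strand (its reverse complement). IUPAC ambiguity codes in the
#' primer match their base sets. The 3'-terminal base of the primer is
#' always required to match exactly, regardless of `max_mismatches`:
#' polymerase extension needs a paired 3' end, so a site with a terminal
#' mismatch would not amplify.
#'
#' @param template A [Biostrings::DNAString] or character DNA sequence.
#' @param primer Primer sequence (character or DNAString), 5'->3'.
#' @param max_mismatches Maximum internal mismatches allowed (default 0).
#' @return A data.frame with one row per site: `start`, `end` (1-based,
#'   inclusive, on the plus strand) and `strand` (`"+"` or `"-"`). A primer
#'   longer than the template yields zero rows.
#' @export
find_primer_sites <- function(template, primer, max_mismatches = 0) {
  if (is.character(template)) {
    template <- Biostrings::DNAString(check_dna(template, "template"))
  }
  primer <- check_dna(as.character(primer), "primer")
  plen <- nchar(primer)
  if (plen > length(template))
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  pstr <- Biostrings::DNAString(primer)
  prc <- Biostrings::reverseComplement(pstr)

  hits_one <- function(pat, strand) {
    m <- Biostrings::matchPattern(pat, template,
                                  max.mismatch = max_mismatches,
                                  fixed = "subject")
    st <- Biostrings::start(m); en <- Biostrings::end(m)
    if (!length(st))
      return(data.frame(start = integer(), end = integer(),
                        strand = character(), stringsAsFactors = FALSE))
    # index (plus-strand coordinate) of the primer's 3'-terminal base
    tpos <- if (strand == "+") en else st
    tbase_primer <- substr(primer, plen, plen)
    ok <- vapply(seq_along(st), function(i) {
      sub <- as.character(template[tpos[i]])
      if (strand == "-")
        sub <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(sub)))
      iupac_base_match(tbase_primer, sub)
    }, TRUE)
    data.frame(start = st[ok], end = en[ok],
               strand = rep(strand, sum(ok)), stringsAsFactors = FALSE)
  }
  rbind(hits_one(pstr, "+"), hits_one(prc, "-"))
}

#' Predict PCR amplicons of a primer pair on a template
#'
#' Enumerates every convergent combination of annealing sites - one primer
#' on the plus strand upstream, the other on the minus strand downstream -
#' and reports the products up to `max_product` bp. Product length is
#' measured from the 5' end of the upstream site to the 5' end of the
#' downstream site, inclusive of both primer footprints, which is how
#' assay product sizes are conventionally reported.
#'
#' @param template A DNAString or character sequence.
#' @param pair One row of a primer table (or a list with `name`, `forward`,
#'   `reverse`).
#' @param max_product Maximum product size in bp (default 2000).
#' @param max_mismatches Mismatches tolerated per primer site (default 0).
#' @param template_id Identifier recorded in the output.
#' @return A data.frame of class `amplicon_prediction`: `template`, `pair`,
#'   `start`, `end`, `length`, `fwd_strand`, `rev_strand`. Zero rows means
#'   no product.
#' @export
predict_amplicons <- function(template, pair, max_product = 2000,
                              max_mismatches = 0, template_id = "template") {
  fwd <- find_primer_sites(template, pair$forward, max_mismatches)
  rev <- find_primer_sites(template, pair$reverse, max_mismatches)
  combos <- rbind(
    merge(fwd[fwd$strand == "+", c("start", "end")],
          rev[rev$strand == "-", c("start", "end")],
          by = NULL, suffixes = c("_up", "_dn")),
    merge(rev[rev$strand == "+", c("start", "end")],
          fwd[fwd$strand == "-", c("start", "end")],
          by = NULL, suffixes = c("_up", "_dn"))
  )
  if (!nrow(combos))
    return(empty_amplicons())
  # convergent: upstream plus-strand site entirely 5' of the downstream
  # minus-strand site; product spans both footprints
  keep <- combos$start_dn > combos$end_up
  combos <- combos[keep, , drop = FALSE]
  len <- combos$end_dn - combos$start_up + 1
  keep2 <- len <= max_product
  combos <- combos[keep2, , drop = FALSE]
  len <- len[keep2]
  out <- data.frame(
    template = rep(template_id, nrow(combos)),
    pair = rep(if (is.null(pair$name)) NA_character_ else pair$name,
               nrow(combos)),
    start = combos$start_up, end = combos$end_dn, length = len,
    fwd_strand = rep("+", nrow(combos)), rev_strand = rep("-", nrow(combos)),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$start, out$length), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("amplicon_prediction", "data.frame")
  out
}

empty_amplicons <- function() {
  out <- data.frame(template = character(), pair = character(),
                    start = integer(), end = integer(), length = integer(),
                    fwd_strand = character(), rev_strand = character(),
                    stringsAsFactors = FALSE)
  class(out) <- c("amplicon_prediction", "data.frame")
  out
}

#' Predict the multiplex band pattern of a diploid genotype
#'
#' Runs every primer pair of the multiplex against the haplotype template
#' of each allele the animal carries and returns the union of predicted
#' product sizes - the in-silico analogue of the multiplex lane on the
#' electrophoresis trace.
#'
#' @param genotype A [diploid_genotype()].
#' @param templates Named [Biostrings::DNAStringSet] (or list of
#'   sequences), one template per allele name.
#' @param primers A primer table (see [cs_demo_primers()],
#'   [read_primer_table()]).
#' @param max_product,max_mismatches Passed to [predict_amplicons()].
#' @param animal Optional animal id.
#' @return An object of class `band_pattern`: list with `animal` and
#'   `sizes` (sorted unique product sizes in bp).
#' @examples
#' tpl <- cs_fixture_templates()
#' multiplex_pattern(diploid_genotype(c("Cs29", "wt")), tpl,
#'                   cs_demo_primers())$sizes  # 318 394
#' @export
multiplex_pattern <- function(genotype, templates, primers,
                              max_product = 2000, max_mismatches = 0,
                              animal = NA_character_) {
  missing_tpl <- setdiff(names(genotype), names(templates))
  if (length(missing_tpl))
    stop("no haplotype template for allele(s): ",
         paste(missing_tpl, collapse = ", "))
  sizes <- integer()
  for (allele in names(genotype)) {
    tpl <- templates[[allele]]
    for (i in seq_len(nrow(primers))) {
      amp <- predict_amplicons(tpl, primers[i, ], max_product,
                               max_mismatches, template_id = allele)
      sizes <- c(sizes, amp$length)
    }
  }
  band_pattern(sort(unique(sizes)), animal = animal)
}

#' @rdname multiplex_pattern
#' @param sizes Numeric vector of band sizes in bp (all `> 0`).
#' @export
band_pattern <- function(sizes, animal = NA_character_) {
  sizes <- as.numeric(sizes)
  if (any(sizes <= 0)) stop("band sizes must be positive")
  structure(list(animal = animal, sizes = sort(unique(sizes))),
            class = "band_pattern")
}

#' @export
print.band_pattern <- function(x, ...) {
  cat(sprintf("<band_pattern> %s: {%s}\n",
              ifelse(is.na(x$animal), "animal", x$animal),
              paste(x$sizes, collapse = ", ")))
  invisible(x)
}

#' Marker map of the Cs multiplex assay
#'
#' Nominal band sizes and their meaning: 318 bp indicates the Cs29
#' translocation junction, 394 bp the wild-type chromosome-29 allele, and
#' 525 bp the Cs6 translocation junction. Cs29 is typed codominantly
#' (together with the wild-type band it resolves hom/het/non-carrier);
#' the Cs6 band is a dominant presence marker.
#'
#' @return A data.frame `size, allele, dominance`.
#' @export
cs_marker_map <- function() {
  data.frame(
    size = c(318, 394, 525),
    allele = c("Cs29", "wt", "Cs6"),
    dominance = c("codominant", "codominant", "dominant-presence"),
    stringsAsFactors = FALSE
  )
}

#' Decode a multiplex band pattern into a translocation genotype call
#'
#' Bands are assigned to the nearest marker class within a relative size
#' tolerance (electrophoretic sizing error). The Cs29 locus is decoded
#' codominantly from the presence/absence of the Cs29 band and the
#' wild-type band: both present = heterozygote, Cs29 band only =
#' homozygote, wild-type band only = non-carrier. The Cs6 marker is
#' dominant: the call is only positive/negative, and a positive call is
#' annotated as "het or hom indistinguishable". If neither a Cs29-class
#' nor a wild-type-class band is present the reaction is reported as
#' failed/uninterpretable rather than given a genotype.
#'
#' @param pattern A [band_pattern()] (or numeric vector of sizes).
#' @param marker_map A marker map (default [cs_marker_map()]).
#' @param size_tolerance Relative matching tolerance (default 0.03, i.e.
#'   +/-3% of the nominal size).
#' @return An object of class `band_call`: list with `animal`, `status`
#'   (`"pass"` or `"failed"`), `cs29_genotype`
#'   (`"hom"`/`"het"`/`"non-carrier"` or `NA` on failure), `cs6_status`
#'   (`"positive"`/`"negative"` or `NA`), `cs6_note`, `unassigned`
#'   (band sizes matching no marker).
#' @examples
#' interpret_bands(band_pattern(c(318, 394)))  # Cs29 het, Cs6 negative
#' @export
interpret_bands <- function(pattern, marker_map = cs_marker_map(),
                            size_tolerance = 0.03) {
  if (is.numeric(pattern)) pattern <- band_pattern(pattern)
  # marker classes must be separated by more than twice the tolerance,
  # otherwise a band could match two classes
  sz <- marker_map$size
  if (length(sz) > 1) {
    for (i in seq_along(sz)[-1]) for (j in seq_len(i - 1))
      if (abs(sz[i] - sz[j]) <= size_tolerance * (sz[i] + sz[j]))
        stop("marker map sizes ", sz[j], " and ", sz[i],
             " are not separated beyond 2x the matching tolerance")
  }
  assign_band <- function(b) {
    d <- abs(b - marker_map$size)
    ok <- d <= size_tolerance * marker_map$size
    if (!any(ok)) return(NA_character_)
    marker_map$allele[which.min(ifelse(ok, d, Inf))]
  }
  assigned <- vapply(pattern$sizes, assign_band, "")
  unassigned <- pattern$sizes[is.na(assigned)]
  has <- function(a) any(assigned == a, na.rm = TRUE)

  cs29 <- has("Cs29"); wt <- has("wt"); cs6 <- has("Cs6")
  if (!cs29 && !wt) {
    return(structure(list(
      animal = pattern$animal, status = "failed",
      cs29_genotype = NA_character_, cs6_status = NA_character_,
      cs6_note = "no Cs29-class or wildtype-class band: PCR failure",
      unassigned = unassigned), class = "band_call"))
  }
  cs29_genotype <- if (cs29 && wt) "het" else if (cs29) "hom" else "non-carrier"
  structure(list(
    animal = pattern$animal, status = "pass",
    cs29_genotype = cs29_genotype,
    cs6_status = if (cs6) "positive" else "negative",
    cs6_note = if (cs6) "het or hom indistinguishable (dominant marker)" else "",
    unassigned = unassigned), class = "band_call")
}

#' @export
print.band_call <- function(x, ...) {
  if (x$status == "failed") {
    cat(sprintf("<band_call> %s: FAILED (%s)\n",
                ifelse(is.na(x$animal), "animal", x$animal), x$cs6_note))
  } else {
    cat(sprintf("<band_call> %s: Cs29 %s; Cs6 %s%s\n",
                ifelse(is.na(x$animal), "animal", x$animal),
                x$cs29_genotype, x$cs6_status,
                if (nzchar(x$cs6_note)) paste0(" (", x$cs6_note, ")") else ""))
  }
  if (length(x$unassigned))
    cat("  unassigned bands:", paste(x$unassigned, collapse = ", "), "\n")
  invisible(x)
}
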