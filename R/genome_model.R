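# ---- Genomic regions --------------------------------------------------------

#' Create a genomic region
#'
#' Regions use the BED convention throughout the package: 0-based,
#' half-open `[start, end)`.
#'
#' @param chrom Chromosome name (character scalar).
#' @param start 0-based start position (integer-like, `>= 0`).
#' @param end End position (exclusive); must satisfy `end > start`.
#' @param label Optional free-text label for the region.
#'
#' @return An object of class `genomic_region`: a list with elements
#'   `chrom`, `start`, `end`, `label`.
#' @examples
#' kit <- genomic_region("6", 70000000, 71500000, label = "KIT")
#' region_width(kit)
#' @export
genomic_region <- function(chrom, start, end, label = NULL) {
  stopifnot(is.character(chrom), length(chrom) == 1L, nzchar(chrom))
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (length(start) != 1L || length(end) != 1L || is.na(start) || is.na(end))
    stop("start and end must be single non-missing numbers")
  if (start < 0) stop("region start must be >= 0 (0-based BED convention)")
  if (end <= start) stop("region end must be greater than start")
  structure(
    list(chrom = chrom, start = start, end = end,
         label = if (is.null(label)) sprintf("%s:%g-%g", chrom, start, end) else label),
    class = "genomic_region"
  )
}

#' @export
print.genomic_region <- function(x, ...) {
  cat(sprintf("<genomic_region> %s  [%s]\n", region_string(x), x$label))
  invisible(x)
}

#' Width of a region in bp
#' @param region A [genomic_region()].
#' @return Numeric width (`end - start`).
#' @export
region_width <- function(region) region$end - region$start

#' Display a region as a 1-based inclusive coordinate string
#'
#' Internally the package stores 0-based half-open coordinates; genome
#' browsers display 1-based inclusive ones. `region_string()` converts for
#' display and `parse_region_string()` converts back.
#'
#' @param region A [genomic_region()].
#' @return A string like `"6:70000001-71500000"`.
#' @export
region_string <- function(region) {
  sprintf("%s:%.0f-%.0f", region$chrom, region$start + 1, region$end)
}

#' @rdname region_string
#' @param x A string `"chrom:start-end"` with 1-based inclusive coordinates.
#' @param label Optional label for the resulting region.
#' @export
parse_region_string <- function(x, label = NULL) {
  m <- regmatches(x, regexec("^([^:]+):([0-9]+)-([0-9]+)$", x))[[1]]
  if (length(m) != 4L) stop("cannot parse region string: ", x)
  genomic_region(m[2], as.numeric(m[3]) - 1, as.numeric(m[4]), label = label)
}

regions_overlap <- function(a, b) {
  identical(a$chrom, b$chrom) && a$start < b$end && b$start < a$end
}

# ---- Translocation allele models -------------------------------------------

#' Define a structural (translocation) allele by the regions it duplicates
#'
#' A translocation allele is modelled purely by its copy-number consequences:
#' the list of genomic regions for which each carried copy of the allele adds
#' `copies_added` extra copies on top of the diploid baseline of 2. The
#' wild-type allele adds no copies anywhere.
#'
#' @param name Allele identifier, e.g. `"Cs29"`, `"Cs6"`, `"wt"`.
#' @param gains A list of [genomic_region()] objects, or a data.frame with
#'   columns `chrom`, `start`, `end` and optionally `label`, `copies_added`.
#' @param copies_added Integer(s) `>= 0`: extra copies contributed per allele
#'   carried, recycled over `gains`. Ignored if `gains` is a data.frame with
#'   its own `copies_added` column.
#'
#' @return An object of class `allele_model` with elements `name` and
#'   `gains` (a data.frame `chrom, start, end, label, copies_added`).
#' @seealso [cs_allele_models()] for the standard Cs29/Cs6 configuration.
#' @export
allele_model <- function(name, gains = list(), copies_added = 1L) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (is.data.frame(gains)) {
    need <- c("chrom", "start", "end")
    if (!all(need %in% names(gains)))
      stop("gains data.frame needs columns chrom, start, end")
    if (!"copies_added" %in% names(gains)) gains$copies_added <- copies_added
    if (!"label" %in% names(gains))
      gains$label <- sprintf("%s:%g-%g", gains$chrom, gains$start, gains$end)
    gl <- lapply(seq_len(nrow(gains)), function(i)
      genomic_region(as.character(gains$chrom[i]), gains$start[i],
                     gains$end[i], gains$label[i]))
    ca <- gains$copies_added
  } else {
    gl <- gains
    ca <- rep_len(copies_added, length(gl))
  }
  if (any(ca < 0) || any(ca != floor(ca)))
    stop("copies_added must be non-negative integers")
  gains_df <- if (length(gl)) data.frame(
    chrom = vapply(gl, `[[`, "", "chrom"),
    start = vapply(gl, `[[`, 0, "start"),
    end = vapply(gl, `[[`, 0, "end"),
    label = vapply(gl, `[[`, "", "label"),
    copies_added = as.integer(ca),
    stringsAsFactors = FALSE
  ) else data.frame(chrom = character(), start = numeric(), end = numeric(),
                    label = character(), copies_added = integer(),
                    stringsAsFactors = FALSE)
  structure(list(name = name, gains = gains_df), class = "allele_model")
}

#' @export
print.allele_model <- function(x, ...) {
  cat(sprintf("<allele_model> %s (%d gained region%s)\n", x$name,
              nrow(x$gains), if (nrow(x$gains) == 1) "" else "s"))
  if (nrow(x$gains)) print(x$gains)
  invisible(x)
}

#' Standard allele models for the Cs29 and Cs6 translocations
#'
#' Cs29 is a translocation of a ~500 kbp chromosome-6 segment containing the
#' KIT gene onto chromosome 29: each Cs29 allele adds one extra copy of that
#' chromosome-6 segment. Cs6 derives from the Cs29 configuration by a further
#' translocation back to chromosome 6 and elevates copy number of both the
#' chromosome-6 KIT segment and a chromosome-29 segment (one extra copy of
#' each per allele). The wild-type allele adds nothing.
#'
#' Coordinates are configuration, not biology: the defaults below are
#' placeholder ARS-UCD1.2-style coordinates for the two regions of interest
#' and should be replaced by lifted-over breakpoint coordinates when scoring
#' real data (see [read_allele_models()] for file-based configuration).
#'
#' @param kit_region [genomic_region()] of the duplicated chromosome-6 KIT
#'   segment.
#' @param cs6_region [genomic_region()] of the chromosome-29 segment whose
#'   copy number Cs6 elevates.
#'
#' @return A named list of three [allele_model()] objects: `wt`, `Cs29`, `Cs6`.
#' @examples
#' models <- cs_allele_models()
#' kit <- genomic_region("6", 70000000, 70500000, "KIT")
#' expected_depth_ratio(diploid_genotype(c("Cs29", "wt")), kit, models)
#' @export
cs_allele_models <- function(
    kit_region = genomic_region("6", 70000000, 70500000, label = "KIT"),
    cs6_region = genomic_region("29", 20000000, 20500000, label = "Cs6_chr29")) {
  list(
    wt = allele_model("wt"),
    Cs29 = allele_model("Cs29", list(kit_region), copies_added = 1L),
    Cs6 = allele_model("Cs6", list(kit_region, cs6_region), copies_added = 1L)
  )
}

model_gain_regions <- function(model) {
  lapply(seq_len(nrow(model$gains)), function(i)
    genomic_region(model$gains$chrom[i], model$gains$start[i],
                   model$gains$end[i], model$gains$label[i]))
}

#' Read / write allele model configuration (YAML)
#'
#' The schema is a named map: allele name to a list of gains, each with
#' `chrom`, `start`, `end`, `copies_added` and optional `label`. An allele
#' with an empty gain list (such as `wt`) adds no copies anywhere.
#'
#' @param path Path to a YAML file.
#' @return For `read_allele_models()`, a named list of [allele_model()]s.
#' @examples
#' cfg <- system.file("extdata", "allele_models.yaml", package = "cstyper")
#' models <- read_allele_models(cfg)
#' names(models)
#' @export
read_allele_models <- function(path) {
  if (!file.exists(path)) stop("allele model file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (!length(raw)) stop("allele model file is empty: ", path)
  out <- lapply(names(raw), function(nm) {
    gains <- raw[[nm]]
    gl <- lapply(gains, function(g) {
      if (is.null(g$chrom) || is.null(g$start) || is.null(g$end))
        stop("allele ", nm, ": each gain needs chrom, start, end")
      genomic_region(as.character(g$chrom), g$start, g$end, g$label)
    })
    ca <- vapply(gains, function(g)
      if (is.null(g$copies_added)) 1L else as.integer(g$copies_added), 1L)
    allele_model(nm, gl, copies_added = ca)
  })
  names(out) <- names(raw)
  out
}

#' @rdname read_allele_models
#' @param models A named list of [allele_model()]s.
#' @export
write_allele_models <- function(models, path) {
  raw <- lapply(models, function(m) {
    lapply(seq_len(nrow(m$gains)), function(i) list(
      chrom = m$gains$chrom[i], start = m$gains$start[i],
      end = m$gains$end[i], label = m$gains$label[i],
      copies_added = m$gains$copies_added[i]))
  })
  names(raw) <- vapply(models, `[[`, "", "name")
  yaml::write_yaml(raw, path)
  invisible(path)
}

# ---- Diploid genotypes ------------------------------------------------------

#' Create a diploid genotype from two allele names or allele counts
#'
#' @param alleles Either a character vector of exactly two allele names
#'   (e.g. `c("Cs29", "wt")`), or a named integer vector of allele counts
#'   summing to 2 (e.g. `c(Cs29 = 1, wt = 1)`).
#'
#' @return An object of class `diploid_genotype`: a named integer vector of
#'   allele counts with total 2.
#' @examples
#' diploid_genotype(c("Cs29", "Cs6"))
#' diploid_genotype(c(Cs29 = 2))
#' @export
diploid_genotype <- function(alleles) {
  if (is.null(names(alleles))) {
    if (length(alleles) != 2L || !is.character(alleles))
      stop("supply two allele names or a named count vector summing to 2")
    counts <- table(alleles)
    out <- as.integer(counts)
    names(out) <- names(counts)
  } else {
    out <- as.integer(alleles)
    names(out) <- names(alleles)
    if (any(out < 0)) stop("allele counts must be non-negative")
    if (sum(out) != 2L) stop("diploid genotype counts must sum to 2")
  }
  out <- out[out > 0L]
  out <- out[order(names(out))]
  structure(out, class = "diploid_genotype")
}

#' @export
format.diploid_genotype <- function(x, ...) {
  paste(rep(names(x), unclass(x)), collapse = "/")
}

#' @export
print.diploid_genotype <- function(x, ...) {
  cat("<diploid_genotype>", format(x), "\n")
  invisible(x)
}

#' Enumerate the diploid genotype space over a set of alleles
#'
#' @param allele_names Character vector of allele names (default: the three
#'   alleles of the Cs29/Cs6 system, giving the six genotypes
#'   wt/wt, Cs29/wt, Cs29/Cs29, Cs6/wt, Cs6/Cs6, Cs29/Cs6).
#' @return A named list of [diploid_genotype()] objects; names are
#'   `"a/b"` strings.
#' @export
genotype_space <- function(allele_names = c("wt", "Cs29", "Cs6")) {
  allele_names <- unique(allele_names)
  combos <- list()
  for (i in seq_along(allele_names))
    for (j in i:length(allele_names))
      combos[[length(combos) + 1L]] <-
        diploid_genotype(c(allele_names[i], allele_names[j]))
  names(combos) <- vapply(combos, format, "")
  combos
}

# ---- Copy-number expectations ----------------------------------------------

genotype_extra_copies <- function(genotype, region, models) {
  model_names <- vapply(models, `[[`, "", "name")
  extra <- 0
  for (allele in names(genotype)) {
    k <- unclass(genotype)[[allele]]
    idx <- match(allele, model_names)
    if (is.na(idx))
      stop("unknown allele in genotype: '", allele,
           "' (models define: ", paste(model_names, collapse = ", "), ")")
    m <- models[[idx]]
    for (g in model_gain_regions(m))
      if (regions_overlap(g, region))
        extra <- extra + k * m$gains$copies_added[m$gains$label == g$label][1]
  }
  extra
}

#' Total copy number and expected depth ratio under a genotype
#'
#' For a diploid genome the baseline copy number of every region is 2; each
#' carried translocation allele adds its configured extra copies over the
#' regions it duplicates. The expected standardized depth-of-coverage ratio
#' is copy number divided by 2, so a heterozygous carrier of a
#' single-copy-gain allele shows 1.5x the genome median and a homozygote 2x.
#'
#' @param genotype A [diploid_genotype()].
#' @param region A [genomic_region()] to evaluate.
#' @param models Named list of [allele_model()]s covering every allele in the
#'   genotype.
#'
#' @return `expected_depth_ratio()`: a positive scalar,
#'   `(2 + total extra copies) / 2`. `copy_number()`: the integer copy
#'   number `2 + total extra copies`.
#' @examples
#' models <- cs_allele_models()
#' kit <- genomic_region("6", 70000000, 70500000, "KIT")
#' expected_depth_ratio(diploid_genotype(c("wt", "wt")), kit, models)    # 1.0
#' expected_depth_ratio(diploid_genotype(c("Cs29", "wt")), kit, models)  # 1.5
#' expected_depth_ratio(diploid_genotype(c(Cs29 = 2)), kit, models)      # 2.0
#' @export
expected_depth_ratio <- function(genotype, region, models) {
  (2 + genotype_extra_copies(genotype, region, models)) / 2
}

#' @rdname expected_depth_ratio
#' @export
copy_number <- function(genotype, region, models) {
  as.integer(2 + genotype_extra_copies(genotype, region, models))
}

#' Copy-number profile of a genotype across a set of regions
#'
#' @inheritParams expected_depth_ratio
#' @param regions A list of [genomic_region()]s.
#' @return A data.frame with one row per region: `region` (label), `chrom`,
#'   `start`, `end`, `copy_number`, `expected_ratio`.
#' @export
copy_number_profile <- function(genotype, regions, models) {
  cn <- vapply(regions, function(r) copy_number(genotype, r, models), 0L)
  data.frame(
    region = vapply(regions, `[[`, "", "label"),
    chrom = vapply(regions, `[[`, "", "chrom"),
    start = vapply(regions, `[[`, 0, "start"),
    end = vapply(regions, `[[`, 0, "end"),
    copy_number = cn,
    expected_ratio = cn / 2,
    stringsAsFactors = FALSE
  )
}
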