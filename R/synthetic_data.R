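# Synthetic-data generators: depth tracks, haplotype sequences with planted
# primer sites, and Hardy-Weinberg population samples with known truth.

# Evaluate `code` under `seed` without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed) && !is.na(seed)) {
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      stats::runif(1)
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  code
}

#' Configuration for depth-track simulation
#'
#' @param window_size Window width in bp (default 10000).
#' @param mean_depth Mean read count per window at diploid copy number
#'   (default 26, a typical mapped whole-genome coverage for this kind of
#'   cohort).
#' @param dispersion Overdispersion of the count model: 0 gives Poisson
#'   counts, values > 0 give negative-binomial counts with variance
#'   `mu + dispersion * mu^2`.
#' @param n_background_windows Number of diploid background windows used to
#'   anchor the genome-wide median (default 5000). The background must
#'   dominate the track, as it does in a real genome where a few Mbp of
#'   duplicated sequence is negligible against the whole assembly;
#'   otherwise the elevated windows drag the median upward and bias every
#'   standardized ratio downward.
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @return A list of class `depth_sim_config`.
#' @export
depth_sim_config <- function(window_size = 10000, mean_depth = 26,
                             dispersion = 0, n_background_windows = 5000,
                             seed = NULL) {
  if (window_size <= 0) stop("window_size must be positive")
  if (mean_depth <= 0) stop("mean_depth must be positive")
  if (dispersion < 0) stop("dispersion must be >= 0")
  structure(list(window_size = window_size, mean_depth = mean_depth,
                 dispersion = dispersion,
                 n_background_windows = as.integer(n_background_windows),
                 seed = seed),
            class = "depth_sim_config")
}

draw_counts <- function(n, mu, dispersion) {
  if (dispersion == 0) stats::rpois(n, mu)
  else stats::rnbinom(n, mu = mu, size = 1 / dispersion)
}

#' Simulate a windowed depth track for a known genotype
#'
#' Generates background windows at diploid copy number (expected ratio 1.0)
#' on a pseudo-chromosome `"bg"`, plus windows tiling each region of
#' interest, with each window's read count drawn from a Poisson (or
#' negative-binomial) distribution with mean
#' `mean_depth x expected_depth_ratio(genotype, window, models)`. Ground
#' truth is known by construction, which is what makes caller-recovery
#' tests possible without real sequencing data.
#'
#' @param genotype A [diploid_genotype()] (the simulated animal's truth).
#' @param models Named list of [allele_model()]s.
#' @param regions List of [genomic_region()]s to tile with windows (the
#'   regions of interest that will later be scored).
#' @param config A [depth_sim_config()].
#' @return A standardizable `depth_track` data.frame (`chrom, start, end,
#'   depth`) with attribute `truth` recording the genotype label.
#' @examples
#' models <- cs_allele_models()
#' kit <- genomic_region("6", 70000000, 71500000, "KIT")
#' tr <- simulate_depth_track(diploid_genotype(c("Cs29", "wt")), models,
#'                            list(kit), depth_sim_config(seed = 1))
#' mean(standardize(tr)$ratio[tr$chrom == "6"])  # close to 1.5
#' @export
simulate_depth_track <- function(genotype, models, regions, config) {
  stopifnot(inherits(config, "depth_sim_config"))
  if (config$n_background_windows < 1)
    stop("n_background_windows must be >= 1 (the median is undefined otherwise)")
  ws <- config$window_size
  with_seed(config$seed, {
    nb <- config$n_background_windows
    bg <- data.frame(
      chrom = "bg",
      start = (seq_len(nb) - 1) * ws,
      end = seq_len(nb) * ws,
      depth = as.numeric(draw_counts(nb, config$mean_depth, config$dispersion)),
      stringsAsFactors = FALSE
    )
    reg_parts <- lapply(regions, function(r) {
      n_win <- floor(region_width(r) / ws)
      if (n_win < 1)
        stop("region ", r$label, " is narrower than one window")
      starts <- r$start + (seq_len(n_win) - 1) * ws
      ratios <- vapply(seq_len(n_win), function(i)
        expected_depth_ratio(genotype,
                             genomic_region(r$chrom, starts[i], starts[i] + ws),
                             models), 0)
      data.frame(
        chrom = r$chrom, start = starts, end = starts + ws,
        depth = as.numeric(draw_counts(n_win, config$mean_depth * ratios,
                                       config$dispersion)),
        stringsAsFactors = FALSE
      )
    })
    out <- new_depth_track(do.call(rbind, c(list(bg), reg_parts)))
    attr(out, "truth") <- format(genotype)
    out
  })
}

# ---- Haplotype sequences with planted primer sites -------------------------

#' Simulate a haplotype template with planted primer annealing sites
#'
#' Builds a random uniform-composition DNA background and plants, for each
#' row of `plan`, the forward primer at its offset and the reverse
#' complement of the reverse primer placed so that the amplicon length
#' (5' end of the forward site to 5' end of the reverse site, inclusive)
#' equals the configured product size. Used to construct breakpoint-junction
#' fixtures whose in-silico PCR products have known sizes.
#'
#' @param base_length Template length in bp.
#' @param plan A data.frame with columns `forward`, `reverse` (primer
#'   sequences, 5'->3'), `size` (target product length in bp) and `offset`
#'   (0-based start of the forward site).
#' @param seed Integer seed for the random background, or `NULL`.
#' @param mutate_sites Number of random substitutions injected into each
#'   planted primer footprint (default 0; used to exercise the mismatch
#'   tolerance of the primer scanner).
#' @return A [Biostrings::DNAString] of length `base_length`.
#' @export
simulate_haplotype <- function(base_length, plan, seed = NULL,
                               mutate_sites = 0) {
  stopifnot(is.data.frame(plan),
            all(c("forward", "reverse", "size", "offset") %in% names(plan)))
  with_seed(seed, {
    seq <- sample(c("A", "C", "G", "T"), base_length, replace = TRUE)
    used <- rep(FALSE, base_length)
    plant <- function(s, at) { # at: 0-based
      idx <- seq.int(at + 1, at + nchar(s))
      if (at < 0 || max(idx) > base_length)
        stop("primer site out of bounds (offset ", at, ", length ",
             nchar(s), ", template ", base_length, ")")
      if (any(used[idx]))
        stop("primer sites overlap at offset ", at)
      used[idx] <<- TRUE
      site <- strsplit(s, "")[[1]]
      if (mutate_sites > 0) {
        pos <- sample(length(site), min(mutate_sites, length(site)))
        site[pos] <- vapply(site[pos], function(b)
          sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
      }
      seq[idx] <<- site
    }
    for (i in seq_len(nrow(plan))) {
      fwd <- toupper(plan$forward[i])
      rev <- toupper(plan$reverse[i])
      size <- plan$size[i]; off <- plan$offset[i]
      if (size < nchar(fwd) + nchar(rev))
        stop("product size ", size, " smaller than the two primer footprints")
      plant(fwd, off)
      rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(rev)))
      plant(rc, off + size - nchar(rev))
    }
    Biostrings::DNAString(paste(seq, collapse = ""))
  })
}

#' Synthetic breakpoint primer set reproducing the published product sizes
#'
#' The real breakpoint primer sequences are published elsewhere and are not
#' part of this package; the module is sequence-generic. This set of
#' synthetic primers, together with [cs_fixture_templates()], reproduces
#' the multiplex marker sizes of the assay: 318 bp for the Cs29 junction
#' (A-E pair), 394 bp for the wild-type chromosome-29 allele (alpha-beta
#' pair), 525 bp for the Cs6 junction (gamma-B pair).
#'
#' @return A `primer_table` data.frame: `name, forward, reverse,
#'   expected_size, marker_for`.
#' @export
cs_demo_primers <- function() {
  new_primer_table(data.frame(
    name = c("A-E", "alpha-beta", "gamma-B"),
    forward = c("GATTACAGGCATGAGCCACC",
                "CCTGTAGTCCCAGCTACTCG",
                "TGGTCTCGAACTCCTGACCT"),
    reverse = c("CAGGCTGGAGTGCAGTGGTA",
                "GTTGCCCAGGCTGGAGTACA",
                "ACCTCAGGTGATCCACCCAC"),
    expected_size = c(318L, 394L, 525L),
    marker_for = c("Cs29", "wt", "Cs6"),
    stringsAsFactors = FALSE
  ))
}

#' Synthetic haplotype templates for the three Cs alleles
#'
#' One template per allele of the chromosome-29 locus, built with
#' [simulate_haplotype()]:
#' * `wt` carries the alpha-beta wild-type junction (394 bp product);
#' * `Cs29` carries only the A-E translocation junction (318 bp product) -
#'   its chromosome 29 is rearranged, so the wild-type product is absent;
#' * `Cs6` carries the gamma-B junction (525 bp product) *and* an
#'   alpha-beta-amplifiable junction (394 bp product), because the second
#'   translocation restores a configuration that supports the wild-type
#'   product. This is precisely what makes the Cs6 assay a dominant marker:
#'   Cs6/wt and Cs6/Cs6 animals yield the same band pattern.
#'
#' @param primers A primer table (default [cs_demo_primers()]).
#' @param base_length Template length in bp (default 2000).
#' @param seed Seed for the random backgrounds (default 101).
#' @return A named [Biostrings::DNAStringSet] with templates `wt`, `Cs29`,
#'   `Cs6`.
#' @export
cs_fixture_templates <- function(primers = cs_demo_primers(),
                                 base_length = 2000, seed = 101) {
  p <- function(nm) primers[primers$name == nm, , drop = FALSE]
  mkplan <- function(rows, offsets) data.frame(
    forward = rows$forward, reverse = rows$reverse,
    size = rows$expected_size, offset = offsets,
    stringsAsFactors = FALSE)
  wt <- simulate_haplotype(base_length, mkplan(p("alpha-beta"), 100),
                           seed = seed)
  cs29 <- simulate_haplotype(base_length, mkplan(p("A-E"), 200),
                             seed = seed + 1)
  cs6 <- simulate_haplotype(
    base_length,
    mkplan(rbind(p("alpha-beta"), p("gamma-B")), c(100, 700)),
    seed = seed + 2)
  out <- Biostrings::DNAStringSet(list(wt = wt, Cs29 = cs29, Cs6 = cs6))
  out
}

# ---- Population samples -----------------------------------------------------

#' Simulate a Hardy-Weinberg population sample with dominance masking
#'
#' Each animal's two alleles are drawn i.i.d. from the given allele
#' frequencies (the remainder to 1 is the wild-type allele), i.e. the
#' population is at Hardy-Weinberg equilibrium. For alleles listed in
#' `dominant_alleles`, the observed record collapses heterozygotes and
#' homozygotes to a single `"positive"` state, emulating a
#' presence/absence (dominant) marker assay; true counts are retained in
#' the output so masking never changes the underlying allele counts, only
#' their observability.
#'
#' @param n_animals Number of animals.
#' @param allele_freqs Named numeric vector of non-wild-type allele
#'   frequencies, e.g. `c(Cs29 = 0.3, Cs6 = 0.1)`; must be `>= 0` and sum
#'   to at most 1.
#' @param dominant_alleles Character vector of allele names typed as
#'   dominant (presence/absence) markers; default `"Cs6"`.
#' @param seed Integer seed or `NULL`.
#' @return A data.frame with one row per animal: `animal`, `allele1`,
#'   `allele2`, `genotype`, and per allele `a` a true count column
#'   `<a>_count` plus an observed column - `<a>_genotype`
#'   (`hom`/`het`/`non-carrier`) for codominant alleles, `<a>_status`
#'   (`positive`/`negative`) for dominant ones.
#' @examples
#' pop <- simulate_population(10, c(Cs29 = 0.5), seed = 1)
#' table(pop$Cs29_genotype)
#' @export
simulate_population <- function(n_animals, allele_freqs,
                                dominant_alleles = "Cs6", seed = NULL) {
  stopifnot(n_animals >= 1, is.numeric(allele_freqs),
            !is.null(names(allele_freqs)))
  if (any(allele_freqs < 0)) stop("allele frequencies must be >= 0")
  if (sum(allele_freqs) > 1 + 1e-12)
    stop("allele frequencies sum to more than 1")
  alleles <- c(names(allele_freqs), "wt")
  probs <- c(allele_freqs, wt = 1 - sum(allele_freqs))
  with_seed(seed, {
    a1 <- sample(alleles, n_animals, replace = TRUE, prob = probs)
    a2 <- sample(alleles, n_animals, replace = TRUE, prob = probs)
    out <- data.frame(
      animal = sprintf("sim%04d", seq_len(n_animals)),
      allele1 = a1, allele2 = a2,
      genotype = vapply(seq_len(n_animals), function(i)
        format(diploid_genotype(c(a1[i], a2[i]))), ""),
      stringsAsFactors = FALSE
    )
    for (a in names(allele_freqs)) {
      cnt <- (a1 == a) + (a2 == a)
      out[[paste0(a, "_count")]] <- cnt
      if (a %in% dominant_alleles) {
        out[[paste0(a, "_status")]] <-
          ifelse(cnt > 0, "positive", "negative")
      } else {
        out[[paste0(a, "_genotype")]] <-
          c("non-carrier", "het", "hom")[cnt + 1L]
      }
    }
    out
  })
}
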