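# Depth-of-coverage genotyping: windowed tracks, median standardization and
# an automated least-squares genotype caller over an enumerated genotype set.

new_depth_track <- function(df) {
  stopifnot(all(c("chrom", "start", "end", "depth") %in% names(df)))
  rownames(df) <- NULL
  class(df) <- c("depth_track", "data.frame")
  df
}

#' Bin per-interval depth records into fixed-width windows
#'
#' Converts a per-base or per-interval coverage table (bedGraph-style:
#' `chrom, start, end, depth`, 0-based half-open) into a track of
#' fixed-width windows whose value is the length-weighted mean depth of the
#' overlapping input intervals. Bases of a window not covered by any input
#' interval do not contribute; windows with no data at all get `NA` depth
#' and are excluded from the standardization median downstream.
#'
#' @param intervals A data.frame with columns `chrom`, `start`, `end`,
#'   `depth`. Intervals must be sorted and non-overlapping within each
#'   chromosome.
#' @param window_size Window width in bp (default 10000, i.e. the 10 kbp
#'   windows used for translocation genotyping).
#'
#' @return A `depth_track` data.frame with columns `chrom`, `start`, `end`,
#'   `depth` (length-weighted mean; `NA` where no data).
#' @examples
#' iv <- data.frame(chrom = "6", start = c(0, 5000), end = c(5000, 10000),
#'                  depth = c(20, 40))
#' bin_depth(iv, 10000)$depth  # 30: length-weighted mean
#' @export
bin_depth <- function(intervals, window_size = 10000) {
  stopifnot(is.data.frame(intervals),
            all(c("chrom", "start", "end", "depth") %in% names(intervals)))
  if (window_size <= 0) stop("window_size must be positive")
  if (any(intervals$end <= intervals$start))
    stop("intervals must have end > start")
  out <- list()
  for (chr in unique(intervals$chrom)) {
    iv <- intervals[intervals$chrom == chr, , drop = FALSE]
    if (is.unsorted(iv$start, strictly = FALSE))
      stop("input intervals not sorted within chromosome ", chr)
    if (nrow(iv) > 1 && any(iv$start[-1] < iv$end[-nrow(iv)]))
      stop("overlapping input intervals on chromosome ", chr)
    n_win <- ceiling(max(iv$end) / window_size)
    cov_sum <- numeric(n_win)   # sum of depth x covered bases per window
    cov_len <- numeric(n_win)   # covered bases per window
    for (i in seq_len(nrow(iv))) {
      s <- iv$start[i]; e <- iv$end[i]; d <- iv$depth[i]
      w0 <- floor(s / window_size); w1 <- floor((e - 1) / window_size)
      for (w in w0:w1) {
        lo <- max(s, w * window_size)
        hi <- min(e, (w + 1) * window_size)
        cov_sum[w + 1] <- cov_sum[w + 1] + d * (hi - lo)
        cov_len[w + 1] <- cov_len[w + 1] + (hi - lo)
      }
    }
    depth <- ifelse(cov_len > 0, cov_sum / pmax(cov_len, 1), NA_real_)
    out[[chr]] <- data.frame(
      chrom = chr,
      start = (seq_len(n_win) - 1) * window_size,
      end = seq_len(n_win) * window_size,
      depth = depth,
      stringsAsFactors = FALSE
    )
  }
  new_depth_track(do.call(rbind, out))
}

#' Standardize a depth track by the genome-wide median window depth
#'
#' Each window's depth is divided by the median depth over all non-missing
#' windows in the track, so a diploid background sits at 1.0, a heterozygous
#' single-copy gain at 1.5 and a homozygous gain at 2.0. The raw depth
#' column is retained, which makes the operation idempotent and invariant
#' under rescaling of the raw depths.
#'
#' @param track A `depth_track` (see [bin_depth()] or
#'   [simulate_depth_track()]).
#' @return The track with an added/updated `ratio` column and attribute
#'   `median_depth`.
#' @export
standardize <- function(track) {
  stopifnot(inherits(track, "data.frame"), "depth" %in% names(track))
  ok <- !is.na(track$depth)
  if (!any(ok)) stop("no non-missing windows to standardize")
  med <- stats::median(track$depth[ok])
  if (med <= 0) stop("median window depth is zero; cannot standardize")
  track$ratio <- track$depth / med
  attr(track, "median_depth") <- med
  new_depth_track(track)
}

#' Observed copy ratio of a region: median standardized depth
#'
#' Summarises the standardized window ratios of all windows lying fully
#' inside the region with their median. Windows straddling the region
#' boundary are excluded: they only partially overlap the duplicated
#' segment and would dilute the copy signal. The median (rather than mean)
#' is robust to residual edge effects and outlier windows.
#'
#' @param track A standardized `depth_track` (with a `ratio` column).
#' @param region A [genomic_region()].
#' @return The median standardized ratio (scalar).
#' @export
region_copy_ratio <- function(track, region) {
  if (!"ratio" %in% names(track))
    stop("track is not standardized; call standardize() first")
  sel <- track$chrom == region$chrom &
    track$start >= region$start & track$end <= region$end &
    !is.na(track$ratio)
  if (!any(sel))
    stop("no non-missing windows fully inside region ", region$label)
  stats::median(track$ratio[sel])
}

# Midpoints between the distinct expected ratio levels that the genotype
# space can produce in one region, e.g. {1.0, 1.5, 2.0} -> {1.25, 1.75}.
ratio_class_midpoints <- function(levels) {
  levels <- sort(unique(levels))
  if (length(levels) < 2) return(numeric())
  (levels[-1] + levels[-length(levels)]) / 2
}

#' Call a translocation genotype from observed region copy ratios
#'
#' Replaces visual comparison of standardized coverage against the 1.5x and
#' 2x reference lines with an explicit decision rule: every genotype in the
#' enumerated space is scored by the sum of squared differences between the
#' observed and expected ratios over the scored regions, and the arg-min
#' genotype is returned. In the single-region case this reduces to nearest
#' expected ratio, i.e. thresholds at the class midpoints (1.25, 1.75 for
#' the 1.0/1.5/2.0 levels).
#'
#' A call is flagged `"ambiguous"` (rather than `"pass"`) when the best and
#' second-best scores differ by less than `margin`, or when any observed
#' ratio lies within `midpoint_tol` of a midpoint between two expected
#' ratio classes.
#'
#' @param observed Named numeric vector of observed copy ratios; names must
#'   match the `label`s of `regions`.
#' @param regions List of [genomic_region()]s that were scored.
#' @param models Named list of [allele_model()]s.
#' @param genotypes Genotype space to search (default [genotype_space()] on
#'   the model allele names).
#' @param animal Optional animal identifier carried into the result.
#' @param margin Ambiguity margin on the best-vs-second score difference
#'   (default 0.01).
#' @param midpoint_tol Half-width of the ambiguity band around class
#'   midpoints (default 0.05).
#'
#' @return An object of class `depth_call`: a list with `animal`,
#'   `observed`, `genotype` ([diploid_genotype()]), `genotype_label`,
#'   `score`, `flag` (`"pass"` or `"ambiguous"`), and `scores` (the full
#'   score table).
#' @examples
#' models <- cs_allele_models()
#' regs <- list(genomic_region("6", 70000000, 70500000, "KIT"),
#'              genomic_region("29", 20000000, 20500000, "Cs6_chr29"))
#' call_genotype(c(KIT = 1.5, Cs6_chr29 = 1.0), regs, models)
#' @export
call_genotype <- function(observed, regions, models,
                          genotypes = genotype_space(
                            vapply(models, `[[`, "", "name")),
                          animal = NA_character_,
                          margin = 0.01, midpoint_tol = 0.05) {
  if (!length(genotypes)) stop("empty genotype space")
  labels <- vapply(regions, `[[`, "", "label")
  if (is.null(names(observed)) || !all(labels %in% names(observed)))
    stop("observed ratios must be named after the region labels: ",
         paste(labels, collapse = ", "))
  observed <- observed[labels]
  if (any(observed < 0)) stop("observed ratios must be >= 0")

  expected <- vapply(genotypes, function(g)
    vapply(regions, function(r) expected_depth_ratio(g, r, models), 0),
    numeric(length(regions)))
  expected <- matrix(expected, nrow = length(regions),
                     dimnames = list(labels, names(genotypes)))
  score <- colSums((expected - observed)^2)
  ord <- order(score)
  best <- ord[1]

  near_mid <- any(vapply(seq_along(regions), function(i) {
    mids <- ratio_class_midpoints(expected[i, ])
    length(mids) > 0 && any(abs(observed[i] - mids) <= midpoint_tol)
  }, TRUE))
  close_scores <- length(score) > 1 &&
    (score[ord[2]] - score[best]) < margin
  flag <- if (near_mid || close_scores) "ambiguous" else "pass"

  structure(list(
    animal = animal,
    observed = observed,
    genotype = genotypes[[best]],
    genotype_label = names(genotypes)[best],
    score = unname(score[best]),
    flag = flag,
    scores = data.frame(genotype = names(genotypes), score = unname(score),
                        stringsAsFactors = FALSE)
  ), class = "depth_call")
}

#' @export
print.depth_call <- function(x, ...) {
  cat(sprintf("<depth_call> %s: %s (score %.4g, %s)\n",
              ifelse(is.na(x$animal), "animal", x$animal),
              x$genotype_label, x$score, x$flag))
  cat("  observed ratios:",
      paste(sprintf("%s=%.3f", names(x$observed), x$observed),
            collapse = ", "), "\n")
  invisible(x)
}

#' Genotype an animal directly from a depth track
#'
#' Convenience wrapper: standardizes the track (if needed), summarises each
#' scored region with [region_copy_ratio()] and calls [call_genotype()].
#'
#' @inheritParams call_genotype
#' @param track A `depth_track`.
#' @param ... Passed to [call_genotype()].
#' @return A `depth_call` (see [call_genotype()]).
#' @export
call_genotype_track <- function(track, regions, models, animal = NA_character_,
                                ...) {
  if (!"ratio" %in% names(track)) track <- standardize(track)
  observed <- vapply(regions, function(r) region_copy_ratio(track, r), 0)
  names(observed) <- vapply(regions, `[[`, "", "label")
  call_genotype(observed, regions, models, animal = animal, ...)
}

#' Summarise depth calls as a table
#'
#' @param calls A list of `depth_call` objects.
#' @return A data.frame with one row per call: animal, one column per
#'   region ratio, genotype, score, flag.
#' @export
depth_call_table <- function(calls) {
  stopifnot(length(calls) > 0)
  obs <- do.call(rbind, lapply(calls, function(x) as.data.frame(t(x$observed))))
  names(obs) <- paste0("ratio_", names(calls[[1]]$observed))
  cbind(
    data.frame(animal = vapply(calls, `[[`, "", "animal"),
               stringsAsFactors = FALSE),
    obs,
    data.frame(genotype = vapply(calls, `[[`, "", "genotype_label"),
               score = vapply(calls, `[[`, 0, "score"),
               flag = vapply(calls, `[[`, "", "flag"),
               stringsAsFactors = FALSE)
  )
}

#' Plot-ready long-format table of standardized coverage around a region
#'
#' Emits the data behind the classic coverage figure: window midpoints and
#' standardized ratios in and around a region of interest, plus the 1.0,
#' 1.5 and 2.0 reference levels, as a tidy table for downstream plotting.
#'
#' @param track A standardized `depth_track`.
#' @param region A [genomic_region()]; windows within `pad` bp of it are
#'   included.
#' @param pad Flank size in bp (default 500000).
#' @return A data.frame `chrom, midpoint, ratio, in_region` with attribute
#'   `reference_lines = c(1, 1.5, 2)`.
#' @export
coverage_plot_table <- function(track, region, pad = 500000) {
  if (!"ratio" %in% names(track))
    stop("track is not standardized; call standardize() first")
  sel <- track$chrom == region$chrom &
    track$end > region$start - pad & track$start < region$end + pad
  df <- track[sel, , drop = FALSE]
  out <- data.frame(
    chrom = df$chrom,
    midpoint = (df$start + df$end) / 2,
    ratio = df$ratio,
    in_region = df$start >= region$start & df$end <= region$end,
    stringsAsFactors = FALSE
  )
  attr(out, "reference_lines") <- c(1, 1.5, 2)
  out
}
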