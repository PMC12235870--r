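# Format readers/writers: bedGraph, BED, FASTA, window-track TSV, primer
# TSV, band-pattern CSV and cohort genotype CSV. All validate strictly and
# report the offending line on malformed input.

stop_line <- function(path, line, msg) {
  stop(basename(path), " line ", line, ": ", msg, call. = FALSE)
}

#' Read / write a bedGraph coverage file
#'
#' Four whitespace-separated columns: chrom, start, end, depth (0-based,
#' half-open). Lines starting with `track` or `#` are skipped.
#'
#' @param path File path.
#' @return `read_bedgraph()`: a data.frame `chrom, start, end, depth`.
#' @export
read_bedgraph <- function(path) {
  if (!file.exists(path)) stop("bedGraph file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(track|#)", lines) & nzchar(trimws(lines))
  out <- list()
  for (i in which(keep)) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) < 4) stop_line(path, i, "expected 4 columns (chrom, start, end, depth)")
    s <- suppressWarnings(as.numeric(f[2])); e <- suppressWarnings(as.numeric(f[3]))
    d <- suppressWarnings(as.numeric(f[4]))
    if (is.na(s) || is.na(e) || is.na(d))
      stop_line(path, i, "non-numeric start/end/depth")
    if (e <= s) stop_line(path, i, "end must be greater than start")
    out[[length(out) + 1L]] <- data.frame(chrom = f[1], start = s, end = e,
                                          depth = d, stringsAsFactors = FALSE)
  }
  if (!length(out)) stop("no data lines in ", path)
  do.call(rbind, out)
}

#' @rdname read_bedgraph
#' @param df A data.frame `chrom, start, end, depth`.
#' @export
write_bedgraph <- function(df, path) {
  utils::write.table(df[, c("chrom", "start", "end", "depth")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read / write a BED file of regions
#'
#' @param path File path; at least 3 columns (chrom, start, end), with an
#'   optional 4th name column used as the region label.
#' @return `read_bed()`: a list of [genomic_region()]s.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("region file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(track|#)", lines) & nzchar(trimws(lines))
  out <- list()
  for (i in which(keep)) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) < 3) stop_line(path, i, "expected at least 3 columns")
    s <- suppressWarnings(as.numeric(f[2])); e <- suppressWarnings(as.numeric(f[3]))
    if (is.na(s) || is.na(e)) stop_line(path, i, "non-numeric start/end")
    if (s < 0) stop_line(path, i, "start must be >= 0")
    if (e <= s) stop_line(path, i, "start must be less than end")
    out[[length(out) + 1L]] <-
      genomic_region(f[1], s, e, label = if (length(f) >= 4) f[4] else NULL)
  }
  if (!length(out)) stop("no regions in ", path)
  out
}

#' @rdname read_bed
#' @param regions A list of [genomic_region()]s.
#' @export
write_bed <- function(regions, path) {
  df <- data.frame(
    chrom = vapply(regions, `[[`, "", "chrom"),
    start = vapply(regions, `[[`, 0, "start"),
    end = vapply(regions, `[[`, 0, "end"),
    name = vapply(regions, `[[`, "", "label")
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write a windowed depth track as TSV
#'
#' Tab-separated with a header: `chrom, start, end, depth` and, for
#' standardized tracks, `ratio`.
#'
#' @param path File path.
#' @return `read_depth_track()`: a `depth_track` data.frame.
#' @export
read_depth_track <- function(path) {
  if (!file.exists(path)) stop("track file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "depth")
  if (!all(need %in% names(df)))
    stop("track file must have columns: ", paste(need, collapse = ", "))
  df$chrom <- as.character(df$chrom)
  new_depth_track(df)
}

#' @rdname read_depth_track
#' @param track A `depth_track`.
#' @export
write_depth_track <- function(track, path) {
  utils::write.table(as.data.frame(track), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write a primer table (TSV)
#'
#' Tab-separated with a header; columns `name`, `forward`, `reverse` and
#' optionally `expected_size`, `marker_for`. Primer sequences are
#' validated as IUPAC DNA and normalized to uppercase.
#'
#' @param path File path.
#' @return `read_primer_table()`: a `primer_table` data.frame.
#' @export
read_primer_table <- function(path) {
  if (!file.exists(path)) stop("primer file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  new_primer_table(df)
}

#' @rdname read_primer_table
#' @param primers A `primer_table`.
#' @export
write_primer_table <- function(primers, path) {
  utils::write.table(as.data.frame(primers), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write FASTA sequences
#'
#' Thin wrappers around Biostrings; sequences are normalized to uppercase
#' on reading, so lowercase and mixed-case input is accepted.
#'
#' @param path File path.
#' @return `read_fasta()`: a named [Biostrings::DNAStringSet].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  x <- Biostrings::readDNAStringSet(path)
  Biostrings::DNAStringSet(toupper(as.character(x)))
}

#' @rdname read_fasta
#' @param seqs A named [Biostrings::DNAStringSet] (or list coercible to one).
#' @export
write_fasta <- function(seqs, path) {
  if (!methods::is(seqs, "DNAStringSet"))
    seqs <- Biostrings::DNAStringSet(vapply(seqs, as.character, ""))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read / write band patterns (CSV: animal, semicolon-separated sizes)
#'
#' @param path File path.
#' @return `read_band_patterns()`: a list of [band_pattern()]s.
#' @export
read_band_patterns <- function(path) {
  if (!file.exists(path)) stop("band pattern file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (!all(c("animal", "sizes") %in% names(df)))
    stop("band pattern file must have columns: animal, sizes")
  lapply(seq_len(nrow(df)), function(i) {
    s <- df$sizes[i]
    sizes <- if (!nzchar(trimws(s))) numeric() else {
      v <- suppressWarnings(as.numeric(strsplit(s, ";")[[1]]))
      if (any(is.na(v)))
        stop_line(path, i + 1L, paste0("non-numeric band size in: ", s))
      v
    }
    if (length(sizes)) band_pattern(sizes, animal = df$animal[i])
    else structure(list(animal = df$animal[i], sizes = numeric()),
                   class = "band_pattern")
  })
}

#' @rdname read_band_patterns
#' @param patterns A list of [band_pattern()]s.
#' @export
write_band_patterns <- function(patterns, path) {
  df <- data.frame(
    animal = vapply(patterns, `[[`, "", "animal"),
    sizes = vapply(patterns, function(p) paste(p$sizes, collapse = ";"), ""),
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Summarise band calls as a table / write them as CSV
#'
#' @param calls A list of `band_call` objects (see [interpret_bands()]).
#' @return `band_call_table()`: a data.frame with one row per animal.
#' @export
band_call_table <- function(calls) {
  data.frame(
    animal = vapply(calls, `[[`, "", "animal"),
    status = vapply(calls, `[[`, "", "status"),
    Cs29_genotype = vapply(calls, `[[`, "", "cs29_genotype"),
    Cs6_status = vapply(calls, `[[`, "", "cs6_status"),
    note = vapply(calls, `[[`, "", "cs6_note"),
    stringsAsFactors = FALSE
  )
}

#' @rdname band_call_table
#' @param path Output CSV path.
#' @export
write_band_calls <- function(calls, path) {
  utils::write.csv(band_call_table(calls), path, row.names = FALSE)
  invisible(path)
}

#' Read / write a cohort genotype table (CSV)
#'
#' Schema: `cohort, animal, Cs29_genotype, Cs6_status` (extra columns such
#' as `breed` are carried through). `Cs29_genotype` must be one of
#' hom/het/non-carrier, `Cs6_status` one of positive/negative.
#'
#' @param path File path.
#' @return `read_cohort_csv()`: a validated data.frame.
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cohort", "animal", "Cs29_genotype", "Cs6_status")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("cohort file missing column(s): ", paste(miss, collapse = ", "))
  bad <- which(!df$Cs29_genotype %in% c("hom", "het", "non-carrier"))
  if (length(bad))
    stop_line(path, bad[1] + 1L,
              paste0("invalid Cs29_genotype '", df$Cs29_genotype[bad[1]],
                     "' (expected hom/het/non-carrier)"))
  bad <- which(!df$Cs6_status %in% c("positive", "negative"))
  if (length(bad))
    stop_line(path, bad[1] + 1L,
              paste0("invalid Cs6_status '", df$Cs6_status[bad[1]],
                     "' (expected positive/negative)"))
  df
}

#' @rdname read_cohort_csv
#' @param df A cohort genotype data.frame.
#' @export
write_cohort_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
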