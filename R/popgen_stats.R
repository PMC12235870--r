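# Cohort allele/genotype frequency estimation with exact Clopper-Pearson
# confidence intervals and an enumeration-based Fisher exact test.

# round half away from zero (report convention; round() rounds half to even)
round_half_away <- function(x, digits = 2) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

new_freq_estimate <- function(point, k, n_trials, ci, level) {
  stopifnot(k >= 0, k <= n_trials, n_trials >= 1)
  structure(list(point = point, k = as.integer(k),
                 n_trials = as.integer(n_trials),
                 ci_low = ci[1], ci_high = ci[2], level = level),
            class = "freq_estimate")
}

#' @export
print.freq_estimate <- function(x, ...) {
  cat(sprintf("<freq_estimate> %s  [%d/%d, %g%% CI]\n",
              format_ci(x), x$k, x$n_trials, 100 * x$level))
  invisible(x)
}

#' Format a frequency estimate as "point (low-high)"
#'
#' Rounds half away from zero to `digits` decimals, the convention used for
#' reporting allele-frequency tables; full precision is retained in the
#' underlying object.
#'
#' @param x A `freq_estimate`.
#' @param digits Decimal places (default 2).
#' @return A string such as `"0.15 (0.06-0.30)"`.
#' @export
format_ci <- function(x, digits = 2) {
  f <- function(v) sprintf(paste0("%.", digits, "f"), round_half_away(v, digits))
  sprintf("%s (%s-%s)", f(x$point), f(x$ci_low), f(x$ci_high))
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Computes the equal-tailed exact interval for a binomial proportion by
#' inverting the binomial test: the lower bound solves
#' `P(X >= k | n, p) = (1 - level)/2` (0 when `k = 0`) and the upper bound
#' solves `P(X <= k | n, p) = (1 - level)/2` (1 when `k = n`). The
#' inversion uses the incomplete-beta representation of the binomial tail
#' (`qbeta`), which is exact to floating-point precision.
#'
#' @param k Number of successes (`0 <= k <= n`).
#' @param n Number of trials (`>= 1`).
#' @param level Confidence level in (0, 1); default 0.95.
#' @return Numeric vector `c(ci_low, ci_high)`.
#' @examples
#' clopper_pearson_ci(6, 40)   # 0.057, 0.298
#' clopper_pearson_ci(0, 10)   # 0, 0.308  (upper bound 1 - 0.025^(1/10))
#' @export
clopper_pearson_ci <- function(k, n, level = 0.95) {
  if (length(k) != 1 || length(n) != 1 || is.na(k) || is.na(n))
    stop("k and n must be single non-missing values")
  if (k != floor(k) || n != floor(n)) stop("k and n must be integers")
  if (n < 1) stop("n must be >= 1")
  if (k < 0 || k > n) stop("k must satisfy 0 <= k <= n")
  if (!(level > 0 && level < 1)) stop("level must be in (0, 1)")
  alpha <- (1 - level) / 2
  low <- if (k == 0) 0 else stats::qbeta(alpha, k, n - k + 1)
  high <- if (k == n) 1 else stats::qbeta(1 - alpha, k + 1, n - k)
  c(low, high)
}

#' Allele frequency of a codominant marker from genotype counts
#'
#' For a codominant assay (all three genotype classes observable, as for
#' Cs29) the allele frequency is estimated on the gametic scale: each of
#' the `n` animals contributes two trials, a homozygote two successes and a
#' heterozygote one, so the point estimate is
#' `(2 * n_hom + n_het) / (2 * n_animals)` with an exact binomial CI on
#' `k = 2 * n_hom + n_het` out of `2 * n_animals` trials.
#'
#' @param n_hom,n_het,n_wt Genotype class counts (homozygous carriers,
#'   heterozygotes, non-carriers).
#' @param level Confidence level (default 0.95).
#' @return A `freq_estimate`.
#' @examples
#' allele_freq_codominant(0, 6, 14)  # 0.15 (0.06-0.30)
#' @export
allele_freq_codominant <- function(n_hom, n_het, n_wt, level = 0.95) {
  counts <- c(n_hom, n_het, n_wt)
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("genotype counts must be non-negative integers")
  n_animals <- sum(counts)
  if (n_animals == 0) stop("no animals: all genotype counts are zero")
  k <- 2 * n_hom + n_het
  n_trials <- 2 * n_animals
  new_freq_estimate(k / n_trials, k, n_trials,
                    clopper_pearson_ci(k, n_trials, level), level)
}

#' Presence frequency of a dominant marker
#'
#' For a dominant assay (heterozygotes and homozygotes indistinguishable,
#' as for Cs6) only the frequency of positive animals is estimable without
#' extra assumptions; the unit of observation is the animal, so
#' `n_trials = n`.
#'
#' @param n_positive Number of marker-positive animals.
#' @param n Number of animals typed.
#' @param level Confidence level (default 0.95).
#' @return A `freq_estimate`.
#' @examples
#' presence_freq_dominant(10, 25)  # 0.40 (0.21-0.61)
#' @export
presence_freq_dominant <- function(n_positive, n, level = 0.95) {
  if (n < 1) stop("n must be >= 1")
  if (n_positive < 0 || n_positive > n)
    stop("n_positive must satisfy 0 <= n_positive <= n")
  new_freq_estimate(n_positive / n, n_positive, n,
                    clopper_pearson_ci(n_positive, n, level), level)
}

#' Hardy-Weinberg allele-frequency estimate for a dominant marker
#'
#' Under Hardy-Weinberg equilibrium the fraction of marker-positive
#' animals is `1 - (1 - q)^2`, so `q = 1 - sqrt(1 - f_positive)`. This is
#' an extension beyond plain presence reporting: it leans on the HWE
#' assumption, which is why presence frequencies are the primary output
#' for dominant markers and this estimator is clearly separated.
#'
#' @param f_positive Observed fraction of positive animals in `[0, 1]`.
#' @return The implied allele frequency `q`.
#' @export
hwe_dominant_allele_freq <- function(f_positive) {
  if (f_positive < 0 || f_positive > 1) stop("f_positive must be in [0, 1]")
  1 - sqrt(1 - f_positive)
}

# ---- Fisher exact test by enumeration --------------------------------------

# log conditional probability of an r x c table given its margins
log_table_prob <- function(tab) {
  sum(lgamma(rowSums(tab) + 1)) + sum(lgamma(colSums(tab) + 1)) -
    lgamma(sum(tab) + 1) - sum(lgamma(tab + 1))
}

# enumerate all non-negative integer tables with the given margins,
# calling fn(table) for each; errors if more than max_tables are visited
enumerate_margin_tables <- function(row_sums, col_sums, fn,
                                    max_tables = 2e6) {
  r <- length(row_sums); c <- length(col_sums)
  tab <- matrix(0L, r, c)
  count <- 0L
  recurse <- function(i, j, row_rem, col_rem) {
    if (i == r) {
      # last row is determined by the column remainders
      if (any(col_rem < 0)) return(invisible())
      tab[r, ] <<- col_rem
      count <<- count + 1L
      if (count > max_tables)
        stop("enumeration exceeds ", max_tables,
             " tables; use a Monte-Carlo approximation instead")
      fn(tab)
      return(invisible())
    }
    if (j == c) {
      # last cell of the row is determined by the row remainder
      v <- row_rem
      if (v < 0 || v > col_rem[c]) return(invisible())
      tab[i, c] <<- v
      recurse(i + 1L, 1L, row_sums[i + 1L],
              col_rem - c(rep(0L, c - 1L), v))
      return(invisible())
    }
    for (v in 0:min(row_rem, col_rem[j])) {
      tab[i, j] <<- v
      cr <- col_rem; cr[j] <- cr[j] - v
      recurse(i, j + 1L, row_rem - v, cr)
    }
  }
  recurse(1L, 1L, row_sums[1L], as.integer(col_sums))
  invisible(count)
}

#' Fisher exact test for an r x c contingency table, by full enumeration
#'
#' Computes the exact conditional two-sided p-value: all tables sharing
#' the observed margins are enumerated, and the p-value is the sum of
#' hypergeometric (multivariate) probabilities of tables no more probable
#' than the observed one. Probabilities within a relative tolerance of
#' 1e-7 of the observed table's probability are counted as ties, absorbing
#' floating-point noise in the comparison.
#'
#' @param tab A matrix of non-negative integer counts with at least 2 rows
#'   and 2 columns.
#' @param max_tables Cap on the number of enumerated tables (default 2e6);
#'   beyond it the function stops and advises a Monte-Carlo approach.
#' @param tie_tol Relative tolerance for probability ties (default 1e-7).
#' @return The two-sided p-value in (0, 1].
#' @examples
#' fisher_exact(matrix(c(3, 1, 1, 3), 2))  # 0.4857143
#' @export
fisher_exact <- function(tab, max_tables = 2e6, tie_tol = 1e-7) {
  tab <- as.matrix(tab)
  if (any(is.na(tab)) || any(tab < 0) || any(tab != floor(tab)))
    stop("table cells must be non-negative integers")
  if (nrow(tab) < 2 || ncol(tab) < 2)
    stop("table must have at least 2 rows and 2 columns")
  if (sum(tab) < 1) stop("table total must be >= 1")
  lp_obs <- log_table_prob(tab)
  # sum probabilities <= observed (with relative tie tolerance on the
  # probability scale: log p <= log p_obs + log(1 + tol))
  cutoff <- lp_obs + log1p(tie_tol)
  p <- 0
  enumerate_margin_tables(rowSums(tab), colSums(tab), function(t2) {
    lp <- log_table_prob(t2)
    if (lp <= cutoff) p <<- p + exp(lp)
  }, max_tables = max_tables)
  min(p, 1)
}

# ---- Cohort comparison ------------------------------------------------------

#' Create a cohort genotype-count table
#'
#' @param label Cohort label (breed and/or sampling period).
#' @param counts Named non-negative integer vector of genotype-class counts,
#'   e.g. `c(hom = 5, het = 8, "non-carrier" = 17)` or
#'   `c(positive = 10, negative = 15)`.
#' @return An object of class `cohort_table`.
#' @export
cohort_table <- function(label, counts) {
  if (is.null(names(counts)) || any(!nzchar(names(counts))))
    stop("counts must be a named vector of genotype classes")
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("counts must be non-negative integers")
  if (sum(counts) < 1) stop("cohort must contain at least one animal")
  structure(list(label = label, counts = counts, n = sum(counts)),
            class = "cohort_table")
}

cohort_freq <- function(cohort, level = 0.95) {
  cls <- names(cohort$counts)
  if (all(c("hom", "het", "non-carrier") %in% cls)) {
    allele_freq_codominant(cohort$counts[["hom"]], cohort$counts[["het"]],
                           cohort$counts[["non-carrier"]], level)
  } else if (all(c("positive", "negative") %in% cls)) {
    presence_freq_dominant(cohort$counts[["positive"]], cohort$n, level)
  } else {
    stop("cannot derive a frequency from classes: ",
         paste(cls, collapse = ", "))
  }
}

#' Compare genotype frequencies between two cohorts
#'
#' Assembles the per-cohort frequency estimates with exact CIs, tests the
#' difference in genotype-class frequencies with the enumeration
#' [fisher_exact()] test on the 2 x c table of counts, and reports whether
#' the two confidence intervals overlap. The genotype classes entering the
#' Fisher test are configurable: `"full"` uses all classes as observed
#' (e.g. hom/het/non-carrier, a 2 x 3 table); `"carrier"` collapses to
#' carrier vs non-carrier (2 x 2).
#'
#' @param cohort_a,cohort_b [cohort_table()]s with identical genotype
#'   classes.
#' @param classes `"full"` (default) or `"carrier"`.
#' @param level Confidence level for the CIs (default 0.95).
#' @return A list of class `cohort_comparison`: `freq_a`, `freq_b`
#'   (`freq_estimate`s), `fisher_p`, `ci_overlap` (logical), `table`.
#' @export
compare_cohorts <- function(cohort_a, cohort_b, classes = c("full", "carrier"),
                            level = 0.95) {
  classes <- match.arg(classes)
  if (!identical(sort(names(cohort_a$counts)), sort(names(cohort_b$counts))))
    stop("cohorts have mismatched genotype classes")
  cls <- names(cohort_a$counts)
  ca <- cohort_a$counts[cls]
  cb <- cohort_b$counts[cls]
  if (classes == "carrier" && all(c("hom", "het", "non-carrier") %in% cls)) {
    ca <- c(carrier = sum(ca[c("hom", "het")]), "non-carrier" = ca[["non-carrier"]])
    cb <- c(carrier = sum(cb[c("hom", "het")]), "non-carrier" = cb[["non-carrier"]])
  }
  tab <- rbind(ca, cb)
  rownames(tab) <- c(cohort_a$label, cohort_b$label)
  fa <- cohort_freq(cohort_a, level)
  fb <- cohort_freq(cohort_b, level)
  structure(list(
    freq_a = fa, freq_b = fb,
    fisher_p = fisher_exact(tab),
    ci_overlap = fa$ci_low <= fb$ci_high && fb$ci_low <= fa$ci_high,
    table = tab
  ), class = "cohort_comparison")
}

#' @export
print.cohort_comparison <- function(x, ...) {
  cat("<cohort_comparison>\n")
  cat(sprintf("  %s: %s\n", rownames(x$table)[1], format_ci(x$freq_a)))
  cat(sprintf("  %s: %s\n", rownames(x$table)[2], format_ci(x$freq_b)))
  cat(sprintf("  Fisher exact p = %.4g; CIs %s\n", x$fisher_p,
              if (x$ci_overlap) "overlap" else "do not overlap"))
  invisible(x)
}

#' Cohort frequency report from a per-animal genotype table
#'
#' Takes a per-animal table in the schema the population simulator and the
#' band decoder emit (`cohort`, `Cs29_genotype` with values
#' hom/het/non-carrier, `Cs6_status` with values positive/negative) and
#' builds a per-cohort report: n, Cs29 allele frequency with exact CI
#' (codominant, gametic scale), Cs6 positive-genotype frequency with exact
#' CI (dominant, animal scale).
#'
#' @param animals A data.frame with columns `cohort`, `Cs29_genotype`,
#'   `Cs6_status`.
#' @param level Confidence level (default 0.95).
#' @return A data.frame with one row per cohort: `cohort`, `n`,
#'   `cs29_freq`, `cs29_low`, `cs29_high`, `cs29_display`, `cs6_freq`,
#'   `cs6_low`, `cs6_high`, `cs6_display`.
#' @export
cohort_report <- function(animals, level = 0.95) {
  need <- c("cohort", "Cs29_genotype", "Cs6_status")
  if (!all(need %in% names(animals)))
    stop("animals table needs columns: ", paste(need, collapse = ", "))
  out <- lapply(split(animals, animals$cohort), function(d) {
    g <- table(factor(d$Cs29_genotype,
                      levels = c("hom", "het", "non-carrier")))
    cs29 <- allele_freq_codominant(g[["hom"]], g[["het"]],
                                   g[["non-carrier"]], level)
    cs6 <- presence_freq_dominant(sum(d$Cs6_status == "positive"),
                                  nrow(d), level)
    data.frame(
      cohort = d$cohort[1], n = nrow(d),
      cs29_freq = cs29$point, cs29_low = cs29$ci_low, cs29_high = cs29$ci_high,
      cs29_display = format_ci(cs29),
      cs6_freq = cs6$point, cs6_low = cs6$ci_low, cs6_high = cs6$ci_high,
      cs6_display = format_ci(cs6),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
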