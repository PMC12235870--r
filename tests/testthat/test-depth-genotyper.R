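test_that("bin_depth computes length-weighted window means", {
  # uniform depth fills every window with the same value
  iv <- data.frame(chrom = "1", start = 0, end = 50000, depth = 30)
  tr <- bin_depth(iv, 10000)
  expect_equal(nrow(tr), 5L)
  expect_true(all(tr$depth == 30))

  # half a window at 20, half at 40 -> 30
  iv2 <- data.frame(chrom = "1", start = c(0, 5000), end = c(5000, 10000),
                    depth = c(20, 40))
  expect_equal(bin_depth(iv2, 10000)$depth, 30)

  # windows with no coverage are missing, not zero
  iv3 <- data.frame(chrom = "1", start = 25000, end = 30000, depth = 12)
  tr3 <- bin_depth(iv3, 10000)
  expect_true(is.na(tr3$depth[1]))
  expect_equal(tr3$depth[3], 12)
})

test_that("bin_depth equals a per-base oracle on intervals spanning windows", {
  set.seed(31)
  # 100 kb toy genome: random-length intervals crossing window boundaries
  breaks <- sort(sample(1:99999, 40))
  edges <- c(0, breaks, 100000)
  iv <- data.frame(chrom = "1", start = edges[-length(edges)],
                   end = edges[-1],
                   depth = sample(5:50, length(edges) - 1, replace = TRUE))
  tr <- bin_depth(iv, 10000)

  # oracle: expand to per-base depth, average each window
  base <- rep(NA_real_, 100000)
  for (r in seq_len(nrow(iv)))
    base[(iv$start[r] + 1):iv$end[r]] <- iv$depth[r]
  oracle <- vapply(1:10, function(w)
    mean(base[((w - 1) * 10000 + 1):(w * 10000)], na.rm = TRUE), 0)
  expect_equal(tr$depth, oracle)
})

test_that("bin_depth rejects unsorted and overlapping intervals", {
  bad1 <- data.frame(chrom = "1", start = c(5000, 0), end = c(10000, 5000),
                     depth = c(1, 2))
  expect_error(bin_depth(bad1, 10000), "not sorted")
  bad2 <- data.frame(chrom = "1", start = c(0, 4000), end = c(5000, 9000),
                     depth = c(1, 2))
  expect_error(bin_depth(bad2, 10000), "overlapping")
})

test_that("standardization divides by the genome-wide median", {
  tr <- bin_depth(data.frame(chrom = "1", start = c(0, 10000, 20000),
                             end = c(10000, 20000, 30000),
                             depth = c(10, 20, 30)), 10000)
  st <- standardize(tr)
  expect_equal(st$ratio, c(0.5, 1.0, 1.5))
  expect_equal(median(st$ratio), 1)

  flat <- bin_depth(data.frame(chrom = "1", start = 0, end = 50000,
                               depth = 26), 10000)
  expect_true(all(standardize(flat)$ratio == 1))

  zero <- bin_depth(data.frame(chrom = "1", start = 0, end = 50000,
                               depth = 0), 10000)
  expect_error(standardize(zero), "median")
})

test_that("standardization is idempotent and scale-invariant", {
  set.seed(12)
  tr <- simulate_depth_track(diploid_genotype(c("Cs29", "wt")), test_models(),
                             test_regions(), depth_sim_config(seed = 12))
  st <- standardize(tr)
  expect_equal(standardize(st)$ratio, st$ratio)

  scaled <- tr
  scaled$depth <- scaled$depth * 3.7
  expect_equal(standardize(scaled)$ratio, st$ratio)
})

test_that("region copy ratio is the median over fully-contained windows", {
  # nine windows; the six baseline windows pin the genome-wide median at 26,
  # so the last three have standardized ratios 1.4, 1.5, 1.6
  tr <- data.frame(
    chrom = "6",
    start = seq(0, 80000, 10000), end = seq(10000, 90000, 10000),
    depth = c(rep(26, 6), 36.4, 39, 41.6)
  )
  class(tr) <- c("depth_track", "data.frame")
  st <- standardize(tr)
  expect_equal(region_copy_ratio(st, genomic_region("6", 60000, 90000)), 1.5)
  expect_equal(region_copy_ratio(st, genomic_region("6", 0, 90000)), 1)
  # boundary-straddling windows are excluded; none fully inside -> error
  expect_error(region_copy_ratio(st, genomic_region("6", 5000, 12000)),
               "no non-missing windows")
  expect_error(region_copy_ratio(st, genomic_region("7", 0, 90000)),
               "no non-missing windows")
  expect_error(region_copy_ratio(tr, genomic_region("6", 0, 90000)),
               "standardize")
})

test_that("the caller reproduces the expected-ratio decision rule", {
  models <- test_models()
  regions <- test_regions()
  obs <- function(kit, cs6) c(KIT = kit, Cs6_chr29 = cs6)
  expect_equal(call_genotype(obs(1.5, 1.0), regions, models)$genotype_label,
               "Cs29/wt")
  expect_equal(call_genotype(obs(2.0, 1.0), regions, models)$genotype_label,
               "Cs29/Cs29")
  expect_equal(call_genotype(obs(1.5, 1.5), regions, models)$genotype_label,
               "Cs6/wt")
  wtcall <- call_genotype(obs(1.02, 0.98), regions, models)
  expect_equal(wtcall$genotype_label, "wt/wt")
  expect_equal(wtcall$flag, "pass")
  expect_error(call_genotype(obs(1, 1), regions, models, genotypes = list()),
               "empty genotype space")
})

test_that("single-region calls equal a nearest-expected-ratio classifier", {
  kit <- test_kit_region()
  models <- cs_allele_models(kit_region = kit)[c("wt", "Cs29")]
  gts <- genotype_space(c("wt", "Cs29"))
  expected <- c(1.0, 1.5, 2.0)  # wt/wt, Cs29/wt, Cs29/Cs29
  for (r in seq(0.8, 2.2, by = 0.01)) {
    call <- call_genotype(c(KIT = r), list(kit), models, genotypes = gts)
    oracle <- names(gts)[which.min(abs(expected - r))]
    expect_equal(call$genotype_label, oracle, info = paste("ratio", r))
  }
})

test_that("calls near class midpoints or with tied scores are ambiguous", {
  kit <- test_kit_region()
  models <- cs_allele_models(kit_region = kit)[c("wt", "Cs29")]
  gts <- genotype_space(c("wt", "Cs29"))
  mid <- call_genotype(c(KIT = 1.27), list(kit), models, genotypes = gts)
  expect_equal(mid$flag, "ambiguous")
  clear <- call_genotype(c(KIT = 1.52), list(kit), models, genotypes = gts)
  expect_equal(clear$flag, "pass")
})

test_that("the caller recovers simulated genotypes and flags low depth", {
  models <- test_models()
  regions <- test_regions()
  gts <- genotype_space()
  run <- function(mean_depth, n = 120, seed0 = 500) {
    correct <- 0; flagged <- 0
    for (i in seq_len(n)) {
      truth <- gts[[((i - 1) %% 6) + 1]]
      cfg <- depth_sim_config(mean_depth = mean_depth, seed = seed0 + i)
      tr <- simulate_depth_track(truth, models, regions, cfg)
      call <- call_genotype_track(tr, regions, models)
      correct <- correct + (call$genotype_label == format(truth))
      flagged <- flagged + (call$flag == "ambiguous")
    }
    c(acc = correct / n, flag = flagged / n)
  }
  deep <- run(26)
  expect_gte(deep[["acc"]], 0.99)
  # with 150 windows per region the median is precise down to a few X;
  # degradation (miscalls and ambiguity flags) appears at ~2X coverage
  shallow <- run(2)
  expect_lt(shallow[["acc"]], deep[["acc"]])
  expect_gt(shallow[["flag"]], deep[["flag"]])
})

test_that("call tables and plot tables expose the expected columns", {
  models <- test_models()
  regions <- test_regions()
  tr <- standardize(simulate_depth_track(diploid_genotype(c("Cs29", "wt")),
                                         models, regions,
                                         depth_sim_config(seed = 77)))
  call <- call_genotype_track(tr, regions, models, animal = "cow1")
  tab <- depth_call_table(list(call))
  expect_equal(tab$animal, "cow1")
  expect_equal(tab$genotype, "Cs29/wt")
  expect_true(all(c("ratio_KIT", "ratio_Cs6_chr29", "score", "flag") %in%
                    names(tab)))

  pt <- coverage_plot_table(tr, test_kit_region(), pad = 100000)
  expect_true(all(c("chrom", "midpoint", "ratio", "in_region") %in% names(pt)))
  expect_equal(attr(pt, "reference_lines"), c(1, 1.5, 2))
  expect_true(any(pt$in_region))
})
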