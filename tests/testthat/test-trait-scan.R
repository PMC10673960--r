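# a genoprob array built directly from hard codes (no HMM), for scan tests
probs_from_codes <- function(codes, cm = seq_len(nrow(codes)), lg = 1L) {
  M <- nrow(codes); n <- ncol(codes)
  pr <- array(0, c(n, M, 3), dimnames = list(colnames(codes), rownames(codes),
                                             c("AA", "AB", "BB")))
  for (s in c("AA", "AB", "BB"))
    pr[, , s] <- t(codes == s) * 1
  attr(pr, "map") <- data.frame(
    marker_id = if (is.null(rownames(codes))) sprintf("m%d", 1:M)
                else rownames(codes),
    lg = rep(lg, length.out = M), cm = cm)
  pr
}

test_that("identical genotype probabilities give zero LOD everywhere", {
  codes <- matrix("AB", 4, 20)
  pr <- probs_from_codes(codes)
  scan <- binary_scan(pr, rep(c(0, 1), 10))
  expect_true(all(scan$lod == 0))
})

test_that("perfect separation saturates at the Bernoulli bound", {
  # 10 offspring, 5 BB affected / 5 AA unaffected: the saturated model has
  # LL 0, the null 10 ln(1/2), so LOD = 10 log10(2)
  codes <- matrix(rep(c("BB", "AA"), each = 5), 1, 10)
  pr <- probs_from_codes(codes)
  y <- rep(c(1, 0), each = 5)
  scan <- binary_scan(pr, y)
  expect_equal(scan$lod, 10 * log10(2), tolerance = 1e-4)
})

test_that("single-class phenotypes yield zero LOD with a warning", {
  codes <- matrix(sample(c("AA", "BB"), 30, TRUE), 3, 10)
  pr <- probs_from_codes(codes)
  expect_warning(scan <- binary_scan(pr, rep(1, 10)), "single class")
  expect_true(all(scan$lod == 0))
})

test_that("the scan localises a fully penetrant locus", {
  # recessive trait deterministic in the hidden intercross genotype (both
  # parents informative), observed through noisy codes
  set.seed(41)
  hits <- 0
  for (rep in 1:100) {
    mk <- data.frame(lg = 1L, cm_pos = seq(0, 48, by = 2))
    tm <- make_transmissions(mk, 75, 50, seed = 1000 + rep,
                             both_parents = TRUE)
    m <- nrow(mk)
    truth <- matrix(paste0(tm$pat, "|", tm$mat), m)
    codes_true <- to_f2_codes(truth)
    locus <- which.min(abs(mk$cm_pos - 24))
    y <- as.numeric(codes_true[locus, ] == "BB")
    # observation noise: 1% miscodes, 5% missing
    codes <- codes_true
    flip <- matrix(runif(length(codes)) < 0.01, m)
    codes[flip] <- vapply(codes[flip], function(g)
      sample(setdiff(c("AA", "AB", "BB"), g), 1), "")
    codes[matrix(runif(length(codes)) < 0.05, m)] <- NA
    map <- data.frame(marker_id = sprintf("m%02d", seq_len(m)), lg = 1L,
                      cm_pos = mk$cm_pos)
    rownames(codes) <- map$marker_id
    pr <- calc_genoprob(map, codes, scan_params(genotyping_error = 0.01))
    scan <- binary_scan(pr, y)
    if (abs(scan$cm[which.max(scan$lod)] - mk$cm_pos[locus]) <= 5)
      hits <- hits + 1
  }
  expect_gte(hits, 95)
})

test_that("permutation thresholds are sane at the edges", {
  set.seed(5)
  codes <- matrix(sample(c("AA", "AB", "BB"), 5 * 40, TRUE,
                         prob = c(0.25, 0.5, 0.25)), 5, 40)
  pr <- probs_from_codes(codes)
  y <- rbinom(40, 1, 0.5)
  thr <- permutation_threshold(pr, y, scan_params(n_perm = 50, seed = 2))
  expect_true(is.finite(thr) && thr >= 0)
  thr_all <- permutation_threshold(pr, y, scan_params(n_perm = 50, alpha = 1,
                                                      seed = 2))
  expect_equal(as.numeric(thr_all), min(attr(thr_all, "perm_max")))
  # determinism under the same seed
  thr2 <- permutation_threshold(pr, y, scan_params(n_perm = 50, seed = 2))
  expect_equal(as.numeric(thr), as.numeric(thr2))
})

test_that("peak finding applies the peakdrop rule", {
  scan <- data.frame(marker_id = sprintf("m%d", 1:3), lg = 1L,
                     cm = c(0, 5, 10), lod = c(5, 2.9, 5))
  p <- find_peaks(scan, threshold = 4, peakdrop = 1.8)
  expect_equal(nrow(p), 2)          # drop 2.1 >= 1.8: independent
  scan$lod <- c(5, 4.0, 5)
  p2 <- find_peaks(scan, threshold = 4, peakdrop = 1.8)
  expect_equal(nrow(p2), 1)         # drop 1.0 < 1.8: merged
  scan$lod <- c(1, 6, 2)
  p3 <- find_peaks(scan, threshold = 4, peakdrop = 1.8)
  expect_equal(nrow(p3), 1)
  expect_equal(p3$cm, 5)
})

test_that("credible intervals match the enumeration oracle and widen monotonically", {
  cm <- c(0, 3, 7, 11, 16)
  lod <- c(0.2, 2.5, 4, 2.8, 0.1)
  scan <- data.frame(marker_id = sprintf("m%d", 1:5), lg = 1L,
                     cm = cm, lod = lod)
  ci <- bayes_interval(scan, 1, 0.95)
  oracle <- bayes_oracle(cm, lod, 0.95)
  expect_equal(c(ci$start_cm, ci$end_cm), unname(oracle))
  # all mass at one position: zero-width interval
  one <- data.frame(marker_id = sprintf("m%d", 1:3), lg = 1L,
                    cm = c(0, 5, 10), lod = c(0, 12, 0))
  ci1 <- bayes_interval(one, 1, 0.95)
  expect_equal(ci1$start_cm, 5)
  expect_equal(ci1$end_cm, 5)
  # widening ci_prob never shrinks the interval
  widths <- vapply(c(0.5, 0.8, 0.9, 0.99), function(p) {
    ci <- bayes_interval(scan, 1, p)
    ci$end_cm - ci$start_cm
  }, 1)
  expect_true(all(diff(widths) >= 0))
})

test_that("allele effects carry the dominance sign pattern", {
  # fully penetrant recessive-B trait: BB affected, AA/AB unaffected
  set.seed(13)
  codes <- matrix(sample(c("AA", "AB", "BB"), 60, TRUE), 2, 30)
  y <- as.numeric(codes[1, ] == "BB")
  pr <- probs_from_codes(codes)
  eff <- allele_effects(pr, y, 1)
  expect_gt(eff$eff_BB[1], eff$eff_AB[1])
  expect_gt(eff$eff_BB[1], eff$eff_AA[1])
  expect_lt(abs(eff$eff_AB[1] - eff$eff_AA[1]), 2)
  expect_true(all(abs(unlist(eff[, c("eff_AA", "eff_AB", "eff_BB")])) <= 20))
  # trait independent of genotype: effects agree within tolerance
  y0 <- rep(c(0, 1), 15)
  eff0 <- allele_effects(probs_from_codes(
    matrix(rep(c("AA", "AB", "BB"), 10), 1, 30)), y0, 1)
  expect_lt(max(abs(diff(as.numeric(eff0[1, c("eff_AA", "eff_AB",
                                              "eff_BB")])))), 1.5)
})

test_that("segregation checking counts phenotype-incompatible homozygotes", {
  codes <- rbind(pos1 = c("BB", "BB", "AA", "AA", "AB", "AB", "AA", "AA"))
  y <- c(1, 1, 0, 0, 1, 0, 1, 1)  # two 'yellow' AAs: the rejection pattern
  seg <- segregation_check(codes, y, positions = 7.429, bb_value = 1)
  expect_equal(seg$n_violations, 2)
  expect_false(seg$consistent)

  y_ok <- c(1, 1, 0, 0, 1, 0, 0, 0)
  seg_ok <- segregation_check(codes, y_ok, positions = 31.385, bb_value = 1)
  expect_equal(seg_ok$n_violations, 0)
  expect_true(seg_ok$consistent)

  het_only <- rbind(p = rep("AB", 6))
  seg_ab <- segregation_check(het_only, c(1, 0, 1, 0, 1, 0), 1, bb_value = 1)
  expect_equal(seg_ab$n_violations, 0)
  expect_true(seg_ab$consistent)

  all_na <- rbind(p = rep(NA_character_, 6))
  seg_na <- segregation_check(all_na, c(1, 0, 1, 0, 1, 0), 1, bb_value = 1)
  expect_true(seg_na$uninformative)
  expect_false(seg_na$consistent)
})

test_that("candidate regions reproduce the printed widths from printed positions", {
  seg_c <- data.frame(position = c(31.385, 32.056, 32.727),
                      n_violations = 0, n_homozygotes = 30,
                      uninformative = FALSE, consistent = TRUE)
  reg_c <- candidate_region(seg_c)
  expect_equal(reg_c$width_cm, 1.3)

  seg_u <- data.frame(position = c(39.511, 40.182), n_violations = 0,
                      n_homozygotes = 30, uninformative = FALSE,
                      consistent = TRUE)
  reg_u <- candidate_region(seg_u)
  expect_equal(reg_u$width_cm, 0.7)

  single <- candidate_region(seg_u[1, ])
  expect_equal(single$width_cm, 0)

  none <- candidate_region(
    data.frame(position = 1, n_violations = 2, n_homozygotes = 10,
               uninformative = FALSE, consistent = FALSE))
  expect_false(none$localised)
})
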