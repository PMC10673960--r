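test_that("haldane map function matches its closed form and limits", {
  expect_equal(haldane_r(0), 0)
  expect_equal(haldane_r(10), (1 - exp(-0.2)) / 2, tolerance = 1e-12)
  expect_equal(haldane_r(10), 0.09063, tolerance = 1e-4)
  expect_lt(abs(haldane_r(1e6) - 0.5), 1e-12)
  expect_error(haldane_r(-1), "non-negative")
  expect_equal(haldane_cm(haldane_r(17.3)), 17.3, tolerance = 1e-9)
  expect_error(haldane_cm(0.5))
})

test_that("simulated genomes respect lengths, sorting and determinism", {
  cfg <- cross_config(lg_lengths_cm = c(50, 0), markers_per_lg = c(8, 5),
                      seed = 3)
  mk <- simulate_genome(cfg)
  expect_equal(nrow(mk), 13)
  expect_true(all(mk$cm_pos[mk$lg == 2] == 0))  # degenerate zero length
  expect_false(is.unsorted(mk$cm_pos[mk$lg == 1]))
  expect_identical(mk, simulate_genome(cfg))
  expect_error(cross_config(lg_lengths_cm = c(-5), markers_per_lg = 3),
               "non-negative")
  # contigs span contiguous runs of markers
  runs <- rle(mk$contig_id)$values
  expect_equal(anyDuplicated(runs), 0)
})

test_that("the published 22 group lengths sum to the published total", {
  tab <- cnemoralis_lg_summary()
  cfg <- cross_config(lg_lengths_cm = tab$length_cm,
                      markers_per_lg = rep(5L, 22), seed = 1)
  mk <- simulate_genome(cfg)
  expect_equal(length(unique(mk$lg)), 22)
  expect_equal(sum(tapply(mk$cm_pos, mk$lg, max) * 0 + tab$length_cm),
               2143, tolerance = 1)
})

test_that("meiosis produces Haldane-consistent recombinant fractions", {
  loci <- data.frame(lg = 1L, cm_pos = c(20, 30))
  hap <- rbind(c(1L, 1L), c(2L, 2L))
  set.seed(42)
  n <- 1e5
  rec <- logical(n)
  for (i in seq_len(n)) {
    s <- snailmap:::meiosis_strands(loci, 60)
    rec[i] <- s[1] != s[2]
  }
  r_exp <- haldane_r(10)
  se <- sqrt(r_exp * (1 - r_exp) / n)
  expect_lt(abs(mean(rec) - r_exp), 3 * se)
})

test_that("zero-length groups give intact haplotypes; groups segregate independently", {
  loci <- data.frame(lg = c(1L, 1L, 2L), cm_pos = c(0, 0, 5))
  hap <- rbind(c(1L, 2L, 1L), c(2L, 1L, 2L))
  g <- simulate_meiosis(hap, loci, c(0, 50), seed = 5)
  expect_equal(length(unique(g$strand[1:2])), 1)  # intact within group
  # independence across groups: correlation of strands ~ 0
  set.seed(7)
  s1 <- integer(4000); s2 <- integer(4000)
  for (i in 1:4000) {
    s <- snailmap:::meiosis_strands(loci, c(0, 50))
    s1[i] <- s[1]; s2[i] <- s[3]
  }
  r_hat <- mean(s1 != s2)
  expect_lt(abs(r_hat - 0.5), 3 * sqrt(0.25 / 4000))
})

test_that("cross phenotypes segregate 1:1 under dominance", {
  cfg <- cross_config(n_offspring = 1e4, genotyping_error = 0,
                      missing_rate = 0, lg_lengths_cm = c(40),
                      markers_per_lg = c(3), seed = 9)
  loci <- default_trait_loci(lg_c = 1, cm_c = 20, lg_u = 1, cm_u = 30)
  cr <- simulate_cross(cfg, loci)
  yellow <- cr$phenotypes$value[cr$phenotypes$trait == "yellow"]
  expect_lt(abs(mean(yellow) - 0.5), 3 * sqrt(0.25 / 1e4))
})

test_that("error-free calls equal truth and the study headcount is 79", {
  cfg <- cross_config(n_offspring = 20, genotyping_error = 0,
                      missing_rate = 0, lg_lengths_cm = c(30, 30),
                      markers_per_lg = c(6, 6), seed = 2)
  cr <- simulate_cross(cfg, default_trait_loci(1, 10, 2, 10))
  expect_identical(cr$calls$gt, cr$truth$gt_true)

  cr79 <- simulate_cross(cross_config(lg_lengths_cm = c(50, 50),
                                      markers_per_lg = c(4, 4), seed = 1),
                         default_trait_loci(1, 25, 2, 25))
  expect_equal(nrow(cr79$samples), 79)
  expect_equal(sum(cr79$samples$role == "offspring"), 75)
})

test_that("the same seed reproduces a bit-identical dataset", {
  cfg <- cross_config(n_offspring = 15, lg_lengths_cm = c(40),
                      markers_per_lg = c(8), seed = 123)
  loci <- default_trait_loci(1, 10, 1, 30)
  expect_identical(simulate_cross(cfg, loci), simulate_cross(cfg, loci))
})

test_that("trait loci on nonexistent groups are rejected", {
  cfg <- cross_config(lg_lengths_cm = c(40), markers_per_lg = c(4))
  expect_error(simulate_cross(cfg, default_trait_loci(1, 10, 7, 10)),
               "nonexistent")
})
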