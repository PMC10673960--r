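test_that("grouping is transitive closure over the LOD threshold", {
  lod <- matrix(0, 3, 3)
  lod[1, 2] <- lod[2, 1] <- 12
  lod[2, 3] <- lod[3, 2] <- 12
  lod[1, 3] <- lod[3, 1] <- 0.1
  lg <- group_markers(lod, grouping_params(size_limit = 1,
                                           join_singles_lod = 1))
  expect_equal(length(unique(lg)), 1)   # one group {A,B,C}

  lg2 <- group_markers(lod, grouping_params(lod_limit = 13, size_limit = 1,
                                            join_singles_lod = 13))
  expect_true(all(table(lg2[lg2 > 0]) <= 1))  # three singletons
})

test_that("grouping equals connected components of the thresholded graph", {
  set.seed(31)
  # 100 markers, two planted clusters: within-LOD 15, between-LOD 2
  n <- 100
  truth <- rep(1:2, each = 50)
  lod <- matrix(2, n, n)
  same <- outer(truth, truth, "==")
  lod[same] <- 15
  lod <- lod + matrix(runif(n * n, -0.5, 0.5), n, n)
  lod <- (lod + t(lod)) / 2
  diag(lod) <- 0
  lg <- group_markers(lod, grouping_params(size_limit = 1,
                                           join_singles_lod = 5))
  expect_equal(length(unique(lg)), 2)
  expect_true(all(tapply(truth, lg, function(z) length(unique(z))) == 1))
  # independent oracle: igraph components of the thresholded graph
  g <- igraph::graph_from_adjacency_matrix(lod >= 9.5, mode = "undirected")
  comp <- igraph::components(g)$membership
  expect_equal(length(unique(paste(lg, comp))), length(unique(comp)))
})

test_that("small groups dissolve and singles rejoin by best linkage", {
  n <- 12
  lod <- matrix(0, n, n)
  block <- function(i, j, v) lod[i, j] <<- lod[j, i] <<- v
  for (i in 1:9) for (j in 1:9) if (i != j) block(i, j, 15)
  block(10, 11, 15)                 # a 2-marker group, below size_limit 3
  block(12, 3, 7)                   # a singleton linked at LOD 7
  lg <- group_markers(lod, grouping_params(size_limit = 3,
                                           join_singles_lod = 5))
  expect_equal(lg[10], 0)           # dissolved
  expect_equal(lg[11], 0)
  expect_equal(lg[12], lg[3])       # joined to the big group
})

test_that("ordering matches the exhaustive oracle for small groups", {
  set.seed(17)
  for (rep in 1:3) {
    m <- sample(5:8, 1)
    mk <- data.frame(lg = 1L, cm_pos = sort(runif(m, 0, 40)))
    tm <- make_transmissions(mk, 80, 50, seed = rep)
    rownames(tm$pat) <- rownames(tm$mat) <- sprintf("m%d", seq_len(m))
    ord <- order_markers(tm, n_restarts = 10, seed = rep)
    D <- pairwise_rf(tm)$r
    got <- sum(D[cbind(match(ord$marker_id[-m], rownames(D)),
                       match(ord$marker_id[-1], rownames(D)))])
    expect_equal(got, best_order_cost(D), tolerance = 1e-12)
  }
})

test_that("error-free dense data recovers the true order exactly", {
  mk <- data.frame(lg = 1L, cm_pos = c(0, 10, 20, 30))
  tm <- make_transmissions(mk, 200, 40, seed = 23)
  rownames(tm$pat) <- rownames(tm$mat) <- sprintf("m%d", 1:4)
  ord <- order_markers(tm, seed = 2)
  idx <- as.integer(sub("m", "", ord$marker_id))
  tau <- abs(cor(seq_len(4), idx, method = "kendall"))
  expect_equal(tau, 1)
  expect_false(is.unsorted(ord$cm_male))
  expect_equal(ord$cm_male[1], 0)
})

test_that("a two-marker group maps to the Haldane image of r-hat", {
  mk <- data.frame(lg = 1L, cm_pos = c(0, 15))
  tm <- make_transmissions(mk, 150, 30, seed = 3)
  rownames(tm$pat) <- rownames(tm$mat) <- c("a", "b")
  ord <- order_markers(tm)
  r <- pairwise_rf(tm)$r[1, 2]
  expect_equal(max(ord$cm_male), haldane_cm(r), tolerance = 1e-9)
})

test_that("map length is invariant to input order and reversal", {
  mk <- data.frame(lg = 1L, cm_pos = c(0, 7, 15, 26, 33))
  tm <- make_transmissions(mk, 120, 40, seed = 8)
  rownames(tm$pat) <- rownames(tm$mat) <- sprintf("m%d", 1:5)
  ord1 <- order_markers(tm, seed = 4)
  perm <- c(4, 1, 5, 3, 2)
  tm2 <- structure(list(pat = tm$pat[perm, ], mat = tm$mat[perm, ],
                        offspring = tm$offspring, phase_known = TRUE),
                   class = "snail_transmissions")
  ord2 <- order_markers(tm2, seed = 4)
  expect_equal(max(ord1$cm_male), max(ord2$cm_male), tolerance = 1e-9)
  expect_equal(ord1$marker_id, ord2$marker_id)  # canonical orientation
})

test_that("all-uninformative groups keep input order with zero distances", {
  tm <- structure(list(pat = matrix(NA_integer_, 3, 10,
                                    dimnames = list(c("a", "b", "c"), NULL)),
                       mat = matrix(NA_integer_, 3, 10,
                                    dimnames = list(c("a", "b", "c"), NULL)),
                       offspring = sprintf("O%d", 1:10),
                       phase_known = TRUE),
                  class = "snail_transmissions")
  expect_warning(ord <- order_markers(tm), "uninformative")
  expect_equal(ord$marker_id, c("a", "b", "c"))
  expect_true(all(ord$cm_male == 0))
})

test_that("LOD-matrix pruning applies the mean-minus-SD rule per location", {
  # sigma = 0: nothing removed
  expect_equal(prune_by_lod(c(1, 1, 1), rep("L1", 3)), rep(FALSE, 3))
  # {0.9, 0.9, 0.9, 0.0}: the zero-support SNP is removed
  expect_equal(prune_by_lod(c(0.9, 0.9, 0.9, 0), rep("L1", 4)),
               c(FALSE, FALSE, FALSE, TRUE))
  # {0.5, 0.6}: cut at ~0.479, none removed
  expect_equal(prune_by_lod(c(0.5, 0.6), rep("L1", 2)), c(FALSE, FALSE))
  # a single SNP at a location is never removed
  expect_equal(prune_by_lod(c(0.1), "L1"), FALSE)
  # normalisation maps each location onto [0, 1]
  norm <- normalize_lod_scores(c(10, 5, 2, 8), c("A", "A", "B", "B"))
  expect_equal(norm, c(1, 0.5, 0.25, 1))
})

test_that("contig-conflict resolution follows the 10-SNP and 10% rules", {
  mk <- function(contig, lgs) data.frame(
    marker_id = paste0(contig, "_", seq_along(lgs)),
    contig_id = contig, lg = lgs, stringsAsFactors = FALSE)
  # 10 SNPs split 6/4: all removed
  r1 <- resolve_contig_conflicts(mk("c1", rep(1:2, c(6, 4))))
  expect_equal(nrow(r1$map), 0)
  expect_equal(unique(r1$log$reason), "split_contig_small")
  # 100 SNPs split 95/5: the 5 removed, the 95 kept
  r2 <- resolve_contig_conflicts(mk("c2", rep(1:2, c(95, 5))))
  expect_equal(nrow(r2$map), 95)
  expect_true(all(r2$map$lg == 1))
  # single-LG contig untouched
  r3 <- resolve_contig_conflicts(mk("c3", rep(1, 100)))
  expect_equal(nrow(r3$map), 100)
  expect_equal(nrow(r3$log), 0)
  # >10 SNPs, >=10% on each group: unresolvable, removed entirely
  r4 <- resolve_contig_conflicts(mk("c4", rep(1:2, c(30, 20))))
  expect_equal(nrow(r4$map), 0)
  expect_equal(unique(r4$log$reason), "split_contig_unresolvable")
})

test_that("sex-averaging is the arithmetic mean of parental positions", {
  map <- data.frame(lg = 1L, cm_male = c(0, 10, 0), cm_female = c(0, 20, 0))
  avg <- sex_average(map)
  expect_equal(avg$cm_avg, c(0, 15, 0))
  same <- sex_average(data.frame(lg = 1L, cm_male = c(0, 5),
                                 cm_female = c(0, 5)))
  expect_equal(same$cm_avg, same$cm_male)
})

test_that("phased genotypes convert to the quoted F2 codes", {
  expect_equal(to_f2_codes(c("1 2", "2 1", "1 1", "2 2")),
               c("AB", "AB", "AA", "BB"))
  expect_equal(to_f2_codes(c("1|2", "2|1")), c("AB", "AB"))
  expect_true(is.na(to_f2_codes(NA)))
  expect_true(is.na(to_f2_codes("0 1")))
})

test_that("phase imputation restores masked strands from flanking markers", {
  mk <- data.frame(lg = 1L, cm_pos = seq(0, 30, by = 2))
  tm <- make_transmissions(mk, 60, 30, seed = 12)
  truth <- tm$pat
  obs <- truth
  set.seed(99)
  obs[sample(length(obs), length(obs) %/% 10)] <- NA
  imp <- phase_impute(obs, diff(mk$cm_pos), error = 0.002)
  expect_gt(mean(imp == truth), 0.99)
})
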