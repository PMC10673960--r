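#' Grouping parameters for linkage-group formation
#'
#' @param lod_limit Two-point LOD needed to join markers into one group
#'   (default 9.5).
#' @param size_limit Minimum group size in markers; smaller groups are
#'   dissolved to singletons (default 600).
#' @param join_singles_lod LOD needed to attach a leftover singleton to the
#'   group of its best-linked marker (default 5).
#' @param distortion_aware Keep segregation-distorted markers by conditioning
#'   two-point likelihoods on the observed parental transmissions
#'   (default TRUE; the package's two-point LOD is conditional by
#'   construction, so this flag is informational).
#' @return List of class `grouping_params`.
#' @export
grouping_params <- function(lod_limit = 9.5, size_limit = 600,
                            join_singles_lod = 5, distortion_aware = TRUE) {
  stopifnot(join_singles_lod <= lod_limit)
  structure(list(lod_limit = lod_limit, size_limit = size_limit,
                 join_singles_lod = join_singles_lod,
                 distortion_aware = distortion_aware),
            class = "grouping_params")
}

#' Extract per-parent transmitted strands from phased calls
#'
#' For each offspring and marker, identifies which parental haplotype
#' (strand 1 or 2) supplied the transmitted allele, using the parent's own
#' phased call as the phase reference. A parent homozygous (or missing) at a
#' marker yields `NA` for that parent's strand, as does a missing or
#' phase-ambiguous offspring call.
#'
#' @param calls A [snail_calls()] object with phased `"a|b"` genotypes
#'   (paternal|maternal order).
#' @param father,mother Sample ids of the two parents.
#' @return List of class `snail_transmissions` with integer matrices `pat`
#'   and `mat` (markers x offspring, entries 1/2/NA) and `offspring` ids.
#' @export
transmissions <- function(calls, father = "C451", mother = "C452") {
  stopifnot(inherits(calls, "snail_calls"))
  off <- calls$samples$id[calls$samples$role == "offspring"]
  if (!length(off)) off <- setdiff(colnames(calls$gt), c(father, mother))
  strand_for <- function(parent, slot) {
    pg <- calls$gt[, parent]
    p1 <- as.integer(substr(pg, 1, 1))
    p2 <- as.integer(substr(pg, 3, 3))
    informative <- !is.na(pg) & p1 != p2
    og <- calls$gt[, off, drop = FALSE]
    tr <- matrix(NA_integer_, nrow(og), ncol(og), dimnames = dimnames(og))
    ok <- !is.na(og)
    tr[ok] <- as.integer(substr(og[ok], slot, slot))
    s <- ifelse(tr == p1[row(tr)], 1L, ifelse(tr == p2[row(tr)], 2L,
                NA_integer_))
    s[!informative, ] <- NA_integer_
    s
  }
  structure(list(pat = strand_for(father, 1L), mat = strand_for(mother, 3L),
                 offspring = off, phase_known = TRUE),
            class = "snail_transmissions")
}

rf_from_counts <- function(k, m, phase_known) {
  if (!phase_known) k <- pmin(k, m - k)
  r <- ifelse(m > 0, pmin(k / m, 0.5), 0.5)
  term <- function(cnt, p) ifelse(cnt > 0, cnt * log10(2 * p), 0)
  lod <- term(k, r) + term(m - k, 1 - r)
  lod[m == 0] <- 0
  list(r = r, lod = pmax(lod, 0), k = k, m = m)
}

#' Two-point recombination fraction and LOD for one marker pair
#'
#' Counts recombinant meioses between two markers, per parent, and returns
#' the maximum-likelihood recombination fraction together with the LOD score
#' against independence (r = 0.5). With `phase_known = FALSE` each parent's
#' phase orientation is chosen to maximise the likelihood (the fixed point
#' an EM over phase converges to for this binomial problem). Counts from the
#' two parents are pooled for the combined estimate; per-parent estimates
#' are also returned.
#'
#' @param s1,s2 Integer vectors of transmitted strands (1/2/NA) for the two
#'   markers from one parent, or `snail_transmissions` row pairs via `tm`.
#' @param s1_mat,s2_mat Optional second-parent strand vectors.
#' @param phase_known Are the strand labels phase-consistent across markers?
#' @return List of class `two_point`: `r_hat`, `lod`, `n_informative`,
#'   `r_pat`, `r_mat`. `lod` is clipped at 0 and is 0 when `r_hat = 0.5`;
#'   a pair with no shared informative meioses is flagged uninformative
#'   (`r_hat = 0.5`, `lod = 0`).
#' @export
#' @examples
#' s <- rep(c(1L, 2L), 5)
#' estimate_rf(s, s)$lod  # 10 * log10(2) ~ 3.01
estimate_rf <- function(s1, s2, s1_mat = NULL, s2_mat = NULL,
                        phase_known = TRUE) {
  count1 <- function(a, b) {
    ok <- !is.na(a) & !is.na(b)
    c(k = sum(a[ok] != b[ok]), m = sum(ok))
  }
  cc <- count1(s1, s2)
  if (!phase_known) cc["k"] <- min(cc["k"], cc["m"] - cc["k"])
  k <- cc["k"]; m <- cc["m"]
  r_pat <- if (m > 0) min(k / m, 0.5) else NA_real_
  r_mat <- NA_real_
  if (!is.null(s1_mat)) {
    cc2 <- count1(s1_mat, s2_mat)
    if (!phase_known) cc2["k"] <- min(cc2["k"], cc2["m"] - cc2["k"])
    r_mat <- if (cc2["m"] > 0) min(cc2["k"] / cc2["m"], 0.5) else NA_real_
    k <- k + cc2["k"]; m <- m + cc2["m"]
  }
  res <- rf_from_counts(k, m, phase_known = TRUE)  # orientation already applied
  structure(list(r_hat = unname(res$r), lod = unname(res$lod),
                 n_informative = unname(m), r_pat = r_pat, r_mat = r_mat,
                 uninformative = m == 0),
            class = "two_point")
}

#' All-pairs two-point estimates
#'
#' Vectorised recombination/LOD estimation for every marker pair, pooling
#' paternal and maternal informative meioses. Same model as [estimate_rf()].
#'
#' @param tm A [transmissions()] object (optionally row-subset).
#' @param phase_known Strand labels phase-consistent across markers?
#' @return List with symmetric matrices `r` (recombination fraction), `lod`,
#'   `n` (informative meioses), and per-parent `r_pat`, `r_mat`.
#' @export
pairwise_rf <- function(tm, phase_known = TRUE) {
  stopifnot(inherits(tm, "snail_transmissions"))
  layer <- function(S) {
    A1 <- (!is.na(S)) & S == 1L
    A2 <- (!is.na(S)) & S == 2L
    storage.mode(A1) <- "numeric"; storage.mode(A2) <- "numeric"
    k <- tcrossprod(A1, A2) + tcrossprod(A2, A1)
    m <- tcrossprod(A1 + A2)
    if (!phase_known) k <- pmin(k, m - k)
    list(k = k, m = m)
  }
  p <- layer(tm$pat); q <- layer(tm$mat)
  k <- p$k + q$k; m <- p$m + q$m
  res <- rf_from_counts(k, m, phase_known = TRUE)
  r_pat <- ifelse(p$m > 0, pmin(p$k / p$m, 0.5), NA_real_)
  r_mat <- ifelse(q$m > 0, pmin(q$k / q$m, 0.5), NA_real_)
  diag(res$lod) <- 0
  ids <- rownames(tm$pat)
  dimnames(res$r) <- dimnames(res$lod) <- list(ids, ids)
  list(r = res$r, lod = res$lod, n = m, r_pat = r_pat, r_mat = r_mat)
}

#' Assign markers to linkage groups
#'
#' Single-linkage transitive closure over marker pairs with two-point LOD at
#' or above `lod_limit`; groups smaller than `size_limit` are dissolved to
#' singletons; each remaining singleton is then joined to the group of its
#' best-linked grouped marker when that LOD reaches `join_singles_lod`.
#' Groups are renumbered by decreasing size.
#'
#' @param lod Symmetric matrix of two-point LOD scores.
#' @param params A [grouping_params()].
#' @return Integer vector of group assignments (0 = unassigned singleton).
#' @export
group_markers <- function(lod, params = grouping_params()) {
  M <- nrow(lod)
  parent <- seq_len(M)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  edges <- which(lod >= params$lod_limit & upper.tri(lod), arr.ind = TRUE)
  for (e in seq_len(nrow(edges))) {
    a <- find(edges[e, 1]); b <- find(edges[e, 2])
    if (a != b) parent[a] <- b
  }
  comp <- vapply(seq_len(M), find, 1L)
  comp <- match(comp, unique(comp))
  sizes <- tabulate(comp)
  lg <- ifelse(sizes[comp] >= params$size_limit, comp, 0L)
  singles <- which(lg == 0L)
  grouped <- which(lg > 0L)
  if (length(singles) && length(grouped)) {
    for (s in singles) {
      best <- grouped[which.max(lod[s, grouped])]
      if (lod[s, best] >= params$join_singles_lod) lg[s] <- lg[best]
    }
  }
  keep <- lg > 0L
  if (any(keep)) {
    tab <- sort(table(lg[keep]), decreasing = TRUE)
    lg[keep] <- match(as.character(lg[keep]), names(tab))
  }
  lg
}

path_cost <- function(ord, D) sum(D[cbind(ord[-length(ord)], ord[-1])])

# 2-opt on an open path with O(1) move evaluation: reversing ord[i..j]
# only changes the edges entering position i and leaving position j
two_opt <- function(ord, D) {
  n <- length(ord)
  if (n < 3) return(ord)
  improved <- TRUE
  while (improved) {
    improved <- FALSE
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        if (i == 1 && j == n) next
        delta <- 0
        if (i > 1)
          delta <- delta + D[ord[i - 1], ord[j]] - D[ord[i - 1], ord[i]]
        if (j < n)
          delta <- delta + D[ord[i], ord[j + 1]] - D[ord[j], ord[j + 1]]
        if (delta < -1e-12) {
          ord[i:j] <- rev(ord[i:j])
          improved <- TRUE
        }
      }
    }
  }
  ord
}

#' Order markers within a linkage group
#'
#' Seriation by greedy nearest-neighbour construction refined by 2-opt
#' reversals, restarted `n_restarts` times from different starting markers
#' (restart seed = `seed + restart index`), keeping the order with the
#' smallest sum of adjacent recombination fractions; cost ties break on the
#' lexicographically smaller marker-id sequence. Per-parent map positions
#' accumulate Haldane distances of adjacent per-parent recombination
#' fractions (an adjacency a parent is uninformative for contributes 0).
#' Orientation is canonical: first marker id below the last, lexicographically.
#'
#' @param tm A [transmissions()] object restricted to one group's markers.
#' @param params A [grouping_params()] (unused knobs tolerated).
#' @param n_restarts Number of seriation restarts (default 20).
#' @param seed Base seed for restart starting points.
#' @return Data frame `marker_id`, `order`, `cm_male`, `cm_female` in map
#'   order (positions start at 0).
#' @export
order_markers <- function(tm, params = grouping_params(), n_restarts = 20,
                          seed = 1L) {
  pw <- pairwise_rf(tm)
  ids <- rownames(tm$pat)
  n <- length(ids)
  if (n == 1)
    return(data.frame(marker_id = ids, order = 1L, cm_male = 0,
                      cm_female = 0, stringsAsFactors = FALSE))
  D <- pw$r
  if (all(pw$n[upper.tri(pw$n)] == 0)) {
    warning("all marker pairs uninformative; keeping input order")
    return(data.frame(marker_id = ids, order = seq_len(n), cm_male = 0,
                      cm_female = 0, stringsAsFactors = FALSE))
  }
  best <- NULL
  best_cost <- Inf
  for (rs in seq_len(n_restarts)) {
    start <- with_seed(stage_seed(seed + rs, "order"), sample.int(n, 1))
    ord <- start
    left <- setdiff(seq_len(n), start)
    while (length(left)) {
      nxt <- left[which.min(D[ord[length(ord)], left])]
      ord <- c(ord, nxt)
      left <- setdiff(left, nxt)
    }
    ord <- two_opt(ord, D)
    cost <- path_cost(ord, D)
    if (cost < best_cost - 1e-12 ||
        (abs(cost - best_cost) <= 1e-12 && !is.null(best) &&
         paste(ids[ord], collapse = ",") < paste(ids[best], collapse = ","))) {
      best <- ord
      best_cost <- cost
    }
  }
  if (ids[best[1]] > ids[best[n]]) best <- rev(best)
  adj_cm <- function(r_layer) {
    r_adj <- r_layer[cbind(best[-n], best[-1])]
    r_adj[is.na(r_adj)] <- 0
    cumsum(c(0, haldane_cm(pmin(r_adj, 0.49))))
  }
  data.frame(marker_id = ids[best], order = seq_len(n),
             cm_male = adj_cm(pw$r_pat), cm_female = adj_cm(pw$r_mat),
             stringsAsFactors = FALSE)
}

#' Normalise per-location LOD scores to \[0, 1\]
#'
#' Divides each SNP's maximum pairwise LOD by the largest such score among
#' SNPs sharing its map location.
#'
#' @param scores Numeric vector of per-SNP maximum LOD scores.
#' @param location Map-location id per SNP.
#' @return Normalised scores in `[0, 1]`.
#' @export
normalize_lod_scores <- function(scores, location) {
  stopifnot(length(scores) == length(location))
  mx <- ave(scores, location, FUN = function(z) {
    m <- max(z)
    if (m > 0) m else 1
  })
  scores / mx
}

#' Prune SNPs with weak normalised LOD support at their map location
#'
#' At each map location holding at least two SNPs, computes the mean and
#' sample standard deviation of the normalised scores and removes a SNP when
#' its score falls below mean minus one standard deviation. A location with
#' a single SNP is never pruned.
#'
#' @param norm_scores Normalised (0-1) per-SNP maximum LOD scores, as from
#'   [normalize_lod_scores()].
#' @param location Map-location id per SNP.
#' @return Logical vector: TRUE where the SNP is removed.
#' @export
prune_by_lod <- function(norm_scores, location) {
  stopifnot(length(norm_scores) == length(location))
  removed <- logical(length(norm_scores))
  for (loc in unique(location)) {
    idx <- which(location == loc)
    if (length(idx) < 2) next
    mu <- mean(norm_scores[idx])
    sdv <- sd(norm_scores[idx])
    removed[idx] <- norm_scores[idx] < mu - sdv
  }
  removed
}

#' Resolve contigs split across linkage groups
#'
#' A contig whose mapped SNPs land on two or more linkage groups is treated
#' as a conflict: with 10 or fewer mapped SNPs the whole contig is removed;
#' with more than 10, its SNPs are dropped from every group holding less
#' than 10\% of the contig's mapped SNPs. A split contig with more than 10
#' SNPs and at least 10\% on every group has no group to blame, and is
#' removed entirely (logged distinctly). Single-group contigs are untouched.
#'
#' @param map Data frame with at least `marker_id`, `contig_id`, `lg`.
#' @return List: `map` (pruned), `log` (data frame of removals with a
#'   `reason` per marker).
#' @export
resolve_contig_conflicts <- function(map) {
  drop <- logical(nrow(map))
  reason <- character(nrow(map))
  for (ctg in unique(map$contig_id)) {
    idx <- which(map$contig_id == ctg)
    lgs <- map$lg[idx]
    if (length(unique(lgs)) < 2) next
    if (length(idx) <= 10) {
      drop[idx] <- TRUE
      reason[idx] <- "split_contig_small"
    } else {
      share <- table(lgs) / length(idx)
      minority <- names(share)[share < 0.10]
      if (length(minority)) {
        sel <- idx[lgs %in% as.integer(minority)]
        drop[sel] <- TRUE
        reason[sel] <- "split_contig_minority_lg"
      } else {
        drop[idx] <- TRUE
        reason[idx] <- "split_contig_unresolvable"
      }
    }
  }
  list(map = map[!drop, , drop = FALSE],
       log = data.frame(marker_id = map$marker_id[drop],
                        contig_id = map$contig_id[drop],
                        lg = map$lg[drop], reason = reason[drop],
                        stringsAsFactors = FALSE))
}

#' Sex-average a genetic map
#'
#' Adds `cm_avg = (cm_male + cm_female)/2` and recomputes per-group lengths
#' from the averaged positions.
#'
#' @param map Data frame with `lg`, `cm_male`, `cm_female`.
#' @return The map with a `cm_avg` column and a `lg_lengths` attribute
#'   (named by group).
#' @export
sex_average <- function(map) {
  map$cm_avg <- (map$cm_male + map$cm_female) / 2
  len <- tapply(map$cm_avg, map$lg, function(z) max(z) - min(z))
  attr(map, "lg_lengths") <- len
  map
}

# pooled (both-parent) adjacent recombination fractions along an ordered
# vector of marker ids
pairwise_adjacent_r <- function(tm, ids) {
  if (length(ids) < 2) return(numeric(0))
  vapply(seq_len(length(ids) - 1), function(i) {
    est <- estimate_rf(tm$pat[ids[i], ], tm$pat[ids[i + 1], ],
                       tm$mat[ids[i], ], tm$mat[ids[i + 1], ])
    if (est$uninformative) 0 else est$r_hat
  }, 1)
}

# cumulative Haldane positions from a completed strand matrix
strand_cm <- function(strands) {
  m <- nrow(strands)
  if (m < 2) return(rep(0, m))
  r_adj <- vapply(seq_len(m - 1), function(i)
    mean(strands[i, ] != strands[i + 1, ]), 1)
  cumsum(c(0, haldane_cm(pmin(r_adj, 0.49))))
}

#' Impute per-parent transmitted strands along a map
#'
#' Completes each parent's transmitted-strand matrix over the mapped markers
#' with a two-state (haplotype 1/2) hidden Markov chain per offspring:
#' transition switch probabilities are the Haldane fractions of the adjacent
#' map gaps, observed strands are emitted with error `error`, and markers
#' where the parent is uninformative emit nothing. Each entry is replaced by
#' the posterior-mode strand. This plays the role of phasing against the
#' grandparents in a pedigree-likelihood mapper: it makes the genotype-code
#' matrix complete so every marker has a defined code for both parents.
#'
#' @param strands Integer matrix (markers x offspring, map order) of
#'   transmitted strands 1/2 with `NA` where uninformative.
#' @param gaps_cm Adjacent map gaps in cM (length `nrow(strands) - 1`).
#' @param error Strand observation error rate (default 0.002).
#' @return Completed integer matrix of strands (1/2 everywhere).
#' @export
phase_impute <- function(strands, gaps_cm, error = 0.002) {
  M <- nrow(strands)
  n <- ncol(strands)
  if (M == 1) {
    out <- strands
    out[is.na(out)] <- 1L
    return(out)
  }
  stopifnot(length(gaps_cm) == M - 1)
  r <- haldane_r(gaps_cm)
  e <- max(error, 1e-6)
  # emission: columns = P(obs | strand 1), P(obs | strand 2)
  emis <- function(t) {
    obs <- strands[t, ]
    E <- matrix(1, n, 2)
    o1 <- !is.na(obs) & obs == 1L
    o2 <- !is.na(obs) & obs == 2L
    E[o1, 1] <- 1 - e; E[o1, 2] <- e
    E[o2, 1] <- e; E[o2, 2] <- 1 - e
    E
  }
  fwd <- vector("list", M)
  f <- matrix(0.5, n, 2) * emis(1)
  f <- f / rowSums(f)
  fwd[[1]] <- f
  for (t in seq_len(M - 1)) {
    stay <- 1 - r[t]
    f <- cbind(f[, 1] * stay + f[, 2] * r[t],
               f[, 1] * r[t] + f[, 2] * stay) * emis(t + 1)
    f <- f / rowSums(f)
    fwd[[t + 1]] <- f
  }
  out <- matrix(1L, M, n, dimnames = dimnames(strands))
  b <- matrix(1, n, 2)
  post <- fwd[[M]]
  out[M, ] <- ifelse(post[, 2] > post[, 1], 2L, 1L)
  for (t in rev(seq_len(M - 1))) {
    be <- b * emis(t + 1)
    stay <- 1 - r[t]
    b <- cbind(be[, 1] * stay + be[, 2] * r[t],
               be[, 1] * r[t] + be[, 2] * stay)
    b <- b / rowSums(b)
    post <- fwd[[t]] * b
    out[t, ] <- ifelse(post[, 2] > post[, 1], 2L, 1L)
  }
  out
}

#' Convert phased genotypes to F2 codes
#'
#' Maps phased two-digit genotypes to intercross codes: `1 2` and `2 1`
#' become `AB`, `1 1` becomes `AA`, `2 2` becomes `BB`; anything else
#' (missing, unphased, malformed) becomes `NA`. Both `"1 2"` and `"1|2"`
#' separators are accepted.
#'
#' @param gt Character vector or matrix of phased genotypes.
#' @return Same shape, with entries in `AA`, `AB`, `BB`, `NA`.
#' @export
to_f2_codes <- function(gt) {
  g <- gsub("[| ]", "", as.character(gt))
  out <- rep(NA_character_, length(g))
  out[g %in% c("12", "21")] <- "AB"
  out[g == "11"] <- "AA"
  out[g == "22"] <- "BB"
  if (is.matrix(gt)) out <- matrix(out, nrow(gt), dimnames = dimnames(gt))
  out
}
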