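#' Configuration for a simulated full-sib cross
#'
#' Bundles the knobs of the synthetic cross generator. The defaults emulate
#' the laboratory cross the package is designed around: two outbred parents
#' (the informative parent heterozygous at every retained marker and at both
#' trait loci), two grandparents of the informative parent, and 75 offspring,
#' sequenced to roughly 10-fold haploid depth.
#'
#' @param n_offspring Number of offspring (default 75).
#' @param genotyping_error Probability that a called genotype is replaced by a
#'   uniformly chosen wrong genotype (default 0.002, matching the error rate
#'   the downstream HMM assumes).
#' @param missing_rate Probability that a call is masked, completely at random
#'   (default 0.05, under the 10\% missingness retention cap).
#' @param mean_depth Expected reads per call (default 10).
#' @param depth_dispersion Negative-binomial overdispersion of depth; 0 gives
#'   Poisson depth (default 0.2).
#' @param seed Integer seed; the same seed reproduces the dataset bit for bit.
#' @param lg_lengths_cm Numeric vector of linkage-group lengths in cM
#'   (default: the 22 published group lengths, see [cnemoralis_lg_summary()]).
#' @param markers_per_lg Integer vector, markers per group (default 20 per
#'   group: a desk-scale stand-in for the published marker density).
#' @param both_parent_het_fraction Fraction of markers heterozygous in the
#'   non-informative parent as well (default 0.3).
#' @return A list of class `cross_config`.
#' @export
cross_config <- function(n_offspring = 75,
                         genotyping_error = 0.002,
                         missing_rate = 0.05,
                         mean_depth = 10,
                         depth_dispersion = 0.2,
                         seed = 1L,
                         lg_lengths_cm = cnemoralis_lg_summary()$length_cm,
                         markers_per_lg = rep(20L, length(lg_lengths_cm)),
                         both_parent_het_fraction = 0.3) {
  stopifnot(n_offspring >= 1,
            genotyping_error >= 0, genotyping_error <= 1,
            missing_rate >= 0, missing_rate <= 1,
            both_parent_het_fraction >= 0, both_parent_het_fraction <= 1,
            mean_depth >= 0, depth_dispersion >= 0,
            length(lg_lengths_cm) == length(markers_per_lg))
  if (any(lg_lengths_cm < 0))
    stop("linkage-group lengths must be non-negative")
  structure(list(n_offspring = as.integer(n_offspring),
                 genotyping_error = genotyping_error,
                 missing_rate = missing_rate,
                 mean_depth = mean_depth,
                 depth_dispersion = depth_dispersion,
                 seed = as.integer(seed),
                 lg_lengths_cm = as.numeric(lg_lengths_cm),
                 markers_per_lg = as.integer(markers_per_lg),
                 both_parent_het_fraction = both_parent_het_fraction),
            class = "cross_config")
}

#' Trait loci of the default cross
#'
#' The two Mendelian shell loci the cross segregates for: the shell ground
#' colour locus `C` (pink dominant over yellow; the scored phenotype "yellow"
#' is the recessive class) and the mid-banded locus `U` (mid-band dominant;
#' the scored phenotype is the dominant class). Both are heterozygous in the
#' informative parent and homozygous recessive in the other, so each
#' segregates 1:1 among offspring. Allele 1 is the dominant allele.
#'
#' @param lg_c,lg_u Linkage groups carrying C and U (defaults 11 and 15).
#' @param cm_c,cm_u Positions in cM (defaults 32 and 40, inside the published
#'   candidate regions).
#' @return A data frame of class `trait_loci` with one row per locus.
#' @export
default_trait_loci <- function(lg_c = 11L, cm_c = 32, lg_u = 15L, cm_u = 40) {
  structure(data.frame(
    name = c("yellow", "midband"),
    lg = c(lg_c, lg_u),
    cm_pos = c(cm_c, cm_u),
    dominant_allele = c(1L, 1L),
    # value 1 is scored for: the recessive class for yellow (C^Y C^Y),
    # the dominant class for mid-banding (U^3 present)
    scored_class = c("recessive", "dominant"),
    informative_parent = c("C451", "C451"),
    stringsAsFactors = FALSE), class = c("trait_loci", "data.frame"))
}

#' Haldane map function
#'
#' Converts a genetic distance in centimorgans to a recombination fraction
#' under the Haldane (no-interference) model,
#' \eqn{r = (1 - e^{-2d/100})/2}{r = (1 - exp(-2d/100))/2}.
#'
#' @param d_cm Distance(s) in cM, non-negative.
#' @return Recombination fraction(s) in `[0, 0.5)`.
#' @export
#' @examples
#' haldane_r(10)  # 0.09063
haldane_r <- function(d_cm) {
  if (any(d_cm < 0)) stop("distances must be non-negative")
  (1 - exp(-2 * d_cm / 100)) / 2
}

#' Inverse Haldane map function
#'
#' @param r Recombination fraction(s) in `[0, 0.5)`.
#' @return Distance(s) in cM.
#' @export
haldane_cm <- function(r) {
  if (any(r < 0) || any(r >= 0.5)) stop("r must be in [0, 0.5)")
  -50 * log(1 - 2 * r)
}

#' Simulate a marker scaffold
#'
#' Draws marker positions uniformly on each linkage group (then sorts them)
#' and assigns markers to contigs spanning contiguous runs, mimicking a
#' fragmented assembly anchored to a map.
#'
#' @param config A [cross_config()].
#' @return Data frame with columns `marker_id`, `contig_id`, `bp_pos`
#'   (0-based), `lg`, `cm_pos`, `ref`, `alt`; cm positions are non-decreasing
#'   within each group.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "cross_config"))
  with_seed(stage_seed(config$seed, "genome"), {
    G <- length(config$lg_lengths_cm)
    out <- vector("list", G)
    bases <- c("A", "C", "G", "T")
    for (g in seq_len(G)) {
      m <- config$markers_per_lg[g]
      len <- config$lg_lengths_cm[g]
      cm <- sort(runif(m, 0, len))
      if (len == 0) cm <- rep(0, m)
      # contigs span contiguous runs of markers (geometric run lengths)
      runs <- integer(0)
      while (sum(runs) < m) runs <- c(runs, 1L + rpois(1, 3))
      contig_of <- rep(seq_along(runs), runs)[seq_len(m)]
      bp <- unlist(lapply(split(seq_len(m), contig_of), function(idx) {
        cumsum(c(0L, as.integer(runif(length(idx) - 1, 1e3, 1e5))))
      }), use.names = FALSE)
      ref <- sample(bases, m, replace = TRUE)
      alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), "")
      out[[g]] <- data.frame(
        marker_id = sprintf("M%02d_%04d", g, seq_len(m)),
        contig_id = sprintf("ctg%02d_%03d", g, contig_of),
        bp_pos = bp, lg = g, cm_pos = cm, ref = ref, alt = alt,
        stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
}

# strand (grandparental origin, 1 or 2) of one gamete at query positions;
# crossovers: Poisson(len/100) per group, breakpoints uniform, no interference
meiosis_strands <- function(loci, lg_lengths_cm) {
  strands <- integer(nrow(loci))
  for (g in unique(loci$lg)) {
    idx <- which(loci$lg == g)
    len <- lg_lengths_cm[g]
    n_co <- if (len > 0) rpois(1, len / 100) else 0L
    breaks <- sort(runif(n_co, 0, len))
    start <- sample(1:2, 1)
    n_below <- findInterval(loci$cm_pos[idx], breaks)
    strands[idx] <- 1L + (start - 1L + n_below) %% 2L
  }
  strands
}

#' Simulate one meiosis
#'
#' Draws a gamete from a phased parent: crossover counts are Poisson in the
#' group's map length (Haldane model, no interference), breakpoints uniform,
#' and each locus takes the allele of the active parental strand.
#'
#' @param haplotypes 2 x L matrix of parental allele indices (rows = the two
#'   phased haplotypes).
#' @param loci Data frame with columns `lg` and `cm_pos` (one row per locus,
#'   same order as the haplotype columns).
#' @param lg_lengths_cm Group lengths in cM, indexed by `lg`.
#' @param seed Optional seed.
#' @return List with `allele` (transmitted allele per locus) and `strand`
#'   (which parental haplotype it came from).
#' @export
simulate_meiosis <- function(haplotypes, loci, lg_lengths_cm, seed = NULL) {
  stopifnot(is.matrix(haplotypes), nrow(haplotypes) == 2,
            ncol(haplotypes) == nrow(loci))
  with_seed(seed, {
    s <- meiosis_strands(loci, lg_lengths_cm)
    list(allele = haplotypes[cbind(s, seq_along(s))], strand = s)
  })
}

#' Simulate a full-sib cross with genotype calls and binary phenotypes
#'
#' Generates the complete study design: phased parents (the informative
#' parent heterozygous at every marker and trait locus), two grandparents of
#' the informative parent, `n_offspring` offspring derived by two independent
#' meioses each, fully penetrant binary phenotypes under dominance, and
#' genotype calls corrupted by genotyping error, missingness and
#' negative-binomial depth.
#'
#' @param config A [cross_config()].
#' @param trait_loci A data frame as from [default_trait_loci()].
#' @param markers Optional pre-built marker scaffold (as returned by
#'   [simulate_genome()]); the default draws one from `config`.
#' @return An object of class `snail_cross`: a list with `markers`, `samples`
#'   (pedigree), `calls` (a `snail_calls` object), `phenotypes`, and `truth`
#'   (parental phase, per-offspring transmitted strands, trait genotypes).
#' @export
simulate_cross <- function(config = cross_config(),
                           trait_loci = default_trait_loci(),
                           markers = NULL) {
  stopifnot(inherits(config, "cross_config"))
  G <- length(config$lg_lengths_cm)
  if (any(trait_loci$lg < 1 | trait_loci$lg > G))
    stop("trait locus placed on a nonexistent linkage group")
  if (is.null(markers)) markers <- simulate_genome(config)
  M <- nrow(markers)
  n_off <- config$n_offspring

  with_seed(stage_seed(config$seed, "cross"), {
    # parental phase over markers: father (C451) het everywhere; mother
    # (C452) het at a fraction of markers, otherwise homozygous
    fa <- rbind(sample(1:2, M, TRUE), 0L); fa[2, ] <- 3L - fa[1, ]
    mo_het <- runif(M) < config$both_parent_het_fraction
    mo1 <- ifelse(mo_het, sample(1:2, M, TRUE), sample(1:2, M, TRUE))
    mo <- rbind(mo1, ifelse(mo_het, 3L - mo1, mo1))
    # trait loci: father het (dominant on a random strand), mother hom recessive
    L <- nrow(trait_loci)
    rec_allele <- ifelse(trait_loci$dominant_allele == 1L, 2L, 1L)
    fa_t <- rbind(sample(1:2, L, TRUE), 0L); fa_t[2, ] <- 3L - fa_t[1, ]
    # make hap1 carry the allele drawn for it; alleles are locus-specific
    # symbols: use 1 = dominant, 2 = recessive
    mo_t <- rbind(rec_allele, rec_allele)

    loci_all <- rbind(markers[, c("lg", "cm_pos")],
                      trait_loci[, c("lg", "cm_pos")])
    fa_hap <- cbind(fa, fa_t)
    mo_hap <- cbind(mo, mo_t)

    pat_allele <- matrix(0L, M + L, n_off)
    mat_allele <- matrix(0L, M + L, n_off)
    pat_strand <- matrix(0L, M + L, n_off)
    mat_strand <- matrix(0L, M + L, n_off)
    for (i in seq_len(n_off)) {
      gp <- simulate_meiosis(fa_hap, loci_all, config$lg_lengths_cm)
      gm <- simulate_meiosis(mo_hap, loci_all, config$lg_lengths_cm)
      pat_allele[, i] <- gp$allele; pat_strand[, i] <- gp$strand
      mat_allele[, i] <- gm$allele; mat_strand[, i] <- gm$strand
    }

    # phenotypes: deterministic from trait-locus genotypes under dominance
    phen <- do.call(rbind, lapply(seq_len(L), function(l) {
      k <- M + l
      has_dom <- pat_allele[k, ] == trait_loci$dominant_allele[l] |
                 mat_allele[k, ] == trait_loci$dominant_allele[l]
      val <- if (trait_loci$scored_class[l] == "dominant")
        as.integer(has_dom) else as.integer(!has_dom)
      data.frame(id = sprintf("O%03d", seq_len(n_off)),
                 trait = trait_loci$name[l], value = val,
                 stringsAsFactors = FALSE)
    }))

    # grandparents of the father: each contributed one of his haplotypes
    gp1 <- rbind(fa[1, ], sample(1:2, M, TRUE))
    gp2 <- rbind(fa[2, ], sample(1:2, M, TRUE))

    ids <- c("G1", "G2", "C451", "C452", sprintf("O%03d", seq_len(n_off)))
    samples <- data.frame(
      id = ids,
      sire = c(NA, NA, "G1", NA, rep("C451", n_off)),
      dam = c(NA, NA, "G2", NA, rep("C452", n_off)),
      generation = c(0L, 0L, 1L, 1L, rep(2L, n_off)),
      role = c("grandparent", "grandparent", "parent", "parent",
               rep("offspring", n_off)),
      stringsAsFactors = FALSE)

    gt_true <- cbind(paste0(gp1[1, ], "|", gp1[2, ]),
                     paste0(gp2[1, ], "|", gp2[2, ]),
                     paste0(fa[1, ], "|", fa[2, ]),
                     paste0(mo[1, ], "|", mo[2, ]),
                     matrix(paste0(pat_allele[seq_len(M), ], "|",
                                   mat_allele[seq_len(M), ]), M, n_off))
    colnames(gt_true) <- ids
    rownames(gt_true) <- markers$marker_id

    gt <- gt_true
    N <- length(ids)
    # symmetric error: replace with a uniformly chosen different phased call
    err <- matrix(runif(M * N) < config$genotyping_error, M, N)
    if (any(err)) {
      cfgs <- c("1|1", "1|2", "2|1", "2|2")
      idx <- which(err)
      gt[idx] <- vapply(gt[idx],
                        function(g) sample(setdiff(cfgs, g), 1), "")
    }
    miss <- matrix(runif(M * N) < config$missing_rate, M, N)
    gt[miss] <- NA_character_

    dp <- if (config$depth_dispersion > 0)
      matrix(rnbinom(M * N, size = 1 / config$depth_dispersion,
                     mu = config$mean_depth), M, N)
    else matrix(rpois(M * N, config$mean_depth), M, N)
    storage.mode(dp) <- "integer"
    dimnames(dp) <- dimnames(gt)

    calls <- snail_calls(gt = gt, dp = dp,
                         qual = rep(999, M), markers = markers,
                         samples = samples)

    structure(list(
      markers = markers, samples = samples, calls = calls,
      phenotypes = phen,
      truth = list(
        father_hap = fa_hap, mother_hap = mo_hap,
        pat_strand = matrix(pat_strand[seq_len(M), ], M,
                            dimnames = list(markers$marker_id,
                                            sprintf("O%03d", seq_len(n_off)))),
        mat_strand = matrix(mat_strand[seq_len(M), ], M,
                            dimnames = list(markers$marker_id,
                                            sprintf("O%03d", seq_len(n_off)))),
        trait_loci = trait_loci,
        trait_pat_allele = pat_allele[M + seq_len(L), , drop = FALSE],
        trait_mat_allele = mat_allele[M + seq_len(L), , drop = FALSE],
        gt_true = gt_true)),
      class = "snail_cross")
  })
}

#' Container for genotype calls
#'
#' @param gt Character matrix (markers x individuals) of phased calls
#'   `"a|b"` with allele indices 1/2 ordered paternal|maternal; `NA` =
#'   missing.
#' @param dp Integer matrix of per-call read depths.
#' @param qual Numeric per-site quality scores.
#' @param markers Marker data frame (`marker_id`, `contig_id`, `bp_pos`,
#'   `lg`, `cm_pos`, `ref`, `alt`).
#' @param samples Sample/pedigree data frame.
#' @return Object of class `snail_calls`.
#' @export
snail_calls <- function(gt, dp, qual, markers, samples) {
  stopifnot(nrow(gt) == nrow(markers), nrow(gt) == length(qual),
            all(dim(gt) == dim(dp)))
  structure(list(gt = gt, dp = dp, qual = qual,
                 markers = markers, samples = samples),
            class = "snail_calls")
}

#' @export
print.snail_calls <- function(x, ...) {
  cat(sprintf("snail_calls: %d markers x %d individuals (%.1f%% missing)\n",
              nrow(x$gt), ncol(x$gt), 100 * mean(is.na(x$gt))))
  invisible(x)
}

#' @export
print.snail_cross <- function(x, ...) {
  cat(sprintf(
    "snail_cross: %d individuals (%d offspring), %d markers on %d groups, %d trait loci\n",
    nrow(x$samples), sum(x$samples$role == "offspring"),
    nrow(x$markers), length(unique(x$markers$lg)),
    nrow(x$truth$trait_loci)))
  invisible(x)
}
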