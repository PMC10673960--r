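#' Parameters of the binary-trait genome scan
#'
#' @param genotyping_error HMM emission error rate (default 0.002).
#' @param n_perm Number of phenotype permutations for the genome-wide
#'   threshold (default 1000).
#' @param alpha Genome-wide type-I error rate (default 0.05).
#' @param peakdrop LOD drop required between independent peaks
#'   (default 1.8).
#' @param ci_prob Bayes credible interval probability (default 0.95).
#' @param seed Seed for the permutations.
#' @return List of class `scan_params`.
#' @export
scan_params <- function(genotyping_error = 0.002, n_perm = 1000,
                        alpha = 0.05, peakdrop = 1.8, ci_prob = 0.95,
                        seed = 1L) {
  stopifnot(genotyping_error >= 0, genotyping_error < 0.5,
            alpha > 0, alpha <= 1, peakdrop > 0,
            ci_prob > 0, ci_prob <= 1)
  structure(list(genotyping_error = genotyping_error,
                 n_perm = as.integer(n_perm), alpha = alpha,
                 peakdrop = peakdrop, ci_prob = ci_prob,
                 seed = as.integer(seed)),
            class = "scan_params")
}

# one genotype slice as an individuals x positions matrix (guarding against
# dimension dropping when a single position is scanned)
prob_slice <- function(probs, state, sel = NULL) {
  if (is.null(sel)) sel <- seq_len(dim(probs)[2])
  matrix(probs[, sel, state], dim(probs)[1], length(sel))
}

geno_transition <- function(r) {
  matrix(c((1 - r)^2, 2 * r * (1 - r), r^2,
           r * (1 - r), (1 - r)^2 + r^2, r * (1 - r),
           r^2, 2 * r * (1 - r), (1 - r)^2),
         3, 3, byrow = TRUE)
}

#' Genotype probabilities along the map by hidden Markov model
#'
#' Forward-backward over the three intercross genotype states AA/AB/BB per
#' offspring and linkage group. Transition probabilities come from the
#' Haldane recombination fraction of each adjacent cM gap with intercross
#' transition structure; the emission model observes the true genotype with
#' probability `1 - e` and each wrong genotype with probability `e/2`;
#' missing observations emit 1 for all states.
#'
#' @param map Data frame with `marker_id`, `lg` and a position column
#'   (`cm_avg` or `cm_pos`), ordered within each group.
#' @param codes Character matrix (markers x individuals) over
#'   `AA`/`AB`/`BB`/`NA`, rows aligned with `map`.
#' @param params A [scan_params()] (only `genotyping_error` is used).
#' @return Array `[individuals, markers, 3]` of posterior genotype
#'   probabilities (rows sum to 1 at every position), with the map attached
#'   as attribute `map`.
#' @export
calc_genoprob <- function(map, codes, params = scan_params()) {
  pos_col <- if ("cm_avg" %in% names(map)) "cm_avg" else "cm_pos"
  stopifnot(nrow(map) == nrow(codes))
  eps <- params$genotyping_error
  emit <- matrix(eps / 2, 3, 3)
  diag(emit) <- 1 - eps
  n_ind <- ncol(codes)
  M <- nrow(map)
  probs <- array(NA_real_, c(n_ind, M, 3),
                 dimnames = list(colnames(codes), map$marker_id,
                                 c("AA", "AB", "BB")))
  code_idx <- matrix(match(codes, c("AA", "AB", "BB")), M, n_ind)
  init <- c(0.25, 0.5, 0.25)
  for (g in unique(map$lg)) {
    idx <- which(map$lg == g)
    pos <- map[[pos_col]][idx]
    if (is.unsorted(pos)) stop("map positions must be ordered within group")
    m <- length(idx)
    gaps <- diff(pos)
    Ts <- lapply(haldane_r(gaps), geno_transition)
    e_at <- function(t) {
      obs <- code_idx[idx[t], ]
      E <- matrix(1, n_ind, 3)
      ok <- !is.na(obs)
      E[ok, ] <- emit[obs[ok], , drop = FALSE]
      E
    }
    fwd <- vector("list", m)
    f <- matrix(init, n_ind, 3, byrow = TRUE) * e_at(1)
    f <- f / rowSums(f)
    fwd[[1]] <- f
    for (t in seq_len(m - 1)) {
      f <- (f %*% Ts[[t]]) * e_at(t + 1)
      f <- f / rowSums(f)
      fwd[[t + 1]] <- f
    }
    b <- matrix(1, n_ind, 3)
    post <- fwd[[m]]
    probs[, idx[m], ] <- post / rowSums(post)
    for (t in rev(seq_len(m - 1))) {
      b <- (b * e_at(t + 1)) %*% t(Ts[[t]])
      b <- b / rowSums(b)
      post <- fwd[[t]] * b
      probs[, idx[t], ] <- post / rowSums(post)
    }
  }
  attr(probs, "map") <- map[, c("marker_id", "lg", pos_col)]
  names(attr(probs, "map"))[3] <- "cm"
  probs
}

#' Logistic-regression genome scan for a binary trait
#'
#' At each map position fits a Bernoulli model whose success probability is
#' logistic in the genotype-probability covariates P(AB) and P(BB) (AA as
#' baseline) by iteratively reweighted least squares, and reports
#' `LOD = (LL_full - LL_null) / ln 10`, clipped at 0. Under complete
#' separation the fit is bounded by clamping fitted probabilities to
#' `[1e-12, 1 - 1e-12]` with an iteration cap of 100.
#'
#' @param probs Genotype probabilities from [calc_genoprob()].
#' @param phenotype Binary vector (0/1) aligned with the individuals of
#'   `probs`.
#' @return Data frame of class `snail_scan`: `marker_id`, `lg`, `cm`, `lod`.
#' @export
binary_scan <- function(probs, phenotype) {
  map <- attr(probs, "map")
  y <- as.numeric(phenotype)
  stopifnot(length(y) == dim(probs)[1])
  if (length(unique(y[!is.na(y)])) < 2) {
    warning("phenotype has a single class; all LOD scores are 0")
    lod <- rep(0, dim(probs)[2])
  } else {
    lod <- scan_binary_cpp(prob_slice(probs, "AB"), prob_slice(probs, "BB"),
                           y)
  }
  out <- data.frame(marker_id = map$marker_id, lg = map$lg, cm = map$cm,
                    lod = lod, stringsAsFactors = FALSE)
  class(out) <- c("snail_scan", "data.frame")
  out
}

#' Permutation threshold for the genome-wide LOD
#'
#' Permutes phenotype labels uniformly `n_perm` times (seeded) and takes the
#' empirical `1 - alpha` quantile of the genome-wide maximum LOD.
#'
#' @param probs Genotype probabilities from [calc_genoprob()].
#' @param phenotype Binary vector.
#' @param params A [scan_params()] (`n_perm`, `alpha`, `seed`).
#' @return Threshold (scalar) with the permuted maxima as attribute
#'   `perm_max`.
#' @export
permutation_threshold <- function(probs, phenotype, params = scan_params()) {
  stopifnot(params$n_perm >= 1)
  y <- as.numeric(phenotype)
  n <- length(y)
  Yp <- with_seed(params$seed,
                  vapply(seq_len(params$n_perm), function(i) y[sample.int(n)],
                         numeric(n)))
  mx <- perm_max_lod_cpp(prob_slice(probs, "AB"), prob_slice(probs, "BB"),
                         Yp)
  thr <- unname(quantile(mx, 1 - params$alpha, type = 7))
  attr(thr, "perm_max") <- mx
  thr
}

#' Find independent LOD peaks
#'
#' Local maxima above the threshold within each linkage group; two adjacent
#' maxima are independent only when the LOD drops, between them, to at or
#' below the lower of the two maxima minus `peakdrop` — otherwise they are
#' merged into the higher one.
#'
#' @param scan A [binary_scan()] result.
#' @param threshold Genome-wide significance threshold.
#' @param peakdrop Required LOD drop (default 1.8).
#' @return Data frame `lg`, `cm`, `lod`, `idx_lo`, `idx_hi` (row range of
#'   the peak's segment within its group, for interval computation).
#' @export
find_peaks <- function(scan, threshold, peakdrop = 1.8) {
  out <- list()
  for (g in unique(scan$lg)) {
    d <- scan[scan$lg == g, ]
    lod <- d$lod
    m <- length(lod)
    # local maxima (plateau start counts once) above threshold
    is_max <- vapply(seq_len(m), function(i) {
      left <- if (i > 1) lod[i - 1] else -Inf
      right <- if (i < m) lod[i + 1] else -Inf
      lod[i] >= threshold & lod[i] > left & lod[i] >= right
    }, TRUE)
    peaks <- which(is_max)
    if (!length(peaks)) next
    repeat {
      if (length(peaks) < 2) break
      merged <- FALSE
      for (k in seq_len(length(peaks) - 1)) {
        i <- peaks[k]; j <- peaks[k + 1]
        valley <- min(lod[i:j])
        if (valley > min(lod[i], lod[j]) - peakdrop) {
          peaks <- peaks[-(if (lod[i] >= lod[j]) k + 1 else k)]
          merged <- TRUE
          break
        }
      }
      if (!merged) break
    }
    # segment boundaries: split at the argmin between adjacent peaks
    bounds <- c(0, vapply(seq_len(length(peaks) - 1), function(k) {
      i <- peaks[k]; j <- peaks[k + 1]
      i - 1 + which.min(lod[i:j])
    }, 1), m)
    for (k in seq_along(peaks)) {
      lo <- bounds[k] + 1
      hi <- bounds[k + 1]
      out[[length(out) + 1]] <- data.frame(
        lg = g, cm = d$cm[peaks[k]], lod = lod[peaks[k]],
        idx_lo = lo, idx_hi = hi)
    }
  }
  if (!length(out))
    return(data.frame(lg = integer(), cm = numeric(), lod = numeric(),
                      idx_lo = integer(), idx_hi = integer()))
  do.call(rbind, out)
}

#' Bayes credible interval for a peak
#'
#' Treats `10^LOD` over the group's map positions as an unnormalised
#' posterior for locus position and returns the smallest contiguous span of
#' positions containing the peak whose mass reaches `ci_prob`. Endpoints are
#' reported at marker positions.
#'
#' @param scan A [binary_scan()] result (or any data frame with `lg`, `cm`,
#'   `lod`).
#' @param lg Linkage group to work on.
#' @param ci_prob Credible mass (default 0.95).
#' @param idx_range Optional `c(lo, hi)` row range within the group (as from
#'   [find_peaks()]) restricting the profile to one peak's segment.
#' @return List: `start_cm`, `end_cm`, `peak_cm`, `prob` (attained mass).
#' @export
bayes_interval <- function(scan, lg, ci_prob = 0.95, idx_range = NULL) {
  d <- scan[scan$lg == lg, ]
  if (!nrow(d)) stop("no positions on that linkage group")
  if (!is.null(idx_range)) d <- d[idx_range[1]:idx_range[2], ]
  w <- 10^(d$lod - max(d$lod))
  w <- w / sum(w)
  peak <- which.max(d$lod)
  m <- nrow(d)
  best <- NULL
  for (a in seq_len(peak)) {
    for (b in seq(peak, m)) {
      mass <- sum(w[a:b])
      if (mass >= ci_prob) {
        cand <- list(a = a, b = b, mass = mass,
                     npos = b - a + 1, width = d$cm[b] - d$cm[a])
        if (is.null(best) ||
            cand$npos < best$npos ||
            (cand$npos == best$npos && cand$width < best$width)) {
          best <- cand
        }
        break  # longer b only widens for this a
      }
    }
  }
  if (is.null(best)) best <- list(a = 1, b = m, mass = sum(w))
  list(start_cm = d$cm[best$a], end_cm = d$cm[best$b],
       peak_cm = d$cm[peak], prob = best$mass)
}

#' Allele effects along a linkage group
#'
#' Per position, the fitted log-odds of the trait for each genotype class,
#' from a no-intercept logistic fit on the three genotype-probability
#' covariates. Effects are capped at plus or minus 20 log-odds under
#' separation.
#'
#' @param probs Genotype probabilities from [calc_genoprob()].
#' @param phenotype Binary vector.
#' @param lg Linkage group to scan.
#' @return Data frame `marker_id`, `lg`, `cm`, `eff_AA`, `eff_AB`, `eff_BB`.
#' @export
allele_effects <- function(probs, phenotype, lg) {
  map <- attr(probs, "map")
  sel <- which(map$lg == lg)
  if (!length(sel)) stop("no positions on that linkage group")
  y <- as.numeric(phenotype)
  if (length(unique(y[!is.na(y)])) < 2)
    warning("phenotype has a single class; effects are not identifiable")
  eff <- effects_cpp(prob_slice(probs, "AA", sel),
                     prob_slice(probs, "AB", sel),
                     prob_slice(probs, "BB", sel), y)
  eff <- pmin(pmax(eff, -20), 20)
  data.frame(marker_id = map$marker_id[sel], lg = lg, cm = map$cm[sel],
             eff_AA = eff[, 1], eff_AB = eff[, 2], eff_BB = eff[, 3],
             stringsAsFactors = FALSE)
}

#' Check raw genotypes against the dominance segregation pattern
#'
#' Under a dominance model one homozygote class implies one phenotype: every
#' `BB` individual must show the B-implied phenotype and every `AA` the
#' other; heterozygotes are exempt (they split between phenotypes when the
#' trait segregates from a heterozygous parent). Counts
#' phenotype-incompatible homozygotes per position.
#'
#' @param codes Character matrix (positions x individuals) of F2 codes.
#' @param phenotype Binary vector aligned with the columns of `codes`.
#' @param positions Positions (cM) labelling the rows.
#' @param bb_value Phenotype value (0/1) implied by the `BB` homozygote;
#'   `AA` implies `1 - bb_value`.
#' @return Data frame of class `segregation_check`: `position`,
#'   `n_violations`, `n_homozygotes`, `uninformative`, `consistent`
#'   (`TRUE` iff zero violations and the position is informative).
#' @export
segregation_check <- function(codes, phenotype, positions, bb_value = 1) {
  codes <- rbind(codes)
  stopifnot(ncol(codes) == length(phenotype),
            nrow(codes) == length(positions))
  y <- as.numeric(phenotype)
  out <- lapply(seq_len(nrow(codes)), function(i) {
    g <- codes[i, ]
    ok <- !is.na(g) & !is.na(y)
    bb <- ok & g == "BB"
    aa <- ok & g == "AA"
    viol <- sum(y[bb] != bb_value) + sum(y[aa] != (1 - bb_value))
    uninf <- !any(ok)
    data.frame(position = positions[i], n_violations = viol,
               n_homozygotes = sum(bb) + sum(aa),
               uninformative = uninf,
               consistent = !uninf && viol == 0)
  })
  out <- do.call(rbind, out)
  class(out) <- c("segregation_check", "data.frame")
  out
}

#' Delimit the candidate region for a Mendelian locus
#'
#' The span of segregation-consistent positions that also lie inside the
#' supported credible interval (the one whose LOD peak carries a matching
#' allele-effect peak). Width is reported to one decimal place.
#'
#' @param seg A [segregation_check()] result.
#' @param interval A [bayes_interval()] result (or list with `start_cm`,
#'   `end_cm`), or NULL to use all consistent positions.
#' @param map_lg Optional map rows (with `cm` or `cm_avg` and `contig_id`)
#'   used to list the contigs at the consistent positions.
#' @return List of class `candidate_region`: `localised`, `positions`,
#'   `span_cm` (`c(start, end)`), `width_cm` (1 dp), `contigs`.
#' @export
candidate_region <- function(seg, interval = NULL, map_lg = NULL) {
  pos <- sort(unique(seg$position[seg$consistent]))
  if (!is.null(interval))
    pos <- pos[pos >= interval$start_cm & pos <= interval$end_cm]
  if (!length(pos)) {
    return(structure(list(localised = FALSE, positions = numeric(),
                          span_cm = c(NA_real_, NA_real_),
                          width_cm = NA_real_, contigs = character()),
                     class = "candidate_region"))
  }
  span <- range(pos)
  contigs <- character()
  if (!is.null(map_lg)) {
    cmcol <- if ("cm" %in% names(map_lg)) "cm" else "cm_avg"
    contigs <- sort(unique(
      map_lg$contig_id[map_lg[[cmcol]] %in% pos]))
  }
  structure(list(localised = TRUE, positions = pos, span_cm = span,
                 width_cm = round(span[2] - span[1], 1), contigs = contigs),
            class = "candidate_region")
}

#' @export
print.candidate_region <- function(x, ...) {
  if (!x$localised) {
    cat("candidate_region: locus not localised\n")
  } else {
    cat(sprintf(
      "candidate_region: ~%.1f cM spanning %.3f-%.3f cM (%d positions, %d contigs)\n",
      x$width_cm, x$span_cm[1], x$span_cm[2], length(x$positions),
      length(x$contigs)))
  }
  invisible(x)
}
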