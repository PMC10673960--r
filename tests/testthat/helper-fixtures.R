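# fixtures built in code: small call sets, marker scaffolds, and the
# independent oracles used by the property tests

# a snail_calls object from explicit genotype strings ("1|2" etc., NA for
# missing); one father, one mother, rest offspring
make_calls <- function(gt, qual = NULL, dp = NULL, ref = NULL, alt = NULL,
                       father = "C451", mother = "C452") {
  M <- nrow(gt)
  N <- ncol(gt)
  ids <- colnames(gt)
  if (is.null(ids)) {
    ids <- c(father, mother, sprintf("O%03d", seq_len(N - 2)))
    colnames(gt) <- ids
  }
  if (is.null(qual)) qual <- rep(999, M)
  if (is.null(dp)) dp <- matrix(15L, M, N, dimnames = dimnames(gt))
  if (is.null(ref)) ref <- rep("A", M)
  if (is.null(alt)) alt <- rep("T", M)
  markers <- data.frame(
    marker_id = if (is.null(rownames(gt))) sprintf("mk%02d", seq_len(M))
                else rownames(gt),
    contig_id = sprintf("ctg%02d", seq_len(M)),
    bp_pos = seq_len(M) * 100L, lg = rep(1L, M),
    cm_pos = seq_len(M), ref = ref, alt = alt, stringsAsFactors = FALSE)
  rownames(gt) <- markers$marker_id
  dimnames(dp) <- dimnames(gt)
  samples <- data.frame(
    id = ids,
    sire = c(NA, NA, rep(father, N - 2)),
    dam = c(NA, NA, rep(mother, N - 2)),
    generation = c(1L, 1L, rep(2L, N - 2)),
    role = c("parent", "parent", rep("offspring", N - 2)),
    stringsAsFactors = FALSE)
  snail_calls(gt = gt, dp = dp, qual = qual, markers = markers,
              samples = samples)
}

# a regular marker scaffold with chosen spacing; optionally a co-located
# cluster of `cluster` markers at each position in `cluster_at`
make_scaffold <- function(lg_lengths, spacing = 2, cluster_at = NULL,
                          cluster = 3L) {
  out <- list()
  for (g in seq_along(lg_lengths)) {
    cm <- seq(0, lg_lengths[g], by = spacing)
    extra <- cluster_at[[g]]
    if (!is.null(extra))
      cm <- sort(c(cm, rep(extra, each = cluster - 1L)))
    m <- length(cm)
    out[[g]] <- data.frame(
      marker_id = sprintf("M%02d_%04d", g, seq_len(m)),
      contig_id = sprintf("ctg%02d_%03d", g, ceiling(seq_len(m) / 5)),
      bp_pos = seq_len(m) * 10000L, lg = g, cm_pos = cm,
      ref = "A", alt = "T", stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# exhaustive hidden-state enumeration oracle for the 3-state genotype HMM
genoprob_oracle <- function(cm, codes_one, eps) {
  m <- length(cm)
  states <- c("AA", "AB", "BB")
  init <- c(0.25, 0.5, 0.25)
  trans <- lapply(haldane_r(diff(cm)), function(r)
    matrix(c((1 - r)^2, 2 * r * (1 - r), r^2,
             r * (1 - r), (1 - r)^2 + r^2, r * (1 - r),
             r^2, 2 * r * (1 - r), (1 - r)^2), 3, 3, byrow = TRUE))
  emit <- function(obs, s) {
    if (is.na(obs)) return(1)
    if (obs == states[s]) 1 - eps else eps / 2
  }
  grid <- as.matrix(expand.grid(rep(list(1:3), m)))
  w <- apply(grid, 1, function(path) {
    p <- init[path[1]] * emit(codes_one[1], path[1])
    for (t in seq_len(m - 1))
      p <- p * trans[[t]][path[t], path[t + 1]] *
        emit(codes_one[t + 1], path[t + 1])
    p
  })
  post <- sapply(seq_len(m), function(t)
    sapply(1:3, function(s) sum(w[grid[, t] == s])))
  sweep(t(post), 1, colSums(post), "/")  # m x 3, rows sum to 1
}

# all permutations of 1..n (for the exhaustive ordering oracle)
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

# exhaustive-search ordering oracle: minimal sum of adjacent distances
best_order_cost <- function(D) {
  perms <- all_perms(nrow(D))
  costs <- apply(perms, 1, function(p)
    sum(D[cbind(p[-length(p)], p[-1])]))
  min(costs)
}

# enumeration oracle for the smallest credible span containing the peak
bayes_oracle <- function(cm, lod, ci_prob) {
  w <- 10^(lod - max(lod)); w <- w / sum(w)
  peak <- which.max(lod)
  best <- NULL
  for (a in seq_len(peak)) for (b in seq(peak, length(cm))) {
    if (sum(w[a:b]) >= ci_prob) {
      cand <- list(a = a, b = b, npos = b - a + 1,
                   width = cm[b] - cm[a])
      if (is.null(best) || cand$npos < best$npos ||
          (cand$npos == best$npos && cand$width < best$width))
        best <- cand
    }
  }
  c(start = cm[best$a], end = cm[best$b])
}

# simulate transmissions for a set of markers directly from meioses of a
# phased parent (error-free), returning a snail_transmissions object
make_transmissions <- function(markers, n_off, lg_lengths, seed = 1,
                               both_parents = FALSE) {
  set.seed(seed)
  M <- nrow(markers)
  pat <- matrix(NA_integer_, M, n_off,
                dimnames = list(markers$marker_id,
                                sprintf("O%03d", seq_len(n_off))))
  mat <- pat
  for (i in seq_len(n_off)) {
    pat[, i] <- snailmap:::meiosis_strands(markers, lg_lengths)
    if (both_parents)
      mat[, i] <- snailmap:::meiosis_strands(markers, lg_lengths)
  }
  structure(list(pat = pat, mat = mat,
                 offspring = colnames(pat), phase_known = TRUE),
            class = "snail_transmissions")
}
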