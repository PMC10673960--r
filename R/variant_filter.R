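#' Marker-retention criteria
#'
#' The strict retention cascade applied to the raw variant calls before
#' mapping: maximum site quality, minor-allele-frequency floor, indel
#' removal, per-site missingness cap, and an inclusive window on mean read
#' depth.
#'
#' @param qual_min Minimum site QUAL (default 999, the bcftools maximum).
#' @param maf_min Minimum minor allele frequency (default 0.05), computed
#'   over the non-missing called alleles of all individuals.
#' @param max_missing_fraction Maximum fraction of individuals missing a
#'   genotype (default 0.10).
#' @param depth_min,depth_max Inclusive bounds on the mean depth across
#'   non-missing calls (defaults 10 and 25).
#' @param drop_indels Remove indels (default TRUE).
#' @return List of class `filter_criteria`.
#' @export
filter_criteria <- function(qual_min = 999, maf_min = 0.05,
                            max_missing_fraction = 0.10,
                            depth_min = 10, depth_max = 25,
                            drop_indels = TRUE) {
  stopifnot(maf_min >= 0, maf_min <= 0.5, depth_min <= depth_max)
  structure(list(qual_min = qual_min, maf_min = maf_min,
                 max_missing_fraction = max_missing_fraction,
                 depth_min = depth_min, depth_max = depth_max,
                 drop_indels = drop_indels),
            class = "filter_criteria")
}

allele_matrices <- function(gt) {
  a1 <- matrix(NA_integer_, nrow(gt), ncol(gt))
  a2 <- a1
  ok <- !is.na(gt)
  a1[ok] <- as.integer(substr(gt[ok], 1, 1))
  a2[ok] <- as.integer(substr(gt[ok], 3, 3))
  list(a1 = a1, a2 = a2)
}

#' Apply the marker-retention cascade
#'
#' A marker is kept iff `QUAL >= qual_min`, it is not an indel, its minor
#' allele frequency is at least `maf_min`, its missing fraction is at most
#' `max_missing_fraction`, and its mean depth over non-missing calls lies in
#' `[depth_min, depth_max]`. Rules are applied in that order for the
#' report's attribution only; the kept set does not depend on the order.
#'
#' @param calls A [snail_calls()] object.
#' @param criteria A [filter_criteria()].
#' @return List with `calls` (the kept markers) and `report` (class
#'   `filter_report`: input count, ordered per-rule removal counts, output
#'   count; counts reconcile exactly).
#' @export
filter_variants <- function(calls, criteria = filter_criteria()) {
  stopifnot(inherits(calls, "snail_calls"),
            inherits(criteria, "filter_criteria"))
  M <- nrow(calls$gt)
  if (M == 0) {
    report <- structure(list(
      input_count = 0L,
      removed = c(qual = 0L, indel = 0L, maf = 0L, missingness = 0L,
                  depth = 0L),
      output_count = 0L), class = "filter_report")
    return(list(calls = calls, report = report))
  }
  al <- allele_matrices(calls$gt)
  n_called <- rowSums(!is.na(calls$gt))
  miss_frac <- rowMeans(is.na(calls$gt))
  cnt2 <- rowSums(al$a1 == 2L, na.rm = TRUE) + rowSums(al$a2 == 2L, na.rm = TRUE)
  maf <- ifelse(n_called > 0, pmin(cnt2, 2 * n_called - cnt2) / (2 * n_called), 0)
  dpm <- calls$dp
  dpm[is.na(calls$gt)] <- NA
  mean_depth <- rowMeans(dpm, na.rm = TRUE)
  mean_depth[n_called == 0] <- 0
  is_indel <- nchar(calls$markers$ref) > 1 | nchar(calls$markers$alt) > 1

  fail_qual <- calls$qual < criteria$qual_min
  fail_indel <- criteria$drop_indels & is_indel
  fail_maf <- maf < criteria$maf_min
  fail_miss <- miss_frac > criteria$max_missing_fraction
  fail_depth <- mean_depth < criteria$depth_min |
                mean_depth > criteria$depth_max

  # attribute each removal to the first failing rule, in the stated order
  fails <- cbind(qual = fail_qual, indel = fail_indel, maf = fail_maf,
                 missingness = fail_miss, depth = fail_depth)
  first_fail <- apply(fails, 1, function(z) {
    w <- which(z)
    if (length(w)) w[1] else NA_integer_
  })
  removed <- vapply(seq_len(ncol(fails)), function(j)
    sum(first_fail == j, na.rm = TRUE), 0L)
  names(removed) <- colnames(fails)
  keep <- is.na(first_fail)

  report <- structure(list(input_count = M, removed = removed,
                           output_count = sum(keep)),
                      class = "filter_report")
  list(calls = subset_calls(calls, keep), report = report)
}

subset_calls <- function(calls, keep) {
  snail_calls(gt = calls$gt[keep, , drop = FALSE],
              dp = calls$dp[keep, , drop = FALSE],
              qual = calls$qual[keep],
              markers = calls$markers[keep, , drop = FALSE],
              samples = calls$samples)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("filter_report: %d in, %d out\n", x$input_count,
              x$output_count))
  for (r in names(x$removed))
    cat(sprintf("  removed by %-11s %d\n", paste0(r, ":"), x$removed[[r]]))
  invisible(x)
}

#' Select markers informative in the designated parent
#'
#' Keeps markers where the informative parent's call is heterozygous and at
#' least one individual (any sample, parents and grandparents included) is
#' not heterozygous; markers at which every called individual is
#' heterozygous carry no segregation signal and are excluded.
#'
#' @param calls A [snail_calls()] object.
#' @param informative_parent Sample id of the informative parent
#'   (default `"C451"`).
#' @return A [snail_calls()] object restricted to informative markers.
#' @export
select_informative <- function(calls, informative_parent = "C451") {
  stopifnot(inherits(calls, "snail_calls"))
  if (!informative_parent %in% colnames(calls$gt))
    stop(sprintf("parent '%s' not found; valid ids: %s", informative_parent,
                 paste(colnames(calls$gt), collapse = ", ")))
  is_het <- function(g) !is.na(g) & substr(g, 1, 1) != substr(g, 3, 3)
  parent_het <- is_het(calls$gt[, informative_parent])
  het_m <- is_het(calls$gt)
  all_het <- rowSums(!het_m & !is.na(calls$gt)) == 0
  subset_calls(calls, parent_het & !all_het)
}
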