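#' Summary statistics of a genetic map
#'
#' Computes the classical map-wide statistics from per-group marker counts
#' and lengths: the average inter-marker interval
#' `s = L_total / (M - G)` (total map length over markers minus groups),
#' the expected genome length `sum_i (L_i + 2 s)` (each group extended by
#' `2 s` for terminal regions), genome coverage
#' `L_total / expected`, the genome-wide recombination rate
#' `L_total / genome_size_mb` in cM/Mb, and each group's percent of the map.
#'
#' @param map Either a sex-averaged map data frame (with `lg` and `cm_avg`),
#'   or a per-group table with columns `lg`, `n_markers` and `length_cm`
#'   (printed map tables can be fed directly in this form).
#' @param genome_size_mb Haploid genome size in Mb (default 3500, the
#'   *C. nemoralis* draft assembly).
#' @return List of class `map_summary`: `per_lg` (with `pct_of_map`),
#'   `n_markers`, `n_lg`, `total_length_cm`, `s`, `expected_length_cm`,
#'   `coverage`, `recomb_rate_cm_per_mb`, `mean_markers_per_lg`. Values are
#'   unrounded; the print method rounds for display.
#' @export
#' @examples
#' summarize_map(data.frame(lg = 1, n_markers = 2, length_cm = 10))
summarize_map <- function(map, genome_size_mb = 3500) {
  stopifnot(genome_size_mb > 0)
  if (all(c("n_markers", "length_cm") %in% names(map))) {
    per_lg <- data.frame(lg = map$lg, n_markers = map$n_markers,
                         length_cm = map$length_cm)
  } else {
    stopifnot(all(c("lg", "cm_avg") %in% names(map)))
    per_lg <- do.call(rbind, lapply(split(map, map$lg), function(d)
      data.frame(lg = d$lg[1], n_markers = nrow(d),
                 length_cm = max(d$cm_avg) - min(d$cm_avg))))
    rownames(per_lg) <- NULL
  }
  M <- sum(per_lg$n_markers)
  G <- nrow(per_lg)
  L <- sum(per_lg$length_cm)
  if (M == G) {
    warning("as many markers as groups: average interval s undefined, using 0")
    s <- 0
  } else s <- L / (M - G)
  expected <- sum(per_lg$length_cm + 2 * s)
  per_lg$pct_of_map <- if (L > 0) 100 * per_lg$length_cm / L else
    rep(0, G)
  structure(list(per_lg = per_lg, n_markers = M, n_lg = G,
                 total_length_cm = L, s = s,
                 expected_length_cm = expected,
                 coverage = if (expected > 0) L / expected else 1,
                 recomb_rate_cm_per_mb = L / genome_size_mb,
                 mean_markers_per_lg = M / G),
            class = "map_summary")
}

#' @export
print.map_summary <- function(x, ...) {
  cat(sprintf("map_summary: %d markers on %d linkage groups\n",
              x$n_markers, x$n_lg))
  cat(sprintf("  total length:       %.2f cM\n", x$total_length_cm))
  cat(sprintf("  mean interval s:    %.2g cM\n", x$s))
  cat(sprintf("  expected length:    %.2f cM\n", x$expected_length_cm))
  cat(sprintf("  genome coverage:    %d%%\n", round(100 * x$coverage)))
  cat(sprintf("  recombination rate: %.2f cM/Mb\n",
              x$recomb_rate_cm_per_mb))
  cat(sprintf("  mean markers/LG:    %.0f\n", x$mean_markers_per_lg))
  invisible(x)
}

#' Write a map summary as TSV plus a JSON block
#'
#' @param summary A [summarize_map()] result.
#' @param tsv_path,json_path Output paths (either may be NULL to skip).
#' @param header Optional comment line(s) prefixed to the TSV.
#' @export
write_map_summary <- function(summary, tsv_path = NULL, json_path = NULL,
                              header = NULL) {
  if (!is.null(tsv_path)) {
    con <- file(tsv_path, "w")
    if (!is.null(header)) writeLines(header, con)
    tab <- summary$per_lg
    tab$length_cm <- round(tab$length_cm, 2)
    tab$pct_of_map <- round(tab$pct_of_map, 2)
    write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(n_markers = summary$n_markers, n_lg = summary$n_lg,
           total_length_cm = summary$total_length_cm,
           s = summary$s,
           expected_length_cm = summary$expected_length_cm,
           coverage = summary$coverage,
           recomb_rate_cm_per_mb = summary$recomb_rate_cm_per_mb,
           mean_markers_per_lg = summary$mean_markers_per_lg),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(summary)
}
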