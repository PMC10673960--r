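#' Pipeline configuration
#'
#' Assembles the configuration of the end-to-end analysis: either a
#' simulated cross (the default) or a VCF plus phenotype/pedigree tables,
#' followed by the marker-retention cascade, grouping/ordering, map
#' statistics, the binary-trait scans, and the power table.
#'
#' @param mode `"simulate"` or `"vcf"`.
#' @param sim A [cross_config()] (simulate mode). The default desk-scale
#'   cross uses the published group lengths with 20 markers per group.
#' @param sim_markers Optional pre-built marker scaffold handed to
#'   [simulate_cross()] (simulate mode).
#' @param trait_loci A [default_trait_loci()]-shaped table (simulate mode).
#' @param vcf,phenotypes,pedigree Input paths (vcf mode).
#' @param filter A [filter_criteria()].
#' @param grouping A [grouping_params()]. The default here lowers
#'   `size_limit` to 5 markers: the study-scale default of 600 is tied to a
#'   215k-marker map and would dissolve every desk-scale group.
#' @param scan A [scan_params()].
#' @param power_spec List with `n`, `h2_grid`, `interval_cm`, `alpha` for
#'   the power table.
#' @param genome_size_mb Haploid genome size for map statistics.
#' @param out_dir Output directory (created if absent).
#' @param seed Master seed; every stochastic stage derives a child seed
#'   from it.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("simulate", "vcf"),
                            sim = cross_config(),
                            sim_markers = NULL,
                            trait_loci = default_trait_loci(),
                            vcf = NULL, phenotypes = NULL, pedigree = NULL,
                            filter = filter_criteria(),
                            grouping = grouping_params(size_limit = 5),
                            scan = scan_params(),
                            power_spec = list(n = 75,
                                              h2_grid = c(0.25, 0.5, 0.75, 1),
                                              interval_cm = c(2, 5),
                                              alpha = 0.01),
                            genome_size_mb = 3500,
                            out_dir = tempfile("snailmap_run_"),
                            seed = 1L) {
  mode <- match.arg(mode)
  cfg <- structure(list(mode = mode, sim = sim, sim_markers = sim_markers,
                        trait_loci = trait_loci,
                        vcf = vcf, phenotypes = phenotypes,
                        pedigree = pedigree, filter = filter,
                        grouping = grouping, scan = scan,
                        power_spec = power_spec,
                        genome_size_mb = genome_size_mb,
                        out_dir = out_dir, seed = as.integer(seed)),
                   class = "pipeline_config")
  if (mode == "vcf") {
    for (f in c("vcf", "phenotypes")) {
      if (is.null(cfg[[f]]) || !file.exists(cfg[[f]]))
        stop(structure(class = c("snailmap_config_error", "error",
                                 "condition"),
                       list(message = sprintf(
                         "config error: %s file missing or not found", f),
                         call = NULL)))
    }
  }
  cfg
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(config[setdiff(names(config), "out_dir")]), f)
  unname(tools::md5sum(f))
}

out_header <- function(config) {
  sprintf("# snailmap %s config_hash=%s",
          as.character(utils::packageVersion("snailmap")),
          config_hash(config))
}

write_tsv_with_header <- function(df, path, header) {
  con <- file(path, "w")
  writeLines(header, con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
}

#' Run the full mapping-and-scanning pipeline
#'
#' Sequences the stages in analysis order: obtain calls (simulate or read),
#' filter, select informative markers, two-point estimation, grouping,
#' per-group ordering, LOD-matrix pruning, contig-conflict resolution,
#' sex-averaging, map statistics, then per trait the HMM genotype
#' probabilities, binary scan, permutation threshold, peak finding, Bayes
#' credible intervals, allele effects, segregation validation and candidate
#' region, and finally the power table. Deterministic given `seed`. Every
#' output file starts with a header line recording the package version and
#' a configuration hash.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the artifact bundle: a list with the filter report,
#'   map, map summary, per-trait scan results and regions, and the power
#'   table. Files are written under `config$out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- out_header(config)
  log_lines <- c(hdr, sprintf("seed=%d mode=%s", config$seed, config$mode))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(structure(class = c("snailmap_data_error", "error", "condition"),
                     list(message = sprintf("stage '%s' failed: %s", name,
                                            conditionMessage(e)),
                          call = NULL)))
    })
  }

  # --- inputs ---------------------------------------------------------
  if (config$mode == "simulate") {
    sim_cfg <- config$sim
    sim_cfg$seed <- stage_seed(config$seed, "simulate")
    cross <- stage("simulate",
                   simulate_cross(sim_cfg, config$trait_loci,
                                  markers = config$sim_markers))
    calls <- cross$calls
    phen <- cross$phenotypes
  } else {
    calls <- stage("read_vcf", read_cross_vcf(config$vcf))
    phen <- stage("read_phenotypes", read_phenotypes(config$phenotypes))
    if (!is.null(config$pedigree)) {
      ped <- read.delim(config$pedigree, na.strings = ".",
                        stringsAsFactors = FALSE)
      calls$samples <- data.frame(id = ped$individual_id, sire = ped$sire,
                                  dam = ped$dam,
                                  generation = ped$generation,
                                  role = ifelse(ped$generation == 2,
                                                "offspring",
                                                ifelse(ped$generation == 1,
                                                       "parent",
                                                       "grandparent")),
                                  stringsAsFactors = FALSE)
    }
    cross <- NULL
  }

  # --- marker retention ----------------------------------------------
  flt <- stage("filter", filter_variants(calls, config$filter))
  inf <- stage("informative", select_informative(flt$calls))
  jsonlite::write_json(
    list(header = hdr, input_count = flt$report$input_count,
         removed = as.list(flt$report$removed),
         output_count = flt$report$output_count,
         informative_count = nrow(inf$gt)),
    file.path(config$out_dir, "filter_report.json"),
    auto_unbox = TRUE, digits = NA)
  log_lines <- c(log_lines,
                 sprintf("filter: %d -> %d -> %d informative",
                         flt$report$input_count, flt$report$output_count,
                         nrow(inf$gt)))

  # --- linkage map ----------------------------------------------------
  tm <- stage("transmissions", transmissions(inf))
  pw <- stage("two_point", pairwise_rf(tm))
  lg <- stage("grouping", group_markers(pw$lod, config$grouping))
  maps <- list()
  for (g in sort(unique(lg[lg > 0]))) {
    sel <- which(lg == g)
    tm_g <- structure(list(pat = tm$pat[sel, , drop = FALSE],
                           mat = tm$mat[sel, , drop = FALSE],
                           offspring = tm$offspring, phase_known = TRUE),
                      class = "snail_transmissions")
    om <- stage("ordering",
                order_markers(tm_g, config$grouping,
                              seed = stage_seed(config$seed, "order")))
    om$lg <- g
    maps[[length(maps) + 1]] <- om
  }
  if (!length(maps))
    stop(structure(class = c("snailmap_data_error", "error", "condition"),
                   list(message = "no linkage groups formed", call = NULL)))
  map <- do.call(rbind, maps)
  map <- merge(map, inf$markers[, c("marker_id", "contig_id", "bp_pos")],
               by = "marker_id", sort = FALSE)
  map <- map[order(map$lg, map$order), ]

  # complete per-parent strands along each ordered group (the phasing /
  # imputation step), then recompute per-parent map positions from the
  # completed strands so both parents have defined positions everywhere
  pat_imp <- matrix(NA_integer_, nrow(map), length(tm$offspring),
                    dimnames = list(map$marker_id, tm$offspring))
  mat_imp <- pat_imp
  for (g in unique(map$lg)) {
    sel <- which(map$lg == g)
    ids <- map$marker_id[sel]
    r_adj <- pairwise_adjacent_r(tm, ids)
    gaps <- haldane_cm(pmin(r_adj, 0.49))
    pat_imp[sel, ] <- phase_impute(tm$pat[ids, , drop = FALSE], gaps,
                                   config$scan$genotyping_error)
    mat_imp[sel, ] <- phase_impute(tm$mat[ids, , drop = FALSE], gaps,
                                   config$scan$genotyping_error)
    map$cm_male[sel] <- strand_cm(pat_imp[sel, , drop = FALSE])
    map$cm_female[sel] <- strand_cm(mat_imp[sel, , drop = FALSE])
  }

  # LOD-matrix pruning of weakly supported co-located SNPs
  max_lod <- apply(pw$lod[map$marker_id, map$marker_id, drop = FALSE], 1, max)
  loc_id <- paste(map$lg, round((map$cm_male + map$cm_female) / 2, 3))
  norm <- normalize_lod_scores(max_lod, loc_id)
  pruned <- prune_by_lod(norm, loc_id)
  map <- map[!pruned, , drop = FALSE]
  pat_imp <- pat_imp[map$marker_id, , drop = FALSE]
  mat_imp <- mat_imp[map$marker_id, , drop = FALSE]

  rc <- stage("contig_conflicts", resolve_contig_conflicts(map))
  map <- sex_average(rc$map)
  pat_imp <- pat_imp[map$marker_id, , drop = FALSE]
  mat_imp <- mat_imp[map$marker_id, , drop = FALSE]
  jsonlite::write_json(
    list(header = hdr,
         pruned_by_lod = sum(pruned),
         contig_conflicts = rc$log),
    file.path(config$out_dir, "removal_log.json"), auto_unbox = TRUE,
    digits = NA)
  write_tsv_with_header(
    map[, c("marker_id", "contig_id", "bp_pos", "lg", "cm_male",
            "cm_female", "cm_avg")],
    file.path(config$out_dir, "map.tsv"), hdr)

  # --- map statistics -------------------------------------------------
  summ <- summarize_map(map, config$genome_size_mb)
  write_map_summary(summ,
                    tsv_path = file.path(config$out_dir, "map_summary.tsv"),
                    json_path = file.path(config$out_dir,
                                          "map_summary.json"),
                    header = hdr)

  # --- trait scans ----------------------------------------------------
  off <- tm$offspring
  codes <- to_f2_codes(matrix(paste0(pat_imp, "|", mat_imp),
                              nrow(map),
                              dimnames = dimnames(pat_imp)))
  scans <- list()
  for (trait in unique(phen$trait)) {
    ph <- phen[phen$trait == trait, ]
    y <- ph$value[match(off, ph$id)]
    sp <- config$scan
    sp$seed <- stage_seed(config$seed, paste0("perm_", trait))
    probs <- stage("genoprob", calc_genoprob(map, codes, sp))
    scan <- stage("scan", binary_scan(probs, y))
    thr <- stage("permutation", permutation_threshold(probs, y, sp))
    peaks <- find_peaks(scan, thr, sp$peakdrop)
    peak_rows <- list()
    region <- structure(list(localised = FALSE), class = "candidate_region")
    best <- NULL
    if (nrow(peaks)) {
      peaks$start_cm <- NA_real_
      peaks$end_cm <- NA_real_
      peaks$eff_contrast <- NA_real_
      for (i in seq_len(nrow(peaks))) {
        ci <- bayes_interval(scan, peaks$lg[i], sp$ci_prob,
                             idx_range = c(peaks$idx_lo[i],
                                           peaks$idx_hi[i]))
        peaks$start_cm[i] <- ci$start_cm
        peaks$end_cm[i] <- ci$end_cm
        eff <- allele_effects(probs, y, peaks$lg[i])
        at <- which.min(abs(eff$cm - peaks$cm[i]))
        peaks$eff_contrast[i] <- abs(eff$eff_BB[at] - eff$eff_AA[at])
      }
      # the supported peak shows an allele-effect peak alongside the LOD peak
      best <- which.max(peaks$eff_contrast)
      eff <- allele_effects(probs, y, peaks$lg[best])
      at <- which.min(abs(eff$cm - peaks$cm[best]))
      bb_value <- as.integer(eff$eff_BB[at] > eff$eff_AA[at])
      on_lg <- which(map$lg == peaks$lg[best])
      in_ci <- on_lg[map$cm_avg[on_lg] >= peaks$start_cm[best] &
                     map$cm_avg[on_lg] <= peaks$end_cm[best]]
      seg <- segregation_check(codes[in_ci, , drop = FALSE], y,
                               map$cm_avg[in_ci], bb_value = bb_value)
      region <- candidate_region(
        seg, list(start_cm = peaks$start_cm[best],
                  end_cm = peaks$end_cm[best]),
        map_lg = map[on_lg, ])
      region$lg <- peaks$lg[best]
      region$bb_value <- bb_value
    }
    scan_path <- file.path(config$out_dir, paste0("scan_", trait, ".tsv"))
    effs <- do.call(rbind, lapply(unique(scan$lg), function(g)
      allele_effects(probs, y, g)))
    scan_out <- merge(scan, effs[, c("marker_id", "eff_AA", "eff_AB",
                                     "eff_BB")],
                      by = "marker_id", sort = FALSE)
    write_tsv_with_header(
      scan_out[, c("lg", "cm", "marker_id", "lod", "eff_AA", "eff_AB",
                   "eff_BB")], scan_path, hdr)
    jsonlite::write_json(
      list(header = hdr, trait = trait, threshold = as.numeric(thr),
           lg = if (region$localised) region$lg else NA,
           localised = region$localised,
           span_cm = if (region$localised) region$span_cm else NULL,
           width_cm = if (region$localised) region$width_cm else NULL,
           contigs = if (region$localised) region$contigs else NULL),
      file.path(config$out_dir, paste0("region_", trait, ".json")),
      auto_unbox = TRUE, digits = NA)
    scans[[trait]] <- list(scan = scan, threshold = as.numeric(thr),
                           peaks = peaks, region = region)
    log_lines <- c(log_lines,
                   sprintf("scan %s: threshold %.2f, %d peak(s), %s", trait,
                           thr, nrow(peaks),
                           if (region$localised)
                             sprintf("locus on LG %d (~%.1f cM)", region$lg,
                                     region$width_cm)
                           else "locus not localised"))
  }
  all_peaks <- do.call(rbind, lapply(names(scans), function(tr) {
    p <- scans[[tr]]$peaks
    if (!nrow(p)) return(NULL)
    data.frame(trait = tr,
               interval_id = paste0(toupper(substr(tr, 1, 1)),
                                    seq_len(nrow(p))),
               lg = p$lg, position = p$cm, lod = p$lod,
               start_position = p$start_cm, end_position = p$end_cm)
  }))
  if (!is.null(all_peaks))
    write_tsv_with_header(all_peaks,
                          file.path(config$out_dir, "peaks.tsv"), hdr)

  # --- power table ----------------------------------------------------
  ps <- config$power_spec
  pow <- expand.grid(n = ps$n, h2 = ps$h2_grid,
                     interval_cm = ps$interval_cm, alpha = ps$alpha)
  pow$power <- mapply(qtl_power, n = pow$n, h2 = pow$h2,
                      interval_cm = pow$interval_cm, alpha = pow$alpha)
  write_tsv_with_header(pow, file.path(config$out_dir, "power.tsv"), hdr)

  writeLines(c(log_lines, "status=ok"),
             file.path(config$out_dir, "run_log.txt"))
  invisible(list(filter_report = flt$report, map = map, summary = summ,
                 scans = scans, peaks = all_peaks, power = pow,
                 cross = cross, out_dir = config$out_dir))
}
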