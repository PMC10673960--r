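#' Write genotype calls to a VCF v4.2 file
#'
#' Emits a minimal plain-text VCF v4.2 with FORMAT `GT:DP` and per-site
#' `QUAL`. Internal allele indices 1/2 map to VCF allele indices 0/1;
#' phased calls are written with `|`, missing calls as `./.`. Base-pair
#' positions are 0-based internally and written 1-based.
#'
#' @param calls A [snail_calls()] object (or a `snail_cross`, whose calls
#'   are used).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cross_vcf <- function(calls, path) {
  if (inherits(calls, "snail_cross")) calls <- calls$calls
  stopifnot(inherits(calls, "snail_calls"))
  m <- calls$markers
  gt <- calls$gt
  gt_vcf <- matrix("./.", nrow(gt), ncol(gt))
  ok <- !is.na(gt)
  a1 <- as.integer(substr(gt[ok], 1, 1)) - 1L
  a2 <- as.integer(substr(gt[ok], 3, 3)) - 1L
  gt_vcf[ok] <- paste0(a1, "|", a2)
  body <- matrix(paste0(gt_vcf, ":", calls$dp), nrow(gt), ncol(gt))
  header <- c(
    "##fileformat=VCFv4.2",
    paste0("##source=snailmap_", as.character(utils::packageVersion("snailmap"))),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(gt)), collapse = "\t"))
  lines <- apply(cbind(m$contig_id, m$bp_pos + 1L, m$marker_id, m$ref, m$alt,
                       calls$qual, ".", ".", "GT:DP", body), 1,
                 paste, collapse = "\t")
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Read genotype calls from a VCF file
#'
#' Parses a VCF v4.2 file (via vcfR) into a [snail_calls()] object. A light
#' structural pre-check reports the first malformed data line by line number
#' before parsing. Sites whose GT uses VCF allele indices 0/1 are converted
#' to internal indices 1/2; `./.` (or `.|.`) becomes `NA`.
#'
#' @param path Path to a VCF file.
#' @param samples Optional sample/pedigree data frame to attach; defaults to
#'   a minimal table built from the VCF sample names.
#' @return A [snail_calls()] object.
#' @export
read_cross_vcf <- function(path, samples = NULL) {
  raw <- readLines(path)
  data_idx <- which(!startsWith(raw, "#"))
  hdr_idx <- which(startsWith(raw, "#CHROM"))
  if (length(hdr_idx) != 1)
    stop("malformed VCF: expected exactly one #CHROM header line")
  n_col <- length(strsplit(raw[hdr_idx], "\t", fixed = TRUE)[[1]])
  n_fields <- lengths(strsplit(raw[data_idx], "\t", fixed = TRUE))
  bad <- data_idx[n_fields != n_col]
  if (length(bad))
    stop(sprintf("malformed VCF: line %d has %d fields, expected %d",
                 bad[1], n_fields[match(bad[1], data_idx)], n_col))

  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  dp <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
  dp[is.na(dp)] <- 0L
  storage.mode(dp) <- "integer"

  gt <- matrix(NA_character_, nrow(gt_raw), ncol(gt_raw),
               dimnames = dimnames(gt_raw))
  ok <- !is.na(gt_raw) & grepl("^[0-9][|/][0-9]$", gt_raw)
  a1 <- as.integer(substr(gt_raw[ok], 1, 1)) + 1L
  a2 <- as.integer(substr(gt_raw[ok], 3, 3)) + 1L
  gt[ok] <- paste0(a1, "|", a2)

  markers <- data.frame(
    marker_id = ifelse(is.na(fix$ID) | fix$ID == ".",
                       paste0(fix$CHROM, ":", fix$POS), fix$ID),
    contig_id = fix$CHROM,
    bp_pos = as.integer(fix$POS) - 1L,
    lg = NA_integer_, cm_pos = NA_real_,
    ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE)
  rownames(gt) <- markers$marker_id
  if (is.null(samples))
    samples <- data.frame(id = colnames(gt), sire = NA, dam = NA,
                          generation = NA_integer_, role = NA_character_,
                          stringsAsFactors = FALSE)
  qual <- suppressWarnings(as.numeric(fix$QUAL))
  qual[is.na(qual)] <- 0
  snail_calls(gt = gt, dp = dp, qual = qual, markers = markers,
              samples = samples)
}

#' Write the phenotype table
#'
#' @param phenotypes Data frame `individual_id`/`id`, `trait_name`/`trait`,
#'   `value` in \{0,1\}.
#' @param path Output TSV path.
#' @export
write_phenotypes <- function(phenotypes, path) {
  df <- data.frame(individual_id = phenotypes$id,
                   trait_name = phenotypes$trait,
                   value = phenotypes$value)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the pedigree table
#'
#' @param samples Sample data frame with `id`, `sire`, `dam`, `generation`.
#' @param path Output TSV path.
#' @export
write_pedigree <- function(samples, path) {
  df <- samples[, c("id", "sire", "dam", "generation")]
  names(df)[1] <- "individual_id"
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = ".")
  invisible(path)
}

#' Read a phenotype table written by [write_phenotypes()]
#' @param path TSV path.
#' @return Data frame with `id`, `trait`, `value`.
#' @export
read_phenotypes <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  data.frame(id = df$individual_id, trait = df$trait_name, value = df$value,
             stringsAsFactors = FALSE)
}
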