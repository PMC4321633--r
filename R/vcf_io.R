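# VCF 4.2 and TSV interchange.
#
# Cohort genotypes travel as unphased GT ("0/1"); phased reference panels as
# "0|1"; imputed dosages in the DS FORMAT field with 4 decimal places,
# alongside the tolerance-called GT. Reading goes through vcfR; a light
# line-level validation pass runs first so malformed input fails with the
# offending line number. All writers stamp provenance meta-lines (tool
# version, optional seed and config hash).

vcf_meta <- function(seed = NULL, config_hash = NULL) {
  c("##fileformat=VCFv4.2",
    sprintf("##source=imputebias-%s", as.character(packageVersion("imputebias"))),
    if (!is.null(seed)) sprintf("##imputebias_seed=%s", seed),
    if (!is.null(config_hash)) sprintf("##imputebias_config=%s", config_hash),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage (alt-allele copies)\">",
    "##contig=<ID=chrS>")
}

vcf_fixed_cols <- function(map) {
  data.frame(CHROM = "chrS", POS = map$pos, ID = map$variant_id,
             REF = map$ref, ALT = map$alt, QUAL = ".", FILTER = ".",
             INFO = ".", stringsAsFactors = FALSE)
}

gt_string <- function(g, sep) {
  out <- rep(paste0(".", sep, "."), length(g))
  out[!is.na(g) & g == 0L] <- paste0("0", sep, "0")
  out[!is.na(g) & g == 1L] <- paste0("0", sep, "1")
  out[!is.na(g) & g == 2L] <- paste0("1", sep, "1")
  out
}

write_vcf_body <- function(path, meta, map, sample_names, format, cells) {
  fixed <- vcf_fixed_cols(map)
  header <- paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                    "INFO", "FORMAT", sample_names), collapse = "\t")
  body <- apply(cbind(fixed, FORMAT = format, cells), 1L, paste, collapse = "\t")
  writeLines(c(meta, header, body), path)
  invisible(path)
}

#' Write a cohort's genotypes as an unphased VCF
#'
#' @param cohort a `cohort`
#' @param path output file
#' @param seed,config_hash optional provenance stamps
#' @return `path`, invisibly
#' @export
write_cohort_vcf <- function(cohort, path, seed = NULL, config_hash = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  g <- cohort$genotypes
  cells <- matrix(gt_string(g, "/"), nrow = ncol(g), byrow = TRUE)
  write_vcf_body(path, vcf_meta(seed, config_hash), cohort$map,
                 rownames(g), "GT", cells)
}

#' Write a phased haplotype panel as a VCF
#'
#' Rows `2k-1`, `2k` of the haplotype matrix become the two phased alleles
#' of individual `k`.
#'
#' @param haplotypes 0/1 matrix with an even number of rows
#' @param map variant map
#' @param path output file
#' @param seed,config_hash optional provenance stamps
#' @return `path`, invisibly
#' @export
write_panel_vcf <- function(haplotypes, map, path,
                            seed = NULL, config_hash = NULL) {
  n <- nrow(haplotypes) / 2
  if (n != floor(n)) stop("panel must have an even number of haplotypes")
  a <- haplotypes[2 * seq_len(n) - 1L, , drop = FALSE]
  b <- haplotypes[2 * seq_len(n), , drop = FALSE]
  cells <- matrix(paste0(t(a), "|", t(b)), nrow = ncol(haplotypes))
  write_vcf_body(path, vcf_meta(seed, config_hash), map,
                 sprintf("ref%04d", seq_len(n)), "GT", cells)
}

#' Write imputed dosages (and optional integer calls) as a VCF
#'
#' Dosages are written to the DS field with 4 decimal places, alt-copy
#' coded; missing dosages as ".". When `calls` is supplied the GT field
#' carries the tolerance-called genotypes.
#'
#' @param dosages samples x variants numeric matrix in `[0, 2]` (alt copies)
#' @param map variant map for the dosage columns
#' @param path output file
#' @param calls optional samples x variants integer matrix of called
#'   genotypes (NA = no call)
#' @param seed,config_hash optional provenance stamps
#' @return `path`, invisibly
#' @export
write_dosage_vcf <- function(dosages, map, path, calls = NULL,
                             seed = NULL, config_hash = NULL) {
  dosages <- as.matrix(dosages)
  if (ncol(dosages) != nrow(map)) stop("dosage columns must match the map")
  ds <- ifelse(is.na(dosages), ".", sprintf("%.4f", dosages))
  if (is.null(calls)) {
    cells <- matrix(t(ds), nrow = ncol(dosages))
    fmt <- "DS"
  } else {
    gt <- matrix(gt_string(as.matrix(calls), "/"),
                 nrow = nrow(dosages))
    cells <- matrix(paste(t(gt), t(ds), sep = ":"), nrow = ncol(dosages))
    fmt <- "GT:DS"
  }
  sn <- rownames(dosages)
  if (is.null(sn)) sn <- sprintf("s%04d", seq_len(nrow(dosages)))
  write_vcf_body(path, vcf_meta(seed, config_hash), map, sn, fmt, cells)
}

validate_vcf_lines <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1], "##fileformat=VCF"))
    stop("not a VCF file (line 1): ", path)
  hdr <- which(startsWith(lines, "#CHROM"))
  if (!length(hdr)) stop("VCF column header line (#CHROM) not found: ", path)
  hdr <- hdr[1]
  ncols <- length(strsplit(lines[hdr], "\t", fixed = TRUE)[[1]])
  if (ncols < 10L) stop("VCF has no sample columns (line ", hdr, ")")
  for (i in seq.int(hdr + 1L, length.out = length(lines) - hdr)) {
    n <- length(strsplit(lines[i], "\t", fixed = TRUE)[[1]])
    if (n != ncols)
      stop(sprintf("malformed VCF record on line %d: expected %d fields, found %d",
                   i, ncols, n))
  }
  invisible(lines)
}

#' Read a VCF written by this package
#'
#' Returns a phased haplotype set when every genotype is phased ("|"), else
#' an unphased `cohort` with empty covariates (phenotype/sex/age come from
#' the sample metadata TSV, see [read_sample_metadata()]). Mixed phasing or
#' non-diploid genotypes raise an error.
#'
#' @param path VCF file
#' @return list with `haplotypes` and `map` (phased input), or a `cohort`
#' @export
read_vcf <- function(path) {
  validate_vcf_lines(path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  fix <- matrix(fix, ncol = ncol(vcfR::getFIX(v)),
                dimnames = dimnames(vcfR::getFIX(v)))
  map <- data.frame(variant_id = unname(fix[, "ID"]),
                    pos = as.integer(fix[, "POS"]),
                    ref = unname(fix[, "REF"]),
                    alt = unname(fix[, "ALT"]),
                    stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt)) stop("VCF lacks a GT FORMAT field: ", path)
  gt[gt == "."] <- NA_character_
  nonmiss <- gt[!is.na(gt)]
  phased <- grepl("|", nonmiss, fixed = TRUE)
  unphased <- grepl("/", nonmiss, fixed = TRUE)
  if (any(!phased & !unphased))
    stop("non-diploid GT entries found in ", path)
  if (any(phased) && any(unphased))
    stop("mixed phased/unphased genotypes in ", path)
  alleles <- function(x) {
    a <- strsplit(x, "[/|]")
    if (any(lengths(a) != 2L, na.rm = TRUE))
      stop("non-diploid GT entries found in ", path)
    a
  }
  if (all(phased)) {
    al <- alleles(as.vector(gt))
    a1 <- vapply(al, function(z) as.integer(z[1]), 1L)
    a2 <- vapply(al, function(z) as.integer(z[2]), 1L)
    # gt is variants x samples; haplotypes are rows
    n <- ncol(gt)
    hap <- matrix(0L, 2L * n, nrow(gt))
    hap[2 * seq_len(n) - 1L, ] <- t(matrix(a1, nrow(gt), n))
    hap[2 * seq_len(n), ] <- t(matrix(a2, nrow(gt), n))
    return(list(haplotypes = hap, map = map))
  }
  count <- function(x) {
    if (is.na(x) || x %in% c("./.", ".")) return(NA_integer_)
    sum(as.integer(strsplit(x, "/", fixed = TRUE)[[1]]))
  }
  g <- apply(gt, c(1, 2), count)
  g <- t(g)  # samples x variants
  n <- nrow(g)
  new_cohort(g, phenotype = rep(NA_integer_, n), sex = rep(NA_integer_, n),
             age = rep(NA_real_, n), map = map)
}

#' Read a dosage VCF's DS field
#'
#' @param path VCF file with a DS FORMAT field
#' @return list with `dosages` (samples x variants), optional `calls`, `map`
#' @export
read_dosage_vcf <- function(path) {
  validate_vcf_lines(path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  map <- data.frame(variant_id = unname(fix[, "ID"]),
                    pos = as.integer(fix[, "POS"]),
                    ref = unname(fix[, "REF"]),
                    alt = unname(fix[, "ALT"]),
                    stringsAsFactors = FALSE)
  ds <- vcfR::extract.gt(v, element = "DS")
  if (is.null(ds)) stop("VCF lacks a DS FORMAT field: ", path)
  ds[ds == "."] <- NA_character_
  dosages <- t(matrix(as.numeric(ds), nrow(ds), ncol(ds),
                      dimnames = dimnames(ds)))
  out <- list(dosages = dosages, map = map)
  gt <- tryCatch(vcfR::extract.gt(v, element = "GT"), error = function(e) NULL)
  if (!is.null(gt)) {
    cnt <- c("0/0" = 0L, "0/1" = 1L, "1/1" = 2L)
    out$calls <- t(matrix(unname(cnt[as.vector(gt)]), nrow(gt), ncol(gt),
                          dimnames = dimnames(gt)))
  }
  out
}

#' Write / read the sample metadata table
#'
#' Tab-separated with header `sample_id phenotype sex age`; provenance as
#' leading `#` comment lines.
#'
#' @param cohort a `cohort`
#' @param path TSV file
#' @param seed optional provenance stamp
#' @return `path` (writer) or a data.frame (reader)
#' @export
write_sample_metadata <- function(cohort, path, seed = NULL) {
  df <- data.frame(sample_id = rownames(cohort$genotypes),
                   phenotype = cohort$phenotype,
                   sex = cohort$sex,
                   age = cohort$age,
                   stringsAsFactors = FALSE)
  write_report_tsv(df, path, seed = seed)
}

#' @rdname write_sample_metadata
#' @export
read_sample_metadata <- function(path) {
  read.table(path, header = TRUE, sep = "\t", comment.char = "#",
             stringsAsFactors = FALSE)
}

#' Write a report table as TSV with provenance comments
#'
#' @param df data.frame
#' @param path output file
#' @param seed optional seed stamp
#' @param extra extra `#` comment lines
#' @return `path`, invisibly
#' @export
write_report_tsv <- function(df, path, seed = NULL, extra = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# imputebias %s", packageVersion("imputebias")), con)
  if (!is.null(seed)) writeLines(sprintf("# seed: %s", seed), con)
  if (!is.null(extra)) writeLines(paste0("# ", extra), con)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE, col.names = TRUE))
  invisible(path)
}

#' @rdname write_report_tsv
#' @export
read_report_tsv <- function(path) {
  read.table(path, header = TRUE, sep = "\t", comment.char = "#",
             stringsAsFactors = FALSE)
}
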