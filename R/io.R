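# Readers/writers.  Panel and counts travel as TSV keyed by snp_id
# (coordinates are 1-based as in VCF); reports and truth records as JSON.

#' Read a SNP panel from TSV
#'
#' Expected columns: `snp_id`, `chrom`, `pos` (1-based), `M1`, `M2`, `P1`,
#' `P2`, `is_y` (0/1; optional).  `NA` or `.` mark absent alleles (Y loci).
#'
#' @param path file path.
#' @return `ff_panel`.
#' @export
read_panel_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   na.strings = c("NA", "."), colClasses = "character")
  df$pos <- as.integer(df$pos)
  if ("is_y" %in% names(df)) df$is_y <- as.integer(df$is_y) > 0L
  build_panel(df)
}

#' Write a SNP panel to TSV
#' @param panel `ff_panel`.
#' @param path file path.
#' @return invisibly, the path.
#' @export
write_panel_tsv <- function(panel, path) {
  stopifnot(inherits(panel, "ff_panel"))
  out <- panel[, c("snp_id", "chrom", "pos", "M1", "M2", "P1", "P2", "is_y")]
  out$is_y <- as.integer(out$is_y)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an allele-count table from TSV
#'
#' Expected header `snp_id A C G T` with non-negative integer counts.
#' Malformed or negative rows are rejected with their line number;
#' zero-depth SNPs are retained (downstream estimation flags them).
#'
#' @param path file path.
#' @return `ff_counts`.
#' @export
read_counts_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("snp_id", .BASES)
  if (!all(need %in% names(df)))
    stop("counts TSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  for (b in .BASES) {
    v <- suppressWarnings(as.numeric(df[[b]]))
    bad <- which(is.na(v) | v < 0 | v != round(v))
    if (length(bad))
      stop(sprintf("invalid count in column %s, file line %d (snp %s)",
                   b, bad[1L] + 1L, df$snp_id[bad[1L]]), call. = FALSE)
    df[[b]] <- v
  }
  allele_count_table(df[, need])
}

#' Write an allele-count table to TSV
#' @param counts `ff_counts`.
#' @param path file path.
#' @return invisibly, the path.
#' @export
write_counts_tsv <- function(counts, path) {
  counts <- allele_count_table(unclass(counts))
  df <- data.frame(snp_id = rownames(counts), counts,
                   stringsAsFactors = FALSE, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a SNP panel from a phased VCF
#'
#' Builds a panel from the phased genotypes of the two parents.  The
#' haplotype-order convention is: the first allele of the mother's phased
#' genotype is M1, the second M2 (and likewise P1/P2 for the father).
#' Getting the maternal orientation wrong flips every Type-4 sign, so the
#' signature carries a self-check flag (`t4_subtypes_same_sign`).  Unphased
#' (`/`), half-called or non-SNV records are skipped and counted.
#'
#' @param path VCF file (plain or bgzipped).
#' @param mother_id,father_id sample names in the VCF.
#' @return `ff_panel` with attribute `skipped` (named counts of skipped
#'   records).
#' @export
read_phased_vcf <- function(path, mother_id, father_id) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("read_phased_vcf requires the VariantAnnotation package",
         call. = FALSE)
  vcf <- VariantAnnotation::readVcf(path)
  gt <- VariantAnnotation::geno(vcf)$GT
  for (id in c(mother_id, father_id))
    if (!id %in% colnames(gt))
      stop("sample '", id, "' not found in VCF", call. = FALSE)
  ref <- as.character(VariantAnnotation::ref(vcf))
  alt <- VariantAnnotation::alt(vcf)
  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  ids <- rownames(gt)

  skipped <- c(unphased = 0L, half_call = 0L, non_snv = 0L)
  rows <- vector("list", nrow(gt))
  for (i in seq_len(nrow(gt))) {
    alleles <- c(ref[i], as.character(alt[[i]]))
    if (any(nchar(alleles) != 1L) || !all(alleles %in% .BASES)) {
      skipped["non_snv"] <- skipped["non_snv"] + 1L; next
    }
    parse_gt <- function(g) {
      if (grepl("/", g, fixed = TRUE)) return("unphased")
      parts <- strsplit(g, "|", fixed = TRUE)[[1L]]
      if (length(parts) != 2L || any(parts == ".")) return("half_call")
      ix <- suppressWarnings(as.integer(parts)) + 1L
      if (anyNA(ix) || any(ix > length(alleles))) return("half_call")
      alleles[ix]
    }
    mg <- parse_gt(gt[i, mother_id]); fg <- parse_gt(gt[i, father_id])
    if (is.character(mg) && length(mg) == 1L) {
      skipped[mg] <- skipped[mg] + 1L; next
    }
    if (is.character(fg) && length(fg) == 1L) {
      skipped[fg] <- skipped[fg] + 1L; next
    }
    rows[[i]] <- data.frame(snp_id = ids[i], chrom = chrom[i], pos = pos[i],
                            M1 = mg[1L], M2 = mg[2L], P1 = fg[1L], P2 = fg[2L],
                            is_y = FALSE, stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows))
    stop("no usable phased biallelic SNVs in VCF", call. = FALSE)
  panel <- build_panel(do.call(rbind, rows))
  attr(panel, "skipped") <- skipped
  if (sum(skipped))
    message(sum(skipped), " VCF record(s) skipped (",
            paste(names(skipped), skipped, sep = "=", collapse = ", "), ")")
  panel
}

#' @keywords internal
.estimate_to_list <- function(e)
  list(value = e$value, dispersion = e$dispersion, sd = e$sd,
       n_snps = e$n_snps, values = e$values, available = e$available)

#' Write a self-contained JSON report
#'
#' Serializes at full precision the per-class FF estimates, dispersions and
#' SNP counts, the regression slopes, the alert decision with reasons, the
#' ranked scenario fits with notes, and an echo of the configuration plus
#' the package version.
#'
#' @param path output file.
#' @param signature `ff_signature` (optional).
#' @param regression `ff_regression` (optional; absent sections are noted).
#' @param call_result `ff_alert` and/or the output of [classify_scenario()]
#'   via `fits` (both optional).
#' @param fits `ff_fits` (optional).
#' @param config list echoed into the report.
#' @return invisibly, the path.
#' @export
write_report <- function(path, signature = NULL, regression = NULL,
                         call_result = NULL, fits = NULL, config = NULL) {
  rep <- list(tool = "ffsig",
              version = as.character(packageVersion("ffsig")))
  if (!is.null(signature)) {
    stopifnot(inherits(signature, "ff_signature"))
    rep$signature <- list(
      t1 = .estimate_to_list(signature$t1),
      t3_p1 = .estimate_to_list(signature$t3_p1),
      t3_p2 = .estimate_to_list(signature$t3_p2),
      t4_alpha = .estimate_to_list(signature$t4_alpha),
      t4_beta = .estimate_to_list(signature$t4_beta),
      background = .estimate_to_list(signature$bkg),
      background_ff_scale = .estimate_to_list(signature$bkg_ff),
      ff_y = .estimate_to_list(signature$ff_y),
      sex = signature$sex,
      xxy_suspect = signature$xxy_suspect,
      class_counts = as.list(signature$class_counts),
      excluded = signature$excluded,
      flags = signature$flags)
  }
  rep$regression <- if (is.null(regression)) {
    list(present = FALSE, note = "no maternal sample provided")
  } else {
    stopifnot(inherits(regression, "ff_regression"))
    c(list(present = TRUE), unclass(regression))
  }
  if (!is.null(call_result)) {
    stopifnot(inherits(call_result, "ff_alert"))
    rep$alert <- unclass(call_result)
  }
  if (!is.null(fits)) {
    stopifnot(inherits(fits, "ff_fits"))
    rep$scenario_fits <- list(ranked = as.data.frame(fits),
                              tied_set = attr(fits, "tied_set"),
                              transmitted = attr(fits, "transmitted"),
                              notes = attr(fits, "notes"))
  }
  rep$config <- config
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", dataframe = "columns")
  invisible(path)
}

#' Read back a JSON report
#' @param path file written by [write_report()].
#' @return nested list.
#' @export
read_report <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)

#' @keywords internal
.truth_to_json <- function(truth, path) {
  sc <- truth$scenario
  jsonlite::write_json(
    list(kind = sc$kind, f = sc$f, m = sc$m, mat_hap = sc$mat_hap,
         pat_hap = sc$pat_hap, twin_split = sc$twin_split,
         twin2_mat = sc$twin2_mat, twin2_pat = sc$twin2_pat,
         seed = truth$seed, depth = truth$depth,
         error_rate = truth$error_rate),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
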