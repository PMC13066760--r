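#' Signature-computation settings
#'
#' @param min_snps minimum usable SNPs per class before an estimate is
#'   considered confident (used by the alert rule).
#' @param max_unexpected_freq loci where an allele incompatible with both
#'   parental genotypes exceeds this frequency are excluded as probable
#'   genotyping errors.
#' @param y_call_threshold fetal sex is called male when mean Y-locus depth
#'   exceeds this multiple of the mean autosomal/X depth.
#' @param xxy_t3_min with a male call, a Type-3 FF above this level flags a
#'   possible 47,XXY pattern (paternal X haplotype present alongside Y).
#' @return list of settings.
#' @export
signature_config <- function(min_snps = 5L, max_unexpected_freq = 0.20,
                             y_call_threshold = 0.01, xxy_t3_min = 0.02) {
  stopifnot(min_snps >= 1L, max_unexpected_freq > 0, max_unexpected_freq < 1,
            y_call_threshold > 0, xxy_t3_min > 0)
  list(min_snps = as.integer(min_snps),
       max_unexpected_freq = max_unexpected_freq,
       y_call_threshold = y_call_threshold,
       xxy_t3_min = xxy_t3_min)
}

# One FF estimate: mean of per-SNP values, with the mean absolute deviation
# ("average deviation" of the bar-chart error bars) and the sample SD used
# by the alert rule.
#' @keywords internal
.estimate <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n == 0L)
    return(structure(list(value = NA_real_, dispersion = NA_real_,
                          sd = NA_real_, n_snps = 0L, values = numeric(0),
                          available = FALSE),
                     class = "ff_estimate"))
  v <- mean(values)
  structure(list(value = v,
                 dispersion = mean(abs(values - v)),
                 sd = if (n > 1L) stats::sd(values) else 0,
                 n_snps = n, values = values, available = TRUE),
            class = "ff_estimate")
}

#' @export
print.ff_estimate <- function(x, ...) {
  if (!x$available) cat("FF estimate: unavailable (0 usable SNPs)\n")
  else cat(sprintf("FF estimate: %.4f (avg dev %.4f, sd %.4f, n = %d)\n",
                   x$value, x$dispersion, x$sd, x$n_snps))
  invisible(x)
}

# Per-SNP estimator values from a frequency matrix.  T1/T3: doubled paternal
# allele frequency; T4: signed M1-minus-M2 frequency difference; T2:
# second-highest allele frequency (raw background).
#' @keywords internal
.per_snp_values <- function(freqs, panel, usable) {
  ci <- function(al) match(al, .BASES)
  pick <- function(mask) which(usable & mask)
  out <- list()
  i <- pick(panel$class == "T1")
  out$t1 <- 2 * freqs[cbind(i, ci(panel$pat_allele[i]))]
  i <- pick(panel$subtype == "T3_P1")
  out$t3_p1 <- 2 * freqs[cbind(i, ci(panel$pat_allele[i]))]
  i <- pick(panel$subtype == "T3_P2")
  out$t3_p2 <- 2 * freqs[cbind(i, ci(panel$pat_allele[i]))]
  i <- pick(panel$subtype == "T4_ALPHA")
  out$t4_alpha <- freqs[cbind(i, ci(panel$m1_allele[i]))] -
    freqs[cbind(i, ci(panel$m2_allele[i]))]
  i <- pick(panel$subtype == "T4_BETA")
  out$t4_beta <- freqs[cbind(i, ci(panel$m1_allele[i]))] -
    freqs[cbind(i, ci(panel$m2_allele[i]))]
  i <- pick(panel$class == "T2")
  out$bkg <- if (length(i))
    apply(freqs[i, , drop = FALSE], 1L,
          function(v) sort(v, decreasing = TRUE)[2L])
  else numeric(0)
  out
}

#' Fetal fraction from Type-1 SNPs
#'
#' FF is twice the mean frequency of the paternal allele over Type-1 SNPs
#' (parents homozygous for different alleles, fetus obligate heterozygote).
#'
#' @param counts `ff_counts` table (or coercible matrix/data.frame).
#' @param panel `ff_panel`.
#' @param config see [signature_config()].
#' @return `ff_estimate`.
#' @export
estimate_ff_type1 <- function(counts, panel, config = signature_config()) {
  pr <- .prep_counts(counts, panel, config)
  .estimate(.per_snp_values(pr$freqs, panel, pr$usable)$t1)
}

#' Fetal fraction from one Type-3 subtype
#'
#' Twice the mean frequency of the paternal-specific allele over SNPs of the
#' requested subtype.  Equals FF when that paternal haplotype was
#' transmitted, and falls within sequencing noise otherwise.
#'
#' @inheritParams estimate_ff_type1
#' @param subtype `"T3_P1"` or `"T3_P2"`.
#' @return `ff_estimate`.
#' @export
estimate_ff_type3 <- function(counts, panel, subtype = c("T3_P1", "T3_P2"),
                              config = signature_config()) {
  subtype <- match.arg(subtype)
  pr <- .prep_counts(counts, panel, config)
  v <- .per_snp_values(pr$freqs, panel, pr$usable)
  .estimate(if (subtype == "T3_P1") v$t3_p1 else v$t3_p2)
}

#' Signed fetal fraction from one Type-4 subtype
#'
#' Mean over subtype SNPs of `freq(M1 allele) - freq(M2 allele)`.  Positive
#' values mean maternal haplotype M1 is over-represented.  In a normal
#' pregnancy the transmitted-haplotype subtype reads +FF (alpha, M1) or -FF
#' (beta, M2) and the other reads 0.
#'
#' @inheritParams estimate_ff_type1
#' @param subtype `"T4_ALPHA"` or `"T4_BETA"`.
#' @return signed `ff_estimate`.
#' @export
estimate_ff_type4 <- function(counts, panel,
                              subtype = c("T4_ALPHA", "T4_BETA"),
                              config = signature_config()) {
  subtype <- match.arg(subtype)
  pr <- .prep_counts(counts, panel, config)
  v <- .per_snp_values(pr$freqs, panel, pr$usable)
  .estimate(if (subtype == "T4_ALPHA") v$t4_alpha else v$t4_beta)
}

#' Sequencing background from Type-2 SNPs
#'
#' Mean frequency of the second most frequent allele at SNPs where both
#' parents are homozygous for the same allele.  `doubled = TRUE` puts the
#' background on the FF scale of the Type-1/Type-3 estimators (which double
#' a frequency).
#'
#' @inheritParams estimate_ff_type1
#' @param doubled report on the doubled (FF) scale.
#' @return `ff_estimate`.
#' @export
estimate_background <- function(counts, panel, doubled = FALSE,
                                config = signature_config()) {
  pr <- .prep_counts(counts, panel, config)
  v <- .per_snp_values(pr$freqs, panel, pr$usable)$bkg
  .estimate(if (doubled) 2 * v else v)
}

#' Fetal sex and FF from Y-chromosome loci
#'
#' A male fetus contributes one Y copy against two copies per genome at
#' X/autosomal loci, so `FF_Y = 2 * mean(Y depth) / reference depth`.
#'
#' @inheritParams estimate_ff_type1
#' @param reference_depth mean molecular depth over non-Y loci; computed
#'   from `counts` when `NULL`.
#' @return list with `sex` (`"male"`/`"female"`), `mean_y_depth`,
#'   `reference_depth` and `ff_y` (an `ff_estimate`; unavailable for a
#'   female call).
#' @export
estimate_ff_y <- function(counts, panel, reference_depth = NULL,
                          config = signature_config()) {
  pr <- .prep_counts(counts, panel, config)
  yi <- which(panel$is_y)
  if (!length(yi)) stop("panel has no Y loci", call. = FALSE)
  if (is.null(reference_depth)) {
    rd <- pr$depth[!panel$is_y & pr$depth > 0]
    if (!length(rd)) stop("no covered non-Y loci for reference depth", call. = FALSE)
    reference_depth <- mean(rd)
  }
  ydep <- pr$depth[yi]
  male <- mean(ydep) > config$y_call_threshold * reference_depth
  list(sex = if (male) "male" else "female",
       mean_y_depth = mean(ydep),
       reference_depth = reference_depth,
       ff_y = if (male) .estimate(2 * ydep / reference_depth) else .estimate(numeric(0)))
}

# Assemble a signature from precomputed per-SNP values (shared between the
# count-based path and the exact oracle path).
#' @keywords internal
.assemble_signature <- function(vals, panel, config, ysex = NULL,
                                excluded = NULL, flags = character(0)) {
  sig <- list(
    t1 = .estimate(vals$t1),
    t3_p1 = .estimate(vals$t3_p1),
    t3_p2 = .estimate(vals$t3_p2),
    t4_alpha = .estimate(vals$t4_alpha),
    t4_beta = .estimate(vals$t4_beta),
    bkg = .estimate(vals$bkg),
    bkg_ff = .estimate(2 * vals$bkg),
    sex = if (is.null(ysex)) NA_character_ else ysex$sex,
    ff_y = if (is.null(ysex)) .estimate(numeric(0)) else ysex$ff_y,
    xxy_suspect = FALSE,
    class_counts = class_counts(panel),
    excluded = if (is.null(excluded))
      data.frame(snp_id = character(0), reason = character(0)) else excluded,
    flags = flags,
    config = config)
  for (k in c("t1", "t3_p1", "t3_p2", "t4_alpha", "t4_beta", "bkg"))
    if (!sig[[k]]$available)
      sig$flags <- c(sig$flags, paste0("no_usable_snps_", k))
  if (identical(sig$sex, "male") &&
      any(c(sig$t3_p1$value, sig$t3_p2$value) > config$xxy_t3_min,
          na.rm = TRUE)) {
    sig$xxy_suspect <- TRUE
    sig$flags <- c(sig$flags, "xxy_pattern_paternal_X_with_Y")
  }
  # orientation self-check: both Type-4 subtypes strongly same-signed points
  # at a maternal-side dosage anomaly (or a flipped M1/M2 convention)
  a <- sig$t4_alpha$value; b <- sig$t4_beta$value
  if (is.finite(a) && is.finite(b) && sign(a) == sign(b) &&
      min(abs(a), abs(b)) > 0.02)
    sig$flags <- c(sig$flags, "t4_subtypes_same_sign")
  structure(sig, class = "ff_signature")
}

#' Compute the fetal-fraction signature of a sample
#'
#' Runs every per-type estimator on one allele-count table: Type-1 FF, both
#' Type-3 subtypes, both signed Type-4 subtypes, Type-2 background (raw and
#' doubled), and -- when the panel carries Y loci -- fetal sex and FF_Y.
#' The resulting pattern is the per-sample QC object: each chromosomal
#' anomaly distorts it in a characteristic way.
#'
#' @inheritParams estimate_ff_type1
#' @return `ff_signature`: list of `ff_estimate`s (`t1`, `t3_p1`, `t3_p2`,
#'   `t4_alpha`, `t4_beta`, `bkg`, `bkg_ff`, `ff_y`), `sex`, `xxy_suspect`,
#'   per-class SNP counts, excluded-SNP log and flags.
#' @export
compute_signature <- function(counts, panel, config = signature_config()) {
  pr <- .prep_counts(counts, panel, config)
  vals <- .per_snp_values(pr$freqs, panel, pr$usable)
  ysex <- if (any(panel$is_y)) {
    rd <- pr$depth[!panel$is_y & pr$depth > 0]
    if (length(rd)) estimate_ff_y(pr$counts, panel, mean(rd), config) else NULL
  } else NULL
  flags <- character(0)
  if (length(pr$extra))
    flags <- c(flags, sprintf("counts_not_in_panel:%d", length(pr$extra)))
  .assemble_signature(vals, panel, config, ysex, pr$excluded, flags)
}

#' @export
print.ff_signature <- function(x, ...) {
  fmt <- function(e, lab) {
    if (!e$available) cat(sprintf("  %-10s unavailable\n", lab))
    else cat(sprintf("  %-10s %+8.4f  (avg dev %.4f, n = %d)\n",
                     lab, e$value, e$dispersion, e$n_snps))
  }
  cat("Fetal-fraction signature\n")
  fmt(x$t1, "T1"); fmt(x$t3_p1, "T3 P1"); fmt(x$t3_p2, "T3 P2")
  fmt(x$t4_alpha, "T4 alpha"); fmt(x$t4_beta, "T4 beta")
  fmt(x$bkg, "Bkg"); fmt(x$bkg_ff, "Bkg (x2)")
  if (!is.na(x$sex)) {
    cat(sprintf("  sex call: %s", x$sex))
    if (x$ff_y$available) cat(sprintf("  (FF_Y = %.4f)", x$ff_y$value))
    cat("\n")
  }
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}
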