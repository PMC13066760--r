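#' @keywords internal
.check_allele <- function(a, what = "allele") {
  if (length(a) != 1L || is.na(a) || !a %in% .BASES)
    stop(sprintf("invalid %s: '%s' (must be one of A, C, G, T)",
                 what, paste(a, collapse = "/")), call. = FALSE)
  invisible(a)
}

#' Classify a SNP from phased parental genotypes
#'
#' SNPs are typed by the equality structure of the four phased parental
#' alleles, following the five-type scheme used in RHDO panels:
#' \describe{
#'   \item{T1}{both parents homozygous, for different alleles.  The fetus is
#'     an obligate heterozygote; the paternal-allele frequency in plasma
#'     measures fetal fraction.}
#'   \item{T2}{both parents homozygous for the same allele; used to measure
#'     sequencing background.}
#'   \item{T3}{father heterozygous, mother homozygous; identifies the
#'     transmitted paternal haplotype.  Subtype `T3_P1` / `T3_P2` names the
#'     paternal haplotype carrying the allele absent in the mother.}
#'   \item{T4}{mother heterozygous, father homozygous; the backbone of RHDO.
#'     Subtype `T4_ALPHA` when the father's allele equals the allele on
#'     maternal haplotype M1, `T4_BETA` when it equals the M2 allele.}
#'   \item{T5}{both parents heterozygous (useful for consanguineous couples;
#'     classified but not used by the estimators here).}
#' }
#'
#' Corner cases under the pure equality-structure rule: at a T3 site where
#' both paternal alleles are absent from the mother (e.g. mother A/A, father
#' G/T), subtype is assigned by P1-precedence; at a T4 site where the
#' father's allele matches neither maternal allele, subtype is `NONE` and the
#' SNP is excluded from alpha/beta estimation.
#'
#' @param maternal_hap length-2 character vector `(M1, M2)` of the mother's
#'   phased alleles.
#' @param paternal_hap length-2 character vector `(P1, P2)`.
#' @return an object of class `snp_class`: list with `snp_type` (`"T1"` ..
#'   `"T5"`), `subtype` (`"NONE"`, `"T3_P1"`, `"T3_P2"`, `"T4_ALPHA"`,
#'   `"T4_BETA"`), `paternal_specific_allele` (T3), `m1_allele`/`m2_allele`
#'   (T4).
#' @examples
#' classify_snp(c("A", "A"), c("G", "G"))$snp_type   # "T1"
#' classify_snp(c("A", "G"), c("A", "A"))$subtype    # "T4_ALPHA"
#' @export
classify_snp <- function(maternal_hap, paternal_hap) {
  if (length(maternal_hap) != 2L || length(paternal_hap) != 2L)
    stop("maternal_hap and paternal_hap must each hold two alleles",
         call. = FALSE)
  m1 <- toupper(as.character(maternal_hap[[1L]]))
  m2 <- toupper(as.character(maternal_hap[[2L]]))
  p1 <- toupper(as.character(paternal_hap[[1L]]))
  p2 <- toupper(as.character(paternal_hap[[2L]]))
  .check_allele(m1, "maternal allele M1"); .check_allele(m2, "maternal allele M2")
  .check_allele(p1, "paternal allele P1"); .check_allele(p2, "paternal allele P2")

  cls <- list(snp_type = NA_character_, subtype = "NONE",
              paternal_specific_allele = NA_character_,
              m1_allele = NA_character_, m2_allele = NA_character_)
  mom_hom <- m1 == m2
  dad_hom <- p1 == p2
  if (mom_hom && dad_hom) {
    cls$snp_type <- if (m1 == p1) "T2" else "T1"
  } else if (mom_hom) {               # father heterozygous, mother homozygous
    cls$snp_type <- "T3"
    if (p1 != m1) {
      cls$subtype <- "T3_P1"; cls$paternal_specific_allele <- p1
    } else {
      cls$subtype <- "T3_P2"; cls$paternal_specific_allele <- p2
    }
  } else if (dad_hom) {               # mother heterozygous, father homozygous
    cls$snp_type <- "T4"
    cls$m1_allele <- m1; cls$m2_allele <- m2
    if (p1 == m1) cls$subtype <- "T4_ALPHA"
    else if (p1 == m2) cls$subtype <- "T4_BETA"
  } else {
    cls$snp_type <- "T5"
  }
  structure(cls, class = "snp_class")
}

#' Build a SNP panel with per-locus classification
#'
#' @param loci data.frame with columns `snp_id`, `chrom`, `pos` (1-based),
#'   `M1`, `M2`, `P1`, `P2` and optionally `is_y` (logical/0-1).  Y loci are
#'   presence/absence markers: their marker allele is stored in `P1` (the Y
#'   chromosome is paternal) and `M1`, `M2`, `P2` may be `NA`.
#' @return `ff_panel`: the input data.frame augmented with `class`
#'   (`"T1"`..`"T5"` or `"Y"`), `subtype`, `pat_allele` (paternal allele
#'   used by the T1/T3 estimators), `m1_allele`, `m2_allele`.
#' @export
build_panel <- function(loci) {
  if (!is.data.frame(loci) || nrow(loci) == 0L)
    stop("loci must be a non-empty data.frame", call. = FALSE)
  need <- c("snp_id", "chrom", "pos", "M1", "M2", "P1", "P2")
  miss <- setdiff(need, names(loci))
  if (length(miss))
    stop("loci is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  loci <- as.data.frame(loci, stringsAsFactors = FALSE)
  if (!"is_y" %in% names(loci)) loci$is_y <- FALSE
  loci$is_y <- as.logical(loci$is_y)
  loci$snp_id <- as.character(loci$snp_id)
  if (anyDuplicated(loci$snp_id))
    stop("duplicate snp_id in panel: ",
         paste(unique(loci$snp_id[duplicated(loci$snp_id)]), collapse = ", "),
         call. = FALSE)
  for (col in c("M1", "M2", "P1", "P2"))
    loci[[col]] <- toupper(as.character(loci[[col]]))

  n <- nrow(loci)
  loci$class <- NA_character_
  loci$subtype <- "NONE"
  loci$pat_allele <- NA_character_
  loci$m1_allele <- NA_character_
  loci$m2_allele <- NA_character_
  for (i in seq_len(n)) {
    if (loci$is_y[i]) {
      .check_allele(loci$P1[i], sprintf("Y marker allele (locus %s)", loci$snp_id[i]))
      loci$class[i] <- "Y"
      next
    }
    cl <- classify_snp(c(loci$M1[i], loci$M2[i]), c(loci$P1[i], loci$P2[i]))
    loci$class[i] <- cl$snp_type
    loci$subtype[i] <- cl$subtype
    loci$m1_allele[i] <- cl$m1_allele
    loci$m2_allele[i] <- cl$m2_allele
    loci$pat_allele[i] <- switch(cl$snp_type,
                                 T1 = loci$P1[i],
                                 T3 = cl$paternal_specific_allele,
                                 NA_character_)
  }
  rownames(loci) <- NULL
  class(loci) <- c("ff_panel", "data.frame")
  loci
}

#' Count SNPs per class/subtype in a panel
#'
#' @param panel an `ff_panel`.
#' @return named integer vector over T1, T2, T3_P1, T3_P2, T4_ALPHA,
#'   T4_BETA, T4_NONE, T5, Y (zero for absent classes).
#' @export
class_counts <- function(panel) {
  stopifnot(inherits(panel, "ff_panel"))
  lab <- ifelse(panel$class %in% c("T3", "T4"),
                ifelse(panel$subtype == "NONE", paste0(panel$class, "_NONE"),
                       panel$subtype),
                panel$class)
  lev <- c("T1", "T2", "T3_P1", "T3_P2", "T3_NONE",
           "T4_ALPHA", "T4_BETA", "T4_NONE", "T5", "Y")
  out <- table(factor(lab, levels = lev))
  v <- as.integer(out)
  names(v) <- lev
  v[setdiff(lev, "T3_NONE")]  # T3 always has a subtype
}

#' @export
print.ff_panel <- function(x, ...) {
  cc <- class_counts(x)
  cat(sprintf("ff_panel: %d loci (%d on Y)\n", nrow(x), sum(x$is_y)))
  print(cc[cc > 0])
  invisible(x)
}
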