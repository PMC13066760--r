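#' Construct an allele-count table
#'
#' @param x matrix or data.frame of non-negative integer consensus-read
#'   counts with one row per SNP and columns `A`, `C`, `G`, `T`; row names
#'   (or a `snp_id` column) identify loci.
#' @return `ff_counts`: numeric matrix with columns A,C,G,T and snp_id row
#'   names.
#' @export
allele_count_table <- function(x) {
  if (is.data.frame(x)) {
    if ("snp_id" %in% names(x)) {
      rn <- as.character(x$snp_id)
      x <- x[, setdiff(names(x), "snp_id"), drop = FALSE]
      rownames(x) <- rn
    }
    x <- as.matrix(x)
  }
  if (!all(.BASES %in% colnames(x)))
    stop("count table must have columns A, C, G, T", call. = FALSE)
  x <- x[, .BASES, drop = FALSE]
  storage.mode(x) <- "double"
  if (is.null(rownames(x)))
    stop("count table must carry snp_id row names", call. = FALSE)
  if (anyNA(x) || any(x < 0))
    stop("counts must be non-negative and non-missing", call. = FALSE)
  structure(x, class = c("ff_counts", class(x)))
}

#' Allele frequencies at one SNP
#'
#' @param counts named numeric vector of per-allele counts (any subset of
#'   A,C,G,T), or a single row of an `ff_counts` matrix.
#' @return named fractions over A,C,G,T summing to 1.
#' @export
allele_frequencies <- function(counts) {
  v <- setNames(numeric(4L), .BASES)
  if (is.null(names(counts)))
    stop("counts must be named by allele", call. = FALSE)
  if (!all(names(counts) %in% .BASES))
    stop("unknown allele name(s): ",
         paste(setdiff(names(counts), .BASES), collapse = ", "), call. = FALSE)
  v[names(counts)] <- as.numeric(counts)
  if (any(v < 0)) stop("counts must be non-negative", call. = FALSE)
  d <- sum(v)
  if (d <= 0) stop("zero depth: no reads at this SNP", call. = FALSE)
  v / d
}

# Align a count table onto a panel: returns an n_panel x 4 matrix (zero rows
# for SNPs absent from the table) plus bookkeeping of mismatches.
#' @keywords internal
.align_counts <- function(counts, panel) {
  counts <- allele_count_table(unclass(counts))
  m <- matrix(0, nrow(panel), 4L,
              dimnames = list(panel$snp_id, .BASES))
  common <- intersect(panel$snp_id, rownames(counts))
  m[common, ] <- counts[common, , drop = FALSE]
  list(counts = m,
       missing = setdiff(panel$snp_id, rownames(counts)),
       extra = setdiff(rownames(counts), panel$snp_id))
}

# Shared pre-processing for the estimators: frequencies, usability mask and
# the genotype-consistency filter (unexpected allele above threshold).
#' @keywords internal
.prep_counts <- function(counts, panel, config = signature_config()) {
  stopifnot(inherits(panel, "ff_panel"))
  al <- .align_counts(counts, panel)
  cm <- al$counts
  depth <- rowSums(cm)
  n <- nrow(panel)
  freqs <- cm / ifelse(depth > 0, depth, NA_real_)

  # expected alleles per locus: parental alleles (marker allele for Y loci)
  expected <- matrix(FALSE, n, 4L, dimnames = dimnames(cm))
  for (tag in c("M1", "M2", "P1", "P2")) {
    a <- panel[[tag]]
    ok <- which(!is.na(a) & (!panel$is_y | tag == "P1"))
    expected[cbind(ok, match(a[ok], .BASES))] <- TRUE
  }
  unexp <- freqs
  unexp[expected] <- 0
  max_unexp <- apply(unexp, 1L, function(v) if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE))
  inconsistent <- !is.na(max_unexp) & max_unexp > config$max_unexpected_freq

  usable <- !panel$is_y & depth > 0 & !inconsistent
  reasons <- character(0); ids <- character(0)
  if (length(al$missing)) { ids <- al$missing; reasons <- rep("missing_from_counts", length(al$missing)) }
  zd <- panel$snp_id[!panel$is_y & depth == 0 & !panel$snp_id %in% al$missing]
  ids <- c(ids, zd); reasons <- c(reasons, rep("zero_depth", length(zd)))
  inc <- panel$snp_id[inconsistent]
  ids <- c(ids, inc); reasons <- c(reasons, rep("unexpected_allele", length(inc)))

  list(counts = cm, depth = depth, freqs = freqs, usable = usable,
       excluded = data.frame(snp_id = ids, reason = reasons,
                             stringsAsFactors = FALSE),
       extra = al$extra)
}
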