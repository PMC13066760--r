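# Exact mixture-model oracle: plasma as a weighted mixture of contributors,
# each carrying a multiset of chromosome copies tagged by haplotype origin.
# Weights are diploid-genome mass fractions, so each copy weighs weight/2 at
# the target locus; a trisomic clone therefore contributes 1.5x its weight,
# which is what makes abnormal FF relations "approximately" (not exactly)
# simple ratios of the Type-1 value.

.SCENARIO_KINDS <- c("NORMAL",
                     "TRI_MAT_MEI1", "TRI_MAT_MEI2",
                     "TRI_PAT_MEI1", "TRI_PAT_MEI2",
                     "MONOSOMY_MAT", "MONOSOMY_PAT",
                     "UPD_MAT_ISO", "UPD_MAT_HETERO",
                     "UPD_PAT_ISO", "UPD_PAT_HETERO",
                     "TWINS_DIZYGOTIC", "MALE_FETUS_X", "XXY")

# kinds that admit a mosaic fraction (abnormal clone share of fetal mass)
.MOSAIC_KINDS <- setdiff(.SCENARIO_KINDS,
                         c("NORMAL", "TWINS_DIZYGOTIC", "MALE_FETUS_X"))

#' Scenario kinds known to the oracle
#' @return character vector of kind names.
#' @export
scenario_kinds <- function() .SCENARIO_KINDS

#' @keywords internal
.other_mat <- function(h) if (h == "M1") "M2" else "M1"
#' @keywords internal
.other_pat <- function(h) if (h == "P1") "P2" else "P1"

#' Define a plasma scenario
#'
#' A scenario fixes what the fetal compartment of plasma looks like: the
#' anomaly kind, fetal fraction `f` (fetal share of total cell-free DNA
#' mass), mosaic fraction `m` (abnormal clone's share of the *fetal* mass,
#' for aneuploidy/UPD kinds), the transmitted haplotypes, and for dizygotic
#' twins the mass split between twins.
#'
#' @param kind one of [scenario_kinds()].
#' @param f fetal fraction in `[0, 1)`; `f = 0` is the no-fetal-DNA edge
#'   case.
#' @param m mosaic fraction in `[0, 1]`; only meaningful (and only accepted)
#'   for trisomy/monosomy/UPD/XXY kinds, where it defaults to 1
#'   (homogeneous).
#' @param mat_hap,pat_hap transmitted maternal/paternal haplotype of the
#'   (euploid or reference) fetal line.
#' @param twin_split twin 1's share of fetal mass (dizygotic twins only).
#' @param twin2_mat,twin2_pat haplotypes of twin 2; default discordant on
#'   both sides.
#' @return `ff_scenario` list.
#' @export
scenario <- function(kind, f = 0.10, m = NULL,
                     mat_hap = "M1", pat_hap = "P1",
                     twin_split = NULL, twin2_mat = NULL, twin2_pat = NULL) {
  kind <- match.arg(kind, .SCENARIO_KINDS)
  stopifnot(is.numeric(f), length(f) == 1L, f >= 0, f < 1)
  stopifnot(mat_hap %in% c("M1", "M2"), pat_hap %in% c("P1", "P2"))
  if (kind %in% .MOSAIC_KINDS) {
    if (is.null(m)) m <- 1
    stopifnot(is.numeric(m), length(m) == 1L, m >= 0, m <= 1)
  } else if (!is.null(m)) {
    stop("mosaic fraction m is only defined for aneuploidy/UPD kinds, not ",
         kind, call. = FALSE)
  }
  if (kind == "TWINS_DIZYGOTIC") {
    if (is.null(twin_split)) twin_split <- 0.5
    stopifnot(twin_split > 0, twin_split < 1)
    if (is.null(twin2_mat)) twin2_mat <- .other_mat(mat_hap)
    if (is.null(twin2_pat)) twin2_pat <- .other_pat(pat_hap)
    stopifnot(twin2_mat %in% c("M1", "M2"), twin2_pat %in% c("P1", "P2"))
  } else if (!is.null(twin_split) || !is.null(twin2_mat) || !is.null(twin2_pat)) {
    stop("twin parameters are only defined for TWINS_DIZYGOTIC", call. = FALSE)
  }
  structure(list(kind = kind, f = f, m = m, mat_hap = mat_hap,
                 pat_hap = pat_hap, twin_split = twin_split,
                 twin2_mat = twin2_mat, twin2_pat = twin2_pat),
            class = "ff_scenario")
}

#' @export
print.ff_scenario <- function(x, ...) {
  cat(sprintf("scenario %s: f = %.3f", x$kind, x$f))
  if (!is.null(x$m)) cat(sprintf(", m = %.3f", x$m))
  cat(sprintf(", transmitted %s/%s", x$mat_hap, x$pat_hap))
  if (!is.null(x$twin_split))
    cat(sprintf(", twin split %.2f (twin2 %s/%s)",
                x$twin_split, x$twin2_mat, x$twin2_pat))
  cat("\n")
  invisible(x)
}

#' @keywords internal
.contributor <- function(label, weight, copies)
  list(label = label, weight = weight, copies = copies)

#' Contributor mixture for a scenario
#'
#' The mother always contributes weight `1 - f` with copies `{M1, M2}`.  The
#' fetal compartment is one clone (weight `f`), an abnormal/normal clone
#' pair (`m*f` and `(1-m)*f`) or two twins (`f*split`, `f*(1-split)`).  Copy
#' multisets per kind: e.g. a maternal meiosis-I trisomy clone carries
#' `{M1, M2, pat}` (both maternal homologs), a meiosis-II clone
#' `{mat, mat, pat}`, paternal heterodisomy `{P1, P2}`, maternal monosomy
#' `{mat}`, a male fetus `{mat, Y}`, 47,XXY `{mat, pat, Y}`.  A `Y` copy
#' carries mass only at Y loci.
#'
#' @param sc an `ff_scenario`.
#' @return `ff_contributors`: list of `(label, weight, copies)` with the
#'   scenario attached as attribute `scenario`; weights sum to 1.
#' @export
contributors_for_scenario <- function(sc) {
  stopifnot(inherits(sc, "ff_scenario"))
  f <- sc$f
  out <- list(.contributor("mother", 1 - f, c("M1", "M2")))
  normal_copies <- c(sc$mat_hap, sc$pat_hap)
  if (sc$kind == "TWINS_DIZYGOTIC") {
    out <- c(out, list(
      .contributor("twin1", f * sc$twin_split, normal_copies),
      .contributor("twin2", f * (1 - sc$twin_split),
                   c(sc$twin2_mat, sc$twin2_pat))))
  } else {
    ab <- switch(sc$kind,
      NORMAL        = normal_copies,
      TRI_MAT_MEI1  = c("M1", "M2", sc$pat_hap),
      TRI_MAT_MEI2  = c(sc$mat_hap, sc$mat_hap, sc$pat_hap),
      TRI_PAT_MEI1  = c(sc$mat_hap, "P1", "P2"),
      TRI_PAT_MEI2  = c(sc$mat_hap, sc$pat_hap, sc$pat_hap),
      MONOSOMY_MAT  = sc$mat_hap,
      MONOSOMY_PAT  = sc$pat_hap,
      UPD_MAT_ISO   = rep(sc$mat_hap, 2L),
      UPD_MAT_HETERO = c("M1", "M2"),
      UPD_PAT_ISO   = rep(sc$pat_hap, 2L),
      UPD_PAT_HETERO = c("P1", "P2"),
      MALE_FETUS_X  = c(sc$mat_hap, "Y"),
      XXY           = c(sc$mat_hap, sc$pat_hap, "Y"))
    m <- if (is.null(sc$m)) 1 else sc$m
    # the euploid counterpart of an XXY mosaic is the 46,XY line
    norm <- if (sc$kind == "XXY") c(sc$mat_hap, "Y") else normal_copies
    out <- c(out, list(.contributor("fetal_abnormal", m * f, ab),
                       .contributor("fetal_normal", (1 - m) * f, norm)))
  }
  out <- Filter(function(co) co$weight > 1e-15, out)
  stopifnot(abs(sum(vapply(out, `[[`, 0, "weight")) - 1) < 1e-12)
  structure(out, class = "ff_contributors", scenario = sc)
}

# Allele-mass matrix (n_loci x 4) of a contributor mixture on a panel.
# Per-copy mass is weight/2; M1/M2/P1/P2 tags act at non-Y loci via the
# panel's phased alleles, Y tags act at Y loci via the marker allele.
#' @keywords internal
.allele_mass <- function(contributors, panel) {
  n <- nrow(panel)
  mass <- matrix(0, n, 4L, dimnames = list(panel$snp_id, .BASES))
  is_y <- panel$is_y
  idx <- lapply(panel[c("M1", "M2", "P1", "P2")], match, table = .BASES)
  y_rows <- which(is_y)
  x_rows <- which(!is_y)
  for (co in contributors) {
    per_copy <- co$weight / 2
    tab <- table(co$copies)
    for (tag in names(tab)) {
      add <- per_copy * as.numeric(tab[[tag]])
      if (tag == "Y") {
        rows <- y_rows; cols <- idx$P1[y_rows]
      } else {
        rows <- x_rows; cols <- idx[[tag]][x_rows]
      }
      keep <- !is.na(cols)
      ij <- cbind(rows[keep], cols[keep])
      mass[ij] <- mass[ij] + add
    }
  }
  mass
}

#' Exact expected allele frequencies at one locus
#'
#' Linear mass balance: `freq(a)` is the summed per-copy mass of copies
#' carrying allele `a`, over the total mass at the locus.
#'
#' @param contributors `ff_contributors`.
#' @param locus a one-row `ff_panel` (or one row of one).
#' @return named fractions over A,C,G,T summing to 1.
#' @export
expected_allele_freqs <- function(contributors, locus) {
  stopifnot(inherits(contributors, "ff_contributors"))
  if (!inherits(locus, "ff_panel")) locus <- build_panel(locus)
  stopifnot(nrow(locus) == 1L)
  m <- .allele_mass(contributors, locus)[1L, ]
  tot <- sum(m)
  if (tot <= 0) stop("zero total mass at locus ", locus$snp_id, call. = FALSE)
  m / tot
}

# Canonical minimal panel: one locus per class/subtype plus one Y marker.
#' @keywords internal
.canonical_panel_env <- new.env(parent = emptyenv())
#' @keywords internal
.canonical_panel <- function() {
  if (is.null(.canonical_panel_env$panel)) {
    .canonical_panel_env$panel <- build_panel(data.frame(
      snp_id = c("c_t1", "c_t2", "c_t3p1", "c_t3p2", "c_t4a", "c_t4b",
                 "c_t5", "c_y"),
      chrom = c(rep("X", 7L), "Y"),
      pos = seq_len(8L) * 1000L,
      M1 = c("A", "A", "A", "A", "A", "A", "A", NA),
      M2 = c("A", "A", "A", "A", "G", "G", "G", NA),
      P1 = c("G", "A", "G", "A", "A", "G", "A", "T"),
      P2 = c("G", "A", "A", "G", "A", "G", "G", NA),
      is_y = c(rep(FALSE, 7L), TRUE),
      stringsAsFactors = FALSE))
  }
  .canonical_panel_env$panel
}

#' Noise-free expected signature of a scenario
#'
#' Applies the signature estimators to the oracle's exact allele
#' frequencies; dispersions are zero.  This is the reference pattern that
#' observed signatures are compared against.
#'
#' @param sc an `ff_scenario`.
#' @param panel optional `ff_panel`; defaults to a minimal canonical panel
#'   with one locus per class.
#' @return `ff_signature` with exact values and zero dispersions.
#' @export
expected_signature <- function(sc, panel = NULL) {
  stopifnot(inherits(sc, "ff_scenario"))
  if (is.null(panel)) panel <- .canonical_panel()
  contributors <- contributors_for_scenario(sc)
  mass <- .allele_mass(contributors, panel)
  totals <- rowSums(mass)
  freqs <- mass / ifelse(totals > 0, totals, NA_real_)
  usable <- !panel$is_y & totals > 0
  vals <- .per_snp_values(freqs, panel, usable)
  ysex <- NULL
  if (any(panel$is_y)) {
    y_mass <- mean(totals[panel$is_y])
    ref_mass <- mean(totals[!panel$is_y])
    male <- y_mass > 0
    ysex <- list(sex = if (male) "male" else "female",
                 mean_y_depth = y_mass, reference_depth = ref_mass,
                 ff_y = if (male) .estimate(2 * y_mass / ref_mass)
                        else .estimate(numeric(0)))
  }
  .assemble_signature(vals, panel, signature_config(min_snps = 1L), ysex)
}

#' Expected Type-4 vs Type-1 regression slopes for a scenario
#'
#' Under in-silico dilution both the signed Type-4 estimates and the Type-1
#' estimate scale linearly through the origin with the dilution proportion
#' (they share the per-locus mass denominator), so the expected slope is the
#' exact ratio of the undiluted expectations.  Closed-form examples: a
#' maternal meiosis-I trisomy in mosaic `m` with the euploid line carrying
#' M1 gives `slope_alpha = 1 - m/2`, `slope_beta = -m/2`.
#'
#' @param sc an `ff_scenario`.
#' @return list `slope_alpha`, `slope_beta`, `defined` (FALSE when the
#'   scenario has no Type-1 signal, e.g. maternal monosomy/UPD).
#' @export
expected_slopes <- function(sc) {
  sig <- expected_signature(sc)
  t1 <- sig$t1$value
  if (!is.finite(t1) || abs(t1) < 1e-12)
    return(list(slope_alpha = NA_real_, slope_beta = NA_real_,
                defined = FALSE))
  list(slope_alpha = sig$t4_alpha$value / t1,
       slope_beta = sig$t4_beta$value / t1,
       defined = TRUE)
}
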