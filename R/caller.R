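# QC calls from a signature (plus optional dilution regression): the
# mean +/- 1 SD alert rule, slope-based flags, grid-search scenario
# classification and mosaic-fraction estimation.

# The five signature components used for pattern comparison, their standard
# errors and inverse-variance weights.
#' @keywords internal
.sig_vec <- function(sig) {
  get <- function(e) if (e$available) e$value else 0
  c(t1 = get(sig$t1), t3_p1 = get(sig$t3_p1), t3_p2 = get(sig$t3_p2),
    t4_alpha = get(sig$t4_alpha), t4_beta = get(sig$t4_beta),
    ff_y = get(sig$ff_y))
}
#' @keywords internal
.sig_weights <- function(sig, eps = 1e-8) {
  w <- vapply(list(sig$t1, sig$t3_p1, sig$t3_p2, sig$t4_alpha, sig$t4_beta),
              function(e) {
                if (!e$available) return(0)
                se2 <- if (e$n_snps > 1L) e$sd^2 / e$n_snps else 0
                1 / (se2 + eps)
              }, 0)
  # FF_Y: absent Y loci carry no information; a female call (Y covered but
  # silent) is informative against male-fetus candidates
  wy <- if (is.na(sig$sex)) 0
        else if (sig$ff_y$available) {
          se2 <- if (sig$ff_y$n_snps > 1L) sig$ff_y$sd^2 / sig$ff_y$n_snps else 0
          1 / (se2 + eps)
        } else 1 / (1e-4 + eps)
  w <- c(w, wy)
  names(w) <- c("t1", "t3_p1", "t3_p2", "t4_alpha", "t4_beta", "ff_y")
  w
}

# Fast expected signature vector on the canonical panel (classification
# inner loop); same arithmetic as expected_signature(), fewer allocations.
#' @keywords internal
.expected_vec <- function(sc) {
  panel <- .canonical_panel()
  mass <- .allele_mass(contributors_for_scenario(sc), panel)
  tot <- rowSums(mass)
  fr <- mass / ifelse(tot > 0, tot, NA_real_)
  ffy <- if (tot[8L] > 0) 2 * tot[8L] / mean(tot[1:7]) else 0
  v <- c(t1 = 2 * fr[1L, 3L], t3_p1 = 2 * fr[3L, 3L], t3_p2 = 2 * fr[4L, 3L],
         t4_alpha = fr[5L, 1L] - fr[5L, 3L], t4_beta = fr[6L, 1L] - fr[6L, 3L],
         ff_y = ffy)
  v[!is.finite(v)] <- 0
  v
}

#' Mean +/- 1 SD alert rule
#'
#' Tentative automated screen: each Type-3/Type-4 subtype must conform to
#' one of two controls -- the Type-1 estimate (signal control) or the
#' doubled Type-2 background (null control).  Conformity means the subtype
#' mean lies within the control's mean +/- 1 SD band, slackened by twice the
#' subtype mean's standard error (the subtype mean is itself noisy; without
#' the slack the null band, a few reads wide, would flag every normal
#' sample).  Type-4 subtypes are compared in magnitude.  A consistent normal
#' pattern additionally requires that each parental side (the T3 pair, the
#' T4 pair) can be read as one signal and one null subtype.  A sample whose
#' Type-1 estimate itself sits in the background band is alerted as "no
#' fetal signal" (no fetal DNA, maternal heterodisomy, or a maternal-side
#' monosomy/isodisomy when T4 still shows signal) -- unless the Y loci call
#' a male fetus, whose X-locus signature legitimately looks like a maternal
#' monosomy with both T4 subtypes at FF_Y/2.
#'
#' @param sig an `ff_signature` (from [compute_signature()]).
#' @param min_snps minimum SNPs per subtype for a confident assessment;
#'   defaults to the signature's config.  Subtypes below it are reported
#'   `low_confidence` and withheld from the decision.
#' @return `ff_alert`: list `alert` (logical), `reasons`, `low_confidence`
#'   (subtypes withheld), `status` (per-subtype conformity data.frame).
#' @export
alert_from_signature <- function(sig, min_snps = NULL) {
  stopifnot(inherits(sig, "ff_signature"))
  if (is.null(min_snps)) min_snps <- sig$config$min_snps
  reasons <- character(0); lowconf <- character(0)

  t1 <- sig$t1; bkg <- sig$bkg_ff
  if (!t1$available || !bkg$available ||
      t1$n_snps < min_snps || bkg$n_snps < min_snps)
    return(structure(list(alert = NA, reasons = "controls_unavailable",
                          low_confidence = c("t1", "bkg")[c(t1$n_snps < min_snps,
                                                            bkg$n_snps < min_snps)],
                          status = NULL), class = "ff_alert"))
  se <- function(e) if (e$n_snps > 1L) e$sd / sqrt(e$n_snps) else 0
  null_hi <- bkg$value + bkg$sd
  sig_band <- c(t1$value - t1$sd, t1$value + t1$sd)
  male <- identical(sig$sex, "male")
  t1_quiet <- t1$value - 2 * se(t1) <= null_hi
  if (male && sig$ff_y$available) {
    # expected T4 magnitude for a 46,XY fetus on the X panel is FF_Y / 2
    c0 <- sig$ff_y$value / 2
    s0 <- max(sig$ff_y$sd / 2, sig$ff_y$dispersion / 2)
    sig_band_t4 <- c(c0 - s0, c0 + s0)
  } else sig_band_t4 <- sig_band

  subtypes <- list(t3_p1 = sig$t3_p1, t3_p2 = sig$t3_p2,
                   t4_alpha = sig$t4_alpha, t4_beta = sig$t4_beta)
  status <- data.frame(subtype = names(subtypes), n_snps = NA_integer_,
                       value = NA_real_, conforms = NA_character_,
                       stringsAsFactors = FALSE)
  conf <- list()
  for (i in seq_along(subtypes)) {
    e <- subtypes[[i]]; nm <- names(subtypes)[i]
    status$n_snps[i] <- e$n_snps
    if (!e$available || e$n_snps < min_snps) {
      lowconf <- c(lowconf, nm); status$conforms[i] <- "low_confidence"
      next
    }
    v <- abs(e$value); status$value[i] <- e$value
    slack <- 2 * se(e)
    band <- if (startsWith(nm, "t4")) sig_band_t4 else sig_band
    can_signal <- v >= band[1L] - slack & v <= band[2L] + slack
    can_null <- v - slack <= null_hi
    conf[[nm]] <- c(signal = can_signal, null = can_null)
    status$conforms[i] <- if (can_signal && can_null) "both"
                          else if (can_signal) "signal"
                          else if (can_null) "null" else "neither"
    if (!can_signal && !can_null)
      reasons <- c(reasons, sprintf("%s outside both controls (%.4f)", nm, e$value))
  }

  if (!male && t1_quiet) {
    others_quiet <- all(vapply(conf, function(x) x[["null"]], TRUE))
    reasons <- c(reasons, if (length(conf) && others_quiet)
      "no fetal signal: no fetal DNA or maternal heterodisomy"
      else "Type-1 silent with T3/T4 signal: maternal monosomy/isodisomy or male fetus pattern")
  }
  # per-side consistency: one signal + one null subtype per parental side
  side_ok <- function(a, b) {
    if (is.null(conf[[a]]) || is.null(conf[[b]])) return(TRUE)  # low conf
    (conf[[a]]["signal"] && conf[[b]]["null"]) ||
      (conf[[a]]["null"] && conf[[b]]["signal"])
  }
  if (!male && !t1_quiet) {
    if (!side_ok("t3_p1", "t3_p2") &&
        !any(grepl("t3_", reasons)))
      reasons <- c(reasons, "both paternal haplotypes detected (twins/heterodisomy pattern)")
    if (!side_ok("t4_alpha", "t4_beta") &&
        !any(grepl("t4_", reasons)))
      reasons <- c(reasons, "Type-4 subtypes inconsistent with single transmitted maternal haplotype")
  }
  if (male) {
    a <- sig$t4_alpha; b <- sig$t4_beta
    if (a$available && b$available && a$n_snps >= min_snps &&
        b$n_snps >= min_snps && sign(a$value) != sign(b$value) &&
        min(abs(a$value), abs(b$value)) > null_hi + 2 * max(se(a), se(b)))
      reasons <- c(reasons, "male fetus with opposite-signed Type-4 subtypes")
    if (sig$xxy_suspect)
      reasons <- c(reasons, "paternal X haplotype together with Y loci: possible 47,XXY")
  }
  structure(list(alert = length(reasons) > 0L, reasons = reasons,
                 low_confidence = lowconf, status = status),
            class = "ff_alert")
}

#' @export
print.ff_alert <- function(x, ...) {
  if (is.na(x$alert)) cat("alert withheld:", x$reasons, "\n")
  else if (x$alert) cat("ALERT:\n", paste(" -", x$reasons, collapse = "\n"), "\n")
  else cat("no alert (signature consistent with a normal pregnancy)\n")
  if (length(x$low_confidence))
    cat(" low confidence:", paste(x$low_confidence, collapse = ", "), "\n")
  invisible(x)
}

#' Flag abnormal regression slopes
#'
#' Normal means the slope pair is within tolerance (max absolute deviation)
#' of `(+1, 0)` (fetus inherited M1) or `(0, -1)` (M2).
#'
#' @param reg `ff_regression`.
#' @param tolerance maximum absolute slope deviation; default 0.15 separates
#'   normal-sample slope ranges from all derived abnormal slopes at mosaic
#'   fractions of 0.25 and above.
#' @return `ff_slope_flag`: list `flagged`, `normal`, `reasons`,
#'   `dist_m1`, `dist_m2`.
#' @export
slope_flags <- function(reg, tolerance = 0.15) {
  stopifnot(inherits(reg, "ff_regression"))
  if (reg$degenerate || !is.finite(reg$slope_alpha) || !is.finite(reg$slope_beta))
    return(structure(list(flagged = TRUE, normal = FALSE,
                          reasons = "slopes undefined (no Type-1 spread: no fetal DNA or maternal-side dosage anomaly)",
                          dist_m1 = NA_real_, dist_m2 = NA_real_),
                     class = "ff_slope_flag"))
  d1 <- max(abs(reg$slope_alpha - 1), abs(reg$slope_beta))
  d2 <- max(abs(reg$slope_alpha), abs(reg$slope_beta + 1))
  normal <- min(d1, d2) <= tolerance
  reasons <- if (normal) character(0) else
    sprintf("slopes (%+.3f, %+.3f) not within %.2f of (+1, 0) or (0, -1)",
            reg$slope_alpha, reg$slope_beta, tolerance)
  structure(list(flagged = !normal, normal = normal, reasons = reasons,
                 dist_m1 = d1, dist_m2 = d2), class = "ff_slope_flag")
}

#' @export
print.ff_slope_flag <- function(x, ...) {
  if (x$normal) cat("slopes normal\n") else cat("slopes FLAGGED:", x$reasons, "\n")
  invisible(x)
}

# enumerate candidate haplotype configurations per kind
#' @keywords internal
.candidate_configs <- function() {
  cfgs <- list()
  add <- function(kind, mat, pat, t2m = NA_character_, t2p = NA_character_)
    cfgs[[length(cfgs) + 1L]] <<- list(kind = kind, mat = mat, pat = pat,
                                       twin2_mat = t2m, twin2_pat = t2p)
  both_m <- c("M1", "M2"); both_p <- c("P1", "P2")
  for (mat in both_m) for (pat in both_p) {
    for (k in c("NORMAL", "TRI_MAT_MEI1", "TRI_MAT_MEI2", "TRI_PAT_MEI1",
                "TRI_PAT_MEI2", "MONOSOMY_MAT", "MONOSOMY_PAT",
                "UPD_MAT_ISO", "UPD_MAT_HETERO", "UPD_PAT_ISO",
                "UPD_PAT_HETERO", "XXY"))
      add(k, mat, pat)
    for (t2m in both_m) for (t2p in both_p)
      add("TWINS_DIZYGOTIC", mat, pat, t2m, t2p)
  }
  add("MALE_FETUS_X", "M1", "P1"); add("MALE_FETUS_X", "M2", "P1")
  cfgs
}

#' @keywords internal
.make_scenario <- function(cfg, f, m = NULL, split = NULL) {
  if (cfg$kind == "TWINS_DIZYGOTIC")
    scenario(cfg$kind, f = f, mat_hap = cfg$mat, pat_hap = cfg$pat,
             twin_split = split, twin2_mat = cfg$twin2_mat,
             twin2_pat = cfg$twin2_pat)
  else if (cfg$kind %in% .MOSAIC_KINDS)
    scenario(cfg$kind, f = f, m = if (is.null(m)) 1 else m,
             mat_hap = cfg$mat, pat_hap = cfg$pat)
  else
    scenario(cfg$kind, f = f, mat_hap = cfg$mat, pat_hap = cfg$pat)
}

#' Classify a signature against the scenario library
#'
#' Grid search over scenario kinds, transmitted-haplotype configurations,
#' mosaic fraction and fetal fraction (twin split for twins), scoring each
#' candidate by the inverse-variance-weighted squared difference between the
#' observed and oracle-expected signature (plus slope terms when a
#' regression is supplied), with local refinement of the best candidates.
#' Scenarios whose expected patterns coincide (monosomy vs isodisomy on the
#' same parental side; maternal heterodisomy vs no fetal DNA; concordant
#' twins vs singleton) come out tied and are reported as a set with the
#' recommended disambiguation, never silently collapsed.
#'
#' @param sig `ff_signature`.
#' @param reg optional `ff_regression`.
#' @param m_grid mosaic-fraction grid.
#' @param max_rank number of ranked fits returned.
#' @return `ff_fits`: ranked data.frame (kind, haplotypes, fitted `f`, `m`,
#'   `twin_split`, `distance`) with attributes `tied_set` (kinds
#'   indistinguishable from the best fit), `notes`, and `transmitted`
#'   (maternal haplotype call: M1, M2, AMBIGUOUS or NONE).
#' @export
classify_scenario <- function(sig, reg = NULL, m_grid = seq(0, 1, 0.05),
                              max_rank = 10L) {
  stopifnot(inherits(sig, "ff_signature"))
  obs <- .sig_vec(sig)
  w <- .sig_weights(sig)
  slopes_obs <- if (!is.null(reg) && !reg$degenerate &&
                    is.finite(reg$slope_alpha))
    c(reg$slope_alpha, reg$slope_beta) else NULL
  w_slope <- 1 / 0.03^2
  dist_fun <- function(sc) {
    d <- sum(w * (.expected_vec(sc) - obs)^2)
    if (!is.null(slopes_obs)) {
      es <- expected_slopes(sc)
      if (es$defined)
        d <- d + w_slope * ((es$slope_alpha - slopes_obs[1])^2 +
                              (es$slope_beta - slopes_obs[2])^2)
    }
    d
  }

  fhat <- max(abs(obs["t1"]), abs(obs["t4_alpha"]) + abs(obs["t4_beta"]),
              abs(obs["t3_p1"]) + abs(obs["t3_p2"]),
              if (sig$ff_y$available) sig$ff_y$value else 0, 0.01)
  f_grid <- unique(c(0, pmin(0.9, fhat * c(0.5, 0.7, 0.85, 1, 1.15, 1.4, 2))))
  split_grid <- seq(0.5, 0.9, 0.1)

  cfgs <- .candidate_configs()
  best <- vector("list", length(cfgs))
  for (ci in seq_along(cfgs)) {
    cfg <- cfgs[[ci]]
    b <- list(d = Inf, f = NA_real_, m = NA_real_, split = NA_real_)
    # a mosaic maternal heterodisomy is a rescaled normal: only m = 1 is a
    # distinct hypothesis
    ms <- if (cfg$kind == "UPD_MAT_HETERO") 1
          else if (cfg$kind %in% .MOSAIC_KINDS) m_grid else NA_real_
    sps <- if (cfg$kind == "TWINS_DIZYGOTIC") split_grid else NA_real_
    for (f in f_grid) for (m in ms) for (sp in sps) {
      d <- dist_fun(.make_scenario(cfg, f,
                                   if (is.na(m)) NULL else m,
                                   if (is.na(sp)) NULL else sp))
      if (d < b$d) b <- list(d = d, f = f, m = m, split = sp)
    }
    best[[ci]] <- b
  }

  # local refinement of the most promising configurations
  ord <- order(vapply(best, `[[`, 0, "d"))
  refine <- head(ord, 12L)
  for (ci in refine) {
    cfg <- cfgs[[ci]]; b <- best[[ci]]
    for (pass in 1:2) {
      of <- optimize(function(f) dist_fun(.make_scenario(cfg, f,
              if (is.na(b$m)) NULL else b$m,
              if (is.na(b$split)) NULL else b$split)),
            interval = c(0, min(0.95, max(0.05, 2.5 * fhat))), tol = 1e-9)
      if (of$objective < b$d) { b$d <- of$objective; b$f <- of$minimum }
      if (!is.na(b$m) && cfg$kind != "UPD_MAT_HETERO") {
        om <- optimize(function(m) dist_fun(.make_scenario(cfg, b$f, m)),
                       interval = c(0, 1), tol = 1e-9)
        if (om$objective < b$d) { b$d <- om$objective; b$m <- om$minimum }
      }
      if (!is.na(b$split)) {
        os <- optimize(function(sp) dist_fun(.make_scenario(cfg, b$f, NULL, sp)),
                       interval = c(0.05, 0.95), tol = 1e-9)
        if (os$objective < b$d) { b$d <- os$objective; b$split <- os$minimum }
      }
    }
    best[[ci]] <- b
  }

  fits <- data.frame(
    kind = vapply(cfgs, `[[`, "", "kind"),
    mat_hap = vapply(cfgs, `[[`, "", "mat"),
    pat_hap = vapply(cfgs, `[[`, "", "pat"),
    twin2_mat = vapply(cfgs, `[[`, "", "twin2_mat"),
    twin2_pat = vapply(cfgs, `[[`, "", "twin2_pat"),
    f = vapply(best, `[[`, 0, "f"),
    m = vapply(best, `[[`, 0, "m"),
    twin_split = vapply(best, `[[`, 0, "split"),
    distance = vapply(best, `[[`, 0, "d"),
    stringsAsFactors = FALSE)
  fits <- fits[order(fits$distance), ]
  rownames(fits) <- NULL
  if (!any(is.finite(fits$distance)))
    stop("unclassifiable signature: no finite-distance fit", call. = FALSE)

  # degenerate limits: every scenario is "pure maternal" at f = 0, every
  # mosaic kind is its euploid counterpart at m = 0, and concordant twins
  # are a singleton -- such fits assert normality (or absence of fetal DNA),
  # not the anomaly, and are relabeled accordingly (generator kind kept in
  # kind_fitted)
  fits$kind_fitted <- fits$kind
  low_m <- !is.na(fits$m) & fits$m < 0.025
  fits$kind[low_m & fits$kind == "XXY"] <- "MALE_FETUS_X"
  fits$kind[low_m & fits$kind_fitted != "XXY"] <- "NORMAL"
  concordant <- fits$kind == "TWINS_DIZYGOTIC" &
    fits$twin2_mat == fits$mat_hap & fits$twin2_pat == fits$pat_hap
  fits$kind[concordant %in% TRUE] <- "NORMAL"
  low_f <- fits$f < 0.005 & fits$kind_fitted != "UPD_MAT_HETERO"
  fits$kind[low_f] <- "NO_FETAL_DNA"

  d0 <- fits$distance[1L]
  tie_tol <- max(1e-6, 0.1 * d0)
  tied <- fits[fits$distance <= d0 + tie_tol, , drop = FALSE]
  tied_set <- unique(tied$kind)
  notes <- character(0)
  if ("TRI_MAT_MEI1" %in% tied_set &&
      any(c("MONOSOMY_PAT", "UPD_PAT_ISO", "TWINS_DIZYGOTIC") %in% tied_set))
    notes <- c(notes, paste("homogeneous maternal meiosis-I trisomy,",
      "homogeneous paternal monosomy, paternal isodisomy and 50:50",
      "maternally-discordant twins share one signature shape at different",
      "effective FFs; the true FF from other chromosomes resolves them"))
  if ("NORMAL" %in% tied_set)
    notes <- c(notes, paste("a normal signature cannot exclude fully",
      "concordant (or monozygotic) twins; RHDO results then apply to both twins"))
  if (all(c("MONOSOMY_MAT", "UPD_MAT_ISO") %in% tied_set) ||
      all(c("MONOSOMY_PAT", "UPD_PAT_ISO") %in% tied_set))
    notes <- c(notes, paste("monosomy and uniparental isodisomy are",
      "indistinguishable on this chromosome; measure FF with SNPs located",
      "on other chromosomes (monosomy shows half the true FF, isodisomy matches it)"))
  if (all(c("UPD_MAT_HETERO", "NO_FETAL_DNA") %in% tied_set))
    notes <- c(notes, paste("maternal heterodisomy cannot be distinguished",
      "from absence of fetal DNA; verify FF with Type-1 SNPs on other chromosomes"))
  if ("TWINS_DIZYGOTIC" %in% tied_set && "NORMAL" %in% tied_set)
    notes <- c(notes, paste("fully concordant twins are indistinguishable",
      "from a singleton at this locus; SNPs on other chromosomes may reveal",
      "dizygotic twins"))

  out <- head(fits, max_rank)
  attr(out, "tied_set") <- tied_set
  attr(out, "notes") <- notes
  attr(out, "transmitted") <- .transmitted_call(sig)
  class(out) <- c("ff_fits", "data.frame")
  out
}

#' @keywords internal
.transmitted_call <- function(sig) {
  b <- sig$bkg_ff
  signif_est <- function(e) {
    if (!e$available) return(NA)
    se <- if (e$n_snps > 1L) e$sd / sqrt(e$n_snps) else 0
    bse <- if (b$available && b$n_snps > 1L) b$sd / sqrt(b$n_snps) else 0
    bval <- if (b$available) b$value else 0
    abs(e$value) - 2 * se > bval + 2 * bse + 1e-9
  }
  a <- signif_est(sig$t4_alpha); bb <- signif_est(sig$t4_beta)
  if (is.na(a) || is.na(bb)) return("AMBIGUOUS")
  if (a && bb) "AMBIGUOUS" else if (a) "M1" else if (bb) "M2" else "NONE"
}

#' @export
print.ff_fits <- function(x, ...) {
  cat("scenario fits (ascending distance):\n")
  print.data.frame(head(x, 5L), digits = 4)
  cat("tied set:", paste(attr(x, "tied_set"), collapse = ", "), "\n")
  cat("transmitted maternal haplotype:", attr(x, "transmitted"), "\n")
  for (n in attr(x, "notes")) cat("note:", n, "\n")
  invisible(x)
}

#' Estimate the mosaic fraction for a fixed scenario kind
#'
#' Mosaic fraction `m` is the abnormal clone's share of fetal cell-free DNA
#' mass.  Closed forms exist for maternal trisomies: from a regression,
#' `m = 2 * min(|slope_alpha|, |slope_beta|)` for meiosis-I (the
#' orientation-free form of `-2 * slope_beta` when M1 was transmitted) and
#' `m = |slope_alpha| + |slope_beta| - 1` for meiosis-II; from a signature,
#' `m = 1 - |t4_alpha + t4_beta| / t1` (meiosis-I) and
#' `m = |t4_alpha + t4_beta| / t1 - 1` (meiosis-II) -- the exact
#' least-squares solutions under the mixture model, using both subtypes.
#' Other kinds are fitted numerically against the oracle.
#'
#' @param x an `ff_signature` or an `ff_regression`.
#' @param kind a mosaic-admitting scenario kind (trisomy/monosomy/UPD/XXY).
#' @return list `m` (clipped to `[0, 1]`), `method`, `note`.
#' @export
estimate_mosaic_fraction <- function(x, kind) {
  kind <- match.arg(kind, .MOSAIC_KINDS)
  clip <- function(v) min(1, max(0, v))
  if (inherits(x, "ff_regression")) {
    if (x$degenerate || !is.finite(x$slope_alpha))
      stop("slopes undefined; cannot estimate mosaic fraction from regression",
           call. = FALSE)
    sa <- x$slope_alpha; sb <- x$slope_beta
    if (kind == "TRI_MAT_MEI1")
      return(list(m = clip(2 * min(abs(sa), abs(sb))), method = "closed_form_slopes",
                  note = "m = 2*min(|slope_alpha|,|slope_beta|)"))
    if (kind == "TRI_MAT_MEI2")
      return(list(m = clip(abs(sa) + abs(sb) - 1), method = "closed_form_slopes",
                  note = "m = |slope_alpha|+|slope_beta|-1"))
    # numeric: slopes depend on m only (f cancels in the ratio)
    obj <- function(m, mat, pat) {
      es <- expected_slopes(scenario(kind, f = 0.1, m = m,
                                     mat_hap = mat, pat_hap = pat))
      if (!es$defined) return(Inf)
      (es$slope_alpha - sa)^2 + (es$slope_beta - sb)^2
    }
    best <- list(m = NA_real_, o = Inf)
    for (mat in c("M1", "M2")) for (pat in c("P1", "P2")) {
      if (!is.finite(obj(0.5, mat, pat))) next
      om <- optimize(obj, c(0, 1), mat = mat, pat = pat)
      if (om$objective < best$o) best <- list(m = om$minimum, o = om$objective)
    }
    if (!is.finite(best$o))
      stop("expected slopes undefined for kind ", kind, call. = FALSE)
    return(list(m = clip(best$m), method = "least_squares_slopes",
                note = "1-D fit of expected slopes"))
  }
  stopifnot(inherits(x, "ff_signature"))
  obs <- .sig_vec(x); w <- .sig_weights(x)
  t1 <- obs[["t1"]]; s4 <- obs[["t4_alpha"]] + obs[["t4_beta"]]
  if (kind == "TRI_MAT_MEI1" && abs(t1) > 1e-9)
    return(list(m = clip(1 - abs(s4) / t1), method = "closed_form_signature",
                note = "m = 1 - |t4_alpha + t4_beta| / t1"))
  if (kind == "TRI_MAT_MEI2" && abs(t1) > 1e-9)
    return(list(m = clip(abs(s4) / t1 - 1), method = "closed_form_signature",
                note = "m = |t4_alpha + t4_beta| / t1 - 1"))
  obj <- function(m, f, mat, pat)
    sum(w * (.expected_vec(scenario(kind, f = f, m = m,
                                    mat_hap = mat, pat_hap = pat)) - obs)^2)
  fhat <- max(abs(t1), abs(obs[["t4_alpha"]]) + abs(obs[["t4_beta"]]), 0.01)
  best <- list(m = NA_real_, o = Inf)
  for (mat in c("M1", "M2")) for (pat in c("P1", "P2")) {
    for (m0 in seq(0, 1, 0.1)) {
      of <- optimize(function(f) obj(m0, f, mat, pat),
                     c(0, min(0.95, 3 * fhat)))
      om <- optimize(function(m) obj(m, of$minimum, mat, pat), c(0, 1))
      if (om$objective < best$o) best <- list(m = om$minimum, o = om$objective)
    }
  }
  list(m = clip(best$m), method = "least_squares_signature",
       note = "2-D (f, m) fit of the expected signature")
}
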