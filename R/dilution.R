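# In-silico dilution: artificially lowering fetal fraction by mixing a
# plasma count table with the matched pure-maternal table, then regressing
# the signed Type-4 FF estimates on the Type-1 estimate across the ladder.

#' Dilute a plasma count table with a maternal count table
#'
#' Per SNP and allele, the mixed count is
#' `round(p * n_sample + (1 - p) * n_maternal * depth_sample / depth_maternal)`:
#' maternal counts are depth-rescaled per SNP so the mixing weight `p` acts
#' on allele *frequencies*.  Rounding is deterministic (half away from
#' zero); `mode = "stochastic"` instead resamples each SNP multinomially at
#' the sample's depth from the mixed frequencies (for noise studies).
#'
#' @param sample,maternal `ff_counts` tables covering the same SNPs (SNPs
#'   present in only one table are dropped with a warning).
#' @param p retained sample proportion in `[0, 1]`; `p = 1` returns the
#'   sample, `p = 0` reproduces maternal frequencies at sample depth.
#' @param mode `"deterministic"` (default) or `"stochastic"`.
#' @param seed seed for stochastic mode.
#' @return `ff_counts`.
#' @export
dilute_counts <- function(sample, maternal, p,
                          mode = c("deterministic", "stochastic"),
                          seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(p), length(p) == 1L, p >= 0, p <= 1)
  sample <- allele_count_table(unclass(sample))
  maternal <- allele_count_table(unclass(maternal))
  common <- intersect(rownames(sample), rownames(maternal))
  dropped <- length(union(rownames(sample), rownames(maternal))) - length(common)
  if (dropped > 0L)
    warning(dropped, " SNP(s) present in only one table were excluded")
  if (!length(common)) stop("no SNPs shared between the tables", call. = FALSE)
  s <- sample[common, , drop = FALSE]
  m <- maternal[common, , drop = FALSE]
  ds <- rowSums(s); dm <- rowSums(m)
  bad <- dm == 0 & ds > 0 & p < 1
  if (any(bad)) {
    warning(sum(bad), " SNP(s) with zero maternal depth were excluded")
    keep <- !bad
    s <- s[keep, , drop = FALSE]; m <- m[keep, , drop = FALSE]
    ds <- ds[keep]; dm <- dm[keep]
  }
  scale <- ifelse(dm > 0, ds / dm, 0)
  mixed <- p * s + (1 - p) * m * scale
  if (mode == "deterministic") {
    out <- trunc(mixed + 0.5 * sign(mixed))   # round half away from zero
  } else {
    out <- .with_seed(seed, {
      o <- mixed * 0
      for (i in which(ds > 0)) {
        pr <- mixed[i, ] / sum(mixed[i, ])
        o[i, ] <- rmultinom(1L, ds[i], pr)[, 1L]
      }
      o
    })
  }
  allele_count_table(out)
}

#' Dilution ladder and Type-4 vs Type-1 regression
#'
#' Computes the signature at each dilution proportion and fits ordinary
#' least squares of each signed Type-4 subtype estimate against the Type-1
#' estimate.  In a normal pregnancy the transmitted-side slope is +1 (M1,
#' alpha) or -1 (M2, beta) and the other slope is 0; dosage anomalies move
#' one or both slopes.  The through-origin slope is reported alongside the
#' free-intercept fit.
#'
#' @param sample,maternal `ff_counts` tables.
#' @param panel `ff_panel`.
#' @param proportions dilution ladder; at least 3 values in `(0, 1]`,
#'   used in decreasing order.  Default `{1, 0.8, 0.6, 0.4, 0.2}`.
#' @param config see [signature_config()].
#' @return `ff_regression`: `points` (data.frame `p`, `ff_t1`,
#'   `ff_t4_alpha`, `ff_t4_beta`), per-subtype `slope`, `intercept`, `r2`
#'   and `slope_origin`, plus a `degenerate` flag when the Type-1 values
#'   have no spread.
#' @export
regression_series <- function(sample, maternal, panel,
                              proportions = c(1, 0.8, 0.6, 0.4, 0.2),
                              config = signature_config()) {
  stopifnot(inherits(panel, "ff_panel"))
  proportions <- sort(unique(as.numeric(proportions)), decreasing = TRUE)
  if (length(proportions) < 3L)
    stop("at least 3 dilution proportions are required", call. = FALSE)
  if (any(proportions <= 0 | proportions > 1))
    stop("proportions must lie in (0, 1]", call. = FALSE)
  pts <- lapply(proportions, function(p) {
    sig <- compute_signature(dilute_counts(sample, maternal, p), panel, config)
    c(p = p, ff_t1 = sig$t1$value,
      ff_t4_alpha = sig$t4_alpha$value, ff_t4_beta = sig$t4_beta$value)
  })
  points <- as.data.frame(do.call(rbind, pts))
  if (anyNA(points))
    stop("signature unavailable at some dilution (missing T1 or T4 SNPs)",
         call. = FALSE)
  x <- points$ff_t1
  degenerate <- var(x) < 1e-18
  fit1 <- function(y) {
    if (degenerate)
      return(list(slope = NA_real_, intercept = NA_real_, r2 = NA_real_,
                  slope_origin = NA_real_))
    fm <- lm(y ~ x)
    rss <- sum(fm$residuals^2)
    tss <- sum((y - mean(y))^2)
    list(slope = unname(coef(fm)[2L]),
         intercept = unname(coef(fm)[1L]),
         r2 = if (tss > 1e-24) 1 - rss / tss else NA_real_,
         slope_origin = sum(x * y) / sum(x * x))
  }
  fa <- fit1(points$ff_t4_alpha)
  fb <- fit1(points$ff_t4_beta)
  structure(list(proportions = proportions, points = points,
                 slope_alpha = fa$slope, slope_beta = fb$slope,
                 intercept_alpha = fa$intercept, intercept_beta = fb$intercept,
                 r2_alpha = fa$r2, r2_beta = fb$r2,
                 slope_alpha_origin = fa$slope_origin,
                 slope_beta_origin = fb$slope_origin,
                 degenerate = degenerate),
            class = "ff_regression")
}

#' @export
print.ff_regression <- function(x, ...) {
  cat(sprintf("Type-4 vs Type-1 regression over %d dilutions\n",
              length(x$proportions)))
  if (x$degenerate) {
    cat("  degenerate: no spread in Type-1 values (no fetal signal?)\n")
  } else {
    cat(sprintf("  alpha: slope %+0.4f (origin %+0.4f), intercept %+0.5f, R2 %s\n",
                x$slope_alpha, x$slope_alpha_origin, x$intercept_alpha,
                format(x$r2_alpha, digits = 4)))
    cat(sprintf("  beta:  slope %+0.4f (origin %+0.4f), intercept %+0.5f, R2 %s\n",
                x$slope_beta, x$slope_beta_origin, x$intercept_beta,
                format(x$r2_beta, digits = 4)))
  }
  invisible(x)
}
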