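# Synthetic composite-sample generator: reproduces in silico the wet-lab
# construction of validation samples (mixtures of maternal DNA with one or
# two "fetal" genotype sets), sampled at molecular (consensus-read) depth
# with a low per-read substitution error.

#' Default SNP-panel composition
#'
#' 389 X-chromosome loci plus four Y marker loci, split across classes:
#' T1 40, T2 60, T3 30+30, T4 100+100, T5 29, Y 4.  The published panel
#' states only the totals; the per-class split is a fixed package default.
#'
#' @return named integer vector.
#' @export
default_panel_composition <- function() {
  c(T1 = 40L, T2 = 60L, T3_P1 = 30L, T3_P2 = 30L,
    T4_ALPHA = 100L, T4_BETA = 100L, T5 = 29L, Y = 4L)
}

#' Simulator settings
#'
#' @param depth mean molecular (consensus) depth per locus in a sample of
#'   normal diploid mass; per-locus expected depth scales with the locus'
#'   mixture mass.  Default 640, the published mean molecular depth.
#' @param error_rate per-consensus-read substitution probability `e`; a read
#'   errs to each of the three other bases with probability `e/3`.  Default
#'   0.001 (molecular-barcode consensus background).
#' @param depth_law `"poisson"` (default) or `"nbinom"` (over-dispersed
#'   option for robustness studies).
#' @param nb_size negative-binomial size when `depth_law = "nbinom"`.
#' @param composition panel composition, see [default_panel_composition()].
#' @return list of settings.
#' @export
sim_config <- function(depth = 640, error_rate = 0.001,
                       depth_law = c("poisson", "nbinom"), nb_size = 20,
                       composition = default_panel_composition()) {
  depth_law <- match.arg(depth_law)
  stopifnot(depth >= 1, error_rate >= 0, error_rate <= 0.05,
            all(composition >= 0), sum(composition) > 0)
  list(depth = depth, error_rate = error_rate, depth_law = depth_law,
       nb_size = nb_size, composition = composition)
}

#' @keywords internal
.with_seed <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

#' Simulate a SNP panel
#'
#' Draws random alleles and phases matching each requested class;
#' deterministic for a given seed.  Every generated locus round-trips
#' through [classify_snp()] to its requested class by construction.
#'
#' @param composition named counts per class (`T1`, `T2`, `T3_P1`, `T3_P2`,
#'   `T4_ALPHA`, `T4_BETA`, `T5`, `Y`).
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return `ff_panel`.
#' @export
simulate_panel <- function(composition = default_panel_composition(),
                           seed = NULL) {
  known <- c("T1", "T2", "T3_P1", "T3_P2", "T4_ALPHA", "T4_BETA", "T5", "Y")
  if (is.null(names(composition)) || !all(names(composition) %in% known))
    stop("composition must be named with classes among: ",
         paste(known, collapse = ", "), call. = FALSE)
  .with_seed(seed, {
    rows <- list()
    two <- function() sample(.BASES, 2L)   # two distinct alleles
    for (cls in names(composition)) {
      k <- composition[[cls]]
      if (k == 0L) next
      for (i in seq_len(k)) {
        g <- switch(cls,
          T1 = { ab <- two(); list(M = c(ab[1], ab[1]), P = c(ab[2], ab[2])) },
          T2 = { a <- sample(.BASES, 1L); list(M = c(a, a), P = c(a, a)) },
          T3_P1 = { ab <- two(); list(M = c(ab[1], ab[1]), P = c(ab[2], ab[1])) },
          T3_P2 = { ab <- two(); list(M = c(ab[1], ab[1]), P = c(ab[1], ab[2])) },
          T4_ALPHA = { ab <- two(); list(M = ab, P = c(ab[1], ab[1])) },
          T4_BETA = { ab <- two(); list(M = ab, P = c(ab[2], ab[2])) },
          T5 = { ab <- two(); list(M = ab, P = sample(ab)) },
          Y = list(M = c(NA, NA), P = c(sample(.BASES, 1L), NA)))
        rows[[length(rows) + 1L]] <- data.frame(
          cls = cls, M1 = g$M[1], M2 = g$M[2], P1 = g$P[1], P2 = g$P[2],
          is_y = cls == "Y", stringsAsFactors = FALSE)
      }
    }
    df <- do.call(rbind, rows)
    n <- nrow(df)
    ord <- sample.int(n)       # interleave classes along the chromosome
    df <- df[ord, , drop = FALSE]
    df$snp_id <- sprintf("snp%04d", seq_len(n))
    df$chrom <- ifelse(df$is_y, "Y", "X")
    df$pos <- sort(sample.int(1.5e8, n))
    build_panel(df[, c("snp_id", "chrom", "pos", "M1", "M2", "P1", "P2", "is_y")])
  })
}

#' Simulate a consensus-read count table
#'
#' Per locus: depth is drawn around `config$depth` scaled by the locus'
#' mixture mass (Poisson by default), true allele fractions come from the
#' exact mixture model, the substitution-error model perturbs them
#' (`p_obs = (1-e) p + e/3 (1-p)` per allele) and counts are multinomial.
#'
#' @param panel `ff_panel`.
#' @param contributors `ff_contributors` (see
#'   [contributors_for_scenario()]), or any list of
#'   `(label, weight, copies)`.
#' @param config see [sim_config()].
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return `ff_counts`.
#' @export
simulate_counts <- function(panel, contributors, config = sim_config(),
                            seed = NULL) {
  stopifnot(inherits(panel, "ff_panel"))
  .with_seed(seed, {
    mass <- .allele_mass(contributors, panel)
    totals <- rowSums(mass)
    n <- nrow(panel)
    depth <- integer(n)
    pos <- totals > 0
    mu <- config$depth * totals[pos]
    depth[pos] <- if (config$depth_law == "poisson") rpois(sum(pos), mu)
                  else rnbinom(sum(pos), mu = mu, size = config$nb_size)
    cm <- matrix(0, n, 4L, dimnames = list(panel$snp_id, .BASES))
    e <- config$error_rate
    for (i in which(depth > 0L)) {
      p <- mass[i, ] / totals[i]
      p_obs <- (1 - e) * p + (e / 3) * (1 - p)
      cm[i, ] <- rmultinom(1L, depth[i], p_obs)[, 1L]
    }
    allele_count_table(cm)
  })
}

#' Simulate a full validation case
#'
#' Builds the contributor mixture for a scenario and draws a plasma count
#' table plus a matched pure-maternal table (for in-silico dilution), with
#' independent sub-seeds, recording the ground truth.
#'
#' @param sc an `ff_scenario`.
#' @param config see [sim_config()].
#' @param seed integer seed (panel uses `seed`, plasma `seed + 1`, maternal
#'   `seed + 2`); `NULL` uses the current RNG state throughout.
#' @return `ff_case`: list `panel`, `plasma`, `maternal`, `truth`.
#' @export
simulate_case <- function(sc, config = sim_config(), seed = NULL) {
  stopifnot(inherits(sc, "ff_scenario"))
  seeds <- if (is.null(seed)) list(NULL, NULL, NULL)
           else as.list(as.integer(seed) + 0:2)
  panel <- simulate_panel(config$composition, seeds[[1L]])
  plasma <- simulate_counts(panel, contributors_for_scenario(sc),
                            config, seeds[[2L]])
  mother <- structure(list(.contributor("mother", 1, c("M1", "M2"))),
                      class = "ff_contributors")
  maternal <- simulate_counts(panel, mother, config, seeds[[3L]])
  structure(list(panel = panel, plasma = plasma, maternal = maternal,
                 truth = list(scenario = sc, seed = seed,
                              depth = config$depth,
                              error_rate = config$error_rate)),
            class = "ff_case")
}
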