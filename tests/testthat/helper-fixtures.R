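# Shared fixtures and a tiny independent oracle for expected frequencies.

# Direct mass bookkeeping, independent of the package internals: each
# contributor is a weight plus the alleles its chromosome copies carry at
# one locus (one allele per copy).  freq(a) = sum(weight/2 over copies of a)
# normalised.
direct_freqs <- function(weights, copy_alleles) {
  mass <- c(A = 0, C = 0, G = 0, T = 0)
  for (i in seq_along(weights))
    for (al in copy_alleles[[i]])
      mass[al] <- mass[al] + weights[i] / 2
  mass / sum(mass)
}

# A minimal mixed panel: one locus of each class plus a Y marker.
tiny_panel <- function() {
  build_panel(data.frame(
    snp_id = c("s1", "s2", "s3", "s4", "s5", "s6", "s7", "sy"),
    chrom = c(rep("X", 7), "Y"),
    pos = 1:8 * 100L,
    M1 = c("A", "C", "A", "A", "A", "A", "A", NA),
    M2 = c("A", "C", "A", "A", "G", "G", "G", NA),
    P1 = c("G", "C", "G", "A", "A", "G", "A", "T"),
    P2 = c("G", "C", "A", "G", "A", "G", "G", NA),
    is_y = c(rep(FALSE, 7), TRUE),
    stringsAsFactors = FALSE))
}

# counts table helper: named rows of A,C,G,T
counts_from <- function(...) {
  rows <- list(...)
  m <- do.call(rbind, rows)
  colnames(m) <- c("A", "C", "G", "T")
  allele_count_table(m)
}

# small composition for fast simulations
small_comp <- function() c(T1 = 8L, T2 = 8L, T3_P1 = 8L, T3_P2 = 8L,
                           T4_ALPHA = 12L, T4_BETA = 12L, T5 = 4L, Y = 2L)

# oracle-exact count tables: expected frequencies scaled to a huge depth so
# that integer rounding is negligible (used for exactness tests)
exact_counts <- function(sc, panel, depth = 1e12) {
  contributors <- contributors_for_scenario(sc)
  m <- matrix(0, nrow(panel), 4L, dimnames = list(panel$snp_id,
                                                  c("A", "C", "G", "T")))
  for (i in seq_len(nrow(panel))) {
    fr <- tryCatch(expected_allele_freqs(contributors, panel[i, ]),
                   error = function(e) NULL)   # zero-mass loci (e.g. female Y)
    if (!is.null(fr)) m[i, ] <- round(fr * depth)
  }
  allele_count_table(m)
}

exact_maternal_counts <- function(panel, depth = 1e12) {
  exact_counts(scenario("NORMAL", f = 0), panel, depth)
}
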