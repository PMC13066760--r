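test_that("contributor mixtures follow the scenario definitions", {
  co <- contributors_for_scenario(scenario("NORMAL", f = 0.10))
  expect_equal(vapply(co, `[[`, "", "label"), c("mother", "fetal_abnormal"))
  expect_equal(vapply(co, `[[`, 0, "weight"), c(0.90, 0.10))
  expect_equal(co[[1]]$copies, c("M1", "M2"))
  expect_equal(co[[2]]$copies, c("M1", "P1"))

  tri <- contributors_for_scenario(scenario("TRI_MAT_MEI1", f = 0.10))
  expect_equal(tri[[2]]$copies, c("M1", "M2", "P1"))
  expect_equal(tri[[2]]$weight, 0.10)

  mos <- contributors_for_scenario(scenario("TRI_MAT_MEI1", f = 0.10, m = 0.25))
  expect_equal(vapply(mos, `[[`, 0, "weight"), c(0.90, 0.025, 0.075))
  expect_equal(mos[[3]]$copies, c("M1", "P1"))

  upd <- contributors_for_scenario(scenario("UPD_MAT_HETERO", f = 0.10))
  expect_equal(upd[[2]]$copies, c("M1", "M2"))   # fetus genotypes = mother's

  expect_error(scenario("NORMAL", m = 0.5), "only defined for aneuploidy")
  expect_error(scenario("TRI_MAT_MEI1", twin_split = 0.5), "TWINS_DIZYGOTIC")
})

test_that("expected_allele_freqs agrees with independent mass bookkeeping", {
  t1_locus <- data.frame(snp_id = "x", chrom = "X", pos = 1L,
                         M1 = "A", M2 = "A", P1 = "G", P2 = "G",
                         stringsAsFactors = FALSE)
  t4_locus <- data.frame(snp_id = "x", chrom = "X", pos = 1L,
                         M1 = "A", M2 = "G", P1 = "A", P2 = "A",
                         stringsAsFactors = FALSE)

  # mother-only, T4 locus: 50/50
  mother_only <- contributors_for_scenario(scenario("NORMAL", f = 0))
  expect_equal(expected_allele_freqs(mother_only, t4_locus),
               direct_freqs(1, list(c("A", "G"))))

  # normal f = 0.10, T1 locus: paternal allele at 0.05
  nrm <- contributors_for_scenario(scenario("NORMAL", f = 0.10))
  fr <- expected_allele_freqs(nrm, t1_locus)
  expect_equal(fr[["G"]], 0.05)
  expect_equal(fr, direct_freqs(c(0.9, 0.1), list(c("A", "A"), c("A", "G"))))

  # maternal MI trisomy: denominator 0.9 + 3 * 0.05
  tri <- contributors_for_scenario(scenario("TRI_MAT_MEI1", f = 0.10))
  fr2 <- expected_allele_freqs(tri, t1_locus)
  expect_equal(fr2[["G"]], 0.05 / 1.05)
  expect_equal(fr2, direct_freqs(c(0.9, 0.1),
                                 list(c("A", "A"), c("A", "A", "G"))))
})

test_that("expected signatures reproduce the derived closed forms", {
  s <- expected_signature(scenario("NORMAL", f = 0.10))
  expect_equal(s$t1$value, 0.10)
  expect_equal(s$t3_p1$value, 0.10)
  expect_equal(s$t3_p2$value, 0)
  expect_equal(s$t4_alpha$value, 0.10)
  expect_equal(s$t4_beta$value, 0)
  expect_equal(s$bkg$value, 0)
  expect_equal(s$t1$dispersion, 0)

  s <- expected_signature(scenario("NORMAL", f = 0.10, mat_hap = "M2"))
  expect_equal(s$t4_alpha$value, 0)
  expect_equal(s$t4_beta$value, -0.10)

  s <- expected_signature(scenario("TRI_MAT_MEI1", f = 0.10))
  expect_equal(s$t1$value, 2 * 0.05 / 1.05)          # 0.095238
  expect_equal(s$t4_alpha$value, 0.05 / 1.05)        # +0.047619
  expect_equal(s$t4_beta$value, -0.05 / 1.05)

  s <- expected_signature(scenario("TRI_PAT_MEI1", f = 0.10))
  expect_equal(s$t1$value, 0.2 / 1.05)               # 0.190476
  expect_equal(s$t3_p1$value, 0.1 / 1.05)
  expect_equal(s$t3_p2$value, 0.1 / 1.05)
  expect_equal(s$t4_alpha$value, 0.15 / 1.05)        # 0.142857, 3/4 of T1
  expect_equal(s$t4_alpha$value / s$t1$value, 0.75)

  s <- expected_signature(scenario("UPD_PAT_HETERO", f = 0.10))
  expect_equal(s$t1$value, 0.20)
  expect_equal(s$t3_p1$value, 0.10)
  expect_equal(s$t3_p2$value, 0.10)
  expect_equal(abs(s$t4_alpha$value), 0.10)
  expect_equal(abs(s$t4_beta$value), 0.10)

  s <- expected_signature(scenario("UPD_MAT_HETERO", f = 0.10))
  for (k in c("t1", "t3_p1", "t3_p2", "t4_alpha", "t4_beta"))
    expect_equal(s[[k]]$value, 0)

  s <- expected_signature(scenario("TWINS_DIZYGOTIC", f = 0.10,
                                   twin_split = 2 / 3))
  expect_equal(s$t3_p1$value / s$t3_p2$value, 2)
  expect_equal(abs(s$t4_alpha$value / s$t4_beta$value), 2)
})

test_that("expected slopes match the closed forms and flag undefined cases", {
  es <- expected_slopes(scenario("NORMAL", f = 0.10))
  expect_equal(c(es$slope_alpha, es$slope_beta), c(1, 0))
  es <- expected_slopes(scenario("NORMAL", f = 0.10, mat_hap = "M2"))
  expect_equal(c(es$slope_alpha, es$slope_beta), c(0, -1))
  es <- expected_slopes(scenario("TRI_MAT_MEI1", f = 0.10))
  expect_equal(c(es$slope_alpha, es$slope_beta), c(0.5, -0.5))
  es <- expected_slopes(scenario("TRI_MAT_MEI1", f = 0.10, m = 0.125))
  expect_equal(c(es$slope_alpha, es$slope_beta), c(0.9375, -0.0625))
  # no Type-1 signal: slopes undefined
  expect_false(expected_slopes(scenario("MONOSOMY_MAT", f = 0.10))$defined)
  expect_false(expected_slopes(scenario("UPD_MAT_HETERO", f = 0.10))$defined)
})

test_that("oracle frequencies sum to 1 and obey relabeling symmetries", {
  panel <- simulate_panel(small_comp(), seed = 5)
  for (kind in scenario_kinds()) {
    sc <- scenario(kind, f = 0.12)
    co <- contributors_for_scenario(sc)
    for (i in which(!panel$is_y)) {
      fr <- expected_allele_freqs(co, panel[i, ])
      expect_equal(sum(fr), 1, tolerance = 1e-12)
      expect_true(all(fr >= 0))
    }
    # M1<->M2 swap: alpha and beta exchange (negated values), T3/T1 invariant
    if (!kind %in% c("TRI_MAT_MEI1", "UPD_MAT_HETERO")) {  # mat-symmetric kinds unchanged by construction
      s1 <- expected_signature(sc)
      s2 <- expected_signature(scenario(kind, f = 0.12,
                                        mat_hap = "M2", pat_hap = "P1"))
      expect_equal(s2$t1$value, s1$t1$value, tolerance = 1e-12)
    }
  }
  # explicit symmetry checks on the normal scenario
  s1 <- expected_signature(scenario("NORMAL", f = 0.1, mat_hap = "M1"))
  s2 <- expected_signature(scenario("NORMAL", f = 0.1, mat_hap = "M2"))
  expect_equal(s2$t4_beta$value, -s1$t4_alpha$value)
  expect_equal(s2$t4_alpha$value, -s1$t4_beta$value)
  s3 <- expected_signature(scenario("NORMAL", f = 0.1, pat_hap = "P2"))
  expect_equal(s3$t3_p2$value, s1$t3_p1$value)
  expect_equal(s3$t3_p1$value, s1$t3_p2$value)
})

test_that("dilution linearity: the Type-4 : Type-1 ratio is invariant in f", {
  for (kind in c("NORMAL", "TRI_MAT_MEI1", "TRI_PAT_MEI2", "UPD_PAT_ISO")) {
    ratios <- vapply(c(0.02, 0.05, 0.1, 0.2, 0.4), function(f) {
      s <- expected_signature(scenario(kind, f = f))
      s$t4_alpha$value / s$t1$value
    }, 0)
    expect_equal(max(ratios) - min(ratios), 0, tolerance = 1e-12)
  }
})
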