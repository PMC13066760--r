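test_that("allele_frequencies normalises and validates", {
  expect_equal(allele_frequencies(c(A = 90, G = 10))[["A"]], 0.9)
  expect_equal(allele_frequencies(c(A = 100))[["A"]], 1.0)
  f <- allele_frequencies(c(A = 475, G = 25, C = 0, T = 0))
  expect_equal(unname(f[c("A", "G")]), c(0.95, 0.05))
  expect_equal(sum(f), 1, tolerance = 1e-12)
  expect_error(allele_frequencies(c(A = 0, G = 0)), "zero depth")
  expect_error(allele_frequencies(c(Z = 5)), "unknown allele")
})

test_that("per-type estimators match hand-computed values on a tiny panel", {
  p <- build_panel(data.frame(
    snp_id = c("t1a", "t1b", "t2", "t3", "t4a", "t4b"),
    chrom = "X", pos = 1:6 * 10L,
    M1 = c("A", "A", "C", "A", "A", "A"),
    M2 = c("A", "A", "C", "A", "G", "G"),
    P1 = c("G", "G", "C", "G", "A", "G"),
    P2 = c("G", "G", "C", "A", "A", "G"),
    stringsAsFactors = FALSE))
  cm <- counts_from(
    t1a = c(950, 0, 50, 0),     # paternal G at 0.05 -> 0.10
    t1b = c(930, 0, 70, 0),     # 0.07 -> 0.14
    t2  = c(1, 995, 4, 0),      # 2nd allele 4/1000
    t3  = c(940, 0, 60, 0),     # paternal-specific G at 0.06 -> 0.12
    t4a = c(550, 0, 450, 0),    # M1 - M2 = +0.10
    t4b = c(450, 0, 550, 0))    # M1 - M2 = -0.10
  rownames(cm) <- c("t1a", "t1b", "t2", "t3", "t4a", "t4b")
  cm <- allele_count_table(unclass(cm))

  e1 <- estimate_ff_type1(cm, p)
  expect_equal(e1$value, 0.12)
  expect_equal(e1$dispersion, 0.02)   # MAD of {0.10, 0.14}
  expect_equal(e1$n_snps, 2L)

  expect_equal(estimate_ff_type3(cm, p, "T3_P1")$value, 0.12)
  expect_equal(estimate_ff_type3(cm, p, "T3_P2")$n_snps, 0L)
  expect_false(estimate_ff_type3(cm, p, "T3_P2")$available)

  expect_equal(estimate_ff_type4(cm, p, "T4_ALPHA")$value, 0.10)
  expect_equal(estimate_ff_type4(cm, p, "T4_BETA")$value, -0.10)

  expect_equal(estimate_background(cm, p)$value, 0.004)
  expect_equal(estimate_background(cm, p, doubled = TRUE)$value, 0.008)

  sig <- compute_signature(cm, p)
  expect_s3_class(sig, "ff_signature")
  expect_equal(sig$t1$value, 0.12)
  expect_equal(sig$bkg_ff$value, 0.008)
})

test_that("doubling all counts leaves every estimate unchanged", {
  case <- simulate_case(scenario("NORMAL", f = 0.10),
                        sim_config(composition = small_comp()), seed = 11)
  s1 <- compute_signature(case$plasma, case$panel)
  s2 <- compute_signature(allele_count_table(unclass(case$plasma) * 2),
                          case$panel)
  for (k in c("t1", "t3_p1", "t3_p2", "t4_alpha", "t4_beta", "bkg"))
    expect_equal(s1[[k]]$value, s2[[k]]$value, tolerance = 1e-12)
})

test_that("relabeling M1<->M2 in the panel negates Type-4 and swaps alpha/beta", {
  case <- simulate_case(scenario("NORMAL", f = 0.10),
                        sim_config(composition = small_comp()), seed = 12)
  p <- case$panel
  df <- as.data.frame(p)[, c("snp_id", "chrom", "pos", "M1", "M2", "P1", "P2", "is_y")]
  tmp <- df$M1; df$M1 <- df$M2; df$M2 <- tmp
  p2 <- build_panel(df)
  s1 <- compute_signature(case$plasma, p)
  s2 <- compute_signature(case$plasma, p2)
  expect_equal(s2$t4_alpha$value, -s1$t4_beta$value, tolerance = 1e-12)
  expect_equal(s2$t4_beta$value, -s1$t4_alpha$value, tolerance = 1e-12)
  expect_equal(s2$t3_p1$value, s1$t3_p1$value, tolerance = 1e-12)
  expect_equal(s2$t1$value, s1$t1$value, tolerance = 1e-12)
})

test_that("genotype-inconsistent SNPs are excluded and logged", {
  p <- build_panel(data.frame(
    snp_id = c("a", "b"), chrom = "X", pos = c(10L, 20L),
    M1 = c("A", "A"), M2 = c("A", "A"), P1 = c("G", "G"), P2 = c("G", "G"),
    stringsAsFactors = FALSE))
  cm <- counts_from(a = c(950, 0, 50, 0),
                    b = c(600, 300, 100, 0))   # C at 30%: not a parental allele
  rownames(cm) <- c("a", "b")
  sig <- compute_signature(allele_count_table(unclass(cm)), p)
  expect_equal(sig$t1$n_snps, 1L)
  expect_true("b" %in% sig$excluded$snp_id)
  expect_true("unexpected_allele" %in% sig$excluded$reason)
})

test_that("Y loci drive the sex call, FF_Y and the 47,XXY flag", {
  cfg <- sim_config(composition = small_comp())
  fem <- simulate_case(scenario("NORMAL", f = 0.10), cfg, seed = 21)
  sf <- compute_signature(fem$plasma, fem$panel)
  expect_equal(sf$sex, "female")
  expect_false(sf$ff_y$available)

  male <- simulate_case(scenario("MALE_FETUS_X", f = 0.10), cfg, seed = 22)
  sm <- compute_signature(male$plasma, male$panel)
  expect_equal(sm$sex, "male")
  expect_true(sm$ff_y$available)
  expect_equal(sm$ff_y$value, 0.10 / (1 - 0.05), tolerance = 0.25)
  expect_false(sm$xxy_suspect)

  xxy <- simulate_case(scenario("XXY", f = 0.10), cfg, seed = 23)
  sx <- compute_signature(xxy$plasma, xxy$panel)
  expect_equal(sx$sex, "male")
  expect_true(sx$xxy_suspect)

  expect_error(estimate_ff_y(fem$plasma,
                             build_panel(as.data.frame(fem$panel)[!fem$panel$is_y,
                               c("snp_id", "chrom", "pos", "M1", "M2", "P1", "P2", "is_y")])),
               "no Y loci")
})
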