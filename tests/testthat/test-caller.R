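test_that("alert rule: normal passes, homogeneous trisomy and silent samples alert", {
  cfg <- sim_config()
  nrm <- simulate_case(scenario("NORMAL", f = 0.10), cfg, seed = 41)
  a1 <- alert_from_signature(compute_signature(nrm$plasma, nrm$panel))
  expect_false(a1$alert)

  tri <- simulate_case(scenario("TRI_MAT_MEI1", f = 0.10), cfg, seed = 42)
  a2 <- alert_from_signature(compute_signature(tri$plasma, tri$panel))
  expect_true(a2$alert)
  expect_true(any(grepl("t4_alpha", a2$reasons)))
  expect_true(any(grepl("t4_beta", a2$reasons)))

  hetero <- simulate_case(scenario("UPD_MAT_HETERO", f = 0.10), cfg, seed = 43)
  a3 <- alert_from_signature(compute_signature(hetero$plasma, hetero$panel))
  expect_true(a3$alert)
  expect_true(any(grepl("no fetal DNA or maternal heterodisomy", a3$reasons)))

  # male fetus on an X panel must NOT alert as a monosomy
  male <- simulate_case(scenario("MALE_FETUS_X", f = 0.10), cfg, seed = 44)
  a4 <- alert_from_signature(compute_signature(male$plasma, male$panel))
  expect_false(a4$alert)
})

test_that("alert is withheld per subtype below the SNP minimum", {
  cfg <- sim_config(composition = c(T1 = 8L, T2 = 8L, T3_P1 = 2L, T3_P2 = 8L,
                                    T4_ALPHA = 8L, T4_BETA = 8L))
  case <- simulate_case(scenario("NORMAL", f = 0.10), cfg, seed = 45)
  al <- alert_from_signature(compute_signature(case$plasma, case$panel))
  expect_true("t3_p1" %in% al$low_confidence)
})

test_that("slope_flags applies the pair tolerance around (+1, 0) and (0, -1)", {
  fake_reg <- function(sa, sb)
    structure(list(slope_alpha = sa, slope_beta = sb, degenerate = FALSE),
              class = "ff_regression")
  expect_false(slope_flags(fake_reg(1.002, -0.004), tolerance = 0.15)$flagged)
  expect_false(slope_flags(fake_reg(0.01, -0.98), tolerance = 0.15)$flagged)
  expect_true(slope_flags(fake_reg(0.5, -0.5), tolerance = 0.15)$flagged)
  expect_true(slope_flags(fake_reg(0.9375, -0.0625), tolerance = 0.05)$flagged)
  expect_false(slope_flags(fake_reg(0.9375, -0.0625), tolerance = 0.15)$flagged)
  deg <- structure(list(slope_alpha = NA_real_, slope_beta = NA_real_,
                        degenerate = TRUE), class = "ff_regression")
  fl <- slope_flags(deg)
  expect_true(fl$flagged)
  expect_match(fl$reasons, "undefined")
})

test_that("classifier recovers oracle scenarios and reports indistinguishable sets", {
  f1 <- classify_scenario(expected_signature(scenario("TRI_MAT_MEI1", f = 0.10)))
  expect_true("TRI_MAT_MEI1" %in% attr(f1, "tied_set"))
  expect_false(attr(f1, "tied_set")[1] == "NORMAL")
  mrow <- which(f1$kind == "TRI_MAT_MEI1")[1]
  expect_equal(f1$m[mrow], 1, tolerance = 0.02)
  expect_equal(attr(f1, "transmitted"), "AMBIGUOUS")

  f2 <- classify_scenario(expected_signature(scenario("MONOSOMY_MAT", f = 0.10)))
  expect_setequal(attr(f2, "tied_set"), c("MONOSOMY_MAT", "UPD_MAT_ISO"))
  expect_true(any(grepl("isodisomy", attr(f2, "notes"))))

  f3 <- classify_scenario(expected_signature(scenario("UPD_MAT_HETERO", f = 0.10)))
  expect_setequal(attr(f3, "tied_set"), c("UPD_MAT_HETERO", "NO_FETAL_DNA"))
  expect_true(any(grepl("heterodisomy", attr(f3, "notes"))))

  f4 <- classify_scenario(expected_signature(
    scenario("TWINS_DIZYGOTIC", f = 0.10, twin_split = 2 / 3)))
  expect_equal(f4$kind[1], "TWINS_DIZYGOTIC")
  # twin labelling is exchangeable: split 2:1 or 1:2 with swapped haplotypes
  expect_lt(min(abs(f4$twin_split[1] - c(1 / 3, 2 / 3))), 0.02)

  # NORMAL is never ranked first on abnormal oracle signatures (m >= 0.125)
  for (kind in c("TRI_MAT_MEI1", "TRI_MAT_MEI2", "UPD_PAT_HETERO")) {
    ff <- classify_scenario(expected_signature(scenario(kind, f = 0.05, m = 0.125)))
    expect_false(ff$kind[1] == "NORMAL", label = paste(kind, "not called NORMAL"))
    expect_false("NORMAL" %in% attr(ff, "tied_set"))
  }
})

test_that("transmitted-haplotype readout follows the Type-4 pattern", {
  expect_equal(attr(classify_scenario(expected_signature(
    scenario("NORMAL", f = 0.10, mat_hap = "M1"))), "transmitted"), "M1")
  expect_equal(attr(classify_scenario(expected_signature(
    scenario("NORMAL", f = 0.10, mat_hap = "M2"))), "transmitted"), "M2")
  expect_equal(attr(classify_scenario(expected_signature(
    scenario("UPD_MAT_HETERO", f = 0.10))), "transmitted"), "NONE")
})

test_that("mosaic-fraction closed forms invert the oracle", {
  panel <- simulate_panel(small_comp(), seed = 46)
  mat <- exact_maternal_counts(panel)
  for (m in c(1, 0.5, 0.125, 0)) {
    reg <- regression_series(exact_counts(scenario("TRI_MAT_MEI1", f = 0.10,
                                                   m = m), panel), mat, panel)
    est <- estimate_mosaic_fraction(reg, "TRI_MAT_MEI1")
    expect_equal(est$m, m, tolerance = 1e-4)
  }
  # closed-form anchor points on the slope scale
  fake_reg <- function(sa, sb)
    structure(list(slope_alpha = sa, slope_beta = sb, degenerate = FALSE),
              class = "ff_regression")
  expect_equal(estimate_mosaic_fraction(fake_reg(0.5, -0.5), "TRI_MAT_MEI1")$m, 1)
  expect_equal(estimate_mosaic_fraction(fake_reg(0.9375, -0.0625),
                                        "TRI_MAT_MEI1")$m, 0.125)
  expect_equal(estimate_mosaic_fraction(fake_reg(1, 0), "TRI_MAT_MEI1")$m, 0)

  # signature route, both transmission orientations
  for (mh in c("M1", "M2")) {
    s <- expected_signature(scenario("TRI_MAT_MEI1", f = 0.10, m = 0.25,
                                     mat_hap = mh))
    expect_equal(estimate_mosaic_fraction(s, "TRI_MAT_MEI1")$m, 0.25,
                 tolerance = 1e-9)
  }
  s <- expected_signature(scenario("TRI_MAT_MEI2", f = 0.10, m = 0.5))
  expect_equal(estimate_mosaic_fraction(s, "TRI_MAT_MEI2")$m, 0.5,
               tolerance = 1e-9)
  expect_error(estimate_mosaic_fraction(s, "NORMAL"))
})
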