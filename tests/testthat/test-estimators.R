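test_that("drive inheritance rate and conversion efficiency follow 2p - 1", {
  expect_equal(drive_inheritance_rate(ct_dsred(50, 100))$point, 0.5)
  expect_equal(drive_inheritance_rate(ct_dsred(87, 100))$point, 0.87)
  expect_equal(conversion_efficiency(ct_dsred(87, 100))$point, 0.74)
  expect_equal(conversion_efficiency(ct_dsred(50, 100))$point, 0)
  expect_equal(conversion_efficiency(ct_dsred(100, 100))$point, 1)
  # sub-Mendelian transmission reported as negative, not clamped
  expect_lt(conversion_efficiency(ct_dsred(40, 100))$point, 0)
  # SE propagates with the factor 2
  e1 <- drive_inheritance_rate(ct_dsred(87, 100))
  e2 <- conversion_efficiency(ct_dsred(87, 100))
  expect_equal(e2$se, 2 * e1$se)
  expect_equal(c(e2$ci_low, e2$ci_high), c(2 * e1$ci_low - 1, 2 * e1$ci_high - 1))
  # degenerate input errors
  empty <- count_table(data.frame())
  expect_error(drive_inheritance_rate(empty), "zero")
  # daughters-only denominator
  t <- ct(sex = c("female", "female", "male"), dsred = c(TRUE, FALSE, TRUE),
          egfp = "not_applicable", body = "wild", count = c(30L, 70L, 100L))
  expect_equal(drive_inheritance_rate(t, denominator = "daughters")$point, 0.3)
  expect_equal(drive_inheritance_rate(t, denominator = "all")$point, 0.65)
})

test_that("embryo r2 rate from the yellow-body readout uses dsRed daughters", {
  expect_equal(embryo_r2_rate_yellow(ct_yellow_daughters(74, 100))$point, 0.74)
  expect_equal(embryo_r2_rate_yellow(ct_yellow_daughters(0, 100))$point, 0)
  expect_equal(embryo_r2_rate_yellow(ct_yellow_daughters(20, 100))$point, 0.20)
  # mosaic-yellow dsRed daughters stay in the denominator, out of the numerator
  t <- ct(sex = "female", dsred = TRUE, egfp = "not_applicable",
          body = c("yellow", "mosaic_yellow", "wild"), count = c(40L, 10L, 50L))
  expect_equal(embryo_r2_rate_yellow(t)$point, 0.4)
  # sons and non-dsRed flies are ignored
  t2 <- ct(sex = c("female", "female", "male", "female"),
           dsred = c(TRUE, TRUE, TRUE, FALSE),
           egfp = "not_applicable",
           body = c("yellow", "wild", "yellow", "yellow"),
           count = c(30L, 70L, 500L, 500L))
  expect_equal(embryo_r2_rate_yellow(t2)$point, 0.3)
  expect_error(embryo_r2_rate_yellow(ct_dsred(0, 100)), "zero")
})

test_that("embryo r2 rate from the EGFP readout uses dsRed offspring of both sexes", {
  t <- ct(sex = "female", dsred = TRUE, egfp = c("none", "full"),
          body = "wild", count = c(88L, 12L))
  expect_equal(embryo_r2_rate_egfp(t)$point, 0.88)
  t <- ct(sex = "female", dsred = TRUE, egfp = "full", body = "wild", count = 100L)
  expect_equal(embryo_r2_rate_egfp(t)$point, 0)
  t <- ct(sex = c("female", "male"), dsred = TRUE, egfp = c("none", "full"),
          body = "wild", count = c(91L, 9L))
  expect_equal(embryo_r2_rate_egfp(t)$point, 0.91)
  # mosaics are not 'none'
  t <- ct(sex = "female", dsred = TRUE, egfp = c("none", "mosaic"),
          body = "wild", count = c(50L, 50L))
  expect_equal(embryo_r2_rate_egfp(t)$point, 0.5)
  # X-linked targets: drive-carrying sons lack EGFP structurally, so the
  # paternal-allele readout restricts to daughters
  t <- ct(sex = c("female", "female", "male"), dsred = TRUE,
          egfp = c("none", "full", "none"), body = "wild",
          count = c(40L, 60L, 100L))
  expect_equal(embryo_r2_rate_egfp(t, denominator = "daughters")$point, 0.4)
  expect_equal(embryo_r2_rate_egfp(t, denominator = "all")$point, 0.7)
})

test_that("germline r2 rate doubles the yellow non-dsRed son fraction", {
  t <- ct(sex = "male", dsred = c(FALSE, FALSE, TRUE), egfp = "not_applicable",
          body = c("yellow", "wild", "yellow"), count = c(6L, 44L, 50L))
  expect_equal(germline_r2_rate_sons(t)$point, 0.12)
  t0 <- ct(sex = "male", dsred = FALSE, egfp = "not_applicable",
           body = "wild", count = 100L)
  expect_equal(germline_r2_rate_sons(t0)$point, 0)
  t25 <- ct(sex = "male", dsred = FALSE, egfp = "not_applicable",
            body = c("yellow", "wild"), count = c(25L, 75L))
  expect_equal(germline_r2_rate_sons(t25)$point, 0.5)
  daughters_only <- ct(sex = "female", dsred = TRUE, egfp = "not_applicable",
                       body = "wild", count = 10L)
  expect_error(germline_r2_rate_sons(daughters_only), "sons")
})

test_that("Wilson interval hits its boundaries and is symmetric at p = 1/2", {
  expect_equal(wilson_ci(0, 10)[1L], 0)
  expect_equal(wilson_ci(10, 10)[2L], 1)
  ci <- wilson_ci(50, 100)
  expect_lt(abs((0.5 - ci[1L]) - (ci[2L] - 0.5)), 1e-9)
  expect_true(all(ci >= 0 & ci <= 1))
  expect_error(wilson_ci(5, 0))
})

test_that("Fisher exact p matches full hypergeometric enumeration", {
  expect_equal(fisher_exact_2x2(3, 1, 1, 3), 34 / 70, tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(4, 0, 0, 4), 2 / 70, tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(5, 5, 5, 5), 1)
  expect_equal(fisher_exact_2x2(matrix(c(3, 1, 1, 3), 2, byrow = TRUE)), 34 / 70)
  expect_warning(p <- fisher_exact_2x2(0, 0, 0, 0), "empty")
  expect_equal(p, 1)
  expect_error(fisher_exact_2x2(-1, 2, 3, 4), "non-negative")
  # exhaustive agreement with the reference implementation at small totals
  for (n in 0:12) for (a in 0:n) for (b in 0:(n - a)) for (cc in 0:(n - a - b)) {
    d <- n - a - b - cc
    if (a + b + cc + d == 0) next
    expect_equal(fisher_exact_2x2(a, b, cc, d),
                 stats::fisher.test(matrix(c(a, cc, b, d), 2))$p.value,
                 tolerance = 1e-10)
  }
})

test_that("estimates are invariant to count-table row order", {
  set.seed(31)
  t <- simulate_experiment(design_catalog()[["D2"]], drive_params(), 5, 100, seed = 8)
  df <- as.data.frame(t)
  perm <- sample(nrow(df))
  t_perm <- count_table(df[perm, ], design = attr(t, "design"))
  for (f in list(drive_inheritance_rate, conversion_efficiency,
                 embryo_r2_rate_yellow, germline_r2_rate_sons)) {
    expect_equal(f(t)$point, f(t_perm)$point)
  }
})

test_that("the jackknife SE flags brood-level variation", {
  res <- simulate_experiment(design_catalog()[["D2"]], drive_params(), 8, 100,
                             seed = 77, keep_crosses = TRUE)
  jk <- jackknife_se(res$crosses, conversion_efficiency)
  expect_equal(jk$point, conversion_efficiency(res$pooled)$point)
  expect_gt(jk$se_jackknife, 0)
  expect_error(jackknife_se(res$crosses[1L], conversion_efficiency), "two")
})
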