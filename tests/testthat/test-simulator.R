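test_that("germline transmission is Mendelian without conversion and complete with c = 1", {
  cfg <- std_cfg()
  mom <- locus_genotype("female", c("DRIVE", "WILD"))
  # c = r = 0: the drive segregates 1:1
  set.seed(11)
  g <- germline_transmit(mom, params = drive_params(c_f = 0, r_f = 0, e_cut = 0),
                         config = cfg, n = 10000)
  p_hat <- mean(g$target == "DRIVE")
  expect_lt(abs(p_hat - 0.5), 2.58 * sqrt(0.25 / 10000))  # 99% binomial CI
  # c = 1: every gamete carries the drive
  set.seed(12)
  g <- germline_transmit(mom, params = drive_params(c_f = 1, r_f = 0, e_cut = 0),
                         config = cfg, n = 2000)
  expect_true(all(g$target == "DRIVE"))
})

test_that("without any Cas9 source a drive heterozygote transmits 1:1", {
  # split-drive het mother, no genomic Cas9, no deposition received
  mom <- locus_genotype("female", c("DRIVE", "WILD"))
  set.seed(13)
  g <- germline_transmit(mom, deposition_state(FALSE, FALSE),
                         drive_params(c_f = 0.9, r_f = 0.1), split_cfg(),
                         n = 10000)
  p_hat <- mean(g$target == "DRIVE")
  expect_lt(abs(p_hat - 0.5), 2.58 * sqrt(0.25 / 10000))
  expect_false(any(g$target %in% c("R1", "R2")))
})

test_that("carried-over maternal Cas9 powers germline conversion at (1 + c)/2", {
  mom <- locus_genotype("female", c("DRIVE", "WILD"))
  params <- drive_params(p_active = 1, c_carry = 0.5, r_carry = 0)
  set.seed(14)
  g <- germline_transmit(mom, deposition_state(cas9_deposited = TRUE),
                         params, split_cfg(), n = 100000)
  p_hat <- mean(g$target == "DRIVE")
  expect_lt(abs(p_hat - 0.75), 3 * sqrt(0.75 * 0.25 / 100000))
})

test_that("embryo modification requires both depositions and hits WILD alleles at e_cut", {
  z <- locus_genotype("female", c("DRIVE", "WILD"))
  # Cas9 without gRNA: unchanged even at e_cut = 1
  set.seed(15)
  out <- embryo_modify(z, deposition_state(TRUE, FALSE),
                       drive_params(e_cut = 1, e_mosaic = 0))
  expect_identical(out, z)
  # both deposited, e_cut = 1, all resistance r2
  out <- embryo_modify(z, deposition_state(TRUE, TRUE),
                       drive_params(e_cut = 1, e_mosaic = 0, r1_fraction = 0))
  expect_equal(out$target, c("DRIVE", "R2"))
  expect_equal(out$mosaic, c("intact", "full_cut"))
  # Monte-Carlo: cut fraction matches e_cut within 3 binomial SE
  set.seed(16)
  n <- 4000
  cut <- vapply(seq_len(n), function(i) {
    embryo_modify(z, deposition_state(TRUE, TRUE),
                  drive_params(e_cut = 0.74, e_mosaic = 0))$target[2L] == "R2"
  }, logical(1))
  expect_lt(abs(mean(cut) - 0.74), 3 * sqrt(0.74 * 0.26 / n))
})

test_that("embryo cutting can produce r1 alleles at r1_fraction and mosaics at e_mosaic", {
  z <- locus_genotype("female", c("WILD", "WILD"))
  set.seed(17)
  out <- embryo_modify(z, deposition_state(TRUE, TRUE),
                       drive_params(e_cut = 1, e_mosaic = 0, r1_fraction = 1))
  expect_equal(out$target, c("R1", "R1"))
  out <- embryo_modify(z, deposition_state(TRUE, TRUE),
                       drive_params(e_cut = 0, e_mosaic = 1))
  expect_equal(out$target, c("WILD", "WILD"))
  expect_equal(out$mosaic, c("mosaic_cut", "mosaic_cut"))
})

test_that("simulate_cross respects X-linked transmission and the Mendelian null", {
  designs <- design_catalog()
  # standard het mother, all rates zero: dsRed 1:1 at 99% CI
  params0 <- drive_params(c_f = 0, r_f = 0, e_cut = 0, e_mosaic = 0)
  set.seed(21)
  off <- simulate_cross(designs[["D6"]], params0, 4000)
  expect_lt(abs(mean(off$dsred) - 0.5), 2.58 * sqrt(0.25 / 4000))
  # sons never carry a paternal target allele at an X-linked target
  set.seed(22)
  off <- simulate_cross(designs[["D2"]], drive_params(), 2000)
  expect_true(all(is.na(off$tp[off$sex == "male"])))
  expect_true(all(!is.na(off$tp[off$sex == "female"])))
  # autosomal target: everyone has both contributions
  set.seed(23)
  off <- simulate_cross(designs[["D1_siteB_female"]], drive_params(), 1000)
  expect_false(anyNA(off$tp))
  # support alleles come one from each parent's pool
  d2 <- designs[["D2"]]
  set.seed(24)
  off <- simulate_cross(d2, drive_params(), 500)
  expect_true(all(off$s1 %in% d2$mother$support))
  expect_true(all(off$s2 %in% d2$father$support))
})

test_that("split-drive cross dsRed fraction matches the closed form (1 + c)/2", {
  set.seed(25)
  off <- simulate_cross(design_catalog()[["D2"]],
                        drive_params(c_f = 0.74, r_f = 0, e_cut = 0), 100000)
  expected <- (1 + 0.74) / 2
  expect_lt(abs(mean(off$dsred) - expected),
            3 * sqrt(expected * (1 - expected) / 100000))
})

test_that("simulate_experiment pools deterministically", {
  d <- design_catalog()[["D2"]]
  a <- simulate_experiment(d, drive_params(), 10, 40, seed = 99)
  b <- simulate_experiment(d, drive_params(), 10, 40, seed = 99)
  expect_identical(a, b)
  expect_equal(sum(a$count), 400)
  # different seed, different table (with overwhelming probability)
  c2 <- simulate_experiment(d, drive_params(), 10, 40, seed = 100)
  expect_false(identical(a, c2))
  # zero crosses: empty table
  e <- simulate_experiment(d, drive_params(), 0, 40, seed = 1)
  expect_equal(sum(e$count), 0)
  expect_equal(nrow(e), 0)
  # 40 x 100 pools to 4000
  t40 <- simulate_experiment(d, drive_params(), 40, 100, seed = 1)
  expect_equal(sum(t40$count), 4000)
})

test_that("per-cross substreams make pooled results order-independent", {
  d <- design_catalog()[["D2"]]
  res <- simulate_experiment(d, drive_params(), 6, 30, seed = 5, keep_crosses = TRUE)
  # re-running any single cross index alone reproduces its tally
  single <- simulate_experiment(d, drive_params(), 1, 30, seed = 5)
  expect_equal(as.data.frame(single), as.data.frame(res$crosses[[1L]]))
})
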