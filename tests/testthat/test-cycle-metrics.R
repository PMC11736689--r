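test_that("Boresch closed form agrees with the 6-D quadrature oracle", {
  ctx <- thermo_context(300)
  cases <- list(
    boresch_params(5, pi / 2, pi / 2, 10, 10, 10, 10, 10, 10),
    boresch_params(8, 1.2, 2.0, 20, 40, 30, 25, 15, 50),
    boresch_params(3, 1.9, 1.1, 50, 80, 60, 100, 45, 70)
  )
  for (p in cases) {
    closed <- boresch_restraint_dg(p, ctx)$value
    oracle <- boresch_quadrature_oracle(p, ctx$kT)
    expect_lt(abs(closed - oracle), 0.05)
  }
})

test_that("Boresch term obeys exact logarithmic shifts", {
  ctx <- thermo_context(300)
  p <- boresch_params(5, pi / 2, pi / 2, 10, 10, 10, 10, 10, 10)
  base <- boresch_restraint_dg(p, ctx)$value

  p2 <- boresch_params(5, pi / 2, pi / 2, 10, 10, 10, 10, 10, 10,
                       V0 = 2 * 1660)
  expect_equal(boresch_restraint_dg(p2, ctx)$value - base,
               -ctx$kT * log(2), tolerance = 1e-12)

  # scaling all six force constants by 4 shifts by -kT*ln(4^3)
  p4 <- boresch_params(5, pi / 2, pi / 2, 40, 40, 40, 40, 40, 40)
  expect_equal(boresch_restraint_dg(p4, ctx)$value - base,
               -3 * ctx$kT * log(4), tolerance = 1e-12)

  # stiffer restraints always lower the imposition free energy
  for (field in c("Kr", "KthetaA", "KphiC")) {
    args <- unclass(p)
    args[[field]] <- args[[field]] * 2
    stiffer <- do.call(boresch_params, args)
    expect_lt(boresch_restraint_dg(stiffer, ctx)$value, base)
  }
})

test_that("cycle assembly applies the double-decoupling sign convention", {
  cc0 <- cycle_components(0, 0, 0, 0, 0)
  expect_equal(assemble_cycle(cc0)$value, 0)
  expect_false(cc0$adjusted)

  cc <- cycle_components(-40, 2, -30, -5, 1)
  expect_equal(assemble_cycle(cc)$value, -16)

  cc_se <- cycle_components(
    free_energy_estimate(-40, 0.3, "TI"),
    free_energy_estimate(2, 0.1, "TI"),
    free_energy_estimate(-30, 0.2, "TI"),
    free_energy_estimate(-5, 0, "ANALYTIC"),
    0)
  expect_equal(assemble_cycle(cc_se)$stderr, sqrt(0.09 + 0.01 + 0.04))

  # linearity under component scaling
  s <- 2.5
  cc_s <- cycle_components(-40 * s, 2 * s, -30 * s, -5 * s, 1 * s)
  expect_equal(assemble_cycle(cc_s)$value, -16 * s)
})

test_that("per-system adjustment zeroes the mean signed error", {
  tbl <- benchmark_table(
    complex_id = sprintf("c%d", 1:2), system_id = c("A", "A"),
    dG_pred = c(-5, -7), dG_pred_err = c(0.1, 0.1), dG_exp = c(-6, -8))
  cc <- conf_correction(tbl)
  expect_equal(unname(cc$per_system["A"]), 1)
  expect_equal(cc$adjusted$dG_pred, c(-6, -8))

  # predictions equal to reference: zero correction, table unchanged
  tbl0 <- benchmark_table(sprintf("c%d", 1:3), rep("A", 3),
                          c(-4, -6, -9), rep(0.2, 3), c(-4, -6, -9))
  cc0 <- conf_correction(tbl0)
  expect_equal(unname(cc0$per_system["A"]), 0)
  expect_equal(cc0$adjusted$dG_pred, tbl0$dG_pred)

  # shifting one system's predictions shifts its correction, not the output
  shift <- tbl
  shift$dG_pred <- shift$dG_pred + 3.3
  ccs <- conf_correction(shift)
  expect_equal(unname(ccs$per_system["A"]), 1 + 3.3)
  expect_equal(ccs$adjusted$dG_pred, cc$adjusted$dG_pred)

  # idempotence: correcting a corrected table gives zero corrections
  cc2 <- conf_correction(cc$adjusted)
  expect_equal(unname(cc2$per_system["A"]), 0, tolerance = 1e-12)

  # undersized systems are skipped with a warning
  mixed <- benchmark_table(sprintf("c%d", 1:3), c("A", "A", "B"),
                           c(-5, -7, -3), rep(0.1, 3), c(-6, -8, -5))
  expect_warning(ccm <- conf_correction(mixed), "B")
  expect_true(is.na(ccm$per_system["B"]))
  expect_equal(ccm$adjusted$dG_pred[3], -3)
})

test_that("accuracy metrics match their definitions", {
  tbl <- benchmark_table(sprintf("c%d", 1:4), rep("A", 4),
                         c(-8, -6.5, -5, -9), c(0.4, 0.6, 1.2, 0.3),
                         c(-8, -6.5, -5, -9))
  rep1 <- accuracy_metrics(tbl, n_boot = 200, seed = 1,
                           thresholds = c(0.5, 1.0))
  expect_equal(unname(rep1$mue["value"]), 0)
  expect_equal(unname(rep1$rmse["value"]), 0)
  expect_equal(unname(rep1$pearson_r["value"]), 1)
  expect_equal(unname(rep1$spearman_rho["value"]), 1)
  # errors {0.4, 0.6, 1.2, 0.3}: 2 of 4 above 0.5, 1 of 4 above 1.0
  expect_equal(unname(rep1$frac_stderr_gt), c(50, 25))

  set.seed(3)
  tbl2 <- benchmark_table(sprintf("c%d", 1:30), rep(c("A", "B"), 15),
                          rnorm(30, -7, 2), runif(30, 0.1, 0.8),
                          rnorm(30, -7, 2))
  rep2 <- accuracy_metrics(tbl2, n_boot = 300, seed = 2)
  expect_gte(unname(rep2$rmse["value"]), unname(rep2$mue["value"]))
  expect_gt(unname(rep2$mue["stderr"]), 0)

  # zero-variance reference flags correlations as undefined
  flat <- benchmark_table(sprintf("c%d", 1:4), rep("A", 4),
                          c(-1, -2, -3, -4), rep(0.1, 4), rep(-5, 4))
  expect_warning(repf <- accuracy_metrics(flat, n_boot = 100, seed = 1),
                 "undefined")
  expect_true(is.na(repf$pearson_r["value"]))
  expect_false(repf$correlation_defined)
})

test_that("RMSE dominates MUE on random tables", {
  set.seed(1234)
  for (i in 1:200) {
    pred <- rnorm(8, 0, 3)
    ref <- rnorm(8, 0, 3)
    err <- pred - ref
    expect_gte(sqrt(mean(err^2)), mean(abs(err)))
  }
})

test_that("correlation invariances hold under monotone transforms", {
  set.seed(71)
  tbl <- benchmark_table(sprintf("c%d", 1:20), rep("A", 20),
                         rnorm(20, -6, 2), runif(20, 0, 1),
                         rnorm(20, -6, 2))
  base <- accuracy_metrics(tbl, n_boot = 100, seed = 4)
  aff <- tbl
  aff$dG_pred <- 1.7 * aff$dG_pred + 3
  m_aff <- accuracy_metrics(aff, n_boot = 100, seed = 4)
  expect_equal(unname(m_aff$pearson_r["value"]),
               unname(base$pearson_r["value"]), tolerance = 1e-10)
  mono <- tbl
  mono$dG_pred <- mono$dG_pred^3  # strictly monotone
  m_mono <- accuracy_metrics(mono, n_boot = 100, seed = 4)
  expect_equal(unname(m_mono$spearman_rho["value"]),
               unname(base$spearman_rho["value"]), tolerance = 1e-10)
})

test_that("benchmark tables roundtrip through TSV", {
  tbl <- benchmark_table(sprintf("c%d", 1:3), c("A", "A", "B"),
                         c(-5.5, -7.25, -3.125), c(0.1, 0.2, 0.3),
                         c(-6, -8, -5))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("complex_id\tsystem_id\tdg_pred\tdg_pred_err\tdg_exp",
               sprintf("%s\t%s\t%.17g\t%.17g\t%.17g", tbl$complex_id,
                       tbl$system_id, tbl$dG_pred, tbl$dG_pred_err,
                       tbl$dG_exp)), path)
  back <- read_benchmark_table(path)
  expect_equal(back$dG_pred, tbl$dG_pred, tolerance = 1e-12)
  expect_abfe_error(
    benchmark_table(c("a", "a"), c("A", "A"), c(1, 2), c(0, 0), c(1, 2)),
    "abfe_format_error")
})
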