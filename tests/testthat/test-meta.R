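test_that("one-tailed conversion halves or complements the two-tailed p", {
  expect_equal(to_one_tailed(0.04, "up", "up"), 0.02)
  expect_equal(to_one_tailed(0.04, "up", "down"), 0.98)
  expect_equal(to_one_tailed(1.0, "down", "down"), 0.5)
  # clipping keeps z-scores finite
  expect_equal(to_one_tailed(1e-20, "up", "up"), 1e-15)
  expect_error(to_one_tailed(0, "up", "up"), "\\(0, 1\\]")
  expect_error(to_one_tailed(1.2, "up", "up"), "\\(0, 1\\]")
})

make_exp <- function(id, genes, p_two, direction, class = "MP",
                     universe = genes) {
  experiment_table(id, class,
                   data.frame(gene = genes, p_two = p_two,
                              direction = direction, stringsAsFactors = FALSE),
                   universe = universe)
}

test_that("p-value matrix assembly masks unmeasured genes and resolves aliases", {
  e1 <- make_exp("e1", c("A", "C"), c(0.04, 0.5), c("up", "down"))
  pm <- assemble_pvalue_matrix(c("A", "B"), list(e1), "up")
  expect_equal(pm$nk, 1L)
  expect_true(is.na(pm$P["B", 1]))
  expect_equal(pm$P["A", 1], 0.02)

  # alias OLD1 -> A fills A's cell
  e2 <- make_exp("e2", c("OLD1", "C"), c(0.1, 0.5), c("up", "down"))
  alias <- data.frame(alias = "OLD1", symbol = "A", stringsAsFactors = FALSE)
  pm2 <- assemble_pvalue_matrix(c("A", "B"), list(e2), "up", alias)
  expect_equal(pm2$P["A", 1], 0.05)
  expect_equal(pm2$nk, 1L)

  # full coverage: 20 genes x 5 experiments -> nk = 100
  genes <- sprintf("g%02d", 1:20)
  exps <- lapply(1:5, function(j)
    make_exp(paste0("x", j), genes, runif(20, 0.01, 1),
             sample(c("up", "down"), 20, TRUE)))
  expect_equal(assemble_pvalue_matrix(genes, exps, "up")$nk, 100L)

  expect_error(assemble_pvalue_matrix(character(0), list(e1), "up"), "empty")
  expect_error(assemble_pvalue_matrix("A", list(), "up"), "empty")
})

test_that("Fisher combination matches the chi-square closed forms", {
  expect_equal(fisher_combine(pm_from(0.2))$p_combined, 0.2)
  r <- fisher_combine(pm_from(c(0.05, 0.05)))
  expect_equal(r$statistic, 11.9829, tolerance = 1e-4)
  expect_equal(r$df, 4L)
  # chi-square(4) survival: (1 + T/2) exp(-T/2)
  expect_equal(r$p_combined, (1 + r$statistic / 2) * exp(-r$statistic / 2))
  expect_equal(r$p_combined, 0.01747866, tolerance = 1e-6)
  expect_equal(fisher_combine(pm_from(rep(1 - 1e-15, 3)))$p_combined, 1,
               tolerance = 1e-9)
})

test_that("Stouffer combination matches the normal-quantile closed forms", {
  expect_equal(stouffer_combine(pm_from(rep(0.5, 4)))$statistic, 0)
  expect_equal(stouffer_combine(pm_from(rep(0.5, 4)))$p_combined, 0.5)
  r <- stouffer_combine(pm_from(c(0.05, 0.05)))
  expect_equal(r$statistic, 2 * qnorm(0.95) / sqrt(2))
  expect_equal(r$statistic, 2.326174, tolerance = 1e-6)
  expect_equal(r$p_combined, 0.01000463, tolerance = 1e-6)
  expect_equal(stouffer_combine(pm_from(0.123))$p_combined, 0.123)
})

test_that("binomial combination uses the exact binomial upper tail", {
  p <- c(rep(0.01, 3), rep(0.5, 7))
  r <- binomial_combine(pm_from(p), p_h = 0.05)
  expect_equal(r$statistic, 3L)
  expect_equal(r$p_combined, 0.01150356, tolerance = 1e-6)
  expect_equal(binomial_combine(pm_from(rep(0.9, 6)))$p_combined, 1)
  expect_equal(binomial_combine(pm_from(rep(0.2, 4)), p_h = 0.5)$p_combined,
               0.0625)
  expect_error(binomial_combine(pm_from(matrix(NA_real_, 1, 1))), "nk = 0")
})

test_that("smaller p-values never increase the combined p", {
  set.seed(9)
  for (rep in 1:20) {
    p <- runif(8)
    p2 <- p
    i <- sample(8, 1)
    p2[i] <- p[i] * runif(1)
    expect_lte(fisher_combine(pm_from(p2))$p_combined,
               fisher_combine(pm_from(p))$p_combined)
    expect_lte(stouffer_combine(pm_from(p2))$p_combined,
               stouffer_combine(pm_from(p))$p_combined)
  }
})

test_that("background bias estimation is seeded and centered on null tables", {
  tabs <- simulate_pvalue_tables(n_genes = 5000, n_experiments = 4, seed = 21)
  b1 <- background_bias(tabs$experiments, m = 20, R = 150, seed = 5)
  b2 <- background_bias(tabs$experiments, m = 20, R = 150, seed = 5)
  expect_identical(b1, b2)
  # null Z is ~N(0,1), but all draws share one realized p-value pool, so the
  # conditional mean carries an extra sqrt(m/n_genes) component
  expect_lt(abs(b1$mean_Z), 3.5 * sqrt(1 / 150 + 20 / 5000))
  expect_equal(b1$sd_Z, 1, tolerance = 0.25)

  b_single <- background_bias(tabs$experiments, m = 20, R = 1, seed = 5)
  expect_true(is.finite(b_single$mean_Z))
  expect_error(background_bias(tabs$experiments, m = 6000, R = 2, seed = 1),
               "universe smaller")
})

test_that("bias-corrected Stouffer shifts Z by the background mean", {
  bias <- structure(list(m = 20, R = 10, mean_Z = 0.8, sd_Z = 1, seed = 1,
                         tested_direction = "up"), class = "BiasEstimate")
  pm_up <- pm_from(rep(0.2, 5), "up")
  r <- corrected_stouffer(pm_up, bias)
  expect_equal(r$corrected_Z, r$statistic - 0.8)
  expect_equal(r$corrected_p, pnorm(r$corrected_Z, lower.tail = FALSE))
  pm_dn <- pm_from(rep(0.2, 5), "down")
  r2 <- corrected_stouffer(pm_dn, bias)
  expect_equal(r2$corrected_Z, r2$statistic + 0.8)
  bias0 <- bias; bias0$mean_Z <- 0
  expect_equal(corrected_stouffer(pm_up, bias0)$corrected_Z,
               stouffer_combine(pm_up)$statistic)
  expect_error(corrected_stouffer(pm_up, bias, tested_direction = "down"),
               "does not match")
})

test_that("class score multiplies directional p-values into log-odds", {
  sc <- class_score(0.01, 0.1)
  expect_equal(sc$combined_p, 0.001)
  expect_equal(sc$log_odds, 3)
  expect_equal(class_score(1, 1)$log_odds, 0)
  expect_equal(class_score(1e-6, 1e-4)$log_odds, 10)
  expect_error(class_score(0, 0.1), "0")
})

test_that("run_meta reports every signature x class with deterministic correction", {
  set.seed(31)
  genes <- sprintf("G%05d", 1:400)
  mk <- function(id, class, seed) {
    set.seed(seed)
    make_exp(id, genes, runif(400, 0.001, 1),
             sample(c("up", "down"), 400, TRUE), class = class)
  }
  exps <- list(mk("a1", "MP", 1), mk("a2", "MP", 2), mk("b1", "GRD", 3))
  sigs <- list(sigA = list(plus = genes[1:10], minus = genes[11:20]),
               sigB = list(plus = genes[21:30], minus = genes[31:40]))
  res <- run_meta(sigs, exps, bias_R = 50, seed = 7)
  expect_equal(nrow(res), 4L)  # 2 signatures x 2 classes
  expect_true(all(c("fisher_p_up", "stouffer_z_dn", "binomial_p_up",
                    "corrected_z_up", "class_log_odds") %in% names(res)))
  res2 <- run_meta(sigs, exps, bias_R = 50, seed = 7)
  expect_identical(res, res2)
  # without correction the corrected columns are absent
  res3 <- run_meta(sigs, exps, bias_R = 0)
  expect_false("corrected_z_up" %in% names(res3))
})
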