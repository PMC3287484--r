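test_that("sign function is strict with no tolerance", {
  expect_equal(mega_sign(c(3.2, 0, -1e-12)), c(1, 0, -1))
  expect_error(mega_sign(NaN), "finite")
})

test_that("single-column scores match hand-derived pairwise sums", {
  # strictly increasing column: all 10 pairwise differences sum to 20
  expect_equal(axis_score(column_grid(c(0, 1, 2, 3, 4)), "N"), 20)
  # fluctuation cancels
  expect_equal(axis_score(column_grid(c(0, 1, 0, 1, 0)), "N"), 0)
  # leap at rows 3->4 (stage N1 -> N2) weighted 10:
  # unweighted score 6 plus (10 - 1) x the consecutive jump of 1
  b <- make_beta(4, c(1, 2), 10)
  expect_equal(axis_score(column_grid(c(0, 0, 0, 1, 1)), "N", beta = b), 15)
  # weight 1 reproduces the unweighted score
  expect_equal(axis_score(column_grid(c(0, 0, 0, 1, 1)), "N",
                          beta = make_beta(4, c(1, 2), 1)), 6)
})

test_that("closed-form contrast equals the pairwise accumulation", {
  expect_equal(column_contrast(c(0, 1, 2, 3, 4)), 20)
  expect_equal(column_contrast(rep(2.5, 5)), 0)
  expect_equal(column_contrast(c(0, 1, 0, 1, 0)), 0)
  set.seed(42)
  for (rep in 1:200) {
    g <- random_grid()
    oracle <- sum(apply(g$X, 2, column_contrast))
    expect_lt(abs(axis_score(g, "N") - oracle), 1e-9)
  }
})

test_that("score is antisymmetric, transpose-symmetric and shift/scale stable", {
  set.seed(7)
  for (rep in 1:25) {
    g <- random_grid()
    neg <- make_grid(-g$X)
    expect_equal(axis_score(neg, "N"), -axis_score(g, "N"))
    expect_equal(normalize_score(axis_score(neg, "N"), neg)$normalized,
                 -normalize_score(axis_score(g, "N"), g)$normalized)
    # transpose symmetry: TE(X) = LE(t(X))
    expect_equal(axis_score(g, "T"), axis_score(make_grid(t(g$X)), "N"))
    # normalized score invariant under X -> cX
    c_pos <- runif(1, 0.1, 5)
    gs <- make_grid(c_pos * g$X)
    expect_equal(normalize_score(axis_score(gs, "N"), gs)$normalized,
                 normalize_score(axis_score(g, "N"), g)$normalized)
    # raw score invariant under adding a constant to a whole column
    # (baseline included, so the contrast weights sum to zero)
    shifted <- g$X
    shifted[, 3] <- shifted[, 3] + 1.3
    expect_equal(sum(apply(shifted, 2, column_contrast)), axis_score(g, "N"))
  }
})

test_that("ascending arrangement maximizes the column contribution", {
  # brute force over all 120 permutations of 5 values
  vals <- c(-1.2, 0.3, 0.7, 1.9, 2.4)
  perms <- expand.grid(a = 1:5, b = 1:5, c = 1:5, d = 1:5, e = 1:5)
  perms <- perms[apply(perms, 1, function(r) length(unique(r)) == 5L), ]
  contrib <- apply(perms, 1, function(r) column_contrast(vals[unlist(r)]))
  expect_equal(max(contrib), column_contrast(sort(vals)))
  best <- perms[which.max(contrib), ]
  expect_equal(vals[unlist(best)], sort(vals))
})

test_that("a strictly increasing column is positive; a constant one is zero", {
  set.seed(11)
  for (rep in 1:20) {
    col <- c(0, cumsum(runif(4, 0.01, 1)))
    expect_gt(axis_score(column_grid(col), "N"), 0)
  }
  expect_equal(axis_score(column_grid(c(0, 2, 2, 2, 2)), "N"),
               column_contrast(c(0, 2, 2, 2, 2)))
})

test_that("leaping factor promotes exactly the genes jumping at the transition", {
  b10 <- make_beta(4, c(1, 2), 10)
  jumpy <- column_grid(c(0, 0.2, 0.3, 1.5, 1.6))   # positive jump at N1->N2
  flat <- column_grid(c(0, 0.5, 1.0, 1.0, 1.5))    # flat at N1->N2
  expect_gt(axis_score(jumpy, "N", beta = b10), axis_score(jumpy, "N"))
  expect_equal(axis_score(flat, "N", beta = b10), axis_score(flat, "N"))
})

test_that("make_beta places the weight and rejects bad transitions", {
  b <- make_beta(4, c(1, 2), 10)
  expect_equal(b[3, 4], 10)
  expect_equal(sum(b != 1), 1L)
  expect_error(make_beta(4, c(0, 3), 10), "consecutive")
  expect_error(check_beta(matrix(2, 5, 5), 4), "superdiagonal")
})

test_that("alpha consistency hook reduces to the base score at alpha = 0", {
  set.seed(3)
  g <- random_grid()
  expect_equal(axis_score(g, "N", alpha = 0), axis_score(g, "N"))
  # a perfectly monotone column gets amplified by (1 + alpha)
  mono <- column_grid(c(0, 1, 2, 3, 4))
  expect_equal(axis_score(mono, "N", alpha = 0.5), 1.5 * 20)
})

test_that("normalization divides by the overall grid SD with degenerate guard", {
  g <- column_grid(c(0, 1, 2, 3, 4))
  s <- normalize_score(20, g)
  expect_equal(s$normalized, 20 / sd(g$X[!g$missing]))
  expect_equal(s$direction, 1)
  # all-zero grid -> 0, not NaN
  z <- make_grid(matrix(0, 5, 5))
  expect_equal(normalize_score(0, z)$normalized, 0)
})

test_that("missing cells skip pairwise terms without breaking scoring", {
  X <- matrix(0, 5, 5)
  X[, 2] <- c(0, 1, 2, 3, 4)
  X[4, 2] <- NA  # N2 cell missing in column T1
  g <- make_grid(X)
  # remaining pairs among rows {0,1,2,4}: sum of x_j - x_i over 6 pairs
  vals <- c(0, 1, 2, 4)
  expected <- sum(outer(vals, vals, "-")[lower.tri(matrix(0, 4, 4))])
  expect_equal(axis_score(g, "N"), expected)
  # fully missing grid errors
  Xa <- matrix(NA_real_, 5, 5); Xa[1, ] <- 0; Xa[, 1] <- 0
  expect_error(axis_score(make_grid(Xa), "N"), "missing")
})

test_that("select_meg returns disjoint top/bottom sets with lexical ties", {
  sc <- data.frame(gene = c("A", "B", "C", "D"),
                   normalized = c(3, -2, 1, -5),
                   excluded = FALSE, axis = "N")
  meg <- select_meg(sc, k = 1)
  expect_equal(meg$plus, "A")
  expect_equal(meg$minus, "D")
  expect_equal(meg$names_plus, "N-MEG+")

  # boundary tie broken by gene symbol ascending
  sc2 <- data.frame(gene = c("ZZ", "AA", "MM", "BB"),
                    normalized = c(2, 2, -1, -1),
                    excluded = FALSE, axis = "N")
  meg2 <- select_meg(sc2, k = 1)
  expect_equal(meg2$plus, "AA")
  expect_equal(meg2$minus, "BB")

  expect_error(select_meg(sc, k = 3), "at least 6")
})

test_that("mega_score ranks a planted monotone gene above noise genes", {
  sim <- simulate_cohort(sim_config(seed = 5, n_mono_up = 5, n_mono_down = 5,
                                    n_leap = 0, n_fluct = 5, n_mono_up_t = 0,
                                    n_null = 35))
  sc <- mega_score(sim$expr, sim$annotations, axis = "N")
  expect_equal(nrow(sc), 50L)
  meg <- select_meg(sc, k = 5)
  arch <- sim$truth$archetype[match(meg$plus, sim$truth$gene)]
  expect_true(all(arch == "mono_up"))
  archm <- sim$truth$archetype[match(meg$minus, sim$truth$gene)]
  expect_true(all(archm == "mono_down"))
})
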