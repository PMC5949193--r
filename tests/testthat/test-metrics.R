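# Overlap fractions, summary convention, ICC, k-fold machinery.

test_that("fractions reproduce the defining set arithmetic", {
  a <- square_mask(20, 20, 5, 5, 10, 10)
  fr <- fractions(a, a)
  expect_equal(fr$TPF, 100)
  expect_equal(fr$FNF, 0)
  expect_equal(fr$FF, 100)

  # same square shifted 2 columns: overlap 80, misses 20, extras 20
  b <- square_mask(20, 20, 5, 7, 10, 10)
  fr2 <- fractions(b, a)
  expect_equal(fr2$TPF, 80)
  expect_equal(fr2$FNF, 20)
  expect_equal(fr2$FF, 60)

  # superset with as many extras as the reference: FF forced to 0
  s <- square_mask(30, 30, 5, 5, 10, 10)
  big <- binary_mask(s$pixels | square_mask(30, 30, 5, 15, 10, 10)$pixels)
  fr3 <- fractions(big, s)
  expect_equal(fr3$TPF, 100)
  expect_equal(fr3$FNF, 0)
  expect_equal(fr3$FF, 0)

  expect_error(fractions(a, binary_mask(matrix(FALSE, 20, 20))), "empty")
  expect_error(fractions(a, square_mask(10, 10, 0, 0, 5, 5)), "differ")
})

test_that("fraction identities hold over random mask pairs", {
  set.seed(123)
  for (i in 1:200) {
    nr <- sample(8:24, 1); nc <- sample(8:24, 1)
    aT <- matrix(runif(nr * nc) < runif(1, 0.2, 0.7), nr, nc)
    if (!any(aT)) aT[1] <- TRUE
    aS <- matrix(runif(nr * nc) < runif(1, 0.1, 0.8), nr, nc)
    fr <- fractions(binary_mask(aS), binary_mask(aT))
    # pixel-count oracle
    expect_identical(fr$a_TP, sum(aS & aT))
    expect_identical(fr$a_FN, sum(aT & !aS))
    expect_identical(fr$a_FP, sum(aS & !aT))
    expect_equal(fr$TPF + fr$FNF, 100)
    expect_lte(fr$FF, fr$TPF)
    expect_identical(fr$FF == 100, identical(aS, aT))
  }
})

test_that("the halfwidth convention reproduces the printed +/- columns", {
  # sigma 3.64 over 50 cases prints as +/- 1.01
  v1 <- scale(rnorm(50)) * 3.64 + 90
  s1 <- summarize_ci(as.numeric(v1))
  expect_equal(round(s1$halfwidth, 2), 1.01)
  expect_equal(s1$halfwidth, 1.96 * s1$sigma / sqrt(50), tolerance = 1e-9)

  # sigma 7.02 over 100 cases prints as +/- 1.38
  v2 <- scale(rnorm(100)) * 7.02 + 90
  s2 <- summarize_ci(as.numeric(v2))
  expect_equal(round(s2$halfwidth, 2), 1.38)

  s0 <- summarize_ci(rep(5, 10))
  expect_equal(s0$sigma, 0)
  expect_equal(s0$halfwidth, 0)
})

test_that("icc_pair matches the definitional cases", {
  x <- c(1, 2, 3, 4, 6)
  same <- icc_pair(x, x)
  expect_equal(same$single, 1)
  expect_equal(same$average, 1)

  off_c <- icc_pair(x, x + 3, model = "consistency")
  off_a <- icc_pair(x, x + 3, model = "agreement")
  expect_equal(off_c$single, 1)
  expect_lt(off_a$single, 1)

  expect_error(icc_pair(c(1, 1, 1), c(1, 1, 1)), "between-subject")
  expect_error(icc_pair(1:2, 1:2), "3 subjects")
})

test_that("icc_pair equals the ANOVA sums-of-squares oracle", {
  x <- c(1, 2, 3, 4); y <- c(1.1, 2.0, 3.2, 3.9)
  got <- icc_pair(x, y)
  want <- icc_oracle(x, y)
  expect_equal(got$single, want$single, tolerance = 1e-10)
  expect_equal(got$average, want$average, tolerance = 1e-10)
  got_a <- icc_pair(x, y, model = "agreement")
  expect_equal(got_a$single, want$single_agreement, tolerance = 1e-10)

  set.seed(77)
  for (i in 1:200) {
    n <- sample(3:10, 1)
    xx <- rnorm(n, 50, 10)
    yy <- xx + rnorm(n, 0, 3) + rnorm(1, 0, 2)
    got <- icc_pair(xx, yy)
    want <- icc_oracle(xx, yy)
    expect_equal(got$single, want$single, tolerance = 1e-10)
    expect_equal(got$average, want$average, tolerance = 1e-10)
    if (got$single >= 0) expect_gte(got$average, got$single)
    expect_lte(got$single, 1)
    expect_lte(got$average, 1)
  }
})

test_that("icc_matrix summarizes pairwise tables and r-bar", {
  set.seed(5)
  base <- rnorm(12, 100, 15)
  areas <- rbind(computer = base + rnorm(12, 0, 6),
                 e1 = base + rnorm(12, 0, 3),
                 e2 = base + rnorm(12, 0, 3))
  im <- icc_matrix(areas)
  expect_true(all(abs(im$single - t(im$single)) < 1e-12, na.rm = TRUE))
  expect_equal(im$r_bar[["computer"]],
               mean(im$single["computer", c("e1", "e2")]))

  two <- icc_matrix(areas[1:2, ])
  expect_equal(two$r_bar[[1]], two$single[1, 2])
  expect_equal(two$r_bar[[1]], two$r_bar[[2]])
})

test_that("k-fold splits are balanced, disjoint, covering and seeded", {
  f <- kfold_split(1000, 10, seed = 3)
  expect_true(all(lengths(f) == 100L))
  expect_identical(sort(unlist(f)), 1:1000)

  singles <- kfold_split(7, 7, seed = 1)
  expect_true(all(lengths(singles) == 1L))

  expect_identical(kfold_split(37, 5, seed = 9), kfold_split(37, 5, seed = 9))
  expect_error(kfold_split(5, 1), "at least 2")
})

test_that("convergence tables keep the row identities", {
  fx <- aam_fixture()
  item <- fx$test[[1]]
  init <- perturb_shape(item$landmarks, seed = 41)
  fit <- fit_aam(item$image, fx$model, init, n_iterations = 6)
  refs <- list(item$mask, item$mask)
  tab <- convergence_table(fit$shapes, refs, dim(item$image$pixels),
                           item$image$spacing)
  expect_equal(nrow(tab), 7L)
  expect_equal(tab$iteration, 0:6)
  expect_equal(tab$TPF_mean, (tab$TPF_1 + tab$TPF_2) / 2, tolerance = 1e-9)
  expect_equal(tab$TPF_mean + tab$FNF_mean, rep(100, 7), tolerance = 1e-9)

  # constant shapes give identical rows
  tab2 <- convergence_table(list(init$points, init$points, init$points),
                            refs, dim(item$image$pixels),
                            item$image$spacing)
  expect_equal(tab2$FF_mean, rep(tab2$FF_mean[1], 3))
})

test_that("crossval rejects a degenerate fold request", {
  ds <- generate_dataset(4, phantom_spec(), seed = 2)
  expect_error(crossval(ds, k = 1, seed = 1), "at least 2")
})
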