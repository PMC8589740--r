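test_that("pearson_r matches the product-moment formula", {
  expect_equal(pearson_r(1:10, 1:10), 1)
  expect_equal(pearson_r(1:10, -(1:10)), -1)
  x <- c(0, 1, 2, 3); y <- c(0, 1, 1, 3)
  # direct formula oracle
  r_direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_r(x, y), r_direct)
  expect_equal(r_direct, 0.9233805, tolerance = 1e-7)
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(pearson_r(1:2, 1:2), "n >= 3")
})

test_that("grade agreement counts identical and within-one cases", {
  ga <- grade_agreement(c(0, 1, 2), c(0, 1, 2), G = 3)
  expect_equal(ga$pct_identical, 100)
  expect_equal(sum(diag(ga$confusion)), 3)
  ga2 <- grade_agreement(c(0, 1, 2), c(1, 2, 3), G = 3)
  expect_equal(ga2$pct_identical, 0)
  expect_equal(ga2$pct_within_one, 100)
  expect_error(grade_agreement(c(0, 5), c(0, 1), G = 4), "range")

  set.seed(31)
  for (rep in 1:20) {
    G <- sample(3:4, 1)
    n <- sample(5:40, 1)
    a <- sample(0:G, n, TRUE)
    b <- sample(0:G, n, TRUE)
    ga <- grade_agreement(a, b, G)
    # brute-force loop oracle
    id <- 0; within <- 0
    conf <- matrix(0L, G + 1, G + 1)
    for (i in seq_len(n)) {
      if (a[i] == b[i]) id <- id + 1
      if (abs(a[i] - b[i]) <= 1) within <- within + 1
      conf[a[i] + 1, b[i] + 1] <- conf[a[i] + 1, b[i] + 1] + 1L
    }
    expect_equal(ga$pct_identical, 100 * id / n)
    expect_equal(ga$pct_within_one, 100 * within / n)
    expect_equal(unname(ga$confusion), unname(conf))
    expect_equal(sum(ga$confusion), n)
    expect_gte(ga$pct_within_one, ga$pct_identical)
    # symmetry under swapping sources
    swapped <- grade_agreement(b, a, G)
    expect_equal(swapped$pct_identical, ga$pct_identical)
    expect_equal(swapped$pct_within_one, ga$pct_within_one)
  }
})

test_that("normality agreement dichotomizes at grade > 1", {
  expect_equal(normality_agreement(c(0, 1, 2, 3), c(1, 0, 3, 2)), 100)
  expect_equal(normality_agreement(c(1, 1), c(2, 2)), 0)
  set.seed(32)
  for (rep in 1:10) {
    a <- sample(0:4, 15, TRUE); b <- sample(0:4, 15, TRUE)
    oracle <- 100 * sum((a > 1) == (b > 1)) / 15
    expect_equal(normality_agreement(a, b), oracle)
  }
})

test_that("weighted kappa is 1 on agreement, 0 at chance, matches oracle", {
  diag_m <- diag(c(5, 3, 7, 2))
  expect_equal(weighted_kappa(diag_m), 1)
  # independence: observed equals the marginal product
  p <- c(0.2, 0.3, 0.5); q <- c(0.5, 0.25, 0.25)
  indep <- outer(p, q) * 400
  expect_equal(weighted_kappa(indep), 0, tolerance = 1e-10)
  m3 <- matrix(c(2, 1, 0, 1, 2, 1, 0, 1, 2), 3, 3, byrow = TRUE)
  # direct-formula oracle with explicit loops
  oracle_kappa <- function(conf, quad = TRUE) {
    G <- nrow(conf) - 1
    n <- sum(conf)
    num <- 0; den <- 0
    for (i in 0:G) for (j in 0:G) {
      w <- if (quad) ((i - j) / G)^2 else as.numeric(i != j)
      e <- sum(conf[i + 1, ]) * sum(conf[, j + 1]) / n
      num <- num + w * conf[i + 1, j + 1]
      den <- den + w * e
    }
    1 - num / den
  }
  expect_equal(weighted_kappa(m3), oracle_kappa(m3))
  set.seed(33)
  for (rep in 1:20) {
    G <- sample(2:4, 1)
    conf <- matrix(rpois((G + 1)^2, 3), G + 1, G + 1)
    conf <- conf + diag(G + 1)  # keep marginals nondegenerate
    expect_equal(weighted_kappa(conf), oracle_kappa(conf),
                 tolerance = 1e-12)
    # identity weighting reduces to unweighted Cohen kappa
    po <- sum(diag(conf)) / sum(conf)
    pe <- sum(rowSums(conf) * colSums(conf)) / sum(conf)^2
    expect_equal(weighted_kappa(conf, "identity"),
                 (po - pe) / (1 - pe), tolerance = 1e-12)
  }
  expect_error(weighted_kappa(matrix(c(5, 3, 0, 0), 2, 2)), "marginal")
})

test_that("Bland-Altman statistics match the direct formula", {
  x <- c(1, 2, 3, 4)
  ba0 <- bland_altman(x, x)
  expect_equal(ba0$mean_diff, 0)
  expect_equal(ba0$loa_low, 0)
  ba1 <- bland_altman(x, x + 1)
  expect_equal(ba1$mean_diff, -1)
  expect_equal(ba1$loa_high, -1)
  set.seed(34)
  a <- rnorm(50); b <- rnorm(50)
  ba <- bland_altman(a, b)
  d <- a - b
  expect_equal(ba$mean_diff, mean(d))
  expect_equal(ba$loa_low, mean(d) - 1.96 * sd(d))
  expect_equal(ba$loa_high, mean(d) + 1.96 * sd(d))
  expect_equal(ba$pairs$mean, (a + b) / 2)
})

test_that("Bland-Altman limits cover ~95% of Gaussian differences", {
  set.seed(35)
  x <- rnorm(200); y <- x + rnorm(200, 0.2, 0.5)
  ba <- bland_altman(x, y)
  inside <- mean(ba$pairs$diff >= ba$loa_low & ba$pairs$diff <= ba$loa_high)
  expect_gte(inside, 0.90)
})

test_that("agreement reports assemble all statistics per scale", {
  set.seed(36)
  g <- runif(40, 0, 3)
  rep_self <- agreement_report(g, g, scale = "gca")
  expect_equal(rep_self$pearson_r, 1)
  expect_equal(rep_self$pct_identical, 100)
  expect_equal(rep_self$pct_within_one, 100)
  expect_equal(rep_self$kappa_quadratic, 1)

  ref <- data.frame(subject_id = sprintf("s%02d", 1:30),
                    mta = runif(30, 0, 4), gca = runif(30, 0, 3),
                    fazekas = runif(30, 0, 3))
  test <- ref
  test$mta <- pmin(pmax(test$mta + rnorm(30, 0, 0.3), 0), 4)
  fr <- full_report(ref, test)
  expect_equal(nrow(fr$summary), 3)
  expect_setequal(fr$summary$scale, c("mta", "gca", "fazekas"))
  expect_true(all(c("pearson_r", "pct_identical", "pct_within_one",
                    "pct_normality_identical", "kappa_quadratic") %in%
                    names(fr$summary)))
  bad <- ref[1:20, ]
  expect_error(full_report(bad, test), "mismatch")
})
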