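test_that("codon_gc counts GC per codon position", {
  x <- codon_gc("ATG")
  expect_equal(unname(x[c("gc1", "gc2", "gc3")]), c(0, 0, 100))
  expect_equal(unname(x["gc"]), 100 / 3)

  y <- codon_gc("GCAGCT")
  expect_equal(unname(y[c("gc1", "gc2", "gc3")]), c(100, 100, 0))
  expect_equal(unname(y["gc"]), 200 / 3)

  expect_error(codon_gc("ATGA"), "multiple of 3")

  # a codon with an ambiguity code is skipped at all three positions
  z <- codon_gc("ATGNGGGGG")  # NGG skipped, counts over ATG + GGG
  expect_equal(unname(z["n_codons"]), 2)
  expect_equal(unname(z[c("gc1", "gc2", "gc3")]), c(50, 50, 100))

  # stop-codon exclusion drops the final codon
  w <- codon_gc("ATGGGGTAA", include_stop = FALSE)
  expect_equal(unname(w["n_codons"]), 2)
  expect_equal(unname(w["gc1"]), 50)
  expect_equal(unname(w["gc3"]), 100)
})

test_that("gc equals the mean of gc1, gc2, gc3 and matches brute force", {
  set.seed(71)
  for (i in 1:100) {
    s <- random_cds(sample(3:60, 1), p_ambig = 0.05)
    got <- codon_gc(s)
    want <- oracle_codon_gc(s)
    expect_equal(unname(got[c("gc", "gc1", "gc2", "gc3")]), want)
    expect_equal(unname(got["gc"]),
                 mean(got[c("gc1", "gc2", "gc3")]), tolerance = 1e-9)
  }
})

test_that("major-axis regression is exact on collinear input", {
  x <- c(1, 2, 3, 4, 5)
  fit <- orthogonal_regression(x, x)
  expect_equal(fit$slope, 1)
  expect_equal(fit$intercept, 0)
  expect_equal(fit$r, 1)
  expect_equal(fit$n, 5L)

  # zero-scatter agreement with OLS on any collinear line
  fit2 <- orthogonal_regression(x, 2 * x + 1)
  expect_equal(fit2$slope, 2, tolerance = 1e-9)
  expect_equal(fit2$intercept, 1, tolerance = 1e-9)
})

test_that("major-axis regression is symmetric and shift-equivariant", {
  set.seed(13)
  x <- rnorm(200, 45, 5)
  y <- 0.7 * x + rnorm(200, 0, 2)
  fit <- orthogonal_regression(x, y)
  swap <- orthogonal_regression(y, x)
  expect_equal(swap$slope, 1 / fit$slope, tolerance = 1e-12)
  expect_equal(swap$r, fit$r, tolerance = 1e-12)

  shifted <- orthogonal_regression(x + 10, y + 10)
  expect_equal(shifted$slope, fit$slope, tolerance = 1e-12)
  expect_equal(shifted$intercept, fit$intercept + 10 * (1 - fit$slope),
               tolerance = 1e-9)

  # r is the plain Pearson correlation
  expect_equal(fit$r, cor(x, y), tolerance = 1e-12)
})

test_that("major-axis regression handles degenerate input", {
  expect_error(orthogonal_regression(1:2, 1:2), "at least 3")
  expect_error(orthogonal_regression(rep(1, 5), rep(2, 5)), "variance")
  expect_error(orthogonal_regression(rep(1, 5), c(1, 2, 3, 4, 5)),
               "variance")
})

test_that("reduced major axis gives the sd-ratio slope", {
  set.seed(3)
  x <- rnorm(100); y <- 0.5 * x + rnorm(100, 0, 0.4)
  fit <- orthogonal_regression(x, y, method = "rma")
  expect_equal(fit$slope, sign(cov(x, y)) * sd(y) / sd(x),
               tolerance = 1e-12)
})

test_that("major axis of a bivariate normal cloud is recovered", {
  # covariance built from eigenvectors along slope 0.8
  u <- c(1, 0.8) / sqrt(1.64); v <- c(-0.8, 1) / sqrt(1.64)
  Sigma <- 25 * tcrossprod(u) + 1 * tcrossprod(v)
  r_pop <- Sigma[1, 2] / sqrt(Sigma[1, 1] * Sigma[2, 2])
  set.seed(29)
  xy <- MASS::mvrnorm(2000, c(40, 45), Sigma)
  fit <- orthogonal_regression(xy[, 1], xy[, 2])
  expect_lt(abs(fit$slope - 0.8), 0.03)
  expect_lt(abs(fit$r - r_pop), 0.02)
})

test_that("histogram overlap is 1 for identical sets and 0 for disjoint", {
  set.seed(31)
  a <- runif(500, 30, 50)
  expect_equal(histogram_overlap(a, a), 1)
  expect_equal(histogram_overlap(a, a + 40), 0)
})

test_that("gc_distributions reports means and overlaps per statistic", {
  set.seed(37)
  tab <- codon_gc_table(setNames(replicate(20, random_cds(30)),
                                 paste0("g", 1:20)))
  d <- gc_distributions(tab, tab)
  expect_equal(unname(d$overlap), rep(1, 4))
  expect_equal(nrow(d$means), 8L)
  # a single pair is degenerate but not an error
  d1 <- gc_distributions(tab[1, ], tab[1, ])
  expect_equal(unname(d1$overlap), rep(1, 4))
})

test_that("pairwise fits cover all position pairs and flag degenerate ones", {
  set.seed(43)
  n <- 4000
  gc1 <- rnorm(n, 45, 6)
  gc2 <- gc1 + rnorm(n, 0, 2)          # tightly coupled
  gc3 <- rnorm(n, 50, 8)               # independent of gc1
  mk <- function(g1, g2, g3) {
    data.frame(id = paste0("g", seq_len(n)), gc = (g1 + g2 + g3) / 3,
               gc1 = g1, gc2 = g2, gc3 = g3, n_codons = 300)
  }
  a <- mk(gc1, gc2, gc3)
  b <- mk(gc1, gc2, rep(20, n))        # constant gc3 in species B
  fits <- pairwise_position_fits(a, b)
  expect_equal(nrow(fits), 6L + 6L + 4L)

  r12 <- fits$r[fits$scope == "within_a" & fits$x_stat == "gc1" &
                  fits$y_stat == "gc2"]
  expect_gt(r12, 0.9)
  r13 <- fits$r[fits$scope == "within_a" & fits$x_stat == "gc1" &
                  fits$y_stat == "gc3"]
  expect_lt(abs(r13), 0.05)
  # zero-variance fits are reported as absent, not as errors
  bad <- fits[fits$scope == "within_b" & fits$y_stat == "gc3" &
                fits$x_stat == "gc1", ]
  expect_true(is.na(bad$slope))
})
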