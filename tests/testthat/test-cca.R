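test_that("CCA degenerates to |Pearson r| for single-variable blocks", {
  set.seed(2)
  x <- matrix(rnorm(30), 30, 1, dimnames = list(NULL, "x1"))
  y <- matrix(0.5 * x + rnorm(30), 30, 1, dimnames = list(NULL, "y1"))
  fit <- cca_fit(x, y)
  expect_equal(fit$correlations, abs(cor(x, y)[1, 1]), tolerance = 1e-12)
  # single-variable loading is 1 up to the sign convention
  expect_equal(abs(fit$x_loadings[1, 1]), 1, tolerance = 1e-12)
  # Rao's F reduces to the squared Pearson t statistic on F(1, n - 2)
  expect_equal(fit$wilks$p.value[1], pearson_p(cor(x, y)[1, 1], 30),
               tolerance = 1e-10)
})

test_that("linearly dependent blocks give canonical correlations of 1", {
  set.seed(3)
  x <- random_block(12, 2, "X")
  m <- matrix(c(1, 2, -1, 0.5), 2, 2)
  y <- x %*% m
  colnames(y) <- c("Y1", "Y2")
  fit <- cca_fit(x, y)
  expect_equal(fit$correlations, c(1, 1), tolerance = 1e-8)
})

test_that("correlations agree with stats::cancor and a grid-search oracle", {
  set.seed(10)
  x <- random_block(10, 2, "X")
  y <- random_block(10, 2, "Y")
  fit <- cca_fit(x, y)
  cc <- stats::cancor(x, y)
  expect_equal(fit$correlations, cc$cor, tolerance = 1e-8)

  # brute force over dense unit-norm coefficient directions on the
  # standardized blocks
  theta <- seq(0, pi, length.out = 2001)
  dirs <- rbind(cos(theta), sin(theta))
  ua <- scale(x) %*% dirs
  vb <- scale(y) %*% dirs
  best <- max(abs(cor(ua, vb)))
  expect_equal(fit$correlations[1], best, tolerance = 1e-3)
})

test_that("wilks, eigenvalue and Rao's F reproduce the algebra", {
  r <- c(0.794, 0.709, 0.536)
  expect_equal(wilks_lambda(r, 1), prod(1 - r^2))
  expect_equal(wilks_lambda(rep(0, 3), 1), 1)
  expect_equal(cca_eigenvalue(0), 0)
  expect_error(cca_eigenvalue(1), "infinite")
  # Lambda = 1: no association at all
  f0 <- rao_f(1, 3, 8, 36, 1)
  expect_equal(f0$statistic, 0)
  expect_equal(f0$p.value, 1)
  expect_error(rao_f(0.5, 3, 3, 5, 1), "too small")
})

test_that("variates are orthonormal with cross-block structure r * I", {
  set.seed(12)
  x <- random_block(40, 3, "X")
  y <- random_block(40, 5, "Y")
  fit <- cca_fit(x, y)
  s <- length(fit$correlations)
  expect_equal(unname(cor(fit$scores$U)), diag(s), tolerance = 1e-8)
  expect_equal(unname(cor(fit$scores$V)), diag(s), tolerance = 1e-8)
  uv <- unname(cor(fit$scores$U, fit$scores$V))
  expect_equal(uv, diag(fit$correlations, s), tolerance = 1e-8)
})

test_that("loadings satisfy their matrix identities", {
  set.seed(13)
  x <- random_block(30, 3, "X")
  y <- random_block(30, 4, "Y")
  fit <- cca_fit(x, y)
  Rxx <- cor(x)
  expect_equal(unname(cca_loadings(fit, "x")),
               unname(Rxx %*% fit$x_coefficients), tolerance = 1e-10)
  # loading really is corr(variable, own variate)
  direct <- cor(scale(y), fit$scores$V)
  expect_equal(unname(cca_loadings(fit, "y")), unname(direct), tolerance = 1e-10)
  # cross-loading = r_k * loading and = corr(variable, opposite variate)
  expect_equal(unname(cca_cross_loadings(fit, "y")),
               unname(sweep(cca_loadings(fit, "y"), 2, fit$correlations, `*`)),
               tolerance = 1e-10)
  direct_cross <- cor(scale(y), fit$scores$U)
  expect_equal(unname(cca_cross_loadings(fit, "y")), unname(direct_cross),
               tolerance = 1e-8)
  # orthonormal x block: loadings coincide with coefficients
  xo <- qr.Q(qr(scale(random_block(25, 3, "Q"), scale = FALSE)))
  colnames(xo) <- paste0("Q", 1:3)
  fo <- cca_fit(xo, random_block(25, 3, "Y"))
  expect_equal(unname(fo$x_loadings), unname(fo$x_coefficients), tolerance = 1e-8)
})

test_that("redundancy index equals the mean squared cross-loading", {
  set.seed(14)
  fit <- cca_fit(random_block(30, 3, "X"), random_block(30, 4, "Y"))
  for (k in seq_along(fit$correlations)) {
    expect_equal(cca_redundancy(fit, "x", k),
                 mean(cca_cross_loadings(fit, "x")[, k]^2), tolerance = 1e-10)
    expect_equal(cca_redundancy(fit, "y", k),
                 mean(cca_cross_loadings(fit, "y")[, k]^2), tolerance = 1e-10)
  }
  # p = 1: loading is +-1, so RI = r^2
  f1 <- cca_fit(random_block(20, 1, "X"), random_block(20, 2, "Y"))
  expect_equal(cca_redundancy(f1, "x", 1), f1$correlations[1]^2, tolerance = 1e-10)
})

test_that("canonical correlations are affine invariant", {
  set.seed(15)
  x <- random_block(25, 3, "X")
  y <- random_block(25, 4, "Y")
  base <- cca_fit(x, y)$correlations
  for (rep in 1:5) {
    mx <- matrix(rnorm(9), 3, 3) + diag(3)
    my <- matrix(rnorm(16), 4, 4) + diag(4)
    x2 <- sweep(x %*% mx, 2, rnorm(3), `+`)
    y2 <- sweep(y %*% my, 2, rnorm(4), `+`)
    colnames(x2) <- colnames(x); colnames(y2) <- colnames(y)
    expect_equal(cca_fit(x2, y2)$correlations, base, tolerance = 1e-8)
  }
})

test_that("sign convention puts the dominant x loading positive", {
  set.seed(16)
  for (rep in 1:5) {
    fit <- cca_fit(random_block(30, 3, "X"), random_block(30, 4, "Y"))
    for (k in seq_along(fit$correlations)) {
      lk <- fit$x_loadings[, k]
      expect_gt(lk[which.max(abs(lk))], 0)
    }
  }
})

test_that("rank-deficient blocks error naming columns, unless ridged", {
  set.seed(17)
  x <- random_block(20, 2, "X")
  x <- cbind(x, X3 = x[, 1] + x[, 2])
  y <- random_block(20, 2, "Y")
  expect_error(cca_fit(x, y), "rank deficient.*X")
  expect_message(fit <- cca_fit(x, y, ridge = 1e-8), "ridge")
  expect_true(all(is.finite(fit$correlations)))
  const <- cbind(random_block(20, 2, "Z"), Z3 = 1)
  expect_error(cca_fit(const, y), "constant")
})

test_that("tidy and glance summarise the fit coherently", {
  set.seed(18)
  fit <- cca_fit(random_block(36, 3, "X"), random_block(36, 4, "Y"))
  td <- tidy(fit)
  expect_equal(nrow(td), 3)
  expect_equal(td$lambda,
               vapply(1:3, function(k) wilks_lambda(fit$correlations, k),
                      numeric(1)))
  expect_true(all(diff(td$correlation) <= 0))
  g <- glance(fit)
  expect_equal(g$first_correlation, fit$correlations[1])
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
})
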