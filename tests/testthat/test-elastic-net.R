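std_pop <- function(x) {
  xc <- sweep(x, 2, colMeans(x))
  sweep(xc, 2, sqrt(colMeans(xc^2)), "/")
}

test_that("the unpenalized fit matches ordinary least squares", {
  withr::with_seed(81, {
    n <- 40; p <- 6
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
    y <- drop(X %*% rnorm(p)) + rnorm(n)
    for (alpha in c(0, 0.5, 1)) {
      fit <- fit_elastic_net(X, y, alpha = alpha, lambda = 0, tol = 1e-10)
      ols <- coef(lm(y ~ std_pop(X)))[-1]
      expect_equal(unname(coef(fit)), unname(ols), tolerance = 1e-6)
    }
  })
})

test_that("the lasso on an orthonormal design soft-thresholds OLS", {
  withr::with_seed(82, {
    n <- 64; p <- 5
    # orthonormal design orthogonal to the intercept: exact mean 0 and
    # (1/n) X'X = I, so the lasso solution has a closed form
    Q <- qr.Q(qr(cbind(1, matrix(rnorm(n * p), n, p))))[, -1]
    X <- Q * sqrt(n)
    y <- rnorm(n)
    yc <- y - mean(y)
    bols <- drop(crossprod(X, yc)) / n
    for (lambda in c(0.02, 0.1, 0.5)) {
      fit <- fit_elastic_net(X, y, alpha = 1, lambda = lambda, tol = 1e-12)
      # X is already standardized, so internal standardization is near-identity
      ref <- sign(bols) * pmax(abs(bols) - lambda, 0)
      expect_equal(unname(coef(fit)), unname(ref), tolerance = 1e-5)
    }
  })
})

test_that("lambda_max zeroes every coefficient", {
  withr::with_seed(83, {
    n <- 30; p <- 8
    X <- matrix(rnorm(n * p), n, p)
    y <- rnorm(n)
    xs <- std_pop(X)
    lmax <- max(abs(crossprod(xs, y - mean(y)) / n))
    fit <- fit_elastic_net(X, y, alpha = 1, lambda = lmax * (1 + 1e-10))
    expect_true(all(coef(fit) == 0))
    just_below <- fit_elastic_net(X, y, alpha = 1, lambda = lmax * 0.95)
    expect_gt(sum(coef(just_below) != 0), 0)
  })
})

test_that("small problems agree with the exact KKT-enumeration oracle", {
  withr::with_seed(84, {
    for (i in 1:8) {
      n <- sample(10:20, 1); p <- sample(2:5, 1)
      X <- matrix(rnorm(n * p), n, p)
      y <- rnorm(n)
      alpha <- sample(c(0.2, 0.5, 1), 1)
      lambda <- stats::runif(1, 0.01, 0.3)
      xs <- std_pop(X)
      fit <- fit_elastic_net(X, y, alpha = alpha, lambda = lambda, tol = 1e-12)
      ref <- enet_oracle(xs, y, alpha, lambda)
      expect_lt(max(abs(coef(fit) - ref)), 1e-5)
    }
  })
})

test_that("solutions track the independent glmnet implementation", {
  skip_if_not_installed("glmnet")
  # glmnet standardizes the response internally, which rescales its ridge
  # penalty; comparisons therefore use a unit-variance response (where the
  # two objectives coincide) and the pure lasso (whose L1 term rescales
  # cleanly regardless)
  withr::with_seed(184, {
    n <- 100; p <- 6
    X <- matrix(rnorm(n * p), n, p)
    y <- drop(X %*% rnorm(p)) + rnorm(n)
    xs <- std_pop(X)
    lam <- 0.15
    path <- exp(seq(log(3), log(lam), length.out = 50))

    fit_l1 <- fit_elastic_net(X, y, alpha = 1, lambda = lam, tol = 1e-13)
    ref_l1 <- glmnet::glmnet(xs, y, alpha = 1, lambda = path,
                             standardize = FALSE, thresh = 1e-14)
    expect_equal(unname(coef(fit_l1)),
                 as.numeric(ref_l1$beta[, ncol(ref_l1$beta)]),
                 tolerance = 1e-6)

    yu <- drop(scale(y)) * sqrt(n / (n - 1))   # unit population variance
    fit_en <- fit_elastic_net(X, yu, alpha = 0.5, lambda = lam, tol = 1e-13)
    ref_en <- glmnet::glmnet(xs, yu, alpha = 0.5, lambda = path,
                             standardize = FALSE, thresh = 1e-14)
    expect_equal(unname(coef(fit_en)),
                 as.numeric(ref_en$beta[, ncol(ref_en$beta)]),
                 tolerance = 1e-5)
  })
})

test_that("degenerate inputs are rejected or handled as documented", {
  X <- cbind(a = rnorm(10), b = rep(2, 10))
  y <- rnorm(10)
  expect_warning(fit <- fit_elastic_net(X, y, 0.5, 0.1), "Zero-variance")
  expect_equal(unname(coef(fit)["b"]), 0)
  X[1, 1] <- NA
  expect_error(fit_elastic_net(X, y, 0.5, 0.1),
               class = "engraftr_parameter_error")
  expect_error(fit_elastic_net(cbind(rnorm(5)), rnorm(5), alpha = 2, lambda = 0),
               class = "engraftr_parameter_error")
})

test_that("the coefficient path is continuous in lambda", {
  withr::with_seed(85, {
    n <- 60; p <- 6
    X <- matrix(rnorm(n * p), n, p)
    y <- drop(X %*% rnorm(p)) + rnorm(n)
    grid <- exp(seq(log(2), log(2e-4), length.out = 100))
    fit <- fit_elastic_net(X, y, alpha = 0.7, lambda = grid)
    jumps <- apply(abs(diff(t(fit$coefficients))), 1, max)
    expect_lt(max(jumps), 0.35)
  })
})

test_that("cross-validation is deterministic and selects sensibly", {
  withr::with_seed(86, {
    n <- 60; p <- 6
    X <- matrix(rnorm(n * p), n, p)
    y <- drop(X %*% c(2, -1, rep(0, p - 2))) + rnorm(n, 0, 0.3)
  })
  a <- cross_validate(X, y, alpha_grid = c(0.1, 0.5, 1), n_lambda = 30, seed = 9)
  b <- cross_validate(X, y, alpha_grid = c(0.1, 0.5, 1), n_lambda = 30, seed = 9)
  expect_equal(glance(a), glance(b))
  expect_equal(tidy(a), tidy(b))
  expect_lte(a$r_squared, 1)
  sel <- a$grid[abs(a$grid$alpha - a$alpha) < 1e-12 &
                  abs(a$grid$lambda - a$lambda) < 1e-12, ]
  expect_equal(sel$mean_rmse, min(a$grid$mean_rmse))
  expect_error(cross_validate(X[1:3, ], y[1:3], folds = 5),
               class = "engraftr_parameter_error")
})

test_that("noiseless linear responses are recovered almost perfectly", {
  withr::with_seed(87, {
    n <- 200; p <- 10
    X <- matrix(rnorm(n * p), n, p)
    y <- drop(X %*% c(1.5, -2, 0.8, rep(0, p - 3)))
  })
  cv <- cross_validate(X, y, seed = 4)
  expect_gt(cv$r_squared, 0.99)
})

test_that("held-out R2 is invariant to affine rescaling of predictors", {
  withr::with_seed(88, {
    n <- 80; p <- 5
    X <- matrix(rnorm(n * p), n, p)
    y <- drop(X %*% rnorm(p)) + rnorm(n, 0, 0.5)
  })
  base <- cross_validate(X, y, alpha_grid = c(0.5, 1), n_lambda = 25, seed = 2)
  X2 <- X
  X2[, 1] <- 100 * X2[, 1] - 7
  X2[, 3] <- -0.01 * X2[, 3] + 42
  scaled <- cross_validate(X2, y, alpha_grid = c(0.5, 1), n_lambda = 25, seed = 2)
  expect_equal(scaled$r_squared, base$r_squared, tolerance = 1e-8)
})

test_that("category comparison returns the four fits with labeled features", {
  withr::with_seed(89, {
    n <- 50
    X <- matrix(rnorm(n * 6), n,
                dimnames = list(NULL, c("a1", "a2", "b1", "b2", "t1", "t2")))
    cats <- stats::setNames(c("alpha", "alpha", "beta", "beta",
                              "top_taxa", "top_taxa"), colnames(X))
    y <- drop(X[, c("t1", "t2")] %*% c(2, -2)) + rnorm(n, 0, 0.2)
  })
  cmp <- compare_feature_categories(X, y, categories = cats,
                                    alpha_grid = c(0.5, 1), n_lambda = 25,
                                    seed = 6)
  expect_setequal(cmp$summary$category, c("alpha", "beta", "top_taxa", "full"))
  # the category actually driving y must beat the unrelated one
  r2 <- stats::setNames(cmp$summary$r.squared, cmp$summary$category)
  expect_gt(r2[["top_taxa"]], r2[["alpha"]])
  # an intercept-only fit cannot beat the variance bound
  expect_lte(r2[["alpha"]], 0.3)
})
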