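# Elastic-net regression by cyclic coordinate descent with soft
# thresholding, and repeated k-fold cross-validation selecting the
# (alpha, lambda) cell with the smallest mean held-out RMSE — the model
# selection scheme used to predict colonization and rejection from
# pre-FMT features.

#' Fit an elastic net at fixed mixing and penalty
#'
#' Minimizes `(1/2n) sum((y - yhat)^2) + lambda * (alpha * |b|_1 +
#' (1-alpha)/2 * |b|_2^2)` by cyclic coordinate descent with soft
#' thresholding. Predictors are standardized internally (mean 0, population
#' SD 1); coefficients are reported on that standardized scale with the
#' centering/scaling stored so predictions work on the original scale.
#' Zero-variance columns are dropped (coefficient 0) with a warning.
#'
#' @param x Numeric predictor matrix or all-numeric data frame (n x p).
#' @param y Numeric response of length n.
#' @param alpha Mixing parameter in \[0, 1\] (1 = lasso, 0 = ridge).
#' @param lambda Non-negative penalty (scalar, or decreasing vector for a
#'   warm-started path).
#' @param tol Convergence tolerance on the max coefficient change per sweep.
#' @param max_sweeps Sweep cap.
#' @return An `engraft_enet` object: standardized-scale coefficients (per
#'   lambda if a path was requested), intercept, and the standardization
#'   parameters.
#' @export
fit_elastic_net <- function(x, y, alpha, lambda, tol = 1e-7,
                            max_sweeps = 1e5) {
  x <- as_numeric_matrix(x)
  y <- as.numeric(y)
  if (nrow(x) != length(y)) abort_parameter("x and y disagree on n.")
  if (nrow(x) < 2) abort_parameter("Need at least 2 observations.")
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    abort_parameter("Non-finite values in x or y.")
  }
  if (alpha < 0 || alpha > 1) abort_parameter("alpha must lie in [0, 1].")
  if (any(lambda < 0)) abort_parameter("lambda must be non-negative.")
  std <- standardize_columns(x)
  if (any(std$sd == 0)) {
    warn(paste0("Zero-variance column(s) dropped from the fit: ",
                toString(colnames(x)[std$sd == 0])))
  }
  ybar <- mean(y)
  lambda <- sort(as.numeric(lambda), decreasing = TRUE)
  B <- enet_path_cd(std$x, y - ybar, alpha, lambda, tol, as.integer(max_sweeps))
  rownames(B) <- colnames(x)
  structure(
    list(
      coefficients = B,
      lambda = lambda,
      alpha = alpha,
      intercept = ybar,
      center = std$center,
      scale = std$sd,
      features = colnames(x)
    ),
    class = "engraft_enet"
  )
}

as_numeric_matrix <- function(x) {
  if (is.data.frame(x)) {
    num <- vapply(x, is.numeric, logical(1))
    if (!all(num)) {
      abort_parameter(paste0("Non-numeric predictor column(s): ",
                             toString(names(x)[!num])))
    }
    x <- as.matrix(x)
  }
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  storage.mode(x) <- "double"
  x
}

# Population (1/n) standardization, glmnet's convention; zero-SD columns are
# scaled to all-zero so their coefficients stay 0.
standardize_columns <- function(x, center = NULL, sd = NULL) {
  if (is.null(center)) center <- colMeans(x)
  xc <- sweep(x, 2, center)
  if (is.null(sd)) sd <- sqrt(colMeans(xc^2))
  xs <- sweep(xc, 2, ifelse(sd > 0, sd, 1), "/")
  xs[, sd == 0] <- 0
  list(x = xs, center = center, sd = sd)
}

#' @export
coef.engraft_enet <- function(object, lambda = NULL, ...) {
  B <- object$coefficients
  if (is.null(lambda)) {
    if (ncol(B) > 1) return(B)
    return(stats::setNames(B[, 1], object$features))
  }
  l <- which.min(abs(object$lambda - lambda))
  stats::setNames(B[, l], object$features)
}

#' @export
predict.engraft_enet <- function(object, newdata, lambda = NULL, ...) {
  x <- as_numeric_matrix(newdata)[, object$features, drop = FALSE]
  xs <- standardize_columns(x, object$center, object$scale)$x
  b <- coef(object, lambda = lambda %||% object$lambda[length(object$lambda)])
  drop(object$intercept + xs %*% b)
}

# Smallest lambda that zeroes every coefficient for the given alpha (alpha
# floored at 1e-3 so ridge-end grids stay finite), on standardized x and
# centered y.
lambda_max <- function(xs, yc, alpha) {
  n <- nrow(xs)
  max(abs(crossprod(xs, yc) / n)) / max(alpha, 1e-3)
}

default_lambda_grid <- function(xs, yc, alpha, n_lambda = 100, decades = 4) {
  lmax <- lambda_max(xs, yc, alpha)
  if (lmax <= 0) lmax <- 1e-3
  exp(seq(log(lmax), log(lmax * 10^(-decades)), length.out = n_lambda))
}

#' Repeated cross-validated elastic net
#'
#' Runs `repeats` independent random `folds`-fold splits, fits the full
#' lambda path for every alpha on each training part, and records held-out
#' RMSE per (alpha, lambda) grid cell. The selected cell attains the
#' smallest mean RMSE over all `repeats x folds` fold-fits; ties break
#' toward larger lambda, then larger alpha (the sparser, then smoother
#' model). The final model is refit on all data at the selected cell.
#'
#' @inheritParams fit_elastic_net
#' @param alpha_grid Mixing-parameter grid (default 0, 0.1, ..., 1).
#' @param n_lambda Number of lambda values per alpha (default 100,
#'   log-spaced over 4 decades down from the all-zero lambda; the grid is
#'   computed on the full standardized data so that all fold-fits share it).
#' @param repeats,folds Cross-validation design (default 5 x 5).
#' @param seed Integer seed driving the fold assignments.
#' @return An `engraft_cv` object: the RMSE `grid` tibble, selected
#'   `alpha`/`lambda`, pooled held-out `rmse` and `r_squared`, training
#'   `r_squared_train`, and the refit `model`.
#' @export
cross_validate <- function(x, y, alpha_grid = seq(0, 1, by = 0.1),
                           n_lambda = 100, repeats = 5, folds = 5,
                           seed = 1L, tol = 1e-7, max_sweeps = 1e5) {
  x <- as_numeric_matrix(x)
  y <- as.numeric(y)
  n <- nrow(x)
  if (n < folds) abort_parameter("Need at least as many observations as folds.")
  std_full <- standardize_columns(x)
  yc_full <- y - mean(y)
  grids <- lapply(alpha_grid, function(a) {
    default_lambda_grid(std_full$x, yc_full, a, n_lambda = n_lambda)
  })

  assignments <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(repeats), function(r) sample(rep_len(seq_len(folds), n)))
  })

  # se[[a]][cell] accumulators: per (alpha, lambda) summed fold RMSE and
  # pooled held-out squared errors at every cell.
  rmse_sum <- lapply(alpha_grid, function(a) numeric(n_lambda))
  sse_pool <- lapply(alpha_grid, function(a) numeric(n_lambda))
  n_fits <- 0
  for (r in seq_len(repeats)) {
    fold_of <- assignments[[r]]
    for (f in seq_len(folds)) {
      test <- fold_of == f
      xtr <- x[!test, , drop = FALSE]
      ytr <- y[!test]
      std <- standardize_columns(xtr)
      ytr_c <- ytr - mean(ytr)
      xte <- standardize_columns(x[test, , drop = FALSE], std$center, std$sd)$x
      for (ai in seq_along(alpha_grid)) {
        B <- enet_path_cd(std$x, ytr_c, alpha_grid[ai], grids[[ai]],
                          tol, as.integer(max_sweeps))
        pred <- mean(ytr) + xte %*% B
        err2 <- (y[test] - pred)^2
        rmse_sum[[ai]] <- rmse_sum[[ai]] + sqrt(colMeans(err2))
        sse_pool[[ai]] <- sse_pool[[ai]] + colSums(err2)
      }
      n_fits <- n_fits + 1
    }
  }

  grid <- dplyr::bind_rows(lapply(seq_along(alpha_grid), function(ai) {
    tibble(
      alpha = alpha_grid[ai],
      lambda = grids[[ai]],
      mean_rmse = rmse_sum[[ai]] / n_fits
    )
  }))
  # ties toward larger lambda then larger alpha
  best <- grid |>
    dplyr::filter(.data$mean_rmse <= min(.data$mean_rmse) + 1e-12) |>
    dplyr::arrange(dplyr::desc(.data$lambda), dplyr::desc(.data$alpha)) |>
    dplyr::slice(1)
  ai <- which(abs(alpha_grid - best$alpha) < 1e-12)[1]
  li <- which.min(abs(grids[[ai]] - best$lambda))
  # every observation is predicted exactly once per repeat, so the pooled
  # held-out SSE is averaged over repeats before comparing with SST
  sst <- sum((y - mean(y))^2)
  r2_heldout <- 1 - (sse_pool[[ai]][li] / repeats) / sst

  model <- fit_elastic_net(x, y, alpha = best$alpha,
                           lambda = grids[[ai]][seq_len(li)],
                           tol = tol, max_sweeps = max_sweeps)
  fitted_full <- predict(model, x, lambda = best$lambda)
  r2_train <- 1 - sum((y - fitted_full)^2) / sst

  structure(
    list(
      grid = grid,
      alpha = best$alpha,
      lambda = best$lambda,
      rmse = best$mean_rmse,
      r_squared = r2_heldout,
      r_squared_train = r2_train,
      model = model,
      repeats = repeats,
      folds = folds,
      seed = as.integer(seed),
      n = n
    ),
    class = "engraft_cv"
  )
}

#' @export
print.engraft_cv <- function(x, ...) {
  cat("Repeated cross-validated elastic net (",
      x$repeats, " x ", x$folds, "-fold, n = ", x$n, ", seed ", x$seed, ")\n",
      sep = "")
  cat(sprintf("  selected alpha = %.2f, lambda = %.4g\n", x$alpha, x$lambda))
  cat(sprintf("  held-out RMSE = %.4g, held-out R2 = %.4f (training R2 = %.4f)\n",
              x$rmse, x$r_squared, x$r_squared_train))
  nz <- sum(coef(x$model, lambda = x$lambda) != 0)
  cat("  nonzero coefficients:", nz, "of", length(x$model$features), "\n")
  invisible(x)
}

#' @describeIn cross_validate Coefficients of the selected model as a
#'   tibble (`feature`, `estimate` on the standardized scale).
#' @param object,x An `engraft_cv` object.
#' @param ... Unused.
#' @export
tidy.engraft_cv <- function(x, ...) {
  b <- coef(x$model, lambda = x$lambda)
  tibble(feature = names(b), estimate = unname(b))
}

#' @describeIn cross_validate One-row model summary: selected parameters,
#'   held-out RMSE and R-squared.
#' @export
glance.engraft_cv <- function(x, ...) {
  tibble(
    alpha = x$alpha,
    lambda = x$lambda,
    rmse = x$rmse,
    r.squared = x$r_squared,
    r.squared.train = x$r_squared_train,
    nobs = x$n
  )
}

#' @describeIn cross_validate Coefficient lollipop plot of the selected
#'   model (nonzero terms, signed, standardized scale).
#' @export
autoplot.engraft_cv <- function(object, ...) {
  df <- tidy(object)
  df <- df[df$estimate != 0, ]
  df$feature <- stats::reorder(df$feature, df$estimate)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$feature)) +
    ggplot2::geom_col(ggplot2::aes(fill = .data$estimate > 0), show.legend = FALSE) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "Standardized coefficient", y = NULL) +
    ggplot2::theme_minimal()
}

#' Compare feature-category models
#'
#' Fits one cross-validated elastic net per predictor category (alpha
#' diversity, beta diversity, top-ten genera) and one on the full feature
#' set, reporting held-out R-squared per category and the full model's
#' signed coefficients.
#'
#' @param x Predictor data frame/matrix whose columns carry category labels.
#' @param y Response vector.
#' @param categories Named character vector: feature -> category. Defaults
#'   to the `feature_categories` attribute of `x` (set by
#'   [build_predictors()]).
#' @param ... Passed to [cross_validate()].
#' @return An `engraft_category_cmp` object: `summary` tibble (one glance
#'   row per category plus the full model), `full` (the full-model
#'   `engraft_cv`), and `fits` (per-category `engraft_cv` objects).
#' @export
compare_feature_categories <- function(x, y, categories = NULL, ...) {
  if (is.null(categories)) categories <- attr(x, "feature_categories")
  if (is.null(categories)) {
    abort_parameter("No category labels found; pass `categories`.")
  }
  xm <- as_numeric_matrix(x)
  categories <- categories[colnames(xm)]
  fits <- lapply(split(names(categories), unname(categories)), function(feats) {
    cross_validate(xm[, feats, drop = FALSE], y, ...)
  })
  full <- cross_validate(xm, y, ...)
  summary <- dplyr::bind_rows(
    c(lapply(fits, glance), list(full = glance(full))),
    .id = "category"
  ) |>
    dplyr::mutate(n_features = c(
      vapply(split(names(categories), unname(categories)), length, integer(1)),
      length(categories)
    ))
  structure(
    list(summary = summary, full = full, fits = fits),
    class = "engraft_category_cmp"
  )
}

#' @export
print.engraft_category_cmp <- function(x, ...) {
  cat("Elastic-net models per feature category\n")
  print(as.data.frame(x$summary[, c("category", "n_features", "alpha",
                                    "lambda", "rmse", "r.squared")]),
        row.names = FALSE, digits = 4)
  invisible(x)
}

#' @describeIn compare_feature_categories Held-out R-squared per category as
#'   a bar plot.
#' @param object An `engraft_category_cmp` object.
#' @export
autoplot.engraft_category_cmp <- function(object, ...) {
  df <- object$summary
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$r.squared)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = NULL, y = "Held-out R²") +
    ggplot2::theme_minimal()
}
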