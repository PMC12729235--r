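# Principal coordinates analysis and PERMANOVA on distance matrices,
# implemented directly (classical metric scaling; pseudo-F with label
# permutation).

#' Principal coordinates analysis
#'
#' Classical metric scaling: eigendecomposition of the double-centered
#' squared-distance matrix. Negative eigenvalues (possible for semi-metric
#' distances) are reported, never silently clipped; coordinates use the
#' leading positive eigenvalues only.
#'
#' @param dm A symmetric distance matrix with sample ids as dimnames.
#' @param k Number of coordinate axes to return (default 2).
#' @return An object of class `engraft_pcoa` with elements `points` (tibble
#'   `sample_id`, `Axis1..Axisk`), `eigenvalues` (all of them, signed) and
#'   `prop_explained` (fractions of the positive eigenvalue total).
#' @export
pcoa_ordination <- function(dm, k = 2) {
  dm <- validate_distance_matrix(dm)
  n <- nrow(dm)
  A <- -0.5 * dm^2
  G <- sweep(sweep(A, 1, rowMeans(A)), 2, colMeans(A)) + mean(A)
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  pos <- sum(e$values > 1e-8 * max(abs(e$values), 1))
  if (k > pos) {
    abort_parameter(paste0(
      "k = ", k, " exceeds the rank of the configuration (", pos, ")."
    ))
  }
  pts <- e$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(e$values[seq_len(k)]), k)
  colnames(pts) <- paste0("Axis", seq_len(k))
  structure(
    list(
      points = dplyr::bind_cols(tibble(sample_id = rownames(dm)), as_tibble(pts)),
      eigenvalues = e$values,
      prop_explained = pmax(e$values, 0) / sum(pmax(e$values, 0))
    ),
    class = "engraft_pcoa"
  )
}

#' @export
print.engraft_pcoa <- function(x, ...) {
  k <- ncol(x$points) - 1
  cat("PCoA ordination: ", nrow(x$points), " samples, ", k, " axes\n", sep = "")
  cat("Proportion explained:",
      paste(sprintf("%.1f%%", 100 * x$prop_explained[seq_len(k)]), collapse = ", "),
      "\n")
  if (any(x$eigenvalues < 0)) {
    cat("Note:", sum(x$eigenvalues < 0), "negative eigenvalue(s) present.\n")
  }
  invisible(x)
}

#' One-way PERMANOVA on a distance matrix
#'
#' Partitions the total sum of squared distances into among- and
#' within-group components and tests the pseudo-F statistic by permuting
#' group labels. The p-value uses the +1 correction
#' `(1 + #(F_perm >= F_obs)) / (1 + n_permutations)`.
#'
#' @param dm A symmetric distance matrix with sample ids as dimnames.
#' @param groups Group label per sample (recycled against the matrix order).
#' @param n_permutations Number of label permutations (default 999).
#' @param seed Integer seed making the permutation p-value reproducible.
#' @return An object of class `engraft_permanova` with `pseudo_f`,
#'   `p_value`, `df_among`, `df_within`, `n_permutations`, `seed`.
#' @export
permanova <- function(dm, groups, n_permutations = 999, seed = 1L) {
  dm <- validate_distance_matrix(dm)
  n <- nrow(dm)
  groups <- as.character(groups)
  if (length(groups) != n) abort_parameter("One group label per sample is required.")
  sizes <- table(groups)
  if (length(sizes) < 2) abort_parameter("PERMANOVA needs at least 2 groups.")
  if (any(sizes < 2)) {
    abort_parameter(paste0(
      "Every group needs >= 2 samples; too small: ",
      toString(names(sizes)[sizes < 2])
    ))
  }
  d2 <- dm^2
  sst <- sum(d2) / (2 * n)
  a <- length(sizes)
  fstat <- function(g) {
    ssw <- 0
    for (lev in unique(g)) {
      i <- which(g == lev)
      ssw <- ssw + sum(d2[i, i]) / (2 * length(i))
    }
    ((sst - ssw) / (a - 1)) / (ssw / (n - a))
  }
  f0 <- fstat(groups)
  exceed <- withr::with_seed(as.integer(seed), {
    sum(vapply(seq_len(n_permutations), function(b) {
      fstat(sample(groups)) >= f0
    }, logical(1)))
  })
  structure(
    list(
      pseudo_f = f0,
      p_value = (1 + exceed) / (1 + n_permutations),
      df_among = a - 1,
      df_within = n - a,
      n_permutations = n_permutations,
      seed = as.integer(seed)
    ),
    class = "engraft_permanova"
  )
}

#' @export
print.engraft_permanova <- function(x, ...) {
  cat("PERMANOVA (", x$n_permutations, " permutations, seed ", x$seed, ")\n",
      sep = "")
  cat(sprintf("  pseudo-F = %.4f on %d and %d df, p = %.4g\n",
              x$pseudo_f, x$df_among, x$df_within, x$p_value))
  invisible(x)
}

#' @describeIn permanova One-row tibble with the test statistic and p-value.
#' @param x An `engraft_permanova` object.
#' @param ... Unused.
#' @export
tidy.engraft_permanova <- function(x, ...) {
  tibble(
    statistic = x$pseudo_f,
    p.value = x$p_value,
    df = x$df_among,
    df.residual = x$df_within,
    n.permutations = x$n_permutations
  )
}

#' @describeIn permanova Alias of `tidy()` for this one-row result.
#' @export
glance.engraft_permanova <- function(x, ...) {
  tidy.engraft_permanova(x, ...)
}

#' Plot a PCoA ordination
#'
#' @param object An `engraft_pcoa` object.
#' @param colour Optional vector (sample-aligned) used to colour points.
#' @param ... Unused.
#' @return A ggplot object of the first two axes.
#' @export
autoplot.engraft_pcoa <- function(object, colour = NULL, ...) {
  df <- object$points
  lab <- sprintf("Axis %d (%.1f%%)", 1:2, 100 * object$prop_explained[1:2])
  p <- if (is.null(colour)) {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$Axis1, y = .data$Axis2))
  } else {
    df$group <- colour
    ggplot2::ggplot(df, ggplot2::aes(x = .data$Axis1, y = .data$Axis2,
                                     colour = .data$group))
  }
  p + ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = lab[1], y = lab[2]) +
    ggplot2::theme_minimal()
}
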