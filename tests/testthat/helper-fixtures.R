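# Shared fixtures and independent oracles, all built in code.

tiny_table <- function(counts = rbind(c(1, 2), c(0, 5), c(3, 0)),
                       samples = paste0("s", seq_len(nrow(counts))),
                       taxa = paste0("t", seq_len(ncol(counts)))) {
  dimnames(counts) <- list(samples, taxa)
  as_feature_table(dplyr::bind_cols(
    tibble::tibble(sample_id = samples),
    tibble::as_tibble(counts)
  ))
}

# unit-branch star tree over the given tips (each tip hangs off the root
# with branch length 1)
star_tree <- function(tips) {
  n <- length(tips)
  tree <- list(
    edge = cbind(rep(n + 1L, n), seq_len(n)),
    edge.length = rep(1, n),
    tip.label = tips,
    Nnode = 1L
  )
  class(tree) <- "phylo"
  attr(tree, "order") <- "cladewise"
  tree
}

# Independent brute-force outcome oracle: assign every genus of the
# universe its (in D, in R, in P) bit triple and map each non-empty pattern
# to its category; fractions are counts over |P|.
oracle_classify <- function(donor, pre, post, universe = union(union(donor, pre), post)) {
  key <- paste0(as.integer(universe %in% donor),
                as.integer(universe %in% pre),
                as.integer(universe %in% post))
  map <- c("111" = "coexistence", "101" = "colonization", "100" = "rejection",
           "011" = "persistence", "001" = "novel", "010" = "loss",
           "110" = "shared_loss")
  cat_of <- map[key]
  n_post <- length(post)
  counts <- table(factor(cat_of, levels = unname(map)))
  stats::setNames(as.numeric(counts) / n_post, names(counts))
}

# Exact independent elastic-net oracle for small p: enumerate coefficient
# sign patterns, solve the stationarity system for each active set in
# closed form, and return the unique solution satisfying the KKT
# conditions of (1/2n)||yc - X b||^2 + lam*(alpha|b|_1 + (1-alpha)/2|b|_2^2)
# with X standardized and y centered.
enet_oracle <- function(xs, y, alpha, lam) {
  n <- nrow(xs); p <- ncol(xs)
  yc <- y - mean(y)
  patterns <- as.matrix(expand.grid(rep(list(c(-1, 0, 1)), p)))
  for (k in seq_len(nrow(patterns))) {
    s <- patterns[k, ]
    A <- which(s != 0)
    b <- numeric(p)
    if (length(A)) {
      M <- crossprod(xs[, A, drop = FALSE]) / n +
        lam * (1 - alpha) * diag(length(A))
      rhs <- drop(crossprod(xs[, A, drop = FALSE], yc)) / n - lam * alpha * s[A]
      sol <- tryCatch(solve(M, rhs), error = function(e) NULL)
      if (is.null(sol) || any(sign(sol) != s[A])) next
      b[A] <- sol
    }
    g <- drop(crossprod(xs, yc - xs %*% b)) / n
    if (all(abs(g[s == 0]) <= lam * alpha + 1e-10)) return(b)
  }
  stop("oracle found no KKT point")
}

random_triad <- function(universe, max_size = length(universe)) {
  draw <- function() sample(universe, sample.int(max_size, 1))
  list(donor = draw(), pre = draw(), post = draw())
}

random_feature_table <- function(n_samples = 5, n_taxa = 12, lambda = 8,
                                 prefix = "s") {
  counts <- matrix(stats::rpois(n_samples * n_taxa, lambda), n_samples, n_taxa)
  tiny_table(counts, samples = paste0(prefix, seq_len(n_samples)),
             taxa = paste0("t", seq_len(n_taxa)))
}

random_distance_matrix <- function(n = 8) {
  pts <- matrix(stats::rnorm(n * 3), n)
  D <- as.matrix(stats::dist(pts))
  dimnames(D) <- list(paste0("s", seq_len(n)), paste0("s", seq_len(n)))
  D
}

simple_metadata <- function() {
  tibble::tibble(
    sample_id = c("d1", "d2", "r1_0", "r1_2", "r1_5", "r2_0", "r2_2"),
    subject_id = c("donorpool", "donorpool", "pig1", "pig1", "pig1", "pig2", "pig2"),
    role = c("donor", "donor", rep("recipient", 5)),
    treatment = c(NA, NA, "oral", "oral", "oral", "rectal", "rectal"),
    day = c(NA, NA, 0L, 2L, 5L, 0L, 2L)
  )
}
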