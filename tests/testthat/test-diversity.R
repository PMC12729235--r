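test_that("observed richness counts taxa with at least one read", {
  expect_equal(alpha_observed(c(5, 0, 2)), 2)
  expect_equal(alpha_observed(c(0, 0)), 0)
  withr::with_seed(11, {
    tbl <- random_feature_table(n_samples = 3, n_taxa = 20, lambda = 15)
    rar <- rarefy(tbl, 100, seed = 1)
    a0 <- alpha_diversity(tbl)
    a1 <- alpha_diversity(rar)
    expect_true(all(a1$observed_features <= a0$observed_features))
  })
})

test_that("Pielou evenness matches its closed form and its bounds", {
  expect_equal(alpha_pielou(c(5, 5, 5, 5)), 1)
  expect_true(is.na(alpha_pielou(c(1, 0, 0))))
  # [9,1]: H = -0.9 ln 0.9 - 0.1 ln 0.1, divided by ln 2
  h <- -(0.9 * log(0.9) + 0.1 * log(0.1))
  expect_equal(alpha_pielou(c(9, 1)), h / log(2))
  expect_equal(round(alpha_pielou(c(9, 1)), 4), 0.469)
  withr::with_seed(2, {
    for (i in 1:20) {
      v <- rpois(10, 3)
      p <- alpha_pielou(v)
      if (!is.na(p)) expect_true(p >= 0 && p <= 1)
    }
  })
})

test_that("Faith PD spans the minimal rooted subtree", {
  tr <- star_tree(c("a", "b", "c"))
  expect_equal(alpha_faith(c("a", "b"), tr), 2)
  expect_equal(alpha_faith(c("a", "b", "c"), tr), 3)
  expect_equal(alpha_faith(character(0), tr), 0)
  expect_error(alpha_faith("zz", tr), "zz", class = "engraftr_parameter_error")
})

test_that("Faith PD agrees with picante and is monotone under taxon addition", {
  skip_if_not_installed("picante")
  withr::with_seed(21, {
    tree <- ape::rcoal(12, tip.label = paste0("t", 1:12))
    for (i in 1:10) {
      taxa <- sample(tree$tip.label, sample(2:10, 1))
      comm <- matrix(as.integer(tree$tip.label %in% taxa), 1,
                     dimnames = list("s1", tree$tip.label))
      ref <- picante::pd(comm, tree, include.root = TRUE)$PD
      expect_equal(alpha_faith(taxa, tree), ref, tolerance = 1e-10)
      extra <- sample(setdiff(tree$tip.label, taxa), 1)
      expect_gte(alpha_faith(c(taxa, extra), tree), alpha_faith(taxa, tree))
    }
  })
})

test_that("Jaccard distance matches enumeration and edge cases", {
  expect_equal(beta_jaccard(c("a", "b", "c"), c("b", "c", "d")), 0.5)
  expect_equal(beta_jaccard(c("a", "b"), c("a", "b")), 0)
  expect_equal(beta_jaccard(c("a"), c("b")), 1)
  expect_equal(beta_jaccard(character(0), character(0)), 0)
})

test_that("Bray-Curtis matches its formula and edge cases", {
  expect_equal(beta_bray_curtis(c(3, 1, 0), c(1, 1, 2)), 0.5)
  expect_equal(beta_bray_curtis(c(2, 5), c(2, 5)), 0)
  expect_equal(beta_bray_curtis(c(3, 0), c(0, 4)), 1)
  expect_true(is.na(beta_bray_curtis(c(0, 0), c(0, 0))))
})

test_that("pairwise distances agree with vegan on random tables", {
  skip_if_not_installed("vegan")
  withr::with_seed(31, {
    tbl <- random_feature_table(n_samples = 6, n_taxa = 15, lambda = 5)
    m <- ft_matrix(tbl)
    bc <- beta_diversity(tbl, metric = "bray_curtis")
    expect_equal(bc, as.matrix(vegan::vegdist(m, "bray")),
                 tolerance = 1e-12, ignore_attr = TRUE)
    jc <- beta_diversity(tbl, metric = "jaccard")
    # vegan's binary jaccard on presence/absence
    ref <- as.matrix(vegan::vegdist(m >= 1, "jaccard", binary = TRUE))
    expect_equal(jc, ref, tolerance = 1e-12, ignore_attr = TRUE)
  })
})

test_that("UniFrac equals Jaccard on unit-branch star trees", {
  withr::with_seed(41, {
    tips <- paste0("t", 1:20)
    tr <- star_tree(tips)
    for (i in 1:15) {
      a <- sample(tips, sample(1:20, 1))
      b <- sample(tips, sample(1:20, 1))
      expect_equal(beta_unifrac(a, b, tr, mode = "unweighted"),
                   beta_jaccard(a, b), tolerance = 1e-12)
    }
  })
})

test_that("UniFrac distances behave at the extremes", {
  withr::with_seed(43, {
    tree <- ape::rcoal(8, tip.label = paste0("t", 1:8))
  })
  a <- c("t1", "t2", "t3")
  counts <- stats::setNames(c(3, 2, 1), a)
  expect_equal(beta_unifrac(a, a, tree, mode = "unweighted"), 0)
  expect_equal(beta_unifrac(counts, counts, tree, mode = "weighted"), 0)
  # two samples confined to the two disjoint root clades are maximally distant
  root <- length(tree$tip.label) + 1
  kids <- tree$edge[tree$edge[, 1] == root, 2]
  clade_tips <- function(node) {
    if (node <= length(tree$tip.label)) return(tree$tip.label[node])
    ape::extract.clade(tree, node)$tip.label
  }
  g1 <- clade_tips(kids[1]); g2 <- clade_tips(kids[2])
  expect_equal(beta_unifrac(g1, g2, tree, mode = "unweighted"), 1)
  w1 <- stats::setNames(rep(1, length(g1)), g1)
  w2 <- stats::setNames(rep(1, length(g2)), g2)
  expect_equal(beta_unifrac(w1, w2, tree, mode = "weighted"), 1)
})

test_that("all metrics are symmetric, non-negative, zero on the diagonal", {
  withr::with_seed(51, {
    tbl <- random_feature_table(n_samples = 5, n_taxa = 12, lambda = 3)
    tree <- ape::rcoal(12, tip.label = paste0("t", 1:12))
    for (metric in c("jaccard", "bray_curtis", "unweighted_unifrac",
                     "weighted_unifrac")) {
      D <- beta_diversity(tbl, metric = metric, tree = tree)
      expect_equal(D, t(D))
      expect_true(all(D >= 0))
      expect_true(all(diag(D) == 0))
    }
  })
})
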