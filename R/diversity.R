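# Alpha and beta diversity, implemented from first principles: observed
# richness, Pielou evenness, Faith phylogenetic diversity, Jaccard,
# Bray-Curtis and UniFrac distances. Established packages (vegan, picante)
# are used only as independent cross-checks in the test suite.

#' Observed richness of one sample
#'
#' @param counts Numeric count vector for one sample.
#' @return Number of taxa with count >= 1.
#' @export
alpha_observed <- function(counts) {
  sum(counts >= 1)
}

#' Pielou's evenness of one sample
#'
#' Shannon entropy (natural log) divided by its maximum, `ln(richness)`.
#' Undefined (NA) when fewer than two taxa are present, since evenness of a
#' single-taxon community has no meaning.
#'
#' @param counts Numeric count vector for one sample.
#' @return Evenness in \[0, 1\], or `NA_real_` when undefined.
#' @export
alpha_pielou <- function(counts) {
  p <- counts[counts > 0]
  if (length(p) < 2) return(NA_real_)
  p <- p / sum(p)
  h <- -sum(p * log(p))
  h / log(length(p))
}

#' Faith's phylogenetic diversity of one sample
#'
#' Total branch length of the minimal subtree connecting the present taxa
#' and the tree root (the rooted convention of common amplicon tooling; an
#' empty set has PD 0).
#'
#' @param taxa Character vector of present taxa (tip labels).
#' @param tree A rooted `phylo` tree whose tips cover `taxa`.
#' @return Total branch length (tree units).
#' @export
alpha_faith <- function(taxa, tree) {
  tree <- validate_tree(tree)
  taxa <- unique(taxa)
  if (length(taxa) == 0) return(0)
  tips <- match(taxa, tree$tip.label)
  if (anyNA(tips)) {
    abort_parameter(paste0(
      "Taxa missing from tree: ", toString(taxa[is.na(tips)])
    ))
  }
  po <- postorder_edges(tree)
  present <- logical(length(tree$tip.label) + tree$Nnode)
  present[tips] <- TRUE
  for (k in seq_len(nrow(po$edge))) {
    if (present[po$edge[k, 2]]) present[po$edge[k, 1]] <- TRUE
  }
  sum(po$length[present[po$edge[, 2]]])
}

postorder_edges <- function(tree) {
  eo <- ape::reorder.phylo(tree, "postorder")
  list(edge = eo$edge, length = eo$edge.length)
}

#' Alpha diversity table
#'
#' Computes observed richness, Pielou evenness and (when a tree is given)
#' Faith PD for every sample of a feature table.
#'
#' @param table A feature-table tibble.
#' @param tree Optional rooted `phylo` tree covering the table's taxa.
#' @return A tibble with one row per sample: `sample_id`,
#'   `observed_features`, `pielou_evenness`, and `faith_pd` if a tree was
#'   supplied.
#' @export
alpha_diversity <- function(table, tree = NULL) {
  table <- as_feature_table(table)
  m <- ft_matrix(table)
  out <- tibble(
    sample_id = rownames(m),
    observed_features = apply(m, 1, alpha_observed),
    pielou_evenness = apply(m, 1, alpha_pielou)
  )
  if (!is.null(tree)) {
    out$faith_pd <- vapply(seq_len(nrow(m)), function(i) {
      alpha_faith(colnames(m)[m[i, ] >= 1], tree)
    }, numeric(1))
  }
  out
}

#' Jaccard distance between two presence sets
#'
#' `1 - |A intersect B| / |A union B|`; two empty sets have distance 0.
#'
#' @param a,b Character vectors (presence sets).
#' @return Distance in \[0, 1\].
#' @export
beta_jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0) return(0)
  1 - length(intersect(a, b)) / u
}

#' Bray-Curtis dissimilarity between two count vectors
#'
#' `sum|u_i - v_i| / sum(u_i + v_i)` over an aligned taxon order.
#'
#' @param u,v Aligned numeric count (or abundance) vectors.
#' @return Distance in \[0, 1\], or `NA_real_` when both samples are empty.
#' @export
beta_bray_curtis <- function(u, v) {
  if (length(u) != length(v)) abort_parameter("Vectors must be aligned (equal length).")
  tot <- sum(u + v)
  if (tot == 0) return(NA_real_)
  sum(abs(u - v)) / tot
}

# Per-edge mass (fraction of a sample's total sitting below each edge's
# child). `weights` is a numeric vector named by tip label.
edge_masses <- function(tree, weights, po) {
  nn <- length(tree$tip.label) + tree$Nnode
  mass <- numeric(nn)
  idx <- match(names(weights), tree$tip.label)
  if (anyNA(idx)) {
    abort_parameter(paste0(
      "Taxa missing from tree: ", toString(names(weights)[is.na(idx)])
    ))
  }
  tot <- sum(weights)
  mass[idx] <- if (tot > 0) weights / tot else 0
  for (k in seq_len(nrow(po$edge))) {
    mass[po$edge[k, 1]] <- mass[po$edge[k, 1]] + mass[po$edge[k, 2]]
  }
  mass[po$edge[, 2]]
}

#' UniFrac distance between two samples
#'
#' Unweighted UniFrac is the fraction of the branch length spanned by either
#' sample that is unique to one of them; weighted UniFrac is the
#' abundance-weighted formulation
#' `sum(b |p_A - p_B|) / sum(b (p_A + p_B))` over branches `b` with
#' per-branch relative-abundance masses `p` (the normalized variant; set
#' `variant = "raw"` for the unnormalized numerator).
#'
#' @param a,b For `mode = "unweighted"`, presence sets (character vectors);
#'   for `mode = "weighted"`, numeric count vectors named by taxon.
#' @param tree A rooted `phylo` tree whose tips cover both samples.
#' @param mode `"unweighted"` or `"weighted"`.
#' @param variant Weighted mode only: `"normalized"` (default) or `"raw"`.
#' @return A non-negative distance (in \[0, 1\] for unweighted and
#'   normalized weighted).
#' @export
beta_unifrac <- function(a, b, tree, mode = c("unweighted", "weighted"),
                         variant = c("normalized", "raw")) {
  mode <- match.arg(mode)
  variant <- match.arg(variant)
  tree <- validate_tree(tree)
  po <- postorder_edges(tree)
  if (mode == "unweighted") {
    wa <- stats::setNames(rep(1, length(unique(a))), unique(a))
    wb <- stats::setNames(rep(1, length(unique(b))), unique(b))
    ma <- edge_masses(tree, wa, po) > 0
    mb <- edge_masses(tree, wb, po) > 0
    denom <- sum(po$length[ma | mb])
    if (denom == 0) return(0)
    sum(po$length[xor(ma, mb)]) / denom
  } else {
    if (is.null(names(a)) || is.null(names(b))) {
      abort_parameter("Weighted UniFrac needs taxon-named count vectors.")
    }
    ma <- edge_masses(tree, a[a > 0], po)
    mb <- edge_masses(tree, b[b > 0], po)
    num <- sum(po$length * abs(ma - mb))
    if (variant == "raw") return(num)
    denom <- sum(po$length * (ma + mb))
    if (denom == 0) return(0)
    num / denom
  }
}

#' All pairwise beta diversities of a feature table
#'
#' @param table A feature-table tibble.
#' @param metric One of `"jaccard"`, `"bray_curtis"`,
#'   `"unweighted_unifrac"`, `"weighted_unifrac"`.
#' @param tree Required for the UniFrac metrics.
#' @param threshold Presence threshold for the presence-based metrics.
#' @param variant Weighted-UniFrac variant, see [beta_unifrac()].
#' @return A symmetric distance matrix with sample ids as dimnames.
#' @export
beta_diversity <- function(table,
                           metric = c("jaccard", "bray_curtis",
                                      "unweighted_unifrac", "weighted_unifrac"),
                           tree = NULL, threshold = 1,
                           variant = c("normalized", "raw")) {
  metric <- match.arg(metric)
  variant <- match.arg(variant)
  table <- as_feature_table(table)
  m <- ft_matrix(table)
  n <- nrow(m)
  ids <- rownames(m)
  needs_tree <- grepl("unifrac", metric)
  if (needs_tree && is.null(tree)) {
    abort_parameter(paste0("Metric `", metric, "` requires a tree."))
  }
  if (needs_tree) {
    tree <- validate_tree(tree)
    po <- postorder_edges(tree)
    mass <- sapply(seq_len(n), function(i) {
      w <- m[i, ]
      edge_masses(tree, w[w > 0], po)
    })
    if (metric == "unweighted_unifrac") pres <- mass > 0
  }
  sets <- if (metric == "jaccard") {
    lapply(seq_len(n), function(i) colnames(m)[m[i, ] >= threshold])
  }
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      d <- switch(metric,
        jaccard = beta_jaccard(sets[[i]], sets[[j]]),
        bray_curtis = beta_bray_curtis(m[i, ], m[j, ]),
        unweighted_unifrac = {
          ui <- pres[, i]; uj <- pres[, j]
          denom <- sum(po$length[ui | uj])
          if (denom == 0) 0 else sum(po$length[xor(ui, uj)]) / denom
        },
        weighted_unifrac = {
          num <- sum(po$length * abs(mass[, i] - mass[, j]))
          if (variant == "raw") num else {
            denom <- sum(po$length * (mass[, i] + mass[, j]))
            if (denom == 0) 0 else num / denom
          }
        }
      )
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}
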