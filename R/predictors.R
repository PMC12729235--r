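# Construction of the 17-feature baseline predictor matrix: 3 alpha
# diversity metrics, 4 recipient-to-donor beta diversity distances, and the
# ten globally most abundant pre-FMT genera.

ALPHA_FEATURES <- c("observed_features", "pielou_evenness", "faith_pd")
BETA_FEATURES <- c("bray_curtis_to_donor", "jaccard_to_donor",
                   "unweighted_unifrac_to_donor", "weighted_unifrac_to_donor")

#' Rank the most abundant genera across baseline samples
#'
#' Genera ranked by mean relative abundance across the given samples (ties
#' broken by genus name for determinism).
#'
#' @param table Genus-level feature-table tibble restricted to (or
#'   containing) the baseline samples.
#' @param sample_ids Samples over which to average (default: all rows).
#' @param n How many genera to return (default 10).
#' @return Character vector of genus names, most abundant first.
#' @export
top_abundant_genera <- function(table, sample_ids = NULL, n = 10) {
  rel <- relative_abundance(table)
  if (!is.null(sample_ids)) rel <- rel[rel$sample_id %in% sample_ids, ]
  if (nrow(rel) == 0) abort_parameter("No samples to rank genera over.")
  mm <- as.matrix(rel[, setdiff(names(rel), "sample_id")])
  means <- colMeans(mm)
  ord <- order(-means, colnames(mm))
  colnames(mm)[ord][seq_len(min(n, ncol(mm)))]
}

#' Build the 17-feature pre-FMT predictor matrix
#'
#' For each recipient's baseline (day-0) sample: the three alpha metrics;
#' the four beta-diversity distances from that sample to the pooled donor
#' profile (the sum of all donor samples' counts); and the baseline
#' relative abundances of the ten genera with the highest mean baseline
#' relative abundance across all recipients. Recipients lacking a baseline
#' sample are dropped with a warning.
#'
#' @param table Genus-level (typically rarefied) feature-table tibble
#'   containing donor and recipient-baseline samples.
#' @param metadata Validated sample metadata.
#' @param tree Rooted `phylo` tree (required for the Faith and UniFrac
#'   features; set `phylogenetic = FALSE` to build the 14 non-phylogenetic
#'   features without one).
#' @param baseline_day Study day of the pre-FMT sample (default 0).
#' @param n_top Number of top genera (default 10).
#' @param threshold Presence threshold for the presence-based metrics.
#' @param phylogenetic Include Faith PD and the UniFrac distances.
#' @return A tibble with `subject_id`, `treatment` and one column per
#'   feature, carrying a `feature_categories` attribute (feature ->
#'   `"alpha"`/`"beta"`/`"top_taxa"`) used by
#'   [compare_feature_categories()].
#' @export
build_predictors <- function(table, metadata, tree = NULL, baseline_day = 0,
                             n_top = 10, threshold = 1, phylogenetic = TRUE) {
  table <- as_feature_table(table)
  metadata <- as_sample_metadata(metadata)
  if (phylogenetic && is.null(tree)) {
    abort_parameter("Phylogenetic features requested but no tree supplied.")
  }
  m <- ft_matrix(table)

  donors <- metadata$sample_id[metadata$role == "donor"]
  donors <- intersect(donors, rownames(m))
  if (length(donors) == 0) abort_parameter("No donor samples in the table.")
  donor_counts <- colSums(m[donors, , drop = FALSE])

  rec <- metadata[metadata$role == "recipient" & metadata$day == baseline_day, ]
  missing <- setdiff(rec$subject_id, rec$subject_id[rec$sample_id %in% rownames(m)])
  all_rec <- unique(metadata$subject_id[metadata$role == "recipient"])
  no_baseline <- setdiff(all_rec, rec$subject_id)
  dropped <- union(missing, no_baseline)
  if (length(dropped)) {
    warn(paste0("Recipient(s) without a day-", baseline_day,
                " sample dropped: ", toString(dropped)))
  }
  rec <- rec[rec$sample_id %in% rownames(m), ]
  if (nrow(rec) == 0) abort_parameter("No recipient baseline samples available.")

  top <- top_abundant_genera(table, sample_ids = rec$sample_id, n = n_top)
  rel <- relative_abundance(table)
  relm <- as.matrix(rel[, setdiff(names(rel), "sample_id")])
  rownames(relm) <- rel$sample_id

  donor_set <- names(donor_counts)[donor_counts >= threshold]
  donor_named <- donor_counts

  rows <- lapply(seq_len(nrow(rec)), function(i) {
    sid <- rec$sample_id[i]
    counts <- m[sid, ]
    pres <- names(counts)[counts >= threshold]
    feats <- c(
      observed_features = alpha_observed(counts),
      pielou_evenness = alpha_pielou(counts),
      bray_curtis_to_donor = beta_bray_curtis(counts, donor_counts),
      jaccard_to_donor = beta_jaccard(pres, donor_set)
    )
    if (phylogenetic) {
      feats <- c(feats,
        faith_pd = alpha_faith(pres, tree),
        unweighted_unifrac_to_donor = beta_unifrac(pres, donor_set, tree,
                                                   mode = "unweighted"),
        weighted_unifrac_to_donor = beta_unifrac(counts, donor_named, tree,
                                                 mode = "weighted")
      )
    }
    genus_feats <- stats::setNames(relm[sid, top], top)
    c(feats, genus_feats)
  })
  feat_mat <- do.call(rbind, rows)

  out <- dplyr::bind_cols(
    tibble(subject_id = rec$subject_id, treatment = rec$treatment),
    as_tibble(feat_mat)
  )
  keep <- stats::complete.cases(feat_mat)
  if (any(!keep)) {
    warn(paste0("Recipient(s) with undefined features dropped: ",
                toString(out$subject_id[!keep])))
    out <- out[keep, ]
  }
  feat_names <- colnames(feat_mat)
  cats <- dplyr::case_when(
    feat_names %in% ALPHA_FEATURES ~ "alpha",
    feat_names %in% BETA_FEATURES ~ "beta",
    TRUE ~ "top_taxa"
  )
  attr(out, "feature_categories") <- stats::setNames(cats, feat_names)
  out
}

#' Extract the numeric feature matrix from a predictor tibble
#'
#' @param predictors Tibble from [build_predictors()].
#' @return Numeric matrix (recipients x features) with subject ids as row
#'   names and the `feature_categories` attribute carried over.
#' @export
predictor_matrix <- function(predictors) {
  cats <- attr(predictors, "feature_categories")
  m <- as.matrix(predictors[, setdiff(names(predictors),
                                      c("subject_id", "treatment"))])
  rownames(m) <- predictors$subject_id
  attr(m, "feature_categories") <- cats
  m
}
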