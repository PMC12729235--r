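# Table normalization: rarefaction to even depth, ASV-to-genus collapse,
# relative abundance and presence sets. These mirror the standard amplicon
# preprocessing the outcome classifier assumes.

#' Rarefy a feature table to a fixed depth
#'
#' Subsamples each sample's reads without replacement (multivariate
#' hypergeometric) down to `depth`. Samples with fewer than `depth` total
#' counts are dropped with a logged list rather than an error, mirroring
#' standard amplicon practice.
#'
#' @param table A feature-table tibble.
#' @param depth Positive integer target depth. The study this package
#'   emulates used 45,110 reads per sample; the default here is a config
#'   value, not a constant.
#' @param seed Integer seed; identical seeds give identical output.
#' @return A rarefied feature-table tibble in which every retained sample
#'   sums exactly to `depth`.
#' @export
rarefy <- function(table, depth, seed = 1L) {
  table <- as_feature_table(table)
  if (length(depth) != 1 || !is.finite(depth) || depth < 1 || depth != floor(depth)) {
    abort_parameter("`depth` must be a positive integer.")
  }
  m <- ft_matrix(table)
  totals <- rowSums(m)
  keep <- totals >= depth
  if (any(!keep)) {
    inform(paste0(
      "Dropped ", sum(!keep), " sample(s) below depth ", depth, ": ",
      toString(rownames(m)[!keep])
    ))
  }
  if (!any(keep)) abort_parameter("All samples fall below the rarefaction depth.")
  m <- m[keep, , drop = FALSE]
  out <- withr::with_seed(as.integer(seed), {
    t(apply(m, 1, rarefy_counts, depth = depth))
  })
  dimnames(out) <- dimnames(m)
  ft_from_matrix(out)
}

# One sample: draw `depth` reads without replacement from the expanded read
# pool. When the sample total equals depth this is the identity.
rarefy_counts <- function(counts, depth) {
  total <- sum(counts)
  if (total == depth) return(counts)
  pool <- rep.int(seq_along(counts), counts)
  drawn <- sample(pool, depth, replace = FALSE)
  tabulate(drawn, nbins = length(counts))
}

#' Collapse an ASV-level table to the genus level
#'
#' Counts of ASVs sharing a genus label are summed. ASVs unresolved at the
#' genus rank collapse to `"unclassified <deepest resolved rank>"` (e.g.
#' `"unclassified Lachnospiraceae"` for a family-level assignment), keeping
#' distinct unclassified lineages apart. Per-sample totals are conserved.
#'
#' @param table A feature-table tibble keyed by ASV/taxon id.
#' @param taxonomy A taxonomy tibble from [read_taxonomy()]/[as_taxonomy()].
#' @return A genus-level feature-table tibble.
#' @export
collapse_to_genus <- function(table, taxonomy) {
  table <- as_feature_table(table)
  taxonomy <- as_taxonomy(taxonomy)
  taxa <- setdiff(names(table), "sample_id")
  missing <- setdiff(taxa, taxonomy$taxon_id)
  if (length(missing)) {
    abort_format(paste0(
      "Taxonomy entry missing for taxon(s): ", toString(head(missing, 10)),
      if (length(missing) > 10) paste0(" and ", length(missing) - 10, " more")
    ))
  }
  labels <- taxonomy$genus_label[match(taxa, taxonomy$taxon_id)]
  m <- ft_matrix(table)
  collapsed <- t(rowsum(t(m), group = labels))
  ft_from_matrix(collapsed[, sort(colnames(collapsed)), drop = FALSE])
}

#' Relative abundances
#'
#' @param table A feature-table tibble with positive per-sample totals.
#' @return A tibble in feature-table layout whose rows sum to 1.
#' @export
relative_abundance <- function(table) {
  table <- as_feature_table(table)
  m <- ft_matrix(table)
  totals <- rowSums(m)
  if (any(totals == 0)) {
    abort_parameter(paste0(
      "Zero-sum sample(s): ", toString(rownames(m)[totals == 0])
    ))
  }
  rel <- sweep(m, 1, totals, "/")
  dplyr::bind_cols(tibble(sample_id = rownames(rel)), as_tibble(rel))
}

#' Presence sets per sample
#'
#' A genus is called present when its count reaches the detection threshold.
#' The study's outcome definitions work purely on these sets.
#'
#' @param table A feature-table tibble (typically rarefied and genus-level).
#' @param threshold Minimum count for presence (default 1).
#' @return A long tibble with columns `sample_id` and `taxon`, one row per
#'   present genus. Samples with no present genus contribute no rows.
#' @export
presence_sets <- function(table, threshold = 1) {
  table <- as_feature_table(table)
  if (length(threshold) != 1 || threshold < 1) {
    abort_parameter("`threshold` must be >= 1.")
  }
  m <- ft_matrix(table)
  idx <- which(m >= threshold, arr.ind = TRUE)
  tibble(
    sample_id = rownames(m)[idx[, 1]],
    taxon = colnames(m)[idx[, 2]]
  ) |> dplyr::arrange(.data$sample_id, .data$taxon)
}

# Named list of character vectors, one per sample (samples with empty sets
# included when `samples` given).
presence_list <- function(presence, samples = NULL) {
  sets <- split(presence$taxon, presence$sample_id)
  if (!is.null(samples)) {
    out <- stats::setNames(vector("list", length(samples)), samples)
    for (s in samples) out[[s]] <- sets[[s]] %||% character(0)
    sets <- out
  }
  sets
}
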