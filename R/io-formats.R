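# Readers and writers for the plain-text artifacts the pipeline touches:
# feature tables, taxonomy maps, sample metadata, newick trees and square
# distance matrices. All tabular artifacts are tab-separated.

TREATMENT_LEVELS <- c("control", "oral", "rectal", "in_feed")
ROLE_LEVELS <- c("donor", "recipient")
TAXONOMIC_RANKS <- c("domain", "phylum", "class", "order", "family", "genus")

#' Validate a samples-by-taxa feature table
#'
#' A feature table is a wide tibble whose first column, `sample_id`, holds
#' unique sample identifiers and whose remaining columns hold non-negative
#' integer counts, one column per taxon.
#'
#' @param x A data frame in feature-table layout.
#' @return The validated table as a tibble (invisibly usable in pipes).
#' @export
as_feature_table <- function(x) {
  x <- as_tibble(x)
  if (!"sample_id" %in% names(x) || names(x)[1] != "sample_id") {
    abort_format("A feature table must have `sample_id` as its first column.")
  }
  x$sample_id <- as.character(x$sample_id)
  if (anyDuplicated(x$sample_id)) {
    dup <- unique(x$sample_id[duplicated(x$sample_id)])
    abort_format(paste0("Duplicated sample id(s): ", toString(dup)))
  }
  taxa <- setdiff(names(x), "sample_id")
  if (anyDuplicated(taxa)) {
    dup <- unique(taxa[duplicated(taxa)])
    abort_format(paste0("Duplicated taxon id(s): ", toString(dup)))
  }
  for (tx in taxa) {
    v <- x[[tx]]
    if (!is.numeric(v)) {
      abort_format(paste0("Non-numeric counts in taxon column `", tx, "`."))
    }
    if (anyNA(v) || any(v < 0) || any(v != floor(v))) {
      abort_format(paste0(
        "Counts must be non-negative integers; offending taxon: `", tx, "`."
      ))
    }
    x[[tx]] <- as.integer(round(v))
  }
  x
}

#' Read a feature table from TSV
#'
#' @param path Path to a tab-separated file.
#' @param taxa_as `"columns"` (samples as rows, the native layout) or
#'   `"rows"` (taxa as rows, the transposed dialect common in amplicon
#'   tooling; the first column is then the taxon id and the header carries
#'   sample ids).
#' @return A validated feature-table tibble.
#' @export
read_feature_table <- function(path, taxa_as = c("columns", "rows")) {
  taxa_as <- match.arg(taxa_as)
  if (!file.exists(path)) abort_format(paste0("No such file: ", path))
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(raw) < 2) abort_format("Feature table needs an id column and at least one count column.")
  if (taxa_as == "rows") {
    ids <- as.character(raw[[1]])
    if (anyDuplicated(ids)) {
      abort_format(paste0(
        "Duplicated taxon id(s): ", toString(unique(ids[duplicated(ids)]))
      ))
    }
    m <- t(as.matrix(raw[, -1]))
    colnames(m) <- ids
    raw <- dplyr::bind_cols(tibble(sample_id = rownames(m)), as_tibble(m))
  } else {
    names(raw)[1] <- "sample_id"
  }
  as_feature_table(raw)
}

#' Write a feature table to TSV
#'
#' @inheritParams read_feature_table
#' @param table A feature-table tibble.
#' @export
write_feature_table <- function(table, path, taxa_as = c("columns", "rows")) {
  taxa_as <- match.arg(taxa_as)
  table <- as_feature_table(table)
  if (taxa_as == "rows") {
    m <- ft_matrix(table)
    out <- dplyr::bind_cols(
      tibble(taxon_id = colnames(m)),
      as_tibble(t(m))
    )
    readr::write_tsv(out, path, progress = FALSE)
  } else {
    readr::write_tsv(table, path, progress = FALSE)
  }
  invisible(path)
}

# Matrix view of a feature table (rows = samples).
ft_matrix <- function(table) {
  m <- as.matrix(table[, setdiff(names(table), "sample_id"), drop = FALSE])
  rownames(m) <- table$sample_id
  storage.mode(m) <- "double"
  m
}

ft_from_matrix <- function(m) {
  as_feature_table(dplyr::bind_cols(
    tibble(sample_id = rownames(m)), as_tibble(m)
  ))
}

#' Read sample metadata
#'
#' Expects columns `sample_id`, `subject_id`, `role`, `treatment`, `day`.
#' Roles are `donor`/`recipient`; recipient records must carry one of the four
#' treatment arms (`control`, `oral`, `rectal`, `in_feed`) and an integer
#' study day. Donor records may leave treatment and day empty.
#'
#' @param path Path to a tab-separated metadata file.
#' @return A validated tibble of sample records.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) abort_format(paste0("No such file: ", path))
  md <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  as_sample_metadata(md)
}

#' Validate a sample-metadata data frame
#'
#' @param md A data frame with the metadata columns described in
#'   [read_metadata()].
#' @return A validated tibble.
#' @export
as_sample_metadata <- function(md) {
  md <- as_tibble(md)
  need <- c("sample_id", "subject_id", "role", "treatment", "day")
  missing <- setdiff(need, names(md))
  if (length(missing)) {
    abort_format(paste0("Metadata missing column(s): ", toString(missing)))
  }
  md <- dplyr::mutate(md, dplyr::across(c("sample_id", "subject_id", "role", "treatment"),
                                        as.character))
  md$day <- suppressWarnings(as.integer(md$day))
  if (anyDuplicated(md$sample_id)) {
    abort_format(paste0(
      "Duplicated sample id(s): ",
      toString(unique(md$sample_id[duplicated(md$sample_id)]))
    ))
  }
  bad_role <- setdiff(unique(md$role), ROLE_LEVELS)
  if (length(bad_role)) {
    abort_format(paste0("Unknown role(s): ", toString(bad_role),
                        "; allowed: ", toString(ROLE_LEVELS)))
  }
  rec <- md[md$role == "recipient", ]
  bad_trt <- setdiff(unique(rec$treatment), TREATMENT_LEVELS)
  bad_trt <- bad_trt[!is.na(bad_trt) & bad_trt != ""]
  if (length(bad_trt) || any(is.na(rec$treatment) | rec$treatment == "")) {
    if (length(bad_trt)) {
      abort_format(paste0("Unknown treatment(s): ", toString(bad_trt),
                          "; allowed: ", toString(TREATMENT_LEVELS)))
    }
    abort_format("Recipient records must carry a treatment arm.")
  }
  if (anyNA(rec$day)) {
    abort_format(paste0(
      "Recipient record(s) missing study day: ",
      toString(rec$sample_id[is.na(rec$day)])
    ))
  }
  md$treatment[md$treatment %in% ""] <- NA_character_
  md
}

#' Read a taxonomy map
#'
#' Two tab-separated columns: `taxon_id` and a semicolon-delimited lineage in
#' canonical rank order (domain; phylum; class; order; family; genus).
#' Unresolved ranks may be empty, `NA`, `unclassified`, or QIIME-style empty
#' prefixes (`g__`); rank prefixes (`d__`, `p__`, ...) are stripped.
#'
#' @param path Path to the taxonomy TSV.
#' @return A tibble with `taxon_id`, one column per rank (NA when
#'   unresolved), and a `genus_label` column where unresolved genera get an
#'   `"unclassified <deepest resolved rank>"` label.
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) abort_format(paste0("No such file: ", path))
  tx <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  if (ncol(tx) < 2) abort_format("Taxonomy needs taxon_id and lineage columns.")
  names(tx)[1:2] <- c("taxon_id", "lineage")
  as_taxonomy(tx[, 1:2])
}

#' Validate/parse a taxonomy data frame
#'
#' @param tx A data frame with `taxon_id` and `lineage` columns (see
#'   [read_taxonomy()]), or one already carrying the six rank columns.
#' @return A parsed taxonomy tibble with per-rank columns and `genus_label`.
#' @export
as_taxonomy <- function(tx) {
  tx <- as_tibble(tx)
  if (!"taxon_id" %in% names(tx)) abort_format("Taxonomy needs a `taxon_id` column.")
  if (anyDuplicated(tx$taxon_id)) {
    abort_format(paste0(
      "Duplicated taxon id(s) in taxonomy: ",
      toString(unique(tx$taxon_id[duplicated(tx$taxon_id)]))
    ))
  }
  if (!all(TAXONOMIC_RANKS %in% names(tx))) {
    if (!"lineage" %in% names(tx)) {
      abort_format("Taxonomy needs either a `lineage` column or all rank columns.")
    }
    ranks <- parse_lineages(tx$lineage)
    tx <- dplyr::bind_cols(tx["taxon_id"], ranks)
  }
  tx$genus_label <- genus_labels(tx)
  tx
}

parse_lineages <- function(lineage) {
  parts <- strsplit(as.character(lineage), ";", fixed = TRUE)
  clean <- function(tok) {
    tok <- trimws(tok)
    tok <- sub("^[dkpcofgs]__", "", tok)
    tok[tok == "" | is.na(tok) | tolower(tok) == "na" |
          grepl("^unclassified$", tok, ignore.case = TRUE)] <- NA_character_
    tok
  }
  m <- t(vapply(parts, function(p) {
    p <- clean(p)
    length(p) <- length(TAXONOMIC_RANKS)
    p
  }, character(length(TAXONOMIC_RANKS))))
  colnames(m) <- TAXONOMIC_RANKS
  as_tibble(m)
}

# Genus label for classification: the resolved genus, or
# "unclassified <deepest resolved rank>" so distinct unclassified families
# are not merged into one artificial genus.
genus_labels <- function(tx) {
  vapply(seq_len(nrow(tx)), function(i) {
    g <- tx$genus[i]
    if (!is.na(g)) return(g)
    for (r in rev(TAXONOMIC_RANKS[-length(TAXONOMIC_RANKS)])) {
      v <- tx[[r]][i]
      if (!is.na(v)) return(paste("unclassified", v))
    }
    paste("unclassified", tx$taxon_id[i])
  }, character(1))
}

#' Read a rooted newick tree
#'
#' Thin wrapper over [ape::read.tree()] adding the validation the pipeline
#' relies on: unique tip labels and non-negative branch lengths. Missing
#' branch lengths default to 0 with a warning.
#'
#' @param path Path to a newick file.
#' @return An [ape] `phylo` object.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) abort_format(paste0("No such file: ", path))
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) abort_format(paste0("Newick parse error: ", conditionMessage(e))))
  if (is.null(tree)) abort_format("Newick parse error: empty or malformed tree.")
  validate_tree(tree)
}

validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) abort_format("Not a phylogenetic tree.")
  if (anyDuplicated(tree$tip.label)) {
    abort_format(paste0(
      "Duplicated tip label(s): ",
      toString(unique(tree$tip.label[duplicated(tree$tip.label)]))
    ))
  }
  if (is.null(tree$edge.length)) {
    warn("Tree has no branch lengths; defaulting all to 0.")
    tree$edge.length <- rep(0, nrow(tree$edge))
  }
  if (anyNA(tree$edge.length)) {
    warn("Missing branch lengths; defaulting them to 0.")
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  if (any(tree$edge.length < 0)) abort_format("Negative branch lengths.")
  tree
}

#' Read/write a square distance matrix
#'
#' TSV with sample ids on both axes. Symmetry (to 1e-12) and a zero diagonal
#' are enforced.
#'
#' @param path Path to the TSV file.
#' @return A symmetric numeric matrix with sample ids as dimnames.
#' @export
read_distance_matrix <- function(path) {
  if (!file.exists(path)) abort_format(paste0("No such file: ", path))
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  ids <- as.character(raw[[1]])
  m <- as.matrix(raw[, -1])
  rownames(m) <- ids
  if (!identical(colnames(m), ids)) {
    abort_format("Distance matrix row and column ids differ.")
  }
  validate_distance_matrix(m)
}

#' @rdname read_distance_matrix
#' @param dm A symmetric distance matrix with dimnames.
#' @export
write_distance_matrix <- function(dm, path) {
  dm <- validate_distance_matrix(dm)
  out <- dplyr::bind_cols(tibble(sample_id = rownames(dm)), as_tibble(dm))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

validate_distance_matrix <- function(dm) {
  dm <- as.matrix(dm)
  if (nrow(dm) != ncol(dm)) abort_format("Distance matrix is not square.")
  if (is.null(rownames(dm))) abort_format("Distance matrix lacks sample ids.")
  if (anyNA(dm)) abort_format("Distance matrix contains missing values.")
  if (any(dm < 0)) abort_format("Distances must be non-negative.")
  if (max(abs(dm - t(dm))) > 1e-12) abort_format("Distance matrix is not symmetric.")
  if (any(diag(dm) != 0)) abort_format("Distance matrix diagonal must be exactly 0.")
  dm
}
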