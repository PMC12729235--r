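# The core computation: classify every genus of a donor/pre/post triad into
# the six ecological outcomes of FMT, normalize per recipient, and average
# per treatment arm and study day.
#
# With D, R, P the presence sets of donor, pre-FMT recipient and post-FMT
# recipient, and |P| the post-FMT genus count:
#   colonization = |D & P  - R| / |P|   donor genus that established
#   rejection    = |D - R - P| / |P|   donor genus that never appeared
#   coexistence  = |D & R & P| / |P|   shared genus that survived
#   persistence  = |R & P - D| / |P|   recipient-only genus that survived
#   novel        = |P - D - R| / |P|   genus from neither source
#   loss         = |R - D - P| / |P|   recipient-only genus that vanished
# The four categories inside P partition it, so their fractions sum to 1.
# One membership pattern (genus in both D and R but absent from P) falls
# outside all six definitions; it is tracked separately as `shared_loss`
# so the category lists jointly cover D | R | P.

OUTCOME_CATEGORIES <- c("colonization", "rejection", "coexistence",
                        "persistence", "novel", "loss")

#' Classify one donor/pre/post triad
#'
#' @param donor,pre,post Character presence sets for the donor community,
#'   the recipient before FMT, and the recipient after FMT.
#' @return A one-row tibble with the six outcome fractions, the auxiliary
#'   `shared_loss` fraction (donor-and-recipient genera that disappeared
#'   post-FMT; outside the six canonical categories), `n_post` = `|P|`, and
#'   list-columns holding the genus list behind every category.
#' @export
classify_triad <- function(donor, pre, post) {
  donor <- unique(donor); pre <- unique(pre); post <- unique(post)
  n_post <- length(post)
  if (n_post == 0) {
    abort_parameter("Post-FMT presence set is empty; outcome fractions are undefined.")
  }
  lists <- list(
    colonization = setdiff(intersect(donor, post), pre),
    rejection    = setdiff(setdiff(donor, pre), post),
    coexistence  = intersect(intersect(donor, pre), post),
    persistence  = setdiff(intersect(pre, post), donor),
    novel        = setdiff(setdiff(post, donor), pre),
    loss         = setdiff(setdiff(pre, donor), post),
    shared_loss  = setdiff(intersect(donor, pre), post)
  )
  fr <- vapply(lists, length, integer(1)) / n_post
  tibble(
    colonization = fr[["colonization"]],
    rejection = fr[["rejection"]],
    coexistence = fr[["coexistence"]],
    persistence = fr[["persistence"]],
    novel = fr[["novel"]],
    loss = fr[["loss"]],
    shared_loss = fr[["shared_loss"]],
    n_post = n_post,
    colonization_genera = list(lists$colonization),
    rejection_genera = list(lists$rejection),
    coexistence_genera = list(lists$coexistence),
    persistence_genera = list(lists$persistence),
    novel_genera = list(lists$novel),
    loss_genera = list(lists$loss),
    shared_loss_genera = list(lists$shared_loss)
  )
}

#' Build donor/pre/post triads from presence sets and metadata
#'
#' One triad is formed per recipient per post-FMT day: the pooled donor set,
#' the recipient's day-0 set, and the recipient's set on that day.
#' Recipients lacking a day-0 sample are skipped with a warning.
#'
#' @param presence Long presence tibble from [presence_sets()].
#' @param metadata Validated metadata tibble (see [read_metadata()]).
#' @param donor_policy `"union"` (default; donor set is the union over all
#'   donor samples, the in-silico analogue of a physically pooled donor) or
#'   `"single"` (exactly one donor sample must exist).
#' @param baseline_day Study day of the pre-FMT sample (default 0).
#' @return A tibble with one row per triad: `subject_id`, `treatment`,
#'   `day`, and list-columns `donor_set`, `pre_set`, `post_set`.
#' @export
build_triads <- function(presence, metadata,
                         donor_policy = c("union", "single"),
                         baseline_day = 0) {
  donor_policy <- match.arg(donor_policy)
  metadata <- as_sample_metadata(metadata)
  sets <- presence_list(presence, samples = metadata$sample_id)
  donors <- metadata$sample_id[metadata$role == "donor"]
  if (length(donors) == 0) abort_parameter("No donor samples in metadata.")
  if (donor_policy == "single" && length(donors) != 1) {
    abort_parameter(paste0(
      "donor_policy = 'single' requires exactly one donor sample; found ",
      length(donors)
    ))
  }
  donor_set <- sort(unique(unlist(sets[donors], use.names = FALSE)))

  rec <- metadata[metadata$role == "recipient", ]
  out <- list()
  for (subj in unique(rec$subject_id)) {
    rows <- rec[rec$subject_id == subj, ]
    base <- rows[rows$day == baseline_day, ]
    if (nrow(base) == 0) {
      warn(paste0("Recipient ", subj, " lacks a day-", baseline_day,
                  " sample; skipped."))
      next
    }
    pre_set <- sets[[base$sample_id[1]]]
    posts <- rows[rows$day > baseline_day, ]
    for (i in seq_len(nrow(posts))) {
      out[[length(out) + 1]] <- tibble(
        subject_id = subj,
        treatment = posts$treatment[i],
        day = posts$day[i],
        donor_set = list(donor_set),
        pre_set = list(pre_set),
        post_set = list(sets[[posts$sample_id[i]]])
      )
    }
  }
  if (length(out) == 0) abort_parameter("No triads could be built.")
  dplyr::bind_rows(out)
}

#' Classify every triad of a cohort
#'
#' @param triads Triad tibble from [build_triads()].
#' @return The triads' identifying columns joined to each triad's outcome
#'   profile (see [classify_triad()]). Triads with an empty post-FMT set are
#'   dropped with a warning.
#' @export
classify_triads <- function(triads) {
  keep <- vapply(triads$post_set, length, integer(1)) > 0
  if (any(!keep)) {
    warn(paste0(sum(!keep), " triad(s) with an empty post-FMT set dropped."))
    triads <- triads[keep, ]
  }
  if (nrow(triads) == 0) abort_parameter("No classifiable triads.")
  profiles <- purrr::pmap(
    list(triads$donor_set, triads$pre_set, triads$post_set),
    classify_triad
  )
  dplyr::bind_cols(
    triads[, c("subject_id", "treatment", "day")],
    dplyr::bind_rows(profiles)
  )
}

#' Average outcome fractions per treatment arm and day
#'
#' The unweighted mean of per-recipient fractions (never pooled counts),
#' matching how per-arm engraftment is summarized in FMT studies.
#'
#' @param profiles Profile tibble from [classify_triads()].
#' @param by Grouping columns (default treatment and day).
#' @return A tibble of group means with `n_recipients` per group.
#' @export
summarize_outcomes <- function(profiles, by = c("treatment", "day")) {
  cols <- c(OUTCOME_CATEGORIES, "shared_loss")
  profiles |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(cols), mean),
      n_recipients = dplyr::n(),
      .groups = "drop"
    )
}

#' Genus-level report of colonizing and rejected taxa
#'
#' Annotates every genus in the chosen categories with its family and phylum
#' and counts genera per lineage, per arm and day.
#'
#' @param profiles Profile tibble from [classify_triads()].
#' @param taxonomy Genus-level taxonomy tibble: `genus_label` (or
#'   `taxon_id`) matching the profile genus lists, plus rank columns.
#' @param categories Outcome categories to report (default colonization and
#'   rejection).
#' @return A tibble with `treatment`, `day`, `category`, `genus`, `family`,
#'   `phylum` and `n_recipients` (how many recipients of that arm/day had
#'   the genus in the category).
#' @export
colonizer_taxon_report <- function(profiles, taxonomy,
                                   categories = c("colonization", "rejection")) {
  taxonomy <- as_taxonomy(taxonomy)
  key <- if (all(profiles_genera(profiles, categories) %in% taxonomy$genus_label)) {
    "genus_label"
  } else {
    "taxon_id"
  }
  rows <- list()
  for (cat in categories) {
    col <- paste0(cat, "_genera")
    long <- profiles |>
      dplyr::select(dplyr::all_of(c("subject_id", "treatment", "day", col))) |>
      tidyr::unnest_longer(dplyr::all_of(col), values_to = "genus") |>
      dplyr::mutate(category = cat)
    rows[[cat]] <- long
  }
  long <- dplyr::bind_rows(rows)
  if (nrow(long) == 0) {
    return(tibble(treatment = character(), day = integer(),
                  category = character(), genus = character(),
                  family = character(), phylum = character(),
                  n_recipients = integer()))
  }
  idx <- match(long$genus, taxonomy[[key]])
  long$family <- taxonomy$family[idx]
  long$phylum <- taxonomy$phylum[idx]
  long |>
    dplyr::count(.data$treatment, .data$day, .data$category, .data$genus,
                 .data$family, .data$phylum, name = "n_recipients") |>
    dplyr::arrange(.data$treatment, .data$day, .data$category,
                   dplyr::desc(.data$n_recipients))
}

profiles_genera <- function(profiles, categories) {
  unique(unlist(lapply(categories, function(cat) {
    unlist(profiles[[paste0(cat, "_genera")]], use.names = FALSE)
  }), use.names = FALSE))
}

#' Plot mean outcome fractions over time
#'
#' @param summary Summary tibble from [summarize_outcomes()].
#' @return A ggplot faceted by treatment, stacking the six outcome
#'   fractions per day.
#' @export
plot_outcome_fractions <- function(summary) {
  long <- summary |>
    tidyr::pivot_longer(dplyr::all_of(OUTCOME_CATEGORIES),
                        names_to = "outcome", values_to = "fraction")
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$day), y = .data$fraction,
                                     fill = .data$outcome)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::facet_wrap(ggplot2::vars(.data$treatment)) +
    ggplot2::labs(x = "Study day", y = "Mean fraction of post-FMT community",
                  fill = "Outcome") +
    ggplot2::theme_minimal()
}
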