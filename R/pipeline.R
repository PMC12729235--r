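# End-to-end pipeline: simulate (or load) -> prep -> diversity -> outcomes
# -> predict, driven by a YAML (or list) configuration, with a manifest of
# every artifact, its content digest, and every seed, so a run can be
# reproduced byte for byte.

#' Default pipeline configuration
#'
#' @param seed Master seed (mandatory in any config; stage seeds derive
#'   from it deterministically).
#' @param out_dir Output directory.
#' @return A nested configuration list with all recognized keys.
#' @export
pipeline_config <- function(seed = 1L, out_dir = tempfile("engraftr_run_")) {
  list(
    seed = as.integer(seed),
    out_dir = out_dir,
    simulate = list(enabled = TRUE),          # simulation_config() overrides
    inputs = NULL,                            # or list(table=, metadata=, taxonomy=, tree=)
    prep = list(depth = NULL, threshold = 1, collapse = FALSE),
    diversity = list(beta_metric = "jaccard", permutations = 999,
                     permanova_day = NULL, pcoa_axes = 2),
    outcomes = list(donor_policy = "union"),
    predict = list(enabled = TRUE, responses = c("colonization", "rejection"),
                   arms = NULL, day = 2, repeats = 5, folds = 5,
                   alpha_grid = seq(0, 1, by = 0.1), n_lambda = 100)
  )
}

read_pipeline_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) abort_config(paste0("No such config file: ", config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort_config("Config must be a list or a YAML file path.")
  base <- pipeline_config(seed = config$seed %||% NA_integer_,
                          out_dir = config$out_dir %||% tempfile("engraftr_run_"))
  cfg <- modifyList(base, config)
  validate_pipeline_config(cfg)
}

validate_pipeline_config <- function(cfg) {
  if (is.null(cfg$seed) || is.na(cfg$seed)) {
    abort_config("Config must set an explicit integer `seed` (no wall-clock default).")
  }
  cfg$seed <- as.integer(cfg$seed)
  simulate_on <- isTRUE(cfg$simulate$enabled %||% TRUE) && is.null(cfg$inputs)
  if (!simulate_on) {
    need <- c("table", "metadata")
    missing <- setdiff(need, names(cfg$inputs))
    if (length(missing)) {
      abort_config(paste0("inputs missing: ", toString(missing)))
    }
    for (p in unlist(cfg$inputs)) {
      if (!file.exists(p)) abort_config(paste0("Input file not found: ", p))
    }
    needs_tree <- grepl("unifrac", cfg$diversity$beta_metric %||% "jaccard")
    if (needs_tree && is.null(cfg$inputs$tree)) {
      abort_config("UniFrac requested but no tree in inputs.")
    }
  }
  cfg$.simulate_on <- simulate_on
  cfg
}

#' Run the full engraftment pipeline
#'
#' Stages run in dependency order: cohort simulation (or loading of
#' user-supplied tables), preparation (optional rarefaction and genus
#' collapse, presence sets), diversity (alpha table, beta distance matrix,
#' PCoA, per-day PERMANOVA on treatment), ecological outcomes (per-triad
#' profiles, per-arm summaries, colonizer report) and prediction
#' (cross-validated elastic net per arm and response). Any stage failure
#' halts the run with the stage named. A manifest recording the config,
#' every artifact's MD5 digest and every seed is written last.
#'
#' @param config A configuration list (see [pipeline_config()]) or the path
#'   to a YAML file with the same structure.
#' @return The manifest, invisibly; all artifacts are written under
#'   `out_dir`.
#' @export
run_pipeline <- function(config) {
  cfg <- read_pipeline_config(config)
  out_dir <- cfg$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- character(0)
  log_stage <- function(stage, msg) inform(paste0("[", stage, "] ", msg))
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("Pipeline stage `", stage, "` failed: ",
                   conditionMessage(e)), class = "engraftr_stage_error")
    })
  }

  # -- inputs ---------------------------------------------------------------
  if (cfg$.simulate_on) {
    cohort <- run_stage("simulate", {
      sim_args <- cfg$simulate
      sim_args$enabled <- NULL
      sim_args$seed <- sim_args$seed %||% cfg$seed
      sim <- simulate_cohort(do.call(simulation_config, sim_args))
      paths <- write_cohort(sim, file.path(out_dir, "cohort"))
      artifacts <- c(artifacts, paths)
      log_stage("simulate", paste0(nrow(sim$counts), " samples written"))
      sim
    })
    table <- cohort$counts
    metadata <- cohort$metadata
    taxonomy <- cohort$taxonomy
    tree <- cohort$tree
  } else {
    run_stage("load", {
      table <- read_feature_table(cfg$inputs$table)
      metadata <- read_metadata(cfg$inputs$metadata)
      taxonomy <- if (!is.null(cfg$inputs$taxonomy)) read_taxonomy(cfg$inputs$taxonomy)
      tree <- if (!is.null(cfg$inputs$tree)) read_newick(cfg$inputs$tree)
      log_stage("load", paste0(nrow(table), " samples loaded"))
    })
  }

  # -- prep -----------------------------------------------------------------
  prepped <- run_stage("prep", {
    tb <- table
    if (isTRUE(cfg$prep$collapse)) {
      if (is.null(taxonomy)) abort_config("Genus collapse requested but no taxonomy.")
      tb <- collapse_to_genus(tb, taxonomy)
    }
    if (!is.null(cfg$prep$depth)) {
      n_before <- nrow(tb)
      tb <- rarefy(tb, cfg$prep$depth, seed = cfg$seed + 1L)
      log_stage("prep", paste0(nrow(tb), "/", n_before,
                               " samples kept at depth ", cfg$prep$depth))
    }
    tb
  })
  presence <- presence_sets(prepped, threshold = cfg$prep$threshold)

  # -- diversity ------------------------------------------------------------
  run_stage("diversity", {
    alpha <- alpha_diversity(prepped, tree = tree)
    p_alpha <- file.path(out_dir, "alpha_diversity.tsv")
    readr::write_tsv(alpha, p_alpha, progress = FALSE)
    dm <- beta_diversity(prepped, metric = cfg$diversity$beta_metric,
                         tree = tree, threshold = cfg$prep$threshold)
    p_dm <- file.path(out_dir, "beta_distance.tsv")
    write_distance_matrix(dm, p_dm)
    ord <- pcoa_ordination(dm, k = cfg$diversity$pcoa_axes)
    p_ord <- file.path(out_dir, "pcoa_coordinates.tsv")
    readr::write_tsv(ord$points, p_ord, progress = FALSE)
    artifacts <- c(artifacts, alpha = p_alpha, beta = p_dm, pcoa = p_ord)

    # per-day treatment PERMANOVA on recipient samples
    rec <- metadata[metadata$role == "recipient", ]
    days <- cfg$diversity$permanova_day %||% setdiff(unique(rec$day), NA)
    perm_rows <- list()
    for (d in days) {
      ids <- rec$sample_id[rec$day == d & rec$sample_id %in% rownames(dm)]
      grp <- rec$treatment[match(ids, rec$sample_id)]
      if (length(unique(grp)) >= 2 && all(table(grp) >= 2)) {
        pr <- permanova(dm[ids, ids], grp,
                        n_permutations = cfg$diversity$permutations,
                        seed = cfg$seed + 2L + as.integer(d))
        perm_rows[[as.character(d)]] <- dplyr::bind_cols(tibble(day = d), tidy(pr))
      }
    }
    if (length(perm_rows)) {
      p_perm <- file.path(out_dir, "permanova.tsv")
      readr::write_tsv(dplyr::bind_rows(perm_rows), p_perm, progress = FALSE)
      artifacts <- c(artifacts, permanova = p_perm)
    }
    log_stage("diversity", paste0("alpha/beta/", cfg$diversity$beta_metric,
                                  "/PCoA written"))
  })

  # -- outcomes -------------------------------------------------------------
  profiles <- run_stage("outcomes", {
    triads <- build_triads(presence, metadata,
                           donor_policy = cfg$outcomes$donor_policy)
    prof <- classify_triads(triads)
    flat <- prof[, c("subject_id", "treatment", "day", OUTCOME_CATEGORIES,
                     "shared_loss", "n_post")]
    p_prof <- file.path(out_dir, "outcome_profiles.tsv")
    readr::write_tsv(flat, p_prof, progress = FALSE)
    summ <- summarize_outcomes(prof)
    p_summ <- file.path(out_dir, "outcome_summary.tsv")
    readr::write_tsv(summ, p_summ, progress = FALSE)
    artifacts <- c(artifacts, profiles = p_prof, summary = p_summ)
    if (!is.null(taxonomy)) {
      rep <- colonizer_taxon_report(prof, taxonomy)
      p_rep <- file.path(out_dir, "colonizer_report.tsv")
      readr::write_tsv(rep, p_rep, progress = FALSE)
      artifacts <- c(artifacts, colonizers = p_rep)
    }
    log_stage("outcomes", paste0(nrow(prof), " triads classified"))
    prof
  })

  # -- predict --------------------------------------------------------------
  if (isTRUE(cfg$predict$enabled)) {
    run_stage("predict", {
      preds <- build_predictors(prepped, metadata, tree = tree,
                                threshold = cfg$prep$threshold,
                                phylogenetic = !is.null(tree))
      arms <- cfg$predict$arms %||% setdiff(unique(preds$treatment), NA)
      rows <- list(); coef_rows <- list()
      for (arm in arms) {
        parm <- preds[preds$treatment == arm, ]
        xm <- predictor_matrix(parm)
        for (resp in cfg$predict$responses) {
          yv <- profiles[profiles$day == cfg$predict$day, ]
          y <- yv[[resp]][match(rownames(xm), yv$subject_id)]
          ok <- !is.na(y)
          if (sum(ok) < cfg$predict$folds) {
            warn(paste0("Too few recipients for ", arm, "/", resp, "; skipped."))
            next
          }
          cv <- cross_validate(xm[ok, , drop = FALSE], y[ok],
                               alpha_grid = cfg$predict$alpha_grid,
                               n_lambda = cfg$predict$n_lambda,
                               repeats = cfg$predict$repeats,
                               folds = cfg$predict$folds,
                               seed = cfg$seed + 10L)
          rows[[paste(arm, resp)]] <- dplyr::bind_cols(
            tibble(treatment = arm, response = resp), glance(cv)
          )
          coef_rows[[paste(arm, resp)]] <- dplyr::bind_cols(
            tibble(treatment = arm, response = resp), tidy(cv)
          )
        }
      }
      if (length(rows)) {
        p_fit <- file.path(out_dir, "prediction_models.tsv")
        readr::write_tsv(dplyr::bind_rows(rows), p_fit, progress = FALSE)
        p_coef <- file.path(out_dir, "prediction_coefficients.tsv")
        readr::write_tsv(dplyr::bind_rows(coef_rows), p_coef, progress = FALSE)
        artifacts <- c(artifacts, models = p_fit, coefficients = p_coef)
        log_stage("predict", paste0(length(rows), " model(s) fitted"))
      }
    })
  }

  # -- manifest -------------------------------------------------------------
  manifest <- list(
    tool = paste0("engraftr ", as.character(utils::packageVersion("engraftr"))),
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), ".simulate_on")],
    artifacts = lapply(stats::setNames(nm = names(artifacts)), function(nm) {
      list(path = unname(artifacts[[nm]]),
           md5 = unname(tools::md5sum(artifacts[[nm]])))
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null", force = TRUE)
  invisible(manifest)
}
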