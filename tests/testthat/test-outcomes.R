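test_that("the worked triad example classifies exactly", {
  prof <- classify_triad(donor = c("a", "b", "c"), pre = c("b", "d"),
                         post = c("a", "b", "d", "e"))
  expect_equal(prof$colonization, 0.25)
  expect_equal(prof$rejection, 0.25)
  expect_equal(prof$coexistence, 0.25)
  expect_equal(prof$persistence, 0.25)
  expect_equal(prof$novel, 0.25)
  expect_equal(prof$loss, 0)
  expect_equal(prof$colonization_genera[[1]], "a")
  expect_equal(prof$rejection_genera[[1]], "c")
  expect_equal(prof$persistence_genera[[1]], "d")
  expect_equal(prof$novel_genera[[1]], "e")
})

test_that("degenerate triads classify as their definitions force", {
  all_shared <- classify_triad(c("a", "b"), c("a", "b"), c("a", "b"))
  expect_equal(all_shared$coexistence, 1)
  expect_equal(sum(all_shared[, c("colonization", "rejection", "persistence",
                                  "novel", "loss")]), 0)

  forced <- classify_triad(donor = "a", pre = "b", post = "b")
  expect_equal(forced$rejection, 1)
  expect_equal(forced$persistence, 1)
  expect_equal(forced$colonization + forced$coexistence + forced$novel +
                 forced$loss, 0)

  expect_error(classify_triad("a", "b", character(0)),
               class = "engraftr_parameter_error")
})

test_that("classification matches the bit-triple oracle on random triads", {
  universe <- paste0("g", 1:300)
  withr::with_seed(71, {
    for (i in 1:200) {
      tr <- random_triad(universe, max_size = 120)
      if (length(tr$post) == 0) next
      prof <- classify_triad(tr$donor, tr$pre, tr$post)
      ref <- oracle_classify(tr$donor, tr$pre, tr$post)
      got <- unlist(prof[, names(ref)])
      expect_equal(got, ref, ignore_attr = TRUE)
      # the four within-P fractions partition P
      expect_equal(prof$colonization + prof$coexistence + prof$persistence +
                     prof$novel, 1, tolerance = 1e-12)
    }
  })
})

test_that("category genus lists are disjoint and cover the triad universe", {
  withr::with_seed(72, {
    universe <- paste0("g", 1:80)
    for (i in 1:50) {
      tr <- random_triad(universe, max_size = 40)
      prof <- classify_triad(tr$donor, tr$pre, tr$post)
      lists <- lapply(paste0(c(OUTCOME_CATEGORIES, "shared_loss"), "_genera"),
                      function(cl) prof[[cl]][[1]])
      all_members <- unlist(lists)
      expect_equal(anyDuplicated(all_members), 0)
      expect_setequal(all_members, union(union(tr$donor, tr$pre), tr$post))
    }
  })
})

test_that("moving a P-only genus into D converts novel to colonization", {
  withr::with_seed(73, {
    universe <- paste0("g", 1:60)
    for (i in 1:20) {
      tr <- random_triad(universe, max_size = 30)
      cand <- setdiff(setdiff(tr$post, tr$donor), tr$pre)
      if (length(cand) == 0) next
      g <- sample(cand, 1)
      before <- classify_triad(tr$donor, tr$pre, tr$post)
      after <- classify_triad(c(tr$donor, g), tr$pre, tr$post)
      expect_equal(after$colonization - before$colonization,
                   1 / length(unique(tr$post)), tolerance = 1e-12)
      expect_equal(before$novel - after$novel, 1 / length(unique(tr$post)),
                   tolerance = 1e-12)
    }
  })
})

test_that("triads are built per recipient and post-FMT day", {
  md <- simple_metadata()
  presence <- tibble::tibble(
    sample_id = c("d1", "d1", "d2", "d2", "r1_0", "r1_2", "r1_5", "r2_0", "r2_2"),
    taxon = c("a", "b", "b", "c", "b", "a", "a", "d", "d")
  )
  triads <- build_triads(presence, md)
  expect_equal(nrow(triads), 3)  # pig1 days 2 and 5, pig2 day 2
  # union donor policy pools donor samples
  expect_equal(triads$donor_set[[1]], c("a", "b", "c"))

  # recipient without a day-0 sample is skipped with a warning
  md2 <- md[md$sample_id != "r2_0", ]
  expect_warning(tr2 <- build_triads(presence[presence$sample_id != "r2_0", ], md2),
                 "pig2")
  expect_equal(nrow(tr2), 2)

  expect_error(build_triads(presence, md[md$role != "donor", ]),
               class = "engraftr_parameter_error")
  expect_error(build_triads(presence, md, donor_policy = "single"),
               class = "engraftr_parameter_error")
})

test_that("outcome summaries average per-recipient fractions, not pooled counts", {
  profiles <- tibble::tibble(
    subject_id = c("p1", "p2", "p3"),
    treatment = c("oral", "oral", "oral"),
    day = c(2L, 2L, 2L),
    colonization = c(0.10, 0.20, 0.60),
    rejection = 0, coexistence = 0, persistence = 0, novel = 0, loss = 0,
    shared_loss = 0,
    n_post = c(10L, 100L, 5L)
  )
  summ <- summarize_outcomes(profiles)
  expect_equal(summ$colonization, 0.3)
  expect_equal(summ$n_recipients, 3)
  # pooled-count mean would differ on this unbalanced input
  pooled <- sum(profiles$colonization * profiles$n_post) / sum(profiles$n_post)
  expect_false(isTRUE(all.equal(pooled, summ$colonization)))

  single <- summarize_outcomes(profiles[1, ])
  expect_equal(single$colonization, 0.1)
})

test_that("colonizer reports annotate lineage and conserve counts", {
  tx <- as_taxonomy(tibble::tibble(
    taxon_id = c("Dorea", "Prevotella"),
    lineage = c("Bacteria;Firmicutes;Clostridia;Lachnospirales;Lachnospiraceae;Dorea",
                "Bacteria;Bacteroidota;Bacteroidia;Bacteroidales;Prevotellaceae;Prevotella")
  ))
  profiles <- classify_triad(donor = c("Dorea", "Prevotella"),
                             pre = "Prevotella",
                             post = c("Dorea", "Prevotella"))
  profiles$subject_id <- "p1"; profiles$treatment <- "oral"; profiles$day <- 2L
  rep <- colonizer_taxon_report(profiles, tx)
  dorea <- rep[rep$genus == "Dorea", ]
  expect_equal(dorea$category, "colonization")
  expect_equal(dorea$family, "Lachnospiraceae")
  expect_equal(dorea$phylum, "Firmicutes")
  # per-phylum counts add up to the total colonizer count
  expect_equal(sum(rep$n_recipients[rep$category == "colonization"]),
               length(profiles$colonization_genera[[1]]))

  empty <- profiles
  empty$colonization_genera <- list(character(0))
  empty$rejection_genera <- list(character(0))
  expect_equal(nrow(colonizer_taxon_report(empty, tx)), 0)
})
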