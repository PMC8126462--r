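fake_est <- function(plant, use, classification, level = "general",
                     cat = "Med") {
  data.frame(plant = plant, use = use,
             level = rep(level, length.out = length(plant)),
             general_category = rep(cat, length.out = length(plant)),
             classification = classification,
             mean_root_p = ifelse(classification == "highly_likely", 0.9,
                                  0.5), stringsAsFactors = FALSE)
}

fake_scores <- function(plant, use, combined, level = "general",
                        cat = "Med") {
  data.frame(plant = plant, use = use, combined = combined,
             positive = combined >= 4,
             level = rep(level, length.out = length(plant)),
             general_category = rep(cat, length.out = length(plant)),
             stringsAsFactors = FALSE)
}

test_that("agreement cells follow the star-marking rule", {
  est <- fake_est(c("a", "b", "c", "d"), "Med",
                  c("highly_likely", "equivocal", "highly_likely",
                    "other"))
  sc <- fake_scores(c("a", "b", "c", "d"), "Med", c(4L, 5L, 3L, 1L))
  conc <- build_concordance(est, sc)
  cells <- setNames(conc$table$cell, conc$table$plant)
  expect_equal(unname(cells[c("a", "b", "c", "d")]),
               c("both_positive", "triangulation_only", "pcm_only",
                 "neither"))
})

test_that("the join is lossless and one-sided keys land in unscored", {
  est <- fake_est(c("a", "b"), "Med", c("highly_likely", "skipped"))
  sc <- fake_scores(c("a", "z"), "Med", c(5L, 4L))
  conc <- build_concordance(est, sc)
  expect_equal(nrow(conc$table), 3L)
  expect_equal(sum(conc$by_category[, c("both_positive", "pcm_only",
                                        "triangulation_only", "neither",
                                        "unscored")]),
               nrow(conc$table))
  cells <- setNames(conc$table$cell, conc$table$plant)
  expect_equal(unname(cells["b"]), "unscored")  # skipped by the model
  expect_equal(unname(cells["z"]), "unscored")  # no estimate
  expect_equal(unname(cells["a"]), "both_positive")
})

test_that("empty inputs give an empty table with zero counts", {
  conc <- build_concordance(fake_est(character(), character(),
                                     character()),
                            fake_scores(character(), character(),
                                        integer()))
  expect_equal(nrow(conc$table), 0L)
  expect_equal(conc$global$highly_likely[["total"]], 0L)
  expect_equal(sum(conc$by_category$n), 0L)
})

test_that("duplicate keys are rejected", {
  est <- fake_est(c("a", "a"), "Med", c("other", "other"))
  expect_error(build_concordance(est, NULL), "duplicate")
})

test_that("category summaries count members and flag empty categories", {
  est <- fake_est(c("a", "b", "c"), c("Food", "Food", "Agri"),
                  c("highly_likely", "highly_likely", "other"),
                  cat = c("Food", "Food", "Agri"))
  sc <- fake_scores(c("a", "b", "c"), c("Food", "Food", "Agri"),
                    c(4L, 5L, 1L), cat = c("Food", "Food", "Agri"))
  cs <- category_summary(build_concordance(est, sc))
  expect_equal(nrow(cs), 9L)
  expect_equal(cs$both_positive[cs$general_category == "Food"], 2L)
  expect_equal(cs$note[cs$general_category == "Vet"], "no data")
  md <- format(cs)
  expect_match(md, "\\| Food \\| 2 \\| 2 \\|")
  expect_equal(length(strsplit(md, "\n")[[1]]), 11L)
})

test_that("per-level splits and per-plant roll-ups add up", {
  est <- fake_est(c("a", "a", "b"), c("Med", "digestive", "Food"),
                  c("highly_likely", "highly_likely", "other"),
                  level = c("general", "specific", "general"),
                  cat = c("Med", "Med", "Food"))
  sc <- fake_scores(c("a", "a", "b"), c("Med", "digestive", "Food"),
                    c(5L, 3L, 4L),
                    level = c("general", "specific", "general"),
                    cat = c("Med", "Med", "Food"))
  g <- build_concordance(est, sc)$global
  expect_equal(g$highly_likely, c(total = 2, general = 1, specific = 1))
  expect_equal(g$triangulation_positive,
               c(total = 2, general = 2, specific = 0))
  expect_equal(g$both_positive, c(total = 1, general = 1, specific = 0))
  expect_equal(g$n_plants_pcm_positive, 1L)
})

test_that("the historical crosscheck counts described uses", {
  est <- fake_est(c("a", "b", "c"), "Med",
                  c("highly_likely", "highly_likely", "highly_likely"))
  ev <- data.frame(plant = c("a", "b"), use = "Med", line = "historical",
                   n_unrelated_sources = c(1L, 0L))
  hc <- historical_crosscheck(est, ev)
  expect_equal(hc$n_highly_likely, 3L)
  expect_equal(hc$n_historical, 1L)
  expect_equal(hc$fraction, 1 / 3)
  # no highly likely calls: undefined, not an error
  hc0 <- historical_crosscheck(fake_est("a", "Med", "other"), ev)
  expect_true(is.na(hc0$fraction))
  # all described
  ev2 <- data.frame(plant = c("a", "b", "c"), use = "Med",
                    line = "historical", n_unrelated_sources = 2L)
  expect_equal(historical_crosscheck(est, ev2)$n_historical, 3L)
})

test_that("report regeneration is byte-stable", {
  d1 <- table1_demo()
  d2 <- table1_demo()
  expect_identical(format(d1$category_summary),
                   format(d2$category_summary))
  expect_identical(d1$scores, d2$scores)
})
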