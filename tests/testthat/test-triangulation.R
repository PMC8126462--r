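rec <- function(line, ...) {
  base <- data.frame(plant = "sorrel", use = "Food", line = line,
                     find_present = FALSE, context_confirmed_use = FALSE,
                     n_unrelated_sources = 0L, name_attested = FALSE,
                     use_indicating_name = FALSE,
                     traceable_to_old_norse = FALSE,
                     pre_viking_loan_phonology = FALSE,
                     override_score = NA_integer_,
                     stringsAsFactors = FALSE)
  args <- list(...)
  for (nm in names(args)) base[[nm]] <- args[[nm]]
  base
}

test_that("the archaeobotanical rubric distinguishes context from find", {
  expect_equal(score_line(rec("archaeobotany", find_present = TRUE,
                              context_confirmed_use = TRUE)), 5L)
  expect_equal(score_line(rec("archaeobotany", find_present = TRUE)), 3L)
  expect_equal(score_line(rec("archaeobotany")), 1L)
  # context implies a find even if the flag was left unset
  expect_equal(score_line(rec("archaeobotany",
                              context_confirmed_use = TRUE)), 5L)
})

test_that("the historical rubric rewards unrelated sources", {
  expect_equal(score_line(rec("historical", n_unrelated_sources = 0L)), 1L)
  expect_equal(score_line(rec("historical", n_unrelated_sources = 1L)), 3L)
  expect_equal(score_line(rec("historical", n_unrelated_sources = 2L)), 4L)
  expect_equal(score_line(rec("historical", n_unrelated_sources = 7L)), 4L)
})

test_that("the linguistic rubric tracks name age and use signal", {
  expect_equal(score_line(rec("linguistic")), 1L)
  expect_equal(score_line(rec("linguistic", name_attested = TRUE)), 2L)
  expect_equal(score_line(rec("linguistic", use_indicating_name = TRUE)),
               3L)
  expect_equal(score_line(rec("linguistic", use_indicating_name = TRUE,
                              traceable_to_old_norse = TRUE)), 4L)
  expect_equal(score_line(rec("linguistic",
                              pre_viking_loan_phonology = TRUE,
                              use_indicating_name = TRUE)), 5L)
  # a name traceable to Old Norse is by definition attested
  expect_equal(score_line(rec("linguistic",
                              traceable_to_old_norse = TRUE)), 2L)
})

test_that("attributes of the wrong line are rejected", {
  expect_error(score_line(rec("archaeobotany", n_unrelated_sources = 2L)),
               "not valid for line")
  expect_error(score_line(rec("historical", use_indicating_name = TRUE)),
               "not valid for line")
})

test_that("combination takes the maximum line score, absent lines are 1", {
  ev <- rbind(rec("archaeobotany", context_confirmed_use = TRUE),
              rec("historical"), rec("linguistic"))
  out <- triangulate(ev)
  expect_equal(out$combined, 5L)
  expect_true(out$positive)

  ev2 <- rbind(rec("archaeobotany", find_present = TRUE),
               rec("historical", n_unrelated_sources = 1L),
               rec("linguistic", use_indicating_name = TRUE))
  out2 <- triangulate(ev2)
  expect_equal(out2$combined, 3L)
  expect_false(out2$positive)

  out3 <- triangulate(rec("historical", n_unrelated_sources = 2L))
  expect_equal(out3$combined, 4L)
  expect_true(out3$positive)

  empty <- triangulate(data.frame(plant = character(), use = character(),
                                  line = character()))
  expect_equal(nrow(empty), 0L)
})

test_that("conflicting duplicate lines are an error, identical collapse", {
  dup <- rbind(rec("historical", n_unrelated_sources = 1L),
               rec("historical", n_unrelated_sources = 2L))
  expect_error(triangulate(dup), "conflicting duplicate")
  same <- rbind(rec("historical", n_unrelated_sources = 2L),
                rec("historical", n_unrelated_sources = 2L))
  expect_equal(triangulate(same)$combined, 4L)
})

test_that("an override score replaces the rubric value", {
  ov <- rec("historical", n_unrelated_sources = 2L, override_score = 2L)
  expect_equal(score_line(ov), 2L)
  expect_equal(triangulate(ov)$combined, 2L)
})

random_evidence <- function(n_uses = 3) {
  plant <- sample(letters, 1)
  uses <- sample(general_use_categories, n_uses)
  do.call(rbind, lapply(uses, function(u) data.frame(
    plant = plant, use = u,
    line = evidence_lines,
    find_present = runif(3) < 0.5,
    context_confirmed_use = runif(3) < 0.3,
    n_unrelated_sources = sample(0:3, 3, replace = TRUE),
    name_attested = runif(3) < 0.5,
    use_indicating_name = runif(3) < 0.4,
    traceable_to_old_norse = runif(3) < 0.4,
    pre_viking_loan_phonology = runif(3) < 0.2)))
}

test_that("triangulation is deterministic and scores stay in 1..5", {
  set.seed(77)
  for (i in 1:200) {
    ev <- random_evidence()
    a <- triangulate(ev)
    b <- triangulate(ev)
    expect_identical(a, b)
    expect_true(all(unlist(a[c("archaeobotany", "historical",
                               "linguistic", "combined")]) %in% 1:5))
  }
})

test_that("adding evidence never lowers a score", {
  bump <- function(ev) {
    i <- sample(nrow(ev), 1)
    flags <- c("find_present", "context_confirmed_use", "name_attested",
               "use_indicating_name", "traceable_to_old_norse",
               "pre_viking_loan_phonology")
    col <- sample(c(flags, "n_unrelated_sources"), 1)
    if (col == "n_unrelated_sources")
      ev[i, col] <- ev[i, col] + 1L else ev[i, col] <- TRUE
    ev
  }
  set.seed(78)
  for (i in 1:200) {
    ev <- random_evidence()
    more <- bump(ev)
    a <- triangulate(ev); b <- triangulate(more)
    key <- paste(a$plant, a$use)
    m <- match(key, paste(b$plant, b$use))
    for (col in c("archaeobotany", "historical", "linguistic", "combined"))
      expect_true(all(b[[col]][m] >= a[[col]]))
  }
})
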