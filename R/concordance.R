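#' Concordance between phylogenetic estimates and triangulated evidence
#'
#' Joins per-(plant, use) ancestral-state classifications with Likert
#' triangulation verdicts. Each combination lands in one agreement cell:
#' \code{both_positive} (highly likely by the phylogenetic model and
#' Likert >= 4), \code{pcm_only}, \code{triangulation_only},
#' \code{neither}; combinations present on only one side (or skipped by
#' the model) go to \code{unscored}, never silently dropped.
#'
#' @param estimates an \code{ancestral_estimates} object, its
#'   \code{summary} data frame, or \code{NULL} (evidence-only table).
#' @param scores a \code{likert_scores} data frame from
#'   \code{\link{triangulate}}, or \code{NULL}.
#' @return object of class \code{concordance}: \code{table} (one row per
#'   combination with both verdicts and the cell), \code{by_category}
#'   (cell counts per general-use category), \code{global} (headline
#'   counts, split by general/specific level where known).
#' @export
build_concordance <- function(estimates, scores) {
  est <- if (inherits(estimates, "ancestral_estimates"))
    estimates$summary else estimates
  if (!is.null(est) && anyDuplicated(est[c("plant", "use")]))
    stop("duplicate (plant, use) keys in estimates")
  if (!is.null(scores) && anyDuplicated(scores[c("plant", "use")]))
    stop("duplicate (plant, use) keys in scores")
  ek <- if (is.null(est)) character() else paste(est$plant, est$use,
                                                 sep = "|")
  sk <- if (is.null(scores)) character() else paste(scores$plant,
                                                    scores$use, sep = "|")
  keys <- union(ek, sk)
  first_of <- function(df, k, col, keyvec) {
    if (is.null(df) || !col %in% names(df)) return(rep(NA, length(k)))
    df[[col]][match(k, keyvec)]
  }
  tab <- data.frame(
    plant = ifelse(keys %in% ek, first_of(est, keys, "plant", ek),
                   first_of(scores, keys, "plant", sk)),
    use = ifelse(keys %in% ek, first_of(est, keys, "use", ek),
                 first_of(scores, keys, "use", sk)),
    stringsAsFactors = FALSE)
  lv <- first_of(est, keys, "level", ek)
  lv2 <- first_of(scores, keys, "level", sk)
  tab$level <- ifelse(!is.na(lv), lv, lv2)
  gc <- first_of(est, keys, "general_category", ek)
  gc2 <- first_of(scores, keys, "general_category", sk)
  tab$general_category <- ifelse(!is.na(gc), gc, gc2)
  tab$classification <- first_of(est, keys, "classification", ek)
  tab$mean_root_p <- first_of(est, keys, "mean_root_p", ek)
  tab$combined_score <- first_of(scores, keys, "combined", sk)
  tab$positive <- first_of(scores, keys, "positive", sk)
  hl <- !is.na(tab$classification) & tab$classification == "highly_likely"
  pos <- !is.na(tab$positive) & tab$positive
  scored <- !is.na(tab$classification) &
    tab$classification != "skipped" & !is.na(tab$positive)
  tab$cell <- rep("unscored", nrow(tab))
  tab$cell[scored & hl & pos] <- "both_positive"
  tab$cell[scored & hl & !pos] <- "pcm_only"
  tab$cell[scored & !hl & pos] <- "triangulation_only"
  tab$cell[scored & !hl & !pos] <- "neither"
  rownames(tab) <- NULL
  cells <- c("both_positive", "pcm_only", "triangulation_only", "neither",
             "unscored")
  by_cat <- do.call(rbind, lapply(general_use_categories, function(g) {
    sub <- tab[!is.na(tab$general_category) & tab$general_category == g, ]
    counts <- vapply(cells, function(cl) sum(sub$cell == cl), 0L)
    data.frame(general_category = g, n = nrow(sub), t(counts))
  }))
  rownames(by_cat) <- NULL
  lvl_split <- function(mask) {
    c(total = sum(mask),
      general = sum(mask & !is.na(tab$level) & tab$level == "general"),
      specific = sum(mask & !is.na(tab$level) & tab$level == "specific"))
  }
  global <- list(
    n_combinations = nrow(tab),
    n_plants = length(unique(tab$plant)),
    n_plants_pcm_positive = length(unique(tab$plant[hl])),
    n_plants_triangulation_positive = length(unique(tab$plant[pos])),
    highly_likely = lvl_split(hl),
    triangulation_positive = lvl_split(pos),
    both_positive = lvl_split(hl & pos))
  structure(list(table = tab, by_category = by_cat, global = global),
            class = "concordance")
}

#' @export
print.concordance <- function(x, ...) {
  g <- x$global
  cat("Concordance over", g$n_combinations, "plant-use combinations (",
      g$n_plants, "plants )\n")
  cat("  PCM highly likely:", g$highly_likely["total"], "(general",
      g$highly_likely["general"], "/ specific",
      g$highly_likely["specific"], ") across", g$n_plants_pcm_positive,
      "plants\n")
  cat("  triangulation positive:", g$triangulation_positive["total"],
      "(general", g$triangulation_positive["general"], "/ specific",
      g$triangulation_positive["specific"], ")\n")
  cat("  positive by both:", g$both_positive["total"], "(general",
      g$both_positive["general"], "/ specific",
      g$both_positive["specific"], ")\n")
  invisible(x)
}

#' Per-category concordance report
#'
#' One row per general-use category with agreement-cell counts and member
#' combinations, rendered as a Markdown report by \code{format()}.
#'
#' @param x a \code{concordance} object.
#' @return data frame of class \code{category_summary} (one row per
#'   general-use category; categories with no scored combinations carry
#'   \code{n = 0} and note \code{"no data"}).
#' @export
category_summary <- function(x) {
  stopifnot(inherits(x, "concordance"))
  tab <- x$table
  out <- x$by_category
  out$note <- ifelse(out$n == 0L, "no data", "")
  out$members_both_positive <- vapply(out$general_category, function(g) {
    sub <- tab[!is.na(tab$general_category) & tab$general_category == g &
                 tab$cell == "both_positive", ]
    paste(paste(sub$plant, sub$use, sep = ":"), collapse = "; ")
  }, "")
  class(out) <- c("category_summary", "data.frame")
  out
}

#' @export
format.category_summary <- function(x, ...) {
  lines <- c("| category | n | both | PCM only | triangulation only | neither | unscored | note |",
             "|---|---|---|---|---|---|---|---|",
             sprintf("| %s | %d | %d | %d | %d | %d | %d | %s |",
                     x$general_category, x$n, x$both_positive, x$pcm_only,
                     x$triangulation_only, x$neither, x$unscored, x$note))
  paste(lines, collapse = "\n")
}

#' @export
print.category_summary <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Cross-check phylogenetic calls against the historical record
#'
#' Of the plant-use combinations called highly likely by the phylogenetic
#' model, how many are described in the historical sources? A combination
#' counts as historically described when its historical evidence line
#' scores at least \code{min_score} (default 3: at least one source
#' mentioning the use).
#'
#' @param estimates \code{ancestral_estimates} or its summary.
#' @param evidence an \code{evidence_table} (rows for the historical line
#'   are consulted; other lines ignored).
#' @param min_score historical line score counted as "described".
#' @return list with \code{n_highly_likely}, \code{n_historical},
#'   \code{fraction} (NA when there are no highly likely calls) and a
#'   per-level breakdown.
#' @export
historical_crosscheck <- function(estimates, evidence, min_score = 3) {
  est <- if (inherits(estimates, "ancestral_estimates"))
    estimates$summary else estimates
  ev <- evidence_table(evidence)
  hist <- ev[ev$line == "historical", ]
  hist$score <- if (nrow(hist)) score_lines(hist) else integer()
  hk <- paste(hist$plant, hist$use, sep = "|")
  hl <- est[!is.na(est$classification) &
              est$classification == "highly_likely", ]
  key <- paste(hl$plant, hl$use, sep = "|")
  described <- key %in% hk[hist$score >= min_score]
  by_level <- if ("level" %in% names(hl) && nrow(hl)) {
    stats::aggregate(described, list(level = hl$level),
                     function(z) c(n = length(z), described = sum(z)))
  } else NULL
  list(n_highly_likely = nrow(hl), n_historical = sum(described),
       fraction = if (nrow(hl)) sum(described) / nrow(hl) else NA_real_,
       by_level = by_level, min_score = min_score)
}
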