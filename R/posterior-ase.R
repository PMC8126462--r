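#' Construct a plant x use x language trait matrix
#'
#' Validates a tidy table of binary plant-use states per language. One row
#' per (plant, use, language); states are 0 (absent), 1 (present) or NA
#' (missing, e.g. poorly documented languages whose absences are not
#' trusted).
#'
#' @param df data frame with columns \code{plant}, \code{use},
#'   \code{level} ("general" or "specific"), \code{general_category} (one
#'   of the nine general use codes), \code{language}, \code{state}.
#' @return the validated data frame, class \code{trait_matrix}.
#' @export
trait_matrix <- function(df) {
  need <- c("plant", "use", "level", "general_category", "language",
            "state")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("trait matrix missing column(s): ", paste(miss, collapse = ", "))
  df <- as.data.frame(df)[need]
  if (!all(df$level %in% c("general", "specific")))
    stop("level must be 'general' or 'specific'")
  badcat <- setdiff(unique(df$general_category), general_use_categories)
  if (length(badcat))
    stop("unknown general use category: ", paste(badcat, collapse = ", "))
  if (!all(is.na(df$state) | df$state %in% c(0, 1)))
    stop("state must be 0, 1 or NA")
  df$state <- as.integer(df$state)
  if (anyDuplicated(df[c("plant", "use", "language")]))
    stop("duplicate (plant, use, language) rows")
  class(df) <- c("trait_matrix", "data.frame")
  df
}

#' Read a trait matrix from tidy CSV
#'
#' @param path CSV with the \code{\link{trait_matrix}} columns; NA allowed
#'   in \code{state}.
#' @export
read_trait_matrix <- function(path) {
  trait_matrix(read.csv(path, stringsAsFactors = FALSE))
}

# languages x characters integer state matrix + character key table
trait_to_wide <- function(traits) {
  key <- unique(traits[c("plant", "use", "level", "general_category")])
  rownames(key) <- NULL
  langs <- sort(unique(traits$language))
  m <- matrix(NA_integer_, length(langs), nrow(key),
              dimnames = list(langs, paste(key$plant, key$use, sep = "|")))
  idx <- cbind(match(traits$language, langs),
               match(paste(traits$plant, traits$use, sep = "|"),
                     colnames(m)))
  m[idx] <- traits$state
  list(states = m, key = key, languages = langs)
}

#' Classify a mean root probability
#'
#' Thresholds follow the reporting convention: mean root probability of
#' presence >= 0.75 is "highly_likely"; within [0.45, 0.55] (inclusive)
#' "equivocal"; <= 0.25 "absent_leaning" (a reporting symmetry, never
#' affecting the first two calls); anything else "other".
#'
#' @param mean_p numeric vector of mean root probabilities in [0, 1].
#' @param high highly-likely threshold (default 0.75).
#' @param equivocal inclusive equivocal band (default c(0.45, 0.55)).
#' @param absent absent-leaning threshold (default 0.25).
#' @return character vector of classifications.
#' @export
classify_root_call <- function(mean_p, high = 0.75,
                               equivocal = c(0.45, 0.55), absent = 0.25) {
  out <- rep("other", length(mean_p))
  out[mean_p >= high] <- "highly_likely"
  out[mean_p >= equivocal[1] & mean_p <= equivocal[2]] <- "equivocal"
  out[mean_p <= absent] <- "absent_leaning"
  out[is.na(mean_p)] <- NA_character_
  out
}

#' Ancestral-state estimation across a posterior tree sample
#'
#' For every (plant, use) character with at least one recorded presence,
#' fits the ER rate and computes the marginal root probability of presence
#' independently on each tree of the sample, then averages root
#' probabilities over trees and classifies the mean. Characters whose
#' observed states are all 0 are skipped with a warning (they carry no
#' signal and are impossible under the ascertainment correction), as are
#' all-missing characters.
#'
#' @param sample a \code{tree_sample} / \code{multiPhylo} whose tip labels
#'   equal the trait matrix languages.
#' @param traits a \code{trait_matrix}.
#' @param ascertainment correction variant, default \code{"no_all_zero"}.
#' @param root_prior root prior, default equal.
#' @param high,equivocal,absent classification thresholds, see
#'   \code{\link{classify_root_call}}.
#' @param tol optimizer tolerance in log q.
#' @return object of class \code{ancestral_estimates}: \code{summary}
#'   (one row per character: mean root probability, classification, mean
#'   and median fitted rate, mean log-likelihood), \code{root_prob},
#'   \code{rates}, \code{logliks} (character x tree matrices) and
#'   \code{options}.
#' @export
run_ase <- function(sample, traits, ascertainment = "no_all_zero",
                    root_prior = c(0.5, 0.5), high = 0.75,
                    equivocal = c(0.45, 0.55), absent = 0.25,
                    tol = 1e-8) {
  if (inherits(sample, "phylo")) sample <- as_tree_sample(sample)
  stopifnot(inherits(traits, "trait_matrix") || is.data.frame(traits))
  traits <- trait_matrix(traits)
  wide <- trait_to_wide(traits)
  tips <- sort(sample[[1]]$tip.label)
  if (!identical(tips, wide$languages)) {
    only_tree <- setdiff(tips, wide$languages)
    only_data <- setdiff(wide$languages, tips)
    stop("language/tip mismatch; only in trees: {",
         paste(only_tree, collapse = ", "), "}; only in traits: {",
         paste(only_data, collapse = ", "), "}")
  }
  asc <- asc_code(ascertainment)
  structs <- lapply(unclass(sample), tree_struct,
                    tip_order = wide$languages)
  heights <- vapply(unclass(sample), tree_height, 0)
  bounds <- rate_bounds(mean(heights))
  nchar_ <- nrow(wide$key)
  ntree <- length(sample)
  root_prob <- rates <- logliks <-
    matrix(NA_real_, nchar_, ntree,
           dimnames = list(colnames(wide$states), NULL))
  status <- rep("estimated", nchar_)
  for (j in seq_len(nchar_)) {
    s <- wide$states[, j]
    obs <- s[!is.na(s)]
    if (length(obs) == 0L) {
      status[j] <- "skipped"
      warning("character ", colnames(wide$states)[j],
              " has no observed states; skipped")
      next
    }
    if (all(obs == 0L)) {
      status[j] <- "skipped"
      warning("character ", colnames(wide$states)[j],
              " has no recorded presence; skipped",
              if (asc > 0L) " (impossible under ascertainment correction)")
      next
    }
    res <- .er_ase_sample_cpp(structs, s, root_prior[1], root_prior[2],
                              asc, bounds[1], bounds[2], tol)
    rates[j, ] <- res[, 1]
    logliks[j, ] <- res[, 2]
    root_prob[j, ] <- res[, 3]
  }
  mean_p <- rowMeans(root_prob)
  cls <- classify_root_call(mean_p, high, equivocal, absent)
  cls[status == "skipped"] <- "skipped"
  summary <- cbind(wide$key,
                   data.frame(mean_root_p = mean_p,
                              classification = cls,
                              mean_q = rowMeans(rates),
                              median_q = apply(rates, 1, stats::median),
                              mean_loglik = rowMeans(logliks),
                              n_present = apply(wide$states, 2, function(x)
                                sum(x == 1L, na.rm = TRUE)),
                              n_observed = apply(wide$states, 2, function(x)
                                sum(!is.na(x)))))
  rownames(summary) <- NULL
  structure(list(summary = summary, root_prob = root_prob, rates = rates,
                 logliks = logliks,
                 options = list(ascertainment = ascertainment,
                                root_prior = root_prior, high = high,
                                equivocal = equivocal, absent = absent,
                                rate_bounds = bounds, n_trees = ntree)),
            class = "ancestral_estimates")
}

#' @export
print.ancestral_estimates <- function(x, ...) {
  cat("Ancestral-state estimates over", x$options$n_trees, "trees;",
      nrow(x$summary), "plant-use characters\n")
  tab <- table(x$summary$classification)
  cat(paste(names(tab), tab, sep = ": ", collapse = "; "), "\n")
  cat("ascertainment:", x$options$ascertainment,
      "| highly-likely threshold:", x$options$high,
      "| equivocal band: [", paste(x$options$equivocal, collapse = ", "),
      "]\n")
  invisible(x)
}

#' Basal-clade diagnostic for equivocal characters
#'
#' Root-state ambiguity could arise trivially when a use is present in
#' only one of the two clades descending from the root. For each
#' equivocal character this computes, per tree, whether at least one tip
#' in each basal clade records presence, and counts the character as
#' "present in both basal clades" when that holds in more than a
#' \code{majority} fraction of trees.
#'
#' @param sample the tree sample used for estimation.
#' @param traits the trait matrix.
#' @param estimates an \code{ancestral_estimates} object.
#' @param majority fraction of trees required (default 0.5, strict).
#' @return list with \code{pct_equivocal} (percent of estimated
#'   characters that are equivocal), \code{pct_both_clades} (percent of
#'   equivocal characters present in both basal clades), and a
#'   \code{per_character} data frame; zero-row summary when no character
#'   is equivocal.
#' @export
equivocal_clade_diagnostic <- function(sample, traits, estimates,
                                       majority = 0.5) {
  if (inherits(sample, "phylo")) sample <- as_tree_sample(sample)
  traits <- trait_matrix(traits)
  wide <- trait_to_wide(traits)
  sm <- estimates$summary
  est_n <- sum(sm$classification != "skipped")
  eq <- which(sm$classification == "equivocal")
  clades <- lapply(unclass(sample), basal_clades)
  per <- data.frame(plant = sm$plant[eq], use = sm$use[eq],
                    frac_trees_both = rep(NA_real_, length(eq)),
                    both_clades = rep(NA, length(eq)))
  for (i in seq_along(eq)) {
    key <- paste(sm$plant[eq[i]], sm$use[eq[i]], sep = "|")
    s <- wide$states[, key]
    present <- names(s)[!is.na(s) & s == 1L]
    hit <- vapply(clades, function(cl)
      any(cl[[1]] %in% present) && any(cl[[2]] %in% present), TRUE)
    per$frac_trees_both[i] <- mean(hit)
    per$both_clades[i] <- mean(hit) > majority
  }
  list(pct_equivocal = if (est_n) 100 * length(eq) / est_n else NA_real_,
       pct_both_clades = if (length(eq))
         100 * mean(per$both_clades) else NA_real_,
       per_character = per)
}
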