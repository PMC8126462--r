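#' Write a run manifest
#'
#' Every pipeline output directory receives exactly one
#' \code{manifest.json} recording the package version, the flag values in
#' force, input-file digests and a timestamp, so that a run can be
#' reproduced from its outputs alone.
#'
#' @param out_dir output directory.
#' @param step pipeline step name.
#' @param inputs named character vector of input file paths (digested).
#' @param options list of flag/threshold values to snapshot.
#' @return the manifest list, invisibly.
#' @export
write_manifest <- function(out_dir, step, inputs = character(),
                           options = list()) {
  digests <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  manifest <- list(step = step,
                   package = "norseplants",
                   version = as.character(packageVersion("norseplants")),
                   inputs = digests, options = options,
                   timestamp = format(Sys.time(), tz = "UTC",
                                      usetz = TRUE))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Generate a full synthetic dataset on disk
#'
#' Runs the seeded generator and writes the tree sample (Newick), the
#' masked trait matrix, the generating truth and the evidence table, plus
#' a manifest.
#'
#' @param config a \code{\link{sim_config}}.
#' @param out_dir output directory (created if needed).
#' @return named vector of output paths, invisibly.
#' @export
pipeline_simulate <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  trees <- simulate_trees(config)
  sim <- simulate_traits(trees, config)
  traits <- mask_missing(sim$traits, config)
  evidence <- simulate_evidence(sim$truth, config)
  paths <- c(trees = file.path(out_dir, "trees.nwk"),
             traits = file.path(out_dir, "traits.csv"),
             truth = file.path(out_dir, "truth.csv"),
             evidence = file.path(out_dir, "evidence.csv"))
  write_tree_sample(trees, paths["trees"])
  write.csv(traits, paths["traits"], row.names = FALSE, na = "")
  write.csv(sim$truth, paths["truth"], row.names = FALSE)
  write.csv(evidence, paths["evidence"], row.names = FALSE)
  write_manifest(out_dir, "simulate",
                 options = unclass(config)[setdiff(names(config), "tips")])
  invisible(paths)
}

#' Ancestral-state estimation step
#'
#' Reads a tree sample and a trait matrix from disk, runs
#' \code{\link{run_ase}}, and writes the per-character summary, the full
#' per-tree root-probability matrix and a manifest.
#'
#' @param trees_path Newick/NEXUS tree sample.
#' @param traits_path tidy trait CSV.
#' @param out_dir output directory.
#' @param ... options passed to \code{\link{run_ase}}.
#' @return the \code{ancestral_estimates}, invisibly.
#' @export
pipeline_ase <- function(trees_path, traits_path, out_dir, ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sample <- read_tree_sample(trees_path)
  traits <- read_trait_matrix(traits_path)
  est <- run_ase(sample, traits, ...)
  write.csv(est$summary, file.path(out_dir, "estimates.csv"),
            row.names = FALSE)
  write.csv(data.frame(character = rownames(est$root_prob),
                       est$root_prob, check.names = FALSE),
            file.path(out_dir, "root_probabilities.csv"),
            row.names = FALSE)
  write_manifest(out_dir, "ase",
                 inputs = c(trees = trees_path, traits = traits_path),
                 options = est$options)
  invisible(est)
}

#' Evidence triangulation step
#'
#' @param evidence_path evidence CSV.
#' @param out_dir output directory.
#' @param positive_min combined Likert score counted positive (default 4).
#' @return the \code{likert_scores}, invisibly.
#' @export
pipeline_triangulate <- function(evidence_path, out_dir,
                                 positive_min = 4) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  scores <- triangulate(read_evidence(evidence_path),
                        positive_min = positive_min)
  write.csv(scores, file.path(out_dir, "scores.csv"), row.names = FALSE)
  write_manifest(out_dir, "triangulate",
                 inputs = c(evidence = evidence_path),
                 options = list(positive_min = positive_min))
  invisible(scores)
}

#' Concordance step
#'
#' Joins an estimates file with a scores file and writes the per-
#' combination table, the per-category Markdown report and the global
#' counts.
#'
#' @param estimates_path \code{estimates.csv} from
#'   \code{\link{pipeline_ase}}.
#' @param scores_path \code{scores.csv} from
#'   \code{\link{pipeline_triangulate}}.
#' @param out_dir output directory.
#' @return the \code{concordance}, invisibly.
#' @export
pipeline_compare <- function(estimates_path, scores_path, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  est <- read.csv(estimates_path, stringsAsFactors = FALSE)
  scores <- read.csv(scores_path, stringsAsFactors = FALSE)
  conc <- build_concordance(est, scores)
  write.csv(conc$table, file.path(out_dir, "concordance.csv"),
            row.names = FALSE)
  writeLines(format(category_summary(conc)),
             file.path(out_dir, "category_summary.md"))
  jsonlite::write_json(conc$global, file.path(out_dir, "global.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  write_manifest(out_dir, "compare",
                 inputs = c(estimates = estimates_path,
                            scores = scores_path))
  invisible(conc)
}
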