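#' Read a posterior sample of trees
#'
#' Reads rooted, branch-length-bearing trees from a Newick or NEXUS file
#' into a tree sample (an ape \code{multiPhylo} with provenance metadata).
#' NEXUS translate tables are resolved to tip labels. Every tree must carry
#' a branch length on every edge; the trait model has no default time
#' scale, so a missing length is an error, not a warning.
#'
#' @param path path to the tree file (UTF-8).
#' @param format \code{"auto"} (sniff the file), \code{"newick"} or
#'   \code{"nexus"}.
#' @return a \code{multiPhylo} of class \code{c("tree_sample",
#'   "multiPhylo")}; attribute \code{provenance} records the source file
#'   and any pruning applied later.
#' @export
read_tree_sample <- function(path, format = c("auto", "newick", "nexus")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("tree file not found: ", path)
  if (format == "auto") {
    head <- toupper(trimws(readLines(path, n = 1L, warn = FALSE)))
    format <- if (startsWith(head, "#NEXUS")) "nexus" else "newick"
  }
  trees <- if (format == "nexus") {
    ape::read.nexus(path)
  } else {
    tryCatch(ape::read.tree(path), error = function(e) {
      lines <- readLines(path, warn = FALSE)
      lines <- lines[nzchar(trimws(lines))]
      for (i in seq_along(lines)) {
        ok <- tryCatch({ape::read.tree(text = lines[i]); TRUE},
                       error = function(e2) FALSE)
        if (!ok) stop("malformed tree string at tree index ", i, call. = FALSE)
      }
      stop("failed to parse newick file: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  if (inherits(trees, "phylo")) trees <- c(trees)  # multiPhylo of one
  as_tree_sample(trees, provenance = list(source = path, format = format))
}

#' Build a tree sample from trees already in memory
#'
#' @param trees a \code{phylo}, \code{multiPhylo}, or list of \code{phylo}.
#' @param provenance free-form list recording where the trees came from.
#' @return a validated \code{tree_sample}.
#' @export
as_tree_sample <- function(trees, provenance = list()) {
  if (inherits(trees, "phylo")) trees <- c(trees)
  if (!inherits(trees, "multiPhylo")) {
    stopifnot(is.list(trees), all(vapply(trees, inherits, TRUE, "phylo")))
    class(trees) <- "multiPhylo"
  }
  if (length(trees) < 1L) stop("tree sample is empty")
  for (i in seq_along(trees)) {
    msg <- validate_tree(trees[[i]])
    if (!is.null(msg)) stop("tree ", i, ": ", msg)
  }
  tips <- sort(trees[[1]]$tip.label)
  for (i in seq_along(trees)) {
    if (!identical(sort(trees[[i]]$tip.label), tips))
      stop("tree ", i, " has a different tip-label set than tree 1")
  }
  attr(trees, "provenance") <- provenance
  class(trees) <- unique(c("tree_sample", class(trees)))
  trees
}

# NULL if valid, otherwise a message
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) return("not a phylo object")
  if (anyDuplicated(tree$tip.label)) return("duplicate tip labels")
  if (is.null(tree$edge.length)) return("missing branch lengths")
  if (any(!is.finite(tree$edge.length)))
    return("missing or non-finite branch length")
  if (any(tree$edge.length < 0)) return("negative branch length")
  if (!ape::is.rooted(tree)) return("tree is not rooted")
  NULL
}

#' Write a tree sample as plain Newick
#'
#' @param sample a \code{tree_sample} or \code{multiPhylo}.
#' @param path output file; one tree per line.
#' @export
write_tree_sample <- function(sample, path) {
  ape::write.tree(sample, file = path)
  invisible(path)
}

#' Prune a tree sample to a taxon set
#'
#' Restricts every tree to the labels in \code{keep}, suppressing the
#' resulting degree-2 nodes (their branch lengths are summed), so that
#' patristic distances among kept tips are unchanged.
#'
#' @param sample a \code{tree_sample}, \code{multiPhylo} or single
#'   \code{phylo}.
#' @param keep character vector of tip labels, at least 2, all present.
#' @return the pruned sample (or tree).
#' @export
prune_taxa <- function(sample, keep) {
  keep <- unique(as.character(keep))
  if (length(keep) < 2L) stop("keep must contain at least 2 labels")
  if (inherits(sample, "phylo")) {
    missing <- setdiff(keep, sample$tip.label)
    if (length(missing))
      stop("labels not found in tree: ", paste(missing, collapse = ", "))
    return(ape::keep.tip(sample, keep))
  }
  missing <- setdiff(keep, sample[[1]]$tip.label)
  if (length(missing))
    stop("labels not found in tree: ", paste(missing, collapse = ", "))
  pruned <- lapply(unclass(sample), ape::keep.tip, tip = keep)
  prov <- c(attr(sample, "provenance"),
            list(pruned_to = keep))
  as_tree_sample(pruned, provenance = prov)
}

#' Split a tip into two daughter tips
#'
#' Divides the pendant edge of \code{tip} (length L) at
#' \code{fraction * L} from its parent: a new internal node placed there
#' carries two daughter tips, each with pendant length
#' \code{(1 - fraction) * L}; the original tip label disappears. Used to
#' split the Norwegian branch into northern and southern tips so that
#' regionally localized trait records enter the model as separate taxa.
#'
#' @param tree a \code{phylo}, \code{multiPhylo} or \code{tree_sample}
#'   (applied to every tree).
#' @param tip label of the tip to split.
#' @param children character vector of two new labels, not already present.
#' @param fraction where along the pendant edge the split node sits,
#'   strictly between 0 and 1 (default 0.5).
#' @return tree(s) with one more tip.
#' @export
split_tip <- function(tree, tip, children, fraction = 0.5) {
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction >= 1)
    stop("fraction must lie strictly between 0 and 1")
  if (length(children) != 2L || anyDuplicated(children))
    stop("children must be two distinct labels")
  if (inherits(tree, "multiPhylo")) {
    prov <- attr(tree, "provenance")
    out <- lapply(unclass(tree), split_tip, tip = tip, children = children,
                  fraction = fraction)
    return(as_tree_sample(out, provenance = c(prov,
      list(split = list(tip = tip, children = children,
                        fraction = fraction)))))
  }
  if (!tip %in% tree$tip.label) stop("tip not found: ", tip)
  clash <- intersect(children, tree$tip.label)
  if (length(clash))
    stop("child label(s) already present: ", paste(clash, collapse = ", "))
  idx <- which(tree$tip.label == tip)
  L <- tree$edge.length[tree$edge[, 2] == idx]
  pendant <- (1 - fraction) * L
  cherry <- ape::read.tree(
    text = sprintf("(%s:%.17g,%s:%.17g);", children[1], pendant,
                   children[2], pendant))
  cherry$root.edge <- 0
  # attach the cherry (1 - fraction) * L below the tip, then remove the
  # original tip; collapsing the degree-2 attachment node leaves the new
  # node at depth fraction * L along the old pendant edge
  out <- ape::bind.tree(tree, cherry, where = idx, position = pendant)
  out <- ape::drop.tip(out, tip)
  out
}

#' Tip sets of the two basal clades
#'
#' Returns the tip labels descending from each of the root's two children.
#' Errors if the root is not bifurcating.
#'
#' @param tree a rooted \code{phylo}.
#' @return list of two character vectors partitioning the tips.
#' @export
basal_clades <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  root <- length(tree$tip.label) + 1L
  kids <- tree$edge[tree$edge[, 1] == root, 2]
  if (length(kids) != 2L) stop("root not bifurcating")
  lapply(kids, function(k) {
    if (k <= length(tree$tip.label)) tree$tip.label[k]
    else ape::extract.clade(tree, k)$tip.label
  })
}

# Flat postorder representation consumed by the C++ pruning core.
# tipmap maps each tree tip (0-based) to its index in `tip_order`.
tree_struct <- function(tree, tip_order = tree$tip.label) {
  po <- stats::reorder(tree, "postorder")
  ntip <- length(po$tip.label)
  tm <- match(po$tip.label, tip_order)
  if (anyNA(tm)) stop("tree tips not covered by tip order: ",
                      paste(po$tip.label[is.na(tm)], collapse = ", "))
  list(parent = po$edge[, 1] - 1L, child = po$edge[, 2] - 1L,
       len = po$edge.length, nnodes = ntip + po$Nnode,
       root = ntip, ntip = ntip, tipmap = tm - 1L)
}
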