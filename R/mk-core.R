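#' Two-state equal-rates Markov model
#'
#' The simplest continuous-time model of a binary trait: gain (0 to 1) and
#' loss (1 to 0) share a single rate \code{q} per unit branch length. The
#' root prior defaults to equal probability on both states.
#'
#' @param q transition rate, >= 0.
#' @param root_prior length-2 probability vector (absent, present).
#' @return an object of class \code{er_model}.
#' @export
er_model <- function(q, root_prior = c(0.5, 0.5)) {
  if (!is.numeric(q) || length(q) != 1L || is.na(q) || q < 0)
    stop("q must be a single non-negative number")
  if (length(root_prior) != 2L || any(root_prior < 0) ||
      abs(sum(root_prior) - 1) > 1e-12)
    stop("root_prior must be two non-negative numbers summing to 1")
  structure(list(q = q, root_prior = as.numeric(root_prior)),
            class = "er_model")
}

#' @export
print.er_model <- function(x, ...) {
  cat("ER (equal-rates) two-state model: q =", format(x$q),
      "; root prior =", paste(format(x$root_prior), collapse = "/"), "\n")
  invisible(x)
}

#' ER transition probability matrix
#'
#' Closed form for the two-state equal-rates process over a branch of
#' length \code{t}: staying probability \code{(1 + exp(-2qt)) / 2},
#' switching probability \code{(1 - exp(-2qt)) / 2}.
#'
#' @param q rate >= 0.
#' @param t branch length >= 0.
#' @return symmetric 2x2 stochastic matrix, states ordered (0, 1).
#' @export
transition_matrix <- function(q, t) {
  if (q < 0 || t < 0) stop("q and t must be non-negative")
  ex <- exp(-2 * q * t)
  ps <- (1 + ex) / 2
  pd <- (1 - ex) / 2
  matrix(c(ps, pd, pd, ps), 2, 2,
         dimnames = list(c("0", "1"), c("0", "1")))
}

# Validate a tip-state vector against a tree and return it in the tree's
# own tip order as integer 0/1/NA.
states_vector <- function(tree, states) {
  if (is.null(names(states)))
    stop("states must be a named vector (names = tip labels)")
  extra <- setdiff(names(states), tree$tip.label)
  missing <- setdiff(tree$tip.label, names(states))
  if (length(extra) || length(missing))
    stop("tip/state label mismatch; missing data for {",
         paste(missing, collapse = ", "), "}; unknown labels {",
         paste(extra, collapse = ", "), "}")
  orig_na <- is.na(states[tree$tip.label])
  s <- suppressWarnings(as.integer(states[tree$tip.label]))
  if (any(is.na(s) & !orig_na) || any(!is.na(s) & !(s %in% c(0L, 1L))))
    stop("states must be 0, 1 or NA")
  s
}

asc_code <- function(ascertainment) {
  match(match.arg(ascertainment, c("none", "no_all_zero", "variable")),
        c("none", "no_all_zero", "variable")) - 1L
}

#' Pruning likelihood of a binary character
#'
#' Felsenstein pruning over the tree: tip partial likelihoods are
#' indicators for observed states and (1, 1) for missing tips, and the
#' likelihood is the root-prior-weighted sum of root partials. With an
#' ascertainment variant other than \code{"none"}, the likelihood is
#' conditioned on the character being observable: divided by
#' \code{1 - P(excluded patterns)} where the excluded patterns are
#' all-observed-absent (\code{"no_all_zero"}) or both constant patterns
#' (\code{"variable"}).
#'
#' @param tree a rooted \code{phylo} with branch lengths.
#' @param states named vector of tip states in \{0, 1, NA\}.
#' @param model an \code{er_model}.
#' @param ascertainment \code{"none"}, \code{"no_all_zero"} or
#'   \code{"variable"}.
#' @return list of class \code{er_likelihood} with elements
#'   \code{loglik} (corrected if requested), \code{loglik_uncorrected},
#'   \code{excluded_prob} (probability mass conditioned away) and
#'   \code{root_partials}.
#' @export
pruning_likelihood <- function(tree, states, model,
                               ascertainment = "none") {
  stopifnot(inherits(model, "er_model"))
  msg <- validate_tree(tree)
  if (!is.null(msg)) stop(msg)
  asc <- asc_code(ascertainment)
  s <- states_vector(tree, states)
  ts <- tree_struct(tree)
  st <- s[ts$tipmap + 1L]
  pi0 <- model$root_prior[1]; pi1 <- model$root_prior[2]
  ll_un <- .er_loglik_cpp(ts$parent, ts$child, ts$len, ts$nnodes, ts$root,
                          ts$ntip, st, model$q, pi0, pi1, 0L)
  pex <- .er_excluded_prob_cpp(ts$parent, ts$child, ts$len, ts$nnodes,
                               ts$root, ts$ntip, st, model$q, pi0, pi1, asc)
  ll <- if (asc == 0L) ll_un else ll_un - log1p(-pex)
  rp <- .er_root_partials_cpp(ts$parent, ts$child, ts$len, ts$nnodes,
                              ts$root, ts$ntip, st, model$q)
  structure(list(loglik = ll, loglik_uncorrected = ll_un,
                 excluded_prob = pex, ascertainment = ascertainment,
                 root_partials = rp[1:2], log_scale = rp[3],
                 model = model),
            class = "er_likelihood")
}

#' Probability of the ascertainment-excluded pattern
#'
#' Probability, under the model, that every observed (non-missing) tip is
#' in state 0, with missing tips marginalized. The corrected likelihood
#' divides by one minus this value.
#'
#' @param tree rooted \code{phylo}.
#' @param model \code{er_model}.
#' @param observed character vector of tip labels with non-missing data
#'   (all other tips are treated as missing).
#' @return probability in (0, 1].
#' @export
ascertainment_prob <- function(tree, model, observed) {
  stopifnot(inherits(model, "er_model"))
  if (length(observed) < 1L) stop("need at least one observed tip")
  states <- setNames(rep(NA_integer_, length(tree$tip.label)),
                     tree$tip.label)
  states[observed] <- 0L
  s <- states_vector(tree, states)
  ts <- tree_struct(tree)
  st <- s[ts$tipmap + 1L]
  exp(.er_loglik_cpp(ts$parent, ts$child, ts$len, ts$nnodes, ts$root,
                     ts$ntip, st, model$q, model$root_prior[1],
                     model$root_prior[2], 0L))
}

# Default log-rate search bounds: three decades either side of 1/height.
rate_bounds <- function(height) {
  if (!is.finite(height) || height <= 0) height <- 1
  c(log(1e-3 / height), log(1e3 / height))
}

tree_height <- function(tree) max(ape::node.depth.edgelength(tree))

#' Maximum-likelihood rate for one character
#'
#' Maximizes the (corrected) log-likelihood over log q by bounded search.
#' The search interval spans three decades either side of one event per
#' tree height, and the optimum is deterministic for fixed inputs.
#'
#' @inheritParams pruning_likelihood
#' @param root_prior root state prior, default equal.
#' @param bounds optional length-2 interval for log q.
#' @param tol convergence tolerance in log q.
#' @return list with \code{model} (the fitted \code{er_model}),
#'   \code{loglik} at the optimum, and \code{root_p1}, the marginal root
#'   probability of state 1 at the fitted rate.
#' @export
fit_rate <- function(tree, states, ascertainment = "no_all_zero",
                     root_prior = c(0.5, 0.5), bounds = NULL,
                     tol = 1e-8) {
  msg <- validate_tree(tree)
  if (!is.null(msg)) stop(msg)
  asc <- asc_code(ascertainment)
  s <- states_vector(tree, states)
  obs <- s[!is.na(s)]
  if (length(obs) == 0L) stop("all tip states are missing")
  if (asc > 0L && all(obs == 0L))
    stop("trait unobservable under ascertainment: all observed tips absent")
  if (is.null(bounds)) bounds <- rate_bounds(tree_height(tree))
  ts <- tree_struct(tree)
  st <- s[ts$tipmap + 1L]
  fit <- .er_fit_character_cpp(ts$parent, ts$child, ts$len, ts$nnodes,
                               ts$root, ts$ntip, st, root_prior[1],
                               root_prior[2], asc, bounds[1], bounds[2],
                               tol)
  list(model = er_model(fit[1], root_prior), loglik = fit[2],
       root_p1 = fit[3], ascertainment = ascertainment, bounds = bounds)
}

#' Pooled maximum-likelihood rate over many characters
#'
#' Fits a single shared rate to a matrix of characters on one tree by
#' summing per-character (corrected) log-likelihoods.
#'
#' @param tree rooted \code{phylo}.
#' @param states_matrix tips x characters matrix of 0/1/NA; rownames are
#'   tip labels.
#' @inheritParams fit_rate
#' @return list with \code{q}, \code{loglik} and \code{n_characters}.
#' @export
fit_rate_pooled <- function(tree, states_matrix,
                            ascertainment = "no_all_zero",
                            root_prior = c(0.5, 0.5), bounds = NULL,
                            tol = 1e-8) {
  stopifnot(is.matrix(states_matrix), !is.null(rownames(states_matrix)))
  asc <- asc_code(ascertainment)
  if (is.null(bounds)) bounds <- rate_bounds(tree_height(tree))
  ts <- tree_struct(tree)
  ord <- match(tree$tip.label[ts$tipmap + 1L], rownames(states_matrix))
  if (anyNA(ord)) stop("states_matrix rownames do not cover the tree tips")
  m <- matrix(as.integer(states_matrix[ord, , drop = FALSE]),
              nrow = ts$ntip)
  f <- function(logq)
    .er_pooled_loglik_cpp(ts$parent, ts$child, ts$len, ts$nnodes, ts$root,
                          ts$ntip, m, exp(logq), root_prior[1],
                          root_prior[2], asc)
  opt <- stats::optimize(f, interval = bounds, maximum = TRUE,
                         tol = tol)
  list(q = exp(opt$maximum), loglik = opt$objective,
       n_characters = ncol(states_matrix), ascertainment = ascertainment)
}

#' Marginal root-state probability
#'
#' Posterior probability that the root is in state 1 (present), i.e.
#' \code{pi1 L1(root) / (pi0 L0(root) + pi1 L1(root))}. The ascertainment
#' divisor cancels in this ratio, so the value does not depend on the
#' correction variant.
#'
#' @inheritParams pruning_likelihood
#' @return probability in [0, 1].
#' @export
marginal_root <- function(tree, states, model) {
  stopifnot(inherits(model, "er_model"))
  s <- states_vector(tree, states)
  ts <- tree_struct(tree)
  st <- s[ts$tipmap + 1L]
  rp <- .er_root_partials_cpp(ts$parent, ts$child, ts$len, ts$nnodes,
                              ts$root, ts$ntip, st, model$q)
  denom <- model$root_prior[1] * rp[1] + model$root_prior[2] * rp[2]
  if (denom <= 0) stop("zero likelihood: data impossible under model")
  unname(model$root_prior[2] * rp[2] / denom)
}

#' Marginal state probabilities at every node
#'
#' Standard up-down marginalization: the up pass collects partial
#' likelihoods below each node, the down pass the likelihood of the rest
#' of the tree, and their product (root-prior weighted) is normalized per
#' node. At the root this coincides with \code{\link{marginal_root}}.
#'
#' @inheritParams pruning_likelihood
#' @param node optional node number (ape numbering: tips 1..n, root n+1);
#'   if given, returns the probability pair for that node only.
#' @return matrix (nodes x 2, columns \code{p0}, \code{p1}) or a single
#'   probability pair.
#' @export
marginal_states <- function(tree, states, model, node = NULL) {
  stopifnot(inherits(model, "er_model"))
  s <- states_vector(tree, states)
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  po <- stats::reorder(tree, "postorder")
  edge <- po$edge; elen <- po$edge.length
  pr <- model$root_prior
  # up pass (normalized per node; constants cancel in the final ratio)
  up <- matrix(1, nn, 2)
  for (i in seq_len(ntip)) {
    if (!is.na(s[i])) up[i, ] <- if (s[i] == 0L) c(1, 0) else c(0, 1)
  }
  P <- vector("list", nrow(edge))
  for (e in seq_len(nrow(edge))) {
    P[[e]] <- transition_matrix(model$q, elen[e])
    p <- edge[e, 1]; ch <- edge[e, 2]
    up[p, ] <- up[p, ] * as.vector(P[[e]] %*% up[ch, ])
    if (p > ntip && max(up[p, ]) > 0) up[p, ] <- up[p, ] / max(up[p, ])
  }
  root <- ntip + 1L
  # down pass in preorder (reverse postorder edge order)
  down <- matrix(NA_real_, nn, 2)
  down[root, ] <- pr
  kids <- split(seq_len(nrow(edge)), edge[, 1])
  for (e in rev(seq_len(nrow(edge)))) {
    p <- edge[e, 1]; ch <- edge[e, 2]
    sib <- setdiff(kids[[as.character(p)]], e)
    contrib <- down[p, ]
    for (b in sib)
      contrib <- contrib * as.vector(P[[b]] %*% up[edge[b, 2], ])
    down[ch, ] <- as.vector(t(P[[e]]) %*% contrib)
    if (max(down[ch, ]) > 0) down[ch, ] <- down[ch, ] / max(down[ch, ])
  }
  m <- up * down
  tot <- rowSums(m)
  if (any(tot <= 0)) stop("zero likelihood: data impossible under model")
  m <- m / tot
  colnames(m) <- c("p0", "p1")
  rownames(m) <- c(tree$tip.label, as.character((ntip + 1L):nn))
  if (!is.null(node)) {
    if (!is.numeric(node) || node < 1 || node > nn)
      stop("unknown node: ", node)
    return(m[node, ])
  }
  m
}
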