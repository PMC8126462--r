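# Independent brute-force oracles: exhaustive enumeration over internal
# (and, where needed, tip) state assignments, sharing nothing with the
# pruning implementation beyond the closed-form edge transition
# probability.

oracle_trans <- function(q, t, from, to) {
  ex <- exp(-2 * q * t)
  if (from == to) (1 + ex) / 2 else (1 - ex) / 2
}

# likelihood (not log) of named tip states (0/1/NA) by summing over all
# internal-node assignments; missing tips contribute a factor of 1
oracle_lik <- function(tree, states, q, prior = c(0.5, 0.5)) {
  ntip <- length(tree$tip.label)
  nint <- tree$Nnode
  tot <- 0
  for (a in 0:(2^nint - 1)) {
    int <- as.integer(intToBits(a))[seq_len(nint)]
    full <- c(unname(states[tree$tip.label]), int)
    p <- prior[full[ntip + 1] + 1]
    for (e in seq_len(nrow(tree$edge))) {
      sc <- full[tree$edge[e, 2]]
      if (is.na(sc)) next  # missing tip: sums to 1
      sp <- full[tree$edge[e, 1]]
      p <- p * oracle_trans(q, tree$edge.length[e], sp, sc)
    }
    tot <- tot + p
  }
  tot
}

# marginal probability of state 1 at an internal node (ape numbering)
oracle_marginal <- function(tree, states, q, node, prior = c(0.5, 0.5)) {
  ntip <- length(tree$tip.label)
  nint <- tree$Nnode
  num <- den <- 0
  for (a in 0:(2^nint - 1)) {
    int <- as.integer(intToBits(a))[seq_len(nint)]
    full <- c(unname(states[tree$tip.label]), int)
    p <- prior[full[ntip + 1] + 1]
    for (e in seq_len(nrow(tree$edge))) {
      sc <- full[tree$edge[e, 2]]
      if (is.na(sc)) next
      sp <- full[tree$edge[e, 1]]
      p <- p * oracle_trans(q, tree$edge.length[e], sp, sc)
    }
    den <- den + p
    if (full[node] == 1L) num <- num + p
  }
  num / den
}

# probability that every tip in `observed` is 0, others marginalized
oracle_all_zero <- function(tree, q, observed, prior = c(0.5, 0.5)) {
  states <- setNames(rep(NA_integer_, length(tree$tip.label)),
                     tree$tip.label)
  states[observed] <- 0L
  oracle_lik(tree, states, q, prior)
}

# all unlabeled rooted binary tree shapes with n tips, as newick skeletons
tree_shapes <- function(n) {
  if (n == 1) return("x")
  out <- character()
  for (k in seq_len(n %/% 2)) {
    for (l in tree_shapes(k)) for (r in tree_shapes(n - k))
      out <- c(out, paste0("(", l, ",", r, ")"))
  }
  unique(out)
}

# instantiate a shape with labels and random branch lengths
shape_to_tree <- function(shape, lengths_fun = function(n) runif(n, 0.1, 2)) {
  n <- lengths(regmatches(shape, gregexpr("x", shape, fixed = TRUE)))
  labs <- paste0("t", seq_len(n))
  for (i in seq_len(n)) shape <- sub("x", labs[i], shape, fixed = TRUE)
  tr <- ape::read.tree(text = paste0(shape, ";"))
  tr$edge.length <- lengths_fun(nrow(tr$edge))
  tr
}

random_states <- function(tree, p_missing = 0.2) {
  n <- length(tree$tip.label)
  s <- sample(c(0L, 1L), n, replace = TRUE)
  s[runif(n) < p_missing] <- NA_integer_
  setNames(s, tree$tip.label)
}

# all 2^n tip patterns over the tree tips (matrix, one row per pattern)
all_patterns <- function(n) {
  as.matrix(expand.grid(rep(list(0:1), n)))
}

# AUC of scores for a binary truth vector (ties counted half)
auc_score <- function(score, truth) {
  pos <- score[truth == 1L]; neg <- score[truth == 0L]
  cmp <- outer(pos, neg, "-")
  (sum(cmp > 0) + 0.5 * sum(cmp == 0)) / (length(pos) * length(neg))
}
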