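# Independent oracles used across tests.  These deliberately avoid the
# package's inference code paths: probabilities are accumulated by looping
# over explicitly enumerated full assignments.

# all 2^n full assignments of a node set, as a data frame
all_assignments <- function(nodes) {
  g <- expand.grid(rep(list(0:1), length(nodes)))
  names(g) <- nodes
  g
}

# chain-rule probability of one full assignment, plain loops
brute_joint <- function(fn, assignment) {
  p <- 1
  for (v in fn$dag$nodes) {
    pars <- fn$cpts[[v]]$parents
    idx <- 1
    if (length(pars))
      for (i in seq_along(pars))
        idx <- idx + assignment[[pars[i]]] * 2^(i - 1)
    p1 <- fn$cpts[[v]]$p1[idx]
    p <- p * if (assignment[[v]] == 1) p1 else 1 - p1
  }
  p
}

# conditional probability by brute-force summation over full assignments
brute_query <- function(fn, targets, evidence = NULL) {
  g <- all_assignments(fn$dag$nodes)
  probs <- vapply(seq_len(nrow(g)), function(i) brute_joint(fn, g[i, ]),
                  numeric(1))
  keep_e <- rep(TRUE, nrow(g))
  for (v in names(evidence)) keep_e <- keep_e & g[[v]] == evidence[[v]]
  keep_t <- keep_e
  for (v in names(targets)) keep_t <- keep_t & g[[v]] == targets[[v]]
  sum(probs[keep_t]) / sum(probs[keep_e])
}

# random DAG + CPTs over n nodes (edge probability 0.4, parents capped at 3)
random_bnet <- function(n_nodes, seed) {
  set.seed(seed)
  nodes <- paste0("N", seq_len(n_nodes))
  parents <- setNames(vector("list", n_nodes), nodes)
  for (j in seq_len(n_nodes)) {
    cand <- if (j > 1) nodes[seq_len(j - 1)] else character(0)
    pick <- cand[runif(length(cand)) < 0.4]
    if (length(pick) > 3) pick <- sample(pick, 3)
    parents[[nodes[j]]] <- pick
  }
  dag <- bn_dag(nodes, parents)
  cpts <- lapply(nodes, function(v)
    runif(2^length(dag$parents[[v]]), 0.05, 0.95))
  names(cpts) <- nodes
  bn_network(dag, cpts)
}

random_binary_matrix <- function(n_rows, n_cols, seed,
                                 dependent = TRUE) {
  set.seed(seed)
  x <- matrix(rbinom(n_rows * n_cols, 1, runif(n_cols, 0.2, 0.8)),
              n_rows, n_cols, byrow = TRUE)
  if (dependent && n_cols >= 2) {
    mix <- runif(n_rows) < 0.6
    x[mix, 2] <- x[mix, 1]
  }
  colnames(x) <- LETTERS[seq_len(n_cols)]
  x
}
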