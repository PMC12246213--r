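#' Directed acyclic graphs over cohort variables
#'
#' Lightweight DAG representation used by structure learning and fitting:
#' a node list plus a per-node parent set.  The constructor verifies
#' acyclicity by topological sort.
#'
#' @param nodes character vector of node names.
#' @param parents named list mapping each node to a character vector of its
#'   parents (missing entries mean no parents).
#' @return object of class `bn_dag` with elements `nodes` and `parents`.
#' @export
bn_dag <- function(nodes, parents = list()) {
  stopifnot(is.character(nodes), !anyDuplicated(nodes))
  pl <- setNames(vector("list", length(nodes)), nodes)
  for (v in nodes) pl[[v]] <- character(0)
  for (v in names(parents)) {
    if (!v %in% nodes) stop("parent set given for unknown node: ", v)
    p <- as.character(parents[[v]])
    if (v %in% p) stop("node cannot be its own parent: ", v)
    if (!all(p %in% nodes))
      stop("unknown parent(s) of ", v, ": ",
           paste(setdiff(p, nodes), collapse = ", "))
    pl[[v]] <- sort(unique(p))
  }
  d <- structure(list(nodes = nodes, parents = pl), class = "bn_dag")
  topological_order(d)  # errors on cycles
  d
}

#' Topological order of a DAG
#' @param dag a [bn_dag()].
#' @return node names, parents before children.
#' @export
topological_order <- function(dag) {
  remaining <- dag$nodes
  placed <- character(0)
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(v)
      all(dag$parents[[v]] %in% placed), logical(1))]
    if (!length(ready)) stop("graph contains a cycle")
    placed <- c(placed, ready)
    remaining <- setdiff(remaining, ready)
  }
  placed
}

#' @export
print.bn_dag <- function(x, ...) {
  ne <- sum(lengths(x$parents))
  cat(sprintf("bn_dag: %d nodes, %d edges\n", length(x$nodes), ne))
  for (v in x$nodes)
    if (length(x$parents[[v]]))
      cat("  ", paste(x$parents[[v]], collapse = ", "), " -> ", v, "\n", sep = "")
  invisible(x)
}

#' Edge list of a DAG
#' @param dag a [bn_dag()].
#' @return two-column character matrix (`from`, `to`).
#' @export
dag_edges <- function(dag) {
  from <- unlist(dag$parents, use.names = FALSE)
  to <- rep(names(dag$parents), lengths(dag$parents))
  cbind(from = from, to = to)
}

.as_complete_matrix <- function(data) {
  x <- if (inherits(data, "cohort_matrix")) data$x else as.matrix(data)
  storage.mode(x) <- "integer"
  if (anyNA(x))
    stop("data contain missing values; impute first (see knn_impute)")
  if (!all(x %in% c(0L, 1L))) stop("data must be binary 0/1")
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  x
}

#' BIC score of a single family (node given parent set)
#'
#' The decomposable score driving structure search: the maximised
#' multinomial log-likelihood of `v` given each parent configuration
#' (natural log, with the convention 0 log 0 = 0), minus the BIC penalty
#' (ln N / 2) * q * (r - 1), where r = 2 states and q = 2^|parents|
#' parent configurations.  Configurations never observed in the data
#' contribute zero likelihood but still count in q.
#'
#' This reference implementation is plain R; [compute_score_table()] holds
#' the compiled equivalent used by the search.
#'
#' @param data complete binary [cohort_matrix()], matrix or data frame.
#' @param v node name.
#' @param parents character vector of parent names (default none).
#' @return the family BIC score (numeric scalar).
#' @export
family_bic_score <- function(data, v, parents = character(0)) {
  x <- .as_complete_matrix(data)
  stopifnot(v %in% colnames(x), all(parents %in% colnames(x)),
            !v %in% parents)
  n <- nrow(x)
  k <- length(parents)
  cfg <- if (k) as.vector(x[, parents, drop = FALSE] %*% 2^(seq_len(k) - 1)) + 1L
         else rep(1L, n)
  q <- 2L^k
  tot <- tabulate(cfg, q)
  ones <- tabulate(cfg[x[, v] == 1L], q)
  zeros <- tot - ones
  ll <- sum(ifelse(ones > 0, ones * log(ones / tot), 0)) +
    sum(ifelse(zeros > 0, zeros * log(zeros / tot), 0))
  ll - (log(n) / 2) * q
}

#' Precompute BIC scores for all families
#'
#' Tabulates the family BIC score of every (node, parent set) combination
#' up to `max_parents`, the precomputation stage of exact structure search.
#' Feasibility is guarded at 20 variables (the table has n * 2^(n-1)
#' entries when uncapped).
#'
#' @param data complete binary data (see [family_bic_score()]).
#' @param max_parents cap on parent-set size (`Inf` = no cap).
#' @return object of class `family_score_table`: list with `nodes`, the
#'   score matrix (rows indexed by parent-set bitmask over `nodes`, columns
#'   by node; `-Inf` marks invalid/over-cap combinations), `N` and
#'   `max_parents`.
#' @export
compute_score_table <- function(data, max_parents = Inf) {
  x <- .as_complete_matrix(data)
  n <- ncol(x)
  if (n > 20)
    stop("exact search is guarded at 20 variables; cap max_parents and/or ",
         "subset the variables")
  mp <- if (is.finite(max_parents)) as.integer(max_parents) else -1L
  sm <- cpp_family_scores(x, mp)
  structure(list(nodes = colnames(x), scores = sm, N = nrow(x),
                 max_parents = max_parents),
            class = "family_score_table")
}

#' @export
print.family_score_table <- function(x, ...) {
  n <- length(x$nodes)
  nent <- sum(is.finite(x$scores))
  cat(sprintf("family_score_table: %d nodes, %d families (N = %d, max_parents = %s)\n",
              n, nent, x$N,
              if (is.finite(x$max_parents)) x$max_parents else "unlimited"))
  invisible(x)
}

#' @describeIn compute_score_table expand a score table to a data frame with
#'   one row per (node, parent set).
#' @param x a `family_score_table`.
#' @param ... unused.
#' @export
as.data.frame.family_score_table <- function(x, ...) {
  n <- length(x$nodes)
  rows <- which(is.finite(x$scores), arr.ind = TRUE)
  ps <- vapply(rows[, 1L] - 1L, function(mask) {
    paste(x$nodes[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0], collapse = ",")
  }, character(1))
  data.frame(node = x$nodes[rows[, 2L]], parents = ps,
             score = x$scores[rows], stringsAsFactors = FALSE)
}

.learn_raw <- function(x, max_parents = Inf) {
  # x: complete integer matrix with columns already in the desired
  # tie-breaking order (name-sorted by the public wrapper)
  mp <- if (is.finite(max_parents)) as.integer(max_parents) else -1L
  sm <- cpp_family_scores(x, mp)
  res <- cpp_learn_exact(sm)
  parents <- lapply(res$parents, function(p) colnames(x)[p + 1L])
  names(parents) <- colnames(x)
  list(parents = parents, score = res$score)
}

#' Exact Bayesian-network structure learning
#'
#' Finds a globally BIC-optimal DAG on complete binary data by the
#' Silander-Myllymaki dynamic program: (i) best parent set within every
#' candidate subset, (ii) a best-sink dynamic program over variable
#' subsets, (iii) order reconstruction.  The search is exact — no
#' hill-climbing — and deterministic: score ties are broken toward the
#' smaller parent set, then lexicographically by node name.
#'
#' @param data complete binary [cohort_matrix()], matrix or data frame
#'   (at most 20 variables).
#' @param max_parents cap on parent-set size (default unlimited).
#' @return a [bn_dag()]; the attained network score is in attribute
#'   `"score"`.
#' @examples
#' gtn <- pcgc_scenario()
#' cm <- sample_cohort(gtn, 2000, seed = 1)
#' learn_exact(cm)
#' @export
learn_exact <- function(data, max_parents = Inf) {
  x <- .as_complete_matrix(data)
  n <- ncol(x)
  if (n > 20)
    stop("exact search is guarded at 20 variables; subset the variables")
  if (n == 1L || nrow(x) == 0L) {
    d <- bn_dag(colnames(x))
    attr(d, "score") <- if (nrow(x))
      family_bic_score(x, colnames(x)[1L]) else NA_real_
    return(d)
  }
  const <- vapply(seq_len(n), function(j) length(unique(x[, j])) == 1L,
                  logical(1))
  if (all(const)) {
    warning("all variables constant; returning the empty DAG")
    d <- bn_dag(colnames(x))
    attr(d, "score") <- sum(vapply(colnames(x), function(v)
      family_bic_score(x, v), numeric(1)))
    return(d)
  }
  ord <- order(colnames(x), method = "radix")  # name order for tie-breaking
  res <- .learn_raw(x[, ord, drop = FALSE], max_parents)
  d <- bn_dag(colnames(x), res$parents)
  attr(d, "score") <- res$score
  d
}

#' Network BIC score of a given DAG
#'
#' By decomposability this is the sum of the family scores of every node.
#'
#' @param data complete binary data.
#' @param dag a [bn_dag()] over the data's variables.
#' @return numeric scalar.
#' @export
network_score <- function(data, dag) {
  sum(vapply(dag$nodes, function(v)
    family_bic_score(data, v, dag$parents[[v]]), numeric(1)))
}

.dag_enum_cache <- new.env(parent = emptyenv())

# all DAGs on n labelled nodes as a matrix of per-node parent bitmasks
.enumerate_dags <- function(n) {
  key <- as.character(n)
  if (!is.null(.dag_enum_cache[[key]])) return(.dag_enum_cache[[key]])
  choices <- lapply(seq_len(n), function(v)
    setdiff(0:(2^n - 1), which(bitwAnd(0:(2^n - 1), 2^(v - 1)) > 0) - 1L))
  grid <- as.matrix(do.call(expand.grid, choices))
  bits <- 2^(seq_len(n) - 1)
  is_acyclic <- function(pmask) {
    placed <- 0L
    repeat {
      ready <- which(bitwAnd(pmask, bitwNot(placed)) == 0L &
                       bitwAnd(placed, bits) == 0L)
      if (!length(ready)) return(placed == 2^n - 1L)
      placed <- bitwOr(placed, sum(bits[ready]))
    }
  }
  keep <- vapply(seq_len(nrow(grid)), function(i)
    is_acyclic(as.integer(grid[i, ])), logical(1))
  res <- grid[keep, , drop = FALSE]
  .dag_enum_cache[[key]] <- res
  res
}

#' Brute-force optimal DAG (test oracle)
#'
#' Enumerates every DAG on at most 4 variables (25 DAGs for 3 nodes, 543
#' for 4), scores each by summed family BIC, and returns a maximal one.
#' Exists purely as an independent oracle for [learn_exact()].
#'
#' @param data complete binary data with at most 4 variables.
#' @return list with `dag` (a [bn_dag()]), `score` and `n_dags` (number of
#'   DAGs enumerated).
#' @export
exhaustive_best_dag <- function(data) {
  x <- .as_complete_matrix(data)
  n <- ncol(x)
  if (n > 4L) stop("exhaustive enumeration is limited to 4 variables")
  vn <- colnames(x)
  bits <- 2^(seq_len(n) - 1)
  fam <- matrix(-Inf, 2^n, n)  # family scores indexed by parent bitmask
  for (v in seq_len(n)) for (mask in 0:(2^n - 1)) {
    if (bitwAnd(mask, bits[v]) > 0) next
    fam[mask + 1L, v] <- family_bic_score(x, vn[v], vn[bitwAnd(mask, bits) > 0])
  }
  dags <- .enumerate_dags(n)
  scores <- rowSums(matrix(fam[cbind(as.vector(dags) + 1L,
                                     rep(seq_len(n), each = nrow(dags)))],
                           nrow(dags), n))
  best <- which.max(scores)
  best_pmask <- as.integer(dags[best, ])
  parents <- setNames(lapply(seq_len(n), function(v)
    vn[bitwAnd(best_pmask[v], bits) > 0]), vn)
  list(dag = bn_dag(vn, parents), score = scores[best], n_dags = nrow(dags))
}

#' Moralize a DAG
#'
#' Connects every pair of co-parents of a common child ("marries" them)
#' and drops edge directions, yielding the undirected graph conventionally
#' used to display learned networks.
#'
#' @param dag a [bn_dag()].
#' @return object of class `bn_ugraph`: list with `nodes` and `edges`
#'   (two-column character matrix, each row an unordered edge with
#'   endpoints sorted; rows sorted).
#' @export
moralize <- function(dag) {
  stopifnot(inherits(dag, "bn_dag"))
  edges <- matrix(character(0), 0, 2)
  for (v in dag$nodes) {
    p <- dag$parents[[v]]
    for (u in p) edges <- rbind(edges, sort(c(u, v)))
    if (length(p) > 1) {
      cp <- utils::combn(sort(p), 2)
      edges <- rbind(edges, t(cp))
    }
  }
  if (nrow(edges)) {
    edges <- unique(edges)
    edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  }
  colnames(edges) <- c("a", "b")
  structure(list(nodes = dag$nodes, edges = edges), class = "bn_ugraph")
}

#' @export
print.bn_ugraph <- function(x, ...) {
  cat(sprintf("bn_ugraph: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  for (i in seq_len(nrow(x$edges)))
    cat("  ", x$edges[i, 1], " -- ", x$edges[i, 2], "\n", sep = "")
  invisible(x)
}
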