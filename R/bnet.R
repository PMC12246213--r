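#' Fit conditional probability tables on a given DAG
#'
#' Estimates, for every node, P(v = 1 | parent configuration) from complete
#' binary data with additive zero-state smoothing:
#' \deqn{P(v=1 \mid pa) = \frac{count(v=1, pa) + s}{count(pa) + 2s}}
#' where the pseudocount `s` is either a fixed value (default 0.01) or the
#' sample-size correction 1/N (`smoothing = "1/N"`).  With `s = 0` the
#' estimate is the MLE; a parent configuration never observed then has an
#' undefined (NA) entry, while any positive `s` gives the symmetric 0.5.
#'
#' @param dag a [bn_dag()] whose nodes all appear in `data`.
#' @param data complete binary [cohort_matrix()], matrix or data frame.
#' @param smoothing non-negative pseudocount, or the string `"1/N"`.
#' @return object of class `bnet`: list with `dag`, `cpts` (per node a list
#'   with `parents` and `p1`, the vector of P(v = 1) per parent
#'   configuration in binary order: first parent is the least-significant
#'   bit), `N`, and `smoothing` (list `policy`, `value`).
#' @seealso [bn_fit()] for the one-stop learn-and-fit front end.
#' @export
fit_cpts <- function(dag, data, smoothing = 0.01) {
  stopifnot(inherits(dag, "bn_dag"))
  x <- .as_complete_matrix(data)
  if (!all(dag$nodes %in% colnames(x)))
    stop("DAG node(s) absent from data: ",
         paste(setdiff(dag$nodes, colnames(x)), collapse = ", "))
  pol <- .smoothing_policy(smoothing, nrow(x))
  cpts <- lapply(dag$nodes, function(v)
    .fit_one_cpt(x, v, dag$parents[[v]], pol$value))
  names(cpts) <- dag$nodes
  structure(list(dag = dag, cpts = cpts, N = nrow(x), smoothing = pol),
            class = "bnet")
}

.smoothing_policy <- function(smoothing, N) {
  if (identical(smoothing, "1/N")) {
    if (N == 0L) stop("smoothing '1/N' undefined for empty data")
    list(policy = "one_over_n", value = 1 / N)
  } else {
    stopifnot(is.numeric(smoothing), length(smoothing) == 1L, smoothing >= 0)
    list(policy = "fixed", value = as.numeric(smoothing))
  }
}

.fit_one_cpt <- function(x, v, parents, s) {
  k <- length(parents)
  q <- 2L^k
  cfg <- if (k) as.vector(x[, parents, drop = FALSE] %*% 2^(seq_len(k) - 1)) + 1L
         else rep(1L, nrow(x))
  tot <- tabulate(cfg, q)
  ones <- tabulate(cfg[x[, v] == 1L], q)
  p1 <- (ones + s) / (tot + 2 * s)
  p1[tot == 0 & s == 0] <- NA_real_  # undefined without smoothing
  list(parents = parents, p1 = p1)
}

#' Fit an exact Bayesian network to a binary cohort
#'
#' The package's central fitting function: learns a globally BIC-optimal
#' DAG by exact search ([learn_exact()]) unless a structure is supplied,
#' then fits smoothed conditional probability tables ([fit_cpts()]).
#' The returned `bnet` object supports `print`, `summary`, `coef`,
#' `logLik`, `simulate`, `predict` and `plot`, plus the exact-inference
#' and risk-ratio functions ([bn_query()], [absolute_rr()],
#' [relative_rr()]).
#'
#' @param data complete binary [cohort_matrix()], matrix or data frame
#'   (impute missing cells first with [knn_impute()]).
#' @param max_parents cap on parent-set size during structure search.
#' @param smoothing pseudocount policy, see [fit_cpts()].
#' @param structure optional [bn_dag()] to fix the structure (skips the
#'   search).
#' @return a fitted `bnet` (see [fit_cpts()] for the layout); the network
#'   BIC score of the learned structure is kept in attribute `"score"`.
#' @examples
#' cm <- sample_cohort(pcgc_scenario(), 2000, seed = 7)
#' fit <- bn_fit(cm)
#' fit
#' absolute_rr(fit, "LVO", "CHRMdGV")
#' @export
bn_fit <- function(data, max_parents = Inf, smoothing = 0.01,
                   structure = NULL) {
  x <- .as_complete_matrix(data)
  dag <- if (is.null(structure)) learn_exact(x, max_parents) else structure
  fn <- fit_cpts(dag, x, smoothing)
  attr(fn, "score") <- attr(dag, "score")
  fn
}

#' @export
print.bnet <- function(x, ...) {
  ne <- sum(lengths(lapply(x$cpts, `[[`, "parents")))
  cat(sprintf("bnet: %d nodes, %d edges, N = %s, smoothing = %s (%s)\n",
              length(x$dag$nodes), ne,
              if (is.na(x$N)) "NA" else x$N,
              format(x$smoothing$value), x$smoothing$policy))
  print(x$dag)
  invisible(x)
}

#' @export
summary.bnet <- function(object, ...) {
  marg <- vapply(object$dag$nodes, function(v)
    bn_query(object, setNames(1L, v)), numeric(1))
  out <- list(nodes = object$dag$nodes,
              edges = dag_edges(object$dag),
              marginals = marg, N = object$N,
              smoothing = object$smoothing,
              score = attr(object, "score"))
  class(out) <- "summary.bnet"
  out
}

#' @export
print.summary.bnet <- function(x, ...) {
  cat(sprintf("Exact Bayesian network over %d binary variables (N = %s)\n",
              length(x$nodes), if (is.na(x$N)) "NA" else x$N))
  if (!is.null(x$score) && !is.na(x$score))
    cat(sprintf("network BIC score: %.4f\n", x$score))
  cat("edges:\n")
  if (nrow(x$edges)) for (i in seq_len(nrow(x$edges)))
    cat("  ", x$edges[i, 1], " -> ", x$edges[i, 2], "\n", sep = "")
  else cat("  (none)\n")
  cat("propagated marginals P(v = 1):\n")
  print(round(x$marginals, 4))
  invisible(x)
}

#' @export
coef.bnet <- function(object, ...) {
  rows <- lapply(object$dag$nodes, function(v) {
    ct <- object$cpts[[v]]
    k <- length(ct$parents)
    cfgs <- if (k) {
      g <- expand.grid(rep(list(0:1), k))
      apply(g, 1, function(r)
        paste(sprintf("%s=%d", ct$parents, r), collapse = ","))
    } else ""
    data.frame(node = v, parents = cfgs, p1 = ct$p1,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
logLik.bnet <- function(object, data = NULL, ...) {
  if (is.null(data))
    stop("supply the data to evaluate the log-likelihood on")
  x <- .as_complete_matrix(data)
  ll <- 0
  for (v in object$dag$nodes) {
    ct <- object$cpts[[v]]
    k <- length(ct$parents)
    cfg <- if (k) as.vector(x[, ct$parents, drop = FALSE] %*%
                              2^(seq_len(k) - 1)) + 1L
           else rep(1L, nrow(x))
    p <- ct$p1[cfg]
    ll <- ll + sum(log(ifelse(x[, v] == 1L, p, 1 - p)))
  }
  npar <- sum(2^lengths(lapply(object$cpts, `[[`, "parents")))
  structure(ll, df = npar, nobs = nrow(x), class = "logLik")
}

# full joint probability vector; cell index bit i (LSB first) = node i's value
.joint_table <- function(fn) {
  nodes <- fn$dag$nodes
  n <- length(nodes)
  if (n > 20) stop("exact enumeration is guarded at 20 nodes")
  cells <- 0:(2^n - 1)
  p <- rep(1, length(cells))
  for (i in seq_len(n)) {
    ct <- fn$cpts[[nodes[i]]]
    if (anyNA(ct$p1))
      stop("undefined CPT entries (unseen parent configuration with s = 0); ",
           "refit with smoothing > 0")
    vi <- bitwAnd(cells, 2^(i - 1)) > 0
    k <- length(ct$parents)
    cfg <- if (k) {
      pidx <- match(ct$parents, nodes)
      Reduce(`+`, lapply(seq_len(k), function(j)
        (bitwAnd(cells, 2^(pidx[j] - 1)) > 0) * 2^(j - 1))) + 1L
    } else rep(1L, length(cells))
    pv <- ct$p1[cfg]
    p <- p * ifelse(vi, pv, 1 - pv)
  }
  p
}

.cell_mask <- function(fn, assignment) {
  # logical vector over joint-table cells matching a partial assignment
  nodes <- fn$dag$nodes
  if (is.null(names(assignment)) || !all(names(assignment) %in% nodes))
    stop("assignment names must be network nodes")
  if (anyDuplicated(names(assignment))) stop("node assigned twice")
  if (!all(assignment %in% c(0, 1))) stop("assignments must be 0/1")
  cells <- 0:(2^length(nodes) - 1)
  keep <- rep(TRUE, length(cells))
  for (v in names(assignment)) {
    i <- match(v, nodes)
    keep <- keep & ((bitwAnd(cells, 2^(i - 1)) > 0) == (assignment[[v]] == 1))
  }
  keep
}

#' Joint probability of a full assignment
#'
#' Chain-rule product of CPT terms; the assignment must cover every node.
#'
#' @param fn a fitted `bnet`.
#' @param assignment named vector of 0/1 values for all nodes.
#' @return probability.
#' @export
joint_probability <- function(fn, assignment) {
  stopifnot(inherits(fn, "bnet"))
  if (!setequal(names(assignment), fn$dag$nodes))
    stop("assignment must cover all nodes exactly; use bn_query for ",
         "partial assignments")
  p <- 1
  for (v in fn$dag$nodes) {
    ct <- fn$cpts[[v]]
    k <- length(ct$parents)
    cfg <- if (k) sum((assignment[ct$parents] == 1) * 2^(seq_len(k) - 1)) + 1L
           else 1L
    pv <- ct$p1[cfg]
    if (is.na(pv)) stop("undefined CPT entry; refit with smoothing > 0")
    p <- p * if (assignment[[v]] == 1) pv else 1 - pv
  }
  unname(p)
}

#' Exact conditional-probability query (network propagation)
#'
#' Computes P(targets | evidence) by exact summation of the network's
#' joint distribution over all hidden variables (full enumeration; the
#' networks this package targets have at most ~20 nodes).
#'
#' @param fn a fitted `bnet`.
#' @param targets named 0/1 vector: the queried partial assignment.
#' @param evidence named 0/1 vector of conditioning values (default none),
#'   disjoint from `targets`.
#' @return the conditional probability.
#' @examples
#' fit <- pcgc_scenario()
#' bn_query(fit, c(MORT = 1), c(CHRMdGV = 1))
#' @export
bn_query <- function(fn, targets, evidence = NULL) {
  stopifnot(inherits(fn, "bnet"))
  if (length(intersect(names(targets), names(evidence))))
    stop("targets and evidence must be disjoint")
  jt <- .joint_table(fn)
  em <- if (length(evidence)) .cell_mask(fn, evidence)
        else rep(TRUE, length(jt))
  pe <- sum(jt[em])
  if (pe <= 0) stop("impossible evidence: P(evidence) = 0")
  tm <- .cell_mask(fn, targets)
  sum(jt[tm & em]) / pe
}

#' Simulate patients from a fitted network
#'
#' Ancestral sampling in topological order: each node is drawn Bernoulli
#' from its CPT row given the already-sampled parents.  Reproducible given
#' `seed`; the topological order is fixed internally, so results do not
#' depend on variable declaration order.
#'
#' @param object a `bnet`.
#' @param nsim number of patients to draw.
#' @param seed RNG seed (optional; the RNG state is restored afterwards
#'   when a seed is given).
#' @param ... unused.
#' @return a [cohort_matrix()] with `nsim` rows.
#' @export
simulate.bnet <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  nodes <- object$dag$nodes
  ord <- topological_order(object$dag)
  x <- matrix(NA_integer_, nsim, length(nodes),
              dimnames = list(if (nsim) sprintf("P%04d", seq_len(nsim))
                              else character(0), nodes))
  for (v in ord) {
    ct <- object$cpts[[v]]
    k <- length(ct$parents)
    cfg <- if (k && nsim) as.vector(x[, ct$parents, drop = FALSE] %*%
                                      2^(seq_len(k) - 1)) + 1L
           else rep(1L, nsim)
    x[, v] <- as.integer(stats::runif(nsim) < ct$p1[cfg])
  }
  roles <- attr(object, "roles")
  cohort_matrix(x, roles = if (!is.null(roles)) roles[nodes] else NULL)
}

#' Per-patient outcome probabilities from a fitted network
#'
#' For each row of `newdata`, computes P(target = 1 | observed values),
#' treating NA cells as hidden and summing them out exactly.
#'
#' @param object a `bnet`.
#' @param newdata [cohort_matrix()], matrix or data frame whose columns are
#'   network nodes (NAs allowed).
#' @param target node whose probability is predicted.
#' @param ... unused.
#' @return numeric vector, one probability per row.
#' @export
predict.bnet <- function(object, newdata, target, ...) {
  stopifnot(target %in% object$dag$nodes)
  x <- if (inherits(newdata, "cohort_matrix")) newdata$x else as.matrix(newdata)
  vars <- intersect(colnames(x), setdiff(object$dag$nodes, target))
  vapply(seq_len(nrow(x)), function(i) {
    ev <- x[i, vars]
    ev <- ev[!is.na(ev)]
    bn_query(object, setNames(1L, target),
             if (length(ev)) ev else NULL)
  }, numeric(1))
}

#' Plot a fitted network
#'
#' Draws the DAG (or its moralized undirected display graph) with igraph.
#'
#' @param x a `bnet` or [bn_dag()].
#' @param moralized draw the moralized undirected graph instead of the DAG.
#' @param ... passed to `plot.igraph`.
#' @export
plot.bnet <- function(x, moralized = FALSE, ...) {
  if (!requireNamespace("igraph", quietly = TRUE))
    stop("plotting requires the igraph package")
  dag <- x$dag
  if (moralized) {
    g <- moralize(dag)
    ig <- igraph::graph_from_data_frame(as.data.frame(g$edges),
                                        directed = FALSE,
                                        vertices = g$nodes)
  } else {
    e <- dag_edges(dag)
    ig <- igraph::graph_from_data_frame(as.data.frame(e), directed = TRUE,
                                        vertices = dag$nodes)
  }
  plot(ig, ...)
  invisible(ig)
}

#' @export
plot.bn_dag <- function(x, moralized = FALSE, ...) {
  plot.bnet(list(dag = x), moralized = moralized, ...)
}
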