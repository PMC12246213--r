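#' Network-propagated risk ratios
#'
#' Two summaries of risk computed from a fitted network by exact
#' inference.  The absolute risk ratio compares the probability of a
#' target state given a condition to its marginal probability in the
#' whole population:
#' \deqn{RR_{abs} = P(T = 1 \mid C = 1) / P(T = 1)}
#' The relative risk ratio contrasts a joint target assignment between
#' carriers and non-carriers of a factor:
#' \deqn{RR_{rel} = P(T \mid F = 1) / P(T \mid F = 0)}
#'
#' @param fn a fitted `bnet`.
#' @param target,condition single node names (absolute ratio: both taken
#'   at value 1).
#' @param targets named 0/1 vector, a joint assignment (relative ratio).
#' @param factor conditioning node (relative ratio), not among `targets`.
#' @return the ratio (numeric scalar).
#' @seealso [bootstrap_risk()] for confidence intervals.
#' @export
absolute_rr <- function(fn, target, condition) {
  stopifnot(inherits(fn, "bnet"),
            target %in% fn$dag$nodes, condition %in% fn$dag$nodes)
  pt <- bn_query(fn, setNames(1L, target))
  if (pt <= 0) stop("marginal P(target) = 0; ratio undefined")
  if (target == condition) return(1 / pt)  # P(T | T) = 1 by definition
  bn_query(fn, setNames(1L, target), setNames(1L, condition)) / pt
}

#' @rdname absolute_rr
#' @export
relative_rr <- function(fn, targets, factor) {
  stopifnot(inherits(fn, "bnet"), factor %in% fn$dag$nodes)
  if (factor %in% names(targets))
    stop("factor must not be among the targets")
  num <- bn_query(fn, targets, setNames(1L, factor))
  den <- bn_query(fn, targets, setNames(0L, factor))
  if (den <= 0) stop("P(targets | factor = 0) = 0; ratio undefined")
  num / den
}

#' Specify a risk query
#'
#' @param kind `"absolute"` or `"relative"`.
#' @param target single target node (absolute).
#' @param condition conditioning node (absolute).
#' @param targets named 0/1 vector (relative).
#' @param factor conditioning node (relative).
#' @return object of class `risk_query`.
#' @export
risk_query <- function(kind = c("absolute", "relative"),
                       target = NULL, condition = NULL,
                       targets = NULL, factor = NULL) {
  kind <- match.arg(kind)
  if (kind == "absolute") {
    stopifnot(is.character(target), is.character(condition))
    q <- list(kind = kind, target = target, condition = condition)
  } else {
    stopifnot(!is.null(names(targets)), is.character(factor))
    q <- list(kind = kind, targets = targets, factor = factor)
  }
  structure(q, class = "risk_query")
}

.query_variables <- function(q) {
  if (q$kind == "absolute") c(q$target, q$condition)
  else c(names(q$targets), q$factor)
}

.query_label <- function(q) {
  if (q$kind == "absolute")
    sprintf("absolute %s=1 | %s=1", q$target, q$condition)
  else
    sprintf("relative %s | %s",
            paste(sprintf("%s=%d", names(q$targets), q$targets),
                  collapse = ","), q$factor)
}

.eval_query <- function(fn, q) {
  if (q$kind == "absolute") absolute_rr(fn, q$target, q$condition)
  else relative_rr(fn, q$targets, q$factor)
}

#' Bootstrap confidence intervals for network-propagated risk ratios
#'
#' Resamples the cohort with replacement `B` times; in every replicate the
#' network structure is re-learned from scratch ([learn_exact()]) and the
#' CPTs refit with zero-state smoothing before the query is evaluated, so
#' the interval reflects structural as well as parametric uncertainty.
#' Replicates whose resample makes the query undefined (a conditioning
#' event with zero probability, e.g. a zero-variance factor) are excluded
#' and counted, never imputed.
#'
#' Two interval summaries are available: `percentile_median` reports the
#' replicate median with the empirical 5th and 95th percentiles (bars may
#' be asymmetric around the median), and `t_mean` reports the replicate
#' mean plus/minus the 97.5 percent t quantile (df = B_used - 1) times the
#' replicate standard deviation.
#'
#' @param cm complete [cohort_matrix()] (impute first), or matrix.
#' @param variables node subset defining the network; must contain every
#'   query variable.
#' @param query a [risk_query()].
#' @param B number of bootstrap replicates (the reference analysis used
#'   1000).
#' @param seed RNG seed; the whole procedure is seed-deterministic.
#' @param summary `"percentile_median"` or `"t_mean"`.
#' @param smoothing CPT pseudocount policy (see [fit_cpts()]); default the
#'   fixed zero-state value 0.01, `"1/N"` selects the sample-size
#'   correction.
#' @param max_parents structure-search cap.
#' @param relearn re-learn the structure in every replicate (default); if
#'   `FALSE` the structure learned on the full data is kept fixed
#'   (ablation mode).
#' @param resample if `FALSE`, replicates use the original data (with
#'   `B = 1` this degenerates to the direct point estimate).
#' @param percentiles interval percentiles for the percentile summary.
#' @param keep_replicates store the replicate values in the result.
#' @return object of class `risk_estimate`: list with `point`, `ci_low`,
#'   `ci_high`, `summary_method`, `B`, `n_undefined`, `seed`, `query`,
#'   and optionally `replicates`.
#' @export
bootstrap_risk <- function(cm, variables = NULL, query, B = 1000, seed = 1,
                           summary = c("percentile_median", "t_mean"),
                           smoothing = 0.01, max_parents = Inf,
                           relearn = TRUE, resample = TRUE,
                           percentiles = c(0.05, 0.95),
                           keep_replicates = TRUE) {
  summary <- match.arg(summary)
  stopifnot(inherits(query, "risk_query"), B >= 1)
  x <- .as_complete_matrix(cm)
  if (is.null(variables)) variables <- colnames(x)
  qv <- .query_variables(query)
  if (!all(qv %in% variables))
    stop("variables must include every query variable")
  x <- x[, variables, drop = FALSE]
  ord <- order(colnames(x), method = "radix")
  x <- x[, ord, drop = FALSE]
  n <- nrow(x)
  fixed_dag <- if (!relearn) learn_exact(x, max_parents) else NULL
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  reps <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    xb <- if (resample) x[sample.int(n, n, replace = TRUE), , drop = FALSE]
          else x
    reps[b] <- tryCatch({
      dag <- if (relearn) {
        res <- .learn_raw(xb, max_parents)
        bn_dag(colnames(xb), res$parents)
      } else fixed_dag
      fn <- fit_cpts(dag, xb, smoothing)
      .eval_query(fn, query)
    }, error = function(e) NA_real_)
  }
  ok <- reps[!is.na(reps)]
  if (!length(ok)) stop("all bootstrap replicates were undefined")
  est <- if (summary == "percentile_median") {
    list(point = stats::median(ok),
         ci = unname(stats::quantile(ok, percentiles)))
  } else {
    m <- mean(ok)
    half <- if (length(ok) > 1)
      stats::qt(0.975, df = length(ok) - 1) * stats::sd(ok) else 0
    list(point = m, ci = c(m - half, m + half))
  }
  structure(list(point = est$point, ci_low = est$ci[1], ci_high = est$ci[2],
                 summary_method = summary, B = B,
                 n_undefined = as.integer(B - length(ok)), seed = seed,
                 query = query,
                 replicates = if (keep_replicates) reps else NULL),
            class = "risk_estimate")
}

#' @export
print.risk_estimate <- function(x, ...) {
  cat(sprintf("%s: %.3f (%.3f, %.3f)  [%s, B = %d, undefined = %d]\n",
              .query_label(x$query), x$point, x$ci_low, x$ci_high,
              x$summary_method, x$B, x$n_undefined))
  invisible(x)
}

#' Conditional-dependency feature screen
#'
#' For each candidate-target pair, estimates the conditional probability
#' P(target = 1 | candidate = 1) as the median over `B` bootstrap
#' networks learned on the pair, divides by the target's baseline
#' probability to obtain an absolute risk ratio, and selects pairs with
#' ratio at or above `threshold` (default 1.0) for downstream network
#' construction.
#'
#' @param cm complete [cohort_matrix()] or matrix.
#' @param candidates candidate conditioning variables (e.g. genotype
#'   flags).
#' @param targets target variables (e.g. phenotype or outcome flags).
#' @param B bootstrap replicates per pair.
#' @param seed RNG seed.
#' @param threshold selection cutoff on the absolute risk ratio.
#' @param ... passed to [bootstrap_risk()].
#' @return data frame with one row per pair: `candidate`, `target`,
#'   `conditional_p`, `baseline_p`, `absolute_rr`, `n_undefined`,
#'   `selected`.
#' @export
screen_features <- function(cm, candidates, targets, B = 1000, seed = 1,
                            threshold = 1.0, ...) {
  x <- .as_complete_matrix(cm)
  stopifnot(all(c(candidates, targets) %in% colnames(x)),
            !length(intersect(candidates, targets)))
  grid <- expand.grid(candidate = candidates, target = targets,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cand <- grid$candidate[i]; targ <- grid$target[i]
    base <- mean(x[, targ])
    est <- bootstrap_risk(x, variables = c(cand, targ),
                          query = risk_query("absolute", target = targ,
                                             condition = cand),
                          B = B, seed = seed + i,
                          summary = "percentile_median",
                          keep_replicates = FALSE, ...)
    data.frame(candidate = cand, target = targ,
               conditional_p = est$point * base, baseline_p = base,
               absolute_rr = est$point, n_undefined = est$n_undefined,
               selected = est$point >= threshold,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Pathway-by-phenotype enrichment table
#'
#' One row per gene-pathway flag, one column per phenotype flag; each cell
#' is the absolute risk ratio of the phenotype given a damaging genotype
#' in the pathway, with a bootstrap confidence interval (t-mean summary by
#' default, matching the convention of reporting the replicate mean and a
#' t-distribution 95 percent interval).  Cells with no carrier of both
#' flags are left empty (NA, printed as a dash).  The `n` column counts
#' patients carrying the pathway flag.
#'
#' @param cm complete [cohort_matrix()] or matrix.
#' @param pathway_flags pathway genotype variables (rows).
#' @param phenotype_flags phenotype variables (columns).
#' @param B bootstrap replicates per cell.
#' @param seed RNG seed.
#' @param summary interval summary (see [bootstrap_risk()]).
#' @param ... passed to [bootstrap_risk()].
#' @return object of class `enrichment_table`: list with `point`,
#'   `ci_low`, `ci_high` (pathway x phenotype matrices), `n_carriers`,
#'   and the call parameters.
#' @export
pathway_enrichment_table <- function(cm, pathway_flags, phenotype_flags,
                                     B = 1000, seed = 1,
                                     summary = "t_mean", ...) {
  x <- .as_complete_matrix(cm)
  stopifnot(all(c(pathway_flags, phenotype_flags) %in% colnames(x)))
  dims <- list(pathway_flags, phenotype_flags)
  point <- lo <- hi <- matrix(NA_real_, length(pathway_flags),
                              length(phenotype_flags), dimnames = dims)
  ncar <- setNames(colSums(x[, pathway_flags, drop = FALSE]), pathway_flags)
  cell <- 0L
  for (pw in pathway_flags) for (ph in phenotype_flags) {
    cell <- cell + 1L
    if (sum(x[, pw] == 1L & x[, ph] == 1L) == 0L) next  # dash cell
    est <- bootstrap_risk(x, variables = c(pw, ph),
                          query = risk_query("absolute", target = ph,
                                             condition = pw),
                          B = B, seed = seed + cell, summary = summary,
                          keep_replicates = FALSE, ...)
    point[pw, ph] <- est$point
    lo[pw, ph] <- est$ci_low
    hi[pw, ph] <- est$ci_high
  }
  structure(list(point = point, ci_low = lo, ci_high = hi,
                 n_carriers = ncar, B = B, summary = summary, seed = seed),
            class = "enrichment_table")
}

#' @export
print.enrichment_table <- function(x, digits = 2, ...) {
  cat(sprintf("Absolute risk ratios (%s, B = %d); dash = no co-carriers\n",
              x$summary, x$B))
  fmt <- matrix("-", nrow(x$point), ncol(x$point),
                dimnames = dimnames(x$point))
  ok <- !is.na(x$point)
  fmt[ok] <- sprintf("%.*f (%.*f, %.*f)", digits, x$point[ok],
                     digits, x$ci_low[ok], digits, x$ci_high[ok])
  df <- data.frame(n = x$n_carriers, fmt, check.names = FALSE)
  print(df)
  invisible(x)
}
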