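#' Binary cohort matrices
#'
#' A `cohort_matrix` holds a patients-by-variables table of presence/absence
#' flags with optional missing entries.  It is the substrate of every
#' downstream stage: collinearity screening, imputation, structure learning
#' and risk estimation.  Rows are patients (unique IDs), columns are binary
#' variables; each variable carries a role drawn from a closed set.
#'
#' @param x integer or logical matrix with entries in \{0, 1, NA\};
#'   rownames are patient IDs, colnames are variable names.
#' @param roles optional named character vector mapping variable names to one
#'   of `"genotype"`, `"cardiac_phenotype"`, `"extracardiac"`, `"surgical"`,
#'   `"outcome"`.  Variables without an entry get role `"unspecified"`.
#' @param missing_cap maximum tolerated per-variable missing fraction
#'   (default 0.10).  Exceeding it is an error unless `allow_excess_missing`.
#' @param allow_excess_missing override the missingness cap.
#' @param imputed logical flag marking a matrix whose missing cells were
#'   filled in by [knn_impute()].
#' @return an object of class `cohort_matrix`: a list with elements `x`
#'   (integer matrix), `roles` (named character) and `imputed` (logical).
#' @seealso [read_cohort_matrix()], [knn_impute()], [collinearity_screen()]
#' @export
cohort_matrix <- function(x, roles = NULL, missing_cap = 0.10,
                          allow_excess_missing = FALSE, imputed = FALSE) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) stop("'x' must be a matrix or data frame")
  storage.mode(x) <- "integer"
  bad <- !is.na(x) & !(x %in% c(0L, 1L))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("non-binary value at row %d, column %d ('%s')",
                 idx[1L], idx[2L],
                 if (is.null(colnames(x))) idx[2L] else colnames(x)[idx[2L]]))
  }
  if (is.null(colnames(x)))
    colnames(x) <- paste0("V", seq_len(ncol(x)))
  if (anyDuplicated(colnames(x)))
    stop("duplicate variable names")
  if (is.null(rownames(x)))
    rownames(x) <- if (nrow(x)) paste0("P", seq_len(nrow(x))) else character(0)
  if (anyDuplicated(rownames(x)))
    stop("duplicate patient IDs")
  role_set <- c("genotype", "cardiac_phenotype", "extracardiac",
                "surgical", "outcome", "unspecified")
  r <- setNames(rep("unspecified", ncol(x)), colnames(x))
  if (!is.null(roles)) {
    unknown <- setdiff(names(roles), colnames(x))
    if (length(unknown))
      stop("roles given for unknown variables: ", paste(unknown, collapse = ", "))
    if (!all(roles %in% role_set))
      stop("role must be one of: ", paste(role_set, collapse = ", "))
    r[names(roles)] <- roles
  }
  if (nrow(x) > 0L) {
    mfrac <- colMeans(is.na(x))
    if (any(mfrac > missing_cap) && !allow_excess_missing)
      stop(sprintf(
        "variable(s) exceed the %.0f%% missingness cap: %s (use allow_excess_missing = TRUE to override)",
        100 * missing_cap,
        paste(colnames(x)[mfrac > missing_cap], collapse = ", ")))
  }
  structure(list(x = x, roles = r, imputed = isTRUE(imputed)),
            class = "cohort_matrix")
}

#' @export
print.cohort_matrix <- function(x, ...) {
  nm <- sum(is.na(x$x))
  cat(sprintf("cohort_matrix: %d patients x %d variables%s\n",
              nrow(x$x), ncol(x$x),
              if (x$imputed) " (imputed)" else ""))
  cat(sprintf("  missing cells: %d (%.2f%%)\n", nm,
              if (length(x$x)) 100 * nm / length(x$x) else 0))
  tab <- table(x$roles)
  cat("  roles: ", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @export
dim.cohort_matrix <- function(x) dim(x$x)

#' @export
as.matrix.cohort_matrix <- function(x, ...) x$x

#' Read a binary cohort matrix from a delimited file
#'
#' Expects a header row of variable names and a first column of patient IDs.
#' Cells must parse to 0, 1 or a missing token (by default `"NA"` or an
#' empty cell).
#'
#' @param path file to read.
#' @param sep field delimiter, `"\t"` (default) or `","`.
#' @param missing_tokens character values interpreted as missing.
#' @param roles,missing_cap,allow_excess_missing passed to [cohort_matrix()].
#' @return a [cohort_matrix()].
#' @export
read_cohort_matrix <- function(path, sep = "\t",
                               missing_tokens = c("NA", ""),
                               roles = NULL, missing_cap = 0.10,
                               allow_excess_missing = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (length(lines) == 0L || !nzchar(trimws(lines[1L])))
    stop("no header: file is empty")
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          na.strings = character(0), quote = "")
  if (ncol(df) < 2L) stop("expected an ID column plus at least one variable")
  ids <- df[[1L]]
  if (anyDuplicated(ids)) stop("duplicate patient IDs in file: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- as.matrix(df[, -1L, drop = FALSE])
  out <- matrix(NA_integer_, nrow(vals), ncol(vals),
                dimnames = list(ids, colnames(vals)))
  is_missing <- vals %in% missing_tokens
  out[vals == "0"] <- 0L
  out[vals == "1"] <- 1L
  unparsed <- !is_missing & is.na(out) & !is.na(vals)
  if (any(unparsed)) {
    idx <- which(matrix(unparsed, nrow(vals)), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-binary cell '%s' at patient '%s', variable '%s'",
                 vals[idx[1L], idx[2L]], ids[idx[1L]], colnames(vals)[idx[2L]]))
  }
  cohort_matrix(out, roles = roles, missing_cap = missing_cap,
                allow_excess_missing = allow_excess_missing)
}

#' Write a cohort matrix to a delimited file
#'
#' Inverse of [read_cohort_matrix()]: first column `patient_id`, one column
#' per variable, missing cells written as `"NA"`.
#'
#' @param cm a [cohort_matrix()].
#' @param path output file.
#' @param sep field delimiter.
#' @export
write_cohort_matrix <- function(cm, path, sep = "\t") {
  stopifnot(inherits(cm, "cohort_matrix"))
  df <- data.frame(patient_id = rownames(cm$x), cm$x,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read/write a variable-role sidecar table
#'
#' Three-column TSV: `name`, `role`, `description`.
#' @param path file path.
#' @return named character vector of roles (descriptions in attribute
#'   `"description"`).
#' @export
read_variable_roles <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "")
  r <- setNames(df$role, df$name)
  attr(r, "description") <- setNames(df$description, df$name)
  r
}

#' Per-variable baseline frequencies
#'
#' The baseline probability P(v = 1) of each variable, computed over its
#' non-missing entries.  These marginals are the denominators of absolute
#' risk ratios and the priors of every network stage.
#'
#' @param cm a [cohort_matrix()].
#' @return data frame with columns `variable`, `frequency`, `n_observed`.
#' @export
variable_frequencies <- function(cm) {
  stopifnot(inherits(cm, "cohort_matrix"))
  nobs <- colSums(!is.na(cm$x))
  if (any(nobs == 0L))
    stop("variable(s) with no observed values: ",
         paste(colnames(cm$x)[nobs == 0L], collapse = ", "))
  data.frame(variable = colnames(cm$x),
             frequency = colMeans(cm$x, na.rm = TRUE),
             n_observed = as.integer(nobs),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Screen a cohort matrix for collinear variable pairs
#'
#' Computes the phi coefficient (Pearson correlation of binary variables)
#' for every variable pair over pairwise-complete observations, and flags
#' pairs whose absolute phi exceeds `threshold`.  Highly correlated
#' variables can distort structure learning and risk estimation, so flagged
#' pairs should be pruned to one representative before network stages.
#' A zero-variance variable has no defined phi; its pairs are reported with
#' `phi = NA` and listed in the `degenerate` component rather than silently
#' set to zero.
#'
#' @param cm a [cohort_matrix()].
#' @param threshold absolute phi above which a pair is flagged (default 0.7).
#' @return object of class `correlation_report`: list with `pairs` (data
#'   frame: `var1`, `var2`, `phi`, `n_complete`), `flagged` (subset with
#'   `|phi| > threshold`), `degenerate` (zero-variance variable names) and
#'   `threshold`.
#' @export
collinearity_screen <- function(cm, threshold = 0.7) {
  stopifnot(inherits(cm, "cohort_matrix"))
  x <- cm$x
  if (ncol(x) < 2L) stop("need at least two variables")
  p <- ncol(x)
  vn <- colnames(x)
  degen <- vn[vapply(seq_len(p), function(j) {
    v <- x[, j]; v <- v[!is.na(v)]
    length(unique(v)) < 2L
  }, logical(1))]
  pairs <- utils::combn(p, 2L)
  res <- data.frame(var1 = vn[pairs[1L, ]], var2 = vn[pairs[2L, ]],
                    phi = NA_real_, n_complete = NA_integer_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(ncol(pairs))) {
    a <- x[, pairs[1L, i]]; b <- x[, pairs[2L, i]]
    ok <- !is.na(a) & !is.na(b)
    res$n_complete[i] <- sum(ok)
    if (sum(ok) >= 2L &&
        length(unique(a[ok])) > 1L && length(unique(b[ok])) > 1L)
      res$phi[i] <- stats::cor(a[ok], b[ok])
  }
  flagged <- res[!is.na(res$phi) & abs(res$phi) > threshold, , drop = FALSE]
  structure(list(pairs = res, flagged = flagged, degenerate = degen,
                 threshold = threshold),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf("correlation_report: %d pairs, threshold |phi| > %.2f\n",
              nrow(x$pairs), x$threshold))
  if (nrow(x$flagged)) {
    cat("flagged pairs:\n")
    print(x$flagged, row.names = FALSE)
  } else cat("no flagged pairs\n")
  if (length(x$degenerate))
    cat("zero-variance (phi undefined): ",
        paste(x$degenerate, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' K-nearest-neighbour imputation for binary cohort matrices
#'
#' Replaces each missing cell by the majority vote of the `k` nearest
#' patients, with distance measured as the Hamming distance over mutually
#' observed variables, normalised by the number of mutually observed
#' variables.  Only neighbours with the target variable observed can vote;
#' if fewer than `k` such neighbours exist the vote falls back to all
#' available ones with a warning.  Ties in distance are broken by patient
#' row order; even votes fall back to the variable's marginal mode, so the
#' procedure is fully deterministic.  Observed cells are never altered.
#'
#' @param cm a [cohort_matrix()] (missingness within the configured cap).
#' @param k number of neighbours (default 10).
#' @return a complete [cohort_matrix()] with `imputed = TRUE`.
#' @export
knn_impute <- function(cm, k = 10L) {
  stopifnot(inherits(cm, "cohort_matrix"), k >= 1L)
  x <- cm$x
  if (!anyNA(x)) {
    out <- cm; out$imputed <- TRUE
    return(out)
  }
  if (any(rowSums(!is.na(x)) == 0L))
    stop("patient(s) with all entries missing: ",
         paste(rownames(x)[rowSums(!is.na(x)) == 0L], collapse = ", "))
  # marginal modes as the even-vote fallback (1 wins exact 0.5 prevalence ties)
  modes <- ifelse(colMeans(x, na.rm = TRUE) >= 0.5, 1L, 0L)
  obs <- !is.na(x)
  x0 <- x; x0[!obs] <- 0L
  n <- nrow(x)
  filled <- x
  warned <- FALSE
  for (i in which(rowSums(!obs) > 0L)) {
    # normalized Hamming distance from patient i to all others
    oi <- obs[i, ]
    overlap <- obs %*% oi                        # mutually observed counts
    diffs <- (x0 != matrix(x0[i, ], n, ncol(x), byrow = TRUE)) & obs &
      matrix(oi, n, ncol(x), byrow = TRUE)
    d <- ifelse(overlap > 0, rowSums(diffs) / overlap, Inf)
    d[i] <- Inf
    ord <- order(d, seq_len(n))                  # distance, then row order
    for (j in which(!obs[i, ])) {
      voters <- ord[obs[ord, j] & is.finite(d[ord])]
      if (length(voters) == 0L) {
        filled[i, j] <- modes[j]
        next
      }
      if (length(voters) < k && !warned) {
        warning(sprintf(
          "fewer than k = %d neighbours with '%s' observed; using all %d available",
          k, colnames(x)[j], length(voters)))
        warned <- TRUE
      }
      vv <- x[utils::head(voters, k), j]
      s <- sum(vv)
      filled[i, j] <- if (2L * s > length(vv)) 1L
                      else if (2L * s < length(vv)) 0L
                      else modes[j]
    }
  }
  cohort_matrix(filled, roles = cm$roles, imputed = TRUE)
}

#' Drop zero-variance variables before network stages
#'
#' Structure learning over a constant column is vacuous and its phi
#' coefficients are undefined, so such columns are reported and removed.
#'
#' @param cm a [cohort_matrix()].
#' @return a [cohort_matrix()] without zero-variance columns; dropped names
#'   in attribute `"dropped"`.
#' @export
drop_zero_variance <- function(cm) {
  stopifnot(inherits(cm, "cohort_matrix"))
  keep <- vapply(seq_len(ncol(cm$x)), function(j) {
    v <- cm$x[, j]; v <- v[!is.na(v)]
    length(unique(v)) > 1L
  }, logical(1))
  dropped <- colnames(cm$x)[!keep]
  if (length(dropped))
    message("dropping zero-variance variable(s): ",
            paste(dropped, collapse = ", "))
  out <- cohort_matrix(cm$x[, keep, drop = FALSE],
                       roles = cm$roles[colnames(cm$x)[keep]],
                       allow_excess_missing = TRUE, imputed = cm$imputed)
  attr(out, "dropped") <- dropped
  out
}

#' Restrict a cohort matrix to a variable subset
#' @param cm a [cohort_matrix()].
#' @param variables character vector of variable names to keep.
#' @return a [cohort_matrix()].
#' @export
subset_variables <- function(cm, variables) {
  stopifnot(inherits(cm, "cohort_matrix"))
  missing_vars <- setdiff(variables, colnames(cm$x))
  if (length(missing_vars))
    stop("unknown variable(s): ", paste(missing_vars, collapse = ", "))
  cohort_matrix(cm$x[, variables, drop = FALSE],
                roles = cm$roles[variables],
                allow_excess_missing = TRUE, imputed = cm$imputed)
}
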