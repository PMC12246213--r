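#' Train the multiclass phenotype classifier
#'
#' Gradient-boosted trees (multi:softprob) over binary phenotype-code
#' features, assigning each patient to one of the five CHD phenotype
#' categories.  Hyperparameters are chosen by k-fold cross-validated grid
#' search minimising multiclass log loss; ties are broken by lower
#' classification error, then lower log-loss standard deviation across
#' folds.  The winning configuration is retrained on all data and the full
#' per-grid-point CV diagnostics are retained.  Training is deterministic
#' given `seed` (single-threaded boosting).
#'
#' @param codes binary patients x codes matrix (rownames = patient IDs).
#' @param labels factor (or character) of categories, one per patient;
#'   every one of the five categories {LVO, HTX, AVC, CTD, OTH} must be
#'   present.
#' @param folds number of CV folds (default 5).
#' @param grid data frame of hyperparameter combinations with columns
#'   `max_depth`, `eta`, `nrounds` and optionally `subsample` (row
#'   subsampling fraction per boosting round); default grid: depth
#'   {3, 4, 6} x eta {0.1, 0.3} x rounds {50, 100, 200}, subsample 1.
#' @param seed RNG seed.
#' @param nthread threads for the boosting library (default 1, which also
#'   guarantees bit-reproducibility).
#' @return object of class `phenotype_classifier`: list with `booster`
#'   (the trained model), `vocabulary`, `categories`, `best` (selected
#'   hyperparameters), `cv` (per-grid-point mean/SD log loss and error),
#'   `folds`, `seed`.
#' @export
train_classifier <- function(codes, labels, folds = 5,
                             grid = default_classifier_grid(),
                             seed = 1, nthread = 1) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "double"
  categories <- c("LVO", "HTX", "AVC", "CTD", "OTH")
  labels <- as.character(labels)
  stopifnot(nrow(codes) == length(labels))
  absent <- setdiff(categories, unique(labels))
  if (length(absent))
    stop("category absent from training labels: ",
         paste(absent, collapse = ", "))
  if (!all(labels %in% categories))
    stop("labels outside the five phenotype categories")
  y <- match(labels, categories) - 1L
  stopifnot(folds >= 2, nrow(grid) >= 1,
            all(c("max_depth", "eta", "nrounds") %in% names(grid)))
  if (is.null(grid$subsample)) grid$subsample <- 1
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  # stratified fold assignment: shuffle within class, deal out round-robin
  fold_id <- integer(length(y))
  for (k in unique(y)) {
    idx <- sample(which(y == k))
    fold_id[idx] <- rep_len(seq_len(folds), length(idx))
  }
  cv <- grid
  cv$mlogloss <- cv$std_mlogloss <- cv$error <- NA_real_
  for (g in seq_len(nrow(grid))) {
    fold_loss <- fold_err <- numeric(folds)
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      bst <- .fit_booster(codes[tr, , drop = FALSE], y[tr], grid[g, ],
                          seed, nthread)
      p <- .predict_probs(bst, codes[!tr, , drop = FALSE], length(categories))
      yt <- y[!tr]
      eps <- 1e-15
      fold_loss[f] <- -mean(log(pmax(p[cbind(seq_along(yt), yt + 1L)], eps)))
      fold_err[f] <- mean(max.col(p) - 1L != yt)
    }
    cv$mlogloss[g] <- mean(fold_loss)
    cv$std_mlogloss[g] <- stats::sd(fold_loss)
    cv$error[g] <- mean(fold_err)
  }
  best <- order(cv$mlogloss, cv$error, cv$std_mlogloss)[1L]
  booster <- .fit_booster(codes, y, grid[best, ], seed, nthread)
  structure(list(booster = booster, vocabulary = colnames(codes),
                 categories = categories, best = grid[best, , drop = FALSE],
                 cv = cv, folds = folds, fold_id = fold_id, seed = seed,
                 nthread = nthread),
            class = "phenotype_classifier")
}

#' @describeIn train_classifier the default hyperparameter grid.
#' @export
default_classifier_grid <- function() {
  g <- expand.grid(max_depth = c(3L, 4L, 6L), eta = c(0.1, 0.3),
                   nrounds = c(50L, 100L, 200L))
  g$subsample <- 1
  g
}

.fit_booster <- function(x, y, hp, seed, nthread) {
  dtrain <- xgboost::xgb.DMatrix(x, label = y)
  params <- list(objective = "multi:softprob", num_class = 5L,
                 max_depth = hp$max_depth, eta = hp$eta,
                 subsample = hp$subsample, nthread = nthread,
                 seed = seed, verbosity = 0)
  xgboost::xgb.train(params = params, data = dtrain,
                     nrounds = hp$nrounds, verbose = 0)
}

.predict_probs <- function(bst, x, ncls) {
  p <- stats::predict(bst, xgboost::xgb.DMatrix(x))
  matrix(p, ncol = ncls, byrow = !is.matrix(p))
}

#' @export
print.phenotype_classifier <- function(x, ...) {
  cat(sprintf("phenotype_classifier: %d codes, %d-fold CV over %d grid points\n",
              length(x$vocabulary), x$folds, nrow(x$cv)))
  cat("selected: ", paste(sprintf("%s=%s", names(x$best), x$best),
                          collapse = ", "), "\n", sep = "")
  b <- which.min(x$cv$mlogloss)
  cat(sprintf("CV mlogloss %.4f (sd %.4f), error %.4f\n",
              x$cv$mlogloss[b], x$cv$std_mlogloss[b], x$cv$error[b]))
  invisible(x)
}

#' Classify patients and report confidence margins
#'
#' Predicts per-patient class probabilities, assigns the most probable
#' category, and reports the confidence margin: the best minus
#' second-best class probability.  The code vocabulary is frozen at
#' training: codes unseen then are dropped with a warning, and training
#' codes absent from `codes` are treated as all-zero columns.
#'
#' @param model a trained [train_classifier()] model.
#' @param codes binary patients x codes matrix.
#' @return data frame with `patient_id`, one probability column per
#'   category, `assigned` and `margin`.
#' @export
predict_assign <- function(model, codes) {
  stopifnot(inherits(model, "phenotype_classifier"))
  codes <- as.matrix(codes)
  if (nrow(codes) == 0L) {
    out <- data.frame(patient_id = character(0))
    for (cc in model$categories) out[[cc]] <- numeric(0)
    out$assigned <- character(0); out$margin <- numeric(0)
    return(out)
  }
  unseen <- setdiff(colnames(codes), model$vocabulary)
  if (length(unseen))
    warning("dropping code(s) unseen at training: ",
            paste(unseen, collapse = ", "))
  x <- matrix(0, nrow(codes), length(model$vocabulary),
              dimnames = list(rownames(codes), model$vocabulary))
  shared <- intersect(colnames(codes), model$vocabulary)
  x[, shared] <- codes[, shared]
  p <- .predict_probs(model$booster, x, length(model$categories))
  colnames(p) <- model$categories
  sorted <- t(apply(p, 1, sort, decreasing = TRUE))
  out <- data.frame(patient_id = if (!is.null(rownames(codes)))
                      rownames(codes) else as.character(seq_len(nrow(codes))),
                    p, stringsAsFactors = FALSE, check.names = FALSE)
  out$assigned <- model$categories[max.col(p, ties.method = "first")]
  out$margin <- sorted[, 1] - sorted[, 2]
  rownames(out) <- NULL
  out
}

#' Classification accuracy metrics
#'
#' Confusion matrix, overall accuracy, and one-vs-rest per-class accuracy,
#' sensitivity and specificity, comparing known category labels to
#' predicted assignments (matched by patient ID).
#'
#' @param labels named character/factor vector of true categories (names =
#'   patient IDs), or unnamed in the order of `preds`.
#' @param preds predictions from [predict_assign()].
#' @return object of class `classifier_metrics`: list with `confusion`,
#'   `accuracy`, `per_class` (data frame: `class`, `accuracy`,
#'   `sensitivity`, `specificity`) and macro-averaged `sensitivity` /
#'   `specificity`.
#' @export
evaluate_classifier <- function(labels, preds) {
  stopifnot(is.data.frame(preds), all(c("patient_id", "assigned") %in%
                                        names(preds)))
  truth <- as.character(labels)
  if (!is.null(names(labels))) {
    if (!setequal(names(labels), preds$patient_id))
      stop("patient IDs of labels and predictions do not match")
    truth <- truth[match(preds$patient_id, names(labels))]
  } else if (length(labels) != nrow(preds))
    stop("labels and predictions have different lengths")
  classes <- sort(unique(c(truth, preds$assigned)))
  conf <- table(truth = factor(truth, classes),
                predicted = factor(preds$assigned, classes))
  acc <- sum(diag(conf)) / sum(conf)
  per <- do.call(rbind, lapply(classes, function(cc) {
    tp <- conf[cc, cc]
    fn <- sum(conf[cc, ]) - tp
    fp <- sum(conf[, cc]) - tp
    tn <- sum(conf) - tp - fn - fp
    data.frame(class = cc,
               accuracy = (tp + tn) / sum(conf),
               sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
               specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  structure(list(confusion = conf, accuracy = acc, per_class = per,
                 sensitivity = mean(per$sensitivity, na.rm = TRUE),
                 specificity = mean(per$specificity, na.rm = TRUE)),
            class = "classifier_metrics")
}

#' @export
print.classifier_metrics <- function(x, ...) {
  cat(sprintf("overall accuracy: %.4f  (macro sens %.4f, spec %.4f)\n",
              x$accuracy, x$sensitivity, x$specificity))
  print(x$per_class, row.names = FALSE)
  cat("confusion matrix:\n")
  print(x$confusion)
  invisible(x)
}
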