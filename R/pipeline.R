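#' Run the end-to-end risk-estimation pipeline
#'
#' Orchestrates the stages — simulate/load, impute, collinearity screen,
#' structure learning, risk estimation with bootstrap intervals, report
#' and network export — from a single configuration, with every source of
#' randomness seeded from the configuration so that identical configs
#' yield byte-identical outputs.
#'
#' Configuration fields (list, or path to a JSON/YAML file):
#' \describe{
#'   \item{input}{path to a cohort TSV (see [read_cohort_matrix()]); or}
#'   \item{scenario}{list `n`, `seed`, optional `missing_rate` — simulate
#'     from [pcgc_scenario()] instead of loading.}
#'   \item{stages}{character subset of `c("simulate", "impute", "screen",
#'     "learn", "bootstrap", "report")`; default all.}
#'   \item{networks}{named list of variable subsets, one learned network
#'     per entry; default one network over all variables.}
#'   \item{queries}{list of query specs: each a list with `kind`
#'     (`"absolute"`/`"relative"`), `network`, and `target`/`condition` or
#'     `targets` (named 0/1)/`factor`.}
#'   \item{impute_k}{KNN neighbour count (default 10).}
#'   \item{smoothing}{CPT pseudocount or `"1/N"` (default 0.01).}
#'   \item{B}{bootstrap replicates (default 1000).}
#'   \item{summary}{`"percentile_median"` (default) or `"t_mean"`.}
#'   \item{seed}{master seed (default 1).}
#'   \item{collinearity_threshold}{flagging threshold (default 0.7).}
#'   \item{outdir}{output directory (required).}
#' }
#'
#' @param config list or path to a JSON/YAML config file.
#' @return the run manifest (list), invisibly; also written to
#'   `manifest.json` in `outdir`.
#' @export
run_pipeline <- function(config) {
  cfg <- .load_config(config)
  if (is.null(cfg$outdir)) stop("config must set 'outdir'")
  stages_all <- c("simulate", "impute", "screen", "learn", "bootstrap",
                  "report")
  stages <- if (is.null(cfg$stages)) stages_all
            else match.arg(unlist(cfg$stages), stages_all, several.ok = TRUE)
  if (is.null(cfg$input) && is.null(cfg$scenario))
    stop("config must provide 'input' or 'scenario'")
  if (!is.null(cfg$input) && !file.exists(cfg$input))
    stop("input file not found: ", cfg$input)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  B <- if (is.null(cfg$B)) 1000L else as.integer(cfg$B)
  smoothing <- if (is.null(cfg$smoothing)) 0.01 else cfg$smoothing
  if (is.character(smoothing) && smoothing != "1/N")
    smoothing <- as.numeric(smoothing)
  summary_method <- if (is.null(cfg$summary)) "percentile_median"
                    else cfg$summary
  manifest <- list(config = cfg, started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   version = as.character(utils::packageVersion("bnrisk")),
                   stages = list(), outputs = list(), warnings = character(0))
  timing <- function(expr) {
    t0 <- proc.time()[["elapsed"]]
    v <- expr
    list(value = v, seconds = round(proc.time()[["elapsed"]] - t0, 3))
  }
  # --- simulate / load -------------------------------------------------
  if ("simulate" %in% stages && !is.null(cfg$scenario)) {
    st <- timing({
      gtn <- pcgc_scenario()
      sc <- cfg$scenario
      cmx <- sample_cohort(gtn, as.integer(sc$n),
                           seed = if (is.null(sc$seed)) seed else
                             as.integer(sc$seed))
      if (!is.null(sc$missing_rate) && sc$missing_rate > 0)
        cmx <- inject_missingness(cmx, sc$missing_rate, seed = seed + 1L)
      cmx
    })
    cm <- st$value
    p <- file.path(cfg$outdir, "cohort.tsv")
    write_cohort_matrix(cm, p)
    manifest$outputs$cohort <- p
    manifest$stages$simulate <- list(seconds = st$seconds,
                                     patients = nrow(cm$x),
                                     variables = ncol(cm$x))
  } else {
    cm <- read_cohort_matrix(cfg$input)
    manifest$stages$load <- list(patients = nrow(cm$x),
                                 variables = ncol(cm$x))
  }
  # --- impute ----------------------------------------------------------
  if ("impute" %in% stages && anyNA(cm$x)) {
    k <- if (is.null(cfg$impute_k)) 10L else as.integer(cfg$impute_k)
    st <- timing(knn_impute(cm, k = k))
    cm <- st$value
    manifest$stages$impute <- list(seconds = st$seconds, k = k)
  }
  if (anyNA(cm$x))
    stop("cohort still contains missing values; enable the impute stage")
  # --- collinearity screen --------------------------------------------
  if ("screen" %in% stages) {
    thr <- if (is.null(cfg$collinearity_threshold)) 0.7
           else cfg$collinearity_threshold
    st <- timing(collinearity_screen(cm, threshold = thr))
    p <- file.path(cfg$outdir, "correlation.tsv")
    utils::write.table(st$value$pairs, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    manifest$outputs$correlation <- p
    manifest$stages$screen <- list(seconds = st$seconds,
                                   flagged = nrow(st$value$flagged))
    if (nrow(st$value$flagged))
      manifest$warnings <- c(manifest$warnings, sprintf(
        "collinear pair flagged: %s-%s (phi = %.3f)",
        st$value$flagged$var1, st$value$flagged$var2,
        st$value$flagged$phi))
  }
  # --- learn one network per configured variable subset ----------------
  networks <- if (is.null(cfg$networks))
    list(full = colnames(cm$x))
  else lapply(cfg$networks, unlist)
  fits <- list()
  if ("learn" %in% stages) {
    st <- timing({
      for (nm in names(networks)) {
        sub <- subset_variables(cm, networks[[nm]])
        fits[[nm]] <- bn_fit(sub, smoothing = smoothing)
        pj <- file.path(cfg$outdir, sprintf("network-%s.json", nm))
        pd <- file.path(cfg$outdir, sprintf("network-%s.dot", nm))
        write_network(fits[[nm]], pj)
        export_network(fits[[nm]], pd, format = "dot", moralized = TRUE)
        manifest$outputs[[paste0("network_", nm)]] <- pj
      }
      fits
    })
    fits <- st$value
    manifest$stages$learn <- list(seconds = st$seconds,
                                  networks = length(fits))
  }
  # --- bootstrap risk estimates ---------------------------------------
  estimates <- list()
  if ("bootstrap" %in% stages && length(cfg$queries)) {
    st <- timing({
      for (i in seq_along(cfg$queries)) {
        qc <- cfg$queries[[i]]
        q <- if (qc$kind == "absolute")
          risk_query("absolute", target = qc$target,
                     condition = qc$condition)
        else risk_query("relative",
                        targets = setNames(as.integer(unlist(qc$targets)),
                                           names(qc$targets)),
                        factor = qc$factor)
        netname <- if (is.null(qc$network)) names(networks)[1] else qc$network
        vars <- networks[[netname]]
        if (is.null(vars)) stop("query references unknown network: ", netname)
        estimates[[i]] <- bootstrap_risk(
          cm, variables = vars, query = q, B = B, seed = seed + 100L + i,
          summary = summary_method, smoothing = smoothing,
          keep_replicates = FALSE)
      }
      estimates
    })
    estimates <- st$value
    nund <- sum(vapply(estimates, `[[`, integer(1), "n_undefined"))
    manifest$stages$bootstrap <- list(seconds = st$seconds, B = B,
                                      queries = length(estimates),
                                      undefined_replicates = nund)
  }
  # --- report ----------------------------------------------------------
  if ("report" %in% stages) {
    p <- file.path(cfg$outdir, "risk_report.tsv")
    write_risk_report(estimates, p)
    manifest$outputs$risk_report <- p
    manifest$stages$report <- list(rows = length(estimates))
  }
  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  manifest$config_hash <- .config_hash(cfg)
  mp <- file.path(cfg$outdir, "manifest.json")
  tmp <- paste0(mp, ".tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", force = TRUE)
  file.rename(tmp, mp)  # atomic manifest write
  invisible(manifest)
}

.load_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("YAML configs require the yaml package; use JSON instead")
      yaml::read_yaml(config)
    } else jsonlite::read_json(config, simplifyVector = FALSE)
  } else if (is.list(config)) config
  else stop("config must be a list or a file path")
}

.config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}
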