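#' Serialize a network to JSON
#'
#' Writes the full model — structure, CPT rows, sample size, smoothing
#' policy, variable roles and any calibration anchors — so that
#' [read_network()] reproduces the `bnet` exactly.
#'
#' @param fn a `bnet`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_network <- function(fn, path) {
  stopifnot(inherits(fn, "bnet"))
  obj <- list(nodes = fn$dag$nodes,
              parents = fn$dag$parents,
              cpts = lapply(fn$cpts, `[[`, "p1"),
              N = fn$N,
              smoothing = fn$smoothing)
  if (!is.null(attr(fn, "roles"))) obj$roles <- as.list(attr(fn, "roles"))
  if (!is.null(attr(fn, "anchors"))) obj$anchors <- attr(fn, "anchors")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}

#' Read a JSON-serialized network
#' @param path file written by [write_network()] (or a scenario preset in
#'   the same schema).
#' @return a `bnet`.
#' @export
read_network <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  nodes <- obj$nodes
  parents <- lapply(obj$parents, function(p) as.character(unlist(p)))
  dag <- bn_dag(nodes, parents)
  cpts <- lapply(obj$cpts, function(p) as.numeric(unlist(p)))
  roles <- if (!is.null(obj$roles)) unlist(obj$roles) else NULL
  fn <- bn_network(dag, cpts[nodes], roles = roles)
  n_stored <- suppressWarnings(as.integer(obj$N[1]))
  if (length(n_stored) && !is.na(n_stored)) fn$N <- n_stored
  if (!is.null(obj$smoothing))
    fn$smoothing <- list(policy = obj$smoothing$policy,
                         value = as.numeric(obj$smoothing$value))
  if (!is.null(obj$anchors)) attr(fn, "anchors") <- obj$anchors
  fn
}

#' Export a network for display or downstream tools
#'
#' `"json"` always carries the full CPTs ([write_network()]).  `"dot"` and
#' `"graphml"` encode the graph only: directed edges, or the moralized
#' undirected display graph when `moralized = TRUE`.
#'
#' @param fn a `bnet`.
#' @param path output file.
#' @param format `"json"`, `"dot"` or `"graphml"`.
#' @param moralized export the moralized undirected graph (ignored for
#'   JSON).
#' @return `path`, invisibly.
#' @export
export_network <- function(fn, path, format = c("json", "dot", "graphml"),
                           moralized = FALSE) {
  format <- tryCatch(match.arg(format),
                     error = function(e) stop("unknown format: ",
                                              format[1]))
  stopifnot(inherits(fn, "bnet"))
  if (format == "json") return(write_network(fn, path))
  if (moralized) {
    g <- moralize(fn$dag)
    edges <- g$edges
    nodes <- g$nodes
    directed <- FALSE
  } else {
    edges <- dag_edges(fn$dag)
    nodes <- fn$dag$nodes
    directed <- TRUE
  }
  if (format == "dot") {
    con <- c(sprintf("%s {", if (directed) "digraph G" else "graph G"),
             sprintf('  "%s";', nodes),
             sprintf('  "%s" %s "%s";', edges[, 1],
                     if (directed) "->" else "--", edges[, 2]),
             "}")
    writeLines(con, path)
  } else {
    lines <- c('<?xml version="1.0" encoding="UTF-8"?>',
               '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
               sprintf('  <graph id="G" edgedefault="%s">',
                       if (directed) "directed" else "undirected"),
               sprintf('    <node id="%s"/>', nodes),
               if (nrow(edges))
                 sprintf('    <edge source="%s" target="%s"/>',
                         edges[, 1], edges[, 2]),
               "  </graph>", "</graphml>")
    writeLines(lines, path)
  }
  invisible(path)
}

#' Write / read a risk report
#'
#' Tab-separated report, one row per estimate, deterministic row order
#' (lexicographic in the query label).  Columns: `kind`, `targets`,
#' `factor`, `point`, `ci_low`, `ci_high`, `summary_method`, `B`,
#' `n_undefined_replicates`, `seed`.
#'
#' @param estimates list of `risk_estimate` objects (see
#'   [bootstrap_risk()]); may be empty.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_risk_report <- function(estimates, path) {
  rows <- lapply(estimates, function(e) {
    q <- e$query
    data.frame(kind = q$kind,
               targets = if (q$kind == "absolute")
                 sprintf("%s=1", q$target)
               else paste(sprintf("%s=%d", names(q$targets), q$targets),
                          collapse = ","),
               factor = if (q$kind == "absolute") q$condition else q$factor,
               point = e$point, ci_low = e$ci_low, ci_high = e$ci_high,
               summary_method = e$summary_method, B = e$B,
               n_undefined_replicates = e$n_undefined, seed = e$seed,
               stringsAsFactors = FALSE)
  })
  df <- if (length(rows)) do.call(rbind, rows)
        else data.frame(kind = character(0), targets = character(0),
                        factor = character(0), point = numeric(0),
                        ci_low = numeric(0), ci_high = numeric(0),
                        summary_method = character(0), B = integer(0),
                        n_undefined_replicates = integer(0),
                        seed = integer(0))
  if (nrow(df))
    df <- df[order(df$kind, df$targets, df$factor, method = "radix"), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_risk_report
#' @export
read_risk_report <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
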