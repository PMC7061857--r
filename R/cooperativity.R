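#' Build an adjacency-context dataset from a measurement table
#'
#' Aggregates per-point absorbances to one mean per sample unit (genotype x
#' replicate), cell type and adjacency context, the working unit of the
#' cell-to-cell cooperativity model.
#'
#' @param table MeasurementTable data.frame with columns `genotype`,
#'   `replicate`, `cell_type`, `adjacent_to`, `absorbance`.
#' @param pairs data.frame with columns `source`, `target`: directed type
#'   pairs under test. Default: all ordered pairs present in the table.
#' @return list of class `adjacency_dataset`: `means` (data.frame `unit`,
#'   `genotype`, `cell_type`, `context`, `mean_dA`), `pairs`, `units`.
#' @export
build_adjacency_dataset <- function(table, pairs = NULL) {
  need <- c("genotype", "replicate", "cell_type", "adjacent_to", "absorbance")
  if (!all(need %in% names(table))) stopf("table lacks column(s): %s",
                                          paste(setdiff(need, names(table)), collapse = ", "))
  types <- unique(table$cell_type)
  if (is.null(pairs)) {
    pairs <- expand.grid(source = types, target = types, stringsAsFactors = FALSE)
    pairs <- pairs[pairs$source != pairs$target, ]
  }
  has_ctx <- vapply(seq_len(nrow(pairs)), function(i)
    any(table$cell_type == pairs$target[i] & table$adjacent_to == pairs$source[i]), TRUE)
  if (any(!has_ctx)) {
    absent <- paste(pairs$source[!has_ctx], pairs$target[!has_ctx], sep = "->")
    if (all(!has_ctx)) stopf("no requested pair has adjacent measurements: %s",
                             paste(absent, collapse = ", "))
    warning("pair(s) with no shared wall in any sample excluded: ",
            paste(absent, collapse = ", "))
    pairs <- pairs[has_ctx, , drop = FALSE]
  }
  unit <- interaction(table$genotype, table$replicate, drop = TRUE, sep = ":")
  agg <- stats::aggregate(absorbance ~ genotype + replicate + cell_type + adjacent_to,
                          data = table, FUN = mean)
  names(agg)[names(agg) == "absorbance"] <- "mean_dA"
  agg$unit <- paste(agg$genotype, agg$replicate, sep = ":")
  structure(list(means = agg, pairs = pairs, units = levels(unit)),
            class = "adjacency_dataset")
}

.context_series <- function(ds, type, context, units) {
  m <- ds$means
  sel <- m$cell_type == type & m$adjacent_to == context
  setNames(m$mean_dA[sel], m$unit[sel])[units]
}

#' Adjacency-conditioned correlation difference for one directed pair
#'
#' For source B and target A, computes across sample units the Pearson
#' correlation of A's adjacent-to-B means with B's own means (`r_adj`), the
#' correlation of A's adjacent-to-self means with the same B series
#' (`r_self`), and their difference `delta_r = r_adj - r_self`. A positive
#' `delta_r` means A's walls look more like B where they touch B.
#'
#' @param ds an [build_adjacency_dataset()] result.
#' @param source,target cell type labels (B and A).
#' @param b_context context used for B's own series (default `"self"`).
#' @return list of class `cooperativity_edge`: `source`, `target`, `r_adj`,
#'   `r_self`, `delta_r`, `r_between` (correlation of the two A series),
#'   `n`, `undefined` flag; `t`/`p` slots are filled by [williams_test()].
#' @export
delta_r <- function(ds, source, target, b_context = "self") {
  units <- ds$units
  a_adj <- .context_series(ds, target, source, units)
  a_self <- .context_series(ds, target, "self", units)
  b <- .context_series(ds, source, b_context, units)
  keep <- is.finite(a_adj) & is.finite(a_self) & is.finite(b)
  n <- sum(keep)
  if (n < 4) stopf("pair %s->%s: only %d complete sample units (need >= 4)",
                   source, target, n)
  a_adj <- a_adj[keep]; a_self <- a_self[keep]; b <- b[keep]
  undef <- sd(a_adj) == 0 || sd(a_self) == 0 || sd(b) == 0
  edge <- list(source = source, target = target, n = n,
               r_adj = if (undef) NA_real_ else cor(a_adj, b),
               r_self = if (undef) NA_real_ else cor(a_self, b),
               r_between = if (undef) NA_real_ else cor(a_adj, a_self),
               undefined = undef, t = NA_real_, p = NA_real_)
  edge$delta_r <- edge$r_adj - edge$r_self
  class(edge) <- "cooperativity_edge"
  edge
}

#' Williams' test for two dependent correlations sharing one variable
#'
#' Tests whether \code{r_adj = cor(X1, Z)} differs from
#' \code{r_self = cor(X2, Z)} when both correlations share the variable Z,
#' with \code{r_between = cor(X1, X2)}. The statistic follows a t
#' distribution with n - 3 degrees of freedom (Williams 1959; Steiger 1980).
#'
#' @param r_adj,r_self the two dependent correlations.
#' @param r_between correlation between the two non-shared series.
#' @param n number of sample units (>= 4).
#' @return list: `t`, `df`, `p` (two-sided).
#' @export
williams_test <- function(r_adj, r_self, r_between, n) {
  if (n < 4) stopf("Williams' test needs n >= 4")
  rs <- c(r_adj, r_self, r_between)
  if (any(!is.finite(rs)) || any(abs(rs) > 1)) stopf("correlations must be finite in [-1, 1]")
  if (any(abs(c(r_adj, r_self)) >= 1 - 1e-12))
    stopf("|r| = 1 input: correlation matrix is degenerate")
  detR <- 1 - r_adj^2 - r_self^2 - r_between^2 + 2 * r_adj * r_self * r_between
  rbar <- (r_adj + r_self) / 2
  denom <- 2 * detR * (n - 1) / (n - 3) + rbar^2 * (1 - r_between)^3
  if (denom <= 0) stopf("degenerate determinant in Williams' test")
  t <- (r_adj - r_self) * sqrt((n - 1) * (1 + r_between) / denom)
  p <- 2 * pt(-abs(t), df = n - 3)
  list(t = t, df = n - 3, p = p)
}

#' Attach Williams-test significance to a cooperativity edge
#'
#' @param edge a [delta_r()] edge.
#' @return the edge with `t` and `p` filled in.
#' @export
test_edge <- function(edge) {
  if (edge$undefined) return(edge)
  wt <- williams_test(edge$r_adj, edge$r_self, edge$r_between, edge$n)
  edge$t <- wt$t; edge$p <- wt$p
  edge
}

#' Relative impact (fold change) of a neighbour on a cell type
#'
#' Per genotype, the ratio of the target type's mean absorbance when
#' adjacent to the source type over its mean absorbance when adjacent to
#' itself, averaged across genotypes.
#'
#' @inheritParams delta_r
#' @return numeric fold change (> 0).
#' @export
relative_impact <- function(ds, source, target) {
  m <- ds$means
  gts <- unique(m$genotype)
  ratios <- vapply(gts, function(g) {
    num <- mean(m$mean_dA[m$genotype == g & m$cell_type == target &
                            m$adjacent_to == source])
    den <- mean(m$mean_dA[m$genotype == g & m$cell_type == target &
                            m$adjacent_to == "self"])
    if (!is.finite(den) || den <= 0) stopf("non-positive adjacent-to-self mean for %s in genotype %s", target, g)
    num / den
  }, 0)
  mean(ratios[is.finite(ratios)])
}

#' Assemble tested edges into a directed cooperativity network
#'
#' Nodes are cell types; each directed edge carries `delta_r` (drawn as
#' circle area), a significance flag at `alpha` (solid vs dashed arrow) and
#' the relative impact fold change (arrow colour).
#'
#' @param edges list of tested `cooperativity_edge`s (with `p` filled).
#' @param impacts optional named numeric vector `"B->A"` of fold changes.
#' @param alpha significance level.
#' @return list of class `cooperativity_network`: `nodes`, `edges`
#'   (data.frame), `graph` (igraph object).
#' @export
build_network <- function(edges, impacts = NULL, alpha = 0.05) {
  if (!length(edges)) stopf("need at least one edge")
  ed <- do.call(rbind, lapply(edges, function(e) {
    key <- paste0(e$source, "->", e$target)
    data.frame(source = e$source, target = e$target,
               delta_r = e$delta_r, r_adj = e$r_adj, r_self = e$r_self,
               p = e$p, significant = is.finite(e$p) && e$p < alpha,
               impact = if (!is.null(impacts)) unname(impacts[key]) else NA_real_,
               undefined = e$undefined, n = e$n)
  }))
  nodes <- sort(unique(c(ed$source, ed$target)))
  g <- igraph::graph_from_data_frame(ed, directed = TRUE,
                                     vertices = data.frame(name = nodes))
  structure(list(nodes = nodes, edges = ed, graph = g, alpha = alpha),
            class = "cooperativity_network")
}

#' Serialise a cooperativity network to JSON and DOT
#'
#' @param net a [build_network()] result.
#' @param json_path,dot_path output files (NULL to skip either).
#' @return invisibly, the paths written.
#' @export
write_network <- function(net, json_path = NULL, dot_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(list(nodes = net$nodes, alpha = net$alpha,
                              edges = net$edges),
                         json_path, dataframe = "rows", digits = NA, auto_unbox = TRUE)
  }
  if (!is.null(dot_path)) igraph::write_graph(net$graph, dot_path, format = "dot")
  invisible(c(json = json_path, dot = dot_path))
}

#' Read a cooperativity network back from JSON
#'
#' @param json_path file written by [write_network()].
#' @return a `cooperativity_network`.
#' @export
read_network <- function(json_path) {
  j <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  ed <- j$edges
  g <- igraph::graph_from_data_frame(ed, directed = TRUE,
                                     vertices = data.frame(name = j$nodes))
  structure(list(nodes = j$nodes, edges = ed, graph = g, alpha = j$alpha),
            class = "cooperativity_network")
}

#' Full cooperativity analysis of a measurement table
#'
#' Convenience wrapper: builds the adjacency dataset, computes and tests
#' every requested directed edge, attaches relative impacts, and returns
#' the network.
#'
#' @inheritParams build_adjacency_dataset
#' @param alpha significance level.
#' @return a `cooperativity_network`.
#' @export
cooperativity_network <- function(table, pairs = NULL, alpha = 0.05) {
  ds <- build_adjacency_dataset(table, pairs)
  edges <- lapply(seq_len(nrow(ds$pairs)), function(i)
    test_edge(delta_r(ds, ds$pairs$source[i], ds$pairs$target[i])))
  imps <- vapply(seq_len(nrow(ds$pairs)), function(i)
    relative_impact(ds, ds$pairs$source[i], ds$pairs$target[i]), 0)
  names(imps) <- paste0(ds$pairs$source, "->", ds$pairs$target)
  build_network(edges, impacts = imps, alpha = alpha)
}
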