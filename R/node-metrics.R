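#' Nodal network metrics
#'
#' Weighted nodal metrics of a structural network. Strength is the sum of a
#' region's connection weights. Betweenness centrality is the fraction of
#' shortest paths between other region pairs passing through the region,
#' normalized by (R-1)(R-2)/2; shortest paths use the edge distance
#' 1/weight (a stronger connection is a shorter distance; a zero weight is
#' no edge), and ties are split fractionally among equally short paths.
#' Eigenvector centrality is the dominant eigenvector of the weight matrix,
#' oriented nonnegative with Euclidean norm 1. Average path length is, per
#' region, the mean shortest-path distance to all other reachable regions;
#' unreachable pairs are excluded, and a region with no reachable partner is
#' reported as `NA`.
#'
#' @param net A [weighted_network()].
#' @return A tibble with columns `region` and `value` (in network order).
#' @name node_metrics
NULL

net_graph <- function(net) {
  g <- igraph::graph_from_adjacency_matrix(net$weights, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::E(g)$distance <- 1 / igraph::E(g)$weight
  g
}

#' @rdname node_metrics
#' @export
node_strength <- function(net) {
  net <- validate_weighted_network(net)
  tibble(region = net$region_names, value = unname(rowSums(net$weights)))
}

#' @rdname node_metrics
#' @export
betweenness_centrality <- function(net) {
  net <- validate_weighted_network(net)
  r <- length(net$region_names)
  if (r < 3) abort("Betweenness centrality requires at least 3 regions.")
  g <- net_graph(net)
  bw <- igraph::betweenness(g, directed = FALSE, weights = igraph::E(g)$distance)
  tibble(region = net$region_names,
         value = unname(bw) / ((r - 1) * (r - 2) / 2))
}

#' @rdname node_metrics
#' @param tol Convergence tolerance for the power iteration.
#' @param max_iter Iteration budget before the computation errors out.
#' @export
eigenvector_centrality <- function(net, tol = 1e-10, max_iter = 10000L) {
  net <- validate_weighted_network(net)
  w <- net$weights
  g <- net_graph(net)
  comp <- igraph::components(g)
  if (comp$no > 1) {
    sizes <- paste(comp$csize, collapse = ", ")
    abort(paste0("Eigenvector centrality requires a connected network; ",
                 "found ", comp$no, " components of sizes ", sizes, "."))
  }
  r <- nrow(w)
  v <- rep(1 / sqrt(r), r)
  for (i in seq_len(max_iter)) {
    v_new <- as.numeric(w %*% v)
    nrm <- sqrt(sum(v_new^2))
    if (nrm == 0) abort("Power iteration collapsed to the zero vector.")
    v_new <- v_new / nrm
    if (max(abs(v_new - v)) < tol) {
      if (sum(v_new) < 0) v_new <- -v_new
      return(tibble(region = net$region_names, value = v_new))
    }
    v <- v_new
  }
  abort(paste0("Eigenvector centrality did not converge within ", max_iter,
               " iterations (tolerance ", tol, ")."))
}

#' @rdname node_metrics
#' @export
average_path_length <- function(net) {
  net <- validate_weighted_network(net)
  g <- net_graph(net)
  d <- igraph::distances(g, weights = igraph::E(g)$distance)
  diag(d) <- NA
  value <- apply(d, 1, function(row) {
    reachable <- row[is.finite(row)]
    if (length(reachable) == 0) NA_real_ else mean(reachable)
  })
  out <- tibble(region = net$region_names, value = unname(value))
  attr(out, "unreachable_policy") <-
    "unreachable pairs excluded from the mean; isolated regions reported as NA"
  out
}

metric_tags <- c(
  NodeBWCent = "betweenness_centrality",
  AvPathLength = "average_path_length",
  Strength = "node_strength",
  EigCent = "eigenvector_centrality"
)

#' Nodal metric table for one network
#'
#' Computes the selected nodal metrics for every region of one network.
#'
#' @param net A [weighted_network()].
#' @param metrics Character subset of `"NodeBWCent"`, `"AvPathLength"`,
#'   `"Strength"`, `"EigCent"`.
#' @return A tibble with a `region` column plus one column per metric tag.
#' @export
node_metric_table <- function(net, metrics = c("NodeBWCent", "AvPathLength")) {
  metrics <- match.arg(metrics, names(metric_tags), several.ok = TRUE)
  out <- tibble(region = validate_weighted_network(net)$region_names)
  for (m in metrics) {
    fn <- get(metric_tags[[m]], mode = "function")
    out[[m]] <- fn(net)$value
  }
  out
}

#' Flatten per-subject nodal metrics into a feature block
#'
#' Turns one nodal-metric table per subject into a subjects x features tibble
#' whose columns follow the `<MetricTag>__<region>` naming scheme
#' (e.g. `NodeBWCent__roi_007`), sorted by metric then region. All subjects
#' must share the same region set.
#'
#' @param tables Named list (by subject id) of tibbles from
#'   [node_metric_table()].
#' @param metrics Metric tags to include; defaults to the betweenness and
#'   average-path-length pair that the final brain models draw on.
#' @return Tibble with `subject_id` plus one column per metric-region pair.
#' @export
flatten_metrics <- function(tables, metrics = c("NodeBWCent", "AvPathLength")) {
  metrics <- match.arg(metrics, names(metric_tags), several.ok = TRUE)
  if (is.null(names(tables))) names(tables) <- sprintf("S%03d", seq_along(tables))
  regions <- tables[[1]]$region
  for (tb in tables) {
    if (!identical(tb$region, regions)) {
      abort("All subjects must share an identical region set (same names, same order).")
    }
    missing <- setdiff(metrics, names(tb))
    if (length(missing) > 0) {
      abort(paste0("Metric(s) not present in table: ", paste(missing, collapse = ", ")))
    }
  }
  metrics <- sort(metrics)
  rows <- purrr::imap(tables, function(tb, sid) {
    vals <- purrr::map(metrics, function(m) setNames(tb[[m]], paste0(m, "__", tb$region)))
    dplyr::bind_cols(tibble(subject_id = sid), as_tibble(as.list(unlist(vals))))
  })
  bind_rows(rows)
}

#' Connectome nodal features for a list of subjects
#'
#' Convenience wrapper: builds the volume-normalized weighted network for each
#' subject, computes the selected nodal metrics, and flattens them into a
#' single feature block.
#'
#' @param fibers Named list of [fiber_connectivity()] objects (names are
#'   subject ids).
#' @param metrics Metric tags, as in [flatten_metrics()].
#' @param volume_convention Passed to [build_weighted_network()].
#' @return Tibble with `subject_id` plus `<MetricTag>__<region>` columns.
#' @export
connectome_features <- function(fibers,
                                metrics = c("NodeBWCent", "AvPathLength"),
                                volume_convention = "sum") {
  tables <- purrr::map(fibers, function(fc) {
    node_metric_table(build_weighted_network(fc, volume_convention), metrics)
  })
  flatten_metrics(tables, metrics)
}
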