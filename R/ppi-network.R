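#' Load a STRING protein-links edge list
#'
#' Reads the STRING protein-links format (two node columns plus
#' `combined_score` on the 0-1000 integer scale), rescales scores to [0, 1],
#' drops edges below the confidence cutoff, and builds a simple undirected
#' graph (duplicate pairs collapsed keeping the maximum score, self-loops
#' removed).
#'
#' @param path whitespace- or tab-separated file with a header.
#' @param score_cut confidence cutoff on the 0-1 scale (default 0.4;
#'   an integer score of 400 is kept, 399 dropped).
#' @return undirected `igraph` with edge attribute `score`.
#' @export
load_string_edges <- function(path, score_cut = 0.4) {
  if (!file.exists(path)) stop_fd("edge file not found: ", path)
  lines <- readLines(path)
  if (!length(lines)) stop_fd("empty edge file: ", path)
  fields <- strsplit(trimws(lines), "[ \t]+")
  n_col <- length(fields[[1]])
  if (n_col < 3) stop_fd("malformed header: expected 3 columns (node, node, combined_score)")
  rows <- fields[-1]
  bad <- which(vapply(rows, length, integer(1)) != n_col)
  if (length(bad))
    stop_fd("malformed line ", bad[1] + 1L, " in ", path)
  p1 <- vapply(rows, `[[`, character(1), 1L)
  p2 <- vapply(rows, `[[`, character(1), 2L)
  sc <- suppressWarnings(as.numeric(vapply(rows, `[[`, character(1), 3L)))
  if (anyNA(sc))
    stop_fd("malformed line ", which(is.na(sc))[1] + 1L, ": non-numeric score")
  score <- sc / 1000
  keep <- score >= score_cut & p1 != p2
  df <- data.frame(from = p1[keep], to = p2[keep], score = score[keep])
  g <- igraph::graph_from_data_frame(df, directed = FALSE)
  g <- igraph::simplify(g, edge.attr.comb = list(score = "max"))
  g <- igraph::set_graph_attr(g, "score_cut", score_cut)
  g
}

#' Induce the FD-dysregulated network on a query gene set
#'
#' Restricts the loaded PPI graph to exactly the query set (signature genes
#' plus the driver): no additional interactors are added, and query genes
#' with no retained edge appear as isolated vertices so that "0-connectivity"
#' genes stay countable.
#'
#' @param graph `igraph` from [load_string_edges()].
#' @param nodes query gene ids (signature genes, usually including the
#'   driver).
#' @param driver driver gene id; when given it must exist in the graph's
#'   node universe.
#' @return induced `igraph` whose vertex set is exactly `nodes` (plus
#'   `driver` if given).
#' @export
induced_network <- function(graph, nodes, driver = NULL) {
  universe <- igraph::V(graph)$name
  if (!is.null(driver)) {
    if (!driver %in% universe)
      stop_fd("driver '", driver, "' absent from the PPI node universe")
    nodes <- union(nodes, driver)
  }
  present <- intersect(nodes, universe)
  sub <- igraph::induced_subgraph(graph, present)
  missing <- setdiff(nodes, present)
  if (length(missing)) sub <- igraph::add_vertices(sub, length(missing), name = missing)
  sub
}

#' Hub genes of a network
#'
#' Hubs are nodes with at least `min_degree` connections, ranked by degree
#' descending with lexicographic tie-break.
#'
#' @param graph `igraph`.
#' @param min_degree hub threshold (default 5).
#' @param categories optional named vector gene -> category (e.g. signature
#'   category or dysregulation direction) carried into the output.
#' @return data.frame: gene, degree, category.
#' @export
network_hubs <- function(graph, min_degree = 5, categories = NULL) {
  deg <- igraph::degree(graph)
  hub <- deg[deg >= min_degree]
  ord <- order(-hub, names(hub))
  out <- data.frame(gene = names(hub)[ord], degree = unname(hub[ord]),
                    stringsAsFactors = FALSE)
  out$category <- if (is.null(categories)) NA_character_ else
    unname(categories[out$gene])
  out
}

#' Shortest distances from the driver gene, with connectivity classes
#'
#' Unweighted BFS distances from the driver. Nodes with no edges at all are
#' "isolated" (the "0-connectivity" display class); nodes with edges but no
#' path to the driver are "unreachable". A distance histogram and percentage
#' summaries are attached.
#'
#' @param graph induced `igraph` (driver included).
#' @param driver driver gene id (default "Elp1").
#' @return `fd_netsummary`: `distances` (named numeric, NA for
#'   isolated/unreachable), `status` (named character:
#'   "driver"/"connected"/"isolated"/"unreachable"), `histogram` (counts per
#'   distance including a "0-connectivity" bin), `pct_connected_to_driver`.
#' @export
distances_from_driver <- function(graph, driver = "Elp1") {
  if (!driver %in% igraph::V(graph)$name)
    stop_fd("driver '", driver, "' not in the network")
  d <- drop(igraph::distances(graph, v = driver, mode = "all"))
  deg <- igraph::degree(graph)
  status <- ifelse(names(d) == driver, "driver",
            ifelse(deg[names(d)] == 0, "isolated",
            ifelse(is.infinite(d), "unreachable", "connected")))
  dist_num <- ifelse(status == "connected", d, NA_real_)
  names(dist_num) <- names(status) <- names(d)
  max_d <- if (any(status == "connected")) max(dist_num, na.rm = TRUE) else 0
  hist <- c("0-connectivity" = sum(status == "isolated"),
            stats::setNames(vapply(seq_len(max_d), function(k)
              sum(dist_num == k, na.rm = TRUE), numeric(1)),
              as.character(seq_len(max_d))),
            unreachable = sum(status == "unreachable"))
  n_other <- sum(names(d) != driver)
  structure(list(driver = driver,
                 distances = dist_num,
                 status = status,
                 histogram = hist,
                 pct_connected_to_driver =
                   if (n_other > 0) pct_report(sum(status == "connected"), n_other) else NA_real_),
            class = "fd_netsummary")
}

#' @export
print.fd_netsummary <- function(x, ...) {
  cat("Distances from", x$driver, "-", sum(x$status == "connected"),
      "connected (", x$pct_connected_to_driver, "% ),",
      sum(x$status == "isolated"), "isolated,",
      sum(x$status == "unreachable"), "unreachable\n")
  print(x$histogram)
  invisible(x)
}

#' Percentage of nodes within k steps of the driver
#'
#' @param netsum `fd_netsummary`.
#' @param k maximal distance.
#' @param denominator count to report against (default: all non-driver
#'   nodes).
#' @return percentage, 2 decimals.
#' @export
pct_within_k <- function(netsum, k, denominator = NULL) {
  n <- sum(netsum$distances <= k, na.rm = TRUE)
  d <- denominator %||% sum(netsum$status != "driver")
  pct_report(n, d)
}

#' Report a fraction as a percentage, two decimals, half-even rounding
#'
#' `pct_report(121, 251)` is 48.21, matching the convention used to print
#' network coverage fractions.
#'
#' @param numerator,denominator counts; denominator must be positive.
#' @return 100 * numerator / denominator rounded half-even to 2 decimals.
#' @export
pct_report <- function(numerator, denominator) {
  if (any(denominator <= 0)) stop_fd("denominator must be positive")
  round(100 * numerator / denominator, 2)
}
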