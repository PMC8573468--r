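# Network assembly from confidence-scored edge lists (STRING-style exports).

#' Build a clean gene network from an edge data.frame
#'
#' Enforces the gene-network invariants: undirected, no self-loops, each
#' unordered pair at most once (highest confidence score kept).
#'
#' @param edges data.frame with columns `gene1`, `gene2` and optionally
#'   `score` in \[0, 1\].
#' @param nodes Optional character vector of additional (possibly isolated)
#'   nodes to include.
#' @return A simple undirected igraph with vertex names and, when scores
#'   were given, an edge attribute `score`.
#' @export
gene_network <- function(edges, nodes = NULL) {
  stopifnot(is.data.frame(edges))
  if (!all(c("gene1", "gene2") %in% names(edges)))
    stop("'edges' needs columns gene1 and gene2", call. = FALSE)
  edges$gene1 <- as.character(edges$gene1)
  edges$gene2 <- as.character(edges$gene2)
  edges <- edges[edges$gene1 != edges$gene2, , drop = FALSE]
  vnames <- sort(unique(c(edges$gene1, edges$gene2, as.character(nodes))))
  has_score <- "score" %in% names(edges)
  df <- data.frame(from = edges$gene1, to = edges$gene2)
  if (has_score) df$score <- as.numeric(edges$score)
  g <- igraph::graph_from_data_frame(df, directed = FALSE,
                                     vertices = data.frame(name = vnames))
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE,
                   edge.attr.comb = list(score = "max", "ignore"))
}

#' Read a confidence-scored edge list and apply the score threshold
#'
#' Reads a STRING-style export: at least three tab- or space-delimited
#' columns (gene1, gene2, combined score). A header line is tolerated.
#' Scores on the 0-1000 integer scale are divided by 1000. Edges are kept
#' when `score >= score_threshold`; self-loops are dropped and duplicate
#' pairs (either orientation) collapsed keeping the maximum score.
#'
#' @param path Path to the edge-list file.
#' @param score_threshold Minimum combined score in \[0, 1\] for an edge to
#'   be retained. The default 0.4 is STRING's "medium confidence" cut.
#' @return A simple undirected igraph with edge attribute `score`.
#' @export
read_edge_list <- function(path, score_threshold = 0.4) {
  score_threshold <- check_number(score_threshold, "score_threshold", 0, 1)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0)
    stop("empty edge-list file: ", path, call. = FALSE)
  toks <- strsplit(trimws(lines), "[ \t]+")
  start <- 1L
  if (is.na(suppressWarnings(as.numeric(toks[[1]][3]))))
    start <- 2L  # header line
  if (start > length(toks)) {
    warning("no data rows in edge-list file", call. = FALSE)
    return(gene_network(data.frame(gene1 = character(0),
                                   gene2 = character(0),
                                   score = numeric(0))))
  }
  rows <- toks[start:length(toks)]
  nf <- lengths(rows)
  if (any(nf < 3))
    stop(sprintf("malformed edge-list row at line %d (need >= 3 fields)",
                 which(nf < 3)[1] + start - 1L), call. = FALSE)
  g1 <- vapply(rows, `[[`, character(1), 1L)
  g2 <- vapply(rows, `[[`, character(1), 2L)
  sc <- suppressWarnings(as.numeric(vapply(rows, `[[`, character(1), 3L)))
  if (anyNA(sc))
    stop(sprintf("malformed score at line %d",
                 which(is.na(sc))[1] + start - 1L), call. = FALSE)
  if (any(sc > 1)) sc <- sc / 1000  # STRING 0-1000 integer convention
  if (any(sc < 0 | sc > 1))
    stop("scores must be in [0, 1] (or 0-1000 integers)", call. = FALSE)
  keep <- sc >= score_threshold
  if (!any(keep))
    warning("no edges pass the score threshold; returning an empty network",
            call. = FALSE)
  gene_network(data.frame(gene1 = g1[keep], gene2 = g2[keep],
                          score = sc[keep], stringsAsFactors = FALSE))
}

#' Union of gene networks
#'
#' Node set is the union of node sets, edge set the union of edge sets;
#' duplicate edges keep the maximum score. Commutative, associative and
#' idempotent.
#'
#' @param ... igraph networks, or a single list of them.
#' @return A simple undirected igraph.
#' @export
graph_union <- function(...) {
  nets <- list(...)
  if (length(nets) == 1 && is.list(nets[[1]]) && !igraph::is_igraph(nets[[1]]))
    nets <- nets[[1]]
  if (length(nets) < 1) stop("need at least one network", call. = FALSE)
  stopifnot(all(vapply(nets, igraph::is_igraph, logical(1))))
  edge_dfs <- lapply(nets, function(g) {
    e <- igraph::as_data_frame(g, what = "edges")
    names(e)[1:2] <- c("gene1", "gene2")
    e
  })
  has_score <- vapply(edge_dfs, function(e) "score" %in% names(e), logical(1))
  if (any(has_score)) {
    edge_dfs <- lapply(edge_dfs, function(e) {
      if (!"score" %in% names(e)) e$score <- NA_real_
      e[, c("gene1", "gene2", "score")]
    })
  } else {
    edge_dfs <- lapply(edge_dfs, function(e) e[, c("gene1", "gene2")])
  }
  all_nodes <- unique(unlist(lapply(nets, function(g) igraph::V(g)$name)))
  gene_network(do.call(rbind, edge_dfs), nodes = all_nodes)
}

#' Largest connected component
#'
#' @param net An igraph network with at least one node. Ties in component
#'   size are broken by the lexicographically smallest member name.
#' @return The induced subgraph on the largest connected node set.
#' @export
largest_component <- function(net) {
  stopifnot(igraph::is_igraph(net))
  if (igraph::vcount(net) == 0)
    stop("empty network has no components", call. = FALSE)
  comp <- igraph::components(net)
  best <- which(comp$csize == max(comp$csize))
  if (length(best) > 1) {
    firsts <- vapply(best, function(b) {
      min(igraph::V(net)$name[comp$membership == b])
    }, character(1))
    best <- best[order(firsts)][1]
  }
  igraph::induced_subgraph(net, which(comp$membership == best))
}

#' Summary statistics of a gene network
#'
#' @param net An igraph network.
#' @param isolates Convention for the local clustering coefficient of
#'   nodes with degree < 2: counted as `"zero"` (default) or `"exclude"`d
#'   from the mean.
#' @return A list: `n_nodes`, `n_edges`, `clustering_coefficient`
#'   (mean local), `n_components`.
#' @export
network_summary <- function(net, isolates = c("zero", "exclude")) {
  isolates <- match.arg(isolates)
  cc <- igraph::transitivity(net, type = "local", isolates = "NaN")
  cc <- if (isolates == "zero") mean(ifelse(is.nan(cc), 0, cc))
        else mean(cc[!is.nan(cc)])
  list(n_nodes = igraph::vcount(net),
       n_edges = igraph::ecount(net),
       clustering_coefficient = if (igraph::vcount(net)) cc else NA_real_,
       n_components = igraph::count_components(net))
}
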