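#' Specification for a synthetic gene network with planted structure
#'
#' Three generators are available:
#' \describe{
#'   \item{`nested_blocks`}{a nested stochastic block model: `branching^levels`
#'     leaf blocks arranged in a balanced hierarchy. The probability of an
#'     edge between two nodes depends on the deepest level at which they
#'     share a block: `p_between[1]` for nodes in different top-level blocks,
#'     up to `p_between[levels]` for nodes sharing a level-`levels - 1` block,
#'     and `p_within_leaf` inside a leaf block. Optional planted "deep hubs"
#'     receive `ceiling(p_hub * block size)` extra edges into every block at
#'     every level, so they remain well connected inside every nested module;
#'     optional "decoy" clumps are high-degree star hubs with their own
#'     satellites, planted as separate components — as high-degree as a
#'     deep hub's neighborhood, but their module bottoms out at the first
#'     hierarchy level because a star is modularity-indivisible.}
#'   \item{`preferential_attachment`}{a Barabasi-Albert graph
#'     (`pa_m` edges per new node), giving a heavy-tailed degree
#'     distribution with exponent near -3.}
#'   \item{`hierarchical_cliques`}{the deterministic Ravasz-Barabasi
#'     hierarchical model: a seed clique of size `branching` replicated
#'     `levels - 1` times, peripheral nodes wired to the central hub.
#'     Its clustering coefficient scales as C(k) ~ 1/k. `n_nodes` is
#'     implied (`branching^levels`) and may be omitted.}
#' }
#'
#' @param kind One of `"nested_blocks"`, `"preferential_attachment"`,
#'   `"hierarchical_cliques"`.
#' @param n_nodes Number of backbone nodes (decoy satellites are extra).
#' @param levels Nesting depth (`nested_blocks`, `hierarchical_cliques`).
#' @param branching Children per block per level, or clique size for
#'   `hierarchical_cliques`.
#' @param p_within_leaf Edge probability inside a leaf block.
#' @param p_between Numeric vector of length `levels` (or a scalar,
#'   recycled), ordered from shallowest (different top-level blocks) to
#'   deepest shared block. Must all be `< p_within_leaf`.
#' @param n_planted_hubs Number of planted deep-hub genes.
#' @param p_hub Fraction of each block a hub is wired into (default 0.5).
#' @param n_decoys Number of decoy star clumps.
#' @param decoy_satellites Satellites per decoy clump (default 60).
#' @param pa_m Edges added per node for `preferential_attachment`.
#' @param seed Integer RNG seed.
#' @return An object of class `"synthetic_network_spec"`.
#' @seealso [generate_network()]
#' @export
synthetic_network_spec <- function(kind = c("nested_blocks",
                                            "preferential_attachment",
                                            "hierarchical_cliques"),
                                   n_nodes = NULL, levels = 2, branching = 2,
                                   p_within_leaf = 0.5, p_between = 0.05,
                                   n_planted_hubs = 0, p_hub = 0.5,
                                   n_decoys = 0, decoy_satellites = 60,
                                   pa_m = 2, seed = 1) {
  kind <- match.arg(kind)
  levels <- check_count(levels, "levels", min = 1L)
  branching <- check_count(branching, "branching", min = 2L)
  if (kind == "hierarchical_cliques") {
    implied <- branching^levels
    if (is.null(n_nodes)) n_nodes <- implied
    if (n_nodes != implied)
      stop(sprintf("'n_nodes' must equal branching^levels (= %d) for hierarchical_cliques",
                   implied), call. = FALSE)
  }
  if (is.null(n_nodes))
    stop("'n_nodes' is required", call. = FALSE)
  spec <- list(
    kind = kind,
    n_nodes = check_count(n_nodes, "n_nodes", min = 2L),
    levels = levels,
    branching = branching,
    p_within_leaf = check_number(p_within_leaf, "p_within_leaf", 0, 1),
    p_between = vapply(rep_len(as.numeric(p_between), levels),
                       check_number, numeric(1), field = "p_between",
                       min = 0, max = 1),
    n_planted_hubs = check_count(n_planted_hubs, "n_planted_hubs"),
    p_hub = check_number(p_hub, "p_hub", 0, 1),
    n_decoys = check_count(n_decoys, "n_decoys"),
    decoy_satellites = check_count(decoy_satellites, "decoy_satellites", 1L),
    pa_m = check_count(pa_m, "pa_m", min = 1L),
    seed = check_count(seed, "seed")
  )
  if (kind == "nested_blocks" &&
      spec$p_within_leaf <= max(spec$p_between))
    stop("'p_within_leaf' must exceed every 'p_between' (no detectable structure otherwise)",
         call. = FALSE)
  structure(spec, class = "synthetic_network_spec")
}

#' Generate a synthetic gene network with known ground truth
#'
#' @param spec A [synthetic_network_spec()].
#' @return A list with elements
#'   \describe{
#'     \item{net}{a simple undirected igraph with gene-symbol vertex names;}
#'     \item{truth}{a list: `blocks`, a data.frame of planted block labels
#'       (`gene`, one `level_<l>` column per level; `nested_blocks` only),
#'       `hubs`, the planted deep-hub names, and `decoys`, the decoy hub
#'       names.}
#'   }
#' @examples
#' out <- generate_network(synthetic_network_spec(
#'   "nested_blocks", n_nodes = 32, levels = 1, branching = 2,
#'   p_within_leaf = 1, p_between = 0, seed = 3))
#' igraph::count_components(out$net)
#' @export
generate_network <- function(spec) {
  if (!inherits(spec, "synthetic_network_spec"))
    stop("'spec' must be a synthetic_network_spec", call. = FALSE)
  switch(spec$kind,
         nested_blocks = gen_nested_blocks(spec),
         preferential_attachment = gen_pref_attachment(spec),
         hierarchical_cliques = gen_hierarchical_cliques(spec))
}

node_names <- function(n) sprintf("N%04d", seq_len(n))

# Simple undirected graph from a 2-column edge matrix of vertex names.
as_simple_graph <- function(edges, vnames) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges[, 1], to = edges[, 2]),
    directed = FALSE,
    vertices = data.frame(name = vnames))
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

gen_nested_blocks <- function(spec) {
  n <- spec$n_nodes
  L <- spec$levels
  b <- spec$branching
  n_leaf <- b^L
  if (n < n_leaf)
    stop("'n_nodes' must be at least branching^levels", call. = FALSE)
  vnames <- node_names(n)
  # contiguous balanced assignment of nodes to leaf blocks
  leaf <- as.integer(cut(seq_len(n), breaks = n_leaf, labels = FALSE))
  # block label at level l (1..L): which level-l block the leaf sits in
  labels <- vapply(seq_len(L), function(l) {
    as.integer((leaf - 1L) %/% (b^(L - l)) + 1L)
  }, integer(n))
  labels <- matrix(labels, nrow = n)

  # deepest shared level per pair: labels are nested, so it is the number
  # of levels at which the two nodes agree
  with_seed(spec$seed, {
    shared <- matrix(0L, n, n)
    for (l in seq_len(L)) {
      shared <- shared + outer(labels[, l], labels[, l], "==")
    }
    pvec <- c(spec$p_between, spec$p_within_leaf)  # index = shared depth + 1
    iu <- which(upper.tri(shared))
    prob <- pvec[shared[iu] + 1L]
    keep <- iu[runif(length(iu)) < prob]
    edges <- cbind(vnames[((keep - 1L) %% n) + 1L],
                   vnames[((keep - 1L) %/% n) + 1L])

    # planted deep hubs: one per leaf block (cycling), wired into every
    # block at every level
    hubs <- character(0)
    if (spec$n_planted_hubs > 0) {
      home_leaves <- ((seq_len(spec$n_planted_hubs) - 1L) %% n_leaf) + 1L
      hub_idx <- vapply(seq_len(spec$n_planted_hubs), function(i) {
        which(leaf == home_leaves[i])[i]
      }, integer(1))
      hubs <- vnames[hub_idx]
      for (h in hub_idx) {
        for (l in seq_len(L)) {
          for (blk in seq_len(b^l)) {
            members <- setdiff(which(labels[, l] == blk), h)
            k <- min(length(members),
                     ceiling(spec$p_hub * length(members)))
            if (k > 0) {
              tgt <- sample(members, k)
              edges <- rbind(edges, cbind(vnames[h], vnames[tgt]))
            }
          }
        }
      }
    }

    # decoy clumps: star hub + sparse satellites, anchored to one leaf block
    decoys <- character(0)
    if (spec$n_decoys > 0) {
      s <- spec$decoy_satellites
      extra <- spec$n_decoys * (s + 1L)
      dnames <- sprintf("D%04d", seq_len(extra))
      vnames_all <- c(vnames, dnames)
      for (d in seq_len(spec$n_decoys)) {
        base <- (d - 1L) * (s + 1L)
        hub <- dnames[base + 1L]
        sats <- dnames[base + 1L + seq_len(s)]
        decoys <- c(decoys, hub)
        # a pure star component: modularity-indivisible, so once the
        # forced component split isolates it the decoy branch is a leaf
        edges <- rbind(edges, cbind(hub, sats))
      }
      vnames <- vnames_all
    }

    blocks <- data.frame(gene = node_names(n), stringsAsFactors = FALSE)
    for (l in seq_len(L)) blocks[[paste0("level_", l)]] <- labels[, l]
    list(net = as_simple_graph(edges, vnames),
         truth = list(blocks = blocks, hubs = hubs, decoys = decoys))
  })
}

gen_pref_attachment <- function(spec) {
  g <- with_seed(spec$seed,
    igraph::sample_pa(spec$n_nodes, power = 1, m = spec$pa_m,
                      directed = FALSE))
  g <- igraph::simplify(g)
  igraph::V(g)$name <- node_names(spec$n_nodes)
  list(net = g,
       truth = list(blocks = NULL, hubs = character(0), decoys = character(0)))
}

# Deterministic Ravasz-Barabasi hierarchical-clique model. Seed clique of
# size b; at each iteration the current graph is replicated b - 1 times and
# the replicas' peripheral nodes are wired to the central hub.
gen_hierarchical_cliques <- function(spec) {
  b <- spec$branching
  edges <- which(upper.tri(matrix(0, b, b)), arr.ind = TRUE)  # K_b
  center <- 1L
  peripheral <- 2:b
  n_cur <- b
  if (spec$levels > 1) {
    for (step in 2:spec$levels) {
      new_edges <- edges
      new_periph <- integer(0)
      for (r in seq_len(b - 1L)) {
        off <- r * n_cur
        new_edges <- rbind(new_edges, edges + off)
        new_periph <- c(new_periph, peripheral + off)
      }
      new_edges <- rbind(new_edges, cbind(new_periph, center))
      edges <- new_edges
      peripheral <- new_periph
      n_cur <- n_cur * b
    }
  }
  vnames <- node_names(n_cur)
  g <- as_simple_graph(cbind(vnames[edges[, 1]], vnames[edges[, 2]]), vnames)
  list(net = g,
       truth = list(blocks = NULL, hubs = vnames[center],
                    decoys = character(0)))
}
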