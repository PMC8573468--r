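# Recursive leading-eigenvector module hierarchy with per-level
# modularity and Constant-Potts-Model Hamiltonian energy.

#' Resolution and stopping parameters for the module hierarchy
#'
#' @param gamma Constant-Potts-Model resolution (> 0): the internal edge
#'   density a community must exceed to lower the Hamiltonian. Default 0.5.
#' @param min_module_size Motif-level floor (>= 3): modules at or below
#'   this size are leaves. A triangle is the smallest motif, hence the
#'   default 3.
#' @param max_depth Optional cap on tree depth (default `Inf`).
#' @return An object of class `"resolution_params"`.
#' @export
resolution_params <- function(gamma = 0.5, min_module_size = 3,
                              max_depth = Inf) {
  if (!is.numeric(gamma) || length(gamma) != 1 || !is.finite(gamma) ||
      gamma <= 0)
    stop("'gamma' must be a single number > 0", call. = FALSE)
  min_module_size <- check_count(min_module_size, "min_module_size", min = 3L)
  if (!(is.numeric(max_depth) && length(max_depth) == 1 &&
        (is.infinite(max_depth) || (max_depth >= 0 && max_depth == round(max_depth)))))
    stop("'max_depth' must be a non-negative integer or Inf", call. = FALSE)
  structure(list(gamma = as.numeric(gamma),
                 min_module_size = min_module_size,
                 max_depth = max_depth),
            class = "resolution_params")
}

# Validate and normalize a membership vector against a network: named by
# vertex, one community label per vertex.
check_membership <- function(net, membership) {
  vn <- igraph::V(net)$name
  if (is.null(names(membership))) {
    if (length(membership) != length(vn))
      stop("unnamed 'membership' must have one entry per vertex", call. = FALSE)
    names(membership) <- vn
  }
  missing <- setdiff(vn, names(membership))
  if (length(missing) > 0)
    stop(sprintf("node '%s' is missing from the partition", missing[1]),
         call. = FALSE)
  setNames(as.character(membership[vn]), vn)
}

#' Newman-Girvan modularity of a partition
#'
#' Q = sum over communities c of \[ m_c / m - (d_c / 2m)^2 \], where m is
#' the total edge count, m_c the number of intra-community edges and d_c
#' the total degree of community c.
#'
#' @param net An igraph network.
#' @param membership Community labels, named by vertex (or in vertex
#'   order). Every vertex must be covered exactly once.
#' @return Modularity Q (0 for a single community; 0 for a graph with no
#'   edges).
#' @export
modularity_q <- function(net, membership) {
  mem <- check_membership(net, membership)
  m <- igraph::ecount(net)
  if (m == 0) return(0)
  comms <- unique(mem)
  deg <- igraph::degree(net)
  names(deg) <- igraph::V(net)$name
  ends <- igraph::as_edgelist(net, names = TRUE)
  intra <- mem[ends[, 1]] == mem[ends[, 2]]
  m_c <- table(factor(mem[ends[, 1]][intra], levels = comms))
  d_c <- tapply(deg, factor(mem, levels = comms), sum)
  sum(as.numeric(m_c) / m - (as.numeric(d_c) / (2 * m))^2)
}

#' Constant-Potts-Model Hamiltonian energy of a partition
#'
#' H = - sum over communities c of \[ m_c - gamma * n_c (n_c - 1) / 2 \]:
#' each community's intra-edge count is weighed against its
#' gamma-discounted internal pair count. Lower (more negative) H means
#' tighter modules; the all-singletons partition has H = 0.
#'
#' @inheritParams modularity_q
#' @param gamma Resolution parameter (> 0).
#' @return The Hamiltonian energy.
#' @export
hamiltonian_cpm <- function(net, membership, gamma = 0.5) {
  mem <- check_membership(net, membership)
  if (!is.numeric(gamma) || gamma <= 0)
    stop("'gamma' must be > 0", call. = FALSE)
  ends <- igraph::as_edgelist(net, names = TRUE)
  intra <- sum(mem[ends[, 1]] == mem[ends[, 2]])
  n_c <- table(mem)
  -(intra - gamma * sum(n_c * (n_c - 1) / 2))
}

# Leading eigenpair of a group's generalized modularity matrix
# B^(g)_ij = A_ij - k_i k_j / 2m - delta_ij * sum_{l in g} B_il
# (for the full graph the diagonal correction vanishes).
leading_modularity_eigen <- function(A, deg, m, idx = NULL,
                                     dense_limit = 800) {
  n_all <- length(deg)
  if (is.null(idx)) idx <- seq_len(n_all)
  n <- length(idx)
  if (n <= dense_limit) {
    B <- as.matrix(A[idx, idx, drop = FALSE]) -
      outer(deg[idx], deg[idx]) / (2 * m)
    if (n < n_all) diag(B) <- diag(B) - rowSums(B)
    e <- eigen(B, symmetric = TRUE)
    list(value = e$values[1], vector = e$vectors[, 1], B = B)
  } else {
    Ag <- A[idx, idx, drop = FALSE]
    kg <- deg[idx]
    row_corr <- if (n < n_all) {
      as.numeric(Ag %*% rep(1, n)) - kg * sum(kg) / (2 * m)
    } else rep(0, n)
    matvec <- function(x) {
      as.numeric(Ag %*% x) - kg * sum(kg * x) / (2 * m) - row_corr * x
    }
    # Gershgorin-safe shift: |lambda| <= 2 * max degree + |corr|
    shift <- 2 * max(kg) + max(abs(row_corr)) + 1
    pl <- power_leading(matvec, n, shift = shift, tol = 1e-10)
    list(value = pl$value, vector = pl$vector, B = NULL, matvec = matvec)
  }
}

#' Leading-eigenvector community split
#'
#' Newman's spectral method on the modularity matrix
#' B = A - k k' / 2m: the subgraph is bipartitioned by the sign of the
#' leading eigenvector of B when the leading eigenvalue is positive and
#' the split increases modularity; otherwise the module is indivisible.
#' Eigenvector entries that are exactly zero are assigned to the positive
#' side (reported via a message).
#'
#' With `recursive = TRUE` the bipartition is re-applied within each part
#' using the generalized modularity matrix, yielding a flat multiway
#' partition (Newman's full algorithm).
#'
#' @param subgraph A connected igraph with at least 2 nodes.
#' @param recursive Recurse within parts to a flat multiway partition?
#' @param tol Positivity tolerance for the leading eigenvalue and the
#'   modularity gain.
#' @return A named membership vector (labels `"1"`, `"2"`, ...) or `NULL`
#'   when the subgraph is indivisible.
#' @examples
#' g <- igraph::make_full_graph(6)
#' igraph::V(g)$name <- letters[1:6]
#' lev_split(g)  # NULL: a clique has no community structure
#' @export
lev_split <- function(subgraph, recursive = FALSE, tol = 1e-10) {
  stopifnot(igraph::is_igraph(subgraph))
  n <- igraph::vcount(subgraph)
  if (n < 2) stop("need at least 2 nodes to split", call. = FALSE)
  if (!igraph::is_connected(subgraph))
    stop("disconnected subgraph: split into components first", call. = FALSE)
  A <- igraph::as_adjacency_matrix(subgraph, sparse = TRUE)
  deg <- igraph::degree(subgraph)
  m <- igraph::ecount(subgraph)
  if (m == 0) return(NULL)
  vn <- igraph::V(subgraph)$name

  if (!recursive) {
    split <- try_bipartition(A, deg, m, seq_len(n), n, tol)
    if (is.null(split)) return(NULL)
    mem <- integer(n)
    mem[split[[1]]] <- 1L
    mem[split[[2]]] <- 2L
    return(setNames(as.character(mem), vn))
  }
  groups <- list(seq_len(n))
  final <- list()
  while (length(groups) > 0) {
    idx <- groups[[1]]
    groups <- groups[-1]
    split <- try_bipartition(A, deg, m, idx, n, tol)
    if (is.null(split)) final <- c(final, list(idx))
    else groups <- c(groups, split)
  }
  if (length(final) < 2) return(NULL)
  mem <- integer(n)
  for (i in seq_along(final)) mem[final[[i]]] <- i
  setNames(as.character(mem), vn)
}

# One spectral bipartition attempt on group `idx`; returns list(part1, part2)
# index vectors or NULL if indivisible.
try_bipartition <- function(A, deg, m, idx, n_all, tol) {
  if (length(idx) < 2) return(NULL)
  le <- leading_modularity_eigen(A, deg, m,
                                 if (length(idx) == n_all) NULL else idx)
  if (le$value <= tol) return(NULL)
  v <- le$vector
  zeros <- sum(v == 0)
  if (zeros > 0)
    message(sprintf("%d zero eigenvector entr%s assigned to the positive side",
                    zeros, if (zeros == 1) "y" else "ies"))
  s <- ifelse(v >= 0, 1, -1)
  if (all(s == s[1])) return(NULL)
  # modularity gain: delta Q = s' B s / 4m
  dq <- if (!is.null(le$B)) {
    as.numeric(t(s) %*% le$B %*% s) / (4 * m)
  } else {
    sum(s * le$matvec(s)) / (4 * m)
  }
  if (dq <= tol) return(NULL)
  list(idx[s > 0], idx[s < 0])
}

#' Build the recursive module tree of a network
#'
#' Level 0 is the whole network. At each level, every module larger than
#' `min_module_size` is examined: a disconnected module is first split
#' into its connected components (a forced, modularity-neutral step);
#' a connected module is bipartitioned by [lev_split()]. Modules that are
#' indivisible, at or below `min_module_size`, or at `max_depth` become
#' leaves. For every split the modularity (`q_of_split`) and CPM
#' Hamiltonian (`he`) of the children partition are recorded on the
#' module's induced subgraph.
#'
#' @param net A non-empty igraph network.
#' @param params A [resolution_params()] object.
#' @return An object of class `"module_tree"`: list with `root` (nested
#'   module nodes: `id`, `level`, `members`, `q_of_split`, `he`,
#'   `children`), `depth`, `params` and `n_nodes`.
#' @examples
#' two <- generate_network(synthetic_network_spec(
#'   "nested_blocks", n_nodes = 8, levels = 1, branching = 2,
#'   p_within_leaf = 1, p_between = 0, seed = 1))
#' tree <- build_module_tree(two$net, resolution_params())
#' tree$depth
#' @export
build_module_tree <- function(net, params = resolution_params()) {
  stopifnot(igraph::is_igraph(net))
  if (!inherits(params, "resolution_params"))
    stop("'params' must be a resolution_params object", call. = FALSE)
  if (igraph::vcount(net) == 0) stop("empty network", call. = FALSE)

  build <- function(members, id, level) {
    node <- list(id = id, level = level, members = members,
                 q_of_split = NA_real_, he = NA_real_, children = list())
    if (length(members) <= params$min_module_size ||
        level >= params$max_depth)
      return(node)
    sub <- igraph::induced_subgraph(net, members)
    comp <- igraph::components(sub)
    if (comp$no > 1) {
      parts <- split(igraph::V(sub)$name, comp$membership)
    } else {
      mem <- lev_split(sub)
      if (is.null(mem)) return(node)
      parts <- split(names(mem), mem)
    }
    mem_vec <- setNames(rep(seq_along(parts), lengths(parts)),
                        unlist(parts))
    node$q_of_split <- modularity_q(sub, mem_vec)
    node$he <- hamiltonian_cpm(sub, mem_vec, params$gamma)
    node$children <- lapply(seq_along(parts), function(i) {
      build(parts[[i]], paste(id, i - 1L, sep = "."), level + 1L)
    })
    node
  }

  root <- build(igraph::V(net)$name, "0", 0L)
  depth <- tree_depth_node(root)
  structure(list(root = root, depth = depth, params = params,
                 n_nodes = igraph::vcount(net)),
            class = "module_tree")
}

tree_depth_node <- function(node) {
  if (length(node$children) == 0) return(node$level)
  max(vapply(node$children, tree_depth_node, integer(1)))
}

#' @export
print.module_tree <- function(x, ...) {
  cat(sprintf("module_tree: %d genes, depth %d, gamma = %g, min size %d\n",
              x$n_nodes, x$depth, x$params$gamma, x$params$min_module_size))
  lv <- level_summary(x)
  print(lv[, c("level", "n_modules")], row.names = FALSE)
  invisible(x)
}

#' Module membership at a given hierarchy level
#'
#' Modules that stopped splitting before `level` carry forward unchanged,
#' so every gene belongs to exactly one module at every level.
#'
#' @param tree A [build_module_tree()] result.
#' @param level Level (0 = whole network).
#' @return Named character vector: gene -> module id at that level.
#' @export
level_membership <- function(tree, level) {
  stopifnot(inherits(tree, "module_tree"), level >= 0)
  out <- character(0)
  walk <- function(node) {
    if (node$level >= level || length(node$children) == 0) {
      out[node$members] <<- node$id
    } else {
      for (ch in node$children) walk(ch)
    }
  }
  walk(tree$root)
  out
}

# Per-level module counts and split statistics.
level_summary <- function(tree) {
  rows <- lapply(0:tree$depth, function(l) {
    mem <- level_membership(tree, l)
    data.frame(level = l, n_modules = length(unique(mem)))
  })
  do.call(rbind, rows)
}

#' Per-level modularity and Hamiltonian energy profile
#'
#' For each level L of the tree, the whole-network partition into level-L
#' modules is scored by modularity (`q_level`) and by the CPM Hamiltonian
#' (`he_level`). `mean_q_split` and `mean_he_split` average `q_of_split` /
#' `he` over the modules split at that level (NA when none). In a
#' well-nested network |HE| and the split modularity decline from the top
#' level toward the motif level.
#'
#' @param tree A [build_module_tree()] result.
#' @param net The network the tree was built from.
#' @param params A [resolution_params()]; defaults to the tree's own.
#' @return data.frame with columns `level`, `n_modules`, `q_level`,
#'   `he_level`, `mean_q_split`, `mean_he_split`.
#' @export
level_energy_profile <- function(tree, net, params = tree$params) {
  stopifnot(inherits(tree, "module_tree"))
  splits_at <- function(node, l, what) {
    vals <- c()
    walk <- function(nd) {
      if (nd$level == l && length(nd$children) > 0)
        vals <<- c(vals, nd[[what]])
      for (ch in nd$children) walk(ch)
    }
    walk(node)
    vals
  }
  rows <- lapply(0:tree$depth, function(l) {
    mem <- level_membership(tree, l)
    qs <- splits_at(tree$root, l, "q_of_split")
    hs <- splits_at(tree$root, l, "he")
    data.frame(level = l,
               n_modules = length(unique(mem)),
               q_level = modularity_q(net, mem),
               he_level = hamiltonian_cpm(net, mem, params$gamma),
               mean_q_split = if (length(qs)) mean(qs) else NA_real_,
               mean_he_split = if (length(hs)) mean(hs) else NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
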