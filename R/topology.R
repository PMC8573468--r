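# Centralities and degree-indexed topology curves.

#' Node centralities
#'
#' Degree, closeness, betweenness and eigenvector centrality for every
#' node. Definitions:
#' \itemize{
#'   \item closeness(v) = (n_c - 1) / sum of distances from v within v's
#'     connected component of size n_c (0 for isolated nodes);
#'   \item betweenness(v) = sum over unordered pairs s != t (both != v) of
#'     the fraction of shortest s-t paths through v (Freeman, unnormalized,
#'     endpoints excluded);
#'   \item eigenvector = principal eigenvector of the adjacency matrix,
#'     computed per connected component, non-negative and scaled to unit
#'     Euclidean norm within each component.
#' }
#'
#' @param net A non-empty igraph network.
#' @return data.frame with columns `node`, `degree`, `closeness`,
#'   `betweenness`, `eigenvector`, one row per node in vertex order.
#' @examples
#' g <- igraph::make_star(6, mode = "undirected")
#' igraph::V(g)$name <- LETTERS[1:6]
#' centralities(g)
#' @export
centralities <- function(net) {
  stopifnot(igraph::is_igraph(net))
  n <- igraph::vcount(net)
  if (n == 0) stop("empty network", call. = FALSE)
  deg <- igraph::degree(net)
  btw <- igraph::betweenness(net, directed = FALSE, normalized = FALSE)
  clo <- numeric(n)
  eig <- numeric(n)
  comp <- igraph::components(net)
  for (ci in seq_len(comp$no)) {
    idx <- which(comp$membership == ci)
    nc <- length(idx)
    if (nc == 1) {
      clo[idx] <- 0
      eig[idx] <- 1
      next
    }
    sub <- igraph::induced_subgraph(net, idx)
    d <- igraph::distances(sub)
    clo[idx] <- (nc - 1) / rowSums(d)
    eig[idx] <- component_eigenvector(sub)
  }
  data.frame(node = igraph::V(net)$name, degree = as.numeric(deg),
             closeness = clo, betweenness = as.numeric(btw),
             eigenvector = eig, row.names = NULL, stringsAsFactors = FALSE)
}

# Principal adjacency eigenvector of a connected graph: exact dense solve
# for small components, shifted power iteration on the sparse adjacency
# for large ones. Returned non-negative with unit Euclidean norm.
component_eigenvector <- function(sub) {
  nc <- igraph::vcount(sub)
  if (nc <= 200) {
    A <- as.matrix(igraph::as_adjacency_matrix(sub, sparse = FALSE))
    v <- eigen(A, symmetric = TRUE)$vectors[, 1]
  } else {
    A <- igraph::as_adjacency_matrix(sub, sparse = TRUE)
    # shift 1 avoids oscillation on bipartite components
    v <- power_leading(function(x) as.numeric(A %*% x), nc, shift = 1,
                       tol = 1e-12)$vector
  }
  if (sum(v) < 0) v <- -v
  v <- pmax(v, 0)  # clip tiny negative round-off
  v / sqrt(sum(v^2))
}

#' Degree-indexed topology profile
#'
#' For each observed degree k: the degree-distribution mass P(k), mean
#' local clustering coefficient C(k), mean neighborhood connectivity CN(k)
#' (mean neighbor degree), mean betweenness CB(k) and mean closeness CC(k)
#' of the degree-k nodes. These are the curves whose power-law behaviour
#' signals a hierarchical scale-free network.
#'
#' @param net An igraph network.
#' @param cents Optional precomputed [centralities()] table for `net`.
#' @return data.frame with columns `k`, `p_k`, `c_k`, `cn_k`, `cb_k`,
#'   `cc_k`, one row per observed degree, ascending. `cn_k` is `NA` for
#'   k = 0 (no neighbors).
#' @export
topology_profile <- function(net, cents = NULL) {
  if (is.null(cents)) cents <- centralities(net)
  stopifnot(nrow(cents) == igraph::vcount(net))
  deg <- cents$degree
  cc_local <- igraph::transitivity(net, type = "local", isolates = "NaN")
  cc_local[is.nan(cc_local)] <- 0  # degree < 2: no closed pairs
  A <- igraph::as_adjacency_matrix(net, sparse = TRUE)
  nbr_deg <- as.numeric(A %*% deg) / deg  # NaN for isolated nodes
  ks <- sort(unique(deg))
  prof <- do.call(rbind, lapply(ks, function(k) {
    sel <- deg == k
    data.frame(k = k,
               p_k = mean(deg == k),
               c_k = mean(cc_local[sel]),
               cn_k = if (k == 0) NA_real_ else mean(nbr_deg[sel]),
               cb_k = mean(cents$betweenness[sel]),
               cc_k = mean(cents$closeness[sel]))
  }))
  rownames(prof) <- NULL
  prof
}

#' Log-log least-squares power-law fit of a degree-indexed curve
#'
#' Fits `log(value) ~ log(k)` by ordinary least squares over the degrees
#' with positive curve value (and k > 0). This is the straight-line fit
#' drawn through P(k), C(k), etc. on log-log axes; the slope is the
#' power-law exponent.
#'
#' @param k Degrees.
#' @param value Curve values at those degrees.
#' @return An object of class `"power_law_fit"`: list with `exponent`
#'   (slope), `intercept` (log scale), `r_squared`, and `k_range` (the
#'   degrees used).
#' @examples
#' k <- 1:20
#' fit_power_law(k, k^-2)  # exponent -2, r^2 = 1
#' @export
fit_power_law <- function(k, value) {
  stopifnot(length(k) == length(value))
  use <- is.finite(k) & is.finite(value) & k > 0 & value > 0
  if (sum(use) < 3)
    stop("insufficient points for a power-law fit (need >= 3 positive values)",
         call. = FALSE)
  x <- log(k[use]); y <- log(value[use])
  fit <- stats::lm.fit(cbind(1, x), y)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  structure(list(exponent = unname(fit$coefficients[2]),
                 intercept = unname(fit$coefficients[1]),
                 r_squared = r2,
                 k_range = range(k[use])),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("power-law fit: value ~ k^%.3f (r^2 = %.3f, k in [%g, %g])\n",
              x$exponent, x$r_squared, x$k_range[1], x$k_range[2]))
  invisible(x)
}
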