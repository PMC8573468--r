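two_cliques <- function(size, bridge = TRUE) {
  g <- igraph::disjoint_union(igraph::make_full_graph(size),
                              igraph::make_full_graph(size))
  if (bridge) g <- igraph::add_edges(g, c(1, size + 1))
  igraph::V(g)$name <- sprintf("v%02d", seq_len(2 * size))
  g
}

test_that("modularity matches closed forms", {
  k6 <- named_graph(igraph::make_full_graph(6))
  expect_equal(modularity_q(k6, setNames(rep(1, 6), igraph::V(k6)$name)), 0)
  g <- two_cliques(3, bridge = FALSE)
  mem <- setNames(rep(1:2, each = 3), igraph::V(g)$name)
  expect_equal(modularity_q(g, mem), 0.5)
  expect_error(modularity_q(g, mem[-1]), "v01")
})

test_that("modularity and CPM Hamiltonian match brute-force sums on random pairs", {
  for (seed in 1:30) {
    tg <- random_test_graph(sample(5:10, 1), runif(1, 0.2, 0.8), seed + 100)
    mem <- sample(1:3, igraph::vcount(tg$g), replace = TRUE)
    names(mem) <- tg$names
    gamma <- runif(1, 0.1, 1.5)
    expect_equal(modularity_q(tg$g, mem), bf_modularity(tg$A, mem),
                 tolerance = 1e-12)
    expect_equal(hamiltonian_cpm(tg$g, mem, gamma),
                 bf_cpm(tg$A, mem, gamma), tolerance = 1e-12)
  }
})

test_that("CPM Hamiltonian closed forms hold", {
  tri <- named_graph(igraph::make_full_graph(3))
  mem1 <- setNames(rep(1, 3), igraph::V(tri)$name)
  for (gamma in c(0.2, 0.5, 1)) {
    expect_equal(hamiltonian_cpm(tri, mem1, gamma), -(3 - 3 * gamma))
  }
  tg <- random_test_graph(8, 0.5, 1)
  singles <- setNames(seq_len(8), tg$names)
  expect_equal(hamiltonian_cpm(tg$g, singles, 0.7), 0)
})

test_that("modularity agrees with igraph's implementation", {
  for (seed in 1:10) {
    tg <- random_test_graph(9, 0.4, seed)
    mem <- sample(1:3, 9, replace = TRUE)
    names(mem) <- tg$names
    expect_equal(modularity_q(tg$g, mem),
                 igraph::modularity(tg$g, mem), tolerance = 1e-12)
  }
})

test_that("lev_split recovers two bridged cliques exactly and optimally", {
  g <- two_cliques(5)
  mem <- lev_split(g)
  truth <- rep(1:2, each = 5)
  expect_equal(ari(mem[igraph::V(g)$name], truth), 1)
  # brute force over all bipartitions: the clique split maximizes Q
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  best_q <- -Inf
  for (code in 1:(2^9 - 1)) {  # fix node 1's side to halve the search
    side <- c(1L, as.integer(intToBits(code)[1:9]))
    q <- bf_modularity(A, side)
    if (q > best_q) { best_q <- q; best_side <- side }
  }
  expect_equal(ari(best_side, truth), 1)
  expect_equal(modularity_q(g, mem), best_q, tolerance = 1e-12)
})

test_that("structureless graphs are indivisible", {
  expect_null(lev_split(named_graph(igraph::make_full_graph(6))))
  expect_error(lev_split(two_cliques(4, bridge = FALSE)), "disconnected")
})

test_that("a split never lowers modularity below the unsplit module", {
  for (seed in 1:20) {
    tg <- random_test_graph(12, runif(1, 0.15, 0.5), seed + 200)
    sub <- largest_component(tg$g)
    if (igraph::vcount(sub) < 3) next
    mem <- lev_split(sub)
    if (!is.null(mem)) expect_gt(modularity_q(sub, mem), 0)
  }
})

test_that("recursive lev_split yields a flat multiway partition of cliques", {
  g <- igraph::disjoint_union(igraph::make_full_graph(5),
                              igraph::make_full_graph(5),
                              igraph::make_full_graph(5))
  g <- igraph::add_edges(g, c(1, 6, 6, 11, 11, 1))
  igraph::V(g)$name <- sprintf("v%02d", 1:15)
  mem <- lev_split(g, recursive = TRUE)
  expect_equal(length(unique(mem)), 3)
  expect_equal(ari(mem[igraph::V(g)$name], rep(1:3, each = 5)), 1)
})

test_that("module tree handles disjoint cliques and indivisible roots", {
  g <- two_cliques(4, bridge = FALSE)
  tree <- build_module_tree(g)
  expect_equal(tree$depth, 1)
  expect_length(tree$root$children, 2)
  expect_true(all(vapply(tree$root$children,
                         function(ch) length(ch$children) == 0, logical(1))))
  k6 <- named_graph(igraph::make_full_graph(6))
  tk6 <- build_module_tree(k6)
  expect_equal(tk6$depth, 0)
  expect_length(tk6$root$children, 0)
})

test_that("tree partitions are proper (disjoint, covering) at every level", {
  out <- generate_network(synthetic_network_spec(
    "nested_blocks", n_nodes = 96, levels = 2, branching = 2,
    p_within_leaf = 0.6, p_between = c(0.01, 0.08), seed = 33))
  tree <- build_module_tree(out$net)
  all_nodes <- sort(igraph::V(out$net)$name)
  for (l in 0:tree$depth) {
    mem <- level_membership(tree, l)
    expect_equal(sort(names(mem)), all_nodes)
    expect_false(anyNA(mem))
  }
  # children partition their parent's members
  check_node <- function(node) {
    if (length(node$children) > 0) {
      kids <- unlist(lapply(node$children, `[[`, "members"))
      expect_setequal(kids, node$members)
      expect_equal(length(kids), length(node$members))
      for (ch in node$children) check_node(ch)
    }
  }
  check_node(tree$root)
})

test_that("min_module_size and max_depth stop the recursion", {
  out <- generate_network(synthetic_network_spec(
    "nested_blocks", n_nodes = 64, levels = 2, branching = 2,
    p_within_leaf = 0.7, p_between = c(0.01, 0.05), seed = 4))
  capped <- build_module_tree(out$net, resolution_params(max_depth = 1))
  expect_lte(capped$depth, 1)
  big_floor <- build_module_tree(out$net,
                                 resolution_params(min_module_size = 64))
  expect_equal(big_floor$depth, 0)
  expect_error(resolution_params(min_module_size = 2), "min_module_size")
  expect_error(resolution_params(gamma = 0), "gamma")
})

test_that("level profile starts at Q = 0 and records split statistics", {
  out <- generate_network(synthetic_network_spec(
    "nested_blocks", n_nodes = 64, levels = 1, branching = 2,
    p_within_leaf = 0.6, p_between = 0.02, seed = 5))
  tree <- build_module_tree(out$net, resolution_params(max_depth = 1))
  prof <- level_energy_profile(tree, out$net)
  expect_equal(prof$q_level[1], 0)
  expect_equal(prof$n_modules, c(1, 2))
  expect_equal(prof$q_level[2], tree$root$q_of_split)
  # singleton partition endpoint: HE = 0
  vn <- igraph::V(out$net)$name
  expect_equal(hamiltonian_cpm(out$net, setNames(seq_along(vn), vn), 0.5), 0)
})

test_that("module trees survive a JSON round trip", {
  out <- generate_network(synthetic_network_spec(
    "nested_blocks", n_nodes = 32, levels = 1, branching = 2,
    p_within_leaf = 0.8, p_between = 0.02, seed = 6))
  tree <- build_module_tree(out$net)
  path <- withr::local_tempfile(fileext = ".json")
  write_module_tree_json(tree, path)
  back <- read_module_tree_json(path)
  expect_equal(back$depth, tree$depth)
  expect_equal(level_membership(back, 1), level_membership(tree, 1))
  expect_equal(back$root$q_of_split, tree$root$q_of_split)
})
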