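write_edges <- function(rows, header = TRUE) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  lines <- vapply(rows, paste, character(1), collapse = "\t")
  if (header) lines <- c("protein1\tprotein2\tcombined_score", lines)
  writeLines(lines, path)
  path
}

test_that("duplicate orientations and self-loops collapse to one clean edge", {
  path <- write_edges(list(c("A", "B", "0.9"), c("B", "A", "0.7"),
                           c("A", "A", "0.8")))
  net <- read_edge_list(path, score_threshold = 0.4)
  expect_equal(igraph::ecount(net), 1)
  expect_false(igraph::any_loop(net))
  expect_equal(igraph::E(net)$score, 0.9)  # max kept
})

test_that("the score threshold filters edges; 0-1000 scores are rescaled", {
  path <- write_edges(list(c("A", "B", "0.30")))
  expect_warning(net <- read_edge_list(path, 0.4), "no edges")
  expect_equal(igraph::ecount(net), 0)
  string_style <- write_edges(list(c("A", "B", "900"), c("B", "C", "150")))
  net2 <- read_edge_list(string_style, 0.4)
  expect_equal(igraph::ecount(net2), 1)
  expect_equal(igraph::E(net2)$score, 0.9)
})

test_that("malformed rows are reported with their line number", {
  path <- write_edges(list(c("A", "B", "0.9"), c("C", "D")))
  expect_error(read_edge_list(path), "line 3")
  bad_score <- write_edges(list(c("A", "B", "high")))
  expect_error(read_edge_list(bad_score), "line 2")
})

test_that("random edge lists reduce to the distinct non-loop unordered pairs", {
  set.seed(10)
  for (rep in 1:5) {
    gs <- sprintf("g%02d", 1:12)
    rows <- lapply(1:100, function(i) {
      c(sample(gs, 1), sample(gs, 1), sprintf("%.3f", runif(1)))
    })
    path <- write_edges(rows)
    net <- suppressWarnings(read_edge_list(path, score_threshold = 0))
    pairs <- t(vapply(rows, function(r) sort(r[1:2]), character(2)))
    expected <- sum(!duplicated(pairs) & pairs[, 1] != pairs[, 2])
    expect_equal(igraph::ecount(net), expected)
  }
})

test_that("graph union is idempotent, commutative and associative", {
  mk <- function(seed) random_test_graph(8, 0.4, seed)$g
  g1 <- mk(1); g2 <- mk(2); g3 <- mk(3)
  canon <- function(g) {
    el <- igraph::as_edgelist(g)
    el <- t(apply(el, 1, sort))
    el[order(el[, 1], el[, 2]), , drop = FALSE]
  }
  expect_equal(canon(graph_union(g1, g1)), canon(g1))
  expect_equal(canon(graph_union(g1, g2)), canon(graph_union(g2, g1)))
  expect_equal(canon(graph_union(graph_union(g1, g2), g3)),
               canon(graph_union(g1, graph_union(g2, g3))))
  # edge set of the union equals the set union of edge sets
  u <- canon(graph_union(g1, g2, g3))
  ref <- unique(rbind(canon(g1), canon(g2), canon(g3)))
  ref <- ref[order(ref[, 1], ref[, 2]), , drop = FALSE]
  expect_equal(u, ref)
})

test_that("union builds paths across networks sharing a node", {
  e1 <- gene_network(data.frame(gene1 = "A", gene2 = "B"))
  e2 <- gene_network(data.frame(gene1 = "B", gene2 = "C"))
  u <- graph_union(e1, e2)
  expect_equal(igraph::vcount(u), 3)
  expect_equal(igraph::ecount(u), 2)
  expect_equal(unname(igraph::distances(u, "A", "C")[1, 1]), 2)
})

test_that("largest_component keeps the biggest (tie: lexicographic) piece", {
  g <- igraph::graph_from_edgelist(rbind(
    c("a", "b"), c("b", "c"), c("c", "d"), c("d", "e"),
    c("x", "y"), c("y", "z")), directed = FALSE)
  lc <- largest_component(g)
  expect_setequal(igraph::V(lc)$name, c("a", "b", "c", "d", "e"))
  # a connected graph is returned whole
  conn <- random_test_graph(6, 0.9, 1)$g
  expect_equal(igraph::vcount(largest_component(conn)), 6)
  # tie between two components of equal size
  tie <- igraph::graph_from_edgelist(rbind(c("m", "n"), c("a", "b")),
                                     directed = FALSE)
  expect_setequal(igraph::V(largest_component(tie))$name, c("a", "b"))
})

test_that("largest_component agrees with a BFS labelling oracle", {
  for (seed in 1:10) {
    tg <- random_test_graph(10, 0.15, seed)
    # BFS flood fill on the adjacency matrix
    n <- nrow(tg$A)
    lab <- rep(0L, n)
    cur <- 0L
    for (v in seq_len(n)) {
      if (lab[v] > 0) next
      cur <- cur + 1L
      queue <- v
      lab[v] <- cur
      while (length(queue) > 0) {
        u <- queue[1]; queue <- queue[-1]
        nb <- which(tg$A[u, ] > 0 & lab == 0)
        lab[nb] <- cur
        queue <- c(queue, nb)
      }
    }
    best <- which.max(tabulate(lab))
    expect_setequal(igraph::V(largest_component(tg$g))$name,
                    tg$names[lab == best])
  }
})

test_that("network invariants hold after every build operation", {
  set.seed(20)
  for (rep in 1:10) {
    df <- data.frame(gene1 = sample(letters[1:8], 30, TRUE),
                     gene2 = sample(letters[1:8], 30, TRUE),
                     score = runif(30))
    net <- gene_network(df)
    expect_false(igraph::any_loop(net))
    expect_false(igraph::any_multiple(net))
    u <- graph_union(net, random_test_graph(8, 0.3, rep)$g)
    expect_false(igraph::any_loop(u))
    expect_false(igraph::any_multiple(u))
  }
})

test_that("network_summary reports both clustering conventions", {
  # triangle plus a pendant node: local cc = (1, 1, 1/3, NaN)
  g <- igraph::graph_from_edgelist(rbind(c("a", "b"), c("b", "c"),
                                         c("a", "c"), c("c", "d")),
                                   directed = FALSE)
  expect_equal(network_summary(g, "zero")$clustering_coefficient, 7 / 12)
  expect_equal(network_summary(g, "exclude")$clustering_coefficient, 7 / 9)
  expect_equal(network_summary(g)$n_components, 1)
})
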