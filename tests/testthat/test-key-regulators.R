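tf_fixture <- function() {
  read_tf_table(system.file("extdata", "tf_targets_example.tsv",
                            package = "keyregnet"))
}

test_that("hub calling ranks by degree with betweenness then name tie-breaks", {
  star <- named_graph(igraph::make_star(7, mode = "undirected"),
                      c("hub", paste0("l", 1:6)))
  expect_equal(call_hubs(centralities(star), 1), "hub")
  # all-equal degree ring: lexicographic tie-break
  ring <- named_graph(igraph::make_ring(6), c("f", "d", "b", "a", "c", "e"))
  expect_equal(call_hubs(centralities(ring), 2), c("a", "b"))
  expect_error(call_hubs(centralities(ring), 7), "exceeds")
})

test_that("gene tracing follows the branch and flags full-depth presence", {
  out <- generate_network(synthetic_network_spec(
    "nested_blocks", n_nodes = 64, levels = 2, branching = 2,
    p_within_leaf = 0.6, p_between = c(0.01, 0.06), n_planted_hubs = 1,
    seed = 21))
  tree <- build_module_tree(out$net, resolution_params(max_depth = 2))
  gene <- out$truth$hubs[1]
  tr <- trace_gene(tree, gene)
  expect_equal(tr$path[1], "0")
  expect_length(tr$path, tree$depth + 1)
  expect_true(tr$present_at_all_levels)
  expect_error(trace_gene(tree, "NOPE"), "unknown gene")
  # a gene in a module that stopped splitting early is not at all levels
  stopped <- build_module_tree(out$net, resolution_params(max_depth = 1))
  tr1 <- trace_gene(stopped, gene)
  expect_equal(tr1$deepest_level, stopped$depth)
})

test_that("planted deep hubs are called; shallow high-degree decoys are not", {
  out <- generate_network(synthetic_network_spec(
    "nested_blocks", n_nodes = 256, levels = 2, branching = 2,
    p_within_leaf = 0.5, p_between = c(0.005, 0.05),
    n_planted_hubs = 3, n_decoys = 3, seed = 31))
  tree <- build_module_tree(out$net, resolution_params(max_depth = 3))
  cents <- centralities(out$net)
  report <- call_key_regulators(tree, cents, n_hubs = 6)
  expect_setequal(report$gene,
                  c(out$truth$hubs, out$truth$decoys))  # top-6 degrees
  called <- report$gene[report$key_regulator]
  expect_setequal(called, out$truth$hubs)
  decoy_rows <- report[report$gene %in% out$truth$decoys, ]
  expect_true(all(decoy_rows$deepest_level < tree$depth))
  # key-regulator set within hub set within node set
  expect_true(all(called %in% report$gene))
  expect_true(all(report$gene %in% igraph::V(out$net)$name))
})

test_that("depth-0 trees flag every hub with a warning; missing DEGs are unknown", {
  k6 <- named_graph(igraph::make_full_graph(6))
  tree <- build_module_tree(k6)
  degs <- data.frame(gene = c("v01", "v02"), direction = c("up", "down"))
  expect_warning(report <- call_key_regulators(tree, centralities(k6),
                                               degs, n_hubs = 3),
                 "depth 0")
  expect_true(all(report$present_at_all_levels))
  expect_equal(sort(report$direction), c("down", "unknown", "up"))
})

test_that("TF annotation is a pure join attaching both roles", {
  tf <- tf_fixture()
  k6 <- named_graph(igraph::make_full_graph(6),
                    c("POSTN", "CDX1", "CAV1", "SP1", "MYC", "XYZ"))
  tree <- build_module_tree(k6)
  suppressWarnings(report <- call_key_regulators(tree, centralities(k6),
                                                 n_hubs = 6))
  ann <- annotate_tf(report, tf)
  roles <- setNames(ann$tf_roles, ann$gene)
  # POSTN is a target of CDX1 with activation mode
  postn <- roles[["POSTN"]]
  expect_true(any(postn$partner == "CDX1" & postn$role == "target" &
                    postn$mode == "activation"))
  expect_equal(nrow(postn), 3)  # CDX1, TWIST2, YY1
  # SP1 is a regulator of CAV1 and MYC
  sp1 <- roles[["SP1"]]
  expect_setequal(sp1$partner[sp1$role == "regulator"], c("CAV1", "MYC"))
  # unmatched gene: empty roles
  expect_equal(nrow(roles[["XYZ"]]), 0)
  # join totals: every matching table row appears exactly once per gene
  total <- sum(vapply(ann$tf_roles, nrow, integer(1)))
  expected <- sum(tf$tf %in% report$gene) + sum(tf$target %in% report$gene)
  expect_equal(total, expected)
})

test_that("a gene appearing as both tf and target carries both roles", {
  tf <- data.frame(tf = c("A", "B"), target = c("B", "C"),
                   mode = c("activation", "Repression"))
  k3 <- named_graph(igraph::make_full_graph(3), c("A", "B", "C"))
  tree <- build_module_tree(k3)
  suppressWarnings(report <- call_key_regulators(tree, centralities(k3),
                                                 n_hubs = 3))
  ann <- annotate_tf(report, tf)
  b <- ann$tf_roles[[which(ann$gene == "B")]]
  expect_setequal(b$role, c("regulator", "target"))
  # mode vocabulary is normalized, unknown values mapped
  expect_setequal(b$mode, c("repression", "activation"))
  # empty table leaves all roles empty
  empty <- annotate_tf(report, tf[0, ])
  expect_true(all(vapply(empty$tf_roles, nrow, integer(1)) == 0))
})

test_that("malformed TF tables are rejected with the line number", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("tf\ttarget\tmode", "A\tB\tactivation", "oops"), path)
  expect_error(read_tf_table(path), "line 3")
  ok <- read_tf_table(tf_path <- system.file(
    "extdata", "tf_targets_example.tsv", package = "keyregnet"))
  expect_equal(names(ok), c("tf", "target", "mode"))
  expect_true(all(ok$mode %in% c("activation", "repression", "unknown")))
})
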