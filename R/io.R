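# Plain-text readers and writers for every pipeline artifact.

#' Write / read an expression matrix as TSV
#'
#' The matrix file has gene rows and sample columns (header row = sample
#' IDs, first column `gene`); the labels file has two columns
#' `sample`, `group`.
#'
#' @param expr An [expression_matrix()].
#' @param matrix_path,labels_path Output/input file paths.
#' @return `write_expression_tsv` returns the paths invisibly;
#'   `read_expression_tsv` returns an [expression_matrix()].
#' @export
write_expression_tsv <- function(expr, matrix_path, labels_path) {
  stopifnot(inherits(expr, "expression_matrix"))
  df <- data.frame(gene = rownames(expr$values), expr$values,
                   check.names = FALSE)
  write.table(df, matrix_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(sample = names(expr$groups),
                         group = as.character(expr$groups)),
              labels_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(matrix_path, labels_path))
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(matrix_path, labels_path) {
  df <- read.delim(matrix_path, check.names = FALSE,
                   stringsAsFactors = FALSE)
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df[[1]]
  labs <- read.delim(labels_path, stringsAsFactors = FALSE)
  expression_matrix(values, setNames(labs$group, labs$sample))
}

#' Write a network as a 3-column edge-list TSV (gene1, gene2, score)
#'
#' Edges without a score attribute are written with score 1.
#'
#' @param net An igraph network.
#' @param path Output path.
#' @export
write_edge_list <- function(net, path) {
  e <- igraph::as_data_frame(net, what = "edges")
  names(e)[1:2] <- c("gene1", "gene2")
  if (!"score" %in% names(e)) e$score <- rep(1, nrow(e))
  write.table(e[, c("gene1", "gene2", "score")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize a module tree to nested JSON
#'
#' Each node carries `id`, `level`, `members`, `q_of_split`, `he` and
#' `children`.
#'
#' @param tree A [build_module_tree()] result.
#' @param path Output path.
#' @export
write_module_tree_json <- function(tree, path) {
  stopifnot(inherits(tree, "module_tree"))
  to_list <- function(node) {
    list(id = node$id, level = node$level, members = node$members,
         q_of_split = node$q_of_split, he = node$he,
         children = lapply(node$children, to_list))
  }
  p <- unclass(tree$params)
  if (is.infinite(p$max_depth)) p$max_depth <- "Inf"
  jsonlite::write_json(
    list(params = p, depth = tree$depth,
         n_nodes = tree$n_nodes, root = to_list(tree$root)),
    path, auto_unbox = TRUE, digits = NA, null = "null", na = "null",
    pretty = TRUE)
  invisible(path)
}

#' @rdname write_module_tree_json
#' @export
read_module_tree_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  from_list <- function(x) {
    list(id = x$id, level = as.integer(x$level),
         members = unlist(x$members),
         q_of_split = if (is.null(x$q_of_split)) NA_real_
                      else as.numeric(x$q_of_split),
         he = if (is.null(x$he)) NA_real_ else as.numeric(x$he),
         children = lapply(x$children, from_list))
  }
  md <- raw$params$max_depth
  params <- resolution_params(
    gamma = raw$params$gamma,
    min_module_size = raw$params$min_module_size,
    max_depth = if (is.null(md) || identical(md, "Inf")) Inf
                else as.numeric(md))
  structure(list(root = from_list(raw$root), depth = as.integer(raw$depth),
                 params = params, n_nodes = as.integer(raw$n_nodes)),
            class = "module_tree")
}
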