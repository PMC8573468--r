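# Hub calling, gene tracing through the module hierarchy, and
# fundamental-key-regulator reporting.

#' Call hub genes by degree
#'
#' The `n_hubs` nodes of highest degree; ties broken by higher
#' betweenness, then lexicographically smallest gene symbol.
#'
#' @param cents A [centralities()] table.
#' @param n_hubs Number of hubs to call (>= 1, at most the node count).
#' @return Character vector of hub gene symbols, in ranking order.
#' @export
call_hubs <- function(cents, n_hubs = 10) {
  stopifnot(is.data.frame(cents),
            all(c("node", "degree", "betweenness") %in% names(cents)))
  n_hubs <- check_count(n_hubs, "n_hubs", min = 1L)
  if (n_hubs > nrow(cents))
    stop(sprintf("'n_hubs' (%d) exceeds the node count (%d)",
                 n_hubs, nrow(cents)), call. = FALSE)
  ord <- order(-cents$degree, -cents$betweenness, cents$node)
  cents$node[ord][seq_len(n_hubs)]
}

#' Trace a gene through the module hierarchy
#'
#' Follows the gene from the root module (level 0) down to the module at
#' which its branch of the tree stops splitting.
#'
#' @param tree A [build_module_tree()] result.
#' @param gene Gene symbol, must be in the network.
#' @return A list: `path` (module ids at levels 0..deepest),
#'   `deepest_level` (level of the gene's leaf module) and
#'   `present_at_all_levels` (`TRUE` when the branch reaches the tree's
#'   maximum depth, i.e. the gene sits inside a proper module at every
#'   hierarchical level).
#' @export
trace_gene <- function(tree, gene) {
  stopifnot(inherits(tree, "module_tree"))
  if (!gene %in% tree$root$members)
    stop(sprintf("unknown gene '%s'", gene), call. = FALSE)
  path <- character(0)
  node <- tree$root
  repeat {
    path <- c(path, node$id)
    if (length(node$children) == 0) break
    nxt <- NULL
    for (ch in node$children) {
      if (gene %in% ch$members) { nxt <- ch; break }
    }
    if (is.null(nxt)) stop("corrupt tree: gene lost below ", node$id,
                           call. = FALSE)  # children partition members
    node <- nxt
  }
  list(path = path,
       deepest_level = node$level,
       present_at_all_levels = node$level == tree$depth)
}

#' Call fundamental key regulators
#'
#' Hubs (top-`n_hubs` degree) whose module-tree trace reaches the maximum
#' tree depth — i.e. genes that stay inside a proper module at every
#' hierarchical level from the whole network down to the motif level.
#' These deeply rooted hubs form the structural backbone of the network.
#'
#' @param tree A [build_module_tree()] result.
#' @param cents A [centralities()] table for the same network.
#' @param degs Optional DEG table ([compute_deg_table()]) used to annotate
#'   each hub's regulation direction; hubs absent from it get
#'   `"unknown"`.
#' @param n_hubs Number of hubs to consider (default 10).
#' @return A data.frame of class `"key_regulator_report"`, one row per
#'   hub, sorted by degree descending: `gene`, `degree`, `betweenness`,
#'   `is_hub`, `deepest_level`, `present_at_all_levels`, `direction`,
#'   `key_regulator`. Key regulators are the rows with
#'   `key_regulator = TRUE`.
#' @export
call_key_regulators <- function(tree, cents, degs = NULL, n_hubs = 10) {
  stopifnot(inherits(tree, "module_tree"), is.data.frame(cents))
  hubs <- call_hubs(cents, n_hubs)
  missing <- setdiff(hubs, tree$root$members)
  if (length(missing) > 0)
    stop(sprintf("hub '%s' is not in the module tree's network", missing[1]),
         call. = FALSE)
  if (tree$depth == 0)
    warning("module tree has depth 0; every hub is trivially present at all levels",
            call. = FALSE)
  traces <- lapply(hubs, trace_gene, tree = tree)
  dirs <- rep("unknown", length(hubs))
  if (!is.null(degs)) {
    idx <- match(hubs, degs$gene)
    dirs[!is.na(idx)] <- degs$direction[idx[!is.na(idx)]]
  }
  ci <- match(hubs, cents$node)
  rep_df <- data.frame(
    gene = hubs,
    degree = cents$degree[ci],
    betweenness = cents$betweenness[ci],
    is_hub = TRUE,
    deepest_level = vapply(traces, `[[`, integer(1), "deepest_level"),
    present_at_all_levels = vapply(traces, `[[`, logical(1),
                                   "present_at_all_levels"),
    direction = dirs,
    stringsAsFactors = FALSE
  )
  rep_df$key_regulator <- rep_df$is_hub & rep_df$present_at_all_levels
  rep_df <- rep_df[order(-rep_df$degree, rep_df$gene), ]
  rownames(rep_df) <- NULL
  class(rep_df) <- c("key_regulator_report", "data.frame")
  rep_df
}

#' Read a TF-target regulatory table
#'
#' Three tab-delimited columns: tf, target, mode (TRRUST-style export).
#' Modes other than `activation`/`repression` (case-insensitive) are
#' mapped to `unknown`.
#'
#' @param path Path to the table; a header line is tolerated.
#' @return data.frame with columns `tf`, `target`, `mode`.
#' @export
read_tf_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "[ \t]+")
  start <- if (length(toks) > 0 &&
               identical(tolower(toks[[1]][1]), "tf")) 2L else 1L
  if (start > length(toks))
    return(data.frame(tf = character(0), target = character(0),
                      mode = character(0)))
  rows <- toks[start:length(toks)]
  bad <- which(lengths(rows) < 3)
  if (length(bad) > 0)
    stop(sprintf("malformed TF-table row at line %d (need 3 fields)",
                 bad[1] + start - 1L), call. = FALSE)
  mode <- tolower(vapply(rows, `[[`, character(1), 3L))
  mode[!mode %in% c("activation", "repression")] <- "unknown"
  data.frame(tf = vapply(rows, `[[`, character(1), 1L),
             target = vapply(rows, `[[`, character(1), 2L),
             mode = mode, stringsAsFactors = FALSE)
}

#' Annotate a key-regulator report against a TF-target table
#'
#' A pure table join: for every reported gene, all rows of `tf_table`
#' where it appears as the transcription factor (role `"regulator"`) or
#' as the target (role `"target"`) are attached.
#'
#' @param report A [call_key_regulators()] report.
#' @param tf_table data.frame with columns `tf`, `target`, `mode`
#'   (see [read_tf_table()]).
#' @return The report with a list-column `tf_roles`: per gene a
#'   data.frame with columns `partner`, `role`, `mode` (zero rows when no
#'   relation matches).
#' @export
annotate_tf <- function(report, tf_table) {
  stopifnot(inherits(report, "key_regulator_report"),
            is.data.frame(tf_table),
            all(c("tf", "target", "mode") %in% names(tf_table)))
  mode <- tolower(as.character(tf_table$mode))
  mode[!mode %in% c("activation", "repression")] <- "unknown"
  report$tf_roles <- lapply(report$gene, function(g) {
    as_tf <- tf_table$tf == g
    as_tg <- tf_table$target == g
    data.frame(
      partner = c(tf_table$target[as_tf], tf_table$tf[as_tg]),
      role = c(rep("regulator", sum(as_tf)), rep("target", sum(as_tg))),
      mode = c(mode[as_tf], mode[as_tg]),
      stringsAsFactors = FALSE)
  })
  report
}

#' @export
print.key_regulator_report <- function(x, ...) {
  kr <- sum(x$key_regulator)
  cat(sprintf("key_regulator_report: %d hubs, %d fundamental key regulator(s)\n",
              nrow(x), kr))
  cols <- setdiff(names(x), "tf_roles")
  print.data.frame(x[, cols], ...)
  invisible(x)
}
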