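#' Call differentially expressed genes between two groups
#'
#' Per-gene Welch two-sample t-test (case vs control) with
#' Benjamini-Hochberg multiple-testing adjustment. A gene is called
#' `"up"` when `log2fc >= fc_cutoff` and `adj_p < p_cutoff`, `"down"` when
#' `log2fc <= -fc_cutoff` and `adj_p < p_cutoff`, otherwise `"none"`.
#' `log2fc` is the case group mean minus the control group mean on the
#' log2 scale, so the fold-change cutoff is applied to the absolute log2
#' fold change.
#'
#' Genes with zero variance in both groups (possible in noise-free
#' synthetic data) get a degenerate p-value: 0 when the group means differ,
#' 1 when they are equal; a warning reports how many such genes were seen.
#'
#' @param expr An [expression_matrix()] with at least 2 samples per group.
#' @param fc_cutoff Non-negative absolute log2 fold-change cutoff
#'   (default 1.5).
#' @param p_cutoff Adjusted-p cutoff (default 0.05).
#' @return A data.frame with one row per gene (input order) and columns
#'   `gene`, `log2fc`, `p_value`, `adj_p`, `direction`.
#' @examples
#' sim <- generate_expression(synthetic_expression_spec(
#'   n_genes = 100, n_up = 5, n_down = 5, n_per_group = 6, seed = 1))
#' degs <- compute_deg_table(sim$expr)
#' table(degs$direction)
#' @export
compute_deg_table <- function(expr, fc_cutoff = 1.5, p_cutoff = 0.05) {
  if (!inherits(expr, "expression_matrix"))
    stop("'expr' must be an expression_matrix", call. = FALSE)
  fc_cutoff <- check_number(fc_cutoff, "fc_cutoff", min = 0)
  p_cutoff <- check_number(p_cutoff, "p_cutoff", min = 0, max = 1)
  v <- expr$values
  ctrl <- expr$groups == "control"
  case <- expr$groups == "case"
  n1 <- sum(ctrl); n2 <- sum(case)
  if (n1 < 2) stop("group 'control' has fewer than 2 samples", call. = FALSE)
  if (n2 < 2) stop("group 'case' has fewer than 2 samples", call. = FALSE)

  m1 <- rowMeans(v[, ctrl, drop = FALSE])
  m2 <- rowMeans(v[, case, drop = FALSE])
  s1 <- rowSums((v[, ctrl, drop = FALSE] - m1)^2) / (n1 - 1)
  s2 <- rowSums((v[, case, drop = FALSE] - m2)^2) / (n2 - 1)
  log2fc <- m2 - m1

  se2 <- s1 / n1 + s2 / n2
  tstat <- log2fc / sqrt(se2)
  df <- se2^2 / ((s1 / n1)^2 / (n1 - 1) + (s2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(tstat), df)

  degen <- se2 == 0
  if (any(degen)) {
    p[degen] <- ifelse(log2fc[degen] == 0, 1, 0)
    warning(sprintf("%d gene(s) had zero variance in both groups; degenerate p-values assigned",
                    sum(degen)), call. = FALSE)
  }
  adj_p <- p.adjust(p, method = "BH")

  direction <- rep("none", nrow(v))
  direction[log2fc >= fc_cutoff & adj_p < p_cutoff] <- "up"
  direction[log2fc <= -fc_cutoff & adj_p < p_cutoff] <- "down"

  data.frame(gene = rownames(v), log2fc = log2fc, p_value = p,
             adj_p = adj_p, direction = direction,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Split a DEG table into up- and down-regulated gene lists
#'
#' @param degs A data.frame as returned by [compute_deg_table()].
#' @return A list with character vectors `up` and `down`, input order
#'   preserved; genes with direction `"none"` are dropped.
#' @export
split_by_direction <- function(degs) {
  stopifnot(is.data.frame(degs), all(c("gene", "direction") %in% names(degs)))
  list(up = degs$gene[degs$direction == "up"],
       down = degs$gene[degs$direction == "down"])
}

#' Integrate DEG calls from several datasets
#'
#' Cross-platform integration by set union of the per-dataset up and down
#' gene lists. A gene called up in one dataset and down in another is kept
#' in both lists (flagged with a warning).
#'
#' @param deg_list A list of DEG tables from [compute_deg_table()].
#' @return A list with character vectors `up` and `down`.
#' @export
union_deg_calls <- function(deg_list) {
  stopifnot(is.list(deg_list), length(deg_list) >= 1)
  parts <- lapply(deg_list, split_by_direction)
  up <- unique(unlist(lapply(parts, `[[`, "up")))
  down <- unique(unlist(lapply(parts, `[[`, "down")))
  both <- intersect(up, down)
  if (length(both) > 0)
    warning(sprintf("%d gene(s) called up in one dataset and down in another",
                    length(both)), call. = FALSE)
  list(up = up, down = down)
}
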