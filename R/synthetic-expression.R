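#' Specification for a synthetic two-group expression matrix
#'
#' Describes a genes-by-samples log2 expression matrix with a planted set of
#' up- and down-regulated genes. Per-gene baselines are drawn once, the
#' planted log2 fold change is added to the case group, and i.i.d. Gaussian
#' noise (on the log2 scale) is added on top. With `noise_sd = 0` the
#' case/control group-mean difference of a planted gene equals
#' `effect_log2fc` exactly.
#'
#' @param n_genes Total number of genes.
#' @param n_up,n_down Numbers of planted up-/down-regulated genes
#'   (`n_up + n_down <= n_genes`).
#' @param n_per_group Samples per group (same for control and case).
#' @param effect_log2fc Planted absolute log2 fold change (log2 units).
#' @param noise_sd Standard deviation of the additive Gaussian noise
#'   (log2 units).
#' @param seed Integer RNG seed; identical seeds give bit-identical output.
#' @return An object of class `"synthetic_expression_spec"`.
#' @seealso [generate_expression()]
#' @export
synthetic_expression_spec <- function(n_genes, n_up = 0, n_down = 0,
                                      n_per_group = 10, effect_log2fc = 2,
                                      noise_sd = 0.25, seed = 1) {
  spec <- list(
    n_genes = check_count(n_genes, "n_genes", min = 1L),
    n_up = check_count(n_up, "n_up"),
    n_down = check_count(n_down, "n_down"),
    n_per_group = check_count(n_per_group, "n_per_group", min = 1L),
    effect_log2fc = check_number(effect_log2fc, "effect_log2fc", min = 0),
    noise_sd = check_number(noise_sd, "noise_sd", min = 0),
    seed = check_count(seed, "seed")
  )
  if (spec$n_up + spec$n_down > spec$n_genes)
    stop("'n_up' + 'n_down' must not exceed 'n_genes'", call. = FALSE)
  structure(spec, class = "synthetic_expression_spec")
}

#' Generate a synthetic expression matrix with planted fold changes
#'
#' The first `n_up` genes are planted up-regulated, the next `n_down`
#' down-regulated, the rest are null. Baselines are drawn from
#' N(8, 1.5^2) per gene (typical log2 microarray intensities).
#'
#' @param spec A [synthetic_expression_spec()].
#' @return A list with elements
#'   \describe{
#'     \item{expr}{an [expression_matrix()];}
#'     \item{truth}{data.frame with columns `gene` and `direction`
#'       (`"up"`, `"down"` or `"none"`), the planted ground truth.}
#'   }
#' @examples
#' out <- generate_expression(synthetic_expression_spec(
#'   n_genes = 50, n_up = 5, n_down = 3, n_per_group = 4, seed = 42))
#' table(out$truth$direction)
#' @export
generate_expression <- function(spec) {
  if (!inherits(spec, "synthetic_expression_spec"))
    stop("'spec' must be a synthetic_expression_spec", call. = FALSE)
  genes <- sprintf("G%05d", seq_len(spec$n_genes))
  n_samp <- 2L * spec$n_per_group
  samples <- sprintf("S%03d", seq_len(n_samp))
  groups <- rep(c("control", "case"), each = spec$n_per_group)
  direction <- rep("none", spec$n_genes)
  if (spec$n_up > 0) direction[seq_len(spec$n_up)] <- "up"
  if (spec$n_down > 0)
    direction[spec$n_up + seq_len(spec$n_down)] <- "down"
  effect <- ifelse(direction == "up", spec$effect_log2fc,
                   ifelse(direction == "down", -spec$effect_log2fc, 0))

  values <- with_seed(spec$seed, {
    baseline <- rnorm(spec$n_genes, mean = 8, sd = 1.5)
    v <- matrix(baseline, nrow = spec$n_genes, ncol = n_samp)
    v[, groups == "case"] <- v[, groups == "case"] + effect
    v + matrix(rnorm(spec$n_genes * n_samp, sd = spec$noise_sd),
               nrow = spec$n_genes)
  })
  dimnames(values) <- list(genes, samples)
  list(
    expr = expression_matrix(values, setNames(groups, samples)),
    truth = data.frame(gene = genes, direction = direction,
                       stringsAsFactors = FALSE)
  )
}
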