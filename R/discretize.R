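#' Ternary discretization of an expression matrix
#'
#' Codes each gene as over-expressed (+1), baseline (0) or under-expressed
#' (-1) per sample.  Each row is z-scored with the population standard
#' deviation (normalized by n) around the chosen center; values at or beyond
#' `threshold_sd` standard deviations are coded +1/-1, the rest 0.
#' Zero-variance rows are coded all 0.  The ternary coding is the input of
#' the discrete Licorn search.
#'
#' @param expr numeric genes x samples matrix (see [read_expression()]).
#' @param threshold_sd positive z threshold (default 1).
#' @param centering `"gene-mean"` (default), `"gene-median"` or `"none"`.
#' @return integer matrix of the same shape with values in \{-1, 0, +1\}.
#' @examples
#' m <- rbind(g1 = c(-3, 0, 3), g2 = c(10, 10, 10))
#' colnames(m) <- paste0("s", 1:3)
#' discretize(m)
#' @export
discretize <- function(expr, threshold_sd = 1,
                       centering = c("gene-mean", "gene-median", "none")) {
  centering <- match.arg(centering)
  validate_expression(expr)
  if (!is.numeric(threshold_sd) || length(threshold_sd) != 1L ||
      threshold_sd <= 0)
    stop("threshold_sd must be a positive number")
  ctr <- switch(centering,
                "gene-mean" = rowMeans(expr),
                "gene-median" = apply(expr, 1L, stats::median),
                "none" = rep(0, nrow(expr)))
  mu <- rowMeans(expr)
  sd_pop <- sqrt(rowMeans((expr - mu)^2))
  denom <- ifelse(sd_pop > 0, sd_pop, Inf)  # zero-variance rows -> z = 0
  z <- (expr - ctr) / denom
  d <- matrix(0L, nrow(expr), ncol(expr), dimnames = dimnames(expr))
  d[z >= threshold_sd] <- 1L
  d[z <= -threshold_sd] <- -1L
  d
}

#' Per-gene code counts of a discrete matrix
#'
#' @param d integer matrix with values in \{-1, 0, +1\}.
#' @return data frame with columns `gene`, `n_down`, `n_zero`, `n_up`; the
#'   three counts sum to the number of samples for every gene.
#' @export
discretization_summary <- function(d) {
  stopifnot(is.matrix(d), all(d %in% c(-1L, 0L, 1L)))
  data.frame(gene = rownames(d),
             n_down = rowSums(d == -1L),
             n_zero = rowSums(d == 0L),
             n_up = rowSums(d == 1L),
             row.names = NULL, stringsAsFactors = FALSE)
}

# Genes informative enough for inference: at least
# ceiling(min_gene_support * n_samples) non-zero codes.
informative_genes <- function(d, min_gene_support) {
  need <- ceiling(min_gene_support * ncol(d) - 1e-9)
  rownames(d)[rowSums(d != 0L) >= need]
}
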