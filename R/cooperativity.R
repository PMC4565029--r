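# Co-regulation network: an edge between two TFs whose shared (same-set)
# targets are significantly more numerous than expected by chance.

#' Pairwise shared-target counts of a network
#'
#' For every unordered TF pair, counts the targets where both TFs occur in
#' the same regulator set of the chosen program (both activators or both
#' repressors -- cooperative, concordant action; opposite-sign co-targeting
#' is not counted).  `n1` and `n2` count targets regulated by each TF with
#' either sign; the universe is the set of retained targets (targets holding
#' a chosen program).
#'
#' @param net a `tf_network`.
#' @return data frame with columns `tf1`, `tf2`, `n_shared`, `n1`, `n2`,
#'   `n_universe`, one row per TF pair.
#' @export
shared_target_counts <- function(net) {
  if (nrow(net$programs) == 0L) stop("empty network")
  e <- network_edges(net)
  tfs <- sort(unique(e$tf))
  targets <- net$programs$target
  if (length(tfs) < 2L)
    return(data.frame(tf1 = character(0), tf2 = character(0),
                      n_shared = integer(0), n1 = integer(0),
                      n2 = integer(0), n_universe = integer(0),
                      stringsAsFactors = FALSE))
  inc <- function(sgn) {
    m <- matrix(0L, length(tfs), length(targets),
                dimnames = list(tfs, targets))
    sub <- e[e$sign == sgn, , drop = FALSE]
    m[cbind(match(sub$tf, tfs), match(sub$target, targets))] <- 1L
    m
  }
  ma <- inc(1L)
  mr <- inc(-1L)
  shared <- tcrossprod(ma) + tcrossprod(mr)
  n_t <- rowSums((ma + mr) > 0L)
  ut <- which(upper.tri(shared), arr.ind = TRUE)
  data.frame(tf1 = tfs[ut[, 1L]], tf2 = tfs[ut[, 2L]],
             n_shared = shared[ut], n1 = n_t[ut[, 1L]], n2 = n_t[ut[, 2L]],
             n_universe = length(targets), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Hypergeometric cooperativity test
#'
#' One-sided upper-tail probability `P(X >= n_shared)` with
#' `X ~ Hypergeom(n_universe, n1, n2)` -- equivalent to a one-sided Fisher
#' exact test on the 2x2 co-regulation table.  Vectorized.
#'
#' @param n_shared shared same-set target count(s).
#' @param n1,n2 per-TF target counts.
#' @param n_universe total retained targets.
#' @return p-value(s) in (0, 1].
#' @export
cooperativity_test <- function(n_shared, n1, n2, n_universe) {
  ok <- n_shared >= 0 & n_shared <= pmin(n1, n2) &
    n1 <= n_universe & n2 <= n_universe
  if (!all(ok))
    stop("count invariants violated: need 0 <= n_shared <= min(n1, n2) ",
         "<= n_universe")
  stats::phyper(n_shared - 1, n1, n_universe - n1, n2, lower.tail = FALSE)
}

#' Build the co-regulation network
#'
#' Tests every TF pair sharing at least `min_shared` same-set targets with
#' [cooperativity_test()], adjusts p-values across tested pairs by
#' Benjamini-Hochberg, and keeps edges with `q <= alpha`.
#'
#' @param net a `tf_network`.
#' @param alpha FDR threshold (default 0.05).
#' @param min_shared minimum shared targets for a pair to be tested
#'   (default 1).
#' @return list of class `coregulation` with `edges` (significant pairs)
#'   and `tested` (all tested pairs with `p` and `q`).
#' @export
build_coregulation_network <- function(net, alpha = 0.05, min_shared = 1L) {
  counts <- shared_target_counts(net)
  tested <- counts[counts$n_shared >= min_shared, , drop = FALSE]
  if (nrow(tested) == 0L) {
    message("build_coregulation_network: no testable TF pair")
    tested$p <- numeric(0)
    tested$q <- numeric(0)
    return(structure(list(edges = tested, tested = tested, alpha = alpha,
                          min_shared = min_shared), class = "coregulation"))
  }
  tested$p <- cooperativity_test(tested$n_shared, tested$n1, tested$n2,
                                 tested$n_universe)
  tested$q <- stats::p.adjust(tested$p, method = "BH")
  rownames(tested) <- NULL
  edges <- tested[tested$q <= alpha, , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(edges = edges, tested = tested, alpha = alpha,
                 min_shared = min_shared), class = "coregulation")
}

#' @export
print.coregulation <- function(x, ...) {
  cat("coregulation:", nrow(x$edges), "significant TF pair(s) of",
      nrow(x$tested), "tested (q <=", x$alpha, ")\n")
  invisible(x)
}

#' Write a co-regulation network to file
#'
#' `tsv` writes the significant pairs with their counts and statistics;
#' `sif` writes one `TF1 coregulates TF2` line per significant pair.
#'
#' @param coop a `coregulation` object.
#' @param path output path.
#' @param format `"tsv"` or `"sif"`.
#' @return `path`, invisibly.
#' @export
write_coregulation <- function(coop, path, format = c("tsv", "sif")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(coop$edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    writeLines(paste(coop$edges$tf1, "coregulates", coop$edges$tf2,
                     sep = "\t"), path)
  }
  invisible(path)
}
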