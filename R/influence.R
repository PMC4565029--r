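# Sample-specific transcriptional influence: a Welch-type statistic
# comparing the expression of a regulator's activated vs repressed targets,
# used as a proxy for the TF's protein-level activity in each sample.

#' Sample-specific TF influence
#'
#' Expression rows are gene-centered; for TF `t` and sample `s`, with the
#' centered values of the activated targets (size `n_a`, mean `m_a`, sample
#' variance `v_a`) and of the repressed targets (`n_r`, `m_r`, `v_r`), the
#' influence is the Welch statistic
#' `(m_a - m_r) / sqrt(v_a / n_a + v_r / n_r)`.
#' A TF with only activated (resp. only repressed) targets gets the
#' one-sample form `m_a / sqrt(v_a / n_a)` (resp. its negation).  TFs with
#' fewer than `min_targets` targets in the matrix are excluded; a target set
#' with a single member has no defined variance and is treated as empty.
#' A zero denominator yields 0 when the means agree and a flagged signed
#' sentinel (1e6) otherwise.
#'
#' @param net a `tf_network`.
#' @param expr expression matrix; centering is applied internally.
#' @param min_targets minimum number of targets (activated + repressed)
#'   for a TF to be scored (default 10, minimum 2).
#' @return TFs x samples numeric matrix of class `influence_matrix`, with a
#'   `targets` attribute (data frame `tf`, `n_act`, `n_rep`).
#' @export
influence_matrix <- function(net, expr, min_targets = 10L) {
  validate_expression(expr)
  stopifnot(min_targets >= 2L)
  ec <- expr - rowMeans(expr)
  idx <- tf_index(net)
  rows <- list()
  info <- list()
  n_flagged <- 0L
  for (tf in names(idx)) {
    act <- intersect(idx[[tf]]$activated, rownames(ec))
    rep_ <- intersect(idx[[tf]]$repressed, rownames(ec))
    if (length(act) < 2L) act <- character(0)
    if (length(rep_) < 2L) rep_ <- character(0)
    if (length(act) + length(rep_) < min_targets) next
    stat_one <- function(ids) {
      m <- ec[ids, , drop = FALSE]
      mu <- colMeans(m)
      v <- colSums((m - rep(mu, each = nrow(m)))^2) / (nrow(m) - 1)
      list(mu = mu, se2 = v / nrow(m))
    }
    if (length(act) && length(rep_)) {
      a <- stat_one(act); r <- stat_one(rep_)
      num <- a$mu - r$mu
      den <- sqrt(a$se2 + r$se2)
    } else if (length(act)) {
      a <- stat_one(act)
      num <- a$mu
      den <- sqrt(a$se2)
    } else {
      r <- stat_one(rep_)
      num <- -r$mu
      den <- sqrt(r$se2)
    }
    val <- num / den
    bad <- den == 0
    if (any(bad)) {
      val[bad & num == 0] <- 0
      flg <- bad & num != 0
      val[flg] <- sign(num[flg]) * 1e6
      n_flagged <- n_flagged + sum(flg)
    }
    rows[[tf]] <- val
    info[[tf]] <- data.frame(tf = tf, n_act = length(act),
                             n_rep = length(rep_), stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    stop("no TF with at least ", min_targets, " targets in the matrix")
  if (n_flagged > 0L)
    warning("influence_matrix: ", n_flagged,
            " value(s) had zero pooled variance; set to signed 1e6")
  out <- do.call(rbind, rows)
  colnames(out) <- colnames(expr)
  structure(out, targets = do.call(rbind, c(info, make.row.names = FALSE)),
            class = c("influence_matrix", "matrix", "array"))
}

#' @export
print.influence_matrix <- function(x, ...) {
  cat("influence_matrix:", nrow(x), "TFs x", ncol(x), "samples\n")
  print(utils::head(unclass(x)[, seq_len(min(5L, ncol(x))), drop = FALSE]))
  invisible(x)
}

#' Randomly rewire a fraction of a network's edges
#'
#' Draws `round(noise_fraction * n_edges)` signed (TF, target) edges
#' uniformly and rewires each to a uniformly chosen different target,
#' preserving the sign and forbidding self-loops and duplicate edges.  The
#' rewiring target universe is the set of targets of the original network.
#' Used by the influence robustness protocol.
#'
#' @param net a `tf_network`.
#' @param noise_fraction fraction of edges to rewire, in \[0, 1\].
#' @param seed optional integer seed (RNG state is restored on exit).
#' @return a `tf_network` rebuilt from the rewired edge list (fit scores are
#'   no longer meaningful and are set to `NA`).
#' @export
perturb_network <- function(net, noise_fraction, seed = NULL) {
  if (!is.numeric(noise_fraction) || noise_fraction < 0 || noise_fraction > 1)
    stop("noise_fraction must lie in [0, 1]")
  edges <- network_edges(net)
  universe <- unique(net$programs$target)
  run <- function() {
    n_sel <- round(noise_fraction * nrow(edges))
    if (n_sel == 0L) return(edges)
    sel <- sample.int(nrow(edges), n_sel)
    for (i in sel) {
      tf <- edges$tf[i]
      # exclude targets this TF already regulates (either sign: duplicate
      # edges and activator/repressor overlaps are both forbidden) and the
      # TF itself (no self-loops)
      taken <- edges$target[edges$tf == tf]
      pool <- setdiff(universe, c(taken, tf))
      if (length(pool) == 0L) next  # saturated regulator, edge kept
      edges$target[i] <- resample1(pool)
    }
    edges
  }
  new_edges <- if (is.null(seed)) run() else with_seed(seed, run())
  params <- net$params
  params$perturbed_noise <- noise_fraction
  network_from_edges(new_edges, params = params)
}

#' Influence robustness under network noise
#'
#' For each noise level and seed, rewires the network with
#' [perturb_network()], recomputes the influence matrix, and correlates
#' (Pearson, across samples) each TF's perturbed influence with its
#' original influence.  Reported per TF as the mean over seeds.  At noise 0
#' the correlation is exactly 1 for every retained TF; on data generated
#' under the model, the mean correlation decreases as noise grows.
#'
#' @param net a `tf_network`.
#' @param expr expression matrix.
#' @param noise_levels at least two levels in \[0, 1\]
#'   (default `c(0, 0.1, 0.2, 0.3, 0.5)`).
#' @param n_seeds replicates per level (default 10).
#' @param min_targets see [influence_matrix()].
#' @param seed base seed; replicate seeds are derived from it.
#' @return list with `per_tf` (TFs x levels matrix of mean correlations;
#'   `NA` when a TF fell below `min_targets` in every replicate) and
#'   `summary` (data frame `level`, `mean_cor` over TFs and seeds).
#' @export
influence_robustness <- function(net, expr,
                                 noise_levels = c(0, 0.1, 0.2, 0.3, 0.5),
                                 n_seeds = 10L, min_targets = 10L,
                                 seed = 1L) {
  if (length(noise_levels) < 2L)
    stop("at least 2 noise levels are required")
  inf0 <- influence_matrix(net, expr, min_targets = min_targets)
  tfs <- rownames(inf0)
  per_tf <- matrix(NA_real_, length(tfs), length(noise_levels),
                   dimnames = list(tfs, as.character(noise_levels)))
  n_missing <- 0L
  for (li in seq_along(noise_levels)) {
    acc <- matrix(NA_real_, length(tfs), n_seeds)
    for (s in seq_len(n_seeds)) {
      p_net <- perturb_network(net, noise_levels[li],
                               seed = seed * 10000L + li * 100L + s)
      inf_p <- try(influence_matrix(p_net, expr, min_targets = min_targets),
                   silent = TRUE)
      if (inherits(inf_p, "try-error")) next
      common <- intersect(tfs, rownames(inf_p))
      n_missing <- n_missing + (length(tfs) - length(common))
      for (tf in common)
        acc[match(tf, tfs), s] <- safe_cor(inf0[tf, ], inf_p[tf, ])
    }
    per_tf[, li] <- rowMeans(acc, na.rm = TRUE)
  }
  if (n_missing > 0L)
    message("influence_robustness: ", n_missing,
            " TF x replicate value(s) missing (TF below min_targets ",
            "after perturbation)")
  per_tf[is.nan(per_tf)] <- NA_real_
  summary <- data.frame(level = noise_levels,
                        mean_cor = colMeans(per_tf, na.rm = TRUE))
  list(per_tf = per_tf, summary = summary)
}
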