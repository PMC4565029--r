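# Synthetic benchmark: ground-truth cooperative networks and expression
# data generated under the linear-Gaussian model the hybrid scoring
# assumes, plus precision-recall scoring of network recovery.

#' Specify a synthetic benchmark dataset
#'
#' The generative model: TF expression rows are i.i.d. standard normal;
#' each gene's row is `effect_size` times the mean expression of its
#' activator TFs minus `effect_size` times the mean of its repressor TFs,
#' plus Gaussian noise.  Cooperative structure is induced by
#' `coactivation_bias`: with that probability a new gene with at least two
#' activators reuses an existing cooperative TF pair instead of drawing
#' fresh TFs.
#'
#' @param n_tf number of TFs (>= 2).
#' @param n_genes number of (non-TF) target genes.
#' @param n_samples number of samples (>= 3).
#' @param coactivation_bias pair-reuse probability in \[0, 1\].
#' @param act_set_size integer range `c(min, max)` of activator set sizes.
#' @param rep_set_size integer range of repressor set sizes.
#' @param effect_size positive regulatory effect size.
#' @param noise_sd non-negative Gaussian noise standard deviation.
#' @param seed integer seed; the dataset is reproducible bit-for-bit from
#'   the spec.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_tf = 20L, n_genes = 200L, n_samples = 100L,
                           coactivation_bias = 0.5,
                           act_set_size = c(1L, 2L),
                           rep_set_size = c(0L, 1L),
                           effect_size = 1, noise_sd = 0.25, seed = 1L) {
  stopifnot(n_tf >= 2L, n_samples >= 3L, n_genes >= 1L,
            coactivation_bias >= 0, coactivation_bias <= 1,
            length(act_set_size) == 2L, length(rep_set_size) == 2L,
            act_set_size[1L] <= act_set_size[2L],
            rep_set_size[1L] <= rep_set_size[2L],
            act_set_size[1L] >= 0L, rep_set_size[1L] >= 0L,
            act_set_size[1L] + rep_set_size[1L] >= 1L,
            effect_size > 0, noise_sd >= 0)
  if (act_set_size[2L] + rep_set_size[2L] > n_tf)
    stop("infeasible regulator set sizes: max |A| + max |R| exceeds n_tf")
  structure(list(n_tf = as.integer(n_tf), n_genes = as.integer(n_genes),
                 n_samples = as.integer(n_samples),
                 coactivation_bias = coactivation_bias,
                 act_set_size = as.integer(act_set_size),
                 rep_set_size = as.integer(rep_set_size),
                 effect_size = effect_size, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic benchmark dataset
#'
#' @param spec a [synthetic_spec()].
#' @return list of class `synthetic_dataset` with `expr` (TF rows followed
#'   by gene rows), `tfs`, `truth` (ground-truth `tf_network`),
#'   `coop_pairs` (ground-truth cooperative TF pairs: pairs co-occurring in
#'   the same regulator set of at least two programs) and `spec`.
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    tf_ids <- sprintf("TF%0*d", nchar(spec$n_tf), seq_len(spec$n_tf))
    gene_ids <- sprintf("G%0*d", nchar(spec$n_genes), seq_len(spec$n_genes))
    sample_ids <- sprintf("S%0*d", nchar(spec$n_samples),
                          seq_len(spec$n_samples))
    tf_expr <- matrix(stats::rnorm(spec$n_tf * spec$n_samples),
                      spec$n_tf, spec$n_samples,
                      dimnames = list(tf_ids, sample_ids))
    pool <- list()
    pool_keys <- character(0)
    acts <- vector("list", spec$n_genes)
    reps <- vector("list", spec$n_genes)
    gene_expr <- matrix(0, spec$n_genes, spec$n_samples,
                        dimnames = list(gene_ids, sample_ids))
    for (g in seq_len(spec$n_genes)) {
      n_a <- resample1(seq(spec$act_set_size[1L], spec$act_set_size[2L]))
      n_r <- resample1(seq(spec$rep_set_size[1L], spec$rep_set_size[2L]))
      if (n_a + n_r == 0L) n_a <- 1L
      a <- character(0)
      if (n_a >= 2L && length(pool) &&
          stats::runif(1L) < spec$coactivation_bias) {
        pair <- pool[[resample1(seq_along(pool))]]
        extra <- if (n_a > 2L)
          sample(setdiff(tf_ids, pair), n_a - 2L) else character(0)
        a <- c(pair, extra)
      } else if (n_a >= 1L) {
        a <- sample(tf_ids, n_a)
        if (n_a >= 2L) {
          key <- paste(sort(a[1:2]), collapse = "|")
          if (!key %in% pool_keys) {
            pool[[length(pool) + 1L]] <- sort(a[1:2])
            pool_keys <- c(pool_keys, key)
          }
        }
      }
      r <- if (n_r >= 1L) sample(setdiff(tf_ids, a), n_r) else character(0)
      acts[[g]] <- a
      reps[[g]] <- r
      mu <- numeric(spec$n_samples)
      if (length(a))
        mu <- mu + spec$effect_size * colMeans(tf_expr[a, , drop = FALSE])
      if (length(r))
        mu <- mu - spec$effect_size * colMeans(tf_expr[r, , drop = FALSE])
      gene_expr[g, ] <- mu + stats::rnorm(spec$n_samples, 0, spec$noise_sd)
    }
    programs <- data.frame(
      target = gene_ids,
      activators = vapply(acts, join_ids, ""),
      repressors = vapply(reps, join_ids, ""),
      mae = NA_real_, r2_adj = NA_real_, stringsAsFactors = FALSE)
    truth <- tf_network(programs,
                        params = list(synthetic = TRUE, seed = spec$seed))
    counts <- shared_target_counts(truth)
    coop_pairs <- counts[counts$n_shared >= 2L, c("tf1", "tf2"),
                         drop = FALSE]
    rownames(coop_pairs) <- NULL
    structure(list(expr = rbind(tf_expr, gene_expr), tfs = tf_ids,
                   truth = truth, coop_pairs = coop_pairs, spec = spec),
              class = "synthetic_dataset")
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("synthetic_dataset:", x$spec$n_tf, "TFs,", x$spec$n_genes, "genes,",
      x$spec$n_samples, "samples;", nrow(network_edges(x$truth)),
      "true signed edges,", nrow(x$coop_pairs),
      "true cooperative pairs\n")
  invisible(x)
}

#' Average precision of a ranked prediction
#'
#' Step-wise (trapezoid-free) integration of the precision-recall curve:
#' the mean, over all positives, of the precision at each retrieved
#' positive's rank, with never-retrieved positives contributing zero.  For
#' a random ranking the expected value approximates the prevalence of
#' positives.
#'
#' @param scores numeric prediction scores (higher = more confident).
#' @param labels logical (or 0/1) truth labels aligned with `scores`.
#' @param n_positive total number of positives (defaults to `sum(labels)`;
#'   pass a larger value when some positives were never scored).
#' @param keys optional character keys used to break score ties
#'   deterministically.
#' @return the area under the precision-recall curve, in \[0, 1\].
#' @export
average_precision <- function(scores, labels, n_positive = sum(labels),
                              keys = NULL) {
  stopifnot(length(scores) == length(labels))
  labels <- as.logical(labels)
  if (n_positive == 0L) return(NA_real_)
  ord <- if (is.null(keys)) order(-scores, method = "radix")
  else order(-scores, keys, method = "radix")
  lab <- labels[ord]
  prec <- cumsum(lab) / seq_along(lab)
  sum(prec[lab]) / n_positive
}

#' Score recovery of a ground-truth network
#'
#' Signed TF-to-gene edges are ranked by the best adjusted R squared of any
#' valid candidate program containing them (edges absent from all candidates
#' rank last and unranked); cooperative TF pairs are ranked by the
#' cooperativity p-value of the inferred network (untested pairs last).
#' Both rankings are summarized by average precision ([average_precision()]),
#' and the chosen programs by exact signed precision/recall.
#'
#' @param inferred a `tf_network` (candidate lists used when present).
#' @param truth the ground-truth `tf_network`.
#' @param coop_pairs optional data frame (`tf1`, `tf2`) of true cooperative
#'   pairs (e.g. from [generate_synthetic()]).
#' @return list with `aupr_signed`, `prevalence_signed`, `precision`,
#'   `recall`, and -- when `coop_pairs` is given -- `aupr_coop`,
#'   `prevalence_coop`.
#' @export
score_recovery <- function(inferred, truth, coop_pairs = NULL) {
  truth_edges <- network_edges(truth)
  inf_edges <- network_edges(inferred)
  tf_univ <- sort(unique(c(truth_edges$tf, inf_edges$tf)))
  targ_univ <- sort(unique(c(truth_edges$target, inf_edges$target)))
  if (length(intersect(c(truth_edges$tf, truth_edges$target),
                       c(inf_edges$tf, inf_edges$target))) == 0L)
    stop("disjoint identifier spaces between inferred and truth networks")
  ekey <- function(tf, target, sign) paste(tf, target, sign)
  truth_keys <- ekey(truth_edges$tf, truth_edges$target, truth_edges$sign)

  # candidate-ranked signed edges
  escore <- new.env(parent = emptyenv())
  add_edges <- function(a, r, s) {
    for (tf in split_ids(a)) {
      k <- ekey(tf, gene, 1L)
      if (is.null(escore[[k]]) || escore[[k]] < s) escore[[k]] <- s
    }
    for (tf in split_ids(r)) {
      k <- ekey(tf, gene, -1L)
      if (is.null(escore[[k]]) || escore[[k]] < s) escore[[k]] <- s
    }
  }
  if (!is.null(inferred$candidates)) {
    for (gene in names(inferred$candidates)) {
      cand <- inferred$candidates[[gene]]
      cand <- cand[cand$valid, , drop = FALSE]
      for (i in seq_len(nrow(cand)))
        add_edges(cand$activators[i], cand$repressors[i],
                  abs(cand$r2_adj[i]))
    }
  } else {
    p <- inferred$programs
    for (i in seq_len(nrow(p))) {
      gene <- p$target[i]
      add_edges(p$activators[i], p$repressors[i],
                if (is.na(p$r2_adj[i])) 0 else abs(p$r2_adj[i]))
    }
  }
  keys <- ls(escore)
  scores <- vapply(keys, function(k) escore[[k]], 1.0)
  n_possible <- sum(vapply(tf_univ, function(t)
    2L * sum(targ_univ != t), 1L))
  prevalence_signed <- length(truth_keys) / n_possible
  aupr_signed <- average_precision(scores, keys %in% truth_keys,
                                   n_positive = length(truth_keys),
                                   keys = keys)

  # exact precision/recall of chosen programs
  chosen_keys <- ekey(inf_edges$tf, inf_edges$target, inf_edges$sign)
  tp <- sum(chosen_keys %in% truth_keys)
  out <- list(aupr_signed = aupr_signed,
              prevalence_signed = prevalence_signed,
              precision = if (length(chosen_keys)) tp / length(chosen_keys)
              else NA_real_,
              recall = tp / length(truth_keys))

  if (!is.null(coop_pairs)) {
    counts <- shared_target_counts(inferred)
    tested <- counts[counts$n_shared >= 1L, , drop = FALSE]
    pkey <- function(a, b) paste(pmin(a, b), pmax(a, b))
    pscore <- if (nrow(tested))
      1 - cooperativity_test(tested$n_shared, tested$n1, tested$n2,
                             tested$n_universe) else numeric(0)
    names(pscore) <- if (nrow(tested)) pkey(tested$tf1, tested$tf2)
    truth_pairs <- if (nrow(coop_pairs))
      pkey(coop_pairs$tf1, coop_pairs$tf2) else character(0)
    all_tfs <- sort(unique(c(tf_univ, coop_pairs$tf1, coop_pairs$tf2)))
    n_pairs <- choose(length(all_tfs), 2L)
    out$prevalence_coop <- length(truth_pairs) / n_pairs
    out$aupr_coop <- average_precision(
      pscore, names(pscore) %in% truth_pairs,
      n_positive = length(truth_pairs), keys = names(pscore))
  }
  out
}
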