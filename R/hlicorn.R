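# Hybrid Licorn: discrete search over candidate co-regulator sets followed
# by continuous linear re-scoring of candidate programs.

# Truth-table lookup vector, indexed by 3*a + r + 5 for a, r in {-1, 0, +1}.
.licorn_table <- c(0L, -1L, -1L,   # a = -1 : r = -1, 0, +1
                   1L,  0L, -1L,   # a =  0
                   1L,  1L,  0L)   # a = +1

#' Collective ternary state of a TF set (unanimity rule)
#'
#' A set of regulators is collectively active (+1) in a sample only if all
#' of its members are coded +1, collectively inactive (-1) only if all are
#' -1, and neutral (0) otherwise.  The empty set is neutral.
#'
#' @param states vector of codes in \{-1, 0, +1\} (may be empty).
#' @return a single code in \{-1, 0, +1\}.
#' @export
collective_state <- function(states) {
  if (length(states) == 0L) return(0L)
  stopifnot(all(states %in% c(-1L, 0L, 1L)))
  if (all(states == 1L)) return(1L)
  if (all(states == -1L)) return(-1L)
  0L
}

#' Ternary Licorn prediction of a target's code
#'
#' Given the collective activator state `a` and collective repressor state
#' `r` of a program in a sample, predicts the target's ternary code.  The
#' table is antisymmetric (`predict(a, r) = -predict(-a, -r)`), monotone
#' non-decreasing in `a` and non-increasing in `r`, and reduces to "follow
#' the activators" / "oppose the repressors" when the other set is neutral.
#'
#' @param a,r collective states in \{-1, 0, +1\}; vectorized.
#' @return predicted code(s) in \{-1, 0, +1\}.
#' @export
licorn_predict <- function(a, r) {
  stopifnot(all(a %in% c(-1L, 0L, 1L)), all(r %in% c(-1L, 0L, 1L)))
  .licorn_table[3L * a + r + 5L]
}

# Collective state of one regulator set across all samples of a discrete
# matrix; integer vector of length n_samples.
collective_state_vector <- function(d, ids) {
  n <- ncol(d)
  if (length(ids) == 0L) return(integer(n))
  sub <- d[ids, , drop = FALSE]
  k <- nrow(sub)
  out <- integer(n)
  out[colSums(sub == 1L) == k] <- 1L
  out[colSums(sub == -1L) == k] <- -1L
  out
}

#' Discrete fit of a regulatory program
#'
#' Mean absolute error, over samples, between the truth-table prediction
#' from the program's collective activator/repressor states and the target's
#' observed ternary code.  Ranges over \[0, 2\].
#'
#' @param activators,repressors character vectors of TF identifiers (either
#'   may be empty, not both).
#' @param target target gene identifier.
#' @param d ternary matrix from [discretize()] containing target and
#'   regulators.
#' @return the mean absolute error (numeric scalar).
#' @export
score_program_discrete <- function(activators, repressors, target, d) {
  ids <- c(activators, repressors, target)
  missing <- setdiff(ids, rownames(d))
  if (length(missing))
    stop("identifiers absent from discrete matrix: ",
         paste(missing, collapse = ", "))
  a <- collective_state_vector(d, activators)
  r <- collective_state_vector(d, repressors)
  mean(abs(licorn_predict(a, r) - d[target, ]))
}

# ---------------------------------------------------------------------------
# Frequent co-regulator set mining (level-wise Apriori over the two ternary
# contexts).

# Level-wise enumeration of itemsets with support >= min_count, up to
# max_size items, over transaction lists (one integer sample vector per
# item).  Items within a set are kept in sorted order; the classic prefix
# join generates every frequent k-set exactly once because support is
# monotone under subsets.
apriori_sets <- function(samples_by_item, min_count, max_size) {
  items <- sort(names(samples_by_item))
  keep <- items[vapply(samples_by_item, length, 1L)[items] >= min_count]
  level <- lapply(keep, function(it)
    list(items = it, samples = samples_by_item[[it]]))
  out <- level
  k <- 2L
  while (k <= max_size && length(level) >= 2L) {
    prefixes <- vapply(level, function(s)
      paste(s$items[-length(s$items)], collapse = "\r"), "")
    lasts <- vapply(level, function(s) s$items[length(s$items)], "")
    nxt <- list()
    for (grp in split(seq_along(level), prefixes)) {
      if (length(grp) < 2L) next
      grp <- grp[order(lasts[grp])]
      for (i in seq_len(length(grp) - 1L)) {
        for (j in (i + 1L):length(grp)) {
          s1 <- level[[grp[i]]]
          samp <- intersect(s1$samples, level[[grp[j]]]$samples)
          if (length(samp) >= min_count)
            nxt[[length(nxt) + 1L]] <-
              list(items = c(s1$items, lasts[grp[j]]), samples = samp)
        }
      }
    }
    out <- c(out, nxt)
    level <- nxt
    k <- k + 1L
  }
  out
}

#' Mine frequent co-regulator sets from discretized TF profiles
#'
#' Treats samples as transactions in two separate encodings: TFs coded +1
#' (the "+1 context", joint over-expression) and TFs coded -1 (the "-1
#' context").  Sets of up to `max_coreg` TFs whose members are unanimously
#' at the context code in at least a fraction `min_coreg_support` of samples
#' are retained (in either context).  For every retained set, the supporting
#' samples in both contexts -- equivalently its collective-state vector --
#' are stored.  A `min_coreg_support` of 0 disables the support filter and
#' enumerates every TF set up to `max_coreg` (exhaustive-search mode).
#'
#' @param d_tf ternary matrix restricted to TF rows.
#' @param min_coreg_support minimum support fraction in \[0, 1\].
#' @param max_coreg maximum co-regulator set size (>= 1).
#' @return an object of class `coreg_sets`: parallel vectors/lists with one
#'   entry per retained set (`sets`, `key`, `size`, `sup_pos`, `sup_neg`,
#'   `freq_pos`, `freq_neg`), the collective `state` matrix (sets x
#'   samples), and a TF membership matrix.
#' @export
mine_coregulator_sets <- function(d_tf, min_coreg_support = 0.1,
                                  max_coreg = 3L) {
  stopifnot(is.matrix(d_tf), nrow(d_tf) >= 1L,
            min_coreg_support >= 0, min_coreg_support <= 1, max_coreg >= 1L)
  n <- ncol(d_tf)
  tf_ids <- rownames(d_tf)
  min_count <- ceiling(min_coreg_support * n - 1e-9)

  pos <- lapply(tf_ids, function(t) which(d_tf[t, ] == 1L))
  neg <- lapply(tf_ids, function(t) which(d_tf[t, ] == -1L))
  names(pos) <- names(neg) <- tf_ids

  fp <- apriori_sets(pos, min_count, max_coreg)
  fn <- apriori_sets(neg, min_count, max_coreg)
  key_fp <- vapply(fp, function(s) paste(s$items, collapse = ","), "")
  key_fn <- vapply(fn, function(s) paste(s$items, collapse = ","), "")

  keys <- unique(c(key_fp, key_fn))
  sets <- lapply(strsplit(keys, ",", fixed = TRUE), identity)
  nsets <- length(sets)
  if (nsets == 0L)
    message("mine_coregulator_sets: no frequent set at support ",
            min_coreg_support)

  sup_pos <- lapply(sets, function(s) Reduce(intersect, pos[s]))
  sup_neg <- lapply(sets, function(s) Reduce(intersect, neg[s]))
  state <- matrix(0L, nsets, n)
  for (i in seq_len(nsets)) {
    state[i, sup_pos[[i]]] <- 1L
    state[i, sup_neg[[i]]] <- -1L
  }
  member <- matrix(FALSE, length(tf_ids), nsets,
                   dimnames = list(tf_ids, NULL))
  for (i in seq_len(nsets)) member[sets[[i]], i] <- TRUE

  structure(list(sets = sets, key = keys, size = lengths(sets),
                 sup_pos = sup_pos, sup_neg = sup_neg, state = state,
                 freq_pos = keys %in% key_fp, freq_neg = keys %in% key_fn,
                 member = member, n_samples = n, tf_ids = tf_ids,
                 min_count = min_count),
            class = "coreg_sets")
}

#' @export
print.coreg_sets <- function(x, ...) {
  cat("coreg_sets:", length(x$sets), "frequent TF sets over", x$n_samples,
      "samples (min count", x$min_count, ")\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Candidate generation.

# Indices (into `index`) of sets passing the coherence rule for a gene's
# code vector.  A set is a coherent activator set when, among the samples
# where it is collectively +1, at least `search_thresh` show the gene at +1,
# and among those where it is collectively -1 at least `search_thresh` show
# the gene at -1; repressor sets mirror the rule (set +1 where gene -1 and
# vice versa).  A condition on an empty support holds vacuously -- under the
# unanimity collective state, joint +/-1 support shrinks rapidly with set
# size, so the inclusion is measured on the set side.
coherent_sets <- function(code, index, search_thresh, exclude = NULL) {
  st <- index$state
  frac_code <- function(sup, gene_code) {
    vapply(sup, function(s) {
      if (length(s) == 0L) return(1)
      mean(code[s] == gene_code)
    }, 1.0)
  }
  a_ok <- frac_code(index$sup_pos, 1L) >= search_thresh &
    frac_code(index$sup_neg, -1L) >= search_thresh
  r_ok <- frac_code(index$sup_pos, -1L) >= search_thresh &
    frac_code(index$sup_neg, 1L) >= search_thresh
  if (!is.null(exclude) && exclude %in% rownames(index$member)) {
    has_gene <- index$member[exclude, ]
    a_ok <- a_ok & !has_gene
    r_ok <- r_ok & !has_gene
  }
  list(act = which(a_ok), rep = which(r_ok))
}

# All admissible (A, R) index pairs for a gene; 0 denotes the empty set.
# Pairs with overlapping sets and the (empty, empty) pair are discarded.
# `overlap` (set-by-set shared-member counts) may be passed in to avoid
# recomputation across genes.
candidate_pairs <- function(code, gene, index, search_thresh,
                            overlap = NULL) {
  coh <- coherent_sets(code, index, search_thresh, exclude = gene)
  a0 <- c(0L, coh$act)
  r0 <- c(0L, coh$rep)
  ai <- rep(a0, times = length(r0))
  ri <- rep(r0, each = length(a0))
  keep <- !(ai == 0L & ri == 0L)
  if (length(index$sets)) {
    if (is.null(overlap)) overlap <- crossprod(index$member)
    both <- keep & ai > 0L & ri > 0L
    keep[both] <- overlap[cbind(ai[both], ri[both])] == 0L
  }
  list(ai = ai[keep], ri = ri[keep])
}

#' Generate candidate (activator, repressor) programs for one gene
#'
#' Applies the coherence rule to the mined frequent sets: a candidate
#' activator set must see the gene over-expressed in at least
#' `search_thresh` of the samples where the set is collectively
#' over-expressed (and under-expressed where the set is collectively
#' under); candidate repressor sets satisfy the mirror image.  The gene
#' itself is excluded, as are pairs whose activator and repressor sets
#' overlap.
#'
#' @param gene target gene identifier.
#' @param d ternary matrix containing the gene.
#' @param index a `coreg_sets` object from [mine_coregulator_sets()].
#' @param search_thresh coherence threshold in \[0, 1\] (default 1/3); 0
#'   disables the filter.
#' @return data frame with columns `activators`, `repressors`
#'   (semicolon-joined), one row per candidate pair.
#' @export
generate_candidates <- function(gene, d, index, search_thresh = 1/3) {
  stopifnot(gene %in% rownames(d),
            search_thresh >= 0, search_thresh <= 1)
  cp <- candidate_pairs(d[gene, ], gene, index, search_thresh)
  set_str <- function(i) if (i == 0L) "" else join_ids(index$sets[[i]])
  data.frame(activators = vapply(cp$ai, set_str, ""),
             repressors = vapply(cp$ri, set_str, ""),
             stringsAsFactors = FALSE)
}

# Vectorized discrete MAE of candidate pairs (ai, ri index vectors, 0 =
# empty set) against one target code vector.
score_pairs_discrete <- function(ai, ri, code, state) {
  n <- length(code)
  mae <- numeric(length(ai))
  for (a in unique(ai)) {
    rows <- which(ai == a)
    astate <- if (a == 0L) integer(n) else state[a, ]
    rs <- ri[rows]
    Rm <- matrix(0L, length(rs), n)
    nz <- rs != 0L
    if (any(nz)) Rm[nz, ] <- state[rs[nz], , drop = FALSE]
    idx <- Rm + rep(3L * astate + 5L, each = length(rs))
    pred <- .licorn_table[idx]
    mae[rows] <- rowMeans(abs(matrix(pred - rep(code, each = length(rs)),
                                     nrow = length(rs))))
  }
  mae
}

# ---------------------------------------------------------------------------
# Continuous (hybrid) re-scoring.

#' Continuous re-scoring of a regulatory program
#'
#' Ordinary least squares of the row-centered target expression on the mean
#' centered expression of the activator set and (negatively expected) of the
#' repressor set, with intercept.  A program is rejected (`valid = FALSE`)
#' when the activator coefficient is negative, the repressor coefficient is
#' positive, or the two regressors are collinear (|correlation| > 0.999).
#'
#' @param activators,repressors character vectors of TF identifiers (either
#'   may be empty, not both).
#' @param target target gene identifier.
#' @param expr expression matrix containing target and regulators, at least
#'   3 samples.
#' @return list with `coef_act`, `coef_rep`, `r2_adj`, `valid`, `reason`.
#' @export
score_program_continuous <- function(activators, repressors, target, expr) {
  stopifnot(ncol(expr) >= 3L)
  ids <- c(activators, repressors, target)
  missing <- setdiff(ids, rownames(expr))
  if (length(missing))
    stop("identifiers absent from expression matrix: ",
         paste(missing, collapse = ", "))
  ec <- expr - rowMeans(expr)
  y <- ec[target, ]
  abar <- if (length(activators))
    colMeans(ec[activators, , drop = FALSE]) else NULL
  rbar <- if (length(repressors))
    colMeans(ec[repressors, , drop = FALSE]) else NULL
  fit_ols(y, abar, rbar)
}

# Core OLS scoring on prepared regressors; shared with the infer loop.
fit_ols <- function(y, abar, rbar) {
  out <- list(coef_act = NA_real_, coef_rep = NA_real_, r2_adj = NA_real_,
              valid = FALSE, reason = "")
  X <- cbind(abar, rbar)
  if (is.null(X) || ncol(X) == 0L) {
    out$reason <- "no regressors"
    return(out)
  }
  if (any(apply(X, 2L, stats::sd) == 0)) {
    out$reason <- "constant regressor"
    return(out)
  }
  if (!is.null(abar) && !is.null(rbar) &&
      abs(stats::cor(abar, rbar)) > 0.999) {
    out$reason <- "collinear regressors"
    return(out)
  }
  n <- length(y)
  p <- ncol(X)
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, X), y)
  beta <- fit$coefficients[-1L]
  if (anyNA(beta)) {
    out$reason <- "rank-deficient fit"
    return(out)
  }
  ca <- if (!is.null(abar)) beta[[1L]] else NA_real_
  cr <- if (!is.null(rbar)) beta[[if (is.null(abar)) 1L else 2L]] else NA_real_
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - rss / tss
  r2_adj <- 1 - (1 - r2) * (n - 1) / (n - 1 - p)
  out$coef_act <- ca
  out$coef_rep <- cr
  out$r2_adj <- r2_adj
  if (!is.na(ca) && ca < 0) {
    out$reason <- "negative activator coefficient"
  } else if (!is.na(cr) && cr > 0) {
    out$reason <- "positive repressor coefficient"
  } else {
    out$valid <- TRUE
  }
  out
}

# ---------------------------------------------------------------------------
# Full inference.

#' Infer a cooperative regulatory network (h-Licorn)
#'
#' For every retained target gene: generate candidate (activator, repressor)
#' programs from the mined frequent TF sets under the coherence rule, keep
#' the `n_grn` best by discrete mean absolute error (ties: smaller program,
#' then lexicographic on sorted regulator identifiers), re-score them by
#' ordinary least squares, and choose the sign-valid candidate with the
#' highest adjusted R squared.  Genes with no valid program are dropped with
#' a message.  The ranked candidate lists are retained for evidence-based
#' refinement.  The whole procedure is deterministic.
#'
#' @param expr expression matrix (see [read_expression()]).
#' @param tfs character vector of TF identifiers (TFs absent from `expr` are
#'   ignored with a warning); at least 2 must be present.
#' @param targets genes to model; defaults to every retained gene (TF genes
#'   may be targets; self-regulation is forbidden).
#' @param min_gene_support minimum fraction of non-zero ternary codes for a
#'   gene to be modeled (default 0.1).
#' @param min_coreg_support minimum co-regulator set support (default 0.1;
#'   0 disables the filter, see [mine_coregulator_sets()]).
#' @param max_coreg maximum regulator-set size (default 3).
#' @param search_thresh coherence threshold (default 1/3; 0 disables).
#' @param n_grn number of top candidates re-scored per gene (default 100).
#' @param threshold_sd,centering discretization parameters, see
#'   [discretize()].
#' @param verbose emit progress messages.
#' @return a `tf_network` with candidate lists.
#' @export
hlicorn <- function(expr, tfs, targets = NULL,
                    min_gene_support = 0.1, min_coreg_support = 0.1,
                    max_coreg = 3L, search_thresh = 1/3, n_grn = 100L,
                    threshold_sd = 1, centering = "gene-mean",
                    verbose = TRUE) {
  validate_expression(expr)
  stopifnot(min_gene_support > 0, min_gene_support <= 1, n_grn >= 1L)
  tfs <- match_tfs(tfs, expr)
  if (length(tfs) < 2L)
    stop("at least 2 TFs must be present in the expression matrix")

  d <- discretize(expr, threshold_sd = threshold_sd, centering = centering)
  retained <- informative_genes(d, min_gene_support)
  targets <- if (is.null(targets)) retained else intersect(targets, retained)
  if (length(targets) == 0L)
    stop("no informative target gene at min_gene_support = ",
         min_gene_support)
  if (verbose)
    message("hlicorn: ", length(targets), " target genes, ", length(tfs),
            " TFs, ", ncol(expr), " samples")

  index <- mine_coregulator_sets(d[tfs, , drop = FALSE],
                                 min_coreg_support = min_coreg_support,
                                 max_coreg = max_coreg)
  if (length(index$sets) == 0L)
    stop("no frequent co-regulator set; lower min_coreg_support")

  ec <- expr - rowMeans(expr)
  # Mean centered-expression profile of every mined set (regressor cache).
  set_means <- matrix(0, length(index$sets), ncol(expr))
  for (i in seq_along(index$sets))
    set_means[i, ] <- colMeans(ec[index$sets[[i]], , drop = FALSE])

  overlap <- crossprod(index$member)
  prog_rows <- list()
  cand_list <- list()
  dropped <- 0L
  for (gene in targets) {
    code <- d[gene, ]
    cp <- candidate_pairs(code, gene, index, search_thresh, overlap)
    if (length(cp$ai) == 0L) { dropped <- dropped + 1L; next }
    mae <- score_pairs_discrete(cp$ai, cp$ri, code, index$state)
    sizes <- ifelse(cp$ai == 0L, 0L, index$size[pmax(cp$ai, 1L)]) +
      ifelse(cp$ri == 0L, 0L, index$size[pmax(cp$ri, 1L)])
    keys <- paste0(ifelse(cp$ai == 0L, "", index$key[pmax(cp$ai, 1L)]), "|",
                   ifelse(cp$ri == 0L, "", index$key[pmax(cp$ri, 1L)]))
    ord <- order(round12(mae), sizes, keys, method = "radix")
    top <- utils::head(ord, n_grn)

    y <- ec[gene, ]
    cand <- vector("list", length(top))
    for (k in seq_along(top)) {
      i <- top[k]
      abar <- if (cp$ai[i] > 0L) set_means[cp$ai[i], ] else NULL
      rbar <- if (cp$ri[i] > 0L) set_means[cp$ri[i], ] else NULL
      sc <- fit_ols(y, abar, rbar)
      cand[[k]] <- data.frame(
        activators = if (cp$ai[i] > 0L)
          join_ids(index$sets[[cp$ai[i]]]) else "",
        repressors = if (cp$ri[i] > 0L)
          join_ids(index$sets[[cp$ri[i]]]) else "",
        mae = mae[i], size = sizes[i], key = keys[i],
        coef_act = sc$coef_act, coef_rep = sc$coef_rep,
        r2_adj = sc$r2_adj, valid = sc$valid,
        stringsAsFactors = FALSE)
    }
    cand <- do.call(rbind, cand)
    ok <- which(cand$valid)
    if (length(ok) == 0L) { dropped <- dropped + 1L; next }
    best <- ok[order(-round12(cand$r2_adj[ok]), round12(cand$mae[ok]),
                     cand$size[ok], cand$key[ok], method = "radix")][1L]
    prog_rows[[gene]] <- data.frame(
      target = gene,
      activators = cand$activators[best], repressors = cand$repressors[best],
      mae = cand$mae[best], r2_adj = cand$r2_adj[best],
      coef_act = cand$coef_act[best], coef_rep = cand$coef_rep[best],
      stringsAsFactors = FALSE)
    cand_list[[gene]] <- cand[, c("activators", "repressors", "mae",
                                  "coef_act", "coef_rep", "r2_adj", "valid")]
  }
  if (dropped > 0L && verbose)
    message("hlicorn: dropped ", dropped, " gene(s) with no valid program")
  if (length(prog_rows) == 0L)
    stop("no gene received a valid program; diagnostics: ",
         length(targets), " targets tried, ", length(index$sets),
         " frequent sets mined")

  params <- list(min_gene_support = min_gene_support,
                 min_coreg_support = min_coreg_support,
                 max_coreg = max_coreg, search_thresh = search_thresh,
                 n_grn = n_grn, threshold_sd = threshold_sd,
                 centering = centering, n_tf = length(tfs),
                 n_samples = ncol(expr))
  if (verbose)
    message("hlicorn: parameters ",
            paste(names(params), unlist(params), sep = "=", collapse = " "))
  tf_network(do.call(rbind, prog_rows), candidates = cand_list,
             params = params)
}
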