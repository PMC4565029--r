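# External evidence integration: regulatory (TF -> gene, e.g. ChIP-seq or
# TF binding sites) and co-regulatory (TF -- TF, e.g. protein interactions)
# pair sets used to select among inferred candidate programs.

#' Read regulatory / co-regulatory evidence files
#'
#' Each file is a 2-column TSV with a header row.  Regulatory files list
#' (TF, target gene) pairs; co-regulatory files list unordered (TF, TF)
#' pairs.  Pairs are deduplicated per source; co-regulatory self-pairs are
#' dropped with a warning.
#'
#' @param paths character vector of file paths.
#' @param kinds per-file kind, `"regulatory"` or `"coregulatory"` (recycled
#'   if length 1).
#' @param sources per-file source labels (default: file base names).
#' @return an object of class `evidence_set` with data frames `regulatory`
#'   (`tf`, `target`, `source`) and `coregulatory` (`tf1`, `tf2`, `source`,
#'   with `tf1 < tf2`).
#' @export
read_evidence <- function(paths, kinds, sources = NULL) {
  if (length(kinds) == 1L) kinds <- rep(kinds, length(paths))
  stopifnot(length(kinds) == length(paths),
            all(kinds %in% c("regulatory", "coregulatory")))
  if (is.null(sources)) sources <- basename(paths)
  reg <- list()
  coreg <- list()
  for (i in seq_along(paths)) {
    df <- utils::read.table(paths[i], header = TRUE, sep = "\t", quote = "",
                            stringsAsFactors = FALSE, comment.char = "")
    if (ncol(df) < 2L)
      stop("evidence file needs 2 columns: ", paths[i])
    a <- as.character(df[[1L]])
    b <- as.character(df[[2L]])
    if (kinds[i] == "regulatory") {
      pairs <- unique(data.frame(tf = a, target = b,
                                 stringsAsFactors = FALSE))
      pairs$source <- rep(sources[i], nrow(pairs))
      reg[[length(reg) + 1L]] <- pairs
    } else {
      self <- a == b
      if (any(self))
        warning("dropping ", sum(self), " self-pair(s) in ", paths[i])
      a2 <- pmin(a[!self], b[!self])
      b2 <- pmax(a[!self], b[!self])
      pairs <- unique(data.frame(tf1 = a2, tf2 = b2,
                                 stringsAsFactors = FALSE))
      pairs$source <- rep(sources[i], nrow(pairs))
      coreg[[length(coreg) + 1L]] <- pairs
    }
  }
  empty_reg <- data.frame(tf = character(0), target = character(0),
                          source = character(0), stringsAsFactors = FALSE)
  empty_coreg <- data.frame(tf1 = character(0), tf2 = character(0),
                            source = character(0), stringsAsFactors = FALSE)
  structure(list(
    regulatory = if (length(reg)) do.call(rbind, reg) else empty_reg,
    coregulatory = if (length(coreg)) do.call(rbind, coreg)
    else empty_coreg,
    sources = data.frame(source = sources, kind = kinds,
                         stringsAsFactors = FALSE)),
    class = "evidence_set")
}

#' @export
print.evidence_set <- function(x, ...) {
  cat("evidence_set:", nrow(x$regulatory), "regulatory pair(s),",
      nrow(x$coregulatory), "co-regulatory pair(s) from",
      nrow(x$sources), "source(s)\n")
  invisible(x)
}

#' Per-source evidence support of a regulatory program
#'
#' For each regulatory source, the fraction of the program's (TF, target)
#' edges present in that source; for each co-regulatory source, the fraction
#' of unordered TF pairs within the activator set and within the repressor
#' set present in that source.  Programs with fewer than two regulators (or
#' no within-set pair) have co-regulatory support 0.
#'
#' @param activators,repressors character vectors of TF identifiers.
#' @param target target gene identifier.
#' @param ev an `evidence_set`.
#' @return named numeric vector of support fractions, one per source.
#' @export
evidence_support <- function(activators, repressors, target, ev) {
  regs <- c(activators, repressors)
  out <- numeric(nrow(ev$sources))
  names(out) <- ev$sources$source
  within_pairs <- function(s) {
    if (length(s) < 2L) return(NULL)
    cbind(t(utils::combn(sort(s), 2L)))
  }
  pr <- rbind(within_pairs(activators), within_pairs(repressors))
  for (i in seq_len(nrow(ev$sources))) {
    src <- ev$sources$source[i]
    if (ev$sources$kind[i] == "regulatory") {
      have <- ev$regulatory[ev$regulatory$source == src, , drop = FALSE]
      if (length(regs) == 0L) next
      hit <- paste(regs, target) %in% paste(have$tf, have$target)
      out[i] <- mean(hit)
    } else {
      if (length(regs) < 2L || is.null(pr)) next
      have <- ev$coregulatory[ev$coregulatory$source == src, , drop = FALSE]
      hit <- paste(pr[, 1L], pr[, 2L]) %in% paste(have$tf1, have$tf2)
      out[i] <- mean(hit)
    }
  }
  out
}

#' Refine a network with external evidence (integrative selection)
#'
#' Re-selects, per gene, the candidate program maximizing an additive
#' integrative score: `w_fit` times the normalized fit rank (best candidate
#' by adjusted R squared -> 1, worst -> 0) plus, per evidence source, its
#' weight times the program's support fraction in that source.  Evidence
#' never creates edges absent from the candidate lists -- it only selects
#' among inferred candidates.  With all weight on fit (or an empty evidence
#' set), refinement is the identity on chosen programs.
#'
#' @param net a `tf_network` retaining candidate lists (from [hlicorn()]).
#' @param ev an `evidence_set`.
#' @param w_fit non-negative fit weight (default 1).
#' @param w_sources named non-negative per-source weights (default 1 each).
#' @return a `tf_network` with re-selected programs (candidates retained).
#' @export
refine_network <- function(net, ev, w_fit = 1, w_sources = NULL) {
  if (is.null(net$candidates))
    stop("network has no candidate lists; re-run hlicorn()")
  if (is.null(w_sources)) {
    w_sources <- rep(1, nrow(ev$sources))
    names(w_sources) <- ev$sources$source
  }
  w_sources <- w_sources[ev$sources$source]
  w_sources[is.na(w_sources)] <- 0
  names(w_sources) <- ev$sources$source
  if (w_fit < 0 || any(w_sources < 0) || (w_fit == 0 && all(w_sources == 0)))
    stop("weights must be non-negative with at least one positive")

  prog_rows <- list()
  for (gene in names(net$candidates)) {
    cand <- net$candidates[[gene]]
    cand <- cand[cand$valid, , drop = FALSE]
    if (nrow(cand) == 0L) next
    rk <- rank(-round12(cand$r2_adj), ties.method = "min")
    norm_fit <- if (nrow(cand) == 1L) 1 else
      (nrow(cand) - rk) / (nrow(cand) - 1)
    supp <- matrix(0, nrow(cand), nrow(ev$sources))
    for (i in seq_len(nrow(cand)))
      supp[i, ] <- evidence_support(split_ids(cand$activators[i]),
                                    split_ids(cand$repressors[i]), gene, ev)
    score <- w_fit * norm_fit + as.vector(supp %*% w_sources)
    size <- lengths(lapply(cand$activators, split_ids)) +
      lengths(lapply(cand$repressors, split_ids))
    key <- mapply(function(a, r) program_key(split_ids(a), split_ids(r)),
                  cand$activators, cand$repressors, USE.NAMES = FALSE)
    best <- order(-round12(score), -round12(cand$r2_adj),
                  round12(cand$mae), size, key, method = "radix")[1L]
    prog_rows[[gene]] <- data.frame(
      target = gene, activators = cand$activators[best],
      repressors = cand$repressors[best], mae = cand$mae[best],
      r2_adj = cand$r2_adj[best], coef_act = cand$coef_act[best],
      coef_rep = cand$coef_rep[best], stringsAsFactors = FALSE)
  }
  params <- net$params
  params$refined <- TRUE
  params$w_fit <- w_fit
  params$w_sources <- w_sources
  tf_network(do.call(rbind, prog_rows), candidates = net$candidates,
             params = params)
}
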