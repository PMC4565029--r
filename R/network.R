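#' Construct a co-regulatory network object
#'
#' A `tf_network` holds one chosen regulatory program per retained target
#' gene: a set of co-activators and a disjoint set of co-repressors with the
#' program's discrete fit (mean absolute error of the ternary truth-table
#' prediction, in \[0, 2\]) and its continuous fit (adjusted R squared of the
#' linear re-scoring).  Networks produced by [hlicorn()] additionally retain
#' the ranked candidate program list of every gene, which downstream
#' evidence-based refinement selects from.
#'
#' @param programs data frame with columns `target`, `activators`,
#'   `repressors` (semicolon-joined identifier strings), `mae`, `r2_adj` and
#'   optionally `coef_act`, `coef_rep`.
#' @param candidates optional named list (one entry per target) of candidate
#'   data frames with the same columns plus `valid`.
#' @param params list of inference parameters recorded for provenance.
#' @return an object of class `tf_network`.
#' @export
tf_network <- function(programs, candidates = NULL, params = list()) {
  req <- c("target", "activators", "repressors", "mae", "r2_adj")
  if (!all(req %in% names(programs)))
    stop("programs must have columns: ", paste(req, collapse = ", "))
  programs$target <- as.character(programs$target)
  programs$activators <- as.character(programs$activators)
  programs$repressors <- as.character(programs$repressors)
  if (anyDuplicated(programs$target))
    stop("one program per target expected")
  for (i in seq_len(nrow(programs))) {
    a <- split_ids(programs$activators[i])
    r <- split_ids(programs$repressors[i])
    if (length(intersect(a, r)))
      stop("activators and repressors overlap for target ",
           programs$target[i])
    if (length(a) + length(r) == 0L)
      stop("empty regulator set for target ", programs$target[i])
    if (programs$target[i] %in% c(a, r))
      stop("self-regulation forbidden (target ", programs$target[i], ")")
  }
  rownames(programs) <- NULL
  structure(list(programs = programs, candidates = candidates,
                 params = params),
            class = "tf_network")
}

#' @export
print.tf_network <- function(x, ...) {
  e <- network_edges(x)
  cat("tf_network:", nrow(x$programs), "target programs,",
      length(unique(e$tf)), "regulators,", nrow(e), "signed edges\n")
  if (!is.null(x$candidates))
    cat("  candidate lists retained (",
        sum(vapply(x$candidates, nrow, 1L)), " candidates )\n", sep = "")
  invisible(x)
}

#' Signed regulator-to-target edge list of a network
#'
#' @param net a `tf_network`.
#' @return data frame with columns `tf`, `target`, `sign` (+1 activation,
#'   -1 repression).
#' @export
network_edges <- function(net) {
  p <- net$programs
  acts <- lapply(p$activators, split_ids)
  reps <- lapply(p$repressors, split_ids)
  data.frame(
    tf = c(unlist(acts), unlist(reps)),
    target = c(rep(p$target, lengths(acts)), rep(p$target, lengths(reps))),
    sign = c(rep(1L, sum(lengths(acts))), rep(-1L, sum(lengths(reps)))),
    stringsAsFactors = FALSE)
}

#' Regulator-centric index of a network
#'
#' Inverts the per-target programs into a per-TF view.  The index is exactly
#' the inversion of the programs: a gene is in `activated(t)` iff `t` is an
#' activator of the gene's program.
#'
#' @param net a `tf_network`.
#' @return named list (sorted TF identifiers); each element is a list with
#'   character vectors `activated` and `repressed`.
#' @export
tf_index <- function(net) {
  e <- network_edges(net)
  tfs <- sort(unique(e$tf))
  out <- lapply(tfs, function(t) {
    list(activated = sort(e$target[e$tf == t & e$sign == 1L]),
         repressed = sort(e$target[e$tf == t & e$sign == -1L]))
  })
  names(out) <- tfs
  out
}

# Rebuild a tf_network from a signed edge list (used by perturbation).
network_from_edges <- function(edges, params = list()) {
  stopifnot(all(c("tf", "target", "sign") %in% names(edges)))
  targets <- unique(edges$target)
  programs <- data.frame(
    target = targets,
    activators = vapply(targets, function(g)
      join_ids(edges$tf[edges$target == g & edges$sign == 1L]), ""),
    repressors = vapply(targets, function(g)
      join_ids(edges$tf[edges$target == g & edges$sign == -1L]), ""),
    mae = NA_real_, r2_adj = NA_real_,
    stringsAsFactors = FALSE)
  tf_network(programs, candidates = NULL, params = params)
}

#' Write a network to file
#'
#' Two formats are supported: `grn-tsv`, one row per program with columns
#' `target`, `activators`, `repressors` (semicolon-joined), `mae`, `r2_adj`;
#' and `sif` (simple interaction format), one row per signed edge,
#' `TF activates|represses gene`, consumable by Cytoscape-class viewers.
#'
#' @param net a `tf_network`.
#' @param path output path.
#' @param format `"grn-tsv"` or `"sif"`.
#' @return `path`, invisibly.
#' @seealso [read_network()]
#' @export
write_network <- function(net, path, format = c("grn-tsv", "sif")) {
  format <- match.arg(format)
  if (format == "grn-tsv") {
    cols <- c("target", "activators", "repressors", "mae", "r2_adj")
    utils::write.table(net$programs[, cols], path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    e <- network_edges(net)
    lines <- paste(e$tf, ifelse(e$sign == 1L, "activates", "represses"),
                   e$target, sep = "\t")
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read a network from a grn-tsv file
#'
#' @param path path to a file written by [write_network()] with format
#'   `grn-tsv`.
#' @return a `tf_network` (without candidate lists).
#' @export
read_network <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE, comment.char = "",
                          colClasses = c("character", "character", "character",
                                         "numeric", "numeric"))
  if (nrow(df) == 0L)
    return(structure(list(programs = df, candidates = NULL, params = list()),
                     class = "tf_network"))
  df$activators[is.na(df$activators)] <- ""
  df$repressors[is.na(df$repressors)] <- ""
  tf_network(df)
}
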