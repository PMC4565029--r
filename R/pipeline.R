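# End-to-end pipeline: infer -> [refine] -> influence -> cooperativity,
# with a provenance file making every output reproducible.

#' Read a plain-text run configuration
#'
#' `key = value` lines; blank lines and `#` comments ignored.  Values are
#' kept as strings; [run_pipeline()] coerces what it needs.
#'
#' @param path path to the configuration file.
#' @return named list of strings.
#' @export
read_run_config <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  bad <- lengths(kv) != 3L
  if (any(bad)) stop("malformed config line: ", lines[bad][1L])
  out <- lapply(kv, function(m) trimws(m[3L]))
  names(out) <- vapply(kv, function(m) trimws(m[2L]), "")
  out
}

# Default pipeline parameters; config entries override.
pipeline_defaults <- function() {
  list(min_gene_support = 0.1, min_coreg_support = 0.1, max_coreg = 3,
       search_thresh = 1/3, n_grn = 100, threshold_sd = 1,
       centering = "gene-mean", min_targets = 10, alpha = 0.05,
       min_shared = 1, w_fit = 1, seed = 1)
}

#' Run the full inference pipeline
#'
#' Reads the expression matrix and TF list, infers the network with
#' [hlicorn()], optionally refines it against evidence files with
#' [refine_network()], computes the influence matrix and the co-regulation
#' network, and writes every artifact plus a `provenance.txt` capturing all
#' parameters, inputs and the package version (no timestamps, so identical
#' configurations yield byte-identical outputs).
#'
#' @param config named list or path to a `key = value` file.  Required keys:
#'   `expr` (expression TSV) and `tf` (TF list).  Optional: `evidence`
#'   (comma-separated `path:kind` entries with kind `regulatory` or
#'   `coregulatory`) and any parameter of [hlicorn()],
#'   [influence_matrix()] or [build_coregulation_network()].
#' @param out_dir output directory (created if missing).
#' @param verbose emit stage messages.
#' @return invisibly, a list with `network`, `influence`, `coregulation`
#'   and the written `paths`.
#' @export
run_pipeline <- function(config, out_dir, verbose = TRUE) {
  if (is.character(config) && length(config) == 1L)
    config <- read_run_config(config)
  p <- pipeline_defaults()
  for (k in intersect(names(p), names(config)))
    p[[k]] <- if (is.character(p[[k]])) as.character(config[[k]])
  else as.numeric(config[[k]])
  if (is.null(config$expr) || is.null(config$tf))
    stop("[input] config must provide 'expr' and 'tf' paths")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  expr <- tryCatch(read_expression(config$expr),
                   error = function(e) stop("[read-expression] ",
                                            conditionMessage(e)))
  tfs <- tryCatch(read_tf_list(config$tf),
                  error = function(e) stop("[read-tf] ",
                                           conditionMessage(e)))
  net <- tryCatch(
    hlicorn(expr, tfs,
            min_gene_support = p$min_gene_support,
            min_coreg_support = p$min_coreg_support,
            max_coreg = as.integer(p$max_coreg),
            search_thresh = p$search_thresh, n_grn = as.integer(p$n_grn),
            threshold_sd = p$threshold_sd, centering = p$centering,
            verbose = verbose),
    error = function(e) stop("[infer] ", conditionMessage(e)))

  if (!is.null(config$evidence) && nzchar(config$evidence)) {
    entries <- strsplit(strsplit(config$evidence, ",", fixed = TRUE)[[1L]],
                        ":", fixed = TRUE)
    if (any(lengths(entries) != 2L))
      stop("[refine] evidence entries must be path:kind")
    ev <- read_evidence(vapply(entries, `[`, "", 1L),
                        vapply(entries, `[`, "", 2L))
    net <- tryCatch(refine_network(net, ev, w_fit = p$w_fit),
                    error = function(e) stop("[refine] ",
                                             conditionMessage(e)))
  }

  paths <- list(network = file.path(out_dir, "network.grn.tsv"),
                sif = file.path(out_dir, "network.sif"),
                influence = file.path(out_dir, "influence.tsv"),
                coop = file.path(out_dir, "coregulation.tsv"),
                coop_sif = file.path(out_dir, "coregulation.sif"),
                provenance = file.path(out_dir, "provenance.txt"))
  write_network(net, paths$network, "grn-tsv")
  write_network(net, paths$sif, "sif")

  infl <- tryCatch(
    influence_matrix(net, expr, min_targets = as.integer(p$min_targets)),
    error = function(e) stop("[influence] ", conditionMessage(e)))
  write_expression(unclass(infl), paths$influence, id_col = "tf_id")

  coop <- tryCatch(
    build_coregulation_network(net, alpha = p$alpha,
                               min_shared = as.integer(p$min_shared)),
    error = function(e) stop("[coop] ", conditionMessage(e)))
  write_coregulation(coop, paths$coop, "tsv")
  write_coregulation(coop, paths$coop_sif, "sif")

  prov <- c(
    paste0("package_version = ", as.character(utils::packageVersion("licornr"))),
    paste0("expr = ", config$expr),
    paste0("tf = ", config$tf),
    paste0("evidence = ", config$evidence %||% ""),
    vapply(names(p), function(k) paste0(k, " = ", p[[k]]), ""))
  writeLines(prov, paths$provenance)
  if (verbose) message("run_pipeline: artifacts written to ", out_dir)
  invisible(list(network = net, influence = infl, coregulation = coop,
                 paths = paths))
}
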