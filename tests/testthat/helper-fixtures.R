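# Shared fixtures: all test data is built in code.

make_expr <- function(n_genes, n_samples, seed = 1, prefix = "g") {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * n_samples), n_genes, n_samples,
              dimnames = list(sprintf("%s%02d", prefix, seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samples))))
  m
}

# A hand-built network: one program per row of `spec_df` with columns
# target, activators, repressors (semicolon-joined strings).
make_net <- function(target, activators, repressors,
                     mae = NA_real_, r2_adj = NA_real_) {
  tf_network(data.frame(target = target, activators = activators,
                        repressors = repressors, mae = mae, r2_adj = r2_adj,
                        stringsAsFactors = FALSE))
}

# Small synthetic dataset + inference with the benchmark protocol
# (support floor of 2 samples, pair-sized programs).
small_inference <- function(seed = 3, n_tf = 6, n_genes = 25,
                            n_samples = 40) {
  ds <- generate_synthetic(synthetic_spec(n_tf = n_tf, n_genes = n_genes,
                                          n_samples = n_samples,
                                          seed = seed))
  net <- hlicorn(ds$expr, ds$tfs,
                 targets = setdiff(rownames(ds$expr), ds$tfs),
                 min_coreg_support = 0.05, max_coreg = 2, verbose = FALSE)
  list(ds = ds, net = net)
}
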