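test_that("the collective state follows the unanimity rule", {
  expect_identical(collective_state(c(1L, 1L)), 1L)
  expect_identical(collective_state(c(-1L, -1L, -1L)), -1L)
  expect_identical(collective_state(c(1L, 0L)), 0L)
  expect_identical(collective_state(c(1L, -1L)), 0L)
  expect_identical(collective_state(integer(0)), 0L)
})

test_that("the prediction table is antisymmetric and monotone", {
  grid <- expand.grid(a = -1:1, r = -1:1)
  # full 9-cell table
  expect_identical(licorn_predict(grid$a, grid$r),
                   c(0L, 1L, 1L, -1L, 0L, 1L, -1L, -1L, 0L))
  expect_identical(licorn_predict(1L, -1L), 1L)
  expect_identical(licorn_predict(0L, 0L), 0L)
  # antisymmetry and monotonicity over all cells
  for (i in seq_len(nrow(grid))) {
    a <- grid$a[i]; r <- grid$r[i]
    expect_identical(licorn_predict(a, r), -licorn_predict(-a, -r))
    if (a < 1L)
      expect_gte(licorn_predict(a + 1L, r), licorn_predict(a, r))
    if (r < 1L)
      expect_lte(licorn_predict(a, r + 1L), licorn_predict(a, r))
  }
})

test_that("discrete program scoring reproduces direct arithmetic", {
  d <- rbind(t1 = c(1L, 0L, -1L), t2 = c(1L, 1L, -1L),
             g_perfect = c(1L, 0L, -1L), g_anti = c(-1L, -1L, -1L),
             g_third = c(1L, 0L, -1L))
  colnames(d) <- paste0("s", 1:3)
  # t1 alone predicts (1, 0, -1)
  expect_equal(score_program_discrete("t1", character(0), "g_perfect", d), 0)
  # prediction (1, 0, -1) against target (-1, -1, -1): errors 2, 1, 0
  expect_equal(score_program_discrete("t1", character(0), "g_anti", d), 1)
  # t2 alone predicts (1, 1, -1) against (1, 0, -1): one error of 1
  expect_equal(score_program_discrete("t2", character(0), "g_third", d), 1/3)
  expect_error(score_program_discrete("nope", character(0), "g_third", d),
               "absent")
  # MAE is bounded by [0, 2] on random instances
  for (seed in 1:5) {
    set.seed(seed)
    dr <- matrix(sample(c(-1L, 0L, 1L), 40, replace = TRUE), 4, 10,
                 dimnames = list(c("a", "b", "c", "g"), paste0("s", 1:10)))
    mae <- score_program_discrete(c("a", "b"), "c", "g", dr)
    expect_gte(mae, 0); expect_lte(mae, 2)
  }
})

test_that("frequent set mining matches exhaustive support counting", {
  # worked example: TF1 at +1 in samples 1-3, TF2 at +1 in samples 2-3
  d <- rbind(TF1 = c(1L, 1L, 1L, 0L), TF2 = c(0L, 1L, 1L, -1L))
  colnames(d) <- paste0("s", 1:4)
  idx <- mine_coregulator_sets(d, min_coreg_support = 0.5, max_coreg = 2)
  expect_setequal(idx$key, c("TF1", "TF2", "TF1,TF2"))
  sup <- lengths(idx$sup_pos) / idx$n_samples
  names(sup) <- idx$key
  expect_equal(unname(sup[c("TF1", "TF2", "TF1,TF2")]), c(0.75, 0.5, 0.5))

  # impossible support -> empty index (with a message)
  expect_message(
    idx0 <- mine_coregulator_sets(d, min_coreg_support = 1, max_coreg = 2),
    "no frequent set")
  expect_length(idx0$sets, 0)

  # brute-force recount of every reported set's support, both contexts
  set.seed(21)
  d2 <- matrix(sample(c(-1L, 0L, 1L), 5 * 30, replace = TRUE), 5, 30,
               dimnames = list(paste0("T", 1:5), paste0("s", 1:30)))
  idx2 <- mine_coregulator_sets(d2, min_coreg_support = 0.1, max_coreg = 3)
  for (i in seq_along(idx2$sets)) {
    s <- idx2$sets[[i]]
    pos_bf <- sum(colSums(d2[s, , drop = FALSE] == 1L) == length(s))
    neg_bf <- sum(colSums(d2[s, , drop = FALSE] == -1L) == length(s))
    expect_equal(length(idx2$sup_pos[[i]]), pos_bf)
    expect_equal(length(idx2$sup_neg[[i]]), neg_bf)
    expect_true(max(pos_bf, neg_bf) >= ceiling(0.1 * 30 - 1e-9))
  }
  # subset closure within each context
  for (i in which(idx2$size > 1)) {
    for (drop in seq_along(idx2$sets[[i]])) {
      sub <- paste(idx2$sets[[i]][-drop], collapse = ",")
      expect_true(sub %in% idx2$key)
      j <- match(sub, idx2$key)
      if (idx2$freq_pos[i]) expect_true(idx2$freq_pos[j])
      if (idx2$freq_neg[i]) expect_true(idx2$freq_neg[j])
    }
  }
})

test_that("coherence keeps copies as activators and mirrors as repressors", {
  set.seed(2)
  code <- sample(c(-1L, 0L, 1L), 30, replace = TRUE)
  d <- rbind(same = code, anti = -code, noise = sample(code), g = code)
  colnames(d) <- paste0("s", 1:30)
  idx <- mine_coregulator_sets(d[c("same", "anti", "noise"), ],
                               min_coreg_support = 0.05, max_coreg = 2)
  cand <- generate_candidates("g", d, idx, search_thresh = 1)
  expect_true("same" %in% cand$activators)
  expect_true("anti" %in% cand$repressors)
  expect_false("same" %in% cand$repressors)
  # the gene never appears in its own candidates
  cand_tf <- generate_candidates("same", d[c("same", "anti", "noise"), ],
                                 idx, search_thresh = 0)
  expect_false(any(grepl("same", cand_tf$activators)))
  expect_false(any(grepl("same", cand_tf$repressors)))
})

test_that("candidate generation equals a brute-force coherence filter", {
  set.seed(14)
  d <- matrix(sample(c(-1L, 0L, 1L), 5 * 24, replace = TRUE), 5, 24,
              dimnames = list(c("T1", "T2", "T3", "T4", "g"),
                              paste0("s", 1:24)))
  tfs <- c("T1", "T2", "T3", "T4")
  idx <- mine_coregulator_sets(d[tfs, ], min_coreg_support = 0.1,
                               max_coreg = 2)
  thr <- 1/3
  cand <- generate_candidates("g", d, idx, search_thresh = thr)
  code <- d["g", ]
  frac <- function(sup, val) if (length(sup) == 0) 1 else
    mean(code[sup] == val)
  a_bf <- r_bf <- character(0)
  for (i in seq_along(idx$sets)) {
    sp <- idx$sup_pos[[i]]; sn <- idx$sup_neg[[i]]
    key <- paste(sort(idx$sets[[i]]), collapse = ";")
    if (frac(sp, 1L) >= thr && frac(sn, -1L) >= thr) a_bf <- c(a_bf, key)
    if (frac(sp, -1L) >= thr && frac(sn, 1L) >= thr) r_bf <- c(r_bf, key)
  }
  expect_setequal(setdiff(unique(cand$activators), ""), a_bf)
  expect_setequal(setdiff(unique(cand$repressors), ""), r_bf)
})

test_that("continuous re-scoring recovers exact linear programs", {
  set.seed(5)
  t1 <- rnorm(20); t2 <- rnorm(20); t3 <- rnorm(20)
  y <- 2 * (t1 - mean(t1)) - ((t2 - mean(t2)) + (t3 - mean(t3))) / 2
  expr <- rbind(t1 = t1, t2 = t2, t3 = t3, g = y)
  colnames(expr) <- paste0("s", 1:20)
  sc <- score_program_continuous("t1", c("t2", "t3"), "g", expr)
  expect_true(sc$valid)
  expect_equal(sc$coef_act, 2, tolerance = 1e-10)
  expect_equal(sc$coef_rep, -1, tolerance = 1e-10)
  expect_equal(sc$r2_adj, 1, tolerance = 1e-10)
})

test_that("orthogonal targets score at zero with non-positive adjusted R2", {
  expr <- rbind(t1 = c(1, -1, 1, -1), t2 = c(1, 1, -1, -1),
                g = c(1, -1, -1, 1))
  colnames(expr) <- paste0("s", 1:4)
  sc <- score_program_continuous("t1", "t2", "g", expr)
  expect_lt(abs(sc$coef_act), 1e-10)
  expect_lt(abs(sc$coef_rep), 1e-10)
  expect_lte(sc$r2_adj, 0)
})

test_that("coefficients match the normal-equation solution", {
  set.seed(8)
  expr <- make_expr(5, 5, seed = 8, prefix = "t")
  rownames(expr) <- c("t1", "t2", "t3", "t4", "g")
  sc <- score_program_continuous(c("t1", "t2"), "t3", "g", expr)
  ec <- expr - rowMeans(expr)
  X <- cbind(1, colMeans(ec[c("t1", "t2"), ]), ec["t3", ])
  beta <- solve(t(X) %*% X, t(X) %*% ec["g", ])
  expect_equal(sc$coef_act, beta[2], tolerance = 1e-10)
  expect_equal(sc$coef_rep, beta[3], tolerance = 1e-10)
})

test_that("sign-incoherent and collinear programs are rejected", {
  set.seed(9)
  t1 <- rnorm(15)
  expr <- rbind(t1 = t1, t2 = -t1 + rnorm(15, sd = 1e-5), g = -2 * t1)
  colnames(expr) <- paste0("s", 1:15)
  # activator fitted with a negative coefficient -> rejected
  sc <- score_program_continuous("t1", character(0), "g", expr)
  expect_false(sc$valid)
  expect_match(sc$reason, "negative activator")
  # near-perfectly anticorrelated regressors -> rejected as collinear
  sc2 <- score_program_continuous("t1", "t2", "g", expr)
  expect_false(sc2$valid)
  expect_match(sc2$reason, "collinear")
})

test_that("noise-free singleton programs are recovered exactly", {
  ds <- generate_synthetic(synthetic_spec(
    n_tf = 6, n_genes = 20, n_samples = 30, noise_sd = 0,
    act_set_size = c(1, 1), rep_set_size = c(0, 0),
    coactivation_bias = 0, seed = 17))
  net <- hlicorn(ds$expr, ds$tfs,
                 targets = setdiff(rownames(ds$expr), ds$tfs),
                 min_coreg_support = 0.05, max_coreg = 2, verbose = FALSE)
  truth <- ds$truth$programs[order(ds$truth$programs$target), ]
  got <- net$programs[order(net$programs$target), ]
  expect_identical(got$target, truth$target)
  expect_identical(got$activators, truth$activators)
  expect_identical(got$repressors, truth$repressors)
  expect_true(all(got$mae == 0))
  expect_equal(got$r2_adj, rep(1, nrow(got)), tolerance = 1e-10)
})

test_that("a gene is never its own regulator and runs are deterministic", {
  run <- small_inference(seed = 6)
  ds <- run$ds
  # include TF rows as potential targets: self-exclusion must hold
  net <- hlicorn(ds$expr, ds$tfs, min_coreg_support = 0.05,
                 max_coreg = 2, verbose = FALSE)
  for (i in seq_len(nrow(net$programs))) {
    regs <- c(strsplit(net$programs$activators[i], ";")[[1]],
              strsplit(net$programs$repressors[i], ";")[[1]])
    expect_false(net$programs$target[i] %in% regs)
  }
  net2 <- hlicorn(ds$expr, ds$tfs, min_coreg_support = 0.05,
                  max_coreg = 2, verbose = FALSE)
  expect_identical(net$programs, net2$programs)
  expect_identical(net$candidates, net2$candidates)
  expect_error(hlicorn(ds$expr, "TF1", verbose = FALSE), "at least 2 TFs")
})

test_that("inference matches the exhaustive oracle on a small instance", {
  ds <- generate_synthetic(synthetic_spec(n_tf = 4, n_genes = 6,
                                          n_samples = 20, seed = 23))
  genes <- setdiff(rownames(ds$expr), ds$tfs)
  net <- hlicorn(ds$expr, ds$tfs, targets = genes,
                 min_coreg_support = 0, search_thresh = 0,
                 max_coreg = 2, verbose = FALSE)
  d <- oracle_discretize(ds$expr)
  retained <- rownames(d)[rowSums(d != 0) >= ceiling(0.1 * ncol(d) - 1e-9)]
  for (g in intersect(genes, retained)) {
    best <- oracle_best_program(g, ds$expr, d, ds$tfs)
    i <- match(g, net$programs$target)
    if (is.null(best)) {
      expect_true(is.na(i))
    } else {
      expect_identical(net$programs$activators[i],
                       paste(sort(best$A), collapse = ";"))
      expect_identical(net$programs$repressors[i],
                       paste(sort(best$R), collapse = ";"))
      expect_equal(net$programs$mae[i], best$mae, tolerance = 1e-12)
      expect_equal(net$programs$r2_adj[i], best$r2_adj, tolerance = 1e-9)
    }
  }
})

test_that("the discrete MAE of a fixed program never improves under noise", {
  # a program fitting perfectly on clean samples: appending samples with
  # randomized target codes cannot lower the MAE (10 seeds)
  base <- rbind(t1 = c(1L, 0L, -1L, 1L, -1L), g = c(1L, 0L, -1L, 1L, -1L))
  colnames(base) <- paste0("s", 1:5)
  mae0 <- score_program_discrete("t1", character(0), "g", base)
  expect_equal(mae0, 0)
  maes <- vapply(1:10, function(seed) {
    set.seed(seed)
    extra <- rbind(t1 = sample(c(-1L, 0L, 1L), 5, replace = TRUE),
                   g = sample(c(-1L, 0L, 1L), 5, replace = TRUE))
    colnames(extra) <- paste0("x", 1:5)
    score_program_discrete("t1", character(0), "g", cbind(base, extra))
  }, 1)
  expect_true(all(maes >= mae0))
  expect_gt(mean(maes), mae0)
})
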