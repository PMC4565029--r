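# Rows with zero mean so that internal centering leaves values intact.
balanced_expr <- function() {
  m <- rbind(a1 = c(1, -1), a2 = c(3, -3), r1 = c(-1, 1), r2 = c(-3, 3))
  colnames(m) <- c("s1", "s2")
  m
}

test_that("influence equals the hand-computed Welch statistic", {
  net <- make_net(c("a1", "a2", "r1", "r2"),
                  activators = c("t1", "t1", "", ""),
                  repressors = c("", "", "t1", "t1"))
  infl <- influence_matrix(net, balanced_expr(), min_targets = 4)
  # sample s1: activated (1, 3), repressed (-1, -3):
  # (2 - (-2)) / sqrt(2/2 + 2/2) = 2 * sqrt(2)
  expect_equal(infl["t1", "s1"], 2 * sqrt(2), tolerance = 1e-12)
  expect_equal(infl["t1", "s2"], -2 * sqrt(2), tolerance = 1e-12)
  tg <- attr(infl, "targets")
  expect_equal(tg$n_act, 2)
  expect_equal(tg$n_rep, 2)
})

test_that("swapping activated and repressed targets negates influence", {
  net <- make_net(c("a1", "a2", "r1", "r2"),
                  activators = c("t1", "t1", "", ""),
                  repressors = c("", "", "t1", "t1"))
  swapped <- make_net(c("a1", "a2", "r1", "r2"),
                      activators = c("", "", "t1", "t1"),
                      repressors = c("t1", "t1", "", ""))
  m <- make_expr(4, 10, seed = 3)
  rownames(m) <- c("a1", "a2", "r1", "r2")
  i1 <- influence_matrix(net, m, min_targets = 4)
  i2 <- influence_matrix(swapped, m, min_targets = 4)
  expect_equal(unclass(i1), -unclass(i2), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("identical activated and repressed values give zero influence", {
  m <- rbind(a1 = c(1, 2, 3), a2 = c(4, 5, 6),
             r1 = c(1, 2, 3), r2 = c(4, 5, 6))
  colnames(m) <- paste0("s", 1:3)
  net <- make_net(c("a1", "a2", "r1", "r2"),
                  activators = c("t1", "t1", "", ""),
                  repressors = c("", "", "t1", "t1"))
  infl <- influence_matrix(net, m, min_targets = 4)
  expect_true(all(infl["t1", ] == 0))
})

test_that("influence matches stats::t.test on random cases", {
  worst <- 0
  for (case in 1:100) {
    set.seed(case)
    n_act <- sample(2:6, 1)
    n_rep <- sample(2:6, 1)
    m <- make_expr(n_act + n_rep, 8, seed = case + 1000)
    acts <- rownames(m)[seq_len(n_act)]
    reps <- rownames(m)[n_act + seq_len(n_rep)]
    net <- make_net(rownames(m),
                    activators = c(rep("t1", n_act), rep("", n_rep)),
                    repressors = c(rep("", n_act), rep("t1", n_rep)))
    infl <- influence_matrix(net, m, min_targets = 4)
    s <- sample(colnames(m), 1)
    ec <- m - rowMeans(m)
    tt <- unname(t.test(ec[acts, s], ec[reps, s])$statistic)
    worst <- max(worst, abs(infl["t1", s] - tt))
  }
  expect_lt(worst, 1e-10)
})

test_that("influence is invariant to per-sample constant shifts", {
  m <- make_expr(8, 6, seed = 12)
  net <- make_net(rownames(m),
                  activators = c(rep("t1", 4), rep("", 4)),
                  repressors = c(rep("", 4), rep("t1", 4)))
  shift <- matrix(rep(rnorm(6), each = nrow(m)), nrow(m))
  i1 <- influence_matrix(net, m, min_targets = 4)
  i2 <- influence_matrix(net, m + shift, min_targets = 4)
  expect_equal(unclass(i1), unclass(i2), tolerance = 1e-9)
})

test_that("TFs below the minimum-target rule are excluded", {
  m <- make_expr(6, 5, seed = 2)
  net <- make_net(rownames(m),
                  activators = c(rep("big", 4), "small", "small"),
                  repressors = "")
  infl <- influence_matrix(net, m, min_targets = 3)
  expect_identical(rownames(infl), "big")
  expect_error(influence_matrix(net, m, min_targets = 10), "no TF")
})

test_that("rewiring preserves edge counts and degenerates correctly", {
  run <- small_inference()
  net <- run$net
  e0 <- network_edges(net)
  # noise 0 is the identity
  p0 <- perturb_network(net, 0, seed = 1)
  a <- p0$programs[order(p0$programs$target),
                   c("target", "activators", "repressors")]
  b <- net$programs[order(net$programs$target),
                    c("target", "activators", "repressors")]
  rownames(a) <- rownames(b) <- NULL
  expect_identical(a, b)
  for (noise in c(0.2, 0.5, 1)) {
    p <- perturb_network(net, noise, seed = 7)
    ep <- network_edges(p)
    expect_equal(nrow(ep), nrow(e0))            # conservation
    expect_true(all(ep$tf != ep$target))        # no self-loops
    # no duplicate signed edges
    expect_false(anyDuplicated(paste(ep$tf, ep$target, ep$sign)) > 0)
  }
  expect_error(perturb_network(net, 1.2), "0, 1")
})

test_that("full rewiring moves every movable edge", {
  net <- make_net(c("g1", "g2"), activators = c("t1", "t2"),
                  repressors = c("", ""))
  p <- perturb_network(net, 1, seed = 5)
  ep <- network_edges(p)
  # the only legal rewiring swaps the two targets
  expect_setequal(paste(ep$tf, ep$target), c("t1 g2", "t2 g1"))
})

test_that("robustness is exact at zero noise and reproducible", {
  run <- small_inference()
  rb <- influence_robustness(run$net, run$ds$expr,
                             noise_levels = c(0, 0.3), n_seeds = 2,
                             min_targets = 5, seed = 4)
  expect_true(all(abs(rb$per_tf[, "0"] - 1) < 1e-12))
  rb2 <- influence_robustness(run$net, run$ds$expr,
                              noise_levels = c(0, 0.3), n_seeds = 2,
                              min_targets = 5, seed = 4)
  expect_identical(rb$per_tf, rb2$per_tf)
  expect_error(influence_robustness(run$net, run$ds$expr,
                                    noise_levels = 0.1), "at least")
})
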