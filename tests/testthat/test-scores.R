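# Exact co-occurrence distributions, tail scores, and Z calibration.

test_that("degenerate distributions are exact", {
  d0 <- cooccurrence_distribution(rep(0, 5))
  expect_equal(d0$probs[1], 1)
  expect_equal(sum(d0$probs), 1)
  expect_equal(d0$n_max, 0)
  d1 <- cooccurrence_distribution(0.5)
  expect_equal(d1$probs[1:2], c(0.5, 0.5))
  expect_error(cooccurrence_distribution(c(0.2, 1.3)), "out of")
})

test_that("the recursion matches exhaustive enumeration on random cases", {
  set.seed(31)
  for (rep in 1:50) {
    M <- sample(1:10, 1)
    w <- runif(M)
    w[runif(M) < 0.2] <- 0          # exercise zero-probability samples
    d <- cooccurrence_distribution(w)
    expect_lt(max(abs(d$probs[seq_len(M + 1)] - enum_pb(w))), 1e-10)
    expect_lt(abs(sum(d$probs) - 1), 1e-10)
  }
})

test_that("tail scores are inclusive negative-log tails", {
  d <- cooccurrence_distribution(c(0.1, 0.2, 0.3))
  expect_equal(unname(tail_scores(d, 0)["S_agg"]), 0)
  expect_equal(unname(tail_scores(d, 3)["S_seg"]), 0)
  en <- enum_pb(c(0.1, 0.2, 0.3))
  expect_equal(unname(tail_scores(d, 3)["S_agg"]), -log(en[4]),
               tolerance = 1e-10)
  expect_equal(unname(tail_scores(d, 2)["S_agg"]), -log(en[3] + en[4]),
               tolerance = 1e-10)
  d1 <- cooccurrence_distribution(0.5)
  expect_equal(unname(tail_scores(d1, 1)["S_agg"]), -log(0.5),
               tolerance = 1e-12)
  expect_error(tail_scores(d, 4), "0..M")
  dz <- cooccurrence_distribution(c(0.4, 0))
  expect_error(tail_scores(dz, 2), "impossible")
})

test_that("aggregation scores grow with the count, segregation scores shrink", {
  set.seed(5)
  d <- cooccurrence_distribution(runif(12))
  s <- t(vapply(0:12, function(n) tail_scores(d, n), numeric(2)))
  expect_true(all(diff(s[, 1]) >= 0))
  expect_true(all(diff(s[, 2]) <= 0))
})

test_that("scores survive extreme tails in log space", {
  # 400 samples at joint probability 0.9, all co-occurring: the upper
  # tail is ~0.9^400 = e^-42, the lower tail underflows linear doubles
  w <- rep(0.9, 400)
  d <- cooccurrence_distribution(w)
  s <- tail_scores(d, 400)
  expect_equal(unname(s["S_agg"]), -400 * log(0.9), tolerance = 1e-8)
  s0 <- tail_scores(d, 0)
  expect_equal(unname(s0["S_seg"]), -400 * log(0.1), tolerance = 1e-6)
  expect_true(is.finite(s0["S_seg"]))
})

test_that("pair scores handle disjoint support and duplicate taxa", {
  # disjoint stratum support: both tails degenerate at zero score
  pi_mat <- rbind(c(0.5, 0.5, 0, 0), c(0, 0, 0.5, 0.5))
  X <- rbind(c(1L, 1L, 0L, 0L), c(0L, 0L, 1L, 1L))
  dimnames(pi_mat) <- dimnames(X) <- list(c("a", "b"), paste0("s", 1:4))
  sc <- pair_scores(presence_matrix(X), fake_model(pi_mat))
  expect_equal(sc$S_agg, 0)
  expect_equal(sc$S_seg, 0)
  expect_equal(sc$n_max, 0)
  # identical duplicate rows present everywhere: S_agg is -log prod(pi^2)
  pi2 <- matrix(runif(6, 0.3, 0.9), 2, 3)
  pi2[2, ] <- pi2[1, ]
  X2 <- matrix(1L, 2, 3)
  sc2 <- pair_scores(presence_matrix(X2), fake_model(pi2))
  expect_equal(sc2$S_agg, -sum(log(pi2[1, ]^2)), tolerance = 1e-10)
})

test_that("all-pair scores match the enumeration oracle on a 10x40 instance", {
  ds <- generate_dataset(synthetic_spec(n_taxa = 10, n_samples = 40,
                                        n_subtypes = 2, seed = 17))
  m <- fit_null_model(ds$presence, ds$env)
  sc <- pair_scores(ds$presence, m)
  for (r in sample(nrow(sc), 12)) {
    i <- match(sc$taxon_i[r], ds$presence$taxa)
    j <- match(sc$taxon_j[r], ds$presence$taxa)
    w <- m$pi[i, ] * m$pi[j, ]
    d <- cooccurrence_distribution(w)
    expect_equal(unname(tail_scores(d, sc$n_ij[r])),
                 c(sc$S_agg[r], sc$S_seg[r]), tolerance = 1e-8)
    expect_equal(sc$n_ij[r],
                 sum(ds$presence$X[i, ] & ds$presence$X[j, ]))
  }
  # inclusive-tail identity on every pair
  expect_lt(max(abs(exp(-sc$S_agg) + exp(-sc$S_seg) - 1 - sc$p_at_n)), 1e-8)
})

test_that("Z calibration standardises against refit replicates", {
  ds <- generate_dataset(synthetic_spec(n_taxa = 12, n_samples = 60,
                                        n_subtypes = 2, seed = 23))
  m <- fit_null_model(ds$presence, ds$env)
  sc <- calibrate_scores(ds$presence, ds$env, m, R = 6, seed = 8)
  reps <- attr(sc, "replicates")
  expect_equal(dim(reps$agg), c(nrow(sc), 6))
  mu <- rowMeans(reps$agg)
  sdv <- apply(reps$agg, 1, sd)
  ok <- sc$evaluable_agg
  expect_equal(sc$Z_agg[ok], ((sc$S_agg - mu) / sdv)[ok], tolerance = 1e-12)
  # determinism
  sc2 <- calibrate_scores(ds$presence, ds$env, m, R = 6, seed = 8)
  expect_equal(sc$Z_agg, sc2$Z_agg)
  # a pair whose score is constant over replicates is non-evaluable
  expect_true(all(is.na(sc$Z_agg[!sc$evaluable_agg])))
})

test_that("pairs with disjoint stratum support are flagged non-evaluable", {
  # two taxa confined to different subtypes: every replicate scores 0
  X <- rbind(a = c(1L, 1L, 0L, 0L, 0L, 0L),
             b = c(0L, 0L, 0L, 1L, 1L, 0L),
             c = c(1L, 0L, 1L, 1L, 0L, 1L))
  colnames(X) <- paste0("s", 1:6)
  env <- environment_hierarchy(data.frame(
    sample = paste0("s", 1:6),
    subtype = rep(c("u", "v"), each = 3),
    type = rep(c("u", "v"), each = 3),
    supertype = "all"))
  m <- fit_null_model(presence_matrix(X), env)
  sc <- calibrate_scores(presence_matrix(X), env, m, R = 5, seed = 2)
  ab <- sc$taxon_i == "a" & sc$taxon_j == "b"
  expect_false(sc$evaluable_agg[ab])
  expect_false(sc$evaluable_seg[ab])
  expect_equal(sc$S_agg[ab], 0)
  expect_equal(sc$S_seg[ab], 0)
})
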