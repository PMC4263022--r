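# FPR/PPV curves, detectability masks, and network construction.

test_that("the empirical-null estimators follow their definitions", {
  expect_equal(ppv_estimate(100, 4), 0.96)
  expect_equal(ppv_estimate(10, 15), 0)       # clamped at zero
  expect_true(is.na(ppv_estimate(0, 2)))
  expect_equal(fpr_estimate(4.1, 10000), 4.1e-4)
})

test_that("calibration curves are monotone and behave at extremes", {
  ds <- generate_dataset(synthetic_spec(n_taxa = 15, n_samples = 100,
                                        n_subtypes = 2, seed = 19))
  m <- fit_null_model(ds$presence, ds$env)
  sc <- calibrate_scores(ds$presence, ds$env, m, R = 8, seed = 5)
  cv <- estimate_fpr_ppv(sc, thresholds = seq(0, 12, 0.5))
  for (ty in c("aggregation", "segregation")) {
    cc <- cv[cv$type == ty, ]
    expect_true(all(diff(cc$obs_count) <= 0))
    expect_true(all(diff(cc$null_mean) <= 0))
    expect_true(all(cc$FPR >= 0 & cc$FPR <= 1))
    expect_true(all(is.na(cc$PPV) | (cc$PPV >= 0 & cc$PPV <= 1)))
  }
})

test_that("a threshold above every null score gives FPR 0 and PPV 1", {
  # three pairs, four replicates with scores near 1; the observed pair 1
  # stands far above every null realization
  df <- data.frame(taxon_i = c("a", "a", "b"), taxon_j = c("b", "c", "c"),
                   n_ij = 1L, S_agg = c(50, 1, 1), S_seg = 1,
                   p_at_n = 0.1, n_max = 10L,
                   S_agg_limit = 60, S_seg_limit = 60,
                   stringsAsFactors = FALSE)
  reps <- matrix(c(1, 1.1, 0.9, 1.05), 3, 4, byrow = TRUE)
  sc <- structure(df, axis = "taxa", ids = c("a", "b", "c"),
                  class = c("score_table", "data.frame"))
  sc$null_mean_agg <- rowMeans(reps); sc$null_sd_agg <- apply(reps, 1, sd)
  sc$null_mean_seg <- sc$null_mean_agg; sc$null_sd_seg <- sc$null_sd_agg
  sc$Z_agg <- (sc$S_agg - sc$null_mean_agg) / sc$null_sd_agg
  sc$Z_seg <- (sc$S_seg - sc$null_mean_seg) / sc$null_sd_seg
  sc$evaluable_agg <- sc$evaluable_seg <- TRUE
  attr(sc, "replicates") <- list(agg = reps, seg = reps)
  attr(sc, "sd_floor") <- 1e-9
  cv <- estimate_fpr_ppv(sc, thresholds = c(0, 30))
  hi <- cv[cv$threshold == 30 & cv$type == "aggregation", ]
  expect_equal(hi$FPR, 0)
  expect_equal(hi$obs_count, 1)
  expect_equal(hi$PPV, 1)
})

test_that("detectability masks match direct tail-probability evaluation", {
  ds <- generate_dataset(synthetic_spec(n_taxa = 10, n_samples = 40,
                                        n_subtypes = 2, habitat_prob = 0.6,
                                        seed = 13))
  m <- fit_null_model(ds$presence, ds$env)
  sc <- pair_scores(ds$presence, m)
  for (T0 in c(1, 3, 6)) {
    mask_a <- detectable_pairs(sc, T0, "aggregation")
    mask_s <- detectable_pairs(sc, T0, "segregation")
    for (r in seq_len(nrow(sc))) {
      i <- match(sc$taxon_i[r], ds$presence$taxa)
      j <- match(sc$taxon_j[r], ds$presence$taxa)
      w <- m$pi[i, ] * m$pi[j, ]
      w <- w[w > 0]
      lim_a <- if (length(w) == 0) 0 else -sum(log(w))
      lim_s <- if (length(w) == 0) 0 else -sum(log1p(-w))
      expect_equal(mask_a[r], lim_a > T0)
      expect_equal(mask_s[r], lim_s > T0)
    }
  }
  # disjoint support is never detectable
  und <- sc$n_max == 0
  if (any(und)) {
    expect_false(any(detectable_pairs(sc, 0.1, "aggregation")[und]))
    expect_false(any(detectable_pairs(sc, 0.1, "segregation")[und]))
  }
  # near-certain joint presence everywhere: segregation always detectable
  pi_hi <- matrix(1 - 1e-6, 2, 10)
  X_hi <- matrix(1L, 2, 10)
  sc_hi <- pair_scores(presence_matrix(X_hi), fake_model(pi_hi))
  expect_true(detectable_pairs(sc_hi, 20, "segregation"))
})

test_that("network construction applies thresholds, flags and conflicts", {
  ds <- generate_dataset(synthetic_spec(n_taxa = 12, n_samples = 80,
                                        n_subtypes = 2, seed = 29))
  m <- fit_null_model(ds$presence, ds$env)
  sc <- calibrate_scores(ds$presence, ds$env, m, R = 6, seed = 4)
  expect_equal(nrow(build_network(sc, Inf, Inf)$edges), 0)
  zmax <- max(sc$Z_agg, na.rm = TRUE)
  net1 <- build_network(sc, zmax - 1e-9, Inf)
  expect_equal(nrow(net1$edges), 1)
  expect_equal(net1$edges$type, "aggregation")
  # edges only on evaluable pairs, no pair with both labels
  net <- build_network(sc, 0.5, 0.5)
  key <- pair_key(net$edges$taxon_i, net$edges$taxon_j)
  expect_equal(anyDuplicated(key), 0)
  # consensus restriction can only shrink the edge set
  net_c <- build_network(sc, 0.5, 0.5, consensus_only = TRUE)
  expect_lte(nrow(net_c$edges), nrow(net$edges))
})

test_that("control networks hit requested edge counts exactly", {
  ds <- generate_dataset(synthetic_spec(n_taxa = 15, n_samples = 100,
                                        n_subtypes = 2, seed = 37))
  m <- fit_null_model(ds$presence, ds$env)
  ctl0 <- build_control_network(m, ds$env, 0, 0, seed = 6, R = 5)
  expect_equal(nrow(ctl0$edges), 0)
  expect_equal(ctl0$provenance, "control")
  ctl <- build_control_network(m, ds$env, 7, 3, seed = 6, R = 5)
  expect_equal(sum(ctl$edges$type == "aggregation"), 7)
  expect_equal(sum(ctl$edges$type == "segregation"), 3)
  expect_equal(anyDuplicated(pair_key(ctl$edges$taxon_i,
                                      ctl$edges$taxon_j)), 0)
  expect_error(build_control_network(m, ds$env, 10000, 0, seed = 6, R = 5),
               "fewer evaluable pairs")
})
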