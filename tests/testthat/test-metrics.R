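# Propensities, nestedness, habitat preference, cosmopolitanism, and
# environment-derived statistics.

test_that("propensity is zero under independence and log 2 in the half case", {
  expect_equal(propensity(25, 50, 50, 100)$value, 0)     # joint = product
  expect_equal(propensity(50, 50, 50, 100)$value, log(2))
  set.seed(3)
  for (rep in 1:20) {
    total <- sample(50:500, 1)
    a <- sample(total, 1); b <- sample(total, 1)
    j <- sample(seq_len(min(a, b)), 1)
    got <- propensity(j, a, b, total)
    expect_equal(got$value,
                 log(j / total) - log(a / total) - log(b / total),
                 tolerance = 1e-12)
    expect_equal(got$value, propensity(j, b, a, total)$value)  # symmetric
  }
  expect_error(propensity(10, 5, 20, 100), "exceeds a marginal")
  expect_false(propensity(0, 5, 20, 100)$defined)
})

test_that("a pure aggregation clique has positive (A|AA) and undefined (S|*)", {
  nodes <- paste0("t", 1:8)               # three nodes stay isolated
  ed <- t(combn(nodes[1:5], 2))
  net <- make_network(data.frame(taxon_i = ed[, 1], taxon_j = ed[, 2],
                                 type = "aggregation", Z = 10,
                                 stringsAsFactors = FALSE), nodes)
  tp <- triangle_propensities(net)
  aAA <- tp[tp$condition == "AA" & tp$type == "aggregation", ]
  expect_true(aAA$defined)
  expect_gt(aAA$propensity, 0)
  expect_false(any(tp$defined[tp$type == "segregation"]))
})

test_that("coin-flip edge types produce triangle propensities near zero", {
  set.seed(77)
  nodes <- paste0("t", 1:40)
  ed <- t(combn(nodes, 2))
  keep <- runif(nrow(ed)) < 0.25
  edges <- data.frame(taxon_i = ed[keep, 1], taxon_j = ed[keep, 2],
                      type = sample(c("aggregation", "segregation"),
                                    sum(keep), TRUE),
                      Z = 10, stringsAsFactors = FALSE)
  tp <- triangle_propensities(make_network(edges, nodes))
  ok <- tp$defined
  expect_true(any(ok))
  expect_true(all(abs(tp$propensity[ok]) < 3 * tp$se[ok] + 0.3))
})

test_that("nestedness hits its boundary cases and closed form", {
  nodes <- c("i", "j", "k1", "k2", "k3", "k4")
  # identical neighbourhoods
  net1 <- make_network(agg_edges("i", "k1", "i", "k2", "j", "k1", "j", "k2"),
                       nodes)
  expect_equal(nestedness(net1, "i", "j"), 1)
  expect_equal(nestedness(net1, "i", "i"), 1)
  # disjoint neighbourhoods
  net2 <- make_network(agg_edges("i", "k1", "j", "k2"), nodes)
  expect_equal(nestedness(net2, "i", "j"), 0)
  # {k1,k2} vs {k2,k3,k4} -> 1/sqrt(6)
  net3 <- make_network(agg_edges("i", "k1", "i", "k2",
                                 "j", "k2", "j", "k3", "j", "k4"), nodes)
  expect_equal(nestedness(net3, "i", "j"), 1 / sqrt(6), tolerance = 1e-12)
  # isolated node undefined
  net4 <- make_network(agg_edges("i", "k1"), nodes)
  expect_true(is.na(nestedness(net4, "i", "j")))
})

test_that("habitat preference needs a strict majority and three samples", {
  mk <- function(counts) {
    M <- sum(counts)
    X <- matrix(1L, 1, M, dimnames = list("t", paste0("s", 1:M)))
    env <- environment_hierarchy(data.frame(
      sample = paste0("s", 1:M),
      subtype = rep(paste0("sub", seq_along(counts)), counts),
      type = rep(paste0("ty", seq_along(counts)), counts),
      supertype = "all"))
    assign_environment_preference(presence_matrix(X), env, "subtype")[[1]]
  }
  expect_equal(mk(c(6, 4)), "sub1")          # 6 of 10
  expect_equal(mk(c(2, 2)), "undefined")     # exactly 50%
  expect_equal(mk(c(3)), "sub1")             # 100% of exactly 3 samples
  expect_equal(mk(c(2, 1)), "undefined")     # majority but below 3 samples
})

test_that("relatedness propensities vanish under label permutation and are
           signed in the extreme case", {
  set.seed(101)
  nodes <- paste0("t", 1:30)
  ed <- t(combn(nodes, 2))
  classes <- data.frame(taxon_i = ed[, 1], taxon_j = ed[, 2],
                        class = sample(c("Same", "Diff"), nrow(ed), TRUE,
                                       prob = c(0.3, 0.7)),
                        stringsAsFactors = FALSE)
  keep <- runif(nrow(ed)) < 0.2
  net <- make_network(data.frame(taxon_i = ed[keep, 1],
                                 taxon_j = ed[keep, 2],
                                 type = "aggregation", Z = 10,
                                 stringsAsFactors = FALSE), nodes)
  rp <- relatedness_propensity(net, classes)
  ok <- rp$defined
  expect_true(all(abs(rp$propensity[ok]) < 3 * rp$se[ok] + 0.3))
  # all aggregations inside one class
  classes2 <- classes
  classes2$class <- ifelse(pair_key(classes2$taxon_i, classes2$taxon_j) %in%
                             pair_key(net$edges$taxon_i, net$edges$taxon_j),
                           "Same", "Diff")
  rp2 <- relatedness_propensity(net, classes2)
  same_a <- rp2[rp2$class == "Same" & rp2$type == "aggregation", ]
  expect_gt(same_a$propensity, 0)
  # a class with fewer than 10 pairs is suppressed
  classes3 <- classes
  classes3$class[1:nrow(ed)] <- "big"
  classes3$class[1:9] <- "tiny"
  rp3 <- relatedness_propensity(net, classes3)
  expect_false("tiny" %in% rp3$class)
})

test_that("phylogenetic pair classes use the deepest shared named rank", {
  tax <- taxonomy_table(data.frame(
    taxon = c("a", "b", "c", "d", "e"),
    phylum = c("P1", "P1", "P1", "P2", ""),
    class = c("C1", "C1", "C2", "C3", ""),
    order = c("O1", "O1", "O2", "O3", ""),
    family = c("F1", "F2", "F3", "F4", "")))
  pc <- pair_phylo_relatedness(tax)
  get <- function(i, j) pc$class[pc$taxon_i == i & pc$taxon_j == j]
  expect_equal(get("a", "b"), "order")
  expect_equal(get("a", "c"), "phylum")
  expect_equal(get("a", "d"), "root")
  expect_equal(get("a", "e"), "root")     # unknown ranks never match
})

test_that("environmental cosmopolitanism counts occupied subtypes", {
  n_sub <- 36
  samples <- paste0("s", seq_len(2 * n_sub))
  env <- environment_hierarchy(data.frame(
    sample = samples,
    subtype = rep(paste0("sub", 1:n_sub), each = 2),
    type = rep(paste0("ty", 1:n_sub), each = 2),
    supertype = "all"))
  X <- matrix(0L, 3, 2 * n_sub, dimnames = list(c("wide", "one", "none"),
                                                samples))
  X["wide", seq(1, 2 * n_sub, 2)] <- 1L    # one sample in each subtype
  X["one", 1] <- 1L
  got <- environmental_cosmopolitanism(presence_matrix(X), env)
  expect_equal(unname(got), c(36, 1, 0))
})

test_that("community cosmopolitanism respects its closed-form limits", {
  samples <- paste0("s", 1:4)
  X <- matrix(0L, 2, 4, dimnames = list(c("t1", "t2"), samples))
  X[1, 1:3] <- 1L
  X[2, 1:4] <- 1L
  S0 <- 4.92
  # all pairs similar (scores above S0): 1
  cc_hi <- community_cosmopolitanism(presence_matrix(X),
                                     make_sample_scores(samples, 10), S0)
  expect_equal(unname(cc_hi), c(1, 1))
  # all pairs different: m_i
  cc_lo <- community_cosmopolitanism(presence_matrix(X),
                                     make_sample_scores(samples, 0), S0)
  expect_equal(unname(cc_lo), c(3, 4))
  # taxon in 3 samples with exactly one of three pairs below S0: 5/3
  svals <- rep(10, 6)
  pr <- t(combn(samples, 2))
  svals[pr[, 1] == "s1" & pr[, 2] == "s2"] <- 1
  cc_mid <- community_cosmopolitanism(presence_matrix(X),
                                      make_sample_scores(samples, svals), S0)
  expect_equal(unname(cc_mid[1]), 1 + 2 * 1 / 3)
  # bounds
  expect_true(all(cc_lo >= 1 & cc_lo <= rowSums(X)))
})

test_that("effective environment counts follow the entropy exponential", {
  samples <- paste0("s", 1:8)
  env <- environment_hierarchy(data.frame(
    sample = samples, subtype = rep(paste0("sub", 1:4), each = 2),
    type = rep(paste0("ty", 1:2), each = 4), supertype = "all"))
  X <- matrix(0L, 2, 8, dimnames = list(c("a", "b"), samples))
  # co-occur once in each of 4 subtypes -> 4
  X[, c(1, 3, 5, 7)] <- 1L
  pm <- presence_matrix(X)
  expect_equal(effective_environment_count(c("a", "b"), pm, env, "subtype"), 4)
  # all co-occurrences in one subtype -> 1
  X2 <- matrix(0L, 2, 8, dimnames = dimnames(X)); X2[, 1:2] <- 1L
  expect_equal(effective_environment_count(c("a", "b"),
                                           presence_matrix(X2), env,
                                           "subtype"), 1)
  # half and half -> 2
  X3 <- matrix(0L, 2, 8, dimnames = dimnames(X)); X3[, c(1, 3)] <- 1L
  expect_equal(effective_environment_count(c("a", "b"),
                                           presence_matrix(X3), env,
                                           "subtype"), 2)
  # never co-occur -> NA
  X4 <- matrix(0L, 2, 8, dimnames = dimnames(X))
  X4[1, 1] <- 1L; X4[2, 2] <- 1L
  expect_true(is.na(effective_environment_count(c("a", "b"),
                                                presence_matrix(X4), env,
                                                "subtype")))
})

test_that("subnetwork selection applies the subtype-occupancy rule", {
  samples <- paste0("s", 1:10)
  env <- environment_hierarchy(data.frame(
    sample = samples, subtype = rep(paste0("g", 1:5), each = 2),
    type = "gut", supertype = "host"))
  X <- matrix(0L, 3, 10, dimnames = list(c("a", "b", "c"), samples))
  X["a", c(1, 3, 5)] <- 1L          # 3 of 5 subtypes
  X["b", c(1, 3)] <- 1L             # 2 of 5
  X["c", c(1, 3, 5, 7, 9)] <- 1L    # 5 of 5
  pm <- presence_matrix(X)
  net <- make_network(agg_edges("a", "b", "a", "c", "b", "c"),
                      c("a", "b", "c"))
  sub <- select_subnetwork(net, pm, env, paste0("g", 1:5), 3)
  expect_setequal(sub$nodes, c("a", "c"))
  expect_equal(nrow(sub$edges), 1)
  full <- select_subnetwork(net, pm, env, paste0("g", 1:5), 0)
  expect_setequal(full$nodes, c("a", "b", "c"))
  expect_error(select_subnetwork(net, pm, env, "nope", 1), "not present")
})
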