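# Independent oracles and small fixture builders used across the suite.

# exhaustive enumeration of the co-occurrence count distribution over all
# 2^M joint outcomes (oracle for the recursion; keep M <= 12)
enum_pb <- function(w) {
  M <- length(w)
  probs <- numeric(M + 1)
  for (mask in 0:(2^M - 1)) {
    bits <- as.integer(intToBits(mask))[seq_len(M)]
    pr <- prod(ifelse(bits == 1, w, 1 - w))
    probs[sum(bits) + 1] <- probs[sum(bits) + 1] + pr
  }
  probs
}

# term-by-term log-likelihood by a naive double loop
naive_loglik <- function(X, Pi) {
  s <- 0
  for (i in seq_len(nrow(X))) {
    for (a in seq_len(ncol(X))) {
      if (X[i, a] == 1) {
        s <- s + log(Pi[i, a])
      } else if (Pi[i, a] > 0) {
        s <- s + log(1 - Pi[i, a])
      }
    }
  }
  s
}

# independent likelihood maximiser: cyclic 1-D optimize() over each
# parameter on a bounded interval, from a crude grid start; honours the
# same occupancy cap pi <= 1 - 1e-12 as the model (i.e. products p*q are
# bounded by -log(1e-12)), so saturated instances stay comparable
oracle_ml_fit <- function(X, sweeps = 400, tcap = -log(1e-12)) {
  N <- nrow(X); M <- ncol(X)
  ll <- function(p, q) {
    T_ <- outer(p, q)
    Pi <- -expm1(-T_)
    sum(ifelse(X == 1, log(Pi), 0)) - sum((1 - X) * T_)
  }
  grid <- c(0.05, 0.2, 0.5, 1, 2)
  p <- rep(grid[which.max(vapply(grid, function(g)
    ll(rep(g, N), rep(1, M)), numeric(1)))], N)
  q <- rep(1, M)
  for (s in seq_len(sweeps)) {
    for (i in seq_len(N))
      p[i] <- stats::optimize(function(v) ll(replace(p, i, v), q),
                              c(1e-9, tcap / max(q)), maximum = TRUE,
                              tol = 1e-12)$maximum
    for (a in seq_len(M))
      q[a] <- stats::optimize(function(v) ll(p, replace(q, a, v)),
                              c(1e-9, tcap / max(p)), maximum = TRUE,
                              tol = 1e-12)$maximum
  }
  cg <- mean(q)
  list(p = p * cg, q = q / cg, pi = -expm1(-outer(p, q)))
}

# model stub whose only job is to carry an occupancy matrix
fake_model <- function(pi_mat) {
  structure(list(pi = pi_mat, level = "global"), class = "cooc_null_model")
}

# hand-built association network
make_network <- function(edges, nodes, provenance = "observed") {
  structure(list(edges = edges, nodes = nodes,
                 thresholds = c(aggregation = 0, segregation = 0),
                 consensus_only = FALSE, provenance = provenance,
                 n_conflicts = 0L),
            class = "assoc_network")
}

agg_edges <- function(...) {
  pr <- matrix(c(...), ncol = 2, byrow = TRUE)
  data.frame(taxon_i = pr[, 1], taxon_j = pr[, 2], type = "aggregation",
             Z = 10, stringsAsFactors = FALSE)
}

# hand-built sample-axis score table (for community cosmopolitanism)
make_sample_scores <- function(samples, S_agg) {
  pr <- t(combn(samples, 2))
  df <- data.frame(taxon_i = pr[, 1], taxon_j = pr[, 2],
                   n_ij = 0L, S_agg = S_agg, S_seg = 0, p_at_n = 0,
                   n_max = 0L, S_agg_limit = 0, S_seg_limit = 0,
                   stringsAsFactors = FALSE)
  structure(df, axis = "samples", ids = samples,
            class = c("score_table", "data.frame"))
}

# planted-coupling spec used by the recovery tests
planted_spec <- function(seed, n_pairs = 15L, rho = 0.6, sign = "+",
                         n_taxa = 60L, n_samples = 600L, n_subtypes = 4L) {
  pp <- data.frame(i = seq(1, 2 * n_pairs - 1, 2),
                   j = seq(2, 2 * n_pairs, 2),
                   sign = sign, rho = rho, stringsAsFactors = FALSE)
  synthetic_spec(n_taxa = n_taxa, n_samples = n_samples,
                 n_subtypes = n_subtypes, planted_pairs = pp, seed = seed)
}

# two coupled groups: aggregation within each, segregation between
modular_spec <- function(seed, group_size = 8L, rho = 0.9,
                         n_taxa = 30L, n_samples = 400L) {
  g1 <- seq_len(group_size)
  g2 <- group_size + seq_len(group_size)
  within <- rbind(t(combn(g1, 2)), t(combn(g2, 2)))
  between <- as.matrix(expand.grid(g1, g2))
  pp <- rbind(
    data.frame(i = within[, 1], j = within[, 2], sign = "+", rho = rho),
    data.frame(i = between[, 1], j = between[, 2], sign = "-", rho = rho))
  synthetic_spec(n_taxa = n_taxa, n_samples = n_samples, n_subtypes = 4L,
                 habitat_prob = 1, p_meanlog = -1.6, p_sdlog = 0.6,
                 planted_pairs = pp, seed = seed)
}

pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
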