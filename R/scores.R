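# Pairwise aggregation/segregation scores.
#
# Under the null model a pair's co-occurrence count is Poisson-binomial
# with per-sample success probabilities w_m = pi_im pi_jm (taxa axis) or
# per-taxon w_i = pi_ia pi_ib (sample axis).  The exact distribution comes
# from the recursion P(n|m) = P(n|m-1)(1 - w_m) + P(n-1|m-1) w_m with
# P(0|0) = 1.  Scores are inclusive negative-log tails in natural log:
#   S_agg = -log P(n >= n_obs),   S_seg = -log P(n <= n_obs).
# The recursion runs in linear space; tails below 1e-280 are recomputed in
# log space, so scores of hundreds of nats stay finite.

#' Exact null distribution of a pair's co-occurrence count
#'
#' @param joint_probs vector of per-sample joint presence probabilities
#'   `pi_im * pi_jm`, each in `[0, 1]`.
#' @return Object of class `cooc_dist`: list with `probs` (vector of
#'   `P(n | M)` for `n = 0..M`), `M`, `n_max` (feasible maximum, the count
#'   of strictly positive entries) and the input `joint_probs`.
#' @export
cooccurrence_distribution <- function(joint_probs) {
  joint_probs <- as.numeric(joint_probs)
  probs <- cpp_pb_dist(joint_probs)           # validates entries
  probs <- probs / sum(probs)                 # renormalise fp drift
  structure(list(probs = probs, M = length(joint_probs),
                 n_max = sum(joint_probs > 0), joint_probs = joint_probs),
            class = "cooc_dist")
}

#' @export
print.cooc_dist <- function(x, ...) {
  cat(sprintf("cooc_dist over M = %d samples (support 0..%d), mean %.3f\n",
              x$M, x$n_max, sum((seq_along(x$probs) - 1L) * x$probs)))
  invisible(x)
}

#' Inclusive tail scores of an observed co-occurrence count
#'
#' `S_agg = -log P(n >= n_obs)` and `S_seg = -log P(n <= n_obs)` (natural
#' log, inclusive tails).  An observation above the feasible maximum is
#' impossible under the model and raises an error.
#'
#' @param dist a [cooccurrence_distribution()].
#' @param n_obs observed co-occurrence count, `0 <= n_obs <= M`.
#' @return named numeric vector `c(S_agg =, S_seg =)`.
#' @export
tail_scores <- function(dist, n_obs) {
  stopifnot(inherits(dist, "cooc_dist"))
  n_obs <- as.integer(n_obs)
  if (n_obs < 0 || n_obs > dist$M) stop("n_obs must lie in 0..M")
  if (n_obs > dist$n_max)
    stop(sprintf("n_obs = %d exceeds the feasible maximum %d: impossible under the model",
                 n_obs, dist$n_max))
  tl <- cpp_pb_tails(dist$joint_probs, n_obs)
  c(S_agg = tl$S_agg, S_seg = tl$S_seg)
}

#' Raw association scores for all pairs on one axis
#'
#' Computes observed co-occurrence counts and inclusive tail scores for
#' every unordered pair of taxa (or of samples, where the roles of the
#' two axes swap and the scores are the sample-aggregation and
#' sample-segregation scores).
#'
#' @param X a [presence_matrix()].
#' @param model fitted [fit_null_model()] on the same layout.
#' @param axis `"taxa"` (default) or `"samples"`.
#' @return Object of class `score_table`: data.frame with one row per
#'   unordered pair, columns `taxon_i`, `taxon_j` (sample identifiers on
#'   the sample axis), `n_ij`, `S_agg`, `S_seg`, `p_at_n` (point
#'   probability at the observed count), `n_max`, and the detectability
#'   limits `S_agg_limit = -log P(n = n_max)`,
#'   `S_seg_limit = -log P(n = 0)`.
#' @export
pair_scores <- function(X, model, axis = c("taxa", "samples")) {
  axis <- match.arg(axis)
  pm <- as_presence(X)
  if (!all(dim(pm$X) == dim(model$pi))) stop("matrix and model shapes disagree")
  if (axis == "taxa") {
    Pi <- model$pi; Xm <- pm$X; ids <- pm$taxa
  } else {
    Pi <- t(model$pi); Xm <- t(pm$X); ids <- pm$samples
  }
  raw <- cpp_all_pair_scores(Pi, Xm)
  out <- data.frame(
    taxon_i = ids[raw[, 1]], taxon_j = ids[raw[, 2]],
    n_ij = as.integer(raw[, 3]),
    S_agg = raw[, 4], S_seg = raw[, 5], p_at_n = raw[, 6],
    n_max = as.integer(raw[, 7]),
    S_agg_limit = raw[, 8], S_seg_limit = raw[, 9],
    stringsAsFactors = FALSE)
  structure(out, axis = axis, ids = ids,
            class = c("score_table", "data.frame"))
}

#' Calibrate raw scores into Z scores over refitted null realizations
#'
#' Draws `R` random matrices from the fitted null model, refits the null
#' model on each replicate, recomputes all pair scores under the
#' replicate's own model, and standardises the observed scores:
#' `Z = (S_obs - mean_r S_r) / sd_r S_r`, separately for aggregation and
#' segregation.  Pairs whose replicate score spread falls below
#' `sd_floor` are flagged non-evaluable instead of receiving an arbitrary
#' Z.
#'
#' @param X observed [presence_matrix()].
#' @param env [environment_hierarchy()] (may be `NULL` for a global fit).
#' @param model fitted null model of `X`.
#' @param R number of null replicates (>= 2; 100 reproduces the canonical
#'   calibration, smaller values are for exploratory runs).
#' @param seed integer seed; the calibration is deterministic given it.
#' @param axis `"taxa"` or `"samples"`.
#' @param sd_floor spread floor below which a pair is non-evaluable.
#' @param refit refit the null model on every replicate (canonical).
#'   `refit = FALSE` scores replicates under the observed model; faster
#'   but non-canonical, for exploration only.
#' @return A `score_table` (see [pair_scores()]) with additional columns
#'   `Z_agg`, `Z_seg`, `null_mean_agg`, `null_sd_agg`, `null_mean_seg`,
#'   `null_sd_seg`, `evaluable_agg`, `evaluable_seg`.  The per-replicate
#'   score matrices are kept in the attribute `"replicates"` so that
#'   calibration curves can reuse them.
#' @export
calibrate_scores <- function(X, env, model, R = 100L, seed = 1L,
                             axis = c("taxa", "samples"),
                             sd_floor = 1e-9, refit = TRUE) {
  axis <- match.arg(axis)
  if (R < 2) stop("R must be at least 2")
  pm <- as_presence(X)
  obs <- pair_scores(pm, model, axis = axis)
  n_pairs <- nrow(obs)

  set.seed(as.integer(seed))
  rep_seeds <- sample.int(.Machine$integer.max - 1L, R)
  S_agg_rep <- matrix(NA_real_, n_pairs, R)
  S_seg_rep <- matrix(NA_real_, n_pairs, R)
  ok <- logical(R)
  for (r in seq_len(R)) {
    Xr <- sample_matrix(model, rep_seeds[r])
    mr <- if (refit) {
      tryCatch(fit_null_model(Xr, env, level = model$level),
               error = function(e) {
                 warning("replicate ", r, " fit failed: ", conditionMessage(e))
                 NULL
               })
    } else model
    if (is.null(mr)) next
    sr <- pair_scores(Xr, mr, axis = axis)
    S_agg_rep[, r] <- sr$S_agg
    S_seg_rep[, r] <- sr$S_seg
    ok[r] <- TRUE
  }
  if (sum(ok) < 0.8 * R)
    stop("more than 20% of calibration replicates failed (",
         R - sum(ok), " of ", R, ")")
  S_agg_rep <- S_agg_rep[, ok, drop = FALSE]
  S_seg_rep <- S_seg_rep[, ok, drop = FALSE]

  std <- function(S_obs, S_rep) {
    m <- rowMeans(S_rep)
    s <- sqrt(pmax(rowSums((S_rep - m)^2) / (ncol(S_rep) - 1), 0))
    eval_ok <- is.finite(m) & s > sd_floor
    list(mean = m, sd = s, evaluable = eval_ok,
         Z = ifelse(eval_ok, (S_obs - m) / s, NA_real_))
  }
  za <- std(obs$S_agg, S_agg_rep)
  zs <- std(obs$S_seg, S_seg_rep)
  obs$Z_agg <- za$Z
  obs$Z_seg <- zs$Z
  obs$null_mean_agg <- za$mean
  obs$null_sd_agg <- za$sd
  obs$null_mean_seg <- zs$mean
  obs$null_sd_seg <- zs$sd
  obs$evaluable_agg <- za$evaluable
  obs$evaluable_seg <- zs$evaluable
  attr(obs, "replicates") <- list(agg = S_agg_rep, seg = S_seg_rep)
  attr(obs, "R") <- ncol(S_agg_rep)
  attr(obs, "sd_floor") <- sd_floor
  attr(obs, "seed") <- seed
  obs
}
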