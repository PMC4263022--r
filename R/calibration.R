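# Threshold calibration and network construction.
#
# Significance thresholds are chosen from simulated operating curves: null
# realizations of the fitted model are treated exactly like the observed
# matrix (refit, score, standardise), every association they produce is a
# false positive, and counting them against the threshold yields
# FPR(T) = mean null count / evaluable pairs and
# PPV(T) = (obs count - mean null count) / obs count (clamped at 0).

#' Estimate FPR and PPV curves from null realizations
#'
#' By default the per-replicate score matrices stored by
#' [calibrate_scores()] are reused: each replicate is standardised
#' against the remaining replicates (leave-one-out), which makes the
#' curve essentially free.  With `reuse = FALSE`, `n_null` fresh
#' realizations are drawn and each receives its own full calibration of
#' `R_cal` replicates — the canonical but much slower route.
#'
#' @param scores_obs calibrated `score_table` of the observed matrix.
#' @param model fitted null model (needed only when `reuse = FALSE`).
#' @param env environment table (only when `reuse = FALSE`).
#' @param thresholds grid of candidate Z thresholds.
#' @param n_null number of fresh null realizations (`reuse = FALSE`).
#' @param R_cal replicates per fresh realization (`reuse = FALSE`).
#' @param seed seed for fresh realizations.
#' @param reuse reuse the calibration replicates (default).
#' @return Object of class `calibration_curve`: data.frame with columns
#'   `type`, `threshold`, `obs_count`, `null_mean`, `FPR`, `PPV`.
#' @export
estimate_fpr_ppv <- function(scores_obs, model = NULL, env = NULL,
                             thresholds = seq(0, 10, by = 0.25),
                             n_null = 10L, R_cal = 10L, seed = 1L,
                             reuse = TRUE) {
  stopifnot(inherits(scores_obs, "score_table"))
  if (reuse) {
    reps <- attr(scores_obs, "replicates")
    if (is.null(reps)) stop("scores_obs carries no replicates; run calibrate_scores() or set reuse = FALSE")
    null_z <- list(aggregation = loo_z(reps$agg, attr(scores_obs, "sd_floor")),
                   segregation = loo_z(reps$seg, attr(scores_obs, "sd_floor")))
  } else {
    if (is.null(model)) stop("model required when reuse = FALSE")
    if (n_null < 1) stop("n_null must be >= 1")
    set.seed(as.integer(seed))
    null_seeds <- sample.int(.Machine$integer.max - 1L, n_null)
    za <- zs <- vector("list", n_null)
    for (r in seq_len(n_null)) {
      Xr <- sample_matrix(model, null_seeds[r])
      mr <- fit_null_model(Xr, env, level = model$level)
      cr <- calibrate_scores(Xr, env, mr, R = R_cal,
                             seed = null_seeds[r] %% 1000003L + 1L,
                             axis = attr(scores_obs, "axis"))
      za[[r]] <- cr$Z_agg
      zs[[r]] <- cr$Z_seg
    }
    null_z <- list(aggregation = do.call(cbind, za),
                   segregation = do.call(cbind, zs))
  }

  curve <- do.call(rbind, lapply(c("aggregation", "segregation"), function(ty) {
    if (ty == "aggregation") {
      z_obs <- scores_obs$Z_agg; eval_obs <- scores_obs$evaluable_agg
    } else {
      z_obs <- scores_obs$Z_seg; eval_obs <- scores_obs$evaluable_seg
    }
    n_eval <- sum(eval_obs)
    zn <- null_z[[ty]]
    obs_count <- vapply(thresholds, function(T)
      sum(z_obs >= T & eval_obs, na.rm = TRUE), numeric(1))
    null_mean <- vapply(thresholds, function(T)
      mean(colSums(zn >= T, na.rm = TRUE)), numeric(1))
    fpr <- fpr_estimate(null_mean, n_eval)
    ppv <- ppv_estimate(obs_count, null_mean)
    data.frame(type = ty, threshold = thresholds, obs_count = obs_count,
               null_mean = null_mean, FPR = fpr, PPV = ppv,
               stringsAsFactors = FALSE)
  }))
  rownames(curve) <- NULL
  structure(curve, n_eval = c(
    aggregation = sum(scores_obs$evaluable_agg),
    segregation = sum(scores_obs$evaluable_seg)),
    class = c("calibration_curve", "data.frame"))
}

#' Empirical-null estimators of PPV and FPR
#'
#' `ppv_estimate` is the excess of observed detections over the mean null
#' count, divided by the observed count (clamped at 0; `NA` when nothing
#' is observed).  `fpr_estimate` is the mean null count divided by the
#' number of evaluable pairs.
#'
#' @param obs_count detections in the observed data at a threshold.
#' @param null_count mean detections over null realizations (all false
#'   positives by construction).
#' @param n_evaluable number of evaluable pairs.
#' @return numeric vector of estimates.
#' @export
ppv_estimate <- function(obs_count, null_count) {
  ifelse(obs_count > 0, pmax(0, (obs_count - null_count) / obs_count),
         NA_real_)
}

#' @rdname ppv_estimate
#' @export
fpr_estimate <- function(null_count, n_evaluable) {
  null_count / pmax(n_evaluable, 1L)
}

# leave-one-out Z standardisation of a pairs-by-replicates score matrix
loo_z <- function(S, sd_floor = 1e-9) {
  if (is.null(sd_floor)) sd_floor <- 1e-9
  R <- ncol(S)
  if (R < 3) stop("leave-one-out standardisation needs at least 3 replicates")
  s1 <- rowSums(S)
  s2 <- rowSums(S^2)
  Z <- matrix(NA_real_, nrow(S), R)
  for (r in seq_len(R)) {
    x <- S[, r]
    m <- (s1 - x) / (R - 1)
    v <- pmax((s2 - x^2 - (R - 1) * m^2) / (R - 2), 0)
    s <- sqrt(v)
    Z[, r] <- ifelse(s > sd_floor, (x - m) / s, NA_real_)
  }
  Z
}

#' Which pairs can in principle reach significance
#'
#' A pair can carry a significant aggregation only if the probability
#' that the two taxa always co-occur is small enough, and a significant
#' segregation only if the probability that they never co-occur is small
#' enough.  The Z threshold is mapped per pair onto the raw score scale
#' through that pair's null mean and spread when a calibration is
#' present; otherwise `threshold` is taken as a raw score directly.
#' The consensus set is the conjunction of the two masks.
#'
#' @param scores a `score_table` (calibrated or raw).
#' @param threshold Z threshold (or raw threshold if uncalibrated).
#' @param type `"aggregation"` or `"segregation"`.
#' @return logical vector, one entry per pair.
#' @export
detectable_pairs <- function(scores, threshold,
                             type = c("aggregation", "segregation")) {
  type <- match.arg(type)
  calibrated <- !is.null(scores$null_mean_agg)
  if (type == "aggregation") {
    lim <- scores$S_agg_limit
    raw_T <- if (calibrated)
      ifelse(scores$evaluable_agg,
             scores$null_mean_agg + threshold * scores$null_sd_agg,
             threshold)
    else threshold
  } else {
    lim <- scores$S_seg_limit
    raw_T <- if (calibrated)
      ifelse(scores$evaluable_seg,
             scores$null_mean_seg + threshold * scores$null_sd_seg,
             threshold)
    else threshold
  }
  lim > raw_T
}

#' Build a signed association network from calibrated scores
#'
#' An edge is an aggregation where `Z_agg >= T_agg` (and the pair is
#' evaluable), a segregation where `Z_seg >= T_seg`; when both exceed
#' their thresholds the type with the larger Z wins and the conflict is
#' recorded.  `consensus_only` restricts edges to pairs where both
#' association types are detectable at the thresholds.
#'
#' @param scores calibrated `score_table`.
#' @param T_agg,T_seg Z thresholds for the two association types.
#' @param consensus_only restrict to the consensus (detectability) set.
#' @param provenance tag recorded on the network (`"observed"`,
#'   `"control"`, `"null-replicate"`).
#' @return Object of class `assoc_network`: list with `edges` (data.frame
#'   `taxon_i`, `taxon_j`, `type`, `Z`), `nodes`, `thresholds`,
#'   `consensus_only`, `provenance`, `n_conflicts`.
#' @export
build_network <- function(scores, T_agg, T_seg, consensus_only = FALSE,
                          provenance = "observed") {
  stopifnot(inherits(scores, "score_table"))
  if (is.null(scores$Z_agg)) stop("scores must be calibrated (run calibrate_scores)")
  hit_a <- !is.na(scores$Z_agg) & scores$evaluable_agg & scores$Z_agg >= T_agg
  hit_s <- !is.na(scores$Z_seg) & scores$evaluable_seg & scores$Z_seg >= T_seg
  if (consensus_only) {
    cons <- detectable_pairs(scores, T_agg, "aggregation") &
      detectable_pairs(scores, T_seg, "segregation")
    hit_a <- hit_a & cons
    hit_s <- hit_s & cons
  }
  both <- hit_a & hit_s
  n_conflicts <- sum(both)
  agg_wins <- both & (scores$Z_agg >= scores$Z_seg)
  take_a <- hit_a & (!both | agg_wins)
  take_s <- hit_s & (!both | !agg_wins)
  edges <- rbind(
    if (any(take_a)) data.frame(taxon_i = scores$taxon_i[take_a],
                                taxon_j = scores$taxon_j[take_a],
                                type = "aggregation",
                                Z = scores$Z_agg[take_a],
                                stringsAsFactors = FALSE),
    if (any(take_s)) data.frame(taxon_i = scores$taxon_i[take_s],
                                taxon_j = scores$taxon_j[take_s],
                                type = "segregation",
                                Z = scores$Z_seg[take_s],
                                stringsAsFactors = FALSE))
  if (is.null(edges))
    edges <- data.frame(taxon_i = character(), taxon_j = character(),
                        type = character(), Z = numeric(),
                        stringsAsFactors = FALSE)
  edges <- edges[order(edges$taxon_i, edges$taxon_j, method = "radix"), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  structure(list(edges = edges, nodes = attr(scores, "ids"),
                 thresholds = c(aggregation = T_agg, segregation = T_seg),
                 consensus_only = consensus_only, provenance = provenance,
                 n_conflicts = n_conflicts),
            class = "assoc_network")
}

#' @export
print.assoc_network <- function(x, ...) {
  cat(sprintf("assoc_network (%s): %d nodes, %d aggregations, %d segregations\n",
              x$provenance, length(x$nodes),
              sum(x$edges$type == "aggregation"),
              sum(x$edges$type == "segregation")))
  cat(sprintf("  thresholds: Z_agg >= %.3g, Z_seg >= %.3g%s\n",
              x$thresholds[["aggregation"]], x$thresholds[["segregation"]],
              if (isTRUE(x$consensus_only)) " (consensus set only)" else ""))
  invisible(x)
}

#' Build a count-matched control network from one null realization
#'
#' Draws a single presence-absence matrix from the null model, treats it
#' exactly like the observed matrix (refit, score, calibrate), and then
#' lowers the thresholds by rank until the control network carries
#' exactly `target_agg` aggregations and `target_seg` segregations.
#' Ties are broken in favour of the lexicographically smallest pair.
#'
#' @param model fitted null model of the observed matrix.
#' @param env environment table used for refitting.
#' @param target_agg,target_seg requested edge counts.
#' @param seed integer seed.
#' @param R calibration replicates for the control matrix.
#' @return An `assoc_network` with provenance `"control"`; the control
#'   matrix's calibrated scores are attached as attribute `"scores"`.
#' @export
build_control_network <- function(model, env, target_agg, target_seg,
                                  seed = 1L, R = 10L) {
  if (target_agg < 0 || target_seg < 0) stop("targets must be >= 0")
  set.seed(as.integer(seed))
  draw_seed <- sample.int(.Machine$integer.max - 1L, 1)
  cal_seed <- sample.int(.Machine$integer.max - 1L, 1)
  Xc <- sample_matrix(model, draw_seed)
  mc <- fit_null_model(Xc, env, level = model$level)
  sc <- calibrate_scores(Xc, env, mc, R = R, seed = cal_seed)

  pick <- function(Z, evaluable, target, taken_key = character()) {
    key <- paste(sc$taxon_i, sc$taxon_j, sep = "\r")
    cand <- which(evaluable & !is.na(Z) & !(key %in% taken_key))
    if (length(cand) < target)
      stop("fewer evaluable pairs (", length(cand),
           ") than the requested count (", target, ")")
    if (target == 0) return(integer())
    ord <- cand[order(-Z[cand], sc$taxon_i[cand], sc$taxon_j[cand],
                      method = "radix")]
    ord[seq_len(target)]
  }
  ia <- pick(sc$Z_agg, sc$evaluable_agg, target_agg)
  key_a <- paste(sc$taxon_i[ia], sc$taxon_j[ia], sep = "\r")
  js <- pick(sc$Z_seg, sc$evaluable_seg, target_seg, taken_key = key_a)

  edges <- rbind(
    if (length(ia)) data.frame(taxon_i = sc$taxon_i[ia],
                               taxon_j = sc$taxon_j[ia],
                               type = "aggregation", Z = sc$Z_agg[ia],
                               stringsAsFactors = FALSE),
    if (length(js)) data.frame(taxon_i = sc$taxon_i[js],
                               taxon_j = sc$taxon_j[js],
                               type = "segregation", Z = sc$Z_seg[js],
                               stringsAsFactors = FALSE))
  if (is.null(edges))
    edges <- data.frame(taxon_i = character(), taxon_j = character(),
                        type = character(), Z = numeric(),
                        stringsAsFactors = FALSE)
  edges <- edges[order(edges$taxon_i, edges$taxon_j, method = "radix"), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  thr <- c(aggregation = if (length(ia)) min(sc$Z_agg[ia]) else Inf,
           segregation = if (length(js)) min(sc$Z_seg[js]) else Inf)
  net <- structure(list(edges = edges, nodes = attr(sc, "ids"),
                        thresholds = thr, consensus_only = FALSE,
                        provenance = "control", n_conflicts = 0L),
                   class = "assoc_network")
  attr(net, "scores") <- sc
  net
}

#' Pick the smallest threshold reaching a target PPV
#'
#' @param curve a `calibration_curve`.
#' @param target_ppv required positive predictive value.
#' @param type association type.
#' @return the smallest threshold on the grid whose PPV is defined and
#'   `>= target_ppv` (falls back to the largest grid threshold).
#' @export
threshold_at_ppv <- function(curve, target_ppv,
                             type = c("aggregation", "segregation")) {
  type <- match.arg(type)
  cv <- curve[curve$type == type, , drop = FALSE]
  ok <- !is.na(cv$PPV) & cv$PPV >= target_ppv
  if (any(ok)) min(cv$threshold[ok]) else max(cv$threshold)
}
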