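# Synthetic presence-absence datasets with known ground truth.
#
# The generator emulates the statistical structure the analysis assumes:
# sparse binary occupancy driven by heavy-tailed per-taxon abundance
# (log-normal p) and per-sample diversity (gamma q, mean 1), habitat
# stratification (each taxon is allowed only in a subset of subtypes and
# has occupancy probability 0 elsewhere), and planted pairwise couplings.
# Positively coupled pairs share one abundance parameter and, with
# probability rho per sample, their two indicators are redrawn from a
# shared uniform (a comonotone merge): at rho = 1 their occupancy vectors
# are identical within shared subtypes, and the per-taxon marginals are
# preserved exactly at every rho.  A negative coupling keeps at most one
# of the two taxa with probability rho per sample (never inflating
# marginals; it deflates them slightly, which is documented, not
# corrected).

#' Specify a synthetic dataset
#'
#' Defaults give roughly 5-15% matrix fill with four subtypes nested in
#' two types and two supertypes, mimicking the sparsity and the
#' stratification of broad environmental surveys.
#'
#' @param n_taxa,n_samples matrix dimensions.
#' @param n_subtypes number of environmental subtypes; samples are split
#'   evenly across them, subtypes nest pairwise into types and types into
#'   supertypes.
#' @param p_meanlog,p_sdlog log-normal parameters of the per-taxon
#'   abundance parameter p.
#' @param q_shape,q_rate gamma parameters of the per-sample diversity
#'   parameter q (defaults have mean 1).
#' @param habitat_prob probability that a taxon is allowed in a given
#'   subtype (at least one subtype is always allowed).
#' @param planted_pairs data.frame with columns `i`, `j` (taxon indices),
#'   `sign` (`"+"` or `"-"`) and `rho` (coupling strength in `[0, 1]`),
#'   or `NULL` for a fully null dataset.
#' @param planted_same_family place positively coupled pairs in the same
#'   taxonomic family.
#' @param seed integer seed; the dataset is deterministic given it.
#' @return Object of class `synthetic_spec` (validated argument list).
#' @export
synthetic_spec <- function(n_taxa = 60L, n_samples = 600L, n_subtypes = 4L,
                           p_meanlog = -2.5, p_sdlog = 1,
                           q_shape = 2, q_rate = 2,
                           habitat_prob = 0.7,
                           planted_pairs = NULL,
                           planted_same_family = FALSE,
                           seed = 1L) {
  stopifnot(n_taxa >= 2, n_samples >= 1, n_subtypes >= 1,
            habitat_prob > 0, habitat_prob <= 1,
            p_sdlog >= 0, q_shape > 0, q_rate > 0)
  if (!is.null(planted_pairs)) {
    need <- c("i", "j", "sign", "rho")
    if (!all(need %in% names(planted_pairs)))
      stop("planted_pairs needs columns: ", paste(need, collapse = ", "))
    bad <- character()
    if (any(planted_pairs$i == planted_pairs$j))
      bad <- c(bad, "a planted pair references the same taxon twice")
    if (any(planted_pairs$i < 1 | planted_pairs$i > n_taxa |
              planted_pairs$j < 1 | planted_pairs$j > n_taxa))
      bad <- c(bad, "planted taxon index out of range")
    if (!all(planted_pairs$sign %in% c("+", "-")))
      bad <- c(bad, "sign must be '+' or '-'")
    if (any(planted_pairs$rho < 0 | planted_pairs$rho > 1))
      bad <- c(bad, "rho must lie in [0, 1]")
    key <- paste(pmin(planted_pairs$i, planted_pairs$j),
                 pmax(planted_pairs$i, planted_pairs$j))
    if (anyDuplicated(key)) bad <- c(bad, "duplicate planted pair")
    if (length(bad) > 0)
      stop("invalid synthetic spec: ", paste(bad, collapse = "; "))
    planted_pairs$i <- as.integer(planted_pairs$i)
    planted_pairs$j <- as.integer(planted_pairs$j)
    planted_pairs$sign <- as.character(planted_pairs$sign)
    planted_pairs$rho <- as.numeric(planted_pairs$rho)
  }
  structure(list(n_taxa = as.integer(n_taxa),
                 n_samples = as.integer(n_samples),
                 n_subtypes = as.integer(n_subtypes),
                 p_meanlog = p_meanlog, p_sdlog = p_sdlog,
                 q_shape = q_shape, q_rate = q_rate,
                 habitat_prob = habitat_prob,
                 planted_pairs = planted_pairs,
                 planted_same_family = isTRUE(planted_same_family),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic dataset with ground truth
#'
#' Baseline cells are independent Bernoulli draws with
#' `pi_ia = 1 - exp(-p_i q_a)` restricted to each taxon's allowed
#' subtypes.  Positively coupled pairs share one abundance parameter and,
#' in coupled samples, are redrawn from a single shared uniform, which
#' forces identical indicators there while leaving each taxon's marginal
#' occupancy exactly Bernoulli(`pi`); negatively coupled pairs lose one
#' member (chosen at random) of any joint presence in coupled samples.
#' With no planted pairs the matrix is exchangeable with
#' [sample_matrix()] run on the same `pi` and the cell seed recorded in
#' the truth object.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `presence` ([presence_matrix()]), `env`
#'   ([environment_hierarchy()]), `taxonomy` ([taxonomy_table()]) and
#'   `truth` (class `synthetic_truth`: the generating `pi`, parameter
#'   draws, habitat masks, the planted pair table with realized
#'   co-occurrence counts, and `cell_seed`).
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  N <- spec$n_taxa; M <- spec$n_samples; S <- spec$n_subtypes
  set.seed(spec$seed)

  taxa <- sprintf("t%03d", seq_len(N))
  samples <- sprintf("s%04d", seq_len(M))
  subtype_of <- sort(rep(seq_len(S), length.out = M))     # contiguous blocks
  sub_lab <- sprintf("sub%02d", subtype_of)
  type_id <- ceiling(subtype_of / 2)
  sup_id <- ceiling(type_id / 2)
  env <- environment_hierarchy(data.frame(
    sample = samples, subtype = sub_lab,
    type = sprintf("type%02d", type_id),
    supertype = sprintf("sup%02d", sup_id),
    stringsAsFactors = FALSE))

  p <- rlnorm(N, spec$p_meanlog, spec$p_sdlog)
  q <- rgamma(M, shape = spec$q_shape, rate = spec$q_rate)
  pp <- spec$planted_pairs
  # connected components of the + coupling graph: members share one
  # abundance parameter and one per-sample latent uniform, so overlapping
  # planted pairs (e.g. coupled cliques) reinforce instead of overwriting
  # each other
  comp_root <- seq_len(N)
  if (!is.null(pp) && any(pp$sign == "+")) {
    parent <- seq_len(N)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    for (r in which(pp$sign == "+")) {
      a <- find(pp$i[r]); b <- find(pp$j[r])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
    comp_root <- vapply(seq_len(N), find, integer(1))
    for (i in seq_len(N)) p[i] <- p[comp_root[i]]
  }
  mask <- matrix(runif(N * S) < spec$habitat_prob, N, S)
  none <- which(rowSums(mask) == 0)
  for (i in none) mask[i, sample.int(S, 1)] <- TRUE
  if (!is.null(pp)) {
    for (r in which(pp$sign == "+")) {       # ensure overlapping habitats
      i <- pp$i[r]; j <- pp$j[r]
      if (!any(mask[i, ] & mask[j, ])) {
        s_shared <- sample(which(mask[i, ]), 1)
        mask[j, s_shared] <- TRUE
      }
    }
  }

  pi_mat <- -expm1(-outer(p, q))
  pi_mat <- pi_mat * mask[, subtype_of]
  dimnames(pi_mat) <- list(taxa, samples)

  cell_seed <- sample.int(.Machine$integer.max - 1L, 1)
  coupling_seed <- sample.int(.Machine$integer.max - 1L, 1)
  X <- draw_cells(pi_mat, cell_seed)$X

  if (!is.null(pp)) {
    set.seed(coupling_seed)
    u_comp <- matrix(runif(N * M), N, M)   # one latent uniform per
    for (r in which(pp$sign == "+")) {     # component and sample
      i <- pp$i[r]; j <- pp$j[r]
      shared <- mask[i, subtype_of] & mask[j, subtype_of]
      act <- shared & (runif(M) < pp$rho[r])
      # redraw both indicators from the component's shared uniform:
      # comonotone within the sample, Bernoulli(pi) marginals untouched,
      # idempotent under overlapping pairs
      u <- u_comp[comp_root[i], act]
      X[i, act] <- (u < pi_mat[i, act]) * 1L
      X[j, act] <- (u < pi_mat[j, act]) * 1L
    }
    for (r in which(pp$sign == "-")) {
      i <- pp$i[r]; j <- pp$j[r]
      shared <- mask[i, subtype_of] & mask[j, subtype_of]
      act <- shared & (runif(M) < pp$rho[r])
      clash <- act & X[i, ] == 1L & X[j, ] == 1L
      if (any(clash)) {
        drop_i <- runif(sum(clash)) < 0.5
        X[i, which(clash)[drop_i]] <- 0L
        X[j, which(clash)[!drop_i]] <- 0L
      }
    }
  }

  # random nested taxonomy: 4 phyla, 2 classes each, 2 orders per class,
  # 2 families per order
  n_fam <- 32L
  fam <- sample.int(n_fam, N, replace = TRUE)
  if (spec$planted_same_family && !is.null(pp)) {
    for (r in which(pp$sign == "+")) fam[pp$j[r]] <- fam[pp$i[r]]
  }
  ord <- ceiling(fam / 2); cls <- ceiling(ord / 2); phy <- ceiling(cls / 2)
  taxonomy <- taxonomy_table(data.frame(
    taxon = taxa,
    phylum = sprintf("p%02d", phy), class = sprintf("c%02d", cls),
    order = sprintf("o%02d", ord), family = sprintf("f%02d", fam),
    stringsAsFactors = FALSE))

  planted <- if (is.null(pp)) {
    data.frame(taxon_i = character(), taxon_j = character(),
               sign = character(), rho = numeric(), n_ij = integer(),
               stringsAsFactors = FALSE)
  } else {
    data.frame(taxon_i = taxa[pmin(pp$i, pp$j)],
               taxon_j = taxa[pmax(pp$i, pp$j)],
               sign = pp$sign, rho = pp$rho,
               n_ij = vapply(seq_len(nrow(pp)), function(r)
                 sum(X[pp$i[r], ] == 1L & X[pp$j[r], ] == 1L), integer(1)),
               stringsAsFactors = FALSE)
  }
  truth <- structure(list(pi = pi_mat, p = p, q = q, mask = mask,
                          planted = planted, cell_seed = cell_seed,
                          spec = spec),
                     class = "synthetic_truth")
  list(presence = presence_matrix(X), env = env, taxonomy = taxonomy,
       truth = truth)
}

#' Ranking recovery of planted positive couplings
#'
#' Area under the ROC curve of the aggregation Z ranking for separating
#' planted positively coupled pairs from all other pairs (rank-sum
#' estimator; non-evaluable pairs rank at the bottom).
#'
#' @param scores calibrated `score_table` on the taxa axis.
#' @param truth a `synthetic_truth`.
#' @return AUC in `[0, 1]`, or `NA` when there is no planted positive pair.
#' @export
recovery_auc <- function(scores, truth) {
  stopifnot(inherits(scores, "score_table"),
            inherits(truth, "synthetic_truth"))
  pos <- truth$planted[truth$planted$sign == "+", , drop = FALSE]
  if (nrow(pos) == 0) return(NA_real_)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  lab <- key(scores$taxon_i, scores$taxon_j) %in%
    key(pos$taxon_i, pos$taxon_j)
  z <- ifelse(is.na(scores$Z_agg), -Inf, scores$Z_agg)
  r <- rank(z, ties.method = "average")
  n1 <- sum(lab); n0 <- sum(!lab)
  (sum(r[lab]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
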