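# Downstream network statistics: propensities, nestedness, habitat
# preference, cosmopolitanism, effective shared-environment counts and
# environment-based subnetwork selection.

#' Propensity of two properties to co-occur
#'
#' `Prop(a, b) = log P(a, b) - log P(a) - log P(b)` estimated from counts
#' out of a common total: `log(joint/total) - log(marg_a/total) -
#' log(marg_b/total)`.  Zero under exact independence, symmetric in the
#' two properties, positive when one favours the other.  The standard
#' error uses the delta method on the multinomial counts; the value is
#' flagged undefined when any count is zero.
#'
#' @param joint count of items with both properties.
#' @param marg_a,marg_b marginal counts.
#' @param total total number of items.
#' @return Object of class `propensity_result`: list with `value`, `se`,
#'   `counts`, `defined`.
#' @export
propensity <- function(joint, marg_a, marg_b, total) {
  if (total <= 0) stop("total must be positive")
  if (joint > min(marg_a, marg_b))
    stop("joint count exceeds a marginal count")
  if (max(joint, marg_a, marg_b) > total)
    stop("counts cannot exceed the total")
  defined <- joint > 0 && marg_a > 0 && marg_b > 0
  value <- if (defined)
    log(joint / total) - log(marg_a / total) - log(marg_b / total)
  else NA_real_
  # Prop = log(J/A) - log(B/T): two binomial proportions, J <= A, B <= T
  se <- if (defined)
    sqrt((1 / joint - 1 / marg_a) + (1 / marg_b - 1 / total))
  else NA_real_
  structure(list(value = value, se = se,
                 counts = c(joint = joint, marg_a = marg_a,
                            marg_b = marg_b, total = total),
                 defined = defined),
            class = "propensity_result")
}

#' @export
print.propensity_result <- function(x, ...) {
  if (x$defined)
    cat(sprintf("propensity %.4f +/- %.4f (joint %d / %d)\n",
                x$value, x$se, x$counts[["joint"]], x$counts[["total"]]))
  else cat("propensity undefined (zero count)\n")
  invisible(x)
}

# internal: edge type matrix (0 none, 1 aggregation, 2 segregation)
adjacency_types <- function(network) {
  nodes <- network$nodes
  A <- matrix(0L, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  ed <- network$edges
  if (nrow(ed) > 0) {
    i <- match(ed$taxon_i, nodes)
    j <- match(ed$taxon_j, nodes)
    ty <- ifelse(ed$type == "aggregation", 1L, 2L)
    A[cbind(i, j)] <- ty
    A[cbind(j, i)] <- ty
  }
  A
}

#' Triangle (clustering) propensities of an association network
#'
#' For every unordered triple where taxa `i` and `j` both associate with
#' a centre `k`, the conditioning pair of edge types is AA, AS or SS, and
#' the `(i, j)` edge contributes an aggregation, a segregation or nothing.
#' The propensity of association type X given condition C compares the
#' conditional frequency of X against its unconditional frequency among
#' evaluable pairs.  Conditions with no triples, or types absent from the
#' network, are flagged undefined.
#'
#' @param network an `assoc_network`.
#' @param scores optional calibrated `score_table` supplying evaluability
#'   flags; by default every node pair counts as evaluable.
#' @return data.frame with one row per (condition, type): `condition`,
#'   `type`, `propensity`, `se`, `n_triples`, `n_hits`, `defined`.
#' @export
triangle_propensities <- function(network, scores = NULL) {
  stopifnot(inherits(network, "assoc_network"))
  nodes <- network$nodes
  nn <- length(nodes)
  A <- adjacency_types(network)
  eval_pair <- matrix(TRUE, nn, nn)
  if (!is.null(scores)) {
    eval_pair <- matrix(FALSE, nn, nn)
    i <- match(scores$taxon_i, nodes)
    j <- match(scores$taxon_j, nodes)
    ok <- scores$evaluable_agg | scores$evaluable_seg
    keep <- !is.na(i) & !is.na(j)
    eval_pair[cbind(i[keep], j[keep])] <- ok[keep]
    eval_pair[cbind(j[keep], i[keep])] <- ok[keep]
  }
  diag(eval_pair) <- FALSE
  n_eval <- sum(eval_pair[upper.tri(eval_pair)])
  K_A <- sum(network$edges$type == "aggregation")
  K_S <- sum(network$edges$type == "segregation")

  conds <- c("AA", "AS", "SS")
  n_cond <- setNames(numeric(3), conds)
  hits <- matrix(0, 3, 2, dimnames = list(conds, c("A", "S")))
  for (k in seq_len(nn)) {
    nb <- which(A[k, ] != 0L)
    if (length(nb) < 2) next
    for (u in seq_len(length(nb) - 1)) {
      for (v in seq((u + 1), length(nb))) {
        i <- nb[u]; j <- nb[v]
        if (!eval_pair[i, j]) next
        tks <- sort(c(A[k, i], A[k, j]))
        cond <- if (tks[1] == 1 && tks[2] == 1) "AA"
        else if (tks[1] == 1) "AS" else "SS"
        n_cond[cond] <- n_cond[cond] + 1
        if (A[i, j] == 1L) hits[cond, "A"] <- hits[cond, "A"] + 1
        if (A[i, j] == 2L) hits[cond, "S"] <- hits[cond, "S"] + 1
      }
    }
  }

  out <- expand.grid(condition = conds, type = c("aggregation", "segregation"),
                     stringsAsFactors = FALSE)
  out <- out[order(out$condition), , drop = FALSE]
  res <- lapply(seq_len(nrow(out)), function(r) {
    cond <- out$condition[r]
    K_X <- if (out$type[r] == "aggregation") K_A else K_S
    n <- n_cond[[cond]]
    k <- hits[cond, if (out$type[r] == "aggregation") "A" else "S"]
    if (n == 0 || k == 0 || K_X == 0 || n_eval == 0)
      return(c(NA_real_, NA_real_, n, k, FALSE))
    val <- log((k / n) / (K_X / n_eval))
    se <- sqrt(max(1 / k - 1 / n, 0) + max(1 / K_X - 1 / n_eval, 0))
    c(val, se, n, k, TRUE)
  })
  res <- do.call(rbind, res)
  out$propensity <- res[, 1]
  out$se <- res[, 2]
  out$n_triples <- res[, 3]
  out$n_hits <- res[, 4]
  out$defined <- as.logical(res[, 5])
  rownames(out) <- NULL
  out
}

#' Nestedness of two nodes in an association network
#'
#' The fraction of network neighbours two nodes share, normalised by the
#' geometric mean of their degrees:
#' `nu_ij = sum_k A_ik A_jk / sqrt(sum_k A_ik * sum_k A_jk)`.
#' One when the nodes share all their links, zero when their
#' neighbourhoods are disjoint; undefined (NA) when either node is
#' isolated.
#'
#' @param network an `assoc_network`.
#' @param i,j node identifiers.
#' @param type which edges form the adjacency (default aggregations, as
#'   in the mutualistic-network usage; `"both"` uses all edges).
#' @return numeric in `[0, 1]`, or `NA` for an isolated node.
#' @export
nestedness <- function(network, i, j,
                       type = c("aggregation", "segregation", "both")) {
  type <- match.arg(type)
  A <- adjacency_types(network)
  adj <- switch(type, aggregation = A == 1L, segregation = A == 2L,
                both = A != 0L)
  if (!(i %in% rownames(adj)) || !(j %in% rownames(adj)))
    stop("node not present in the network")
  di <- sum(adj[i, ]); dj <- sum(adj[j, ])
  if (di == 0 || dj == 0) return(NA_real_)
  sum(adj[i, ] & adj[j, ]) / sqrt(di * dj)
}

#' Assign each taxon its preferred environment
#'
#' A taxon is associated with an environment at the chosen level when
#' strictly more than 50%, and at least 3, of the samples where it is
#' found belong to that environment; otherwise its preference is
#' `"undefined"`.
#'
#' @param X a [presence_matrix()].
#' @param env an [environment_hierarchy()].
#' @param level `"subtype"`, `"type"` or `"supertype"`.
#' @return named character vector (one entry per taxon).
#' @export
assign_environment_preference <- function(X, env,
                                          level = c("subtype", "type", "supertype")) {
  level <- match.arg(level)
  pm <- as_presence(X)
  labels <- stratum_labels(pm$samples, env, level)
  vapply(seq_along(pm$taxa), function(i) {
    present <- pm$X[i, ] == 1L
    m_i <- sum(present)
    if (m_i == 0) return("undefined")
    tab <- table(labels[present])
    top <- which.max(tab)
    if (tab[top] > 0.5 * m_i && tab[top] >= 3) names(tab)[top] else "undefined"
  }, character(1)) -> pref
  setNames(pref, pm$taxa)
}

#' Environmental relatedness classes for all taxon pairs
#'
#' For each pair and each hierarchy level the class is `"Same"` when both
#' taxa prefer the same environment, `"Diff"` when they prefer different
#' ones, and `"Und"` when the preference of at least one is undefined.
#'
#' @param preferences named list with components `subtype`, `type`,
#'   `supertype`, each a named preference vector from
#'   [assign_environment_preference()].
#' @return data.frame with `taxon_i`, `taxon_j`, one column per level,
#'   and `class` (the combined `supertype.type.subtype` label).
#' @export
pair_env_relatedness <- function(preferences) {
  taxa <- names(preferences[[1]])
  pr <- combn(taxa, 2)
  out <- data.frame(taxon_i = pr[1, ], taxon_j = pr[2, ],
                    stringsAsFactors = FALSE)
  for (lev in c("subtype", "type", "supertype")) {
    a <- preferences[[lev]][out$taxon_i]
    b <- preferences[[lev]][out$taxon_j]
    out[[lev]] <- ifelse(a == "undefined" | b == "undefined", "Und",
                         ifelse(a == b, "Same", "Diff"))
  }
  out$class <- paste(out$supertype, out$type, out$subtype, sep = ".")
  out
}

#' Deepest shared taxonomic rank for all taxon pairs
#'
#' Classes are `family`, `order`, `class`, `phylum` (deepest named rank
#' the two lineages share) or `root` when they share none.  Unknown ranks
#' (empty strings) never match.
#'
#' @param taxonomy a [taxonomy_table()].
#' @return data.frame with `taxon_i`, `taxon_j`, `class`.
#' @export
pair_phylo_relatedness <- function(taxonomy) {
  tx <- as.data.frame(taxonomy)
  pr <- combn(tx$taxon, 2)
  i <- match(pr[1, ], tx$taxon)
  j <- match(pr[2, ], tx$taxon)
  shared <- rep("root", ncol(pr))
  for (rank in c("phylum", "class", "order", "family")) {
    hit <- tx[[rank]][i] != "" & tx[[rank]][i] == tx[[rank]][j]
    shared[hit] <- rank
  }
  data.frame(taxon_i = pr[1, ], taxon_j = pr[2, ], class = shared,
             stringsAsFactors = FALSE)
}

#' Association propensity per relatedness class
#'
#' For each pair class (environmental or phylogenetic relatedness) and
#' each association type, the propensity that pairs of that class carry
#' that association, against the unconditional association frequency
#' among evaluable pairs.  Classes with fewer than `min_pairs` pairs are
#' suppressed from the output.
#'
#' @param network an `assoc_network`.
#' @param pair_classes data.frame with `taxon_i`, `taxon_j`, `class`.
#' @param scores optional calibrated `score_table` for evaluability.
#' @param min_pairs minimum class size retained (default 10).
#' @return data.frame: `class`, `type`, `propensity`, `se`, `n_pairs`,
#'   `n_edges`, `defined`.
#' @export
relatedness_propensity <- function(network, pair_classes, scores = NULL,
                                   min_pairs = 10L) {
  stopifnot(inherits(network, "assoc_network"))
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  pc_key <- key(pair_classes$taxon_i, pair_classes$taxon_j)
  keep <- rep(TRUE, nrow(pair_classes))
  if (!is.null(scores)) {
    ev <- scores$evaluable_agg | scores$evaluable_seg
    ev_key <- key(scores$taxon_i, scores$taxon_j)[ev]
    keep <- pc_key %in% ev_key
  }
  classes <- pair_classes$class[keep]
  pc_key <- pc_key[keep]
  total <- length(pc_key)
  ed <- network$edges
  edge_class <- list(
    aggregation = classes[pc_key %in%
                            key(ed$taxon_i, ed$taxon_j)[ed$type == "aggregation"]],
    segregation = classes[pc_key %in%
                            key(ed$taxon_i, ed$taxon_j)[ed$type == "segregation"]])
  cls_tab <- table(classes)
  cls <- names(cls_tab)[cls_tab >= min_pairs]
  out <- do.call(rbind, lapply(cls, function(cl) {
    do.call(rbind, lapply(c("aggregation", "segregation"), function(ty) {
      joint <- sum(edge_class[[ty]] == cl)
      marg_c <- cls_tab[[cl]]
      marg_t <- length(edge_class[[ty]])
      defined <- joint > 0 && marg_t > 0
      val <- if (defined) log(joint / total) - log(marg_c / total) -
        log(marg_t / total) else NA_real_
      se <- if (defined)
        sqrt(max(1 / joint - 1 / marg_c, 0) + max(1 / marg_t - 1 / total, 0))
      else NA_real_
      data.frame(class = cl, type = ty, propensity = val, se = se,
                 n_pairs = marg_c, n_edges = joint, defined = defined,
                 stringsAsFactors = FALSE)
    }))
  }))
  if (is.null(out))
    out <- data.frame(class = character(), type = character(),
                      propensity = numeric(), se = numeric(),
                      n_pairs = integer(), n_edges = integer(),
                      defined = logical(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Environmental cosmopolitanism of each taxon
#'
#' The number of distinct environmental subtypes in which a taxon is
#' present at least once.
#'
#' @param X a [presence_matrix()].
#' @param env an [environment_hierarchy()].
#' @return named integer vector.
#' @export
environmental_cosmopolitanism <- function(X, env) {
  pm <- as_presence(X)
  labels <- stratum_labels(pm$samples, env, "subtype")
  setNames(vapply(seq_along(pm$taxa), function(i)
    length(unique(labels[pm$X[i, ] == 1L])), integer(1)), pm$taxa)
}

#' Community cosmopolitanism of each taxon
#'
#' The effective number of significantly different communities a taxon
#' inhabits:
#' `1 + 2 * sum_{a<b} X_ia X_ib theta(S0 - S_ab) / sum_a X_ia`,
#' where `S_ab` is the sample-aggregation score of the sample pair and
#' the indicator counts pairs with `S_ab < S0` (communities that are
#' *not* significantly similar).  Equals 1 when all of a taxon's
#' communities are significantly similar and `m_i` when they are all
#' different.  Taxa with zero prevalence are `NA`.
#'
#' @param X a [presence_matrix()].
#' @param sample_scores a `score_table` on the sample axis.
#' @param S0 significance threshold on the sample-aggregation score
#'   (default 4.92, the raw score at which its PPV reaches 0.96).
#' @return named numeric vector.
#' @export
community_cosmopolitanism <- function(X, sample_scores, S0 = 4.92) {
  stopifnot(inherits(sample_scores, "score_table"))
  if (attr(sample_scores, "axis") != "samples")
    stop("sample_scores must be computed on the sample axis")
  pm <- as_presence(X)
  M <- length(pm$samples)
  S <- matrix(NA_real_, M, M, dimnames = list(pm$samples, pm$samples))
  i <- match(sample_scores$taxon_i, pm$samples)
  j <- match(sample_scores$taxon_j, pm$samples)
  S[cbind(i, j)] <- sample_scores$S_agg
  S[cbind(j, i)] <- sample_scores$S_agg
  setNames(vapply(seq_along(pm$taxa), function(t) {
    present <- which(pm$X[t, ] == 1L)
    m_i <- length(present)
    if (m_i == 0) return(NA_real_)
    if (m_i == 1) return(1)
    sub <- S[present, present]
    n_diff <- sum(sub[upper.tri(sub)] < S0)
    1 + 2 * n_diff / m_i
  }, numeric(1)), pm$taxa)
}

#' Effective number of environments where a pair co-occurs
#'
#' The exponential of the Shannon entropy of the environment fractions of
#' the samples where both taxa are present, `exp(-sum_i f_i log f_i)`,
#' which discounts rare environments.  1 when all co-occurrences fall in
#' one environment, `k` when they spread uniformly over `k`.
#'
#' @param pair character vector of two taxon identifiers.
#' @param X a [presence_matrix()].
#' @param env an [environment_hierarchy()].
#' @param level hierarchy level at which environments are counted.
#' @return numeric `>= 1`, or `NA` when the pair never co-occurs.
#' @export
effective_environment_count <- function(pair, X, env,
                                        level = c("subtype", "type", "supertype")) {
  level <- match.arg(level)
  pm <- as_presence(X)
  idx <- match(pair, pm$taxa)
  if (anyNA(idx) || length(idx) != 2) stop("pair must name two taxa in X")
  both <- pm$X[idx[1], ] == 1L & pm$X[idx[2], ] == 1L
  if (!any(both)) return(NA_real_)
  labels <- stratum_labels(pm$samples, env, level)
  f <- table(labels[both])
  f <- f / sum(f)
  exp(-sum(f * log(f)))
}

#' Induced subnetwork of taxa tied to a group of environments
#'
#' Keeps taxa that are present in at least `min_subtypes` of the given
#' environmental subtypes and induces the subgraph on them; edges retain
#' their globally computed scores.
#'
#' @param network an `assoc_network`.
#' @param X the [presence_matrix()] the network was computed from.
#' @param env an [environment_hierarchy()].
#' @param subtypes character vector of subtype labels.
#' @param min_subtypes minimum number of those subtypes a taxon must
#'   occupy.
#' @return An `assoc_network` on the selected taxa.
#' @export
select_subnetwork <- function(network, X, env, subtypes, min_subtypes) {
  stopifnot(inherits(network, "assoc_network"))
  pm <- as_presence(X)
  labels <- stratum_labels(pm$samples, env, "subtype")
  unknown <- setdiff(subtypes, unique(labels))
  if (length(unknown) > 0)
    stop("subtypes not present in the hierarchy: ",
         paste(unknown, collapse = ", "))
  n_in <- vapply(seq_along(pm$taxa), function(i)
    length(unique(labels[pm$X[i, ] == 1L & labels %in% subtypes])),
    integer(1))
  keep <- pm$taxa[n_in >= min_subtypes]
  if (length(keep) == 0) warning("no taxa satisfy the subtype condition")
  ed <- network$edges
  ed <- ed[ed$taxon_i %in% keep & ed$taxon_j %in% keep, , drop = FALSE]
  rownames(ed) <- NULL
  structure(list(edges = ed, nodes = keep,
                 thresholds = network$thresholds,
                 consensus_only = network$consensus_only,
                 provenance = network$provenance,
                 n_conflicts = network$n_conflicts),
            class = "assoc_network")
}
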