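# Maximum-likelihood occupancy null model.
#
# Occupancy probabilities follow pi_ia = 1 - exp(-p_i q_a), with a
# per-taxon abundance parameter p_i and a per-sample diversity parameter
# q_a, estimated by maximising
#   L = sum_ia [ X_ia log(pi_ia) + (1 - X_ia) log(1 - pi_ia) ].
# Habitat preferences enter by fitting the taxon parameters separately
# within each environmental subtype: p_i(A) = 0 exactly for taxa never
# observed in subtype A, so such taxa are never drawn there either.
#
# Only the products p_i q_a are identifiable; the gauge is fixed by
# constraining mean(q) = 1 within each stratum.  The solver is a damped
# Newton method on (log p, log q) with analytic gradient and Hessian and
# Armijo backtracking; when the Newton step fails it falls back to one
# sweep of block coordinate ascent (the likelihood is concave in each
# single parameter, so 1-D Newton steps are safe).  Taxa present in every
# sample of a stratum push their parameter to +Inf; a saturation guard
# caps products so that pi <= 1 - 1e-12 and flags the stratum.

EPS_CAP <- 1e-12
TCAP <- -log(EPS_CAP)   # max allowed p*q product

as_presence <- function(X) {
  if (inherits(X, "presence_matrix")) return(X)
  presence_matrix(as.matrix(X))
}

# stratum labels for every sample, given the configured hierarchy level
stratum_labels <- function(samples, env, level) {
  if (level == "global") return(setNames(rep("global", length(samples)), samples))
  if (is.null(env)) stop("stratified fit requires an environment table")
  idx <- match(samples, env$sample)
  if (anyNA(idx))
    stop("samples missing from the environment table: ",
         paste(utils::head(samples[is.na(idx)], 3), collapse = ", "))
  setNames(env[[level]][idx], samples)
}

# gradient of L with respect to (p, q) at the current parameters
ll_gradient <- function(Xs, p, q) {
  T_ <- outer(p, q)
  E <- exp(-T_)
  Pi <- -expm1(-T_)
  A <- Xs * (E / Pi) - (1 - Xs)          # dL/dT
  list(g_p = as.vector(A %*% q), g_q = as.vector(crossprod(A, p)),
       T_ = T_, E = E, Pi = Pi, A = A)
}

stratum_loglik <- function(Xs, p, q) {
  T_ <- outer(p, q)
  Pi <- -expm1(-T_)
  lp <- ifelse(Xs == 1, log(Pi), 0)
  sum(lp) - sum((1 - Xs) * T_)
}

# exact-ish conditional maximisation of one parameter block (vectorised
# 1-D Newton in log space; each coordinate's conditional likelihood is
# concave, steps are clamped for safety)
solve_block <- function(Xs, p, q, block = c("p", "q"), sweeps = 8) {
  block <- match.arg(block)
  for (s in seq_len(sweeps)) {
    gr <- ll_gradient(Xs, p, q)
    B <- Xs * gr$E / gr$Pi^2
    if (block == "p") {
      g <- gr$g_p
      h <- -as.vector(B %*% (q^2))
      gu <- p * g
      hu <- p^2 * h + gu
      step <- ifelse(hu < 0, -gu / hu, sign(gu))
      p <- p * exp(pmax(pmin(step, 2), -2))
      p <- pmin(p, TCAP / max(q))
    } else {
      g <- gr$g_q
      h <- -as.vector(crossprod(B, p^2))
      gv <- q * g
      hv <- q^2 * h + gv
      step <- ifelse(hv < 0, -gv / hv, sign(gv))
      q <- q * exp(pmax(pmin(step, 2), -2))
      q <- pmin(q, TCAP / max(p))
    }
  }
  list(p = p, q = q)
}

fit_stratum <- function(Xs, tol = 1e-8, max_iter = 500L) {
  nr <- nrow(Xs); nc <- ncol(Xs)
  rf <- pmin(rowMeans(Xs), 1 - 1e-10)
  cf <- pmin(colMeans(Xs), 1 - 1e-10)
  p <- pmax(-log(1 - rf), 1e-6)
  q <- pmax(-log(1 - cf), 1e-6)
  cg <- mean(q); q <- q / cg; p <- p * cg
  cap_clamp <- function(p, q) {
    p <- pmin(p, TCAP / max(q))
    q <- pmin(q, TCAP / max(p))
    list(p = p, q = q)
  }
  cl <- cap_clamp(p, q); p <- cl$p; q <- cl$q
  L <- stratum_loglik(Xs, p, q)
  converged <- FALSE
  it <- 0L
  grad_norm <- Inf
  for (it in seq_len(max_iter)) {
    gr <- ll_gradient(Xs, p, q)
    sat_p <- p >= TCAP / max(q) - 1e-9
    sat_q <- q >= TCAP / max(p) - 1e-9
    free_g <- c(gr$g_p[!sat_p], gr$g_q[!sat_q])
    grad_norm <- if (length(free_g) > 0) max(abs(free_g)) else 0
    if (grad_norm < tol) { converged <- TRUE; break }

    # assemble the log-space Newton system
    B <- Xs * gr$E / gr$Pi^2
    h_pp <- -as.vector(B %*% (q^2))
    h_qq <- -as.vector(crossprod(B, p^2))
    H_pq <- gr$A - Xs * gr$T_ * gr$E / gr$Pi^2
    gu <- p * gr$g_p
    gv <- q * gr$g_q
    Huu <- p^2 * h_pp + gu
    Hvv <- q^2 * h_qq + gv
    Huv <- gr$T_ * H_pq
    g_log <- c(gu, gv)
    # block solve of [diag(Huu) Huv; t(Huv) diag(Hvv)] delta = -g_log,
    # eliminating the larger block through the Schur complement
    delta <- tryCatch({
      if (min(abs(Huu)) < 1e-300 || min(abs(Hvv)) < 1e-300)
        stop("singular diagonal block")
      if (nc >= nr) {
        binv <- 1 / Hvv
        S <- -Huv %*% (binv * t(Huv))
        diag(S) <- diag(S) + Huu
        du <- solve(S, -gu + Huv %*% (binv * gv))
        dv <- binv * (-gv - as.vector(crossprod(Huv, du)))
        c(du, dv)
      } else {
        ainv <- 1 / Huu
        S <- -t(Huv) %*% (ainv * Huv)
        diag(S) <- diag(S) + Hvv
        dv <- solve(S, -gv + t(Huv) %*% (ainv * gu))
        du <- ainv * (-gu - as.vector(Huv %*% dv))
        c(du, dv)
      }
    }, error = function(e) NULL)

    accepted <- FALSE
    if (!is.null(delta) && all(is.finite(delta)) &&
        sum(delta * g_log) > 0) {
      alpha <- 1
      for (bt in 1:30) {
        p_new <- p * exp(alpha * delta[seq_len(nr)])
        q_new <- q * exp(alpha * delta[nr + seq_len(nc)])
        cl <- cap_clamp(p_new, q_new)
        L_new <- stratum_loglik(Xs, cl$p, cl$q)
        if (is.finite(L_new) &&
            L_new >= L + 1e-4 * alpha * sum(delta * g_log) - 1e-12) {
          p <- cl$p; q <- cl$q; L <- L_new
          accepted <- TRUE
          break
        }
        alpha <- alpha / 2
      }
    }
    if (!accepted) {       # coordinate-ascent fallback sweep
      bl <- solve_block(Xs, p, q, "p", sweeps = 2)
      bl <- solve_block(Xs, bl$p, bl$q, "q", sweeps = 2)
      cl <- cap_clamp(bl$p, bl$q)
      L_new <- stratum_loglik(Xs, cl$p, cl$q)
      if (is.finite(L_new) && L_new >= L - 1e-10) {
        p <- cl$p; q <- cl$q; L <- L_new
      }
    }
    cg <- mean(q); q <- q / cg; p <- p * cg     # re-fix the gauge
  }
  sat_p <- p >= TCAP / max(q) - 1e-9
  sat_q <- q >= TCAP / max(p) - 1e-9
  saturated <- any(sat_p) || any(sat_q)
  list(p = p, q = q, loglik = L, grad_norm = grad_norm,
       iterations = it, converged = converged || saturated,
       saturated = saturated)
}

#' Fit the stratified maximum-likelihood occupancy null model
#'
#' Estimates per-taxon abundance parameters `p_i(A)` and per-sample
#' diversity parameters `q_a` of the occupancy model
#' `pi_ia = 1 - exp(-p_i(A(a)) q_a)` by maximum likelihood, solving the
#' likelihood equations separately for the samples of each environmental
#' stratum.  Taxa never observed within a stratum receive `p_i(A) = 0`
#' exactly, so the null model never places them there.
#'
#' @param X a [presence_matrix()] (or plain binary matrix).
#' @param env an [environment_hierarchy()] table; may be `NULL` when
#'   `level = "global"`.
#' @param level stratification level: `"subtype"` (default), `"type"`,
#'   `"supertype"` or `"global"` (a single all-samples stratum).
#' @param tol convergence tolerance on the infinity norm of the
#'   likelihood gradient with respect to `(p, q)` per stratum.
#' @param max_iter maximum Newton iterations per stratum.
#' @return Object of class `cooc_null_model`: list with `p` (taxa-by-strata
#'   parameter matrix), `q` (per-sample vector), `pi` (occupancy
#'   probability matrix), `strata` (per-sample stratum labels), `level`,
#'   and `fit` (per-stratum diagnostics: log-likelihood, gradient norm,
#'   iteration count, saturation flag).
#' @export
fit_null_model <- function(X, env = NULL,
                           level = c("subtype", "global", "type", "supertype"),
                           tol = 1e-8, max_iter = 500L) {
  level <- match.arg(level)
  pm <- as_presence(X)
  Xm <- pm$X
  N <- nrow(Xm); M <- ncol(Xm)
  if (N == 0 || M == 0) stop("presence matrix must be non-empty")
  strata <- stratum_labels(pm$samples, env, level)
  stratum_names <- unique(strata)

  p_mat <- matrix(0, N, length(stratum_names),
                  dimnames = list(pm$taxa, stratum_names))
  q_vec <- setNames(numeric(M), pm$samples)
  pi_mat <- matrix(0, N, M, dimnames = list(pm$taxa, pm$samples))
  reports <- vector("list", length(stratum_names))

  for (k in seq_along(stratum_names)) {
    A <- stratum_names[k]
    cols <- which(strata == A)
    if (length(cols) == 0) {
      warning("stratum '", A, "' has no samples; skipped")
      next
    }
    Xa <- Xm[, cols, drop = FALSE]
    rows <- which(rowSums(Xa) > 0)         # taxa observed in this stratum
    report <- list(stratum = A, n_taxa = length(rows),
                   n_samples = length(cols), loglik = 0,
                   grad_norm = 0, iterations = 0L,
                   converged = TRUE, saturated = FALSE)
    if (length(rows) > 0) {
      Xs_full <- Xa[rows, , drop = FALSE]
      use_cols <- which(colSums(Xs_full) > 0)  # samples with >= 1 observed taxon
      if (length(use_cols) > 0) {
        Xs <- Xs_full[, use_cols, drop = FALSE]
        fit <- fit_stratum(Xs, tol = tol, max_iter = max_iter)
        if (!fit$converged)
          stop(sprintf(
            "null model did not converge in stratum '%s' (gradient norm %.3g after %d iterations)",
            A, fit$grad_norm, fit$iterations))
        p_mat[rows, k] <- fit$p
        q_vec[cols[use_cols]] <- fit$q
        pi_mat[rows, cols[use_cols]] <- -expm1(-outer(fit$p, fit$q))
        report$loglik <- fit$loglik
        report$grad_norm <- fit$grad_norm
        report$iterations <- fit$iterations
        report$converged <- fit$converged
        report$saturated <- fit$saturated
      }
    }
    reports[[k]] <- report
  }
  fit_report <- do.call(rbind, lapply(reports[!vapply(reports, is.null, TRUE)],
                                      as.data.frame))
  structure(list(p = p_mat, q = q_vec, pi = pi_mat, strata = strata,
                 level = level, fit = fit_report,
                 taxa = pm$taxa, samples = pm$samples),
            class = "cooc_null_model")
}

#' @export
print.cooc_null_model <- function(x, ...) {
  cat(sprintf("cooc_null_model: %d taxa x %d samples, level '%s', %d strata\n",
              nrow(x$pi), ncol(x$pi), x$level, ncol(x$p)))
  cat(sprintf("  total log-likelihood %.4f; max gradient norm %.3g%s\n",
              sum(x$fit$loglik), max(x$fit$grad_norm),
              if (any(x$fit$saturated)) " (saturation guard engaged)" else ""))
  invisible(x)
}

#' Log-likelihood of a presence matrix under a fitted null model
#'
#' Evaluates `sum_ia [X_ia log(pi_ia) + (1 - X_ia) log(1 - pi_ia)]` with
#' the convention `0 * log 0 = 0`; the result is `-Inf` only when a taxon
#' is observed in a cell the model assigns probability zero.
#'
#' @param X a [presence_matrix()] or binary matrix.
#' @param model a fitted `cooc_null_model` (or any list with a `pi` matrix).
#' @return scalar log-likelihood.
#' @export
log_likelihood <- function(X, model) {
  pm <- as_presence(X)
  Pi <- model$pi
  if (!all(dim(pm$X) == dim(Pi))) stop("matrix and model shapes disagree")
  Xm <- pm$X
  t1 <- sum(ifelse(Xm == 1, log(Pi), 0))
  t2 <- sum(ifelse(Xm == 0, log1p(-Pi), 0))
  t1 + t2
}

#' Draw a random presence-absence matrix from the null model
#'
#' Each cell is an independent Bernoulli draw with probability `pi_ia`.
#' Identical seeds give identical matrices; cells with `pi_ia = 0` are
#' always absent.
#'
#' @param model a fitted `cooc_null_model`.
#' @param seed integer seed.
#' @return a [presence_matrix()].
#' @export
sample_matrix <- function(model, seed) {
  draw_cells(model$pi, seed)
}

# shared cell-drawing primitive (also used by the synthetic generator so
# that an uncoupled synthetic matrix and a null draw from the same pi and
# seed are bit-identical)
draw_cells <- function(pi_mat, seed) {
  set.seed(as.integer(seed))
  u <- matrix(runif(length(pi_mat)), nrow(pi_mat), ncol(pi_mat))
  X <- (u < pi_mat) * 1L
  dimnames(X) <- dimnames(pi_mat)
  presence_matrix(X)
}
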