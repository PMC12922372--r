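#' Mid-rank transform
#'
#' Joint ranking of all observations; ties receive the average (mid) rank,
#' so the rank sum is always `n(n+1)/2`.
#'
#' @param values numeric vector of length >= 2.
#' @return numeric vector of mid-ranks.
#' @export
rank_transform <- function(values) {
  stopifnot(length(values) >= 2)
  rank(values, ties.method = "average")
}

# Symmetric inverse square root with eigenvalue clipping; used for the
# CR2 residual adjustment (I - H_gg)^{-1/2}.
.sym_inv_sqrt <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  vals <- pmax(e$values, 1e-12)
  e$vectors %*% (t(e$vectors) / sqrt(vals))
}

# Core fitting engine: OLS of mid-ranks on group indicators (cell-means
# coding) with a cluster-robust sandwich covariance. type = "CR2" applies
# the small-sample residual adjustment; Satterthwaite degrees of freedom
# per contrast follow the Bell-McCaffrey construction.
.rank_ols_cluster <- function(y, group, cluster, type = c("CR2", "CR0")) {
  type <- match.arg(type)
  group <- droplevels(as.factor(group))
  cluster <- as.factor(as.character(cluster))
  k <- nlevels(group)
  if (k < 2) stop("at least two groups are required")
  tab <- table(unique(data.frame(g = group, cl = cluster))$g)
  cl_per_group <- tapply(cluster, group, function(x) length(unique(x)))
  if (any(cl_per_group < 2))
    stop(sprintf("every group needs >= 2 clusters (got: %s)",
                 paste(cl_per_group, collapse = ", ")))
  r <- rank_transform(y)
  X <- stats::model.matrix(~ 0 + group)
  XtX <- crossprod(X)
  if (any(diag(XtX) == 0)) stop("singular design: empty group")
  M <- solve(XtX)
  beta <- drop(M %*% crossprod(X, r))
  e <- r - drop(X %*% beta)
  G <- nlevels(cluster)
  n <- length(y)
  cl_idx <- split(seq_len(n), cluster)
  scores <- matrix(0, G, k)
  adj <- vector("list", G)
  for (gi in seq_len(G)) {
    ii <- cl_idx[[gi]]
    Xg <- X[ii, , drop = FALSE]
    if (type == "CR2") {
      Hgg <- Xg %*% M %*% t(Xg)
      Ag <- .sym_inv_sqrt(diag(length(ii)) - Hgg)
      adj[[gi]] <- Ag
      scores[gi, ] <- crossprod(Xg, Ag %*% e[ii])
    } else {
      adj[[gi]] <- diag(length(ii))
      scores[gi, ] <- crossprod(Xg, e[ii])
    }
  }
  meat <- crossprod(scores)
  V <- M %*% meat %*% M
  # Satterthwaite df for a contrast c (Bell-McCaffrey): eigenvalues of
  # T'T where column g of T is (I - H)' s_g and s_g holds A_g X_g M c on
  # cluster g's rows.
  satt_df <- function(cvec) {
    Tm <- matrix(0, n, G)
    for (gi in seq_len(G)) {
      ii <- cl_idx[[gi]]
      s <- rep(0, n)
      s[ii] <- drop(adj[[gi]] %*% (X[ii, , drop = FALSE] %*% (M %*% cvec)))
      Tm[, gi] <- s - drop(X %*% (M %*% crossprod(X, s)))
    }
    lam <- eigen(crossprod(Tm), symmetric = TRUE, only.values = TRUE)$values
    lam <- pmax(lam, 0)
    if (sum(lam^2) == 0) return(G - k)
    sum(lam)^2 / sum(lam^2)
  }
  list(beta = beta, V = V, groups = levels(group), k = k, G = G, n = n,
       n_per_group = as.vector(table(group)),
       clusters_per_group = as.vector(cl_per_group),
       satt_df = satt_df, type = type)
}

#' Tukey adjustment of pairwise contrast p-values
#'
#' Adjusted p-values from the studentized-range distribution at the
#' contrasts' (robust) degrees of freedom. Defined on the full family of
#' `k(k-1)/2` pairwise comparisons; with `k = 2` the adjusted p equals the
#' raw p.
#'
#' @param t_stats vector of contrast t statistics (all pairs).
#' @param k number of groups.
#' @param df degrees of freedom (scalar or per contrast).
#' @param p_raw optional raw p-values; adjusted values are never smaller.
#' @return adjusted p-values.
#' @export
tukey_adjust <- function(t_stats, k, df, p_raw = NULL) {
  if (length(t_stats) != k * (k - 1) / 2)
    stop(sprintf("Tukey adjustment requires the full family of %d pairwise contrasts",
                 k * (k - 1) / 2))
  df <- rep_len(df, length(t_stats))
  p <- stats::ptukey(sqrt(2) * abs(t_stats), nmeans = k, df = df,
                     lower.tail = FALSE)
  if (!is.null(p_raw)) p <- pmax(p, p_raw)
  p
}

.contrast_rows <- function(fit, alpha, adjust = c("tukey", "holm", "none")) {
  adjust <- match.arg(adjust)
  k <- fit$k
  pairs <- utils::combn(k, 2)
  rows <- data.frame(group1 = fit$groups[pairs[1, ]],
                     group2 = fit$groups[pairs[2, ]])
  est <- se <- df <- tt <- pp <- numeric(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    cvec <- rep(0, k)
    cvec[pairs[1, j]] <- 1; cvec[pairs[2, j]] <- -1
    est[j] <- sum(cvec * fit$beta)
    se[j] <- sqrt(drop(t(cvec) %*% fit$V %*% cvec))
    df[j] <- fit$satt_df(cvec)
    tt[j] <- if (se[j] > 0) est[j] / se[j] else 0
    pp[j] <- 2 * stats::pt(-abs(tt[j]), df[j])
  }
  rows$estimate <- est; rows$se <- se; rows$df <- df
  rows$t <- tt; rows$p <- pp
  rows$p_adj <- switch(adjust,
                       tukey = tukey_adjust(tt, k, df, p_raw = pp),
                       holm = stats::p.adjust(pp, "holm"),
                       none = pp)
  rows
}

#' Cluster-robust rank-based one-way ANOVA
#'
#' The omnibus and pairwise inference used for per-cell measurements with
#' more than two groups: (1) mid-rank transform of the response, jointly
#' over all observations; (2) least squares of ranks on group indicators;
#' (3) cluster-robust sandwich covariance with a CR2-type small-sample
#' adjustment; (4) omnibus Wald F with a cluster-count denominator df; (5)
#' all pairwise rank-mean contrasts with Satterthwaite df, Tukey-adjusted.
#'
#' @param table data.frame of per-cell measurements.
#' @param response,group,cluster column names.
#' @param alpha significance level.
#' @param type `"CR2"` (small-sample adjusted, default) or `"CR0"`.
#' @param adjust multiplicity adjustment for the pairwise contrasts:
#'   `"tukey"` (default), `"holm"` or `"none"`.
#' @return a `rank_test_result`: omnibus `F`, `df1`, `df2`, `p`; a
#'   `contrasts` data.frame (estimate = rank-mean difference, robust SE,
#'   Satterthwaite df, raw and adjusted p); group sizes; the variance
#'   estimator label.
#' @export
cluster_robust_rank_anova <- function(table, response = "value",
                                      group = "group", cluster = "cluster",
                                      alpha = 0.05, type = c("CR2", "CR0"),
                                      adjust = c("tukey", "holm", "none")) {
  type <- match.arg(type); adjust <- match.arg(adjust)
  y <- table[[response]]; g <- table[[group]]; cl <- table[[cluster]]
  keep <- !is.na(y)
  fit <- .rank_ols_cluster(y[keep], g[keep], cl[keep], type)
  k <- fit$k
  contrasts <- .contrast_rows(fit, alpha, adjust)
  # omnibus Wald F on k-1 difference contrasts; Satterthwaite-style
  # denominator df: the smallest Bell-McCaffrey df over the pairwise
  # contrasts, a conservative small-sample reference driven by the
  # cluster count
  R <- cbind(-1, diag(k - 1))
  Rb <- drop(R %*% fit$beta)
  RVR <- R %*% fit$V %*% t(R)
  Fstat <- if (all(abs(Rb) < 1e-12)) 0 else
    drop(t(Rb) %*% solve(RVR, Rb)) / (k - 1)
  df2 <- min(contrasts$df)
  p_omni <- stats::pf(Fstat, k - 1, df2, lower.tail = FALSE)
  structure(list(test = "cluster-robust rank one-way ANOVA",
                 groups = fit$groups,
                 omnibus = list(statistic = Fstat, df1 = k - 1, df2 = df2,
                                p = p_omni, distribution = "F"),
                 contrasts = contrasts,
                 n_cells = fit$n_per_group,
                 n_clusters = fit$clusters_per_group,
                 variance_estimator = fit$type,
                 adjust = adjust, alpha = alpha),
            class = "rank_test_result")
}

#' Cluster-robust rank-based two-sample t-test
#'
#' The two-group case: ranks are computed over the two groups being
#' compared, the group contrast is tested with a CR2-type cluster-robust
#' SE and Satterthwaite df; no multiplicity adjustment.
#'
#' @inheritParams cluster_robust_rank_anova
#' @return a `rank_test_result` with a single contrast.
#' @export
cluster_robust_rank_ttest <- function(table, response = "value",
                                      group = "group", cluster = "cluster",
                                      alpha = 0.05, type = c("CR2", "CR0")) {
  type <- match.arg(type)
  y <- table[[response]]; g <- droplevels(as.factor(table[[group]]))
  if (nlevels(g) != 2) stop("exactly two groups are required")
  keep <- !is.na(y)
  fit <- .rank_ols_cluster(y[keep], g[keep], table[[cluster]][keep], type)
  contrasts <- .contrast_rows(fit, alpha, adjust = "none")
  structure(list(test = "cluster-robust rank two-sample t-test",
                 groups = fit$groups,
                 omnibus = list(statistic = contrasts$t[1]^2, df1 = 1,
                                df2 = contrasts$df[1], p = contrasts$p[1],
                                distribution = "F"),
                 contrasts = contrasts,
                 n_cells = fit$n_per_group,
                 n_clusters = fit$clusters_per_group,
                 variance_estimator = fit$type,
                 adjust = "none", alpha = alpha),
            class = "rank_test_result")
}

#' Naive rank-based one-way ANOVA (clusters ignored)
#'
#' The classical F test on mid-ranks with no clustering adjustment. Kept as
#' the comparison baseline: with correlated cells within animals or
#' experiments it is anti-conservative, which is the motivation for the
#' cluster-robust procedure.
#'
#' @inheritParams cluster_robust_rank_anova
#' @return `list(statistic, df1, df2, p)`.
#' @export
naive_rank_anova <- function(table, response = "value", group = "group") {
  y <- table[[response]]; g <- droplevels(as.factor(table[[group]]))
  keep <- !is.na(y)
  r <- rank_transform(y[keep])
  fit <- stats::aov(r ~ g[keep])
  s <- summary(fit)[[1]]
  list(statistic = s$`F value`[1], df1 = s$Df[1], df2 = s$Df[2],
       p = s$`Pr(>F)`[1])
}

#' Two-sided Mann-Whitney U test
#'
#' Exact enumeration of the permutation distribution of U (mid-ranks, so
#' ties are handled) when the pooled sample is small; tie-corrected normal
#' approximation with continuity correction otherwise.
#'
#' @param x,y numeric samples (non-empty).
#' @param exact force exact (`TRUE`) or approximate (`FALSE`); default
#'   enumerates exactly when `length(x) + length(y) <= 20`.
#' @return `list(statistic = U for x, p.value, method)`.
#' @export
mann_whitney <- function(x, y, exact = NULL) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  pooled <- c(x, y)
  r <- rank(pooled, ties.method = "average")
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (is.null(exact)) exact <- n <= 20
  if (exact) {
    splits <- utils::combn(n, n1)
    usum <- colSums(matrix(r[splits], nrow = n1)) - n1 * (n1 + 1) / 2
    p_lo <- mean(usum <= U + 1e-9)
    p_hi <- mean(usum >= U - 1e-9)
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "exact enumeration"
  } else {
    mu <- n1 * n2 / 2
    ties <- table(r)
    sig2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sig2 <= 0) return(list(statistic = U, p.value = 1,
                               method = "normal approximation (degenerate)"))
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation with tie correction"
  }
  list(statistic = U, p.value = p, method = method)
}

#' Significance stars
#'
#' The 0.05 / 0.01 / 0.001 ladder used in figure legends.
#'
#' @param p p-value vector.
#' @return character vector: `"n.s."`, `"*"`, `"**"`, `"***"`.
#' @export
sig_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "n.s.")))
}

#' @export
print.rank_test_result <- function(x, ...) {
  cat(sprintf("%s (%s variance estimator)\n", x$test, x$variance_estimator))
  cat(sprintf("groups: %s; cells per group: %s; clusters per group: %s\n",
              paste(x$groups, collapse = ", "),
              paste(x$n_cells, collapse = ", "),
              paste(x$n_clusters, collapse = ", ")))
  cat(sprintf("omnibus: F(%g, %g) = %.4g, p = %.4g %s\n",
              x$omnibus$df1, x$omnibus$df2, x$omnibus$statistic,
              x$omnibus$p, sig_stars(x$omnibus$p)))
  ct <- x$contrasts
  for (i in seq_len(nrow(ct)))
    cat(sprintf("  %s vs %s: diff = %.3g, SE = %.3g, df = %.1f, p = %.4g, adj p = %.4g %s\n",
                ct$group1[i], ct$group2[i], ct$estimate[i], ct$se[i],
                ct$df[i], ct$p[i], ct$p_adj[i], sig_stars(ct$p_adj[i])))
  invisible(x)
}
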