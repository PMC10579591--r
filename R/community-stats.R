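#' Shannon diversity index
#'
#' Shannon entropy of a community profile in natural-log units (nats),
#' \eqn{H = -\sum_i p_i \ln p_i}, computed over the strictly positive
#' entries after normalizing the vector to sum to one.
#'
#' @param x Numeric vector of nonnegative abundances (relative or raw;
#'   the index is scale-invariant).
#' @return Shannon diversity in nats.
#' @examples
#' shannon_diversity(rep(1, 4))  # log(4)
#' @export
shannon_diversity <- function(x) {
  if (!is.numeric(x) || any(x < 0)) stop("abundances must be nonnegative numbers")
  s <- sum(x)
  if (s <= 0) stop("Shannon diversity is undefined for an all-zero profile")
  p <- x[x > 0] / s
  -sum(p * log(p))
}

#' Observed richness
#'
#' Number of entities with abundance strictly above a detection
#' threshold (default 0, i.e. any positive abundance counts).
#'
#' @param x Numeric vector of nonnegative abundances.
#' @param threshold Detection threshold; entries must exceed it strictly.
#' @return Integer count.
#' @export
observed_richness <- function(x, threshold = 0) {
  if (threshold < 0) stop("threshold must be >= 0")
  sum(x > threshold)
}

#' Bray-Curtis dissimilarity matrix
#'
#' Pairwise Bray-Curtis dissimilarity between the columns (samples) of an
#' abundance matrix: \eqn{D_{st} = \sum_i |a_{is}-a_{it}| / \sum_i
#' (a_{is}+a_{it})}.  Pairs in which both samples are all-zero have an
#' undefined dissimilarity and are returned as `NA` with a warning.
#'
#' @param mat Numeric matrix, features x samples, entries >= 0.
#' @return Symmetric samples x samples matrix with zero diagonal.
#' @export
bray_curtis <- function(mat) {
  mat <- as.matrix(mat)
  if (any(mat < 0)) stop("abundances must be nonnegative")
  n <- ncol(mat)
  D <- matrix(0, n, n, dimnames = list(colnames(mat), colnames(mat)))
  tot <- colSums(mat)
  for (i in seq_len(n - 1)) {
    xi <- mat[, i]
    num <- colSums(abs(mat[, (i + 1):n, drop = FALSE] - xi))
    den <- tot[(i + 1):n] + tot[i]
    d <- ifelse(den > 0, num / den, NA_real_)
    D[i, (i + 1):n] <- d
    D[(i + 1):n, i] <- d
  }
  if (anyNA(D)) warning("pairs of all-zero samples have undefined Bray-Curtis dissimilarity (NA)")
  D
}

#' Principal coordinates analysis (classical MDS)
#'
#' Gower double-centering of the squared distance matrix,
#' \eqn{B = -\tfrac12 J (D \circ D) J} with \eqn{J = I - \mathbf{1}\mathbf{1}'/n},
#' followed by eigendecomposition.  Coordinates are eigenvectors scaled
#' by the square root of their (positive) eigenvalues; negative
#' eigenvalues are reported unchanged and receive no correction.
#'
#' @param d Distance matrix (symmetric matrix or `dist`).
#' @return Object of class `pcoa_ordination`: list with `points`
#'   (samples x axes), `eigenvalues` (all, decreasing), and
#'   `proportion` (variance fraction per positive axis, relative to the
#'   sum of positive eigenvalues).
#' @export
pcoa_ordination <- function(d) {
  D <- as.matrix(d)
  n <- nrow(D)
  if (n < 3) stop("PCoA requires at least 3 samples")
  if (!isSymmetric(unname(D), tol = 1e-8)) stop("distance matrix must be symmetric")
  G <- dbl_center(D)
  eg <- eigen(G, symmetric = TRUE)
  ev <- eg$values
  tol <- max(abs(ev)) * 1e-9
  pos <- which(ev > tol)
  pts <- eg$vectors[, pos, drop = FALSE] %*% diag(sqrt(ev[pos]), length(pos))
  rownames(pts) <- rownames(D)
  colnames(pts) <- paste0("PCo", seq_along(pos))
  structure(list(points = pts,
                 eigenvalues = ev,
                 proportion = ev[pos] / sum(ev[pos])),
            class = "pcoa_ordination")
}

#' @export
print.pcoa_ordination <- function(x, ...) {
  cat("Principal coordinates analysis:", nrow(x$points), "samples,",
      ncol(x$points), "positive axes\n")
  k <- min(2, length(x$proportion))
  cat("Variance explained by first axes:",
      paste0(sprintf("%.1f%%", 100 * x$proportion[seq_len(k)]), collapse = ", "), "\n")
  invisible(x)
}

# Gower double-centered Gram matrix from a distance matrix
dbl_center <- function(D) {
  A <- -0.5 * D^2
  rm_ <- rowMeans(A)
  A - outer(rm_, rep(1, ncol(A))) - outer(rep(1, nrow(A)), colMeans(A)) + mean(A)
}

#' PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance.  With the
#' double-centered Gram matrix \eqn{G} and the hat matrix \eqn{H} of the
#' centered design, \eqn{R^2 = \mathrm{tr}(HGH)/\mathrm{tr}(G)},
#' \eqn{F = (SS_{model}/df_{model}) / (SS_{res}/df_{res})}, and the
#' p-value is obtained by permuting samples:
#' \eqn{p = (1 + \#\{F_{perm} \ge F_{obs}\}) / (1 + n_{perm})}, or the
#' exact fraction over all \eqn{n!} permutations when `exhaustive`.
#' The adjusted \eqn{R^2} is \eqn{1 - (1-R^2)(n-1)/(n-df_{model}-1)}.
#'
#' @param d Distance matrix (symmetric matrix or `dist`).
#' @param predictors Vector/factor (one predictor) or data.frame/matrix
#'   of predictors, rows aligned with the samples of `d`.  Categorical
#'   predictors are expanded to treatment contrasts; continuous ones are
#'   used as given.
#' @param n_permutations Number of random permutations (default 999).
#' @param seed Integer seed; mandatory when random permutations are used.
#' @param exhaustive If `TRUE`, enumerate all n! permutations (error if
#'   that exceeds 1e6).
#' @param strata Optional factor; permutations are then performed within
#'   its levels.
#' @param drop_collinear If `TRUE`, linearly dependent design columns are
#'   dropped (rank handling); if `FALSE` (default) a rank-deficient
#'   design is an error.
#' @return Object of class `permanova`: list with `r2`, `adjusted_r2`,
#'   `f_stat`, `p_value`, `df_model`, `df_residual`, `n_permutations`,
#'   `seed`, `exhaustive`.
#' @export
permanova <- function(d, predictors, n_permutations = 999, seed = NULL,
                      exhaustive = FALSE, strata = NULL,
                      drop_collinear = FALSE) {
  D <- as.matrix(d)
  n <- nrow(D)
  if (n < 4) stop("PERMANOVA requires at least 4 samples")
  X <- build_design(predictors, n)
  Xc <- sweep(X, 2, colMeans(X))
  qx <- qr(Xc)
  r <- qx$rank
  if (r == 0) stop("design has no variation (constant predictor)")
  if (r < ncol(Xc) && !drop_collinear)
    stop("rank-deficient design; set drop_collinear = TRUE to drop dependent columns")
  Q <- qr.Q(qx)[, seq_len(r), drop = FALSE]
  G <- dbl_center(D)
  ss_total <- sum(diag(G))
  df_model <- r
  df_res <- n - r - 1
  if (df_res <= 0) stop("too many predictors for the number of samples")
  ss_model <- sum(Q * (G %*% Q))
  ss_res <- ss_total - ss_model
  f_obs <- (ss_model / df_model) / (ss_res / df_res)
  r2 <- ss_model / ss_total
  adj <- 1 - (1 - r2) * (n - 1) / (n - df_model - 1)

  perm_f <- function(p) {
    Qp <- Q[p, , drop = FALSE]
    ssm <- sum(Qp * (G %*% Qp))
    (ssm / df_model) / ((ss_total - ssm) / df_res)
  }
  # saturated fits (zero residual) have infinite F; only an equally
  # saturated permutation can tie them
  thr <- if (is.finite(f_obs)) f_obs - 1e-10 * max(1, abs(f_obs)) else Inf
  if (exhaustive) {
    if (!is.null(strata)) stop("exhaustive permutation does not support strata")
    n_all <- factorial(n)
    if (n_all > 1e6) stop("exhaustive enumeration infeasible: ", n_all, " permutations > 1e6")
    perms <- all_permutations(n)
    fs <- vapply(perms, perm_f, numeric(1))
    p_val <- sum(fs >= thr) / n_all
    n_perm <- n_all
  } else {
    if (n_permutations < 1) stop("n_permutations must be >= 1")
    if (is.null(seed)) stop("a seed is mandatory for random permutations")
    set.seed(as.integer(seed))
    count <- 0L
    for (k in seq_len(n_permutations)) {
      p <- if (is.null(strata)) sample.int(n) else strata_permutation(strata)
      if (perm_f(p) >= thr) count <- count + 1L
    }
    p_val <- (1 + count) / (1 + n_permutations)
    n_perm <- n_permutations
  }
  structure(list(r2 = r2, adjusted_r2 = adj, f_stat = f_obs, p_value = p_val,
                 df_model = df_model, df_residual = df_res,
                 n_permutations = n_perm, seed = seed, exhaustive = exhaustive),
            class = "permanova")
}

#' @export
print.permanova <- function(x, ...) {
  cat(sprintf("PERMANOVA: R2 = %.4f (adjusted %.4f), F(%d,%d) = %.3f, p = %.4g [%s permutations]\n",
              x$r2, x$adjusted_r2, x$df_model, x$df_residual, x$f_stat, x$p_value,
              if (x$exhaustive) paste("exhaustive", x$n_permutations) else x$n_permutations))
  invisible(x)
}

build_design <- function(predictors, n) {
  if (is.matrix(predictors)) {
    df <- as.data.frame(predictors)
  } else if (is.data.frame(predictors)) {
    df <- predictors
  } else {
    df <- data.frame(x = predictors)
  }
  names(df) <- make.unique(make.names(names(df)))
  if (nrow(df) != n) stop("predictors must align with the distance matrix samples")
  X <- stats::model.matrix(~ ., data = df)
  X[, -1, drop = FALSE]  # intercept handled by centering
}

all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 1L
  for (p in sub) {
    for (pos in seq_len(n)) {
      out[[k]] <- append(p, n, after = pos - 1L)
      k <- k + 1L
    }
  }
  out
}

strata_permutation <- function(strata) {
  p <- seq_along(strata)
  for (lev in unique(strata)) {
    idx <- which(strata == lev)
    p[idx] <- idx[sample.int(length(idx))]
  }
  p
}

#' Wilcoxon rank-sum test
#'
#' Two-sided two-sample Wilcoxon (Mann-Whitney) test reporting the
#' rank-sum statistic of `x`.  The exact p-value enumerates all
#' \eqn{\binom{n_x+n_y}{n_x}} group assignments when both samples have
#' at most 10 observations and there are no ties; otherwise the normal
#' approximation with tie and continuity corrections is used.
#'
#' @param x,y Numeric vectors (each non-empty).
#' @param mode `"auto"` (default), `"exact"` or `"normal"`.
#' @return List of class `gf_test` with `statistic` (rank sum of `x`),
#'   `p_value`, and `method`.
#' @export
wilcoxon_rank_sum <- function(x, y, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  if (length(x) < 1 || length(y) < 1) stop("both groups must be non-empty")
  nx <- length(x); ny <- length(y); n <- nx + ny
  r <- rank(c(x, y))
  w <- sum(r[seq_len(nx)])
  mu <- nx * (n + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- switch(mode,
                      exact = TRUE,
                      normal = FALSE,
                      auto = !ties && nx <= 10 && ny <= 10)
  if (use_exact && ties) stop("exact mode requires tie-free data")
  if (use_exact) {
    combos <- utils::combn(n, nx)
    ranks <- seq_len(n)  # no ties: ranks are 1..n
    ws <- colSums(matrix(ranks[combos], nrow = nx))
    p <- mean(abs(ws - mu) >= abs(w - mu) - 1e-9)
    method <- "wilcoxon-exact"
  } else {
    tab <- table(r)
    sigma2 <- nx * ny / 12 * ((n + 1) - sum(tab^3 - tab) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "wilcoxon-normal"
  }
  structure(list(statistic = w, p_value = p, method = method), class = "gf_test")
}

#' Kruskal-Wallis test
#'
#' Rank-based k-sample test with tie correction; p-value from the
#' chi-squared distribution on k-1 degrees of freedom.
#'
#' @param groups List of >= 3 non-empty numeric vectors.
#' @return `gf_test` list with `statistic` (H), `p_value`, `method`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 3) stop("at least 3 groups are required")
  if (any(lengths(groups) == 0)) stop("all groups must be non-empty")
  v <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), lengths(groups))
  n <- length(v)
  r <- rank(v)
  h <- 12 / (n * (n + 1)) * sum(tapply(r, g, sum)^2 / lengths(groups)) - 3 * (n + 1)
  tab <- table(v)
  corr <- 1 - sum(tab^3 - tab) / (n^3 - n)
  if (corr > 0) h <- h / corr
  p <- stats::pchisq(h, df = length(groups) - 1, lower.tail = FALSE)
  structure(list(statistic = h, p_value = p, method = "kruskal-wallis"), class = "gf_test")
}

#' Student's t test
#'
#' Two-sided Student's t test: pooled-variance unpaired, or paired on
#' the within-pair differences.
#'
#' @param x,y Numeric vectors; equal length required when `paired`.
#' @param paired Logical.
#' @return `gf_test` list with `statistic` (t), `p_value`, `df`, `method`.
#' @export
t_test2 <- function(x, y, paired = FALSE) {
  if (paired) {
    if (length(x) != length(y)) stop("paired test requires equal lengths")
    d <- x - y
    n <- length(d)
    se <- stats::sd(d) / sqrt(n)
    t <- if (se == 0) 0 else mean(d) / se
    df <- n - 1
  } else {
    nx <- length(x); ny <- length(y)
    sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2)
    se <- sqrt(sp2 * (1 / nx + 1 / ny))
    t <- if (se == 0) 0 else (mean(x) - mean(y)) / se
    df <- nx + ny - 2
  }
  p <- 2 * stats::pt(-abs(t), df = df)
  structure(list(statistic = t, p_value = p, df = df,
                 method = if (paired) "t-paired" else "t-pooled"), class = "gf_test")
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate control: with order statistics
#' \eqn{p_{(1)} \le \dots \le p_{(m)}},
#' \eqn{q_{(i)} = \min_{j \ge i} \min(1, p_{(j)} m / j)}.
#'
#' @param p Numeric vector of p-values in \[0, 1\]; `NA`s are preserved
#'   and excluded from the adjustment.
#' @return q-values in the original order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  m <- length(ok)
  if (m == 0) return(q)
  o <- order(p[ok])
  adj <- rev(cummin(rev(pmin(1, p[ok][o] * m / seq_len(m)))))
  q[ok[o]] <- adj
  q
}

#' Spearman rank correlation
#'
#' Spearman's rho as the Pearson correlation of mid-ranks, with a
#' two-sided p-value from the t approximation on n-2 degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return `gf_test` list with `statistic` (rho), `p_value`, `method`.
#' @export
spearman_test <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("at least 3 paired observations are required")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant input: rho undefined")
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1 - 1e-12) {
    p <- 0
  } else {
    t <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(t), df = n - 2)
  }
  structure(list(statistic = rho, p_value = p, method = "spearman"), class = "gf_test")
}

#' @export
print.gf_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g\n", x$method, x$statistic, x$p_value))
  invisible(x)
}
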