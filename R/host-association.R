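#' Between-sample distance on a metabolome matrix
#'
#' Default is Bray-Curtis on total-intensity-normalized metabolite
#' profiles (symmetric with the species-level analysis); alternatives
#' are Euclidean on log1p-transformed intensities or plain Euclidean.
#'
#' @param intensities Metabolite x sample matrix of nonnegative
#'   intensities.
#' @param transform `"bray"` (default), `"log_euclidean"`, or
#'   `"euclidean"`.
#' @return Symmetric sample x sample distance matrix.
#' @export
metabolome_distance <- function(intensities, transform = c("bray", "log_euclidean", "euclidean")) {
  transform <- match.arg(transform)
  M <- as.matrix(intensities)
  if (ncol(M) < 3) stop("at least 3 samples are required")
  if (anyDuplicated(rownames(M))) stop("duplicate metabolite ids")
  if (transform == "bray") {
    tot <- colSums(M)
    if (any(tot == 0)) warning("zero-total sample(s) flagged: ",
                               paste(colnames(M)[tot == 0], collapse = ", "))
    tot[tot == 0] <- 1
    return(bray_curtis(sweep(M, 2, tot, "/")))
  }
  if (transform == "log_euclidean") M <- log1p(M)
  as.matrix(stats::dist(t(M)))
}

#' One-to-all effect size of a single species on a metabolome
#'
#' PERMANOVA of the metabolome distance matrix on one continuous
#' predictor, the species' relative abundance across samples; the R2 is
#' the fraction of metabolome distance-space variance attributable to
#' that species.
#'
#' @param species_abundance Numeric vector of the species' relative
#'   abundance per sample, aligned with `d`.
#' @param d Sample x sample metabolome distance matrix.
#' @param n_permutations,seed Passed to [permanova()].
#' @return List with `r2`, `adjusted_r2`, `p_value`, `f_stat`; all `NA`
#'   (with `flag = "constant_predictor"`) when the predictor has no
#'   variation.
#' @export
one_to_all_effect <- function(species_abundance, d, n_permutations = 999, seed = NULL) {
  if (length(species_abundance) != nrow(as.matrix(d)))
    stop("species abundance must align with the distance matrix")
  if (length(species_abundance) < 5) stop("at least 5 samples are required")
  if (stats::sd(species_abundance) == 0)
    return(list(r2 = NA_real_, adjusted_r2 = NA_real_, p_value = NA_real_,
                f_stat = NA_real_, flag = "constant_predictor"))
  fit <- permanova(d, species_abundance, n_permutations = n_permutations, seed = seed)
  list(r2 = fit$r2, adjusted_r2 = fit$adjusted_r2, p_value = fit$p_value,
       f_stat = fit$f_stat, flag = NA_character_)
}

#' One-to-all screen across a species set
#'
#' Applies [one_to_all_effect()] to every species of an abundance
#' matrix and controls the FDR across species by Benjamini-Hochberg.
#'
#' @param abundance Species x sample relative-abundance matrix, columns
#'   aligned with `d`.
#' @param d Metabolome distance matrix.
#' @param n_permutations,seed Passed to [permanova()]; species i uses
#'   `seed + i - 1` so the screen is reproducible yet streams differ.
#' @return Data frame `species_id`, `r2`, `p_value`, `q_value`, `flag`.
#' @export
one_to_all_screen <- function(abundance, d, n_permutations = 999, seed = 1) {
  abundance <- as.matrix(abundance)
  res <- vector("list", nrow(abundance))
  for (i in seq_len(nrow(abundance))) {
    r <- one_to_all_effect(abundance[i, ], d, n_permutations = n_permutations,
                           seed = seed + i - 1)
    res[[i]] <- data.frame(species_id = rownames(abundance)[i], r2 = r$r2,
                           p_value = r$p_value, flag = r$flag,
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  out$q_value <- bh_adjust(out$p_value)
  out[, c("species_id", "r2", "p_value", "q_value", "flag")]
}

#' Combined effect size of a species set on a metabolome
#'
#' Multivariate PERMANOVA with the selected species' relative
#' abundances as joint continuous predictors.  Exactly collinear
#' predictors (e.g. duplicated species) are dropped, so they do not
#' change the R2; the number of independent predictors must stay below
#' n - 2.
#'
#' @param abundance Species x sample relative-abundance matrix.
#' @param d Metabolome distance matrix.
#' @param selection Species ids (rownames of `abundance`) to include;
#'   default all.
#' @param n_permutations,seed Passed to [permanova()].
#' @return `permanova` object (includes `r2` and `adjusted_r2`).
#' @export
combined_effect <- function(abundance, d, selection = rownames(abundance),
                            n_permutations = 999, seed = 1) {
  abundance <- as.matrix(abundance)
  miss <- setdiff(selection, rownames(abundance))
  if (length(miss)) stop("unknown species in selection: ", paste(miss, collapse = ", "))
  X <- t(abundance[selection, , drop = FALSE])
  rank_x <- qr(sweep(X, 2, colMeans(X)))$rank
  n <- nrow(X)
  if (rank_x > n - 2)
    stop("too many independent predictors (", rank_x, ") for ", n,
         " samples; select a smaller species set (e.g. a univariate screen)")
  permanova(d, X, n_permutations = n_permutations, seed = seed,
            drop_collinear = TRUE)
}

#' Screen species-clinical Spearman correlations
#'
#' Computes Spearman's rho for every (species, clinical variable) pair
#' over samples where both are observed, applies Benjamini-Hochberg
#' across all computed pairs, and reports the pairs passing both the
#' effect-size and FDR thresholds (defaults |rho| > 0.35, q < 0.05).
#'
#' @param abundance Species x sample relative-abundance matrix.
#' @param clinical Clinical-variable x sample numeric matrix (may
#'   contain `NA`).
#' @param rho_threshold Minimum |rho| (strict), default 0.35.
#' @param q_threshold Maximum q (strict), default 0.05.
#' @param min_obs Minimum paired observations per pair (default 5).
#' @return List with `pairs` (passing pairs: `species_id`, `variable`,
#'   `rho`, `p_value`, `q_value`), `n_tested`, and `skipped` (pairs
#'   with a constant member or too few observations).
#' @export
correlate_clinical <- function(abundance, clinical, rho_threshold = 0.35,
                               q_threshold = 0.05, min_obs = 5) {
  abundance <- as.matrix(abundance)
  clinical <- as.matrix(clinical)
  common <- intersect(colnames(abundance), colnames(clinical))
  if (length(common) < min_obs) stop("fewer than ", min_obs, " shared samples")
  A <- abundance[, common, drop = FALSE]
  C <- clinical[, common, drop = FALSE]
  rows <- list(); skipped <- list()
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(C))) {
    ok <- !is.na(A[i, ]) & !is.na(C[j, ])
    if (sum(ok) < min_obs) {
      skipped[[length(skipped) + 1L]] <- c(rownames(A)[i], rownames(C)[j], "too_few_obs")
      next
    }
    x <- A[i, ok]; y <- C[j, ok]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      skipped[[length(skipped) + 1L]] <- c(rownames(A)[i], rownames(C)[j], "constant")
      next
    }
    tst <- spearman_test(x, y)
    rows[[length(rows) + 1L]] <- data.frame(
      species_id = rownames(A)[i], variable = rownames(C)[j],
      rho = tst$statistic, p_value = tst$p_value, stringsAsFactors = FALSE)
  }
  tested <- if (length(rows)) do.call(rbind, rows) else
    data.frame(species_id = character(0), variable = character(0),
               rho = numeric(0), p_value = numeric(0))
  tested$q_value <- bh_adjust(tested$p_value)
  pass <- abs(tested$rho) > rho_threshold & tested$q_value < q_threshold
  list(pairs = tested[which(pass), , drop = FALSE],
       n_tested = nrow(tested),
       skipped = if (length(skipped)) as.data.frame(do.call(rbind, skipped),
                                                    stringsAsFactors = FALSE)
                 else NULL)
}
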