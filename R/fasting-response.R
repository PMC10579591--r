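#' Validate a longitudinal study design
#'
#' Checks the sample/subject/timepoint table and derives the phase:
#' fasting for timepoints T1 and T2, non-fasting otherwise.
#'
#' @param design Data frame with columns `sample_id`, `subject_id`,
#'   `timepoint`.
#' @return The design with an added `phase` column.
#' @export
study_design <- function(design) {
  need <- c("sample_id", "subject_id", "timepoint")
  miss <- setdiff(need, names(design))
  if (length(miss)) stop("design lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(design$sample_id)) stop("duplicate sample_id in design")
  if (anyDuplicated(design[, c("subject_id", "timepoint")]))
    stop("a (subject, timepoint) pair appears more than once")
  design$phase <- ifelse(design$timepoint %in% c("T1", "T2"), "fasting", "non_fasting")
  design
}

#' Classify fasting-resistant and fasting-sensitive bacteria
#'
#' Per species (after a prevalence filter), compares relative
#' abundances between the fasting samples (T1 and T2 pooled) and the
#' non-fasting samples (T0, T3, T4 pooled) with a two-sided Wilcoxon
#' rank-sum test, controls the FDR across species by Benjamini-
#' Hochberg, and labels a species FRB (fasting-resistant) when
#' `q < alpha` with a higher fasting median, FSB (fasting-sensitive)
#' when `q < alpha` with a lower fasting median, and neutral otherwise.
#'
#' @param abundance Species x sample relative-abundance matrix.
#' @param design Study design (see [study_design()]); must cover the
#'   columns of `abundance`.
#' @param alpha FDR threshold (default 0.05).
#' @param min_prevalence Minimum fraction of samples in which a species
#'   must be detected (abundance > 0) to be tested (default 0.1);
#'   untested species are labelled neutral with `NA` p/q.
#' @param paired If `TRUE`, tests per-subject mean fasting vs
#'   non-fasting abundances with a paired Wilcoxon signed-rank
#'   surrogate (rank test on within-subject differences).
#' @return Data frame of class `fasting_response`: `species_id`,
#'   `prevalence`, `median_fasting`, `median_nonfasting`, `direction`
#'   (difference of medians), `log2_fold` (with 1e-6 pseudocount),
#'   `p_value`, `q_value`, `label`.
#' @export
classify_fasting_response <- function(abundance, design, alpha = 0.05,
                                      min_prevalence = 0.1, paired = FALSE) {
  abundance <- as.matrix(abundance)
  design <- study_design(design)
  design <- design[match(colnames(abundance), design$sample_id), ]
  if (anyNA(design$sample_id)) stop("design does not cover all samples")
  fasting <- design$phase == "fasting"
  if (sum(fasting) < 2 || sum(!fasting) < 2)
    stop("each phase needs at least 2 samples")
  n_sp <- nrow(abundance)
  prevalence <- rowMeans(abundance > 0)
  p <- rep(NA_real_, n_sp)
  for (i in seq_len(n_sp)) {
    if (prevalence[i] < min_prevalence) next
    a <- abundance[i, ]
    if (all(a == a[1])) { p[i] <- 1; next }  # constant (incl. all-zero): no signal
    if (paired) {
      mf <- tapply(a[fasting], design$subject_id[fasting], mean)
      mn <- tapply(a[!fasting], design$subject_id[!fasting], mean)
      subj <- intersect(names(mf), names(mn))
      p[i] <- wilcoxon_signed_rank(mf[subj] - mn[subj])
    } else {
      p[i] <- wilcoxon_rank_sum(a[fasting], a[!fasting], mode = "normal")$p_value
    }
  }
  q <- bh_adjust(p)
  med_f <- apply(abundance[, fasting, drop = FALSE], 1, stats::median)
  med_n <- apply(abundance[, !fasting, drop = FALSE], 1, stats::median)
  direction <- med_f - med_n
  label <- rep("neutral", n_sp)
  sig <- !is.na(q) & q < alpha & direction != 0
  label[sig & direction > 0] <- "FRB"
  label[sig & direction < 0] <- "FSB"
  out <- data.frame(species_id = rownames(abundance),
                    prevalence = prevalence,
                    median_fasting = med_f,
                    median_nonfasting = med_n,
                    direction = direction,
                    log2_fold = log2((med_f + 1e-6) / (med_n + 1e-6)),
                    p_value = p, q_value = q, label = label,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("fasting_response", "data.frame")
  out
}

# two-sided Wilcoxon signed-rank normal approximation on differences
wilcoxon_signed_rank <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  if (n < 2) return(1)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24)
  z <- (v - mu - sign(v - mu) * 0.5) / sigma
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' @export
print.fasting_response <- function(x, ...) {
  tab <- table(factor(x$label, levels = c("FRB", "FSB", "neutral")))
  cat(sprintf("Fasting response: %d species tested; %d FRB, %d FSB, %d neutral\n",
              sum(!is.na(x$p_value)), tab[["FRB"]], tab[["FSB"]], tab[["neutral"]]))
  invisible(x)
}

#' @export
summary.fasting_response <- function(object, ...) {
  print(object)
  sig <- as.data.frame(object)[object$label != "neutral", ]
  if (nrow(sig)) {
    cat("Strongest responders by |log2 fold|:\n")
    print(utils::head(sig[order(-abs(sig$log2_fold)),
                          c("species_id", "label", "log2_fold", "q_value")], 5),
          row.names = FALSE)
  }
  invisible(object)
}

#' Gross relative abundance of responder groups
#'
#' Per sample, sums the relative abundances of the species in each
#' label group; the three groups partition the community, so their
#' sums add to each sample's total.
#'
#' @param abundance Species x sample relative-abundance matrix.
#' @param labels Named vector (species -> FRB/FSB/neutral) or a
#'   `fasting_response` table.
#' @return Group x sample matrix with rows FRB, FSB, neutral.
#' @export
group_relative_abundance <- function(abundance, labels) {
  abundance <- as.matrix(abundance)
  if (inherits(labels, "fasting_response"))
    labels <- stats::setNames(labels$label, labels$species_id)
  lab <- labels[rownames(abundance)]
  if (anyNA(lab)) stop("labels must cover every species")
  out <- matrix(0, 3, ncol(abundance),
                dimnames = list(c("FRB", "FSB", "neutral"), colnames(abundance)))
  for (g in rownames(out))
    out[g, ] <- colSums(abundance[lab == g, , drop = FALSE])
  out
}

#' Total bacterial load from qPCR by the 2^-ddCt method
#'
#' Replicate Ct values are averaged per sample (replicates spanning
#' more than one cycle are flagged).  For each reference strain r,
#' `N_r = cells_ref_r * 2^(Ct_ref_r - Ct_test)`; per-reference
#' estimates are combined by geometric mean (Ct space is logarithmic)
#' and divided by the feces mass to give cells per gram.
#'
#' @param measurements Data frame `sample_id`, `replicate`, `ct`,
#'   `mass_g`.
#' @param references Data frame `strain`, `ct`, `cells` (one row per
#'   reference strain).
#' @param efficiency Amplification factor per cycle (default 2, the
#'   2^-ddCt assumption).
#' @return Data frame of class `load_estimate`: `sample_id`, `mean_ct`,
#'   `ct_range`, `flagged` (replicate range > 1 cycle), one
#'   `cells_<strain>` column per reference, and `cells_per_g`.
#' @export
qpcr_total_load <- function(measurements, references, efficiency = 2) {
  need <- c("sample_id", "ct", "mass_g")
  miss <- setdiff(need, names(measurements))
  if (length(miss)) stop("measurements lack column(s): ", paste(miss, collapse = ", "))
  if (nrow(references) < 1) stop("at least one reference strain is required")
  if (anyNA(references$ct) || anyNA(references$cells)) stop("missing reference Ct or cells")
  if (any(references$cells <= 0)) stop("reference cell counts must be positive")
  if (any(measurements$mass_g <= 0)) stop("feces mass must be positive")
  if (anyNA(measurements$ct)) stop("missing replicate Ct value(s)")
  ids <- unique(measurements$sample_id)
  mean_ct <- tapply(measurements$ct, measurements$sample_id, mean)[ids]
  rng <- tapply(measurements$ct, measurements$sample_id, function(x) diff(range(x)))[ids]
  mass <- tapply(measurements$mass_g, measurements$sample_id, unique)
  if (any(lengths(mass) != 1)) stop("inconsistent feces mass within a sample")
  mass <- unlist(mass)[ids]
  per_ref <- sapply(seq_len(nrow(references)), function(r)
    references$cells[r] * efficiency^(references$ct[r] - mean_ct))
  per_ref <- matrix(per_ref, ncol = nrow(references))
  combined <- exp(rowMeans(log(per_ref)))
  out <- data.frame(sample_id = ids, mean_ct = as.numeric(mean_ct),
                    ct_range = as.numeric(rng), flagged = as.numeric(rng) > 1,
                    stringsAsFactors = FALSE)
  for (r in seq_len(nrow(references)))
    out[[paste0("cells_ref", r)]] <- as.numeric(per_ref[, r] / mass)
  out$cells_per_g <- as.numeric(combined / mass)
  if (any(out$flagged))
    warning(sum(out$flagged), " sample(s) with replicate Ct range > 1 cycle")
  class(out) <- c("load_estimate", "data.frame")
  out
}

#' Absolute abundance of responder groups
#'
#' Cells per gram of feces attributed to each group:
#' `cells_{g,s} = load_s * sum of the group's relative abundances`, so
#' groups that partition the community sum to the sample's total load.
#'
#' @param group_relative Group x sample matrix (see
#'   [group_relative_abundance()]).
#' @param loads `load_estimate` table or named vector of cells per gram
#'   per sample.
#' @return Group x sample matrix of cells per gram; samples without a
#'   load estimate are dropped with a warning.
#' @export
group_absolute_abundance <- function(group_relative, loads) {
  if (inherits(loads, "data.frame"))
    loads <- stats::setNames(loads$cells_per_g, loads$sample_id)
  have <- colnames(group_relative) %in% names(loads)
  if (!all(have)) {
    warning("no load estimate for sample(s): ",
            paste(colnames(group_relative)[!have], collapse = ", "), "; skipped")
    group_relative <- group_relative[, have, drop = FALSE]
  }
  sweep(group_relative, 2, loads[colnames(group_relative)], "*")
}

#' Replication-rate dynamics of responder groups
#'
#' Pools species x sample replication rates by label group and
#' timepoint, and compares every later timepoint with the baseline
#' (T0) group-wise using two-sided Wilcoxon rank-sum tests with
#' Benjamini-Hochberg correction across all comparisons.
#'
#' @param rates Species x sample matrix of replication rates.
#' @param labels Named species -> FRB/FSB/neutral vector or
#'   `fasting_response` table.
#' @param design Study design data frame.
#' @return Data frame with one row per (group, timepoint): `group`,
#'   `timepoint`, `n`, `median_rate`, `p_value` and `q_value` (vs T0;
#'   `NA` at T0 itself).
#' @export
replication_rate_summary <- function(rates, labels, design) {
  design <- study_design(design)
  if (!"T0" %in% design$timepoint) stop("design has no T0 baseline timepoint")
  if (inherits(labels, "fasting_response"))
    labels <- stats::setNames(labels$label, labels$species_id)
  lab <- labels[rownames(rates)]
  tps <- unique(design$timepoint)
  groups <- c("FRB", "FSB", "neutral")
  rows <- expand.grid(group = groups, timepoint = tps,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pool <- function(g, tp) {
    cols <- design$sample_id[design$timepoint == tp]
    as.numeric(rates[lab == g, colnames(rates) %in% cols])
  }
  rows$n <- NA_integer_; rows$median_rate <- NA_real_; rows$p_value <- NA_real_
  for (k in seq_len(nrow(rows))) {
    v <- pool(rows$group[k], rows$timepoint[k])
    rows$n[k] <- length(v)
    rows$median_rate[k] <- stats::median(v)
    if (rows$timepoint[k] != "T0") {
      v0 <- pool(rows$group[k], "T0")
      rows$p_value[k] <- wilcoxon_rank_sum(v, v0, mode = "normal")$p_value
    }
  }
  rows$q_value <- bh_adjust(rows$p_value)
  rows
}

#' Read a study design TSV
#'
#' @param path Tab-separated file with columns `sample_id`,
#'   `subject_id`, `timepoint`.
#' @return Validated design with `phase` column.
#' @export
read_design <- function(path) {
  study_design(utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE))
}
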