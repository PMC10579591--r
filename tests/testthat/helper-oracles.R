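# Independent oracles and fixture builders shared across test files.

# ---- Boolean-module oracle -------------------------------------------------
# Random step/definition trees are built here, serialized to definition
# syntax by an independent writer, and evaluated by disjunctive-normal-form
# expansion -- a different route than the package's recursive evaluator.

# wildcards occur only as whole steps and optionals only as complex
# components, mirroring where the definition grammar admits them
rand_node <- function(pool, depth = 0) {
  kind <- if (depth >= 2) "ko" else sample(c("ko", "or", "and"), 1,
                                           prob = c(0.5, 0.25, 0.25))
  switch(kind,
    ko = list(kind = "ko", ko = sample(pool, 1)),
    or = list(kind = "or",
              children = lapply(seq_len(sample(2:3, 1)),
                                function(i) rand_node(pool, depth + 1))),
    and = {
      children <- lapply(seq_len(sample(2:3, 1)),
                         function(i) rand_node(pool, depth + 1))
      if (stats::runif(1) < 0.3)
        children <- c(children, list(list(kind = "optional",
                                          children = list(rand_node(pool, 2)))))
      list(kind = "and", children = children)
    })
}

rand_step <- function(pool) {
  if (stats::runif(1) < 0.05) list(kind = "wildcard") else rand_node(pool)
}

# serialize a test-side tree into module-definition syntax
write_node <- function(node, parent = "top") {
  switch(node$kind,
    ko = node$ko,
    wildcard = "--",
    optional = paste0("-", write_node(node$children[[1]], "plus")),
    or = {
      s <- paste(vapply(node$children, write_node, "", parent = "comma"),
                 collapse = ",")
      if (parent == "plus") paste0("(", s, ")") else s
    },
    and = {
      parts <- vapply(node$children, write_node, "", parent = "plus")
      s <- parts[1]
      for (pp in parts[-1]) s <- paste0(s, if (startsWith(pp, "-")) "" else "+", pp)
      if (parent == "comma") paste0("(", s, ")") else s
    })
}

# DNF expansion: list of KO sets; a step is satisfied iff any set is a
# subset of the present KOs.  Optionals and wildcards contribute the
# empty requirement.
dnf <- function(node) {
  switch(node$kind,
    ko = list(node$ko),
    wildcard = list(character(0)),
    optional = list(character(0)),
    or = do.call(c, lapply(node$children, dnf)),
    and = {
      terms <- list(character(0))
      for (ch in node$children) {
        chd <- dnf(ch)
        terms <- unlist(lapply(terms, function(t)
          lapply(chd, function(u) unique(c(t, u)))), recursive = FALSE)
      }
      terms
    })
}

dnf_satisfied <- function(node, present) {
  any(vapply(dnf(node), function(t) all(t %in% present), logical(1)))
}

# syntactic "counts toward MCR" check, written independently
oracle_has_required <- function(node) {
  switch(node$kind,
    ko = TRUE,
    wildcard = FALSE,
    optional = FALSE,
    any(vapply(node$children, oracle_has_required, logical(1))))
}

oracle_kos <- function(node) {
  switch(node$kind,
    ko = node$ko,
    wildcard = character(0),
    optional = unlist(lapply(node$children, oracle_kos)),
    unlist(lapply(node$children, oracle_kos)))
}

# truth-table MCR for a list of step trees over one KO subset
oracle_mcr <- function(steps, present) {
  counted <- vapply(steps, oracle_has_required, logical(1))
  if (!any(counted)) return(0)
  sat <- vapply(steps[counted], dnf_satisfied, logical(1), present = present)
  sum(sat) / sum(counted)
}

# same, with the per-step DNFs expanded once up front
oracle_mcr_precomputed <- function(dnfs, counted, present) {
  if (!any(counted)) return(0)
  sat <- vapply(dnfs[counted], function(terms)
    any(vapply(terms, function(t) all(t %in% present), logical(1))), logical(1))
  sum(sat) / sum(counted)
}

all_subsets <- function(kos) {
  n <- length(kos)
  lapply(seq_len(2^n) - 1, function(mask)
    kos[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0])
}

# ---- rank-test oracles -----------------------------------------------------

# two-sided exact Wilcoxon by direct enumeration of group assignments
enum_wilcoxon_p <- function(x, y) {
  n <- length(x) + length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_along(x)])
  mu <- length(x) * (n + 1) / 2
  combos <- utils::combn(n, length(x))
  ws <- apply(combos, 2, function(idx) sum(r[idx]))
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
}

# ---- PERMANOVA oracles -----------------------------------------------------

# R2 from within/total squared-distance sums (Anderson's partition),
# independent of the Gram-matrix trace route
oracle_permanova_r2 <- function(D, groups) {
  D <- as.matrix(D)
  n <- nrow(D)
  ss_total <- sum(D[upper.tri(D)]^2) / n
  ss_within <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    sub <- D[idx, idx, drop = FALSE]
    ss_within <- ss_within + sum(sub[upper.tri(sub)]^2) / length(idx)
  }
  1 - ss_within / ss_total
}

oracle_permanova_f <- function(D, groups) {
  r2 <- oracle_permanova_r2(D, groups)
  k <- length(unique(groups))
  n <- nrow(as.matrix(D))
  (r2 / (k - 1)) / ((1 - r2) / (n - k))
}

# exhaustive p over all distinct group assignments (two groups)
enum_permanova_p <- function(D, groups) {
  n <- nrow(as.matrix(D))
  n1 <- sum(groups == unique(groups)[1])
  f_obs <- oracle_permanova_f(D, groups)
  combos <- utils::combn(n, n1)
  fs <- apply(combos, 2, function(idx) {
    g <- rep("b", n); g[idx] <- "a"
    oracle_permanova_f(D, g)
  })
  mean(fs >= f_obs - 1e-10)
}

# ---- study fixtures --------------------------------------------------------

small_config <- function(...) {
  args <- list(n_subjects = 8, n_species = 60, n_frb = 15, n_fsb = 15,
               reads_per_sample = 2e5, n_metabolites = 40,
               n_driven_metabolites = 5, seed = 1)
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}

genome_lengths <- function(catalog) {
  stats::setNames(catalog$species$genome_length, catalog$species$species_id)
}

# sensitivity / FDR of a classification against planted labels
recovery_metrics <- function(called, truth_labels) {
  called <- stats::setNames(called$label, called$species_id)[names(truth_labels)]
  true_pos <- truth_labels != "neutral"
  called_pos <- called != "neutral"
  sens <- mean(called[true_pos] == truth_labels[true_pos])
  fdr <- if (any(called_pos)) mean(truth_labels[called_pos] != called[called_pos]) else 0
  list(sensitivity = sens, fdr = fdr,
       call_rate = mean(called_pos))
}
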