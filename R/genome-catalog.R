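#' Genome length and GC content from a FASTA file
#'
#' Length is the total number of non-gap bases over all records; GC is
#' `100 * (G + C) / (A + C + G + T)` with ambiguous bases (N, IUPAC
#' codes) excluded from the denominator.
#'
#' @param fasta Path to a (possibly multi-record, wrapped or unwrapped)
#'   DNA FASTA file.
#' @return List with `genome_length` (bp) and `gc` (percent).
#' @export
compute_genome_stats <- function(fasta) {
  seqs <- tryCatch(Biostrings::readDNAStringSet(fasta),
                   error = function(e) stop("cannot parse FASTA: ", conditionMessage(e)))
  if (length(seqs) == 0) stop("FASTA contains no sequences")
  af <- colSums(Biostrings::alphabetFrequency(seqs))
  len <- sum(af) - af[["-"]]
  acgt <- af[["A"]] + af[["C"]] + af[["G"]] + af[["T"]]
  if (acgt == 0) stop("GC content undefined: no unambiguous A/C/G/T bases")
  list(genome_length = unname(len), gc = 100 * (af[["G"]] + af[["C"]]) / acgt)
}

#' Validate a bin metadata table
#'
#' Checks the fields required by the quality gate and merge criteria:
#' positive depth and genome length, GC and completeness in \[0, 100\],
#' nonnegative contamination.
#'
#' @param bins Data frame with columns `bin_id`, `sample_id`, `depth`,
#'   `gc`, `completeness`, `contamination`, `taxonomy`, `genome_length`.
#' @return The validated data frame (invisibly unchanged).
#' @export
validate_bins <- function(bins) {
  need <- c("bin_id", "sample_id", "depth", "gc", "completeness",
            "contamination", "taxonomy", "genome_length")
  miss <- setdiff(need, names(bins))
  if (length(miss)) stop("bin table lacks column(s): ", paste(miss, collapse = ", "))
  bad <- function(cond) bins$bin_id[which(cond)]
  problems <- c(
    if (length(b <- bad(!(bins$depth > 0)))) paste("nonpositive depth:", paste(b, collapse = ",")),
    if (length(b <- bad(bins$gc < 0 | bins$gc > 100))) paste("GC out of [0,100]:", paste(b, collapse = ",")),
    if (length(b <- bad(bins$completeness < 0 | bins$completeness > 100))) paste("completeness out of [0,100]:", paste(b, collapse = ",")),
    if (length(b <- bad(bins$contamination < 0))) paste("negative contamination:", paste(b, collapse = ",")),
    if (length(b <- bad(!(bins$genome_length > 0)))) paste("nonpositive length:", paste(b, collapse = ","))
  )
  if (length(problems)) stop("invalid bin record(s): ", paste(problems, collapse = "; "))
  invisible(bins)
}

#' Quality gate for genome bins
#'
#' Retains bins with `completeness >= min_completeness` and
#' `contamination <= max_contamination` (both bounds inclusive).
#' Defaults implement the high-quality MAG gate of >= 90% completeness
#' and <= 5% contamination.
#'
#' @param bins Bin metadata data frame (see [validate_bins()]).
#' @param min_completeness,max_contamination Percent thresholds in
#'   \[0, 100\].
#' @return The retained rows, in input order.
#' @export
quality_filter <- function(bins, min_completeness = 90, max_contamination = 5) {
  if (min_completeness < 0 || min_completeness > 100 ||
      max_contamination < 0 || max_contamination > 100)
    stop("thresholds must lie in [0, 100]")
  if (nrow(bins) == 0) return(bins)
  bins[bins$completeness >= min_completeness &
         bins$contamination <= max_contamination, , drop = FALSE]
}

# species rank from a rank-prefixed lineage such as
# "d__Bacteria;p__Firmicutes;...;s__Blautia obeum"; "" when absent
species_taxon <- function(taxonomy) {
  vapply(strsplit(taxonomy, ";"), function(parts) {
    parts <- trimws(parts)
    sp <- parts[startsWith(parts, "s__")]
    if (length(sp) == 0) return("")
    trimws(gsub("\\s+", " ", sub("^s__", "", sp[1])))
  }, character(1))
}

#' Propose same-sample bin merges
#'
#' Implements the bin-merge refinement for low-quality bins: two bins
#' are compatible iff (1) they come from the same metagenomic sample,
#' (2) their sequencing depths differ by at most `depth_tol` of the pair
#' mean and their GC contents by at most `gc_tol` percentage points, and
#' (3) they carry an identical species-level taxonomic assignment
#' (whitespace-normalized exact match; bins without a species call are
#' never merged).  Merge groups are the connected components of the
#' compatibility graph within each (sample, species) block; singleton
#' components are omitted.  Because grouping is transitive, a group may
#' contain a pair that is marginally incompatible on its own; such
#' groups are flagged.
#'
#' @param bins Bin metadata data frame (see [validate_bins()]).
#' @param depth_tol Relative depth tolerance (default 0.10 = +/-10% of
#'   the pair mean).
#' @param gc_tol Absolute GC tolerance in percentage points (default 2).
#' @return Data frame with one row per merge group: `group_id`,
#'   `sample_id`, `species`, `members` (comma-separated bin ids),
#'   `n_members`, `pooled_length`, `depth` and `gc`
#'   (genome-length-weighted means), and `all_pairs_compatible`.
#' @export
propose_merges <- function(bins, depth_tol = 0.10, gc_tol = 2.0) {
  validate_bins(bins)
  bins$..species <- species_taxon(bins$taxonomy)
  eligible <- bins[nzchar(bins$..species), , drop = FALSE]
  groups <- list()
  if (nrow(eligible)) {
    key <- paste(eligible$sample_id, eligible$..species, sep = "\r")
    for (k in sort(unique(key))) {
      blk <- eligible[key == k, , drop = FALSE]
      blk <- blk[order(blk$bin_id), , drop = FALSE]
      m <- nrow(blk)
      if (m < 2) next
      compat <- matrix(FALSE, m, m)
      for (i in seq_len(m - 1)) for (j in (i + 1):m) {
        compat[i, j] <- compat[j, i] <-
          abs(blk$depth[i] - blk$depth[j]) <= depth_tol * mean(c(blk$depth[i], blk$depth[j])) &&
          abs(blk$gc[i] - blk$gc[j]) <= gc_tol
      }
      comp <- connected_components(compat)
      for (cc in comp) {
        if (length(cc) < 2) next
        sub <- blk[cc, , drop = FALSE]
        w <- sub$genome_length
        all_ok <- all(compat[cc, cc][upper.tri(matrix(0, length(cc), length(cc)))])
        groups[[length(groups) + 1L]] <- data.frame(
          sample_id = sub$sample_id[1],
          species = sub$..species[1],
          members = paste(sub$bin_id, collapse = ","),
          n_members = length(cc),
          pooled_length = sum(sub$genome_length),
          depth = sum(w * sub$depth) / sum(w),
          gc = sum(w * sub$gc) / sum(w),
          all_pairs_compatible = all_ok,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(groups) == 0) {
    return(data.frame(group_id = character(0), sample_id = character(0),
                      species = character(0), members = character(0),
                      n_members = integer(0), pooled_length = numeric(0),
                      depth = numeric(0), gc = numeric(0),
                      all_pairs_compatible = logical(0)))
  }
  out <- do.call(rbind, groups)
  out <- cbind(group_id = sprintf("merge_%03d", seq_len(nrow(out))), out)
  rownames(out) <- NULL
  out
}

# connected components of an undirected adjacency matrix (union-find)
connected_components <- function(adj) {
  n <- nrow(adj)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (adj[i, j]) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  unname(split(seq_len(n), roots))
}

#' Read a bin metadata TSV
#'
#' Tab-separated with header; columns as in [validate_bins()].
#'
#' @param path File path.
#' @return Validated bin data frame.
#' @export
read_bin_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_bins(df)
  df
}
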