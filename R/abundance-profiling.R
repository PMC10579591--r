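#' Length-normalized relative abundance
#'
#' Converts a mapped-read count matrix into relative abundances:
#' \eqn{a_{is} = (r_{is}/L_i) / \sum_j (r_{js}/L_j)}.  Samples whose
#' total mapped count is zero are kept as all-zero columns and recorded
#' in the `empty_samples` attribute rather than divided.
#'
#' @param counts Entity x sample matrix of nonnegative mapped-read
#'   counts (rownames are entity ids).
#' @param lengths Named numeric vector of entity lengths in bp (genome
#'   length for species, gene length for genes); must cover every row
#'   of `counts`.
#' @return Abundance matrix of the same shape; non-empty columns sum to
#'   1.  Attribute `empty_samples` lists flagged all-zero samples.
#' @export
relative_abundance <- function(counts, lengths) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("counts must have entity ids as rownames")
  if (anyDuplicated(rownames(counts))) stop("duplicate entity ids in counts")
  if (any(counts < 0)) stop("negative counts are invalid")
  miss <- setdiff(rownames(counts), names(lengths))
  if (length(miss)) stop("missing length for: ", paste(miss, collapse = ", "))
  L <- lengths[rownames(counts)]
  if (any(L <= 0)) stop("lengths must be positive")
  dens <- counts / L
  tot <- colSums(dens)
  empty <- colnames(counts)[tot == 0]
  tot[tot == 0] <- 1  # leave empty columns all-zero
  ab <- sweep(dens, 2, tot, "/")
  attr(ab, "empty_samples") <- empty
  ab
}

#' @rdname relative_abundance
#' @export
species_relative_abundance <- function(counts, lengths) relative_abundance(counts, lengths)

#' @rdname relative_abundance
#' @export
gene_relative_abundance <- function(counts, lengths) relative_abundance(counts, lengths)

#' Roll species abundances up to a higher taxonomic rank
#'
#' Per sample, the abundance of a taxon is the sum of the relative
#' abundances of its member species; column sums are preserved.
#' Species lacking a name at the requested rank are pooled into an
#' `unclassified_<rank>` bucket.
#'
#' @param abundance Species x sample abundance matrix.
#' @param taxonomy Data frame with a `species_id` column and one column
#'   per rank (e.g. `phylum`, ..., `genus`); empty strings or `NA` mean
#'   unclassified.
#' @param rank Rank column to roll up to.
#' @return Taxon x sample abundance matrix.
#' @export
rollup_taxa <- function(abundance, taxonomy, rank) {
  abundance <- as.matrix(abundance)
  if (!rank %in% names(taxonomy)) stop("taxonomy table has no rank column '", rank, "'")
  tax <- taxonomy[[rank]][match(rownames(abundance), taxonomy$species_id)]
  tax[is.na(tax) | !nzchar(tax)] <- paste0("unclassified_", rank)
  taxa <- sort(unique(tax))
  out <- matrix(0, length(taxa), ncol(abundance),
                dimnames = list(taxa, colnames(abundance)))
  for (t in taxa) out[t, ] <- colSums(abundance[tax == t, , drop = FALSE])
  attr(out, "empty_samples") <- attr(abundance, "empty_samples")
  out
}

#' Functional (KO / CAZy family) profile from gene abundances
#'
#' The abundance of a functional ortholog group is the summed abundance
#' of its member genes divided by the summed abundance of all genes
#' carrying an assignment of that kind, so each sample's profile sums to
#' 1 over the annotated mass.  Samples without annotated-gene signal are
#' flagged all-zero.
#'
#' @param gene_abundance Gene x sample abundance matrix.
#' @param annotation Data frame with columns `gene_id` and the feature
#'   column (`ko` or `cazy`); empty strings/`NA` mean unannotated.
#' @param feature Annotation column to profile (default `"ko"`).
#' @return Feature x sample abundance matrix with an `empty_samples`
#'   attribute.
#' @export
ko_profile <- function(gene_abundance, annotation, feature = "ko") {
  gene_abundance <- as.matrix(gene_abundance)
  if (!feature %in% names(annotation)) stop("annotation has no '", feature, "' column")
  lab <- annotation[[feature]][match(rownames(gene_abundance), annotation$gene_id)]
  lab[is.na(lab)] <- ""
  annotated <- nzchar(lab)
  feats <- sort(unique(lab[annotated]))
  out <- matrix(0, length(feats), ncol(gene_abundance),
                dimnames = list(feats, colnames(gene_abundance)))
  denom <- colSums(gene_abundance[annotated, , drop = FALSE])
  for (f in feats)
    out[f, ] <- colSums(gene_abundance[annotated & lab == f, , drop = FALSE])
  empty <- colnames(gene_abundance)[denom == 0]
  denom[denom == 0] <- 1
  out <- sweep(out, 2, denom, "/")
  attr(out, "empty_samples") <- empty
  out
}

#' Read a count matrix TSV
#'
#' First column holds entity ids, remaining columns one sample each.
#'
#' @param path File path.
#' @return Numeric matrix with entity rownames.
#' @export
read_count_matrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "numeric"
  m
}

#' Write a numeric matrix as TSV
#'
#' Ids in the first column; values at 10 significant digits.
#'
#' @param mat Matrix with rownames.
#' @param path Output path.
#' @param id_column Header of the id column (default `"id"`).
#' @export
write_tsv_matrix <- function(mat, path, id_column = "id") {
  df <- data.frame(rownames(mat), signif(as.matrix(mat), 10), check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
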