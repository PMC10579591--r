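#' Parse a KEGG-style module definition
#'
#' Module definitions are Boolean descriptions of a metabolic pathway as
#' an ordered series of reaction steps.  Top-level tokens separated by
#' spaces at parenthesis depth 0 are the steps.  Within a step, `+`
#' joins obligatory complex components (AND, binds tightest), `,` joins
#' alternatives (OR), a space inside parentheses joins sub-steps (AND,
#' loosest), `-X` marks an optional component, and `--` is a wildcard
#' for an unknown/unannotatable enzyme.  Parentheses group.
#'
#' @param text Definition string, e.g. `"(K00001,K00002) K00003+K00004"`.
#' @param module_id Optional identifier carried on the result.
#' @return Object of class `module_expression`: list with `module_id`,
#'   `steps` (list of expression trees; nodes are lists with `kind` in
#'   `"ko"`, `"and"`, `"or"`, `"optional"`, `"wildcard"`), and
#'   `definition` (the canonical re-serialized string).
#' @export
parse_module_definition <- function(text, module_id = NULL) {
  if (!is.character(text) || length(text) != 1 || !nzchar(trimws(text)))
    stop("definition must be a non-empty string")
  toks <- tokenize_definition(text)
  steps_tok <- split_steps(toks)
  steps <- lapply(steps_tok, function(st) {
    p <- parse_space_expr(st, 1L)
    if (p$pos <= length(st))
      stop("parse error at token ", p$pos, " ('", st[[p$pos]]$text, "') in: ", text)
    p$node
  })
  expr <- structure(list(module_id = module_id, steps = steps, definition = NA_character_),
                    class = "module_expression")
  expr$definition <- deparse_module_expression(expr)
  expr
}

tokenize_definition <- function(text) {
  chars <- strsplit(text, "")[[1]]
  toks <- list()
  i <- 1L; n <- length(chars)
  push <- function(type, txt, pos) toks[[length(toks) + 1L]] <<- list(type = type, text = txt, pos = pos)
  while (i <= n) {
    ch <- chars[i]
    if (ch == " ") {
      push("space", " ", i); i <- i + 1L
    } else if (ch %in% c("(", ")", ",", "+")) {
      push(ch, ch, i); i <- i + 1L
    } else if (ch == "-") {
      if (i < n && chars[i + 1] == "-") {
        push("wildcard", "--", i); i <- i + 2L
      } else {
        push("minus", "-", i); i <- i + 1L
      }
    } else if (ch == "K") {
      j <- i + 1L
      while (j <= n && grepl("[0-9]", chars[j])) j <- j + 1L
      ko <- paste(chars[i:(j - 1)], collapse = "")
      if (!grepl("^K[0-9]{5}$", ko))
        stop("malformed KO id '", ko, "' at position ", i)
      push("ko", ko, i); i <- j
    } else {
      stop("unexpected character '", ch, "' at position ", i)
    }
  }
  # collapse runs of spaces
  out <- list(); prev_space <- FALSE
  for (t in toks) {
    if (t$type == "space" && prev_space) next
    prev_space <- t$type == "space"
    out[[length(out) + 1L]] <- t
  }
  out
}

# split token stream into steps at depth-0 spaces
split_steps <- function(toks) {
  depth <- 0L; cur <- list(); steps <- list()
  for (t in toks) {
    if (t$type == "(") depth <- depth + 1L
    if (t$type == ")") {
      depth <- depth - 1L
      if (depth < 0L) stop("unbalanced parentheses at position ", t$pos)
    }
    if (t$type == "space" && depth == 0L) {
      if (length(cur)) steps[[length(steps) + 1L]] <- cur
      cur <- list()
    } else if (t$type != "space" || depth > 0L) {
      cur[[length(cur) + 1L]] <- t
    }
  }
  if (depth != 0L) stop("unbalanced parentheses in definition")
  if (length(cur)) steps[[length(steps) + 1L]] <- cur
  steps
}

node_ko <- function(ko) list(kind = "ko", ko = ko)
node_op <- function(kind, children) {
  if (length(children) == 1) return(children[[1]])
  list(kind = kind, children = children)
}

# grammar (tightest to loosest): primary, '-' optional prefix, '+'/'-' complex
# chain (AND), ',' alternatives (OR), space inside parentheses (AND)
parse_space_expr <- function(toks, pos) {
  children <- list()
  repeat {
    p <- parse_comma_expr(toks, pos)
    children[[length(children) + 1L]] <- p$node
    pos <- p$pos
    if (pos > length(toks) || toks[[pos]]$type != "space") break
    pos <- pos + 1L
  }
  list(node = node_op("and", children), pos = pos)
}

parse_comma_expr <- function(toks, pos) {
  children <- list()
  repeat {
    p <- parse_plus_chain(toks, pos)
    children[[length(children) + 1L]] <- p$node
    pos <- p$pos
    if (pos > length(toks) || toks[[pos]]$type != ",") break
    pos <- pos + 1L
  }
  list(node = node_op("or", children), pos = pos)
}

parse_plus_chain <- function(toks, pos) {
  p <- parse_unary(toks, pos)
  children <- list(p$node)
  pos <- p$pos
  while (pos <= length(toks) && toks[[pos]]$type %in% c("+", "minus")) {
    optional <- toks[[pos]]$type == "minus"
    pos <- pos + 1L
    p <- parse_primary(toks, pos)
    node <- p$node
    if (optional) node <- list(kind = "optional", children = list(node))
    children[[length(children) + 1L]] <- node
    pos <- p$pos
  }
  list(node = node_op("and", children), pos = pos)
}

parse_unary <- function(toks, pos) {
  if (pos <= length(toks) && toks[[pos]]$type == "minus") {
    p <- parse_primary(toks, pos + 1L)
    return(list(node = list(kind = "optional", children = list(p$node)), pos = p$pos))
  }
  parse_primary(toks, pos)
}

parse_primary <- function(toks, pos) {
  if (pos > length(toks)) stop("dangling operator at end of definition")
  t <- toks[[pos]]
  if (t$type == "ko") return(list(node = node_ko(t$text), pos = pos + 1L))
  if (t$type == "wildcard") return(list(node = list(kind = "wildcard"), pos = pos + 1L))
  if (t$type == "(") {
    p <- parse_space_expr(toks, pos + 1L)
    if (p$pos > length(toks) || toks[[p$pos]]$type != ")")
      stop("unbalanced parentheses at position ", t$pos)
    return(list(node = p$node, pos = p$pos + 1L))
  }
  stop("unexpected token '", t$text, "' at position ", t$pos)
}

#' Canonical serialization of a parsed module definition
#'
#' Inverse of [parse_module_definition()]: re-parsing the canonical
#' string yields an identical expression tree.
#'
#' @param expr `module_expression`.
#' @return Single definition string.
#' @export
deparse_module_expression <- function(expr) {
  paste(vapply(expr$steps, deparse_node, character(1), ctx = "top"), collapse = " ")
}

deparse_node <- function(node, ctx) {
  wrap <- function(s, need) if (need) paste0("(", s, ")") else s
  switch(node$kind,
    ko = node$ko,
    wildcard = "--",
    optional = paste0("-", deparse_node(node$children[[1]], "plus")),
    or = {
      s <- paste(vapply(node$children, deparse_node, character(1), ctx = "comma"),
                 collapse = ",")
      wrap(s, ctx %in% c("plus"))
    },
    and = {
      # serialized as a '+' chain; optional children keep their '-' prefix
      parts <- vapply(node$children, function(ch) {
        if (ch$kind == "optional")
          paste0("-", deparse_node(ch$children[[1]], "plus"))
        else deparse_node(ch, "plus")
      }, character(1))
      s <- parts[1]
      for (pp in parts[-1]) s <- paste0(s, if (startsWith(pp, "-")) "" else "+", pp)
      wrap(s, ctx %in% c("comma"))
    })
}

#' @export
print.module_expression <- function(x, ...) {
  cat("Module", if (!is.null(x$module_id)) x$module_id else "<unnamed>",
      "-", length(x$steps), "steps:", x$definition, "\n")
  invisible(x)
}

eval_node <- function(node, present) {
  switch(node$kind,
    ko = node$ko %in% present,
    wildcard = TRUE,
    optional = TRUE,
    or = any(vapply(node$children, eval_node, logical(1), present = present)),
    and = all(vapply(node$children, eval_node, logical(1), present = present)))
}

# does the subtree contain at least one non-optional KO leaf?
has_required_ko <- function(node) {
  switch(node$kind,
    ko = TRUE,
    wildcard = FALSE,
    optional = FALSE,
    any(vapply(node$children, has_required_ko, logical(1))))
}

collect_kos <- function(node, include_optional = FALSE) {
  switch(node$kind,
    ko = node$ko,
    wildcard = character(0),
    optional = if (include_optional)
      unlist(lapply(node$children, collect_kos, include_optional = include_optional))
      else character(0),
    unlist(lapply(node$children, collect_kos, include_optional = include_optional)))
}

#' KO identifiers of a module
#'
#' @param expr `module_expression`.
#' @param include_optional Include KOs appearing only as optional
#'   components (default `FALSE`).
#' @return Character vector of distinct KO ids.
#' @export
module_kos <- function(expr, include_optional = FALSE) {
  unique(unlist(lapply(expr$steps, collect_kos, include_optional = include_optional)))
}

#' Module completion ratio (MCR)
#'
#' Fraction of a module's counted reaction steps whose Boolean KO
#' requirement is satisfied by a genome's KO repertoire.  Optional
#' components evaluate as neutrally true; steps consisting only of
#' wildcards/optionals are excluded from both numerator and denominator.
#' A module with no counted steps has MCR 0.
#'
#' @param expr `module_expression` (or definition string, parsed on the
#'   fly).
#' @param present_kos Character vector of KO ids present in the genome.
#' @return MCR in \[0, 1\].
#' @export
module_completion_ratio <- function(expr, present_kos) {
  if (is.character(expr)) expr <- parse_module_definition(expr)
  counted <- vapply(expr$steps, has_required_ko, logical(1))
  if (!any(counted)) return(0)
  sat <- vapply(expr$steps[counted], eval_node, logical(1), present = present_kos)
  sum(sat) / sum(counted)
}

#' Per-genome module abundance
#'
#' Number of KEGG-ortholog gene copies times the module completion
#' ratio: the gene-copy count is summed over the module's distinct
#' required (non-optional) KOs present in the genome's annotation.
#'
#' @param expr `module_expression` or definition string.
#' @param ko_counts Named integer vector: gene copies per KO for one
#'   genome.
#' @param distinct If `TRUE`, count distinct KOs present instead of gene
#'   copies.
#' @return Nonnegative module abundance value.
#' @export
module_abundance <- function(expr, ko_counts, distinct = FALSE) {
  if (is.character(expr)) expr <- parse_module_definition(expr)
  if (length(ko_counts) && (is.null(names(ko_counts)) || any(ko_counts < 0)))
    stop("ko_counts must be a named vector of nonnegative gene counts")
  kos <- module_kos(expr, include_optional = FALSE)
  present <- intersect(kos, names(ko_counts)[ko_counts > 0])
  n_genes <- if (distinct) length(present) else sum(ko_counts[present])
  mcr <- module_completion_ratio(expr, names(ko_counts)[ko_counts > 0])
  n_genes * mcr
}

#' Read a module-definition flat file
#'
#' Format: one `module_id<TAB>definition` per line; `#` starts a
#' comment line.
#'
#' @param path File path.
#' @return Named list of `module_expression` objects keyed by module id.
#' @export
read_module_definitions <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t")[[1]]
    if (length(parts) < 2) stop("malformed module line: ", ln)
    out[[parts[1]]] <- parse_module_definition(parts[2], module_id = parts[1])
  }
  out
}

#' Read a GMM flat file
#'
#' Gut metabolic modules as flat KO sets:
#' `module_id<TAB>name<TAB>category<TAB>K00001,K00002,...` per line,
#' `#` comments allowed.
#'
#' @param path File path.
#' @return Data frame with columns `module_id`, `name`, `category`, and
#'   list-column `kos`.
#' @export
read_gmm_definitions <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t")
  if (any(lengths(parts) < 4)) stop("malformed GMM line(s)")
  df <- data.frame(module_id = vapply(parts, `[`, "", 1),
                   name = vapply(parts, `[`, "", 2),
                   category = vapply(parts, `[`, "", 3),
                   stringsAsFactors = FALSE)
  df$kos <- lapply(parts, function(p) unique(strsplit(p[4], ",")[[1]]))
  if (any(lengths(df$kos) == 0)) stop("GMM with empty KO set")
  df
}

#' Per-sample GMM profile
#'
#' For each sample and gut metabolic module, the abundance is the
#' median abundance of the module's KOs detected (abundance > 0) in the
#' sample, set to 0 when fewer than half of the module's KOs are
#' detected.  Coverage (detected fraction) is returned alongside.
#'
#' @param ko_abundance KO x sample abundance matrix (rownames are KO
#'   ids).
#' @param gmms GMM table from [read_gmm_definitions()].
#' @param median_over_all If `TRUE`, take the median over all of the
#'   module's KOs (zeros included) instead of over detected KOs only.
#' @return List with `abundance` and `coverage` (GMM x sample matrices).
#' @export
gmm_sample_profile <- function(ko_abundance, gmms, median_over_all = FALSE) {
  ko_abundance <- as.matrix(ko_abundance)
  n_gmm <- nrow(gmms)
  ab <- matrix(0, n_gmm, ncol(ko_abundance),
               dimnames = list(gmms$module_id, colnames(ko_abundance)))
  cov <- ab
  missing_all <- character(0)
  for (i in seq_len(n_gmm)) {
    kos <- gmms$kos[[i]]
    hit <- intersect(kos, rownames(ko_abundance))
    if (length(hit) == 0) { missing_all <- c(missing_all, gmms$module_id[i]); next }
    sub <- ko_abundance[hit, , drop = FALSE]
    # KOs of the module absent from the matrix are undetected (abundance 0)
    for (s in seq_len(ncol(sub))) {
      det <- sub[, s] > 0
      cov[i, s] <- sum(det) / length(kos)
      if (cov[i, s] >= 0.5) {
        vals <- if (median_over_all) c(sub[, s], rep(0, length(kos) - length(hit)))
                else sub[det, s]
        ab[i, s] <- stats::median(vals)
      }
    }
  }
  if (length(missing_all))
    warning("GMM(s) with no KOs in the matrix: ", paste(missing_all, collapse = ", "))
  list(abundance = ab, coverage = cov)
}

#' GMM category summary
#'
#' Arithmetic mean of member-GMM abundances per category and sample.
#'
#' @param gmm_abundance GMM x sample matrix (e.g.
#'   `gmm_sample_profile()$abundance`).
#' @param categories Named character vector mapping GMM id to category.
#' @return Category x sample matrix of means.
#' @export
gmm_category_summary <- function(gmm_abundance, categories) {
  gmm_abundance <- as.matrix(gmm_abundance)
  if (!all(rownames(gmm_abundance) %in% names(categories)))
    stop("every GMM must have a category")
  cat_of <- categories[rownames(gmm_abundance)]
  cats <- sort(unique(cat_of))
  out <- matrix(0, length(cats), ncol(gmm_abundance),
                dimnames = list(cats, colnames(gmm_abundance)))
  for (cc in cats) out[cc, ] <- colMeans(gmm_abundance[cat_of == cc, , drop = FALSE])
  out
}

#' Module profile of a set of genomes
#'
#' Convenience wrapper computing MCR, KO gene count and module
#' abundance for every (genome, module) pair.
#'
#' @param ko_counts Named list: per genome, a named vector of gene
#'   copies per KO.
#' @param modules Named list of `module_expression` objects.
#' @return Data frame with `genome`, `module_id`, `mcr`,
#'   `ko_gene_count`, `module_abundance`.
#' @export
genome_module_profile <- function(ko_counts, modules) {
  rows <- expand.grid(genome = names(ko_counts), module_id = names(modules),
                      stringsAsFactors = FALSE)
  res <- mapply(function(g, m) {
    expr <- modules[[m]]
    cnt <- ko_counts[[g]]
    present <- names(cnt)[cnt > 0]
    mcr <- module_completion_ratio(expr, present)
    kos <- module_kos(expr)
    ngene <- sum(cnt[intersect(kos, present)])
    c(mcr = mcr, ko_gene_count = ngene, module_abundance = ngene * mcr)
  }, rows$genome, rows$module_id)
  cbind(rows, as.data.frame(t(res)))
}
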