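#' @keywords internal
RELATIONS <- c("pp", "mm", "pm")

INTERACTION_TYPES <- c("ac", "re", "du")

#' Construct a pair-list of co-expression edges
#'
#' A pair-list is the tabular edge representation used throughout the
#' package: one row per gene pair with a relation class and the number of
#' supporting samples. `pp` (up-together) and `mm` (down-together) edges are
#' unordered and stored with `gene1 < gene2`; `pm` (up-down) edges are
#' directed, `gene1` being the up-regulated gene.
#'
#' @param gene1,gene2 Character vectors of gene identifiers.
#' @param relation Character vector with entries in `"pp"`, `"mm"`, `"pm"`.
#' @param support Non-negative integer count of supporting samples per edge.
#' @param dedup Collapse duplicate records (same canonical pair and
#'   relation), keeping the maximum support.
#' @return A `data.frame` of class `pair_list` with columns `gene1`,
#'   `gene2`, `relation`, `support`.
#' @examples
#' pair_list(c("b", "a"), c("a", "c"), c("pp", "pm"), c(3L, 2L))
#' @export
pair_list <- function(gene1 = character(), gene2 = character(),
                      relation = character(), support = integer(),
                      dedup = TRUE) {
  gene1 <- as.character(gene1)
  gene2 <- as.character(gene2)
  relation <- as.character(relation)
  support <- as.integer(support)
  n <- length(gene1)
  if (length(gene2) != n || length(relation) != n || length(support) != n)
    stop("gene1, gene2, relation and support must have equal length")
  bad <- setdiff(unique(relation), RELATIONS)
  if (length(bad))
    stop("unknown relation token(s): ", paste(bad, collapse = ", "))
  if (any(gene1 == gene2))
    stop("self-pairs are not allowed in a pair_list")
  if (any(support < 0, na.rm = TRUE) || anyNA(support))
    stop("support must be a non-negative integer")
  # canonical order for the undirected relations
  swap <- relation %in% c("pp", "mm") & gene1 > gene2
  tmp <- gene1[swap]; gene1[swap] <- gene2[swap]; gene2[swap] <- tmp
  df <- data.frame(gene1 = gene1, gene2 = gene2, relation = relation,
                   support = support, stringsAsFactors = FALSE)
  if (dedup && n > 0) {
    key <- paste(df$gene1, df$gene2, df$relation, sep = "\r")
    if (anyDuplicated(key)) {
      sup <- tapply(df$support, key, max)
      df <- df[!duplicated(key), , drop = FALSE]
      df$support <- as.integer(sup[paste(df$gene1, df$gene2, df$relation,
                                         sep = "\r")])
    }
  }
  df <- df[order(df$relation, df$gene1, df$gene2), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("pair_list", "data.frame")
  df
}

#' @export
print.pair_list <- function(x, ...) {
  cat("pair_list with", nrow(x), "edge(s)\n")
  tab <- table(factor(x$relation, levels = RELATIONS))
  cat(" ", paste(names(tab), tab, sep = ": ", collapse = "  "), "\n")
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("  ...", nrow(x) - 10, "more rows\n")
  invisible(x)
}

as_pair_list <- function(df, dedup = TRUE) {
  pair_list(df$gene1, df$gene2, df$relation, df$support, dedup = dedup)
}

# relation-aware matching keys; unordered for pp/mm (and for pm on request)
pair_keys <- function(pl, ignore_pm_direction = FALSE) {
  ordered <- pl$relation == "pm" & !ignore_pm_direction
  lo <- ifelse(ordered, pl$gene1, pmin(pl$gene1, pl$gene2))
  hi <- ifelse(ordered, pl$gene2, pmax(pl$gene1, pl$gene2))
  paste(lo, hi, sep = "\r")
}

#' Construct a named gene set
#'
#' @param name Set label (e.g. `"Eu"` for European-up genes).
#' @param genes Character vector of gene identifiers; duplicates are removed.
#' @return A list of class `gene_set` with elements `name` and `genes`.
#' @export
gene_set <- function(name, genes) {
  genes <- unique(as.character(genes))
  if (!length(genes)) stop("gene set '", name, "' is empty")
  structure(list(name = as.character(name)[1], genes = genes),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat("gene_set '", x$name, "': ", length(x$genes), " gene(s)\n", sep = "")
  invisible(x)
}

as_gene_vector <- function(x) {
  if (inherits(x, "gene_set")) x$genes else unique(as.character(x))
}

#' Construct a signed regulatory network
#'
#' Directed regulator-to-target interactions with a type label:
#' `ac` (activation), `re` (repression) or `du` (dual action). The gene
#' universe may be larger than the set of interacting genes, e.g. to carry
#' background (`bgr_`) genes that have no regulatory definitions.
#'
#' @param interactions `data.frame` with columns `regulator`, `target`,
#'   `type`.
#' @param gene_universe Character vector of all genes; defaults to the genes
#'   appearing in `interactions`.
#' @return A list of class `signed_regnet`.
#' @export
signed_regnet <- function(interactions, gene_universe = NULL) {
  stopifnot(is.data.frame(interactions))
  need <- c("regulator", "target", "type")
  if (!all(need %in% names(interactions)))
    stop("interactions must have columns regulator, target, type")
  interactions <- data.frame(
    regulator = as.character(interactions$regulator),
    target = as.character(interactions$target),
    type = as.character(interactions$type),
    stringsAsFactors = FALSE)
  bad <- setdiff(unique(interactions$type), INTERACTION_TYPES)
  if (length(bad))
    stop("unknown interaction type(s): ", paste(bad, collapse = ", "))
  key <- paste(interactions$regulator, interactions$target, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (regulator, target) records in interaction table")
  inv <- unique(c(interactions$regulator, interactions$target))
  if (is.null(gene_universe)) {
    gene_universe <- inv
  } else {
    gene_universe <- unique(as.character(gene_universe))
    missing <- setdiff(inv, gene_universe)
    if (length(missing))
      stop("interacting gene(s) absent from gene_universe: ",
           paste(utils::head(missing, 5), collapse = ", "))
  }
  structure(list(interactions = interactions, gene_universe = gene_universe),
            class = "signed_regnet")
}

#' @export
print.signed_regnet <- function(x, ...) {
  tab <- table(factor(x$interactions$type, levels = INTERACTION_TYPES))
  cat("signed_regnet:", nrow(x$interactions), "interaction(s) over",
      length(x$gene_universe), "gene(s)\n")
  cat(" ", paste(names(tab), tab, sep = ": ", collapse = "  "), "\n")
  invisible(x)
}

validate_expression_matrix <- function(m, min_genes = 2L, min_samples = 2L) {
  if (!is.matrix(m) || !is.numeric(m))
    stop("expression matrix must be a numeric matrix")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("expression matrix needs gene row names and sample column names")
  if (nrow(m) < min_genes)
    stop("expression matrix needs at least ", min_genes, " genes")
  if (ncol(m) < min_samples)
    stop("expression matrix needs at least ", min_samples, " samples")
  if (anyDuplicated(colnames(m)))
    stop("duplicate sample identifiers")
  if (any(!is.finite(m)))
    stop("expression values must be finite")
  invisible(m)
}
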