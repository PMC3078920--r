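# Network comparison, randomization significance and spectral reordering.

#' Intersect two pair-lists
#'
#' Matching is on gene pairs: unordered for pp/mm edges and for any
#' comparison involving them, ordered for pm-vs-pm unless
#' `ignore_pm_direction` is set. The returned edges come from `a` (its
#' relations and supports).
#'
#' @param a,b [pair_list()]s.
#' @param ignore_pm_direction Treat pm edges as undirected when matching.
#' @return List: `intersection` ([pair_list()]) and `report` (class
#'   `comparison_report`: sizes, shared count, Jaccard; for pm-pm
#'   comparisons both the direction-sensitive and direction-ignored counts).
#' @export
intersect_pairlists <- function(a, b, ignore_pm_direction = FALSE) {
  stopifnot(inherits(a, "pair_list"), inherits(b, "pair_list"))
  both_pm <- all(a$relation == "pm") && all(b$relation == "pm") &&
    nrow(a) > 0 && nrow(b) > 0
  # a pm edge can only match unordered against a pp/mm edge
  ignore <- ignore_pm_direction || !both_pm
  ka <- pair_keys(a, ignore_pm_direction = ignore)
  kb <- pair_keys(b, ignore_pm_direction = ignore)
  keep <- ka %in% kb
  shared <- length(unique(ka[keep]))
  report <- structure(list(size_a = nrow(a), size_b = nrow(b),
                           shared = shared,
                           jaccard = if (nrow(a) + nrow(b) - shared > 0)
                             shared / (length(unique(ka)) +
                                       length(unique(kb)) - shared)
                           else NA_real_),
                      class = "comparison_report")
  if (both_pm) {
    kda <- pair_keys(a, ignore_pm_direction = FALSE)
    kdb <- pair_keys(b, ignore_pm_direction = FALSE)
    kua <- pair_keys(a, ignore_pm_direction = TRUE)
    kub <- pair_keys(b, ignore_pm_direction = TRUE)
    report$pm_direction_sensitive <- length(unique(kda[kda %in% kdb]))
    report$pm_direction_ignored <- length(unique(kua[kua %in% kub]))
  }
  list(intersection = as_pair_list(a[keep, , drop = FALSE]),
       report = report)
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("comparison: |a| =", x$size_a, " |b| =", x$size_b,
      " shared =", x$shared, " Jaccard =", signif(x$jaccard, 3), "\n")
  if (!is.null(x$pm_direction_sensitive))
    cat("  pm directed:", x$pm_direction_sensitive,
        " direction-ignored:", x$pm_direction_ignored, "\n")
  invisible(x)
}

#' Reciprocal pairs between or within networks
#'
#' Two supported senses of reciprocity:
#' \describe{
#'   \item{mm:pp}{`x` an mm and `y` a pp pair-list (either order): the
#'     unordered pairs present in both, i.e. genes that are both
#'     down-together and up-together.}
#'   \item{pm:mp}{`x` a pm pair-list (`y` omitted): pairs (A, B) for which
#'     both directions A->B and B->A are present.}
#' }
#'
#' @param x A [pair_list()].
#' @param y Optional second [pair_list()] for the mm:pp sense.
#' @return A [pair_list()] of the reciprocal pairs, stored with
#'   `gene1 < gene2` and the minimum support of the two senses.
#' @export
reciprocal_pairs <- function(x, y = NULL) {
  stopifnot(inherits(x, "pair_list"))
  if (is.null(y)) {
    if (nrow(x) && !all(x$relation == "pm"))
      stop("single-list reciprocity is defined for pm pair-lists only")
    fwd <- paste(x$gene1, x$gene2, sep = "\r")
    rev <- paste(x$gene2, x$gene1, sep = "\r")
    keep <- fwd %in% rev & x$gene1 < x$gene2  # one record per unordered pair
    sup_rev <- x$support[match(rev[keep], fwd)]
    return(pair_list(x$gene1[keep], x$gene2[keep],
                     rep("pm", sum(keep)),
                     pmin(x$support[keep], sup_rev)))
  }
  stopifnot(inherits(y, "pair_list"))
  rels <- sort(c(unique(x$relation), unique(y$relation)))
  if (nrow(x) && nrow(y) && !identical(rels, c("mm", "pp")))
    stop("two-list reciprocity is defined for an mm and a pp pair-list")
  kx <- pair_keys(x); ky <- pair_keys(y)
  keep <- kx %in% ky
  sup_y <- y$support[match(kx[keep], ky)]
  pair_list(x$gene1[keep], x$gene2[keep], x$relation[keep],
            pmin(x$support[keep], sup_y))
}

#' Significance of the observed network size against shuffled nulls
#'
#' Builds the networks once from the given discretized matrix and `n_rand`
#' times from row-shuffled copies ([shuffle_rows()]), which preserve every
#' gene's code histogram while destroying co-occurrence structure. A
#' one-sample t-statistic of the null sizes against the observed size is
#' reported (null minus observed, so strong structure gives large-magnitude
#' negative t) with a one-sided p from Student's t on `n_rand - 1` degrees
#' of freedom.
#'
#' @param d A `discretized_matrix`.
#' @param n_rand Number of randomizations (>= 2; 100 is typical).
#' @param seed Optional integer seed.
#' @param quantile,mode,reps Null-table parameters (see
#'   [null_threshold_table()]); the table is shared between observed and
#'   shuffled runs since shuffling preserves densities.
#' @param relations Which relations contribute to "size" (default all
#'   three).
#' @return List of class `size_significance`: `observed_size`,
#'   `null_sizes`, `t_statistic`, `p_value`, `n_randomizations`, `flag`
#'   (`"ok"`, `"zero_variance_null"` with an exact count comparison, or
#'   `"empty"`).
#' @export
network_size_significance <- function(d, n_rand = 100L, seed = NULL,
                                      quantile = 0.995,
                                      mode = c("exact", "monte_carlo"),
                                      reps = 1000L,
                                      relations = c("pp", "mm", "pm")) {
  mode <- match.arg(mode)
  validate_discretized(d)
  if (n_rand < 2) stop("n_rand must be at least 2")
  if (!is.null(seed)) set.seed(seed)
  n <- ncol(d)
  tbl <- null_threshold_table(n, quantile, mode, reps,
                              seed = if (mode == "monte_carlo") seed)
  size_of <- function(dd) {
    nets <- extract_networks(count_cooccurrence(dd), dd, tbl)
    network_total_size(nets, relations)
  }
  observed <- size_of(d)
  null_sizes <- vapply(seq_len(n_rand),
                       function(i) size_of(shuffle_rows(d)), 0L)
  if (observed == 0 && all(null_sizes == 0)) {
    t_stat <- NA_real_; p <- 1; flag <- "empty"
  } else if (stats::sd(null_sizes) == 0) {
    t_stat <- NA_real_
    p <- mean(null_sizes >= observed)
    flag <- "zero_variance_null"
  } else {
    t_stat <- (mean(null_sizes) - observed) /
      (stats::sd(null_sizes) / sqrt(n_rand))
    p <- stats::pt(t_stat, df = n_rand - 1)
    flag <- "ok"
  }
  structure(list(observed_size = observed, null_sizes = null_sizes,
                 t_statistic = t_stat, p_value = p,
                 n_randomizations = n_rand, flag = flag),
            class = "size_significance")
}

#' @export
print.size_significance <- function(x, ...) {
  cat("network size significance:", x$observed_size, "edges observed;",
      "null mean", signif(mean(x$null_sizes), 4), "over",
      x$n_randomizations, "shuffles\n")
  cat("  t =", format(x$t_statistic), " p =", format(x$p_value),
      " [", x$flag, "]\n")
  invisible(x)
}

#' Reorder network nodes by the leading eigenvector of the adjacency
#'
#' Builds the symmetric adjacency of the pair-list restricted to the given
#' genes (0/1 by default, support-weighted on request; pm edges are
#' symmetrized with a warning), takes the eigenvector of the largest
#' eigenvalue, fixes its sign so the largest-magnitude component is
#' positive, and sorts nodes by decreasing component (ties broken by gene
#' name). Densely interconnected cliques end up contiguous, and the
#' per-gene ranks can be compared across runs (e.g. male vs female
#' networks).
#'
#' @param pl A [pair_list()].
#' @param genes Optional [gene_set()] or character vector restricting the
#'   sub-network; defaults to all genes in `pl`.
#' @param weighted Use supports as edge weights instead of 0/1.
#' @return List of class `spectral_order`: `ordering` (gene names, first =
#'   largest component), `values` (named eigenvector components), `ranks`
#'   (named position of each gene in the ordering), `eigenvalue`.
#' @export
spectral_reorder <- function(pl, genes = NULL, weighted = FALSE) {
  stopifnot(inherits(pl, "pair_list"))
  if (is.null(genes)) genes <- sort(unique(c(pl$gene1, pl$gene2)))
  else genes <- sort(as_gene_vector(genes))
  keep <- pl$gene1 %in% genes & pl$gene2 %in% genes
  pl <- pl[keep, , drop = FALSE]
  if (!nrow(pl) || length(genes) < 2)
    stop("empty sub-network: no edges among the requested genes")
  if (any(pl$relation == "pm"))
    warning("pm edges symmetrized for spectral reordering")
  A <- matrix(0, length(genes), length(genes),
              dimnames = list(genes, genes))
  w <- if (weighted) pl$support else rep(1, nrow(pl))
  i <- match(pl$gene1, genes); j <- match(pl$gene2, genes)
  A[cbind(i, j)] <- pmax(A[cbind(i, j)], w)
  A[cbind(j, i)] <- pmax(A[cbind(j, i)], w)
  e <- eigen(A, symmetric = TRUE)
  v <- e$vectors[, 1]
  if (v[which.max(abs(v))] < 0) v <- -v
  names(v) <- genes
  ord <- order(-v, genes)
  ordering <- genes[ord]
  structure(list(ordering = ordering,
                 values = v,
                 ranks = stats::setNames(match(genes, ordering), genes),
                 eigenvalue = e$values[1]),
            class = "spectral_order")
}

#' @export
print.spectral_order <- function(x, ...) {
  cat("spectral_order over", length(x$ordering), "gene(s); leading",
      "eigenvalue", signif(x$eigenvalue, 4), "\n")
  cat("  head:", paste(utils::head(x$ordering, 8), collapse = " "), "\n")
  invisible(x)
}
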