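# Co-occurrence counting and the density-conditional null.
#
# For two genes with d1 and d2 marked samples out of n, the number of
# samples marked in both after independently permuting each vector is
# hypergeometric (population n, successes d1, draws d2). The Monte Carlo
# permutation null therefore depends only on (d1, d2, n), so thresholds are
# cached per density pair; the exact hypergeometric mode is the reference.

#' Count per-pair co-occurrences via indicator inner products
#'
#' Computes `P P'` (pp: up-together), `M M'` (mm: down-together) and `P M'`
#' (pm: gene1 up while gene2 down). The pp/mm matrices are symmetric and
#' stored upper-triangular with a zero diagonal; pm is square and asymmetric
#' with a structurally zero diagonal (a gene cannot be up and down in the
#' same sample).
#'
#' @param ind An indicator pair from [split_indicators()], or a
#'   `discretized_matrix` (split internally).
#' @return List of class `cooccurrence_counts` with elements `pp`, `mm`,
#'   `pm`, `n_samples`, `gene_ids`.
#' @export
count_cooccurrence <- function(ind) {
  if (inherits(ind, "discretized_matrix")) ind <- split_indicators(ind)
  stopifnot(is.list(ind), is.matrix(ind$P), is.matrix(ind$M))
  P <- ind$P; M <- ind$M
  if (!identical(dim(P), dim(M)))
    stop("P and M must have identical dimensions")
  pp <- P %*% t(P)
  mm <- M %*% t(M)
  pm <- P %*% t(M)
  pp[lower.tri(pp, diag = TRUE)] <- 0
  mm[lower.tri(mm, diag = TRUE)] <- 0
  diag(pm) <- 0
  structure(list(pp = pp, mm = mm, pm = pm, n_samples = ncol(P),
                 gene_ids = rownames(P)),
            class = "cooccurrence_counts")
}

#' Acceptance thresholds for co-occurrence counts under the permutation null
#'
#' For each density pair `(d1, d2)` the threshold is the stated quantile of
#' the overlap of two random binary vectors with those densities in
#' `n_samples` positions. In `"exact"` mode the overlap distribution is
#' hypergeometric and the threshold is the smallest `k` with
#' `CDF(k) >= quantile`; in `"monte_carlo"` mode both vectors are permuted
#' `reps` times, the linear-interpolation quantile (`type = 7`) of the
#' simulated overlaps is taken and rounded up to an integer. An observed
#' count forms an edge only if it *strictly exceeds* the threshold.
#'
#' @param n_samples Number of samples.
#' @param quantile Acceptance quantile in (0,1); default 0.995 (P = 0.005).
#' @param mode `"exact"` (default) or `"monte_carlo"`.
#' @param reps Permutations per density pair in Monte Carlo mode.
#' @param seed Integer seed for Monte Carlo mode (a per-cell stream is
#'   derived from it so lookup order does not matter).
#' @param densities Optional two-column matrix/data.frame of `(d1, d2)`
#'   pairs to precompute; in exact mode the full grid is computed.
#' @return List of class `null_threshold_table`; thresholds are stored in a
#'   `(n+1) x (n+1)` matrix indexed by `d + 1`, `NA` meaning not yet
#'   computed (filled on demand by [threshold_for()] and
#'   [extract_networks()]).
#' @export
null_threshold_table <- function(n_samples, quantile = 0.995,
                                 mode = c("exact", "monte_carlo"),
                                 reps = 1000L, seed = NULL,
                                 densities = NULL) {
  mode <- match.arg(mode)
  stopifnot(n_samples >= 1, quantile > 0, quantile < 1, reps >= 1)
  if (mode == "monte_carlo" && is.null(seed))
    stop("monte_carlo mode requires a seed for reproducibility")
  n <- as.integer(n_samples)
  thr <- matrix(NA_integer_, n + 1L, n + 1L)
  tbl <- structure(list(quantile = quantile, n_samples = n,
                        reps = as.integer(reps), mode = mode, seed = seed,
                        thresholds = thr),
                   class = "null_threshold_table")
  if (mode == "exact") {
    d <- 0:n
    tbl$thresholds <- outer(d, d, function(d1, d2)
      as.integer(stats::qhyper(quantile, d1, n - d1, d2)))
  } else if (!is.null(densities)) {
    densities <- as.matrix(densities)
    tbl <- fill_thresholds(tbl, densities[, 1], densities[, 2])
  }
  tbl
}

mc_threshold <- function(n, d1, d2, quantile, reps, seed) {
  if (d1 > n || d2 > n || d1 < 0 || d2 < 0)
    stop("density out of range [0, n]: d1=", d1, " d2=", d2, " n=", n)
  if (d1 == 0 || d2 == 0) return(0L)
  dlo <- min(d1, d2); dhi <- max(d1, d2)
  if (!is.null(seed))   # symmetric per-cell stream
    set.seed((seed + 2654435761 * dlo + 40503 * dhi) %% 2147483647)
  hit <- logical(n)
  overlaps <- integer(reps)
  for (r in seq_len(reps)) {
    hit[] <- FALSE
    hit[sample.int(n, dlo)] <- TRUE
    overlaps[r] <- sum(hit[sample.int(n, dhi)])
  }
  as.integer(ceiling(stats::quantile(overlaps, quantile, type = 7,
                                     names = FALSE)))
}

fill_thresholds <- function(tbl, d1, d2) {
  n <- tbl$n_samples
  if (any(d1 > n | d2 > n | d1 < 0 | d2 < 0))
    stop("density out of range [0, n]")
  idx <- unique(cbind(pmin(d1, d2), pmax(d1, d2)))
  for (r in seq_len(nrow(idx))) {
    a <- idx[r, 1]; b <- idx[r, 2]
    if (is.na(tbl$thresholds[a + 1L, b + 1L])) {
      th <- if (tbl$mode == "exact")
        as.integer(stats::qhyper(tbl$quantile, a, n - a, b))
      else
        mc_threshold(n, a, b, tbl$quantile, tbl$reps, tbl$seed)
      tbl$thresholds[a + 1L, b + 1L] <- th
      tbl$thresholds[b + 1L, a + 1L] <- th
    }
  }
  tbl
}

#' Look up (computing on demand) the acceptance threshold for a density pair
#'
#' @param tbl A [null_threshold_table()].
#' @param d1,d2 Densities (number of marked samples for each gene).
#' @return Integer threshold; counts must strictly exceed it.
#' @export
threshold_for <- function(tbl, d1, d2) {
  stopifnot(inherits(tbl, "null_threshold_table"))
  tbl <- fill_thresholds(tbl, d1, d2)
  tbl$thresholds[cbind(d1 + 1L, d2 + 1L)]
}

#' Extract pp/mm/pm networks from co-occurrence counts
#'
#' An edge is retained when its observed count strictly exceeds the null
#' threshold for the two genes' sign-specific densities: the number of `+1`
#' codes for the P side and of `-1` codes for the M side (for pm, gene1's
#' `+1` density and gene2's `-1` density). Support is the observed count; pm
#' edges are directed with gene1 up.
#'
#' @param counts A [count_cooccurrence()] result.
#' @param d The `discretized_matrix` the counts came from (source of the
#'   densities).
#' @param tbl A [null_threshold_table()] built for the same number of
#'   samples; missing density pairs are computed on demand.
#' @return List with [pair_list()]s `pp`, `mm`, `pm`.
#' @export
extract_networks <- function(counts, d, tbl) {
  stopifnot(inherits(counts, "cooccurrence_counts"),
            inherits(tbl, "null_threshold_table"))
  validate_discretized(d)
  if (tbl$n_samples != counts$n_samples)
    stop("threshold table built for ", tbl$n_samples,
         " samples but counts have ", counts$n_samples)
  if (!identical(rownames(d), counts$gene_ids))
    stop("gene order of counts and discretized matrix differ")
  dp <- rowSums(unclass(d) == 1L)
  dm <- rowSums(unclass(d) == -1L)
  tbl <- fill_thresholds(tbl,
                         rep(c(dp, dm), times = length(dp) + length(dm)),
                         rep(c(dp, dm), each = length(dp) + length(dm)))
  genes <- counts$gene_ids
  ng <- length(genes)
  take_sym <- function(cnt, dens) {
    th <- matrix(tbl$thresholds[cbind(rep(dens + 1L, ng),
                                      rep(dens + 1L, each = ng))], ng, ng)
    keep <- upper.tri(cnt) & cnt > th
    ij <- which(keep, arr.ind = TRUE)
    list(i = ij[, 1], j = ij[, 2], support = cnt[keep])
  }
  pp <- take_sym(counts$pp, dp)
  mm <- take_sym(counts$mm, dm)
  th_pm <- matrix(tbl$thresholds[cbind(rep(dp + 1L, ng),
                                       rep(dm + 1L, each = ng))], ng, ng)
  keep_pm <- counts$pm > th_pm
  diag(keep_pm) <- FALSE
  ij <- which(keep_pm, arr.ind = TRUE)
  list(
    pp = pair_list(genes[pp$i], genes[pp$j],
                   rep("pp", length(pp$i)), pp$support),
    mm = pair_list(genes[mm$i], genes[mm$j],
                   rep("mm", length(mm$i)), mm$support),
    pm = pair_list(genes[ij[, 1]], genes[ij[, 2]],
                   rep("pm", nrow(ij)), counts$pm[keep_pm])
  )
}

#' Run the whole discretization network pipeline on an expression matrix
#'
#' Convenience wrapper: discretize, split indicators, count co-occurrences,
#' build (or reuse) the null threshold table, extract the three networks.
#'
#' @param expr Numeric gene-by-sample matrix.
#' @param z_cutoff Discretization cutoff (default 0.4).
#' @param quantile Null acceptance quantile (default 0.995).
#' @param mode `"exact"` or `"monte_carlo"` null.
#' @param reps Monte Carlo permutations per density pair.
#' @param seed Seed for Monte Carlo mode.
#' @param sd_type Standard deviation convention for discretization.
#' @param null_table Optional prebuilt [null_threshold_table()] to reuse.
#' @return List of class `triexnet_networks`: `pp`, `mm`, `pm` pair-lists,
#'   the `discretized` matrix, the `null_table` and the parameters used.
#' @examples
#' study <- simulate_study(simulation_config(n_defined_genes = 20,
#'   n_background = 5, n_samples = 40, seed = 1))
#' nets <- build_networks(study$expr)
#' nrow(nets$pp)
#' @export
build_networks <- function(expr, z_cutoff = 0.4, quantile = 0.995,
                           mode = c("exact", "monte_carlo"), reps = 1000L,
                           seed = NULL, sd_type = "sample",
                           null_table = NULL) {
  mode <- match.arg(mode)
  d <- discretize_matrix(expr, z_cutoff, sd_type)
  counts <- count_cooccurrence(d)
  if (is.null(null_table))
    null_table <- null_threshold_table(ncol(expr), quantile, mode,
                                       reps, seed)
  nets <- extract_networks(counts, d, null_table)
  structure(list(pp = nets$pp, mm = nets$mm, pm = nets$pm,
                 discretized = d, null_table = null_table,
                 params = list(z_cutoff = z_cutoff, quantile = quantile,
                               mode = mode, reps = reps, seed = seed)),
            class = "triexnet_networks")
}

#' @export
print.triexnet_networks <- function(x, ...) {
  cat("triexnet networks (Z =", x$params$z_cutoff,
      ", quantile =", x$params$quantile, ",", x$params$mode, "null)\n")
  cat("  pp:", nrow(x$pp), " mm:", nrow(x$mm), " pm:", nrow(x$pm),
      "edges\n")
  invisible(x)
}

network_total_size <- function(nets, relations = c("pp", "mm", "pm")) {
  sum(vapply(relations, function(r) nrow(nets[[r]]), 0L))
}
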