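# Expected co-expression pairs from a signed regulatory network, and
# scoring of inferred networks against those expectations.

#' Signed adjacency matrix of a regulatory network
#'
#' `A[regulator, target]` is `+1` for activation (`ac`), `-1` for repression
#' (`re`) and `0` for dual-action (`du`) edges, which carry no consistent
#' sign and are ignored in sign propagation.
#'
#' @param net A [signed_regnet()].
#' @return Square integer matrix over `net$gene_universe` with class
#'   `signed_adjacency`.
#' @export
signed_adjacency <- function(net) {
  stopifnot(inherits(net, "signed_regnet"))
  genes <- net$gene_universe
  A <- matrix(0L, length(genes), length(genes),
              dimnames = list(genes, genes))
  i <- net$interactions
  sgn <- c(ac = 1L, re = -1L, du = 0L)[i$type]
  A[cbind(match(i$regulator, genes), match(i$target, genes))] <- sgn
  structure(A, class = c("signed_adjacency", class(A)))
}

# positive / negative walk-count matrices for path lengths 1..max_k:
# Pk[s,t] = number of s->t walks of length k whose edge-sign product is +,
# Nk[s,t] = the same for -. du edges (0) never contribute.
walk_sign_counts <- function(A, max_k) {
  Ap <- (unclass(A) == 1L) * 1
  An <- (unclass(A) == -1L) * 1
  pos <- vector("list", max_k); neg <- vector("list", max_k)
  pos[[1]] <- Ap; neg[[1]] <- An
  for (k in seq_len(max_k)[-1]) {
    pos[[k]] <- Ap %*% pos[[k - 1]] + An %*% neg[[k - 1]]
    neg[[k]] <- Ap %*% neg[[k - 1]] + An %*% pos[[k - 1]]
  }
  list(pos = pos, neg = neg)
}

pairs_from_evidence <- function(pos, neg, genes) {
  ut <- upper.tri(pos)
  mk <- function(mask) {
    ij <- which(mask & ut, arr.ind = TRUE)
    a <- genes[ij[, 1]]; b <- genes[ij[, 2]]
    out <- cbind(gene1 = pmin(a, b), gene2 = pmax(a, b))
    out[order(out[, 1], out[, 2]), , drop = FALSE]
  }
  list(positive = mk(pos > 0 & neg == 0),
       negative = mk(neg > 0 & pos == 0),
       ambiguous = mk(pos > 0 & neg > 0))
}

#' Predict transitive co-expression pairs from a signed adjacency
#'
#' Positive and negative walk counts are tracked separately (the adjacency
#' is split into its activation and repression parts before taking powers),
#' so sign cancellations that would vanish in a power of the signed matrix
#' are made explicit as "ambiguous" pairs instead of being silently lost.
#'
#' Two complementary views are produced for every path depth `k`:
#' \describe{
#'   \item{walk}{source-target pairs connected by a walk of length <= k;
#'     the expected co-expression sign is the walk-sign (all-activator
#'     chains give positive pairs, an odd number of repressions negative).}
#'   \item{shared}{target-target pairs reached from a common regulator by
#'     walks of length <= k; same sign products predict positive
#'     co-expression (two activated or two repressed targets move
#'     together), opposite products negative.}
#' }
#' The top-level `positive`/`negative`/`ambiguous` sets per depth merge both
#' views; a pair with conflicting evidence is ambiguous.
#'
#' @param x A [signed_adjacency()] or [signed_regnet()].
#' @param max_k Maximum path depth, in `{1, 2, 3}`.
#' @return List of class `prediction_set` with `genes`, `max_k`, and
#'   `by_k[[k]]`, each holding two-column pair matrices `positive`,
#'   `negative`, `ambiguous` plus the `walk` and `shared` sub-views.
#' @examples
#' net <- signed_regnet(data.frame(regulator = c("S", "S"),
#'   target = c("B", "C"), type = c("ac", "re")))
#' transitive_predictions(net, 1)$by_k[[1]]$negative   # (B, C)
#' @export
transitive_predictions <- function(x, max_k = 3L) {
  if (inherits(x, "signed_regnet")) x <- signed_adjacency(x)
  if (!inherits(x, "signed_adjacency"))
    stop("x must be a signed_regnet or signed_adjacency")
  if (!max_k %in% 1:3) stop("max_k must be 1, 2 or 3")
  genes <- rownames(x)
  w <- walk_sign_counts(x, max_k)
  by_k <- vector("list", max_k)
  cum_p <- matrix(0, nrow(x), ncol(x))
  cum_n <- cum_p
  for (k in seq_len(max_k)) {
    cum_p <- cum_p + w$pos[[k]]
    cum_n <- cum_n + w$neg[[k]]
    shared_pos <- t(cum_p) %*% cum_p + t(cum_n) %*% cum_n
    shared_neg <- t(cum_p) %*% cum_n + t(cum_n) %*% cum_p
    walk_pos <- cum_p + t(cum_p)
    walk_neg <- cum_n + t(cum_n)
    by_k[[k]] <- c(
      pairs_from_evidence(shared_pos + walk_pos, shared_neg + walk_neg,
                          genes),
      list(walk = pairs_from_evidence(walk_pos, walk_neg, genes),
           shared = pairs_from_evidence(shared_pos, shared_neg, genes)))
  }
  structure(list(genes = genes, max_k = max_k, by_k = by_k),
            class = "prediction_set")
}

#' @export
print.prediction_set <- function(x, ...) {
  cat("prediction_set over", length(x$genes), "gene(s), depths 1..",
      x$max_k, "\n", sep = "")
  for (k in seq_len(x$max_k))
    cat("  k<=", k, ": +", nrow(x$by_k[[k]]$positive), "  -",
        nrow(x$by_k[[k]]$negative), "  ?", nrow(x$by_k[[k]]$ambiguous),
        "\n", sep = "")
  invisible(x)
}

unordered_keys <- function(g1, g2) {
  paste(pmin(g1, g2), pmax(g1, g2), sep = "\r")
}
pairmat_keys <- function(pm) {
  if (is.null(pm) || nrow(pm) == 0) return(character())
  unordered_keys(pm[, 1], pm[, 2])
}

#' Score inferred networks against regulatory-network definitions
#'
#' For each of the pp/mm/pm networks, counts how many direct `ac`/`du`/`re`
#' definitions are recovered (matched as unordered gene pairs), how many
#' further edges are explained by transitive predictions of the appropriate
#' sign (positive for pp/mm, negative for pm), how many edges are explained
#' by neither (candidate false positives), and how many touch background
#' (`bgr_`-prefixed) genes. Every edge is counted exactly once among
#' direct / transitive / unexplained.
#'
#' @param pp,mm,pm [pair_list()]s from [extract_networks()] (any may be
#'   empty).
#' @param net The ground-truth [signed_regnet()].
#' @param preds Optional precomputed [transitive_predictions()]; built at
#'   `max_k` otherwise.
#' @param max_k Path depth for the predictions.
#' @return List of class `validation_report`: `per_network` data.frame and
#'   the definition totals.
#' @export
score_against_definitions <- function(pp, mm, pm, net, preds = NULL,
                                      max_k = 3L) {
  stopifnot(inherits(net, "signed_regnet"))
  if (is.null(preds)) preds <- transitive_predictions(net, max_k)
  ints <- net$interactions
  def_keys <- function(type)
    unique(unordered_keys(ints$regulator[ints$type == type],
                          ints$target[ints$type == type]))
  ac <- def_keys("ac"); du <- def_keys("du"); re <- def_keys("re")
  direct <- unique(c(ac, du, re))
  top <- preds$by_k[[preds$max_k]]
  pred_pos <- setdiff(pairmat_keys(top$positive), direct)
  pred_neg <- setdiff(pairmat_keys(top$negative), direct)
  score_one <- function(pl, name) {
    keys <- unique(unordered_keys(pl$gene1, pl$gene2))
    pred <- if (name == "pm") pred_neg else pred_pos
    n_direct <- sum(keys %in% direct)
    n_trans <- sum(keys %in% pred)
    bgr <- grepl("^bgr_", pl$gene1) | grepl("^bgr_", pl$gene2)
    data.frame(
      network = name, n_edges = length(keys),
      ac_recovered = sum(ac %in% keys), du_recovered = sum(du %in% keys),
      re_recovered = sum(re %in% keys),
      ac_fraction = if (length(ac)) sum(ac %in% keys) / length(ac) else NA,
      re_fraction = if (length(re)) sum(re %in% keys) / length(re) else NA,
      direct = n_direct, transitive = n_trans,
      unexplained = length(keys) - n_direct - n_trans,
      bgr_edges = sum(bgr), stringsAsFactors = FALSE)
  }
  per_network <- rbind(score_one(pp, "pp"), score_one(mm, "mm"),
                       score_one(pm, "pm"))
  rownames(per_network) <- per_network$network
  structure(list(per_network = per_network,
                 n_definitions = c(ac = length(ac), du = length(du),
                                   re = length(re)),
                 max_k = preds$max_k),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("validation against", sum(x$n_definitions),
      "definitions (ac:", x$n_definitions["ac"],
      "du:", x$n_definitions["du"], "re:", x$n_definitions["re"],
      "), transitive depth <=", x$max_k, "\n")
  print.data.frame(x$per_network, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Genes with variance below a fraction of the modal variance
#'
#' The modal variance is estimated as the mode of the histogram of
#' log-variances (Freedman-Diaconis bins); genes whose variance falls below
#' `fraction_of_modal` times it are returned. In simulated data these are
#' dominated by noise-only background genes and are candidates for spurious
#' edges.
#'
#' @param m Numeric gene-by-sample matrix with at least 10 genes (the mode
#'   is unstable below that).
#' @param fraction_of_modal Positive fraction (default 0.5).
#' @return Character vector of gene identifiers (possibly empty);
#'   zero-variance genes are always included.
#' @export
low_variance_genes <- function(m, fraction_of_modal = 0.5) {
  validate_expression_matrix(m)
  if (nrow(m) < 10) stop("need at least 10 genes to estimate modal variance")
  if (fraction_of_modal <= 0) stop("fraction_of_modal must be positive")
  v <- apply(m, 1, stats::var)
  pos <- v[v > 0]
  if (!length(pos)) return(rownames(m))
  lv <- log(pos)
  if (length(unique(lv)) == 1) {
    modal <- exp(lv[1])
  } else {
    h <- tryCatch(graphics::hist(lv, breaks = "FD", plot = FALSE),
                  error = function(e)
                    graphics::hist(lv, breaks = "Sturges", plot = FALSE))
    modal <- exp(h$mids[which.max(h$counts)])
  }
  rownames(m)[v < fraction_of_modal * modal]
}

#' Consensus networks from random sample subsets
#'
#' Randomly partitions the samples into `k_subsets` (near-)equal groups,
#' runs the full discretization pipeline on each, and intersects the
#' resulting networks per relation. Requiring an edge in every subset
#' preferentially discards pairs of low-variance genes while losing almost
#' no defined relations.
#'
#' @param expr Numeric gene-by-sample matrix.
#' @param k_subsets Number of subsets (>= 2); needs `>= 2 * k_subsets`
#'   samples.
#' @param seed Optional integer seed for the partition.
#' @param ... Pipeline parameters passed to [build_networks()].
#' @return List: `assignment` (subset index per sample), `subsets` (list of
#'   `triexnet_networks`), `intersection` (list of pp/mm/pm pair-lists,
#'   pm direction respected).
#' @export
subset_consensus <- function(expr, k_subsets = 2L, seed = NULL, ...) {
  validate_expression_matrix(expr)
  if (k_subsets < 2) stop("k_subsets must be at least 2")
  if (ncol(expr) < 2 * k_subsets)
    stop("need at least ", 2 * k_subsets, " samples")
  if (!is.null(seed)) set.seed(seed)
  idx <- sample(rep_len(seq_len(k_subsets), ncol(expr)))
  subsets <- lapply(seq_len(k_subsets), function(k)
    build_networks(expr[, idx == k, drop = FALSE], ...))
  inter <- lapply(c(pp = "pp", mm = "mm", pm = "pm"), function(rel) {
    acc <- subsets[[1]][[rel]]
    for (k in seq_len(k_subsets)[-1])
      acc <- intersect_pairlists(acc, subsets[[k]][[rel]])$intersection
    acc
  })
  list(assignment = stats::setNames(idx, colnames(expr)),
       subsets = subsets, intersection = inter)
}
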