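# Pearson correlation networks with the t-test cutoff, used both as a
# stand-alone method and as a filter on discretization networks.

#' Two-tailed p-value for a Pearson correlation coefficient
#'
#' Uses the t transform `t = r * sqrt(N - 2) / sqrt(1 - r^2)` with `N - 2`
#' degrees of freedom. At N = 100, r = 0.1 corresponds to p = 0.32 and
#' r = 0.3 to p = 0.0024.
#'
#' @param r Pearson correlation coefficient(s), `|r| < 1`.
#' @param N Number of observations (>= 3).
#' @return Two-tailed p-value(s).
#' @export
r_to_p <- function(r, N) {
  if (any(N < 3)) stop("N must be at least 3")
  if (any(abs(r) >= 1)) stop("|r| must be < 1")
  t <- r * sqrt(N - 2) / sqrt(1 - r^2)
  2 * stats::pt(-abs(t), df = N - 2)
}

#' Correlation cutoff giving a desired two-tailed p-value
#'
#' Inverse of [r_to_p()]: the (positive) `r` for which the two-tailed
#' t-test p-value equals `p` at `N` observations. E.g. p = 0.005 at N = 1021
#' gives the +-0.1032-type cutoffs used to match the discretization
#' acceptance probability.
#'
#' @param p Two-tailed p-value in (0, 1).
#' @param N Number of observations (>= 3).
#' @return Positive correlation cutoff; `r_to_p(p_to_r(p, N), N) == p`.
#' @export
p_to_r <- function(p, N) {
  if (any(p <= 0 | p >= 1)) stop("p must be in (0, 1)")
  if (any(N < 3)) stop("N must be at least 3")
  t <- stats::qt(1 - p / 2, df = N - 2)
  t / sqrt(t^2 + N - 2)
}

#' Build a signed Pearson correlation network
#'
#' All-pairs Pearson correlation across samples; pairs with `r` above the
#' positive cutoff form the positive edge set, below the negative cutoff the
#' negative set. Constant genes (undefined r) are skipped with a note.
#'
#' @param m Numeric gene-by-sample matrix with >= 3 samples.
#' @param r_cutoff Positive correlation cutoff; give either this or
#'   `p_cutoff`.
#' @param p_cutoff Two-tailed p-value converted to a cutoff via [p_to_r()].
#' @return List of class `corr_network`: full `r` matrix (over retained
#'   genes), `r_cutoff`, `n_obs`, `positive` and `negative` edge
#'   data frames (`gene1 < gene2`, `r`), and `dropped_genes`.
#' @export
correlation_network <- function(m, r_cutoff = NULL, p_cutoff = NULL) {
  validate_expression_matrix(m, min_samples = 3L)
  if (is.null(r_cutoff) == is.null(p_cutoff))
    stop("give exactly one of r_cutoff or p_cutoff")
  if (!is.null(p_cutoff)) r_cutoff <- p_to_r(p_cutoff, ncol(m))
  if (r_cutoff < 0) stop("r_cutoff must be non-negative")
  sds <- apply(m, 1, stats::sd)
  dropped <- rownames(m)[sds == 0]
  keep <- m[sds > 0, , drop = FALSE]
  if (nrow(keep) == 0) {
    warning("all genes constant; empty correlation network")
    empty <- data.frame(gene1 = character(), gene2 = character(),
                        r = numeric(), stringsAsFactors = FALSE)
    return(structure(list(r = NULL, r_cutoff = r_cutoff, n_obs = ncol(m),
                          positive = empty, negative = empty,
                          dropped_genes = dropped),
                     class = "corr_network"))
  }
  r <- stats::cor(t(keep))
  edge_set <- function(mask) {
    mask[lower.tri(mask, diag = TRUE)] <- FALSE
    ij <- which(mask, arr.ind = TRUE)
    g1 <- rownames(r)[ij[, 1]]; g2 <- rownames(r)[ij[, 2]]
    swap <- g1 > g2
    tmp <- g1[swap]; g1[swap] <- g2[swap]; g2[swap] <- tmp
    o <- order(g1, g2)
    data.frame(gene1 = g1[o], gene2 = g2[o], r = r[mask][o],
               stringsAsFactors = FALSE)
  }
  structure(list(r = r, r_cutoff = r_cutoff, n_obs = ncol(m),
                 positive = edge_set(r > r_cutoff),
                 negative = edge_set(r < -r_cutoff),
                 dropped_genes = dropped),
            class = "corr_network")
}

#' @export
print.corr_network <- function(x, ...) {
  cat("corr_network (|r| cutoff ", signif(x$r_cutoff, 4), ", N = ",
      x$n_obs, "): ", nrow(x$positive), " positive, ", nrow(x$negative),
      " negative edge(s)\n", sep = "")
  invisible(x)
}

#' Filter a discretization pair-list by a correlation network
#'
#' Positive correlation is required for `pp`/`mm` edges and negative
#' correlation for `pm` edges: an edge is retained only if the gene pair is
#' present in the matching signed edge set of the correlation network.
#' Supports are unchanged. This removes most spurious pairs involving
#' noise-only background genes while keeping almost all true relations.
#'
#' @param pl A [pair_list()].
#' @param cn A [correlation_network()] (or one read back from disk).
#' @param relation Optional single relation; if given, `pl` must contain
#'   only that relation (mismatch is an error).
#' @return Filtered [pair_list()] (a subset of `pl`).
#' @export
correlation_filter <- function(pl, cn, relation = NULL) {
  stopifnot(inherits(pl, "pair_list"), inherits(cn, "corr_network"))
  if (!is.null(relation)) {
    relation <- match.arg(relation, RELATIONS)
    if (any(pl$relation != relation))
      stop("pair_list contains relations other than '", relation, "'")
  }
  pos_keys <- paste(cn$positive$gene1, cn$positive$gene2, sep = "\r")
  neg_keys <- paste(cn$negative$gene1, cn$negative$gene2, sep = "\r")
  lo <- pmin(pl$gene1, pl$gene2)
  hi <- pmax(pl$gene1, pl$gene2)
  keys <- paste(lo, hi, sep = "\r")
  keep <- ifelse(pl$relation == "pm", keys %in% neg_keys, keys %in% pos_keys)
  as_pair_list(pl[keep, , drop = FALSE])
}

#' Read / write a correlation network edge table
#'
#' TSV columns `gene1`, `gene2`, `r`, `sign`; the cutoff and number of
#' observations travel in comment lines, so a written network can be read
#' back and used with [correlation_filter()] (the full r matrix is not
#' stored).
#'
#' @param path File path.
#' @return [read_corr_network()] returns a `corr_network` (with `r = NULL`).
#' @export
read_corr_network <- function(path) {
  raw <- readLines(path, encoding = "UTF-8")
  grab <- function(tag) {
    l <- grep(paste0("^#\\s*", tag, ":"), raw, value = TRUE)
    if (length(l)) as.numeric(sub(paste0("^#\\s*", tag, ":\\s*"), "", l[1]))
    else NA_real_
  }
  r_cutoff <- grab("r_cutoff"); n_obs <- grab("n_obs")
  tl <- read_tsv_lines(path)
  empty <- data.frame(gene1 = character(), gene2 = character(),
                      r = numeric(), stringsAsFactors = FALSE)
  pos <- empty; neg <- empty
  if (length(tl$lines)) {
    fields <- strsplit(tl$lines, "\t", fixed = TRUE)
    if (any(lengths(fields) != 4))
      stop("correlation network rows need 4 columns: ", path)
    m <- do.call(rbind, fields)
    if (m[1, 4] %in% c("positive", "negative")) start <- 1L else start <- 2L
    if (start <= nrow(m)) {
      m <- m[seq(start, nrow(m)), , drop = FALSE]
      df <- data.frame(gene1 = m[, 1], gene2 = m[, 2],
                       r = as.numeric(m[, 3]), sign = m[, 4],
                       stringsAsFactors = FALSE)
      pos <- df[df$sign == "positive", c("gene1", "gene2", "r")]
      neg <- df[df$sign == "negative", c("gene1", "gene2", "r")]
      rownames(pos) <- rownames(neg) <- NULL
    }
  }
  structure(list(r = NULL, r_cutoff = r_cutoff, n_obs = n_obs,
                 positive = pos, negative = neg, dropped_genes = character()),
            class = "corr_network")
}

#' @param cn A `corr_network`.
#' @rdname read_corr_network
#' @export
write_corr_network <- function(cn, path) {
  stopifnot(inherits(cn, "corr_network"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(paste0("# r_cutoff: ", cn$r_cutoff),
               paste0("# n_obs: ", cn$n_obs),
               "gene1\tgene2\tr\tsign"), con)
  wr <- function(df, sgn) {
    if (nrow(df))
      writeLines(paste(df$gene1, df$gene2,
                       format(df$r, trim = TRUE, digits = 15), sgn,
                       sep = "\t"), con)
  }
  wr(cn$positive, "positive")
  wr(cn$negative, "negative")
  invisible(path)
}
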