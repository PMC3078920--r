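# Ternary discretization: each gene is compared to its own mean across
# samples and coded +1 (unexpectedly high), -1 (unexpectedly low) or 0
# (around the mean), using a z-score cutoff.

#' Discretize an expression matrix into ternary codes
#'
#' Per gene `g`, values are standardized against the gene's mean and
#' standard deviation across samples; codes are `+1` where the z-score
#' exceeds `z_cutoff`, `-1` where it is below `-z_cutoff`, else `0`
#' (strict inequality at the boundary). Genes with zero variance get all-zero
#' codes, so constant background genes pass through harmlessly.
#'
#' @param m Numeric gene-by-sample matrix (at least 2 samples).
#' @param z_cutoff Positive z-score cutoff; 0.4 is the default working value
#'   (low enough to capture observable but modest expression changes).
#' @param sd_type `"sample"` (n-1 denominator, default) or `"population"`
#'   (n).
#' @return Integer matrix of class `discretized_matrix` with entries in
#'   `{-1, 0, 1}` and attributes `z_cutoff`, `sd_type`.
#' @examples
#' m <- rbind(g1 = c(0, 0, 0, 0, 10), g2 = rep(5, 5))
#' colnames(m) <- paste0("s", 1:5)
#' discretize_matrix(m, 0.4)
#' @export
discretize_matrix <- function(m, z_cutoff = 0.4,
                              sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  validate_expression_matrix(m)
  if (!is.numeric(z_cutoff) || length(z_cutoff) != 1 || z_cutoff <= 0)
    stop("z_cutoff must be a single positive number")
  n <- ncol(m)
  mu <- rowMeans(m)
  dev <- m - mu
  ss <- rowSums(dev^2)
  denom <- if (sd_type == "sample") n - 1L else n
  s <- sqrt(ss / denom)
  z <- dev / ifelse(s > 0, s, Inf)   # zero-variance rows -> z = 0
  codes <- matrix(0L, nrow(m), n, dimnames = dimnames(m))
  codes[z > z_cutoff] <- 1L
  codes[z < -z_cutoff] <- -1L
  structure(codes, z_cutoff = z_cutoff, sd_type = sd_type,
            class = c("discretized_matrix", class(codes)))
}

validate_discretized <- function(d) {
  if (!is.matrix(d) || !all(d %in% c(-1L, 0L, 1L)))
    stop("discretized matrix must contain only -1, 0, 1")
  invisible(d)
}

#' Split a discretized matrix into positive/negative indicator matrices
#'
#' `P` marks `+1` codes and `M` marks `-1` codes, both "in all positive
#' forms" (binary). `P - M` reconstructs the codes, and the inner products
#' `P P'`, `M M'`, `P M'` count the samples supporting each gene pair
#' ([count_cooccurrence()]).
#'
#' @param d A `discretized_matrix` (or any ternary matrix).
#' @return List with binary matrices `P` and `M`.
#' @export
split_indicators <- function(d) {
  validate_discretized(d)
  P <- (unclass(d) == 1L) * 1
  M <- (unclass(d) == -1L) * 1
  dimnames(P) <- dimnames(M) <- dimnames(d)
  list(P = P, M = M)
}

#' Independently permute each row of a discretized matrix
#'
#' The null model for network-size significance: each gene keeps its code
#' histogram (its density of +1/0/-1) but the sample assignment is
#' randomized, destroying all gene-gene co-occurrence structure.
#'
#' @param d A `discretized_matrix`.
#' @param seed Optional integer for reproducibility.
#' @return A `discretized_matrix` of the same shape and attributes.
#' @export
shuffle_rows <- function(d, seed = NULL) {
  validate_discretized(d)
  if (!is.null(seed)) set.seed(seed)
  out <- d
  n <- ncol(d)
  for (i in seq_len(nrow(d))) out[i, ] <- d[i, sample.int(n)]
  out
}

#' Per-sample clique scores for a gene set
#'
#' Sums the discretized codes of a gene clique in every sample: samples in
#' which the clique is coordinately "on" score near `+|genes|`, coordinately
#' "off" near `-|genes|`. This is the stratification step that maps a
#' discovered gene module back onto individual samples.
#'
#' @param d A `discretized_matrix`.
#' @param genes A [gene_set()] or character vector, all present in
#'   `rownames(d)`.
#' @return Named integer vector (one score per sample).
#' @export
clique_sample_scores <- function(d, genes) {
  validate_discretized(d)
  g <- as_gene_vector(genes)
  missing <- setdiff(g, rownames(d))
  if (length(missing))
    stop("gene(s) not in matrix: ", paste(missing, collapse = ", "))
  colSums(unclass(d)[g, , drop = FALSE])
}

#' Read / write a discretized matrix
#'
#' Same TSV layout as the expression matrix but integer entries, so cliques
#' and samples can be inspected by eye; the z cutoff is carried in a
#' `# z_cutoff:` comment line.
#'
#' @param path File path.
#' @return [read_discretized()] returns a `discretized_matrix`.
#' @export
read_discretized <- function(path) {
  raw <- readLines(path, encoding = "UTF-8")
  z <- NA_real_
  zl <- grep("^#\\s*z_cutoff:", raw, value = TRUE)
  if (length(zl)) z <- as.numeric(sub("^#\\s*z_cutoff:\\s*", "", zl[1]))
  parsed <- parse_matrix_lines(read_tsv_lines(path), path)
  m <- parsed$matrix
  if (!all(m %in% c(-1, 0, 1)))
    stop("discretized matrix entries must be -1, 0 or 1: ", path)
  codes <- matrix(as.integer(m), nrow(m), ncol(m), dimnames = dimnames(m))
  structure(codes, z_cutoff = z, sd_type = "sample",
            class = c("discretized_matrix", class(codes)))
}

#' @param d A `discretized_matrix`.
#' @rdname read_discretized
#' @export
write_discretized <- function(d, path) {
  validate_discretized(d)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  z <- attr(d, "z_cutoff")
  if (!is.null(z) && !is.na(z)) writeLines(paste0("# z_cutoff: ", z), con)
  writeLines(paste(c("gene_id", colnames(d)), collapse = "\t"), con)
  writeLines(paste(rownames(d),
                   apply(unclass(d), 1, paste, collapse = "\t"), sep = "\t"),
             con)
  invisible(path)
}
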