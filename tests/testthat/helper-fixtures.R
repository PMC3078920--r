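# Shared fixtures, built in code at test time.

# wrap a ternary integer matrix as a discretized_matrix
as_disc <- function(codes, z_cutoff = 0.4) {
  storage.mode(codes) <- "integer"
  if (is.null(rownames(codes)))
    rownames(codes) <- sprintf("g%03d", seq_len(nrow(codes)))
  if (is.null(colnames(codes)))
    colnames(codes) <- sprintf("s%03d", seq_len(ncol(codes)))
  structure(codes, z_cutoff = z_cutoff, sd_type = "sample",
            class = c("discretized_matrix", class(codes)))
}

random_ternary <- function(n_genes, n_samples,
                           prob = c(1, 1, 1) / 3) {
  as_disc(matrix(sample(c(-1L, 0L, 1L), n_genes * n_samples,
                        replace = TRUE, prob = prob),
                 n_genes, n_samples))
}

# independent oracle: accumulate pair counts sample by sample
brute_counts <- function(codes) {
  ng <- nrow(codes)
  pp <- mm <- pm <- matrix(0, ng, ng)
  for (s in seq_len(ncol(codes))) {
    p <- codes[, s] == 1L
    m <- codes[, s] == -1L
    pp <- pp + outer(p, p)
    mm <- mm + outer(m, m)
    pm <- pm + outer(p, m)
  }
  list(pp = pp, mm = mm, pm = pm)
}

unordered_keys_of <- function(g1, g2) paste(pmin(g1, g2), pmax(g1, g2),
                                            sep = "|")
pl_ukeys <- function(pl) unique(unordered_keys_of(pl$gene1, pl$gene2))

small_expr <- function() {
  m <- rbind(gA = c(1.0, 2.0, 3.0, 4.0),
             gB = c(2.1, 1.9, 3.3, 0.7),
             gC = c(5.0, 5.0, 5.0, 5.0))
  colnames(m) <- paste0("s", 1:4)
  m
}

# planted two-block 0/1 adjacency as a pp pair_list
planted_blocks_pairlist <- function(sizes = c(20, 15), p_in = 0.8,
                                    p_between = 0.02) {
  n <- sum(sizes)
  genes <- sprintf("n%02d", seq_len(n))
  block <- rep(seq_along(sizes), sizes)
  g1 <- character(); g2 <- character()
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    p <- if (block[i] == block[j]) p_in else p_between
    if (stats::runif(1) < p) { g1 <- c(g1, genes[i]); g2 <- c(g2, genes[j]) }
  }
  list(pl = pair_list(g1, g2, rep("pp", length(g1)),
                      rep(1L, length(g1))),
       genes = genes, block = block)
}
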