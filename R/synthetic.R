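# Simulator: expression data driven by a known signed regulatory network
# plus pure-noise background genes, in the style of gene-network benchmark
# generators. Every pipeline stage can be exercised against a known truth
# without any external data.

#' Configuration for the synthetic study generator
#'
#' Defaults describe the reference study conditions used throughout the
#' package's tests: 100 genes with known relations plus 100 background
#' genes, 200 samples, low biological noise (0.1), and interaction-type
#' fractions close to the E. coli-style definition mix (roughly 65%
#' activation, 27.5% repression, 7.5% dual-action).
#'
#' @param n_defined_genes Genes wired into the regulatory network.
#' @param n_background Pure-noise background genes (named `bgr_...`).
#' @param n_samples Number of samples to simulate.
#' @param bio_noise Noise-to-signal scale (standard deviation of the
#'   Gaussian noise added to every regulated gene, and the whole standard
#'   deviation of background genes). 0.1-0.5 spans low to high noise.
#' @param frac_re,frac_du Fractions of repression and dual-action edges
#'   (the rest are activations).
#' @param effect_size Multiplier on the summed parent signal.
#' @param n_roots Number of root regulators (no parents); default ~8% of
#'   the defined genes, at least 2.
#' @param mean_parents Mean number of parents per non-root gene, in [1, 2].
#' @param seed Integer seed; all randomness in the generator and simulator
#'   derives from it.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(n_defined_genes = 100L, n_background = 100L,
                              n_samples = 200L, bio_noise = 0.1,
                              frac_re = 0.275, frac_du = 0.075,
                              effect_size = 1, n_roots = NULL,
                              mean_parents = 1.5, seed = 1L) {
  if (is.null(n_roots)) n_roots <- max(2L, round(0.08 * n_defined_genes))
  stopifnot(n_defined_genes >= 2, n_background >= 0, n_samples >= 2,
            bio_noise >= 0, frac_re >= 0, frac_du >= 0,
            frac_re + frac_du <= 1, effect_size > 0,
            n_roots >= 1, n_roots < n_defined_genes,
            mean_parents >= 1, mean_parents <= 2)
  structure(list(n_defined_genes = as.integer(n_defined_genes),
                 n_background = as.integer(n_background),
                 n_samples = as.integer(n_samples), bio_noise = bio_noise,
                 frac_re = frac_re, frac_du = frac_du,
                 effect_size = effect_size, n_roots = as.integer(n_roots),
                 mean_parents = mean_parents, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Generate a random acyclic signed regulatory network
#'
#' Genes are laid out in a fixed order and each non-root gene receives one
#' or two parents among earlier genes, chosen with preferential attachment
#' (weights proportional to current out-degree + 1). Hubs therefore emerge
#' naturally, guaranteeing shared-regulator motifs, and the graph is acyclic
#' by construction. Edge types are drawn independently at the configured
#' ac/re/du fractions. Background genes enter the gene universe but carry
#' no interactions.
#'
#' @param cfg A [simulation_config()].
#' @return A [signed_regnet()] whose `gene_universe` includes the
#'   `bgr_`-prefixed background genes.
#' @export
generate_regnet <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  n <- cfg$n_defined_genes
  genes <- sprintf("g%03d", seq_len(n))
  bgr <- if (cfg$n_background > 0)
    sprintf("bgr_%03d", seq_len(cfg$n_background)) else character()
  outdeg <- integer(n)
  reg <- character(0); tgt <- character(0)
  p_extra <- cfg$mean_parents - 1
  for (i in seq(cfg$n_roots + 1L, n)) {
    np <- 1L + stats::rbinom(1L, 1L, p_extra)
    cand <- seq_len(i - 1L)
    np <- min(np, length(cand))
    parents <- if (length(cand) == 1L) cand else
      sample(cand, np, prob = outdeg[cand] + 1)
    outdeg[parents] <- outdeg[parents] + 1L
    reg <- c(reg, genes[parents])
    tgt <- c(tgt, rep(genes[i], np))
  }
  p_ac <- 1 - cfg$frac_re - cfg$frac_du
  type <- sample(INTERACTION_TYPES, length(reg), replace = TRUE,
                 prob = c(p_ac, cfg$frac_re, cfg$frac_du))
  signed_regnet(data.frame(regulator = reg, target = tgt, type = type,
                           stringsAsFactors = FALSE),
                gene_universe = c(genes, bgr))
}

topological_order <- function(ints, genes) {
  parents <- split(ints$regulator, ints$target)
  placed <- character(0)
  remaining <- genes
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(g)
      all(parents[[g]] %in% placed) || is.null(parents[[g]]), TRUE)]
    if (!length(ready))
      stop("regulatory network contains a cycle; cannot simulate")
    placed <- c(placed, ready)
    remaining <- setdiff(remaining, ready)
  }
  placed
}

#' Simulate expression data from a signed regulatory network
#'
#' Linear signed propagation: per sample, root genes draw from a standard
#' normal; every other defined gene sums `(+parent)` for activation and
#' `(-parent)` for repression (a dual-action parent contributes with a
#' random sign per sample). The summed signal is rescaled to unit variance
#' (times `effect_size`) and Gaussian noise of standard deviation
#' `bio_noise` is added, so `bio_noise` is a genuine noise-to-signal scale
#' at every depth of the cascade. Background genes are pure Gaussian noise
#' of standard deviation `bio_noise`: they vary little relative to
#' regulated genes and are the natural source of spurious edges. Noise is
#' drawn fresh from the seeded generator, so independent runs with
#' different seeds have independent background streams.
#'
#' @param net A [signed_regnet()] (must be acyclic).
#' @param cfg A [simulation_config()].
#' @return List of class `simulated_study`: `expr` (matrix over the full
#'   gene universe), `truth` (the network), `config`.
#' @export
simulate_expression <- function(net, cfg) {
  stopifnot(inherits(net, "signed_regnet"),
            inherits(cfg, "simulation_config"))
  set.seed((cfg$seed + 1L) %% .Machine$integer.max)
  genes <- net$gene_universe
  defined <- genes[!grepl("^bgr_", genes)]
  ord <- topological_order(net$interactions, defined)
  ns <- cfg$n_samples
  expr <- matrix(0, length(genes), ns,
                 dimnames = list(genes, sprintf("s%03d", seq_len(ns))))
  ints <- net$interactions
  by_target <- split(seq_len(nrow(ints)), ints$target)
  for (g in ord) {
    rows <- by_target[[g]]
    if (is.null(rows)) {
      expr[g, ] <- stats::rnorm(ns)
    } else {
      sig <- numeric(ns)
      for (r in rows) {
        pv <- expr[ints$regulator[r], ]
        sgn <- switch(ints$type[r],
                      ac = 1,
                      re = -1,
                      du = sample(c(-1, 1), ns, replace = TRUE))
        sig <- sig + sgn * pv
      }
      ssd <- stats::sd(sig)
      if (ssd > 0) sig <- sig / ssd
      expr[g, ] <- cfg$effect_size * sig +
        cfg$bio_noise * stats::rnorm(ns)
    }
  }
  bgr <- genes[grepl("^bgr_", genes)]
  if (length(bgr))
    expr[bgr, ] <- cfg$bio_noise *
      matrix(stats::rnorm(length(bgr) * ns), length(bgr), ns)
  structure(list(expr = expr, truth = net, config = cfg),
            class = "simulated_study")
}

#' Generate a complete synthetic study (network + expression)
#'
#' @param cfg A [simulation_config()].
#' @return A `simulated_study` (see [simulate_expression()]).
#' @examples
#' study <- simulate_study(simulation_config(n_defined_genes = 10,
#'   n_background = 5, n_samples = 30, seed = 3))
#' dim(study$expr)
#' @export
simulate_study <- function(cfg) {
  simulate_expression(generate_regnet(cfg), cfg)
}

#' @export
print.simulated_study <- function(x, ...) {
  cat("simulated_study:", nrow(x$expr), "gene(s) x", ncol(x$expr),
      "sample(s);", nrow(x$truth$interactions), "interaction(s);",
      "bio_noise =", x$config$bio_noise, "\n")
  invisible(x)
}
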