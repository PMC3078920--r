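regnet_of <- function(reg, tgt, type, universe = NULL) {
  signed_regnet(data.frame(regulator = reg, target = tgt, type = type,
                           stringsAsFactors = FALSE),
                gene_universe = universe)
}

test_that("signed adjacency encodes ac as +1, re as -1, du as 0", {
  expect_equal(signed_adjacency(regnet_of("A", "B", "ac"))["A", "B"], 1L)
  expect_equal(signed_adjacency(regnet_of("A", "B", "re"))["A", "B"], -1L)
  Adu <- signed_adjacency(regnet_of("A", "B", "du"))
  expect_true(all(Adu == 0L))
})

test_that("shared-regulator motifs predict the expected signs", {
  pos_pair <- function(preds, k, a, b) {
    p <- preds$by_k[[k]]$positive
    any(p[, 1] == min(a, b) & p[, 2] == max(a, b))
  }
  neg_pair <- function(preds, k, a, b) {
    p <- preds$by_k[[k]]$negative
    any(p[, 1] == min(a, b) & p[, 2] == max(a, b))
  }
  # two activated targets move together
  p1 <- transitive_predictions(regnet_of(c("S", "S"), c("B", "C"),
                                         c("ac", "ac")), 1)
  expect_true(pos_pair(p1, 1, "B", "C"))
  # two repressed targets also move together
  p2 <- transitive_predictions(regnet_of(c("S", "S"), c("B", "C"),
                                         c("re", "re")), 1)
  expect_true(pos_pair(p2, 1, "B", "C"))
  # mixed regulation is asymmetric: negative pair
  p3 <- transitive_predictions(regnet_of(c("S", "S"), c("B", "C"),
                                         c("ac", "re")), 1)
  expect_true(neg_pair(p3, 1, "B", "C"))
})

test_that("prediction sets are monotone in path depth", {
  set.seed(51)
  net <- generate_regnet(simulation_config(n_defined_genes = 30,
                                           n_background = 0, seed = 51))
  preds <- transitive_predictions(net, 3)
  keys <- function(k, what)
    if (nrow(preds$by_k[[k]][[what]]))
      paste(preds$by_k[[k]][[what]][, 1], preds$by_k[[k]][[what]][, 2])
    else character()
  for (k in 1:2) {
    deeper <- c(keys(k + 1, "positive"), keys(k + 1, "ambiguous"))
    expect_true(all(keys(k, "positive") %in% deeper))
    deeper_neg <- c(keys(k + 1, "negative"), keys(k + 1, "ambiguous"))
    expect_true(all(keys(k, "negative") %in% deeper_neg))
  }
  expect_error(transitive_predictions(net, 4), "1, 2 or 3")
})

test_that("conflicting evidence is flagged ambiguous, not signed", {
  net <- regnet_of(c("S1", "S1", "S2", "S2"), c("B", "C", "B", "C"),
                   c("ac", "ac", "ac", "re"))
  preds <- transitive_predictions(net, 1)
  amb <- preds$by_k[[1]]$ambiguous
  expect_true(any(amb[, 1] == "B" & amb[, 2] == "C"))
  expect_false(any(preds$by_k[[1]]$positive[, 1] == "B" &
                   preds$by_k[[1]]$positive[, 2] == "C"))
})

test_that("scoring recovers self-evident and empty comparisons", {
  net <- regnet_of(c("A", "B", "C"), c("B", "C", "D"),
                   c("ac", "ac", "re"))
  pp <- pair_list(c("A", "B"), c("B", "C"), c("pp", "pp"), c(5L, 5L))
  empty <- pair_list()
  rep1 <- score_against_definitions(pp, empty, empty, net)
  expect_equal(rep1$per_network["pp", "ac_recovered"], 2)
  expect_equal(rep1$per_network["pp", "ac_fraction"], 1)
  expect_equal(rep1$per_network["pp", "unexplained"], 0)
  rep0 <- score_against_definitions(empty, empty, empty, net)
  expect_true(all(rep0$per_network$n_edges == 0))
  expect_true(all(rep0$per_network$ac_recovered == 0))
})

test_that("every network edge lands in exactly one explanation bucket", {
  study <- simulate_study(simulation_config(
    n_defined_genes = 40, n_background = 20, n_samples = 80, seed = 52))
  nets <- build_networks(study$expr)
  rep <- score_against_definitions(nets$pp, nets$mm, nets$pm, study$truth)
  with(rep$per_network,
       expect_equal(n_edges, direct + transitive + unexplained))
})

test_that("low-variance genes are found below the modal variance", {
  set.seed(53)
  m <- rbind(matrix(rnorm(90 * 50, sd = 1), 90, 50),
             matrix(rnorm(10 * 50, sd = sqrt(0.2)), 10, 50))
  dimnames(m) <- list(c(sprintf("hi%02d", 1:90), sprintf("lo%02d", 1:10)),
                      sprintf("s%02d", 1:50))
  low <- low_variance_genes(m, 0.5)
  expect_true(all(grepl("^lo", low)))
  expect_gte(length(low), 8)   # most of the planted low-variance genes
  # equal variances: nothing is below half the mode
  me <- matrix(rnorm(20), 12, 20, byrow = TRUE,
               dimnames = list(sprintf("g%02d", 1:12),
                               sprintf("s%02d", 1:20)))
  expect_length(low_variance_genes(me, 0.5), 0)
  # a zero-variance gene is always selected
  m2 <- m; m2["lo01", ] <- 5
  expect_true("lo01" %in% low_variance_genes(m2, 0.5))
  expect_error(low_variance_genes(m[1:5, ], 0.5), "at least 10")
})

test_that("subset consensus is deterministic and prunes noise pairs", {
  study <- simulate_study(simulation_config(
    n_defined_genes = 40, n_background = 40, n_samples = 120,
    bio_noise = 0.3, seed = 54))
  con1 <- subset_consensus(study$expr, 2, seed = 55)
  con2 <- subset_consensus(study$expr, 2, seed = 55)
  expect_equal(con1$assignment, con2$assignment)
  expect_equal(con1$intersection$pp, con2$intersection$pp)
  # intersection is a subset of each subset network
  k1 <- pl_ukeys(con1$subsets[[1]]$pp)
  expect_true(all(pl_ukeys(con1$intersection$pp) %in% k1))
  # background pairs are discarded at a higher rate than defined relations
  ints <- study$truth$interactions
  ac <- unique(unordered_keys_of(ints$regulator[ints$type == "ac"],
                                 ints$target[ints$type == "ac"]))
  union_keys <- unique(c(pl_ukeys(con1$subsets[[1]]$pp),
                         pl_ukeys(con1$subsets[[2]]$pp)))
  inter_keys <- pl_ukeys(con1$intersection$pp)
  bgr_union <- grep("bgr_", union_keys, value = TRUE)
  if (length(bgr_union) >= 10) {
    ac_kept <- mean(ac[ac %in% union_keys] %in% inter_keys)
    bgr_kept <- mean(bgr_union %in% inter_keys)
    expect_gt(ac_kept, bgr_kept)
  }
  expect_error(subset_consensus(study$expr[, 1:3], 2), "at least 4")
})
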