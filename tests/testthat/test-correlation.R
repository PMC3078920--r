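test_that("r_to_p matches the t transform and is monotone", {
  expect_equal(signif(r_to_p(0.1, 100), 2), 0.32)
  expect_equal(signif(r_to_p(0.3, 100), 2), 0.0024)
  expect_equal(r_to_p(0, 50), 1)
  rs <- seq(0.05, 0.9, by = 0.05)
  expect_true(all(diff(r_to_p(rs, 40)) < 0))            # decreasing in |r|
  Ns <- c(10, 50, 100, 500)
  expect_true(all(diff(r_to_p(0.2, Ns)) < 0))           # decreasing in N
  expect_error(r_to_p(0.5, 2), "at least 3")
  expect_error(r_to_p(1, 10), "< 1")
})

test_that("p_to_r inverts r_to_p", {
  expect_equal(p_to_r(1 - 1e-12, 100), 0, tolerance = 1e-5)
  expect_equal(p_to_r(0.32, 100), 0.1, tolerance = 0.01)
  for (N in c(100, 200, 1021)) {
    r <- p_to_r(0.005, N)
    expect_equal(r_to_p(r, N), 0.005, tolerance = 1e-9)
  }
  # cutoffs shrink with sample size at fixed p
  expect_true(all(diff(p_to_r(0.005, c(100, 200, 620, 1021))) < 0))
  expect_error(p_to_r(0, 100), "in \\(0, 1\\)")
})

test_that("correlation networks split signed edges and skip constants", {
  m <- rbind(a = c(1, 2, 3, 4, 5),
             b = c(2, 4, 6, 8, 10),
             c = c(5, 4, 3, 2, 1),
             k = c(7, 7, 7, 7, 7))
  colnames(m) <- paste0("s", 1:5)
  cn <- correlation_network(m, r_cutoff = 0.5)
  expect_equal(cn$dropped_genes, "k")
  expect_true(any(cn$positive$gene1 == "a" & cn$positive$gene2 == "b" &
                  abs(cn$positive$r - 1) < 1e-12))
  expect_true(any(cn$negative$gene1 == "a" & cn$negative$gene2 == "c" &
                  abs(cn$negative$r + 1) < 1e-12))
  allc <- matrix(3, 4, 5, dimnames = list(letters[1:4], paste0("s", 1:5)))
  expect_warning(cn0 <- correlation_network(allc, r_cutoff = 0.3),
                 "constant")
  expect_equal(nrow(cn0$positive) + nrow(cn0$negative), 0L)
})

test_that("correlation edge acceptance is calibrated on null data", {
  set.seed(31)
  m <- matrix(rnorm(100 * 100), 100, 100,
              dimnames = list(sprintf("g%03d", 1:100),
                              sprintf("s%03d", 1:100)))
  cn <- correlation_network(m, p_cutoff = 0.005)
  rate <- (nrow(cn$positive) + nrow(cn$negative)) / choose(100, 2)
  se <- sqrt(0.005 * 0.995 / choose(100, 2))
  expect_lt(abs(rate - 0.005), 3 * se)
})

test_that("correlation_filter keeps concordant edges only", {
  m <- rbind(a = c(1, 2, 3, 4, 5),
             b = c(1.1, 2.2, 2.9, 4.2, 5.1),
             c = c(5, 4, 3.1, 2, 0.9))
  colnames(m) <- paste0("s", 1:5)
  cn <- correlation_network(m, r_cutoff = 0.1)
  pl <- pair_list(c("a", "a"), c("b", "b"), c("pp", "pm"), c(4L, 4L))
  out <- correlation_filter(pl, cn)
  expect_equal(out$relation, "pp")      # positive r keeps pp, kills pm
  plneg <- pair_list(c("a", "a"), c("c", "c"), c("pm", "pp"), c(3L, 3L))
  outn <- correlation_filter(plneg, cn)
  expect_equal(outn$relation, "pm")     # negative r keeps pm, kills pp
  expect_error(correlation_filter(pl, cn, relation = "pp"), "other than")
  # filtered list is always a subset
  expect_true(all(pl_ukeys(out) %in% pl_ukeys(pl)))
})

test_that("corr networks round-trip through disk for filtering", {
  m <- rbind(a = c(1, 2, 3, 4, 6), b = c(1, 2.2, 2.7, 4.4, 6.1),
             c = c(6, 4, 3, 2, 1))
  colnames(m) <- paste0("s", 1:5)
  cn <- correlation_network(m, p_cutoff = 0.05)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_corr_network(cn, f)
  back <- read_corr_network(f)
  expect_equal(back$positive, cn$positive, tolerance = 1e-12)
  expect_equal(back$negative, cn$negative, tolerance = 1e-12)
  expect_equal(back$r_cutoff, cn$r_cutoff, tolerance = 1e-12)
  pl <- pair_list("a", "b", "pp", 5L)
  expect_equal(correlation_filter(pl, back), correlation_filter(pl, cn))
})

test_that("the correlation filter strips background pairs from networks", {
  study <- simulate_study(simulation_config(
    n_defined_genes = 40, n_background = 40, n_samples = 100,
    bio_noise = 0.1, seed = 41))
  nets <- build_networks(study$expr)
  ints <- study$truth$interactions
  ac_keys <- unique(unordered_keys_of(ints$regulator[ints$type == "ac"],
                                      ints$target[ints$type == "ac"]))
  is_bgr <- function(pl) grepl("^bgr_", pl$gene1) | grepl("^bgr_", pl$gene2)
  # strict filter (r = 0.3): chance-level background pairs sit near the
  # null correlation scale and are removed; true relations (r near 1) stay
  cn3 <- correlation_network(study$expr, r_cutoff = 0.3)
  bgr_before <- 0L; bgr_after <- 0L
  for (rel in c("pp", "mm", "pm")) {
    f <- correlation_filter(nets[[rel]], cn3)
    bgr_before <- bgr_before + sum(is_bgr(nets[[rel]]))
    bgr_after <- bgr_after + sum(is_bgr(f))
  }
  expect_gte(bgr_before, 10)
  expect_lt(bgr_after, 0.5 * bgr_before)
  pp_f3 <- correlation_filter(nets$pp, cn3)
  before_ac <- sum(ac_keys %in% pl_ukeys(nets$pp))
  after_ac <- sum(ac_keys %in% pl_ukeys(pp_f3))
  expect_gte(after_ac, 0.95 * before_ac)     # true relations retained
  # the permissive filter (r = 0.1) also keeps essentially everything true
  cn1 <- correlation_network(study$expr, r_cutoff = 0.1)
  pp_f1 <- correlation_filter(nets$pp, cn1)
  expect_gte(sum(ac_keys %in% pl_ukeys(pp_f1)), 0.95 * before_ac)
})
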