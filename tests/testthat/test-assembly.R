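two_clade_tree <- function() {
  # two clear clades (internal separation 1.0), 4 tips each
  ape::read.tree(text = paste0(
    "(((t1:0.05,t2:0.05):0.05,(t3:0.05,t4:0.05):0.05):0.5,",
    "((t5:0.05,t6:0.05):0.05,(t7:0.05,t8:0.05):0.05):0.5);"))
}

test_that("bins split clear clades and merge undersized ones", {
  tr <- two_clade_tree()
  cm <- matrix(rpois(16, 20) + 1L, 8, 2,
               dimnames = list(paste0("t", 1:8), c("s1", "s2")))
  b <- build_bins(tr, cm, ds = 0.2, min_size = 2)
  expect_length(b$bins, 2)
  expect_equal(sum(b$weights), 1)
  expect_setequal(b$bins[[b$membership[["t1"]]]], paste0("t", 1:4))
  # min_size larger than either clade forces a single merged bin
  b2 <- build_bins(tr, cm, ds = 0.2, min_size = 5)
  expect_length(b2$bins, 1)
  # unresolved tree errors
  tr0 <- tr; tr0$edge.length[] <- 0
  expect_error(build_bins(tr0, cm), "unresolved")
})

test_that("bin weights sum to one for arbitrary inputs", {
  sim <- small_sim(seed = 61)
  b <- build_bins(sim$tree, sim$counts, ds = 0.3, min_size = 8)
  expect_equal(sum(b$weights), 1, tolerance = 1e-9)
  expect_setequal(unlist(b$bins), rownames(sim$counts))
})

test_that("process classification applies the documented decision rule", {
  expect_equal(classify_process(-2.5, NA), "HoS")
  expect_equal(classify_process(2.5, NA), "HeS")
  expect_equal(classify_process(0.3, 0.99), "DL")
  expect_equal(classify_process(0.3, -0.99), "HD")
  expect_equal(classify_process(0.3, 0.0), "DR")
  expect_equal(classify_process(NA, 0.3), "DR")
  expect_equal(classify_process(c(-3, 3, 0, 0, 0), c(NA, NA, 1, -1, 0)),
               c("HoS", "HeS", "DL", "HD", "DR"))
})

test_that("importance aggregation is weight-renormalized and sums to one", {
  pb <- data.frame(
    sample_1 = c("s1", "s1", "s2"),
    sample_2 = c("s2", "s2", "s3"),
    bin = c("binA", "binB", "binA"),
    process = c("HoS", "DL", "DR"))
  w <- c(binA = 0.5, binB = 0.5)
  agg <- aggregate_importance(pb, w)
  expect_equal(sum(agg$community), 1, tolerance = 1e-9)
  # pair s1-s2 splits HoS/DL evenly; pair s2-s3 (binA only) is all DR
  expect_equal(unname(agg$community),
               c(0.25, 0, 0.25, 0, 0.5))
  expect_equal(unname(rowSums(agg$sample)), rep(1, 3), tolerance = 1e-9)
  # all-DR input gives DR = 1
  pb2 <- pb; pb2$process <- "DR"
  expect_equal(unname(aggregate_importance(pb2, w)$community[5]), 1)
})

test_that("beta index is invariant to joint relabeling of tips and counts", {
  tr <- two_clade_tree()
  set.seed(3)
  cm <- matrix(rpois(16, 15) + 1L, 8, 2,
               dimnames = list(paste0("t", 1:8), c("s1", "s2")))
  coph <- ape::cophenetic.phylo(tr)
  r1 <- beta_index(cm, coph, paste0("t", 1:8), c("s1", "s2"), seed = 5)
  perm <- sample(8)
  cm2 <- cm[perm, ]
  r2 <- beta_index(cm2, coph, rownames(cm2), c("s1", "s2"), seed = 5)
  expect_equal(r1$obs, r2$obs, tolerance = 1e-12)
  # bin absent from one sample -> NA
  cm3 <- cm; cm3[, "s2"] <- 0L
  r3 <- beta_index(cm3, coph, paste0("t", 1:8), c("s1", "s2"), seed = 5)
  expect_true(is.na(r3$z))
})

test_that("beta z stays small for neutral data and batched matches per-pair", {
  sim <- simulate_community(sim_config(
    seed = 71, n_lineages = 24, lineage_sizes = rep(c(2L, 4L), 12),
    n_samples = 12, n_sites = 4, n_events = 3, equal_intensities = TRUE,
    n_crt = 0, depth = 10000))
  b <- build_bins(sim$tree, sim$counts, ds = 2, min_size = 2)
  mem <- b$bins[[1]]
  sub <- sim$counts[mem, ]
  z <- amdniche:::bin_beta_z(sub, b$coph[mem, mem], n_null = 99, seed = 13)
  zz <- z[upper.tri(z)]
  expect_gt(mean(abs(zz) <= 1.96, na.rm = TRUE), 0.9)
})

test_that("Raup-Crick hits its bounds for identical and disjoint communities", {
  ids <- paste0("t", 1:6)
  cm <- matrix(0L, 6, 3, dimnames = list(ids, c("s1", "s2", "s3")))
  cm[, "s1"] <- c(30L, 20L, 10L, 5L, 0L, 0L)
  cm[, "s2"] <- cm[, "s1"]              # identical
  cm[, "s3"] <- c(0L, 0L, 0L, 0L, 40L, 25L)  # disjoint
  rc_same <- raup_crick(cm, ids, c("s1", "s2"), n_null = 199, seed = 3)
  expect_lt(rc_same, -0.9)
  rc_diff <- raup_crick(cm, ids, c("s1", "s3"), n_null = 199, seed = 3)
  expect_gt(rc_diff, 0.5)
  expect_true(is.na(raup_crick(cm, ids, c("s1", "s1")) -> x) || x <= 1)
})

test_that("RC is near-uniform when data come from the null model itself", {
  # disjoint sample pairs keep the RC values independent (shared samples
  # would correlate them and invalidate the KS test)
  set.seed(14)
  m <- 12; n <- 160; k <- 6; N <- 500L
  cm <- matrix(0L, m, n, dimnames = list(paste0("t", 1:m), paste0("s", 1:n)))
  for (s in seq_len(n)) {
    sel <- sample(m, k)
    cm[sel, s] <- rmultinom(1, N, rep(1 / k, k))
  }
  rcs <- vapply(1:80, function(i) {
    pr <- c(2 * i - 1, 2 * i)
    raup_crick(cm, rownames(cm), colnames(cm)[pr], n_null = 299,
               seed = 1000 + i)
  }, 0)
  ks <- suppressWarnings(ks.test(rcs, "punif", -1, 1))
  expect_gt(ks$p.value, 0.01)
})

test_that("full assembly run returns coherent fractions at every scope", {
  sim <- simulate_community(sim_config(
    seed = 81, n_lineages = 20, lineage_sizes = rep(c(2L, 4L), 10),
    n_samples = 10, n_sites = 5, n_events = 2, habitats = "water",
    n_crt = 0, depth = 10000))
  asm <- assembly_processes(sim$counts, sim$tree, ds = 0.3, min_size = 10,
                            n_null_z = 49, n_null_rc = 99, seed = 2)
  expect_equal(sum(asm$importance), 1, tolerance = 1e-9)
  expect_equal(unname(rowSums(asm$sample_importance)),
               rep(1, nrow(asm$sample_importance)), tolerance = 1e-9)
  expect_true(all(asm$pair_bin$process %in%
                    c("HoS", "HeS", "DL", "HD", "DR")))
  # determinism under a fixed seed
  asm2 <- assembly_processes(sim$counts, sim$tree, ds = 0.3, min_size = 10,
                             n_null_z = 49, n_null_rc = 99, seed = 2)
  expect_identical(asm$pair_bin, asm2$pair_bin)
})
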