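test_that("alpha diversity matches closed-form hand calculations", {
  # sample with S_obs = 10, f1 = 4, f2 = 2 -> Chao1 = 10 + 4*3/(2*3) = 12
  x <- c(rep(1L, 4), rep(2L, 2), 5L, 9L, 13L, 20L)
  cm <- matrix(x, ncol = 1, dimnames = list(paste0("t", 1:10), "s1"))
  a <- alpha_diversity(cm)
  expect_equal(a$richness, 10)
  expect_equal(a$chao1, 12)
  p <- x / sum(x)
  expect_equal(a$shannon, -sum(p * log(p)), tolerance = 1e-12)
  # no singletons -> Chao1 = S_obs; equal abundances -> Shannon = ln k
  cm2 <- matrix(rep(5L, 8), ncol = 1, dimnames = list(paste0("t", 1:8), "s"))
  a2 <- alpha_diversity(cm2)
  expect_equal(a2$chao1, 8)
  expect_equal(a2$shannon, log(8), tolerance = 1e-12)
  # empty sample -> NA record
  cm3 <- cbind(cm2, empty = rep(0L, 8))
  expect_true(is.na(alpha_diversity(cm3)$chao1[2]))
  # five fixed toys against independent arithmetic
  set.seed(30)
  for (k in 1:5) {
    v <- as.integer(rpois(20, 3))
    cmk <- matrix(v, ncol = 1, dimnames = list(paste0("t", 1:20), "s"))
    if (sum(v) == 0) next
    ak <- alpha_diversity(cmk)
    sobs <- sum(v > 0); f1 <- sum(v == 1); f2 <- sum(v == 2)
    expect_equal(ak$chao1, sobs + f1 * (f1 - 1) / (2 * (f2 + 1)),
                 tolerance = 1e-12)
    pk <- v[v > 0] / sum(v)
    expect_equal(ak$shannon, -sum(pk * log(pk)), tolerance = 1e-12)
    expect_gte(ak$chao1, ak$richness)
  }
})

test_that("group tests handle identity, degeneracy and planted shifts", {
  expect_message(expect_null(group_test(1:4, c("a", "a", "b", "b"))),
                 "degenerate")
  x <- c(rnorm(10), rnorm(10))
  g <- rep(c("a", "b"), each = 10)
  same <- group_test(rep(1:10, 2), g, "wilcoxon")
  expect_equal(same$pairwise$p, 1, tolerance = 1e-9)
  set.seed(31)
  hits <- vapply(1:40, function(k) {
    v <- c(rnorm(20), rnorm(20, 2))
    gt <- group_test(v, g <- rep(c("a", "b"), each = 20), "wilcoxon")
    gt$pairwise$p_adj < 0.05
  }, TRUE)
  expect_gt(mean(hits), 0.95)
  # Kruskal-Wallis + Dunn: omnibus agrees with stats::kruskal.test
  set.seed(32)
  v3 <- c(rnorm(12), rnorm(12, 1.5), rnorm(12, 3))
  g3 <- rep(letters[1:3], each = 12)
  kt <- group_test(v3, g3, "kruskal_dunn_bonferroni")
  expect_equal(kt$omnibus$p, kruskal.test(v3, factor(g3))$p.value)
  expect_equal(nrow(kt$pairwise), 3)
  expect_true(all(kt$pairwise$p <= 1))
  expect_lt(kt$pairwise$p[kt$pairwise$group_1 == "a" &
                            kt$pairwise$group_2 == "c"], 0.05)
})

test_that("ANOSIM matches vegan and hand-rank arithmetic", {
  set.seed(33)
  x <- rbind(matrix(rnorm(30, 0), 3), matrix(rnorm(30, 3), 3))
  d <- dist(x)
  g <- rep(c("a", "b"), each = 3)
  res <- anosim_test(d, g, n_perm = 199, seed = 7)
  veg <- vegan::anosim(d, g, permutations = 19)
  expect_equal(res$R, unname(veg$statistic), tolerance = 1e-9)
  # perfectly separated groups -> R = 1
  dm <- matrix(0, 4, 4)
  dm[1:2, 3:4] <- 10; dm[3:4, 1:2] <- 10
  dm[1, 2] <- dm[2, 1] <- 1; dm[3, 4] <- dm[4, 3] <- 1
  expect_equal(anosim_test(dm, c("a", "a", "b", "b"), n_perm = 99)$R, 1)
  # hand-rank oracle on a 6-sample toy
  set.seed(34)
  toy <- as.matrix(dist(matrix(rnorm(12), 6)))
  gt <- rep(c("u", "v"), each = 3)
  up <- upper.tri(toy)
  rk <- rank(toy[up])
  within <- outer(gt, gt, "==")[up]
  rhand <- (mean(rk[!within]) - mean(rk[within])) / (6 * 5 / 4)
  expect_equal(anosim_test(toy, gt, n_perm = 9)$R, rhand, tolerance = 1e-12)
  expect_error(anosim_test(toy, c("a", rep("b", 5))), "size 1")
  # null labels give mean R near 0
  set.seed(35)
  rs <- vapply(1:100, function(k)
    anosim_test(toy, sample(gt), n_perm = 9, seed = k)$R, 0)
  expect_lt(abs(mean(rs)), 0.1)
})

test_that("Spearman tables flag monotone relationships with tie handling", {
  ra <- rbind(up = (1:10) / 100, down = (10:1) / 100,
              tied = c(1, 1, 2, 2, 3, 3, 4, 4, 5, 5) / 100)
  colnames(ra) <- paste0("s", 1:10)
  meta <- data.frame(pH = 1:10, row.names = colnames(ra))
  tab <- spearman_env(ra, meta, "pH")
  expect_equal(tab$rho[tab$asv_id == "up"], 1)
  expect_equal(tab$rho[tab$asv_id == "down"], -1)
  ct <- suppressWarnings(cor.test(ra["tied", ], meta$pH,
                                  method = "spearman", exact = FALSE))
  expect_equal(tab$rho[tab$asv_id == "tied"], unname(ct$estimate))
  expect_equal(tab$stars[tab$asv_id == "up"], "**")
})

test_that("co-occurrence network recovers planted trios, is threshold-monotone", {
  set.seed(36)
  n <- 30
  driver <- rlnorm(n, 0, 1)
  trio <- t(vapply(1:3, function(k) driver * rlnorm(n, 0, 0.1), numeric(n)))
  noise <- matrix(rlnorm(20 * n), 20, n)
  ra <- rbind(trio, noise)
  rownames(ra) <- c(paste0("p", 1:3), paste0("n", 1:20))
  colnames(ra) <- paste0("s", 1:n)
  ra <- sweep(ra, 2, colSums(ra), "/")
  edges <- cooccurrence_network(ra)
  planted <- paste0("p", 1:3)
  got <- sum(edges$asv_1 %in% planted & edges$asv_2 %in% planted)
  expect_equal(got, 3)
  expect_lte(nrow(edges) - got, 2)
  # stricter thresholds give an edge subset
  loose <- cooccurrence_network(ra, rho_min = 0.5, p_adj_max = 0.05)
  strict <- cooccurrence_network(ra, rho_min = 0.7, p_adj_max = 0.01)
  key <- function(e) paste(e$asv_1, e$asv_2)
  expect_true(all(key(strict) %in% key(loose)))
  expect_error(cooccurrence_network(ra[, 1:5]), ">= 10")
})

test_that("Mantel association detects constructed signal and respects nulls", {
  set.seed(37)
  sim <- small_sim(seed = 101)
  ra <- to_relative(sim$counts)
  res <- env_community_dissim(ra, sim$meta, n_perm = 199, seed = 5)
  # simulated communities track the pH-anchored environment by construction
  expect_gt(res$statistic, 0)
  expect_lt(res$p, 0.05)
})
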