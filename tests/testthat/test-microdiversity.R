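test_that("greedy clustering merges identical and splits divergent sequences", {
  seqs <- c(a = strrep("ACGT", 100), b = strrep("ACGT", 100))
  cm <- matrix(c(10L, 5L, 3L, 2L), 2, 2,
               dimnames = list(c("a", "b"), c("s1", "s2")))
  otus <- cluster_otus(seqs, cm)
  expect_equal(nrow(otus), 1L)
  expect_equal(otus$centroid, "a")      # higher total abundance wins
  expect_equal(otus$n_members, 2L)

  set.seed(1)
  s1 <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  v <- strsplit(s1, "")[[1]]
  pos <- sample(400, 40)                 # 10% divergent
  for (i in pos) v[i] <- setdiff(c("A", "C", "G", "T"), v[i])[1]
  seqs2 <- c(a = s1, b = paste(v, collapse = ""))
  otus2 <- cluster_otus(seqs2, cm)
  expect_equal(nrow(otus2), 2L)

  expect_error(cluster_otus(seqs[1], cm), "missing sequence")
})

test_that("clustering recovers the planted lineage count", {
  sim <- small_sim(seed = 31)
  otus <- cluster_otus(sim$sequences, sim$counts)
  expect_equal(nrow(otus), sim$config$n_lineages)
  # membership maps every ASV to the OTU of its planted lineage
  memb <- attr(otus, "membership")
  lin <- sim$truth$taxa$lineage[match(names(memb), sim$truth$taxa$asv_id)]
  expect_equal(length(unique(paste(memb, lin))), sim$config$n_lineages)
})

test_that("rarefaction subsamples to the exact depth with correct expectation", {
  m <- matrix(c(6000L, 3000L, 2000L, 1000L), 2, 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  r <- rarefy_otu(m, depth = 5000, seed = 1)
  expect_equal(sum(r), 5000)
  expect_equal(dim(r), dim(m))
  expect_true(all(r <= m))
  expect_message(out <- rarefy_otu(matrix(c(3000L, 1999L), 2, 1,
                                          dimnames = list(c("a", "b"), "s")),
                                   depth = 5000),
                 "excluded")
  expect_null(out)

  # hypergeometric expectation: mean share over seeds matches original share
  shares <- t(vapply(1:200, function(s)
    rowSums(rarefy_otu(m, 5000, seed = s)) / 5000, numeric(2)))
  expect_equal(unname(colMeans(shares)),
               unname(rowSums(m) / sum(m)), tolerance = 0.02)
})

test_that("effective microdiversity equals exp(Shannon) of member totals", {
  uni <- matrix(rep(1250L, 4), 4, 1,
                dimnames = list(paste0("m", 1:4), "s"))
  expect_equal(effective_microdiversity(uni), 4)
  single <- matrix(5000L, 1, 1, dimnames = list("m", "s"))
  expect_equal(effective_microdiversity(single), 1)
  skew <- matrix(c(2500L, 1250L, 625L, 625L), 4, 1,
                 dimnames = list(paste0("m", 1:4), "s"))
  p <- c(0.5, 0.25, 0.125, 0.125)
  expect_equal(effective_microdiversity(skew), exp(-sum(p * log(p))))
  expect_equal(effective_microdiversity(skew), 3.3636, tolerance = 1e-4)
  # invariant to member relabeling and sample order
  m <- matrix(c(10L, 40L, 25L, 25L), 2, 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_equal(effective_microdiversity(m),
               effective_microdiversity(m[2:1, 2:1]))
})

test_that("persistence and variability follow their definitions", {
  m <- matrix(c(10L, 0L, 10L, 0L), 1, 4,
              dimnames = list("a", paste0("s", 1:4)))
  pv <- persistence_and_variability(m)
  expect_equal(pv[["persistence"]], 0.5)
  expect_equal(pv[["variability"]], sd(c(10, 0, 10, 0)) / 5)
  eq <- matrix(rep(5L, 4), 1, 4, dimnames = list("a", paste0("s", 1:4)))
  expect_equal(persistence_and_variability(eq)[["variability"]], 0)
  zero <- matrix(0L, 1, 3, dimnames = list("a", paste0("s", 1:3)))
  expect_true(is.na(persistence_and_variability(zero)[["variability"]]))
})

test_that("planted within-OTU richness is recovered by effective microdiversity", {
  cfg <- sim_config(seed = 41, n_lineages = 16,
                    lineage_sizes = rep(c(1L, 2L, 4L, 8L), 4),
                    n_crt = 0, equal_members = TRUE, microdiv_link = TRUE,
                    n_samples = 24, n_sites = 4, n_events = 3, depth = 20000)
  sim <- simulate_community(cfg)
  mdp <- microdiversity_profile(sim$counts, sim$sequences, depth = 5000,
                                seed = 9)
  k <- table(sim$truth$taxa$lineage)
  mdp$true_k <- as.integer(k[as.character(
    sim$truth$taxa$lineage[match(mdp$centroid, sim$truth$taxa$asv_id)])])
  med <- tapply(mdp$effective_microdiversity, mdp$true_k, median)
  for (kk in names(med))
    expect_lt(abs(med[[kk]] - as.numeric(kk)) / as.numeric(kk), 0.15)
  expect_true(all(mdp$effective_microdiversity <= mdp$n_members))
})

test_that("group comparison is null-safe and detects planted persistence gaps", {
  few <- data.frame(microdiv_class = c("high", "low"),
                    persistence = c(1, 0.5), variability = c(0.2, 0.4))
  expect_message(expect_null(compare_microdiv_groups(few)), "degenerate")

  cfg <- sim_config(seed = 43, n_lineages = 24,
                    lineage_sizes = rep(c(1L, 1L, 4L, 8L), 6),
                    microdiv_link = TRUE, n_crt = 0, equal_members = TRUE,
                    n_samples = 40, n_sites = 10, n_events = 2,
                    depth = 30000)
  sim <- simulate_community(cfg)
  mdp <- microdiversity_profile(sim$counts, sim$sequences, seed = 3)
  res <- compare_microdiv_groups(mdp)
  pers <- res[res$response == "persistence", ]
  expect_lt(pers$p_adj, 0.05)
  expect_gt(pers$median_high, pers$median_low)
})

test_that("rarefaction is reproducible under a fixed seed", {
  m <- matrix(as.integer(rpois(20, 600)), 4, 5,
              dimnames = list(paste0("m", 1:4), paste0("s", 1:5)))
  expect_identical(rarefy_otu(m, 2000, seed = 77),
                   rarefy_otu(m, 2000, seed = 77))
})
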