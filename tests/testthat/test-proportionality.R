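test_that("per-genus preprocessing applies the five filters in order", {
  n <- 100
  cm <- rbind(
    keep1 = c(rep(10L, 50), rep(0L, 50)) + rep(c(0L, 5L), 50),
    keep2 = rep(c(3L, 9L, 27L, 1L), 25),
    allzero = rep(0L, n),
    sparse = c(rep(1L, 2), rep(0L, n - 2)),      # present in 2 of 100
    constant = rep(7L, n))                        # CV = 0
  colnames(cm) <- paste0("s", seq_len(n))
  tax <- data.frame(asv_id = rownames(cm), genus = "G")
  filt <- preprocess_genus(cm, tax, "G")
  expect_setequal(rownames(filt), c("keep1", "keep2"))
  # pseudocount of exactly 1 added to every surviving cell
  expect_equal(unname(filt["keep2", 1:4]), c(3, 9, 27, 1) + 1)
  # too little left -> NULL with message
  small <- cm[c("allzero", "sparse"), ]
  expect_message(expect_null(preprocess_genus(small, tax, "G")), "skipped")
})

test_that("rho matches the brute-force variance formula on random instances", {
  set.seed(8)
  for (k in 1:100) {
    nr <- sample(3:6, 1); nc <- sample(4:12, 1)
    filt <- matrix(rpois(nr * nc, 30) + 1, nr, nc,
                   dimnames = list(paste0("a", 1:nr), paste0("s", 1:nc)))
    expect_equal(rho_matrix(filt), rho_brute(filt), tolerance = 1e-9)
  }
  # identical rows are perfectly proportional; matrix symmetric, diag 1
  filt <- matrix(rpois(40, 20) + 1, 4, 10,
                 dimnames = list(paste0("a", 1:4), paste0("s", 1:10)))
  filt[2, ] <- filt[1, ]
  r <- rho_matrix(filt)
  expect_equal(r[1, 2], 1)
  expect_equal(r, t(r))
  expect_equal(unname(diag(r)), rep(1, 4))
})

test_that("rho on raw positive data is invariant to per-sample scaling", {
  set.seed(9)
  x <- matrix(runif(50, 1, 100), 5, 10,
              dimnames = list(paste0("a", 1:5), paste0("s", 1:10)))
  sc <- sweep(x, 2L, runif(10, 0.5, 5), "*")
  expect_equal(rho_matrix(x), rho_matrix(sc), tolerance = 1e-9)
})

test_that("permutation FDR calibration flags planted signal, controls null", {
  set.seed(10)
  # planted proportional pair among noise
  base <- rlnorm(12, 3, 1)
  noise <- matrix(rpois(10 * 12, 50), 10, 12)
  pairx <- rpois(12, 300 * base / mean(base))
  pairy <- rpois(12, 600 * base / mean(base))
  filt <- rbind(noise, px = pairx, py = pairy) + 1
  rownames(filt) <- c(paste0("n", 1:10), "px", "py")
  colnames(filt) <- paste0("s", 1:12)
  cal <- calibrate_fdr_cutoff(filt, n_perm = 100, seed = 4)
  expect_true(is.finite(cal$cutoff))
  expect_true(cal$significant["px", "py"])
  expect_error(calibrate_fdr_cutoff(filt, n_perm = 0), "n_perm")

  # pure noise: few significant pairs
  nullm <- matrix(rpois(10 * 20, 50), 10, 20,
                  dimnames = list(paste0("n", 1:10), paste0("s", 1:20))) + 1
  caln <- calibrate_fdr_cutoff(nullm, n_perm = 100, seed = 5)
  expect_lte(sum(caln$significant) / 2, 3)
})

test_that("pairwise divergence counts substitutions and internal gaps", {
  s <- paste(rep("ACGT", 103), collapse = "")
  s <- substr(s, 1, 412)
  seqs <- c(a = s, b = s)
  expect_equal(pairwise_divergence(seqs)$divergence, 0L)
  v <- strsplit(s, "")[[1]]
  v[100] <- setdiff(c("A", "C", "G", "T"), v[100])[1]
  seqs2 <- c(a = s, b = paste(v, collapse = ""))
  expect_equal(pairwise_divergence(seqs2)$divergence, 1L)
  # 2-nt internal insertion plus 1 substitution -> 3
  v3 <- strsplit(s, "")[[1]]
  v3[50] <- setdiff(c("A", "C", "G", "T"), v3[50])[1]
  with_ins <- paste(c(v3[1:200], "G", "G", v3[201:412]), collapse = "")
  seqs3 <- c(a = s, b = with_ins)
  expect_equal(pairwise_divergence(seqs3)$divergence, 3L)
  expect_error(pairwise_divergence(seqs3, c("a", "zz")), "missing")
})

test_that("divergence behaves as a metric on planted sequence sets", {
  sim <- small_sim(seed = 51)
  ids <- sample(names(sim$sequences), 12)
  dv <- pairwise_divergence(sim$sequences, ids)
  key <- function(i, j) which((dv$asv_1 == i & dv$asv_2 == j) |
                                (dv$asv_1 == j & dv$asv_2 == i))
  set.seed(6)
  for (k in 1:100) {
    tri <- sample(ids, 3)
    dij <- dv$divergence[key(tri[1], tri[2])]
    dik <- dv$divergence[key(tri[1], tri[3])]
    djk <- dv$divergence[key(tri[2], tri[3])]
    expect_lte(dij, dik + djk)
  }
})

test_that("genus selection applies the linkage-component rule", {
  set.seed(12)
  base <- paste(sample(c("A", "C", "G", "T"), 412, TRUE), collapse = "")
  mut <- function(s, pos) {
    v <- strsplit(s, "")[[1]]
    for (i in pos) v[i] <- setdiff(c("A", "C", "G", "T"), v[i])[1]
    paste(v, collapse = "")
  }
  # component of 12 within 5 nt
  seqs <- setNames(c(base, vapply(1:11, function(i) mut(base, i), "")),
                   paste0("a", 1:12))
  # a second, far-away component of 6
  base2 <- mut(base, 1:60)
  seqs2 <- setNames(c(base2, vapply(1:5, function(i) mut(base2, 100 + i), "")),
                    paste0("b", 1:6))
  tax <- data.frame(asv_id = c(names(seqs), names(seqs2)),
                    genus = rep(c("Gbig", "Gsmall"), c(12, 6)))
  sel <- select_genera(c(seqs, seqs2), tax, min_asvs = 10, max_div = 5)
  expect_named(sel, "Gbig")
  expect_setequal(sel$Gbig, names(seqs))
  # two 6-member components in one genus do not qualify
  tax2 <- data.frame(asv_id = c(names(seqs)[1:6], names(seqs2)),
                     genus = "Gsplit")
  sel2 <- select_genera(c(seqs[1:6], seqs2), tax2, min_asvs = 10,
                        max_div = 5)
  expect_length(sel2, 0)
})

test_that("rho-divergence OLS recovers an exact linear relationship", {
  rho <- matrix(NA_real_, 6, 6, dimnames = list(paste0("a", 1:6),
                                                paste0("a", 1:6)))
  dv <- expand.grid(i = 1:6, j = 1:6)
  dv <- dv[dv$i < dv$j, ]
  div <- abs(dv$i - dv$j)
  for (k in seq_len(nrow(dv))) {
    r <- 1 - 0.1 * div[k]
    rho[dv$i[k], dv$j[k]] <- r
    rho[dv$j[k], dv$i[k]] <- r
  }
  diag(rho) <- 1
  dd <- data.frame(asv_1 = paste0("a", dv$i), asv_2 = paste0("a", dv$j),
                   divergence = div)
  fit <- fit_rho_vs_divergence(rho, dd)
  expect_equal(fit$slope, -0.1, tolerance = 1e-9)
  expect_lt(fit$p, 1e-12)
  # zero divergence variance -> skipped
  dd0 <- dd; dd0$divergence <- 3L
  expect_message(expect_null(fit_rho_vs_divergence(rho, dd0)), "skipped")
})

test_that("niche centroids are abundance-weighted env means", {
  cm <- matrix(c(10L, 0L, 5L, 5L), 2, 2, byrow = TRUE,
               dimnames = list(c("a", "b"), c("s1", "s2")))
  meta <- data.frame(pH = c(2, 6), Fe = c(100, 1),
                     row.names = c("s1", "s2"))
  ctr <- niche_centroids(cm, meta, c("pH", "Fe"))
  E <- scale(log1p(as.matrix(meta)))
  expect_equal(unname(ctr["a", ]), unname(E[1, ]))        # all weight on s1
  expect_equal(unname(ctr["b", ]), unname(colMeans(E)))   # equal weights
  # identical abundance profiles -> zero env distance
  cm2 <- rbind(a = c(3L, 7L), b = c(3L, 7L))
  colnames(cm2) <- c("s1", "s2")
  ctr2 <- niche_centroids(cm2, meta, c("pH", "Fe"))
  expect_equal(unname(dist(ctr2)[1]), 0)
  expect_message(niche_centroids(cm, meta, c("pH", "Zn")), "Zn")
})
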