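test_that("preprocessing re-wraps dihedrals about the circular mean", {
  fs <- feature_set("dihedral", rbind(c(1, 2, 3, 4)))
  fm <- feature_matrix(matrix(c(179, -179), 2, 1), fs)
  prep <- ic_preprocess(fm)
  expect_equal(as.vector(prep$centered), c(-1, 1))
  expect_equal(stats::var(prep$centered[, 1]), 2)  # n-1 denominator

  # already-centred bond column unchanged; constant column becomes zero
  fsb <- feature_set("bond", rbind(c(1, 2), c(2, 3)))
  vals <- cbind(c(-1, 0, 1), c(5, 5, 5))
  prep2 <- ic_preprocess(feature_matrix(vals, fsb))
  expect_equal(prep2$centered[, 1], c(-1, 0, 1))
  expect_equal(prep2$centered[, 2], c(0, 0, 0))
})

test_that("masked cells are imputed and fully-masked columns error", {
  fs <- feature_set("dihedral", rbind(c(1, 2, 3, 4), c(2, 3, 4, 5)))
  vals <- cbind(c(10, NA, 20), c(NA, NA, NA))
  expect_error(ic_preprocess(feature_matrix(vals, fs)), "degenerate")
  vals2 <- cbind(c(10, NA, 20), c(0, 10, 20))
  prep <- ic_preprocess(feature_matrix(vals2, fs))
  expect_false(anyNA(prep$centered))
  expect_equal(sum(prep$imputed), 1L)
})

test_that("covariance eigendecomposition recovers known spectra", {
  # two orthogonal columns with sample variances 4 and 1
  c1 <- c(-1, -1, 1, 1) * sqrt(3)
  c2 <- c(-1, 1, 1, -1) * sqrt(3) / 2
  dec <- ic_pca(cbind(c1, c2))
  expect_equal(dec$eigenvalues, c(4, 1))
  expect_equal(dec$total_variance, 5)

  # duplicated column pair: one zero eigenvalue in the 2-subspace
  dup <- cbind(c1, c1)
  dec2 <- ic_pca(dup)
  expect_equal(dec2$eigenvalues[2], 0, tolerance = 1e-12)

  expect_error(ic_pca(matrix(1, 1, 3)), "2 frames")
})

test_that("reconstruction from all PCs reproduces the covariance", {
  set.seed(21)
  x <- matrix(rnorm(60), 12, 5)
  x <- sweep(x, 2, colMeans(x))
  dec <- ic_pca(x)
  cv <- stats::cov(x)
  rebuilt <- dec$loadings %*% diag(dec$eigenvalues) %*% t(dec$loadings)
  expect_lt(max(abs(rebuilt - cv)), 1e-8)
  expect_lt(abs(sum(dec$eigenvalues) - sum(diag(cv))) /
              sum(diag(cv)), 1e-8)
  gram <- t(dec$loadings) %*% dec$loadings
  expect_lt(max(abs(gram - diag(5))), 1e-8)
})

test_that("PC subset selection takes the smallest 90% prefix", {
  expect_equal(select_pcs(c(8, 1, 1)), 1:2)
  expect_equal(select_pcs(c(95, 5)), 1L)
  expect_equal(select_pcs(rep(1, 10)), 1:9)  # 0.9 reached exactly at 9
  expect_equal(select_pcs(c(8, 1, 1), threshold = 1), 1:3)
  expect_error(select_pcs(c(0, 0)), "no variance")
  expect_error(select_pcs(c(1, 1), threshold = 0), "threshold")
})

test_that("eigenvalue-weighted scores and top sets follow the definition", {
  load <- matrix(c(0.8, 0.6), 2, 1)
  rk <- score_rank(5, load, 1L, fraction = 0.5)
  expect_equal(rk$scores, c(4.0, 3.0))
  expect_equal(rk$order, c(1L, 2L))
  expect_equal(rk$top, 1L)
  expect_equal(score_rank(5, load, 1L, fraction = 1)$top_size, 2L)
  expect_error(score_rank(5, load, 1L, fraction = 0), "fraction")
  # ceil rule: 77 features at 10% -> 8
  expect_equal(ceiling(0.10 * 77), 8)
})

test_that("scores ignore loading signs and commute with permutations", {
  set.seed(33)
  for (rep in 1:5) {
    x <- matrix(rnorm(20 * 6), 20, 6)
    x <- sweep(x, 2, colMeans(x))
    dec <- ic_pca(x)
    pcs <- select_pcs(dec$eigenvalues)
    rk <- score_rank(dec$eigenvalues, dec$loadings, pcs)
    flip <- dec$loadings %*% diag(sample(c(-1, 1), 6, replace = TRUE))
    rk_flip <- score_rank(dec$eigenvalues, flip, pcs)
    expect_equal(rk_flip$scores, rk$scores)

    perm <- sample(6)
    xp <- x[, perm]
    rk_p <- score_rank(ic_pca(xp)$eigenvalues, ic_pca(xp)$loadings, pcs)
    expect_equal(rk_p$scores, rk$scores[perm], tolerance = 1e-8)
  }
})

test_that("full ranking matches the SVD-route oracle", {
  set.seed(55)
  for (rep in 1:6) {
    nfeat <- sample(3:6, 1)
    fs <- feature_set("bond", cbind(seq_len(nfeat), seq_len(nfeat) + 1L))
    vals <- matrix(rnorm(15 * nfeat, sd = rep(runif(nfeat, 0.5, 3),
                                              each = 15)), 15, nfeat)
    fm <- feature_matrix(vals, fs)
    rk <- pca_rank(fm)
    oracle <- svd_score_oracle(sweep(vals, 2, colMeans(vals)))
    expect_lt(max(abs(rk$scores - oracle$scores)) /
                max(abs(oracle$scores)), 1e-8)
    expect_equal(rk$top, oracle$top)
    expect_equal(rk$pcs, oracle$pcs)
  }
})

test_that("overlap reports count multiplicities across ensembles", {
  fs <- feature_set("bond", cbind(1:10, 2:11))
  mk <- function(top) {
    scores <- rep(0, 10); scores[top] <- 10 - seq_along(top)
    structure(list(scores = scores, top = sort(top),
                   top_size = length(top), features = fs),
              class = "pca_ranking")
  }
  ov <- compare_rankings(list(a = mk(c(1, 2)), b = mk(c(2, 3))))
  expect_equal(ov$multiplicity[2], 2)
  expect_equal(ov$multiplicity[c(1, 3)], c(1, 1))
  expect_equal(ov$summary, c(2L, 1L))
  ov2 <- compare_rankings(list(a = mk(c(4, 5)), b = mk(c(4, 5))))
  expect_equal(ov2$summary, c(0L, 2L))
  expect_error(compare_rankings(list(mk(1), mk(2))), "named")
})

test_that("random top sets overlap at the hypergeometric rate", {
  n <- 259; k <- ceiling(0.10 * n); m <- 4
  p <- k / n
  expected <- n * (1 - (1 - p)^m - m * p * (1 - p)^(m - 1))
  set.seed(77)
  observed <- replicate(15, {
    rks <- lapply(1:m, function(i) {
      fm <- generate_feature_matrix(n_frames = 40, n_features = n,
                                    hot = integer(0), kind = "bond",
                                    seed = sample.int(1e6, 1))
      pca_rank(fm)
    })
    names(rks) <- paste0("ff", 1:m)
    sum(compare_rankings(rks)$multiplicity >= 2)
  })
  mc <- replicate(400, {
    draws <- replicate(m, sample.int(n, k))
    sum(table(draws) >= 2)
  })
  # observed mean within Monte-Carlo error of the null expectation
  expect_lt(abs(mean(observed) - expected), 4 * sd(mc) / sqrt(15) +
              4 * sd(observed) / sqrt(15) + 1)
  expect_lt(abs(mean(mc) - expected), 4 * sd(mc) / sqrt(400) + 0.5)
})
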