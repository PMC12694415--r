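# Frozen rank placements: rank_placement_matrix(p) holds value p - i + 1 at
# gene i, so gene g0k has descending rank k and ascending rank p - k + 1.

test_that("scSE scores are count fractions (sum) or per-gene fractions (mean)", {
  X <- matrix(c(15, 5, 80), 3,
              dimnames = list(c("g1", "g2", "g3"), "s1"))
  sets <- list(A = c("g1", "g2"), ALL = c("g1", "g2", "g3"))
  expect_equal(replaid_scse(X, sets)["A", "s1"], 0.2)
  expect_equal(replaid_scse(X, sets)["ALL", "s1"], 1)  # conservation
  expect_equal(replaid_scse(X, sets, "mean")["A", "s1"], 0.1)

  X0 <- cbind(X, s2 = c(0, 0, 0))
  expect_error(replaid_scse(X0, sets), "zero total count.*s2")
  expect_error(replaid_scse(-X, sets), "nonnegative")

  # random counts vs loop oracle; totals use all genes, not just shared ones
  Xc <- as.matrix(simulate_counts(150, 12, zero_fraction = 0.7, seed = 31))
  rs <- random_collection(15, rownames(Xc)[1:100], c(4, 20), seed = 32)
  expect_equal(replaid_scse(Xc, rs), oracle_scse(Xc, rs), tolerance = 1e-12)
  expect_equal(replaid_scse(Xc, rs, "mean"), oracle_scse(Xc, rs, "mean"),
               tolerance = 1e-12)
})

test_that("singscore maps mean member rank onto [0, 1]", {
  X <- rank_placement_matrix(5)  # ascending rank of g0k is 6 - k
  expect_equal(replaid_sing(X, list(S = c("g01", "g02")))["S", "s1"], 1)
  expect_equal(replaid_sing(X, list(S = c("g04", "g05")))["S", "s1"], 0)
  expect_equal(replaid_sing(X, list(S = c("g02", "g04")))["S", "s1"], 0.5)
  expect_error(replaid_sing(X, list(S = rownames(X))), "whole shared feature")

  Xg <- dense_gaussian_matrix(120, 9, seed = 33)
  sets <- random_collection(14, rownames(Xg), c(4, 30), seed = 34)
  expect_equal(replaid_sing(Xg, sets), oracle_sing(Xg, sets),
               tolerance = 1e-12)
})

test_that("UCell scoring matches the clipped Mann-Whitney statistic", {
  X <- rank_placement_matrix(10)
  # members at the two best descending ranks: U = 0, score 1
  expect_equal(replaid_ucell(X, list(S = c("g01", "g02")), rmax = 10)["S", 1],
               1)
  # members at descending ranks 3 and 5 with rmax = 10: score 0.75
  expect_equal(replaid_ucell(X, list(S = c("g03", "g05")), rmax = 10)["S", 1],
               0.75)
  # all members beyond rmax: clipped score (s - 1) / (2 rmax)
  expect_equal(replaid_ucell(X, list(S = c("g09", "g10")), rmax = 5)["S", 1],
               (2 - 1) / (2 * 5))
  expect_error(replaid_ucell(X, list(S = paste0("g0", 1:6)), rmax = 3),
               "rmax")

  Xg <- dense_gaussian_matrix(200, 10, seed = 35)
  sets <- random_collection(12, rownames(Xg), c(4, 25), seed = 36)
  expect_equal(replaid_ucell(Xg, sets, rmax = 80),
               oracle_ucell(Xg, sets, rmax = 80), tolerance = 1e-12)
})

test_that("AUCell scoring equals the step recovery-curve area", {
  X <- rank_placement_matrix(10)
  # members at descending ranks 1, 3, 7 with k = 5: area 8 of max 12
  S <- replaid_aucell(X, list(S = c("g01", "g03", "g07")), auc_max_frac = 0.5)
  expect_equal(S["S", 1], 8 / 12)
  # all members within the top |S| ranks -> 1; none within top k -> 0
  expect_equal(replaid_aucell(X, list(S = c("g01", "g02")), 0.5)["S", 1], 1)
  expect_equal(replaid_aucell(X, list(S = c("g09", "g10")), 0.5)["S", 1], 0)

  Xg <- dense_gaussian_matrix(200, 10, seed = 37)
  sets <- random_collection(12, rownames(Xg), c(4, 25), seed = 38)
  expect_equal(replaid_aucell(Xg, sets), oracle_aucell(Xg, sets),
               tolerance = 1e-12)
})

test_that("ssGSEA closed form equals the running-sum area exactly", {
  # p = 4, members at ascending ranks 3 and 4, alpha = 0.25
  X <- rank_placement_matrix(4)
  S <- replaid_ssgsea(X, list(S = c("g01", "g02")), alpha = 0.25)
  expect_equal(S["S", 1], 2.0179708, tolerance = 1e-6)
  expect_equal(S["S", 1],
               oracle_ssgsea_area(X, list(S = c("g01", "g02")))["S", 1],
               tolerance = 1e-12)

  # exhaustive identity and maximal placement for p <= 8
  for (p in 5:8) {
    X <- rank_placement_matrix(p)
    for (s in c(1, 2, 3)) {
      combos <- utils::combn(rownames(X), s, simplify = FALSE)
      es <- vapply(combos, function(mem) {
        sets <- list(S = mem)
        es1 <- replaid_ssgsea(X, sets)["S", 1]
        expect_equal(es1, oracle_ssgsea_area(X, sets)["S", 1],
                     tolerance = 1e-12)
        es1
      }, numeric(1))
      top <- which(vapply(combos, function(mem)
        setequal(mem, rownames(X)[seq_len(s)]), logical(1)))
      expect_equal(which.max(es), top)  # all members at top maximizes ES
    }
  }

  # random instances up to p = 500
  set.seed(39)
  for (k in 1:5) {
    p <- sample(50:500, 1)
    Xr <- matrix(rnorm(p), p, dimnames = list(sprintf("g%03d", 1:p), "s1"))
    sets <- list(S = sample(rownames(Xr), sample(5:40, 1)))
    expect_equal(replaid_ssgsea(Xr, sets)[1, 1],
                 oracle_ssgsea_area(Xr, sets)[1, 1], tolerance = 1e-12)
  }
  expect_error(replaid_ssgsea(rank_placement_matrix(3),
                              list(S = paste0("g0", 1:3))), "whole shared")
})

test_that("unweighted ssGSEA is centered at zero for random sets", {
  set.seed(40)
  p <- 100
  X <- matrix(rnorm(p), p, dimnames = list(sprintf("g%03d", 1:p), "s1"))
  es <- vapply(1:1000, function(i)
    replaid_ssgsea(X, list(S = sample(rownames(X), 10)), alpha = 0)[1, 1],
    numeric(1))
  expect_lt(abs(mean(es)), 0.02 * p)
})

test_that("GSVA-style scoring is symmetric and tracks the literal walk", {
  # duplicated sample columns give identical score columns
  set.seed(41)
  X <- matrix(rnorm(60), 20, 3,
              dimnames = list(sprintf("g%02d", 1:20), c("a", "b", "c")))
  X2 <- cbind(X, d = X[, "a"])
  sets <- list(S1 = rownames(X)[1:5], S2 = rownames(X)[8:15])
  S <- replaid_gsva(X2, sets, kcdf = "gaussian")
  expect_equal(S[, "a"], S[, "d"], tolerance = 1e-12)

  # zero-variance gene: flat 0.5 contribution with a warning
  Xz <- X
  Xz[1, ] <- 5
  expect_warning(replaid_gsva(Xz, sets), "zero-variance")

  expect_error(replaid_gsva(X[, 1:2], sets), "at least 3 samples")

  # concordance with the brute-force max-deviation walk (small instance;
  # the per-sample bound at full size is asserted in the acceptance suite)
  Xg <- dense_gaussian_matrix(50, 20, seed = 42)
  rs <- random_collection(10, rownames(Xg), c(4, 15), seed = 43)
  for (kcdf in c("gaussian", "ecdf")) {
    S1 <- replaid_gsva(Xg, rs, kcdf = kcdf)
    S2 <- oracle_gsva_walk(Xg, rs, kcdf = kcdf)
    sp <- vapply(seq_len(ncol(Xg)), function(j)
      cor(S1[, j], S2[, j], method = "spearman"), numeric(1))
    expect_gte(mean(sp), 0.7)
  }
})

test_that("scores stay in bounds and respond monotonically to member expression", {
  Xl <- log_transform(simulate_counts(150, 10, zero_fraction = 0.85,
                                      seed = 44))
  Xc <- simulate_counts(150, 10, zero_fraction = 0.85, seed = 44)
  sets <- random_collection(10, rownames(Xl), c(5, 20), seed = 45)

  expect_true(all(replaid_sing(Xl, sets) >= 0 & replaid_sing(Xl, sets) <= 1))
  expect_true(all(replaid_ucell(Xl, sets) >= 0 &
                  replaid_ucell(Xl, sets) <= 1))
  expect_true(all(replaid_aucell(Xl, sets) >= 0 &
                  replaid_aucell(Xl, sets) <= 1))
  Sscse <- replaid_scse(Xc, sets)
  expect_true(all(Sscse >= 0 & Sscse <= 1))

  # raising one member gene in one sample never lowers that sample's score
  mem <- sets[[1]][1]
  X2 <- as.matrix(Xl)
  X2[mem, 4] <- X2[mem, 4] + 3
  for (f in list(replaid_sing, replaid_ucell, replaid_aucell)) {
    expect_gte(f(X2, sets)[1, 4], f(as.matrix(Xl), sets)[1, 4])
  }
  Xc2 <- as.matrix(Xc)
  Xc2[mem, 4] <- Xc2[mem, 4] + 50
  expect_gte(replaid_scse(Xc2, sets)[1, 4],
             replaid_scse(as.matrix(Xc), sets)[1, 4])
})

test_that("massively tied sparse columns yield finite scores everywhere", {
  X <- Matrix::Matrix(0, 100, 4, sparse = TRUE,
                      dimnames = list(sprintf("g%03d", 1:100),
                                      paste0("s", 1:4)))
  X[1:5, ] <- 3  # 95% zeros, constant nonzeros
  sets <- list(A = rownames(X)[3:12], B = rownames(X)[50:60])
  for (S in list(replaid_sing(X, sets), replaid_ucell(X, sets),
                 replaid_aucell(X, sets), replaid_ssgsea(X, sets),
                 suppressWarnings(replaid_gsva(X, sets, kcdf = "ecdf")),
                 plaid(X, sets))) {
    expect_true(all(is.finite(S)))
  }
})

test_that("concordance_report computes per-sample and per-set correlations", {
  set.seed(46)
  S1 <- matrix(rnorm(40), 8, 5, dimnames = list(paste0("set", 1:8),
                                                paste0("s", 1:5)))
  S2 <- 2 * S1 + 1
  rep1 <- concordance_report(S1, S2)
  expect_equal(rep1$per_sample$pearson, rep(1, 5))   # affine invariance
  expect_equal(rep1$per_set$spearman, rep(1, 8))
  expect_equal(concordance_report(S1, -S1)$per_sample$pearson, rep(-1, 5))

  # row-centering is applied before correlating
  S3 <- S1 + matrix(rnorm(8, sd = 5), 8, 5)  # scrambled baselines
  cen <- concordance_report(S1, S3, center = TRUE)
  expect_equal(cen$per_sample$pearson,
               concordance_report(S1 - rowMeans(S1),
                                  S3 - rowMeans(S3))$per_sample$pearson)

  expect_error(concordance_report(S1, S2[, 1:3]), "different dimensions")
})

test_that("the method dispatcher exposes all eight scorers", {
  Xc <- simulate_counts(100, 8, zero_fraction = 0.8, seed = 47)
  Xl <- log_transform(Xc)
  sets <- random_collection(6, rownames(Xl), c(5, 15), seed = 48)
  for (m in c("plaid", "singscore", "ssgsea", "ucell", "aucell")) {
    S <- replaid(Xl, sets, method = m)
    expect_identical(dim(S), c(6L, 8L))
  }
  expect_identical(dim(replaid(Xc, sets, method = "scse")), c(6L, 8L))
  expect_identical(dim(replaid(Xc, sets, method = "scse.mean")), c(6L, 8L))
  expect_identical(dim(suppressWarnings(
    replaid(Xl, sets, method = "gsva", kcdf = "ecdf"))), c(6L, 8L))
  expect_error(replaid(Xl, sets, method = "nope"))
})
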