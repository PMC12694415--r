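# Independent brute-force reference implementations used as oracles.
# Deliberately naive: explicit per-set, per-sample loops over dense data,
# sharing no code with the package's cross-product back-end.

oracle_plaid <- function(X, sets, offset = 1e-8) {
  X <- as.matrix(X)
  S <- matrix(NA_real_, length(sets), ncol(X),
              dimnames = list(names(sets), colnames(X)))
  for (g in seq_along(sets)) {
    mem <- intersect(sets[[g]], rownames(X))
    s <- length(mem)
    for (j in seq_len(ncol(X)))
      S[g, j] <- mean(X[mem, j]) * s / (s + offset)
  }
  S
}

oracle_masked_plaid <- function(X, sets, offset = 1e-8) {
  S <- matrix(NA_real_, length(sets), ncol(X),
              dimnames = list(names(sets), colnames(X)))
  for (g in seq_along(sets)) {
    mem <- intersect(sets[[g]], rownames(X))
    for (j in seq_len(ncol(X))) {
      v <- X[mem, j]
      v <- v[!is.na(v)]
      S[g, j] <- sum(v) / (length(v) + offset)
    }
  }
  S
}

oracle_median_normalize <- function(S) {
  med <- vapply(seq_len(ncol(S)), function(j) stats::median(S[, j]),
                numeric(1))
  out <- S
  for (j in seq_len(ncol(S))) out[, j] <- S[, j] - med[j] + mean(med)
  out
}

# singscore: normalized mean member rank, mapped between the minimal and
# maximal achievable mean rank.
oracle_sing <- function(X, sets) {
  X <- as.matrix(X)
  p <- nrow(X)
  S <- matrix(NA_real_, length(sets), ncol(X),
              dimnames = list(names(sets), colnames(X)))
  for (j in seq_len(ncol(X))) {
    r <- rank(X[, j])
    for (g in seq_along(sets)) {
      mem <- intersect(sets[[g]], rownames(X))
      s <- length(mem)
      m <- mean(r[mem])
      mn <- (s + 1) / 2
      mx <- (2 * p - s + 1) / 2
      S[g, j] <- (m - mn) / (mx - mn)
    }
  }
  S
}

oracle_ucell <- function(X, sets, rmax = 1500) {
  X <- as.matrix(X)
  S <- matrix(NA_real_, length(sets), ncol(X),
              dimnames = list(names(sets), colnames(X)))
  for (j in seq_len(ncol(X))) {
    r <- rank(-X[, j])
    r[r > rmax] <- rmax + 1
    for (g in seq_along(sets)) {
      mem <- intersect(sets[[g]], rownames(X))
      s <- length(mem)
      U <- sum(r[mem]) - s * (s + 1) / 2
      S[g, j] <- min(1, max(0, 1 - U / (s * rmax)))
    }
  }
  S
}

# AUCell: explicit step recovery curve over the top-k thresholds (integer
# positions by descending expression; assumes untied data).
oracle_aucell <- function(X, sets, auc_max_frac = 0.05) {
  X <- as.matrix(X)
  p <- nrow(X)
  k <- ceiling(auc_max_frac * p)
  S <- matrix(NA_real_, length(sets), ncol(X),
              dimnames = list(names(sets), colnames(X)))
  for (j in seq_len(ncol(X))) {
    top <- rownames(X)[order(X[, j], decreasing = TRUE)][seq_len(k)]
    for (g in seq_along(sets)) {
      mem <- intersect(sets[[g]], rownames(X))
      hits <- cumsum(top %in% mem)
      maxhits <- cumsum(rep(1, k))
      maxhits[maxhits > length(mem)] <- length(mem)
      S[g, j] <- sum(hits) / sum(maxhits)
    }
  }
  S
}

oracle_scse <- function(X, sets, aggregate = "sum") {
  X <- as.matrix(X)
  S <- matrix(NA_real_, length(sets), ncol(X),
              dimnames = list(names(sets), colnames(X)))
  for (j in seq_len(ncol(X))) {
    tot <- sum(X[, j])
    for (g in seq_along(sets)) {
      mem <- intersect(sets[[g]], rownames(X))
      v <- sum(X[mem, j]) / tot
      S[g, j] <- if (aggregate == "mean") v / length(mem) else v
    }
  }
  S
}

# Weighted KS running sum for one sample; returns the full walk (length p),
# stepping through genes by decreasing value.
ssgsea_walk <- function(x, members, alpha = 0.25) {
  p <- length(x)
  a <- rank(x)
  ord <- order(a, decreasing = TRUE)
  inset <- names(x)[ord] %in% members
  w <- a[ord]^alpha
  w[!inset] <- 0
  Pin <- cumsum(w) / sum(w)
  Pout <- cumsum(!inset) / (p - sum(inset))
  Pin - Pout
}

# Area form of the ssGSEA statistic via the explicit walk.
oracle_ssgsea_area <- function(X, sets, alpha = 0.25) {
  X <- as.matrix(X)
  S <- matrix(NA_real_, length(sets), ncol(X),
              dimnames = list(names(sets), colnames(X)))
  for (j in seq_len(ncol(X))) {
    x <- X[, j]
    names(x) <- rownames(X)
    for (g in seq_along(sets)) {
      mem <- intersect(sets[[g]], rownames(X))
      S[g, j] <- sum(ssgsea_walk(x, mem, alpha))
    }
  }
  S
}

# Literal GSVA: kernel/empirical CDF stage, symmetric rank statistic, and
# the max-deviation random walk (signed maximum of |running sum|).
oracle_gsva_walk <- function(X, sets, tau = 1, kcdf = "gaussian") {
  X <- as.matrix(X)
  p <- nrow(X)
  n <- ncol(X)
  FF <- matrix(0, p, n, dimnames = dimnames(X))
  for (i in seq_len(p)) {
    x <- X[i, ]
    if (kcdf == "gaussian") {
      s <- stats::sd(x)
      FF[i, ] <- if (s == 0) 0.5
                 else rowMeans(stats::pnorm(outer(x, x, "-") / (s / 4)))
    } else {
      FF[i, ] <- vapply(x, function(v) mean(x <= v), numeric(1))
    }
  }
  S <- matrix(NA_real_, length(sets), n,
              dimnames = list(names(sets), colnames(X)))
  for (j in seq_len(n)) {
    rdesc <- rank(-FF[, j])
    z <- abs(p / 2 - rdesc)^tau
    ord <- order(FF[, j], decreasing = TRUE)
    for (g in seq_along(sets)) {
      inset <- rownames(X)[ord] %in% sets[[g]]
      w <- z[ord]
      w[!inset] <- 0
      run <- cumsum(w) / sum(w) - cumsum(!inset) / (p - sum(inset))
      S[g, j] <- run[which.max(abs(run))]
    }
  }
  S
}
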