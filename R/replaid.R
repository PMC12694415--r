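# Replication suite: six established single-sample scoring methods recast
# as per-gene transforms aggregated through the sparse cross-product
# back-end. Each method reduces to set-level sums of an elementwise
# transform of per-sample ranks (or raw counts for scSE), so a handful of
# cross-products replaces the per-set loops of the original tools. Where the
# original statistic is a running-walk extremum (ssGSEA, GSVA) the integral
# (area) form of the walk is used instead: the area is an exact per-gene sum
# and therefore cross-product computable; this is the documented source of
# approximation for those two methods.

.prep_sets <- function(X, genesets) {
  # the indicator is laid out over the expression feature space, so the
  # rank universe p is the shared feature set, not the union of members
  G <- if (is.list(genesets)) gmt2mat(genesets,
                                      feature_universe = rownames(X))
       else genesets
  pr <- intersect_features(X, G)
  list(X = pr$X, G = pr$G, s = Matrix::colSums(pr$G), p = nrow(pr$X))
}

.score_dimnames <- function(S, G, X) {
  dimnames(S) <- list(colnames(G), colnames(X))
  S
}

#' scSE-style signature scores
#'
#' Score of a set in a cell: the sum of raw counts over member genes divided
#' by the cell's total count over all genes of `X` (computed before feature
#' intersection). The `"mean"` variant divides additionally by the set size,
#' giving scores on the scale of a per-gene expression fraction; raw
#' fractions are emitted (no x100 rescaling).
#'
#' @param X Nonnegative count matrix (features x samples), sparse or dense.
#' @param genesets Collection (named list) or binary feature-by-set matrix.
#' @param aggregate `"sum"` (count fraction) or `"mean"` (fraction / set
#'   size).
#' @return Score matrix (sets x samples).
#' @export
replaid_scse <- function(X, genesets, aggregate = c("sum", "mean")) {
  aggregate <- match.arg(aggregate)
  neg <- if (methods::is(X, "sparseMatrix")) any(X@x < 0) else any(X < 0)
  if (neg) stop("scSE scoring requires nonnegative counts")
  tot <- Matrix::colSums(X)
  if (any(tot <= 0))
    stop("sample(s) with zero total count: ",
         paste(utils::head(colnames(X)[tot <= 0], 5L), collapse = ", "))
  pr <- .prep_sets(X, genesets)
  num <- as.matrix(Matrix::crossprod(pr$G, pr$X))
  S <- sweep(num, 2L, tot, "/")
  if (aggregate == "mean") S <- S / pr$s
  .score_dimnames(S, pr$G, pr$X)
}

#' singscore-style signature scores
#'
#' Per sample, genes are ranked ascending; the mean rank of the set members
#' is mapped onto \[0, 1\] between its theoretical minimum (members hold the
#' lowest ranks) and maximum (members hold the highest). The member rank sum
#' is a single cross-product.
#'
#' @inheritParams replaid_scse
#' @return Score matrix (sets x samples), values in \[0, 1\].
#' @export
replaid_sing <- function(X, genesets) {
  pr <- .prep_sets(X, genesets)
  s <- pr$s
  p <- pr$p
  if (any(s >= p))
    stop("gene set(s) spanning the whole shared feature universe ",
         "cannot be scored: ",
         paste(utils::head(colnames(pr$G)[s >= p], 5L), collapse = ", "))
  parts <- .rank_parts(pr$X, "ascending")
  m <- .agg_ranks(pr$G, parts) / s
  S <- (m - (s + 1) / 2) / (p - s)
  .score_dimnames(S, pr$G, pr$X)
}

#' UCell-style signature scores
#'
#' Mann-Whitney U scoring on clipped descending ranks: per sample, genes are
#' ranked descending, ranks beyond `rmax` are clipped to `rmax + 1`, the
#' member rank sum R gives U = R - s(s+1)/2, and the score is
#' 1 - U / (s * rmax), clamped to \[0, 1\]. Rank clipping caps the influence
#' of the massive tied block of zeros in sparse data.
#'
#' @inheritParams replaid_scse
#' @param rmax Rank ceiling (default 1500); must be at least the largest
#'   set size.
#' @return Score matrix (sets x samples), values in \[0, 1\].
#' @export
replaid_ucell <- function(X, genesets, rmax = 1500) {
  pr <- .prep_sets(X, genesets)
  s <- pr$s
  p <- pr$p
  if (rmax < max(s))
    stop("rmax (", rmax, ") is smaller than the largest gene set (",
         max(s), ")")
  parts <- .rank_parts(pr$X, "ascending")
  gclip <- function(r) pmin(p + 1 - r, rmax + 1)
  R <- .agg_ranks(pr$G, parts, gclip)
  U <- R - s * (s + 1) / 2
  S <- 1 - U / (s * rmax)
  S[S < 0] <- 0
  S[S > 1] <- 1
  .score_dimnames(S, pr$G, pr$X)
}

#' AUCell-style signature scores
#'
#' Area under the recovery curve within the top `k = ceiling(auc_max_frac *
#' p)` ranked genes of each sample: each member at descending rank r
#' contributes max(0, k - r + 1) — the number of top-k thresholds at which
#' it has been recovered — and the member sum is normalized by the maximal
#' achievable area (all members at the very top).
#'
#' @inheritParams replaid_scse
#' @param auc_max_frac Fraction of the ranking that defines the top window
#'   (default 0.05).
#' @return Score matrix (sets x samples), values in \[0, 1\].
#' @export
replaid_aucell <- function(X, genesets, auc_max_frac = 0.05) {
  if (auc_max_frac <= 0 || auc_max_frac > 1)
    stop("auc_max_frac must be in (0, 1]")
  pr <- .prep_sets(X, genesets)
  s <- pr$s
  p <- pr$p
  k <- ceiling(auc_max_frac * p)
  parts <- .rank_parts(pr$X, "ascending")
  gtop <- function(r) pmax(k - (p + 1 - r) + 1, 0)
  raw <- .agg_ranks(pr$G, parts, gtop)
  max_raw <- vapply(s, function(si)
    sum(seq.int(k, by = -1, length.out = min(si, k))), numeric(1))
  S <- raw / max_raw
  .score_dimnames(S, pr$G, pr$X)
}

#' ssGSEA-style signature scores (integral form)
#'
#' Per sample, genes are ranked ascending and members weighted by
#' rank^alpha. The enrichment score is the area of the weighted
#' Kolmogorov-Smirnov running sum, which collapses to the closed form
#' sum(w * a over members) / sum(w over members) -
#' sum(a over non-members) / (p - s), computable from three cross-products
#' (of rank^(alpha+1), rank^alpha and rank). No global max-min rescaling is
#' applied (see [rescale_scores()]).
#'
#' @inheritParams replaid_scse
#' @param alpha Rank-weight exponent (default 0.25).
#' @return Score matrix (sets x samples), on the rank scale.
#' @export
replaid_ssgsea <- function(X, genesets, alpha = 0.25) {
  if (alpha < 0) stop("alpha must be nonnegative")
  pr <- .prep_sets(X, genesets)
  s <- pr$s
  p <- pr$p
  if (any(s >= p))
    stop("gene set(s) spanning the whole shared feature universe ",
         "cannot be scored")
  parts <- .rank_parts(pr$X, "ascending")
  S1 <- .agg_ranks(pr$G, parts, function(r) r^(alpha + 1))
  S2 <- .agg_ranks(pr$G, parts, function(r) r^alpha)
  S3 <- .agg_ranks(pr$G, parts)
  tot <- p * (p + 1) / 2
  S <- S1 / S2 - (tot - S3) / (p - s)
  .score_dimnames(S, pr$G, pr$X)
}

#' GSVA-style signature scores (integral form)
#'
#' Three stages. (1) Per gene, a cross-sample cumulative score: in
#' `"gaussian"` mode the mean of Normal CDFs centered at each sample's value
#' with bandwidth sd/4 (zero-variance genes get a flat 0.5 with a warning);
#' in `"ecdf"` mode the empirical CDF. (2) Per sample, genes are ranked by
#' that score and the symmetric rank statistic |p/2 - r_desc|^tau becomes
#' the gene weight, so both tails of the profile carry weight. (3) The
#' weighted running-sum area as in [replaid_ssgsea()], with the stage-2
#' weights — a mean-statistic approximation of the original max-deviation
#' walk.
#'
#' @inheritParams replaid_scse
#' @param tau Weight exponent (default 1).
#' @param kcdf `"gaussian"` or `"ecdf"`.
#' @return Score matrix (sets x samples).
#' @export
replaid_gsva <- function(X, genesets, tau = 1, kcdf = c("gaussian", "ecdf")) {
  kcdf <- match.arg(kcdf)
  if (tau < 0) stop("tau must be nonnegative")
  pr <- .prep_sets(X, genesets)
  s <- pr$s
  p <- pr$p
  if (any(s >= p))
    stop("gene set(s) spanning the whole shared feature universe ",
         "cannot be scored")
  Xd <- if (methods::is(pr$X, "sparseMatrix")) .densify(pr$X) else pr$X
  n <- ncol(Xd)
  if (n < 3L)
    stop("GSVA-style scoring needs at least 3 samples for the ",
         "cross-sample density estimate")
  FF <- matrix(0, p, n)
  if (kcdf == "gaussian") {
    sds <- apply(Xd, 1L, stats::sd)
    flat <- sds == 0
    if (any(flat)) {
      warning(sum(flat), " zero-variance gene(s) in gaussian mode; ",
              "their cumulative score is flat 0.5")
      FF[flat, ] <- 0.5
    }
    for (i in which(!flat)) {
      x <- Xd[i, ]
      FF[i, ] <- rowMeans(stats::pnorm(outer(x, x, "-") / (sds[i] / 4)))
    }
  } else {
    for (i in seq_len(p)) {
      x <- Xd[i, ]
      FF[i, ] <- rank(x, ties.method = "max") / n
    }
  }
  A <- apply(FF, 2L, rank, ties.method = "average")
  if (!is.matrix(A)) A <- matrix(A, nrow = p)
  W <- abs(p / 2 - (p + 1 - A))^tau
  SwA <- as.matrix(Matrix::crossprod(pr$G, W * A))
  Sw <- as.matrix(Matrix::crossprod(pr$G, W))
  SA <- as.matrix(Matrix::crossprod(pr$G, A))
  tot <- p * (p + 1) / 2
  first <- ifelse(Sw > 0, SwA / pmax(Sw, .Machine$double.xmin), 0)
  S <- first - (tot - SA) / (p - s)
  .score_dimnames(S, pr$G, pr$X)
}

#' Score gene sets with any supported method
#'
#' Dispatcher over the PLAID scorer and the six replication methods.
#'
#' @param X Expression matrix (log-intensity for all methods except
#'   `"scse"`/`"scse.mean"`, which expect raw counts).
#' @param genesets Collection (named list) or binary feature-by-set matrix.
#' @param method One of `"plaid"`, `"singscore"`, `"scse"`, `"scse.mean"`,
#'   `"ssgsea"`, `"gsva"`, `"ucell"`, `"aucell"`.
#' @param ... Passed to the method (e.g. `alpha`, `tau`, `rmax`,
#'   `auc_max_frac`, `offset`, `min_sets`, `normalize`, `kcdf`).
#' @return Score matrix (sets x samples).
#' @export
replaid <- function(X, genesets,
                    method = c("plaid", "singscore", "scse", "scse.mean",
                               "ssgsea", "gsva", "ucell", "aucell"),
                    ...) {
  method <- match.arg(method)
  switch(method,
         plaid = plaid(X, genesets, ...),
         singscore = replaid_sing(X, genesets, ...),
         scse = replaid_scse(X, genesets, aggregate = "sum", ...),
         scse.mean = replaid_scse(X, genesets, aggregate = "mean", ...),
         ssgsea = replaid_ssgsea(X, genesets, ...),
         gsva = replaid_gsva(X, genesets, ...),
         ucell = replaid_ucell(X, genesets, ...),
         aucell = replaid_aucell(X, genesets, ...))
}

#' Per-sample and per-set concordance between two score matrices
#'
#' Pearson and Spearman correlations per sample column (across sets) and per
#' set row (across samples). With `center = TRUE` each set row of both
#' matrices is mean-centered first, which removes static set baselines and
#' compares the sample-to-sample variation the two methods report.
#'
#' @param S1,S2 Score matrices sharing set and sample spaces.
#' @param center Row-center both matrices before correlating.
#' @return `list(per_sample =, per_set =)` of data frames with `pearson`
#'   and `spearman` columns.
#' @export
concordance_report <- function(S1, S2, center = FALSE) {
  if (!all(dim(S1) == dim(S2)))
    stop("score matrices have different dimensions")
  if (!is.null(rownames(S1)) && !is.null(rownames(S2))) {
    if (!setequal(rownames(S1), rownames(S2)) ||
        !setequal(colnames(S1), colnames(S2)))
      stop("score matrices do not share set and sample spaces")
    S2 <- S2[rownames(S1), colnames(S1), drop = FALSE]
  }
  S1 <- as.matrix(S1)
  S2 <- as.matrix(S2)
  if (center) {
    S1 <- S1 - rowMeans(S1)
    S2 <- S2 - rowMeans(S2)
  }
  cor_by <- function(margin) {
    idx <- seq_len(dim(S1)[margin])
    get <- function(M, i) if (margin == 2L) M[, i] else M[i, ]
    data.frame(
      id = if (margin == 2L) colnames(S1) %||% as.character(idx)
           else rownames(S1) %||% as.character(idx),
      pearson = vapply(idx, function(i)
        stats::cor(get(S1, i), get(S2, i)), numeric(1)),
      spearman = vapply(idx, function(i)
        stats::cor(get(S1, i), get(S2, i), method = "spearman"), numeric(1)),
      row.names = NULL
    )
  }
  list(per_sample = cor_by(2L), per_set = cor_by(1L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
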