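# Core scoring engine. The score of a gene set in a sample is the mean
# log-intensity of its member features, obtained as the cross-product of a
# column-normalized sparse indicator matrix with the expression matrix.

# Single densification point for expression matrices. The sparse scoring
# path must never call this; tests rely on that to assert the out-of-core
# contract.
.densify <- function(X) as.matrix(X)

.check_finite <- function(X) {
  if (methods::is(X, "sparseMatrix")) {
    if (any(!is.finite(X@x)))
      stop("nonfinite values in expression matrix")
  } else {
    if (anyNA(X))
      stop("missing values present; use masked_plaid_score() or plaid(), ",
           "which handle them")
    if (any(!is.finite(X)))
      stop("nonfinite values in expression matrix")
  }
  invisible(TRUE)
}

#' Restrict an expression matrix and a gene-set matrix to shared features
#'
#' Both matrices are subset to the intersection of their feature ids, rows
#' aligned in identical order. Gene sets left without members are dropped
#' with a warning.
#'
#' @param X Expression matrix (features x samples) with row names.
#' @param G Binary gene-set matrix (features x sets) with row names.
#' @return `list(X =, G =)` with aligned rows.
#' @export
intersect_features <- function(X, G) {
  fx <- rownames(X)
  fg <- rownames(G)
  if (is.null(fx) || is.null(fg))
    stop("both matrices need feature row names")
  if (anyDuplicated(fx)) stop("duplicate feature ids in expression matrix")
  if (anyDuplicated(fg)) stop("duplicate feature ids in gene-set matrix")
  shared <- intersect(fx, fg)
  if (length(shared) == 0L)
    stop("no shared features between expression matrix and gene sets")
  X2 <- X[shared, , drop = FALSE]
  G2 <- G[shared, , drop = FALSE]
  s <- Matrix::colSums(G2)
  if (any(s == 0)) {
    empty <- colnames(G2)[s == 0]
    warning("dropping ", length(empty),
            " gene set(s) with no shared features: ",
            paste(utils::head(empty, 5L), collapse = ", "),
            if (length(empty) > 5L) ", ..." else "")
    G2 <- G2[, s > 0, drop = FALSE]
    if (ncol(G2) == 0L)
      stop("no gene sets left after feature intersection")
  }
  list(X = X2, G = G2)
}

#' Column-normalize a gene-set indicator matrix
#'
#' Scales each column of a binary indicator matrix by its column sum plus a
#' small offset, so every non-empty column sums to s/(s + offset), i.e. to 1
#' within numerical tolerance. The offset keeps all-zero columns at zero
#' instead of dividing by zero.
#'
#' @param G Binary feature-by-set matrix.
#' @param offset Nonnegative scalar added to each column sum (default 1e-8).
#' @return Sparse weight matrix of the same shape.
#' @export
normalize_set_columns <- function(G, offset = 1e-8) {
  if (!is.numeric(offset) || length(offset) != 1L || is.na(offset) ||
      offset < 0)
    stop("offset must be a nonnegative scalar")
  G <- methods::as(Matrix::Matrix(G, sparse = TRUE), "CsparseMatrix")
  if (length(G@x) && !all(G@x %in% c(0, 1)))
    stop("indicator matrix must be binary (0/1)")
  s <- Matrix::colSums(G)
  W <- G %*% Matrix::Diagonal(x = 1 / (s + offset))
  dimnames(W) <- dimnames(G)
  W
}

#' Plan chunked computation over sample columns
#'
#' The chunk size is the integer ceiling divided by the number of gene-set
#' columns: each cross-product block then stays below the machine integer
#' indexing limit. Chunking activates automatically when the number of
#' samples reaches the estimated chunk size, or when forced.
#'
#' @param n_sets,n_samples Positive integers.
#' @param int_limit Integer ceiling used for the estimate (default
#'   `.Machine$integer.max`, i.e. 2^31 - 1).
#' @param chunk_size Optional manual chunk size; supplying one forces
#'   chunked computation (useful for testing).
#' @param force Force activation at the estimated size.
#' @return An object of class `"chunk_plan"`: `chunk_size`, `boundaries`
#'   (two-column matrix of 1-based inclusive start/end), `int_limit`,
#'   `active`.
#' @examples
#' estimate_chunk_plan(61459, 1000)
#' @export
estimate_chunk_plan <- function(n_sets, n_samples,
                                int_limit = .Machine$integer.max,
                                chunk_size = NULL, force = FALSE) {
  if (n_sets < 1 || n_samples < 1 || int_limit < 1)
    stop("n_sets, n_samples and int_limit must be positive")
  manual <- !is.null(chunk_size)
  if (manual) {
    if (chunk_size < 1) stop("chunk_size must be positive")
  } else {
    chunk_size <- max(1, floor(int_limit / n_sets))
  }
  active <- isTRUE(force) || manual || n_samples >= chunk_size
  step <- if (active) min(chunk_size, n_samples) else n_samples
  starts <- seq.int(1L, n_samples, by = step)
  ends <- pmin(starts + step - 1, n_samples)
  structure(list(chunk_size = chunk_size,
                 boundaries = cbind(start = starts, end = ends),
                 int_limit = int_limit,
                 active = active),
            class = "chunk_plan")
}

#' @export
print.chunk_plan <- function(x, ...) {
  cat("chunk plan: size", x$chunk_size,
      if (x$active) "(active," else "(inactive,",
      nrow(x$boundaries), "block(s))\n")
  invisible(x)
}

#' Raw PLAID scores via sparse cross-product
#'
#' Computes `t(W) %*% X`: for each gene set and sample, the weighted sum of
#' member log-intensities, i.e. the member mean times s/(s + offset). The
#' input matrix is neither centered nor ranked. When the chunk plan is
#' active the product is computed block-by-block over sample columns and
#' concatenated; the result is identical to the unchunked product.
#'
#' @param X Expression matrix (features x samples), log scale, no missing
#'   values (use [masked_plaid_score()] for dense matrices with `NA`).
#' @param W Weight matrix from [normalize_set_columns()], rows aligned
#'   with `X`.
#' @param plan Optional [estimate_chunk_plan()] result; computed
#'   automatically when `NULL`.
#' @return Dense score matrix (sets x samples), attribute
#'   `normalized = FALSE`.
#' @export
plaid_score <- function(X, W, plan = NULL) {
  if (!identical(rownames(X), rownames(W)))
    stop("expression and weight matrices are not aligned on the same features")
  .check_finite(X)
  if (is.null(plan)) plan <- estimate_chunk_plan(ncol(W), ncol(X))
  if (isTRUE(plan$active) && nrow(plan$boundaries) > 1L) {
    b <- plan$boundaries
    blocks <- vector("list", nrow(b))
    for (k in seq_len(nrow(b))) {
      blocks[[k]] <- as.matrix(
        Matrix::crossprod(W, X[, b[k, 1L]:b[k, 2L], drop = FALSE]))
    }
    S <- do.call(cbind, blocks)
  } else {
    S <- as.matrix(Matrix::crossprod(W, X))
  }
  dimnames(S) <- list(colnames(W), colnames(X))
  attr(S, "normalized") <- FALSE
  S
}

#' Missing-value-aware PLAID scores
#'
#' For dense matrices carrying `NA` as a missing-value flag: each (set,
#' sample) score is the mean over the member features observed in that
#' sample, computed as a ratio of two cross-products — member values (with
#' missing entries zeroed) over member observedness — with the offset
#' protecting empty denominators. A pair with no observed members scores 0
#' and is reported in the `"unobserved"` attribute.
#'
#' @param X Dense expression matrix, `NA` = missing.
#' @param G Binary gene-set matrix, rows aligned with `X`.
#' @param offset Denominator offset (default 1e-8).
#' @return Dense score matrix (sets x samples) with attributes
#'   `normalized = FALSE`, `n_unobserved`, and (when any) `unobserved`
#'   (index matrix of the affected pairs).
#' @export
masked_plaid_score <- function(X, G, offset = 1e-8) {
  if (methods::is(X, "sparseMatrix"))
    stop("masked scoring requires a dense matrix; ",
         "sparse matrices carry no missing-value flag (zeros are data)")
  if (!identical(rownames(X), rownames(G)))
    stop("expression and gene-set matrices are not aligned on the same features")
  if (all(is.na(X))) stop("all expression values are missing")
  if (any(!is.finite(X) & !is.na(X)))
    stop("nonfinite non-missing values in expression matrix")
  X0 <- X
  X0[is.na(X0)] <- 0
  obs <- (!is.na(X)) * 1
  num <- as.matrix(Matrix::crossprod(G, X0))
  den <- as.matrix(Matrix::crossprod(G, obs))
  S <- num / (den + offset)
  dimnames(S) <- list(colnames(G), colnames(X))
  attr(S, "normalized") <- FALSE
  empty <- den == 0
  attr(S, "n_unobserved") <- sum(empty)
  if (any(empty)) attr(S, "unobserved") <- which(empty, arr.ind = TRUE)
  S
}

#' Median-normalize a score matrix
#'
#' Each sample column is median-centered, then the overall mean of the
#' column medians is added back, so every normalized column has the same
#' median (the grand mean of the raw column medians). Applied by default
#' when more than `min_sets` gene sets were scored.
#'
#' @param S Raw score matrix (sets x samples).
#' @param min_sets Normalize automatically when `nrow(S) > min_sets`
#'   (default 20).
#' @param enable `NULL` for the automatic rule, or `TRUE`/`FALSE` to
#'   override it.
#' @return Score matrix with attribute `normalized` set accordingly.
#' @export
median_normalize <- function(S, min_sets = 20, enable = NULL) {
  if (!is.matrix(S)) stop("S must be a dense score matrix")
  active <- if (is.null(enable)) nrow(S) > min_sets else isTRUE(enable)
  if (!active) {
    attr(S, "normalized") <- FALSE
    return(S)
  }
  med <- apply(S, 2L, stats::median)
  out <- sweep(S, 2L, med, "-") + mean(med)
  attr(out, "normalized") <- TRUE
  out
}

#' PLAID single-sample gene set enrichment scores
#'
#' End-to-end scoring: convert the collection to a sparse indicator matrix,
#' restrict both inputs to shared features, column-normalize the indicator,
#' cross-multiply (chunked automatically for very large inputs; via the
#' masked path when the dense input contains `NA`), and median-normalize
#' the score matrix when more than `min_sets` sets were scored.
#'
#' @param X Log-intensity matrix (features x samples), sparse (`dgCMatrix`)
#'   or dense, with dimnames.
#' @param genesets Named list of member vectors, or a binary feature-by-set
#'   matrix.
#' @param offset Column-sum offset (default 1e-8).
#' @param min_sets Median-normalization threshold (default 20).
#' @param normalize `"auto"` (normalize when `n_sets > min_sets`), `"on"`,
#'   or `"off"`.
#' @param chunk_size Optional manual chunk size (forces chunked computation).
#' @param int_limit Integer ceiling for the automatic chunk estimate.
#' @return Dense score matrix (sets x samples) with attribute `normalized`.
#' @examples
#' X <- matrix(c(2, 4, 99), 3, dimnames = list(c("g1", "g2", "g3"), "s1"))
#' plaid(X, list(A = c("g1", "g2")))  # mean of g1, g2
#' @export
plaid <- function(X, genesets, offset = 1e-8, min_sets = 20,
                  normalize = c("auto", "on", "off"),
                  chunk_size = NULL, int_limit = .Machine$integer.max) {
  normalize <- match.arg(normalize)
  G <- if (is.list(genesets)) gmt2mat(genesets,
                                      feature_universe = rownames(X))
       else genesets
  pr <- intersect_features(X, G)
  plan <- estimate_chunk_plan(ncol(pr$G), ncol(pr$X),
                              int_limit = int_limit, chunk_size = chunk_size)
  if (!methods::is(pr$X, "sparseMatrix") && anyNA(pr$X)) {
    S <- masked_plaid_score(pr$X, pr$G, offset)
  } else {
    W <- normalize_set_columns(pr$G, offset)
    S <- plaid_score(pr$X, W, plan)
  }
  en <- switch(normalize, auto = NULL, on = TRUE, off = FALSE)
  out <- median_normalize(S, min_sets = min_sets, enable = en)
  for (a in c("n_unobserved", "unobserved"))
    if (!is.null(attr(S, a))) attr(out, a) <- attr(S, a)
  out
}

#' Rescale a score matrix globally
#'
#' Optional post-hoc rescaling by the global score range, as performed by
#' some of the original methods. Off by default everywhere in this package
#' because it couples samples: adding a sample changes all scores.
#'
#' @param S Score matrix.
#' @return `S / (max(S) - min(S))`.
#' @export
rescale_scores <- function(S) {
  rng <- max(S) - min(S)
  if (rng == 0) stop("constant score matrix cannot be rescaled")
  S / rng
}
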