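# Per-sample rank machinery shared by the replication suite. For sparse
# columns, all zero entries share the average rank of the zero block
# ("zeros_share_bottom"): the stored entries get exact full-column ranks
# without ever densifying the expression matrix, and set-level sums of any
# elementwise transform of the ranks reduce to one sparse cross-product plus
# a per-column constant.

# Decompose per-column average-tie ranks of X. Returns either a dense rank
# matrix (dense input) or a sparse matrix holding the exact rank of each
# stored entry plus the shared rank of the zero block per column.
.rank_parts <- function(X, direction = c("ascending", "descending")) {
  direction <- match.arg(direction)
  p <- nrow(X)
  if (methods::is(X, "sparseMatrix")) {
    M <- Matrix::drop0(methods::as(X, "CsparseMatrix"))
    n <- ncol(M)
    xp <- M@p
    xv <- M@x
    rank_nz <- numeric(length(xv))
    zero_rank <- numeric(n)
    for (j in seq_len(n)) {
      idx <- if (xp[j + 1L] > xp[j]) (xp[j] + 1L):xp[j + 1L] else integer(0)
      v <- xv[idx]
      n0 <- p - length(v)
      if (length(v)) {
        # full-column ascending rank: zeros sit between the negative and
        # positive stored values (stored entries are never exactly zero)
        r <- rank(v, ties.method = "average") + n0 * (v > 0)
        rank_nz[idx] <- r
      }
      zero_rank[j] <- sum(v < 0) + (n0 + 1) / 2
    }
    if (direction == "descending") {
      rank_nz <- p + 1 - rank_nz
      zero_rank <- p + 1 - zero_rank
    }
    R <- M
    R@x <- rank_nz
    list(sparse = TRUE, p = p, nz = R, zero_rank = zero_rank)
  } else {
    R <- apply(X, 2L, rank, ties.method = "average")
    if (!is.matrix(R)) R <- matrix(R, nrow = p, ncol = ncol(X))
    if (direction == "descending") R <- p + 1 - R
    list(sparse = FALSE, p = p, R = R)
  }
}

# Sum of g(rank) over the members of each set, per sample:
# crossprod of the indicator with the transformed rank matrix. On the sparse
# path, g(rank) = [g(rank) - g(zero_rank_j)] (sparse) + g(zero_rank_j), so
# the member sum is crossprod(G, sparse part) + set_size * g(zero_rank_j).
.agg_ranks <- function(G, parts, g = identity) {
  if (!parts$sparse) {
    return(as.matrix(Matrix::crossprod(G, g(parts$R))))
  }
  M <- parts$nz
  gz <- g(parts$zero_rank)
  jj <- rep.int(seq_len(ncol(M)), diff(M@p))
  M@x <- g(M@x) - gz[jj]
  s <- Matrix::colSums(G)
  as.matrix(Matrix::crossprod(G, M)) + outer(s, gz)
}

#' Per-sample feature ranks
#'
#' Ranks every column of the expression matrix with average ties. Under
#' `"zeros_share_bottom"` a sparse column is ranked without densifying it:
#' all zero entries share the average rank of the zero block, and stored
#' entries get their exact full-column rank (identical to ranking the dense
#' column). `"dense_full"` ranks the densified column directly. With no
#' ties, descending ranks equal `p + 1 -` ascending ranks.
#'
#' @param X Expression matrix (features x samples).
#' @param direction `"ascending"` (smallest value gets rank 1) or
#'   `"descending"`.
#' @param sparse_policy `"zeros_share_bottom"` or `"dense_full"`.
#' @return Dense matrix of ranks, same shape and dimnames as `X`.
#' @examples
#' column_ranks(matrix(c(2, 5, 5, 1), 4))  # 2, 3.5, 3.5, 1
#' @export
column_ranks <- function(X, direction = c("ascending", "descending"),
                         sparse_policy = c("zeros_share_bottom",
                                           "dense_full")) {
  direction <- match.arg(direction)
  sparse_policy <- match.arg(sparse_policy)
  if (methods::is(X, "sparseMatrix") && sparse_policy == "dense_full")
    X <- .densify(X)
  parts <- .rank_parts(X, direction)
  if (!parts$sparse) {
    R <- parts$R
  } else {
    R <- matrix(rep(parts$zero_rank, each = parts$p), nrow = parts$p)
    nz <- methods::as(parts$nz, "TsparseMatrix")
    R[cbind(nz@i + 1L, nz@j + 1L)] <- nz@x
  }
  dn <- dimnames(X)
  if (!is.null(dn) && !all(vapply(dn, is.null, logical(1))))
    dimnames(R) <- dn
  R
}
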