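# Gene-set collections are plain named lists of character vectors (one entry
# per set, members as feature ids), with an optional "descriptions" attribute
# holding the GMT description field per set. Indicator matrices are dgCMatrix
# (features x sets, binary).

#' Read a GMT gene-set file
#'
#' Parses a Gene Matrix Transposed (GMT) file: one gene set per line, with
#' tab-separated fields `name`, `description`, then one or more member
#' feature identifiers. Duplicate members within a line are collapsed;
#' trailing empty fields are ignored.
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors (set members), with a
#'   `"descriptions"` attribute (named character vector).
#' @examples
#' f <- tempfile(fileext = ".gmt")
#' writeLines("SETA\tdemo\tg1\tg2", f)
#' read_gmt(f)
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    out <- structure(list(), names = character(0))
    attr(out, "descriptions") <- structure(character(0), names = character(0))
    return(out)
  }
  cm <- startsWith(lines, "#")
  if (any(cm))
    stop("comment lines are not valid GMT (line ", lineno[which(cm)[1L]], ")")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  n <- length(parts)
  sets <- vector("list", n)
  descs <- character(n)
  nms <- character(n)
  for (i in seq_len(n)) {
    f <- parts[[i]]
    if (length(f) < 3L)
      stop("malformed GMT line ", lineno[i],
           ": fewer than 3 tab-separated fields")
    if (!nzchar(f[1L]))
      stop("malformed GMT line ", lineno[i], ": empty set name")
    members <- unique(f[-c(1L, 2L)])
    members <- members[nzchar(members)]
    if (length(members) == 0L)
      stop("malformed GMT line ", lineno[i], ": no members")
    nms[i] <- f[1L]
    descs[i] <- f[2L]
    sets[[i]] <- members
  }
  if (anyDuplicated(nms))
    stop("duplicate set name(s): ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  names(sets) <- nms
  names(descs) <- nms
  attr(sets, "descriptions") <- descs
  sets
}

#' Write a gene-set collection to a GMT file
#'
#' @param collection Named list of character vectors (as from [read_gmt()]).
#'   Descriptions are taken from the `"descriptions"` attribute when present.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(collection, path) {
  .check_collection(collection)
  descs <- attr(collection, "descriptions")
  nms <- names(collection)
  if (is.null(descs)) descs <- structure(rep("", length(nms)), names = nms)
  lines <- vapply(seq_along(collection), function(i) {
    d <- descs[[nms[i]]]
    if (is.null(d) || is.na(d)) d <- ""
    paste(c(nms[i], d, collection[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

.check_collection <- function(collection) {
  if (!is.list(collection)) stop("collection must be a named list")
  if (length(collection) > 0L &&
      (is.null(names(collection)) || any(!nzchar(names(collection)))))
    stop("all gene sets must be named")
  if (anyDuplicated(names(collection)))
    stop("duplicate set names in collection")
  invisible(TRUE)
}

#' Convert a gene-set collection to a sparse indicator matrix
#'
#' Builds a binary feature-by-set indicator matrix with a 1 where a feature
#' belongs to a set. When `feature_universe` is given, rows follow it and
#' members outside the universe are discarded; otherwise rows are the union
#' of all members in first-appearance order. Sets left empty after universe
#' filtering are dropped with a warning.
#'
#' @param collection Named list of member vectors.
#' @param feature_universe Optional duplicate-free character vector of
#'   feature ids defining the row space.
#' @return A binary `dgCMatrix` (features x sets) with dimnames.
#' @examples
#' gmt2mat(list(A = c("g1", "g2"), B = "g2"))
#' @export
gmt2mat <- function(collection, feature_universe = NULL) {
  .check_collection(collection)
  if (length(collection) == 0L) stop("empty gene-set collection")
  members <- lapply(collection, function(m) unique(as.character(m)))
  if (!is.null(feature_universe)) {
    feature_universe <- as.character(feature_universe)
    if (anyDuplicated(feature_universe))
      stop("feature_universe contains duplicates")
    features <- feature_universe
    members <- lapply(members, function(m) m[m %in% features])
  } else {
    features <- unique(unlist(members, use.names = FALSE))
  }
  sizes <- lengths(members)
  if (any(sizes == 0L)) {
    empty <- names(members)[sizes == 0L]
    warning("dropping ", length(empty), " empty gene set(s): ",
            paste(utils::head(empty, 5L), collapse = ", "),
            if (length(empty) > 5L) ", ..." else "")
    members <- members[sizes > 0L]
    if (length(members) == 0L)
      stop("no non-empty gene sets remain")
  }
  i <- match(unlist(members, use.names = FALSE), features)
  j <- rep.int(seq_along(members), lengths(members))
  Matrix::sparseMatrix(i = i, j = j, x = 1,
                       dims = c(length(features), length(members)),
                       dimnames = list(features, names(members)))
}

#' Convert a sparse indicator matrix back to a gene-set collection
#'
#' Inverse of [gmt2mat()] over the represented feature universe. Entries must
#' be 0/1; all-zero columns (empty sets) are dropped with a warning.
#'
#' @param gsm Binary feature-by-set matrix with dimnames.
#' @return Named list of member character vectors.
#' @export
mat2gmt <- function(gsm) {
  if (is.null(rownames(gsm)) || is.null(colnames(gsm)))
    stop("gene-set matrix needs feature row names and set column names")
  Gt <- methods::as(methods::as(gsm, "CsparseMatrix"), "TsparseMatrix")
  nz <- Gt@x != 0
  if (!all(Gt@x[nz] == 1))
    stop("gene-set matrix must be binary (0/1)")
  jj <- Gt@j[nz] + 1L
  ii <- Gt@i[nz] + 1L
  sets <- split(rownames(gsm)[ii],
                factor(jj, levels = seq_len(ncol(gsm))))
  names(sets) <- colnames(gsm)
  sizes <- lengths(sets)
  if (any(sizes == 0L)) {
    warning("dropping ", sum(sizes == 0L), " empty gene set(s)")
    sets <- sets[sizes > 0L]
  }
  if (length(sets) == 0L) stop("no non-empty gene sets in matrix")
  lapply(sets, as.character)
}

#' Read an expression matrix
#'
#' Reads a feature-by-sample matrix either from a MatrixMarket coordinate
#' file with plain-text feature/sample name sidecars (one id per line; the
#' usual single-cell triplet layout) or from a dense TSV/CSV with a header
#' row of sample ids and feature ids in the first column. MatrixMarket input
#' is kept sparse; TSV/CSV input is dense and may contain `NA` entries,
#' which are treated as missing values downstream.
#'
#' @param path Path to the matrix file.
#' @param format One of `"mtx"`, `"tsv"`, `"csv"`.
#' @param features,samples For `mtx`, paths to the sidecar id files. Default
#'   to `<path minus .mtx>_features.txt` / `_samples.txt`.
#' @return A numeric matrix (`dgCMatrix` for mtx, base matrix otherwise)
#'   with feature row names and sample column names.
#' @export
read_expression <- function(path, format = c("mtx", "tsv", "csv"),
                            features = NULL, samples = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "mtx") {
    m <- Matrix::readMM(path)
    # pattern matrices (all-1 indicators) come back as ngCMatrix
    m <- methods::as(methods::as(m, "dMatrix"), "CsparseMatrix")
    stem <- sub("\\.mtx$", "", path)
    if (is.null(features)) features <- paste0(stem, "_features.txt")
    if (is.null(samples)) samples <- paste0(stem, "_samples.txt")
    fids <- readLines(features, warn = FALSE)
    sids <- readLines(samples, warn = FALSE)
    if (length(fids) != nrow(m))
      stop("feature sidecar has ", length(fids), " ids but matrix has ",
           nrow(m), " rows")
    if (length(sids) != ncol(m))
      stop("sample sidecar has ", length(sids), " ids but matrix has ",
           ncol(m), " columns")
    if (anyDuplicated(fids)) stop("duplicate feature ids")
    if (anyDuplicated(sids)) stop("duplicate sample ids")
    if (any(!is.finite(m@x))) stop("nonfinite values in sparse matrix")
    dimnames(m) <- list(fids, sids)
    return(m)
  }
  sep <- if (format == "tsv") "\t" else ","
  df <- utils::read.delim(path, sep = sep, header = TRUE,
                          check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2L) stop("expression table needs feature ids plus >=1 sample")
  fids <- df[[1L]]
  sids <- colnames(df)[-1L]
  if (anyDuplicated(fids)) stop("duplicate feature ids")
  if (anyDuplicated(sids)) stop("duplicate sample ids")
  vals <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim(vals)))
  bad <- is.na(num) & !is.na(vals) & !(trimws(vals) %in% c("NA", "NaN", ""))
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1L, ]
    stop("non-numeric value '", vals[w[1L], w[2L]], "' at feature '",
         fids[w[1L]], "', sample '", sids[w[2L]], "'")
  }
  dimnames(num) <- list(fids, sids)
  num
}

#' Write an expression (or indicator) matrix in MatrixMarket layout
#'
#' Writes `<path>.mtx` plus `<path>_features.txt` and `<path>_samples.txt`
#' sidecars, the layout [read_expression()] expects.
#'
#' @param X Matrix with dimnames.
#' @param path Output stem (without the `.mtx` extension).
#' @return Invisibly, the `.mtx` path.
#' @export
write_expression <- function(X, path) {
  if (is.null(rownames(X)) || is.null(colnames(X)))
    stop("matrix needs dimnames")
  Xs <- methods::as(Matrix::Matrix(X, sparse = TRUE), "CsparseMatrix")
  mtx <- paste0(path, ".mtx")
  Matrix::writeMM(Xs, mtx)
  writeLines(rownames(X), paste0(path, "_features.txt"))
  writeLines(colnames(X), paste0(path, "_samples.txt"))
  invisible(mtx)
}

#' Write a score matrix as TSV
#'
#' Tab-separated output with gene sets in rows and samples in columns; the
#' first column (`geneset`) holds the set names.
#'
#' @param S Score matrix (sets x samples) with dimnames.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_scores <- function(S, path) {
  df <- data.frame(geneset = rownames(S), as.data.frame(S, check.names = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
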