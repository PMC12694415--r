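# Deterministic synthetic fixtures: zero-inflated sparse count matrices
# with optional spiked-in signatures, random gene-set collections, and a
# signal-recovery statistic. Every generator pins the RNG algorithm so a
# seed means the same data everywhere.

.set_seed <- function(seed) {
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
}

#' Simulate a sparse zero-inflated count matrix
#'
#' Gene-level means are drawn log-normal around `mu` (real transcriptomes
#' and proteomes have long-tailed feature means; `gene_mean_sdlog = 0`
#' recovers a homogeneous matrix). Counts are then drawn per entry from a
#' negative binomial (default dispersion 0.5) or Poisson model; spiked
#' (gene, cell) blocks are multiplied by their fold before zero-masking;
#' extra zeros are finally injected by independent Bernoulli masking, with
#' the masking probability solved from the model's mean intrinsic zero rate
#' so the realized zero fraction matches the request in expectation.
#' Requests below the intrinsic zero rate yield the intrinsic rate with a
#' warning.
#'
#' @param n_genes,n_cells Matrix dimensions.
#' @param zero_fraction Target zero fraction in \[0, 1).
#' @param count_model `"nbinom"` or `"poisson"`.
#' @param mu Mean count across genes (default 1).
#' @param dispersion Negative-binomial dispersion (1/size; default 0.5).
#' @param gene_mean_sdlog Log-scale spread of the gene-level means
#'   (default 1.5).
#' @param seed Integer seed; fixed seed means identical output.
#' @param spikes List of spikes, each `list(genes =, cells =, fold =)` with
#'   gene/cell ids or indices and a multiplicative fold >= 1.
#' @return Sparse `dgCMatrix` of counts (genes x cells) with dimnames
#'   `gene0001...` / `cell0001...`.
#' @export
simulate_counts <- function(n_genes, n_cells, zero_fraction = 0.9,
                            count_model = c("nbinom", "poisson"),
                            mu = 1.0, dispersion = 0.5,
                            gene_mean_sdlog = 1.5,
                            seed = 1L, spikes = list()) {
  count_model <- match.arg(count_model)
  if (n_genes < 1 || n_cells < 1) stop("dimensions must be positive")
  if (zero_fraction < 0 || zero_fraction >= 1)
    stop("zero_fraction must be in [0, 1)")
  gene_ids <- sprintf("gene%04d", seq_len(n_genes))
  cell_ids <- sprintf("cell%04d", seq_len(n_cells))
  .set_seed(seed)
  mu_g <- if (gene_mean_sdlog > 0) {
    mu * exp(stats::rnorm(n_genes, -gene_mean_sdlog^2 / 2, gene_mean_sdlog))
  } else {
    rep(mu, n_genes)
  }
  MU <- matrix(mu_g, n_genes, n_cells, dimnames = list(gene_ids, cell_ids))
  for (sp in spikes) {
    if (is.null(sp$genes) || is.null(sp$cells) || is.null(sp$fold))
      stop("each spike needs genes, cells and fold")
    if (sp$fold < 1) stop("spike fold must be >= 1")
    gi <- if (is.character(sp$genes)) match(sp$genes, gene_ids) else sp$genes
    ci <- if (is.character(sp$cells)) match(sp$cells, cell_ids) else sp$cells
    if (anyNA(gi) || any(gi < 1) || any(gi > n_genes))
      stop("spike genes outside the gene universe")
    if (anyNA(ci) || any(ci < 1) || any(ci > n_cells))
      stop("spike cells outside the cell universe")
    # fold acts on the expected count of the block (a differential-
    # expression factor), so upregulation also reduces intrinsic dropout
    MU[gi, ci] <- MU[gi, ci] * sp$fold
  }
  m <- if (count_model == "nbinom") {
    matrix(stats::rnbinom(n_genes * n_cells, mu = MU, size = 1 / dispersion),
           n_genes, n_cells)
  } else {
    matrix(stats::rpois(n_genes * n_cells, lambda = MU), n_genes, n_cells)
  }
  dimnames(m) <- list(gene_ids, cell_ids)
  p0 <- if (count_model == "nbinom") {
    size <- 1 / dispersion
    mean((size / (size + mu_g))^size)
  } else {
    mean(exp(-mu_g))
  }
  if (zero_fraction > p0) {
    q <- (zero_fraction - p0) / (1 - p0)
    mask <- matrix(stats::rbinom(n_genes * n_cells, 1L, q), n_genes, n_cells)
    m[mask == 1L] <- 0
  } else if (zero_fraction > 0) {
    warning("count model's intrinsic zero rate (", signif(p0, 3),
            ") exceeds requested zero_fraction; no masking applied")
  }
  methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
}

#' Log-transform a count matrix
#'
#' Elementwise `log(1 + x)` (natural log by default), which maps zeros to
#' zeros and therefore preserves sparsity.
#'
#' @param X Nonnegative count matrix, sparse or dense.
#' @param base Logarithm base (default `exp(1)`; use 2 for log2(1 + x)).
#' @return Matrix of the same representation on the log scale.
#' @export
log_transform <- function(X, base = exp(1)) {
  if (methods::is(X, "sparseMatrix")) {
    if (any(X@x < 0)) stop("negative counts cannot be log-transformed")
    Y <- X
    Y@x <- log1p(X@x) / log(base)
    return(Y)
  }
  if (any(X < 0, na.rm = TRUE))
    stop("negative counts cannot be log-transformed")
  log1p(X) / log(base)
}

#' Simulate a random gene-set collection
#'
#' Set sizes are uniform over `size_range`; members are sampled without
#' replacement from the universe. Designated sets (e.g. spiked signatures)
#' can be prepended verbatim via `include`.
#'
#' @param n_sets Number of random sets.
#' @param size_range Length-2 integer range of set sizes.
#' @param universe Character vector of feature ids.
#' @param seed Integer seed.
#' @param include Optional named list of fixed sets placed first.
#' @return Named list of member vectors (a gene-set collection).
#' @export
simulate_collection <- function(n_sets, size_range = c(10, 50), universe,
                                seed = 1L, include = NULL) {
  if (max(size_range) > length(universe))
    stop("maximum set size exceeds the universe")
  .set_seed(seed)
  sizes <- sample(seq.int(size_range[1L], size_range[2L]), n_sets,
                  replace = TRUE)
  sets <- lapply(sizes, function(k) sample(universe, k))
  names(sets) <- sprintf("random_set_%03d", seq_len(n_sets))
  if (!is.null(include)) {
    .check_collection(include)
    if (any(names(include) %in% names(sets)))
      stop("included set names collide with generated names")
    sets <- c(include, sets)
  }
  attr(sets, "descriptions") <-
    structure(rep("synthetic", length(sets)), names = names(sets))
  sets
}

.auroc <- function(x, positive) {
  n1 <- sum(positive)
  n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L) stop("need both positive and negative samples")
  r <- rank(x)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Spike-recovery separation statistic
#'
#' For each spiked set, the area under the ROC curve of its scores
#' separating spiked from non-spiked cells. AUROC is a rank statistic, so
#' it is invariant under any strictly monotone transform of the scores.
#'
#' @param scores Score matrix (sets x samples).
#' @param spiked_sets Names (or indices) of the spiked sets.
#' @param spiked_cells Names (or indices) of the spiked cells, or a logical
#'   vector over columns.
#' @return `list(auroc = mean over spiked sets, per_set = named vector)`.
#' @export
signal_recovery_check <- function(scores, spiked_sets, spiked_cells) {
  pos <- if (is.logical(spiked_cells)) spiked_cells
         else colnames(scores) %in% spiked_cells |
              seq_len(ncol(scores)) %in% spiked_cells
  if (all(pos) || !any(pos))
    stop("degenerate spike labelling: need spiked and non-spiked cells")
  per_set <- vapply(spiked_sets, function(g) .auroc(scores[g, ], pos),
                    numeric(1))
  names(per_set) <- if (is.character(spiked_sets)) spiked_sets
                    else rownames(scores)[spiked_sets]
  list(auroc = mean(per_set), per_set = per_set)
}
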