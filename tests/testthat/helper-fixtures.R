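# Shared in-code fixtures.

random_collection <- function(n_sets, universe, size_range = c(3, 15),
                              seed = 1) {
  simulate_collection(n_sets, size_range, universe, seed = seed)
}

dense_gaussian_matrix <- function(p, n, seed = 1) {
  set.seed(seed)
  matrix(stats::rnorm(p * n), p, n,
         dimnames = list(sprintf("g%04d", seq_len(p)),
                         sprintf("s%03d", seq_len(n))))
}

# A column vector matrix whose gene at row i holds descending rank i
# (values p, p-1, ..., 1), convenient for placing members at exact ranks.
rank_placement_matrix <- function(p) {
  matrix(seq.int(p, 1), p,
         dimnames = list(sprintf("g%02d", seq_len(p)), "s1"))
}

# Spiked single-cell style fixture used by the concordance and recovery
# checks; mirrors a fold-change signature in a subset of cells.
spiked_fixture <- function(n_genes, n_cells, n_sets, set_size = c(20, 50),
                           n_spiked_sets = 3, spike_size = 40, fold = 4,
                           cell_frac = 0.2, zero_fraction = 0.85, seed = 1) {
  gene_ids <- sprintf("gene%04d", seq_len(n_genes))
  cell_ids <- sprintf("cell%04d", seq_len(n_cells))
  set.seed(seed + 10000L)
  spiked_cells <- sample(cell_ids, round(cell_frac * n_cells))
  spikes <- lapply(seq_len(n_spiked_sets), function(k) {
    list(genes = sample(gene_ids, spike_size), cells = spiked_cells,
         fold = fold)
  })
  X <- simulate_counts(n_genes, n_cells, zero_fraction = zero_fraction,
                       seed = seed, spikes = spikes)
  include <- lapply(spikes, `[[`, "genes")
  names(include) <- sprintf("spiked_set_%02d", seq_len(n_spiked_sets))
  sets <- simulate_collection(n_sets, set_size, gene_ids, seed = seed,
                              include = include)
  list(counts = X, logx = log_transform(X), sets = sets,
       spiked_sets = names(include), spiked_cells = spiked_cells)
}
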