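# shared fixture builders (everything generated in code)

straight_chain <- function(n, cell_id = "line", genomic_kb = 1) {
  conformation(cbind(seq_len(n) - 1, 0, 0), cell_id = cell_id,
               genomic_kb = genomic_kb)
}

random_walk_conformation <- function(n, seed, cell_id = "rw",
                                     genomic_kb = 1) {
  set.seed(seed)
  steps <- matrix(rnorm(3 * (n - 1)), ncol = 3)
  conformation(rbind(c(0, 0, 0), apply(steps, 2, cumsum)),
               cell_id = cell_id, genomic_kb = genomic_kb)
}

random_walk_ensemble <- function(n_cells, n_beads, seed,
                                 length_unit = "arbitrary",
                                 resolution_kb = 1) {
  confs <- lapply(seq_len(n_cells), function(k)
    random_walk_conformation(n_beads, seed + k,
                             cell_id = paste0("cell_", k)))
  conformation_ensemble(confs, length_unit = length_unit,
                        resolution_kb = resolution_kb)
}

# brute-force O(n^2) <Rs> oracle: plain double loop over all (i, i+s) pairs
brute_force_rs <- function(coords) {
  n <- nrow(coords)
  vapply(seq_len(n - 1), function(s) {
    acc <- 0
    for (i in seq_len(n - s))
      acc <- acc + sqrt(sum((coords[i + s, ] - coords[i, ])^2))
    acc / (n - s)
  }, numeric(1))
}
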