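# Small shared fixtures built in code.

# expression matrix with given dimensions of independent N(mu, sd) genes
random_expr <- function(n_genes, n_samples, seed = 1, mu = 6, sd = 1,
                        prefix = "g") {
  set.seed(seed)
  m <- matrix(stats::rnorm(n_genes * n_samples, mu, sd), nrow = n_genes,
              dimnames = list(sprintf("%s%03d", prefix, seq_len(n_genes)),
                              sprintf("s%03d", seq_len(n_samples))))
  m
}

# compact synthetic study used by several unit-test files
tiny_config <- function(seed = 5) {
  synth_config(n_tfs = 6, n_genes = 240, targets_per_tf = 15,
               n_ref_samples = 60, n_pairs = 30, n_up_tfs = 2, n_down_tfs = 1,
               master_seed = seed)
}

# paired tumor/normal sheet for a matrix with columns t1..tn, n1..nn
paired_sheet <- function(n_pairs) {
  data.frame(sample_id = c(sprintf("t%02d", seq_len(n_pairs)),
                           sprintf("n%02d", seq_len(n_pairs))),
             group = rep(c("tumor", "normal"), each = n_pairs),
             pair_id = rep(sprintf("p%02d", seq_len(n_pairs)), 2))
}

# toy ontology:        root
#                     /    \
#                   mid1   mid2      (diamond: leaf1 under both mids)
#                   /   \  /
#                leaf0  leaf1
toy_ontology <- function() {
  ontology(id = c("GO:R", "GO:M1", "GO:M2", "GO:L0", "GO:L1"),
           name = c("root", "mid1", "mid2", "leaf0", "leaf1"),
           parents = list(`GO:R` = character(0), `GO:M1` = "GO:R",
                          `GO:M2` = "GO:R", `GO:L0` = "GO:M1",
                          `GO:L1` = c("GO:M1", "GO:M2")))
}
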