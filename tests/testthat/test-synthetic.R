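test_that("the generator is fully deterministic under the master seed", {
  cfg <- tiny_config(seed = 41)
  s1 <- simulate_regnet(cfg)
  s2 <- simulate_regnet(cfg)
  expect_identical(s1$truth$tf_targets, s2$truth$tf_targets)
  expect_identical(s1$truth$deregulated, s2$truth$deregulated)
  expect_identical(vapply(s1$promoters, `[[`, "", "sequence"),
                   vapply(s2$promoters, `[[`, "", "sequence"))
  expect_identical(s1$ref_raw, s2$ref_raw)
  expect_identical(s1$dataset_raw, s2$dataset_raw)
  expect_identical(s1$ppi, s2$ppi)
  expect_identical(s1$curated, s2$curated)
  s3 <- simulate_regnet(tiny_config(seed = 42))
  expect_false(identical(s1$truth$tf_targets, s3$truth$tf_targets))
})

test_that("planted truth respects the configured geometry", {
  cfg <- tiny_config(seed = 43)
  truth <- generate_truth(cfg)
  expect_length(truth$tfs, cfg$n_tfs)
  expect_true(all(lengths(truth$tf_targets) == cfg$targets_per_tf))
  # disjoint blocks by default
  expect_equal(anyDuplicated(unlist(truth$tf_targets)), 0)
  expect_equal(nrow(truth$deregulated), cfg$n_up_tfs + cfg$n_down_tfs)
  expect_true(all(truth$deregulated$tf_id %in% truth$tfs))
  # no deregulation requested
  cfg0 <- tiny_config(); cfg0$n_up_tfs <- 0; cfg0$n_down_tfs <- 0
  expect_equal(nrow(generate_truth(cfg0)$deregulated), 0)
  # impossible geometry
  bad <- tiny_config(); bad$targets_per_tf <- 1000
  expect_error(generate_truth(bad), "exceeds available genes")
  # overlapping target blocks share the configured fraction
  cfgo <- tiny_config(seed = 44); cfgo$target_overlap <- 0.4
  to <- generate_truth(cfgo)
  expect_true(all(lengths(to$tf_targets) == cfgo$targets_per_tf))
  expect_gt(anyDuplicated(unlist(to$tf_targets)), 0)
})

test_that("promoters carry recoverable planted sites for true pairs", {
  cfg <- tiny_config(seed = 45)
  cfg$site_plant_prob <- 1
  truth <- generate_truth(cfg)
  prom <- generate_promoters(truth, cfg)
  expect_true(all(grepl("^[ACGT]+$",
                        vapply(prom$promoters[1:20], `[[`, "", "sequence"))))
  # scan back every true pair: at full plant probability nearly all pairs
  # must yield a proximal hit
  mt <- motif_feature_table(prom$models, prom$promoters)
  hit <- logical(0)
  for (tf in truth$tfs) {
    cols <- paste(tf, ocregnet:::MOTIF_BIN_NAMES, sep = ".")
    hit <- c(hit, rowSums(mt[truth$tf_targets[[tf]], cols]) > 0)
  }
  expect_gte(mean(hit), 0.9)
  # without planting, true pairs hit at the background rate only
  cfg0 <- tiny_config(seed = 45); cfg0$site_plant_prob <- 0
  prom0 <- generate_promoters(generate_truth(cfg0), cfg0)
  mt0 <- motif_feature_table(prom0$models, prom0$promoters)
  tf1 <- truth$tfs[1]
  all_rate <- mean(mt0 > 0)
  true_rate <- mean(mt0[generate_truth(cfg0)$tf_targets[[tf1]],
                        paste(tf1, ocregnet:::MOTIF_BIN_NAMES, sep = ".")] > 0)
  expect_lt(abs(true_rate - all_rate), 0.1)
})

test_that("expression realizes the planted co-expression and deregulation", {
  cfg <- tiny_config(seed = 46)
  truth <- generate_truth(cfg)
  ex <- generate_expression(truth, cfg)
  ref <- normalize_expression(ex$ref_raw)
  # median TF-target correlation close to the planted level
  pccs <- unlist(lapply(truth$tfs, function(tf)
    pcc_profile(ref, tf, truth$tf_targets[[tf]])))
  expect_lt(abs(median(pccs) - cfg$planted_pcc), 0.1)
  # genes targeted by nobody stay uncorrelated with every TF
  free <- setdiff(truth$genes, unlist(truth$tf_targets))[1:30]
  null_pccs <- unlist(lapply(truth$tfs[1:3], function(tf)
    pcc_profile(ref, tf, free)))
  expect_lte(median(abs(null_pccs)), 0.2)
  # a null dataset calls (virtually) nothing differentially expressed
  ex0 <- generate_expression(truth, cfg, deregulation_lfc = 0)
  de0 <- differential_expression(normalize_expression(ex0$dataset_raw),
                                 ex0$samples)
  expect_lte(sum(de0$direction != "none"), 2)
  # pairing keys link tumor and normal columns one to one
  expect_equal(sort(table(ex$samples$pair_id)), sort(rep(2L, cfg$n_pairs)),
               ignore_attr = TRUE)
  cfg2 <- cfg; cfg2$n_pairs <- 2
  expect_error(generate_expression(truth, cfg2), "3")
})

test_that("the PPI neighborhood is informative about regulation", {
  cfg <- tiny_config(seed = 47)
  truth <- generate_truth(cfg)
  ppi <- generate_ppi(truth, cfg)
  for (tf in truth$tfs)
    expect_gte(length(ocregnet:::ppi_neighbors(ppi, tf)), 1)
  expect_identical(ppi, generate_ppi(truth, cfg))
  # a target's neighborhood-median correlation beats its background median
  ex <- generate_expression(truth, cfg)
  ref <- normalize_expression(ex$ref_raw)
  tf <- truth$tfs[1]
  cand <- truth$tf_targets[[tf]][1]
  nq <- neighborhood_quantiles(ref, ppi, tf, cand)
  bq <- background_quantiles(ref, cand, sample(truth$genes, 200))
  expect_gt(nq[2], bq[2])
})

test_that("curated subsets sample the true network exactly", {
  cfg <- tiny_config(seed = 48)
  truth <- generate_truth(cfg)
  n_edges <- sum(lengths(truth$tf_targets))
  full <- generate_curated_subset(truth, curated_fraction = 1)
  expect_equal(nrow(full), n_edges)
  half <- generate_curated_subset(truth, curated_fraction = 0.5)
  expect_equal(nrow(half), round(0.5 * n_edges))
  key <- function(df) paste(df$tf_id, df$gene_id)
  expect_true(all(key(half) %in% key(full)))
  expect_equal(names(half), c("tf_id", "gene_id", "mode", "source"))
  expect_error(generate_curated_subset(truth, curated_fraction = 0), "fraction")
})

test_that("recovery scoring demands matching direction", {
  truth <- list(deregulated = data.frame(tf_id = c("a", "b", "c"),
                                         direction = c("up", "up", "down")))
  perfect <- data.frame(tf_id = c("a", "b", "c"),
                        direction = c("up", "up", "down"))
  r <- score_recovery(perfect, truth)
  expect_equal(c(r$precision, r$recall), c(1, 1))
  disjoint <- data.frame(tf_id = "z", direction = "up")
  expect_equal(score_recovery(disjoint, truth)$precision, 0)
  # direction flip counts as both a miss and a false positive
  flipped <- data.frame(tf_id = "c", direction = "up")
  rf <- score_recovery(flipped, truth)
  expect_equal(rf$precision, 0)
  expect_equal(rf$recall, 0)
  none <- list(deregulated = data.frame(tf_id = character(),
                                        direction = character()))
  expect_true(is.na(score_recovery(perfect, none)$recall))
})
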