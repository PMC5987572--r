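# small helper: Gaussian blob pair features with plausible scales
blob_features <- function(n, seed = 1, shift = 0) {
  set.seed(seed)
  counts <- matrix(rpois(n * 12, 0.4), ncol = 12)
  coexpr <- cbind(runif(n, .4, .9), matrix(runif(n * 6, -.2, .6), ncol = 6))
  X <- cbind(counts, coexpr + shift)
  colnames(X) <- ocregnet:::PAIR_FEATURE_NAMES
  structure(list(tf_id = rep("tf1", n),
                 gene_id = sprintf("g%04d", seq_len(n)), X = X),
            class = "pair_features")
}

test_that("the scaler freezes on positives and is idempotent", {
  pf <- blob_features(100)
  expect_error(scale_pair_features(pair_scaler(), pf), "not been fitted")
  sc <- fit_pair_scaler(pf)
  z <- scale_pair_features(sc, pf)
  expect_true(isTRUE(attr(z$X, "scaled")))
  expect_equal(unname(colMeans(z$X)), rep(0, 19), tolerance = 1e-12)
  expect_equal(unname(apply(z$X, 2, sd)), rep(1, 19), tolerance = 1e-12)
  # applying the transform to already-scaled features changes nothing
  expect_identical(scale_pair_features(sc, z)$X, z$X)
  # deterministic: two identical calls give identical vectors
  v1 <- assemble_feature_vector(rep(0, 12), rep(0, 7), sc)
  v2 <- assemble_feature_vector(rep(0, 12), rep(0, 7), sc)
  expect_identical(v1, v2)
  expect_equal(unname(v1), unname(-sc$center / sc$scale))
  expect_error(assemble_feature_vector(rep(0, 11), rep(0, 7), sc), "12")
  expect_error(assemble_feature_vector(rep(0, 12), rep(0, 6), sc), "7")
})

test_that("pair_feature_matrix joins motif bins with co-expression", {
  set.seed(10)
  models <- list(build_pwm(random_pfm(6), tf_id = "tfA"))
  proms <- lapply(1:5, function(i)
    promoter_record(paste0("g", i), random_dna(2000), 1000))
  mt <- motif_feature_table(models, proms, p_threshold = 0.001)
  expr <- random_expr(10, 30, seed = 1, prefix = "gg")
  rownames(expr)[1:6] <- c("tfA", paste0("g", 1:5))
  cx <- coexpr_feature_table(expr, data.frame(a = "tfA", b = "g1"), "tfA",
                             candidates = paste0("g", 1:5), n_background = 4)
  pf <- pair_feature_matrix(mt, cx, pairs = data.frame(tf_id = "tfA",
                                                       gene_id = c("g2", "g4")))
  expect_equal(dim(pf$X), c(2, 19))
  expect_equal(unname(pf$X[1, 1:12]),
               unname(mt["g2", paste("tfA", ocregnet:::MOTIF_BIN_NAMES, sep = ".")]))
  expect_equal(unname(pf$X[2, 13:19]), unname(cx$tfA["g4", ]))
  # pairs without features are dropped with a warning
  expect_warning(pd <- pair_feature_matrix(mt, cx,
    pairs = data.frame(tf_id = "tfA", gene_id = c("g1", "nope"))), "dropped")
  expect_equal(pd$gene_id, "g1")
})

test_that("synthetic negatives are reproducible and carry real labels", {
  set.seed(2)
  models <- list(build_pwm(random_pfm(7), tf_id = "tfA"),
                 build_pwm(random_pfm(7), tf_id = "tfB"))
  expr <- random_expr(15, 30, seed = 3)
  cx <- coexpr_feature_table(expr, data.frame(a = "g001", b = "g002"),
                             c("g001", "g002"), n_background = 5)
  names(cx) <- c("tfA", "tfB")
  n1 <- synthesize_negatives(models, cx, n_seq = 6, length = 1500, seed = 7)
  n2 <- synthesize_negatives(models, cx, n_seq = 6, length = 1500, seed = 7)
  expect_identical(n1$X, n2$X)
  n3 <- synthesize_negatives(models, cx, n_seq = 6, length = 1500, seed = 8)
  expect_false(identical(n1$X, n3$X))
  expect_equal(nrow(n1$X), 12)  # one row per (TF, synthetic gene)
  # co-expression block is copied verbatim from the drawn real-gene label
  lab <- n1$labels[n1$gene_id[1]]
  expect_equal(unname(n1$X[1, 13:19]), unname(cx[[n1$tf_id[1]]][lab, ]))
  # the published construction is the default geometry
  expect_equal(eval(formals(synthesize_negatives)$n_seq), 1000)
  expect_equal(eval(formals(synthesize_negatives)$length), 20000)
})

test_that("one-class training honors the nu bound and rejects far outliers", {
  gauss <- function(n, seed) {
    set.seed(seed)
    X <- matrix(rnorm(n * 19, sd = 0.5), ncol = 19,
                dimnames = list(NULL, ocregnet:::PAIR_FEATURE_NAMES))
    attr(X, "scaled") <- TRUE
    X
  }
  z <- gauss(800, 4)
  for (nu in c(0.05, 0.1, 0.3, 0.5)) {
    m <- ocsvm_train(z, nu, gamma = 2^-5)
    expect_lte(1 - mean(ocregnet:::ocsvm_accept(m, z)), nu + 0.02)
  }
  # fresh in-distribution points from the tight blob are mostly accepted
  fresh <- gauss(500, 5)
  m <- ocsvm_train(z, 0.1, 2^-5)
  expect_gte(mean(ocregnet:::ocsvm_accept(m, fresh)), 0.85)
  # points ten standard deviations away are rejected
  far <- fresh + 10
  expect_equal(mean(ocregnet:::ocsvm_accept(m, far)), 0)
  expect_error(ocsvm_train(z[1:10, ], 0.1, 2^-5), "at least 20")
  expect_error(ocsvm_train(matrix(1, 30, 19), 0.1, 2^-5), "degenerate")
  expect_error(ocsvm_train(z, 1.2, 2^-5), "nu")
})

test_that("grid evaluation is deterministic and internally consistent", {
  pf <- blob_features(120, seed = 6)
  sc <- fit_pair_scaler(pf)
  z <- scale_pair_features(sc, pf)$X
  # negatives drawn from the identical distribution as the positives
  neg <- scale_pair_features(sc, blob_features(300, seed = 61))$X
  g1 <- ocsvm_grid_eval(z, neg, nu_grid = c(0.1, 0.5), gamma_grid = 2^-5,
                        folds = 5, seed = 3)
  g2 <- ocsvm_grid_eval(z, neg, nu_grid = c(0.1, 0.5), gamma_grid = 2^-5,
                        folds = 5, seed = 3)
  expect_identical(g1, g2)
  # indistinguishable classes: FPR tracks held-out sensitivity
  expect_true(all(abs(g1$fpr - g1$sensitivity) <= 0.05))
  expect_error(ocsvm_grid_eval(z[1:3, ], neg, folds = 10), "fewer positives")
  expect_error(ocsvm_grid_eval(z, neg, nu_grid = numeric(0)), "non-empty")
})

test_that("model selection maximizes sensitivity under the FPR ceiling", {
  rec <- data.frame(nu = c(0.1, 0.5, 0.9), gamma = rep(2^-5, 3),
                    sensitivity = c(0.8, 0.5, 0.4),
                    fpr = c(0.05, 0.002, 0.001),
                    n_eval_pos = 100, n_eval_neg = 100)
  pick <- select_model(rec, 0.002)
  expect_equal(pick$sensitivity, 0.5)
  # vacuous ceiling: the most sensitive record wins
  expect_equal(select_model(rec, 1)$sensitivity, 0.8)
  # nothing qualifies: minimal-FPR record plus a warning flag
  expect_warning(fallback <- select_model(rec, 1e-5), "minimal-FPR")
  expect_equal(fallback$fpr, 0.001)
  expect_true(attr(fallback, "warned"))
  # ties break toward smaller nu then smaller gamma
  tie <- data.frame(nu = c(0.5, 0.1), gamma = c(2^-5, 2^-8),
                    sensitivity = 0.6, fpr = 0.001,
                    n_eval_pos = 10, n_eval_neg = 10)
  expect_equal(select_model(tie, 0.002)$nu, 0.1)
})

test_that("network prediction accepts training positives and summarizes degrees", {
  pf <- blob_features(200, seed = 9)
  sc <- fit_pair_scaler(pf)
  z <- scale_pair_features(sc, pf)
  nu <- 0.2
  m <- ocsvm_train(z$X, nu, 2^-5)
  net <- predict_network(m, z, block_size = 64)
  expect_gte(nrow(net$edges) / nrow(z$X), 1 - nu - 0.02)
  expect_error(predict_network(m, pf), "scaled")
  empty <- z; empty$X <- z$X[0, , drop = FALSE]
  empty$tf_id <- character(0); empty$gene_id <- character(0)
  expect_equal(nrow(predict_network(m, empty)$edges), 0)
  # degree summaries against a direct recount
  toy <- structure(list(edges = data.frame(tf_id = c("a", "a", "b"),
                                           gene_id = c("x", "y", "x")),
                        tfs = c("a", "b"), genes = c("x", "y", "z")),
                   class = "regulatory_network")
  s <- network_degree_summary(toy)
  expect_equal(s$per_tf$out_degree[s$per_tf$tf_id == "a"], 2L)
  expect_equal(s$per_gene$in_degree[s$per_gene$gene_id == "z"], 0L)
  expect_equal(unname(s$gene_summary["min"]), 0)
  one <- toy; one$edges <- one$edges[3, ]
  s1 <- network_degree_summary(one)
  expect_equal(s1$per_tf$out_degree, c(0L, 1L))
})

test_that("the ocsvm_regnet fit bundles scaler, grid, selection and model", {
  pos <- blob_features(120, seed = 12)
  neg <- blob_features(400, seed = 13, shift = -2)  # displaced negatives
  fit <- ocsvm_regnet(pos, neg, nu_grid = c(0.1, 0.5), gamma_grid = 2^c(-5, -8),
                      folds = 5, target_fpr = 0.05, seed = 1)
  expect_s3_class(fit, "ocsvm_regnet")
  expect_equal(nrow(fit$grid), 4)
  expect_true(fit$selected$fpr <= 0.05 || isTRUE(attr(fit$selected, "warned")))
  acc <- predict(fit, pos, type = "accept")
  expect_gte(mean(acc), 1 - fit$selected$nu - 0.05)
  net <- predict(fit, neg)
  expect_s3_class(net, "regulatory_network")
  expect_lte(nrow(net$edges) / nrow(neg$X), 2 * max(fit$grid$fpr) + 0.05)
  expect_output(print(fit), "selected")
  expect_output(print(summary(fit)), "Target FPR")
})
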