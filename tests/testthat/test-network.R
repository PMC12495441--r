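test_that("forward pass yields finite per-task outputs, isolated per example", {
  cfg <- toy_net_config()
  net <- build_network(cfg, seed = 1)
  ex <- toy_embedding_pair(seed = 1)
  out <- dtaforge:::.forward_example(net$params, cfg, ex$Xm, ex$Xp)$out
  expect_length(out, 2)
  expect_true(all(is.finite(out)))
  # no cross-example state: the same example gives the same output regardless
  # of what else is in the batch
  ex2 <- toy_embedding_pair(seed = 2)
  b1 <- dtaforge:::network_loss_grads(net, list(ex), matrix(c(5, 6), 1),
                                      weights = 1)
  b2 <- dtaforge:::network_loss_grads(net, list(ex, ex2),
                                      matrix(c(5, 7, 6, 8), 2), weights = c(1, 1))
  expect_equal(b2$predictions[1, ], b1$predictions[1, ])
  # width mismatch is rejected
  expect_error(dtaforge:::.forward_example(net$params, cfg, ex$Xp, ex$Xp),
               "width")
})

test_that("attention cost splits into per-sequence quadratic terms", {
  cfg <- toy_net_config()
  counts <- attention_entry_count(cfg, len_m = 30, len_p = 100)
  expect_equal(unname(counts["encoder_self"]), 1 * 100^2)
  expect_equal(unname(counts["decoder_self"]), 2 * 30^2)
  expect_equal(unname(counts["cross"]), 2 * 30 * 100)
  # per layer the conditioned design beats the concatenated one
  per_layer <- 100^2 + 30^2 + 30 * 100
  expect_lt(per_layer, (100 + 30)^2)
})

test_that("masked weighted loss: analytic values, masking, weight-duplication identity", {
  # all present, unit weights -> plain MSE
  p <- matrix(c(1, 2, 3, 4), 2)
  t <- matrix(c(2, 2, 5, 0), 2)
  expect_equal(masked_weighted_loss(p, t), mean((p - t)^2))
  # hand-computed analytic case with a missing cell and weights
  p2 <- matrix(c(5, 17), 1)
  t2 <- matrix(c(5, NA), 1)
  expect_equal(masked_weighted_loss(p2, t2, weights = 3), 0)
  p3 <- matrix(c(1, 4, 2, 100), 2)
  t3 <- matrix(c(2, 2, 1, NA), 2)   # cells: (1,1)e=-1 (2,1)e=2 (1,2)e=1
  w3 <- c(1, 3)
  expect_equal(masked_weighted_loss(p3, t3, w3),
               (1 * 1 + 3 * 4 + 1 * 1) / (1 + 3 + 1))
  # doubling a weight equals duplicating the example
  pd <- rbind(p3, p3[2, ]); td <- rbind(t3, t3[2, ])
  expect_equal(masked_weighted_loss(pd, td, c(1, 3, 3)),
               masked_weighted_loss(p3, t3, c(1, 6)))
  expect_error(masked_weighted_loss(p2, matrix(c(NA, NA), 1)), "missing")
  # zero at perfect prediction, positive otherwise
  expect_equal(masked_weighted_loss(t, t), 0)
  expect_gt(masked_weighted_loss(p, t), 0)
})

test_that("analytic gradients match finite differences everywhere", {
  cfg <- dta_network_config(d_model = 8L, protein_width = 12L,
                            encoder_layers = 1L, decoder_layers = 2L,
                            attention_heads = 2L, feedforward_width = 16L,
                            dropout = 0, conv_kernel = 3L)
  net <- build_network(cfg, seed = 42)
  batch <- list(toy_embedding_pair(5, 7, seed = 7),
                toy_embedding_pair(4, 6, seed = 8))
  targets <- matrix(c(5, NA, 6.5, 7), 2, 2)
  weights <- c(1, 2)
  lg <- dtaforge:::network_loss_grads(net, batch, targets, weights)
  eps <- 1e-6
  withr::with_seed(1, {
    for (nm in names(net$params)) {
      p <- net$params[[nm]]
      for (i in sample(length(p), min(2, length(p)))) {
        net2 <- net
        net2$params[[nm]][i] <- p[i] + eps
        lp <- dtaforge:::network_loss_grads(net2, batch, targets, weights)$loss
        net2$params[[nm]][i] <- p[i] - eps
        lm <- dtaforge:::network_loss_grads(net2, batch, targets, weights)$loss
        num <- (lp - lm) / (2 * eps)
        ana <- lg$grads[[nm]][i]
        expect_lt(abs(num - ana) / max(1e-4, abs(num) + abs(ana)), 1e-3)
      }
    }
  })
})

test_that("a batch with one task everywhere missing gives that head zero gradient", {
  cfg <- toy_net_config()
  net <- build_network(cfg, seed = 3)
  batch <- list(toy_embedding_pair(seed = 4), toy_embedding_pair(seed = 5))
  targets <- matrix(c(5.5, 6.5, NA, NA), 2, 2)   # task 2 all missing
  lg <- dtaforge:::network_loss_grads(net, batch, targets, c(1, 1))
  expect_equal(lg$grads[["head.W"]][, 2], rep(0, cfg$d_model))
  expect_equal(lg$grads[["head.b"]][2], 0)
  expect_gt(sum(abs(lg$grads[["head.W"]][, 1])), 0)
})

test_that("training runs, respects patience, and is seed-reproducible", {
  withr::with_seed(10, {
    pairs <- tibble::tibble(
      protein_sequence = replicate(10, paste(sample(c("A", "C", "D", "E"), 60,
                                                    TRUE), collapse = "")),
      canonical_smiles = replicate(10, paste(sample(c("C", "N", "O"), 8, TRUE),
                                             collapse = "")),
      p_ki = rnorm(10, 6), p_ic50 = rnorm(10, 6), weight = 1
    )
  })
  lig <- synthetic_provider(dim = 8, seed = 1)
  pro <- synthetic_provider(dim = 12, seed = 2)
  fold <- list(train = pairs[1:8, ], validation = pairs[9:10, ])
  # patience 0 stops after exactly one epoch
  sm0 <- train_fold(fold, toy_net_config(),
                    dta_train_config(max_epochs = 10, patience = 0, seed = 1,
                                     batch_size = 4),
                    lig, pro)
  expect_equal(nrow(sm0$manifest), 1L)
  # identical seeds give bit-identical loss trajectories
  tc <- dta_train_config(max_epochs = 3, patience = 3, seed = 7,
                         batch_size = 4, learning_rate = 1e-3)
  sm1 <- train_fold(fold, toy_net_config(), tc, lig, pro)
  sm2 <- train_fold(fold, toy_net_config(), tc, lig, pro)
  expect_identical(sm1$manifest, sm2$manifest)
  expect_true(all(is.finite(sm1$manifest$train_loss)))
})

test_that("toy training reduces validation loss on a learnable task", {
  cfg <- generator_config(n_proteins = 10, n_ligands = 40, n_pairs = 120,
                          noise_sd = 0.2, seed = 31)
  pairs <- suppressWarnings(generate_pair_table(cfg))
  lig <- synthetic_provider(dim = 16, seed = 1)
  pro <- synthetic_provider(dim = 24, seed = 2)
  net_cfg <- dta_network_config(d_model = 16, protein_width = 24,
                                encoder_layers = 1, decoder_layers = 1,
                                attention_heads = 2, feedforward_width = 32,
                                dropout = 0)
  tc <- dta_train_config(learning_rate = 3e-3, batch_size = 16,
                         max_epochs = 6, patience = 6, seed = 5)
  fold <- list(train = pairs[1:90, ], validation = pairs[91:120, ])
  sm <- train_fold(fold, net_cfg, tc, lig, pro)
  expect_lt(dplyr::last(sm$manifest$val_loss), sm$manifest$val_loss[1])
})

test_that("ensemble prediction is the arithmetic mean of submodels", {
  pairs <- tibble::tibble(
    protein_sequence = strrep("ACDEFGHIKL", 6),
    canonical_smiles = c("CCO", "CCN"),
    p_ki = c(5, 6), p_ic50 = c(6, 7), weight = 1
  )
  lig <- synthetic_provider(dim = 8, seed = 1)
  pro <- synthetic_provider(dim = 12, seed = 2)
  cfg <- toy_net_config()
  tc <- dta_train_config(max_epochs = 1, patience = 0, seed = 1,
                         batch_size = 2)
  # duplicate one trained submodel: ensemble of identical submodels equals it
  fold <- list(train = pairs, validation = pairs)
  sm <- train_fold(fold, cfg, tc, lig, pro)
  ens1 <- structure(list(submodels = list(sm), config = cfg, k = 1, seed = 1),
                    class = "dta_ensemble")
  ens3 <- structure(list(submodels = list(sm, sm, sm), config = cfg, k = 3,
                         seed = 1), class = "dta_ensemble")
  p1 <- predict_ensemble(ens1, pairs, lig, pro)
  p3 <- predict_ensemble(ens3, pairs, lig, pro)
  expect_equal(p1$pKi_pred, p3$pKi_pred)
  expect_equal(p1$pIC50_pred, p3$pIC50_pred)
  # permuting submodels leaves the mean unchanged; distinct submodels average
  sm2 <- train_fold(fold, cfg, dta_train_config(max_epochs = 1, patience = 0,
                                                seed = 9, batch_size = 2),
                    lig, pro)
  ens_ab <- structure(list(submodels = list(sm, sm2), config = cfg, k = 2,
                           seed = 1), class = "dta_ensemble")
  ens_ba <- structure(list(submodels = list(sm2, sm), config = cfg, k = 2,
                           seed = 1), class = "dta_ensemble")
  pab <- predict_ensemble(ens_ab, pairs, lig, pro)
  pba <- predict_ensemble(ens_ba, pairs, lig, pro)
  expect_equal(pab$pKi_pred, pba$pKi_pred)
  pa <- predict_ensemble(ens1, pairs, lig, pro)
  pb <- predict_ensemble(structure(list(submodels = list(sm2), config = cfg,
                                        k = 1, seed = 1),
                                   class = "dta_ensemble"), pairs, lig, pro)
  expect_equal(pab$pKi_pred, (pa$pKi_pred + pb$pKi_pred) / 2)
  # empty ensemble errors
  expect_error(predict_ensemble(structure(list(submodels = list(),
                                               config = cfg),
                                          class = "dta_ensemble"),
                                pairs, lig, pro), "no submodels")
})

test_that("k-fold ensembling trains each example k-1 times across folds", {
  withr::with_seed(11, {
    pairs <- tibble::tibble(
      protein_sequence = replicate(12, paste(sample(LETTERS[1:4], 55, TRUE),
                                             collapse = "")),
      canonical_smiles = replicate(12, paste(sample(c("C", "N", "O"), 6, TRUE),
                                             collapse = "")),
      p_ki = rnorm(12, 6), p_ic50 = NA_real_, weight = 1
    )
  })
  folds <- kfold(pairs, k = 3, seed = 4)
  seen <- unlist(lapply(folds, function(f) f$train$protein_sequence))
  counts <- table(seen)
  expect_true(all(counts == 2))   # k - 1
  vals <- unlist(lapply(folds, function(f) f$validation$protein_sequence))
  expect_setequal(vals, pairs$protein_sequence)
})

test_that("multitask training transfers signal to a half-missing task", {
  # correlated latent tasks; half the pIC50 labels removed. With a shared
  # trunk, the pKi labels should not hurt -- and typically help -- the pIC50
  # validation error at an equal training budget, once both runs are allowed
  # to reach their early-stopping optimum (at short truncated budgets the
  # second task mechanically halves the first task's effective step size).
  # Averaged over seeds to damp noise.
  deltas <- vapply(c(101, 202, 303), function(seed) {
    cfg <- generator_config(n_proteins = 10, n_ligands = 50, n_pairs = 150,
                            protein_length_range = c(50, 80),
                            noise_sd = 0.2, task_correlation = 0.8,
                            missing_ki = 0, missing_ic50 = 0, seed = seed)
    pairs <- suppressWarnings(generate_pair_table(cfg))
    withr::with_seed(seed, {
      drop_ic <- sample(nrow(pairs), round(0.5 * nrow(pairs)))
    })
    pairs$p_ic50[drop_ic] <- NA
    fold <- list(train = pairs[1:110, ], validation = pairs[111:150, ])
    lig <- synthetic_provider(dim = 16, seed = 1)
    pro <- synthetic_provider(dim = 24, seed = 2)
    net_cfg <- dta_network_config(d_model = 16, protein_width = 24,
                                  encoder_layers = 1, decoder_layers = 1,
                                  attention_heads = 2, feedforward_width = 32,
                                  dropout = 0)
    tc <- dta_train_config(learning_rate = 3e-3, batch_size = 16,
                           max_epochs = 40, patience = 5, seed = seed)
    multi <- train_fold(fold, net_cfg, tc, lig, pro)
    single_pairs <- fold
    single_pairs$train$p_ki <- NA_real_
    single_pairs$validation$p_ki <- NA_real_
    single <- train_fold(single_pairs, net_cfg, tc, lig, pro)
    val <- fold$validation[!is.na(fold$validation$p_ic50), ]
    cache <- embedding_cache()
    rmse_of <- function(sm) {
      ens <- structure(list(submodels = list(sm),
                            config = net_cfg, k = 1, seed = 1),
                       class = "dta_ensemble")
      pred <- predict_ensemble(ens, val, lig, pro, cache)
      mse_rmse(pred$pIC50_pred, val$p_ic50)[["rmse"]]
    }
    rmse_of(single) - rmse_of(multi)
  }, numeric(1))
  expect_gte(mean(deltas), 0)
})
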