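test_that("stratified split preserves dataset x label shares", {
  samples <- tibble::tibble(
    gene_id = sprintf("G%03d", 1:100),
    dataset_id = "d1",
    label = rep(c(1L, 0L), c(10, 90)))
  sp <- stratified_split(samples, val_fraction = 0.2, seed = 1)
  expect_equal(sum(sp$.split == "validation" & sp$label == 1), 2L)
  expect_equal(sum(sp$.split == "validation" & sp$label == 0), 18L)
  # disjoint and exhaustive
  expect_equal(sort(unique(sp$.split)), c("train", "validation"))
  expect_equal(nrow(sp), 100L)
  # deterministic under a fixed seed
  sp2 <- stratified_split(samples, val_fraction = 0.2, seed = 1)
  expect_identical(sp$.split, sp2$.split)
  # exact .5 resolves toward the floor: 0.2 * 12 = 2.4 -> 2; 0.5 frac of 5 -> 2
  s5 <- tibble::tibble(gene_id = sprintf("G%d", 1:5), dataset_id = "d",
                       label = 0L)
  sp5 <- stratified_split(s5, val_fraction = 0.5, seed = 1)
  expect_equal(sum(sp5$.split == "validation"), 2L)
  # a stratum too small for validation goes to train with a warning
  tiny <- tibble::tibble(gene_id = c("A", "B"), dataset_id = "d",
                         label = c(1L, 0L))
  # both strata are too small, so two warnings are raised
  expect_warning(expect_warning(spt <- stratified_split(tiny, 0.2, seed = 1),
                                "train"), "train")
  expect_true(all(spt$.split == "train"))
})

test_that("early stopping terminates at last improvement + patience and keeps best state", {
  # contrived trajectory: improvement only up to epoch k = 7
  k <- 7L
  losses <- c(seq(1.0, 0.4, length.out = k), rep(0.5, 100))
  loop <- early_stopping_loop(
    step_fn = function(e) losses[e],
    eval_fn = function(e) list(loss = losses[e], state = list(epoch = e)),
    max_epochs = 200L, patience = 30L)
  expect_equal(loop$stopped_epoch, k + 30L)
  expect_equal(loop$best_epoch, k)
  expect_equal(loop$best_state$epoch, k)  # epoch-k parameters returned
  expect_equal(nrow(loop$history), k + 30L)

  # max_epochs caps the run when improvement never stalls long enough
  loop2 <- early_stopping_loop(
    step_fn = function(e) 1 / e,
    eval_fn = function(e) list(loss = 1 / e, state = e),
    max_epochs = 25L, patience = 10L)
  expect_equal(loop2$stopped_epoch, 25L)
  expect_equal(loop2$best_epoch, 25L)

  # divergence is an error naming the epoch
  expect_error(early_stopping_loop(function(e) NaN,
                                   function(e) list(loss = 1, state = e),
                                   10L, 3L),
               "epoch 1")
})

test_that("training learns the planted signal and records its history", {
  sim <- small_sim()
  fit <- gat_train(sim$features, sim$network, gat_config(),
                   train_config(max_epochs = 60, patience = 20, seed = 42))
  expect_s3_class(fit, "gat_fit")
  # best validation loss beats the first epoch (there is learnable signal)
  expect_lt(fit$history$val_loss[fit$best_epoch], fit$history$val_loss[1])
  # early stopping never returns parameters from after the best epoch
  expect_lte(fit$best_epoch, fit$stopped_epoch)
  expect_equal(nrow(fit$history), fit$stopped_epoch)

  # reproducibility: same seeds, identical scores
  fit2 <- gat_train(sim$features, sim$network, gat_config(),
                    train_config(max_epochs = 60, patience = 20, seed = 42))
  sc1 <- score_genes(fit, sim$network, sim$features)
  sc2 <- score_genes(fit2, sim$network, sim$features)
  expect_identical(sc1$raw_score, sc2$raw_score)

  # the fitted model separates planted functional genes from the rest
  expect_gt(auroc(sc1, sim$truth), 0.8)

  # broom-style accessors
  td <- tidy(fit)
  expect_equal(sort(unique(td$split)), c("train", "validation"))
  gl <- glance(fit)
  expect_equal(gl$best_epoch, fit$best_epoch)
  expect_gt(gl$n_parameters, 0)
  expect_s3_class(ggplot2::autoplot(fit), "ggplot")
})

test_that("scoring normalizes, ranks and selects top genes deterministically", {
  # closed-form check of the normalizers on a fixed vector
  x <- c(0.2, 0.5, 0.8)
  expect_equal(gatm5c:::normalize_minmax(x), c(0, 0.5, 1))
  expect_equal(gatm5c:::normalize_z(c(1, 2, 3)),
               c(-1.2247449, 0, 1.2247449), tolerance = 1e-6)
  # degenerate rules
  expect_equal(gatm5c:::normalize_minmax(c(2, 2)), c(0.5, 0.5))
  expect_equal(gatm5c:::normalize_z(c(2, 2)), c(0, 0))

  sim <- small_sim()
  fit <- gat_train(sim$features, sim$network, gat_config(),
                   train_config(max_epochs = 10, patience = 5, seed = 1))
  sc <- score_genes(fit, sim$network, sim$features)
  expect_equal(nrow(sc), length(sim$network$nodes))
  expect_true(all(sc$raw_score > 0 & sc$raw_score < 1))
  expect_equal(sc$rank, seq_len(nrow(sc)))
  expect_equal(min(sc$minmax_score), 0)
  expect_equal(max(sc$minmax_score), 1)
  # ranks follow raw scores with lexicographic tie-break
  expect_true(all(diff(sc$raw_score) <= 0))
  top <- top_genes(sc, 20)
  expect_equal(top, sc$gene_id[1:20])
})
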