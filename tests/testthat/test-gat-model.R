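test_that("configuration invariants are enforced", {
  cfg <- gat_config()
  expect_equal(cfg$layer_in, c(2L, 32L, 32L))  # concat of 2 x 16 feeds layers 2-3
  expect_error(gat_config(dropout = 1), "dropout")
  expect_error(train_config(patience = 200, max_epochs = 200), "patience")
})

test_that("parameter initialization is seeded and shape-consistent", {
  cfg <- gat_config()
  p1 <- init_gat_parameters(cfg, 3, seed = 5)
  p2 <- init_gat_parameters(cfg, 3, seed = 5)
  p3 <- init_gat_parameters(cfg, 3, seed = 6)
  expect_identical(p1, p2)
  expect_false(identical(p1, p3))
  expect_silent(gatm5c:::check_shapes(p1, cfg))
  expect_equal(dim(p1$layers[[1]]$heads[[1]]$W), c(2L, 16L))
  expect_equal(dim(p1$layers[[2]]$heads[[2]]$W), c(32L, 16L))
  expect_equal(dim(p1$layers[[3]]$heads[[1]]$W), c(32L, 1L))
  expect_equal(dim(p1$layers[[1]]$edge_embed), c(4L, 32L))  # 3 types + self
  expect_true(all(p1$layers[[1]]$heads[[1]]$bias == 0))
})

test_that("attention coefficients normalize per node and match the scalar oracle", {
  net <- triangle_net()
  cfg <- gat_config()
  params <- init_gat_parameters(cfg, length(net$edge_type_vocab), seed = 2)
  x <- matrix(rnorm(6), 3, 2, dimnames = list(net$nodes, NULL))

  a <- attention_coefficients(net, x, params, cfg, layer = 1, head = 1)
  sums <- tapply(a$alpha, a$target, sum)
  expect_true(all(abs(sums - 1) < 1e-6))
  expect_true(all(a$alpha >= 0))

  # independent per-edge scalar recomputation of the attention formula
  ref <- reference_attention(net, x, params, cfg, layer = 1, head = 1)
  merged <- dplyr::inner_join(a, ref, by = c("source", "target"),
                              suffix = c("", "_ref"))
  expect_equal(nrow(merged), nrow(a))
  expect_equal(merged$alpha, merged$alpha_ref, tolerance = 1e-10)

  # second layer / second head against the oracle too
  x2 <- matrix(rnorm(3 * 32), 3, 32)
  a2 <- attention_coefficients(net, x2, params, cfg, layer = 2, head = 2)
  ref2 <- reference_attention(net, x2, params, cfg, layer = 2, head = 2)
  m2 <- dplyr::inner_join(a2, ref2, by = c("source", "target"),
                          suffix = c("", "_ref"))
  expect_equal(m2$alpha, m2$alpha_ref, tolerance = 1e-10)

  expect_error(attention_coefficients(net, x * NA, params, cfg), "finite")
})

test_that("isolated and symmetric neighborhoods give the forced coefficients", {
  # a node with only its self-loop: alpha_ii = 1
  rec <- edge_records(list(c("A", "B")))
  net <- build_network(rec)
  net2 <- star_net(2)  # HUB with two leaves sharing features and edge type
  cfg <- gat_config()
  params <- init_gat_parameters(cfg, 1, seed = 4)

  lone <- build_network(edge_records(list(c("A", "B"), c("C", "D"))))
  x <- matrix(0, 4, 2, dimnames = list(lone$nodes, NULL))
  a <- attention_coefficients(lone, x, params, cfg)
  # with all-equal features every in-neighborhood is uniform
  self_only <- a[a$target == a$source & a$target == "A", ]
  expect_equal(sum(a$alpha[a$target == "A"]), 1, tolerance = 1e-12)

  # two identical neighbors + self-loop with identical features and a
  # shared (null) edge-type term: each coefficient is exactly 1/3
  pz <- params
  pz$layers[[1]]$edge_embed[] <- 0
  xs <- matrix(1, 3, 2, dimnames = list(net2$nodes, NULL))
  as_ <- attention_coefficients(net2, xs, pz, cfg)
  hub <- as_[as_$target == "HUB", ]
  expect_equal(hub$alpha, rep(1 / 3, 3), tolerance = 1e-10)
})

test_that("forward pass honors symmetry, permutation equivariance and determinism", {
  cfg <- gat_config()
  net <- path_net(c("A", "B", "C", "D"))
  params <- init_gat_parameters(cfg, 1, seed = 9)
  x <- matrix(c(1, -1, -1, 1, 0.5, 0.2, 0.2, 0.5), 4, 2,
              dimnames = list(net$nodes, NULL))

  # zeroed final layer: sigmoid(0) = 0.5 everywhere
  p0 <- params
  p0$layers[[3]]$heads[[1]]$W[] <- 0
  p0$layers[[3]]$heads[[1]]$bias[] <- 0
  p0$layers[[3]]$heads[[1]]$a_src[] <- 0
  p0$layers[[3]]$heads[[1]]$a_dst[] <- 0
  s0 <- gat_forward(net, x, p0, cfg)
  expect_equal(s0$score, rep(0.5, 4))

  # structurally interchangeable nodes with identical features score equally:
  # A and D (path ends) mirror each other, as do B and C
  s <- gat_forward(net, x, params, cfg)
  expect_equal(s$score[s$gene_id == "A"], s$score[s$gene_id == "D"], tolerance = 1e-12)
  expect_equal(s$score[s$gene_id == "B"], s$score[s$gene_id == "C"], tolerance = 1e-12)

  # eval mode is a pure function
  expect_identical(s, gat_forward(net, x, params, cfg))

  # permutation equivariance: relabeling nodes permutes scores exactly
  relabel <- c(A = "W", B = "Z", C = "Q", D = "M")
  rec <- edge_records(list(c("W", "Z"), c("Z", "Q"), c("Q", "M")))
  pnet <- build_network(rec)
  px <- x[match(pnet$nodes, relabel[net$nodes]), , drop = FALSE]
  ps <- gat_forward(pnet, px, params, cfg)
  expect_equal(ps$score[match(relabel[s$gene_id], ps$gene_id)], s$score,
               tolerance = 1e-12)

  # shape mismatch against config errors
  expect_error(gat_forward(net, x[, 1, drop = FALSE], params, cfg), "columns")
})

test_that("analytic gradients match central finite differences on a small fixture", {
  sim <- generate_synthetic(synthetic_spec(n_genes = 10, n_datasets = 1,
                                           attachment_edges = 2, seed = 5))
  net <- sim$network
  al <- align_features(net, sim$features, "sim01")
  cfg <- gat_config(dropout = 0)  # deterministic train-mode pass
  params <- init_gat_parameters(cfg, 1, seed = 11)
  ea <- gatm5c:::edge_arrays(net)
  theta <- gatm5c:::flatten_params(params)
  loss_at <- function(th) {
    pp <- gatm5c:::unflatten_params(th, params)
    f <- gatm5c:::gat_forward_cached(ea, al$x, pp, cfg, train = TRUE)
    gatm5c:::bce_masked(f$logit, al$y, seq_along(al$y))$loss
  }
  fw <- gatm5c:::gat_forward_cached(ea, al$x, params, cfg, train = TRUE)
  lo <- gatm5c:::bce_masked(fw$logit, al$y, seq_along(al$y))
  gr <- gatm5c:::flatten_params(gatm5c:::gat_backward(ea, fw, lo$dlogit, params, cfg))

  idx <- withr::with_seed(1, sample(which(gatm5c:::trainable_mask(params)), 80))
  eps <- 1e-5
  fd <- vapply(idx, function(i) {
    up <- replace(theta, i, theta[i] + eps)
    dn <- replace(theta, i, theta[i] - eps)
    (loss_at(up) - loss_at(dn)) / (2 * eps)
  }, numeric(1))
  rel <- abs(gr[idx] - fd) / pmax(abs(fd), 1e-6)
  expect_lt(max(rel), 1e-4)
})

test_that("checkpoints round-trip parameters and validate shapes", {
  sim <- small_sim()
  fit <- gat_train(sim$features, sim$network, gat_config(),
                   train_config(max_epochs = 5, patience = 2, seed = 3))
  f <- withr::local_tempfile(fileext = ".json")
  write_checkpoint(fit, f)
  back <- read_checkpoint(f)
  expect_equal(gatm5c:::flatten_params(back$params),
               gatm5c:::flatten_params(fit$params), tolerance = 1e-12)
  al <- align_features(sim$network, sim$features, "sim01")
  s1 <- gat_forward(sim$network, al$x, fit$params, fit$config)
  s2 <- gat_forward(sim$network, al$x, back$params, back$config)
  expect_equal(s1$score, s2$score, tolerance = 1e-12)
})
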