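test_that("auroc equals exhaustive pair counting, including tied scores", {
  sc <- tibble::tibble(gene_id = c("A", "B", "C", "D"),
                       raw_score = c(0.9, 0.8, 0.3, 0.1))
  expect_equal(auroc(sc, c("A", "C")), 0.75)  # verified by pair counting below
  expect_equal(auroc(sc, c("A", "B")), 1.0)   # perfect separation
  expect_equal(auroc(sc, c("C", "D")), 0.0)   # anti-ranked

  # randomized fixtures up to 50 genes, with ties injected
  for (i in 1:20) {
    fx <- withr::with_seed(100 + i, {
      n <- sample(5:50, 1)
      tibble::tibble(
        gene_id = sprintf("G%02d", seq_len(n)),
        raw_score = sample(round(runif(n), 2), n, replace = TRUE))
    })
    pos <- withr::with_seed(200 + i, sample(fx$gene_id, sample(1:(nrow(fx) - 1), 1)))
    expect_equal(auroc(fx, pos), pair_count_auroc(fx, pos), tolerance = 1e-12)
  }
  expect_error(auroc(sc, c("A", "B", "C", "D")), "Degenerate")
  expect_error(auroc(sc, "ZZZ"), "Degenerate")
})

test_that("degree-based filter ranks by degree information only", {
  # 5-node star: degrees (4,1,1,1,1); seed = a leaf -> hub is the top candidate
  star <- star_net(4)
  got <- degree_based_candidate_filter(star, "L1", k = 1)
  expect_equal(got, "HUB")
  # hand evaluation of the score: degree * mean(seed degree)
  expect_equal(unname(star$degree["HUB"] * mean(star$degree["L1"])), 4)

  # k = all non-seed genes returns the full non-seed set
  all_c <- degree_based_candidate_filter(star, "L1", k = 4)
  expect_setequal(all_c, setdiff(star$nodes, "L1"))

  expect_error(degree_based_candidate_filter(star, character(0)), "at least one")
  expect_error(degree_based_candidate_filter(star, "L1", k = 5), "exceeds")

  # exact invariance under degree-preserving randomization, many networks
  sim <- small_sim()
  net <- sim$network
  seeds <- sample_seed_genes(sim$features, 10, seed = 5)
  base <- degree_based_candidate_filter(net, seeds, k = 30)
  for (s in 1:100) {
    r <- degree_preserving_randomize(net, seed = s)
    expect_identical(degree_based_candidate_filter(r, seeds, k = 30), base)
  }
})

test_that("robustness protocol reports zero difference for the degree filter", {
  sim <- small_sim()
  seeds <- sample_seed_genes(sim$features, 10, seed = 2)
  res <- robustness_protocol(sim$network, seeds, n_networks = 10, k = 30,
                             methods = "degree_filter", seed = 7)
  expect_s3_class(res, "robustness_result")
  expect_equal(res$n_differing, 0L)
  expect_identical(res$consensus_a[[1]], res$consensus_b[[1]])
  expect_length(res$sets_a[[1]], 10L)
})

test_that("rewiring perturbs RWR candidate sets with non-negligible probability", {
  # RWR reads distances, not just degrees: across independently rewired
  # ensembles its consensus candidate sets should differ on a 200-node graph
  sim <- generate_synthetic(synthetic_spec(n_genes = 200, n_datasets = 1, seed = 3))
  seeds <- sample_seed_genes(sim$features, 10, seed = 4)
  res <- robustness_protocol(sim$network, seeds, n_networks = 20, k = 25,
                             methods = c("degree_filter", "rwr"), seed = 11)
  expect_equal(res$n_differing[res$method == "degree_filter"], 0L)
  expect_gt(res$n_differing[res$method == "rwr"], 0L)

  # identical ensembles (same randomization seeds) are a hard zero for both
  same <- function(method) {
    nets <- lapply(1:5, function(j) degree_preserving_randomize(sim$network, seed = j))
    sets <- lapply(nets, function(g) {
      if (method == "degree_filter") degree_based_candidate_filter(g, seeds, 25)
      else {
        sc <- rwr(g, seeds)
        sc <- sc[!sc$gene_id %in% seeds, ]
        sc$gene_id[order(-sc$score, sc$gene_id)][1:25]
      }
    })
    counts <- table(unlist(sets))
    sort(names(counts)[counts >= 0.5 * length(sets)])
  }
  expect_identical(same("rwr"), same("rwr"))
})

test_that("over-representation matches the hypergeometric tail by direct summation", {
  universe <- sprintf("U%02d", 1:20)
  top <- universe[1:5]
  sets <- list(hit3 = universe[c(1, 2, 3, 6)],   # overlap 3 of a 4-gene set
               none = universe[16:20],            # zero overlap with top
               exact = universe[1:5])
  res <- over_representation(top, sets, universe)
  # direct tail sum: P(X >= 3), X ~ Hypergeom(m=4, N-m=16, n=5)
  p_hand <- sum(sapply(3:4, function(i) choose(4, i) * choose(16, 5 - i))) / choose(20, 5)
  expect_equal(res$p_value[res$set == "hit3"], p_hand, tolerance = 1e-12)
  # extreme overlap closed form: 1 / C(|U|, |top|)
  expect_equal(res$p_value[res$set == "exact"], 1 / choose(20, 5), tolerance = 1e-12)
  # zero overlap: p close to 1, BH q bounded by 1
  expect_gt(res$p_value[res$set == "none"], 0.9)
  expect_true(all(res$q_value <= 1))
  # BH is monotone in p
  expect_true(all(diff(res$q_value[order(res$p_value)]) >= -1e-12))
  # ordered by p
  expect_equal(res$set[1], "exact")
  expect_error(over_representation(top, sets, character(0)), "empty")
})

test_that("timing harness records repetitions and the degree filter beats RWR", {
  sim <- small_sim()
  seeds <- sample_seed_genes(sim$features, 10, seed = 1)
  th <- timing_harness(list(
    degree_filter = function() degree_based_candidate_filter(sim$network, seeds, 30),
    rwr = function() rwr(sim$network, seeds)
  ), repetitions = 3, net = sim$network)
  expect_equal(nrow(th$timings), 6L)
  expect_setequal(th$summary$method, c("degree_filter", "rwr"))
  expect_equal(unique(th$summary$n_nodes), length(sim$network$nodes))
  # asserted as an ordering only, never as a ratio
  expect_lt(th$summary$median_s[th$summary$method == "degree_filter"],
            th$summary$median_s[th$summary$method == "rwr"])
})
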