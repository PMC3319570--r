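test_that("config validation rejects infeasible structures", {
  expect_error(simulation_config(10, 2, 0), "at least 3 samples")
  expect_error(simulation_config(10, 6, modules = list(
    list(genes = 1:3, rho = 1.2))), "infeasible")
  expect_error(simulation_config(10, 6, modules = list(
    list(genes = c(1, 11), rho = 0.9))), "outside")
  expect_error(simulation_config(10, 6, modules = list(
    list(genes = 1:3, rho = 0.9), list(genes = 3:5, rho = 0.8))),
    "overlap")
  # disjointness is per condition: rewired modules may reuse genes
  cfg <- simulation_config(10, 4, 4, modules = list(
    list(genes = 1:3, rho = 0.9, conditions = "control"),
    list(genes = 3:5, rho = 0.8, conditions = "exposed")))
  expect_s3_class(cfg, "simulation_config")
  expect_error(simulation_config(10, 6, de_genes = c(nope = 1)), "universe")
})

test_that("generation is deterministic and hits the target correlation", {
  cfg <- simulation_config(2, 1000, modules = list(
    list(genes = 1:2, rho = 0.99)), seed = 123)
  sim1 <- generate_expression(cfg)
  sim2 <- generate_expression(cfg)
  expect_identical(sim1$matrix, sim2$matrix)
  r <- cor(sim1$matrix[1, ], sim1$matrix[2, ])
  expect_equal(r, 0.99, tolerance = 0.011)   # large-n law of large numbers

  # no modules: population correlation 0, sample r small at n = 1000
  cfg0 <- simulation_config(4, 1000, seed = 5)
  sim0 <- generate_expression(cfg0)
  cors <- cor(t(sim0$matrix))
  expect_lt(max(abs(cors[upper.tri(cors)])), 0.12)

  # negative loadings give negative expected correlation
  cfgn <- simulation_config(2, 1000, modules = list(
    list(genes = 1:2, rho = 0.9, signs = c(1, -1))), seed = 9)
  simn <- generate_expression(cfgn)
  expect_equal(cor(simn$matrix[1, ], simn$matrix[2, ]), -0.9,
               tolerance = 0.03)
})

test_that("planted fold changes and subgroup structure land in the data", {
  cfg <- simulation_config(20, 200, 200, de_genes = c(g003 = -1.0),
                           subgroup_levels = 3, subgroup_sd = 1,
                           noise_sd = 0.25, seed = 42)
  sim <- generate_expression(cfg)
  is_e <- sim$metadata$condition == "exposed"
  expect_equal(mean(sim$matrix["g003", is_e]) -
               mean(sim$matrix["g003", !is_e]), -1.0, tolerance = 0.1)
  expect_equal(sim$truth$true_de$gene, "g003")
  # subgroup labels present and balanced within condition
  expect_equal(sort(unique(sim$metadata$subgroup)),
               c("sub1", "sub2", "sub3"))
  # subgroup effects shift means between levels for most genes
  g <- sim$truth$subgroup[!is_e]
  spread <- apply(sim$matrix[, !is_e], 1, function(v) {
    diff(range(tapply(v, g, mean)))
  })
  expect_gt(median(spread), 0.5)
})

test_that("ground-truth edges enumerate within-module pairs with signs", {
  cfg <- simulation_config(10, 6, modules = list(
    list(genes = 1:3, rho = 0.9),
    list(genes = c(4, 5), rho = 0.8, signs = c(1, -1))))
  te <- ground_truth_edges(cfg)
  expect_equal(nrow(te), choose(3, 2) + 1L)
  expect_equal(sum(te$sign == "-"), 1L)
  expect_true(all(te$gene_a < te$gene_b))
  # two disjoint 2-gene modules -> 2 pairs, no cross-module pair
  cfg2 <- simulation_config(10, 6, modules = list(
    list(genes = 1:2, rho = 0.9), list(genes = 3:4, rho = 0.9)))
  expect_equal(nrow(ground_truth_edges(cfg2)), 2L)
  # condition filter respects rewiring
  cfg3 <- simulation_config(10, 4, 4, modules = list(
    list(genes = 1:2, rho = 0.9, conditions = "exposed")))
  expect_equal(nrow(ground_truth_edges(cfg3, condition = "control")), 0L)
  expect_equal(nrow(ground_truth_edges(cfg3, condition = "exposed")), 1L)
})

test_that("recovery_report computes confusion counts over unordered pairs", {
  truth <- data.frame(gene_a = c("a", "a", "b"), gene_b = c("b", "c", "c"))
  truth$sign <- "+"
  genes <- letters[1:5]
  perfect <- recovery_report(cbind(truth, r = 1), truth, genes)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  expect_equal(perfect$sign_accuracy, 1)

  none <- recovery_report(truth[0, ], truth, genes)
  expect_equal(none$sensitivity, 0)
  expect_equal(none$tn, choose(5, 2) - 3)

  # 8 of 10 true found plus 1 false positive
  truth10 <- data.frame(gene_a = letters[1:10], gene_b = LETTERS[1:10],
                        sign = "+")
  det <- rbind(truth10[1:8, c("gene_a", "gene_b")],
               data.frame(gene_a = "a", gene_b = "B"))
  rep10 <- recovery_report(det, truth10, c(letters[1:10], LETTERS[1:10]))
  expect_equal(rep10$sensitivity, 0.8)
  expect_equal(rep10$fp, 1L)
  # order of the pair does not matter
  det_sw <- det; det_sw[1, ] <- rev(det_sw[1, ])
  expect_equal(recovery_report(det_sw, truth10,
                               c(letters[1:10], LETTERS[1:10]))$sensitivity,
               0.8)
})

test_that("preset scenarios produce coherent multi-setting data", {
  sc <- simulate_scenario("experiment1", seed = 2)
  expect_setequal(unique(sc$metadata$setting_id), c("human", "mouse", "rat"))
  expect_equal(ncol(sc$matrix), 8 + 12 + 12)
  expect_true(all(sc$metadata$condition == "control"))
  # shared modules: the gatekeeper pairs are planted in every setting
  for (s in names(sc$truth)) {
    expect_true(all(c("Esr2", "Kdm1") %in%
                    unlist(sc$truth[[s]]$true_edges[, 1:2])))
  }
  sc2 <- simulate_scenario("experiment2", seed = 2)
  expect_equal(ncol(sc2$matrix), 12)
  expect_equal(sum(sc2$metadata$condition == "exposed"), 6)
  expect_equal(length(unique(na.omit(sc2$metadata$subgroup))), 3L)
  expect_setequal(sc2$truth$vinclozolin$true_de$gene, c("Kdm6b", "Ehmt1"))
  sc6 <- simulate_scenario("experiment6", seed = 2)
  expect_equal(length(unique(sc6$metadata$setting_id)), 7L)
  expect_equal(nrow(sc6$truth$control$true_edges), 0L)
  expect_gt(nrow(sc6$truth$triadimefon_high$true_edges), 0L)
})
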