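test_that("composite ranking matches the brute-force oracle on random tables", {
  set.seed(101)
  for (i in 1:25) {
    m <- random_table(10, 6)
    ranked <- occupancy_abundance_rank(m)
    expect_identical(ranked$asv_id, oracle_rank(m))
    expect_identical(ranked$composite_rank, seq_len(nrow(ranked)))
  }
})

test_that("ranking favours dominant taxa and breaks exact ties lexicographically", {
  m <- count_table(matrix(c(50, 1, 40, 0, 60, 0), 2,
                          dimnames = list(c("big", "rare"),
                                          c("s1", "s2", "s3"))))
  expect_identical(occupancy_abundance_rank(m)$asv_id[1], "big")

  tied <- count_table(matrix(c(5, 5, 7, 7), 2,
                             dimnames = list(c("zeta", "alpha"), c("s1", "s2"))))
  r1 <- occupancy_abundance_rank(tied)
  expect_identical(r1$asv_id, c("alpha", "zeta"))
  expect_identical(occupancy_abundance_rank(tied)$asv_id, r1$asv_id)
  expect_error(occupancy_abundance_rank(m, samples = character()), "empty")
})

test_that("explained curve matches the pairwise oracle and its analytic properties", {
  set.seed(202)
  for (i in 1:10) {
    m <- random_table(20, 6)
    ranked <- occupancy_abundance_rank(m)
    curve <- explained_bc_curve(m, ranked)
    expect_equal(curve$explained, oracle_curve(m, ranked$asv_id),
                 tolerance = 1e-12)
    expect_true(all(diff(curve$explained) >= -1e-12))
    expect_equal(curve$explained[nrow(curve)], 1, tolerance = 1e-9)
    # ratio invariance under count rescaling
    curve10 <- explained_bc_curve(m * 10, ranked)
    expect_equal(curve10$explained, curve$explained, tolerance = 1e-12)
  }
})

test_that("explained curve hand example: disjoint two-sample table splits 50/50", {
  m <- count_table(matrix(c(10, 0, 0, 10), 2,
                          dimnames = list(c("a", "b"), c("s1", "s2"))))
  ranked <- data.frame(asv_id = c("a", "b"))
  curve <- explained_bc_curve(m, ranked)
  expect_equal(curve$explained, c(0.5, 1.0))
  same <- count_table(matrix(c(3, 1, 3, 1), 2,
                             dimnames = list(c("a", "b"), c("s1", "s2"))))
  expect_error(explained_bc_curve(same, ranked), "degenerate")
})

test_that("marginal-gain stopping rule selects the documented k", {
  curve <- data.frame(asv_id = paste0("a", 1:4),
                      explained = c(0.50, 0.70, 0.703, 0.706))
  res <- select_core(curve, threshold = 0.005)
  expect_equal(res$k, 2L)
  expect_identical(res$core_set, c("a1", "a2"))

  flat <- data.frame(asv_id = paste0("a", 1:3),
                     explained = c(0.002, 0.004, 0.005))
  expect_warning(res0 <- select_core(flat, threshold = 0.005), "empty")
  expect_length(res0$core_set, 0L)

  bad <- data.frame(asv_id = c("a", "b"), explained = c(0.9, 0.5))
  expect_error(select_core(bad), "non-decreasing")
})

test_that("core selection recovers planted core taxa on synthetic data", {
  prec <- rec <- numeric(0)
  for (sd in 1:3) {
    s <- simulate_community(sim_config(seed = sd))
    res <- core_microbiome(s$counts)
    truth <- s$truth$asv_id[s$truth$class == "core"]
    prec <- c(prec, mean(res$core_set %in% truth))
    rec <- c(rec, mean(truth %in% res$core_set))
  }
  expect_gte(mean(prec), 0.8)
  expect_gte(mean(rec), 0.9)
})

test_that("group-restricted selection differs from cross-site selection", {
  s <- simulate_community(sim_config(n_core_site = 20, seed = 17))
  all_core <- core_microbiome(s$counts)$core_set
  ditch <- s$metadata$sample_id[s$metadata$land_use_class == "agri_ditch"]
  ditch_core <- core_microbiome(s$counts, samples = ditch)$core_set
  expect_gt(length(intersect(all_core, ditch_core)), 0L)
  expect_false(setequal(all_core, ditch_core))
})
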