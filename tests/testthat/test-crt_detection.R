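test_that("bimodality coefficient matches the e1071-based oracle to 1e-12", {
  skip_if_not_installed("e1071")
  set.seed(301)
  for (i in 1:50) {
    x <- rnorm(sample(4:30, 1))
    expect_equal(bimodality_coefficient(x), oracle_b(x), tolerance = 1e-12)
  }
  two_point <- c(0, 0, 0, 1, 1, 1)
  expect_equal(bimodality_coefficient(two_point), oracle_b(two_point),
               tolerance = 1e-12)
})

test_that("bimodality coefficient rejects degenerate input and honours its limits", {
  expect_error(bimodality_coefficient(c(5, 5, 5, 5)), "degenerate")
  expect_error(bimodality_coefficient(c(1, 2, 3)), ">= 4")
  # large balanced two-point sample: population b = (0 + 1) / (-2 + 3) = 1
  x <- rep(c(0, 1), 5000)
  expect_equal(bimodality_coefficient(x), 1, tolerance = 1e-3)
  # affine invariance
  set.seed(5)
  y <- rexp(40)
  expect_equal(bimodality_coefficient(3 - 7 * y), bimodality_coefficient(y),
               tolerance = 1e-12)
})

test_that("detect_crt screens on max abundance, excludes core, and reason-codes degeneracies", {
  # mostly rare at ~0.01%, sporadic spikes at ~1.3%
  n <- 40
  depth <- 10000
  counts <- matrix(1, 3, n, dimnames = list(c("spiky", "core1", "flat"),
                                            paste0("s", 1:n)))
  counts["spiky", ] <- 1
  counts["spiky", c(4, 17, 35)] <- 200
  counts["core1", ] <- 5000
  counts["flat", ] <- 3
  filler <- matrix(depth, 1, n, dimnames = list("filler", colnames(counts)))
  m <- count_table(rbind(counts, filler))

  res <- detect_crt(m, core_set = "core1")
  spk <- res[res$asv_id == "spiky", ]
  expect_gte(spk$max_relabund, 0.001)
  expect_equal(spk$is_crt, spk$b >= 0.90)
  expect_equal(spk$b, oracle_b(m["spiky", ] / colSums(m)), tolerance = 1e-12)
  expect_true(spk$is_crt)

  expect_false(res$is_crt[res$asv_id == "core1"])
  expect_equal(res$reason[res$asv_id == "core1"], "in_core_set")
  expect_equal(res$reason[res$asv_id == "flat"], "below_abundance_threshold")

  part <- partition_taxa(res, "core1")
  expect_setequal(unique(part), c("core", "crt", "other"))
  expect_equal(sum(table(part)), nrow(res))
})

test_that("short series are reason-coded rather than flagged", {
  m <- count_table(matrix(c(100, 1, 1, 100, 900, 900), 2,
                          dimnames = list(c("a", "b"), paste0("s", 1:3))))
  res <- detect_crt(m)
  expect_true(all(!res$is_crt))
  expect_true(all(res$reason[res$max_relabund >= 0.001] == "too_few_observations"))
})

test_that("optional conditional-rarity requirement drops always-abundant taxa", {
  n <- 24
  m <- rbind(high = rep(c(400, 100), n / 2), filler = rep(10000, n))
  colnames(m) <- paste0("s", 1:n)
  m <- count_table(m)
  free <- detect_crt(m)
  strict <- detect_crt(m, min_rare_fraction = 0.5)
  hi_free <- free[free$asv_id == "high", ]
  hi_strict <- strict[strict$asv_id == "high", ]
  if (hi_free$is_crt) {
    expect_false(hi_strict$is_crt)
    expect_equal(hi_strict$reason, "insufficient_rarity")
  } else {
    succeed()
  }
})

test_that("planted CRT are recovered with low background false-positive rate", {
  rec <- fpr <- numeric(0)
  for (sd in 1:3) {
    s <- simulate_community(sim_config(seed = sd))
    core <- core_microbiome(s$counts)
    crt <- detect_crt(s$counts, core_set = core$core_set)
    truth_crt <- s$truth$asv_id[s$truth$class == "crt"]
    truth_bg <- s$truth$asv_id[s$truth$class == "background"]
    rec <- c(rec, mean(truth_crt %in% crt$asv_id[crt$is_crt]))
    fpr <- c(fpr, mean(crt$is_crt[crt$asv_id %in% truth_bg]))
  }
  expect_gte(mean(rec), 0.8)
  expect_lte(mean(fpr), 0.05)
})
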