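test_that("Bray-Curtis dissimilarity follows its definition", {
  expect_equal(bray_curtis(c(3, 1, 4), c(3, 1, 4)), 0)
  expect_equal(bray_curtis(c(5, 0), c(0, 7)), 1)
  expect_equal(bray_curtis(c(6, 2), c(2, 2)), 1 / 3)
  expect_error(bray_curtis(c(0, 0), c(0, 0)), "all-zero")
  expect_error(bray_curtis(c(1, 2), c(1, 2, 3)), "length")
  skip_if_not_installed("vegan")
  set.seed(401)
  for (i in 1:20) {
    x <- rpois(15, 8); y <- rpois(15, 8)
    expect_equal(bray_curtis(x, y),
                 as.numeric(vegan::vegdist(rbind(x, y), "bray")),
                 tolerance = 1e-12)
  }
})

test_that("partial Bray-Curtis is the additive per-taxon decomposition", {
  x <- c(a = 10, b = 0)
  y <- c(a = 0, b = 10)
  expect_equal(partial_bray_curtis(x, y, "a"), 0.5)
  expect_equal(partial_bray_curtis(x, y, "a") + partial_bray_curtis(x, y, "b"),
               bray_curtis(x, y))
  expect_equal(partial_bray_curtis(x, y, integer(0)), 0)
  expect_equal(partial_bray_curtis(x, y, c("a", "b")), bray_curtis(x, y))
  set.seed(402)
  for (i in 1:20) {
    x <- rpois(12, 6); y <- rpois(12, 6)
    shares <- vapply(seq_along(x),
                     function(j) partial_bray_curtis(x, y, j), numeric(1))
    expect_equal(sum(shares), bray_curtis(x, y), tolerance = 1e-12)
  }
})

test_that("contribution series matches the explicit pair-loop oracle on a toy design", {
  set.seed(403)
  m <- random_table(12, 4)
  colnames(m) <- paste0("S", 1:4, "_d1")
  meta <- toy_meta(colnames(m), paste0("S", 1:4), rep("2018-06-01", 4))
  sub <- rownames(m)[c(2, 5, 9)]
  cs <- contribution_series(m, meta, sub)
  expect_equal(cs$contribution_pct,
               oracle_contribution(m, paste0("S", 1:4), sub),
               tolerance = 1e-12)
  expect_equal(cs$n_pairs, 6L)
  # full community -> 100%, empty subcommunity -> 0%
  expect_equal(contribution_series(m, meta, rownames(m))$contribution_pct, 100)
  expect_equal(contribution_series(m, meta, character(0))$contribution_pct, 0)
})

test_that("per-taxon shares sum to 100% and ordering of samples is irrelevant", {
  set.seed(404)
  m <- random_table(8, 6)
  colnames(m) <- paste0("S", 1:6)
  meta <- toy_meta(colnames(m), paste0("S", 1:6), rep("2018-06-01", 6))
  shares <- vapply(rownames(m), function(id) {
    contribution_series(m, meta, id)$contribution_pct
  }, numeric(1))
  expect_equal(sum(shares), 100, tolerance = 1e-9)

  perm <- sample(ncol(m))
  cs1 <- contribution_series(m, meta, rownames(m)[1:3])
  cs2 <- contribution_series(m[, perm], meta[perm, ], rownames(m)[1:3])
  expect_equal(cs1$contribution_pct, cs2$contribution_pct, tolerance = 1e-12)
})

test_that("dates with one sample or zero dissimilarity are skipped with reasons", {
  m <- random_table(5, 3)
  colnames(m) <- c("S1_a", "S2_a", "S1_b")
  meta <- toy_meta(colnames(m), c("S1", "S2", "S1"),
                   c("2018-06-01", "2018-06-01", "2018-06-15"))
  cs <- contribution_series(m, meta, rownames(m)[1])
  expect_equal(nrow(cs), 1L)
  expect_equal(attr(cs, "skipped"),
               c("2018-06-15" = "fewer_than_two_samples"))

  same <- count_table(matrix(c(4, 4), 1, dimnames = list("a", c("S1_a", "S2_a"))))
  meta2 <- toy_meta(colnames(same), c("S1", "S2"), rep("2018-06-01", 2))
  expect_error(contribution_series(same, meta2, "a"), "no date")
})

test_that("blocked sites are averaged before pairing", {
  m <- count_table(matrix(c(10, 0, 30, 0, 0, 20), 2,
                          dimnames = list(c("a", "b"),
                                          c("S18_d", "S19_d", "S20_d"))))
  meta <- toy_meta(colnames(m), c("S18", "S19", "S20"), rep("2018-06-01", 3))
  blocks <- c(S18 = "B1", S19 = "B1")
  cs <- contribution_series(m, meta, "a", blocks = blocks)
  # block B1 = mean of S18,S19 = (20, 0); vs S20 = (0, 20): share of a = 0.5
  expect_equal(cs$n_pairs, 1L)
  expect_equal(cs$contribution_pct, 50)
})

test_that("CRT contribution concentrates on planted spike dates", {
  s <- simulate_community(sim_config(seed = 6))
  crt_true <- s$truth$asv_id[s$truth$class == "crt"]
  cs <- contribution_series(s$counts, s$metadata, crt_true)
  is_spike <- as.character(cs$date) %in% s$spike_dates
  skip_if(sum(is_spike) == 0, "no spike event drawn for this seed")
  expect_gt(min(cs$contribution_pct[is_spike]),
            median(cs$contribution_pct[!is_spike]))
})
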