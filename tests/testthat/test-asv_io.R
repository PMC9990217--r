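test_that("count table round-trips through TSV and validation catches bad cells", {
  m <- count_table(matrix(c(5, 0, 2, 1, 3, 4), nrow = 3,
                          dimnames = list(paste0("asv", 1:3), c("s1", "s2"))))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_count_table(m, path)
  back <- read_count_table(path)
  expect_identical(dim(back), c(3L, 2L))
  expect_equal(back, m, ignore_attr = FALSE)

  bad <- m
  bad["asv2", "s1"] <- -4
  expect_error(count_table(bad), "asv2.*s1")
  bad2 <- m
  bad2[1, 1] <- 2.5
  expect_error(count_table(bad2), "non-integer")
  dup <- rbind(m, m[1, , drop = FALSE])
  expect_error(count_table(dup), "duplicate ASV id.*asv1")
})

test_that("BIOM tables are readable through the optional biomformat route", {
  skip_if_not_installed("biomformat")
  m <- random_table(6, 4)
  path <- withr::local_tempfile(fileext = ".biom")
  biomformat::write_biom(biomformat::make_biom(m), path)
  back <- read_count_table(path, format = "biom")
  expect_equal(back[rownames(m), colnames(m)], m)
})

test_that("metadata validation enforces required columns and ISO dates", {
  meta <- toy_meta(c("a", "b"), c("S1", "S2"), c("2017-05-01", "2017-05-01"))
  out <- validate_sample_metadata(meta)
  expect_s3_class(out$date, "Date")
  expect_equal(out$year, c(2017L, 2017L))
  expect_error(validate_sample_metadata(meta[, -2]), "site")
  meta$date[1] <- "05/01/2017"
  expect_error(validate_sample_metadata(meta), "ISO-8601")
})

test_that("merging filter fractions sums counts, unions ASVs, and is commutative/associative", {
  a <- count_table(matrix(c(2, 0), 1, dimnames = list("x", c("s1", "s2"))))
  b <- count_table(matrix(c(3, 5), 1, dimnames = list("x", c("s1", "s2"))))
  ab <- merge_fraction_tables(a, b)
  expect_equal(unname(ab["x", ]), c(5, 5))

  u <- count_table(matrix(c(1, 2), 1, dimnames = list("u", c("s1", "s2"))))
  v <- count_table(matrix(c(7, 0), 1, dimnames = list("v", c("s1", "s2"))))
  uv <- merge_fraction_tables(u, v)
  expect_setequal(rownames(uv), c("u", "v"))
  expect_equal(unname(uv["v", ]), c(7, 0))

  empty <- count_table(matrix(0, 1, 2, dimnames = list("x", c("s1", "s2"))))
  expect_equal(merge_fraction_tables(a, empty)["x", ], a["x", ])

  m1 <- random_table(5, 3); m2 <- random_table(7, 3); m3 <- random_table(4, 3)
  lhs <- merge_fraction_tables(merge_fraction_tables(m1, m2), m3)
  rhs <- merge_fraction_tables(m1, merge_fraction_tables(m3, m2))
  expect_equal(lhs[sort(rownames(lhs)), ], rhs[sort(rownames(rhs)), ])

  amiss <- a[, "s1", drop = FALSE]
  expect_error(merge_fraction_tables(amiss, b), "s2")
  expect_warning(out <- merge_fraction_tables(amiss, b, strict = FALSE), "zeros")
  expect_equal(unname(out["x", c("s1", "s2")]), c(5, 5))
})

test_that("rarefaction conserves depth, never exceeds input counts, and is seed-deterministic", {
  set.seed(42)
  m <- random_table(30, 6, lambda = 40)
  m[, 6] <- 0
  m["t01", 6] <- 50  # sample below depth -> dropped
  expect_message(r <- rarefy(m, 100, seed = 7), "dropped")
  expect_equal(ncol(r), 5L)
  expect_true(all(colSums(r) == 100))
  expect_true(all(r <= m[, colnames(r)]))
  r2 <- suppressMessages(rarefy(m, 100, seed = 7))
  expect_identical(r, r2)

  exact <- count_table(matrix(c(60, 40), 2, 1, dimnames = list(c("a", "b"), "s")))
  expect_equal(rarefy(exact, 100, seed = 1), exact)
  single <- count_table(matrix(100, 1, 1, dimnames = list("only", "s")))
  expect_equal(unname(rarefy(single, 10, seed = 1)[1, 1]), 10)
  expect_error(rarefy(m, 0, seed = 1), "positive")
  expect_error(rarefy(m, 100), "seed")
})

test_that("relative abundance normalises columns and flags all-zero samples", {
  m <- count_table(matrix(c(1, 1, 2, 0, 0, 0), 3,
                          dimnames = list(paste0("a", 1:3), c("s1", "s2"))))
  expect_warning(rel <- relative_abundance(m), "all-zero")
  expect_equal(unname(rel[, "s1"]), c(0.25, 0.25, 0.5))
  expect_equal(unname(rel[, "s2"]), c(0, 0, 0))
  expect_equal(attr(rel, "zero_samples"), "s2")

  r <- suppressMessages(rarefy(random_table(10, 4, 30), 50, seed = 3))
  expect_equal(unname(colSums(relative_abundance(r))), rep(1, ncol(r)))
})
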