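# Cleaning, imputation, binarization, splitting, distribution QC.

test_that("unmapped '*' sites are removed and counted", {
  v <- matrix(runif(40), 4, 10)
  pos <- data.frame(site = sprintf("S%d", 1:10), chromosome = "chr1",
                    position = as.character(1:10))
  pos$position[c(3, 7)] <- "*"
  m <- toy_matrix(v, positions = pos)
  expect_message(out <- drop_unmapped_sites(m), "removed 2")
  expect_equal(ncol(out$values), 8)
  expect_equal(out$drop_log$unmapped_sites, 2)

  # no '*' sites: identity
  clean <- toy_matrix(v, positions = transform(pos, position = as.character(1:10)))
  expect_identical(drop_unmapped_sites(clean), clean)

  # all sites unmapped: explicit error
  allbad <- toy_matrix(v, positions = transform(pos, position = "*"))
  expect_error(drop_unmapped_sites(allbad), "all sites")
})

test_that("the 15% filter drops sites first, then patients (7x5 toy)", {
  # S1 has 2/7 NA (0.29 > 0.15) -> dropped in pass 1; S2 (1/7 = 0.14) stays.
  # After pass 1, P7's single NA is 1/4 of its remaining sites (0.25 > 0.15)
  # -> P7 dropped in pass 2. One site, then one patient: 6x4 remains.
  v <- matrix(0.5, 7, 5, dimnames = list(paste0("P", 1:7), paste0("S", 1:5)))
  v[c("P1", "P2"), "S1"] <- NA
  v["P7", "S2"] <- NA
  out <- suppressMessages(filter_missing(toy_matrix(v)))
  expect_equal(dim(out$values), c(6L, 4L))
  expect_equal(rownames(out$values), paste0("P", 1:6))
  expect_equal(colnames(out$values), c("S2", "S3", "S4", "S5"))
  expect_equal(out$drop_log$na_sites, 1)
  expect_equal(out$drop_log$na_patients, 1)
  # order regression: P1 and P2 (NA only in the dropped site) survive, which
  # a patients-first filter (their overall NA fraction is 0.2 > 0.15) would not
  expect_true(all(c("P1", "P2") %in% rownames(out$values)))
})

test_that("the missingness threshold is strict: exactly 15% is retained", {
  v <- matrix(0.5, 20, 3, dimnames = list(sprintf("P%02d", 1:20), c("A", "B", "C")))
  v[1:3, "A"] <- NA   # 3/20 = 0.15 exactly
  v[1:4, "B"] <- NA   # 4/20 = 0.20
  out <- suppressMessages(filter_missing(toy_matrix(v)))
  expect_true("A" %in% colnames(out$values))
  expect_false("B" %in% colnames(out$values))
})

test_that("NA-free matrices pass the filter unchanged", {
  m <- toy_matrix(matrix(runif(20), 4, 5))
  expect_identical(filter_missing(m)$values, m$values)
})

test_that("mean imputation fills NAs with the per-site mean and nothing else", {
  v <- matrix(c(0.2, 0.4, NA,
                0.1, 0.1, 0.1,
                NA, 0.6, 0.9), 3, 3,
              dimnames = list(paste0("P", 1:3), paste0("S", 1:3)))
  out <- impute_site_mean(toy_matrix(v))
  expect_equal(out$values["P3", "S1"], 0.3)           # mean(0.2, 0.4)
  expect_equal(out$values["P1", "S3"], 0.75)          # mean(0.6, 0.9)
  untouched <- !is.na(v)
  expect_identical(out$values[untouched], v[untouched])
  expect_false(anyNA(out$values))

  complete <- toy_matrix(matrix(runif(9), 3, 3))
  expect_identical(impute_site_mean(complete), complete)
})

test_that("binarization uses the inclusive 0.3 boundary", {
  v <- matrix(c(0.30, 0.29, 0, 1, 0.3000001, 0.95), 2, 3)
  out <- binarize(toy_matrix(v))
  expect_equal(as.vector(out$values), c(1, 0, 0, 1, 1, 1))
  expect_true(out$binary)
  # idempotent on already-binary data
  expect_equal(binarize(out)$values, out$values)
  # incomplete data must be imputed first
  v[1, 1] <- NA
  expect_error(binarize(toy_matrix(v)), "missing")
})

test_that("split sizes reproduce all nine reference partition counts", {
  expect_equal(split_sizes(439), c(train = 307, validation = 88, test = 44))
  expect_equal(split_sizes(484), c(train = 339, validation = 97, test = 48))
  expect_equal(split_sizes(542), c(train = 379, validation = 108, test = 55))
})

test_that("split partitions are disjoint, exhaustive and reproducible", {
  m <- toy_matrix(matrix(runif(439 * 4), 439, 4),
                  labels = rep(c("Cancer", "Normal"), c(300, 139)))
  sp <- split_dataset(m, seed = 42)
  ids <- lapply(sp[c("train", "validation", "test")],
                function(p) rownames(p$values))
  expect_equal(lengths(ids), c(train = 307L, validation = 88L, test = 44L))
  expect_equal(length(unique(unlist(ids))), 439)      # disjoint + exhaustive
  expect_equal(sort(unlist(ids, use.names = FALSE)), sort(rownames(m$values)))
  expect_identical(sp$test$partition, "test")

  sp2 <- split_dataset(m, seed = 42)
  expect_identical(sp$train$values, sp2$train$values)
  expect_identical(sp$test$values, sp2$test$values)
  sp3 <- split_dataset(m, seed = 43)
  expect_false(identical(rownames(sp$train$values), rownames(sp3$train$values)))

  expect_error(split_dataset(m, fractions = c(0.7, 0.2, 0.2)), "summing|sum")
  expect_error(split_dataset(toy_matrix(matrix(runif(4), 2, 2))), "at least 3")
})

test_that("stratified splitting preserves per-class proportions", {
  m <- toy_matrix(matrix(runif(200 * 3), 200, 3),
                  labels = rep(c("Cancer", "Normal"), c(140, 60)))
  sp <- split_dataset(m, seed = 1, stratify = TRUE)
  expect_equal(sum(sp$train$labels == "Cancer"), round(0.7 * 140))
  expect_equal(sum(sp$validation$labels == "Normal"), round(0.2 * 60))
})

test_that("group moments follow the population conventions", {
  # constant group: variance 0, skewness/kurtosis undefined
  v <- matrix(0.5, 4, 3)
  gm <- group_moments(toy_matrix(v, labels = rep(c("Cancer", "Normal"), 2)))
  expect_equal(gm$mean, c(0.5, 0.5))
  expect_equal(gm$variance, c(0, 0))
  expect_true(all(is.na(gm$skewness)))

  # Cancer group with balanced {0, 1} values: mean 0.5, population var 0.25;
  # Normal group symmetric around 0.5: (near) zero skewness
  v2 <- rbind(rep(c(0, 1), 3),
              c(0.1, 0.3, 0.5, 0.5, 0.7, 0.9))
  gm2 <- group_moments(toy_matrix(v2, labels = c("Cancer", "Normal")))
  crow <- gm2[gm2$group == "Cancer", ]
  expect_equal(crow$mean, 0.5)
  expect_equal(crow$variance, 0.25)
  expect_equal(crow$skewness, 0)
  expect_equal(gm2$skewness[gm2$group == "Normal"], 0, tolerance = 1e-12)

  # an empty group is an error
  one <- toy_matrix(matrix(0.2, 1, 3), labels = "Normal")
  expect_error(group_moments(one), "empty group")
})
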