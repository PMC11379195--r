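# Entropy trees, iterative masked selection, separation score.

test_that("node entropy is base-2: 1 when evenly mixed, 0 when pure", {
  expect_identical(node_entropy(0.5, 0.5), 1)
  expect_identical(node_entropy(1, 0), 0)
  expect_identical(node_entropy(0, 1), 0)
  expect_equal(node_entropy(0.75, 0.25), 0.8113, tolerance = 1e-4)
  expect_error(node_entropy(0.5, 0.4), "sum to 1")
})

test_that("the root split maximizes information gain (worked example)", {
  # labels C,C,C,N,N,N; site A misclassifies one sample, site B is perfect:
  # gain(B) = 1.0 beats gain(A) ~ 0.459
  X <- cbind(A = c(1, 1, 1, 0, 0, 1), B = c(1, 1, 1, 0, 0, 0))
  rownames(X) <- paste0("P", 1:6)
  y <- c("Cancer", "Cancer", "Cancer", "Normal", "Normal", "Normal")
  tree <- fit_depth2_tree(X, y)
  expect_equal(tree$site, "B")
  expect_equal(tree$gain, 1.0)
  expect_equal(tree$left$entropy, 0)
  expect_equal(tree$right$entropy, 0)
  expect_equal(tree_accuracy(tree, X, y), 1.0)
  # with B masked, A becomes the root and its mistake is uncorrectable
  treeA <- fit_depth2_tree(X, y, excluded = "B")
  expect_equal(treeA$site, "A")
  expect_equal(treeA$gain, 1 - 4 / 6 * node_entropy(0.25, 0.75), tolerance = 1e-12)
})

test_that("root choice matches an exhaustive information-gain oracle", {
  set.seed(101)
  for (rep in 1:8) {
    n <- sample(8:20, 1)
    p <- sample(20:200, 1)
    X <- matrix(rbinom(n * p, 1, runif(1, 0.2, 0.8)), n, p,
                dimnames = list(NULL, paste0("S", seq_len(p))))
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    labels <- ifelse(y == 1, "Cancer", "Normal")
    gains <- oracle_gains(X, y)
    tree <- tryCatch(fit_depth2_tree(X, labels),
                     methpanel_no_informative_split = function(e) NULL)
    if (max(gains) <= 1e-15) {
      expect_null(tree)
    } else {
      expect_equal(tree$gain, max(gains), tolerance = 1e-9)
      best_set <- colnames(X)[gains >= max(gains) - 1e-9]
      expect_true(tree$site %in% best_set)
    }
  }
})

test_that("exact gain ties break to the lowest column index", {
  X <- cbind(S1 = c(1, 1, 0, 0), S2 = c(0, 0, 1, 1), S3 = c(1, 1, 0, 0))
  rownames(X) <- paste0("P", 1:4)
  y <- c("Cancer", "Cancer", "Normal", "Normal")
  # all three sites separate perfectly; the first column wins
  expect_equal(fit_depth2_tree(X, y)$site, "S1")
  expect_equal(fit_depth2_tree(X, y, excluded = "S1")$site, "S2")
})

test_that("a fully uninformative or fully masked matrix signals no split", {
  X <- matrix(c(1, 1, 0, 0), 4, 3, dimnames = list(NULL, c("A", "B", "C")))
  y <- c("Cancer", "Normal", "Cancer", "Normal")  # independent of every site
  expect_error(fit_depth2_tree(X, y), class = "methpanel_no_informative_split")
  Xp <- cbind(X, D = c(1, 1, 0, 0))
  expect_error(fit_depth2_tree(Xp, c("Cancer", "Cancer", "Normal", "Normal"),
                               excluded = c("A", "B", "C", "D")),
               class = "methpanel_no_informative_split")
})

test_that("trees never exceed depth 2 and never split on masked sites", {
  cfg <- small_config(seed = 13)
  co <- suppressMessages(impute_site_mean(filter_missing(simulate_cohort(cfg))))
  bin <- binarize(co)
  mask <- co$truth$informative[1:3]
  tree <- fit_depth2_tree(bin, excluded = mask)
  sites <- methpanel:::tree_sites(tree)
  expect_false(any(sites %in% mask))
  expect_lte(length(sites), 3)
  for (child in list(tree$left, tree$right)) {
    if (child$type == "split") {
      expect_equal(child$left$type, "leaf")
      expect_equal(child$right$type, "leaf")
    }
  }
})

test_that("iterative selection accumulates 10-12 distinct sites under the mask", {
  # 12 mutually independent perfect separators guarantee a clean panel
  set.seed(5)
  n <- 40
  y <- rep(c("Cancer", "Normal"), each = n / 2)
  perfect <- matrix(rep(c(1, 0), each = n / 2), n, 12)
  noise <- matrix(rbinom(n * 30, 1, 0.5), n, 30)
  X <- cbind(perfect, noise)
  colnames(X) <- c(sprintf("good%02d", 1:12), sprintf("bg%02d", 1:30))
  rownames(X) <- paste0("P", seq_len(n))
  panel <- iterative_select(X, y, min_panel = 10)
  expect_gte(nrow(panel), 10)
  expect_lte(nrow(panel), 12)
  expect_equal(anyDuplicated(panel$site), 0)
  expect_equal(panel$order, seq_len(nrow(panel)))
  # the mask grows strictly run over run
  expect_true(all(diff(panel$run) %in% c(0, 1)))
})

test_that("selection stops early with a warning when informative sites run out", {
  # only 4 informative sites; constant background can never split
  set.seed(8)
  n <- 30
  y <- rep(c("Cancer", "Normal"), c(18, 12))
  info <- sapply(1:4, function(i) ifelse(y == "Cancer",
                                         rbinom(n, 1, 0.95), rbinom(n, 1, 0.05)))
  bg <- matrix(1, n, 20)
  X <- cbind(info, bg)
  colnames(X) <- c(paste0("info", 1:4), paste0("bg", 1:20))
  rownames(X) <- paste0("P", seq_len(n))
  expect_warning(panel <- iterative_select(X, y, min_panel = 10),
                 "no informative split")
  expect_lt(nrow(panel), 10)
  # the constant background can never carry a split
  expect_true(all(grepl("^info", panel$site)))
})

test_that("separation score has the documented magnitude and sign behavior", {
  # opposite-side medians: -((0.8-0.3)/0.1) * ((0.1-0.3)/0.1) = 10
  expect_equal(separation_score(0.8, 0.1, 0.1, 0.1), 10.0)
  # both medians below the cutoff: -((-1) * (-2)) = -2
  expect_equal(separation_score(0.2, 0.1, 0.1, 0.1), -2.0)
  # a median exactly at the cutoff zeroes the score
  expect_equal(separation_score(0.3, 0.1, 0.05, 0.1), 0)
  # zero SD: undefined
  expect_true(is.na(separation_score(0.8, 0.1, 0, 0.1)))
  # swapping which side each group occupies flips neither sign nor magnitude
  expect_equal(separation_score(0.1, 0.8, 0.1, 0.1),
               separation_score(0.8, 0.1, 0.1, 0.1))
  # sign is negative iff the medians share a side (property over a grid)
  for (cm in c(0.1, 0.2, 0.5, 0.9)) {
    for (nm in c(0.05, 0.25, 0.6, 0.8)) {
      s <- separation_score(cm, nm, 0.07, 0.11)
      same_side <- (cm - 0.3) * (nm - 0.3) > 0
      if (same_side) expect_lt(s, 0) else expect_gt(s, 0)
    }
  }
})

test_that("refinement keeps strictly positive scores and records exclusions", {
  set.seed(31)
  n <- 40
  labels <- rep(c("Cancer", "Normal"), each = n / 2)
  mk_site <- function(cm, nm) c(rnorm(n / 2, cm, 0.05), rnorm(n / 2, nm, 0.05))
  v <- cbind(good1 = mk_site(0.8, 0.1), bad = mk_site(0.2, 0.1),
             good2 = mk_site(0.7, 0.15), const = rep(0.5, n))
  v <- pmin(pmax(v, 0), 1)
  m <- toy_matrix(v, labels = labels)
  panel <- structure(data.frame(site = colnames(v), run = 1L, order = 1:4,
                                stringsAsFactors = FALSE),
                     class = c("cpg_panel", "data.frame"))
  refined <- suppressMessages(refine_panel(panel, m))
  expect_equal(refined$site[refined$retained], c("good1", "good2"))
  expect_lt(refined$separation_score[refined$site == "bad"], 0)
  expect_true(is.na(refined$separation_score[refined$site == "const"]))

  # an all-positive panel passes through unchanged
  m2 <- toy_matrix(v[, c("good1", "good2")], labels = labels)
  panel2 <- structure(data.frame(site = c("good1", "good2"), run = 1L,
                                 order = 1:2, stringsAsFactors = FALSE),
                      class = c("cpg_panel", "data.frame"))
  refined2 <- refine_panel(panel2, m2)
  expect_true(all(refined2$retained))
  expect_equal(refined2$site, panel2$site)
})

test_that("known separation scores classify retention as in the reference table", {
  # three bladder-panel scores: 2.64 and 1.356 retained, -16.968 removed
  scores <- c(2.64, -16.968, 1.356)
  retained <- scores > 0
  expect_equal(retained, c(TRUE, FALSE, TRUE))
})

test_that("selection plus refinement recovers planted sites from noise", {
  cfg <- cohort_config(n_cancer = 80, n_normal = 50, n_sites = 600,
                       n_informative = 12, n_bad_sites = 0, n_bad_patients = 0,
                       na_rate_base = 0, seed = 99)
  co <- generate_cohort(cfg)
  bin <- binarize(co)
  panel <- iterative_select(bin, min_panel = 10)
  refined <- suppressMessages(refine_panel(panel, co))
  kept <- refined$site[refined$retained]
  expect_gte(length(kept), 10)
  expect_gte(mean(kept %in% co$truth$informative), 0.8)
})
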