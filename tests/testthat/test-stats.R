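test_that("fold changes reproduce printed group-mean ratios", {
  # published expression means (tpm) and their printed fold differences
  expect_equal(round(fold_change(1452, 7275.3), 1), 5.0)
  expect_equal(fold_change(0, 9), Inf)
  expect_equal(round(fold_change(35.4, 2366.1)), 67)
  expect_equal(round(fold_change(2759.8, 9608.1), 1), 3.5)
  expect_equal(round(fold_change(5255.7, 15151.5), 1), 2.9)
  expect_equal(fold_change(7, 7), 1)
  expect_true(is.nan(fold_change(0, 0)))
  expect_error(fold_change(-1, 5), "non-negative")
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Holm adjustment matches the step-down definition", {
  expect_equal(holm_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(holm_adjust(0.2), 0.2)
  expect_equal(holm_adjust(c(0.03, 0.03)), c(0.06, 0.06))
})

test_that("BH and Holm agree with brute-force formula evaluation on random vectors", {
  set.seed(61)
  for (i in 1:50) {
    m <- sample(1:40, 1)
    p <- round(runif(m), 3)  # ties included
    expect_equal(bh_fdr(p), oracle_bh(p))
    expect_equal(holm_adjust(p), oracle_holm(p))
  }
})

de_fixture <- function(n_true = 1, n_null = 100, fold = 1000, seed = 67) {
  set.seed(seed)
  base <- runif(n_true + n_null, 10, 500)
  mat <- cbind(a1 = base, a2 = base, a3 = base,
               b1 = base, b2 = base, b3 = base)
  mat <- mat * matrix(rnorm(length(mat), 1, 0.02), nrow(mat))
  bcol <- c("b1", "b2", "b3")
  mat[seq_len(n_true), bcol] <- mat[seq_len(n_true), bcol] * fold
  tibble::as_tibble(cbind(
    tibble::tibble(identifier = sprintf("m%03d", seq_len(nrow(mat)))),
    tibble::as_tibble(mat)))
}

test_that("differential expression flags constructed signal and applies the filter chain", {
  expr <- de_fixture()
  group <- c("a", "a", "a", "b", "b", "b")
  de <- diff_expression(expr, group)
  expect_s3_class(de, "mirna_de")
  expect_true(de$significant[de$identifier == "m001"])
  expect_lt(sum(de$significant), 3)  # essentially only the planted one
  expect_equal(de$fold[1], de$mean_b[1] / de$mean_a[1])
  # identical groups: nothing significant, folds 1
  same <- de_fixture(n_true = 0, n_null = 30)
  mat <- as.matrix(same[-1])
  mat[, 4:6] <- mat[, 1:3]
  same[-1] <- tibble::as_tibble(mat)
  de0 <- diff_expression(same, group)
  expect_false(any(de0$significant))
  expect_equal(de0$fold, rep(1, nrow(de0)), tolerance = 1e-12)
  # strong q but fold below 1.5 is filtered out
  flat <- tibble::tibble(identifier = "x", a1 = 1000, a2 = 1001,
                         a3 = 1000.5, b1 = 1400, b2 = 1401, b3 = 1400.5)
  de_flat <- diff_expression(flat, group)
  expect_lt(de_flat$q, 0.05)
  expect_false(de_flat$significant)
  # low-abundance transcripts below min_tpm never pass
  low <- tibble::tibble(identifier = "y", a1 = 0.1, a2 = 0.1, a3 = 0.12,
                        b1 = 4, b2 = 4.1, b3 = 4.2)
  expect_false(diff_expression(low, group)$significant)
  expect_error(diff_expression(expr, c("a", "b", "b", "b", "b", "b")), "2 samples")
})

test_that("moderated t shrinks variances and still finds the planted signal", {
  expr <- de_fixture(n_true = 2, n_null = 60, fold = 50, seed = 71)
  de <- diff_expression(expr, c("a", "a", "a", "b", "b", "b"),
                        de_params(test = "moderated_t"))
  expect_true(all(de$significant[1:2]))
  expect_lt(sum(de$significant[-(1:2)]), 3)
})

test_that("moderated t agrees in ranking with an established empirical-Bayes fit", {
  skip_if_not_installed("limma")
  expr <- de_fixture(n_true = 3, n_null = 40, fold = 20, seed = 73)
  group <- c("a", "a", "a", "b", "b", "b")
  de <- diff_expression(expr, group, de_params(test = "moderated_t"))
  mat <- sqrt(as.matrix(expr[-1]))
  fit <- limma::eBayes(limma::lmFit(mat, stats::model.matrix(~factor(group))))
  limma_p <- fit$p.value[, 2]
  expect_gt(cor(rank(de$p), rank(limma_p), method = "spearman"), 0.95)
})

test_that("permuted null labels keep the significant fraction at or below alpha", {
  set.seed(79)
  expr <- de_fixture(n_true = 0, n_null = 200, seed = 79)
  de <- diff_expression(expr, c("a", "b", "a", "b", "a", "b"))
  expect_lte(mean(de$significant), 0.05)
})

test_that("global test statistic decomposes into contributions and handles degeneracy", {
  set.seed(83)
  x <- matrix(rnorm(6 * 5), 6, 5, dimnames = list(NULL, paste0("i", 1:5)))
  g <- rep(c("a", "b"), each = 3)
  fit <- global_test(x, g)
  expect_equal(sum(fit$contributions$Q_i), fit$Q)
  expect_equal(fit$method, "exhaustive")
  expect_equal(fit$n_labelings, choose(6, 3))
  expect_gt(fit$p, 0)
  expect_lte(fit$p, 1)
  # constant matrix: Q = 0, p = 1
  fit0 <- global_test(matrix(1, 6, 3), g)
  expect_equal(fit0$Q, 0)
  expect_equal(fit0$p, 1)
})

test_that("a covariate proportional to the labels attains the minimal permutation p", {
  g <- rep(c("a", "b"), each = 2)
  y <- c(0, 0, 1, 1)
  x <- cbind(iso = y)
  fit <- global_test(x, g)
  # Q is maximal over all labelings; ties only at the complement labeling
  expect_equal(fit$p, 2 / choose(4, 2))
  expect_equal(fit$n_labelings, 6)
})

test_that("global-test type-I error is controlled under exchangeable labels", {
  set.seed(89)
  n_sim <- 400
  g <- rep(c("a", "b"), each = 4)  # 70 exhaustive labelings
  pvals <- vapply(seq_len(n_sim), function(i) {
    x <- matrix(rnorm(8 * 6), 8, 6)
    global_test(x, g)$p
  }, numeric(1))
  expect_lte(mean(pvals <= 0.05), 0.05 + 2 * sqrt(0.05 * 0.95 / n_sim))
  # p-values live on the permutation grid
  expect_true(all(pvals >= 1 / 70))
})

test_that("isomir-level filters drop N sequences and low-abundance isomirs", {
  samples <- c("e1", "e2", "h1", "h2")
  groups <- setNames(c("EM", "EM", "HT", "HT"), samples)
  iso <- tidyr::expand_grid(sample = samples,
                            isomir_id = c("i1", "i2", "iN", "ilow")) |>
    dplyr::mutate(identifier = "miRNA|T1|5p|m|sense",
                  sequence = ifelse(isomir_id == "iN", "ACGNACGT", "ACGTACGT"),
                  tpm = dplyr::case_when(
                    isomir_id == "i1" & sample %in% c("h1", "h2") ~ 200,
                    isomir_id == "i1" ~ 20,
                    isomir_id == "i2" ~ 30,
                    isomir_id == "iN" ~ 50,
                    TRUE ~ 2))
  res <- isomir_global_tests(iso, groups)
  expect_equal(nrow(res), 1)
  expect_equal(res$n_isomirs, 2L)  # iN (N base) and ilow (< 10 tpm) dropped
  expect_true(res$mab_ok)          # most abundant isomir at 200 tpm > 50
  # the 10-tpm rule keeps isomirs reaching the threshold in either group
  iso2 <- iso |>
    dplyr::mutate(tpm = ifelse(isomir_id == "ilow" & sample %in% c("h1", "h2"),
                               6, tpm))
  res2 <- isomir_global_tests(iso2, groups)
  expect_equal(res2$n_isomirs, 3L)  # 6 + 6 = 12 >= 10 in HT
})

test_that("subset detection finds the single differential isomir among nulls", {
  set.seed(97)
  n <- 12
  g <- rep(c("a", "b"), each = 6)
  x <- matrix(rnorm(n * 6, 10, 0.5), n, 6,
              dimnames = list(NULL, paste0("i", 1:6)))
  x[g == "b", 1] <- x[g == "b", 1] + 15  # one strongly differential isomir
  fit <- global_test(x, g)
  subs <- isomir_subsets(fit, alpha = 0.1)
  leaves <- subs$nodes[subs$nodes$is_leaf, ]
  sig_leaves <- unlist(leaves$members[leaves$significant])
  expect_equal(sig_leaves, "i1")
  # perfectly correlated differential isomirs: the root is significant
  # as a whole branch
  y <- as.numeric(g == "b")
  xx <- sapply(1:5, function(i) 10 + 15 * y + rnorm(n, 0, 0.1))
  colnames(xx) <- paste0("c", 1:5)
  fit2 <- global_test(xx, g)
  subs2 <- isomir_subsets(fit2, alpha = 0.1)
  root <- subs2$nodes[which.max(subs2$nodes$n_members), ]
  expect_true(root$significant)
  expect_true(root$maximal)
  # no signal: no significant nodes
  x0 <- matrix(rnorm(n * 5), n, 5)
  subs0 <- isomir_subsets(global_test(x0, g), alpha = 0.1)
  expect_false(any(subs0$nodes$significant))
})

test_that("uniform group folds produce same-signed isomir contributions", {
  set.seed(101)
  g <- rep(c("a", "b"), each = 3)
  y <- as.numeric(g == "b")
  x <- sapply(1:8, function(i) {
    base <- runif(1, 5, 20)
    base * (1 + 2 * y) + rnorm(6, 0, 0.2)
  })
  fit <- global_test(x, g)
  dirs <- fit$contributions$direction
  expect_true(all(dirs == dirs[1]))
})
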