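#' Permutation global test of an isomir complement
#'
#' Quadratic score test of whether a set of covariates (a miRNA's
#' isomirs, on the sqrt(tpm) scale) is associated with a two-group
#' label. With the centred group indicator `y` and centred covariate
#' columns `x_i`, the statistic is `Q = sum_i (x_i . y)^2 / m`; its
#' null distribution comes from label permutations - exhaustive over
#' all distinct labelings when there are at most `exhaustive_limit` of
#' them, otherwise `n_perm` Monte-Carlo draws with an add-one
#' correction. Per-isomir contributions `Q_i = (x_i . y)^2 / m` sum to
#' `Q` exactly.
#'
#' @param x Numeric matrix (or wide tibble) of samples x isomirs,
#'   sqrt(tpm) scale.
#' @param group Two-level factor/character of length `nrow(x)`.
#' @param n_perm Monte-Carlo permutation count used above the
#'   exhaustive limit.
#' @param exhaustive_limit Maximum number of distinct labelings for
#'   exhaustive enumeration (default 10000).
#' @param seed Optional integer seed for the Monte-Carlo path.
#' @return A `global_test_result`: `Q`, `p`, `n_isomirs`,
#'   `n_labelings`, `method` ("exhaustive" or "monte_carlo"), and
#'   `contributions` (tibble `isomir`, `Q_i`, `direction` - the sign
#'   of the covariate's association with the second group level).
#' @export
global_test <- function(x, group, n_perm = 10000, exhaustive_limit = 10000,
                        seed = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  group <- as.factor(group)
  if (nrow(x) != length(group)) abort("group must label every row (sample) of x")
  if (nlevels(group) != 2) abort("exactly two groups are required")
  m <- ncol(x)
  if (m < 1) abort("at least one covariate column is required")
  y <- as.numeric(group == levels(group)[2])
  y <- y - mean(y)
  xc <- scale(x, center = TRUE, scale = FALSE)
  score <- drop(crossprod(xc, y))
  Q <- sum(score^2) / m
  n <- nrow(x)
  n1 <- sum(group == levels(group)[2])
  n_label <- choose(n, n1)
  if (n_label <= exhaustive_limit) {
    method <- "exhaustive"
    sets <- combn(n, n1)
    yperm <- matrix(-n1 / n, nrow = n, ncol = ncol(sets))
    yperm[cbind(as.vector(sets),
                rep(seq_len(ncol(sets)), each = n1))] <- 1 - n1 / n
    qstar <- colSums(crossprod(xc, yperm)^2) / m
    p <- mean(qstar >= Q - 1e-12 * max(Q, 1))
    n_labelings <- n_label
  } else {
    method <- "monte_carlo"
    if (!is.null(seed)) set.seed(seed)
    yperm <- vapply(seq_len(n_perm), function(i) sample(y), numeric(n))
    qstar <- colSums(crossprod(xc, yperm)^2) / m
    p <- (1 + sum(qstar >= Q - 1e-12 * max(Q, 1))) / (n_perm + 1)
    n_labelings <- n_perm
  }
  structure(list(
    Q = Q, p = p, n_isomirs = m, n_labelings = n_labelings, method = method,
    contributions = tibble(isomir = colnames(x) %||% paste0("x", seq_len(m)),
                           Q_i = score^2 / m,
                           direction = sign(score)),
    x = x, group = group), class = "global_test_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.global_test_result <- function(x, ...) {
  cat(sprintf("<global_test_result> Q = %.4g, p = %.4g (%s, %d labelings), %d isomirs\n",
              x$Q, x$p, x$method, x$n_labelings, x$n_isomirs))
  invisible(x)
}

#' @export
tidy.global_test_result <- function(x, ...) {
  x$contributions
}

#' @export
glance.global_test_result <- function(x, ...) {
  tibble(Q = x$Q, p = x$p, n_isomirs = x$n_isomirs,
         n_labelings = x$n_labelings, method = x$method)
}

#' @export
autoplot.global_test_result <- function(object, ...) {
  d <- object$contributions |>
    mutate(isomir = factor(.data$isomir, levels = .data$isomir[order(-.data$Q_i)]),
           direction = factor(.data$direction, levels = c(-1, 0, 1),
                              labels = c("down", "flat", "up")))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$isomir, y = .data$Q_i,
                                  fill = .data$direction)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "isomir", y = "contribution to Q",
                  title = "Per-isomir contributions to the global test") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Global tests across all miRNAs of an isomir expression table
#'
#' Applies the pre-test filters (isomirs whose sequence contains `N`
#' are excluded; isomirs are retained only when their within-group tpm
#' sum reaches `min_group_sum` in at least one group), runs
#' [global_test()] per miRNA with at least two surviving isomirs, BH-
#' adjusts across miRNAs, and flags miRNAs whose most abundant isomir
#' does not exceed `mab_tpm` as below the abundance reporting filter.
#'
#' @param isomirs Long isomir tibble with `sample`, `identifier`,
#'   `isomir_id`, `sequence`, `tpm`.
#' @param groups Named vector: sample -> group label (two levels).
#' @param min_group_sum Minimal within-group tpm sum for an isomir to
#'   be kept (default 10).
#' @param mab_tpm Most-abundant-isomir tpm threshold for the reporting
#'   flag (default 50).
#' @inheritParams global_test
#' @return A `mirna_global_tests` tibble: `identifier`, `n_isomirs`,
#'   `Q`, `p`, `q`, `mab_tpm`, `mab_ok`, plus a `fits` list-column of
#'   the per-miRNA `global_test_result` objects.
#' @export
isomir_global_tests <- function(isomirs, groups, min_group_sum = 10,
                                mab_tpm = 50, n_perm = 10000, seed = NULL) {
  need <- c("sample", "identifier", "isomir_id", "sequence", "tpm")
  missing <- setdiff(need, names(isomirs))
  if (length(missing)) {
    abort(sprintf("isomirs lack column(s): %s", paste(missing, collapse = ", ")))
  }
  keep <- isomirs |>
    filter(!grepl("N", .data$sequence, fixed = TRUE)) |>
    mutate(group = unname(groups[.data$sample]))
  sums <- keep |>
    group_by(.data$identifier, .data$isomir_id, .data$group) |>
    summarise(tpm_sum = sum(.data$tpm), .groups = "drop") |>
    group_by(.data$identifier, .data$isomir_id) |>
    summarise(retain = max(.data$tpm_sum) >= min_group_sum, .groups = "drop")
  keep <- keep |>
    left_join(sums, by = c("identifier", "isomir_id")) |>
    filter(.data$retain)
  samples <- names(groups)
  out <- keep |>
    group_by(.data$identifier) |>
    tidyr::nest() |>
    ungroup()
  fits <- vector("list", nrow(out))
  rows <- vector("list", nrow(out))
  for (i in seq_len(nrow(out))) {
    d <- out$data[[i]]
    wide <- d |>
      select("sample", "isomir_id", "tpm") |>
      tidyr::pivot_wider(names_from = "isomir_id", values_from = "tpm",
                         values_fill = 0)
    wide <- wide[match(samples, wide$sample), ]
    wide$sample <- samples
    wide[is.na(wide)] <- 0
    mat <- sqrt(as.matrix(wide[setdiff(names(wide), "sample")]))
    if (ncol(mat) < 2) {
      rows[[i]] <- NULL
      next
    }
    fit <- global_test(mat, groups[samples], n_perm = n_perm, seed = seed)
    mab <- d |>
      group_by(.data$isomir_id, .data$group) |>
      summarise(mean_tpm = mean(.data$tpm), .groups = "drop")
    mab_val <- max(mab$mean_tpm)
    mab_pass <- mab_val > mab_tpm
    fits[[i]] <- fit
    rows[[i]] <- tibble(identifier = out$identifier[i],
                        n_isomirs = fit$n_isomirs, Q = fit$Q, p = fit$p,
                        mab_tpm = mab_val, mab_ok = mab_pass)
  }
  keep_i <- !vapply(rows, is.null, logical(1))
  res <- bind_rows(rows[keep_i])
  if (nrow(res) == 0) {
    return(structure(tibble(identifier = character(), n_isomirs = integer(),
                            Q = numeric(), p = numeric(), q = numeric(),
                            mab_tpm = numeric(), mab_ok = logical(),
                            fits = list()),
                     class = c("mirna_global_tests", class(tibble()))))
  }
  res$q <- bh_fdr(res$p)
  res$fits <- fits[keep_i]
  res <- res |>
    select("identifier", "n_isomirs", "Q", "p", "q", "mab_tpm", "mab_ok",
           "fits") |>
    arrange(.data$p, .data$identifier)
  class(res) <- c("mirna_global_tests", class(res))
  res
}

#' Detect the isomir subsets driving a significant global test
#'
#' Isomirs are clustered by average-linkage on `1 - Pearson
#' correlation` across samples; the global test is then applied to the
#' isomir set of every node of the tree (leaves included), Holm-
#' adjusted across all tested nodes. Returned are all nodes with their
#' adjusted p-values, plus flags for significant leaves and maximal
#' significant nodes (significant nodes with no significant ancestor -
#' the "whole branch" case when the root itself is significant).
#'
#' @param fit A `global_test_result` (with at least 2 isomirs).
#' @param alpha Holm-adjusted significance threshold (default 0.1).
#' @inheritParams global_test
#' @return An `isomir_subsets` list: `nodes` tibble (`node`,
#'   `is_leaf`, `n_members`, `members` list-column, `Q`, `p`,
#'   `p_holm`, `significant`, `maximal`), the `hclust` tree and
#'   `alpha`.
#' @export
isomir_subsets <- function(fit, alpha = 0.1, n_perm = 10000, seed = NULL) {
  stopifnot(inherits(fit, "global_test_result"))
  x <- fit$x
  m <- ncol(x)
  labels <- colnames(x) %||% paste0("x", seq_len(m))
  if (m < 2) {
    node <- tibble(node = 1L, is_leaf = TRUE, n_members = m,
                   members = list(labels), Q = fit$Q, p = fit$p,
                   p_holm = fit$p, significant = fit$p <= alpha,
                   maximal = fit$p <= alpha)
    return(structure(list(nodes = node, tree = NULL, alpha = alpha),
                     class = "isomir_subsets"))
  }
  cc <- suppressWarnings(cor(x))
  cc[is.na(cc)] <- 0
  diag(cc) <- 1
  tree <- hclust(as.dist(1 - cc), method = "average")
  node_members <- vector("list", m - 1)
  for (i in seq_len(m - 1)) {
    mem <- integer()
    for (j in tree$merge[i, ]) {
      mem <- c(mem, if (j < 0) -j else node_members[[j]])
    }
    node_members[[i]] <- sort(mem)
  }
  all_sets <- c(as.list(seq_len(m)), node_members)
  is_leaf <- c(rep(TRUE, m), rep(FALSE, m - 1))
  stats <- purrr::map(all_sets, function(idx) {
    sub <- global_test(x[, idx, drop = FALSE], fit$group, n_perm = n_perm,
                       seed = seed)
    c(Q = sub$Q, p = sub$p)
  })
  Q <- vapply(stats, `[[`, numeric(1), "Q")
  p <- vapply(stats, `[[`, numeric(1), "p")
  p_holm <- holm_adjust(p)
  significant <- p_holm <= alpha
  # ancestor chain: leaf/internal node -> merge row that absorbs it
  parent <- integer(length(all_sets))
  for (i in seq_len(m - 1)) {
    for (j in tree$merge[i, ]) {
      child <- if (j < 0) -j else m + j
      parent[child] <- m + i
    }
  }
  has_sig_ancestor <- vapply(seq_along(all_sets), function(i) {
    a <- parent[i]
    while (a != 0) {
      if (significant[a]) return(TRUE)
      a <- parent[a]
    }
    FALSE
  }, logical(1))
  nodes <- tibble(node = seq_along(all_sets), is_leaf = is_leaf,
                  n_members = lengths(all_sets),
                  members = lapply(all_sets, function(i) labels[i]),
                  Q = Q, p = p, p_holm = p_holm, significant = significant,
                  maximal = significant & !has_sig_ancestor)
  structure(list(nodes = nodes, tree = tree, alpha = alpha),
            class = "isomir_subsets")
}

#' @export
print.isomir_subsets <- function(x, ...) {
  cat(sprintf("<isomir_subsets> %d nodes tested, %d significant at Holm %.2g (%d maximal)\n",
              nrow(x$nodes), sum(x$nodes$significant), x$alpha,
              sum(x$nodes$maximal)))
  invisible(x)
}
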