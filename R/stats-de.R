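#' Differential-expression parameters
#'
#' @param fdr_alpha BH false-discovery-rate threshold (default 0.05).
#' @param min_fold Minimal fold change on the tpm scale (default 1.5).
#' @param min_tpm Minimal group-mean tpm in at least one group
#'   (default 5).
#' @param test `"plain_t"` (Welch two-sample t, the default) or
#'   `"moderated_t"` (empirical-Bayes variance shrinkage with
#'   augmented degrees of freedom).
#' @return A `de_params` list.
#' @export
de_params <- function(fdr_alpha = 0.05, min_fold = 1.5, min_tpm = 5,
                      test = c("plain_t", "moderated_t")) {
  test <- match.arg(test)
  if (fdr_alpha <= 0 || fdr_alpha >= 1) abort("fdr_alpha must lie in (0, 1)")
  if (min_fold < 1) abort("min_fold must be >= 1")
  structure(list(fdr_alpha = fdr_alpha, min_fold = min_fold,
                 min_tpm = min_tpm, test = test), class = "de_params")
}

#' Fold change between two group means
#'
#' Ratio `mean_b / mean_a` on the tpm scale; a zero denominator with a
#' positive numerator yields `Inf`, and `0/0` yields `NaN` (undefined).
#'
#' @param mean_a,mean_b Non-negative group means (tpm).
#' @return Numeric ratio vector.
#' @examples
#' fold_change(1452, 7275.3)
#' @export
fold_change <- function(mean_a, mean_b) {
  if (any(mean_a < 0 | mean_b < 0)) abort("group means must be non-negative")
  ifelse(mean_a == 0 & mean_b == 0, NaN, mean_b / mean_a)
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values in the input order.
#' @export
bh_fdr <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}

#' Holm step-down familywise-error adjustment
#'
#' @inheritParams bh_fdr
#' @return Adjusted values in the input order.
#' @export
holm_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(pvalues, method = "holm")
}

#' Test transcripts for differential expression between two groups
#'
#' Per transcript, a two-sample t-test on `sqrt(tpm)` (Welch by
#' default, or a moderated t with empirical-Bayes variance shrinkage),
#' BH adjustment over all tested transcripts, and the significance
#' filter chain: `q <= fdr_alpha`, fold change (computed from the
#' tpm-scale group means, larger-over-smaller) at least `min_fold`,
#' and a group-mean tpm of at least `min_tpm` in one group.
#'
#' @param expr Wide tibble: an `identifier` column plus one numeric
#'   tpm column per sample.
#' @param group Factor/character of length `ncol(expr) - 1` giving the
#'   two group labels, in the column order of `expr`; at least two
#'   samples per group.
#' @param params A [de_params()].
#' @return A `mirna_de` tibble: `identifier`, `mean_a`, `mean_b`
#'   (tpm), `fold` (b over a), `p`, `q`, `significant`. Group `a` is
#'   the first factor level.
#' @export
diff_expression <- function(expr, group, params = de_params()) {
  stopifnot(inherits(params, "de_params"))
  group <- as.factor(group)
  if (nlevels(group) != 2) abort("exactly two groups are required")
  if (any(table(group) < 2)) {
    abort("at least 2 samples per group are required (treat repeated runs as technical replicates)")
  }
  mat <- as.matrix(expr[setdiff(names(expr), "identifier")])
  if (ncol(mat) != length(group)) {
    abort("group must label every sample column of expr")
  }
  a <- levels(group)[1]
  xa <- mat[, group == a, drop = FALSE]
  xb <- mat[, group != a, drop = FALSE]
  mean_a <- rowMeans(xa); mean_b <- rowMeans(xb)
  tt <- switch(params$test,
    plain_t = welch_rows(sqrt(xa), sqrt(xb)),
    moderated_t = moderated_rows(sqrt(xa), sqrt(xb)))
  q <- bh_fdr(tt$p)
  fold <- fold_change(mean_a, mean_b)
  fold_mag <- ifelse(is.nan(fold), 1, pmax(fold, 1 / fold))
  res <- tibble(identifier = expr$identifier, mean_a = mean_a,
                mean_b = mean_b, fold = fold, p = tt$p, q = q,
                significant = q <= params$fdr_alpha &
                  fold_mag >= params$min_fold &
                  pmax(mean_a, mean_b) >= params$min_tpm)
  attr(res, "params") <- params
  attr(res, "group_levels") <- levels(group)
  class(res) <- c("mirna_de", class(res))
  res
}

# Vectorised Welch t over matrix rows. Zero-variance rows: equal means
# give p = 1, unequal means give p -> 0 (t = Inf).
welch_rows <- function(xa, xb) {
  na <- ncol(xa); nb <- ncol(xb)
  va <- apply(xa, 1, var); vb <- apply(xb, 1, var)
  d <- rowMeans(xb) - rowMeans(xa)
  se2 <- va / na + vb / nb
  t <- ifelse(se2 > 0, d / sqrt(se2), ifelse(d == 0, 0, Inf * sign(d)))
  df <- ifelse(se2 > 0,
               se2^2 / (((va / na)^2 / (na - 1)) + ((vb / nb)^2 / (nb - 1))),
               na + nb - 2)
  df[is.nan(df)] <- na + nb - 2
  p <- 2 * pt(-abs(t), pmax(df, 1))
  p[se2 == 0 & d == 0] <- 1
  list(t = t, df = df, p = p)
}

# Moderated t: pooled per-row variances shrunk toward a scaled
# inverse-chi-square prior whose d0 and s0^2 come from method-of-
# moments on log s^2 (digamma/trigamma equations), t referred to a
# t(d + d0) distribution.
moderated_rows <- function(xa, xb) {
  na <- ncol(xa); nb <- ncol(xb)
  d_res <- na + nb - 2
  va <- apply(xa, 1, var); vb <- apply(xb, 1, var)
  s2 <- ((na - 1) * va + (nb - 1) * vb) / d_res
  pos <- s2 > 0
  if (sum(pos) < 2) {
    return(welch_rows(xa, xb))
  }
  z <- log(s2[pos])
  e <- z - digamma(d_res / 2) + log(d_res / 2)
  ev <- mean(e)
  vz <- mean((z - mean(z))^2) * length(z) / max(length(z) - 1, 1)
  excess <- vz - trigamma(d_res / 2)
  if (excess > 0) {
    d0 <- 2 * inv_trigamma(excess)
    s02 <- exp(ev + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s02 <- exp(ev)
  }
  s2_tilde <- if (is.infinite(d0)) rep(s02, length(s2)) else {
    (d0 * s02 + d_res * s2) / (d0 + d_res)
  }
  d <- rowMeans(xb) - rowMeans(xa)
  t <- d / sqrt(s2_tilde * (1 / na + 1 / nb))
  df_total <- min(d0 + d_res, 1e6)
  p <- 2 * pt(-abs(t), df_total)
  p[s2_tilde == 0 & d == 0] <- 1
  list(t = t, df = df_total, p = p)
}

# Newton solve of trigamma(y) = x, following the standard approach of
# starting from the asymptotic inverse 1/y ~ x.
inv_trigamma <- function(x) {
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif) < 1e-10 * y) break
  }
  y
}

#' @export
tidy.mirna_de <- function(x, ...) {
  as_tibble(x)
}

#' @export
glance.mirna_de <- function(x, ...) {
  p <- attr(x, "params")
  tibble(n_tested = nrow(x), n_significant = sum(x$significant),
         fdr_alpha = p$fdr_alpha, min_fold = p$min_fold,
         min_tpm = p$min_tpm, test = p$test)
}

#' @export
autoplot.mirna_de <- function(object, ...) {
  d <- as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = sqrt(.data$mean_a),
                                  y = sqrt(.data$mean_b),
                                  colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "group A mean, sqrt(tpm)",
                  y = "group B mean, sqrt(tpm)",
                  colour = "significant") +
    ggplot2::theme_minimal()
}
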