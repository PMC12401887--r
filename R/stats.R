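#' Fixed-effects treatment-by-biome ANOVA (Type III)
#'
#' Two-way fixed-effects analysis of variance with Type III (marginal) sums of
#' squares, the appropriate decomposition for the unbalanced designs that
#' arise when plants drop out of a glasshouse experiment. Factors are coded
#' with sum-to-zero contrasts and each term's sum of squares is obtained by
#' comparing the full model against the model with that term's columns
#' removed (all other terms, including the interaction, retained).
#'
#' @param values Numeric response (e.g. per-plant delta-T or beta).
#' @param treatment,biome Factors (or coercible); each must have at least two
#'   observed levels.
#' @return A tibble of class `anova_table` with one row per term (`treatment`,
#'   `biome`, `treatment:biome`, `residuals`): `df`, `sum_sq`, `f`, `p`;
#'   attributes `r_squared` and `df_residual`.
#' @export
two_way_anova <- function(values, treatment, biome) {
  y <- as.numeric(values)
  a <- droplevels(factor(treatment))
  b <- droplevels(factor(biome))
  stopifnot(length(y) == length(a), length(y) == length(b))
  if (nlevels(a) < 2L) stop("treatment factor has a single level", call. = FALSE)
  if (nlevels(b) < 2L) stop("biome factor has a single level", call. = FALSE)
  ok <- !is.na(y) & !is.na(a) & !is.na(b)
  y <- y[ok]; a <- droplevels(a[ok]); b <- droplevels(b[ok])

  dat <- data.frame(y = y, a = a, b = b)
  ctr <- list(a = "contr.sum", b = "contr.sum")
  X <- stats::model.matrix(~ a * b, dat, contrasts.arg = ctr)
  asgn <- attr(X, "assign") # 0 = intercept, 1 = a, 2 = b, 3 = a:b

  rss <- function(cols) {
    fit <- lm.fit(X[, cols, drop = FALSE], y)
    sum(fit$residuals^2)
  }
  rss_full <- rss(seq_len(ncol(X)))
  df_res <- length(y) - qr(X)$rank

  terms <- c(treatment = 1L, biome = 2L, `treatment:biome` = 3L)
  rows <- lapply(names(terms), function(nm) {
    k <- terms[[nm]]
    keep <- which(asgn != k)
    ss <- rss(keep) - rss_full
    df <- sum(asgn == k)
    ms <- ss / df
    f <- ms / (rss_full / df_res)
    tibble::tibble(term = nm, df = df, sum_sq = ss, f = f,
      p = pf(f, df, df_res, lower.tail = FALSE))
  })
  out <- dplyr::bind_rows(rows)
  out <- dplyr::bind_rows(out, tibble::tibble(term = "residuals",
    df = df_res, sum_sq = rss_full, f = NA_real_, p = NA_real_))
  tss <- sum((y - mean(y))^2)
  attr(out, "r_squared") <- 1 - rss_full / tss
  attr(out, "df_residual") <- df_res
  class(out) <- c("anova_table", class(out))
  out
}

#' Pairwise contrasts among group means
#'
#' All pairwise mean differences among groups with family-wise adjusted
#' p-values: Tukey's honest significant differences using the studentized
#' range (Tukey-Kramer for unequal group sizes), or Holm-adjusted t tests.
#' The error variance and degrees of freedom come from the one-way cell-means
#' model pooled across all retained groups. Groups with a single observation
#' carry no within-group information and are excluded with a warning.
#'
#' @param values Numeric response.
#' @param groups Group labels (e.g. the biome x treatment cell).
#' @param method `"tukey"` (default) or `"holm"`.
#' @param level Confidence level for the interval on each difference.
#' @return A tibble with one row per pair: `group_1`, `group_2`, `diff`,
#'   `se`, `lo`, `hi`, `p_adj`.
#' @export
pairwise_contrasts <- function(values, groups, method = c("tukey", "holm"),
                               level = 0.95) {
  method <- match.arg(method)
  y <- as.numeric(values)
  g <- droplevels(factor(groups))
  ok <- !is.na(y) & !is.na(g)
  y <- y[ok]; g <- droplevels(g[ok])
  ns <- table(g)
  singletons <- names(ns)[ns < 2]
  if (length(singletons) > 0L) {
    warning("excluding group(s) with n = 1: ",
      paste(singletons, collapse = ", "), call. = FALSE)
    keep <- !(g %in% singletons)
    y <- y[keep]; g <- droplevels(g[keep])
    ns <- table(g)
  }
  k <- nlevels(g)
  if (k < 2L) stop("need at least two groups with n >= 2", call. = FALSE)
  means <- tapply(y, g, mean)
  df <- length(y) - k
  s2 <- sum(tapply(y, g, function(v) sum((v - mean(v))^2))) / df

  pairs <- utils::combn(levels(g), 2)
  rows <- apply(pairs, 2, function(pr) {
    n1 <- ns[[pr[1]]]; n2 <- ns[[pr[2]]]
    d <- means[[pr[2]]] - means[[pr[1]]]
    se <- sqrt(s2 * (1 / n1 + 1 / n2))
    if (method == "tukey") {
      q <- abs(d) / sqrt(s2 * 0.5 * (1 / n1 + 1 / n2))
      p <- ptukey(q, k, df, lower.tail = FALSE)
      crit <- stats::qtukey(level, k, df) / sqrt(2)
    } else {
      p <- 2 * pt(abs(d) / se, df, lower.tail = FALSE)
      crit <- stats::qt(1 - (1 - level) / 2, df)
    }
    tibble::tibble(group_1 = pr[1], group_2 = pr[2], diff = d, se = se,
      lo = d - crit * se, hi = d + crit * se, p_adj = p)
  })
  out <- dplyr::bind_rows(rows)
  if (method == "holm") out$p_adj <- p.adjust(out$p_adj, "holm")
  out
}

#' Nonparametric bootstrap confidence interval for a mean
#'
#' Percentile bootstrap: the mean of each of `n_boot` resamples (with
#' replacement) is computed and the interval taken as the matching quantiles
#' of the resampled means. Seeded for reproducibility without touching the
#' caller's RNG state.
#'
#' @param values Numeric vector, n >= 2.
#' @param n_boot Number of bootstrap resamples.
#' @param level Confidence level.
#' @param seed Optional integer seed (RNG state is restored on exit).
#' @return A one-row tibble: `mean`, `lo`, `hi`, `n`.
#' @export
bootstrap_mean_ci <- function(values, n_boot = 1000, level = 0.95,
                              seed = NULL) {
  x <- as.numeric(values)
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 2L) stop("need at least two observations to bootstrap", call. = FALSE)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", .GlobalEnv)) rm(".Random.seed", envir = .GlobalEnv)
      } else {
        assign(".Random.seed", old, .GlobalEnv)
      }
    })
    set.seed(seed)
  }
  draws <- matrix(sample(x, n * n_boot, replace = TRUE), nrow = n)
  boots <- colMeans(draws)
  alpha <- (1 - level) / 2
  ci <- quantile(boots, c(alpha, 1 - alpha), names = FALSE)
  tibble::tibble(mean = mean(x), lo = ci[1], hi = ci[2], n = n)
}

#' Group means with bootstrap confidence intervals
#'
#' Applies [bootstrap_mean_ci()] within each group of a grouping column pair
#' (typically biome x treatment).
#'
#' @param data Tibble containing `value_col` and the grouping columns.
#' @param value_col Name of the response column.
#' @param group_cols Character vector of grouping columns.
#' @inheritParams bootstrap_mean_ci
#' @return A tibble with one row per group: the grouping columns plus `mean`,
#'   `lo`, `hi`, `n`.
#' @export
group_summaries <- function(data, value_col, group_cols = c("biome", "treatment"),
                            n_boot = 1000, level = 0.95, seed = NULL) {
  stopifnot(value_col %in% names(data), all(group_cols %in% names(data)))
  groups <- data[, group_cols, drop = FALSE]
  key <- interaction(groups, drop = TRUE, lex.order = TRUE)
  keys <- levels(key)
  rows <- lapply(seq_along(keys), function(i) {
    sel <- key == keys[i]
    ci <- bootstrap_mean_ci(data[[value_col]][sel], n_boot, level,
      seed = if (is.null(seed)) NULL else seed + i)
    dplyr::bind_cols(groups[which(sel)[1], , drop = FALSE], ci)
  })
  dplyr::bind_rows(rows)
}
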