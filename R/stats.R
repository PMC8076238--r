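#' One-way analysis of variance across site groups
#'
#' Classical equal-variance one-way ANOVA (between/within decomposition, F
#' with `k-1` and `N-k` degrees of freedom) across named groups, as used to
#' compare the four measurement-site groups.  When every observation is
#' identical the between-group sum of squares is zero and `F = 0`, `p = 1`.
#'
#' @param groups named list of numeric vectors, each of length >= 2.
#' @return A list of class `anova_result`: `F`, `df_between`, `df_within`,
#'   `p_value`, `group_means`, `ms_within`.
#' @export
one_way_anova <- function(groups) {
  .check_groups(groups)
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  fit <- aov(values ~ g)
  tab <- summary(fit)[[1]]
  ssb <- tab["g", "Sum Sq"]
  ssw <- tab["Residuals", "Sum Sq"]
  dfb <- tab["g", "Df"]
  dfw <- tab["Residuals", "Df"]
  sst <- ssb + ssw
  # guard degenerate decompositions against floating-point dust
  scale2 <- max(sst, max(abs(values))^2 * .Machine$double.eps)
  if (diff(range(values)) == 0 || ssb <= 1e-10 * scale2) {
    F <- 0; p <- 1
  } else if (ssw <= 1e-12 * sst) {
    F <- Inf; p <- 0
  } else {
    F <- (ssb / dfb) / (ssw / dfw)
    p <- pf(F, dfb, dfw, lower.tail = FALSE)
  }
  means <- vapply(groups, mean, 0)
  if (is.null(names(means))) names(means) <- paste0("group", seq_along(groups))
  structure(list(F = F, df_between = dfb, df_within = dfw, p_value = p,
                 group_means = means, ms_within = ssw / dfw),
            class = "anova_result")
}

.check_groups <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("need a list of >= 2 groups")
  n <- lengths(groups)
  if (any(n < 2))
    stop("insufficient data: every group needs n >= 2 (group sizes: ",
         paste(n, collapse = ", "), ")")
  if (!all(vapply(groups, function(x) all(is.finite(x)), TRUE)))
    stop("non-finite values in groups")
  invisible(n)
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.3g\n",
              x$df_between, x$df_within, x$F, x$p_value))
  invisible(x)
}

#' Scheffe post-hoc pairwise tests
#'
#' For each pair of groups,
#' `F_pair = (mean_i - mean_j)^2 / (MSW * (1/n_i + 1/n_j))` and
#' `p = P(F_{k-1, N-k} > F_pair / (k-1))` -- the conservative Scheffe
#' contrast test run after a significant one-way ANOVA on the same groups.
#' `sig` flags pairs with `p < alpha`.
#'
#' @inheritParams one_way_anova
#' @param alpha familywise significance level.
#' @return A list of class `scheffe_result`: symmetric `p_value` and `sig`
#'   matrices, `ms_within`, `alpha`.
#' @export
scheffe_test <- function(groups, alpha = 0.05) {
  n <- .check_groups(groups)
  k <- length(groups)
  aov_res <- one_way_anova(groups)
  msw <- aov_res$ms_within
  dfw <- aov_res$df_within
  means <- vapply(groups, mean, 0)
  p <- matrix(1, k, k)
  nm <- names(groups)
  if (is.null(nm)) nm <- paste0("group", seq_len(k))
  dimnames(p) <- list(nm, nm)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    if (msw <= 0) {
      pij <- if (means[i] == means[j]) 1 else 0
    } else {
      Fp <- (means[i] - means[j])^2 / (msw * (1 / n[i] + 1 / n[j]))
      pij <- pf(Fp / (k - 1), k - 1, dfw, lower.tail = FALSE)
    }
    p[i, j] <- p[j, i] <- pij
  }
  structure(list(p_value = p, sig = (p < alpha) * 1L, ms_within = msw,
                 alpha = alpha),
            class = "scheffe_result")
}

#' @export
print.scheffe_result <- function(x, ...) {
  cat("Scheffe pairwise p-values (alpha =", x$alpha, "):\n")
  print(round(x$p_value, 4))
  invisible(x)
}

#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("x and y must have equal length >= 3")
  if (sd(x) == 0 || sd(y) == 0)
    stop("undefined correlation: zero variance")
  stats::cor(x, y, method = "pearson")
}

#' Box-and-whisker summary statistics
#'
#' Quartiles by linear interpolation of order statistics
#' ([stats::quantile()] type 7), outliers beyond 1.5 IQR from the box, and
#' whiskers extending to the most extreme non-outlying points -- the
#' convention used for the cohort box plots.
#'
#' @param values numeric vector, length >= 4.
#' @return A list of class `box_stats`: `q25`, `q75`, `mean`, `median`,
#'   `whisker_low`, `whisker_high`, `outliers`.
#' @export
box_whisker_stats <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 4)
    stop("insufficient data: need >= 4 finite values")
  q <- quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  lo <- q[1] - 1.5 * iqr
  hi <- q[3] + 1.5 * iqr
  out <- values[values < lo | values > hi]
  inl <- values[values >= lo & values <= hi]
  structure(list(q25 = q[1], q75 = q[3], mean = mean(values), median = q[2],
                 whisker_low = min(inl), whisker_high = max(inl),
                 outliers = out),
            class = "box_stats")
}
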