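#' Median and interquartile range
#'
#' Summarises a sample by its median (middle order statistic, mean of the two
#' middles for even n) and interquartile range. Quartiles use the linear
#' order-statistic interpolation in which quantile `q` sits at position
#' `1 + q * (n - 1)` (the default convention of [stats::quantile()]).
#'
#' @param x A non-empty numeric vector; `NA`s are dropped.
#' @return A one-row tibble with columns `n`, `median`, `iqr`.
#' @examples
#' median_iqr(c(1, 2, 3, 4)) # median 2.5, IQR 1.5
#' @export
median_iqr <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) abort("median_iqr: empty sample")
  q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  tibble(n = length(x), median = q[2], iqr = q[3] - q[1])
}

#' Mann-Whitney rank test for two groups
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test with tie handling by
#' midranks. For small pooled samples (`n_x + n_y <= exact_limit`) the
#' p-value is computed by complete permutation enumeration of the observed
#' midranks, so it is exact even under ties. Otherwise a normal approximation
#' with tie-corrected variance and a continuity correction of 1/2 is used.
#' The result carries per-group medians, IQRs and sizes.
#'
#' Missing values (e.g. districts whose utilization rate is undefined because
#' they have no insured population) are excluded with a message stating how
#' many were dropped: an undefined value has no rank.
#'
#' @param x,y Numeric samples for the two groups (both non-empty after
#'   dropping `NA`s).
#' @param labels Length-2 character vector of group labels.
#' @param exact_limit Largest pooled sample size for which the exact
#'   permutation branch is used (default 12).
#' @return An object of class `rank_test`: a list with `test` (name),
#'   `statistic` (U of the first group), `p_value`, `method`
#'   (`"exact-permutation"` or `"normal-approximation"`), and `groups`
#'   (a tibble of label, n, median, iqr). Use [generics::tidy()] /
#'   [generics::glance()] to extract tibbles.
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6)) # exact p = 0.1
#' @export
mann_whitney <- function(x, y, labels = c("x", "y"), exact_limit = 12) {
  dropped <- sum(is.na(x)) + sum(is.na(y))
  if (dropped > 0) {
    inform(sprintf("mann_whitney: excluded %d undefined value(s)", dropped))
  }
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) == 0 || length(y) == 0) {
    abort("mann_whitney: both groups must be non-empty")
  }

  nx <- length(x)
  ny <- length(y)
  n <- nx + ny
  r <- rank(c(x, y)) # midranks
  u_x <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  mu <- nx * ny / 2

  if (n <= exact_limit) {
    # permutation distribution of U over all assignments of the observed
    # midranks to the first group; symmetric about mu, so the two-sided
    # p-value is the tail mass at least as far from mu as observed
    sets <- combn(n, nx)
    u_all <- colSums(matrix(r[sets], nrow = nx)) - nx * (nx + 1) / 2
    p <- mean(abs(u_all - mu) >= abs(u_x - mu) - 1e-9)
    method <- "exact-permutation"
  } else {
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- nx * ny / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- max(abs(u_x - mu) - 0.5, 0) / sqrt(sigma2) # continuity correction
      p <- min(1, 2 * pnorm(-z))
    }
    method <- "normal-approximation"
  }

  new_rank_test(
    test = "Mann-Whitney",
    statistic = c(U = u_x),
    p_value = p,
    method = method,
    groups = bind_rows(
      mutate(median_iqr(x), label = labels[1], .before = 1),
      mutate(median_iqr(y), label = labels[2], .before = 1)
    )
  )
}

#' Kruskal-Wallis rank test for two or more groups
#'
#' Rank-based one-way comparison of `k >= 2` groups. H is computed from
#' midranks with the standard tie correction and referred to the chi-square
#' law with `k - 1` degrees of freedom. The result carries per-group medians,
#' IQRs and sizes. When every pooled value is identical, H is 0 and p is 1.
#'
#' @param x A named list of numeric samples, or a numeric vector accompanied
#'   by `g`.
#' @param g Group labels (same length as `x`) when `x` is a vector.
#' @return An object of class `rank_test` (see [mann_whitney()]).
#' @examples
#' kruskal_wallis(list(a = c(1, 5, 8), b = c(2, 3, 4), c = c(6, 7, 9)))
#' @export
kruskal_wallis <- function(x, g = NULL) {
  if (!is.list(x)) {
    stopifnot(!is.null(g), length(g) == length(x))
    keep <- !is.na(x)
    x <- split(x[keep], g[keep])
  } else {
    x <- lapply(x, function(v) v[!is.na(v)])
  }
  x <- x[lengths(x) > 0]
  k <- length(x)
  if (k < 2) abort("kruskal_wallis: need at least 2 non-empty groups")
  if (is.null(names(x))) names(x) <- paste0("group", seq_len(k))

  pooled <- unlist(x, use.names = FALSE)
  n_j <- lengths(x)
  n <- length(pooled)
  r <- rank(pooled)
  grp <- rep(seq_len(k), n_j)
  r_sums <- vapply(split(r, grp), sum, numeric(1))

  h_raw <- 12 / (n * (n + 1)) * sum(r_sums^2 / n_j) - 3 * (n + 1)
  ties <- table(r)
  correction <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (correction <= 0) {
    h <- 0 # all pooled values identical
    p <- 1
  } else {
    h <- h_raw / correction
    p <- pchisq(h, df = k - 1, lower.tail = FALSE)
  }

  new_rank_test(
    test = "Kruskal-Wallis",
    statistic = c(H = h),
    p_value = p,
    method = "chi-square-approximation",
    groups = purrr::imap_dfr(
      x, function(v, nm) mutate(median_iqr(v), label = nm, .before = 1)
    )
  )
}

new_rank_test <- function(test, statistic, p_value, method, groups) {
  structure(
    list(test = test, statistic = statistic, p_value = p_value,
         method = method, groups = groups),
    class = "rank_test"
  )
}

#' @export
print.rank_test <- function(x, ...) {
  cat(sprintf("%s test (%s)\n", x$test, x$method))
  cat(sprintf("  %s = %.4g, p = %.4g\n",
              names(x$statistic), x$statistic, x$p_value))
  cat(sprintf("  %s: n = %d, median = %.4g, IQR = %.4g\n",
              x$groups$label, x$groups$n, x$groups$median, x$groups$iqr),
      sep = "")
  invisible(x)
}

#' Tidiers for rank tests
#'
#' `tidy()` returns the per-group summaries (label, n, median, IQR);
#' `glance()` returns a one-row tibble with the statistic, p-value, method
#' and sizes.
#'
#' @param x A `rank_test` object.
#' @param ... Unused.
#' @method tidy rank_test
#' @export
tidy.rank_test <- function(x, ...) {
  x$groups
}

#' @rdname tidy.rank_test
#' @method glance rank_test
#' @export
glance.rank_test <- function(x, ...) {
  tibble(
    test = x$test,
    statistic = unname(x$statistic),
    p.value = x$p_value,
    method = x$method,
    n_groups = nrow(x$groups),
    n_total = sum(x$groups$n)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
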