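# Nonparametric cohort statistics: Mann-Whitney U comparisons, inverse
# diameter-velocity regression, quartile outlier flagging, subgroup splits.

#' Two-tailed Mann-Whitney U test
#'
#' Rank-sum U with midrank ties. For small untied samples
#' (`min(n) <= 8`) the p-value is exact, computed from the full null
#' distribution of U; otherwise the normal approximation with tie-corrected
#' variance and continuity correction is used. If every value in both
#' samples is identical, `p = 1` by convention.
#'
#' @param x,y numeric samples (non-empty).
#' @param alpha significance level for the `significant` flag.
#' @return object of class `group_comparison`: per-group n/mean/SD/median/
#'   IQR, `u` (U statistic of `x`), two-tailed `p`, `significant`, `method`.
#' @export
mann_whitney <- function(x, y, alpha = 0.05) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(c(x, y))
  has_ties <- any(ties > 1L)
  if (all(c(x, y) == c(x, y)[1L])) {
    p <- 1; method <- "degenerate"
  } else if (!has_ties && min(n1, n2) <= 8L) {
    cdf <- u_null_cdf(n1, n2)           # P(U <= u), u = 0..n1*n2
    u_int <- as.integer(round(u1))
    p_le <- cdf[u_int + 1L]
    p_ge <- 1 - (if (u_int >= 1L) cdf[u_int] else 0)
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    nn <- n1 + n2
    tiecor <- sum(ties^3 - ties) / (nn * (nn - 1))
    sig2 <- n1 * n2 / 12 * ((nn + 1) - tiecor)
    z <- (u1 - mu - sign(u1 - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal"
  }
  iqr_ex <- function(v) { q <- quartiles_exclusive(v); unname(q[2L] - q[1L]) }
  structure(list(n = c(length(x), length(y)),
                 mean = c(mean(x), mean(y)), sd = c(stats::sd(x), stats::sd(y)),
                 median = c(stats::median(x), stats::median(y)),
                 iqr = c(iqr_ex(x), iqr_ex(y)),
                 u = u1, p = p, significant = p < alpha, alpha = alpha,
                 method = method),
            class = "group_comparison")
}

# exact null CDF of the Mann-Whitney U statistic (no ties): enumerate the
# rank-sum distribution of n1 ranks drawn from 1..n1+n2 by subset-sum
# dynamic programming, then shift to U = W - n1(n1+1)/2
u_null_cdf <- function(n1, n2) {
  nn <- n1 + n2
  smax <- sum((n2 + 1L):nn)            # largest possible rank sum
  g <- matrix(0, n1 + 1L, smax + 1L)   # g[k+1, s+1]: #subsets of size k, sum s
  g[1L, 1L] <- 1
  for (t in seq_len(nn)) {
    for (k in rev(seq_len(min(t, n1)))) {
      src <- seq_len(smax + 1L - t)
      g[k + 1L, src + t] <- g[k + 1L, src + t] + g[k, src]
    }
  }
  w_counts <- g[n1 + 1L, ]
  smin <- n1 * (n1 + 1L) / 2           # smallest rank sum -> U = 0
  u_counts <- w_counts[(smin + 1L):(smin + n1 * n2 + 1L)]
  cumsum(u_counts) / sum(u_counts)
}

#' @exportS3Method base::print
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> n = (%d, %d), U = %.1f, p = %.4g (%s)%s\n",
              x$n[1L], x$n[2L], x$u, x$p, x$method,
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Inverse diameter-velocity regression U = a/D
#'
#' Least squares on the transformed regressor `1/D` with no intercept:
#' `a = sum(U/D) / sum(1/D^2)`. The coefficient of determination is taken
#' against the mean-of-U baseline and may be negative when the forced
#' inverse model fits worse than a constant.
#'
#' @param d diameters in mm, all > 0.
#' @param u representative velocities in mm/s.
#' @return object of class `inverse_fit`: `a` (mm^2/s), `r_squared`,
#'   `residuals`, `fitted`.
#' @export
fit_inverse <- function(d, u) {
  ok <- !is.na(d) & !is.na(u)
  d <- d[ok]; u <- u[ok]
  if (length(d) < 2L) stop("need at least 2 observations")
  if (any(d <= 0)) stop("all diameters must be > 0")
  a <- sum(u / d) / sum(1 / d^2)
  fit <- a / d
  ss_res <- sum((u - fit)^2)
  ss_tot <- sum((u - mean(u))^2)
  structure(list(a = a, r_squared = 1 - ss_res / ss_tot,
                 residuals = u - fit, fitted = fit, n = length(d)),
            class = "inverse_fit")
}

#' @exportS3Method base::print
print.inverse_fit <- function(x, ...) {
  cat(sprintf("<inverse_fit> U = a/D with a = %.2f mm^2/s, R^2 = %.3f (n = %d)\n",
              x$a, x$r_squared, x$n))
  invisible(x)
}

# median-exclusive (Moore) quartiles: medians of the lower/upper halves,
# excluding the overall median when n is odd
quartiles_exclusive <- function(x) {
  x <- sort(x[!is.na(x)])
  n <- length(x)
  h <- n %/% 2L
  c(q1 = stats::median(x[seq_len(h)]), q3 = stats::median(x[n - h + seq_len(h)]))
}

#' Flag outliers outside the interquartile range
#'
#' Literal quartile rule: values strictly below Q1 or strictly above Q3 are
#' flagged, with median-exclusive quartiles. The conventional Tukey
#' `1.5 x IQR` fence is available as `rule = "fence"`.
#'
#' @param x numeric sample (n >= 4).
#' @param rule `"iqr"` (outside [Q1, Q3]) or `"fence"` (outside
#'   [Q1 - 1.5 IQR, Q3 + 1.5 IQR]).
#' @return integer indices of flagged values, with attribute `bounds`.
#' @export
flag_outliers <- function(x, rule = c("iqr", "fence")) {
  rule <- match.arg(rule)
  if (sum(!is.na(x)) < 4L) stop("need at least 4 observations")
  q <- quartiles_exclusive(x)
  bounds <- if (rule == "iqr") q
            else c(q1 = q[[1L]] - 1.5 * (q[[2L]] - q[[1L]]),
                   q3 = q[[2L]] + 1.5 * (q[[2L]] - q[[1L]]))
  idx <- which(x < bounds[[1L]] | x > bounds[[2L]])
  attr(idx, "bounds") <- bounds
  attr(idx, "quartile_method") <- "median-exclusive"
  idx
}

#' Split a cohort into comparison subgroups
#'
#' Sex split and age split with the young/older boundary at 65 years
#' (`>= 65` is older). Subjects with missing age are excluded from the age
#' split with a warning.
#'
#' @param cohort a `csf_cohort` data frame (needs `sex`, `age`).
#' @param age_boundary years.
#' @return list of index vectors: `male`, `female`, `young`, `older`.
#' @export
split_groups <- function(cohort, age_boundary = 65) {
  if (any(is.na(cohort$age))) {
    warning(sprintf("%d subjects with missing age excluded from the age split",
                    sum(is.na(cohort$age))))
  }
  list(male = which(cohort$sex == "male"),
       female = which(cohort$sex == "female"),
       young = which(!is.na(cohort$age) & cohort$age < age_boundary),
       older = which(!is.na(cohort$age) & cohort$age >= age_boundary))
}

#' Ordinary least-squares fit with intercept
#'
#' Used for the mix-norm-versus-Reynolds-number relationship.
#'
#' @param x,y numeric vectors (n >= 2, `x` non-degenerate).
#' @return list with `slope`, `intercept`, `r_squared`.
#' @export
linear_fit <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2L) stop("need at least 2 observations")
  if (stats::sd(x) == 0) stop("degenerate x: zero variance")
  fit <- stats::lm(y ~ x)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 0)
}
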