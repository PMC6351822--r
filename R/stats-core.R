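# Self-contained statistical kernels used by every analysis stage.
# Rank tests use mid-ranks for ties and the tie-corrected formulas; tail
# probabilities come from base R's distribution functions.

check_groups <- function(groups, min_size = 1L) {
  if (!is.list(groups) || length(groups) < 2L)
    cf_stop("`groups` must be a list of at least two numeric vectors")
  if (any(!vapply(groups, is.numeric, logical(1))))
    cf_stop("all groups must be numeric")
  sizes <- lengths(groups)
  if (any(sizes < min_size))
    cf_stop("every group needs at least ", min_size, " value(s)")
  if (any(!vapply(groups, function(g) all(is.finite(g)), logical(1))))
    cf_stop("groups must not contain NA or infinite values")
  invisible(sizes)
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected Kruskal-Wallis H across two or more groups, with the p-value
#' from the asymptotic chi-square distribution on k - 1 degrees of freedom.
#' Mid-ranks are used for ties. When every observation is identical the tie
#' correction degenerates; H is then 0 and p is 1.
#'
#' @param groups List of (at least two) non-empty numeric vectors.
#' @return A list of class `cffrag_test` with elements `statistic` (H), `df`,
#'   `p.value` and `method`.
#' @examples
#' kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))$statistic  # 7.2
#' @export
kruskal_wallis <- function(groups) {
  check_groups(groups)
  x <- unlist(groups, use.names = FALSE)
  g <- rep.int(seq_along(groups), lengths(groups))
  n <- length(x)
  if (n < 3L) cf_stop("need at least 3 observations in total")
  r <- rank(x)
  rsum <- rowsum(r, g)[, 1L]
  h0 <- 12 / (n * (n + 1)) * sum(rsum^2 / lengths(groups)) - 3 * (n + 1)
  t <- tabulate(match(x, unique(x)))
  corr <- 1 - sum(t^3 - t) / (n^3 - n)
  if (corr <= 0) {
    h <- 0
    p <- 1
  } else {
    h <- h0 / corr
    p <- pchisq(h, df = length(groups) - 1L, lower.tail = FALSE)
  }
  structure(list(statistic = h, df = length(groups) - 1L, p.value = p,
                 method = "Kruskal-Wallis rank test (tie-corrected)"),
            class = "cffrag_test")
}

#' Dunn's post hoc pairwise test
#'
#' All pairwise z statistics after a Kruskal-Wallis test,
#' \eqn{z = (\bar R_i - \bar R_j) / \sqrt{(N(N+1)/12 - T)(1/n_i + 1/n_j)}}
#' with tie term \eqn{T = \sum (t^3 - t) / (12 (N - 1))}, two-sided normal
#' p-values and Benjamini-Hochberg adjustment across the pairs.
#'
#' @param groups List of non-empty numeric vectors; names label the groups.
#' @return Data frame with one row per unordered pair: `group1`, `group2`,
#'   `z` (sign of group1 minus group2 mean rank), `p`, `p_adj`.
#' @export
dunn_posthoc <- function(groups) {
  check_groups(groups)
  nm <- names(groups) %||% paste0("group", seq_along(groups))
  names(groups) <- nm
  x <- unlist(groups, use.names = FALSE)
  g <- rep.int(seq_along(groups), lengths(groups))
  n <- length(x)
  r <- rank(x)
  rbar <- rowsum(r, g)[, 1L] / lengths(groups)
  t <- tabulate(match(x, unique(x)))
  tie <- sum(t^3 - t) / (12 * (n - 1))
  pairs <- utils::combn(seq_along(groups), 2L)
  z <- p <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    s2 <- (n * (n + 1) / 12 - tie) * (1 / lengths(groups)[i] + 1 / lengths(groups)[j])
    if (s2 <= 0) {
      z[k] <- 0
      p[k] <- 1
    } else {
      z[k] <- (rbar[i] - rbar[j]) / sqrt(s2)
      p[k] <- 2 * pnorm(-abs(z[k]))
    }
  }
  data.frame(group1 = nm[pairs[1L, ]], group2 = nm[pairs[2L, ]],
             z = z, p = p, p_adj = bh_fdr(p), row.names = NULL)
}

#' Brown-Forsythe (median-centred Levene) variance test
#'
#' One-way ANOVA F statistic on absolute deviations from each group's centre
#' (median by default, the Brown-Forsythe variant; `center = "mean"` gives the
#' classical Levene test). Degenerate cases are resolved deterministically:
#' zero between- and within-group deviation spread gives W = 0, p = 1;
#' positive between-group spread with zero within-group spread gives W = Inf,
#' p = 0.
#'
#' @param groups List of numeric vectors, each with at least two values.
#' @param center `"median"` (default) or `"mean"`.
#' @return A `cffrag_test` list: `statistic` (W), `df`, `p.value`.
#' @export
levene_bf <- function(groups, center = c("median", "mean")) {
  center <- match.arg(center)
  check_groups(groups, min_size = 2L)
  cfun <- if (center == "median") stats::median else mean
  z <- lapply(groups, function(g) abs(g - cfun(g)))
  k <- length(z)
  n <- lengths(z)
  ntot <- sum(n)
  zbar_i <- vapply(z, mean, numeric(1))
  zbar <- sum(unlist(z)) / ntot
  num <- sum(n * (zbar_i - zbar)^2) / (k - 1)
  den <- sum(vapply(z, function(zi) sum((zi - mean(zi))^2), numeric(1))) / (ntot - k)
  if (den == 0) {
    w <- if (num == 0) 0 else Inf
    p <- if (num == 0) 1 else 0
  } else {
    w <- num / den
    p <- pf(w, k - 1, ntot - k, lower.tail = FALSE)
  }
  structure(list(statistic = w, df = c(k - 1L, ntot - k), p.value = p,
                 method = paste0("Brown-Forsythe/Levene test (", center, "-centred)")),
            class = "cffrag_test")
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up FDR adjustment: sorted p-values are multiplied by m/rank, the
#' running minimum is taken from the largest p downwards, and results are
#' clipped at 1. Adjusted values are never smaller than the input and keep
#' the sort order of the raw p-values.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in the original order.
#' @export
bh_fdr <- function(p) {
  if (!is.numeric(p)) cf_stop("`p` must be numeric")
  if (length(p) == 0L) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    cf_stop("p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / (m:1) * p[o]))[ro]
}

#' Coefficient of variation, in percent
#'
#' `100 * sd(x) / mean(x)` with the sample (n - 1) standard deviation, the
#' replicate-variability summary used for window means around anchors.
#'
#' @param x Numeric vector with at least two values and non-zero mean.
#' @return Scalar percent CV.
#' @export
cv_percent <- function(x) {
  if (length(x) < 2L) cf_stop("CV needs at least two replicates")
  m <- mean(x)
  if (m == 0) cf_stop("CV undefined for zero mean")
  100 * stats::sd(x) / m
}

# Split-chain potential scale reduction factor for a single parameter chain.
split_rhat <- function(x) {
  n <- floor(length(x) / 2) * 2
  if (n < 4L) return(NA_real_)
  half <- matrix(x[seq_len(n)], ncol = 2L)
  w <- mean(apply(half, 2L, stats::var))
  b <- (n / 2) * stats::var(colMeans(half))
  if (w == 0) return(1)
  sqrt(((n / 2 - 1) / (n / 2) * w + b / (n / 2)) / w)
}

#' Gibbs sampler for a normal random-intercept model
#'
#' Fits \eqn{y_{ij} = \beta_{g(j)} + u_i + \epsilon_{ij}} with bin random
#' intercepts \eqn{u_i \sim N(0, \sigma_u^2)} and residuals
#' \eqn{\epsilon \sim N(0, \sigma_e^2)} by Gibbs sampling with conjugate
#' updates: flat-ish normal priors on the group means \eqn{\beta_g} and
#' inverse-gamma(`prior_shape`, `prior_rate`) priors on both variances.
#' Group contrasts (the quantity of scientific interest) are differences of
#' the \eqn{\beta_g} draws; see [posterior_pairwise()].
#'
#' @param y Numeric response vector (one value per bin x sample observation).
#' @param bin Factor-like vector of bin identifiers, same length as `y`.
#' @param group Factor-like vector of group labels, same length as `y`.
#' @param n_iter,burn_in,thin MCMC settings; the defaults (13000 / 3000 / 10)
#'   follow common animal-model defaults and leave 1000 retained draws.
#' @param seed RNG seed; the chain is fully reproducible.
#' @param prior_shape,prior_rate Inverse-gamma hyperparameters for both
#'   variance components.
#' @param effect_prior_var Prior variance of each group mean.
#' @return Object of class `gibbs_fit`: `draws` (matrix of retained draws with
#'   columns `beta.<level>`, `sigma_u2`, `sigma_e2`), `groups`, `rhat` per
#'   column and a `converged` flag (all split-chain R-hat <= 1.1).
#' @export
gibbs_random_intercept <- function(y, bin, group, n_iter = 13000L,
                                   burn_in = 3000L, thin = 10L, seed = 1L,
                                   prior_shape = 0.001, prior_rate = 0.001,
                                   effect_prior_var = 1e8) {
  if (length(y) == 0L) cf_stop("no observations")
  if (length(bin) != length(y) || length(group) != length(y))
    cf_stop("`bin` and `group` must match `y` in length")
  if (any(!is.finite(y))) cf_stop("`y` must be finite")
  if (stats::var(y) == 0) cf_stop("all responses identical: variance components are degenerate")
  bin <- factor(bin)
  group <- factor(group)
  nb <- nlevels(bin)
  ng <- nlevels(group)
  if (ng < 2L) cf_stop("need at least 2 groups")
  if (nb < 2L) cf_stop("need at least 2 bins")
  if (!(n_iter > burn_in && thin >= 1L)) cf_stop("invalid MCMC settings")
  bi <- as.integer(bin)
  gi <- as.integer(group)
  n <- length(y)
  cnt_g <- tabulate(gi, ng)
  cnt_b <- tabulate(bi, nb)
  if (any(cnt_g == 0L)) cf_stop("empty group level")

  keep <- seq.int(burn_in + thin, n_iter, by = thin)
  draws <- matrix(NA_real_, length(keep), ng + 2L)
  colnames(draws) <- c(paste0("beta.", levels(group)), "sigma_u2", "sigma_e2")

  with_seed(seed, {
    beta <- rowsum(y, gi)[, 1L] / cnt_g
    u <- numeric(nb)
    se2 <- max(stats::var(y), 1e-8)
    su2 <- se2 / 2
    kidx <- 1L
    for (it in seq_len(n_iter)) {
      r <- y - u[bi]
      v <- 1 / (cnt_g / se2 + 1 / effect_prior_var)
      beta <- rnorm(ng, v * rowsum(r, gi)[, 1L] / se2, sqrt(v))
      r2 <- y - beta[gi]
      vb <- 1 / (cnt_b / se2 + 1 / su2)
      u <- rnorm(nb, vb * rowsum(r2, bi)[, 1L] / se2, sqrt(vb))
      su2 <- 1 / rgamma(1, prior_shape + nb / 2, prior_rate + sum(u^2) / 2)
      resid <- r2 - u[bi]
      se2 <- 1 / rgamma(1, prior_shape + n / 2, prior_rate + sum(resid^2) / 2)
      if (kidx <= length(keep) && it == keep[kidx]) {
        draws[kidx, ] <- c(beta, su2, se2)
        kidx <- kidx + 1L
      }
    }
  })

  rhat <- apply(draws, 2L, split_rhat)
  structure(list(draws = draws, groups = levels(group),
                 settings = list(n_iter = n_iter, burn_in = burn_in,
                                 thin = thin, seed = seed),
                 rhat = rhat,
                 converged = all(is.na(rhat) | rhat <= 1.1)),
            class = "gibbs_fit")
}

#' Pairwise posterior group contrasts from a Gibbs fit
#'
#' For every unordered pair of groups, summarises the posterior of
#' \eqn{\beta_a - \beta_b}: median, central credible interval and a
#' significance flag (interval excludes zero).
#'
#' @param fit A [gibbs_random_intercept()] result.
#' @param prob Credible interval mass (default 0.95).
#' @return Data frame: `group1`, `group2`, `median`, `lo`, `hi`, `significant`.
#' @export
posterior_pairwise <- function(fit, prob = 0.95) {
  stopifnot(inherits(fit, "gibbs_fit"), prob > 0, prob < 1)
  g <- fit$groups
  pairs <- utils::combn(seq_along(g), 2L)
  alpha <- (1 - prob) / 2
  out <- vector("list", ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    d <- fit$draws[, paste0("beta.", g[i])] - fit$draws[, paste0("beta.", g[j])]
    q <- unname(stats::quantile(d, c(alpha, 0.5, 1 - alpha)))
    out[[k]] <- data.frame(group1 = g[i], group2 = g[j], median = q[2L],
                           lo = q[1L], hi = q[3L],
                           significant = q[1L] > 0 || q[3L] < 0)
  }
  do.call(rbind, out)
}

#' @export
print.cffrag_test <- function(x, ...) {
  cat(x$method, "\n  statistic =", format(x$statistic, digits = 6),
      " df =", paste(x$df, collapse = ", "),
      " p =", format.pval(x$p.value, digits = 4), "\n")
  invisible(x)
}
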