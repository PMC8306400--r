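#' Kruskal-Wallis rank test
#'
#' H statistic with the standard tie correction and a chi-square reference
#' distribution on k - 1 degrees of freedom. Used to confirm an overall
#' effect of collection time point on a metabolite before the many-one
#' comparisons.
#'
#' @param groups list of numeric vectors, one per group (>= 2 non-empty
#'   groups).
#' @return list with `H`, `p`, `df`. All-identical data gives `H = 0`,
#'   `p = 1`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2 || any(lengths(groups) == 0))
    stop("need >= 2 non-empty groups")
  x <- unlist(groups, use.names = FALSE)
  N <- length(x)
  if (length(unique(x)) == 1) return(list(H = 0, p = 1, df = length(groups) - 1))
  r <- avg_rank(x)
  g <- rep(seq_along(groups), lengths(groups))
  Rj <- tapply(r, g, sum)
  nj <- lengths(groups)
  H <- 12 / (N * (N + 1)) * sum(Rj^2 / nj) - 3 * (N + 1)
  C <- 1 - tie_term(x) / (N^3 - N)
  H <- H / C
  df <- length(groups) - 1
  list(H = H, p = stats::pchisq(H, df, lower.tail = FALSE), df = df)
}

# P(max_k Z_k <= z) for an equicorrelated-by-factor multivariate normal with
# Z_k = sqrt(lambda_k) U + sqrt(1 - lambda_k) e_k. The many-one rank
# statistics against a shared control have exactly this one-factor structure
# with lambda_k = n_k / (n_k + n0), so the maximum distribution reduces to a
# one-dimensional integral evaluated by adaptive quadrature.
pmax_mvn <- function(z, lambda, two_sided = FALSE) {
  s <- sqrt(1 - lambda)
  a <- sqrt(lambda)
  f <- function(u) {
    lg <- rep(0, length(u))
    for (k in seq_along(lambda)) {
      up <- stats::pnorm((z - a[k] * u) / s[k])
      if (two_sided) up <- up - stats::pnorm((-z - a[k] * u) / s[k])
      lg <- lg + log(pmax(up, 0))
    }
    exp(lg) * stats::dnorm(u)
  }
  stats::integrate(f, -Inf, Inf, rel.tol = 1e-10, abs.tol = 1e-12)$value
}

# Tie-corrected rank-sum z statistic of one treatment against the control.
steel_z <- function(control, trt) {
  n0 <- length(control); nj <- length(trt); N <- n0 + nj
  comb <- c(control, trt)
  r <- avg_rank(comb)
  R <- sum(r[(n0 + 1):N])
  E <- nj * (N + 1) / 2
  V <- n0 * nj / 12 * ((N + 1) - tie_term(comb) / (N * (N - 1)))
  if (V <= 0) return(list(R = R, z = 0, degenerate = TRUE))
  list(R = R, z = (R - E) / sqrt(V), degenerate = FALSE)
}

#' Steel's many-one rank test
#'
#' Compares each of several treatment groups against one shared control by
#' Wilcoxon rank sums, controlling the family-wise error over the whole set
#' of comparisons. Each comparison's rank sum is standardized with the
#' tie-corrected variance; the adjusted p-value of treatment j is
#' P(max_k Z_k >= z_j) under the joint multivariate normal null, whose
#' correlation structure (rho_jk = sqrt(lambda_j lambda_k),
#' lambda_j = n_j/(n_j + n0)) is evaluated exactly by one-dimensional
#' quadrature. A permutation mode re-randomizes group labels jointly and
#' serves as the ground-truth reference: it enumerates all assignments
#' exactly for a single small treatment group, otherwise it samples.
#'
#' @param control numeric vector, the shared control group (time point zero).
#' @param treatments list of numeric vectors, one per treatment group.
#' @param side "greater" (treatment exceeds control, the default for
#'   fermentation products), "less", or "two.sided".
#' @param method "mvn" (quadrature on the joint normal null) or
#'   "permutation".
#' @param n_perm permutations sampled when enumeration is infeasible.
#' @param seed RNG seed for sampled permutations.
#' @return data.frame of class `steel_result`: per treatment `group`, `n`,
#'   `rank_sum`, `z`, `p_adjusted`; attributes `side`, `method`, `n_control`.
#' @export
steel_test <- function(control, treatments,
                       side = c("greater", "less", "two.sided"),
                       method = c("mvn", "permutation"),
                       n_perm = 10000, seed = NULL) {
  side <- match.arg(side)
  method <- match.arg(method)
  if (length(treatments) == 0) stop("need at least one treatment group")
  if (length(control) == 0 || any(lengths(treatments) == 0))
    stop("control and every treatment must be non-empty")
  n0 <- length(control)
  nj <- lengths(treatments)
  stats_j <- lapply(treatments, steel_z, control = control)
  z <- vapply(stats_j, `[[`, numeric(1), "z")
  R <- vapply(stats_j, `[[`, numeric(1), "R")
  degen <- vapply(stats_j, `[[`, logical(1), "degenerate")
  zdir <- switch(side, greater = z, less = -z, two.sided = abs(z))

  if (method == "mvn") {
    lambda <- nj / (nj + n0)
    padj <- vapply(seq_along(z), function(j) {
      if (degen[j]) return(1)
      1 - pmax_mvn(zdir[j], lambda, two_sided = (side == "two.sided"))
    }, numeric(1))
  } else {
    padj <- steel_perm_p(control, treatments, zdir, side, n_perm, seed)
    padj[degen] <- 1
  }
  padj <- pmin(pmax(padj, 0), 1)
  out <- data.frame(
    group = if (!is.null(names(treatments))) names(treatments)
            else as.character(seq_along(treatments)),
    n = as.integer(nj), rank_sum = R, z = z, p_adjusted = padj)
  attr(out, "side") <- side
  attr(out, "method") <- method
  attr(out, "n_control") <- n0
  class(out) <- c("steel_result", "data.frame")
  out
}

# Permutation reference distribution of max_k z_k (directional). Exact
# enumeration for one treatment when feasible, otherwise Monte Carlo over
# joint label permutations.
steel_perm_p <- function(control, treatments, zdir_obs, side, n_perm, seed) {
  n0 <- length(control)
  nj <- lengths(treatments)
  pool <- c(control, unlist(treatments, use.names = FALSE))
  N <- length(pool)
  dir_z <- function(zz) switch(side, greater = zz, less = -zz,
                               two.sided = abs(zz))
  if (length(treatments) == 1 && choose(N, n0) <= 50000) {
    idx <- utils::combn(N, n0)
    zs <- apply(idx, 2, function(ci)
      dir_z(steel_z(pool[ci], pool[-ci])$z))
    return(vapply(zdir_obs, function(zo)
      mean(zs >= zo - 1e-12), numeric(1)))
  }
  if (!is.null(seed)) set.seed(seed)
  maxz <- numeric(n_perm)
  bounds <- c(0, cumsum(nj))
  for (b in seq_len(n_perm)) {
    perm <- sample(pool)
    ctrl <- perm[seq_len(n0)]
    rest <- perm[-seq_len(n0)]
    zz <- vapply(seq_along(nj), function(j)
      dir_z(steel_z(ctrl, rest[(bounds[j] + 1):bounds[j + 1]])$z),
      numeric(1))
    maxz[b] <- max(zz)
  }
  vapply(zdir_obs, function(zo)
    (1 + sum(maxz >= zo - 1e-12)) / (n_perm + 1), numeric(1))
}
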