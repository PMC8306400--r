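# Canonical term names of the storage ANOVA and their model labels.
ANOVA_TERMS <- c(
  time = "time", temp = "temp", replicate = "replicate",
  time2 = "I(time^2)", temp2 = "I(temp^2)",
  `time:temp` = "time:temp", `time:replicate` = "time:replicate",
  `temp:replicate` = "temp:replicate")

anova_formula <- function(response, terms) {
  rhs <- if (length(terms) == 0) "1" else
    paste(unname(ANOVA_TERMS[terms]), collapse = " + ")
  stats::as.formula(paste0("`", response, "` ~ ", rhs))
}

# parents of a higher-order term (hierarchy guard)
term_parents <- function(term) {
  switch(term,
    time2 = "time", temp2 = "temp",
    `time:temp` = c("time", "temp"),
    `time:replicate` = c("time", "replicate"),
    `temp:replicate` = c("temp", "replicate"),
    character(0))
}

# Brown-Forsythe test: one-way ANOVA on absolute deviations from group
# medians; robust homoscedasticity check across design cells.
brown_forsythe <- function(values, groups) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2) return(list(F = NA_real_, p = NA_real_))
  med <- tapply(values, groups, stats::median)
  z <- abs(values - med[groups])
  fit <- stats::aov(z ~ groups)
  sm <- summary(fit)[[1]]
  list(F = sm[1, "F value"], p = sm[1, "Pr(>F)"])
}

#' Multifactor ANOVA of a metabolite's concentrations
#'
#' Fits a least-squares linear model of one metabolite on storage time and
#' temperature (continuous), biological replicate (discrete, dummy coded),
#' plus optional square and interaction terms, and reports a partial
#' (drop-one) F test per term. Residual diagnostics are a Shapiro-Wilk
#' normality test and a Brown-Forsythe homoscedasticity test across
#' replicate-by-temperature cells.
#'
#' @param data data.frame with columns `time`, `temp`, `replicate`, and the
#'   response column.
#' @param response name of the response column.
#' @param terms character subset of `c("time", "temp", "replicate", "time2",
#'   "temp2", "time:temp", "time:replicate", "temp:replicate")`.
#' @param alpha significance level used by the elimination rule.
#' @param transform "none", "log", or "johnson_su" applied to the response
#'   before fitting.
#' @return `anova_result`: list with `table` (term, df, F, p), `terms`,
#'   `transform`, `diagnostics` (`normality_p`, `homoscedasticity_p`),
#'   `model` (the `lm` fit), `response`, `alpha`.
#' @export
fit_anova <- function(data, response, terms = names(ANOVA_TERMS),
                      alpha = 0.05,
                      transform = c("none", "log", "johnson_su")) {
  transform <- match.arg(transform)
  stopifnot(all(c("time", "temp", "replicate", response) %in% names(data)))
  bad <- setdiff(terms, names(ANOVA_TERMS))
  if (length(bad) > 0) stop("unknown term(s): ", paste(bad, collapse = ", "))
  d <- data
  d$replicate <- as.factor(d$replicate)
  if (nlevels(d$replicate) < 2) stop("need >= 2 replicates")
  y <- d[[response]]
  tr_params <- NULL
  if (transform == "log") {
    if (any(y <= 0)) stop("log transform needs positive values")
    d[[response]] <- log(y)
  } else if (transform == "johnson_su") {
    js <- johnson_su_transform(y)
    d[[response]] <- js$values
    tr_params <- js$params
  }
  fit <- stats::lm(anova_formula(response, terms), data = d)
  if (any(is.na(stats::coef(fit)))) {
    nac <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; aliased: ", paste(nac, collapse = ", "))
  }
  tab <- if (length(terms) > 0) {
    dr <- stats::drop1(fit, scope = stats::formula(fit), test = "F")
    lbl <- rownames(dr)[-1]
    canon <- names(ANOVA_TERMS)[match(lbl, ANOVA_TERMS)]
    data.frame(term = canon, df = dr$Df[-1], F = dr$`F value`[-1],
               p = dr$`Pr(>F)`[-1], row.names = NULL)
  } else data.frame(term = character(0), df = numeric(0), F = numeric(0),
                    p = numeric(0))
  res <- stats::resid(fit)
  norm_p <- if (length(res) >= 3 && length(res) <= 5000)
    tryCatch(stats::shapiro.test(res)$p.value, error = function(e) NA_real_)
  else NA_real_
  bf <- brown_forsythe(res, interaction(d$replicate, factor(d$temp)))
  out <- list(table = tab, terms = terms, transform = transform,
              transform_params = tr_params,
              diagnostics = list(normality_p = norm_p,
                                 homoscedasticity_p = bf$p),
              model = fit, response = response, alpha = alpha)
  class(out) <- "anova_result"
  out
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("<anova_result '%s' (%s transform)>\n", x$response,
              x$transform))
  print(x$table, digits = 4)
  invisible(x)
}

#' Backward elimination of insignificant ANOVA terms
#'
#' Starting from the full model, repeatedly drops the term with the largest
#' partial-F p-value at or above `alpha` and refits, until every remaining
#' term is significant. With `hierarchy = TRUE` (the default) a main effect
#' is never dropped while any retained square or interaction term contains
#' it. The elimination order is recorded.
#'
#' @inheritParams fit_anova
#' @param hierarchy enforce model hierarchy during elimination.
#' @return `anova_result` of the final model, with an extra `trace`
#'   data.frame (`step`, `dropped`, `p`).
#' @export
backward_eliminate <- function(data, response, terms = names(ANOVA_TERMS),
                               alpha = 0.05,
                               transform = c("none", "log", "johnson_su"),
                               hierarchy = TRUE) {
  transform <- match.arg(transform)
  cur <- terms
  trace <- data.frame(step = integer(0), dropped = character(0),
                      p = numeric(0))
  step <- 0L
  repeat {
    res <- fit_anova(data, response, cur, alpha = alpha,
                     transform = transform)
    if (length(cur) == 0) break
    droppable <- cur
    if (hierarchy) {
      protected <- unique(unlist(lapply(cur, term_parents)))
      droppable <- setdiff(cur, protected)
    }
    cand <- res$table[res$table$term %in% droppable &
                        res$table$p >= alpha, , drop = FALSE]
    if (nrow(cand) == 0) break
    worst <- cand$term[which.max(cand$p)]
    step <- step + 1L
    trace <- rbind(trace, data.frame(step = step, dropped = worst,
                                     p = max(cand$p)))
    cur <- setdiff(cur, worst)
  }
  res$trace <- trace
  res
}

#' Johnson SU normalization transform
#'
#' Fits the four-parameter Johnson SU family
#' `u = gamma + delta * asinh((x - xi) / lambda)` by the quantile-matching
#' method (symmetric quantiles at +/- z and +/- 3z of the standard normal,
#' z = 0.524), falling back to maximum likelihood when the quantile
#' discriminant falls outside the SU region (as happens for near-normal
#' data). The transform is invertible with the stored parameters.
#'
#' @param x numeric vector, >= 8 non-constant observations.
#' @param z quantile spacing parameter of the matching method.
#' @return list with `values` (transformed data), `params`
#'   (`gamma`, `delta`, `xi`, `lambda`), `method` ("quantile" or "mle").
#' @export
johnson_su_transform <- function(x, z = 0.524) {
  x <- x[is.finite(x)]
  if (length(x) < 8) stop("need >= 8 observations")
  if (stats::sd(x) == 0) stop("constant input")
  qs <- stats::quantile(x, stats::pnorm(c(-3, -1, 1, 3) * z), names = FALSE,
                        type = 7)
  m <- qs[4] - qs[3]; n <- qs[2] - qs[1]; p <- qs[3] - qs[2]
  params <- NULL; method <- "quantile"
  if (p > 0 && m * n / p^2 > 1 + 1e-8) {
    mp <- m / p; np <- n / p
    delta <- 2 * z / acosh(0.5 * (mp + np))
    gamma <- delta * asinh((np - mp) / (2 * sqrt(mp * np - 1)))
    lambda <- 2 * p * sqrt(mp * np - 1) /
      ((mp + np - 2) * sqrt(mp + np + 2))
    xi <- (qs[3] + qs[2]) / 2 + p * (np - mp) / (2 * (mp + np - 2))
    if (is.finite(delta) && is.finite(lambda) && lambda > 0 && delta > 0)
      params <- list(gamma = gamma, delta = delta, xi = xi, lambda = lambda)
  }
  if (is.null(params)) {
    method <- "mle"
    nll <- function(par) {
      gamma <- par[1]; delta <- exp(par[2]); xi <- par[3]
      lambda <- exp(par[4])
      s <- (x - xi) / lambda
      u <- gamma + delta * asinh(s)
      -sum(log(delta) - log(lambda) - 0.5 * log1p(s^2) - u^2 / 2 -
             0.5 * log(2 * pi))
    }
    st <- c(0, log(1.5), mean(x), log(stats::sd(x) * 2))
    opt <- stats::optim(st, nll, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-12))
    params <- list(gamma = opt$par[1], delta = exp(opt$par[2]),
                   xi = opt$par[3], lambda = exp(opt$par[4]))
  }
  u <- params$gamma + params$delta * asinh((x - params$xi) / params$lambda)
  list(values = u, params = params, method = method)
}

#' @rdname johnson_su_transform
#' @param u transformed values.
#' @param params parameter list as returned by [johnson_su_transform()].
#' @return `johnson_su_inverse`: the back-transformed values.
#' @export
johnson_su_inverse <- function(u, params) {
  params$xi + params$lambda * sinh((u - params$gamma) / params$delta)
}
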