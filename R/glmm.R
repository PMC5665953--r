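# Gauss-Hermite nodes/weights (physicists' convention:
# integral of exp(-x^2) f(x) dx = sum w_k f(x_k)) by Golub-Welsch.
gauss_hermite <- function(n) {
  stopifnot(n >= 1, n == round(n))
  if (n == 1) return(list(nodes = 0, weights = sqrt(pi)))
  J <- matrix(0, n, n)
  off <- sqrt(seq_len(n - 1) / 2)
  J[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- off
  J[cbind(seq_len(n - 1) + 1, seq_len(n - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord], weights = sqrt(pi) * e$vectors[1, ord]^2)
}

log1pexp <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

#' Build the fixed-effect design for the preference GLMM
#'
#' One row per retained animal x test record; the response is the pair
#' (seconds visiting the conditioned source, total seconds visiting both
#' sources). Categorical terms use treatment coding with `test = "pre"` as
#' reference and the control group (or the first group) as the training
#' reference, so a negative `testpost` coefficient is a post-training
#' preference decline. Column order is deterministic: intercept, test,
#' training contrasts, then their interactions.
#'
#' @param records Retained preference-test records (see
#'   [generate_preferences()], [apply_retention_filter()]).
#' @param design `"test_by_training"` (fixed effects test, training, and
#'   their interaction) or `"test_only"` (single-group experiments).
#' @param ref_group Reference training group; defaults to a group named
#'   `"control"` if present, else the first group in sort order.
#' @return A list with the response (`y`, `size`), fixed-effect matrix `X`,
#'   animal grouping, term names and coding metadata.
#' @export
build_design <- function(records, design = c("test_by_training", "test_only"),
                         ref_group = NULL) {
  design <- match.arg(design)
  if (!is.data.frame(records) || nrow(records) == 0) {
    abort("no records to build a design from")
  }
  needed <- c("animal_id", "group", "test", "seconds_conditioned", "seconds_control")
  missing <- setdiff(needed, names(records))
  if (length(missing)) {
    abort(sprintf("records missing columns: %s", paste(missing, collapse = ", ")))
  }
  if (!all(records$test %in% c("pre", "post"))) {
    abort("test must be 'pre' or 'post'")
  }
  groups <- sort(unique(records$group))
  if (design == "test_by_training" && length(groups) < 2) {
    abort("test_by_training design needs at least two groups")
  }
  ref_group <- ref_group %||% (if ("control" %in% groups) "control" else groups[1])
  if (!ref_group %in% groups) abort(sprintf("reference group '%s' not in data", ref_group))
  df <- data.frame(
    test = factor(records$test, levels = c("pre", "post")),
    training = factor(records$group, levels = c(ref_group, setdiff(groups, ref_group)))
  )
  X <- if (design == "test_by_training") {
    stats::model.matrix(~ test * training, df)
  } else {
    stats::model.matrix(~ test, df)
  }
  animal <- factor(records$animal_id)
  y <- as.numeric(records$seconds_conditioned)
  size <- y + as.numeric(records$seconds_control)
  if (any(size <= 0)) abort("records with zero total visiting time cannot be modeled")
  list(y = y, size = size, X = X, animal = as.integer(animal),
       animal_levels = levels(animal), terms = colnames(X),
       design = design, ref_group = ref_group,
       coding = sprintf(
         "treatment coding; reference levels: test = pre, training = %s", ref_group),
       n_obs = length(y), n_animals = nlevels(animal))
}

# Marginal negative log-likelihood of the binomial random-intercept model,
# integrating the intercept by adaptive Gauss-Hermite quadrature centred on
# the per-animal posterior mode. `cache` carries warm-started modes across
# optimizer evaluations.
agq_nll <- function(par, d, gh, cache, sigma_fixed = NULL) {
  p <- ncol(d$X)
  beta <- par[seq_len(p)]
  sigma <- if (is.null(sigma_fixed)) exp(par[p + 1]) else sigma_fixed
  eta0 <- drop(d$X %*% beta)
  if (sigma < 1e-8) {
    return(-sum(d$y * eta0 - d$size * log1pexp(eta0)))
  }
  ai <- d$animal
  u <- cache$u
  for (it in 1:50) {
    mu <- plogis(eta0 + u[ai])
    g1 <- rowsum(d$y - d$size * mu, ai)[, 1] - u / sigma^2
    info <- rowsum(d$size * mu * (1 - mu), ai)[, 1] + 1 / sigma^2
    step <- g1 / info
    step <- pmin(pmax(step, -5), 5)
    u <- u + step
    if (max(abs(step)) < 1e-9) break
  }
  cache$u <- u
  mu <- plogis(eta0 + u[ai])
  tau <- 1 / sqrt(rowsum(d$size * mu * (1 - mu), ai)[, 1] + 1 / sigma^2)
  U <- outer(u, rep(1, length(gh$nodes))) + sqrt(2) * outer(tau, gh$nodes)
  ETA <- eta0 + U[ai, , drop = FALSE]
  LL <- d$y * ETA - d$size * log1pexp(ETA)
  H <- rowsum(LL, ai) - U^2 / (2 * sigma^2) - log(sigma) - 0.5 * log(2 * pi)
  logw <- log(gh$weights) + gh$nodes^2
  S <- sweep(H, 2, logw, `+`)
  hmax <- apply(S, 1, max)
  logL <- 0.5 * log(2) + log(tau) + hmax + log(rowSums(exp(S - hmax)))
  -sum(logL)
}

#' Fit the binomial random-intercept preference model
#'
#' Maximum marginal likelihood for the paper-style analysis model: binomial
#' response (seconds on the conditioned source out of total visiting
#' seconds, treated as conditionally independent per-second Bernoulli
#' choices), logit link, fixed effects for test, training group and their
#' interaction, and a Normal random intercept per animal. The random
#' intercept is integrated out by adaptive Gauss-Hermite quadrature centred
#' per animal on the posterior mode (`quadrature_nodes = 1` is the Laplace
#' approximation); standard errors come from the inverse observed
#' information at the optimum.
#'
#' Non-retained records (total visiting time below 10 s) are dropped before
#' modeling by default, mirroring the assay's rejection rule.
#'
#' @param records Preference-test records.
#' @param design,ref_group Passed to [build_design()].
#' @param quadrature_nodes Number of quadrature nodes (default 9; 1 =
#'   Laplace).
#' @param sigma_u `NULL` to estimate the random-intercept SD; a fixed
#'   non-negative value otherwise (`sigma_u = 0` reduces the fit to
#'   ordinary binomial logistic regression).
#' @param filter_retained Apply [apply_retention_filter()] first (default
#'   `TRUE`).
#' @return An object of class `pe_glmm` with elements `beta`, `se`, `vcov`,
#'   `sigma_u`, `loglik`, `converged`, `n_animals`, `n_obs`,
#'   `quadrature_nodes`, `coding` and `optim` diagnostics. Methods:
#'   [tidy()], [glance()], [wald_tests()], `print()`.
#' @examples
#' gw <- tibble::tibble(group = c("control", "blocking"),
#'                      w_cs_cr = c(0.51, 0.024))
#' recs <- generate_preferences(gw, behavior_params(n_per_group = 15,
#'                                                  theta1 = 2), seed = 3)
#' fit <- fit_preference_glmm(recs)
#' tidy(fit)
#' @export
fit_preference_glmm <- function(records,
                                design = c("test_by_training", "test_only"),
                                ref_group = NULL,
                                quadrature_nodes = 9,
                                sigma_u = NULL,
                                filter_retained = TRUE) {
  design <- match.arg(design)
  stopifnot(quadrature_nodes >= 1)
  if (filter_retained) records <- apply_retention_filter(records)
  if (nrow(records) == 0) abort("no records remain after the retention filter")
  d <- build_design(records, design, ref_group)
  gh <- gauss_hermite(quadrature_nodes)
  p <- ncol(d$X)

  start_beta <- tryCatch(
    glm.fit(d$X, cbind(d$y, d$size - d$y), family = binomial())$coefficients,
    error = function(e) rep(0, p))
  start_beta[!is.finite(start_beta)] <- 0
  cache <- new.env(parent = emptyenv())
  cache$u <- rep(0, d$n_animals)

  estimate_sigma <- is.null(sigma_u)
  nll <- if (estimate_sigma) {
    function(par) agq_nll(par, d, gh, cache)
  } else {
    function(par) agq_nll(par, d, gh, cache, sigma_fixed = sigma_u)
  }
  par0 <- if (estimate_sigma) c(start_beta, log(0.5)) else start_beta
  opt <- optim(par0, nll, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-10))
  hess <- tryCatch(optimHess(opt$par, nll), error = function(e) NULL)
  vc <- if (!is.null(hess)) tryCatch(solve(hess), error = function(e) NULL)
  ok_vc <- !is.null(vc) && all(is.finite(diag(vc)[seq_len(p)])) &&
    all(diag(vc)[seq_len(p)] > 0)
  converged <- opt$convergence == 0 && ok_vc

  beta <- setNames(opt$par[seq_len(p)], d$terms)
  se <- if (ok_vc) setNames(sqrt(diag(vc)[seq_len(p)]), d$terms) else
    setNames(rep(NA_real_, p), d$terms)
  sigma_hat <- if (estimate_sigma) unname(exp(opt$par[p + 1])) else sigma_u
  loglik <- -opt$value + sum(lchoose(d$size, d$y))

  structure(
    list(beta = beta, se = se,
         vcov = if (ok_vc) vc[seq_len(p), seq_len(p), drop = FALSE] else NULL,
         sigma_u = sigma_hat, sigma_u_fixed = !estimate_sigma,
         loglik = loglik, converged = converged,
         n_animals = d$n_animals, n_obs = d$n_obs,
         quadrature_nodes = quadrature_nodes,
         design = d$design, ref_group = d$ref_group, coding = d$coding,
         optim = list(convergence = opt$convergence, counts = opt$counts,
                      message = opt$message)),
    class = "pe_glmm"
  )
}

#' @export
print.pe_glmm <- function(x, ...) {
  cat(sprintf("<pe_glmm> binomial logit, random intercept per animal (AGQ, %d nodes)\n",
              x$quadrature_nodes))
  cat(sprintf("  %s\n", x$coding))
  cat(sprintf("  n_obs: %d   n_animals: %d   sigma_u%s: %.4f   logLik: %.2f   converged: %s\n",
              x$n_obs, x$n_animals, if (x$sigma_u_fixed) " (fixed)" else "",
              x$sigma_u, x$loglik, x$converged))
  if (x$converged) print(as.data.frame(wald_tests(x)), digits = 4)
  invisible(x)
}

#' Wald z tests for a fitted preference GLMM
#'
#' `z = beta / se`, two-sided `p = 2 * (1 - pnorm(|z|))`, significance at
#' 0.05.
#'
#' @param fit A converged `pe_glmm`.
#' @return Tibble with columns `term`, `estimate`, `std.error`,
#'   `statistic`, `p.value`, `significant`.
#' @export
wald_tests <- function(fit) {
  stopifnot(inherits(fit, "pe_glmm"))
  if (!fit$converged) abort("fit did not converge; Wald tests unavailable")
  z <- fit$beta / fit$se
  tibble(term = names(fit$beta),
         estimate = unname(fit$beta),
         std.error = unname(fit$se),
         statistic = unname(z),
         p.value = unname(2 * pnorm(-abs(z))),
         significant = unname(2 * pnorm(-abs(z)) < 0.05))
}

#' @exportS3Method generics::tidy
tidy.pe_glmm <- function(x, ...) wald_tests(x)

#' @exportS3Method generics::glance
glance.pe_glmm <- function(x, ...) {
  tibble(sigma_u = x$sigma_u, logLik = x$loglik, converged = x$converged,
         n_animals = x$n_animals, n_obs = x$n_obs,
         quadrature_nodes = x$quadrature_nodes)
}
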