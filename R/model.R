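# Hierarchical Bayesian regression of community temperature index at two
# timepoints: fixed effects with time interactions, iid subplot random
# effects, and a Matern spatial Gaussian field over plot centroids. With a
# flat prior on the coefficients the conditional posterior of beta is
# Gaussian in closed form; variance/spatial hyperparameters are estimated by
# maximizing the (restricted) marginal likelihood (empirical Bayes, default)
# or sampled by random-walk Metropolis (mcmc option).

#' Matern covariance matrix from pairwise distances
#'
#' sigma_u^2 * (2^(1-nu)/Gamma(nu)) * (sqrt(2 nu) d / rho)^nu *
#' K_nu(sqrt(2 nu) d / rho), with value sigma_u^2 at d = 0. nu = 0.5 gives
#' the exponential kernel sigma_u^2 * exp(-d/rho).
#'
#' @param distances nonnegative pairwise distance matrix (km).
#' @param sigma_u marginal SD.
#' @param rho range-like length scale, km (> 0).
#' @param nu smoothness (> 0).
#' @return covariance matrix of the same dimension.
#' @export
matern_cov <- function(distances, sigma_u, rho, nu = 1) {
  d <- as.matrix(distances)
  if (any(d < 0)) stop("distances must be nonnegative", call. = FALSE)
  if (rho <= 0 || nu <= 0) stop("rho and nu must be positive", call. = FALSE)
  x <- sqrt(2 * nu) * d / rho
  out <- x
  pos <- x > 0
  out[pos] <- sigma_u^2 * (2^(1 - nu) / gamma(nu)) * x[pos]^nu *
    besselK(x[pos], nu)
  out[!pos] <- sigma_u^2
  out
}

#' Model specification for the CTI regression
#'
#' @param matern_nu Matern smoothness of the plot-level spatial field.
#' @param inference_method "empirical_bayes" (hyperparameters at the marginal
#'   likelihood maximum; coefficient credible intervals from the conditional
#'   Gaussian posterior, hyperparameter uncertainty not propagated) or "mcmc"
#'   (random-walk Metropolis over log hyperparameters under log-uniform
#'   priors, coefficients sampled from their conditional posterior).
#' @param fixed named list fixing hyperparameters instead of estimating them;
#'   names among sigma, d, sigma_u, rho (e.g. `list(sigma_u = 0, d = 0)`
#'   collapses the model to ordinary least squares).
#' @param hyper_uncertainty "laplace" (default) integrates the coefficient
#'   posterior over hyperparameter uncertainty by importance-weighted mixing
#'   of conditional posteriors at draws from a Laplace (Gaussian)
#'   approximation to the hyperparameter posterior on the log scale; "none"
#'   conditions on the marginal-likelihood mode (narrower intervals).
#' @param hyper_draws number of hyperparameter draws for the laplace mode.
#' @param jitter relative diagonal jitter added to the spatial covariance.
#' @param maxit optimizer iteration cap.
#' @param reltol optimizer relative tolerance.
#' @param mcmc_iter,mcmc_burnin,mcmc_proposal_sd MCMC controls.
#' @param seed seed for the mcmc option.
#' @return list of class `model_spec`.
#' @export
model_spec <- function(matern_nu = 1,
                       inference_method = c("empirical_bayes", "mcmc"),
                       fixed = list(),
                       hyper_uncertainty = c("laplace", "none"),
                       hyper_draws = 64,
                       jitter = 1e-8,
                       maxit = 500,
                       reltol = 1e-10,
                       mcmc_iter = 2000,
                       mcmc_burnin = 500,
                       mcmc_proposal_sd = 0.15,
                       seed = 1L) {
  inference_method <- match.arg(inference_method)
  hyper_uncertainty <- match.arg(hyper_uncertainty)
  if (matern_nu <= 0) stop("matern_nu must be positive", call. = FALSE)
  bad <- setdiff(names(fixed), c("sigma", "d", "sigma_u", "rho"))
  if (length(bad) > 0L) {
    stop("unknown fixed hyperparameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (any(unlist(fixed) < 0)) stop("fixed variances must be >= 0", call. = FALSE)
  structure(list(matern_nu = matern_nu, inference_method = inference_method,
                 fixed = fixed, hyper_uncertainty = hyper_uncertainty,
                 hyper_draws = hyper_draws, jitter = jitter, maxit = maxit,
                 reltol = reltol, mcmc_iter = mcmc_iter,
                 mcmc_burnin = mcmc_burnin,
                 mcmc_proposal_sd = mcmc_proposal_sd, seed = seed),
            class = "model_spec")
}

#' Build the long-format design table for one response variant
#'
#' Each subplot contributes a T1 row (k = 0) and a T2 row (k = 1) sharing all
#' predictors; interaction columns i2...i11 equal k times x2...x11 and are
#' therefore exactly zero on T1 rows. Counterfactual variants replace only
#' the T2 response; the predictors and T1 responses are unchanged. Rows whose
#' CTI is undefined are dropped (the paired row is retained), with counts in
#' attribute "dropped".
#'
#' @param cti long CTI table from [cti_table()].
#' @param covariates standardized covariate table from [build_covariates()].
#' @param variant response variant: "all", "mortality", "growth",
#'   "recruitment" or "sapling".
#' @return data.frame: Y, plot_id, subplot_id, k, x2...x11, i2...i11, with
#'   attributes "dropped" and "coding".
#' @export
build_design <- function(cti, covariates, variant = "all") {
  if (!isTRUE(attr(covariates, "standardized"))) {
    stop("covariates must be standardized (build_covariates(scale = TRUE))",
         call. = FALSE)
  }
  sub <- cti[cti$variant == variant, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no CTI rows for variant '", variant, "'", call. = FALSE)
  key_cov <- paste(covariates$plot_id, covariates$subplot_id)
  sub$k <- ifelse(sub$timepoint == "t2", 1L, 0L)
  idx <- match(paste(sub$plot_id, sub$subplot_id), key_cov)
  if (any(is.na(idx))) {
    stop("CTI rows without matching covariates", call. = FALSE)
  }
  xcols <- paste0("x", 2:11)
  out <- data.frame(Y = sub$cti_degC, plot_id = sub$plot_id,
                    subplot_id = sub$subplot_id, k = sub$k)
  out[xcols] <- covariates[idx, xcols]
  out[paste0("i", 2:11)] <- out$k * out[xcols]
  drop_na <- is.na(out$Y) | !stats::complete.cases(out[xcols])
  dropped <- sum(drop_na)
  out <- out[!drop_na, , drop = FALSE]
  out <- out[order(out$plot_id, out$subplot_id, out$k), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  attr(out, "coding") <- attr(covariates, "coding")
  attr(out, "variant") <- variant
  out
}

# ---- internal likelihood machinery -----------------------------------------

# Restricted marginal log-likelihood and GLS quantities for
# V = sigma^2 I + d^2 (subplot blocks) + Z_plot Matern(sigma_u, rho) Z_plot'.
# Exploits the nesting: D = sigma^2 I + d^2 blockdiag(J_m) has analytic
# inverse, and Z'D^{-1}Z is diagonal, so each evaluation costs O(P^3) in the
# number of plots.
marginal_eval <- function(theta, prep) {
  if (!all(is.finite(theta))) return(NULL)
  sigma2 <- theta["sigma"]^2
  d2 <- theta["d"]^2
  su <- theta["sigma_u"]
  rho <- theta["rho"]
  if (su > 0 && rho <= 0) return(NULL)  # underflowed range draw
  B <- prep$B
  n <- nrow(B)
  p <- ncol(B) - 1L

  m_row <- prep$m_row                      # subplot block size per row
  denom_row <- sigma2 + m_row * d2
  # D^{-1} B per subplot block: (B - d2/denom * 1 * colsum) / sigma2
  block_sums <- rowsum(B, prep$sub_key, reorder = FALSE)
  DB <- (B - (d2 / denom_row) * block_sums[prep$sub_idx, , drop = FALSE]) / sigma2
  m_blk <- prep$m_blk
  logdetD <- sum((m_blk - 1) * log(sigma2) + log(sigma2 + m_blk * d2))

  if (su > 0) {
    sigma_sp <- matern_cov(prep$plot_dist, su, rho, prep$nu)
    diag(sigma_sp) <- diag(sigma_sp) + prep$jitter * su^2
    cS <- tryCatch(chol(sigma_sp), error = function(e) NULL)
    if (is.null(cS)) return(NULL)
    w_row <- 1 / denom_row                 # D^{-1} Z entries
    ZB <- rowsum(w_row * B, prep$plot_key, reorder = FALSE)   # Z'D^{-1}B
    a <- as.numeric(rowsum(m_blk / (sigma2 + m_blk * d2),
                           prep$plot_of_block, reorder = FALSE))
    K <- chol2inv(cS)
    diag(K) <- diag(K) + a
    cK <- tryCatch(chol(K), error = function(e) NULL)
    if (is.null(cK)) return(NULL)
    S <- backsolve(cK, forwardsolve(t(cK), ZB))               # K^{-1} Z'D^{-1}B
    ViB <- DB - w_row * S[prep$plot_idx, , drop = FALSE]
    logdetV <- logdetD + 2 * sum(log(diag(cS))) + 2 * sum(log(diag(cK)))
  } else {
    ViB <- DB
    logdetV <- logdetD
  }

  G <- crossprod(B, ViB)
  XtViX <- G[seq_len(p), seq_len(p), drop = FALSE]
  XtViy <- G[seq_len(p), p + 1L]
  ytViy <- G[p + 1L, p + 1L]
  cX <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(cX)) return(NULL)
  beta <- backsolve(cX, forwardsolve(t(cX), XtViy))
  quad <- ytViy - sum(beta * XtViy)
  ll <- -0.5 * (logdetV + 2 * sum(log(diag(cX))) + quad) -
    0.5 * (n - p) * log(2 * pi)
  list(ll = ll, beta = beta, cov_beta = chol2inv(cX), chol_XtViX = cX)
}

prepare_model <- function(design, coords, nu, jitter) {
  # canonical row order: results are exactly invariant to input permutation
  design <- design[order(design$plot_id, design$subplot_id, design$k), ,
                   drop = FALSE]
  xcols <- c(paste0("x", 2:11))
  icols <- c(paste0("i", 2:11))
  X <- cbind(1, design$k, as.matrix(design[xcols]), as.matrix(design[icols]))
  colnames(X) <- c("beta0", "beta1", paste0("beta", 2:11), paste0("beta", 12:21))
  # drop exactly-collinear columns (e.g. a centered-constant covariate)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop_cols <- setdiff(seq_len(ncol(X)), qrX$pivot[seq_len(qrX$rank)])
    stop("singular design: collinear column(s) ",
         paste(colnames(X)[drop_cols], collapse = ", "), call. = FALSE)
  }
  plots <- unique(design$plot_id)
  if (length(plots) < 2L) stop("at least 2 plots are required", call. = FALSE)
  cidx <- match(plots, coords$plot_id)
  if (any(is.na(cidx))) stop("missing plot coordinates", call. = FALSE)
  plot_dist <- as.matrix(stats::dist(cbind(coords$x_km[cidx], coords$y_km[cidx])))

  sub_key <- factor(paste(design$plot_id, design$subplot_id),
                    levels = unique(paste(design$plot_id, design$subplot_id)))
  plot_key <- factor(design$plot_id, levels = plots)
  m_blk <- as.numeric(table(sub_key))
  plot_of_block <- factor(design$plot_id[!duplicated(sub_key)], levels = plots)

  list(B = cbind(X, Y = design$Y), xnames = colnames(X),
       sub_key = sub_key, sub_idx = as.integer(sub_key),
       plot_key = plot_key, plot_idx = as.integer(plot_key),
       m_row = m_blk[as.integer(sub_key)], m_blk = m_blk,
       plot_of_block = plot_of_block,
       plot_dist = plot_dist, nu = nu, jitter = jitter,
       n = nrow(X), p = ncol(X))
}

theta_from_free <- function(free, free_names, fixed) {
  th <- c(sigma = NA_real_, d = NA_real_, sigma_u = NA_real_, rho = NA_real_)
  th[free_names] <- exp(free)
  for (nm in names(fixed)) th[nm] <- fixed[[nm]]
  th
}

# ---- fitting ---------------------------------------------------------------

#' Fit the hierarchical CTI regression
#'
#' Estimates beta0...beta21 (intercept, time effect, ten baseline effects and
#' their ten time interactions) with a subplot iid random effect (SD `d`), a
#' plot-level Matern spatial random field (SD `sigma_u`, range `rho`) and
#' residual SD `sigma`. Under the flat coefficient prior the coefficient
#' posterior given hyperparameters is Gaussian; hyperparameters maximize the
#' restricted marginal likelihood (default) or are sampled (mcmc).
#'
#' @param design design table from [build_design()] (or
#'   [simulate_from_model()]).
#' @param coords data.frame plot_id, x_km, y_km (one row per plot).
#' @param spec a [model_spec()].
#' @return object of class `cti_fit`: list with `summary` (term, mean, sd,
#'   lower, upper for each coefficient and hyperparameter), `beta`,
#'   `cov_beta`, `hyper`, `logLik`, `coding`, `variant`, `n`, `dropped`,
#'   `spec`.
#' @export
fit_cti_model <- function(design, coords, spec = model_spec()) {
  prep <- prepare_model(design, coords, spec$matern_nu, spec$jitter)
  fixed <- spec$fixed
  free_names <- setdiff(c("sigma", "d", "sigma_u", "rho"), names(fixed))
  # sigma must stay positive; a fixed zero residual variance is degenerate
  if ("sigma" %in% names(fixed) && fixed$sigma <= 0) {
    stop("residual SD sigma must be positive", call. = FALSE)
  }
  if (("sigma_u" %in% names(fixed)) && fixed$sigma_u == 0) {
    fixed$rho <- fixed$rho %||% 1
    free_names <- setdiff(free_names, "rho")
  }
  ols_sd <- {
    X <- prep$B[, seq_len(prep$p), drop = FALSE]
    y <- prep$B[, prep$p + 1L]
    r <- stats::lm.fit(X, y)$residuals
    max(stats::sd(r), 1e-3)
  }
  start <- log(c(sigma = 0.8 * ols_sd, d = 0.4 * ols_sd,
                 sigma_u = 0.4 * ols_sd,
                 rho = max(stats::median(prep$plot_dist), 1e-3)))
  start <- start[free_names]

  objective <- function(free) {
    th <- theta_from_free(free, free_names, fixed)
    if (th["sigma"] <= 1e-8) return(1e10)
    ev <- marginal_eval(th, prep)
    if (is.null(ev) || !is.finite(ev$ll)) return(1e10)
    -ev$ll
  }

  if (length(free_names) > 0L) {
    opt <- stats::optim(start, objective,
                        method = if (length(start) == 1L) "Brent" else "Nelder-Mead",
                        lower = if (length(start) == 1L) start - 10 else -Inf,
                        upper = if (length(start) == 1L) start + 10 else Inf,
                        control = list(maxit = spec$maxit, reltol = spec$reltol))
    theta <- theta_from_free(opt$par, free_names, fixed)
  } else {
    theta <- theta_from_free(numeric(0), character(0), fixed)
  }
  ev <- marginal_eval(theta, prep)
  if (is.null(ev)) stop("covariance not positive definite at the optimum",
                        call. = FALSE)

  if (spec$inference_method == "mcmc" && length(free_names) > 0L) {
    return(fit_mcmc(prep, spec, fixed, free_names,
                    log(theta[free_names]), design))
  }

  lap <- NULL
  if (spec$hyper_uncertainty == "laplace" && length(free_names) > 0L) {
    lap <- laplace_mixture(prep, theta, free_names, fixed, spec)
  }
  if (!is.null(lap)) {
    beta <- lap$beta
    cov_beta <- lap$cov_beta
    hyper <- lap$hyper_summary
  } else {
    beta <- ev$beta
    cov_beta <- ev$cov_beta
    hyper <- data.frame(term = c("sigma", "d", "sigma_u", "rho"),
                        mean = as.numeric(theta[c("sigma", "d", "sigma_u", "rho")]),
                        sd = NA_real_, lower = NA_real_, upper = NA_real_)
  }
  names(beta) <- prep$xnames
  se <- sqrt(diag(cov_beta))
  summ <- data.frame(term = prep$xnames, mean = as.numeric(beta), sd = se,
                     lower = as.numeric(beta) + stats::qnorm(0.025) * se,
                     upper = as.numeric(beta) + stats::qnorm(0.975) * se)
  structure(list(summary = rbind(summ, hyper), beta = beta,
                 cov_beta = cov_beta, hyper = theta, logLik = ev$ll,
                 coding = attr(design, "coding") %||% "dummy",
                 variant = attr(design, "variant") %||% "all",
                 n = prep$n, dropped = attr(design, "dropped") %||% 0L,
                 spec = spec),
            class = "cti_fit")
}

# Integrate the coefficient posterior over hyperparameter uncertainty:
# Gaussian (Laplace) approximation to the log-hyperparameter posterior at the
# marginal-likelihood mode, importance-reweighted draws, and moment-matched
# mixing of the conditional Gaussian coefficient posteriors. Returns NULL
# (callers fall back to conditioning on the mode) when the curvature is not
# positive definite or the importance weights degenerate.
laplace_mixture <- function(prep, theta, free_names, fixed, spec) {
  free_hat <- log(theta[free_names])
  nll <- function(fr) {
    th <- theta_from_free(fr, free_names, fixed)
    if (th["sigma"] <= 1e-8) return(1e10)
    ev <- marginal_eval(th, prep)
    if (is.null(ev) || !is.finite(ev$ll)) return(1e10) else -ev$ll
  }
  H <- tryCatch(stats::optimHess(free_hat, nll), error = function(e) NULL)
  if (is.null(H)) return(NULL)
  Sth <- tryCatch(solve((H + t(H)) / 2), error = function(e) NULL)
  if (is.null(Sth)) return(NULL)
  L <- tryCatch(chol((Sth + t(Sth)) / 2), error = function(e) NULL)
  if (is.null(L)) return(NULL)

  nfree <- length(free_hat)
  S <- spec$hyper_draws
  set.seed(spec$seed)
  Z <- matrix(stats::rnorm(S * nfree), S, nfree)
  draws <- sweep(Z %*% L, 2, free_hat, "+")
  logw <- rep(-Inf, S)
  evs <- vector("list", S)
  ths <- matrix(NA_real_, S, 4, dimnames = list(NULL, c("sigma", "d", "sigma_u", "rho")))
  for (s in seq_len(S)) {
    th_s <- theta_from_free(draws[s, ], free_names, fixed)
    if (th_s["sigma"] <= 1e-8) next
    ev_s <- marginal_eval(th_s, prep)
    if (is.null(ev_s) || !is.finite(ev_s$ll)) next
    evs[[s]] <- ev_s
    ths[s, ] <- th_s
    # proposal density in z-space is N(0, I); constants cancel on
    # self-normalization
    logw[s] <- ev_s$ll + 0.5 * sum(Z[s, ]^2)
  }
  ok <- is.finite(logw)
  if (sum(ok) < 5L) return(NULL)
  w <- exp(logw[ok] - max(logw[ok]))
  w <- w / sum(w)
  if (1 / sum(w^2) < 5) return(NULL)  # effective sample size guard

  p <- prep$p
  m1 <- numeric(p)
  M2 <- matrix(0, p, p)
  kept <- which(ok)
  for (j in seq_along(kept)) {
    ev_s <- evs[[kept[j]]]
    m1 <- m1 + w[j] * ev_s$beta
    M2 <- M2 + w[j] * (ev_s$cov_beta + tcrossprod(ev_s$beta))
  }
  covb <- (M2 + t(M2)) / 2 - tcrossprod(m1)

  wq <- function(v, probs) {
    o <- order(v)
    cw <- cumsum(w[o])
    vapply(probs, function(q) v[o][which(cw >= q)[1]], numeric(1))
  }
  hyper_summary <- do.call(rbind, lapply(c("sigma", "d", "sigma_u", "rho"),
                                         function(nm) {
    if (nm %in% free_names) {
      v <- ths[kept, nm]
      qs <- wq(v, c(0.025, 0.975))
      data.frame(term = nm, mean = sum(w * v),
                 sd = sqrt(max(sum(w * v^2) - sum(w * v)^2, 0)),
                 lower = qs[1], upper = qs[2])
    } else {
      data.frame(term = nm, mean = theta[[nm]], sd = 0,
                 lower = theta[[nm]], upper = theta[[nm]])
    }
  }))
  list(beta = m1, cov_beta = covb, hyper_summary = hyper_summary)
}

fit_mcmc <- function(prep, spec, fixed, free_names, start, design) {
  set.seed(spec$seed)
  n_free <- length(start)
  cur <- start
  th <- theta_from_free(cur, free_names, fixed)
  cur_ev <- marginal_eval(th, prep)
  cur_ll <- cur_ev$ll
  keep <- spec$mcmc_iter - spec$mcmc_burnin
  beta_draws <- matrix(NA_real_, keep, prep$p)
  hyper_draws <- matrix(NA_real_, keep, 4,
                        dimnames = list(NULL, c("sigma", "d", "sigma_u", "rho")))
  accept <- 0L
  for (it in seq_len(spec$mcmc_iter)) {
    prop <- cur + stats::rnorm(n_free, 0, spec$mcmc_proposal_sd)
    th_p <- theta_from_free(prop, free_names, fixed)
    ev_p <- if (th_p["sigma"] > 1e-8) marginal_eval(th_p, prep) else NULL
    if (!is.null(ev_p) && is.finite(ev_p$ll) &&
        log(stats::runif(1)) < ev_p$ll - cur_ll) {
      cur <- prop; cur_ev <- ev_p; cur_ll <- ev_p$ll; accept <- accept + 1L
    }
    if (it > spec$mcmc_burnin) {
      j <- it - spec$mcmc_burnin
      L <- chol(cur_ev$cov_beta)
      beta_draws[j, ] <- cur_ev$beta + drop(t(L) %*% stats::rnorm(prep$p))
      hyper_draws[j, ] <- theta_from_free(cur, free_names, fixed)
    }
  }
  qs <- function(m) t(apply(m, 2, function(v) {
    c(mean = mean(v), sd = stats::sd(v),
      lower = stats::quantile(v, 0.025, names = FALSE),
      upper = stats::quantile(v, 0.975, names = FALSE))
  }))
  bq <- qs(beta_draws)
  hq <- qs(hyper_draws)
  summ <- rbind(
    data.frame(term = prep$xnames, mean = bq[, "mean"], sd = bq[, "sd"],
               lower = bq[, "lower"], upper = bq[, "upper"]),
    data.frame(term = rownames(hq), mean = hq[, "mean"], sd = hq[, "sd"],
               lower = hq[, "lower"], upper = hq[, "upper"])
  )
  rownames(summ) <- NULL
  beta_mean <- colMeans(beta_draws)
  names(beta_mean) <- prep$xnames
  structure(list(summary = summ, beta = beta_mean,
                 cov_beta = stats::cov(beta_draws),
                 hyper = colMeans(hyper_draws), logLik = cur_ll,
                 coding = attr(design, "coding") %||% "dummy",
                 variant = attr(design, "variant") %||% "all",
                 n = prep$n, dropped = attr(design, "dropped") %||% 0L,
                 spec = spec, acceptance_rate = accept / spec$mcmc_iter),
            class = "cti_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cti_fit <- function(x, ...) {
  cat("Hierarchical CTI regression (", x$spec$inference_method, "), variant '",
      x$variant, "', ", x$n, " rows\n", sep = "")
  b <- x$summary[x$summary$term %in% c("beta0", "beta1"), ]
  for (i in seq_len(nrow(b))) {
    cat(sprintf("  %-6s %8.4f  [%8.4f, %8.4f]\n", b$term[i], b$mean[i],
                b$lower[i], b$upper[i]))
  }
  cat(sprintf("  sigma %.4f  d %.4f  sigma_u %.4f  rho %.2f km\n",
              x$hyper["sigma"], x$hyper["d"], x$hyper["sigma_u"],
              x$hyper["rho"]))
  invisible(x)
}

#' Simulate a design and response from the hierarchical model itself
#'
#' Draws plot coordinates uniformly over a square domain, standard-normal
#' continuous predictors at the appropriate level (x2-x7 at plot level,
#' x8-x11 at subplot level), and the response Y = X beta + u + v + eps with a
#' Matern plot field u, iid subplot effects v and residual noise. Used for
#' parameter-recovery and calibration checks.
#'
#' @param n_plots,n_subplots numbers of plots and subplots per plot.
#' @param beta named or positional numeric vector of length 22
#'   (beta0...beta21).
#' @param sigma_u,rho,nu spatial field parameters.
#' @param d,sigma subplot and residual SDs.
#' @param domain_km square domain side, km.
#' @param seed integer seed.
#' @return list: design (as from [build_design()]), coords, beta, and the
#'   latent u and v.
#' @export
simulate_from_model <- function(n_plots = 200, n_subplots = 4,
                                beta = c(8, 0.05, rep(0, 20)),
                                sigma_u = 0.3, rho = 30, nu = 1,
                                d = 0.2, sigma = 0.3,
                                domain_km = 100, seed = 1L) {
  stopifnot(length(beta) == 22L)
  set.seed(seed)
  coords <- data.frame(plot_id = seq_len(n_plots),
                       x_km = stats::runif(n_plots, 0, domain_km),
                       y_km = stats::runif(n_plots, 0, domain_km))
  nsub <- n_plots * n_subplots
  plot_of_sub <- rep(seq_len(n_plots), each = n_subplots)
  xplot <- matrix(stats::rnorm(n_plots * 6), n_plots, 6)       # x2..x7
  xsub <- matrix(stats::rnorm(nsub * 4), nsub, 4)              # x8..x11
  X10 <- cbind(xplot[plot_of_sub, , drop = FALSE], xsub)
  colnames(X10) <- paste0("x", 2:11)

  if (sigma_u > 0) {
    dmat <- as.matrix(stats::dist(cbind(coords$x_km, coords$y_km)))
    S <- matern_cov(dmat, sigma_u, rho, nu)
    diag(S) <- diag(S) + 1e-8 * sigma_u^2
    u <- drop(t(chol(S)) %*% stats::rnorm(n_plots))
  } else {
    u <- rep(0, n_plots)
  }
  v <- stats::rnorm(nsub, 0, d)

  design <- data.frame(
    plot_id = rep(plot_of_sub, each = 2L),
    subplot_id = rep(rep(seq_len(n_subplots), times = n_plots), each = 2L),
    k = rep(c(0L, 1L), times = nsub)
  )
  design[paste0("x", 2:11)] <- X10[rep(seq_len(nsub), each = 2L), ]
  design[paste0("i", 2:11)] <- design$k * design[paste0("x", 2:11)]
  Xmat <- cbind(1, design$k, as.matrix(design[paste0("x", 2:11)]),
                as.matrix(design[paste0("i", 2:11)]))
  sub_row <- rep(seq_len(nsub), each = 2L)
  design$Y <- drop(Xmat %*% beta) + u[design$plot_id] + v[sub_row] +
    stats::rnorm(nrow(design), 0, sigma)
  design <- design[, c("Y", setdiff(names(design), "Y"))]
  attr(design, "coding") <- "weighted_effect"
  attr(design, "variant") <- "all"
  attr(design, "dropped") <- 0L
  list(design = design, coords = coords, beta = beta, u = u, v = v)
}

#' Population mean thermophilization from a fitted model
#'
#' Under weighted effect coding of the binary damage predictors (and
#' mean-centered continuous predictors) the time coefficient beta1 is the
#' population-mean change in community temperature index over the census
#' interval; dividing by the interval length gives the annual rate.
#'
#' @param fit a [fit_cti_model()] result with coding "weighted_effect".
#' @param interval_years census interval length, years.
#' @return list: estimate, lower, upper (degC per interval), rate_per_year
#'   and its interval (degC/y).
#' @export
mean_thermophilization <- function(fit, interval_years = 10) {
  if (!inherits(fit, "cti_fit")) stop("expected a cti_fit", call. = FALSE)
  if (!identical(fit$coding, "weighted_effect")) {
    stop("population mean thermophilization requires a weighted-effect-coded ",
         "fit; dummy coding estimates the undamaged-subplot mean instead",
         call. = FALSE)
  }
  b1 <- fit$summary[fit$summary$term == "beta1", ]
  list(estimate = b1$mean, lower = b1$lower, upper = b1$upper,
       rate_per_year = b1$mean / interval_years,
       rate_lower = b1$lower / interval_years,
       rate_upper = b1$upper / interval_years,
       interval_years = interval_years)
}

#' Combine posterior summaries across response variants
#'
#' @param fits named list of [fit_cti_model()] results (names are variant
#'   labels).
#' @return data.frame: variant, term, mean, sd, lower, upper.
#' @export
effect_table <- function(fits) {
  if (length(fits) == 0L) stop("at least one fitted variant is required",
                               call. = FALSE)
  if (is.null(names(fits)) || any(names(fits) == "")) {
    names(fits) <- vapply(fits, function(f) f$variant, character(1))
  }
  out <- do.call(rbind, lapply(names(fits), function(v) {
    cbind(variant = v, fits[[v]]$summary)
  }))
  rownames(out) <- NULL
  out
}
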