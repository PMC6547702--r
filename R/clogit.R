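#' Solver settings for the conditional-logistic fits
#'
#' @param tol convergence tolerance on the maximum coefficient change per
#'   iteration (log rate-ratio scale).
#' @param max_iter iteration cap (Newton iterations, or coordinate-descent
#'   sweeps per penalty value).
#' @param n_lambda number of penalties on the geometric path.
#' @param lambda_min_ratio smallest path penalty as a fraction of
#'   `lambda_max`.
#' @param cv_folds folds for cross-validated penalty choice.
#' @param z_level normal quantile used for confidence intervals (default:
#'   two-sided 95%).
#' @return object of class `solver_config`.
#' @export
solver_config <- function(tol = 1e-8, max_iter = 10000L, n_lambda = 100L,
                          lambda_min_ratio = 1e-3, cv_folds = 5L,
                          z_level = 1.959964) {
  stopifnot(tol > 0, max_iter >= 1, n_lambda >= 2,
            lambda_min_ratio > 0, lambda_min_ratio < 1, cv_folds >= 2)
  structure(list(tol = tol, max_iter = as.integer(max_iter),
                 n_lambda = as.integer(n_lambda),
                 lambda_min_ratio = lambda_min_ratio,
                 cv_folds = as.integer(cv_folds), z_level = z_level),
            class = "solver_config")
}

# weighted conditional log-likelihood on collapsed patterns
.wll <- function(U, w, beta) {
  eta <- drop(U %*% beta)
  sum(w * stats::plogis(eta, log.p = TRUE))
}

#' Conditional log-likelihood of a pair-difference matrix
#'
#' For 1:1 self-matched pairs the conditional likelihood reduces to
#' `sum_i log sigma(beta' d_i)` over informative difference vectors `d_i`,
#' with no intercept and no stratum bookkeeping. At `beta = 0` this is
#' `-n log 2`.
#'
#' @param beta numeric coefficient vector (log rate ratios), one per drug
#'   column of `D`.
#' @param D a [difference_matrix()] result (entries -1/0/1).
#' @return the conditional log-likelihood (always <= 0).
#' @export
conditional_loglik <- function(beta, D) {
  stop_if_not_diff(D)
  if (length(beta) != ncol(D))
    stop("beta has length ", length(beta), " but D has ", ncol(D),
         " drug columns", call. = FALSE)
  .wll(D, rep(1, nrow(D)), beta)
}

#' Univariable discordant-pair estimator
#'
#' The closed-form 1:1 conditional MLE for a single drug: rate ratio
#' `n10 / n01` with log-scale standard error `sqrt(1/n10 + 1/n01)` and Wald
#' confidence limits. Zero counts on either side make the MLE infinite or
#' zero; those rows are flagged `degenerate` and carry no Wald interval
#' rather than raising an error.
#'
#' @param counts data.frame with columns `n10`, `n01` (and optionally
#'   `drug_code`), e.g. from [discordant_counts()].
#' @param config a [solver_config()] (only `z_level` is used).
#' @return data.frame with `drug_code`, `n10`, `n01`, `rr`, `log_rr`, `se`,
#'   `ci_low`, `ci_high`, `degenerate`.
#' @export
univariable_estimate <- function(counts, config = solver_config()) {
  stopifnot(all(c("n10", "n01") %in% names(counts)))
  n10 <- counts$n10; n01 <- counts$n01
  if (any(n10 + n01 <= 0))
    stop("n10 + n01 must be positive: no discordant pairs to estimate from",
         call. = FALSE)
  degenerate <- n10 == 0 | n01 == 0
  rr <- n10 / n01
  log_rr <- log(rr)
  se <- ifelse(degenerate, NA_real_, sqrt(1 / n10 + 1 / n01))
  z <- config$z_level
  data.frame(
    drug_code = counts$drug_code %||% sprintf("drug%02d", seq_along(n10)),
    n10 = n10, n01 = n01,
    rr = rr, log_rr = log_rr, se = se,
    ci_low = ifelse(degenerate, NA_real_, exp(log_rr - z * se)),
    ci_high = ifelse(degenerate, NA_real_, exp(log_rr + z * se)),
    degenerate = degenerate,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

# columns whose nonzero (positively weighted) entries are single-signed are
# separation-degenerate: the conditional MLE is +/-Inf
.degenerate_columns <- function(U, w) {
  pos <- colSums((U > 0) * w) > 0
  neg <- colSums((U < 0) * w) > 0
  list(degenerate = !(pos & neg), sign = ifelse(pos, 1, ifelse(neg, -1, NA)))
}

.newton_clogit <- function(U, w, tol, max_iter) {
  p <- ncol(U)
  beta <- numeric(p)
  ll <- .wll(U, w, beta)
  converged <- FALSE
  it <- 0L
  H <- NULL
  while (it < max_iter) {
    it <- it + 1L
    eta <- drop(U %*% beta)
    pr <- stats::plogis(eta)
    g <- drop(crossprod(U, w * (1 - pr)))
    H <- crossprod(U * sqrt(w * pr * (1 - pr)))
    step <- tryCatch(solve(H, g), error = function(e)
      stop("observed information is singular: collinear drug columns",
           call. = FALSE))
    t_ <- 1
    repeat {
      cand <- beta + t_ * step
      ll_new <- .wll(U, w, cand)
      if (ll_new >= ll - 1e-12 || t_ < 1e-4) break
      t_ <- t_ / 2
    }
    moved <- max(abs(t_ * step))
    beta <- cand
    ll <- ll_new
    if (moved < tol) { converged <- TRUE; break }
  }
  eta <- drop(U %*% beta)
  pr <- stats::plogis(eta)
  H <- crossprod(U * sqrt(w * pr * (1 - pr)))
  vcov <- tryCatch(solve(H), error = function(e) matrix(NA_real_, p, p))
  list(beta = beta, vcov = vcov, loglik = ll, converged = converged,
       iterations = it)
}

.make_fit <- function(drugs, beta, se, loglik, lambda, converged, iterations,
                      degenerate, n_pairs, vcov = NULL, kkt = NA_real_) {
  z <- 1.959964
  structure(list(
    coefficients = setNames(beta, drugs),
    se = setNames(se, drugs),
    rr = setNames(exp(beta), drugs),
    ci_low = setNames(exp(beta - z * se), drugs),
    ci_high = setNames(exp(beta + z * se), drugs),
    loglik = loglik, lambda = lambda, converged = converged,
    iterations = iterations,
    degenerate = setNames(degenerate, drugs),
    n_pairs = n_pairs, vcov = vcov, kkt_gap = kkt
  ), class = "cclogit")
}

#' Unpenalized conditional logistic fit (joint MLE)
#'
#' Maximizes the 1:1 conditional likelihood over all drug columns jointly by
#' Newton-Raphson with step halving; standard errors come from the inverse
#' of the observed information. Columns exhibiting complete separation
#' (all discordant pairs on one side) are flagged `degenerate`, reported as
#' `+Inf`/`-Inf` with no standard error, and excluded from the joint
#' maximization; all-zero columns are reported as `NA`.
#'
#' @param D a [difference_matrix()] result.
#' @param config a [solver_config()].
#' @return object of class `cclogit`; see [coef.cclogit()] and friends.
#' @export
cclogit <- function(D, config = solver_config()) {
  stop_if_not_diff(D)
  drugs <- colnames(D) %||% sprintf("drug%02d", seq_len(ncol(D)))
  cp <- collapse_patterns(unclass(D))
  w <- as.numeric(cp$counts)
  U <- cp$patterns
  deg <- .degenerate_columns(U, w)
  p <- ncol(U)
  beta <- rep(NA_real_, p); se <- rep(NA_real_, p)
  beta[deg$degenerate] <- deg$sign[deg$degenerate] * Inf
  keep <- which(!deg$degenerate)
  vcov <- NULL
  loglik <- NA_real_; converged <- TRUE; iterations <- 0L
  if (length(keep)) {
    fit <- .newton_clogit(U[, keep, drop = FALSE], w, config$tol,
                          config$max_iter)
    beta[keep] <- fit$beta
    se[keep] <- sqrt(diag(fit$vcov))
    vcov <- fit$vcov
    dimnames(vcov) <- list(drugs[keep], drugs[keep])
    loglik <- fit$loglik
    converged <- fit$converged
    iterations <- fit$iterations
    if (!converged)
      warning("Newton iteration reached max_iter without meeting tol",
              call. = FALSE)
  } else {
    loglik <- .wll(U[, 0, drop = FALSE], w, numeric(0))
  }
  .make_fit(drugs, beta, se, loglik, 0, converged, iterations,
            deg$degenerate, n_pairs = nrow(D), vcov = vcov)
}

#' Smallest penalty with an all-zero L1 solution
#'
#' Equals the largest absolute component of the conditional score at
#' `beta = 0`, i.e. `max_j |0.5 * sum_i d_ij|`.
#'
#' @param D a [difference_matrix()] result.
#' @return a non-negative penalty value.
#' @export
lambda_max <- function(D) {
  stop_if_not_diff(D)
  max(abs(0.5 * colSums(unclass(D))))
}

.lambda_path <- function(lmax, config) {
  lmax * exp(seq(0, log(config$lambda_min_ratio),
                 length.out = config$n_lambda))
}

# coordinate-descent path on collapsed patterns; columns must be -1/0/1
.fit_path <- function(U, w, lambdas, config) {
  storage.mode(U) <- "double"
  cd_l1_path_cpp(U, as.numeric(w), as.numeric(lambdas),
                 config$tol, config$max_iter)
}

#' L1-penalized conditional logistic fit
#'
#' Maximizes `conditional_loglik(beta) - lambda * sum_j |beta_j|` by cyclic
#' coordinate-wise Newton steps with soft-thresholding, warm-started along a
#' short geometric path from [lambda_max()] down to the requested penalty.
#' At `lambda = 0` the solution coincides with the unpenalized MLE; at
#' `lambda >= lambda_max(D)` it is exactly the zero vector. Penalized fits
#' report no standard errors.
#'
#' @param D a [difference_matrix()] result.
#' @param lambda non-negative penalty on the sum of absolute log rate
#'   ratios.
#' @param config a [solver_config()].
#' @return object of class `cclogit` with `lambda` set; `kkt_gap` records
#'   the largest violation of the stationarity conditions at the solution.
#' @export
cclogit_l1 <- function(D, lambda, config = solver_config()) {
  stop_if_not_diff(D)
  if (lambda < 0) stop("lambda must be non-negative", call. = FALSE)
  drugs <- colnames(D) %||% sprintf("drug%02d", seq_len(ncol(D)))
  cp <- collapse_patterns(unclass(D))
  w <- as.numeric(cp$counts)
  U <- cp$patterns
  lmax <- max(abs(0.5 * colSums(U * w)))
  if (lambda >= lmax) {
    path <- lambda
  } else if (lambda > 0) {
    path <- c(lmax * exp(seq(0, log(max(lambda / lmax, 1e-12)),
                             length.out = 20L))[-20L], lambda)
  } else {
    path <- c(lmax * exp(seq(0, log(1e-4), length.out = 20L)), 0)
  }
  fit <- .fit_path(U, w, path, config)
  k <- length(path)
  beta <- fit$beta[, k]
  if (!fit$converged[k])
    warning("coordinate descent reached max_iter without meeting tol",
            call. = FALSE)
  # KKT stationarity audit
  eta <- drop(U %*% beta)
  g <- drop(crossprod(U, w * (1 - stats::plogis(eta))))
  kkt <- max(ifelse(beta == 0, pmax(abs(g) - lambda, 0),
                    abs(g - lambda * sign(beta))))
  .make_fit(drugs, beta, rep(NA_real_, length(beta)), fit$loglik[k], lambda,
            fit$converged[k], fit$iterations[k],
            degenerate = rep(FALSE, length(beta)), n_pairs = nrow(D),
            kkt = kkt)
}

#' Cross-validated penalty choice
#'
#' Lays a geometric path of `n_lambda` penalties from [lambda_max()] down to
#' `lambda_min_ratio * lambda_max`, assigns informative pairs to
#' `cv_folds` folds (seeded), fits the path on each training split and
#' scores each penalty by the total held-out conditional log-likelihood.
#' Ties are broken toward the larger (sparser) penalty.
#'
#' @param D a [difference_matrix()] result.
#' @param config a [solver_config()].
#' @param seed integer seed for the fold assignment (recorded in the
#'   result's attributes).
#' @return the selected penalty, with attributes `lambda_path`,
#'   `cv_loglik` and `seed`.
#' @export
cv_select_lambda <- function(D, config = solver_config(), seed = 1L) {
  stop_if_not_diff(D)
  n <- nrow(D)
  if (n < config$cv_folds)
    stop("fewer informative pairs than cv_folds", call. = FALSE)
  lmax <- lambda_max(D)
  if (lmax == 0) {
    warning("score at the origin is zero in every column; ",
            "the penalty path is degenerate", call. = FALSE)
    return(structure(0, lambda_path = 0, cv_loglik = NA_real_, seed = seed))
  }
  path <- .lambda_path(lmax, config)
  cp <- collapse_patterns(unclass(D))
  U <- cp$patterns
  set.seed(seed)
  folds <- sample(rep_len(seq_len(config$cv_folds), n))
  cvll <- numeric(length(path))
  for (f in seq_len(config$cv_folds)) {
    w_train <- pattern_weights(cp, as.numeric(folds != f))
    w_test <- pattern_weights(cp, as.numeric(folds == f))
    fit <- .fit_path(U, w_train, path, config)
    for (l in seq_along(path))
      cvll[l] <- cvll[l] + .wll(U, w_test, fit$beta[, l])
  }
  best <- which.max(cvll) # path is decreasing: first max = largest lambda
  structure(path[best], lambda_path = path, cv_loglik = cvll, seed = seed)
}

# --- methods ----------------------------------------------------------------

#' @export
print.cclogit <- function(x, ...) {
  type <- if (x$lambda > 0) sprintf("L1-penalized (lambda = %.4g)", x$lambda)
          else "unpenalized MLE"
  cat("Conditional logistic fit (1:1 case-crossover), ", type, "\n", sep = "")
  cat("  informative pairs:", x$n_pairs, "| drugs:", length(x$coefficients),
      "| log-likelihood:", format(x$loglik, digits = 6), "\n")
  nz <- sum(x$coefficients != 0, na.rm = TRUE)
  if (x$lambda > 0) cat("  nonzero coefficients:", nz, "\n")
  if (any(x$degenerate))
    cat("  separation-degenerate drugs:", sum(x$degenerate), "\n")
  invisible(x)
}

#' @export
summary.cclogit <- function(object, ...) {
  out <- data.frame(
    drug_code = names(object$coefficients),
    log_rr = unname(object$coefficients),
    rr = unname(object$rr),
    se = unname(object$se),
    ci_low = unname(object$ci_low),
    ci_high = unname(object$ci_high),
    degenerate = unname(object$degenerate),
    stringsAsFactors = FALSE
  )
  print(object)
  print(out, digits = 4)
  invisible(out)
}

#' Extract log rate ratios from a conditional-logistic fit
#' @param object,... a `cclogit` object.
#' @export
coef.cclogit <- function(object, ...) object$coefficients

#' @export
vcov.cclogit <- function(object, ...) object$vcov

#' Confidence limits on the rate-ratio scale
#'
#' Wald limits `exp(beta +/- z * se)`; `NA` for penalized fits and for
#' separation-degenerate drugs.
#'
#' @param object a `cclogit` object.
#' @param parm,level,... ignored (limits are fixed at the solver's
#'   `z_level`, 95% by default).
#' @export
confint.cclogit <- function(object, parm, level = 0.95, ...) {
  cbind(ci_low = object$ci_low, ci_high = object$ci_high)
}

#' @export
logLik.cclogit <- function(object, ...) {
  structure(object$loglik,
            df = sum(object$coefficients != 0, na.rm = TRUE),
            nobs = object$n_pairs, class = "logLik")
}
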