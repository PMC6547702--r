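#' Bootstrap specification for BOLASSO selection
#'
#' @param n_bootstrap number of bootstrap resamples (1000 for a
#'   register-scale run; 100 is the desk-scale quickstart).
#' @param consensus fraction of bootstraps in which a drug must be selected;
#'   1.0 is the strict intersection-of-supports rule, 0.9 the soft variant.
#' @param seed master seed; each bootstrap draws from its own substream
#'   derived from `(seed, b)`, so enlarging `n_bootstrap` does not reshuffle
#'   earlier resamples.
#' @param lambda_mode `"cv"` chooses the penalty per bootstrap by
#'   cross-validated held-out likelihood; `"fixed"` uses `lambda` in every
#'   bootstrap.
#' @param lambda penalty for `lambda_mode = "fixed"`.
#' @return object of class `bootstrap_spec`.
#' @export
bootstrap_spec <- function(n_bootstrap = 1000L, consensus = 1.0, seed = 1L,
                           lambda_mode = c("cv", "fixed"), lambda = NULL) {
  lambda_mode <- match.arg(lambda_mode)
  stopifnot(n_bootstrap >= 1, consensus > 0, consensus <= 1)
  if (lambda_mode == "fixed") {
    if (is.null(lambda) || lambda < 0)
      stop("lambda_mode = \"fixed\" requires a non-negative lambda",
           call. = FALSE)
  }
  structure(list(n_bootstrap = as.integer(n_bootstrap), consensus = consensus,
                 seed = as.integer(seed), lambda_mode = lambda_mode,
                 lambda = lambda),
            class = "bootstrap_spec")
}

# cross-validated penalty on a weighted (resampled) instance; idx are the
# resampled original-row indices, so folds partition the bootstrap multiset
.cv_lambda_weighted <- function(U, cp, idx, config) {
  m <- nrow(U)
  w_full <- tabulate(cp$id[idx], nbins = m)
  lmax <- max(abs(0.5 * colSums(U * w_full)))
  if (lmax == 0) return(list(lambda = 0, w = w_full))
  path <- .lambda_path(lmax, config)
  folds <- sample(rep_len(seq_len(config$cv_folds), length(idx)))
  cvll <- numeric(length(path))
  for (f in seq_len(config$cv_folds)) {
    w_train <- tabulate(cp$id[idx[folds != f]], nbins = m)
    w_test <- tabulate(cp$id[idx[folds == f]], nbins = m)
    fit <- .fit_path(U, w_train, path, config)
    for (l in seq_along(path))
      cvll[l] <- cvll[l] + .wll(U, w_test, fit$beta[, l])
  }
  list(lambda = path[which.max(cvll)], w = w_full)
}

#' BOLASSO: bootstrap-enhanced LASSO drug selection
#'
#' Resamples informative pairs (rows of `D`) with replacement to the
#' original size, fits the L1-penalized conditional logistic model on each
#' resample (penalty per `lambda_mode`), and records which drugs have
#' nonzero coefficients. Drugs whose selection frequency reaches
#' `consensus` form the selected set, which is then refit jointly without
#' penalty on the original (unresampled) data — reported effects are
#' mutually adjusted and free of shrinkage.
#'
#' The resampling unit is the whole pair: the two periods of a patient are
#' never separated, preserving the self-matching of the design. Columns
#' that are separation-degenerate within a resample (all discordant pairs
#' on one side) are dropped from that fit and count as not selected there.
#'
#' @param D a [difference_matrix()] result.
#' @param spec a [bootstrap_spec()].
#' @param config a [solver_config()].
#' @return object of class `bolasso`: `frequencies` (per-drug selection
#'   fraction), `selected` (drug codes), `refit` (a [cclogit] fit on the
#'   selected columns, or `NULL` if none), `lambdas` (per-bootstrap
#'   penalties), plus the specs used.
#' @export
bolasso <- function(D, spec = bootstrap_spec(), config = solver_config()) {
  stop_if_not_diff(D)
  drugs <- colnames(D) %||% sprintf("drug%02d", seq_len(ncol(D)))
  colnames(D) <- drugs
  n <- nrow(D)
  p <- ncol(D)
  cp <- collapse_patterns(unclass(D))
  U <- cp$patterns
  support_counts <- integer(p)
  lambdas <- numeric(spec$n_bootstrap)

  for (b in seq_len(spec$n_bootstrap)) {
    set.seed(substream_seed(spec$seed, b))
    idx <- sample.int(n, n, replace = TRUE)
    w_b <- tabulate(cp$id[idx], nbins = nrow(U))
    deg <- .degenerate_columns(U, w_b)$degenerate
    keep <- which(!deg)
    if (!length(keep)) { lambdas[b] <- NA_real_; next }
    Uk <- U[, keep, drop = FALSE]
    if (spec$lambda_mode == "fixed") {
      lam <- spec$lambda
    } else {
      cpk <- list(id = cp$id)
      lam <- .cv_lambda_weighted(Uk, cpk, idx, config)$lambda
    }
    lambdas[b] <- lam
    lmax_b <- max(abs(0.5 * colSums(Uk * w_b)))
    if (lam >= lmax_b && lam > 0) next # all-zero solution
    path <- if (lam <= 0) {
      c(lmax_b * exp(seq(0, log(1e-4), length.out = 20L)), 0)
    } else {
      c(lmax_b * exp(seq(0, log(lam / lmax_b), length.out = 20L)))
    }
    fit <- .fit_path(Uk, w_b, path, config)
    nz <- fit$beta[, length(path)] != 0
    support_counts[keep[nz]] <- support_counts[keep[nz]] + 1L
  }

  freq <- setNames(support_counts / spec$n_bootstrap, drugs)
  selected <- drugs[freq >= spec$consensus - 1e-9]
  refit <- NULL
  if (length(selected)) {
    Dsel <- unclass(D)[, selected, drop = FALSE]
    class(Dsel) <- c("pair_diff", class(Dsel))
    refit <- cclogit(Dsel, config)
  }
  structure(list(frequencies = freq, selected = selected, refit = refit,
                 lambdas = lambdas, spec = spec, config = config,
                 n_pairs = n, drugs = drugs),
            class = "bolasso")
}

#' @export
print.bolasso <- function(x, ...) {
  cat("BOLASSO selection over", length(x$drugs), "drugs,",
      x$spec$n_bootstrap, "bootstraps (consensus",
      format(x$spec$consensus), ")\n")
  cat("  informative pairs:", x$n_pairs, "\n")
  cat("  selected:", length(x$selected),
      if (length(x$selected)) paste0("[", paste(x$selected, collapse = ", "), "]")
      else "(empty)", "\n")
  invisible(x)
}

#' @export
summary.bolasso <- function(object, ...) {
  tab <- selection_report(object)
  print(object)
  print(tab[order(-tab$frequency), ], digits = 4, row.names = FALSE)
  invisible(tab)
}

#' Refit coefficients of the selected drugs
#' @param object,... a `bolasso` object.
#' @return named log rate ratios of the unpenalized joint refit (empty
#'   numeric if nothing was selected).
#' @export
coef.bolasso <- function(object, ...) {
  if (is.null(object$refit)) return(setNames(numeric(0), character(0)))
  coef(object$refit)
}

#' Selection-frequency plot
#' @param x a `bolasso` object.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.bolasso <- function(x, ...) {
  ord <- order(-x$frequencies)
  barplot(x$frequencies[ord], las = 2, ylim = c(0, 1),
          ylab = "bootstrap selection frequency",
          cex.names = 0.6, ...)
  abline(h = x$spec$consensus, lty = 2)
  invisible(x)
}

#' Tabular selection report
#'
#' One row per drug: bootstrap selection frequency, whether it met the
#' consensus threshold, and (for selected drugs) the refit rate ratio with
#' Wald limits.
#'
#' @param x a `bolasso` object.
#' @return data.frame with `drug_code`, `frequency`, `selected`, `rr`,
#'   `ci_low`, `ci_high`.
#' @export
selection_report <- function(x) {
  stopifnot(inherits(x, "bolasso"))
  out <- data.frame(drug_code = x$drugs,
                    frequency = unname(x$frequencies),
                    selected = x$drugs %in% x$selected,
                    rr = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                    stringsAsFactors = FALSE)
  if (!is.null(x$refit)) {
    i <- match(names(coef(x$refit)), out$drug_code)
    out$rr[i] <- unname(x$refit$rr)
    out$ci_low[i] <- unname(x$refit$ci_low)
    out$ci_high[i] <- unname(x$refit$ci_high)
  }
  out
}

#' Evaluate a selection against planted truth
#'
#' @param result a `bolasso` object.
#' @param truth named vector of true rate ratios over the drug universe
#'   (e.g. [planted_truth()]).
#' @return list with `sensitivity` (fraction of truly non-null drugs
#'   selected), `false_positive_count` (null drugs selected) and
#'   `mean_signed_bias` (mean of refit log-RR minus true log-RR over truly
#'   non-null selected drugs; `NA` if none).
#' @export
selection_metrics <- function(result, truth) {
  stopifnot(inherits(result, "bolasso"))
  missing_drugs <- setdiff(result$drugs, names(truth))
  if (length(missing_drugs))
    stop("truth does not cover the drug universe: ",
         paste(missing_drugs, collapse = ", "), call. = FALSE)
  nonnull <- names(truth)[truth != 1]
  sel <- result$selected
  tp <- intersect(sel, nonnull)
  sens <- if (length(nonnull)) length(tp) / length(nonnull) else NA_real_
  fp <- length(setdiff(sel, nonnull))
  bias <- NA_real_
  if (length(tp) && !is.null(result$refit)) {
    b <- coef(result$refit)[tp]
    ok <- is.finite(b)
    if (any(ok)) bias <- mean(b[ok] - log(truth[tp][ok]))
  }
  list(sensitivity = sens, false_positive_count = fp,
       mean_signed_bias = bias)
}
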