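#' Reconstruct a log-scale standard error from printed confidence limits
#'
#' Published relative risks usually come with a 95% interval but no standard
#' error; for a Wald interval on the log scale,
#' `se = (ln(ci_high) - ln(ci_low)) / (2 * z)`. Vectorized.
#'
#' @param ci_low,ci_high positive confidence limits on the ratio scale.
#' @param z_level normal quantile of the interval (default two-sided 95%).
#' @return non-negative standard errors on the log rate-ratio scale.
#' @export
se_from_ci <- function(ci_low, ci_high, z_level = 1.959964) {
  if (any(ci_low <= 0) || any(ci_high <= 0))
    stop("confidence limits must be positive ratios", call. = FALSE)
  if (any(ci_high < ci_low))
    stop("ci_high must be >= ci_low", call. = FALSE)
  se <- (log(ci_high) - log(ci_low)) / (2 * z_level)
  if (any(se == 0))
    warning("degenerate interval (ci_low == ci_high): se = 0", call. = FALSE)
  se
}

#' Inverse-variance fixed-effect combination of country estimates
#'
#' Combines log relative risks with weights `1/se^2` under a common-effect
#' assumption: the pooled log-RR is the weighted mean and its standard
#' error `(sum of weights)^(-1/2)`. Cochran's Q and I-squared are computed
#' and carried along for inspection but never gate the combination.
#'
#' @param estimates data.frame with columns `log_rr` and `se` (one row per
#'   country) and optionally `drug_code` and `country`; all rows must refer
#'   to the same drug.
#' @param z_level normal quantile for the combined interval.
#' @return object of class `meta_fe`: `drug_code`, `log_rr`, `se`, `rr`,
#'   `ci_low`, `ci_high`, `k` (number of strata), `Q`, `I2`.
#' @export
fixed_effect <- function(estimates, z_level = 1.959964) {
  stopifnot(is.data.frame(estimates),
            all(c("log_rr", "se") %in% names(estimates)),
            nrow(estimates) >= 1)
  if (any(estimates$se <= 0))
    stop("standard errors must be positive", call. = FALSE)
  drug <- NA_character_
  if ("drug_code" %in% names(estimates)) {
    u <- unique(estimates$drug_code)
    if (length(u) > 1)
      stop("estimates mix drug codes: ", paste(u, collapse = ", "),
           call. = FALSE)
    drug <- u
  }
  w <- 1 / estimates$se^2
  mu <- sum(w * estimates$log_rr) / sum(w)
  se <- 1 / sqrt(sum(w))
  Q <- sum(w * (estimates$log_rr - mu)^2)
  k <- nrow(estimates)
  I2 <- if (k > 1 && Q > 0) max(0, (Q - (k - 1)) / Q) else 0
  structure(list(drug_code = drug, log_rr = mu, se = se,
                 rr = exp(mu),
                 ci_low = exp(mu - z_level * se),
                 ci_high = exp(mu + z_level * se),
                 k = k, Q = Q, I2 = I2),
            class = "meta_fe")
}

#' @export
print.meta_fe <- function(x, ...) {
  cat(sprintf("Fixed-effect combined estimate%s: RR %.3f (%.3f-%.3f), k = %d",
              if (is.na(x$drug_code)) "" else paste0(" [", x$drug_code, "]"),
              x$rr, x$ci_low, x$ci_high, x$k),
      sprintf(" | Q = %.2f, I2 = %.0f%%\n", x$Q, 100 * x$I2))
  invisible(x)
}

#' Drugs selected in every country
#'
#' @param selections list (length >= 2) of `bolasso` objects or character
#'   vectors of selected drug codes.
#' @return character vector: the intersection of the selected sets.
#' @export
common_hits <- function(selections) {
  stopifnot(is.list(selections), length(selections) >= 2)
  sets <- lapply(selections, function(s) {
    if (inherits(s, "bolasso")) s$selected else as.character(s)
  })
  Reduce(intersect, sets)
}

#' Reference combined estimates from a two-country AMI screen
#'
#' Country-specific and combined relative risks (with 95% intervals and
#' discordant-pair counts) for the 48 drugs selected in both countries by a
#' pharmacopeia-wide case-crossover screen of first acute myocardial
#' infarction against national prescription registers (Sweden 2005-2014,
#' Norway 2004-2014; case period 1-7 days, control period 15-21 days before
#' the index date). Country effects are mutually adjusted BOLASSO refits;
#' the combined column is their inverse-variance fixed-effect combination.
#' Values are as printed (two decimals), so reconstructions match only to
#' print precision.
#'
#' @return data.frame with columns `atc_code`, `drug_name`, `sw_n10`,
#'   `sw_n01`, `sw_rr`, `sw_lo`, `sw_hi`, `no_n10`, `no_n01`, `no_rr`,
#'   `no_lo`, `no_hi`, `comb_rr`, `comb_lo`, `comb_hi`.
#' @export
ami_screen_estimates <- function() {
  path <- system.file("extdata", "ami_common_hits.tsv", package = "pwascc",
                      mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}
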