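# End-to-end orchestration: simulate or ingest two (or more) countries, run
# exposure construction -> BOLASSO selection per country, intersect the
# selected sets, and combine the per-country refits by fixed-effect
# meta-analysis.

.variant_presets <- function(variant, window, filters) {
  switch(variant,
    main = list(window = window, filters = filters),
    extended_windows = list(window = window_spec(c(1L, 14L), c(29L, 42L)),
                            filters = filters),
    hospital_only = {
      filters$hospital_only <- TRUE
      list(window = window, filters = filters)
    },
    age_lt80 = {
      filters$age_split_at <- 80L; filters$age_side <- "below"
      list(window = window, filters = filters)
    },
    age_ge80 = {
      filters$age_split_at <- 80L; filters$age_side <- "above"
      list(window = window, filters = filters)
    },
    stop("unknown variant: ", variant, call. = FALSE)
  )
}

# tiny polynomial hash over the deparsed configuration, for provenance
# stamping (not cryptographic)
.config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run a pharmacopeia-wide case-crossover screen end to end
#'
#' For each country: obtain registry tables (simulating them when a
#' [registry_config()] is given), build exposure windows, reduce to
#' informative pairs, and run BOLASSO selection. Selections are intersected
#' across countries and, for each common hit, the per-country unpenalized
#' refit estimates are combined by inverse-variance fixed-effect
#' meta-analysis.
#'
#' @param countries named list with one element per country, each either a
#'   [registry_config()] or a list with `dispensings` and `events`
#'   data.frames (the [write_registry()] schema).
#' @param window a [window_spec()]; overridden by `variant`.
#' @param filters an [eligibility_filters()]; possibly extended by
#'   `variant`.
#' @param solver a [solver_config()].
#' @param bootstrap a [bootstrap_spec()]; its seed is re-derived per country
#'   from `seed`.
#' @param variant one of `"main"`, `"extended_windows"`, `"hospital_only"`,
#'   `"age_lt80"`, `"age_ge80"`.
#' @param seed master seed governing per-country bootstrap substreams.
#' @param out_dir optional directory; when given, per-country selection
#'   reports, the combined report and a machine-readable key-value summary
#'   are written as tab-separated text.
#' @return object of class `pwas`: per-country results (`exposures` funnel
#'   counts, `selection`), `common`, `combined` (data.frame), `summary`
#'   (named list of funnel counts), and provenance (`variant`, `seed`,
#'   `config_hash`).
#' @export
run_pwas <- function(countries, window = window_spec(),
                     filters = eligibility_filters(),
                     solver = solver_config(),
                     bootstrap = bootstrap_spec(n_bootstrap = 100L),
                     variant = "main", seed = 1L, out_dir = NULL) {
  stopifnot(is.list(countries), length(countries) >= 1,
            !is.null(names(countries)), all(nzchar(names(countries))))
  preset <- .variant_presets(variant, window, filters)
  window <- preset$window; filters <- preset$filters

  per_country <- list()
  for (i in seq_along(countries)) {
    label <- names(countries)[i]
    cin <- countries[[i]]
    if (inherits(cin, "registry_config")) {
      sim <- simulate_registry(cin)
      dispensings <- sim$dispensings; events <- sim$events
      truth <- setNames(sim$truth$true_rr, sim$truth$drug_code)
    } else {
      dispensings <- cin$dispensings; events <- cin$events
      truth <- NULL
    }
    exposures <- build_exposures(dispensings, events, window, filters)
    D <- difference_matrix(exposures)
    bspec <- bootstrap
    bspec$seed <- substream_seed(seed, i * 1000L)
    selection <- bolasso(D, bspec, solver)
    per_country[[label]] <- list(
      label = label, exposures = exposures, selection = selection,
      truth = truth,
      funnel = c(patients_in = exposures$n_events_in,
                 patients_retained = exposures$n_retained,
                 drugs_dispensed = exposures$n_drugs_dispensed,
                 drugs_either_window = length(exposures$drugs),
                 informative_pairs = nrow(D),
                 drugs_selected = length(selection$selected))
    )
  }

  common <- if (length(per_country) >= 2)
    common_hits(lapply(per_country, `[[`, "selection"))
  else per_country[[1]]$selection$selected

  combined <- data.frame(drug_code = character(0))
  if (length(common)) {
    rows <- lapply(sort(common), function(drug) {
      est <- do.call(rbind, lapply(per_country, function(pc) {
        fit <- pc$selection$refit
        b <- coef(fit)[drug]; s <- fit$se[drug]
        data.frame(country = pc$label, drug_code = drug,
                   log_rr = unname(b), se = unname(s),
                   stringsAsFactors = FALSE)
      }))
      est <- est[is.finite(est$log_rr) & is.finite(est$se) & est$se > 0, ,
                 drop = FALSE]
      if (nrow(est) == 0) return(NULL)
      fe <- fixed_effect(est, z_level = solver$z_level)
      out <- data.frame(drug_code = drug, stringsAsFactors = FALSE)
      for (j in seq_len(nrow(est))) {
        pfx <- est$country[j]
        out[[paste0(pfx, "_rr")]] <- exp(est$log_rr[j])
        out[[paste0(pfx, "_lo")]] <- exp(est$log_rr[j] - solver$z_level * est$se[j])
        out[[paste0(pfx, "_hi")]] <- exp(est$log_rr[j] + solver$z_level * est$se[j])
      }
      out$comb_rr <- fe$rr; out$comb_lo <- fe$ci_low; out$comb_hi <- fe$ci_high
      out$Q <- fe$Q; out$I2 <- fe$I2
      out
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (length(rows)) combined <- do.call(rbind, rows)
  }

  res <- structure(list(
    countries = per_country,
    common = common,
    combined = combined,
    window = window, filters = filters, variant = variant, seed = seed,
    solver = solver, bootstrap = bootstrap,
    config_hash = .config_hash(list(variant = variant, seed = seed,
                                    window = unclass(window),
                                    filters = unclass(filters),
                                    n_bootstrap = bootstrap$n_bootstrap,
                                    consensus = bootstrap$consensus)),
    summary = c(
      setNames(lapply(per_country, `[[`, "funnel"), names(per_country)),
      list(common_hits = length(common))
    )
  ), class = "pwas")
  if (!is.null(out_dir)) write_pwas(res, out_dir)
  res
}

#' @export
print.pwas <- function(x, ...) {
  cat("Pharmacopeia-wide case-crossover screen (variant:", x$variant,
      "| seed:", x$seed, "| config:", x$config_hash, ")\n")
  print(x$window)
  for (pc in x$countries) {
    f <- pc$funnel
    cat(sprintf("  %s: %d patients in -> %d retained; %d drugs dispensed -> %d in either window -> %d selected\n",
                pc$label, f["patients_in"], f["patients_retained"],
                f["drugs_dispensed"], f["drugs_either_window"],
                f["drugs_selected"]))
  }
  cat("  common hits:", length(x$common),
      if (length(x$common)) paste0("[", paste(x$common, collapse = ", "), "]")
      else "", "\n")
  invisible(x)
}

#' Combined-report table of a screen
#'
#' One row per common-hit drug with per-country rate ratios and the
#' fixed-effect combination, in stable drug-code order. An empty common-hit
#' set yields a header-only (zero-row) table.
#'
#' @param x a `pwas` object from [run_pwas()].
#' @return data.frame.
#' @export
make_report <- function(x) {
  stopifnot(inherits(x, "pwas"))
  x$combined
}

#' Write screen artifacts as tab-separated text
#'
#' Per-country selection reports, the combined report, and a deterministic
#' key-value summary (`summary.txt`) carrying the funnel counts, seed,
#' variant and configuration hash.
#'
#' @param x a `pwas` object.
#' @param out_dir output directory, created if needed.
#' @return invisibly, the paths written.
#' @export
write_pwas <- function(x, out_dir) {
  stopifnot(inherits(x, "pwas"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (pc in x$countries) {
    p <- file.path(out_dir, paste0("selection_", pc$label, ".tsv"))
    write.table(selection_report(pc$selection), p, sep = "\t", quote = FALSE,
                row.names = FALSE)
    paths <- c(paths, p)
  }
  p <- file.path(out_dir, "combined_report.tsv")
  write.table(make_report(x), p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, p)

  kv <- c(
    sprintf("variant=%s", x$variant),
    sprintf("seed=%d", x$seed),
    sprintf("config_hash=%s", x$config_hash),
    sprintf("case_window=%d-%d", x$window$case_range[1], x$window$case_range[2]),
    sprintf("control_window=%d-%d", x$window$control_range[1],
            x$window$control_range[2]),
    unlist(lapply(x$countries, function(pc)
      sprintf("%s.%s=%d", pc$label, names(pc$funnel), pc$funnel))),
    sprintf("common_hits=%d", length(x$common))
  )
  p <- file.path(out_dir, "summary.txt")
  writeLines(kv, p)
  invisible(c(paths, p))
}
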