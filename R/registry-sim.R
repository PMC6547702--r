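#' Default drug-profile table for the registry simulator
#'
#' Emulates a national pharmacy mix: most substances are dispensed
#' episodically (antibiotics, analgesics: a homogeneous point process among
#' users) and the rest are chronic maintenance therapy refilled on a roughly
#' monthly-to-quarterly cycle. Profiles are deterministic in `n_drugs` so a
#' configuration fully specifies the generating process.
#'
#' @param n_drugs number of distinct drug codes in the universe.
#' @param acute_fraction fraction of the universe dispensed episodically.
#' @return data.frame with one row per drug: `drug_code`, `use_prevalence`,
#'   `mode` ("acute" or "chronic"), `acute_rate` (dispensings per
#'   patient-year among users), `refill_interval_days`, `refill_jitter_days`.
#' @export
default_drug_profiles <- function(n_drugs, acute_fraction = 0.7) {
  stopifnot(n_drugs >= 1)
  n_acute <- max(1L, round(n_drugs * acute_fraction))
  mode <- rep(c("acute", "chronic"), c(n_acute, n_drugs - n_acute))
  data.frame(
    drug_code = sprintf("D%03d", seq_len(n_drugs)),
    use_prevalence = round(rep_len(c(0.05, 0.10, 0.20, 0.30, 0.15), n_drugs), 3),
    mode = mode,
    acute_rate = ifelse(mode == "acute", rep_len(c(1, 2, 4, 6), n_drugs), 0),
    refill_interval_days = ifelse(mode == "chronic", rep_len(c(28L, 30L, 90L), n_drugs), NA_integer_),
    refill_jitter_days = ifelse(mode == "chronic", 3L, NA_integer_),
    stringsAsFactors = FALSE
  )
}

# age distribution shaped after a Scandinavian first-AMI case mix:
# probabilities per decade band, ages drawn uniformly within band
.age_bands <- data.frame(
  lo = c(18L, 30L, 40L, 50L, 60L, 70L, 80L, 90L, 100L),
  hi = c(29L, 39L, 49L, 59L, 69L, 79L, 89L, 99L, 105L),
  prob = c(0.0005, 0.0035, 0.0233, 0.0764, 0.1693, 0.2525, 0.3545, 0.1186, 0.0014)
)

#' Configuration of the synthetic prescription-registry generator
#'
#' Describes one "country": a cohort of patients observed for
#' `observation_days`, a drug universe with per-drug dispensing processes,
#' and a daily event hazard on which planted drugs act multiplicatively
#' while they were dispensed within the preceding `trigger_window_days`.
#' Two configurations sharing `planted_effects` emulate two countries with
#' common true triggering effects.
#'
#' The real registries this emulates are restricted-access national
#' registers; every distribution here is a synthetic stand-in, not an
#' estimate from data.
#'
#' @param n_patients cohort size.
#' @param n_drugs size of the drug universe (ignored if `drug_profiles`
#'   is supplied).
#' @param observation_days length of the observation period in days.
#' @param drug_profiles data.frame as returned by
#'   [default_drug_profiles()]; one row per drug.
#' @param planted_effects named numeric vector of triggering rate ratios
#'   (names are drug codes); drugs not listed have rate ratio 1.
#' @param trigger_window_days look-back window (days) during which a
#'   dispensing multiplies the event hazard; defaults to 7 so the planted
#'   rate ratio equals the estimand of the default analysis window.
#' @param baseline_hazard events per patient-day in the unexposed state.
#' @param death_fraction probability an event is recorded via the cause-of-
#'   death register ("death") rather than hospital discharge ("hospital").
#' @param country_label short label attached to output tables.
#' @param seed integer seed; identical seeds give byte-identical output.
#' @return object of class `registry_config`.
#' @export
registry_config <- function(n_patients = 20000, n_drugs = 40,
                            observation_days = 3650,
                            drug_profiles = NULL,
                            planted_effects = numeric(0),
                            trigger_window_days = 7,
                            baseline_hazard = 1e-4,
                            death_fraction = 0.176,
                            country_label = "SIM",
                            seed = 1L) {
  if (is.null(drug_profiles)) drug_profiles <- default_drug_profiles(n_drugs)
  n_drugs <- nrow(drug_profiles)
  stopifnot(
    n_patients >= 1, observation_days > 42,
    all(drug_profiles$use_prevalence >= 0 & drug_profiles$use_prevalence <= 1),
    death_fraction >= 0, death_fraction <= 1,
    trigger_window_days >= 1
  )
  if (baseline_hazard <= 0)
    stop("baseline_hazard must be positive", call. = FALSE)
  if (any(drug_profiles$mode == "acute" & drug_profiles$acute_rate < 0) ||
      any(drug_profiles$mode == "acute" & !is.finite(drug_profiles$acute_rate)))
    stop("acute_rate must be a non-negative finite rate", call. = FALSE)
  chron <- drug_profiles$mode == "chronic"
  if (any(chron & (is.na(drug_profiles$refill_interval_days) |
                   drug_profiles$refill_interval_days <= 0)))
    stop("refill_interval_days must be positive for chronic drugs", call. = FALSE)
  if (length(planted_effects)) {
    if (is.null(names(planted_effects)) || any(!nzchar(names(planted_effects))))
      stop("planted_effects must be a named vector of rate ratios", call. = FALSE)
    if (any(planted_effects <= 0))
      stop("planted rate ratios must be positive", call. = FALSE)
    unknown <- setdiff(names(planted_effects), drug_profiles$drug_code)
    if (length(unknown))
      stop("planted_effects name drugs outside the universe: ",
           paste(unknown, collapse = ", "), call. = FALSE)
  }
  structure(list(
    n_patients = as.integer(n_patients),
    observation_days = as.integer(observation_days),
    drug_profiles = drug_profiles,
    planted_effects = planted_effects,
    trigger_window_days = as.integer(trigger_window_days),
    baseline_hazard = baseline_hazard,
    death_fraction = death_fraction,
    country_label = country_label,
    seed = as.integer(seed)
  ), class = "registry_config")
}

#' @export
print.registry_config <- function(x, ...) {
  cat("Synthetic registry configuration (", x$country_label, ")\n", sep = "")
  cat("  patients:", x$n_patients, " observation:", x$observation_days, "days\n")
  cat("  drugs:", nrow(x$drug_profiles),
      sprintf("(%d acute / %d chronic)\n",
              sum(x$drug_profiles$mode == "acute"),
              sum(x$drug_profiles$mode == "chronic")))
  cat("  baseline hazard:", format(x$baseline_hazard), "per patient-day;",
      "trigger window:", x$trigger_window_days, "days\n")
  np <- sum(planted_truth(x) != 1)
  cat("  planted triggering effects:", np, "drug(s); seed:", x$seed, "\n")
  invisible(x)
}

#' Planted ground truth of a simulator configuration
#'
#' @param config a [registry_config()].
#' @return named numeric vector of true triggering rate ratios over the full
#'   drug universe; drugs without a planted effect map to 1.
#' @export
planted_truth <- function(config) {
  stopifnot(inherits(config, "registry_config"))
  rr <- setNames(rep(1, nrow(config$drug_profiles)),
                 config$drug_profiles$drug_code)
  if (length(config$planted_effects))
    rr[names(config$planted_effects)] <- config$planted_effects
  rr
}

# dispensing times for one drug across the cohort, vectorised over users
.simulate_drug_dispensings <- function(profile, n_patients, obs_days) {
  users <- which(runif(n_patients) < profile$use_prevalence)
  if (!length(users)) return(NULL)
  if (profile$mode == "acute") {
    lam <- profile$acute_rate * obs_days / 365.25
    k <- rpois(length(users), lam)
    keep <- k > 0
    if (!any(keep)) return(NULL)
    pid <- rep(users[keep], k[keep])
    day <- floor(runif(sum(k)) * obs_days)
    data.frame(patient_id = pid, day = as.integer(day))
  } else {
    # chronic maintenance: therapy initiates at a uniformly random day of
    # the observation period and persists with refills every
    # refill_interval_days +/- jitter (a renewal process). Initiation during
    # observation is what produces the persistent-user asymmetry between a
    # later and an earlier look-back window.
    nu <- length(users)
    init <- floor(runif(nu) * obs_days)
    interval <- profile$refill_interval_days
    jit <- profile$refill_jitter_days
    kmax <- ceiling(obs_days / interval) + 2L
    gaps <- matrix(interval + sample(seq(-jit, jit), nu * kmax, replace = TRUE),
                   nrow = kmax)
    gaps[gaps < 1L] <- 1L
    times <- rbind(rep(0L, nu), apply(gaps, 2L, cumsum)) +
      rep(init, each = kmax + 1L)
    keep <- times < obs_days
    if (!any(keep)) return(NULL)
    pid <- rep(users, each = kmax + 1L)[keep]
    data.frame(patient_id = pid, day = as.integer(times[keep]))
  }
}

#' Generate a synthetic dispensing + event registry
#'
#' Draws per-patient dispensing histories from the configured drug profiles,
#' then simulates a daily event process whose hazard on day t is
#' `baseline_hazard` multiplied by the planted rate ratio of every drug with
#' at least one dispensing in the preceding `trigger_window_days` days.
#' Patients enter the at-risk period on day 42 so that the longest default
#' control window and wash-out always fit inside observed history; the first
#' event (if any) becomes the patient's index event.
#'
#' @param config a [registry_config()].
#' @return list of class `registry_sim` with elements
#'   `dispensings` (patient_id, drug_code, dispense_date),
#'   `events` (patient_id, index_date, source, age_years, sex; one row per
#'   patient with an event), `truth` (data.frame drug_code, true_rr) and
#'   `config`.
#' @export
simulate_registry <- function(config) {
  stopifnot(inherits(config, "registry_config"))
  if (1 - (1 - config$baseline_hazard)^42 > 0.5)
    warning("baseline hazard implies >50% of patients would have an event ",
            "within the 42-day run-in; the design is degenerate at this scale")
  set.seed(config$seed)
  n <- config$n_patients
  obs <- config$observation_days
  prof <- config$drug_profiles

  disp <- vector("list", nrow(prof))
  for (j in seq_len(nrow(prof))) {
    dj <- .simulate_drug_dispensings(prof[j, ], n, obs)
    if (!is.null(dj)) dj$drug_code <- prof$drug_code[j]
    disp[[j]] <- dj
  }
  disp <- do.call(rbind, disp[!vapply(disp, is.null, logical(1))])
  if (is.null(disp))
    disp <- data.frame(patient_id = integer(0), day = integer(0),
                       drug_code = character(0))
  disp <- disp[order(disp$patient_id, disp$day, disp$drug_code), ]

  truth <- planted_truth(config)
  h0 <- config$baseline_hazard
  W <- config$trigger_window_days
  risk_start <- 42L
  days_at_risk <- obs - risk_start
  event_day <- rep(NA_integer_, n)

  planted <- names(truth)[truth != 1]
  if (length(planted) && nrow(disp)) {
    pd <- disp[disp$drug_code %in% planted, , drop = FALSE]
  } else {
    pd <- disp[0, , drop = FALSE]
  }
  exposed_ids <- unique(pd$patient_id)
  plain_ids <- setdiff(seq_len(n), exposed_ids)

  # constant-hazard patients: geometric first-event time past the run-in
  if (length(plain_ids) && days_at_risk > 0) {
    g <- rgeom(length(plain_ids), h0)
    hit <- g < days_at_risk
    event_day[plain_ids[hit]] <- risk_start + g[hit]
  }

  # patients carrying planted drugs: explicit daily Bernoulli thinning over
  # the piecewise-constant hazard
  if (length(exposed_ids) && days_at_risk > 0) {
    split_days <- split(pd[c("day", "drug_code")], pd$patient_id)
    for (nm in names(split_days)) {
      pid <- as.integer(nm)
      mult <- rep(1, days_at_risk)
      dd <- split_days[[nm]]
      for (drug in unique(dd$drug_code)) {
        s <- dd$day[dd$drug_code == drug]
        idx <- unique(unlist(lapply(s, function(si) {
          from <- max(si + 1L, risk_start)
          to <- min(si + W, obs - 1L)
          if (from > to) integer(0) else seq.int(from, to)
        })))
        if (length(idx)) mult[idx - risk_start + 1L] <- mult[idx - risk_start + 1L] * truth[[drug]]
      }
      haz <- pmin(h0 * mult, 1)
      u <- runif(days_at_risk)
      t <- which(u < haz)
      if (length(t)) event_day[pid] <- risk_start + t[1L] - 1L
    }
  }

  cases <- which(!is.na(event_day))
  band <- sample.int(nrow(.age_bands), length(cases), replace = TRUE,
                     prob = .age_bands$prob)
  age <- .age_bands$lo[band] +
    floor(runif(length(cases)) * (.age_bands$hi[band] - .age_bands$lo[band] + 1L))
  events <- data.frame(
    patient_id = cases,
    index_date = event_day[cases],
    source = ifelse(runif(length(cases)) < config$death_fraction,
                    "death", "hospital"),
    age_years = as.integer(age),
    sex = ifelse(runif(length(cases)) < 0.536, "male", "female"),
    stringsAsFactors = FALSE
  )

  dispensings <- data.frame(patient_id = disp$patient_id,
                            drug_code = disp$drug_code,
                            dispense_date = disp$day,
                            stringsAsFactors = FALSE)
  rownames(dispensings) <- NULL
  structure(list(
    dispensings = dispensings,
    events = events,
    truth = data.frame(drug_code = names(truth), true_rr = unname(truth),
                       stringsAsFactors = FALSE),
    config = config
  ), class = "registry_sim")
}

#' @export
print.registry_sim <- function(x, ...) {
  cat("Synthetic registry (", x$config$country_label, "): ",
      nrow(x$dispensings), " dispensings, ",
      nrow(x$events), " index events among ",
      x$config$n_patients, " patients\n", sep = "")
  invisible(x)
}

#' Write / read a registry as tab-separated text
#'
#' The on-disk schema is the package's exchange format (and the schema
#' accepted for real register exports): `<label>_dispensing.tsv`
#' (patient_id, drug_code, dispense_date), `<label>_events.tsv`
#' (patient_id, index_date, source, age_years, sex) and, for simulated
#' registries, `<label>_truth.tsv` (drug_code, true_rr).
#'
#' @param x a `registry_sim` object.
#' @param dir output directory (created if needed).
#' @param label file-name prefix; defaults to the configured country label.
#' @return invisibly, the file paths written.
#' @export
write_registry <- function(x, dir, label = NULL) {
  stopifnot(inherits(x, "registry_sim"))
  label <- label %||% x$config$country_label
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(label, c("_dispensing.tsv", "_events.tsv",
                                          "_truth.tsv")))
  write.table(x$dispensings, paths[1], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(x$events, paths[2], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(x$truth, paths[3], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' @rdname write_registry
#' @param dir directory holding the files written by [write_registry()].
#' @export
read_registry <- function(dir, label) {
  disp <- read.delim(file.path(dir, paste0(label, "_dispensing.tsv")),
                     stringsAsFactors = FALSE)
  ev <- read.delim(file.path(dir, paste0(label, "_events.tsv")),
                   stringsAsFactors = FALSE)
  tf <- file.path(dir, paste0(label, "_truth.tsv"))
  truth <- if (file.exists(tf)) read.delim(tf, stringsAsFactors = FALSE) else NULL
  list(dispensings = disp, events = ev, truth = truth)
}
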