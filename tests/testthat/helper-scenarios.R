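# Shared fixtures: simulation scenarios, toy difference matrices, and the
# independent grid-search oracle for the penalized objective.

# Recovery / null-calibration scenario: 40 episodically dispensed drugs so
# the null is exactly exchangeable between windows; five drugs carry a
# planted triggering effect at prescription-drug-like prevalence and rate.
scenario_cfg <- function(planted = TRUE, seed = 1L, label = "A", rr = 2.0) {
  prof <- default_drug_profiles(40, acute_fraction = 1)
  prof$use_prevalence[1:5] <- 0.5
  prof$acute_rate[1:5] <- 6
  registry_config(
    n_patients = 8000, drug_profiles = prof, observation_days = 1095,
    baseline_hazard = 2.2e-4,
    planted_effects = if (planted) setNames(rep(rr, 5), sprintf("D%03d", 1:5))
                      else numeric(0),
    country_label = label, seed = seed
  )
}

# One chronically refilled drug whose refill period equals the spacing of
# the default case/control windows; no causal effect.
chronic_cfg <- function(seed = 1L, interval = 14L) {
  prof <- data.frame(drug_code = "C001", use_prevalence = 0.6,
                     mode = "chronic", acute_rate = 0,
                     refill_interval_days = as.integer(interval),
                     refill_jitter_days = 3L, stringsAsFactors = FALSE)
  registry_config(n_patients = 4000, drug_profiles = prof,
                  observation_days = 365, baseline_hazard = 1e-3,
                  seed = seed)
}

run_scenario <- function(config) {
  sim <- simulate_registry(config)
  ex <- suppressMessages(build_exposures(sim$dispensings, sim$events))
  list(sim = sim, exposures = ex, counts = discordant_counts(ex),
       D = difference_matrix(ex))
}

# single-drug difference matrix with given discordant counts
single_drug_D <- function(n10, n01, drug = "X01") {
  D <- matrix(c(rep(1L, n10), rep(-1L, n01)), ncol = 1,
              dimnames = list(NULL, drug))
  class(D) <- c("pair_diff", class(D))
  D
}

random_instance <- function(n, p, require_both_signs = FALSE) {
  repeat {
    D <- matrix(sample(c(-1L, 0L, 1L), n * p, replace = TRUE,
                       prob = c(0.3, 0.4, 0.3)), n, p,
                dimnames = list(NULL, sprintf("X%02d", seq_len(p))))
    D <- D[rowSums(D != 0L) > 0L, , drop = FALSE]
    if (nrow(D) < 2L) next
    if (require_both_signs &&
        !all(colSums(D > 0) > 0 & colSums(D < 0) > 0)) next
    class(D) <- c("pair_diff", class(D))
    return(D)
  }
}

# Exhaustive grid-search oracle for the (penalized) conditional objective:
# coarse grid over [-5, 5], then repeated local refinement halving the step.
# Independent of the package solver: the objective is summed pair by pair.
grid_objective <- function(B, D, lambda) {
  eta <- B %*% t(unclass(D))
  ll <- stats::plogis(as.vector(eta), log.p = TRUE)
  dim(ll) <- dim(eta)
  rowSums(ll) - lambda * rowSums(abs(B))
}

grid_optimum <- function(D, lambda = 0, lo = -5, hi = 5, final_step = 0.0025) {
  p <- ncol(D)
  step <- (hi - lo) / 20
  B <- as.matrix(expand.grid(rep(list(seq(lo, hi, by = step)), p)))
  obj <- grid_objective(B, D, lambda)
  best <- as.numeric(B[which.max(obj), ])
  value <- max(obj)
  while (step > final_step) {
    step <- step / 2
    B <- as.matrix(expand.grid(lapply(best, function(c) c + step * (-4:4))))
    obj <- grid_objective(B, D, lambda)
    best <- as.numeric(B[which.max(obj), ])
    value <- max(obj)
  }
  list(beta = best, objective = value)
}
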