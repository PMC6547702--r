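test_that("conditional log-likelihood matches per-pair summation", {
  D <- single_drug_D(6, 4)
  expect_equal(conditional_loglik(0, D), -10 * log(2))
  # beta -> +Inf on a single concordant-in-favour pair approaches 0 from below
  d1 <- single_drug_D(1, 0)
  expect_lt(conditional_loglik(50, d1), 0)
  expect_gt(conditional_loglik(50, d1), -1e-20)
  # random instance versus a direct per-pair loop
  set.seed(42)
  D <- random_instance(30, 3)
  beta <- c(0.4, -1.1, 0.25)
  direct <- 0
  for (i in seq_len(nrow(D)))
    direct <- direct - log(1 + exp(-sum(beta * D[i, ])))
  expect_equal(conditional_loglik(beta, D), direct, tolerance = 1e-12)
  expect_error(conditional_loglik(c(1, 2), D), "drug columns")
})

test_that("univariable discordant-pair estimator matches its closed form", {
  counts <- data.frame(drug_code = c("a", "b", "c"),
                       n10 = c(5L, 2195L, 256L), n01 = c(5L, 1515L, 42L))
  est <- univariable_estimate(counts)
  expect_equal(est$rr, c(1, 2195 / 1515, 256 / 42))
  expect_equal(est$rr[3], 6.095238, tolerance = 1e-6)
  expect_equal(est$ci_low[3], 4.398273, tolerance = 1e-6)
  expect_equal(est$ci_high[3], 8.446935, tolerance = 1e-6)
  expect_equal(est$se, sqrt(1 / counts$n10 + 1 / counts$n01))
  # zero cells are flagged, not fatal
  deg <- univariable_estimate(data.frame(n10 = c(3L, 0L), n01 = c(0L, 4L)))
  expect_true(all(deg$degenerate))
  expect_identical(deg$rr, c(Inf, 0))
  expect_true(all(is.na(deg$ci_low)))
  expect_error(univariable_estimate(data.frame(n10 = 0L, n01 = 0L)),
               "positive")
})

test_that("joint MLE reduces to the closed form for single and separable drugs", {
  D <- single_drug_D(97, 29)
  fit <- cclogit(D)
  expect_equal(unname(coef(fit)), log(97 / 29), tolerance = 1e-6)
  expect_equal(unname(fit$se), sqrt(1 / 97 + 1 / 29), tolerance = 1e-6)
  # two drugs never discordant in the same pair: joint fit = per-drug fits
  D2 <- matrix(0L, 60, 2, dimnames = list(NULL, c("A", "B")))
  D2[1:30, 1] <- rep(c(1L, -1L), c(20, 10))
  D2[31:60, 2] <- rep(c(1L, -1L), c(12, 18))
  class(D2) <- c("pair_diff", class(D2))
  fit2 <- cclogit(D2)
  expect_equal(unname(coef(fit2)), c(log(20 / 10), log(12 / 18)),
               tolerance = 1e-6)
})

test_that("joint MLE agrees with survival::clogit on expanded pairs", {
  library(survival)
  set.seed(5)
  D <- random_instance(300, 4, require_both_signs = TRUE)
  fit <- cclogit(D)
  case <- pmax(unclass(D), 0); ctrl <- pmax(-unclass(D), 0)
  dat <- data.frame(y = rep(c(1, 0), each = nrow(D)),
                    rbind(case, ctrl), id = rep(seq_len(nrow(D)), 2))
  f <- as.formula(paste("y ~", paste(colnames(D), collapse = "+"),
                        "+ strata(id)"))
  sf <- survival::clogit(f, data = dat)
  expect_equal(unname(coef(fit)), unname(coef(sf)), tolerance = 1e-7)
  expect_equal(unname(fit$se), unname(sqrt(diag(vcov(sf)))), tolerance = 1e-7)
  expect_equal(fit$loglik, sf$loglik[2], tolerance = 1e-8)
})

test_that("complete separation is flagged per drug, not fatal", {
  D <- matrix(0L, 20, 2, dimnames = list(NULL, c("sep", "ok")))
  D[1:8, 1] <- 1L                      # single-signed column
  D[9:20, 2] <- rep(c(1L, -1L), 6)
  class(D) <- c("pair_diff", class(D))
  fit <- cclogit(D)
  expect_true(fit$degenerate[["sep"]])
  expect_identical(unname(coef(fit)[["sep"]]), Inf)
  expect_true(is.na(fit$se[["sep"]]))
  expect_equal(unname(coef(fit)[["ok"]]), 0, tolerance = 1e-8)
})

test_that("lambda_max is the score at the origin and brackets the null model", {
  D <- matrix(0L, 12, 2, dimnames = list(NULL, c("A", "B")))
  D[, 1] <- c(rep(1L, 11), -1L)  # column sum 10
  D[, 2] <- rep(c(1L, -1L), 6)   # column sum 0
  class(D) <- c("pair_diff", class(D))
  expect_equal(lambda_max(D), 5)
  set.seed(9)
  R <- random_instance(40, 3, require_both_signs = TRUE)
  lmax <- lambda_max(R)
  expect_true(all(coef(cclogit_l1(R, lmax)) == 0))
  expect_true(any(coef(cclogit_l1(R, 0.99 * lmax)) != 0))
})

test_that("penalty-free limit, shrinkage monotonicity and sign equivariance", {
  set.seed(13)
  D <- random_instance(80, 3, require_both_signs = TRUE)
  mle <- cclogit(D)
  l0 <- cclogit_l1(D, 0)
  expect_lt(max(abs(coef(l0) - coef(mle))), 1e-5)
  lmax <- lambda_max(D)
  norms <- vapply(seq(0, 1.05, by = 0.05) * lmax,
                  function(l) sum(abs(coef(cclogit_l1(D, l)))), numeric(1))
  expect_true(all(diff(norms) <= 1e-8))
  # negating a column negates its coefficient
  Dn <- unclass(D); Dn[, 2] <- -Dn[, 2]
  class(Dn) <- c("pair_diff", class(Dn))
  lam <- 0.3 * lmax
  b1 <- coef(cclogit_l1(D, lam)); b2 <- coef(cclogit_l1(Dn, lam))
  expect_equal(unname(b1[2]), -unname(b2[2]), tolerance = 1e-7)
  expect_equal(unname(b1[-2]), unname(b2[-2]), tolerance = 1e-7)
  expect_equal(unname(coef(cclogit(Dn))[2]), -unname(coef(cclogit(D))[2]),
               tolerance = 1e-7)
  # stationarity conditions hold at the reported solution
  expect_lt(cclogit_l1(D, lam)$kkt_gap, 1e-5)
})

test_that("penalized solutions match glmnet on the sign-flipped encoding", {
  set.seed(5)
  D <- random_instance(300, 4, require_both_signs = TRUE)
  s <- sample(c(-1, 1), nrow(D), replace = TRUE)
  X <- unclass(D) * s
  y <- (s + 1) / 2
  for (frac in c(0.6, 0.3, 0.1)) {
    lam <- frac * lambda_max(D)
    gf <- glmnet::glmnet(X, y, family = "binomial", alpha = 1,
                         intercept = FALSE, standardize = FALSE,
                         lambda = lam / nrow(D), thresh = 1e-12)
    expect_equal(unname(coef(cclogit_l1(D, lam))), as.numeric(gf$beta),
                 tolerance = 1e-6)
  }
})

test_that("cross-validated penalty choice is seeded and sane", {
  set.seed(31)
  cfg <- scenario_cfg(TRUE, seed = 3)
  out <- run_scenario(cfg)
  l1 <- cv_select_lambda(out$D, seed = 4)
  l2 <- cv_select_lambda(out$D, seed = 4)
  expect_identical(as.numeric(l1), as.numeric(l2))
  expect_lt(as.numeric(l1), lambda_max(out$D)) # planted signal enters
  # degenerate path: every column score zero at the origin
  Dz <- matrix(c(1L, -1L, 1L, -1L), 4, 1, dimnames = list(NULL, "A"))
  class(Dz) <- c("pair_diff", class(Dz))
  expect_warning(lz <- cv_select_lambda(Dz, solver_config(cv_folds = 2)),
                 "degenerate")
  expect_identical(as.numeric(lz), 0)
})
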