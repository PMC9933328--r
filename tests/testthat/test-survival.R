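# builds a mortality table directly from expected counts or given cumulative
# death vectors
mkTable <- function(times, cum, n = 100, strain = "s1", cond = "treated",
                    rep = 1) {
  MortalityTable(data.frame(strain = strain, replicate = rep,
                            condition = cond, time_h = times,
                            cum_dead = cum, n_start = n, n_injured = 0L))
}

test_that("probit MLE recovers parameters from exact expected frequencies", {
  a <- -7.2; b <- 6
  times <- c(8, 10, 12, 14, 16, 18, 20, 24, 28)
  n <- 1e6  # expected counts at large n make the MLE land on the truth
  cum <- round(n * pnorm(a + b * log10(times)))
  fit <- fitProbit(mkTable(times, cum, n), "s1")
  expect_true(fit@converged)
  expect_equal(fit@lt50, 10^(1.2), tolerance = 1e-4)
  expect_equal(fit@intercept, a, tolerance = 1e-3)
  expect_equal(fit@slope, b, tolerance = 1e-3)
  # closed-form identity LT50 = 10^(-a/b)
  expect_equal(fit@lt50, 10^(-fit@intercept / fit@slope))
  # the Finney compatibility mode agrees on exact data
  fin <- fitProbit(mkTable(times, cum, n), "s1", mode = "finney")
  expect_equal(fin@lt50, 10^(1.2), tolerance = 5e-3)
})

test_that("symmetric two-checkpoint data give LT50 at the midpoint", {
  # 50% dead at t = 10 with symmetric flanks on the log scale
  times <- c(10 / 1.3, 10, 10 * 1.3)
  cum <- c(20, 50, 80)
  fit <- fitProbit(mkTable(times, cum, 100), "s1")
  expect_equal(fit@lt50, 10, tolerance = 0.02)
})

test_that("non-identifiable mortality is flagged, never silently fitted", {
  expect_warning(f0 <- fitProbit(mkTable(c(10, 20), c(0, 0), 50), "s1"),
                 "non-identifiable")
  expect_false(f0@converged)
  expect_true(is.na(lt50(f0)))
  expect_warning(f1 <- fitProbit(mkTable(c(10, 20), c(50, 50), 50), "s1"),
                 "non-identifiable")
  expect_false(f1@converged)
})

test_that("per-replicate fits are available for diagnostics", {
  sim <- genMortality(simConfig(seed = 2, nStrains = 1, nFliesPerRep = 200))
  fits <- suppressWarnings(fitProbit(sim$table, "strain001", pool = FALSE))
  expect_length(fits, 3)
  expect_true(all(vapply(fits, function(f) is(f, "ProbitFit"), logical(1))))
})

test_that("exclusion rule uses strict 10% and is idempotent", {
  mk <- function(strain, ctlDead) {
    rbind(data.frame(strain = strain, replicate = 1, condition = "treated",
                     time_h = c(10, 20), cum_dead = c(30, 90), n_start = 100,
                     n_injured = 0),
          data.frame(strain = strain, replicate = 1, condition = "control",
                     time_h = c(10, 20), cum_dead = c(0, ctlDead),
                     n_start = 100, n_injured = 0))
  }
  tbl <- MortalityTable(rbind(mk("at_threshold", 10), mk("above", 11),
                              mk("clean", 0)))
  ex <- excludeStrains(tbl)
  expect_setequal(unique(mortalityData(ex$retained)$strain),
                  c("at_threshold", "clean"))
  expect_equal(ex$report$excluded[ex$report$strain == "above"], TRUE)
  # idempotent
  ex2 <- excludeStrains(ex$retained)
  expect_equal(mortalityData(ex2$retained), mortalityData(ex$retained))
  # no control data -> excluded with reason
  tr <- mortalityData(tbl)
  noCtl <- MortalityTable(tr[tr$strain == "clean" & tr$condition == "treated", ])
  exn <- excludeStrains(noCtl)
  expect_equal(exn$report$reason, "no control data")
  expect_equal(nrow(mortalityData(exn$retained)), 0)
})

test_that("the 74-strain exclusion pattern leaves 59 strains", {
  mk <- function(strain, ctlDead) {
    rbind(data.frame(strain = strain, replicate = 1:3, condition = "treated",
                     time_h = 20, cum_dead = 10, n_start = 15, n_injured = 0),
          data.frame(strain = strain, replicate = 1:3, condition = "control",
                     time_h = 20, cum_dead = ctlDead, n_start = 15,
                     n_injured = 0))
  }
  rows <- do.call(rbind, c(
    lapply(1:59, function(i) mk(sprintf("ok%02d", i), 0L)),
    lapply(1:15, function(i) mk(sprintf("bad%02d", i), 2L))))  # 2/15 > 10%
  ex <- excludeStrains(MortalityTable(rows))
  expect_equal(sum(!ex$report$excluded), 59)
  expect_equal(sum(ex$report$excluded), 15)
})

test_that("observed LT100 averages replicate full-mortality times", {
  # all replicates fully dead at 24 h -> 24
  rows <- do.call(rbind, lapply(1:3, function(r) {
    data.frame(strain = "s1", replicate = r, condition = "treated",
               time_h = c(16, 20, 24, 28),
               cum_dead = c(5, 10, 15, 15), n_start = 15, n_injured = 0)
  }))
  expect_equal(observedLT100(MortalityTable(rows), "s1"), 24)
  # full at 20, 24, 28 -> mean 24
  rows2 <- do.call(rbind, Map(function(r, tfull) {
    data.frame(strain = "s1", replicate = r, condition = "treated",
               time_h = c(16, 20, 24, 28),
               cum_dead = ifelse(c(16, 20, 24, 28) >= tfull, 15, 5),
               n_start = 15, n_injured = 0)
  }, 1:3, c(20, 24, 28)))
  expect_equal(observedLT100(MortalityTable(rows2), "s1"), 24)
  # a censored replicate makes LT100 undefined
  rows3 <- rows2
  rows3$cum_dead[rows3$replicate == 3] <- 5
  out <- observedLT100(MortalityTable(rows3), "s1")
  expect_true(is.na(out))
  expect_true(attr(out, "censored"))
})

test_that("rank correlation matches an exact permutation oracle", {
  expect_equal(rankCorrelation(1:8, (1:8)^3, alternative = "two.sided")$rho, 1)
  expect_equal(rankCorrelation(1:8, -(1:8), alternative = "two.sided")$rho, -1)
  expect_error(rankCorrelation(rep(1, 5), 1:5), "constant")
  set.seed(4)
  x <- rnorm(6); y <- rnorm(6)
  got <- rankCorrelation(x, y, alternative = "greater")
  # oracle: enumerate all 720 permutations of y
  rhoOf <- function(y) cor(rank(x), rank(y))
  perms <- gtools_permutations <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in gtools_permutations(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  rhos <- vapply(perms(y), rhoOf, numeric(1))
  pPerm <- mean(rhos >= rhoOf(y) - 1e-12)
  expect_equal(got$p, pPerm, tolerance = 1e-6)
  expect_equal(got$rho, rhoOf(y), tolerance = 1e-12)
})

test_that("climate ANOVA handles degenerate and m = 2 cases", {
  set.seed(1)
  meta <- data.frame(climate = rep(c("Bsk", "Csa"), each = 10),
                     LT100 = c(rnorm(10, 26), rnorm(10, 22)))
  out <- climateAnova(meta)
  # with two groups the Tukey adjusted p equals the ANOVA p
  expect_equal(out$tukey[["p adj"]], out$p, tolerance = 1e-3)
  degen <- data.frame(climate = rep(c("A", "B"), each = 3), LT100 = 5)
  res <- climateAnova(degen)
  expect_true(res$degenerate)
  expect_true(is.na(res$F))
  expect_true(is.na(res$p))
  single <- data.frame(climate = c("A", "A", "B", "B", "C"),
                       LT100 = c(1, 2, 3, 4, 5))
  expect_warning(climateAnova(single), "singleton")
})

test_that("climate ANOVA flags a shifted group in most replications", {
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    meta <- data.frame(climate = rep(LETTERS[1:5], each = 50),
                       LT100 = rnorm(250, 22) + rep(c(3, 0, 0, 0, 0), each = 50))
    tk <- climateAnova(meta)$tukey
    flagged <- rownames(tk)[tk[["p adj"]] < 0.05]
    withA <- grepl("A", flagged)
    all(withA) && sum(withA) == 4
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("VIF pruning matches a normal-equations oracle and its invariants", {
  set.seed(7)
  X <- cbind(a = rnorm(50), b = rnorm(50), c = rnorm(50))
  X <- cbind(X, d = X[, "a"] + 0.5 * X[, "b"] + rnorm(50, 0, 0.3))
  out <- vifPrune(X, threshold = 5)
  # oracle VIF from the correlation-matrix inverse (diagonal elements)
  oracleVif <- function(M) diag(solve(cor(M)))
  expect_equal(unname(out$vif),
               unname(oracleVif(X[, out$retained]))[seq_along(out$vif)],
               tolerance = 1e-8)
  expect_true(all(out$vif < 5))
  # orthogonal covariates (orthogonal polynomials are also centred,
  # so the regressions see exactly zero correlation): all VIFs 1
  Q <- poly(1:20, 4)
  colnames(Q) <- letters[1:4]
  o2 <- vifPrune(Q)
  expect_equal(unname(o2$vif), rep(1, 4), tolerance = 1e-8)
  expect_equal(nrow(o2$removed), 0)
  # duplicated column: exactly one copy removed first, as infinite VIF
  X3 <- cbind(a = rnorm(30), b = rnorm(30))
  X3 <- cbind(X3, a2 = X3[, "a"])
  o3 <- vifPrune(X3)
  expect_equal(o3$removed$variable[1], "a")
  expect_true(is.infinite(o3$removed$vif[1]))
  expect_equal(sum(c("a", "a2") %in% o3$retained), 1)
})

test_that("environment model identifies planted structure", {
  set.seed(5)
  meta <- data.frame(altitude = runif(60, 0, 1000), evaporation = rnorm(60))
  meta$LT100 <- meta$altitude
  out <- suppressWarnings(environmentModel(meta))
  expect_gt(out$adj_r_squared, 0.999)
  expect_lt(out$coefficients["altitude", "Pr(>|t|)"], 1e-20)
  # pure-noise response: adjusted R^2 is non-positive in expectation
  adjr <- vapply(1:500, function(s) {
    set.seed(s)
    meta$LT100 <- rnorm(60)
    environmentModel(meta)$adj_r_squared
  }, numeric(1))
  expect_lt(mean(adjr), 0.005)
  # planted interaction at 1 SD: detected in >= 90% of seeds
  hits <- vapply(1:50, function(s) {
    set.seed(s)
    alt <- rnorm(60); ev <- rnorm(60)
    meta <- data.frame(altitude = alt, evaporation = ev,
                       LT100 = alt * ev + rnorm(60))
    environmentModel(meta)$coefficients["altitude:evaporation",
                                        "Pr(>|t|)"] < 0.01
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("LT50 bias vanishes as flies per replicate grow", {
  biasAt <- function(n) {
    sim <- genMortality(simConfig(seed = 13, nStrains = 8, nFliesPerRep = n,
                                  trueLT50 = c(14, 26)))
    est <- vapply(sim$truth$strain, function(s) {
      lt50(suppressWarnings(fitProbit(sim$table, s)))
    }, numeric(1))
    mean(abs(est - sim$truth$lt50_true), na.rm = TRUE)
  }
  b <- vapply(c(20, 100, 500), biasAt, numeric(1))
  expect_lt(b[3], b[1])
  expect_lt(b[3], 0.5)
})
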