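test_that("water content and loss follow their defining arithmetic", {
  wc <- waterContent(1.0, 0.5)
  expect_equal(wc$absolute, 0.5)
  expect_equal(wc$fraction, 0.5)
  expect_equal(waterContent(2, 2)$fraction, 0)
  expect_error(waterContent(1, 1.1), "exceeds")
  expect_equal(waterLossPct(1.0, 0.95, 0.5), 10)
  expect_equal(waterLossPct(1.0, 1.0, 0.5), 0)
  expect_error(waterLossPct(1, 0.9, 0), "waterFraction")
  # total-mass denominator mode
  expect_equal(waterLossPct(1.0, 0.9, 1), 10)
})

test_that("simulated 45% vs 50% water groups are recovered and separate", {
  p <- genPhysChc(simConfig(seed = 12))
  g <- p$gravimetric
  wc <- waterContent(g$wet_mass, g$dry_mass)
  m <- tapply(wc$fraction, g$phenotype, mean)
  expect_lt(abs(m[["tolerant"]] - 0.45), 0.01)
  expect_lt(abs(m[["sensitive"]] - 0.50), 0.01)
  rt <- rankTest(wc$fraction[g$phenotype == "sensitive"],
                 wc$fraction[g$phenotype == "tolerant"])
  expect_lt(rt$p, 1e-6)
  # 10% vs 15% water loss separates by the rank test at study sizes
  loss <- waterLossPct(g$pre_mass, g$post_mass,
                       ifelse(g$phenotype == "tolerant", 0.45, 0.50))
  lm <- tapply(loss, g$phenotype, mean)
  expect_lt(abs(lm[["tolerant"]] - 10), 1.5)
  expect_lt(abs(lm[["sensitive"]] - 15), 1.5)
  expect_lt(rankTest(loss[g$phenotype == "sensitive"],
                     loss[g$phenotype == "tolerant"])$p, 1e-6)
})

test_that("rank test uses exact enumeration for small untied samples", {
  # complete separation at n = 5 vs 5: two-sided p = 2 / choose(10, 5)
  out <- rankTest(1:5, 6:10)
  expect_equal(out$p, 2 / choose(10, 5), tolerance = 1e-12)
  expect_equal(rankTest(c(2, 2, 2), c(2, 2, 2))$p, 1)
  big <- rankTest(rnorm(30), rnorm(30))
  expect_true(big$p > 0 && big$p <= 1)
})

test_that("rank-test p-values are calibrated under the null", {
  set.seed(33)
  ps <- vapply(1:1000, function(i) rankTest(rnorm(20), rnorm(20))$p,
               numeric(1))
  rej <- mean(ps < 0.05)
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.07)
})

test_that("Yeo-Johnson transform honours its closed forms", {
  x <- c(-3.2, -1, 0, 0.5, 4)
  expect_equal(yeoJohnson(x, 1)$y, x)
  expect_equal(yeoJohnson(0, 0.37)$y, 0)
  expect_equal(yeoJohnson(exp(1) - 1, 0)$y, 1)
  expect_equal(yeoJohnson(-(exp(1) - 1), 2)$y, -1)
  # strictly increasing for every lambda
  xs <- sort(rnorm(50, 0, 3))
  for (l in c(-1, 0, 0.5, 1, 2, 3)) {
    expect_true(all(diff(yeoJohnson(xs, l)$y) > 0))
  }
  # fixed-lambda values agree with the car implementation
  expect_equal(yeoJohnson(x, 0.4)$y, unname(car::yjPower(x, 0.4)),
               tolerance = 1e-10)
  # ML lambda approximately inverts a planted transformation
  set.seed(2)
  z <- rnorm(400)
  skewed <- exp(z / 2) - 1  # YJ with small lambda renormalises this
  ml <- yeoJohnson(skewed, "ml")
  expect_lt(ml$lambda, 0.6)
  expect_lt(abs(ml$lambda -
                  car::powerTransform(skewed, family = "yjPower")$lambda),
            0.02)
})

test_that("interaction LRT detects planted interactions and not their absence", {
  p1 <- genPhysChc(simConfig(seed = 3),
                   respEffects = list(base = 4, stress = -0.6,
                                      phenotype = 0.3, interaction = 0.8))
  out1 <- interactionLRT(p1$respirometry)
  expect_lt(out1$p, 1e-6)
  expect_equal(out1$decision, "interaction")
  expect_gte(out1$statistic, 0)
  p0 <- genPhysChc(simConfig(seed = 3),
                   respEffects = list(base = 4, stress = -0.6,
                                      phenotype = 0.3, interaction = 0))
  out0 <- interactionLRT(p0$respirometry)
  expect_gt(out0$p, 0.001)
  # invariant to strain relabelling
  d <- p1$respirometry
  d$strain <- factor(d$strain, labels = sample(LETTERS[1:6]))
  out2 <- interactionLRT(d)
  expect_equal(out2$statistic, out1$statistic, tolerance = 1e-6)
})

test_that("single-strain LRT equals the nested fixed-effects LRT", {
  p <- genPhysChc(simConfig(seed = 6))
  d <- p$respirometry[p$respirometry$strain %in% c("T01", "S01"), ]
  d1 <- d[d$strain == "T01", ]
  d1$phenotype <- rep(c("tolerant", "sensitive"),
                      length.out = nrow(d1))  # synthetic 2-level factor
  out <- interactionLRT(d1, transform = FALSE)
  expect_equal(out$backend, "lm")
  sub <- d1[d1$minute >= 60 & d1$minute <= 119, ]
  m0 <- lm(co2_rate ~ condition + phenotype, sub)
  m1 <- lm(co2_rate ~ condition * phenotype, sub)
  want <- 2 * (as.numeric(logLik(m1)) - as.numeric(logLik(m0)))
  expect_equal(out$statistic, want, tolerance = 1e-8)
})

test_that("retention indices interpolate the alkane ladder linearly", {
  set.seed(4)
  rts <- cumsum(runif(24, 0.5, 1.5))
  ladder <- data.frame(carbon = 7:30, rt_min = rts)
  # the Cn alkane itself indexes 100 n
  expect_equal(lri(ladder$rt_min, ladder), 100 * (7:30))
  # midpoint between C22 and C23 -> 2250
  mid <- (ladder$rt_min[ladder$carbon == 22] +
            ladder$rt_min[ladder$carbon == 23]) / 2
  expect_equal(lri(mid, ladder), 2250)
  # random peaks vs the formula coded directly
  for (i in 1:20) {
    t0 <- runif(1, min(rts), max(rts))
    n <- max(which(rts <= t0))
    want <- 100 * (ladder$carbon[n] + (t0 - rts[n]) / (rts[n + 1] - rts[n]))
    expect_equal(lri(t0, ladder), want, tolerance = 1e-10)
  }
  expect_warning(out <- lri(max(rts) + 1, ladder), "outside")
  expect_true(is.na(out))
})

test_that("CHC quantification follows the internal-standard arithmetic", {
  peaks <- data.frame(compound = c("IS", "c1", "c2"),
                      area = c(1000, 1000, 500),
                      is_internal_standard = c(TRUE, FALSE, FALSE))
  out <- chcAmounts(peaks)
  # area equal to the IS: 200 ng / 5 flies = 40 ng per insect
  expect_equal(out$amount_ng_per_insect[out$compound == "c1"], 40)
  expect_equal(sum(out$relative_pct), 100, tolerance = 1e-9)
  expect_error(chcAmounts(peaks[-1, ]), "internal-standard")
  set.seed(5)
  for (i in 1:10) {
    a <- runif(4, 10, 2000)
    pk <- data.frame(compound = c("IS", "x", "y", "z"), area = a,
                     is_internal_standard = c(TRUE, FALSE, FALSE, FALSE))
    got <- chcAmounts(pk, isMass = 200, fliesPerSample = 5)
    expect_equal(got$amount_ng_per_insect, a[-1] / a[1] * 40)
  }
})

test_that("balance ratio is bounded and takes its closed-form values", {
  expect_equal(balanceRatio(c(3, 3), c("desaturated", "saturated")), 0)
  expect_equal(balanceRatio(c(3, 0), c("desaturated", "saturated")), 1)
  expect_equal(balanceRatio(c(0, 2), c("desaturated", "saturated")), -1)
  expect_error(balanceRatio(c(0, 0), c("desaturated", "saturated")),
               "undefined")
  set.seed(7)
  for (i in 1:20) {
    amt <- runif(13)
    cls <- sample(c("saturated", "desaturated"), 13, replace = TRUE,
                  prob = c(0.3, 0.7))
    if (all(cls == cls[1])) next
    b <- balanceRatio(amt, cls)
    expect_true(b >= -1 && b <= 1)
    D <- sum(amt[cls == "desaturated"]); S <- sum(amt[cls == "saturated"])
    expect_equal(b, (D - S) / (D + S))
  }
})

test_that("composition PCA matches the eigen-decomposition oracle", {
  set.seed(8)
  X <- matrix(rexp(20 * 6), 20, 6)
  colnames(X) <- paste0("c", 1:6)
  out <- chcPCA(X, logTransform = TRUE)
  expect_equal(sum(out$var_explained), 100, tolerance = 1e-9)
  ev <- eigen(cov(log(X + out$offset)))$values
  expect_equal(out$var_explained, 100 * ev / sum(ev), tolerance = 1e-8)
  # data on a line: PC1 explains everything
  line <- cbind(1:10, 2 * (1:10))
  colnames(line) <- c("a", "b")
  outL <- chcPCA(line, logTransform = FALSE)
  expect_equal(outL$var_explained[1], 100, tolerance = 1e-9)
  expect_warning(chcPCA(cbind(a = rep(2, 5), b = rnorm(5), c = rnorm(5)),
                        logTransform = FALSE), "constant")
})

test_that("ddCt fold changes follow the defining powers of two", {
  expect_equal(ddct(20, 15, 20, 15), 1)
  expect_equal(ddct(19, 15, 20, 15), 2)
  expect_equal(ddct(20, 15, 22, 15), 4)
  expect_error(ddct(NA, 15, 20, 15), "finite")
})
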