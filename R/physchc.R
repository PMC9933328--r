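#' Water content from wet and dry mass
#'
#' @param wet,dry masses (mg), vectorised; `dry > wet` is an error.
#' @return list(absolute = wet - dry in mg, fraction = (wet - dry)/wet).
#' @examples
#' waterContent(1.0, 0.5)
#' @export
waterContent <- function(wet, dry) {
  if (any(dry > wet)) stop("dry mass exceeds wet mass")
  list(absolute = wet - dry, fraction = (wet - dry) / wet)
}

#' Water loss as a percentage of water content
#'
#' `100 * (pre - post) / (waterFraction * pre)`: the mass lost under stress
#' is attributed to water, and expressed relative to the water content
#' implied by the group-level water fraction (water content is measured on
#' different flies than the loss assay, so a group mean is the denominator;
#' pass `waterFraction = 1` for a total-mass denominator).
#'
#' @param pre,post masses before/after stress (mg).
#' @param waterFraction water content as a fraction of body mass, in (0, 1].
#' @return Percent of water content lost.
#' @examples
#' waterLossPct(1.0, 0.95, 0.5)  # 10
#' @export
waterLossPct <- function(pre, post, waterFraction) {
  stopifnot(all(waterFraction > 0), all(waterFraction <= 1))
  if (any(pre <= 0)) stop("pre-stress mass must be positive")
  100 * (pre - post) / (waterFraction * pre)
}

#' Two-sample rank test
#'
#' Wilcoxon rank-sum (Mann-Whitney) test for two independent groups: exact
#' enumeration when the combined sample is small and untied, normal
#' approximation with tie correction otherwise. The study's group
#' comparisons are between independent strains, so the rank-sum form is the
#' default; `paired = TRUE` gives the signed-rank form.
#'
#' @param a,b numeric vectors (non-empty).
#' @param paired paired (signed-rank) mode.
#' @param exactMax use exact enumeration when `length(a) + length(b) <=`
#'   this and there are no ties.
#' @return list(W, p).
#' @examples
#' rankTest(1:5, 6:10)
#' @export
rankTest <- function(a, b, paired = FALSE, exactMax = 12L) {
  stopifnot(length(a) >= 1, length(b) >= 1)
  if (length(unique(c(a, b))) == 1L) return(list(W = NA_real_, p = 1))
  exact <- (length(a) + length(b) <= exactMax) &&
    !anyDuplicated(c(a, b)) && !paired
  wt <- suppressWarnings(
    wilcox.test(a, b, paired = paired, exact = exact, correct = !exact))
  list(W = unname(wt$statistic), p = wt$p.value)
}

#' Yeo-Johnson power transform
#'
#' Piecewise power transform handling both signs:
#' for `x >= 0`, `((x+1)^l - 1)/l` (or `log(x+1)` at `l = 0`); for `x < 0`,
#' `-(((-x+1)^(2-l) - 1)/(2-l))` (or `-log(-x+1)` at `l = 2`). With
#' `lambda = "ml"` the exponent is chosen by profile maximum likelihood
#' (normal likelihood with the log-Jacobian) on a grid with golden-section
#' refinement. The transform is strictly increasing in x for every lambda,
#' and lambda = 1 is the identity.
#'
#' @param x finite numeric vector.
#' @param lambda numeric exponent, or `"ml"`.
#' @return list(y = transformed values, lambda = exponent used).
#' @examples
#' yeoJohnson(c(-2, 0, 3), lambda = 1)$y
#' @export
yeoJohnson <- function(x, lambda = "ml") {
  stopifnot(all(is.finite(x)))
  tf <- function(x, l) {
    y <- numeric(length(x))
    pos <- x >= 0
    y[pos] <- if (abs(l) < 1e-12) log1p(x[pos]) else ((x[pos] + 1)^l - 1) / l
    y[!pos] <- if (abs(l - 2) < 1e-12) -log1p(-x[!pos]) else
      -(((-x[!pos] + 1)^(2 - l)) - 1) / (2 - l)
    y
  }
  if (is.numeric(lambda)) return(list(y = tf(x, lambda), lambda = lambda))
  stopifnot(identical(lambda, "ml"))
  n <- length(x)
  negLogLik <- function(l) {
    y <- tf(x, l)
    s2 <- mean((y - mean(y))^2)
    if (s2 <= 0) return(Inf)
    n / 2 * log(s2) - (l - 1) * sum(sign(x) * log1p(abs(x)))
  }
  grid <- seq(-2, 3, by = 0.1)
  vals <- vapply(grid, negLogLik, numeric(1))
  j <- which.min(vals)
  lo <- grid[max(1, j - 1)]; hi <- grid[min(length(grid), j + 1)]
  opt <- optimize(negLogLik, c(lo, hi), tol = 1e-8)  # golden-section search
  list(y = tf(x, opt$minimum), lambda = opt$minimum)
}

#' Likelihood-ratio test for a condition x phenotype interaction
#'
#' Fits nested linear mixed models of the (transformed) respiration rate by
#' maximum likelihood (not REML) with random intercepts for strain and for
#' replicate within strain: `y ~ condition + phenotype + (1|strain/replicate)`
#' against `y ~ condition * phenotype + (1|strain/replicate)`, and compares
#' them with `LRT = 2 (logLik_full - logLik_reduced)` on 1 df. Only readings
#' inside the stable `window` (minutes, inclusive) enter the fit — flies
#' need about an hour to settle, so the second hour is the default. With a
#' single strain the grouping is degenerate and the models fall back to
#' fixed-effects least squares (flagged in the result); non-convergence is
#' flagged, never silent.
#'
#' @param data data.frame with `condition`, `phenotype`, `strain`,
#'   `replicate`, `minute` (optional if `window = NULL`) and the response.
#' @param response response column (default `"co2_rate"`).
#' @param window minutes kept, inclusive (default `c(60, 119)`, the second
#'   hour); `NULL` keeps everything.
#' @param transform apply [yeoJohnson()] with ML lambda first (default
#'   TRUE, as in the study).
#' @param alpha decision level (default 0.05).
#' @return list(statistic, df, p, decision, lambda, backend, converged,
#'   singular). A singular (boundary) random-effect fit is recorded, not an
#'   error: it is expected when a variance component is truly near zero.
#' @export
interactionLRT <- function(data, response = "co2_rate", window = c(60, 119),
                           transform = TRUE, alpha = 0.05) {
  need <- c("condition", "phenotype", "strain", "replicate", response)
  stopifnot(all(need %in% names(data)))
  d <- data
  if (!is.null(window)) {
    stopifnot("minute" %in% names(d))
    d <- d[d$minute >= window[1] & d$minute <= window[2], ]
  }
  lambda <- NA_real_
  if (transform) {
    yj <- yeoJohnson(d[[response]], "ml")
    d$.y <- yj$y
    lambda <- yj$lambda
  } else {
    d$.y <- d[[response]]
  }
  d$strain <- factor(d$strain)
  d$replicate <- factor(d$replicate)
  singleStrain <- nlevels(d$strain) < 2
  if (singleStrain) {
    m0 <- lm(.y ~ condition + phenotype, data = d)
    m1 <- lm(.y ~ condition * phenotype, data = d)
    stat <- max(0, 2 * (as.numeric(logLik(m1)) - as.numeric(logLik(m0))))
    conv <- TRUE
    backend <- "lm"
  } else {
    fit <- function(fml) {
      ok <- TRUE
      m <- withCallingHandlers(
        lme4::lmer(fml, data = d, REML = FALSE),
        warning = function(w) {
          if (grepl("converge", conditionMessage(w))) ok <<- FALSE
          invokeRestart("muffleWarning")
        },
        message = function(m) invokeRestart("muffleMessage"))
      list(m = m, ok = ok)
    }
    f0 <- fit(.y ~ condition + phenotype + (1 | strain / replicate))
    f1 <- fit(.y ~ condition * phenotype + (1 | strain / replicate))
    conv <- f0$ok && f1$ok
    if (!conv) warning("mixed-model fit did not converge; LRT flagged")
    singular <- lme4::isSingular(f0$m) || lme4::isSingular(f1$m)
    stat <- max(0, 2 * (as.numeric(logLik(f1$m)) - as.numeric(logLik(f0$m))))
    backend <- "lmer"
  }
  if (singleStrain) singular <- FALSE
  p <- pchisq(stat, df = 1, lower.tail = FALSE)
  list(statistic = stat, df = 1L, p = p,
       decision = if (p < alpha) "interaction" else "additive",
       lambda = lambda, backend = backend, converged = conv,
       singular = singular)
}

#' Linear retention index against an n-alkane ladder
#'
#' For a peak eluting between the Cn and Cn+1 alkanes:
#' `LRI = 100 (n + (t - t_n) / (t_{n+1} - t_n))`. A peak outside the ladder
#' range is undefined (`NA`, with a warning).
#'
#' @param rt peak retention time(s), minutes.
#' @param ladder data.frame with `carbon` and `rt_min` (strictly increasing
#'   in carbon number).
#' @return LRI value(s); the Cn alkane itself indexes exactly 100n.
#' @examples
#' ladder <- data.frame(carbon = 7:30, rt_min = seq(2, 25, length.out = 24))
#' lri(ladder$rt_min[17], ladder)  # 2300
#' @export
lri <- function(rt, ladder) {
  stopifnot(all(c("carbon", "rt_min") %in% names(ladder)))
  ladder <- ladder[order(ladder$carbon), ]
  stopifnot(all(diff(ladder$rt_min) > 0))
  vapply(rt, function(t) {
    if (t < min(ladder$rt_min) || t > max(ladder$rt_min)) {
      warning("retention time outside the alkane ladder; LRI undefined")
      return(NA_real_)
    }
    i <- findInterval(t, ladder$rt_min, rightmost.closed = TRUE)
    100 * (ladder$carbon[i] +
             (t - ladder$rt_min[i]) /
               (ladder$rt_min[i + 1] - ladder$rt_min[i]))
  }, numeric(1))
}

#' Quantify CHC amounts against the internal standard
#'
#' Per sample: `amount_i = area_i / area_IS * isMass / fliesPerSample`
#' (ng/insect), and relative percentages over the compounds (the internal
#' standard is excluded from the composition). The defaults encode the
#' extraction protocol: 20 ul of 10 ng/ul tridecane = 200 ng IS, 5 flies
#' per sample.
#'
#' @param peaks data.frame for one sample: `compound`, `area`,
#'   `is_internal_standard`.
#' @param isMass internal-standard mass (ng, default 200).
#' @param fliesPerSample flies extracted per sample (default 5).
#' @return data.frame: compound, amount_ng_per_insect, relative_pct.
#' @export
chcAmounts <- function(peaks, isMass = 200, fliesPerSample = 5) {
  isRow <- peaks$is_internal_standard
  if (sum(isRow) != 1) stop("exactly one internal-standard peak required")
  areaIS <- peaks$area[isRow]
  if (areaIS <= 0) stop("internal-standard area must be positive")
  cmp <- peaks[!isRow, , drop = FALSE]
  amount <- cmp$area / areaIS * isMass / fliesPerSample
  data.frame(compound = cmp$compound,
             amount_ng_per_insect = amount,
             relative_pct = 100 * amount / sum(amount))
}

#' Balance ratio of desaturated vs saturated compounds
#'
#' `(D - S) / (D + S)` on summed (relative) amounts; bounded in `[-1, 1]`.
#'
#' @param amounts numeric amounts per compound.
#' @param classes `"saturated"` / `"desaturated"` per compound.
#' @return The balance ratio; `D + S = 0` is undefined (error).
#' @examples
#' balanceRatio(c(3, 1), c("desaturated", "saturated"))
#' @export
balanceRatio <- function(amounts, classes) {
  stopifnot(length(amounts) == length(classes),
            all(classes %in% c("saturated", "desaturated")))
  D <- sum(amounts[classes == "desaturated"])
  S <- sum(amounts[classes == "saturated"])
  if (D + S == 0) stop("balance ratio undefined: D + S = 0")
  (D - S) / (D + S)
}

#' PCA of CHC composition profiles
#'
#' Log-transforms (with a documented offset for zeros: half the smallest
#' positive value unless given), column-centres, and decomposes by SVD.
#' Constant columns are dropped with a warning. Variance-explained
#' percentages sum to 100.
#'
#' @param profiles samples x compounds matrix of (relative) amounts.
#' @param logTransform log-transform first (default TRUE, as in the study).
#' @param offset value added before the log; default half the minimum
#'   positive entry.
#' @return list(scores, loadings, var_explained, offset).
#' @export
chcPCA <- function(profiles, logTransform = TRUE, offset = NULL) {
  X <- as.matrix(profiles)
  stopifnot(nrow(X) >= 2, ncol(X) >= 2)
  if (logTransform) {
    offset <- offset %||% (min(X[X > 0]) / 2)
    X <- log(X + offset)
  }
  keep <- apply(X, 2, var) > 0
  if (!all(keep)) {
    warning("dropping constant compound column(s): ",
            paste(colnames(X)[!keep], collapse = ", "))
    X <- X[, keep, drop = FALSE]
  }
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  ve <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x, loadings = pc$rotation, var_explained = ve,
       offset = if (logTransform) offset else NA_real_)
}

#' Relative expression by the 2^(-ddCt) method
#'
#' `2^-((ct_target - ct_ref) - (ct_target_ctrl - ct_ref_ctrl))`.
#'
#' @param ctTarget,ctRef treated-sample Ct of target and reference genes.
#' @param ctTargetCtrl,ctRefCtrl control-sample Ct values.
#' @return Fold change.
#' @examples
#' ddct(20, 15, 22, 15)  # 4
#' @export
ddct <- function(ctTarget, ctRef, ctTargetCtrl, ctRefCtrl) {
  stopifnot(all(is.finite(c(ctTarget, ctRef, ctTargetCtrl, ctRefCtrl))))
  2^(-((ctTarget - ctRef) - (ctTargetCtrl - ctRefCtrl)))
}
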