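#' Apply the control-mortality exclusion rule
#'
#' Strains whose pooled control mortality fraction strictly exceeds
#' `controlThreshold` are removed from the table, as are strains without any
#' control replicate (flagged in the report). Injured flies (dead before the
#' first check) are subtracted from all denominators. The operation is
#' idempotent.
#'
#' @param tbl a [MortalityTable-class].
#' @param controlThreshold maximum tolerated control mortality fraction
#'   (default 0.10; exactly 10% is retained).
#' @return A list with `retained` (a [MortalityTable-class]) and `report`
#'   (data.frame: strain, control_mortality, excluded, reason).
#' @examples
#' sim <- genMortality(simConfig(seed = 1, nStrains = 5,
#'                               controlMortalityRate = 0.2))
#' excludeStrains(sim$table)$report
#' @export
excludeStrains <- function(tbl, controlThreshold = 0.10) {
  d <- mortalityData(tbl)
  strains <- unique(d$strain)
  rep_ <- lapply(strains, function(s) {
    ctl <- d[d$strain == s & d$condition == "control", ]
    if (nrow(ctl) == 0) {
      return(data.frame(strain = s, control_mortality = NA_real_,
                        excluded = TRUE, reason = "no control data"))
    }
    # final cumulative deaths per replicate
    last <- do.call(rbind, lapply(split(ctl, ctl$replicate), function(g) {
      g[which.max(g$time_h), c("cum_dead", "n_start", "n_injured")]
    }))
    frac <- sum(last$cum_dead) / sum(last$n_start - last$n_injured)
    excl <- frac > controlThreshold
    data.frame(strain = s, control_mortality = frac, excluded = excl,
               reason = if (excl) sprintf("control mortality %.3f > %.2f",
                                          frac, controlThreshold) else "")
  })
  report <- do.call(rbind, rep_)
  keep <- report$strain[!report$excluded]
  list(retained = MortalityTable(d[d$strain %in% keep, , drop = FALSE]),
       report = report)
}

# pooled treated interval counts for one strain
.intervalCounts <- function(d, strain) {
  tr <- d[d$strain == strain & d$condition == "treated", ]
  if (nrow(tr) == 0) stop("no treated data for strain ", strain)
  times <- sort(unique(tr$time_h))
  newly <- numeric(length(times))
  nTot <- 0L
  for (g in split(tr, tr$replicate)) {
    g <- g[order(g$time_h), ]
    stopifnot(identical(g$time_h, times))
    newly <- newly + c(g$cum_dead[1], diff(g$cum_dead))
    nTot <- nTot + g$n_start[1] - g$n_injured[1]
  }
  list(times = times, newly = newly, n = nTot,
       censored = nTot - sum(newly))
}

#' Interval-censored probit fit of a mortality curve
#'
#' Maximum-likelihood fit of the probit dose-time model
#' `P(dead by t) = Phi(a + b * log10 t)` to pooled interval mortality counts:
#' the newly dead in each inter-checkpoint interval follow a multinomial with
#' cell probabilities `Phi(a + b log10 t_k) - Phi(a + b log10 t_{k-1})`, with
#' a right-censored cell for survivors past the last check.
#' `LT50 = 10^(-a/b)`; its standard error is delta-method. The classic
#' cumulative-proportion regression of Finney is available as a
#' compatibility mode (`mode = "finney"`), and per-replicate pooling can be
#' switched off for diagnostics (`pool = FALSE` returns one fit per
#' replicate).
#'
#' @param tbl a [MortalityTable-class].
#' @param strain strain id to fit.
#' @param mode `"interval"` (canonical MLE) or `"finney"` (probit regression
#'   on cumulative proportions, unweighted, with 1/(2n) clipping).
#' @param pool pool replicates within strain (default) or fit each
#'   replicate.
#' @return A [ProbitFit-class] (or a list of them when `pool = FALSE`).
#'   Non-identifiable data (no deaths, or everything dead at the first
#'   check) yield `converged = FALSE` with `NA` estimates, never a silent
#'   answer.
#' @examples
#' sim <- genMortality(simConfig(seed = 1, nStrains = 2, nFliesPerRep = 100))
#' fitProbit(sim$table, "strain001")
#' @export
fitProbit <- function(tbl, strain, mode = c("interval", "finney"),
                      pool = TRUE) {
  mode <- match.arg(mode)
  d <- mortalityData(tbl)
  if (!pool) {
    tr <- d[d$strain == strain & d$condition == "treated", ]
    return(lapply(split(tr, tr$replicate), function(g) {
      g$replicate <- 1L
      fitProbit(MortalityTable(g), strain, mode = mode, pool = TRUE)
    }))
  }
  ic <- .intervalCounts(d, strain)
  times <- ic$times; newly <- ic$newly; n <- ic$n
  failed <- function() new("ProbitFit", intercept = NA_real_, slope = NA_real_,
                           lt50 = NA_real_,
                           se = c(intercept = NA_real_, slope = NA_real_,
                                  lt50 = NA_real_),
                           converged = FALSE, logLik = NA_real_,
                           n = as.integer(n))
  if (sum(newly) == 0 || (newly[1] == n) || length(times) < 2) {
    warning("non-identifiable mortality data for strain ", strain)
    return(failed())
  }

  lt <- log10(times)
  cum <- cumsum(newly)
  # Finney-style start values (and the compatibility mode itself)
  pEmp <- pmin(pmax(cum / n, 1 / (2 * n)), 1 - 1 / (2 * n))
  fin <- lm(qnorm(pEmp) ~ lt)
  a0 <- coef(fin)[[1]]; b0 <- max(coef(fin)[[2]], 1e-3)

  if (mode == "finney") {
    V <- vcov(fin)
    a <- a0; b <- b0
    l50 <- 10^(-a / b)
    gr <- l50 * log(10) * c(-1 / b, a / b^2)
    seL <- sqrt(drop(t(gr) %*% V %*% gr))
    return(new("ProbitFit", intercept = a, slope = b, lt50 = l50,
               se = c(intercept = sqrt(V[1, 1]), slope = sqrt(V[2, 2]),
                      lt50 = seL),
               converged = TRUE, logLik = NA_real_, n = as.integer(n)))
  }

  nll <- function(par) {
    p <- pnorm(par[1] + par[2] * lt)
    cells <- c(p[1], diff(p), 1 - p[length(p)])
    cells <- pmax(cells, 1e-12)
    -sum(c(newly, ic$censored) * log(cells))
  }
  opt <- tryCatch(
    optim(c(a0, b0), nll, method = "BFGS", hessian = TRUE,
          control = list(maxit = 500, reltol = 1e-12)),
    error = function(e) NULL)
  if (is.null(opt) || opt$convergence != 0) {
    warning("probit fit did not converge for strain ", strain)
    return(failed())
  }
  a <- opt$par[1]; b <- opt$par[2]
  V <- tryCatch(solve(opt$hessian), error = function(e) matrix(NA_real_, 2, 2))
  l50 <- 10^(-a / b)
  gr <- l50 * log(10) * c(-1 / b, a / b^2)
  seL <- if (anyNA(V)) NA_real_ else sqrt(drop(t(gr) %*% V %*% gr))
  new("ProbitFit", intercept = a, slope = b, lt50 = l50,
      se = c(intercept = sqrt(V[1, 1]), slope = sqrt(V[2, 2]), lt50 = seL),
      converged = TRUE, logLik = -opt$value, n = as.integer(n))
}

#' Observed LT100 (empirical full-mortality time)
#'
#' The mean over treated replicates of the first checkpoint at which the
#' cumulative dead equals the number of assayed flies. Undefined (NA, with a
#' `"censored"` attribute) when any replicate never reaches full mortality;
#' such strains are dropped from LT100 analyses.
#'
#' @param tbl a [MortalityTable-class].
#' @param strain strain id.
#' @return Hours, or `NA` when censored.
#' @examples
#' sim <- genMortality(simConfig(seed = 1, nStrains = 2))
#' observedLT100(sim$table, "strain001")
#' @export
observedLT100 <- function(tbl, strain) {
  d <- mortalityData(tbl)
  tr <- d[d$strain == strain & d$condition == "treated", ]
  if (nrow(tr) == 0) stop("no treated data for strain ", strain)
  times <- vapply(split(tr, tr$replicate), function(g) {
    g <- g[order(g$time_h), ]
    full <- g$n_start[1] - g$n_injured[1]
    i <- which(g$cum_dead == full)[1]
    if (is.na(i)) NA_real_ else g$time_h[i]
  }, numeric(1))
  if (anyNA(times)) {
    out <- NA_real_
    attr(out, "censored") <- TRUE
    return(out)
  }
  mean(times)
}

#' Per-strain lethal-time summary table
#'
#' Convenience wrapper: applies the exclusion rule, fits the probit LT50 and
#' computes the empirical LT100 for every retained strain.
#'
#' @param tbl a [MortalityTable-class].
#' @param controlThreshold passed to [excludeStrains()].
#' @return data.frame: strain, lt50, lt50_se, converged, lt100.
#' @export
ltTable <- function(tbl, controlThreshold = 0.10) {
  ex <- excludeStrains(tbl, controlThreshold)
  d <- mortalityData(ex$retained)
  strains <- unique(d$strain)
  do.call(rbind, lapply(strains, function(s) {
    f <- suppressWarnings(fitProbit(ex$retained, s))
    data.frame(strain = s, lt50 = f@lt50, lt50_se = f@se[["lt50"]],
               converged = f@converged,
               lt100 = suppressWarnings(as.numeric(observedLT100(ex$retained, s))))
  }))
}

#' Spearman rank correlation (one-tailed by default)
#'
#' Tie-corrected Spearman correlation, one-tailed as used for the LT50/LT100
#' agreement check.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param alternative passed to [stats::cor.test()]; default `"greater"`.
#' @return list(rho, p).
#' @examples
#' rankCorrelation(1:10, (1:10)^2)
#' @export
rankCorrelation <- function(x, y, alternative = "greater") {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (sd(x) == 0 || sd(y) == 0) {
    stop("rank correlation undefined for constant input")
  }
  ct <- suppressWarnings(
    cor.test(x, y, method = "spearman", alternative = alternative))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' One-way ANOVA of lethal time by climate zone, with Tukey HSD
#'
#' Reports the Shapiro-Wilk normality check first, then the one-way ANOVA of
#' the response across climate-zone groups and Tukey HSD adjusted pairwise
#' p-values. Singleton groups are excluded with a warning; a response with
#' zero variance in every group is flagged as degenerate.
#'
#' @param meta data.frame with a `climate` column and the response column.
#' @param response response column name (default `"LT100"`).
#' @return list(shapiro_p, F, p, tukey, excluded_groups, degenerate).
#' @examples
#' meta <- data.frame(climate = rep(c("Bsk", "Csa", "Cfb"), each = 6),
#'                    LT100 = c(rnorm(6, 26), rnorm(6, 22), rnorm(6, 23)))
#' climateAnova(meta)$p
#' @export
climateAnova <- function(meta, response = "LT100") {
  stopifnot(all(c("climate", response) %in% names(meta)))
  d <- meta[!is.na(meta[[response]]), c("climate", response)]
  names(d) <- c("climate", "y")
  sizes <- table(d$climate)
  singles <- names(sizes)[sizes < 2]
  if (length(singles)) {
    warning("excluding singleton climate group(s): ",
            paste(singles, collapse = ", "))
    d <- d[!d$climate %in% singles, ]
  }
  if (length(unique(d$climate)) < 2) stop("need >= 2 climate groups")
  d$climate <- factor(d$climate)
  if (var(d$y) == 0) {
    return(list(shapiro_p = NA_real_, F = NA_real_, p = NA_real_,
                tukey = NULL, excluded_groups = singles, degenerate = TRUE))
  }
  sw <- shapiro.test(d$y)
  fit <- aov(y ~ climate, data = d)
  at <- anova(fit)
  tk <- TukeyHSD(fit)$climate
  list(shapiro_p = sw$p.value, F = at[1, "F value"], p = at[1, "Pr(>F)"],
       tukey = as.data.frame(tk), excluded_groups = singles,
       degenerate = FALSE)
}

#' Iterative variance-inflation-factor pruning
#'
#' `VIF_j = 1 / (1 - R^2_j)` from regressing covariate j on all others.
#' While the largest VIF is at or above the threshold, the covariate with
#' the largest VIF is dropped (ties broken by column order); a perfectly
#' collinear covariate is reported as `Inf` and removed first. All final
#' VIFs are strictly below the threshold.
#'
#' @param covariates numeric matrix or data.frame (n rows > p columns).
#' @param threshold VIF threshold (default 5, the study's cut).
#' @return list(retained = column names, vif = final named VIFs,
#'   removed = data.frame(variable, vif, step)).
#' @examples
#' X <- cbind(a = rnorm(30), b = rnorm(30))
#' X <- cbind(X, ab = X[, "a"] + 0.01 * rnorm(30))
#' vifPrune(X)$retained
#' @export
vifPrune <- function(covariates, threshold = 5) {
  X <- as.data.frame(covariates)
  stopifnot(ncol(X) >= 2, all(vapply(X, is.numeric, logical(1))))
  X <- X[complete.cases(X), , drop = FALSE]
  vifOf <- function(X) {
    vapply(seq_len(ncol(X)), function(j) {
      fit <- lm(X[[j]] ~ ., data = X[, -j, drop = FALSE])
      r2 <- suppressWarnings(summary(fit)$r.squared)
      if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    }, numeric(1))
  }
  removed <- data.frame(variable = character(0), vif = numeric(0),
                        step = integer(0))
  step <- 0L
  repeat {
    v <- vifOf(X)
    names(v) <- colnames(X)
    if (max(v) < threshold || ncol(X) <= 2) break
    step <- step + 1L
    j <- which.max(v)  # which.max takes the first on ties: column order
    removed <- rbind(removed, data.frame(variable = colnames(X)[j],
                                         vif = v[[j]], step = step))
    X <- X[, -j, drop = FALSE]
  }
  v <- vifOf(X)
  names(v) <- colnames(X)
  if (max(v) >= threshold) {
    step <- step + 1L
    j <- which.max(v)
    removed <- rbind(removed, data.frame(variable = colnames(X)[j],
                                         vif = v[[j]], step = step))
    X <- X[, -j, drop = FALSE]
    v <- setNames(rep(1, ncol(X)), colnames(X))
  }
  list(retained = colnames(X), vif = v, removed = removed)
}

#' Environment association model for lethal time
#'
#' Ordinary least squares of the response on VIF-retained covariates with an
#' interaction term (the study's model is
#' `LT100 ~ altitude * evaporation`). Rank deficiency is flagged.
#'
#' @param meta data.frame holding the response and covariates.
#' @param formula model formula; default `LT100 ~ altitude * evaporation`.
#' @return list(coefficients = coefficient table with t-based p-values,
#'   adj_r_squared, rank_deficient, model).
#' @examples
#' meta <- data.frame(LT100 = rnorm(40, 25), altitude = runif(40, 0, 500),
#'                    evaporation = rnorm(40))
#' environmentModel(meta)$adj_r_squared
#' @export
environmentModel <- function(meta, formula = LT100 ~ altitude * evaporation) {
  fit <- lm(formula, data = meta)
  sm <- summary(fit)
  rankDef <- fit$rank < length(coef(fit)) || anyNA(coef(fit))
  if (rankDef) warning("environment model is rank deficient")
  list(coefficients = as.data.frame(sm$coefficients),
       adj_r_squared = sm$adj.r.squared,
       rank_deficient = rankDef, model = fit)
}
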