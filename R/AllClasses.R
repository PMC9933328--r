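#' SimConfig: parameters of the synthetic study world
#'
#' Holds every tunable of the synthetic-data generators. The defaults encode
#' the study conditions: 74 strains scored every 4 h until hour 12 and at
#' shorter intervals afterwards, 15 flies per replicate, 3 replicates, strain
#' LT50 spread between 12 and 30 h, and an RNA-seq design of 3 tolerant plus
#' 3 sensitive strains with 3 replicates per condition.
#'
#' @slot seed integer root seed; every generator derives a named child stream
#'   from it via [childSeed()].
#' @slot nStrains number of strains in the mortality world.
#' @slot nFliesPerRep flies per replicate vial.
#' @slot nReps replicates per strain and condition.
#' @slot checkpointTimes hours of the survival checks (strictly increasing).
#' @slot trueLT50 per-strain true LT50 in hours (length `nStrains`, or length
#'   2 giving the uniform range to draw from).
#' @slot probitSlope probit slope per log10 hour.
#' @slot controlMortalityRate per-fly death probability in control vials.
#' @slot nGenes genes in the expression world.
#' @slot deFraction fraction of genes carrying a condition effect.
#' @slot log2Effect absolute log2 fold change of planted DE genes.
#' @slot nbDispersion negative-binomial dispersion (0 = Poisson).
#' @slot nTrnas mature tRNAs in the small-RNA world.
#' @slot nTranscripts transcripts scanned for tRF target sites.
#' @slot plantedTargetFraction fraction of transcripts given a planted site.
#' @slot teDensity transposable elements per megabase.
#' @slot enrichmentFactor multiplicative enrichment (>1) or depletion (<1) of
#'   TE placement near DE-labelled genes; 1 = no association.
#' @export
setClass("SimConfig", representation(
  seed = "integer",
  nStrains = "integer",
  nFliesPerRep = "integer",
  nReps = "integer",
  checkpointTimes = "numeric",
  trueLT50 = "numeric",
  probitSlope = "numeric",
  controlMortalityRate = "numeric",
  nGenes = "integer",
  deFraction = "numeric",
  log2Effect = "numeric",
  nbDispersion = "numeric",
  nTrnas = "integer",
  nTranscripts = "integer",
  plantedTargetFraction = "numeric",
  teDensity = "numeric",
  enrichmentFactor = "numeric"
))

setValidity("SimConfig", function(object) {
  msg <- character(0)
  ct <- object@checkpointTimes
  if (length(ct) < 1L || any(ct <= 0) || any(diff(ct) <= 0)) {
    msg <- c(msg, "checkpointTimes must be positive and strictly increasing")
  }
  probs <- c(object@controlMortalityRate, object@deFraction,
             object@plantedTargetFraction)
  if (any(probs < 0 | probs > 1)) {
    msg <- c(msg, "probabilities must lie in [0, 1]")
  }
  if (object@nbDispersion < 0) msg <- c(msg, "nbDispersion must be >= 0")
  if (object@teDensity < 0) msg <- c(msg, "teDensity must be >= 0")
  if (object@enrichmentFactor < 0) msg <- c(msg, "enrichmentFactor must be > 0 or 0 for total depletion")
  if (!(length(object@trueLT50) %in% c(2L, object@nStrains))) {
    msg <- c(msg, "trueLT50 must have length 2 (range) or nStrains")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SimConfig
#'
#' @param seed integer root seed.
#' @param nStrains,nFliesPerRep,nReps,checkpointTimes,trueLT50,probitSlope,controlMortalityRate
#'   mortality-world parameters; see [SimConfig-class].
#' @param nGenes,deFraction,log2Effect,nbDispersion expression-world parameters.
#' @param nTrnas,nTranscripts,plantedTargetFraction small-RNA-world parameters.
#' @param teDensity,enrichmentFactor transposable-element-world parameters.
#' @return A validated [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(seed = 1)
#' cfg
#' @export
simConfig <- function(seed = 1L,
                      nStrains = 74L,
                      nFliesPerRep = 15L,
                      nReps = 3L,
                      checkpointTimes = c(4, 8, 12, 14, 16, 18, 20,
                                          22, 24, 26, 28, 30, 32),
                      trueLT50 = c(12, 30),
                      probitSlope = 6,
                      controlMortalityRate = 0.05,
                      nGenes = 2000L,
                      deFraction = 0.10,
                      log2Effect = 2,
                      nbDispersion = 0.2,
                      nTrnas = 10L,
                      nTranscripts = 20L,
                      plantedTargetFraction = 0.3,
                      teDensity = 100,
                      enrichmentFactor = 2) {
  new("SimConfig",
      seed = as.integer(seed), nStrains = as.integer(nStrains),
      nFliesPerRep = as.integer(nFliesPerRep), nReps = as.integer(nReps),
      checkpointTimes = as.numeric(checkpointTimes),
      trueLT50 = as.numeric(trueLT50), probitSlope = as.numeric(probitSlope),
      controlMortalityRate = as.numeric(controlMortalityRate),
      nGenes = as.integer(nGenes), deFraction = as.numeric(deFraction),
      log2Effect = as.numeric(log2Effect),
      nbDispersion = as.numeric(nbDispersion),
      nTrnas = as.integer(nTrnas), nTranscripts = as.integer(nTranscripts),
      plantedTargetFraction = as.numeric(plantedTargetFraction),
      teDensity = as.numeric(teDensity),
      enrichmentFactor = as.numeric(enrichmentFactor))
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig (seed ", object@seed, ")\n", sep = "")
  cat("  mortality : ", object@nStrains, " strains x ", object@nReps,
      " reps x ", object@nFliesPerRep, " flies; ",
      length(object@checkpointTimes), " checks to ",
      max(object@checkpointTimes), " h\n", sep = "")
  cat("  expression: ", object@nGenes, " genes, ",
      round(100 * object@deFraction), "% DE at |log2FC| ",
      object@log2Effect, ", dispersion ", object@nbDispersion, "\n", sep = "")
  cat("  small RNA : ", object@nTrnas, " tRNAs, ", object@nTranscripts,
      " transcripts, ", round(100 * object@plantedTargetFraction),
      "% planted targets\n", sep = "")
  cat("  TE world  : ", object@teDensity, " TEs/Mb, enrichment x",
      object@enrichmentFactor, "\n", sep = "")
})

#' MortalityTable: per-strain interval mortality records
#'
#' Long-format cumulative death counts at each survival checkpoint, per
#' strain, replicate and condition. Flies dead before the first check are
#' recorded as injured and excluded from all denominators.
#'
#' @slot data data.frame with columns `strain`, `replicate`, `condition`
#'   (`"treated"` or `"control"`), `time_h`, `cum_dead`, `n_start`,
#'   `n_injured`.
#' @export
setClass("MortalityTable", representation(data = "data.frame"))

setValidity("MortalityTable", function(object) {
  d <- object@data
  need <- c("strain", "replicate", "condition", "time_h", "cum_dead",
            "n_start", "n_injured")
  if (!all(need %in% names(d))) {
    return(paste("missing columns:", paste(setdiff(need, names(d)), collapse = ", ")))
  }
  if (!all(d$condition %in% c("treated", "control"))) {
    return("condition must be 'treated' or 'control'")
  }
  if (any(d$cum_dead < 0) || any(d$cum_dead > d$n_start - d$n_injured)) {
    return("cum_dead must lie in [0, n_start - n_injured]")
  }
  key <- interaction(d$strain, d$replicate, d$condition, drop = TRUE)
  for (g in split(d[order(d$time_h), ], key[order(d$time_h)])) {
    if (any(diff(g$time_h) <= 0)) return("checkpoint times must be strictly increasing")
    if (any(diff(g$cum_dead) < 0)) return("cum_dead must be non-decreasing in time")
  }
  TRUE
})

#' @rdname MortalityTable-class
#' @param data data.frame in the documented long format.
#' @return `MortalityTable()` returns a validated object;
#'   `mortalityData()` its underlying data.frame.
#' @examples
#' tbl <- genMortality(simConfig(seed = 1, nStrains = 3))$table
#' head(mortalityData(tbl))
#' @export
MortalityTable <- function(data) new("MortalityTable", data = as.data.frame(data))

#' @rdname MortalityTable-class
#' @param x a `MortalityTable`.
#' @export
mortalityData <- function(x) {
  stopifnot(is(x, "MortalityTable"))
  x@data
}

setMethod("show", "MortalityTable", function(object) {
  d <- object@data
  cat("MortalityTable: ", length(unique(d$strain)), " strains, ",
      length(unique(d$time_h[d$condition == "treated"])),
      " treated checkpoints, ", nrow(d), " rows\n", sep = "")
})

#' ProbitFit: interval-censored probit mortality fit
#'
#' Result of [fitProbit()]: the linear predictor is
#' `probit(P(dead by t)) = a + b * log10(t)`, so `LT50 = 10^(-a/b)`.
#'
#' @slot intercept probit intercept `a`.
#' @slot slope probit slope `b` per log10 hour.
#' @slot lt50 hours at 50% mortality, `10^(-a/b)`.
#' @slot se standard errors: named vector (`intercept`, `slope`, `lt50`);
#'   the LT50 SE is delta-method.
#' @slot converged logical convergence flag.
#' @slot logLik maximised log-likelihood.
#' @slot n number of flies used.
#' @export
setClass("ProbitFit", representation(
  intercept = "numeric", slope = "numeric", lt50 = "numeric",
  se = "numeric", converged = "logical", logLik = "numeric", n = "integer"))

#' @rdname ProbitFit-class
#' @param object,x a `ProbitFit`.
#' @return `lt50()` returns the fitted LT50 in hours.
#' @export
lt50 <- function(x) {
  stopifnot(is(x, "ProbitFit"))
  x@lt50
}

setMethod("show", "ProbitFit", function(object) {
  cat(sprintf("ProbitFit: a = %.4f, b = %.4f, LT50 = %.3f h (SE %.3f), %s\n",
              object@intercept, object@slope, object@lt50,
              object@se[["lt50"]],
              if (object@converged) "converged" else "NOT converged"))
})
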