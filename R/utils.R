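#' @useDynLib desiccatR, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats aov anova as.formula complete.cases cor.test ks.test
#'   lm logLik na.omit optim vcov optimize p.adjust pchisq pnorm prcomp pt
#'   qnorm quantile rbinom rmultinom rnbinom rnorm runif sd setNames
#'   shapiro.test t.test TukeyHSD var wilcox.test rpois dnbinom phyper
#'   chisq.test coef
#' @importFrom utils head read.delim write.table
NULL

#' Derive a reproducible child seed from a root seed and a stream name
#'
#' Each synthetic-data generator consumes its own named random stream derived
#' from the single root seed, so adding or reordering generators never
#' perturbs the draws of the others.
#'
#' @param seed integer root seed.
#' @param stream character stream name.
#' @return An integer in `[1, 2^31 - 2]` suitable for [set.seed()].
#' @examples
#' childSeed(1, "mortality")
#' @export
childSeed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  h <- 0
  for (k in utf8ToInt(stream)) h <- (h * 131 + k) %% 2147483647
  out <- (abs(as.numeric(seed)) %% 2147483647) * 69621 + h * 40014 + 1
  as.integer(out %% 2147483646 + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# strict run-length clusters of TRUE positions (1-based [start, end])
runsOfTrue <- function(mask) {
  stopifnot(is.logical(mask))
  if (!any(mask)) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}
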