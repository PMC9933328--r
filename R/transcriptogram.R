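#' Counts per million
#'
#' @param counts genes x samples count matrix.
#' @return CPM matrix (`count / library size * 1e6`).
#' @export
cpm <- function(counts) {
  counts <- as.matrix(counts)
  lib <- colSums(counts)
  if (any(lib == 0)) stop("zero library size")
  t(t(counts) / lib) * 1e6
}

#' Filter lowly expressed genes by CPM
#'
#' Keeps genes with CPM strictly above `cpmMin` in at least k samples, where
#' k is the smallest group size.
#'
#' @param counts genes x samples count matrix, or a SummarizedExperiment
#'   with a `counts` assay and a `condition` column in its colData.
#' @param groups group label per sample (ignored for a SummarizedExperiment).
#' @param cpmMin CPM threshold (default 0.5; strictly greater passes).
#' @return The filtered count matrix. An empty result is an error.
#' @examples
#' m <- matrix(c(0, 100, 0, 120), 2, dimnames = list(c("g1", "g2"), NULL))
#' filterLowExpression(m, groups = c("a", "b"))
#' @export
filterLowExpression <- function(counts, groups = NULL, cpmMin = 0.5) {
  if (is(counts, "SummarizedExperiment")) {
    groups <- SummarizedExperiment::colData(counts)$condition
    counts <- SummarizedExperiment::assay(counts, "counts")
  }
  stopifnot(ncol(counts) >= 2, !is.null(groups),
            length(groups) == ncol(counts))
  k <- min(table(groups))
  keep <- rowSums(cpm(counts) > cpmMin) >= k
  if (!any(keep)) stop("no genes pass the CPM filter")
  counts[keep, , drop = FALSE]
}

#' Trimmed-mean-of-M-values scaling factors
#'
#' Library scaling factors via edgeR's TMM (the reference sample is the one
#' whose upper quartile is closest to the mean upper quartile; 30% of
#' log-ratios and 5% of log-intensities trimmed; factors normalised to
#' geometric mean 1).
#'
#' @param counts filtered genes x samples count matrix.
#' @return Named numeric vector of scaling factors.
#' @export
tmmFactors <- function(counts) {
  f <- edgeR::calcNormFactors(as.matrix(counts), method = "TMM")
  setNames(as.numeric(f), colnames(counts))
}

#' TMM-scaled log2 CPM
#'
#' `log2(count / (libsize * factor) * 1e6 + offset)`; the 0.5 offset keeps
#' zeros finite and matches the CPM filter scale.
#'
#' @param counts count matrix.
#' @param factors scaling factors from [tmmFactors()].
#' @param offset pseudo-CPM added before the log (default 0.5).
#' @return log2-CPM matrix.
#' @export
logCPM <- function(counts, factors = tmmFactors(counts), offset = 0.5) {
  counts <- as.matrix(counts)
  eff <- colSums(counts) * factors
  log2(t(t(counts) / eff) * 1e6 + offset)
}

# quadratic placement cost of an order: sum over edges of (pos_i - pos_j)^2
.orderCost <- function(pos, edges) sum((pos[edges[, 1]] - pos[edges[, 2]])^2)

#' Order genes on a line by simulated annealing over a PPI graph
#'
#' Searches for a permutation of the graph's vertices minimising the
#' quadratic edge-length cost `sum over edges (pos_i - pos_j)^2`, so that
#' genes whose products interact end up as neighbours. Pairwise-swap
#' proposals with geometric cooling; seeded and reproducible; the returned
#' order never costs more than the initial one. `nSteps = 0` returns the
#' initial (vertex) order.
#'
#' @param g igraph of gene interactions.
#' @param seed integer seed for the annealing stream.
#' @param nSteps number of proposal steps.
#' @param t0 initial temperature (default: scaled to the cost of the initial
#'   order).
#' @param cooling geometric cooling rate per step.
#' @return Character vector: gene ids in optimised order.
#' @examples
#' g <- igraph::make_ring(6)
#' igraph::V(g)$name <- letters[1:6]
#' orderGenes(g, seed = 1, nSteps = 500)
#' @export
orderGenes <- function(g, seed = 1L, nSteps = 20000L, t0 = NULL,
                       cooling = 0.999) {
  nodes <- igraph::V(g)$name
  n <- length(nodes)
  edges <- igraph::as_edgelist(g, names = FALSE)
  pos <- seq_len(n)                       # pos[vertex] = rank
  if (nSteps == 0 || nrow(edges) == 0) return(nodes[order(pos)])
  set.seed(as.integer(seed))
  # adjacency list for incremental cost deltas
  adj <- vector("list", n)
  for (e in seq_len(nrow(edges))) {
    a <- edges[e, 1]; b <- edges[e, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  cost <- .orderCost(pos, edges)
  bestPos <- pos; bestCost <- cost
  temp <- t0 %||% max(cost / max(nrow(edges), 1), 1)
  vertexCost <- function(v, pos) sum((pos[v] - pos[adj[[v]]])^2)
  for (step in seq_len(nSteps)) {
    vw <- sample.int(n, 2)
    v <- vw[1]; w <- vw[2]
    before <- vertexCost(v, pos) + vertexCost(w, pos)
    pos2 <- pos
    pos2[c(v, w)] <- pos[c(w, v)]
    after <- vertexCost(v, pos2) + vertexCost(w, pos2)
    delta <- after - before
    if (delta <= 0 || runif(1) < exp(-delta / temp)) {
      pos <- pos2
      cost <- cost + delta
      if (cost < bestCost) { bestCost <- cost; bestPos <- pos }
    }
    temp <- temp * cooling
  }
  nodes[order(bestPos)]
}

#' Sliding-window mean along the ordered gene list
#'
#' Assigns to each position the mean of the values in a window of the given
#' radius centred on it; windows truncate at the ends of the list (the
#' ordered list is linear, not circular). `r = 0` is the identity.
#'
#' @param values numeric vector of per-position values, or a positions x
#'   samples matrix (smoothed per column).
#' @param r window radius in positions (the study default is 125).
#' @return Smoothed vector or matrix of the same shape.
#' @examples
#' windowSmooth(c(0, 1, 2, 3, 4), r = 1)
#' @export
windowSmooth <- function(values, r) {
  stopifnot(r >= 0)
  if (is.matrix(values)) return(apply(values, 2, windowSmooth, r = r))
  n <- length(values)
  if (r == 0 || n == 0) return(values)
  cs <- cumsum(c(0, values))
  lo <- pmax(seq_len(n) - r, 1)
  hi <- pmin(seq_len(n) + r, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Per-position differential test of smoothed transcriptogram profiles
#'
#' Two-sample Welch t-test per position between the smoothed profiles of the
#' two groups, with Benjamini-Hochberg adjustment across positions. The
#' paired mode averages replicate profiles within each pairing unit (strain)
#' and condition, then tests the per-unit differences with a one-sample t —
#' matching a within-strain control/stress design. Positions with zero
#' variance in both groups get p = 1 by convention.
#'
#' @param profiles positions x samples matrix of smoothed log-CPM.
#' @param group length-ncol factor/character with exactly 2 levels; the
#'   first level (or `levels[1]`) is the test condition, direction is its
#'   sign relative to the second.
#' @param deFdr BH threshold for the significance mask (default 0.01).
#' @param paired logical; use the paired design.
#' @param pairId pairing unit per sample (e.g. strain), required when
#'   `paired = TRUE`.
#' @param levels optional explicit ordering of the two group levels
#'   (test, reference).
#' @return data.frame: position, t, p, q, direction (+1/-1/0), significant.
#' @export
differentialPositions <- function(profiles, group, deFdr = 0.01,
                                  paired = FALSE, pairId = NULL,
                                  levels = NULL) {
  profiles <- as.matrix(profiles)
  group <- as.character(group)
  lv <- levels %||% unique(group)
  stopifnot(length(lv) == 2, all(group %in% lv))
  if (paired) {
    stopifnot(!is.null(pairId), length(pairId) == ncol(profiles))
    units <- unique(pairId)
    diffs <- vapply(units, function(u) {
      rowMeans(profiles[, pairId == u & group == lv[1], drop = FALSE]) -
        rowMeans(profiles[, pairId == u & group == lv[2], drop = FALSE])
    }, numeric(nrow(profiles)))
    m <- rowMeans(diffs)
    v <- apply(diffs, 1, var)
    k <- ncol(diffs)
    stopifnot(k >= 2)
    tstat <- m / sqrt(v / k)
    df <- rep(k - 1, length(m))
  } else {
    x1 <- profiles[, group == lv[1], drop = FALSE]
    x2 <- profiles[, group == lv[2], drop = FALSE]
    n1 <- ncol(x1); n2 <- ncol(x2)
    stopifnot(n1 >= 2, n2 >= 2)
    m1 <- rowMeans(x1); m2 <- rowMeans(x2)
    v1 <- apply(x1, 1, var); v2 <- apply(x2, 1, var)
    sse <- v1 / n1 + v2 / n2
    tstat <- (m1 - m2) / sqrt(sse)
    df <- sse^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    m <- m1 - m2
  }
  zeroVar <- !is.finite(tstat)
  p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  p[zeroVar] <- 1
  q <- p.adjust(p, method = "BH")
  data.frame(position = seq_len(nrow(profiles)), t = tstat, p = p, q = q,
             direction = sign(m) * (!zeroVar),
             significant = q < deFdr)
}

#' Call contiguous clusters of significant positions
#'
#' Maximal runs of consecutive significant positions become clusters; the
#' member genes are those at the run's positions (window centres); cluster
#' direction is the majority sign. Singleton runs are allowed.
#'
#' @param significant logical mask over positions.
#' @param order gene ids in list order (gene at position i = `order[i]`).
#' @param direction per-position sign (+1 up, -1 down) as from
#'   [differentialPositions()].
#' @return data.frame: cluster, start, end, n, direction, and a `genes`
#'   list-column.
#' @examples
#' callClusters(c(TRUE, TRUE, FALSE, TRUE), letters[1:4], c(1, 1, 0, -1))
#' @export
callClusters <- function(significant, order, direction = NULL) {
  stopifnot(length(significant) == length(order))
  runs <- runsOfTrue(significant)
  if (nrow(runs) == 0) {
    out <- data.frame(cluster = integer(0), start = integer(0),
                      end = integer(0), n = integer(0),
                      direction = character(0))
    out$genes <- list()
    return(out)
  }
  dirOf <- function(s, e) {
    if (is.null(direction)) return(NA_character_)
    d <- direction[s:e]
    if (sum(d > 0) >= sum(d < 0)) "up" else "down"
  }
  out <- data.frame(cluster = seq_len(nrow(runs)), start = runs$start,
                    end = runs$end, n = runs$end - runs$start + 1L,
                    direction = mapply(dirOf, runs$start, runs$end))
  out$genes <- Map(function(s, e) order[s:e], runs$start, runs$end)
  out
}

#' Run the transcriptogram differential-expression pipeline
#'
#' Filter by CPM, TMM-normalise, project log2-CPM onto the gene order,
#' smooth with the sliding window, test per position and call clusters.
#'
#' @param counts genes x samples count matrix.
#' @param samples data.frame with `condition` (and `strain` when paired).
#' @param order gene ids in list order; genes absent from the filtered
#'   matrix are dropped from the order (and vice versa).
#' @param radius window radius (study default 125; 50 and 80 were also
#'   explored).
#' @param deFdr BH threshold (default 0.01).
#' @param cpmMin CPM filter (default 0.5).
#' @param paired paired (within-strain) contrast; default unpaired (with
#'   few strains the paired test has very few degrees of freedom).
#' @param levels optional explicit (test, reference) condition ordering.
#' @param centerProfiles subtract each sample's median smoothed value
#'   before testing (default TRUE). Strongly asymmetric differential
#'   expression shifts library composition in a way the trimmed-mean
#'   normalisation only partly absorbs; median centering removes the
#'   residual depth offset under the assumption that most windows are
#'   unchanged.
#' @return list(positions = per-position test table with gene column,
#'   clusters = cluster table, profiles = smoothed matrix,
#'   order = order used).
#' @export
transcriptogramDE <- function(counts, samples, order, radius = 125,
                              deFdr = 0.01, cpmMin = 0.5, paired = FALSE,
                              levels = NULL, centerProfiles = TRUE) {
  counts <- as.matrix(counts)
  stopifnot(nrow(samples) == ncol(counts), "condition" %in% names(samples))
  filt <- filterLowExpression(counts, samples$condition, cpmMin)
  ordUse <- order[order %in% rownames(filt)]
  filt <- filt[ordUse, , drop = FALSE]
  lc <- logCPM(filt)
  sm <- windowSmooth(lc, radius)
  if (centerProfiles) {
    # median-of-differences normalisation of the contrast: the median
    # profile difference between the groups estimates the residual depth
    # offset, assuming most windows are unchanged
    lv <- levels %||% unique(samples$condition)
    g1 <- samples$condition == lv[1]
    delta <- rowMeans(sm[, g1, drop = FALSE]) -
      rowMeans(sm[, !g1, drop = FALSE])
    # iteratively trimmed median: truly shifted windows are one-sided
    # outliers that would otherwise drag a plain median
    m <- stats::median(delta)
    for (it in 1:3) {
      keep <- abs(delta - m) <= 3 * stats::mad(delta - m)
      if (any(keep)) m <- stats::median(delta[keep])
    }
    sm[, g1] <- sm[, g1] - m
  }
  res <- differentialPositions(sm, samples$condition, deFdr = deFdr,
                               paired = paired,
                               pairId = samples$strain, levels = levels)
  res$gene <- ordUse
  cl <- callClusters(res$significant, ordUse, res$direction)
  list(positions = res, clusters = cl, profiles = sm, order = ordUse)
}

#' Hypergeometric gene-set over-representation for cluster genes
#'
#' One-sided hypergeometric (over-representation) p-value per gene set, BH
#' adjusted across sets; the top sets per cluster (ordered by adjusted p,
#' most significant first) are reported.
#'
#' @param clusterGenes character vector of cluster member genes.
#' @param universe all analysed genes.
#' @param geneSets named list of gene-id vectors (GMT-style).
#' @param fdr BH significance threshold (study default 0.005 for GO).
#' @param topN sets reported per cluster (default 10).
#' @return data.frame: set, overlap, set_size, p, q, significant; `topN`
#'   rows ordered by q.
#' @examples
#' sets <- list(s1 = letters[1:5], s2 = letters[6:10])
#' genesetEnrichment(letters[1:4], letters, sets)
#' @export
genesetEnrichment <- function(clusterGenes, universe, geneSets,
                              fdr = 0.005, topN = 10) {
  if (length(universe) == 0) stop("empty universe")
  universe <- unique(universe)
  clusterGenes <- intersect(unique(clusterGenes), universe)
  n <- length(clusterGenes)
  N <- length(universe)
  rows <- lapply(names(geneSets), function(nm) {
    K <- length(intersect(geneSets[[nm]], universe))
    k <- length(intersect(geneSets[[nm]], clusterGenes))
    p <- if (K == 0) 1 else phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, overlap = k, set_size = K, p = p)
  })
  out <- do.call(rbind, rows)
  out$q <- p.adjust(out$p, method = "BH")
  out$significant <- out$q < fdr
  out <- out[order(out$q, out$p), ]
  head(out, topN)
}

#' Tissue enrichment of a DEG list at an expression cutoff
#'
#' Per tissue, genes with RPKM strictly above `rpkmMin` are flagged as
#' highly expressed; the DEG list is tested for over-representation among
#' flagged genes by a hypergeometric test, Bonferroni-corrected across
#' tissues.
#'
#' @param degs DEG gene ids.
#' @param tissueRPKM genes x tissues RPKM matrix (rownames = gene ids),
#'   covering the universe.
#' @param rpkmMin high-expression cutoff (default 51, strictly greater).
#' @param alpha Bonferroni-adjusted significance level (default 0.001).
#' @return data.frame: tissue, flagged, overlap, p, p_adj, significant.
#' @export
tissueEnrichment <- function(degs, tissueRPKM, rpkmMin = 51, alpha = 0.001) {
  tissueRPKM <- as.matrix(tissueRPKM)
  universe <- rownames(tissueRPKM)
  degs <- intersect(degs, universe)
  N <- length(universe)
  n <- length(degs)
  rows <- lapply(colnames(tissueRPKM), function(ts) {
    flagged <- universe[tissueRPKM[, ts] > rpkmMin]
    K <- length(flagged)
    k <- length(intersect(flagged, degs))
    p <- if (K == 0) 1 else phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(tissue = ts, flagged = K, overlap = k, p = p)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- pmin(out$p * ncol(tissueRPKM), 1)
  out$significant <- out$p_adj < alpha
  out
}
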