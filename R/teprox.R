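#' k-nearest transposable elements per gene
#'
#' For each gene, reports up to `k` nearest TEs with reference-strand signed
#' gap distances: 0 for any overlap (or book-ended intervals), negative when
#' the TE lies upstream (lower coordinates) of the gene, positive
#' downstream. All ties at the k-th distance are reported. TEs shorter than
#' `minTeWidth` are discarded first (the annotation floor is 120 bp).
#' "Within 1 kb" means gap <= `window` inclusive.
#'
#' @param genes,tes [GenomicRanges::GRanges-class] with a `feature_id`
#'   metadata column.
#' @param k maximum TEs per gene (default 10).
#' @param window proximity window in bp (default 1000, inclusive).
#' @param minTeWidth minimum TE width in bp (default 120).
#' @return data.frame: gene_id, te_id, distance, within_window. Genes on a
#'   chromosome with no TE get one row with `NA` te_id and distance.
#' @export
nearestTE <- function(genes, tes, k = 10L, window = 1000L,
                      minTeWidth = 120L) {
  tes <- tes[GenomicRanges::width(tes) >= minTeWidth]
  gIds <- genes$feature_id
  out <- vector("list", length(genes))
  teChrom <- as.character(GenomicRanges::seqnames(tes))
  teCoords <- lapply(split(seq_along(tes), teChrom), function(ix) {
    list(start = GenomicRanges::start(tes)[ix],
         end = GenomicRanges::end(tes)[ix],
         id = tes$feature_id[ix])
  })
  gs <- GenomicRanges::start(genes); ge <- GenomicRanges::end(genes)
  gChrom <- as.character(GenomicRanges::seqnames(genes))
  for (i in seq_along(genes)) {
    te <- teCoords[[gChrom[i]]]
    if (is.null(te) || length(te$start) == 0) {
      out[[i]] <- list(gene_id = gIds[i], te_id = NA_character_,
                       distance = NA_real_)
      next
    }
    ts <- te$start; tn <- te$end
    # gap between closest ends; 0 for overlap or book-ended neighbours
    gapLeft <- gs[i] - tn - 1L   # > 0 when TE entirely upstream
    gapRight <- ts - ge[i] - 1L  # > 0 when TE entirely downstream
    dist <- ifelse(gapLeft > 0, -gapLeft, pmax(gapRight, 0))
    ord <- order(abs(dist), te$id)
    kk <- min(k, length(ord))
    cut <- abs(dist[ord[kk]])
    sel <- ord[abs(dist[ord]) <= cut]  # keep all ties at the k-th distance
    out[[i]] <- list(gene_id = rep(gIds[i], length(sel)),
                     te_id = te$id[sel], distance = dist[sel])
  }
  res <- data.frame(
    gene_id = unlist(lapply(out, `[[`, "gene_id"), use.names = FALSE),
    te_id = unlist(lapply(out, `[[`, "te_id"), use.names = FALSE),
    distance = unlist(lapply(out, `[[`, "distance"), use.names = FALSE))
  res$within_window <- !is.na(res$distance) & abs(res$distance) <= window
  res
}

#' DEG-status by TE-proximity contingency table
#'
#' Partitions the gene universe into the 2x2 table
#' (DEG, non-DEG) x (TE within the window, none), using the proximity table
#' from [nearestTE()]. Degenerate margins (all genes DEG, or no gene near
#' any TE) are flagged.
#'
#' @param prox proximity table from [nearestTE()].
#' @param degs DEG gene ids (must be a subset of `universe`).
#' @param universe all gene ids.
#' @return 2x2 integer matrix with a `degenerate` attribute; rows
#'   DEG/non-DEG, columns TE-near/TE-far; the cells sum to
#'   `length(universe)`.
#' @export
proximityCounts <- function(prox, degs, universe) {
  stopifnot(all(degs %in% universe))
  nearGenes <- unique(prox$gene_id[prox$within_window])
  isDeg <- universe %in% degs
  isNear <- universe %in% nearGenes
  tab <- matrix(c(sum(isDeg & isNear), sum(isDeg & !isNear),
                  sum(!isDeg & isNear), sum(!isDeg & !isNear)),
                2, 2, byrow = TRUE,
                dimnames = list(c("DEG", "nonDEG"), c("TE_near", "TE_far")))
  attr(tab, "degenerate") <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  tab
}

#' Pearson chi-square test of a 2x2 table
#'
#' Without continuity correction by default (the correction is available as
#' a mode). A zero margin is an error.
#'
#' @param table 2x2 matrix of counts.
#' @param correct apply Yates continuity correction.
#' @return list(statistic, df, p).
#' @examples
#' chiSquare2x2(matrix(c(30, 10, 20, 40), 2))
#' @export
chiSquare2x2 <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == 2))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("zero margin: chi-square test undefined")
  }
  ct <- suppressWarnings(chisq.test(table, correct = correct))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

#' Post hoc standardized residuals of a contingency table
#'
#' Per cell: `Z = (O - E) / sqrt(E (1 - row_p)(1 - col_p))` (the
#' standardized Pearson residual), a two-sided normal p-value, and
#' Bonferroni adjustment across the cells. A cell is labelled enriched
#' (Z > 0) or depleted (Z < 0) when its adjusted p is below `alpha`. For a
#' 2x2 table at alpha 0.05 the implied critical |Z| is 2.497705
#' (Bonferroni-corrected p of 0.0125).
#'
#' @param table contingency matrix.
#' @param alpha significance level before Bonferroni division (default
#'   0.05).
#' @return data.frame: row, col, observed, expected, z, p, p_adj, direction
#'   (`"enriched"`, `"depleted"` or `"ns"`).
#' @export
posthocResiduals <- function(table, alpha = 0.05) {
  O <- as.matrix(table)
  n <- sum(O)
  rp <- rowSums(O) / n
  cp <- colSums(O) / n
  E <- outer(rowSums(O), colSums(O)) / n
  Z <- (O - E) / sqrt(E * outer(1 - rp, 1 - cp))
  m <- length(O)
  p <- 2 * pnorm(abs(Z), lower.tail = FALSE)
  pAdj <- pmin(p * m, 1)
  idx <- expand.grid(row = rownames(O) %||% seq_len(nrow(O)),
                     col = colnames(O) %||% seq_len(ncol(O)))
  data.frame(idx,
             observed = as.vector(O), expected = as.vector(E),
             z = as.vector(Z), p = as.vector(p), p_adj = as.vector(pAdj),
             direction = ifelse(as.vector(pAdj) >= alpha, "ns",
                                ifelse(as.vector(Z) > 0, "enriched",
                                       "depleted")))
}

#' Critical Z for Bonferroni-corrected cell residuals
#'
#' The standard-normal quantile at `1 - (alpha / m) / 2`: the absolute
#' residual above which a cell is significant after Bonferroni correction
#' over `m` cells at family level `alpha`.
#'
#' @param alpha family-wise significance level.
#' @param m number of cells tested.
#' @return Critical |Z|.
#' @examples
#' criticalZ(0.05, 4)  # 2.497705
#' @export
criticalZ <- function(alpha, m) {
  stopifnot(alpha > 0, alpha < 1, m >= 1)
  qnorm(1 - (alpha / m) / 2)
}
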