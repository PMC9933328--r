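# Independent oracles used across the suite. Each re-derives the quantity by
# a route separate from the package implementation (enumeration, brute force,
# or the published algorithm coded from its description).

# exhaustive enumeration of all antiparallel pairings (gaps <= 1 per side)
# under the same parameter table as the DP
oracleDuplex <- function(query, target, params = duplexParams()) {
  codeOf <- function(s) {
    match(strsplit(chartr("tT", "uU", toupper(s)), "")[[1]],
          c("A", "C", "G", "U")) - 1L
  }
  pairNames <- c("AU", "CG", "GC", "GU", "UA", "UG")
  pairOf <- function(a, b) {
    key <- paste0(c("A", "C", "G", "U")[a + 1], c("A", "C", "G", "U")[b + 1])
    if (key %in% pairNames) key else NA_character_
  }
  q <- codeOf(query)
  r <- rev(codeOf(target))
  m <- length(q); n <- length(r)
  pr <- matrix(NA_character_, m, n)
  for (i in seq_len(m)) for (j in seq_len(n)) pr[i, j] <- pairOf(q[i], r[j])
  best <- Inf
  steps <- list(c(1, 1), c(2, 1), c(1, 2), c(2, 2))
  dfs <- function(i, j, e) {
    best <<- min(best, e + params$endPen[[pr[i, j]]])
    for (st in steps) {
      i2 <- i + st[1]; j2 <- j + st[2]
      if (i2 <= m && j2 <= n && !is.na(pr[i2, j2])) {
        add <- if (st[1] == 1 && st[2] == 1) {
          params$stacks[pr[i, j], pr[i2, j2]]
        } else if (st[1] == 2 && st[2] == 2) {
          params$loop11
        } else {
          params$bulge1 + params$stacks[pr[i, j], pr[i2, j2]]
        }
        dfs(i2, j2, e + add)
      }
    }
  }
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      if (!is.na(pr[i, j])) dfs(i, j, params$init + params$endPen[[pr[i, j]]])
    }
  }
  if (is.infinite(best)) NULL else best
}

# maximal cliques by exhaustive subset enumeration (n <= 15 or so)
bruteCliques <- function(adj) {
  n <- nrow(adj)
  stopifnot(n <= 15)
  cliques <- list()
  for (mask in seq_len(2^n - 1)) {
    mem <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    k <- length(mem)
    if (k > 1 && !all(adj[mem, mem][upper.tri(diag(k))])) next
    # maximal iff no outside vertex is adjacent to every member
    ext <- setdiff(seq_len(n), mem)
    if (length(ext) && any(colSums(adj[mem, ext, drop = FALSE]) == k)) next
    cliques[[length(cliques) + 1L]] <- mem
  }
  cliques
}

bruteMCC <- function(adj) {
  cl <- bruteCliques(adj)
  mcc <- numeric(nrow(adj))
  for (c0 in cl) mcc[c0] <- mcc[c0] + factorial(length(c0) - 1)
  mcc
}

# all-pairs quadratic scan for gene-TE gap distances
bruteNearestFlags <- function(geneStart, geneEnd, teStart, teEnd, window) {
  vapply(seq_along(geneStart), function(i) {
    if (!length(teStart)) return(FALSE)
    gaps <- vapply(seq_along(teStart), function(j) {
      if (teEnd[j] < geneStart[i]) geneStart[i] - teEnd[j] - 1
      else if (teStart[j] > geneEnd[i]) teStart[j] - geneEnd[i] - 1
      else 0
    }, numeric(1))
    any(gaps <= window)
  }, logical(1))
}

bruteNearestMin <- function(gs, ge, teStart, teEnd) {
  if (!length(teStart)) return(NA_real_)
  gaps <- ifelse(teEnd < gs, gs - teEnd - 1,
                 ifelse(teStart > ge, teStart - ge - 1, 0))
  sign <- ifelse(teEnd < gs & gaps > 0, -1, 1)
  (sign * gaps)[which.min(abs(gaps))]
}

# weighted trimmed-mean-of-M-values scaling, coded from the published
# algorithm (reference = sample with upper quartile closest to the mean;
# 30% log-ratio and 5% log-intensity trim; precision weighting; geometric
# mean 1)
textbookTMM <- function(counts, logratioTrim = 0.3, sumTrim = 0.05) {
  counts <- as.matrix(counts)
  lib <- colSums(counts)
  uq <- apply(sweep(counts, 2, lib, "/"), 2, quantile, probs = 0.75)
  ref <- which.min(abs(uq - mean(uq)))
  oneFactor <- function(obs, refv, nO, nR) {
    keep0 <- obs > 0 & refv > 0
    obs <- obs[keep0]; refv <- refv[keep0]
    logR <- log2((obs / nO) / (refv / nR))
    absE <- (log2(obs / nO) + log2(refv / nR)) / 2
    v <- (nO - obs) / nO / obs + (nR - refv) / nR / refv
    n <- length(logR)
    loL <- floor(n * logratioTrim) + 1; hiL <- n + 1 - loL
    loS <- floor(n * sumTrim) + 1; hiS <- n + 1 - loS
    keep <- rank(logR) >= loL & rank(logR) <= hiL &
      rank(absE) >= loS & rank(absE) <= hiS
    2^(sum(logR[keep] / v[keep]) / sum(1 / v[keep]))
  }
  f <- vapply(seq_len(ncol(counts)), function(j) {
    oneFactor(counts[, j], counts[, ref], lib[j], lib[ref])
  }, numeric(1))
  f / exp(mean(log(f)))
}

# random simple graph as an adjacency matrix plus the matching igraph
randomGraph <- function(n, p) {
  adj <- matrix(FALSE, n, n)
  adj[upper.tri(adj)] <- runif(n * (n - 1) / 2) < p
  adj <- adj | t(adj)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::V(g)$name <- sprintf("n%02d", seq_len(n))
  list(adj = adj, g = g)
}

randomRNA <- function(len) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}
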