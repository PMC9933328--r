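#' Simulate interval mortality tables
#'
#' Draws, for each strain and replicate, cumulative death counts at every
#' survival checkpoint from the interval probabilities of a probit model:
#' `P(dead by t) = Phi(b * (log10 t - log10 LT50))`. Deaths are simulated on
#' the interval scale (newly dead between consecutive checks follow a
#' multinomial), matching how the assay records data. Control replicates
#' apply a per-fly binomial death probability with a uniformly drawn death
#' time.
#'
#' @param cfg a [SimConfig-class]; an infinite `probitSlope` gives the
#'   degenerate step mortality curve.
#' @return A list with `table` (a [MortalityTable-class]) and `truth`
#'   (data.frame of `strain`, `lt50_true`).
#' @examples
#' sim <- genMortality(simConfig(seed = 1, nStrains = 4))
#' sim$truth
#' @export
genMortality <- function(cfg) {
  stopifnot(is(cfg, "SimConfig"))
  validObject(cfg)
  set.seed(childSeed(cfg@seed, "mortality"))
  times <- cfg@checkpointTimes
  strains <- sprintf("strain%03d", seq_len(cfg@nStrains))
  lt50s <- if (length(cfg@trueLT50) == cfg@nStrains) cfg@trueLT50 else
    runif(cfg@nStrains, min(cfg@trueLT50), max(cfg@trueLT50))
  n <- cfg@nFliesPerRep

  cumP <- function(lt50) {
    if (is.infinite(cfg@probitSlope)) {
      as.numeric(times >= lt50)
    } else {
      pnorm(cfg@probitSlope * (log10(times) - log10(lt50)))
    }
  }

  rows <- vector("list", cfg@nStrains * cfg@nReps * 2L)
  idx <- 0L
  for (s in seq_len(cfg@nStrains)) {
    p <- cumP(lt50s[s])
    intProbs <- c(p[1], diff(p), 1 - p[length(p)])  # cells + right-censored
    for (rep in seq_len(cfg@nReps)) {
      newly <- as.vector(rmultinom(1, n, intProbs))
      cum <- cumsum(newly[seq_along(times)])
      idx <- idx + 1L
      rows[[idx]] <- data.frame(
        strain = strains[s], replicate = rep, condition = "treated",
        time_h = times, cum_dead = cum, n_start = n, n_injured = 0L)
      # control vial: per-fly binomial death with uniform death time
      deadCtl <- rbinom(1, n, cfg@controlMortalityRate)
      when <- if (deadCtl > 0) sample(seq_along(times), deadCtl, replace = TRUE) else integer(0)
      cumCtl <- cumsum(tabulate(when, nbins = length(times)))
      idx <- idx + 1L
      rows[[idx]] <- data.frame(
        strain = strains[s], replicate = rep, condition = "control",
        time_h = times, cum_dead = cumCtl, n_start = n, n_injured = 0L)
    }
  }
  list(table = MortalityTable(do.call(rbind, rows)),
       truth = data.frame(strain = strains, lt50_true = lt50s))
}

#' Simulate an RNA-seq count matrix with planted, clustered DE genes
#'
#' Negative-binomial counts for a design of 3 tolerant and 3 sensitive
#' strains, control and stress conditions, and `cfg@nReps` replicates.
#' A `deFraction` subset of genes carries a `log2Effect` stress effect,
#' 90% of them downregulated by default (mirroring the observed asymmetry of
#' desiccation responses). Planted DE genes occupy contiguous blocks of the
#' gene order: the ordered-gene-list method assumes functionally related
#' (hence co-responding) genes are neighbours, and the generator emulates
#' exactly that structure.
#'
#' Replicate-level biological variation is simulated at two scales: the
#' negative-binomial dispersion per gene, and a log-normal activity factor
#' shared by contiguous co-expression modules of `moduleSize` genes
#' (transcriptional programs fluctuate together between replicates; without
#' this, window-averaged profiles would be unrealistically noise-free).
#'
#' @param cfg a [SimConfig-class].
#' @param downFraction fraction of DE genes that go down under stress.
#' @param nBlocks number of contiguous DE blocks along the gene order.
#' @param moduleSize genes per co-expression module for replicate-level
#'   module noise.
#' @param moduleSd standard deviation (log2) of the module activity factor.
#' @return A list with `se` (a
#'   [SummarizedExperiment::SummarizedExperiment-class] of counts with
#'   `strain`, `phenotype`, `condition`, `replicate` column data) and `truth`
#'   (list: `deGenes`, `direction`, `blocks` data.frame of 1-based spans).
#' @examples
#' sim <- genExpression(simConfig(seed = 7, nGenes = 200))
#' table(sim$truth$direction)
#' @export
genExpression <- function(cfg, downFraction = 0.9, nBlocks = 2L,
                          moduleSize = 50L, moduleSd = 0.15) {
  stopifnot(is(cfg, "SimConfig"))
  validObject(cfg)
  set.seed(childSeed(cfg@seed, "expression"))
  nG <- cfg@nGenes
  genes <- sprintf("gene%05d", seq_len(nG))
  strains <- c(paste0("T", 1:3), paste0("S", 1:3))
  samples <- expand.grid(replicate = seq_len(cfg@nReps),
                         condition = c("control", "stress"),
                         strain = strains, stringsAsFactors = FALSE)
  samples$phenotype <- ifelse(grepl("^T", samples$strain), "tolerant", "sensitive")
  samples$sample <- with(samples, paste(strain, condition, replicate, sep = "."))

  nDE <- round(cfg@deFraction * nG)
  blocks <- data.frame(start = integer(0), end = integer(0))
  deIdx <- integer(0)
  if (nDE > 0) {
    nBlocks <- max(1L, min(nBlocks, nDE))
    sizes <- rep(nDE %/% nBlocks, nBlocks)
    sizes[seq_len(nDE %% nBlocks)] <- sizes[seq_len(nDE %% nBlocks)] + 1L
    # place blocks at well-separated anchors along the order
    anchors <- floor(nG * (seq_len(nBlocks) - 0.5) / nBlocks)
    starts <- pmax(1L, pmin(nG - sizes + 1L, anchors - sizes %/% 2L))
    blocks <- data.frame(start = as.integer(starts),
                         end = as.integer(starts + sizes - 1L))
    deIdx <- unlist(Map(seq, blocks$start, blocks$end))
  }
  direction <- rep("none", nG)
  if (length(deIdx)) {
    down <- runif(length(deIdx)) < downFraction
    direction[deIdx] <- ifelse(down, "down", "up")
  }
  if (cfg@log2Effect == 0) {
    deIdx <- integer(0)
    direction <- rep("none", nG)
    blocks <- data.frame(start = integer(0), end = integer(0))
  }

  baseMu <- 2^runif(nG, 3, 9)
  counts <- matrix(0L, nG, nrow(samples),
                   dimnames = list(genes, samples$sample))
  fcMat <- matrix(1, nG, nrow(samples))
  stressCols <- samples$condition == "stress"
  lfc <- ifelse(direction == "down", -cfg@log2Effect,
                ifelse(direction == "up", cfg@log2Effect, 0))
  fcMat[, stressCols] <- 2^lfc
  mu <- baseMu * fcMat
  if (moduleSd > 0) {
    module <- ceiling(seq_len(nG) / moduleSize)
    modFac <- matrix(2^rnorm(max(module) * nrow(samples), 0, moduleSd),
                     max(module), nrow(samples))
    mu <- mu * modFac[module, ]
  }
  if (cfg@nbDispersion == 0) {
    counts[] <- rpois(length(mu), mu)
  } else {
    counts[] <- rnbinom(length(mu), mu = mu, size = 1 / cfg@nbDispersion)
  }

  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(samples, row.names = samples$sample),
    rowData = S4Vectors::DataFrame(gene = genes, de = direction != "none",
                                   direction = direction))
  list(se = se,
       truth = list(deGenes = genes[deIdx], direction = direction,
                    blocks = blocks))
}

#' Simulate a planted-partition PPI graph and its gene order
#'
#' Builds a modular undirected graph (dense within modules, sparse between)
#' with integer confidence scores on the 0-1000 scale, together with a gene
#' order that keeps module members contiguous, optionally perturbed by random
#' swaps.
#'
#' @param cfg a [SimConfig-class] (only the seed is consumed).
#' @param nModules,moduleSize module layout; total nodes =
#'   `nModules * moduleSize` (must be >= 10).
#' @param pWithin,pBetween edge probabilities within / between modules.
#' @param shuffle number of random pairwise swaps applied to the
#'   module-contiguous order (0 = perfectly contiguous).
#' @return A list with `graph` (igraph, `score` edge attribute) and `order`
#'   (character vector of gene ids).
#' @examples
#' w <- genPPIOrder(simConfig(seed = 2), nModules = 2, moduleSize = 5,
#'                  pBetween = 0)
#' igraph::count_components(w$graph)
#' @export
genPPIOrder <- function(cfg, nModules = 10L, moduleSize = 10L,
                        pWithin = 0.8, pBetween = 0.01, shuffle = 0L) {
  stopifnot(is(cfg, "SimConfig"))
  n <- nModules * moduleSize
  stopifnot(n >= 10L)
  set.seed(childSeed(cfg@seed, "ppi"))
  genes <- sprintf("gene%05d", seq_len(n))
  module <- rep(seq_len(nModules), each = moduleSize)
  pairs <- t(utils::combn(n, 2))
  same <- module[pairs[, 1]] == module[pairs[, 2]]
  p <- ifelse(same, pWithin, pBetween)
  keep <- runif(nrow(pairs)) < p
  el <- pairs[keep, , drop = FALSE]
  score <- integer(nrow(el))
  sameKept <- same[keep]
  score[sameKept] <- sample(800:1000, sum(sameKept), replace = TRUE)
  score[!sameKept] <- sample(150:799, sum(!sameKept), replace = TRUE)
  g <- igraph::graph_from_edgelist(
    cbind(genes[el[, 1]], genes[el[, 2]]), directed = FALSE)
  g <- igraph::add_vertices(g, sum(!genes %in% igraph::V(g)$name),
                            name = genes[!genes %in% igraph::V(g)$name])
  igraph::E(g)$score <- score
  ord <- genes  # module members contiguous by construction
  if (shuffle > 0) {
    for (k in seq_len(shuffle)) {
      ij <- sample(n, 2)
      ord[ij] <- ord[rev(ij)]
    }
  }
  list(graph = g, order = ord)
}

# sample one GC-rich 12-nt seed whose perfect duplex is stable
.sampleStableSeed <- function(seedLen, maxEnergy, params) {
  for (try in 1:500) {
    s <- paste(sample(c("A", "C", "G", "U"), seedLen, replace = TRUE,
                      prob = c(0.12, 0.33, 0.42, 0.13)), collapse = "")
    if (perfectDuplexEnergy(s, params) <= maxEnergy) return(s)
  }
  stop("could not sample a stable seed; relax maxEnergy")
}

.revCompRNA <- function(s) {
  chartr("ACGU", "UGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

#' Simulate the tRNA / tRF / transcript world with planted targets
#'
#' Generates mature tRNA sequences ending in CCA; tRF records of the three
#' positional classes (5', 3', 3'-CCA) with lengths 17-30 nt; decoy
#' transcripts; and planted target sites: a `plantedTargetFraction` subset of
#' transcripts carries the exact reverse complement of the 12-nt seed of one
#' dedicated 5' tRF. Per-replicate fragment counts encode a per-phenotype
#' targeting state (control-only = loss under stress, stress-only = gain,
#' both, or none), noiselessly by default: counts are `onCount` in "on"
#' cells and 0 elsewhere, so the read filter recovers the planted truth
#' exactly.
#'
#' Planted seeds are rejection-sampled to form stable perfect duplexes
#' (energy at most `seedMaxEnergy`), and decoy transcripts are
#' rejection-sampled to contain no non-planted site scoring at or below
#' `decoyThreshold`, so planted truth is exactly recoverable at any seed.
#'
#' @param cfg a [SimConfig-class]; requires
#'   `nTrnas >= round(plantedTargetFraction * nTranscripts)`.
#' @param transcriptLen decoy transcript length (nt).
#' @param seedLen seed length used for planting (12, matching the analysis).
#' @param seedMaxEnergy stability bound for planted seeds (kcal/mol).
#' @param decoyThreshold energy at/below which a decoy site would count as a
#'   spurious hit; decoys are resampled until clean.
#' @param onCount reads per replicate in targeted states.
#' @param noise logical; add Poisson jitter to nonzero counts (off by
#'   default: the truth-recovery contract is stated for noiseless counts).
#' @return A list: `trna`, `transcripts` (named
#'   [Biostrings::RNAStringSet-class]), `fragments` (data.frame: fragment id,
#'   parent tRNA, class, sequence), `counts` (fragments x samples matrix),
#'   `samples` (data.frame: sample, phenotype, condition, replicate) and
#'   `truth` (data.frame: transcript, fragment, phenotype, state).
#' @examples
#' w <- genTrnaWorld(simConfig(seed = 3, nTrnas = 4, nTranscripts = 6))
#' head(w$truth)
#' @export
genTrnaWorld <- function(cfg, transcriptLen = 300L, seedLen = 12L,
                         seedMaxEnergy = -25, decoyThreshold = -20,
                         onCount = 100L, noise = FALSE) {
  stopifnot(is(cfg, "SimConfig"))
  validObject(cfg)
  set.seed(childSeed(cfg@seed, "trna"))
  params <- duplexParams()
  nT <- cfg@nTrnas
  nTx <- cfg@nTranscripts
  nPlanted <- round(cfg@plantedTargetFraction * nTx)
  if (nPlanted > nT) stop("need nTrnas >= planted transcript count")

  bases <- c("A", "C", "G", "U")
  trnaSeqs <- character(nT)
  seeds <- character(nT)
  for (i in seq_len(nT)) {
    seeds[i] <- .sampleStableSeed(seedLen, seedMaxEnergy, params)
    body <- paste(sample(bases, sample(55:61, 1), replace = TRUE), collapse = "")
    trnaSeqs[i] <- paste0(seeds[i], body, "CCA")
  }
  trnaIds <- sprintf("tRNA%02d", seq_len(nT))
  names(trnaSeqs) <- trnaIds

  # one fragment of each class per tRNA; 5' fragments start at position 1
  frags <- do.call(rbind, lapply(seq_len(nT), function(i) {
    L <- nchar(trnaSeqs[i])
    len5 <- sample(17:30, 1)
    len3 <- sample(17:30, 1)
    lenC <- sample(17:30, 1)
    data.frame(
      fragment = sprintf("%s.%s", trnaIds[i], c("5p", "3p", "cca")),
      trna = trnaIds[i],
      class = c("five_prime", "three_prime", "cca"),
      sequence = c(substr(trnaSeqs[i], 1, len5),
                   substr(trnaSeqs[i], L - 3 - len3 + 1, L - 3),
                   substr(trnaSeqs[i], L - lenC + 1, L)),
      stringsAsFactors = FALSE)
  }))

  txIds <- sprintf("tx%03d", seq_len(nTx))
  plantedTx <- if (nPlanted > 0) sort(sample(nTx, nPlanted)) else integer(0)
  plantedFrag <- if (nPlanted > 0) sample(nT, nPlanted) else integer(0)

  randomCleanTx <- function(len, forbidSeeds) {
    for (try in 1:200) {
      s <- paste(sample(bases, len, replace = TRUE), collapse = "")
      ok <- TRUE
      for (sd in forbidSeeds) {
        h <- duplexMFE(sd, s, params)
        if (!is.null(h) && h$mfe <= decoyThreshold) { ok <- FALSE; break }
      }
      if (ok) return(s)
    }
    stop("could not sample a clean decoy transcript")
  }

  txSeqs <- character(nTx)
  for (j in seq_len(nTx)) {
    s <- randomCleanTx(transcriptLen, seeds)
    if (j %in% plantedTx) {
      f <- plantedFrag[match(j, plantedTx)]
      site <- .revCompRNA(seeds[f])
      pos <- sample(seq_len(transcriptLen - nchar(site) + 1), 1)
      s <- paste0(substr(s, 1, pos - 1), site,
                  substr(s, pos + nchar(site), transcriptLen))
      # the insertion may create a site for another seed; re-check and retry
      for (sd in setdiff(seeds, seeds[f])) {
        h <- duplexMFE(sd, s, params)
        if (!is.null(h) && h$mfe <= decoyThreshold) {
          s <- NA_character_
          break
        }
      }
      while (is.na(s)) {
        s0 <- randomCleanTx(transcriptLen, seeds)
        pos <- sample(seq_len(transcriptLen - nchar(site) + 1), 1)
        s <- paste0(substr(s0, 1, pos - 1), site,
                    substr(s0, pos + nchar(site), transcriptLen))
        for (sd in setdiff(seeds, seeds[f])) {
          h <- duplexMFE(sd, s, params)
          if (!is.null(h) && h$mfe <= decoyThreshold) { s <- NA_character_; break }
        }
      }
    }
    txSeqs[j] <- s
  }
  names(txSeqs) <- txIds

  samples <- expand.grid(replicate = seq_len(3L),
                         condition = c("control", "stress"),
                         phenotype = c("tolerant", "sensitive"),
                         stringsAsFactors = FALSE)
  samples$sample <- with(samples, paste(phenotype, condition, replicate, sep = "."))

  states <- c("none", "control_only", "stress_only", "both")
  counts <- matrix(0L, nrow(frags), nrow(samples),
                   dimnames = list(frags$fragment, samples$sample))
  # background fragments are expressed everywhere but target nothing
  bg <- !(frags$class == "five_prime" &
            frags$trna %in% trnaIds[plantedFrag])
  counts[bg, ] <- onCount

  truth <- NULL
  for (m in seq_along(plantedTx)) {
    fr <- sprintf("%s.5p", trnaIds[plantedFrag[m]])
    tx <- txIds[plantedTx[m]]
    for (ph in c("tolerant", "sensitive")) {
      st <- sample(states, 1, prob = c(0.1, 0.3, 0.3, 0.3))
      on <- switch(st, none = character(0), control_only = "control",
                   stress_only = "stress", both = c("control", "stress"))
      cols <- samples$phenotype == ph & samples$condition %in% on
      counts[fr, cols] <- onCount
      truth <- rbind(truth, data.frame(transcript = tx, fragment = fr,
                                       phenotype = ph, state = st,
                                       stringsAsFactors = FALSE))
    }
  }
  if (noise) {
    nz <- counts > 0
    counts[nz] <- rpois(sum(nz), counts[nz])
  }

  list(trna = Biostrings::RNAStringSet(trnaSeqs),
       transcripts = Biostrings::RNAStringSet(txSeqs),
       fragments = frags, counts = counts, samples = samples,
       truth = truth %||% data.frame(transcript = character(0),
                                     fragment = character(0),
                                     phenotype = character(0),
                                     state = character(0)))
}

#' Simulate gene and transposable-element annotations
#'
#' Places non-overlapping genes on one synthetic chromosome (2 kb genes
#' separated by 4 kb), labels a `deFraction` subset as differentially
#' expressed, and drops TEs whose placement is enriched (or depleted) near
#' DE-labelled genes by `enrichmentFactor`: each TE picks a gene uniformly
#' and lands within 1 kb of it with probability `pNear` scaled by the factor
#' for DE genes, otherwise in the deep-intergenic background (> 1 kb from
#' every gene). `enrichmentFactor = 1` gives exact independence of DE status
#' and TE proximity.
#'
#' @param cfg a [SimConfig-class].
#' @param pNear baseline probability that a TE lands near its chosen gene.
#' @param teLenRange TE length range in bp (minimum 120, the annotation
#'   cutoff below which TEs are discarded).
#' @return A list with `genes` and `tes`
#'   ([GenomicRanges::GRanges-class] with `feature_id` metadata) and `degs`
#'   (character vector of DE gene ids).
#' @examples
#' w <- genTEAnnotation(simConfig(seed = 5, nGenes = 50, teDensity = 50))
#' length(w$tes)
#' @export
genTEAnnotation <- function(cfg, pNear = 0.3, teLenRange = c(120, 1000)) {
  stopifnot(is(cfg, "SimConfig"))
  validObject(cfg)
  if (cfg@teDensity < 0) stop("te_density must be >= 0")
  set.seed(childSeed(cfg@seed, "te"))
  nG <- cfg@nGenes
  geneLen <- 2000L
  gap <- 4000L
  pitch <- geneLen + gap
  chromLen <- nG * pitch
  geneStart <- (seq_len(nG) - 1L) * pitch + 1L  # 1-based closed internal
  geneIds <- sprintf("gene%05d", seq_len(nG))
  degs <- sort(sample(nG, round(cfg@deFraction * nG)))
  genes <- GenomicRanges::GRanges(
    "chrSyn", IRanges::IRanges(geneStart, geneStart + geneLen - 1L),
    strand = sample(c("+", "-"), nG, replace = TRUE),
    feature_id = geneIds)

  nTE <- round(cfg@teDensity * chromLen / 1e6)
  if (nTE == 0) {
    tes <- GenomicRanges::GRanges(seqnames = character(0),
                                  ranges = IRanges::IRanges(),
                                  feature_id = character(0))
    return(list(genes = genes, tes = tes, degs = geneIds[degs]))
  }
  teLen <- round(runif(nTE, teLenRange[1], teLenRange[2]))
  host <- sample(nG, nTE, replace = TRUE)
  pHere <- pmin(1, pNear * ifelse(host %in% degs, cfg@enrichmentFactor, 1))
  near <- runif(nTE) < pHere
  teStart <- integer(nTE)
  for (i in seq_len(nTE)) {
    g0 <- geneStart[host[i]]
    if (near[i]) {
      # anywhere overlapping the gene or within 1 kb of it
      lo <- max(1L, g0 - 1000L - teLen[i] + 1L)
      hi <- min(chromLen - teLen[i] + 1L, g0 + geneLen - 1L + 1000L)
    } else {
      # deep intergenic: strictly > 1 kb from the host gene and its neighbour
      lo <- g0 + geneLen + 1001L
      hi <- g0 + pitch - 1001L - teLen[i]
      if (hi < lo) { lo <- g0 + geneLen + 1001L; hi <- lo }
    }
    teStart[i] <- round(runif(1, lo, hi))
  }
  ord <- order(teStart)
  tes <- GenomicRanges::GRanges(
    "chrSyn", IRanges::IRanges(teStart[ord], teStart[ord] + teLen[ord] - 1L),
    strand = "+",
    feature_id = sprintf("TE%05d", seq_len(nTE)))
  list(genes = genes, tes = tes, degs = geneIds[degs])
}

#' Simulate physiology and cuticular-hydrocarbon tables
#'
#' Generates (i) a gravimetric table: wet/dry masses per replicate of 10
#' flies with group-specific water fractions, and pre/post-stress masses per
#' replicate of 5 flies with group-specific water-loss fractions; (ii) a
#' respirometry table of per-minute CO2 readings with a stabilisation drift
#' during the first hour, strain and replicate random effects, and a
#' condition x phenotype interaction; (iii) a GC-MS peak table with a C7-C30
#' n-alkane ladder, a tridecane internal-standard peak, and 13 compound peaks
#' with group-specific log-normal areas.
#'
#' @param cfg a [SimConfig-class] (seed source).
#' @param waterFraction named group means of water content as a fraction of
#'   wet mass (`tolerant`, `sensitive`).
#' @param lossFraction named group means of the fraction of water content
#'   lost under 3 h of stress.
#' @param respEffects list of respirometry fixed effects: `base` level,
#'   `stress` main effect, `phenotype` main effect, `interaction`
#'   (tolerant x stress), all in ug CO2 / g / min; `interaction = 0` is the
#'   additive null.
#' @param nStrainsPerGroup,nRepsGrav,nRepsResp design sizes.
#' @return A list: `gravimetric` (data.frame), `respirometry` (data.frame of
#'   per-minute readings), `chc` (list with `peaks` and `ladder`
#'   data.frames).
#' @examples
#' p <- genPhysChc(simConfig(seed = 4))
#' head(p$gravimetric)
#' @export
genPhysChc <- function(cfg,
                       waterFraction = c(tolerant = 0.45, sensitive = 0.50),
                       lossFraction = c(tolerant = 0.10, sensitive = 0.15),
                       respEffects = list(base = 4, stress = -0.6,
                                          phenotype = 0.3, interaction = 0.8),
                       nStrainsPerGroup = 10L, nRepsGrav = 10L,
                       nRepsResp = 3L) {
  stopifnot(is(cfg, "SimConfig"))
  set.seed(childSeed(cfg@seed, "physchc"))
  phenos <- c("tolerant", "sensitive")
  strains <- c(sprintf("T%02d", seq_len(nStrainsPerGroup)),
               sprintf("S%02d", seq_len(nStrainsPerGroup)))
  pheno <- rep(phenos, each = nStrainsPerGroup)

  grav <- do.call(rbind, lapply(seq_along(strains), function(i) {
    wf <- waterFraction[[pheno[i]]]
    lf <- lossFraction[[pheno[i]]]
    wet <- rnorm(nRepsGrav, 12, 0.6)                 # mg, 10 flies
    dry <- pmin(wet * (1 - wf) + rnorm(nRepsGrav, 0, 0.12), wet)
    pre <- rnorm(nRepsGrav, 6, 0.3)                  # mg, 5 flies
    post <- pmin(pre - lf * wf * pre + rnorm(nRepsGrav, 0, 0.03), pre)
    data.frame(strain = strains[i], phenotype = pheno[i],
               replicate = seq_len(nRepsGrav),
               wet_mass = wet, dry_mass = dry,
               pre_mass = pre, post_mass = post)
  }))

  respStrains <- c(sprintf("T%02d", 1:3), sprintf("S%02d", 1:3))
  respPheno <- rep(phenos, each = 3)
  minutes <- 0:179
  resp <- do.call(rbind, lapply(seq_along(respStrains), function(i) {
    strRE <- rnorm(1, 0, 0.3)
    do.call(rbind, lapply(seq_len(nRepsResp), function(r) {
      repRE <- rnorm(1, 0, 0.15)
      do.call(rbind, lapply(c("control", "stress"), function(cond) {
        mu <- respEffects$base + strRE + repRE +
          (cond == "stress") * respEffects$stress +
          (respPheno[i] == "tolerant") * respEffects$phenotype +
          (cond == "stress") * (respPheno[i] == "tolerant") *
            respEffects$interaction
        drift <- 1.5 * exp(-minutes / 20)            # settling in hour one
        data.frame(strain = respStrains[i], phenotype = respPheno[i],
                   replicate = r, condition = cond, minute = minutes,
                   co2_rate = mu + drift + rnorm(length(minutes), 0, 0.25))
      }))
    }))
  }))

  # retention-time model: strictly increasing, mildly curved in carbon number
  rtOf <- function(lri) 2 + 1.05 * (lri / 100 - 7) + 0.004 * (lri / 100 - 7)^2
  ladder <- data.frame(carbon = 7:30, rt_min = rtOf(100 * (7:30)))
  compounds <- data.frame(
    compound = c("7-tricosene", "5-tricosene", "tricosane",
                 "2-methyltetracosane", "9-pentacosene", "7-pentacosene",
                 "5-pentacosene", "pentacosane", "7,11-heptacosadiene",
                 "5,9-heptacosadiene", "7-heptacosene", "9,13-nonacosadiene",
                 "7,11-nonacosadiene"),
    lri = c(2279, 2290, 2298, 2464, 2473, 2480, 2482, 2498,
            2657, 2670, 2693, 2841, 2872),
    carbon_class = c("desaturated", "desaturated", "saturated", "saturated",
                     "desaturated", "desaturated", "desaturated", "saturated",
                     "desaturated", "desaturated", "desaturated",
                     "desaturated", "desaturated"),
    chain_length = c(23, 23, 23, 25, 25, 25, 25, 25, 27, 27, 27, 29, 29),
    stringsAsFactors = FALSE)
  # group-specific mean log-areas; a few compounds differ between phenotypes
  shift <- setNames(rep(0, nrow(compounds)), compounds$compound)
  shift[c("5-tricosene", "tricosane", "7-pentacosene")] <- 0.5
  shift[c("7,11-heptacosadiene")] <- -0.4

  nRepsChc <- 3L
  peaks <- do.call(rbind, lapply(seq_along(strains), function(i) {
    do.call(rbind, lapply(seq_len(nRepsChc), function(r) {
      tol <- pheno[i] == "tolerant"
      area <- exp(rnorm(nrow(compounds), 6 + if (tol) shift else 0, 0.3))
      isArea <- exp(rnorm(1, 6.2, 0.2))
      data.frame(strain = strains[i], phenotype = pheno[i], replicate = r,
                 compound = c("tridecane_IS", compounds$compound),
                 rt_min = c(rtOf(1300), rtOf(compounds$lri)),
                 area = c(isArea, area),
                 is_internal_standard = c(TRUE, rep(FALSE, nrow(compounds))),
                 carbon_class = c("saturated", compounds$carbon_class),
                 chain_length = c(13, compounds$chain_length))
    }))
  }))

  list(gravimetric = grav, respirometry = resp,
       chc = list(peaks = peaks, ladder = ladder))
}
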