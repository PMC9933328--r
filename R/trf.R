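#' Classify a tRNA fragment by its position on the mature tRNA
#'
#' A fragment is `five_prime` when it starts at the tRNA 5' end, `cca` when
#' it ends at the 3' end (including the post-transcriptional CCA),
#' `three_prime` when it ends exactly 3 nt before the 3' end (abutting the
#' CCA), and `internal` otherwise (internal fragments are excluded from
#' target prediction). A fragment matching at several positions is assigned
#' every matching class and flagged ambiguous.
#'
#' @param fragment fragment sequence (RNA or DNA alphabet).
#' @param trna mature tRNA sequence ending in CCA.
#' @return Character vector of classes (usually length 1) with an
#'   `ambiguous` attribute.
#' @examples
#' classifyFragment("GGAUUCGAUCCGGGAUU", paste0("GGAUUCGAUCCGGGAUU",
#'                  strrep("A", 50), "CCA"))
#' @export
classifyFragment <- function(fragment, trna) {
  f <- chartr("tT", "uU", toupper(fragment))
  s <- chartr("tT", "uU", toupper(trna))
  if (!endsWith(s, "CCA")) stop("mature tRNA must end in CCA")
  L <- nchar(s)
  hits <- gregexpr(f, s, fixed = TRUE)[[1]]
  if (hits[1] == -1) stop("fragment is not a substring of the tRNA")
  classes <- vapply(hits, function(st) {
    en <- st + nchar(f) - 1L
    if (st == 1L) "five_prime"
    else if (en == L) "cca"
    else if (en == L - 3L) "three_prime"
    else "internal"
  }, character(1))
  out <- unique(classes)
  attr(out, "ambiguous") <- length(hits) > 1L
  out
}

#' Extract the seed of a tRNA fragment
#'
#' The 5'-most `seedLen` nucleotides (the seed region used as the query for
#' target prediction). Fragments shorter than the seed are excluded with a
#' warning (returns `NA`).
#'
#' @param sequence fragment sequence.
#' @param seedLen seed length (study: 12 nt).
#' @return Seed string, or `NA_character_` for a too-short fragment.
#' @examples
#' extractSeed("GGAUUCGAUCCGGGAUUCCA")
#' @export
extractSeed <- function(sequence, seedLen = 12L) {
  s <- chartr("tT", "uU", toupper(sequence))
  if (nchar(s) < seedLen) {
    warning("fragment shorter than the seed length; excluded")
    return(NA_character_)
  }
  substr(s, 1, seedLen)
}

#' Predict tRF targets by seed-anchored duplex energy
#'
#' For every fragment of the selected classes, hybridises the fragment's
#' 12-nt seed against each transcript with [duplexMFE()] and keeps the best
#' site when its energy is at or below `mfeThreshold`. Only 5' fragments are
#' used by default (most tRFs derive from the 5' terminus); the stringent
#' -30 kcal/mol cut is the default, with -20 available as the explored
#' compatibility mode. At most one hit per (fragment, transcript).
#'
#' @param fragments data.frame with columns `fragment`, `class`, `sequence`
#'   (as produced by [genTrnaWorld()]).
#' @param transcripts named character vector or
#'   [Biostrings::RNAStringSet-class].
#' @param mfeThreshold hit threshold in kcal/mol (default -30).
#' @param classes fragment classes entering prediction.
#' @param seedLen seed length (default 12).
#' @param params duplex parameters, see [duplexParams()].
#' @return data.frame of hits: fragment, transcript, t_start, t_end
#'   (0-based half-open), mfe.
#' @export
predictTargets <- function(fragments, transcripts, mfeThreshold = -30,
                           classes = "five_prime", seedLen = 12L,
                           params = duplexParams()) {
  txt <- as.character(transcripts)
  stopifnot(!is.null(names(txt)))
  use <- fragments[fragments$class %in% classes, , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(use))) {
    seed <- suppressWarnings(extractSeed(use$sequence[i], seedLen))
    if (is.na(seed)) next
    for (tx in names(txt)) {
      h <- duplexMFE(seed, txt[[tx]], params)
      if (!is.null(h) && h$mfe <= mfeThreshold) {
        rows[[length(rows) + 1L]] <- data.frame(
          fragment = use$fragment[i], transcript = tx,
          t_start = h$t_start, t_end = h$t_end, mfe = h$mfe,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(fragment = character(0), transcript = character(0),
                      t_start = integer(0), t_end = integer(0),
                      mfe = numeric(0)))
  }
  do.call(rbind, rows)
}

#' Replicate read filter: targeted transcripts per phenotype and condition
#'
#' A transcript counts as targeted in a (phenotype, condition) state iff it
#' has at least one predicted hit and the reads of its hitting fragments
#' reach `minReads` in every one of the state's `nReps` replicates. The
#' default mode sums reads over all fragments hitting the transcript; the
#' `"per_fragment"` mode instead requires a single fragment to clear the
#' threshold in every replicate.
#'
#' @param hits hit table from [predictTargets()].
#' @param counts fragments x samples count matrix.
#' @param samples data.frame with `sample`, `phenotype`, `condition`,
#'   `replicate` matching the count columns.
#' @param minReads per-replicate read threshold (default 10, inclusive).
#' @param nReps required replicate count per state (default 3); states with
#'   fewer replicates are skipped with a warning.
#' @param mode `"sum"` or `"per_fragment"`.
#' @return data.frame: phenotype, condition, transcript (the targeting
#'   states).
#' @export
applyReadFilter <- function(hits, counts, samples, minReads = 10,
                            nReps = 3L, mode = c("sum", "per_fragment")) {
  mode <- match.arg(mode)
  stopifnot(all(c("phenotype", "condition", "replicate", "sample") %in%
                  names(samples)),
            all(samples$sample %in% colnames(counts)))
  out <- list()
  for (ph in unique(samples$phenotype)) {
    for (cond in unique(samples$condition)) {
      cols <- samples$sample[samples$phenotype == ph &
                               samples$condition == cond]
      if (length(cols) < nReps) {
        warning(sprintf("state (%s, %s) has %d < %d replicates; skipped",
                        ph, cond, length(cols), nReps))
        next
      }
      for (tx in unique(hits$transcript)) {
        frs <- intersect(hits$fragment[hits$transcript == tx],
                         rownames(counts))
        if (!length(frs)) next
        sub <- counts[frs, cols, drop = FALSE]
        ok <- if (mode == "sum") {
          all(colSums(sub) >= minReads)
        } else {
          any(apply(sub >= minReads, 1, all))
        }
        if (ok) {
          out[[length(out) + 1L]] <- data.frame(
            phenotype = ph, condition = cond, transcript = tx,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(phenotype = character(0), condition = character(0),
                      transcript = character(0)))
  }
  do.call(rbind, out)
}

#' Gain/loss differential targeting between conditions
#'
#' For one phenotype: `gain` = transcripts targeted under stress but not
#' control; `loss` = targeted under control but not stress. The two sets are
#' disjoint by construction.
#'
#' @param states targeting-state table from [applyReadFilter()].
#' @param phenotype phenotype to compare.
#' @param control,stress condition labels.
#' @return list(gain, loss) of transcript id vectors.
#' @examples
#' st <- data.frame(phenotype = "tolerant",
#'                  condition = c("control", "stress"),
#'                  transcript = c("tx1", "tx2"))
#' differentialTargeting(st, "tolerant")
#' @export
differentialTargeting <- function(states, phenotype,
                                  control = "control", stress = "stress") {
  ctl <- states$transcript[states$phenotype == phenotype &
                             states$condition == control]
  str <- states$transcript[states$phenotype == phenotype &
                             states$condition == stress]
  list(gain = sort(setdiff(str, ctl)), loss = sort(setdiff(ctl, str)))
}

#' Overlap count and percentage of two gene sets
#'
#' `|a intersect b|` and `100 * |a intersect b| / |denominator|`, the
#' percentage rounded to an integer for reporting (full precision is kept
#' in `percent_exact`).
#'
#' @param a,b character vectors (sets).
#' @param denom denominator set: `"smaller"` (default), `"a"` or `"b"`.
#' @return list(count, percent, percent_exact, denom_size).
#' @examples
#' overlapStats(letters[1:10], letters[5:8], denom = "b")
#' @export
overlapStats <- function(a, b, denom = c("smaller", "a", "b")) {
  denom <- match.arg(denom)
  a <- unique(a); b <- unique(b)
  dset <- switch(denom,
                 smaller = if (length(a) <= length(b)) a else b,
                 a = a, b = b)
  if (length(dset) == 0) stop("empty denominator set; overlap undefined")
  k <- length(intersect(a, b))
  pct <- 100 * k / length(dset)
  list(count = k, percent = round(pct), percent_exact = pct,
       denom_size = length(dset))
}
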