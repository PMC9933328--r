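
.desiccatREnv <- new.env(parent = emptyenv())

#' Duplex energy parameters
#'
#' Loads the versioned nearest-neighbour parameter set used by [duplexMFE()]:
#' a Turner-2004-derived RNA/RNA stack table (shipped as a plain-text file in
#' `extdata` so exact energies are reproducible) plus the fixed loop terms.
#' Energies are free energies at 37 degrees C in kcal/mol; more negative is
#' more stable.
#'
#' @return A list with elements `stacks` (6x6 matrix over pair types AU, CG,
#'   GC, GU, UA, UG), `init` (duplex initiation, +4.09), `endPen` (terminal
#'   AU/GU penalty +0.45 per helix end closed by an A-U or G-U pair),
#'   `bulge1` (+3.81 for a 1-nt bulge; the flanking stack is retained),
#'   `loop11` (+1.50 for a 1x1 internal loop, no stack across it) and
#'   `version`.
#' @examples
#' duplexParams()$stacks["GC", "CG"]
#' @export
duplexParams <- function() {
  if (!is.null(.desiccatREnv$duplexParams)) return(.desiccatREnv$duplexParams)
  f <- system.file("extdata", "duplex_stacks_v1.tsv", package = "desiccatR")
  tab <- read.delim(f, comment.char = "#", stringsAsFactors = FALSE)
  pairs <- c("AU", "CG", "GC", "GU", "UA", "UG")
  stacks <- matrix(NA_real_, 6, 6, dimnames = list(pairs, pairs))
  stacks[cbind(tab$p1, tab$p2)] <- tab$dG
  stopifnot(!anyNA(stacks))
  endPen <- c(AU = 0.45, CG = 0, GC = 0, GU = 0.45, UA = 0.45, UG = 0.45)
  p <- list(stacks = stacks, init = 4.09, endPen = endPen,
            bulge1 = 3.81, loop11 = 1.50, version = "v1")
  .desiccatREnv$duplexParams <- p
  p
}

# uppercase, DNA->RNA, validate alphabet; returns integer codes A=0 C=1 G=2 U=3
rnaCodes <- function(seq) {
  s <- chartr("tT", "uU", toupper(as.character(seq)))
  v <- strsplit(s, "")[[1]]
  codes <- match(v, c("A", "C", "G", "U")) - 1L
  if (anyNA(codes)) stop("non-RNA characters in sequence: ", s)
  codes
}

#' Minimum-free-energy hybridisation site of a short RNA on a target
#'
#' Computes the single best antiparallel intermolecular duplex between a
#' short query (a tRF seed) and a target transcript by dynamic programming
#' over Watson-Crick and GU pairs with nearest-neighbour stack energies,
#' allowing bulges and internal loops of at most one nucleotide per side.
#' Intramolecular pairing is not modelled. Equivalent to scanning the target
#' and reporting one best site.
#'
#' @param query RNA string (<= 30 nt; T is read as U).
#' @param target RNA string (<= 18500 nt).
#' @param params parameter list from [duplexParams()].
#' @param maxBulge,maxLoop maximum bulge / internal-loop size per side; only
#'   the value 1 is supported (the shipped parameter set is defined for it).
#' @return A one-row data.frame with columns `mfe` (kcal/mol), `t_start`,
#'   `t_end` (0-based half-open site on the target), `q_start`, `q_end`, and
#'   a `pairs` list-column holding the paired-position map (matrix with
#'   1-based `qpos`, `tpos`), or `NULL` when no pairing exists.
#' @examples
#' duplexMFE("GGGGGGGGGGGG", "AAACCCCCCCCCCCCAAA")
#' @export
duplexMFE <- function(query, target, params = duplexParams(),
                      maxBulge = 1L, maxLoop = 1L) {
  stopifnot(maxBulge == 1L, maxLoop == 1L)
  q <- rnaCodes(query)
  t <- rnaCodes(target)
  if (length(q) > 30) stop("query longer than 30 nt")
  if (length(t) > 18500) stop("target longer than 18500 nt")
  res <- .duplexDP(q, t, params$stacks, params$init,
                   unname(params$endPen), params$bulge1, params$loop11)
  if (!is.finite(res$energy)) return(NULL)
  pairs <- cbind(qpos = res$qpos, tpos = res$tpos)
  out <- data.frame(mfe = res$energy,
                    t_start = min(res$tpos) - 1L, t_end = max(res$tpos),
                    q_start = min(res$qpos) - 1L, q_end = max(res$qpos))
  out$pairs <- list(pairs)
  out
}

#' Free energy of a perfect Watson-Crick duplex of a sequence
#'
#' Closed-form energy of the full-length perfect complement duplex:
#' initiation + both terminal penalties + the sum of consecutive stack terms.
#' Used by the synthetic generator to guarantee that planted seed sites form
#' stable hybrids.
#'
#' @param seq RNA string.
#' @inheritParams duplexMFE
#' @return Energy in kcal/mol.
#' @export
perfectDuplexEnergy <- function(seq, params = duplexParams()) {
  codes <- rnaCodes(seq)
  # pair of each query base with its Watson-Crick complement
  pairName <- c("AU", "CG", "GC", "UA")[codes + 1L]
  e <- params$init + params$endPen[[pairName[1]]] +
    params$endPen[[pairName[length(pairName)]]]
  if (length(pairName) > 1) {
    for (i in seq_len(length(pairName) - 1)) {
      e <- e + params$stacks[pairName[i], pairName[i + 1]]
    }
  }
  unname(e)
}
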