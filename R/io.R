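#' Read / write mortality tables as TSV
#'
#' Column layout: strain, replicate, condition, time_h, cum_dead, n_start,
#' n_injured.
#'
#' @param path file path.
#' @return [MortalityTable-class] for the reader; invisible path for the
#'   writer.
#' @export
readMortalityTSV <- function(path) {
  MortalityTable(read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname readMortalityTSV
#' @param tbl a [MortalityTable-class].
#' @export
writeMortalityTSV <- function(tbl, path) {
  write.table(mortalityData(tbl), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write a GRanges as BED6 (0-based half-open)
#'
#' @param gr a [GenomicRanges::GRanges-class] with a `feature_id` column.
#' @param path output path.
#' @param score score column (default 0).
#' @return invisible path.
#' @export
writeBED6 <- function(gr, path, score = 0L) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,  # BED is 0-based half-open
    end = GenomicRanges::end(gr),
    name = gr$feature_id,
    score = score,
    strand = as.character(GenomicRanges::strand(gr)))
  df$strand[df$strand == "*"] <- "."
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a BED6 file into a GRanges
#'
#' @param path BED6 path (0-based half-open on disk).
#' @return [GenomicRanges::GRanges-class] with `feature_id`.
#' @export
readBED6 <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(df)[1:6] <- c("chrom", "start", "end", "name", "score", "strand")
  df$strand[!df$strand %in% c("+", "-")] <- "*"
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(df$start + 1L, df$end),
                         strand = df$strand, feature_id = df$name)
}

#' Write RNA sequences as FASTA
#'
#' @param seqs named character vector or
#'   [Biostrings::RNAStringSet-class].
#' @param path output path.
#' @return invisible path.
#' @export
writeFastaRNA <- function(seqs, path) {
  if (!is(seqs, "RNAStringSet")) seqs <- Biostrings::RNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
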