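# Read trimming: a fixed 3' cut (primer removal) followed by 3' quality
# trimming at a Phred floor, the order the sequencing methods describe.

#' Trim reads at the 3' end
#'
#' Two steps per read: (1) remove `trim3` bases from the 3' end; (2) remove
#' further 3' bases while the terminal base quality is below `qmin`. Reads
#' shorter than `min_len` after trimming are discarded. The quality clause is
#' applied as 3' trimming, not whole-read discard; set `whole_read = TRUE` to
#' instead drop any read whose minimum remaining quality is below `qmin`.
#'
#' @param reads Tibble with `read_id`, `seq`, `qual` (Phred+33 string).
#' @param trim3 Fixed number of 3' bases to remove first (>= 0).
#' @param qmin Quality floor (0-60).
#' @param min_len Minimum surviving read length.
#' @param whole_read Discard instead of trim on low quality.
#' @return The trimmed tibble (always a prefix of the input read), with a
#'   `trim_log` attribute: n_in, n_kept, n_discarded, bases_removed.
#' @export
trim_reads <- function(reads, trim3 = 15L, qmin = 25L, min_len = 20L,
                       whole_read = FALSE) {
  check_that(trim3 >= 0, "trim3", "must be >= 0")
  check_that(qmin >= 0 && qmin <= 60, "qmin", "must be in [0, 60]")
  n_in <- nrow(reads)
  len0 <- nchar(reads$seq)
  stopifnot(all(len0 == nchar(reads$qual)))
  cut1 <- pmax(0L, len0 - as.integer(trim3))
  qints <- lapply(reads$qual, qual_to_int)
  newlen <- vapply(seq_len(n_in), function(i) {
    k <- cut1[i]
    q <- qints[[i]]
    if (whole_read) {
      if (k > 0 && any(q[seq_len(k)] < qmin)) return(-1L)  # marker: discard
      return(k)
    }
    while (k > 0 && q[k] < qmin) k <- k - 1L
    k
  }, integer(1))
  discard_q <- newlen < 0L
  newlen[discard_q] <- 0L
  keep <- !discard_q & newlen >= min_len
  out <- tibble(read_id = reads$read_id[keep],
                seq = substr(reads$seq[keep], 1L, newlen[keep]),
                qual = substr(reads$qual[keep], 1L, newlen[keep]))
  attr(out, "trim_log") <- tibble(
    n_in = n_in, n_kept = sum(keep), n_discarded = n_in - sum(keep),
    bases_removed = sum(len0[keep] - newlen[keep]) +
      sum(len0[!keep])
  )
  out
}

#' Retrieve the trimming log attached by [trim_reads()]
#' @param x A trimmed read tibble.
#' @return A one-row tibble of counts.
#' @export
trim_log <- function(x) attr(x, "trim_log")
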