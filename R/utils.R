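#' @importFrom rlang abort warn .data :=
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   left_join inner_join bind_rows bind_cols n across all_of rename distinct pull
#' @importFrom tibble tibble as_tibble
#' @importFrom stats rnorm rlnorm rpois runif median sd var pf pt pnorm
#'   setNames quantile plogis hclust dist as.dendrogram order.dendrogram
#' @importFrom utils combn head
NULL

# Validation helper: abort with the offending field name, so generator specs
# fail loudly and specifically.
check_that <- function(ok, field, msg) {
  if (!isTRUE(ok)) {
    abort(sprintf("invalid `%s`: %s", field, msg), class = "netscan_validation_error")
  }
  invisible(TRUE)
}

#' Derive a stage seed from a global seed
#'
#' One global seed fans out to per-stage seeds through a fixed recorded
#' derivation, so pipeline stages are independently re-runnable. Kept below
#' 2^31 to stay a valid R integer.
#'
#' @param seed Global integer seed.
#' @param stage Stage name (character).
#' @return An integer seed.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.double(seed) * 7919 + h * 104729) %% 2147483587L) + 1L
}

# Reverse complement of a plain character vector of DNA strings.
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Phred+33 helpers for FASTQ quality strings.
qual_to_int <- function(q) utf8ToInt(q) - 33L
int_to_qual <- function(v) intToUtf8(v + 33L)

`%||%` <- function(a, b) if (is.null(a)) b else a
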