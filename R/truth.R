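# Machine-readable record of every planted signal, so simulation results can
# be scored (sensitivity, false-call rate) without re-deriving the truth.

#' Build a truth record for a simulation
#'
#' @param planted A [planted_signal()] (or NULL).
#' @param genome A `synthetic_genome` (or NULL).
#' @param differential Optional tibble of differential proteins
#'   (`protein`, `direction`, `true_ratio`) from [simulate_lfq()].
#' @param params List of generator parameters (seeds included).
#' @return A `truth_record` list; serializes losslessly to JSON.
#' @export
truth_record <- function(planted = NULL, genome = NULL, differential = NULL,
                         params = list()) {
  g <- NULL
  if (!is.null(genome)) {
    g <- list(chrom_lengths = as.list(setNames(as.integer(genome$spec$chrom_lengths),
                                               genome$spec$chrom_names)),
              mt_name = genome$spec$mt_name,
              mt_len = genome$spec$mt_len,
              mt_circular = genome$spec$mt_circular,
              telomere_array_len = genome$spec$telomere_array_len,
              telomere_3prime = genome$telomere_3prime,
              seed = genome$spec$seed)
  }
  p <- NULL
  if (!is.null(planted)) {
    p <- list(samples = planted$samples,
              intervals = planted$intervals,
              mt_multiplier = planted$mt_multiplier,
              telomere_rate = planted$telomere_rate)
  }
  structure(list(planted = p, genome = g,
                 differential = differential, params = params),
            class = "truth_record")
}

#' Write / read a truth record as JSON
#'
#' Round-trip is lossless for all fields the generators produce.
#'
#' @param truth A `truth_record`.
#' @param path Output path.
#' @return `read_truth()` returns the `truth_record`.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "truth_record"))
  x <- unclass(truth)
  if (!is.null(x$planted)) {
    # named-vector fields as explicit maps so length-1 cases keep their names
    x$planted$mt_multiplier <- as.list(x$planted$mt_multiplier)
    x$planted$telomere_rate <- as.list(x$planted$telomere_rate)
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(x$planted)) {
    iv <- as_tibble(x$planted$intervals)
    if (nrow(iv) == 0) {
      iv <- tibble(sample = character(), chrom = character(),
                   start = integer(), end = integer(),
                   multiplier = double(), direction = character())
    } else {
      # JSON carries no integer/double distinction; restore the generator's
      iv <- mutate(iv, start = as.integer(.data$start),
                   end = as.integer(.data$end),
                   multiplier = as.double(.data$multiplier))
    }
    x$planted$intervals <- iv
    x$planted$mt_multiplier <- vapply(x$planted$mt_multiplier, as.double, 0)
    x$planted$telomere_rate <- vapply(x$planted$telomere_rate, as.double, 0)
  }
  if (!is.null(x$differential)) x$differential <- as_tibble(x$differential)
  structure(x, class = "truth_record")
}
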