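# Synthetic genome generator: autosome-like chromosomes capped by telomeric
# TTAGGG arrays plus a small circular mitochondrial chromosome, with a gene /
# exon annotation. Stands in for a real reference at desk scale; every
# structural choice is recorded so downstream truth scoring is exact.

#' Specification for a synthetic genome
#'
#' @param chrom_lengths Named integer vector of autosome lengths in nt.
#' @param telomere_array_len Length in nt of the tandem TTAGGG array placed at
#'   each autosome end; must be a positive multiple of 6.
#' @param mt_name,mt_len Name and length of the mitochondrial chromosome;
#'   `mt_len` must be >= 500 so at least one full 500-nt window exists.
#' @param gc_fraction GC content of the random background sequence.
#' @param seed Integer seed; the generator is a pure function of spec + seed.
#' @return A `genome_spec` list.
#' @export
genome_spec <- function(chrom_lengths = c(chr1 = 100000L, chr2 = 100000L,
                                          chr3 = 100000L),
                        telomere_array_len = 600L,
                        mt_name = "MT", mt_len = 2000L,
                        gc_fraction = 0.41, seed = 1L) {
  if (is.list(chrom_lengths)) chrom_lengths <- unlist(chrom_lengths)
  check_that(length(chrom_lengths) >= 1 && all(chrom_lengths > 0) &&
               !is.null(names(chrom_lengths)) && !any(names(chrom_lengths) == ""),
             "chrom_lengths", "must be a named vector of positive lengths")
  check_that(telomere_array_len > 0 && telomere_array_len %% 6 == 0,
             "telomere_array_len", "must be a positive multiple of 6")
  check_that(all(chrom_lengths > 2 * telomere_array_len), "chrom_lengths",
             "each autosome must exceed twice the telomere array length")
  check_that(mt_len >= 500, "mt_len",
             "must be >= 500 so that >= 1 full 500-nt window exists")
  check_that(gc_fraction > 0 && gc_fraction < 1, "gc_fraction",
             "must be in (0, 1)")
  structure(list(chrom_lengths = as.integer(chrom_lengths),
                 chrom_names = names(chrom_lengths),
                 telomere_array_len = as.integer(telomere_array_len),
                 mt_name = mt_name, mt_len = as.integer(mt_len),
                 mt_circular = TRUE,
                 gc_fraction = gc_fraction, seed = as.integer(seed)),
            class = "genome_spec")
}

random_dna <- function(n, gc) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

tandem <- function(unit, len) {
  stopifnot(len %% nchar(unit) == 0)
  strrep(unit, len / nchar(unit))
}

#' Generate a synthetic genome and annotation
#'
#' Each autosome starts with `telomere_array_len` nt of tandem TTAGGG and
#' ends with the same array on the reverse strand (tandem CCCTAA on the
#' forward strand, the generator's recorded choice). The mitochondrial
#' chromosome is random background sequence, flagged circular (reads never
#' wrap the origin). At least ten non-overlapping genes are placed per
#' autosome, each with one or more exons, none inside the telomeric arrays.
#'
#' @param spec A [genome_spec()].
#' @return A list of class `synthetic_genome`: `seq` (named character vector
#'   of chromosome sequences), `annotation` (tibble of genes and exons,
#'   0-based half-open), and the `spec`.
#' @export
make_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  set.seed(derive_seed(spec$seed, "genome"))
  telo5 <- tandem("TTAGGG", spec$telomere_array_len)
  telo3 <- tandem("CCCTAA", spec$telomere_array_len)  # TTAGGG on minus strand

  seqs <- character(0)
  genes <- list()
  for (i in seq_along(spec$chrom_names)) {
    nm <- spec$chrom_names[i]
    L <- spec$chrom_lengths[i]
    mid <- random_dna(L - 2L * spec$telomere_array_len, spec$gc_fraction)
    seqs[nm] <- paste0(telo5, mid, telo3)
    genes[[nm]] <- place_genes(nm, L, spec$telomere_array_len, i)
  }
  seqs[spec$mt_name] <- random_dna(spec$mt_len, spec$gc_fraction)

  structure(list(seq = seqs, annotation = bind_rows(genes), spec = spec,
                 telomere_3prime = "minus"),
            class = "synthetic_genome")
}

# Lay out n_genes non-overlapping genes in the non-telomeric interior of one
# autosome; each gene gets 1-3 exons inside its body.
place_genes <- function(chrom, L, telo_len, chrom_idx, n_genes = 12L) {
  lo <- telo_len + 200L
  hi <- L - telo_len - 200L
  slot <- (hi - lo) %/% n_genes
  out <- vector("list", n_genes)
  for (g in seq_len(n_genes)) {
    s0 <- lo + (g - 1L) * slot
    glen <- sample(seq(max(200L, slot %/% 4L), slot - 100L), 1L)
    gstart <- s0 + sample.int(slot - glen, 1L) - 1L
    gend <- gstart + glen
    strand <- sample(c("+", "-"), 1L)
    sym <- sprintf("GENE%d_%02d", chrom_idx, g)
    n_ex <- sample.int(3L, 1L)
    bnds <- sort(sample(seq(gstart, gend - 20L), n_ex))
    exons <- tibble(
      gene_id = sprintf("%s.ex%d", sym, seq_len(n_ex)),
      symbol = sym, chrom = chrom,
      start = bnds,
      end = pmin(bnds + pmax(20L, glen %/% (2L * n_ex)), gend),
      strand = strand, kind = "exon"
    )
    out[[g]] <- bind_rows(
      tibble(gene_id = sym, symbol = sym, chrom = chrom, start = gstart,
             end = gend, strand = strand, kind = "gene"),
      exons
    )
  }
  bind_rows(out)
}
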