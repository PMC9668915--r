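# Format boundaries. Internally every interval is 0-based half-open; SAM and
# GFF3 are converted at read/write time, BED is native. FASTA/FASTQ go
# through Biostrings, BED/GFF3 through rtracklayer. The minimal SAM text
# dialect (header @SQ lines; single-M CIGAR) is parsed directly.

#' Read / write a FASTA reference
#'
#' @param path File path.
#' @param seqs Named character vector of sequences.
#' @return `read_fasta()` returns a named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read / write FASTQ (Phred+33)
#'
#' @param path File path.
#' @param reads Tibble with `read_id`, `seq`, `qual`.
#' @return `read_fastq()` returns a tibble with `read_id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  tibble(read_id = sub("\\s.*$", "", names(x)),
         seq = unname(as.character(x)),
         qual = unname(as.character(S4Vectors::mcols(x)$qualities)))
}

#' @rdname read_fastq
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(setNames(reads$seq, reads$read_id))
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qual))
  invisible(path)
}

aln_cols <- c("read_id", "chrom", "start", "end", "strand", "mapq")

#' Read / write alignments (minimal SAM dialect or 6-column TSV)
#'
#' The SAM dialect requires `@SQ` header lines and single-run `<n>M` CIGARs;
#' POS is converted from 1-based to the internal 0-based half-open
#' convention. SEQ/QUAL are carried when present (re-oriented to read
#' orientation for minus-strand records). The TSV dialect is
#' `read_id, chrom, start0, end0, strand, mapq` (native 0-based) with
#' optional `seq`, `qual` columns.
#'
#' @param path File path; format guessed from the extension unless given.
#' @param format "auto", "sam" or "tsv".
#' @param chrom_lengths Optional named vector; alignments on unknown
#'   chromosomes raise an error listing the offenders.
#' @return A tibble with columns read_id, chrom, start, end, strand, mapq
#'   (and seq/qual when available).
#' @export
read_alignments <- function(path, format = c("auto", "sam", "tsv"),
                            chrom_lengths = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.sam$", path, ignore.case = TRUE)) "sam" else "tsv"
  }
  aln <- if (format == "sam") read_sam_impl(path) else read_aln_tsv_impl(path)
  if (!is.null(chrom_lengths)) {
    unknown <- setdiff(unique(aln$chrom), names(chrom_lengths))
    if (length(unknown) > 0) {
      abort(paste0("alignments reference unknown chromosomes: ",
                   paste(unknown, collapse = ", ")))
    }
  }
  aln
}

read_sam_impl <- function(path) {
  lines <- readLines(path)
  body <- which(!startsWith(lines, "@"))
  if (length(body) == 0) {
    return(tibble(read_id = character(), chrom = character(),
                  start = integer(), end = integer(), strand = character(),
                  mapq = integer(), seq = character(), qual = character()))
  }
  parts <- strsplit(lines[body], "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 6)
  if (length(bad) > 0) {
    abort(sprintf("malformed SAM record at line %d (< 6 fields)", body[bad[1]]))
  }
  get <- function(i) vapply(parts, function(p) if (length(p) >= i) p[i] else "*", "")
  cigar <- get(6)
  ok <- grepl("^[0-9]+M$", cigar)
  if (!all(ok)) {
    abort(sprintf("unsupported CIGAR '%s' at line %d (single M run required)",
                  cigar[!ok][1], body[which(!ok)[1]]))
  }
  mlen <- as.integer(sub("M$", "", cigar))
  flag <- as.integer(get(2))
  pos <- as.integer(get(4))
  if (anyNA(flag) || anyNA(pos)) {
    abort(sprintf("malformed SAM record at line %d (non-numeric FLAG/POS)",
                  body[which(is.na(flag) | is.na(pos))[1]]))
  }
  minus <- bitwAnd(flag, 16L) > 0L
  seqs <- get(10); quals <- get(11)
  # SAM stores SEQ/QUAL in reference orientation; flip back to read orientation
  flip <- minus & seqs != "*"
  if (any(flip)) {
    seqs[flip] <- revcomp(seqs[flip])
    quals[flip] <- vapply(quals[flip], function(q)
      intToUtf8(rev(utf8ToInt(q))), "")
  }
  tibble(read_id = get(1), chrom = get(3), start = pos - 1L,
         end = pos - 1L + mlen, strand = ifelse(minus, "-", "+"),
         mapq = as.integer(get(5)),
         seq = ifelse(seqs == "*", NA_character_, seqs),
         qual = ifelse(quals == "*", NA_character_, quals))
}

read_aln_tsv_impl <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("read_id", "chrom", "start0", "end0", "strand", "mapq")
  if (!all(need %in% names(x))) {
    abort(paste0("alignment TSV must have columns: ", paste(need, collapse = ", ")))
  }
  out <- tibble(read_id = as.character(x$read_id), chrom = as.character(x$chrom),
                start = as.integer(x$start0), end = as.integer(x$end0),
                strand = as.character(x$strand), mapq = as.integer(x$mapq))
  if ("seq" %in% names(x)) out$seq <- as.character(x$seq)
  if ("qual" %in% names(x)) out$qual <- as.character(x$qual)
  out
}

#' @rdname read_alignments
#' @param aln Alignment tibble (internal convention).
#' @export
write_sam <- function(aln, chrom_lengths, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
                   as.integer(chrom_lengths)))
  if (nrow(aln) == 0) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  minus <- aln$strand == "-"
  seqs <- if ("seq" %in% names(aln)) aln$seq else rep("*", nrow(aln))
  quals <- if ("qual" %in% names(aln)) aln$qual else rep("*", nrow(aln))
  seqs[is.na(seqs)] <- "*"; quals[is.na(quals)] <- "*"
  flip <- minus & seqs != "*"
  if (any(flip)) {
    seqs[flip] <- revcomp(seqs[flip])
    quals[flip] <- vapply(quals[flip], function(q)
      intToUtf8(rev(utf8ToInt(q))), "")
  }
  rec <- sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t%s",
                 aln$read_id, ifelse(minus, 16L, 0L), aln$chrom,
                 aln$start + 1L, aln$mapq, aln$end - aln$start, seqs, quals)
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' @rdname read_alignments
#' @export
write_alignments_tsv <- function(aln, path) {
  out <- tibble(read_id = aln$read_id, chrom = aln$chrom,
                start0 = aln$start, end0 = aln$end,
                strand = aln$strand, mapq = aln$mapq)
  if ("seq" %in% names(aln)) out$seq <- aln$seq
  if ("qual" %in% names(aln)) out$qual <- aln$qual
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read / write gene and exon annotation (BED or GFF3)
#'
#' BED is read natively (0-based half-open); GFF3 coordinates are converted
#' from 1-based inclusive. Both return the internal annotation tibble.
#'
#' @param path File path (.bed / .gff3 / .gff).
#' @return A tibble: gene_id, symbol, chrom, start, end, strand, kind.
#' @export
read_intervals <- function(path) {
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    gr <- rtracklayer::import(path, format = "bed")
    nm <- if (!is.null(gr$name)) as.character(gr$name) else
      sprintf("iv%05d", seq_along(gr))
    return(tibble(gene_id = nm, symbol = nm,
                  chrom = as.character(GenomicRanges::seqnames(gr)),
                  start = GenomicRanges::start(gr) - 1L,
                  end = GenomicRanges::end(gr),
                  strand = as.character(GenomicRanges::strand(gr)),
                  kind = "gene"))
  }
  gr <- rtracklayer::import(path, format = "gff3")
  id <- if (!is.null(gr$ID)) as.character(gr$ID) else sprintf("iv%05d", seq_along(gr))
  sym <- if (!is.null(gr$Name)) as.character(gr$Name) else id
  tibble(gene_id = id, symbol = sym,
         chrom = as.character(GenomicRanges::seqnames(gr)),
         start = GenomicRanges::start(gr) - 1L,
         end = GenomicRanges::end(gr),
         strand = as.character(GenomicRanges::strand(gr)),
         kind = as.character(gr$type))
}

#' @rdname read_intervals
#' @param annotation Annotation tibble.
#' @export
write_annotation_gff3 <- function(annotation, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = annotation$chrom,
    ranges = IRanges::IRanges(start = annotation$start + 1L,
                              end = annotation$end),
    strand = ifelse(annotation$strand %in% c("+", "-"), annotation$strand, "*")
  )
  gr$source <- "netscan"
  gr$type <- annotation$kind
  gr$ID <- annotation$gene_id
  gr$Name <- annotation$symbol
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname read_intervals
#' @export
write_genes_bed <- function(annotation, path) {
  g <- filter(annotation, .data$kind == "gene")
  gr <- GenomicRanges::GRanges(
    seqnames = g$chrom,
    ranges = IRanges::IRanges(start = g$start + 1L, end = g$end),
    strand = ifelse(g$strand %in% c("+", "-"), g$strand, "*")
  )
  gr$name <- g$symbol
  gr$score <- 0L
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}
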