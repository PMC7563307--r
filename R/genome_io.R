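## Genome / annotation model and track I/O.
##
## Internal coordinates are 1-based inclusive throughout (GFF3 convention);
## BED/bedGraph conversion happens only at the file boundary.

#' Construct a genome model
#'
#' Bundles the replicon table, the CDS annotation and (optionally) the
#' nucleotide sequences into the container the rest of the pipeline consumes.
#'
#' @param replicons data.frame with columns `name` (unique) and `length`
#'   (nt, >= 1).
#' @param cds data.frame with columns `replicon`, `start`, `end` (1-based
#'   inclusive, `start <= end`), `strand` (`"+"`/`"-"`), `locus_tag`, and
#'   optionally `functional_class` (single eggNOG/COG-style letter; missing
#'   values become `"S"`, unknown function).
#' @param seq optional [Biostrings::DNAStringSet] named by replicon; lengths
#'   must equal the `length` column.
#' @return An object of class `tss_genome`: a list with elements `replicons`,
#'   `cds` and `seq`. The CDS table gains a `tss_start` column holding the
#'   translation-start coordinate (`start` on `+`, `end` on `-`).
#' @export
tss_genome <- function(replicons, cds, seq = NULL) {
  replicons <- as.data.frame(replicons)
  stopifnot(all(c("name", "length") %in% names(replicons)))
  if (anyDuplicated(replicons$name))
    stop("replicon names must be unique")
  if (any(replicons$length < 1))
    stop("replicon lengths must be >= 1")
  cds <- as.data.frame(cds)
  needed <- c("replicon", "start", "end", "strand", "locus_tag")
  if (nrow(cds) > 0 && !all(needed %in% names(cds)))
    stop("cds table needs columns: ", paste(needed, collapse = ", "))
  if (nrow(cds) == 0) {
    cds <- data.frame(replicon = character(), start = integer(),
                      end = integer(), strand = character(),
                      locus_tag = character(), functional_class = character())
  }
  if (is.null(cds$functional_class)) cds$functional_class <- "S"
  cds$functional_class[is.na(cds$functional_class)] <- "S"
  bad <- !cds$replicon %in% replicons$name
  if (any(bad))
    stop("CDS feature(s) reference unknown replicon: ",
         paste(unique(cds$locus_tag[bad]), collapse = ", "))
  if (!all(cds$strand %in% c("+", "-")))
    stop("CDS strand must be '+' or '-' (strandless CDS rejected)")
  rl <- stats::setNames(replicons$length, replicons$name)
  if (any(cds$start < 1) || any(cds$end < cds$start))
    stop("CDS coordinates must satisfy 1 <= start <= end")
  over <- cds$end > rl[cds$replicon]
  if (any(over))
    stop("CDS end beyond replicon length: ",
         paste(cds$locus_tag[over], collapse = ", "))
  if (!is.null(seq)) {
    seq <- Biostrings::DNAStringSet(seq)
    if (!all(replicons$name %in% names(seq)))
      stop("sequence set must be named by replicon")
    if (!all(Biostrings::width(seq[replicons$name]) == replicons$length))
      stop("sequence widths disagree with replicon lengths")
    seq <- seq[replicons$name]
  }
  cds$tss_start <- ifelse(cds$strand == "+", cds$start, cds$end)
  structure(list(replicons = replicons, cds = cds, seq = seq),
            class = "tss_genome")
}

#' @export
print.tss_genome <- function(x, ...) {
  cat(sprintf("<tss_genome> %d replicon(s), %d CDS, sequence: %s\n",
              nrow(x$replicons), nrow(x$cds),
              if (is.null(x$seq)) "absent" else "present"))
  invisible(x)
}

#' Read a genome and its CDS annotation
#'
#' @param fasta_path genome FASTA (multi-replicon).
#' @param gff3_path GFF3 annotation; every feature of type `CDS` must
#'   reference a FASTA sequence identifier.
#' @param functional_class_attr GFF3 attribute key carrying the single-letter
#'   functional class; absent attributes become class `"S"`.
#' @return A [tss_genome()] model.
#' @export
read_genome <- function(fasta_path, gff3_path,
                        functional_class_attr = "eggnog_class") {
  seq <- Biostrings::readDNAStringSet(fasta_path)
  names(seq) <- sub("\\s.*$", "", names(seq))
  replicons <- data.frame(name = names(seq),
                          length = Biostrings::width(seq))
  gff <- rtracklayer::import(gff3_path, format = "gff3")
  gff <- gff[gff$type == "CDS"]
  if (length(gff) > 0) {
    tag <- as.character(gff$locus_tag)
    if (is.null(gff$locus_tag) || all(is.na(tag))) tag <- as.character(gff$ID)
    fc <- S4Vectors::mcols(gff)[[functional_class_attr]]
    if (is.null(fc)) fc <- rep(NA_character_, length(gff))
    cds <- data.frame(
      replicon = as.character(GenomicRanges::seqnames(gff)),
      start = GenomicRanges::start(gff),
      end = GenomicRanges::end(gff),
      strand = as.character(GenomicRanges::strand(gff)),
      locus_tag = tag,
      functional_class = as.character(fc))
  } else {
    cds <- data.frame()
  }
  tss_genome(replicons, cds, seq = seq)
}

## ---- 5'-end count tracks ---------------------------------------------------

#' Construct a 5'-end count track set
#'
#' One track set corresponds to one sequencing library (one replicate of one
#' condition) and holds sparse per-base read 5'-end counts for every
#' replicon/strand it covers.
#'
#' @param counts data.frame with columns `replicon`, `strand` (`"+"`/`"-"`),
#'   `pos` (1-based) and `count` (non-negative integer). Duplicate positions
#'   are summed.
#' @param library_size total mapped reads of the source library. Defaults to
#'   the sum of `count`; the track may be a subset of the library, so an
#'   externally known (larger) size can be given.
#' @param replicon_lengths optional named vector; when present, positions are
#'   validated against it.
#' @param condition optional condition label carried along for bookkeeping.
#' @return Object of class `end_track_set`.
#' @export
end_track_set <- function(counts, library_size = NULL,
                          replicon_lengths = NULL, condition = NULL) {
  counts <- data.table::as.data.table(counts)
  if (nrow(counts) == 0) {
    counts <- data.table::data.table(replicon = character(),
                                     strand = character(),
                                     pos = integer(), count = integer())
  }
  stopifnot(all(c("replicon", "strand", "pos", "count") %in% names(counts)))
  if (!all(counts$strand %in% c("+", "-")))
    stop("track strand must be '+' or '-'")
  if (any(counts$pos < 1)) stop("track positions must be >= 1")
  if (any(counts$count < 0)) stop("track counts must be >= 0")
  counts <- counts[, list(count = sum(count)),
                   by = c("replicon", "strand", "pos")]
  data.table::setorderv(counts, c("replicon", "strand", "pos"))
  if (!is.null(replicon_lengths)) {
    bad <- counts$pos > replicon_lengths[counts$replicon]
    if (any(is.na(bad)) || any(bad))
      stop("track positions outside replicon bounds")
  }
  if (is.null(library_size)) library_size <- sum(counts$count)
  structure(list(counts = counts,
                 library_size = as.numeric(library_size),
                 replicon_lengths = replicon_lengths,
                 condition = condition),
            class = "end_track_set")
}

#' @export
print.end_track_set <- function(x, ...) {
  cat(sprintf(
    "<end_track_set> %d positions, %d reads, library_size %g%s\n",
    nrow(x$counts), sum(x$counts$count), x$library_size,
    if (is.null(x$condition)) "" else paste0(", condition ", x$condition)))
  invisible(x)
}

#' Read a 5'-end track from BED or a per-strand bedGraph pair
#'
#' A single path is read as 6-column BED of single-base read 5' ends (one
#' record per read); BED's 0-based half-open interval `[p, p+1)` becomes the
#' internal 1-based position `p+1`. A length-2 vector named `plus`/`minus`
#' is read as a pair of per-strand bedGraphs of per-base counts (run-length
#' intervals are expanded to single bases).
#'
#' @param path one BED path, or `c(plus = ..., minus = ...)` bedGraph paths.
#' @param library_size override for the source library size (default: total
#'   count loaded).
#' @param replicon_lengths optional named vector for validation.
#' @param condition optional condition label.
#' @return An [end_track_set()].
#' @export
read_end_counts <- function(path, library_size = NULL,
                            replicon_lengths = NULL, condition = NULL) {
  if (length(path) == 2) {
    if (is.null(names(path))) names(path) <- c("plus", "minus")
    stopifnot(all(c("plus", "minus") %in% names(path)))
    counts <- data.table::rbindlist(list(
      read_bedgraph_counts(path[["plus"]], "+"),
      read_bedgraph_counts(path[["minus"]], "-")))
  } else if (length(path) == 1) {
    bed <- rtracklayer::import(path, format = "BED")
    if (length(bed) == 0) {
      counts <- data.table::data.table(replicon = character(),
                                       strand = character(),
                                       pos = integer(), count = integer())
    } else {
      if (any(GenomicRanges::width(bed) != 1))
        stop("BED interval wider than 1 base: not a read 5'-end track")
      if (any(GenomicRanges::start(bed) < 1))
        stop("negative BED coordinates")
      strand <- as.character(GenomicRanges::strand(bed))
      if (any(strand == "*"))
        stop("BED records must be stranded")
      counts <- data.table::data.table(
        replicon = as.character(GenomicRanges::seqnames(bed)),
        strand = strand,
        pos = GenomicRanges::start(bed),
        count = 1L)
    }
  } else {
    stop("path must be one BED file or a plus/minus bedGraph pair")
  }
  end_track_set(counts, library_size = library_size,
                replicon_lengths = replicon_lengths, condition = condition)
}

## bedGraph is a bare 4-column TSV; fread keeps multi-million-line synthetic
## tracks fast. Track definition lines are tolerated and skipped.
read_bedgraph_counts <- function(path, strand) {
  empty_counts <- data.table::data.table(replicon = character(),
                                         strand = character(),
                                         pos = integer(), count = integer())
  first <- readLines(path, n = 1)
  if (length(first) == 0) return(empty_counts)
  raw <- data.table::fread(path, header = FALSE, sep = "\t",
                           colClasses = list(character = 1),
                           skip = as.integer(grepl("^(track|#)", first)))
  if (nrow(raw) == 0) return(empty_counts)
  if (ncol(raw) < 4) stop("bedGraph needs 4 columns: ", path)
  data.table::setnames(raw, 1:4, c("replicon", "bstart", "bend", "count"))
  if (any(raw$bstart < 0)) stop("negative bedGraph coordinates")
  n <- raw$bend - raw$bstart
  if (any(n < 1)) stop("bedGraph interval of non-positive width")
  data.table::data.table(
    replicon = rep(raw$replicon, n),
    strand = strand,
    pos = as.integer(rep(raw$bstart, n) + sequence(n)),
    count = as.integer(rep(raw$count, n)))
}

#' Write a 5'-end track set as a per-strand bedGraph pair
#'
#' @param track an [end_track_set()].
#' @param plus_path,minus_path output paths. Per-base records (width-1
#'   intervals) are written; counts of zero are omitted.
#' @return Invisibly, the two paths.
#' @export
write_end_counts <- function(track, plus_path, minus_path) {
  for (s in c("+", "-")) {
    p <- if (s == "+") plus_path else minus_path
    x <- track$counts[track$counts$strand == s, ]
    out <- data.table::data.table(chrom = x$replicon,
                                  start = x$pos - 1L, end = x$pos,
                                  count = x$count)
    data.table::fwrite(out, p, sep = "\t", col.names = FALSE)
  }
  invisible(c(plus_path, minus_path))
}

## ---- TSS table / BED output ------------------------------------------------

TSS_TSV_COMMENT <- "# tagtss TSS table; coordinates 1-based inclusive; heights in reads per reference library"

#' Write annotated (or raw) TSS calls as TSV
#'
#' The file starts with a comment line naming units and the coordinate
#' convention, followed by a header row. [read_tss_table()] reverses it
#' exactly.
#'
#' @param x data.frame of TSS calls or annotations.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_tss_table <- function(x, path) {
  writeLines(TSS_TSV_COMMENT, path)
  suppressWarnings(
    data.table::fwrite(as.data.frame(x), path, sep = "\t", append = TRUE,
                       col.names = TRUE, na = "NA"))
  invisible(path)
}

#' Read a TSV written by [write_tss_table()]
#' @param path input path.
#' @return data.frame.
#' @export
read_tss_table <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t", skip = 1L,
                                  header = TRUE, na.strings = "NA"))
}

#' Write TSS calls as BED6
#'
#' Internal 1-based positions become 0-based half-open single-base intervals.
#'
#' @param calls data.frame with `replicon`, `pos`, `strand`, optionally
#'   `tss_class` (used as name) and `norm_height` (rounded into the score).
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_tss_bed <- function(calls, path) {
  name <- if (!is.null(calls$tss_class)) calls$tss_class
          else sprintf("TSS_%d", seq_len(nrow(calls)))
  score <- if (!is.null(calls$norm_height)) round(calls$norm_height) else 0
  out <- data.table::data.table(chrom = calls$replicon,
                                start = calls$pos - 1L, end = calls$pos,
                                name = name, score = score,
                                strand = calls$strand)
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Write a genome model to FASTA + GFF3
#'
#' @param genome [tss_genome()] with sequence.
#' @param fasta_path,gff3_path output paths.
#' @return Invisibly, the two paths.
#' @export
write_genome <- function(genome, fasta_path, gff3_path) {
  if (is.null(genome$seq)) stop("genome has no sequence to write")
  Biostrings::writeXStringSet(genome$seq, fasta_path)
  cds <- genome$cds
  gr <- GenomicRanges::GRanges(cds$replicon,
                               IRanges::IRanges(cds$start, cds$end),
                               strand = cds$strand)
  GenomeInfoDb::seqlengths(gr) <- stats::setNames(
    genome$replicons$length, genome$replicons$name)[
      GenomeInfoDb::seqlevels(gr)]
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    type = "CDS", phase = 0L, ID = cds$locus_tag,
    locus_tag = cds$locus_tag, eggnog_class = cds$functional_class)
  rtracklayer::export(gr, gff3_path, format = "gff3")
  invisible(c(fasta_path, gff3_path))
}
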