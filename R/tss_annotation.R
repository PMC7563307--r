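## Five-class TSS classification and downstream annotation analyses.
##
## Classes, in cascade priority order (a call eligible for several classes
## takes the highest):
##   pTSS  strongest call within `p_window` nt upstream of a start codon on
##         the sense strand, provided it is at least `dominance_factor` times
##         the runner-up in that window (a lone candidate is automatically
##         primary);
##   sTSS  the other calls in such a window (all of them when the dominance
##         rule fails, so a CDS may have secondary TSSs but no primary one);
##   iTSS  inside a CDS on the coding strand;
##   aTSS  on the non-coding strand of a CDS, or on the non-coding strand
##         within `antisense_upstream` nt upstream of its start codon;
##   oTSS  everything else (intergenic, unassociated).

#' Classification parameters
#'
#' @param p_window upstream window for primary/secondary TSSs, nt (default
#'   200); measured from the first base of the start codon, inclusive of the
#'   start base, so a 5'UTR length of 0 is possible.
#' @param dominance_factor how much stronger the top candidate must be than
#'   the runner-up to be primary (default 2).
#' @param antisense_upstream antisense window upstream of the start codon,
#'   nt (default 100), inclusive of the start base.
#' @param leaderless_max_utr 5'UTR lengths strictly below this are flagged
#'   leaderless (default 5 nt).
#' @param long_utr_range distance range (nt) upstream of a start codon in
#'   which an orphan TSS can mark a long 5'UTR (default 200--300).
#' @param orf_min_length minimum ORF length in nt, start through stop codon
#'   inclusive (default 150).
#' @param orf_start_codons accepted start codons (default ATG, GTG, TTG).
#' @param orf_search_distance how far downstream of an orphan TSS an ORF may
#'   begin, nt (default 200).
#' @param coverage_min minimum per-base coverage for the uninterrupted
#'   5'UTR-coverage check (default 1).
#' @param rbs_consensus,rbs_max_mismatch,rbs_spacer_range ribosome-binding
#'   site model for re-annotation: best match to the consensus (default
#'   AGGAGG) with at most `rbs_max_mismatch` mismatches (default 2) ending
#'   `rbs_spacer_range` nt (default 4--14) before the proposed start codon.
#' @return Object of class `classification_params`.
#' @export
classification_params <- function(p_window = 200L, dominance_factor = 2,
                                  antisense_upstream = 100L,
                                  leaderless_max_utr = 5L,
                                  long_utr_range = c(200L, 300L),
                                  orf_min_length = 150L,
                                  orf_start_codons = c("ATG", "GTG", "TTG"),
                                  orf_search_distance = 200L,
                                  coverage_min = 1L,
                                  rbs_consensus = "AGGAGG",
                                  rbs_max_mismatch = 2L,
                                  rbs_spacer_range = c(4L, 14L)) {
  stopifnot(p_window > 0, antisense_upstream > 0, dominance_factor >= 1,
            leaderless_max_utr > 0, orf_min_length > 0,
            length(long_utr_range) == 2, length(rbs_spacer_range) == 2)
  structure(list(p_window = as.integer(p_window),
                 dominance_factor = dominance_factor,
                 antisense_upstream = as.integer(antisense_upstream),
                 leaderless_max_utr = as.integer(leaderless_max_utr),
                 long_utr_range = as.integer(long_utr_range),
                 orf_min_length = as.integer(orf_min_length),
                 orf_start_codons = toupper(orf_start_codons),
                 orf_search_distance = as.integer(orf_search_distance),
                 coverage_min = as.integer(coverage_min),
                 rbs_consensus = toupper(rbs_consensus),
                 rbs_max_mismatch = as.integer(rbs_max_mismatch),
                 rbs_spacer_range = as.integer(rbs_spacer_range)),
            class = "classification_params")
}

TSS_CLASSES <- c("pTSS", "sTSS", "iTSS", "aTSS", "oTSS")

genome_seqinfo <- function(genome) {
  GenomeInfoDb::Seqinfo(seqnames = genome$replicons$name,
                        seqlengths = genome$replicons$length)
}

cds_granges <- function(genome) {
  cds <- genome$cds
  GenomicRanges::GRanges(cds$replicon,
                         IRanges::IRanges(cds$start, cds$end),
                         strand = cds$strand,
                         seqinfo = genome_seqinfo(genome))
}

calls_granges <- function(calls, genome) {
  GenomicRanges::GRanges(calls$replicon,
                         IRanges::IRanges(calls$pos, width = 1),
                         strand = calls$strand,
                         seqinfo = genome_seqinfo(genome))
}

## 5'UTR length of a position relative to a CDS's translation start, in the
## translation sense (>= 0 means upstream of / at the start codon).
utr_distance <- function(pos, cds_strand, cds_tss_start) {
  ifelse(cds_strand == "+", cds_tss_start - pos, pos - cds_tss_start)
}

## Position along the CDS in translation sense, scaled to [0, 1] over the
## CDS body; negative for positions upstream of the start codon.
relative_cds_position <- function(pos, cds) {
  len <- cds$end - cds$start
  from5 <- ifelse(cds$strand == "+", pos - cds$start, cds$end - pos)
  ifelse(len == 0, 0, from5 / len)
}

#' Classify detected TSSs relative to coding sequences
#'
#' Applies the five-class cascade (primary > secondary > internal >
#' antisense > orphan); a call eligible for several classes, including via
#' several CDSs, takes the highest-priority class. With zero annotated CDSs
#' every call is an orphan.
#'
#' @param calls data.frame from [detect_tss()] (columns `replicon`,
#'   `strand`, `pos`, `norm_height` required).
#' @param genome [tss_genome()] model.
#' @param params [classification_params()].
#' @return The call table with added columns `tss_class`, `cognate_locus`,
#'   `utr_length` (pTSS/sTSS only), `relative_position` (iTSS/aTSS only; for
#'   aTSSs assigned through the upstream window the value is negative), and
#'   `leaderless` (`utr_length < leaderless_max_utr`, primary/secondary
#'   only).
#' @export
classify_tss <- function(calls, genome, params = classification_params()) {
  calls <- as.data.frame(calls)
  n <- nrow(calls)
  ann <- calls
  ann$tss_class <- rep("oTSS", n)
  ann$cognate_locus <- rep(NA_character_, n)
  ann$utr_length <- rep(NA_integer_, n)
  ann$relative_position <- rep(NA_real_, n)
  ann$leaderless <- rep(FALSE, n)
  if (n == 0 || nrow(genome$cds) == 0) return(ann)

  cds <- genome$cds
  cds_gr <- cds_granges(genome)
  call_gr <- calls_granges(calls, genome)

  ## --- primary / secondary: sense-strand calls in the upstream window ----
  pwin <- GenomicRanges::trim(suppressWarnings(
    GenomicRanges::promoters(cds_gr, upstream = params$p_window,
                             downstream = 1)))
  hits <- GenomicRanges::findOverlaps(call_gr, pwin)
  if (length(hits) > 0) {
    h <- data.frame(call = S4Vectors::queryHits(hits),
                    cds = S4Vectors::subjectHits(hits))
    h$height <- calls$norm_height[h$call]
    h$utr <- utr_distance(calls$pos[h$call], cds$strand[h$cds],
                          cds$tss_start[h$cds])
    ## per CDS: dominance rule decides which window call (if any) is primary
    h$cls <- "sTSS"
    for (ci in unique(h$cds)) {
      rows <- which(h$cds == ci)
      ord <- rows[order(-h$height[rows], calls$pos[h$call[rows]])]
      if (length(ord) == 1 ||
          h$height[ord[1]] >= params$dominance_factor * h$height[ord[2]])
        h$cls[ord[1]] <- "pTSS"
    }
    ## per call: best class, then smallest 5'UTR
    h <- h[order(h$call, match(h$cls, TSS_CLASSES), h$utr), ]
    best <- h[!duplicated(h$call), ]
    ann$tss_class[best$call] <- best$cls
    ann$cognate_locus[best$call] <- cds$locus_tag[best$cds]
    ann$utr_length[best$call] <- as.integer(best$utr)
    ann$leaderless[best$call] <- best$utr < params$leaderless_max_utr
  }

  rest <- which(ann$tss_class == "oTSS")

  ## --- internal: inside a CDS on the coding strand -----------------------
  if (length(rest) > 0) {
    hits <- GenomicRanges::findOverlaps(call_gr[rest], cds_gr)
    if (length(hits) > 0) {
      h <- data.frame(call = rest[S4Vectors::queryHits(hits)],
                      cds = S4Vectors::subjectHits(hits))
      h$rel <- relative_cds_position(calls$pos[h$call], cds[h$cds, ])
      ## a call inside several (overlapping) CDSs is assigned to the one
      ## whose 5' end it is closest to
      h <- h[order(h$call, h$rel), ]
      best <- h[!duplicated(h$call), ]
      ann$tss_class[best$call] <- "iTSS"
      ann$cognate_locus[best$call] <- cds$locus_tag[best$cds]
      ann$relative_position[best$call] <- best$rel
    }
  }

  rest <- which(ann$tss_class == "oTSS")

  ## --- antisense: opposite strand of the CDS body or its upstream part ---
  if (length(rest) > 0) {
    ext <- ifelse(cds$strand == "+",
                  cds$start - params$antisense_upstream, cds$start)
    ext_end <- ifelse(cds$strand == "+",
                      cds$end, cds$end + params$antisense_upstream)
    areg <- GenomicRanges::trim(suppressWarnings(GenomicRanges::GRanges(
      cds$replicon, IRanges::IRanges(pmax(ext, 1L), ext_end),
      strand = ifelse(cds$strand == "+", "-", "+"),
      seqinfo = genome_seqinfo(genome))))
    hits <- GenomicRanges::findOverlaps(call_gr[rest], areg)
    if (length(hits) > 0) {
      h <- data.frame(call = rest[S4Vectors::queryHits(hits)],
                      cds = S4Vectors::subjectHits(hits))
      h$rel <- relative_cds_position(calls$pos[h$call], cds[h$cds, ])
      ## prefer the CDS the call actually lies in; otherwise the one whose
      ## upstream window it sits in, closest to the start codon
      h$in_body <- h$rel >= 0 & h$rel <= 1
      h <- h[order(h$call, !h$in_body, abs(h$rel)), ]
      best <- h[!duplicated(h$call), ]
      ann$tss_class[best$call] <- "aTSS"
      ann$cognate_locus[best$call] <- cds$locus_tag[best$cds]
      ann$relative_position[best$call] <- best$rel
    }
  }
  ann
}

#' Per-replicon, per-class condition summary
#'
#' Counts classified TSSs per replicon and class for two conditions and
#' their positional intersection (calls of the same class matched within
#' `tolerance` nt), in the layout of a per-replicon TSS summary table, plus
#' a whole-genome row.
#'
#' @param ann_a,ann_b annotation tables from [classify_tss()] for the two
#'   conditions.
#' @param tolerance match tolerance in nt for the intersection (default 5,
#'   one window width).
#' @param labels condition labels for the output columns.
#' @return data.frame with columns `replicon`, `tss_class`, the two
#'   condition counts and `intersection`.
#' @export
summarize_tss_classes <- function(ann_a, ann_b, tolerance = 5,
                                  labels = c("CT", "Cu")) {
  reps <- sort(unique(c(ann_a$replicon, ann_b$replicon)))
  grid <- expand.grid(replicon = c(reps, "genome"),
                      tss_class = TSS_CLASSES,
                      stringsAsFactors = FALSE)
  count_one <- function(ann, rep, cls) {
    sum((rep == "genome" | ann$replicon == rep) & ann$tss_class == cls)
  }
  inter_one <- function(rep, cls) {
    a <- ann_a[(rep == "genome" | ann_a$replicon == rep) &
                 ann_a$tss_class == cls, ]
    b <- ann_b[(rep == "genome" | ann_b$replicon == rep) &
                 ann_b$tss_class == cls, ]
    nrow(match_tss_calls(a, b, tolerance)$pairs)
  }
  grid[[labels[1]]] <- mapply(count_one, list(ann_a),
                              grid$replicon, grid$tss_class)
  grid[[labels[2]]] <- mapply(count_one, list(ann_b),
                              grid$replicon, grid$tss_class)
  grid$intersection <- mapply(inter_one, grid$replicon, grid$tss_class)
  grid[order(match(grid$replicon, c(reps, "genome")),
             match(grid$tss_class, TSS_CLASSES)), ]
}

## ---- CDS re-annotation -----------------------------------------------------

## Best RBS match upstream of a proposed translation start. Returns
## list(found, spacer, mismatches); spacer counts the nt between the last
## motif base and the first base of the start codon.
find_rbs <- function(seqchar, start_pos, strand, params) {
  motif <- strsplit(params$rbs_consensus, "")[[1]]
  k <- length(motif)
  best <- list(found = FALSE, spacer = NA_integer_, mismatches = NA_integer_)
  for (s in params$rbs_spacer_range[1]:params$rbs_spacer_range[2]) {
    if (strand == "+") {
      a <- start_pos - s - k
      if (a < 1) next
      cand <- substr(seqchar, a, a + k - 1L)
    } else {
      a <- start_pos + s + 1L
      if (a + k - 1L > nchar(seqchar)) next
      cand <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(substr(seqchar, a, a + k - 1L))))
    }
    mm <- sum(strsplit(cand, "")[[1]] != motif)
    if (mm <= params$rbs_max_mismatch &&
        (!best$found || mm < best$mismatches)) {
      best <- list(found = TRUE, spacer = s, mismatches = mm)
    }
  }
  best
}

#' Propose CDS start-codon re-annotations
#'
#' A CDS is a re-annotation candidate when (a) it has no primary TSS, (b) an
#' internal TSS lies strictly between the annotated translation start and an
#' externally predicted alternative start, and (c) a ribosome-binding-site
#' motif precedes the alternative start within the configured spacer range.
#' Alternative starts outside the CDS or out of frame with the annotated
#' stop are skipped with a warning.
#'
#' @param genome [tss_genome()] with sequence (required for the RBS scan).
#' @param annotations output of [classify_tss()].
#' @param alt_starts data.frame `locus_tag`, `alt_start` (1-based coordinate
#'   of the predicted alternative translation start, from an external gene
#'   caller).
#' @param params [classification_params()].
#' @return data.frame of candidates: `locus_tag`, `original_start`,
#'   `proposed_start`, `supporting_itss_position`, `rbs_found`,
#'   `rbs_spacer`.
#' @export
propose_reannotations <- function(genome, annotations, alt_starts,
                                  params = classification_params()) {
  if (is.null(genome$seq))
    stop("genome sequence required for the RBS scan")
  empty <- data.frame(locus_tag = character(), original_start = integer(),
                      proposed_start = integer(),
                      supporting_itss_position = integer(),
                      rbs_found = logical(), rbs_spacer = integer())
  if (nrow(alt_starts) == 0) return(empty)
  cds <- genome$cds
  has_ptss <- unique(annotations$cognate_locus[
    annotations$tss_class == "pTSS"])
  itss <- annotations[annotations$tss_class == "iTSS", ]
  out <- list()
  for (i in seq_len(nrow(alt_starts))) {
    tag <- alt_starts$locus_tag[i]
    alt <- alt_starts$alt_start[i]
    ci <- match(tag, cds$locus_tag)
    if (is.na(ci)) {
      warning("alt start for unknown locus skipped: ", tag)
      next
    }
    if (tag %in% has_ptss) next
    strand <- cds$strand[ci]
    orig <- cds$tss_start[ci]
    inside <- alt >= cds$start[ci] && alt <= cds$end[ci]
    in_frame <- if (strand == "+") (alt - cds$start[ci]) %% 3 == 0
                else (cds$end[ci] - alt) %% 3 == 0
    if (!inside || !in_frame) {
      warning(sprintf(
        "alt start for %s %s; candidate skipped", tag,
        if (!inside) "outside annotated CDS" else "out of frame"))
      next
    }
    sup <- itss[!is.na(itss$cognate_locus) & itss$cognate_locus == tag, ]
    between <- if (strand == "+") sup$pos > orig & sup$pos < alt
               else sup$pos < orig & sup$pos > alt
    sup <- sup[between, ]
    if (nrow(sup) == 0) next
    sup <- sup[order(-sup$norm_height, sup$pos), ][1, ]
    seqchar <- as.character(genome$seq[[cds$replicon[ci]]])
    rbs <- find_rbs(seqchar, alt, strand, params)
    if (!rbs$found) next
    out[[length(out) + 1]] <- data.frame(
      locus_tag = tag, original_start = orig, proposed_start = alt,
      supporting_itss_position = sup$pos,
      rbs_found = TRUE, rbs_spacer = rbs$spacer)
  }
  if (length(out) == 0) return(empty)
  do.call(rbind, out)
}

## ---- orphan triage ---------------------------------------------------------

## Longest ORF requirement: start codon within `search` nt downstream of
## `pos` (translation sense), in-frame stop within the replicon; length is
## start through stop codon inclusive.
find_orf_downstream <- function(seqchar, pos, strand, params,
                                max_walk = 9000L) {
  L <- nchar(seqchar)
  scan_get <- function(p) substr(seqchar, p, p + 2L)
  stops_plus <- c("TAA", "TAG", "TGA")
  if (strand == "+") {
    limit <- min(L - 2L, pos + params$orf_search_distance)
    if (pos > limit) return(NULL)
    for (s in pos:limit) {
      if (!scan_get(s) %in% params$orf_start_codons) next
      p <- s + 3L
      while (p + 2L <= L && p - s <= max_walk) {
        if (scan_get(p) %in% stops_plus) {
          len <- p + 2L - s + 1L
          if (len >= params$orf_min_length)
            return(list(orf_start = s, orf_length = len))
          break
        }
        p <- p + 3L
      }
    }
  } else {
    rc_get <- function(p) as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(substr(seqchar, p - 2L, p))))
    limit <- max(3L, pos - params$orf_search_distance)
    if (pos < limit) return(NULL)
    for (s in pos:limit) {
      if (s < 3L) break
      if (!rc_get(s) %in% params$orf_start_codons) next
      p <- s - 3L
      while (p - 2L >= 1L && s - p <= max_walk) {
        if (rc_get(p) %in% stops_plus) {
          len <- s - (p - 2L) + 1L
          if (len >= params$orf_min_length)
            return(list(orf_start = s, orf_length = len))
          break
        }
        p <- p - 3L
      }
    }
  }
  NULL
}

#' Triage orphan TSSs
#'
#' Categorizes every orphan TSS, in priority order, as marking a long 5'UTR
#' (within `long_utr_range` nt upstream of a start codon on the sense
#' strand, with uninterrupted coverage from the TSS to the start codon),
#' as associated with a downstream open reading frame (start codon within
#' `orf_search_distance` nt on the same strand, in-frame stop, length at
#' least `orf_min_length` nt), or as a small-RNA candidate.
#'
#' @param genome [tss_genome()]; sequence required for the ORF scan (without
#'   it the scan is skipped with a warning and those orphans fall through to
#'   sRNA candidates).
#' @param annotations output of [classify_tss()].
#' @param coverage optional [end_track_set()] of per-base full-transcript
#'   coverage from the untagged library; without it the long-5'UTR check is
#'   skipped with a warning.
#' @param params [classification_params()].
#' @return The orphan rows of `annotations` with added columns
#'   `orphan_category` (`long_5utr`, `orf_associated`, `srna_candidate`),
#'   `target_locus`, `orf_start`, `orf_length`.
#' @export
triage_orphans <- function(genome, annotations, coverage = NULL,
                           params = classification_params()) {
  orphans <- annotations[annotations$tss_class == "oTSS", , drop = FALSE]
  orphans$orphan_category <- rep("srna_candidate", nrow(orphans))
  orphans$target_locus <- rep(NA_character_, nrow(orphans))
  orphans$orf_start <- rep(NA_integer_, nrow(orphans))
  orphans$orf_length <- rep(NA_integer_, nrow(orphans))
  if (nrow(orphans) == 0) return(orphans)
  if (is.null(coverage))
    warning("no coverage track: long-5'UTR check skipped")
  if (is.null(genome$seq))
    warning("no genome sequence: ORF check skipped, orphans fall through ",
            "to sRNA candidates")
  cds <- genome$cds
  ## plain data.frame: bare-name subsetting below must see the locals, not
  ## data.table's column scope
  covdf <- if (!is.null(coverage)) as.data.frame(coverage$counts)
  seqchars <- if (!is.null(genome$seq))
    stats::setNames(as.character(genome$seq), names(genome$seq)) else NULL
  for (i in seq_len(nrow(orphans))) {
    pos <- orphans$pos[i]
    strand <- orphans$strand[i]
    repl <- orphans$replicon[i]
    ## long 5'UTR: a sense start codon 200--300 nt downstream, continuously
    ## covered from the TSS to the start codon
    if (!is.null(coverage)) {
      cand <- cds[cds$replicon == repl & cds$strand == strand, ]
      d <- utr_distance(pos, cand$strand, cand$tss_start)
      cand <- cand[d >= params$long_utr_range[1] &
                     d <= params$long_utr_range[2], , drop = FALSE]
      if (nrow(cand) > 0) {
        cand <- cand[order(utr_distance(pos, cand$strand,
                                        cand$tss_start)), , drop = FALSE]
        for (j in seq_len(nrow(cand))) {
          span <- sort(c(pos, cand$tss_start[j]))
          cov <- covdf[covdf$replicon == repl & covdf$strand == strand &
                         covdf$pos >= span[1] & covdf$pos <= span[2], ]
          covered <- sum(cov$count >= params$coverage_min)
          if (covered == span[2] - span[1] + 1) {
            orphans$orphan_category[i] <- "long_5utr"
            orphans$target_locus[i] <- cand$locus_tag[j]
            break
          }
        }
        if (orphans$orphan_category[i] == "long_5utr") next
      }
    }
    ## downstream ORF on the same strand
    if (!is.null(seqchars)) {
      orf <- find_orf_downstream(seqchars[[repl]], pos, strand, params)
      if (!is.null(orf)) {
        orphans$orphan_category[i] <- "orf_associated"
        orphans$orf_start[i] <- orf$orf_start
        orphans$orf_length[i] <- orf$orf_length
      }
    }
  }
  orphans
}

#' Relative expression of alternative TSS isoforms
#'
#' Share of each alternative TSS of one gene in the gene's total TSS signal.
#'
#' @param heights numeric vector of normalized TSS heights (or a data.frame
#'   with a `norm_height` column), one entry per isoform.
#' @return Percentages summing to 100.
#' @export
isoform_shares <- function(heights) {
  if (is.data.frame(heights)) heights <- heights$norm_height
  if (length(heights) == 0) stop("no isoforms given")
  if (any(heights < 0) || sum(heights) <= 0)
    stop("heights must be non-negative with a positive sum")
  100 * heights / sum(heights)
}
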