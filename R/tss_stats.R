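## Per-TSS differential expression, positional profiles, and
## functional-class enrichment.
##
## Fisher's exact test and the Benjamini-Hochberg step-up are implemented
## from their definitions so the pipeline's statistics are self-contained
## and fully specified (two-sided convention: minimum likelihood).

#' Per-TSS log2 fold change
#'
#' Normalized pseudocount log-ratio of pooled raw counts between two
#' conditions:
#' `log2(((count_b + pseudocount)/libsize_b) / ((count_a + pseudocount)/libsize_a))`.
#' No count-model p-value is attached; differential calls use a bare
#' |logFC| threshold.
#'
#' @param count_a,count_b pooled raw counts in conditions A and B
#'   (vectorized).
#' @param libsize_a,libsize_b pooled library sizes (> 0).
#' @param pseudocount added to both counts (default 0.5).
#' @return log2 fold change of B over A.
#' @export
tss_log_fc <- function(count_a, libsize_a, count_b, libsize_b,
                       pseudocount = 0.5) {
  stopifnot(all(libsize_a > 0), all(libsize_b > 0), pseudocount > 0)
  log2(((count_b + pseudocount) / libsize_b) /
         ((count_a + pseudocount) / libsize_a))
}

#' Differential TSS table for two conditions
#'
#' Matches calls between two annotated sets (same replicon/strand, within
#' `tolerance` nt) and computes the per-TSS log2 fold change on pooled raw
#' counts; calls detected in only one condition contribute a zero count on
#' the missing side.
#'
#' @param ann_a,ann_b annotation (or call) tables carrying `raw_count` and
#'   `library_size`.
#' @param tolerance match tolerance, nt.
#' @param lfc_threshold |logFC| above which `de_flag` is set (default 1).
#' @param pseudocount see [tss_log_fc()].
#' @return data.frame: identity columns (from condition A where matched),
#'   `count_a`, `count_b`, `libsize_a`, `libsize_b`, `log_fc`, `de_flag`,
#'   `detected_in`.
#' @export
diff_tss <- function(ann_a, ann_b, tolerance = 5, lfc_threshold = 1,
                     pseudocount = 0.5) {
  lib_a <- if (nrow(ann_a)) ann_a$library_size[1] else 1
  lib_b <- if (nrow(ann_b)) ann_b$library_size[1] else 1
  m <- match_tss_calls(ann_a, ann_b, tolerance)
  take <- function(ann, idx, count_a, count_b, detected_in) {
    if (length(idx) == 0) return(NULL)
    data.frame(replicon = ann$replicon[idx], strand = ann$strand[idx],
               pos = ann$pos[idx],
               tss_class = if (!is.null(ann$tss_class))
                 ann$tss_class[idx] else NA_character_,
               count_a = count_a, count_b = count_b,
               detected_in = detected_in)
  }
  parts <- list(
    take(ann_a, m$pairs$idx_a,
         count_a = ann_a$raw_count[m$pairs$idx_a],
         count_b = ann_b$raw_count[m$pairs$idx_b],
         detected_in = "both"),
    take(ann_a, m$unmatched_a,
         count_a = ann_a$raw_count[m$unmatched_a],
         count_b = 0, detected_in = "a_only"),
    take(ann_b, m$unmatched_b, count_a = 0,
         count_b = ann_b$raw_count[m$unmatched_b],
         detected_in = "b_only"))
  out <- do.call(rbind, Filter(Negate(is.null), parts))
  if (is.null(out))
    out <- data.frame(replicon = character(), strand = character(),
                      pos = integer(), tss_class = character(),
                      count_a = numeric(), count_b = numeric(),
                      detected_in = character())
  out$libsize_a <- lib_a
  out$libsize_b <- lib_b
  out$log_fc <- tss_log_fc(out$count_a, lib_a, out$count_b, lib_b,
                           pseudocount)
  out$de_flag <- abs(out$log_fc) > lfc_threshold
  rownames(out) <- NULL
  out
}

#' Positional profile of a TSS class along its cognate CDS
#'
#' Histogram of `relative_position` (0 = translation start, 1 = stop end,
#' in the sense-CDS coordinate system) over `n_bins` equal bins. Positions
#' outside [0, 1] (antisense TSSs matched through the upstream window) are
#' excluded.
#'
#' @param annotations output of [classify_tss()].
#' @param tss_class class to profile (`"iTSS"` or `"aTSS"`).
#' @param n_bins number of bins (default 10 = deciles).
#' @return data.frame `bin`, `lower`, `upper`, `n`, `fraction`; fractions
#'   sum to 1 when any TSS falls in range, empty class gives an empty
#'   profile.
#' @export
positional_profile <- function(annotations, tss_class = "iTSS",
                               n_bins = 10L) {
  rel <- annotations$relative_position[
    annotations$tss_class == tss_class &
      !is.na(annotations$relative_position)]
  rel <- rel[rel >= 0 & rel <= 1]
  if (length(rel) == 0) {
    return(data.frame(bin = integer(), lower = numeric(),
                      upper = numeric(), n = integer(),
                      fraction = numeric()))
  }
  bin <- pmin(floor(rel * n_bins) + 1L, n_bins)
  n <- tabulate(bin, nbins = n_bins)
  data.frame(bin = seq_len(n_bins),
             lower = (seq_len(n_bins) - 1) / n_bins,
             upper = seq_len(n_bins) / n_bins,
             n = n, fraction = n / sum(n))
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Computed from the hypergeometric definition: the two-sided p-value sums
#' the probabilities of all tables with the observed margins whose
#' probability does not exceed that of the observed table (minimum-
#' likelihood convention). The odds ratio is the sample odds ratio
#' `(a*d)/(b*c)` (`NaN` when 0/0).
#'
#' @param a,b,c,d table counts: `a` in-set & in-class, `b` in-set & not,
#'   `c` not-in-set & in-class, `d` neither.
#' @return list with `p_value` and `odds_ratio`.
#' @export
fisher_exact <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("table counts must be non-negative integers")
  m <- a + b
  n <- c + d
  k <- a + c
  if (m + n == 0) return(list(p_value = 1, odds_ratio = NaN))
  x <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(x, m, n, k)
  p0 <- stats::dhyper(a, m, n, k)
  p <- min(1, sum(probs[probs <= p0 * (1 + 1e-7)]))
  list(p_value = p, odds_ratio = (a * d) / (b * c))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: `adj_(i) = min_{j >= i} min(1, p_(j) * m / j)`
#' over the sorted p-values, returned in the input order.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return Adjusted p-values, same length and order as `p`.
#' @export
benjamini_hochberg <- function(p) {
  if (length(p) == 0) return(numeric())
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p)
  ord <- order(p)
  adj <- pmin(1, p[ord] * m / seq_len(m))
  if (m > 1) for (j in (m - 1):1) adj[j] <- min(adj[j], adj[j + 1])
  adj[order(ord)]
}

#' Functional-class enrichment of a TSS-derived gene set
#'
#' One two-sided Fisher's exact test per functional-class label comparing
#' membership in `target` against the rest of `universe`, with
#' Benjamini-Hochberg correction across labels.
#'
#' @param target character vector of gene identifiers (subset of
#'   `universe`), e.g. the cognate loci of one TSS class.
#' @param universe all gene identifiers considered.
#' @param class_map named character vector (or data.frame `id`, `class`)
#'   giving each universe member's single-letter class; members without a
#'   label get `"S"`.
#' @param alpha adjusted-p significance cutoff (default 0.05).
#' @return data.frame per class: `class_label`, `a`, `b`, `c`, `d`,
#'   `odds_ratio`, `p_value`, `adjusted_p`, `significant`.
#' @export
class_enrichment <- function(target, universe, class_map, alpha = 0.05) {
  if (length(universe) == 0) stop("empty universe")
  universe <- unique(universe)
  target <- unique(target)
  if (!all(target %in% universe))
    stop("target must be a subset of universe")
  if (is.data.frame(class_map))
    class_map <- stats::setNames(as.character(class_map$class),
                                 class_map$id)
  cls <- class_map[universe]
  cls[is.na(cls)] <- "S"
  in_target <- universe %in% target
  labels <- sort(unique(cls))
  rows <- lapply(labels, function(lb) {
    a <- sum(in_target & cls == lb)
    b <- sum(in_target & cls != lb)
    cc <- sum(!in_target & cls == lb)
    d <- sum(!in_target & cls != lb)
    ft <- fisher_exact(a, b, cc, d)
    data.frame(class_label = lb, a = a, b = b, c = cc, d = d,
               odds_ratio = ft$odds_ratio, p_value = ft$p_value)
  })
  out <- do.call(rbind, rows)
  out$adjusted_p <- benjamini_hochberg(out$p_value)
  out$significant <- out$adjusted_p < alpha
  out
}
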