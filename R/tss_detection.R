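## Sliding-window TSS detection on pooled 5'-end count tracks.
##
## A window of `window_width` nt qualifies when its summed 5'-end count,
## scaled to the reference library size, strictly exceeds `threshold_reads`
## ("exceeded" in the original rule). Overlapping qualifying windows are
## merged into maximal runs; each run yields one TSS at the coverage-weighted
## mean position, rounded to the nearest integer (round-half-even).

#' Detection parameters
#'
#' @param window_width sliding-window width in nt (default 5).
#' @param threshold_reads read threshold relative to the reference library
#'   (default 50); strict inequality.
#' @param reference_library_size library size the threshold refers to
#'   (default 2e6 reads).
#' @param top_n optional: keep only the `top_n` calls by normalized height
#'   genome-wide (ties broken by replicon order, then position). Emulates
#'   tuning the caller to a fixed number of most highly expressed TSSs.
#' @param merge_adjacent merge overlapping qualifying windows into one call
#'   per maximal run (default TRUE). With FALSE every qualifying window
#'   emits its own call; a single sharp peak then yields up to
#'   `window_width` near-duplicate calls.
#' @return Object of class `detection_params`.
#' @export
detection_params <- function(window_width = 5L, threshold_reads = 50,
                             reference_library_size = 2e6, top_n = NULL,
                             merge_adjacent = TRUE) {
  stopifnot(window_width >= 1, threshold_reads > 0,
            reference_library_size >= 1)
  structure(list(window_width = as.integer(window_width),
                 threshold_reads = threshold_reads,
                 reference_library_size = reference_library_size,
                 top_n = top_n, merge_adjacent = isTRUE(merge_adjacent)),
            class = "detection_params")
}

#' Pool replicate track sets into a single library
#'
#' Counts are summed position-wise and library sizes add, mirroring the
#' pooling of triplicate TSS libraries from one condition into a single
#' library before detection.
#'
#' @param tracks list of [end_track_set()] objects from the same genome.
#' @return One pooled [end_track_set()].
#' @export
pool_tracks <- function(tracks) {
  stopifnot(length(tracks) >= 1)
  if (inherits(tracks, "end_track_set")) tracks <- list(tracks)
  lens <- lapply(tracks, `[[`, "replicon_lengths")
  lens <- unique(Filter(Negate(is.null), lens))
  if (length(lens) > 1)
    stop("cannot pool tracks with mismatched replicon lengths")
  counts <- data.table::rbindlist(lapply(tracks, `[[`, "counts"))
  end_track_set(counts,
                library_size = sum(vapply(tracks, `[[`, 0, "library_size")),
                replicon_lengths = if (length(lens)) lens[[1]] else NULL,
                condition = tracks[[1]]$condition)
}

#' Detect TSSs on a pooled 5'-end track
#'
#' @param track pooled [end_track_set()]; `library_size` must be positive.
#' @param params [detection_params()].
#' @param condition condition label attached to every call.
#' @return data.frame of calls: `replicon`, `strand`, `pos` (1-based,
#'   coverage-weighted), `raw_count` (summed counts of the qualifying run),
#'   `norm_height` (`raw_count * reference_library_size / library_size`),
#'   `condition`, `library_size`, plus the qualifying-run bounds
#'   `run_start`/`run_end`. Sorted by replicon then position.
#' @export
detect_tss <- function(track, params = detection_params(),
                       condition = "CT") {
  stopifnot(inherits(track, "end_track_set"))
  if (track$library_size <= 0)
    stop("library_size must be positive for detection")
  empty <- data.frame(replicon = character(), strand = character(),
                      pos = integer(), raw_count = numeric(),
                      norm_height = numeric(), condition = character(),
                      library_size = numeric(),
                      run_start = integer(), run_end = integer())
  cnt <- track$counts
  if (nrow(cnt) == 0) return(empty)
  scale <- params$reference_library_size / track$library_size
  groups <- split(seq_len(nrow(cnt)),
                  list(cnt$replicon, cnt$strand), drop = TRUE)
  out <- lapply(groups, function(idx) {
    g <- cnt[idx, ]
    calls <- detect_in_group(g$pos, as.numeric(g$count),
                             params$window_width,
                             params$threshold_reads, scale,
                             params$merge_adjacent)
    if (is.null(calls)) return(NULL)
    data.frame(replicon = g$replicon[1], strand = g$strand[1], calls)
  })
  out <- data.table::rbindlist(Filter(Negate(is.null), out))
  if (nrow(out) == 0) return(empty)
  out$norm_height <- out$raw_count * scale
  out$condition <- condition
  out$library_size <- track$library_size
  rep_order <- unique(cnt$replicon)
  out <- out[order(match(out$replicon, rep_order), out$pos, out$strand), ]
  if (!is.null(params$top_n) && nrow(out) > params$top_n) {
    keep <- order(-out$norm_height, match(out$replicon, rep_order),
                  out$pos)[seq_len(params$top_n)]
    out <- out[sort(keep), ]
  }
  out <- as.data.frame(out)
  rownames(out) <- NULL
  out[, names(empty)]
}

## Core scan for one replicon/strand. `pos` sorted ascending, sparse.
detect_in_group <- function(pos, count, w, threshold, scale, merge) {
  lo <- max(1L, min(pos) - w + 1L)
  hi <- max(pos)
  v <- numeric(hi - lo + 1L)
  v[pos - lo + 1L] <- count
  n <- length(v)
  cs <- cumsum(v)
  ends <- pmin(seq_len(n) + w - 1L, n)
  wsum <- cs[ends] - c(0, cs)[seq_len(n)]
  qual <- which(wsum * scale > threshold)
  if (length(qual) == 0) return(NULL)
  if (merge) {
    runs <- IRanges::reduce(IRanges::IRanges(qual, pmin(qual + w - 1L, n)))
    a <- IRanges::start(runs)
    b <- IRanges::end(runs)
  } else {
    a <- qual
    b <- pmin(qual + w - 1L, n)
  }
  res <- lapply(seq_along(a), function(i) {
    sel <- a[i]:b[i]
    cc <- v[sel]
    nz <- cc > 0
    p_abs <- (sel + lo - 1L)[nz]
    cc <- cc[nz]
    raw <- sum(cc)
    c(pos = round(sum(p_abs * cc) / raw), raw_count = raw,
      run_start = a[i] + lo - 1L, run_end = b[i] + lo - 1L)
  })
  res <- as.data.frame(do.call(rbind, res))
  res$pos <- as.integer(res$pos)
  res[, c("pos", "raw_count", "run_start", "run_end")]
}

#' Match two call lists by position
#'
#' Greedy nearest-position matching on the same replicon and strand: pairs
#' are taken in order of increasing distance (ties by position) and each
#' call is used at most once.
#'
#' @param calls_a,calls_b data.frames with `replicon`, `strand`, `pos`.
#' @param tolerance maximum |position difference| in nt for a match.
#' @return list with `pairs` (data.frame `idx_a`, `idx_b`, `pos_a`, `pos_b`,
#'   `dist`), `unmatched_a`, `unmatched_b` (row indices into the inputs).
#' @export
match_tss_calls <- function(calls_a, calls_b, tolerance = 5) {
  pairs <- data.frame(idx_a = integer(), idx_b = integer(),
                      pos_a = integer(), pos_b = integer(), dist = integer())
  na <- nrow(calls_a)
  nb <- nrow(calls_b)
  if (na > 0 && nb > 0) {
    key_a <- paste(calls_a$replicon, calls_a$strand)
    key_b <- paste(calls_b$replicon, calls_b$strand)
    cand <- lapply(intersect(unique(key_a), unique(key_b)), function(k) {
      ia <- which(key_a == k)
      ib <- which(key_b == k)
      d <- abs(outer(calls_a$pos[ia], calls_b$pos[ib], "-"))
      ok <- which(d <= tolerance, arr.ind = TRUE)
      if (nrow(ok) == 0) return(NULL)
      data.frame(idx_a = ia[ok[, 1]], idx_b = ib[ok[, 2]],
                 dist = d[ok])
    })
    cand <- data.table::rbindlist(Filter(Negate(is.null), cand))
    if (nrow(cand) > 0) {
      cand <- cand[order(cand$dist, calls_a$pos[cand$idx_a],
                         calls_b$pos[cand$idx_b]), ]
      used_a <- logical(na)
      used_b <- logical(nb)
      keep <- logical(nrow(cand))
      for (i in seq_len(nrow(cand))) {
        ia <- cand$idx_a[i]
        ib <- cand$idx_b[i]
        if (!used_a[ia] && !used_b[ib]) {
          keep[i] <- TRUE
          used_a[ia] <- TRUE
          used_b[ib] <- TRUE
        }
      }
      cand <- as.data.frame(cand[keep, ])
      pairs <- data.frame(idx_a = cand$idx_a, idx_b = cand$idx_b,
                          pos_a = calls_a$pos[cand$idx_a],
                          pos_b = calls_b$pos[cand$idx_b],
                          dist = cand$dist)
    }
  }
  list(pairs = pairs,
       unmatched_a = setdiff(seq_len(na), pairs$idx_a),
       unmatched_b = setdiff(seq_len(nb), pairs$idx_b))
}
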