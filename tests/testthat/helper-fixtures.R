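# Shared fixtures: a minimal track builder, a brute-force detection oracle,
# and a hand-constructed toy genome whose classification was derived by hand.

make_track <- function(pos, count, lib = 2e6, strand = "+",
                       replicon = "chr", replicon_lengths = NULL) {
  end_track_set(data.frame(replicon = replicon, strand = strand,
                           pos = pos, count = count),
                library_size = lib, replicon_lengths = replicon_lengths)
}

# Independent brute-force oracle: enumerate every window over the full
# replicon, test the (strict) threshold, merge overlapping-or-adjacent
# qualifying windows by hand, and take the coverage-weighted mean of the
# non-zero positions in each merged run.
oracle_detect <- function(pos, count, L, w = 5, threshold = 50,
                          ref = 2e6, lib = 2e6) {
  cnt <- numeric(L)
  cnt[pos] <- count
  qual <- integer()
  for (p in seq_len(L)) {
    s <- sum(cnt[p:min(p + w - 1, L)])
    if (s * ref / lib > threshold) qual <- c(qual, p)
  }
  if (length(qual) == 0)
    return(data.frame(pos = integer(), raw_count = numeric()))
  iv <- cbind(qual, pmin(qual + w - 1L, L))
  runs <- list(iv[1, ])
  if (nrow(iv) > 1) {
    for (i in 2:nrow(iv)) {
      cur <- runs[[length(runs)]]
      if (iv[i, 1] <= cur[2] + 1) {
        cur[2] <- max(cur[2], iv[i, 2])
        runs[[length(runs)]] <- cur
      } else {
        runs[[length(runs) + 1]] <- iv[i, ]
      }
    }
  }
  out <- lapply(runs, function(r) {
    span <- r[1]:r[2]
    cc <- cnt[span]
    keep <- cc > 0
    data.frame(pos = as.integer(round(sum(span[keep] * cc[keep]) /
                                        sum(cc[keep]))),
               raw_count = sum(cc[keep]))
  })
  do.call(rbind, out)
}

random_sparse_track <- function(L = NULL, lib = NULL) {
  if (is.null(L)) L <- sample(200:10000, 1)
  n <- sample(1:40, 1)
  pos <- sort(sample(L, n))
  count <- sample(1:500, n, replace = TRUE)
  if (is.null(lib)) lib <- sample(c(5e5, 1e6, 2e6, 4e6), 1)
  list(pos = pos, count = count, L = L, lib = lib)
}

# Toy genome: 10 CDSs on a single 20-kb replicon, exercising the dominance
# failure branch, the dual-eligibility cascade case, leaderless 5'UTR
# offsets 0-6, window/antisense boundaries, and both strands.
toy_genome <- function() {
  cds <- data.frame(
    replicon = "toy",
    start = c(1001, 3001, 5001, 8001, 11001, 13001, 15001, 17001,
              18501, 301),
    end = c(2000, 4000, 6001, 9000, 12000, 13900, 16900, 18000,
            19000, 601),
    strand = c("+", "+", "+", "+", "-", "+", "+", "+", "-", "-"),
    locus_tag = paste0("g", 1:10),
    functional_class = c("P", "K", "E", "P", "L", "K", "S", "T", "M", "S"))
  tss_genome(data.frame(name = "toy", length = 20000L), cds)
}

# Calls for the toy genome with their hand-derived expected annotation.
toy_truth_table <- function() {
  df <- function(pos, strand, h, cls, locus, utr, lless, rel) {
    data.frame(pos = pos, strand = strand, norm_height = h,
               exp_class = cls, exp_locus = locus, exp_utr = utr,
               exp_leaderless = lless, exp_rel = rel)
  }
  rbind(
    df(851,  "+", 500, "pTSS", "g1", 150L, FALSE, NA),
    df(901,  "+", 200, "sTSS", "g1", 100L, FALSE, NA),
    df(801,  "+",  50, "sTSS", "g1", 200L, FALSE, NA),   # window edge, in
    df(800,  "+",  50, "oTSS", NA,   NA,   FALSE, NA),   # window edge, out
    df(2901, "+", 100, "sTSS", "g2", 100L, FALSE, NA),   # dominance fails:
    df(2951, "+",  60, "sTSS", "g2",  50L, FALSE, NA),   # 100 < 2 * 60
    df(3500, "+",  80, "iTSS", "g2", NA, FALSE, 499 / 999),
    df(5001, "+",  90, "pTSS", "g3", 0L, TRUE, NA),      # at the start base
    df(5401, "+",  70, "iTSS", "g3", NA, FALSE, 0.4),
    df(5951, "+",  70, "iTSS", "g3", NA, FALSE, 0.95),
    df(7951, "-",  40, "aTSS", "g4", NA, FALSE, -50 / 999),
    df(8500, "-",  40, "aTSS", "g4", NA, FALSE, 499 / 999),
    df(8001, "-",  40, "aTSS", "g4", NA, FALSE, 0),
    df(12150, "-", 300, "pTSS", "g5", 150L, FALSE, NA),
    df(12000, "-", 100, "sTSS", "g5", 0L, TRUE, NA),
    df(13001, "+", 400, "pTSS", "g6", 0L, TRUE, NA),     # leaderless 0..6
    df(13000, "+", 100, "sTSS", "g6", 1L, TRUE, NA),
    df(12999, "+",  90, "sTSS", "g6", 2L, TRUE, NA),
    df(12998, "+",  80, "sTSS", "g6", 3L, TRUE, NA),
    df(12997, "+",  70, "sTSS", "g6", 4L, TRUE, NA),
    df(12996, "+",  60, "sTSS", "g6", 5L, FALSE, NA),
    df(12995, "+",  50, "sTSS", "g6", 6L, FALSE, NA),
    df(16850, "+", 120, "pTSS", "g8", 151L, FALSE, NA),  # inside g7, window g8
    df(19100, "+",  30, "aTSS", "g9", NA, FALSE, -100 / 499),
    df(19101, "+",  30, "oTSS", NA, NA, FALSE, NA),      # 101 nt upstream
    df(526,  "-",  60, "iTSS", "g10", NA, FALSE, 0.25),
    df(10500, "+",  45, "oTSS", NA, NA, FALSE, NA),
    df(10400, "-",  45, "oTSS", NA, NA, FALSE, NA),
    df(7000, "-",  25, "oTSS", NA, NA, FALSE, NA),
    df(14950, "-",  25, "aTSS", "g7", NA, FALSE, -51 / 1899))
}

toy_calls <- function() {
  tt <- toy_truth_table()
  data.frame(replicon = "toy", strand = tt$strand, pos = tt$pos,
             raw_count = tt$norm_height, norm_height = tt$norm_height,
             condition = "CT", library_size = 2e6)
}
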