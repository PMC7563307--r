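# Synthetic genome/truth/track generator: determinism, placement geometry,
# and the statistical properties of the simulated counts.

small_params <- function(seed = 3, ...) {
  sim_params(n_tss = 60, n_cds = 80,
             replicon_lengths = c(a = 150000L, b = 100000L),
             seed = seed, ...)
}

test_that("the generator is deterministic under a fixed seed", {
  p <- small_params()
  g1 <- generate_genome(p)
  g2 <- generate_genome(p)
  expect_identical(as.character(g1$seq), as.character(g2$seq))
  expect_identical(g1$cds, g2$cds)
  t1 <- plant_truth_tss(g1, p)
  t2 <- plant_truth_tss(g2, p)
  expect_identical(t1, t2)
  tr1 <- simulate_end_tracks(t1, g1, p, "CT")
  tr2 <- simulate_end_tracks(t2, g2, p, "CT")
  expect_identical(lapply(tr1, `[[`, "counts"),
                   lapply(tr2, `[[`, "counts"))
  d <- withr::local_tempdir()
  write_genome(g1, file.path(d, "a.fasta"), file.path(d, "a.gff3"))
  write_genome(g2, file.path(d, "b.fasta"), file.path(d, "b.gff3"))
  expect_identical(readLines(file.path(d, "a.gff3")),
                   readLines(file.path(d, "b.gff3")))
})

test_that("generated CDSs respect counts, bounds, and codon boundaries", {
  p <- small_params()
  g <- generate_genome(p)
  expect_equal(nrow(g$cds), 80L)
  lens <- stats::setNames(g$replicons$length, g$replicons$name)
  expect_true(all(g$cds$start >= 1))
  expect_true(all(g$cds$end <= lens[g$cds$replicon]))
  expect_true(all(g$cds$start <= g$cds$end))
  expect_true(all((g$cds$end - g$cds$start + 1) %% 3 == 0))
  # start codons are written into the sequence
  ch <- as.character(g$seq)
  plus <- g$cds[g$cds$strand == "+", ][1, ]
  expect_equal(substr(ch[[plus$replicon]], plus$start, plus$start + 2),
               "ATG")
})

test_that("an unplaceable CDS request is a hard error", {
  expect_error(generate_genome(
    sim_params(n_cds = 500, replicon_lengths = c(a = 50000L))),
    "unplaceable")
})

test_that("planted positions obey the class geometry they are meant to recover", {
  p <- small_params(seed = 9)
  g <- generate_genome(p)
  truth <- plant_truth_tss(g, p)
  cds <- g$cds
  expect_equal(nrow(truth), 60L)
  # primary/secondary: within 200 nt upstream of the cognate start codon
  ps <- truth[truth$intended_class %in% c("pTSS", "sTSS"), ]
  ci <- match(ps$cognate_locus, cds$locus_tag)
  d <- ifelse(cds$strand[ci] == "+", cds$tss_start[ci] - ps$position,
              ps$position - cds$tss_start[ci])
  expect_true(all(d >= 0 & d <= 200))
  expect_equal(ps$strand, cds$strand[ci])
  # internal: strictly inside the cognate CDS on the coding strand
  it <- truth[truth$intended_class == "iTSS", ]
  ci <- match(it$cognate_locus, cds$locus_tag)
  expect_true(all(it$position > cds$start[ci] &
                    it$position < cds$end[ci]))
  expect_equal(it$strand, cds$strand[ci])
  # orphans: exhaustive distance check against every CDS and every
  # 300-nt-upstream window
  ot <- truth[truth$intended_class == "oTSS", ]
  for (i in seq_len(nrow(ot))) {
    rc <- cds[cds$replicon == ot$replicon[i], ]
    gap_body <- pmax(rc$start - ot$position[i], ot$position[i] - rc$end)
    expect_true(all(gap_body > 300))
  }
  # planted TSSs on one strand never sit closer than the spacing margin
  by <- split(truth$position, paste(truth$replicon, truth$strand))
  expect_true(all(vapply(by, function(x)
    length(x) < 2 || min(diff(sort(x))) >= p$min_spacing, TRUE)))
})

test_that("a degenerate all-primary mix puts every TSS upstream of a start codon", {
  p <- small_params(seed = 5,
                    class_mix = c(pTSS = 1, sTSS = 0, iTSS = 0,
                                  aTSS = 0, oTSS = 0))
  g <- generate_genome(p)
  truth <- plant_truth_tss(g, p)
  expect_true(all(truth$intended_class == "pTSS"))
  cds <- g$cds
  ci <- match(truth$cognate_locus, cds$locus_tag)
  d <- ifelse(cds$strand[ci] == "+", cds$tss_start[ci] - truth$position,
              truth$position - cds$tss_start[ci])
  expect_true(all(d >= 0 & d <= 200))
})

test_that("a mix demanding more primaries than CDSs is a hard error", {
  p <- sim_params(n_tss = 200, n_cds = 80,
                  replicon_lengths = c(a = 150000L, b = 100000L),
                  class_mix = c(pTSS = 1, sTSS = 0, iTSS = 0,
                                aTSS = 0, oTSS = 0), seed = 3)
  g <- generate_genome(p)  # only 80 CDSs available
  expect_error(plant_truth_tss(g, p), "more pTSSs than eligible")
})

test_that("pooled peak counts match the configured expectation within 5%", {
  p <- sim_params(n_tss = 200, n_cds = 220, background_rate = 0,
                  seed = 31)
  g <- generate_genome(p)
  truth <- plant_truth_tss(g, p)
  pooled <- pool_tracks(simulate_end_tracks(truth, g, p, "CT"))
  cnt <- pooled$counts
  realized <- vapply(seq_len(nrow(truth)), function(i) {
    sum(cnt$count[cnt$replicon == truth$replicon[i] &
                    cnt$strand == truth$strand[i] &
                    abs(cnt$pos - truth$position[i]) <= 2])
  }, 0)
  expect_lt(abs(sum(realized) / sum(truth$mean_height) - 1), 0.05)
})

test_that("condition B counts scale by the planted fold change", {
  p <- sim_params(n_tss = 100, n_cds = 150, background_rate = 0,
                  de_fraction = 1, de_fold = 4, seed = 8)
  g <- generate_genome(p)
  truth <- plant_truth_tss(g, p)
  expect_true(all(truth$fold_change == 4))
  a <- pool_tracks(simulate_end_tracks(truth, g, p, "CT"))
  b <- pool_tracks(simulate_end_tracks(truth, g, p, "Cu"))
  ratio <- sum(b$counts$count) / sum(a$counts$count)
  expect_lt(abs(ratio / 4 - 1), 0.05)
})

test_that("a zero truth set with zero background yields empty tracks", {
  p <- small_params(background_rate = 0)
  g <- generate_genome(p)
  empty <- plant_truth_tss(g, p)[0, ]
  tr <- simulate_end_tracks(empty, g, p, "CT")
  expect_true(all(vapply(tr, function(t) nrow(t$counts), 0L) == 0))
})
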