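# Five-class cascade classification, re-annotation, orphan triage, and
# isoform shares on hand-derived fixtures.

test_that("the toy genome is classified exactly as hand-derived", {
  genome <- toy_genome()
  truth <- toy_truth_table()
  ann <- classify_tss(toy_calls(), genome)
  expect_equal(ann$tss_class, truth$exp_class)
  expect_equal(ann$cognate_locus, truth$exp_locus)
  expect_equal(ann$utr_length, truth$exp_utr)
  expect_equal(ann$leaderless, truth$exp_leaderless)
  expect_equal(ann$relative_position, truth$exp_rel, tolerance = 1e-12)
})

test_that("classes partition the calls (per-class counts sum to the total)", {
  ann <- classify_tss(toy_calls(), toy_genome())
  tab <- table(factor(ann$tss_class, c("pTSS", "sTSS", "iTSS", "aTSS",
                                       "oTSS")))
  expect_equal(sum(tab), nrow(ann))
  expect_true(all(ann$tss_class %in% names(tab)))
})

test_that("a genome without CDSs makes every call an orphan", {
  g <- tss_genome(data.frame(name = "toy", length = 20000L),
                  data.frame())
  ann <- classify_tss(toy_calls(), g)
  expect_true(all(ann$tss_class == "oTSS"))
})

test_that("assigned classes agree with independently computed eligibility on random genomes", {
  # cascade property: a call eligible for a higher-priority class is never
  # left in a lower one
  for (seed in 1:5) {
    p <- sim_params(n_tss = 40, n_cds = 40,
                    replicon_lengths = c(r = 80000L), seed = seed)
    genome <- generate_genome(p)
    set.seed(seed + 500)
    calls <- data.frame(replicon = "r",
                        strand = sample(c("+", "-"), 150, replace = TRUE),
                        pos = sort(sample(80000L, 150)),
                        norm_height = runif(150, 51, 500))
    calls$raw_count <- calls$norm_height
    ann <- classify_tss(calls, genome)
    cds <- genome$cds
    for (i in seq_len(nrow(ann))) {
      pos <- ann$pos[i]
      s <- ann$strand[i]
      same <- cds[cds$strand == s, ]
      opp <- cds[cds$strand != s, ]
      in_window <- any(ifelse(same$strand == "+",
                              pos >= same$tss_start - 200 &
                                pos <= same$tss_start,
                              pos >= same$tss_start &
                                pos <= same$tss_start + 200))
      in_body <- any(pos >= same$start & pos <= same$end)
      in_anti <- any(ifelse(opp$strand == "+",
                            pos >= opp$start - 100 & pos <= opp$end,
                            pos >= opp$start & pos <= opp$end + 100))
      expected <- if (in_window) c("pTSS", "sTSS")
                  else if (in_body) "iTSS"
                  else if (in_anti) "aTSS"
                  else "oTSS"
      expect_true(ann$tss_class[i] %in% expected,
                  info = sprintf("seed %d pos %d%s: got %s, eligible %s",
                                 seed, pos, s, ann$tss_class[i],
                                 paste(expected, collapse = "/")))
    }
  }
})

test_that("per-replicon summaries are consistent and conserve totals", {
  ann <- classify_tss(toy_calls(), toy_genome())
  s_same <- summarize_tss_classes(ann, ann, tolerance = 0)
  expect_equal(s_same$intersection, s_same$CT)
  expect_equal(s_same$CT, s_same$Cu)
  shifted <- ann
  shifted$pos <- shifted$pos + 5000L  # disjoint positions
  s_disj <- summarize_tss_classes(ann, shifted, tolerance = 3)
  expect_true(all(s_disj$intersection == 0))
  # genome row equals the sum over replicons
  for (cls in unique(s_same$tss_class)) {
    sub <- s_same[s_same$tss_class == cls, ]
    expect_equal(sub$CT[sub$replicon == "genome"],
                 sum(sub$CT[sub$replicon != "genome"]))
  }
})

# Re-annotation fixture: one + strand CDS without a pTSS, an iTSS between
# the annotated and the predicted start, and an AGGAGG motif 8 nt before
# the predicted start.
reannotation_fixture <- function(rbs = TRUE) {
  L <- 2000L
  chars <- rep("C", L)
  start <- 501L
  alt <- 546L           # 45 nt into the ORF, in frame
  chars[start:(start + 2)] <- c("A", "T", "G")
  chars[alt:(alt + 2)] <- c("A", "T", "G")
  if (rbs) chars[(alt - 14):(alt - 9)] <- c("A", "G", "G", "A", "G", "G")
  genome <- tss_genome(
    data.frame(name = "r", length = L),
    data.frame(replicon = "r", start = start, end = 1700L, strand = "+",
               locus_tag = "gene1", functional_class = "P"),
    seq = Biostrings::DNAStringSet(c(r = paste(chars, collapse = ""))))
  calls <- data.frame(replicon = "r", strand = "+", pos = 531L,  # iTSS
                      raw_count = 80, norm_height = 80,
                      condition = "CT", library_size = 2e6)
  list(genome = genome, ann = classify_tss(calls, genome))
}

test_that("re-annotation requires no pTSS, an intervening iTSS, and an RBS", {
  fx <- reannotation_fixture()
  expect_equal(fx$ann$tss_class, "iTSS")
  cand <- propose_reannotations(fx$genome, fx$ann,
                                data.frame(locus_tag = "gene1",
                                           alt_start = 546L))
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$original_start, 501L)
  expect_equal(cand$proposed_start, 546L)
  expect_equal(cand$supporting_itss_position, 531L)
  expect_true(cand$rbs_found)
  expect_equal(cand$rbs_spacer, 8L)
})

test_that("a CDS with a pTSS is never a re-annotation candidate", {
  fx <- reannotation_fixture()
  ptss <- data.frame(replicon = "r", strand = "+", pos = 451L,
                     raw_count = 500, norm_height = 500,
                     condition = "CT", library_size = 2e6)
  ann <- classify_tss(rbind(ptss, fx$ann[names(ptss)]), fx$genome)
  expect_equal(ann$tss_class, c("pTSS", "iTSS"))
  cand <- propose_reannotations(fx$genome, ann,
                                data.frame(locus_tag = "gene1",
                                           alt_start = 546L))
  expect_equal(nrow(cand), 0L)
})

test_that("missing iTSS, missing RBS, or out-of-frame alt start drop the candidate", {
  fx <- reannotation_fixture()
  # no iTSS between the starts (alt start upstream of the iTSS)
  expect_equal(nrow(propose_reannotations(
    fx$genome, fx$ann,
    data.frame(locus_tag = "gene1", alt_start = 528L))), 0L)
  # no RBS near the predicted start
  fx2 <- reannotation_fixture(rbs = FALSE)
  expect_equal(nrow(propose_reannotations(
    fx2$genome, fx2$ann,
    data.frame(locus_tag = "gene1", alt_start = 546L))), 0L)
  # out of frame: skipped with a warning
  expect_warning(
    cand <- propose_reannotations(
      fx$genome, fx$ann,
      data.frame(locus_tag = "gene1", alt_start = 547L)),
    "out of frame")
  expect_equal(nrow(cand), 0L)
})

# Orphan-triage fixture: a replicon whose sequence is A/C only (no start
# codons anywhere) except where ORFs are planted explicitly.
orphan_fixture <- function() {
  L <- 3000L
  set.seed(42)
  chars <- sample(c("A", "C"), L, replace = TRUE)
  # CDS at 1001..1600 (+) for the long-5'UTR branch
  chars[1001:1003] <- c("A", "T", "G")
  chars[1598:1600] <- c("T", "A", "A")
  # a 153-nt ORF starting 20 nt downstream of position 2001
  orf_start <- 2021L
  chars[orf_start:(orf_start + 2)] <- c("A", "T", "G")
  chars[(orf_start + 150):(orf_start + 152)] <- c("T", "A", "A")
  genome <- tss_genome(
    data.frame(name = "r", length = L),
    data.frame(replicon = "r", start = 1001L, end = 1600L, strand = "+",
               locus_tag = "cdsA", functional_class = "P"),
    seq = Biostrings::DNAStringSet(c(r = paste(chars, collapse = ""))))
  genome
}

orphan_annotations <- function(pos) {
  data.frame(replicon = "r", strand = "+", pos = pos,
             raw_count = 60, norm_height = 60, condition = "CT",
             library_size = 2e6, tss_class = "oTSS",
             cognate_locus = NA_character_, utr_length = NA_integer_,
             relative_position = NA_real_, leaderless = FALSE)
}

full_coverage <- function(L = 3000L) {
  end_track_set(data.frame(replicon = "r",
                           strand = rep(c("+", "-"), each = L),
                           pos = rep(seq_len(L), 2), count = 5L))
}

test_that("orphans upstream of a start codon with uninterrupted coverage mark long 5'UTRs", {
  genome <- orphan_fixture()
  ann <- orphan_annotations(751L)  # 250 nt upstream of the start at 1001
  out <- triage_orphans(genome, ann, full_coverage())
  expect_equal(out$orphan_category, "long_5utr")
  expect_equal(out$target_locus, "cdsA")
})

test_that("one uncovered base between the orphan and the start codon breaks the long-5'UTR call", {
  genome <- orphan_fixture()
  cov <- full_coverage()
  cov$counts$count[cov$counts$strand == "+" & cov$counts$pos == 900] <- 0L
  out <- triage_orphans(genome, orphan_annotations(751L), cov)
  expect_false(out$orphan_category == "long_5utr")
})

test_that("an orphan just upstream of a qualifying ORF is ORF-associated", {
  genome <- orphan_fixture()
  out <- triage_orphans(genome, orphan_annotations(2001L), full_coverage())
  expect_equal(out$orphan_category, "orf_associated")
  expect_equal(out$orf_start, 2021L)
  expect_equal(out$orf_length, 153L)
})

test_that("an orphan in a start-codon desert is an sRNA candidate, and categories are exhaustive", {
  genome <- orphan_fixture()
  ann <- rbind(orphan_annotations(751L), orphan_annotations(2001L),
               orphan_annotations(2600L))
  out <- triage_orphans(genome, ann, full_coverage())
  expect_equal(out$orphan_category,
               c("long_5utr", "orf_associated", "srna_candidate"))
  expect_true(all(out$orphan_category %in%
                    c("long_5utr", "orf_associated", "srna_candidate")))
})

test_that("missing coverage or sequence degrade triage with a warning", {
  genome <- orphan_fixture()
  expect_warning(out <- triage_orphans(genome, orphan_annotations(751L),
                                       NULL),
                 "coverage")
  expect_false(out$orphan_category[1] == "long_5utr")
  g2 <- genome
  g2$seq <- NULL
  expect_warning(out2 <- triage_orphans(g2, orphan_annotations(2001L),
                                        full_coverage()),
                 "sequence")
  expect_equal(out2$orphan_category, "srna_candidate")
})

test_that("isoform shares reproduce known relative expressions", {
  expect_equal(isoform_shares(c(6.1, 81.1, 12.8)), c(6.1, 81.1, 12.8))
  expect_equal(isoform_shares(42), 100)
  expect_equal(isoform_shares(rep(3, 4)), rep(25, 4))
  expect_equal(sum(isoform_shares(runif(7))), 100)
  expect_error(isoform_shares(numeric()), "no isoforms")
})
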