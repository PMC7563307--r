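## Synthetic multi-replicon genome, CDS annotation, and per-replicate
## 5'-end count tracks with a planted TSS truth set.
##
## The generator's defining contract: every planted TSS is placed so that
## the classifier, run on noise-free jitter-free tracks, assigns exactly the
## intended class. Placement therefore enforces the same geometric rules the
## classifier applies (upstream windows, CDS bodies, antisense regions) plus
## spacing margins so the detector never merges two planted peaks.

#' Simulation parameters
#'
#' Defaults describe the study conditions used throughout the package's
#' validation: a 500-kb two-replicon genome, 220 CDSs, 200 planted TSSs
#' with the five-class mix observed genome-wide in real bacterial TSS maps,
#' lognormal pooled peak heights floored at twice the detection threshold,
#' +-1 nt positional jitter, sparse uniform background, and triplicate
#' libraries per condition.
#'
#' @param replicon_lengths named integer vector of replicon lengths (nt).
#' @param n_cds number of CDSs to place (non-overlapping, both strands).
#' @param cds_length_range CDS length range, nt (rounded to codon
#'   multiples).
#' @param n_tss number of TSSs to plant.
#' @param class_mix named proportions over the five classes (sums to 1).
#' @param height_meanlog,height_sdlog lognormal parameters of the expected
#'   pooled peak height (reads at the TSS position, summed over
#'   replicates).
#' @param height_floor minimum expected pooled peak height; the default
#'   (300 raw reads = normalized height 100 at three pooled 2e6-read
#'   libraries) is twice the detection threshold.
#' @param jitter named probability mass over read-start offsets (names are
#'   offsets in nt).
#' @param background_rate expected uniform noise reads per nt per strand
#'   per replicate.
#' @param n_replicates replicates per condition.
#' @param library_size nominal per-replicate library size used for
#'   normalization (the 5'-end track is a subset of the library); `NULL`
#'   records the realized track total instead.
#' @param de_fraction fraction of TSSs given `fold_change = de_fold`
#'   (condition B vs A); the rest get 1.
#' @param de_fold fold change of the differentially expressed subset.
#' @param leaderless_fraction fraction of primary TSSs planted with 5'UTR
#'   length 0--4 nt (leaderless).
#' @param overdispersion gamma noise multiplier variance per TSS per
#'   replicate (0 = pure Poisson).
#' @param gc GC content of the synthetic sequence.
#' @param min_gap,max_gap intergenic gap range between placed CDSs, nt;
#'   `min_gap` must exceed the upstream classification window so planted
#'   windows never overlap neighboring CDSs.
#' @param min_spacing minimum distance between planted TSSs on the same
#'   strand, nt (keeps detection runs separate).
#' @param seed fixes every downstream draw.
#' @return Object of class `sim_params`.
#' @export
sim_params <- function(replicon_lengths = c(chr = 300000L, chr2 = 200000L),
                       n_cds = 220L,
                       cds_length_range = c(300L, 1500L),
                       n_tss = 200L,
                       class_mix = c(pTSS = 0.31, sTSS = 0.13, iTSS = 0.26,
                                     aTSS = 0.23, oTSS = 0.07),
                       height_meanlog = log(600), height_sdlog = 0.6,
                       height_floor = 300,
                       jitter = c("-1" = 0.1, "0" = 0.8, "1" = 0.1),
                       background_rate = 0.01,
                       n_replicates = 3L,
                       library_size = 2e6,
                       de_fraction = 0.3, de_fold = 4,
                       leaderless_fraction = 0.05,
                       overdispersion = 0,
                       gc = 0.61,
                       min_gap = 450L, max_gap = 1200L,
                       min_spacing = 15L,
                       seed = 1L) {
  stopifnot(all(sort(names(class_mix)) == sort(TSS_CLASSES)),
            abs(sum(class_mix) - 1) < 1e-8, all(class_mix >= 0),
            background_rate >= 0, n_replicates >= 1,
            de_fraction >= 0, de_fraction <= 1, de_fold > 0,
            abs(sum(jitter) - 1) < 1e-8, all(jitter >= 0),
            min_gap > 210, height_floor > 0)
  if (is.null(names(replicon_lengths)))
    names(replicon_lengths) <- sprintf("rep%02d", seq_along(replicon_lengths))
  structure(list(replicon_lengths = replicon_lengths,
                 n_cds = as.integer(n_cds),
                 cds_length_range = as.integer(cds_length_range),
                 n_tss = as.integer(n_tss),
                 class_mix = class_mix[TSS_CLASSES],
                 height_meanlog = height_meanlog,
                 height_sdlog = height_sdlog,
                 height_floor = height_floor,
                 jitter = jitter,
                 background_rate = background_rate,
                 n_replicates = as.integer(n_replicates),
                 library_size = library_size,
                 de_fraction = de_fraction, de_fold = de_fold,
                 leaderless_fraction = leaderless_fraction,
                 overdispersion = overdispersion,
                 gc = gc,
                 min_gap = as.integer(min_gap),
                 max_gap = as.integer(max_gap),
                 min_spacing = as.integer(min_spacing),
                 seed = as.integer(seed)),
            class = "sim_params")
}

## Evaluate `code` under `seed` without disturbing the caller's RNG stream.
with_sim_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

derive_seed <- function(base, offset) {
  (abs(base) %% 1000000L) * 1000L + offset
}

#' Generate a synthetic genome with non-overlapping CDSs
#'
#' CDSs are placed sequentially on randomly chosen strands with intergenic
#' gaps drawn from `min_gap`--`max_gap`, so every upstream classification
#' window is fully intergenic. Start (ATG) and stop (TAA) codons are written
#' into the sequence at each CDS's translation boundaries. Deterministic
#' under `params$seed`.
#'
#' @param params [sim_params()].
#' @return A [tss_genome()] with sequence.
#' @export
generate_genome <- function(params) {
  with_sim_seed(derive_seed(params$seed, 1L), {
    lens <- params$replicon_lengths
    quota <- round(params$n_cds * as.numeric(lens) / sum(as.numeric(lens)))
    quota[1] <- params$n_cds - sum(quota[-1])
    seqs <- list()
    cds <- list()
    fun_classes <- c("C", "E", "F", "J", "K", "L", "M", "O", "P", "T", "S")
    for (ri in seq_along(lens)) {
      L <- lens[[ri]]
      rname <- names(lens)[ri]
      chars <- sample(c("A", "C", "G", "T"), L, replace = TRUE,
                      prob = c((1 - params$gc) / 2, params$gc / 2,
                               params$gc / 2, (1 - params$gc) / 2))
      cur <- params$min_gap
      placed <- 0L
      while (placed < quota[ri]) {
        gap <- sample(params$min_gap:params$max_gap, 1L)
        len <- sample(params$cds_length_range[1]:params$cds_length_range[2],
                      1L)
        len <- len - len %% 3L
        start <- cur + gap
        end <- start + len - 1L
        if (end > L - params$min_gap)
          stop("requested CDS count unplaceable; reduce n_cds or ",
               "cds_length_range, or enlarge replicons")
        strand <- sample(c("+", "-"), 1L)
        if (strand == "+") {
          chars[start:(start + 2L)] <- c("A", "T", "G")
          chars[(end - 2L):end] <- c("T", "A", "A")
        } else {
          chars[(end - 2L):end] <- c("C", "A", "T")
          chars[start:(start + 2L)] <- c("T", "T", "A")
        }
        placed <- placed + 1L
        cds[[length(cds) + 1L]] <- data.frame(
          replicon = rname, start = start, end = end, strand = strand,
          locus_tag = sprintf("SYN_%s_%04d", rname, placed),
          functional_class = sample(fun_classes, 1L))
        cur <- end
      }
      seqs[[rname]] <- paste(chars, collapse = "")
    }
    genome <- tss_genome(
      replicons = data.frame(name = names(lens),
                             length = as.integer(unname(lens))),
      cds = do.call(rbind, cds),
      seq = Biostrings::DNAStringSet(unlist(seqs)))
    genome
  })
}

## Per-strand region index used to verify the geometric class of a planted
## position (same rules the classifier applies).
plant_geometry <- function(genome, p_window = 200L,
                           antisense_upstream = 100L) {
  cds <- genome$cds
  g <- list()
  for (rname in genome$replicons$name) {
    for (s in c("+", "-")) {
      same <- cds[cds$replicon == rname & cds$strand == s, ]
      opp <- cds[cds$replicon == rname & cds$strand != s, ]
      g[[rname]][[s]] <- list(
        window = if (nrow(same)) IRanges::reduce(IRanges::IRanges(
          ifelse(same$strand == "+",
                 pmax(1L, same$tss_start - p_window), same$tss_start),
          ifelse(same$strand == "+",
                 same$tss_start, same$tss_start + p_window)))
          else IRanges::IRanges(),
        body = if (nrow(same)) IRanges::reduce(
          IRanges::IRanges(same$start, same$end)) else IRanges::IRanges(),
        anti = if (nrow(opp)) IRanges::reduce(IRanges::IRanges(
          ifelse(opp$strand == "+",
                 pmax(1L, opp$start - antisense_upstream), opp$start),
          ifelse(opp$strand == "+",
                 opp$end, opp$end + antisense_upstream)))
          else IRanges::IRanges())
    }
  }
  g
}

in_ranges <- function(ir, pos) {
  if (length(ir) == 0) return(rep(FALSE, length(pos)))
  IRanges::overlapsAny(IRanges::IRanges(pos, pos), ir)
}

#' Plant a TSS truth set on a synthetic genome
#'
#' Positions are placed so that each TSS's intended class is the class the
#' classifier must assign: primary TSSs go into the upstream window of a
#' CDS (one per CDS, dominant by construction), secondary TSSs pair with a
#' planted primary at under half its height, internal TSSs go strictly
#' inside a CDS on the coding strand, antisense TSSs onto the non-coding
#' strand of a CDS or just upstream of its start, and orphan TSSs at least
#' 300 nt from every CDS. A `de_fraction` subset receives
#' `fold_change = de_fold`.
#'
#' @param genome output of [generate_genome()].
#' @param params [sim_params()].
#' @return data.frame truth set: `replicon`, `strand`, `position`,
#'   `intended_class`, `mean_height`, `fold_change`, `jitter_sd`,
#'   `cognate_locus`, `utr_length` (primary/secondary only).
#' @export
plant_truth_tss <- function(genome, params) {
  with_sim_seed(derive_seed(params$seed, 2L), {
    n_k <- round(params$n_tss * params$class_mix)
    n_k[1] <- params$n_tss - sum(n_k[-1])
    if (any(n_k < 0)) stop("class_mix rounding failed; adjust n_tss")
    cds <- genome$cds
    geom <- plant_geometry(genome)
    offs <- as.integer(names(params$jitter))
    jsd <- sqrt(sum(params$jitter * offs^2) -
                  sum(params$jitter * offs)^2)
    ## eligible CDSs for primaries: full window inside the replicon
    elig <- which(ifelse(cds$strand == "+", cds$tss_start - 200 >= 1,
                         cds$tss_start + 200 <=
                           genome$replicons$length[
                             match(cds$replicon, genome$replicons$name)]))
    if (n_k[["pTSS"]] > length(elig))
      stop("class_mix demands more pTSSs than eligible CDSs")
    if (n_k[["sTSS"]] > n_k[["pTSS"]])
      stop("every secondary TSS needs a planted primary on the same CDS; ",
           "class_mix demands more sTSSs than pTSSs")
    planted <- list()  # per replicon|strand position registry
    reg_key <- function(r, s) paste(r, s)
    ok_spacing <- function(r, s, pos) {
      ex <- planted[[reg_key(r, s)]]
      is.null(ex) || all(abs(ex - pos) >= params$min_spacing)
    }
    note <- function(r, s, pos) {
      k <- reg_key(r, s)
      planted[[k]] <<- c(planted[[k]], pos)
    }
    draw_height <- function(n) {
      pmax(stats::rlnorm(n, params$height_meanlog, params$height_sdlog),
           params$height_floor)
    }
    rows <- list()
    add_row <- function(r, s, pos, cls, h, locus, utr = NA_integer_) {
      note(r, s, pos)
      rows[[length(rows) + 1L]] <<- data.frame(
        replicon = r, strand = s, position = as.integer(pos),
        intended_class = cls, mean_height = h, fold_change = 1,
        jitter_sd = jsd, cognate_locus = locus,
        utr_length = as.integer(utr))
    }

    ## primaries (and their paired secondaries)
    p_cds <- sample(elig, n_k[["pTSS"]])
    paired <- rep(FALSE, n_k[["pTSS"]])
    if (n_k[["sTSS"]] > 0) paired[seq_len(n_k[["sTSS"]])] <- TRUE
    for (i in seq_along(p_cds)) {
      ci <- p_cds[i]
      r <- cds$replicon[ci]
      s <- cds$strand[ci]
      utr_p <- if (stats::runif(1) < params$leaderless_fraction)
        sample(0:4, 1L) else sample(15:120, 1L)
      pos_p <- cds$tss_start[ci] + if (s == "+") -utr_p else utr_p
      if (paired[i]) {
        s_h <- draw_height(1L)
        p_h <- s_h * stats::runif(1, 3, 6)
        utr_s <- utr_p + sample(params$min_spacing:70, 1L)
        pos_s <- cds$tss_start[ci] + if (s == "+") -utr_s else utr_s
        add_row(r, s, pos_p, "pTSS", p_h, cds$locus_tag[ci], utr_p)
        add_row(r, s, pos_s, "sTSS", s_h, cds$locus_tag[ci], utr_s)
      } else {
        add_row(r, s, pos_p, "pTSS", draw_height(1L),
                cds$locus_tag[ci], utr_p)
      }
    }

    ## internal: strictly inside a CDS, coding strand, clear of margins
    margin <- 30L
    wide <- which(cds$end - cds$start >= 2L * margin + 20L)
    h_i <- draw_height(n_k[["iTSS"]])
    placed <- 0L
    tries <- 0L
    while (placed < n_k[["iTSS"]]) {
      if ((tries <- tries + 1L) > 200L * n_k[["iTSS"]])
        stop("could not place internal TSSs; enlarge CDSs")
      ci <- sample(wide, 1L)
      r <- cds$replicon[ci]
      s <- cds$strand[ci]
      pos <- sample((cds$start[ci] + margin):(cds$end[ci] - margin), 1L)
      gg <- geom[[r]][[s]]
      if (in_ranges(gg$window, pos) || !ok_spacing(r, s, pos)) next
      placed <- placed + 1L
      add_row(r, s, pos, "iTSS", h_i[placed], cds$locus_tag[ci])
    }

    ## antisense: opposite strand of a CDS body (or <= 100 nt upstream)
    h_a <- draw_height(n_k[["aTSS"]])
    placed <- 0L
    tries <- 0L
    while (placed < n_k[["aTSS"]]) {
      if ((tries <- tries + 1L) > 200L * max(1L, n_k[["aTSS"]]))
        stop("could not place antisense TSSs")
      ci <- sample(nrow(cds), 1L)
      r <- cds$replicon[ci]
      s_call <- if (cds$strand[ci] == "+") "-" else "+"
      upstream <- stats::runif(1) < 0.15
      pos <- if (!upstream) {
        sample((cds$start[ci] + 10L):(cds$end[ci] - 10L), 1L)
      } else if (cds$strand[ci] == "+") {
        cds$start[ci] - sample(5:95, 1L)
      } else {
        cds$end[ci] + sample(5:95, 1L)
      }
      if (pos < 1 || pos > genome$replicons$length[
        match(r, genome$replicons$name)]) next
      gg <- geom[[r]][[s_call]]
      if (in_ranges(gg$window, pos) || in_ranges(gg$body, pos) ||
            !in_ranges(gg$anti, pos) || !ok_spacing(r, s_call, pos)) next
      placed <- placed + 1L
      add_row(r, s_call, pos, "aTSS", h_a[placed], cds$locus_tag[ci])
    }

    ## orphans: > 300 nt from every CDS on either strand
    forbid <- lapply(stats::setNames(nm = genome$replicons$name),
                     function(rname) {
      rc <- cds[cds$replicon == rname, ]
      if (nrow(rc) == 0) return(IRanges::IRanges())
      IRanges::reduce(IRanges::IRanges(pmax(1L, rc$start - 300L),
                                       rc$end + 300L))
    })
    h_o <- draw_height(n_k[["oTSS"]])
    placed <- 0L
    tries <- 0L
    while (placed < n_k[["oTSS"]]) {
      if ((tries <- tries + 1L) > 500L * max(1L, n_k[["oTSS"]]))
        stop("could not place orphan TSSs; enlarge intergenic space")
      ri <- sample(nrow(genome$replicons), 1L)
      r <- genome$replicons$name[ri]
      pos <- sample(genome$replicons$length[ri], 1L)
      s <- sample(c("+", "-"), 1L)
      if (in_ranges(forbid[[r]], pos) || !ok_spacing(r, s, pos)) next
      placed <- placed + 1L
      add_row(r, s, pos, "oTSS", h_o[placed], NA_character_)
    }

    truth <- do.call(rbind, rows)
    n_de <- floor(params$de_fraction * nrow(truth))
    if (n_de > 0)
      truth$fold_change[sample(nrow(truth), n_de)] <- params$de_fold
    rownames(truth) <- NULL
    truth
  })
}

#' Simulate per-replicate 5'-end count tracks
#'
#' For each replicate, each planted TSS contributes a Poisson draw with
#' mean `mean_height * fold_change^(condition is B) / n_replicates`,
#' spread over nearby offsets by the jitter mass; uniform background is
#' added as Poisson(`background_rate`) per nt per strand. Deterministic
#' under (`params$seed`, condition, replicate index).
#'
#' @param truth output of [plant_truth_tss()].
#' @param genome output of [generate_genome()].
#' @param params [sim_params()].
#' @param condition `"CT"` (reference) or `"Cu"` (fold changes applied).
#' @return list of [end_track_set()], one per replicate.
#' @export
simulate_end_tracks <- function(truth, genome, params,
                                condition = c("CT", "Cu")) {
  condition <- match.arg(condition)
  lens <- stats::setNames(genome$replicons$length, genome$replicons$name)
  offs <- as.integer(names(params$jitter))
  lapply(seq_len(params$n_replicates), function(rep_i) {
    seed <- derive_seed(params$seed,
                        10L * (1L + (condition == "Cu")) + rep_i)
    with_sim_seed(seed, {
      parts <- list()
      if (nrow(truth) > 0) {
        lam <- truth$mean_height *
          (if (condition == "Cu") truth$fold_change else 1) /
          params$n_replicates
        if (params$overdispersion > 0) {
          shp <- 1 / params$overdispersion
          lam <- lam * stats::rgamma(length(lam), shape = shp, rate = shp)
        }
        ntot <- stats::rpois(length(lam), lam)
        spread <- vapply(ntot, function(nn)
          stats::rmultinom(1, nn, params$jitter)[, 1],
          integer(length(offs)))
        k <- length(offs)
        parts$tss <- data.table::data.table(
          replicon = rep(truth$replicon, each = k),
          strand = rep(truth$strand, each = k),
          pos = pmin(pmax(rep(truth$position, each = k) +
                            rep(offs, nrow(truth)), 1L),
                     lens[rep(truth$replicon, each = k)]),
          count = as.integer(spread))
        parts$tss <- parts$tss[parts$tss$count > 0, ]
      }
      if (params$background_rate > 0) {
        bg <- lapply(names(lens), function(rname) {
          out <- lapply(c("+", "-"), function(s) {
            tot <- stats::rpois(1, params$background_rate * lens[[rname]])
            if (tot == 0) return(NULL)
            data.table::data.table(
              replicon = rname, strand = s,
              pos = sample.int(lens[[rname]], tot, replace = TRUE),
              count = 1L)
          })
          data.table::rbindlist(Filter(Negate(is.null), out))
        })
        parts$bg <- data.table::rbindlist(bg)
      }
      counts <- data.table::rbindlist(parts)
      end_track_set(counts, library_size = params$library_size,
                    replicon_lengths = lens, condition = condition)
    })
  })
}

#' Run the full simulation: genome, truth set, and both conditions' tracks
#'
#' @param params [sim_params()].
#' @param out_dir optional directory; when given, writes `genome.fasta`,
#'   `annotation.gff3`, `truth.tsv`, and per-replicate per-strand bedGraph
#'   tracks under `tracks/`.
#' @return list with `genome`, `truth`, `tracks` (list `CT`/`Cu` of
#'   per-replicate [end_track_set()]s) and `params`.
#' @export
simulate_tagrnaseq <- function(params = sim_params(), out_dir = NULL) {
  genome <- generate_genome(params)
  truth <- plant_truth_tss(genome, params)
  tracks <- list(CT = simulate_end_tracks(truth, genome, params, "CT"),
                 Cu = simulate_end_tracks(truth, genome, params, "Cu"))
  if (!is.null(out_dir)) {
    dir.create(file.path(out_dir, "tracks"), recursive = TRUE,
               showWarnings = FALSE)
    write_genome(genome, file.path(out_dir, "genome.fasta"),
                 file.path(out_dir, "annotation.gff3"))
    write_tss_table(truth, file.path(out_dir, "truth.tsv"))
    for (cond in names(tracks)) {
      for (i in seq_along(tracks[[cond]])) {
        write_end_counts(
          tracks[[cond]][[i]],
          file.path(out_dir, "tracks",
                    sprintf("%s_rep%d_plus.bedGraph", cond, i)),
          file.path(out_dir, "tracks",
                    sprintf("%s_rep%d_minus.bedGraph", cond, i)))
      }
    }
  }
  list(genome = genome, truth = truth, tracks = tracks, params = params)
}
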