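# Simulated evidence layers (homology hits, EST alignments, corrupted
# ab initio prediction tracks) over the planted truth, with bookkeeping
# sufficient to predict every downstream pipeline output exactly.

#' Simulate protein-homology hits for planted genes
#'
#' One tabular hit per exon, covering the coding exons except the stop
#' codon (protein alignments end at the last sense codon), with a
#' per-gene E-value drawn in the strict tier (<= 1e-10) or, for a minority
#' of genes, only in the relaxed tier (1e-10, 1e-5].
#'
#' @param truth one insert's truth.
#' @param p_relaxed_only probability a gene's evidence only clears the
#'   relaxed cutoff.
#' @return list with `hits` (data.frame as from [read_blast_tab()]) and
#'   `tiers` (named character vector of per-gene planted tiers).
#' @export
simulate_hits <- function(truth, p_relaxed_only = 0.1) {
  rows <- list()
  tiers <- character(0)
  for (g in truth$genes) {
    relaxed <- stats::runif(1) < p_relaxed_only
    e <- if (relaxed) 10^-stats::runif(1, 5.2, 9.5)
         else 10^-stats::runif(1, 15, 60)
    tiers[g$gene_id] <- if (relaxed) "relaxed" else "strict"
    ex <- g$exons
    # trim the stop codon from the terminal coding exon
    if (g$strand == "+") ex$end[nrow(ex)] <- ex$end[nrow(ex)] - 3L
    else ex$start[1L] <- ex$start[1L] + 3L
    for (r in seq_len(nrow(ex))) {
      rows[[length(rows) + 1L]] <- data.frame(
        query_id = truth$insert_id, subject_id = g$subject,
        pct_identity = round(stats::runif(1, 60, 95), 2),
        aln_length = as.integer((ex$end[r] - ex$start[r] + 1L) %/% 3L),
        query_start = ex$start[r], query_end = ex$end[r],
        strand = g$strand, e_value = e,
        bit_score = round(stats::runif(1, 80, 400), 1),
        description = g$description, stringsAsFactors = FALSE)
    }
  }
  list(hits = do.call(rbind, c(rows, list(empty_hits()))), tiers = tiers)
}

#' Simulate spliced EST alignments over planted genes
#'
#' Each gene draws a coverage class.  `complete` genes get one or two
#' top-tier ESTs whose pooled segments tile every coding base (segments
#' follow the planted exon boundaries); `partial` genes get a top-tier EST
#' covering a proper subset; `none` genes get at most a second-tier
#' (85-94.5% identity) EST.  Planted EST-only regions get a top-tier EST
#' of their own.
#'
#' @param truth one insert's truth.
#' @param cfg a [sim_config()].
#' @return list with `ests` (tidy segment table) and `classes` (named
#'   per-gene coverage classes).
#' @export
simulate_ests <- function(truth, cfg = sim_config()) {
  segs <- list()
  classes <- character(0)
  eid <- 0L
  add_est <- function(exdf, identity, strand) {
    eid <<- eid + 1L
    data.frame(est_id = sprintf("%s_E%03d", truth$insert_id, eid),
               source_genus = "Fragaria", pct_identity = identity,
               strand = strand, seg_start = exdf$start, seg_end = exdf$end,
               stringsAsFactors = FALSE)
  }
  for (g in truth$genes) {
    cls <- sample(names(cfg$est_class_probs), 1L, prob = cfg$est_class_probs)
    classes[g$gene_id] <- cls
    ex <- g$exons
    if (cls == "complete") {
      if (nrow(ex) >= 3L && stats::runif(1) < 0.5) {
        b <- sample(2:(nrow(ex) - 1L), 1L)   # shared boundary exon
        segs[[length(segs) + 1L]] <- add_est(ex[1:b, , drop = FALSE],
                                             round(stats::runif(1, 95, 99.8), 2),
                                             g$strand)
        segs[[length(segs) + 1L]] <- add_est(ex[b:nrow(ex), , drop = FALSE],
                                             round(stats::runif(1, 95, 99.8), 2),
                                             g$strand)
      } else {
        segs[[length(segs) + 1L]] <- add_est(ex,
                                             round(stats::runif(1, 95, 99.8), 2),
                                             g$strand)
      }
    } else if (cls == "partial") {
      if (nrow(ex) >= 2L) {
        drop5 <- stats::runif(1) < 0.5
        keep <- if (drop5) 2:nrow(ex) else 1:(nrow(ex) - 1L)
        sub <- ex[keep, , drop = FALSE]
      } else {
        sub <- ex
        trim <- sample(30:100, 1L)
        if (stats::runif(1) < 0.5) sub$start <- sub$start + trim
        else sub$end <- sub$end - trim
      }
      segs[[length(segs) + 1L]] <- add_est(sub,
                                           round(stats::runif(1, 95, 99.5), 2),
                                           g$strand)
    } else {
      if (stats::runif(1) < 0.5)
        segs[[length(segs) + 1L]] <- add_est(ex,
                                             round(stats::runif(1, 85, 94.5), 2),
                                             g$strand)
    }
  }
  for (e in truth$est_only) {
    exdf <- data.frame(start = e$start, end = e$end)
    segs[[length(segs) + 1L]] <- add_est(exdf,
                                         round(stats::runif(1, 95, 99.5), 2),
                                         sample(c("+", "-"), 1L))
  }
  list(ests = do.call(rbind, c(segs, list(empty_ests()))), classes = classes)
}

#' Corrupt the planted gene set into ab initio prediction tracks
#'
#' Applies, per model, the failure modes of real predictors: missed genes,
#' gene mergers (one prediction spanning two adjacent same-strand non-TE
#' genes), gene splits (two predictions partitioning one multi-exon gene
#' at an intron), spurious predictions in feature-free background, and
#' codon jitter (a predicted boundary displaced by a small in-frame
#' offset).  Every applied event is logged, and the expected
#' reconciliation report ([summarize_models()] run against the truth
#' sites) is computed from the event log alone.
#'
#' @param truth one insert's truth.
#' @param cfg a [sim_config()].
#' @param frame_len length of the insert's padded frame.
#' @return list with `tracks` (named list of `prediction_track`),
#'   `expected` (data.frame of per-model expected report cells), and
#'   `events` (per-model event log).
#' @export
corrupt_predictions <- function(truth, cfg = sim_config(),
                                frame_len = NULL) {
  genes <- truth$genes
  n <- length(genes)
  ord <- order(vapply(genes, function(g) g$start, 1))
  genes <- genes[ord]
  all_codons <- unlist(lapply(genes, function(g)
    c(g$start_codon, g$stop_codon)))
  # feature-free pockets for spurious predictions
  occ <- cbind(
    start = vapply(genes, function(g) g$start, 1) - 50L,
    end = vapply(genes, function(g) g$end, 1) + 50L)
  if (nrow(truth$ssr_tracts))
    occ <- rbind(occ, cbind(truth$ssr_tracts$start - 10L,
                            truth$ssr_tracts$end + 10L))
  for (e in truth$est_only) occ <- rbind(occ, cbind(e$start - 50L, e$end + 50L))
  if (nrow(truth$gap_positions))
    occ <- rbind(occ, cbind(truth$gap_positions$pos - 50L,
                            truth$gap_positions$pos +
                              truth$gap_positions$pad + 50L))
  tracks <- list(); expected <- list(); events <- list()
  for (mn in cfg$model_names) {
    jitter_codon <- function(value) {
      repeat {
        v <- value + 3L * sample(c(-2L, -1L, 1L, 2L), 1L)
        if (!(v %in% all_codons) && v > 3L) return(v)
      }
    }
    preds <- list(); ev <- list()
    vs <- 0L; vp <- 0L; mergers <- 0L; genes_merged <- 0L; splits <- 0L
    take_codon <- function(value) {
      # returns list(value, valid): jittered codons never validate
      if (stats::runif(1) < cfg$p_codon_jitter)
        list(v = jitter_codon(value), ok = FALSE)
      else list(v = value, ok = TRUE)
    }
    gid <- 0L
    i <- 1L
    while (i <= n) {
      g <- genes[[i]]
      if (stats::runif(1) < cfg$p_miss) {
        ev[[length(ev) + 1L]] <- list(type = "miss", gene = g$gene_id)
        i <- i + 1L
        next
      }
      nxt <- if (i < n) genes[[i + 1L]] else NULL
      eo_between <- !is.null(nxt) && length(truth$est_only) &&
        any(vapply(truth$est_only, function(e)
          e$start > g$end && e$end < nxt$start, TRUE))
      mergeable <- !is.null(nxt) && nxt$strand == g$strand &&
        g$category != "te_related" && nxt$category != "te_related" &&
        !eo_between
      if (mergeable && stats::runif(1) < cfg$p_merge) {
        gid <- gid + 1L
        first5 <- if (g$strand == "+") g else nxt     # gene providing the start
        last3 <- if (g$strand == "+") nxt else g
        st <- take_codon(first5$start_codon)
        sp <- take_codon(last3$stop_codon)
        vs <- vs + st$ok; vp <- vp + sp$ok
        mergers <- mergers + 1L; genes_merged <- genes_merged + 2L
        preds[[length(preds) + 1L]] <- list(
          gene_id = sprintf("%s_%s_p%02d", truth$insert_id, mn, gid),
          start = g$start, end = nxt$end, strand = g$strand,
          start_codon = st$v, stop_codon = sp$v,
          exons = rbind(g$exons, nxt$exons))
        ev[[length(ev) + 1L]] <- list(type = "merge",
                                      genes = c(g$gene_id, nxt$gene_id))
        i <- i + 2L
        next
      }
      if (nrow(g$exons) >= 2L && stats::runif(1) < cfg$p_split) {
        b <- sample(seq_len(nrow(g$exons) - 1L), 1L)
        exA <- g$exons[1:b, , drop = FALSE]
        exB <- g$exons[(b + 1L):nrow(g$exons), , drop = FALSE]
        # transcript start lives in the leftmost part for +, rightmost for -
        mk <- function(ex, has_start, has_stop) {
          gid <<- gid + 1L
          st <- if (has_start) take_codon(g$start_codon) else
            list(v = NA_integer_, ok = FALSE)
          sp <- if (has_stop) take_codon(g$stop_codon) else
            list(v = NA_integer_, ok = FALSE)
          vs <<- vs + st$ok; vp <<- vp + sp$ok
          list(gene_id = sprintf("%s_%s_p%02d", truth$insert_id, mn, gid),
               start = min(ex$start), end = max(ex$end), strand = g$strand,
               start_codon = st$v, stop_codon = sp$v, exons = ex)
        }
        if (g$strand == "+") {
          preds[[length(preds) + 1L]] <- mk(exA, TRUE, FALSE)
          preds[[length(preds) + 1L]] <- mk(exB, FALSE, TRUE)
        } else {
          preds[[length(preds) + 1L]] <- mk(exA, FALSE, TRUE)
          preds[[length(preds) + 1L]] <- mk(exB, TRUE, FALSE)
        }
        splits <- splits + 1L
        ev[[length(ev) + 1L]] <- list(type = "split", gene = g$gene_id)
        i <- i + 1L
        next
      }
      gid <- gid + 1L
      st <- take_codon(g$start_codon); sp <- take_codon(g$stop_codon)
      vs <- vs + st$ok; vp <- vp + sp$ok
      preds[[length(preds) + 1L]] <- list(
        gene_id = sprintf("%s_%s_p%02d", truth$insert_id, mn, gid),
        start = g$start, end = g$end, strand = g$strand,
        start_codon = st$v, stop_codon = sp$v, exons = g$exons)
      i <- i + 1L
    }
    # spurious predictions in feature-free pockets
    n_spur <- stats::rpois(1L, cfg$spurious_per_insert)
    L <- frame_len %||% max(occ[, 2]) + 1000L
    spur_placed <- 0L
    if (n_spur > 0L) {
      occ2 <- occ
      if (length(preds))
        occ2 <- rbind(occ2, cbind(
          vapply(preds, function(p) p$start, 1) - 50L,
          vapply(preds, function(p) p$end, 1) + 50L))
      for (s in seq_len(n_spur)) {
        for (try in 1:50) {
          w <- sample(300:900, 1L)
          st0 <- sample(seq(100L, max(101L, L - w - 100L)), 1L)
          if (!any(st0 <= occ2[, 2] & (st0 + w) >= occ2[, 1])) {
            gid <- gid + 1L
            preds[[length(preds) + 1L]] <- list(
              gene_id = sprintf("%s_%s_p%02d", truth$insert_id, mn, gid),
              start = st0, end = st0 + w, strand = sample(c("+", "-"), 1L),
              start_codon = NA_integer_, stop_codon = NA_integer_,
              exons = data.frame(start = st0, end = st0 + w))
            occ2 <- rbind(occ2, cbind(st0 - 50L, st0 + w + 50L))
            spur_placed <- spur_placed + 1L
            break
          }
        }
      }
    }
    gdf <- data.frame(
      gene_id = vapply(preds, `[[`, "", "gene_id"),
      start = vapply(preds, function(p) as.integer(p$start), 1L),
      end = vapply(preds, function(p) as.integer(p$end), 1L),
      strand = vapply(preds, `[[`, "", "strand"),
      start_codon = vapply(preds, function(p) as.integer(p$start_codon), 1L),
      stop_codon = vapply(preds, function(p) as.integer(p$stop_codon), 1L),
      stringsAsFactors = FALSE)
    gdf$exons <- I(lapply(preds, `[[`, "exons"))
    tracks[[mn]] <- prediction_track(mn, gdf)
    expected[[mn]] <- data.frame(
      model_name = mn, predicted_genes = length(preds),
      unsupported = spur_placed, mergers = mergers,
      genes_merged = genes_merged, splits = splits,
      validated_starts = vs, validated_stops = vp,
      validated_total = vs + vp, stringsAsFactors = FALSE)
    events[[mn]] <- ev
  }
  list(tracks = tracks,
       expected = do.call(rbind, c(expected, list(make.row.names = FALSE))),
       events = events)
}

#' Assign reference loci and build the matching gene order
#'
#' Gives each non-TE planted gene an AGI-style locus code.  In
#' `"colinear"` mode, codes run consecutively (step 10) along each insert,
#' so an insert with n ordered genes yields exactly n-1 colinear pairs.
#'
#' @param truths list of per-insert truths.
#' @param mode `"colinear"` (default).
#' @return list with `site_loci` (named vector gene_id -> locus) and
#'   `order` (a [reference_gene_order()] table).
#' @export
simulate_reference_order <- function(truths, mode = "colinear") {
  loci <- character(0)
  for (ti in seq_along(truths)) {
    tr <- truths[[ti]]
    gs <- tr$genes[order(vapply(tr$genes, function(g) g$start, 1))]
    keep <- vapply(gs, function(g) g$category != "te_related", TRUE)
    gs <- gs[keep]
    if (length(gs) == 0L) next
    chrom <- sample(1:5, 1L)
    base <- sample(seq(10000L, 80000L, by = 1000L), 1L)
    for (i in seq_along(gs))
      loci[gs[[i]]$gene_id] <- sprintf("At%dg%05d", chrom, base + 10L * (i - 1L))
  }
  list(site_loci = loci, order = reference_gene_order(unname(loci)))
}

#' Simulate a complete study: inserts, truth, and all evidence layers
#'
#' Seeds the RNG once from `cfg$seed`; identical (seed, config) pairs give
#' byte-identical output.
#'
#' @param cfg a [sim_config()].
#' @return list with `records`, `truths`, `hits` (per insert), `tiers`,
#'   `ests`, `est_classes`, `tracks` (per insert, per model),
#'   `expected_reports` (per insert), `ref` (locus assignment + order).
#' @export
simulate_study <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  ids <- sprintf("ins%02d", seq_len(cfg$n_inserts))
  records <- list(); truths <- list(); hits <- list(); tiers <- list()
  ests <- list(); est_classes <- list(); tracks <- list(); expected <- list()
  for (id in ids) {
    gi <- generate_insert(cfg, id)
    records[[id]] <- gi$record
    truths[[id]] <- gi$truth
    h <- simulate_hits(gi$truth)
    hits[[id]] <- h$hits
    tiers[[id]] <- h$tiers
    e <- simulate_ests(gi$truth, cfg)
    ests[[id]] <- e$ests
    est_classes[[id]] <- e$classes
    cp <- corrupt_predictions(gi$truth, cfg,
                              frame_len = frame_length(gi$record))
    tracks[[id]] <- cp$tracks
    expected[[id]] <- cp$expected
  }
  ref <- simulate_reference_order(truths)
  list(records = records, truths = truths, hits = hits, tiers = tiers,
       ests = ests, est_classes = est_classes, tracks = tracks,
       expected_reports = expected, ref = ref)
}
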