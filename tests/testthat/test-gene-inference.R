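mk_hit <- function(qs, qe, subject = "SUBJ", strand = "+", e = 1e-30,
                   desc = "conserved protein", bits = 200) {
  data.frame(query_id = "fix", subject_id = subject, pct_identity = 90,
             aln_length = as.integer((qe - qs + 1) / 3), query_start = qs,
             query_end = qe, strand = strand, e_value = e, bit_score = bits,
             description = desc, stringsAsFactors = FALSE)
}

test_that("hit clustering applies dual cutoffs, chaining, and paralog merging", {
  p <- evidence_params()
  # a single strong hit gives one strict-tier site
  s <- cluster_hits_to_sites(mk_hit(100, 500, e = 2.3e-39))
  expect_identical(nrow(s), 1L)
  expect_identical(s$tier, "strict")
  # a hit between the cutoffs is retained only at the relaxed tier
  s <- cluster_hits_to_sites(mk_hit(100, 500, e = 1e-7))
  expect_identical(s$tier, "relaxed")
  # beyond the relaxed cutoff: discarded
  expect_identical(nrow(cluster_hits_to_sites(mk_hit(100, 500, e = 1e-4))), 0L)
  # strict/relaxed partition the admitted set
  hits <- rbind(mk_hit(100, 500, "A", e = 1e-40),
                mk_hit(2000, 2400, "B", e = 1e-7),
                mk_hit(8000, 8400, "C", e = 1e-12))
  s <- cluster_hits_to_sites(hits)
  expect_identical(sum(s$tier == "strict") + sum(s$tier == "relaxed"),
                   nrow(s))
  expect_identical(sum(s$tier == "strict"), 2L)

  # same-subject same-strand hits 500 bp apart chain into one site
  s <- cluster_hits_to_sites(rbind(mk_hit(100, 400), mk_hit(901, 1300)))
  expect_identical(nrow(s), 1L)
  expect_equal(c(s$start, s$end), c(100, 1300))
  # opposite strands never chain
  s <- cluster_hits_to_sites(rbind(mk_hit(100, 400),
                                   mk_hit(901, 1300, strand = "-")))
  expect_identical(nrow(s), 2L)
  # a gap beyond max_chain_gap splits the chain
  s <- cluster_hits_to_sites(rbind(mk_hit(100, 400), mk_hit(3000, 3400)))
  expect_identical(nrow(s), 2L)
  # two paralogous subjects over one physical site merge (>= 50% overlap)
  s <- cluster_hits_to_sites(rbind(mk_hit(100, 1000, "At5g66900", e = 1e-56),
                                   mk_hit(150, 1050, "At5g66910", e = 1e-54)))
  expect_identical(nrow(s), 1L)
  expect_identical(s$best_subject, "At5g66900")
  # no two output sites on one strand overlap by more than the threshold
  set.seed(9)
  hits <- do.call(rbind, lapply(1:12, function(i) {
    st <- sample(1:5000, 1)
    mk_hit(st, st + sample(200:800, 1), paste0("S", sample(1:4, 1)))
  }))
  s <- cluster_hits_to_sites(hits)
  if (nrow(s) >= 2) for (i in 1:(nrow(s) - 1)) for (j in (i + 1):nrow(s)) {
    ov <- min(s$end[i], s$end[j]) - max(s$start[i], s$start[j]) + 1
    shorter <- min(s$end[i] - s$start[i], s$end[j] - s$start[j]) + 1
    expect_lt(ov / shorter, p$same_site_overlap + 1e-9)
  }
})

test_that("sites are categorized by description keywords and probe identity", {
  sites <- rbind(
    make_site("s1", start = 1, end = 10, desc = "retroviral polyprotein-like"),
    make_site("s2", start = 20, end = 30, desc = "unknown protein"),
    make_site("s3", start = 40, end = 50, subject = "CHS_PROBE",
              desc = "chalcone synthase"),
    make_site("s4", start = 60, end = 70, desc = "protein kinase, putative"))
  probes <- data.frame(probe = "CHS", subject_id = "CHS_PROBE",
                       pct_identity = 98.5)
  out <- categorize_sites(sites, probes)
  expect_identical(out$category,
                   c("te_related", "unknown", "targeted", "known"))
  # a probe match below the identity floor is not targeted
  probes$pct_identity <- 95
  expect_identical(categorize_sites(sites, probes)$category[3], "known")
})

test_that("start/stop codons are inferred from frame-anchored scans", {
  set.seed(5)
  cds <- make_cds(aa = 30, stop_codon = "TAG")          # 93 bp
  up <- "GGCCGGCCGGCC"; down <- "CCGGCCGGCCGGTTT"
  rec <- make_record_with_gene(up, cds, down)
  gstart <- nchar(up) + 1L
  gend <- nchar(up) + nchar(cds)
  # homology region = cds minus the stop codon; anchor ATG is the start
  site <- make_site(start = gstart, end = gend - 3L, anchor3 = gstart)
  out <- infer_start_stop(site, rec)
  expect_identical(out$start_codon, gstart)
  expect_identical(out$stop_codon, gend - 2L)

  # minus strand: same gene reverse-complemented
  rc <- revcomp(paste0(up, cds, down))
  recm <- assemble_insert(c(c1 = rc), insert_id = "fixm")
  L <- nchar(rc)
  sitem <- make_site(start = L - (gend - 3L) + 1L, end = L - gstart + 1L,
                     strand = "-", anchor3 = L - gstart + 1L)
  outm <- infer_start_stop(sitem, recm)
  expect_identical(outm$start_codon, L - gstart + 1L)
  expect_identical(outm$stop_codon, L - (gend - 2L) + 1L)

  # upstream in-frame ATG opening a longer open stretch is preferred when
  # the homology region does not begin with ATG
  body <- paste0("ATG", "GCTGCTGCT")                    # ATG then 3 Ala
  rec2 <- make_record_with_gene("CCTTAACC", paste0(body, "CATCATCAT", "TAA"),
                                "GGGG")
  # homology starts at the CAT stretch (in frame with the ATG, 8+12+1)
  h5 <- 8L + 12L + 1L
  site2 <- make_site(start = h5, end = h5 + 8L, anchor3 = h5)
  out2 <- infer_start_stop(site2, rec2)
  expect_identical(out2$start_codon, 9L)                # the planted ATG
  expect_identical(out2$stop_codon, h5 + 9L)

  # site truncated by the insert end before any in-frame stop
  cds_nostop <- substr(make_cds(aa = 30), 1, 87)        # no stop codon
  rec3 <- make_record_with_gene("GG", cds_nostop, "")
  site3 <- make_site(start = 3L, end = 2L + 87L, anchor3 = 3L)
  out3 <- infer_start_stop(site3, rec3)
  expect_true(is.na(out3$stop_codon))

  # a site spanning a contig gap gets no codons and a contig_break flag
  recg <- assemble_insert(c(c1 = rand_dna(500), c2 = rand_dna(500)),
                          gap_pad = 100L)
  siteg <- make_site(start = 400L, end = 700L)
  outg <- infer_start_stop(siteg, recg)
  expect_true(is.na(outg$start_codon) && is.na(outg$stop_codon))
  expect_match(outg$truncation, "contig_break")
})

test_that("truncation flags distinguish artifactual, contig-break, and biological", {
  rec <- assemble_insert(c(c1 = rand_dna(10000)))
  # plus-strand site ending 10 bp before the insert end: artifactual 3'
  s <- flag_truncation(make_site(start = 8000, end = 9990), rec)
  expect_identical(s$truncation, "artifactual_3p")
  # minus-strand site near the insert start: its 3' end is truncated
  s <- flag_truncation(make_site(start = 5, end = 900, strand = "-"), rec)
  expect_identical(s$truncation, "artifactual_3p")
  # interior site much shorter than its homolog: biological truncation
  s <- flag_truncation(make_site(start = 4000, end = 4600), rec,
                       homolog_len = 450, predicted_len = 200)
  expect_identical(s$truncation, "biological")
  # full-length interior site: no flags
  s <- flag_truncation(make_site(start = 4000, end = 4600), rec,
                       homolog_len = 200, predicted_len = 200)
  expect_identical(s$truncation, "")
  # an artifactual explanation suppresses the biological call
  s <- flag_truncation(make_site(start = 8000, end = 9990), rec,
                       homolog_len = 450, predicted_len = 200)
  expect_identical(s$truncation, "artifactual_3p")
})

test_that("tandem duplicates are paired by subject and classified by orientation", {
  sites <- rbind(
    make_site("s1", start = 1000, end = 2000, strand = "-", subject = "CHS"),
    make_site("s2", start = 4500, end = 5500, strand = "-", subject = "CHS"),
    make_site("s3", start = 8000, end = 9000, strand = "-", subject = "ADH"),
    make_site("s4", start = 11000, end = 12000, strand = "+", subject = "ADH"),
    make_site("s5", start = 14000, end = 15000, strand = "+", subject = "TPS"),
    make_site("s6", start = 17000, end = 18000, strand = "-", subject = "PPR"))
  out <- detect_tandem_duplicates(sites)
  expect_identical(nrow(out), 2L)
  expect_identical(out$orientation[out$subject == "CHS"], "head_to_tail")
  expect_identical(out$orientation[out$subject == "ADH"], "head_to_head")
  # convergent pair via family matching (TPS-1 / TPS-2 style labels)
  fam <- rbind(
    make_site("f1", start = 100, end = 200, strand = "+", subject = "TPS-1"),
    make_site("f2", start = 500, end = 700, strand = "-", subject = "TPS-2"))
  out2 <- detect_tandem_duplicates(fam, subject_match = "same_family")
  expect_identical(out2$orientation, "tail_to_tail")
  # unrelated adjacent subjects yield no pair
  expect_identical(nrow(detect_tandem_duplicates(sites[c(2, 3), ])), 0L)
  # intervening-site limit respected
  expect_identical(detect_tandem_duplicates(sites)$intervening, c(0L, 0L))
})
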