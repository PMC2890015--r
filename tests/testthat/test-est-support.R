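test_that("EST tiering partitions identities with exact band edges", {
  expect_identical(tier_est(95.08), "top")
  expect_identical(tier_est(95.00), "top")
  expect_identical(tier_est(94.999), "second")
  expect_identical(tier_est(94), "second")
  expect_identical(tier_est(85), "second")
  expect_identical(tier_est(84.9), "unclassified")
  expect_error(tier_est(101), "outside")
  # partition: exactly one label each
  ids <- seq(0, 100, by = 0.5)
  expect_true(all(table(tier_est(ids)) > 0))
  expect_identical(length(tier_est(ids)), length(ids))
})

test_that("coverage classification pools spliced top-tier evidence at base level", {
  # two ESTs whose union (with within-EST splice gaps) tiles the cds
  cds <- c(1000L, 3000L)
  e1 <- rbind(make_est("E1", 1000, 1400), make_est("E1", 1900, 2200))
  e2 <- rbind(make_est("E2", 1900, 2200), make_est("E2", 2600, 3000))
  # gaps 1401-1899 and 2201-2599 are introns internal to single ESTs
  expect_identical(classify_coverage(cds[1], cds[2], rbind(e1, e2)),
                   "complete")
  # only the 5' and 3' ends covered, by different ESTs: partial
  ends <- rbind(make_est("E3", 1000, 1400), make_est("E4", 2600, 3000))
  expect_identical(classify_coverage(cds[1], cds[2], ends), "partial")
  # a single EST whose segments bracket the whole cds is complete
  one <- rbind(make_est("E5", 1000, 1500), make_est("E5", 2500, 3000))
  expect_identical(classify_coverage(cds[1], cds[2], one), "complete")
  # ... but not when its internal gap exceeds a plausible intron
  expect_identical(classify_coverage(cds[1], cds[2], one, max_intron = 500L),
                   "partial")
  # second-tier evidence never counts
  expect_identical(classify_coverage(cds[1], cds[2],
                                     make_est("E6", 1000, 3000, identity = 94)),
                   "none")
  expect_identical(classify_coverage(cds[1], cds[2], make_est("E7", 5000, 6000)),
                   "none")
  # monotone: adding an EST never demotes the class
  ranks <- c(none = 0L, partial = 1L, complete = 2L)
  base <- ranks[classify_coverage(cds[1], cds[2], ends)]
  more <- ranks[classify_coverage(cds[1], cds[2], rbind(ends, e1, e2))]
  expect_gte(more, base)
})

test_that("EST-only sites appear where neither homology nor predictions do", {
  rec <- assemble_insert(c(c1 = rand_dna(10000)), insert_id = "fix")
  sites <- make_site("s1", start = 2000, end = 3000)
  track <- make_track("At", start = 6000L, end = 6800L)
  ests <- rbind(
    make_est("Enew", 4200, 4800),              # free interior: new site
    make_est("Einside", 2100, 2500),           # inside a site: nothing
    make_est("Epred", 6100, 6500),             # inside a prediction: nothing
    make_est("Eedge", 9970, 9999),             # at the boundary: flagged
    make_est("Elow", 4900, 5400, identity = 90))  # second tier: ignored
  eo <- find_est_only_sites(ests, sites, list(track), rec)
  expect_identical(nrow(eo), 2L)
  expect_identical(eo$category, c("est_only", "est_only"))
  expect_identical(eo$start, c(4200L, 9970L))
  expect_identical(eo$truncation, c("", "artifactual_boundary"))
})

test_that("gene models are built from complete coverage and refuse otherwise", {
  # CHS-like: two exons, one intron
  site <- make_site("chs", start = 1000, end = 2200,
                    start_codon = 1000L, stop_codon = 2198L)
  ests <- rbind(make_est("E1", 1000, 1500), make_est("E1", 1901, 2200))
  gm <- build_gene_model(site, ests)
  expect_s3_class(gm, "gene_model")
  expect_identical(gm$intron_count, 1L)
  expect_identical(gm$introns$start, 1501L)
  expect_identical(gm$introns$end, 1900L)
  expect_identical(nrow(gm$exons), 2L)

  # HY5-like: three exons from two pooled ESTs, two introns
  site2 <- make_site("hy5", start = 1000, end = 3000,
                     start_codon = 1000L, stop_codon = 2998L)
  e <- rbind(make_est("A", 1000, 1400), make_est("A", 1801, 2200),
             make_est("B", 1801, 2200), make_est("B", 2601, 3000))
  gm2 <- build_gene_model(site2, e)
  expect_identical(gm2$intron_count, 2L)
  expect_identical(gm2$intron_lengths, c(400L, 400L))

  # single-exon EST spanning the whole cds: zero introns
  gm3 <- build_gene_model(site, make_est("E2", 900, 2300))
  expect_identical(gm3$intron_count, 0L)

  # undetermined codons refuse
  expect_error(build_gene_model(make_site("x", start = 1, end = 10), ests),
               "undetermined")
  # incomplete coverage refuses rather than guessing
  expect_error(build_gene_model(site, make_est("E3", 1000, 1500)),
               "not complete")
  # conflicting splice boundaries between ESTs are reported
  conflict <- rbind(make_est("A", 1000, 1500), make_est("A", 1901, 2200),
                    make_est("B", 1000, 2200))
  expect_error(build_gene_model(site, conflict), "conflicting splice")
})

test_that("intron statistics summarize counts and lengths over models", {
  mk_model <- function(id, lens) structure(
    list(site_id = id, intron_count = length(lens),
         intron_lengths = as.integer(lens)), class = "gene_model")
  # 43 introns over 15 genes reproduces the mean of 2.87
  set.seed(3)
  counts <- c(0, 1, 1, 1, 2, 2, 2, 3, 3, 3, 4, 5, 5, 6, 5)
  stopifnot(sum(counts) == 43)
  lens <- sample(84:933, 43, TRUE)
  off <- cumsum(c(0L, counts))
  models <- lapply(seq_along(counts), function(i)
    mk_model(paste0("g", i), lens[seq_len(counts[i]) + off[i]]))
  st <- intron_stats(models)
  expect_identical(st$total_introns, 43L)
  expect_identical(st$mean_per_gene, 2.87)
  expect_identical(st$min_per_gene, 0L)
  expect_identical(st$n_genes, 15L)
  expect_identical(st$n_below_threshold, sum(lens[seq_len(43)] < 150))
  # degenerate single intronless model
  st0 <- intron_stats(list(mk_model("g", integer(0))))
  expect_identical(st0$mean_per_gene, 0)
  expect_true(is.na(st0$mean_length))
  expect_error(intron_stats(list()), "empty")
})
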