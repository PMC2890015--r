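test_that("simulation is byte-identical under a fixed seed and config", {
  a <- simulate_study(sim_config(seed = 3, n_inserts = 2))
  b <- simulate_study(sim_config(seed = 3, n_inserts = 2))
  expect_identical(a$records[[1]]$sequence, b$records[[1]]$sequence)
  expect_identical(a$truths, b$truths)
  expect_identical(a$tracks, b$tracks)
  c <- simulate_study(sim_config(seed = 4, n_inserts = 2))
  expect_false(identical(a$records[[1]]$sequence, c$records[[1]]$sequence))
})

test_that("a zero-SSR configuration produces a scan-clean insert", {
  set.seed(1)
  gi <- generate_insert(sim_config(seed = 1, ssr_per_insert = 0,
                                   p_contig_break = 0), "insZ")
  expect_identical(nrow(gi$truth$ssr_tracts), 0L)
  expect_identical(nrow(scan_ssrs(gi$record$sequence)), 0L)
})

test_that("planted SSR tracts and operational loci are recovered exactly", {
  cfg <- sim_config(seed = 21, n_inserts = 5)
  st <- simulate_study(cfg)
  for (id in names(st$records)) {
    tr <- st$truths[[id]]
    got <- scan_ssrs(st$records[[id]]$sequence, insert_id = id)
    expect_identical(got$start, tr$ssr_tracts$start)
    expect_identical(got$end, tr$ssr_tracts$end)
    expect_identical(got$motif, tr$ssr_tracts$motif)
    expect_identical(got$repeat_count, tr$ssr_tracts$repeat_count)
    # motif classes agree with the planted canonical classes
    expect_identical(got$canonical_motif,
                     vapply(tr$ssr_tracts$motif, canonical_motif, "",
                            USE.NAMES = FALSE))
    loci <- merge_operational_loci(got)
    expect_identical(nrow(loci), length(unique(tr$expected_locus_group)))
    # conservation: every tract in exactly one locus
    expect_identical(sum(loci$n_tracts), nrow(got))
  }
})

test_that("planted genes are recovered with exact extents, strands, tiers, and codons", {
  cfg <- sim_config(seed = 33, n_inserts = 5)
  st <- simulate_study(cfg)
  for (id in names(st$records)) {
    rec <- st$records[[id]]
    ts <- truth_sites(st$truths[[id]], tiers = st$tiers[[id]])
    sites <- cluster_hits_to_sites(st$hits[[id]], insert_id = id)
    expect_identical(nrow(sites), nrow(ts))
    # homology extent excludes the stop codon the hits do not cover
    exp_start <- ifelse(ts$strand == "+", ts$start, ts$start + 3L)
    exp_end <- ifelse(ts$strand == "+", ts$end - 3L, ts$end)
    m <- match(paste(sites$start, sites$end), paste(exp_start, exp_end))
    expect_false(anyNA(m))
    expect_identical(sites$strand, ts$strand[m])
    expect_identical(sites$tier, ts$tier[m])
    for (i in seq_len(nrow(sites)))
      sites[i, ] <- infer_start_stop(sites[i, ], rec, st$ests[[id]])
    expect_identical(sites$start_codon, ts$start_codon[m])
    expect_identical(sites$stop_codon, ts$stop_codon[m])
  }
})

test_that("strict plus relaxed-only sites partition the admitted set as planted", {
  cfg <- sim_config(seed = 13, n_inserts = 4)
  st <- simulate_study(cfg)
  for (id in names(st$records)) {
    sites <- cluster_hits_to_sites(st$hits[[id]], insert_id = id)
    planted <- st$tiers[[id]]
    expect_identical(sum(sites$tier == "strict"),
                     sum(planted == "strict"))
    expect_identical(sum(sites$tier == "relaxed") + sum(sites$tier == "strict"),
                     length(planted))
  }
})

test_that("zero corruption reproduces the truth track; forced merging merges", {
  cfg0 <- sim_config(seed = 8, n_inserts = 1, p_merge = 0, p_split = 0,
                     p_miss = 0, p_codon_jitter = 0, spurious_per_insert = 0)
  set.seed(8)
  gi <- generate_insert(cfg0, "insA")
  cp <- corrupt_predictions(gi$truth, cfg0, frame_length(gi$record))
  ts <- truth_sites(gi$truth)
  tr <- cp$tracks[[1]]
  expect_identical(nrow(tr$genes), nrow(ts))
  expect_identical(tr$genes$start, ts$start[order(ts$start)])
  rep <- summarize_models(cp$tracks, ts)
  expect_true(all(rep$unsupported == 0L))
  expect_true(all(rep$mergers == 0L))
  expect_true(all(rep$splits == 0L))
  expect_identical(rep$validated_starts, rep$predicted_genes)

  # p_merge = 1 merges every eligible adjacent same-strand pair
  cfg1 <- sim_config(seed = 8, n_inserts = 1, p_merge = 1, p_split = 0,
                     p_miss = 0, p_codon_jitter = 0, spurious_per_insert = 0)
  set.seed(8)
  gi1 <- generate_insert(cfg1, "insA")
  cp1 <- corrupt_predictions(gi1$truth, cfg1, frame_length(gi1$record))
  rep1 <- summarize_models(cp1$tracks, truth_sites(gi1$truth))
  expect_identical(rep1$mergers, cp1$expected$mergers)
  expect_true(all(rep1$genes_merged == 2L * rep1$mergers))
})

test_that("EST simulation honors the drawn coverage classes", {
  cfg <- sim_config(seed = 29, n_inserts = 4)
  st <- simulate_study(cfg)
  for (id in names(st$records)) {
    ts <- truth_sites(st$truths[[id]])
    for (i in seq_len(nrow(ts))) {
      s <- ts[i, ]
      cds <- sort(c(s$start_codon, s$stop_codon))
      cds <- if (s$strand == "+") c(cds[1], cds[2] + 2L)
             else c(cds[1] - 2L, cds[2])
      expect_identical(classify_coverage(cds[1], cds[2], st$ests[[id]]),
                       unname(st$est_classes[[id]][s$site_id]),
                       label = paste(id, s$site_id))
    }
  }
})

test_that("gene models from complete simulated coverage recover planted structure", {
  cfg <- sim_config(seed = 29, n_inserts = 6)
  st <- simulate_study(cfg)
  n_checked <- 0L
  for (id in names(st$records)) {
    tr <- st$truths[[id]]
    ts <- truth_sites(tr)
    for (i in seq_len(nrow(ts))) {
      s <- ts[i, ]
      if (st$est_classes[[id]][s$site_id] != "complete") next
      gm <- build_gene_model(s, st$ests[[id]])
      g <- tr$genes[[which(vapply(tr$genes, function(x)
        x$gene_id == s$site_id, TRUE))]]
      expect_identical(gm$intron_count, nrow(g$exons) - 1L)
      expect_identical(gm$exons$start, as.integer(g$exons$start))
      expect_identical(gm$exons$end, as.integer(g$exons$end))
      n_checked <- n_checked + 1L
    }
  }
  expect_gte(n_checked, 3L)
})
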