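test_that("an interrupted repeat is two tracts that merge into one operational locus", {
  # (TCC)6 TCT (TCC)5: the TCT interruption splits the repeat
  s <- paste0(strrep("TCC", 6), "TCT", strrep("TCC", 5))
  tr <- scan_ssrs(s, insert_id = "14K06")
  expect_identical(nrow(tr), 2L)
  expect_identical(tr$motif, c("TCC", "TCC"))
  expect_identical(tr$repeat_count, c(6L, 5L))
  expect_identical(tr$start, c(1L, 22L))
  expect_identical(tr$end, c(18L, 36L))
  expect_identical(tr$start[2] - tr$end[1] - 1L, 3L)   # 3 bp apart
  loci <- merge_operational_loci(tr, merge_gap = 100L)
  expect_identical(nrow(loci), 1L)
  expect_identical(loci$n_tracts, 2L)

  expect_identical(nrow(scan_ssrs("ACGTACGCATG")), 0L)
})

test_that("tracts are maximal, primitive, and never contain N", {
  # (AT)10 is reported once under its primitive dinucleotide unit
  tr <- scan_ssrs(paste0("GGC", strrep("AT", 10), "CCG"))
  expect_identical(nrow(tr), 1L)
  expect_identical(tr$motif, "AT")
  expect_identical(tr$repeat_count, 10L)
  # an N terminates a tract
  trN <- scan_ssrs(paste0(strrep("AG", 7), "N", strrep("AG", 7)))
  expect_identical(nrow(trN), 2L)
  expect_identical(trN$repeat_count, c(7L, 7L))
  # below min_repeats: nothing
  expect_identical(nrow(scan_ssrs(strrep("AG", 4))), 0L)
})

test_that("motif canonicalization folds rotations and reverse complements as configured", {
  expect_identical(canonical_motif("CT", "rotation_rc"), "AG")
  expect_identical(canonical_motif("GAA", "rotation"), "AAG")
  expect_error(canonical_motif("ATAT"), "non-primitive")
  # mixed per-unit-length grouping: dinucleotides fold over rc,
  # trinucleotides do not (ACT and AGT remain distinct classes)
  expect_identical(canonical_motif("CT", "per_unit_length"), "AG")
  expect_identical(canonical_motif("AGT", "per_unit_length"), "AGT")
  expect_identical(canonical_motif("ACT", "per_unit_length"), "ACT")
  expect_identical(canonical_motif("AGT", "rotation_rc"), "ACT")
})

test_that("scanner output equals a brute-force oracle on random sequences", {
  set.seed(101)
  for (i in 1:100) {
    n <- sample(200:2000, 1)
    s <- rand_dna(n)
    # salt some sequences with genuine repeats so the comparison is not
    # vacuous on repeat-free backgrounds
    if (i %% 3 == 0) {
      unit <- sample(c("AG", "AT", "GAA", "ATCG", "TC"), 1)
      reps <- sample(5:12, 1)
      at <- sample(seq_len(n - nchar(unit) * reps), 1)
      substr(s, at, at + nchar(unit) * reps - 1L) <- strrep(unit, reps)
    }
    got <- scan_ssrs(s)[, c("start", "end", "motif", "unit_length",
                            "repeat_count")]
    exp <- brute_force_ssrs(s)
    rownames(got) <- rownames(exp) <- NULL
    expect_identical(got, exp, label = sprintf("sequence %d", i))
  }
})

test_that("locus merging is strict single-linkage chaining", {
  mk <- function(starts, len = 10L) data.frame(
    insert_id = "x", start = starts, end = starts + len - 1L,
    motif = "AG", canonical_motif = "AG", unit_length = 2L,
    repeat_count = 5L, stringsAsFactors = FALSE)
  # gap of exactly 100 bp does NOT merge (threshold is strict)
  tr <- mk(c(1L, 111L))     # gap = 111 - 10 - 1 = 100
  expect_identical(nrow(merge_operational_loci(tr, 100L)), 2L)
  tr <- mk(c(1L, 110L))     # gap = 99
  expect_identical(nrow(merge_operational_loci(tr, 100L)), 1L)
  # transitive chain: gaps 50 and 50 give one locus of three tracts
  tr <- mk(c(1L, 61L, 121L))
  loci <- merge_operational_loci(tr, 100L)
  expect_identical(nrow(loci), 1L)
  expect_identical(loci$n_tracts, 3L)
  expect_error(merge_operational_loci(
    rbind(mk(1L), within(mk(200L), insert_id <- "y"))), "multiple inserts")
})

test_that("density arithmetic reproduces per-Mb, spacing, and per-cM figures", {
  expect_identical(ssr_density_per_Mb(158, 708363), 223L)
  expect_identical(ssr_density_per_Mb(35, 708363), 49L)
  expect_identical(ssr_density_per_Mb(0, 1000), 0L)
  expect_error(ssr_density_per_Mb(1, 0), "positive")

  ctx <- genome_context(708363, 206e6, 424)
  r <- loci_per_cM(144, 708363, ctx)
  expect_identical(r$kb_per_cM, 486L)
  expect_equal(r$loci_per_cM, 144 / 708363 * 206e6 / 424, tolerance = 1e-12)
  expect_equal(round(r$loci_per_cM, 1), 98.8)
  # definitional identity: one locus per (genome/map) bp is 1 locus/cM
  bp_per_cM <- 206e6 / 424
  expect_equal(loci_per_cM(1, bp_per_cM, ctx)$loci_per_cM, 1.0,
               tolerance = 1e-9)
})

test_that("the SSR summary table conserves counts and reports spacings", {
  set.seed(7)
  cfg <- sim_config(seed = 7, n_inserts = 4)
  st <- simulate_study(cfg)
  tracts <- do.call(rbind, lapply(names(st$records), function(id)
    scan_ssrs(st$records[[id]]$sequence, insert_id = id)))
  loci <- do.call(rbind, lapply(split(tracts, tracts$insert_id),
                                merge_operational_loci))
  total_bp <- sum(vapply(st$records, function(r) r$total_length, 1))
  ctx <- genome_context(total_bp)
  sm <- summarize_ssrs(tracts, loci, ctx)
  # conservation: class counts sum to the total; every tract is in a locus
  expect_identical(sum(sm$classes$n), sm$total_tracts)
  expect_identical(sum(sm$subtotals$n), sm$total_tracts)
  expect_identical(sum(loci$n_tracts), nrow(tracts))
  expect_identical(sm$n_loci, nrow(loci))
  expect_equal(sm$kb_per_tract, round(total_bp / nrow(tracts) / 1000, 1))
  # empty input gives an all-zero table
  sm0 <- summarize_ssrs(empty_tracts_for_test(), NULL, ctx)
  expect_identical(sm0$total_tracts, 0L)
  expect_true(is.na(sm0$kb_per_tract))
})

test_that("raising min_repeats or merge_gap never increases tract or locus counts", {
  set.seed(31)
  for (i in 1:20) {
    s <- rand_dna(1500)
    unit <- sample(c("AG", "TA", "GAA"), 1)
    at <- sample(1:1000, 1)
    substr(s, at, at + nchar(unit) * 8 - 1L) <- strrep(unit, 8)
    n5 <- nrow(scan_ssrs(s, ssr_params(min_repeats = 5)))
    n6 <- nrow(scan_ssrs(s, ssr_params(min_repeats = 6)))
    expect_lte(n6, n5)
    tr <- scan_ssrs(s)
    if (nrow(tr) >= 2) {
      expect_lte(nrow(merge_operational_loci(tr, 200L)),
                 nrow(merge_operational_loci(tr, 50L)))
    }
  }
})
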