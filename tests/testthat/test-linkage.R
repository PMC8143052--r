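test_that("marker selection applies each design's set rule", {
  test <- vt("chr1", c(100L, 200L), "G", "A", af = c(0.9, 0.8))
  ctrl <- vt("chr1", 100L, "G", "A", af = 1, sample = "control")

  # design A: test minus control
  mA <- select_informative_markers(test, ctrl, "A")
  expect_identical(mA$pos, 200L)
  expect_identical(mA$source, "ems_induced")
  expect_identical(attr(mA, "orientation"), "maximize_af")

  # design B: intersection, oriented to minimise
  testB <- vt("chr1", c(100L, 300L), "A", "C", af = c(0.9, 0.1))
  ctrlB <- vt("chr1", c(100L, 300L), "A", "C", af = 1, sample = "control")
  mB <- select_informative_markers(testB, ctrlB, "B")
  expect_identical(mB$pos, c(100L, 300L))
  expect_identical(attr(mB, "orientation"), "minimize_af")
  # peak logic favours the low-AF marker under the 1-af transform
  pr <- compute_window_profile(mB, c(chr1 = 400L), window_size = 90L,
                               step = 90L, min_markers_per_window = 1L)
  pk <- locate_mapping_region(smooth_profile(pr))
  expect_true(pk$window$start <= 300L && pk$window$end >= 300L)

  # design C: intersection scored in both samples, delta oriented
  testC <- vt("chr1", c(100L, 200L), "G", "A", af = c(0.95, 0.5), dp = 100L)
  ctrlC <- vt("chr1", c(100L, 200L), "G", "A", af = c(0.33, 0.5), dp = 100L,
              sample = "control")
  mC <- select_informative_markers(testC, ctrlC, "C")
  expect_equal(mC$value, c(0.95 - 0.33, 0), tolerance = 1e-9)

  # design D: intersection markers plus a separate EMS pool
  testD <- vt("chr1", c(100L, 200L, 250L), "G", "A", af = 1)
  ctrlD <- vt("chr1", c(100L, 200L), "G", "A", af = 1, sample = "control")
  mD <- select_informative_markers(testD, ctrlD, "D")
  expect_identical(mD$pos, c(100L, 200L))
  expect_identical(attr(mD, "ems_pool")$pos, 250L)

  # a wrong design/control pairing aborts with a diagnostic
  expect_error(select_informative_markers(test, test, "A"), "informative")
})

test_that("window grids cover chromosomes as specified", {
  mk <- data.frame(chrom = "chr1", pos = c(2e6L, 3e6L), value = c(0.4, 0.6))
  pr <- compute_window_profile(mk, c(chr1 = 10e6), window_size = 4e6,
                               step = 2e6, min_markers_per_window = 1L)
  expect_identical(pr$start, c(1L, 2000001L, 4000001L, 6000001L))
  expect_identical(pr$end[4L], 10000000L)
  # both markers inside the first window average to 0.5
  expect_equal(pr$mean_af[1L], 0.5)
  # a window with no markers is flagged empty
  expect_true(pr$empty[4L])
  # a chromosome shorter than the window collapses to one window
  pr2 <- compute_window_profile(mk, c(chr1 = 3e6), window_size = 4e6,
                                step = 2e6, min_markers_per_window = 1L)
  expect_identical(nrow(pr2), 1L)
  expect_identical(pr2$end, 3000000L)
  # a trailing remainder gets a final truncated window
  pr3 <- compute_window_profile(mk, c(chr1 = 10500000), window_size = 4e6,
                                step = 2e6, min_markers_per_window = 1L)
  expect_identical(pr3$start[nrow(pr3)], 8000001L)
  expect_identical(pr3$end[nrow(pr3)], 10500000L)
  expect_error(compute_window_profile(mk, c(chr1 = 1e6), 1e5, 2e5, 1L),
               "step")
})

test_that("profile smoothing equals the brute-force weighted average", {
  # spec'd interior spike: (4*1 + (3+2+1)*2*0.5) / 16 = 0.625
  spike <- profile_fixture(c(0.5, 0.5, 0.5, 1.0, 0.5, 0.5, 0.5))
  sm <- smooth_profile(spike)
  expect_equal(sm$smoothed_af[4L], 0.625, tolerance = 1e-12)

  # constant profiles are fixed points
  const <- smooth_profile(profile_fixture(rep(0.5, 9)))
  expect_equal(const$smoothed_af, rep(0.5, 9), tolerance = 1e-12)

  # edge windows renormalise over the neighbours actually present
  edge <- profile_fixture(c(1, 0.5, 0.5, 0.5))
  sm_e <- smooth_profile(edge)
  expect_equal(sm_e$smoothed_af[1L], (4 * 1 + 3 * 0.5 + 2 * 0.5 + 1 * 0.5) / 10,
               tolerance = 1e-12)

  # 100 random profiles, including empties and chromosome edges
  set.seed(77)
  for (i in 1:100) {
    n <- sample(1:12, 1L)
    vals <- runif(n)
    vals[runif(n) < 0.2] <- NA
    pr <- profile_fixture(vals)
    sm <- smooth_profile(pr)
    expect_equal(sm$smoothed_af, oracle_smooth(vals, is.na(vals)),
                 tolerance = 1e-12)
  }

  # smoothing never crosses chromosomes
  two <- rbind(profile_fixture(c(1, 1, 1)),
               profile_fixture(c(0, 0, 0), chrom = "chr2"))
  attr(two, "orientation") <- "maximize_af"
  class(two) <- c("window_profile", "data.frame")
  sm2 <- smooth_profile(two)
  expect_equal(sm2$smoothed_af, c(1, 1, 1, 0, 0, 0), tolerance = 1e-12)
})

test_that("peak location follows orientation and breaks ties low", {
  pr <- profile_fixture(c(0.5, 0.9, 0.6))
  pr$smoothed_af <- pr$mean_af
  pk <- locate_mapping_region(pr)
  expect_identical(pk$window$start, 6L)
  expect_identical(pk$center, as.integer((6L + 15L) %/% 2L))

  pr2 <- profile_fixture(c(0.5, 0.1), orientation = "minimize_af")
  pr2$smoothed_af <- pr2$mean_af
  expect_identical(locate_mapping_region(pr2)$window$start, 6L)

  pr3 <- profile_fixture(c(0.7, 0.7, 0.2))
  pr3$smoothed_af <- pr3$mean_af
  expect_identical(locate_mapping_region(pr3)$window$start, 1L)

  pr4 <- profile_fixture(c(NA, NA))
  expect_error(locate_mapping_region(pr4), "empty")
})

test_that("candidate intervals size by genome and clip to chromosomes", {
  # genome-size-dependent defaults: 4 / 10 / 20 Mb
  small <- c(chr1 = 120e6)
  mid <- c(chr1 = 300e6, chr2 = 200e6)
  big <- c(chr1 = 1.2e9, chr2 = 1.0e9)
  expect_identical(define_candidate_interval("chr1", 60e6, small)$size,
                   as.integer(4e6))
  expect_identical(define_candidate_interval("chr1", 60e6, mid)$size,
                   as.integer(10e6))
  expect_identical(define_candidate_interval("chr1", 60e6, big)$size,
                   as.integer(20e6))

  iv <- define_candidate_interval("chr1", 10e6, c(chr1 = 30e6), size = 4e6)
  expect_identical(iv$start, 8000001L)
  expect_identical(iv$end, 12000000L)

  # near the start the interval shifts rather than shrinks
  iv2 <- define_candidate_interval("chr1", 1e6, c(chr1 = 30e6), size = 4e6)
  expect_identical(iv2$start, 1L)
  expect_identical(iv2$end, 4000000L)

  # short chromosomes truncate
  iv3 <- define_candidate_interval("chr1", 1e6, c(chr1 = 3e6), size = 4e6)
  expect_identical(iv3$start, 1L)
  expect_identical(iv3$end, 3000000L)
})

test_that("candidate mutation selection filters and reports", {
  iv <- structure(list(chrom = "chr1", center = 500L, start = 1L,
                       end = 1000L, size = 1000L),
                  class = "candidate_interval")
  v <- vt("chr1", c(100L, 200L, 300L, 2000L), "G", "A",
          af = c(0.95, 1.0, 0.4, 1.0))
  v$ref[2L] <- "A"; v$alt[2L] <- "C"  # non-EMS change inside the interval
  sel <- select_candidate_mutations(v, iv, min_candidate_af = 0.75,
                                    ems_only = TRUE)
  expect_identical(sel$candidates$pos, 100L)     # EMS, af .95, inside
  expect_identical(nrow(sel$all_variants), 4L)   # everything reported
  expect_false(sel$all_variants$ems_type[2L])
  expect_true(all(sel$candidates$pos %in% sel$all_variants$pos))

  # non-EMS candidates allowed when ems_only is off
  sel2 <- select_candidate_mutations(v, iv, 0.75, ems_only = FALSE)
  expect_identical(sel2$candidates$pos, c(100L, 200L))

  # raising the threshold never adds candidates
  prev <- NULL
  for (thr in c(0, 0.25, 0.5, 0.75, 0.9, 1)) {
    cur <- select_candidate_mutations(v, iv, thr, TRUE)$candidates$pos
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("designs A and B pick the same window under the mirror transform", {
  set.seed(88)
  for (rep in 1:5) {
    vals <- runif(12, 0.3, 0.9)
    prA <- profile_fixture(vals, orientation = "maximize_af")
    prB <- profile_fixture(1 - vals, orientation = "minimize_af")
    pkA <- locate_mapping_region(smooth_profile(prA))
    pkB <- locate_mapping_region(smooth_profile(prB))
    expect_identical(pkA$window$start, pkB$window$start)
    expect_equal(pkA$score, pkB$score, tolerance = 1e-12)
  }
})

test_that("the full linkage pipeline maps a simulated design-A mutant", {
  g <- random_genome(c(chr1 = 4e5), seed = 90)
  idx <- build_index(g, 16L)
  run <- run_linkage_simulation(
    g, idx, design = "A", n_mutations = 60, n_individuals = 40,
    cM_per_Mb = 50,   # compressed genome: keep linkage informative
    spec = read_sim_spec(depth = 25, read_length = 75),
    seed = 91, interval_size = 1e5, window_size = 2e4, step = 1e4,
    min_markers_per_window = 2L)
  expect_true(run$recovered)
  expect_true(run$causal_in_candidates)
  expect_s3_class(run$result, "linkage_map")
  expect_identical(nrow(run$test_variants), 60L)
  # candidates all lie inside the interval and are EMS-type
  cd <- run$result$candidates
  expect_true(all(cd$pos >= run$result$interval$start &
                    cd$pos <= run$result$interval$end))
  expect_true(all(is_ems_type(cd$ref, cd$alt)))
})

test_that("variant lists can arrive as VCF or SAM files", {
  g <- random_genome(c(chr1 = 50000L), seed = 92)
  idx <- build_index(g, 16L)
  muts <- simulate_ems_mutations(g, 12, seed = 93)
  hp <- haplotype_pool(muts, matrix(TRUE, 1L, nrow(muts)))
  reads <- simulate_reads(g, read_sim_spec(depth = 25, read_length = 75),
                          pool = hp, seed = 94)
  aln <- align_reads(idx, reads, paired = TRUE)
  v <- call_variants(pileup_from_alignments(aln, g), g)
  fv <- tmpfile(".vcf")
  vcf_write(v, fv)
  empty <- variant_table(sample = "control")
  fc <- tmpfile(".vcf")
  vcf_write(empty, fc)
  res <- map_point_mutation(fv, fc, g, design = "A", interval_size = 2e4,
                            window_size = 5e3, step = 2500,
                            min_markers_per_window = 1L)
  expect_s3_class(res, "linkage_map")
  expect_identical(nrow(res$test_variants), nrow(v))

  fs <- tmpfile(".sam")
  sam_write(aln, g, fs)
  res2 <- map_point_mutation(fs, fc, g, design = "A", interval_size = 2e4,
                             window_size = 5e3, step = 2500,
                             min_markers_per_window = 1L)
  expect_identical(res2$test_variants$pos, res$test_variants$pos)
})
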