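# Combing measurement calculus.

test_that("fiber construction enforces tract invariants", {
  f <- fiber("f", 100, list(c(10, 12), c(40, 45)))
  expect_equal(nrow(f$tracts), 2L)
  # abutting tracts are merged on construction
  f2 <- fiber("f", 100, list(c(10, 12), c(12, 15)))
  expect_equal(unname(f2$tracts), matrix(c(10, 15), ncol = 2))
  expect_error(fiber("f", 100, list(c(10, 14), c(12, 15))), "overlap")
  expect_error(fiber("f", 100, list(c(12, 10))), "exceed")
  expect_error(fiber("f", 100, list(c(90, 110))), "outside")
  expect_error(fiber("f", -1), "positive")
})

test_that("merge_gaps absorbs sub-threshold gaps and is idempotent", {
  expect_equal(unname(merge_gaps(rbind(c(10, 12), c(12.5, 13.2)), 1)),
               matrix(c(10, 13.2), ncol = 2))
  m <- rbind(c(10, 12), c(13.5, 14.5))
  expect_equal(unname(merge_gaps(m, 1)), unname(m))  # gap 1.5 >= 1 kept
  # gap exactly at threshold is a real gap
  m2 <- rbind(c(0, 5), c(6, 8))
  expect_equal(nrow(merge_gaps(m2, 1)), 2L)
  # chained merging
  m3 <- rbind(c(0, 1), c(1.5, 2), c(2.9, 3.5))
  expect_equal(unname(merge_gaps(m3, 1)), matrix(c(0, 3.5), ncol = 2))
  expect_equal(nrow(merge_gaps(NULL, 1)), 0L)
  expect_error(merge_gaps(rbind(c(5, 8), c(1, 2)), 1), "sorted")
  expect_error(merge_gaps(rbind(c(1, 5), c(4, 8)), 1), "sorted|disjoint")
  # idempotence on random inputs
  set.seed(31)
  for (i in 1:20) {
    f <- random_fiber(sprintf("r%d", i))
    g <- merge_gaps(f$tracts, 1)
    expect_equal(merge_gaps(g, 1), g)
  }
})

test_that("call_eyes applies the scoring rules in order", {
  # merged gap, interior eyes, discarded sub-threshold end tract
  ca <- call_eyes(fiber("A", 100, list(c(10, 12), c(12.5, 13.2), c(40, 45),
                                       c(99.5, 100))))
  expect_equal(unname(ca$eyes), rbind(c(10, 13.2), c(40, 45)))
  expect_equal(nrow(ca$terminal_tracks), 0L)
  expect_equal(unname(ca$discarded_tracts), rbind(c(99.5, 100)))
  expect_equal(ca$fork_count, 4L)

  # terminal track = one fork
  cb <- call_eyes(fiber("B", 50, list(c(0, 8), c(20, 24))))
  expect_equal(unname(cb$eyes), rbind(c(20, 24)))
  expect_equal(unname(cb$terminal_tracks), rbind(c(0, 8)))
  expect_equal(cb$fork_count, 3L)

  # fully replicated fiber: both forks ran off the fiber
  cc <- call_eyes(fiber("C", 100, list(c(0, 100))))
  expect_equal(nrow(cc$eyes), 0L)
  expect_equal(unname(cc$terminal_tracks), rbind(c(0, 100)))
  expect_equal(cc$fork_count, 0L)

  # an eye of exactly min_eye_kb is kept
  cd <- call_eyes(fiber("D", 50, list(c(10, 11))))
  expect_equal(nrow(cd$eyes), 1L)

  # terminal tolerance pulls near-extremity tracts into terminal class
  ce <- call_eyes(fiber("E", 50, list(c(0.3, 6))),
                  analysis_config(terminal_tolerance_kb = 0.5))
  expect_equal(nrow(ce$terminal_tracks), 1L)
  expect_equal(ce$fork_count, 1L)
})

test_that("fiber_summary computes EL, ETED, origins, replicated length", {
  sa <- fiber_summary(call_eyes(fiber("A", 100,
                                      list(c(10, 12), c(12.5, 13.2),
                                           c(40, 45), c(99.5, 100)))))
  expect_equal(sa$replicated_kb, 8.2)
  expect_equal(sa$eye_lengths_kb, c(3.2, 5.0))
  expect_equal(sa$origins_kb, c(11.6, 42.5))
  expect_equal(sa$eteds_kb, 30.9)

  sb <- fiber_summary(call_eyes(fiber("B", 50, list(c(0, 8), c(20, 24)))))
  expect_equal(sb$replicated_kb, 12.0)
  expect_equal(sb$eye_lengths_kb, 4.0)
  expect_equal(sb$eteds_kb, numeric(0))

  s0 <- fiber_summary(call_eyes(fiber("empty", 80)))
  expect_equal(s0$replicated_kb, 0)
  expect_equal(s0$n_eyes, 0L)
  expect_equal(s0$fork_count, 0L)
  expect_equal(s0$origins_kb, numeric(0))
})

test_that("aggregate_fibers pools length-weightedly", {
  fa <- fiber("A", 100, list(c(10, 12), c(12.5, 13.2), c(40, 45), c(99.5, 100)))
  fb <- fiber("B", 50, list(c(0, 8), c(20, 24)))
  agg <- aggregate_fibers(list(fa, fb))
  expect_equal(agg$replicated_fraction, 20.2 / 150)
  expect_equal(agg$fork_density_per_100kb, 100 * 7 / 150)
  expect_equal(agg$pct_unreplicated_fibers, 0)

  # duplicating every fiber leaves pooled fraction and density unchanged
  agg2 <- aggregate_fibers(list(fa, fb, fa, fb))
  expect_equal(agg2$replicated_fraction, agg$replicated_fraction)
  expect_equal(agg2$fork_density_per_100kb, agg$fork_density_per_100kb)

  # a single unlabeled fiber
  agg0 <- aggregate_fibers(fiber("U", 120))
  expect_equal(agg0$replicated_fraction, 0)
  expect_equal(agg0$fork_density_per_100kb, 0)
  expect_equal(agg0$pct_unreplicated_fibers, 100)

  # a fiber whose only tract is sub-threshold counts as unreplicated
  aggt <- aggregate_fibers(fiber("T", 120, list(c(50, 50.4))))
  expect_equal(aggt$pct_unreplicated_fibers, 100)

  expect_error(aggregate_fibers(list()), "no fibers")
  expect_error(aggregate_fibers(list(
    fiber("x", 10, condition = "mock", time_min = 1),
    fiber("y", 10, condition = "depleted", time_min = 1))), "multiple")
})

test_that("calculus agrees exactly with the brute-force oracle", {
  set.seed(41)
  cfg <- analysis_config()
  for (i in 1:300) {
    f <- random_fiber(sprintf("f%d", i))
    got <- fiber_summary(call_eyes(f, cfg))
    want <- oracle_eyes(f$length_kb, f$tracts)
    expect_equal(got$fork_count, want$forks, info = f$fiber_id)
    expect_equal(got$replicated_kb, want$replicated_kb, info = f$fiber_id)
    expect_equal(got$eye_lengths_kb, want$el, info = f$fiber_id)
    expect_equal(got$eteds_kb, want$eted, info = f$fiber_id)
    expect_equal(got$origins_kb, want$origins, info = f$fiber_id)
  }
})

test_that("lowering thresholds never decreases fork count; reapplication is stable", {
  set.seed(42)
  for (i in 1:60) {
    f <- random_fiber(sprintf("m%d", i))
    full <- call_eyes(f, analysis_config(min_eye_kb = 1, min_gap_kb = 1))
    lower_eye <- call_eyes(f, analysis_config(min_eye_kb = 0.25, min_gap_kb = 1))
    expect_gte(lower_eye$fork_count, full$fork_count)
    # with no eye-size filter, keeping more gaps splits eyes and can only
    # add forks (with min_eye > 0 the two filters interact: an un-merged
    # pair of sub-threshold tracts can be discarded where the merged tract
    # survived, so monotonicity in min_gap only holds at min_eye = 0)
    gap1 <- call_eyes(f, analysis_config(min_eye_kb = 0, min_gap_kb = 1))
    gap0 <- call_eyes(f, analysis_config(min_eye_kb = 0, min_gap_kb = 0.25))
    expect_gte(gap0$fork_count, gap1$fork_count)
    # merge_gaps then call_eyes is idempotent: re-running the calculus on
    # the called tracts changes nothing
    kept <- rbind(full$eyes, full$terminal_tracks)
    kept <- kept[order(kept[, 1]), , drop = FALSE]
    if (nrow(kept)) {
      again <- call_eyes(fiber(f$fiber_id, f$length_kb, kept),
                         analysis_config(min_eye_kb = 1, min_gap_kb = 1))
      expect_equal(again$fork_count, full$fork_count)
      expect_equal(unname(again$eyes), unname(full$eyes))
    }
  }
})

test_that("per-fiber invariants hold on simulated data", {
  p <- sim_params(n_fibers = 25, sample_times_min = c(15, 35), seed = 17)
  ex <- simulate_experiment(p)
  for (f in ex$fibers) {
    s <- fiber_summary(call_eyes(f))
    expect_lte(s$replicated_kb, s$length_kb + 1e-9)
    expect_lte(sum(s$eye_lengths_kb), s$replicated_kb + 1e-9)
    expect_equal(length(s$eteds_kb), max(0L, s$n_eyes - 1L))
    expect_equal(length(s$origins_kb), s$n_eyes)
  }
  st <- summarize_experiment(ex)
  expect_true(all(st$replicated_fraction >= 0 & st$replicated_fraction <= 1))
  expect_true(all(st$fork_density_per_100kb >= 0))
})

test_that("fiber table round-trips and validates", {
  p <- sim_params(n_fibers = 8, sample_times_min = c(10, 30), seed = 23)
  ex <- simulate_experiment(p)
  tsv <- tempfile(fileext = ".tsv")
  write_fiber_table(ex, tsv)
  fibers <- read_fiber_table(tsv)
  expect_length(fibers, 32L)
  # write(read(x)) reproduces the file byte for byte
  tsv2 <- tempfile(fileext = ".tsv")
  write_fiber_table(fibers, tsv2)
  expect_identical(readLines(tsv), readLines(tsv2))

  # unlabeled fibers survive the round trip and count in totals
  tsv3 <- tempfile(fileext = ".tsv")
  write_fiber_table(list(fiber("u1", 75, condition = "mock", time_min = 5),
                         fiber("u2", 60, list(c(5, 9)),
                               condition = "mock", time_min = 5)), tsv3)
  back <- read_fiber_table(tsv3)
  expect_length(back, 2L)
  expect_equal(aggregate_fibers(back)$pct_unreplicated_fibers, 50)

  # malformed coordinates are rejected naming the fiber
  bad <- tempfile(fileext = ".tsv")
  writeLines(c(paste(c("condition", "time_min", "fiber_id", "fiber_length_kb",
                       "tract_start_kb", "tract_end_kb"), collapse = "\t"),
               "mock\t10\tfX\t100.000\t12.000\t8.000"), bad)
  expect_error(read_fiber_table(bad), "fX")
  bad2 <- tempfile(fileext = ".tsv")
  writeLines(c(paste(c("condition", "time_min", "fiber_id", "fiber_length_kb",
                       "tract_start_kb", "tract_end_kb"), collapse = "\t"),
               "mock\t10\tfY\tnot_a_number\t1.000\t2.000"), bad2)
  expect_error(read_fiber_table(bad2), "line")
})

test_that("summaries and BED export are written", {
  p <- sim_params(n_fibers = 6, sample_times_min = 20, seed = 29)
  ex <- simulate_experiment(p)
  st <- summarize_experiment(ex)
  dir <- tempfile()
  write_summaries(attr(st, "stats"), dir)
  expect_true(all(file.exists(file.path(dir, c("pooled_stats.tsv",
                                               "pooled_stats.json",
                                               "per_fiber.tsv",
                                               "el_eted.tsv")))))
  pooled <- read.delim(file.path(dir, "pooled_stats.tsv"))
  expect_equal(nrow(pooled), 2L)

  bed <- tempfile(fileext = ".bed")
  calls <- lapply(ex$fibers[1:5], call_eyes)
  write_eyes_bed(calls, bed)
  n_eyes <- sum(vapply(calls, function(x) nrow(x$eyes), integer(1)))
  if (n_eyes > 0) {
    b <- read.delim(bed, header = FALSE)
    expect_equal(nrow(b), n_eyes)
    expect_true(all(b$V3 > b$V2))
  }

  yml <- tempfile(fileext = ".yaml")
  write_manifest(ex, yml)
  man <- yaml::read_yaml(yml)
  expect_equal(man$seed, 29L)
  expect_equal(man$n_fibers, 6L)
})
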