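# IPD table parsing, outlier/coverage filtering, and site partitioning.

toy_metadata <- function() {
  data.table::data.table(sample_id = c("s1", "dam"),
                         role = c("timepoint", "dam_control"),
                         time_h = c(8, NA_real_))
}

write_meta <- function(meta) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  write_tsv_table(meta, path, overwrite = TRUE)
  path
}

test_that("well-formed rows parse and malformed rows are logged, not fatal", {
  meta <- toy_metadata()
  lines <- c(
    "genome_id\tposition\tstrand\tbase\tipd\tsample_id",
    "g\t4\t+\tA\t1.5\ts1",
    "g\t4\t+\tA\tNA\ts1",          # non-numeric ipd
    "g\t5\t-\tA\t2.5\ts1",
    "g\t5\t-\tA\t1.1\tmystery",    # unknown sample
    "g\t4\t+\tA\t0.9\tdam"
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(lines, path)
  got <- read_ipd_table(path, meta)
  expect_equal(nrow(got$records), 3L)
  expect_equal(got$n_rejected, 2L)
  expect_setequal(got$rejected$line, c(3L, 5L))
  expect_match(got$rejected$reason[got$rejected$line == 3L], "ipd")
  expect_match(got$rejected$reason[got$rejected$line == 5L], "sample_id")
  expect_equal(got$records$time_h[got$records$sample_id == "s1"], c(8, 8))
})

test_that("missing columns and out-of-bounds positions are caught", {
  meta <- toy_metadata()
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("genome_id\tposition\tstrand\tipd", "g\t1\t+\t2"), path)
  expect_error(read_ipd_table(path, meta), "missing required columns")
  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("genome_id\tposition\tstrand\tbase\tipd\tsample_id",
               "g\t999\t+\tA\t2\ts1"), path2)
  g <- genome_sequence("g", strrep("A", 100))
  got <- read_ipd_table(path2, meta, genome = g)
  expect_equal(nrow(got$records), 0L)
  expect_match(got$rejected$reason, "bounds")
})

test_that("simulator output round-trips losslessly through the TSV dialect", {
  cfg <- sim_config(genome_length = 4000, gatc_count_target = 10,
                    background_per_site = 0, seed = 4)
  sim <- simulate_timecourse(cfg)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_tsv_table(sim$ipd, path, overwrite = TRUE)
  got <- read_ipd_table(path, sim$metadata)
  expect_equal(got$n_rejected, 0L)
  expect_equal(nrow(got$records), nrow(sim$ipd))
  data.table::setorderv(got$records, c("sample_id", "position", "strand", "ipd"))
  want <- data.table::copy(sim$ipd)
  data.table::setorderv(want, c("sample_id", "position", "strand", "ipd"))
  expect_equal(got$records$ipd, want$ipd, tolerance = 1e-12)
  expect_equal(got$records$position, want$position)
})

test_that("the outlier cutoff and coverage threshold apply as stated", {
  rec <- data.table::data.table(
    genome_id = "g", position = 4L, strand = "+", base = "A",
    ipd = c(3, 7, 60000), sample_id = "s1", role = "timepoint", time_h = 8)
  cl <- clean_observations(rec, outlier_cutoff = 50000, min_coverage = 2)
  expect_equal(sort(cl$observations$ipd), c(3, 7))
  expect_equal(cl$cells$n_outliers, 1L)
  expect_false(cl$cells$excluded)
  # boundary: 19 kept < 20 excluded; exactly 20 kept included
  rec19 <- data.table::data.table(
    genome_id = "g", position = 4L, strand = "+", base = "A",
    ipd = rep(1, 19), sample_id = "s1", role = "timepoint", time_h = 8)
  expect_true(clean_observations(rec19, min_coverage = 20)$cells$excluded)
  rec20 <- rec19[rep(1, 20)]
  expect_false(clean_observations(rec20, min_coverage = 20)$cells$excluded)
})

test_that("cleaning conserves counts and is idempotent", {
  cfg <- sim_config(genome_length = 4000, gatc_count_target = 10,
                    outlier_rate = 0.05, background_per_site = 0, seed = 5)
  sim <- simulate_timecourse(cfg)
  cl <- clean_observations(sim$ipd)
  expect_equal(cl$cells$n_raw, cl$cells$n_kept + cl$cells$n_outliers)
  expect_equal(sum(cl$report$n_raw), nrow(sim$ipd))
  expect_equal(sum(cl$report$n_kept), nrow(cl$observations))
  # idempotence on already-clean data
  cl2 <- clean_observations(cl$observations)
  expect_equal(sum(cl2$cells$n_outliers), 0L)
  expect_equal(nrow(cl2$observations), nrow(cl$observations))
})

test_that("partitioning yields one cell per site-sample with missing markers", {
  g <- genome_sequence("g", "AAGATCTTGGGATCAA")
  sites <- scan_motif(g, "GATC", 2)
  rec <- data.table::rbindlist(lapply(c("s1", "dam"), function(s) {
    data.table::data.table(
      genome_id = "g",
      position = rep(sites$position, each = 25),
      strand = rep(sites$strand, each = 25),
      base = "A", ipd = stats::runif(25 * nrow(sites), 1, 5),
      sample_id = s, role = ifelse(s == "dam", "dam_control", "timepoint"),
      time_h = ifelse(s == "dam", NA_real_, 8))
  }))
  # starve one cell below the coverage threshold
  rec <- rec[!(sample_id == "s1" & position == 12 & strand == "+" &
                 seq_len(.N) %in% which(sample_id == "s1" & position == 12 &
                                          strand == "+")[1:10])]
  cl <- clean_observations(rec, min_coverage = 20)
  tab <- partition_by_site(cl, sites)
  expect_equal(nrow(tab), nrow(sites) * 2L)
  expect_equal(sum(tab$status == "missing"), 1L)
  expect_equal(tab[status == "missing"]$position, 12L)
  expect_equal(sum(tab$n_kept), nrow(cl$observations))
  # a site key outside the motif list is an error
  bad <- data.table::copy(cl)
  bad$observations$position[1] <- 999L
  bad$cells$position[1] <- 999L
  expect_error(partition_by_site(bad, sites), "not in the motif site list")
})
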