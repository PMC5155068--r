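# LC-MS fraction / CV propagation / Chargaff checks and qPCR fold changes.

peak_row <- function(analyte, area, dil = 1, rep = 1, sample = "s") {
  data.table::data.table(sample_id = sample, replicate = rep,
                         analyte = analyte, peak_area = area,
                         dilution_factor = dil)
}

test_that("the meA fraction is area-ratio based and dilution-invariant", {
  peaks <- rbind(peak_row("meA", 1), peak_row("A", 3))
  expect_equal(mea_fraction(peaks)$fraction, 0.25)
  # same physical sample with meA measured at 5x dilution, factor applied
  diluted <- rbind(peak_row("meA", 1 / 5, dil = 5), peak_row("A", 3))
  expect_equal(mea_fraction(diluted)$fraction, 0.25)
  # dam control: no meA at all
  dam <- rbind(peak_row("meA", 0), peak_row("A", 2))
  expect_equal(mea_fraction(dam)$fraction, 0)
  both_zero <- rbind(peak_row("meA", 0), peak_row("A", 0))
  expect_true(mea_fraction(both_zero)$undefined)
  expect_error(mea_fraction(peak_row("A", 1)), "meA")
})

test_that("fraction is monotone in the meA area with A fixed", {
  f <- vapply(c(0.5, 1, 2, 4), function(a) {
    mea_fraction(rbind(peak_row("meA", a), peak_row("A", 3)))$fraction
  }, numeric(1))
  expect_true(all(diff(f) > 0))
  expect_true(all(f >= 0 & f <= 1))
})

test_that("percent CV evaluates directly and propagates as 3-4-5", {
  expect_equal(percent_cv(c(0.5, 0.5)), 0)
  expect_equal(percent_cv(c(0.4, 0.6)), 100 * stats::sd(c(0.4, 0.6)) / 0.5)
  expect_equal(percent_cv(c(0.4, 0.6)), 28.2842712, tolerance = 1e-6)
  expect_equal(propagate_cv(c(3, 4))$propagated, 5)
  got <- propagate_cv(list(c(0.5, 0.5), c(0.4, 0.6)))
  expect_equal(got$component_cv[1], 0)
  expect_equal(got$propagated, got$component_cv[2])
  # scale invariance of the CV
  expect_equal(percent_cv(7 * c(0.4, 0.6)), percent_cv(c(0.4, 0.6)))
})

test_that("Chargaff ratios count meA with the purines and flag losses", {
  eq <- rbind(peak_row("A", 1), peak_row("T", 1), peak_row("G", 1),
              peak_row("C", 1))
  r <- chargaff_ratios(eq)
  expect_equal(r$at_ratio, 1)
  expect_equal(r$gc_ratio, 1)
  expect_false(r$at_flag); expect_false(r$gc_flag)
  # moving adenine signal into the meA channel conserves the purine ratio
  moved <- rbind(peak_row("A", 0.7), peak_row("meA", 0.3), peak_row("T", 1),
                 peak_row("G", 1), peak_row("C", 1))
  expect_equal(chargaff_ratios(moved)$at_ratio, 1)
  lost <- rbind(peak_row("A", 1), peak_row("T", 1), peak_row("G", 0.9),
                peak_row("C", 1))
  r2 <- chargaff_ratios(lost)
  expect_equal(r2$gc_ratio, 0.9)
  expect_false(r2$gc_flag)  # within the default 0.1 tolerance
  expect_true(chargaff_ratios(lost, tolerance = 0.05)$gc_flag)
})

qpcr_rows <- function(gene, strain, ct, time_h = 8, mass = 25, eff = 1,
                      reps = seq_along(ct)) {
  data.table::data.table(gene = gene, strain = strain, time_h = time_h,
                         replicate = reps, ct = ct, rna_mass = mass,
                         primer_efficiency = eff)
}

test_that("relative expression is 2^dCT with mass/efficiency handling", {
  recs <- rbind(qpcr_rows("dnaE", "WT", c(20, 20, 20)),
                qpcr_rows("dnaE", "dam", c(20, 20, 20)))
  r <- relative_expression(recs, "dnaE", 8)
  expect_equal(r$fold, 1)   # Dam-independent control behavior
  expect_equal(r$sd, 0)
  recs4 <- rbind(qpcr_rows("nanC", "WT", c(20, 20, 20)),
                 qpcr_rows("nanC", "dam", c(22, 22, 22)))
  expect_equal(relative_expression(recs4, "nanC", 8)$fold, 4)
  # mass normalization: doubling the dam RNA mass halves its template need
  recs_m <- rbind(qpcr_rows("g", "WT", 20, mass = 25),
                  qpcr_rows("g", "dam", 20, mass = 50))
  expect_equal(relative_expression(recs_m, "g", 8, ref_mass = 25)$fold, 0.5)
  expect_error(relative_expression(recs4, "nanC", 72), "72")
})

test_that("self-comparison gives exactly fold 1", {
  recs <- rbind(qpcr_rows("g", "WT", c(19.2, 20.1, 20.7)),
                qpcr_rows("g", "dam", c(19.2, 20.1, 20.7)))
  expect_equal(relative_expression(recs, "g", 8)$fold, 1)
})

test_that("the fold-change table mirrors the plate structure", {
  plate <- simulate_qpcr_plate(c(nanC = 0.25, dnaE = 1), ct_noise_sd = 0,
                               seed = 6)
  tab <- fold_change_table(plate)
  expect_equal(nrow(tab), 4L)  # 2 genes x 2 time points
  expect_equal(tab[gene == "nanC" & time_h == 72]$fold, 0.25)
  expect_equal(tab[gene == "dnaE" & time_h == 8]$fold, 1)
  expect_equal(tab$sd, rep(0, 4))
  # a missing cell is marked, not dropped
  part <- plate[!(plate$gene == "nanC" & plate$time_h == 72 &
                    plate$strain == "dam")]
  tab2 <- fold_change_table(part)
  expect_true(tab2[gene == "nanC" & time_h == 72]$missing)
  expect_false(tab2[gene == "nanC" & time_h == 8]$missing)
})

test_that("simulated plates with noise recover the true fold within bounds", {
  folds <- vapply(1:200, function(s) {
    plate <- simulate_qpcr_plate(c(nanC = 0.25), ct_noise_sd = 0.1, seed = s,
                                 timepoints_h = 72)
    fold_change_table(plate)$fold
  }, numeric(1))
  expect_lt(abs(mean(log2(folds)) - log2(0.25)),
            3 * (0.1 * sqrt(2) / sqrt(3)) / sqrt(200))
})
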