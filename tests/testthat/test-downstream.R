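test_that("stratified evaluation matches a constructed hand-counted case", {
  # one correct nucleus outside, one missed nucleus inside the artifact
  gt <- matrix(0L, 16, 16)
  gt[2:4, 2:4] <- 1L                                 # outside, predicted
  gt[10:12, 10:12] <- 1L                             # inside, missed
  pred <- matrix(0L, 16, 16)
  pred[2:4, 2:4] <- 1L
  art <- matrix(0L, 16, 16)
  art[8:14, 8:14] <- 1L
  rep <- stratified_nuclei_eval(pred, gt, art)
  expect_equal(rep$inside_artifacts$pixel_report$recall, 0)
  expect_equal(rep$outside_artifacts$pixel_report$f1, 1)
  expect_equal(rep$all$pixel_report$recall, 0.5)
  # object level: outside pair matches, inside object is a miss
  expect_equal(rep$outside_artifacts$object_report$f1, 1)
  expect_equal(rep$inside_artifacts$object_report$counts$fn, 1L)
})

test_that("region counts are additive over the disjoint partition", {
  set.seed(19)
  for (i in 1:20) {
    pred <- random_mask(14, 14, 0.3)
    gt <- random_mask(14, 14, 0.3)
    art <- random_mask(14, 14, 0.2)
    rep <- stratified_nuclei_eval(pred, gt, art)
    for (f in c("tp", "fp", "fn", "tn")) {
      expect_equal(rep$inside_artifacts$pixel_report$counts[[f]] +
                     rep$outside_artifacts$pixel_report$counts[[f]],
                   rep$all$pixel_report$counts[[f]])
    }
  }
})

test_that("empty artifact region is flagged, not fabricated", {
  pred <- matrix(0L, 8, 8); pred[2:3, 2:3] <- 1L
  gt <- pred
  rep <- stratified_nuclei_eval(pred, gt, matrix(0L, 8, 8))
  expect_true(rep$inside_artifacts$empty_region)
  expect_equal(rep$outside_artifacts$pixel_report$counts,
               rep$all$pixel_report$counts)
})

test_that("morphometry: squares are solid, crosses are not", {
  lab <- matrix(0L, 20, 20)
  lab[3:12, 3:12] <- 1L                              # 10x10 square
  rec <- morphometry(lab)
  expect_equal(rec$area, 100)
  expect_equal(rec$solidity, 1.0)

  # plus-shaped object: area 5; hull of the pixel corners is an octagon
  # whose exact area is the 3x3 box minus four half-unit corner triangles
  lab2 <- matrix(0L, 9, 9)
  lab2[4, 3:5] <- 2L; lab2[3:5, 4] <- 2L
  rec2 <- morphometry(lab2)
  expect_equal(rec2$area, 5)
  expect_equal(rec2$solidity, 5 / (9 - 4 * 0.5))

  both <- matrix(0L, 30, 30)
  both[2:4, 2:4] <- 3L; both[20:24, 20:22] <- 7L
  rec3 <- morphometry(both)
  expect_equal(rec3$object_id, c(3, 7))
  expect_equal(nrow(rec3), 2)
  expect_true(all(rec3$solidity > 0 & rec3$solidity <= 1))
})

test_that("well intensities follow the pixel-subset means", {
  fl <- matrix(10, 20, 20)
  cell <- matrix(0L, 20, 20); cell[5:10, 5:10] <- 1L
  fl[cell == 1L] <- 100
  rec <- list(well = "W01", ligand = "L", concentration = 1e-7,
              fluor = fl, cell_mask = cell,
              artifact_mask = matrix(0L, 20, 20))
  w <- well_specific_intensity(list(rec))
  expect_equal(w$specific_intensity, 90)
  expect_equal(w$n_images_averaged, 1)

  # artifact covering half the cell area at aberrant intensity
  art <- matrix(0L, 20, 20); art[5:10, 5:7] <- 1L
  fl2 <- fl; fl2[art == 1L] <- 5000
  rec2 <- rec; rec2$fluor <- fl2; rec2$artifact_mask <- art
  w2 <- well_specific_intensity(list(rec2))
  keep_cell <- cell == 1L & art == 0L
  keep_bg <- cell == 0L & art == 0L
  expect_equal(w2$specific_intensity,
               mean(fl2[keep_cell]) - mean(fl2[keep_bg]))
  # without removal the aberrant pixels bias the estimate
  w3 <- well_specific_intensity(list(rec2), use_artifact_masks = FALSE)
  expect_gt(w3$specific_intensity, w2$specific_intensity)

  # four images in one well -> mean of the four per-image values
  recs <- lapply(1:4, function(i) {
    r <- rec; r$fluor <- fl + i; r
  })
  w4 <- well_specific_intensity(recs)
  expect_equal(w4$n_images_averaged, 4)
  expect_equal(w4$specific_intensity,
               mean(vapply(recs, function(r)
                 mean(r$fluor[cell == 1L]) - mean(r$fluor[cell == 0L]),
                 numeric(1))))
})

test_that("noise-free Hill data is recovered to 1e-4 log units", {
  conc <- 10^seq(-10, -4, length.out = 8)
  y <- 100 + (1000 - 100) / (1 + 10^(log10(conc) - (-7)))
  fit <- fit_hill(conc, y)
  expect_lt(abs(fit$logIC50 - (-7)), 1e-4)
  expect_gte(fit$r2, 0.999999)
  expect_equal(fit$top, 1000, tolerance = 1e-3)
  expect_equal(fit$bottom, 100, tolerance = 1e-3)
  # midpoint identity: fitted curve passes through (Top+Bottom)/2 at LogIC50
  mid <- predict(fit, 10^fit$logIC50)
  expect_equal(mid, (fit$top + fit$bottom) / 2, tolerance = 1e-9)
  # r2 equals an independent recomputation from residuals
  expect_equal(fit$r2, 1 - sum(fit$residuals^2) / sum((y - mean(y))^2),
               tolerance = 1e-12)
})

test_that("Hill fit validates inputs", {
  expect_error(fit_hill(c(-1, 1e-7, 1e-6, 1e-5), 1:4), "positive")
  expect_error(fit_hill(rep(1e-7, 5), rnorm(5)), "distinct")
})

test_that("Hill parameter recovery over simulated noisy plates", {
  # pixel noise at 5% of Top, duplicates per concentration; the well
  # averaging over cell pixels is part of the pipeline under test
  errs <- vapply(1:50, function(i) {
    lg_true <- -8 + (i %% 5) * 0.4                   # spread of true values
    assay <- assay_spec(logIC50_true = lg_true, top = 1000, bottom = 100,
                        noise_sd = 0.05 * 1000, artifact_rate = 0,
                        seed = 1000 + i)
    plate <- generate_plate(assay, field_spec(48, 48, noise_sd = 0,
                                              nucleus_count = 6,
                                              nucleus_radius_range = c(3, 5)))
    wells <- well_specific_intensity(plate$images)
    fit <- fit_hill(wells$concentration_M, wells$specific_intensity)
    abs(fit$logIC50 - lg_true)
  }, numeric(1))
  expect_lt(median(errs), 0.05)
})

test_that("sd(logIC50) brackets the empirical spread within a factor of two", {
  set.seed(56)
  conc <- 10^seq(-9.5, -4.5, length.out = 8)
  y_true <- 100 + 900 / (1 + 10^(log10(conc) - (-7)))
  fits <- replicate(60, {
    y <- rep(y_true, each = 2) + rnorm(16, 0, 50)
    f <- fit_hill(rep(conc, each = 2), y)
    c(f$logIC50, f$sd_logIC50)
  })
  emp_sd <- sd(fits[1, ])
  mean_asym <- mean(fits[2, ])
  expect_gt(mean_asym / emp_sd, 0.5)
  expect_lt(mean_asym / emp_sd, 2)
})

test_that("removal comparison: identity gives zero shift, Pearson matches closed form", {
  conc <- 10^seq(-9, -5, length.out = 6)
  y <- 100 + 900 / (1 + 10^(log10(conc) + 7))
  wells <- data.frame(well = sprintf("W%02d", 1:6), ligand = "L",
                      concentration_M = conc, specific_intensity = y)
  fit <- fit_hill(conc, y)
  ref <- list(wells = wells, fits = list(L = fit))
  cmp <- compare_removal(ref, ref)
  expect_equal(cmp$mean_abs_dlogIC50, 0)
  expect_equal(cmp$pearson_r, 1.0)

  set.seed(77)
  alt_wells <- wells
  alt_wells$specific_intensity <- y + rnorm(6, 0, 40)
  alt <- list(wells = alt_wells,
              fits = list(L = fit_hill(conc, alt_wells$specific_intensity)))
  cmp2 <- compare_removal(ref, alt)
  expect_equal(cmp2$pearson_r,
               oracle_pearson(y, alt_wells$specific_intensity),
               tolerance = 1e-12)
  expect_gte(cmp2$mean_abs_dlogIC50, 0)
})

test_that("plate ground truth round-trips through the Hill fit", {
  assay <- assay_spec(logIC50_true = -7.3, noise_sd = 0, artifact_rate = 0,
                      seed = 2)
  plate <- generate_plate(assay, field_spec(64, 64, noise_sd = 0,
                                            nucleus_count = 8))
  wells <- well_specific_intensity(plate$images)
  fit <- fit_hill(wells$concentration_M, wells$specific_intensity)
  expect_lt(abs(fit$logIC50 - (-7.3)), 1e-4)
})
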