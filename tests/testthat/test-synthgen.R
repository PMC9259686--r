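test_that("fields without artifact specs are clean and deterministic", {
  sp <- field_spec(64, 64, seed = 4)
  f1 <- generate_field(sp)
  expect_equal(sum(f1$artifact_mask), 0)
  expect_equal(f1$label, "clean")
  f2 <- generate_field(sp)
  expect_identical(f1$image, f2$image)
  expect_identical(f1$nuclei_label_mask, f2$nuclei_label_mask)
})

test_that("ellipse artifact pixel count matches the pixel-inequality enumeration", {
  sp <- field_spec(96, 96, nucleus_count = 0,
                   artifact_specs = list(artifact_spec("ellipse", c(20, 10),
                                                       -8000, c(48, 48))),
                   seed = 2)
  fld <- generate_field(sp)
  # brute-force enumeration over integer pixel centers
  count <- 0L
  for (r in 1:96) for (c in 1:96) {
    if (((c - 48) / 20)^2 + ((r - 48) / 10)^2 <= 1) count <- count + 1L
  }
  expect_equal(sum(fld$artifact_mask), count)
  expect_equal(fld$label, "artifact")
})

test_that("label always equals artifact-mask nonemptiness and shapes agree", {
  ds <- generate_dataset(12, 0.5, field_spec(64, 64), seed = 8)
  for (f in ds$fields) {
    expect_equal(f$label == "artifact", sum(f$artifact_mask) > 0)
    expect_equal(dim(f$image), dim(f$artifact_mask))
    expect_equal(dim(f$image), dim(f$nuclei_label_mask))
  }
})

test_that("artifact pixels carry the configured texture against the clean render", {
  sp <- field_spec(96, 96, noise_sd = 100, nucleus_count = 5,
                   artifact_specs = list(artifact_spec("ellipse", c(12, 8),
                                                       -9000, c(40, 40))),
                   seed = 12)
  fld <- generate_field(sp)
  d <- (fld$image - fld$clean_image)[fld$artifact_mask == 1L]
  # mean offset equals the texture contrast; speckle spreads around it
  expect_lt(abs(mean(d) - (-9000)), 500)
  expect_identical(fld$image[fld$artifact_mask == 0L],
                   fld$clean_image[fld$artifact_mask == 0L])
})

test_that("dataset honours exact artifact counts and split arithmetic", {
  ds <- generate_dataset(100, 0.5, field_spec(64, 64), c(0.6, 0.2, 0.2),
                         seed = 3)
  expect_equal(sum(ds$labels == "artifact"), 50)
  ds0 <- generate_dataset(10, 0, field_spec(64, 64), seed = 3)
  expect_true(all(ds0$labels == "clean"))
  expect_true(all(vapply(ds0$fields,
                         function(f) sum(f$artifact_mask) == 0, logical(1))))
  ds2 <- generate_dataset(10, 0.4, field_spec(64, 64), c(0.6, 0.2, 0.2),
                          seed = 9)
  expect_equal(as.vector(table(ds2$split)), c(6, 2, 2))
  expect_equal(length(ds2$fields), 10)
  expect_error(generate_dataset(100, 1.5, field_spec()), "fraction")
})

test_that("generated datasets are reproducible from the master seed", {
  d1 <- generate_dataset(8, 0.5, field_spec(64, 64), seed = 17)
  d2 <- generate_dataset(8, 0.5, field_spec(64, 64), seed = 17)
  expect_identical(lapply(d1$fields, `[[`, "image"),
                   lapply(d2$fields, `[[`, "image"))
  expect_identical(d1$split, d2$split)
})

test_that("noise-free artifact-free plates lie exactly on the Hill curve", {
  assay <- assay_spec(logIC50_true = -7, top = 1000, bottom = 100,
                      noise_sd = 0, artifact_rate = 0, seed = 6)
  plate <- generate_plate(assay, field_spec(64, 64, noise_sd = 0,
                                            nucleus_count = 8))
  wells <- well_specific_intensity(plate$images)
  expected <- assay$bottom + (assay$top - assay$bottom) /
    (1 + 10^(log10(wells$concentration_M) - assay$logIC50_true))
  expect_equal(wells$specific_intensity, expected, tolerance = 1e-10)
  # duplicates: each concentration appears in exactly 2 wells
  expect_true(all(table(plate$wells$concentration_M) == 2))
})

test_that("injected plate artifacts perturb cell intensities by the masked offset", {
  assay <- assay_spec(noise_sd = 0, artifact_rate = 1, seed = 10)
  plate <- generate_plate(assay, field_spec(64, 64, noise_sd = 0,
                                            nucleus_count = 10))
  rec <- NULL
  for (r in plate$images) if (sum(r$artifact_mask) > 0) { rec <- r; break }
  expect_false(is.null(rec))
  cm <- rec$cell_mask == 1L
  d_mean <- mean(rec$fluor[cm]) - mean(rec$fluor_clean[cm])
  offset <- 4 * (assay$top - assay$bottom)
  expected <- offset * sum(rec$artifact_mask == 1L & cm) / sum(cm)
  expect_equal(d_mean, expected, tolerance = 1e-9)
})
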