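# Data model invariants and imzML / TSV round trips.

test_that("spectrum and dataset constructors enforce their invariants", {
  expect_error(new_spectrum(c(700, 699), c(1, 1)), "ascending")
  expect_error(new_spectrum(c(700, 701), c(1, -1)), "non-negative")
  s <- new_spectrum(c(700.5, 701.5), c(1, 2), c(3, 4))
  expect_error(new_ims_dataset(list(s), dims = c(2, 2)), "outside")
  expect_error(new_ims_dataset(list(s, s), dims = c(8, 8)), "duplicate")
  expect_error(
    new_ims_dataset(list(new_spectrum(650, 1, c(0, 0))), dims = c(4, 4),
                    mz_range = c(700, 900)),
    "outside the declared range")
  expect_error(new_roi(matrix(FALSE, 2, 2)), "empty")
})

test_that("imzML round trip preserves the dataset", {
  ph <- small_phantom(seed = 3, width = 16, height = 16, n_molecules = 4)
  path <- file.path(tempdir(), "roundtrip.imzML")
  write_imzml(ph$dataset, path)
  back <- read_imzml(path)

  expect_equal(back$dims, ph$dataset$dims)
  expect_equal(back$raster, ph$dataset$raster)
  expect_equal(back$mz_range, ph$dataset$mz_range)
  expect_equal(n_pixels(back), n_pixels(ph$dataset))
  for (i in seq_along(back$spectra)) {
    expect_identical(back$spectra[[i]]$coord, ph$dataset$spectra[[i]]$coord)
    # m/z stored as 64-bit floats: exact
    expect_identical(back$spectra[[i]]$mz, ph$dataset$spectra[[i]]$mz)
    # intensities stored as 32-bit floats
    expect_equal(back$spectra[[i]]$intensity,
                 ph$dataset$spectra[[i]]$intensity, tolerance = 1e-6)
  }
  # rewriting the identical dataset gives byte-identical files
  path2 <- file.path(tempdir(), "roundtrip2.imzML")
  write_imzml(ph$dataset, path2)
  expect_identical(unname(tools::md5sum(sub("imzML$", "ibd", path))),
                   unname(tools::md5sum(sub("imzML$", "ibd", path2))))
})

test_that("an empty-pixel imzML file reads back with valid dims", {
  ds <- new_ims_dataset(list(), dims = c(5, 4))
  path <- file.path(tempdir(), "empty.imzML")
  write_imzml(ds, path)
  back <- read_imzml(path)
  expect_equal(n_pixels(back), 0)
  expect_equal(back$dims, c(5L, 4L))
})

test_that("written imzML is parseable by an independent reader", {
  ds <- new_ims_dataset(
    list(new_spectrum(c(720.1234, 801.5), c(10, 2.5), c(0, 0)),
         new_spectrum(c(750.25), c(7), c(2, 1))),
    dims = c(3, 2))
  path <- file.path(tempdir(), "cross.imzML")
  write_imzml(ds, path)

  script <- sprintf("
from pyimzml.ImzMLParser import ImzMLParser
p = ImzMLParser(%s)
print(len(p.coordinates))
for i in range(len(p.coordinates)):
    mz, it = p.getspectrum(i)
    x, y = p.coordinates[i][0], p.coordinates[i][1]
    print(x, y, ' '.join('%%.6f' %% v for v in mz), '|',
          ' '.join('%%.4f' %% v for v in it))
", deparse(path))
  out <- system2("python", c("-c", shQuote(script)), stdout = TRUE,
                 stderr = TRUE)
  status <- attr(out, "status")
  expect_true(is.null(status) || status == 0,
              info = paste(out, collapse = "\n"))
  expect_equal(out[1], "2")
  expect_equal(out[2], "1 1 720.123400 801.500000 | 10.0000 2.5000")
  expect_equal(out[3], "3 2 750.250000 | 7.0000")
})

test_that("ion-image tables export and re-import losslessly", {
  imgs <- list(
    new_ion_image(matrix(c(1, 2, 3, 4), 2, 2), center = 834.6141,
                  halfwidth = 0.004),
    new_ion_image(matrix(c(0, 0.5, 0, 9), 2, 2), center = 856.5917,
                  halfwidth = 0.004))
  path <- file.path(tempdir(), "images.tsv")
  export_ion_image_table(imgs, path)

  tab <- read.delim(path, check.names = FALSE)
  expect_equal(nrow(tab), 4)   # 2x2 grid
  expect_equal(ncol(tab), 4)   # x, y + 2 images
  # labels carry the centre m/z to 3 decimals
  expect_equal(colnames(tab)[3:4], c("834.614", "856.592"))

  back <- read_ion_image_table(path)
  expect_equal(back[[1]]$values, imgs[[1]]$values)
  expect_equal(back[[2]]$values, imgs[[2]]$values)

  bad <- list(imgs[[1]], new_ion_image(matrix(1, 3, 3), 700, 0.004))
  expect_error(export_ion_image_table(bad, path), "dimensions")
})

test_that("ROI masks and ground-truth manifests round-trip through text", {
  masks <- make_region_masks(20, 16)
  roi <- tissue_roi(masks)
  path <- file.path(tempdir(), "roi.tsv")
  write_roi_mask(roi, path)
  expect_equal(read_roi_mask(path)$mask, roi$mask)

  truth <- make_ground_truth(10, formula_table = default_formula_library(),
                             seed = 2)
  tpath <- file.path(tempdir(), "truth.tsv")
  write_ground_truth(truth, tpath)
  back <- read_ground_truth(tpath, seed = truth$seed)
  expect_equal(back$molecules$name, truth$molecules$name)
  expect_equal(back$molecules$archetype, truth$molecules$archetype)
  expect_equal(unclass(back$molecules$adducts),
               unclass(truth$molecules$adducts))
  expect_equal(back$molecules$base_intensity, truth$molecules$base_intensity,
               tolerance = 1e-9)
})
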