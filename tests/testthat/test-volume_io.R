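test_that("ct_volume enforces its invariants", {
  v <- array(0, c(4, 4, 4))
  expect_error(ct_volume(v, c(1, -1, 1)), "positive")
  expect_error(ct_volume(array(NA_real_, c(2, 2, 2)), c(1, 1, 1)), "finite")
  expect_warning(ct_volume(array(5000, c(2, 2, 2)), c(1, 1, 1)), "plausible")
  expect_s3_class(ct_volume(v, c(0.8, 0.8, 3)), "ct_volume")
})

test_that("NIfTI write/read round-trips voxels and spacing", {
  ph <- generate_phantom(tiny_phantom_spec(seed = 3))
  f <- tempfile(fileext = ".nii.gz")
  save_volume(ph$volume, f)
  v2 <- load_volume(f)
  expect_equal(v2$voxels, ph$volume$voxels, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(v2$spacing, ph$volume$spacing, tolerance = 1e-9)
  # idempotence: a second round trip is bitwise stable
  f2 <- tempfile(fileext = ".nii.gz")
  save_volume(v2, f2)
  v3 <- load_volume(f2)
  expect_identical(v3$voxels, v2$voxels)
})

test_that("a flipped-orientation file canonicalizes to the unflipped voxels", {
  ph <- generate_phantom(tiny_phantom_spec(seed = 4))
  a <- ph$volume$voxels
  d <- dim(a)
  # write superior-to-inferior flipped data with the matching (negative-z)
  # affine, as a scanner exporting head-first data would
  img <- RNifti::asNifti(a[, , d[3]:1])
  m <- diag(c(ph$volume$spacing[1:2], -ph$volume$spacing[3], 1))
  m[3, 4] <- (d[3] - 1) * ph$volume$spacing[3]
  img <- RNifti::`sform<-`(img, structure(m, code = 2L))
  img <- RNifti::`qform<-`(img, structure(m, code = 1L))
  RNifti::pixdim(img) <- ph$volume$spacing
  f <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(img, f)
  v <- load_volume(f)
  expect_equal(v$voxels, a, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(v$spacing, ph$volume$spacing, tolerance = 1e-6)
})

test_that("isotropic resampling preserves geometry, extent and constants", {
  # identity: already isotropic at target
  v <- ct_volume(array(rnorm(10 * 10 * 10, 0, 100), c(10, 10, 10)), c(1, 1, 1))
  expect_identical(resample_isotropic(v, 1)$voxels, v$voxels)

  # anisotropic (1,1,3) -> 1 mm: k extent roughly triples, physical extent kept
  a <- array(rnorm(8 * 8 * 10, 0, 100), c(8, 8, 10))
  v2 <- ct_volume(a, c(1, 1, 3))
  r2 <- resample_isotropic(v2, 1)
  expect_equal(dim(r2$voxels), c(8L, 8L, 28L))
  expect_equal(r2$spacing, c(1, 1, 1))
  in_extent <- (dim(a) - 1) * v2$spacing
  out_extent <- (dim(r2$voxels) - 1) * r2$spacing
  expect_true(all(abs(in_extent - out_extent) <= 1))

  # constants are preserved exactly by linear interpolation
  vc <- ct_volume(array(100, c(6, 6, 6)), c(2, 2, 2))
  expect_true(all(abs(resample_isotropic(vc, 1)$voxels - 100) < 1e-9))

  # degenerate output is refused
  expect_error(resample_isotropic(ct_volume(array(0, c(2, 2, 2)), c(1, 1, 1)), 10),
               "degenerate")
})

test_that("annotation sidecar round-trips centres and masks", {
  ph <- generate_phantom(tiny_phantom_spec(seed = 5))
  f <- tempfile(fileext = ".json")
  save_annotation(ph$annotation, f)
  ann <- load_annotation(f)
  expect_equal(ann$l1_center, ph$annotation$l1_center)
  expect_equal(ann$l3_center, ph$annotation$l3_center)
  expect_identical(ann$l1_mask$labels, ph$annotation$l1_mask$labels)
  expect_identical(ann$l3_mask$labels, ph$annotation$l3_mask$labels)
  expect_identical(ann$l3_mask$classes, level_classes("L3"))
})

test_that("annotation requires L1 superior to L3", {
  expect_error(annotation(c(1, 1, 10), c(1, 1, 20)), "superior")
})

test_that("DICOM series load applies rescale and slice ordering", {
  skip_if(Sys.which("python") == "", "python not on PATH")
  dir <- tempfile("dcm")
  dir.create(dir)
  # fixture written by pydicom (independent implementation): 3 slices,
  # shuffled InstanceNumbers, stored value 1024 with intercept -1024 -> HU 0
  code <- sprintf("
import numpy as np, pydicom, os
from pydicom.dataset import Dataset, FileMetaDataset
from pydicom.uid import ExplicitVRLittleEndian, generate_uid
os.makedirs(r'%s', exist_ok=True)
for idx, (z, inst) in enumerate([(0.0, 3), (4.0, 1), (2.0, 2)]):
    ds = Dataset()
    ds.Rows = 4; ds.Columns = 6
    ds.PixelSpacing = ['0.8', '0.7']
    ds.ImagePositionPatient = ['0', '0', str(z)]
    ds.ImageOrientationPatient = ['1','0','0','0','1','0']
    ds.InstanceNumber = inst
    ds.RescaleSlope = '1'; ds.RescaleIntercept = '-1024'
    ds.BitsAllocated = 16; ds.BitsStored = 16; ds.HighBit = 15
    ds.PixelRepresentation = 0
    ds.SamplesPerPixel = 1
    ds.PhotometricInterpretation = 'MONOCHROME2'
    arr = np.full((4, 6), 1024 + 10*int(z), dtype=np.uint16)
    arr[0, 0] = 1024 + 100  # marker at DICOM row 0, col 0
    ds.PixelData = arr.tobytes()
    meta = FileMetaDataset()
    meta.TransferSyntaxUID = ExplicitVRLittleEndian
    meta.MediaStorageSOPClassUID = generate_uid()
    meta.MediaStorageSOPInstanceUID = generate_uid()
    ds.file_meta = meta
    ds.save_as(os.path.join(r'%s', f'sl{idx}.dcm'), write_like_original=False)
print('ok')
", dir, dir)
  res <- system2("python", "-", input = code, stdout = TRUE, stderr = TRUE)
  skip_if(!any(grepl("^ok$", res)), paste("pydicom unavailable:", paste(res, collapse = " ")))
  v <- load_volume(dir)
  expect_equal(dim(v$voxels), c(6L, 4L, 3L))
  # rescale: stored 1024, intercept -1024 -> 0 HU on the z=0 slice
  expect_equal(v$voxels[1, 1, 1], 0)
  # slices ordered by position (z = 0, 2, 4), not InstanceNumber (3, 1, 2)
  expect_equal(v$voxels[1, 1, 2], 20)
  expect_equal(v$voxels[1, 1, 3], 40)
  # LPS -> RAS: DICOM (row 0, col 0) marker lands at flipped indices
  expect_equal(v$voxels[6, 4, 1], 100)
  # PixelSpacing is (row, col) = (y, x); slice step from positions
  expect_equal(v$spacing, c(0.7, 0.8, 2))
})
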