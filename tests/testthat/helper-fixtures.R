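# Shared fixtures built in code at test time.

# uniform random volume
rand_volume <- function(dim = c(8, 8, 8), spacing = c(1, 1, 1),
                        origin = c(0, 0, 0), seed = 1) {
  set.seed(seed)
  volume(array(stats::runif(prod(dim), 0, 100), dim = dim), spacing, origin)
}

# dark volume containing one bright axis-aligned box
box_volume <- function(dim = c(20, 20, 20), lo = c(6, 7, 3), hi = c(10, 11, 7),
                       value = 100) {
  a <- array(0, dim = dim)
  a[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- value
  volume(a)
}

# digital ball mask of the given radius centred in a cubic grid
ball_mask <- function(n, radius, center = rep((n + 1) / 2, 3)) {
  ax1 <- (seq_len(n) - center[1])^2
  ax2 <- (seq_len(n) - center[2])^2
  ax3 <- (seq_len(n) - center[3])^2
  array(sqrt(outer(outer(ax1, ax2, "+"), ax3, "+")) <= radius, dim = rep(n, 3))
}

# small fast phantom spec for pipeline tests
test_phantom_spec <- function(seed = 1, ...) {
  phantom_spec(size = 64L, rng_seed = seed, ...)
}

# test-scale pipeline config (32^3 blocks, 4 filters, depth 3)
test_pipeline_config <- function(...) {
  pipeline_config(block_size = 32L, depth = 3L, base_filters = 4L,
                  bias_iterations = 20L, augment = FALSE,
                  learning_rate = 2e-3, max_epochs = 40L,
                  early_stop_patience = 10L, ...)
}

# independent brute-force flood fill (R implementation, queue-based)
bf_flood_fill <- function(vol, seeds, lo, hi, connectivity = 26) {
  d <- dim(vol)
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  ord <- abs(offs$dx) + abs(offs$dy) + abs(offs$dz)
  offs <- offs[ord > 0 & ord <= c("6" = 1, "18" = 2, "26" = 3)[
    as.character(connectivity)], ]
  mask <- array(FALSE, dim = d)
  queue <- list()
  for (i in seq_len(nrow(seeds))) {
    p <- as.integer(seeds[i, ])
    v <- vol[p[1], p[2], p[3]]
    if (v >= lo && v <= hi && !mask[p[1], p[2], p[3]]) {
      mask[p[1], p[2], p[3]] <- TRUE
      queue[[length(queue) + 1]] <- p
    }
  }
  while (length(queue) > 0) {
    p <- queue[[length(queue)]]
    queue[[length(queue)]] <- NULL
    for (j in seq_len(nrow(offs))) {
      q <- p + c(offs$dx[j], offs$dy[j], offs$dz[j])
      if (any(q < 1) || any(q > d)) next
      if (mask[q[1], q[2], q[3]]) next
      v <- vol[q[1], q[2], q[3]]
      if (v >= lo && v <= hi) {
        mask[q[1], q[2], q[3]] <- TRUE
        queue[[length(queue) + 1]] <- q
      }
    }
  }
  mask
}

# write a tiny synthetic DICOM series via pydicom (oracle writer); returns
# the directory, or NULL if python/pydicom is unavailable
write_dicom_fixture <- function(dir, n_slices = 4, rows = 6, cols = 5,
                                spacing = c(0.7, 0.8, 1.2), seed = 0,
                                shuffle = FALSE) {
  py <- Sys.which("python")
  if (!nzchar(py)) return(NULL)
  script <- sprintf('
import numpy as np, os, sys
try:
    import pydicom
    from pydicom.dataset import Dataset
    from pydicom.uid import ExplicitVRLittleEndian, generate_uid
except Exception:
    sys.exit(3)
outdir = %s
os.makedirs(outdir, exist_ok=True)
series = generate_uid()
rng = np.random.default_rng(%d)
vol = rng.integers(0, 1000, size=(%d, %d, %d)).astype(np.uint16)
order = list(range(%d))
if %d:
    rng.shuffle(order)
for j, k in enumerate(order):
    ds = Dataset()
    ds.SOPClassUID = pydicom.uid.MRImageStorage
    ds.SOPInstanceUID = generate_uid()
    ds.SeriesInstanceUID = series
    ds.Modality = "MR"
    ds.Rows, ds.Columns = %d, %d
    ds.BitsAllocated = 16; ds.BitsStored = 16; ds.HighBit = 15
    ds.PixelRepresentation = 0
    ds.SamplesPerPixel = 1
    ds.PhotometricInterpretation = "MONOCHROME2"
    ds.PixelSpacing = ["%g", "%g"]
    ds.SliceThickness = "%g"
    ds.InstanceNumber = k + 1
    ds.ImagePositionPatient = ["1.0", "2.0", str(5.0 + %g * k)]
    ds.ImageOrientationPatient = ["1","0","0","0","1","0"]
    ds.PixelData = vol[k].tobytes()
    ds.file_meta = pydicom.dataset.FileMetaDataset()
    ds.file_meta.TransferSyntaxUID = ExplicitVRLittleEndian
    ds.file_meta.MediaStorageSOPClassUID = ds.SOPClassUID
    ds.file_meta.MediaStorageSOPInstanceUID = ds.SOPInstanceUID
    pydicom.dcmwrite(os.path.join(outdir, "slice%%02d.dcm" %% j), ds,
                     write_like_original=False)
np.save(outdir + "_vol.npy", vol)
', deparse(dir), seed, n_slices, rows, cols, n_slices, as.integer(shuffle),
    rows, cols, spacing[2], spacing[1], spacing[3], spacing[3])
  sf <- tempfile(fileext = ".py")
  writeLines(script, sf)
  status <- system2(py, sf, stdout = FALSE, stderr = FALSE)
  if (status != 0) return(NULL)
  dir
}
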