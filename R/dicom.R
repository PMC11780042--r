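# Minimal DICOM reader for uncompressed little-endian CT series (implicit or
# explicit VR), covering the geometry and rescale tags a CT pipeline needs.
# Slices are ordered by the projection of ImagePositionPatient onto the slice
# normal (not InstanceNumber), rescale slope/intercept convert stored values
# to HU, and axes are flipped from the DICOM LPS convention to the canonical
# RAS frame.

dcm_u16 <- function(raw2) as.integer(raw2[1]) + 256L * as.integer(raw2[2])
dcm_u32 <- function(raw4) sum(as.numeric(raw4) * 256^(0:3))

# Parse one DICOM file into a list of elements keyed by "gggg,eeee".
dcm_parse <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 140 || rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM (part-10) file: ", path)
  pos <- 133L
  elems <- list()
  ts <- NULL
  long_vrs <- c("OB", "OW", "OF", "OL", "OD", "SQ", "UC", "UR", "UT", "UN")
  n <- length(raw)
  while (pos + 7L <= n) {
    grp <- dcm_u16(raw[pos:(pos + 1L)]); ele <- dcm_u16(raw[(pos + 2L):(pos + 3L)])
    pos <- pos + 4L
    # the file meta group (0002) is always explicit LE; the dataset follows
    # the transfer syntax announced in (0002,0010)
    explicit <- grp == 2L || is.null(ts) || ts == "1.2.840.10008.1.2.1"
    if (explicit) {
      vr <- rawToChar(raw[pos:(pos + 1L)])
      if (vr %in% long_vrs) {
        len <- dcm_u32(raw[(pos + 4L):(pos + 7L)]); pos <- pos + 8L
      } else {
        len <- dcm_u16(raw[(pos + 2L):(pos + 3L)]); pos <- pos + 4L
      }
    } else {
      vr <- NA_character_
      len <- dcm_u32(raw[pos:(pos + 3L)]); pos <- pos + 4L
    }
    if (len == 4294967295) stop("undefined-length element not supported: ", path)
    key <- sprintf("%04x,%04x", grp, ele)
    elems[[key]] <- list(vr = vr,
                         bytes = if (len > 0) raw[pos:(pos + len - 1L)] else raw(0))
    pos <- pos + len
    if (key == "0002,0010") {
      b <- elems[[key]]$bytes
      ts <- trimws(rawToChar(b[b != as.raw(0)]))
      if (!ts %in% c("1.2.840.10008.1.2", "1.2.840.10008.1.2.1"))
        stop("unsupported transfer syntax ", ts, " in ", path)
    }
  }
  elems
}

dcm_str <- function(elems, key, default = NULL) {
  e <- elems[[key]]
  if (is.null(e)) return(default)
  b <- e$bytes
  trimws(rawToChar(b[b != as.raw(0)]))
}

dcm_ds <- function(elems, key, default = NULL) {
  s <- dcm_str(elems, key)
  if (is.null(s)) return(default)
  as.numeric(strsplit(s, "\\\\")[[1]])
}

dcm_us <- function(elems, key) {
  e <- elems[[key]]
  if (is.null(e)) return(NULL)
  readBin(e$bytes, "integer", n = length(e$bytes) / 2, size = 2,
          endian = "little", signed = FALSE)[1]
}

# Read one uncompressed little-endian CT series from a directory.
load_dicom_series <- function(dir, subject = basename(dir)) {
  files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0) stop("no files in DICOM directory: ", dir)
  slices <- lapply(files, function(f) {
    el <- dcm_parse(f)
    rows <- dcm_us(el, "0028,0010"); cols <- dcm_us(el, "0028,0011")
    if (is.null(rows) || is.null(cols)) stop("missing Rows/Columns in ", f)
    ps <- dcm_ds(el, "0028,0030")
    ipp <- dcm_ds(el, "0020,0032")
    iop <- dcm_ds(el, "0020,0037", default = c(1, 0, 0, 0, 1, 0))
    if (is.null(ps) || is.null(ipp)) stop("missing spacing/position metadata in ", f)
    slope <- dcm_ds(el, "0028,1053", default = 1)
    icept <- dcm_ds(el, "0028,1052", default = 0)
    bits <- dcm_us(el, "0028,0100"); if (is.null(bits)) bits <- 16L
    signed <- identical(dcm_us(el, "0028,0103"), 1L)
    px <- el[["7fe0,0010"]]
    if (is.null(px)) stop("missing PixelData in ", f)
    v <- readBin(px$bytes, "integer", n = rows * cols, size = bits / 8,
                 endian = "little", signed = signed || bits == 32)
    if (!signed && bits == 16) v <- ifelse(v < 0, v + 65536L, v)
    hu <- matrix(v * slope + icept, nrow = cols)  # dims (x, y) in LPS
    normal <- c(iop[2] * iop[6] - iop[3] * iop[5],
                iop[3] * iop[4] - iop[1] * iop[6],
                iop[1] * iop[5] - iop[2] * iop[4])
    list(hu = hu, z = sum(ipp * normal),
         spacing_xy = c(ps[2], ps[1]))   # PixelSpacing is (row, col) = (y, x)
  })
  ord <- order(vapply(slices, `[[`, 0, "z"))
  slices <- slices[ord]
  zs <- vapply(slices, `[[`, 0, "z")
  dz <- if (length(zs) > 1) median(diff(zs)) else 1
  d2 <- dim(slices[[1]]$hu)
  vox <- array(0, c(d2, length(slices)))
  for (k in seq_along(slices)) vox[, , k] <- slices[[k]]$hu
  # DICOM LPS -> canonical RAS: flip x (left->right) and y (posterior->anterior)
  vox <- vox[rev(seq_len(d2[1])), rev(seq_len(d2[2])), , drop = FALSE]
  ct_volume(vox, c(slices[[1]]$spacing_xy, abs(dz)), subject = subject)
}
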