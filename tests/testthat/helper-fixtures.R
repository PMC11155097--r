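# Shared fixtures: a cached default-size phantom, mask/image builders and a
# minimal explicit-VR little-endian DICOM writer for I/O round trips.

.fixture_env <- new.env(parent = emptyenv())

# one default-condition phantom, generated once per test run
cached_phantom <- function(seed = 7L, label = 1L) {
  key <- sprintf("ph_%d_%d", seed, label)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- generate_phantom(phantom_spec(seed = seed), label)
  }
  .fixture_env[[key]]
}

dice <- function(a, b) {
  a <- if (inherits(a, "binary_mask")) a$pixels else a
  b <- if (inherits(b, "binary_mask")) b$pixels else b
  2 * sum(a & b) / (sum(a) + sum(b))
}

# a zero image with a horizontal bright bar of given half-thickness
bar_image <- function(n = 64, center = NULL, half = 1, value = 100) {
  if (is.null(center)) center <- n %/% 2
  m <- matrix(0, n, n)
  m[(center - half):(center + half), ] <- value
  m
}

# wide-separated horizontal bars: each is a single skeleton segment
bars_mask <- function(n = 200, rows = seq(15, 186, by = 19), cols = 30:170,
                      half = 1) {
  m <- matrix(FALSE, n, n)
  for (r in rows) m[(r - half):(r + half), cols] <- TRUE
  m
}

# ---- minimal DICOM writer (explicit VR little endian, single frame) ----

.u16raw <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
.u32raw <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

.dcm_short <- function(group, elem, vr, value) {
  if (is.character(value)) value <- charToRaw(value)
  if (length(value) %% 2 == 1) {
    value <- c(value, as.raw(if (vr == "UI") 0L else 0x20))
  }
  c(.u16raw(group), .u16raw(elem), charToRaw(vr), .u16raw(length(value)), value)
}

.dcm_long <- function(group, elem, vr, value) {
  c(.u16raw(group), .u16raw(elem), charToRaw(vr), as.raw(c(0, 0)),
    .u32raw(length(value)), value)
}

# write one slice; `px` integer matrix (rows x cols), values < 32768
write_dicom_slice <- function(path, px, slice_location,
                              pixel_spacing = c(1, 1), slice_spacing = 1,
                              transfer_syntax = "1.2.840.10008.1.2.1") {
  stopifnot(max(px) < 32768, min(px) >= 0)
  pix <- writeBin(as.integer(t(px)), raw(), size = 2, endian = "little")
  body <- c(
    .dcm_short(0x0002, 0x0010, "UI", transfer_syntax),
    .dcm_short(0x0018, 0x0050, "DS", format(slice_spacing)),
    .dcm_short(0x0018, 0x0088, "DS", format(slice_spacing)),
    .dcm_short(0x0020, 0x1041, "DS", format(slice_location)),
    .dcm_short(0x0028, 0x0010, "US", .u16raw(nrow(px))),
    .dcm_short(0x0028, 0x0011, "US", .u16raw(ncol(px))),
    .dcm_short(0x0028, 0x0030, "DS",
               paste(format(pixel_spacing), collapse = "\\")),
    .dcm_short(0x0028, 0x0100, "US", .u16raw(16)),
    .dcm_short(0x0028, 0x0103, "US", .u16raw(0)),
    .dcm_long(0x7fe0, 0x0010, "OW", pix)
  )
  writeBin(c(raw(128), charToRaw("DICM"), body), path)
  invisible(path)
}

write_dicom_series_dir <- function(dir, slices, locations, ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(slices)) {
    write_dicom_slice(file.path(dir, sprintf("slice_%03d.dcm", i)),
                      slices[[i]], locations[i], ...)
  }
  invisible(dir)
}
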