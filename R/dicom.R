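# Minimal DICOM series reader: uncompressed, explicit-VR little-endian,
# single-frame monochrome files only — enough to ingest the scanner exports
# this pipeline consumes. Slices are ordered by slice location and the
# series is rejected when the location grid is not uniform (missing slice).

.dcm_u16 <- function(raw, off) as.integer(raw[off + 1]) + 256L * as.integer(raw[off + 2])
.dcm_u32 <- function(raw, off) {
  sum(as.numeric(raw[off + 1:4]) * c(1, 256, 65536, 16777216))
}

# Parse one file; returns named list of the tags we need.
.dcm_parse_file <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 140 || rawToChar(raw[129:132]) != "DICM") {
    stop("DICOM parse error: missing DICM magic in ", basename(path), call. = FALSE)
  }
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  off <- 132L  # 0-based offset just past the magic
  out <- list()
  n <- length(raw)
  while (off + 8 <= n) {
    group <- .dcm_u16(raw, off); elem <- .dcm_u16(raw, off + 2L)
    vr <- rawToChar(raw[off + 5:6])
    if (vr %in% long_vrs) {
      len <- .dcm_u32(raw, off + 8L); hdr <- 12L
    } else {
      len <- .dcm_u16(raw, off + 6L); hdr <- 8L
    }
    val_off <- off + hdr
    if (val_off + len > n) stop("DICOM parse error: truncated element in ",
                                basename(path), call. = FALSE)
    key <- sprintf("%04x,%04x", group, elem)
    body <- raw[seq.int(val_off + 1L, length.out = len)]
    if (key %in% c("0028,0010", "0028,0011", "0028,0100", "0028,0103")) {
      out[[key]] <- .dcm_u16(body, 0L)
    } else if (key %in% c("0028,0030", "0018,0050", "0018,0088",
                          "0020,0032", "0020,1041")) {
      out[[key]] <- as.numeric(strsplit(trimws(rawToChar(body)), "\\\\")[[1]])
    } else if (key == "0002,0010") {
      out[[key]] <- trimws(rawToChar(body[body != as.raw(0)]))
    } else if (key == "7fe0,0010") {
      out[["pixel_data"]] <- body
      break
    }
    off <- val_off + len
  }
  out
}

# Read all files of a directory as one volume.
read_dicom_series <- function(dir) {
  if (!dir.exists(dir)) stop("load_volume: directory not found: ", dir, call. = FALSE)
  files <- sort(list.files(dir, pattern = "\\.dcm$", full.names = TRUE, ignore.case = TRUE))
  if (length(files) == 0) files <- sort(list.files(dir, full.names = TRUE))
  if (length(files) == 0) stop("load_volume: no DICOM files in ", dir, call. = FALSE)
  slices <- lapply(files, .dcm_parse_file)
  for (i in seq_along(slices)) {
    s <- slices[[i]]
    ts <- s[["0002,0010"]]
    if (!is.null(ts) && ts != "1.2.840.10008.1.2.1") {
      stop("DICOM format error: unsupported transfer syntax ", ts, call. = FALSE)
    }
    if (is.null(s[["pixel_data"]]) || is.null(s[["0028,0010"]])) {
      stop("DICOM format error: no image data in ", basename(files[i]), call. = FALSE)
    }
    if (!is.null(s[["0028,0100"]]) && s[["0028,0100"]] != 16) {
      stop("DICOM format error: only 16-bit data supported", call. = FALSE)
    }
  }
  loc <- vapply(slices, function(s) {
    if (!is.null(s[["0020,1041"]])) s[["0020,1041"]][1]
    else if (!is.null(s[["0020,0032"]])) s[["0020,0032"]][3]
    else NA_real_
  }, numeric(1))
  if (anyNA(loc)) stop("DICOM format error: slice locations missing", call. = FALSE)
  ord <- order(loc)
  slices <- slices[ord]; loc <- loc[ord]
  if (length(loc) > 2) {
    d <- diff(loc)
    if (any(d <= 0) || (max(d) - min(d)) > 1e-3 * max(abs(d), 1e-9)) {
      stop("DICOM format error: inconsistent slice spacing (missing slice?)",
           call. = FALSE)
    }
  }
  rows <- slices[[1]][["0028,0010"]]; cols <- slices[[1]][["0028,0011"]]
  vol <- array(0, dim = c(length(slices), rows, cols))
  for (i in seq_along(slices)) {
    s <- slices[[i]]
    if (s[["0028,0010"]] != rows || s[["0028,0011"]] != cols) {
      stop("DICOM format error: slice dimensions differ across the series",
           call. = FALSE)
    }
    signed <- isTRUE(s[["0028,0103"]] == 1)
    v <- readBin(s[["pixel_data"]], "integer", n = rows * cols, size = 2,
                 signed = signed, endian = "little")
    if (!signed) v[v < 0] <- v[v < 0] + 65536
    vol[i, , ] <- matrix(v, nrow = rows, byrow = TRUE)
  }
  ps <- slices[[1]][["0028,0030"]]
  if (is.null(ps)) ps <- c(1, 1)
  dz <- if (!is.null(slices[[1]][["0018,0088"]])) slices[[1]][["0018,0088"]][1]
        else if (length(loc) > 1) median(diff(loc))
        else if (!is.null(slices[[1]][["0018,0050"]])) slices[[1]][["0018,0050"]][1]
        else 1
  list(volume = vol, spacing = abs(c(dz, ps[1], ps[2])))
}
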