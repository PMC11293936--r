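# Minimal DICOM CT-series support (explicit VR, little endian, uncompressed).
# Covers CT Image Storage geometry + modality rescale; anything fancier
# (compressed transfer syntaxes, undefined-length sequences) is rejected.

CT_SOP_CLASS <- "1.2.840.10008.5.1.4.1.1.2"
EXPLICIT_VR_LE <- "1.2.840.10008.1.2.1"

dcm_uid <- function() {
  paste0("2.25.", paste(sample(0:9, 30, replace = TRUE), collapse = ""))
}

# ---- writer ----------------------------------------------------------------

dcm_pad <- function(x) if (length(x) %% 2 == 1) c(x, as.raw(0)) else x

dcm_element <- function(group, element, vr, value) {
  raw_val <- switch(vr,
    UI = dcm_pad(charToRaw(value)),            # UID: pad with NUL
    CS = , DS = , IS = , LO = , SH = dcm_pad(charToRaw(value)),
    US = writeBin(as.integer(value), raw(), size = 2, endian = "little"),
    UL = writeBin(as.integer(value), raw(), size = 4, endian = "little"),
    OW = value,
    stop("unsupported VR ", vr))
  if (vr == "UI" && raw_val[length(raw_val)] == as.raw(32)) {
    raw_val[length(raw_val)] <- as.raw(0)
  }
  head_ <- c(writeBin(as.integer(group), raw(), size = 2, endian = "little"),
             writeBin(as.integer(element), raw(), size = 2, endian = "little"),
             charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(head_, as.raw(c(0, 0)),
      writeBin(length(raw_val), raw(), size = 4, endian = "little"), raw_val)
  } else {
    c(head_, writeBin(length(raw_val), raw(), size = 2, endian = "little"),
      raw_val)
  }
}

dcm_ds <- function(x) paste(formatC(x, digits = 10, format = "g"),
                            collapse = "\\")

#' Write a CT volume as an uncompressed DICOM series
#'
#' One explicit-VR little-endian CT Image Storage file per axial slice
#' (stored values = HU + 1024, rescale slope 1 / intercept -1024).
#'
#' @param vol a [ct_volume()].
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_dicom_series <- function(vol, dir) {
  stopifnot(inherits(vol, "ct_volume"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  dims <- dim(vol$values)
  series_uid <- dcm_uid()
  study_uid <- dcm_uid()
  iop <- c(vol$direction[, 1], vol$direction[, 2])
  for (k in seq_len(dims[3])) {
    stored <- round(vol$values[, , k] + 1024)
    stored <- pmin(pmax(stored, -32768), 32767)
    pix <- writeBin(as.integer(stored), raw(), size = 2, endian = "little")
    ipp <- index_to_world(vol, c(0, 0, k - 1))[1, ]
    sop_uid <- dcm_uid()
    meta <- c(
      dcm_element(0x0002, 0x0002, "UI", CT_SOP_CLASS),
      dcm_element(0x0002, 0x0003, "UI", sop_uid),
      dcm_element(0x0002, 0x0010, "UI", EXPLICIT_VR_LE))
    body <- c(
      dcm_element(0x0008, 0x0016, "UI", CT_SOP_CLASS),
      dcm_element(0x0008, 0x0018, "UI", sop_uid),
      dcm_element(0x0008, 0x0060, "CS", "CT"),
      dcm_element(0x0020, 0x000D, "UI", study_uid),
      dcm_element(0x0020, 0x000E, "UI", series_uid),
      dcm_element(0x0020, 0x0013, "IS", as.character(k)),
      dcm_element(0x0020, 0x0032, "DS", dcm_ds(ipp)),
      dcm_element(0x0020, 0x0037, "DS", dcm_ds(iop)),
      dcm_element(0x0028, 0x0002, "US", 1L),
      dcm_element(0x0028, 0x0004, "CS", "MONOCHROME2"),
      dcm_element(0x0028, 0x0010, "US", dims[2]),   # Rows
      dcm_element(0x0028, 0x0011, "US", dims[1]),   # Columns
      dcm_element(0x0028, 0x0030, "DS",
                  dcm_ds(c(vol$spacing[2], vol$spacing[1]))),
      dcm_element(0x0028, 0x0100, "US", 16L),
      dcm_element(0x0028, 0x0101, "US", 16L),
      dcm_element(0x0028, 0x0102, "US", 15L),
      dcm_element(0x0028, 0x0103, "US", 1L),
      dcm_element(0x0028, 0x1052, "DS", "-1024"),
      dcm_element(0x0028, 0x1053, "DS", "1"),
      dcm_element(0x7FE0, 0x0010, "OW", pix))
    grouplen <- dcm_element(0x0002, 0x0000, "UL", length(meta))
    con <- file(file.path(dir, sprintf("slice%04d.dcm", k)), "wb")
    writeBin(c(raw(128), charToRaw("DICM"), grouplen, meta, body), con)
    close(con)
  }
  invisible(dir)
}

# ---- reader ----------------------------------------------------------------

read_dicom_file <- function(path) {
  buf <- readBin(path, raw(), n = file.info(path)$size)
  if (length(buf) < 132 || rawToChar(buf[129:132]) != "DICM") {
    stop("not a DICOM part-10 file: ", path)
  }
  pos <- 133L
  tags <- list()
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  u16 <- function(i) readBin(buf[i:(i + 1)], "integer", size = 2,
                             endian = "little", signed = FALSE)
  u32 <- function(i) readBin(buf[i:(i + 3)], "integer", size = 4,
                             endian = "little")
  while (pos + 7 <= length(buf)) {
    group <- u16(pos); element <- u16(pos + 2)
    vr <- rawToChar(buf[(pos + 4):(pos + 5)])
    if (vr %in% long_vrs) {
      len <- u32(pos + 8); data_at <- pos + 12L
    } else {
      len <- u16(pos + 6); data_at <- pos + 8L
    }
    if (len < 0 || (vr == "SQ")) {
      stop("unsupported DICOM encoding (sequence/undefined length) in ", path)
    }
    key <- sprintf("%04X,%04X", group, element)
    raw_val <- if (len > 0) buf[data_at:(data_at + len - 1)] else raw(0)
    tags[[key]] <- list(vr = vr, raw = raw_val)
    pos <- data_at + len
  }
  tags
}

dcm_str <- function(tags, key) {
  v <- tags[[key]]
  if (is.null(v)) return(NULL)
  trimws(gsub("\\x00", "", rawToChar(v$raw), useBytes = TRUE))
}

dcm_num <- function(tags, key) {
  s <- dcm_str(tags, key)
  if (is.null(s)) return(NULL)
  as.numeric(strsplit(s, "\\\\")[[1]])
}

dcm_us <- function(tags, key) {
  v <- tags[[key]]
  if (is.null(v)) return(NULL)
  readBin(v$raw, "integer", size = 2, endian = "little", signed = FALSE)
}

#' @rdname read_volume
#' @param dir directory containing one DICOM CT series.
#' @export
read_dicom_series <- function(dir) {
  files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0) stop("no files in DICOM directory ", dir)
  slices <- lapply(files, read_dicom_file)
  iops <- vapply(slices, function(t) dcm_num(t, "0020,0037"),
                 numeric(6))
  ref <- iops[, 1]
  bad <- which(colSums(abs(iops - ref)) > 1e-4)
  if (length(bad) > 0) {
    stop("mixed-orientation DICOM series; offending slices: ",
         paste(basename(files[bad]), collapse = ", "))
  }
  rdir <- unitv(ref[1:3]); cdir <- unitv(ref[4:6])
  normal <- cross3(rdir, cdir)
  ipp <- vapply(slices, function(t) dcm_num(t, "0020,0032"), numeric(3))
  zpos <- as.numeric(crossprod(normal, ipp))
  ord <- order(zpos)
  slices <- slices[ord]; ipp <- ipp[, ord, drop = FALSE]
  zpos <- zpos[ord]; files <- files[ord]
  dz <- diff(zpos)
  if (length(dz) > 0) {
    med <- stats::median(dz)
    gaps <- which(abs(dz - med) > 0.01 * med + 1e-6)
    if (length(gaps) > 0) {
      stop("non-uniform slice spacing (missing slices?) after: ",
           paste(basename(files[gaps]), collapse = ", "))
    }
  }
  nx <- dcm_us(slices[[1]], "0028,0011")
  ny <- dcm_us(slices[[1]], "0028,0010")
  ps <- dcm_num(slices[[1]], "0028,0030")  # row spacing, col spacing
  vals <- vapply(slices, function(t) {
    slope <- dcm_num(t, "0028,1053"); if (is.null(slope)) slope <- 1
    inter <- dcm_num(t, "0028,1052"); if (is.null(inter)) inter <- 0
    stored <- readBin(t[["7FE0,0010"]]$raw, "integer", n = nx * ny,
                      size = 2, endian = "little", signed = TRUE)
    hu_rescale(stored, slope, inter)
  }, numeric(nx * ny))
  dzv <- if (length(dz) > 0) stats::median(dz) else 1
  ct_volume(array(vals, c(nx, ny, length(slices))),
            spacing = c(ps[2], ps[1], dzv),
            origin = ipp[, 1], direction = cbind(rdir, cdir, normal))
}
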