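# Minimal DICOM series reader.
#
# Scope: uncompressed single-frame CT slices, little-endian implicit or
# explicit VR, axis-aligned image orientation. That covers routine axial CT
# exports; anything else (compressed transfer syntaxes, oblique gantry-tilt
# series, multiframe objects) raises a clear error rather than a guess.

dicom_tag <- function(group, element) sprintf("%04X,%04X", group, element)

# VRs whose explicit encoding uses a 2-byte reserved field + 4-byte length.
.long_vrs <- c("OB", "OW", "OF", "OD", "OL", "SQ", "UC", "UR", "UT", "UN")

# Parse one DICOM file, returning the handful of tags the reader needs.
parse_dicom_file <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 140 || rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM part-10 file: ", path)
  pos <- 133L  # first byte after "DICM" (1-based)
  n <- length(raw)

  u16 <- function(at) as.integer(raw[at]) + 256L * as.integer(raw[at + 1L])
  u32 <- function(at) sum(as.numeric(raw[at + 0:3]) * 256^(0:3))

  explicit <- TRUE         # file meta group is always explicit little-endian
  transfer_syntax <- NULL
  wanted <- c("0002,0010", "0008,0018", "0020,000E", "0020,0013", "0020,0032",
              "0020,0037", "0028,0010", "0028,0011", "0028,0030", "0028,0100",
              "0028,0103", "0028,1052", "0028,1053", "7FE0,0010")
  out <- list()

  while (pos + 7L <= n) {
    group <- u16(pos); element <- u16(pos + 2L)
    tag <- dicom_tag(group, element)
    in_meta <- group == 2L
    expl <- explicit || in_meta
    if (expl) {
      vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
      if (vr %in% .long_vrs) {
        len <- u32(pos + 8L); hdr <- 12L
      } else {
        len <- u16(pos + 6L); hdr <- 8L
      }
    } else {
      vr <- NA_character_
      len <- u32(pos + 4L); hdr <- 8L
    }
    if (len == 4294967295) {  # undefined length (sequences)
      stop("unsupported DICOM element with undefined length at tag ", tag,
           " in ", path)
    }
    start <- pos + hdr
    if (tag %in% wanted && len > 0)
      out[[tag]] <- list(vr = vr, bytes = raw[start:(start + len - 1L)])
    if (tag == "0002,0010")
      transfer_syntax <- sub("\\s+$", "", rawToChar(out[[tag]]$bytes))
    # Leaving the file meta group: adopt the dataset transfer syntax.
    if (in_meta && pos + hdr + len <= n) {
      nxt_group <- if (pos + hdr + len + 1L <= n) u16(pos + hdr + len) else NA
      if (!is.na(nxt_group) && nxt_group != 2L) {
        if (is.null(transfer_syntax))
          stop("DICOM file meta lacks a transfer syntax UID: ", path)
        explicit <- switch(transfer_syntax,
                           "1.2.840.10008.1.2" = FALSE,
                           "1.2.840.10008.1.2.1" = TRUE,
                           stop("unsupported DICOM transfer syntax ",
                                transfer_syntax, " (only uncompressed ",
                                "little-endian is supported): ", path))
      }
    }
    pos <- start + len
  }

  str_at <- function(tag) {
    v <- out[[tag]]
    if (is.null(v)) return(NULL)
    sub("\\s+$", "", sub("^\\s+", "", rawToChar(v$bytes)))
  }
  nums_at <- function(tag) {
    s <- str_at(tag)
    if (is.null(s)) return(NULL)
    as.numeric(strsplit(s, "\\\\")[[1]])
  }
  us_at <- function(tag) {
    v <- out[[tag]]
    if (is.null(v)) return(NULL)
    readBin(v$bytes, "integer", size = 2, signed = FALSE, endian = "little")
  }

  list(series_uid = str_at("0020,000E"),
       sop_uid = str_at("0008,0018"),
       instance = nums_at("0020,0013"),
       position = nums_at("0020,0032"),
       orientation = nums_at("0020,0037"),
       rows = us_at("0028,0010"),
       cols = us_at("0028,0011"),
       pixel_spacing = nums_at("0028,0030"),
       bits_allocated = us_at("0028,0100"),
       pixel_representation = us_at("0028,0103"),
       rescale_intercept = nums_at("0028,1052"),
       rescale_slope = nums_at("0028,1053"),
       pixel_data = out[["7FE0,0010"]]$bytes)
}

read_dicom_series <- function(path) {
  files <- list.files(path, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0) stop("no files in DICOM directory ", path)
  slices <- lapply(files, parse_dicom_file)

  uids <- unique(vapply(slices, function(s) s$series_uid %||% "<missing>",
                        character(1)))
  if (length(uids) > 1)
    stop("DICOM directory contains more than one series: ",
         paste(uids, collapse = ", "))

  first <- slices[[1]]
  if (is.null(first$pixel_spacing) || length(first$pixel_spacing) != 2)
    stop("DICOM series lacks PixelSpacing (0028,0030); refusing to assume 1 mm")
  if (!is.null(first$orientation)) {
    o <- round(first$orientation, 4)
    if (!isTRUE(all.equal(abs(o), c(1, 0, 0, 0, 1, 0), tolerance = 1e-3)))
      stop("oblique DICOM orientation [", paste(o, collapse = ", "),
           "] is not supported; resample the series to an axis-aligned grid")
  }
  if (is.null(first$position) || length(first$position) != 3)
    stop("DICOM series lacks ImagePositionPatient; cannot order slices")

  zs <- vapply(slices, function(s) s$position[3], numeric(1))
  ord <- order(zs)
  slices <- slices[ord]
  zs <- zs[ord]
  dz <- diff(zs)
  if (length(dz) == 0)
    stop("DICOM series has a single slice; need >= 2 to derive z spacing")
  if (any(dz <= 0)) stop("duplicate slice positions in DICOM series")
  if (max(dz) - min(dz) > 1e-2 * stats::median(dz) + 1e-6)
    stop("non-uniform slice spacing in DICOM series (",
         signif(min(dz), 5), " .. ", signif(max(dz), 5), " mm)")

  nxp <- first$cols; nyp <- first$rows
  vox <- array(0, dim = c(nxp, nyp, length(slices)))
  for (k in seq_along(slices)) {
    s <- slices[[k]]
    if (is.null(s$pixel_data)) stop("DICOM slice without PixelData")
    bits <- s$bits_allocated %||% 16L
    if (bits != 16) stop("only 16-bit DICOM pixel data is supported")
    signed <- isTRUE((s$pixel_representation %||% 0L) == 1L)
    vals <- readBin(s$pixel_data, "integer", n = nxp * nyp, size = 2,
                    signed = signed, endian = "little")
    if (!signed) vals[vals < 0] <- vals[vals < 0] + 65536
    slope <- (s$rescale_slope %||% 1)
    inter <- (s$rescale_intercept %||% 0)
    # DICOM pixel data is row-major (rows of the image in sequence): value
    # (r, c) sits at index c + cols*r, so a cols x rows matrix fill puts x
    # (column) on the first array axis.
    vox[, , k] <- matrix(vals * slope + inter, nrow = nxp, ncol = nyp)
  }
  spacing <- c(first$pixel_spacing[2], first$pixel_spacing[1],
               stats::median(dz))
  ct_volume(vox, spacing = spacing, origin = c(0, 0, 0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
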