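#' CT-like attenuation volume
#'
#' Container for a 3-D scalar grid of attenuation values in Hounsfield units
#' (HU) together with its physical geometry. Voxel centers sit at
#' `origin + (index + 0.5) * spacing` with 0-based indices, all lengths in mm.
#'
#' @param values 3-D numeric array of attenuation values (HU).
#' @param spacing numeric length-3, voxel spacing in mm per axis (> 0).
#' @param origin numeric length-3, physical position (mm) of the corner of
#'   voxel (0,0,0).
#' @param orientation character length-3 axis labels; purely informative.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(values, spacing, origin = c(0, 0, 0),
                         orientation = c("L", "P", "S")) {
  if (length(dim(values)) != 3L) stop("values must be a 3-D array")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three positive finite numbers (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be three finite numbers (mm)")
  if (any(!is.finite(values))) stop("attenuation values must be finite")
  structure(list(values = values, spacing = spacing, origin = origin,
                 orientation = as.character(orientation)),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$values)
  cat("<image_volume> ", paste(d, collapse = " x "), " voxels, spacing ",
      paste(signif(x$spacing, 4), collapse = " x "), " mm\n", sep = "")
  cat("  origin (mm): ", paste(signif(x$origin, 6), collapse = ", "), "\n",
      sep = "")
  cat("  HU range: [", signif(min(x$values), 5), ", ",
      signif(max(x$values), 5), "]\n", sep = "")
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$values)

# physical voxel-center coordinates along one axis (mm)
axis_centers <- function(vol, axis) {
  n <- dim(vol$values)[axis]
  vol$origin[axis] + (seq_len(n) - 0.5) * vol$spacing[axis]
}

# voxel volume in mm^3
voxel_volume <- function(vol) prod(vol$spacing)

#' Read an attenuation volume
#'
#' Reads a NIfTI file (`.nii` / `.nii.gz`) or a directory containing an
#' uncompressed explicit-VR little-endian DICOM series (one slice per file).
#' Voxel spacing is taken from the headers; DICOM slice positions must form a
#' uniform grid, otherwise (e.g. a missing slice) an error is raised.
#'
#' @param path file (NIfTI) or directory (DICOM series).
#' @return An [image_volume].
#' @export
read_volume <- function(path) {
  if (dir.exists(path)) return(read_dicom_series(path))
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  vals <- array(as.numeric(img), dim = dim(img))
  sp <- attr(img, "pixdim")[1:3]
  xf <- RNifti::xform(img)
  org <- as.numeric(xf[1:3, 4]) - 0.5 * sp  # center of voxel 0 -> corner
  image_volume(vals, spacing = sp, origin = org)
}

#' Write an attenuation volume
#'
#' Writes NIfTI (default) or an uncompressed explicit-VR little-endian DICOM
#' series (`format = "dicom"`, one axial slice per file, 16-bit signed with
#' identity rescale).
#'
#' @param vol an [image_volume].
#' @param path output file (NIfTI) or directory (DICOM).
#' @param format `"nifti"` or `"dicom"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, format = c("nifti", "dicom")) {
  format <- match.arg(format)
  if (format == "dicom") return(write_dicom_series(vol, path))
  img <- RNifti::asNifti(vol$values)
  RNifti::pixdim(img) <- vol$spacing
  xf <- diag(4)
  diag(xf)[1:3] <- vol$spacing
  xf[1:3, 4] <- vol$origin + 0.5 * vol$spacing
  RNifti::qform(img) <- structure(xf, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

## ---- minimal DICOM series support -----------------------------------------
## No DICOM toolkit is required at run time: the subset written and parsed
## here is plain explicit-VR little-endian, uncompressed, one slice per file,
## which is sufficient for round-tripping phantoms and for header checks.

dcm_tag <- function(group, elem) sprintf("%04X,%04X", group, elem)

read_dicom_file <- function(file) {
  raw <- readBin(file, "raw", n = file.info(file)$size)
  if (length(raw) < 140 || rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM file: ", file)
  pos <- 133L
  u16 <- function(at) readBin(raw[at + 0:1], "integer", size = 2,
                              endian = "little", signed = FALSE)
  u32 <- function(at) readBin(raw[at + 0:3], "integer", size = 4,
                              endian = "little")
  tags <- list()
  long_vr <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  while (pos + 7 <= length(raw)) {
    group <- u16(pos); elem <- u16(pos + 2L)
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    if (vr %in% long_vr) {
      len <- u32(pos + 8L); vstart <- pos + 12L
    } else {
      len <- u16(pos + 6L); vstart <- pos + 8L
    }
    val <- raw[vstart + seq_len(len) - 1L]
    tags[[dcm_tag(group, elem)]] <- list(vr = vr, value = val)
    pos <- vstart + len
    if (group == 0x7FE0 && elem == 0x0010) break
  }
  tags
}

dcm_str <- function(tags, tag) {
  v <- tags[[tag]]
  if (is.null(v)) stop("missing DICOM tag ", tag)
  trimws(rawToChar(v$value))
}

dcm_nums <- function(tags, tag)
  as.numeric(strsplit(dcm_str(tags, tag), "\\\\")[[1]])

dcm_u16 <- function(tags, tag) {
  v <- tags[[tag]]
  if (is.null(v)) stop("missing DICOM tag ", tag)
  readBin(v$value, "integer", size = 2, endian = "little", signed = FALSE)
}

read_dicom_series <- function(dir) {
  files <- sort(list.files(dir, full.names = TRUE, pattern = "\\.dcm$"))
  if (!length(files)) stop("no .dcm files in ", dir)
  slices <- lapply(files, read_dicom_file)
  zpos <- vapply(slices, function(t) dcm_nums(t, dcm_tag(0x0020, 0x0032))[3],
                 0)
  ord <- order(zpos)
  slices <- slices[ord]; zpos <- zpos[ord]
  t1 <- slices[[1]]
  nx <- dcm_u16(t1, dcm_tag(0x0028, 0x0011))  # Columns
  ny <- dcm_u16(t1, dcm_tag(0x0028, 0x0010))  # Rows
  ps <- dcm_nums(t1, dcm_tag(0x0028, 0x0030))
  if (length(zpos) > 1) {
    dz <- diff(zpos)
    if (any(dz <= 0) || max(dz) - min(dz) > 1e-4 * max(dz))
      stop("inconsistent slice spacing in DICOM series (missing slice?)")
    dz <- mean(dz)
  } else {
    dz <- dcm_nums(t1, dcm_tag(0x0018, 0x0050))
  }
  slope <- tryCatch(dcm_nums(t1, dcm_tag(0x0028, 0x1053)), error = function(e) 1)
  inter <- tryCatch(dcm_nums(t1, dcm_tag(0x0028, 0x1052)), error = function(e) 0)
  vals <- array(0, c(nx, ny, length(slices)))
  for (s in seq_along(slices)) {
    px <- slices[[s]][[dcm_tag(0x7FE0, 0x0010)]]
    if (is.null(px)) stop("missing pixel data in DICOM slice ", s)
    v <- readBin(px$value, "integer", n = nx * ny, size = 2,
                 endian = "little", signed = TRUE)
    vals[, , s] <- v * slope + inter
  }
  ipp <- dcm_nums(t1, dcm_tag(0x0020, 0x0032))
  sp <- c(ps[2], ps[1], dz)  # PixelSpacing is row\col = y\x
  org <- c(ipp[1], ipp[2], zpos[1]) - 0.5 * sp
  image_volume(vals, spacing = sp, origin = org)
}

dcm_element <- function(group, elem, vr, value_raw) {
  len <- length(value_raw)
  if (len %% 2L == 1L) {
    pad <- if (vr %in% c("UI", "OB")) as.raw(0) else charToRaw(" ")
    value_raw <- c(value_raw, pad); len <- len + 1L
  }
  head <- c(writeBin(as.integer(c(group, elem)), raw(), size = 2,
                     endian = "little"),
            charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(head, as.raw(c(0, 0)),
      writeBin(as.integer(len), raw(), size = 4, endian = "little"),
      value_raw)
  } else {
    c(head, writeBin(as.integer(len), raw(), size = 2, endian = "little"),
      value_raw)
  }
}

dcm_ds <- function(group, elem, x)
  dcm_element(group, elem, "DS",
              charToRaw(paste(format(x, digits = 10, trim = TRUE),
                              collapse = "\\")))

write_dicom_series <- function(vol, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(vol$values)
  ts <- charToRaw("1.2.840.10008.1.2.1")
  meta <- c(dcm_element(0x0002, 0x0010, "UI", ts))
  meta <- c(dcm_element(0x0002, 0x0000, "UL",
                        writeBin(length(meta), raw(), size = 4,
                                 endian = "little")), meta)
  for (k in seq_len(d[3])) {
    sl <- round(vol$values[, , k])
    sl[sl < -32768] <- -32768; sl[sl > 32767] <- 32767
    px <- writeBin(as.integer(sl), raw(), size = 2, endian = "little")
    zc <- vol$origin[3] + (k - 0.5) * vol$spacing[3]
    body <- c(
      dcm_element(0x0018, 0x0050, "DS",
                  charToRaw(format(vol$spacing[3], digits = 10))),
      dcm_ds(0x0020, 0x0032, c(vol$origin[1] + 0.5 * vol$spacing[1],
                               vol$origin[2] + 0.5 * vol$spacing[2], zc)),
      dcm_ds(0x0020, 0x0037, c(1, 0, 0, 0, 1, 0)),
      dcm_element(0x0028, 0x0010, "US",
                  writeBin(d[2], raw(), size = 2, endian = "little")),
      dcm_element(0x0028, 0x0011, "US",
                  writeBin(d[1], raw(), size = 2, endian = "little")),
      dcm_ds(0x0028, 0x0030, c(vol$spacing[2], vol$spacing[1])),
      dcm_element(0x0028, 0x0100, "US",
                  writeBin(16L, raw(), size = 2, endian = "little")),
      dcm_element(0x0028, 0x0103, "US",
                  writeBin(1L, raw(), size = 2, endian = "little")),
      dcm_ds(0x0028, 0x1052, 0),
      dcm_ds(0x0028, 0x1053, 1),
      dcm_element(0x7FE0, 0x0010, "OW", px))
    con <- file.path(dir, sprintf("slice_%04d.dcm", k))
    writeBin(c(raw(128), charToRaw("DICM"), meta, body), con)
  }
  invisible(dir)
}
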