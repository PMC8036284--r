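# Minimal PET DICOM codec: single-frame, Explicit VR Little Endian,
# one file per axial slice. Covers the tags needed to reconstruct the
# activity volume and the SUV calibration; everything else is opaque.
#
# Unit convention: RadionuclideTotalDose (0018,1074) is stored in mCi and
# decoded activity values are concentrations in mCi/kg, matching the SUV
# formula SUV = concentration * weight / injected_activity. The convention
# is configurable on read via `dose_unit`.

DCM_LONG_VRS <- c("OB", "OW", "SQ", "UN", "UT")

uint16_to_raw <- function(v) {
  v <- as.integer(round(v))
  v[v > 32767L] <- v[v > 32767L] - 65536L
  writeBin(v, raw(), size = 2L, endian = "little")
}

dcm_element <- function(group, elem, vr, value) {
  val <- switch(vr,
    US = uint16_to_raw(value),
    UL = writeBin(as.integer(value), raw(), size = 4L, endian = "little"),
    OW = uint16_to_raw(value),
    OB = as.raw(value),
    {
      # string VRs: join multi-values with backslash, pad to even length
      s <- paste(value, collapse = "\\")
      r <- charToRaw(s)
      if (length(r) %% 2L == 1L) {
        r <- c(r, if (vr == "UI") as.raw(0L) else charToRaw(" "))
      }
      r
    })
  tag <- c(uint16_to_raw(group), uint16_to_raw(elem))
  if (vr %in% DCM_LONG_VRS) {
    c(tag, charToRaw(vr), as.raw(c(0L, 0L)),
      writeBin(length(val), raw(), size = 4L, endian = "little"), val)
  } else {
    c(tag, charToRaw(vr), uint16_to_raw(length(val)), val)
  }
}

dcm_format_ds <- function(x) sprintf("%.8g", x)

#' Write a PET series as a DICOM file set
#'
#' Writes one single-frame, Explicit-VR little-endian PET DICOM file per
#' axial slice, with pixel spacing, slice location/position, rescale
#' slope/intercept, patient weight and injected dose -- the tags needed for
#' the SUV formula. The rescale slope is chosen so the 16-bit stored range
#' covers the maximum activity, hence [read_series()] round-trips the
#' volume to within one rescale quantisation step.
#'
#' @param series A [pet_series()].
#' @param directory Output directory (created if needed).
#' @param id Series identifier used in file names and UIDs.
#' @return Invisibly, the vector of file paths written.
#' @export
write_dicom <- function(series, directory, id = "series1") {
  if (!inherits(series, "pet_series")) abort("`series` must be a pet_series.")
  if (!dir.exists(directory) &&
      !dir.create(directory, recursive = TRUE, showWarnings = FALSE)) {
    abort(sprintf("cannot create directory '%s'", directory))
  }
  d <- dim(series$activity)
  amax <- max(series$activity)
  slope <- if (amax > 0) amax / 65535 else 1
  seed <- series$meta$phantom_spec$seed %||% 0L
  uid_root <- sprintf("2.25.%d.%d", abs(as.integer(seed)), 4242L)
  series_uid <- paste0(uid_root, ".1")
  study_uid <- paste0(uid_root, ".0")
  paths <- character(d[1])
  for (s in seq_len(d[1])) {
    sl <- series$activity[s, , ]
    stored <- round(sl / slope)
    z <- index_to_mm(s, series$slice_thickness_mm)
    sop_uid <- sprintf("%s.2.%d", uid_root, s)
    body <- c(
      dcm_element(0x0008, 0x0016, "UI", "1.2.840.10008.5.1.4.1.1.128"),
      dcm_element(0x0008, 0x0018, "UI", sop_uid),
      dcm_element(0x0008, 0x0060, "CS", "PT"),
      if (is.finite(series$body_weight_kg))
        dcm_element(0x0010, 0x1030, "DS", dcm_format_ds(series$body_weight_kg)),
      dcm_element(0x0018, 0x0050, "DS", dcm_format_ds(series$slice_thickness_mm)),
      if (is.finite(series$injected_activity_mCi))
        dcm_element(0x0018, 0x1074, "DS",
                    dcm_format_ds(series$injected_activity_mCi)),
      dcm_element(0x0020, 0x000D, "UI", study_uid),
      dcm_element(0x0020, 0x000E, "UI", series_uid),
      dcm_element(0x0020, 0x0013, "IS", as.character(s)),
      dcm_element(0x0020, 0x0032, "DS",
                  dcm_format_ds(c(0, 0, z))),
      dcm_element(0x0020, 0x1041, "DS", dcm_format_ds(z)),
      dcm_element(0x0028, 0x0002, "US", 1L),
      dcm_element(0x0028, 0x0004, "CS", "MONOCHROME2"),
      dcm_element(0x0028, 0x0010, "US", d[2]),
      dcm_element(0x0028, 0x0011, "US", d[3]),
      dcm_element(0x0028, 0x0030, "DS",
                  dcm_format_ds(rep(series$in_plane_spacing_mm, 2))),
      dcm_element(0x0028, 0x0100, "US", 16L),
      dcm_element(0x0028, 0x0101, "US", 16L),
      dcm_element(0x0028, 0x0102, "US", 15L),
      dcm_element(0x0028, 0x0103, "US", 0L),
      dcm_element(0x0028, 0x1052, "DS", "0"),
      dcm_element(0x0028, 0x1053, "DS", dcm_format_ds(slope)),
      dcm_element(0x7FE0, 0x0010, "OW", as.vector(t(stored)))
    )
    meta <- c(
      dcm_element(0x0002, 0x0001, "OB", c(0L, 1L)),
      dcm_element(0x0002, 0x0002, "UI", "1.2.840.10008.5.1.4.1.1.128"),
      dcm_element(0x0002, 0x0003, "UI", sop_uid),
      dcm_element(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1")
    )
    header <- c(as.raw(rep(0L, 128)), charToRaw("DICM"),
                dcm_element(0x0002, 0x0000, "UL", length(meta)), meta)
    paths[s] <- file.path(directory, sprintf("%s_%03d.dcm", id, s))
    con <- file(paths[s], "wb")
    writeBin(c(header, body), con)
    close(con)
  }
  invisible(paths)
}

# parse one DICOM file into a named list of decoded elements
dcm_read_file <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 140 || rawToChar(raw[129:132]) != "DICM") {
    abort(sprintf("'%s' is not a DICOM file (missing DICM magic)", basename(path)))
  }
  pos <- 133L
  n <- length(raw)
  u16 <- function(at) {
    as.integer(raw[at]) + 256L * as.integer(raw[at + 1L])
  }
  u32 <- function(at) {
    as.integer(raw[at]) + 256 * as.integer(raw[at + 1L]) +
      65536 * as.integer(raw[at + 2L]) + 16777216 * as.integer(raw[at + 3L])
  }
  out <- list()
  while (pos + 7L <= n) {
    group <- u16(pos); elem <- u16(pos + 2L)
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    if (!grepl("^[A-Z]{2}$", vr)) {
      abort(sprintf("unsupported (implicit VR?) encoding in '%s'", basename(path)))
    }
    if (vr %in% DCM_LONG_VRS) {
      len <- u32(pos + 8L)
      vstart <- pos + 12L
    } else {
      len <- u16(pos + 6L)
      vstart <- pos + 8L
    }
    if (vstart + len - 1L > n) abort(sprintf("truncated element in '%s'", basename(path)))
    val_raw <- if (len > 0) raw[vstart:(vstart + len - 1L)] else raw(0)
    key <- sprintf("%04X%04X", group, elem)
    out[[key]] <- switch(vr,
      US = {
        m <- matrix(as.integer(val_raw), ncol = 2, byrow = TRUE)
        m[, 1] + 256L * m[, 2]
      },
      UL = u32(vstart),
      OW = ,
      OB = val_raw,
      {
        s <- rawToChar(val_raw[val_raw != as.raw(0L)])
        s <- sub(" +$", "", s)
        strsplit(s, "\\\\")[[1]]
      })
    pos <- vstart + len
  }
  out
}

dcm_num <- function(el, key) {
  v <- el[[key]]
  if (is.null(v)) return(NULL)
  as.numeric(v)
}

#' Read a PET DICOM series from a directory
#'
#' Reads every DICOM file in `directory`, checks that all belong to one
#' series with uniform in-plane spacing, sorts slices by slice location,
#' applies the rescale slope/intercept, and populates the SUV calibration
#' fields (flagged `NA` when the weight or dose tag is absent, in which
#' case raw activity is still returned and only SUV computation is
#' unavailable).
#'
#' @param directory Directory holding the slice files of one series.
#' @param dose_unit Unit of the injected-dose tag; `"mCi"` (the package's
#'   write convention) or `"Bq"`.
#' @return A [pet_series()].
#' @export
read_series <- function(directory, dose_unit = c("mCi", "Bq")) {
  dose_unit <- match.arg(dose_unit)
  files <- list.files(directory, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0) abort(sprintf("no files in '%s'", directory))
  slices <- lapply(files, dcm_read_file)
  series_uids <- vapply(slices, function(el) el[["0020000E"]][1] %||% "", "")
  if (length(unique(series_uids)) != 1L) {
    abort(sprintf("directory mixes %d series; expected one",
                  length(unique(series_uids))))
  }
  spacings <- t(vapply(slices, function(el) {
    ps <- dcm_num(el, "00280030")
    if (is.null(ps)) abort("missing PixelSpacing tag")
    ps
  }, numeric(2)))
  if (max(spacings) - min(spacings) > 1e-6) {
    abort("nonuniform pixel spacing across slices")
  }
  if (abs(spacings[1, 1] - spacings[1, 2]) > 1e-6) {
    abort("non-square pixel spacing is unsupported")
  }
  locs <- vapply(slices, function(el) {
    z <- dcm_num(el, "00201041")
    if (is.null(z)) z <- dcm_num(el, "00200032")[3]
    if (is.null(z) || !is.finite(z)) abort("missing slice location")
    z
  }, 0)
  ord <- order(locs)
  slices <- slices[ord]
  locs <- locs[ord]
  if (length(locs) > 1) {
    steps <- diff(locs)
    if (any(steps <= 0)) abort("duplicate slice locations in series")
    if (max(steps) - min(steps) > 1e-3) {
      abort("nonuniform slice spacing across series")
    }
  }
  first <- slices[[1]]
  nr <- as.integer(first[["00280010"]][1])
  nc <- as.integer(first[["00280011"]][1])
  thickness <- dcm_num(first, "00180050") %||%
    (if (length(locs) > 1) diff(locs)[1] else 1)
  vol <- array(0, dim = c(length(slices), nr, nc))
  for (s in seq_along(slices)) {
    el <- slices[[s]]
    pix <- el[["7FE00010"]]
    if (is.null(pix)) abort(sprintf("missing pixel data in slice %d", s))
    m <- matrix(as.integer(pix), ncol = 2, byrow = TRUE)
    stored <- m[, 1] + 256 * m[, 2]
    slope <- dcm_num(el, "00281053") %||% 1
    icpt <- dcm_num(el, "00281052") %||% 0
    vol[s, , ] <- matrix(stored * slope + icpt, nrow = nr, ncol = nc,
                         byrow = TRUE)
  }
  dose <- dcm_num(first, "00181074")
  if (!is.null(dose) && dose_unit == "Bq") dose <- dose / 3.7e7
  weight <- dcm_num(first, "00101030")
  pet_series(vol,
             in_plane_spacing_mm = spacings[1, 1],
             slice_thickness_mm = thickness,
             injected_activity_mCi = dose %||% NA_real_,
             body_weight_kg = weight %||% NA_real_,
             meta = list(series_uid = series_uids[1],
                         suv_available = !is.null(dose) && !is.null(weight)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
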