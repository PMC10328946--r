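# Minimal DICOM codec: explicit VR little endian only, restricted to the
# attribute subset the pipeline uses (RT Plan MLC geometry + meterset
# weights, RT Dose grids). Sequences are written with defined lengths;
# the reader also accepts undefined-length sequences/items.

SOP_RTPLAN <- "1.2.840.10008.5.1.4.1.1.481.5"
SOP_RTDOSE <- "1.2.840.10008.5.1.4.1.1.481.2"
TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"

LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

# Deterministic instance UIDs (no RNG use: writing files must not disturb
# a seeded simulation stream).
.uid_counter <- new.env(parent = emptyenv())
.uid_counter$n <- 0L
uid_new <- function() {
  .uid_counter$n <- .uid_counter$n + 1L
  sprintf("2.25.%d.%d", Sys.getpid(), .uid_counter$n)
}

raw_u16 <- function(x) writeBin(as.integer(x), raw(), size = 2,
                                endian = "little")
raw_u32 <- function(x) writeBin(as.integer(x), raw(), size = 4,
                                endian = "little")

pad_even <- function(r, pad = as.raw(0x20)) {
  if (length(r) %% 2 == 1) c(r, pad) else r
}

encode_value <- function(vr, value) {
  switch(vr,
    DS = pad_even(charToRaw(paste(vapply(value, function(x)
      sprintf("%.8g", x), character(1)), collapse = "\\"))),
    IS = pad_even(charToRaw(paste(as.integer(value), collapse = "\\"))),
    US = raw_u16(value),
    UL = raw_u32(value),
    UI = pad_even(charToRaw(paste(value, collapse = "\\")), as.raw(0x00)),
    CS = , SH = , LO = , ST = pad_even(charToRaw(paste(value, collapse = "\\"))),
    OW = value,  # already raw
    stop("unsupported VR for writing: ", vr))
}

encode_element <- function(group, element, vr, value) {
  body <- if (vr == "SQ") {
    items <- lapply(value, function(item_elems) {
      payload <- do.call(c, item_elems)
      c(raw_u16(0xFFFE), raw_u16(0xE000), raw_u32(length(payload)), payload)
    })
    if (length(items)) do.call(c, items) else raw(0)
  } else {
    encode_value(vr, value)
  }
  head <- c(raw_u16(group), raw_u16(element), charToRaw(vr))
  if (vr %in% LONG_VRS) {
    c(head, as.raw(c(0, 0)), raw_u32(length(body)), body)
  } else {
    if (length(body) > 65534) stop("value too long for short VR")
    c(head, raw_u16(length(body)), body)
  }
}

dicom_file <- function(sop_class, dataset_raw, path) {
  sop_instance <- uid_new()
  meta <- c(
    encode_element(0x0002, 0x0002, "UI", sop_class),
    encode_element(0x0002, 0x0003, "UI", sop_instance),
    encode_element(0x0002, 0x0010, "UI", TS_EXPLICIT_LE))
  meta <- c(encode_element(0x0002, 0x0000, "UL", length(meta)), meta)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128), charToRaw("DICM"), meta, dataset_raw), con)
  invisible(path)
}

# ---- reader ----------------------------------------------------------------

dicom_parse <- function(raw_bytes) {
  if (length(raw_bytes) < 132 ||
      rawToChar(raw_bytes[129:132]) != "DICM") {
    stop("not a DICOM file (missing DICM marker)")
  }
  env <- new.env()
  env$buf <- raw_bytes
  env$pos <- 133L
  take <- function(n) {
    if (env$pos + n - 1L > length(env$buf)) stop("truncated DICOM stream")
    out <- env$buf[env$pos:(env$pos + n - 1L)]
    env$pos <- env$pos + n
    out
  }
  u16 <- function() readBin(take(2L), "integer", size = 2, signed = FALSE,
                            endian = "little")
  u32 <- function() readBin(take(4L), "integer", size = 4, endian = "little")

  parse_value <- function(vr, body) {
    txt <- function() sub(" +$", "", rawToChar(body[body != as.raw(0)]))
    switch(vr,
      DS = as.numeric(strsplit(txt(), "\\\\")[[1]]),
      IS = as.integer(strsplit(txt(), "\\\\")[[1]]),
      US = readBin(body, "integer", n = length(body) / 2, size = 2,
                   signed = FALSE, endian = "little"),
      UL = readBin(body, "integer", n = length(body) / 4, size = 4,
                   endian = "little"),
      UI = , CS = , SH = , LO = , ST = , LT = , PN = , AE = ,
      DA = , TM = , DT = txt(),
      body)
  }

  parse_dataset <- function(end_pos, in_item = FALSE) {
    out <- list()
    while (env$pos < end_pos) {
      g <- u16(); e <- u16()
      if (g == 0xFFFE) {  # delimiters
        len <- u32()
        if (e == 0xE00D && in_item) return(out)  # item delimiter
        if (e == 0xE0DD) next                    # sequence delimiter
        stop("unexpected item tag outside a sequence")
      }
      vr <- rawToChar(take(2L))
      len <- if (vr %in% LONG_VRS) { take(2L); u32() } else u16()
      tag <- sprintf("%04X,%04X", g, e)
      if (vr == "SQ") {
        items <- list()
        sq_end <- if (len == -1L) length(env$buf) + 1L else env$pos + len
        while (env$pos < sq_end) {
          ig <- u16(); ie <- u16(); ilen <- u32()
          if (ig == 0xFFFE && ie == 0xE0DD) break  # sequence delimiter
          if (!(ig == 0xFFFE && ie == 0xE000)) stop("malformed sequence item")
          item_end <- if (ilen == -1L) length(env$buf) + 1L else env$pos + ilen
          items[[length(items) + 1L]] <- parse_dataset(item_end,
                                                       in_item = ilen == -1L)
        }
        out[[tag]] <- list(vr = "SQ", value = items)
      } else {
        out[[tag]] <- list(vr = vr, value = parse_value(vr, take(len)))
      }
    }
    out
  }

  ds <- parse_dataset(length(env$buf) + 1L)
  ts <- ds[["0002,0010"]]$value
  if (!is.null(ts) && !identical(ts, TS_EXPLICIT_LE)) {
    stop("unsupported transfer syntax: ", ts)
  }
  ds
}

dget <- function(ds, tag, required = FALSE, what = tag) {
  el <- ds[[tag]]
  if (is.null(el) && required) stop("missing required attribute ", what)
  el$value
}

# ---- RT Plan ---------------------------------------------------------------

#' Write a plan as a DICOM-RT Plan file
#'
#' Emits an explicit-VR-little-endian RT Plan with one beam sequence item
#' per beam: leaf-position boundaries, and per control point the MLCX leaf
#' positions (bank A then bank B) and the cumulative meterset weight.
#' Collision-violating plans are refused with the offending leaf row named.
#'
#' @param plan an `mlc_plan`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_rtplan <- function(plan, path) {
  stopifnot(inherits(plan, "mlc_plan"))
  validate_plan(plan)
  beam_items <- lapply(seq_along(plan$beams), function(bi) {
    b <- plan$beams[[bi]]
    n_pairs <- length(b$control_points[[1]]$bank_a)
    bld <- list(list(
      encode_element(0x300A, 0x00B8, "CS", "MLCX"),
      encode_element(0x300A, 0x00BC, "IS", n_pairs),
      encode_element(0x300A, 0x00BE, "DS", b$leaf_edges)))
    cum <- cumsum(vapply(b$control_points, `[[`, numeric(1), "mu_weight"))
    cp_items <- lapply(seq_along(b$control_points), function(ci) {
      cp <- b$control_points[[ci]]
      list(
        encode_element(0x300A, 0x0112, "IS", ci - 1L),
        encode_element(0x300A, 0x011A, "SQ", list(list(
          encode_element(0x300A, 0x00B8, "CS", "MLCX"),
          encode_element(0x300A, 0x011C, "DS", c(cp$bank_a, cp$bank_b))))),
        encode_element(0x300A, 0x011E, "DS", b$gantry_angle),
        encode_element(0x300A, 0x0134, "DS", cum[ci]))
    })
    list(
      encode_element(0x300A, 0x00B6, "SQ", bld),
      encode_element(0x300A, 0x00C0, "IS", bi),
      encode_element(0x300A, 0x0110, "IS", length(b$control_points)),
      encode_element(0x300A, 0x0111, "SQ", cp_items))
  })
  dataset <- c(
    encode_element(0x0008, 0x0016, "UI", SOP_RTPLAN),
    encode_element(0x0008, 0x0018, "UI", uid_new()),
    encode_element(0x0008, 0x0060, "CS", "RTPLAN"),
    encode_element(0x300A, 0x0002, "SH", plan$case_name),
    encode_element(0x300A, 0x0004, "LO", plan$label),
    encode_element(0x300A, 0x00B0, "SQ", beam_items))
  dicom_file(SOP_RTPLAN, dataset, path)
}

#' Read a DICOM-RT Plan file
#'
#' Reads plans written by [write_rtplan()] (and standard-conforming files
#' using the same attribute subset): MLCX leaf positions per control point,
#' cumulative meterset weights, gantry angle and leaf boundaries.
#'
#' @param path file path.
#' @return an `mlc_plan`.
#' @export
read_rtplan <- function(path) {
  ds <- dicom_parse(readBin(path, raw(), file.size(path)))
  if (!identical(dget(ds, "0008,0016"), SOP_RTPLAN)) {
    stop("not an RT Plan file")
  }
  case <- dget(ds, "300A,0002", required = TRUE, "RTPlanLabel")
  label <- dget(ds, "300A,0004")
  beams_sq <- dget(ds, "300A,00B0", required = TRUE, "BeamSequence")
  beams <- lapply(seq_along(beams_sq), function(bi) {
    bd <- beams_sq[[bi]]
    bld <- dget(bd, "300A,00B6")
    if (is.null(bld)) {
      stop("beam ", bi, ": missing beam-limiting-device sequence")
    }
    edges <- dget(bld[[1]], "300A,00BE", required = TRUE,
                  "LeafPositionBoundaries")
    cps_sq <- dget(bd, "300A,0111")
    if (is.null(cps_sq)) {
      stop("beam ", bi, ": missing control-point sequence")
    }
    gantry <- 0; cum_prev <- 0
    cps <- vector("list", length(cps_sq))
    for (ci in seq_along(cps_sq)) {
      cd <- cps_sq[[ci]]
      pos_sq <- dget(cd, "300A,011A")
      if (is.null(pos_sq)) {
        stop("beam ", bi, ", control point ", ci,
             ": missing beam-limiting-device position sequence")
      }
      pos <- dget(pos_sq[[1]], "300A,011C", required = TRUE,
                  "LeafJawPositions")
      n <- length(pos) / 2L
      ga <- dget(cd, "300A,011E")
      if (!is.null(ga)) gantry <- ga
      cum <- dget(cd, "300A,0134", required = TRUE,
                  "CumulativeMetersetWeight")
      cps[[ci]] <- control_point(pos[seq_len(n)], pos[n + seq_len(n)],
                                 cum - cum_prev)
      cum_prev <- cum
    }
    mlc_beam(gantry, cps, leaf_width = diff(edges)[1], leaf_edges = edges)
  })
  mlc_plan(case, beams, label = if (is.null(label)) "error_free" else label)
}

# ---- RT Dose ---------------------------------------------------------------

#' Write a dose grid as a DICOM-RT Dose file
#'
#' 32-bit pixel data with a dose-grid-scaling factor chosen so the dose
#' maximum maps near the top of the integer range; voxel values round-trip
#' to within one scaling quantum.
#'
#' @param dose a [dose_grid()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_rtdose <- function(dose, path) {
  stopifnot(inherits(dose, "dose_grid"))
  d <- dim(dose$values)
  maxd <- max(dose$values)
  # power-of-ten scaling: exact as a decimal string, so the factor survives
  # the DS value representation and voxels round-trip within one quantum
  scaling <- if (maxd > 0) 10^ceiling(log10(maxd / (2^31 - 1))) else 1
  pix <- as.integer(round(dose$values / scaling))
  offsets <- (seq_len(d[3]) - 1) * dose$spacing[3]
  dataset <- c(
    encode_element(0x0008, 0x0016, "UI", SOP_RTDOSE),
    encode_element(0x0008, 0x0018, "UI", uid_new()),
    encode_element(0x0008, 0x0060, "CS", "RTDOSE"),
    encode_element(0x0020, 0x0032, "DS", dose$origin),
    encode_element(0x0020, 0x0037, "DS", c(1, 0, 0, 0, 1, 0)),
    encode_element(0x0028, 0x0002, "US", 1L),
    encode_element(0x0028, 0x0004, "CS", "MONOCHROME2"),
    encode_element(0x0028, 0x0008, "IS", d[3]),
    encode_element(0x0028, 0x0010, "US", d[2]),
    encode_element(0x0028, 0x0011, "US", d[1]),
    encode_element(0x0028, 0x0030, "DS", dose$spacing[c(2, 1)]),
    encode_element(0x0028, 0x0100, "US", 32L),
    encode_element(0x0028, 0x0101, "US", 32L),
    encode_element(0x0028, 0x0102, "US", 31L),
    encode_element(0x0028, 0x0103, "US", 0L),
    encode_element(0x3004, 0x0002, "CS", "GY"),
    encode_element(0x3004, 0x0004, "CS", "PHYSICAL"),
    encode_element(0x3004, 0x000A, "CS", "PLAN"),
    encode_element(0x3004, 0x000C, "DS", offsets),
    encode_element(0x3004, 0x000E, "DS", scaling),
    encode_element(0x7FE0, 0x0010, "OW",
                   writeBin(pix, raw(), size = 4, endian = "little")))
  dicom_file(SOP_RTDOSE, dataset, path)
}

#' Read a DICOM-RT Dose file
#'
#' Scales pixel data by the dose-grid-scaling factor to Gy. Non-uniform
#' frame (slice) spacing is rejected.
#'
#' @param path file path.
#' @return a [dose_grid()].
#' @export
read_rtdose <- function(path) {
  ds <- dicom_parse(readBin(path, raw(), file.size(path)))
  if (!identical(dget(ds, "0008,0016"), SOP_RTDOSE)) {
    stop("not an RT Dose file")
  }
  rows <- dget(ds, "0028,0010", required = TRUE, "Rows")
  cols <- dget(ds, "0028,0011", required = TRUE, "Columns")
  nframes <- dget(ds, "0028,0008", required = TRUE, "NumberOfFrames")
  ps <- dget(ds, "0028,0030", required = TRUE, "PixelSpacing")
  offsets <- dget(ds, "3004,000C", required = TRUE, "GridFrameOffsetVector")
  scaling <- dget(ds, "3004,000E", required = TRUE, "DoseGridScaling")
  origin <- dget(ds, "0020,0032", required = TRUE, "ImagePositionPatient")
  dz <- if (nframes > 1) {
    steps <- diff(offsets)
    if (max(steps) - min(steps) > 1e-6) {
      stop("non-uniform slice spacing in GridFrameOffsetVector")
    }
    steps[1]
  } else 1
  pix_raw <- dget(ds, "7FE0,0010", required = TRUE, "PixelData")
  pix <- readBin(pix_raw, "integer", n = cols * rows * nframes, size = 4,
                 endian = "little")
  dose_grid(array(pix * scaling, dim = c(cols, rows, nframes)),
            spacing = c(ps[2], ps[1], dz), origin = origin)
}
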