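# Minimal DICOM element codec: little-endian explicit VR (written and read)
# and implicit VR (read only), covering the subset an RT structure set
# needs. Values are kept as raw vectors; helpers decode the string VRs.
# Tags are handled as "GGGGEEEE" uppercase hex keys.

# tags that are sequences, needed to recurse when reading implicit VR
DICOM_SQ_TAGS <- c(
  "30060010",  # ReferencedFrameOfReferenceSequence
  "30060012", "30060014",  # RTReferencedStudy/SeriesSequence
  "30060020",  # StructureSetROISequence
  "30060039",  # ROIContourSequence
  "30060040",  # ContourSequence
  "30060080",  # RTROIObservationsSequence
  "300C0002"   # ReferencedRTPlanSequence
)

# VRs carrying a 4-byte length (with 2 reserved bytes) in explicit encoding
DICOM_LONG_VRS <- c("OB", "OW", "OF", "OD", "OL", "SQ", "UC", "UR", "UT", "UN")

dcm_tag_key <- function(group, element) {
  sprintf("%04X%04X", group, element)
}

dcm_uint16 <- function(x) writeBin(as.integer(x), raw(), size = 2L,
                                   endian = "little")
dcm_uint32 <- function(x) {
  # writeBin has no unsigned 32-bit; lengths here stay far below 2^31
  writeBin(as.integer(x), raw(), size = 4L, endian = "little")
}

# pad a string value to even length (DS/IS/etc pad with space, UI with NUL)
dcm_pad <- function(bytes, pad = as.raw(0x20)) {
  if (length(bytes) %% 2L == 1L) c(bytes, pad) else bytes
}

# one explicit-VR little-endian element as raw
dcm_element <- function(group, element, vr, value) {
  if (is.character(value))
    value <- charToRaw(paste(value, collapse = "\\"))
  value <- dcm_pad(value, if (vr == "UI") as.raw(0x00) else as.raw(0x20))
  head <- c(dcm_uint16(group), dcm_uint16(element), charToRaw(vr))
  if (vr %in% DICOM_LONG_VRS) {
    c(head, as.raw(c(0, 0)), dcm_uint32(length(value)), value)
  } else {
    if (length(value) > 65534L)
      stop(sprintf("DICOM value too long (%d bytes) for VR %s",
                   length(value), vr))
    c(head, dcm_uint16(length(value)), value)
  }
}

# a defined-length sequence of items, each item a raw vector of elements
dcm_sequence <- function(group, element, items) {
  body <- raw(0)
  for (it in items)
    body <- c(body, dcm_uint16(0xFFFE), dcm_uint16(0xE000),
              dcm_uint32(length(it)), it)
  dcm_element(group, element, "SQ", body)
}

# --- reading ---------------------------------------------------------------

dcm_read_uint16 <- function(raw, at) {
  as.integer(raw[at]) + 256L * as.integer(raw[at + 1L])
}
dcm_read_uint32 <- function(raw, at) {
  # as double: undefined length 0xFFFFFFFF exceeds .Machine$integer.max
  sum(as.numeric(raw[at + 0:3]) * 256^(0:3))
}

# parse a dataset (raw slice) into a named list tag -> value; sequence tags
# map to a list of item datasets. explicit toggles the VR encoding.
dcm_parse_dataset <- function(raw, explicit, pos = 1L, end = length(raw)) {
  out <- list()
  while (pos + 7 <= end) {
    group <- dcm_read_uint16(raw, pos)
    element <- dcm_read_uint16(raw, pos + 2L)
    key <- dcm_tag_key(group, element)
    pos <- pos + 4L
    if (group == 0xFFFE) {  # delimiters: item end / sequence end
      len <- dcm_read_uint32(raw, pos)
      pos <- pos + 4L
      if (element %in% c(0xE00D, 0xE0DD))
        return(list(data = out, pos = pos))
      stop("unexpected item tag outside sequence")
    }
    vr <- NULL
    if (explicit) {
      vr <- rawToChar(raw[pos + 0:1])
      if (vr %in% DICOM_LONG_VRS) {
        len <- dcm_read_uint32(raw, pos + 4L)
        pos <- pos + 8L
      } else {
        len <- dcm_read_uint16(raw, pos + 2L)
        pos <- pos + 4L
      }
    } else {
      len <- dcm_read_uint32(raw, pos)
      pos <- pos + 4L
    }
    is_seq <- identical(vr, "SQ") ||
      (!explicit && (key %in% DICOM_SQ_TAGS || len == 4294967295))
    if (is_seq) {
      parsed <- dcm_parse_sequence(raw, explicit, pos, len)
      out[[key]] <- parsed$items
      pos <- parsed$pos
    } else {
      if (len == 4294967295)
        stop(sprintf("undefined length on non-sequence tag %s", key))
      out[[key]] <- raw[seq.int(pos, length.out = len)]
      pos <- pos + len
    }
  }
  list(data = out, pos = pos)
}

# parse sequence items starting at pos; len is the sequence byte length or
# the undefined-length sentinel
dcm_parse_sequence <- function(raw, explicit, pos, len) {
  items <- list()
  undefined <- len == 4294967295
  stop_at <- if (undefined) length(raw) else pos + len - 1
  while (pos <= stop_at) {
    group <- dcm_read_uint16(raw, pos)
    element <- dcm_read_uint16(raw, pos + 2L)
    ilen <- dcm_read_uint32(raw, pos + 4L)
    pos <- pos + 8L
    if (group != 0xFFFE)
      stop("malformed sequence: expected item tag")
    if (element == 0xE0DD)  # sequence delimiter
      return(list(items = items, pos = pos))
    if (element != 0xE000)
      stop("malformed sequence item tag")
    if (ilen == 4294967295) {  # undefined-length item: ends at delimiter
      parsed <- dcm_parse_dataset(raw, explicit, pos, stop_at)
      items[[length(items) + 1L]] <- parsed$data
      pos <- parsed$pos
    } else {
      parsed <- dcm_parse_dataset(raw, explicit, pos, pos + ilen - 1)
      items[[length(items) + 1L]] <- parsed$data
      pos <- pos + ilen
    }
  }
  list(items = items, pos = pos)
}

# read a DICOM part-10 file -> list(meta, data); dispatches on the transfer
# syntax found in the file meta group
dcm_read_file <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 140 || rawToChar(raw[129:132]) != "DICM")
    stop(sprintf("not a DICOM part-10 file: %s", path))
  pos <- 133L
  # file meta group (0002,xxxx) is always explicit VR little endian
  meta <- list()
  while (pos + 7 <= length(raw) && dcm_read_uint16(raw, pos) == 2L) {
    element <- dcm_read_uint16(raw, pos + 2L)
    vr <- rawToChar(raw[pos + 4:5])
    if (vr %in% DICOM_LONG_VRS) {
      len <- dcm_read_uint32(raw, pos + 8L)
      vstart <- pos + 12L
    } else {
      len <- dcm_read_uint16(raw, pos + 6L)
      vstart <- pos + 8L
    }
    meta[[dcm_tag_key(2L, element)]] <- raw[seq.int(vstart, length.out = len)]
    pos <- vstart + len
  }
  ts <- dcm_string(meta, "00020010")
  explicit <- !identical(ts, "1.2.840.10008.1.2")
  if (!is.null(ts) && !ts %in% c("1.2.840.10008.1.2", "1.2.840.10008.1.2.1"))
    stop(sprintf("unsupported transfer syntax: %s", ts))
  data <- dcm_parse_dataset(raw, explicit, pos)$data
  list(meta = meta, data = data)
}

# --- value decoding --------------------------------------------------------

dcm_string <- function(ds, key) {
  v <- ds[[key]]
  if (is.null(v)) return(NULL)
  s <- rawToChar(v[v != as.raw(0)])
  sub("\\s+$", "", s)
}

dcm_numbers <- function(ds, key) {
  s <- dcm_string(ds, key)
  if (is.null(s)) return(NULL)
  as.numeric(strsplit(s, "\\", fixed = TRUE)[[1]])
}
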