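# Minimal baseline TIFF + OME-XML support.
#
# No TIFF package is available in the target R environment, so the package
# carries its own codec for the one dialect it needs: uncompressed,
# little-endian, single-sample-per-pixel, 64-bit IEEE float, one strip per
# page, OME-XML ImageDescription on the first page carrying dimension sizes
# and physical voxel sizes. The reader additionally accepts 8/16-bit
# unsigned pages and multi-strip layouts written by other software.

TIFF_TYPE_BYTES <- c(`1` = 1, `2` = 1, `3` = 2, `4` = 4, `5` = 8,
                     `6` = 1, `7` = 1, `8` = 2, `9` = 4, `10` = 8,
                     `11` = 4, `12` = 8)

ome_description <- function(nx, ny, nz, nc, nt, voxel_size) {
  paste0(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<OME xmlns="http://www.openmicroscopy.org/Schemas/OME/2016-06">',
    '<Image ID="Image:0"><Pixels ID="Pixels:0" DimensionOrder="XYZCT" ',
    'Type="double" BigEndian="false" ',
    sprintf('SizeX="%d" SizeY="%d" SizeZ="%d" SizeC="%d" SizeT="%d" ',
            nx, ny, nz, nc, nt),
    sprintf('PhysicalSizeX="%.10g" PhysicalSizeY="%.10g" PhysicalSizeZ="%.10g" ',
            voxel_size[3], voxel_size[2], voxel_size[1]),
    'PhysicalSizeXUnit="µm" PhysicalSizeYUnit="µm" PhysicalSizeZUnit="µm"/>',
    '</Image></OME>')
}

#' Write a two-channel stack (or time-lapse) as OME-TIFF
#'
#' Pages are ordered z-fastest, then channel (0 = green, 1 = red), then
#' frame (OME dimension order XYZCT); pixels are 64-bit floats so stacks
#' round-trip bit-exactly. The first
#' page carries an OME-XML description with dimension sizes and physical
#' voxel sizes in micrometres.
#'
#' @param grids A [voxel_grid()] or list of them (one per frame, equal
#'   shapes).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tiff_stack <- function(grids, path) {
  if (inherits(grids, "voxel_grid")) grids <- list(grids)
  stopifnot(length(grids) >= 1L)
  for (g in grids) stopifnot(inherits(g, "voxel_grid"))
  d <- dim(grids[[1]]$green)
  nz <- d[1]; ny <- d[2]; nx <- d[3]
  nt <- length(grids); nc <- 2L
  desc <- ome_description(nx, ny, nz, nc, nt, grids[[1]]$voxel_size)
  desc_raw <- c(charToRaw(desc), as.raw(0))
  if (length(desc_raw) %% 2 == 1) desc_raw <- c(desc_raw, as.raw(0))

  n_pages <- nt * nc * nz
  page_bytes <- nx * ny * 8
  # layout: header (8) | description | page data ... | IFDs
  desc_off <- 8L
  data_off <- desc_off + length(desc_raw)
  ifd_off <- data_off + n_pages * page_bytes
  n_entries <- function(p) if (p == 1L) 10L else 9L
  ifd_bytes <- function(p) 2L + 12L * n_entries(p) + 4L
  ifd_offsets <- integer(n_pages)
  off <- ifd_off
  for (p in seq_len(n_pages)) {
    ifd_offsets[p] <- off
    off <- off + ifd_bytes(p)
  }

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(as.integer(ifd_offsets[1]), con, size = 4, endian = "little")
  writeBin(desc_raw, con)
  # page data: frame-major, then channel, then z
  for (t in seq_len(nt)) {
    g <- grids[[t]]
    for (ch in c("green", "red")) {
      arr <- g[[ch]]
      for (z in seq_len(nz)) {
        plane <- arr[z, , ]                 # [y, x]
        writeBin(as.numeric(t(plane)), con, size = 8, endian = "little")
      }
    }
  }
  entry <- function(tag, type, count, value) {
    writeBin(as.integer(tag), con, size = 2, endian = "little")
    writeBin(as.integer(type), con, size = 2, endian = "little")
    writeBin(as.integer(count), con, size = 4, endian = "little")
    writeBin(as.integer(value), con, size = 4, endian = "little")
  }
  for (p in seq_len(n_pages)) {
    strip_off <- data_off + (p - 1L) * page_bytes
    writeBin(n_entries(p), con, size = 2, endian = "little")
    entry(256, 4, 1, nx)                     # ImageWidth
    entry(257, 4, 1, ny)                     # ImageLength
    entry(258, 3, 1, 64)                     # BitsPerSample
    entry(259, 3, 1, 1)                      # Compression: none
    entry(262, 3, 1, 1)                      # Photometric: BlackIsZero
    if (p == 1L) entry(270, 2, length(desc_raw), desc_off)
    entry(273, 4, 1, strip_off)              # StripOffsets
    entry(278, 4, 1, ny)                     # RowsPerStrip
    entry(279, 4, 1, page_bytes)             # StripByteCounts
    entry(339, 3, 1, 3)                      # SampleFormat: IEEE float
    nxt <- if (p < n_pages) ifd_offsets[p + 1L] else 0L
    writeBin(as.integer(nxt), con, size = 4, endian = "little")
  }
  invisible(path)
}

read_uint <- function(raw, off, size, endian = "little") {
  b <- as.integer(raw[off + seq_len(size)])
  if (endian == "big") b <- rev(b)
  sum(b * 256^(seq_len(size) - 1))
}

# Parse all IFDs of a TIFF file. Returns list of per-page tag lists.
parse_tiff <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 8) stop("not a TIFF file: too short")
  order_tag <- rawToChar(raw[1:2])
  endian <- if (order_tag == "II") "little" else if (order_tag == "MM") "big"
    else stop("not a TIFF file: bad byte-order mark")
  if (read_uint(raw, 2, 2, endian) != 42) stop("not a TIFF file: magic != 42")
  pages <- list()
  off <- read_uint(raw, 4, 4, endian)
  while (off != 0) {
    n <- read_uint(raw, off, 2, endian)
    tags <- list()
    for (i in seq_len(n)) {
      e <- off + 2 + (i - 1) * 12
      tag <- read_uint(raw, e, 2, endian)
      type <- read_uint(raw, e + 2, 2, endian)
      count <- read_uint(raw, e + 4, 4, endian)
      tb <- TIFF_TYPE_BYTES[as.character(type)]
      if (is.na(tb)) next
      total <- tb * count
      voff <- if (total <= 4) e + 8 else read_uint(raw, e + 8, 4, endian)
      vals <- if (type == 2) {
        b <- raw[voff + seq_len(count)]
        rawToChar(b[b != as.raw(0)])
      } else if (type == 3) {
        vapply(seq_len(count) - 1, function(k)
          read_uint(raw, voff + 2 * k, 2, endian), 0)
      } else if (type == 4) {
        vapply(seq_len(count) - 1, function(k)
          read_uint(raw, voff + 4 * k, 4, endian), 0)
      } else if (type == 5) {
        vapply(seq_len(count) - 1, function(k)
          read_uint(raw, voff + 8 * k, 4, endian) /
            read_uint(raw, voff + 8 * k + 4, 4, endian), 0)
      } else NULL
      if (!is.null(vals)) tags[[as.character(tag)]] <- vals
    }
    pages[[length(pages) + 1L]] <- tags
    off <- read_uint(raw, off + 2 + n * 12, 4, endian)
  }
  list(pages = pages, raw = raw, endian = endian)
}

read_tiff_page <- function(tf, page) {
  tags <- tf$pages[[page]]
  need <- function(tag) {
    v <- tags[[as.character(tag)]]
    if (is.null(v)) stop(sprintf("TIFF page %d missing tag %d", page, tag))
    v
  }
  nx <- need(256); ny <- need(257)
  bits <- if (is.null(tags[["258"]])) 1 else tags[["258"]][1]
  comp <- if (is.null(tags[["259"]])) 1 else tags[["259"]]
  if (comp != 1) stop("only uncompressed TIFF is supported")
  fmt <- if (is.null(tags[["339"]])) 1 else tags[["339"]][1]
  offs <- need(273); cnts <- need(279)
  bytes_per <- bits / 8
  buf <- raw(0)
  for (s in seq_along(offs))
    buf <- c(buf, tf$raw[offs[s] + seq_len(cnts[s])])
  n_px <- nx * ny
  vals <- if (fmt == 3 && bits %in% c(32, 64)) {
    readBin(buf, "numeric", n = n_px, size = bits / 8, endian = tf$endian)
  } else if (bits %in% c(8, 16) && fmt %in% c(1, 2)) {
    readBin(buf, "integer", n = n_px, size = bytes_per,
            signed = bits == 8 && fmt == 2, endian = tf$endian)
  } else stop(sprintf("unsupported TIFF pixel type: %d-bit format %d",
                      bits, fmt))
  t(matrix(as.numeric(vals), nrow = nx, ncol = ny))   # -> [y, x]
}

parse_ome_sizes <- function(desc) {
  grab <- function(attr) {
    m <- regmatches(desc, regexpr(sprintf('%s="[^"]+"', attr), desc))
    if (length(m) == 0) return(NA_real_)
    as.numeric(sub(sprintf('%s="([^"]+)"', attr), "\\1", m))
  }
  list(nx = grab("SizeX"), ny = grab("SizeY"), nz = grab("SizeZ"),
       nc = grab("SizeC"), nt = grab("SizeT"),
       voxel_size = c(grab("PhysicalSizeZ"), grab("PhysicalSizeY"),
                      grab("PhysicalSizeX")))
}

#' Load a two-channel stack (or time-lapse) from TIFF
#'
#' Reads OME-TIFF written by [write_tiff_stack()] (sizes and voxel sizes
#' from the embedded OME-XML) or plain multi-page TIFF, for which `sizes`
#' and `voxel_size` must be supplied. Pages are interpreted z-fastest,
#' then channel, then frame.
#'
#' @param path TIFF file path.
#' @param channel_map Length-2 integer vector naming which channel index
#'   (1-based) is green and which is red, e.g. `c(green = 1, red = 2)`.
#' @param sizes Optional list with `nz`, `nc`, `nt` for files without
#'   OME metadata.
#' @param voxel_size Optional `(z, y, x)` micrometre override; mandatory
#'   for files without OME physical sizes.
#' @return A [voxel_grid()] for single-frame files, else a list of them.
#' @export
load_stack <- function(path, channel_map = c(green = 1L, red = 2L),
                       sizes = NULL, voxel_size = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  stopifnot(length(channel_map) == 2L)
  if (channel_map[1] == channel_map[2])
    stop("channel indices must be distinct")
  tf <- parse_tiff(path)
  n_pages <- length(tf$pages)
  desc <- tf$pages[[1]][["270"]]
  meta <- if (!is.null(desc) && grepl("SizeX", desc)) parse_ome_sizes(desc)
          else NULL
  nz <- if (!is.null(sizes$nz)) sizes$nz else meta$nz
  nc <- if (!is.null(sizes$nc)) sizes$nc else meta$nc
  nt <- if (!is.null(sizes$nt)) sizes$nt else meta$nt
  if (is.null(nz) || is.na(nz) || is.null(nc) || is.na(nc))
    stop("axis metadata missing (SizeZ/SizeC): supply `sizes`")
  if (is.null(nt) || is.na(nt)) nt <- n_pages / (nz * nc)
  nz <- as.integer(nz); nc <- as.integer(nc); nt <- as.integer(nt)
  if (nz * nc * nt != n_pages)
    stop(sprintf("page count %d does not match SizeZ*SizeC*SizeT = %d",
                 n_pages, nz * nc * nt))
  if (nc < 2L) stop("single-channel file: two channels required")
  if (max(channel_map) > nc) stop("channel_map index exceeds SizeC")
  vs <- if (!is.null(voxel_size)) as.numeric(voxel_size)
        else meta$voxel_size
  if (is.null(vs) || any(is.na(vs)))
    stop("voxel size missing from metadata: supply `voxel_size`")
  p1 <- read_tiff_page(tf, 1)
  ny <- nrow(p1); nx <- ncol(p1)
  grids <- vector("list", nt)
  for (t in seq_len(nt)) {
    chan <- lapply(seq_len(nc), function(c) {
      arr <- array(0, dim = c(nz, ny, nx))
      for (z in seq_len(nz)) {
        page <- (t - 1L) * nc * nz + (c - 1L) * nz + z
        arr[z, , ] <- read_tiff_page(tf, page)
      }
      arr
    })
    grids[[t]] <- voxel_grid(chan[[channel_map[1]]], chan[[channel_map[2]]],
                             voxel_size = vs, frame_index = t - 1L)
  }
  if (nt == 1L) grids[[1]] else grids
}

#' Write a label mask as 16-bit TIFF
#'
#' @param mask A `nucleus_mask`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask_tiff <- function(mask, path) {
  stopifnot(inherits(mask, "nucleus_mask"))
  d <- dim(mask$labels)
  if (max(mask$labels) > 65535) stop("more than 65535 labels")
  con <- file(path, "wb")
  on.exit(close(con))
  nz <- d[1]; ny <- d[2]; nx <- d[3]
  page_bytes <- nx * ny * 2
  data_off <- 8L
  ifd_off <- data_off + nz * page_bytes
  ifd_bytes <- 2L + 12L * 8L + 4L
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(as.integer(ifd_off), con, size = 4, endian = "little")
  for (z in seq_len(nz))
    writeBin(as.integer(t(mask$labels[z, , ])), con, size = 2,
             endian = "little")
  entry <- function(tag, type, count, value) {
    writeBin(as.integer(tag), con, size = 2, endian = "little")
    writeBin(as.integer(type), con, size = 2, endian = "little")
    writeBin(as.integer(count), con, size = 4, endian = "little")
    writeBin(as.integer(value), con, size = 4, endian = "little")
  }
  for (z in seq_len(nz)) {
    writeBin(8L, con, size = 2, endian = "little")
    entry(256, 4, 1, nx)
    entry(257, 4, 1, ny)
    entry(258, 3, 1, 16)
    entry(259, 3, 1, 1)
    entry(262, 3, 1, 1)
    entry(273, 4, 1, data_off + (z - 1L) * page_bytes)
    entry(278, 4, 1, ny)
    entry(279, 4, 1, page_bytes)
    nxt <- if (z < nz) ifd_off + z * ifd_bytes else 0L
    writeBin(as.integer(nxt), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Write a table as CSV with a provenance header
#'
#' Provenance lines start with `#` and record the package version, seed,
#' config hash and inputs, keeping every output traceable; the body is
#' plain comma-separated UTF-8 with a header row, `.` decimals, and
#' missing values as empty fields.
#'
#' @param df data.frame to write.
#' @param path Output path.
#' @param seed Seed recorded in the header.
#' @param config_hash Optional configuration hash string.
#' @param inputs Optional character vector of input identifiers.
#' @return `path`, invisibly.
#' @export
write_table_provenance <- function(df, path, seed = NA_integer_,
                                   config_hash = NULL, inputs = NULL) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  version <- as.character(utils::packageVersion("nucratio"))
  writeLines(sprintf("# nucratio %s", version), con)
  writeLines(sprintf("# seed: %s", seed), con)
  if (!is.null(config_hash))
    writeLines(sprintf("# config_hash: %s", config_hash), con)
  if (!is.null(inputs))
    writeLines(sprintf("# inputs: %s", paste(inputs, collapse = ", ")), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, na = "",
                     qmethod = "double")
  invisible(path)
}

#' Read a provenance-headed CSV
#'
#' @param path CSV file written by [write_table_provenance()].
#' @return data.frame; provenance lines are returned in attribute
#'   `"provenance"`.
#' @export
read_table_provenance <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  prov <- lines[startsWith(lines, "#")]
  df <- utils::read.csv(text = lines[!startsWith(lines, "#")],
                        stringsAsFactors = FALSE)
  attr(df, "provenance") <- prov
  df
}

#' Read cell outlines from CSV
#'
#' Expected columns: `cell_label`, `z`, `vertex_index`, `y`, `x`; one row
#' per polygon vertex.
#'
#' @param path CSV path.
#' @return List of [cell_outline()] objects, one per `(cell_label, z)`.
#' @export
read_outlines_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("cell_label", "z", "vertex_index", "y", "x")
  stopifnot(all(need %in% names(df)))
  keys <- unique(df[, c("cell_label", "z")])
  lapply(seq_len(nrow(keys)), function(i) {
    sub <- df[df$cell_label == keys$cell_label[i] & df$z == keys$z[i], ]
    sub <- sub[order(sub$vertex_index), ]
    cell_outline(keys$cell_label[i], keys$z[i],
                 as.matrix(sub[, c("y", "x")]))
  })
}

# Stable short hash of a configuration object (md5 of canonical JSON).
config_hash <- function(config) {
  js <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(js, tmp)
  unname(tools::md5sum(tmp))
}
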