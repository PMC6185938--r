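#' Multi-channel image stack
#'
#' Container for a multi-channel, optionally z-stacked fluorescence image.
#' Pixels are stored as a 4-D array indexed `[y, x, channel, z]` (row-major
#' in the y/x plane, origin top-left, 1-based as usual in R). Intensities are
#' non-negative reals regardless of on-disk bit depth; the in-plane pixel
#' size is assumed isotropic and is carried in micrometres per pixel.
#'
#' @param pixels numeric array: a `[y, x]` matrix, a `[y, x, channel]` array,
#'   or a `[y, x, channel, z]` array. All values must be >= 0.
#' @param pixel_size_um in-plane physical pixel size, um/pixel (> 0).
#' @param channel_labels character vector of unique channel names, one per
#'   channel (e.g. `c("ARL13B", "DAPI")`).
#' @param source_id provenance string (file path or simulator id).
#' @return An object of class `ImageStack`.
#' @examples
#' img <- array(runif(32 * 32 * 2), dim = c(32, 32, 2))
#' stk <- image_stack(img, pixel_size_um = 0.1,
#'                    channel_labels = c("ARL13B", "DAPI"))
#' dim(stk$pixels)
#' @export
image_stack <- function(pixels, pixel_size_um, channel_labels,
                        source_id = "<memory>") {
  if (is.matrix(pixels)) dim(pixels) <- c(dim(pixels), 1L, 1L)
  if (length(dim(pixels)) == 3L) dim(pixels) <- c(dim(pixels), 1L)
  if (length(dim(pixels)) != 4L)
    stop("`pixels` must have dimensions [y, x, channel, z]")
  if (any(pixels < 0)) stop("intensities must be non-negative")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      is.na(pixel_size_um) || pixel_size_um <= 0)
    stop("`pixel_size_um` must be a single positive number")
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != dim(pixels)[3L])
    stop("number of channel labels (", length(channel_labels),
         ") does not match channel extent (", dim(pixels)[3L], ")")
  if (anyDuplicated(channel_labels))
    stop("channel labels must be unique")
  structure(
    list(pixels = pixels, pixel_size_um = pixel_size_um,
         channel_labels = channel_labels, source_id = source_id),
    class = "ImageStack")
}

#' @export
print.ImageStack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("ImageStack %dx%d px, %d channel(s) [%s], %d z-plane(s), %.4g um/px\n",
              d[1], d[2], d[3], paste(x$channel_labels, collapse = ", "),
              d[4], x$pixel_size_um))
  invisible(x)
}

#' Channel role mapping
#'
#' Names which channel of a stack carries the cilium marker and which the
#' nuclear stain.
#'
#' @param cilia_channel channel label of the cilium marker (e.g. "ARL13B").
#' @param nuclei_channel channel label of the nuclear stain (e.g. "DAPI").
#' @return A `channel_map` list.
#' @export
channel_map <- function(cilia_channel = "ARL13B", nuclei_channel = "DAPI") {
  cilia_channel <- as.character(cilia_channel)
  nuclei_channel <- as.character(nuclei_channel)
  if (identical(cilia_channel, nuclei_channel))
    stop("cilia and nuclei channels must be distinct")
  structure(list(cilia_channel = cilia_channel,
                 nuclei_channel = nuclei_channel),
            class = "channel_map")
}

# ---- minimal OME-XML for the ImageDescription tag -------------------------

ome_xml_build <- function(ny, nx, n_channels, nz, pixel_size_um,
                          channel_labels, name = "cilimetry") {
  channels <- paste0(
    sprintf('<Channel ID="Channel:0:%d" Name="%s" SamplesPerPixel="1"/>',
            seq_len(n_channels) - 1L, channel_labels),
    collapse = "")
  sprintf(paste0(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<OME xmlns="http://www.openmicroscopy.org/Schemas/OME/2016-06">',
    '<Image ID="Image:0" Name="%s">',
    '<Pixels ID="Pixels:0" DimensionOrder="XYCZT" Type="uint16"',
    ' SizeX="%d" SizeY="%d" SizeC="%d" SizeZ="%d" SizeT="1"',
    ' PhysicalSizeX="%.10g" PhysicalSizeY="%.10g"',
    ' PhysicalSizeXUnit="µm" PhysicalSizeYUnit="µm">',
    '%s<TiffData/></Pixels></Image></OME>'),
    name, nx, ny, n_channels, nz, pixel_size_um, pixel_size_um, channels)
}

# Parse the OME bits we use from an ImageDescription string. Returns NULL if
# the string is not OME-XML.
ome_xml_parse <- function(desc) {
  if (is.null(desc) || !nzchar(desc) || !grepl("<OME", desc, fixed = TRUE))
    return(NULL)
  doc <- tryCatch(xml2::read_xml(desc), error = function(e) NULL)
  if (is.null(doc)) return(NULL)
  xml2::xml_ns_strip(doc)
  px <- xml2::xml_find_first(doc, ".//Pixels")
  if (inherits(px, "xml_missing")) return(NULL)
  num_attr <- function(node, a) {
    v <- xml2::xml_attr(node, a)
    if (is.na(v)) NA_real_ else as.numeric(v)
  }
  int_attr <- function(node, a) {
    v <- num_attr(node, a)
    if (is.na(v)) NA_integer_ else as.integer(v)
  }
  ch <- xml2::xml_find_all(doc, ".//Channel")
  list(
    size_x = int_attr(px, "SizeX"), size_y = int_attr(px, "SizeY"),
    size_c = int_attr(px, "SizeC"), size_z = int_attr(px, "SizeZ"),
    dimension_order = xml2::xml_attr(px, "DimensionOrder"),
    physical_size_x = num_attr(px, "PhysicalSizeX"),
    physical_size_y = num_attr(px, "PhysicalSizeY"),
    channel_names = if (length(ch)) xml2::xml_attr(ch, "Name") else character())
}

# ---- TIFF ImageDescription patcher ----------------------------------------
# tiff::writeTIFF cannot emit custom tags, so the OME-XML block is spliced
# into the file afterwards: a copy of the first IFD with an added tag 270
# (ImageDescription, ASCII) is appended at the end of the file and the
# header's first-IFD pointer is redirected to it. Nothing else moves, so all
# existing value offsets stay valid.
tiff_set_description <- function(path, desc) {
  raw <- readBin(path, "raw", file.info(path)$size)
  le <- identical(rawToChar(raw[1:2]), "II")
  if (!le && !identical(rawToChar(raw[1:2]), "MM"))
    stop("not a TIFF file: ", path)
  r_u16 <- function(off) { # off is 0-based
    b <- as.integer(raw[off + (1:2)])
    if (le) b[1] + 256 * b[2] else b[2] + 256 * b[1]
  }
  r_u32 <- function(off) {
    b <- as.integer(raw[off + (1:4)])
    if (!le) b <- rev(b)
    b[1] + 256 * (b[2] + 256 * (b[3] + 256 * b[4]))
  }
  w_u16 <- function(v) {
    b <- as.raw(c(v %% 256, v %/% 256 %% 256))
    if (le) b else rev(b)
  }
  w_u32 <- function(v) {
    b <- as.raw(c(v %% 256, v %/% 256 %% 256, v %/% 65536 %% 256,
                  v %/% 16777216 %% 256))
    if (le) b else rev(b)
  }
  ifd_off <- r_u32(4)
  n_entries <- r_u16(ifd_off)
  entries <- lapply(seq_len(n_entries) - 1L, function(i) {
    off <- ifd_off + 2 + 12 * i
    list(tag = r_u16(off), bytes = raw[off + (1:12)])
  })
  next_ifd <- r_u32(ifd_off + 2 + 12 * n_entries)
  if (any(vapply(entries, `[[`, 0, "tag") == 270L))
    entries <- entries[vapply(entries, `[[`, 0, "tag") != 270L]
  desc_raw <- c(charToRaw(enc2utf8(desc)), as.raw(0L))
  desc_count <- length(desc_raw)          # includes the single trailing NUL
  if (desc_count %% 2L == 1L) desc_raw <- c(desc_raw, as.raw(0L))  # pad only
  out <- raw
  if (length(out) %% 2L == 1L) out <- c(out, as.raw(0L))
  desc_off <- length(out)
  out <- c(out, desc_raw)
  new_entry <- c(w_u16(270L), w_u16(2L), w_u32(desc_count),
                 w_u32(desc_off))
  entries <- c(entries, list(list(tag = 270L, bytes = new_entry)))
  entries <- entries[order(vapply(entries, `[[`, 0, "tag"))]
  new_ifd_off <- length(out)
  ifd <- c(w_u16(length(entries)),
           unlist(lapply(entries, `[[`, "bytes")),
           w_u32(next_ifd))
  out <- c(out, ifd)
  out[4 + (1:4)] <- w_u32(new_ifd_off)
  writeBin(out, path)
  invisible(path)
}

# ---- read / write ---------------------------------------------------------

#' Read a TIFF/OME-TIFF micrograph
#'
#' Reads a multi-channel, optionally z-stacked TIFF into an [image_stack()].
#' When the file carries an OME-XML `ImageDescription` block, the channel/z
#' layout (`SizeC`, `SizeZ`, `DimensionOrder`), channel names and physical
#' pixel size are taken from it; otherwise every plane in the file is treated
#' as one channel of a single z-plane. `pixel_size_override`, when given,
#' always wins over metadata; with neither, reading fails. Anisotropic
#' metadata (`PhysicalSizeX != PhysicalSizeY`) is rejected rather than
#' averaged, because all downstream length measures assume one scale.
#'
#' Intensities are returned as integer digital numbers on the original bit
#' depth scale (a 16-bit file yields values in 0..65535).
#'
#' @param path TIFF/OME-TIFF file path.
#' @param channels a [channel_map()]; both labels must name channels of the
#'   file (OME channel names when present, else `"C1"`, `"C2"`, ... in file
#'   order, and numeric strings like `"1"` are accepted as indices).
#' @param pixel_size_override optional pixel size in um/pixel; overrides any
#'   metadata value.
#' @return An [image_stack()].
#' @examples
#' \donttest{
#' stk0 <- render_field(simulation_config(seed = 1))$stack
#' f <- tempfile(fileext = ".ome.tiff")
#' write_image(stk0, f)
#' stk <- read_image(f, channel_map("ARL13B", "DAPI"))
#' stk$pixel_size_um
#' }
#' @export
read_image <- function(path, channels = channel_map(),
                       pixel_size_override = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  planes <- tiff::readTIFF(path, all = TRUE, info = TRUE, as.is = TRUE)
  if (!is.list(planes)) planes <- list(planes)
  # flatten multi-sample planes (e.g. RGB) into one plane per sample
  planes <- unlist(lapply(planes, function(p) {
    if (length(dim(p)) == 3L)
      lapply(seq_len(dim(p)[3L]), function(s) {
        q <- p[, , s]
        attributes(q)[c("description")] <- attributes(p)[c("description")]
        q
      })
    else list(p)
  }), recursive = FALSE)
  desc <- attr(planes[[1L]], "description")
  ome <- ome_xml_parse(desc)

  n_planes <- length(planes)
  if (!is.null(ome) && !is.na(ome$size_c) && !is.na(ome$size_z)) {
    nc <- ome$size_c
    nz <- ome$size_z
    if (nc * nz != n_planes)
      stop("OME metadata declares ", nc * nz, " planes but file has ",
           n_planes)
    dimord <- if (is.na(ome$dimension_order)) "XYCZT" else ome$dimension_order
    plane_index <- function(c, z) {
      if (grepl("^XYZC", dimord)) (c - 1L) * nz + z else (z - 1L) * nc + c
    }
    labels <- ome$channel_names
    if (length(labels) != nc || anyDuplicated(labels) || any(is.na(labels)))
      labels <- paste0("C", seq_len(nc))
  } else {
    nc <- n_planes
    nz <- 1L
    plane_index <- function(c, z) c
    labels <- paste0("C", seq_len(nc))
  }

  pixel_size <- NULL
  if (!is.null(pixel_size_override)) {
    pixel_size <- pixel_size_override
  } else if (!is.null(ome) && !is.na(ome$physical_size_x)) {
    if (!is.na(ome$physical_size_y) &&
        abs(ome$physical_size_y - ome$physical_size_x) >
          1e-6 * ome$physical_size_x)
      stop("anisotropic pixel size in metadata (PhysicalSizeX = ",
           ome$physical_size_x, ", PhysicalSizeY = ", ome$physical_size_y,
           "); supply `pixel_size_override` only if this is intentional")
    pixel_size <- ome$physical_size_x
  }
  if (is.null(pixel_size))
    stop("no pixel size in metadata and no `pixel_size_override` given: ",
         path)

  ny <- nrow(planes[[1L]])
  nx <- ncol(planes[[1L]])
  px <- array(0, dim = c(ny, nx, nc, nz))
  for (z in seq_len(nz))
    for (c in seq_len(nc))
      px[, , c, z] <- planes[[plane_index(c, z)]]
  # readTIFF(as.is = TRUE) returns integer DNs already; guard against any
  # float rounding
  px <- round(px)

  stk <- image_stack(px, pixel_size, labels, source_id = path)
  # validate the channel map against the file
  resolve_channel(stk, channels$cilia_channel)
  resolve_channel(stk, channels$nuclei_channel)
  stk
}

# Resolve a channel given by label or numeric index to its index; errors if
# absent.
resolve_channel <- function(stack, channel) {
  if (is.numeric(channel) ||
      (is.character(channel) && grepl("^[0-9]+$", channel))) {
    i <- as.integer(channel)
    if (i < 1L || i > length(stack$channel_labels))
      stop("channel index ", i, " out of range (stack has ",
           length(stack$channel_labels), " channels)")
    return(i)
  }
  i <- match(channel, stack$channel_labels)
  if (is.na(i))
    stop("channel '", channel, "' not found; stack has: ",
         paste(stack$channel_labels, collapse = ", "))
  i
}

#' Write an image stack as OME-TIFF
#'
#' Writes the stack as a multi-page 16-bit TIFF (plane order `XYCZT`: channel
#' varies fastest) with an OME-XML `ImageDescription` block carrying the
#' dimensions, channel names and `PhysicalSizeX`/`PhysicalSizeY` in um.
#' Intensities are clamped to `[0, 65535]` and rounded; a write-then-read
#' round trip is therefore bit-exact for integer-valued stacks, which is what
#' the simulator produces.
#'
#' @param stack an [image_stack()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_image <- function(stack, path) {
  stopifnot(inherits(stack, "ImageStack"))
  d <- dim(stack$pixels)
  planes <- vector("list", d[3L] * d[4L])
  i <- 0L
  for (z in seq_len(d[4L]))
    for (c in seq_len(d[3L])) {
      i <- i + 1L
      planes[[i]] <- pmin(pmax(round(stack$pixels[, , c, z]), 0), 65535) / 65535
    }
  tiff::writeTIFF(planes, path, bits.per.sample = 16L, compression = "none")
  tiff_set_description(
    path,
    ome_xml_build(d[1L], d[2L], d[3L], d[4L], stack$pixel_size_um,
                  stack$channel_labels,
                  name = basename(path)))
  invisible(path)
}

#' Maximum-intensity projection
#'
#' Collapses the z-extent of one channel by taking the per-pixel maximum over
#' z, the standard way a z-stack is reduced to a single 2-D working image
#' before intensity-based segmentation. A single-plane stack is returned
#' unchanged.
#'
#' @param stack an [image_stack()].
#' @param channel channel label or index.
#' @return A numeric `[y, x]` matrix.
#' @examples
#' px <- array(c(1, 5, 3, 2), dim = c(1, 1, 1, 4))
#' stk <- image_stack(px, 0.1, "ARL13B")
#' max_intensity_projection(stk, "ARL13B")  # 5
#' @export
max_intensity_projection <- function(stack, channel) {
  stopifnot(inherits(stack, "ImageStack"))
  i <- resolve_channel(stack, channel)
  ch <- stack$pixels[, , i, , drop = FALSE]
  d <- dim(stack$pixels)
  out <- apply(array(ch, dim = c(d[1L], d[2L], d[4L])), c(1L, 2L), max)
  matrix(out, d[1L], d[2L])
}
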