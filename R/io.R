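# Frame-stack I/O: minimal baseline TIFF (multi-page, uncompressed,
# grayscale float32 out; float/uint gray or RGB in) plus JSON sidecars.
# No TIFF package is available in the target library set, so the small
# subset of the format the pipeline needs is read and written directly.

tiff_types <- c(BYTE = 1L, SHORT = 3L, LONG = 4L)

#' Write a multi-page grayscale TIFF
#'
#' Writes one 32-bit float (little-endian, uncompressed, single-strip) page
#' per frame. This is the on-disk format for per-angle frame stacks: one
#' file per angle, pages in frame order.
#'
#' @param frames A matrix, a list of matrices, or an `N x M x F` array.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tiff <- function(frames, path) {
  if (is.matrix(frames)) frames <- list(frames)
  if (is.array(frames) && length(dim(frames)) == 3)
    frames <- lapply(seq_len(dim(frames)[3]),
                     function(k) frames[, , k])
  n_pages <- length(frames)
  con <- file(path, "wb")
  on.exit(close(con))
  w <- function(x, size) writeBin(x, con, size = size, endian = "little")

  tag <- function(id, type, count, value) {
    w(as.integer(id), 2); w(tiff_types[[type]], 2); w(as.integer(count), 4)
    w(as.integer(value), 4)
  }
  # layout: 8-byte header, then per page [pixel data][IFD]
  n_tags <- 10L
  ifd_size <- 2 + n_tags * 12 + 4
  offsets <- vector("list", n_pages)
  pos <- 8
  for (k in seq_len(n_pages)) {
    nbytes <- length(frames[[k]]) * 4
    offsets[[k]] <- list(data = pos, ifd = pos + nbytes)
    pos <- pos + nbytes + ifd_size
  }
  writeChar("II", con, eos = NULL); w(42L, 2)
  w(as.integer(offsets[[1]]$ifd), 4)
  for (k in seq_len(n_pages)) {
    m <- frames[[k]]
    w(as.numeric(t(m)), 4)                       # row-major float32
    w(n_tags, 2)
    tag(256, "LONG", 1, ncol(m))                 # ImageWidth
    tag(257, "LONG", 1, nrow(m))                 # ImageLength
    tag(258, "SHORT", 1, 32L)                    # BitsPerSample
    tag(259, "SHORT", 1, 1L)                     # Compression: none
    tag(262, "SHORT", 1, 1L)                     # Photometric: BlackIsZero
    tag(273, "LONG", 1, offsets[[k]]$data)       # StripOffsets
    tag(277, "SHORT", 1, 1L)                     # SamplesPerPixel
    tag(278, "LONG", 1, nrow(m))                 # RowsPerStrip
    tag(279, "LONG", 1, length(m) * 4)           # StripByteCounts
    tag(339, "SHORT", 1, 3L)                     # SampleFormat: IEEE float
    w(if (k < n_pages) as.integer(offsets[[k + 1]]$ifd) else 0L, 4)
  }
  invisible(path)
}

#' Read a (simple) multi-page TIFF
#'
#' Reads uncompressed striped TIFFs: grayscale 8/16-bit unsigned or 32-bit
#' float, and 8-bit RGB (converted to grayscale luma with a note, since the
#' downstream keypoint detector requires grayscale input). Both byte orders
#' are handled.
#'
#' @param path File path.
#' @return List of numeric matrices, one per page.
#' @export
read_tiff <- function(path) {
  raw_all <- readBin(path, "raw", file.size(path))
  if (length(raw_all) < 8) stop(sprintf("not a TIFF file: %s", path))
  order_tag <- rawToChar(raw_all[1:2])
  endian <- if (order_tag == "II") "little" else if (order_tag == "MM")
    "big" else stop(sprintf("not a TIFF file: %s", path))
  rd <- function(off, what, n, size, signed = TRUE)
    readBin(raw_all[(off + 1):(off + n * size)], what, n = n, size = size,
            endian = endian, signed = signed)
  if (rd(2, "integer", 1, 2) != 42)
    stop(sprintf("not a TIFF file: %s", path))

  read_value <- function(off, type, count) {
    size <- c(1, 1, 2, 4)[type]
    if (is.na(size)) return(NULL)
    total <- size * count
    voff <- if (total <= 4) off else rd(off, "integer", 1, 4)
    if (type == 3) rd(voff, "integer", count, 2, signed = FALSE)
    else if (type == 4) rd(voff, "integer", count, 4)
    else as.integer(rd(voff, "integer", count, 1, signed = FALSE))
  }

  pages <- list()
  ifd_off <- rd(4, "integer", 1, 4)
  page <- 0L
  while (ifd_off != 0) {
    page <- page + 1L
    n_tags <- rd(ifd_off, "integer", 1, 2)
    tags <- list()
    for (t in seq_len(n_tags)) {
      base <- ifd_off + 2 + (t - 1) * 12
      id <- rd(base, "integer", 1, 2, signed = FALSE)
      type <- rd(base + 2, "integer", 1, 2)
      count <- rd(base + 4, "integer", 1, 4)
      tags[[as.character(id)]] <- read_value(base + 8, type, count)
    }
    g <- function(id, default = NULL) {
      v <- tags[[as.character(id)]]
      if (is.null(v)) default else v
    }
    width <- g(256); height <- g(257)
    bits <- g(258, 1L)[1]; comp <- g(259, 1L); spp <- g(277, 1L)
    fmt <- g(339, 1L)[1]
    strip_off <- g(273); strip_cnt <- g(279)
    if (is.null(width) || is.null(height) || is.null(strip_off))
      stop(sprintf("malformed TIFF page %d in %s", page, path))
    if (comp != 1)
      stop(sprintf("page %d of %s is compressed; only uncompressed TIFF is supported",
                   page, path))
    bytes <- raw(0)
    for (sidx in seq_along(strip_off))
      bytes <- c(bytes, raw_all[(strip_off[sidx] + 1):
                                  (strip_off[sidx] + strip_cnt[sidx])])
    npx <- width * height * spp
    vals <- if (fmt == 3 && bits == 32) {
      readBin(bytes, "numeric", n = npx, size = 4, endian = endian)
    } else if (bits == 8) {
      as.numeric(readBin(bytes, "integer", n = npx, size = 1,
                         endian = endian, signed = FALSE))
    } else if (bits == 16) {
      as.numeric(readBin(bytes, "integer", n = npx, size = 2,
                         endian = endian, signed = FALSE))
    } else {
      stop(sprintf("page %d of %s: unsupported sample format (%d bits)",
                   page, path, bits))
    }
    m <- if (spp == 1) {
      matrix(vals, height, width, byrow = TRUE)
    } else if (spp == 3) {
      message(sprintf("page %d of %s is RGB; converting to grayscale",
                      page, path))
      a <- aperm(array(vals, dim = c(3, width, height)), c(3, 2, 1))
      0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3]
    } else {
      stop(sprintf("page %d of %s: unsupported samples per pixel (%d)",
                   page, path, spp))
    }
    pages[[page]] <- m
    ifd_off <- rd(ifd_off + 2 + n_tags * 12, "integer", 1, 4)
  }
  pages
}

#' Write a per-angle frame stack with its sidecar
#'
#' Writes the frames as a multi-page float TIFF and a JSON sidecar
#' (`<path>.json`) recording the angle index and any extra metadata.
#'
#' @param frames Matrix list or `N x M x F` array.
#' @param path Output TIFF path.
#' @param angle_index Integer angle index stored in the sidecar.
#' @param meta Optional named list merged into the sidecar.
#' @return `path`, invisibly.
#' @export
write_stack <- function(frames, path, angle_index = NA_integer_,
                        meta = list()) {
  write_tiff(frames, path)
  sidecar <- c(list(angle_index = angle_index,
                    package = "tomogate",
                    version = as.character(utils::packageVersion("tomogate"))),
               meta)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a per-angle frame stack
#'
#' Reads a multi-page TIFF into a frame array; the angle index is taken
#' from the JSON sidecar when present, otherwise parsed from a trailing
#' number in the file name.
#'
#' @param path TIFF path.
#' @return List with `frames` (`N x M x F` array) and `angle_index`.
#' @export
read_stack <- function(path) {
  pages <- read_tiff(path)
  dims <- vapply(pages, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop(sprintf("pages of %s have inconsistent shapes", path))
  frames <- array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
  angle_index <- NA_integer_
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    sc <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(sc$angle_index)) angle_index <- as.integer(sc$angle_index)
  } else {
    m <- regmatches(basename(path),
                    regexpr("[0-9]+(?=\\.[A-Za-z]+$)", basename(path),
                            perl = TRUE))
    if (length(m)) angle_index <- as.integer(m)
  }
  list(frames = frames, angle_index = angle_index)
}

#' Write an acquisition (all angles) to a directory
#'
#' One multi-page TIFF per angle (`angle_###.tif`) plus an
#' `acquisition.json` sidecar with the geometry and ground-truth stage
#' labels.
#'
#' @param acq Result of [make_breathing_phantom()].
#' @param dir Output directory (created if needed).
#' @param seed Seed recorded in the sidecar.
#' @return `dir`, invisibly.
#' @export
write_acquisition <- function(acq, dir, seed = NA_integer_) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (a in seq_along(acq$stacks))
    write_stack(acq$stacks[[a]],
                file.path(dir, sprintf("angle_%03d.tif", a)),
                angle_index = a)
  g <- acq$geometry
  jsonlite::write_json(
    list(n_angles = g$n_angles, angle_step = g$angle_step,
         frames_per_angle = g$frames_per_angle, R1 = g$R1, R2 = g$R2,
         wavelength = g$wavelength, pixel_pitch = g$pixel_pitch,
         labels = acq$truth$labels, seed = seed),
    file.path(dir, "acquisition.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read an acquisition directory written by [write_acquisition()]
#' @param dir Directory containing `angle_###.tif` files.
#' @return List with `stacks`, `angles` and `geometry`.
#' @export
read_acquisition <- function(dir) {
  files <- sort(list.files(dir, pattern = "^angle_[0-9]+\\.tif$",
                           full.names = TRUE))
  if (!length(files)) stop(sprintf("no angle_###.tif files in %s", dir))
  stacks <- lapply(files, function(f) read_stack(f)$frames)
  meta <- jsonlite::read_json(file.path(dir, "acquisition.json"),
                              simplifyVector = TRUE)
  geometry <- acquisition_geometry(
    R1 = meta$R1, R2 = meta$R2, wavelength = meta$wavelength,
    pixel_pitch = meta$pixel_pitch, n_angles = meta$n_angles,
    angle_step = meta$angle_step, frames_per_angle = meta$frames_per_angle)
  list(stacks = stacks, angles = geometry_angles(geometry),
       geometry = geometry)
}
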