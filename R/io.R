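# File IO: minimal baseline TIFF 6.0 codec (uncompressed grayscale, 8/16-bit,
# multi-page, ImageJ description tag) plus JSON sidecar metadata.  Written
# from scratch because no TIFF package is available in the target library;
# the reader handles single- and multi-strip uncompressed grayscale pages in
# either byte order, which covers ImageJ-style stacks.

rd_int <- function(raw, offset, n, size, endian) {
  # sizes 1-2 read unsigned; size 4 must be read signed (R has no uint32,
  # and TIFF offsets here stay far below 2^31)
  readBin(raw[(offset + 1):(offset + n * size)], "integer", n = n,
          size = size, signed = size > 2, endian = endian)
}

wr_u16 <- function(con, x) writeBin(as.integer(x), con, size = 2,
                                    endian = "little")
wr_u32 <- function(con, x) writeBin(as.integer(x), con, size = 4,
                                    endian = "little")

# one 12-byte IFD entry; `value` already packed for the 4-byte field
wr_entry <- function(con, tag, type, count, value, short_value = FALSE) {
  wr_u16(con, tag); wr_u16(con, type); wr_u32(con, count)
  if (short_value) { wr_u16(con, value); wr_u16(con, 0L) } else wr_u32(con, value)
}

#' Write an image stack as a multi-page TIFF
#'
#' Uncompressed grayscale baseline TIFF, little-endian, one strip per page,
#' with an ImageJ-compatible description tag.  Values are clipped to the
#' selected bit depth.
#'
#' @param frames numeric array (ny, nx, nt) or a matrix (single page).
#' @param path output file.
#' @param bit_depth 8 or 16.
#' @export
write_tiff <- function(frames, path, bit_depth = 16) {
  if (is.matrix(frames)) dim(frames) <- c(dim(frames), 1L)
  stopifnot(length(dim(frames)) == 3, bit_depth %in% c(8, 16))
  ny <- dim(frames)[1]; nx <- dim(frames)[2]; nt <- dim(frames)[3]
  bpp <- bit_depth / 8
  page_bytes <- ny * nx * bpp
  desc <- sprintf("ImageJ=1.53t\nimages=%d\nslices=%d\nloop=false\n", nt, nt)
  desc_raw <- c(charToRaw(desc), as.raw(0))
  n_entries <- c(11L, rep(10L, max(nt - 1L, 0L)))
  ifd_sizes <- 2L + n_entries * 12L + 4L
  data_start <- 8L
  ifd_start <- data_start + nt * page_bytes
  ifd_offsets <- ifd_start + c(0L, cumsum(ifd_sizes))[seq_len(nt)]
  desc_offset <- ifd_start + sum(ifd_sizes)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con); wr_u16(con, 42L); wr_u32(con, ifd_offsets[1])
  top <- 2^bit_depth - 1
  for (k in seq_len(nt)) {
    v <- round(frames[, , k])
    v[v < 0] <- 0; v[v > top] <- top
    v <- as.integer(t(v))            # TIFF stores rows sequentially
    if (bit_depth == 8) {
      writeBin(as.raw(v), con)
    } else {
      v[v > 32767L] <- v[v > 32767L] - 65536L
      writeBin(v, con, size = 2, endian = "little")
    }
  }
  for (k in seq_len(nt)) {
    wr_u16(con, n_entries[k])
    wr_entry(con, 256L, 4L, 1L, nx)
    wr_entry(con, 257L, 4L, 1L, ny)
    wr_entry(con, 258L, 3L, 1L, bit_depth, short_value = TRUE)
    wr_entry(con, 259L, 3L, 1L, 1L, short_value = TRUE)
    wr_entry(con, 262L, 3L, 1L, 1L, short_value = TRUE)
    if (k == 1L) wr_entry(con, 270L, 2L, length(desc_raw), desc_offset)
    wr_entry(con, 273L, 4L, 1L, data_start + (k - 1L) * page_bytes)
    wr_entry(con, 277L, 3L, 1L, 1L, short_value = TRUE)
    wr_entry(con, 278L, 4L, 1L, ny)
    wr_entry(con, 279L, 4L, 1L, page_bytes)
    wr_entry(con, 339L, 3L, 1L, 1L, short_value = TRUE)
    wr_u32(con, if (k < nt) ifd_offsets[k + 1L] else 0L)
  }
  writeBin(desc_raw, con)
  invisible(path)
}

read_ifd_entries <- function(raw, offset, endian) {
  n <- rd_int(raw, offset, 1, 2, endian)
  entries <- list()
  for (i in seq_len(n)) {
    base <- offset + 2 + (i - 1) * 12
    tag <- rd_int(raw, base, 1, 2, endian)
    type <- rd_int(raw, base + 2, 1, 2, endian)
    count <- rd_int(raw, base + 4, 1, 4, endian)
    size <- c(1, 1, 2, 4, 8)[type]
    if (is.na(size)) next
    inline <- count * size <= 4
    voff <- if (inline) base + 8 else rd_int(raw, base + 8, 1, 4, endian)
    value <- switch(as.character(type),
      "3" = rd_int(raw, voff, count, 2, endian),
      "4" = rd_int(raw, voff, count, 4, endian),
      "2" = rawToChar(raw[(voff + 1):(voff + count - 1)]),
      "1" = as.integer(raw[(voff + 1):(voff + count)]),
      NULL)
    entries[[as.character(tag)]] <- value
  }
  nxt <- rd_int(raw, offset + 2 + n * 12, 1, 4, endian)
  list(entries = entries, next_offset = nxt)
}

#' Read a multi-page grayscale TIFF
#'
#' Supports uncompressed 8- or 16-bit grayscale pages (single- or
#' multi-strip) in either byte order.
#'
#' @param path TIFF file.
#' @return numeric array (ny, nx, nt).
#' @export
read_tiff <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  order_tag <- rawToChar(raw[1:2])
  endian <- switch(order_tag, II = "little", MM = "big",
                   stop("not a TIFF file: ", path, call. = FALSE))
  if (rd_int(raw, 2, 1, 2, endian) != 42L)
    stop("not a TIFF file: ", path, call. = FALSE)
  offset <- rd_int(raw, 4, 1, 4, endian)
  # first pass: collect per-page geometry and strip locations
  pages <- list()
  while (offset != 0) {
    ifd <- read_ifd_entries(raw, offset, endian)
    e <- ifd$entries
    comp <- if (is.null(e[["259"]])) 1L else e[["259"]]
    if (comp != 1L)
      stop("unsupported TIFF compression scheme ", comp, call. = FALSE)
    bits <- if (is.null(e[["258"]])) 1L else e[["258"]][1]
    if (!bits %in% c(8, 16))
      stop("unsupported bit depth ", bits, call. = FALSE)
    pages[[length(pages) + 1L]] <- list(nx = e[["256"]], ny = e[["257"]],
                                        bits = bits, offs = e[["273"]],
                                        counts = e[["279"]])
    offset <- ifd$next_offset
  }
  if (!length(pages)) stop("TIFF contains no pages", call. = FALSE)
  ny <- pages[[1]]$ny; nx <- pages[[1]]$nx
  if (!all(vapply(pages, function(p) p$ny == ny && p$nx == nx, logical(1))))
    stop("non-uniform frame shapes in TIFF", call. = FALSE)
  # second pass: decode strips into a preallocated array
  out <- array(0L, dim = c(ny, nx, length(pages)))
  for (k in seq_along(pages)) {
    p <- pages[[k]]
    data <- if (length(p$offs) == 1L) raw[(p$offs + 1):(p$offs + p$counts)]
            else raw[unlist(mapply(function(o, cnt) (o + 1):(o + cnt),
                                   p$offs, p$counts, SIMPLIFY = FALSE))]
    vals <- if (p$bits == 8) as.integer(data)
            else readBin(data, "integer", n = length(data) / 2, size = 2,
                         signed = FALSE, endian = endian)
    out[, , k] <- matrix(vals, nrow = ny, byrow = TRUE)
  }
  out
}

sidecar_path <- function(path) paste0(sub("\\.tiff?$", "", path), ".json")

#' Write a FRAP series to disk (TIFF + JSON sidecar)
#'
#' The sidecar records the physical calibration (`pixel_size`,
#' `frame_interval`), the 0-based `bleach_frame_index`, and, when available,
#' the generating config and ground truth.
#'
#' @param series a [frap_series()].
#' @param path output TIFF path; the sidecar goes to the same name with a
#'   `.json` extension.
#' @param bit_depth 8 or 16.
#' @param truth optional ground-truth record to embed in the sidecar.
#' @return `path`, invisibly.
#' @export
write_stack <- function(series, path, bit_depth = 16, truth = NULL) {
  write_tiff(series$frames, path, bit_depth)
  meta <- list(
    pixel_size = series$pixel_size,
    frame_interval = series$frame_interval,
    bleach_frame_index = series$bleach_frame - 1L,
    n_frames = dim(series$frames)[3],
    bit_depth = bit_depth
  )
  cfg <- series$metadata$config
  if (!is.null(cfg)) meta$config <- unclass(cfg)
  if (!is.null(truth)) meta$ground_truth <- unclass(truth)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a FRAP series from disk
#'
#' Loads a multi-page TIFF and its calibration.  Calibration comes from the
#' JSON sidecar written by [write_stack()] (same name, `.json` extension) or
#' from the explicit arguments, which take precedence.
#'
#' @param path TIFF file.
#' @param pixel_size,frame_interval,bleach_frame_index optional explicit
#'   calibration (um/px, s, 0-based index of the first post-bleach frame).
#' @return a [frap_series()]; frames are numeric regardless of stored depth.
#' @export
read_stack <- function(path, pixel_size = NULL, frame_interval = NULL,
                       bleach_frame_index = NULL) {
  frames <- read_tiff(path)
  meta <- list()
  sc <- sidecar_path(path)
  if (file.exists(sc)) meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  pixel_size <- pixel_size %||% meta$pixel_size
  frame_interval <- frame_interval %||% meta$frame_interval
  bleach_frame_index <- bleach_frame_index %||% meta$bleach_frame_index
  if (is.null(pixel_size) || is.null(frame_interval) ||
      is.null(bleach_frame_index))
    stop("missing calibration for ", path, ": provide a sidecar JSON (",
         sc, ") or pass pixel_size, frame_interval and bleach_frame_index",
         call. = FALSE)
  frap_series(frames * 1.0, pixel_size, frame_interval,
              bleach_frame = as.integer(bleach_frame_index) + 1L,
              metadata = meta[setdiff(names(meta), c(
                "pixel_size", "frame_interval", "bleach_frame_index"))])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- structured outputs ----------------------------------------------------

#' Write a recovery curve as CSV
#' @param curve a `frap_curve`.
#' @param path output CSV.
#' @export
write_curve_csv <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}

#' Write a FRAP result as JSON
#' @param result a `frap_result`.
#' @param path output JSON.
#' @export
write_result_json <- function(result, path) {
  out <- result[c("i_f", "tau_a", "tau_b", "tau_half", "mobile_fraction",
                  "immobile_fraction", "smoothing_window", "tail_frames")]
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

# Region <-> plain-list (JSON) conversion.
region_from_list <- function(x) {
  switch(x$shape,
    disc = roi_disc(unlist(x$center), x$radius),
    rect = roi_rect(unlist(x$xlim), unlist(x$ylim)),
    polygon = roi_polygon(unlist(x$x), unlist(x$y)),
    stop("unknown region shape in ROI file: ", x$shape, call. = FALSE))
}

#' Read a ROI set from a JSON file
#'
#' Expected layout: an object with `bleach`, `reference` and `background`
#' entries, each `{"shape": "disc"|"rect"|"polygon", ...}` with coordinates
#' in um (`center`/`radius`, `xlim`/`ylim`, or `x`/`y`).
#'
#' @param path JSON file.
#' @return a [roi_set()].
#' @export
read_roi_set <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("bleach", "reference", "background"))
    if (is.null(x[[nm]]))
      stop("ROI file must define '", nm, "'", call. = FALSE)
  roi_set(region_from_list(x$bleach), region_from_list(x$reference),
          region_from_list(x$background))
}

#' Write a ROI set to a JSON file
#' @param rois a [roi_set()].
#' @param path output JSON.
#' @export
write_roi_set <- function(rois, path) {
  jsonlite::write_json(lapply(rois, unclass), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

# Run manifest: resolved parameters + software version, written next to every
# CLI output so a run is reproducible from the manifest alone.
write_manifest <- function(dir, command, params) {
  manifest <- list(
    command = command,
    package = "frapkit",
    version = as.character(utils::packageVersion("frapkit")),
    parameters = params
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
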