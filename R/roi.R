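# ImageJ ROI file I/O. The binary .roi format is the RoiDecoder layout:
# big-endian, 64-byte header ("Iout", version, type byte at offset 6,
# bounds as shorts at 8..15, vertex count at 16, stroke color as ARGB at
# 40), followed for polygon-family ROIs by n shorts of x then n shorts of
# y, relative to the bounding box. Only the shapes needed for 2D spheroid
# ground truth are supported: polygon (0), rectangle (1), oval (2),
# freehand (7), traced (8).

ROI_TYPES <- c(polygon = 0L, rect = 1L, oval = 2L, freehand = 7L, traced = 8L)

# class convention of the 5-class ground truth: contour colors map to
# 1 well-separated (red), 2 overlapping-brighter (green),
# 3 overlapping-dimmer (magenta), 4 touching (cyan), 5 border (blue)
ROI_CLASS_COLORS <- c("1" = "#FF0000", "2" = "#00FF00", "3" = "#FF00FF",
                      "4" = "#00FFFF", "5" = "#0000FF")

roi_color_to_class <- function(rgb_hex) {
  m <- match(toupper(rgb_hex), ROI_CLASS_COLORS)
  if (is.na(m)) NA_integer_ else as.integer(names(ROI_CLASS_COLORS)[m])
}

#' Read an ImageJ .roi file
#'
#' Parses the binary region-of-interest format written by ImageJ/FIJI's
#' RoiManager. Polygon, freehand, traced, rectangle and oval ROIs are
#' supported. The stroke color is decoded and translated to the 5-class
#' ground-truth convention (red, green, magenta, cyan, blue = classes
#' 1..5) when it matches.
#'
#' @param path Path to a `.roi` file (or a raw vector).
#' @return List of class `imagej_roi`: `type` (name), `coords` (matrix of
#'   x, y vertex coordinates, 0-based pixel frame), `bounds`
#'   (top, left, bottom, right), `stroke_color` (hex or NA), `gt_class`
#'   (1..5 or NA), `name`.
#' @export
read_imagej_roi <- function(path) {
  raw <- if (is.raw(path)) path else readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 64 || rawToChar(raw[1:4]) != "Iout")
    stop("not an ImageJ ROI file (missing 'Iout' magic)")
  rd_short <- function(off) readBin(raw[(off + 1):(off + 2)], "integer",
                                    size = 2, endian = "big", signed = TRUE)
  type_code <- as.integer(raw[7])
  type <- names(ROI_TYPES)[match(type_code, ROI_TYPES)]
  if (is.na(type))
    stop(sprintf("unsupported ROI type code %d", type_code))
  top <- rd_short(8); left <- rd_short(10)
  bottom <- rd_short(12); right <- rd_short(14)
  n <- rd_short(16)
  stroke <- raw[41:44]  # ARGB
  stroke_hex <- if (all(stroke == as.raw(0))) NA_character_ else
    toupper(sprintf("#%02X%02X%02X", as.integer(stroke[2]),
                    as.integer(stroke[3]), as.integer(stroke[4])))
  coords <- NULL
  if (type %in% c("polygon", "freehand", "traced") && n > 0) {
    body <- readBin(raw[65:(64 + 4 * n)], "integer", n = 2 * n, size = 2,
                    endian = "big", signed = TRUE)
    coords <- cbind(x = body[seq_len(n)] + left, y = body[n + seq_len(n)] + top)
  }
  structure(list(type = type, coords = coords,
                 bounds = c(top = top, left = left, bottom = bottom,
                            right = right),
                 stroke_color = stroke_hex,
                 gt_class = if (is.na(stroke_hex)) NA_integer_ else
                   roi_color_to_class(stroke_hex),
                 name = if (!is.raw(path))
                   sub("\\.roi$", "", basename(path)) else ""),
            class = "imagej_roi")
}

#' Write a polygon ImageJ .roi file
#'
#' Emits the RoiDecoder binary layout for a polygon ROI, with the stroke
#' color carrying the 5-class ground-truth convention. Round-trips with
#' [read_imagej_roi()].
#'
#' @param path Output path.
#' @param coords Matrix/data frame of vertex `x`, `y` (0-based pixels).
#' @param gt_class Ground-truth class 1..5 (sets the stroke color), or
#'   `NULL` for no color.
#' @return Invisibly, `path`.
#' @export
write_imagej_roi <- function(path, coords, gt_class = NULL) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  left <- min(coords[, 1]); top <- min(coords[, 2])
  right <- max(coords[, 1]); bottom <- max(coords[, 2])
  wr_short <- function(v) writeBin(as.integer(v), con, size = 2, endian = "big")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("Iout"), con)
  wr_short(227)                    # version
  writeBin(as.raw(c(0, 0)), con)   # type = polygon (0), unused byte
  wr_short(top); wr_short(left); wr_short(bottom); wr_short(right)
  wr_short(n)
  writeBin(numeric(4), con, size = 4, endian = "big")  # x1,y1,x2,y2 floats
  wr_short(0)                      # stroke width
  writeBin(0L, con, size = 4, endian = "big")  # shape roi size
  if (is.null(gt_class)) writeBin(0L, con, size = 4, endian = "big")
  else {
    col <- grDevices::col2rgb(ROI_CLASS_COLORS[as.character(gt_class)])
    writeBin(as.raw(c(255, col[1], col[2], col[3])), con)
  }
  writeBin(0L, con, size = 4, endian = "big")  # fill color
  wr_short(0); wr_short(0)         # subtype, options
  writeBin(as.raw(c(0, 0)), con)   # arrow style, head size
  wr_short(0)                      # rounded rect arc
  writeBin(0L, con, size = 4, endian = "big")  # position
  writeBin(0L, con, size = 4, endian = "big")  # header2 offset
  wr_short(coords[, 1] - left)
  wr_short(coords[, 2] - top)
  invisible(path)
}

#' Rasterize an ImageJ ROI to a logical mask
#'
#' Polygon-family ROIs are filled with an even-odd scanline rule over
#' pixel centers; rectangles and ovals use their bounding box (right and
#' bottom bounds exclusive, as in ImageJ).
#'
#' @param roi An [read_imagej_roi()] object.
#' @param dim_yx Image dimensions `c(ny, nx)`.
#' @return Logical matrix.
#' @export
roi_to_mask <- function(roi, dim_yx) {
  stopifnot(inherits(roi, "imagej_roi"))
  b <- roi$bounds
  if (roi$type == "rect") {
    m <- matrix(FALSE, dim_yx[1], dim_yx[2])
    ys <- seq(max(1, b["top"] + 1), min(dim_yx[1], b["bottom"]))
    xs <- seq(max(1, b["left"] + 1), min(dim_yx[2], b["right"]))
    m[ys, xs] <- TRUE
    return(m)
  }
  if (roi$type == "oval") {
    return(rasterize_ellipse(dim_yx,
                             xc = (b["left"] + b["right"] - 1) / 2,
                             yc = (b["top"] + b["bottom"] - 1) / 2,
                             a = (b["right"] - b["left"]) / 2,
                             b = (b["bottom"] - b["top"]) / 2))
  }
  fill_polygon(roi$coords, dim_yx)
}

# Even-odd scanline fill over 0-based pixel centers.
fill_polygon <- function(coords, dim_yx) {
  m <- matrix(FALSE, dim_yx[1], dim_yx[2])
  xs <- coords[, 1]; ys <- coords[, 2]
  n <- length(xs)
  j <- c(n, seq_len(n - 1))
  for (row in seq_len(dim_yx[1])) {
    y <- row - 1 + 1e-9  # nudge off integer vertices
    cross <- ((ys <= y) & (ys[j] > y)) | ((ys[j] <= y) & (ys > y))
    if (!any(cross)) next
    cx <- sort(xs[cross] + (y - ys[cross]) * (xs[j][cross] - xs[cross]) /
                 (ys[j][cross] - ys[cross]))
    for (k in seq(1, length(cx) - 1, by = 2)) {
      x1 <- ceiling(cx[k] - 1e-9); x2 <- floor(cx[k + 1] + 1e-9)
      if (x2 >= x1) {
        c1 <- max(1, x1 + 1); c2 <- min(dim_yx[2], x2 + 1)
        if (c2 >= c1) m[row, c1:c2] <- TRUE
      }
    }
  }
  m
}

#' Read a RoiManager .zip archive of ROIs
#'
#' @param path Path to a `.zip` produced by ImageJ's RoiManager (or by
#'   [write_roi_zip()]).
#' @return List of `imagej_roi` objects, named by entry.
#' @export
read_roi_zip <- function(path) {
  exdir <- tempfile("roizip")
  files <- utils::unzip(path, exdir = exdir)
  on.exit(unlink(exdir, recursive = TRUE))
  rois <- lapply(sort(files[grepl("\\.roi$", files)]), read_imagej_roi)
  stats::setNames(rois, vapply(rois, `[[`, "", "name"))
}

#' Ground-truth label image and classes from a ROI archive
#'
#' Rasterizes every ROI in an archive into one label image (later ROIs
#' overwrite earlier ones on overlap, as when painting contours in order)
#' and collects the 5-class annotations from the contour colors.
#'
#' @param path `.zip` archive path.
#' @param dim_yx Image dimensions `c(ny, nx)`.
#' @return List: `labels` (integer matrix), `classes` (tibble `label`,
#'   `gt_class`, `name`).
#' @export
read_ground_truth <- function(path, dim_yx) {
  rois <- read_roi_zip(path)
  labels <- matrix(0L, dim_yx[1], dim_yx[2])
  cls <- integer(length(rois))
  for (i in seq_along(rois)) {
    labels[roi_to_mask(rois[[i]], dim_yx)] <- i
    cls[i] <- rois[[i]]$gt_class
  }
  list(labels = labels,
       classes = tibble::tibble(label = seq_along(rois), gt_class = cls,
                                name = names(rois)))
}

# --- minimal store-only ZIP writer -----------------------------------------
# RoiManager archives are plain ZIPs; entries are written uncompressed
# (method 0) with a table-driven CRC-32, which R's internal unzip reads.

crc32_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      t <- integer(256)
      for (i in 0:255) {
        c <- i
        for (k in 1:8)
          c <- if (bitwAnd(c, 1L) == 1L)
            bitwXor(-306674912L, bitwShiftR(bitwAnd(c, -2L), 1)) else
              bitwShiftR(bitwAnd(c, -2L), 1)
        t[i + 1] <- c
      }
      tab <<- t
    }
    tab
  }
})

crc32 <- function(bytes) {
  tab <- crc32_table()
  crc <- -1L
  for (b in as.integer(bytes)) {
    idx <- bitwAnd(bitwXor(crc, b), 255L) + 1L
    crc <- bitwXor(bitwShiftR(bitwAnd(crc, -256L), 8), tab[idx])
  }
  bitwXor(crc, -1L)
}

int_le <- function(v, size) {
  writeBin(as.integer(v), raw(), size = size, endian = "little")
}

#' Write ROIs into a RoiManager-compatible .zip archive
#'
#' Store-only ZIP writer (no external `zip` tool needed); the archive
#' opens in ImageJ's RoiManager and in [read_roi_zip()].
#'
#' @param path Output `.zip` path.
#' @param rois Named list; each element is a list with `coords` (polygon
#'   vertices) and optional `gt_class`.
#' @return Invisibly, `path`.
#' @export
write_roi_zip <- function(path, rois) {
  if (is.null(names(rois)) || any(names(rois) == ""))
    names(rois) <- sprintf("roi-%03d", seq_along(rois))
  entries <- list()
  for (nm in names(rois)) {
    tmp <- tempfile(fileext = ".roi")
    write_imagej_roi(tmp, rois[[nm]]$coords, rois[[nm]]$gt_class)
    entries[[paste0(nm, ".roi")]] <- readBin(tmp, "raw", file.info(tmp)$size)
    unlink(tmp)
  }
  con <- file(path, "wb")
  on.exit(close(con))
  offsets <- integer(length(entries))
  pos <- 0L
  for (i in seq_along(entries)) {
    data <- entries[[i]]
    name <- charToRaw(names(entries)[i])
    crc <- crc32(data)
    header <- c(int_le(67324752L, 4), int_le(20L, 2), int_le(0L, 2),
                int_le(0L, 2), int_le(0L, 2), int_le(0L, 2),
                int_le(crc, 4), int_le(length(data), 4),
                int_le(length(data), 4), int_le(length(name), 2),
                int_le(0L, 2))
    offsets[i] <- pos
    writeBin(c(header, name, data), con)
    pos <- pos + length(header) + length(name) + length(data)
  }
  cd_start <- pos
  cd_size <- 0L
  for (i in seq_along(entries)) {
    data <- entries[[i]]
    name <- charToRaw(names(entries)[i])
    rec <- c(int_le(33639248L, 4), int_le(20L, 2), int_le(20L, 2),
             int_le(0L, 2), int_le(0L, 2), int_le(0L, 2), int_le(0L, 2),
             int_le(crc32(data), 4), int_le(length(data), 4),
             int_le(length(data), 4), int_le(length(name), 2),
             int_le(0L, 2), int_le(0L, 2), int_le(0L, 2), int_le(0L, 2),
             int_le(0L, 4), int_le(offsets[i], 4))
    writeBin(c(rec, name), con)
    cd_size <- cd_size + length(rec) + length(name)
  }
  writeBin(c(int_le(101010256L, 4), int_le(0L, 2), int_le(0L, 2),
             int_le(length(entries), 2), int_le(length(entries), 2),
             int_le(cd_size, 4), int_le(cd_start, 4), int_le(0L, 2)), con)
  invisible(path)
}
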