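#' Raster images
#'
#' A `raster_image` is the raw input unit of the annotation pipeline: an
#' H x W x 3 numeric array of RGB values in `[0, 1]` plus an image id.
#' On disk images are ordinary 8-bit PNG/TIFF/JPEG files; internally all
#' arithmetic is done on `[0, 1]` doubles.
#'
#' @param pixels numeric H x W x 3 array (or H x W matrix, replicated to
#'   three identical channels) with values in `[0, 1]`.
#' @param id character image identifier.
#' @return A `raster_image` object.
#' @export
raster_image <- function(pixels, id = "img") {
  if (is.matrix(pixels)) pixels <- array(rep(pixels, 3L), c(dim(pixels), 3L))
  stopifnot(is.array(pixels), length(dim(pixels)) == 3L, dim(pixels)[3] == 3L)
  if (dim(pixels)[1] < 2L || dim(pixels)[2] < 2L)
    stop("raster_image needs height >= 2 and width >= 2")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 1)
    stop("pixel values must lie in [0, 1]")
  structure(list(id = as.character(id), pixels = pixels),
            class = "raster_image")
}

#' @export
print.raster_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<raster_image '%s': %d x %d px, RGB>\n", x$id, d[1], d[2]))
  invisible(x)
}

#' @export
dim.raster_image <- function(x) dim(x$pixels)[1:2]

#' Load an image from disk
#'
#' Reads a PNG, TIFF or JPEG file into a [raster_image]. Greyscale files are
#' replicated to three channels; an alpha channel, if present, is dropped.
#' The image id is the file name without its extension.
#'
#' @param path path to a decodable PNG/TIFF/JPEG file.
#' @return A [raster_image].
#' @export
load_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image file: ", path)
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e) stop("cannot decode image file: ", path,
                                           " (", conditionMessage(e), ")"))
  px <- EBImage::imageData(img)
  # EBImage stores x (column) as the first index; transpose to row-major H x W
  if (length(dim(px)) == 2L) {
    px <- t(px)
    px <- array(rep(px, 3L), c(dim(px), 3L))
  } else {
    px <- px[, , 1:3, drop = FALSE]
    px <- aperm(px, c(2L, 1L, 3L))
  }
  px[px < 0] <- 0; px[px > 1] <- 1
  raster_image(px, id = sub("\\.[^.]+$", "", basename(path)))
}

#' Write an image to disk
#'
#' @param img a [raster_image].
#' @param path output path; the extension (.png/.tiff/.jpg) selects the codec.
#' @return `path`, invisibly.
#' @export
save_image <- function(img, path) {
  stopifnot(inherits(img, "raster_image"))
  eb <- EBImage::Image(aperm(img$pixels, c(2L, 1L, 3L)), colormode = "Color")
  EBImage::writeImage(eb, path)
  invisible(path)
}

#' Rescale an image
#'
#' Bilinear resampling to a target width and height. Images at the target
#' size are returned unchanged, so rescaling to the native size is the
#' pixel-wise identity.
#'
#' @param img a [raster_image].
#' @param w,h target width and height in pixels, both >= 2.
#' @return A [raster_image] of exactly `h` rows and `w` columns.
#' @export
rescale <- function(img, w, h) {
  stopifnot(inherits(img, "raster_image"))
  if (w < 2 || h < 2) stop("target dimensions must be >= 2")
  d <- dim(img$pixels)
  if (d[1] == h && d[2] == w) return(img)
  eb <- EBImage::Image(aperm(img$pixels, c(2L, 1L, 3L)), colormode = "Color")
  out <- EBImage::resize(eb, w = w, h = h) # bilinear
  px <- aperm(EBImage::imageData(out), c(2L, 1L, 3L))
  px[px < 0] <- 0; px[px > 1] <- 1
  raster_image(px, id = img$id)
}

#' Annotation matrices
#'
#' An `annotation_matrix` maps n image ids to m binary terms. It is stored
#' as an n x m integer matrix of 0/1 with image ids as row names and term
#' names as column names.
#'
#' @param values n x m matrix of 0/1 (numeric or integer).
#' @param image_ids character vector of n unique image ids.
#' @param terms character vector of m term names.
#' @return An `annotation_matrix` object.
#' @export
annotation_matrix <- function(values, image_ids, terms) {
  values <- as.matrix(values)
  if (anyDuplicated(image_ids)) stop("duplicate image ids in annotation matrix")
  if (nrow(values) != length(image_ids) || ncol(values) != length(terms))
    stop("annotation dimensions do not match ids/terms")
  if (!all(values %in% c(0, 1)))
    stop("annotation entries must all be 0 or 1")
  storage.mode(values) <- "integer"
  dimnames(values) <- list(as.character(image_ids), as.character(terms))
  structure(values, class = c("annotation_matrix", "matrix"))
}

#' @export
print.annotation_matrix <- function(x, ...) {
  cat(sprintf("<annotation_matrix: %d images x %d terms, %.1f%% positive>\n",
              nrow(x), ncol(x), 100 * mean(x)))
  invisible(x)
}

#' Read an annotation matrix from TSV
#'
#' The file must be tab-separated with a header row: the first column is
#' `image_id`, the remaining columns are term names, and every cell is 0
#' or 1. Offending cells are reported with their row and column.
#'
#' @param path path to the TSV file.
#' @return An [annotation_matrix].
#' @export
load_annotations <- function(path) {
  if (!file.exists(path)) stop("cannot read annotation file: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2L) stop("annotation TSV needs an image_id column plus terms")
  ids <- df[[1L]]
  vals <- as.matrix(df[, -1L, drop = FALSE])
  bad <- which(!(vals %in% c("0", "1")))
  if (length(bad)) {
    rc <- arrayInd(bad[1L], dim(vals))
    stop(sprintf("non-binary annotation cell '%s' at row %d, column '%s'",
                 vals[bad[1L]], rc[1L], colnames(vals)[rc[2L]]))
  }
  storage.mode(vals) <- "integer"
  annotation_matrix(vals, ids, colnames(vals))
}

#' Write an annotation matrix to TSV
#'
#' @param ann an [annotation_matrix].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_annotations <- function(ann, path) {
  stopifnot(inherits(ann, "annotation_matrix"))
  df <- data.frame(image_id = rownames(ann), unclass(ann),
                   check.names = FALSE, row.names = NULL)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
as.data.frame.annotation_matrix <- function(x, ...) {
  data.frame(image_id = rownames(x), unclass(x),
             check.names = FALSE, row.names = NULL)
}

#' Save / load a bag dataset archive
#'
#' Bags, the term list and the feature provenance (scheme, number of regions,
#' feature parameters, optional standardization statistics) are serialized as
#' a single versioned JSON document, stable across runs and platforms.
#'
#' @param dataset a [bag_dataset].
#' @param path output path (`.json`).
#' @return `path` (for save) or the restored [bag_dataset] (for load).
#' @export
save_bags <- function(dataset, path) {
  stopifnot(inherits(dataset, "bag_dataset"))
  doc <- list(
    format = "milanno-bags", version = 1L,
    terms = dataset$terms,
    meta = dataset$meta,
    annotation = if (is.null(dataset$annotation)) NULL else
      list(image_ids = rownames(dataset$annotation),
           terms = colnames(dataset$annotation),
           values = unclass(dataset$annotation)),
    bags = lapply(dataset$bags, function(b)
      list(image_id = b$image_id, scheme = b$scheme, instances = b$instances))
  )
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_bags
#' @export
load_bags <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = TRUE)
  if (!identical(doc$format, "milanno-bags"))
    stop("not a milanno bag archive: ", path)
  bags <- lapply(seq_len(nrow(doc$bags)), function(i) {
    inst <- doc$bags$instances[[i]]
    bag(as.matrix(inst), image_id = doc$bags$image_id[i],
        scheme = doc$bags$scheme[i])
  })
  ann <- NULL
  if (!is.null(doc$annotation))
    ann <- annotation_matrix(doc$annotation$values,
                             doc$annotation$image_ids, doc$annotation$terms)
  bag_dataset(bags, terms = doc$terms, annotation = ann, meta = doc$meta)
}
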