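#' A labelled stack of grayscale fly image chips
#'
#' Chips are stored as an H x W x n array of intensities in [0,1] (or
#' standardized values), with one metadata row per chip: individual identity,
#' sex, recording day, viewpoint and frame index within the day. Native chips
#' are 181x181, centred, anterior facing up.
#'
#' @param images numeric array H x W x n.
#' @param identity integer vector of fly ids (length n).
#' @param sex character vector, "M" or "F".
#' @param day integer vector of recording days (>= 1).
#' @param viewpoint character vector: dorsal/ventral/lateral/other.
#' @param frame integer frame index within (identity, day).
#' @return object of class \code{chip_stack}.
#' @export
chip_stack <- function(images, identity, sex, day, viewpoint, frame = NULL) {
  stopifnot(is.array(images), length(dim(images)) == 3L)
  n <- dim(images)[3]
  if (is.null(frame)) frame <- stats::ave(seq_len(n), identity, day,
                                          FUN = seq_along)
  meta <- data.frame(identity = as.integer(identity),
                     sex = as.character(sex),
                     day = as.integer(day),
                     viewpoint = as.character(viewpoint),
                     frame = as.integer(frame),
                     stringsAsFactors = FALSE)
  if (nrow(meta) != n) stop("metadata length does not match number of chips")
  if (!all(meta$viewpoint %in% c("dorsal", "ventral", "lateral", "other")))
    stop("viewpoint must be dorsal, ventral, lateral or other")
  if (any(meta$day < 1L)) stop("day must be >= 1")
  structure(list(images = images, meta = meta), class = "chip_stack")
}

#' @export
print.chip_stack <- function(x, ...) {
  d <- dim(x$images)
  cat("<chip_stack> ", d[3], " chips of ", d[1], "x", d[2], "; ",
      length(unique(x$meta$identity)), " individuals, days {",
      paste(sort(unique(x$meta$day)), collapse = ","), "}\n", sep = "")
  invisible(x)
}

#' Number of chips in a stack
#' @param stack a [chip_stack()].
#' @export
n_chips <- function(stack) dim(stack$images)[3]

#' Subset a chip stack by chip index
#' @param stack a [chip_stack()].
#' @param idx integer indices.
#' @return a \code{chip_stack} with the selected chips, other attributes kept.
#' @export
subset_stack <- function(stack, idx) {
  out <- stack
  out$images <- stack$images[, , idx, drop = FALSE]
  out$meta <- stack$meta[idx, , drop = FALSE]
  rownames(out$meta) <- NULL
  out
}

#' Flatten a stack into a model input matrix
#'
#' One chip per row, pixels in column-major order — the layout expected by
#' [forward_network()].
#'
#' @param stack a [chip_stack()].
#' @return n x (H*W) numeric matrix.
#' @export
as_matrix_stack <- function(stack) {
  d <- dim(stack$images)
  t(matrix(stack$images, d[1] * d[2], d[3]))
}

#' Apply a per-chip transform to every chip of a stack
#'
#' @param stack a [chip_stack()].
#' @param f function taking and returning a matrix (e.g. [bottleneck_29()]).
#' @return a transformed \code{chip_stack}.
#' @export
map_chips <- function(stack, f) {
  n <- n_chips(stack)
  first <- f(stack$images[, , 1])
  out <- array(NA_real_, c(nrow(first), ncol(first), n))
  out[, , 1] <- first
  if (n > 1L) for (i in 2:n) out[, , i] <- f(stack$images[, , i])
  res <- stack
  res$images <- out
  res
}

#' Write / read a chip stack as HDF5
#'
#' Datasets: \code{/images} (H x W x n), \code{/identity}, \code{/sex},
#' \code{/day}, \code{/viewpoint}, \code{/frame}, plus per-fly covariates
#' \code{/fly_id}, \code{/fly_sex}, \code{/fly_size} when present.
#'
#' @param stack a [chip_stack()].
#' @param path HDF5 file path.
#' @param overwrite replace an existing file (default FALSE: error).
#' @return \code{path} (write) or the restored \code{chip_stack} (read).
#' @export
write_chips <- function(stack, path, overwrite = FALSE) {
  if (file.exists(path)) {
    if (!overwrite) stop("file exists (use overwrite = TRUE): ", path)
    unlink(path)
  }
  rhdf5::h5createFile(path)
  rhdf5::h5write(stack$images, path, "images")
  rhdf5::h5write(stack$meta$identity, path, "identity")
  rhdf5::h5write(stack$meta$sex, path, "sex")
  rhdf5::h5write(stack$meta$day, path, "day")
  rhdf5::h5write(stack$meta$viewpoint, path, "viewpoint")
  rhdf5::h5write(stack$meta$frame, path, "frame")
  sizes <- attr(stack, "fly_sizes")
  if (!is.null(sizes)) {
    rhdf5::h5write(as.integer(names(sizes)), path, "fly_id")
    rhdf5::h5write(as.numeric(sizes), path, "fly_size")
    sexes <- attr(stack, "fly_sexes")
    if (!is.null(sexes)) rhdf5::h5write(as.character(sexes), path, "fly_sex")
  }
  rhdf5::h5closeAll()
  invisible(path)
}

#' @rdname write_chips
#' @export
read_chips <- function(path) {
  imgs <- rhdf5::h5read(path, "images")
  st <- chip_stack(imgs,
                   identity = as.integer(rhdf5::h5read(path, "identity")),
                   sex = as.character(rhdf5::h5read(path, "sex")),
                   day = as.integer(rhdf5::h5read(path, "day")),
                   viewpoint = as.character(rhdf5::h5read(path, "viewpoint")),
                   frame = as.integer(rhdf5::h5read(path, "frame")))
  contents <- rhdf5::h5ls(path)$name
  if ("fly_size" %in% contents) {
    sizes <- as.numeric(rhdf5::h5read(path, "fly_size"))
    names(sizes) <- as.character(as.integer(rhdf5::h5read(path, "fly_id")))
    attr(st, "fly_sizes") <- sizes
    if ("fly_sex" %in% contents) {
      sexes <- as.character(rhdf5::h5read(path, "fly_sex"))
      names(sexes) <- names(sizes)
      attr(st, "fly_sexes") <- sexes
    }
  }
  rhdf5::h5closeAll()
  st
}

#' Write / read a single chip as an 8-bit grayscale PNG
#'
#' @param chip numeric matrix in [0,1].
#' @param path PNG path.
#' @export
write_chip_png <- function(chip, path) {
  png::writePNG(pmin(pmax(chip, 0), 1), path)
  invisible(path)
}

#' @rdname write_chip_png
#' @export
read_chip_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) x <- x[, , 1]
  x
}
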