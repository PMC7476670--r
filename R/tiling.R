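#' Tumor ratio of a mask window
#'
#' Fraction of pixels flagged as tumor in a square mask window. A window is
#' kept as a tumor patch when this ratio strictly exceeds the configured
#' threshold (default 0.9, i.e. >90% tumor area).
#'
#' @param mask_window square 0/1 matrix.
#' @return fraction in \[0,1\].
#' @export
compute_tumor_ratio <- function(mask_window) {
  if (length(mask_window) == 0) stop("empty mask window")
  d <- dim(mask_window)
  if (is.null(d) || d[1] != d[2]) stop("mask window must be square")
  sum(mask_window != 0) / length(mask_window)
}

#' Tile a slide into labeled tumor patches
#'
#' Applies non-overlapping, axis-aligned tiling to the tumor region of a
#' slide: windows of side `patch_dim` are anchored at multiples of
#' `patch_dim` from the top-left corner of the tumor-mask bounding box
#' (half-open pixel windows, 0-based grid indices, row-major). Only full-size
#' windows inside the slide are considered; a window is selected when its
#' tumor ratio strictly exceeds `min_tumor_ratio`. Selected windows are
#' cropped from the image, resized to `resize_to` by area averaging, and
#' labeled with the slide label (weak label transfer).
#'
#' @param slide a `slide_record` (see [generate_slide()]) or any list with
#'   `image`, `tumor_mask`, `label`, `slide_id`.
#' @param patch_dim window side in pixels.
#' @param min_tumor_ratio selection threshold (strict `>`); default 0.9.
#' @param resize_to output patch side; default 256.
#' @param anchor `"bbox"` (default) anchors the grid at the mask bounding
#'   box; `"slide"` anchors at the slide origin.
#' @return list with `grid` (a `patch_grid`: `slide_id`, `grid_shape`,
#'   `tumor_cells` 0/1 matrix, `origin` in pixels, `patch_dim`) and `patches`
#'   (list of `patch_record`: `slide_id`, `grid_row`, `grid_col`, `pixels`,
#'   `label`, `native_dim`, `tumor_ratio`).
#' @export
tile_slide <- function(slide, patch_dim, min_tumor_ratio = 0.9,
                       resize_to = 256, anchor = c("bbox", "slide")) {
  anchor <- match.arg(anchor)
  mask <- slide$tumor_mask
  img <- slide$image
  H <- nrow(mask); W <- ncol(mask)
  if (patch_dim > H || patch_dim > W)
    stop("patch_dim exceeds slide dimensions")
  if (resize_to > patch_dim)
    stop("resize_to larger than patch_dim: upscaling patches is not supported")

  nz <- which(mask != 0, arr.ind = TRUE)
  if (nrow(nz) == 0) {
    warning("tumor mask is all zero: no patches selected for slide ",
            slide$slide_id)
    grid <- structure(list(slide_id = slide$slide_id, grid_shape = c(0L, 0L),
                           tumor_cells = matrix(0L, 0, 0),
                           origin = c(0L, 0L), patch_dim = patch_dim),
                      class = "patch_grid")
    return(list(grid = grid, patches = list()))
  }
  if (anchor == "bbox") {
    r0 <- min(nz[, 1]); c0 <- min(nz[, 2])
    ext_r <- max(nz[, 1]) - r0 + 1L
    ext_c <- max(nz[, 2]) - c0 + 1L
  } else {
    r0 <- 1L; c0 <- 1L
    ext_r <- H; ext_c <- W
  }
  gh <- as.integer(ceiling(ext_r / patch_dim))
  gw <- as.integer(ceiling(ext_c / patch_dim))
  tumor_cells <- matrix(0L, gh, gw)
  patches <- list()
  for (i in seq_len(gh)) {
    for (j in seq_len(gw)) {
      rs <- r0 + (i - 1L) * patch_dim
      cs <- c0 + (j - 1L) * patch_dim
      if (rs + patch_dim - 1L > H || cs + patch_dim - 1L > W) next
      rr <- rs:(rs + patch_dim - 1L)
      cc <- cs:(cs + patch_dim - 1L)
      ratio <- compute_tumor_ratio(mask[rr, cc])
      if (ratio > min_tumor_ratio) {
        tumor_cells[i, j] <- 1L
        px <- img[rr, cc, , drop = FALSE]
        if (resize_to != patch_dim) px <- resize_area(px, resize_to)
        patches[[length(patches) + 1L]] <- structure(
          list(slide_id = slide$slide_id, grid_row = i - 1L,
               grid_col = j - 1L, pixels = px, label = slide$label,
               native_dim = patch_dim, tumor_ratio = ratio),
          class = "patch_record")
      }
    }
  }
  grid <- structure(list(slide_id = slide$slide_id,
                         grid_shape = c(gh, gw), tumor_cells = tumor_cells,
                         origin = c(r0, c0), patch_dim = patch_dim),
                    class = "patch_grid")
  list(grid = grid, patches = patches)
}

#' Resize a patch by area averaging
#'
#' Downscales an RGB patch to `target` x `target` with exact area averaging
#' (anti-aliased; constant inputs map to the same constant). Upscaling is
#' rejected unless `allow_upscale = TRUE` (then nearest-neighbour-free area
#' weights still apply, amounting to linear interpolation of coverage).
#'
#' @param window n x n x 3 numeric array.
#' @param target output side.
#' @param allow_upscale permit n < target.
#' @return target x target x 3 array.
#' @export
resize_patch <- function(window, target, allow_upscale = FALSE) {
  d <- dim(window)
  stopifnot(length(d) == 3, d[1] == d[2])
  if (d[1] < target && !allow_upscale)
    stop("input smaller than target; set allow_upscale = TRUE to permit")
  if (d[1] == target) return(window)
  resize_area(window, target)
}

#' Collect patch records into a dense patch set
#'
#' Stacks a list of `patch_record`s (possibly from several slides) into the
#' in-memory structure consumed by the training and prediction functions.
#'
#' @param patches list of `patch_record`.
#' @return object of class `patch_set`: list with `pixels` (N x h x w x 3
#'   array), `label` (character POS/NEG), `slide_id`, `grid_row`, `grid_col`,
#'   `tumor_ratio`, `native_dim`.
#' @export
as_patch_set <- function(patches) {
  if (length(patches) == 0) stop("no patches to collect")
  d <- dim(patches[[1]]$pixels)
  px <- array(0, c(length(patches), d))
  for (i in seq_along(patches)) px[i, , , ] <- patches[[i]]$pixels
  structure(list(
    pixels = px,
    label = vapply(patches, `[[`, character(1), "label"),
    slide_id = vapply(patches, `[[`, character(1), "slide_id"),
    grid_row = vapply(patches, function(p) as.integer(p$grid_row), integer(1)),
    grid_col = vapply(patches, function(p) as.integer(p$grid_col), integer(1)),
    tumor_ratio = vapply(patches, `[[`, numeric(1), "tumor_ratio"),
    native_dim = vapply(patches, function(p) as.integer(p$native_dim),
                        integer(1))),
    class = "patch_set")
}

#' @export
print.patch_set <- function(x, ...) {
  cat(sprintf("<patch_set> %d patches (%d POS / %d NEG) from %d slides, %dx%d px\n",
              length(x$label), sum(x$label == "POS"), sum(x$label == "NEG"),
              length(unique(x$slide_id)), dim(x$pixels)[2], dim(x$pixels)[3]))
  invisible(x)
}

# Subset a patch_set by index.
subset_patch_set <- function(ps, idx) {
  structure(list(pixels = ps$pixels[idx, , , , drop = FALSE],
                 label = ps$label[idx], slide_id = ps$slide_id[idx],
                 grid_row = ps$grid_row[idx], grid_col = ps$grid_col[idx],
                 tumor_ratio = ps$tumor_ratio[idx],
                 native_dim = ps$native_dim[idx]),
            class = "patch_set")
}

#' Write patches and an index table to disk
#'
#' Persists patches as PNG files named `slide_id/r_c.png` plus a delimited
#' index table (`patch_index.tsv`) with columns slide_id, grid_row, grid_col,
#' path, label, tumor_ratio, native_dim.
#'
#' @param patches list of `patch_record`.
#' @param out_dir output directory.
#' @return the index data.frame, invisibly written to
#'   `file.path(out_dir, "patch_index.tsv")`.
#' @export
write_patches <- function(patches, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(patches, function(p) {
    sd <- file.path(out_dir, p$slide_id)
    dir.create(sd, showWarnings = FALSE)
    path <- file.path(sd, sprintf("%d_%d.png", p$grid_row, p$grid_col))
    write_image(p$pixels, path)
    data.frame(slide_id = p$slide_id, grid_row = p$grid_row,
               grid_col = p$grid_col, path = path, label = p$label,
               tumor_ratio = p$tumor_ratio, native_dim = p$native_dim,
               stringsAsFactors = FALSE)
  })
  idx <- do.call(rbind, rows)
  utils::write.table(idx, file.path(out_dir, "patch_index.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(idx)
}
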