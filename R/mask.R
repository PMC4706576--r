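#' Mid-sagittal corpus callosum mask
#'
#' Wraps a 2-D binary raster with its physical pixel spacing. The grid is
#' stored row-major with row 1 at the image top (radiological screen
#' convention); physical coordinates place x along image columns (increasing
#' anterior to posterior) and y along flipped rows (increasing ventral to
#' dorsal), with pixel centres at half-spacing offsets.
#'
#' @param grid logical or 0/1 matrix; `TRUE`/nonzero is foreground.
#' @param spacing numeric length-2, physical pixel size in mm as
#'   `c(row_mm, col_mm)`. A single value is recycled to both.
#' @return An object of class `cc_mask`.
#' @examples
#' m <- matrix(FALSE, 20, 90); m[6:15, 6:85] <- TRUE
#' mask <- cc_mask(m, spacing = 1)
#' @export
cc_mask <- function(grid, spacing) {
  if (is.numeric(grid)) grid <- grid != 0
  stopifnot(is.matrix(grid), is.logical(grid))
  if (length(spacing) == 1L) spacing <- c(spacing, spacing)
  if (length(spacing) != 2L || any(!is.finite(spacing)) || any(spacing <= 0))
    cc_stop("bad-spacing", "spacing must be two positive finite values (mm)")
  if (!any(grid)) cc_stop("empty-mask", "mask has no foreground pixels")
  structure(list(grid = grid, spacing = as.numeric(spacing)),
            class = "cc_mask")
}

#' @export
print.cc_mask <- function(x, ...) {
  cat(sprintf("<cc_mask> %d x %d px, spacing %.3g x %.3g mm, %d foreground px\n",
              nrow(x$grid), ncol(x$grid), x$spacing[1L], x$spacing[2L],
              sum(x$grid)))
  invisible(x)
}

#' Read a binary mask from a PNG file
#'
#' Any nonzero pixel (maximum over channels) is foreground. PNG carries no
#' physical calibration, so the pixel spacing must be supplied.
#'
#' @param path PNG file path.
#' @param spacing pixel size in mm, `c(row_mm, col_mm)` or a single value.
#' @return A [cc_mask()].
#' @export
read_mask_png <- function(path, spacing) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- apply(img, c(1L, 2L), max)
  cc_mask(img > 0, spacing)
}

#' Read a binary mask from a single-slice NIfTI file
#'
#' The in-plane pixel dimensions recorded in the NIfTI header provide the
#' spacing. Volumes must contain a single slice (any singleton dimensions
#' are dropped).
#'
#' @param path NIfTI file path (`.nii` or `.nii.gz`).
#' @return A [cc_mask()].
#' @export
read_mask_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  arr <- drop(as.array(img))
  if (length(dim(arr)) != 2L)
    cc_stop("not-a-slice", "NIfTI input must reduce to a single 2-D slice")
  cc_mask(arr != 0, spacing = pd[seq_len(2L)])
}

#' Write a mask to a PNG file
#'
#' @param mask a [cc_mask()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  stopifnot(inherits(mask, "cc_mask"))
  png::writePNG(mask$grid * 1.0, path)
  invisible(path)
}
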