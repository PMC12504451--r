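## Rasterization of a normalized segment into the CNN's input image: a
## square grayscale grid in which time maps to columns and amplitude to
## rows, and each column is filled with the min-max envelope of the samples
## it covers.  Deterministic, backend-free, no axes or anti-aliasing.

#' Rasterize a segment into a grayscale image patch
#'
#' Column `c` (1-based) covers the samples with 0-based index in
#' `[(c-1) * L / width, c * L / width)`.  Amplitude maps linearly to rows
#' with +1 at the top row and -1 at the bottom; a pixel is set to 1
#' whenever its amplitude interval intersects the column's min-max sample
#' envelope, so the trace is a filled vertical run per column.  Negating
#' the input flips the image exactly across the horizontal midline.
#'
#' @param segment numeric vector of samples already normalized to
#'   `[-1, 1]` (see [normalizeAmplitude()]), or a single-segment slot of a
#'   [SegmentSet-class].
#' @param width,height image size in pixels (default 96x96, the model's
#'   input resolution; both >= 8).
#' @param meta optional list stored in the patch (segment offset, record id).
#' @return an [ImagePatch-class] with values in {0, 1}.
#' @examples
#' img <- rasterizeSegment(sin(2 * pi * seq(0, 10, length.out = 1000)))
#' dim(pixels(img))
#' @export
rasterizeSegment <- function(segment, width = 96L, height = 96L,
                             meta = list()) {
  x <- as.numeric(segment)
  if (width < 8L || height < 8L)
    stop_argument("image must be at least 8x8 pixels")
  if (!all(is.finite(x)))
    stop_argument("segment contains non-finite samples")
  if (any(x < -1 | x > 1))
    stop_argument("samples outside [-1, 1]; normalize the signal first (normalizeAmplitude)")
  L <- length(x)
  if (L < 1L) stop_argument("empty segment")
  px <- matrix(0, nrow = height, ncol = width)
  # 0-based sample ranges per column; exhaustive and disjoint
  breaks <- floor((0:width) * L / width)
  for (cc in seq_len(width)) {
    lo <- breaks[cc] + 1L
    hi <- breaks[cc + 1L]
    if (hi < lo) next
    amin <- min(x[lo:hi])
    amax <- max(x[lo:hi])
    # pixel r (1-based) covers amplitudes [1 - 2r/H, 1 - 2(r-1)/H]; fill
    # every pixel whose closed interval meets [amin, amax] -- this closed
    # intersection rule is what makes negation an exact vertical mirror
    r1 <- max(1L, as.integer(ceiling(height * (1 - amax) / 2)))
    r2 <- min(height, as.integer(floor(height * (1 - amin) / 2) + 1L))
    px[r1:r2, cc] <- 1
  }
  new("ImagePatch", pixels = px, meta = meta)
}

#' Write an image patch as an 8-bit grayscale PNG
#'
#' Intensities are inverted on export (trace 1 maps to black 0 on a white
#' background) for conventional viewing; [readImagePatch()] undoes the
#' inversion.
#'
#' @param patch an [ImagePatch-class].
#' @param path output file path (`<record_id>_seg<k>.png` by convention).
#' @return `path`, invisibly.
#' @export
writeImagePatch <- function(patch, path) {
  png::writePNG(1 - patch@pixels, target = path)
  invisible(path)
}

#' Read an image patch from a grayscale PNG written by [writeImagePatch()]
#'
#' @param path PNG file path.
#' @param meta optional metadata list to attach.
#' @return an [ImagePatch-class].
#' @export
readImagePatch <- function(path, meta = list()) {
  if (!file.exists(path)) stop_format("no such image file: %s", path)
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  new("ImagePatch", pixels = 1 - img, meta = meta)
}
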