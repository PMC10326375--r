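#' Read a grayscale TIFF image stack
#'
#' Reads a single- or multi-frame grayscale TIFF into a list of numeric
#' matrices on the original count scale (16-bit data are returned as counts
#' in 0..65535, not the 0..1 scale used by the underlying reader).
#'
#' @param path Path to a TIFF file.
#' @return A list of numeric matrices, one per frame, with attribute
#'   `"path"` recording the source file.
#' @export
read_image_stack <- function(path) {
  if (!file.exists(path)) abort(sprintf("TIFF file not found: %s", path))
  frames <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (is.matrix(frames)) frames <- list(frames)
  frames <- lapply(frames, function(f) {
    if (length(dim(f)) == 3L) f <- f[, , 1L]  # collapse accidental RGB
    storage.mode(f) <- "double"
    f
  })
  attr(frames, "path") <- path
  frames
}

#' Write a grayscale image stack as 16-bit TIFF
#'
#' Values are clamped to the 16-bit range (0..65535) and written as
#' one directory per frame.
#'
#' @param stack A numeric matrix or list/array of frames, in counts.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(stack, path) {
  if (is.matrix(stack)) stack <- list(stack)
  if (is.array(stack) && length(dim(stack)) == 3L) {
    stack <- lapply(seq_len(dim(stack)[3]), function(i) stack[, , i])
  }
  frames <- lapply(stack, function(f) {
    f <- pmin(pmax(f, 0), 65535)
    f / 65535
  })
  tiff::writeTIFF(frames, path, bits.per.sample = 16L)
  invisible(path)
}

# average all frames of a stack stored as list or 3-D array into one matrix
stack_to_frames <- function(stack) {
  if (is.matrix(stack)) return(list(stack))
  if (is.array(stack) && length(dim(stack)) == 3L) {
    return(lapply(seq_len(dim(stack)[3]), function(i) stack[, , i]))
  }
  if (is.list(stack)) return(stack)
  abort("`stack` must be a matrix, a 3-D array, or a list of matrices.")
}
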