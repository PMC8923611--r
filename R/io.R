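# Image input/output and intensity normalization. Real data travel as
# NIfTI-1 (.nii / .nii.gz, via RNifti); a plain-text array container
# (.txt) serves tests and debugging. The solver always works on the
# normalized periodic domain [0, 2*pi)^d; the physical voxel spacing from
# a NIfTI header is recorded on write but does not enter the solve
# (anisotropic spacing is out of scope), and only square/cubic volumes
# are accepted because the grid is periodic and square by construction.

image_format <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) return("nifti")
  if (grepl("\\.txt$", path, ignore.case = TRUE)) return("text")
  stop(sprintf("unknown image extension in '%s' (expected .nii, .nii.gz or .txt)",
               path))
}

check_image_array <- function(vals, path) {
  dims <- dim(vals)
  dims <- dims[dims > 1L]  # drop singleton axes (e.g. 2D stored as X x Y x 1)
  if (!(length(dims) %in% c(2L, 3L))) {
    stop(sprintf("'%s' is not a single-channel 2D or 3D volume", path))
  }
  if (length(unique(dims)) != 1L) {
    stop(sprintf(paste0("'%s' has non-square dims (%s); the periodic grid ",
                        "requires equal extent per axis"),
                 path, paste(dims, collapse = " x ")))
  }
  if (anyNA(vals) || !all(is.finite(vals))) {
    stop(sprintf("'%s' contains NaN or non-finite voxels", path))
  }
  array(as.numeric(vals), dim = dims)
}

#' Read an image into a scalar field
#'
#' Reads a NIfTI-1 volume (\code{.nii} / \code{.nii.gz}) or the package's
#' plain-text array container (\code{.txt}). The volume must be a
#' single-channel, square (all axes equal) 2D or 3D array with finite
#' values; it is placed on the periodic grid \eqn{[0, 2\pi)^d}.
#'
#' @param path file path.
#' @return a [ScalarField-class].
#' @seealso [writeImage()]
#' @export
readImage <- function(path) {
  fmt <- image_format(path)
  if (fmt == "nifti") {
    img <- RNifti::readNifti(path)
    vals <- check_image_array(as.array(img), path)
  } else {
    con <- file(path, "r")
    on.exit(close(con))
    dims <- as.integer(strsplit(trimws(readLines(con, n = 1L)), "\\s+")[[1]])
    raw <- as.numeric(readLines(con))
    if (length(raw) != prod(dims)) {
      stop(sprintf("'%s': expected %d values, found %d", path, prod(dims),
                   length(raw)))
    }
    vals <- check_image_array(array(raw, dim = dims), path)
  }
  scalarField(makeGrid(dim(vals)), vals)
}

#' Write a scalar field to disk
#'
#' NIfTI output is written in double precision so a write-read round trip
#' is bit-exact; the voxel spacing is recorded in the header pixdim.
#' The \code{.txt} container stores the dims on the first line and one
#' value per line at full (17 significant digit) precision.
#'
#' @param field a [ScalarField-class].
#' @param path output path (\code{.nii}, \code{.nii.gz} or \code{.txt}).
#' @param pixdim physical voxel spacing per axis recorded in the NIfTI
#'   header; defaults to the grid spacing.
#' @return the path, invisibly.
#' @export
writeImage <- function(field, path, pixdim = NULL) {
  stopifnot(is(field, "ScalarField"))
  fmt <- image_format(path)
  if (fmt == "nifti") {
    img <- RNifti::asNifti(field@values)
    if (is.null(pixdim)) pixdim <- field@grid@spacing
    RNifti::pixdim(img) <- pixdim
    RNifti::writeNifti(img, path, datatype = "double")
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste(dim(field@values), collapse = " "), con)
    writeLines(sprintf("%.17g", as.vector(field@values)), con)
  }
  invisible(path)
}

#' Rescale image intensities to [0, 1]
#'
#' Affine (rank-preserving) rescaling \eqn{(f - \min f)/(\max f - \min f)}.
#' A constant field maps to all zeros by convention.
#'
#' @param f a [ScalarField-class].
#' @return a [ScalarField-class] with min 0 and max 1 (or all zeros).
#' @export
normalizeIntensity <- function(f) {
  stopifnot(is(f, "ScalarField"))
  rng <- range(f@values)
  if (rng[2] == rng[1]) {
    return(scalarField(f@grid, array(0, dim = f@grid@dims)))
  }
  scalarField(f@grid, (f@values - rng[1]) / (rng[2] - rng[1]))
}

#' Read a registration configuration file
#'
#' Flat \code{key = value} text format whose keys mirror the
#' [RegistrationConfig-class] field names (\code{regModel}, \code{alpha},
#' \code{divGamma}, \code{nt}, \code{interpOrder}, \code{outerTol},
#' \code{outerMaxit}, \code{krylovTol}, \code{krylovMaxit}, \code{lsC1},
#' \code{lsMaxit}, \code{precondShift}). Lines starting with \code{#} are
#' comments. Unset keys take the [registrationConfig()] defaults.
#'
#' @param path file path.
#' @param overrides named list of values taking precedence over the file
#'   (used by the CLI for flag overrides).
#' @return a [RegistrationConfig-class].
#' @export
readConfigFile <- function(path, overrides = list()) {
  args <- list()
  if (!is.null(path)) {
    lines <- readLines(path)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    for (ln in lines) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      if (length(kv) != 2L) stop(sprintf("malformed config line: '%s'", ln))
      key <- trimws(kv[1])
      val <- trimws(kv[2])
      args[[key]] <- val
    }
  }
  args[names(overrides)] <- overrides
  numeric_keys <- c("alpha", "divGamma", "outerTol", "krylovTol", "lsC1",
                    "precondShift")
  integer_keys <- c("nt", "interpOrder", "outerMaxit", "krylovMaxit",
                    "lsMaxit")
  for (k in names(args)) {
    if (k %in% numeric_keys) args[[k]] <- as.numeric(args[[k]])
    if (k %in% integer_keys) args[[k]] <- as.integer(args[[k]])
  }
  unknown <- setdiff(names(args),
                     c(numeric_keys, integer_keys, "regModel"))
  if (length(unknown)) {
    stop(sprintf("unknown config keys: %s", paste(unknown, collapse = ", ")))
  }
  do.call(registrationConfig, args)
}
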