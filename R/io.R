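## NIfTI, CSV, JSON and PNG input/output. Volumes are written uncompressed
## (.nii) with the source affine preserved; the 4-D time axis is the 4th
## dimension. Voxel data round-trip losslessly at the stored datatype.

#' Read and write volumes as NIfTI
#'
#' `writeVolume` stores a 3-D/4-D array as an uncompressed `.nii` file
#' (float64 by default; integer arrays as int32 so label maps round-trip as
#' integers). `readVolume` returns a plain array with the NIfTI attributes
#' dropped.
#'
#' @param x numeric or integer array (3-D or 4-D).
#' @param path file path ending in `.nii`.
#' @param template optional image whose affine/pixel dimensions to reuse.
#' @return `readVolume` returns an array; `writeVolume` the path, invisibly.
#' @export
writeVolume <- function(x, path, template = NULL) {
  dt <- if (is.integer(x)) "int32" else "double"
  img <- RNifti::asNifti(x, reference = template, datatype = dt)
  RNifti::writeNifti(img, path, datatype = dt)
  invisible(path)
}

#' @rdname writeVolume
#' @export
readVolume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- array(as.vector(img), dim(img))
  if (RNifti::niftiHeader(img)$datatype %in% c(4L, 8L, 256L, 512L))
    storage.mode(arr) <- "integer"
  arr
}

#' Fused RGB probability rendering
#'
#' Writes one PNG per axial slice with the Model-3 probability in the red
#' channel, Model-2 in green and Model-1 in blue; voxels outside the mask
#' are black.
#'
#' @param probVolume a [ProbabilityVolume-class].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return character vector of written paths, invisibly.
#' @export
writeFusedRGB <- function(probVolume, dir, prefix = "pnms_rgb") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- probVolume@probs
  d <- dim(probVolume@mask)
  paths <- character(d[3])
  for (z in seq_len(d[3])) {
    img <- array(0, c(d[2], d[1], 3))
    r <- p[, , z, 3]; g <- p[, , z, 2]; b <- p[, , z, 1]
    r[!is.finite(r)] <- 0; g[!is.finite(g)] <- 0; b[!is.finite(b)] <- 0
    img[, , 1] <- t(r); img[, , 2] <- t(g); img[, , 3] <- t(b)
    paths[z] <- file.path(dir, sprintf("%s_slice%02d.png", prefix, z))
    png::writePNG(pmin(pmax(img, 0), 1), paths[z])
  }
  invisible(paths)
}

#' Write a provenance manifest
#'
#' A JSON record of the stage, the configuration used (echoed in full), the
#' derived seeds and the artifact list, sufficient to regenerate every
#' output deterministically. No timestamps are included, so a rerun with the
#' same configuration is byte-identical.
#'
#' @param dir output directory.
#' @param stage character stage name.
#' @param config the run configuration (list).
#' @param seeds named list of derived seeds.
#' @param files character vector of artifact paths (relative).
#' @return the manifest path, invisibly.
#' @export
writeManifest <- function(dir, stage, config, seeds, files) {
  path <- file.path(dir, paste0("manifest_", stage, ".json"))
  jsonlite::write_json(list(stage = stage, config = config, seeds = seeds,
                            files = sort(files)),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
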