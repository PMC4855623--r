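#' Read and write volumes as NIfTI-1
#'
#' Thin wrappers over RNifti. Volumes are written RAS+ with the voxel
#' size in the header; all internal coordinates are 0-based voxel
#' indices in R's native 1-based arrays.
#'
#' @param x 3D or 4D numeric array.
#' @param path Output file path (`.nii` or `.nii.gz`).
#' @param voxel_mm Isotropic voxel size recorded in the header.
#' @return `write_volume_nifti` returns `path` invisibly;
#'   `read_volume_nifti` returns a plain numeric array with attribute
#'   `voxel_mm`.
#' @export
write_volume_nifti <- function(x, path, voxel_mm = 1) {
  img <- RNifti::asNifti(x, reference = NULL)
  RNifti::pixdim(img) <- rep(voxel_mm, length(dim(x)))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume_nifti
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  out <- array(as.numeric(img), dim(img))
  attr(out, "voxel_mm") <- RNifti::pixdim(img)[1]
  out
}

#' Write quantitative maps to a directory
#'
#' Writes `r1.nii`, `pd.nii`, `r2s.nii` and `mask.nii` plus a JSON
#' sidecar with the voxel size and QC report.
#'
#' @param maps A [quantitative_maps()].
#' @param dir Output directory (created if needed).
#' @param compress Write `.nii.gz` instead of `.nii`.
#' @return The directory, invisibly.
#' @export
write_maps <- function(maps, dir, compress = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (compress) ".nii.gz" else ".nii"
  for (nm in c("r1", "pd", "r2s"))
    write_volume_nifti(maps[[nm]], file.path(dir, paste0(nm, ext)),
                       maps$voxel_mm)
  write_volume_nifti(maps$mask + 0, file.path(dir, paste0("mask", ext)),
                     maps$voxel_mm)
  side <- list(voxel_mm = maps$voxel_mm, qc = maps$qc %||% list())
  jsonlite::write_json(side, file.path(dir, "maps.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_maps
#' @export
read_maps <- function(dir) {
  ext <- if (file.exists(file.path(dir, "r1.nii"))) ".nii" else ".nii.gz"
  vols <- lapply(c("r1", "pd", "r2s", "mask"), function(nm)
    read_volume_nifti(file.path(dir, paste0(nm, ext))))
  side <- jsonlite::read_json(file.path(dir, "maps.json"))
  quantitative_maps(vols[[1]], vols[[2]], vols[[3]], vols[[4]] > 0.5,
                    voxel_mm = side$voxel_mm %||% 1)
}

write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null", force = TRUE)
  invisible(path)
}
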