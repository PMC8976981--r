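# NIfTI reading/writing and case (de)serialization. One single-label NIfTI
# file per channel and per mask for maximal interoperability; voxel spacing
# travels in the NIfTI header (pixdim); truth parameters and the seed go into
# a JSON sidecar. Voxel indexing in all writers is 0-based x/y/z in the NIfTI
# sense (fastest-varying axis first).

nifti_spacing <- function(img) {
  pd <- RNifti::pixdim(img)
  as.numeric(pd[1:3])
}

#' Write a 3-D volume as NIfTI
#'
#' @param arr 3-D array (numeric or logical; logical is written as 0/1
#'   integers).
#' @param path output path (`.nii` or `.nii.gz`).
#' @param spacing voxel spacing in mm.
#' @return The path, invisibly.
#' @export
write_volume <- function(arr, path, spacing = c(1, 1, 1)) {
  assert_that(length(dim(arr)) == 3L, "arr must be a 3-D array")
  if (is.logical(arr)) arr <- array(as.integer(arr), dim(arr))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read one or more NIfTI files as a multi-channel volume
#'
#' All files must share grid shape and voxel spacing; a mismatch raises an
#' error naming the offending file.
#'
#' @param paths character vector of NIfTI paths; names become channel names
#'   (else file basenames are used).
#' @return A [multichannel_volume].
#' @export
read_volume <- function(paths) {
  assert_that(length(paths) >= 1L && all(file.exists(paths)),
              "all NIfTI paths must exist")
  nms <- names(paths) %||% sub("\\.nii(\\.gz)?$", "", basename(paths))
  imgs <- lapply(paths, RNifti::readNifti)
  sp <- nifti_spacing(imgs[[1]])
  d <- dim(imgs[[1]])
  for (i in seq_along(imgs)) {
    if (!identical(dim(imgs[[i]]), d) ||
        max(abs(nifti_spacing(imgs[[i]]) - sp)) > 1e-4) {
      stop_sx("geometry of '%s' does not match '%s'", paths[i], paths[1])
    }
  }
  multichannel_volume(stats::setNames(lapply(imgs, function(x) array(as.numeric(x), d)), nms),
                      spacing = sp)
}

#' Read label NIfTI files as a label volume
#'
#' Files are read with integer semantics: non-integral voxel values raise an
#' error (a float image is not a label map).
#'
#' @param class_map_path path of the class-map NIfTI (values 0/1/2).
#' @param gland_path,tumor_rad_path,tumor_histo_path optional mask NIfTIs.
#' @return A [label_volume].
#' @export
read_labels <- function(class_map_path, gland_path = NULL,
                        tumor_rad_path = NULL, tumor_histo_path = NULL) {
  read_int <- function(path) {
    img <- RNifti::readNifti(path)
    v <- as.numeric(img)
    if (max(abs(v - round(v))) > 1e-6) {
      stop_sx("'%s' contains non-integral values and cannot be read as labels",
              path)
    }
    list(arr = array(as.integer(round(v)), dim(img)),
         spacing = nifti_spacing(img))
  }
  cm <- read_int(class_map_path)
  as_mask <- function(path) {
    if (is.null(path)) return(NULL)
    m <- read_int(path)
    array(m$arr > 0L, dim(m$arr))
  }
  label_volume(cm$arr, gland_mask = as_mask(gland_path),
               tumor_mask_rad = as_mask(tumor_rad_path),
               tumor_mask_histo = as_mask(tumor_histo_path),
               spacing = cm$spacing)
}

#' Write a phantom case to a directory
#'
#' One NIfTI per channel and per mask plus a JSON sidecar with the generation
#' seed and gland/lesion geometry.
#'
#' @param case a [phantom_case].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return The directory, invisibly.
#' @export
write_phantom_case <- function(case, dir, prefix = "case") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sp <- case$image$spacing
  for (nm in names(case$image$channels)) {
    write_volume(case$image$channels[[nm]],
                 file.path(dir, sprintf("%s_%s.nii.gz", prefix, nm)), sp)
  }
  lb <- case$labels
  write_volume(lb$class_map, file.path(dir, sprintf("%s_labels.nii.gz", prefix)), sp)
  write_volume(lb$gland_mask, file.path(dir, sprintf("%s_gland.nii.gz", prefix)), sp)
  write_volume(lb$tumor_mask_rad,
               file.path(dir, sprintf("%s_tumor_rad.nii.gz", prefix)), sp)
  write_volume(lb$tumor_mask_histo,
               file.path(dir, sprintf("%s_tumor_histo.nii.gz", prefix)), sp)
  side <- list(seed = case$truth_params$seed,
               gland = case$truth_params$gland,
               lesions = case$truth_params$lesions,
               spacing = sp)
  jsonlite::write_json(side, file.path(dir, sprintf("%s_truth.json", prefix)),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a phantom case written by [write_phantom_case]
#'
#' @param dir directory containing the files.
#' @param prefix file-name prefix used at write time.
#' @return A [phantom_case]-like list with `image` and `labels` (the truth
#'   parameter fields are not round-tripped; the JSON sidecar carries the
#'   seed and geometry).
#' @export
read_phantom_case <- function(dir, prefix = "case") {
  f <- function(x) file.path(dir, sprintf("%s_%s.nii.gz", prefix, x))
  chans <- c("t2", "adc", "highb")
  image <- read_volume(stats::setNames(vapply(chans, f, ""), chans))
  labels <- read_labels(f("labels"), f("gland"), f("tumor_rad"),
                        f("tumor_histo"))
  side_path <- file.path(dir, sprintf("%s_truth.json", prefix))
  truth <- if (file.exists(side_path)) jsonlite::read_json(side_path) else NULL
  structure(list(image = image, labels = labels, truth_params = truth),
            class = "phantom_case")
}
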