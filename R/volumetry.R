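#' Structure label volume
#'
#' A 3D integer atlas of the nine posterior-circulation structures. Voxel
#' values are 0 (non-structure tissue) or a structure label 1-9 following
#' [structure_names()]. Axis order is (slice, row, col) and `spacing` gives
#' the millimetres per voxel along the same axes.
#'
#' @param data integer 3D array with values in 0..9.
#' @param spacing numeric length-3, mm per voxel along (slice, row, col).
#' @param brain optional logical array of the same shape marking intracranial
#'   voxels; defaults to `NULL`, in which case downstream code treats all
#'   nonbackground voxels plus labeled structures as brain.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(data, spacing = c(5, 0.5, 0.5), brain = NULL) {
  if (length(dim(data)) != 3L) stopf("label data must be a 3D array")
  spacing <- check_spacing(spacing)
  vals <- unique(as.integer(data))
  if (any(vals < 0L | vals > 9L))
    stopf("labels must lie in 0..9, found %s",
          paste(setdiff(vals, 0:9), collapse = ", "))
  if (!is.null(brain) && !identical(dim(brain), dim(data)))
    stopf("brain mask shape differs from label volume shape")
  structure(list(data = array(as.integer(data), dim(data)),
                 spacing = spacing, brain = brain),
            class = "label_volume")
}

#' Binary ischemic lesion mask
#'
#' @param data logical (or 0/1) 3D array; `TRUE` marks ischemic voxels.
#' @param spacing numeric length-3, mm per voxel along (slice, row, col).
#' @return An object of class `lesion_mask`.
#' @export
lesion_mask <- function(data, spacing = c(5, 0.5, 0.5)) {
  if (length(dim(data)) != 3L) stopf("lesion data must be a 3D array")
  structure(list(data = array(as.logical(data), dim(data)),
                 spacing = check_spacing(spacing)),
            class = "lesion_mask")
}

#' @export
print.label_volume <- function(x, ...) {
  cat("<label_volume>", paste(dim(x$data), collapse = "x"),
      "voxels @", paste(x$spacing, collapse = "x"), "mm\n")
  tab <- table(factor(x$data[x$data > 0], levels = 1:9))
  names(tab) <- structure_names()
  print(tab)
  invisible(x)
}

#' @export
print.lesion_mask <- function(x, ...) {
  cat("<lesion_mask>", paste(dim(x$data), collapse = "x"), "voxels,",
      sum(x$data), "lesion voxels (",
      format(sum(x$data) * voxel_ml(x$spacing), digits = 4), "mL )\n")
  invisible(x)
}

as_label_volume <- function(x) {
  if (inherits(x, "label_volume")) return(x)
  if (inherits(x, "structure_atlas")) return(x$labels)
  stopf("expected a label_volume or structure_atlas")
}

check_paired <- function(labels, lesion) {
  labels <- as_label_volume(labels)
  if (!inherits(lesion, "lesion_mask")) stopf("expected a lesion_mask")
  if (!identical(dim(labels$data), dim(lesion$data)))
    stopf("lesion mask shape (%s) does not match label volume shape (%s)",
          paste(dim(lesion$data), collapse = "x"),
          paste(dim(labels$data), collapse = "x"))
  labels
}

#' Per-structure volumes in millilitres
#'
#' Volume of each of the nine structures: voxel count times voxel volume,
#' reported in mL. Absent labels yield 0 mL with a warning.
#'
#' @param labels a [label_volume()] or [build_atlas()] result.
#' @return Named numeric vector of nine volumes (mL), in label order.
#' @export
structure_volumes <- function(labels) {
  labels <- as_label_volume(labels)
  counts <- tabulate(labels$data[labels$data > 0L], nbins = 9L)
  if (any(counts == 0L))
    warnf("structure(s) with zero volume: %s",
          paste(structure_names()[counts == 0L], collapse = ", "))
  stats::setNames(counts * voxel_ml(labels$spacing), structure_names())
}

#' Ten-parameter lesion-proportion feature vector
#'
#' Converts a structure label volume plus an ischemic lesion mask into the
#' ten dimensionless parameters used by the quantitative integrated score:
#' `f1..f9` are the lesioned fraction of each structure,
#' `vol(lesion & structure_i) / vol(structure_i)`, and `f10` summarizes the
#' lesion outside all nine structures. With `other = "region"` (default)
#' `f10` is the lesioned fraction of the remaining brain,
#' `vol(lesion outside structures) / vol(brain minus structures)`, keeping
#' all ten features on the same "fraction of region lesioned" scale; with
#' `other = "lesion"` it is the fraction of total lesion volume that falls
#' outside the structures.
#'
#' Features are ratios, hence independent of voxel spacing. A structure with
#' zero volume contributes feature 0 with a warning (never NaN).
#'
#' @param labels a [label_volume()] or atlas.
#' @param lesion a paired [lesion_mask()].
#' @param other denominator convention for `f10`; see Details.
#' @return Named numeric vector `f1..f10`, each in `[0, 1]`.
#' @export
lesion_features <- function(labels, lesion, other = c("region", "lesion")) {
  other <- match.arg(other)
  labels <- check_paired(labels, lesion)
  lab <- labels$data
  les <- lesion$data
  struct_counts <- tabulate(lab[lab > 0L], nbins = 9L)
  hit_counts <- tabulate(lab[les & lab > 0L], nbins = 9L)
  f <- numeric(10)
  nz <- struct_counts > 0L
  f[1:9][nz] <- hit_counts[nz] / struct_counts[nz]
  if (any(!nz))
    warnf("zero-volume structure(s) get feature 0: %s",
          paste(structure_names()[!nz], collapse = ", "))
  brain <- labels$brain
  if (is.null(brain)) brain <- lab > 0L | les
  outside <- brain & lab == 0L
  les_out <- sum(les & outside)
  if (other == "region") {
    f[10] <- if (sum(outside) > 0L) les_out / sum(outside) else 0
  } else {
    f[10] <- if (sum(les) > 0L) les_out / sum(les) else 0
  }
  stats::setNames(f, paste0("f", 1:10))
}

#' Stack per-slice annotations into aligned 3D volumes
#'
#' Annotation workflows label individual axial slices; this stacks a list of
#' equally shaped 2D label matrices (and, optionally, lesion matrices) into a
#' [label_volume()] and [lesion_mask()] pair.
#'
#' @param label_slices list of integer matrices (values 0..9), in slice order.
#' @param lesion_slices optional list of logical/0-1 matrices, same shapes.
#' @param spacing mm per voxel along (slice, row, col).
#' @return A list with elements `labels` ([label_volume()]) and `lesion`
#'   ([lesion_mask()] or `NULL`).
#' @export
masks_from_slices <- function(label_slices, lesion_slices = NULL,
                              spacing = c(5, 0.5, 0.5)) {
  if (!length(label_slices)) stopf("no slices given")
  shp <- dim(label_slices[[1]])
  for (i in seq_along(label_slices))
    if (!identical(dim(label_slices[[i]]), shp))
      stopf("slice %d has shape (%s), expected (%s)", i,
            paste(dim(label_slices[[i]]), collapse = "x"),
            paste(shp, collapse = "x"))
  stack <- function(slices) {
    a <- array(0L, c(length(slices), shp))
    for (i in seq_along(slices)) a[i, , ] <- slices[[i]]
    a
  }
  labels <- label_volume(stack(label_slices), spacing)
  lesion <- NULL
  if (!is.null(lesion_slices)) {
    if (length(lesion_slices) != length(label_slices))
      stopf("lesion slice count (%d) differs from label slice count (%d)",
            length(lesion_slices), length(label_slices))
    for (i in seq_along(lesion_slices))
      if (!identical(dim(lesion_slices[[i]]), shp))
        stopf("lesion slice %d has shape (%s), expected (%s)", i,
              paste(dim(lesion_slices[[i]]), collapse = "x"),
              paste(shp, collapse = "x"))
    lesion <- lesion_mask(stack(lapply(lesion_slices, function(s) s != 0)),
                          spacing)
  }
  list(labels = labels, lesion = lesion)
}

#' Read per-slice PNG label maps
#'
#' Secondary input dialect for annotation tools that export one grayscale
#' PNG per axial slice, with structure labels encoded as the gray levels
#' 0..9 (0 = background). Slices are stacked in the given order.
#'
#' @param paths character vector of PNG paths, in slice order.
#' @param spacing mm per voxel along (slice, row, col).
#' @return A [label_volume()].
#' @export
read_label_png_slices <- function(paths, spacing = c(5, 0.5, 0.5)) {
  if (!requireNamespace("png", quietly = TRUE))
    stopf("the 'png' package is required to read PNG slices")
  slices <- lapply(seq_along(paths), function(i) {
    img <- png::readPNG(paths[i])
    if (length(dim(img)) == 3L) img <- img[, , 1]
    lab <- round(img * 255)
    if (any(lab > 9))
      stopf("slice %d: gray levels above 9 are not valid labels", i)
    matrix(as.integer(lab), nrow(lab), ncol(lab))
  })
  masks_from_slices(slices, spacing = spacing)$labels
}

#' Read / write volumes as NIfTI
#'
#' Volumes are stored with the package's (slice, row, col) axis order mapped
#' directly onto the NIfTI data axes and spacing carried in `pixdim`.
#'
#' @param x a [label_volume()] or [lesion_mask()].
#' @param path output `.nii` / `.nii.gz` path.
#' @return `write_volume_nifti` returns `path` invisibly;
#'   `read_label_nifti` / `read_lesion_nifti` return the corresponding object.
#' @export
write_volume_nifti <- function(x, path) {
  dat <- if (inherits(x, "lesion_mask")) array(as.integer(x$data), dim(x$data))
         else x$data
  img <- RNifti::asNifti(dat, reference = NULL)
  RNifti::pixdim(img) <- x$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume_nifti
#' @param path input NIfTI path.
#' @export
read_label_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  label_volume(array(as.integer(round(img)), dim(img)[1:3]),
               spacing = RNifti::pixdim(img)[1:3])
}

#' @rdname write_volume_nifti
#' @export
read_lesion_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  lesion_mask(array(img != 0, dim(img)[1:3]),
              spacing = RNifti::pixdim(img)[1:3])
}
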