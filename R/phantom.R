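#' Names of the nine posterior-circulation structures
#'
#' Label order used throughout the package: 1 left cerebellum, 2 right
#' cerebellum, 3 left occipital lobe, 4 right occipital lobe, 5 left
#' thalamus, 6 right thalamus, 7 medulla oblongata, 8 midbrain, 9 pons.
#'
#' @return Character vector of length 9.
#' @export
structure_names <- function() {
  c("left_cerebellum", "right_cerebellum",
    "left_occipital", "right_occipital",
    "left_thalamus", "right_thalamus",
    "medulla", "midbrain", "pons")
}

# Stylized anatomy: ellipsoid primitives in fractional (slice, row, col)
# coordinates of the grid's physical extent. Left/right pairs are exact
# mirrors about the midsagittal plane (col fraction 0.5); the brainstem
# stack (medulla, pons, midbrain) sits on the midline. Only the topology
# matters downstream (nine disjoint regions, L/R symmetry); no anatomical
# fidelity is claimed.
phantom_geometry <- function() {
  g <- rbind(
    left_cerebellum  = c(0.33, 0.68, 0.31, 0.130, 0.160, 0.140),
    right_cerebellum = c(0.33, 0.68, 0.69, 0.130, 0.160, 0.140),
    left_occipital   = c(0.68, 0.76, 0.33, 0.120, 0.140, 0.130),
    right_occipital  = c(0.68, 0.76, 0.67, 0.120, 0.140, 0.130),
    left_thalamus    = c(0.70, 0.42, 0.40, 0.055, 0.070, 0.060),
    right_thalamus   = c(0.70, 0.42, 0.60, 0.055, 0.070, 0.060),
    medulla          = c(0.16, 0.47, 0.50, 0.085, 0.060, 0.060),
    midbrain         = c(0.54, 0.42, 0.50, 0.065, 0.075, 0.075),
    pons             = c(0.36, 0.44, 0.50, 0.085, 0.085, 0.085))
  colnames(g) <- c("cz", "cy", "cx", "az", "ay", "ax")
  g
}

phantom_brain_geometry <- function() c(0.50, 0.56, 0.50, 0.495, 0.460, 0.470)

# Fractional voxel-center coordinate arrays for a grid
voxel_coords <- function(grid) {
  list(z = array(rep((seq_len(grid[1]) - 0.5) / grid[1],
                     times = grid[2] * grid[3]), grid),
       y = array(rep(rep((seq_len(grid[2]) - 0.5) / grid[2], each = grid[1]),
                     times = grid[3]), grid),
       x = array(rep((seq_len(grid[3]) - 0.5) / grid[3],
                     each = grid[1] * grid[2]), grid))
}

#' Build the synthetic structure atlas
#'
#' Voxelizes nine disjoint ellipsoidal structures (stylized posterior-fossa
#' anatomy: paired cerebella, occipital lobes and thalami mirrored across the
#' midsagittal plane, plus the midline brainstem stack medulla-pons-midbrain)
#' onto a regular grid, together with an ellipsoidal brain envelope. The
#' layout is defined in fractions of the grid's physical extent, so any grid
#' large enough to give every structure at least one voxel is accepted.
#'
#' @param grid_shape integer length-3, voxels along (slice, row, col);
#'   default `c(40, 256, 256)`.
#' @param spacing mm per voxel along the same axes; default
#'   `c(5, 0.5, 0.5)` (routine head CT: 0.5 mm in-plane, 5 mm slices).
#' @return An object of class `structure_atlas`: a list with the voxelized
#'   [label_volume()] (`$labels`, brain mask attached), the structure table
#'   (`$structures`: label, name, center and semi-axes in mm), `$grid_shape`
#'   and `$spacing`.
#' @export
build_atlas <- function(grid_shape = c(40, 256, 256), spacing = c(5, 0.5, 0.5)) {
  spacing <- check_spacing(spacing)
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 1L))
    stopf("grid_shape must be three positive integers")
  geom <- phantom_geometry()
  co <- voxel_coords(grid_shape)
  lab <- array(0L, grid_shape)
  inside <- function(p) {
    ((co$z - p[1]) / p[4])^2 + ((co$y - p[2]) / p[5])^2 +
      ((co$x - p[3]) / p[6])^2 <= 1
  }
  for (i in seq_len(nrow(geom))) {
    m <- inside(geom[i, ])
    if (!any(m))
      stopf("grid %s is too small to voxelize structure '%s'",
            paste(grid_shape, collapse = "x"), rownames(geom)[i])
    if (any(lab[m] > 0L))
      stopf("structure '%s' overlaps an earlier structure on this grid",
            rownames(geom)[i])
    lab[m] <- i
  }
  brain <- inside(phantom_brain_geometry())
  extent <- grid_shape * spacing
  structures <- data.frame(
    label = seq_len(9L), name = rownames(geom),
    center_z_mm = geom[, "cz"] * extent[1],
    center_y_mm = geom[, "cy"] * extent[2],
    center_x_mm = geom[, "cx"] * extent[3],
    semi_z_mm = geom[, "az"] * extent[1],
    semi_y_mm = geom[, "ay"] * extent[2],
    semi_x_mm = geom[, "ax"] * extent[3],
    shape = "ellipsoid", row.names = NULL)
  structure(list(labels = label_volume(lab, spacing, brain = brain),
                 structures = structures,
                 grid_shape = grid_shape, spacing = spacing),
            class = "structure_atlas")
}

#' @export
print.structure_atlas <- function(x, ...) {
  cat("<structure_atlas>", paste(x$grid_shape, collapse = "x"), "voxels @",
      paste(x$spacing, collapse = "x"), "mm\n")
  vols <- structure_volumes(x$labels)
  print(round(vols, 2))
  invisible(x)
}

# Shift a logical 3D array by one voxel along an axis (zero-fill).
shift1 <- function(a, axis, dir) {
  b <- array(FALSE, dim(a))
  n <- dim(a)[axis]
  if (n < 2L) return(b)
  src <- if (dir > 0) 1:(n - 1) else 2:n
  dst <- if (dir > 0) 2:n else 1:(n - 1)
  if (axis == 1L) b[dst, , ] <- a[src, , ]
  else if (axis == 2L) b[, dst, ] <- a[, src, ]
  else b[, , dst] <- a[, , src]
  b
}

neighbors6 <- function(a) {
  shift1(a, 1L, +1) | shift1(a, 1L, -1) |
    shift1(a, 2L, +1) | shift1(a, 2L, -1) |
    shift1(a, 3L, +1) | shift1(a, 3L, -1)
}

# Randomized seeded region growing inside `region` (logical array), cropped
# to its bounding box. Returns linear indices (into the full array) in
# growth order, at least n_needed of them (or all reachable voxels).
# Growth proceeds in waves: each frontier voxel is accepted independently
# with probability `accept`, accepted voxels are appended in random order.
# The full ordering is a deterministic function of (region, seed), so the
# first-n prefix is nested in n: achieved fractions are monotone in the
# requested fraction for a fixed seed.
grow_order <- function(region, n_needed, seed, accept = 0.7) {
  idx_all <- which(region)
  bb <- apply(arrayInd(idx_all, dim(region)), 2, range)
  sub <- region[bb[1, 1]:bb[2, 1], bb[1, 2]:bb[2, 2], bb[1, 3]:bb[2, 3],
                drop = FALSE]
  sub <- array(sub, c(bb[2, ] - bb[1, ] + 1L))
  order_sub <- with_seed(seed, {
    start <- sample(which(sub), 1L)
    grown <- array(FALSE, dim(sub))
    grown[start] <- TRUE
    out <- start
    while (length(out) < n_needed) {
      frontier <- which(neighbors6(grown) & sub & !grown)
      if (!length(frontier)) break
      take <- frontier[stats::runif(length(frontier)) < accept]
      if (!length(take)) take <- frontier[sample.int(length(frontier), 1L)]
      take <- if (length(take) > 1L) sample(take) else take
      grown[take] <- TRUE
      out <- c(out, take)
    }
    out
  })
  # map bbox-local linear indices back to full-array linear indices
  loc <- arrayInd(order_sub, dim(sub))
  full <- cbind(loc[, 1] + bb[1, 1] - 1L, loc[, 2] + bb[1, 2] - 1L,
                loc[, 3] + bb[1, 3] - 1L)
  d <- dim(region)
  full[, 1] + (full[, 2] - 1L) * d[1] + (full[, 3] - 1L) * d[1] * d[2]
}

#' Place synthetic ischemic lesions in the phantom
#'
#' Grows one connected, irregular lesion per targeted region by seeded
#' region growing (6-connectivity, randomized wave order) restricted to that
#' region, until the requested fraction of the region's voxels is reached.
#' Because voxels are added one wave at a time from a deterministic growth
#' ordering, the achieved fraction equals `round(fraction * n) / n` exactly,
#' and for a fixed seed the lesion at a smaller fraction is a subset of the
#' lesion at a larger one.
#'
#' @param atlas a [build_atlas()] result.
#' @param fractions named numeric vector of target volume fractions in
#'   `[0, 1]`; names are [structure_names()] entries or `"other"` (brain
#'   tissue outside all nine structures).
#' @param seed integer seed; the mask is bit-identical under a fixed
#'   (atlas, fractions, seed).
#' @return A [lesion_mask()] aligned to the atlas grid.
#' @export
place_lesion <- function(atlas, fractions, seed = 1L) {
  if (!inherits(atlas, "structure_atlas")) stopf("expected a structure_atlas")
  if (length(fractions) && is.null(names(fractions)))
    stopf("fractions must be named by structure (or 'other')")
  valid <- c(structure_names(), "other")
  bad <- setdiff(names(fractions), valid)
  if (length(bad)) stopf("unknown lesion target(s): %s", paste(bad, collapse = ", "))
  if (any(fractions < 0 | fractions > 1))
    stopf("lesion volume fractions must lie in [0, 1]")
  lab <- atlas$labels$data
  brain <- atlas$labels$brain
  les <- array(FALSE, dim(lab))
  for (target in names(fractions)) {
    frac <- fractions[[target]]
    if (frac == 0) next
    region <- if (target == "other") brain & lab == 0L
              else lab == match(target, structure_names())
    n_region <- sum(region)
    n_needed <- round(frac * n_region)
    if (n_needed == 0L) next
    ord <- grow_order(region, n_needed, derive_seed(seed, target))
    if (length(ord) < n_needed)
      stopf("region '%s': only %d of %d requested voxels reachable (max achievable fraction %.3f)",
            target, length(ord), n_needed, length(ord) / n_region)
    les[ord[seq_len(n_needed)]] <- TRUE
  }
  lesion_mask(les, atlas$spacing)
}

#' Render a noncontrast-CT-like intensity volume
#'
#' Assigns each voxel the mean Hounsfield value of its tissue class --
#' background air outside the brain envelope, non-structure parenchyma, one
#' (stylized, per-structure distinct) mean per labeled structure, and a
#' hypodense value for lesion voxels -- then adds i.i.d. Gaussian noise.
#' Deterministic under a fixed seed.
#'
#' @param atlas a [build_atlas()] result.
#' @param lesion optional [lesion_mask()]; lesion voxels override their
#'   tissue class.
#' @param noise_sd Gaussian noise standard deviation in HU (default 2).
#' @param hu_background HU outside the brain envelope (default -1000).
#' @param hu_parenchyma HU of non-structure brain tissue (default 35).
#' @param hu_structures length-9 HU means for labels 1..9; the default
#'   `38 + 4 * label` gives each structure a distinct, stylized contrast so
#'   that desk-scale segmentation benchmarks are well posed (real
#'   noncontrast CT offers no such per-structure contrast).
#' @param lesion_hypodensity HU subtracted from `hu_parenchyma` for lesion
#'   voxels (default 20; acute ischemia is hypodense on noncontrast CT).
#' @param seed integer seed for the noise.
#' @return 3D numeric array of intensities (HU), same shape as the atlas.
#' @export
render_ct <- function(atlas, lesion = NULL, noise_sd = 2,
                      hu_background = -1000, hu_parenchyma = 35,
                      hu_structures = 38 + 4 * (1:9),
                      lesion_hypodensity = 20, seed = 1L) {
  if (!inherits(atlas, "structure_atlas")) stopf("expected a structure_atlas")
  lab <- atlas$labels$data
  brain <- atlas$labels$brain
  img <- array(hu_background, dim(lab))
  img[brain & lab == 0L] <- hu_parenchyma
  for (i in 1:9) img[lab == i] <- hu_structures[i]
  if (!is.null(lesion)) {
    if (!identical(dim(lesion$data), dim(lab)))
      stopf("lesion mask shape does not match atlas grid")
    img[lesion$data] <- hu_parenchyma - lesion_hypodensity
  }
  if (noise_sd > 0)
    img <- img + with_seed(seed, array(stats::rnorm(length(img), 0, noise_sd),
                                       dim(img)))
  img
}
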