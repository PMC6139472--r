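# Node construction from stereotaxic coordinates: Talairach/MNI conversion,
# 27-voxel cube ROIs, and voxel-wise time-series extraction.
#
# Conventions: world coordinates are RAS+ mm; voxel indices in affines and in
# NodeSpec cubes are 0-based (NIfTI style). R array subscripts are voxel
# index + 1. Cube voxel rows are ordered lexicographically by (x, y, z).

# Lacadie et al. (2008) best-fit affine, MNI -> Talairach (the published
# coefficients of the Yale conversion tool).
.lacadie_mni2tal <- matrix(c(
   0.9357,  0.0029, -0.0072, -1.0423,
  -0.0065,  0.9396, -0.0726, -1.3940,
   0.0103,  0.0752,  0.8967,  3.8475,
   0,       0,       0,       1), 4, 4, byrow = TRUE)

.apply_xfm <- function(M, coord) {
  coord <- rbind(matrix(coord, ncol = 3))
  stopifnot(all(is.finite(coord)))
  out <- t(M %*% t(cbind(coord, 1)))[, 1:3, drop = FALSE]
  if (nrow(out) == 1) drop(out) else out
}

#' Convert Talairach coordinates to MNI space
#'
#' Applies the inverse of the published Lacadie-style MNI-to-Talairach
#' best-fit affine. The transform is pluggable: pass any 4x4 matrix (mapping
#' Talairach mm to MNI mm) as `method` to substitute another calibration.
#'
#' @param coord length-3 mm coordinate or an n x 3 matrix of coordinates.
#' @param method `"lacadie"` (default) or a 4x4 transform matrix.
#' @return coordinate(s) in MNI mm, same shape as the input.
#' @seealso [mni2tal()]
#' @export
tal2mni <- function(coord, method = "lacadie") {
  M <- if (is.matrix(method) && all(dim(method) == c(4, 4))) method
       else if (identical(method, "lacadie")) solve(.lacadie_mni2tal)
       else stop("unknown tal2mni method")
  .apply_xfm(M, coord)
}

#' Convert MNI coordinates to Talairach space
#'
#' @inheritParams tal2mni
#' @param method `"lacadie"` (default) or a 4x4 matrix mapping MNI mm to
#'   Talairach mm.
#' @return coordinate(s) in Talairach mm.
#' @export
mni2tal <- function(coord, method = "lacadie") {
  M <- if (is.matrix(method) && all(dim(method) == c(4, 4))) method
       else if (identical(method, "lacadie")) .lacadie_mni2tal
       else stop("unknown mni2tal method")
  .apply_xfm(M, coord)
}

#' Build a 27-voxel cube node around an MNI coordinate
#'
#' The node is the 3x3x3 voxel block centered on the voxel nearest
#' `center_mni` under `affine`. The nearest voxel uses round-half-away-from-
#' zero on the fractional voxel coordinate, so centers exactly between two
#' voxels resolve deterministically away from the grid origin.
#'
#' @param center_mni length-3 mm coordinate of the node center.
#' @param affine 4x4 voxel(0-based)-to-mm map of the target grid.
#' @param grid_shape integer vector of 3 grid dimensions.
#' @param name optional node label.
#' @return an object of class `fc_node`: list with `name`, `center_mni`,
#'   `center_voxel` (0-based), and `voxel_cube` (27 x 3 matrix of 0-based
#'   voxel indices, lexicographic by (x, y, z)).
#' @export
build_node_cube <- function(center_mni, affine, grid_shape, name = NULL) {
  vox <- drop(mm_to_voxel(affine, center_mni))
  cv <- round_half_away(vox)
  label <- if (is.null(name)) paste(signif(center_mni, 4), collapse = ",") else name
  if (any(cv - 1 < 0) || any(cv + 1 > grid_shape - 1))
    stop("node cube for '", label, "' is clipped by the grid boundary ",
         "(center voxel ", paste(cv, collapse = ","), ", grid ",
         paste(grid_shape, collapse = "x"), ")")
  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))[, 3:1]
  cube <- sweep(offs, 2, cv, `+`)
  cube <- cube[order(cube[, 1], cube[, 2], cube[, 3]), , drop = FALSE]
  dimnames(cube) <- list(NULL, c("x", "y", "z"))
  structure(list(name = name, center_mni = as.numeric(center_mni),
                 center_voxel = as.integer(cv), voxel_cube = cube),
            class = "fc_node")
}

#' Build all nodes of a node table
#'
#' @param node_table data frame with columns `name`, `x`, `y`, `z`, `space`
#'   (`"MNI"` or `"TAL"`; Talairach rows are converted with [tal2mni()]).
#' @param affine 4x4 voxel-to-mm map.
#' @param grid_shape grid dimensions.
#' @param tal_method transform passed to [tal2mni()].
#' @return named list of `fc_node` objects, in node-table order.
#' @export
build_nodes <- function(node_table, affine, grid_shape, tal_method = "lacadie") {
  node_table <- validate_node_table(node_table)
  nodes <- lapply(seq_len(nrow(node_table)), function(i) {
    mm <- as.numeric(node_table[i, c("x", "y", "z")])
    if (toupper(node_table$space[i]) == "TAL") mm <- tal2mni(mm, method = tal_method)
    build_node_cube(mm, affine, grid_shape, name = node_table$name[i])
  })
  names(nodes) <- node_table$name
  nodes
}

validate_node_table <- function(node_table) {
  req <- c("name", "x", "y", "z")
  if (!all(req %in% names(node_table)))
    stop("node table must have columns name, x, y, z (and optionally space)")
  if (is.null(node_table$space)) node_table$space <- "MNI"
  if (anyDuplicated(node_table$name))
    stop("node names must be unique")
  node_table
}

#' Extract the voxel-wise time-series block of a node
#'
#' @param bold_run 4D array (or `RNifti` image) of BOLD data, x-y-z-time.
#' @param node an `fc_node` from [build_node_cube()].
#' @return 27 x n_volumes matrix; rows follow the node's lexicographic voxel
#'   order, row names `"x_y_z"` (0-based voxel indices).
#' @export
extract_block <- function(bold_run, node) {
  arr <- if (is.array(bold_run)) bold_run else as.array(bold_run)
  stopifnot(length(dim(arr)) == 4)
  dims <- dim(arr)[1:3]
  cube <- node$voxel_cube
  if (any(cube < 0) || any(sweep(cube, 2, dims - 1, `>`)))
    stop("node cube for '", node$name, "' lies outside the image grid")
  nt <- dim(arr)[4]
  block <- matrix(0, nrow(cube), nt)
  for (r in seq_len(nrow(cube)))
    block[r, ] <- arr[cube[r, 1] + 1, cube[r, 2] + 1, cube[r, 3] + 1, ]
  rownames(block) <- apply(cube, 1, paste, collapse = "_")
  block
}

#' Read / write a node table CSV
#'
#' Node tables have columns `name, x, y, z, space` with coordinates in mm and
#' `space` in `{MNI, TAL}`. [write_node_table()] fills both spaces (columns
#' `x_mni..z_mni` and `x_tal..z_tal`) using the Lacadie-style transform.
#'
#' @param path CSV file path.
#' @return data frame of node specifications.
#' @export
read_node_table <- function(path) {
  validate_node_table(read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_node_table
#' @param node_table node table data frame.
#' @export
write_node_table <- function(node_table, path) {
  node_table <- validate_node_table(node_table)
  xyz <- as.matrix(node_table[, c("x", "y", "z")])
  is_tal <- toupper(node_table$space) == "TAL"
  mni <- xyz; tal <- xyz
  if (any(is_tal)) mni[is_tal, ] <- rbind(tal2mni(xyz[is_tal, , drop = FALSE]))
  if (any(!is_tal)) tal[!is_tal, ] <- rbind(mni2tal(xyz[!is_tal, , drop = FALSE]))
  out <- data.frame(name = node_table$name,
                    x = mni[, 1], y = mni[, 2], z = mni[, 3], space = "MNI",
                    x_tal = tal[, 1], y_tal = tal[, 2], z_tal = tal[, 3])
  write.csv(out, path, row.names = FALSE)
  invisible(out)
}

#' Synthetic 16-node table
#'
#' A fixture node table for simulation and tests: the 16 region labels of the
#' subjective-recollection network with synthetic MNI coordinates laid out on
#' a 15-mm lattice (the true meta-analytic peak coordinates are not
#' redistributed here; any valid, non-overlapping set of centers exercises
#' the geometry identically). Coordinates fit both the default 64x64x32 and
#' the compact 24x24x16 test grids at 3 mm.
#'
#' @return data frame with columns `name, x, y, z, space`.
#' @export
synthetic_node_table <- function() {
  names16 <- c(
    "Parahippocampal_Gyrus_R", "Parahippocampal_Gyrus/Hippocampus_L",
    "Postcentral_Gyrus_L", "Precentral_Gyrus_R", "Angular_Gyrus_L",
    "Precuneus_L", "Medial_Frontal_Gyrus/Anterior_Cingulate_L",
    "Middle_Temporal_Gyrus_R_#1", "Middle_Temporal_Gyrus_R_#2",
    "Cerebellum_R", "Inferior_Temporal_Gyrus_L",
    "Inferior_Parietal_Lobule_L", "Fusiform_Gyrus_L",
    "Superior_Temporal_Gyrus_L", "Inferior_Frontal_Gyrus_R",
    "Parahippocampal_Gyrus_L")
  lat <- c(-22.5, -7.5, 7.5, 22.5)
  grid <- expand.grid(y = lat, x = lat)   # x slowest: row-major over (x, y)
  data.frame(name = names16, x = grid$x, y = grid$y, z = 1.5,
             space = "MNI", stringsAsFactors = FALSE)
}

#' Write a NIfTI mask of all node cubes (for visual QC)
#'
#' Voxels of node i get value i; background is 0.
#'
#' @param nodes list of `fc_node` objects.
#' @param grid_shape grid dimensions.
#' @param affine 4x4 voxel-to-mm map.
#' @param path output NIfTI path.
#' @export
write_node_mask <- function(nodes, grid_shape, affine, path) {
  mask <- array(0L, dim = grid_shape)
  for (i in seq_along(nodes)) {
    cube <- nodes[[i]]$voxel_cube + 1
    mask[cube] <- i
  }
  img <- RNifti::asNifti(mask)
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}
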