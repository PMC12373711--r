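#' The seven canonical resting-state networks
#'
#' Network labels used throughout the package, in the canonical order:
#' visual, somatomotor, dorsal attention, ventral attention, limbic,
#' frontoparietal, default. Regions not assigned to any of the seven carry
#' the label \code{"unassigned"} and are excluded from network-level
#' computation.
#'
#' @format Character vector of length 7.
#' @export
YEO7_NETWORKS <- c("visual", "somatomotor", "dorsal_attention",
                   "ventral_attention", "limbic", "frontoparietal", "default")

VALID_NETWORKS <- c(YEO7_NETWORKS, "unassigned")

#' Construct an atlas definition
#'
#' An atlas definition is the spatial vocabulary of every analysis stage: a
#' region catalogue (id, name, abbreviation, network membership) plus an
#' optional integer label volume with its voxel-to-world (MNI mm) affine.
#'
#' @param regions data.frame with columns \code{id} (unique positive
#'   integers), \code{name}, \code{abbreviation} (nonempty short codes) and
#'   \code{network} (one of the seven canonical networks or
#'   \code{"unassigned"}).
#' @param label_volume optional 3-D integer array; 0 is background, every
#'   nonzero value must appear in \code{regions$id}.
#' @param affine optional 4x4 voxel-to-mm transform (NIfTI convention: R
#'   voxel index \code{(i,j,k)} maps through \code{affine \%*\% c(i-1, j-1,
#'   k-1, 1)}).
#' @return An object of class \code{atlas_definition} with fields
#'   \code{regions}, \code{label_volume}, \code{affine} and, when a volume is
#'   present, \code{voxel_counts} (named by region id).
#' @export
atlas_definition <- function(regions, label_volume = NULL, affine = NULL) {
  stopifnot(is.data.frame(regions))
  required <- c("id", "name", "abbreviation", "network")
  missing_cols <- setdiff(required, names(regions))
  if (length(missing_cols) > 0L)
    stop("region table lacks column(s): ", paste(missing_cols, collapse = ", "))
  regions <- as.data.frame(regions)[, required]
  regions$id <- as.integer(regions$id)
  regions$name <- as.character(regions$name)
  regions$abbreviation <- as.character(regions$abbreviation)
  regions$network <- as.character(regions$network)

  if (anyNA(regions$id) || any(regions$id < 1L))
    stop("region ids must be positive integers")
  if (anyDuplicated(regions$id))
    stop("region ids must be unique")
  if (any(!nzchar(regions$abbreviation)))
    stop("region abbreviations must be nonempty")
  if (anyDuplicated(regions$abbreviation))
    stop("region abbreviations must be unique")
  bad_net <- setdiff(unique(regions$network), VALID_NETWORKS)
  if (length(bad_net) > 0L)
    stop("unknown network label(s): ", paste(bad_net, collapse = ", "),
         " (expected one of ", paste(VALID_NETWORKS, collapse = ", "), ")")

  voxel_counts <- NULL
  if (!is.null(label_volume)) {
    if (length(dim(label_volume)) != 3L)
      stop("label volume must be a 3-D array")
    label_volume <- coerce_integer_labels(label_volume)
    labs <- label_volume[label_volume != 0L]
    present <- sort(unique(labs))
    orphan <- setdiff(present, regions$id)
    if (length(orphan) > 0L)
      stop("label volume contains label(s) absent from the region table: ",
           paste(orphan, collapse = ", "))
    counts <- tabulate(labs, nbins = max(regions$id))
    voxel_counts <- counts[regions$id]
    names(voxel_counts) <- regions$id
    empty <- regions$id[voxel_counts == 0L]
    if (length(empty) > 0L)
      warning("region id(s) with no voxels in the label volume: ",
              paste(empty, collapse = ", "))
    if (is.null(affine)) affine <- diag(4)
    stopifnot(is.matrix(affine), all(dim(affine) == c(4L, 4L)))
  }

  structure(list(regions = regions, label_volume = label_volume,
                 affine = affine, voxel_counts = voxel_counts),
            class = "atlas_definition")
}

# Label volumes must be integer after load; floats are accepted only when
# they sit within 1e-6 of an integer (NIfTI files often store labels as
# float32).
coerce_integer_labels <- function(vol) {
  d <- dim(vol)
  v <- as.vector(vol)
  if (!is.integer(v)) {
    r <- round(v)
    if (max(abs(v - r)) > 1e-6)
      stop("label volume is not integer-valued")
    v <- as.integer(r)
  }
  array(v, dim = d)
}

#' @export
print.atlas_definition <- function(x, ...) {
  cat("Atlas definition:", nrow(x$regions), "regions,",
      length(setdiff(unique(x$regions$network), "unassigned")),
      "networks", if (is.null(x$label_volume)) "(catalogue only)" else
        paste0("(label volume ", paste(dim(x$label_volume), collapse = "x"), ")"),
      "\n")
  invisible(x)
}

#' Load an atlas from a NIfTI label volume and a region table
#'
#' @param label_volume_path path to a NIfTI (.nii or .nii.gz) integer label
#'   volume.
#' @param region_table_path path to a tab-separated region table with header
#'   \code{id name abbreviation network}.
#' @return An \code{\link{atlas_definition}} with voxel counts populated.
#'   Regions listed in the table but absent from the volume get a voxel
#'   count of 0 and a warning; a nonzero label in the volume that is missing
#'   from the table is a hard error naming the label.
#' @export
load_atlas <- function(label_volume_path, region_table_path) {
  img <- RNifti::readNifti(label_volume_path)
  affine <- unclass(RNifti::xform(img))
  attributes(affine) <- list(dim = dim(affine))
  regions <- utils::read.delim(region_table_path, sep = "\t",
                               stringsAsFactors = FALSE)
  atlas_definition(regions, label_volume = array(as.vector(img), dim = dim(img)),
                   affine = affine)
}

#' Write an atlas to a NIfTI label volume and a TSV region table
#'
#' Inverse of \code{\link{load_atlas}}; writing then loading reproduces the
#' catalogue exactly and the TSV byte-for-byte on a second round trip.
#'
#' @param atlas an \code{atlas_definition} with a label volume.
#' @param label_volume_path,region_table_path output paths.
#' @return Invisibly, the two paths.
#' @export
write_atlas <- function(atlas, label_volume_path, region_table_path) {
  stopifnot(inherits(atlas, "atlas_definition"))
  if (is.null(atlas$label_volume))
    stop("atlas has no label volume")
  img <- RNifti::asNifti(atlas$label_volume)
  vox <- sqrt(colSums(atlas$affine[1:3, 1:3]^2))
  RNifti::pixdim(img) <- vox
  RNifti::sform(img) <- structure(atlas$affine, code = 2L)
  RNifti::qform(img) <- structure(atlas$affine, code = 2L)
  RNifti::writeNifti(img, label_volume_path)
  utils::write.table(atlas$regions, region_table_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(label_volume_path, region_table_path))
}

#' Binary mask of one network
#'
#' @param atlas an \code{atlas_definition} with a label volume.
#' @param network one of the seven canonical network labels (or
#'   \code{"unassigned"}).
#' @return Logical 3-D array, TRUE exactly where the voxel's region belongs
#'   to the network. Masks of different networks are disjoint because each
#'   region belongs to exactly one network.
#' @export
network_mask <- function(atlas, network) {
  stopifnot(inherits(atlas, "atlas_definition"))
  if (is.null(atlas$label_volume))
    stop("atlas has no label volume")
  if (!(network %in% VALID_NETWORKS))
    stop("unknown network: ", network)
  ids <- atlas$regions$id[atlas$regions$network == network]
  array(atlas$label_volume %in% ids & atlas$label_volume != 0L,
        dim = dim(atlas$label_volume))
}

#' Region ids belonging to a network
#' @keywords internal
network_region_ids <- function(atlas, network) {
  atlas$regions$id[atlas$regions$network == network]
}

#' Build a small deterministic fixture atlas
#'
#' Packs \code{7 * regions_per_network} cuboid regions into a 3-D grid, one
#' region per lattice cell with a one-voxel background margin so regions are
#' disjoint and non-adjacent, assigns ids 1..n sequentially to the seven
#' networks in canonical order, and attaches an MNI-like affine (3 mm
#' isotropic voxels, x axis flipped, origin at the grid centre). The seed
#' fixes the random placement of regions on the lattice; the catalogue is
#' the same for every seed.
#'
#' @param grid_shape integer 3-vector, the label-volume dimensions.
#' @param regions_per_network regions in each of the 7 networks.
#' @param seed integer seed; identical seeds give identical atlases.
#' @return An \code{atlas_definition}. Errors if the grid cannot hold the
#'   requested number of regions with at least one voxel each.
#' @export
make_fixture_atlas <- function(grid_shape = c(24L, 24L, 24L),
                               regions_per_network = 2L, seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 1L),
            regions_per_network >= 1L)
  n_regions <- 7L * regions_per_network

  # lattice of cells, each holding one region in its interior
  k <- ceiling(n_regions^(1 / 3))
  cells <- NULL
  repeat {
    per_axis <- pmin(k, grid_shape)
    if (prod(per_axis) >= n_regions) {
      cell_size <- grid_shape %/% per_axis
      # interior after a 1-voxel margin on each side where the cell allows it
      inner <- pmax(cell_size - 2L, pmin(cell_size, 1L))
      if (all(cell_size >= 1L) && all(inner >= 1L)) {
        cells <- list(per_axis = per_axis, cell_size = cell_size,
                      inner = inner)
        break
      }
    }
    k <- k + 1L
    if (any(k > grid_shape) && prod(pmin(k, grid_shape)) < n_regions)
      stop("cannot pack ", n_regions, " regions into a ",
           paste(grid_shape, collapse = "x"), " grid")
  }

  per_axis <- cells$per_axis
  cell_size <- cells$cell_size
  inner <- cells$inner
  cell_index <- expand.grid(i = seq_len(per_axis[1]) - 1L,
                            j = seq_len(per_axis[2]) - 1L,
                            k = seq_len(per_axis[3]) - 1L)

  set.seed(seed)
  slots <- sample(nrow(cell_index), n_regions)

  vol <- array(0L, dim = grid_shape)
  for (r in seq_len(n_regions)) {
    cell <- as.integer(cell_index[slots[r], ])
    lo <- cell * cell_size + 1L
    margin <- as.integer(cell_size > 2L)
    start <- lo + margin
    end <- start + inner - 1L
    vol[start[1]:end[1], start[2]:end[2], start[3]:end[3]] <- r
  }

  net <- rep(YEO7_NETWORKS, each = regions_per_network)
  within <- rep(seq_len(regions_per_network), times = 7L)
  abbrev_stub <- c("VIS", "SMN", "DAN", "VAN", "LIM", "FPN", "DMN")
  regions <- data.frame(
    id = seq_len(n_regions),
    name = paste0(gsub("_", " ", net), " region ", within),
    abbreviation = paste0(rep(abbrev_stub, each = regions_per_network),
                          "_", within),
    network = net,
    stringsAsFactors = FALSE
  )

  # MNI-like: 3 mm voxels, radiological x flip, origin at grid centre
  centre <- (grid_shape - 1) / 2
  affine <- diag(c(-3, 3, 3, 1))
  affine[1:3, 4] <- c(3, -3, -3) * centre

  atlas_definition(regions, label_volume = vol, affine = affine)
}
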