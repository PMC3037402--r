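#' @import methods
NULL

#' Sampling grid of an image series
#'
#' Describes the voxel raster on which all volumes of an analysis live:
#' the matrix size, the voxel edge lengths in millimetres, the repetition
#' time of the functional acquisition, and the world-space position of the
#' first voxel. The voxel-to-world mapping is the diagonal affine
#' `world = origin + (index - 1) * voxelSize`, applied per axis.
#'
#' @slot dims integer(3), voxels along x, y, z.
#' @slot voxelSize numeric(3), voxel edge lengths in mm.
#' @slot TR numeric(1), repetition time in seconds.
#' @slot origin numeric(3), world coordinate (mm) of voxel (1, 1, 1).
#' @export
setClass("GridSpec", representation(
  dims = "integer", voxelSize = "numeric", TR = "numeric", origin = "numeric"
))

setValidity("GridSpec", function(object) {
  msg <- character()
  if (length(object@dims) != 3L || any(object@dims < 1L)) {
    msg <- c(msg, "dims must be three integers >= 1")
  }
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0)) {
    msg <- c(msg, "voxelSize must be three positive lengths (mm)")
  }
  if (length(object@TR) != 1L || object@TR <= 0) {
    msg <- c(msg, "TR must be a single positive number (s)")
  }
  if (length(object@origin) != 3L || any(!is.finite(object@origin))) {
    msg <- c(msg, "origin must be three finite coordinates (mm)")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GridSpec
#'
#' @param dims integer(3) matrix size (x, y, z).
#' @param voxelSize numeric(3) voxel edge lengths in mm.
#' @param TR repetition time in seconds.
#' @param origin world coordinate (mm) of the first voxel.
#' @return A [GridSpec-class] object.
#' @examples
#' gridSpec(c(53L, 63L, 35L), c(3, 3, 4), TR = 3)
#' @export
gridSpec <- function(dims, voxelSize = c(3, 3, 4), TR = 3, origin = c(0, 0, 0)) {
  new("GridSpec", dims = as.integer(dims), voxelSize = as.numeric(voxelSize),
      TR = as.numeric(TR), origin = as.numeric(origin))
}

#' 4D functional image series
#'
#' The raster currency of the pipeline: a voxel time series on a
#' [GridSpec-class], stored as an x-by-y-by-z-by-time array, together
#' with per-subject metadata (identifier and mean head motion, used
#' downstream as a confounding covariate).
#'
#' @slot data numeric 4D array, dims `c(grid@dims, T)`.
#' @slot grid the sampling [GridSpec-class].
#' @slot subjectId character(1) subject identifier.
#' @slot meanMotion numeric(1) mean of the six realignment parameters (a.u.).
#' @export
setClass("Image4D", representation(
  data = "array", grid = "GridSpec", subjectId = "character",
  meanMotion = "numeric"
))

setValidity("Image4D", function(object) {
  d <- dim(object@data)
  msg <- character()
  if (length(d) != 4L) {
    msg <- c(msg, "data must be a 4D array (x, y, z, time)")
  } else {
    if (!identical(d[1:3], object@grid@dims)) {
      msg <- c(msg, "spatial dims of data must match grid dims")
    }
    if (d[4L] < 2L) msg <- c(msg, "time dimension must have length >= 2")
  }
  if (!all(is.finite(object@data))) msg <- c(msg, "data must be finite")
  if (length(msg)) msg else TRUE
})

#' Construct an Image4D
#'
#' @param data 4D numeric array (x, y, z, time).
#' @param grid a [GridSpec-class]; its dims must match `dim(data)[1:3]`.
#' @param subjectId subject identifier.
#' @param meanMotion mean motion scalar for the subject (a.u.).
#' @return An [Image4D-class].
#' @export
image4D <- function(data, grid, subjectId = "s1", meanMotion = 0) {
  new("Image4D", data = data, grid = grid, subjectId = as.character(subjectId),
      meanMotion = as.numeric(meanMotion))
}

#' Group ICA decomposition
#'
#' Holds the result of group spatial ICA: Z-scored group component maps,
#' the group mixing matrix with its per-subject block structure, and the
#' back-reconstructed per-subject maps and time courses. The `stability`
#' slot stores the per-component ICASSO-style reliability index (NA until
#' computed).
#'
#' @slot groupMaps K x N matrix of Z-scored group spatial maps.
#' @slot mixing M x K group mixing matrix (M = subjects x C).
#' @slot timecourses list (one per subject) of time x K matrices.
#' @slot subjectMaps list (one per subject) of K x N matrices.
#' @slot K integer component count.
#' @slot reducedDim integer per-subject retained PCA dimensionality (C).
#' @slot subjects character vector of subject identifiers (block order).
#' @slot stability numeric(K) per-component stability index in [-1, 1].
#' @slot grid the [GridSpec-class] the maps live on.
#' @slot mask logical 3D array of in-analysis voxels (columns of the maps).
#' @slot converged logical(1), Infomax convergence status.
#' @export
setClass("ComponentSet", representation(
  groupMaps = "matrix", mixing = "matrix", timecourses = "list",
  subjectMaps = "list", K = "integer", reducedDim = "integer", subjects = "character",
  stability = "numeric", grid = "GridSpec", mask = "array",
  converged = "logical"
))

setValidity("ComponentSet", function(object) {
  msg <- character()
  K <- object@K
  if (nrow(object@groupMaps) != K) msg <- c(msg, "groupMaps must have K rows")
  if (ncol(object@mixing) != K) msg <- c(msg, "mixing must have K columns")
  nS <- length(object@subjects)
  if (nS > 0L && nrow(object@mixing) != nS * object@reducedDim) {
    msg <- c(msg, "mixing rows must partition into subjects x C blocks")
  }
  if (length(object@stability) != K) {
    msg <- c(msg, "stability must have one entry per component")
  }
  ok <- is.na(object@stability) |
    (object@stability >= -1 - 1e-9 & object@stability <= 1 + 1e-9)
  if (!all(ok)) msg <- c(msg, "stability indices must lie in [-1, 1]")
  if (length(msg)) msg else TRUE
})

#' Voxelwise statistic map
#'
#' A statistic volume with matching p-values, a cluster-label volume
#' (6-face connectivity) and a table of clusters surviving the extent and
#' family-wise-error rules.
#'
#' @slot tValues numeric 3D array of statistics (0 outside the mask).
#' @slot pValues numeric 3D array of p-values (1 outside the mask).
#' @slot clusterLabels integer 3D array, 0 = background.
#' @slot clusters data.frame: label, extent, peak world coordinates,
#'   peak statistic, FWE-corrected p, significance flag.
#' @slot grid the [GridSpec-class].
#' @slot df numeric(1) degrees of freedom of the statistic.
#' @export
setClass("StatMap", representation(
  tValues = "array", pValues = "array", clusterLabels = "array",
  clusters = "data.frame", grid = "GridSpec", df = "numeric"
))

setValidity("StatMap", function(object) {
  msg <- character()
  if (!identical(dim(object@tValues), object@grid@dims)) {
    msg <- c(msg, "tValues dims must match grid")
  }
  if (!identical(dim(object@pValues), object@grid@dims)) {
    msg <- c(msg, "pValues dims must match grid")
  }
  if (length(msg)) msg else TRUE
})

#' Seed voxels of a cortical region
#'
#' Voxels at the grey-matter/white-matter interface of a region of
#' interest, used as streamline starting points.
#'
#' @slot roiName region-of-interest identifier.
#' @slot coords integer matrix (n x 3) of 1-based voxel indices.
#' @slot subjectId subject identifier.
#' @slot hemisphere "L", "R" or "" (used for contralateral exclusions).
#' @slot grid the [GridSpec-class] of the segmentation volumes.
#' @export
setClass("SeedSet", representation(
  roiName = "character", coords = "matrix", subjectId = "character",
  hemisphere = "character", grid = "GridSpec"
))

setValidity("SeedSet", function(object) {
  msg <- character()
  if (ncol(object@coords) != 3L) msg <- c(msg, "coords must be n x 3")
  if (nrow(object@coords) > 0L) {
    inside <- object@coords >= 1L &
      object@coords <= matrix(object@grid@dims, nrow(object@coords), 3L, byrow = TRUE)
    if (!all(inside)) msg <- c(msg, "all seed coordinates must lie inside the grid")
  }
  if (length(msg)) msg else TRUE
})

#' Seed-by-region connectivity profile matrix
#'
#' Rows are seeds (with subject provenance), columns are atlas regions,
#' entries are nonnegative streamline visitation counts summed within each
#' region. Seed-containing and contralateral regions are excluded at
#' construction.
#'
#' @slot counts numeric matrix, seeds x regions, nonnegative.
#' @slot seedInfo data.frame with one row per seed: subject, roi,
#'   hemisphere and (for synthetic cohorts) the planted cluster label.
#' @slot regionInfo data.frame with one row per retained region: name,
#'   hemisphere.
#' @export
setClass("ProfileMatrix", representation(
  counts = "matrix", seedInfo = "data.frame", regionInfo = "data.frame"
))

setValidity("ProfileMatrix", function(object) {
  msg <- character()
  if (any(object@counts < 0)) msg <- c(msg, "counts must be nonnegative")
  if (nrow(object@seedInfo) != nrow(object@counts)) {
    msg <- c(msg, "seedInfo must have one row per seed")
  }
  if (nrow(object@regionInfo) != ncol(object@counts)) {
    msg <- c(msg, "regionInfo must have one row per region column")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a ProfileMatrix
#'
#' @param counts seeds x regions nonnegative count matrix.
#' @param seedInfo data.frame of per-seed provenance (subject, roi,
#'   hemisphere, trueLabel); defaults are filled when omitted.
#' @param regionInfo data.frame of per-region metadata (name, hemisphere);
#'   defaults to the column names of `counts`.
#' @return A [ProfileMatrix-class].
#' @export
profileMatrix <- function(counts, seedInfo = NULL, regionInfo = NULL) {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("region%02d", seq_len(ncol(counts)))
  }
  if (is.null(seedInfo)) {
    seedInfo <- data.frame(
      subject = rep("s1", nrow(counts)), roi = rep("roi", nrow(counts)),
      hemisphere = rep("", nrow(counts)), trueLabel = rep(NA_integer_, nrow(counts)),
      stringsAsFactors = FALSE
    )
  }
  if (is.null(regionInfo)) {
    regionInfo <- data.frame(name = colnames(counts),
                             hemisphere = rep("", ncol(counts)),
                             stringsAsFactors = FALSE)
  }
  new("ProfileMatrix", counts = counts, seedInfo = seedInfo, regionInfo = regionInfo)
}

#' Connectivity-based parcellation of a seed set
#'
#' The output of silhouette-guided k-means on a [ProfileMatrix-class]:
#' per-seed labels, cluster centroid profiles, the mean-silhouette curve
#' over the candidate cluster numbers, the selected number of clusters,
#' and per-subject seed counts per cluster.
#'
#' @slot labels integer per-seed cluster assignment (1..chosenK).
#' @slot centroids chosenK x regions matrix of centroid profiles.
#' @slot silhouetteCurve named numeric, mean silhouette per candidate k.
#' @slot chosenK integer, argmax of the curve (NA when no structure).
#' @slot noStructure logical(1), TRUE when clustering found no support.
#' @slot seedCounts subjects x clusters matrix of per-subject seed counts.
#' @slot group character(1) cohort label.
#' @export
setClass("ParcellationResult", representation(
  labels = "integer", centroids = "matrix", silhouetteCurve = "numeric",
  chosenK = "integer", noStructure = "logical", seedCounts = "matrix",
  group = "character"
))

setValidity("ParcellationResult", function(object) {
  msg <- character()
  if (!object@noStructure && length(object@labels)) {
    k <- object@chosenK
    if (is.na(k)) msg <- c(msg, "chosenK must be set unless noStructure")
    else if (any(object@labels < 1L | object@labels > k)) {
      msg <- c(msg, "labels must lie in 1..chosenK")
    }
  }
  if (length(msg)) msg else TRUE
})
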