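#' @include AllClasses.R
NULL

#' Accessors for pipeline objects
#'
#' Small accessor generics used throughout the package in preference to
#' direct slot access.
#'
#' @param x an object of the documented class.
#' @param value replacement value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("gridDims", function(x) standardGeneric("gridDims"))
#' @rdname accessors
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))
#' @rdname accessors
#' @export
setGeneric("repetitionTime", function(x) standardGeneric("repetitionTime"))
#' @rdname accessors
#' @export
setGeneric("imgData", function(x) standardGeneric("imgData"))
#' @rdname accessors
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))
#' @rdname accessors
#' @export
setGeneric("meanMotion", function(x) standardGeneric("meanMotion"))
#' @rdname accessors
#' @export
setGeneric("componentMaps", function(x) standardGeneric("componentMaps"))
#' @rdname accessors
#' @export
setGeneric("mixingMatrix", function(x) standardGeneric("mixingMatrix"))
#' @rdname accessors
#' @export
setGeneric("timecourses", function(x) standardGeneric("timecourses"))
#' @rdname accessors
#' @export
setGeneric("subjectMaps", function(x) standardGeneric("subjectMaps"))
#' @rdname accessors
#' @export
setGeneric("nComponents", function(x) standardGeneric("nComponents"))
#' @rdname accessors
#' @export
setGeneric("stabilityIndex", function(x) standardGeneric("stabilityIndex"))
#' @rdname accessors
#' @export
setGeneric("stabilityIndex<-", function(x, value) standardGeneric("stabilityIndex<-"))
#' @rdname accessors
#' @export
setGeneric("statValues", function(x) standardGeneric("statValues"))
#' @rdname accessors
#' @export
setGeneric("clusterTable", function(x) standardGeneric("clusterTable"))
#' @rdname accessors
#' @export
setGeneric("profileCounts", function(x) standardGeneric("profileCounts"))
#' @rdname accessors
#' @export
setGeneric("seedInfo", function(x) standardGeneric("seedInfo"))
#' @rdname accessors
#' @export
setGeneric("regionNames", function(x) standardGeneric("regionNames"))
#' @rdname accessors
#' @export
setGeneric("chosenK", function(x) standardGeneric("chosenK"))
#' @rdname accessors
#' @export
setGeneric("silhouetteCurve", function(x) standardGeneric("silhouetteCurve"))
#' @rdname accessors
#' @export
setGeneric("centroids", function(x) standardGeneric("centroids"))
#' @rdname accessors
#' @export
setGeneric("clusterAssignments", function(x) standardGeneric("clusterAssignments"))
#' @rdname accessors
#' @export
setGeneric("seedCounts", function(x) standardGeneric("seedCounts"))
#' @rdname accessors
#' @export
setGeneric("seedCoords", function(x) standardGeneric("seedCoords"))

#' @rdname accessors
#' @export
setMethod("gridDims", "GridSpec", function(x) x@dims)
#' @rdname accessors
#' @export
setMethod("gridDims", "Image4D", function(x) x@grid@dims)
#' @rdname accessors
#' @export
setMethod("voxelSize", "GridSpec", function(x) x@voxelSize)
#' @rdname accessors
#' @export
setMethod("voxelSize", "Image4D", function(x) x@grid@voxelSize)
#' @rdname accessors
#' @export
setMethod("repetitionTime", "GridSpec", function(x) x@TR)
#' @rdname accessors
#' @export
setMethod("repetitionTime", "Image4D", function(x) x@grid@TR)
#' @rdname accessors
#' @export
setMethod("imgData", "Image4D", function(x) x@data)
#' @rdname accessors
#' @export
setMethod("subjectId", "Image4D", function(x) x@subjectId)
#' @rdname accessors
#' @export
setMethod("meanMotion", "Image4D", function(x) x@meanMotion)
#' @rdname accessors
#' @export
setMethod("componentMaps", "ComponentSet", function(x) x@groupMaps)
#' @rdname accessors
#' @export
setMethod("mixingMatrix", "ComponentSet", function(x) x@mixing)
#' @rdname accessors
#' @export
setMethod("timecourses", "ComponentSet", function(x) x@timecourses)
#' @rdname accessors
#' @export
setMethod("subjectMaps", "ComponentSet", function(x) x@subjectMaps)
#' @rdname accessors
#' @export
setMethod("nComponents", "ComponentSet", function(x) x@K)
#' @rdname accessors
#' @export
setMethod("stabilityIndex", "ComponentSet", function(x) x@stability)
#' @rdname accessors
#' @export
setReplaceMethod("stabilityIndex", "ComponentSet", function(x, value) {
  x@stability <- as.numeric(value)
  validObject(x)
  x
})
#' @rdname accessors
#' @export
setMethod("statValues", "StatMap", function(x) x@tValues)
#' @rdname accessors
#' @export
setMethod("clusterTable", "StatMap", function(x) x@clusters)
#' @rdname accessors
#' @export
setMethod("profileCounts", "ProfileMatrix", function(x) x@counts)
#' @rdname accessors
#' @export
setMethod("seedInfo", "ProfileMatrix", function(x) x@seedInfo)
#' @rdname accessors
#' @export
setMethod("regionNames", "ProfileMatrix", function(x) x@regionInfo$name)
#' @rdname accessors
#' @export
setMethod("chosenK", "ParcellationResult", function(x) x@chosenK)
#' @rdname accessors
#' @export
setMethod("silhouetteCurve", "ParcellationResult", function(x) x@silhouetteCurve)
#' @rdname accessors
#' @export
setMethod("centroids", "ParcellationResult", function(x) x@centroids)
#' @rdname accessors
#' @export
setMethod("clusterAssignments", "ParcellationResult", function(x) x@labels)
#' @rdname accessors
#' @export
setMethod("seedCounts", "ParcellationResult", function(x) x@seedCounts)
#' @rdname accessors
#' @export
setMethod("seedCoords", "SeedSet", function(x) x@coords)

#' Voxel/world coordinate conversion
#'
#' The grid's affine is diagonal: `world = origin + (index - 1) * voxelSize`.
#' Conversions are exact inverses of each other.
#'
#' @param grid a [GridSpec-class].
#' @param idx n x 3 matrix (or length-3 vector) of 1-based voxel indices.
#' @param xyz n x 3 matrix (or length-3 vector) of world coordinates (mm).
#' @return n x 3 matrix of converted coordinates.
#' @export
voxelToWorld <- function(grid, idx) {
  idx <- rbind_coords(idx)
  sweep(sweep(idx - 1, 2L, grid@voxelSize, "*"), 2L, grid@origin, "+")
}

#' @rdname voxelToWorld
#' @export
worldToVoxel <- function(grid, xyz) {
  xyz <- rbind_coords(xyz)
  sweep(sweep(xyz, 2L, grid@origin, "-"), 2L, grid@voxelSize, "/") + 1
}

rbind_coords <- function(x) {
  if (is.null(dim(x))) matrix(as.numeric(x), 1L, 3L) else {
    storage.mode(x) <- "double"
    x
  }
}

#' Voxel volume in cubic millimetres
#' @param grid a [GridSpec-class].
#' @return numeric(1), product of the voxel edge lengths.
#' @export
voxelVolume <- function(grid) prod(grid@voxelSize)

setMethod("show", "GridSpec", function(object) {
  cat(sprintf("GridSpec: %s voxels, %s mm, TR = %g s\n",
              paste(object@dims, collapse = "x"),
              paste(object@voxelSize, collapse = "x"), object@TR))
})

setMethod("show", "Image4D", function(object) {
  d <- dim(object@data)
  cat(sprintf("Image4D '%s': %dx%dx%d voxels x %d volumes (TR = %g s)\n",
              object@subjectId, d[1L], d[2L], d[3L], d[4L], object@grid@TR))
})

setMethod("show", "ComponentSet", function(object) {
  cat(sprintf("ComponentSet: K = %d components, %d subjects (C = %d), %s voxels in mask\n",
              object@K, length(object@subjects), object@reducedDim, sum(object@mask)))
  st <- object@stability
  if (any(!is.na(st))) {
    cat(sprintf("  stability index: %.2f - %.2f\n",
                min(st, na.rm = TRUE), max(st, na.rm = TRUE)))
  }
})

setMethod("show", "StatMap", function(object) {
  cat(sprintf("StatMap (%s voxels, df = %g): %d cluster(s), %d significant\n",
              paste(object@grid@dims, collapse = "x"), object@df,
              nrow(object@clusters),
              sum(object@clusters$significant %in% TRUE)))
})

setMethod("show", "SeedSet", function(object) {
  cat(sprintf("SeedSet '%s' (%s): %d seeds\n", object@roiName,
              object@subjectId, nrow(object@coords)))
})

setMethod("show", "ProfileMatrix", function(object) {
  cat(sprintf("ProfileMatrix: %d seeds x %d regions, %d subject(s)\n",
              nrow(object@counts), ncol(object@counts),
              length(unique(object@seedInfo$subject))))
})

setMethod("show", "ParcellationResult", function(object) {
  if (object@noStructure) {
    cat("ParcellationResult: no cluster structure detected\n")
  } else {
    cat(sprintf("ParcellationResult (%s): k = %d (mean silhouette %.3f)\n",
                object@group, object@chosenK,
                max(object@silhouetteCurve)))
  }
})
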