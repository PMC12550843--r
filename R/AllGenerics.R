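#' @include AllClasses.R
NULL

#' Number of frames in a per-frame container
#' @param x a ColvarTable, PuckerCoords, ConformerSeries or
#'   SyntheticTrajectory.
#' @return integer frame count.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Variable names of a collective-variable container
#' @param x a ColvarTable or SyntheticTrajectory.
#' @return character vector of column names.
#' @export
setGeneric("variableNames", function(x) standardGeneric("variableNames"))

#' Free-energy values of a profile or surface
#' @param x a FreeEnergyProfile or FreeEnergySurface.
#' @return numeric vector or matrix of delta-G (kJ/mol), NA where masked.
#' @export
setGeneric("deltaG", function(x) standardGeneric("deltaG"))

#' Block-averaged standard errors of a profile
#' @param x a FreeEnergyProfile.
#' @return numeric vector of SEM (kJ/mol).
#' @export
setGeneric("standardError", function(x) standardGeneric("standardError"))

#' Temperature associated with an object
#' @param x a FreeEnergyProfile, FreeEnergySurface or ReplicaLadder.
#' @return Kelvin.
#' @export
setGeneric("temperature", function(x) standardGeneric("temperature"))

#' Conformer strings of a labelled series
#' @param x a ConformerSeries.
#' @return character vector, NA for frames with missing angles.
#' @export
setGeneric("conformerStrings", function(x) standardGeneric("conformerStrings"))

#' Latent-space scores
#' @param x a LatentSpace.
#' @return frames x components numeric matrix.
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))

#' Latent-space loadings
#' @param x a LatentSpace.
#' @return features x components numeric matrix.
#' @export
setGeneric("featureLoadings", function(x) standardGeneric("featureLoadings"))

#' Explained-variance fractions
#' @param x a LatentSpace.
#' @return numeric vector, non-increasing.
#' @export
setGeneric("explainedVariance", function(x) standardGeneric("explainedVariance"))

#' Coerce a container to a data.frame
#' @param x object.
#' @param ... unused.
#' @export
setGeneric("asDataFrame", function(x, ...) standardGeneric("asDataFrame"))
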