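#' @include AllGenerics.R
NULL

#' @describeIn nFrames frames in a collective-variable table
#' @export
setMethod("nFrames", "ColvarTable", function(x) length(x@time))

#' @describeIn nFrames frames in a pucker-coordinate set
#' @export
setMethod("nFrames", "PuckerCoords", function(x) length(x@Q))

#' @describeIn nFrames frames in a conformer series
#' @export
setMethod("nFrames", "ConformerSeries", function(x) length(x@strings))

#' @describeIn nFrames frames in a synthetic trajectory
#' @export
setMethod("nFrames", "SyntheticTrajectory", function(x) length(x@colvar@time))

#' @describeIn variableNames columns of a collective-variable table
#' @export
setMethod("variableNames", "ColvarTable", function(x) colnames(x@values))

#' @describeIn variableNames columns of the generated table
#' @export
setMethod("variableNames", "SyntheticTrajectory",
          function(x) colnames(x@colvar@values))

#' @describeIn deltaG per-bin free energies of a 1D profile
#' @export
setMethod("deltaG", "FreeEnergyProfile", function(x) x@deltaG)

#' @describeIn deltaG free-energy grid of a 2D surface
#' @export
setMethod("deltaG", "FreeEnergySurface", function(x) x@deltaG)

#' @describeIn standardError block-averaged SEM per bin
#' @export
setMethod("standardError", "FreeEnergyProfile", function(x) x@sem)

#' @describeIn temperature of a 1D profile
#' @export
setMethod("temperature", "FreeEnergyProfile", function(x) x@temperature)

#' @describeIn temperature of a 2D surface
#' @export
setMethod("temperature", "FreeEnergySurface", function(x) x@temperature)

#' @describeIn temperature base temperature of a replica ladder
#' @export
setMethod("temperature", "ReplicaLadder", function(x) x@T0)

#' @describeIn conformerStrings per-frame strings
#' @export
setMethod("conformerStrings", "ConformerSeries", function(x) x@strings)

#' @describeIn scores latent-space scores
#' @export
setMethod("scores", "LatentSpace", function(x) x@scores)

#' @describeIn featureLoadings latent-space loadings
#' @export
setMethod("featureLoadings", "LatentSpace", function(x) x@loadings)

#' @describeIn explainedVariance variance fractions per component
#' @export
setMethod("explainedVariance", "LatentSpace", function(x) x@explained)

#' @describeIn asDataFrame time plus variable columns
#' @export
setMethod("asDataFrame", "ColvarTable", function(x, ...)
  data.frame(time = x@time, as.data.frame(x@values), check.names = FALSE))

#' @describeIn asDataFrame per-frame Q, theta, phi, definedPhi
#' @export
setMethod("asDataFrame", "PuckerCoords", function(x, ...)
  data.frame(Q = x@Q, theta = x@theta, phi = x@phi,
             definedPhi = x@definedPhi))

#' @describeIn asDataFrame per-replica ladder parameters
#' @export
setMethod("asDataFrame", "ReplicaLadder", function(x, ...)
  data.frame(replica = seq_along(x@lambda) - 1L, lambda = x@lambda,
             gamma = x@gamma, teff = x@teff, deltaT = x@deltaT,
             height = x@height))

#' @describeIn asDataFrame conformer distribution table
#' @export
setMethod("asDataFrame", "ConformerDistribution", function(x, ...) x@table)

setMethod("show", "ColvarTable", function(object) {
  cat(sprintf("ColvarTable: %d frames, %d variables\n",
              length(object@time), ncol(object@values)))
  if (ncol(object@values))
    cat("  variables:", paste(colnames(object@values), collapse = ", "), "\n")
  if (length(object@time))
    cat(sprintf("  time: %.6g .. %.6g ps\n",
                object@time[1], object@time[length(object@time)]))
})

setMethod("show", "PuckerCoords", function(object) {
  cat(sprintf("PuckerCoords: %d frames\n", length(object@Q)))
  if (length(object@Q))
    cat(sprintf("  mean Q = %.3f A, theta range [%.3f, %.3f] rad\n",
                mean(object@Q, na.rm = TRUE),
                suppressWarnings(min(object@theta, na.rm = TRUE)),
                suppressWarnings(max(object@theta, na.rm = TRUE))))
})

setMethod("show", "FreeEnergyProfile", function(object) {
  pop <- sum(!is.na(object@deltaG))
  cat(sprintf(
    "FreeEnergyProfile: %d bins (%d populated), T = %.2f K, %d blocks\n",
    length(object@centers), pop, object@temperature, object@nBlocks))
})

setMethod("show", "FreeEnergySurface", function(object) {
  cat(sprintf("FreeEnergySurface: %d x %d bins (%s vs %s), T = %.2f K\n",
              nrow(object@deltaG), ncol(object@deltaG),
              object@xname, object@yname, object@temperature))
  cat(sprintf("  populated cells: %d\n", sum(!is.na(object@deltaG))))
})

setMethod("show", "BasinMap", function(object) {
  cat(sprintf("BasinMap: %d dihedrals, %d bins, prominence %.3g kJ/mol\n",
              length(object@entries), object@bins, object@prominence))
  for (nm in names(object@entries))
    cat(sprintf("  %s: %s\n", nm,
                paste(object@entries[[nm]]$letters, collapse = " ")))
})

setMethod("show", "GlycanTopology", function(object) {
  cat(sprintf("GlycanTopology: %d residues, %d linkages, root '%s'\n",
              length(object@residues), nrow(object@linkages), object@root))
})

setMethod("show", "ConformerSeries", function(object) {
  ok <- !is.na(object@strings)
  cat(sprintf("ConformerSeries: %d frames (%d labelled), %d distinct\n",
              length(object@strings), sum(ok),
              length(unique(object@strings[ok]))))
})

setMethod("show", "ConformerDistribution", function(object) {
  cat(sprintf("ConformerDistribution: %d conformers, %d frames, minProb %.3g\n",
              nrow(object@table), object@nFrames, object@minProb))
  print(utils::head(object@table, 8), row.names = FALSE)
})

setMethod("show", "LatentSpace", function(object) {
  cat(sprintf("LatentSpace: %d frames x %d components (%d features)\n",
              nrow(object@scores), ncol(object@scores), nrow(object@loadings)))
  cat("  explained:", paste(sprintf("%.1f%%", 100 * object@explained[
        seq_len(min(4, length(object@explained)))]), collapse = ", "), "\n")
})

setMethod("show", "CorrelationMatrix", function(object) {
  cat(sprintf("CorrelationMatrix: %d x %d, n = %d frames\n",
              nrow(object@r), ncol(object@r), object@n))
})

setMethod("show", "ReplicaLadder", function(object) {
  cat(sprintf(
    "ReplicaLadder: %d replicas, T0 = %.2f K, Teff %.1f .. %.1f K\n",
    length(object@lambda), object@T0, min(object@teff), max(object@teff)))
  cat(sprintf("  tau = %g ps, tauG = %g ps, hill width = %g rad\n",
              object@tau, object@tauG, object@hillWidth))
})

setMethod("show", "SelectionConfig", function(object) {
  cat(sprintf("SelectionConfig: %d rings, %d linkages\n",
              length(object@rings), length(object@linkages)))
})

setMethod("show", "SyntheticConfig", function(object) {
  cat(sprintf(
    "SyntheticConfig: %d frames, %d conformer states, %d pucker states, c = %.2f\n",
    object@nFrames, length(object@states), length(object@puckerStates),
    object@coupling))
})

setMethod("show", "SyntheticTrajectory", function(object) {
  cat(sprintf("SyntheticTrajectory: %d frames, coupling c = %.2f\n",
              length(object@colvar@time), object@config@coupling))
})
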