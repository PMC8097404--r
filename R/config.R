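#' Analysis configuration
#'
#' Bundles every distance cutoff and binning parameter used across the
#' analyses, with the field's customary defaults: 6 A lipid-protein contact
#' cutoff, 4.0 A hydrophobic (carbon-carbon) cutoff, 3.5 A hydrogen-to-acceptor
#' hydrogen-bond cutoff, 4.0 A N-O salt-bridge cutoff, 1 A occupancy-grid
#' resolution, 0.5 A slab thickness along the bilayer normal, 3 A contact
#' shells for slab profiles, contour thresholds at 10/15/20/30% occupancy, and
#' a 500-ns running-average window.
#'
#' @param contactCutoff lipid-protein contact cutoff, Angstrom
#' @param hydrophobicCutoff carbon-carbon direct-contact cutoff, Angstrom
#' @param hbondCutoff hydrogen-to-acceptor cutoff, Angstrom
#' @param saltbridgeCutoff N-O cutoff, Angstrom
#' @param gridResolution occupancy-grid voxel size, Angstrom
#' @param slabThickness z-bin width for slab profiles, Angstrom
#' @param shellCutoff contact-shell radius for slab profiles, Angstrom
#' @param occupancyThresholds contour threshold fractions in (0, 1)
#' @param runningAverageWindow window for running averages, ns
#' @param binderPersistence fraction of frames a direct contact must persist
#'   for a residue to be called a binder residue
#' @param quantileType quantile convention for Q3/IQR (R `type`; 7 = linear
#'   interpolation between order statistics)
#' @param seed integer RNG seed
#' @return a named list of class `AnalysisConfig`
#' @export
analysisConfig <- function(contactCutoff = 6.0, hydrophobicCutoff = 4.0,
                           hbondCutoff = 3.5, saltbridgeCutoff = 4.0,
                           gridResolution = 1.0, slabThickness = 0.5,
                           shellCutoff = 3.0,
                           occupancyThresholds = c(0.10, 0.15, 0.20, 0.30),
                           runningAverageWindow = 500,
                           binderPersistence = 0.5,
                           quantileType = 7L, seed = 1L) {
  cfg <- list(contactCutoff = contactCutoff,
              hydrophobicCutoff = hydrophobicCutoff,
              hbondCutoff = hbondCutoff, saltbridgeCutoff = saltbridgeCutoff,
              gridResolution = gridResolution, slabThickness = slabThickness,
              shellCutoff = shellCutoff,
              occupancyThresholds = occupancyThresholds,
              runningAverageWindow = runningAverageWindow,
              binderPersistence = binderPersistence,
              quantileType = as.integer(quantileType), seed = as.integer(seed))
  cuts <- c(contactCutoff, hydrophobicCutoff, hbondCutoff, saltbridgeCutoff,
            gridResolution, slabThickness, shellCutoff)
  if (any(cuts <= 0)) stop("all cutoffs and bin widths must be positive")
  if (any(occupancyThresholds <= 0 | occupancyThresholds >= 1))
    stop("occupancy thresholds must lie in (0, 1)")
  class(cfg) <- "AnalysisConfig"
  cfg
}
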