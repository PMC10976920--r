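#' @keywords internal
FAMILY_FEATURES <- list(
  first_order = c("Energy", "Entropy", "Minimum", "Percentile10", "Percentile90",
                  "Maximum", "Mean", "Median", "InterquartileRange", "Range",
                  "MeanAbsoluteDeviation", "RobustMeanAbsoluteDeviation",
                  "RootMeanSquared", "Skewness", "Kurtosis", "Variance",
                  "Uniformity"),
  shape = c("Elongation", "Flatness", "LeastAxisLength", "MajorAxisLength",
            "Maximum2DDiameterColumn", "Maximum2DDiameterRow",
            "Maximum2DDiameterSlice", "Maximum3DDiameter", "MeshVolume",
            "MinorAxisLength", "Sphericity", "SurfaceArea",
            "SurfaceVolumeRatio", "VoxelVolume"),
  glcm = c("Autocorrelation", "ClusterProminence", "ClusterShade",
           "ClusterTendency", "Contrast", "Correlation", "DifferenceAverage",
           "DifferenceEntropy", "DifferenceVariance", "Id", "Idm", "Idmn",
           "Idn", "Imc1", "Imc2", "InverseVariance", "JointAverage",
           "JointEnergy", "JointEntropy", "MaximumProbability", "SumAverage",
           "SumEntropy", "SumSquares"),
  glrlm = c("GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
            "GrayLevelVariance", "HighGrayLevelRunEmphasis", "LongRunEmphasis",
            "LongRunHighGrayLevelEmphasis", "LongRunLowGrayLevelEmphasis",
            "LowGrayLevelRunEmphasis", "RunEntropy", "RunLengthNonUniformity",
            "RunLengthNonUniformityNormalized", "RunPercentage", "RunVariance",
            "ShortRunEmphasis", "ShortRunHighGrayLevelEmphasis",
            "ShortRunLowGrayLevelEmphasis"),
  glszm = c("GrayLevelNonUniformity", "GrayLevelVariance",
            "HighGrayLevelZoneEmphasis", "LargeAreaEmphasis",
            "LargeAreaHighGrayLevelEmphasis", "LargeAreaLowGrayLevelEmphasis",
            "LowGrayLevelZoneEmphasis", "SizeZoneNonUniformity",
            "SizeZoneNonUniformityNormalized", "SmallAreaEmphasis",
            "SmallAreaHighGrayLevelEmphasis", "SmallAreaLowGrayLevelEmphasis",
            "ZoneEntropy", "ZonePercentage", "ZoneVariance"),
  ngtdm = c("Busyness", "Coarseness", "Complexity", "Contrast", "Strength"),
  gldm = c("DependenceEntropy", "DependenceNonUniformity",
           "DependenceNonUniformityNormalized", "DependenceVariance",
           "GrayLevelNonUniformity", "GrayLevelVariance",
           "HighGrayLevelEmphasis", "LargeDependenceEmphasis",
           "LargeDependenceHighGrayLevelEmphasis",
           "LargeDependenceLowGrayLevelEmphasis", "LowGrayLevelEmphasis",
           "SmallDependenceEmphasis", "SmallDependenceHighGrayLevelEmphasis",
           "SmallDependenceLowGrayLevelEmphasis"))

WAVELET_BANDS <- c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH")

DEFAULT_IMAGE_TYPES <- c("original", "log-sigma-1-0-mm-3D", "log-sigma-3-0-mm-3D",
                         paste0("wavelet-", WAVELET_BANDS))

#' Build the radiomics feature catalog
#'
#' The default catalog enumerates 1004 features: 17 first-order, 23 GLCM, 16
#' GLRLM, 15 GLSZM, 5 NGTDM and 14 GLDM features on each of 11 image types
#' (original, two Laplacian-of-Gaussian scales, eight wavelet sub-bands),
#' plus 14 3D shape features computed on the original image only. Feature
#' ids follow the `<imageType>_<family>_<FeatureName>` convention.
#'
#' @param image_types subset of the 11 default image types, or NULL for all.
#' @param families subset of
#'   `c("first_order","shape","glcm","glrlm","glszm","ngtdm","gldm")`, or
#'   NULL for all.
#' @param bin_width fixed discretisation bin width in HU for original and LoG
#'   images (default 25).
#' @param wavelet_bins fixed discretisation bin count for wavelet bands,
#'   whose value ranges are not HU-scaled (default 16).
#' @return an `fg_catalog` with a feature table and discretisation settings.
#' @export
build_catalog <- function(image_types = NULL, families = NULL,
                          bin_width = 25, wavelet_bins = 16) {
  if (is.null(image_types)) image_types <- DEFAULT_IMAGE_TYPES
  if (is.null(families)) families <- names(FAMILY_FEATURES)
  bad <- setdiff(image_types, DEFAULT_IMAGE_TYPES)
  if (length(bad)) stop("unknown image type(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(families, names(FAMILY_FEATURES))
  if (length(bad)) stop("unknown family(ies): ", paste(bad, collapse = ", "))
  image_types <- DEFAULT_IMAGE_TYPES[DEFAULT_IMAGE_TYPES %in% image_types]
  families <- names(FAMILY_FEATURES)[names(FAMILY_FEATURES) %in% families]
  rows <- list()
  for (it in image_types) {
    for (fam in families) {
      if (fam == "shape" && it != "original") next
      rows[[length(rows) + 1]] <- data.frame(
        image_type = it, family = fam, feature = FAMILY_FEATURES[[fam]],
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  tab$id <- paste(tab$image_type, tab$family, tab$feature, sep = "_")
  stopifnot(!anyDuplicated(tab$id))
  structure(list(table = tab[, c("id", "image_type", "family", "feature")],
                 image_types = image_types, families = families,
                 bin_width = bin_width, wavelet_bins = wavelet_bins),
            class = "fg_catalog")
}

#' @exportS3Method base::print
print.fg_catalog <- function(x, ...) {
  cat(sprintf("<fg_catalog> %d features over %d image type(s)\n",
              nrow(x$table), length(x$image_types)))
  print(table(x$table$family))
  invisible(x)
}

#' @export
length.fg_catalog <- function(x) nrow(x$table)
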