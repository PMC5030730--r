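# Feature registry: the ordered list of per-object features. Signature
# vectors are ordered by this registry, so the order is fixed and shipped
# with the package (inst/extdata/feature_registry.csv).

intensity_feature_names <- c(
  "IntegratedIntensity", "MeanIntensity", "StdIntensity", "MinIntensity",
  "MaxIntensity", "IntegratedIntensityEdge", "MeanIntensityEdge",
  "StdIntensityEdge", "MinIntensityEdge", "MaxIntensityEdge",
  "MassDisplacement", "LowerQuartileIntensity", "MedianIntensity",
  "MADIntensity", "UpperQuartileIntensity", "CenterMassIntensityRow",
  "CenterMassIntensityCol")

shape_feature_names <- c(
  "Area", "Perimeter", "FormFactor", "Compactness", "Eccentricity",
  "MajorAxisLength", "MinorAxisLength", "Orientation", "Solidity", "Extent",
  "EulerNumber", "EquivalentDiameter", "MaxFeretDiameter", "MinFeretDiameter",
  "MeanRadius", "MedianRadius", "MaximumRadius")

neighbor_feature_names <- c(
  "NumberOfNeighbors", "PercentTouching", "FirstClosestObjectNumber",
  "FirstClosestDistance", "SecondClosestObjectNumber", "SecondClosestDistance",
  "AngleBetweenNeighbors")

radial_feature_names <- function(n_rings = 4L) {
  c(sprintf("FracAtD_%dof%d", seq_len(n_rings), n_rings),
    sprintf("MeanFrac_%dof%d", seq_len(n_rings), n_rings),
    sprintf("RadialCV_%dof%d", seq_len(n_rings), n_rings))
}

#' Default per-object feature registry
#'
#' 53 features in a fixed, documented order: 17 intensity, 17 area/shape,
#' 7 neighbour and 12 radial-distribution features (4 rings for the
#' intensity-fraction and normalized-fraction measures, 8 wedges for the
#' radial coefficient of variation). Object-table columns are named
#' `Family_FeatureName` (e.g. `Intensity_MassDisplacement`). The registry is
#' a plain data.frame and can be subset or extended; every downstream step
#' (measurement, trend summaries, signature vectors) respects its order.
#'
#' @param n_rings number of radial rings (default 4).
#' @return data.frame with columns `name`, `family`, `column`, `order`.
#' @export
feature_registry <- function(n_rings = 4L) {
  reg <- rbind(
    data.frame(name = intensity_feature_names, family = "Intensity"),
    data.frame(name = shape_feature_names, family = "Shape"),
    data.frame(name = neighbor_feature_names, family = "Neighbors"),
    data.frame(name = radial_feature_names(n_rings), family = "Radial"))
  reg$column <- paste(reg$family, reg$name, sep = "_")
  reg$order <- seq_len(nrow(reg))
  if (anyDuplicated(reg$column)) stopf("duplicate feature names in registry")
  reg
}

#' Read a feature registry from CSV
#'
#' @param file CSV with columns `name`, `family`, `order`.
#' @return registry data.frame as from [feature_registry()].
#' @export
read_feature_registry <- function(file) {
  reg <- read.csv(file, stringsAsFactors = FALSE)
  req <- c("name", "family", "order")
  miss <- setdiff(req, names(reg))
  if (length(miss)) stopf("registry %s missing column(s): %s", file,
                          paste(miss, collapse = ", "))
  reg <- reg[order(reg$order), , drop = FALSE]
  reg$column <- paste(reg$family, reg$name, sep = "_")
  if (anyDuplicated(reg$column)) stopf("duplicate feature names in registry %s", file)
  rownames(reg) <- NULL
  reg
}

#' Write a feature registry to CSV
#'
#' @param registry registry data.frame.
#' @param file destination CSV.
#' @export
write_feature_registry <- function(registry, file) {
  write.table(registry[, c("name", "family", "order")], file, sep = ",",
              row.names = FALSE, qmethod = "double")
  invisible(file)
}
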