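# Closed-form histomorphometry: lesion volume (Cavalieri rule over serial
# sections), cortical thickness, cell density and synaptic-pair density.
# Quantities carry explicit units; mixing units is an error, not a cast.

#' Lesion volume from serial section areas
#'
#' Rectangular (Cavalieri) rule: the outlined lesion area of each coronal
#' section times the section spacing, summed over the series.
#'
#' @param areas_mm2 per-section lesion areas (mm^2), in section order.
#' @param section_spacing_mm distance between consecutive analysed sections
#'   (mm); 0.05 mm corresponds to consecutive 50-um sections.
#' @return lesion volume in mm^3.
#' @export
lesion_volume <- function(areas_mm2, section_spacing_mm = 0.05) {
  abort_if(length(areas_mm2) < 1L, "at least one section area is required")
  abort_if(any(areas_mm2 < 0), "section areas must be >= 0")
  abort_if(section_spacing_mm <= 0, "section spacing must be > 0")
  sum(areas_mm2) * section_spacing_mm
}

#' Cortical thickness from three medio-lateral measurements
#'
#' The layer VI-to-layer I distance is measured at three medio-lateral
#' positions (by convention 1, 1.5 and 2 mm from the midline) and averaged.
#'
#' @param measurements_mm numeric vector of exactly three positive
#'   thickness measurements (mm).
#' @return mean cortical thickness (mm).
#' @export
cortical_thickness <- function(measurements_mm) {
  abort_if(length(measurements_mm) != 3L,
           "exactly 3 thickness measurements are required, got %d",
           length(measurements_mm))
  abort_if(any(measurements_mm <= 0), "thickness measurements must be > 0")
  mean(measurements_mm)
}

#' Cell density from a count over an outlined area
#'
#' @param n_cells cell count.
#' @param area_mm2 outlined area (mm^2), strictly positive.
#' @return cells per mm^2.
#' @export
cell_density <- function(n_cells, area_mm2) {
  abort_if(any(n_cells < 0), "cell counts must be >= 0")
  abort_if(any(area_mm2 <= 0), "area must be > 0")
  n_cells / area_mm2
}

#' Synaptic-pair density along a dendritic segment
#'
#' Counts of colocalised excitatory and inhibitory pre/post-synaptic marker
#' pairs along an outlined dendritic perimeter, per micrometre. Pooling
#' concatenated segments (summed counts over summed lengths) equals the
#' length-weighted mean of the per-segment densities.
#'
#' @param excitatory_pairs,inhibitory_pairs pair counts.
#' @param perimeter_length_um outlined dendritic perimeter (um), positive.
#' @return data.frame with `excitatory_per_um` and `inhibitory_per_um`.
#' @export
synaptic_pair_density <- function(excitatory_pairs, inhibitory_pairs,
                                  perimeter_length_um) {
  abort_if(any(excitatory_pairs < 0) || any(inhibitory_pairs < 0),
           "pair counts must be >= 0")
  abort_if(any(perimeter_length_um <= 0), "perimeter length must be > 0")
  data.frame(excitatory_per_um = excitatory_pairs / perimeter_length_um,
             inhibitory_per_um = inhibitory_pairs / perimeter_length_um)
}

#' Convert between millimetre- and micrometre-based units
#'
#' Explicit unit conversion for lengths, areas and the derived densities;
#' round-trips are exact in floating point for powers of 10.
#'
#' @param x numeric values.
#' @param from,to unit names: `"mm"`, `"um"`, `"mm2"`, `"um2"`, `"per_mm2"`,
#'   `"per_um2"`, `"per_mm"`, `"per_um"`, `"mm3"`, `"um3"`.
#' @return converted values.
#' @export
convert_units <- function(x, from, to) {
  scale <- c(mm = 1e3, um = 1, mm2 = 1e6, um2 = 1,
             mm3 = 1e9, um3 = 1,
             per_mm = 1e-3, per_um = 1, per_mm2 = 1e-6, per_um2 = 1)
  abort_if(!from %in% names(scale) || !to %in% names(scale),
           "unknown unit name")
  base <- function(u) {
    inv <- startsWith(u, "per_")
    pow <- if (grepl("2$", u)) 2L else if (grepl("3$", u)) 3L else 1L
    paste0(if (inv) "inv" else "len", pow)
  }
  abort_if(base(from) != base(to),
           "cannot convert %s to %s: incompatible dimensions", from, to)
  x * scale[[from]] / scale[[to]]
}
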