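# Atlas label table: maps ROI columns to names, hemispheres and bilateral
# region pairs. The default is a 90-node automated-anatomical-labelling style
# parcellation in the conventional interleaved order (odd = left, even =
# right), so the four regions used throughout (thalamus, hippocampus,
# caudate, insula) sit at their usual indices.

aal90_regions <- c(
  "Precentral", "Frontal_Sup", "Frontal_Sup_Orb", "Frontal_Mid",
  "Frontal_Mid_Orb", "Frontal_Inf_Oper", "Frontal_Inf_Tri",
  "Frontal_Inf_Orb", "Rolandic_Oper", "Supp_Motor_Area", "Olfactory",
  "Frontal_Sup_Medial", "Frontal_Med_Orb", "Rectus", "Insula",
  "Cingulum_Ant", "Cingulum_Mid", "Cingulum_Post", "Hippocampus",
  "ParaHippocampal", "Amygdala", "Calcarine", "Cuneus", "Lingual",
  "Occipital_Sup", "Occipital_Mid", "Occipital_Inf", "Fusiform",
  "Postcentral", "Parietal_Sup", "Parietal_Inf", "SupraMarginal",
  "Angular", "Precuneus", "Paracentral_Lobule", "Caudate", "Putamen",
  "Pallidum", "Thalamus", "Heschl", "Temporal_Sup", "Temporal_Pole_Sup",
  "Temporal_Mid", "Temporal_Pole_Mid", "Temporal_Inf"
)

#' Default 90-ROI atlas label table
#'
#' Returns the label table used when no atlas file is supplied: 45 bilateral
#' regions interleaved left/right (odd indices left, even indices right), the
#' layout of the standard 90-node anatomical parcellation. Every region has
#' exactly one left and one right member, which is what [bilateral_average()]
#' relies on.
#'
#' @return A tibble with columns `index`, `name` (e.g. `"Thalamus_L"`),
#'   `hemisphere` (`"L"`/`"R"`) and `region` (the bilateral pair label).
#' @export
#' @examples
#' atlas <- default_atlas()
#' dplyr::filter(atlas, region == "Thalamus")
default_atlas <- function() {
  tibble::tibble(
    index = seq_len(2L * length(aal90_regions)),
    region = rep(aal90_regions, each = 2L),
    hemisphere = rep(c("L", "R"), times = length(aal90_regions))
  ) |>
    dplyr::mutate(name = paste0(.data$region, "_", .data$hemisphere)) |>
    dplyr::select("index", "name", "hemisphere", "region")
}

# Resolve a bilateral region to its (L, R) row indices; errors if unpaired.
region_indices <- function(atlas, region) {
  rows <- atlas[atlas$region == region, , drop = FALSE]
  if (nrow(rows) == 0L) {
    stop(sprintf("region '%s' not found in atlas", region), call. = FALSE)
  }
  if (!setequal(rows$hemisphere, c("L", "R")) || nrow(rows) != 2L) {
    stop(sprintf("region '%s' does not have exactly one L and one R member", region),
         call. = FALSE)
  }
  c(L = rows$index[rows$hemisphere == "L"], R = rows$index[rows$hemisphere == "R"])
}
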