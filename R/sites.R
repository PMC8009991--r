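#' Region labels of the 90-region AAL parcellation
#'
#' Standard ordering of the 90 cortical and subcortical regions (45 per
#' hemisphere, left/right interleaved) of the automated anatomical labeling
#' atlas used to parcellate the fMRI data.
#'
#' @return Character vector of length 90.
#' @export
aal90_labels <- function() {
  base <- c(
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
  paste0(rep(base, each = 2), c("_L", "_R"))
}

#' Default stimulation-site map
#'
#' Maps 10-10 system electrode labels (the cathode positions occurring in the
#' study cohort, including two-electrode midpoints written "C3-FC1" etc.) to
#' AAL region indices. Electrode-to-region assignment is anatomically
#' plausible but is a package convention, not ground truth: in the clinical
#' workflow this mapping is made per patient by clinicians. Override it by
#' passing your own named list of integer vectors wherever a `site_map` is
#' accepted.
#'
#' For parcellations with fewer than 90 regions (synthetic reduced cohorts)
#' the 90-region indices are rescaled onto `1..n_regions`; such maps are
#' synthetic stand-ins and are flagged by a `"synthetic"` attribute.
#'
#' @param n_regions Number of regions in the parcellation (default 90).
#' @return Named list: electrode label -> integer vector of region indices.
#' @export
default_site_map <- function(n_regions = 90L) {
  # indices into aal90_labels(): odd = left, even = right
  map90 <- list(
    "F7"     = c(11L, 13L),        # Frontal_Inf_Oper_L, Frontal_Inf_Tri_L
    "F8"     = c(12L, 14L),        # right homologues
    "F4"     = 8L,                 # Frontal_Mid_R
    "F3"     = 7L,                 # Frontal_Mid_L
    "CP6"    = 64L,                # SupraMarginal_R
    "C3-FC1" = c(1L, 19L),         # Precentral_L, Supp_Motor_Area_L
    "C3-F3"  = c(1L, 7L),          # Precentral_L, Frontal_Mid_L
    "F4-Fz"  = c(8L, 20L),         # Frontal_Mid_R, Supp_Motor_Area_R
    "C4-P4"  = c(2L, 60L)          # Precentral_R, Parietal_Sup_R
  )
  n_regions <- as.integer(n_regions)
  if (n_regions == 90L) return(map90)
  stopifnot(n_regions >= 2L)
  map <- lapply(map90, function(idx) {
    unique(pmax(1L, pmin(n_regions, as.integer(round(idx * n_regions / 90)))))
  })
  attr(map, "synthetic") <- TRUE
  map
}

#' Clinical seizure-diary table of the study cohort
#'
#' Per-subject arm assignment, cathode placement and 4-week baseline /
#' follow-up seizure counts for the 20 analysed subjects (12 active, 8 sham),
#' as published. Used for response labelling and group bookkeeping.
#'
#' @return Tibble with columns `subject_id`, `arm`, `stimulation_sites`
#'   (semicolon-separated electrode labels), `baseline_seizures`,
#'   `followup_seizures`.
#' @export
clinical_cohort <- function() {
  path <- system.file("extdata", "clinical_cohort.csv", package = "ctdcsnet",
                      mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
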