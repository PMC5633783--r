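# Destrieux-style cortical parcellation registry: 74 gyri and sulci per
# hemisphere.  Structure codes follow the FreeSurfer aparc.a2009s naming so
# that aparc-stats tables can be joined directly; lobe labels partition the
# cortex into frontal / insular / limbic / temporal / parietal / occipital.

.destrieux_structures <- function() {
  tab <- matrix(c(
    "G_and_S_frontomargin",      "Frontomarginal gyrus/sulcus",                    "frontal",
    "G_and_S_occipital_inf",     "Inferior occipital gyrus/sulcus",                "occipital",
    "G_and_S_paracentral",       "Paracentral lobule/sulcus",                      "parietal",
    "G_and_S_subcentral",        "Subcentral gyrus/sulcus",                        "frontal",
    "G_and_S_transv_frontopol",  "Transverse frontopolar gyrus/sulcus",            "frontal",
    "G_and_S_cingul-Ant",        "Anterior cingulate gyrus/sulcus",                "limbic",
    "G_and_S_cingul-Mid-Ant",    "Middle anterior cingulate gyrus/sulcus",         "limbic",
    "G_and_S_cingul-Mid-Post",   "Middle posterior cingulate gyrus/sulcus",        "limbic",
    "G_cingul-Post-dorsal",      "Posterior dorsal cingulate gyrus",               "limbic",
    "G_cingul-Post-ventral",     "Posterior ventral cingulate gyrus",              "limbic",
    "G_cuneus",                  "Cuneus",                                         "occipital",
    "G_front_inf-Opercular",     "Inferior frontal gyrus, opercular part",         "frontal",
    "G_front_inf-Orbital",       "Inferior frontal gyrus, orbital part",           "frontal",
    "G_front_inf-Triangul",      "Inferior frontal gyrus, triangular part",        "frontal",
    "G_front_middle",            "Middle frontal gyrus",                           "frontal",
    "G_front_sup",               "Superior frontal gyrus",                         "frontal",
    "G_Ins_lg_and_S_cent_ins",   "Long insular gyrus/central insular sulcus",      "insular",
    "G_insular_short",           "Short insular gyri",                             "insular",
    "G_occipital_middle",        "Middle occipital gyrus",                         "occipital",
    "G_occipital_sup",           "Superior occipital gyrus",                       "occipital",
    "G_oc-temp_lat-fusifor",     "Lateral occipito-temporal (fusiform) gyrus",     "temporal",
    "G_oc-temp_med-Lingual",     "Lingual gyrus",                                  "occipital",
    "G_oc-temp_med-Parahip",     "Parahippocampal gyrus",                          "limbic",
    "G_orbital",                 "Orbital gyri",                                   "frontal",
    "G_pariet_inf-Angular",      "Angular gyrus",                                  "parietal",
    "G_pariet_inf-Supramar",     "Supramarginal gyrus",                            "parietal",
    "G_parietal_sup",            "Superior parietal lobule",                       "parietal",
    "G_postcentral",             "Postcentral gyrus",                              "parietal",
    "G_precentral",              "Precentral gyrus",                               "frontal",
    "G_precuneus",               "Precuneus",                                      "parietal",
    "G_rectus",                  "Gyrus rectus",                                   "frontal",
    "G_subcallosal",             "Subcallosal gyrus",                              "limbic",
    "G_temp_sup-G_T_transv",     "Transverse temporal gyrus",                      "temporal",
    "G_temp_sup-Lateral",        "Superior temporal gyrus, lateral aspect",        "temporal",
    "G_temp_sup-Plan_polar",     "Planum polare",                                  "temporal",
    "G_temp_sup-Plan_tempo",     "Planum temporale",                               "temporal",
    "G_temporal_inf",            "Inferior temporal gyrus",                        "temporal",
    "G_temporal_middle",         "Middle temporal gyrus",                          "temporal",
    "Lat_Fis-ant-Horizont",      "Anterior lateral sulcus, horizontal part",       "insular",
    "Lat_Fis-ant-Vertical",      "Anterior lateral sulcus, vertical part",         "insular",
    "Lat_Fis-post",              "Posterior lateral sulcus",                       "insular",
    "Pole_occipital",            "Occipital pole",                                 "occipital",
    "Pole_temporal",             "Temporal pole",                                  "temporal",
    "S_calcarine",               "Calcarine sulcus",                               "occipital",
    "S_central",                 "Central sulcus",                                 "frontal",
    "S_cingul-Marginalis",       "Cingulate sulcus, marginal part",                "limbic",
    "S_circular_insula_ant",     "Anterior circular insular sulcus",               "insular",
    "S_circular_insula_inf",     "Inferior circular insular sulcus",               "insular",
    "S_circular_insula_sup",     "Superior circular insular sulcus",               "insular",
    "S_collat_transv_ant",       "Anterior transverse collateral sulcus",          "temporal",
    "S_collat_transv_post",      "Posterior transverse collateral sulcus",         "occipital",
    "S_front_inf",               "Inferior frontal sulcus",                        "frontal",
    "S_front_middle",            "Middle frontal sulcus",                          "frontal",
    "S_front_sup",               "Superior frontal sulcus",                        "frontal",
    "S_interm_prim-Jensen",      "Primary intermediate sulcus of Jensen",          "parietal",
    "S_intrapariet_and_P_trans", "Intraparietal and transverse parietal sulci",    "parietal",
    "S_oc_middle_and_Lunatus",   "Middle occipital and lunate sulci",              "occipital",
    "S_oc_sup_and_transversal",  "Superior occipital and transverse sulci",        "occipital",
    "S_occipital_ant",           "Anterior occipital sulcus",                      "occipital",
    "S_oc-temp_lat",             "Lateral occipito-temporal sulcus",               "temporal",
    "S_oc-temp_med_and_Lingual", "Medial occipito-temporal and lingual sulci",     "occipital",
    "S_orbital_lateral",         "Lateral orbital sulcus",                         "frontal",
    "S_orbital_med-olfact",      "Medial orbital (olfactory) sulcus",              "frontal",
    "S_orbital-H_Shaped",        "H-shaped orbital sulci",                         "frontal",
    "S_parieto_occipital",       "Parieto-occipital sulcus",                       "occipital",
    "S_pericallosal",            "Pericallosal sulcus",                            "limbic",
    "S_postcentral",             "Postcentral sulcus",                             "parietal",
    "S_precentral-inf-part",     "Inferior precentral sulcus",                     "frontal",
    "S_precentral-sup-part",     "Superior precentral sulcus",                     "frontal",
    "S_suborbital",              "Suborbital sulcus",                              "frontal",
    "S_subparietal",             "Subparietal sulcus",                             "limbic",
    "S_temporal_inf",            "Inferior temporal sulcus",                       "temporal",
    "S_temporal_sup",            "Superior temporal sulcus",                       "temporal",
    "S_temporal_transverse",     "Transverse temporal sulcus",                     "temporal"
  ), ncol = 3, byrow = TRUE)
  data.frame(structure = tab[, 1], name = tab[, 2], lobe = tab[, 3],
             stringsAsFactors = FALSE)
}

#' Default cortical parcellation registry
#'
#' Returns the bundled Destrieux-style parcellation: 74 named cortical
#' structures (gyri and sulci) per hemisphere, 148 rows in total, each with a
#' lobe assignment.  Region identifiers are `lh_`/`rh_`-prefixed structure
#' codes following the FreeSurfer `aparc.a2009s` naming, so per-subject
#' aparc-stats tables join directly (see [read_aparc_stats()]).
#'
#' @return A data frame with columns `region_id`, `region_name`,
#'   `hemisphere` (`"left"`/`"right"`) and `lobe` (one of `"frontal"`,
#'   `"insular"`, `"limbic"`, `"temporal"`, `"parietal"`, `"occipital"`),
#'   ordered left hemisphere first, structures in registry order.
#' @examples
#' parc <- default_parcellation()
#' nrow(parc)           # 148
#' table(parc$hemisphere)
#' @export
default_parcellation <- function() {
  s <- .destrieux_structures()
  out <- rbind(
    data.frame(region_id = paste0("lh_", s$structure),
               region_name = s$name, hemisphere = "left", lobe = s$lobe,
               stringsAsFactors = FALSE),
    data.frame(region_id = paste0("rh_", s$structure),
               region_name = s$name, hemisphere = "right", lobe = s$lobe,
               stringsAsFactors = FALSE)
  )
  rownames(out) <- NULL
  out
}

.validate_parcellation <- function(parc) {
  required <- c("region_id", "region_name", "hemisphere", "lobe")
  missing <- setdiff(required, names(parc))
  if (length(missing))
    stop("parcellation table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (anyDuplicated(parc$region_id))
    stop("duplicate region_id in parcellation: ",
         paste(unique(parc$region_id[duplicated(parc$region_id)]),
               collapse = ", "), call. = FALSE)
  bad_hemi <- setdiff(unique(parc$hemisphere), c("left", "right"))
  if (length(bad_hemi))
    stop("invalid hemisphere value(s): ", paste(bad_hemi, collapse = ", "),
         call. = FALSE)
  lobes <- c("frontal", "insular", "limbic", "temporal", "parietal",
             "occipital")
  bad_lobe <- setdiff(unique(parc$lobe), lobes)
  if (length(bad_lobe))
    stop("invalid lobe value(s): ", paste(bad_lobe, collapse = ", "),
         call. = FALSE)
  invisible(parc)
}
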