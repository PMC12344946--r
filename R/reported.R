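# Published cohort summary tables, encoded as package data.
#
# These are the printed inputs the synthetic-cohort generator and the
# confusion-matrix reconstruction consume: per-group parameter summaries,
# ROC operating points, group sizes and morphology prevalences from the
# source glioma study (95 subjects: 52 IDH wild-type glioblastomas, 12
# IDH-mutant 1p/19q non-codeleted astrocytomas, 31 IDH-mutant codeleted
# oligodendrogliomas).

#' Published per-group parameter summaries
#'
#' Summary statistics of the nine VOI-mean diffusion parameters per molecular
#' group. Groups `"idh_wild"` and `"idh_mutant"` are the two arms of the IDH
#' comparison (median and quartiles); `"noncodeleted"` and `"codeleted"` are
#' the two arms of the 1p/19q comparison within IDH-mutant tumors (median and
#' quartiles, except IVIM_D and IVIM_f which were reported as mean +/- SD,
#' flagged by `family = "mean_sd"`).
#'
#' @return Tibble with columns `group`, `parameter`, `location`, `q1`, `q3`,
#'   `scale` (SD; for quartile rows, IQR/1.349) and `family`.
#' @export
reported_parameter_summaries <- function() {
  q <- function(group, parameter, med, q1, q3) {
    tibble::tibble(group = group, parameter = parameter, location = med,
                   q1 = q1, q3 = q3, scale = (q3 - q1) / 1.349,
                   family = "median_iqr")
  }
  m <- function(group, parameter, mean, sd) {
    tibble::tibble(group = group, parameter = parameter, location = mean,
                   q1 = NA_real_, q3 = NA_real_, scale = sd,
                   family = "mean_sd")
  }
  rbind(
    q("idh_wild", "Mono_ADC",   1.088, 0.997, 1.219),
    q("idh_wild", "IVIM_D",     0.983, 0.883, 1.083),
    q("idh_wild", "IVIM_Dstar", 7.298, 6.630, 7.929),
    q("idh_wild", "IVIM_f",     0.089, 0.075, 0.106),
    q("idh_wild", "SEM_alpha",  0.867, 0.840, 0.880),
    q("idh_wild", "SEM_DDC",    1.117, 1.029, 1.274),
    q("idh_wild", "CTRW_alpha", 0.825, 0.789, 0.849),
    q("idh_wild", "CTRW_beta",  0.938, 0.917, 0.956),
    q("idh_wild", "CTRW_Dm",    1.218, 1.102, 1.365),
    q("idh_mutant", "Mono_ADC",   1.200, 1.141, 1.307),
    q("idh_mutant", "IVIM_D",     1.099, 1.028, 1.157),
    q("idh_mutant", "IVIM_Dstar", 7.443, 6.991, 8.676),
    q("idh_mutant", "IVIM_f",     0.085, 0.060, 0.104),
    q("idh_mutant", "SEM_alpha",  0.875, 0.835, 0.911),
    q("idh_mutant", "SEM_DDC",    1.233, 1.163, 1.342),
    q("idh_mutant", "CTRW_alpha", 0.867, 0.844, 0.890),
    q("idh_mutant", "CTRW_beta",  0.935, 0.904, 0.968),
    q("idh_mutant", "CTRW_Dm",    1.335, 1.254, 1.396),
    q("noncodeleted", "Mono_ADC",   1.281, 1.193, 1.377),
    m("noncodeleted", "IVIM_D",     1.188, 0.159),
    q("noncodeleted", "IVIM_Dstar", 7.399, 6.981, 9.730),
    m("noncodeleted", "IVIM_f",     0.087, 0.035),
    q("noncodeleted", "SEM_alpha",  0.874, 0.827, 0.911),
    q("noncodeleted", "SEM_DDC",    1.347, 1.288, 1.421),
    q("noncodeleted", "CTRW_alpha", 0.894, 0.885, 0.906),
    q("noncodeleted", "CTRW_beta",  0.908, 0.880, 0.973),
    q("noncodeleted", "CTRW_Dm",    1.387, 1.364, 1.466),
    q("codeleted", "Mono_ADC",   1.188, 1.140, 1.238),
    m("codeleted", "IVIM_D",     1.089, 0.098),
    q("codeleted", "IVIM_Dstar", 7.453, 6.991, 8.541),
    m("codeleted", "IVIM_f",     0.084, 0.028),
    q("codeleted", "SEM_alpha",  0.875, 0.839, 0.911),
    q("codeleted", "SEM_DDC",    1.210, 1.155, 1.272),
    q("codeleted", "CTRW_alpha", 0.860, 0.836, 0.876),
    q("codeleted", "CTRW_beta",  0.937, 0.911, 0.967),
    q("codeleted", "CTRW_Dm",    1.309, 1.251, 1.348)
  )
}

#' Published ROC operating points
#'
#' The per-parameter ROC rows for one genotype question: Youden-optimal
#' threshold, AUC with 95% CI, and sensitivity / specificity / accuracy at
#' the threshold. For the IDH question the positive class is IDH-mutant
#' (n = 43) versus wild-type (n = 52); for the 1p/19q question the positive
#' class is non-codeleted (n = 12) versus codeleted (n = 31).
#'
#' @param question `"IDH"` or `"1p19q"`.
#' @return Tibble with one row per parameter.
#' @export
reported_roc_table <- function(question = c("IDH", "1p19q")) {
  question <- match.arg(question)
  r <- function(parameter, threshold, auc, lo, hi, sens, spec, acc) {
    tibble::tibble(parameter = parameter, threshold = threshold, auc = auc,
                   ci_lo = lo, ci_hi = hi, sensitivity = sens,
                   specificity = spec, accuracy = acc)
  }
  if (question == "IDH") {
    rbind(
      r("Mono_ADC",   1.122, 0.737, 0.634, 0.839, 0.860, 0.673, 0.758),
      r("IVIM_D",     0.998, 0.750, 0.644, 0.843, 0.884, 0.654, 0.758),
      r("IVIM_Dstar", 8.586, 0.592, 0.470, 0.707, 0.279, 0.904, 0.621),
      r("IVIM_f",     0.067, 0.568, 0.447, 0.686, 0.372, 0.865, 0.642),
      r("SEM_alpha",  0.896, 0.584, 0.456, 0.703, 0.419, 0.904, 0.684),
      r("SEM_DDC",    1.130, 0.728, 0.623, 0.826, 0.907, 0.577, 0.726),
      r("CTRW_alpha", 0.855, 0.761, 0.661, 0.854, 0.651, 0.846, 0.758),
      r("CTRW_beta",  0.909, 0.511, 0.388, 0.634, 0.326, 0.846, 0.611),
      r("CTRW_Dm",    1.248, 0.694, 0.585, 0.793, 0.791, 0.596, 0.684)
    )
  } else {
    rbind(
      r("Mono_ADC",   1.250, 0.704, 0.503, 0.882, 0.667, 0.774, 0.744),
      r("IVIM_D",     1.134, 0.683, 0.465, 0.866, 0.667, 0.806, 0.767),
      r("IVIM_Dstar", 9.357, 0.554, 0.344, 0.750, 0.333, 0.935, 0.767),
      r("IVIM_f",     0.100, 0.508, 0.306, 0.712, 0.417, 0.742, 0.651),
      r("SEM_alpha",  0.853, 0.505, 0.290, 0.731, 0.500, 0.677, 0.628),
      r("SEM_DDC",    1.265, 0.750, 0.556, 0.917, 0.833, 0.742, 0.767),
      r("CTRW_alpha", 0.886, 0.790, 0.613, 0.941, 0.750, 0.903, 0.860),
      r("CTRW_beta",  0.893, 0.583, 0.344, 0.801, 0.500, 0.903, 0.791),
      r("CTRW_Dm",    1.353, 0.731, 0.532, 0.898, 0.833, 0.806, 0.814)
    )
  }
}

#' Published group sizes per genotype question
#'
#' @param question `"IDH"` or `"1p19q"`.
#' @return List with `n_pos` and `n_neg` (positive class first: IDH-mutant
#'   for IDH; 1p/19q non-codeleted for 1p/19q).
#' @export
reported_group_sizes <- function(question = c("IDH", "1p19q")) {
  question <- match.arg(question)
  if (question == "IDH") list(n_pos = 43L, n_neg = 52L)
  else list(n_pos = 12L, n_neg = 31L)
}

# Morphology prevalences per molecular group (proportion with the feature).
reported_morphology <- function() {
  tibble::tibble(
    group = c("idh_wild", "noncodeleted", "codeleted"),
    cystic_necrosis = c(44 / 52, 7 / 12, 21 / 31),
    hemorrhage = c(4 / 52, 0, 0),
    edema = c(42 / 52, 7 / 12, 17 / 31),
    enhancement = c(47 / 52, 5 / 12, 13 / 31),
    frontal_insula = c(18 / 52, 9 / 12, 22 / 31)
  )
}
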