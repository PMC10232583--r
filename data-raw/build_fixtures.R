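# Builds the packaged fixtures under inst/extdata/:
#   csurv_core_124.json          -- the C-Surv core variable schema
#   mappings_{airwave,elsa,genscot,memento}.json -- per-cohort rules
#   presence_matrix.csv          -- variable x cohort availability grid
#
# Run from the package root:  Rscript data-raw/build_fixtures.R
#
# The script cross-checks every count the fixtures must jointly satisfy
# (theme x cohort coverage, per-cohort totals, overlap histogram, unique
# counts, strategy tallies) and stops on any violation, so the committed
# fixtures are consistent by construction.

suppressPackageStartupMessages(library(jsonlite))

out_dir <- "inst/extdata"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

# ---------------------------------------------------------------------------
# Themes (level 1 of the C-Surv taxonomy)
# ---------------------------------------------------------------------------

themes <- data.frame(
  theme_number = 1:18,
  theme_name = c(
    "Administration", "Sociodemographic", "Early life experience",
    "Medical history", "Family disease history", "Psychological status",
    "Cognitive status", "Lifestyle", "Life functionality",
    "Physical environment", "Social environment", "Physical examination",
    "Imaging", "Linkage data", "Healthcare utilisation data",
    "Biosample assays", "Molecular", "Device data"
  ),
  stringsAsFactors = FALSE
)

# ---------------------------------------------------------------------------
# Codebooks
# ---------------------------------------------------------------------------

cb <- function(codes, labels) {
  lapply(seq_along(codes), function(i) list(code = codes[i], label = labels[i]))
}

codebooks <- list(
  yn = cb(c(1L, 0L), c("yes", "no")),
  gender = cb(1:2, c("male", "female")),
  ethnicity = cb(1:5, c("white", "black", "asian", "mixed", "other")),
  cohabitation = cb(1:5, c("single", "married/cohabiting",
                           "separated/divorced", "widowed", "other")),
  education = cb(1:4, c("postgraduate or equivalent", "degree or equivalent",
                        "secondary", "junior or less")),
  income_q = cb(1:4, c("first quantile (lowest)", "second quantile",
                       "third quantile", "fourth quantile (highest)")),
  smoking = cb(c(0L, 1L, 2L), c("never smoked", "past smoker",
                                "current smoker")),
  housing = cb(1:4, c("house/bungalow", "apartment",
                      "sheltered/residential", "other")),
  apoe = cb(1:6, c("2/2", "2/3", "2/4", "3/3", "3/4", "4/4")),
  icd11 = cb(1:18, c(
    "infectious or parasitic diseases", "neoplasms", "diseases of the blood",
    "diseases of the immune system", "endocrine or metabolic diseases",
    "mental or behavioural disorders", "sleep-wake disorders",
    "diseases of the nervous system", "diseases of the visual system",
    "diseases of the ear", "diseases of the circulatory system",
    "diseases of the respiratory system", "diseases of the digestive system",
    "diseases of the skin", "diseases of the musculoskeletal system",
    "diseases of the genitourinary system", "conditions of sexual health",
    "pregnancy or childbirth"
  ))
)

# ---------------------------------------------------------------------------
# Core variable list.
# pres: which cohorts carry the variable (A airwave, E elsa, G genscot,
#       M memento); "" = not found in any cohort.
# ---------------------------------------------------------------------------

v <- function(row, id, name, theme, declared, type, pres,
              units = NA, cbk = NA, rule = NA) {
  list(row = row, id = id, name = name, theme = theme, declared = declared,
       type = type, pres = pres, units = units, cbk = cbk, rule = rule)
}

vars <- list(
  # -- Administration (theme 1) --
  v(1, "cohort_id", "Cohort ID", 1, "SC", "text", "AEGM",
    rule = "Anonymised by cohort"),
  v(2, "assessment_date", "Assessment date", 1, "SC", "date", "AEGM"),
  v(3, "date_of_birth", "Date of birth", 1, "SC", "date", "AEGM"),
  v(4, "date_of_death", "Date of death", 1, "SC", "date", "EM"),
  v(5, "cause_of_death", "Cause of death", 1, "SC", "text", "M",
    cbk = "icd11", rule = "ICD-11 categories 1-18"),
  v(6, "dna_extracted", "DNA extracted", 1, "SC", "categorical", "AEGM",
    cbk = "yn"),
  v(7, "plasma_collected", "Plasma collected", 1, "SC", "categorical", "AEGM",
    cbk = "yn"),
  v(8, "serum_collected", "Serum collected", 1, "SC", "categorical", "AEGM",
    cbk = "yn"),
  v(9, "csf_collected", "CSF collected", 1, "SC", "categorical", "M",
    cbk = "yn"),
  # -- Sociodemographic (theme 2) --
  v(10, "age", "Age", 2, "SC", "quantitative", "AEGM", units = "years"),
  v(11, "gender", "Gender", 2, "SC", "categorical", "AEGM", cbk = "gender"),
  v(12, "ethnicity", "Ethnicity", 2, "AT", "categorical", "AEG",
    cbk = "ethnicity"),
  v(13, "cohabitation", "Cohabitation", 2, "AT", "categorical", "AEGM",
    cbk = "cohabitation"),
  v(14, "years_education", "Years education", 2, "SC", "quantitative", "EGM",
    units = "years"),
  v(15, "educational_level", "Educational level", 2, "AT", "categorical",
    "AEGM", cbk = "education"),
  v(16, "income", "Income", 2, "AT", "categorical", "AEGM", cbk = "income_q",
    rule = "Quantiles using local currency"),
  # -- Early life experience (theme 3) --
  v(17, "childhood_physical_abuse", "Childhood physical abuse", 3, "SC",
    "categorical", "E", cbk = "yn"),
  v(18, "adolescent_physical_abuse", "Adolescent physical abuse", 3, "SC",
    "categorical", "E", cbk = "yn"),
  v(19, "sexual_abuse", "Sexual abuse", 3, "SC", "categorical", "E",
    cbk = "yn"),
  v(20, "parental_smoking", "Parental smoking behaviour", 3, "SC",
    "categorical", "E", cbk = "yn"),
  # -- Medical history (theme 4) --
  v(21, "t1d_diagnosis", "Type 1 diabetes diagnosis", 4, "AT", "categorical",
    "AEGM", cbk = "yn"),
  v(22, "t2d_diagnosis", "Type 2 diabetes diagnosis", 4, "AT", "categorical",
    "AEGM", cbk = "yn"),
  v(23, "ad_diagnosis", "AD diagnosis", 4, "AT", "categorical", "M",
    cbk = "yn"),
  v(24, "ad_ftd_diagnosis", "AD FTD diagnosis", 4, "AT", "categorical", "M",
    cbk = "yn"),
  v(25, "ad_mixed_diagnosis", "AD mixed diagnosis", 4, "AT", "categorical",
    "M", cbk = "yn"),
  v(26, "vad_diagnosis", "VaD diagnosis", 4, "AT", "categorical", "M",
    cbk = "yn"),
  v(27, "pd_diagnosis", "PD diagnosis", 4, "AT", "categorical", "M",
    cbk = "yn"),
  v(28, "depression_diagnosis", "Depression diagnosis", 4, "AT",
    "categorical", "AEGM", cbk = "yn"),
  v(29, "visual_difficulty", "Self-report visual difficulty", 4, "AT",
    "categorical", "AEM", cbk = "yn"),
  v(30, "hearing_difficulty", "Self-report hearing difficulty", 4, "AT",
    "categorical", "AEM", cbk = "yn"),
  v(31, "angina_diagnosis", "Angina diagnosis", 4, "AT", "categorical",
    "AEGM", cbk = "yn"),
  v(32, "mi_diagnosis", "MI diagnosis", 4, "AT", "categorical", "AEGM",
    cbk = "yn"),
  v(33, "hypertension_diagnosis", "Hypertension diagnosis", 4, "AT",
    "categorical", "AEGM", cbk = "yn"),
  v(34, "stroke_diagnosis", "Stroke diagnosis", 4, "AT", "categorical",
    "AEGM", cbk = "yn"),
  v(35, "head_injury", "Head injury", 4, "AT", "categorical", "EM",
    cbk = "yn"),
  v(36, "copd_diagnosis", "COPD diagnosis", 4, "AT", "categorical", "EG",
    cbk = "yn"),
  v(37, "arthritis_diagnosis", "Arthritis diagnosis", 4, "AT", "categorical",
    "AEGM", cbk = "yn"),
  v(38, "current_pain", "Current pain", 4, "AT", "categorical", "M",
    cbk = "yn"),
  v(39, "general_health", "Self-report general health", 4, "AT",
    "categorical", "EG", cbk = "yn"),
  v(40, "medications", "Medications", 4, "SC", "quantitative", "M",
    units = "count", rule = "Value: number prescribed"),
  # -- Family disease history (theme 5) --
  v(41, "dementia_parent", "Dementia parent", 5, "SC", "categorical", "GM",
    cbk = "yn"),
  v(42, "dementia_grandparent", "Dementia grandparent", 5, "SC",
    "categorical", "G", cbk = "yn"),
  v(43, "dementia_sibling", "Dementia sibling", 5, "SC", "categorical", "GM",
    cbk = "yn"),
  v(44, "ad_parent", "AD parent", 5, "SC", "categorical", "GM", cbk = "yn"),
  v(45, "ad_grandparent", "AD grandparent", 5, "SC", "categorical", "G",
    cbk = "yn"),
  v(46, "ad_sibling", "AD sibling", 5, "SC", "categorical", "GM", cbk = "yn"),
  v(47, "vad_parent", "VaD parent", 5, "SC", "categorical", "GM", cbk = "yn"),
  v(48, "vad_grandparent", "VaD grandparent", 5, "SC", "categorical", "M",
    cbk = "yn"),
  v(49, "vad_sibling", "VaD sibling", 5, "SC", "categorical", "G",
    cbk = "yn"),
  v(50, "pd_parent", "PD parent", 5, "SC", "categorical", "GM", cbk = "yn"),
  v(51, "pd_grandparent", "PD grandparent", 5, "SC", "categorical", "M",
    cbk = "yn"),
  v(52, "pd_sibling", "PD sibling", 5, "SC", "categorical", "G", cbk = "yn"),
  v(53, "chd_parent", "CHD parent", 5, "SC", "categorical", "GM", cbk = "yn"),
  v(54, "chd_grandparent", "CHD grandparent", 5, "SC", "categorical", "G",
    cbk = "yn"),
  v(55, "chd_sibling", "CHD sibling", 5, "SC", "categorical", "G",
    cbk = "yn"),
  v(56, "stroke_parent", "Stroke parent", 5, "SC", "categorical", "GM",
    cbk = "yn"),
  v(57, "stroke_grandparent", "Stroke grandparent", 5, "SC", "categorical",
    "M", cbk = "yn"),
  v(58, "stroke_sibling", "Stroke sibling", 5, "SC", "categorical", "GM",
    cbk = "yn"),
  # -- Psychological status (theme 6) --
  v(59, "ghq_score", "GHQ score", 6, "AT", "quantitative", "M",
    units = "score", rule = "Scale score"),
  v(60, "self_report_depression", "Self-report depression", 6, "AT",
    "categorical", "AEM", cbk = "yn"),
  v(61, "loss_of_interest", "Loss of interest", 6, "AT", "categorical", "EM",
    cbk = "yn"),
  v(62, "depression_score", "Depression score", 6, "AT", "quantitative",
    "AEGM", units = "score", rule = "Scale score"),
  v(63, "epq_neuroticism", "EPQ Neuroticism", 6, "AT", "quantitative", "EG",
    units = "score", rule = "Scale score"),
  v(64, "epq_extraversion", "EPQ Extraversion", 6, "AT", "quantitative", "EG",
    units = "score", rule = "Scale score"),
  v(65, "life_satisfaction_score", "Life satisfaction score", 6, "AT",
    "quantitative", "E", units = "score", rule = "Scale score"),
  v(66, "job_satisfaction_score", "Job satisfaction score", 6, "AT",
    "quantitative", "AE", units = "score", rule = "Scale score"),
  v(67, "quality_of_life_score", "Quality of Life score", 6, "AT",
    "quantitative", "M", units = "score", rule = "Scale score"),
  v(68, "loneliness_score", "Loneliness scale score", 6, "AT",
    "quantitative", "", units = "score", rule = "Scale score"),
  # -- Cognitive status (theme 7) --
  v(69, "immediate_recall", "Immediate recall score", 7, "S", "quantitative",
    "AEGM", units = "score", rule = "Z score"),
  v(70, "delayed_recall", "Delayed recall score", 7, "S", "quantitative",
    "AEGM", units = "score", rule = "Z score"),
  v(71, "digit_symbol_substitution", "Digit symbol substitution score", 7,
    "S", "quantitative", "AM", units = "score", rule = "Z score"),
  v(72, "verbal_fluency", "Verbal fluency score", 7, "S", "quantitative",
    "EG", units = "score", rule = "Z score"),
  v(73, "choice_reaction_time", "Choice reaction time mSec", 7, "S",
    "quantitative", "AGM", units = "msec", rule = "Z score"),
  v(74, "fluid_intelligence", "Fluid intelligence score", 7, "S",
    "quantitative", "E", units = "score", rule = "Z score"),
  v(75, "mmse_score", "MMSE score", 7, "SC", "quantitative", "M",
    units = "score", rule = "Scale score"),
  v(76, "adas_cog_score", "ADAS cog total score", 7, "SC", "quantitative",
    "", units = "score", rule = "Scale score"),
  v(77, "cdr_score", "CDR total score", 7, "SC", "quantitative", "M",
    units = "score", rule = "Scale score"),
  v(78, "subjective_memory_complaint", "Subjective memory complaint", 7,
    "AT", "categorical", "E", cbk = "yn"),
  v(79, "mci_diagnosis", "MCI diagnosis", 7, "AT", "categorical", "",
    cbk = "yn"),
  # -- Lifestyle (theme 8) --
  v(80, "alcohol_consumption", "Alcohol consumption", 8, "AT",
    "quantitative", "EM", units = "units/week",
    rule = "Alcohol units per week, other"),
  v(81, "smoking_status", "Smoking status", 8, "AT", "categorical", "AEGM",
    cbk = "smoking"),
  v(82, "vigorous_exercise", "Vigorous exercise", 8, "AT", "categorical",
    "AEGM", cbk = "yn"),
  v(83, "moderate_exercise", "Moderate exercise", 8, "AT", "categorical",
    "AEM", cbk = "yn"),
  v(84, "walking", "Walking", 8, "AT", "categorical", "EM", cbk = "yn"),
  v(85, "sleep_quality", "Sleep quality scale", 8, "AT", "quantitative", "E",
    units = "score", rule = "Scale score"),
  v(86, "sleep_hours", "Sleep hours per night", 8, "SC", "quantitative",
    "EM", units = "hours", rule = "Hours per night"),
  # -- Life functionality (theme 9) --
  v(87, "adl_score", "ADL score", 9, "AT", "quantitative", "EM",
    units = "score",
    rule = "Scale score (higher value higher independence)"),
  v(88, "iadl_score", "IADL score", 9, "AT", "quantitative", "EM",
    units = "score", rule = "Scale score (higher value higher functioning)"),
  # -- Physical environment (theme 10) --
  v(89, "house_occupants", "Number of house occupants", 10, "SC",
    "quantitative", "AEG", units = "count", rule = "Value (occupants)"),
  v(90, "number_of_rooms", "Number of rooms", 10, "SC", "quantitative",
    "EGM", units = "count", rule = "Value (rooms)"),
  v(91, "accommodation_type", "Type of accommodation", 10, "AT",
    "categorical", "GM", cbk = "housing"),
  v(92, "pollution_grime", "Pollution (grime in house)", 10, "SC",
    "categorical", "", cbk = "yn"),
  # -- Social environment (theme 11) --
  v(93, "social_contacts_month", "Number of contacts/month", 11, "SC",
    "quantitative", "E", units = "count",
    rule = "Value (number of social contacts)"),
  v(94, "social_media_sites", "Social media sites used", 11, "SC",
    "quantitative", "E", units = "count",
    rule = "Value (number of sites used)"),
  v(95, "social_media_daily", "Social media use daily", 11, "SC",
    "quantitative", "E", units = "count", rule = "Value (types used daily)"),
  # -- Physical examination (theme 12) --
  v(96, "height", "Height", 12, "SC", "quantitative", "AEGM", units = "cm"),
  v(97, "weight", "Weight", 12, "SC", "quantitative", "AEGM", units = "kg"),
  v(98, "bmi", "BMI", 12, "SC", "quantitative", "AEGM", units = "kg/m^2"),
  v(99, "grip_strength", "Grip strength", 12, "SC", "quantitative", "EM",
    units = "kg"),
  v(100, "gait_speed", "Gait (walking) speed", 12, "SC", "quantitative", "E",
    units = "m/sec"),
  v(101, "systolic_bp", "Systolic BP", 12, "SC", "quantitative", "AEGM",
    units = "mm/hg"),
  v(102, "diastolic_bp", "Diastolic BP", 12, "SC", "quantitative", "AEGM",
    units = "mm/hg"),
  # -- Imaging (theme 13) --
  v(103, "white_matter_volume", "White matter volume", 13, "SC",
    "quantitative", "M", units = "mm^3"),
  v(104, "grey_matter_volume", "Grey matter volume", 13, "SC",
    "quantitative", "M", units = "mm^3"),
  v(105, "left_hippocampal_volume", "Left hippocampal volume", 13, "SC",
    "quantitative", "M", units = "mm^3"),
  v(106, "right_hippocampal_volume", "Right hippocampal volume", 13, "SC",
    "quantitative", "M", units = "mm^3"),
  v(107, "wm_hyperintensities", "WM hyperintensities", 13, "SC",
    "quantitative", "M", units = "mm^3"),
  v(108, "amyloid_pib_suvr", "Amyloid PiB SUVR", 13, "SC", "quantitative",
    "M", units = "ratio"),
  # -- Biosample assays (theme 16) --
  v(109, "haemoglobin", "Haemoglobin", 16, "SC", "quantitative", "EM",
    units = "mg/dl"),
  v(110, "white_cell_count", "White cell count", 16, "SC", "quantitative",
    "EM", units = "mg/dl"),
  v(111, "rbc_count", "RBC count", 16, "SC", "quantitative", "E",
    units = "mg/dl"),
  v(112, "total_cholesterol", "Total cholesterol", 16, "SC", "quantitative",
    "AEGM", units = "mg/dl"),
  v(113, "hdl_cholesterol", "HDL cholesterol", 16, "SC", "quantitative",
    "AEGM", units = "mg/dl"),
  v(114, "creatinine", "Creatinine", 16, "SC", "quantitative", "AEGM",
    units = "mg/dl"),
  v(115, "glucose", "Glucose", 16, "SC", "quantitative", "AEGM",
    units = "mg/dl"),
  v(116, "crp", "CRP", 16, "SC", "quantitative", "AEM", units = "mg/dl"),
  v(117, "cortisol_decrease", "Cortisol decrease", 16, "SC", "quantitative",
    "A", units = "mg/dl"),
  v(118, "abeta_42_plasma", "Abeta 1-42 (plasma)", 16, "SC", "quantitative",
    "AM", units = "pg/ml"),
  v(119, "abeta_40_plasma", "Abeta 1-40 (plasma)", 16, "SC", "quantitative",
    "AM", units = "pg/ml"),
  v(120, "abeta_42_csf", "Abeta 1-42 (CSF)", 16, "SC", "quantitative", "M",
    units = "pg/ml"),
  v(121, "abeta_40_csf", "Abeta 1-40 (CSF)", 16, "SC", "quantitative", "M",
    units = "pg/ml"),
  v(122, "total_tau", "Total tau", 16, "SC", "quantitative", "M",
    units = "pg/ml"),
  v(123, "p_tau", "P tau", 16, "SC", "quantitative", "M", units = "pg/ml"),
  # -- Molecular (theme 17) --
  v(124, "apoe_status", "APOE status", 17, "SC", "categorical", "AEGM",
    cbk = "apoe")
)

stopifnot(length(vars) == 124)

interpretive9 <- c("ethnicity", "cohabitation", "educational_level", "income",
                   "smoking_status", "vigorous_exercise", "moderate_exercise",
                   "walking", "accommodation_type")

# Applied strategy: the classification used in the utility evaluation.
# All yes/no items harmonised by inference or recode count as algorithmic
# (44 of them), plus the nine interpretive transformations; the six
# cognitive scores are standardised; everything else is a direct map.
applied_at_rows <- c(17:20, 21:39, 41:58, 60, 61, 78)
applied_for <- function(x) {
  if (x$id %in% interpretive9) return("AT")
  if (x$declared == "S") return("S")
  if (x$row %in% applied_at_rows) return("AT")
  if (x$pres == "") return(x$declared)   # absent: keep the declared tag
  "SC"
}

default_rule_text <- function(x) {
  if (!is.na(x$rule)) return(x$rule)
  if (x$type == "date") return("Gregorian calendar (yyyy-mm-dd)")
  if (x$type == "categorical") {
    entries <- codebooks[[x$cbk]]
    return(paste(vapply(entries, function(e)
      paste(e$code, e$label), ""), collapse = "; "))
  }
  if (x$type == "quantitative") return(paste0("Value (", x$units, ")"))
  "Free text"
}

schema_vars <- lapply(vars, function(x) {
  list(
    variable_id = x$id,
    display_name = x$name,
    row_number = x$row,
    theme_number = x$theme,
    declared_strategy = x$declared,
    applied_strategy = applied_for(x),
    type = x$type,
    rule_text = default_rule_text(x),
    units = if (is.na(x$units)) NULL else x$units,
    codebook = if (is.na(x$cbk)) NULL else codebooks[[x$cbk]],
    missing_policy = "empty field",
    interpretive = x$id %in% interpretive9
  )
})

schema <- list(
  schema_name = "csurv_core_124",
  version = "1.0",
  themes = lapply(seq_len(nrow(themes)), function(i)
    list(theme_number = themes$theme_number[i],
         theme_name = themes$theme_name[i])),
  variables = schema_vars
)

write_json(schema, file.path(out_dir, "csurv_core_124.json"),
           auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null")

# ---------------------------------------------------------------------------
# Presence matrix fixture
# ---------------------------------------------------------------------------

cohorts <- c(A = "airwave", E = "elsa", G = "genscot", M = "memento")

pres <- data.frame(
  variable_id = vapply(vars, `[[`, "", "id"),
  airwave = vapply(vars, function(x) as.integer(grepl("A", x$pres)), 0L),
  elsa = vapply(vars, function(x) as.integer(grepl("E", x$pres)), 0L),
  genscot = vapply(vars, function(x) as.integer(grepl("G", x$pres)), 0L),
  memento = vapply(vars, function(x) as.integer(grepl("M", x$pres)), 0L),
  stringsAsFactors = FALSE
)
write.csv(pres, file.path(out_dir, "presence_matrix.csv"), row.names = FALSE)

# --- consistency checks against the published counting claims -------------

m <- as.matrix(pres[, -1])
theme_of <- vapply(vars, `[[`, 0, "theme")

# per-cohort totals
stopifnot(identical(unname(colSums(m)), c(47, 73, 60, 92)))
# overlap histogram
rs <- rowSums(m)
stopifnot(identical(unname(table(factor(rs, levels = 0:4))),
                    table(factor(c(rep(0, 4), rep(1, 46), rep(2, 30),
                                   rep(3, 10), rep(4, 34)), levels = 0:4)) |>
                      unname()))
# unique-variable counts
stopifnot(sum(rs == 1 & m[, "elsa"] == 1) == 13,
          sum(rs == 1 & m[, "memento"] == 1) == 26)
# theme x cohort table
tab <- rowsum(m, group = theme_of)
expected <- rbind(
  `1` = c(6, 7, 6, 9), `2` = c(6, 7, 7, 6), `3` = c(0, 4, 0, 0),
  `4` = c(10, 13, 10, 18), `5` = c(0, 0, 15, 12), `6` = c(3, 7, 3, 5),
  `7` = c(4, 5, 4, 6), `8` = c(3, 7, 2, 6), `9` = c(0, 2, 0, 2),
  `10` = c(1, 2, 3, 2), `11` = c(0, 3, 0, 0), `12` = c(5, 7, 5, 6),
  `13` = c(0, 0, 0, 6), `16` = c(8, 8, 4, 13), `17` = c(1, 1, 1, 1)
)
stopifnot(nrow(tab) == nrow(expected), all(tab == expected))
# strategy tallies on represented variables
applied <- vapply(vars, applied_for, "")
rep_idx <- rs > 0
stopifnot(sum(applied[rep_idx] == "SC") == 61,
          sum(applied[rep_idx] == "AT") == 53,
          sum(applied[rep_idx] == "S") == 6)
# themes covered
stopifnot(identical(sort(unique(theme_of)),
                    setdiff(1:18, c(14, 15, 18)) * 1.0))

# ---------------------------------------------------------------------------
# Per-cohort mapping files
# ---------------------------------------------------------------------------

conv <- list(
  airwave = list(yes = "Yes", no = "No", date_dialect = "dmy",
                 id_field = "pid", currency = "GBP"),
  elsa = list(yes = "yes", no = "no", date_dialect = "ymd",
              id_field = "idauniq", currency = "GBP"),
  genscot = list(yes = "Y", no = "N", date_dialect = "dmy",
                 id_field = "id", currency = "GBP"),
  memento = list(yes = "Oui", no = "Non", date_dialect = "ymd",
                 id_field = "num_id", currency = "EUR")
)

# default simulation hints by units (location, scale for a normal draw)
sim_by_units <- list(
  years = c(62, 9), score = c(20, 5), count = c(3, 2), cm = c(168, 9),
  kg = c(76, 13), `kg/m^2` = c(27, 4), `mm/hg` = c(120, 15),
  `m/sec` = c(1.2, 0.25), `mm^3` = c(4200, 600), ratio = c(1.3, 0.25),
  `mg/dl` = c(110, 30), `pg/ml` = c(180, 70), hours = c(7, 1.1),
  `units/week` = c(9, 6), msec = c(620, 120)
)

recode_map <- function(...) {
  # preserves entry order; names are source labels, values target codes
  entries <- list(...)
  lapply(names(entries), function(nm) list(label = nm, code = entries[[nm]]))
}

yn_recode <- function(cid, src) {
  k <- conv[[cid]]
  args <- stats::setNames(list(1L, 0L), c(k$yes, k$no))
  list(kind = "recode", source = src, map = do.call(recode_map, args),
       unmapped_policy = "missing")
}

num_identity <- function(src, sim = NULL) {
  r <- list(kind = "identity", source = src, value_type = "numeric")
  if (!is.null(sim)) r$sim <- sim
  r
}

# Education recodes (native qualification labels -> 4-level experience scale)
edu_maps <- list(
  airwave = recode_map("Post grad" = 1L, "Deg. equiv" = 2L,
                       "A level NVQ3" = 3L, "GCSE NVQ2" = 3L, "NVQ1" = 3L,
                       "No qualification" = 4L),
  elsa = recode_map("Deg. equiv" = 2L, "Higher ed" = 3L, "NVQ3" = 3L,
                    "NVQ2" = 3L, "NVQ1" = 3L, "Foreign/other" = 3L,
                    "No qualification" = 4L),
  genscot = recode_map("College/Uni" = 2L, "Highers" = 3L, "Standards" = 3L,
                       "No qualification" = 4L),
  memento = recode_map("Higher dipl" = 1L, "Degree" = 2L,
                       "General Bac" = 3L, "Tech Bac" = 3L, "CAP/BEP" = 3L,
                       "Elementary" = 3L, "Certificate" = 4L, "Primary" = 4L,
                       "No qualification" = 4L)
)

eth_maps <- list(
  airwave = recode_map("White" = 1L, "Black" = 2L, "Asian" = 3L,
                       "Mixed" = 4L, "Other" = 5L),
  elsa = recode_map("White" = 1L, "Non white" = 5L),
  genscot = recode_map("White" = 1L, "Black" = 2L, "Asian" = 3L,
                       "Mixed" = 4L, "Other" = 5L)
)

cohab_maps <- list(
  airwave = recode_map("Single" = 1L, "Married" = 2L, "Remarried" = 2L,
                       "Divorced" = 3L, "Separated" = 3L, "Widowed" = 4L,
                       "Other" = 5L),
  elsa = recode_map("Single" = 1L, "Married" = 2L, "Cohabiting" = 2L,
                    "Divorced/separated" = 3L, "Widowed" = 4L),
  # Generation Scotland asks "Are you living as a couple?"
  genscot = recode_map("Y" = 2L, "N" = 1L),
  memento = recode_map("Single" = 1L, "Married/cohabiting" = 2L,
                       "Divorced/separated" = 3L, "Widowed" = 4L,
                       "Other" = 5L)
)

housing_maps <- list(
  genscot = recode_map("House/bungalow" = 1L, "Apartment/flat" = 2L,
                       "Hostel" = 3L, "Mobile/caravan" = 4L,
                       "Homeless" = 4L, "Other" = 4L),
  memento = recode_map("Single family dwelling" = 1L, "Apartment" = 2L,
                       "Residential" = 3L, "Sheltered" = 3L,
                       "Care home" = 3L, "Other" = 4L)
)

# income band -> midpoint maps (open top band = 1.5 x lower bound)
income_bands <- list(
  airwave = list(
    list(label = "<£25,999", midpoint = 13000),
    list(label = "£26,000-£37,999", midpoint = 32000),
    list(label = "£38,000-£59,999", midpoint = 49000),
    list(label = "£60,000+", midpoint = 90000)
  ),
  memento = list(
    list(label = "€400-<800", midpoint = 600),
    list(label = "€800-<1200", midpoint = 1000),
    list(label = "€1200-<1800", midpoint = 1500),
    list(label = "€1800-<2500", midpoint = 2150),
    list(label = "€2500-<4000", midpoint = 3250),
    list(label = "€4000-<6000", midpoint = 5000),
    list(label = "€6000+", midpoint = 9000)
  )
)

freq_recode <- function(src) {
  list(kind = "recode", source = src,
       map = recode_map("More than once a week" = 1L, "Once a week" = 1L,
                        "One to three times a month" = 1L,
                        "Hardly ever or never" = 0L),
       unmapped_policy = "missing")
}

any_positive <- function(src_stub) {
  list(kind = "any_positive",
       sources = paste0(src_stub, c("_days_week", "_hours_day", "_min_day")))
}

# ELSA medical-history variables inferred from a recorded diagnosis date
elsa_date_presence <- function(vid)
  list(kind = "date_presence", source = paste0(vid, "_diagdate"),
       dialect = "ymd")

# Memento clinical conclusions share one source field
memento_dx <- function(trigger)
  list(kind = "proxy_condition", source = "diagnosis_conclusion",
       trigger = trigger)

# Per-variable overrides: rules[[variable_id]][[cohort_id]].  Anything not
# listed here falls through to a type-driven default rule.
overrides <- list(
  cohort_id = lapply(conv, function(k)
    list(kind = "identity", source = k$id_field, value_type = "text")),
  gender = list(
    airwave = list(kind = "recode", source = "gender",
                   map = recode_map("Male" = 1L, "Female" = 2L),
                   unmapped_policy = "missing"),
    elsa = list(kind = "recode", source = "gender",
                map = recode_map("male" = 1L, "female" = 2L),
                unmapped_policy = "missing"),
    genscot = list(kind = "recode", source = "sex",
                   map = recode_map("M" = 1L, "F" = 2L),
                   unmapped_policy = "missing"),
    memento = list(kind = "recode", source = "sexe",
                   map = recode_map("Homme" = 1L, "Femme" = 2L),
                   unmapped_policy = "missing")
  ),
  ethnicity = list(
    airwave = list(kind = "recode", source = "ethnic_group",
                   map = eth_maps$airwave, unmapped_policy = "missing"),
    elsa = list(kind = "recode", source = "ethnicity",
                map = eth_maps$elsa, unmapped_policy = "missing"),
    genscot = list(kind = "recode", source = "ethnic_group",
                   map = eth_maps$genscot, unmapped_policy = "missing"),
    memento = list(kind = "not_collected",
                   reason = "not collected (legal restriction)")
  ),
  cohabitation = list(
    airwave = list(kind = "recode", source = "marital_status",
                   map = cohab_maps$airwave, unmapped_policy = "missing"),
    elsa = list(kind = "recode", source = "marital_status",
                map = cohab_maps$elsa, unmapped_policy = "missing"),
    genscot = list(kind = "recode", source = "living_as_couple",
                   map = cohab_maps$genscot, unmapped_policy = "missing"),
    memento = list(kind = "recode", source = "marital_status",
                   map = cohab_maps$memento, unmapped_policy = "missing")
  ),
  educational_level = list(
    airwave = list(kind = "recode", source = "qualification",
                   map = edu_maps$airwave, unmapped_policy = "missing"),
    elsa = list(kind = "recode", source = "qualification",
                map = edu_maps$elsa, unmapped_policy = "missing"),
    genscot = list(kind = "recode", source = "qualification",
                   map = edu_maps$genscot, unmapped_policy = "missing"),
    memento = list(kind = "recode", source = "qualification",
                   map = edu_maps$memento, unmapped_policy = "missing")
  ),
  income = list(
    airwave = list(kind = "quantile", source = "income_band",
                   bands = income_bands$airwave),
    elsa = list(kind = "quantile", source = "annual_income",
                sim = list(dist = "lnorm", meanlog = 10.1, sdlog = 0.55)),
    genscot = list(kind = "quantile", source = "annual_income",
                   sim = list(dist = "lnorm", meanlog = 10.2, sdlog = 0.5)),
    memento = list(kind = "quantile", source = "monthly_income_band",
                   bands = income_bands$memento)
  ),
  # ELSA: medical conditions inferred from diagnosis dates or symptom scores
  t1d_diagnosis = list(elsa = elsa_date_presence("t1d")),
  t2d_diagnosis = list(elsa = elsa_date_presence("t2d")),
  depression_diagnosis = list(
    elsa = elsa_date_presence("depression"),
    memento = list(kind = "score_threshold", source = "cesd_score",
                   threshold = 16, direction = "ge",
                   sim = list(min = 0, max = 60))
  ),
  visual_difficulty = list(
    elsa = list(kind = "score_threshold", source = "eyesight_rating",
                threshold = 4, direction = "ge", sim = list(min = 1, max = 6))
  ),
  hearing_difficulty = list(
    elsa = list(kind = "score_threshold", source = "hearing_rating",
                threshold = 4, direction = "ge", sim = list(min = 1, max = 6))
  ),
  angina_diagnosis = list(
    elsa = elsa_date_presence("angina"),
    genscot = list(kind = "proxy_condition", source = "heart_disease",
                   trigger = "Y")
  ),
  mi_diagnosis = list(
    elsa = elsa_date_presence("mi"),
    genscot = list(kind = "proxy_condition", source = "heart_disease",
                   trigger = "Y")
  ),
  hypertension_diagnosis = list(elsa = elsa_date_presence("hypertension")),
  stroke_diagnosis = list(elsa = elsa_date_presence("stroke")),
  head_injury = list(elsa = elsa_date_presence("head_injury")),
  copd_diagnosis = list(elsa = elsa_date_presence("copd")),
  arthritis_diagnosis = list(elsa = elsa_date_presence("arthritis")),
  ad_diagnosis = list(memento = memento_dx("AD")),
  ad_ftd_diagnosis = list(memento = memento_dx("FTD")),
  ad_mixed_diagnosis = list(memento = memento_dx("AD mixed")),
  vad_diagnosis = list(memento = memento_dx("VaD")),
  pd_diagnosis = list(memento = memento_dx("PD")),
  current_pain = list(
    memento = list(kind = "score_threshold", source = "pain_vas",
                   threshold = 4, direction = "ge",
                   sim = list(min = 0, max = 10))
  ),
  medications = list(
    memento = num_identity("n_prescribed", sim = list(dist = "norm",
                                                      mean = 3, sd = 2,
                                                      round = TRUE, min = 0))
  ),
  cause_of_death = list(
    memento = list(kind = "text_lookup", source = "cause_of_death_text",
                   lookup = recode_map("myocardial infarction" = 11L,
                                       "stroke" = 11L,
                                       "lung cancer" = 2L,
                                       "pneumonia" = 12L,
                                       "dementia" = 6L,
                                       "renal failure" = 16L))
  ),
  alcohol_consumption = list(
    elsa = list(kind = "alcohol_units", source = "units_week"),
    memento = list(kind = "alcohol_units", source = "units_week",
                   flag_field = "drinks_unquantified", flag_trigger = "Oui")
  ),
  smoking_status = list(
    airwave = list(kind = "recode", source = "smoking",
                   map = recode_map("Never" = 0L, "Ex" = 1L, "Current" = 2L),
                   unmapped_policy = "missing"),
    elsa = list(kind = "recode", source = "smoking",
                map = recode_map("Never" = 0L, "Ex" = 1L, "Current" = 2L),
                unmapped_policy = "missing"),
    genscot = list(kind = "smoking_two_field", ever_field = "ever_smoked",
                   current_field = "smoking_now", yes = "Y", no = "N"),
    memento = list(kind = "recode", source = "smoking",
                   map = recode_map("Never" = 0L, "Ex" = 1L, "Current" = 2L),
                   unmapped_policy = "missing")
  ),
  vigorous_exercise = list(
    airwave = yn_recode("airwave", "vigorous_exercise"),
    elsa = freq_recode("vigorous_activity_freq"),
    genscot = list(kind = "proxy_condition", source = "sports_club",
                   trigger = "Y"),
    memento = any_positive("vig")
  ),
  moderate_exercise = list(
    airwave = yn_recode("airwave", "moderate_exercise"),
    elsa = freq_recode("moderate_activity_freq"),
    memento = any_positive("mod")
  ),
  walking = list(
    elsa = freq_recode("walking_freq"),
    memento = any_positive("walk")
  ),
  accommodation_type = list(
    genscot = list(kind = "recode", source = "accommodation",
                   map = housing_maps$genscot, unmapped_policy = "missing"),
    memento = list(kind = "recode", source = "accommodation",
                   map = housing_maps$memento, unmapped_policy = "missing")
  ),
  height = list(
    # Memento records height in metres
    memento = list(kind = "unit_convert", source = "height_m", factor = 100,
                   offset = 0, sim = list(dist = "norm", mean = 1.68,
                                          sd = 0.09))
  ),
  glucose = list(
    # Generation Scotland assays glucose in mmol/l
    genscot = list(kind = "unit_convert", source = "glucose_mmol",
                   factor = 18.016, offset = 0,
                   sim = list(dist = "norm", mean = 5.5, sd = 1.1))
  ),
  choice_reaction_time = list(
    airwave = list(kind = "zscore", source = "crt_msec",
                   sim = list(dist = "lnorm", meanlog = 6.4, sdlog = 0.6)),
    genscot = list(kind = "zscore", source = "crt_msec",
                   sim = list(dist = "lnorm", meanlog = 6.45, sdlog = 0.6)),
    memento = list(kind = "zscore", source = "crt_msec",
                   sim = list(dist = "lnorm", meanlog = 6.5, sdlog = 0.6))
  ),
  apoe_status = list(
    airwave = list(kind = "apoe", source = "apoe_genotype"),
    elsa = list(kind = "apoe", source = "apoe_genotype"),
    genscot = list(kind = "apoe", source = "apoe_genotype"),
    memento = list(kind = "apoe", source = "apoe_genotype")
  )
)

default_rule <- function(x, cid) {
  k <- conv[[cid]]
  if (x$type == "date")
    return(list(kind = "date_truncate", source = x$id,
                dialect = k$date_dialect))
  if (x$type == "categorical" && identical(x$cbk, "yn"))
    return(yn_recode(cid, x$id))
  if (x$declared == "S")
    return(list(kind = "zscore", source = x$id))
  if (x$type == "quantitative") {
    s <- sim_by_units[[x$units]]
    sim <- list(dist = "norm", mean = s[1], sd = s[2])
    if (x$units == "count") sim$round <- TRUE
    if (x$units %in% c("count", "units/week", "score")) sim$min <- 0
    return(num_identity(x$id, sim = sim))
  }
  if (x$type == "text")
    return(list(kind = "identity", source = x$id, value_type = "text"))
  stop("no default rule for ", x$id)
}

for (cid in unname(cohorts)) {
  letter <- names(cohorts)[match(cid, cohorts)]
  rules <- list()
  for (x in vars) {
    has_override <- !is.null(overrides[[x$id]]) &&
      !is.null(overrides[[x$id]][[cid]])
    present <- grepl(letter, x$pres)
    if (!present && !(x$id == "ethnicity" && cid == "memento")) next
    rule <- if (has_override) overrides[[x$id]][[cid]] else
      default_rule(x, cid)
    rule <- c(list(variable_id = x$id), rule)
    rules[[length(rules) + 1]] <- rule
  }
  doc <- list(
    cohort_id = cid,
    display_name = c(airwave = "Airwave Health Monitoring Study",
                     elsa = "English Longitudinal Study of Ageing",
                     genscot = "Generation Scotland",
                     memento = "Memento")[[cid]],
    currency = conv[[cid]]$currency,
    date_dialect = conv[[cid]]$date_dialect,
    rules = rules
  )
  write_json(doc, file.path(out_dir, paste0("mappings_", cid, ".json")),
             auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null")
}

# rule-count check: rules per cohort = presence totals (+1 for the memento
# ethnicity "not collected" marker rule)
for (cid in unname(cohorts)) {
  doc <- read_json(file.path(out_dir, paste0("mappings_", cid, ".json")))
  expected_n <- sum(pres[[cid]]) + as.integer(cid == "memento")
  stopifnot(length(doc$rules) == expected_n)
}

cat("fixtures written and verified\n")
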