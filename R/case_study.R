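#' Bundled case study: provisional restorations in single-tooth implant
#' treatment
#'
#' Seven provisional-restoration alternatives assessed qualitatively on
#' eight criteria drawn from the prosthodontic literature. Criteria 1
#' (esthetic potential), 2 (patient comfort), 6 (ease of removal),
#' 7 (durability) and 8 (modifications) are benefit criteria; 3
#' (treatment time), 4 (laboratory cost) and 5 (occlusal clearance) are
#' cost criteria. Columns are scored with the built-in ordinal rules:
#' rule 1 for criteria 1, 2 and 7; rule 2 for criterion 3; rule 3 for
#' criterion 4; rule 4 for criterion 5; rule 5 for criteria 6 and 8.
#' Criterion 2 uses only part of rule 1's vocabulary (excellent, good,
#' poor) but keeps the full 1-5 mapping.
#'
#' @return A [raw_assessment_table()] with 7 alternatives and 8 criteria.
#' @seealso [convert_table()], [case_study_matrix()]
#' @export
load_case_study <- function() {
  criteria <- list(
    criterion_spec("esthetic potential", "max", 1),
    criterion_spec("patient comfort",    "max", 1),
    criterion_spec("treatment time",     "min", 2),
    criterion_spec("laboratory cost",    "min", 3),
    criterion_spec("occlusal clearance", "min", 4),
    criterion_spec("ease of removal",    "max", 5),
    criterion_spec("durability",         "max", 1),
    criterion_spec("modifications",      "max", 5)
  )
  alternatives <- c(
    "Removable partial denture",
    "Vacuum-formed appliances",
    "Bonded extracted tooth or denture",
    "Metal or fiber-reinforced resin-bonded fixed partial denture",
    "Wire-retained resin-bonded fixed partial denture",
    "Acrylic resin provisional fixed partial denture",
    "Implant-supported fixed provisional restoration"
  )
  labels <- matrix(c(
    "Good",      "Poor",      "Minimal",  "Medium", "Substantial", "Easy",      "Fair",      "Easy",
    "Fair",      "Poor",      "Minimal",  "Low",    "None",        "Easy",      "Fair",      "Moderate",
    "Poor",      "Good",      "Moderate", "None",   "Minimal",     "Moderate",  "Poor",      "Difficult",
    "Good",      "Good",      "Lengthy",  "High",   "Moderate",    "Difficult", "Good",      "Difficult",
    "Good",      "Good",      "Moderate", "Low",    "Moderate",    "Easy",      "Good",      "Moderate",
    "Very good", "Excellent", "Lengthy",  "Low",    "Minimal",     "Easy",      "Fair",      "Easy",
    "Excellent", "Excellent", "Lengthy",  "Medium", "Minimal",     "Easy",      "Excellent", "Easiest"
  ), nrow = 7, byrow = TRUE)
  raw_assessment_table(labels, criteria, alternatives)
}

#' Numeric decision matrix of the bundled case study
#'
#' The hard-coded published numeric form of the case study, kept as an
#' independent fixture against which [convert_table()] of
#' [load_case_study()] is validated (they must agree cell-for-cell).
#'
#' @return A [decision_matrix()] (7 alternatives x 8 criteria).
#' @export
case_study_matrix <- function() {
  raw <- load_case_study()
  x <- matrix(c(
    3, 1, 1, 3, 4, 3, 2, 3,
    2, 1, 1, 2, 1, 3, 2, 2,
    1, 3, 2, 1, 2, 2, 1, 1,
    3, 3, 3, 4, 3, 1, 3, 1,
    3, 3, 2, 2, 3, 3, 3, 2,
    4, 5, 3, 2, 2, 3, 2, 3,
    5, 5, 3, 3, 2, 3, 5, 4
  ), nrow = 7, byrow = TRUE)
  decision_matrix(x, raw$criteria, raw$alternatives)
}
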