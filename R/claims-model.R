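#' @importFrom rlang .data abort warn
#' @importFrom dplyr %>%
NULL

# Closed vocabularies shared across the package. The nine expense
# classifications mirror the structure of a rural public-insurance claims
# system; the insurer's own labels are not public, so this set is a
# documented, configurable stand-in with the same cardinality.

#' Controlled vocabularies for claims records
#'
#' @description
#' `ncms_classifications()` returns the nine expense classifications used to
#' itemize hospitalization costs. `cancer_sites()`, `cancer_stages()`,
#' `therapy_classes()`, `facility_tiers()`, and `trial_arms()` return the
#' closed sets of values the validators accept for the corresponding columns.
#'
#' @return A character vector of allowed values.
#' @export
ncms_classifications <- function() {
  c("bed", "nursing", "diagnostics", "imaging", "laboratory",
    "surgery", "radiation", "medication_chemo", "medication_other")
}

#' @rdname ncms_classifications
#' @export
cancer_sites <- function() {
  c("esophageal", "cardial", "non_cardial_gastric", "duodenal")
}

#' @rdname ncms_classifications
#' @export
cancer_stages <- function() {
  c("0-I", "II", "III", "IV", "unknown")
}

#' @rdname ncms_classifications
#' @export
therapy_classes <- function() {
  c("endoscopic", "single_radical_resection", "radical_plus_adjuvant",
    "radio_chemo_only", "supportive")
}

#' @rdname ncms_classifications
#' @export
facility_tiers <- function() {
  c("primary", "secondary", "tertiary")
}

#' @rdname ncms_classifications
#' @export
trial_arms <- function() {
  c("screening", "control")
}

#' Diagnosis-code prefixes identifying upper G.I. cancer claims
#'
#' ICD-10 block-level prefixes for esophageal cancer (C15), gastric cancer
#' (C16), carcinoma in situ of digestive organs (D00) and other diseases of
#' the esophagus (K22, covering precancerous lesions). Matching is by string
#' prefix, so "C15.3" matches "C15".
#'
#' @return Character vector of code prefixes.
#' @export
upper_gi_code_prefixes <- function() {
  c("C15", "C16", "D00", "K22")
}

#' Expense classifications counted as upper-G.I.-directed therapy
#'
#' Used by [verify_case()] as the second qualification route: a case whose
#' diagnosis codes never name an upper G.I. condition still qualifies when
#' its line items record cancer-directed therapy (surgery, radiation, or
#' chemotherapy medication).
#'
#' @return Character vector of classification labels.
#' @export
upper_gi_therapy_classes <- function() {
  c("surgery", "radiation", "medication_chemo")
}

chk <- function(cond, msg, ...) {
  if (!cond) abort(sprintf(msg, ...))
}

assert_enum <- function(x, allowed, table, column) {
  bad <- !is.na(x) & !(x %in% allowed)
  chk(!any(bad),
      "%s: column '%s' contains values outside {%s}: %s",
      table, column, paste(allowed, collapse = ", "),
      paste(unique(x[bad]), collapse = ", "))
}

assert_cols <- function(df, cols, table) {
  missing <- setdiff(cols, names(df))
  chk(length(missing) == 0,
      "%s: missing required column(s): %s", table,
      paste(missing, collapse = ", "))
}

as_date_col <- function(x, table, column) {
  if (inherits(x, "Date")) return(x)
  out <- as.Date(as.character(x), format = "%Y-%m-%d")
  bad <- which(is.na(out) & !is.na(x))
  chk(length(bad) == 0,
      "%s: column '%s' has unparseable ISO-8601 dates at row(s) %s",
      table, column, paste(utils::head(bad, 5), collapse = ", "))
  out
}

#' Validate a participant roster
#'
#' Coerces types and enforces the participant invariants: ISO dates, arm in
#' `trial_arms()`, and `end_of_followup >= enrollment_date`.
#'
#' @param participants A data frame with columns `participant_id`, `arm`,
#'   `enrollment_date`, `end_of_followup`, `age_at_enrollment`, `gender`,
#'   `education`, `occupation`, `household_income_per_capita`.
#' @return A validated tibble.
#' @export
validate_participants <- function(participants) {
  tbl <- "participants"
  df <- tibble::as_tibble(participants)
  assert_cols(df, c("participant_id", "arm", "enrollment_date",
                    "end_of_followup", "age_at_enrollment", "gender",
                    "education", "occupation",
                    "household_income_per_capita"), tbl)
  df$participant_id <- as.character(df$participant_id)
  chk(!anyDuplicated(df$participant_id),
      "%s: duplicated participant_id(s): %s", tbl,
      paste(unique(df$participant_id[duplicated(df$participant_id)]),
            collapse = ", "))
  assert_enum(df$arm, trial_arms(), tbl, "arm")
  assert_enum(df$education, c("primary-or-below", "middle-or-above"),
              tbl, "education")
  df$enrollment_date <- as_date_col(df$enrollment_date, tbl, "enrollment_date")
  df$end_of_followup <- as_date_col(df$end_of_followup, tbl, "end_of_followup")
  bad <- which(df$end_of_followup < df$enrollment_date)
  chk(length(bad) == 0,
      "%s: end_of_followup precedes enrollment_date for: %s", tbl,
      paste(df$participant_id[utils::head(bad, 5)], collapse = ", "))
  chk(all(df$household_income_per_capita >= 0, na.rm = TRUE),
      "%s: negative household_income_per_capita", tbl)
  df
}

#' Validate a cancer-case table
#'
#' Enforces the closed site/stage/therapy vocabularies and, when the
#' participant roster is supplied, that each diagnosis date falls inside the
#' owning participant's follow-up interval.
#'
#' @param cases Data frame with columns `participant_id`, `site`,
#'   `detection_mode`, `diagnosis_date`, `stage`, `therapy`.
#' @param participants Optional validated participant roster for the
#'   cross-table date invariant.
#' @return A validated tibble.
#' @export
validate_cases <- function(cases, participants = NULL) {
  tbl <- "cases"
  df <- tibble::as_tibble(cases)
  assert_cols(df, c("participant_id", "site", "detection_mode",
                    "diagnosis_date", "stage", "therapy"), tbl)
  df$participant_id <- as.character(df$participant_id)
  assert_enum(df$site, cancer_sites(), tbl, "site")
  assert_enum(df$detection_mode, c("screen_detected", "clinically_diagnosed"),
              tbl, "detection_mode")
  assert_enum(df$stage, cancer_stages(), tbl, "stage")
  assert_enum(df$therapy, therapy_classes(), tbl, "therapy")
  df$diagnosis_date <- as_date_col(df$diagnosis_date, tbl, "diagnosis_date")
  if (!is.null(participants)) {
    p <- participants[, c("participant_id", "enrollment_date",
                          "end_of_followup")]
    j <- dplyr::left_join(df, p, by = "participant_id")
    chk(!anyNA(j$enrollment_date),
        "%s: participant_id(s) absent from roster: %s", tbl,
        paste(unique(j$participant_id[is.na(j$enrollment_date)]),
              collapse = ", "))
    bad <- which(j$diagnosis_date < j$enrollment_date |
                   j$diagnosis_date > j$end_of_followup)
    chk(length(bad) == 0,
        "%s: diagnosis_date outside follow-up interval for: %s", tbl,
        paste(j$participant_id[utils::head(bad, 5)], collapse = ", "))
  }
  df
}

#' Validate a hospitalization-episode table
#'
#' Enforces `discharge_date >= admission_date`, non-negative totals, and the
#' accounting identity `out_of_pocket_expense = total_expense -
#' reimbursed_expense` within `tol` CNY.
#'
#' @param episodes Data frame with columns `episode_id`, `participant_id`,
#'   `facility_tier`, `admission_date`, `discharge_date`,
#'   `discharge_diagnosis_code`, `total_expense`, `reimbursed_expense`,
#'   `out_of_pocket_expense`.
#' @param tol Absolute tolerance (CNY) for the out-of-pocket identity.
#' @return A validated tibble.
#' @export
validate_episodes <- function(episodes, tol = 0.01) {
  tbl <- "episodes"
  df <- tibble::as_tibble(episodes)
  assert_cols(df, c("episode_id", "participant_id", "facility_tier",
                    "admission_date", "discharge_date",
                    "discharge_diagnosis_code", "total_expense",
                    "reimbursed_expense", "out_of_pocket_expense"), tbl)
  df$episode_id <- as.character(df$episode_id)
  df$participant_id <- as.character(df$participant_id)
  chk(!anyDuplicated(df$episode_id), "%s: duplicated episode_id", tbl)
  assert_enum(df$facility_tier, facility_tiers(), tbl, "facility_tier")
  df$admission_date <- as_date_col(df$admission_date, tbl, "admission_date")
  df$discharge_date <- as_date_col(df$discharge_date, tbl, "discharge_date")
  bad <- which(df$discharge_date < df$admission_date)
  chk(length(bad) == 0,
      "%s: discharge_date precedes admission_date at row(s) %s (episode %s)",
      tbl, paste(utils::head(bad, 5), collapse = ", "),
      paste(df$episode_id[utils::head(bad, 5)], collapse = ", "))
  chk(all(df$total_expense >= 0), "%s: negative total_expense", tbl)
  gap <- abs(df$out_of_pocket_expense -
               (df$total_expense - df$reimbursed_expense))
  bad <- which(gap > tol)
  chk(length(bad) == 0,
      "%s: out_of_pocket != total - reimbursed (>%g CNY) for episode(s): %s",
      tbl, tol, paste(df$episode_id[utils::head(bad, 5)], collapse = ", "))
  df
}

#' Validate a cost line-item table
#'
#' @param line_items Data frame with columns `episode_id`, `service_date`,
#'   `classification`, `quantity`, `unit_cost`, `out_of_pocket_portion`.
#' @param classifications Allowed classification labels.
#' @param tol Absolute tolerance (CNY) for `out_of_pocket_portion <=
#'   quantity * unit_cost`.
#' @return A validated tibble.
#' @export
validate_line_items <- function(line_items,
                                classifications = ncms_classifications(),
                                tol = 0.01) {
  tbl <- "line_items"
  df <- tibble::as_tibble(line_items)
  assert_cols(df, c("episode_id", "service_date", "classification",
                    "quantity", "unit_cost", "out_of_pocket_portion"), tbl)
  df$episode_id <- as.character(df$episode_id)
  assert_enum(df$classification, classifications, tbl, "classification")
  df$service_date <- as_date_col(df$service_date, tbl, "service_date")
  chk(all(df$quantity >= 0), "%s: negative quantity", tbl)
  bad <- which(df$out_of_pocket_portion > df$quantity * df$unit_cost + tol)
  chk(length(bad) == 0,
      "%s: out_of_pocket_portion exceeds quantity * unit_cost at row(s) %s",
      tbl, paste(utils::head(bad, 5), collapse = ", "))
  df
}

#' Validate a full claims dataset
#'
#' Runs all four table validators and the cross-table invariants, returning
#' the dataset with coerced types.
#'
#' @param data List with elements `participants`, `cases`, `episodes`,
#'   `line_items`.
#' @return The validated dataset (a list of four tibbles, class
#'   `claims_data`).
#' @export
validate_claims_data <- function(data) {
  participants <- validate_participants(data$participants)
  cases <- validate_cases(data$cases, participants)
  episodes <- validate_episodes(data$episodes)
  line_items <- validate_line_items(data$line_items)
  orphan <- setdiff(episodes$participant_id, participants$participant_id)
  chk(length(orphan) == 0,
      "episodes: participant_id(s) absent from roster: %s",
      paste(utils::head(orphan, 5), collapse = ", "))
  orphan <- setdiff(line_items$episode_id, episodes$episode_id)
  chk(length(orphan) == 0,
      "line_items: episode_id(s) absent from episodes: %s",
      paste(utils::head(orphan, 5), collapse = ", "))
  structure(list(participants = participants, cases = cases,
                 episodes = episodes, line_items = line_items),
            class = "claims_data")
}

#' Rule-based verification that claims constitute a treated upper G.I. cancer
#'
#' A participant's hospitalizations qualify when either (a) some episode's
#' discharge diagnosis code starts with one of the upper G.I. block prefixes
#' (C15, C16, D00, K22 by default), or (b) some line item's classification is
#' in the configured cancer-directed therapy set. An empty episode set is
#' simply not a case (`FALSE`), never an error. Including the precancerous
#' blocks D00/K22 as qualifying is the default and configurable via
#' `code_prefixes`.
#'
#' @param episodes Episode tibble for a single participant.
#' @param line_items Line-item tibble (only rows matching `episodes` are
#'   consulted); may be `NULL` when no itemization exists.
#' @param code_prefixes Diagnosis-code prefixes that qualify.
#' @param therapy_classes Line-item classifications that qualify.
#' @return Length-one logical.
#' @export
verify_case <- function(episodes, line_items = NULL,
                        code_prefixes = upper_gi_code_prefixes(),
                        therapy_classes = upper_gi_therapy_classes()) {
  if (is.null(episodes) || nrow(episodes) == 0) return(FALSE)
  stopifnot(length(unique(episodes$participant_id)) == 1)
  codes <- as.character(episodes$discharge_diagnosis_code)
  code_hit <- any(vapply(
    codes,
    function(cd) any(startsWith(cd, code_prefixes)),
    logical(1)
  ))
  if (code_hit) return(TRUE)
  if (is.null(line_items) || nrow(line_items) == 0) return(FALSE)
  li <- line_items[line_items$episode_id %in% episodes$episode_id, ,
                   drop = FALSE]
  any(li$classification %in% therapy_classes)
}

#' Verify every case in a dataset
#'
#' Applies [verify_case()] per participant listed in `data$cases` and returns
#' the case table with a logical `verified` column.
#'
#' @param data A `claims_data` list.
#' @inheritParams verify_case
#' @return The case tibble with a `verified` column.
#' @export
verify_cases <- function(data, code_prefixes = upper_gi_code_prefixes(),
                         therapy_classes = upper_gi_therapy_classes()) {
  eps <- split(data$episodes, data$episodes$participant_id)
  verified <- vapply(data$cases$participant_id, function(pid) {
    verify_case(eps[[pid]], data$line_items, code_prefixes, therapy_classes)
  }, logical(1), USE.NAMES = FALSE)
  dplyr::mutate(data$cases, verified = verified)
}

#' Follow-up length in whole days
#'
#' Calendar difference `end_of_followup - enrollment_date`, closed on both
#' ends, in integer days.
#'
#' @param participants Validated participant tibble (or any data frame with
#'   the two date columns).
#' @return Integer vector, one element per row.
#' @export
followup_days <- function(participants) {
  as.integer(participants$end_of_followup - participants$enrollment_date)
}

#' Read a claims dataset from delimited text
#'
#' Reads `participants.csv`, `cases.csv`, `episodes.csv`, and
#' `line_items.csv` (UTF-8, header row, ISO-8601 dates) from a directory and
#' validates every invariant. Errors name the offending table, row, and
#' column.
#'
#' @param dir Directory containing the four CSV files.
#' @return A validated `claims_data` list.
#' @export
read_claims_tables <- function(dir) {
  read1 <- function(name) {
    path <- file.path(dir, paste0(name, ".csv"))
    chk(file.exists(path), "read_tables: missing input file '%s'", path)
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
  validate_claims_data(list(
    participants = read1("participants"),
    cases = read1("cases"),
    episodes = read1("episodes"),
    line_items = read1("line_items")
  ))
}

#' Write a claims dataset as delimited text
#'
#' Inverse of [read_claims_tables()]: writes the four tables as CSV so that a
#' write-then-read round trip reproduces the dataset exactly.
#'
#' @param data A `claims_data` list.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_claims_tables <- function(data, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (name in c("participants", "cases", "episodes", "line_items")) {
    readr::write_csv(data[[name]], file.path(dir, paste0(name, ".csv")),
                     progress = FALSE)
  }
  invisible(dir)
}
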