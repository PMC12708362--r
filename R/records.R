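#' Expected participant-record column names for a codebook
#'
#' One row per participant per wave. Likert responses are stored as the
#' tokens "1".."5" plus "no_opinion"; missing values use the literal "NA"
#' token in CSV files.
#'
#' @param codebook a `kap_codebook`.
#' @return Character vector of column names in canonical order.
#' @export
record_columns <- function(codebook = default_codebook()) {
  ppe_cols <- as.vector(t(outer(codebook$ppe$part,
                                c("access", "freq"),
                                function(p, s) sprintf("ppe_%s_%s", p, s))))
  c("participant_id", "cluster_id", "arm", "wave",
    codebook$knowledge$id, codebook$attitude$id, codebook$practice$id,
    "mixes_pesticides", "applies_knapsack",
    ppe_cols, "change_time", "shower_time",
    codebook$symptoms,
    "age", "sex", "education", "income", "prior_training")
}

likert_tokens <- function() c("1", "2", "3", "4", "5", "no_opinion")

arm_levels <- function() c("control", "education", "education_sms")

#' Validate a participant-record table
#'
#' Checks the schema and the trial-structure invariants: required columns,
#' value domains per field, uniqueness of (participant_id, wave), and
#' constant arm within cluster (cluster randomization). Violations are
#' reported with the offending row number and field; nothing is silently
#' coerced.
#'
#' @param records a data.frame of participant-wave rows.
#' @param codebook a `kap_codebook`.
#' @return `records`, invisibly, if valid; otherwise an error.
#' @export
validate_records <- function(records, codebook = default_codebook()) {
  stopifnot(is.data.frame(records))
  needed <- record_columns(codebook)
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols))
    stop("schema error: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (nrow(records) == 0L) return(invisible(records))

  problems <- character(0)
  bad <- function(col, ok) {
    rows <- which(!ok)
    if (length(rows))
      problems <<- c(problems, sprintf("row %d, field %s: invalid value '%s'",
                                       rows, col,
                                       as.character(records[[col]][rows])))
  }

  in_set <- function(x, set) !is.na(x) & as.character(x) %in% set
  for (k in codebook$knowledge$id)
    bad(k, is.na(records[[k]]) | records[[k]] %in% c(1L, 2L, 3L))
  for (a in c(codebook$attitude$id, codebook$practice$id))
    bad(a, is.na(records[[a]]) | in_set(records[[a]], likert_tokens()))
  for (s in codebook$symptoms)
    bad(s, is.na(records[[s]]) | records[[s]] %in% c(0L, 1L))
  for (b in c("mixes_pesticides", "applies_knapsack", "prior_training"))
    bad(b, is.na(records[[b]]) | is.logical(records[[b]]))
  for (p in codebook$ppe$part) {
    bad(sprintf("ppe_%s_access", p),
        is.na(records[[sprintf("ppe_%s_access", p)]]) |
          is.logical(records[[sprintf("ppe_%s_access", p)]]))
    bad(sprintf("ppe_%s_freq", p),
        is.na(records[[sprintf("ppe_%s_freq", p)]]) |
          in_set(records[[sprintf("ppe_%s_freq", p)]],
                 names(codebook$freq_map)))
  }
  bad("change_time", is.na(records$change_time) |
        in_set(records$change_time, names(codebook$hygiene$change_time)))
  bad("shower_time", is.na(records$shower_time) |
        in_set(records$shower_time, names(codebook$hygiene$shower_time)))
  bad("wave", in_set(records$wave, c("baseline", "followup")))
  bad("arm", !is.na(records$arm) & nzchar(as.character(records$arm)))
  bad("sex", is.na(records$sex) | in_set(records$sex, c("male", "female")))
  bad("education", is.na(records$education) |
        in_set(records$education, c("primary_or_below", "above_primary")))
  bad("income", is.na(records$income) |
        in_set(records$income, c("below_poverty", "above_poverty")))
  bad("age", is.na(records$age) | (is.numeric(records$age) & records$age >= 0))

  if (length(problems))
    stop("schema error:\n", paste(problems, collapse = "\n"), call. = FALSE)

  dup <- duplicated(records[, c("participant_id", "wave")])
  if (any(dup))
    stop("integrity error: duplicate (participant_id, wave) at row(s) ",
         paste(which(dup), collapse = ", "), call. = FALSE)

  arms_per_cluster <- tapply(as.character(records$arm),
                             as.character(records$cluster_id),
                             function(x) length(unique(x)))
  if (any(arms_per_cluster > 1L))
    stop("integrity error: cluster(s) with more than one arm: ",
         paste(names(arms_per_cluster)[arms_per_cluster > 1L],
               collapse = ", "), call. = FALSE)
  if (length(unique(records$arm)) < 2L && nrow(records) > 0L)
    warning("records contain a single arm; effect estimation needs >= 2",
            call. = FALSE)
  invisible(records)
}

#' Read participant records from CSV
#'
#' CSV dialect: UTF-8, comma-separated, literal token "NA" for missing,
#' header row matching [record_columns()].
#'
#' @param path CSV file path.
#' @param codebook a `kap_codebook`.
#' @return A validated data.frame of participant-wave records.
#' @export
read_records <- function(path, codebook = default_codebook()) {
  records <- utils::read.csv(path, stringsAsFactors = FALSE,
                             na.strings = "NA", colClasses = NA,
                             encoding = "UTF-8")
  # Likert and categorical token columns must stay character even when a
  # file happens to contain only numeric tokens.
  tok_cols <- c(codebook$attitude$id, codebook$practice$id,
                "change_time", "shower_time", "wave", "arm", "sex",
                "education", "income", "participant_id", "cluster_id",
                sprintf("ppe_%s_freq", codebook$ppe$part))
  for (cc in intersect(tok_cols, names(records)))
    records[[cc]] <- as.character(records[[cc]])
  int_cols <- c(codebook$knowledge$id, codebook$symptoms)
  for (cc in intersect(int_cols, names(records)))
    records[[cc]] <- as.integer(records[[cc]])
  validate_records(records, codebook)
  records
}

#' Write participant records (or any scores table) to CSV
#'
#' Round-trips losslessly with [read_records()]: UTF-8, comma separator,
#' missing written as the literal "NA".
#'
#' @param records data.frame to write.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, na = "NA",
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_records
#' @export
write_scores <- function(records, path) write_records(records, path)

#' Read a scores table written by [write_scores()]
#' @param path CSV path.
#' @return data.frame.
#' @export
read_scores <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "NA",
                  encoding = "UTF-8")
}
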