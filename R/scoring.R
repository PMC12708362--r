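#' Code a knowledge item response against its answer key
#'
#' Knowledge items use a categorical scale: 1 = yes, 2 = no,
#' 3 = do not know. One point is awarded iff the response matches the
#' keyed correct answer; "do not know" is always incorrect. The instrument
#' keys every item to "yes", but negatively-keyed items are representable.
#'
#' @param response integer vector with values in \{1, 2, 3\}; NA allowed
#'   (propagates).
#' @param key "yes" or "no", recycled across responses.
#' @return Integer vector of 0/1 (NA where response was NA).
#' @export
code_knowledge_item <- function(response, key = "yes") {
  response <- as.integer(as.character(response))
  if (any(!is.na(response) & !response %in% 1:3))
    stop("coding error: knowledge response outside {1, 2, 3}", call. = FALSE)
  if (any(!key %in% c("yes", "no")))
    stop("coding error: knowledge key must be 'yes' or 'no'", call. = FALSE)
  correct <- ifelse(key == "yes", 1L, 2L)
  out <- as.integer(response == correct)
  out[is.na(response)] <- NA_integer_
  out
}

#' Code a Likert item response, with optional reverse scoring
#'
#' Responses 1-5 are dichotomized: 1-3 -> 0 (incorrect/unsafe),
#' 4-5 -> 1 (correct/safe). Negatively worded items are reverse-scored
#' (r -> 6 - r) before dichotomization. "no_opinion" codes to missing.
#'
#' @param response vector of tokens "1".."5" (or integers 1-5) and
#'   "no_opinion"; NA allowed (propagates).
#' @param reverse logical; reverse-score before dichotomizing.
#' @return Integer vector of 0/1 with NA for no-opinion/missing.
#' @export
code_likert_item <- function(response, reverse = FALSE) {
  response <- as.character(response)
  ok <- is.na(response) | response %in% likert_tokens()
  if (any(!ok))
    stop("coding error: invalid Likert token '",
         paste(unique(response[!ok]), collapse = "', '"), "'", call. = FALSE)
  r <- suppressWarnings(as.integer(response))  # no_opinion -> NA
  if (isTRUE(reverse)) r <- 6L - r
  as.integer(r >= 4L)
}

#' Sum 15 coded items into a domain score
#'
#' Under the default "complete" policy the domain score is missing if any
#' item is missing (matching a complete-case analysis); the "prorate"
#' policy rescales the available-item mean to the 0-15 range.
#'
#' @param coded numeric vector of exactly 15 values in \{0, 1, NA\}.
#' @param missing_policy "complete" (default) or "prorate".
#' @return list with `score` (0-15 or NA) and `percent` (100 * score/15).
#' @export
domain_score <- function(coded, missing_policy = c("complete", "prorate")) {
  missing_policy <- match.arg(missing_policy)
  if (length(coded) != 15L)
    stop("contract error: domain_score needs exactly 15 coded items, got ",
         length(coded), call. = FALSE)
  if (any(!is.na(coded) & !coded %in% c(0, 1)))
    stop("contract error: coded items must be 0/1/missing", call. = FALSE)
  score <- if (missing_policy == "complete") {
    if (anyNA(coded)) NA_real_ else sum(coded)
  } else {
    if (all(is.na(coded))) NA_real_ else 15 * mean(coded, na.rm = TRUE)
  }
  list(score = score, percent = 100 * score / 15)
}

#' Count poisoning signs and symptoms
#'
#' @param symptoms logical or 0/1 vector of exactly 31 indicators; must be
#'   complete under the default policy.
#' @return list with `count` (0-31) and `percent` (100 * count/31).
#' @export
symptom_count <- function(symptoms) {
  if (length(symptoms) != 31L)
    stop("contract error: symptom_count needs exactly 31 indicators, got ",
         length(symptoms), call. = FALSE)
  s <- as.integer(symptoms)
  if (any(!is.na(s) & !s %in% c(0L, 1L)))
    stop("contract error: symptoms must be binary", call. = FALSE)
  count <- if (anyNA(s)) NA_integer_ else sum(s)
  list(count = count, percent = 100 * count / 31)
}

#' Round a percentage for reporting (1 decimal)
#'
#' Scores are kept exact internally; percents are rounded only at the
#' reporting layer.
#' @param x numeric.
#' @return numeric rounded to 1 decimal.
#' @export
report_percent <- function(x) round(x, 1)

# Vectorized domain scoring over a record table: returns numeric vector of
# per-row sums under the complete-domain policy (NA if any item NA), or
# prorated sums otherwise.
sum_coded_matrix <- function(mat, missing_policy) {
  if (missing_policy == "complete") {
    out <- rowSums(mat)              # NA propagates
  } else {
    avail <- rowSums(!is.na(mat))
    out <- 15 * rowSums(mat, na.rm = TRUE) / avail
    out[avail == 0L] <- NA_real_
  }
  out
}

#' Score a participant-record table into per-row outcomes
#'
#' Applies knowledge/Likert coding, domain summation, the Exposure
#' Intensity Score with its sub-components, and the symptom count to every
#' participant-wave row, carrying identifiers and demographics through.
#' Every outcome is emitted both raw and as percent of its maximum
#' (15 for KAP domains, 13 for EIS, 31 for symptoms, 1 for EIS
#' sub-scores).
#'
#' @param records validated participant records (see [validate_records()]).
#' @param codebook a `kap_codebook`.
#' @param missing_policy domain-score missing policy, see [domain_score()].
#' @return data.frame with one row per input row: ids, arm, wave,
#'   demographics, and `<outcome>` / `<outcome>_pct` columns.
#' @export
score_records <- function(records, codebook = default_codebook(),
                          missing_policy = c("complete", "prorate")) {
  missing_policy <- match.arg(missing_policy)
  n <- nrow(records)

  kmat <- vapply(seq_len(15), function(i)
    code_knowledge_item(records[[codebook$knowledge$id[i]]],
                        codebook$knowledge$key[i]),
    integer(n))
  amat <- vapply(seq_len(15), function(i)
    code_likert_item(records[[codebook$attitude$id[i]]],
                     codebook$attitude$reverse[i]),
    integer(n))
  pmat <- vapply(seq_len(15), function(i)
    code_likert_item(records[[codebook$practice$id[i]]],
                     codebook$practice$reverse[i]),
    integer(n))
  if (n == 1L) {   # vapply returns a vector for single-row input
    kmat <- matrix(kmat, nrow = 1L)
    amat <- matrix(amat, nrow = 1L)
    pmat <- matrix(pmat, nrow = 1L)
  }

  knowledge <- sum_coded_matrix(kmat, missing_policy)
  attitude <- sum_coded_matrix(amat, missing_policy)
  practice <- sum_coded_matrix(pmat, missing_policy)

  smat <- as.matrix(records[, codebook$symptoms, drop = FALSE])
  storage.mode(smat) <- "integer"
  symptoms <- rowSums(smat)

  ex <- eis_table(records, codebook)

  out <- data.frame(
    participant_id = records$participant_id,
    cluster_id = records$cluster_id,
    arm = records$arm,
    wave = records$wave,
    age = records$age,
    sex = records$sex,
    education = records$education,
    income = records$income,
    prior_training = records$prior_training,
    knowledge = knowledge, knowledge_pct = 100 * knowledge / 15,
    attitude = attitude, attitude_pct = 100 * attitude / 15,
    practice = practice, practice_pct = 100 * practice / 15,
    eis = ex$eis, eis_pct = 100 * ex$eis / 13,
    ppe_score = ex$ppe_score, ppe_pct = 100 * ex$ppe_score,
    change_factor = ex$change_factor, change_pct = 100 * ex$change_factor,
    shower_factor = ex$shower_factor, shower_pct = 100 * ex$shower_factor,
    symptom_count = symptoms, symptom_pct = 100 * symptoms / 31,
    stringsAsFactors = FALSE
  )
  out
}
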