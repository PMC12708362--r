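#' Codebook: declarative item metadata for scoring
#'
#' A codebook bundles everything the scoring layer needs to know about the
#' questionnaire instrument: the item identifiers per KAP domain, the
#' knowledge answer key, reverse-scoring flags for Likert items, the PPE
#' weight table for the six body parts, the frequency-to-protection map,
#' and the hygiene (time-to-change / time-to-shower) factor maps used by
#' the Exposure Intensity Score.
#'
#' The instrument itself publishes item counts (15 per KAP domain, 31
#' symptoms, 6 PPE body parts) but not item texts, so the default codebook
#' ships with placeholder labels; all of it is a human-editable YAML file
#' in deployed use.
#'
#' @section Invariants:
#' * PPE maximum weights sum to 1 and minimum contributions sum to 0.1,
#'   so the PPE exposure sub-score spans exactly \[0.1, 1\].
#' * Hygiene factors lie in \[0.7, 1\] and are monotone non-decreasing in
#'   delay.
#'
#' @param eis_variant `"literal"` (protective factors multiply the
#'   application weight only, the printed operator precedence) or
#'   `"modified_sum"` (they multiply the mixing weight too).
#' @return An object of class `kap_codebook`.
#' @examples
#' cb <- default_codebook()
#' sum(cb$ppe$w)  # 1
#' @export
default_codebook <- function(eis_variant = c("literal", "modified_sum")) {
  eis_variant <- match.arg(eis_variant)
  parts <- c("upper_body", "mouth", "eye", "hand", "leg", "feet")
  cb <- structure(list(
    knowledge = data.frame(
      id = sprintf("k%02d", 1:15),
      label = sprintf("knowledge item %d (placeholder)", 1:15),
      key = rep("yes", 15),
      stringsAsFactors = FALSE
    ),
    attitude = data.frame(
      id = sprintf("a%02d", 1:15),
      label = sprintf("attitude item %d (placeholder)", 1:15),
      reverse = rep(FALSE, 15),
      stringsAsFactors = FALSE
    ),
    practice = data.frame(
      id = sprintf("p%02d", 1:15),
      label = sprintf("practice item %d (placeholder)", 1:15),
      reverse = rep(FALSE, 15),
      stringsAsFactors = FALSE
    ),
    symptoms = sprintf("sym%02d", 1:31),
    ppe = data.frame(
      part = parts,
      w = rep(1 / 6, 6),      # maximum (unprotected) contribution
      m = rep(0.1 / 6, 6),    # minimum (fully protected) contribution
      stringsAsFactors = FALSE
    ),
    freq_map = c(never = 0, rarely = 0.25, sometimes = 0.5,
                 often = 0.75, always = 1),
    hygiene = list(
      change_time = c(immediate = 0.7, same_day = 0.85, later = 1.0),
      shower_time = c(immediate = 0.7, same_day = 0.85, later = 1.0)
    ),
    eis_variant = eis_variant
  ), class = "kap_codebook")
  validate_codebook(cb)
}

#' Validate a codebook against its structural invariants
#'
#' @param cb a `kap_codebook` (or a plain list with the same fields).
#' @return `cb`, invisibly classed as `kap_codebook`, or an error naming
#'   the violated invariant.
#' @export
validate_codebook <- function(cb) {
  stopifnot(is.list(cb))
  for (dom in c("knowledge", "attitude", "practice")) {
    if (nrow(cb[[dom]]) != 15L)
      stop(sprintf("codebook: domain '%s' must have exactly 15 items, has %d",
                   dom, nrow(cb[[dom]])), call. = FALSE)
  }
  if (!all(cb$knowledge$key %in% c("yes", "no")))
    stop("codebook: knowledge keys must be 'yes' or 'no'", call. = FALSE)
  if (length(cb$symptoms) != 31L)
    stop("codebook: exactly 31 symptom items required", call. = FALSE)
  if (nrow(cb$ppe) != 6L)
    stop("codebook: exactly 6 PPE body parts required", call. = FALSE)
  if (abs(sum(cb$ppe$w) - 1) > 1e-8)
    stop("codebook: PPE maximum weights must sum to 1", call. = FALSE)
  if (abs(sum(cb$ppe$m) - 0.1) > 1e-8)
    stop("codebook: PPE minimum contributions must sum to 0.1", call. = FALSE)
  if (any(cb$ppe$m > cb$ppe$w))
    stop("codebook: PPE minimum contribution exceeds maximum for some part",
         call. = FALSE)
  fm <- cb$freq_map
  if (!all(c("never", "always") %in% names(fm)) || any(fm < 0 | fm > 1))
    stop("codebook: frequency map must cover never..always within [0,1]",
         call. = FALSE)
  for (h in names(cb$hygiene)) {
    hv <- cb$hygiene[[h]]
    if (any(hv < 0.7 - 1e-8 | hv > 1 + 1e-8))
      stop(sprintf("codebook: hygiene factors for %s outside [0.7, 1]", h),
           call. = FALSE)
    if (is.unsorted(hv))
      stop(sprintf("codebook: hygiene factors for %s must be monotone
non-decreasing in delay", h), call. = FALSE)
  }
  if (!cb$eis_variant %in% c("literal", "modified_sum"))
    stop("codebook: eis_variant must be 'literal' or 'modified_sum'",
         call. = FALSE)
  class(cb) <- "kap_codebook"
  invisible(cb)
}

#' Write a codebook to a YAML file
#'
#' @param cb a `kap_codebook`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_codebook <- function(cb, path) {
  validate_codebook(cb)
  x <- list(
    knowledge = cb$knowledge, attitude = cb$attitude, practice = cb$practice,
    symptoms = cb$symptoms,
    ppe = cb$ppe,
    freq_map = as.list(cb$freq_map),
    hygiene = lapply(cb$hygiene, as.list),
    eis_variant = cb$eis_variant
  )
  x$knowledge <- lapply(seq_len(15), function(i) as.list(cb$knowledge[i, ]))
  x$attitude <- lapply(seq_len(15), function(i) as.list(cb$attitude[i, ]))
  x$practice <- lapply(seq_len(15), function(i) as.list(cb$practice[i, ]))
  x$ppe <- lapply(seq_len(6), function(i) as.list(cb$ppe[i, ]))
  yaml::write_yaml(x, path, precision = 12)
  invisible(path)
}

#' Read a codebook from a YAML file
#'
#' @param path YAML file written by [write_codebook()] (or hand-edited).
#' @return A validated `kap_codebook`.
#' @export
read_codebook <- function(path) {
  x <- yaml::read_yaml(path)
  bind_items <- function(lst) do.call(rbind, lapply(lst, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  cb <- list(
    knowledge = bind_items(x$knowledge),
    attitude = bind_items(x$attitude),
    practice = bind_items(x$practice),
    symptoms = unlist(x$symptoms),
    ppe = bind_items(x$ppe),
    freq_map = unlist(x$freq_map),
    hygiene = lapply(x$hygiene, unlist),
    eis_variant = x$eis_variant
  )
  validate_codebook(cb)
  cb <- structure(cb, class = "kap_codebook")
  cb
}
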