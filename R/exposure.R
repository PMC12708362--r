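#' Per-part protection fraction from PPE access and use frequency
#'
#' No access, or a use frequency of "never", gives no protection (0);
#' "always" gives full protection (1); intermediate frequencies map
#' through the codebook's frequency table (default rarely 0.25,
#' sometimes 0.5, often 0.75).
#'
#' @param access logical vector.
#' @param freq character vector of frequency tokens.
#' @param freq_map named numeric map, e.g. `default_codebook()$freq_map`.
#' @return numeric protection fractions in \[0, 1\].
#' @export
ppe_fraction <- function(access, freq, freq_map = default_codebook()$freq_map) {
  freq <- as.character(freq)
  unknown <- !is.na(freq) & !freq %in% names(freq_map)
  if (any(unknown))
    stop("coding error: unknown PPE frequency token '",
         paste(unique(freq[unknown]), collapse = "', '"), "'", call. = FALSE)
  f <- unname(freq_map[freq])
  f[!is.na(access) & !access] <- 0
  f
}

#' PPE exposure sub-score over six body parts
#'
#' Each body part contributes `w_p - f_p * (w_p - m_p)` where `f_p` is its
#' protection fraction, `w_p` its maximum (unprotected) weight and `m_p`
#' its minimum (fully protected) contribution. With the default equal
#' weights the score spans exactly \[0.1, 1\]; higher means more exposed.
#'
#' @param fractions numeric vector (or n x 6 matrix) of per-part
#'   protection fractions in part order `codebook$ppe$part`.
#' @param ppe_weights data.frame with columns `part`, `w`, `m`.
#' @return numeric PPE exposure score(s) in \[0.1, 1\].
#' @export
ppe_score <- function(fractions, ppe_weights = default_codebook()$ppe) {
  if (is.matrix(fractions)) {
    stopifnot(ncol(fractions) == nrow(ppe_weights))
    return(as.numeric(sum(ppe_weights$w) -
                        fractions %*% (ppe_weights$w - ppe_weights$m)))
  }
  if (length(fractions) != nrow(ppe_weights))
    stop("contract error: one protection fraction per body part required",
         call. = FALSE)
  if (any(!is.na(fractions) & (fractions < 0 | fractions > 1)))
    stop("contract error: protection fractions must lie in [0, 1]",
         call. = FALSE)
  sum(ppe_weights$w) - sum(fractions * (ppe_weights$w - ppe_weights$m))
}

#' Hygiene factor from a time-to-change / time-to-shower category
#'
#' @param category character vector of ordinal categories.
#' @param map named numeric map from the codebook (values in \[0.7, 1\],
#'   monotone non-decreasing with delay).
#' @return numeric factor(s) in \[0.7, 1\].
#' @export
hygiene_factor <- function(category,
                           map = default_codebook()$hygiene$change_time) {
  category <- as.character(category)
  unknown <- !is.na(category) & !category %in% names(map)
  if (any(unknown))
    stop("coding error: unmapped hygiene category '",
         paste(unique(category[unknown]), collapse = "', '"), "'",
         call. = FALSE)
  unname(map[category])
}

#' Exposure Intensity Score from task weights and protective factors
#'
#' The semi-quantitative algorithm combines two exposure-increasing tasks
#' (mixing, weight 5; knapsack application, weight 8) with three
#' multiplicative protective factors: the PPE sub-score (0.1-1), and the
#' time-to-change and time-to-shower hygiene factors (0.7-1 each). The
#' published formula is written without parentheses; under standard
#' operator precedence the protective factors multiply the application
#' weight only (`variant = "literal"`):
#' \deqn{EIS = MIX + APPLICATION \times PPE \times CHANGE \times SHOWER}
#' The `"modified_sum"` variant applies them to both task weights,
#' \eqn{(MIX + APPLICATION) \times PPE \times CHANGE \times SHOWER}, as in
#' the predecessor exposure algorithms. Both variants span \[0, 13\].
#'
#' @param mix logical (mixes pesticides) or numeric weight contribution.
#' @param application logical (applies with knapsack sprayer) or numeric.
#' @param ppe PPE exposure sub-score in \[0.1, 1\].
#' @param change,shower hygiene factors in \[0.7, 1\].
#' @param variant "literal" or "modified_sum".
#' @return numeric EIS in \[0, 13\].
#' @export
eis <- function(mix, application, ppe, change, shower,
                variant = c("literal", "modified_sum")) {
  variant <- match.arg(variant)
  mix_w <- if (is.logical(mix)) 5 * mix else mix
  app_w <- if (is.logical(application)) 8 * application else application
  if (any(!is.na(mix_w) & !mix_w %in% c(0, 5)) ||
      any(!is.na(app_w) & !app_w %in% c(0, 8)))
    stop("contract error: task weights are fixed at MIX = 5, APPLICATION = 8",
         call. = FALSE)
  if (variant == "literal")
    mix_w + app_w * ppe * change * shower
  else
    (mix_w + app_w) * ppe * change * shower
}

#' Compute EIS and sub-components for a full record
#'
#' @param record a single-row participant record (or list) with the
#'   exposure fields of the record schema.
#' @param codebook a `kap_codebook`.
#' @return list of class `kap_exposure`: `eis`, `ppe_score`,
#'   `change_factor`, `shower_factor`, `variant`.
#' @export
exposure_result <- function(record, codebook = default_codebook()) {
  ex <- eis_table(as.data.frame(record, stringsAsFactors = FALSE), codebook)
  structure(c(as.list(ex[1, ]), variant = codebook$eis_variant),
            class = "kap_exposure")
}

# Vectorized exposure computation over a record table.
eis_table <- function(records, codebook) {
  parts <- codebook$ppe$part
  fr <- vapply(parts, function(p)
    ppe_fraction(records[[sprintf("ppe_%s_access", p)]],
                 records[[sprintf("ppe_%s_freq", p)]],
                 codebook$freq_map),
    numeric(nrow(records)))
  if (nrow(records) == 1L) fr <- matrix(fr, nrow = 1L)
  ppe <- ppe_score(fr, codebook$ppe)
  change <- hygiene_factor(records$change_time, codebook$hygiene$change_time)
  shower <- hygiene_factor(records$shower_time, codebook$hygiene$shower_time)
  data.frame(
    eis = eis(as.logical(records$mixes_pesticides),
              as.logical(records$applies_knapsack),
              ppe, change, shower, codebook$eis_variant),
    ppe_score = ppe, change_factor = change, shower_factor = shower
  )
}
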