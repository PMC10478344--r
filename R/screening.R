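#' Protocol screening rules
#'
#' Protocols are excluded when (in this order of attribution): the fraction
#' of blank items strictly exceeds `max_missing_fraction`; the infrequency
#' validity score exceeds the normative mean by more than
#' `infrequency_sd_cutoff` normative SDs; or the participant is manually
#' flagged. The normative mean/SD are properties of the validity instrument's
#' reference sample and must be supplied by the analyst.
#'
#' @param max_missing_fraction Maximum tolerated blank-item fraction
#'   (default 0.02; exclusion requires strictly more).
#' @param infrequency_norm_mean,infrequency_norm_sd Normative mean and SD of
#'   the infrequency validity scale.
#' @param infrequency_sd_cutoff SD multiplier above the normative mean
#'   (default 2.5).
#' @param manual_exclusions Character vector of participant ids flagged by
#'   inspection.
#' @return A `screening_rules` list.
#' @export
screening_rules <- function(max_missing_fraction = 0.02,
                            infrequency_norm_mean, infrequency_norm_sd,
                            infrequency_sd_cutoff = 2.5,
                            manual_exclusions = character()) {
  if (max_missing_fraction < 0 || max_missing_fraction >= 1) {
    stop("max_missing_fraction must be in [0, 1)", call. = FALSE)
  }
  if (infrequency_sd_cutoff <= 0) stop("infrequency_sd_cutoff must be > 0", call. = FALSE)
  structure(list(max_missing_fraction = max_missing_fraction,
                 infrequency_norm_mean = infrequency_norm_mean,
                 infrequency_norm_sd = infrequency_norm_sd,
                 infrequency_sd_cutoff = infrequency_sd_cutoff,
                 manual_exclusions = as.character(manual_exclusions)),
            class = "screening_rules")
}

#' Screen protocols for missingness, infrequent responding, and manual flags
#'
#' Applies [screening_rules()] to an item response table spanning all
#' instruments. A participant is excluded iff their blank-item fraction is
#' strictly greater than the missingness limit, their infrequency score lies
#' above `mean + cutoff * SD` of the normative sample, or they are manually
#' flagged; each excluded participant is attributed to the first rule that
#' catches them (missingness, then infrequency, then manual), so ledger
#' counts are disjoint. Screening is idempotent: re-screening the retained
#' set excludes no one.
#'
#' @param responses Item response table over all instruments (data frame with
#'   id column, or matrix with id rownames).
#' @param validity_scores Named numeric vector of per-participant infrequency
#'   totals (prorated sums), covering every participant.
#' @param rules A [screening_rules()].
#' @return A list with `retained` (the surviving rows of `responses`),
#'   `ledger` (tibble: participant_id, rule, missing_fraction, infrequency),
#'   and `counts` (named vector: missingness, infrequency, manual, retained).
#' @export
screen_protocols <- function(responses, validity_scores, rules) {
  m <- as_response_matrix(responses)
  ids <- rownames(m)
  if (nrow(m) == 0L) stop("empty response matrix", call. = FALSE)
  if (is.null(names(validity_scores)) || !all(ids %in% names(validity_scores))) {
    stop("validity_scores must be named and cover all participants", call. = FALSE)
  }
  unknown <- setdiff(rules$manual_exclusions, ids)
  if (length(unknown)) {
    stop(sprintf("manual_exclusions reference unknown participants: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  miss_frac <- rowMeans(is.na(m))
  inf <- validity_scores[ids]
  threshold <- rules$infrequency_norm_mean +
    rules$infrequency_sd_cutoff * rules$infrequency_norm_sd

  rule <- rep(NA_character_, length(ids))
  rule[ids %in% rules$manual_exclusions] <- "manual"
  rule[!is.na(inf) & inf > threshold] <- "infrequency"
  rule[miss_frac > rules$max_missing_fraction] <- "missingness"

  excluded <- !is.na(rule)
  ledger <- tibble::tibble(participant_id = ids[excluded],
                           rule = rule[excluded],
                           missing_fraction = unname(miss_frac[excluded]),
                           infrequency = unname(inf[excluded]))
  counts <- c(missingness = sum(rule == "missingness", na.rm = TRUE),
              infrequency = sum(rule == "infrequency", na.rm = TRUE),
              manual = sum(rule == "manual", na.rm = TRUE),
              retained = sum(!excluded))

  retained <- if (is.matrix(responses)) {
    responses[!excluded, , drop = FALSE]
  } else {
    responses[!excluded, , drop = FALSE]
  }
  list(retained = retained, ledger = ledger, counts = counts)
}
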