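## Prorated aggregate of one participant's item responses.
## Sum scales return mean(answered) * n_items (the prorated sum); mean scales
## return mean(answered). Participants answering less than `min_answered` of
## the items get NA.
prorate_score <- function(values, aggregation, min_answered = 0.8) {
  n <- length(values)
  answered <- sum(!is.na(values))
  if (answered == 0L || answered / n < min_answered) return(NA_real_)
  m <- mean(values, na.rm = TRUE)
  if (aggregation == "sum") m * n else m
}

#' Score one scale of an instrument
#'
#' Aggregates a participant's responses on the scale's items, prorating over
#' residual item missingness: a score is computed when at least
#' `min_answered` (default 80%) of the scale's items are answered, otherwise
#' the participant's score is missing. Sum-aggregated scales return the
#' prorated sum (mean of answered items times the item count); mean-scored
#' scales return the mean of answered items.
#'
#' @param responses Item response table: data frame whose first column is the
#'   participant id, or a numeric matrix with ids as rownames. Values outside
#'   the key's response bounds are an error.
#' @param key A [scoring_key()].
#' @param scale Scale label present in the key.
#' @param min_answered Minimum answered fraction for proration.
#' @return Named numeric vector of scores (names are participant ids).
#' @export
score_scale <- function(responses, key, scale, min_answered = 0.8) {
  if (!scale %in% names(key$scale_map)) {
    stop(sprintf("unknown scale '%s' for instrument %s", scale, key$instrument),
         call. = FALSE)
  }
  m <- as_response_matrix(responses)
  items <- key$scale_map[[scale]]
  missing_items <- setdiff(items, colnames(m))
  if (length(missing_items)) {
    stop(sprintf("response table lacks items: %s",
                 paste(utils::head(missing_items, 5L), collapse = ", ")), call. = FALSE)
  }
  m <- m[, items, drop = FALSE]
  if (all(is.na(m))) stop("all items missing", call. = FALSE)
  rng <- range(m, na.rm = TRUE)
  if (rng[1] < key$response_min || rng[2] > key$response_max) {
    stop("responses outside the key's response bounds", call. = FALSE)
  }
  out <- apply(m, 1L, prorate_score, aggregation = key$aggregation,
               min_answered = min_answered)
  stats::setNames(as.numeric(out), rownames(m))
}

#' Score the eight octants of a circumplex instrument
#'
#' Applies the [score_scale()] aggregation and proration contract octant by
#' octant. Columns are ordered per the geometry.
#'
#' @inheritParams score_scale
#' @param geometry An [octant_geometry()].
#' @return Numeric matrix, participants x 8 octants, rownames = participant
#'   ids, colnames = octant codes in geometry order.
#' @export
score_octants <- function(responses, key, geometry = octant_geometry(),
                          min_answered = 0.8) {
  if (is.null(key$octant_map)) {
    stop(sprintf("instrument %s has no octant map", key$instrument), call. = FALSE)
  }
  m <- as_response_matrix(responses)
  out <- sapply(geometry$codes, function(code) {
    items <- key$octant_map[[code]]
    missing_items <- setdiff(items, colnames(m))
    if (length(missing_items)) {
      stop(sprintf("octant %s lacks items: %s", code,
                   paste(missing_items, collapse = ", ")), call. = FALSE)
    }
    apply(m[, items, drop = FALSE], 1L, prorate_score,
          aggregation = key$aggregation, min_answered = min_answered)
  })
  out <- matrix(as.numeric(out), nrow = nrow(m),
                dimnames = list(rownames(m), geometry$codes))
  out
}
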