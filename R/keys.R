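#' Scoring key for an instrument
#'
#' A scoring key maps item ids to scales (and, for circumplex instruments,
#' to octants), records the response bounds, and says how items aggregate
#' into a score (`sum` or `mean`).
#'
#' @param instrument Instrument name.
#' @param item_ids Ordered character vector of item labels.
#' @param scale_map Named list: scale label -> character vector of item ids.
#' @param response_min,response_max Integer response bounds.
#' @param aggregation `"sum"` or `"mean"`.
#' @param octant_map Optional named list covering all 8 octant codes with
#'   equal item counts (circumplex instruments only).
#' @param geometry An [octant_geometry()] used to validate `octant_map`.
#' @return A `scoring_key` list.
#' @export
scoring_key <- function(instrument, item_ids, scale_map,
                        response_min, response_max,
                        aggregation = c("sum", "mean"),
                        octant_map = NULL, geometry = octant_geometry()) {
  aggregation <- match.arg(aggregation)
  item_ids <- as.character(item_ids)
  if (anyDuplicated(item_ids)) stop("item ids must be unique", call. = FALSE)
  if (response_min >= response_max) stop("response_min must be < response_max", call. = FALSE)
  all_keyed <- unique(unlist(scale_map, use.names = FALSE))
  if (!all(all_keyed %in% item_ids)) stop("scale_map references unknown items", call. = FALSE)
  if (!all(item_ids %in% all_keyed)) stop("every item must belong to at least one scale", call. = FALSE)
  if (!is.null(octant_map)) {
    if (!setequal(names(octant_map), geometry$codes)) {
      stop("octant_map must cover all 8 octants", call. = FALSE)
    }
    counts <- lengths(octant_map)
    if (length(unique(counts)) != 1L) {
      stop("octant_map must assign equal item counts per octant", call. = FALSE)
    }
    if (!all(unlist(octant_map) %in% item_ids)) {
      stop("octant_map references unknown items", call. = FALSE)
    }
    octant_map <- octant_map[geometry$codes]
  }
  structure(list(instrument = instrument, item_ids = item_ids,
                 scale_map = scale_map, response_min = response_min,
                 response_max = response_max, aggregation = aggregation,
                 octant_map = octant_map),
            class = "scoring_key")
}

#' @export
print.scoring_key <- function(x, ...) {
  cat("<scoring_key> ", x$instrument, ": ", length(x$item_ids), " items, ",
      length(x$scale_map), " scale(s), responses ", x$response_min, "-",
      x$response_max, ", ", x$aggregation,
      if (!is.null(x$octant_map)) ", octant-keyed" else "", "\n", sep = "")
  invisible(x)
}

## Block-assign items to groups in order; used by the bundled synthetic keys.
block_map <- function(prefix, counts) {
  ids <- sprintf("%s_%02d", prefix, seq_len(sum(counts)))
  split(ids, rep(names(counts), counts))[names(counts)]
}

#' Bundled synthetic scoring keys
#'
#' Schematic keys for the instruments the package models. Item counts,
#' response formats and aggregation match the published instruments, but the
#' item-to-scale allocations are synthetic block assignments (items numbered
#' consecutively within scale/octant): the copyrighted item keys are not
#' reproduced. They pair with data from [simulate_sample()] /
#' [make_study_fixture()], which generate items under the same allocation.
#'
#' * `key_iip_sc()`: interpersonal problems circumplex, 32 items, 0-4,
#'   4 items per octant, mean aggregation.
#' * `key_isc()`: interpersonal sensitivities circumplex, 64 items, 1-8,
#'   8 items per octant, mean aggregation.
#' * `key_mss()`: true/false (0/1) schizotypy scale, 77 items, summed
#'   subscales Negative (26), Positive (26), Disorganized (25).
#' * `key_spq_bru()`: 32 items, 1-5, mean-scored subscales Interpersonal (8),
#'   Social Anxiety (5), Cognitive-Perceptual (12), Disorganized (7), plus a
#'   combined three-factor Interpersonal scale (13 items).
#' * `key_ffsi()`: 90 items, 1-5, mean-scored domains Agreeableness (10),
#'   Extraversion (30), Neuroticism (20), Openness (30).
#' * `key_pid5_stpd()`: 57 STPD-facet items, 0-3, mean-scored domains
#'   Detachment (24) and Psychoticism (33).
#' * `key_pai_infrequency()`: 8 validity items, 0-3, summed.
#'
#' @param geometry An [octant_geometry()] (circumplex keys only).
#' @return A [scoring_key()].
#' @name bundled_keys
NULL

#' @rdname bundled_keys
#' @export
key_iip_sc <- function(geometry = octant_geometry()) {
  om <- block_map("IIP", stats::setNames(rep(4L, 8L), geometry$codes))
  scoring_key("IIP-SC", unlist(om, use.names = FALSE), om, 0L, 4L, "mean",
              octant_map = om, geometry = geometry)
}

#' @rdname bundled_keys
#' @export
key_isc <- function(geometry = octant_geometry()) {
  om <- block_map("ISC", stats::setNames(rep(8L, 8L), geometry$codes))
  scoring_key("ISC", unlist(om, use.names = FALSE), om, 1L, 8L, "mean",
              octant_map = om, geometry = geometry)
}

#' @rdname bundled_keys
#' @export
key_mss <- function() {
  sm <- block_map("MSS", c(Negative = 26L, Positive = 26L, Disorganized = 25L))
  scoring_key("MSS", unlist(sm, use.names = FALSE), sm, 0L, 1L, "sum")
}

#' @rdname bundled_keys
#' @export
key_spq_bru <- function() {
  sm <- block_map("SPQ", c(Interpersonal = 8L, `Social Anxiety` = 5L,
                           `Cognitive-Perceptual` = 12L, Disorganized = 7L))
  sm[["Interpersonal (3-factor)"]] <- c(sm[["Interpersonal"]], sm[["Social Anxiety"]])
  scoring_key("SPQ-BRU", unique(unlist(sm, use.names = FALSE)), sm, 1L, 5L, "mean")
}

#' @rdname bundled_keys
#' @export
key_ffsi <- function() {
  sm <- block_map("FFSI", c(Agreeableness = 10L, Extraversion = 30L,
                            Neuroticism = 20L, Openness = 30L))
  scoring_key("FFSI", unlist(sm, use.names = FALSE), sm, 1L, 5L, "mean")
}

#' @rdname bundled_keys
#' @export
key_pid5_stpd <- function() {
  sm <- block_map("PID5", c(Detachment = 24L, Psychoticism = 33L))
  scoring_key("PID-5 STPD", unlist(sm, use.names = FALSE), sm, 0L, 3L, "mean")
}

#' @rdname bundled_keys
#' @export
key_pai_infrequency <- function() {
  sm <- block_map("INF", c(Infrequency = 8L))
  scoring_key("PAI-Infrequency", unlist(sm, use.names = FALSE), sm, 0L, 3L, "sum")
}

#' Read or write a scoring key as YAML
#'
#' @param path Path to a YAML key file.
#' @param geometry An [octant_geometry()].
#' @return `read_scoring_key()` returns a [scoring_key()];
#'   `write_scoring_key()` returns `path` invisibly.
#' @export
read_scoring_key <- function(path, geometry = octant_geometry()) {
  y <- yaml::read_yaml(path)
  scoring_key(instrument = y$instrument,
              item_ids = as.character(y$item_ids),
              scale_map = lapply(y$scale_map, as.character),
              response_min = y$response_min, response_max = y$response_max,
              aggregation = y$aggregation,
              octant_map = if (!is.null(y$octant_map)) lapply(y$octant_map, as.character),
              geometry = geometry)
}

#' @rdname read_scoring_key
#' @param key A [scoring_key()].
#' @export
write_scoring_key <- function(key, path) {
  yaml::write_yaml(unclass(key), path)
  invisible(path)
}
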