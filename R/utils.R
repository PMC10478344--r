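## RNG state save/restore so seeded functions don't clobber the caller's stream.
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

## Coerce a participant-rows table (first column id) to a numeric matrix with
## rownames. Accepts a matrix with rownames as-is.
as_response_matrix <- function(responses, id_col = 1L) {
  if (is.matrix(responses)) {
    if (nrow(responses) == 0L) stop("empty response matrix", call. = FALSE)
    if (is.null(rownames(responses))) {
      stop("response matrix needs participant ids as rownames", call. = FALSE)
    }
    storage.mode(responses) <- "double"
    return(responses)
  }
  responses <- as.data.frame(responses)
  if (nrow(responses) == 0L) stop("empty response matrix", call. = FALSE)
  ids <- as.character(responses[[id_col]])
  if (anyDuplicated(ids)) stop("participant ids must be unique", call. = FALSE)
  m <- as.matrix(responses[, -id_col, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' Read a delimited item-response file
#'
#' Expects a header row of item ids, one row per participant, the first
#' column holding the participant id; empty cells are missing responses.
#'
#' @param path Path to a CSV (or TSV with `sep = "\t"`) file.
#' @param sep Field separator.
#' @return A tibble with a `participant_id` column followed by item columns.
#' @export
read_responses <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          na.strings = c("", "NA"), stringsAsFactors = FALSE)
  names(df)[1] <- "participant_id"
  df$participant_id <- as.character(df$participant_id)
  tibble::as_tibble(df)
}

#' Write a participant table to a delimited file
#' @param x Data frame or matrix with participant ids (first column or rownames).
#' @param path Output path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_responses <- function(x, path, sep = ",") {
  if (is.matrix(x)) {
    x <- data.frame(participant_id = rownames(x), x, check.names = FALSE)
  }
  utils::write.table(x, path, sep = sep, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
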