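#' Read raw value-survey responses
#'
#' Reads a delimited participant x item table: first column participant id,
#' remaining columns one per survey item, ratings on the quasi-bipolar
#' -1..7 scale (-1 opposed to my values, 0 not important, 7 of supreme
#' importance). Empty cells and `NA` are treated as missing.
#'
#' @param path delimited file with a header row of item ids.
#' @param sep field separator (default tab; use "," for CSV).
#' @return a `value_survey_responses` object: list with `participant_ids`,
#'   `item_ids` and the integer `ratings` matrix (participants x items).
#' @export
read_value_responses <- function(path, sep = "\t") {
  tab <- read.delim(path, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE)
  if (ncol(tab) < 3) stop("expected a participant-id column plus >= 2 items")
  ids <- as.character(tab[[1]])
  ratings <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(ratings) <- "double"
  rownames(ratings) <- ids
  value_survey_responses(ratings)
}

#' Construct a value-survey response object
#'
#' Validates that all non-missing ratings are integers on the -1..7 scale
#' and that every participant rated at least two items.
#'
#' @param ratings numeric matrix, participants x items, with participant ids
#'   as row names and item ids as column names; `NA` for missing.
#' @return a `value_survey_responses` object.
#' @export
value_survey_responses <- function(ratings) {
  ratings <- as.matrix(ratings)
  if (is.null(rownames(ratings))) {
    rownames(ratings) <- paste0("p", seq_len(nrow(ratings)))
  }
  if (is.null(colnames(ratings))) {
    stop("ratings must have item ids as column names")
  }
  vals <- ratings[!is.na(ratings)]
  if (any(vals != round(vals))) {
    stop("ratings must be integers on the -1..7 scale; found non-integer values")
  }
  if (any(vals < -1 | vals > 7)) {
    bad <- range(vals)
    stop("ratings outside the -1..7 scale (observed range ",
         bad[1], "..", bad[2], ")")
  }
  n_rated <- rowSums(!is.na(ratings))
  if (any(n_rated < 2)) {
    stop("participants with fewer than 2 rated items: ",
         paste(rownames(ratings)[n_rated < 2], collapse = ", "))
  }
  out <- list(participant_ids = rownames(ratings),
              item_ids = colnames(ratings),
              ratings = ratings)
  class(out) <- "value_survey_responses"
  out
}

#' Ipsatize survey ratings
#'
#' Centers each participant's ratings on that participant's own mean across
#' their non-missing items. This removes individual differences in scale
#' use (rating style) before value-type scores are formed; all 56 items
#' contribute to the mean, including any items not assigned to a value type.
#'
#' @param responses a `value_survey_responses` object or a ratings matrix.
#' @return numeric matrix of centered ratings, same shape; each row of
#'   non-missing values has mean zero.
#' @export
#' @examples
#' m <- rbind(p1 = c(i1 = 4, i2 = 4), p2 = c(-1, 7))
#' ipsatize(value_survey_responses(m))
ipsatize <- function(responses) {
  ratings <- if (inherits(responses, "value_survey_responses")) {
    responses$ratings
  } else {
    as.matrix(responses)
  }
  all_missing <- rowSums(!is.na(ratings)) == 0
  if (any(all_missing)) {
    stop("participants with all items missing: ",
         paste(rownames(ratings)[all_missing], collapse = ", "))
  }
  ratings - rowMeans(ratings, na.rm = TRUE)
}

#' Read an item-to-value-type map
#'
#' Two-column delimited file (item_id, value_type) with the literal string
#' `"NA"` (or an empty field) marking items that belong to no value type.
#'
#' @param path file path.
#' @param sep field separator.
#' @return a named character vector: item id -> value type, `NA` for
#'   unassigned items.
#' @export
read_item_map <- function(path, sep = "\t") {
  tab <- read.delim(path, sep = sep, stringsAsFactors = FALSE,
                    na.strings = c("NA", ""))
  if (ncol(tab) < 2) stop("item map needs columns item_id and value_type")
  if (anyDuplicated(tab[[1]])) {
    stop("duplicate item ids in map: ",
         paste(unique(tab[[1]][duplicated(tab[[1]])]), collapse = ", "))
  }
  stats::setNames(as.character(tab[[2]]), as.character(tab[[1]]))
}

#' Default 56-item map onto the ten value types
#'
#' The standard 56-item value survey assigns 54 items to the ten value
#' types (universalism 7, benevolence 9, tradition 6, conformity 4,
#' security 6, power 5, achievement 6, hedonism 2, stimulation 3,
#' self-direction 6); two items belong to no type and contribute only to
#' the ipsatization mean. Item ids here are positional placeholders
#' (`item01`..`item56`), since the mapping of ids to item wording is
#' instrument-specific.
#'
#' @return named character vector, item id -> value type (`NA` for the two
#'   unassigned items).
#' @export
schwartz_item_map <- function() {
  counts <- c(universalism = 7, benevolence = 9, tradition = 6,
              conformity = 4, security = 6, power = 5, achievement = 6,
              hedonism = 2, stimulation = 3, "self-direction" = 6)
  types <- c(rep(names(counts), counts), NA_character_, NA_character_)
  stats::setNames(types, sprintf("item%02d", seq_along(types)))
}

#' Aggregate centered ratings into value-type scores
#'
#' Averages each participant's centered (ipsatized) ratings over the items
#' assigned to each value type. Items with no assignment are ignored here
#' (they still shaped the ipsatization mean).
#'
#' @param centered matrix of centered ratings from [ipsatize()].
#' @param item_map named character vector, item id -> value type, `NA` for
#'   unassigned; defaults to [schwartz_item_map()].
#' @return a `value_type_scores` object: list with `participant_ids` and a
#'   participants x types `scores` matrix.
#' @export
aggregate_value_types <- function(centered, item_map = schwartz_item_map()) {
  centered <- as.matrix(centered)
  unknown <- setdiff(names(item_map)[!is.na(item_map)], colnames(centered))
  if (length(unknown) > 0) {
    stop("item map refers to items absent from the ratings: ",
         paste(unknown, collapse = ", "))
  }
  types <- unique(item_map[!is.na(item_map)])
  scores <- matrix(NA_real_, nrow(centered), length(types),
                   dimnames = list(rownames(centered), types))
  for (type in types) {
    items <- names(item_map)[!is.na(item_map) & item_map == type]
    sub <- centered[, items, drop = FALSE]
    n_ok <- rowSums(!is.na(sub))
    if (any(n_ok == 0)) {
      stop("value type '", type, "' has no non-missing items for ",
           "participant(s): ",
           paste(rownames(centered)[n_ok == 0], collapse = ", "))
    }
    scores[, type] <- rowMeans(sub, na.rm = TRUE)
  }
  out <- list(participant_ids = rownames(centered), scores = scores)
  class(out) <- "value_type_scores"
  out
}

#' Cronbach's alpha
#'
#' Internal-consistency coefficient
#' `alpha = k/(k-1) * (1 - sum of item variances / variance of the total)`.
#' Rows with any missing item are dropped (the total score is otherwise
#' undefined).
#'
#' @param item_matrix numeric matrix, participants x items (k >= 2 columns).
#' @return alpha (a single number, at most 1; can be negative for
#'   inconsistent items).
#' @export
#' @examples
#' x <- rnorm(20)
#' cronbach_alpha(cbind(x, x))  # identical items: alpha = 1
cronbach_alpha <- function(item_matrix) {
  m <- as.matrix(item_matrix)
  if (ncol(m) < 2) stop("Cronbach's alpha needs at least 2 items")
  m <- m[complete.cases(m), , drop = FALSE]
  if (nrow(m) < 2) stop("need at least 2 complete participants")
  k <- ncol(m)
  total_var <- var(rowSums(m))
  if (total_var <= 0) stop("total score has zero variance; alpha undefined")
  k / (k - 1) * (1 - sum(apply(m, 2, var)) / total_var)
}

#' Cronbach's alpha per value type
#'
#' Computes alpha for each value type over its assigned items, mirroring the
#' standard per-type reliability table for the 56-item survey. Alphas are
#' computed on the centered (ipsatized) ratings by default, matching the
#' scores that enter the analysis.
#'
#' @param ratings matrix of (centered or raw) ratings, participants x items.
#' @param item_map item -> type map; defaults to [schwartz_item_map()].
#' @return data.frame with columns `value_type`, `n_items`, `alpha`. Types
#'   with fewer than 2 items get `NA` with a warning.
#' @export
value_type_alphas <- function(ratings, item_map = schwartz_item_map()) {
  ratings <- as.matrix(ratings)
  types <- unique(item_map[!is.na(item_map)])
  res <- lapply(types, function(type) {
    items <- intersect(names(item_map)[!is.na(item_map) & item_map == type],
                       colnames(ratings))
    alpha <- if (length(items) >= 2) {
      cronbach_alpha(ratings[, items, drop = FALSE])
    } else {
      NA_real_
    }
    data.frame(value_type = type, n_items = length(items), alpha = alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (anyNA(out$alpha)) {
    warning("alpha undefined for types with < 2 items: ",
            paste(out$value_type[is.na(out$alpha)], collapse = ", "))
  }
  out
}

#' Score a questionnaire scale with reverse-keyed items
#'
#' Reverse-keyed items are recoded as `lo + hi - rating` before averaging;
#' the scale score is the mean of the keyed ratings over a participant's
#' non-missing items.
#'
#' @param responses numeric matrix, participants x items, item ids as column
#'   names.
#' @param items character vector of item ids making up the scale.
#' @param reverse_keyed subset of `items` to reverse before averaging.
#' @param scale_range numeric `c(lo, hi)` of the response scale (used for
#'   reversal).
#' @return named numeric vector of per-participant scale scores.
#' @export
#' @examples
#' m <- cbind(q1 = c(2, 4), q2 = c(4, 2))
#' score_scale(m, c("q1", "q2"), reverse_keyed = "q2", scale_range = c(1, 5))
score_scale <- function(responses, items, reverse_keyed = character(),
                        scale_range) {
  m <- as.matrix(responses)
  if (length(scale_range) != 2 || scale_range[1] >= scale_range[2]) {
    stop("scale_range must be c(lo, hi) with lo < hi")
  }
  if (!all(reverse_keyed %in% items)) {
    stop("reverse_keyed items not in the scale: ",
         paste(setdiff(reverse_keyed, items), collapse = ", "))
  }
  missing_items <- setdiff(items, colnames(m))
  if (length(missing_items) > 0) {
    stop("scale items absent from responses: ",
         paste(missing_items, collapse = ", "))
  }
  sub <- m[, items, drop = FALSE]
  n_ok <- rowSums(!is.na(sub))
  if (any(n_ok == 0)) {
    stop("participants with all scale items missing: ",
         paste(rownames(m)[n_ok == 0], collapse = ", "))
  }
  rng <- range(sub, na.rm = TRUE)
  if (rng[1] < scale_range[1] || rng[2] > scale_range[2]) {
    stop("ratings outside the declared scale range ",
         scale_range[1], "..", scale_range[2])
  }
  for (it in reverse_keyed) {
    sub[, it] <- scale_range[1] + scale_range[2] - sub[, it]
  }
  rowMeans(sub, na.rm = TRUE)
}

#' Write value-type scores to TSV
#'
#' @param value_scores a `value_type_scores` object.
#' @param path output path.
#' @return invisibly, the written data.frame.
#' @export
write_value_scores <- function(value_scores, path) {
  stopifnot(inherits(value_scores, "value_type_scores"))
  tab <- data.frame(participant_id = value_scores$participant_ids,
                    value_scores$scores, check.names = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}
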