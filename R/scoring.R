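# Bin scoring: raw slider distances -> equal-frequency bin scores (1-6),
# with persistent per-item bin boundaries so retest data is scored
# against the boundaries established in the main test.

#' Raw absolute-distance scores
#'
#' One raw score per non-missing response: the absolute difference
#' between the item's target and the respondent's final slider position.
#' Unmoved sliders are scored at the default position, not treated as
#' missing.
#'
#' @param responses `tpt_responses`.
#' @param session `tpt_session` whose scored items cover the responses.
#' @return Data frame `respondent_id`, `item_id`, `distance` (class
#'   `tpt_raw_scores`).
#' @export
raw_scores <- function(responses, session) {
  items <- scored_items(session)
  resp <- responses[responses$item_id %in% c(items$item_id), , drop = FALSE]
  unknown <- setdiff(responses$item_id, session$items$item_id)
  if (length(unknown) > 0) {
    stop("responses reference unknown item(s): ",
         paste(unique(unknown), collapse = ", "), call. = FALSE)
  }
  target <- items$target_slider[match(resp$item_id, items$item_id)]
  final <- ifelse(resp$moved, resp$final_slider, session$default_slider)
  out <- data.frame(respondent_id = resp$respondent_id,
                    item_id = resp$item_id,
                    distance = abs(target - final),
                    stringsAsFactors = FALSE)
  out <- out[!is.na(out$distance), , drop = FALSE]
  class(out) <- c("tpt_raw_scores", "data.frame")
  out
}

#' Flag items with too many unmoved sliders
#'
#' Items whose fraction of unmoved-slider observations exceeds the
#' threshold (strictly) are excluded from binning: too many responses
#' piled at one value leave too few distinct observations to form
#' equal-frequency bins with discriminatory power.
#'
#' @param responses `tpt_responses`.
#' @param threshold Exclusion threshold on the unmoved fraction
#'   (default 0.30; a fraction of exactly 0.30 is retained).
#' @return Character vector of flagged item ids.
#' @export
flag_items <- function(responses, threshold = 0.30) {
  if (nrow(responses) == 0) stop("no responses", call. = FALSE)
  frac <- tapply(!responses$moved, responses$item_id, mean)
  names(frac)[frac > threshold]
}

#' Compute equal-frequency bin boundaries
#'
#' For each retained item, places the five interior boundaries at the
#' type-1 (inverse empirical CDF) quantiles j/k of the observed distance
#' distribution, defining k = 6 bins with roughly equal occupancy.
#' Observations equal to a boundary fall in the lower-distance (better)
#' bin.
#'
#' @param raw `tpt_raw_scores`.
#' @param k Number of bins (default 6).
#' @param exclude Item ids to exclude (e.g. from [flag_items()]).
#' @param version Session version the boundaries belong to (recorded so
#'   retest scoring can refuse a mismatched table).
#' @return `tpt_bins`: list with `boundaries` (named list of length-(k-1)
#'   numeric vectors), `k`, `version`, `excluded`.
#' @export
compute_bins <- function(raw, k = 6, exclude = character(0),
                         version = "full") {
  ids <- setdiff(unique(raw$item_id), exclude)
  boundaries <- lapply(ids, function(id) {
    d <- raw$distance[raw$item_id == id]
    if (length(d) < k) {
      stop("item ", id, ": fewer observations (", length(d),
           ") than bins (", k, ")", call. = FALSE)
    }
    if (length(unique(d)) < k) {
      stop("item ", id, ": distance distribution too degenerate for ",
           k, " bins", call. = FALSE)
    }
    unname(stats::quantile(d, probs = seq_len(k - 1) / k, type = 1))
  })
  names(boundaries) <- ids
  structure(list(boundaries = boundaries, k = k, version = version,
                 excluded = exclude), class = "tpt_bins")
}

#' @export
print.tpt_bins <- function(x, ...) {
  cat(sprintf("Bin table (%s session): %d items, %d bins each, %d excluded\n",
              x$version, length(x$boundaries), x$k, length(x$excluded)))
  invisible(x)
}

bin_number <- function(distance, bounds) {
  # ties at a boundary fall in the lower (better) bin
  1L + vapply(distance, function(d) sum(d > bounds), integer(1))
}

#' Apply bin boundaries to raw scores
#'
#' Maps each distance to its bin and assigns the score k+1-bin, so the
#' smallest-distance bin scores k (best) and the largest scores 1
#' (worst). Scores are aggregated by averaging across items within each
#' block-by-variant cell, plus match, memory and overall means.
#'
#' @param raw `tpt_raw_scores`.
#' @param bins `tpt_bins` from [compute_bins()] (or [load_bins()] for
#'   retest scoring).
#' @param session `tpt_session` the raw scores came from.
#' @return `tpt_score_report`: list with `item_scores` (long data frame)
#'   and `respondent_scores` (one row per respondent with block/variant
#'   means, match/memory totals and overall score).
#' @export
apply_bins <- function(raw, bins, session) {
  if (any(raw$distance < 0 | raw$distance > 100)) {
    stop("distances must lie in [0, 100]", call. = FALSE)
  }
  keep <- raw$item_id %in% names(bins$boundaries)
  raw <- raw[keep, , drop = FALSE]
  items <- scored_items(session)
  score <- integer(nrow(raw))
  for (id in unique(raw$item_id)) {
    sel <- raw$item_id == id
    score[sel] <- bins$k + 1L - bin_number(raw$distance[sel],
                                           bins$boundaries[[id]])
  }
  item_scores <- data.frame(raw, score = score, stringsAsFactors = FALSE)
  item_scores$block <- items$block[match(item_scores$item_id, items$item_id)]
  item_scores$variant <- items$variant[match(item_scores$item_id, items$item_id)]

  per_resp <- function(df) {
    out <- list()
    known <- !is.na(df$block) & !is.na(df$variant)
    cells <- unique(df[known, c("block", "variant")])
    for (i in seq_len(nrow(cells))) {
      b <- cells$block[i]; v <- cells$variant[i]
      out[[paste(b, v, sep = "_")]] <-
        mean(df$score[known & df$block == b & df$variant == v])
    }
    if (any(known & df$variant == "match")) {
      out$match_total <- mean(df$score[known & df$variant == "match"])
    }
    if (any(known & df$variant == "memory")) {
      out$memory_total <- mean(df$score[known & df$variant == "memory"])
    }
    out$overall <- mean(df$score)
    as.data.frame(out)
  }
  parts <- lapply(split(item_scores, item_scores$respondent_id), per_resp)
  respondent_scores <- do.call(rbind, parts)
  respondent_scores <- data.frame(respondent_id = names(parts),
                                  respondent_scores,
                                  stringsAsFactors = FALSE)
  rownames(respondent_scores) <- NULL
  structure(list(item_scores = item_scores,
                 respondent_scores = respondent_scores),
            class = "tpt_score_report")
}

#' @export
print.tpt_score_report <- function(x, ...) {
  cat(sprintf("Score report: %d respondents, %d scored responses\n",
              nrow(x$respondent_scores), nrow(x$item_scores)))
  cat(sprintf("  mean overall score %.2f (range %.2f-%.2f)\n",
              mean(x$respondent_scores$overall),
              min(x$respondent_scores$overall),
              max(x$respondent_scores$overall)))
  invisible(x)
}

#' Score a response table end to end
#'
#' Raw distances, item flagging, bin computation (unless a pre-computed
#' bin table is supplied) and bin-score aggregation in one call.
#'
#' @param responses `tpt_responses`.
#' @param session `tpt_session`.
#' @param bins Optional pre-established `tpt_bins` (retest scoring);
#'   when supplied its version must match the session's.
#' @param k Number of bins when computing fresh boundaries.
#' @param flag_threshold Unmoved-fraction exclusion threshold.
#' @return List with `report` (`tpt_score_report`), `bins` (`tpt_bins`)
#'   and `flagged` (character vector).
#' @export
score_responses <- function(responses, session, bins = NULL, k = 6,
                            flag_threshold = 0.30) {
  raw <- raw_scores(responses, session)
  flagged <- flag_items(responses, flag_threshold)
  if (is.null(bins)) {
    bins <- compute_bins(raw, k = k, exclude = flagged,
                         version = session$version)
  } else if (!identical(bins$version, session$version)) {
    stop("bin table was computed for a '", bins$version,
         "' session, not '", session$version, "'", call. = FALSE)
  }
  list(report = apply_bins(raw, bins, session), bins = bins,
       flagged = flagged)
}

#' Persist bin boundaries
#'
#' Saves the bin table as JSON so retest data can be scored against the
#' boundaries established in the main test.
#'
#' @param bins `tpt_bins`.
#' @param path Output JSON path.
#' @return Invisibly, the path.
#' @export
save_bins <- function(bins, path) {
  jsonlite::write_json(unclass(bins), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load persisted bin boundaries
#'
#' @param path JSON path written by [save_bins()].
#' @return `tpt_bins`.
#' @export
load_bins <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$boundaries <- lapply(x$boundaries, as.numeric)
  x$excluded <- as.character(x$excluded)
  structure(x, class = "tpt_bins")
}
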