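# Test protocol: item structure, session construction, response tables.

BLOCKS <- c("envelope", "flux", "centroid")

#' Default parameter sets for the five stimulus targets
#'
#' Five parameter sets place target slider values \{10, 30, 50, 70, 90\}
#' on each dimension, crossed with the five pitches through a 5x5 Latin
#' square so every set pairs different values across dimensions. All
#' values are configurable; these defaults span the slider scale.
#'
#' @param values Five target slider values (default `c(10,30,50,70,90)`).
#' @param pitches Five pitch names (default `names(tpt_pitch_set())`).
#' @return Data frame with one row per parameter set: `param_set`,
#'   `envelope_slider`, `flux_slider`, `centroid_slider`, `pitch`.
#' @export
tpt_parameter_sets <- function(values = c(10, 30, 50, 70, 90),
                               pitches = names(tpt_pitch_set())) {
  stopifnot(length(values) == 5, length(pitches) == 5)
  i <- 1:5
  data.frame(
    param_set = i,
    envelope_slider = values[i],
    flux_slider = values[(i %% 5) + 1],
    centroid_slider = values[((i + 1) %% 5) + 1],
    pitch = pitches[i],
    stringsAsFactors = FALSE
  )
}

make_items <- function(block, variant, sets, rep_tag = "") {
  tag <- substr(block, 1, 3)
  vtag <- c(match = "match", memory = "mem", training = "train")[variant]
  data.frame(
    item_id = sprintf("%s_%s_s%d%s", tag, vtag, sets$param_set, rep_tag),
    block = block,
    variant = variant,
    param_set = sets$param_set,
    target_slider = sets[[paste0(block, "_slider")]],
    envelope_slider = sets$envelope_slider,
    flux_slider = sets$flux_slider,
    centroid_slider = sets$centroid_slider,
    pitch = sets$pitch,
    stringsAsFactors = FALSE
  )
}

new_session <- function(items, version, default_slider = 50) {
  structure(list(items = items, version = version,
                 default_slider = default_slider),
            class = "tpt_session")
}

#' @export
print.tpt_session <- function(x, ...) {
  sc <- scored_items(x)
  cat(sprintf("TPT session (%s): %d items (%d scored)\n", x$version,
              nrow(x$items), nrow(sc)))
  print(table(sc$block, sc$variant))
  invisible(x)
}

#' Scored items of a session
#'
#' Items excluding training trials; the unit of scoring.
#'
#' @param session `tpt_session`.
#' @return Data frame of scored items.
#' @export
scored_items <- function(session) {
  session$items[session$items$variant != "training", , drop = FALSE]
}

#' Build the full test session
#'
#' Three blocks (envelope, flux, centroid), each with one training item,
#' five match trials covering all five parameter sets once, and ten
#' memory trials covering the sets twice — 45 scored items in total.
#' Within-block presentation order is permuted by the seed; item
#' identities are stable across seeds.
#'
#' @param seed Integer seed controlling presentation order.
#' @param sets Parameter sets (default [tpt_parameter_sets()]).
#' @param default_slider Default (untouched) slider position, used when a
#'   respondent leaves the slider unmoved (default 50).
#' @return `tpt_session` with `version = "full"`.
#' @export
#' @examples
#' s <- build_full_session(seed = 1)
#' nrow(scored_items(s))  # 45
build_full_session <- function(seed = 1, sets = tpt_parameter_sets(),
                               default_slider = 50) {
  rng <- local({ set.seed(seed); function(n) sample.int(n) })
  blocks <- lapply(BLOCKS, function(b) {
    train <- make_items(b, "training", sets[3, , drop = FALSE])
    match <- make_items(b, "match", sets)[rng(5), ]
    memory <- rbind(make_items(b, "memory", sets, "r1"),
                    make_items(b, "memory", sets, "r2"))[rng(10), ]
    rbind(train, match, memory)
  })
  items <- do.call(rbind, blocks)
  rownames(items) <- NULL
  new_session(items, "full", default_slider)
}

#' Item identifiers excluded from the short version by default
#'
#' The envelope and flux match items whose targets sit at the default
#' slider position (raw distance 0 from an unmoved slider); these attract
#' unmoved-slider responses and are dropped from the short version.
#'
#' @param sets Parameter sets (default [tpt_parameter_sets()]).
#' @param default_slider Default slider position (default 50).
#' @return Character vector of two item ids.
#' @export
tpt_default_flags <- function(sets = tpt_parameter_sets(),
                              default_slider = 50) {
  env_set <- sets$param_set[which.min(abs(sets$envelope_slider - default_slider))]
  flux_set <- sets$param_set[which.min(abs(sets$flux_slider - default_slider))]
  c(sprintf("env_match_s%d", env_set), sprintf("flu_match_s%d", flux_set))
}

#' Build the short (match-only) session
#'
#' Keeps only match trials and removes the flagged items — by default one
#' envelope and one flux item — leaving 13 items: four envelope, four
#' flux and five centroid match trials.
#'
#' @param flagged_items Character vector of match item ids to exclude
#'   (default [tpt_default_flags()]).
#' @param seed Integer seed controlling presentation order.
#' @param sets Parameter sets.
#' @param default_slider Default slider position.
#' @return `tpt_session` with `version = "short"`.
#' @export
#' @examples
#' nrow(scored_items(build_short_session()))  # 13
build_short_session <- function(flagged_items = tpt_default_flags(),
                                seed = 1, sets = tpt_parameter_sets(),
                                default_slider = 50) {
  full <- build_full_session(seed, sets, default_slider)
  match <- full$items[full$items$variant == "match", , drop = FALSE]
  unknown <- setdiff(flagged_items, match$item_id)
  if (length(unknown) > 0) {
    stop("flagged items not among the session's match items: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  items <- match[!match$item_id %in% flagged_items, , drop = FALSE]
  rownames(items) <- NULL
  new_session(items, "short", default_slider)
}

# Response tables -------------------------------------------------------

RESPONSE_COLS <- c("respondent_id", "item_id", "final_slider", "moved",
                   "n_stimulus_playbacks", "n_reproduction_playbacks")

#' Construct a response table
#'
#' One row per (respondent, item): the final slider position, whether the
#' slider was moved at all, and playback counts. Unmoved sliders are
#' recorded at the default position with `moved = FALSE`, never as
#' missing.
#'
#' @param df Data frame with columns `respondent_id`, `item_id`,
#'   `final_slider`, `moved`, `n_stimulus_playbacks`,
#'   `n_reproduction_playbacks`.
#' @return `tpt_responses` (a validated data frame).
#' @export
tpt_responses <- function(df) {
  missing_cols <- setdiff(RESPONSE_COLS, names(df))
  if (length(missing_cols) > 0) {
    stop("response table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad <- which(!is.na(df$final_slider) &
                 (df$final_slider < 0 | df$final_slider > 100))
  if (length(bad) > 0) {
    stop("final_slider outside [0, 100] in row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  over <- which(grepl("_mem_", df$item_id) & df$n_stimulus_playbacks > 1)
  if (length(over) > 0) {
    warning("memory item(s) with more than one stimulus playback in row(s): ",
            paste(over, collapse = ", "), call. = FALSE)
  }
  df <- df[, RESPONSE_COLS]
  class(df) <- c("tpt_responses", "data.frame")
  df
}

#' Read a response table from CSV
#'
#' @param path CSV file with a header naming the response fields.
#' @return `tpt_responses`.
#' @export
read_responses <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  tpt_responses(df)
}

#' Write a response table to CSV
#'
#' @param responses `tpt_responses`.
#' @param path Output CSV path.
#' @return Invisibly, the path.
#' @export
write_responses <- function(responses, path) {
  utils::write.csv(as.data.frame(responses), path, row.names = FALSE)
  invisible(path)
}
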