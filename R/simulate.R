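# Synthetic respondents: a latent-ability noise model on the slider
# scale, so scoring and psychometrics can be exercised end to end
# without human data.

#' Construct a synthetic respondent model
#'
#' A respondent reproduces an item's target slider value with additive
#' Gaussian noise whose standard deviation shrinks with latent ability:
#' sd = sigma_dim * exp(-kappa * ability), multiplied by
#' `memory_multiplier` on memory trials (the single allowed playback
#' degrades reproduction accuracy). With probability `p_stick` the
#' slider is left at the default position.
#'
#' @param ability Latent ability on a standard-normal scale.
#' @param sigma_dim Baseline noise sd in slider units, one value per
#'   dimension (recycled; default 15 for all three).
#' @param kappa Ability sensitivity (>= 0; default 1).
#' @param memory_multiplier Noise inflation on memory trials (>= 1;
#'   default 1.5).
#' @param p_stick Probability of leaving the slider at default
#'   (default 0.05).
#' @return Object of class `tpt_respondent`.
#' @export
respondent_model <- function(ability = 0,
                             sigma_dim = c(envelope = 15, flux = 15,
                                           centroid = 15),
                             kappa = 1, memory_multiplier = 1.5,
                             p_stick = 0.05) {
  if (length(sigma_dim) == 1) {
    sigma_dim <- stats::setNames(rep(sigma_dim, 3), BLOCKS)
  }
  stopifnot(all(sigma_dim > 0), kappa >= 0, memory_multiplier >= 1,
            p_stick >= 0, p_stick <= 1)
  structure(list(ability = ability, sigma_dim = sigma_dim, kappa = kappa,
                 memory_multiplier = memory_multiplier, p_stick = p_stick),
            class = "tpt_respondent")
}

response_sd <- function(model, block, variant) {
  sd <- model$sigma_dim[[block]] * exp(-model$kappa * model$ability)
  if (identical(variant, "memory")) sd <- sd * model$memory_multiplier
  sd
}

#' Simulate one trial response
#'
#' @param model `tpt_respondent`.
#' @param item One row of a session's item table.
#' @param default_slider Default slider position (default 50).
#' @return One-row `tpt_responses` data frame. Uses the current RNG
#'   state; seed at the cohort level for reproducibility.
#' @export
simulate_response <- function(model, item, default_slider = 50) {
  stick <- stats::runif(1) < model$p_stick
  if (stick) {
    final <- default_slider
  } else {
    sd <- response_sd(model, item$block, item$variant)
    final <- item$target_slider + stats::rnorm(1, 0, sd)
    final <- min(100, max(0, final))
  }
  n_stim <- if (identical(item$variant, "memory")) 1L else
    1L + stats::rpois(1, 3)
  data.frame(respondent_id = NA_character_,
             item_id = item$item_id,
             final_slider = final,
             moved = !stick,
             n_stimulus_playbacks = n_stim,
             n_reproduction_playbacks = 1L + stats::rpois(1, 3),
             stringsAsFactors = FALSE)
}

#' Specify a synthetic cohort
#'
#' @param n_respondents Cohort size (default 95).
#' @param ability_mean,ability_sd Latent ability distribution
#'   (standard normal by default).
#' @param sigma_dim,kappa,memory_multiplier,p_stick Respondent-model
#'   parameters shared by the cohort (see [respondent_model()]).
#' @param seed Integer seed; the cohort is a pure function of the spec.
#' @return Object of class `tpt_cohort_spec`.
#' @export
cohort_spec <- function(n_respondents = 95, ability_mean = 0,
                        ability_sd = 1,
                        sigma_dim = c(envelope = 15, flux = 15,
                                      centroid = 15),
                        kappa = 1, memory_multiplier = 1.5,
                        p_stick = 0.05, seed = 1) {
  stopifnot(n_respondents >= 1)
  structure(list(n_respondents = n_respondents,
                 ability_mean = ability_mean, ability_sd = ability_sd,
                 sigma_dim = sigma_dim, kappa = kappa,
                 memory_multiplier = memory_multiplier,
                 p_stick = p_stick, seed = seed),
            class = "tpt_cohort_spec")
}

draw_abilities <- function(spec) {
  stats::rnorm(spec$n_respondents, spec$ability_mean, spec$ability_sd)
}

simulate_matrix <- function(spec, session, abilities) {
  items <- scored_items(session)
  n_items <- nrow(items)
  sigma <- spec$sigma_dim
  if (length(sigma) == 1) sigma <- stats::setNames(rep(sigma, 3), BLOCKS)
  base_sd <- unname(sigma[items$block]) *
    ifelse(items$variant == "memory", spec$memory_multiplier, 1)
  is_memory <- items$variant == "memory"
  rows <- vector("list", spec$n_respondents)
  for (r in seq_len(spec$n_respondents)) {
    sd <- base_sd * exp(-spec$kappa * abilities[r])
    stick <- stats::runif(n_items) < spec$p_stick
    final <- pmin(100, pmax(0, items$target_slider +
                              stats::rnorm(n_items, 0, sd)))
    final[stick] <- session$default_slider
    rows[[r]] <- data.frame(
      respondent_id = sprintf("R%03d", r),
      item_id = items$item_id,
      final_slider = final,
      moved = !stick,
      n_stimulus_playbacks = ifelse(is_memory, 1L,
                                    1L + stats::rpois(n_items, 3)),
      n_reproduction_playbacks = 1L + stats::rpois(n_items, 3),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  tpt_responses(out)
}

#' Simulate a cohort of respondents
#'
#' Independent respondents with abilities drawn from the cohort
#' distribution; fully reproducible given the spec's seed.
#'
#' @param spec `tpt_cohort_spec`.
#' @param session `tpt_session`.
#' @return List with `responses` (`tpt_responses`) and `abilities`
#'   (named numeric vector).
#' @export
#' @examples
#' sess <- build_full_session(seed = 1)
#' sim <- simulate_cohort(cohort_spec(n_respondents = 10, seed = 7), sess)
simulate_cohort <- function(spec, session) {
  set.seed(spec$seed)
  abilities <- draw_abilities(spec)
  responses <- simulate_matrix(spec, session, abilities)
  list(responses = responses,
       abilities = stats::setNames(abilities,
                                   sprintf("R%03d",
                                           seq_len(spec$n_respondents))))
}

#' Simulate a test-retest pair
#'
#' The same respondents (same abilities) answer the session twice with
#' independent noise draws, emulating a retest after an interval long
#' enough for no item memory but no ability change.
#'
#' @param spec `tpt_cohort_spec`.
#' @param session `tpt_session`.
#' @return List with `test`, `retest` (both `tpt_responses`) and
#'   `abilities`.
#' @export
simulate_retest <- function(spec, session) {
  set.seed(spec$seed)
  abilities <- draw_abilities(spec)
  test <- simulate_matrix(spec, session, abilities)
  retest <- simulate_matrix(spec, session, abilities)
  list(test = test, retest = retest,
       abilities = stats::setNames(abilities,
                                   sprintf("R%03d",
                                           seq_len(spec$n_respondents))))
}
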