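#' Re-evaluate the preset models against a deposited dataset
#'
#' Opt-in integration entry point: given locally downloaded trait,
#' observation and split tables for the study's specimens (e.g. from the
#' public data deposition), evaluates the three preset models on the modeling
#' and testing groups and reports MSD, MSE and r squared per model and group.
#' Nothing in the default test suite calls this with real data; it exists so
#' the dataset-level metrics can be reproduced when the files are available.
#'
#' @param traits_path Trait table path (see [read_trait_table()]); derived
#'   columns are computed when absent.
#' @param observations_path Observation table path (see
#'   [read_observation_table()]), one row per replicate with per-row medium.
#' @param split_path CSV with columns `specimen_id` and `group`
#'   ("modeling"/"testing").
#' @param statistic Central statistic for replicate aggregation.
#' @return A tibble with one row per model x group: `model`, `group`, `n`,
#'   `msd`, `mse`, `r_squared`.
#' @export
reproduce_study_metrics <- function(traits_path, observations_path,
                                    split_path,
                                    statistic = c("mean", "median")) {
  statistic <- match.arg(statistic)
  traits <- read_trait_table(traits_path)
  if (!all(c("rho", "d_n", "s_f") %in% names(traits))) {
    traits <- derive_traits(traits)
  }
  obs <- read_observation_table(observations_path)
  split_df <- readr::read_csv(split_path, col_types = readr::cols(),
                              progress = FALSE)
  if (!all(c("specimen_id", "group") %in% names(split_df))) {
    abort_validity("split table needs specimen_id and group columns")
  }
  agg <- aggregate_replicates(obs, statistic)
  data <- prepare_fit_data(traits, agg)
  labels <- setNames(split_df$group, split_df$specimen_id)
  sets <- split_modeling_testing(data, labels)

  purrr::map_dfr(c("A", "B", "C"), function(st) {
    model <- model_spec(st)
    purrr::map_dfr(c("modeling", "testing"), function(grp) {
      set <- sets[[grp]]
      pred <- predict_velocity(set, medium = NULL, model = model)
      evaluate_predictions(
        set |> left_join(pred |> select(all_of(c("specimen_id", "omega_pred"))),
                         by = "specimen_id"),
        group = grp
      ) |>
        mutate(model = st, .before = 1) |>
        select(-"residuals")
    })
  })
}
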