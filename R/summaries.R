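# Small defined study statistics: pharmacokinetic brain-to-plasma ratios,
# novel-object discrimination index, and Racine-scale kindling bookkeeping.

#' Published cannabidiol pharmacokinetic table
#'
#' Per-rat plasma (ng/mL) and brain (ng/g) cannabidiol concentrations at
#' 1 h (around peak) and 24 h (trough) after a 60 mg/kg oral dose, as
#' printed in the source study (five rats per timepoint; one 24 h brain
#' sample excluded for inadequate perfusion and recorded as `NA`).
#'
#' @return A tibble: `rat`, `timepoint_h`, `plasma_ng_ml`, `brain_ng_g`.
#' @export
cbd_pk <- function() {
  path <- system.file("extdata", "cbd_pk_table.csv", package = "hippocount",
                      mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path))
}

#' Brain-to-plasma concentration ratio
#'
#' Per-animal index of brain penetration: brain concentration (ng/g)
#' divided by plasma concentration (ng/mL). Undefined (`NA`) when the brain
#' value is missing. Conventionally reported to 3 decimals.
#'
#' @param plasma_ng_ml,brain_ng_g Numeric vectors; plasma must be positive.
#' @return Numeric vector of ratios (full precision).
#' @export
brain_plasma_ratio <- function(plasma_ng_ml, brain_ng_g) {
  if (any(plasma_ng_ml <= 0, na.rm = TRUE)) {
    stop("plasma concentrations must be positive", call. = FALSE)
  }
  ifelse(is.na(brain_ng_g), NA_real_, brain_ng_g / plasma_ng_ml)
}

#' Mean and standard error of the mean
#'
#' Sample SD with n - 1 denominator; SEM = SD / sqrt(n). The printed source
#' table labels some dispersion rows "SEM" while printing the sample SD;
#' `convention = "sd"` reproduces that printed convention for cross-checks.
#'
#' @param x Numeric vector with at least 2 non-missing values (missing
#'   values are dropped).
#' @param convention `"sem"` (true SEM, default) or `"sd"`.
#' @return A one-row tibble: `n`, `mean`, `sem`.
#' @export
mean_sem <- function(x, convention = c("sem", "sd")) {
  convention <- match.arg(convention)
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 2) stop("need at least 2 values", call. = FALSE)
  s <- stats::sd(x)
  tibble::tibble(n = n, mean = mean(x),
                 sem = if (convention == "sem") s / sqrt(n) else s)
}

#' Per-timepoint pharmacokinetic summary
#'
#' Adds per-animal brain-to-plasma ratios and summarises plasma, brain and
#' ratio by timepoint (mean and SEM over non-missing values).
#'
#' @param data A tibble like [cbd_pk()].
#' @param convention Passed to [mean_sem()].
#' @return A tibble with one row per timepoint and quantity.
#' @export
pk_summary <- function(data, convention = "sem") {
  data |>
    dplyr::mutate(ratio = brain_plasma_ratio(.data$plasma_ng_ml,
                                             .data$brain_ng_g)) |>
    tidyr::pivot_longer(c("plasma_ng_ml", "brain_ng_g", "ratio"),
                        names_to = "quantity", values_to = "value") |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::group_by(.data$timepoint_h, .data$quantity) |>
    dplyr::group_modify(~ mean_sem(.x$value, convention = convention)) |>
    dplyr::ungroup()
}

#' Novel-object discrimination index
#'
#' `DI = (TN - TF) / (TN + TF)` where TN and TF are the times spent
#' exploring the novel and the familiar object. Bounded in `[-1, 1]`;
#' antisymmetric under swapping the objects.
#'
#' @param tn,tf Non-negative exploration times (s); each pair must have a
#'   positive total.
#' @return Numeric vector of indices.
#' @export
discrimination_index <- function(tn, tf) {
  if (any(tn < 0 | tf < 0)) stop("exploration times must be >= 0", call. = FALSE)
  if (any(tn + tf <= 0)) stop("total exploration time must be > 0", call. = FALSE)
  (tn - tf) / (tn + tf)
}

#' Discrimination indices with the familiarization inclusion rule
#'
#' An animal enters the memory test only if it interacted with each object
#' for at least `min_fam_s` seconds during familiarization; excluded
#' animals get `NA`.
#'
#' @param data Tibble with columns `tn_s`, `tf_s`, `fam1_s`, `fam2_s`.
#' @param min_fam_s Minimum familiarization interaction per object (s).
#' @return `data` with logical `included` and numeric `di` columns.
#' @export
nor_di <- function(data, min_fam_s = 2.5) {
  data |>
    dplyr::mutate(
      included = .data$fam1_s >= min_fam_s & .data$fam2_s >= min_fam_s &
        (.data$tn_s + .data$tf_s) > 0,
      di = ifelse(.data$included,
                  (.data$tn_s - .data$tf_s) / (.data$tn_s + .data$tf_s),
                  NA_real_))
}

#' Injection index at which an animal became kindled
#'
#' An animal is kindled at the second of the first pair of consecutive
#' injections scoring stage `min_stage` or higher on the (modified) Racine
#' scale; `NA` when never kindled.
#'
#' @param scores Integer vector of per-injection Racine scores (0-5).
#' @param min_stage Stage threshold (default 4).
#' @return Integer index or `NA_integer_`.
#' @export
kindled_at <- function(scores, min_stage = 4) {
  if (length(scores) == 0) stop("empty seizure log", call. = FALSE)
  if (any(!scores %in% 0:5)) stop("Racine scores must be integers 0-5",
                                  call. = FALSE)
  hi <- scores >= min_stage
  for (i in seq_along(hi)[-1]) {
    if (hi[i] && hi[i - 1]) return(i)
  }
  NA_integer_
}

#' Sensitivity screen on the first two injections
#'
#' Animals with two consecutive stage-5 seizures after the first two doses
#' are excluded from a kindling study before it starts.
#'
#' @param scores Per-injection Racine scores.
#' @return `TRUE` when the animal fails the screen (is excluded).
#' @export
ptz_screen_excluded <- function(scores) {
  length(scores) >= 2 && scores[1] >= 5 && scores[2] >= 5
}

#' Group summary of seizure logs
#'
#' Tabulates the descriptive kindling quantities per group: group size,
#' mortality fraction, injections to the kindled state (median over kindled
#' animals), and mean +/- SEM of the latency to and duration of generalized
#' seizures. Inferential tests are left to standard routines.
#'
#' @param data Tibble with columns `rat`, `group`, `injection`, `score`,
#'   and optionally `latency_s`, `duration_s` (present for stage >= 4
#'   rows), `survived` (per-rat logical).
#' @return A list with `groups` (one row per group) and `per_injection`
#'   (generalized-seizure counts by group and injection).
#' @export
seizure_summary <- function(data) {
  if (nrow(data) == 0) stop("empty seizure log", call. = FALSE)
  if (!"survived" %in% names(data)) data$survived <- TRUE
  per_rat <- data |>
    dplyr::group_by(.data$group, .data$rat) |>
    dplyr::summarise(
      survived = all(.data$survived),
      kindled_injection = kindled_at(.data$score[order(.data$injection)]),
      .groups = "drop")
  groups <- per_rat |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_died = sum(!.data$survived),
      mortality = sum(!.data$survived) / dplyr::n(),
      n_kindled = sum(!is.na(.data$kindled_injection)),
      median_injections_to_kindled =
        stats::median(.data$kindled_injection, na.rm = TRUE),
      .groups = "drop")
  gen <- dplyr::filter(data, .data$score >= 4)
  if (nrow(gen) > 0 && all(c("latency_s", "duration_s") %in% names(data))) {
    lat <- gen |>
      dplyr::group_by(.data$group) |>
      dplyr::summarise(
        latency_mean_s = mean(.data$latency_s, na.rm = TRUE),
        latency_sem_s = stats::sd(.data$latency_s, na.rm = TRUE) /
          sqrt(sum(!is.na(.data$latency_s))),
        duration_mean_s = mean(.data$duration_s, na.rm = TRUE),
        duration_sem_s = stats::sd(.data$duration_s, na.rm = TRUE) /
          sqrt(sum(!is.na(.data$duration_s))),
        .groups = "drop")
    groups <- dplyr::left_join(groups, lat, by = "group")
  }
  per_injection <- data |>
    dplyr::group_by(.data$group, .data$injection) |>
    dplyr::summarise(n_generalized = sum(.data$score >= 4), .groups = "drop")
  list(groups = groups, per_injection = per_injection)
}
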