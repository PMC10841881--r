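#' Select each group's best model per assessment unit
#'
#' Within the top `n` ranked models the best is the one with the highest
#' CAPRI category, ties broken by higher DockQ, then by lower rank number.
#'
#' @param manifest tibble with `group_id`, `au_id`, `model_rank`,
#'   `category`, `dockq` (optionally `role`, `score_au_norm`, `multi`).
#' @param n evaluation depth (5 for top-5, 1 for top-1).
#' @return One row per (group, AU): the selected best model.
#' @export
top_n_selection <- function(manifest, n = 5) {
  stopifnot(n >= 1)
  manifest |>
    filter(.data$model_rank <= n) |>
    mutate(.cat = factor(as.character(.data$category),
                         levels = CATEGORY_LEVELS, ordered = TRUE)) |>
    group_by(.data$group_id, .data$au_id) |>
    arrange(desc(.data$.cat), desc(.data$dockq), .data$model_rank,
            .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    select(-".cat")
}

#' Group score: weighted count of correct assessment units
#'
#' `score_g = w1*N_acc + w2*N_med + w3*N_high` over a group's AUs, counting
#' each AU once in its best category. Multi-interface AUs contribute their
#' normalized AU score (`score_au_norm` column, with `multi = TRUE`) instead
#' of a plain category weight. Incorrect models contribute nothing.
#'
#' @param per_au_best tibble with one row per (group, AU): `group_id`,
#'   `au_id`, `category`, `dockq`; optional `multi` and `score_au_norm`.
#' @param weights category weights (default 1, 2, 3).
#' @return One row per group: `score_g`, `n_acc`, `n_med`, `n_high`,
#'   `n_correct`, `sum_dockq`.
#' @export
score_group <- function(per_au_best,
                        weights = c(Acceptable = 1, Medium = 2, High = 3)) {
  df <- per_au_best
  if (!"multi" %in% names(df)) df$multi <- FALSE
  if (!"score_au_norm" %in% names(df)) df$score_au_norm <- NA_real_
  df |>
    mutate(
      cat = as.character(.data$category),
      w = dplyr::case_when(
        cat == "Acceptable" ~ weights[["Acceptable"]],
        cat == "Medium" ~ weights[["Medium"]],
        cat == "High" ~ weights[["High"]],
        TRUE ~ 0),
      contrib = ifelse(.data$multi & !is.na(.data$score_au_norm),
                       .data$score_au_norm, .data$w)) |>
    group_by(.data$group_id) |>
    summarise(
      score_g = sum(.data$contrib),
      n_acc = sum(.data$cat == "Acceptable"),
      n_med = sum(.data$cat == "Medium"),
      n_high = sum(.data$cat == "High"),
      n_correct = sum(.data$cat != "Incorrect"),
      sum_dockq = sum(.data$dockq, na.rm = TRUE),
      .groups = "drop")
}

#' Summed DockQ over assessment units
#'
#' Unlike the CAPRI score, sub-cutoff (incorrect) models still contribute
#' their DockQ; AUs without a submission contribute 0.
#'
#' @param per_au_best tibble with `group_id` and `dockq`.
#' @return Tibble `group_id`, `sum_dockq`.
#' @export
sum_dockq <- function(per_au_best) {
  per_au_best |>
    group_by(.data$group_id) |>
    summarise(sum_dockq = sum(.data$dockq, na.rm = TRUE), .groups = "drop")
}

#' Positive-truncated Z-score ranking
#'
#' Per AU, scores are standardized across groups (missing submissions enter
#' as 0 before standardization; a zero-variance AU yields all-zero Z);
#' negative Z-scores are truncated to 0, per-group sums are ranked
#' descending with ties broken by group id.
#'
#' @param per_au_best tibble with `group_id`, `au_id` and a score column.
#' @param value column to standardize: "dockq" (default) or "score" etc.
#' @return Tibble `group_id`, `sum_z`, `rank`, sorted by rank.
#' @export
zscore_rank <- function(per_au_best, value = "dockq") {
  if (length(unique(per_au_best$group_id)) < 2) {
    abort("Z-score ranking needs at least 2 groups")
  }
  wide <- per_au_best |>
    select("group_id", "au_id", value = all_of(value)) |>
    tidyr::pivot_wider(names_from = "au_id", values_from = "value",
                       values_fill = 0)
  m <- as.matrix(wide[, -1, drop = FALSE])
  z <- apply(m, 2, function(x) {
    s <- stats::sd(x)
    if (is.na(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
  })
  z <- matrix(pmax(z, 0), nrow = nrow(m))
  out <- tibble(group_id = wide$group_id, sum_z = rowSums(z)) |>
    arrange(desc(.data$sum_z), .data$group_id) |>
    mutate(rank = dplyr::row_number())
  out
}

#' Rank predictor groups from a submission manifest
#'
#' Applies [top_n_selection()] then aggregates per group: CAPRI score
#' (Eq.-4-style weighted counts), summed DockQ, and the positive-truncated
#' Z-score sum.
#'
#' @param manifest tibble of ranked models per (group, AU); see
#'   [top_n_selection()].
#' @param top_n evaluation depth (default 5).
#' @param weights category weights.
#' @param z_value score standardized in the Z ranking ("dockq" default,
#'   "score_g contribution" via "w" not exposed).
#' @return Tibble of class `capri_ranking`, one row per group, ranked by
#'   `score_g` (ties: sum_dockq, then group id).
#' @export
rank_groups <- function(manifest, top_n = 5,
                        weights = c(Acceptable = 1, Medium = 2, High = 3),
                        z_value = "dockq") {
  best <- top_n_selection(manifest, top_n)
  sg <- score_group(best, weights)
  zr <- if (length(unique(best$group_id)) >= 2) {
    zscore_rank(best, z_value)
  } else {
    tibble(group_id = unique(best$group_id), sum_z = NA_real_, rank = 1L)
  }
  out <- sg |>
    left_join(zr, by = "group_id") |>
    arrange(desc(.data$score_g), desc(.data$sum_dockq), .data$group_id) |>
    mutate(capri_rank = dplyr::row_number())
  if ("role" %in% names(manifest)) {
    roles <- distinct(manifest, .data$group_id, .data$role)
    out <- left_join(out, roles, by = "group_id")
  }
  structure(out, class = c("capri_ranking", class(out)),
            top_n = top_n, weights = weights,
            n_aus = length(unique(manifest$au_id)),
            per_au_best = best)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy capri_ranking
#' @export
tidy.capri_ranking <- function(x, ...) {
  as_tibble(x)[, intersect(c("capri_rank", "group_id", "role", "score_g",
                             "n_acc", "n_med", "n_high", "n_correct",
                             "sum_dockq", "sum_z"), names(x))]
}

#' @method glance capri_ranking
#' @export
glance.capri_ranking <- function(x, ...) {
  tibble(
    n_groups = nrow(x),
    n_aus = attr(x, "n_aus"),
    top_n = attr(x, "top_n"),
    best_group = x$group_id[which.max(x$score_g)],
    max_score_g = max(x$score_g),
    max_sum_dockq = max(x$sum_dockq))
}

#' Write the ranking report files
#'
#' One ranked TSV per role (`ranking_<role>.tsv`), a per-AU best-category
#' matrix (`au_matrix.tsv`), and a per-AU DockQ summary
#' (`per_target_summary.tsv`).
#'
#' @param ranking a `capri_ranking`.
#' @param dir output directory (created if missing).
#' @return Invisibly, the written file paths.
#' @export
render_reports <- function(ranking, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  best <- attr(ranking, "per_au_best")
  td <- tidy(ranking)
  roles <- if ("role" %in% names(td)) unique(td$role) else "predictor"
  paths <- character(0)
  for (r in roles) {
    sub <- if ("role" %in% names(td)) td[td$role == r, ] else td
    p <- file.path(dir, paste0("ranking_", r, ".tsv"))
    utils::write.table(sub, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  mat <- best |>
    mutate(category = as.character(.data$category)) |>
    select("group_id", "au_id", "category") |>
    tidyr::pivot_wider(names_from = "au_id", values_from = "category",
                       values_fill = "Incorrect") |>
    arrange(.data$group_id)
  p <- file.path(dir, "au_matrix.tsv")
  utils::write.table(mat, p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, p)
  summ <- best |>
    group_by(.data$au_id) |>
    summarise(n_groups = dplyr::n(),
              best_dockq = max(.data$dockq),
              median_dockq = stats::median(.data$dockq),
              n_correct = sum(as.character(.data$category) != "Incorrect"),
              .groups = "drop") |>
    arrange(.data$au_id)
  p <- file.path(dir, "per_target_summary.tsv")
  utils::write.table(summ, p, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(paths, p))
}
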