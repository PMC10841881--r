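TARGET_TABLE_MD5 <- "600cd75a0ed97a552c378b230dd79101"

#' Load the CAPRI Round 54 target metadata
#'
#' The packaged transcription of the Round 54 target table: 37 targets with
#' CAPRI/CASP ids, category (I-V), kingdom, sequence length and buried
#' surface area (inert, paper-sourced metadata; never computed here),
#' topology and assessment-unit ids. Sizes and BSA are kept as printed
#' strings because several rows list ranges or per-chain values.
#'
#' @param path override the packaged TSV (checksum then not verified).
#' @return Tibble with one row per target.
#' @export
load_target_table <- function(path = NULL) {
  packaged <- is.null(path)
  path <- path %||% system.file("extdata", "targets_round54.tsv",
                                package = "capriq")
  if (!file.exists(path)) abort("target table fixture not found")
  if (packaged) {
    sum <- unname(tools::md5sum(path))
    if (!identical(sum, TARGET_TABLE_MD5)) {
      abort("target table fixture is corrupted (checksum mismatch)")
    }
  }
  tb <- utils::read.delim(path, sep = "\t", colClasses = "character") |>
    as_tibble()
  stopifnot(!anyDuplicated(tb$capri_id), all(tb$category %in% c("I", "II", "III", "IV", "V")))
  tb
}

#' Paths of the packaged assessment-unit configurations
#' @return Named character vector of YAML file paths.
#' @export
packaged_au_configs <- function() {
  nm <- c(T203 = "au_t203.yaml", T204 = "au_t204.yaml",
          T219_221 = "au_t219_221.yaml")
  vapply(nm, function(f) system.file("extdata", f, package = "capriq"),
         character(1))
}

#' Load and validate an assessment-unit configuration
#'
#' @param path YAML file with a top-level `au_configs` list; each AU has
#'   `au_id`, `targets`, and `interface_groups` (each group a list of member
#'   interfaces).
#' @return List of AU definitions; each gains `K` (number of groups) and
#'   `n_members` (total member interfaces).
#' @export
load_au_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$au_configs)) abort("AU config lacks an 'au_configs' key")
  lapply(y$au_configs, function(au) {
    stopifnot(!is.null(au$au_id), length(au$interface_groups) >= 1)
    ids <- unlist(lapply(au$interface_groups, function(g)
      vapply(g$members, function(m) paste(m$target, m$interface), character(1))))
    if (anyDuplicated(ids)) abort("AU interface groups are not disjoint")
    au$K <- length(au$interface_groups)
    au$n_members <- length(ids)
    au
  })
}

#' Assessment-unit accounting for the Round 54 target set
#'
#' Expands the per-target AU ids into the distinct assessment units,
#' attaching K and member counts from the packaged AU configurations where
#' a target is split or merged.
#'
#' @param targets output of [load_target_table()].
#' @return Tibble: `au_id`, `targets` (list column), `K`, `n_members`.
#' @export
au_table <- function(targets = load_target_table()) {
  long <- targets |>
    mutate(au_id = strsplit(.data$au_ids, ";")) |>
    tidyr::unnest("au_id")
  cfg <- unlist(lapply(packaged_au_configs(), load_au_config),
                recursive = FALSE)
  cfg_ids <- vapply(cfg, function(a) a$au_id, character(1))
  long |>
    group_by(.data$au_id) |>
    summarise(targets = list(.data$capri_id), .groups = "drop") |>
    mutate(
      K = unname(vapply(.data$au_id, function(a) {
        i <- match(a, cfg_ids)
        if (is.na(i)) 1L else as.integer(cfg[[i]]$K)
      }, integer(1))),
      n_members = unname(vapply(.data$au_id, function(a) {
        i <- match(a, cfg_ids)
        if (is.na(i)) 1L else as.integer(cfg[[i]]$n_members)
      }, integer(1)))) |>
    arrange(.data$au_id)
}

#' Round 54 submission protocol constants
#'
#' Predictors upload up to 100 models but only the 5 top-ranking ones are
#' evaluated; 15 scorer groups each submit 5 models per target.
#' @return Named list.
#' @export
round54_protocol <- function() {
  list(n_scorer_groups = 15L,
       models_per_submission = 5L,
       uploader_max_models = 100L)
}
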