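#' Assessment configuration
#'
#' All tunable constants of the assessment in one list, overridable per call
#' or from a YAML file ([read_config()]). Defaults are the CAPRI/DockQ
#' conventions: residue contacts at 5 Angstrom, interface residues at 10,
#' clashes below 3, DockQ scaling d1 = 8.5 (L_rms) and d2 = 1.5 (i_rms),
#' and 0.23 as the DockQ value roughly separating incorrect models.
#'
#' @param ... named overrides of the defaults.
#' @return Named list of class `capriq_config`.
#' @export
capriq_config <- function(...) {
  cfg <- list(
    contact_threshold = 5,
    interface_threshold = 10,
    clash_threshold = 3,
    clash_cap = Inf,
    d1 = 8.5,
    d2 = 1.5,
    incorrect_cutoff = 0.23,
    category_table = capri_category_table(),
    weights = c(Acceptable = 1, Medium = 2, High = 3),
    top_n = 5,
    mapping_budget = 720,
    similarity_tolerance = 0.7,
    min_contacts = 1
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad) > 0) abort(paste("unknown config keys:", paste(bad, collapse = ", ")))
  cfg[names(over)] <- over
  num <- c("contact_threshold", "interface_threshold", "clash_threshold",
           "d1", "d2", "incorrect_cutoff")
  if (any(unlist(cfg[num]) <= 0)) abort("thresholds must be positive")
  structure(cfg, class = c("capriq_config", "list"))
}

#' Read an assessment configuration from YAML
#'
#' Keys under the top-level `quality:` section override [capriq_config()]
#' defaults.
#' @param path YAML file.
#' @return A `capriq_config`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(capriq_config, y$quality %||% list())
}

#' The CAPRI four-category threshold table
#'
#' A model is High when fnat >= 0.5 and (L_rms <= 1.0 or i_rms <= 1.0);
#' Medium when fnat >= 0.3 and (L_rms <= 5.0 or i_rms <= 2.0); Acceptable
#' when fnat >= 0.1 and (L_rms <= 10.0 or i_rms <= 4.0); otherwise
#' Incorrect. Thresholds are inclusive. The table is exposed so alternative
#' criteria can be tested.
#'
#' @return Tibble `category`, `fnat_min`, `lrms_max`, `irms_max`, best first.
#' @export
capri_category_table <- function() {
  tibble(
    category = c("High", "Medium", "Acceptable"),
    fnat_min = c(0.5, 0.3, 0.1),
    lrms_max = c(1.0, 5.0, 10.0),
    irms_max = c(1.0, 2.0, 4.0))
}

CATEGORY_LEVELS <- c("Incorrect", "Acceptable", "Medium", "High")

#' Scaled RMS deviation term of DockQ
#'
#' `1 / (1 + (rms / d)^2)`: 1 at rms 0, 0.5 at rms = d.
#' @param rms RMSD in Angstrom (>= 0).
#' @param d scaling factor in Angstrom (> 0).
#' @return Score in (0, 1].
#' @export
rms_scaled <- function(rms, d) {
  if (any(rms < 0, na.rm = TRUE) || any(d <= 0)) {
    abort("rms must be >= 0 and d > 0")
  }
  1 / (1 + (rms / d)^2)
}

#' DockQ score
#'
#' The mean of fnat and the scaled L_rms and i_rms terms:
#' `(fnat + rms_scaled(lrms, d1) + rms_scaled(irms, d2)) / 3`.
#'
#' @param fnat fraction of native contacts in \[0, 1\].
#' @param lrms,irms RMSDs in Angstrom.
#' @param d1,d2 scaling factors (defaults 8.5 and 1.5 Angstrom).
#' @return DockQ in (0, 1]; vectorized.
#' @export
dockq <- function(fnat, lrms, irms, d1 = 8.5, d2 = 1.5) {
  if (any(fnat < 0 | fnat > 1, na.rm = TRUE)) abort("fnat must be in [0, 1]")
  (fnat + rms_scaled(lrms, d1) + rms_scaled(irms, d2)) / 3
}

#' CAPRI four-category classification
#'
#' @param fnat,lrms,irms the metric values (vectorized). `NA` metrics (a
#'   non-assessable interface) classify as Incorrect.
#' @param disqualified logical; disqualified models (clash rule) are forced
#'   Incorrect.
#' @param table threshold table, see [capri_category_table()].
#' @return Factor with levels Incorrect < Acceptable < Medium < High.
#' @export
classify <- function(fnat, lrms, irms, disqualified = FALSE,
                     table = capri_category_table()) {
  n <- max(length(fnat), length(lrms), length(irms))
  fnat <- rep_len(fnat, n); lrms <- rep_len(lrms, n); irms <- rep_len(irms, n)
  disqualified <- rep_len(disqualified, n)
  out <- rep("Incorrect", n)
  for (i in rev(seq_len(nrow(table)))) {  # Acceptable first, High overwrites
    hit <- !is.na(fnat) & fnat >= table$fnat_min[i] &
      ((!is.na(lrms) & lrms <= table$lrms_max[i]) |
         (!is.na(irms) & irms <= table$irms_max[i]))
    out[hit] <- table$category[i]
  }
  out[disqualified] <- "Incorrect"
  factor(out, levels = CATEGORY_LEVELS, ordered = TRUE)
}

#' Flag category/DockQ discordance
#'
#' There is no strict correspondence between the discrete CAPRI category and
#' DockQ; this diagnostic flags models whose category and the DockQ
#' incorrect cutoff (0.23) disagree. It never alters labels.
#'
#' @param category factor/character of CAPRI categories.
#' @param dockq numeric DockQ values.
#' @param incorrect_cutoff DockQ value below which a model is nominally
#'   incorrect (default 0.23).
#' @return Tibble `category`, `dockq`, `discordant`.
#' @export
dockq_consistency <- function(category, dockq, incorrect_cutoff = 0.23) {
  correct <- as.character(category) != "Incorrect"
  tibble(category = as.character(category), dockq = dockq,
         discordant = correct != (dockq >= incorrect_cutoff))
}

#' Append category and DockQ columns to a metrics table
#'
#' @param metrics tibble with `fnat`, `lrms`, `irms`, `clashes` columns
#'   (as from [interface_metrics()]).
#' @param config a [capriq_config()].
#' @param batch logical: apply the batch-relative clash disqualification
#'   over all rows (else the absolute cap).
#' @return `metrics` with `disqualified`, `category`, `dockq` appended.
#' @export
append_quality <- function(metrics, config = capriq_config(), batch = FALSE) {
  clashes <- ifelse(is.na(metrics$clashes), 0L, metrics$clashes)
  dq <- if (batch) disqualify_clashes(clashes)
        else clashes > config$clash_cap
  metrics |>
    mutate(
      disqualified = dq,
      category = classify(.data$fnat, .data$lrms, .data$irms, dq,
                          table = config$category_table),
      dockq = ifelse(is.na(.data$fnat), 0,
                     dockq(.data$fnat, .data$lrms, .data$irms,
                           config$d1, config$d2)))
}
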