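#' Residue correspondence between a model and its target
#'
#' Residues of mapped chain pairs are paired by global sequence alignment
#' (Biostrings, BLOSUM62), never by author numbering, so renumbered models
#' map correctly. Only aligned positions with identical residues enter the
#' common set: model and target share the construct sequence, so a
#' substitution indicates a mis-mapping, not a mutation to tolerate.
#'
#' @param model,target `assembly` objects.
#' @param chain_map named character vector, model chain -> target chain.
#'   Default: identity when both structures use the same chain ids, else
#'   in-order matching within sequence-equivalence classes.
#' @param min_identity minimal fraction of identical aligned residues per
#'   chain pair before the mapping is declared wrong (default 0.3).
#' @return Tibble of class `residue_correspondence` with columns
#'   `model_chain`, `model_key`, `target_chain`, `target_key`, `resid`;
#'   attributes `chain_map` and `per_chain_identity`.
#' @export
build_correspondence <- function(model, target, chain_map = NULL,
                                 min_identity = 0.3) {
  if (is.null(chain_map)) chain_map <- default_chain_map(model, target)
  mt <- residue_table(model)
  tt <- residue_table(target)
  rows <- list()
  ident <- numeric(0)
  for (mc in names(chain_map)) {
    tc <- chain_map[[mc]]
    mres <- mt[mt$chain == mc, , drop = FALSE]
    tres <- tt[tt$chain == tc, , drop = FALSE]
    al <- align_residues(
      dplyr::coalesce(AA3TO1[mres$resid], "X"),
      dplyr::coalesce(AA3TO1[tres$resid], "X"))
    ident[mc] <- al$identity
    if (al$identity < min_identity) {
      abort(sprintf(
        "chains %s (model) and %s (target) align at %.0f%% identity; wrong chain_map?",
        mc, tc, 100 * al$identity))
    }
    if (length(al$i) > 0) {
      rows[[mc]] <- tibble(
        model_chain = mc,
        model_key = mres$key[al$i],
        target_chain = tc,
        target_key = tres$key[al$j],
        resid = tres$resid[al$j])
    }
  }
  out <- bind_rows(rows)
  structure(out,
            class = c("residue_correspondence", class(out)),
            chain_map = chain_map,
            per_chain_identity = ident)
}

# global alignment of two one-letter residue vectors; returns indices of
# aligned *identical* positions and the identity over aligned columns
align_residues <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) {
    return(list(i = integer(0), j = integer(0), identity = 0))
  }
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(paste(a, collapse = "")),
    Biostrings::AAString(paste(b, collapse = "")),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5)
  p <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  ip <- cumsum(p != "-")
  is <- cumsum(s != "-")
  both <- p != "-" & s != "-"
  same <- both & p == s
  identity <- if (any(both)) sum(same) / sum(both) else 0
  list(i = ip[same], j = is[same], identity = identity)
}

default_chain_map <- function(model, target) {
  mids <- chain_ids(model); tids <- chain_ids(target)
  if (length(mids) != length(tids)) {
    abort(sprintf("model has %d chains, target %d; supply chain_map",
                  length(mids), length(tids)))
  }
  if (setequal(mids, tids)) {
    stats::setNames(tids[match(mids, tids)], mids)
  } else {
    stats::setNames(tids, mids)
  }
}

#' Intersect the common residue sets of several models
#'
#' In batch mode every model is measured over the residues present in all of
#' them; this returns that intersection, expressed on the first model's
#' correspondence. Apply it to the others with [restrict_correspondence()].
#'
#' @param corrs list of `residue_correspondence` objects for the same target.
#' @return The first correspondence restricted to target residues present in
#'   every correspondence.
#' @export
common_residue_set <- function(corrs) {
  if (inherits(corrs, "residue_correspondence")) corrs <- list(corrs)
  stopifnot(length(corrs) >= 1)
  keys <- Reduce(intersect, lapply(corrs, function(cc) cc$target_key))
  if (length(keys) == 0) {
    abort("no residue is shared by all models; consider per-model evaluation")
  }
  restrict_correspondence(corrs[[1]], keys)
}

#' Restrict a correspondence to a set of target residues
#' @param corr a `residue_correspondence`.
#' @param target_keys target residue keys to keep.
#' @return The filtered correspondence (attributes preserved).
#' @export
restrict_correspondence <- function(corr, target_keys) {
  out <- corr[corr$target_key %in% target_keys, , drop = FALSE]
  attributes(out)[c("chain_map", "per_chain_identity")] <-
    attributes(corr)[c("chain_map", "per_chain_identity")]
  out
}
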