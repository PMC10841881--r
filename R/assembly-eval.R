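#' Enumerate the interfaces of a target assembly
#'
#' One [native_contacts()] definition per chain pair with at least
#' `min_contacts` residue contacts, in deterministic (sorted chain pair)
#' order.
#'
#' @param target an `assembly` with >= 2 chains.
#' @param min_contacts minimal native-contact count (default 1).
#' @param contact_threshold,interface_threshold Angstrom.
#' @return Named list of `interface_def` objects.
#' @export
enumerate_interfaces <- function(target, min_contacts = 1,
                                 contact_threshold = 5,
                                 interface_threshold = 10) {
  ids <- sort(chain_ids(target))
  if (length(ids) < 2) abort("target has fewer than 2 chains")
  pairs <- utils::combn(ids, 2, simplify = FALSE)
  ifaces <- list()
  for (p in pairs) {
    nc <- native_contacts(target, p[1], p[2], contact_threshold,
                          interface_threshold)
    if (nrow(nc$native_contacts) >= min_contacts) ifaces[[nc$id]] <- nc
  }
  if (length(ifaces) == 0) abort("target has no interface to assess")
  ifaces
}

# relabeling-invariant contact fingerprint: residue ordinals within chains
iface_fingerprint <- function(iface, target) {
  rt <- residue_table(target)
  ord <- function(keys, chain) {
    keys_chain <- rt$key[rt$chain == chain]
    match(keys, keys_chain)
  }
  nc <- iface$native_contacts
  list(
    fp = paste(ord(nc$rec_key, iface$receptor_chain),
               ord(nc$lig_key, iface$ligand_chain), sep = "-"),
    rec_seq = chain_sequence(target, iface$receptor_chain),
    lig_seq = chain_sequence(target, iface$ligand_chain))
}

jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}

#' Group structurally similar interfaces of a target
#'
#' Interfaces whose residue-level contact fingerprints match under chain
#' relabeling (Jaccard similarity >= `tolerance`, single linkage) fall into
#' one group; symmetric copies of an interface in a homo-oligomer thus count
#' once. Explicit configuration (an AU config file) overrides this automatic
#' grouping.
#'
#' @param ifaces list from [enumerate_interfaces()].
#' @param target the target `assembly`.
#' @param tolerance Jaccard threshold (default 0.7).
#' @param au_id identifier for the resulting assessment unit.
#' @return List of class `au_def`: `au_id`, `groups` (list of interface-id
#'   character vectors), `K` (number of groups).
#' @export
group_similar_interfaces <- function(ifaces, target, tolerance = 0.7,
                                     au_id = "AU1") {
  n <- length(ifaces)
  fps <- lapply(ifaces, iface_fingerprint, target = target)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      a <- fps[[i]]; b <- fps[[j]]
      sim <- 0
      if (a$rec_seq == b$rec_seq && a$lig_seq == b$lig_seq) {
        sim <- max(sim, jaccard(a$fp, b$fp))
      }
      if (a$rec_seq == b$lig_seq && a$lig_seq == b$rec_seq) {
        swapped <- sub("^([0-9]+)-([0-9]+)$", "\\2-\\1", b$fp)
        sim <- max(sim, jaccard(a$fp, swapped))
      }
      if (sim >= tolerance) parent[find(j)] <- find(i)
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  groups <- split(names(ifaces), root)
  groups <- groups[order(vapply(groups, function(g) min(match(g, names(ifaces))), 1L))]
  names(groups) <- paste0("G", seq_along(groups))
  structure(list(au_id = au_id, groups = groups, K = length(groups)),
            class = "au_def")
}

permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations(n - 1)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

# match model chain classes to target chain classes by alignment identity
match_classes <- function(model, target) {
  mst <- stoichiometry(model); tst <- stoichiometry(target)
  if (nrow(mst) != nrow(tst) || !all(sort(mst$n) == sort(tst$n))) {
    abort(sprintf(
      "incompatible stoichiometry: model %s vs target %s",
      attr(mst, "formula"), attr(tst, "formula")))
  }
  used <- rep(FALSE, nrow(tst))
  out <- list()
  for (i in seq_len(nrow(mst))) {
    mseq <- chain_sequence(model, mst$chains[[i]][1])
    best <- 0; best_j <- NA
    for (j in seq_len(nrow(tst))) {
      if (used[j] || tst$n[j] != mst$n[i]) next
      tseq <- chain_sequence(target, tst$chains[[j]][1])
      idt <- align_residues(strsplit(mseq, "")[[1]], strsplit(tseq, "")[[1]])$identity
      if (idt > best) { best <- idt; best_j <- j }
    }
    if (is.na(best_j) || best < 0.3) {
      abort("incompatible stoichiometry: no matching chain class for model class")
    }
    used[best_j] <- TRUE
    out[[i]] <- list(model_chains = mst$chains[[i]],
                     target_chains = tst$chains[[best_j]])
  }
  out
}

#' Best stoichiometry-respecting chain mapping of a model onto a target
#'
#' All admissible assignments (permutations within sequence-equivalence
#' classes) are enumerated exhaustively up to `budget` mappings, then a
#' hill-climbing search over within-class swaps takes over. The mapping
#' maximizing summed per-interface quality is selected: CAPRI category
#' weights first, total DockQ as tie-break; remaining ties fall to the first
#' mapping in enumeration order (deterministic).
#'
#' @param model,target `assembly` objects with compatible stoichiometry.
#' @param ifaces target interfaces (default: [enumerate_interfaces()]).
#' @param config a [capriq_config()].
#' @return List: `chain_map` (model -> target), `metrics` (per-interface
#'   tibble with quality columns), `score` (the selection score).
#' @export
best_chain_mapping <- function(model, target, ifaces = NULL,
                               config = capriq_config()) {
  if (is.null(ifaces)) {
    ifaces <- enumerate_interfaces(target, config$min_contacts,
                                   config$contact_threshold,
                                   config$interface_threshold)
  }
  classes <- match_classes(model, target)
  perms <- lapply(classes, function(cl) permutations(length(cl$model_chains)))
  counts <- vapply(perms, nrow, 1L)
  total <- prod(counts)

  eval_map <- function(chain_map) {
    corr <- build_correspondence(model, target, chain_map)
    met <- bind_rows(lapply(ifaces, function(ifc)
      interface_metrics(model, target, corr, ifc, config$clash_threshold)))
    met <- append_quality(met, config)
    w <- config$weights
    cat_score <- sum(ifelse(met$category == "Incorrect", 0,
                            w[as.character(met$category)]), na.rm = TRUE)
    list(metrics = met, cat = cat_score, dq = sum(met$dockq, na.rm = TRUE))
  }
  map_from <- function(idx) {
    cm <- character(0)
    for (k in seq_along(classes)) {
      cl <- classes[[k]]
      cm[cl$model_chains] <- cl$target_chains[perms[[k]][idx[k], ]]
    }
    cm
  }

  best <- NULL; best_map <- NULL
  if (total <= config$mapping_budget) {
    grid <- expand.grid(lapply(counts, seq_len))
    for (r in seq_len(nrow(grid))) {
      cm <- map_from(as.integer(grid[r, ]))
      ev <- eval_map(cm)
      if (is.null(best) || ev$cat > best$cat ||
          (ev$cat == best$cat && ev$dq > best$dq + 1e-12)) {
        best <- ev; best_map <- cm
      }
    }
  } else {
    # greedy: start from in-order assignment, hill-climb within-class swaps
    cm <- map_from(rep(1L, length(classes)))
    best <- eval_map(cm); best_map <- cm
    improved <- TRUE
    while (improved) {
      improved <- FALSE
      for (cl in classes) {
        mc <- cl$model_chains
        if (length(mc) < 2) next
        for (a in seq_along(mc)) for (b in seq_along(mc)) {
          if (b <= a) next
          cand <- best_map
          cand[c(mc[a], mc[b])] <- cand[c(mc[b], mc[a])]
          ev <- eval_map(cand)
          if (ev$cat > best$cat ||
              (ev$cat == best$cat && ev$dq > best$dq + 1e-9)) {
            best <- ev; best_map <- cand; improved <- TRUE
          }
        }
      }
    }
  }
  list(chain_map = best_map, metrics = best$metrics,
       score = c(category = best$cat, dockq = best$dq))
}

#' Assess one model against its target
#'
#' Enumerates target interfaces, finds the best chain mapping, and returns
#' per-interface metrics with CAPRI category and DockQ appended.
#'
#' @inheritParams best_chain_mapping
#' @param target_id,group,model_rank identifiers copied into the output.
#' @return Tibble (one row per interface) with attribute `chain_map`.
#' @export
evaluate_assembly <- function(model, target, config = capriq_config(),
                              target_id = "T1", group = "G1", model_rank = 1L) {
  bm <- best_chain_mapping(model, target, config = config)
  out <- bm$metrics |>
    mutate(target_id = target_id, group = group, model_rank = model_rank,
           .before = 1)
  attr(out, "chain_map") <- bm$chain_map
  out
}

#' Assessment-unit score (weighted category counts)
#'
#' Each distinct interface group is counted once, in the best category
#' achieved for it: `score_au = w1*n_acc + w2*n_med + w3*n_high` with
#' default weights (1, 2, 3), and `score_au_norm = score_au / K`.
#'
#' @param per_group_best character/factor vector: best CAPRI category per
#'   interface group (length K).
#' @param weights named weights for Acceptable/Medium/High.
#' @return One-row tibble: `K`, `n_acc`, `n_med`, `n_high`, `score_au`,
#'   `score_au_norm`.
#' @export
score_au <- function(per_group_best,
                     weights = c(Acceptable = 1, Medium = 2, High = 3)) {
  cat <- as.character(per_group_best)
  stopifnot(all(cat %in% CATEGORY_LEVELS))
  K <- length(cat)
  n_acc <- sum(cat == "Acceptable")
  n_med <- sum(cat == "Medium")
  n_high <- sum(cat == "High")
  s <- weights[["Acceptable"]] * n_acc + weights[["Medium"]] * n_med +
    weights[["High"]] * n_high
  tibble(K = K, n_acc = n_acc, n_med = n_med, n_high = n_high,
         score_au = s, score_au_norm = s / K)
}

#' Assessment-unit DockQ
#'
#' The mean over distinct interface groups of the best DockQ achieved per
#' group; symmetric replicas within a group contribute through their best
#' score only.
#'
#' @param per_group_best numeric vector of per-group best DockQ, or a list
#'   of numeric vectors (replica scores; the max of each is taken).
#' @return The AU-level DockQ in \[0, 1\].
#' @export
dockq_au <- function(per_group_best) {
  if (is.list(per_group_best)) {
    per_group_best <- vapply(per_group_best, max, numeric(1))
  }
  mean(per_group_best)
}
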