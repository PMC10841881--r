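#' @name synthetic
#' @title Synthetic complexes and decoys
#'
#' @description
#' Fully self-contained fixture generation: parametric toy complexes built
#' from ideal alpha-helices (rise 1.5 Angstrom, twist 100 degrees per
#' residue) with varied side chains, graded decoys with analytically or
#' oracle-known metrics, and random submission manifests. Geometry is ideal
#' rather than taken from real structures so that no downloads are needed
#' and the metrics have closed-form handles (a pure ligand translation t
#' gives L_rms = |t| exactly).
NULL

SIDECHAIN_TEMPLATES <- list(
  ALA = list(CB = c(3.6, 0.00, 0.2)),
  VAL = list(CB = c(3.6, 0.00, 0.2), CG1 = c(4.8, 0.18, 0.1),
             CG2 = c(4.8, -0.18, 0.5)),
  LEU = list(CB = c(3.6, 0.00, 0.2), CG = c(4.9, 0.00, 0.3),
             CD1 = c(6.0, 0.15, 0.0), CD2 = c(6.0, -0.15, 0.6)),
  SER = list(CB = c(3.6, 0.00, 0.2), OG = c(4.7, 0.00, 0.3)),
  THR = list(CB = c(3.6, 0.00, 0.2), OG1 = c(4.7, 0.15, 0.2),
             CG2 = c(4.8, -0.15, 0.4)),
  GLY = list()
)

# one ideal-helix chain along z, centered on the z axis. Sequences come
# from two fixed aperiodic banks of five residue types: a periodic sequence
# would make residue alignments ambiguous under truncation or relabeling,
# and the two banks keep hetero partners clearly distinguishable.
SEQ_BANKS <- c(
  "VTTSSTVAVSALTLLALATLATVVVLASLAVTVVATTTLLATSTTVLTALLSTTTVAATATSAS",
  "TVSVVLTSTVVTVTLASVLVLLALTVALALLLSSAVAVSALVALSSVATSTTSVSVTTSTAVLL")

helix_sequence <- function(n, bank = 1) {
  lut <- c(A = "ALA", V = "VAL", S = "SER", L = "LEU", T = "THR")
  letters1 <- strsplit(SEQ_BANKS[bank], "")[[1]]
  if (n > length(letters1)) {
    letters1 <- rep_len(letters1, n)   # chains longer than the bank repeat
  }
  unname(lut[letters1[seq_len(n)]])
}

build_helix_chain <- function(n, chain_id, bank = 1,
                              rise = 1.5, twist = 100) {
  seqs <- helix_sequence(n, bank)
  rows <- list()
  for (i in seq_len(n)) {
    th <- (i - 1) * twist * pi / 180
    z <- (i - 1) * rise
    resid <- seqs[i]
    pol <- function(r, dth, dz) c(r * cos(th + dth), r * sin(th + dth), z + dz)
    at <- list(N = pol(1.5, -0.5, -0.95), CA = pol(2.3, 0, 0),
               C = pol(2.0, 0.45, 0.6), O = pol(2.1, 0.55, 1.75))
    for (nm in names(SIDECHAIN_TEMPLATES[[resid]])) {
      p <- SIDECHAIN_TEMPLATES[[resid]][[nm]]
      at[[nm]] <- pol(p[1], p[2], p[3])
    }
    rows[[i]] <- tibble(
      chain = chain_id, resno = i, ins = "", resid = resid,
      elety = names(at),
      x = vapply(at, `[`, 1, 1), y = vapply(at, `[`, 1, 2),
      z = vapply(at, `[`, 1, 3))
  }
  bind_rows(rows)
}

rot_z <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3)

#' Rotation matrix from axis and angle
#' @param axis length-3 axis (normalized internally).
#' @param angle_deg angle in degrees.
#' @return 3x3 proper rotation matrix.
#' @export
rot_axis_angle <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  a <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3)
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

min_interchain_dist <- function(s, ca, cb) {
  min(oracle_cross_dist(coords(chain_atoms(s, ca)),
                        coords(chain_atoms(s, cb))))
}

#' Specification of a toy complex
#'
#' @param n_chains number of chains (2-6).
#' @param chain_length residues per chain (scalar, or length-2 for a hetero
#'   dimer).
#' @param symmetry "C2", "C3", "C6" or "none" (hetero dimer); default picked
#'   from `n_chains`.
#' @param hetero logical: two chains with different sequences (dimer only).
#' @param seed integer; carried along for downstream decoy generation (toy
#'   geometry itself is deterministic).
#' @return List of class `toy_spec`.
#' @export
toy_complex_spec <- function(n_chains = 2, chain_length = 20, symmetry = NULL,
                             hetero = FALSE, seed = 1) {
  if (hetero && n_chains != 2) abort("hetero toys are dimers")
  symmetry <- symmetry %||%
    if (hetero) "none" else paste0("C", n_chains)
  stopifnot(n_chains >= 2, n_chains <= 6, all(chain_length >= 8))
  structure(list(n_chains = n_chains, chain_length = chain_length,
                 symmetry = symmetry, hetero = hetero, seed = seed,
                 rise = 1.5, twist = 100),
            class = "toy_spec")
}

#' Build a toy complex from its specification
#'
#' Chains are ideal helices placed side by side (C2 / hetero dimer) or on a
#' ring (C3/C6) at the smallest separation that leaves no reference clash
#' (minimal inter-chain distance >= 3.2 Angstrom) while keeping at least 10
#' native contacts at 5 Angstrom between neighboring chains. Deterministic:
#' the same spec always yields identical coordinates.
#'
#' @param spec a [toy_complex_spec()].
#' @return An `assembly`.
#' @export
make_toy_complex <- function(spec) {
  stopifnot(inherits(spec, "toy_spec"))
  n <- spec$n_chains
  len <- rep_len(spec$chain_length, n)
  ids <- LETTERS[seq_len(n)]
  a <- build_helix_chain(len[1], ids[1])
  b0 <- if (n == 2) {
    build_helix_chain(len[2], ids[2], bank = if (spec$hetero) 2 else 1)
  } else {
    mutate(a, chain = ids[2])
  }
  axyz <- as.matrix(a[, c("x", "y", "z")])
  resno_a <- a$resno; resno_b <- b0$resno

  # Smallest clash-free neighbor separation with a rich interface. The
  # relative helix phase (and axial shift for dimers, axis tilt for rings)
  # is searched because the contact surface of an ideal helix is bumpy.
  # All work on raw matrices; results are cached (generation is
  # deterministic, so the cache never changes an outcome).
  ck <- paste(n, paste(len, collapse = ","), spec$symmetry, spec$hetero)
  if (!is.null(.toy_cache[[ck]])) {
    s <- .toy_cache[[ck]]
    attr(s, "toy_spec") <- spec
    return(s)
  }
  rot_x <- function(a) matrix(c(1, 0, 0, 0, cos(a), sin(a),
                                0, -sin(a), cos(a)), 3)
  bxyz0 <- as.matrix(b0[, c("x", "y", "z")])
  cen <- colMeans(bxyz0)
  zshifts <- if (n == 2) seq(0, 2.625, by = 0.375) else 0
  tilts <- if (n == 2) 0 else c(0, 15, 20) * pi / 180
  phases <- seq(0, 345, by = 15) * pi / 180
  variants <- list()
  for (tilt in tilts) for (phase in phases) for (zshift in zshifts) {
    v <- sweep(bxyz0, 2, cen) %*% t(rot_z(phase)) %*% t(rot_x(tilt))
    v <- sweep(v, 2, cen, "+")
    v[, 3] <- v[, 3] + zshift
    variants[[length(variants) + 1]] <-
      list(xyz = v, phase = phase, zshift = zshift, tilt = tilt)
  }
  n_contacts <- function(D) {
    hit <- which(D < 5, arr.ind = TRUE)
    nrow(unique(cbind(resno_a[hit[, 1]], resno_b[hit[, 2]])))
  }
  place_ring <- function(v, sep, k) {
    R <- sep / (2 * sin(pi / n))
    w <- cbind(v[, 1] + R, v[, 2], v[, 3])
    w %*% t(rot_z(2 * pi * (k - 1) / n))
  }
  for (sep in seq(8, 25, by = 0.25)) {
    for (v in variants) {
      if (n == 2) {
        # proper 180-degree rotation about the vertical axis at (sep/2, 0)
        bxyz <- cbind(sep - v$xyz[, 1], -v$xyz[, 2], v$xyz[, 3])
        D <- oracle_cross_dist(axyz, bxyz)
        if (min(D) < 3.02 || n_contacts(D) < 10) next
      } else {
        c1 <- place_ring(v$xyz, sep, 1)
        c2 <- place_ring(v$xyz, sep, 2)
        D <- oracle_cross_dist(c1, c2)
        if (min(D) < 3.02 || n_contacts(D) < 10) next
        if (n >= 4 &&
            min(oracle_cross_dist(c1, place_ring(v$xyz, sep, 3))) < 3.02) next
      }
      out <- if (n == 2) {
        b <- b0
        b$x <- bxyz[, 1]; b$y <- bxyz[, 2]; b$z <- bxyz[, 3]
        bind_rows(a, b)
      } else {
        bind_rows(lapply(seq_len(n), function(k) {
          w <- place_ring(v$xyz, sep, k)
          mutate(a, chain = ids[k], x = w[, 1], y = w[, 2], z = w[, 3])
        }))
      }
      s <- as_assembly(out, source_format = "synthetic")
      attr(s, "placement") <- list(sep = sep, phase = v$phase,
                                   zshift = v$zshift, tilt = v$tilt)
      .toy_cache[[ck]] <- s
      attr(s, "toy_spec") <- spec
      return(s)
    }
  }
  abort("toy placement found no clash-free arrangement with >= 10 contacts")
}

.toy_cache <- new.env(parent = emptyenv())

# ---- independent brute-force oracle -------------------------------------

#' All-pairs cross-distance matrix (oracle path)
#'
#' Straight dense computation used as the independent check for the grid
#' neighbor search.
#' @param a,b n x 3 matrices.
#' @return |a| x |b| distance matrix.
#' @export
oracle_cross_dist <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  sqrt(pmax(d2, 0))
}

#' Residue contact pairs by all-pairs enumeration (oracle path)
#' @param s an `assembly`.
#' @param ca,cb chain ids.
#' @param cutoff Angstrom (strict `<`).
#' @return Tibble `key_a`, `key_b` of contacting residue pairs.
#' @export
oracle_residue_contacts <- function(s, ca, cb, cutoff) {
  A <- chain_atoms(s, ca); B <- chain_atoms(s, cb)
  D <- oracle_cross_dist(coords(A), coords(B))
  hit <- which(D < cutoff, arr.ind = TRUE)
  distinct(tibble(key_a = atom_keys(A)[hit[, 1]],
                  key_b = atom_keys(B)[hit[, 2]]))
}

#' Inter-chain clash count by all-pairs enumeration (oracle path)
#' @inheritParams oracle_residue_contacts
#' @export
oracle_clash_count <- function(s, ca, cb, cutoff = 3) {
  A <- chain_atoms(s, ca); B <- chain_atoms(s, cb)
  sum(oracle_cross_dist(coords(A), coords(B)) < cutoff)
}

# matched atoms between decoy and its base by construction (same keys)
oracle_matched <- function(model, base, keys, part) {
  t_at <- base; t_at$key <- atom_keys(base)
  m_at <- model; m_at$key <- atom_keys(model)
  t_at <- t_at[t_at$key %in% keys, , drop = FALSE]
  if (part == "backbone") {
    t_at <- t_at[t_at$elety %in% BACKBONE_ATOMS, , drop = FALSE]
  } else if (part == "sidechain") {
    t_at <- t_at[!(t_at$elety %in% BACKBONE_ATOMS), , drop = FALSE]
  }
  j <- inner_join(as_tibble(t_at)[, c("key", "elety", "x", "y", "z")],
                  as_tibble(m_at)[, c("key", "elety", "x", "y", "z")],
                  by = c("key", "elety"), suffix = c("_t", "_m"))
  list(target = as.matrix(j[, c("x_t", "y_t", "z_t")]),
       model = as.matrix(j[, c("x_m", "y_m", "z_m")]), n = nrow(j))
}

#' Brute-force reference metrics for a decoy of a toy complex
#'
#' Independent route: all-pairs contact enumeration and bio3d least-squares
#' fitting (`fit.xyz`), with residues matched by identifier (decoys never
#' renumber).
#'
#' @param model the decoy `assembly`.
#' @param base the unperturbed complex it was made from.
#' @param rec,lig receptor and ligand chain ids.
#' @param contact_threshold,interface_threshold,clash_threshold Angstrom.
#' @return One-row tibble `fnat`, `lrms`, `irms`, `srms`, `clashes`.
#' @export
oracle_metrics <- function(model, base, rec, lig, contact_threshold = 5,
                           interface_threshold = 10, clash_threshold = 3) {
  native <- oracle_residue_contacts(base, rec, lig, contact_threshold)
  modelc <- oracle_residue_contacts(model, rec, lig, contact_threshold)
  model_keys <- unique(atom_keys(model))
  fn <- mean(paste(native$key_a, native$key_b) %in%
               paste(modelc$key_a, modelc$key_b))
  cl <- oracle_clash_count(model, rec, lig, clash_threshold)

  keyof <- function(s, ch) unique(atom_keys(chain_atoms(s, ch)))
  common_rec <- intersect(keyof(base, rec), keyof(model, rec))
  common_lig <- intersect(keyof(base, lig), keyof(model, lig))
  rb <- oracle_matched(model, base, common_rec, "backbone")
  lb <- oracle_matched(model, base, common_lig, "backbone")
  lr <- NA_real_
  if (rb$n >= 3 && lb$n >= 3) {
    fixed <- as.numeric(t(rbind(rb$target, lb$target)))
    mob <- as.numeric(t(rbind(rb$model, lb$model)))
    inds <- bio3d::atom2xyz(seq_len(rb$n))
    moved <- bio3d::fit.xyz(fixed, mob, fixed.inds = inds, mobile.inds = inds)
    lig_inds <- bio3d::atom2xyz(rb$n + seq_len(lb$n))
    lr <- sqrt(mean((moved[lig_inds] - fixed[lig_inds])^2) * 3)
  }

  D <- oracle_cross_dist(coords(chain_atoms(base, rec)),
                         coords(chain_atoms(base, lig)))
  hit <- which(D < interface_threshold, arr.ind = TRUE)
  ikeys <- unique(c(atom_keys(chain_atoms(base, rec))[hit[, 1]],
                    atom_keys(chain_atoms(base, lig))[hit[, 2]]))
  ikeys <- intersect(ikeys, model_keys)
  ib <- oracle_matched(model, base, ikeys, "backbone")
  is_ <- oracle_matched(model, base, ikeys, "sidechain")
  ir <- NA_real_; sr <- NA_real_
  if (ib$n >= 3) {
    fixed <- as.numeric(t(rbind(ib$target, is_$target)))
    mob <- as.numeric(t(rbind(ib$model, is_$model)))
    bb <- bio3d::atom2xyz(seq_len(ib$n))
    moved <- bio3d::fit.xyz(fixed, mob, fixed.inds = bb, mobile.inds = bb)
    ir <- sqrt(mean((moved[bb] - fixed[bb])^2) * 3)
    if (is_$n >= 1) {
      sc <- bio3d::atom2xyz(ib$n + seq_len(is_$n))
      sr <- sqrt(mean((moved[sc] - fixed[sc])^2) * 3)
    }
  }
  tibble(fnat = fn, lrms = lr, irms = ir, srms = sr, clashes = cl)
}

# ---- decoys --------------------------------------------------------------

#' Generate a decoy by perturbing one subunit
#'
#' The ligand chain is rotated about its centroid and translated; side-chain
#' atoms (all chains) are optionally jittered (Gaussian, per coordinate);
#' the ligand is optionally truncated at the C-terminus. Expected metrics accompany the structure:
#' for a pure rigid translation (no rotation) the expected `lrms` is exactly
#' `|translation|`; all other values come from the module's brute-force
#' oracle ([oracle_metrics()]).
#'
#' @param base an `assembly` (typically a [make_toy_complex()] output).
#' @param translation length-3 vector, Angstrom.
#' @param rotation_angle degrees about `rotation_axis` through the ligand
#'   centroid.
#' @param rotation_axis length-3 vector.
#' @param sidechain_sigma Gaussian sigma (Angstrom, per coordinate) added to
#'   every side-chain heavy atom; backbones stay exact, so `lrms` keeps its
#'   analytic value and `srms` approaches `sigma * sqrt(3)` for large atom
#'   counts.
#' @param truncate number of C-terminal ligand residues to delete.
#' @param ligand_chain defaults to the last chain.
#' @param seed RNG seed for the side-chain jitter.
#' @return List: `structure` (the decoy), `expected` (one-row metrics
#'   tibble), `receptor`, `ligand`.
#' @export
make_decoy <- function(base, translation = c(0, 0, 0), rotation_angle = 0,
                       rotation_axis = c(0, 0, 1), sidechain_sigma = 0,
                       truncate = 0, ligand_chain = NULL, seed = 1) {
  ids <- chain_ids(base)
  lig <- ligand_chain %||% ids[length(ids)]
  rec <- setdiff(ids, lig)[1]
  s <- base
  if (rotation_angle != 0) {
    cen <- colMeans(coords(chain_atoms(s, lig)))
    s <- transform_assembly(s, rot_axis_angle(rotation_axis, rotation_angle),
                            chains = lig, center = cen)
  }
  s <- transform_assembly(s, translation = translation, chains = lig)
  if (sidechain_sigma > 0) {
    set.seed(seed)
    idx <- !(s$elety %in% BACKBONE_ATOMS)
    nj <- sum(idx)
    s$x[idx] <- s$x[idx] + stats::rnorm(nj, 0, sidechain_sigma)
    s$y[idx] <- s$y[idx] + stats::rnorm(nj, 0, sidechain_sigma)
    s$z[idx] <- s$z[idx] + stats::rnorm(nj, 0, sidechain_sigma)
  }
  if (truncate > 0) {
    keep_res <- residue_table(s) |> filter(.data$chain == lig)
    drop <- utils::tail(keep_res$key, truncate)
    s <- s[!(atom_keys(s) %in% drop), , drop = FALSE]
    s <- as_assembly(s, source_format = "synthetic")
  }
  expected <- oracle_metrics(s, base, rec, lig)
  if (rotation_angle == 0 && truncate >= 0) {
    # receptor untouched, ligand uniformly translated: lrms = |t| exactly
    expected$lrms_analytic <- sqrt(sum(translation^2))
  }
  list(structure = s, expected = expected, receptor = rec, ligand = lig)
}

# independent re-implementation of the category table for truth labels
ladder_classify <- function(fnat, lrms, irms) {
  if (fnat >= 0.5 && (lrms <= 1 || irms <= 1)) return("High")
  if (fnat >= 0.3 && (lrms <= 5 || irms <= 2)) return("Medium")
  if (fnat >= 0.1 && (lrms <= 10 || irms <= 4)) return("Acceptable")
  "Incorrect"
}

near_boundary <- function(x, thresholds, margin = 0.05) {
  any(abs(x - thresholds) < margin * thresholds)
}

#' Generate a ladder of decoys with known quality categories
#'
#' Rejection-samples rigid perturbations of the ligand chain until
#' `n_per_category` decoys of each intended category (High, Medium,
#' Acceptable, Incorrect) are found. Truth labels come from the module's own
#' brute-force oracle and an independent re-implementation of the category
#' table; samples within 5% of any category threshold are rejected so
#' labels are stable under floating-point variation.
#'
#' @param base an `assembly` (dimer recommended).
#' @param n_per_category decoys per category (>= 1).
#' @param seed RNG seed.
#' @param max_attempts per category before giving up.
#' @return List: `decoys` (named list of structures), `truth` (tibble with
#'   `decoy_id`, `intended`, `category`, metrics and oracle DockQ).
#' @export
make_decoy_ladder <- function(base, n_per_category = 2, seed = 1,
                              max_attempts = 1e4) {
  stopifnot(n_per_category >= 1)
  set.seed(seed)
  ranges <- list(
    High = list(t = c(0.15, 0.7), a = c(0, 4)),
    Medium = list(t = c(1.3, 4.3), a = c(0, 12)),
    Acceptable = list(t = c(5.3, 8.6), a = c(0, 20)),
    Incorrect = list(t = c(13, 28), a = c(0, 180)))
  decoys <- list(); rows <- list()
  for (cat in names(ranges)) {
    found <- 0; attempts <- 0
    while (found < n_per_category) {
      attempts <- attempts + 1
      if (attempts > max_attempts) {
        abort(paste("category", cat, "unreachable in", max_attempts, "attempts"))
      }
      u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
      tmag <- stats::runif(1, ranges[[cat]]$t[1], ranges[[cat]]$t[2])
      ang <- stats::runif(1, ranges[[cat]]$a[1], ranges[[cat]]$a[2])
      ax <- stats::rnorm(3)
      d <- make_decoy(base, translation = tmag * u, rotation_angle = ang,
                      rotation_axis = ax)
      m <- d$expected
      if (any(is.na(c(m$fnat, m$lrms, m$irms)))) next
      label <- ladder_classify(m$fnat, m$lrms, m$irms)
      if (label != cat) next
      if (near_boundary(m$fnat, c(0.1, 0.3, 0.5)) ||
          near_boundary(m$lrms, c(1, 5, 10)) ||
          near_boundary(m$irms, c(1, 2, 4))) next
      found <- found + 1
      id <- sprintf("%s_%02d", tolower(cat), found)
      decoys[[id]] <- d$structure
      rows[[id]] <- tibble(
        decoy_id = id, intended = cat, category = label,
        fnat = m$fnat, lrms = m$lrms, irms = m$irms, srms = m$srms,
        clashes = m$clashes,
        dockq = (m$fnat + 1 / (1 + (m$lrms / 8.5)^2) +
                   1 / (1 + (m$irms / 1.5)^2)) / 3,
        translation = tmag, angle = ang)
    }
  }
  list(decoys = decoys, truth = bind_rows(rows))
}

#' Simulate a blind-prediction submission manifest
#'
#' Per group x assessment unit, five ranked models are drawn. Each model's
#' latent quality is `v = skill * (0.7 + 0.3 u)` with `u ~ U(0, 1)`, mapped
#' to a category at v >= 0.7 (High), 0.45 (Medium), 0.2 (Acceptable); DockQ
#' is `v` itself. A skill-1 group therefore submits only High models and a
#' skill-0 group only Incorrect ones.
#'
#' @param n_groups,n_aus counts (>= 1).
#' @param skills per-group skill in \[0, 1\]; default evenly spaced from
#'   0.95 down to 0.2.
#' @param seed RNG seed.
#' @param role role label for all groups.
#' @return Tibble: `group_id`, `role`, `au_id`, `model_rank`, `category`,
#'   `dockq`; attribute `skills`.
#' @export
make_submission_manifest <- function(n_groups = 5, n_aus = 6, skills = NULL,
                                     seed = 1, role = "predictor") {
  stopifnot(n_groups >= 1, n_aus >= 1)
  skills <- skills %||% seq(0.95, 0.2, length.out = n_groups)
  skills <- rep_len(skills, n_groups)
  set.seed(seed)
  grid <- tidyr::expand_grid(
    group_id = sprintf("G%02d", seq_len(n_groups)),
    au_id = sprintf("AU%02d", seq_len(n_aus)),
    model_rank = 1:5)
  v <- skills[match(grid$group_id, sprintf("G%02d", seq_len(n_groups)))] *
    (0.7 + 0.3 * stats::runif(nrow(grid)))
  out <- grid |>
    mutate(role = role, .after = "group_id") |>
    mutate(
      dockq = v,
      category = dplyr::case_when(
        v >= 0.7 ~ "High", v >= 0.45 ~ "Medium",
        v >= 0.2 ~ "Acceptable", TRUE ~ "Incorrect"))
  attr(out, "skills") <- stats::setNames(skills, sprintf("G%02d", seq_len(n_groups)))
  out
}
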