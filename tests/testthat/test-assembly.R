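test_that("interface enumeration matches the chain-pair contact oracle", {
  expect_length(enumerate_interfaces(toy_dimer()), 1)
  expect_length(enumerate_interfaces(toy_trimer()), 3)

  hexa <- toy_hexamer()
  ifs <- enumerate_interfaces(hexa)
  # oracle: all chain pairs with any residue contact at 5 A
  ids <- chain_ids(hexa)
  pairs <- utils::combn(sort(ids), 2, simplify = FALSE)
  expected <- vapply(pairs, function(p) {
    length(naive_contacts(hexa, p[1], p[2], 5)) > 0
  }, logical(1))
  expect_equal(length(ifs), sum(expected))
  expect_length(ifs, 6)   # ring: neighbors only
  expect_identical(names(ifs), sort(names(ifs)))

  solo <- as_assembly(toy_dimer()[toy_dimer()$chain == "A", ])
  expect_error(enumerate_interfaces(solo), "2 chains")
})

test_that("symmetric interfaces group together, dissimilar ones stay apart", {
  tri <- toy_trimer()
  au <- group_similar_interfaces(enumerate_interfaces(tri), tri)
  expect_equal(au$K, 1)
  expect_length(au$groups[[1]], 3)

  hexa <- toy_hexamer()
  au6 <- group_similar_interfaces(enumerate_interfaces(hexa), hexa)
  expect_equal(au6$K, 1)

  # hetero dimer: single interface, its own group
  het <- make_toy_complex(toy_complex_spec(2, c(20, 16), hetero = TRUE))
  auh <- group_similar_interfaces(enumerate_interfaces(het), het)
  expect_equal(auh$K, 1)

  # a chain with two unrelated partners yields two groups
  a <- het[het$chain == "A", ]
  b <- het[het$chain == "B", ]
  c_chain <- dplyr::mutate(a, chain = "C",
                           x = 2 * mean(range(b$x)) - x)  # mirror-side copy
  tri_het <- as_assembly(dplyr::bind_rows(a, b, c_chain))
  ifs <- enumerate_interfaces(tri_het)
  if (length(ifs) >= 2) {
    aut <- group_similar_interfaces(ifs, tri_het)
    expect_gte(aut$K, 2)
  }
})

test_that("packaged AU configurations reproduce the published groupings", {
  cfgs <- packaged_au_configs()
  t203 <- load_au_config(cfgs[["T203"]])
  expect_equal(vapply(t203, `[[`, character(1), "au_id"),
               c("AU203.1", "AU203.2"))
  expect_equal(vapply(t203, `[[`, integer(1), "K"), c(3L, 1L))

  t204 <- load_au_config(cfgs[["T204"]])
  expect_equal(vapply(t204, `[[`, integer(1), "K"), c(2L, 6L))
  expect_equal(sum(vapply(t204, `[[`, integer(1), "n_members")), 8L)

  ruv <- load_au_config(cfgs[["T219_221"]])
  expect_equal(vapply(ruv, `[[`, character(1), "au_id"),
               c("AU219", "AU220"))
  au219 <- ruv[[1]]
  expect_equal(au219$K, 3L)
  expect_equal(au219$n_members, 9L)
  expect_setequal(au219$targets, c("T219", "T220", "T221"))
  expect_equal(ruv[[2]]$n_members, 2L)
})

test_that("chain mapping recovers relabelings of symmetric models", {
  s <- toy_dimer()
  cfg <- capriq_config()
  # homodimer with swapped labels scores identically to the identity labels
  swapped <- s; swapped$chain <- c(A = "B", B = "A")[swapped$chain]
  bm0 <- best_chain_mapping(s, s, config = cfg)
  bm1 <- best_chain_mapping(swapped, s, config = cfg)
  expect_equal(bm1$metrics$fnat, bm0$metrics$fnat)
  expect_equal(bm1$metrics$lrms, bm0$metrics$lrms, tolerance = 1e-9)

  # heterodimer: one admissible mapping only
  het <- make_toy_complex(toy_complex_spec(2, c(20, 16), hetero = TRUE))
  bmh <- best_chain_mapping(het, het, config = cfg)
  expect_identical(bmh$chain_map, c(A = "A", B = "B"))

  # trimer rotated one position in labeling: full recovery, fnat 1 everywhere
  tri <- toy_trimer()
  rot <- tri; rot$chain <- c(A = "B", B = "C", C = "A")[rot$chain]
  bmt <- best_chain_mapping(rot, tri, config = cfg)
  expect_equal(bmt$metrics$fnat, rep(1, 3))
  expect_equal(max(bmt$metrics$irms), 0, tolerance = 1e-6)

  # exhaustive 3! oracle: no permutation beats the selected mapping
  perms <- list(c("A","B","C"), c("A","C","B"), c("B","A","C"),
                c("B","C","A"), c("C","A","B"), c("C","B","A"))
  ifaces <- enumerate_interfaces(tri)
  scores <- vapply(perms, function(p) {
    cm <- stats::setNames(p, c("A", "B", "C"))
    corr <- build_correspondence(rot, tri, cm)
    met <- dplyr::bind_rows(lapply(ifaces, function(ifc)
      interface_metrics(rot, tri, corr, ifc)))
    sum(dockq(met$fnat, met$lrms, met$irms))
  }, numeric(1))
  expect_gte(bmt$score[["dockq"]] + 1e-9, max(scores))

  # incompatible stoichiometry is refused with the class counts
  expect_error(best_chain_mapping(het, tri, config = cfg), "stoichiometry")
})

test_that("metrics are invariant to relabeling within an equivalence class", {
  tri <- toy_trimer()
  perms <- list(c("A","B","C"), c("B","C","A"), c("C","A","B"),
                c("B","A","C"))
  base_metrics <- NULL
  for (p in perms) {
    m <- tri; m$chain <- stats::setNames(p, c("A", "B", "C"))[m$chain]
    bm <- best_chain_mapping(m, tri, config = capriq_config())
    vals <- sort(round(bm$metrics$dockq, 9))
    if (is.null(base_metrics)) base_metrics <- vals
    expect_equal(vals, base_metrics)
  }
})

test_that("AU scoring follows the weighted exclusive count", {
  r <- score_au(c("High", "Medium", "Acceptable"))
  expect_equal(r$score_au, 6)
  expect_equal(r$score_au_norm, 2)
  expect_equal(score_au(rep("Incorrect", 4))$score_au, 0)
  one <- score_au("High")
  expect_equal(one$score_au, 3)
  expect_equal(one$score_au_norm, 3)

  # exhaustive bounds: 0 <= score_au <= 3K over all label assignments, K <= 4
  for (K in 1:4) {
    labs <- c("Incorrect", "Acceptable", "Medium", "High")
    combos <- expand.grid(rep(list(labs), K), stringsAsFactors = FALSE)
    scores <- apply(combos, 1, function(row) score_au(row)$score_au)
    expect_true(all(scores >= 0 & scores <= 3 * K))
    expect_equal(max(scores), 3 * K)
    expect_equal(min(scores), 0)
  }
})

test_that("AU DockQ averages distinct groups and takes best replicas", {
  expect_equal(dockq_au(c(0.8, 0.4)), 0.6)
  expect_equal(dockq_au(list(c(0.2, 0.9))), 0.9)
  expect_equal(dockq_au(0.37), 0.37)
  vals <- c(0.1, 0.5, 0.9)
  expect_lte(dockq_au(vals), max(vals))
  expect_gte(dockq_au(vals), min(vals))
})

test_that("a non-assessable interface degrades to Incorrect, not an error", {
  s <- toy_dimer()
  far <- transform_assembly(s, translation = c(60, 0, 0), chains = "B")
  iface <- native_contacts(s, "A", "B")
  # model with one chain displaced far away: fnat 0, huge rms, Incorrect
  met <- interface_metrics(far, s, build_correspondence(far, s), iface)
  q <- append_quality(met)
  expect_equal(as.character(q$category), "Incorrect")
  expect_true(q$assessable)
})
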