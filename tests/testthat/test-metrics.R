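test_that("native contacts match brute-force enumeration and the 10 A rule", {
  # toy pair with exactly one CB-CB distance at 4.0 A, all others > 6 A
  two <- mini_assembly(tibble::tibble(
    chain = rep(c("A", "B"), each = 4),
    resno = rep(1:2, 2, each = 2),
    resid = "ALA",
    elety = rep(c("CA", "CB"), 4),
    element = "C",
    x = c(0, 0, 0, 0, 10, 4, 10, 12),
    y = c(0, 0, 8, 8, 0, 0, 8, 8),
    z = 0))
  iface <- native_contacts(two, "A", "B")
  expect_equal(nrow(iface$native_contacts), 1)
  expect_true(iface$assessable)

  # chains 50 A apart: nothing to assess
  far <- toy_dimer()
  far <- transform_assembly(far, translation = c(50, 0, 0), chains = "B")
  expect_false(native_contacts(far, "A", "B")$assessable)

  # threshold monotonicity + all-pairs agreement on a real fixture
  s <- toy_dimer()
  i5 <- native_contacts(s, "A", "B", contact_threshold = 5)
  i10 <- native_contacts(s, "A", "B", contact_threshold = 10)
  keys5 <- paste(i5$native_contacts$rec_key, i5$native_contacts$lig_key)
  keys10 <- paste(i10$native_contacts$rec_key, i10$native_contacts$lig_key)
  expect_true(all(keys5 %in% keys10))
  expect_identical(sort(keys5), naive_contacts(s, "A", "B", 5))
  expect_identical(sort(unique(i5$interface_residues)) |> length() > 0, TRUE)
})

test_that("grid neighbor search equals the dense all-pairs oracle", {
  set.seed(42)
  for (rep in 1:5) {
    a <- matrix(stats::runif(90, 0, 20), ncol = 3)
    b <- matrix(stats::runif(120, 0, 20), ncol = 3)
    np <- neighbor_pairs(a, b, 4.5)
    D <- oracle_cross_dist(a, b)
    hit <- which(D < 4.5, arr.ind = TRUE)
    expect_equal(nrow(np), nrow(hit))
    expect_setequal(paste(np$i, np$j), paste(hit[, 1], hit[, 2]))
  }
})

test_that("fnat recalls native contacts with the target denominator", {
  s <- toy_dimer()
  iface <- native_contacts(s, "A", "B")
  corr <- build_correspondence(s, s)
  expect_equal(fnat(s, corr, iface), 1)

  shifted <- transform_assembly(s, translation = c(50, 0, 0), chains = "B")
  expect_equal(fnat(shifted, build_correspondence(shifted, s), iface), 0)

  # residues missing from the model count as missed contacts
  nc <- iface$native_contacts
  gone <- unique(nc$lig_key)[1]
  lost <- sum(nc$lig_key == gone)
  m <- as_assembly(s[paste(s$chain, s$resno, s$ins, sep = "|") != gone, ])
  got <- fnat(m, build_correspondence(m, s), iface)
  expect_lte(got, (nrow(nc) - lost) / nrow(nc))
})

test_that("a constructed toy recalls exactly half of 4 native contacts", {
  # 4 residue pairs in contact at 4 A; the model pushes two of them to 20 A
  mk <- function(xoff) mini_assembly(tibble::tibble(
    chain = rep(c("A", "B"), each = 4),
    resno = rep(1:4, 2),
    resid = "ALA", elety = "CA", element = "C",
    x = c(rep(0, 4), xoff),
    y = rep(seq(0, 30, 10), 2), z = 0))
  target <- mk(rep(4, 4))
  model <- mk(c(4, 4, 20, 20))
  iface <- native_contacts(target, "A", "B")
  expect_equal(nrow(iface$native_contacts), 4)
  expect_equal(fnat(model, build_correspondence(model, target), iface), 0.5)
})

test_that("clash counting matches brute force", {
  s <- toy_dimer()
  expect_equal(clash_count(s, "A", "B"), 0)   # reference is clash-free

  pair <- mini_assembly(tibble::tibble(
    chain = c("A", "B"), resno = 1L, resid = "ALA", elety = "CA",
    element = "C", x = c(0, 2.5), y = 0, z = 0))
  expect_equal(clash_count(pair, "A", "B"), 1)

  overlap <- transform_assembly(s, translation = c(-10, 0, 0), chains = "B")
  expect_equal(clash_count(overlap, "A", "B"),
               naive_clashes(overlap, "A", "B"))
  expect_gt(clash_count(overlap, "A", "B"), 0)
})

test_that("batch clash disqualification flags outliers only", {
  counts <- c(rep(1L, 10), 30L)   # 30 > mean + 2 SD of this batch
  expect_identical(disqualify_clashes(counts), counts > 21.2)
  expect_identical(disqualify_clashes(5), FALSE)        # single model, no cap
  expect_identical(disqualify_clashes(5, cap = 3), TRUE)
})

test_that("superposition is exact on rigid motion and optimal vs a grid", {
  set.seed(1)
  x <- matrix(stats::rnorm(30), ncol = 3)
  expect_equal(superpose(x, x)$rmsd, 0, tolerance = 1e-10)

  R90 <- rot_axis_angle(c(0, 0, 1), 90)
  y <- x %*% t(R90) + matrix(rep(c(3, -2, 7), each = 10), ncol = 3)
  sp <- superpose(y, x)
  expect_lt(sp$rmsd, 1e-8)
  expect_equal(det(sp$rotation), 1, tolerance = 1e-8)
  expect_equal(apply_superposition(y, sp), x, tolerance = 1e-8)

  # optimality: no sampled rotation (plus centroid-matching translation)
  # may beat the closed-form fit
  for (rep in 1:5) {
    a <- matrix(stats::rnorm(30), ncol = 3)
    b <- matrix(stats::rnorm(30), ncol = 3)
    fit <- superpose(a, b)$rmsd
    ac <- sweep(a, 2, colMeans(a)); bc <- sweep(b, 2, colMeans(b))
    grid_best <- min(vapply(1:400, function(i) {
      sqrt(mean(rowSums((ac %*% t(random_rotation()) - bc)^2)))
    }, numeric(1)))
    expect_lte(fit, grid_best + 1e-9)
  }

  expect_error(superpose(x[1:2, ], x[1:2, ]), "3 points")
  line <- cbind(1:5, 0, 0)
  expect_error(superpose(line, line), "degenerate")
})

test_that("lrms is exact for pure translations and explicit for rotations", {
  s <- toy_dimer()
  iface <- native_contacts(s, "A", "B")
  corr <- build_correspondence(s, s)
  expect_equal(lrms(s, s, corr, iface), 0, tolerance = 1e-9)

  t3 <- transform_assembly(s, translation = c(2, -1, 2), chains = "B")
  expect_equal(lrms(t3, s, build_correspondence(t3, s), iface), 3,
               tolerance = 1e-9)

  # rotation about the ligand centroid: value equals the per-atom formula
  bb <- s[s$chain == "B" & s$elety %in% c("N", "CA", "C", "O"), ]
  xyz <- as.matrix(bb[, c("x", "y", "z")])
  cen <- colMeans(as.matrix(s[s$chain == "B", c("x", "y", "z")]))
  R <- rot_axis_angle(c(1, 1, 0), 25)
  expected <- sqrt(mean(rowSums(
    (sweep(xyz, 2, cen) %*% t(R) - sweep(xyz, 2, cen))^2)))
  rotated <- transform_assembly(s, rotation = R, chains = "B", center = cen)
  expect_equal(lrms(rotated, s, build_correspondence(rotated, s), iface),
               expected, tolerance = 1e-9)
})

test_that("irms vanishes under global motion and is bounded by the shift", {
  s <- toy_dimer()
  iface <- native_contacts(s, "A", "B")
  corr <- build_correspondence(s, s)
  expect_equal(irms(s, s, corr, iface), 0, tolerance = 1e-9)

  moved <- transform_assembly(s, rotation = rot_axis_angle(c(1, 2, 3), 40),
                              translation = c(5, 6, -7))
  expect_equal(irms(moved, s, build_correspondence(moved, s), iface), 0,
               tolerance = 1e-6)

  t2 <- transform_assembly(s, translation = c(0, 0, 2), chains = "B")
  v <- irms(t2, s, build_correspondence(t2, s), iface)
  expect_gt(v, 0)
  expect_lt(v, 2)
  # cross-check against an independent fit of the same interface set
  keys <- intersect(iface$interface_residues, corr$target_key)
  bb <- s[paste(s$chain, s$resno, s$ins, sep = "|") %in% keys &
            s$elety %in% c("N", "CA", "C", "O"), ]
  mb <- t2[paste(t2$chain, t2$resno, t2$ins, sep = "|") %in% keys &
             t2$elety %in% c("N", "CA", "C", "O"), ]
  sp <- superpose(as.matrix(mb[, c("x", "y", "z")]),
                  as.matrix(bb[, c("x", "y", "z")]))
  expect_equal(v, sp$rmsd, tolerance = 1e-9)
})

test_that("srms follows the irms fit and flags all-glycine interfaces", {
  s <- toy_dimer()
  iface <- native_contacts(s, "A", "B")
  corr <- build_correspondence(s, s)
  expect_equal(srms(s, s, corr, iface), 0, tolerance = 1e-9)

  # Monte-Carlo: jitter sigma per coordinate -> srms ~ sigma * sqrt(3)
  sigma <- 0.25
  vals <- vapply(1:10, function(i) {
    d <- make_decoy(s, sidechain_sigma = sigma, seed = i)
    srms(d$structure, s, build_correspondence(d$structure, s), iface)
  }, numeric(1))
  n_sc <- sum(!(s$elety %in% c("N", "CA", "C", "O")) &
                paste(s$chain, s$resno, s$ins, sep = "|") %in%
                  iface$interface_residues)
  se <- sigma * sqrt(3) / sqrt(2 * n_sc)   # rough chi SE
  expect_lt(abs(mean(vals) - sigma * sqrt(3)), 3 * se + 0.05)

  # an all-glycine interface has no shared side-chain atom
  gly <- mini_assembly(tibble::tibble(
    chain = rep(c("A", "B"), each = 12),
    resno = rep(rep(1:3, each = 4), 2),
    resid = "GLY",
    elety = rep(c("N", "CA", "C", "O"), 6),
    element = rep(c("N", "C", "C", "O"), 6),
    x = c(rep(c(0, 1, 2, 2.4), 3), rep(c(4, 5, 6, 6.4), 3)),
    y = rep(rep(c(0, 4, 8), each = 4), 2),
    z = rep(c(0, 0.3, 0.1, 1.2), 6)))
  gif <- native_contacts(gly, "A", "B")
  gcorr <- build_correspondence(gly, gly)
  expect_true(is.na(srms(gly, gly, gcorr, gif)))
})

test_that("all metrics are invariant under global rigid transforms", {
  s <- toy_dimer()
  iface <- native_contacts(s, "A", "B")
  set.seed(99)
  d <- make_decoy(s, translation = c(2, 1, -1), rotation_angle = 8,
                  rotation_axis = c(0, 1, 1))
  m0 <- interface_metrics(d$structure, s, build_correspondence(d$structure, s),
                          iface)
  for (rep in 1:3) {
    g <- transform_assembly(d$structure, rotation = random_rotation(),
                            translation = stats::rnorm(3, 0, 20))
    m1 <- interface_metrics(g, s, build_correspondence(g, s), iface)
    expect_equal(m1$fnat, m0$fnat)
    expect_equal(m1$clashes, m0$clashes)
    expect_equal(m1$lrms, m0$lrms, tolerance = 1e-6)
    expect_equal(m1$irms, m0$irms, tolerance = 1e-6)
    expect_equal(m1$srms, m0$srms, tolerance = 1e-6)
  }
})

test_that("fnat decays monotonically along a fixed displacement direction", {
  s <- toy_dimer()
  iface <- native_contacts(s, "A", "B")
  vals <- vapply(c(0, 1, 2, 4, 8, 16), function(t) {
    m <- transform_assembly(s, translation = c(t, 0, 0), chains = "B")
    fnat(m, build_correspondence(m, s), iface)
  }, numeric(1))
  expect_true(all(diff(vals) <= 0))
  expect_equal(vals[1], 1)
})
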