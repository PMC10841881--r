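# Shared fixtures and naive oracles for the test suite. The naive oracles
# here are deliberately written as plain double loops / dense matrices so
# they share no code path with the package's grid search.

toy_dimer <- function(len = 20) make_toy_complex(toy_complex_spec(2, len))
toy_trimer <- function(len = 15) make_toy_complex(toy_complex_spec(3, len))
toy_hexamer <- function(len = 15) make_toy_complex(toy_complex_spec(6, len))

# slow but independent residue-contact enumeration
naive_contacts <- function(s, ca, cb, cutoff) {
  A <- s[s$chain == ca, ]; B <- s[s$chain == cb, ]
  out <- character(0)
  for (i in seq_len(nrow(A))) {
    d <- sqrt((A$x[i] - B$x)^2 + (A$y[i] - B$y)^2 + (A$z[i] - B$z)^2)
    hit <- which(d < cutoff)
    if (length(hit) > 0) {
      out <- c(out, paste(paste(A$chain[i], A$resno[i], A$ins[i], sep = "|"),
                          paste(B$chain[hit], B$resno[hit], B$ins[hit],
                                sep = "|")))
    }
  }
  sort(unique(out))
}

naive_clashes <- function(s, ca, cb, cutoff = 3) {
  A <- s[s$chain == ca, ]; B <- s[s$chain == cb, ]
  n <- 0L
  for (i in seq_len(nrow(A))) {
    d2 <- (A$x[i] - B$x)^2 + (A$y[i] - B$y)^2 + (A$z[i] - B$z)^2
    n <- n + sum(d2 < cutoff^2)
  }
  n
}

# a tiny hand-built two-chain structure: one CA/CB pseudo-residue per row
mini_assembly <- function(df) as_assembly(df, source_format = "synthetic")

# random proper rotation (QR-based)
random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# plain-R recomputation of the group score, independent of dplyr pipelines
naive_score_group <- function(best, w = c(Acceptable = 1, Medium = 2, High = 3)) {
  out <- numeric(0)
  for (g in sort(unique(best$group_id))) {
    rows <- best[best$group_id == g, ]
    s <- 0
    has_multi <- all(c("multi", "score_au_norm") %in% names(rows))
    for (i in seq_len(nrow(rows))) {
      cat <- as.character(rows$category[i])
      multi <- has_multi && isTRUE(rows$multi[i]) &&
        !is.na(rows$score_au_norm[i])
      s <- s + if (multi) rows$score_au_norm[i]
               else if (cat %in% names(w)) w[[cat]] else 0
    }
    out[g] <- s
  }
  out
}

random_manifest <- function(seed, n_groups = 4, n_aus = 5) {
  set.seed(seed)
  g <- expand.grid(group_id = sprintf("G%02d", 1:n_groups),
                   au_id = sprintf("AU%d", 1:n_aus),
                   model_rank = 1:5, stringsAsFactors = FALSE)
  g$category <- sample(c("Incorrect", "Acceptable", "Medium", "High"),
                       nrow(g), replace = TRUE)
  g$dockq <- round(stats::runif(nrow(g)), 4)
  tibble::as_tibble(g)
}

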