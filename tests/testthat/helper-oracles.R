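# Independent oracles and small fixtures used across the suite.

# Welch t test from the textbook formulas (independent of stats::t.test)
welch_oracle <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Naive Ward.D2 agglomeration via the Lance-Williams update on squared
# Manhattan distances; independent of stats::hclust
ward_oracle <- function(X) {
  n <- nrow(X)
  D2 <- as.matrix(dist(X, method = "manhattan"))^2
  sizes <- rep(1, n)
  active <- 1:n
  labels_sets <- lapply(1:n, function(i) rownames(X)[i])
  node_of <- -(1:n)
  heights <- numeric(0)
  sets <- list()
  while (length(active) > 1) {
    bv <- Inf; bi <- bj <- NA
    for (a in seq_along(active)) {
      for (b in seq_along(active)) {
        if (a < b && D2[active[a], active[b]] < bv) {
          bv <- D2[active[a], active[b]]; bi <- active[a]; bj <- active[b]
        }
      }
    }
    heights <- c(heights, sqrt(bv))
    new_set <- sort(c(labels_sets[[bi]], labels_sets[[bj]]))
    sets[[length(sets) + 1]] <- new_set
    ni <- sizes[bi]; nj <- sizes[bj]
    for (k in active) {
      if (k != bi && k != bj) {
        nk <- sizes[k]
        D2[bi, k] <- D2[k, bi] <-
          ((ni + nk) * D2[bi, k] + (nj + nk) * D2[bj, k] - nk * bv) / (ni + nj + nk)
      }
    }
    sizes[bi] <- ni + nj
    labels_sets[[bi]] <- new_set
    node_of[bi] <- length(sets)
    active <- setdiff(active, bj)
  }
  list(heights = heights, sets = sets)
}

# signatures with no metabolite effects, for null simulations
null_signatures <- function(moa_ids = c("peroxisome_proliferation",
                                        "enzyme_induction",
                                        "enzyme_inhibition")) {
  sigs <- lapply(moa_ids, function(m) effect_signature(m, numeric()))
  names(sigs) <- moa_ids
  sigs
}

two_substance_design <- function() {
  default_study_substances()[c(2, 4), ]
}

# ratio + within-sample normalization in one step
normalize_both <- function(ex, qc = NULL) {
  normalize_within_sample(
    normalize_to_reference(ex$measurements, qc = qc, layouts = ex$layouts)
  )
}
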