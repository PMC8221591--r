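# Independent brute-force oracles, written with explicit loops so they share
# no code path with the package implementations they check.

# Two-way variance-decomposition stability, computed gene by gene and group
# by group with plain loops. Mirrors the documented model: sample-centred
# values, per-group gene deviation from the gene's across-group mean,
# bias-corrected within-group variance, stability = mean over groups of
# |d| + sqrt(sigma2 / n).
oracleModelStability <- function(Y, group) {
  k <- nrow(Y)
  glev <- unique(group)
  out <- data.frame(gene = rownames(Y), stability = NA_real_,
                    intergroup_diff = NA_real_)
  Z <- Y
  for (j in seq_len(ncol(Y))) {
    Z[, j] <- Y[, j] - mean(Y[, j])
  }
  for (i in seq_len(k)) {
    zbars <- numeric(length(glev))
    vars <- numeric(length(glev))
    ns <- integer(length(glev))
    for (gi in seq_along(glev)) {
      vals <- Z[i, group == glev[gi]]
      zbars[gi] <- mean(vals)
      vars[gi] <- sum((vals - mean(vals))^2) / (length(vals) - 1)
      ns[gi] <- length(vals)
    }
    ds <- zbars - mean(zbars)
    terms <- numeric(length(glev))
    for (gi in seq_along(glev)) {
      vsum <- 0
      for (h in seq_len(k)) {
        vals_h <- Z[h, group == glev[gi]]
        vsum <- vsum + sum((vals_h - mean(vals_h))^2) / (length(vals_h) - 1)
      }
      sig2 <- (vars[gi] - vsum / (k * (k - 1))) * k / (k - 2)
      if (sig2 < 0) sig2 <- 0
      terms[gi] <- abs(ds[gi]) + sqrt(sig2 / ns[gi])
    }
    out$stability[i] <- mean(terms)
    out$intergroup_diff[i] <- ds[2] - ds[1]
  }
  out
}

# A long CT table from a genes x samples matrix plus sample groups.
ctTableFromMatrix <- function(Y, group) {
  df <- expand.grid(gene = rownames(Y), sample = colnames(Y),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df$ct <- Y[cbind(match(df$gene, rownames(Y)), match(df$sample, colnames(Y)))]
  df$group <- group[match(df$sample, colnames(Y))]
  df
}

# ComponentSet built directly from a label matrix and an intensity plane,
# bypassing detection (for the arithmetic examples).
componentSetFromLabels <- function(labels, plane, calibration) {
  labs <- sort(unique(labels[labels > 0]))
  if (length(labs) == 0) {
    return(methods::new("ComponentSet",
                        labels = matrix(as.integer(labels), nrow(labels)),
                        stats = data.frame(label = integer(), n_px = integer(),
                                           area_um2 = numeric(),
                                           total_intensity = numeric(),
                                           mean_intensity = numeric(),
                                           centroid_row = numeric(),
                                           centroid_col = numeric()),
                        calibration = calibration))
  }
  stats <- do.call(rbind, lapply(labs, function(l) {
    idx <- which(labels == l)
    data.frame(label = l, n_px = length(idx),
               area_um2 = length(idx) * calibration^2,
               total_intensity = sum(plane[idx]),
               mean_intensity = mean(plane[idx]),
               centroid_row = mean(row(labels)[idx]) - 1,
               centroid_col = mean(col(labels)[idx]) - 1)
  }))
  methods::new("ComponentSet", labels = matrix(as.integer(labels), nrow(labels)),
               stats = stats, calibration = calibration)
}

# Flat image with one centred disk at a multiple of the background.
diskImage <- function(size_px = 120, background = 100, mult = 3, area_px = 160) {
  p <- matrix(background, size_px, size_px)
  r <- sqrt(area_px / pi)
  d2 <- (row(p) - size_px / 2)^2 + (col(p) - size_px / 2)^2
  p[d2 <= r^2] <- background * mult
  p
}

hkCandidates <- c("Actg1", "Hprt1", "Gapdh", "Tuba4a", "Pgk1", "Tbp")
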