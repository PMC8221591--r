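#' Average technical replicates of a CT table
#'
#' One row per gene x sample; per-sample CT is the arithmetic mean of the
#' technical replicates, with the replicate SD retained as QC column
#' `ct_sd` (NA for a single replicate).
#'
#' @param table long-format CT table (see [validateCtTable()]).
#' @return aggregated CT table with columns `gene`, `sample`, carried
#'   metadata (`group`, `region`, `fraction` when present), `ct`, `ct_sd`,
#'   `n_replicates`.
#' @export
aggregateReplicates <- function(table) {
  table <- validateCtTable(table)
  keys <- intersect(c("gene", "sample", "group", "region", "fraction"),
                    names(table))
  agg <- aggregate(table$ct, by = table[keys], FUN = mean)
  names(agg)[ncol(agg)] <- "ct"
  sdv <- aggregate(table$ct, by = table[keys],
                   FUN = function(x) if (length(x) > 1L) sd(x) else NA_real_)
  nv <- aggregate(table$ct, by = table[keys], FUN = length)
  agg$ct_sd <- sdv$x[match(do.call(paste, agg[keys]), do.call(paste, sdv[keys]))]
  agg$n_replicates <- nv$x[match(do.call(paste, agg[keys]), do.call(paste, nv[keys]))]
  agg[order(agg$gene, agg$sample), , drop = FALSE]
}

## genes x samples CT matrix for a candidate set, plus the group of each
## sample column. Errors on missing gene x sample combinations.
.ctMatrix <- function(table, genes, groups = NULL) {
  table <- validateCtTable(table, require_group = TRUE)
  if ("replicate" %in% names(table) &&
      anyDuplicated(table[c("gene", "sample")])) {
    table <- aggregateReplicates(table)
  }
  table <- table[table$gene %in% genes, , drop = FALSE]
  if (!is.null(groups)) table <- table[table$group %in% groups, , drop = FALSE]
  samples <- unique(table$sample)
  Y <- matrix(NA_real_, length(genes), length(samples),
              dimnames = list(genes, samples))
  Y[cbind(match(table$gene, genes), match(table$sample, samples))] <- table$ct
  if (anyNA(Y)) stop("every candidate gene must be measured in every sample")
  grp <- table$group[match(samples, table$sample)]
  list(Y = Y, group = grp)
}

#' Model-based (NormFinder-style) stability
#'
#' Variance-decomposition stability for candidate reference genes on the CT
#' (log) scale. Per group, sample effects are removed by centering each
#' sample across the candidate genes; the gene's intergroup difference is
#' the deviation of its group mean (of centred values) from its across-group
#' mean, and its intragroup variance is the bias-corrected within-group
#' variance of the centred values,
#' `sigma2_ig = (v_ig - sum_h v_hg / (k (k - 1))) * k / (k - 2)` (clamped at
#' 0), which removes the variance leaked in by the centering. The combined
#' stability value is the across-group mean of
#' `|d_ig| + sqrt(sigma2_ig / n_g)`; lower is more stable.
#'
#' @param table CT table with a `group` column (technical replicates are
#'   averaged first if present).
#' @param candidate_genes character vector of >= 3 candidate genes.
#' @param groups optional character(2) restricting/ordering the groups
#'   (reference first); the signed `intergroup_diff` is
#'   `d(group 2) - d(group 1)` in cycles.
#' @return data.frame: `gene`, per-group `var_<g>` and `d_<g>`,
#'   `intergroup_diff`, `stability`.
#' @export
stabilityModelBased <- function(table, candidate_genes, groups = NULL) {
  if (length(candidate_genes) < 3L) {
    stop("the model-based decomposition needs >= 3 candidate genes")
  }
  cm <- .ctMatrix(table, candidate_genes, groups)
  glev <- if (is.null(groups)) unique(cm$group) else groups
  if (length(glev) < 2L) stop("at least two groups are required")
  for (g in glev) {
    if (sum(cm$group == g) < 2L) stop("each group needs >= 2 samples")
  }
  k <- length(candidate_genes)
  Z <- sweep(cm$Y, 2L, colMeans(cm$Y))
  zbar <- sapply(glev, function(g) rowMeans(Z[, cm$group == g, drop = FALSE]))
  dmat <- zbar - rowMeans(zbar)
  vmat <- sapply(glev, function(g) apply(Z[, cm$group == g, drop = FALSE], 1L, var))
  sig2 <- sapply(seq_along(glev), function(j) {
    pmax((vmat[, j] - sum(vmat[, j]) / (k * (k - 1))) * k / (k - 2), 0)
  })
  colnames(sig2) <- glev
  ng <- vapply(glev, function(g) sum(cm$group == g), integer(1))
  stab <- rowMeans(abs(dmat) + sqrt(sweep(sig2, 2L, ng, "/")))
  out <- data.frame(gene = candidate_genes, stringsAsFactors = FALSE)
  for (j in seq_along(glev)) {
    out[[paste0("var_", glev[j])]] <- sig2[, j]
    out[[paste0("d_", glev[j])]] <- dmat[, j]
  }
  out$intergroup_diff <- dmat[, 2L] - dmat[, 1L]
  out$stability <- stab
  rownames(out) <- NULL
  out
}

#' Pairwise-M (geNorm-style) stability
#'
#' `M_g` = mean over the other candidates `h` of the SD across samples of
#' the pairwise difference `CT_g - CT_h` (CT is already a log scale, so the
#' difference is the log expression ratio). Invariant to per-gene constant
#' shifts. With `iterative = TRUE` the ranking additionally records the
#' geNorm exclusion order (worst gene dropped, M recomputed).
#'
#' @param table CT table.
#' @param candidate_genes >= 2 candidate genes.
#' @param iterative also compute the iterative-exclusion rank.
#' @return data.frame `gene`, `M` (and `rank_iterative` when requested;
#'   the two final survivors share rank 1).
#' @export
stabilityPairwiseM <- function(table, candidate_genes, iterative = FALSE) {
  if (length(candidate_genes) < 2L) stop("pairwise M needs >= 2 genes")
  cm <- .ctMatrix(table, candidate_genes)
  Mfun <- function(Y) {
    vapply(rownames(Y), function(g) {
      others <- setdiff(rownames(Y), g)
      mean(vapply(others, function(h) sd(Y[g, ] - Y[h, ]), numeric(1)))
    }, numeric(1))
  }
  out <- data.frame(gene = candidate_genes, M = unname(Mfun(cm$Y)),
                    stringsAsFactors = FALSE)
  if (iterative) {
    Y <- cm$Y
    order_out <- character()
    while (nrow(Y) > 2L) {
      m <- Mfun(Y)
      worst <- names(which.max(m))
      order_out <- c(order_out, worst)
      Y <- Y[setdiff(rownames(Y), worst), , drop = FALSE]
    }
    rk <- setNames(rep(1L, 2L), rownames(Y))
    rk[rev(order_out)] <- 2L + seq_along(order_out)
    out$rank_iterative <- unname(rk[out$gene])
  }
  out
}

#' Raw CT standard deviation stability
#'
#' SD of a gene's CT across all samples (BestKeeper-style raw variability).
#'
#' @inheritParams stabilityPairwiseM
#' @return data.frame `gene`, `raw_sd`
#' @export
stabilityRawSd <- function(table, candidate_genes) {
  cm <- .ctMatrix(table, candidate_genes)
  data.frame(gene = candidate_genes, raw_sd = apply(cm$Y, 1L, sd),
             stringsAsFactors = FALSE)
}

#' Comparative delta-Ct stability
#'
#' Mean across partner genes of the SD of the pairwise CT difference: the
#' comparative delta-Ct measure shares its computational core with
#' non-iterative pairwise M, and the two produce identical values by
#' construction (documented; both are reported because the rank aggregation
#' mirrors a four-method consensus).
#'
#' @inheritParams stabilityPairwiseM
#' @return data.frame `gene`, `mean_pairwise_sd`
#' @export
stabilityCompDeltaCt <- function(table, candidate_genes) {
  m <- stabilityPairwiseM(table, candidate_genes)
  data.frame(gene = m$gene, mean_pairwise_sd = m$M, stringsAsFactors = FALSE)
}

#' Aggregate per-method stability ranks
#'
#' Geometric mean of the per-method ranks (RefFinder-style consensus),
#' ties in the aggregate broken by the first method's rank (the model-based
#' rank in [stabilityReport()]).
#'
#' @param ranks data.frame or matrix, one row per gene, one column per
#'   method (>= 2), of per-method ranks; row names or a `gene` column name
#'   the genes.
#' @return data.frame `gene`, `rank_geomean`, `rank_aggregate` (1 = best).
#' @export
stabilityAggregate <- function(ranks) {
  df <- as.data.frame(ranks)
  gene <- if ("gene" %in% names(df)) df$gene else rownames(df)
  df <- df[setdiff(names(df), "gene")]
  if (ncol(df) < 2L) stop("rank aggregation needs >= 2 methods")
  gm <- exp(rowMeans(log(as.matrix(df))))
  agg <- rank(gm, ties.method = "min")
  tied <- duplicated(agg) | duplicated(agg, fromLast = TRUE)
  ord <- order(gm, df[[1L]], seq_along(gm))
  final <- integer(length(gm))
  final[ord] <- seq_along(gm)
  data.frame(gene = gene, rank_geomean = gm, rank_aggregate = final,
             stringsAsFactors = FALSE)
}

#' Full reference-gene stability report with pair selection
#'
#' Runs the four stability measures (model-based, pairwise-M, raw CT SD,
#' comparative delta-Ct), aggregates their ranks, selects the countervailing
#' housekeeping pair among the `top_k` aggregated candidates (the pair
#' minimizing `|d1 + d2|`, the absolute sum of signed intergroup
#' differences, ties broken by summed stability values), and reports the
#' selected pair's group expression ratio and signed fold change as the
#' final stability check.
#'
#' @param table CT table with groups.
#' @param candidate_genes >= 3 candidates.
#' @param groups character(2), reference group then alternative group.
#' @param top_k pool size for pair selection (default 4).
#' @return a [StabilityReport]
#' @export
stabilityReport <- function(table, candidate_genes, groups, top_k = 4L) {
  mb <- stabilityModelBased(table, candidate_genes, groups)
  pm <- stabilityPairwiseM(table, candidate_genes)
  rs <- stabilityRawSd(table, candidate_genes)
  cd <- stabilityCompDeltaCt(table, candidate_genes)
  per <- Reduce(function(a, b) merge(a, b, by = "gene", sort = FALSE),
                list(mb, pm, rs, cd))
  rks <- data.frame(
    gene = per$gene,
    model_based = rank(per$stability, ties.method = "first"),
    pairwise_M = rank(per$M, ties.method = "first"),
    raw_sd = rank(per$raw_sd, ties.method = "first"),
    comp_delta_ct = rank(per$mean_pairwise_sd, ties.method = "first"))
  agg <- stabilityAggregate(rks)
  per <- merge(per, rks, by = "gene", sort = FALSE)
  per <- merge(per, agg, by = "gene", sort = FALSE)
  pair <- selectPair(per, top_k = top_k)
  pr <- pairGroupRatio(table, pair, groups)
  new("StabilityReport", perGene = per, selectedPair = pair,
      pairRatio = pr$ratio, pairFoldChange = pr$fold_change, groups = groups)
}

#' Select the countervailing housekeeping pair
#'
#' Among the candidates whose aggregated rank is within the top `top_k`,
#' returns the pair minimizing the absolute sum of signed intergroup
#' differences `|d1 + d2|` (countervailing drifts cancel in the pair mean);
#' exact ties are broken by the summed stability values.
#'
#' @param perGene per-gene table with columns `gene`, `intergroup_diff`,
#'   `stability`, `rank_aggregate` (as built by [stabilityReport()]), or a
#'   [StabilityReport].
#' @param top_k pool size (default 4).
#' @return character(2): the selected pair, ordered by aggregated rank.
#' @export
selectPair <- function(perGene, top_k = 4L) {
  if (is(perGene, "StabilityReport")) perGene <- perGene@perGene
  pool <- perGene[perGene$rank_aggregate <= top_k, , drop = FALSE]
  if (nrow(pool) < 2L) stop("fewer than 2 candidates within the top-k ranks")
  cmb <- combn(seq_len(nrow(pool)), 2L)
  sums <- abs(pool$intergroup_diff[cmb[1L, ]] + pool$intergroup_diff[cmb[2L, ]])
  stab <- pool$stability[cmb[1L, ]] + pool$stability[cmb[2L, ]]
  best <- order(sums, stab)[1L]
  idx <- cmb[, best]
  idx <- idx[order(pool$rank_aggregate[idx])]
  pool$gene[idx]
}

#' Group expression ratio and fold change of a housekeeping pair
#'
#' Per sample, the pair expression is `2^(-mean CT over the pair)`; the
#' ratio is the alternative-group mean over the reference-group mean, and
#' the signed fold change is [foldChangeConvert()] of that ratio. A perfect
#' pair has ratio (and fold change) 1.
#'
#' @param table CT table (replicates averaged if present).
#' @param pair character(2) housekeeping genes.
#' @param groups character(2): reference group, then alternative group.
#' @return list: `ratio`, `fold_change`, `per_sample` data.frame.
#' @export
pairGroupRatio <- function(table, pair, groups) {
  stopifnot(length(pair) == 2L, length(groups) == 2L)
  table <- validateCtTable(table, require_group = TRUE)
  if ("replicate" %in% names(table) &&
      anyDuplicated(table[c("gene", "sample")])) {
    table <- aggregateReplicates(table)
  }
  tab <- table[table$gene %in% pair & table$group %in% groups, , drop = FALSE]
  ok <- tapply(tab$gene, tab$sample, function(g) all(pair %in% g))
  bad <- names(ok)[!ok]
  if (length(bad)) {
    warning("dropping sample(s) missing a pair gene: ", paste(bad, collapse = ", "))
    tab <- tab[!tab$sample %in% bad, , drop = FALSE]
  }
  meanct <- aggregate(list(ct = tab$ct),
                      by = list(sample = tab$sample), FUN = mean)
  meanct$group <- tab$group[match(meanct$sample, tab$sample)]
  meanct$expression <- 2^(-meanct$ct)
  gmeans <- tapply(meanct$expression, meanct$group, mean)
  if (anyNA(gmeans[groups])) stop("both groups must be present")
  ratio <- unname(gmeans[groups[2L]] / gmeans[groups[1L]])
  list(ratio = ratio, fold_change = foldChangeConvert(ratio),
       per_sample = meanct)
}
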