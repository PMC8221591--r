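#' Convert an expression ratio to a signed fold change
#'
#' `F = r` when `r >= 1` and `F = -1/r` when `r < 1`, rounded to
#' `digits` decimals for report tables (set `digits = NULL` to keep the full
#' value). Antisymmetric around 1: `F(1/r) = -F(r)`; always `|F| >= 1`.
#'
#' @param ratio positive expression ratio(s).
#' @param digits decimals for the report convention (default 2).
#' @return signed fold change(s)
#' @examples
#' foldChangeConvert(0.98)  # -1.02
#' foldChangeConvert(1.02)  #  1.02
#' @export
foldChangeConvert <- function(ratio, digits = 2) {
  if (any(!is.finite(ratio)) || any(ratio <= 0)) {
    stop("ratio must be a positive finite number")
  }
  f <- ifelse(ratio >= 1, ratio, -1 / ratio)
  if (!is.null(digits)) f <- round(f, digits)
  f
}

#' Normalize target CT values to a housekeeping pair
#'
#' `delta CT = CT_target - mean(CT_hk1, CT_hk2)` per sample, using the
#' arithmetic mean of the housekeeping pair. Samples missing a housekeeping
#' value are dropped with a warning. Adding a constant to every CT of a
#' sample leaves its delta CT unchanged.
#'
#' @param table CT table (replicates averaged if present).
#' @param pair character(2) housekeeping genes.
#' @param targets genes to normalize (default: all non-pair genes).
#' @return data.frame: `sample`, `gene`, carried `group` when present,
#'   `delta_ct`.
#' @export
deltaCt <- function(table, pair, targets = NULL) {
  stopifnot(length(pair) == 2L)
  table <- validateCtTable(table)
  if ("replicate" %in% names(table) &&
      anyDuplicated(table[c("gene", "sample")])) {
    table <- aggregateReplicates(table)
  }
  if (is.null(targets)) targets <- setdiff(unique(table$gene), pair)
  hk <- table[table$gene %in% pair, , drop = FALSE]
  ok <- tapply(hk$gene, hk$sample, function(g) all(pair %in% g))
  hkmean <- tapply(hk$ct, hk$sample, mean)
  tg <- table[table$gene %in% targets, , drop = FALSE]
  bad <- unique(tg$sample[!(tg$sample %in% names(ok)[ok])])
  if (length(bad)) {
    warning("dropping sample(s) without both housekeeping genes: ",
            paste(bad, collapse = ", "))
    tg <- tg[!tg$sample %in% bad, , drop = FALSE]
  }
  out <- data.frame(sample = tg$sample, gene = tg$gene,
                    delta_ct = tg$ct - unname(hkmean[tg$sample]),
                    stringsAsFactors = FALSE)
  if ("group" %in% names(tg)) out$group <- tg$group
  rownames(out) <- NULL
  out
}

#' Delta-delta-CT fold change with propagated error
#'
#' `ddCT = mean(delta CT, alt group) - mean(delta CT, ref group)`;
#' `log2 fold change = -ddCT`; `ratio = 2^-ddCT`; the signed fold change is
#' [foldChangeConvert()] of the ratio (unrounded). The standard error is
#' propagated to first order as the root sum of squares of the two group
#' SEMs (of the per-sample delta CT values); a seeded bootstrap SE over
#' samples is available for verification.
#'
#' @param dct_ref,dct_alt numeric vectors of per-sample delta CT values for
#'   the reference (e.g. sleep) and alternative (e.g. sleep-deprived)
#'   groups; >= 2 samples each.
#' @param bootstrap number of bootstrap resamples for the optional `se_boot`
#'   column (0 = skip).
#' @param seed seed for the bootstrap.
#' @return one-row data.frame: `n_ref`, `n_alt`, `mean_ref`, `mean_alt`,
#'   `sem_ref`, `sem_alt`, `ddct`, `se_ddct`, `log2_fc`, `se_log2_fc`,
#'   `ratio`, `fold_change` (and `se_boot` when requested).
#' @export
ddctFoldChange <- function(dct_ref, dct_alt, bootstrap = 0L, seed = 1L) {
  if (length(dct_ref) < 2L || length(dct_alt) < 2L) {
    stop("at least 2 samples per group are required")
  }
  sem <- function(x) sd(x) / sqrt(length(x))
  res <- ddctFromSummary(mean(dct_ref), sem(dct_ref), length(dct_ref),
                         mean(dct_alt), sem(dct_alt), length(dct_alt))
  if (bootstrap > 0L) {
    set.seed(seed)
    bs <- replicate(bootstrap, mean(sample(dct_alt, replace = TRUE)) -
                      mean(sample(dct_ref, replace = TRUE)))
    res$se_boot <- sd(bs)
  }
  res
}

#' @rdname ddctFoldChange
#' @param mean_ref,sem_ref,n_ref,mean_alt,sem_alt,n_alt group summaries
#'   (mean, SEM and size of the per-sample delta CT values), for computing
#'   the same result from published summary tables.
#' @export
ddctFromSummary <- function(mean_ref, sem_ref, n_ref = NA_integer_,
                            mean_alt, sem_alt, n_alt = NA_integer_) {
  ddct <- mean_alt - mean_ref
  se <- sqrt(sem_ref^2 + sem_alt^2)
  ratio <- 2^(-ddct)
  data.frame(n_ref = n_ref, n_alt = n_alt,
             mean_ref = mean_ref, mean_alt = mean_alt,
             sem_ref = sem_ref, sem_alt = sem_alt,
             ddct = ddct, se_ddct = se,
             log2_fc = -ddct, se_log2_fc = se,
             ratio = ratio,
             fold_change = foldChangeConvert(ratio, digits = NULL))
}

#' Marker enrichment of affinity-purified versus input mRNA
#'
#' Per biological sample, the log2 enrichment of a cell marker is the
#' delta-delta-CT between the affinity-purified (IP) fraction and the whole
#' homogenate input, `-(delta CT_IP - delta CT_input)`; enrichment across
#' samples is compared with a null hypothetical value of 0 by a one-sample
#' t test. Unpaired samples are dropped with a warning. With all
#' enrichments exactly equal the t statistic is degenerate: by convention
#' `t = 0, p = 1` when the common value is 0, and `t = +/-Inf, p = 0`
#' otherwise.
#'
#' @param dct_ip,dct_input named numeric vectors (names = sample ids) of
#'   per-sample delta CT in the IP and input fractions, or data.frames with
#'   columns `sample` and `delta_ct`.
#' @return list: `per_sample` (data.frame `sample`, `enrichment_log2`),
#'   `mean`, `se`, `t`, `df`, `p`.
#' @export
enrichmentVsInput <- function(dct_ip, dct_input) {
  asVec <- function(x) {
    if (is.data.frame(x)) setNames(x$delta_ct, x$sample) else x
  }
  ip <- asVec(dct_ip); inp <- asVec(dct_input)
  if (is.null(names(ip)) || is.null(names(inp))) {
    stop("per-sample values must be named by sample id (or given as data.frames)")
  }
  shared <- intersect(names(ip), names(inp))
  dropped <- setdiff(union(names(ip), names(inp)), shared)
  if (length(dropped)) {
    warning("dropping unpaired sample(s): ", paste(dropped, collapse = ", "))
  }
  if (length(shared) < 2L) stop("at least 2 paired samples are required")
  enr <- -(ip[shared] - inp[shared])
  m <- mean(enr)
  if (sd(enr) == 0) {
    t <- if (m == 0) 0 else sign(m) * Inf
    p <- if (m == 0) 1 else 0
    se <- 0
  } else {
    tt <- t.test(enr, mu = 0)
    t <- unname(tt$statistic); p <- tt$p.value
    se <- sd(enr) / sqrt(length(enr))
  }
  list(per_sample = data.frame(sample = shared, enrichment_log2 = unname(enr)),
       mean = m, se = se, t = t, df = length(enr) - 1L, p = p)
}
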