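#' End-to-end in situ quantification pipeline
#'
#' For every scene: detects Pvalb cell bodies on the cell channel
#' (cell-scale area threshold), partitions each anatomical region into
#' Pvalb+ and non-Pvalb+ ROIs, quantifies every dot channel in both ROI
#' classes (background, single-dot calibration, total dot number, dot
#' density), computes co-expression overlap metrics and per-cell Pvalb
#' intensities. When group labels are supplied, per
#' (region x ROI class x channel) contrasts are tested with [groupTest()] on
#' the per-scene dot densities and adjusted with [holmSidak()] within each
#' region family.
#'
#' @param scenes named list of [Scene] objects (one per animal/section).
#' @param groups optional named/ordered character vector of group labels
#'   (`"sleep"`/`"SD"`), one per scene.
#' @param config a [RunConfig].
#' @param cell_channel channel carrying the Pvalb signal (default
#'   `"Pvalb"`); dot channels are all other channels.
#' @param group_levels character(2), reference then alternative group.
#' @return list of tidy tables: `roi` (per scene x region x ROI class x
#'   channel quantification), `overlap`, `cell_intensity`, `comparisons`
#'   (NULL without groups), and a `manifest`.
#' @export
runInsituPipeline <- function(scenes, groups = NULL, config = runConfig(),
                              cell_channel = "Pvalb",
                              group_levels = c("sleep", "SD")) {
  stopifnot(is(config, "RunConfig"))
  if (is.null(names(scenes))) names(scenes) <- paste0("scene", seq_along(scenes))
  roi_rows <- list(); ov_rows <- list(); ci_rows <- list()
  warnings_log <- character()
  for (id in names(scenes)) {
    sc <- scenes[[id]]
    stopifnot(is(sc, "Scene"))
    calib <- calibration(sc)
    if (!cell_channel %in% names(sc)) {
      stop(sprintf("scene '%s' has no '%s' channel", id, cell_channel))
    }
    cells <- detectComponents(getChannel(sc, cell_channel), calib,
                              config@threshold_ratio,
                              config@min_component_area_um2,
                              config@surround_window_um)
    dot_channels <- setdiff(names(sc), cell_channel)
    for (maskName in regionMaskNames(sc)) {
      rois <- withCallingHandlers(
        classifyRois(cells, getRegionMask(sc, maskName), calib),
        warning = function(w) {
          warnings_log <<- c(warnings_log, conditionMessage(w))
          invokeRestart("muffleWarning")
        })
      for (regName in names(rois)) {
        roi <- rois[[regName]]
        region_id <- paste(maskName, regName, sep = ":")
        if (roi$empty) {
          roi_rows[[length(roi_rows) + 1L]] <- data.frame(
            scene = id, region = region_id, roi_class = NA_character_,
            channel = NA_character_, roi_area_um2 = 0,
            background_mean = NA_real_, single_dot_intensity = NA_real_,
            total_dot_number = NA_real_, dots_per_mm2 = NA_real_,
            dots_per_um2 = NA_real_, missing = TRUE)
          next
        }
        pvalbMask <- roi$cellLabels > 0L
        for (ch in dot_channels) {
          plane <- getChannel(sc, ch)
          comp <- detectComponents(plane, calib, config@threshold_ratio,
                                   config@dot_min_area_um2,
                                   config@surround_window_um)
          for (cls in c("Pvalb+", "non-Pvalb+")) {
            mask <- if (cls == "Pvalb+") pvalbMask else roi$nonPvalb
            if (!any(mask)) next
            row <- tryCatch(
              quantifyRoi(plane, mask, comp, calib, roi_class = cls,
                          region = region_id, channel = ch,
                          average = config@dot_average),
              error = function(e) NULL, warning = function(w) NULL)
            if (!is.null(row)) {
              row$scene <- id
              row$missing <- FALSE
              roi_rows[[length(roi_rows) + 1L]] <- row
            }
          }
          ## overlap of this channel's expression with the Pvalb cells
          regCells <- new("ComponentSet", labels = roi$cellLabels,
                          stats = componentStats(cells)[
                            componentStats(cells)$label %in%
                              unique(roi$cellLabels[roi$cellLabels > 0L]), ,
                            drop = FALSE],
                          calibration = calib)
          ov <- overlapMetrics(regCells, comp, config@overlap_min_fraction)
          ov$scene <- id; ov$region <- region_id; ov$channel <- ch
          ov_rows[[length(ov_rows) + 1L]] <- ov
        }
        ## per-cell Pvalb intensity distribution
        if (any(pvalbMask)) {
          plane <- getChannel(sc, cell_channel)
          cellComp <- detectComponents(plane, calib, config@threshold_ratio,
                                       config@min_component_area_um2,
                                       config@surround_window_um)
          bg <- tryCatch(estimateBackground(plane, roi$region, cellComp@labels),
                         error = function(e) NA_real_)
          if (is.finite(bg)) {
            regCells <- new("ComponentSet", labels = roi$cellLabels,
                            stats = componentStats(cells)[
                              componentStats(cells)$label %in%
                                unique(roi$cellLabels[roi$cellLabels > 0L]), ,
                              drop = FALSE],
                            calibration = calib)
            if (nComponents(regCells) > 0L) {
              pci <- perCellIntensity(plane, regCells, bg)$cells
              pci$scene <- id; pci$region <- region_id
              ci_rows[[length(ci_rows) + 1L]] <- pci
            }
          }
        }
      }
    }
  }
  roi_tab <- if (length(roi_rows)) do.call(rbind, roi_rows) else NULL
  ov_tab <- if (length(ov_rows)) do.call(rbind, ov_rows) else NULL
  ci_tab <- if (length(ci_rows)) do.call(rbind, ci_rows) else NULL

  comparisons <- NULL
  if (!is.null(groups) && !is.null(roi_tab)) {
    if (is.null(names(groups))) names(groups) <- names(scenes)
    roi_tab$group <- unname(groups[roi_tab$scene])
    ok <- !roi_tab$missing & !is.na(roi_tab$roi_class)
    fam <- split(roi_tab[ok, , drop = FALSE],
                 roi_tab$region[ok], drop = TRUE)
    comp_rows <- list()
    for (regName in names(fam)) {
      sub <- fam[[regName]]
      cells_f <- split(sub, paste(sub$roi_class, sub$channel, sep = "|"))
      rows <- lapply(cells_f, function(s) {
        x <- s$dots_per_mm2[s$group == group_levels[1L]]
        y <- s$dots_per_mm2[s$group == group_levels[2L]]
        if (length(x) < 2L || length(y) < 2L) return(NULL)
        gt <- groupTest(x, y)
        data.frame(region = regName, roi_class = s$roi_class[1L],
                   channel = s$channel[1L],
                   mean_ref = mean(x), mean_alt = mean(y),
                   t = gt$t, df = gt$df, p = gt$p)
      })
      rows <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
      if (!is.null(rows) && nrow(rows)) {
        hs <- holmSidak(rows$p, config@alpha)
        rows$p_adj <- hs$p_adj
        rows$significant <- hs$reject
        comp_rows[[regName]] <- rows
      }
    }
    comparisons <- if (length(comp_rows)) do.call(rbind, comp_rows) else NULL
    if (!is.null(comparisons)) rownames(comparisons) <- NULL
  }
  list(roi = roi_tab, overlap = ov_tab, cell_intensity = ci_tab,
       comparisons = comparisons,
       manifest = runManifest(config, stages = list(
         scenes = length(scenes),
         roi_rows = if (is.null(roi_tab)) 0L else nrow(roi_tab),
         overlap_rows = if (is.null(ov_tab)) 0L else nrow(ov_tab),
         warnings = warnings_log)))
}

#' End-to-end TRAP qPCR pipeline
#'
#' Aggregates technical replicates, ranks the candidate reference genes,
#' selects the countervailing housekeeping pair and verifies its group fold
#' change, normalizes the targets to the pair mean, and reports per-target
#' group delta CT means with SEM, log2 fold change with propagated SE,
#' Welch p values and step-down Sidak adjusted p values (one family across
#' the reported targets).
#'
#' @param table long-format CT table with `group`.
#' @param candidates character vector of candidate reference genes (>= 3).
#' @param targets character vector of target genes (default: all others).
#' @param groups character(2): reference then alternative group.
#' @param config a [RunConfig] (uses `top_k` and `alpha`).
#' @return list: `stability` (a [StabilityReport]), `results` (per-target
#'   table), `delta_ct` (per-sample normalized values), `manifest`.
#' @export
runTrapPipeline <- function(table, candidates, targets = NULL,
                            groups = c("sleep", "SD"), config = runConfig()) {
  stopifnot(is(config, "RunConfig"))
  table <- validateCtTable(table, require_group = TRUE)
  agg <- aggregateReplicates(table)
  if (is.null(targets)) targets <- setdiff(unique(agg$gene), candidates)
  stab <- stabilityReport(agg, candidates, groups, top_k = config@top_k)
  pair <- selectedPair(stab)
  dct <- deltaCt(agg, pair, targets)
  rows <- lapply(targets, function(g) {
    x <- dct$delta_ct[dct$gene == g & dct$group == groups[1L]]
    y <- dct$delta_ct[dct$gene == g & dct$group == groups[2L]]
    if (length(x) < 2L || length(y) < 2L) return(NULL)
    fc <- ddctFoldChange(x, y)
    gt <- groupTest(x, y)
    cbind(data.frame(gene = g), fc, data.frame(t = gt$t, df = gt$df, p = gt$p))
  })
  rows <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (!is.null(rows) && nrow(rows)) {
    hs <- holmSidak(rows$p, config@alpha)
    rows$p_adj <- hs$p_adj
    rows$significant <- hs$reject
    rownames(rows) <- NULL
  }
  list(stability = stab, results = rows, delta_ct = dct,
       manifest = runManifest(config, stages = list(
         input_rows = nrow(table), samples = length(unique(table$sample)),
         pair = pair)))
}

#' Run manifest
#'
#' Deterministic record of a pipeline run: package version, the full
#' configuration, and per-stage row counts/warnings. Re-running the same
#' inputs with the same manifest configuration reproduces the outputs
#' bit for bit (no timestamps are recorded).
#'
#' @param config a [RunConfig].
#' @param stages named list of per-stage counts and notes.
#' @return list with `version`, `config`, `stages`.
#' @export
runManifest <- function(config, stages = list()) {
  list(version = as.character(utils::packageVersion("riboquant")),
       config = configAsList(config), stages = stages)
}

#' @rdname runManifest
#' @param manifest a manifest list.
#' @param path output JSON path.
#' @export
writeManifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
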