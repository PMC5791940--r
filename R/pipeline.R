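#' Pipeline run configuration
#'
#' Bundles every tunable constant of the analysis with the run inputs. Two
#' entry modes exist: image mode (PET volumes plus a per-subject survival
#' table; segmentation and feature extraction run first) and table mode (a
#' ready per-subject table of features and survival columns; imaging stages
#' are skipped). The configuration is serialized verbatim into every output
#' directory, and a run is deterministic given the configuration and seed.
#'
#' @param volumes image mode: a named list, one entry per subject, each a
#'   list with `volume` (a [pet_volume()] or NIfTI path) and `seed_voxel`
#'   (length-3 voxel index).
#' @param survival_table image mode: data frame keyed by `id` with
#'   `pfs_time`, `event` and the clinical covariates.
#' @param table table mode: per-subject data frame (or CSV path) with
#'   `pfs_time`, `event`, clinical covariates and feature columns.
#' @param suv_threshold segmentation isocontour (default 3.5).
#' @param gray_levels quantization levels (default 64).
#' @param mv_cutoff_cm3 metabolic-volume category cutoff (default 45).
#' @param reference_feature screening reference (default `"co_entropy"`).
#' @param screen_alpha Bonferroni-adjusted screening threshold (0.001).
#' @param cutoff_p_threshold Wald threshold in the cutoff search (0.05).
#' @param min_group_fraction minimum group fraction in the cutoff search
#'   (0.05).
#' @param adjustment_covariates covariates of the adjusted Cox models
#'   (default ECOG group, disease status, MV category).
#' @param base_covariates covariates of the base concordance model (default
#'   disease status and ECOG group).
#' @param n_boot bootstrap replicates for concordance comparison (500).
#' @param seed integer seed for all stochastic stages.
#' @return A list of class `run_config`.
#' @export
run_config <- function(volumes = NULL, survival_table = NULL, table = NULL,
                       suv_threshold = 3.5, gray_levels = 64L,
                       mv_cutoff_cm3 = 45,
                       reference_feature = "co_entropy",
                       screen_alpha = 0.001,
                       cutoff_p_threshold = 0.05,
                       min_group_fraction = 0.05,
                       adjustment_covariates = c("ecog_group",
                                                 "disease_status",
                                                 "mv_category"),
                       base_covariates = c("disease_status", "ecog_group"),
                       n_boot = 500L, seed = 1L) {
  stopifnot(suv_threshold > 0, gray_levels >= 2L, mv_cutoff_cm3 > 0,
            screen_alpha > 0, cutoff_p_threshold > 0,
            min_group_fraction > 0, min_group_fraction < 0.5, n_boot >= 1L)
  if (is.null(table) && is.null(volumes))
    stop("provide either 'table' (table mode) or 'volumes' (image mode)",
         call. = FALSE)
  if (!is.null(volumes) && is.null(survival_table))
    stop("image mode needs 'survival_table'", call. = FALSE)
  structure(list(volumes = volumes, survival_table = survival_table,
                 table = table, suv_threshold = suv_threshold,
                 gray_levels = as.integer(gray_levels),
                 mv_cutoff_cm3 = mv_cutoff_cm3,
                 reference_feature = reference_feature,
                 screen_alpha = screen_alpha,
                 cutoff_p_threshold = cutoff_p_threshold,
                 min_group_fraction = min_group_fraction,
                 adjustment_covariates = adjustment_covariates,
                 base_covariates = base_covariates,
                 n_boot = as.integer(n_boot), seed = as.integer(seed)),
            class = "run_config")
}

stage <- function(name, log, expr) {
  log(paste0("stage ", name, ": start"))
  res <- tryCatch(expr, error = function(e)
    stop("stage ", name, ": ", conditionMessage(e), call. = FALSE))
  log(paste0("stage ", name, ": done"))
  res
}

#' Run the full heterogeneity-survival pipeline
#'
#' Orchestrates (image mode) segment -> extract or (table mode) table
#' loading, then Spearman screening with panel selection, optimal-cutoff Cox
#' dichotomization with adjusted models, concordance-index comparison, and
#' Kaplan-Meier plots. All tabular outputs, a run log, and the serialized
#' configuration are written to `output_dir`.
#'
#' @param config a [run_config()].
#' @param output_dir directory for outputs (created if needed).
#' @return Invisibly, a list with elements `subjects`, `screening`, `panel`,
#'   `cutoffs` (the Table-2-shaped data frame) and `cindex` (the
#'   Table-3-shaped data frame).
#' @export
run_pipeline <- function(config, output_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(output_dir, "run.log")
  log_lines <- character(0)
  logf <- function(msg) {
    log_lines <<- c(log_lines, msg)
    message(msg)
  }
  cfg_out <- config[!(names(config) %in% c("volumes", "survival_table",
                                           "table"))]
  yaml::write_yaml(cfg_out, file.path(output_dir, "config.yaml"))

  subjects <- stage("assemble", logf, {
    if (!is.null(config$table)) {
      tab <- config$table
      if (is.character(tab)) tab <- utils::read.csv(tab)
      logf(sprintf("  table mode: %d subjects, imaging stages skipped",
                   nrow(tab)))
      tab
    } else {
      feats <- lapply(names(config$volumes), function(id) {
        entry <- config$volumes[[id]]
        vol <- entry$volume
        if (is.character(vol)) vol <- load_pet_volume(vol)
        m <- segment_tumor(vol, entry$seed_voxel,
                           threshold = config$suv_threshold)
        fv <- extract_features(vol, m, levels = config$gray_levels)
        data.frame(id = id, as.list(unclass(fv)), check.names = FALSE)
      })
      feats <- do.call(rbind, feats)
      feats$mv_category <-
        as.integer(feats$metabolic_volume > config$mv_cutoff_cm3)
      logf(sprintf("  image mode: %d lesions segmented and extracted",
                   nrow(feats)))
      merge(config$survival_table, feats, by = "id")
    }
  })
  subjects <- stage("validate", logf, {
    if (!"mv_category" %in% names(subjects) &&
        "metabolic_volume" %in% names(subjects))
      subjects$mv_category <-
        as.integer(subjects$metabolic_volume > config$mv_cutoff_cm3)
    check_records(subjects)
  })
  utils::write.csv(subjects, file.path(output_dir, "features.csv"),
                   row.names = FALSE)

  screening <- stage("screen", logf, {
    drop <- c("id", "pfs_time", "event", "ecog_group", "disease_status",
              "mv_category")
    spearman_screen(subjects[setdiff(names(subjects), drop)],
                    reference = config$reference_feature,
                    alpha = config$screen_alpha)
  })
  utils::write.csv(screening, file.path(output_dir, "corr.csv"),
                   row.names = FALSE)
  panel <- stage("panel", logf, select_panel(screening))
  logf(paste("  panel:", paste(panel, collapse = ", ")))

  table2 <- stage("cutoffs", logf, {
    targets <- unique(c(panel, intersect(c("suv_max", "suv_average",
                                           "metabolic_volume"),
                                         names(subjects))))
    rows <- lapply(targets, function(f) {
      cr <- optimal_cutoff(subjects, f,
                           min_group_fraction = config$min_group_fraction,
                           p_threshold = config$cutoff_p_threshold)
      row <- data.frame(feature = f, cutoff = cr$cutoff,
                        n_above = cr$n_above, n_below = cr$n_below,
                        hr = cr$hr, ci_low = cr$ci_low, ci_high = cr$ci_high,
                        p = cr$p, significant = cr$significant,
                        ahr = NA_real_, ahr_ci_low = NA_real_,
                        ahr_ci_high = NA_real_, ahr_p = NA_real_)
      adj <- setdiff(config$adjustment_covariates, f)
      adj <- intersect(adj, names(subjects))
      if (cr$significant && length(adj)) {
        rec <- subjects
        rec$.risk <- as.integer(rec[[f]] > cr$cutoff)
        afit <- tryCatch(fit_cox(rec, c(".risk", adj)),
                         error = function(e) NULL)
        if (!is.null(afit)) {
          arow <- afit$coefficients[afit$coefficients$term == ".risk", ]
          row$ahr <- arow$hr
          row$ahr_ci_low <- arow$ci_low
          row$ahr_ci_high <- arow$ci_high
          row$ahr_p <- arow$p
        }
      }
      row
    })
    do.call(rbind, rows)
  })
  utils::write.csv(table2, file.path(output_dir, "table2.csv"),
                   row.names = FALSE)

  table3 <- stage("cindex", logf, {
    base <- intersect(config$base_covariates, names(subjects))
    rows <- lapply(panel, function(f) {
      cmp <- compare_c(subjects, base, c(base, f),
                       n_boot = config$n_boot, seed = config$seed)
      data.frame(feature = f, c_base = cmp$c_base,
                 c_extended = cmp$c_extended, delta = cmp$delta, p = cmp$p)
    })
    do.call(rbind, rows)
  })
  utils::write.csv(table3, file.path(output_dir, "table3.csv"),
                   row.names = FALSE)

  stage("km_plots", logf, {
    for (i in seq_len(nrow(table2))) {
      f <- table2$feature[i]
      if (!is.finite(table2$cutoff[i])) next
      grp <- ifelse(subjects[[f]] > table2$cutoff[i], "above", "below")
      if (length(unique(grp)) < 2L) next
      sf <- km_curve(subjects, grp)
      grDevices::pdf(file.path(output_dir, paste0("km_", f, ".pdf")),
                     width = 6, height = 5)
      graphics::plot(sf, col = c("firebrick", "steelblue"), lwd = 2,
                     xlab = "Months on TKI",
                     ylab = "Progression-free survival",
                     main = f)
      graphics::legend("topright", c("above cutoff", "below cutoff"),
                       col = c("firebrick", "steelblue"), lwd = 2, bty = "n")
      grDevices::dev.off()
    }
    invisible(NULL)
  })

  writeLines(log_lines, log_path)
  invisible(list(subjects = subjects, screening = screening, panel = panel,
                 cutoffs = table2, cindex = table3))
}
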