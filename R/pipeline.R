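#' Pipeline configuration
#'
#' Validated bundle of every tunable the end-to-end analysis uses; all seeds
#' are explicit so a rerun with the same configuration is bit-identical.
#'
#' @param band band-pass edges in Hz (`c(lo, hi)`), or `NULL` to skip.
#' @param notch_hz notch frequency, or `NULL` to skip.
#' @param target_fs downsampling target, or `NULL` to keep the native rate.
#' @param k number of microstate classes; `NA` selects it per subject pool via
#'   [choose_k()] at the group stage.
#' @param k_range candidate range for [choose_k()].
#' @param n_restarts modified k-means restarts.
#' @param n_perm TANOVA permutations.
#' @param alpha nominal significance level for contrasts and correlations.
#' @param alpha_family optional fixed Bonferroni threshold (default
#'   `alpha / m`).
#' @param fdr logical: apply BH FDR to trait correlations.
#' @param seed master seed.
#' @param conditions the two condition labels, baseline first.
#' @return Object of class `"ms_config"`.
#' @export
pipeline_config <- function(band = c(1, 40), notch_hz = NULL, target_fs = NULL,
                            k = 4, k_range = 1:12, n_restarts = 50,
                            n_perm = 4999, alpha = 0.05, alpha_family = NULL,
                            fdr = TRUE, seed = 1,
                            conditions = c("neutral", "fear")) {
  if (!is.null(band) && !(length(band) == 2 && band[1] > 0 &&
                          band[2] > band[1])) {
    stop("'band' must be c(lo, hi) with 0 < lo < hi")
  }
  if (length(conditions) != 2) stop("exactly two conditions are supported")
  structure(list(band = band, notch_hz = notch_hz, target_fs = target_fs,
                 k = k, k_range = k_range, n_restarts = n_restarts,
                 n_perm = n_perm, alpha = alpha, alpha_family = alpha_family,
                 fdr = fdr, seed = seed, conditions = conditions),
            class = "ms_config")
}

preprocess_recording <- function(rec, config) {
  rec <- average_reference(rec)
  if (!is.null(config$band)) {
    hi <- min(config$band[2], rec$fs / 2 - 1)
    rec <- bandpass(rec, config$band[1], hi)
  }
  if (!is.null(config$notch_hz) && config$notch_hz < rec$fs / 2) {
    rec <- notch(rec, config$notch_hz)
  }
  if (!is.null(config$target_fs) && config$target_fs < rec$fs) {
    rec <- downsample(rec, config$target_fs)
  }
  average_reference(rec)
}

#' Build the cohort parameter table
#'
#' Backfits every recording with its condition's group templates and pools the
#' per-epoch segmentations into one set of temporal parameters per subject,
#' condition and class.
#'
#' @param segmentations nested list: `segmentations[[condition]][[subject]]` =
#'   list of per-epoch `"ms_segmentation"`.
#' @param k number of classes.
#' @param trait optional data.frame (`subject`, `trait`) merged in.
#' @return data.frame: subject, condition, class, mean_duration,
#'   time_coverage (+ trait).
#' @export
cohort_params <- function(segmentations, k, trait = NULL) {
  rows <- list()
  for (cond in names(segmentations)) {
    per_subj <- segmentations[[cond]]
    for (s in seq_along(per_subj)) {
      tp <- temporal_params(per_subj[[s]], k = k)
      rows[[length(rows) + 1L]] <- data.frame(
        subject = s, condition = cond, class = tp$class,
        mean_duration = tp$mean_duration, time_coverage = tp$time_coverage)
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(trait)) out <- merge(out, trait, by = "subject")
  out[order(out$subject, out$condition, out$class), , drop = FALSE]
}

#' Run the full microstate analysis pipeline
#'
#' Stages: preprocessing (average reference, optional band-pass/notch/
#' downsampling) — GFP-peak extraction — per subject x condition modified
#' k-means — group-level clustering per condition on the pooled subject
#' templates — cross-condition class pairing with a per-class TANOVA gate —
#' winner-takes-all backfitting with the group templates — temporal parameters
#' — repeated-measures ANOVA, Bonferroni-controlled paired contrasts and
#' FDR-controlled trait correlations.
#'
#' Classes are reported in the baseline condition's template order; the
#' affected condition's classes are aligned to it by optimal |spatial
#' correlation| pairing.
#'
#' @param cohort an `"ms_cohort"` from [simulate_cohort()], or a list with
#'   `recordings` (list of [recording()] carrying subject/condition metadata)
#'   and optionally `trait`.
#' @param config an [pipeline_config()].
#' @param out_dir optional directory; when given, every stage's tables plus
#'   the configuration and seed are written there as TSV/JSON.
#' @return Object of class `"ms_pipeline"`: list with `group_fits`,
#'   `pairing`, `tanova`, `segmentations`, `params` (cohort table), `anova`
#'   (per parameter), `contrasts`, `trait_correlations`, `config`.
#' @export
run_pipeline <- function(cohort, config = pipeline_config(), out_dir = NULL) {
  recs <- cohort$recordings
  conds <- config$conditions
  subjects <- sort(unique(vapply(recs,
                                 function(r) as.integer(r$meta$subject),
                                 integer(1))))
  with_seed(config$seed, {
    # ---- preprocess + GFP peaks, grouped by condition x subject ----
    peaks <- list()
    pre <- list()
    for (cond in conds) peaks[[cond]] <- vector("list", length(subjects))
    for (r in recs) {
      rp <- preprocess_recording(r, config)
      cond <- as.character(rp$meta$condition)
      s <- match(as.integer(rp$meta$subject), subjects)
      g <- compute_gfp(rp)
      pk <- detect_gfp_peaks(g, rp$mask)
      peaks[[cond]][[s]] <- rbind(peaks[[cond]][[s]], peak_maps(rp, pk))
      pre[[length(pre) + 1L]] <- rp
    }
    # ---- subject-level then group-level clustering, per condition ----
    k <- config$k
    if (is.na(k)) {
      sel <- choose_k(peaks[[conds[1]]][[1]], k_range = config$k_range,
                      n_restarts = max(5, config$n_restarts %/% 5))
      k <- sel$chosen_k
    } else {
      sel <- NULL
    }
    levels <- lapply(conds, function(cond) {
      two_level_clustering(peaks[[cond]], k, n_restarts = config$n_restarts)
    })
    names(levels) <- conds
    group_fits <- lapply(levels, `[[`, "group")
    # ---- pairing + TANOVA gate --------------------------------------
    pairing <- pair_conditions(group_fits[[conds[1]]], group_fits[[conds[2]]])
    # reorder affected-condition classes to the baseline order
    group_fits[[conds[2]]]$maps <-
      group_fits[[conds[2]]]$maps[pairing$pairing, , drop = FALSE]
    tanova_res <- lapply(seq_len(k), function(j) {
      subj_maps <- function(cond, jj) {
        t(vapply(seq_along(subjects), function(s) {
          m <- coef(levels[[cond]]$subject[[s]])
          cm <- abs(tcrossprod(normalize_maps(m),
                               group_fits[[cond]]$maps[jj, , drop = FALSE]))
          m[which.max(cm), ]
        }, numeric(ncol(group_fits[[cond]]$maps))))
      }
      tanova(subj_maps(conds[1], j), subj_maps(conds[2], j),
             n_perm = config$n_perm)
    })
    # ---- backfit + temporal parameters ------------------------------
    segmentations <- list()
    for (cond in conds) {
      segmentations[[cond]] <- lapply(seq_along(subjects), function(s) {
        idx <- which(vapply(pre, function(r) {
          as.character(r$meta$condition) == cond &&
            as.integer(r$meta$subject) == subjects[s]
        }, logical(1)))
        lapply(pre[idx], function(r) backfit(r, group_fits[[cond]]))
      })
    }
    trait <- if (!is.null(cohort$trait)) cohort$trait else NULL
    params <- cohort_params(segmentations, k, trait)
    # ---- statistics --------------------------------------------------
    anova_res <- list(
      mean_duration = rm_anova(params, "mean_duration"),
      time_coverage = rm_anova(params, "time_coverage"))
    contrasts <- paired_contrasts(params, alpha = config$alpha,
                                  alpha_family = config$alpha_family,
                                  conditions = conds)
    trait_cor <- NULL
    if (!is.null(trait) && nrow(trait) >= 4) {
      wide <- list()
      for (cond in conds) for (p in c("mean_duration", "time_coverage")) {
        for (j in seq_len(k)) {
          v <- params[params$condition == cond & params$class == j, ]
          wide[[sprintf("%s_%s_class%d", cond, p, j)]] <-
            v[[p]][order(v$subject)]
        }
      }
      wide <- as.data.frame(wide)
      trait_cor <- pearson_with_fdr(trait$trait[order(trait$subject)], wide,
                                    alpha = config$alpha)
    }
    result <- structure(list(group_fits = group_fits, k = k,
                             k_selection = sel, pairing = pairing,
                             tanova = tanova_res,
                             segmentations = segmentations, params = params,
                             anova = anova_res, contrasts = contrasts,
                             trait_correlations = trait_cor,
                             config = config),
                        class = "ms_pipeline")
    if (!is.null(out_dir)) write_pipeline(result, out_dir)
    result
  })
}

#' @export
print.ms_pipeline <- function(x, ...) {
  cat(sprintf("<ms_pipeline> K = %d classes, %d subjects\n",
              x$k, length(unique(x$params$subject))))
  cat(sprintf("  group GEV: %s\n",
              paste(sprintf("%s %.3f", names(x$group_fits),
                            vapply(x$group_fits, `[[`, numeric(1), "gev")),
                    collapse = ", ")))
  cat(sprintf("  TANOVA p per class: %s\n",
              paste(sprintf("%.3g", vapply(x$tanova, `[[`, numeric(1), "p")),
                    collapse = ", ")))
  cat(sprintf("  interaction p (coverage): %.3g\n",
              x$anova$time_coverage$p[3]))
  invisible(x)
}

# write all result tables + provenance to a run directory
write_pipeline <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  wt(result$params, "parameters.tsv")
  wt(result$contrasts, "contrasts.tsv")
  if (!is.null(result$trait_correlations)) {
    wt(result$trait_correlations, "trait_correlations.tsv")
  }
  for (nm in names(result$anova)) {
    wt(as.data.frame(result$anova[[nm]]), sprintf("anova_%s.tsv", nm))
  }
  for (cond in names(result$group_fits)) {
    m <- t(result$group_fits[[cond]]$maps)
    utils::write.table(m, file.path(out_dir,
                                    sprintf("templates_%s.tsv", cond)),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = paste0("class", seq_len(ncol(m))))
  }
  cfg <- result$config
  cfg_list <- unclass(cfg)
  summary_json <- list(
    config = cfg_list,
    config_hash = config_hash(cfg),
    k = result$k,
    gev = lapply(result$group_fits, `[[`, "gev"),
    tanova_p = lapply(result$tanova, `[[`, "p"),
    anova_interaction_p = lapply(result$anova, function(a) a$p[3]),
    schema_version = 1)
  jsonlite::write_json(summary_json, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}

# order-stable hash of the configuration for provenance stamping
config_hash <- function(config) {
  s <- paste(utils::capture.output(utils::str(unclass(config))),
             collapse = "\n")
  # small polynomial rolling hash; stdlib-only, stable across sessions
  h <- 17
  for (ch in utf8ToInt(s)) h <- (h * 131 + ch) %% 2147483647
  sprintf("%08x", h)
}
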