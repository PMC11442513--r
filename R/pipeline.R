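#' Pipeline run configuration
#'
#' Bundles every stage's settings with the master seed and the band
#' definitions. Bands must be non-overlapping and lie within the analysis
#' grid.
#'
#' @param mode `"synthetic"` (generate a cohort) or `"files"` (read
#'   recordings from `input_dir`).
#' @param seed master seed for generation, surrogates and statistics.
#' @param n_subjects,hemispheres_per_subject cohort size (synthetic mode).
#' @param duration_s,fs recording length and generation rate (synthetic
#'   mode).
#' @param cohort a [cohort_config()].
#' @param preprocess a [preprocess_config()].
#' @param freqs analysis frequency grid (Hz).
#' @param n_cycles Morlet wavelet cycles.
#' @param bands named list of band ranges.
#' @param pairs list of structure pairs to analyze.
#' @param measures subset of `c("power", "icoh", "wpli", "granger")`.
#' @param n_surrogates surrogate count per pair for the coupling null.
#' @param input_dir directory of native-format recordings (files mode).
#' @param severity_file CSV with `subject_id`, `severity` (files mode).
#' @return list of class `bg_run_config`.
#' @export
run_config <- function(mode = c("synthetic", "files"), seed = 1,
                       n_subjects = 10, hemispheres_per_subject = 2,
                       duration_s = 180, fs = 1000,
                       cohort = cohort_config(),
                       preprocess = preprocess_config(),
                       freqs = default_freqs(), n_cycles = 7,
                       bands = BG_BANDS,
                       pairs = list(c("STR", "GPi"), c("STR", "GPe"),
                                    c("GPe", "GPi")),
                       measures = c("power", "icoh", "wpli", "granger"),
                       n_surrogates = 200,
                       input_dir = NULL, severity_file = NULL) {
  mode <- match.arg(mode)
  cfg <- as.list(environment())
  bmat <- do.call(rbind, bands)
  if (any(bmat[, 1] >= bmat[, 2])) stopf("band limits must be increasing")
  if (nrow(bmat) > 1) {
    o <- order(bmat[, 1])
    b <- bmat[o, , drop = FALSE]
    if (any(b[-1, 1] <= b[-nrow(b), 2])) stopf("bands must not overlap")
  }
  if (min(bmat) < min(freqs) || max(bmat) > max(freqs)) {
    stopf("bands must lie within the analysis grid [%g, %g] Hz",
          min(freqs), max(freqs))
  }
  class(cfg) <- "bg_run_config"
  cfg
}

# conditioned + epoched + wavelet-transformed channels per structure
hemisphere_tfrs <- function(rec, cfg) {
  chans <- if (rec$bipolar) {
    lapply(seq_len(nrow(rec$samples)), function(i) {
      structure(list(pair = c(i, i), labels = rec$contacts[i],
                     samples = rec$samples[i, ],
                     structure = unname(rec$contact_structure[i]),
                     fs = rec$fs),
                class = "bg_bipolar")
    })
  } else {
    derive_bipolar(rec)
  }
  retained <- assign_structures(chans)
  out <- list()
  for (s in names(retained)) {
    x <- condition(retained[[s]], cfg = cfg$preprocess)
    ep <- epoch(x, cfg$preprocess$epoch_length_s)
    out[[s]] <- morlet_transform(ep, cfg$freqs, cfg$n_cycles)
  }
  out
}

# frequency-bin selector covering all configured bands
band_bins <- function(freqs, bands) {
  sel <- rep(FALSE, length(freqs))
  for (b in bands) sel <- sel | (freqs >= b[1] & freqs <= b[2])
  sel
}

#' Analyze one hemisphere recording
#'
#' Runs montage derivation, structure assignment, conditioning, epoching,
#' the wavelet transform, normalized power spectra with peak detection,
#' and the configured coupling measures with epoch-shuffle surrogates for
#' every configured structure pair present in the recording. When
#' `"granger"` is among the measures, the STR-GPi pair additionally gets
#' time-reversed-corrected Granger spectra and the bin-wise directionality
#' designation (gated on surrogate-significant coupling).
#'
#' @param rec a `bg_recording`.
#' @param cfg a [run_config()].
#' @param seed seed for the surrogate draws.
#' @return list with `spectra`, `peaks`, `pairs` (per-pair measures) and
#'   `designation`.
#' @export
analyze_hemisphere <- function(rec, cfg = run_config(), seed = NULL) {
  tfrs <- hemisphere_tfrs(rec, cfg)
  spectra <- lapply(tfrs, power_spectrum, bands = cfg$bands)
  peaks <- lapply(spectra, function(sp) {
    lapply(names(cfg$bands), function(b) detect_peak(sp, cfg$bands[[b]]))
  })
  for (s in names(peaks)) names(peaks[[s]]) <- names(cfg$bands)
  pair_res <- list()
  designation <- NULL
  want <- intersect(c("icoh", "wpli"), cfg$measures)
  seeds <- derive_seeds(seed %||% 0L, length(cfg$pairs))
  for (pi in seq_along(cfg$pairs)) {
    pr <- cfg$pairs[[pi]]
    if (!all(pr %in% names(tfrs))) next
    key <- paste(pr, collapse = "_")
    cs <- cross_spectrum(tfrs[[pr[1]]], tfrs[[pr[2]]])
    res <- list(pair = pr, freqs = cs$freqs)
    if ("icoh" %in% cfg$measures) {
      res$icoh <- imaginary_coherence(cs)
      for (b in names(cfg$bands)) {
        res[[paste0("icoh_", b)]] <- band_mean(res$icoh, cs$freqs,
                                               cfg$bands[[b]], abs = TRUE)
      }
    }
    if ("wpli" %in% cfg$measures) {
      res$wpli <- wpli(cs)
      for (b in names(cfg$bands)) {
        res[[paste0("wpli_", b)]] <- band_mean(res$wpli, cs$freqs,
                                               cfg$bands[[b]])
      }
    }
    if (length(want) > 0 && cfg$n_surrogates > 0) {
      sel <- band_bins(cfg$freqs, cfg$bands)
      sur <- shuffle_surrogate(tfr_subset_freqs(tfrs[[pr[1]]], sel),
                               tfr_subset_freqs(tfrs[[pr[2]]], sel),
                               n_surrogates = cfg$n_surrogates,
                               seed = if (is.null(seed)) NULL else seeds[pi],
                               measures = want)
      res$surrogate <- sur
      for (b in names(cfg$bands)) {
        if ("icoh" %in% want) {
          obs <- res[[paste0("icoh_", b)]]
          null_bm <- apply(sur$icoh, 1, band_mean, freqs = sur$freqs,
                           band = cfg$bands[[b]], abs = TRUE)
          res[[paste0("icoh_", b, "_shuffled")]] <- mean(null_bm)
          res[[paste0("icoh_", b, "_p95")]] <- unname(stats::quantile(null_bm, 0.95))
          res[[paste0("icoh_", b, "_significant")]] <-
            obs > res[[paste0("icoh_", b, "_p95")]]
        }
        if ("wpli" %in% want) {
          null_w <- apply(sur$wpli, 1, band_mean, freqs = sur$freqs,
                          band = cfg$bands[[b]])
          res[[paste0("wpli_", b, "_shuffled")]] <- mean(null_w)
          res[[paste0("wpli_", b, "_p95")]] <- unname(stats::quantile(null_w, 0.95))
        }
      }
    }
    if ("granger" %in% cfg$measures && identical(sort(pr), c("GPi", "STR"))) {
      # orient so that fwd = STR -> GPi
      cs_g <- if (pr[1] == "STR") cs else cross_spectrum(tfrs[["STR"]],
                                                         tfrs[["GPi"]])
      g <- granger_time_reversed(cs_g)
      res$granger <- g
      gate <- res$icoh_lf_significant %||% NULL
      designation <- directionality_designation(
        g$fwd_corrected, g$rev_corrected, g$freqs, band = cfg$bands$lf,
        coupling_significant = gate)
    }
    pair_res[[key]] <- res
  }
  list(subject_id = rec$subject_id, hemisphere = rec$hemisphere,
       structures = names(tfrs), spectra = spectra, peaks = peaks,
       pairs = pair_res, designation = designation)
}

# flatten one hemisphere analysis into a single data.frame row
hemisphere_row <- function(h, bands) {
  row <- data.frame(subject_id = h$subject_id, hemisphere = h$hemisphere,
                    stringsAsFactors = FALSE)
  for (s in c("STR", "GPe", "GPi")) {
    for (b in names(bands)) {
      row[[paste0("power_", s, "_", b)]] <-
        if (s %in% names(h$spectra)) h$spectra[[s]]$band_means[[b]] else NA_real_
      pk <- if (s %in% names(h$peaks)) h$peaks[[s]][[b]] else NULL
      row[[paste0("peak_", s, "_", b)]] <-
        if (!is.null(pk)) pk$freq_hz else NA_real_
    }
  }
  for (key in c("STR_GPi", "STR_GPe", "GPe_GPi")) {
    pr <- h$pairs[[key]]
    for (b in names(bands)) {
      for (m in c("icoh", "wpli")) {
        nm <- paste0(m, "_", b)
        row[[paste0(m, "_", key, "_", b)]] <-
          if (!is.null(pr) && !is.null(pr[[nm]])) pr[[nm]] else NA_real_
        shuf <- paste0(m, "_", b, "_shuffled")
        row[[paste0(m, "_", key, "_", b, "_shuffled")]] <-
          if (!is.null(pr) && !is.null(pr[[shuf]])) pr[[shuf]] else NA_real_
      }
    }
  }
  if (!is.null(h$designation)) {
    row$striatal_driving <- h$designation$striatal_driving
    row$n_bins_str <- h$designation$n_bins_str
    row$n_bins_gpi <- h$designation$n_bins_gpi
    g <- h$pairs$STR_GPi$granger
    row$granger_str_gpi_lf <- band_mean(g$fwd_corrected, g$freqs, bands$lf)
    row$granger_gpi_str_lf <- band_mean(g$rev_corrected, g$freqs, bands$lf)
  }
  row
}

#' Run the full cohort analysis
#'
#' Applies [analyze_hemisphere()] to every recording, assembles the
#' hemisphere-level table, averages estimates across hemispheres to one
#' row per subject, joins severity scores and computes the
#' severity-correlation battery (per-structure low-frequency and beta
#' power; per-pair low-frequency and beta coupling), FDR-corrected within
#' the power and coupling families.
#'
#' @param cohort a `bg_cohort`, or `recordings` + `subjects` supplied
#'   separately.
#' @param cfg a [run_config()].
#' @return list with `hemispheres` (data.frame), `subjects` (data.frame
#'   with severity), `correlations` (data.frame), `analyses` (per
#'   hemisphere, detail retained only when `keep_detail`).
#' @param keep_detail retain the full per-hemisphere analysis objects.
#' @export
run_cohort_analysis <- function(cohort, cfg = run_config(),
                                keep_detail = FALSE) {
  recs <- cohort$recordings
  seeds <- derive_seeds(cfg$seed, length(recs))
  analyses <- vector("list", length(recs))
  rows <- vector("list", length(recs))
  for (i in seq_along(recs)) {
    h <- analyze_hemisphere(recs[[i]], cfg, seed = seeds[i])
    rows[[i]] <- hemisphere_row(h, cfg$bands)
    if (keep_detail) analyses[[i]] <- h
  }
  hemis <- do.call(rbind, rows)
  subj <- aggregate_hemispheres(hemis)
  subj <- merge(subj, cohort$subjects, by = "subject_id", all.x = TRUE)
  estimates <- c(outer(c("power_STR_", "power_GPe_", "power_GPi_"),
                       names(cfg$bands), paste0),
                 c(outer(c("icoh_STR_GPi_", "icoh_STR_GPe_", "icoh_GPe_GPi_"),
                         names(cfg$bands), paste0)))
  estimates <- intersect(estimates, names(subj))
  estimates <- estimates[colSums(!is.na(subj[estimates])) >= 3]
  cor_seeds <- derive_seeds(cfg$seed + 1L, length(estimates))
  cors <- do.call(rbind, lapply(seq_along(estimates), function(k) {
    est <- estimates[k]
    ct <- correlate_with_severity(subj, est, seed = cor_seeds[k])
    data.frame(estimate = est, r = ct$statistic, p = ct$p_value,
               n = ct$n, normality_ok = ct$normality_ok,
               stringsAsFactors = FALSE)
  }))
  if (!is.null(cors)) {
    fam <- ifelse(grepl("^power", cors$estimate), "power", "coupling")
    cors$p_fdr <- NA_real_
    for (f in unique(fam)) {
      cors$p_fdr[fam == f] <- fdr_correct(cors$p[fam == f])$adjusted
    }
  }
  list(hemispheres = hemis, subjects = subj, correlations = cors,
       analyses = if (keep_detail) analyses else NULL)
}

#' One-command end-to-end run
#'
#' Executes synth (or file input), montage, preprocessing, spectral,
#' connectivity and statistics stages in order, writing all tables,
#' figures, a JSON summary and the resolved configuration (with seed) to
#' the output directory. Any stage failure halts with a stage-named
#' error; the run directory carries an `INCOMPLETE` marker until the run
#' finishes.
#'
#' @param cfg a [run_config()].
#' @param out_dir output directory.
#' @param figures write PNG figures (default `TRUE`).
#' @return the [run_cohort_analysis()] result, invisibly.
#' @export
run_all <- function(cfg = run_config(), out_dir = "bgosc_run",
                    figures = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  marker <- file.path(out_dir, "INCOMPLETE")
  file.create(marker)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stopf("stage '%s' failed: %s", name, conditionMessage(e))
    })
  }
  cohort <- stage("input", {
    if (cfg$mode == "synthetic") {
      generate_cohort(cfg$n_subjects, cfg$hemispheres_per_subject,
                      cfg$cohort, seed = cfg$seed,
                      duration_s = cfg$duration_s, fs = cfg$fs)
    } else {
      read_cohort_dir(cfg$input_dir, cfg$severity_file)
    }
  })
  message(sprintf("[input] %d recordings, %d subjects",
                  length(cohort$recordings), nrow(cohort$subjects)))
  res <- stage("analysis", run_cohort_analysis(cohort, cfg,
                                               keep_detail = figures))
  message(sprintf("[analysis] %d hemisphere rows, %d correlations",
                  nrow(res$hemispheres), nrow(res$correlations)))
  stage("output", {
    utils::write.csv(res$hemispheres, file.path(out_dir, "hemispheres.csv"),
                     row.names = FALSE)
    utils::write.csv(res$subjects, file.path(out_dir, "subjects.csv"),
                     row.names = FALSE)
    utils::write.csv(res$correlations, file.path(out_dir, "correlations.csv"),
                     row.names = FALSE)
    summary <- list(
      seed = cfg$seed,
      n_recordings = length(cohort$recordings),
      n_subjects = nrow(res$subjects),
      striatal_driving = if ("striatal_driving" %in% names(res$hemispheres))
        sum(res$hemispheres$striatal_driving, na.rm = TRUE) else NULL,
      correlations = res$correlations
    )
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE,
                         dataframe = "rows")
    cfg_out <- cfg
    cfg_out$cohort <- cfg$cohort[setdiff(names(cfg$cohort), "drop_hemispheres")]
    jsonlite::write_json(cfg_out, file.path(out_dir, "resolved_config.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  })
  if (figures) {
    stage("figures", write_run_figures(res, cfg, out_dir))
  }
  file.remove(marker)
  message(sprintf("[done] outputs in %s", out_dir))
  invisible(res)
}

#' Read a directory of native-format recordings as a cohort
#'
#' @param input_dir directory of `.bin` + `.bin.json` pairs (or `.tsv`).
#' @param severity_file CSV with columns `subject_id`, `severity`.
#' @return a `bg_cohort`-shaped list (without ground truths).
#' @export
read_cohort_dir <- function(input_dir, severity_file = NULL) {
  if (is.null(input_dir) || !dir.exists(input_dir)) {
    stopf("input_dir does not exist: %s", input_dir %||% "<NULL>")
  }
  files <- list.files(input_dir, pattern = "\\.(bin|tsv)$", full.names = TRUE)
  if (length(files) == 0) stopf("no recordings found in %s", input_dir)
  recs <- lapply(files, read_recording)
  subjects <- data.frame(
    subject_id = unique(vapply(recs, `[[`, character(1), "subject_id")))
  if (!is.null(severity_file)) {
    sev <- utils::read.csv(severity_file)
    if (!all(c("subject_id", "severity") %in% names(sev))) {
      stopf("severity file must have subject_id and severity columns")
    }
    subjects <- merge(subjects, sev, by = "subject_id", all.x = TRUE)
  } else {
    subjects$severity <- NA_real_
  }
  structure(list(recordings = recs, truths = NULL, subjects = subjects,
                 seed = NA_integer_, config = NULL),
            class = "bg_cohort")
}

# group-level figures: spectra per structure, coupling vs surrogate,
# direction counts, severity scatterplots
write_run_figures <- function(res, cfg, out_dir) {
  analyses <- res$analyses
  if (is.null(analyses)) return(invisible(NULL))
  cols <- c(STR = "#7B3294", GPi = "#008837", GPe = "#0571B0")
  grDevices::png(file.path(out_dir, "fig_spectra.png"), 1200, 500, res = 120)
  graphics::par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
  for (s in c("STR", "GPi", "GPe")) {
    specs <- lapply(analyses, function(h) h$spectra[[s]])
    specs <- specs[!vapply(specs, is.null, logical(1))]
    if (length(specs) == 0) next
    fr <- specs[[1]]$freqs
    pm <- vapply(specs, `[[`, numeric(length(fr)), "power")
    graphics::matplot(fr, pm, type = "l", lty = 1, col = "grey80",
                      xlab = "Frequency (Hz)", ylab = "Normalized power (a.u.)",
                      main = s, xlim = c(1, 45), log = "y")
    graphics::lines(fr, rowMeans(pm), col = cols[[s]], lwd = 2)
  }
  grDevices::dev.off()
  grDevices::png(file.path(out_dir, "fig_coupling.png"), 1200, 500, res = 120)
  graphics::par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
  for (key in c("STR_GPi", "STR_GPe", "GPe_GPi")) {
    prs <- lapply(analyses, function(h) h$pairs[[key]])
    prs <- prs[!vapply(prs, is.null, logical(1))]
    if (length(prs) == 0 || is.null(prs[[1]]$icoh)) next
    fr <- prs[[1]]$freqs
    im <- vapply(prs, function(p) abs(p$icoh), numeric(length(fr)))
    graphics::matplot(fr, im, type = "l", lty = 1, col = "grey80",
                      xlab = "Frequency (Hz)", ylab = "|iCOH|",
                      main = gsub("_", "-", key), xlim = c(1, 45))
    graphics::lines(fr, rowMeans(im), lwd = 2,
                    col = cols[[strsplit(key, "_")[[1]][2]]])
    sur <- prs[[1]]$surrogate
    if (!is.null(sur)) {
      sm <- rowMeans(vapply(prs, function(p)
        colMeans(abs(p$surrogate$icoh)), numeric(length(sur$freqs))))
      graphics::lines(sur$freqs, sm, col = "grey40", lwd = 2, lty = 2)
    }
  }
  grDevices::dev.off()
  grDevices::png(file.path(out_dir, "fig_severity.png"), 1000, 500, res = 120)
  graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  subj <- res$subjects
  for (est in c("power_GPi_lf", "icoh_STR_GPi_lf")) {
    if (!est %in% names(subj) || all(is.na(subj$severity))) next
    graphics::plot(subj[[est]], subj$severity, pch = 19,
                   xlab = est, ylab = "Severity (BFMDRS)")
    r <- res$correlations
    ri <- if (is.null(r)) r else r[r$estimate == est, ]
    if (!is.null(ri) && nrow(ri) == 1) {
      graphics::abline(stats::lm(subj$severity ~ subj[[est]]), col = "red")
      graphics::mtext(sprintf("R = %.2f, p = %.3g", ri$r, ri$p), cex = 0.8)
    }
  }
  grDevices::dev.off()
  invisible(NULL)
}
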