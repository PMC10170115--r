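#' Gestational age bins
#'
#' Maps postconceptional weeks to the three analysis bins used throughout:
#' 13-15, 18-20 and 21-23 PCW.
#'
#' @param pcw Numeric vector of postconceptional weeks.
#' @return Character vector of bin labels (`NA` outside the bins).
#' @export
age_bin <- function(pcw) {
  dplyr::case_when(pcw >= 13 & pcw <= 15 ~ "13-15",
                   pcw >= 18 & pcw <= 20 ~ "18-20",
                   pcw >= 21 & pcw <= 23 ~ "21-23",
                   TRUE ~ NA_character_)
}

#' End-to-end wholemount analysis
#'
#' For each manifest row, runs the full wholemount chain on synthetic
#' tissue: generate a soma pattern (csr / striped / grid), assign subtype
#' labels, render a z-stack, segment it back to a point pattern, compute the
#' CIF and z-score difference against hard-core CSR nulls, estimate stripe
#' periodicity, and measure subtype fractions. Per-sample failures are
#' warned and skipped; the run fails only if every sample fails. Reruns with
#' the same manifest and seed are identical.
#'
#' @param manifest Data frame with one row per sample. Recognized columns:
#'   `sample` (id; default row number), `mode` (`"csr"`, `"striped"`,
#'   `"grid"`), `n` (default 300), `region`, `pcw` (optional metadata).
#' @param n_sim Null samples per z-score (default 100).
#' @param subtype_fractions Named marker fractions applied to every sample
#'   (default `c(calr = 0.4)`); `NULL` to skip subtype counting.
#' @param render Render and re-segment each field (default `TRUE`); with
#'   `FALSE` the statistics run on the generated coordinates directly.
#' @param L,bin,smooth_sd,d_min CIF / null settings (see [compute_cif()]).
#' @param margin Border inset for generated patterns when rendering.
#' @param output_dir If given, per-sample and summary CSVs are written
#'   there.
#' @param seed Master seed; per-sample substreams are derived from it.
#' @return List of class `ens_run`: `samples` (one row per sample),
#'   `summary` (means by region x age bin), `failures`, `config`.
#' @export
run_wholemount_pipeline <- function(manifest,
                                    n_sim = 100,
                                    subtype_fractions = c(calr = 0.4),
                                    render = TRUE,
                                    L = 200, bin = 4, smooth_sd = 20,
                                    d_min = 5, margin = 10,
                                    output_dir = NULL,
                                    seed = 1) {
  manifest <- as_tibble(manifest)
  if (nrow(manifest) == 0) abort("empty manifest")
  if (!"mode" %in% names(manifest)) abort("manifest needs a `mode` column")
  if (!"sample" %in% names(manifest)) manifest$sample <- seq_len(nrow(manifest))
  if (!"n" %in% names(manifest)) manifest$n <- 300L
  seeds <- derive_seeds(seed, nrow(manifest))
  config <- list(n_sim = n_sim, subtype_fractions = subtype_fractions,
                 render = render, L = L, bin = bin, smooth_sd = smooth_sd,
                 d_min = d_min, margin = margin, seed = seed)
  rows <- list(); failures <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    res <- tryCatch(
      wholemount_one(row, seeds[i], config),
      error = function(e) e)
    if (inherits(res, "error")) {
      warn(sprintf("sample %s failed: %s", row$sample, conditionMessage(res)))
      failures[[length(failures) + 1L]] <-
        tibble(sample = row$sample, error = conditionMessage(res))
    } else {
      rows[[length(rows) + 1L]] <- res
    }
  }
  if (length(rows) == 0) abort("all samples failed")
  samples <- dplyr::bind_rows(rows)
  grouping <- intersect(c("region", "age_bin"), names(samples))
  summary <- if (length(grouping) > 0) {
    dplyr::summarise(dplyr::group_by(samples, dplyr::across(dplyr::all_of(grouping))),
                     dplyr::across(dplyr::where(is.numeric), mean),
                     .groups = "drop")
  } else {
    dplyr::summarise(samples, dplyr::across(dplyr::where(is.numeric), mean))
  }
  out <- structure(list(samples = samples, summary = summary,
                        failures = dplyr::bind_rows(failures),
                        config = config),
                   class = "ens_run")
  if (!is.null(output_dir)) write_run(out, output_dir, "wholemount")
  out
}

wholemount_one <- function(row, sub_seed, cfg) {
  pat <- generate_point_pattern(row$mode, n = row$n, d_min = cfg$d_min,
                                margin = cfg$margin, seed = sub_seed)
  frac_row <- NULL
  if (cfg$render) {
    if (!is.null(cfg$subtype_fractions))
      pat <- assign_subtypes(pat, cfg$subtype_fractions, seed = sub_seed + 1L)
    stk <- render_wholemount(pat, seed = sub_seed + 2L)
    seg <- segment_neurons(stk)
    pat_meas <- as_pattern(seg)
    if (!is.null(cfg$subtype_fractions)) {
      frac_row <- purrr::map_dfr(names(cfg$subtype_fractions), function(m) {
        sf <- subtype_fraction(
          image_stack(stk$channels["huc"], stk$pixel_size, stk$z_step),
          image_stack(stk$channels[m], stk$pixel_size, stk$z_step))
        tibble(marker = m, fraction = sf$fraction)
      })
    }
  } else {
    pat_meas <- pat
  }
  zs <- zscore_difference(pat_meas, L = cfg$L, bin = cfg$bin,
                          smooth_sd = cfg$smooth_sd, d_min = cfg$d_min,
                          n_sim = cfg$n_sim, seed = sub_seed + 3L)
  per <- stripe_periodicity(zs$cif)
  out <- tibble(sample = row$sample, mode = row$mode, n = row$n,
                n_detected = nrow(pat_meas),
                statistic = zs$statistic, z_diff = zs$z_diff,
                band_lo = zs$band[1], band_hi = zs$band[2],
                outside_band = zs$z_diff > zs$band[2],
                period = per$period, period_significant = per$significant,
                seed = sub_seed,
                provenance = rlang::hash(list(row, cfg)))
  if ("region" %in% names(row)) out$region <- row$region
  if ("pcw" %in% names(row)) out$age_bin <- age_bin(row$pcw)
  if (!is.null(frac_row)) {
    wide <- tidyr::pivot_wider(frac_row, names_from = "marker",
                               values_from = "fraction",
                               names_prefix = "fraction_")
    out <- dplyr::bind_cols(out, wide)
  }
  out
}

#' End-to-end motility analysis
#'
#' For each manifest row, simulates a staged recording, computes its STM,
#' detects and classifies contractions, and pairs baseline with TTX
#' recordings of the same sample for the condition comparison. Unpaired
#' treated recordings are summarized unpaired with a warning.
#'
#' @param manifest Data frame with columns `sample`, `stage` (a
#'   [motility_scenario()] stage), `condition` (`"baseline"` or `"ttx"`),
#'   and optional `region`.
#' @param duration_s Recording length per video (default 600).
#' @param seed Master seed.
#' @param ... Passed to [motility_scenario()].
#' @return List of class `ens_run`: `segments` (one summary row per
#'   recording), `comparisons` (one row per baseline/ttx pair), `config`.
#' @export
run_motility_pipeline <- function(manifest, duration_s = 600, seed = 1, ...) {
  manifest <- as_tibble(manifest)
  if (nrow(manifest) == 0) abort("empty manifest")
  need <- c("sample", "stage", "condition")
  if (!all(need %in% names(manifest)))
    abort("manifest needs columns sample, stage, condition")
  seeds <- derive_seeds(seed, nrow(manifest))
  stms <- list(); rows <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    vid <- motility_scenario(row$stage, ttx = row$condition == "ttx",
                             duration_s = duration_s, seed = seeds[i], ...)
    stm <- compute_stm(vid)
    ev <- detect_contractions(stm)
    cls <- classify_pattern(ev, stm)
    stms[[paste(row$sample, row$condition)]] <- stm
    rows[[i]] <- dplyr::bind_cols(
      tibble(sample = row$sample, stage = row$stage,
             condition = row$condition, seed = seeds[i]), cls)
  }
  segments <- dplyr::bind_rows(rows)
  comparisons <- list()
  for (s in unique(manifest$sample)) {
    b <- stms[[paste(s, "baseline")]]
    t <- stms[[paste(s, "ttx")]]
    if (!is.null(b) && !is.null(t)) {
      comparisons[[length(comparisons) + 1L]] <-
        dplyr::bind_cols(tibble(sample = s), compare_conditions(b, t))
    } else if (!is.null(t)) {
      warn(sprintf("sample %s has a TTX recording but no baseline; left unpaired", s))
    }
  }
  structure(list(segments = segments,
                 comparisons = dplyr::bind_rows(comparisons),
                 config = list(duration_s = duration_s, seed = seed)),
            class = "ens_run")
}

#' @export
print.ens_run <- function(x, ...) {
  nm <- if (!is.null(x$samples)) "samples" else "segments"
  cat(sprintf("<ens_run> %d %s\n", nrow(x[[nm]]), nm))
  print(x[[nm]])
  invisible(x)
}

write_run <- function(run, dir, prefix) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(run$samples %||% run$segments,
                   file.path(dir, paste0(prefix, "_samples.csv")),
                   row.names = FALSE)
  if (!is.null(run$summary))
    utils::write.csv(run$summary,
                     file.path(dir, paste0(prefix, "_summary.csv")),
                     row.names = FALSE)
  jsonlite::write_json(run$config,
                       file.path(dir, paste0(prefix, "_config.json")),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(run)
}
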