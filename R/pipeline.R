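# End-to-end orchestration: simulate study samples from ground-truth
# parameters, fit the threshold model per condition, apply the gender
# relevance rule, and emit limit and comparison tables.

#' Pipeline configuration
#'
#' Collects every tunable of an end-to-end run. Defaults reproduce the study
#' conditions: significance level 0.05, quantile 0.75, a 70%-male worker
#' group, exact-on-imputed fitting, and the published parameter table as the
#' simulator's ground truth.
#'
#' @param seed Root seed; all stage randomness derives from it.
#' @param q Limit quantile.
#' @param x_G Male fraction of the target group.
#' @param sigma Significance level for the gender-relevance rule.
#' @param fit_mode `"exact"` or `"interval"`.
#' @param family Distribution family to fit.
#' @param scale Roster scale factor in (0, 1]; shrinks group sizes for quick
#'   runs (each gender is floored at 3 subjects per group).
#' @param locations Location ids to include (default: all 24 measured).
#' @param noise_sd Measurement noise SD in measurand units.
#' @param repeats_pinching,repeats_impact Repeats per subject (impact repeats
#'   are per pendulum mass series, pooled downstream).
#' @param truth Ground-truth parameter tibble (default [threshold_params()]).
#' @param out_dir Output directory or `NULL` for no files.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1, q = 0.75, x_G = 0.7, sigma = 0.05,
                            fit_mode = c("exact", "interval"),
                            family = "log-logistic", scale = 1,
                            locations = NULL, noise_sd = 0.5,
                            repeats_pinching = 3, repeats_impact = 1,
                            truth = threshold_params(), out_dir = NULL) {
  fit_mode <- match.arg(fit_mode)
  stopifnot(sigma > 0, sigma < 1, q > 0, q < 1, x_G >= 0, x_G <= 1,
            scale > 0, scale <= 1)
  structure(list(seed = seed, q = q, x_G = x_G, sigma = sigma,
                 fit_mode = fit_mode, family = family, scale = scale,
                 locations = locations %||% unique(truth$location_id),
                 noise_sd = noise_sd, repeats_pinching = repeats_pinching,
                 repeats_impact = repeats_impact, truth = truth,
                 out_dir = out_dir),
            class = "pipeline_config")
}

cell_seed <- function(root, location_id, cond_index) {
  as.integer((abs(root) %% 20000L) * 100000L + location_id * 100L + cond_index)
}

#' Simulate the sample of one test condition
#'
#' Draws per-subject ground-truth thresholds from the condition's expanded
#' log-logistic law and pushes them through the condition's measurement
#' process: noisy switch-event readings of a quasi-static ramp for pinching
#' (exact observations), or stepped pendulum staircases per pendulum mass for
#' impact (interval-censored observations). Repeats are imputed, averaged per
#' subject, and assembled into a sample.
#'
#' @param roster Subject tibble from [sample_population()].
#' @param beta0,beta1,alpha Ground-truth parameters of the condition.
#' @param location_id,load_type,contact_type Condition labels.
#' @param repeats Repeats per subject (per mass for impact).
#' @param noise_sd Measurement noise SD.
#' @param head Use the reduced head velocity step for staircases.
#' @param seed Seed for this cell.
#' @return A sample tibble (see [assemble_sample()]).
#' @export
simulate_condition_sample <- function(roster, beta0, beta1, alpha,
                                      location_id, load_type, contact_type,
                                      repeats = 1, noise_sd = 0.5,
                                      head = location_id %in% c(1, 2, 3, 5),
                                      seed = 1) {
  local_rng(seed)
  if (location_id == 9) roster <- dplyr::filter(roster, .data$gender_code == 1)
  proto <- default_protocol(beta0, beta1, alpha, load_type = load_type,
                            head = head, noise_sd = noise_sd)
  thr <- draw_threshold(nrow(roster), beta0, beta1, alpha,
                        gender_code = roster$gender_code)
  obs <- purrr::map_dfr(seq_len(nrow(roster)), function(i) {
    if (load_type == "pinching") {
      y <- pmax(thr[i] + rnorm(repeats, 0, noise_sd), 1e-6)
      tibble::tibble(subject_id = roster$subject_id[i],
                     gender_code = roster$gender_code[i],
                     L = y, R = y, censor_type = "exact")
    } else {
      purrr::map_dfr(seq_len(repeats), function(r) {
        st <- simulate_pendulum_staircase(thr[i], proto)
        iv <- intervals_from_staircase(
          tibble::tibble(series = st$mass, peak = pmax(st$peak_measured, 0),
                         pain = st$pain))
        iv$subject_id <- roster$subject_id[i]
        iv$gender_code <- roster$gender_code[i]
        iv[, c("subject_id", "gender_code", "L", "R", "censor_type")]
      })
    }
  })
  means <- average_repeats(impute_midpoint(obs))
  assemble_sample(means, location_id, load_type, contact_type)
}

#' Run the full limit-derivation pipeline
#'
#' Simulates every configured body location x condition cell from the ground
#' truth, fits the expanded threshold model, applies the two-condition gender
#' relevance rule per location (refitting with `beta1 = 0` where gender is
#' not relevant), and builds the quantile-limit and standard-style rounded
#' tables. Deterministic for a fixed root seed; when `out_dir` is set, the
#' samples, fitted parameters, limit tables and a run log are written as CSV
#' and JSON with the seed recorded.
#'
#' @param config A [pipeline_config()].
#' @return A list: `samples`, `fits` (tibble with `fit` list-column),
#'   `relevance`, `limits`, `limits_rounded`, `w_bar`, `config`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  truth <- dplyr::filter(config$truth,
                         .data$location_id %in% config$locations)
  cmap <- group_condition_map()
  rosters <- group_rosters()
  log_lines <- character()
  say <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
  }

  pops <- purrr::pmap(rosters, function(group, n_female, n_male) {
    # floor each gender at 3 so every cell (including the male-only pectoral
    # muscle) stays fittable at small roster scales
    nf <- max(3L, ceiling(n_female * config$scale))
    nm <- max(3L, ceiling(n_male * config$scale))
    sample_population(nf + nm, nm / (nf + nm),
                      seed = cell_seed(config$seed, 99,
                                       match(group, rosters$group)),
                      group = group)
  })
  names(pops) <- rosters$group

  conds <- dplyr::distinct(truth, .data$load_type, .data$contact_type)
  fits <- purrr::map_dfr(seq_len(nrow(truth)), function(i) {
    row <- truth[i, ]
    ci <- match(paste(row$load_type, row$contact_type),
                paste(conds$load_type, conds$contact_type))
    grp <- cmap$group[cmap$location_id == row$location_id &
                        cmap$load_type == row$load_type &
                        cmap$contact_type == row$contact_type]
    roster <- pops[[grp]]
    smp <- simulate_condition_sample(
      roster, row$beta0, row$beta1, row$alpha, row$location_id,
      row$load_type, row$contact_type,
      repeats = if (row$load_type == "pinching") config$repeats_pinching
                else config$repeats_impact,
      noise_sd = config$noise_sd,
      seed = cell_seed(config$seed, row$location_id, ci))
    mode <- if (row$load_type == "impact") config$fit_mode else "exact"
    single_gender <- length(unique(smp$gender_code)) < 2
    fit <- fit_aft(smp, family = config$family,
                   constrain_beta1_zero = single_gender, mode = mode)
    say("INFO sample loc=%d %s/%s group=%s n=%d censored=%d converged=%s",
        row$location_id, row$load_type, row$contact_type, grp, nrow(smp),
        sum(smp$censor_type != "exact"), fit$convergence)
    tibble::tibble(location_id = row$location_id,
                   location_name = row$location_name,
                   load_type = row$load_type, contact_type = row$contact_type,
                   units = row$units, n = nrow(smp),
                   p_value = fit$p_beta1 %||% NA_real_,
                   sample = list(smp), fit = list(fit))
  })

  # gender relevance per location, then constrained refits where not relevant
  relevance <- fits |>
    dplyr::group_by(.data$location_id) |>
    dplyr::summarise(relevant = {
      ps <- .data$p_value[!is.na(.data$p_value)]
      length(ps) > 0 && gender_relevance(ps, config$sigma)$relevant
    })
  fits <- dplyr::left_join(fits, relevance, by = "location_id")
  fits$fit <- purrr::pmap(list(fits$fit, fits$relevant, fits$sample,
                               fits$load_type),
                          function(f, rel, smp, lt) {
    # refit with beta1 = 0 only where gender is not relevant and the original
    # fit was unconstrained; single-gender samples stay constrained either way
    if (f$constrained || isTRUE(rel)) return(f)
    mode <- if (lt == "impact") config$fit_mode else "exact"
    fit_aft(smp, family = config$family, constrain_beta1_zero = TRUE,
            mode = mode)
  })

  params <- fits |>
    dplyr::mutate(beta0 = purrr::map_dbl(.data$fit, "beta0"),
                  beta1 = purrr::map_dbl(.data$fit, "beta1"),
                  alpha = purrr::map_dbl(.data$fit, "alpha")) |>
    dplyr::select(dplyr::all_of(c("location_id", "location_name", "load_type",
                                  "contact_type", "units", "n", "beta0",
                                  "beta1", "alpha", "relevant")), "fit")
  limits <- build_limit_table(params, q = config$q, x_G = config$x_G)
  # the neck estimate needs the temple; without it, round without appending
  rounded <- if (2 %in% limits$location_id) {
    round_for_standard(limits)
  } else {
    out <- limits
    out$limit <- round_half_away(out$y_B, 10)
    out$estimated <- FALSE
    out
  }
  w_bar <- suppressWarnings(relative_difference(limits, "blunt")$w_bar)
  say("INFO limits rows=%d rounded_rows=%d w_bar_blunt=%.2f",
      nrow(limits), nrow(rounded), w_bar)

  result <- list(samples = dplyr::select(fits, -"fit"),
                 fits = params, relevance = relevance, limits = limits,
                 limits_rounded = rounded, w_bar = w_bar, config = config,
                 log = log_lines)
  if (!is.null(config$out_dir)) write_pipeline_outputs(result, config$out_dir)
  invisible(result)
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(seed = result$config$seed, q = result$config$q,
               x_G = result$config$x_G, sigma = result$config$sigma,
               fit_mode = result$config$fit_mode, scale = result$config$scale)
  jsonlite::write_json(meta, file.path(out_dir, "run_config.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  samples <- tidyr::unnest(result$samples[, c("location_id", "load_type",
                                              "contact_type", "sample")],
                           "sample", names_repair = "minimal")
  samples <- samples[, !duplicated(names(samples))]
  samples$R_bar <- ifelse(is.infinite(samples$R_bar), "inf",
                          format(samples$R_bar, digits = 10))
  write.csv(samples, file.path(out_dir, "samples.csv"), row.names = FALSE)
  fits <- dplyr::select(result$fits, -"fit")
  write.csv(fits, file.path(out_dir, "fits.csv"), row.names = FALSE)
  jsonlite::write_json(fits, file.path(out_dir, "fits.json"), digits = NA)
  write.csv(result$limits, file.path(out_dir, "limits.csv"), row.names = FALSE)
  write.csv(result$limits_rounded, file.path(out_dir, "limits_rounded.csv"),
            row.names = FALSE)
  writeLines(result$log, file.path(out_dir, "run.log"))
  invisible(out_dir)
}
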