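#' Configuration for a full circumplex construct-validation study
#'
#' @param data Study data: a [make_study_fixture()] result or a list with the
#'   same shape (`responses`, `scale_scores`, `validity_scores`, `rules`,
#'   `keys` where `keys` maps each surface label to its octant-keyed
#'   [scoring_key()] and `validity` to the infrequency key).
#' @param surfaces Surface labels to analyze (must be names in `data$keys`).
#' @param scales External scale labels to profile; default every scale-score
#'   column in the data.
#' @param pairs Data frame of comparison pairs (columns `a`, `b`); default
#'   none.
#' @param rules Optional [screening_rules()] overriding `data$rules`.
#' @param cutoffs An [ssm_cutoffs()].
#' @param boot A [bootstrap_config()]; its seed is ignored in favor of
#'   deterministic per-task seeds derived from `seed`.
#' @param randall_mode `"exhaustive"` or `"sampled"` structure check.
#' @param seed Master seed; the whole run is a pure function of data,
#'   config, and this seed.
#' @return A `study_config` list.
#' @export
study_config <- function(data, surfaces = NULL, scales = NULL, pairs = NULL,
                         rules = NULL, cutoffs = ssm_cutoffs(),
                         boot = bootstrap_config(), randall_mode = "exhaustive",
                         seed = 1) {
  if (is.null(surfaces)) {
    surfaces <- setdiff(names(data$keys), "validity")
  }
  if (!all(surfaces %in% names(data$keys))) {
    stop("every surface needs a scoring key in data$keys", call. = FALSE)
  }
  if (is.null(scales)) {
    scales <- setdiff(colnames(data$scale_scores), "participant_id")
  }
  if (!all(scales %in% colnames(data$scale_scores))) {
    stop("config references undeclared scales", call. = FALSE)
  }
  if (!is.null(pairs)) {
    pairs <- as.data.frame(pairs)
    if (!all(c(pairs$a, pairs$b) %in% scales)) {
      stop("comparison pairs must reference declared scales", call. = FALSE)
    }
  }
  structure(list(data = data, surfaces = surfaces, scales = scales,
                 pairs = pairs, rules = if (is.null(rules)) data$rules else rules,
                 cutoffs = cutoffs, boot = boot, randall_mode = randall_mode,
                 seed = as.integer(seed)),
            class = "study_config")
}

## Deterministic per-task seed stream derived from the master seed.
task_seed <- function(seed, i) as.integer((seed + 7919 * i) %% 2147483629L)

#' Run the full screening-to-convergence study workflow
#'
#' Executes, in order: protocol screening; octant and scale scoring of the
#' retained protocols; octant internal consistencies (omega-total) and
#' descriptives; the randomization test of circumplex order relations per
#' surface; SSM fitting with bootstrapped CIs per scale per surface;
#' interpretation gating; paired bootstrap contrasts for the configured
#' pairs; convergence calls; and plot-ready coordinates (amplitude and angle
#' CIs per scale, with a dashed flag for non-prototypical profiles). All
#' randomness flows deterministically from `config$seed`.
#'
#' @param config A [study_config()].
#' @return A `study_report` list with elements `exclusions`, `reliability`,
#'   `randall`, `ssm`, `contrasts`, `convergence`, `plot_coords`, `meta`.
#' @export
run_study <- function(config) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  data <- config$data

  screened <- stage("screen", screen_protocols(data$responses,
                                               data$validity_scores,
                                               config$rules))
  retained_ids <- as.character(screened$retained[[1L]])

  octants <- stage("score", {
    lapply(stats::setNames(config$surfaces, config$surfaces), function(s) {
      score_octants(screened$retained, data$keys[[s]])
    })
  })
  scale_tab <- as.data.frame(data$scale_scores)
  rownames(scale_tab) <- scale_tab$participant_id
  scale_tab <- scale_tab[retained_ids, config$scales, drop = FALSE]

  reliability <- stage("reliability", {
    rows <- list()
    for (s in config$surfaces) {
      key <- data$keys[[s]]
      items <- as_response_matrix(screened$retained)
      for (code in names(key$octant_map)) {
        rel <- omega_total(items[, key$octant_map[[code]], drop = FALSE],
                           scale = code)
        sc <- octants[[s]][, code]
        rows[[length(rows) + 1L]] <- tibble::tibble(
          surface = s, scale = code, omega_t = rel$omega_t,
          estimator = rel$estimator, n = sum(!is.na(sc)),
          mean = mean(sc, na.rm = TRUE), sd = stats::sd(sc, na.rm = TRUE),
          min = min(sc, na.rm = TRUE), max = max(sc, na.rm = TRUE))
      }
    }
    do.call(rbind, rows)
  })

  randall <- stage("randall", {
    rows <- list()
    for (i in seq_along(config$surfaces)) {
      s <- config$surfaces[i]
      R <- stats::cor(octants[[s]], use = "pairwise.complete.obs")
      res <- randall_test(R, mode = config$randall_mode,
                          seed = task_seed(config$seed, 100L + i))
      rows[[i]] <- tibble::tibble(surface = s,
                                  n_predictions = res$n_predictions,
                                  n_met = res$n_met,
                                  correspondence_index = res$correspondence_index,
                                  p_value = res$p_value,
                                  exhaustive = res$exhaustive)
    }
    do.call(rbind, rows)
  })

  boots <- list()
  ssm_tab <- stage("ssm", {
    rows <- list(); ti <- 0L
    for (s in config$surfaces) {
      for (sc in config$scales) {
        ti <- ti + 1L
        cfg <- bootstrap_config(config$boot$n_boot, config$boot$level,
                                seed = task_seed(config$seed, 1000L + ti))
        bt <- bootstrap_ssm(scale_tab[[sc]], octants[[s]],
                            config = cfg, scale = sc, surface = s)
        boots[[paste(s, sc, sep = "|")]] <- bt
        gate <- apply_cutoffs(bt$point, config$cutoffs)
        ci <- bt$ci
        get_ci <- function(p, w) ci[[w]][ci$parameter == p]
        rows[[length(rows) + 1L]] <- tibble::tibble(
          surface = s, scale = sc,
          e = bt$point$e, x = bt$point$x, y = bt$point$y,
          a = bt$point$a, theta = bt$point$theta, r2 = bt$point$r2,
          e_lower = get_ci("e", "lower"), e_upper = get_ci("e", "upper"),
          x_lower = get_ci("x", "lower"), x_upper = get_ci("x", "upper"),
          y_lower = get_ci("y", "lower"), y_upper = get_ci("y", "upper"),
          a_lower = get_ci("a", "lower"), a_upper = get_ci("a", "upper"),
          theta_lower = get_ci("theta", "lower"),
          theta_upper = get_ci("theta", "upper"),
          elevated = gate$elevated, prototypical = gate$prototypical,
          differentiated = gate$differentiated,
          angle_interpretable = gate$angle_interpretable,
          B_effective = bt$B_effective)
      }
    }
    do.call(rbind, rows)
  })

  contrast_objs <- list()
  contrasts <- stage("contrast", {
    if (is.null(config$pairs) || nrow(config$pairs) == 0L) {
      NULL
    } else {
      rows <- list(); ti <- 0L
      for (s in config$surfaces) {
        for (p in seq_len(nrow(config$pairs))) {
          ti <- ti + 1L
          a <- config$pairs$a[p]; b <- config$pairs$b[p]
          cfg <- bootstrap_config(config$boot$n_boot, config$boot$level,
                                  seed = task_seed(config$seed, 2000L + ti))
          ct <- contrast_profiles(scale_tab[[a]], scale_tab[[b]], octants[[s]],
                                  config = cfg, cutoffs = config$cutoffs,
                                  labels = c(a, b), surface = s)
          contrast_objs[[paste(s, a, b, sep = "|")]] <- ct
          d <- ct$delta
          get_d <- function(p, w) d[[w]][d$parameter == p]
          rows[[length(rows) + 1L]] <- tibble::tibble(
            surface = s, scale_a = a, scale_b = b,
            delta_e = get_d("e", "estimate"),
            delta_e_lower = get_d("e", "lower"), delta_e_upper = get_d("e", "upper"),
            delta_x = get_d("x", "estimate"),
            delta_x_lower = get_d("x", "lower"), delta_x_upper = get_d("x", "upper"),
            delta_y = get_d("y", "estimate"),
            delta_y_lower = get_d("y", "lower"), delta_y_upper = get_d("y", "upper"),
            delta_a = get_d("a", "estimate"),
            delta_a_lower = get_d("a", "lower"), delta_a_upper = get_d("a", "upper"),
            delta_theta = get_d("theta", "estimate"),
            delta_theta_lower = get_d("theta", "lower"),
            delta_theta_upper = get_d("theta", "upper"),
            e_significant = get_d("e", "significant"),
            x_significant = get_d("x", "significant"),
            y_significant = get_d("y", "significant"),
            a_significant = get_d("a", "significant"),
            theta_significant = get_d("theta", "significant"),
            angle_status = ct$angle_status,
            distinct_angle = ct$distinct_angle)
        }
      }
      do.call(rbind, rows)
    }
  })

  convergence <- stage("convergence", {
    if (is.null(contrasts)) NULL else
      evaluate_convergence(contrasts, cutoffs = config$cutoffs)
  })

  plot_coords <- stage("plot", {
    cbind(ssm_tab[, c("surface", "scale", "a", "theta",
                      "a_lower", "a_upper", "theta_lower", "theta_upper")],
          tibble::tibble(dashed = !ssm_tab$prototypical))
  })

  structure(list(exclusions = list(ledger = screened$ledger,
                                   counts = screened$counts),
                 reliability = reliability, randall = randall, ssm = ssm_tab,
                 contrasts = contrasts, convergence = convergence,
                 plot_coords = plot_coords,
                 boots = boots, contrast_objs = contrast_objs,
                 meta = list(surfaces = config$surfaces, scales = config$scales,
                             n_retained = length(retained_ids),
                             seed = config$seed, level = config$boot$level,
                             n_boot = config$boot$n_boot)),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report> n retained = ", x$meta$n_retained,
      "; surfaces: ", paste(x$meta$surfaces, collapse = ", "),
      "; ", length(x$meta$scales), " scales\n", sep = "")
  cat("exclusions: ", paste(names(x$exclusions$counts), x$exclusions$counts,
                            sep = " = ", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Classify angular convergence of contrasted scale pairs
#'
#' A pair is *convergent* when its angular-difference CI contains zero,
#' *statistically distinct but overlapping* when the CI excludes zero but the
#' point difference is smaller than the angular distinctness heuristic (half
#' an octant by default), *distinct* when the CI excludes zero and the
#' difference is at least that large, and *excluded* when gating suppressed
#' the angular contrast.
#'
#' @param contrasts A contrast table (the `contrasts` element of a
#'   [run_study()] report, or any data frame with columns `delta_theta`,
#'   `delta_theta_lower`, `delta_theta_upper`, optionally `angle_status`), or
#'   a list of [contrast_profiles()] results.
#' @param cutoffs An [ssm_cutoffs()] supplying `angle_distinct_min`.
#' @return Tibble with the pair identifiers and a `call` column.
#' @export
evaluate_convergence <- function(contrasts, cutoffs = ssm_cutoffs()) {
  if (is.list(contrasts) && !is.data.frame(contrasts) &&
      all(vapply(contrasts, inherits, logical(1), "ssm_contrast"))) {
    contrasts <- do.call(rbind, lapply(contrasts, function(ct) {
      d <- ct$delta
      tibble::tibble(surface = ct$surface,
                     scale_a = ct$scale_pair[1], scale_b = ct$scale_pair[2],
                     delta_theta = d$estimate[d$parameter == "theta"],
                     delta_theta_lower = d$lower[d$parameter == "theta"],
                     delta_theta_upper = d$upper[d$parameter == "theta"],
                     angle_status = ct$angle_status)
    }))
  }
  contrasts <- as.data.frame(contrasts)
  status <- if ("angle_status" %in% names(contrasts)) {
    contrasts$angle_status
  } else {
    rep("ok", nrow(contrasts))
  }
  call <- character(nrow(contrasts))
  for (i in seq_len(nrow(contrasts))) {
    if (status[i] != "ok" || is.na(contrasts$delta_theta[i])) {
      call[i] <- "excluded"
    } else {
      lo <- contrasts$delta_theta_lower[i]; hi <- contrasts$delta_theta_upper[i]
      excludes0 <- lo > 0 || hi < 0
      if (!excludes0) {
        call[i] <- "convergent"
      } else if (abs(contrasts$delta_theta[i]) < cutoffs$angle_distinct_min) {
        call[i] <- "statistically distinct but overlapping"
      } else {
        call[i] <- "distinct"
      }
    }
  }
  id_cols <- intersect(c("surface", "scale_a", "scale_b",
                         "delta_theta", "delta_theta_lower", "delta_theta_upper"),
                       names(contrasts))
  out <- tibble::as_tibble(contrasts[, id_cols, drop = FALSE])
  out$call <- call
  out
}

## Round report columns the way published SSM tables print: parameters to 2
## decimals, angles to 1, R2 to 3.
round_report_df <- function(df) {
  for (nm in names(df)) {
    if (!is.numeric(df[[nm]])) next
    digits <- if (grepl("theta", nm)) 1L else if (grepl("r2", nm)) 3L
              else if (nm %in% c("n", "n_predictions", "n_met", "B_effective")) NA
              else 2L
    if (!is.na(digits)) df[[nm]] <- round(df[[nm]], digits)
  }
  df
}

#' Serialize a study report to CSV files and JSON
#'
#' Writes one CSV per report table (rounded the way published SSM tables
#' print: parameters to 2 decimals, angles to 1, R2 to 3) and a single
#' `report.json` carrying every table at full precision.
#'
#' @param report A [run_study()] result.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tabs <- list(exclusion_ledger = report$exclusions$ledger,
               reliability = report$reliability,
               randall = report$randall,
               ssm_parameters = report$ssm,
               contrasts = report$contrasts,
               convergence = report$convergence,
               plot_coordinates = report$plot_coords)
  for (nm in names(tabs)) {
    if (is.null(tabs[[nm]])) next
    utils::write.csv(round_report_df(as.data.frame(tabs[[nm]])),
                     file.path(dir, paste0(nm, ".csv")), row.names = FALSE)
  }
  json <- list(meta = report$meta,
               exclusion_counts = as.list(report$exclusions$counts),
               exclusion_ledger = report$exclusions$ledger,
               reliability = report$reliability,
               randall = report$randall,
               ssm = report$ssm,
               contrasts = report$contrasts,
               convergence = report$convergence,
               plot_coordinates = report$plot_coords)
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  invisible(dir)
}
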