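#' Pool arm-level means into the all-arm mean
#'
#' Size-weighted mean: `sum(n_a * mean_a) / sum(n_a)`. Used both when
#' summarizing records and when pooling published arm-level table rows.
#'
#' @param means numeric arm means.
#' @param ns integer arm sizes.
#' @return pooled mean.
#' @export
pooled_mean <- function(means, ns) {
  stopifnot(length(means) == length(ns), all(ns >= 0), sum(ns) > 0)
  sum(means * ns) / sum(ns)
}

#' Pool arm-level category counts into the all-arm percentage
#'
#' @param counts integer counts of the category per arm.
#' @param ns integer arm sizes (denominators).
#' @return list with `count`, `n`, `percent` (unrounded).
#' @export
pooled_percent <- function(counts, ns) {
  stopifnot(length(counts) == length(ns), all(counts >= 0),
            all(counts <= ns))
  list(count = sum(counts), n = sum(ns),
       percent = 100 * sum(counts) / sum(ns))
}

#' Baseline descriptive table (Table-1 style)
#'
#' Arm-wise and pooled summaries of the baseline wave: n, age mean and SD,
#' and count (%) for the categorical demographics. Percentages are
#' computed from counts at render time; the pooled mean equals the
#' size-weighted mean of arm means.
#'
#' @param records participant records; only the baseline wave is used
#'   (follow-up rows, if present, are ignored).
#' @return list of class `kap_table1` with one element per
#'   characteristic; each a data.frame with one row per arm plus a
#'   `pooled` row.
#' @export
table1 <- function(records) {
  b <- records[records$wave == "baseline", ]
  if (nrow(b) == 0L) stop("no baseline records", call. = FALSE)
  arms <- unique(b$arm)
  empty <- vapply(arms, function(a) sum(b$arm == a) == 0L, logical(1))
  if (any(empty)) {
    warning("empty arm(s) omitted: ", paste(arms[empty], collapse = ", "),
            call. = FALSE)
    arms <- arms[!empty]
  }
  per_arm <- function(f) vapply(arms, function(a) f(b[b$arm == a, ]),
                                numeric(1))
  ns <- per_arm(nrow)

  cont_row <- function(x_of) {
    m <- per_arm(function(d) mean(x_of(d)))
    s <- per_arm(function(d) stats::sd(x_of(d)))
    data.frame(arm = c(arms, "pooled"),
               n = c(ns, sum(ns)),
               mean = c(m, pooled_mean(m, ns)),
               sd = c(s, stats::sd(x_of(b))),
               stringsAsFactors = FALSE, row.names = NULL)
  }
  cat_row <- function(pred) {
    cnt <- per_arm(function(d) sum(pred(d)))
    pooled <- pooled_percent(cnt, ns)
    data.frame(arm = c(arms, "pooled"),
               n = c(ns, sum(ns)),
               count = c(cnt, pooled$count),
               percent = 100 * c(cnt, pooled$count) / c(ns, sum(ns)),
               stringsAsFactors = FALSE, row.names = NULL)
  }

  structure(list(
    age = cont_row(function(d) d$age),
    age_below_40 = cat_row(function(d) d$age < 40),
    male = cat_row(function(d) d$sex == "male"),
    primary_or_below = cat_row(function(d) d$education == "primary_or_below"),
    below_poverty = cat_row(function(d) d$income == "below_poverty"),
    prior_training = cat_row(function(d) d$prior_training)
  ), class = "kap_table1")
}

#' @export
print.kap_table1 <- function(x, ...) {
  for (nm in names(x)) {
    cat("--", nm, "--\n")
    df <- x[[nm]]
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], round, 1)
    print(df, row.names = FALSE)
  }
  invisible(x)
}

#' Render an effect-estimate table to a markdown report
#'
#' @param effects a `kap_effects` data.frame.
#' @param path output file path (markdown).
#' @return `path`, invisibly.
#' @export
write_effects_report <- function(effects, path) {
  lines <- c("# Intervention effect estimates", "",
             "Coefficients are percent-point differences versus the",
             "reference arm; outcomes are percent of maximum.", "",
             "| outcome | variant | contrast | B | 95% CI | n |",
             "|---|---|---|---|---|---|")
  fmt <- sprintf("| %s | %s | %s | %.1f | (%.1f, %.1f) | %d |",
                 effects$outcome, effects$variant, effects$contrast,
                 effects$estimate, effects$conf_low, effects$conf_high,
                 effects$n)
  writeLines(c(lines, fmt), path)
  invisible(path)
}

#' Forest plot of intervention effect estimates
#'
#' Coefficient-and-CI intervals grouped by outcome and model variant,
#' with a zero reference line.
#'
#' @param effects a `kap_effects` data.frame (>= 1 row).
#' @param file optional output path (e.g. `.png` or `.pdf`); when `NULL`
#'   the ggplot object is returned unsaved.
#' @param width,height device size in inches.
#' @return the ggplot object, invisibly when saved.
#' @export
forest_plot <- function(effects, file = NULL, width = 7, height = 5) {
  if (is.null(effects) || nrow(effects) == 0L)
    stop("no estimates to plot", call. = FALSE)
  effects$label <- paste(effects$outcome, effects$contrast, sep = ": ")
  p <- ggplot2::ggplot(effects,
                       ggplot2::aes(x = estimate, y = label,
                                    color = variant)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, color = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = conf_low, xmax = conf_high),
                             position = ggplot2::position_dodge(0.5)) +
    ggplot2::labs(x = "Effect (percent points vs reference)", y = NULL,
                  color = "model") +
    ggplot2::theme_minimal()
  if (!is.null(file)) {
    ggplot2::ggsave(file, p, width = width, height = height, dpi = 150)
    return(invisible(p))
  }
  p
}

#' Run the full pipeline: simulate (or read), score, estimate, report
#'
#' In simulation mode a synthetic cohort is generated from `config`; in
#' input mode an existing participants CSV is read. The stage outputs
#' (cohort CSV, ground-truth latents CSV in simulation mode, scores CSV,
#' estimates CSV, descriptive table, consort summary, run log with seed)
#' are written to `out_dir`. A rerun with the same config and seed
#' reproduces the same artifacts.
#'
#' @param out_dir output directory (created if needed).
#' @param seed integer seed (required in simulation mode).
#' @param config a `kap_simconfig` (simulation mode) or `NULL`.
#' @param input_csv participants CSV path (input mode) or `NULL`.
#' @param codebook a `kap_codebook`.
#' @param variants model variants to fit.
#' @param make_plot also write a forest plot (`forest.png`).
#' @return invisible list with the in-memory artifacts
#'   (`records`, `scores`, `effects`, `table1`, `consort`, `paths`).
#' @export
run_pipeline <- function(out_dir, seed = NULL, config = simulation_config(),
                         input_csv = NULL, codebook = default_codebook(),
                         variants = c("primary", "adjusted", "combined"),
                         make_plot = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    log_lines <<- c(log_lines, sprintf("stage=%s ok", name))
    res
  }

  if (is.null(input_csv)) {
    if (is.null(seed)) stop("simulation mode requires a seed", call. = FALSE)
    cohort <- stage("simulate", generate_cohort(config, seed = seed,
                                                codebook = codebook))
    records <- cohort$records
    write_records(records, file.path(out_dir, "cohort.csv"))
    write_records(cohort$latents, file.path(out_dir, "latents.csv"))
    yaml::write_yaml(list(seed = seed, n_clusters = config$n_clusters,
                          arms = as.list(config$arms), icc = config$icc,
                          dropout_rate = config$dropout_rate),
                     file.path(out_dir, "config.yml"))
  } else {
    records <- stage("read", read_records(input_csv, codebook))
  }
  log_lines <- c(log_lines,
                 sprintf("stage=records rows=%d", nrow(records)))

  scores <- stage("score", score_records(records, codebook))
  write_scores(scores, file.path(out_dir, "scores.csv"))
  log_lines <- c(log_lines, sprintf("stage=score rows=%d", nrow(scores)))

  t1 <- stage("table1", table1(records))
  utils::capture.output(print(t1),
                        file = file.path(out_dir, "table1.txt"))

  base_n <- table(records$arm[records$wave == "baseline"])
  fu_n <- table(factor(records$arm[records$wave == "followup"],
                       levels = names(base_n)))
  consort <- stage("consort",
                   consort_flow(as.integer(base_n),
                                as.integer(base_n) - as.integer(fu_n)))
  utils::capture.output(print(consort),
                        file = file.path(out_dir, "consort.txt"))

  effects <- NULL
  if (length(unique(records$arm)) >= 2 &&
      all(c("baseline", "followup") %in% records$wave)) {
    effects <- stage("estimate", do.call(rbind, lapply(variants, function(v)
      fit_all_outcomes(scores, variant = v))))
    write_records(effects, file.path(out_dir, "estimates.csv"))
    write_effects_report(effects, file.path(out_dir, "estimates.md"))
    log_lines <- c(log_lines,
                   sprintf("stage=estimate rows=%d", nrow(effects)))
    if (make_plot)
      forest_plot(effects[effects$variant == "primary" &
                            grepl("vs", effects$contrast), ],
                  file.path(out_dir, "forest.png"))
  }

  writeLines(c(sprintf("seed=%s", ifelse(is.null(seed), "NA", seed)),
               log_lines), file.path(out_dir, "run.log"))
  invisible(list(records = records, scores = scores, effects = effects,
                 table1 = t1, consort = consort, out_dir = out_dir))
}
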