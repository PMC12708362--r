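#' Randomize clusters to arms with (near-)equal allocation
#'
#' Uniformly random balanced assignment: with `n` clusters and `k` arms,
#' each arm receives `floor(n/k)` or `ceiling(n/k)` clusters. Deterministic
#' given the seed.
#'
#' @param cluster_ids character vector of cluster labels.
#' @param arms character vector of arm labels (default the trial's three).
#' @param seed integer RNG seed (required for reproducibility).
#' @return named character vector: `cluster_id -> arm`.
#' @export
randomize_clusters <- function(cluster_ids, arms = arm_levels(), seed) {
  if (missing(seed) || is.null(seed))
    stop("a seed is required for reproducible randomization", call. = FALSE)
  n <- length(cluster_ids)
  k <- length(arms)
  if (n < k)
    stop("fewer clusters (", n, ") than arms (", k, ")", call. = FALSE)
  if (anyDuplicated(cluster_ids))
    stop("duplicate cluster ids", call. = FALSE)
  slots <- rep(arms, length.out = n)  # near-equal: first arms get the extras
  set.seed(seed)
  stats::setNames(sample(slots), cluster_ids)
}

#' Variance inflation (design effect) for cluster randomization
#'
#' @param m average cluster size (>= 1).
#' @param icc intraclass correlation in \[0, 1).
#' @return `1 + (m - 1) * icc`.
#' @examples design_effect(45, 0.4)  # 18.6
#' @export
design_effect <- function(m, icc) {
  stopifnot(all(m >= 1), all(icc >= 0), all(icc < 1))
  1 + (m - 1) * icc
}

#' Sample size for a two-sample comparison of means in a cluster design
#'
#' Unadjusted per-arm n from the normal-approximation two-sample formula
#' \eqn{n = (z_{1-\alpha/2} + z_{power})^2 (\sigma_1^2 + \sigma_2^2) /
#' \Delta^2}; the cluster design effect is then applied self-consistently
#' with cluster size `m = n / clusters_per_arm`, i.e.
#' \eqn{n = n_0 (1 - icc) / (1 - n_0 \, icc / k)}, which has a positive
#' solution only when `clusters_per_arm > n0 * icc`. With few clusters and
#' a high ICC no feasible n exists; this is reported as a structured
#' infeasibility, not an exception. Finally the n is inflated for
#' anticipated dropout by `1 / (1 - dropout)` and rounded up.
#'
#' @param mean1,sd1,mean2,sd2 group means and SDs (SDs > 0, means differ).
#' @param power target power (default 0.8).
#' @param alpha two-sided significance level (default 0.05).
#' @param icc intraclass correlation (default 0: individual randomization).
#' @param clusters_per_arm number of clusters per arm (used when icc > 0).
#' @param dropout anticipated dropout fraction in \[0, 1).
#' @return list: `n_unadjusted` (per arm, before inflation),
#'   `feasible`, `n_per_arm`, `n_total` (3 arms not assumed; total is
#'   `2 * n_per_arm` for the two compared arms), `design_effect`,
#'   `message`.
#' @export
sample_size_two_means <- function(mean1, sd1, mean2, sd2,
                                  power = 0.8, alpha = 0.05,
                                  icc = 0, clusters_per_arm = NULL,
                                  dropout = 0) {
  stopifnot(sd1 > 0, sd2 > 0, mean1 != mean2,
            power > 0, power < 1, alpha > 0, alpha < 1,
            icc >= 0, icc < 1, dropout >= 0, dropout < 1)
  z <- stats::qnorm(1 - alpha / 2) + stats::qnorm(power)
  delta <- mean1 - mean2
  n0 <- z^2 * (sd1^2 + sd2^2) / delta^2
  out <- list(n_unadjusted = ceiling(n0), feasible = TRUE,
              design_effect = 1, message = "")
  n <- n0
  if (icc > 0) {
    if (is.null(clusters_per_arm))
      stop("clusters_per_arm required when icc > 0", call. = FALSE)
    k <- clusters_per_arm
    denom <- 1 - n0 * icc / k
    if (denom <= 0) {
      out$feasible <- FALSE
      out$n_per_arm <- NA_integer_
      out$n_total <- NA_integer_
      out$message <- sprintf(
        paste("infeasible: with %d clusters per arm and ICC %.2f the",
              "self-consistent design-effect equation n = n0 * (1 + (n/k - 1)",
              "* icc) has no positive solution (requires clusters_per_arm >",
              "n0 * icc = %.1f)"),
        k, icc, n0 * icc)
      return(out)
    }
    n <- n0 * (1 - icc) / denom
    out$design_effect <- design_effect(n / k, icc)
  }
  n <- n / (1 - dropout)
  out$n_per_arm <- ceiling(n)
  out$n_total <- 2L * out$n_per_arm
  out
}

#' Inflate a computed sample size for anticipated dropout
#'
#' @param n sample size before dropout inflation.
#' @param dropout anticipated dropout fraction in \[0, 1).
#' @return ceiling of `n / (1 - dropout)`.
#' @examples inflate_for_dropout(470, 0.13)  # 541
#' @export
inflate_for_dropout <- function(n, dropout) {
  stopifnot(dropout >= 0, dropout < 1)
  ceiling(n / (1 - dropout))
}

#' CONSORT-style participant flow accounting
#'
#' All percentages are recomputed from the integer counts at call time
#' (1-decimal rounding); nothing is carried as a stored percentage.
#'
#' @param enrolled named integer vector of enrolled participants per arm.
#' @param lost named integer vector of losses to follow-up per arm (same
#'   names as `enrolled`).
#' @param compliance optional named list; each element a list with
#'   `noncompliant` and `denominator` counts (e.g. training
#'   non-completion out of those offered training).
#' @return list of class `kap_consort`: per-arm and total enrolled, lost,
#'   completers, `response_rate` (percent, 1 decimal), and compliance
#'   percentages.
#' @export
consort_flow <- function(enrolled, lost, compliance = list()) {
  enrolled <- as.integer(enrolled)
  lost <- as.integer(lost)
  if (any(enrolled < 0) || any(lost < 0))
    stop("negative counts", call. = FALSE)
  if (length(lost) != length(enrolled))
    stop("enrolled and lost must align per arm", call. = FALSE)
  if (any(lost > enrolled))
    stop("losses exceed enrolled in some arm", call. = FALSE)
  completers <- enrolled - lost
  total_enrolled <- sum(enrolled)
  total_completers <- sum(completers)
  comp <- lapply(compliance, function(x) {
    stopifnot(x$noncompliant >= 0, x$denominator > 0,
              x$noncompliant <= x$denominator)
    list(noncompliant = as.integer(x$noncompliant),
         denominator = as.integer(x$denominator),
         percent = round(100 * x$noncompliant / x$denominator, 1))
  })
  structure(list(
    enrolled = enrolled, lost = lost, completers = completers,
    total_enrolled = total_enrolled, total_lost = sum(lost),
    total_completers = total_completers,
    response_rate = round(100 * total_completers / total_enrolled, 1),
    compliance = comp
  ), class = "kap_consort")
}

#' @export
print.kap_consort <- function(x, ...) {
  cat("Participant flow\n")
  cat("  enrolled:  ", sum(x$enrolled), " (",
      paste(x$enrolled, collapse = "/"), ")\n", sep = "")
  cat("  lost:      ", x$total_lost, "\n", sep = "")
  cat("  completed: ", x$total_completers, " (response rate ",
      x$response_rate, "%)\n", sep = "")
  for (nm in names(x$compliance)) {
    ci <- x$compliance[[nm]]
    cat("  ", nm, ": ", ci$noncompliant, "/", ci$denominator, " (",
        ci$percent, "%)\n", sep = "")
  }
  invisible(x)
}
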