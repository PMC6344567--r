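#' Compute the RNA-seq fusion fraction of a sample
#'
#' The fusion fraction (FF) is a per-sample genomic-instability proxy:
#' validated-fusion evidence normalized per 10 million mapped paired reads.
#' Only INTER and INTRA fusions count; TICs arise from read-through
#' transcription of neighbouring genes, not chromosomal breaks, and are
#' excluded from the sum. Two readings of the evidence are supported:
#' `mode = "span_sum"` (default) sums the caller span counts over validated
#' INTER+INTRA fusions, `mode = "fusion_count"` counts the fusions
#' themselves; both are divided by `mapped_paired_reads / 1e7`.
#'
#' @param validated Output of [validate_fusions()] carrying `fusion_class`
#'   (from [classify_fusions()]), `span_count` and `validated`.
#' @param mapped_paired_reads Positive number of mapped paired reads.
#' @param sample_id Sample label, default `"sample"`.
#' @param mode `"span_sum"` or `"fusion_count"`.
#' @param min_recommended_reads Emit a warning when `mapped_paired_reads`
#'   falls below this depth (default 40 million, under which de novo
#'   assembly misses prominent fusion transcripts).
#' @return One-row tibble: `sample_id`, `n_validated` (INTER+INTRA),
#'   `span_total`, `mapped_paired_reads`, `fusion_fraction`.
#' @export
fusion_fraction <- function(validated, mapped_paired_reads,
                            sample_id = "sample",
                            mode = c("span_sum", "fusion_count"),
                            min_recommended_reads = 4e7) {
  mode <- match.arg(mode)
  if (!is.numeric(mapped_paired_reads) || length(mapped_paired_reads) != 1L ||
      is.na(mapped_paired_reads) || mapped_paired_reads <= 0) {
    abort("mapped_paired_reads must be a single positive number")
  }
  if (mapped_paired_reads < min_recommended_reads) {
    warn(sprintf(paste0("sample %s has %.1f M mapped paired reads; below the ",
                        "recommended minimum of %.0f M, assembly may miss ",
                        "prominent fusion transcripts"),
                 sample_id, mapped_paired_reads / 1e6, min_recommended_reads / 1e6))
  }
  if (!"fusion_class" %in% names(validated)) {
    abort("validated table lacks fusion_class; run classify_fusions() first")
  }
  hit <- validated[validated$validated &
                     validated$fusion_class %in% c("INTER", "INTRA"), ]
  span_total <- sum(hit$span_count)
  numerator <- if (mode == "span_sum") span_total else nrow(hit)
  tibble(sample_id = sample_id,
         n_validated = nrow(hit),
         span_total = as.integer(span_total),
         mapped_paired_reads = mapped_paired_reads,
         fusion_fraction = numerator / (mapped_paired_reads / 1e7))
}

#' Flag samples with a high fusion fraction relative to controls
#'
#' A sample is high-FF when its fusion fraction strictly exceeds
#' `multiplier` times the control (normal osteoblast) fusion fraction; a
#' sample at exactly the multiple is not flagged.
#'
#' @param ff Numeric vector of sample fusion fractions.
#' @param control_ff Non-negative control fusion fraction.
#' @param multiplier Fold-change rule, default 2.
#' @return Logical vector.
#' @export
high_ff <- function(ff, control_ff, multiplier = 2) {
  stopifnot_scalar_number(control_ff, "control_ff", 0)
  stopifnot_scalar_number(multiplier, "multiplier", 0)
  ff > multiplier * control_ff
}

#' Kaplan-Meier survival stratification by fusion fraction
#'
#' Splits samples into `HIGH_FF` (`ff > threshold`, default 2.7; samples at
#' exactly the threshold go to `LOW_FF`) and `LOW_FF` groups, computes the
#' Kaplan-Meier product-limit survival estimate per group, and tests the
#' difference with the two-sample log-rank statistic (1 df chi-square),
#' all from the standard formulas. At each distinct event time the observed
#' group-1 events are compared with their hypergeometric expectation and
#' variance given the risk sets; the statistic is
#' `(sum(O1 - E1))^2 / sum(V1)`.
#'
#' @param records Tibble with columns `sample_id`, `time` (non-negative,
#'   e.g. months), `event` (logical or 0/1; `TRUE` = death/event observed),
#'   `ff` (fusion fraction) -- or a precomputed `group` column with values
#'   `HIGH_FF`/`LOW_FF`, in which case `ff` is not needed.
#' @param threshold FF split point, default 2.7.
#' @return An object of class `km_stratification`: a list with `curves`
#'   (tidy per-group step function: `group`, `time`, `n_risk`, `n_event`,
#'   `survival`), `chisq`, `p_value`, `df`, `observed`, `expected`,
#'   `threshold`, `groups`. Has [tidy()], [glance()] and [autoplot()]
#'   methods.
#' @export
km_stratify <- function(records, threshold = 2.7) {
  if (!"group" %in% names(records)) {
    if (!"ff" %in% names(records)) abort("records need an `ff` or `group` column")
    records$group <- ifelse(records$ff > threshold, "HIGH_FF", "LOW_FF")
  }
  if (any(is.na(records$time)) || any(records$time < 0)) {
    abort("survival times must be non-negative and non-missing")
  }
  records$event <- as.logical(records$event)
  groups <- c("HIGH_FF", "LOW_FF")
  n_by_group <- table(factor(records$group, levels = groups))
  if (any(n_by_group == 0L)) {
    abort(paste0("stratification needs at least one sample per group; empty: ",
                 paste(groups[n_by_group == 0L], collapse = ", ")))
  }

  # per-group product-limit estimate
  curves <- purrr::map(groups, function(g) {
    sub <- records[records$group == g, ]
    times <- sort(unique(sub$time[sub$event]))
    n_risk <- vapply(times, function(t) sum(sub$time >= t), numeric(1))
    n_event <- vapply(times, function(t) sum(sub$time == t & sub$event), numeric(1))
    surv <- cumprod(1 - n_event / n_risk)
    tibble(group = g,
           time = c(0, times), n_risk = c(nrow(sub), n_risk),
           n_event = c(0, n_event), survival = c(1, surv))
  }) |> bind_rows()

  # two-sample log-rank over pooled distinct event times
  event_times <- sort(unique(records$time[records$event]))
  o1 <- e1 <- v1 <- 0
  for (t in event_times) {
    at_risk <- records$time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & records$group == groups[1])
    d <- sum(records$time == t & records$event)
    d1 <- sum(records$time == t & records$event & records$group == groups[1])
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    if (n > 1) v1 <- v1 + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- if (v1 > 0) (o1 - e1)^2 / v1 else 0
  structure(list(curves = curves, chisq = chisq,
                 p_value = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
                 df = 1L,
                 observed = stats::setNames(c(o1, sum(records$event) - o1), groups),
                 expected = stats::setNames(c(e1, sum(records$event) - e1), groups),
                 threshold = threshold,
                 groups = stats::setNames(as.vector(n_by_group), groups)),
            class = "km_stratification")
}

#' @export
print.km_stratification <- function(x, ...) {
  cat("Kaplan-Meier stratification by fusion fraction (threshold ",
      x$threshold, ")\n", sep = "")
  cat(sprintf("  HIGH_FF n=%d, LOW_FF n=%d\n", x$groups[["HIGH_FF"]],
              x$groups[["LOW_FF"]]))
  cat(sprintf("  log-rank chi-square = %.4g on %d df, p = %.4g\n",
              x$chisq, x$df, x$p_value))
  invisible(x)
}

#' @rdname km_stratify
#' @param x,object A `km_stratification` object.
#' @param ... Unused.
#' @method tidy km_stratification
#' @export
tidy.km_stratification <- function(x, ...) {
  x$curves
}

#' @rdname km_stratify
#' @method glance km_stratification
#' @export
glance.km_stratification <- function(x, ...) {
  tibble(n_high = x$groups[["HIGH_FF"]], n_low = x$groups[["LOW_FF"]],
         observed_high = x$observed[["HIGH_FF"]],
         expected_high = x$expected[["HIGH_FF"]],
         statistic = x$chisq, df = x$df, p_value = x$p_value,
         threshold = x$threshold)
}

#' @rdname km_stratify
#' @method autoplot km_stratification
#' @export
autoplot.km_stratification <- function(object, ...) {
  ggplot2::ggplot(object$curves,
                  ggplot2::aes(x = .data$time, y = .data$survival,
                               colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time", y = "Survival probability", colour = NULL,
                  subtitle = sprintf("log-rank p = %.3g", object$p_value)) +
    ggplot2::theme_minimal()
}

#' Exon/intron read ratio for a transcription-induced chimera
#'
#' Quantifies the abundance of a read-through chimera relative to the total
#' transcription of its downstream gene: the mean depth over the first 10 nt
#' of the retained intron (chimera-only reads) divided by the mean depth
#' over the last 10 nt of the upstream shared exon (chimera plus native
#' transcripts).
#'
#' @param exon_depths Numeric vector of per-base depths over the terminal
#'   10 nt of the shared exon.
#' @param intron_depths Numeric vector of per-base depths over the first
#'   10 nt of the retained intron.
#' @param width Expected window width, default 10.
#' @return One-row tibble: `exon_mean_depth`, `intron_mean_depth`, `ratio`.
#' @export
tic_read_ratio <- function(exon_depths, intron_depths, width = 10) {
  if (length(exon_depths) != width || length(intron_depths) != width) {
    abort(sprintf("both windows must have exactly %d per-base depths", width))
  }
  if (any(exon_depths < 0) || any(intron_depths < 0)) abort("negative depth")
  exon_mean <- mean(exon_depths)
  intron_mean <- mean(intron_depths)
  if (exon_mean == 0) {
    abort("exon window has zero mean depth; chimera ratio is undefined")
  }
  tibble(exon_mean_depth = exon_mean, intron_mean_depth = intron_mean,
         ratio = intron_mean / exon_mean)
}
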