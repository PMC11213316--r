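#' Score called DMRs against known truth
#'
#' Two overlap criteria are supported. Equal overlap (EO): a call is a true
#' positive only if some true region has identical chromosome, start and end;
#' it measures whether a method recovers the exact extent of a region. Any
#' overlap (AO): a call is a true positive if its closed interval shares at
#' least one base pair with a true region.
#'
#' Counts follow the confusion-table margins of region benchmarking:
#' `TP` = number of true regions detected under the criterion, `FN` = `n_true
#' - TP`, `FP` = number of calls that qualify as true positives for no true
#' region, `TN` = `n_null - FP` where `n_null` is the number of null candidate
#' regions. A call overlapping two true regions credits both (affects FN, not
#' FP).
#'
#' @param called data frame of calls with columns `chrom`, `start`, `end`.
#' @param truth data frame of candidate regions with columns `chrom`, `start`,
#'   `end` and either a logical `is_true` or a `label` column where `"null"`
#'   marks null regions (anything else is a true DMR). True regions must not
#'   overlap one another within a chromosome.
#' @param criterion `"EO"` or `"AO"`.
#' @return List of class `region_confusion`: `criterion`, `TP`, `FP`, `FN`,
#'   `TN`, `n_true`, `n_null`, `n_calls`.
#' @export
classify_calls <- function(called, truth, criterion = c("EO", "AO")) {
  criterion <- match.arg(criterion)
  is_true <- if ("is_true" %in% names(truth)) as.logical(truth$is_true)
             else if ("label" %in% names(truth)) truth$label != "null"
             else stop("truth needs an is_true or label column")
  tr <- truth[is_true, , drop = FALSE]
  n_true <- nrow(tr); n_null <- sum(!is_true)
  n_calls <- nrow(called)
  if (n_true > 1L) {
    ov <- unlist(lapply(split(seq_len(n_true), tr$chrom), function(ii) {
      o <- order(tr$start[ii])
      s <- tr$start[ii][o]; e <- tr$end[ii][o]
      if (length(s) > 1L) any(s[-1] <= e[-length(e)] & TRUE) else FALSE
    }))
    if (any(ov)) stop("true regions overlap within a chromosome")
  }
  if (n_calls == 0L) {
    conf <- list(criterion = criterion, TP = 0L, FP = 0L, FN = n_true,
                 TN = n_null, n_true = n_true, n_null = n_null, n_calls = 0L)
    class(conf) <- "region_confusion"
    return(conf)
  }
  if (criterion == "EO") {
    ckey <- paste(called$chrom, called$start, called$end)
    tkey <- paste(tr$chrom, tr$start, tr$end)
    call_tp <- ckey %in% tkey
    true_hit <- tkey %in% ckey
  } else {
    call_tp <- logical(n_calls)
    true_hit <- logical(n_true)
    for (ch in unique(c(called$chrom, tr$chrom))) {
      ci <- which(called$chrom == ch)
      ti <- which(tr$chrom == ch)
      if (length(ci) && length(ti)) {
        call_tp[ci] <- .any_overlap(called$start[ci], called$end[ci],
                                    tr$start[ti], tr$end[ti])
        true_hit[ti] <- .any_overlap(tr$start[ti], tr$end[ti],
                                     called$start[ci], called$end[ci])
      }
    }
  }
  TP <- sum(true_hit)
  FP <- sum(!call_tp)
  conf <- list(criterion = criterion, TP = TP, FP = FP, FN = n_true - TP,
               TN = n_null - FP, n_true = n_true, n_null = n_null,
               n_calls = n_calls)
  class(conf) <- "region_confusion"
  conf
}

# for each query interval, does it overlap (closed, >=1 shared bp) any
# reference interval? references may overlap each other.
.any_overlap <- function(q_start, q_end, r_start, r_end) {
  o <- order(r_start)
  rs <- r_start[o]
  re_cm <- cummax(r_end[o])
  k <- findInterval(q_end, rs)          # last reference with start <= q_end
  k >= 1L & re_cm[pmax(k, 1L)] >= q_start
}

#' @export
print.region_confusion <- function(x, ...) {
  cat("Region confusion (", x$criterion, " criterion)\n", sep = "")
  m <- matrix(c(x$TP, x$FP, x$TP + x$FP,
                x$FN, x$TN, x$FN + x$TN,
                x$n_true, x$n_null, x$n_true + x$n_null),
              nrow = 3, byrow = TRUE,
              dimnames = list(c("Sig.", "Not Sig.", "Total"),
                              c("True DMR", "No DMR", "Total")))
  print(m)
  invisible(x)
}

#' Precision, recall, F1 and region-level type I error
#'
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)`,
#' `F1 = 2 * precision * recall / (precision + recall)` (0 when both are 0),
#' `type1 = FP / n_null`. Undefined ratios (zero denominators) are reported
#' as `NA`.
#'
#' @param conf a `region_confusion` from [classify_calls()].
#' @return List of class `metric_set` with `precision`, `recall`, `f1`,
#'   `type1`.
#' @export
compute_metrics <- function(conf) {
  precision <- if (conf$TP + conf$FP == 0L) NA_real_ else conf$TP / (conf$TP + conf$FP)
  recall <- if (conf$n_true == 0L) NA_real_ else conf$TP / conf$n_true
  f1 <- if (is.na(precision) || is.na(recall)) NA_real_
        else if (precision + recall == 0) 0
        else 2 * precision * recall / (precision + recall)
  type1 <- if (conf$n_null == 0L) NA_real_ else conf$FP / conf$n_null
  structure(list(precision = precision, recall = recall, f1 = f1, type1 = type1),
            class = "metric_set")
}

#' Evaluate calls under one or both overlap criteria
#'
#' @inheritParams classify_calls
#' @param criteria character vector among `"EO"`, `"AO"`.
#' @return Data frame with one row per criterion: confusion counts and
#'   metrics.
#' @export
evaluate_calls <- function(called, truth, criteria = c("EO", "AO")) {
  rows <- lapply(criteria, function(cr) {
    conf <- classify_calls(called, truth, cr)
    m <- compute_metrics(conf)
    data.frame(criterion = cr, TP = conf$TP, FP = conf$FP, FN = conf$FN,
               TN = conf$TN, n_true = conf$n_true, n_null = conf$n_null,
               n_calls = conf$n_calls, precision = m$precision,
               recall = m$recall, f1 = m$f1, type1 = m$type1,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Summarize metrics across simulation replicates
#'
#' Per metric and grouping (mode and criterion when present): mean, five-number
#' summary, and the count of replicates where the metric was defined
#' (replicates with an undefined metric are excluded from that metric's
#' summary, with a message).
#'
#' @param metrics per-replicate data frame as returned by [run_replicates()].
#' @param metrics_cols metric columns to summarize.
#' @return Long data frame: grouping columns, `metric`, `mean`, `min`, `q1`,
#'   `median`, `q3`, `max`, `n_used`.
#' @export
aggregate_replicates <- function(metrics,
                                 metrics_cols = c("precision", "recall", "f1", "type1")) {
  if (nrow(metrics) == 0L) stop("no replicates to aggregate")
  by_cols <- intersect(c("mode", "criterion"), names(metrics))
  key <- if (length(by_cols)) interaction(metrics[by_cols], drop = TRUE)
         else factor(rep("all", nrow(metrics)))
  rows <- list()
  for (g in levels(key)) {
    sub <- metrics[key == g, , drop = FALSE]
    for (mc in intersect(metrics_cols, names(metrics))) {
      v <- sub[[mc]]
      n_na <- sum(is.na(v))
      if (n_na > 0) message(n_na, " replicate(s) with undefined ", mc,
                            " excluded from its summary (", g, ")")
      v <- v[!is.na(v)]
      qs <- if (length(v)) stats::quantile(v, c(0, .25, .5, .75, 1), names = FALSE)
            else rep(NA_real_, 5)
      row <- sub[1, by_cols, drop = FALSE]
      row$metric <- mc
      row$mean <- if (length(v)) mean(v) else NA_real_
      row$min <- qs[1]; row$q1 <- qs[2]; row$median <- qs[3]
      row$q3 <- qs[4]; row$max <- qs[5]
      row$n_used <- length(v)
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
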