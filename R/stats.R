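#' Collapse field summaries into one value per strain and experiment
#'
#' Implements the published aggregation rule: the fields of a strain within
#' one experiment (typically three) are averaged into a single data point.
#' The result feeds the experiment-linked ANOVA, which requires a complete
#' strain x experiment design.
#'
#' @param fieldSummaries either a data.frame of field rows (columns
#'   `strain`, `experiment_id`, `field_id` plus metric columns, as produced
#'   by [summarizeField()]`$summary`) or a list of [summarizeField()]
#'   results.
#' @param metric `"mean_ld_per_cell"` or `"pct_cells_supersized"` (any
#'   numeric field column works).
#' @return data.frame with columns `strain`, `experiment_id`, `value`; one
#'   row per strain x experiment.
#' @export
buildExperimentTable <- function(fieldSummaries,
                                 metric = c("mean_ld_per_cell",
                                            "pct_cells_supersized")) {
  metric <- metric[1]
  fields <- if (is.data.frame(fieldSummaries)) fieldSummaries else
    do.call(rbind, lapply(fieldSummaries, function(x)
      if (is.list(x) && !is.null(x$summary)) x$summary else x))
  if (!metric %in% names(fields)) {
    stop("metric '", metric, "' not found among: ",
         paste(setdiff(names(fields),
                       c("strain", "experiment_id", "field_id")),
               collapse = ", "))
  }
  strains <- unique(fields$strain)
  exps <- unique(fields$experiment_id)
  full <- expand.grid(strain = strains, experiment_id = exps,
                      stringsAsFactors = FALSE)
  have <- unique(fields[, c("strain", "experiment_id")])
  missing <- full[!paste(full$strain, full$experiment_id) %in%
                    paste(have$strain, have$experiment_id), ]
  if (nrow(missing)) {
    stop("incomplete design; missing strain x experiment cells: ",
         paste(missing$strain, missing$experiment_id, sep = "/",
               collapse = ", "))
  }
  agg <- stats::aggregate(fields[[metric]],
                          by = list(strain = fields$strain,
                                    experiment_id = fields$experiment_id),
                          FUN = mean)
  names(agg)[3] <- "value"
  agg[order(agg$experiment_id, agg$strain), , drop = FALSE]
}

#' Experiment-linked one-way ANOVA
#'
#' One-way ANOVA on per-experiment strain means with strains linked within
#' each experiment: the experiment is treated as a block (randomized
#' complete block / repeated-measures layout), so the total sum of squares
#' decomposes into strain, block and residual terms, and
#' `F = MS_strain / MS_residual` on `(s - 1, (s - 1)(b - 1))` degrees of
#' freedom.
#'
#' @param table an experiment table from [buildExperimentTable()]: complete
#'   `s x b` design, `s >= 2` strains, `b >= 2` experiments.
#' @return list of class `AnovaResult`: `F`, `pValue`, `dfStrain`,
#'   `dfBlock`, `dfResidual`, `ssStrain`, `ssBlock`, `ssResidual`,
#'   `msResidual`, `strainMeans`, `nBlocks`.
#' @export
linkedAnova <- function(table) {
  stopifnot(all(c("strain", "experiment_id", "value") %in% names(table)))
  s <- length(unique(table$strain))
  b <- length(unique(table$experiment_id))
  if (s < 2 || b < 2) stop("need at least 2 strains and 2 experiments")
  if (nrow(table) != s * b ||
      anyDuplicated(table[, c("strain", "experiment_id")])) {
    stop("table must hold exactly one value per strain x experiment")
  }
  d <- data.frame(value = table$value,
                  strain = factor(table$strain),
                  block = factor(table$experiment_id))
  fit <- stats::lm(value ~ strain + block, data = d)
  an <- stats::anova(fit)  # sequential SS == definitional RCBD sums (balanced)
  ssStrain <- an["strain", "Sum Sq"]
  ssBlock <- an["block", "Sum Sq"]
  ssRes <- an["Residuals", "Sum Sq"]
  dfRes <- an["Residuals", "Df"]
  if (dfRes < 1) stop("zero residual degrees of freedom")
  msRes <- ssRes / dfRes
  Fval <- (ssStrain / (s - 1)) / msRes
  res <- list(F = Fval,
              pValue = stats::pf(Fval, s - 1, dfRes, lower.tail = FALSE),
              dfStrain = s - 1L, dfBlock = b - 1L, dfResidual = dfRes,
              ssStrain = ssStrain, ssBlock = ssBlock, ssResidual = ssRes,
              msResidual = msRes,
              strainMeans = tapply(d$value, d$strain, mean),
              nBlocks = b)
  class(res) <- "AnovaResult"
  res
}

#' @export
print.AnovaResult <- function(x, ...) {
  cat(sprintf(
    "Experiment-linked one-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
    x$dfStrain, x$dfResidual, x$F, x$pValue))
  cat(sprintf("  SS strain %.4g, SS block %.4g, SS residual %.4g\n",
              x$ssStrain, x$ssBlock, x$ssResidual))
  invisible(x)
}

#' Step-down Sidak (Holm-Sidak) comparisons on preselected strain pairs
#'
#' For each preselected pair, a t statistic on the ANOVA residual degrees of
#' freedom using the pooled residual mean square,
#' `t = (mean_i - mean_j) / sqrt(2 MS_res / b)`, with a two-sided p value.
#' The m raw p values are then adjusted step-down: sorted ascending,
#' `p_adj(k) = 1 - (1 - p(k))^(m - k + 1)`, enforced non-decreasing by
#' running maximum and capped at 1. `method = "holm"` substitutes classical
#' Holm-Bonferroni stepping.
#'
#' Pairs must be preselected explicitly; there is no all-pairs default,
#' since silently changing m changes every adjusted p value.
#'
#' @param pairs list of length-2 character vectors, or strings `"A:B"`.
#' @param table the experiment table the ANOVA was fit on.
#' @param anova an `AnovaResult` from [linkedAnova()].
#' @param alpha significance level used for the `significant` flag.
#' @param method `"sidak"` (default) or `"holm"`.
#' @return data.frame with one row per pair: `strain_i`, `strain_j`,
#'   `mean_diff`, `t`, `df`, `p_raw`, `p_adjusted`, `significant`, `stars`.
#' @export
holmSidak <- function(pairs, table, anova, alpha = 0.05,
                      method = c("sidak", "holm")) {
  method <- match.arg(method)
  if (is.character(pairs)) pairs <- as.list(pairs)
  pairs <- lapply(pairs, function(p) {
    if (length(p) == 1) p <- strsplit(p, ":", fixed = TRUE)[[1]]
    if (length(p) != 2) stop("each pair must name exactly two strains")
    p
  })
  means <- anova$strainMeans
  b <- anova$nBlocks
  se <- sqrt(2 * anova$msResidual / b)
  rows <- lapply(pairs, function(p) {
    p <- unlist(p)
    if (!all(p %in% names(means))) {
      stop("unknown strain in pair: ", paste(p, collapse = ":"))
    }
    diff <- unname(means[p[1]] - means[p[2]])
    t <- diff / se
    data.frame(strain_i = p[1], strain_j = p[2], mean_diff = diff, t = t,
               df = anova$dfResidual,
               p_raw = 2 * stats::pt(-abs(t), anova$dfResidual))
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- adjustStepDown(out$p_raw, method)
  out$significant <- out$p_adjusted < alpha
  out$stars <- pStars(out$p_adjusted)
  out
}

# step-down adjustment over m preselected comparisons
adjustStepDown <- function(p, method = c("sidak", "holm")) {
  method <- match.arg(method)
  if (method == "holm") return(stats::p.adjust(p, method = "holm"))
  m <- length(p)
  ord <- order(p)
  adj <- 1 - (1 - p[ord])^(m - seq_len(m) + 1)
  adj <- pmin(cummax(adj), 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

#' Significance stars for adjusted p values
#'
#' `***` for p < 0.001, `**` for p < 0.01, `*` for p < 0.05, `NS` otherwise.
#'
#' @param p numeric vector of (adjusted) p values.
#' @return character vector.
#' @export
pStars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
         ifelse(p < 0.05, "*", "NS")))
}

#' Write the strain-comparison report
#'
#' Writes `pairwise.csv` (round-trippable) and a short human-readable
#' summary with star annotations; also writes `anova.csv` when an
#' `AnovaResult` is supplied.
#'
#' @param pairwise data.frame from [holmSidak()] (may have zero rows).
#' @param dir output directory.
#' @param anova optional `AnovaResult`.
#' @return invisible vector of paths written.
#' @export
writeStatsReport <- function(pairwise, dir, anova = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, "pairwise.csv")
  utils::write.csv(pairwise, csv, row.names = FALSE)
  paths <- csv
  if (!is.null(anova)) {
    acsv <- file.path(dir, "anova.csv")
    utils::write.csv(data.frame(
      F = anova$F, p_value = anova$pValue, df_strain = anova$dfStrain,
      df_block = anova$dfBlock, df_residual = anova$dfResidual,
      ss_strain = anova$ssStrain, ss_block = anova$ssBlock,
      ss_residual = anova$ssResidual), acsv, row.names = FALSE)
    paths <- c(paths, acsv)
  }
  txt <- file.path(dir, "summary.txt")
  lines <- c("Strain comparisons (step-down Sidak adjusted)",
             if (!is.null(anova)) sprintf(
               "ANOVA: F(%d, %d) = %.4g, p = %.4g", anova$dfStrain,
               anova$dfResidual, anova$F, anova$pValue),
             if (nrow(pairwise)) sprintf(
               "%s vs %s: diff = %.4g, t = %.3g, p_adj = %.4g %s",
               pairwise$strain_i, pairwise$strain_j, pairwise$mean_diff,
               pairwise$t, pairwise$p_adjusted, pairwise$stars) else
               "(no pairs)")
  writeLines(lines, txt)
  invisible(c(paths, txt))
}
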