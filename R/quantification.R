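# Relative expression from qPCR Ct tables via the 2^-ddCt (Livak) method,
# and conversion of measured fold-changes into knockdown interventions.

.CT_COLUMNS <- c("sample", "condition", "role", "tech_rep", "ct")

#' Validate a qPCR Ct table
#'
#' A Ct table has one row per technical-replicate measurement with columns
#' `sample` (biological replicate id), `condition` (`"treatment"` or
#' `"control"`), `role` (`"target"` or `"reference"`), `tech_rep` and `ct`
#' (cycles, > 0).  Every sample must carry both target and reference
#' measurements.
#'
#' @param table A data frame.
#' @return The table, with class `"ct_table"` prepended, invisibly valid.
#' @export
as_ct_table <- function(table) {
  stopifnot(is.data.frame(table))
  missing_cols <- setdiff(.CT_COLUMNS, names(table))
  if (length(missing_cols)) {
    stop("Ct table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!all(table$role %in% c("target", "reference"))) {
    stop("'role' must be 'target' or 'reference'")
  }
  if (!is.numeric(table$ct) || any(!is.finite(table$ct)) ||
      any(table$ct <= 0)) {
    stop("'ct' values must be finite positive cycle numbers")
  }
  combos <- unique(table[, c("sample", "condition")])
  for (i in seq_len(nrow(combos))) {
    sub <- table[table$sample == combos$sample[i] &
                   table$condition == combos$condition[i], ]
    gap <- setdiff(c("target", "reference"), unique(sub$role))
    if (length(gap)) {
      stop("sample '", combos$sample[i], "' (", combos$condition[i],
           ") lacks ", paste(gap, collapse = " and "), " measurements")
    }
  }
  if (!inherits(table, "ct_table")) {
    class(table) <- c("ct_table", class(table))
  }
  table
}

#' Read a Ct table from delimited text
#'
#' @param path CSV or TSV file with the columns documented in
#'   [as_ct_table()]; the delimiter is inferred from the extension
#'   (`.tsv`/`.txt` tab, otherwise comma) unless given.
#' @param sep Field delimiter override.
#' @return A validated `"ct_table"`.
#' @export
read_ct_table <- function(path, sep = NULL) {
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  as_ct_table(tab)
}

#' Average technical replicates on the Ct scale
#'
#' Collapses a Ct table to one row per (sample, condition, role), taking
#' the arithmetic mean of the technical-replicate Ct values — standard
#' Livak practice, applied before any delta is formed.
#'
#' @param table A `"ct_table"` (validated if not already).
#' @return A `"ct_table"` without `tech_rep`, with columns `ct` (mean) and
#'   `n_tech` (replicates averaged).
#' @examples
#' tab <- data.frame(sample = "s1", condition = "control",
#'                   role = rep(c("target", "reference"), each = 3),
#'                   tech_rep = rep(1:3, 2),
#'                   ct = c(19.8, 20.0, 20.2, 18.0, 18.1, 17.9))
#' technical_mean(as_ct_table(tab))
#' @export
technical_mean <- function(table) {
  table <- as_ct_table(table)
  agg <- stats::aggregate(
    ct ~ sample + condition + role, data = table, FUN = mean
  )
  n <- stats::aggregate(
    ct ~ sample + condition + role, data = table, FUN = length
  )
  agg$n_tech <- n$ct
  agg <- agg[order(agg$condition, agg$sample, agg$role), ]
  rownames(agg) <- NULL
  class(agg) <- c("ct_table", class(agg))
  agg
}

#' Relative expression by the 2^-ddCt method
#'
#' For each biological replicate, `dCt = Ct(target) - Ct(reference)`;
#' `ddCt = dCt - mean(dCt over control replicates)`; relative fold
#' expression `= 2^-ddCt` (amplification efficiency fixed at 2).
#' Technical replicates are averaged first if still present.
#'
#' @param table A `"ct_table"`.
#' @param control Label of the calibrator condition (default `"control"`).
#' @return A data frame of class `"fold_change"` with one row per
#'   biological replicate: `sample`, `condition`, `dct`, `ddct`, `fold`.
#'   Attribute `mean_fold` is the summary fold `2^-mean(ddCt)` over the
#'   non-control replicates — aggregation stays on the Ct scale, as in the
#'   per-replicate deltas, so the summary is the geometric mean of the
#'   replicate folds; `sd_fold` is the dispersion of the per-replicate
#'   folds and `control_dct` records the calibrator mean dCt.
#' @examples
#' tab <- data.frame(
#'   sample = rep(c("t1", "c1"), each = 2),
#'   condition = rep(c("treatment", "control"), each = 2),
#'   role = rep(c("target", "reference"), 2),
#'   tech_rep = 1L,
#'   ct = c(24, 20, 22, 20))
#' delta_delta_ct(as_ct_table(tab))   # ddCt = 2, fold = 0.25
#' @export
delta_delta_ct <- function(table, control = "control") {
  table <- technical_mean(table)
  if (!control %in% table$condition) {
    stop("no samples with control condition '", control, "'")
  }
  wide <- merge(
    table[table$role == "target", c("sample", "condition", "ct")],
    table[table$role == "reference", c("sample", "condition", "ct")],
    by = c("sample", "condition"), suffixes = c("_target", "_reference")
  )
  wide$dct <- wide$ct_target - wide$ct_reference
  control_dct <- mean(wide$dct[wide$condition == control])
  wide$ddct <- wide$dct - control_dct
  wide$fold <- 2^(-wide$ddct)
  out <- wide[order(wide$condition != control, wide$sample),
              c("sample", "condition", "dct", "ddct", "fold")]
  rownames(out) <- NULL
  treat <- out$condition != control
  attr(out, "mean_fold") <-
    if (any(treat)) 2^(-mean(out$ddct[treat])) else NA_real_
  attr(out, "sd_fold") <-
    if (sum(treat) > 1) stats::sd(out$fold[treat]) else NA_real_
  attr(out, "control_dct") <- control_dct
  class(out) <- c("fold_change", "data.frame")
  out
}

#' @export
print.fold_change <- function(x, digits = 4, ...) {
  print.data.frame(as.data.frame(x), row.names = FALSE, digits = digits)
  cat(sprintf("mean fold (non-control): %.4g  (sd %.4g)\n",
              attr(x, "mean_fold"), attr(x, "sd_fold")))
  invisible(x)
}

#' Convert a measured fold-change into a knockdown intervention
#'
#' A fold expression of phi relative to control is modelled as retained
#' expression fraction `min(phi, 1)`; values above 1 (no silencing, or
#' upregulation) are clamped and flagged.
#'
#' @param fold Positive fold expression, or a `"fold_change"` object whose
#'   `mean_fold` is used.
#' @param class Allele class the silencing targets (default `"brush"`).
#' @return A [knockdown()] intervention; attribute `clamped` records
#'   whether the fold exceeded 1.
#' @examples
#' fold_to_knockdown(0.25)
#' @export
fold_to_knockdown <- function(fold, class = "brush") {
  if (inherits(fold, "fold_change")) fold <- attr(fold, "mean_fold")
  if (!is.numeric(fold) || length(fold) != 1L || !is.finite(fold) ||
      fold <= 0) {
    stop("'fold' must be a single positive number")
  }
  iv <- knockdown(class, min(fold, 1))
  attr(iv, "clamped") <- fold > 1
  iv
}
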