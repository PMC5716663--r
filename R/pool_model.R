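#' Define a channel-subunit locus
#'
#' A locus in the CNGC.IVA cluster, characterised by whether it is
#' transcribed and by a relative transcription weight per allele copy.
#' Weights are dimensionless: only ratios matter for the subunit pool.
#'
#' @param id Short locus name, e.g. `"BRUSH"` or `"CNGC.IVA3"`.
#' @param expressed Logical; an unexpressed locus contributes no subunits
#'   regardless of genotype.
#' @param baseline_weight Non-negative relative transcription weight per
#'   allele copy.
#' @return An object of class `"locus"`.
#' @export
locus <- function(id, expressed = TRUE, baseline_weight = 1) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (!is.numeric(baseline_weight) || length(baseline_weight) != 1L ||
      !is.finite(baseline_weight) || baseline_weight < 0) {
    stop("'baseline_weight' must be a single non-negative finite number")
  }
  structure(
    list(id = id, expressed = isTRUE(expressed),
         baseline_weight = baseline_weight),
    class = "locus"
  )
}

#' Default CNGC.IVA cluster loci
#'
#' The five-locus cluster with the four transcribed members (BRUSH,
#' CNGC.IVA3, CNGC.IVA4, CNGC.IVA5) at equal weight 1 per allele copy —
#' the "equal likelihood" model assumption made explicit.  CNGC.IVA2
#' carries a transposon insertion and no detectable transcript, so it is
#' present but unexpressed.
#'
#' @param weights Optional named numeric vector overriding baseline weights
#'   by locus id.
#' @return A list of [locus()] objects.
#' @export
default_loci <- function(weights = NULL) {
  ids <- c("BRUSH", "CNGC.IVA2", "CNGC.IVA3", "CNGC.IVA4", "CNGC.IVA5")
  loci <- lapply(ids, function(id) {
    w <- 1
    if (!is.null(weights) && id %in% names(weights)) w <- weights[[id]]
    locus(id, expressed = id != "CNGC.IVA2", baseline_weight = w)
  })
  names(loci) <- ids
  loci
}

.ALLELE_CLASSES <- c("WT", "brush", "null")

#' Specify a diploid genotype over the cluster loci
#'
#' Each named argument gives the allele copy counts at one locus as a named
#' integer vector over the allele classes `WT`, `brush`, `null`; counts at a
#' locus must sum to 2 (diploid).  Loci not mentioned are homozygous WT.
#'
#' @param ... Named per-locus allele counts, e.g.
#'   `BRUSH = c(WT = 1, brush = 1)`.
#' @return An object of class `"cluster_genotype"`.
#' @examples
#' genotype(BRUSH = c(WT = 1, brush = 1))   # heterozygote
#' genotype(BRUSH = c(brush = 2))           # homozygous mutant
#' genotype(BRUSH = c(null = 2))            # premature-stop null
#' @export
genotype <- function(...) {
  g <- list(...)
  if (length(g) && (is.null(names(g)) || any(!nzchar(names(g))))) {
    stop("all genotype entries must be named by locus id")
  }
  g <- lapply(g, function(counts) {
    if (is.null(names(counts)) || !all(names(counts) %in% .ALLELE_CLASSES)) {
      stop("allele classes must be among: ",
           paste(.ALLELE_CLASSES, collapse = ", "))
    }
    counts <- counts[counts > 0]
    if (any(counts != round(counts)) || any(counts < 0)) {
      stop("allele copy counts must be non-negative integers")
    }
    if (sum(counts) != 2) {
      stop("allele copies at each locus must sum to 2 (diploid)")
    }
    counts
  })
  structure(g, class = "cluster_genotype")
}

#' Expression-level interventions
#'
#' `overexpression()` adds a transgene source expressing subunits of one
#' allele class with the given weight (same dimensionless units as locus
#' baseline weights; the constitutive polyubiquitin-promoter constructs are
#' modelled this way).  `knockdown()` multiplies the expression of an allele
#' class by a retained fraction in \[0, 1\], emulating RNAi silencing.
#'
#' @param class Allele class targeted (`"WT"` or `"brush"`).
#' @param weight Transgene expression weight, >= 0.
#' @param fraction Retained-expression fraction in \[0, 1\].
#' @param source Which sources a knockdown hits: `"native"` (default),
#'   `"transgene"`, or `"all"`.
#' @param label Free-text label carried into reports.
#' @return An object of class `"intervention"`.
#' @name interventions
NULL

#' @rdname interventions
#' @export
overexpression <- function(class, weight, label = paste0("OE-", class)) {
  stopifnot(class %in% .ALLELE_CLASSES)
  if (!is.numeric(weight) || length(weight) != 1L || !is.finite(weight) ||
      weight < 0) {
    stop("overexpression 'weight' must be a single non-negative number")
  }
  structure(
    list(kind = "overexpression", class = class, weight = weight,
         label = label),
    class = "intervention"
  )
}

#' @rdname interventions
#' @export
knockdown <- function(class, fraction, source = c("native", "transgene", "all"),
                      label = paste0("RNAi-", class)) {
  stopifnot(class %in% .ALLELE_CLASSES)
  source <- match.arg(source)
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      !is.finite(fraction) || fraction < 0 || fraction > 1) {
    stop("knockdown 'fraction' must be a single number in [0, 1]")
  }
  structure(
    list(kind = "knockdown", class = class, fraction = fraction,
         source = source, label = label),
    class = "intervention"
  )
}

.new_pool <- function(class, frequency, num = NULL, den = NULL,
                      mutant_class = "brush") {
  structure(
    list(class = class,
         frequency = stats::setNames(frequency, class),
         num = num, den = den,
         exact = !is.null(num),
         mutant_class = mutant_class),
    class = "subunit_pool"
  )
}

#' Build the subunit pool for a genotype under interventions
#'
#' Converts a genotype plus expression-level interventions into the
#' frequency vector of subunit classes competing for tetramer assembly.
#' Each allele copy of an expressed locus contributes its locus baseline
#' weight; null alleles and unexpressed loci contribute nothing; knockdowns
#' scale and overexpression transgenes add weight.  The frequency of class
#' c is its total weight divided by the grand total.  When every weight is
#' rational the frequencies are carried as exact rationals, so downstream
#' odds such as 1:4096 are reproduced bit-exactly.
#'
#' @param genotype A [genotype()].
#' @param loci List of [locus()] definitions (default [default_loci()]).
#' @param interventions List of [overexpression()] / [knockdown()] objects.
#' @param collapse_wt Pool WT subunits from all loci into one class
#'   (default); if `FALSE`, WT classes are kept distinct per locus
#'   (`"WT:<locus>"`) for composition bookkeeping.
#' @return A `"subunit_pool"`: named frequencies summing to 1, with exact
#'   numerator/denominator vectors when available.
#' @examples
#' # heterozygote: 1 brush copy among 8 expressed copies -> f(brush) = 1/8
#' build_pool(genotype(BRUSH = c(WT = 1, brush = 1)))
#' @export
build_pool <- function(genotype, loci = default_loci(),
                       interventions = list(), collapse_wt = TRUE) {
  if (!inherits(genotype, "cluster_genotype")) {
    stop("'genotype' must be created with genotype()")
  }
  if (inherits(interventions, "intervention")) {
    interventions <- list(interventions)
  }
  stopifnot(all(vapply(interventions, inherits, TRUE, "intervention")))
  if (is.null(names(loci))) {
    names(loci) <- vapply(loci, `[[`, "", "id")
  }
  unknown <- setdiff(names(genotype), names(loci))
  if (length(unknown)) {
    stop("genotype names unknown locus: ", paste(unknown, collapse = ", "))
  }

  # one row per subunit source: (class label, allele class, source, weight)
  rows <- list()
  for (lc in loci) {
    if (!lc$expressed) next
    counts <- genotype[[lc$id]]
    if (is.null(counts)) counts <- c(WT = 2)
    for (allele in names(counts)) {
      if (allele == "null") next  # truncated product assumed absent
      w <- counts[[allele]] * lc$baseline_weight
      cls <- if (allele == "WT" && !collapse_wt) {
        paste0("WT:", lc$id)
      } else {
        allele
      }
      rows[[length(rows) + 1L]] <- list(
        class = cls, allele = allele, source = "native", weight = w
      )
    }
  }
  for (iv in interventions) {
    if (iv$kind != "overexpression") next
    rows[[length(rows) + 1L]] <- list(
      class = iv$class, allele = iv$class, source = "transgene",
      weight = iv$weight
    )
  }
  for (iv in interventions) {
    if (iv$kind != "knockdown") next
    for (i in seq_along(rows)) {
      if (rows[[i]]$allele == iv$class &&
          (iv$source == "all" || rows[[i]]$source == iv$source)) {
        rows[[i]]$weight <- rows[[i]]$weight * iv$fraction
        rows[[i]]$kd <- c(rows[[i]]$kd, iv$fraction)
      }
    }
  }
  if (!length(rows)) {
    stop(errorCondition(
      "empty pool: no expressed locus contributes subunits",
      class = c("tetradose_empty_pool", "error", "condition")
    ))
  }

  classes <- unique(vapply(rows, `[[`, "", "class"))
  # the mutant class is always carried (frequency 0 if absent), listed last
  classes <- c(setdiff(classes, "brush"), "brush")
  weight <- stats::setNames(numeric(length(classes)), classes)
  for (r in rows) weight[[r$class]] <- weight[[r$class]] + r$weight
  total <- sum(weight)
  if (total <= 0) {
    stop(errorCondition(
      "empty pool: total subunit weight is zero",
      class = c("tetradose_empty_pool", "error", "condition")
    ))
  }

  # exact path: rebuild the per-class totals in rational arithmetic
  rat_rows <- lapply(rows, function(r) {
    rw <- .as_rational(r$weight)
    kd <- r$kd
    if (!is.null(kd) && !is.null(rw) && prod(kd) > 0) {
      # weight already includes the knockdown in floating point; redo it
      # exactly from the pre-knockdown weight when both parts are rational
      base <- .as_rational(r$weight / prod(kd))
      kds <- lapply(kd, .as_rational)
      if (!is.null(base) && !any(vapply(kds, is.null, TRUE))) {
        rw <- Reduce(.rat_mul, kds, base)
      }
    }
    rw
  })
  num <- den <- NULL
  if (!any(vapply(rat_rows, is.null, TRUE))) {
    rat_w <- stats::setNames(
      rep(list(c(num = 0, den = 1)), length(classes)), classes
    )
    for (i in seq_along(rows)) {
      cls <- rows[[i]]$class
      rat_w[[cls]] <- .rat_add(rat_w[[cls]], rat_rows[[i]])
    }
    rat_total <- .rat_sum(rat_w)
    if (!is.null(rat_total) && !any(vapply(rat_w, is.null, TRUE))) {
      freqs <- lapply(rat_w, .rat_div, b = rat_total)
      if (!any(vapply(freqs, is.null, TRUE))) {
        num <- vapply(freqs, `[[`, 0, 1)
        den <- vapply(freqs, `[[`, 0, 2)
      }
    }
  }

  frequency <- if (!is.null(num)) num / den else weight / total
  .new_pool(classes, unname(frequency), num = unname(num),
            den = unname(den))
}

#' Construct a subunit pool from explicit class frequencies
#'
#' Direct constructor for arbitrary pools.  Frequencies must be
#' non-negative and sum to 1; when every frequency is exactly rational the
#' pool is carried in exact arithmetic.
#'
#' @param frequency Named non-negative numeric vector summing to 1.
#' @param mutant_class Name of the mutant class (default `"brush"`; need
#'   not be present among the frequencies).
#' @return A `"subunit_pool"`.
#' @examples
#' subunit_pool(c(WT = 3 / 4, brush = 1 / 4))
#' subunit_pool(c(A = 1 / 3, B = 1 / 3, C = 1 / 3))
#' @export
subunit_pool <- function(frequency, mutant_class = "brush") {
  if (!is.numeric(frequency) || is.null(names(frequency)) ||
      any(!nzchar(names(frequency)))) {
    stop("'frequency' must be a named numeric vector")
  }
  if (any(!is.finite(frequency)) || any(frequency < 0)) {
    stop("frequencies must be non-negative and finite")
  }
  rats <- lapply(frequency, .as_rational)
  num <- den <- NULL
  if (!any(vapply(rats, is.null, TRUE))) {
    s <- .rat_sum(rats)
    if (!is.null(s)) {
      if (s[[1]] != s[[2]]) stop("frequencies must sum to exactly 1")
      num <- vapply(rats, `[[`, 0, 1)
      den <- vapply(rats, `[[`, 0, 2)
    }
  }
  if (is.null(num) && abs(sum(frequency) - 1) > 1e-9) {
    stop("frequencies must sum to 1")
  }
  .new_pool(names(frequency), unname(frequency), num = unname(num),
            den = unname(den), mutant_class = mutant_class)
}

#' Two-class pool from a mutant subunit fraction
#'
#' Convenience constructor for the model's central quantity: a pool with
#' mutant fraction `f` and WT fraction `1 - f`.
#'
#' @param f Mutant subunit fraction in \[0, 1\].
#' @param mutant_class Name of the mutant class (default `"brush"`).
#' @return A `"subunit_pool"` with classes `WT` and `mutant_class`.
#' @examples
#' pool_from_fraction(1 / 8)
#' @export
pool_from_fraction <- function(f, mutant_class = "brush") {
  if (!is.numeric(f) || length(f) != 1L || !is.finite(f) || f < 0 || f > 1) {
    stop("'f' must be a single number in [0, 1]")
  }
  rf <- .as_rational(f)
  num <- den <- NULL
  if (!is.null(rf)) {
    comp <- .rat(rf[[2]] - rf[[1]], rf[[2]])
    num <- c(comp[[1]], rf[[1]])
    den <- c(comp[[2]], rf[[2]])
  }
  .new_pool(c("WT", mutant_class), c(1 - f, f), num = num, den = den,
            mutant_class = mutant_class)
}

#' @export
print.subunit_pool <- function(x, ...) {
  cat("Subunit pool (", if (x$exact) "exact" else "floating",
      " frequencies)\n", sep = "")
  for (i in seq_along(x$class)) {
    frac <- if (x$exact) {
      sprintf(" = %s/%s", format(x$num[i], scientific = FALSE),
              format(x$den[i], scientific = FALSE))
    } else ""
    cat(sprintf("  %-14s %.6g%s\n", x$class[i], x$frequency[i], frac))
  }
  invisible(x)
}

#' @export
as.data.frame.subunit_pool <- function(x, ...) {
  data.frame(class = x$class, frequency = unname(x$frequency),
             stringsAsFactors = FALSE)
}

#' Write a pool as TSV
#'
#' @param pool A `"subunit_pool"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pool <- function(pool, path) {
  utils::write.table(as.data.frame(pool), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

# frequency of one class, with exact num/den attributes when available
.pool_class_freq <- function(pool, class) {
  i <- match(class, pool$class)
  if (is.na(i)) stop("class '", class, "' not present in pool")
  f <- pool$frequency[[i]]
  if (pool$exact) {
    attr(f, "num") <- pool$num[i]
    attr(f, "den") <- pool$den[i]
  }
  f
}
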