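#' Arm ratio r = L/S
#'
#' The centromeric index of Levan: the long arm divided by the short arm.
#' Vectorized.
#'
#' @param long_arm_um,short_arm_um arm lengths in um; requires
#'   `short_arm_um > 0` and `long_arm_um >= short_arm_um` (repair inverted
#'   arms upstream, see [measurement_dataset()]).
#' @return numeric ratio(s), all >= 1.
#' @examples
#' arm_ratio(3.4, 1.0)
#' @export
arm_ratio <- function(long_arm_um, short_arm_um) {
  if (any(short_arm_um <= 0)) stop_domain("short arm must be > 0")
  if (any(long_arm_um < short_arm_um))
    stop_domain("long arm must be >= short arm (repair arm order upstream)")
  long_arm_um / short_arm_um
}

#' Morphology classification scheme
#'
#' Arm-ratio class boundaries and per-class arm-count convention.  The
#' default follows Levan's nomenclature: metacentric (M) for r in [1, 1.7),
#' submetacentric (SM) [1.7, 3), subtelocentric (ST) [3, 7) and acrocentric
#' (A) [7, Inf); boundaries are lower-inclusive.  Two arms are counted for
#' M and SM, one for ST and A (the usual fundamental-number convention in
#' ant cytogenetics).
#'
#' @param bounds named numeric vector of lower bounds per class, in class
#'   order; first bound must be 1.
#' @param arms named integer vector of arms counted per class.
#' @return object of class `morphology_scheme`.
#' @export
levan_scheme <- function(bounds = c(M = 1, SM = 1.7, ST = 3, A = 7),
                         arms = c(M = 2L, SM = 2L, ST = 1L, A = 1L)) {
  stopifnot(length(bounds) >= 2, !is.null(names(bounds)),
            identical(names(bounds), names(arms)),
            bounds[1] == 1, !is.unsorted(bounds, strictly = TRUE),
            all(arms %in% 1:2))
  structure(list(bounds = bounds, arms = as.integer(arms)),
            class = "morphology_scheme")
}

#' Classify chromosome morphology from the arm ratio
#'
#' Maps arm ratios to morphology class labels by the scheme's
#' lower-inclusive boundaries; the class is a non-decreasing step function
#' of r (M, SM, ST, A in order of increasing acrocentricity).
#'
#' @param r arm ratio(s), >= 1.
#' @param scheme a [levan_scheme()].
#' @return character vector of class labels.
#' @examples
#' classify_morphology(c(1, 1.7, 3, 6.999, 7))
#' @export
classify_morphology <- function(r, scheme = levan_scheme()) {
  if (any(!is.finite(r)) || any(r < 1)) stop_domain("arm ratio must be >= 1")
  labs <- names(scheme$bounds)
  idx <- findInterval(r, scheme$bounds)  # lower-inclusive by construction
  labs[idx]
}

#' Relative chromosome length (percent)
#'
#' A chromosome's total length as a percentage of the summed lengths of all
#' chromosomes in the sample: TL x 100 / sum(TL).
#'
#' @param tl total length(s) in um.
#' @param sum_tl sum of all chromosome lengths in the reference set (um);
#'   defaults to `sum(tl)` so a whole-metaphase vector can be passed alone.
#' @return percentage(s) in (0, 100].
#' @export
relative_length <- function(tl, sum_tl = sum(tl)) {
  if (sum_tl <= 0) stop_domain("sum of lengths must be > 0")
  if (any(tl <= 0) || any(tl > sum_tl + 1e-9))
    stop_domain("each length must satisfy 0 < TL <= sum(TL)")
  tl * 100 / sum_tl
}

#' Karyotype asymmetry index (percent)
#'
#' Sum of long arms over sum of total lengths, times 100.  Equals 50 for a
#' perfectly metacentric karyotype (all L = S) and approaches 100 in the
#' telocentric limit.
#'
#' @param x a metaphase: a data.frame with columns `long_arm_um` and
#'   `short_arm_um` (a [measurement_dataset()] restricted to one specimen,
#'   typically).
#' @return asymmetry index in [50, 100].
#' @export
asymmetry_index <- function(x) {
  x <- as.data.frame(x)
  if (!nrow(x)) stop_domain("empty karyotype")
  L <- x$long_arm_um; S <- x$short_arm_um
  if (any(S <= 0) || any(L < S)) stop_domain("invalid arm measurements")
  sum(L) / sum(L + S) * 100
}

#' Karyotype length (KL, um)
#'
#' The sum of chromosome total lengths: over the measured chromosomes of a
#' metaphase, or over the averaged homologue lengths of a population
#' summary.
#'
#' @param x a `measurement_dataset` restricted to one metaphase, a plain
#'   data.frame with a `total_length_um` column, a `population_summary`, or
#'   a bare numeric vector of lengths.
#' @return length in um.
#' @export
karyotype_length <- function(x) {
  if (inherits(x, "population_summary")) return(sum(x$mean_tl_um))
  if (is.data.frame(x)) {
    if (!nrow(x)) stop_domain("empty karyotype")
    return(sum(x$total_length_um))
  }
  if (!length(x)) stop_domain("empty karyotype")
  sum(as.numeric(x))
}

#' Karyotype formula and diploid arm number
#'
#' Renders the diploid karyotype formula (e.g. `"2K = 20M"`) from a
#' sequence of per-chromosome morphology labels and computes the diploid
#' arm number 2AN under the scheme's arm-count convention.  Classes appear
#' in fixed scheme order with zero counts omitted, joined by `" + "`.
#'
#' @param classes character vector of morphology labels, one per
#'   chromosome of the diploid set (length 2n, even).
#' @param scheme a [levan_scheme()] supplying class order and arm counts.
#' @return list with `counts` (named integer), `formula_string`,
#'   `arm_number_2AN`, `ploidy_2n`, `haploid_n`; class `karyotype_formula`.
#' @examples
#' karyotype_formula(rep("M", 20))$formula_string
#' @export
karyotype_formula <- function(classes, scheme = levan_scheme()) {
  n2 <- length(classes)
  if (n2 == 0L || n2 %% 2L != 0L)
    stop_domain("class sequence length must be even and positive (2n)")
  labs <- names(scheme$bounds)
  if (!all(classes %in% labs))
    stop_domain("unknown morphology label(s): ",
                paste(setdiff(classes, labs), collapse = ", "))
  counts <- setNames(vapply(labs, function(l) sum(classes == l), 0L), labs)
  nz <- counts[counts > 0]
  structure(list(
    counts = counts,
    formula_string = paste0("2K = ",
                            paste0(nz, names(nz), collapse = " + ")),
    arm_number_2AN = as.integer(sum(counts * scheme$arms)),
    ploidy_2n = as.integer(n2),
    haploid_n = as.integer(n2 / 2)),
    class = "karyotype_formula")
}

#' @export
print.karyotype_formula <- function(x, ...) {
  cat(sprintf("%s   (2n = %d, n = %d, 2AN = %d)\n", x$formula_string,
              x$ploidy_2n, x$haploid_n, x$arm_number_2AN))
  invisible(x)
}

#' Summarize one population's karyotype across metaphases
#'
#' For each homologue rank, the mean and sample SD (n - 1 denominator) of
#' total length across the population's metaphases, the mean arm ratio and
#' the morphology class of that mean ratio; the karyotype length is the sum
#' of the rank means.  The averaging unit is the metaphase by default; pass
#' `grouping = "colony"` to first average metaphases within colonies and
#' then summarize colony means.
#'
#' @param dataset a [measurement_dataset()].
#' @param population_id which population to summarize.
#' @param grouping `"metaphase"` (default) or `"colony"`.
#' @param scheme a [levan_scheme()] for classifying the mean arm ratio.
#' @return a `population_summary`: data.frame with one row per chromosome
#'   rank (`rank`, `pair`, `mean_tl_um`, `sd_tl_um`, `mean_r`,
#'   `morphology`) and attributes `population_id`, `n_metaphases`,
#'   `karyotype_length_um`, `sd_defined`.
#' @export
summarize_population <- function(dataset, population_id,
                                 grouping = c("metaphase", "colony"),
                                 scheme = levan_scheme()) {
  grouping <- match.arg(grouping)
  x <- as.data.frame(dataset)
  x <- x[x$population_id == population_id, , drop = FALSE]
  if (!nrow(x)) stop_domain("no metaphases for population ", population_id)
  x$r <- x$long_arm_um / x$short_arm_um

  if (grouping == "colony") {
    x <- aggregate(cbind(total_length_um, r) ~ colony_id + chromosome_index,
                   data = x, FUN = mean)
    unit_col <- "colony_id"
  } else unit_col <- "specimen_id"
  n_units <- length(unique(x[[unit_col]]))

  by_rank <- split(x, x$chromosome_index)
  ranks <- as.integer(names(by_rank))
  mean_tl <- vapply(by_rank, function(g) mean(g$total_length_um), 0)
  sd_tl <- if (n_units >= 2)
    vapply(by_rank, function(g) sd(g$total_length_um), 0)
  else rep(0, length(by_rank))
  mean_r <- vapply(by_rank, function(g) mean(g$r), 0)

  out <- data.frame(rank = ranks, pair = homologue_pair(ranks),
                    mean_tl_um = mean_tl, sd_tl_um = sd_tl,
                    mean_r = mean_r,
                    morphology = classify_morphology(mean_r, scheme),
                    stringsAsFactors = FALSE)
  out <- out[order(out$rank), ]
  rownames(out) <- NULL
  structure(out, population_id = population_id, n_metaphases = n_units,
            karyotype_length_um = sum(out$mean_tl_um),
            sd_defined = n_units >= 2,
            class = c("population_summary", "data.frame"))
}

#' @export
print.population_summary <- function(x, ...) {
  cat(sprintf("<population_summary> %s: %d metaphases, KL = %.2f um\n",
              attr(x, "population_id"), attr(x, "n_metaphases"),
              attr(x, "karyotype_length_um")))
  NextMethod()
}

#' Coefficient of variation of karyotype length
#'
#' Sample SD of per-specimen karyotype lengths divided by their mean
#' (dimensionless); used to quantify measurement repeatability.
#'
#' @param per_specimen_kls numeric vector of KL values, length >= 2.
#' @return CV (SD/mean).
#' @export
karyotype_cv <- function(per_specimen_kls) {
  if (length(per_specimen_kls) < 2)
    stop_domain("need >= 2 karyotype lengths for a CV")
  sd(per_specimen_kls) / mean(per_specimen_kls)
}

#' Validate per-specimen CVs against the one-SD rule
#'
#' Flags every CV lying more than one sample SD from the mean CV; the set
#' of measurements passes when no CV is flagged.
#'
#' @param per_specimen_cvs numeric vector of CVs, length >= 2.
#' @return list with `pass` (logical), `flagged` (indices), `mean_cv`,
#'   `sd_cv`.
#' @export
cv_validation <- function(per_specimen_cvs) {
  if (length(per_specimen_cvs) < 2) stop_domain("need >= 2 CV values")
  m <- mean(per_specimen_cvs); s <- sd(per_specimen_cvs)
  flagged <- which(abs(per_specimen_cvs - m) > s)
  list(pass = length(flagged) == 0L, flagged = flagged,
       mean_cv = m, sd_cv = s)
}
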