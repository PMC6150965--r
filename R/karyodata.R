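#' Construct a validated chromosome measurement dataset
#'
#' A measurement dataset holds one row per chromosome per metaphase with the
#' long arm (L), short arm (S) and total length (TL) in micrometres.  On
#' construction rows are grouped into metaphases by specimen, arms with
#' L < S are repaired (or rejected), TL is filled in as L + S where absent
#' and checked against L + S where present, and chromosomes are re-ranked by
#' descending TL within each metaphase.  Homologue pairs are taken to be
#' consecutive ranks in that order (ranks 1-2 form pair 1, and so on): with
#' a morphologically uniform karyotype, size rank is the only pairing
#' information the measurements carry.
#'
#' @param x data.frame with columns `population_id`, `specimen_id`,
#'   `long_arm_um`, `short_arm_um`; optional `colony_id`,
#'   `chromosome_index`, `total_length_um`.
#' @param ploidy_2n expected diploid number; default inferred from the data
#'   (all metaphases must agree).
#' @param tl_tolerance maximum tolerated |TL - (L + S)| in um when a TL
#'   column is supplied (TL is treated as the authoritative, independently
#'   measured value).
#' @param arm_order `"swap"` (default) silently-logged repair of rows with
#'   L < S, or `"strict"` to reject them.
#' @return object of class `measurement_dataset` (a data.frame with
#'   attributes `ploidy_2n` and `n_swapped`).
#' @examples
#' d <- measurement_dataset(data.frame(
#'   population_id = "P1", specimen_id = "s1",
#'   long_arm_um = c(3, 2.5, 2, 1.8), short_arm_um = c(2.8, 2.4, 2, 1.7)))
#' attr(d, "ploidy_2n")
#' @export
measurement_dataset <- function(x, ploidy_2n = NULL, tl_tolerance = 0.05,
                                arm_order = c("swap", "strict")) {
  arm_order <- match.arg(arm_order)
  required <- c("population_id", "specimen_id", "long_arm_um", "short_arm_um")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols))
    stop_domain("missing required column(s): ",
                paste(missing_cols, collapse = ", "))
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  if (!nrow(x)) {
    out <- empty_measurement_frame()
    return(structure(out, ploidy_2n = ploidy_2n %||% 0L, n_swapped = 0L,
                     class = c("measurement_dataset", "data.frame")))
  }
  if (is.null(x$colony_id)) x$colony_id <- x$population_id
  for (col in c("long_arm_um", "short_arm_um"))
    x[[col]] <- as.numeric(x[[col]])
  if (any(!is.finite(x$long_arm_um)) || any(!is.finite(x$short_arm_um)))
    stop_domain("non-finite arm length encountered")
  if (any(x$long_arm_um <= 0 & x$short_arm_um <= 0) ||
      any(pmax(x$long_arm_um, x$short_arm_um) <= 0))
    stop_domain("arm lengths must be positive")

  swap <- x$long_arm_um < x$short_arm_um
  n_swapped <- sum(swap)
  if (n_swapped > 0) {
    if (arm_order == "strict")
      stop_domain(n_swapped, " row(s) have long arm < short arm ",
                  "(strict mode rejects; use arm_order = \"swap\")")
    tmp <- x$long_arm_um[swap]
    x$long_arm_um[swap] <- x$short_arm_um[swap]
    x$short_arm_um[swap] <- tmp
    warning(n_swapped, " row(s) had long arm < short arm; arms swapped",
            call. = FALSE)
  }
  if (any(x$short_arm_um <= 0))
    stop_domain("short arm lengths must be positive")

  if (is.null(x$total_length_um) || all(is.na(x$total_length_um))) {
    x$total_length_um <- x$long_arm_um + x$short_arm_um
  } else {
    x$total_length_um <- as.numeric(x$total_length_um)
    fill <- is.na(x$total_length_um)
    x$total_length_um[fill] <- x$long_arm_um[fill] + x$short_arm_um[fill]
    dev <- abs(x$total_length_um - (x$long_arm_um + x$short_arm_um))
    if (any(dev > tl_tolerance))
      stop_domain("TL deviates from L + S by more than ", tl_tolerance,
                  " um in ", sum(dev > tl_tolerance), " row(s); first at ",
                  "specimen ", x$specimen_id[which.max(dev > tl_tolerance)])
  }

  key <- interaction(x$population_id, x$specimen_id, drop = TRUE)
  counts <- table(key)
  if (any(counts %% 2L != 0L))
    stop_domain("odd chromosome count in metaphase(s): ",
                paste(names(counts)[counts %% 2L != 0L], collapse = ", "))
  if (is.null(ploidy_2n)) ploidy_2n <- as.integer(counts[1])
  if (any(counts != ploidy_2n))
    stop_domain("all metaphases must have 2n = ", ploidy_2n,
                " chromosomes; offending specimen(s): ",
                paste(names(counts)[counts != ploidy_2n], collapse = ", "))

  # re-rank by descending TL within each metaphase
  ord <- order(x$population_id, x$specimen_id, -x$total_length_um)
  x <- x[ord, , drop = FALSE]
  x$chromosome_index <- as.integer(
    sequence(rle(paste(x$population_id, x$specimen_id, sep = "\r"))$lengths))
  x <- x[, c("population_id", "colony_id", "specimen_id", "chromosome_index",
             "long_arm_um", "short_arm_um", "total_length_um")]
  rownames(x) <- NULL
  structure(x, ploidy_2n = as.integer(ploidy_2n),
            n_swapped = as.integer(n_swapped),
            class = c("measurement_dataset", "data.frame"))
}

empty_measurement_frame <- function() {
  data.frame(population_id = character(), colony_id = character(),
             specimen_id = character(), chromosome_index = integer(),
             long_arm_um = numeric(), short_arm_um = numeric(),
             total_length_um = numeric(), stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Homologue pair index for a chromosome rank
#'
#' Consecutive ranks in the TL-descending order form pairs: ranks 1 and 2
#' are pair 1, ranks 3 and 4 pair 2, etc.
#' @param chromosome_index integer rank(s) within a metaphase.
#' @return integer pair index (1..n).
#' @export
homologue_pair <- function(chromosome_index) {
  as.integer(ceiling(chromosome_index / 2))
}

#' Read a chromosome measurement table
#'
#' Reads a comma- or tab-separated table with a header row (decimal point,
#' lengths in um) and returns a validated [measurement_dataset()].  Required
#' columns: `population_id`, `specimen_id`, `long_arm_um`, `short_arm_um`;
#' `colony_id`, `chromosome_index` and `total_length_um` are optional (TL is
#' computed as L + S when absent).
#'
#' @param path file path.
#' @param dialect `"auto"` (default; sniff the separator from the header),
#'   `"csv"` or `"tsv"`.
#' @inheritParams measurement_dataset
#' @return a `measurement_dataset`.
#' @seealso [write_measurements()]
#' @export
read_measurements <- function(path, dialect = c("auto", "csv", "tsv"),
                              ploidy_2n = NULL, tl_tolerance = 0.05,
                              arm_order = c("swap", "strict")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_domain("file not found: ", path)
  if (dialect == "auto") {
    header <- readLines(path, n = 1L)
    dialect <- if (grepl("\t", header)) "tsv" else "csv"
  }
  sep <- if (dialect == "tsv") "\t" else ","
  x <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  measurement_dataset(x, ploidy_2n = ploidy_2n, tl_tolerance = tl_tolerance,
                      arm_order = arm_order)
}

#' Write a chromosome measurement table
#'
#' Writes a CSV with deterministic column order and rows ordered by
#' population, specimen and chromosome rank, so that
#' `read_measurements(write_measurements(d))` reproduces `d` exactly.
#'
#' @param dataset a `measurement_dataset`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(dataset, path) {
  stopifnot(inherits(dataset, "measurement_dataset"))
  x <- as.data.frame(dataset)
  x <- x[order(x$population_id, x$specimen_id, x$chromosome_index), ,
         drop = FALSE]
  write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate a measurement dataset against its structural invariants
#'
#' Reports (rather than errors on) every invariant violation: non-positive
#' or inverted arms, TL inconsistent with L + S beyond the tolerance, odd
#' chromosome counts, metaphases disagreeing on 2n, and ranks not sorted by
#' descending TL.  An empty report means the dataset is valid.
#'
#' @param dataset a `measurement_dataset` or plain data.frame with the same
#'   columns.
#' @param tl_tolerance maximum tolerated |TL - (L + S)| in um.
#' @return data.frame with columns `specimen_id`, `population_id`, `rule`,
#'   `detail`; zero rows iff valid.
#' @export
validate_dataset <- function(dataset, tl_tolerance = 0.05) {
  x <- as.data.frame(dataset)
  viol <- list()
  add <- function(spec, pop, rule, detail)
    viol[[length(viol) + 1L]] <<- data.frame(
      specimen_id = spec, population_id = pop, rule = rule, detail = detail,
      stringsAsFactors = FALSE)
  if (!nrow(x)) return(violation_frame())

  bad_arm <- which(x$short_arm_um <= 0 | x$long_arm_um < x$short_arm_um)
  for (i in bad_arm)
    add(x$specimen_id[i], x$population_id[i], "arm_order",
        sprintf("row %d: L=%.3f S=%.3f", i, x$long_arm_um[i],
                x$short_arm_um[i]))
  dev <- abs(x$total_length_um - (x$long_arm_um + x$short_arm_um))
  for (i in which(dev > tl_tolerance))
    add(x$specimen_id[i], x$population_id[i], "tl_mismatch",
        sprintf("row %d: |TL-(L+S)| = %.3f > %.3f", i, dev[i], tl_tolerance))

  sp <- split(seq_len(nrow(x)), list(x$population_id, x$specimen_id),
              drop = TRUE)
  n2 <- attr(dataset, "ploidy_2n") %||% max(lengths(sp))
  for (nm in names(sp)) {
    idx <- sp[[nm]]
    spec <- x$specimen_id[idx[1]]; pop <- x$population_id[idx[1]]
    if (length(idx) %% 2L != 0L)
      add(spec, pop, "odd_count",
          sprintf("%d chromosomes in metaphase", length(idx)))
    else if (length(idx) != n2)
      add(spec, pop, "ploidy_mismatch",
          sprintf("%d chromosomes, expected 2n = %d", length(idx), n2))
    tl <- x$total_length_um[idx][order(x$chromosome_index[idx])]
    if (is.unsorted(rev(tl), strictly = FALSE))
      add(spec, pop, "unsorted", "TL not non-increasing with rank")
  }
  if (length(viol)) do.call(rbind, viol) else violation_frame()
}

violation_frame <- function() {
  data.frame(specimen_id = character(), population_id = character(),
             rule = character(), detail = character(),
             stringsAsFactors = FALSE)
}

#' @export
print.measurement_dataset <- function(x, ...) {
  cat(sprintf("<measurement_dataset> %d chromosomes, %d metaphases, 2n = %d\n",
              nrow(x),
              if (nrow(x)) length(unique(paste(x$population_id,
                                               x$specimen_id))) else 0L,
              attr(x, "ploidy_2n")))
  NextMethod()
}

#' Expand the packaged karyomorphometric summary table to a dataset
#'
#' Builds a one-metaphase-per-population [measurement_dataset()] from a
#' homologue-level summary table (mean TL per ranked homologue), assigning
#' perfectly metacentric arms (L = S = TL/2).  Used to exercise the
#' measurement pipeline on the packaged population summary fixture.
#'
#' @param params list of population parameter sets as returned by
#'   [table1_params()].
#' @return a `measurement_dataset` with one synthetic metaphase per
#'   population whose chromosome lengths equal the summary means.
#' @export
summary_to_dataset <- function(params) {
  rows <- lapply(params, function(p) {
    tl <- p$mean_tl_um
    data.frame(population_id = p$population_id,
               colony_id = p$population_id,
               specimen_id = paste0(p$population_id, "_mean"),
               long_arm_um = tl / 2, short_arm_um = tl / 2,
               total_length_um = tl, stringsAsFactors = FALSE)
  })
  measurement_dataset(do.call(rbind, rows))
}
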